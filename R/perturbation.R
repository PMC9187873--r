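#' Plate-wise average control composition
#'
#' Per plate, the arithmetic mean of the control samples' fraction rows,
#' renormalised to sum 1.
#'
#' @param compositions a [composition_table()] covering the screen.
#' @param meta a [sample_meta()] table.
#' @return plates x subpops matrix of control means.
#' @export
average_plate_controls <- function(compositions, meta) {
  fr <- compositions$fractions
  ctl <- meta[meta$is_control, , drop = FALSE]
  plates <- unique(meta$plate[!meta$is_control & !is.na(meta$plate)])
  missing <- setdiff(plates, unique(ctl$plate))
  .assert(length(missing) == 0L,
          "average_plate_controls: plate(s) without controls: %s",
          paste(missing, collapse = ", "))
  all_plates <- unique(stats::na.omit(meta$plate))
  out <- t(vapply(all_plates, function(pl) {
    ids <- intersect(ctl$sample_id[ctl$plate == pl], rownames(fr))
    .assert(length(ids) > 0,
            "average_plate_controls: no deconvolved controls for plate %s", pl)
    m <- colMeans(fr[ids, , drop = FALSE])
    m / sum(m)
  }, numeric(ncol(fr))))
  rownames(out) <- all_plates
  out
}

#' Per-subpopulation drug susceptibility
#'
#' For subpopulation k with treated replicate compositions `TC_j` and
#' plate-matched control mean `CC`:
#' `S_k = 100 / |P| * sum_j (TC_jk - CC_k) / (TC_jk + CC_k)`,
#' a replicate-averaged normalised difference bounded in `[-100, 100]`
#' percent.  A 0/0 term (subpopulation absent from both treated and
#' control) contributes 0, the limit along `TC = CC -> 0`.
#'
#' @param treated replicates x subpops matrix (or a single row vector) of
#'   treated compositions `TC_j`.
#' @param control_mean control mean composition `CC` (vector).
#' @return susceptibility per subpopulation, in percent.
#' @export
susceptibility <- function(treated, control_mean) {
  if (is.null(dim(treated))) treated <- matrix(treated, nrow = 1)
  treated <- as.matrix(treated)
  control_mean <- as.vector(control_mean)
  .assert(ncol(treated) == length(control_mean),
          "susceptibility: dimension mismatch")
  .assert(min(treated) >= 0 && min(control_mean) >= 0,
          "susceptibility: negative fractions")
  cc <- matrix(control_mean, nrow(treated), ncol(treated), byrow = TRUE)
  num <- treated - cc
  den <- treated + cc
  term <- ifelse(den == 0, 0, num / den)
  s <- 100 * colMeans(term)
  names(s) <- colnames(treated)
  s
}

#' Treatment consistency
#'
#' For a perturbagen-concentration-time condition, the median
#' susceptibility of the same drug over all strictly higher doses (same
#' time point unless `across_time`); `NA` when no higher dose exists.
#'
#' @param pct data.frame (`pert_id`, `dose_um`, `time_h`), one row per
#'   condition.
#' @param susc conditions x subpops susceptibility matrix (percent),
#'   aligned to `pct` rows.
#' @param across_time pool doses across time points.
#' @return conditions x subpops matrix of consistency values (percent,
#'   `NA` where undefined).
#' @export
consistency <- function(pct, susc, across_time = FALSE) {
  susc <- as.matrix(susc)
  out <- matrix(NA_real_, nrow(pct), ncol(susc),
                dimnames = list(NULL, colnames(susc)))
  for (i in seq_len(nrow(pct))) {
    higher <- pct$pert_id == pct$pert_id[i] & pct$dose_um > pct$dose_um[i]
    if (!across_time) higher <- higher & pct$time_h == pct$time_h[i]
    if (any(higher)) {
      out[i, ] <- apply(susc[higher, , drop = FALSE], 2L, stats::median)
    }
  }
  out
}

#' Classify killed subpopulations
#'
#' A subpopulation counts as killed by a condition when its susceptibility
#' is strictly below the threshold (default -90 percent).
#'
#' @param susc susceptibility values (percent), any shape.
#' @param threshold kill threshold.
#' @return logical of the same shape.
#' @export
classify_killed <- function(susc, threshold = -90) {
  out <- susc < threshold
  out[is.na(susc)] <- FALSE
  out
}

#' Shannon entropy of a composition
#'
#' `-sum f_k log2 f_k` with `0 log 0 = 0`; the intraclonal-heterogeneity
#' summary of a fraction row.
#'
#' @param fractions simplex vector, or matrix of simplex rows.
#' @return entropy in bits (one value per row).
#' @export
shannon_entropy <- function(fractions) {
  one <- function(f) {
    f <- f[f > 0]
    -sum(f * log2(f))
  }
  if (is.null(dim(fractions))) one(fractions) else apply(fractions, 1L, one)
}

#' Build the full susceptibility table of a screen
#'
#' Composes [average_plate_controls()], [susceptibility()],
#' [consistency()] and [classify_killed()] over every
#' perturbagen-concentration-time condition with at least
#' `min_replicates` deconvolved replicates.
#'
#' @param compositions a [composition_table()] of all screen samples.
#' @param meta a [sample_meta()] table.
#' @param kill_threshold percent threshold for the killed flag.
#' @param min_replicates minimum replicates per condition (default 3).
#' @param across_time pool consistency across time points.
#' @return object of class `susceptibility_table`: `pct` (data.frame with
#'   `pert_id`, `dose_um`, `time_h`, `n_reps`, `plates`),
#'   `susceptibility`, `consistency`, `killed` (each conditions x
#'   subpops).
#' @export
build_susceptibility_table <- function(compositions, meta, kill_threshold = -90,
                                       min_replicates = 3, across_time = FALSE) {
  fr <- compositions$fractions
  missing <- setdiff(meta$sample_id, rownames(fr))
  .assert(length(missing) == 0L,
          "build_susceptibility_table: samples without compositions: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  cc <- average_plate_controls(compositions, meta)
  treated <- meta[!meta$is_control, , drop = FALSE]
  conds <- unique(treated[, c("pert_id", "dose_um", "time_h")])
  conds <- conds[order(conds$pert_id, conds$dose_um, conds$time_h), , drop = FALSE]
  rows <- list(); smat <- list()
  for (i in seq_len(nrow(conds))) {
    sel <- treated$pert_id == conds$pert_id[i] &
      treated$dose_um == conds$dose_um[i] & treated$time_h == conds$time_h[i]
    reps <- treated[sel, , drop = FALSE]
    if (nrow(reps) < min_replicates) next
    plates <- unique(reps$plate)
    # per-replicate terms use that replicate's own plate control mean
    tc <- fr[reps$sample_id, , drop = FALSE]
    terms <- vapply(seq_len(nrow(reps)), function(j)
      susceptibility(tc[j, , drop = FALSE], cc[reps$plate[j], ]),
      numeric(ncol(fr)))
    s <- rowMeans(terms)
    rows[[length(rows) + 1L]] <- data.frame(
      pert_id = conds$pert_id[i], dose_um = conds$dose_um[i],
      time_h = conds$time_h[i], n_reps = nrow(reps),
      plates = paste(plates, collapse = ";"), stringsAsFactors = FALSE)
    smat[[length(smat) + 1L]] <- s
  }
  .assert(length(rows) > 0,
          "build_susceptibility_table: no condition has >= %d replicates",
          min_replicates)
  pct <- do.call(rbind, rows)
  rownames(pct) <- NULL
  susc <- do.call(rbind, smat)
  colnames(susc) <- colnames(fr)
  cons <- consistency(pct, susc, across_time = across_time)
  structure(list(pct = pct, susceptibility = susc, consistency = cons,
                 killed = classify_killed(susc, kill_threshold),
                 kill_threshold = kill_threshold),
            class = "susceptibility_table")
}

#' @export
print.susceptibility_table <- function(x, ...) {
  cat(sprintf("<susceptibility_table> %d conditions x %d subpopulations (kill < %g%%)\n",
              nrow(x$pct), ncol(x$susceptibility), x$kill_threshold))
  invisible(x)
}
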