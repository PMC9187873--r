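#' Ground truth for synthetic subpopulation fixtures
#'
#' Draws a complete generative model: non-negative mean expression profiles
#' per subpopulation with disjoint up-regulated marker sets, gene-wise
#' multiplicative batch factors, a gene-wise platform-shift vector
#' (single-cell to bulk), and an empty kill-rate table to be filled by
#' [make_kill_rates()] or by hand.  Everything downstream of this object is
#' a pure function of `(parameters, seed)`.
#'
#' The defaults emulate what the framework assumes about real data: a
#' log-normal baseline of expression magnitudes, a handful of
#' subpopulations distinguished by a few dozen strongly up-regulated
#' markers, batch-to-batch multiplicative wobble, and a substantial
#' platform shift between the single-cell and bulk measurement spaces.
#'
#' @param n_genes total genes.
#' @param n_subpops number of subpopulations.
#' @param n_markers_per_subpop markers up-regulated per subpopulation;
#'   `n_markers_per_subpop * n_subpops` must not exceed `n_genes`.
#' @param base_meanlog,base_sdlog log-normal law of baseline expression.
#' @param fold_change multiplicative up-regulation of each subpopulation's
#'   markers.
#' @param batches character vector of batch labels.
#' @param batch_sdlog sd (log scale) of gene-wise multiplicative batch
#'   factors; 0 disables batch structure.
#' @param platform_sdlog sd (log scale) of the gene-wise single-cell to
#'   bulk platform shift.
#' @param seed integer seed.
#' @return object of class `ground_truth`: `profiles` (genes x subpops),
#'   `marker_sets` (list of gene-id vectors), `batch_factors` (genes x
#'   batches), `platform_shift` (gene vector), `kill_rates` (empty
#'   data.frame), `seed`.
#' @export
make_ground_truth <- function(n_genes = 1000, n_subpops = 6,
                              n_markers_per_subpop = 25,
                              base_meanlog = 1, base_sdlog = 1,
                              fold_change = 8,
                              batches = c("b1", "b2"),
                              batch_sdlog = 0.3,
                              platform_sdlog = 0.5,
                              seed = 1) {
  .assert(n_markers_per_subpop * n_subpops <= n_genes,
          "make_ground_truth: %d markers x %d subpops exceeds %d genes",
          n_markers_per_subpop, n_subpops, n_genes)
  set.seed(seed)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  subpop_ids <- paste0("sp", seq_len(n_subpops))
  base <- stats::rlnorm(n_genes, base_meanlog, base_sdlog)
  profiles <- matrix(base, n_genes, n_subpops,
                     dimnames = list(gene_ids, subpop_ids))
  marker_idx <- matrix(sample.int(n_genes, n_markers_per_subpop * n_subpops),
                       ncol = n_subpops)
  marker_sets <- list()
  for (k in seq_len(n_subpops)) {
    profiles[marker_idx[, k], k] <- profiles[marker_idx[, k], k] * fold_change
    marker_sets[[subpop_ids[k]]] <- gene_ids[sort(marker_idx[, k])]
  }
  batch_factors <- sapply(batches, function(b)
    stats::rlnorm(n_genes, 0, batch_sdlog))
  if (length(batches) == 1L) batch_factors <- matrix(batch_factors, ncol = 1L)
  dimnames(batch_factors) <- list(gene_ids, batches)
  platform_shift <- stats::rlnorm(n_genes, 0, platform_sdlog)
  names(platform_shift) <- gene_ids
  structure(list(profiles = profiles, marker_sets = marker_sets,
                 batch_factors = batch_factors,
                 platform_shift = platform_shift,
                 kill_rates = data.frame(pert_id = character(),
                                         dose_um = numeric(),
                                         time_h = numeric(),
                                         subpop = character(),
                                         survival = numeric(),
                                         stringsAsFactors = FALSE),
                 seed = seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d genes, %d subpops, %d batches, %d kill-rate rows\n",
              nrow(x$profiles), ncol(x$profiles), ncol(x$batch_factors),
              nrow(x$kill_rates)))
  invisible(x)
}

#' Fill the kill-rate table of a ground truth
#'
#' For each perturbagen, draws which subpopulations it targets and a
#' per-target potency, then lays survival on a dose ladder via a Hill-type
#' decay so that survival is non-increasing in dose.  Survival 1 means
#' untouched, 0 means complete kill.
#'
#' @param truth a [make_ground_truth()] object.
#' @param perturbagens character vector of perturbagen ids.
#' @param doses_um dose ladder (micromolar), shared by all perturbagens.
#' @param times_h time points (hours).
#' @param targets_per_pert how many subpopulations each perturbagen can kill.
#' @param full_kill_top_dose if TRUE, targeted subpopulations have survival
#'   exactly 0 at the top dose (gives known "killed" ground truth).
#' @param seed integer seed.
#' @return `truth` with `kill_rates` filled (one row per
#'   pert x dose x time x subpop).
#' @export
make_kill_rates <- function(truth, perturbagens = paste0("drug", 1:4),
                            doses_um = c(0.1, 1, 10), times_h = 24,
                            targets_per_pert = 2, full_kill_top_dose = TRUE,
                            seed = truth$seed + 1) {
  set.seed(seed)
  subpops <- colnames(truth$profiles)
  rows <- list()
  for (p in perturbagens) {
    targets <- sample(subpops, min(targets_per_pert, length(subpops)))
    ec50 <- stats::runif(length(subpops), min(doses_um), stats::median(doses_um))
    names(ec50) <- subpops
    for (d in doses_um) for (t in times_h) {
      surv <- rep(1, length(subpops))
      names(surv) <- subpops
      for (s in targets) {
        surv[s] <- 1 / (1 + (d / ec50[s])^2)
        if (full_kill_top_dose && d == max(doses_um)) surv[s] <- 0
      }
      rows[[length(rows) + 1L]] <- data.frame(
        pert_id = p, dose_um = d, time_h = t, subpop = subpops,
        survival = unname(surv), stringsAsFactors = FALSE)
    }
  }
  truth$kill_rates <- do.call(rbind, rows)
  rownames(truth$kill_rates) <- NULL
  truth
}

#' Sample single cells from a ground truth
#'
#' Each cell draws its counts from a multinomial over its subpopulation's
#' batch-scaled profile at a fixed capture depth (so per-cell totals are
#' exactly `capture_depth`), optionally with a shared cell-cycle gene
#' program planted in a random subset of cells.  True subpopulation, batch
#' and cycle labels are recorded in the metadata.
#'
#' @param truth a [make_ground_truth()] object.
#' @param n_cells_per_subpop cells per subpopulation (scalar or vector).
#' @param capture_depth total counts per cell.
#' @param batches batch label per cell, recycled; must name columns of
#'   `truth$batch_factors`.
#' @param cycle_genes optional gene ids forming the cycle program.
#' @param cycle_fold fold applied to `cycle_genes` in cycling cells.
#' @param cycle_fraction fraction of cells cycling.
#' @param seed integer seed.
#' @return a [cell_matrix()] with metadata columns `subpop`, `batch`,
#'   `phase` (`"G2M"` for cycling cells else `"G1"`).
#' @export
sample_cells <- function(truth, n_cells_per_subpop = 200, capture_depth = 5000,
                         batches = colnames(truth$batch_factors),
                         cycle_genes = NULL, cycle_fold = 10,
                         cycle_fraction = 0.3, seed = truth$seed + 2) {
  set.seed(seed)
  subpops <- colnames(truth$profiles)
  n_per <- rep_len(n_cells_per_subpop, length(subpops))
  n_cells <- sum(n_per)
  .assert(all(batches %in% colnames(truth$batch_factors)),
          "sample_cells: unknown batch label(s): %s",
          paste(setdiff(batches, colnames(truth$batch_factors)), collapse = ", "))
  cell_subpop <- rep(subpops, n_per)
  # cycle batches within each subpop so batch is not confounded with subpop
  cell_batch <- unlist(lapply(n_per, function(n) rep_len(batches, n)))
  cycling <- rep(FALSE, n_cells)
  if (!is.null(cycle_genes)) {
    .assert(all(cycle_genes %in% rownames(truth$profiles)),
            "sample_cells: cycle genes absent from truth")
    cycling <- stats::runif(n_cells) < cycle_fraction
  }
  counts <- matrix(0L, nrow(truth$profiles), n_cells)
  for (i in seq_len(n_cells)) {
    p <- truth$profiles[, cell_subpop[i]] * truth$batch_factors[, cell_batch[i]]
    if (cycling[i]) p[cycle_genes] <- p[cycle_genes] * cycle_fold
    counts[, i] <- stats::rmultinom(1L, capture_depth, p / sum(p))
  }
  rownames(counts) <- rownames(truth$profiles)
  colnames(counts) <- sprintf("cell%05d", seq_len(n_cells))
  cell_matrix(counts,
              cell_meta = data.frame(cell_id = colnames(counts),
                                     subpop = cell_subpop,
                                     batch = cell_batch,
                                     phase = ifelse(cycling, "G2M", "G1"),
                                     stringsAsFactors = FALSE))
}

#' Mix bulk samples of known composition from a ground truth
#'
#' Sample `s` has expected value `sum_k f[s,k] * profile[,k]`, gene-wise
#' multiplied by the platform-shift vector when enabled, with optional
#' multiplicative log-normal noise, then scaled to a common depth.
#'
#' @param truth a [make_ground_truth()] object.
#' @param fractions samples x subpops matrix; rows must sum to 1 (within
#'   1e-8) and be non-negative.
#' @param depth target column sum of each bulk sample.
#' @param noise_sd sd (log scale) of multiplicative log-normal noise; 0
#'   disables noise.
#' @param apply_platform_shift multiply by `truth$platform_shift`.
#' @param seed integer seed.
#' @return list: `bulk` (a linear-scale [bulk_matrix()]) and `fractions`
#'   (the input, with dimnames filled).
#' @export
mix_bulk <- function(truth, fractions, depth = 1e6, noise_sd = 0.1,
                     apply_platform_shift = TRUE, seed = truth$seed + 3) {
  set.seed(seed)
  fractions <- as.matrix(fractions)
  .assert(min(fractions) >= 0, "mix_bulk: negative fractions")
  .assert(max(abs(rowSums(fractions) - 1)) <= 1e-8,
          "mix_bulk: fraction rows must sum to 1 within 1e-8")
  if (is.null(colnames(fractions))) colnames(fractions) <- colnames(truth$profiles)
  if (is.null(rownames(fractions)))
    rownames(fractions) <- sprintf("mix%03d", seq_len(nrow(fractions)))
  expected <- truth$profiles %*% t(fractions)          # genes x samples
  if (apply_platform_shift) expected <- expected * truth$platform_shift
  if (noise_sd > 0) {
    expected <- expected * matrix(stats::rlnorm(length(expected), 0, noise_sd),
                                  nrow(expected))
  }
  vals <- sweep(expected, 2L, colSums(expected) / depth, "/")
  list(bulk = bulk_matrix(vals, scale = "linear"),
       fractions = fractions)
}

#' Screen design for a simulated perturbation experiment
#'
#' @param perturbagens perturbagen ids.
#' @param doses_um dose ladder shared by all perturbagens.
#' @param times_h time points.
#' @param replicates replicates per perturbagen-concentration-time
#'   condition (must be >= 1).
#' @param controls_per_plate control wells per plate (must be >= 1).
#' @param conditions_per_plate treated conditions per plate.
#' @return object of class `screen_design` (a list of the above).
#' @export
screen_design <- function(perturbagens = paste0("drug", 1:4),
                          doses_um = c(0.1, 1, 10), times_h = 24,
                          replicates = 3, controls_per_plate = 3,
                          conditions_per_plate = 6) {
  .assert(replicates >= 1, "screen_design: replicates must be >= 1")
  .assert(controls_per_plate >= 1, "screen_design: every plate needs a control")
  structure(list(perturbagens = perturbagens, doses_um = doses_um,
                 times_h = times_h, replicates = replicates,
                 controls_per_plate = controls_per_plate,
                 conditions_per_plate = conditions_per_plate),
            class = "screen_design")
}

#' Simulate a dose-laddered perturbation screen
#'
#' The control composition is the stated baseline; under each
#' perturbagen-concentration-time condition the treated composition is
#' `baseline * survival`, renormalised.  Each replicate (and each plate
#' control) becomes one bulk sample generated by [mix_bulk()].
#'
#' @param truth a [make_ground_truth()] object with `kill_rates` filled.
#' @param design a [screen_design()].
#' @param baseline control composition over subpopulations (default
#'   uniform).
#' @param depth,noise_sd,apply_platform_shift passed to [mix_bulk()].
#' @param seed integer seed.
#' @return list: `bulk` ([bulk_matrix()]), `meta` ([sample_meta()]),
#'   `true_compositions` (samples x subpops, incl. controls),
#'   `true_susceptibility` (PCT x subpops, in percent, computed from the
#'   true compositions).
#' @export
simulate_perturbation_screen <- function(truth, design,
                                         baseline = NULL, depth = 1e6,
                                         noise_sd = 0.1,
                                         apply_platform_shift = TRUE,
                                         seed = truth$seed + 4) {
  subpops <- colnames(truth$profiles)
  if (is.null(baseline)) baseline <- rep(1 / length(subpops), length(subpops))
  baseline <- baseline / sum(baseline)
  names(baseline) <- subpops
  kr <- truth$kill_rates
  conds <- expand.grid(pert_id = design$perturbagens,
                       dose_um = design$doses_um,
                       time_h = design$times_h,
                       stringsAsFactors = FALSE)
  have <- nrow(merge(conds, kr))
  .assert(have == nrow(conds) * length(subpops),
          "simulate_perturbation_screen: missing kill-rate entries for %d design condition(s)",
          nrow(conds) - have / length(subpops))
  conds <- conds[order(conds$pert_id, conds$dose_um, conds$time_h), , drop = FALSE]
  conds$plate <- paste0("plate", 1L +
                          (seq_len(nrow(conds)) - 1L) %/% design$conditions_per_plate)

  frac_rows <- list(); meta_rows <- list()
  for (i in seq_len(nrow(conds))) {
    key <- kr$pert_id == conds$pert_id[i] & kr$dose_um == conds$dose_um[i] &
      kr$time_h == conds$time_h[i]
    surv <- kr$survival[key][match(subpops, kr$subpop[key])]
    comp <- baseline * surv
    .assert(sum(comp) > 0, "simulate_perturbation_screen: all subpops killed; composition undefined")
    comp <- comp / sum(comp)
    for (r in seq_len(design$replicates)) {
      sid <- sprintf("%s_%g_%g_r%d", conds$pert_id[i], conds$dose_um[i],
                     conds$time_h[i], r)
      frac_rows[[sid]] <- comp
      meta_rows[[sid]] <- data.frame(sample_id = sid,
                                     pert_id = conds$pert_id[i],
                                     dose_um = conds$dose_um[i],
                                     time_h = conds$time_h[i],
                                     plate = conds$plate[i],
                                     is_control = FALSE,
                                     stringsAsFactors = FALSE)
    }
  }
  for (pl in unique(conds$plate)) {
    for (r in seq_len(design$controls_per_plate)) {
      sid <- sprintf("ctl_%s_r%d", pl, r)
      frac_rows[[sid]] <- baseline
      meta_rows[[sid]] <- data.frame(sample_id = sid, pert_id = NA_character_,
                                     dose_um = NA_real_, time_h = NA_real_,
                                     plate = pl, is_control = TRUE,
                                     stringsAsFactors = FALSE)
    }
  }
  fractions <- do.call(rbind, frac_rows)
  colnames(fractions) <- subpops
  mixed <- mix_bulk(truth, fractions, depth = depth, noise_sd = noise_sd,
                    apply_platform_shift = apply_platform_shift, seed = seed)
  meta <- sample_meta(do.call(rbind, meta_rows))

  # true susceptibility from the noise-free compositions
  true_s <- matrix(NA_real_, nrow(conds), length(subpops),
                   dimnames = list(NULL, subpops))
  for (i in seq_len(nrow(conds))) {
    sel <- !meta$is_control & meta$pert_id == conds$pert_id[i] &
      meta$dose_um == conds$dose_um[i] & meta$time_h == conds$time_h[i]
    tc <- fractions[meta$sample_id[sel], , drop = FALSE]
    true_s[i, ] <- susceptibility(tc, baseline)
  }
  list(bulk = mixed$bulk, meta = meta, true_compositions = fractions,
       true_susceptibility = cbind(conds[, c("pert_id", "dose_um", "time_h")],
                                   as.data.frame(true_s)))
}
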