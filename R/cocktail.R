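#' Greedy minimal drug-cocktail search
#'
#' Iteratively selects the perturbagen-concentration-time condition that
#' kills the greatest number of remaining subpopulations, where a
#' subpopulation counts as killable by a condition when its
#' susceptibility is strictly below `kill_threshold` (default -90%) and
#' its consistency passes `consistency_threshold` (inclusive, default
#' -80%).  Ties are broken by lowest concentration, then shortest time,
#' then lexicographic perturbagen id.  The selected condition's killed
#' subpopulations and every condition of the selected perturbagen are
#' removed; the loop stops when no condition kills any remaining
#' subpopulation.
#'
#' An undefined consistency (no higher dose exists) passes by default,
#' with the condition's own susceptibility as surrogate; set
#' `strict_consistency = TRUE` to make undefined consistency fail.
#'
#' @param table a `susceptibility_table` (see
#'   [build_susceptibility_table()]).
#' @param kill_threshold susceptibility below which a subpopulation is
#'   killed (strict).
#' @param consistency_threshold consistency at or below which a kill is
#'   trusted (inclusive).
#' @param strict_consistency treat undefined consistency as failing.
#' @return object of class `cocktail`: `selections` (data.frame: `step`,
#'   `pert_id`, `dose_um`, `time_h`, `kills` (";"-joined subpop ids),
#'   `n_kills`) and `residual` (subpop ids never killed by any eligible
#'   condition).
#' @export
greedy_cocktail <- function(table, kill_threshold = -90,
                            consistency_threshold = -80,
                            strict_consistency = FALSE) {
  subpops <- colnames(table$susceptibility)
  empty <- function(residual) {
    structure(list(selections = data.frame(step = integer(),
                                           pert_id = character(),
                                           dose_um = numeric(),
                                           time_h = numeric(),
                                           kills = character(),
                                           n_kills = integer(),
                                           stringsAsFactors = FALSE),
                   residual = residual),
              class = "cocktail")
  }
  if (is.null(table$pct) || nrow(table$pct) == 0L) return(empty(subpops))

  pct <- table$pct
  susc <- table$susceptibility
  cons <- table$consistency
  # eligibility per (condition, subpop): killed by susceptibility AND
  # consistency passes (undefined = surrogate by own susceptibility)
  cons_eff <- cons
  if (!strict_consistency) {
    cons_eff[is.na(cons)] <- susc[is.na(cons)]
  }
  eligible <- (susc < kill_threshold) & !is.na(cons_eff) &
    (cons_eff <= consistency_threshold)

  remaining <- subpops
  active <- rep(TRUE, nrow(pct))
  sel <- list()
  step <- 0L
  while (length(remaining) > 0L && any(active)) {
    kills_n <- vapply(seq_len(nrow(pct)), function(i) {
      if (!active[i]) return(0L)
      sum(eligible[i, remaining, drop = FALSE])
    }, integer(1))
    if (max(kills_n) == 0L) break
    cand <- which(kills_n == max(kills_n))
    ord <- order(pct$dose_um[cand], pct$time_h[cand], pct$pert_id[cand])
    pick <- cand[ord[1L]]
    killed_now <- remaining[eligible[pick, remaining]]
    step <- step + 1L
    sel[[step]] <- data.frame(step = step,
                              pert_id = pct$pert_id[pick],
                              dose_um = pct$dose_um[pick],
                              time_h = pct$time_h[pick],
                              kills = paste(killed_now, collapse = ";"),
                              n_kills = length(killed_now),
                              stringsAsFactors = FALSE)
    remaining <- setdiff(remaining, killed_now)
    active <- active & pct$pert_id != pct$pert_id[pick]
  }
  if (step == 0L) return(empty(subpops))
  structure(list(selections = do.call(rbind, sel), residual = remaining),
            class = "cocktail")
}

#' @export
print.cocktail <- function(x, ...) {
  if (nrow(x$selections) == 0L) {
    cat("<cocktail> empty\n")
  } else {
    cat(sprintf("<cocktail> %d selection(s):\n", nrow(x$selections)))
    for (i in seq_len(nrow(x$selections))) {
      s <- x$selections[i, ]
      cat(sprintf("  %d. %s %g uM %g h -> kills %s\n", s$step, s$pert_id,
                  s$dose_um, s$time_h, s$kills))
    }
  }
  if (length(x$residual)) {
    cat("  surviving subpopulation(s):", paste(x$residual, collapse = ", "), "\n")
  }
  invisible(x)
}
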