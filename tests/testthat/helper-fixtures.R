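# Shared fixtures (memoised per test session) and independent oracles.

.fx <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

# small fixture for unit tests: 6 subpops x 50 cells
fx_truth <- function() memo("truth", {
  make_kill_rates(make_ground_truth(seed = 1),
                  perturbagens = paste0("drug", 1:4),
                  doses_um = c(1, 10), times_h = 24)
})

fx_cells_small <- function() memo("cells_small", {
  sample_cells(fx_truth(), n_cells_per_subpop = 50, seed = 3)
})

# the packaged 2,000-cell fixture used by the acceptance suite
fx_cells_big <- function() memo("cells_big", {
  sample_cells(fx_truth(), n_cells_per_subpop = 333, seed = 3)
})

fx_sig_big <- function() memo("sig_big", {
  cells <- fx_cells_big()
  lab <- cells$cell_meta$subpop
  de <- wilcoxon_de(cells, lab, alpha = 0.01)
  build_signature(cells, lab, de)
})

fx_screen <- function() memo("screen", {
  des <- screen_design(perturbagens = paste0("drug", 1:4),
                       doses_um = c(1, 10), times_h = 24)
  simulate_perturbation_screen(fx_truth(), des, seed = 11)
})

fx_mixtures20 <- function() memo("mixtures20", {
  set.seed(42)
  f <- matrix(rgamma(20 * 6, 1), 20)
  f <- f / rowSums(f)
  mix_bulk(fx_truth(), f, noise_sd = 0.1, apply_platform_shift = TRUE, seed = 7)
})

# -- independent oracles ----------------------------------------------------

# susceptibility by plain scalar loops
oracle_susceptibility <- function(tc, cc) {
  tc <- as.matrix(tc)
  out <- numeric(ncol(tc))
  for (k in seq_len(ncol(tc))) {
    acc <- 0
    for (j in seq_len(nrow(tc))) {
      num <- tc[j, k] - cc[k]
      den <- tc[j, k] + cc[k]
      acc <- acc + if (den == 0) 0 else num / den
    }
    out[k] <- 100 * acc / nrow(tc)
  }
  out
}

# NNLS by exhaustive support enumeration + KKT check (small systems only)
oracle_nnls <- function(A, b) {
  k <- ncol(A)
  best <- NULL
  for (size in 0:k) {
    for (supp in if (size == 0) list(integer(0)) else
         asplit(utils::combn(k, size), 2)) {
      supp <- as.integer(supp)
      x <- numeric(k)
      if (length(supp)) {
        sol <- tryCatch(qr.solve(A[, supp, drop = FALSE], b),
                        error = function(e) NULL)
        if (is.null(sol) || any(sol < -1e-10)) next
        x[supp] <- pmax(sol, 0)
      }
      grad <- crossprod(A, A %*% x - b)
      if (all(grad >= -1e-7)) {
        rss <- sum((A %*% x - b)^2)
        if (is.null(best) || rss < best$rss - 1e-12) best <- list(x = x, rss = rss)
      }
    }
  }
  best$x
}

# greedy cocktail re-implemented independently (data.frame filtering style)
oracle_greedy <- function(pct, susc, cons, kill_threshold = -90,
                          consistency_threshold = -80,
                          strict_consistency = FALSE) {
  subpops <- colnames(susc)
  df <- cbind(pct, as.data.frame(susc))
  remaining <- subpops
  banned_perts <- character(0)
  picks <- list()
  repeat {
    counts <- integer(nrow(df))
    killmat <- matrix(FALSE, nrow(df), length(subpops),
                      dimnames = list(NULL, subpops))
    for (i in seq_len(nrow(df))) {
      if (df$pert_id[i] %in% banned_perts) next
      for (s in remaining) {
        ok_kill <- susc[i, s] < kill_threshold
        cv <- cons[i, s]
        ok_cons <- if (is.na(cv)) {
          if (strict_consistency) FALSE else susc[i, s] <= consistency_threshold
        } else cv <= consistency_threshold
        if (ok_kill && ok_cons) {
          counts[i] <- counts[i] + 1L
          killmat[i, s] <- TRUE
        }
      }
    }
    if (max(counts) == 0L) break
    cand <- which(counts == max(counts))
    cand <- cand[order(df$dose_um[cand], df$time_h[cand], df$pert_id[cand])]
    pick <- cand[1L]
    killed <- subpops[killmat[pick, ]]
    picks[[length(picks) + 1L]] <- list(pert_id = df$pert_id[pick],
                                        dose_um = df$dose_um[pick],
                                        time_h = df$time_h[pick],
                                        kills = sort(killed))
    remaining <- setdiff(remaining, killed)
    banned_perts <- c(banned_perts, df$pert_id[pick])
  }
  list(picks = picks, residual = remaining)
}

# random susceptibility table for cocktail property tests
random_susc_table <- function(n_subpops, n_pct, seed) {
  set.seed(seed)
  perts <- paste0("p", sample(1:max(2, n_pct %/% 2), n_pct, replace = TRUE))
  pct <- data.frame(pert_id = perts,
                    dose_um = sample(c(0.1, 0.3, 1, 3, 10), n_pct, replace = TRUE),
                    time_h = sample(c(6, 24), n_pct, replace = TRUE),
                    stringsAsFactors = FALSE)
  pct <- unique(pct)
  susc <- matrix(runif(nrow(pct) * n_subpops, -100, 20), nrow(pct),
                 dimnames = list(NULL, paste0("sp", seq_len(n_subpops))))
  cons <- consistency(pct, susc)
  structure(list(pct = pct, susceptibility = susc, consistency = cons,
                 killed = classify_killed(susc), kill_threshold = -90),
            class = "susceptibility_table")
}
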