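#' Composition table
#'
#' Samples x subpopulations fraction estimates (rows on the simplex) plus
#' per-sample fit diagnostics.
#'
#' @param fractions samples x subpops matrix; rows must sum to 1 within
#'   1e-8 with entries in `[0, 1]`.
#' @param diagnostics optional data.frame (`sample_id`, `rmse`, `r`,
#'   `p_value`, `nu`).
#' @return object of class `composition_table`.
#' @export
composition_table <- function(fractions, diagnostics = NULL) {
  fractions <- as.matrix(fractions)
  .assert(min(fractions) >= -1e-12 && max(fractions) <= 1 + 1e-12,
          "composition_table: fractions outside [0, 1]")
  .assert(max(abs(rowSums(fractions) - 1)) <= 1e-8,
          "composition_table: rows must sum to 1 within 1e-8")
  fractions[fractions < 0] <- 0
  structure(list(fractions = fractions, diagnostics = diagnostics),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("<composition_table> %d samples x %d subpopulations\n",
              nrow(x$fractions), ncol(x$fractions)))
  invisible(x)
}

#' Non-negative least squares
#'
#' Solves `min ||A x - b||` subject to `x >= 0` (Lawson-Hanson active
#' set, via \pkg{pracma}).
#'
#' @param A design matrix.
#' @param b response vector.
#' @return non-negative coefficient vector.
#' @export
nnls_fit <- function(A, b) {
  as.vector(pracma::lsqnonneg(as.matrix(A), as.vector(b))$x)
}

#' Artificial mixtures of labeled single cells
#'
#' Draws, per mixture, a composition from the flat simplex (symmetric
#' Dirichlet, concentration 1), samples cells with replacement with those
#' subpopulation probabilities, sums their CPM profiles and renormalises
#' to CPM.  Used by S-mode to expose the platform difference between the
#' single-cell space and real bulk.
#'
#' @param cells a [cell_matrix()].
#' @param labels subpopulation label per cell.
#' @param n_mixtures number of artificial samples.
#' @param cells_per_mixture cells drawn per mixture.
#' @param seed integer seed.
#' @return list: `bulk` (CPM-scale [bulk_matrix()]) and `fractions`
#'   (mixtures x subpops, the known compositions).
#' @export
make_artificial_mixtures <- function(cells, labels, n_mixtures = 150,
                                     cells_per_mixture = 1000, seed = 1) {
  labels <- as.character(labels)
  subpops <- sort(unique(labels))
  .assert(all(table(labels) >= 1), "make_artificial_mixtures: empty subpopulation")
  if (n_mixtures < length(subpops)) {
    .warnf("make_artificial_mixtures: fewer mixtures (%d) than subpops (%d); adjustment may be rank-deficient",
           n_mixtures, length(subpops))
  }
  norm <- if (cells$normalized) cells else cpm_normalize(cells)
  expr <- .as_dense(norm$counts)
  idx_by <- split(seq_along(labels), labels)
  set.seed(seed)
  fractions <- .rdirichlet(n_mixtures, length(subpops))
  colnames(fractions) <- subpops
  rownames(fractions) <- sprintf("art%03d", seq_len(n_mixtures))
  vals <- matrix(0, nrow(expr), n_mixtures,
                 dimnames = list(rownames(expr), rownames(fractions)))
  for (m in seq_len(n_mixtures)) {
    counts_per <- as.vector(stats::rmultinom(1L, cells_per_mixture, fractions[m, ]))
    picked <- unlist(lapply(seq_along(subpops), function(k) {
      if (counts_per[k] == 0) return(integer(0))
      sample(idx_by[[subpops[k]]], counts_per[k], replace = TRUE)
    }))
    vals[, m] <- rowSums(expr[, picked, drop = FALSE])
    # the realised composition is what was actually drawn
    fractions[m, ] <- counts_per / cells_per_mixture
  }
  list(bulk = bulk_matrix(cpm_normalize.default(vals), scale = "linear",
                          normalized = TRUE),
       fractions = fractions)
}

#' S-mode cross-platform signature adjustment
#'
#' Two steps on the gene set shared by the signature, the artificial
#' mixtures and the real bulk, treating the artificial mixtures and the
#' real bulk as two batches: (1) per-gene multiplicative location
#' matching -- each gene of the artificial batch is rescaled by the ratio
#' of real to artificial means, the natural batch map for non-negative
#' expression under a gene-wise multiplicative platform shift
#' (`scale = "locscale"` instead matches mean and standard deviation
#' additively); (2) the adjusted signature is re-derived gene by gene by
#' non-negative least squares from the corrected artificial mixtures and
#' their known fractions.
#'
#' @param signature a [signature_matrix()].
#' @param artificial output of [make_artificial_mixtures()] (or a list
#'   with `bulk` and `fractions`).
#' @param real_bulk a linear-scale [bulk_matrix()].
#' @param scale `"ratio"` (default) or `"locscale"`.
#' @param use_expected use the mixtures' expected expression given their
#'   compositions (`signature %*% t(fractions)`) instead of the sampled
#'   values (default `TRUE`; cell resampling only adds Monte-Carlo noise
#'   to the adjustment, so the expectation is both stabler and exact in
#'   the many-cells limit).
#' @return adjusted [signature_matrix()] on the shared gene set.
#' @export
smode_adjust <- function(signature, artificial, real_bulk,
                         scale = c("ratio", "locscale"),
                         use_expected = TRUE) {
  scale <- match.arg(scale)
  .assert(real_bulk$scale == "linear", "smode_adjust: real bulk must be linear scale")
  genes <- Reduce(intersect, list(signature$gene_ids,
                                  artificial$bulk$gene_ids,
                                  real_bulk$gene_ids))
  .assert(length(genes) >= 10,
          "smode_adjust: only %d shared gene(s); need >= 10", length(genes))
  F <- artificial$fractions
  M <- if (use_expected) {
    signature$values[genes, colnames(F), drop = FALSE] %*% t(F)
  } else {
    artificial$bulk$values[genes, , drop = FALSE]
  }
  Rb <- real_bulk$values[genes, , drop = FALSE]

  # artificial-batch location: expectation under the flat simplex design
  # (equal subpop weights) when using expected mixtures -- the realised
  # mean composition of a finite Dirichlet draw would leak coherent
  # column-scale noise into the per-gene ratios
  mu_a <- if (use_expected) {
    rowMeans(signature$values[genes, , drop = FALSE])
  } else {
    rowMeans(M)
  }
  mu_r <- rowMeans(Rb)
  if (scale == "ratio") {
    M_adj <- M * ifelse(mu_a > 1e-12, mu_r / pmax(mu_a, 1e-12), 1)
  } else {
    sd_a <- apply(M, 1L, stats::sd); sd_r <- apply(Rb, 1L, stats::sd)
    M_adj <- (M - mu_a) * ifelse(sd_a > 1e-12, sd_r / pmax(sd_a, 1e-12), 1) + mu_r
    M_adj[M_adj < 0] <- 0
  }

  k <- ncol(F)
  S_adj <- t(vapply(seq_along(genes), function(g)
    nnls_fit(F, M_adj[g, ]), numeric(k)))
  dimnames(S_adj) <- list(genes, colnames(F))
  keep <- rowSums(S_adj) > 0
  S_adj <- S_adj[keep, , drop = FALSE]
  # keep subpop order of the input signature
  S_adj <- S_adj[, signature$subpop_ids, drop = FALSE]
  signature_matrix(S_adj, provenance = c(signature$provenance,
                                         list(smode = TRUE)))
}

# Deconvolve one sample against a signature by linear nu-SVR on the
# row-centred system.  Row-centring removes the large expression baseline
# shared by all subpopulation columns (which otherwise dominates the
# conditioning); because the fractions sum to one the mixing identity
# y - rowMeans(S) = (S - rowMeans(S)) f holds exactly, and the centred
# columns' single null direction (they sum to zero gene-wise) is resolved
# by restoring the mean coefficient (1 - sum(w)) / k afterwards.
# `sample` and `S` must share row order; returns fractions, rmse, r, nu.
.svr_deconvolve_one <- function(S, sample, nu_grid) {
  k <- ncol(S)
  # bring the sample onto the signature's scale (makes the fit invariant
  # to positive rescaling of the input)
  sample <- sample * mean(colSums(S)) / max(sum(sample), 1e-12)
  m <- rowMeans(S)
  Sc <- S - m
  yc <- sample - m
  sd_S <- max(stats::sd(Sc), 1e-12)
  sd_y <- max(stats::sd(yc), 1e-12)
  Sz <- (Sc - mean(Sc)) / sd_S
  y_z <- (yc - mean(yc)) / sd_y
  best <- NULL
  for (nu in nu_grid) {
    fit <- e1071::svm(x = Sz, y = y_z, type = "nu-regression",
                      kernel = "linear", nu = nu, scale = FALSE)
    w <- as.vector(t(fit$coefs) %*% fit$SV)
    recon <- as.vector(Sz %*% w) - fit$rho
    rmse <- sqrt(mean((recon - y_z)^2))
    if (is.null(best) || rmse < best$rmse) {
      best <- list(w = w, rmse = rmse, recon = recon, nu = nu)
    }
  }
  w0 <- best$w * sd_y / sd_S
  w <- pmax(w0 + (1 - sum(w0)) / k, 0)
  if (sum(w) == 0) {
    frac <- rep(1 / k, k)
    attr(frac, "degenerate") <- TRUE
  } else {
    frac <- w / sum(w)
  }
  r <- suppressWarnings(stats::cor(best$recon, y_z))
  list(fractions = frac, rmse = best$rmse, r = if (is.na(r)) 0 else r,
       nu = best$nu)
}

#' Estimate subpopulation fractions by nu-support-vector regression
#'
#' Per sample, over the genes shared with the signature: the sample is
#' rescaled to the signature's overall magnitude, both sides are
#' row-centred by the signature's per-gene mean (exact under the mixing
#' identity because fractions sum to one, and far better conditioned than
#' the raw columns, which share a dominant expression baseline), and a
#' linear nu-SVR of the centred sample on the centred signature columns
#' is fitted for each nu in the grid; the nu minimising the
#' root-mean-square reconstruction error wins.  The centred system's mean
#' coefficient is restored from the sum-to-one constraint, negative
#' coefficients are clamped to zero and the rest normalised to sum 1.
#'
#' @param bulk a linear-scale [bulk_matrix()].
#' @param signature a [signature_matrix()] (S-mode adjusted or not).
#' @param nu_grid candidate nu values (default 0.25, 0.5, 0.75).
#' @param n_perm permutations for the per-sample significance (0 = skip;
#'   see [permutation_significance()]).
#' @param seed seed for the permutation draw.
#' @return a [composition_table()].
#' @export
deconvolve <- function(bulk, signature, nu_grid = c(0.25, 0.5, 0.75),
                       n_perm = 0, seed = 1) {
  .assert(bulk$scale == "linear",
          "deconvolve: bulk is log2-scaled; delog() first")
  genes <- intersect(signature$gene_ids, bulk$gene_ids)
  .assert(length(genes) >= 2, "deconvolve: no usable shared genes")
  if (length(genes) < 0.5 * length(signature$gene_ids)) {
    .warnf("deconvolve: only %d of %d signature genes found in bulk",
           length(genes), length(signature$gene_ids))
  }
  S <- signature$values[genes, , drop = FALSE]
  res <- vector("list", length(bulk$sample_ids))
  for (i in seq_along(bulk$sample_ids)) {
    y <- bulk$values[genes, i]
    fit <- .svr_deconvolve_one(S, y, nu_grid)
    p <- NA_real_
    if (isTRUE(attr(fit$fractions, "degenerate"))) {
      .warnf("deconvolve: all-zero coefficients for sample %s; uniform fractions",
             bulk$sample_ids[i])
      p <- 1
    } else if (n_perm > 0) {
      p <- permutation_significance(y, signature, n_perm = n_perm,
                                    seed = seed + i, nu_grid = nu_grid,
                                    genes = genes)
    }
    res[[i]] <- list(frac = as.vector(fit$fractions), rmse = fit$rmse,
                     r = fit$r, nu = fit$nu, p = p)
  }
  fr <- do.call(rbind, lapply(res, `[[`, "frac"))
  dimnames(fr) <- list(bulk$sample_ids, signature$subpop_ids)
  diag <- data.frame(sample_id = bulk$sample_ids,
                     rmse = vapply(res, `[[`, 0, "rmse"),
                     r = vapply(res, `[[`, 0, "r"),
                     p_value = vapply(res, `[[`, 0, "p"),
                     nu = vapply(res, `[[`, 0, "nu"),
                     stringsAsFactors = FALSE)
  composition_table(fr, diag)
}

#' Permutation significance of a deconvolution fit
#'
#' Builds a null distribution of the reconstruction correlation by
#' shuffling the sample's gene values `n_perm` times and re-fitting;
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @param sample named numeric vector of one bulk sample's linear
#'   expression (names = gene ids), or unnamed when `genes` is given.
#' @param signature a [signature_matrix()].
#' @param n_perm number of permutations (>= 10).
#' @param seed integer seed.
#' @param nu_grid as in [deconvolve()].
#' @param genes optional pre-intersected gene set.
#' @return p-value in `[1/(n_perm+1), 1]`.
#' @export
permutation_significance <- function(sample, signature, n_perm = 500,
                                     seed = 1, nu_grid = c(0.25, 0.5, 0.75),
                                     genes = NULL) {
  .assert(n_perm >= 10, "permutation_significance: n_perm must be >= 10")
  if (is.null(genes)) {
    genes <- intersect(signature$gene_ids, names(sample))
    .assert(length(genes) >= 2, "permutation_significance: no shared genes")
    sample <- sample[genes]
  }
  S <- signature$values[genes, , drop = FALSE]
  obs <- .svr_deconvolve_one(S, sample, nu_grid)$r
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(b) {
    yp <- base::sample(sample)
    .svr_deconvolve_one(S, yp, nu_grid)$r
  }, numeric(1))
  (1 + sum(null >= obs)) / (n_perm + 1)
}
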