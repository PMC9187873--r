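#' Quality-control presets
#'
#' Bounds on mitochondrial content and expressed-gene counts.  Two named
#' presets match common practice for breast-cancer cell lines and PBMCs:
#' `mcf7` removes cells with more than 15% or less than 1% mitochondrial
#' content, or more than 5,000 or fewer than 1,000 expressed genes; `pbmc`
#' uses 10%/1% and 3,500/500.  All bounds are strict: a cell is removed
#' only when strictly outside them.
#'
#' @param name `"mcf7"`, `"pbmc"` or `"custom"`.
#' @param mito_max,mito_min mitochondrial-content bounds (fractions).
#' @param genes_max,genes_min expressed-gene bounds (a gene is "expressed"
#'   in a cell when its count is > 0).
#' @return object of class `qc_preset`.
#' @export
qc_preset <- function(name = c("mcf7", "pbmc", "custom"),
                      mito_max = NULL, mito_min = NULL,
                      genes_max = NULL, genes_min = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    mcf7 = list(mito_max = 0.15, mito_min = 0.01, genes_max = 5000, genes_min = 1000),
    pbmc = list(mito_max = 0.10, mito_min = 0.01, genes_max = 3500, genes_min = 500),
    custom = list(mito_max = 1, mito_min = 0, genes_max = Inf, genes_min = 0))
  p <- list(name = name,
            mito_max = mito_max %||% defaults$mito_max,
            mito_min = mito_min %||% defaults$mito_min,
            genes_max = genes_max %||% defaults$genes_max,
            genes_min = genes_min %||% defaults$genes_min)
  .assert(p$mito_min >= 0 && p$mito_min < p$mito_max && p$mito_max <= 1,
          "qc_preset: need 0 <= mito_min < mito_max <= 1")
  .assert(p$genes_min < p$genes_max, "qc_preset: need genes_min < genes_max")
  structure(p, class = "qc_preset")
}

#' Filter low-quality cells
#'
#' Removes cells strictly outside the preset's mitochondrial-content or
#' expressed-gene bounds.  Mitochondrial genes are identified by an id
#' prefix (default `"MT-"`).  Counts must be raw.
#'
#' @param cells a [cell_matrix()] with raw counts.
#' @param preset a [qc_preset()].
#' @param mito_prefix gene-id prefix of mitochondrial genes.
#' @param drop_mito_genes also remove the mitochondrial genes themselves
#'   (useful when merging with a dataset that lacks them).
#' @return filtered [cell_matrix()]; attribute `"qc_report"` records how
#'   many cells each rule removed.
#' @export
qc_filter <- function(cells, preset = qc_preset("mcf7"), mito_prefix = "MT-",
                      drop_mito_genes = FALSE) {
  .assert(!cells$normalized, "qc_filter: counts must be raw")
  counts <- cells$counts
  mito <- startsWith(cells$gene_ids, mito_prefix)
  totals <- Matrix::colSums(counts)
  n_expressed <- Matrix::colSums(counts > 0)
  keep <- rep(TRUE, length(cells$cell_ids))
  report <- c(mito_high = 0L, mito_low = 0L, genes_high = 0L, genes_low = 0L)
  if (any(mito)) {
    frac <- Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(totals, 1)
    hi <- frac > preset$mito_max
    lo <- frac < preset$mito_min
    report["mito_high"] <- sum(hi); report["mito_low"] <- sum(lo & !hi)
    keep <- keep & !hi & !lo
  } else if (preset$mito_max < 1 || preset$mito_min > 0) {
    .warnf("qc_filter: no genes with prefix '%s'; mitochondrial rules skipped",
           mito_prefix)
  }
  hi <- n_expressed > preset$genes_max
  lo <- n_expressed < preset$genes_min
  report["genes_high"] <- sum(hi & keep); report["genes_low"] <- sum(lo & keep & !hi)
  keep <- keep & !hi & !lo
  .assert(any(keep),
          "qc_filter: every cell removed; the preset bounds (preset '%s') do not fit this dataset",
          preset$name)
  out_counts <- counts[if (drop_mito_genes) !mito else TRUE, keep, drop = FALSE]
  out <- cell_matrix(out_counts,
                     cell_meta = cells$cell_meta[keep, , drop = FALSE])
  attr(out, "qc_report") <- report
  out
}

#' Counts-per-million normalisation
#'
#' Scales every column so its sum is one million.  Idempotent and invariant
#' to positive rescaling of the input.
#'
#' @param x a [cell_matrix()], [bulk_matrix()] or plain matrix.
#' @return same type, normalised; the `normalized` flag is set.
#' @export
cpm_normalize <- function(x) {
  UseMethod("cpm_normalize")
}

#' @export
cpm_normalize.default <- function(x) {
  .assert(min(x) >= 0, "cpm_normalize: negative entries")
  cs <- Matrix::colSums(x)
  zero <- which(cs == 0)
  .assert(length(zero) == 0L, "cpm_normalize: all-zero column(s): %s",
          paste(colnames(x)[zero] %||% zero, collapse = ", "))
  if (inherits(x, "Matrix")) {
    x %*% Matrix::Diagonal(ncol(x), 1e6 / cs)
  } else {
    sweep(x, 2L, cs / 1e6, "/")
  }
}

#' @export
cpm_normalize.cell_matrix <- function(x) {
  out <- cpm_normalize.default(x$counts)
  dimnames(out) <- dimnames(x$counts)
  cell_matrix(out, cell_meta = x$cell_meta, normalized = TRUE)
}

#' @export
cpm_normalize.bulk_matrix <- function(x) {
  .assert(x$scale == "linear", "cpm_normalize: matrix is log2-scaled; delog() first")
  bulk_matrix(cpm_normalize.default(x$values), scale = "linear",
              normalized = TRUE)
}

#' Back-transform a log2-scaled bulk matrix
#'
#' Entry-wise `2^x - pseudocount`.  L1000-style level-3 values are log2 of
#' positive expression with no documented pseudocount, so the default
#' pseudocount is 0 (plain `2^x`).  Refuses matrices already flagged
#' linear.
#'
#' @param bulk a [bulk_matrix()] flagged `log2`.
#' @param pseudocount subtracted after exponentiation.
#' @return linear-scale [bulk_matrix()].
#' @export
delog <- function(bulk, pseudocount = 0) {
  .assert(inherits(bulk, "bulk_matrix"), "delog: expected a bulk_matrix")
  .assert(bulk$scale == "log2", "delog: matrix is already linear")
  bulk_matrix(pmax(2^bulk$values - pseudocount, 0), scale = "linear")
}

#' Score and assign cell-cycle phases
#'
#' Per cell, the score of a phase is the mean standardised expression of
#' its marker set minus the mean over a size-matched random background
#' gene set; the label is the argmax phase if its score is positive, else
#' `"G1"`.  Marker lists are user-supplied.
#'
#' @param cells a [cell_matrix()]; scored on CPM log1p values internally.
#' @param s_markers,g2m_markers character vectors of gene ids.
#' @param seed seed for the background draw.
#' @return character vector of labels (`"S"`, `"G2M"`, `"G1"`), named by
#'   cell id, with per-phase scores in attribute `"scores"`.
#' @export
assign_cycle_phase <- function(cells, s_markers, g2m_markers, seed = 1) {
  .assert(length(s_markers) > 0 && length(g2m_markers) > 0,
          "assign_cycle_phase: marker lists must be non-empty")
  norm <- if (cells$normalized) cells else cpm_normalize(cells)
  expr <- log1p(.as_dense(norm$counts))
  mu <- rowMeans(expr)
  sd <- apply(expr, 1L, stats::sd)
  sd[sd == 0] <- 1
  z <- (expr - mu) / sd
  set.seed(seed)
  score_one <- function(markers, phase) {
    present <- intersect(markers, rownames(z))
    if (length(present) < length(markers)) {
      .warnf("assign_cycle_phase: %d %s marker(s) absent; dropped",
             length(markers) - length(present), phase)
    }
    .assert(length(present) > 0, "assign_cycle_phase: no %s markers present", phase)
    pool <- setdiff(rownames(z), present)
    bg <- sample(pool, min(length(present), length(pool)))
    colMeans(z[present, , drop = FALSE]) - colMeans(z[bg, , drop = FALSE])
  }
  s_score <- score_one(s_markers, "S")
  g2m_score <- score_one(g2m_markers, "G2M")
  best <- ifelse(s_score >= g2m_score, "S", "G2M")
  top <- pmax(s_score, g2m_score)
  labels <- ifelse(top > 0, best, "G1")
  names(labels) <- cells$cell_ids
  attr(labels, "scores") <- cbind(S = s_score, G2M = g2m_score)
  labels
}

#' Iterative embedding-space batch correction
#'
#' A soft-clustering batch-correction procedure in the style of iterative
#' mixture-based harmonisation: (1) soft k-means assignment of cells to
#' clusters, with a diversity penalty that down-weights assignments of a
#' cell to clusters already crowded by its own batch (strength `theta`);
#' (2) within each cluster, removal of the batch-specific linear offset
#' (weighted by the soft assignments); iterate on the corrected embedding
#' until the hard cluster assignment stabilises or `max_iter` is reached.
#' Single-batch input is returned unchanged, as is any input when
#' `max_iter = 0`.
#'
#' @param embedding cells x components numeric matrix (row names = cell
#'   ids).
#' @param batch character/factor batch label per cell.
#' @param n_soft_clusters number of soft clusters (>= 2).
#' @param max_iter maximum outer iterations.
#' @param theta diversity-penalty strength; 0 disables batch-aware
#'   weighting (one iteration then reduces to per-cluster centering).
#' @param tol stop when the fraction of cells changing hard cluster falls
#'   below this.
#' @param seed seed for the k-means initialisation.
#' @return corrected embedding, same dimensions and row order.
#' @export
correct_batches <- function(embedding, batch, n_soft_clusters = 10,
                            max_iter = 10, theta = 2, tol = 0.01, seed = 1) {
  embedding <- as.matrix(embedding)
  .assert(all(is.finite(embedding)), "correct_batches: non-finite embedding")
  .assert(length(batch) == nrow(embedding),
          "correct_batches: one batch label per cell required")
  .assert(n_soft_clusters >= 2, "correct_batches: n_soft_clusters must be >= 2")
  batch <- as.character(batch)
  batches <- unique(batch)
  if (length(batches) < 2L || max_iter == 0L) return(embedding)
  n <- nrow(embedding)
  K <- min(n_soft_clusters, n - 1L)
  B <- matrix(0, n, length(batches), dimnames = list(NULL, batches))
  B[cbind(seq_len(n), match(batch, batches))] <- 1
  batch_freq <- colMeans(B)

  set.seed(seed)
  Z <- embedding
  centers <- stats::kmeans(Z, centers = K, nstart = 5, iter.max = 50)$centers
  hard_prev <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(Z^2), rep(1, K)) - 2 * Z %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    sigma2 <- max(mean(apply(d2, 1L, min)), 1e-8)
    R <- exp(-(d2 - apply(d2, 1L, min)) / sigma2)
    if (theta > 0) {
      # diversity weight: (expected batch share / observed)^theta per cluster
      O <- t(B) %*% R + 1e-8                      # batches x K
      E <- outer(batch_freq, colSums(R)) + 1e-8
      W <- (E / O)^theta                          # batches x K
      R <- R * (B %*% W)  # each cell picks its own batch's per-cluster weights
    }
    R <- R / rowSums(R)
    hard <- max.col(R)
    centers <- crossprod(R, Z) / pmax(colSums(R), 1e-8)
    # per-cluster, per-batch offset removal weighted by soft assignment
    corr <- matrix(0, n, ncol(Z))
    for (k in seq_len(K)) {
      w <- R[, k]
      mu_k <- colSums(Z * w) / max(sum(w), 1e-8)
      for (b in batches) {
        in_b <- batch == b
        wb <- w * in_b
        swb <- sum(wb)
        if (swb < 1e-8) next
        mu_bk <- colSums(Z * wb) / swb
        corr[in_b, ] <- corr[in_b, ] +
          outer(w[in_b], mu_bk - mu_k)
      }
    }
    Z <- Z - corr
    changed <- mean(hard != hard_prev)
    hard_prev <- hard
    if (it > 1L && changed < tol) break
  }
  dimnames(Z) <- dimnames(embedding)
  Z
}
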