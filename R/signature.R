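#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact null by enumeration of all rank assignments when both groups have
#' at most 8 observations (ties handled by enumerating over the observed
#' midranks); otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y numeric vectors (the two groups).
#' @return two-sided p-value.
#' @export
rank_sum_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  .assert(n1 >= 1 && n2 >= 1, "rank_sum_test: empty group")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (n1 <= 8 && n2 <= 8) {
    # exact: enumerate all C(n1+n2, n1) subsets of the observed midranks
    combos <- utils::combn(n1 + n2, n1)
    sums <- colSums(matrix(r[combos], nrow = n1))
    eps <- 1e-9
    p_low <- mean(sums <= w + eps)
    p_high <- mean(sums >= w - eps)
    return(min(1, 2 * min(p_low, p_high)))
  }
  n <- n1 + n2
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

# Vectorised one-vs-rest rank-sum z-test over all genes (normal
# approximation with tie correction + continuity); used for the large-n
# path of wilcoxon_de.
.rank_sum_z_all_genes <- function(expr, in_group) {
  n1 <- sum(in_group); n2 <- sum(!in_group); n <- n1 + n2
  ranks <- t(apply(expr, 1L, rank))
  w <- rowSums(ranks[, in_group, drop = FALSE])
  mu <- n1 * (n + 1) / 2
  tie_term <- apply(ranks, 1L, function(r) {
    tt <- table(r)
    sum(tt^3 - tt)
  })
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(pmax(sigma2, 1e-12))
  p <- 2 * stats::pnorm(-abs(z))
  p[sigma2 <= 0] <- 1
  pmin(p, 1)
}

#' One-vs-rest Wilcoxon differential expression
#'
#' For each subpopulation, tests each gene's CPM expression in that
#' subpopulation's cells against all other cells with a two-sided rank-sum
#' test (exact by enumeration when both groups have <= 8 cells, normal
#' approximation with tie and continuity correction otherwise).  Genes
#' with p < `alpha` are the subpopulation's significant set.
#'
#' @param cells a [cell_matrix()] (CPM-normalised internally if raw).
#' @param labels subpopulation label per cell.
#' @param alpha significance cut-off on the raw p-value (default 0.01).
#' @param bh apply Benjamini-Hochberg correction before thresholding
#'   (off by default).
#' @return named list of gene-id vectors per subpopulation; the full
#'   p-value matrix is attached as attribute `"p_values"`.
#' @export
wilcoxon_de <- function(cells, labels, alpha = 0.01, bh = FALSE) {
  .assert(length(labels) == length(cells$cell_ids),
          "wilcoxon_de: one label per cell required")
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  .assert(length(groups) >= 2, "wilcoxon_de: need at least 2 subpopulations")
  sizes <- table(labels)
  singles <- names(sizes)[sizes < 2]
  if (length(singles)) {
    .warnf("wilcoxon_de: subpop(s) %s have a single cell; excluded from testing",
           paste(singles, collapse = ", "))
    groups <- setdiff(groups, singles)
  }
  norm <- if (cells$normalized) cells else cpm_normalize(cells)
  expr <- .as_dense(norm$counts)
  pmat <- matrix(NA_real_, nrow(expr), length(groups),
                 dimnames = list(rownames(expr), groups))
  for (g in groups) {
    in_g <- labels == g
    if (sum(in_g) <= 8 && sum(!in_g) <= 8) {
      pmat[, g] <- apply(expr, 1L, function(v)
        rank_sum_test(v[in_g], v[!in_g]))
    } else {
      pmat[, g] <- .rank_sum_z_all_genes(expr, in_g)
    }
  }
  if (bh) pmat <- apply(pmat, 2L, stats::p.adjust, method = "BH")
  sets <- lapply(groups, function(g) rownames(pmat)[pmat[, g] < alpha])
  names(sets) <- groups
  attr(sets, "p_values") <- pmat
  sets
}

#' Subpopulation signature matrix
#'
#' @param values selected genes x subpopulations matrix of mean CPM
#'   expression (non-negative).
#' @param provenance optional named list (alpha, min_expression, cell
#'   counts) recorded with the object.
#' @return object of class `signature_matrix`.
#' @export
signature_matrix <- function(values, provenance = list()) {
  values <- as.matrix(values)
  .assert(min(values) >= 0, "signature_matrix: negative entries")
  .assert(ncol(values) >= 2, "signature_matrix: need >= 2 subpopulations")
  .assert(all(rowSums(values) > 0), "signature_matrix: all-zero gene row")
  structure(list(values = values, gene_ids = rownames(values),
                 subpop_ids = colnames(values), provenance = provenance),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  kappa <- tryCatch(base::kappa(x$values, exact = TRUE), error = function(e) NA)
  cat(sprintf("<signature_matrix> %d genes x %d subpopulations (condition number %.3g)\n",
              nrow(x$values), ncol(x$values), kappa))
  invisible(x)
}

#' Build the signature matrix from labeled cells
#'
#' Candidate genes are the union of the per-subpopulation significant
#' sets; genes whose mean raw count over all cells is strictly below
#' `min_expression` (default 0.5 counts per cell) are removed; the
#' signature value for gene g and subpopulation k is the mean CPM of g
#' over k's cells.  Warns when the signature's condition number exceeds
#' 1e4.
#'
#' @param cells a [cell_matrix()] with raw counts.
#' @param labels subpopulation label per cell.
#' @param de_gene_sets output of [wilcoxon_de()].
#' @param min_expression minimum mean raw count per cell.
#' @return a [signature_matrix()].
#' @export
build_signature <- function(cells, labels, de_gene_sets, min_expression = 0.5) {
  .assert(!cells$normalized, "build_signature: raw counts required for the expression filter")
  labels <- as.character(labels)
  candidates <- unique(unlist(de_gene_sets))
  mean_raw <- Matrix::rowMeans(cells$counts)
  keep <- candidates[mean_raw[candidates] >= min_expression]
  .assert(length(keep) >= 2,
          "build_signature: only %d gene(s) survive; lower alpha or min_expression",
          length(keep))
  cpm <- cpm_normalize(cells)
  expr <- .as_dense(cpm$counts)[keep, , drop = FALSE]
  groups <- names(de_gene_sets)
  vals <- vapply(groups, function(g)
    rowMeans(expr[, labels == g, drop = FALSE]), numeric(length(keep)))
  vals <- vals[rowSums(vals) > 0, , drop = FALSE]
  sig <- signature_matrix(vals,
                          provenance = list(alpha = attr(de_gene_sets, "alpha") %||% NA,
                                            min_expression = min_expression,
                                            n_cells = as.list(table(labels))))
  kap <- tryCatch(base::kappa(sig$values, exact = TRUE), error = function(e) NA)
  if (is.finite(kap) && kap > 1e4) {
    .warnf("build_signature: condition number %.3g exceeds 1e4", kap)
  }
  sig
}
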