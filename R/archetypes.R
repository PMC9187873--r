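#' PCA embedding of a cell matrix
#'
#' Log1p of CPM values, gene-centred, projected onto the top principal
#' components by singular value decomposition.  Sign convention: within
#' each component the loading of largest magnitude is positive, so the
#' embedding is deterministic.
#'
#' @param cells a [cell_matrix()] (CPM-normalised input recommended; raw
#'   counts are CPM-normalised internally).
#' @param n_components number of components (< number of cells).
#' @param log1p take log1p before centring (default TRUE).
#' @return cells x components matrix with cell ids as row names;
#'   attribute `"explained_variance"` holds the per-component variance.
#' @export
embed_pca <- function(cells, n_components = 15, log1p = TRUE) {
  norm <- if (cells$normalized) cells else cpm_normalize(cells)
  X <- .as_dense(norm$counts)
  if (log1p) X <- log1p(X)
  n <- ncol(X)
  .assert(n_components < n, "embed_pca: n_components must be < number of cells")
  Xc <- X - rowMeans(X)                       # centre each gene
  sv <- svd(t(Xc), nu = n_components, nv = n_components)
  emb <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  # deterministic sign: largest-|loading| positive per component
  for (j in seq_len(n_components)) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) emb[, j] <- -emb[, j]
  }
  rownames(emb) <- cells$cell_ids
  colnames(emb) <- paste0("PC", seq_len(n_components))
  attr(emb, "explained_variance") <- sv$d[seq_len(n_components)]^2 / (n - 1)
  emb
}

# Archetypal analysis at one level k by alternating accelerated
# projected-gradient (FISTA) steps: cells approximated by convex
# combinations of archetypes (A, column-stochastic k x n) and archetypes
# constrained to convex combinations of cells (B, column-stochastic
# n x k).  X is d x n.
.aa_update_A <- function(X, Z, A, inner = 30) {
  ZtZ <- crossprod(Z)
  L <- max(eigen(ZtZ, symmetric = TRUE, only.values = TRUE)$values, 1e-12)
  ZtX <- crossprod(Z, X)
  Y <- A; t_prev <- 1
  for (i in seq_len(inner)) {
    A_new <- .project_simplex_cols(Y - (ZtZ %*% Y - ZtX) / L)
    # gradient-mapping adaptive restart keeps the acceleration monotone
    if (sum((Y - A_new) * (A_new - A)) > 0) {
      Y <- A_new; t_prev <- 1
    } else {
      t_new <- (1 + sqrt(1 + 4 * t_prev^2)) / 2
      Y <- A_new + ((t_prev - 1) / t_new) * (A_new - A)
      t_prev <- t_new
    }
    A <- A_new
  }
  A
}

.aa_update_B <- function(X, A, B, XtX_norm, inner = 30) {
  AAt <- tcrossprod(A)
  L <- XtX_norm * max(eigen(AAt, symmetric = TRUE, only.values = TRUE)$values, 1e-12)
  XAt <- X %*% t(A)
  Y <- B; t_prev <- 1
  for (i in seq_len(inner)) {
    G <- crossprod(X, (X %*% Y) %*% AAt - XAt)          # n x k
    B_new <- .project_simplex_cols(Y - G / L)
    if (sum((Y - B_new) * (B_new - B)) > 0) {
      Y <- B_new; t_prev <- 1
    } else {
      t_new <- (1 + sqrt(1 + 4 * t_prev^2)) / 2
      Y <- B_new + ((t_prev - 1) / t_new) * (B_new - B)
      t_prev <- t_new
    }
    B <- B_new
  }
  B
}

# Furthest-point initialisation: pick k cells spanning the data.
.aa_init <- function(X, k, seed) {
  set.seed(seed)
  n <- ncol(X)
  first <- which.max(colSums((X - rowMeans(X))^2))
  idx <- first
  d2 <- colSums((X - X[, first])^2)
  while (length(idx) < k) {
    nxt <- which.max(d2)
    idx <- c(idx, nxt)
    d2 <- pmin(d2, colSums((X - X[, nxt])^2))
  }
  B <- matrix(0, n, k)
  B[cbind(idx, seq_len(k))] <- 1
  B
}

.aa_fit_one <- function(X, k, tol, max_iter, seed) {
  n <- ncol(X)
  XtX_norm <- max(eigen(tcrossprod(X), symmetric = TRUE,
                        only.values = TRUE)$values, 1e-12)
  B <- .aa_init(X, k, seed)
  Z <- X %*% B
  A <- .aa_update_A(X, Z, .project_simplex_cols(matrix(1 / k, k, n)),
                    inner = 100)
  rss_prev <- Inf
  total <- sum(X^2)
  it <- 0L
  for (it in seq_len(max_iter)) {
    A <- .aa_update_A(X, Z, A)
    B <- .aa_update_B(X, A, B, XtX_norm)
    Z <- X %*% B
    rss <- sum((X - Z %*% A)^2)
    if (is.finite(rss_prev) && abs(rss_prev - rss) <= tol * max(total, 1e-12)) {
      rss_prev <- rss
      break
    }
    rss_prev <- rss
  }
  list(A = A, B = B, Z = Z, rss = rss_prev, k = k, iters = it)
}

#' Multi-level archetypal analysis
#'
#' Fits an archetypal decomposition of the embedding at every depth
#' `k = 2..k_max`, pools the archetypes of all levels, merges archetypes
#' whose embedding-space profiles correlate above `merge_threshold`
#' (keeping, within each merge group, the archetype with the largest total
#' footprint mass), and recomputes the per-cell convex weights
#' ("footprints", the archetypal explicit function) against the merged
#' archetype set.  Footprint columns are non-negative and sum to 1.
#'
#' @param embedding cells x components matrix (e.g. from [embed_pca()],
#'   after [correct_batches()]).
#' @param k_max maximum decomposition depth (default 30).
#' @param merge_threshold correlation above which two archetypes merge.
#' @param tol relative objective-change tolerance per level.
#' @param max_iter outer iterations per level.
#' @param seed integer seed (initialisation).
#' @return object of class `archetype_model`: `archetypes` (components x
#'   n_archetypes), `footprints` (n_archetypes x cells, columns on the
#'   simplex), `confidence` (per-cell max footprint weight), `cell_ids`,
#'   `embedding`, `k_max`, `levels` (archetypes retained per depth),
#'   `subpop` (NULL until [cluster_subpopulations()]).
#' @export
fit_archetypes <- function(embedding, k_max = 30, merge_threshold = 0.95,
                           tol = 1e-6, max_iter = 50, seed = 1) {
  .assert(k_max >= 2, "fit_archetypes: k_max must be >= 2")
  embedding <- as.matrix(embedding)
  X <- t(embedding)                             # d x n
  fits <- lapply(2:k_max, function(k)
    .aa_fit_one(X, k, tol = tol, max_iter = max_iter, seed = seed + k))
  warn <- vapply(fits, function(f) f$iters >= max_iter, logical(1))
  if (any(warn)) {
    .warnf("fit_archetypes: %d level(s) hit max_iter; final objectives: %s",
           sum(warn),
           paste(sprintf("k=%d rss=%.3g", vapply(fits[warn], `[[`, 0, "k"),
                         vapply(fits[warn], `[[`, 0, "rss")), collapse = ", "))
  }
  Z_all <- do.call(cbind, lapply(fits, `[[`, "Z"))
  B_all <- do.call(cbind, lapply(fits, `[[`, "B"))
  mass_all <- unlist(lapply(fits, function(f) rowSums(f$A)))
  level_all <- unlist(lapply(fits, function(f) rep(f$k, f$k)))

  # Merge redundant archetypes pooled across depths.  An archetype's
  # profile is its centred inner-product evaluation over all cells
  # (equivalently, the direction it points to from the data centre in the
  # data's metric): two archetypes representing the same extreme state
  # correlate near 1 regardless of embedding dimension.  Greedy merge by
  # profile correlation, largest footprint mass first; after each merge
  # pass the kept archetypes are re-optimised jointly (alternating
  # updates), and merging repeats until the archetype count is stable.
  centre <- rowMeans(X)
  Xc <- X - centre
  profile_cor <- function(Z) {
    P <- crossprod(Xc, Z - centre)
    suppressWarnings(stats::cor(P))
  }
  merge_pass <- function(Z, mass) {
    cors <- profile_cor(Z)
    cors[is.na(cors)] <- 1
    ord <- order(mass, decreasing = TRUE)
    kept <- integer(0)
    for (j in ord) {
      if (length(kept) && max(cors[j, kept]) > merge_threshold) next
      kept <- c(kept, j)
    }
    sort(kept)
  }
  kept <- merge_pass(Z_all, mass_all)
  Z <- Z_all[, kept, drop = FALSE]
  B <- B_all[, kept, drop = FALSE]
  levels_kept <- level_all[kept]
  XtX_norm <- max(eigen(tcrossprod(X), symmetric = TRUE,
                        only.values = TRUE)$values, 1e-12)
  for (round in 1:3) {
    # polish the merged set to its joint optimum
    A <- .aa_update_A(X, Z, .project_simplex_cols(
      matrix(1 / ncol(Z), ncol(Z), ncol(X))), inner = 100)
    rss_prev <- Inf
    total <- sum(X^2)
    for (it in seq_len(max_iter)) {
      A <- .aa_update_A(X, Z, A)
      B <- .aa_update_B(X, A, B, XtX_norm)
      Z <- X %*% B
      rss <- sum((X - Z %*% A)^2)
      if (is.finite(rss_prev) && abs(rss_prev - rss) <= tol * max(total, 1e-12)) break
      rss_prev <- rss
    }
    kept2 <- merge_pass(Z, rowSums(A))
    if (length(kept2) == ncol(Z)) break
    Z <- Z[, kept2, drop = FALSE]
    B <- B[, kept2, drop = FALSE]
    levels_kept <- levels_kept[kept2]
  }
  colnames(Z) <- paste0("A", seq_len(ncol(Z)))

  # final footprints against the merged archetype set
  k <- ncol(Z)
  A <- .project_simplex_cols(matrix(1 / k, k, ncol(X)))
  A <- .aa_update_A(X, Z, A, inner = 200)
  rownames(A) <- colnames(Z)
  colnames(A) <- rownames(embedding)
  structure(list(archetypes = Z, footprints = A,
                 confidence = apply(A, 2L, max),
                 cell_ids = rownames(embedding),
                 embedding = embedding,
                 k_max = k_max,
                 levels = table(levels_kept),
                 subpop = NULL),
            class = "archetype_model")
}

#' @export
print.archetype_model <- function(x, ...) {
  cat(sprintf("<archetype_model> %d archetypes (k_max=%d), %d cells%s\n",
              ncol(x$archetypes), x$k_max, length(x$cell_ids),
              if (is.null(x$subpop)) "" else
                sprintf(", %d subpopulations", length(unique(x$subpop)))))
  invisible(x)
}

#' Prune cells with ambiguous archetype representation
#'
#' Removes cells whose maximum footprint weight is strictly below the
#' threshold (default 0.6); a cell at exactly the threshold is kept.
#'
#' @param model an `archetype_model`.
#' @param threshold minimum max-footprint weight.
#' @return pruned model.
#' @export
prune_ambiguous_cells <- function(model, threshold = 0.6) {
  keep <- model$confidence >= threshold
  .assert(any(keep),
          "prune_ambiguous_cells: all cells pruned at threshold %.2f; lower it",
          threshold)
  model$footprints <- model$footprints[, keep, drop = FALSE]
  model$confidence <- model$confidence[keep]
  model$cell_ids <- model$cell_ids[keep]
  model$embedding <- model$embedding[keep, , drop = FALSE]
  if (!is.null(model$subpop)) model$subpop <- model$subpop[keep]
  model
}

#' Group cells into subpopulations
#'
#' Builds a k-nearest-neighbour graph on the footprint vectors (Euclidean
#' metric) and detects communities with the Leiden algorithm (modularity
#' objective) at the stated resolution.  Labels are `1..n_subpops`,
#' ordered by decreasing community size.
#'
#' @param model an `archetype_model` (prune first if desired).
#' @param n_neighbors neighbours in the kNN graph.
#' @param resolution Leiden resolution (default 1).
#' @param seed seed for the community detection.
#' @return the model with `$subpop` set (integer labels named by cell id).
#' @export
cluster_subpopulations <- function(model, n_neighbors = 30, resolution = 1,
                                   seed = 1) {
  F <- t(model$footprints)                      # cells x archetypes
  n <- nrow(F)
  .assert(n >= n_neighbors + 1,
          "cluster_subpopulations: need at least n_neighbors + 1 cells")
  d2 <- outer(rowSums(F^2), rep(1, n)) - 2 * tcrossprod(F) +
    outer(rep(1, n), rowSums(F^2))
  diag(d2) <- Inf
  nn <- t(apply(d2, 1L, function(r) order(r)[seq_len(n_neighbors)]))
  edges <- cbind(rep(seq_len(n), n_neighbors), as.vector(nn))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  labels <- unname(relabel[as.character(memb)])
  names(labels) <- model$cell_ids
  model$subpop <- labels
  model
}

#' Characterise subpopulations by their archetypes and marker genes
#'
#' For each subpopulation: the dominant archetype (argmax of the mean
#' footprint weight within the subpopulation, lowest index on ties), the
#' normalised archetype composition, and per-archetype marker genes ranked
#' by one-vs-rest standardised mean expression difference of high-weight
#' cells.
#'
#' @param model a clustered `archetype_model`.
#' @param cells the [cell_matrix()] the model was learned from (any cells
#'   pruned from the model are ignored); CPM-normalised internally.
#' @param top_n markers reported per archetype.
#' @param high_weight_quantile cells above this footprint-weight quantile
#'   count as "high-weight" for an archetype.
#' @return list: `dominant` (archetype id per subpop), `composition`
#'   (subpops x archetypes, rows sum to 1), `markers` (list of gene-id
#'   vectors per archetype), `marker_scores` (z-scores backing `markers`).
#' @export
characterize_subpopulations <- function(model, cells, top_n = 10,
                                        high_weight_quantile = 0.75) {
  .assert(!is.null(model$subpop), "characterize_subpopulations: cluster first")
  F <- model$footprints
  subpops <- sort(unique(model$subpop))
  comp <- t(vapply(subpops, function(s)
    rowMeans(F[, model$subpop == s, drop = FALSE]), numeric(nrow(F))))
  comp <- comp / rowSums(comp)
  rownames(comp) <- paste0("subpop", subpops)
  dominant <- apply(comp, 1L, which.max)        # lowest index wins ties

  norm <- if (cells$normalized) cells else cpm_normalize(cells)
  expr <- log1p(.as_dense(norm$counts))[, model$cell_ids, drop = FALSE]
  markers <- list(); scores <- list()
  small <- subpops[vapply(subpops, function(s) sum(model$subpop == s) < 3, logical(1))]
  if (length(small)) {
    .warnf("characterize_subpopulations: subpop(s) %s have < 3 cells; markers skipped",
           paste(small, collapse = ", "))
  }
  for (a in seq_len(nrow(F))) {
    w <- F[a, ]
    thr <- stats::quantile(w, high_weight_quantile)
    hi <- w >= thr & w > 0
    if (sum(hi) < 3 || sum(!hi) < 3) {
      markers[[rownames(F)[a]]] <- character(0)
      next
    }
    m1 <- rowMeans(expr[, hi, drop = FALSE])
    m0 <- rowMeans(expr[, !hi, drop = FALSE])
    v1 <- apply(expr[, hi, drop = FALSE], 1L, stats::var)
    v0 <- apply(expr[, !hi, drop = FALSE], 1L, stats::var)
    se <- sqrt(v1 / sum(hi) + v0 / sum(!hi))
    z <- (m1 - m0) / pmax(se, 1e-8)
    ord <- order(z, decreasing = TRUE)
    markers[[rownames(F)[a]]] <- rownames(expr)[ord[seq_len(min(top_n, length(ord)))]]
    scores[[rownames(F)[a]]] <- z
  }
  list(dominant = stats::setNames(colnames(comp)[dominant], rownames(comp)),
       composition = comp, markers = markers, marker_scores = scores)
}
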