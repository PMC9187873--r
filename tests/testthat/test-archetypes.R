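test_that("PCA embedding is deterministic with ordered variance", {
  cells <- fx_cells_small()
  e1 <- embed_pca(cells, n_components = 8)
  e2 <- embed_pca(cells, n_components = 8)
  expect_identical(e1, e2)
  ev <- attr(e1, "explained_variance")
  expect_true(all(diff(ev) <= 1e-9))
  expect_error(embed_pca(cells, n_components = ncol(cells$counts)), "<")

  # rank-2 non-negative data: components beyond the second carry nothing
  set.seed(3)
  basis <- matrix(runif(2 * 30), 2, 30)
  scores <- matrix(runif(2 * 100, 1, 5), 100, 2)
  flat <- scores %*% basis
  cm <- cell_matrix(t(flat), gene_ids = paste0("g", 1:30),
                    cell_ids = paste0("c", 1:100), normalized = TRUE)
  e <- embed_pca(cm, n_components = 5, log1p = FALSE)
  ev2 <- attr(e, "explained_variance")
  expect_lt(sum(ev2[3:5]), 1e-12 * sum(ev2))
})

test_that("degenerate three-point geometry yields exact one-hot archetypes", {
  pts <- matrix(c(0, 0, 1, 0, 0, 1), ncol = 2, byrow = TRUE)
  emb <- pts[rep(1:3, each = 50), ]
  rownames(emb) <- paste0("c", 1:150)
  m <- suppressWarnings(fit_archetypes(emb, k_max = 3, seed = 1))
  expect_equal(ncol(m$archetypes), 3L)
  found <- apply(m$archetypes, 2, function(z)
    min(sqrt(colSums((t(pts) - z)^2))))
  expect_true(all(found < 1e-6))
  expect_true(all(abs(m$confidence - 1) < 1e-6))
  # footprint columns live on the simplex
  expect_true(all(m$footprints >= -1e-12))
  expect_equal(unname(colSums(m$footprints)), rep(1, 150), tolerance = 1e-8)
})

test_that("uniform triangle data recovers every vertex", {
  set.seed(7)
  V <- matrix(c(0, 0, 4, 0, 1, 3), ncol = 2, byrow = TRUE)
  w <- matrix(rexp(500 * 3), 500); w <- w / rowSums(w)
  emb <- w %*% V
  rownames(emb) <- paste0("c", 1:500)
  m <- suppressWarnings(fit_archetypes(emb, k_max = 3, seed = 1))
  diam <- max(dist(V))
  vertex_dist <- apply(V, 1, function(v)
    min(sqrt(colSums((m$archetypes - v)^2))))
  expect_lt(mean(vertex_dist), 0.05 * diam)
  expect_true(all(m$footprints >= -1e-12))
  expect_equal(unname(colSums(m$footprints)), rep(1, 500), tolerance = 1e-8)
})

fake_model <- function(footprints, embedding = NULL) {
  structure(list(archetypes = diag(nrow(footprints)),
                 footprints = footprints,
                 confidence = apply(footprints, 2, max),
                 cell_ids = colnames(footprints),
                 embedding = embedding %||%
                   matrix(0, ncol(footprints), 2,
                          dimnames = list(colnames(footprints), NULL)),
                 k_max = 3, levels = NULL, subpop = NULL),
            class = "archetype_model")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("pruning drops strictly-below-threshold cells and keeps the boundary", {
  F <- cbind(c1 = c(0.55, 0.45), c2 = c(1, 0), c3 = c(0.6, 0.4))
  rownames(F) <- c("A1", "A2")
  m <- fake_model(F)
  p <- prune_ambiguous_cells(m, 0.6)
  expect_equal(p$cell_ids, c("c2", "c3"))   # 0.55 pruned, exactly 0.6 kept
  expect_equal(prune_ambiguous_cells(m, 0)$cell_ids, colnames(F))
  expect_error(prune_ambiguous_cells(m, 1.5), "all cells pruned")
})

test_that("community detection separates one-hot blobs and obeys the resolution limit", {
  F <- cbind(matrix(rep(c(1, 0), 40), 2), matrix(rep(c(0, 1), 40), 2))
  colnames(F) <- paste0("c", 1:80); rownames(F) <- c("A1", "A2")
  m <- fake_model(F)
  mc <- cluster_subpopulations(m, n_neighbors = 10, seed = 1)
  expect_equal(length(unique(mc$subpop)), 2L)
  expect_equal(length(unique(mc$subpop[1:40])), 1L)
  expect_equal(length(unique(mc$subpop[41:80])), 1L)
  expect_gte(sum(mc$subpop == 1), sum(mc$subpop == 2))

  # resolution -> 0 collapses a connected cloud into one community
  set.seed(5)
  Fc <- matrix(abs(rnorm(2 * 80)), 2)
  Fc <- sweep(Fc, 2, colSums(Fc), "/")
  colnames(Fc) <- paste0("c", 1:80); rownames(Fc) <- c("A1", "A2")
  low <- cluster_subpopulations(fake_model(Fc), n_neighbors = 10,
                                resolution = 1e-4, seed = 1)
  expect_equal(length(unique(low$subpop)), 1L)
})

test_that("the learn stage recovers the planted subpopulations end-to-end", {
  cells <- fx_cells_small()
  emb <- correct_batches(embed_pca(cells, n_components = 10),
                         cells$cell_meta$batch, seed = 1)
  m <- suppressWarnings(fit_archetypes(emb, k_max = 8, seed = 1))
  m <- cluster_subpopulations(m, n_neighbors = 15, seed = 1)
  m <- prune_ambiguous_cells(m, 0.6)
  truth_lab <- cells$cell_meta$subpop[match(m$cell_ids, cells$cell_ids)]
  expect_gte(mclust::adjustedRandIndex(m$subpop, truth_lab), 0.8)

  # permuting cell order permutes labels identically
  perm <- sample(length(cells$cell_ids))
  cells_p <- cell_matrix(cells$counts[, perm],
                         cell_meta = cells$cell_meta[perm, ])
  emb_p <- emb[cells_p$cell_ids, ]
  m_p <- suppressWarnings(fit_archetypes(emb_p, k_max = 8, seed = 1))
  m_p <- cluster_subpopulations(m_p, n_neighbors = 15, seed = 1)
  m_p <- prune_ambiguous_cells(m_p, 0.6)
  shared <- intersect(m$cell_ids, m_p$cell_ids)
  expect_gt(length(shared), 100)
  expect_gte(mclust::adjustedRandIndex(m$subpop[shared], m_p$subpop[shared]),
             0.95)
})

test_that("characterisation reports dominant archetypes, compositions and markers", {
  cells <- fx_cells_small()
  F <- matrix(0, 3, length(cells$cell_ids),
              dimnames = list(paste0("A", 1:3), cells$cell_ids))
  lab <- cells$cell_meta$subpop
  F[1, lab == "sp1"] <- 1
  F[2, lab == "sp2"] <- 1
  F[3, !(lab %in% c("sp1", "sp2"))] <- 1
  m <- fake_model(F)
  m$subpop <- ifelse(lab == "sp1", 1L, ifelse(lab == "sp2", 2L, 3L))
  names(m$subpop) <- cells$cell_ids
  ch <- characterize_subpopulations(m, cells, top_n = 25)
  expect_equal(unname(ch$dominant["subpop1"]), "A1")
  expect_equal(unname(rowSums(ch$composition)), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(ch$composition["subpop1", "A1"]), 1)
  # planted sp1 markers dominate archetype A1's marker list
  truth <- fx_truth()
  expect_gt(mean(truth$marker_sets$sp1 %in% ch$markers$A1), 0.8)
})
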