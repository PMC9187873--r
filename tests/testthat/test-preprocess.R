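# a hand-built count matrix with controlled mito content / gene counts
toy_cells <- function() {
  genes <- c("MT-1", "MT-2", paste0("g", 1:8))
  counts <- matrix(0L, 10, 4, dimnames = list(genes, paste0("c", 1:4)))
  # c1: 16% mito (removed by mcf7 preset), 8 expressed genes
  counts[, 1] <- c(10, 6, rep(10, 8))
  # c2: 5% mito, healthy
  counts[, 2] <- c(3, 2, rep(12, 8))
  # c3: 0.5% mito (below 1% floor)
  counts[, 3] <- c(1, 0, rep(25, 8))
  # c4: 5% mito but only 2 expressed genes
  counts[, 4] <- c(2, 3, 50, 45, rep(0, 6))
  cell_matrix(counts)
}

test_that("QC filtering applies the preset bounds strictly", {
  cells <- toy_cells()
  kept <- qc_filter(cells, qc_preset("mcf7", genes_min = 5), mito_prefix = "MT-")
  expect_equal(kept$cell_ids, "c2")
  rep <- attr(kept, "qc_report")
  expect_equal(unname(rep["mito_high"]), 1L)
  expect_equal(unname(rep["mito_low"]), 1L)
  expect_equal(unname(rep["genes_low"]), 1L)

  # boundary: a cell with exactly 4,999 expressed genes passes the mcf7 preset
  big <- matrix(1L, 5100, 2)
  big[5000:5100, 1] <- 0L   # cell 1: 4999 expressed genes
  rownames(big) <- paste0("g", 1:5100); colnames(big) <- c("a", "b")
  big[1, 2] <- 1L
  out <- suppressWarnings(qc_filter(cell_matrix(big), qc_preset("mcf7")))
  expect_true("a" %in% out$cell_ids)

  # pbmc preset: 3,600 expressed genes exceeds the 3,500 cap
  m2 <- matrix(1L, 3700, 2, dimnames = list(paste0("g", 1:3700), c("a", "b")))
  m2[3601:3700, 1] <- 0L  # cell a: 3600 expressed
  m2[501:3700, 2] <- 0L   # cell b: 500 expressed -> strict "< 500" keeps it
  out2 <- suppressWarnings(qc_filter(cell_matrix(m2), qc_preset("pbmc")))
  expect_false("a" %in% out2$cell_ids)
  expect_true("b" %in% out2$cell_ids)

  # idempotence
  once <- qc_filter(cells, qc_preset("mcf7", genes_min = 5))
  twice <- qc_filter(once, qc_preset("mcf7", genes_min = 5))
  expect_identical(as.matrix(once$counts), as.matrix(twice$counts))

  nomito <- cell_matrix(matrix(5L, 3, 2, dimnames = list(paste0("g", 1:3),
                                                         c("a", "b"))))
  expect_warning(qc_filter(nomito, qc_preset("mcf7", genes_min = 1)),
                 "mitochondrial")
})

test_that("CPM normalisation conserves, is idempotent and scale-invariant", {
  m <- matrix(c(1, 1, 2), 3, 1, dimnames = list(paste0("g", 1:3), "s"))
  expect_equal(as.vector(cpm_normalize(m)), c(250000, 250000, 500000))

  set.seed(1)
  r <- matrix(rpois(500, 5) + 1, 50, 10,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:10)))
  n1 <- cpm_normalize(r)
  expect_equal(unname(colSums(n1)), rep(1e6, 10), tolerance = 1e-9)
  expect_equal(cpm_normalize(n1), n1, tolerance = 1e-9)
  expect_equal(cpm_normalize(r * 3.7), n1, tolerance = 1e-9)

  bad <- cbind(r[, 1], 0)
  colnames(bad) <- c("ok", "empty"); rownames(bad) <- rownames(r)
  expect_error(cpm_normalize(bad), "empty")
})

test_that("delog inverts log2 scaling and refuses linear input", {
  b <- bulk_matrix(matrix(c(0, 1, 2, 3), 2, 2,
                          dimnames = list(c("g1", "g2"), c("a", "b"))),
                   scale = "log2")
  lin <- delog(b)
  expect_equal(as.vector(lin$values), c(1, 2, 4, 8))
  expect_equal(lin$scale, "linear")
  expect_error(delog(lin), "already linear")

  set.seed(2)
  x <- matrix(rlnorm(20), 4, 5, dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  round_trip <- delog(bulk_matrix(log2(x), scale = "log2"))
  expect_equal(round_trip$values, x, tolerance = 1e-12)
})

test_that("cycle-phase scoring labels planted programs and defaults to G1", {
  genes <- paste0("g", 1:40)
  m <- matrix(5, 40, 3, dimnames = list(genes, c("s_cell", "flat", "zero")))
  m[1:5, 1] <- 80          # S markers strongly up in cell 1
  m[, 3] <- 0
  m[1, 3] <- 1             # avoid the all-zero column for CPM
  cells <- cell_matrix(m)
  lab <- suppressWarnings(assign_cycle_phase(cells, s_markers = genes[1:5],
                                             g2m_markers = genes[6:10], seed = 1))
  expect_equal(unname(lab["s_cell"]), "S")
  expect_equal(unname(lab["flat"]), "G1")

  # planted G2M program at fold 10 in the generator is recovered
  truth <- make_ground_truth(n_genes = 400, n_subpops = 2, batch_sdlog = 0,
                             seed = 4)
  cyc_genes <- rownames(truth$profiles)[301:320]
  cells2 <- sample_cells(truth, n_cells_per_subpop = 100,
                         cycle_genes = cyc_genes, cycle_fold = 10,
                         cycle_fraction = 0.4, seed = 5)
  lab2 <- assign_cycle_phase(cells2, s_markers = cyc_genes[1:10],
                             g2m_markers = cyc_genes[11:20], seed = 1)
  cycling <- cells2$cell_meta$phase == "G2M"
  expect_gt(mean(lab2[cycling] != "G1"), 0.95)
})

test_that("batch correction removes a planted offset and respects identities", {
  truth <- fx_truth()
  cells <- fx_cells_small()
  emb <- embed_pca(cells, n_components = 10)
  batch <- cells$cell_meta$batch

  expect_identical(correct_batches(emb, rep("one", nrow(emb))), emb)
  expect_identical(correct_batches(emb, batch, max_iter = 0), emb)
  expect_error(correct_batches(emb, batch, n_soft_clusters = 1), ">= 2")

  corrected <- correct_batches(emb, batch, seed = 1)
  expect_identical(rownames(corrected), rownames(emb))

  lab <- cells$cell_meta$subpop
  ari_before <- mclust::adjustedRandIndex(
    kmeans(emb, 6, nstart = 10)$cluster, lab)
  ari_after <- mclust::adjustedRandIndex(
    kmeans(corrected, 6, nstart = 10)$cluster, lab)
  expect_lt(ari_before, 0.5)
  expect_gt(ari_after, 0.8)
})
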