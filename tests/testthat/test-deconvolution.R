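test_that("nnls_fit matches the support-enumeration oracle on random systems", {
  set.seed(17)
  for (i in 1:20) {
    A <- matrix(rnorm(15), 5, 3)
    b <- rnorm(5)
    expect_equal(nnls_fit(A, b), oracle_nnls(A, b), tolerance = 1e-6)
  }
})

test_that("artificial mixtures carry valid fractions and the expected profiles", {
  cells <- fx_cells_small()
  lab <- cells$cell_meta$subpop
  art <- make_artificial_mixtures(cells, lab, n_mixtures = 30,
                                  cells_per_mixture = 1000, seed = 2)
  expect_equal(unname(rowSums(art$fractions)), rep(1, 30), tolerance = 1e-9)
  expect_true(all(art$fractions >= 0))

  # expected mixture equals fractions x per-subpop mean profiles
  cpm <- cpm_normalize(cells)
  S <- sapply(sort(unique(lab)), function(k)
    rowMeans(as.matrix(cpm$counts)[, lab == k]))
  pred <- S %*% t(art$fractions)
  pred <- sweep(pred, 2, colSums(pred) / 1e6, "/")
  cors <- diag(cor(pred, art$bulk$values))
  expect_true(all(cors > 0.99))

  expect_warning(make_artificial_mixtures(cells, lab, n_mixtures = 3, seed = 1),
                 "rank-deficient")
})

test_that("S-mode adjustment is a no-op without platform shift and recovers a known shift", {
  # batch-free truth isolates the platform shift: with batch factors on,
  # the adjustment would (correctly) also remove the cell-vs-bulk batch
  # discrepancy and no longer equal the unadjusted signature
  truth <- make_ground_truth(seed = 1, batch_sdlog = 0, batches = "b1")
  # equal per-subpop totals: the no-shift identity is exact only when the
  # subpopulations have equal RNA content (otherwise per-cell and per-bulk
  # normalisation weigh the subpopulations differently)
  truth$profiles <- sweep(truth$profiles, 2,
                          colSums(truth$profiles) /
                            mean(colSums(truth$profiles)), "/")
  cells <- sample_cells(truth, n_cells_per_subpop = 400, seed = 3)
  lab <- cells$cell_meta$subpop
  de <- wilcoxon_de(cells, lab, alpha = 0.01)
  sig <- build_signature(cells, lab, de)
  art <- make_artificial_mixtures(cells, lab, n_mixtures = 100,
                                  cells_per_mixture = 2000, seed = 5)

  f <- matrix(1 / 6, 30, 6)   # uniform: the real batch mean is composition-free
  no_shift <- mix_bulk(truth, f, noise_sd = 0, apply_platform_shift = FALSE,
                       seed = 6)$bulk
  adj0 <- smode_adjust(sig, art, no_shift)
  shared <- adj0$gene_ids
  rel <- norm(adj0$values - sig$values[shared, ], "F") /
    norm(sig$values[shared, ], "F")
  expect_lt(rel, 0.05)
  expect_true(all(adj0$values >= 0))

  # a known gene-wise multiplicative shift is recovered
  shifted <- mix_bulk(truth, f, noise_sd = 0, apply_platform_shift = TRUE,
                      seed = 6)$bulk
  adj1 <- smode_adjust(sig, art, shifted)
  g <- adj1$gene_ids
  target <- sig$values[g, ] * truth$platform_shift[g]
  # columns are scale-coupled through CPM; compare per-gene after per-column scaling
  s <- colSums(adj1$values * target) / colSums(target^2)
  rel_err <- abs(adj1$values - sweep(target, 2, s, "*")) /
    pmax(sweep(target, 2, s, "*"), 1e-6)
  expect_lt(median(rel_err), 0.1)
})

test_that("deconvolution recovers noiseless mixes and respects symmetries", {
  sig <- fx_sig_big()
  f <- c(0.2, 0.3, 0.5, 0, 0, 0)
  y <- sig$values %*% f
  bulk <- bulk_matrix(cbind(s1 = y[, 1]), gene_ids = sig$gene_ids,
                      scale = "linear")
  est <- deconvolve(bulk, sig)$fractions
  expect_lt(sum(abs(est - f)), 0.02)

  # permuting signature columns permutes the output identically
  perm <- c(3, 1, 2, 6, 4, 5)
  sig_p <- signature_matrix(sig$values[, perm])
  est_p <- deconvolve(bulk, sig_p)$fractions
  # the QP solver's numerical path depends slightly on column order, so
  # equality is asserted at solver precision rather than machine precision
  expect_equal(est_p[, colnames(est)], est[1, colnames(est)], tolerance = 2e-3,
               ignore_attr = TRUE)

  # scale invariance of the input bulk
  bulk_scaled <- bulk_matrix(bulk$values * 37.5, gene_ids = sig$gene_ids,
                             scale = "linear")
  expect_equal(deconvolve(bulk_scaled, sig)$fractions, est, tolerance = 1e-4)

  # refuses log2-flagged input
  logb <- bulk_matrix(log2(bulk$values + 1), gene_ids = sig$gene_ids,
                      scale = "log2")
  expect_error(deconvolve(logb, sig), "delog")

  # SVR solution matches NNLS on noiseless square-ish systems
  set.seed(19)
  for (i in 1:5) {
    fr <- rgamma(6, 1); fr <- fr / sum(fr)
    yy <- sig$values %*% fr
    bb <- bulk_matrix(cbind(s = yy[, 1]), gene_ids = sig$gene_ids,
                      scale = "linear")
    svr <- deconvolve(bb, sig)$fractions[1, ]
    nn <- nnls_fit(sig$values, yy[, 1]); nn <- nn / sum(nn)
    expect_lt(sum(abs(svr - nn)), 0.02)
  }
})

test_that("permutation significance is bounded, extreme for real signal, flat for noise", {
  sig <- fx_sig_big()
  set.seed(23)
  f <- rgamma(6, 1); f <- f / sum(f)
  y <- as.vector(sig$values %*% f)
  names(y) <- sig$gene_ids
  p <- permutation_significance(y, sig, n_perm = 500, seed = 1)
  expect_equal(p, 1 / 501, tolerance = 1e-12)

  expect_error(permutation_significance(y, sig, n_perm = 5), ">= 10")

  # pure-noise samples give p-values spread over the unit interval
  ps <- vapply(1:20, function(i) {
    set.seed(100 + i)
    yn <- rlnorm(length(sig$gene_ids), 5, 1)
    names(yn) <- sig$gene_ids
    permutation_significance(yn, sig, n_perm = 49, seed = i)
  }, numeric(1))
  expect_true(all(ps >= 1 / 50 & ps <= 1))
  expect_gt(median(ps), 0.2)
  expect_lt(median(ps), 0.8)
})
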