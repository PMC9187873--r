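make_table <- function(pct, susc, cons = NULL) {
  if (is.null(cons)) cons <- consistency(pct, susc)
  structure(list(pct = pct, susceptibility = susc, consistency = cons,
                 killed = classify_killed(susc), kill_threshold = -90),
            class = "susceptibility_table")
}

test_that("an empty table yields an empty cocktail with everything residual", {
  empty <- structure(list(pct = data.frame(), susceptibility =
                            matrix(0, 0, 3, dimnames = list(NULL, c("A", "B", "C"))),
                          consistency = NULL, killed = NULL),
                     class = "susceptibility_table")
  ck <- greedy_cocktail(empty)
  expect_equal(nrow(ck$selections), 0L)
  expect_equal(sort(ck$residual), c("A", "B", "C"))
})

test_that("the worked selection example follows the stated rule", {
  # drug alpha kills {A,B} at 1 uM, {A,B,C} at 10 uM; beta kills {D} at 0.5 uM
  pct <- data.frame(pert_id = c("alpha", "alpha", "beta"),
                    dose_um = c(1, 10, 0.5), time_h = 24,
                    stringsAsFactors = FALSE)
  susc <- rbind(c(-95, -95, -10, 0),
                c(-99, -99, -95, 0),
                c(0, 0, 0, -99))
  colnames(susc) <- c("A", "B", "C", "D")
  cons <- matrix(-95, 3, 4, dimnames = list(NULL, colnames(susc)))
  ck <- greedy_cocktail(make_table(pct, susc, cons))
  expect_equal(ck$selections$pert_id, c("alpha", "beta"))
  expect_equal(ck$selections$dose_um, c(10, 0.5))
  expect_equal(ck$selections$kills, c("A;B;C", "D"))
  expect_equal(length(ck$residual), 0L)
})

test_that("tie-breaking prefers lowest dose, then time, then perturbagen id", {
  pct <- data.frame(pert_id = c("zeta", "alpha", "alpha"),
                    dose_um = c(1, 1, 1), time_h = c(24, 24, 6),
                    stringsAsFactors = FALSE)
  susc <- matrix(-99, 3, 2, dimnames = list(NULL, c("A", "B")))
  cons <- matrix(-95, 3, 2, dimnames = list(NULL, c("A", "B")))
  ck <- greedy_cocktail(make_table(pct, susc, cons))
  expect_equal(ck$selections$pert_id[1], "alpha")
  expect_equal(ck$selections$time_h[1], 6)
})

test_that("undefined consistency passes by default and fails under strict mode", {
  pct <- data.frame(pert_id = "a", dose_um = 10, time_h = 24,
                    stringsAsFactors = FALSE)
  susc <- matrix(-99, 1, 1, dimnames = list(NULL, "A"))
  tab <- make_table(pct, susc)            # highest dose: consistency NA
  expect_equal(nrow(greedy_cocktail(tab)$selections), 1L)
  expect_equal(nrow(greedy_cocktail(tab, strict_consistency = TRUE)$selections),
               0L)
})

test_that("greedy output matches an independent implementation on 200 instances", {
  for (i in 1:200) {
    tab <- random_susc_table(n_subpops = sample(2:6, 1),
                             n_pct = sample(4:20, 1), seed = 1000 + i)
    mine <- greedy_cocktail(tab)
    ref <- oracle_greedy(tab$pct, tab$susceptibility, tab$consistency)
    expect_equal(nrow(mine$selections), length(ref$picks), info = paste("seed", i))
    if (length(ref$picks)) {
      for (j in seq_along(ref$picks)) {
        expect_equal(mine$selections$pert_id[j], ref$picks[[j]]$pert_id)
        expect_equal(mine$selections$dose_um[j], ref$picks[[j]]$dose_um)
        expect_equal(sort(strsplit(mine$selections$kills[j], ";")[[1]]),
                     ref$picks[[j]]$kills)
      }
    }
    expect_equal(sort(mine$residual), sort(ref$residual))

    # credited kills are killable; residual subpops are unreachable by any
    # eligible condition of a drug outside the cocktail (subpops killable
    # only by a removed dose of a selected drug may legitimately survive)
    cons_eff <- tab$consistency
    cons_eff[is.na(cons_eff)] <- tab$susceptibility[is.na(cons_eff)]
    eligible <- tab$susceptibility < -90 & cons_eff <= -80
    killable <- colnames(tab$susceptibility)[colSums(eligible) > 0]
    credited <- as.character(unlist(strsplit(mine$selections$kills, ";")))
    expect_true(all(credited %in% killable))
    unselected <- !(tab$pct$pert_id %in% mine$selections$pert_id)
    for (s in mine$residual) {
      expect_false(any(eligible[unselected, s]))
    }

    # determinism under row shuffling
    set.seed(i)
    perm <- sample(nrow(tab$pct))
    tab_p <- tab
    tab_p$pct <- tab$pct[perm, , drop = FALSE]
    tab_p$susceptibility <- tab$susceptibility[perm, , drop = FALSE]
    tab_p$consistency <- tab$consistency[perm, , drop = FALSE]
    tab_p$killed <- tab$killed[perm, , drop = FALSE]
    mine_p <- greedy_cocktail(tab_p)
    expect_equal(mine_p$selections$pert_id, mine$selections$pert_id)
    expect_equal(mine_p$selections$dose_um, mine$selections$dose_um)
  }
})

test_that("greedy cover size respects the harmonic approximation bound", {
  min_cover <- function(kill_sets, universe) {
    n <- length(kill_sets)
    for (size in 1:n) {
      for (idx in asplit(utils::combn(n, size), 2)) {
        if (setequal(Reduce(union, kill_sets[as.integer(idx)]), universe))
          return(size)
      }
    }
    n
  }
  for (i in 1:30) {
    tab <- random_susc_table(n_subpops = sample(3:6, 1), n_pct = 10,
                             seed = 3000 + i)
    mine <- greedy_cocktail(tab)
    if (nrow(mine$selections) == 0) next
    cons_eff <- tab$consistency
    cons_eff[is.na(cons_eff)] <- tab$susceptibility[is.na(cons_eff)]
    eligible <- tab$susceptibility < -90 & cons_eff <= -80
    killable <- colnames(tab$susceptibility)[colSums(eligible) > 0]
    # one candidate set per perturbagen: its best achievable kill set
    per_pert <- lapply(split(seq_len(nrow(tab$pct)), tab$pct$pert_id),
                       function(rows) {
      sets <- lapply(rows, function(r)
        colnames(eligible)[eligible[r, ]])
      sets[[which.max(lengths(sets))]]
    })
    per_pert <- per_pert[lengths(per_pert) > 0]
    opt <- min_cover(per_pert, killable)
    n <- length(killable)
    expect_lte(nrow(mine$selections), ceiling((1 + sum(1 / seq_len(max(n, 1)))) * opt))
  }
})
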