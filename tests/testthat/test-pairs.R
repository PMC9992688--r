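# Build mismatch connectomes for a 2R-region parcellation directly from a
# subjects x pairs matrix of left values and one of right values.
mismatch_from_values <- function(parc, pairs, lvals, rvals) {
  n <- n_regions(parc)
  lapply(seq_len(nrow(lvals)), function(k) {
    m <- matrix(NaN, n, n)
    for (j in seq_len(nrow(pairs))) {
      m[pairs$u[j], pairs$v[j]] <- m[pairs$v[j], pairs$u[j]] <- lvals[k, j]
      m[pairs$hu[j], pairs$hv[j]] <- m[pairs$hv[j], pairs$hu[j]] <- rvals[k, j]
    }
    connectome(m, "mFCSC", sprintf("s%02d", k))
  })
}

full_intra_mask <- function(parc) {
  edge_mask(intra_hemispheric_mask(parc)$matrix, "analysis")
}

test_that("pair enumeration matches the combinatorics", {
  expect_equal(nrow(enumerate_bilateral_pairs(tiny_parcellation(42))), 861L)
  expect_equal(nrow(enumerate_bilateral_pairs(tiny_parcellation(2))), 1L)
  expect_equal(nrow(enumerate_bilateral_pairs(tiny_parcellation(3))), 3L)
  p <- enumerate_bilateral_pairs(tiny_parcellation(3))
  expect_true(all(p$u < p$v))
  parc <- tiny_parcellation(3)
  expect_identical(p$hu, parc$homolog[p$u])
  expect_identical(p$hv, parc$homolog[p$v])
})

test_that("identical bilateral mismatches are flagged, never significant", {
  parc <- tiny_parcellation(3)
  pairs <- enumerate_bilateral_pairs(parc)
  set.seed(30)
  vals <- matrix(rnorm(10 * 3), 10, 3)
  mism <- mismatch_from_values(parc, pairs, vals, vals)
  res <- test_bilateral_mismatch(mism, pairs, full_intra_mask(parc))
  expect_true(all(res$note == "zero_variance"))
  expect_true(all(is.na(res$p_value)))
  expect_false(any(res$significant))
})

test_that("a constant bilateral offset is detected with the right category", {
  parc <- tiny_parcellation(3)
  pairs <- enumerate_bilateral_pairs(parc)
  set.seed(31)
  n_subj <- 50
  rvals <- matrix(rnorm(n_subj * 3, 0.05, 0.01), n_subj, 3)
  lvals <- rvals
  # constant 0.3 offset plus tiny jitter on the difference
  lvals[, 2] <- lvals[, 2] + 0.3 + rnorm(n_subj, 0, 0.005)
  mism <- mismatch_from_values(parc, pairs, lvals, rvals)
  res <- test_bilateral_mismatch(mism, pairs, full_intra_mask(parc), 0.05)
  expect_true(res$significant[2])
  expect_false(any(res$significant[-2]))
  expect_match(res$category[2], "L>R", fixed = TRUE)
  expect_match(res$category[2], "\\+/\\+")
  expect_equal(res$dof, rep(n_subj - 1L, 3))
  # independent oracle: stats::t.test on the same paired differences
  tt <- t.test(lvals[, 2], rvals[, 2], paired = TRUE)
  expect_equal(res$t_statistic[2], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p_value[2], tt$p.value, tolerance = 1e-12)
  # Bonferroni threshold uses the full enumerated pair count
  expect_equal(attr(res, "threshold"), 0.05 / 3)
})

test_that("the Bonferroni denominator is the enumerated count, not the testable count", {
  parc <- tiny_parcellation(3)
  pairs <- enumerate_bilateral_pairs(parc)
  # mask only pair 1 testable; other pairs' edges excluded
  mask_m <- matrix(FALSE, 6, 6)
  mask_m[pairs$u[1], pairs$v[1]] <- mask_m[pairs$v[1], pairs$u[1]] <- TRUE
  mask_m[pairs$hu[1], pairs$hv[1]] <- mask_m[pairs$hv[1], pairs$hu[1]] <- TRUE
  mask <- edge_mask(mask_m, "analysis")
  set.seed(32)
  n_subj <- 12
  rv <- matrix(rnorm(n_subj * 3, 0, 0.05), n_subj, 3)
  lv <- rv
  # a difference whose p lands between alpha/3 and alpha would be declared
  # significant if the denominator (wrongly) shrank to the testable count
  repeat {
    lv[, 1] <- rv[, 1] + rnorm(n_subj, 0.035, 0.05)
    p <- t.test(lv[, 1] - rv[, 1])$p.value
    if (p > 0.05 / 3 && p < 0.05) break
  }
  mism <- mismatch_from_values(parc, pairs, lv, rv)
  res <- test_bilateral_mismatch(mism, pairs, mask, 0.05)
  expect_equal(sum(res$testable), 1L)
  expect_false(res$significant[1])
  expect_true(all(res$note[!res$testable] == "not_in_mask"))
})

test_that("swapping hemisphere labels negates t and swaps asymmetry direction", {
  parc <- tiny_parcellation(3)
  pairs <- enumerate_bilateral_pairs(parc)
  set.seed(33)
  n_subj <- 20
  lv <- matrix(rnorm(n_subj * 3, 0, 0.1), n_subj, 3)
  rv <- matrix(rnorm(n_subj * 3, 0, 0.1), n_subj, 3)
  lv[, 1] <- lv[, 1] + 0.5
  mism <- mismatch_from_values(parc, pairs, lv, rv)
  mask <- full_intra_mask(parc)
  res <- test_bilateral_mismatch(mism, pairs, mask)
  # swapped-world: left and right values exchanged
  mism_sw <- mismatch_from_values(parc, pairs, rv, lv)
  res_sw <- test_bilateral_mismatch(mism_sw, pairs, mask)
  expect_equal(res_sw$t_statistic, -res$t_statistic, tolerance = 1e-12)
  expect_identical(res_sw$significant, res$significant)

  fcs <- mismatch_from_values(parc, pairs, lv, rv)
  fcs <- lapply(fcs, function(m) connectome(m$matrix, "mFCSC", m$subject_id))
  scr <- fc_asymmetry_screen(mism, res, pairs, mask)
  scr_sw <- fc_asymmetry_screen(mism_sw, res_sw, pairs, mask)
  expect_identical(scr$direction == "leftward", scr_sw$direction == "rightward")
})

test_that("the FC-asymmetry screen removes mismatch-significant pairs", {
  parc <- tiny_parcellation(3)
  pairs <- enumerate_bilateral_pairs(parc)
  mask <- full_intra_mask(parc)
  set.seed(34)
  n_subj <- 40
  # FC: pair 1 leftward asymmetry, pair 2 leftward asymmetry, pair 3 none
  fc_r <- matrix(rnorm(n_subj * 3, 0.2, 0.05), n_subj, 3)
  fc_l <- fc_r + cbind(rnorm(n_subj, 0.4, 0.02), rnorm(n_subj, 0.4, 0.02),
                       rnorm(n_subj, 0, 0.02))
  fcs <- mismatch_from_values(parc, pairs, fc_l, fc_r)
  fcs <- lapply(fcs, function(m) {
    mm <- m$matrix; mm[is.nan(mm)] <- 0
    connectome(mm, "FC", m$subject_id)
  })
  # mismatch: pair 1 significant difference, pairs 2-3 null
  mm_r <- matrix(rnorm(n_subj * 3, 0, 0.05), n_subj, 3)
  mm_l <- mm_r + cbind(rnorm(n_subj, 0.5, 0.02), 0, 0)
  mism <- mismatch_from_values(parc, pairs, mm_l, mm_r)
  mres <- test_bilateral_mismatch(mism, pairs, mask)
  expect_identical(mres$significant, c(TRUE, FALSE, FALSE))
  scr <- fc_asymmetry_screen(fcs, mres, pairs, mask)
  expect_identical(scr$direction, c("leftward", "leftward", "none"))
  # asymmetric + mismatch-significant -> excluded; asymmetric + null -> survives
  expect_identical(scr$survived, c(FALSE, TRUE, FALSE))
})

test_that("a null cohort yields no asymmetric pairs at the corrected threshold", {
  parc <- tiny_parcellation(3)
  pairs <- enumerate_bilateral_pairs(parc)
  mask <- full_intra_mask(parc)
  set.seed(35)
  vals_l <- matrix(rnorm(30 * 3), 30, 3)
  vals_r <- matrix(rnorm(30 * 3), 30, 3)
  mism <- mismatch_from_values(parc, pairs, vals_l, vals_r)
  mres <- test_bilateral_mismatch(mism, pairs, mask)
  fcs <- lapply(mism, function(m) {
    mm <- m$matrix; mm[is.nan(mm)] <- 0
    connectome(mm, "FC", m$subject_id)
  })
  scr <- fc_asymmetry_screen(fcs, mres, pairs, mask)
  expect_true(all(scr$direction == "none"))
  expect_false(any(scr$survived))
})

test_that("six-way categorisation follows signs and ordering of the means", {
  expect_equal(categorize_pair(0.3, 0.1, 2), "+/+ L>R")
  expect_equal(categorize_pair(0.1, 0.3, -2), "+/+ L<R")
  expect_equal(categorize_pair(0.3, -0.1, 2), "+/- L>R")
  expect_equal(categorize_pair(-0.3, 0.1, -2), "-/+ L<R")
  expect_equal(categorize_pair(-0.1, -0.3, 2), "-/- L>R")
  expect_equal(categorize_pair(-0.3, -0.1, -2), "-/- L<R")
  # zero means take the sign of t; full ties are indeterminate
  expect_equal(categorize_pair(0, 0.1, 3), "+/+ L<R")
  expect_equal(categorize_pair(0, 0, 0), "indeterminate")
})
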