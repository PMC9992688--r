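#' Enumerate bilateral pairs of unilateral connections
#'
#' A bilateral pair is a left-hemisphere intra-hemispheric connection
#' \{u,v\} together with its homologous right-hemisphere connection
#' \{homolog(u), homolog(v)\}. One pair is produced per unordered left edge,
#' giving `choose(n_left, 2)` pairs (861 for 42 regions per hemisphere).
#'
#' @param parcellation a [parcellation()].
#' @return A data frame with one row per pair: left edge indices `u`, `v`
#'   (`u < v`), right edge indices `hu`, `hv`, and a `label` built from the
#'   left regions' labels.
#' @export
enumerate_bilateral_pairs <- function(parcellation) {
  stopifnot(inherits(parcellation, "parcellation"))
  left <- which(parcellation$hemisphere == "left")
  if (length(left) < 2L)
    return(data.frame(u = integer(), v = integer(), hu = integer(),
                      hv = integer(), label = character()))
  cmb <- utils::combn(left, 2)
  u <- cmb[1, ]; v <- cmb[2, ]
  hom <- parcellation$homolog
  data.frame(
    u = u, v = v, hu = hom[u], hv = hom[v],
    label = paste(parcellation$label[u], parcellation$label[v], sep = "-")
  )
}

# Vectorised paired two-sample t-tests on per-subject left-right differences.
# lmat/rmat are subjects x pairs matrices; rows with a missing value on
# either side are dropped pairwise. Zero-variance differences leave p
# undefined and are flagged.
paired_edge_tests <- function(lmat, rmat) {
  n_pairs <- ncol(lmat)
  out <- data.frame(n = integer(n_pairs), mean_left = NA_real_,
                    mean_right = NA_real_, t_statistic = NA_real_,
                    dof = NA_integer_, p_value = NA_real_,
                    note = "", stringsAsFactors = FALSE)
  for (j in seq_len(n_pairs)) {
    ok <- is.finite(lmat[, j]) & is.finite(rmat[, j])
    l <- lmat[ok, j]; r <- rmat[ok, j]
    nk <- length(l)
    out$n[j] <- nk
    if (nk < 3L) {
      out$note[j] <- "too_few_subjects"
      next
    }
    d <- l - r
    out$mean_left[j] <- mean(l)
    out$mean_right[j] <- mean(r)
    sd_d <- stats::sd(d)
    out$dof[j] <- nk - 1L
    if (sd_d == 0) {
      out$note[j] <- "zero_variance"
      next
    }
    tstat <- mean(d) / (sd_d / sqrt(nk))
    out$t_statistic[j] <- tstat
    out$p_value[j] <- 2 * stats::pt(-abs(tstat), nk - 1L)
  }
  out
}

# Fig-style six-way categorisation from the signs and ordering of the group
# mean mismatches; zero means fall back on the sign of the t statistic, and
# exact ties are reported as indeterminate.
categorize_pair <- function(mean_left, mean_right, t_statistic) {
  sgn <- function(m) {
    s <- sign(m)
    if (is.na(s)) return(NA_real_)
    s
  }
  sl <- sgn(mean_left); sr <- sgn(mean_right)
  ts <- if (is.na(t_statistic)) 0 else sign(t_statistic)
  if (!is.na(sl) && sl == 0) sl <- ts
  if (!is.na(sr) && sr == 0) sr <- ts
  if (is.na(sl) || is.na(sr) || sl == 0 || sr == 0) return("indeterminate")
  ord <- if (isTRUE(mean_left > mean_right)) "L>R"
         else if (isTRUE(mean_left < mean_right)) "L<R"
         else if (ts > 0) "L>R" else if (ts < 0) "L<R" else NA_character_
  if (is.na(ord)) return("indeterminate")
  signs <- paste0(ifelse(sl > 0, "+", "-"), "/", ifelse(sr > 0, "+", "-"))
  paste(signs, ord)
}

#' Paired bilateral tests of the FC-SC mismatch
#'
#' For each bilateral pair whose two edges are both in the analysis mask, a
#' two-tailed paired two-sample t-test of the per-subject left-right
#' difference in mismatch. Significance is Bonferroni-controlled at
#' `alpha / n_total_pairs`, where the denominator is the full enumerated pair
#' count — not the testable count — so the decision threshold does not depend
#' on how many connections earlier stages excluded.
#'
#' @param mismatches list of `mFCSC` [connectome()]s, one per subject.
#' @param pairs pair table from [enumerate_bilateral_pairs()].
#' @param mask the analysis [edge_mask()].
#' @param alpha family-wise error rate (default 0.05).
#' @return A data frame with one row per pair: `label`, `testable`, `n`,
#'   `mean_left`, `mean_right`, `t_statistic`, `dof`, `p_value`,
#'   `significant`, `category` (six-way sign/order classification of the
#'   group means), and `note` (`"zero_variance"` when the paired differences
#'   have no variance and p is undefined).
#' @export
test_bilateral_mismatch <- function(mismatches, pairs, mask, alpha = 0.05) {
  stopifnot(inherits(mask, "edge_mask"), is.data.frame(pairs))
  if (length(mismatches) < 3L)
    abort_validation("need at least 3 subjects, got %d", length(mismatches))
  n_total <- nrow(pairs)
  testable <- mask$matrix[cbind(pairs$u, pairs$v)] &
    mask$matrix[cbind(pairs$hu, pairs$hv)]
  lmat <- vapply(mismatches, function(m) m$matrix[cbind(pairs$u, pairs$v)],
                 numeric(n_total))
  rmat <- vapply(mismatches, function(m) m$matrix[cbind(pairs$hu, pairs$hv)],
                 numeric(n_total))
  lmat <- t(matrix(lmat, nrow = n_total)); rmat <- t(matrix(rmat, nrow = n_total))
  lmat[, !testable] <- NA_real_
  rmat[, !testable] <- NA_real_
  res <- paired_edge_tests(lmat, rmat)
  res$note[!testable] <- "not_in_mask"
  threshold <- alpha / n_total
  significant <- !is.na(res$p_value) & res$p_value < threshold
  category <- vapply(seq_len(n_total), function(j)
    categorize_pair(res$mean_left[j], res$mean_right[j], res$t_statistic[j]),
    character(1))
  category[!testable] <- NA_character_
  out <- cbind(
    data.frame(label = pairs$label, testable = testable),
    res[, c("n", "mean_left", "mean_right", "t_statistic", "dof", "p_value")],
    data.frame(significant = significant, category = category,
               note = res$note)
  )
  attr(out, "alpha") <- alpha
  attr(out, "n_total_pairs") <- n_total
  attr(out, "threshold") <- threshold
  out
}

#' Screen FC asymmetries against hemispheric mismatch differences
#'
#' FC asymmetry (significantly different FC in the left and right connections
#' of a bilateral pair) is conventionally read as hemispheric dominance, but
#' that reading presupposes that both connections serve the same brain
#' function. Step 1 runs paired t-tests on FC left vs right with the same
#' Bonferroni rule as the mismatch analysis, splitting significant pairs into
#' leftward (`mean(FC_L - FC_R) > 0`) and rightward sets. Step 2 removes any
#' pair whose mismatch test was itself significant — there the left and right
#' connections likely have distinct functional specialisations and FC
#' asymmetry is not interpretable as dominance. Pairs that survive are those
#' where FC asymmetry remains a meaningful dominance indicator.
#'
#' @param fc_connectomes list of `FC` [connectome()]s, one per subject, in
#'   the same order as the mismatch analysis.
#' @param mismatch_results result of [test_bilateral_mismatch()] on the same
#'   pairs.
#' @param pairs pair table from [enumerate_bilateral_pairs()].
#' @param mask the analysis [edge_mask()].
#' @param alpha family-wise error rate (default 0.05).
#' @param restrict_to_mask if `TRUE` (default) only pairs inside the analysis
#'   mask are tested; if `FALSE` all enumerated pairs are.
#' @return A data frame with one row per pair: `label`, `tested`, `n`,
#'   `mean_left`, `mean_right`, `t_statistic`, `dof`, `p_value`,
#'   `significant`, `direction` (`"leftward"`, `"rightward"`, or `"none"`),
#'   `mismatch_significant`, and `survived` (significant asymmetry whose pair
#'   passed the mismatch screen).
#' @export
fc_asymmetry_screen <- function(fc_connectomes, mismatch_results, pairs,
                                mask, alpha = 0.05,
                                restrict_to_mask = TRUE) {
  stopifnot(is.data.frame(mismatch_results), is.data.frame(pairs),
            inherits(mask, "edge_mask"))
  if (nrow(mismatch_results) != nrow(pairs))
    abort_validation("mismatch results and pair table differ in length")
  n_total <- nrow(pairs)
  tested <- if (restrict_to_mask) {
    mask$matrix[cbind(pairs$u, pairs$v)] &
      mask$matrix[cbind(pairs$hu, pairs$hv)]
  } else rep(TRUE, n_total)
  lmat <- vapply(fc_connectomes, function(m) m$matrix[cbind(pairs$u, pairs$v)],
                 numeric(n_total))
  rmat <- vapply(fc_connectomes, function(m) m$matrix[cbind(pairs$hu, pairs$hv)],
                 numeric(n_total))
  lmat <- t(matrix(lmat, nrow = n_total)); rmat <- t(matrix(rmat, nrow = n_total))
  lmat[, !tested] <- NA_real_
  rmat[, !tested] <- NA_real_
  res <- paired_edge_tests(lmat, rmat)
  res$note[!tested] <- "not_in_mask"
  threshold <- alpha / n_total
  significant <- !is.na(res$p_value) & res$p_value < threshold
  direction <- rep("none", n_total)
  direction[significant & res$mean_left > res$mean_right] <- "leftward"
  direction[significant & res$mean_left < res$mean_right] <- "rightward"
  mism_sig <- mismatch_results$significant
  survived <- significant & !mism_sig
  out <- cbind(
    data.frame(label = pairs$label, tested = tested),
    res[, c("n", "mean_left", "mean_right", "t_statistic", "dof", "p_value")],
    data.frame(significant = significant, direction = direction,
               mismatch_significant = mism_sig, survived = survived,
               note = res$note)
  )
  attr(out, "threshold") <- threshold
  out
}
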