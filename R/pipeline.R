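#' Run the full FC-SC mismatch pipeline
#'
#' Executes the method's stages in their mandated order: (1) group-average SC
#' and FC; (2) fit the power-law transform at group level and apply it to the
#' group and to every subject; (3) build the direct-edge set on the
#' group-averaged transformed SC (full graph, before any hemispheric
#' restriction, since shortest paths need the complete connectome); (4)
#' restrict to intra-hemispheric, bilaterally preserved edges; (5) fit each
#' subject's FC ~ transformed-SC regression over the analysis mask and emit
#' mismatch connectomes; (6) paired bilateral tests and the FC-asymmetry
#' screen. All exclusions are decided once on group averages and applied to
#' every subject.
#'
#' @param cohort a [cohort()] (see [read_cohort()] to build one from disk).
#' @param alpha family-wise error rate for both test stages (default 0.05).
#' @param out_dir optional output directory; when given, all stage outputs
#'   are written there (`transform.json`, `e_direct.csv`,
#'   `analysis_mask.csv`, `edges.tsv`, `mfcsc/<subject>.csv`, `models.tsv`,
#'   `pair_tests.tsv`, `fc_asymmetry.tsv`, `run_log.txt`).
#' @param screen_restrict_to_mask passed to [fc_asymmetry_screen()].
#' @return A list with elements `params`, `e_direct`, `e_intra`, `mask`,
#'   `models`, `mismatches`, `pairs`, `pair_tests`, `fc_asymmetry`, and
#'   `counts` (edge/pair bookkeeping), invisibly when writing to disk.
#' @export
run_pipeline <- function(cohort, alpha = 0.05, out_dir = NULL,
                         screen_restrict_to_mask = TRUE) {
  stopifnot(inherits(cohort, "cohort"))
  parc <- cohort$parcellation
  scs <- lapply(cohort$subjects, `[[`, "sc")
  fcs <- lapply(cohort$subjects, `[[`, "fc")

  group_sc <- group_average(scs)
  group_fc <- group_average(fcs)
  params <- fit_power_law(group_sc, group_fc)
  group_sc_trans <- apply_power_law(group_sc, params)

  e_direct <- direct_edge_set(group_sc_trans)
  e_intra <- intra_hemispheric_mask(parc)
  mask <- restrict_bilateral(e_direct, e_intra, parc)

  sc_trans <- lapply(scs, apply_power_law, params = params)
  models <- Map(fit_subject_model, fcs, sc_trans,
                MoreArgs = list(mask = mask))
  mismatches <- Map(compute_mismatch, fcs, sc_trans, models,
                    MoreArgs = list(mask = mask))

  pairs <- enumerate_bilateral_pairs(parc)
  pair_tests <- test_bilateral_mismatch(mismatches, pairs, mask, alpha)
  fc_asym <- fc_asymmetry_screen(fcs, pair_tests, pairs, mask, alpha,
                                 restrict_to_mask = screen_restrict_to_mask)

  counts <- list(
    n_regions = n_regions(parc),
    n_subjects = length(cohort$subjects),
    n_intra_edges = n_edges(e_intra),
    n_direct_edges = n_edges(e_direct),
    n_analysis_edges = n_edges(mask),
    n_intra_excluded = n_edges(e_intra) - n_edges(mask),
    n_total_pairs = nrow(pairs),
    n_testable_pairs = sum(pair_tests$testable),
    n_significant_pairs = sum(pair_tests$significant),
    group_r = stats::cor(group_sc_trans$matrix[upper_tri(n_regions(parc))],
                         group_fc$matrix[upper_tri(n_regions(parc))])
  )
  result <- list(params = params, group_sc_trans = group_sc_trans,
                 e_direct = e_direct, e_intra = e_intra, mask = mask,
                 models = models, mismatches = mismatches, pairs = pairs,
                 pair_tests = pair_tests, fc_asymmetry = fc_asym,
                 counts = counts)

  if (!is.null(out_dir)) {
    write_pipeline_outputs(result, parc, out_dir, alpha)
    return(invisible(result))
  }
  result
}

write_pipeline_outputs <- function(result, parc, out_dir, alpha) {
  dir.create(file.path(out_dir, "mfcsc"), recursive = TRUE,
             showWarnings = FALSE)
  write_power_law(result$params, file.path(out_dir, "transform.json"))
  write_edge_mask(result$e_direct, file.path(out_dir, "e_direct.csv"))
  write_edge_mask(result$mask, file.path(out_dir, "analysis_mask.csv"))
  utils::write.table(edge_report(result$e_direct, result$mask, parc),
                     file.path(out_dir, "edges.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (m in result$mismatches)
    write_connectome(m, file.path(out_dir, "mfcsc",
                                  paste0(m$subject_id, ".csv")))
  utils::write.table(model_table(result$models),
                     file.path(out_dir, "models.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(result$pair_tests,
                     file.path(out_dir, "pair_tests.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(result$fc_asymmetry,
                     file.path(out_dir, "fc_asymmetry.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cn <- result$counts
  log_lines <- c(
    sprintf("mfcsc %s", as.character(utils::packageVersion("mfcsc"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("alpha: %g", alpha),
    sprintf("bonferroni threshold: %.6g", alpha / max(cn$n_total_pairs, 1)),
    sprintf("power law: multiplier %.6g exponent %.6g offset %.6g (L1 %.6g)",
            result$params$multiplier, result$params$exponent,
            result$params$offset, result$params$residual_sum),
    sprintf("regions: %d, subjects: %d", cn$n_regions, cn$n_subjects),
    sprintf("intra-hemispheric edges: %d", cn$n_intra_edges),
    sprintf("edges in E_direct: %d", cn$n_direct_edges),
    sprintf("analysis edges: %d (%d intra-hemispheric excluded)",
            cn$n_analysis_edges, cn$n_intra_excluded),
    sprintf("group-level r(SC_trans, FC): %.4f", cn$group_r),
    sprintf("bilateral pairs: %d total, %d testable, %d significant",
            cn$n_total_pairs, cn$n_testable_pairs, cn$n_significant_pairs)
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
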