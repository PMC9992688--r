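#' Configuration for a synthetic connectome cohort
#'
#' The generator emulates the statistical structure the mismatch method
#' assumes: a heavy-tailed (log-normal) structural connectome mirrored across
#' hemispheres, functional connectivity linked to structure through a
#' power law, per-subject affine variation in the FC scale and mean, and
#' i.i.d. edge noise. Defaults correspond to a cohort of 50 subjects on an
#' 84-region bilaterally symmetric parcellation with the power-law link
#' observed on SIFT2/resting-state data.
#'
#' @param n_regions_per_hemisphere regions per hemisphere (default 42).
#' @param n_subjects number of subjects (default 50, minimum 3).
#' @param sc_log_mean,sc_log_sd log-normal parameters of the ground-truth SC
#'   edge weights (defaults 5 and 1: median weight ~148 with a long right
#'   tail, skewness > 2).
#' @param link_params [power_law_params()] linking FC to SC (default
#'   multiplier 0.4114, exponent 0.0926, offset -0.3789).
#' @param fc_noise_sd standard deviation of i.i.d. Gaussian edge noise added
#'   to FC (default 0.05).
#' @param subject_sc_log_sd log-normal sd of per-subject multiplicative SC
#'   perturbations around the ground-truth template (default 0.1).
#' @param subject_fc_scale_sd sd of the per-subject FC scale factor around 1
#'   (default 0.1).
#' @param subject_fc_shift_sd sd of the per-subject additive FC shift
#'   (default 0.1).
#' @param mismatch_injections list of injections, each a list with fields
#'   `u`, `v` (left-hemisphere region indices), `side` (`"left"` or
#'   `"right"`), `delta` (additive offset), and optionally
#'   `target = "fc"` (default) or `"sc"`. FC injections add `delta` to the
#'   designated side's FC edge for every subject, modelling complex neural
#'   interactions confined to one hemisphere; SC injections multiply the
#'   designated side's SC edge by `exp(delta)` instead.
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_regions_per_hemisphere = 42, n_subjects = 50,
                       sc_log_mean = 5, sc_log_sd = 1,
                       link_params = power_law_params(0.4114, 0.0926, -0.3789),
                       fc_noise_sd = 0.05,
                       subject_sc_log_sd = 0.1,
                       subject_fc_scale_sd = 0.1,
                       subject_fc_shift_sd = 0.1,
                       mismatch_injections = list(),
                       seed = 1L) {
  stopifnot(n_regions_per_hemisphere >= 1, n_subjects >= 3,
            sc_log_sd >= 0, fc_noise_sd >= 0, subject_sc_log_sd >= 0,
            subject_fc_scale_sd >= 0, subject_fc_shift_sd >= 0)
  structure(list(
    n_regions_per_hemisphere = as.integer(n_regions_per_hemisphere),
    n_subjects = as.integer(n_subjects),
    sc_log_mean = sc_log_mean, sc_log_sd = sc_log_sd,
    link_params = link_params, fc_noise_sd = fc_noise_sd,
    subject_sc_log_sd = subject_sc_log_sd,
    subject_fc_scale_sd = subject_fc_scale_sd,
    subject_fc_shift_sd = subject_fc_shift_sd,
    mismatch_injections = mismatch_injections,
    seed = as.integer(seed)), class = "sim_config")
}

# Bilaterally mirrored parcellation L1..Ln, R1..Rn with Li <-> Ri.
mirrored_parcellation <- function(n_per_hemisphere) {
  n <- n_per_hemisphere
  parcellation(
    label = c(paste0("L", seq_len(n)), paste0("R", seq_len(n))),
    hemisphere = rep(c("left", "right"), each = n),
    homolog = c(seq_len(n) + n, seq_len(n))
  )
}

# Symmetric matrix whose entries are constant on orbits of the homolog map,
# i.e. m[u,v] == m[hom(u),hom(v)] for every edge. Values are drawn by `draw`
# (a function of a count) for one representative per orbit.
mirrored_edge_matrix <- function(n, hom, draw) {
  ed <- edge_table(n)
  code <- function(a, b) pmin(a, b) * (n + 1) + pmax(a, b)
  own <- code(ed$u, ed$v)
  mirror <- code(hom[ed$u], hom[ed$v])
  orbit <- pmin(own, mirror)
  reps <- match(orbit, sort(unique(orbit)))
  vals <- draw(length(unique(orbit)))[reps]
  m <- matrix(0, n, n)
  m[cbind(ed$u, ed$v)] <- vals
  m[cbind(ed$v, ed$u)] <- vals
  m
}

#' Generate a synthetic SC/FC cohort
#'
#' The ground-truth SC template has log-normal edge weights mirrored across
#' hemispheres (every edge equals its homolog image), so without injections
#' the left and right edge-value distributions are exchangeable and
#' downstream bilateral tests are null-calibrated. Each subject's SC is the
#' template with independent multiplicative log-normal perturbations; each
#' subject's FC is the power-law link applied to that subject's SC, scaled
#' and shifted by subject-level affine factors, plus i.i.d. Gaussian edge
#' noise, symmetrised. Injections then add their offset to the designated
#' side's FC edge (or scale its SC edge) for all subjects.
#'
#' @param config a [sim_config()].
#' @return A [cohort()] with attribute `"ground_truth"` recording the
#'   template, the link parameters and the injections.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  parc <- mirrored_parcellation(config$n_regions_per_hemisphere)
  n <- n_regions(parc)
  hom <- parc$homolog
  template <- mirrored_edge_matrix(n, hom, function(k)
    stats::rlnorm(k, config$sc_log_mean, config$sc_log_sd))

  # validate injections against the parcellation before drawing subjects
  for (inj in config$mismatch_injections) {
    if (is.null(inj$u) || is.null(inj$v) || inj$u == inj$v ||
        parc$hemisphere[inj$u] != "left" || parc$hemisphere[inj$v] != "left")
      abort_validation("injection must name two distinct left-hemisphere regions")
    if (!inj$side %in% c("left", "right"))
      abort_validation("injection side must be 'left' or 'right'")
  }
  inj_edge <- function(inj) {
    if (inj$side == "left") c(inj$u, inj$v) else c(hom[inj$u], hom[inj$v])
  }

  link <- config$link_params
  ut <- upper_tri(n)
  subjects <- lapply(seq_len(config$n_subjects), function(k) {
    id <- sprintf("sub-%03d", k)
    pert <- matrix(0, n, n)
    pert[ut] <- stats::rnorm(sum(ut), 0, config$subject_sc_log_sd)
    pert <- pert + t(pert)
    sc <- template * exp(pert)
    for (inj in config$mismatch_injections) {
      if (identical(inj$target, "sc")) {
        e <- inj_edge(inj)
        sc[e[1], e[2]] <- sc[e[1], e[2]] * exp(inj$delta)
        sc[e[2], e[1]] <- sc[e[1], e[2]]
      }
    }
    scale_k <- 1 + stats::rnorm(1, 0, config$subject_fc_scale_sd)
    shift_k <- stats::rnorm(1, 0, config$subject_fc_shift_sd)
    fc <- scale_k * (link$multiplier * sc^link$exponent + link$offset) + shift_k
    noise <- matrix(0, n, n)
    noise[ut] <- stats::rnorm(sum(ut), 0, config$fc_noise_sd)
    fc <- fc + noise + t(noise)
    for (inj in config$mismatch_injections) {
      if (!identical(inj$target, "sc")) {
        e <- inj_edge(inj)
        fc[e[1], e[2]] <- fc[e[1], e[2]] + inj$delta
        fc[e[2], e[1]] <- fc[e[1], e[2]]
      }
    }
    diag(sc) <- 0
    diag(fc) <- 0
    list(sc = connectome(sc, "SC_raw", id),
         fc = connectome(fc, "FC", id))
  })
  out <- cohort(parc, subjects)
  attr(out, "ground_truth") <- list(
    template = template, link_params = link,
    injections = config$mismatch_injections, config = config)
  out
}

#' Write a cohort to disk in the pipeline's input layout
#'
#' Creates `sc/` and `fc/` directories of dense CSV matrices (one file per
#' subject), `parcellation.csv`, and a `ground_truth.json` sidecar recording
#' the generating parameters.
#'
#' @param cohort a [cohort()], typically from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(file.path(dir, "sc"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "fc"), recursive = TRUE, showWarnings = FALSE)
  write_parcellation(cohort$parcellation, file.path(dir, "parcellation.csv"))
  for (s in cohort$subjects) {
    write_connectome(s$sc, file.path(dir, "sc", paste0(s$sc$subject_id, ".csv")))
    write_connectome(s$fc, file.path(dir, "fc", paste0(s$fc$subject_id, ".csv")))
  }
  gt <- attr(cohort, "ground_truth")
  if (!is.null(gt)) {
    cfg <- gt$config
    jsonlite::write_json(
      list(link_params = unclass(gt$link_params)[c("multiplier", "exponent", "offset")],
           injections = gt$injections,
           config = unclass(cfg)[setdiff(names(cfg), "link_params")]),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
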