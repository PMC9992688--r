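#' Power-law transform parameters
#'
#' The transform `x -> multiplier * x^exponent + offset` maps raw SC onto the
#' FC scale. A successful fit has `multiplier > 0` and `exponent > 0`, so the
#' transform is strictly increasing on `[0, Inf)` and preserves SC ranks.
#'
#' @param multiplier positive scale factor.
#' @param exponent positive power.
#' @param offset additive constant (typically negative, since FC values
#'   centre near zero while SC is nonnegative).
#' @param residual_sum sum of absolute residuals at the optimum, if fitted.
#' @param converged logical convergence flag.
#' @return An object of class `power_law_params`.
#' @export
power_law_params <- function(multiplier, exponent, offset,
                             residual_sum = NA_real_, converged = NA) {
  stopifnot(is.finite(multiplier), is.finite(exponent), is.finite(offset))
  structure(list(multiplier = multiplier, exponent = exponent,
                 offset = offset, residual_sum = residual_sum,
                 converged = converged),
            class = "power_law_params")
}

#' @export
print.power_law_params <- function(x, ...) {
  cat(sprintf("power law: %.6g * x^%.6g + %.6g  (L1 residual %.4g)\n",
              x$multiplier, x$exponent, x$offset, x$residual_sum))
  invisible(x)
}

# Soft-L1 residual transform: sum(fvec^2) equals the soft-L1 loss
# sum(2 * delta^2 * (sqrt(1 + (r/delta)^2) - 1)), which tends to
# 2 * delta * sum(|r|) for |r| >> delta. delta is chosen small relative to
# the FC scale so the fit realises a least-absolute-residuals criterion
# while staying smooth enough for a Levenberg-Marquardt optimiser.
soft_l1_fvec <- function(r, delta) {
  sign(r) * sqrt(2 * delta^2 * (sqrt(1 + (r / delta)^2) - 1))
}

#' Fit the SC-to-FC power-law transform by rank matching
#'
#' Both group-averaged connectomes are reduced to their upper-triangular
#' off-diagonal edge vectors and sorted in ascending order, pairing each SC
#' value with the equal-rank FC value; this matches the two marginal
#' distributions rather than individual connections. The parameters of
#' `multiplier * sc^exponent + offset` are then estimated by minimising the
#' sum of absolute residuals between the sorted FC vector and the transformed
#' sorted SC vector, via a smooth soft-L1 loss inside a Levenberg-Marquardt
#' optimiser with a multi-start grid over the exponent.
#'
#' @param group_sc group-averaged `SC_raw` [connectome()].
#' @param group_fc group-averaged `FC` [connectome()] of the same dimension.
#' @param starts numeric vector of exponent starting values for multi-start.
#' @return A [power_law_params()] with fit diagnostics.
#' @export
fit_power_law <- function(group_sc, group_fc,
                          starts = c(0.1, 0.5, 1)) {
  stopifnot(inherits(group_sc, "connectome"), inherits(group_fc, "connectome"))
  n <- nrow(group_sc$matrix)
  if (nrow(group_fc$matrix) != n)
    abort_validation("SC and FC dimensions differ (%d vs %d)",
                     n, nrow(group_fc$matrix))
  ut <- upper_tri(n)
  x <- sort(group_sc$matrix[ut])
  y <- sort(group_fc$matrix[ut])
  if (length(x) < 4L)
    abort_validation("need at least 4 edges to fit the transform, got %d",
                     length(x))
  if (min(x) < 0)
    abort_validation("SC entries must be nonnegative")
  if (stats::sd(x) == 0)
    abort_validation("SC is constant over the edge set; exponent unidentifiable")

  delta <- 1e-3 * max(stats::sd(y), 1e-8)
  resid_fun <- function(p) y - (p[1] * x^p[2] + p[3])
  fvec_fun <- function(p) soft_l1_fvec(resid_fun(p), delta)

  best <- NULL
  best_l1 <- Inf
  any_converged <- FALSE
  for (e0 in starts) {
    xr <- x^e0
    span <- max(xr) - min(xr)
    m0 <- if (span > 0) (max(y) - min(y)) / span else 1
    m0 <- max(m0, 1e-8)
    o0 <- min(y) - m0 * min(xr)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(m0, e0, o0), fn = fvec_fun,
        lower = c(1e-12, 1e-6, -Inf),
        control = minpack.lm::nls.lm.control(
          maxiter = 1000, maxfev = 100000, ftol = 1e-13, ptol = 1e-13)),
      error = function(e) NULL)
    if (is.null(fit)) next
    p <- fit$par
    l1 <- sum(abs(resid_fun(p)))
    # info 1-4: converged; 6-8: tolerance reached machine limits, i.e. no
    # further reduction possible, which we also accept. 0 and 5 are failures.
    conv <- fit$info %in% c(1:4, 6:8)
    any_converged <- any_converged || conv
    if (l1 < best_l1) {
      best_l1 <- l1
      best <- list(par = p, converged = conv)
    }
  }
  if (is.null(best))
    abort_validation("power-law fit failed from every starting point")
  params <- power_law_params(best$par[1], best$par[2], best$par[3],
                             residual_sum = best_l1,
                             converged = best$converged)
  if (!any_converged) {
    cond <- structure(
      class = c("mfcsc_fit_error", "mfcsc_error", "error", "condition"),
      list(message = "power-law fit did not converge from any start",
           call = sys.call(), params = params))
    stop(cond)
  }
  params
}

#' Apply a fitted power-law transform to a raw SC connectome
#'
#' Every off-diagonal entry `x` becomes `multiplier * x^exponent + offset`.
#' The parameters are fitted once at group level and applied to each subject
#' separately; the output may contain negative values (zero-SC entries map to
#' the offset).
#'
#' @param connectome an `SC_raw` [connectome()].
#' @param params a [power_law_params()].
#' @return An `SC_trans` [connectome()] for the same subject.
#' @export
apply_power_law <- function(connectome, params) {
  stopifnot(inherits(connectome, "connectome"),
            inherits(params, "power_law_params"))
  if (connectome$modality != "SC_raw")
    abort_validation("apply_power_law expects an SC_raw connectome, got %s",
                     connectome$modality)
  m <- params$multiplier * connectome$matrix^params$exponent + params$offset
  diag(m) <- 0
  connectome(m, "SC_trans", connectome$subject_id, tol = Inf)
}

#' Write fitted transform parameters to a JSON sidecar
#'
#' @param params a [power_law_params()].
#' @param path output path (conventionally `transform.json`).
#' @return `path`, invisibly.
#' @export
write_power_law <- function(params, path) {
  stopifnot(inherits(params, "power_law_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read transform parameters from a JSON sidecar
#' @param path path written by [write_power_law()].
#' @return A [power_law_params()].
#' @export
read_power_law <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  power_law_params(p$multiplier, p$exponent, p$offset,
                   residual_sum = p$residual_sum %||% NA_real_,
                   converged = p$converged %||% NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
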