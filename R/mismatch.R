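#' Fit one subject's FC ~ transformed-SC regression
#'
#' Ordinary least squares of FC (response) on transformed SC (predictor) over
#' the masked upper-triangle edges, each undirected edge contributing exactly
#' one observation. The model is fitted separately per subject so that
#' inter-individual differences in the scale and mean of the FC distribution
#' are absorbed by the slope and intercept rather than leaking into the
#' residuals.
#'
#' @param fc the subject's `FC` [connectome()].
#' @param sc_trans the subject's `SC_trans` [connectome()].
#' @param mask [edge_mask()] restricting the fitted edge set (>= 3 edges).
#' @return An object of class `subject_model` with fields `subject_id`,
#'   `intercept`, `slope`, `n_edges`, and `r` (Pearson correlation of FC with
#'   transformed SC over the fitted edges).
#' @export
fit_subject_model <- function(fc, sc_trans, mask) {
  stopifnot(inherits(fc, "connectome"), inherits(sc_trans, "connectome"),
            inherits(mask, "edge_mask"))
  n <- nrow(fc$matrix)
  if (nrow(sc_trans$matrix) != n || nrow(mask$matrix) != n)
    abort_validation("fc, sc_trans and mask dimensions differ")
  sel <- upper_tri(n) & mask$matrix
  x <- sc_trans$matrix[sel]
  y <- fc$matrix[sel]
  if (length(x) < 3L)
    abort_validation("need at least 3 masked edges to fit, got %d", length(x))
  if (stats::var(x) == 0)
    abort_validation("degenerate predictor: transformed SC constant over mask")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  r <- if (stats::var(y) == 0) 0 else stats::cor(x, y)
  structure(list(subject_id = fc$subject_id,
                 intercept = unname(co[1]), slope = unname(co[2]),
                 n_edges = length(x), r = r),
            class = "subject_model")
}

#' @export
print.subject_model <- function(x, ...) {
  cat(sprintf("subject model '%s': FC = %.4g + %.4g * SC_trans  (r = %.3f, %d edges)\n",
              x$subject_id, x$intercept, x$slope, x$r, x$n_edges))
  invisible(x)
}

#' Compute a subject's FC-SC mismatch connectome
#'
#' The mismatch on a masked connection is the residual of the subject's
#' regression: `FC - (intercept + slope * SC_trans)` — geometrically, the
#' vertical distance of the connection's point from the subject's regression
#' line. Entries outside the mask are undefined and stored as `NaN`.
#'
#' @param fc the subject's `FC` [connectome()].
#' @param sc_trans the subject's `SC_trans` [connectome()].
#' @param model the [fit_subject_model()] fitted on the same mask.
#' @param mask the [edge_mask()] the model was fitted on.
#' @return An `mFCSC` [connectome()].
#' @export
compute_mismatch <- function(fc, sc_trans, model, mask) {
  stopifnot(inherits(model, "subject_model"), inherits(mask, "edge_mask"))
  n <- nrow(fc$matrix)
  if (sum(mask$matrix[upper_tri(n)]) != model$n_edges)
    abort_validation("mask has %d edges but model was fitted on %d",
                     sum(mask$matrix[upper_tri(n)]), model$n_edges)
  resid <- fc$matrix - (model$intercept + model$slope * sc_trans$matrix)
  out <- matrix(NaN, n, n)
  out[mask$matrix] <- resid[mask$matrix]
  connectome(out, "mFCSC", fc$subject_id, tol = Inf)
}

#' Per-subject model table
#'
#' @param models list of [fit_subject_model()] results.
#' @return A data frame with one row per subject (`subject_id`, `intercept`,
#'   `slope`, `r`, `n_edges`).
#' @export
model_table <- function(models) {
  do.call(rbind, lapply(models, function(m)
    data.frame(subject_id = m$subject_id, intercept = m$intercept,
               slope = m$slope, r = m$r, n_edges = m$n_edges)))
}
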