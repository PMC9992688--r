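# Internal helpers shared across the package.

# Signal a named validation error so callers can distinguish bad inputs
# from programming errors.
abort_validation <- function(msg, ..., class = "mfcsc_validation_error") {
  stop(structure(
    class = c(class, "mfcsc_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Logical index of the strict upper triangle, the canonical edge order used
# everywhere an undirected edge must contribute exactly one observation.
upper_tri <- function(n) upper.tri(matrix(0L, n, n))

# Edge list (u < v) for an n-region parcellation, in upper-triangle order.
edge_table <- function(n) {
  idx <- which(upper_tri(n), arr.ind = TRUE)
  data.frame(u = idx[, "row"], v = idx[, "col"])
}

is_square_matrix <- function(m) {
  is.matrix(m) && is.numeric(m) && nrow(m) == ncol(m)
}

# Maximum absolute asymmetry, ignoring entries that are NaN on either side.
max_asymmetry <- function(m) {
  d <- abs(m - t(m))
  d <- d[is.finite(d)]
  if (length(d) == 0L) return(0)
  max(d)
}
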