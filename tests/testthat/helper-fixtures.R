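# Shared fixtures and independent oracles, built in code at test time.

# 2R-region bilaterally symmetric parcellation L1..LR, R1..RR.
tiny_parcellation <- function(n_per_hemisphere = 2) {
  n <- n_per_hemisphere
  parcellation(
    label = c(paste0("L", seq_len(n)), paste0("R", seq_len(n))),
    hemisphere = rep(c("left", "right"), each = n),
    homolog = c(seq_len(n) + n, seq_len(n))
  )
}

# Random symmetric nonnegative matrix with zero diagonal.
random_symmetric <- function(n, rfun = stats::runif) {
  m <- matrix(0, n, n)
  ut <- upper.tri(m)
  m[ut] <- rfun(sum(ut))
  m + t(m)
}

write_parcellation_csv <- function(labels, hemis, homolog_labels,
                                   path = tempfile(fileext = ".csv")) {
  writeLines(c("label,hemisphere,homolog_label",
               paste(labels, hemis, homolog_labels, sep = ",")), path)
  path
}

# Independent oracle for the direct-edge criterion: enumerate every simple
# path between u and v by depth-first recursion over the adjacency matrix
# and compare the direct reciprocal length against the shortest indirect
# path's sum of reciprocals.
oracle_direct_edges <- function(w) {
  n <- nrow(w)
  keep <- matrix(FALSE, n, n)
  path_lengths <- function(wm, u, v, visited, len) {
    # lengths of all simple paths from u to v avoiding `visited`
    out <- numeric(0)
    for (r in seq_len(n)) {
      if (visited[r] || wm[u, r] <= 0) next
      step <- len + 1 / wm[u, r]
      if (r == v) {
        out <- c(out, step)
      } else {
        vis <- visited
        vis[r] <- TRUE
        out <- c(out, path_lengths(wm, r, v, vis, step))
      }
    }
    out
  }
  for (u in seq_len(n - 1)) {
    for (v in (u + 1):n) {
      if (w[u, v] <= 0) next
      # indirect paths only: drop the direct edge before enumerating
      w2 <- w
      w2[u, v] <- 0
      w2[v, u] <- 0
      visited <- rep(FALSE, n)
      visited[u] <- TRUE
      lens <- path_lengths(w2, u, v, visited, 0)
      direct <- 1 / w[u, v]
      ok <- if (length(lens) == 0) TRUE else direct < min(lens)
      keep[u, v] <- keep[v, u] <- ok
    }
  }
  keep
}

# Closed-form OLS oracle from the normal equations.
ols_closed_form <- function(x, y) {
  slope <- (mean(x * y) - mean(x) * mean(y)) / (mean(x^2) - mean(x)^2)
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}
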