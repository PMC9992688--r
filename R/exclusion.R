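#' Construct an edge mask
#'
#' A boolean symmetric matrix with a `FALSE` diagonal, marking the edge set a
#' processing stage works with: `E_direct` (direct link dominates), `E_intra`
#' (intra-hemispheric), or the final `analysis` mask.
#'
#' @param matrix logical square matrix, symmetric, diagonal `FALSE`.
#' @param kind one of `"E_direct"`, `"E_intra"`, `"analysis"`.
#' @return An object of class `edge_mask`.
#' @export
edge_mask <- function(matrix, kind = c("E_direct", "E_intra", "analysis")) {
  kind <- match.arg(kind)
  if (!is.matrix(matrix) || !is.logical(matrix) ||
      nrow(matrix) != ncol(matrix))
    abort_validation("edge mask must be a square logical matrix")
  if (!identical(matrix, t(matrix)))
    abort_validation("edge mask must be symmetric")
  if (any(diag(matrix)))
    abort_validation("edge mask diagonal must be FALSE")
  dimnames(matrix) <- NULL
  structure(list(kind = kind, matrix = matrix), class = "edge_mask")
}

#' @export
print.edge_mask <- function(x, ...) {
  cat(sprintf("edge mask [%s]: %d of %d edges\n", x$kind,
              n_edges(x), sum(upper_tri(nrow(x$matrix)))))
  invisible(x)
}

#' Number of (undirected) edges in a mask
#' @param mask an [edge_mask()].
#' @return Integer count of included unordered region pairs.
#' @export
n_edges <- function(mask) {
  stopifnot(inherits(mask, "edge_mask"))
  sum(mask$matrix[upper_tri(nrow(mask$matrix))])
}

#' Edges whose direct structural path beats every indirect path
#'
#' Treating the group-averaged transformed SC as a weighted graph, a path's
#' length is the sum of the reciprocals of its edge weights (strong
#' connections are short). Edge \{u,v\} with weight `w > 0` is preserved iff
#' its direct length `1/w` is strictly smaller than the shortest indirect
#' path from `u` to `v`, i.e. the shortest path in the graph with that edge
#' removed. On preserved edges the direct link is plausibly the main driver
#' of FC; elsewhere FC is likely dominated by indirect routes and the FC-SC
#' mismatch is uninterpretable. Edges with non-positive transformed weight
#' are treated as absent: never preserved and never part of any path.
#'
#' @param group_sc_trans group-averaged `SC_trans` [connectome()].
#' @return An [edge_mask()] of kind `E_direct`.
#' @export
direct_edge_set <- function(group_sc_trans) {
  stopifnot(inherits(group_sc_trans, "connectome"))
  w <- group_sc_trans$matrix
  n <- nrow(w)
  adj <- w
  adj[adj <= 0] <- 0
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  keep <- matrix(FALSE, n, n)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  wts <- igraph::E(g)$weight
  for (i in seq_len(igraph::ecount(g))) {
    u <- ends[i, 1]; v <- ends[i, 2]
    g2 <- igraph::delete_edges(g, i)
    indirect <- igraph::distances(g2, v = u, to = v,
                                  weights = 1 / igraph::E(g2)$weight,
                                  algorithm = "dijkstra")[1, 1]
    if (1 / wts[i] < indirect) {
      keep[u, v] <- TRUE
      keep[v, u] <- TRUE
    }
  }
  edge_mask(keep, "E_direct")
}

#' Intra-hemispheric edge mask
#'
#' Includes \{u,v\} iff both regions lie in the same hemisphere. The FC-SC
#' relationship differs between intra- and inter-hemispheric connections, so
#' the analysis is restricted to one type (here: intra-hemispheric).
#'
#' @param parcellation a [parcellation()].
#' @return An [edge_mask()] of kind `E_intra`.
#' @export
intra_hemispheric_mask <- function(parcellation) {
  stopifnot(inherits(parcellation, "parcellation"))
  same <- outer(parcellation$hemisphere, parcellation$hemisphere, `==`)
  diag(same) <- FALSE
  edge_mask(same, "E_intra")
}

#' Final analysis mask: intra-hemispheric edges preserved bilaterally
#'
#' An intra-hemispheric edge enters the analysis only if both it and its
#' contralateral homolog are in `E_direct`, so every analysed connection has
#' an analysable partner and bilateral pairing is always defined.
#'
#' @param e_direct an [edge_mask()] of kind `E_direct`.
#' @param e_intra an [edge_mask()] of kind `E_intra`.
#' @param parcellation the matching [parcellation()].
#' @return An [edge_mask()] of kind `analysis`.
#' @export
restrict_bilateral <- function(e_direct, e_intra, parcellation) {
  stopifnot(inherits(e_direct, "edge_mask"), inherits(e_intra, "edge_mask"),
            inherits(parcellation, "parcellation"))
  n <- n_regions(parcellation)
  if (nrow(e_direct$matrix) != n || nrow(e_intra$matrix) != n)
    abort_validation("mask dimension does not match parcellation")
  hom <- parcellation$homolog
  mirrored <- e_direct$matrix[hom, hom]
  edge_mask(e_intra$matrix & e_direct$matrix & mirrored, "analysis")
}

#' Write an edge mask as a 0/1 CSV matrix
#' @param mask an [edge_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_mask <- function(mask, path) {
  stopifnot(inherits(mask, "edge_mask"))
  utils::write.table(mask$matrix * 1L, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an edge mask from a 0/1 CSV matrix
#' @param path path written by [write_edge_mask()].
#' @param kind mask kind, see [edge_mask()].
#' @return An [edge_mask()].
#' @export
read_edge_mask <- function(path, kind = "analysis") {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  edge_mask(m != 0, kind)
}

#' Edge-level exclusion report
#'
#' One row per unordered region pair with its membership in `E_direct` and
#' the final analysis mask.
#'
#' @param e_direct,analysis [edge_mask()]s.
#' @param parcellation the matching [parcellation()].
#' @return A data frame with columns `region_a`, `region_b`, `in_E_direct`,
#'   `in_analysis`.
#' @export
edge_report <- function(e_direct, analysis, parcellation) {
  n <- n_regions(parcellation)
  ed <- edge_table(n)
  data.frame(
    region_a = parcellation$label[ed$u],
    region_b = parcellation$label[ed$v],
    in_E_direct = e_direct$matrix[cbind(ed$u, ed$v)],
    in_analysis = analysis$matrix[cbind(ed$u, ed$v)]
  )
}
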