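triangle <- function(w_uv, w_ur, w_rv) {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- w_uv
  m[1, 3] <- m[3, 1] <- w_ur
  m[3, 2] <- m[2, 3] <- w_rv
  connectome(m, "SC_trans", "g", tol = Inf)
}

test_that("direct edges are kept iff strictly shorter than any indirect path", {
  # strong direct edge: 1/4 < 1/1 + 1/1
  keep <- direct_edge_set(triangle(4, 1, 1))
  expect_true(keep$matrix[1, 2])
  # weak direct edge: 1/1 > 1/4 + 1/4
  drop <- direct_edge_set(triangle(1, 4, 4))
  expect_false(drop$matrix[1, 2])
  expect_true(drop$matrix[1, 3]) # 1/4 < 1/1 + 1/4
  # exact tie is excluded (strict inequality): 1/1 vs 1/2 + 1/2
  tie <- direct_edge_set(triangle(1, 2, 2))
  expect_false(tie$matrix[1, 2])
  # no indirect path at all: vacuously preserved
  m <- matrix(0, 2, 2); m[1, 2] <- m[2, 1] <- 5
  expect_true(direct_edge_set(connectome(m, "SC_trans"))$matrix[1, 2])
})

test_that("non-positive transformed weights are absent edges", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- -0.2 # negative after transform offset
  m[1, 3] <- m[3, 1] <- 1
  m[2, 3] <- m[3, 2] <- 1
  keep <- direct_edge_set(connectome(m, "SC_trans", tol = Inf))
  expect_false(keep$matrix[1, 2]) # never preserved
  expect_true(keep$matrix[1, 3]) # and it cannot serve as a path edge
  # a negative edge must not create an indirect route either: direct 1/1
  # would lose against |path| through a huge negative edge if it counted
  m2 <- triangle(1, -100, -100)$matrix
  expect_true(direct_edge_set(connectome(m2, "SC_trans", tol = Inf))$matrix[1, 2])
})

test_that("direct_edge_set agrees with exhaustive simple-path enumeration", {
  set.seed(20)
  for (rep in 1:60) {
    n <- sample(4:8, 1)
    w <- random_symmetric(n, function(k) runif(k, 0.1, 5))
    # random sparsity, occasionally non-positive entries
    zero <- random_symmetric(n, function(k) runif(k)) < 0.3
    w[zero] <- 0
    if (rep %% 5 == 0) w[1, 2] <- w[2, 1] <- -runif(1)
    got <- direct_edge_set(connectome(w, "SC_trans", tol = Inf))
    expect_identical(got$matrix, oracle_direct_edges(w),
                     label = sprintf("replicate %d", rep))
  }
})

test_that("strengthening an edge can only move it into the preserved set", {
  set.seed(21)
  for (rep in 1:20) {
    w <- random_symmetric(6, function(k) runif(k, 0.1, 3))
    base <- direct_edge_set(connectome(w, "SC_trans", tol = Inf))$matrix[1, 2]
    w2 <- w
    w2[1, 2] <- w2[2, 1] <- w[1, 2] * 2
    up <- direct_edge_set(connectome(w2, "SC_trans", tol = Inf))$matrix[1, 2]
    expect_true(!base || up) # preserved stays preserved
  }
})

test_that("intra-hemispheric mask counts match the combinatorics", {
  expect_equal(n_edges(intra_hemispheric_mask(tiny_parcellation(2))), 2L)
  expect_equal(n_edges(intra_hemispheric_mask(tiny_parcellation(42))), 1722L)
  expect_equal(n_edges(intra_hemispheric_mask(tiny_parcellation(1))), 0L)
  mask <- intra_hemispheric_mask(tiny_parcellation(2))
  expect_true(mask$matrix[1, 2]) # L1-L2
  expect_true(mask$matrix[3, 4]) # R1-R2
  expect_false(mask$matrix[1, 3]) # inter-hemispheric
})

test_that("the analysis mask requires bilateral membership in E_direct", {
  parc <- tiny_parcellation(3)
  n <- n_regions(parc)
  e_intra <- intra_hemispheric_mask(parc)
  direct <- matrix(FALSE, n, n)
  # L1-L2 and its homolog R1-R2 both direct -> both analysed
  direct[1, 2] <- direct[2, 1] <- TRUE
  direct[4, 5] <- direct[5, 4] <- TRUE
  # L1-L3 direct but homolog R1-R3 not -> neither analysed
  direct[1, 3] <- direct[3, 1] <- TRUE
  # inter-hemispheric edge in E_direct -> never analysed
  direct[1, 4] <- direct[4, 1] <- TRUE
  mask <- restrict_bilateral(edge_mask(direct, "E_direct"), e_intra, parc)
  expect_true(mask$matrix[1, 2])
  expect_true(mask$matrix[4, 5])
  expect_false(mask$matrix[1, 3])
  expect_false(mask$matrix[4, 6])
  expect_false(mask$matrix[1, 4])
  # bilateral symmetry invariant: edge in mask iff homolog image is
  hom <- parc$homolog
  expect_identical(mask$matrix, mask$matrix[hom, hom])
})

test_that("the analysis mask is invariant under swapping hemisphere labels", {
  set.seed(22)
  parc <- tiny_parcellation(4)
  w <- random_symmetric(8, function(k) runif(k, 0.05, 2))
  # mirror weights so both parcellations describe the same brain
  gst <- connectome(w, "SC_trans", tol = Inf)
  e_direct <- direct_edge_set(gst)
  m1 <- restrict_bilateral(e_direct, intra_hemispheric_mask(parc), parc)
  swapped <- parcellation(parc$label,
                          ifelse(parc$hemisphere == "left", "right", "left"),
                          parc$homolog)
  m2 <- restrict_bilateral(e_direct, intra_hemispheric_mask(swapped), swapped)
  expect_identical(m1$matrix, m2$matrix)
})

test_that("masks and edge reports round-trip to disk", {
  parc <- tiny_parcellation(2)
  direct <- matrix(FALSE, 4, 4)
  direct[1, 2] <- direct[2, 1] <- TRUE
  direct[3, 4] <- direct[4, 3] <- TRUE
  e_direct <- edge_mask(direct, "E_direct")
  mask <- restrict_bilateral(e_direct, intra_hemispheric_mask(parc), parc)
  path <- tempfile(fileext = ".csv")
  write_edge_mask(mask, path)
  expect_identical(read_edge_mask(path)$matrix, mask$matrix)
  rep <- edge_report(e_direct, mask, parc)
  expect_equal(nrow(rep), 6L)
  expect_equal(sum(rep$in_analysis), 2L)
  expect_equal(rep$region_a[rep$in_analysis], c("L1", "R1"))
})
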