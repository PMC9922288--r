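test_that("forward correspondences match the brute-force oracle", {
  set.seed(42)
  # identity: source == target
  m <- tiny_mesh()
  cs <- nearest_correspondences(m, m)
  expect_equal(cs$points, m$vertices)
  expect_true(all(cs$dist == 0))
  expect_true(all(cs$weights == 1))

  for (rep in 1:5) {
    src <- matrix(runif(15), 5, 3)
    tgt <- matrix(runif(21), 7, 3)
    cs <- nearest_correspondences(src, tgt)
    bf <- brute_nn(src, tgt)
    expect_identical(cs$target_index, bf$index)
    expect_equal(cs$dist, bf$dist)
  }

  cs <- nearest_correspondences(m, m, landmark_vertices = seq_len(nrow(m$vertices)))
  expect_true(all(cs$weights == 0))

  expect_error(nearest_correspondences(m, matrix(0, 0, 3)), "empty")
})

test_that("optional pruning zeroes border and normal-incompatible matches", {
  src <- hemisphere_mesh(1, 6, 12)
  tgt <- hemisphere_mesh(1.05, 8, 16)
  plain <- nearest_correspondences(src, tgt)
  expect_true(all(plain$weights == 1))

  pruned <- nearest_correspondences(src, tgt, prune = list(borders = TRUE))
  border <- unique(as.vector(cardiotrack:::boundary_directed_edges(tgt)))
  expect_true(all(pruned$weights[pruned$target_index %in% border] == 0))
  expect_true(any(pruned$weights == 0))
  expect_true(any(pruned$weights == 1))

  # flipped source normals oppose the target everywhere
  flipped <- src
  flipped$faces <- src$faces[, c(1, 3, 2)]
  pn <- nearest_correspondences(flipped, tgt, prune = list(normals = TRUE))
  expect_true(all(pn$weights == 0))
})

test_that("reverse correspondences match the oracle and allow duplicates", {
  m <- tiny_mesh()
  rc <- reverse_correspondences(seq_len(nrow(m$vertices)), m, m)
  expect_identical(rc$source_index, seq_len(nrow(m$vertices)))

  set.seed(7)
  src <- matrix(runif(24), 8, 3)
  tgt <- matrix(runif(30), 10, 3)
  sub <- c(2L, 5L, 9L)
  rc <- reverse_correspondences(sub, tgt, src)
  bf <- brute_nn(tgt[sub, , drop = FALSE], src)
  expect_identical(rc$source_index, bf$index)
  expect_equal(rc$target_points, tgt[sub, , drop = FALSE])

  # two target vertices nearest to the same source vertex are both kept
  src2 <- rbind(c(0, 0, 0), c(10, 0, 0))
  tgt2 <- rbind(c(0, 0.1, 0), c(0, -0.1, 0))
  rc2 <- reverse_correspondences(1:2, tgt2, src2)
  expect_identical(rc2$source_index, c(1L, 1L))

  expect_error(reverse_correspondences(integer(0), tgt, src), "empty")
})

test_that("poisson subsample is maximal, spaced and permutation-invariant", {
  m <- icosphere(1, 2)
  pts <- m$vertices
  diag_len <- sqrt(sum((apply(pts, 2, max) - apply(pts, 2, min))^2))

  # tiny radius keeps every vertex
  expect_identical(poisson_subsample(m, 1e-9), seq_len(nrow(pts)))

  # radius >= bbox diagonal keeps exactly one
  expect_length(poisson_subsample(m, 1.0), 1)

  sel <- poisson_subsample(m, 0.3)
  r <- 0.3 * diag_len
  d <- as.matrix(dist(pts[sel, ]))
  expect_true(all(d[upper.tri(d)] >= r))
  # maximality: every unselected vertex is within r of a selected one
  un <- setdiff(seq_len(nrow(pts)), sel)
  dmin <- apply(pts[un, , drop = FALSE], 1, function(p) {
    min(sqrt(colSums((t(pts[sel, , drop = FALSE]) - p)^2)))
  })
  expect_true(all(dmin < r))

  # storage permutation of vertices does not change the selected set
  set.seed(1)
  perm <- sample(nrow(pts))
  mp <- surface_mesh(pts[perm, ], matrix(match(m$faces, perm), ncol = 3))
  sel_p <- poisson_subsample(mp, 0.3)
  expect_setequal(perm[sel_p], sel)
})
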