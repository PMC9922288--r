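test_that("stiffness schedules match the stated endpoints and spacing", {
  ch <- make_stiffness_schedule("chambers")
  expect_length(ch, 100)
  expect_equal(ch[1], 100)
  expect_equal(ch[100], 1)
  laa <- make_stiffness_schedule("laa")
  expect_length(laa, 20)
  expect_equal(laa[1], 100)
  expect_equal(laa[20], 10)
  for (s in list(ch, laa)) {
    expect_true(all(diff(s) < 0))
    expect_lt(max(abs(diff(diff(s)))), 1e-9)  # uniform decrements
  }
  expect_error(make_stiffness_schedule("lungs"))
})

test_that("assembled system realizes the four cost terms exactly", {
  set.seed(11)
  cfg <- registration_config(gamma = 1.7, beta = 10, lambda_bidir = 0.5,
                             use_bidir = TRUE)
  for (rep in 1:5) {
    src <- tiny_mesh()
    src$vertices <- src$vertices + matrix(rnorm(36, sd = 0.05), ncol = 3)
    n <- nrow(src$vertices)
    tgt <- surface_mesh(src$vertices + matrix(rnorm(3 * n, sd = 0.1), ncol = 3),
                        src$faces)
    lm <- list(indices = c(1L, 4L), positions = matrix(rnorm(6), 2, 3))
    corr <- nearest_correspondences(src, tgt, lm$indices)
    rev <- reverse_correspondences(c(2L, 5L, 7L), tgt, src)
    alpha <- runif(1, 1, 50)
    sys <- assemble_system(src, corr, lm, alpha, cfg, rev)
    ne <- nrow(mesh_edges(src))
    expect_equal(unname(sys$block_rows),
                 c(4 * ne, n, 2L, 3L))
    X <- identity_transforms(n) + matrix(rnorm(4 * n * 3, sd = 0.1), ncol = 3)
    c1 <- system_cost(sys, X)
    c2 <- four_term_cost(src, X, corr, lm, alpha, cfg, rev)
    expect_lt(abs(c1 - c2) / c2, 1e-10)
  }
  # without landmarks / bi-directional: rows are 4e + n
  cfg0 <- registration_config()
  src <- tiny_mesh()
  corr <- nearest_correspondences(src, src)
  sys0 <- assemble_system(src, corr, NULL, 5, cfg0)
  expect_equal(nrow(sys0$A), 4 * nrow(mesh_edges(src)) + nrow(src$vertices))
  # identity transforms on identity correspondences: distance residual 0
  expect_lt(system_cost(sys0, identity_transforms(nrow(src$vertices))), 1e-20)
  expect_error(assemble_system(src, corr, NULL, 0, cfg0), "alpha")
})

test_that("optimal step equals the dense least-squares oracle", {
  set.seed(5)
  cfg <- registration_config(use_bidir = TRUE)
  for (rep in 1:6) {
    src <- tiny_mesh()
    tgt <- surface_mesh(src$vertices * 1.08 +
                          matrix(rnorm(36, sd = 0.05), ncol = 3), src$faces)
    lm <- if (rep %% 2) list(indices = 2L, positions = src$vertices[2, , drop = FALSE]) else NULL
    corr <- nearest_correspondences(src, tgt, if (is.null(lm)) integer(0) else lm$indices)
    rev <- if (rep %% 3) reverse_correspondences(c(1L, 6L), tgt, src) else NULL
    sys <- assemble_system(src, corr, lm, runif(1, 0.5, 20), cfg, rev)
    X <- optimal_step_solve(sys)
    Xd <- dense_solve(sys)
    expect_lt(max(abs(X - Xd)) / max(abs(Xd)), 1e-8)
  }
})

test_that("identity and rigid-translation limits", {
  src <- tiny_mesh()
  n <- nrow(src$vertices)
  # identity fixed point
  corr <- nearest_correspondences(src, src)
  sys <- assemble_system(src, corr, NULL, 7, registration_config())
  X <- optimal_step_solve(sys)
  pos <- as.matrix(homogeneous_layout(src$vertices) %*% X)
  expect_lt(max(abs(pos - src$vertices)), 1e-8 * 2)  # bbox diag ~2

  # cost-free translation: every vertex displaced by ~t
  t_vec <- c(0.3, -0.2, 0.5)
  tgt <- surface_mesh(sweep(src$vertices, 2, t_vec, "+"), src$faces)
  corr <- list(target_index = seq_len(n),
               points = tgt$vertices, weights = rep(1, n), dist = NULL)
  sys <- assemble_system(src, corr, NULL, 50, registration_config())
  X <- optimal_step_solve(sys)
  pos <- as.matrix(homogeneous_layout(src$vertices) %*% X)
  expect_lt(max(abs(pos - tgt$vertices)), 1e-6)
  expect_lt(max(abs(X - dense_solve(sys))), 1e-8)

  # alpha -> infinity forces equal per-vertex transforms
  sys_inf <- assemble_system(src, corr, NULL, 1e6, registration_config())
  Xi <- optimal_step_solve(sys_inf)
  blocks <- lapply(seq_len(n), function(i) Xi[(4 * i - 3):(4 * i), ])
  spread <- max(vapply(blocks, function(b) max(abs(b - blocks[[1]])), 0))
  expect_lt(spread, 1e-6)
})

test_that("inner steps never increase the cost under fixed correspondences", {
  set.seed(3)
  src <- tiny_mesh()
  tgt <- surface_mesh(src$vertices * 1.15 + matrix(rnorm(36, sd = 0.08), ncol = 3),
                      src$faces)
  cfg <- registration_config()
  X <- identity_transforms(nrow(src$vertices))
  D <- homogeneous_layout(src$vertices)
  for (alpha in c(50, 10, 2)) {
    corr <- nearest_correspondences(as.matrix(D %*% X), tgt)
    sys <- assemble_system(src, corr, NULL, alpha, cfg)
    X_new <- optimal_step_solve(sys)
    expect_lte(system_cost(sys, X_new), system_cost(sys, X) * (1 + 1e-12))
    X <- X_new
  }
})

test_that("register_surfaces: identity, scaling and landmark contracts", {
  src <- icosphere(0.3, 2, center = c(0.5, 0.5, 0.5))
  cfg <- registration_config(alpha_schedule = seq(100, 1, length.out = 10))
  diag_len <- sqrt(3) * 0.6

  r_id <- register_surfaces(src, src, NULL, cfg)
  expect_lt(max(abs(r_id$positions - src$vertices)), 1e-6 * diag_len)

  tgt <- icosphere(0.33, 3, center = c(0.5, 0.5, 0.5))
  r_sc <- register_surfaces(src, tgt, NULL, cfg)
  expect_lt(r_sc$mean_dist_end, 0.02 * diag_len)
  expect_lte(r_sc$mean_dist_end, r_sc$mean_dist_start)

  # frozen landmarks stay within 1% of size at beta = 10
  lm_idx <- c(1L, 5L, 9L)
  lm <- list(indices = lm_idx, positions = src$vertices[lm_idx, , drop = FALSE])
  r_lm <- register_surfaces(src, tgt, lm, cfg)
  lm_disp <- sqrt(rowSums((r_lm$positions[lm_idx, ] - src$vertices[lm_idx, ])^2))
  expect_lt(max(lm_disp), 0.01 * diag_len)
})
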