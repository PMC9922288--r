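# Optimal-step nonrigid ICP: per-vertex affine transforms X (4n x 3) found as
# the exact least-squares minimizer of a four-term stacked sparse system
# (stiffness, distance, landmark, bi-directional), iterated over a
# decreasing stiffness schedule with nearest-neighbor correspondences
# recomputed inside each stiffness step.

#' Registration configuration
#'
#' Collects all weights and schedules of the registration cost.
#'
#' @param alpha_schedule decreasing positive stiffness sequence; `NULL` means
#'   "choose from `region` at registration time" (see
#'   [make_stiffness_schedule()]).
#' @param gamma weight of the translation component inside the stiffness
#'   term (`G = diag(1, 1, 1, gamma)`); default 1.
#' @param beta landmark weight; default 10 (large enough that landmark
#'   vertices effectively do not move).
#' @param lambda_bidir weight of the bi-directional term; default 0.5.
#' @param use_bidir enable the bi-directional term (default `FALSE`; the
#'   tracking layer enables it for LAA passes, where it prevents the source
#'   from collapsing away from unexplained target regions).
#' @param subsample_radius_fraction exclusion radius of the bi-directional
#'   target subsample, as a fraction of the target bounding-box diagonal;
#'   default 0.05.
#' @param epsilon inner-loop convergence threshold on the Frobenius norm of
#'   the change in `X` (unit-cube coordinates); default 1e-4.
#' @param max_inner_iterations cap on inner iterations per stiffness value;
#'   default 10.
#' @param schedule_spacing `"linear"` (default) or `"geometric"` spacing of
#'   the stiffness schedule.
#' @param prune_borders,prune_normals optional correspondence pruning
#'   (drop matches to target-boundary vertices / normal-incompatible
#'   matches); both off by default.
#' @return object of class `registration_config`.
#' @export
registration_config <- function(alpha_schedule = NULL,
                                gamma = 1,
                                beta = 10,
                                lambda_bidir = 0.5,
                                use_bidir = FALSE,
                                subsample_radius_fraction = 0.05,
                                epsilon = 1e-4,
                                max_inner_iterations = 10L,
                                schedule_spacing = c("linear", "geometric"),
                                prune_borders = FALSE,
                                prune_normals = FALSE) {
  schedule_spacing <- match.arg(schedule_spacing)
  if (!is.null(alpha_schedule)) {
    if (any(alpha_schedule <= 0)) stop("alpha schedule must be strictly positive")
    if (any(diff(alpha_schedule) > 0)) stop("alpha schedule must be non-increasing")
  }
  if (beta < 0 || lambda_bidir < 0) stop("beta and lambda must be nonnegative")
  if (epsilon <= 0) stop("epsilon must be positive")
  structure(list(alpha_schedule = alpha_schedule, gamma = gamma, beta = beta,
                 lambda_bidir = lambda_bidir, use_bidir = use_bidir,
                 subsample_radius_fraction = subsample_radius_fraction,
                 epsilon = epsilon,
                 max_inner_iterations = as.integer(max_inner_iterations),
                 schedule_spacing = schedule_spacing,
                 prune_borders = prune_borders,
                 prune_normals = prune_normals),
            class = "registration_config")
}

#' Stiffness schedule for a registration pass
#'
#' The stiffness weight is lowered from 100 to 1 in 100 steps for the
#' chamber (LA + LV) registration and from 100 to 10 in 20 steps for the
#' LAA registration.  Steps are uniformly (linearly) spaced by default.
#'
#' @param region `"chambers"` or `"laa"`.
#' @param spacing `"linear"` or `"geometric"`.
#' @param n_steps override the number of steps (e.g. for reduced-schedule
#'   runs); endpoints are kept.
#' @return strictly decreasing numeric vector.
#' @export
make_stiffness_schedule <- function(region = c("chambers", "laa"),
                                    spacing = c("linear", "geometric"),
                                    n_steps = NULL) {
  region <- match.arg(region)
  spacing <- match.arg(spacing)
  ends <- switch(region, chambers = c(100, 1), laa = c(100, 10))
  k <- if (is.null(n_steps)) switch(region, chambers = 100L, laa = 20L)
       else as.integer(n_steps)
  if (k < 2) stop("schedule needs at least 2 steps")
  if (spacing == "linear") seq(ends[1], ends[2], length.out = k)
  else exp(seq(log(ends[1]), log(ends[2]), length.out = k))
}

#' Identity transform stack
#'
#' @param n number of source vertices.
#' @return 4n x 3 matrix whose 4 x 3 blocks are `rbind(diag(3), 0)`; applying
#'   it through the homogeneous layout reproduces source positions exactly.
#' @export
identity_transforms <- function(n) {
  block <- rbind(diag(3), rep(0, 3))
  do.call(rbind, rep(list(block), n))
}

#' Homogeneous source layout D
#'
#' Sparse n x 4n matrix in which source vertex i contributes its homogeneous
#' coordinate row `(x, y, z, 1)` against its own 4-column block, so that
#' `D %*% X` yields the n x 3 transformed positions.
#'
#' @param vertices n x 3 source coordinates.
#' @return sparse n x 4n matrix.
#' @export
homogeneous_layout <- function(vertices) {
  n <- nrow(vertices)
  Matrix::sparseMatrix(
    i = rep(seq_len(n), 4),
    j = c(4 * (seq_len(n) - 1) + 1, 4 * (seq_len(n) - 1) + 2,
          4 * (seq_len(n) - 1) + 3, 4 * seq_len(n)),
    x = c(vertices[, 1], vertices[, 2], vertices[, 3], rep(1, n)),
    dims = c(n, 4 * n))
}

#' Assemble the stacked registration system
#'
#' Builds the sparse design matrix and right-hand side whose least-squares
#' solution is the optimal transform stack for the current correspondences:
#' row blocks `alpha * (M x G)` (stiffness; `x` the Kronecker product),
#' `W D` (distance), `beta D_L` (landmarks) and `lambda D_Tar`
#' (bi-directional), against `0`, `W U`, `beta U_L` and `lambda U_Tar`.
#'
#' @param source a [surface_mesh] (current source topology and reference
#'   coordinates entering `D`).
#' @param correspondences forward correspondences from
#'   [nearest_correspondences()].
#' @param landmarks `NULL` or list with `indices` and `positions` (k x 3
#'   prescribed positions `U_L`).
#' @param alpha stiffness weight (> 0).
#' @param config a [registration_config()].
#' @param reverse `NULL` or reverse correspondences from
#'   [reverse_correspondences()]; used only when `config$use_bidir`.
#' @return object of class `registration_system`: list with sparse `A`,
#'   dense `B`, `n`, and `block_rows` (sizes 4e, n, k, r).
#' @export
assemble_system <- function(source, correspondences, landmarks = NULL,
                            alpha, config = registration_config(),
                            reverse = NULL) {
  if (alpha <= 0) stop("alpha must be > 0")
  v <- source$vertices
  n <- nrow(v)
  M <- build_incidence_matrix(source)
  G <- Matrix::Diagonal(4, c(1, 1, 1, config$gamma))
  MG <- Matrix::kronecker(M, G)
  D <- homogeneous_layout(v)
  w <- correspondences$weights
  Dw <- Matrix::Diagonal(n, w) %*% D
  U <- correspondences$points * w

  blocks_A <- list(alpha * MG, Dw)
  blocks_B <- list(matrix(0, nrow(MG), 3), U)
  k_lm <- 0L
  if (!is.null(landmarks) && length(landmarks$indices)) {
    if (any(landmarks$indices < 1L | landmarks$indices > n)) {
      stop("landmark indices out of range")
    }
    k_lm <- length(landmarks$indices)
    DL <- D[landmarks$indices, , drop = FALSE]
    blocks_A <- c(blocks_A, list(config$beta * DL))
    blocks_B <- c(blocks_B, list(config$beta * landmarks$positions))
  }
  k_rev <- 0L
  if (config$use_bidir && !is.null(reverse) && length(reverse$source_index)) {
    k_rev <- length(reverse$source_index)
    DT <- D[reverse$source_index, , drop = FALSE]
    blocks_A <- c(blocks_A, list(config$lambda_bidir * DT))
    blocks_B <- c(blocks_B, list(config$lambda_bidir * reverse$target_points))
  }
  structure(list(A = do.call(rbind, blocks_A),
                 B = do.call(rbind, blocks_B),
                 n = n,
                 block_rows = c(stiffness = nrow(MG), distance = n,
                                landmark = k_lm, bidirectional = k_rev)),
            class = "registration_system")
}

#' Total cost of a candidate transform stack
#'
#' Squared Frobenius residual of the stacked system; equals the sum of the
#' four squared-residual terms of the registration cost.
#'
#' @param system a `registration_system`.
#' @param X 4n x 3 transform stack.
#' @return nonnegative scalar.
#' @export
system_cost <- function(system, X) {
  r <- system$A %*% X - system$B
  sum(r^2)
}

#' Solve the registration system (optimal step)
#'
#' The unique linear least-squares minimizer of the stacked system, via the
#' sparse normal equations with a direct sparse Cholesky factorization.
#' Nonsingular whenever the stiffness weight is positive and the source mesh
#' is connected.
#'
#' @param system a `registration_system` from [assemble_system()].
#' @return the 4n x 3 transform stack `X`.
#' @export
optimal_step_solve <- function(system) {
  AtA <- Matrix::crossprod(system$A)
  AtB <- Matrix::crossprod(system$A, system$B)
  X <- tryCatch(
    Matrix::solve(AtA, AtB),
    error = function(e) {
      stop("registration system is singular (", conditionMessage(e),
           "); increase alpha or check that the source mesh is connected")
    })
  as.matrix(X)
}

#' Register a source surface onto a target surface
#'
#' Runs the optimal-step N-ICP loop: for each stiffness value of the
#' schedule, alternately recompute correspondences (forward, and reverse if
#' the bi-directional term is enabled) and solve the stacked least-squares
#' system, until the transform stack change falls below `config$epsilon` or
#' `config$max_inner_iterations` is hit.  Meshes are expected in normalized
#' (unit-cube) coordinates; see [normalize_to_unit_cube()].
#'
#' @param source a [surface_mesh].
#' @param target a [surface_mesh] (topology may differ from the source).
#' @param landmarks `NULL` or list with `indices` (into source vertices) and
#'   `positions` (prescribed k x 3 positions).
#' @param config a [registration_config()]; its `alpha_schedule` is used if
#'   set, otherwise the schedule for `region`.
#' @param region `"chambers"` or `"laa"`; selects the default stiffness
#'   schedule.
#' @return list with `positions` (final deformed n x 3 coordinates),
#'   `X` (final transform stack), `mean_dist_start`, `mean_dist_end`
#'   (mean source-to-target nearest distances before/after), and
#'   `iterations` (total inner iterations).
#' @export
register_surfaces <- function(source, target, landmarks = NULL,
                              config = registration_config(),
                              region = c("chambers", "laa")) {
  region <- match.arg(region)
  schedule <- config$alpha_schedule
  if (is.null(schedule)) {
    schedule <- make_stiffness_schedule(region, config$schedule_spacing)
  }
  n <- nrow(source$vertices)
  D <- homogeneous_layout(source$vertices)
  lm_idx <- if (is.null(landmarks)) integer(0) else landmarks$indices
  sub <- NULL
  if (config$use_bidir) {
    sub <- poisson_subsample(target, config$subsample_radius_fraction)
  }
  prune <- if (config$prune_borders || config$prune_normals) {
    list(borders = config$prune_borders, normals = config$prune_normals)
  } else NULL
  X <- identity_transforms(n)
  deformed <- as.matrix(D %*% X)
  start_dist <- mean(nn_index(deformed, target$vertices)$dist)
  iterations <- 0L
  for (alpha in schedule) {
    for (j in seq_len(config$max_inner_iterations)) {
      query <- if (is.null(prune)) deformed else {
        m <- source; m$vertices <- deformed; m
      }
      corr <- nearest_correspondences(query, target, lm_idx, prune)
      rev <- NULL
      if (config$use_bidir) {
        rev <- reverse_correspondences(sub, target, deformed)
      }
      system <- assemble_system(source, corr, landmarks, alpha, config, rev)
      X_new <- optimal_step_solve(system)
      delta <- sqrt(sum((X_new - X)^2))
      X <- X_new
      deformed <- as.matrix(D %*% X)
      iterations <- iterations + 1L
      if (delta < config$epsilon) break
    }
  }
  end_dist <- mean(nn_index(deformed, target$vertices)$dist)
  list(positions = deformed, X = X,
       mean_dist_start = start_dist, mean_dist_end = end_dist,
       iterations = iterations)
}
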