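# shared fixtures: brute-force oracles and small test meshes

# exhaustive nearest-neighbor scan (independent oracle for the kd-tree path)
brute_nn <- function(query, ref) {
  idx <- integer(nrow(query))
  d <- numeric(nrow(query))
  for (i in seq_len(nrow(query))) {
    dd <- sqrt(colSums((t(ref) - query[i, ])^2))
    idx[i] <- which.min(dd)
    d[i] <- dd[idx[i]]
  }
  list(index = idx, dist = d)
}

# hand-summed four-term registration cost (independent of the assembled system)
four_term_cost <- function(source, X, corr, landmarks, alpha, config, rev) {
  n <- nrow(source$vertices)
  blk <- function(i) X[(4 * (i - 1) + 1):(4 * i), , drop = FALSE]
  e <- mesh_edges(source)
  g <- c(1, 1, 1, config$gamma)
  stiff <- 0
  for (k in seq_len(nrow(e))) {
    d <- blk(e[k, 2]) - blk(e[k, 1])
    stiff <- stiff + sum((g * d)^2)
  }
  hom <- cbind(source$vertices, 1)
  pos <- t(vapply(seq_len(n), function(i) hom[i, ] %*% blk(i), numeric(3)))
  dist <- sum(corr$weights^2 * rowSums((pos - corr$points)^2))
  lmc <- 0
  if (!is.null(landmarks)) {
    lmc <- config$beta^2 *
      sum((pos[landmarks$indices, , drop = FALSE] - landmarks$positions)^2)
  }
  bid <- 0
  if (!is.null(rev)) {
    bid <- config$lambda_bidir^2 *
      sum((pos[rev$source_index, , drop = FALSE] - rev$target_points)^2)
  }
  alpha^2 * stiff + dist + lmc + bid
}

# dense least-squares oracle for the registration system
dense_solve <- function(system) {
  qr.solve(as.matrix(system$A), as.matrix(system$B))
}

# small connected test mesh (icosahedron, 12 vertices / 30 edges)
tiny_mesh <- function(radius = 1, center = c(0, 0, 0)) {
  icosphere(radius, subdivisions = 0, center = center)
}

# tetrahedron surface: 4 vertices, 4 faces, 6 edges, outward oriented
tetra_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  surface_mesh(v, f)
}

# coarse phantom for structural tests (fast to build)
coarse_phantom_spec <- function(...) {
  phantom_spec(mesh_resolution = 8, laa_axial_resolution = 2.5, ...)
}

# a tracked_sequence with prescribed per-frame positions built on a mesh
fake_sequence <- function(mesh, offsets, cycle_length = 1) {
  n_frames <- length(offsets)
  positions <- lapply(offsets, function(o) sweep(mesh$vertices, 2, o, "+"))
  structure(list(positions = positions, faces = mesh$faces,
                 labels = mesh$labels,
                 frame_times = (seq_len(n_frames) - 1) / n_frames * cycle_length,
                 cycle_length = cycle_length),
            class = "tracked_sequence")
}

# synthetic mitral flow curve: two filling pulses + one ejection pulse
synthetic_mv_curve <- function(dt = 0.005, T = 1, e_peak = 400, a_peak = 200,
                               e_time = 0.5, a_time = 0.8, sigma = 0.03,
                               shift = 0) {
  tt <- seq(0, T, by = dt)
  tw <- (tt - shift) %% T
  raw <- e_peak * exp(-(tw - e_time)^2 / (2 * sigma^2)) +
    a_peak * exp(-(tw - a_time)^2 / (2 * sigma^2)) -
    700 * exp(-(tw - 0.15)^2 / (2 * 0.05^2))
  structure(data.frame(time = tt, flow = pmax(raw, 0)),
            class = c("flow_curve", "data.frame"),
            raw = raw, dt = dt, orifice = "mitral")
}
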