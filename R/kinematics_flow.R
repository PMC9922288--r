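# Temporal B-spline smoothing of tracked trajectories, divergence-theorem
# volume curves on a 5 ms grid, flow curves by time differentiation, and the
# scalar flow indices (E/A peaks, time span, stroke volume, Ef/Af, LAA peak
# outflow, LAA area factor).

#' Fit per-vertex cubic B-spline motion
#'
#' Least-squares cubic B-spline over one cardiac cycle, per vertex and
#' coordinate, with `n_knots` uniformly spaced interior knots.  The sample
#' set is periodically extended by repeating frame 0 at `t = cycle_length`,
#' so the fitted motion closes the cycle.
#'
#' @param seq a `tracked_sequence` from [track_cycle()], or any list with
#'   `positions`, `frame_times`, `cycle_length`, `faces`, `labels`.
#' @param n_knots number of interior knots (default 15).
#' @param pad_frames number of frames wrapped around each end of the cycle
#'   before fitting, so the fit is smooth across the cycle seam (periodicity
#'   by sample extension).
#' @return object of class `spline_motion`; evaluate with [sample_motion()].
#' @export
fit_motion_splines <- function(seq, n_knots = 15, pad_frames = 3) {
  times <- seq$frame_times
  T <- seq$cycle_length
  n_frames <- length(seq$positions)
  if (n_frames < 8) stop("need at least 8 frames")
  df <- n_knots + 4
  if (df > n_frames + 1) {
    stop("n_knots too large for the frame count (need n_knots + 4 <= frames + 1)")
  }
  pad_frames <- min(pad_frames, n_frames - 1L)
  n <- nrow(seq$positions[[1]])
  # wrapped sample set: frames, frame 0 repeated at t = T, and pad_frames
  # extra wrapped frames on each side of the seam
  pre <- (n_frames - pad_frames + 1):n_frames
  post <- 2:(pad_frames + 1)
  ts <- c(times[pre] - T, times, T, times[post] + T)
  frames <- c(pre, seq_len(n_frames), 1L, post)
  Y <- matrix(0, length(frames), 3 * n)
  for (k in seq_along(frames)) Y[k, ] <- as.vector(seq$positions[[frames[k]]])
  # uniform cubic B-spline basis with n_knots interior knots in (0, T);
  # boundary knots continue the uniform spacing beyond the padded samples
  h <- T / (n_knots + 1)
  n_out <- ceiling(max(pad_frames * T / n_frames, 0) / h) + 4
  knots <- seq(-n_out * h, T + n_out * h, by = h)
  Phi <- splines::splineDesign(knots, ts, ord = 4)
  keep <- colSums(abs(Phi)) > 0                 # basis functions with support
  Phi <- Phi[, keep, drop = FALSE]
  coef_k <- qr.coef(qr(Phi), Y)
  coef_k[is.na(coef_k)] <- 0
  coef <- matrix(0, length(knots) - 4, 3 * n)
  coef[keep, ] <- coef_k
  fit_dev <- max(abs(Phi %*% coef_k - Y))
  structure(list(coef = coef, knots = knots, n = n,
                 cycle_length = T, n_knots = n_knots,
                 faces = seq$faces, labels = seq$labels,
                 fit_deviation = fit_dev),
            class = "spline_motion")
}

#' Evaluate spline motion
#'
#' @param motion a `spline_motion`.
#' @param t time(s) in seconds within `[0, cycle_length]`.
#' @return for a single time, an n x 3 position matrix; for several times, a
#'   list of such matrices.
#' @export
sample_motion <- function(motion, t) {
  t <- pmin(pmax(t, 0), motion$cycle_length)
  Phi <- splines::splineDesign(motion$knots, t, ord = 4)
  P <- Phi %*% motion$coef
  out <- lapply(seq_along(t), function(i) matrix(P[i, ], ncol = 3))
  if (length(t) == 1) out[[1]] else out
}

#' Time grid for spline export
#'
#' @param motion a `spline_motion`.
#' @param dt sample spacing in seconds (default 0.5 ms).
#' @return vector `seq(0, cycle_length, by = dt)` (for `T = 1` s and
#'   `dt = 0.5` ms: 2001 samples).
#' @export
motion_times <- function(motion, dt = 5e-4) {
  seq(0, motion$cycle_length, by = dt)
}

# precompute the capped submesh topology of a region so volumes can be
# evaluated at many time points without re-deriving connectivity
capped_region_topology <- function(motion, region) {
  mesh0 <- surface_mesh(sample_motion(motion, 0), motion$faces, motion$labels)
  sub <- extract_region(mesh0, motion$labels, region)
  loops <- boundary_loops(sub$mesh)
  capped <- cap_boundary_loops(sub$mesh)
  if (signed_volume_mm3(capped$vertices, capped$faces) < 0) {
    capped$faces <- capped$faces[, c(1, 3, 2)]
  }
  list(vertex_map = sub$vertex_map, n_sub = nrow(sub$mesh$vertices),
       loops = loops, faces = capped$faces)
}

capped_region_vertices <- function(topo, positions) {
  v <- positions[topo$vertex_map, , drop = FALSE]
  if (length(topo$loops)) {
    cents <- t(vapply(topo$loops,
                      function(l) colMeans(v[l, , drop = FALSE]), numeric(3)))
    v <- rbind(v, cents)
  }
  v
}

#' Volume curve of a region over the cycle
#'
#' Samples the spline motion on a uniform grid (default every 5 ms),
#' extracts the region submesh, caps its boundary loops (vessel cuts, the
#' mitral annulus for the LV, the ostium for the LAA) and applies the
#' divergence theorem.
#'
#' @param motion a `spline_motion` (carrying topology and labels).
#' @param region region name, e.g. `"LV"` or `"LAA"`.
#' @param dt grid spacing, s (default 0.005).
#' @return object of class `volume_curve`: data.frame with `time` (s) and
#'   `volume` (ml); attributes `region` and `dt`.
#' @export
volume_curve <- function(motion, region, dt = 0.005) {
  topo <- capped_region_topology(motion, region)
  times <- seq(0, motion$cycle_length, by = dt)
  pos <- sample_motion(motion, times)
  if (length(times) == 1) pos <- list(pos)
  vols <- vapply(pos, function(p) {
    v <- capped_region_vertices(topo, p)
    abs(signed_volume_mm3(v, topo$faces)) / 1000
  }, numeric(1))
  if (any(vols <= 0)) warning("non-positive region volume on the grid")
  structure(data.frame(time = times, volume = vols),
            class = c("volume_curve", "data.frame"),
            region = region, dt = dt)
}

# circular central difference of a cyclic sample series (first sample == last
# sample in phase); returns the derivative at every grid point
cyclic_derivative <- function(y, dt) {
  N <- length(y)
  m <- N - 1                       # unique phases
  yc <- y[seq_len(m)]
  d <- (yc[c(2:m, 1)] - yc[c(m, 1:(m - 1))]) / (2 * dt)
  c(d, d[1])
}

#' Transmitral flow curve from the LV volume curve
#'
#' Differentiates the LV volume with respect to time (cycle-wrapped central
#' differences).  Volume increase is transmitral inflow; the returned `flow`
#' holds the positive part (ejection-phase samples are 0 in the mitral
#' curve), while the uninterpreted derivative is kept in the `raw`
#' attribute.
#'
#' @param lv_volume a `volume_curve` of the LV.
#' @return object of class `flow_curve`: data.frame with `time` (s) and
#'   `flow` (ml/s); attributes `raw` (dV/dt) and `dt`.
#' @export
mitral_flow_curve <- function(lv_volume) {
  dt <- attr(lv_volume, "dt")
  q <- cyclic_derivative(lv_volume$volume, dt)
  structure(data.frame(time = lv_volume$time, flow = pmax(q, 0)),
            class = c("flow_curve", "data.frame"),
            raw = q, dt = dt, orifice = "mitral")
}

#' Default LAA orifice plane
#'
#' Least-squares plane through the `LAA_OSTIUM` ring at frame 0, oriented so
#' the LAA interior lies on the negative side; held static over the cycle.
#'
#' @param motion a `spline_motion`.
#' @return an [orifice_plane()].
#' @export
laa_orifice_plane <- function(motion) {
  pos0 <- sample_motion(motion, 0)
  ring <- which(motion$labels == REGION[["LAA_OSTIUM"]])
  laa <- which(motion$labels == REGION[["LAA"]])
  if (!length(ring) || !length(laa)) stop("labels lack LAA_OSTIUM / LAA")
  la <- which(motion$labels == REGION[["LA"]])
  fit_plane(pos0[ring, , drop = FALSE],
            toward = colMeans(pos0[la, , drop = FALSE]))
}

#' LAA outflow curve through a static orifice plane
#'
#' The LAA volume on the grid is the part of the capped LAA submesh on the
#' negative side of the (static) orifice plane, obtained by exact plane
#' clipping; outflow is `-dV/dt` (emptying positive).
#'
#' @param motion a `spline_motion`.
#' @param plane an [orifice_plane()]; default [laa_orifice_plane()].
#' @param dt grid spacing, s.
#' @param separation_tol maximal allowed distance of the frame-0 ostium ring
#'   from the plane, as a fraction of the LAA extent (validation that the
#'   plane separates LAA from LA).
#' @return `flow_curve` with attributes `volumes` (the clipped LAA volume
#'   curve) and `raw`.
#' @export
laa_flow_curve <- function(motion, plane = laa_orifice_plane(motion),
                           dt = 0.005, separation_tol = 0.15) {
  pos0 <- sample_motion(motion, 0)
  ring <- which(motion$labels == REGION[["LAA_OSTIUM"]])
  d0 <- abs(as.numeric(sweep(pos0[ring, , drop = FALSE], 2, plane$point) %*%
                         plane$normal))
  laa_ids <- which(motion$labels %in% REGION[c("LAA", "LAA_OSTIUM")])
  ext <- max(apply(pos0[laa_ids, , drop = FALSE], 2,
                   function(x) diff(range(x))))
  if (max(d0) > separation_tol * ext) {
    stop("orifice plane does not separate LAA from LA (ostium ring is ",
         signif(max(d0), 3), " mm from the plane)")
  }
  topo <- capped_region_topology(motion, "LAA")
  times <- seq(0, motion$cycle_length, by = dt)
  pos <- sample_motion(motion, times)
  if (length(times) == 1) pos <- list(pos)
  vols <- vapply(pos, function(p) {
    v <- capped_region_vertices(topo, p)
    m <- surface_mesh(v, topo$faces)
    enclosed_volume(clip_by_plane(m, plane), warn_orientation = FALSE)
  }, numeric(1))
  q <- -cyclic_derivative(vols, dt)
  structure(data.frame(time = times, flow = q),
            class = c("flow_curve", "data.frame"),
            raw = q, dt = dt, orifice = "laa",
            volumes = data.frame(time = times, volume = vols))
}

#' Per-frame LAA surface area
#'
#' @param seq a `tracked_sequence`.
#' @return numeric vector: LAA-region surface area (mm^2) at each frame.
#' @export
laa_area_series <- function(seq) {
  laa_mask <- seq$labels %in% REGION[c("LAA", "LAA_OSTIUM")]
  f <- seq$faces
  fmask <- laa_mask[f[, 1]] & laa_mask[f[, 2]] & laa_mask[f[, 3]]
  vapply(seq$positions, function(p) {
    surface_area(list(vertices = p, faces = f[fmask, , drop = FALSE]))
  }, numeric(1))
}

# local maxima of a cyclic-ordered series (strict left, non-strict right)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Clinical flow metrics from the mitral and LAA flow curves
#'
#' Diastole is located as the contiguous (cycle-wrapped) interval where the
#' raw dV/dt stays above minus 10% of its maximum (tolerating smoothing
#' ripple around diastasis) and which contains the global mitral-flow
#' maximum.  The E peak is the first and the A peak the last local maximum
#' inside diastole (peaks below 10% of the global maximum are ignored); they
#' must be distinct, at least 5% of the cycle apart and separated by a local
#' minimum, otherwise the curve is reported as not E/A-separable.  Stroke
#' volume is the net integral of raw dV/dt over diastole, which equals the
#' diastolic volume rise and is insensitive to smoothing ripple.
#'
#' @param mv mitral `flow_curve`.
#' @param laa LAA `flow_curve` (may be `NULL`: LAA metrics become `NA`).
#' @param areas per-frame LAA areas from [laa_area_series()] (may be `NULL`).
#' @return object of class `flow_metrics`: list with `e_peak`, `a_peak`
#'   (ml/s), `e_time`, `a_time`, `peak_time_span` (s), `stroke_volume` (ml),
#'   `ef_af_ratio`, `laa_peak_outflow` (ml/s), `laa_peak_time` (s),
#'   `laa_area_factor`.
#' @export
flow_metrics <- function(mv, laa = NULL, areas = NULL) {
  dt <- attr(mv, "dt")
  raw <- attr(mv, "raw")
  m <- nrow(mv) - 1                      # unique cyclic phases
  rawc <- raw[seq_len(m)]
  flowc <- mv$flow[seq_len(m)]
  tol <- 0.10 * max(rawc)
  pos_mask <- rawc > -tol
  imax <- which.max(flowc)
  if (!pos_mask[imax]) stop("no positive inflow interval found")
  # grow the contiguous circular run of non-negative inflow around the max
  wrap <- function(i) (i - 1) %% m + 1
  if (all(pos_mask)) {
    run <- wrap(imax:(imax + m - 1))
  } else {
    lo <- imax
    while (pos_mask[wrap(lo - 1)]) lo <- lo - 1
    hi <- imax
    while (pos_mask[wrap(hi + 1)]) hi <- hi + 1
    run <- wrap(lo:hi)
  }
  # trim the ends to non-negative inflow so the interval starts and ends at
  # the volume extremes rather than inside the ejection tail
  while (length(run) > 2 && rawc[run[1]] < 0) run <- run[-1]
  while (length(run) > 2 && rawc[run[length(run)]] < 0) run <- run[-length(run)]
  x <- flowc[run]

  peaks <- local_maxima(c(-Inf, x, -Inf)) - 1L   # allow peaks at run ends
  peaks <- peaks[x[peaks] >= 0.10 * max(x)]      # ignore low-lying ripple
  if (length(peaks) < 2) stop("E/A not separable: fewer than two distinct diastolic maxima")
  e_i <- peaks[1]
  a_i <- peaks[length(peaks)]
  if ((a_i - e_i) * dt < 0.05 * (m * dt)) {
    stop("E/A not separable: peaks closer than 5% of the cycle")
  }
  valley <- min(x[e_i:a_i])
  if (!(valley < x[e_i] && valley < x[a_i])) {
    stop("E/A not separable: no local minimum between the peaks")
  }
  e_peak <- x[e_i]; a_peak <- x[a_i]
  e_time <- mv$time[run[e_i]]
  a_time <- mv$time[run[a_i]]
  # net transmitral volume over diastole (the raw derivative integrates to
  # the volume change, so smoothing ripple does not inflate the estimate)
  sv <- sum(rawc[run]) * dt

  laa_peak <- NA_real_; laa_peak_time <- NA_real_
  if (!is.null(laa)) {
    j <- which.max(laa$flow)
    laa_peak <- laa$flow[j]
    laa_peak_time <- laa$time[j]
  }
  area_factor <- if (is.null(areas)) NA_real_ else max(areas) / min(areas)

  structure(list(e_peak = e_peak, a_peak = a_peak,
                 e_time = e_time, a_time = a_time,
                 peak_time_span = (a_i - e_i) * dt,
                 stroke_volume = sv,
                 ef_af_ratio = e_peak / a_peak,
                 laa_peak_outflow = laa_peak,
                 laa_peak_time = laa_peak_time,
                 laa_area_factor = area_factor),
            class = "flow_metrics")
}

#' @export
print.flow_metrics <- function(x, ...) {
  cat("Flow metrics:\n")
  cat(sprintf("  E peak          %8.1f ml/s at %.3f s\n", x$e_peak, x$e_time))
  cat(sprintf("  A peak          %8.1f ml/s at %.3f s\n", x$a_peak, x$a_time))
  cat(sprintf("  peak time span  %8.3f s\n", x$peak_time_span))
  cat(sprintf("  stroke volume   %8.1f ml\n", x$stroke_volume))
  cat(sprintf("  Ef/Af ratio     %8.2f\n", x$ef_af_ratio))
  if (!is.na(x$laa_peak_outflow)) {
    cat(sprintf("  LAA peak outflow%8.1f ml/s at %.3f s\n",
                x$laa_peak_outflow, x$laa_peak_time))
  }
  if (!is.na(x$laa_area_factor)) {
    cat(sprintf("  LAA area factor %8.2f\n", x$laa_area_factor))
  }
  invisible(x)
}
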