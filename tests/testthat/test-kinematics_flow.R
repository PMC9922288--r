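test_that("spline motion reproduces constant and harmonic trajectories", {
  m <- tiny_mesh()
  # constant trajectory -> constant spline, zero deviation
  seq_c <- fake_sequence(m, rep(list(c(0, 0, 0)), 20))
  mot <- fit_motion_splines(seq_c)
  expect_lt(mot$fit_deviation, 1e-9)
  expect_lt(max(abs(sample_motion(mot, 0.37) - m$vertices)), 1e-9)

  # single harmonic sampled at 20 frames: reproduced within 2% of amplitude
  A <- 5
  tt <- (0:19) / 20
  seq_h <- fake_sequence(m, lapply(tt, function(t) c(A * sin(2 * pi * t), 0, 0)))
  mot_h <- fit_motion_splines(seq_h)
  tg <- seq(0, 1, by = 0.01)
  for (t in tg) {
    err <- sample_motion(mot_h, t)[1, 1] - (m$vertices[1, 1] + A * sin(2 * pi * t))
    expect_lt(abs(err), 0.02 * A)
  }

  # 0.5 ms export grid: T / 0.0005 + 1 samples
  expect_length(motion_times(mot_h, 5e-4), 2001)

  expect_error(fit_motion_splines(seq_c, n_knots = 30), "n_knots too large")
})

test_that("volume curve: translation invariance and grid layout", {
  ph <- generate_phantom_cycle(coarse_phantom_spec())
  src <- ph$source
  # rigid translation per frame: region volume constant to 1e-6 relative
  offs <- lapply((0:19) / 20, function(t) c(10 * sin(2 * pi * t), 5 * t, 0))
  seq_t <- fake_sequence(surface_mesh(src$vertices, src$faces, ph$labels), offs)
  mot <- fit_motion_splines(seq_t)
  vc <- volume_curve(mot, "LV", dt = 0.05)
  expect_lt(diff(range(vc$volume)) / mean(vc$volume), 1e-6)

  # dt = cycle/4 gives 5 inclusive grid points
  vc4 <- volume_curve(mot, "LV", dt = 0.25)
  expect_length(vc4$time, 5)
})

test_that("spline smoothing does not bias the cycle-mean volume", {
  # phantom truth frames as a perfectly tracked sequence
  spec <- coarse_phantom_spec()
  fam <- cardiotrack:::build_phantom_family(spec)
  tt <- (0:19) / 20
  pos <- lapply(tt, function(t) cardiotrack:::family_state(fam, spec, t))
  seqp <- structure(list(positions = pos, faces = fam$mesh$faces,
                         labels = fam$labels, frame_times = tt,
                         cycle_length = 1), class = "tracked_sequence")
  mot <- fit_motion_splines(seqp)
  vc <- volume_curve(mot, "LV", dt = 0.01)
  frame_means <- vapply(pos, function(p) {
    m <- surface_mesh(p, fam$mesh$faces, fam$labels)
    s <- extract_region(m, fam$labels, "LV")
    enclosed_volume(cap_boundary_loops(s$mesh), warn_orientation = FALSE)
  }, 0)
  expect_lt(abs(mean(vc$volume) - mean(frame_means)) / mean(frame_means), 0.01)
})

test_that("mitral flow differentiates the volume curve", {
  # linear ramp: exact central difference in the interior
  tt <- seq(0, 1, by = 0.005)
  ramp <- structure(data.frame(time = tt, volume = 50 + 100 * tt),
                    class = c("volume_curve", "data.frame"), dt = 0.005)
  q <- mitral_flow_curve(ramp)
  interior <- 2:(length(tt) - 2)
  expect_lt(max(abs(q$flow[interior] - 100)), 1e-9)

  const <- structure(data.frame(time = tt, volume = rep(80, length(tt))),
                     class = c("volume_curve", "data.frame"), dt = 0.005)
  expect_true(all(mitral_flow_curve(const)$flow == 0))
})

test_that("LAA flow: static LAA gives zero flow and near-zero circulation", {
  ph <- generate_phantom_cycle(coarse_phantom_spec())
  m <- surface_mesh(ph$source$vertices, ph$source$faces, ph$labels)
  seq_s <- fake_sequence(m, rep(list(c(0, 0, 0)), 20))
  mot <- fit_motion_splines(seq_s)
  laa <- laa_flow_curve(mot, dt = 0.05)
  expect_lt(max(abs(laa$flow)), 1e-9)
  vols <- attr(laa, "volumes")$volume
  expect_true(all(vols > 0))
  # periodic volume: net circulation below 1% of the maximal LAA volume
  expect_lt(abs(sum(laa$flow[-1]) * 0.05), 0.01 * max(vols))

  # a plane far from the ostium fails the separation check
  bad <- orifice_plane(colMeans(m$vertices) + c(0, 0, 80), c(0, 0, 1))
  expect_error(laa_flow_curve(mot, plane = bad), "does not separate")
})

test_that("flow metrics: constructed two-peak curve and invariances", {
  mv <- synthetic_mv_curve()
  met <- flow_metrics(mv)
  expect_lt(abs(met$e_peak - 400) / 400, 0.01)
  expect_lt(abs(met$a_peak - 200) / 200, 0.01)
  expect_lt(abs(met$e_time - 0.5), 0.006)
  expect_lt(abs(met$a_time - 0.8), 0.006)
  expect_lt(abs(met$peak_time_span - 0.3), 0.011)
  expect_lt(abs(met$ef_af_ratio - 2), 0.02)
  # integral of the two Gaussians
  sv_expect <- (400 + 200) * sqrt(2 * pi) * 0.03
  expect_lt(abs(met$stroke_volume - sv_expect) / sv_expect, 0.02)

  # time-origin shift leaves the metrics unchanged
  met_s <- flow_metrics(synthetic_mv_curve(shift = 0.37))
  for (f in c("e_peak", "a_peak", "peak_time_span", "stroke_volume",
              "ef_af_ratio")) {
    expect_lt(abs(met_s[[f]] - met[[f]]) / abs(met[[f]]), 0.02)
  }

  # grid refinement changes the peaks by < 2%
  met_f <- flow_metrics(synthetic_mv_curve(dt = 0.0025))
  expect_lt(abs(met_f$e_peak - met$e_peak) / met$e_peak, 0.02)
  expect_lt(abs(met_f$a_peak - met$a_peak) / met$a_peak, 0.02)

  # LAA channel and area factor
  laa <- structure(data.frame(time = mv$time,
                              flow = 30 * exp(-(mv$time - 0.65)^2 / (2 * 0.02^2))),
                   class = c("flow_curve", "data.frame"),
                   raw = NULL, dt = 0.005)
  met_l <- flow_metrics(mv, laa, areas = rep(1200, 20))
  expect_lt(abs(met_l$laa_peak_outflow - 30) / 30, 0.01)
  expect_equal(met_l$laa_area_factor, 1)

  # single-peak curve is reported as not separable
  single <- synthetic_mv_curve(a_peak = 0)
  expect_error(flow_metrics(single), "E/A not separable")
})
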