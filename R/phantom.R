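# Deforming left-heart phantom (LV + LA + LAA) with analytic ground truth.
#
# Geometry: LV and LA are truncated ellipsoids of revolution sharing a fixed
# mitral annulus ring at z = 0; the LA roof carries an open pulmonary-vein
# cut (boundary ring) and a carved wall patch whose perimeter is the LAA
# ostium ring, from which a tapered LAA tube extends outward.  Motion is a
# one-parameter contraction field per region (linear in its parameter, zero
# on the annulus / ostium / boundary rings), and the per-frame parameter is
# root-solved so that the *meshed* capped chamber volume equals the
# closed-form truth volume curve exactly.  Volume recovery errors in
# downstream tests therefore isolate registration + smoothing error.

# ---- C-infinity monotone transition (compact support) -----------------------

# S: [0,1] -> [0,1], smooth with all derivatives vanishing at both ends.
smoothstep <- function(s) {
  out <- numeric(length(s))
  out[s >= 1] <- 1
  mid <- s > 0 & s < 1
  if (any(mid)) {
    f <- function(x) exp(-1 / x)
    out[mid] <- f(s[mid]) / (f(s[mid]) + f(1 - s[mid]))
  }
  out
}

smoothstep_deriv <- function(s) {
  out <- numeric(length(s))
  mid <- s > 0 & s < 1
  if (any(mid)) {
    x <- s[mid]
    f <- exp(-1 / x)
    g <- exp(-1 / (1 - x))
    fp <- f / x^2
    gp <- g / (1 - x)^2
    out[mid] <- (fp * g + f * gp) / (f + g)^2
  }
  out
}

# cumulative pulse: area * S((t - (center - hw)) / (2 hw)), periodic in T
pulse_cum <- function(t, center, halfwidth, area, T) {
  area * smoothstep(((t %% T) - (center - halfwidth)) / (2 * halfwidth))
}

pulse_rate <- function(t, center, halfwidth, area, T) {
  area * smoothstep_deriv(((t %% T) - (center - halfwidth)) / (2 * halfwidth)) /
    (2 * halfwidth)
}

# ---- phantom specification --------------------------------------------------

#' Phantom specification
#'
#' States the simulated physiology of the deforming left-heart phantom.
#' Times are fractions of the cardiac cycle (0.55 = 55% RR).  Defaults
#' describe a healthy-range heart: stroke volume 70 ml with a dominant
#' early-filling wave (E at 55% RR, A at 85% RR, 70/30 split), and an LAA
#' emptying from 8 to 3 ml with peak contraction late in the cycle.
#'
#' @param cycle_length cycle duration, s.
#' @param n_frames number of reconstructed phases (fixed grid 0, 5, ... 95%
#'   RR for the default 20).
#' @param lv_edv,lv_esv LV end-diastolic / end-systolic volume, ml.
#' @param e_fraction,a_fraction split of the filling volume between the E
#'   and A waves (must sum to 1).
#' @param e_time,a_time E / A wave centers as fractions of RR.
#' @param pulse_halfwidth filling-pulse half-support as a fraction of RR
#'   (each wave spans `center +- pulse_halfwidth`).
#' @param ejection_time,ejection_halfwidth systolic ejection pulse center
#'   and half-support (fractions of RR).
#' @param laa_vmax,laa_vmin LAA maximum / minimum volume, ml.
#' @param laa_contraction_time time of minimal LAA volume (fraction of RR).
#' @param laa_dip_power sharpness of the LAA emptying dip (cosine-power
#'   profile; larger = more rapid late contraction).
#' @param mesh_resolution target element size, mm.
#' @param laa_axial_resolution element size along the LAA tube axis, mm
#'   (the LAA is meshed finer than the chambers).
#' @param target_jitter_sd Gaussian noise added to target vertices, mm.
#' @param seed RNG seed for the jitter.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(cycle_length = 1.0, n_frames = 20L,
                         lv_edv = 120, lv_esv = 50,
                         e_fraction = 0.7, a_fraction = 0.3,
                         e_time = 0.55, a_time = 0.85,
                         pulse_halfwidth = 0.10,
                         ejection_time = 0.17, ejection_halfwidth = 0.15,
                         laa_vmax = 8, laa_vmin = 3,
                         laa_contraction_time = 0.90,
                         laa_dip_power = 4,
                         mesh_resolution = 4,
                         laa_axial_resolution = 1,
                         target_jitter_sd = 0,
                         seed = 1L) {
  if (!(lv_edv > lv_esv && lv_esv > 0)) stop("need lv_edv > lv_esv > 0")
  if (abs(e_fraction + a_fraction - 1) > 1e-12) {
    stop("e_fraction + a_fraction must equal 1")
  }
  if (!(laa_vmax > laa_vmin && laa_vmin > 0)) stop("need laa_vmax > laa_vmin > 0")
  if (e_time - pulse_halfwidth <= ejection_time + ejection_halfwidth) {
    stop("E wave overlaps ejection; adjust timings")
  }
  if (a_time - pulse_halfwidth <= e_time + pulse_halfwidth) {
    stop("E and A waves overlap; adjust timings")
  }
  if (a_time + pulse_halfwidth >= 1) stop("A wave must end before cycle end")
  structure(as.list(environment()), class = "phantom_spec")
}

# ---- closed-form truth curves ----------------------------------------------

#' Analytic phantom truth at arbitrary times
#'
#' Closed-form evaluation of the phantom's volume and flow-rate curves.
#' `Q_MV` is the raw LV volume derivative (transmitral inflow positive,
#' systolic ejection negative); `Q_LAA` is the LAA outflow (emptying
#' positive).  `A_LAA` is the idealized self-similar LAA surface area,
#' `A ~ V^(2/3)`, normalized so that `A_LAA = area_ref` at `V = laa_vmax`.
#'
#' @param spec a [phantom_spec()].
#' @param t time(s) in seconds, within `[0, cycle_length]` (periodic).
#' @param area_ref reference LAA area at maximal volume (mm^2); default 1
#'   gives the dimensionless area factor.
#' @return data.frame with columns `t`, `V_LV`, `V_LAA`, `A_LAA`, `Q_MV`,
#'   `Q_LAA`.
#' @export
phantom_truth_at <- function(spec, t, area_ref = 1) {
  T <- spec$cycle_length
  sv <- spec$lv_edv - spec$lv_esv
  e_c <- spec$e_time * T; a_c <- spec$a_time * T
  ej_c <- spec$ejection_time * T
  hw <- spec$pulse_halfwidth * T
  ej_hw <- spec$ejection_halfwidth * T
  V_LV <- spec$lv_edv -
    pulse_cum(t, ej_c, ej_hw, sv, T) +
    pulse_cum(t, e_c, hw, spec$e_fraction * sv, T) +
    pulse_cum(t, a_c, hw, spec$a_fraction * sv, T)
  Q_MV <- -pulse_rate(t, ej_c, ej_hw, sv, T) +
    pulse_rate(t, e_c, hw, spec$e_fraction * sv, T) +
    pulse_rate(t, a_c, hw, spec$a_fraction * sv, T)
  tc <- spec$laa_contraction_time * T
  p <- spec$laa_dip_power
  b <- (1 + cos(2 * pi * (t - tc) / T)) / 2
  V_LAA <- spec$laa_vmin + (spec$laa_vmax - spec$laa_vmin) * (1 - b^p)
  db <- -pi / T * sin(2 * pi * (t - tc) / T)
  Q_LAA <- (spec$laa_vmax - spec$laa_vmin) * p * b^(p - 1) * db
  A_LAA <- area_ref * (V_LAA / spec$laa_vmax)^(2 / 3)
  data.frame(t = t, V_LV = V_LV, V_LAA = V_LAA, A_LAA = A_LAA,
             Q_MV = Q_MV, Q_LAA = Q_LAA)
}

#' Analytic truth flow metrics of a phantom
#'
#' E and A peaks are at the centers of their (symmetric) filling pulses with
#' closed-form heights; the LAA outflow peak is located on a fine grid of
#' the closed-form outflow curve.
#'
#' @param spec a [phantom_spec()].
#' @return list with `e_peak`, `a_peak`, `e_time`, `a_time`,
#'   `peak_time_span`, `stroke_volume` (ml, ml/s, s), `ef_af_ratio`,
#'   `laa_peak_outflow`, `laa_peak_time`, `laa_area_factor`.
#' @export
phantom_truth_metrics <- function(spec) {
  T <- spec$cycle_length
  sv <- spec$lv_edv - spec$lv_esv
  hw <- spec$pulse_halfwidth * T
  sp_mid <- smoothstep_deriv(0.5)
  e_peak <- spec$e_fraction * sv * sp_mid / (2 * hw)
  a_peak <- spec$a_fraction * sv * sp_mid / (2 * hw)
  tg <- seq(0, T, by = T / 20000)
  q <- phantom_truth_at(spec, tg)$Q_LAA
  i <- which.max(q)
  list(e_peak = e_peak, a_peak = a_peak,
       e_time = spec$e_time * T, a_time = spec$a_time * T,
       peak_time_span = (spec$a_time - spec$e_time) * T,
       stroke_volume = sv,
       ef_af_ratio = e_peak / a_peak,
       laa_peak_outflow = q[i], laa_peak_time = tg[i],
       laa_area_factor = (spec$laa_vmax / spec$laa_vmin)^(2 / 3))
}

# ---- mesh family builder ----------------------------------------------------

# Builds one resolution level of the phantom: reference mesh + labels +
# per-region linear displacement fields.  phi_offset rotates the angular
# grid so source and target tessellations are never index-aligned.
build_phantom_family <- function(spec, resolution = spec$mesh_resolution,
                                 phi_offset = 0,
                                 laa_axial = spec$laa_axial_resolution,
                                 laa_len = 45, laa_taper = 0.3) {
  # --- chamber sizing from target volumes (continuous ellipsoid formulas) --
  cap_factor <- function(u) 2 / 3 + u - u^3 / 3     # V = pi a^2 c * cap_factor
  v_lv_ref <- spec$lv_edv * 1000 * 1.10             # mm^3, headroom above EDV
  u0_lv <- 0.75; c_over_a <- 1.6
  a_lv <- (v_lv_ref / (pi * c_over_a * cap_factor(u0_lv)))^(1 / 3)
  c_lv <- c_over_a * a_lv
  h_lv <- u0_lv * c_lv
  r_ann <- a_lv * sqrt(1 - u0_lv^2)
  u0_la <- 0.7
  a_la <- r_ann / sqrt(1 - u0_la^2)
  c_la <- a_la
  h_la <- u0_la * c_la
  theta_a <- acos(u0_lv)                   # LV junction polar angle
  theta_j <- acos(-u0_la)                  # LA junction polar angle
  theta_pv <- asin(0.25)                   # pulmonary-vein cut

  n_phi <- max(16L, round(2 * pi * max(a_lv, a_la) / resolution))
  phi <- phi_offset + 2 * pi * (seq_len(n_phi) - 1) / n_phi
  n_la <- max(5L, round(c_la * (theta_j - theta_pv) / resolution))
  n_lv <- max(5L, round(c_lv * (pi - theta_a) / resolution))

  th_la <- seq(theta_pv, theta_j, length.out = n_la + 1)   # rows 0..n_la
  th_lv <- seq(theta_a, pi, length.out = n_lv + 1)         # annulus..apex

  # vertex rows: LA rows 0..n_la (row n_la = annulus), LV rows 1..n_lv-1,
  # then the apex vertex
  rows <- list()
  row_label <- integer(0)
  for (i in 0:n_la) {
    th <- th_la[i + 1]
    rows[[length(rows) + 1]] <- cbind(a_la * sin(th) * cos(phi),
                                      a_la * sin(th) * sin(phi),
                                      h_la + c_la * cos(th))
    row_label <- c(row_label,
                   if (i == 0) REGION[["BOUNDARY_RING"]]
                   else if (i == n_la) REGION[["LV"]]      # annulus ring
                   else REGION[["LA"]])
  }
  for (i in 1:(n_lv - 1)) {
    th <- th_lv[i + 1]
    rows[[length(rows) + 1]] <- cbind(a_lv * sin(th) * cos(phi),
                                      a_lv * sin(th) * sin(phi),
                                      -h_lv + c_lv * cos(th))
    row_label <- c(row_label, REGION[["LV"]])
  }
  n_rows <- length(rows)
  verts <- do.call(rbind, rows)
  labels <- rep(row_label, each = n_phi)
  apex <- c(0, 0, -h_lv - c_lv)
  verts <- rbind(verts, apex)
  labels <- c(labels, REGION[["LV"]])
  apex_i <- nrow(verts)
  idx <- function(i, j) (i * n_phi) + ((j - 1L) %% n_phi) + 1L  # i = 0-based row

  j_all <- seq_len(n_phi)
  faces <- matrix(integer(0), 0, 3)
  for (i in 0:(n_rows - 2)) {
    v00 <- idx(i, j_all); v01 <- idx(i, j_all + 1L)
    v10 <- idx(i + 1L, j_all); v11 <- idx(i + 1L, j_all + 1L)
    faces <- rbind(faces, cbind(v00, v10, v11), cbind(v00, v11, v01))
  }
  last <- n_rows - 1L
  faces <- rbind(faces, cbind(idx(last, j_all), apex_i, idx(last, j_all + 1L)))

  # --- carve the ostium patch on the LA wall ------------------------------
  k_taper <- integrate(function(s) (1 - laa_taper * s)^2, 0, 1)$value  # mean tau^2
  r_ost <- sqrt(spec$laa_vmax * 1000 * 1.17 / (pi * laa_len * k_taper))
  th_c <- theta_pv + 0.45 * (theta_j - theta_pv)
  i_c <- round((th_c - theta_pv) / (th_la[2] - th_la[1]))
  d_th <- th_la[2] - th_la[1]
  dr <- max(1L, round(r_ost / (c_la * d_th)))
  dc <- max(1L, round(r_ost / (a_la * sin(th_c) * (2 * pi / n_phi))))
  i1 <- i_c - dr; i2 <- i_c + dr            # vertex row range of the patch
  if (i1 < 1L || i2 > n_la - 1L) stop("infeasible phantom spec: LAA patch does not fit on the LA wall")
  if (2L * dc + 1L > n_phi - 2L) stop("infeasible phantom spec: LAA patch too wide")
  j_c <- 1L                                  # patch centered at phi ~ 0
  js <- ((j_c - dc - 1L):(j_c + dc - 1L)) %% n_phi + 1L  # vertex cols j1..j2
  # faces inside the patch: both rows in [i1, i2-1], cols within patch span
  in_patch_vert <- matrix(FALSE, nrow(verts), 1)
  patch_vids <- as.vector(outer(i1:i2, js, function(i, j) idx(i, j)))
  in_patch_vert[patch_vids] <- TRUE
  fmask <- in_patch_vert[faces[, 1]] & in_patch_vert[faces[, 2]] &
    in_patch_vert[faces[, 3]]
  faces <- faces[!fmask, , drop = FALSE]

  # ostium perimeter loop, ordered; interior patch vertices become the tube
  per <- c(idx(i1, (j_c - dc):(j_c + dc)),
           idx((i1 + 1):(i2), j_c + dc),
           idx(i2, rev((j_c - dc):(j_c + dc - 1))),
           idx(rev((i1 + 1):(i2 - 1)), j_c - dc))
  interior <- setdiff(patch_vids, per)
  labels[per] <- REGION[["LAA_OSTIUM"]]

  # --- LAA tube -----------------------------------------------------------
  cen0 <- colMeans(verts[per, , drop = FALSE])
  nrm <- c(cen0[1] / a_la^2, cen0[2] / a_la^2, (cen0[3] - h_la) / c_la^2)
  nrm <- nrm / sqrt(sum(nrm^2))
  shape <- sweep(verts[per, , drop = FALSE], 2, cen0)
  shape <- shape - outer(as.numeric(shape %*% nrm), nrm)  # project to cross-plane
  # the LAA is meshed finer along its axis than the chambers (the source
  # surface uses smaller triangles in the LAA region); the low final
  # stiffness of the LAA schedule needs a dense transform sampling along
  # the contraction gradient to express the large emptying deformation
  K <- max(4L, round(laa_len / min(resolution, laa_axial)))
  tube_rows <- list()
  for (k in 1:K) {
    tau <- 1 - laa_taper * (k / K)
    ck <- cen0 + (k / K) * laa_len * nrm
    tube_rows[[k]] <- sweep(tau * shape, 2, ck, "+")
  }
  tube_v <- do.call(rbind, tube_rows)
  tip <- cen0 + 1.04 * laa_len * nrm
  base_i <- nrow(verts)
  verts <- rbind(verts, tube_v, tip)
  labels <- c(labels, rep(REGION[["LAA"]], nrow(tube_v) + 1L))
  tip_i <- nrow(verts)
  L <- length(per)
  ring_ids <- function(k) if (k == 0) per else base_i + (k - 1L) * L + seq_len(L)
  # wind the tube so its ring-0 edges run opposite to the carved hole's
  # boundary direction (keeps the whole mesh consistently oriented)
  hole_be <- boundary_directed_edges(list(vertices = verts, faces = faces))
  forward <- any(hole_be[, 1] == per[1] & hole_be[, 2] == per[2])
  nx <- c(2:L, 1)
  for (k in 1:K) {
    r0 <- ring_ids(k - 1L); r1 <- ring_ids(k)
    if (forward) {
      faces <- rbind(faces, cbind(r0[nx], r0, r1), cbind(r0[nx], r1, r1[nx]))
    } else {
      faces <- rbind(faces, cbind(r0, r0[nx], r1[nx]), cbind(r0, r1[nx], r1))
    }
  }
  rl <- ring_ids(K)
  faces <- rbind(faces,
                 if (forward) cbind(rl[nx], rl, tip_i) else cbind(rl, rl[nx], tip_i))

  # drop the interior patch vertices, reindex everything
  keep <- setdiff(seq_len(nrow(verts)), interior)
  remap <- integer(nrow(verts))
  remap[keep] <- seq_along(keep)
  verts <- verts[keep, , drop = FALSE]
  labels <- labels[keep]
  faces <- matrix(remap[faces], ncol = 3)
  per <- remap[per]
  tip_i <- remap[tip_i]

  mesh <- surface_mesh(verts, faces, labels)
  # global orientation: capped LV must have positive signed volume
  lv <- extract_region(mesh, labels, "LV")
  lv_closed <- cap_boundary_loops(lv$mesh)
  if (signed_volume_mm3(lv_closed$vertices, lv_closed$faces) < 0) {
    faces <- faces[, c(1, 3, 2)]
    mesh <- surface_mesh(verts, faces, labels)
  }

  # --- linear displacement fields -----------------------------------------
  n <- nrow(verts)
  depth <- h_lv + c_lv
  z_top <- h_la + c_la * cos(theta_pv)
  d_lv <- matrix(0, n, 3)
  lv_mask <- labels == REGION[["LV"]] & verts[, 3] <= 0
  w_lv <- pmin(1, -verts[lv_mask, 3] / (0.6 * depth))
  d_lv[lv_mask, 1] <- -verts[lv_mask, 1] * w_lv
  d_lv[lv_mask, 2] <- -verts[lv_mask, 2] * w_lv

  d_la <- matrix(0, n, 3)
  la_mask <- labels %in% REGION[c("LA", "LAA_OSTIUM")] & verts[, 3] > 0
  w_la <- sin(pi * pmin(1, pmax(0, verts[la_mask, 3] / z_top)))^2
  d_la[la_mask, 1] <- -verts[la_mask, 1] * w_la
  d_la[la_mask, 2] <- -verts[la_mask, 2] * w_la
  # the LAA tube rides rigidly on the mean ostium-ring displacement
  delta_ost <- colMeans(d_la[per, , drop = FALSE])
  laa_mask <- labels == REGION[["LAA"]]
  d_la[laa_mask, ] <- matrix(delta_ost, sum(laa_mask), 3, byrow = TRUE)

  d_laa <- matrix(0, n, 3)
  for (k in 1:K) {
    ids <- remap[base_i + (k - 1L) * L + seq_len(L)]
    ck <- cen0 + (k / K) * laa_len * nrm
    # near-uniform radial emptying (ramp over the proximal half): the sack
    # narrows everywhere instead of pancaking at the tip, as a real LAA does
    d_laa[ids, ] <- -sweep(verts[ids, , drop = FALSE], 2, ck) * min(1, 2 * k / K)
  }
  # tip stays on the axis (zero radial offset)

  list(mesh = mesh, labels = labels, ostium = per, tip = tip_i,
       d_lv = d_lv, d_la = d_la, d_laa = d_laa,
       params = list(a_lv = a_lv, c_lv = c_lv, h_lv = h_lv, r_ann = r_ann,
                     a_la = a_la, c_la = c_la, h_la = h_la,
                     laa_len = laa_len, n_phi = n_phi))
}

# positions of the family at given region parameters
family_positions <- function(fam, u_lv = 0, u_la = 0, u_laa = 0) {
  fam$mesh$vertices + u_lv * fam$d_lv + u_la * fam$d_la + u_laa * fam$d_laa
}

# capped region volume (ml) of the family at given parameters
family_region_volume <- function(fam, region, u_lv = 0, u_la = 0, u_laa = 0) {
  m <- fam$mesh
  m$vertices <- family_positions(fam, u_lv, u_la, u_laa)
  sub <- extract_region(m, fam$labels, region)
  enclosed_volume(cap_boundary_loops(sub$mesh), warn_orientation = FALSE)
}

# solve the region parameter so the meshed volume matches v_target (ml)
family_solve_u <- function(fam, region, v_target, u_la = 0,
                           bracket = c(-0.5, 0.95)) {
  f <- function(u) {
    if (region == "LV") family_region_volume(fam, "LV", u_lv = u) - v_target
    else family_region_volume(fam, "LAA", u_la = u_la, u_laa = u) - v_target
  }
  lo <- f(bracket[1]); hi <- f(bracket[2])
  if (lo < 0 || hi > 0) {
    stop("infeasible phantom spec: cannot reach a ", region, " volume of ",
         signif(v_target, 4), " ml")
  }
  uniroot(f, bracket, tol = 1e-12)$root
}

# full solved state (vertex positions) of a family at cycle time t
family_state <- function(fam, spec, t) {
  tr <- phantom_truth_at(spec, t)
  u_lv <- family_solve_u(fam, "LV", tr$V_LV)
  u_la <- 0.12 * (tr$V_LV - spec$lv_esv) / (spec$lv_edv - spec$lv_esv)
  u_laa <- family_solve_u(fam, "LAA", tr$V_LAA, u_la = u_la)
  family_positions(fam, u_lv, u_la, u_laa)
}

# ---- public generator -------------------------------------------------------

#' Generate a deforming left-heart phantom cycle
#'
#' Produces the labeled source surface at 0% RR, per-frame chamber and LAA
#' target surfaces (independently remeshed at a different tessellation than
#' the source, optionally jittered), and the analytic ground truth.  Frame
#' meshes satisfy the truth volume curves exactly: the capped LV and LAA
#' submesh volumes equal `V_LV(t)` and `V_LAA(t)` to root-solver precision.
#'
#' @param spec a [phantom_spec()].
#' @return list with `source` (labeled [surface_mesh]), `labels`,
#'   `targets_full` (list of chamber-only target meshes, one per frame),
#'   `targets_laa` (list of LAA target meshes), `frame_times` (s), `truth`
#'   (see [phantom_truth_at()] / [phantom_truth_metrics()]; includes the
#'   frame-resolved truth table), and `spec`.
#' @export
generate_phantom_cycle <- function(spec = phantom_spec()) {
  set.seed(spec$seed)
  t_frames <- (seq_len(spec$n_frames) - 1) / spec$n_frames * spec$cycle_length

  src_fam <- build_phantom_family(spec, spec$mesh_resolution, phi_offset = 0)
  # targets emulate dense threshold-segmentation isosurfaces: much finer
  # than the regularized source mesh, so nearest-vertex correspondences are
  # not limited by target vertex spacing
  tgt_fam <- build_phantom_family(spec, spec$mesh_resolution * 0.4,
                                  phi_offset = pi / 32,
                                  laa_axial = spec$laa_axial_resolution * 0.5)

  src_mesh <- src_fam$mesh
  src_mesh$vertices <- family_state(src_fam, spec, 0)

  targets_full <- vector("list", spec$n_frames)
  targets_laa <- vector("list", spec$n_frames)
  for (k in seq_len(spec$n_frames)) {
    m <- tgt_fam$mesh
    m$vertices <- family_state(tgt_fam, spec, t_frames[k])
    full <- extract_region(m, tgt_fam$labels, "chambers")$mesh
    laa <- extract_region(m, tgt_fam$labels, "LAA")$mesh
    if (spec$target_jitter_sd > 0) {
      full$vertices <- full$vertices +
        matrix(rnorm(length(full$vertices), sd = spec$target_jitter_sd),
               ncol = 3)
      laa$vertices <- laa$vertices +
        matrix(rnorm(length(laa$vertices), sd = spec$target_jitter_sd),
               ncol = 3)
    }
    targets_full[[k]] <- full
    targets_laa[[k]] <- laa
  }

  truth_frames <- phantom_truth_at(spec, t_frames)
  truth <- list(at = function(t) phantom_truth_at(spec, t),
                frames = truth_frames,
                metrics = phantom_truth_metrics(spec),
                edv = spec$lv_edv, esv = spec$lv_esv)

  list(source = src_mesh, labels = src_fam$labels,
       targets_full = targets_full, targets_laa = targets_laa,
       frame_times = t_frames, truth = truth, spec = spec)
}
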