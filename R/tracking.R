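# Orchestrates registration through the 20-phase cardiac cycle:
# normalization to the unit cube, chamber-then-LAA two-pass registration per
# frame, forward and backward chains meeting at mid-cycle.

#' Normalize meshes jointly into the unit cube
#'
#' A single isotropic scale and translation maps the union bounding box of
#' all given meshes into `[0, 1]^3` (longest axis spans `[0, 1]`), so
#' relative geometry between meshes is preserved.  The transform is exactly
#' invertible.
#'
#' @param meshes a [surface_mesh] or list of them.
#' @param cube `"unit"` (default, `[0,1]^3`) or `"symmetric"` (`[-1,1]^3`,
#'   the literal reading of a symmetric normalization cube; twice the
#'   scale).
#' @return list with `meshes` (scaled, same shape as the input) and
#'   `transform` (list with `scale` and `offset`; forward map is
#'   `(x - offset) * scale + shift`).
#' @export
normalize_to_unit_cube <- function(meshes, cube = c("unit", "symmetric")) {
  cube <- match.arg(cube)
  single <- inherits(meshes, "surface_mesh")
  ml <- if (single) list(meshes) else meshes
  if (!length(ml)) stop("no meshes")
  allv <- do.call(rbind, lapply(ml, function(m) m$vertices))
  lo <- apply(allv, 2, min)
  hi <- apply(allv, 2, max)
  ext <- max(hi - lo)
  if (ext <= 0) stop("degenerate (zero-extent) geometry")
  tf <- if (cube == "unit") list(scale = 1 / ext, offset = lo, shift = 0)
        else list(scale = 2 / ext, offset = lo, shift = -1)
  out <- lapply(ml, function(m) {
    m$vertices <- apply_unit_transform(m$vertices, tf)
    m
  })
  list(meshes = if (single) out[[1]] else out, transform = tf)
}

#' Apply / invert the unit-cube normalization
#'
#' @param x n x 3 coordinate matrix.
#' @param transform transform from [normalize_to_unit_cube()].
#' @return transformed n x 3 matrix.
#' @export
apply_unit_transform <- function(x, transform) {
  shift <- transform$shift %||% 0
  sweep(x, 2, transform$offset) * transform$scale + shift
}

#' @rdname apply_unit_transform
#' @export
invert_unit_transform <- function(x, transform) {
  shift <- transform$shift %||% 0
  sweep((x - shift) / transform$scale, 2, transform$offset, "+")
}

#' Default registration configurations for cycle tracking
#'
#' Chamber passes run the 100-step (100 to 1) stiffness schedule without the
#' bi-directional term; LAA passes run the 20-step (100 to 10) schedule with
#' the bi-directional term enabled.  `fast = TRUE` shortens the schedules to
#' 25 and 10 steps (same endpoints) for reduced-scale runs.
#'
#' @param fast use the reduced schedules.
#' @param ... further arguments passed to both [registration_config()] calls.
#' @return list with elements `chambers` and `laa`.
#' @export
default_tracking_configs <- function(fast = FALSE, ...) {
  list(
    chambers = registration_config(
      alpha_schedule = make_stiffness_schedule("chambers",
                                               n_steps = if (fast) 25L else NULL),
      use_bidir = FALSE, ...),
    laa = registration_config(
      alpha_schedule = make_stiffness_schedule("laa",
                                               n_steps = if (fast) 10L else NULL),
      use_bidir = TRUE, ...))
}

#' Track one frame transition (two-pass registration)
#'
#' Pass 1 registers the chamber submesh (everything except the LAA interior)
#' onto the full-chamber target with all `BOUNDARY_RING` vertices held as
#' landmarks at their frame-0 positions (vessel cuts are non-moving).
#' Pass 2 registers the LAA submesh onto the LAA target with the
#' `LAA_OSTIUM` ring held as landmarks at its pass-1 positions, using the
#' LAA schedule and the bi-directional term.  Results are merged into one
#' full-mesh position array; merged ostium positions are the pass-1 results
#' (prescribed landmarks are copied, not re-solved).
#'
#' All coordinates are expected in normalized (unit-cube) space.
#'
#' @param current_vertices n x 3 current (previous-frame) positions.
#' @param faces,labels topology and region labels of the tracked mesh.
#' @param target_full chamber target [surface_mesh] for this frame.
#' @param target_laa LAA target [surface_mesh] for this frame (`NULL` is an
#'   error: frames with missing LAA coverage cannot be tracked).
#' @param frame0_vertices n x 3 frame-0 positions (landmark anchors for the
#'   boundary rings).
#' @param configs list with `chambers` and `laa` registration configs (see
#'   [default_tracking_configs()]).
#' @return n x 3 matrix of next-frame positions.
#' @export
track_frame <- function(current_vertices, faces, labels, target_full,
                        target_laa, frame0_vertices,
                        configs = default_tracking_configs()) {
  if (is.null(target_laa)) stop("missing LAA target for this frame")
  mesh_now <- surface_mesh(current_vertices, faces, labels)

  # pass 1: chambers
  ch <- extract_region(mesh_now, labels, "chambers")
  ch_labels <- labels[ch$vertex_map]
  ring_sub <- which(ch_labels == REGION[["BOUNDARY_RING"]])
  lm1 <- if (length(ring_sub)) {
    list(indices = ring_sub,
         positions = frame0_vertices[ch$vertex_map[ring_sub], , drop = FALSE])
  } else NULL
  reg1 <- register_surfaces(ch$mesh, target_full, lm1, configs$chambers,
                            region = "chambers")
  out <- write_back(current_vertices, reg1$positions, ch$vertex_map)

  # pass 2: LAA, ostium prescribed from pass 1
  laa <- extract_region(surface_mesh(out, faces, labels), labels, "LAA")
  laa_labels <- labels[laa$vertex_map]
  ost_sub <- which(laa_labels == REGION[["LAA_OSTIUM"]])
  lm2 <- list(indices = ost_sub,
              positions = out[laa$vertex_map[ost_sub], , drop = FALSE])
  reg2 <- register_surfaces(laa$mesh, target_laa, lm2, configs$laa,
                            region = "laa")
  out2 <- write_back(out, reg2$positions, laa$vertex_map)
  # prescribed ostium landmarks are copied from pass 1, not re-solved
  ost_parent <- laa$vertex_map[ost_sub]
  out2[ost_parent, ] <- out[ost_parent, ]
  attr(out2, "pass1_positions") <- out
  attr(out2, "ostium_vertices") <- ost_parent
  out2
}

#' Track a full cardiac cycle
#'
#' Registers the frame-0 source chain-wise through the 20 phases: forward
#' 0% -> 5% -> ... -> 50% RR and backward 0% -> 95% -> ... -> 50% RR, each
#' step using the previous result as the new source.  The 50% RR frame is
#' the per-vertex arithmetic mean of the forward and backward results; every
#' other frame comes from exactly one chain.  All registrations run in
#' jointly normalized unit-cube coordinates computed once from the source.
#'
#' @param source labeled source [surface_mesh] at 0% RR.
#' @param labels per-vertex region codes (defaults to `source$labels`).
#' @param targets_full list of 20 chamber target meshes (frames 0,5,...,95%
#'   RR; frame 1 corresponds to the source phase and is not registered to).
#' @param targets_laa list of 20 LAA target meshes.
#' @param configs see [default_tracking_configs()].
#' @param cycle_length cycle duration in seconds.
#' @return object of class `tracked_sequence`: list with `positions` (list
#'   of 20 n x 3 matrices, mm), `faces`, `labels`, `frame_times` (s),
#'   `cycle_length`.  Attribute `chains` records which chain produced each
#'   frame.
#' @export
track_cycle <- function(source, labels = source$labels, targets_full,
                        targets_laa, configs = default_tracking_configs(),
                        cycle_length = 1.0) {
  n_frames <- 20L
  if (length(targets_full) != n_frames || length(targets_laa) != n_frames) {
    stop("expected ", n_frames, " target frames (0 to 95% RR in 5% steps)")
  }
  if (is.null(labels)) stop("source labels required")
  nrm <- normalize_to_unit_cube(source)
  tf <- nrm$transform
  src_n <- nrm$meshes
  tgt_full_n <- lapply(targets_full, function(m) {
    m$vertices <- apply_unit_transform(m$vertices, tf); m
  })
  tgt_laa_n <- lapply(targets_laa, function(m) {
    if (is.null(m)) return(NULL)
    m$vertices <- apply_unit_transform(m$vertices, tf); m
  })

  faces <- source$faces
  v0 <- src_n$vertices
  positions <- vector("list", n_frames)
  chains <- character(n_frames)
  positions[[1]] <- source$vertices   # frame-0 identity, bit-exact
  chains[1] <- "source"

  mid <- n_frames / 2 + 1L            # frame index of 50% RR
  # forward chain: frames 2 .. mid
  cur <- v0
  forward_mid <- NULL
  for (k in 2:mid) {
    cur <- track_frame(cur, faces, labels, tgt_full_n[[k]], tgt_laa_n[[k]],
                       v0, configs)
    attr(cur, "pass1_positions") <- NULL
    attr(cur, "ostium_vertices") <- NULL
    if (k < mid) {
      positions[[k]] <- invert_unit_transform(cur, tf)
      chains[k] <- "forward"
    } else {
      forward_mid <- cur
    }
  }
  # backward chain: frames 20, 19, .. mid
  cur <- v0
  backward_mid <- NULL
  for (k in n_frames:mid) {
    cur <- track_frame(cur, faces, labels, tgt_full_n[[k]], tgt_laa_n[[k]],
                       v0, configs)
    attr(cur, "pass1_positions") <- NULL
    attr(cur, "ostium_vertices") <- NULL
    if (k > mid) {
      positions[[k]] <- invert_unit_transform(cur, tf)
      chains[k] <- "backward"
    } else {
      backward_mid <- cur
    }
  }
  positions[[mid]] <- invert_unit_transform((forward_mid + backward_mid) / 2, tf)
  chains[mid] <- "blended"

  structure(list(positions = positions, faces = faces, labels = labels,
                 frame_times = (seq_len(n_frames) - 1) / n_frames * cycle_length,
                 cycle_length = cycle_length),
            class = "tracked_sequence",
            chains = chains)
}

#' @export
print.tracked_sequence <- function(x, ...) {
  cat(sprintf("tracked_sequence: %d frames, %d vertices, cycle %.3g s\n",
              length(x$positions), nrow(x$positions[[1]]), x$cycle_length))
  invisible(x)
}
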