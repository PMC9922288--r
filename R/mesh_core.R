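#' @useDynLib cardiotrack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods as
#' @importFrom stats rnorm runif sd uniroot
#' @importFrom utils read.csv write.csv head tail
NULL

# ---- region label coding ----------------------------------------------------

#' Region label codes
#'
#' Integer codes used in per-vertex region label vectors.  Every vertex of a
#' labeled left-heart surface carries exactly one of these codes:
#' left ventricle (`LV`), left atrium (`LA`), left atrial appendage interior
#' (`LAA`), open-boundary rings at vessel cuts (`BOUNDARY_RING`, e.g.
#' pulmonary veins / aorta), and the closed ring of vertices at the LAA
#' ostium (`LAA_OSTIUM`) which is shared between the LA and the LAA.
#'
#' @format A named integer vector with elements `LV`, `LA`, `LAA`,
#'   `BOUNDARY_RING`, `LAA_OSTIUM`.
#' @export
REGION <- c(LV = 1L, LA = 2L, LAA = 3L, BOUNDARY_RING = 4L, LAA_OSTIUM = 5L)

#' Resolve a region specifier to integer label codes
#'
#' @param region a character vector of region names (see [REGION]), the
#'   special name `"chambers"` (= LV + LA + BOUNDARY_RING + LAA_OSTIUM),
#'   or integer codes.
#' @return integer vector of label codes.
#' @keywords internal
region_codes <- function(region) {
  if (is.numeric(region)) {
    codes <- as.integer(region)
    if (!all(codes %in% REGION)) stop("unknown region code(s): ",
                                      paste(setdiff(codes, REGION), collapse = ", "))
    return(codes)
  }
  if (identical(region, "chambers")) {
    return(unname(REGION[c("LV", "LA", "BOUNDARY_RING", "LAA_OSTIUM")]))
  }
  bad <- setdiff(region, names(REGION))
  if (length(bad)) stop("unknown region label(s): ", paste(bad, collapse = ", "))
  unname(REGION[region])
}

# ---- surface mesh -----------------------------------------------------------

#' Create a triangle surface mesh
#'
#' The basic geometric container of the package: an oriented triangle mesh
#' with vertex coordinates in millimetres.  Faces are 1-based index triples;
#' consistent orientation (outward normals for closed regions) is assumed by
#' the volume routines and validated there.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param labels optional integer vector of per-vertex region codes
#'   (see [REGION]).
#' @return an object of class `surface_mesh`: a list with elements
#'   `vertices`, `faces` and optionally `labels`.
#' @export
#' @examples
#' m <- surface_mesh(rbind(c(0,0,0), c(1,0,0), c(0,1,0)), rbind(c(1,2,3)))
#' surface_area(m)
surface_mesh <- function(vertices, faces, labels = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 3) stop("vertices must be n x 3")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (length(faces) && ncol(faces) != 3) stop("faces must be m x 3")
  n <- nrow(vertices)
  if (length(faces)) {
    if (min(faces) < 1L || max(faces) > n) stop("face indices out of range [1, n]")
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3])) {
      stop("degenerate faces (repeated vertex indices) are not allowed")
    }
  }
  m <- list(vertices = vertices, faces = faces)
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n) stop("labels must have one entry per vertex")
    if (!all(labels %in% REGION)) stop("labels contain unknown region codes")
    m$labels <- labels
  }
  class(m) <- "surface_mesh"
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$labels)) ", labeled" else ""))
  invisible(x)
}

#' Unique undirected edges of a mesh
#'
#' @param mesh a [surface_mesh].
#' @return integer e x 2 matrix, each row `(i, j)` with `i < j`, sorted
#'   lexicographically.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  if (!length(f)) return(matrix(integer(0), 0, 2))
  e <- rbind(f[, 1:2, drop = FALSE], f[, 2:3, drop = FALSE], f[, c(3, 1), drop = FALSE])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

#' Node-arc incidence matrix of a mesh
#'
#' One row per unique undirected edge and one column per vertex; the row for
#' edge `(i, j)` (with `i < j`) holds `-1` at column `i` and `+1` at column
#' `j`.  This is the connectivity operator of the stiffness term of the
#' registration cost: `M %*% P` computes edge-wise differences of any
#' per-vertex quantity `P`.
#'
#' @param mesh a [surface_mesh] with at least one edge.
#' @return a [Matrix::sparseMatrix] of dimension e x n.
#' @export
build_incidence_matrix <- function(mesh) {
  e <- mesh_edges(mesh)
  if (!nrow(e)) stop("no edges")
  ne <- nrow(e)
  Matrix::sparseMatrix(
    i = c(seq_len(ne), seq_len(ne)),
    j = c(e[, 1], e[, 2]),
    x = c(rep(-1, ne), rep(1, ne)),
    dims = c(ne, nrow(mesh$vertices)))
}

# directed edges that appear in only one face (mesh boundary), in face order
boundary_directed_edges <- function(mesh) {
  f <- mesh$faces
  if (!length(f)) return(matrix(integer(0), 0, 2))
  de <- rbind(f[, 1:2, drop = FALSE], f[, 2:3, drop = FALSE], f[, c(3, 1), drop = FALSE])
  n <- nrow(mesh$vertices)
  key <- (de[, 1] - 1) * n + de[, 2]       # directed key
  rkey <- (de[, 2] - 1) * n + de[, 1]      # reverse key
  de[!(rkey %in% key), , drop = FALSE]
}

#' Boundary loops of a mesh
#'
#' @param mesh a [surface_mesh].
#' @return list of integer vectors, each an ordered closed loop of vertex
#'   indices following boundary edge direction.  Errors on non-manifold
#'   boundaries (a vertex with more than one outgoing boundary edge).
#' @export
boundary_loops <- function(mesh) {
  be <- boundary_directed_edges(mesh)
  if (!nrow(be)) return(list())
  if (anyDuplicated(be[, 1])) {
    v <- be[duplicated(be[, 1]), 1][1]
    bad <- be[be[, 1] == v, , drop = FALSE]
    stop(sprintf("non-manifold boundary at edge (%d, %d)", bad[1, 1], bad[1, 2]))
  }
  nxt <- integer(max(be))
  nxt[be[, 1]] <- be[, 2]
  remaining <- be[, 1]
  loops <- list()
  visited <- logical(max(be))
  for (s in sort(remaining)) {
    if (visited[s]) next
    loop <- integer(0)
    v <- s
    repeat {
      if (visited[v]) stop("open boundary chain; mesh boundary is not a set of closed loops")
      loop <- c(loop, v)
      visited[v] <- TRUE
      v <- nxt[v]
      if (v == s) break
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Enclosed volume of a closed oriented mesh (divergence theorem)
#'
#' Computes `|sum_f v1 . (v2 x v3)| / 6`, converted from cubic millimetres to
#' millilitres.  The mesh must be closed (no boundary edges); cap open
#' boundaries first with [cap_boundary_loops()].  If the signed volume is
#' negative (inward orientation) the absolute value is returned with a
#' warning.
#'
#' @param mesh a closed, consistently oriented [surface_mesh].
#' @param warn_orientation warn when the signed volume is negative.
#' @return volume in ml.
#' @export
enclosed_volume <- function(mesh, warn_orientation = TRUE) {
  if (!nrow(mesh$faces)) return(0)
  if (nrow(boundary_directed_edges(mesh))) {
    stop("mesh not closed; cap boundaries first")
  }
  s <- signed_volume_mm3(mesh$vertices, mesh$faces)
  if (s < 0 && warn_orientation) {
    warning("mesh orientation is inward (signed volume < 0); reporting |volume|")
  }
  abs(s) / 1000
}

# signed volume in mm^3 for a vertex/face pair (no closedness check)
signed_volume_mm3 <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
      a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Total surface area of a mesh
#'
#' @param mesh a [surface_mesh].
#' @return area in mm^2 (sum of triangle areas; degenerate triangles
#'   contribute zero).
#' @export
surface_area <- function(mesh) {
  f <- mesh$faces
  if (!length(f)) return(0)
  v <- mesh$vertices
  ab <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  ac <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2]
  cy <- ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3]
  cz <- ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Close all boundary loops of a mesh with centroid fans
#'
#' Each boundary loop is fan-triangulated to its centroid with winding
#' consistent with the surrounding surface, so a consistently oriented open
#' mesh becomes a consistently oriented closed mesh.  Near-planar loops
#' (vessel cuts, valve annuli, clip cross-sections) are capped
#' volume-exactly in the planar limit.
#'
#' @param mesh a [surface_mesh] with zero or more boundary loops.
#' @return a closed [surface_mesh]; returned unchanged when already closed.
#'   Labels (if present) are extended with the label of the first loop
#'   vertex for each added centroid.
#' @export
cap_boundary_loops <- function(mesh) {
  loops <- boundary_loops(mesh)
  if (!length(loops)) return(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  labs <- mesh$labels
  for (loop in loops) {
    cen <- colMeans(v[loop, , drop = FALSE])
    ci <- nrow(v) + 1L
    v <- rbind(v, cen)
    k <- length(loop)
    # boundary edges run loop[i] -> loop[i+1]; cap triangles take the
    # reverse direction to keep global orientation consistent
    nxt <- c(loop[-1], loop[1])
    f <- rbind(f, cbind(nxt, loop, ci))
    if (!is.null(labs)) labs <- c(labs, labs[loop[1]])
  }
  surface_mesh(v, f, labs)
}

# ---- orifice plane ----------------------------------------------------------

#' Define an orifice plane
#'
#' @param point a point on the plane (mm).
#' @param normal plane normal; normalized internally.  By convention the
#'   normal points from the LAA toward the LA, so the LAA lies on the
#'   negative side.
#' @return object of class `orifice_plane` with unit normal.
#' @export
orifice_plane <- function(point, normal) {
  nrm <- sqrt(sum(normal^2))
  if (nrm == 0) stop("zero-length plane normal")
  structure(list(point = as.numeric(point), normal = as.numeric(normal) / nrm),
            class = "orifice_plane")
}

#' Least-squares plane through a set of points
#'
#' Fits the plane minimizing squared orthogonal distances (smallest principal
#' component), then orients the normal so that `toward` lies on the positive
#' side.
#'
#' @param pts k x 3 matrix of points.
#' @param toward optional 3-vector; the normal is flipped so that
#'   `dot(toward - centroid, normal) > 0`.
#' @return an [orifice_plane()].
#' @export
fit_plane <- function(pts, toward = NULL) {
  cen <- colMeans(pts)
  x <- sweep(pts, 2, cen)
  sv <- svd(x, nu = 0)
  n <- sv$v[, 3]
  if (!is.null(toward) && sum((toward - cen) * n) < 0) n <- -n
  orifice_plane(cen, n)
}

#' Clip a closed mesh by a plane, keeping the negative-normal side
#'
#' Triangles are split exactly at the plane; the sub-surface on the
#' negative-normal side (the LAA side under the package's plane convention)
#' is returned capped at the plane, so volume is conserved:
#' `volume(whole) == volume(kept) + volume(other side)` to roundoff.
#'
#' @param mesh a closed, consistently oriented [surface_mesh].
#' @param plane an [orifice_plane()].
#' @param cap close the cut cross-section with a planar cap (default); with
#'   `cap = FALSE` the cut is left open (an open boundary ring, as at a
#'   vessel cut).
#' @return a closed [surface_mesh] (empty mesh when nothing lies on the kept
#'   side).
#' @export
clip_by_plane <- function(mesh, plane, cap = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  if (!nrow(f)) return(mesh)
  d <- as.numeric(sweep(v, 2, plane$point) %*% plane$normal)
  # vertices exactly on (or within roundoff of) the plane produce degenerate
  # splits and non-manifold cap boundaries; nudge the plane by an
  # infinitesimal deterministic offset so every vertex is strictly off-plane
  eps <- 1e-12 * max(apply(v, 2, function(x) diff(range(x))), 1)
  if (any(abs(d) < eps)) {
    delta <- 2 * eps
    while (any(abs(d - delta) < eps)) delta <- delta * 1.6180339887
    d <- d - delta
  }
  keep_all <- d[f[, 1]] <= 0 & d[f[, 2]] <= 0 & d[f[, 3]] <= 0
  drop_all <- d[f[, 1]] >= 0 & d[f[, 2]] >= 0 & d[f[, 3]] >= 0
  # coplanar faces (all three on the plane) count as dropped
  keep_all <- keep_all & !drop_all
  mixed <- which(!keep_all & !drop_all)

  new_v <- v
  new_f <- f[keep_all, , drop = FALSE]
  # cache of plane-intersection vertices, one per undirected crossing edge
  cut_idx <- new.env(parent = emptyenv())
  edge_cut <- function(i, j) {
    a <- min(i, j); b <- max(i, j)
    key <- paste0(a, "_", b)
    hit <- get0(key, envir = cut_idx)
    if (!is.null(hit)) return(hit)
    t <- d[a] / (d[a] - d[b])
    p <- v[a, ] + t * (v[b, ] - v[a, ])
    new_v <<- rbind(new_v, p)
    idx <- nrow(new_v)
    assign(key, idx, envir = cut_idx)
    idx
  }
  for (fi in mixed) {
    tri <- f[fi, ]
    # Sutherland-Hodgman clip of the triangle against d <= 0
    poly <- integer(0)
    for (k in 1:3) {
      a <- tri[k]; b <- tri[if (k == 3) 1 else k + 1]
      if (d[a] <= 0) poly <- c(poly, a)
      if ((d[a] < 0 && d[b] > 0) || (d[a] > 0 && d[b] < 0)) {
        poly <- c(poly, edge_cut(a, b))
      }
    }
    if (length(poly) >= 3) {
      for (k in 2:(length(poly) - 1)) {
        new_f <- rbind(new_f, c(poly[1], poly[k], poly[k + 1]))
      }
    }
  }
  if (!nrow(new_f)) {
    return(surface_mesh(matrix(0, 0, 3), matrix(integer(0), 0, 3)))
  }
  # drop unused vertices, reindex
  used <- sort(unique(as.vector(new_f)))
  remap <- integer(nrow(new_v))
  remap[used] <- seq_along(used)
  out <- surface_mesh(new_v[used, , drop = FALSE],
                      matrix(remap[new_f], ncol = 3))
  if (cap) cap_boundary_loops(out) else out
}

#' Cut a surface by one or more planes (vessel-cut emulation)
#'
#' Removes everything on the positive-normal side of each plane and leaves
#' the cuts open, so each cut produces an open boundary ring — emulating the
#' pulmonary-vein / aortic cuts applied to segmented surfaces before
#' tracking.
#'
#' @param mesh a [surface_mesh].
#' @param planes an [orifice_plane()] or list of them; the kept side is the
#'   negative-normal side of each.
#' @return an open [surface_mesh].
#' @export
slice_surface <- function(mesh, planes) {
  if (inherits(planes, "orifice_plane")) planes <- list(planes)
  for (pl in planes) mesh <- clip_by_plane(mesh, pl, cap = FALSE)
  mesh
}

# ---- region extraction ------------------------------------------------------

#' Extract a labeled region as a submesh
#'
#' Returns the submesh of all faces whose three vertices are labeled with the
#' requested region or `LAA_OSTIUM` (the ostium ring is shared between the LA
#' and LAA sides), together with an index map back to the parent mesh so that
#' deformed submesh vertices can be written back in place.
#'
#' @param mesh a [surface_mesh].
#' @param labels integer per-vertex region codes (defaults to `mesh$labels`).
#' @param region region name (see [region_codes()]); `"chambers"` selects
#'   everything except the LAA interior.
#' @return list with `mesh` (the submesh, labels carried over) and
#'   `vertex_map` (integer vector: submesh vertex i is parent vertex
#'   `vertex_map[i]`).
#' @export
extract_region <- function(mesh, labels = mesh$labels, region) {
  if (is.null(labels)) stop("no labels given and mesh carries none")
  codes <- unique(c(region_codes(region), REGION[["LAA_OSTIUM"]]))
  if (!any(labels %in% region_codes(region))) {
    stop("region not present in labels: ", paste(region, collapse = ", "))
  }
  vmask <- labels %in% codes
  f <- mesh$faces
  fmask <- vmask[f[, 1]] & vmask[f[, 2]] & vmask[f[, 3]]
  sub_f <- f[fmask, , drop = FALSE]
  used <- sort(unique(as.vector(sub_f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  sub <- surface_mesh(mesh$vertices[used, , drop = FALSE],
                      matrix(remap[sub_f], ncol = 3),
                      labels[used])
  list(mesh = sub, vertex_map = used)
}

#' Write submesh vertex positions back into the parent vertex array
#'
#' @param parent_vertices n x 3 parent coordinates.
#' @param sub_vertices k x 3 submesh coordinates.
#' @param vertex_map index map from [extract_region()].
#' @return updated n x 3 matrix.
#' @export
write_back <- function(parent_vertices, sub_vertices, vertex_map) {
  parent_vertices[vertex_map, ] <- sub_vertices
  parent_vertices
}

# ---- primitive generators (used by tests and the phantom) -------------------

#' Icosphere mesh
#'
#' Subdivided icosahedron projected to a sphere; consistently oriented
#' outward.
#'
#' @param radius sphere radius (mm).
#' @param subdivisions number of 4-to-1 subdivision passes.
#' @param center sphere center.
#' @return a closed [surface_mesh].
#' @export
icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    midcache <- new.env(parent = emptyenv())
    nf <- matrix(integer(0), 0, 3)
    for (i in seq_len(nrow(f))) {
      tri <- f[i, ]
      mid <- integer(3)
      for (k in 1:3) {
        a <- tri[k]; b <- tri[if (k == 3) 1 else k + 1]
        key <- paste0(min(a, b), "_", max(a, b))
        m <- get0(key, envir = midcache)
        if (is.null(m)) {
          v <- rbind(v, (v[a, ] + v[b, ]) / 2)
          m <- nrow(v)
          assign(key, m, envir = midcache)
        }
        mid[k] <- m
      }
      nf <- rbind(nf,
                  c(tri[1], mid[1], mid[3]), c(tri[2], mid[2], mid[1]),
                  c(tri[3], mid[3], mid[2]), c(mid[1], mid[2], mid[3]))
    }
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  v <- sweep(v, 2, center, "+")
  surface_mesh(v, f)
}

#' Axis-aligned box mesh
#'
#' @param lo,hi opposite corners (mm).
#' @return closed [surface_mesh] (12 triangles, outward orientation).
#' @export
box_mesh <- function(lo = c(0, 0, 0), hi = c(1, 1, 1)) {
  g <- expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]), z = c(lo[3], hi[3]))
  v <- as.matrix(g)  # index bit pattern: 1 + x + 2 y + 4 z
  quad <- function(a, b, c, d) rbind(c(a, b, c), c(a, c, d))
  f <- rbind(
    quad(1, 3, 4, 2),  # z = lo (normal -z)
    quad(5, 6, 8, 7),  # z = hi (+z)
    quad(1, 2, 6, 5),  # y = lo (-y)
    quad(3, 7, 8, 4),  # y = hi (+y)
    quad(1, 5, 7, 3),  # x = lo (-x)
    quad(2, 4, 8, 6))  # x = hi (+x)
  surface_mesh(v, f)
}

#' Open cylinder mesh (no end caps)
#'
#' @param radius,height cylinder radius and height (mm); axis z, base at z=0.
#' @param n_phi,n_z angular and axial segment counts.
#' @return an open [surface_mesh] with two boundary loops, outward oriented.
#' @export
cylinder_mesh <- function(radius = 1, height = 1, n_phi = 32, n_z = 4) {
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  z <- seq(0, height, length.out = n_z + 1)
  v <- do.call(rbind, lapply(z, function(zz) cbind(radius * cos(phi),
                                                   radius * sin(phi), zz)))
  f <- matrix(integer(0), 0, 3)
  for (iz in seq_len(n_z)) {
    b0 <- (iz - 1) * n_phi
    b1 <- iz * n_phi
    j2 <- c(2:n_phi, 1)
    f <- rbind(f,
               cbind(b0 + seq_len(n_phi), b0 + j2, b1 + j2),
               cbind(b0 + seq_len(n_phi), b1 + j2, b1 + seq_len(n_phi)))
  }
  surface_mesh(v, f)
}

#' Hemisphere mesh (open at the equator)
#'
#' Latitude-band tessellation of the upper half sphere: dome over z >= 0,
#' single boundary loop exactly on the equator circle, outward oriented.
#'
#' @param radius radius (mm).
#' @param n_theta latitude bands between pole and equator.
#' @param n_phi angular segments.
#' @return open [surface_mesh].
#' @export
hemisphere_mesh <- function(radius = 1, n_theta = 24, n_phi = 48) {
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  theta <- seq(0, pi / 2, length.out = n_theta + 1)[-1]  # skip pole
  v <- rbind(c(0, 0, radius),
             do.call(rbind, lapply(theta, function(th) {
               cbind(radius * sin(th) * cos(phi),
                     radius * sin(th) * sin(phi),
                     radius * cos(th))
             })))
  j2 <- c(2:n_phi, 1)
  f <- cbind(1L, 1L + seq_len(n_phi), 1L + j2)  # pole fan
  for (ir in seq_len(n_theta - 1)) {
    b0 <- 1L + (ir - 1L) * n_phi
    b1 <- 1L + ir * n_phi
    f <- rbind(f,
               cbind(b0 + seq_len(n_phi), b1 + seq_len(n_phi), b1 + j2),
               cbind(b0 + seq_len(n_phi), b1 + j2, b0 + j2))
  }
  m <- surface_mesh(v, f)
  # enforce outward orientation (capped signed volume positive)
  cm <- cap_boundary_loops(m)
  if (signed_volume_mm3(cm$vertices, cm$faces) < 0) {
    m$faces <- m$faces[, c(1, 3, 2)]
  }
  m
}
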