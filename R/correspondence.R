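# Point correspondences driving the registration cost: forward (source ->
# nearest target vertex, the distance term) and reverse (subsampled target ->
# nearest source vertex, the bi-directional term).

as_coords <- function(x) {
  if (inherits(x, "surface_mesh")) x$vertices else {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    x
  }
}

#' Nearest-neighbor index lookup
#'
#' kd-tree nearest neighbor of each query point among the reference points.
#'
#' @param query q x 3 matrix.
#' @param ref r x 3 matrix.
#' @return list with `index` (into `ref`) and `dist`.
#' @keywords internal
nn_index <- function(query, ref) {
  if (!nrow(ref)) stop("empty reference point set")
  res <- FNN::get.knnx(ref, query, k = 1)
  list(index = as.integer(res$nn.index[, 1]), dist = as.numeric(res$nn.dist[, 1]))
}

#' Area-weighted vertex normals
#'
#' @param mesh a [surface_mesh].
#' @return n x 3 matrix of unit vertex normals (zero rows for unused
#'   vertices).
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  n <- matrix(0, nrow(v), 3)
  if (!length(f)) return(n)
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # 2x area-weighted
  for (k in 1:3) {
    for (d in 1:3) {
      acc <- tapply(fn[, d], f[, k], sum)
      idx <- as.integer(names(acc))
      n[idx, d] <- n[idx, d] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Forward correspondences (distance term)
#'
#' For every vertex of the deformed source, finds its nearest vertex in the
#' target (Euclidean).  Landmark vertices receive weight 0 so that the
#' distance term never competes with their prescribed positions; all other
#' vertices receive weight 1.  Optionally (off by default, as in the
#' default cost) matches can be pruned — weight set to 0 — when the
#' matched target vertex lies on the target's open boundary or when the
#' vertex normals oppose.
#'
#' @param deformed_source a [surface_mesh] or n x 3 matrix of current source
#'   positions.
#' @param target a [surface_mesh] or m x 3 matrix of target points.
#' @param landmark_vertices integer indices of landmark source vertices.
#' @param prune `NULL` (default, no pruning) or a list with logical fields
#'   `borders` and/or `normals`; normal pruning requires both arguments to
#'   be meshes.
#' @return list with `target_index` (n), `points` (n x 3, the matched target
#'   positions `U`), `weights` (n, in `{0, 1}`), `dist` (n).
#' @export
nearest_correspondences <- function(deformed_source, target,
                                    landmark_vertices = integer(0),
                                    prune = NULL) {
  src <- as_coords(deformed_source)
  tgt <- as_coords(target)
  if (!nrow(src)) stop("empty source")
  if (!nrow(tgt)) stop("empty target")
  nn <- nn_index(src, tgt)
  w <- rep(1, nrow(src))
  if (isTRUE(prune$borders) && inherits(target, "surface_mesh")) {
    border <- unique(as.vector(boundary_directed_edges(target)))
    w[nn$index %in% border] <- 0
  }
  if (isTRUE(prune$normals) && inherits(target, "surface_mesh") &&
      inherits(deformed_source, "surface_mesh")) {
    ns <- vertex_normals(deformed_source)
    nt <- vertex_normals(target)
    w[rowSums(ns * nt[nn$index, , drop = FALSE]) < 0] <- 0
  }
  w[landmark_vertices] <- 0
  list(target_index = nn$index,
       points = tgt[nn$index, , drop = FALSE],
       weights = w,
       dist = nn$dist)
}

#' Poisson-disk style vertex subsample
#'
#' Greedy maximal selection over a canonically ordered vertex list such that
#' no two selected vertices are closer than
#' `radius_fraction * bounding-box diagonal`.  Vertices are visited in
#' lexicographic coordinate order, so the result is invariant to vertex
#' storage permutation.
#'
#' @param target a [surface_mesh] or m x 3 matrix.
#' @param radius_fraction exclusion radius as a fraction of the bounding-box
#'   diagonal, in (0, 1) (the bi-directional term uses about 5% of the LAA
#'   size).
#' @return integer vector of selected vertex indices (into `target`).
#' @export
poisson_subsample <- function(target, radius_fraction = 0.05) {
  pts <- as_coords(target)
  if (!(radius_fraction > 0)) stop("radius_fraction must be positive")
  diag_len <- sqrt(sum((apply(pts, 2, max) - apply(pts, 2, min))^2))
  r <- radius_fraction * diag_len
  ord <- order(pts[, 1], pts[, 2], pts[, 3])
  if (r == 0) return(sort(ord))  # degenerate geometry: keep everything
  sel <- integer(0)
  r2 <- r * r
  for (i in ord) {
    if (!length(sel)) {
      sel <- i
      next
    }
    dx <- pts[sel, 1] - pts[i, 1]
    dy <- pts[sel, 2] - pts[i, 2]
    dz <- pts[sel, 3] - pts[i, 3]
    if (all(dx * dx + dy * dy + dz * dz >= r2)) sel <- c(sel, i)
  }
  sort(sel)
}

#' Reverse correspondences (bi-directional term)
#'
#' For each subsampled target vertex, finds the nearest vertex of the
#' deformed source.  The same source vertex may be matched by several target
#' vertices.
#'
#' @param subsample integer indices into the target vertices.
#' @param target a [surface_mesh] or m x 3 matrix.
#' @param deformed_source a [surface_mesh] or n x 3 matrix of current source
#'   positions.
#' @return list with `source_index` (k, rows of `D_Tar`) and `target_points`
#'   (k x 3, rows of `U_Tar`).
#' @export
reverse_correspondences <- function(subsample, target, deformed_source) {
  if (!length(subsample)) stop("empty subsample")
  tgt <- as_coords(target)[subsample, , drop = FALSE]
  src <- as_coords(deformed_source)
  nn <- nn_index(tgt, src)
  list(source_index = nn$index, target_points = tgt)
}
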