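#' 3D scalar volume with world geometry
#'
#' Container for a 3D image: a voxel array plus the geometry that places each
#' voxel in the patient (world) coordinate frame. The internal world frame is
#' LPS (left-posterior-superior), voxel indices are 0-based, and coordinates
#' refer to voxel centers. The world position of voxel index `v` is
#' `origin + direction %*% (spacing * v)`.
#'
#' @param voxels 3D numeric array of intensities (stored as double).
#' @param spacing length-3 numeric, mm per voxel along each grid axis; all > 0.
#' @param origin length-3 numeric, world position (mm, LPS) of voxel (0,0,0).
#' @param direction 3x3 orthonormal direction-cosine matrix (|det| = 1).
#' @return An object of class `volume3d`.
#' @examples
#' v <- volume3d(array(0, c(4, 4, 4)), spacing = c(0.5, 0.5, 2))
#' index_to_world(v, c(1, 1, 1))
#' @export
volume3d <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     direction = diag(3)) {
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array, got ", length(dim(voxels)), " dimensions")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  direction <- matrix(as.numeric(direction), 3, 3)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm/voxel)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be a finite 3-vector (mm)")
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6 ||
      abs(abs(det(direction)) - 1) > 1e-6)
    stop("`direction` must be orthonormal (|det| = 1 within 1e-6)")
  storage.mode(voxels) <- "double"
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 direction = direction),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume3d> %d x %d x %d voxels, spacing %s mm, origin (%s) mm\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  if (max(abs(x$direction - diag(3))) > 1e-12) {
    cat("direction:\n"); print(signif(x$direction, 6))
  }
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$voxels)

as_point_matrix <- function(p) {
  if (is.null(dim(p))) {
    if (length(p) != 3L) stop("point must have 3 coordinates")
    matrix(as.numeric(p), 1, 3)
  } else {
    p <- as.matrix(p)
    if (ncol(p) != 3L) stop("points must be an N x 3 matrix")
    storage.mode(p) <- "double"
    p
  }
}

#' Convert voxel indices to world coordinates (and back)
#'
#' Indices are 0-based and continuous (voxel-center convention); both
#' functions accept a single length-3 vector or an N x 3 matrix.
#'
#' @param volume a [volume3d()].
#' @param index,world length-3 vector or N x 3 matrix.
#' @return N x 3 matrix (or length-3 vector for vector input) of world mm /
#'   continuous 0-based indices.
#' @export
index_to_world <- function(volume, index) {
  v <- as_point_matrix(index)
  out <- t(volume$direction %*% (t(v) * volume$spacing) + volume$origin)
  if (is.null(dim(index))) drop(out) else out
}

#' @rdname index_to_world
#' @export
world_to_index <- function(volume, world) {
  w <- as_point_matrix(world)
  out <- t((t(volume$direction) %*% (t(w) - volume$origin)) / volume$spacing)
  if (is.null(dim(world))) drop(out) else out
}

#' Sample a volume at world coordinates by trilinear interpolation
#'
#' @param volume a [volume3d()].
#' @param world length-3 vector or N x 3 matrix of world coordinates (mm).
#' @return numeric vector of interpolated intensities; `NA` outside the grid.
#' @export
sample_at_world <- function(volume, world) {
  idx <- as_point_matrix(world_to_index(volume, as_point_matrix(world)))
  interp_trilinear_cpp(volume$voxels, dim(volume$voxels), idx)
}

#' Axis-aligned region of interest in world coordinates
#'
#' An ROI is a world-space (LPS mm) box; because it lives in world space the
#' same ROI applies across grids of different resolution.
#'
#' @param lower,upper length-3 numeric, mm; `lower < upper` componentwise.
#' @return An object of class `roi3d`.
#' @export
roi3d <- function(lower, upper) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != 3L || length(upper) != 3L || any(!is.finite(c(lower, upper))))
    stop("`lower` and `upper` must be finite 3-vectors (mm)")
  if (any(lower >= upper)) stop("ROI requires lower < upper componentwise")
  structure(list(lower = lower, upper = upper), class = "roi3d")
}

#' @export
print.roi3d <- function(x, ...) {
  cat(sprintf("<roi3d> [%s] to [%s] mm\n",
              paste(signif(x$lower, 4), collapse = ", "),
              paste(signif(x$upper, 4), collapse = ", ")))
  invisible(x)
}

#' World-space ROI spanning a volume's full extent
#'
#' The box that contains every voxel center, padded by half a voxel so
#' boundary centers are strictly inside.
#' @param volume a [volume3d()].
#' @return an [roi3d()].
#' @export
volume_extent_roi <- function(volume) {
  d <- dim(volume$voxels)
  corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1), c(0, d[3] - 1)))
  w <- index_to_world(volume, corners)
  pad <- as.numeric(abs(volume$direction) %*% (volume$spacing / 2))
  roi3d(apply(w, 2, min) - pad * 0.999, apply(w, 2, max) + pad * 0.999)
}

roi_contains <- function(roi, pts) {
  pts <- as_point_matrix(pts)
  pts[, 1] >= roi$lower[1] & pts[, 1] <= roi$upper[1] &
    pts[, 2] >= roi$lower[2] & pts[, 2] <= roi$upper[2] &
    pts[, 3] >= roi$lower[3] & pts[, 3] <= roi$upper[3]
}

axis_aligned_direction <- function(direction) {
  all(colSums(abs(direction) > 1e-9) == 1) && all(rowSums(abs(direction) > 1e-9) == 1)
}

#' Crop a volume to a world-space region of interest
#'
#' Keeps exactly the voxels whose centers fall inside `roi`. World
#' coordinates of the retained voxels are unchanged: only the origin moves,
#' spacing and direction are preserved. For oblique grids (direction matrix
#' not axis-aligned) the set of qualifying centers need not be a box in index
#' space; the minimal index bounding box of qualifying centers is returned.
#'
#' @param volume a [volume3d()].
#' @param roi an [roi3d()] in world mm.
#' @return the cropped [volume3d()].
#' @export
crop_to_roi <- function(volume, roi) {
  stopifnot(inherits(volume, "volume3d"), inherits(roi, "roi3d"))
  d <- dim(volume$voxels)
  if (axis_aligned_direction(volume$direction)) {
    # per grid axis: world axis it maps to, and the index interval inside roi
    rng <- vector("list", 3)
    for (ax in 1:3) {
      wax <- which(abs(volume$direction[, ax]) > 1e-9)
      sgn <- sign(volume$direction[wax, ax])
      # world coordinate along wax of center with index i on this axis:
      # origin[wax] + sgn * spacing[ax] * i  (other axes contribute on other rows)
      w0 <- volume$origin[wax]
      s <- sgn * volume$spacing[ax]
      lo <- (roi$lower[wax] - w0) / s; hi <- (roi$upper[wax] - w0) / s
      if (s < 0) { tmp <- lo; lo <- hi; hi <- tmp }
      idx <- seq(ceiling(lo - 1e-9), floor(hi + 1e-9))
      idx <- idx[idx >= 0 & idx <= d[ax] - 1]
      if (length(idx) == 0) stop("ROI does not intersect the volume")
      rng[[ax]] <- range(idx)
    }
    lo <- vapply(rng, `[`, 0, 1); hi <- vapply(rng, `[`, 0, 2)
  } else {
    g <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
    keep <- roi_contains(roi, index_to_world(volume, g))
    if (!any(keep)) stop("ROI does not intersect the volume")
    lo <- apply(g[keep, , drop = FALSE], 2, min)
    hi <- apply(g[keep, , drop = FALSE], 2, max)
  }
  vox <- volume$voxels[(lo[1]:hi[1]) + 1, (lo[2]:hi[2]) + 1, (lo[3]:hi[3]) + 1,
                       drop = FALSE]
  volume3d(vox, volume$spacing,
           origin = as.numeric(index_to_world(volume, lo)),
           direction = volume$direction)
}

volume_world_center <- function(volume) {
  d <- dim(volume$voxels)
  as.numeric(index_to_world(volume, (d - 1) / 2))
}

#' Mirror a volume about its center plane
#'
#' Reflects the volume about the plane through its world-space center whose
#' normal is the world direction of grid axis `plane_axis` (the direction
#' matrix's `plane_axis` column; for axis-aligned volumes this is a world
#' axis). The operation is an isometry and an involution, so a mirrored atlas
#' occupies the same world extent and preserves all pairwise distances --
#' which is what makes a single atlas usable for both left and right ears.
#'
#' @param volume a [volume3d()].
#' @param plane_axis grid axis index in 1..3 whose direction is the mirror
#'   normal.
#' @return the mirrored [volume3d()].
#' @seealso [mirror_point()] to mirror fiducials consistently.
#' @export
mirror_volume <- function(volume, plane_axis = 1) {
  stopifnot(inherits(volume, "volume3d"))
  if (!plane_axis %in% 1:3) stop("`plane_axis` must be 1, 2 or 3")
  d <- dim(volume$voxels)
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  idx[[plane_axis]] <- rev(idx[[plane_axis]])
  vox <- volume$voxels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  # flipping index axis a while keeping geometry reflects world positions
  # about the center plane with normal direction[, a]
  volume3d(vox, volume$spacing, volume$origin, volume$direction)
}

#' Reflect world points about a volume's mirror plane
#'
#' Applies the same reflection as [mirror_volume()] to explicit points, so
#' fiducials can be mirrored consistently with their volume.
#'
#' @param points length-3 vector or N x 3 matrix, world mm.
#' @param volume the (unmirrored) [volume3d()] defining center and normal.
#' @param plane_axis grid axis in 1..3, as in [mirror_volume()].
#' @return reflected points, same shape as input.
#' @export
mirror_point <- function(points, volume, plane_axis = 1) {
  p <- as_point_matrix(points)
  ctr <- volume_world_center(volume)
  n <- volume$direction[, plane_axis]
  n <- n / sqrt(sum(n^2))
  rel <- sweep(p, 2, ctr)
  out <- p - 2 * (rel %*% n) %*% t(n)
  if (is.null(dim(points))) drop(out) else out
}
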