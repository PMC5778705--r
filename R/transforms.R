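#' Affine (or rigid) spatial transform
#'
#' Maps world point `x` (mm) to `matrix %*% x + translation`. A rigid
#' transform is the 6-degree-of-freedom specialization whose matrix is a pure
#' rotation; the general affine has 12 degrees of freedom (translation,
#' rotation, scaling and shearing in each of x, y, z).
#'
#' @param matrix invertible 3x3 matrix.
#' @param translation length-3 numeric, mm.
#' @param kind `"affine"` or `"rigid"` (rigid requires an orthonormal matrix
#'   with det +1).
#' @return an object of class `affine_transform`.
#' @export
affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0),
                             kind = c("affine", "rigid")) {
  kind <- match.arg(kind)
  m <- base::matrix(as.numeric(matrix), 3, 3)
  tr <- as.numeric(translation)
  if (length(tr) != 3L || any(!is.finite(c(m, tr))))
    stop("affine transform needs a finite 3x3 matrix and 3-vector translation")
  if (abs(det(m)) < 1e-12) stop("affine matrix is singular")
  if (kind == "rigid" &&
      (max(abs(crossprod(m) - diag(3))) > 1e-6 || det(m) < 0))
    stop("a rigid transform's matrix must be a rotation")
  structure(list(matrix = m, translation = tr, kind = kind),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("<%s transform> translation (%s) mm\n", x$kind,
              paste(signif(x$translation, 5), collapse = ", ")))
  print(signif(x$matrix, 6))
  invisible(x)
}

identity_affine <- function() affine_transform(diag(3), c(0, 0, 0), kind = "rigid")

invert_affine <- function(tf) {
  mi <- solve(tf$matrix)
  affine_transform(mi, -as.numeric(mi %*% tf$translation),
                   kind = if (tf$kind == "rigid") "rigid" else "affine")
}

compose_affine <- function(outer, inner) {
  # (outer o inner)(x) = outer(inner(x))
  affine_transform(outer$matrix %*% inner$matrix,
                   as.numeric(outer$matrix %*% inner$translation) + outer$translation,
                   kind = if (outer$kind == "rigid" && inner$kind == "rigid")
                     "rigid" else "affine")
}

## 12-parameter affine parameterization used by the optimizer:
## translation (3, mm) + Euler rotation (3, rad) + log-scale (3) + shear (3),
## composed as M = Rz Ry Rx . Shear . diag(exp(s)), acting about a fixed
## center: T(x) = M (x - c) + c + t.
rotation_from_euler <- function(a) {
  ca <- cos(a[1]); sa <- sin(a[1]); cb <- cos(a[2]); sb <- sin(a[2])
  cg <- cos(a[3]); sg <- sin(a[3])
  rx <- rbind(c(1, 0, 0), c(0, ca, -sa), c(0, sa, ca))
  ry <- rbind(c(cb, 0, sb), c(0, 1, 0), c(-sb, 0, cb))
  rz <- rbind(c(cg, -sg, 0), c(sg, cg, 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

affine_from_params <- function(params, center = c(0, 0, 0)) {
  stopifnot(length(params) == 12L)
  tr <- params[1:3]; eul <- params[4:6]; ls <- params[7:9]; sh <- params[10:12]
  shear <- diag(3); shear[1, 2] <- sh[1]; shear[1, 3] <- sh[2]; shear[2, 3] <- sh[3]
  m <- rotation_from_euler(eul) %*% shear %*% diag(exp(ls))
  affine_transform(m, center + tr - as.numeric(m %*% center))
}

#' Cubic B-spline free-form deformation
#'
#' A non-rigid transform defined by a coarse regular grid of control-point
#' displacements, interpolated into a C2-smooth dense displacement field by
#' tensor-product cubic B-splines: `T(x) = x + D(x)`. Zero displacements give
#' the identity map. Control point `(i, j, k)` (0-based) sits at
#' `grid_origin + grid_spacing * (i, j, k)`; cubic support requires a full
#' 4x4x4 control neighbourhood, so the valid domain is
#' `grid_origin + grid_spacing` to `grid_origin + grid_spacing * (shape - 2)`.
#'
#' @param grid_shape integer 3-vector, control points per axis (each >= 4).
#' @param grid_origin length-3 numeric, mm.
#' @param grid_spacing length-3 numeric, mm, all > 0.
#' @param displacements `prod(grid_shape) x 3` matrix of control-point
#'   displacements (mm), rows in column-major grid order; defaults to zero.
#' @return an object of class `bspline_transform`.
#' @export
bspline_transform <- function(grid_shape, grid_origin, grid_spacing,
                              displacements = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    stop("`grid_shape` must be 3 integers, each >= 4")
  grid_origin <- as.numeric(grid_origin); grid_spacing <- as.numeric(grid_spacing)
  if (any(grid_spacing <= 0)) stop("`grid_spacing` must be positive")
  n <- prod(grid_shape)
  if (is.null(displacements)) displacements <- base::matrix(0, n, 3)
  displacements <- as.matrix(displacements)
  if (nrow(displacements) != n || ncol(displacements) != 3L)
    stop("`displacements` must be ", n, " x 3")
  storage.mode(displacements) <- "double"
  structure(list(grid_shape = grid_shape, grid_origin = grid_origin,
                 grid_spacing = grid_spacing, displacements = displacements),
            class = "bspline_transform")
}

#' @export
print.bspline_transform <- function(x, ...) {
  cat(sprintf("<bspline transform> %s control grid, spacing (%s) mm, max |d| %.3g mm\n",
              paste(x$grid_shape, collapse = "x"),
              paste(signif(x$grid_spacing, 4), collapse = ", "),
              max(sqrt(rowSums(x$displacements^2)))))
  invisible(x)
}

#' B-spline control grid covering a region of interest
#'
#' Places `grid_shape` control points so that the full-support domain of the
#' spline is exactly `roi` (with a tiny numerical margin): spacing
#' `(upper - lower) / (shape - 3)` and origin one spacing below `lower`.
#'
#' @param roi an [roi3d()].
#' @param grid_shape integer 3-vector (default `c(4, 4, 4)`, the 64-control-
#'   point mesh).
#' @param margin fractional padding of the ROI before fitting (default 1e-6).
#' @return a zero-displacement [bspline_transform()].
#' @export
bspline_grid_for_roi <- function(roi, grid_shape = c(4, 4, 4), margin = 1e-6) {
  ext <- roi$upper - roi$lower
  lo <- roi$lower - margin * ext; up <- roi$upper + margin * ext
  spacing <- (up - lo) / (grid_shape - 3)
  bspline_transform(grid_shape, lo - spacing, spacing)
}

bspline_displacement <- function(tf, pts) {
  pts <- as_point_matrix(pts)
  t <- sweep(sweep(pts, 2, tf$grid_origin), 2, tf$grid_spacing, "/")
  bspline_disp_cpp(t, tf$displacements, tf$grid_shape)
}

#' Chain of transforms applied in estimation order
#'
#' The registration cascade estimates rigid, then affine, then B-spline
#' stages; the chain applies them in that same order, mapping atlas-space
#' coordinates to target-space coordinates.
#'
#' @param ... transforms ([affine_transform()], [bspline_transform()], or
#'   other `transform_chain`s, flattened), applied left to right.
#' @return an object of class `transform_chain`.
#' @export
transform_chain <- function(...) {
  tfs <- list(...)
  if (length(tfs) == 1L && is.list(tfs[[1]]) && !inherits(tfs[[1]], c("affine_transform", "bspline_transform")))
    tfs <- tfs[[1]]
  out <- list()
  for (tf in tfs) {
    if (inherits(tf, "transform_chain")) out <- c(out, tf$transforms)
    else if (inherits(tf, c("affine_transform", "bspline_transform")))
      out <- c(out, list(tf))
    else stop("unsupported transform of class ", paste(class(tf), collapse = "/"))
  }
  structure(list(transforms = out), class = "transform_chain")
}

#' @export
print.transform_chain <- function(x, ...) {
  cat(sprintf("<transform_chain> %d stage(s): %s\n", length(x$transforms),
              paste(vapply(x$transforms, function(t)
                if (inherits(t, "affine_transform")) t$kind else "bspline", ""),
                collapse = " -> ")))
  invisible(x)
}

#' Apply a transform to world points
#'
#' @param transform an [affine_transform()], [bspline_transform()] or
#'   [transform_chain()].
#' @param point length-3 vector or N x 3 matrix of world coordinates (mm).
#' @return mapped coordinates, same shape as the input.
#' @export
apply_to_point <- function(transform, point) UseMethod("apply_to_point")

#' @export
apply_to_point.affine_transform <- function(transform, point) {
  p <- as_point_matrix(point)
  out <- t(transform$matrix %*% t(p) + transform$translation)
  if (is.null(dim(point))) drop(out) else out
}

#' @export
apply_to_point.bspline_transform <- function(transform, point) {
  p <- as_point_matrix(point)
  d <- bspline_displacement(transform, p)
  if (anyNA(d))
    stop("point outside the B-spline support domain")
  out <- p + d
  if (is.null(dim(point))) drop(out) else out
}

#' @export
apply_to_point.transform_chain <- function(transform, point) {
  p <- as_point_matrix(point)
  for (tf in transform$transforms) p <- apply_to_point(tf, p)
  if (is.null(dim(point))) drop(p) else p
}

#' Degrees of freedom of a transform
#'
#' Follows the registration-literature counting: a rigid transform has 6, a
#' 3D affine 12, and a B-spline free-form deformation one per control point
#' (so the standard 4x4x4 mesh has 64). For B-splines the scalar parameter
#' count (3 per control point) is attached as attribute
#' `scalar_parameters`; for chains, the per-stage counts as `per_stage`.
#'
#' @param transform a transform or [transform_chain()].
#' @return integer degrees of freedom.
#' @export
dof <- function(transform) UseMethod("dof")

#' @export
dof.affine_transform <- function(transform)
  if (transform$kind == "rigid") 6L else 12L

#' @export
dof.bspline_transform <- function(transform) {
  n <- prod(transform$grid_shape)
  structure(as.integer(n), scalar_parameters = 3L * as.integer(n))
}

#' @export
dof.transform_chain <- function(transform) {
  per <- vapply(transform$transforms, function(t) as.integer(dof(t)), 0L)
  structure(sum(per), per_stage = per)
}

chain_affine_part <- function(chain) {
  # composition of the leading affine stages of a chain
  out <- identity_affine()
  for (tf in chain$transforms) {
    if (!inherits(tf, "affine_transform")) break
    out <- compose_affine(tf, out)
  }
  out
}

invert_chain_at <- function(chain, points, tol = 1e-6, max_iter = 30) {
  # fixed-point inversion of y = T(x); valid for chains whose non-rigid part
  # is a bounded perturbation of the affine part
  y <- as_point_matrix(points)
  aff <- chain_affine_part(chain)
  x <- apply_to_point(invert_affine(aff), y)
  for (it in seq_len(max_iter)) {
    fx <- chain_apply_na(chain, x)
    r <- fx - y
    r[is.na(r)] <- 0
    x <- x - r
    if (max(abs(r)) < tol) break
  }
  x
}

chain_apply_na <- function(chain, pts) {
  # like apply_to_point but B-spline displacements outside support are 0
  p <- as_point_matrix(pts)
  for (tf in chain$transforms) {
    if (inherits(tf, "affine_transform")) p <- apply_to_point(tf, p)
    else {
      d <- bspline_displacement(tf, p)
      d[is.na(d)] <- 0
      p <- p + d
    }
  }
  p
}

#' Sample the displacement field of a transform on a regular grid
#'
#' Evaluates `T(p) - p` at the nodes of an axis-aligned grid covering `roi`
#' with step `grid_step`, for external visualization of the deformation.
#' Write the result with [write_displacement_field()].
#'
#' @param transform a transform or [transform_chain()].
#' @param roi an [roi3d()].
#' @param grid_step scalar or length-3 step in mm (> 0).
#' @return an object of class `displacement_field`: list with `origin`,
#'   `step`, `dims` and the `nx x ny x nz x 3` array `field` (mm).
#' @export
export_displacement_field <- function(transform, roi, grid_step) {
  grid_step <- rep(as.numeric(grid_step), length.out = 3)
  if (any(grid_step <= 0)) stop("`grid_step` must be > 0")
  ax <- lapply(1:3, function(a) seq(roi$lower[a], roi$upper[a], by = grid_step[a]))
  dims <- vapply(ax, length, 0L)
  g <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  mapped <- if (inherits(transform, "transform_chain"))
    chain_apply_na(transform, g)
  else if (inherits(transform, "bspline_transform")) {
    d <- bspline_displacement(transform, g); d[is.na(d)] <- 0; g + d
  } else apply_to_point(transform, g)
  disp <- mapped - g
  structure(list(origin = roi$lower, step = grid_step, dims = dims,
                 field = array(disp, c(dims, 3))),
            class = "displacement_field")
}

#' Write a displacement field as a 3-component NRRD volume
#'
#' @param field a `displacement_field` from [export_displacement_field()].
#' @param path output `.nrrd` path.
#' @return the path, invisibly.
#' @export
write_displacement_field <- function(field, path) {
  stopifnot(inherits(field, "displacement_field"))
  m <- diag(field$step)
  hdr <- c("NRRD0004",
           "type: double",
           "dimension: 4",
           "space: left-posterior-superior",
           paste("sizes: 3", paste(field$dims, collapse = " ")),
           paste("space directions: none", nrrd_vec(m[, 1]), nrrd_vec(m[, 2]), nrrd_vec(m[, 3])),
           "kinds: vector domain domain domain",
           "endian: little",
           "encoding: gzip",
           paste("space origin:", nrrd_vec(field$origin)),
           "")
  con <- file(path, "wb")
  writeLines(hdr, con)
  zcon <- gzcon(con)
  # vector component fastest
  writeBin(as.double(aperm(field$field, c(4, 1, 2, 3))), zcon, size = 8,
           endian = "little")
  close(zcon)
  invisible(path)
}

## ---- JSON serialization ------------------------------------------------

transform_to_list <- function(tf) {
  if (inherits(tf, "affine_transform"))
    list(type = tf$kind, matrix = as.numeric(tf$matrix),
         translation = tf$translation)
  else if (inherits(tf, "bspline_transform"))
    list(type = "bspline", grid_shape = tf$grid_shape,
         grid_origin = tf$grid_origin, grid_spacing = tf$grid_spacing,
         displacements = as.numeric(tf$displacements))
  else if (inherits(tf, "transform_chain"))
    list(type = "chain", stages = lapply(tf$transforms, transform_to_list))
  else stop("unsupported transform")
}

transform_from_list <- function(x) {
  switch(x$type,
         rigid = ,
         affine = affine_transform(matrix(x$matrix, 3, 3), x$translation,
                                   kind = x$type),
         bspline = bspline_transform(x$grid_shape, x$grid_origin, x$grid_spacing,
                                     matrix(x$displacements, ncol = 3)),
         chain = transform_chain(lapply(x$stages, transform_from_list)),
         stop("unknown transform type: ", x$type))
}

#' Read or write a transform (or chain) as JSON
#'
#' @param transform a transform or [transform_chain()].
#' @param path file path.
#' @return `write_transform_json()` the path invisibly; `read_transform_json()`
#'   the transform.
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(transform_to_list(transform), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  transform_from_list(jsonlite::read_json(path, simplifyVector = TRUE,
                                          simplifyDataFrame = FALSE,
                                          simplifyMatrix = FALSE))
}
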