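#' Synthetic cochlea phantom specification
#'
#' Parameterizes a cochlea-like spiral tube: a logarithmically decaying
#' planar spiral with a vertical pitch, swept by a tube of constant radius.
#' The geometry is analytic, so fiducials and the true A-value are known in
#' closed form before voxelization -- the phantom's purpose is ground truth
#' for validating the registration pipeline, with anatomical realism
#' secondary. The spiral center curve at turning angle `phi` (radians) is
#' `center + (r(phi) cos phi, r(phi) sin phi, z0 + height_pitch * phi/2pi)`
#' with `r(phi) = basal_radius * radius_decay^(phi/2pi)`. The round-window
#' fiducial sits on the outer tube wall at the spiral start and the
#' basal-turn fiducial on the outer wall half a turn later (diametrically
#' across the basal turn), giving the closed-form A-value
#' `sqrt((basal_radius + r(pi) + 2 tube_radius)^2 + (height_pitch/2)^2)`.
#'
#' Defaults emulate a human-scale cochlea (A about 8.8 mm, 2.5 turns) on an
#' atlas-like 0.1 mm / 128^3 grid.
#'
#' @param basal_radius mm, spiral radius at the start (controls the A-value).
#' @param turns number of spiral turns.
#' @param tube_radius mm, radius of the swept tube.
#' @param height_pitch mm of axial rise per turn.
#' @param radius_decay radial decay factor per turn, in (0, 1].
#' @param grid_shape integer 3-vector of voxels.
#' @param spacing mm per voxel.
#' @param noise_sd additive Gaussian noise SD (intensity units; tube = 1).
#' @param blur_fwhm Gaussian blur FWHM in mm (point-spread emulation).
#' @param seed integer, makes the generated volume deterministic.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(basal_radius = 4.0, turns = 2.5, tube_radius = 0.65,
                         height_pitch = 1.8, radius_decay = 0.75,
                         grid_shape = c(128L, 128L, 128L),
                         spacing = c(0.1, 0.1, 0.1),
                         noise_sd = 0.02, blur_fwhm = 0.25,
                         seed = 20180122L) {
  stopifnot(basal_radius > 0, turns > 0.5, tube_radius > 0,
            height_pitch >= 0, radius_decay > 0, radius_decay <= 1,
            length(grid_shape) == 3, all(grid_shape >= 8),
            length(spacing) == 3 || length(spacing) == 1,
            noise_sd >= 0, blur_fwhm >= 0)
  spacing <- rep(as.numeric(spacing), length.out = 3)
  structure(list(basal_radius = basal_radius, turns = turns,
                 tube_radius = tube_radius, height_pitch = height_pitch,
                 radius_decay = radius_decay,
                 grid_shape = as.integer(grid_shape), spacing = spacing,
                 noise_sd = noise_sd, blur_fwhm = blur_fwhm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

phantom_radius_at <- function(spec, phi)
  spec$basal_radius * spec$radius_decay^(phi / (2 * pi))

phantom_z0 <- function(spec) -spec$height_pitch * spec$turns / 2

#' Points on the phantom's spiral center curve
#'
#' The phantom volume is centered on the world origin, so curve coordinates
#' are absolute world mm.
#'
#' @param spec a [phantom_spec()].
#' @param phi numeric vector of turning angles in radians
#'   (`0` to `2 * pi * turns`).
#' @return `length(phi)` x 3 matrix of world points.
#' @export
phantom_curve <- function(spec, phi) {
  r <- phantom_radius_at(spec, phi)
  cbind(r * cos(phi), r * sin(phi),
        phantom_z0(spec) + spec$height_pitch * phi / (2 * pi))
}

#' Analytic fiducials of a phantom
#'
#' `round_window` and `basal_turn` are the A-value pair (outer tube wall at
#' the spiral start and half a turn across the basal turn); `apex` (curve
#' end), `modiolus` (central axis) and `oval_window` (outer wall a third of
#' a turn in) serve as the four registration-initialization landmarks.
#'
#' @param spec a [phantom_spec()].
#' @return a [fiducial_set()] (laterality `"right"`).
#' @export
phantom_fiducials <- function(spec) {
  z0 <- phantom_z0(spec)
  rpi <- phantom_radius_at(spec, pi)
  phi_ow <- 2 * pi / 3
  row_ow <- phantom_radius_at(spec, phi_ow) + spec$tube_radius
  apex_phi <- 2 * pi * spec$turns
  apex <- drop(phantom_curve(spec, apex_phi))
  fiducial_set(list(
    round_window = c(spec$basal_radius + spec$tube_radius, 0, z0),
    basal_turn = c(-(rpi + spec$tube_radius), 0, z0 + spec$height_pitch / 2),
    apex = apex,
    modiolus = c(0, 0, 0),
    oval_window = c(row_ow * cos(phi_ow), row_ow * sin(phi_ow),
                    z0 + spec$height_pitch * phi_ow / (2 * pi))),
    laterality = "right")
}

#' Closed-form A-value of a phantom
#' @param spec a [phantom_spec()].
#' @return A-value in mm.
#' @export
phantom_true_a_value <- function(spec) {
  dx <- spec$basal_radius + phantom_radius_at(spec, pi) + 2 * spec$tube_radius
  dz <- spec$height_pitch / 2
  sqrt(dx^2 + dz^2)
}

#' Minimum distance from world points to the phantom center curve
#'
#' Dense sampling of the curve followed by local golden-section refinement;
#' used to verify voxelized tube surfaces against the analytic geometry.
#'
#' @param spec a [phantom_spec()].
#' @param points length-3 vector or N x 3 matrix of world points.
#' @param n_samples curve discretization for the global search.
#' @return numeric vector of distances (mm).
#' @export
phantom_curve_distance <- function(spec, points, n_samples = 4000L) {
  p <- as_point_matrix(points)
  phi <- seq(0, 2 * pi * spec$turns, length.out = n_samples)
  cv <- phantom_curve(spec, phi)
  vapply(seq_len(nrow(p)), function(i) {
    d2 <- (cv[, 1] - p[i, 1])^2 + (cv[, 2] - p[i, 2])^2 + (cv[, 3] - p[i, 3])^2
    j <- which.min(d2)
    lo <- phi[max(1, j - 1)]; hi <- phi[min(n_samples, j + 1)]
    f <- function(a) sum((drop(phantom_curve(spec, a)) - p[i, ])^2)
    sqrt(stats::optimize(f, c(lo, hi))$objective)
  }, 0)
}

#' Generate a voxelized cochlea phantom with known ground truth
#'
#' Rasterizes the spiral tube (bright tube on dark background), applies
#' Gaussian blur and additive Gaussian noise, and returns the volume
#' together with analytically placed fiducials and the closed-form A-value.
#' Deterministic for a fixed spec (including its seed). The volume is
#' centered on the world origin with an axis-aligned identity direction.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` ([volume3d()]), `fiducials`
#'   ([fiducial_set()]), `true_a_value` (mm) and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  # geometric sanity: adjacent windings must not merge
  if (spec$turns > 1) {
    phi_last <- 2 * pi * (spec$turns - 1)
    gap_r <- phantom_radius_at(spec, phi_last) - phantom_radius_at(spec, phi_last + 2 * pi)
    gap <- sqrt(gap_r^2 + spec$height_pitch^2)
    if (gap < 2 * spec$tube_radius)
      stop("tube self-intersects: winding gap ", signif(gap, 3),
           " mm < tube diameter")
  }
  half_extent <- (spec$grid_shape - 1) * spec$spacing / 2
  rmax_xy <- spec$basal_radius + spec$tube_radius
  zmax <- spec$height_pitch * spec$turns / 2 + spec$tube_radius
  if (rmax_xy > min(half_extent[1:2]) || zmax > half_extent[3])
    stop("tube exceeds the grid extent; enlarge grid_shape or spacing")
  origin <- -half_extent
  # curve sampled finely relative to the voxel size
  step <- min(spec$spacing) / 3
  arc <- 2 * pi * spec$basal_radius * spec$turns # upper bound on length
  phi <- seq(0, 2 * pi * spec$turns, length.out = max(200L, ceiling(arc / step)))
  cv <- phantom_curve(spec, phi)
  dist <- tube_distance_cpp(spec$grid_shape, spec$spacing, origin, cv,
                            spec$tube_radius + 2 * max(spec$spacing))
  vox <- array(as.numeric(dist <= spec$tube_radius), spec$grid_shape)
  vol <- volume3d(vox, spec$spacing, origin)
  if (spec$blur_fwhm > 0)
    vol <- smooth_volume(vol, rep(spec$blur_fwhm / 2.35482, 3))
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed,
                       stats::rnorm(length(vol$voxels), sd = spec$noise_sd))
    vol$voxels <- vol$voxels + array(noise, dim(vol$voxels))
  }
  fids <- phantom_fiducials(spec)
  list(volume = vol, fiducials = fids,
       true_a_value = phantom_true_a_value(spec), spec = spec)
}

#' Random deformation specification
#'
#' Ranges for the simulated inter-specimen variation applied to a phantom: a
#' random affine (per-axis scaling, rotation about a random axis,
#' translation) composed with a random smooth B-spline displacement field.
#'
#' @param scale_range length-2, per-axis scale factors drawn uniformly.
#' @param rotation_max_deg max rotation angle (degrees) about a random axis.
#' @param translation_max_mm max translation magnitude (mm).
#' @param nonrigid_grid B-spline control grid shape.
#' @param nonrigid_max_mm max control-point (hence field) displacement, mm.
#' @param seed integer seed.
#' @return an object of class `deformation_spec`.
#' @export
deformation_spec <- function(scale_range = c(0.9, 1.1), rotation_max_deg = 10,
                             translation_max_mm = 5,
                             nonrigid_grid = c(4L, 4L, 4L),
                             nonrigid_max_mm = 2, seed = 1L) {
  stopifnot(length(scale_range) == 2, scale_range[1] <= scale_range[2],
            scale_range[1] > 0, rotation_max_deg >= 0, translation_max_mm >= 0,
            nonrigid_max_mm >= 0, all(nonrigid_grid >= 4))
  structure(list(scale_range = as.numeric(scale_range),
                 rotation_max_deg = rotation_max_deg,
                 translation_max_mm = translation_max_mm,
                 nonrigid_grid = as.integer(nonrigid_grid),
                 nonrigid_max_mm = nonrigid_max_mm, seed = as.integer(seed)),
            class = "deformation_spec")
}

rotation_axis_angle <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  k <- rbind(c(0, -a[3], a[2]), c(a[3], 0, -a[1]), c(-a[2], a[1], 0))
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}

#' Draw a random deformation (affine + smooth B-spline) for a region
#'
#' Deterministic per seed. The affine part is centered on the ROI center;
#' the non-rigid control displacements have norms at most `nonrigid_max_mm`
#' (and at most 0.4x the control spacing, preserving invertibility), which
#' bounds the whole interpolated field by the same amount.
#'
#' @param spec a [deformation_spec()].
#' @param roi [roi3d()] the deformation must cover (e.g. the phantom's
#'   extent, [volume_extent_roi()]).
#' @return a [transform_chain()] (affine then B-spline).
#' @export
sample_deformation <- function(spec, roi) {
  stopifnot(inherits(spec, "deformation_spec"), inherits(roi, "roi3d"))
  draws <- with_seed(spec$seed, {
    list(scales = stats::runif(3, spec$scale_range[1], spec$scale_range[2]),
         axis = stats::rnorm(3),
         angle = stats::runif(1, 0, spec$rotation_max_deg * pi / 180),
         tdir = stats::rnorm(3),
         tmag = stats::runif(1, 0, spec$translation_max_mm),
         cdisp = matrix(stats::rnorm(prod(spec$nonrigid_grid) * 3),
                        ncol = 3))
  })
  r <- if (spec$rotation_max_deg > 0)
    rotation_axis_angle(draws$axis, draws$angle) else diag(3)
  m <- r %*% diag(draws$scales)
  tvec <- if (spec$translation_max_mm > 0)
    draws$tdir / sqrt(sum(draws$tdir^2)) * draws$tmag else c(0, 0, 0)
  ctr <- (roi$lower + roi$upper) / 2
  aff <- affine_transform(m, ctr + tvec - as.numeric(m %*% ctr))
  grid <- bspline_grid_for_roi(roi, spec$nonrigid_grid, margin = 0.02)
  cap <- min(spec$nonrigid_max_mm, 0.4 * min(grid$grid_spacing))
  disp <- draws$cdisp
  nrm <- sqrt(rowSums(disp^2))
  scale_to <- with_seed(spec$seed + 1L, stats::runif(nrow(disp), 0, cap))
  disp <- disp / pmax(nrm, 1e-12) * scale_to
  if (spec$nonrigid_max_mm == 0) disp[] <- 0
  # the bspline acts in post-affine coordinates; anchor its grid there
  corners <- as.matrix(expand.grid(c(roi$lower[1], roi$upper[1]),
                                   c(roi$lower[2], roi$upper[2]),
                                   c(roi$lower[3], roi$upper[3])))
  mapped <- apply_to_point(aff, corners)
  span <- roi3d(apply(mapped, 2, min), apply(mapped, 2, max))
  grid2 <- bspline_grid_for_roi(span, spec$nonrigid_grid, margin = 0.02)
  bs <- bspline_transform(grid2$grid_shape, grid2$grid_origin,
                          grid2$grid_spacing, disp)
  transform_chain(aff, bs)
}

#' Resample a phantom through a deformation onto a clinical-like grid
#'
#' Renders the "clinical CT" counterpart of an atlas-like phantom: the
#' volume is resampled through the chain (target intensity at `y` is the
#' phantom at `T^-1(y)`) onto a coarser grid centered on the mapped phantom,
#' then degraded with extra blur, a linear intensity transfer and Gaussian
#' noise to emulate the modality gap. Fiducials are mapped through the
#' chain directly, and the true A-value is recomputed from the mapped pair.
#'
#' @param phantom_volume the source [volume3d()].
#' @param fiducials the source [fiducial_set()].
#' @param chain a [transform_chain()] mapping source to target coordinates.
#' @param target_spacing mm per voxel of the target grid (default 0.6, a
#'   clinical-CT-like resolution).
#' @param grid_shape target grid size (default 64^3).
#' @param blur_fwhm extra Gaussian blur FWHM in mm (default 0.7).
#' @param noise_sd additive Gaussian noise SD after the intensity transfer.
#' @param intensity_scale,intensity_offset linear transfer applied to the
#'   resampled intensities (NCC is invariant to it; defaults emulate a
#'   CT-number-like range).
#' @param background intensity assumed outside the source volume.
#' @param seed noise seed.
#' @return list with `volume`, `fiducials` (chain-mapped),
#'   `true_a_value` (mm).
#' @export
make_target <- function(phantom_volume, fiducials, chain,
                        target_spacing = c(0.6, 0.6, 0.6),
                        grid_shape = c(64L, 64L, 64L),
                        blur_fwhm = 0.7, noise_sd = 20,
                        intensity_scale = 1000, intensity_offset = -200,
                        background = 0, seed = 1L) {
  stopifnot(inherits(phantom_volume, "volume3d"),
            inherits(fiducials, "fiducial_set"))
  if (!inherits(chain, "transform_chain")) chain <- transform_chain(chain)
  target_spacing <- rep(as.numeric(target_spacing), length.out = 3)
  grid_shape <- rep(as.integer(grid_shape), length.out = 3)
  ctr <- chain_apply_na(chain, matrix(volume_world_center(phantom_volume), 1))
  origin <- as.numeric(ctr) - (grid_shape - 1) * target_spacing / 2
  tgt <- volume3d(array(0, grid_shape), target_spacing, origin)
  y <- sample_grid_points(tgt, volume_extent_roi(tgt), 1L)
  x <- invert_chain_at(chain, y)
  vals <- sample_at_world(phantom_volume, x)
  vals[is.na(vals)] <- background
  tgt$voxels <- array(vals, grid_shape)
  if (blur_fwhm > 0) tgt <- smooth_volume(tgt, rep(blur_fwhm / 2.35482, 3))
  tgt$voxels <- tgt$voxels * intensity_scale + intensity_offset
  if (noise_sd > 0)
    tgt$voxels <- tgt$voxels +
      array(with_seed(seed, stats::rnorm(length(tgt$voxels), sd = noise_sd)),
            grid_shape)
  pts <- apply_to_point(chain, fiducials$points)
  rownames(pts) <- rownames(fiducials$points)
  if (!all(roi_contains(volume_extent_roi(tgt), pts)))
    stop("a mapped fiducial falls outside the target grid")
  fids <- fiducial_set(pts, fiducials$laterality)
  truth <- if (all(c("round_window", "basal_turn") %in% rownames(pts)))
    compute_a_value(fids) else NA_real_
  list(volume = tgt, fiducials = fids, true_a_value = truth)
}
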