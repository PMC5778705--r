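#' Normalized cross-correlation of two intensity vectors
#'
#' Pearson-form NCC: the mean-centered dot product divided by the product of
#' standard deviations, in `[-1, 1]`. Invariant to positive affine intensity
#' rescaling of either vector, which is what makes it usable across the
#' micro-CT / clinical-CT contrast gap.
#'
#' @param fixed_samples,moving_samples numeric vectors of equal length >= 2.
#' @return NCC in `[-1, 1]`.
#' @export
ncc <- function(fixed_samples, moving_samples) {
  a <- as.numeric(fixed_samples); b <- as.numeric(moving_samples)
  if (length(a) != length(b)) stop("sample vectors must have equal length")
  if (length(a) < 2L) stop("NCC needs at least 2 samples")
  a <- a - mean(a); b <- b - mean(b)
  va <- sum(a * a); vb <- sum(b * b)
  if (va <= 0 || vb <= 0)
    stop("degenerate metric: zero intensity variance in a sample vector")
  sum(a * b) / sqrt(va * vb)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

roi_index_grid <- function(volume, roi) {
  # 0-based indices of voxel centers inside roi (axis-aligned volumes:
  # separable per-axis ranges; otherwise full scan)
  d <- dim(volume$voxels)
  if (axis_aligned_direction(volume$direction)) {
    ax_idx <- vector("list", 3)
    for (ax in 1:3) {
      wax <- which(abs(volume$direction[, ax]) > 1e-9)
      s <- sign(volume$direction[wax, ax]) * volume$spacing[ax]
      w0 <- volume$origin[wax]
      lo <- (roi$lower[wax] - w0) / s; hi <- (roi$upper[wax] - w0) / s
      if (s < 0) { tmp <- lo; lo <- hi; hi <- tmp }
      idx <- seq(ceiling(lo - 1e-9), floor(hi + 1e-9))
      ax_idx[[ax]] <- idx[idx >= 0 & idx <= d[ax] - 1]
    }
    if (any(vapply(ax_idx, length, 0L) == 0))
      stop("ROI contains no voxel centers")
    list(axes = ax_idx,
         count = prod(vapply(ax_idx, length, 0L)))
  } else {
    g <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
    keep <- roi_contains(roi, index_to_world(volume, g))
    if (!any(keep)) stop("ROI contains no voxel centers")
    list(grid = g[keep, , drop = FALSE], count = sum(keep))
  }
}

grid_point_from_flat <- function(ax, flat) {
  # flat is a 1-based index into the implicit expand.grid of ax (axis lists)
  n1 <- length(ax[[1]]); n2 <- length(ax[[2]])
  f <- flat - 1
  i <- f %% n1
  j <- (f %/% n1) %% n2
  k <- f %/% (n1 * n2)
  cbind(ax[[1]][i + 1], ax[[2]][j + 1], ax[[3]][k + 1])
}

#' Random sample of voxel-center world points inside an ROI
#'
#' Uniform sample without replacement of the voxel centers whose world
#' coordinates fall inside `roi`, of size `round(fraction * count)`;
#' `fraction = 1` returns every center. Deterministic for a fixed seed. This
#' is the sparse-sampling step of the affine stage (default fraction 0.001).
#'
#' @param volume a [volume3d()].
#' @param roi an [roi3d()].
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer RNG seed.
#' @return N x 3 matrix of world coordinates (mm).
#' @export
sample_points <- function(volume, roi, fraction, seed = 20180122L) {
  if (!(fraction > 0 && fraction <= 1)) stop("`fraction` must be in (0, 1]")
  gi <- roi_index_grid(volume, roi)
  n <- round(fraction * gi$count)
  if (fraction == 1) n <- gi$count
  if (n < 10)
    stop("sample size ", n, " < 10; increase `fraction` or enlarge the ROI")
  if (!is.null(gi$axes)) {
    flat <- if (n == gi$count) seq_len(gi$count)
            else with_seed(seed, sample.int(gi$count, n))
    idx <- grid_point_from_flat(gi$axes, sort(flat))
  } else {
    rows <- if (n == gi$count) seq_len(gi$count)
            else with_seed(seed, sample.int(gi$count, n))
    idx <- gi$grid[sort(rows), , drop = FALSE]
  }
  index_to_world(volume, idx)
}

sample_grid_points <- function(volume, roi, stride) {
  # every stride-th voxel center inside roi (the dense stage at clinical
  # voxel density)
  stride <- rep(as.integer(stride), length.out = 3)
  gi <- roi_index_grid(volume, roi)
  if (!is.null(gi$axes)) {
    ax <- lapply(1:3, function(a) gi$axes[[a]][seq(1, length(gi$axes[[a]]), by = stride[a])])
    idx <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  } else {
    keep <- rep(TRUE, nrow(gi$grid))
    for (a in 1:3) keep <- keep & (gi$grid[, a] %% stride[a] == 0)
    idx <- gi$grid[keep, , drop = FALSE]
  }
  index_to_world(volume, idx)
}

#' Evaluate the NCC objective for a transform
#'
#' Computes NCC between the atlas intensities at `points` (world mm, sampled
#' in the atlas) and the target intensities, trilinearly interpolated at the
#' transformed positions. Points mapping outside the target extent (or
#' outside a B-spline stage's support) are excluded from both vectors; if
#' fewer than half remain the overlap is considered insufficient.
#'
#' @param atlas,target [volume3d()] images.
#' @param transform transform or [transform_chain()] mapping atlas world
#'   coordinates to target world coordinates.
#' @param points N x 3 world points in the atlas (e.g. from
#'   [sample_points()]).
#' @return NCC value with attribute `n_used`.
#' @export
evaluate_metric <- function(atlas, target, transform, points) {
  pts <- as_point_matrix(points)
  f <- sample_at_world(atlas, pts)
  mapped <- chain_apply_na(if (inherits(transform, "transform_chain"))
    transform else transform_chain(transform), pts)
  m <- sample_at_world(target, mapped)
  ok <- !is.na(f) & !is.na(m)
  if (sum(ok) < 0.5 * nrow(pts))
    stop("insufficient overlap: only ", sum(ok), " of ", nrow(pts),
         " sample points map into the target")
  structure(ncc(f[ok], m[ok]), n_used = sum(ok))
}

#' Registration configuration
#'
#' Defaults mirror the standard cascade parameters: NCC objective
#' throughout, 0.1% sparse sampling for the affine stage, dense (full
#' clinical-density) sampling for the B-spline stage, and a 4x4x4 control
#' mesh (64 control points).
#'
#' @param metric similarity metric; only `"NCC"` is provided.
#' @param affine_sample_fraction fraction of atlas-ROI voxel centers used by
#'   the affine stage (default 0.001, i.e. 0.1%).
#' @param bspline_sample_fraction fraction for the B-spline stage (default 1:
#'   every point of the clinical-density subgrid).
#' @param max_iterations_affine,max_iterations_bspline optimizer iteration
#'   caps per stage (per resolution level for affine).
#' @param convergence_tol stop when the NCC improvement stays below this for
#'   `convergence_patience` consecutive iterations (default 1e-5 / 5).
#' @param convergence_patience see `convergence_tol`.
#' @param multiresolution_levels smoothing/downsampling pyramid depth for the
#'   affine stage (default 3: factors 4, 2, 1).
#' @param grid_shape B-spline control points per axis (default `c(4, 4, 4)`).
#' @param displacement_cap_factor per-axis control displacement bound as a
#'   fraction of the control spacing (default 0.4, preserves invertibility).
#' @param n_starts number of optimizer starts for the affine stage (start 1
#'   is the initialization; further starts are small seeded perturbations).
#' @param histogram_match match target intensities to the atlas histogram
#'   before registration (off by default; NCC's linear-intensity invariance
#'   is the primary defense against the modality gap).
#' @param ncc_floor final-NCC floor below which a low-confidence warning is
#'   attached to results (default 0.3).
#' @param rng_seed seed for the sparse sampling and multi-start perturbations.
#' @return an object of class `registration_config`.
#' @export
registration_config <- function(metric = "NCC",
                                affine_sample_fraction = 0.001,
                                bspline_sample_fraction = 1,
                                max_iterations_affine = 200L,
                                max_iterations_bspline = 100L,
                                convergence_tol = 1e-5,
                                convergence_patience = 5L,
                                multiresolution_levels = 3L,
                                grid_shape = c(4L, 4L, 4L),
                                displacement_cap_factor = 0.4,
                                n_starts = 1L,
                                histogram_match = FALSE,
                                ncc_floor = 0.3,
                                rng_seed = 20180122L) {
  if (!identical(toupper(metric), "NCC"))
    stop('only metric = "NCC" is supported')
  stopifnot(affine_sample_fraction > 0, affine_sample_fraction <= 1,
            bspline_sample_fraction > 0, bspline_sample_fraction <= 1,
            max_iterations_affine >= 1, max_iterations_bspline >= 1,
            convergence_tol > 0, multiresolution_levels >= 1,
            length(grid_shape) == 3, all(grid_shape >= 4),
            displacement_cap_factor > 0, n_starts >= 1)
  structure(list(metric = "NCC",
                 affine_sample_fraction = affine_sample_fraction,
                 bspline_sample_fraction = bspline_sample_fraction,
                 max_iterations_affine = as.integer(max_iterations_affine),
                 max_iterations_bspline = as.integer(max_iterations_bspline),
                 convergence_tol = convergence_tol,
                 convergence_patience = as.integer(convergence_patience),
                 multiresolution_levels = as.integer(multiresolution_levels),
                 grid_shape = as.integer(grid_shape),
                 displacement_cap_factor = displacement_cap_factor,
                 n_starts = as.integer(n_starts),
                 histogram_match = isTRUE(histogram_match),
                 ncc_floor = ncc_floor,
                 rng_seed = as.integer(rng_seed)),
            class = "registration_config")
}

#' Read a registration configuration from a YAML file
#'
#' The file is a flat key/value mapping whose keys are the arguments of
#' [registration_config()]; missing keys take the defaults.
#'
#' @param path YAML file path.
#' @return a [registration_config()].
#' @export
read_registration_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(registration_config))
  extra <- setdiff(names(vals), known)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "))
  do.call(registration_config, vals)
}

#' Match a volume's intensity histogram to a reference
#'
#' Monotone quantile mapping of `volume`'s intensities onto the distribution
#' of `reference`. Optional preprocessing to soften a strong modality
#' contrast gap; NCC itself is invariant to affine intensity maps.
#'
#' @param volume,reference [volume3d()] images.
#' @param n_quantiles number of quantile anchors.
#' @return `volume` with remapped intensities.
#' @export
match_histogram <- function(volume, reference, n_quantiles = 256L) {
  p <- seq(0, 1, length.out = n_quantiles)
  qa <- stats::quantile(volume$voxels, p, names = FALSE)
  qr <- stats::quantile(reference$voxels, p, names = FALSE)
  qa <- cummax(qa + seq_along(qa) * 1e-12) # enforce strictly increasing knots
  v <- stats::approx(qa, qr, xout = as.numeric(volume$voxels), rule = 2)$y
  volume3d(array(v, dim(volume$voxels)), volume$spacing, volume$origin,
           volume$direction)
}
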