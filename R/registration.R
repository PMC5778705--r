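#' Closed-form rigid landmark registration
#'
#' Least-squares rigid fit (rotation + translation, no scaling; 6 degrees of
#' freedom) of corresponding labeled landmarks, via the SVD (Kabsch)
#' solution. This is the initialization stage of the cascade: it places the
#' atlas and target in the same spatial region before intensity-driven
#' refinement.
#'
#' @param atlas_landmarks,target_landmarks [fiducial_set()]s sharing at least
#'   3 non-collinear labels (typically apex, modiolus, round window, oval
#'   window).
#' @return a rigid [affine_transform()] mapping atlas to target world
#'   coordinates, with attributes `residual_rms` (mm) and `labels`.
#' @export
register_landmarks <- function(atlas_landmarks, target_landmarks) {
  stopifnot(inherits(atlas_landmarks, "fiducial_set"),
            inherits(target_landmarks, "fiducial_set"))
  labs <- intersect(fiducial_labels(atlas_landmarks),
                    fiducial_labels(target_landmarks))
  missing_a <- setdiff(fiducial_labels(target_landmarks), fiducial_labels(atlas_landmarks))
  missing_t <- setdiff(fiducial_labels(atlas_landmarks), fiducial_labels(target_landmarks))
  if (length(labs) < 3)
    stop("need >= 3 shared landmark labels; unmatched: ",
         paste(c(missing_a, missing_t), collapse = ", "))
  a <- atlas_landmarks$points[labs, , drop = FALSE]
  b <- target_landmarks$points[labs, , drop = FALSE]
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  if (qr(a0)$rank < 2)
    stop("degenerate landmark configuration: points are collinear")
  h <- crossprod(a0, b0)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cb - as.numeric(r %*% ca)
  out <- affine_transform(r, tr, kind = "rigid")
  res <- sweep(a %*% t(r), 2, -tr) - b
  attr(out, "residual_rms") <- sqrt(mean(rowSums(res^2)))
  attr(out, "labels") <- labs
  out
}

smooth_volume <- function(volume, sigma_mm) {
  if (all(sigma_mm <= 0)) return(volume)
  sig_vox <- sigma_mm / volume$spacing
  v <- gauss_smooth3d_cpp(volume$voxels, dim(volume$voxels), sig_vox)
  volume3d(array(v, dim(volume$voxels)), volume$spacing, volume$origin,
           volume$direction)
}

## Regular-step gradient ascent in a scaled parameter space.
## f takes the unscaled parameter vector and returns a scalar (-Inf allowed).
regular_step_ascent <- function(f, theta0, scales, max_iter, tol, patience,
                                step0 = 1, min_step = 1e-4, grad_h = 0.01) {
  u <- theta0 / scales
  fu <- function(u) f(u * scales)
  best <- fu(u)
  if (!is.finite(best)) return(list(theta = theta0, value = best, trace = best,
                                    converged = FALSE))
  step <- step0
  trace <- best
  stall <- 0L
  it <- 0L
  np <- length(u)
  while (it < max_iter) {
    it <- it + 1L
    g <- numeric(np)
    for (i in seq_len(np)) {
      up <- u; up[i] <- up[i] + grad_h
      um <- u; um[i] <- um[i] - grad_h
      fp <- fu(up); fm <- fu(um)
      g[i] <- if (is.finite(fp) && is.finite(fm)) (fp - fm) / (2 * grad_h) else 0
    }
    gn <- sqrt(sum(g^2))
    if (gn < 1e-14) break
    improved <- FALSE
    while (step >= min_step) {
      cand <- u + step * g / gn
      fc <- fu(cand)
      if (is.finite(fc) && fc > best) {
        gain <- fc - best
        u <- cand; best <- fc; improved <- TRUE
        stall <- if (gain < tol) stall + 1L else 0L
        step <- min(step * 1.5, step0)
        break
      }
      step <- step / 2
    }
    trace <- c(trace, best)
    if (!improved) break
    if (stall >= patience) break
  }
  list(theta = u * scales, value = best, trace = trace,
       converged = it < max_iter || stall >= patience)
}

#' Intensity-driven affine registration (12 DOF)
#'
#' Refines an initial chain (typically the landmark rigid fit) with a
#' 12-parameter affine correction -- translation, rotation, scaling and
#' shearing in each of x, y and z -- maximizing normalized cross-correlation
#' over a sparse random sample (default 0.1%) of atlas-ROI voxel centers.
#' Optimization is regular-step gradient ascent with central-difference
#' gradients over a Gaussian multiresolution pyramid. The returned transform
#' is the correction to apply *after* `init`; the optimizer never returns a
#' point worse than its start.
#'
#' @param atlas,target [volume3d()] images (atlas maps onto target).
#' @param init [transform_chain()] (or single transform) initializing the
#'   mapping; `NULL` for identity.
#' @param config a [registration_config()].
#' @param roi atlas-space [roi3d()] to sample from; default the full atlas
#'   extent (the atlas is assumed pre-cropped to the cochlear region).
#' @return an [affine_transform()] with attributes `ncc_initial`,
#'   `ncc_final`, `converged`, `trace`.
#' @export
register_affine <- function(atlas, target, init = NULL,
                            config = registration_config(), roi = NULL) {
  if (is.null(init)) init <- transform_chain(identity_affine())
  if (!inherits(init, "transform_chain")) init <- transform_chain(init)
  if (is.null(roi)) roi <- volume_extent_roi(atlas)
  if (config$histogram_match) target <- match_histogram(target, atlas)
  levels <- rev(seq_len(config$multiresolution_levels)) # e.g. 3 2 1
  factors <- 2^(levels - 1)
  params <- rep(0, 12)
  ncc_initial <- NA_real_
  fit <- NULL
  for (li in seq_along(factors)) {
    f <- factors[li]
    pts <- sample_points(atlas, roi, config$affine_sample_fraction,
                         seed = config$rng_seed + li)
    sigma <- if (f > 1) (f / 2) * max(target$spacing) else 0
    atl_s <- smooth_volume(atlas, rep(sigma, 3))
    tgt_s <- smooth_volume(target, rep(sigma, 3))
    fv <- sample_at_world(atl_s, pts)
    keepf <- !is.na(fv)
    pts <- pts[keepf, , drop = FALSE]; fv <- fv[keepf]
    pm <- chain_apply_na(init, pts)
    center <- colMeans(pm)
    obj <- function(theta) {
      tf <- affine_from_params(theta, center)
      m <- sample_at_world(tgt_s, apply_to_point(tf, pm))
      ok <- !is.na(m)
      if (sum(ok) < 0.5 * length(m)) return(-Inf)
      fo <- fv[ok]; mo <- m[ok]
      if (stats::sd(fo) == 0 || stats::sd(mo) == 0) return(-Inf)
      ncc(fo, mo)
    }
    if (li == 1 && !is.finite(obj(rep(0, 12))))
      stop("insufficient overlap at initialization; check landmarks/ROI")
    scales <- c(rep(1, 3), rep(0.05, 9))
    starts <- list(params)
    if (li == 1 && config$n_starts > 1) {
      for (s in seq_len(config$n_starts - 1))
        starts[[s + 1]] <- params + with_seed(config$rng_seed + 1000L + s,
          c(stats::runif(3, -1, 1), stats::runif(9, -0.03, 0.03)))
    }
    # never start a level worse than the identity correction
    if (li > 1 && obj(rep(0, 12)) > obj(params)) starts[[1]] <- rep(0, 12)
    fits <- lapply(starts, function(th0)
      regular_step_ascent(obj, th0, scales,
                          max_iter = config$max_iterations_affine,
                          tol = config$convergence_tol,
                          patience = config$convergence_patience))
    fit <- fits[[which.max(vapply(fits, `[[`, 0, "value"))]]
    params <- fit$theta
  }
  # initial metric on the final level's sample: the ascent starts from the
  # better of the carried parameters and the identity correction, so
  # ncc_final >= ncc_initial by construction
  ncc_initial <- obj(rep(0, 12))
  if (!fit$converged)
    warning("affine registration hit max_iterations without convergence")
  out <- affine_from_params(params, center = center)
  attr(out, "ncc_initial") <- ncc_initial
  attr(out, "ncc_final") <- fit$value
  attr(out, "converged") <- fit$converged
  attr(out, "trace") <- fit$trace
  out
}

#' Intensity-driven B-spline free-form deformation registration
#'
#' Refines the affine-aligned mapping with a cubic B-spline deformation on a
#' coarse control mesh (default 4x4x4 = 64 control points, 192 scalar
#' parameters), maximizing NCC over the dense sample: every atlas-ROI voxel
#' center on a subgrid strided to the target's voxel density, i.e. 100% of
#' the clinical-resolution information. Ascent uses the analytic NCC
#' gradient with respect to the control displacements; displacements are
#' capped at `displacement_cap_factor * grid_spacing` per axis to keep the
#' deformation invertible. The correction applies after `init`; the final
#' NCC is never below the NCC of the initialization.
#'
#' @inheritParams register_affine
#' @param init [transform_chain()] containing the rigid and affine stages.
#' @param stride integer (scalar or per-axis) subgrid stride for the dense
#'   sample; default `round(target_spacing / atlas_spacing)`, clamped to
#'   >= 1.
#' @return a [bspline_transform()] with attributes `ncc_initial`,
#'   `ncc_final`, `n_points`, `converged`.
#' @export
register_bspline <- function(atlas, target, init,
                             config = registration_config(), roi = NULL,
                             stride = NULL) {
  if (!inherits(init, "transform_chain")) init <- transform_chain(init)
  if (is.null(roi)) roi <- volume_extent_roi(atlas)
  if (config$histogram_match) target <- match_histogram(target, atlas)
  if (is.null(stride))
    stride <- pmax(1L, as.integer(round(target$spacing / atlas$spacing)))
  pts <- sample_grid_points(atlas, roi, stride)
  if (config$bspline_sample_fraction < 1) {
    n <- max(10L, round(config$bspline_sample_fraction * nrow(pts)))
    pts <- pts[sort(with_seed(config$rng_seed, sample.int(nrow(pts), n))), ,
               drop = FALSE]
  }
  fv <- sample_at_world(atlas, pts)
  keep <- !is.na(fv)
  pts <- pts[keep, , drop = FALSE]; fv <- fv[keep]
  q <- chain_apply_na(init, pts)
  # control grid spans the init-mapped atlas ROI (slightly padded)
  corners <- as.matrix(expand.grid(c(roi$lower[1], roi$upper[1]),
                                   c(roi$lower[2], roi$upper[2]),
                                   c(roi$lower[3], roi$upper[3])))
  mc <- chain_apply_na(init, corners)
  span <- roi3d(apply(mc, 2, min), apply(mc, 2, max))
  grid <- bspline_grid_for_roi(span, config$grid_shape, margin = 0.02)
  if (any(vapply(1:3, function(a) {
    lo <- grid$grid_origin[a] + grid$grid_spacing[a]
    hi <- grid$grid_origin[a] + grid$grid_spacing[a] * (grid$grid_shape[a] - 2)
    min(q[, a]) < lo - 1e-9 || max(q[, a]) > hi + 1e-9
  }, TRUE)))
    stop("B-spline control grid does not cover the registration ROI")
  cap <- config$displacement_cap_factor * grid$grid_spacing
  # world -> continuous target index, as an affine map for the C++ kernel
  A <- diag(1 / target$spacing) %*% t(target$direction)
  bv <- as.numeric(-A %*% target$origin)
  evalf <- function(disp, want_grad = FALSE)
    bspline_ncc_grad_cpp(q, fv, target$voxels, dim(target$voxels), A, bv,
                         grid$grid_origin, grid$grid_spacing, disp,
                         grid$grid_shape, want_grad)
  disp <- grid$displacements
  cur <- evalf(disp, want_grad = TRUE)
  if (is.na(cur$ncc) || cur$n_used < 0.5 * nrow(pts))
    stop("insufficient overlap at B-spline initialization")
  ncc_init <- cur$ncc
  best <- cur$ncc
  g <- cur$grad
  step <- 0.5 * min(target$spacing)
  step0 <- step
  stall <- 0L; it <- 0L; converged <- FALSE
  while (it < config$max_iterations_bspline) {
    it <- it + 1L
    gmax <- max(abs(g))
    if (gmax < 1e-14) { converged <- TRUE; break }
    dir <- g / gmax
    improved <- FALSE
    while (step >= 1e-4) {
      cand <- disp + step * dir
      for (a in 1:3) cand[, a] <- pmin(pmax(cand[, a], -cap[a]), cap[a])
      fc <- evalf(cand)$ncc
      if (!is.na(fc) && fc > best) {
        gain <- fc - best
        disp <- cand; best <- fc; improved <- TRUE
        stall <- if (gain < config$convergence_tol) stall + 1L else 0L
        step <- min(step * 1.5, step0)
        break
      }
      step <- step / 2
    }
    if (!improved) { converged <- TRUE; break }
    if (stall >= config$convergence_patience) { converged <- TRUE; break }
    g <- evalf(disp, want_grad = TRUE)$grad
  }
  if (!converged)
    warning("B-spline registration hit max_iterations without convergence")
  out <- bspline_transform(grid$grid_shape, grid$grid_origin,
                           grid$grid_spacing, disp)
  attr(out, "ncc_initial") <- ncc_init
  attr(out, "ncc_final") <- best
  attr(out, "n_points") <- nrow(pts)
  attr(out, "converged") <- converged
  out
}
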