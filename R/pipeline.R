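#' Atlas bundle: reference volume plus its fiducials
#'
#' Bundles the atlas image with the two measurement fiducials (round window
#' center and the furthest point on the basal turn, whose distance is the
#' A-value) and the four initialization landmarks (cochlear apex, modiolus,
#' round window, oval window), all in the volume's world frame.
#'
#' @param volume atlas [volume3d()] (already cropped to the cochlear region).
#' @param aval_fiducials [fiducial_set()] with `round_window` and
#'   `basal_turn`.
#' @param init_landmarks [fiducial_set()] with `apex`, `modiolus`,
#'   `round_window`, `oval_window`.
#' @param laterality `"left"` or `"right"`.
#' @return an object of class `atlas_bundle`.
#' @export
atlas_bundle <- function(volume, aval_fiducials, init_landmarks, laterality) {
  stopifnot(inherits(volume, "volume3d"),
            inherits(aval_fiducials, "fiducial_set"),
            inherits(init_landmarks, "fiducial_set"))
  aval_fiducials <- subset_fiducials(aval_fiducials, c("round_window", "basal_turn"))
  for (lab in c("apex", "modiolus", "round_window", "oval_window"))
    fiducial_point(init_landmarks, lab) # errors if missing
  if (!laterality %in% c("left", "right"))
    stop('atlas `laterality` must be "left" or "right"')
  structure(list(volume = volume, aval_fiducials = aval_fiducials,
                 init_landmarks = init_landmarks, laterality = laterality),
            class = "atlas_bundle")
}

#' @export
print.atlas_bundle <- function(x, ...) {
  cat(sprintf("<atlas_bundle> %s cochlea, A-value %.3f mm\n", x$laterality,
              compute_a_value(x$aval_fiducials)))
  print(x$volume)
  invisible(x)
}

#' Mirror an atlas bundle to the opposite laterality
#'
#' Volume and both fiducial sets are reflected about the same center plane
#' (an isometry, so the atlas A-value is preserved exactly) and the
#' laterality flag is flipped.
#'
#' @param bundle an [atlas_bundle()].
#' @param plane_axis grid axis for [mirror_volume()].
#' @return the mirrored [atlas_bundle()].
#' @export
mirror_atlas <- function(bundle, plane_axis = 1) {
  atlas_bundle(mirror_volume(bundle$volume, plane_axis),
               mirror_fiducials(bundle$aval_fiducials, bundle$volume, plane_axis),
               mirror_fiducials(bundle$init_landmarks, bundle$volume, plane_axis),
               if (bundle$laterality == "left") "right" else "left")
}

#' Select (or derive) the atlas matching a target's laterality
#'
#' Returns the bundle unchanged when lateralities agree; otherwise the
#' mirrored bundle, so a single atlas serves both ears.
#'
#' @param bundle an [atlas_bundle()].
#' @param target_laterality `"left"` or `"right"`.
#' @param plane_axis mirroring axis, as in [mirror_volume()].
#' @return an [atlas_bundle()] with the requested laterality.
#' @export
select_atlas <- function(bundle, target_laterality, plane_axis = 1) {
  if (!is.character(target_laterality) ||
      !target_laterality %in% c("left", "right"))
    stop('`target_laterality` must be "left" or "right" (pass the flag explicitly)')
  if (identical(bundle$laterality, target_laterality)) bundle
  else mirror_atlas(bundle, plane_axis)
}

#' A-value from a fiducial set
#'
#' The A-value is the straight-line distance (mm) from the center of the
#' round window to the furthest point on the basal turn.
#'
#' @param fiducials a [fiducial_set()] containing `round_window` and
#'   `basal_turn`.
#' @return distance in mm.
#' @export
compute_a_value <- function(fiducials) {
  rw <- fiducial_point(fiducials, "round_window")
  bt <- fiducial_point(fiducials, "basal_turn")
  sqrt(sum((rw - bt)^2))
}

#' Default registration ROI around the target landmarks
#'
#' A fixed-margin axis-aligned box around the four initialization landmarks;
#' the margin (default 10 mm) is configurable because cropping margins are a
#' user choice.
#'
#' @param landmarks target [fiducial_set()].
#' @param margin_mm margin beyond the landmark bounding box.
#' @return an [roi3d()].
#' @export
landmark_roi <- function(landmarks, margin_mm = 10) {
  pts <- landmarks$points
  roi3d(apply(pts, 2, min) - margin_mm, apply(pts, 2, max) + margin_mm)
}

#' Measure the A-value of a target scan by atlas registration
#'
#' Runs the full cascade: closed-form landmark rigid fit, ROI cropping of
#' the target, sparse-sample affine refinement, dense B-spline free-form
#' refinement; then applies the recovered chain to the atlas A-value
#' fiducials and reports the distance between the propagated round-window
#' and basal-turn points as the target's A-value. Per-stage NCC values are
#' evaluated on the common dense sample, and the affine stage is only
#' retained if it does not degrade that metric, so `stage_metrics` is
#' non-decreasing.
#'
#' @param atlas an [atlas_bundle()] (select laterality first with
#'   [select_atlas()]).
#' @param target target [volume3d()].
#' @param target_landmarks [fiducial_set()] with the four initialization
#'   landmarks placed on the target.
#' @param roi target-space [roi3d()]; default [landmark_roi()] of
#'   `target_landmarks`.
#' @param config a [registration_config()].
#' @param cdl_equations optional list of [cdl_equation()]s evaluated at the
#'   measured A-value.
#' @param verbose log each stage to the console.
#' @return an object of class `a_value_result`: list with `a_value` (mm),
#'   `propagated_fiducials`, `transform_chain`, `stage_metrics` (NCC after
#'   the landmark, affine and B-spline stages), `cdl_estimates`,
#'   `low_confidence` flag and `landmark_residual_rms`.
#' @export
measure_a_value <- function(atlas, target, target_landmarks, roi = NULL,
                            config = registration_config(),
                            cdl_equations = list(), verbose = FALSE) {
  stopifnot(inherits(atlas, "atlas_bundle"), inherits(target, "volume3d"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  if (is.null(roi)) roi <- landmark_roi(target_landmarks)

  rigid <- stage("landmark", register_landmarks(atlas$init_landmarks, target_landmarks))
  say("landmark stage: residual RMS %.4f mm", attr(rigid, "residual_rms"))
  tgt <- stage("crop", crop_to_roi(target, roi))
  atlas_roi <- volume_extent_roi(atlas$volume)

  # common dense sample for stage metrics (clinical-density subgrid)
  stride <- pmax(1L, as.integer(round(tgt$spacing / atlas$volume$spacing)))
  dense <- sample_grid_points(atlas$volume, atlas_roi, stride)
  metric_of <- function(chain)
    as.numeric(evaluate_metric(atlas$volume, tgt, chain, dense))

  chain1 <- transform_chain(rigid)
  ncc1 <- stage("landmark", metric_of(chain1))
  say("landmark stage: NCC %.4f", ncc1)

  affine <- stage("affine", register_affine(atlas$volume, tgt, chain1, config,
                                            roi = atlas_roi))
  chain2 <- transform_chain(rigid, affine)
  ncc2 <- stage("affine", metric_of(chain2))
  if (ncc2 < ncc1) { # keep the cascade monotone on the reporting sample
    affine <- identity_affine()
    chain2 <- transform_chain(rigid, affine)
    ncc2 <- ncc1
  }
  say("affine stage: NCC %.4f", ncc2)

  bspl <- stage("bspline", register_bspline(atlas$volume, tgt, chain2, config,
                                            roi = atlas_roi, stride = stride))
  chain3 <- transform_chain(rigid, affine, bspl)
  ncc3 <- stage("bspline", metric_of(chain3))
  if (ncc3 < ncc2) {
    bspl <- bspline_transform(bspl$grid_shape, bspl$grid_origin, bspl$grid_spacing)
    chain3 <- transform_chain(rigid, affine, bspl)
    ncc3 <- ncc2
  }
  say("bspline stage: NCC %.4f", ncc3)

  prop <- chain_apply_na(chain3, atlas$aval_fiducials$points)
  rownames(prop) <- rownames(atlas$aval_fiducials$points)
  prop_set <- fiducial_set(prop, atlas$laterality)
  a <- compute_a_value(prop_set)
  low_conf <- ncc3 < config$ncc_floor
  if (low_conf)
    warning(sprintf("final NCC %.3f below confidence floor %.2f: low-confidence A-value",
                    ncc3, config$ncc_floor))
  cdl <- lapply(cdl_equations, function(eq) estimate_cdl(a, eq))
  names(cdl) <- vapply(cdl_equations, function(eq) eq$name, "")
  structure(list(a_value = a,
                 propagated_fiducials = prop_set,
                 transform_chain = chain3,
                 stage_metrics = c(landmark = ncc1, affine = ncc2, bspline = ncc3),
                 cdl_estimates = cdl,
                 low_confidence = low_conf,
                 landmark_residual_rms = attr(rigid, "residual_rms")),
            class = "a_value_result")
}

#' @export
print.a_value_result <- function(x, ...) {
  cat(sprintf("<a_value_result> A-value %.2f mm%s\n", x$a_value,
              if (x$low_confidence) " (LOW CONFIDENCE)" else ""))
  cat(sprintf("stage NCC: landmark %.4f -> affine %.4f -> bspline %.4f\n",
              x$stage_metrics[1], x$stage_metrics[2], x$stage_metrics[3]))
  if (length(x$cdl_estimates))
    for (nm in names(x$cdl_estimates))
      cat(sprintf("CDL [%s]: %.2f mm\n", nm, x$cdl_estimates[[nm]]))
  invisible(x)
}

#' Serialize an A-value result to JSON
#'
#' Writes the A-value (0.01 mm precision in the summary field, full
#' precision alongside), propagated fiducials, per-stage NCC, CDL estimates
#' and the transform chain.
#'
#' @param result an `a_value_result` from [measure_a_value()].
#' @param path output `.json` path.
#' @return the path, invisibly.
#' @export
write_a_value_result <- function(result, path) {
  stopifnot(inherits(result, "a_value_result"))
  obj <- list(
    a_value_mm = round(result$a_value, 2),
    a_value_mm_full = result$a_value,
    low_confidence = result$low_confidence,
    stage_metrics = as.list(result$stage_metrics),
    landmark_residual_rms_mm = result$landmark_residual_rms,
    propagated_fiducials = apply(result$propagated_fiducials$points, 1,
                                 as.numeric, simplify = FALSE),
    cdl_estimates_mm = result$cdl_estimates,
    transform_chain = transform_to_list(result$transform_chain))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
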