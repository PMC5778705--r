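toy_landmarks <- function(pts, labs = c("apex", "modiolus", "round_window",
                                        "oval_window")) {
  rownames(pts) <- labs
  fiducial_set(pts)
}

test_that("landmark registration recovers known rigid motions to 1e-9 mm", {
  a <- toy_landmarks(rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 2), c(0, 3, 9)))
  expect_id <- register_landmarks(a, a)
  expect_lt(max(abs(expect_id$matrix - diag(3))), 1e-12)
  expect_lt(attr(expect_id, "residual_rms"), 1e-12)
  th <- 30 * pi / 180
  r <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- t(r %*% t(a$points)) + rep(c(5, -2, 1), each = 4)
  b <- toy_landmarks(moved)
  tf <- register_landmarks(a, b)
  expect_equal(tf$kind, "rigid")
  expect_lt(max(abs(apply_to_point(tf, a$points) - b$points)), 1e-9)
})

test_that("uniform scaling cannot be absorbed by a 6-DOF fit", {
  a <- toy_landmarks(rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 2), c(0, 3, 9)))
  b <- toy_landmarks(a$points * 1.2)
  tf <- register_landmarks(a, b)
  expect_gt(attr(tf, "residual_rms"), 0.1)
})

test_that("degenerate and mismatched landmark sets error clearly", {
  a <- toy_landmarks(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)))
  expect_error(register_landmarks(a, a), "collinear")
  b <- fiducial_set(list(apex = c(1, 1, 1), modiolus = c(2, 2, 2)))
  g <- fiducial_set(list(x = c(0, 0, 0), y = c(1, 1, 1), z = c(0, 1, 0)))
  expect_error(register_landmarks(b, g), "unmatched")
})

test_that("closed-form rigid fit matches an exhaustive small-angle grid search", {
  set.seed(13)
  base <- matrix(runif(12, -5, 5), 4, 3)
  ang_true <- c(0.04, -0.03, 0.05)
  r <- cochmetric:::rotation_from_euler(ang_true)
  target <- t(r %*% t(base)) + rep(c(0.5, -0.2, 0.3), each = 4) +
    matrix(rnorm(12, sd = 0.05), 4, 3) # noise so the optimum is nontrivial
  a <- toy_landmarks(base); b <- toy_landmarks(target)
  tf <- register_landmarks(a, b)
  closed_rms <- attr(tf, "residual_rms")
  rms_for <- function(ang) {
    rr <- cochmetric:::rotation_from_euler(ang)
    ta <- t(rr %*% t(base))
    shift <- colMeans(target) - colMeans(ta)
    sqrt(mean(rowSums((sweep(ta, 2, -shift) - target)^2)))
  }
  # hierarchical exhaustive grid search over Euler angles
  ctr <- c(0, 0, 0); half <- 0.2
  for (round in 1:5) {
    grid <- expand.grid(seq(ctr[1] - half, ctr[1] + half, length.out = 9),
                        seq(ctr[2] - half, ctr[2] + half, length.out = 9),
                        seq(ctr[3] - half, ctr[3] + half, length.out = 9))
    vals <- apply(grid, 1, rms_for)
    ctr <- as.numeric(grid[which.min(vals), ])
    half <- half / 4
  }
  expect_lt(abs(min(vals) - closed_rms), 1e-6)
  expect_lte(closed_rms, min(vals) + 1e-9) # closed form is at least as good
})

test_that("self-registration stays at the identity with NCC ~ 1", {
  ph <- small_phantom()
  v <- ph$volume
  tf <- suppressWarnings(register_affine(v, v, config = quick_config()))
  expect_gte(attr(tf, "ncc_final"), 0.999)
  # within 0.1 voxel of the identity on the fiducial points
  pts <- ph$fiducials$points
  expect_lt(max(abs(apply_to_point(tf, pts) - pts)), 0.1 * min(v$spacing))
})

test_that("the affine optimizer never returns a worse point and its trace ascends", {
  ph <- small_phantom()
  v <- ph$volume
  tf <- suppressWarnings(register_affine(v, v, config = quick_config()))
  tr <- attr(tf, "trace")
  expect_true(all(diff(tr) >= 0))
  expect_gte(attr(tf, "ncc_final"), attr(tf, "ncc_initial"))
})

test_that("a known affine deformation is recovered within half a coarse voxel", {
  ph <- small_phantom()
  chain <- sample_deformation(
    deformation_spec(scale_range = c(1.05, 1.05), rotation_max_deg = 5,
                     translation_max_mm = 2, nonrigid_max_mm = 0, seed = 3),
    volume_extent_roi(ph$volume))
  tg <- make_target(ph$volume, ph$fiducials, chain,
                    target_spacing = c(0.5, 0.5, 0.5),
                    grid_shape = c(56, 56, 56), seed = 3)
  rigid <- register_landmarks(init_landmarks_of(ph$fiducials),
                              init_landmarks_of(tg$fiducials))
  aff <- suppressWarnings(
    register_affine(ph$volume, tg$volume, transform_chain(rigid),
                    quick_config()))
  mapped <- apply_to_point(transform_chain(rigid, aff), ph$fiducials$points)
  err <- sqrt(rowSums((mapped - tg$fiducials$points)^2))
  expect_lt(max(err), 0.5 * 0.5) # half the coarse voxel size
  expect_gte(attr(aff, "ncc_final"), attr(aff, "ncc_initial"))
})

test_that("B-spline refinement stays near zero for already-aligned images", {
  ph <- small_phantom()
  v <- ph$volume
  bs <- suppressWarnings(
    register_bspline(v, v, transform_chain(affine_transform()),
                     quick_config()))
  expect_lte(max(sqrt(rowSums(bs$displacements^2))), 0.1)
  expect_equal(as.integer(dof(bs)), 64)
  expect_equal(attr(dof(bs), "scalar_parameters"), 192)
  expect_gte(attr(bs, "ncc_final"), attr(bs, "ncc_initial"))
})

test_that("registration is deterministic for identical inputs and seed", {
  ph <- small_phantom()
  chain <- sample_deformation(
    deformation_spec(nonrigid_max_mm = 1, translation_max_mm = 2,
                     rotation_max_deg = 5, seed = 4),
    volume_extent_roi(ph$volume))
  tg <- make_target(ph$volume, ph$fiducials, chain, seed = 4)
  rigid <- register_landmarks(init_landmarks_of(ph$fiducials),
                              init_landmarks_of(tg$fiducials))
  cfg <- quick_config()
  a1 <- suppressWarnings(register_affine(ph$volume, tg$volume,
                                         transform_chain(rigid), cfg))
  a2 <- suppressWarnings(register_affine(ph$volume, tg$volume,
                                         transform_chain(rigid), cfg))
  expect_identical(a1$matrix, a2$matrix)
  expect_identical(a1$translation, a2$translation)
  b1 <- suppressWarnings(register_bspline(ph$volume, tg$volume,
                                          transform_chain(rigid, a1), cfg))
  b2 <- suppressWarnings(register_bspline(ph$volume, tg$volume,
                                          transform_chain(rigid, a1), cfg))
  expect_identical(b1$displacements, b2$displacements)
})
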