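test_that("generated fiducials reproduce the closed-form A-value exactly", {
  spec <- phantom_spec()
  expect_equal(compute_a_value(phantom_fiducials(spec)),
               phantom_true_a_value(spec), tolerance = 1e-12)
  ph <- small_phantom()
  expect_equal(compute_a_value(ph$fiducials), ph$true_a_value,
               tolerance = 1e-12)
})

test_that("phantom generation is deterministic per seed", {
  spec <- phantom_spec(grid_shape = c(32, 32, 32), spacing = c(0.4, 0.4, 0.4),
                       seed = 5)
  p1 <- generate_phantom(spec)
  p2 <- generate_phantom(spec)
  expect_identical(p1$volume$voxels, p2$volume$voxels)
  p3 <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 32),
                                      spacing = c(0.4, 0.4, 0.4), seed = 6))
  expect_false(identical(p1$volume$voxels, p3$volume$voxels))
})

test_that("phantom geometry guards fire", {
  expect_error(generate_phantom(phantom_spec(grid_shape = c(16, 16, 16),
                                             spacing = c(0.2, 0.2, 0.2))),
               "extent")
  expect_error(generate_phantom(phantom_spec(height_pitch = 0.5,
                                             radius_decay = 1)),
               "self-intersects")
})

surface_spec <- function(spacing, shape)
  phantom_spec(basal_radius = 2.5, turns = 1.5, tube_radius = 0.5,
               height_pitch = 1.4, radius_decay = 0.8, grid_shape = shape,
               spacing = rep(spacing, 3), noise_sd = 0, blur_fwhm = 0)

boundary_surface_error <- function(spec) {
  # at every inside/outside 6-neighbour face the tube surface crosses the
  # segment between the two voxel centers, so the face midpoint lies within
  # spacing/2 of the analytic surface
  ph <- generate_phantom(spec)
  vox <- ph$volume$voxels > 0.5
  d <- dim(vox)
  mids <- list()
  for (ax in 1:3) {
    take <- function(a, drop_last) {
      i <- lapply(d, seq_len)
      i[[a]] <- if (drop_last) seq_len(d[a] - 1) else 2:d[a]
      i
    }
    i1 <- take(ax, TRUE); i2 <- take(ax, FALSE)
    cross <- vox[i1[[1]], i1[[2]], i1[[3]]] != vox[i2[[1]], i2[[2]], i2[[3]]]
    w <- which(cross, arr.ind = TRUE)
    if (nrow(w) == 0) next
    idx0 <- w - 1 # 0-based index of the lower voxel of the pair
    mid <- index_to_world(ph$volume, idx0)
    mid[, ax] <- mid[, ax] + spec$spacing[ax] / 2
    mids[[ax]] <- mid
  }
  pts <- do.call(rbind, mids)
  set.seed(1)
  pick <- sample(nrow(pts), min(300, nrow(pts)))
  dists <- phantom_curve_distance(spec, pts[pick, , drop = FALSE])
  max(abs(dists - spec$tube_radius))
}

test_that("the voxelized tube surface converges to the analytic surface", {
  e_coarse <- boundary_surface_error(surface_spec(0.4, c(20, 20, 12)))
  e_fine <- boundary_surface_error(surface_spec(0.2, c(40, 40, 24)))
  # boundary voxels sit within half a voxel of the true surface
  expect_lt(e_coarse, 0.4 / 2 + 1e-9)
  expect_lt(e_fine, 0.2 / 2 + 1e-9)
  # halving the spacing halves the surface error, within factor 1.5
  ratio <- e_coarse / e_fine
  expect_gt(ratio, 2 / 1.5)
  expect_lt(ratio, 2 * 1.5)
})

test_that("sample_deformation degenerates to the identity and exact scalings", {
  roi <- roi3d(c(-6, -6, -6), c(6, 6, 6))
  idch <- sample_deformation(deformation_spec(scale_range = c(1, 1),
                                              rotation_max_deg = 0,
                                              translation_max_mm = 0,
                                              nonrigid_max_mm = 0, seed = 1),
                             roi)
  p <- matrix(runif(30, -4, 4), 10, 3)
  expect_equal(apply_to_point(idch, p), p, tolerance = 1e-12)
  sc <- sample_deformation(deformation_spec(scale_range = c(1.1, 1.1),
                                            rotation_max_deg = 0,
                                            translation_max_mm = 0,
                                            nonrigid_max_mm = 0, seed = 2),
                           roi)
  p2 <- apply_to_point(sc, p)
  d_orig <- as.numeric(dist(p)); d_new <- as.numeric(dist(p2))
  expect_equal(d_new, 1.1 * d_orig, tolerance = 1e-9)
})

test_that("non-rigid deformation magnitude respects the requested cap", {
  roi <- roi3d(c(-6, -6, -6), c(6, 6, 6))
  ch <- sample_deformation(deformation_spec(scale_range = c(1, 1),
                                            rotation_max_deg = 0,
                                            translation_max_mm = 0,
                                            nonrigid_max_mm = 2, seed = 3),
                           roi)
  g <- as.matrix(expand.grid(seq(-5, 5, 0.5), seq(-5, 5, 0.5), seq(-5, 5, 0.5)))
  mapped <- apply_to_point(ch, g)
  expect_lte(max(sqrt(rowSums((mapped - g)^2))), 2 + 1e-9)
})

test_that("deformations are deterministic per seed", {
  roi <- roi3d(c(-6, -6, -6), c(6, 6, 6))
  c1 <- sample_deformation(deformation_spec(seed = 9), roi)
  c2 <- sample_deformation(deformation_spec(seed = 9), roi)
  p <- matrix(runif(9, -3, 3), 3, 3)
  expect_identical(apply_to_point(c1, p), apply_to_point(c2, p))
})

test_that("make_target with an identity chain is a faithful resampling", {
  ph <- small_phantom()
  idch <- transform_chain(affine_transform())
  tg <- make_target(ph$volume, ph$fiducials, idch,
                    target_spacing = ph$volume$spacing,
                    grid_shape = dim(ph$volume), blur_fwhm = 0, noise_sd = 0,
                    intensity_scale = 1, intensity_offset = 0)
  expect_equal(tg$volume$voxels, ph$volume$voxels, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(tg$fiducials$points, ph$fiducials$points)
  expect_equal(tg$true_a_value, ph$true_a_value)
})

test_that("make_target maps fiducials through the chain", {
  ph <- small_phantom()
  tr <- transform_chain(affine_transform(diag(3), c(1, -2, 0.5)))
  tg <- make_target(ph$volume, ph$fiducials, tr, blur_fwhm = 0, noise_sd = 0)
  expect_equal(tg$fiducials$points,
               ph$fiducials$points + rep(c(1, -2, 0.5), each = 5),
               ignore_attr = TRUE)
  expect_equal(tg$true_a_value, ph$true_a_value, tolerance = 1e-9)
  # a grid too small to hold the cochlea leaves fiducials outside
  expect_error(make_target(ph$volume, ph$fiducials, tr,
                           target_spacing = c(0.5, 0.5, 0.5),
                           grid_shape = c(8, 8, 8)), "outside")
})
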