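random_geometry_volume <- function(seed) {
  set.seed(seed)
  # random orthonormal direction via QR
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  volume3d(array(rnorm(5 * 6 * 7), c(5, 6, 7)),
           spacing = runif(3, 0.1, 2), origin = rnorm(3, sd = 20),
           direction = q)
}

test_that("index<->world round trip is exact for random geometries", {
  for (s in 1:10) {
    v <- random_geometry_volume(s)
    idx <- matrix(runif(30, 0, 4), 10, 3)
    back <- world_to_index(v, index_to_world(v, idx))
    expect_lt(max(abs(back - idx)), 1e-9)
  }
})

test_that("world coordinates follow origin + spacing * index", {
  v <- volume3d(array(0, c(8, 8, 8)))
  expect_equal(index_to_world(v, c(2, 3, 4)), c(2, 3, 4))
  v2 <- volume3d(array(0, c(8, 8, 8)), spacing = c(0.5, 0.5, 2),
                 origin = c(10, 0, -5))
  expect_equal(index_to_world(v2, c(4, 2, 1)), c(12, 1, -3))
})

test_that("volume3d validates geometry", {
  expect_error(volume3d(array(0, c(4, 4))), "3D")
  expect_error(volume3d(array(0, c(4, 4, 4)), spacing = c(0, 1, 1)), "positive")
  expect_error(volume3d(array(0, c(4, 4, 4)), direction = diag(3) * 2),
               "orthonormal")
})

test_that("crop_to_roi keeps exactly the voxel centers inside the ROI", {
  v <- volume3d(array(seq_len(1000), c(10, 10, 10)))
  cr <- crop_to_roi(v, roi3d(rep(2.5, 3), rep(7.5, 3)))
  expect_equal(dim(cr$voxels), c(5, 5, 5))
  expect_equal(cr$origin, c(3, 3, 3))
  # world-coordinate intensities unchanged
  p <- c(4, 5, 6)
  expect_equal(sample_at_world(cr, p), sample_at_world(v, p))
  # full-extent crop is the identity
  full <- crop_to_roi(v, volume_extent_roi(v))
  expect_identical(full$voxels, v$voxels)
  expect_equal(full$origin, v$origin)
  # idempotent
  cr2 <- crop_to_roi(cr, roi3d(rep(2.5, 3), rep(7.5, 3)))
  expect_identical(cr2$voxels, cr$voxels)
  expect_error(crop_to_roi(v, roi3d(c(100, 100, 100), c(110, 110, 110))),
               "intersect")
})

test_that("mirror_volume is an involution, an isometry, and fixes the center plane", {
  set.seed(3)
  v <- volume3d(array(rnorm(6 * 7 * 8), c(6, 7, 8)), spacing = c(0.5, 1, 2),
                origin = c(-1, 2, 3))
  for (ax in 1:3) {
    expect_identical(mirror_volume(mirror_volume(v, ax), ax)$voxels, v$voxels)
  }
  # isometry on world distances between mirrored point pairs
  p1 <- c(0.2, 3.1, 5.5); p2 <- c(-0.7, 6.2, 9.0)
  m1 <- mirror_point(p1, v, 1); m2 <- mirror_point(p2, v, 1)
  expect_equal(sqrt(sum((m1 - m2)^2)), sqrt(sum((p1 - p2)^2)))
  # a point on the center plane maps to itself
  ctr <- cochmetric:::volume_world_center(v)
  on_plane <- ctr + c(0, 0.4, -0.8) # offset orthogonal to axis-1 normal
  expect_equal(mirror_point(on_plane, v, 1), on_plane, tolerance = 1e-12)
  # mirrored voxel value sits at the reflected world position
  idx <- c(1, 2, 3)
  w <- index_to_world(v, idx)
  mv <- mirror_volume(v, 1)
  expect_equal(as.numeric(sample_at_world(mv, mirror_point(w, v, 1))),
               v$voxels[2, 3, 4])
  expect_error(mirror_volume(v, 4), "plane_axis")
})

test_that("volume I/O round trips are lossless for every format", {
  set.seed(7)
  v <- volume3d(array(rnorm(8 * 7 * 6), c(8, 7, 6)), spacing = c(0.5, 0.5, 2),
                origin = c(10, 0, -5))
  for (ext in c(".nii", ".nii.gz", ".nrrd", ".mha", ".mhd")) {
    f <- tempfile(fileext = ext)
    write_volume(v, f)
    v2 <- read_volume(f)
    expect_equal(v2$voxels, v$voxels, ignore_attr = TRUE)
    expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
    expect_equal(v2$origin, v$origin, tolerance = 1e-6)
    expect_equal(v2$direction, v$direction, tolerance = 1e-6)
  }
})

test_that("non-identity direction matrices survive round trips", {
  th <- 30 * pi / 180
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  v <- volume3d(array(runif(5^3), c(5, 5, 5)), spacing = c(1, 1.5, 2),
                origin = c(3, -2, 8), direction = rot)
  for (ext in c(".nii.gz", ".nrrd", ".mha")) {
    f <- tempfile(fileext = ext)
    write_volume(v, f)
    v2 <- read_volume(f)
    expect_equal(v2$direction, v$direction, tolerance = 1e-6)
    # world coordinates of all voxel centers preserved
    g <- as.matrix(expand.grid(0:4, 0:4, 0:4))
    expect_lt(max(abs(index_to_world(v2, g) - index_to_world(v, g))), 1e-4)
  }
})

test_that("NRRD -> NIfTI -> NRRD chain preserves world coordinates", {
  set.seed(11)
  v <- volume3d(array(rnorm(4^3), c(4, 4, 4)), spacing = c(0.3, 0.7, 1.1),
                origin = c(-4, 2, 0.5))
  f1 <- tempfile(fileext = ".nrrd"); f2 <- tempfile(fileext = ".nii.gz")
  f3 <- tempfile(fileext = ".nrrd")
  write_volume(v, f1)
  write_volume(read_volume(f1), f2)
  write_volume(read_volume(f2), f3)
  v3 <- read_volume(f3)
  g <- as.matrix(expand.grid(0:3, 0:3, 0:3))
  expect_lt(max(abs(index_to_world(v3, g) - index_to_world(v, g))), 1e-4)
  expect_equal(v3$voxels, v$voxels, ignore_attr = TRUE)
})

test_that("I/O errors are informative", {
  expect_error(read_volume("does-not-exist.nrrd"), "not found")
  bad <- tempfile(fileext = ".xyz")
  writeLines("not a volume", bad)
  expect_error(read_volume(bad), "unsupported")
  v <- volume3d(array(0, c(4, 4, 4)))
  expect_error(write_volume(v, file.path(tempdir(), "no-such-dir", "a.nrrd")),
               "directory")
})
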