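test_that("affine transforms apply matrix then translation", {
  id <- affine_transform()
  expect_equal(apply_to_point(id, c(4, -2, 7)), c(4, -2, 7))
  tf <- affine_transform(diag(c(2, 1, 1)), c(0, 0, 1))
  expect_equal(apply_to_point(tf, c(1, 1, 1)), c(2, 1, 2))
  expect_error(affine_transform(matrix(0, 3, 3)), "singular")
  expect_error(affine_transform(diag(c(2, 1, 1)), kind = "rigid"), "rotation")
})

test_that("B-spline point mapping matches the de Boor tensor-product oracle", {
  set.seed(5)
  tf <- bspline_transform(c(5, 4, 6), grid_origin = c(-2, 1, 0),
                          grid_spacing = c(1.5, 2, 1),
                          displacements = matrix(rnorm(5 * 4 * 6 * 3, sd = 0.4),
                                                 ncol = 3))
  # random points strictly inside the support domain
  lo <- tf$grid_origin + tf$grid_spacing
  hi <- tf$grid_origin + tf$grid_spacing * (tf$grid_shape - 2)
  for (i in 1:100) {
    x <- lo + runif(3, 0.01, 0.99) * (hi - lo)
    expect_lt(max(abs(apply_to_point(tf, x) - oracle_bspline_point(tf, x))),
              1e-9)
  }
})

test_that("zero-displacement B-spline is the identity; support is enforced", {
  tf <- bspline_transform(c(4, 4, 4), c(-10, -10, -10), c(5, 5, 5))
  # full cubic support requires points in [origin + h, origin + (n-2) h]
  p <- matrix(runif(30, -4.9, -0.1), 10, 3)
  expect_equal(apply_to_point(tf, p), p)
  expect_error(apply_to_point(tf, c(100, 0, 0)), "support")
})

test_that("transform chains apply stages in estimation order", {
  a <- affine_transform(diag(c(2, 2, 2)), c(1, 0, 0))
  b <- affine_transform(diag(3), c(0, 5, 0))
  ch <- transform_chain(a, b)
  # b(a(x)), not a(b(x))
  expect_equal(apply_to_point(ch, c(1, 1, 1)), c(3, 7, 2))
  nested <- transform_chain(ch, affine_transform(diag(3), c(0, 0, 1)))
  expect_length(nested$transforms, 3)
})

test_that("degrees of freedom follow the field's counting conventions", {
  expect_equal(dof(affine_transform(kind = "rigid")), 6)
  expect_equal(dof(affine_transform()), 12)
  bs <- bspline_transform(c(4, 4, 4), c(0, 0, 0), c(1, 1, 1))
  expect_equal(as.integer(dof(bs)), 64)
  expect_equal(attr(dof(bs), "scalar_parameters"), 192)
  ch <- transform_chain(affine_transform(kind = "rigid"), affine_transform(), bs)
  expect_equal(as.integer(dof(ch)), 6 + 12 + 64)
  expect_equal(attr(dof(ch), "per_stage"), c(6L, 12L, 64L))
})

test_that("displacement-field export matches direct evaluation", {
  roi <- roi3d(c(0, 0, 0), c(10, 10, 10))
  idf <- export_displacement_field(transform_chain(affine_transform()), roi, 2)
  expect_equal(max(abs(idf$field)), 0)
  tr <- affine_transform(diag(3), c(1.5, -2, 0.5))
  trf <- export_displacement_field(tr, roi, 2)
  expect_equal(range(trf$field[, , , 1]), c(1.5, 1.5))
  expect_equal(range(trf$field[, , , 2]), c(-2, -2))
  expect_equal(range(trf$field[, , , 3]), c(0.5, 0.5))
  # B-spline field agrees with apply_to_point at the grid nodes
  set.seed(2)
  bs <- bspline_transform(c(4, 4, 4), c(-10, -10, -10), c(10, 10, 10),
                          matrix(rnorm(64 * 3), ncol = 3))
  fld <- export_displacement_field(bs, roi, 5)
  nodes <- as.matrix(expand.grid(seq(0, 10, 5), seq(0, 10, 5), seq(0, 10, 5)))
  direct <- apply_to_point(bs, nodes) - nodes
  expect_lt(max(abs(matrix(fld$field, ncol = 3) - direct)), 1e-9)
  # writable as a multi-component NRRD
  f <- tempfile(fileext = ".nrrd")
  write_displacement_field(fld, f)
  expect_true(file.exists(f) && file.size(f) > 0)
})

test_that("transform JSON serialization round trips exactly", {
  set.seed(9)
  ch <- transform_chain(
    affine_transform(cochmetric:::rotation_from_euler(c(0.1, 0.2, -0.3)),
                     c(1, 2, 3), kind = "rigid"),
    affine_transform(matrix(rnorm(9) + diag(3) * 3, 3), c(-1, 0, 2)),
    bspline_transform(c(4, 5, 4), c(0, 0, 0), c(2, 2, 2),
                      matrix(rnorm(80 * 3), ncol = 3)))
  f <- tempfile(fileext = ".json")
  write_transform_json(ch, f)
  ch2 <- read_transform_json(f)
  expect_equal(ch2$transforms[[1]]$kind, "rigid")
  for (i in 1:2) {
    expect_equal(ch2$transforms[[i]]$matrix, ch$transforms[[i]]$matrix)
    expect_equal(ch2$transforms[[i]]$translation, ch$transforms[[i]]$translation)
  }
  expect_equal(ch2$transforms[[3]]$displacements, ch$transforms[[3]]$displacements)
  # interior points of the deserialized spline map identically
  p <- matrix(runif(15, 2.2, 3.8), 5, 3)
  expect_equal(apply_to_point(ch2$transforms[[3]], p),
               apply_to_point(ch$transforms[[3]], p), tolerance = 1e-12)
})
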