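# Independent oracles used across test files.

# Tensor-product cubic B-spline displacement via the Cox-de Boor recursion
# on an integer knot grid, summed by brute force over all control points.
deboor_basis <- function(j, k, x, knots) {
  if (k == 1) return(as.numeric(x >= knots[j] & x < knots[j + 1]))
  w1 <- if (knots[j + k - 1] > knots[j])
    (x - knots[j]) / (knots[j + k - 1] - knots[j]) else 0
  w2 <- if (knots[j + k] > knots[j + 1])
    (knots[j + k] - x) / (knots[j + k] - knots[j + 1]) else 0
  w1 * deboor_basis(j, k - 1, x, knots) + w2 * deboor_basis(j + 1, k - 1, x, knots)
}

ctrl_weight <- function(c, t) deboor_basis(1, 4, t, knots = (c - 2):(c + 2))

oracle_bspline_point <- function(tf, x) {
  t <- (x - tf$grid_origin) / tf$grid_spacing
  d <- c(0, 0, 0)
  ng <- tf$grid_shape
  for (k in 0:(ng[3] - 1)) for (j in 0:(ng[2] - 1)) for (i in 0:(ng[1] - 1)) {
    w <- ctrl_weight(i, t[1]) * ctrl_weight(j, t[2]) * ctrl_weight(k, t[3])
    if (w != 0)
      d <- d + w * tf$displacements[1 + i + ng[1] * (j + ng[2] * k), ]
  }
  x + d
}

# Signed-rank null distribution by explicit enumeration of all 2^n patterns.
brute_force_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  vals <- vapply(0:(2^n - 1), function(mask) {
    sum(r[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
  }, 0)
  p_le <- mean(vals <= v + 1e-9)
  p_ge <- mean(vals >= v - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
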