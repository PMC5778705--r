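test_that("absolute percentage difference behaves as specified", {
  expect_equal(abs_pct_diff(9, 10), 10)
  expect_equal(abs_pct_diff(10, 10), 0)
  expect_equal(abs_pct_diff(9.55, 9.30), 100 * 0.25 / 9.30)
  # scale invariance
  set.seed(1)
  m <- runif(10, 8, 11); g <- runif(10, 8, 11)
  expect_equal(abs_pct_diff(3.7 * m, 3.7 * g), abs_pct_diff(m, g))
  expect_error(abs_pct_diff(9, 0), "> 0")
})

test_that("improvement is the difference of mean percentage errors", {
  expect_equal(improvement(9.5, 2.7), 6.8)
  expect_equal(improvement(4.2, 4.2), 0)
  expect_equal(improvement(10.0, 2.5), 7.5)
  expect_error(improvement(-1, 2), ">= 0")
})

test_that("exact Wilcoxon p matches brute-force enumeration", {
  # balanced antisymmetric differences -> p = 1
  w <- wilcoxon_matched_pairs(c(1, -1, 2, -2, 3, -3) + 10, rep(10, 6))
  expect_equal(w$p, 1.0)
  # n = 6 all positive -> 2 * (1 / 2^6)
  w2 <- wilcoxon_matched_pairs(c(11, 12, 13, 14, 15, 16), rep(10, 6))
  expect_equal(w2$p, 2 / 64)
  expect_equal(w2$method, "exact")
  # property: agreement with 2^n enumeration on random data (with ties)
  set.seed(42)
  for (i in 1:50) {
    n <- sample(5:10, 1)
    d <- sample(c(-3, -2, -1, 1, 2, 3), n, replace = TRUE) +
      round(rnorm(n), 1)
    d <- d[d != 0]
    if (length(d) < 5) next
    w <- wilcoxon_matched_pairs(d + 10, rep(10, length(d)))
    # the oracle must see the same float differences the test statistic does
    expect_equal(w$p, brute_force_wilcoxon_p((d + 10) - 10), tolerance = 1e-12)
  }
})

test_that("exact Wilcoxon agrees with stats::wilcox.test on tie-free data", {
  set.seed(7)
  for (i in 1:20) {
    d <- rnorm(8)
    w <- wilcoxon_matched_pairs(d + 5, rep(5, 8))
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(w$statistic, unname(ref$statistic))
    expect_equal(w$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large-sample Wilcoxon uses the corrected normal approximation", {
  set.seed(3)
  d <- rnorm(30, mean = 0.4)
  w <- wilcoxon_matched_pairs(d + 5, rep(5, 30))
  expect_equal(w$method, "normal")
  ref <- stats::wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_equal(w$p, ref$p.value, tolerance = 1e-10)
})

test_that("Wilcoxon zero handling supports both conventions", {
  m <- c(10, 10, 11, 12, 13, 14, 9); g <- rep(10, 7)
  w_drop <- wilcoxon_matched_pairs(m, g, zero_method = "wilcoxon")
  expect_equal(w_drop$n_used, 5)
  w_pratt <- wilcoxon_matched_pairs(m, g, zero_method = "pratt")
  expect_equal(w_pratt$n_used, 5)
  expect_false(isTRUE(all.equal(w_drop$statistic, w_pratt$statistic)))
  expect_error(wilcoxon_matched_pairs(rep(5, 6), rep(5, 6)), "degenerate")
})

test_that("Spearman equals Pearson on mid-ranks, including ties", {
  set.seed(11)
  # strict monotone pairing
  x <- sort(runif(10)); y <- exp(x)
  expect_equal(spearman(x, y)$r, 1.0)
  expect_equal(spearman(x, rev(y))$r, -1.0)
  # tied data vs an explicit average-rank Pearson oracle
  for (i in 1:20) {
    a <- sample(1:5, 9, replace = TRUE)
    b <- sample(1:5, 9, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    mid_rank <- function(v) {
      vapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2, 0)
    }
    oracle <- stats::cor(mid_rank(a), mid_rank(b))
    expect_equal(spearman(a, b)$r, oracle, tolerance = 1e-12)
  }
  expect_error(spearman(rep(1, 5), 1:5), "constant")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(12)
  x <- rnorm(15); y <- rnorm(15)
  base <- spearman(x, y)
  expect_equal(spearman(exp(x), y)$r, base$r, tolerance = 1e-12)
  expect_equal(spearman(x, y^3 + 5 * y)$r, base$r, tolerance = 1e-12)
  expect_equal(spearman(exp(x), y)$p, base$p, tolerance = 1e-12)
})

test_that("Spearman p agrees with the reference implementation", {
  set.seed(13)
  x <- rnorm(7); y <- rnorm(7)
  sp <- spearman(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(sp$r, unname(ref$estimate), tolerance = 1e-12)
  # larger n: t approximation against cor.test's AS89 within loose agreement
  x2 <- rnorm(25); y2 <- x2 + rnorm(25)
  sp2 <- spearman(x2, y2)
  ref2 <- suppressWarnings(stats::cor.test(x2, y2, method = "spearman"))
  expect_equal(sp2$r, unname(ref2$estimate), tolerance = 1e-12)
  expect_lt(abs(sp2$p - ref2$p.value), 0.02)
})

test_that("Shapiro-Wilk gate behaves sensibly", {
  set.seed(14)
  clean <- 1:20 + rnorm(20, sd = 0.01)
  spiked <- c(clean[1:19], 100)
  expect_gt(shapiro_wilk(clean)$W, shapiro_wilk(spiked)$W)
  w <- shapiro_wilk(rnorm(50))$W
  expect_gt(w, 0); expect_lte(w, 1)
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
})

test_that("Bland-Altman summaries match hand arithmetic", {
  ba <- bland_altman(c(11, 9), c(10, 10)) # d = (+1, -1)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(ba$loa_high, 1.96 * sqrt(2))
  expect_equal(ba$loa_low, -1.96 * sqrt(2))
  expect_equal(ba$frac_outside_clinical, 0)
  ba2 <- bland_altman(c(5, 5, 5), c(5, 5, 5))
  expect_equal(ba2$mean_diff, 0); expect_equal(ba2$loa_low, 0)
  expect_equal(ba2$frac_outside_clinical, 0)
  d <- c(0.5, -2.0, 1.2, 0.1)
  ba3 <- bland_altman(10 + d, rep(10, 4))
  expect_equal(ba3$frac_outside_clinical, 0.5)
})

test_that("limits of agreement contain ~95% of Gaussian differences", {
  set.seed(15)
  n <- 1e4
  d <- rnorm(n, mean = 0.2, sd = 0.8)
  ba <- bland_altman(10 + d, rep(10, n))
  inside <- mean(d >= ba$loa_low & d <= ba$loa_high)
  expect_lt(abs(inside - 0.95), 0.01)
})

test_that("the full agreement report assembles every statistic", {
  set.seed(16)
  gold <- runif(12, 8, 10.5)
  method <- gold * (1 + rnorm(12, 0, 0.03))
  pairs <- paired_measurements(sprintf("s%02d", 1:12), method, gold)
  rep <- evaluate_agreement(pairs, clinical_bound = 1.05)
  expect_equal(rep$abs_pct_diff_mean, mean(abs_pct_diff(method, gold)))
  expect_equal(rep$spearman_r, spearman(method, gold)$r)
  expect_true(rep$wilcoxon_label %in% c("ns", "*", "**"))
  expect_equal(rep$bland_altman$clinical_bound, 1.05)
  f <- tempfile(fileext = ".json")
  write_agreement_report(rep, f)
  parsed <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(parsed$spearman_r, rep$spearman_r, tolerance = 1e-12)
  # CSV loader
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(id = pairs$ids, method_mm = method,
                              gold_mm = gold), csv, row.names = FALSE)
  p2 <- read_paired_csv(csv)
  expect_equal(p2$method_values, method)
  expect_error(paired_measurements("a", 1, 1), ">= 3")
  expect_error(paired_measurements(c("a", "b", "c"), c(1, 2, 3), c(1, -1, 2)),
               "> 0")
})
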