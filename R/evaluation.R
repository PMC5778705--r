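#' Paired method-vs-gold measurements
#'
#' @param ids specimen labels.
#' @param method_values measurements from the method under evaluation (mm).
#' @param gold_values gold-standard reference measurements (mm, > 0).
#' @return an object of class `paired_measurements`.
#' @export
paired_measurements <- function(ids, method_values, gold_values) {
  ids <- as.character(ids)
  method_values <- as.numeric(method_values); gold_values <- as.numeric(gold_values)
  n <- length(ids)
  if (n < 3 || length(method_values) != n || length(gold_values) != n)
    stop("need >= 3 specimens with equal-length id/method/gold vectors")
  if (any(!is.finite(method_values)) || any(!is.finite(gold_values)))
    stop("measurements must be finite")
  if (any(gold_values <= 0)) stop("gold-standard values must be > 0")
  structure(list(ids = ids, method_values = method_values,
                 gold_values = gold_values), class = "paired_measurements")
}

#' Read paired measurements from a CSV (`id,method_mm,gold_mm`)
#' @param path CSV path.
#' @return a [paired_measurements()].
#' @export
read_paired_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "method_mm", "gold_mm")
  if (!all(need %in% names(d)))
    stop("pairs CSV must have columns id,method_mm,gold_mm: ", path)
  paired_measurements(d$id, d$method_mm, d$gold_mm)
}

#' Absolute percentage difference from a gold standard
#'
#' `100 * |method - gold| / gold`; scale-invariant in the sense that
#' rescaling both values by the same positive factor leaves it unchanged.
#'
#' @param method,gold measurements (same units); `gold > 0`.
#' @return percentage (vectorized).
#' @export
abs_pct_diff <- function(method, gold) {
  if (any(gold <= 0)) stop("`gold` must be > 0")
  100 * abs(method - gold) / gold
}

#' Accuracy improvement between two mean percentage errors
#'
#' The difference `manual_mean_pct - automated_mean_pct`, i.e. by how many
#' percentage points the automated method reduces the mean absolute
#' percentage error.
#'
#' @param manual_mean_pct,automated_mean_pct mean absolute percentage
#'   differences (>= 0).
#' @return improvement in percentage points.
#' @export
improvement <- function(manual_mean_pct, automated_mean_pct) {
  if (any(manual_mean_pct < 0) || any(automated_mean_pct < 0))
    stop("percentage errors must be >= 0")
  manual_mean_pct - automated_mean_pct
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided signed-rank test of paired differences. For n (non-zero
#' differences) up to `exact_max` the null distribution is enumerated
#' exactly over all 2^n sign patterns (valid with ties, which are
#' mid-ranked); otherwise a normal approximation with tie-corrected
#' variance and continuity correction is used. Zero differences are dropped
#' by default (Wilcoxon's procedure); `zero_method = "pratt"` keeps them in
#' the ranking and drops only their rank contribution.
#'
#' @param method,gold paired measurement vectors.
#' @param zero_method `"wilcoxon"` (drop zeros) or `"pratt"`.
#' @param exact_max largest n for exact enumeration (default 12).
#' @return list with `statistic` (V, the positive-rank sum), `p`, `n_used`,
#'   and `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_matched_pairs <- function(method, gold,
                                   zero_method = c("wilcoxon", "pratt"),
                                   exact_max = 12L) {
  zero_method <- match.arg(zero_method)
  d <- as.numeric(method) - as.numeric(gold)
  if (length(d) < 5) stop("need >= 5 pairs")
  if (all(d == 0)) stop("degenerate test: all differences are zero")
  if (zero_method == "wilcoxon") {
    d <- d[d != 0]
    r <- rank(abs(d))
    keep <- rep(TRUE, length(d))
  } else {
    r <- rank(abs(d))
    keep <- d != 0
    d <- d[keep]; r <- r[keep]
  }
  n <- length(d)
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- exact_signed_rank_p(r, v)
    list(statistic = v, p = p, n_used = n, method = "exact")
  } else {
    mu <- sum(r) / 2
    sigma2 <- sum(r^2) / 4 # tie-correct: variance of random-sign rank sum
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(statistic = v, p = p, n_used = n, method = "normal")
  }
}

exact_signed_rank_p <- function(ranks, v) {
  # exact two-sided p over all 2^n sign patterns, computed by dynamic
  # programming: mid-ranks are multiples of 1/2, so 2*rank convolves over an
  # integer lattice
  r2 <- as.integer(round(2 * ranks))
  counts <- c(1, numeric(sum(r2))) # counts[s + 1] = #patterns with sum 2V = s
  for (ri in r2) {
    shifted <- c(numeric(ri), counts[seq_len(length(counts) - ri)])
    counts <- counts + shifted
  }
  total <- 2^length(ranks)
  v2 <- 2 * v
  p_le <- sum(counts[seq_len(min(length(counts), floor(v2 + 1e-9) + 1))]) / total
  p_ge <- sum(counts[(ceiling(v2 - 1e-9) + 1):length(counts)]) / total
  min(1, 2 * min(p_le, p_ge))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average (mid) ranks. The p-value uses exact
#' permutation enumeration for n up to `exact_max` (default 8) and the
#' t-distribution approximation otherwise; two-sided throughout.
#'
#' @param method,gold paired measurement vectors (n >= 3).
#' @param exact_max largest n for exact permutation p.
#' @return list with `r`, `p`, `n` and `method` (`"exact"`/`"t"`).
#' @export
spearman <- function(method, gold, exact_max = 8L) {
  x <- as.numeric(method); y <- as.numeric(gold)
  n <- length(x)
  if (n < 3 || length(y) != n) stop("need paired vectors of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector")
  rx <- rank(x); ry <- rank(y)
  r <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- permutations_of(n)
    robs <- abs(r) - 1e-12
    rs <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rs) >= robs)
    list(r = r, p = p, n = n, method = "exact")
  } else {
    tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-15))
    p <- min(1, 2 * stats::pt(-abs(tstat), df = n - 2))
    list(r = r, p = p, n = n, method = "t")
  }
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Shapiro-Wilk normality test
#'
#' The normality gate reported before choosing the nonparametric comparison;
#' delegates to the standard implementation in `stats`.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  sw <- stats::shapiro.test(as.numeric(values))
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Bland-Altman agreement summary with a clinical acceptance band
#'
#' Differences `d = method - gold`; reports their mean, sample SD, the 95%
#' limits of agreement `mean +/- 1.96 SD`, and the fraction of cases whose
#' absolute difference exceeds the clinically acceptable error bound
#' (default +/- 1.05 mm for the A-value).
#'
#' @param method,gold paired measurement vectors (n >= 3... n >= 2 for the
#'   SD; at least 3 recommended).
#' @param clinical_bound acceptable absolute error in mm (default 1.05).
#' @return list with `mean_diff`, `sd_diff`, `loa_low`, `loa_high`,
#'   `clinical_bound`, `frac_outside_clinical`, `n`.
#' @export
bland_altman <- function(method, gold, clinical_bound = 1.05) {
  d <- as.numeric(method) - as.numeric(gold)
  if (length(d) < 2) stop("need >= 2 pairs")
  m <- mean(d); s <- stats::sd(d)
  list(mean_diff = m, sd_diff = s,
       loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       clinical_bound = clinical_bound,
       frac_outside_clinical = mean(abs(d) > clinical_bound),
       n = length(d))
}

significance_label <- function(p) {
  if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Full agreement report of a method against a gold standard
#'
#' The complete statistical battery: absolute percentage difference
#' (mean +/- SD), Shapiro-Wilk normality gate on the differences, Wilcoxon
#' matched-pairs test, Spearman correlation, and Bland-Altman analysis with
#' the clinical acceptance band.
#'
#' @param pairs a [paired_measurements()].
#' @param clinical_bound clinical acceptance bound in mm (default 1.05).
#' @return an object of class `agreement_report`.
#' @export
evaluate_agreement <- function(pairs, clinical_bound = 1.05) {
  stopifnot(inherits(pairs, "paired_measurements"))
  m <- pairs$method_values; g <- pairs$gold_values
  pct <- abs_pct_diff(m, g)
  sw <- shapiro_wilk(m - g)
  wx <- wilcoxon_matched_pairs(m, g)
  sp <- spearman(m, g)
  ba <- bland_altman(m, g, clinical_bound)
  structure(list(n = length(m),
                 abs_pct_diff_mean = mean(pct),
                 abs_pct_diff_sd = stats::sd(pct),
                 shapiro_W = sw$W, shapiro_p = sw$p,
                 wilcoxon_statistic = wx$statistic, wilcoxon_p = wx$p,
                 wilcoxon_label = significance_label(wx$p),
                 spearman_r = sp$r, spearman_p = sp$p,
                 spearman_label = significance_label(sp$p),
                 bland_altman = ba),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d\n", x$n))
  cat(sprintf("%% difference: %.1f +/- %.1f%%\n",
              x$abs_pct_diff_mean, x$abs_pct_diff_sd))
  cat(sprintf("Shapiro-Wilk: W = %.3f, p = %.3g\n", x$shapiro_W, x$shapiro_p))
  cat(sprintf("Wilcoxon: V = %.1f, p = %.3g (%s)\n",
              x$wilcoxon_statistic, x$wilcoxon_p, x$wilcoxon_label))
  cat(sprintf("Spearman: r = %.2f, p = %.3g (%s)\n",
              x$spearman_r, x$spearman_p, x$spearman_label))
  ba <- x$bland_altman
  cat(sprintf("Bland-Altman: mean %.3f mm, LoA [%.3f, %.3f] mm, %.0f%% outside +/-%.2f mm\n",
              ba$mean_diff, ba$loa_low, ba$loa_high,
              100 * ba$frac_outside_clinical, ba$clinical_bound))
  invisible(x)
}

#' Write an agreement report as JSON
#' @param report an `agreement_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_agreement_report <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
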