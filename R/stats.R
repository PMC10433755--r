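#' Exact two-sided binomial test
#'
#' Minimum-likelihood two-sided method: the p-value sums the probabilities
#' of all outcomes no more likely than the observed count (with a 1 + 1e-7
#' relative tolerance on the comparison), clipped to \[0, 1\]. This is the
#' convention implemented by `stats::binom.test`, to which the computation
#' is delegated.
#'
#' @param k observed successes.
#' @param n trials.
#' @param p0 null success probability.
#' @return two-sided p-value.
#' @export
#' @examples
#' binomial_test(5, 18, 0.354)
binomial_test <- function(k, n, p0) {
  if (n < 0 || k < 0 || k > n || k != floor(k) || n != floor(n)) {
    stop("need integers 0 <= k <= n")
  }
  if (p0 < 0 || p0 > 1) stop("p0 must be a probability")
  min(1, max(0, stats::binom.test(k, n, p0)$p.value))
}

#' One-sample t-test against a reference mean
#'
#' @param values numeric sample (n >= 2, non-zero spread).
#' @param mu0 reference mean (default 1, the normalized activity of a
#'   negative-control reporter fragment).
#' @return list with `t`, `df`, `p` (two-sided), `mean`, `sd`.
#' @export
one_sample_t <- function(values, mu0 = 1) {
  if (length(values) < 2) stop("need at least 2 values")
  if (stats::sd(values) == 0) stop("zero variance sample")
  ht <- stats::t.test(values, mu = mu0)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean = mean(values), sd = stats::sd(values))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of tests.
#' @return per-test threshold `alpha / m`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 18)
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1 || m != floor(m)) stop("m must be a positive integer")
  alpha / m
}

#' Mann-Whitney U test
#'
#' U from rank sums with average ranks on ties. The p-value is exact (by
#' enumeration of rank configurations) when the combined sample size is at
#' most 12 and there are no ties, and otherwise uses the normal
#' approximation with tie and continuity corrections. Delegates to
#' `stats::wilcox.test` under those settings.
#'
#' @param x,y numeric samples.
#' @return list with `U` and `p` (two-sided).
#' @export
mann_whitney <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Pearson correlation test
#'
#' Product-moment correlation with the t-based two-sided test,
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors (n >= 3, non-constant).
#' @return list with `r`, `t`, `df`, `p`.
#' @export
pearson_correlation_test <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), t = unname(ht$statistic),
       df = unname(ht$parameter), p = ht$p.value)
}

#' Dual-luciferase activity analysis
#'
#' Reproduces the reporter-assay normalization and testing chain: each
#' replicate's firefly luminescence is divided by its own renilla
#' measurement, fragment ratios are expressed relative to the mean ratio of
#' the negative-control fragment, and each test fragment's relative
#' activities are compared with 1 by a one-sample t-test. A fragment is
#' called active when its p-value clears the Bonferroni threshold
#' `alpha / m` (m = number of test fragments) *and* its mean relative
#' activity exceeds 1.
#'
#' @param table tibble/data.frame with columns `fragment_id`, `replicate`,
#'   `firefly`, `renilla`, `is_negative_control` (exactly one control
#'   fragment).
#' @param alpha family-wise error rate (default 0.05).
#' @return tibble, one row per test fragment: `fragment_id`, `n`,
#'   `mean_activity`, `sd_activity`, `t`, `df`, `p_value`, `significant`,
#'   plus attributes `threshold` and `m`.
#' @export
luciferase_analysis <- function(table, alpha = 0.05) {
  need <- c("fragment_id", "replicate", "firefly", "renilla",
            "is_negative_control")
  if (!all(need %in% names(table))) {
    stop("table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(table$renilla <= 0)) stop("renilla measurements must be positive")
  neg_ids <- unique(table$fragment_id[table$is_negative_control])
  if (length(neg_ids) != 1) {
    stop("exactly one negative-control fragment is required")
  }
  ratio <- table$firefly / table$renilla
  neg_mean <- mean(ratio[table$fragment_id == neg_ids])
  rel <- ratio / neg_mean
  test_ids <- setdiff(unique(table$fragment_id), neg_ids)
  m <- length(test_ids)
  threshold <- bonferroni_threshold(alpha, m)
  rows <- lapply(test_ids, function(id) {
    v <- rel[table$fragment_id == id]
    if (length(v) < 2) stop("fragment ", id, " has fewer than 2 replicates")
    ht <- one_sample_t(v, mu0 = 1)
    tibble::tibble(fragment_id = id, n = length(v),
                   mean_activity = ht$mean, sd_activity = ht$sd,
                   t = ht$t, df = ht$df, p_value = ht$p,
                   significant = ht$p < threshold && ht$mean > 1)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  attr(out, "m") <- m
  out
}

#' Read a luciferase replicate table from CSV
#'
#' Expects the header `fragment_id,replicate,firefly,renilla,
#' is_negative_control`.
#'
#' @param path CSV path.
#' @return tibble suitable for [luciferase_analysis()].
#' @export
read_luciferase_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$is_negative_control <- as.logical(df$is_negative_control)
  tibble::as_tibble(df)
}
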