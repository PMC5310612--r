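# Comparing host discrimination abilities.
#
# The steepness of the psychometric function along the natural blue-green ->
# brown gradient measures how strictly a host discriminates. Slopes are
# resampled by refitting the single-threshold GLM on random 90% subsamples;
# the two hosts' slope distributions are then compared with a Monte-Carlo
# Kolmogorov-Smirnov normality check and a Wilcoxon rank-sum test with the
# rank-biserial correlation as effect size.

#' Resample psychometric slopes from data subsamples
#'
#' Each replicate draws `floor(fraction * n)` rows without replacement
#' (subsampling, not bootstrap), refits the GLM with `model_predictors` and
#' records the coefficient of `predictor`. Failed refits are dropped and
#' counted.
#'
#' @param t Trial table.
#' @param predictor Coefficient to record (default the blue-green -> brown
#'   axis).
#' @param link Link function.
#' @param B Replicates (default 10 000).
#' @param fraction Subsample proportion in (0, 1] (default 0.9).
#' @param seed Integer seed.
#' @param model_predictors Predictors of the refitted model; defaults to the
#'   single-threshold scenario model.
#' @return An object of class `slope_sample`: `values`, `B`, `fraction`,
#'   `seed`, `n_failed`, `predictor`.
#' @export
resample_slopes <- function(t, predictor = "x_bgbr", link = "logit",
                            B = 10000L, fraction = 0.9, seed = 1L,
                            model_predictors = c("x_bgbr", "x_gp", "x_uv",
                                                 "achromatic_contrast")) {
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  if (!predictor %in% model_predictors)
    stop("predictor must be part of model_predictors")
  n <- nrow(t)
  m <- floor(fraction * n)
  if (m < length(model_predictors) + 3L)
    stop("subsample too small for the model")
  vals <- with_seed(seed, {
    out <- rep(NA_real_, B)
    for (b in seq_len(B)) {
      idx <- sample.int(n, m, replace = FALSE)
      out[b] <- tryCatch({
        fb <- suppressWarnings(fit_binomial_glm(t[idx, , drop = FALSE],
                                                model_predictors, link = link))
        if (!fb$converged) NA_real_ else fb$coefficients[[predictor]]
      }, error = function(e) NA_real_)
    }
    out
  })
  ok <- vals[!is.na(vals)]
  structure(list(values = ok, B = B, fraction = fraction, seed = seed,
                 n_failed = B - length(ok), predictor = predictor),
            class = "slope_sample")
}

#' @export
print.slope_sample <- function(x, ...) {
  cat(sprintf(
    "<slope_sample '%s': %d values (B = %d, %.0f%% subsamples, %d failed), median %.3f>\n",
    x$predictor, length(x$values), x$B, 100 * x$fraction, x$n_failed,
    stats::median(x$values)))
  invisible(x)
}

#' Monte-Carlo Kolmogorov-Smirnov normality test
#'
#' Lilliefors-style: the KS statistic D is computed against a normal with
#' the sample's own mean and standard deviation, and its null distribution
#' is built from `nsim` parametric simulations of the same size with
#' parameters re-estimated per simulation. The p-value uses the add-one rule
#' p = (1 + #\{D_sim >= D_obs\}) / (nsim + 1), so it is never exactly zero.
#'
#' @param x Numeric sample (n >= 5, non-zero variance).
#' @param nsim Monte-Carlo simulations (default 1 000).
#' @param seed Integer seed.
#' @return An object of class `ks_result`: `D`, `p`, `nsim`.
#' @export
ks_normality_mc <- function(x, nsim = 1000L, seed = 1L) {
  x <- as.numeric(x)
  if (length(x) < 5L) stop("need at least 5 observations")
  if (stats::sd(x) == 0) stop("zero-variance sample")
  ks_stat <- function(v) {
    n <- length(v)
    z <- stats::pnorm(sort(v), mean(v), stats::sd(v))
    max(seq_len(n) / n - z, z - (seq_len(n) - 1L) / n)
  }
  D <- ks_stat(x)
  n <- length(x)
  m <- mean(x); s <- stats::sd(x)
  exceed <- with_seed(seed, {
    cnt <- 0L
    for (i in seq_len(nsim))
      if (ks_stat(stats::rnorm(n, m, s)) >= D) cnt <- cnt + 1L
    cnt
  })
  structure(list(D = D, p = (1 + exceed) / (nsim + 1), nsim = nsim),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("<KS normality: D = %.4f, Monte-Carlo p = %.4g (nsim = %d)>\n",
              x$D, x$p, x$nsim))
  invisible(x)
}

#' Wilcoxon rank-sum test with rank-biserial effect size
#'
#' The Mann-Whitney statistic U counts pairs with x_i > y_j (ties count
#' half), computed from rank sums in O(n log n). The two-sided p-value uses
#' the exact null distribution when n1 * n2 <= 400 and there are no ties,
#' otherwise a tie-corrected, continuity-corrected normal approximation.
#' The rank-biserial correlation r = 2U/(n1 n2) - 1 is +1 when every x
#' exceeds every y (complete separation) and -1 in the reverse case.
#'
#' @param x,y Numeric samples.
#' @param ci Also report the difference of sample medians with a bootstrap
#'   percentile CI?
#' @param B_ci Bootstrap replicates for the median-difference CI.
#' @param seed Seed for the CI bootstrap.
#' @return An object of class `rank_test_result`: `U`, `p`, `r_rb`,
#'   `method`, `n1`, `n2`, and (if `ci`) `median_diff` (median(x) -
#'   median(y)) with `median_diff_ci`.
#' @export
wilcoxon_rank_sum <- function(x, y, ci = FALSE, B_ci = 2000L, seed = 1L) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("empty sample")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && n1 * n2 <= 400) {
    method <- "exact"
    p <- min(1, 2 * min(stats::pwilcox(U, n1, n2),
                        stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)))
  } else {
    method <- "normal approximation"
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sigma
      p <- min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
    }
  }
  out <- list(U = U, p = p, r_rb = 2 * U / (n1 * n2) - 1, method = method,
              n1 = n1, n2 = n2)
  if (isTRUE(ci)) {
    out$median_diff <- stats::median(x) - stats::median(y)
    diffs <- with_seed(seed, vapply(seq_len(B_ci), function(b)
      stats::median(sample(x, n1, replace = TRUE)) -
        stats::median(sample(y, n2, replace = TRUE)), numeric(1)))
    out$median_diff_ci <- stats::quantile(diffs, c(0.025, 0.975),
                                          names = FALSE)
  }
  structure(out, class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("<rank-sum: U = %g (n1 = %d, n2 = %d), p = %.4g (%s), r_rb = %.3f>\n",
              x$U, x$n1, x$n2, x$p, x$method, x$r_rb))
  invisible(x)
}
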