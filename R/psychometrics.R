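# Binomial psychometric models of egg rejection.
#
# Rejection probability as a monotone function of a colour predictor:
# logit link = logistic psychometric function, probit = Gaussian,
# complementary log-log = Weibull. Fitting is maximum likelihood by
# iteratively reweighted least squares (IRLS); the decision threshold is the
# predictor value at which the fitted rejection probability is 0.50.

.links <- c("logit", "probit", "cloglog")

# run code with a private RNG state, restoring the caller's
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Validate a trial table
#'
#' One row per nest: binary `response` (1 = reject, 0 = accept) plus the
#' modelled columns. Checks for missing values and the 0/1 coding; `flushed`
#' is coded 1 = female flushed from the nest.
#'
#' @param t data.frame of trials.
#' @param columns Columns that must be present and complete (besides
#'   `response`).
#' @return `t`, invisibly, or an error.
#' @export
validate_trials <- function(t, columns = character(0)) {
  if (!"response" %in% names(t)) stop("trial table needs a 'response' column")
  if (!all(t$response %in% c(0, 1))) stop("response must be coded 0/1")
  for (cn in columns) {
    if (!cn %in% names(t)) stop("missing trial column: ", cn)
    if (any(is.na(t[[cn]]))) stop("missing values in trial column: ", cn)
  }
  invisible(t)
}

#' Fit a binomial psychometric GLM by IRLS
#'
#' Maximum-likelihood fit of `response ~ predictors` under a binomial model
#' with the requested link, by iteratively reweighted least squares
#' (deviance-change tolerance 1e-8, at most 50 iterations). Standard errors
#' come from the inverse Fisher information at the optimum. Coefficients
#' exceeding 15 in absolute value, or non-convergence, set
#' `converged = FALSE` with a "possible separation" warning; the fit is
#' returned, never silently dropped.
#'
#' @param t Trial table (data.frame with 0/1 `response`).
#' @param predictors Character vector of predictor column names (may be
#'   empty for the intercept-only model).
#' @param link One of `"logit"`, `"probit"`, `"cloglog"`.
#' @param response Name of the response column.
#' @return An object of class `glm_fit`: coefficients, `se`, `vcov`,
#'   `loglik`, `null_loglik`, `deviance`, `n`, `k`, `converged`, plus the
#'   design matrix and response for downstream refits.
#' @export
fit_binomial_glm <- function(t, predictors = character(0),
                             link = c("logit", "probit", "cloglog"),
                             response = "response") {
  link <- match.arg(link)
  validate_trials(
    stats::setNames(data.frame(t[[response]]), "response"))
  for (cn in predictors) {
    if (!cn %in% names(t)) stop("predictor not in table: ", cn)
    if (any(is.na(t[[cn]]))) stop("missing values in predictor: ", cn)
  }
  y <- as.numeric(t[[response]])
  n <- length(y)
  X <- cbind(`(intercept)` = rep(1, n))
  if (length(predictors))
    X <- cbind(X, as.matrix(as.data.frame(lapply(t[predictors], as.numeric))))
  colnames(X) <- c("(intercept)", predictors)
  k <- ncol(X)
  if (n < k + 2) stop("too few trials for the requested model (n < k + 2)")
  if (qr(X)$rank < k) stop("rank-deficient design matrix")

  lk <- stats::make.link(link)
  eps <- .Machine$double.eps
  clamp <- function(mu) pmin(pmax(mu, eps), 1 - eps)
  devfun <- function(mu) -2 * sum(y * log(mu) + (1 - y) * log1p(-mu))

  mu <- (y + 0.5) / 2
  eta <- lk$linkfun(mu)
  dev <- devfun(clamp(mu))
  beta <- rep(0, k)
  converged <- FALSE
  # deviance-change tolerance 1e-8; the extra coefficient-stability
  # criterion matters for non-canonical links, where Fisher scoring
  # converges only linearly near the optimum. Step-halving keeps the
  # deviance monotone non-increasing, so quasi-separated fits drift toward
  # the likelihood supremum instead of diverging numerically.
  beta_old <- beta
  for (it in seq_len(50L)) {
    mu <- clamp(lk$linkinv(eta))
    mu_eta <- pmax(lk$mu.eta(eta), eps)
    w <- mu_eta^2 / (mu * (1 - mu))
    z <- eta + (y - mu) / mu_eta
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    if (any(!is.finite(beta_new))) beta_new <- beta
    dev_new <- devfun(clamp(lk$linkinv(drop(X %*% beta_new))))
    halvings <- 0L
    while ((!is.finite(dev_new) || dev_new > dev + 1e-12) && halvings < 30L &&
           it > 1L) {
      beta_new <- (beta_new + beta) / 2
      dev_new <- devfun(clamp(lk$linkinv(drop(X %*% beta_new))))
      halvings <- halvings + 1L
    }
    step <- max(abs(beta_new - beta))
    beta <- beta_new
    eta <- drop(X %*% beta)
    if (abs(dev_new - dev) / (abs(dev_new) + 0.1) < 1e-8 &&
        step < 1e-10 * (1 + max(abs(beta)))) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  mu <- clamp(lk$linkinv(eta))
  if (any(abs(beta) > 15)) converged <- FALSE
  if (!converged) warning("possible separation: fit not converged or |beta| > 15")

  mu_eta <- pmax(lk$mu.eta(eta), eps)
  W <- mu_eta^2 / (mu * (1 - mu))
  XtWX <- crossprod(X, X * W)
  vc <- tryCatch(solve(XtWX), error = function(e) matrix(NA_real_, k, k))
  dimnames(vc) <- list(colnames(X), colnames(X))
  ll <- sum(y * log(mu) + (1 - y) * log1p(-mu))
  pbar <- mean(y)
  ll0 <- if (pbar %in% c(0, 1)) 0 else
    n * (pbar * log(pbar) + (1 - pbar) * log(1 - pbar))

  structure(list(
    link = link, predictors = predictors,
    coefficients = stats::setNames(as.numeric(beta), colnames(X)),
    se = sqrt(pmax(diag(vc), 0)), vcov = vc,
    loglik = ll, null_loglik = ll0, deviance = dev,
    n = n, k = k, converged = converged,
    X = X, y = y
  ), class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit: %s link, n = %d, k = %d, logLik = %.3f%s>\n",
              x$link, x$n, x$k, x$loglik,
              if (x$converged) "" else ", NOT CONVERGED"))
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' Whole-model diagnostics for a psychometric fit
#'
#' Nagelkerke's R^2, the small-sample corrected AICc, variance inflation
#' factors for the non-intercept predictors (from ordinary least-squares
#' regressions of each predictor on the others), and the likelihood-ratio
#' model chi-squared against the intercept-only model.
#'
#' @param f A [fit_binomial_glm()] result.
#' @return List: `nagelkerke_r2`, `aic`, `aicc`, `vif` (named, length 0 for
#'   the intercept-only model), `model_chi2`, `model_df`, `model_p`.
#' @export
fit_diagnostics <- function(f) {
  stopifnot(inherits(f, "glm_fit"))
  n <- f$n; k <- f$k
  if (n <= k + 1) stop("AICc undefined: n <= k + 1")
  r2_cs <- 1 - exp((2 / n) * (f$null_loglik - f$loglik))
  denom <- 1 - exp((2 / n) * f$null_loglik)
  r2 <- if (denom <= 0) 0 else max(0, min(1, r2_cs / denom))
  aic <- -2 * f$loglik + 2 * k
  aicc <- aic + 2 * k * (k + 1) / (n - k - 1)
  vif <- numeric(0)
  p <- length(f$predictors)
  if (p >= 1) {
    vif <- stats::setNames(rep(1, p), f$predictors)
    if (p >= 2) {
      Xp <- f$X[, f$predictors, drop = FALSE]
      for (j in seq_len(p)) {
        fit <- stats::lm.fit(cbind(1, Xp[, -j, drop = FALSE]), Xp[, j])
        ssr <- sum(fit$residuals^2)
        sst <- sum((Xp[, j] - mean(Xp[, j]))^2)
        r2j <- if (sst <= 0) 0 else 1 - ssr / sst
        vif[j] <- 1 / max(1 - r2j, 1e-12)
      }
    }
  }
  chi2 <- max(0, 2 * (f$loglik - f$null_loglik))
  df <- k - 1
  list(nagelkerke_r2 = r2, aic = aic, aicc = aicc, vif = vif,
       model_chi2 = chi2, model_df = df,
       model_p = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE)
                 else NA_real_)
}

#' Per-term coefficient table
#'
#' Mirrors the usual psychometric-GLM reporting: estimate, Wald standard
#' error, 95% Wald confidence limits, z-score, a per-term likelihood-ratio
#' chi-squared from drop-one refits (df = 1), its p-value, and VIF. Wald
#' intervals are used throughout (profile-likelihood intervals are not
#' provided).
#'
#' @param f A [fit_binomial_glm()] result built from a trial table `t`.
#' @param t The trial table used for the fit (needed for drop-one refits).
#' @return data.frame, one row per coefficient (intercept first).
#' @export
coef_table <- function(f, t) {
  stopifnot(inherits(f, "glm_fit"))
  est <- f$coefficients; se <- f$se
  z <- est / se
  vif <- fit_diagnostics(f)$vif
  out <- data.frame(
    parameter = names(est), estimate = est, se = se,
    lcl = est - 1.96 * se, ucl = est + 1.96 * se, z = z,
    chi2 = NA_real_, df = NA_integer_, p = NA_real_,
    vif = c(NA_real_, if (length(vif)) vif else NULL),
    row.names = NULL, stringsAsFactors = FALSE
  )
  for (j in seq_along(f$predictors)) {
    sub <- suppressWarnings(
      fit_binomial_glm(t, setdiff(f$predictors, f$predictors[j]),
                       link = f$link))
    lr <- max(0, 2 * (f$loglik - sub$loglik))
    out$chi2[j + 1] <- lr
    out$df[j + 1] <- 1L
    out$p[j + 1] <- stats::pchisq(lr, 1, lower.tail = FALSE)
  }
  out
}

#' Decision threshold of a single-predictor psychometric function
#'
#' The predictor value at which the fitted rejection probability equals
#' 0.50: x* = (g(0.5) - beta0) / beta1, where g is the link function.
#' g(0.5) = 0 for logit and probit and ln(ln 2) = -0.36651 for the
#' complementary log-log link.
#'
#' @param f A [fit_binomial_glm()] with exactly one non-intercept predictor.
#' @return Scalar threshold, in the predictor's units (JND).
#' @export
threshold_location <- function(f) {
  stopifnot(inherits(f, "glm_fit"))
  if (length(f$predictors) != 1L)
    stop("threshold requires an intercept + single-predictor model")
  b0 <- f$coefficients[[1L]]
  b1 <- f$coefficients[[2L]]
  if (abs(b1) < 1e-8)
    stop("threshold undefined (flat psychometric function)")
  (stats::make.link(f$link)$linkfun(0.5) - b0) / b1
}

#' Bootstrap uncertainty for a decision threshold
#'
#' Nonparametric case resampling: each replicate redraws n rows with
#' replacement, refits the intercept + single-predictor model and records
#' its p = 0.50 threshold. Replicates that fail to converge or have a flat
#' slope (|beta1| < 1e-8) are dropped and counted. Reported as the median
#' and inter-quartile range (linear-interpolation quantiles) of the
#' surviving replicates.
#'
#' @param t Trial table.
#' @param predictor Single predictor column name.
#' @param link Link function.
#' @param B Number of bootstrap replicates (default 10 000).
#' @param seed Integer seed; the same seed reproduces the estimate exactly.
#' @return An object of class `threshold_estimate`: `point` (full-data
#'   threshold), `boot_median`, `boot_iqr`, `boot_q25`, `boot_q75`, `B`,
#'   `n_failed`, `seed`, `reliable` (FALSE when more than half the
#'   replicates failed), `values` (surviving thresholds).
#' @export
bootstrap_threshold <- function(t, predictor, link = "logit", B = 10000L,
                                seed = 1L) {
  stopifnot(B >= 1L)
  full <- suppressWarnings(fit_binomial_glm(t, predictor, link = link))
  point <- threshold_location(full)
  n <- nrow(t)
  vals <- with_seed(seed, {
    out <- rep(NA_real_, B)
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      out[b] <- tryCatch({
        fb <- suppressWarnings(fit_binomial_glm(t[idx, , drop = FALSE],
                                                predictor, link = link))
        if (!fb$converged) NA_real_ else threshold_location(fb)
      }, error = function(e) NA_real_)
    }
    out
  })
  ok <- vals[!is.na(vals)]
  n_failed <- B - length(ok)
  q <- if (length(ok)) stats::quantile(ok, c(0.25, 0.5, 0.75), type = 7,
                                       names = FALSE)
       else rep(NA_real_, 3)
  structure(list(point = point, boot_median = q[2L],
                 boot_iqr = q[3L] - q[1L], boot_q25 = q[1L],
                 boot_q75 = q[3L], B = B, n_failed = n_failed, seed = seed,
                 reliable = n_failed < 0.5 * B, values = ok),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf(
    "<threshold: point %.3f, boot median %.3f, IQR %.3f (B = %d, failed %d%s)>\n",
    x$point, x$boot_median, x$boot_iqr, x$B, x$n_failed,
    if (x$reliable) "" else "; UNRELIABLE"))
  invisible(x)
}
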