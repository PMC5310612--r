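# shared fixture builders (all data generated in code; nothing on disk)

fixture_grid <- function(step = 5) seq(300, 700, by = step)

# flat-illuminant visual system with Gaussian cones; densities/webers default
fixture_vs <- function() make_visual_system("uvs_default")

# receptor catches with arbitrary positive values (for metric-level tests)
fixture_catches <- function(Q, Q_D = 1, label = "x") {
  structure(list(Q = Q, Q_D = Q_D, label = label),
            class = "receptor_catches")
}

fixture_noise <- function(omega, omega_D = 0.1) {
  structure(list(omega = omega, omega_D = omega_D), class = "noise_vector")
}

# minimal glm_fit for diagnostics-formula tests
fixture_glm_fit <- function(loglik, null_loglik, n, k,
                            predictors = character(0), X = NULL) {
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(intercept)"))
  structure(list(link = "logit", predictors = predictors,
                 coefficients = stats::setNames(rep(0, k), colnames(X)),
                 se = rep(1, k), vcov = diag(k), loglik = loglik,
                 null_loglik = null_loglik, deviance = -2 * loglik,
                 n = n, k = k, converged = TRUE, X = X,
                 y = rep(0:1, length.out = n)),
            class = "glm_fit")
}

# 8-row toy trial table with a clean sigmoidal response pattern
fixture_toy_trials <- function() {
  data.frame(response = c(0, 0, 1, 0, 1, 1, 1, 1),
             x = c(-2, -1, -0.5, 0, 0.5, 1, 1.5, 2))
}

# logistic trials with known intercept/slope on one predictor
fixture_logit_trials <- function(n, beta0, beta1, seed,
                                 xmin = -2, xmax = 4) {
  set.seed(seed)
  x <- stats::runif(n, xmin, xmax)
  data.frame(response = stats::rbinom(n, 1, stats::plogis(beta0 + beta1 * x)),
             x = x)
}

# independent maximum-likelihood oracle: derivative-free search on the
# binomial log-likelihood (never IRLS)
ml_oracle <- function(t, predictors, link, response = "response") {
  X <- cbind(1, as.matrix(t[predictors]))
  y <- t[[response]]
  inv <- stats::make.link(link)$linkinv
  nll <- function(b) {
    mu <- pmin(pmax(inv(drop(X %*% b)), 1e-12), 1 - 1e-12)
    -sum(y * log(mu) + (1 - y) * log(1 - mu))
  }
  b <- rep(0, ncol(X))
  for (i in 1:5)
    b <- stats::optim(b, nll,
                      control = list(reltol = 1e-16, maxit = 50000))$par
  stats::optim(b, nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))$par
}

# synthetic model_record list with stated AICc values (for candidate-set and
# averaging arithmetic tests)
fixture_records <- function(aicc, coefs, ses) {
  iw <- if (length(aicc) == 1L)
    list(delta = 0, rel_likelihood = 1, weight = 1)
  else information_weights(aicc)
  lapply(seq_along(aicc), function(i) {
    cf <- coefs[[i]]; se <- ses[[i]]
    structure(list(
      predictors = setdiff(names(cf), "(intercept)"),
      fit = list(coefficients = cf, se = se),
      aicc = aicc[i], delta = iw$delta[i],
      rel_likelihood = iw$rel_likelihood[i], weight = iw$weight[i]),
      class = "model_record")
  })
}
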