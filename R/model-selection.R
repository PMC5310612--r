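# Information-theoretic model comparison and multimodel averaging.
#
# Models are ranked by the small-sample corrected AICc; relative likelihoods
# exp(-delta/2) give Akaike weights and evidence ratios. The candidate set
# keeps models whose relative likelihood is at least 1/8 of the best
# (boundary inclusive), and averaging uses the "zero method": a predictor's
# coefficient counts as 0 in models that exclude it, shrinking averaged
# effects toward zero rather than away from it.

#' Akaike weights and evidence ratios from AICc values
#'
#' @param aicc Numeric vector of finite AICc values (>= 2 models).
#' @return List: `delta` (AICc minus the minimum), `rel_likelihood`
#'   (exp(-delta/2)), `weight` (normalized), `evidence_ratio` (matrix with
#'   ER\[i, j\] = weight_i / weight_j, the empirical support for model i over
#'   model j).
#' @export
information_weights <- function(aicc) {
  if (length(aicc) < 2L) stop("need at least two AICc values")
  if (any(!is.finite(aicc))) stop("non-finite AICc")
  delta <- aicc - min(aicc)
  rl <- exp(-delta / 2)
  w <- rl / sum(rl)
  er <- outer(w, w, "/")
  list(delta = delta, rel_likelihood = rl, weight = w, evidence_ratio = er)
}

#' Fit every predictor subset of a global model
#'
#' Exhaustively fits all 2^p subsets of the global predictor list (the
#' intercept is always included), recording each model's AICc. Models that
#' fail to converge are skipped with a warning. Records are sorted by AICc
#' ascending, ties broken by the lexicographic order of the predictor
#' subset.
#'
#' @param t Trial table.
#' @param global_predictors Up to 12 predictor names.
#' @param link Link function, as in [fit_binomial_glm()].
#' @return List of `model_record`s: `predictors`, `fit`, `aicc`, plus
#'   `delta`, `rel_likelihood` and `weight` computed over the full
#'   enumeration.
#' @export
enumerate_models <- function(t, global_predictors, link = "logit") {
  p <- length(global_predictors)
  if (p > 12L) stop("exhaustive enumeration too large (> 12 predictors)")
  n_mod <- 2L^p
  records <- vector("list", n_mod)
  dropped <- 0L
  for (i in seq_len(n_mod)) {
    bits <- as.logical(bitwAnd(i - 1L, bitwShiftL(1L, seq_len(p) - 1L)))
    preds <- global_predictors[bits]
    rec <- tryCatch({
      fit <- suppressWarnings(fit_binomial_glm(t, preds, link = link))
      if (!fit$converged) NULL
      else list(predictors = preds, fit = fit,
                aicc = fit_diagnostics(fit)$aicc)
    }, error = function(e) NULL)
    if (is.null(rec)) dropped <- dropped + 1L else records[[i]] <- rec
  }
  records <- Filter(Negate(is.null), records)
  if (dropped > 0L)
    warning(sprintf("%d of %d models skipped (non-convergence)", dropped, n_mod))
  if (length(records) == 0L) stop("no model converged")
  key <- vapply(records, function(r) paste(r$predictors, collapse = "+"),
                character(1))
  ord <- order(vapply(records, `[[`, numeric(1), "aicc"), key)
  records <- records[ord]
  iw <- if (length(records) >= 2L)
    information_weights(vapply(records, `[[`, numeric(1), "aicc"))
  else list(delta = 0, rel_likelihood = 1, weight = 1)
  for (i in seq_along(records)) {
    records[[i]]$delta <- iw$delta[i]
    records[[i]]$rel_likelihood <- iw$rel_likelihood[i]
    records[[i]]$weight <- iw$weight[i]
    class(records[[i]]) <- "model_record"
  }
  records
}

#' Build the relative-likelihood candidate set
#'
#' Keeps models whose relative likelihood exp(-delta/2) is at least 1/8 of
#' the best model (equivalently delta <= 2 ln 8 = 4.1589; the boundary is
#' inclusive) and renormalizes Akaike weights within the kept set.
#'
#' @param records Output of [enumerate_models()].
#' @return An object of class `candidate_set`: `records` (with renormalized
#'   `weight`), `cutoff` (= 1/8), `n_considered`.
#' @export
candidate_set <- function(records) {
  if (length(records) == 0L) stop("empty model list")
  rl <- vapply(records, `[[`, numeric(1), "rel_likelihood")
  keep <- rl >= (1 / 8) * (1 - 1e-12)
  kept <- records[keep]
  w <- vapply(kept, `[[`, numeric(1), "rel_likelihood")
  w <- w / sum(w)
  for (i in seq_along(kept)) kept[[i]]$weight <- w[i]
  structure(list(records = kept, cutoff = 1 / 8,
                 n_considered = length(records)),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set: %d of %d models (relative likelihood >= 1/8)>\n",
              length(x$records), x$n_considered))
  invisible(x)
}

#' Zero-method multimodel averaging
#'
#' Averaged estimate for predictor j: sum over candidate models of
#' weight_i * beta_ij, where beta_ij = 0 (with se 0) when j is absent from
#' model i. The adjusted standard error is the unconditional-variance
#' estimator sum_i w_i * sqrt(se_ij^2 + (beta_ij - mean)^2). Relative
#' importance is the summed weight of candidate models containing the
#' predictor (1 for a predictor in every model). Between-model covariances
#' are ignored, per the standard estimator.
#'
#' @param cs A [candidate_set()].
#' @param predictors Predictors to report; defaults to the union over the
#'   candidate set (intercept always reported first).
#' @return data.frame: parameter, estimate, se_adjusted, lcl, ucl (95% Wald),
#'   z, importance (NA for the intercept).
#' @export
model_average <- function(cs, predictors = NULL) {
  stopifnot(inherits(cs, "candidate_set"))
  recs <- cs$records
  if (length(recs) == 0L) stop("empty candidate set")
  if (is.null(predictors))
    predictors <- unique(unlist(lapply(recs, `[[`, "predictors")))
  params <- c("(intercept)", predictors)
  w <- vapply(recs, `[[`, numeric(1), "weight")
  out <- lapply(params, function(pn) {
    beta <- vapply(recs, function(r) {
      if (pn %in% names(r$fit$coefficients)) r$fit$coefficients[[pn]] else 0
    }, numeric(1))
    se <- vapply(recs, function(r) {
      if (pn %in% names(r$fit$se)) r$fit$se[[pn]] else 0
    }, numeric(1))
    present <- vapply(recs, function(r)
      pn == "(intercept)" || pn %in% r$predictors, logical(1))
    est <- sum(w * beta)
    se_adj <- sum(w * sqrt(se^2 + (beta - est)^2))
    data.frame(parameter = pn, estimate = est, se_adjusted = se_adj,
               lcl = est - 1.96 * se_adj, ucl = est + 1.96 * se_adj,
               z = if (se_adj > 0) abs(est) / se_adj else NA_real_,
               importance = if (pn == "(intercept)") NA_real_
                            else sum(w[present]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Compare the single- and multiple-threshold decision rules
#'
#' Fits the two scenario models of the decision-rule test — multiple
#' threshold: rejection driven by absolute perceived dissimilarity
#' (`chromatic_contrast` + `achromatic_contrast`); single threshold:
#' rejection driven by signed position along the colour gradients (`x_bgbr`,
#' `x_gp`, `x_uv` + `achromatic_contrast`) — and reports the two-model
#' Akaike weights and the evidence ratio for the single-threshold rule over
#' the multiple-threshold rule.
#'
#' @param t Trial table containing the five colour predictors.
#' @param link Link function.
#' @return List: `multiple`, `single` (each: fit, diagnostics, weight),
#'   `evidence_ratio_single_vs_multiple`, `link`.
#' @export
compare_decision_rules <- function(t, link = "logit") {
  multiple <- c("chromatic_contrast", "achromatic_contrast")
  single <- c("x_bgbr", "x_gp", "x_uv", "achromatic_contrast")
  fm <- suppressWarnings(fit_binomial_glm(t, multiple, link = link))
  fs <- suppressWarnings(fit_binomial_glm(t, single, link = link))
  dm <- fit_diagnostics(fm); ds <- fit_diagnostics(fs)
  iw <- information_weights(c(dm$aicc, ds$aicc))
  list(
    multiple = list(fit = fm, diagnostics = dm, weight = iw$weight[1L]),
    single = list(fit = fs, diagnostics = ds, weight = iw$weight[2L]),
    evidence_ratio_single_vs_multiple = iw$evidence_ratio[2L, 1L],
    link = link
  )
}
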