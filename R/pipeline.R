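# End-to-end analysis orchestration.
#
# spectra -> JND predictors -> scenario GLMs (single vs multiple threshold)
# -> p = 0.5 thresholds with bootstrap -> candidate-set model averaging ->
# (optionally) between-host slope comparison. A pure function of
# (inputs, config, seed): reruns with the same config are byte-identical.

# derive a per-stage seed from the root seed, kept below 2^31
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647L) + 1L
}

#' Compute JND colour predictors for a set of egg spectra
#'
#' Runs the visual model end to end: quantum catches for every spectrum,
#' geometric-mean host reference, gradient axes from the four endpoint
#' stimuli, signed axis coordinates and chromatic/achromatic contrast to
#' the host mean.
#'
#' @param eggs [spectrum_set()] of foreign-egg spectra.
#' @param host_eggs [spectrum_set()] of host own-egg spectra (defines the
#'   origin).
#' @param vs A [visual_system()].
#' @param endpoints Named list of four [spectrum()]s: `bluegreen_end`,
#'   `brown_end`, `green_end`, `purple_end`. Defaults to the synthetic
#'   gradient endpoint templates.
#' @return List: `predictors` (data.frame with label, x_bgbr, x_gp, x_uv,
#'   chromatic_contrast, achromatic_contrast), `axes`, `origin_catches`.
#' @export
compute_predictors <- function(eggs, host_eggs, vs = make_visual_system(),
                               endpoints = NULL) {
  stopifnot(inherits(eggs, "spectrum_set"), inherits(host_eggs, "spectrum_set"))
  noise <- receptor_noise(vs)
  basis <- jnd_basis(noise)
  if (is.null(endpoints))
    endpoints <- list(
      bluegreen_end = eggshell_spectrum("natural_bluegreen_brown", 0,
                                        vs$grid, "bluegreen_end"),
      brown_end = eggshell_spectrum("natural_bluegreen_brown", 1, vs$grid,
                                    "brown_end"),
      green_end = eggshell_spectrum("artificial_green_purple", 0, vs$grid,
                                    "green_end"),
      purple_end = eggshell_spectrum("artificial_green_purple", 1, vs$grid,
                                     "purple_end"))
  axes_spec <- lapply(endpoints, function(s)
    jnd_coordinates(quantum_catches(s, vs), noise, basis))
  host_catches <- lapply(host_eggs$spectra, quantum_catches, vs = vs)
  origin_catches <- host_mean_catches(host_catches)
  axes_spec$origin <- jnd_coordinates(origin_catches, noise, basis)
  catches <- lapply(eggs$spectra, quantum_catches, vs = vs)
  pts <- lapply(catches, jnd_coordinates, noise = noise, basis = basis)
  proj <- gradient_projection(pts, axes_spec, noise)
  pred <- proj$predictors
  pred$achromatic_contrast <- vapply(catches, achromatic_contrast, numeric(1),
                                     b = origin_catches,
                                     omega_D = noise$omega_D)
  list(predictors = pred, axes = proj$axes, origin_catches = origin_catches)
}

#' Default pipeline configuration
#'
#' @param seed Root seed; all stage seeds derive from it.
#' @param links Links to fit (first is primary).
#' @param bootstrap_B Bootstrap replicates for thresholds.
#' @param resample_B Slope-resampling replicates.
#' @param resample_fraction Subsample proportion.
#' @param threshold_predictors Predictors whose p = 0.5 thresholds are
#'   bootstrapped.
#' @param global_predictors Global model for candidate-set averaging.
#' @param outdir Output directory, or `NULL` to skip file output.
#' @return Named list of settings.
#' @export
pipeline_config <- function(seed = 1L,
                            links = c("logit", "probit", "cloglog"),
                            bootstrap_B = 10000L, resample_B = 10000L,
                            resample_fraction = 0.9,
                            threshold_predictors = c("x_bgbr", "x_gp",
                                                     "chromatic_contrast"),
                            global_predictors = c(
                              "x_bgbr", "x_gp", "x_uv", "chromatic_contrast",
                              "achromatic_contrast", "flushed", "clutch_size",
                              "laying_date", "nest_age"),
                            outdir = NULL) {
  list(seed = as.integer(seed), links = links,
       bootstrap_B = as.integer(bootstrap_B),
       resample_B = as.integer(resample_B),
       resample_fraction = resample_fraction,
       threshold_predictors = threshold_predictors,
       global_predictors = global_predictors, outdir = outdir)
}

#' Load a pipeline configuration from YAML
#'
#' Recognized keys mirror the [pipeline_config()] arguments, plus optional
#' `trials` (CSV path), `trials2` (second host for the slope comparison),
#' `spectra`, `host_spectra`, `visual_system` (CSV path with
#' `densities`, `weber_ref`, `weber_double` sub-keys).
#'
#' @param path YAML file.
#' @return List with `config` ([pipeline_config()]) and `inputs` (paths).
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  cfg <- do.call(pipeline_config, args)
  inputs <- y[intersect(names(y), c("trials", "trials2", "spectra",
                                    "host_spectra", "visual_system"))]
  list(config = cfg, inputs = inputs)
}

#' Run the full decision-rule analysis
#'
#' Stages: (1) scenario comparison — single- vs multiple-threshold GLMs for
#' every requested link, with AICc weights and the evidence ratio;
#' (2) bootstrap p = 0.5 thresholds for each predictor of interest, from
#' single-predictor refits; (3) exhaustive candidate-set model averaging of
#' the global predictor set (primary link); (4) if a second trial table is
#' supplied, the between-host slope comparison (90% subsample resampling,
#' Monte-Carlo KS normality, rank-sum test with rank-biserial correlation).
#' With `outdir` set, writes table1.csv, thresholds.json, table2.csv,
#' predictors.csv (trial predictors), slopes.csv, comparison.json and
#' run.log.
#'
#' @param trials Trial table (data.frame) with the five colour predictors
#'   and covariates.
#' @param config A [pipeline_config()].
#' @param trials2 Optional second host's trial table for the slope
#'   comparison.
#' @return List of class `decision_rule_report`: `table1` (data.frame),
#'   `scenarios` (per link), `thresholds`, `table2`, `averaged`,
#'   `comparison` (or NULL), `config`.
#' @export
run_decision_rule_analysis <- function(trials, config = pipeline_config(),
                                       trials2 = NULL) {
  validate_trials(trials, c("x_bgbr", "x_gp", "x_uv", "chromatic_contrast",
                            "achromatic_contrast"))
  log_lines <- c(sprintf("eggdiscrim %s | R %s | seed %d",
                         as.character(utils::packageVersion("eggdiscrim")),
                         paste(R.version$major, R.version$minor, sep = "."),
                         config$seed))
  stage <- "scenario_comparison"
  out <- tryCatch({
    scenarios <- lapply(config$links, function(lk)
      compare_decision_rules(trials, link = lk))
    names(scenarios) <- config$links
    table1 <- do.call(rbind, lapply(config$links, function(lk) {
      cr <- scenarios[[lk]]
      rows <- lapply(c("multiple", "single"), function(sc) {
        f <- cr[[sc]]$fit; d <- cr[[sc]]$diagnostics
        ct <- coef_table(f, trials)
        cbind(link = lk, scenario = paste0(sc, "_threshold"),
              model_chi2 = d$model_chi2, nagelkerke_r2 = d$nagelkerke_r2,
              aicc = d$aicc, w_i = cr[[sc]]$weight, model_p = d$model_p,
              n = f$n, ct)
      })
      do.call(rbind, rows)
    }))
    log_lines <- c(log_lines, sprintf(
      "scenario comparison done; ER(single/multiple, %s) = %.4g",
      config$links[1],
      scenarios[[1]]$evidence_ratio_single_vs_multiple))

    stage <- "thresholds"
    primary <- config$links[1]
    thresholds <- list()
    for (i in seq_along(config$threshold_predictors)) {
      pn <- config$threshold_predictors[i]
      for (j in seq_along(config$links)) {
        lk <- config$links[j]
        th <- bootstrap_threshold(trials, pn, link = lk,
                                  B = config$bootstrap_B,
                                  seed = stage_seed(config$seed,
                                                    100 + 10 * i + j))
        thresholds[[paste(pn, lk, sep = ".")]] <- th
        if (th$n_failed > 0)
          log_lines <- c(log_lines, sprintf(
            "WARNING: %d/%d bootstrap replicates dropped for %s (%s)",
            th$n_failed, th$B, pn, lk))
      }
    }

    stage <- "model_averaging"
    records <- enumerate_models(trials, config$global_predictors,
                                link = primary)
    cs <- candidate_set(records)
    table2 <- model_average(cs, predictors = config$global_predictors)
    log_lines <- c(log_lines, sprintf(
      "model averaging: %d/%d models in candidate set",
      length(cs$records), cs$n_considered))

    stage <- "slope_comparison"
    comparison <- NULL
    slopes <- NULL
    if (!is.null(trials2)) {
      validate_trials(trials2, c("x_bgbr", "x_gp", "x_uv",
                                 "chromatic_contrast",
                                 "achromatic_contrast"))
      s1 <- resample_slopes(trials, link = primary, B = config$resample_B,
                            fraction = config$resample_fraction,
                            seed = stage_seed(config$seed, 201))
      s2 <- resample_slopes(trials2, link = primary, B = config$resample_B,
                            fraction = config$resample_fraction,
                            seed = stage_seed(config$seed, 202))
      ks1 <- ks_normality_mc(s1$values, seed = stage_seed(config$seed, 203))
      ks2 <- ks_normality_mc(s2$values, seed = stage_seed(config$seed, 204))
      wt <- wilcoxon_rank_sum(s2$values, s1$values, ci = TRUE,
                              seed = stage_seed(config$seed, 205))
      slopes <- data.frame(
        host = rep(c("host1", "host2"),
                   c(length(s1$values), length(s2$values))),
        slope = c(s1$values, s2$values))
      comparison <- list(
        host1 = list(median = stats::median(s1$values),
                     iqr = stats::IQR(s1$values), ks = ks1,
                     n_failed = s1$n_failed),
        host2 = list(median = stats::median(s2$values),
                     iqr = stats::IQR(s2$values), ks = ks2,
                     n_failed = s2$n_failed),
        rank_test = wt)
      log_lines <- c(log_lines, sprintf(
        "slope comparison: medians %.3f vs %.3f, r_rb = %.3f",
        stats::median(s1$values), stats::median(s2$values), wt$r_rb))
    }

    structure(list(table1 = table1, scenarios = scenarios,
                   thresholds = thresholds, table2 = table2,
                   candidate_set = cs, slopes = slopes,
                   comparison = comparison, config = config,
                   log = log_lines),
              class = "decision_rule_report")
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  if (!is.null(config$outdir)) write_report(out, trials, config$outdir)
  out
}

# serialize the report bundle (internal)
write_report <- function(report, trials, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  num <- function(df) {
    for (j in seq_along(df)) if (is.numeric(df[[j]]))
      df[[j]] <- signif(df[[j]], 10)
    df
  }
  utils::write.csv(num(report$table1), file.path(outdir, "table1.csv"),
                   row.names = FALSE)
  utils::write.csv(num(report$table2), file.path(outdir, "table2.csv"),
                   row.names = FALSE)
  utils::write.csv(num(trials), file.path(outdir, "predictors.csv"),
                   row.names = FALSE)
  th <- lapply(report$thresholds, function(x)
    x[c("point", "boot_median", "boot_iqr", "B", "n_failed", "seed",
        "reliable")])
  jsonlite::write_json(th, file.path(outdir, "thresholds.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$slopes))
    utils::write.csv(num(report$slopes), file.path(outdir, "slopes.csv"),
                     row.names = FALSE)
  if (!is.null(report$comparison)) {
    cmp <- report$comparison
    cmp$host1$ks <- unclass(cmp$host1$ks)
    cmp$host2$ks <- unclass(cmp$host2$ks)
    cmp$rank_test <- unclass(cmp$rank_test)
    jsonlite::write_json(cmp, file.path(outdir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  writeLines(report$log, file.path(outdir, "run.log"))
  invisible(outdir)
}

#' @export
print.decision_rule_report <- function(x, ...) {
  cat("<decision_rule_report>\n")
  for (lk in names(x$scenarios))
    cat(sprintf("  %s: ER(single/multiple) = %.4g\n", lk,
                x$scenarios[[lk]]$evidence_ratio_single_vs_multiple))
  for (nm in names(x$thresholds)) {
    th <- x$thresholds[[nm]]
    cat(sprintf("  threshold %s: median %.3f (IQR %.3f)\n", nm,
                th$boot_median, th$boot_iqr))
  }
  if (!is.null(x$comparison))
    cat(sprintf("  slope comparison: r_rb = %.3f, p = %.4g\n",
                x$comparison$rank_test$r_rb, x$comparison$rank_test$p))
  invisible(x)
}

#' Plot a fitted psychometric function
#'
#' Base-graphics plot of the binary responses against one predictor with
#' the fitted rejection-probability curves for each requested link.
#'
#' @param trials Trial table.
#' @param predictor Predictor column.
#' @param links Links to draw.
#' @param ... Passed to [plot()].
#' @return Invisibly, the matrix of curve values.
#' @export
plot_psychometric <- function(trials, predictor = "x_bgbr",
                              links = c("logit", "probit", "cloglog"), ...) {
  x <- trials[[predictor]]
  xx <- seq(min(x), max(x), length.out = 200)
  graphics::plot(x, trials$response, pch = 16,
                 col = grDevices::adjustcolor("black", 0.5),
                 xlab = sprintf("%s (JND)", predictor),
                 ylab = "rejection probability", ylim = c(0, 1), ...)
  lty <- c(logit = 1, probit = 2, cloglog = 3)
  curves <- sapply(links, function(lk) {
    f <- suppressWarnings(fit_binomial_glm(trials, predictor, link = lk))
    yy <- stats::make.link(lk)$linkinv(f$coefficients[1] +
                                         f$coefficients[2] * xx)
    graphics::lines(xx, yy, lty = lty[[lk]])
    yy
  })
  graphics::legend("bottomright", legend = links, lty = lty[links],
                   bty = "n")
  invisible(curves)
}
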