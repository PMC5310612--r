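# Synthetic eggshell spectra and simulated rejection experiments.
#
# Real eggshell colours vary along a single natural axis from blue-green
# (biliverdin-dominated) to brown (protoporphyrin-dominated). The generator
# produces smooth reflectance templates along this natural gradient and
# along an artificial green -> purple gradient roughly orthogonal to it in
# the avian perceptual space, plus binary rejection responses under a
# stated decision rule, so every pipeline stage is exercisable without
# field data. Template shapes are package constants, synthetic rather than
# measured; they are calibrated so the natural gradient spans roughly
# 0-8 JND under the default visual system.

# reflectance templates on an arbitrary grid (internal)
.tmpl <- list(
  bluegreen = function(wl) 0.10 + 0.45 * exp(-((wl - 500) / 55)^2 / 2),
  brown     = function(wl) 0.06 + 0.55 / (1 + exp(-(wl - 600) / 45)),
  green     = function(wl) 0.08 + 0.45 * exp(-((wl - 505) / 45)^2 / 2),
  purple    = function(wl) 0.08 + 0.25 * exp(-((wl - 390) / 35)^2 / 2) +
                           0.25 * exp(-((wl - 670) / 45)^2 / 2)
)

#' Synthetic eggshell reflectance along a colour gradient
#'
#' Linear mix of two endpoint templates, clipped to \[0, 1\]:
#' * `natural_bluegreen_brown` — m = 0 is a blue-green egg (reflectance peak
#'   near 500 nm), m = 1 a brown egg (sigmoidal rise toward 700 nm);
#' * `artificial_green_purple` — m = 0 is green (single mid-wavelength
#'   peak), m = 1 purple (bimodal short + long wavelength peaks).
#'
#' @param gradient Which gradient.
#' @param m Position along the gradient in \[0, 1\].
#' @param grid Wavelength grid (default [canonical_grid()]).
#' @param label Spectrum label.
#' @return A [spectrum()].
#' @export
eggshell_spectrum <- function(gradient = c("natural_bluegreen_brown",
                                           "artificial_green_purple"),
                              m, grid = canonical_grid(),
                              label = NULL) {
  gradient <- match.arg(gradient)
  if (!(is.numeric(m) && length(m) == 1L && m >= 0 && m <= 1))
    stop("m must be a scalar in [0, 1]")
  ends <- if (gradient == "natural_bluegreen_brown")
    c("bluegreen", "brown") else c("green", "purple")
  v <- (1 - m) * .tmpl[[ends[1L]]](grid) + m * .tmpl[[ends[2L]]](grid)
  v <- pmin(pmax(v, 0), 1)
  if (is.null(label)) label <- sprintf("%s_m%.3f", gradient, m)
  spectrum(grid, v, label = label)
}

#' Built-in visual system presets
#'
#' `uvs_default`: an ultraviolet-sensitive passerine stand-in with Gaussian
#' sensitivity templates peaking at 370/445/505/565 nm (U/S/M/L, sd 35 nm),
#' a broad double cone peaking at 565 nm (sd 65 nm), a flat (ideal-white)
#' illuminant, receptor densities 1:2:2:4 and Weber fractions 0.1 for both
#' the reference (L) cone and the achromatic channel. These are
#' conventional defaults for passerine receptor-noise modelling, not
#' measured curves; drop in published curves via [read_visual_system()] to
#' override.
#'
#' @param preset Preset name.
#' @return A [visual_system()].
#' @export
make_visual_system <- function(preset = "uvs_default") {
  known <- c("uvs_default")
  if (!preset %in% known)
    stop("unknown preset '", preset, "'; available: ",
         paste(known, collapse = ", "))
  grid <- canonical_grid()
  gauss <- function(peak, sd) spectrum(grid, exp(-((grid - peak) / sd)^2 / 2),
                                       label = sprintf("gauss%d", peak),
                                       check_reflectance = FALSE)
  visual_system(
    sensitivities = list(U = gauss(370, 35), S = gauss(445, 35),
                         M = gauss(505, 35), L = gauss(565, 35)),
    double_cone = gauss(565, 65),
    illuminant = spectrum(grid, rep(1, length(grid)), label = "flat",
                          check_reflectance = FALSE),
    densities = c(U = 1, S = 2, M = 2, L = 4),
    weber_ref = 0.1, weber_double = 0.1
  )
}

#' Simulation parameters for a rejection experiment
#'
#' Defaults describe a robin-scale experiment: n = 52 nests, logistic
#' psychometric function with slope 2.43 per JND and intercept 0.24 (the
#' single-threshold fit reported for that host), responses generated under
#' the single-threshold rule. Covariates are nuisance variables: flushed ~
#' Bernoulli(0.5), clutch size uniform on \{3, 4, 5\}, laying date uniform
#' on a 60-day window, nest age uniform on 1-10 days.
#'
#' @param rule `"single_threshold"` (response driven by the signed
#'   blue-green -> brown position) or `"multiple_threshold"` (driven by
#'   absolute chromatic contrast).
#' @param link Psychometric link.
#' @param beta0,beta1 Intercept and slope on the driving colour predictor
#'   (log-odds per JND for the logit link).
#' @param beta_achro Optional slope on achromatic contrast (default 0).
#' @param n Number of nests (>= 10).
#' @param gradient_split Proportion of nests receiving natural-gradient
#'   eggs; the rest receive artificial-gradient eggs.
#' @param host_m Host population's own position on the natural gradient.
#' @param host_sd Between-egg sd of host positions (for the host reference
#'   sample).
#' @param n_host_eggs Host eggs measured for the population mean colour.
#' @param seed Integer seed.
#' @return List of class `simulation_params`.
#' @export
simulation_params <- function(rule = c("single_threshold",
                                       "multiple_threshold"),
                              link = "logit", beta0 = 0.24, beta1 = 2.43,
                              beta_achro = 0, n = 52L, gradient_split = 0.5,
                              host_m = 0.7, host_sd = 0.03,
                              n_host_eggs = 20L, seed = 1L) {
  rule <- match.arg(rule)
  stopifnot(n >= 10L, is.finite(beta1), gradient_split >= 0,
            gradient_split <= 1, host_m >= 0, host_m <= 1)
  structure(list(rule = rule, link = link, beta0 = beta0, beta1 = beta1,
                 beta_achro = beta_achro, n = as.integer(n),
                 gradient_split = gradient_split, host_m = host_m,
                 host_sd = host_sd, n_host_eggs = as.integer(n_host_eggs),
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Simulate a foreign-egg rejection experiment
#'
#' Draws one foreign egg per nest at a uniform position m on its assigned
#' gradient, renders its reflectance spectrum, runs the full visual model
#' (quantum catches -> JND embedding -> gradient projection relative to the
#' host population's geometric-mean egg colour) and generates the binary
#' rejection response from Bernoulli(linkinv(beta0 + beta1 * x +
#' beta_achro * achromatic)), where x is the blue-green -> brown coordinate
#' under the single-threshold rule or the absolute chromatic contrast under
#' the multiple-threshold rule. Fully seeded: the same parameters reproduce
#' the identical trial table.
#'
#' @param p A [simulation_params()].
#' @param vs A [visual_system()] (default [make_visual_system()]).
#' @return List of class `simulated_experiment`: `trials` (trial table with
#'   colour predictors, covariates, gradient and m), `spectra`
#'   ([spectrum_set()] of the model eggs), `host_spectra`, `axes`
#'   (`gradient_axes`), `params`, and `true_threshold` (the generating
#'   p = 0.5 location on the driving predictor).
#' @export
simulate_experiment <- function(p = simulation_params(),
                                vs = make_visual_system()) {
  stopifnot(inherits(p, "simulation_params"), inherits(vs, "visual_system"))
  noise <- receptor_noise(vs)
  basis <- jnd_basis(noise)
  grid <- vs$grid
  emb <- function(spec) jnd_coordinates(quantum_catches(spec, vs), noise, basis)

  axes_spec <- list(
    bluegreen_end = emb(eggshell_spectrum("natural_bluegreen_brown", 0, grid,
                                          "bluegreen_end")),
    brown_end = emb(eggshell_spectrum("natural_bluegreen_brown", 1, grid,
                                      "brown_end")),
    green_end = emb(eggshell_spectrum("artificial_green_purple", 0, grid,
                                      "green_end")),
    purple_end = emb(eggshell_spectrum("artificial_green_purple", 1, grid,
                                       "purple_end"))
  )

  with_seed(p$seed, {
    # host population reference: geometric mean catches of measured eggs
    host_pos <- pmin(pmax(stats::rnorm(p$n_host_eggs, p$host_m, p$host_sd),
                          0), 1)
    host_specs <- lapply(seq_along(host_pos), function(i)
      eggshell_spectrum("natural_bluegreen_brown", host_pos[i], grid,
                        sprintf("host_egg_%02d", i)))
    host_catches <- lapply(host_specs, quantum_catches, vs = vs)
    origin_catches <- host_mean_catches(host_catches)
    axes_spec$origin <- jnd_coordinates(origin_catches, noise, basis)

    n <- p$n
    gradient <- ifelse(stats::runif(n) < p$gradient_split,
                       "natural_bluegreen_brown", "artificial_green_purple")
    m <- stats::runif(n)
    specs <- lapply(seq_len(n), function(i)
      eggshell_spectrum(gradient[i], m[i], grid, sprintf("egg_%03d", i)))
    catches <- lapply(specs, quantum_catches, vs = vs)
    pts <- lapply(catches, jnd_coordinates, noise = noise, basis = basis)
    proj <- gradient_projection(pts, axes_spec, noise)
    pred <- proj$predictors
    pred$achromatic_contrast <- vapply(catches, achromatic_contrast,
                                       numeric(1), b = origin_catches,
                                       omega_D = noise$omega_D)

    x <- switch(p$rule,
                single_threshold = pred$x_bgbr,
                multiple_threshold = pred$chromatic_contrast)
    eta <- p$beta0 + p$beta1 * x + p$beta_achro * pred$achromatic_contrast
    prob <- stats::make.link(p$link)$linkinv(eta)
    response <- stats::rbinom(n, 1L, prob)

    trials <- data.frame(
      nest_id = sprintf("nest_%03d", seq_len(n)),
      response = response,
      x_bgbr = pred$x_bgbr, x_gp = pred$x_gp, x_uv = pred$x_uv,
      chromatic_contrast = pred$chromatic_contrast,
      achromatic_contrast = pred$achromatic_contrast,
      flushed = stats::rbinom(n, 1L, 0.5),
      clutch_size = sample(3:5, n, replace = TRUE),
      laying_date = sample(100:159, n, replace = TRUE),
      nest_age = sample(1:10, n, replace = TRUE),
      gradient = gradient, m = m,
      stringsAsFactors = FALSE
    )
    structure(list(
      trials = trials,
      spectra = spectrum_set(specs, source = "synthetic"),
      host_spectra = spectrum_set(host_specs, source = "synthetic"),
      axes = proj$axes, params = p,
      true_threshold = (stats::make.link(p$link)$linkfun(0.5) - p$beta0) /
        p$beta1
    ), class = "simulated_experiment")
  })
}

#' @export
print.simulated_experiment <- function(x, ...) {
  cat(sprintf(
    "<simulated_experiment: %d nests, %s rule, %s link, rejection rate %.2f>\n",
    nrow(x$trials), x$params$rule, x$params$link, mean(x$trials$response)))
  invisible(x)
}
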