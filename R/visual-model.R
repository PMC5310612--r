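# Receptor-noise-limited (RNL) visual modelling.
#
# Pipeline: reflectance spectrum -> receptor quantum catches Q_i ->
# log-catch contrasts weighted by Weber-fraction noise -> chromatic /
# achromatic contrast in just-noticeable-difference (JND) units, and a
# Cartesian chromaticity embedding in which Euclidean distance equals
# chromatic contrast (a "perceptually uniform chromaticity diagram").

#' Define a tetrachromatic visual system
#'
#' @param sensitivities Named list of four [spectrum()] objects, in order
#'   `U`, `S`, `M`, `L` (ultraviolet- to long-wavelength-sensitive cones).
#' @param double_cone [spectrum()] for the achromatic (double cone) channel.
#' @param illuminant [spectrum()], irradiance in arbitrary linear units.
#' @param densities Relative receptor abundances, positive, same order/names
#'   as `sensitivities`. Only ratios matter.
#' @param weber_ref Weber fraction of the reference (most abundant) receptor,
#'   in (0, 1).
#' @param weber_double Weber fraction of the achromatic channel, in (0, 1).
#' @return An object of class `visual_system`. All spectra are resampled onto
#'   [canonical_grid()].
#' @export
visual_system <- function(sensitivities, double_cone, illuminant,
                          densities = c(U = 1, S = 2, M = 2, L = 4),
                          weber_ref = 0.1, weber_double = 0.1) {
  if (length(sensitivities) != 4L)
    stop("exactly 4 chromatic receptors required (tetrachromat)")
  if (is.null(names(sensitivities)))
    names(sensitivities) <- c("U", "S", "M", "L")
  densities <- densities[names(sensitivities)]
  if (any(is.na(densities)) || any(densities <= 0))
    stop("receptor densities must be positive and named like the sensitivities")
  if (!(weber_ref > 0 && weber_ref < 1)) stop("weber_ref must be in (0, 1)")
  if (!(weber_double > 0 && weber_double < 1))
    stop("weber_double must be in (0, 1)")
  grid <- canonical_grid()
  sens <- lapply(sensitivities, resample_to_grid, grid = grid)
  structure(list(
    receptor_names = names(sensitivities),
    sensitivities = sens,
    double_cone = resample_to_grid(double_cone, grid),
    illuminant = resample_to_grid(illuminant, grid),
    densities = densities,
    weber_ref = weber_ref,
    weber_double = weber_double,
    grid = grid
  ), class = "visual_system")
}

#' @export
print.visual_system <- function(x, ...) {
  cat(sprintf(
    "<visual_system: receptors %s; densities %s; weber_ref %.3g; weber_double %.3g>\n",
    paste(x$receptor_names, collapse = "/"),
    paste(x$densities, collapse = ":"), x$weber_ref, x$weber_double))
  invisible(x)
}

#' Read a visual system from CSV
#'
#' Expects columns `wl`, `U`, `S`, `M`, `L`, `D` (double cone), `illum`.
#'
#' @param path CSV path.
#' @inheritParams visual_system
#' @return A [visual_system()].
#' @export
read_visual_system <- function(path, densities = c(U = 1, S = 2, M = 2, L = 4),
                               weber_ref = 0.1, weber_double = 0.1) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("wl", "U", "S", "M", "L", "D", "illum")
  if (!all(need %in% names(df)))
    stop("visual system CSV must have columns: ", paste(need, collapse = ", "))
  mk <- function(col) spectrum(df$wl, df[[col]], label = col,
                               check_reflectance = FALSE)
  visual_system(list(U = mk("U"), S = mk("S"), M = mk("M"), L = mk("L")),
                double_cone = mk("D"), illuminant = mk("illum"),
                densities = densities, weber_ref = weber_ref,
                weber_double = weber_double)
}

#' Receptor quantum catches
#'
#' Q_i = integral of R(lambda) S_i(lambda) I(lambda) d lambda over the
#' working grid (trapezoidal quadrature), for the four single cones and the
#' double cone.
#'
#' @param reflectance A [spectrum()]; resampled onto the system grid if
#'   needed.
#' @param vs A [visual_system()].
#' @return An object of class `receptor_catches`: list with `Q` (named
#'   length-4 vector), `Q_D`, `label`.
#' @export
quantum_catches <- function(reflectance, vs) {
  stopifnot(inherits(reflectance, "spectrum"), inherits(vs, "visual_system"))
  r <- resample_to_grid(reflectance, vs$grid)
  illum <- vs$illuminant$values
  Q <- vapply(vs$sensitivities, function(s)
    trapz(vs$grid, r$values * s$values * illum), numeric(1))
  Q_D <- trapz(vs$grid, r$values * vs$double_cone$values * illum)
  if (any(Q <= 0) || Q_D <= 0)
    stop(sprintf("non-positive quantum catch for '%s'", reflectance$label))
  structure(list(Q = Q, Q_D = Q_D, label = reflectance$label),
            class = "receptor_catches")
}

#' Receptor noise (Weber fractions) from relative densities
#'
#' omega_i = weber_ref * sqrt(eta_ref / eta_i), where eta_ref is the largest
#' relative density; noise falls with the square root of receptor abundance.
#'
#' @param vs A [visual_system()].
#' @return An object of class `noise_vector`: list with `omega` (named
#'   length-4 vector) and `omega_D`.
#' @export
receptor_noise <- function(vs) {
  stopifnot(inherits(vs, "visual_system"))
  eta <- vs$densities
  omega <- vs$weber_ref * sqrt(max(eta) / eta)
  if (any(omega <= 0) || any(omega >= 1))
    stop("derived Weber fractions outside (0, 1); check densities/weber_ref")
  structure(list(omega = omega, omega_D = vs$weber_double),
            class = "noise_vector")
}

# log catch contrast vector between two stimuli
.delta_f <- function(a, b) {
  stopifnot(inherits(a, "receptor_catches"), inherits(b, "receptor_catches"))
  if (any(a$Q <= 0) || any(b$Q <= 0)) stop("non-positive quantum catch")
  log(a$Q) - log(b$Q)
}

#' Chromatic contrast in JND units
#'
#' The receptor-noise-limited colour distance for n >= 2 receptors:
#' \deqn{\Delta S^2 = \frac{\sum_{i<j} \big(\prod_{k \ne i,j} \omega_k^2\big)
#'   (\Delta f_i - \Delta f_j)^2}{\sum_{|T| = n-1} \prod_{k \in T}
#'   \omega_k^2}}
#' with \eqn{\Delta f_i = \ln(Q_i^a / Q_i^b)}. For two receptors this reduces
#' to \eqn{|\Delta f_1 - \Delta f_2| / \sqrt{\omega_1^2 + \omega_2^2}}; the
#' package uses the tetrachromatic (n = 4) form, with the lower-dimensional
#' reductions retained for test oracles.
#'
#' @param a,b [quantum_catches()] results (or, for reduced-dimension oracles,
#'   lists with positive `Q` vectors of equal length).
#' @param noise A [receptor_noise()] result, or a list with an `omega` vector
#'   matching the catches.
#' @return Non-negative scalar, JND units.
#' @export
chromatic_contrast <- function(a, b, noise) {
  df <- .delta_f(a, b)
  omega <- noise$omega
  n <- length(df)
  stopifnot(length(omega) == n, n >= 2)
  w2 <- omega^2
  pairs <- utils::combn(n, 2)
  num <- sum(apply(pairs, 2, function(ij) {
    prod(w2[-ij]) * (df[ij[1L]] - df[ij[2L]])^2
  }))
  den <- sum(vapply(seq_len(n), function(i) prod(w2[-i]), numeric(1)))
  sqrt(num / den)
}

#' Achromatic contrast in JND units
#'
#' |ln(Q_D^a / Q_D^b)| / omega_D: the double-cone log catch ratio scaled by
#' the achromatic Weber fraction.
#'
#' @param a,b [quantum_catches()] results.
#' @param omega_D Achromatic Weber fraction (scalar) or a [receptor_noise()]
#'   result.
#' @return Non-negative scalar, JND units.
#' @export
achromatic_contrast <- function(a, b, omega_D) {
  if (inherits(omega_D, "noise_vector")) omega_D <- omega_D$omega_D
  if (a$Q_D <= 0 || b$Q_D <= 0) stop("non-positive double-cone catch")
  abs(log(a$Q_D) - log(b$Q_D)) / omega_D
}

#' Orthonormal chromatic basis for a noise vector
#'
#' In the space y_i = ln(Q_i) / omega_i, a uniform (achromatic) catch scaling
#' moves y along v = (1/omega_1, ..., 1/omega_n). Euclidean distance after
#' projecting v out equals the RNL chromatic contrast, so an orthonormal
#' basis of v's complement yields JND-metric Cartesian coordinates. The basis
#' is computed deterministically (Householder QR seeded with v).
#'
#' @param noise A [receptor_noise()] result.
#' @return n x (n-1) matrix with orthonormal columns spanning the chromatic
#'   subspace.
#' @export
jnd_basis <- function(noise) {
  v <- 1 / noise$omega
  n <- length(v)
  qrd <- qr(cbind(v, diag(n)))
  Q <- qr.Q(qrd)[, 2:n, drop = FALSE]
  # fix signs for determinism: make the largest-magnitude entry positive
  for (j in seq_len(ncol(Q))) {
    k <- which.max(abs(Q[, j]))
    if (Q[k, j] < 0) Q[, j] <- -Q[, j]
  }
  Q
}

#' JND chromaticity coordinates
#'
#' Embeds a stimulus in Cartesian coordinates (3-D for a tetrachromat) such
#' that Euclidean distance between any two embedded stimuli equals their
#' [chromatic_contrast()] and uniform catch scaling (achromatic change) does
#' not move the point.
#'
#' @param catches A [quantum_catches()] result.
#' @param noise A [receptor_noise()] result.
#' @param basis Optional precomputed [jnd_basis()] (saves recomputation in
#'   loops).
#' @return An object of class `chromaticity_point`: list with `coords`
#'   (length n-1) and `label`.
#' @export
jnd_coordinates <- function(catches, noise, basis = NULL) {
  if (any(catches$Q <= 0)) stop("non-positive quantum catch")
  if (is.null(basis)) basis <- jnd_basis(noise)
  y <- log(catches$Q) / noise$omega
  structure(list(coords = drop(crossprod(basis, y)), label = catches$label),
            class = "chromaticity_point")
}

#' @export
print.chromaticity_point <- function(x, ...) {
  cat(sprintf("<chromaticity_point '%s': (%s) JND>\n", x$label,
              paste(sprintf("%.3f", x$coords), collapse = ", ")))
  invisible(x)
}

#' Geometric-mean reference catches for a host population
#'
#' The host's "own colour" reference is the mean of log quantum catches
#' across measured eggs (the geometric mean of catches), which keeps the
#' reference inside the log-catch geometry of the embedding.
#'
#' @param catches_list List of [quantum_catches()] results.
#' @param label Label for the reference stimulus.
#' @return A `receptor_catches` object.
#' @export
host_mean_catches <- function(catches_list, label = "host_mean") {
  stopifnot(length(catches_list) >= 1L)
  Qs <- vapply(catches_list, function(x) x$Q, numeric(4))
  QD <- vapply(catches_list, function(x) x$Q_D, numeric(1))
  structure(list(Q = exp(rowMeans(log(Qs))), Q_D = exp(mean(log(QD))),
                 label = label),
            class = "receptor_catches")
}

#' Project chromaticity points onto experimental colour-gradient axes
#'
#' Builds an orthonormal gradient basis from endpoint stimuli and returns
#' signed JND predictors for each point, relative to an origin (the host
#' population's mean egg colour):
#' * `x_bgbr` — position along the natural blue-green -> brown axis
#'   (positive = browner);
#' * `x_gp` — along the artificial gradient, orthogonalized against the
#'   first axis (positive = greener);
#' * `x_uv` — the remaining orthogonal direction, signed so that increasing
#'   ultraviolet-cone catch increases `x_uv`;
#' * `chromatic_contrast` — Euclidean (= RNL) distance to the origin.
#'
#' @param points List of [jnd_coordinates()] results (or a single one).
#' @param axes_spec Named list of `chromaticity_point`s: `bluegreen_end`,
#'   `brown_end`, `green_end`, `purple_end`, `origin`.
#' @param noise A [receptor_noise()] result (used to locate the direction of
#'   increasing U catch in the embedding).
#' @param uv_receptor Index of the ultraviolet cone in the catch vector
#'   (default 1).
#' @return List with `predictors` (data.frame: label, x_bgbr, x_gp, x_uv,
#'   chromatic_contrast) and `axes` (class `gradient_axes`: origin coords and
#'   3 x 3 orthonormal `basis` with rows bluegreen_brown, green_purple,
#'   uv_axis).
#' @export
gradient_projection <- function(points, axes_spec, noise, uv_receptor = 1L) {
  if (inherits(points, "chromaticity_point")) points <- list(points)
  need <- c("bluegreen_end", "brown_end", "green_end", "purple_end", "origin")
  if (!all(need %in% names(axes_spec)))
    stop("axes_spec must contain: ", paste(need, collapse = ", "))
  cc <- function(p) p$coords
  a1 <- cc(axes_spec$brown_end) - cc(axes_spec$bluegreen_end)
  if (sqrt(sum(a1^2)) < 1e-9) stop("degenerate gradient geometry")
  a1 <- a1 / sqrt(sum(a1^2))
  g <- cc(axes_spec$green_end) - cc(axes_spec$purple_end)  # positive = greener
  a2 <- g - sum(g * a1) * a1
  if (sqrt(sum(a2^2)) < 1e-9)
    stop("degenerate gradient geometry: artificial gradient colinear with natural")
  a2 <- a2 / sqrt(sum(a2^2))
  a3 <- c(a1[2] * a2[3] - a1[3] * a2[2],
          a1[3] * a2[1] - a1[1] * a2[3],
          a1[1] * a2[2] - a1[2] * a2[1])
  # sign a3 so increasing U catch increases x_uv
  basis <- jnd_basis(noise)
  uv_dir <- basis[uv_receptor, ] / noise$omega[uv_receptor]
  if (sum(a3 * uv_dir) < 0) a3 <- -a3
  B <- rbind(bluegreen_brown = a1, green_purple = a2, uv_axis = a3)
  o <- cc(axes_spec$origin)
  pred <- do.call(rbind, lapply(points, function(p) {
    d <- p$coords - o
    data.frame(label = p$label,
               x_bgbr = sum(d * B[1, ]), x_gp = sum(d * B[2, ]),
               x_uv = sum(d * B[3, ]),
               chromatic_contrast = sqrt(sum(d^2)),
               stringsAsFactors = FALSE)
  }))
  rownames(pred) <- NULL
  axes <- structure(list(origin = o, basis = B), class = "gradient_axes")
  list(predictors = pred, axes = axes)
}
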