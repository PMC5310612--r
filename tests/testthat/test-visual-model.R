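# quantum catches, RNL contrasts, JND embedding, gradient projection

test_that("quantum catches: normalization identity, linearity, quadrature", {
  grid <- canonical_grid()
  flat1 <- spectrum(grid, rep(1, length(grid)), "white")
  gauss <- function(peak, sd, norm = TRUE) {
    v <- exp(-((grid - peak) / sd)^2 / 2)
    if (norm) v <- v / sum((v[-1] + v[-length(v)]) / 2)  # unit trapz integral
    spectrum(grid, v, check_reflectance = FALSE)
  }
  vs1 <- visual_system(
    list(U = gauss(370, 30), S = gauss(445, 30), M = gauss(505, 30),
         L = gauss(565, 30)),
    double_cone = gauss(565, 60), illuminant = flat1)
  q <- quantum_catches(flat1, vs1)
  expect_equal(unname(q$Q), rep(1, 4), tolerance = 1e-9)
  expect_equal(q$Q_D, 1, tolerance = 1e-9)

  # doubling the illuminant doubles every catch
  vs2 <- visual_system(
    list(U = gauss(370, 30), S = gauss(445, 30), M = gauss(505, 30),
         L = gauss(565, 30)),
    double_cone = gauss(565, 60),
    illuminant = spectrum(grid, rep(2, length(grid)),
                          check_reflectance = FALSE))
  q2 <- quantum_catches(flat1, vs2)
  expect_equal(q2$Q, 2 * q$Q, tolerance = 1e-12)
  expect_equal(q2$Q_D, 2 * q$Q_D, tolerance = 1e-12)

  # 1-nm trapezoid vs independent 0.1-nm fine-grid quadrature
  ramp <- function(wl) wl / 700
  sens <- function(wl) exp(-((wl - 500) / 30)^2 / 2)
  vs3 <- visual_system(
    list(U = gauss(370, 30, norm = FALSE), S = gauss(445, 30, norm = FALSE),
         M = spectrum(grid, sens(grid), check_reflectance = FALSE),
         L = gauss(565, 30, norm = FALSE)),
    double_cone = gauss(565, 60, norm = FALSE), illuminant = flat1)
  qM <- quantum_catches(spectrum(grid, ramp(grid), "ramp"), vs3)$Q[["M"]]
  fine <- seq(300, 700, by = 0.1)
  f <- ramp(fine) * sens(fine)
  oracle <- sum((f[-1] + f[-length(f)]) / 2) * 0.1
  expect_equal(qM, oracle, tolerance = 1e-6 * oracle)
})

test_that("receptor noise follows the square-root density rule", {
  vs <- fixture_vs()  # densities 1:2:2:4, weber_ref 0.1
  nv <- receptor_noise(vs)
  expect_equal(unname(nv$omega), c(0.2, 0.1 * sqrt(2), 0.1 * sqrt(2), 0.1),
               tolerance = 1e-12)
  # equal densities -> all omega = weber_ref; density scaling irrelevant
  mk <- function(d) {
    v <- vs; v$densities <- d
    receptor_noise(v)$omega
  }
  expect_equal(unname(mk(c(U = 3, S = 3, M = 3, L = 3))), rep(0.1, 4))
  expect_equal(mk(10 * vs$densities), receptor_noise(vs)$omega)
})

test_that("chromatic contrast: identity, symmetry, closed-form reductions", {
  noise4 <- fixture_noise(c(0.2, 0.1414214, 0.1414214, 0.1))
  a <- fixture_catches(c(1.2, 0.9, 1.1, 1.4))
  b <- fixture_catches(c(1.0, 1.0, 1.0, 1.0))
  expect_equal(chromatic_contrast(a, a, noise4), 0)
  expect_equal(chromatic_contrast(a, b, noise4),
               chromatic_contrast(b, a, noise4))
  expect_error(chromatic_contrast(fixture_catches(c(-1, 1, 1, 1)), b, noise4),
               "non-positive")

  # dichromat closed form |df1 - df2| / sqrt(w1^2 + w2^2)
  n2 <- fixture_noise(c(0.1, 0.1))
  expect_equal(
    chromatic_contrast(fixture_catches(c(1.2, 1)), fixture_catches(c(1, 1)),
                       n2),
    abs(log(1.2)) / sqrt(0.02), tolerance = 1e-9)
  expect_equal(
    chromatic_contrast(fixture_catches(c(1.2, 1)), fixture_catches(c(1, 1)),
                       n2),
    1.2892, tolerance = 1e-4)

  # trichromat closed form
  w <- c(0.15, 0.2, 0.1)
  set.seed(11)
  qa <- exp(stats::rnorm(3)); qb <- exp(stats::rnorm(3))
  df <- log(qa) - log(qb)
  num <- w[1]^2 * (df[2] - df[3])^2 + w[2]^2 * (df[1] - df[3])^2 +
    w[3]^2 * (df[1] - df[2])^2
  den <- (w[1] * w[2])^2 + (w[1] * w[3])^2 + (w[2] * w[3])^2
  expect_equal(chromatic_contrast(fixture_catches(qa), fixture_catches(qb),
                                  fixture_noise(w)),
               sqrt(num / den), tolerance = 1e-9)
})

test_that("embedding is an isometry of the RNL metric and drops achromatic shifts", {
  noise <- receptor_noise(fixture_vs())
  basis <- jnd_basis(noise)
  set.seed(7)
  for (i in 1:50) {
    a <- fixture_catches(exp(stats::rnorm(4)))
    b <- fixture_catches(exp(stats::rnorm(4)))
    d_direct <- chromatic_contrast(a, b, noise)
    d_embed <- sqrt(sum((jnd_coordinates(a, noise, basis)$coords -
                           jnd_coordinates(b, noise, basis)$coords)^2))
    expect_equal(d_embed, d_direct, tolerance = 1e-9)
  }
  # uniform catch scaling (achromatic) leaves coordinates unchanged
  a <- fixture_catches(c(0.5, 1.2, 2.0, 3.1))
  ac <- fixture_catches(7.3 * a$Q)
  expect_equal(jnd_coordinates(ac, noise)$coords,
               jnd_coordinates(a, noise)$coords, tolerance = 1e-9)
  # identical stimuli map to identical coordinates
  expect_equal(jnd_coordinates(a, noise)$coords,
               jnd_coordinates(fixture_catches(a$Q), noise)$coords)
})

test_that("triangle inequality and log-ratio invariance hold", {
  noise <- receptor_noise(fixture_vs())
  set.seed(21)
  for (i in 1:25) {
    x <- fixture_catches(exp(stats::rnorm(4)))
    y <- fixture_catches(exp(stats::rnorm(4)))
    z <- fixture_catches(exp(stats::rnorm(4)))
    expect_lte(chromatic_contrast(x, z, noise),
               chromatic_contrast(x, y, noise) +
                 chromatic_contrast(y, z, noise) + 1e-12)
    # identical per-receptor rescaling of both stimuli
    s <- exp(stats::rnorm(4))
    expect_equal(chromatic_contrast(fixture_catches(s * x$Q),
                                    fixture_catches(s * y$Q), noise),
                 chromatic_contrast(x, y, noise), tolerance = 1e-9)
  }
})

test_that("achromatic contrast: ln ratio over omega_D, symmetric, Q_D-only", {
  a <- fixture_catches(c(1, 1, 1, 1), Q_D = exp(1))
  b <- fixture_catches(c(2, 3, 4, 5), Q_D = 1)
  expect_equal(achromatic_contrast(a, b, 0.1), 10, tolerance = 1e-12)
  expect_equal(achromatic_contrast(b, a, 0.1),
               achromatic_contrast(a, b, 0.1))
  expect_equal(achromatic_contrast(a, a, 0.1), 0)
  # chromatic perturbation holding Q_D fixed changes nothing
  b2 <- fixture_catches(c(9, 1, 7, 2), Q_D = 1)
  expect_equal(achromatic_contrast(a, b2, 0.1),
               achromatic_contrast(a, b, 0.1))
  expect_error(achromatic_contrast(fixture_catches(c(1, 1, 1, 1), Q_D = 0),
                                   b, 0.1), "non-positive")
})

test_that("gradient projection yields signed orthonormal predictors", {
  noise <- receptor_noise(fixture_vs())
  pt <- function(coords, label = "p")
    structure(list(coords = coords, label = label),
              class = "chromaticity_point")
  o <- pt(c(0, 0, 0), "origin")
  axes_spec <- list(bluegreen_end = pt(c(-1, 0.2, 0)),
                    brown_end = pt(c(3, 0.2, 0)),
                    green_end = pt(c(0.5, 2, 0.1)),
                    purple_end = pt(c(0.5, -4, 0.1)),
                    origin = o)
  gp <- gradient_projection(list(o), axes_spec, noise)
  expect_equal(unlist(gp$predictors[1, c("x_bgbr", "x_gp", "x_uv",
                                         "chromatic_contrast")]),
               c(x_bgbr = 0, x_gp = 0, x_uv = 0, chromatic_contrast = 0),
               tolerance = 1e-12)
  B <- gp$axes$basis
  expect_equal(B %*% t(B), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  # a point 1 JND along the first axis
  p1 <- pt(o$coords + B[1, ])
  pr <- gradient_projection(list(p1), axes_spec, noise)$predictors
  expect_equal(unlist(pr[1, c("x_bgbr", "x_gp", "x_uv")]),
               c(x_bgbr = 1, x_gp = 0, x_uv = 0), tolerance = 1e-9)
  expect_equal(pr$chromatic_contrast, 1, tolerance = 1e-9)
  # Pythagoras for arbitrary points
  set.seed(5)
  pts <- lapply(1:20, function(i) pt(stats::rnorm(3)))
  pr <- gradient_projection(pts, axes_spec, noise)$predictors
  expect_equal(sqrt(pr$x_bgbr^2 + pr$x_gp^2 + pr$x_uv^2),
               pr$chromatic_contrast, tolerance = 1e-9)
  # degenerate geometry
  bad <- axes_spec
  bad$green_end <- pt(c(2, 0.2, 0)); bad$purple_end <- pt(c(-2, 0.2, 0))
  expect_error(gradient_projection(list(o), bad, noise),
               "degenerate gradient geometry")
})
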