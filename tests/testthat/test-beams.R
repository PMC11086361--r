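k0_085 <- 2 * pi / 0.85

test_that("gaussian aperture field has the defining amplitude and phase", {
  g <- lateral_grid(64, 64, 1, 1)
  UL <- gaussian_aperture(WL = 8, z0 = 252, k = k0_085, grid = g)
  ctr <- c(33, 33)
  expect_equal(UL[ctr[1], ctr[2]], 1 + 0i)
  expect_equal(abs(UL[ctr[1] + 8, ctr[2]]), exp(-1), tolerance = 1e-12)
  # phase at r = 10 um for the reference focused beam: -k * 100 / 504 ~ -1.4667
  ULf <- gaussian_aperture(WL = 35.9, z0 = 252, k = k0_085, grid = g)
  expect_equal(Arg(ULf[ctr[1] + 10, ctr[2]]), -k0_085 * 100 / 504, tolerance = 1e-9)
  expect_equal(Arg(ULf[ctr[1] + 10, ctr[2]]), -1.4667, tolerance = 1e-4)
  expect_error(gaussian_aperture(WL = 1.5, z0 = 252, k = k0_085, grid = g),
               "under-sampled")
})

test_that("gaussian beam parameters reproduce the strong-focus relations", {
  p <- gaussian_params(0.85, 252, WL = 35.88)
  expect_equal(p$W0, 1.90, tolerance = 0.01)
  p2 <- gaussian_params(0.85, 252, WL = 2 * 35.88)
  expect_equal(p2$W0, p$W0 / 2, tolerance = 1e-6)      # W0 ~ 1/WL
  expect_equal(p$W(252), p$W0)                          # W(z0) = W0 exactly
  expect_equal(p$R(0), 252, tolerance = 252 * 0.01)     # R(0) ~ z0 when strongly focused
  # waist-specified weak focus round-trips through the exact width relation
  pw <- gaussian_params(0.85, 252, W0 = 12.6)
  expect_equal(pw$W(0), pw$WL, tolerance = 1e-9)
  expect_equal(pw$WL, 13.71, tolerance = 0.01)
  # strong-focus consistency: pi W0^2/(lambda z0) << 1 => reciprocal waist relation
  expect_lt(abs(p$W0 - 0.85 * 252 / (pi * 35.88)) / p$W0, 0.01)
})

test_that("lorentzian aperture has half-amplitude width a and exponential spectrum decay", {
  g <- lateral_grid(64, 64, 1, 1)
  UL <- lorentzian_aperture(a = 8, z0 = 252, k = k0_085, grid = g)
  expect_equal(abs(UL[33, 33]), 1)
  expect_equal(abs(UL[41, 33]), 0.5, tolerance = 1e-12)
  # collimated case: log-magnitude of the angular spectrum is asymptotically
  # linear in |k_perp| with slope -a (2D transform of a Lorentzian ~ K0(a k))
  gl <- lateral_grid(256, 256, 2)
  a <- 8
  ULc <- matrix(a^2 / (a^2 + outer(gl$x^2, gl$y^2, `+`)), 256, 256) + 0i
  sp <- abs(lateral_spectrum(ULc, gl)[, 129])
  sel <- gl$kx > 0.15 & gl$kx < 0.8
  # the sqrt(k) factor of K0's asymptote is removed before fitting the slope
  fit <- stats::lm(log(sp[sel] * sqrt(gl$kx[sel])) ~ gl$kx[sel])
  expect_equal(unname(stats::coef(fit)[2]), -a, tolerance = 0.05 * a)
})

test_that("bessel aperture produces a depth-invariant central lobe of radius 2.405/beta", {
  g <- lateral_grid(192, 192, 1)
  beta <- 0.6; W_amp <- 40
  UL <- bessel_aperture(W_amp, beta, k0_085, g)
  gs <- lateral_spectrum(UL, g)
  first_zero <- function(z) {
    u <- kspaceoct:::k_to_scan(gs * propagator(k0_085, z, g), g)
    prof <- abs(u[, 97])
    ip <- which.max(prof)
    i <- ip
    while (i < 192 && prof[i + 1] < prof[i]) i <- i + 1
    abs(g$x[i] - g$x[ip])
  }
  radii <- vapply(c(100, 200, 300, 400, 500), first_zero, 0)
  expect_true(all(abs(radii - 2.405 / beta) / (2.405 / beta) < 0.1))
  expect_lt(diff(range(radii)) / mean(radii), 0.1)   # < 10% over the Bessel zone
  # beta = 0 reduces continuously to the collimated Gaussian aperture
  expect_lt(max(abs(bessel_aperture(20, 0, k0_085, g) -
                    exp(-outer(g$x^2, g$y^2, `+`) / 400))), 1e-12)
  expect_error(bessel_aperture(20, k0_085 * 1.1, k0_085, g), "evanescent|cone")
})

test_that("numerical angular spectra match the exact closed-form Gaussian transform", {
  z0 <- 252
  cases <- list(list(WL = 20, n = 192, dx = 0.75),
                list(WL = 35.9, n = 256, dx = 0.75),
                list(WL = 60, n = 448, dx = 0.75))
  for (cs in cases) {
    g <- lateral_grid(cs$n, cs$n, cs$dx)
    UL <- gaussian_aperture(cs$WL, z0, k0_085, g)
    gn <- angular_spectrum_of(UL, g, check_leakage = FALSE)
    a <- 1 / cs$WL^2 + 1i * k0_085 / (2 * z0)
    kp2 <- outer(g$kx^2, g$ky^2, `+`)
    gex <- (pi / a) * exp(-kp2 / (4 * a))
    mask <- kp2 <= k0_085^2
    expect_lt(sqrt(sum(abs(gn[mask] - gex[mask])^2) / sum(abs(gex[mask])^2)), 0.01)
  }
  # the textbook large-Fresnel-number form converges to the exact coefficient
  coef_err <- vapply(c(20, 35.9, 120), function(WL) {
    a <- 1 / WL^2 + 1i * k0_085 / (2 * z0)
    exact <- 1 / (4 * a)
    approx <- z0^2 / (k0_085^2 * WL^2) - 1i * z0 / (2 * k0_085)
    abs(approx - exact) / abs(exact)
  }, 0)
  expect_true(all(diff(coef_err) < 0))
  expect_lt(coef_err[3], 0.01)
})

test_that("angular spectrum flags under-sampled fields and handles a discrete delta", {
  g <- lateral_grid(32, 32, 4)   # coarse grid, strongly chirped field
  expect_error(angular_spectrum_of(gaussian_aperture(60, 100, k0_085, g), g),
               "under-sampled")
  f <- matrix(0i, 32, 32); f[17, 17] <- 1
  sp <- angular_spectrum_of(f, g, check_leakage = FALSE)
  expect_lt(diff(range(abs(sp))), 1e-12)   # flat magnitude
})

test_that("aperture fields satisfy Parseval across beam kinds", {
  g <- lateral_grid(128, 128, 1.5)
  beams <- list(
    gaussian_aperture(25, 252, k0_085, g),
    lorentzian_aperture(10, 252, k0_085, g),
    bessel_aperture(30, 0.4, k0_085, g)
  )
  for (UL in beams) {
    e_sp <- sum(abs(UL)^2) * g$dx * g$dy
    e_k <- sum(abs(lateral_spectrum(UL, g))^2) * g$dkx * g$dky / (2 * pi)^2
    expect_lt(abs(e_sp - e_k) / e_sp, 1e-10)
  }
})

test_that("Zernike polynomials follow the OSA convention and are orthogonal on the disk", {
  g <- lateral_grid(128, 128, 1)
  Ra <- 50
  Z00 <- zernike(0, 0, g, Ra)
  rho <- sqrt(outer(g$x^2, g$y^2, `+`)) / Ra
  expect_true(all(Z00[rho <= 1] == 1))
  expect_true(all(Z00[rho > 1] == 0))
  # coma (3 rho^3 - 2 rho) cos(phi) has unit edge value on the x-axis
  Z31 <- zernike(3, 1, g, Ra)
  ctr <- 65
  expect_equal(Z31[ctr + 50, ctr], 3 - 2, tolerance = 1e-12)
  expect_equal(Z31[ctr + 25, ctr], 3 * 0.125 - 1, tolerance = 1e-12)
  # discrete orthogonality against defocus Z_2^0
  Z20 <- zernike(2, 0, g, Ra)
  ip <- sum(Z31 * Z20) * g$dx * g$dy / (pi * Ra^2)
  norm31 <- sum(Z31^2) * g$dx * g$dy / (pi * Ra^2)
  expect_lt(abs(ip) / norm31, 0.01)
  expect_error(zernike(3, 2, g, Ra), "parity|invalid")
})

test_that("aberration functions are phase-only and multiply the aperture field", {
  g <- lateral_grid(64, 64, 1.5)
  ab <- aberration_function(list(list(n = 3, m = 1, A0 = 60)), Ra = 48)
  Q <- kspaceoct:::aberration_field(ab, g)
  expect_true(all(abs(abs(Q) - 1) < 1e-12))
  UL <- gaussian_aperture(20, 252, k0_085, g)
  ULa <- apply_aberration(UL, ab, g)
  expect_equal(abs(ULa), abs(UL), tolerance = 1e-12)
  expect_equal(apply_aberration(UL, matrix(1 + 0i, 64, 64), g), UL)
  expect_error(apply_aberration(UL, matrix(1 + 0i, 32, 32), g), "match")
})
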