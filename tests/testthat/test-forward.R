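k0_085 <- 2 * pi / 0.85

test_that("propagators are unit-magnitude phase factors with exact inverses", {
  g <- lateral_grid(64, 64, 1)
  for (mode in c("full", "paraxial")) {
    h <- propagator(k0_085, 252, g, mode)
    kp2 <- outer(g$kx^2, g$ky^2, `+`)
    mask <- kp2 <= k0_085^2
    expect_true(all(abs(abs(h[mask]) - 1) < 1e-12))
    expect_true(all(h[!mask] == 0))
    # on-axis component advances by exp(i k dz) in both modes
    expect_equal(h[33, 33], exp(1i * k0_085 * 252), tolerance = 1e-9)
    hb <- propagator(k0_085, -252, g, mode)
    expect_lt(max(abs((h * hb)[mask] - 1)), 1e-12)
  }
  # grazing component (kx^2+ky^2 = k^2) has zero accumulated phase in full mode
  g2 <- lateral_grid(8, 8, pi / k0_085)   # makes kx = k0/4 grid steps
  expect_equal(propagator(k0_085, 100, g2, "full")[1, 5],
               exp(1i * 100 * sqrt(k0_085^2 - g2$kx[1]^2)), tolerance = 1e-9)
  # full-vs-paraxial phase difference at kx = 0.1 k, dz = 252:
  # dz * k * (sqrt(0.99) - 0.995) ~ -0.0233 rad
  dphi <- 252 * k0_085 * (sqrt(0.99) - 0.995)
  expect_equal(dphi, -0.0234, tolerance = 1e-2)
})

test_that("incident field peaks on axis at focus and is shift-covariant", {
  g <- lateral_grid(64, 64, 1.5)
  UL <- gaussian_aperture(20, 150, k0_085, g)
  gs <- lateral_spectrum(UL, g)
  Us0 <- incident_field(gs, k0_085, list(xs = 0, ys = 0, zs = 150), g)
  pk <- which(abs(Us0) == max(abs(Us0)), arr.ind = TRUE)[1, ]
  expect_equal(unname(pk), c(33, 33))   # maximal when the beam axis hits the scatterer
  # shifting the scatterer by a grid vector circularly shifts the scan map
  Us1 <- incident_field(gs, k0_085, list(xs = 6, ys = -3, zs = 150), g)
  ix <- ((seq_len(64) - 1 - 4) %% 64) + 1   # 6 um = 4 samples along x
  iy <- ((seq_len(64) - 1 + 2) %% 64) + 1   # -3 um = -2 samples along y
  expect_lt(max(abs(Us1 - Us0[ix, iy])) / max(abs(Us0)), 1e-10)
  expect_error(incident_field(gs, k0_085, list(xs = 100, ys = 0, zs = 150), g),
               "window")
})

test_that("incident field matches direct plane-wave double summation on a 16x16 grid", {
  g <- lateral_grid(16, 16, 2)
  set.seed(5)
  gs <- rand_cplx(16)
  kp2 <- outer(g$kx^2, g$ky^2, `+`)
  gs[kp2 > k0_085^2] <- 0
  sct <- list(xs = 3, ys = -5, zs = 80)
  Us <- incident_field(gs, k0_085, sct, g)
  h <- propagator(k0_085, 80, g, "full")
  direct <- matrix(0i, 16, 16)
  for (i in 1:16) for (j in 1:16) {
    ph <- outer(g$kx * (sct$xs - g$x[i]), g$ky * (sct$ys - g$y[j]), `+`)
    direct[i, j] <- sum(gs * h * exp(1i * ph)) * g$dkx * g$dky
  }
  expect_lt(max(abs(Us - direct)) / max(abs(direct)), 1e-10)
})

test_that("received amplitude is Ks times the squared incident field", {
  Us <- rand_cplx(8)
  expect_true(all(received_amplitude(Us, 0) == 0))
  Bs <- received_amplitude(Us, 2i)
  expect_equal(Arg(Bs[1, 1]),
               ((2 * Arg(Us[1, 1]) + pi / 2 + pi) %% (2 * pi)) - pi,
               tolerance = 1e-12)
  # squaring a Gaussian field narrows its 1/e width by sqrt(2)
  x <- seq(-20, 20, by = 0.5)
  w <- 4
  prof2 <- abs(exp(-x^2 / w^2)^2)
  expect_equal(x[which.min(abs(prof2 - exp(-1)))[1]], -w / sqrt(2), tolerance = 0.3)
})

test_that("volumes localize scatterers axially and sum linearly", {
  cfg <- config_focused_chain(n_x = 64, dx = 1.5)
  sc <- chain_scene(1, 200, 200)
  v <- simulate_volume(sc, cfg)
  ax <- apply(abs(v$A), 3, max)
  expect_lt(abs(v$depth$z[which.max(ax)] - 200), v$depth$dz)
  # linearity across disjoint scenes
  sa <- chain_scene(1, 100, 100)
  sb <- chain_scene(1, 300, 300, x = 10.5)
  expect_lt(volume_linearity_check(sa, sb, cfg), 1e-10)
  expect_equal(volume_linearity_check(sa, sa[0, ], cfg), 0)
  # scaling all Ks scales the volume exactly
  s3 <- sa; s3$Ks <- 3 + 0i
  v1 <- simulate_volume(sa, cfg)
  v3 <- simulate_volume(s3, cfg)
  expect_lt(max(abs(v3$A - 3 * v1$A)) / max(abs(v3$A)), 1e-12)
})

test_that("axial amplitude width follows the double-pass Fourier pair", {
  cfg <- config_focused_chain(n_x = 64, dx = 1.5, n_k = 64, pad_factor = 4L, dz = 1)
  v <- simulate_volume(chain_scene(1, 128, 128), cfg)
  ax <- apply(abs(v$A), 3, max)
  z <- v$depth$z
  keep <- which(ax > 0.2 * max(ax))
  fit <- stats::lm(log(ax[keep]) ~ I((z[keep] - 128)^2))
  sig_z <- sqrt(-1 / (2 * unname(stats::coef(fit)[2])))  # |A| ~ exp(-dz^2/(2 sig_z^2))
  sig_k <- cfg$spectrum$fractional_bandwidth * cfg$spectrum$k0 / 6
  fwhm <- 2 * sqrt(2 * log(2)) * sig_z
  expect_equal(fwhm, 2 * sqrt(2 * log(2)) / (2 * sig_k), tolerance = 0.05)
})

test_that("out-of-focus image width follows the Gaussian beam width over 3 Rayleigh ranges", {
  # weakly focused waist-specified beam: W0 = 6 um, zR ~ 133 um
  g <- lateral_grid(96, 96, 1.5)
  spec <- kspaceoct:::chain_spectrum(0.85, 16, 4L, 8)
  beam <- beam_spec("gaussian", W0 = 6, z0 = 256, lambda0_um = 0.85)
  cfg <- sim_config(g, spec, beam, propagator_mode = "paraxial", pad_factor = 4L)
  p <- gaussian_params(0.85, 256, W0 = 6)
  for (zs in c(64, 256, 448)) {
    v <- simulate_volume(chain_scene(1, zs, zs), cfg)
    expect_equal(sqrt(2) * lateral_width(v, zs), p$W(zs),
                 tolerance = 0.05 * p$W(zs))
  }
})

test_that("full and paraxial propagators agree at low NA and diverge as NA grows", {
  g <- lateral_grid(96, 96, 1.5)
  spec <- kspaceoct:::chain_spectrum(0.85, 8, 2L, 16)
  sc <- chain_scene(1, 160, 160)
  sim <- function(W0, mode) {
    beam <- beam_spec("gaussian", W0 = W0, z0 = 160, lambda0_um = 0.85)
    simulate_volume(sc, sim_config(g, spec, beam, propagator_mode = mode,
                                   pad_factor = 2L))
  }
  low <- rel_rms(sim(6, "full")$A, sim(6, "paraxial")$A)    # NA ~ 0.045
  high <- rel_rms(sim(2.2, "full")$A, sim(2.2, "paraxial")$A) # NA ~ 0.12
  expect_lt(low, 0.01)
  expect_gt(high, low)
})

test_that("scan-domain spectra factorize the lateral scatterer position", {
  # scan spacing well below the focal radius so the double-pass spectrum
  # stays inside the K-window (the Nyquist condition of the scan geometry)
  g <- lateral_grid(96, 96, 0.5)
  spec <- source_spectrum(0.85, 0, 1)
  beam <- beam_spec("gaussian", WL = 15, z0 = 150, lambda0_um = 0.85)
  cfg <- sim_config(g, spec, beam, depth = depth_axis(150))
  on_axis <- consistency_check_factorization(list(xs = 0, ys = 0, zs = 150, Ks = 1 + 0i), cfg)
  expect_lt(on_axis, 1e-10)
  off <- consistency_check_factorization(list(xs = 10, ys = 0, zs = 150, Ks = 1 + 0i), cfg)
  expect_lt(off, 1e-8)
  off_scaled <- consistency_check_factorization(list(xs = 10, ys = 0, zs = 150, Ks = 5 - 2i), cfg)
  expect_equal(off, off_scaled, tolerance = 1e-9)
})
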