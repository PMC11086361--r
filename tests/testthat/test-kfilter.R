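k0_085 <- 2 * pi / 0.85

test_that("numeric depth kernels match direct autoconvolution quadrature on 16x16", {
  g <- lateral_grid(16, 16, 1)
  beam <- beam_spec("custom", field = function(grid, k) {
    set.seed(3)
    rand_cplx(grid$n_x)
  })
  ks <- depth_kernel(beam, g, k0_085, depths = 50)
  # direct circular autoconvolution of f = g * h over the K-grid
  f <- lateral_spectrum(beam$field(g, k0_085), g) * propagator(k0_085, 50, g)
  n <- 16
  I_direct <- matrix(0i, n, n)
  for (a in 1:n) for (b in 1:n) {
    acc <- 0i
    for (p in 1:n) for (q in 1:n) {
      # index of -k_ab - k_pq on the wrapped centered grid
      r <- ((n / 2 + 1 - 1) - (a - n / 2 - 1) - (p - n / 2 - 1)) %% n + 1
      s <- ((n / 2 + 1 - 1) - (b - n / 2 - 1) - (q - n / 2 - 1)) %% n + 1
      acc <- acc + f[p, q] * f[r, s]
    }
    I_direct[a, b] <- acc * g$dkx * g$dky * (2 * pi)^2
  }
  expect_lt(max(abs(ks$I[, , 1] - I_direct)) / max(abs(I_direct)), 1e-10)
})

test_that("numeric Gaussian kernels match the analytic paraxial autoconvolution", {
  g <- lateral_grid(256, 256, 0.75)
  WL <- 35.9; z0 <- 252
  beam <- beam_spec("gaussian", WL = WL, z0 = z0, lambda0_um = 0.85)
  depths <- c(100, 252, 400)
  num <- depth_kernel(beam, g, k0_085, depths, mode = "paraxial")
  kp2 <- outer(g$kx^2, g$ky^2, `+`)
  a_cplx <- 1 / WL^2 + 1i * k0_085 / (2 * z0)   # exact Gaussian transform pair
  rel <- function(a, b, m) {
    cc <- sum(Conj(b[m]) * a[m]) / sum(abs(b[m])^2)
    sqrt(sum(abs(a[m] - cc * b[m])^2) / sum(abs(cc * b[m])^2))
  }
  cf <- gaussian_kernel_stack(beam$W0, z0, k0_085, g, depths)
  for (q in seq_along(depths)) {
    # exact: autoconvolution halves the exponent of g * h
    exact <- exp(-kp2 * (1 / (8 * a_cplx) + 1i * depths[q] / (4 * k0_085)))
    m <- abs(exact) > 1e-3
    # discrete autoconvolution reproduces the analytic result essentially exactly
    expect_lt(rel(num$I[, , q], exact, m), 1e-3)
    # the waist-form closed kernel is the strong-focus approximation of it:
    # at the reference Fresnel number the shapes agree to ~3%
    expect_lt(rel(cf$I[, , q], exact, m), 0.03)
  }
  # at the focus depth the closed-form kernel is purely real (no defocus phase)
  expect_lt(max(abs(Im(cf$I[, , 2]))), 1e-12)
})

test_that("the kernel-ratio filter obeys its contract and degenerates correctly", {
  g <- lateral_grid(32, 32, 1)
  ki <- gaussian_kernel_stack(2, 100, k0_085, g, c(50, 150))
  # identity: target = initial, alpha = 0
  f_id <- filter_function(ki, ki, alpha = 0)
  expect_lt(max(abs(f_id$F - 1)), 1e-12)
  # division-by-zero guard for alpha = 0 with zeros on the target support
  k0s <- ki; k0s$I[1, 1, 1] <- 0
  expect_error(filter_function(k0s, ki, alpha = 0), "alpha = 0")
  expect_error(filter_function(ki, gaussian_kernel_stack(2, 100, k0_085, g, 50)),
               "depths")
})

test_that("waist-conserving filters reduce to the pure one-step phase kernel", {
  g <- lateral_grid(64, 64, 1)
  W0 <- 1.9; z0 <- 252
  depths <- c(100, 300)
  ki <- gaussian_kernel_stack(W0, z0, k0_085, g, depths)
  kt <- gaussian_kernel_stack(W0, function(z) z, k0_085, g, depths)
  filt <- filter_function(ki, kt, alpha = 0)
  kp2 <- outer(g$kx^2, g$ky^2, `+`)
  for (q in 1:2) {
    phase_only <- exp(-1i * (z0 - depths[q]) * kp2 / (4 * k0_085))
    expect_lt(max(abs(filt$F[, , q] - phase_only)), 1e-10)
  }
})

test_that("narrowband filtering is identity for unit filters and energy-preserving for phase filters", {
  cfg <- config_focused_chain(n_x = 64, dx = 1.5)
  v <- simulate_volume(chain_scene(3, 100, 400), cfg)
  g <- v$grid
  unit <- structure(list(F = array(1 + 0i, dim(v$A)), k = cfg$spectrum$k0,
                         depths = v$depth$z, grid = g, alpha = 0,
                         init = "unit", target = "unit"),
                    class = "filter_stack")
  expect_lt(max(abs(apply_filter_narrowband(v, unit)$A - v$A)) / max(abs(v$A)), 1e-12)
  vr <- refocus_one_step(v)   # pure-phase spectral kernel
  for (q in seq_along(v$depth$z)) {
    e0 <- sum(abs(v$A[, , q])^2)
    e1 <- sum(abs(vr$A[, , q])^2)
    if (e0 > 0) expect_lt(abs(e1 - e0) / e0, 1e-10)
  }
  # provenance is appended by every applied transform
  expect_length(vr$provenance, length(v$provenance) + 1)
})

test_that("full per-wavenumber filtering agrees with the narrowband path at a few percent bandwidth", {
  cfg <- config_focused_chain(n_x = 96, dx = 1)
  v <- simulate_volume(chain_scene(3, 100, 400), cfg)
  b <- cfg$beam
  filt_at <- function(k) {
    ki <- gaussian_kernel_stack(b$W0, b$z0, k, v$grid, v$depth$z)
    kt <- gaussian_kernel_stack(b$W0, function(z) z, k, v$grid, v$depth$z)
    filter_function(ki, kt, alpha = 0)
  }
  v13 <- apply_filter_full(v, filt_at)
  v14 <- apply_filter_narrowband(v, filt_at(cfg$spectrum$k0))
  expect_lt(rel_rms(v13$A, v14$A), 0.01)
})

test_that("monochromatic volumes take the same route through both filter paths", {
  g <- lateral_grid(48, 48, 1)
  spec <- source_spectrum(0.85, 0, 1)
  beam <- beam_spec("gaussian", WL = 12, z0 = 120, lambda0_um = 0.85)
  cfg <- sim_config(g, spec, beam, depth = depth_axis(120))
  v <- simulate_volume(chain_scene(1, 120, 120), cfg)
  filt_at <- function(k) {
    ki <- gaussian_kernel_stack(beam$W0, beam$z0, k, g, 120)
    kt <- gaussian_kernel_stack(beam$W0, function(z) z, k, g, 120)
    filter_function(ki, kt, alpha = 0)
  }
  expect_equal(apply_filter_full(v, filt_at)$A,
               apply_filter_narrowband(v, filt_at(spec$k0))$A,
               tolerance = 1e-12)
})

test_that("refocusing filters compose to the identity on the kernel support", {
  cfg <- config_focused_chain(n_x = 64, dx = 1.5)
  v <- simulate_volume(chain_scene(3, 100, 400), cfg)
  b <- cfg$beam
  k0 <- cfg$spectrum$k0
  ki <- gaussian_kernel_stack(b$W0, b$z0, k0, v$grid, v$depth$z)
  kt <- gaussian_kernel_stack(b$W0, function(z) z, k0, v$grid, v$depth$z)
  there <- filter_function(ki, kt, alpha = 0)
  back <- filter_function(kt, ki, alpha = 0)
  v2 <- apply_filter_narrowband(apply_filter_narrowband(v, there), back)
  expect_lt(max(abs(v2$A - v$A)) / max(abs(v$A)), 1e-6)
})

test_that("filtering acts identically on scatterers regardless of lateral position", {
  g <- lateral_grid(96, 96, 1)
  spec <- source_spectrum(0.85, 0, 1)
  beam <- beam_spec("gaussian", WL = 15, z0 = 150, lambda0_um = 0.85)
  cfg <- sim_config(g, spec, beam, depth = depth_axis(200))
  ki <- depth_kernel(beam, g, spec$k0, 200)
  kt <- gaussian_kernel_stack(beam$W0, function(z) z, spec$k0, g, 200)
  kt$I <- kt$I * max(abs(ki$I))   # match the numeric kernel scale
  filt <- filter_function(ki, kt, alpha = 1e-6)
  win <- function(cx, cy) {
    v <- simulate_volume(scene_at(xs = cx, ys = cy, zs = 200), cfg)
    vf <- apply_filter_narrowband(v, filt)
    i <- which.min(abs(g$x - cx)); j <- which.min(abs(g$y - cy))
    patch <- vf$A[(i - 8):(i + 8), (j - 8):(j + 8), 1]
    patch / patch[9, 9]
  }
  expect_lt(max(abs(win(0, 0) - win(15, -10))), 1e-6)
})
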