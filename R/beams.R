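#' Parametric description of an illuminating/receiving beam
#'
#' A `beam_spec` resolves deterministically to one complex aperture field
#' `UL(x, y; k)` per (grid, wavenumber). Supported kinds:
#'
#' * `"gaussian"` - amplitude `exp(-r^2/WL^2)` with spherical phase
#'   `-k r^2 / (2 R)`. Given the aperture radius `WL` and focus depth `z0`
#'   the curvature is the strong-focus `R = z0`; given the focal waist `W0`
#'   and `z0`, `WL` and the exact aperture curvature `R(0, z0)` are derived
#'   from the Gaussian-beam relations, which also covers weak focusing.
#' * `"lorentzian"` - amplitude `a^2/(a^2 + r^2)` (half-amplitude at `r = a`)
#'   with the same spherical phase; its angular spectrum decays
#'   `~ exp(-|k_perp| a)`, much slower than a Gaussian's.
#' * `"bessel"` - Gaussian amplitude `exp(-r^2/W_amp^2)` with the conical
#'   (axicon) phase `-beta r`, producing a non-diverging Bessel zone with
#'   central-lobe radius `2.405/beta`.
#' * `"custom"` - a user function `f(grid, k)` returning the complex field.
#'
#' An optional aberration function `Q(x, y)` (see [aberration_function()])
#' multiplies the aperture field.
#'
#' @param kind one of `"gaussian"`, `"lorentzian"`, `"bessel"`, `"custom"`
#' @param WL Gaussian 1/e amplitude radius at the aperture (um)
#' @param W0 Gaussian focal-waist 1/e radius (um); alternative to `WL`
#' @param z0 focus depth (um) for gaussian/lorentzian kinds
#' @param a Lorentzian half-width (um)
#' @param W_amp Bessel Gaussian amplitude radius at the aperture (um)
#' @param beta axicon radial phase slope (rad/um)
#' @param field function(grid, k) for `kind = "custom"`
#' @param lambda0_um reference wavelength used to resolve `WL <-> W0` (um)
#' @param aberration an [aberration_function()] or NULL
#' @return object of class `beam_spec`
#' @export
beam_spec <- function(kind = c("gaussian", "lorentzian", "bessel", "custom"),
                      WL = NULL, W0 = NULL, z0 = NULL, a = NULL,
                      W_amp = NULL, beta = NULL, field = NULL,
                      lambda0_um = 0.85, aberration = NULL) {
  kind <- match.arg(kind)
  b <- list(kind = kind, WL = WL, W0 = W0, z0 = z0, a = a, W_amp = W_amp,
            beta = beta, field = field, lambda0_um = lambda0_um,
            aberration = aberration)
  if (kind == "gaussian") {
    if (is.null(z0) || z0 <= 0) stop("gaussian beam needs a focus depth z0 > 0")
    if (is.null(WL) && is.null(W0)) stop("give either WL or W0")
    p <- gaussian_params(lambda0_um, z0, WL = WL, W0 = W0)
    b$WL <- p$WL; b$W0 <- p$W0
    b$R0 <- if (is.null(WL)) p$R(0) else z0  # aperture curvature radius
    b$params <- p
  } else if (kind == "lorentzian") {
    if (is.null(a) || a <= 0 || is.null(z0) || z0 <= 0)
      stop("lorentzian beam needs a > 0 and z0 > 0")
  } else if (kind == "bessel") {
    if (is.null(W_amp) || W_amp <= 0 || is.null(beta) || beta < 0)
      stop("bessel beam needs W_amp > 0 and beta >= 0")
  } else if (is.null(field) || !is.function(field)) {
    stop("custom beam needs a field function(grid, k)")
  }
  class(b) <- "beam_spec"
  b
}

format_beam <- function(b) {
  switch(b$kind,
    gaussian = sprintf("gaussian (WL = %.3g um, W0 = %.3g um, z0 = %g um%s)",
                       b$WL, b$W0, b$z0,
                       if (is.null(b$aberration)) "" else ", aberrated"),
    lorentzian = sprintf("lorentzian (a = %g um, z0 = %g um)", b$a, b$z0),
    bessel = sprintf("bessel (W_amp = %g um, beta = %g rad/um)", b$W_amp, b$beta),
    "custom"
  )
}

#' @export
print.beam_spec <- function(x, ...) {
  cat("<beam_spec>", format_beam(x), "\n")
  invisible(x)
}

#' Gaussian-beam parameters
#'
#' Derived quantities of a Gaussian beam focused at depth `z0`: focal-waist
#' radius `W0`, aperture radius `WL = W(0, z0)`, and the width, wavefront
#' curvature and Gouy-phase functions
#' `W(z) = W0 sqrt(1 + ((lambda (z - z0))/(pi W0^2))^2)`,
#' `R(z) = (z0 - z) (1 + (pi W0^2 / (lambda (z0 - z)))^2)`,
#' `Phi(z) = atan(lambda (z - z0) / (pi W0^2))`.
#'
#' Given `WL`, the waist follows from the strong-focus relation
#' `W0 = lambda z0 / (pi WL)` when `lambda z0 / (pi WL^2) < 0.1`, and from the
#' exact inversion of the width relation otherwise.
#'
#' @param lambda wavelength (um)
#' @param z0 focus depth (um)
#' @param WL aperture 1/e radius (um); give this or `W0`
#' @param W0 focal-waist 1/e radius (um)
#' @return list with `W0`, `WL`, `z0`, `lambda`, Rayleigh range `zR`, and
#'   functions `W(z)`, `R(z)`, `Phi(z)`
#' @examples
#' gaussian_params(0.85, 252, WL = 35.88)$W0  # ~1.9
#' @export
gaussian_params <- function(lambda, z0, WL = NULL, W0 = NULL) {
  stopifnot(lambda > 0, z0 > 0)
  if (is.null(W0)) {
    if (is.null(WL) || WL <= 0) stop("give WL or W0")
    sf <- lambda * z0 / (pi * WL^2)  # strong-focus parameter (small => tight)
    if (sf < 0.1) {
      W0 <- lambda * z0 / (pi * WL)
    } else {
      # WL^2 = W0^2 + (lambda z0 / (pi W0))^2, quadratic in W0^2
      disc <- WL^4 - 4 * (lambda * z0 / pi)^2
      if (disc < 0)
        stop("aperture radius WL too small to place a waist at depth z0")
      W0 <- sqrt((WL^2 - sqrt(disc)) / 2)
    }
  } else {
    if (W0 <= 0) stop("W0 must be positive")
    WL <- W0 * sqrt(1 + (lambda * z0 / (pi * W0^2))^2)
  }
  zR <- pi * W0^2 / lambda
  list(
    W0 = W0, WL = WL, z0 = z0, lambda = lambda, zR = zR,
    W = function(z) W0 * sqrt(1 + ((lambda * (z - z0)) / (pi * W0^2))^2),
    R = function(z) (z0 - z) * (1 + (pi * W0^2 / (lambda * (z0 - z)))^2),
    Phi = function(z) atan(lambda * (z - z0) / (pi * W0^2))
  )
}

## radial coordinate matrix on a grid
grid_r2 <- function(grid) outer(grid$x^2, grid$y^2, `+`)

#' Gaussian aperture field
#'
#' `UL = exp(-r^2/WL^2) exp(-i k r^2 / (2 R))` with `R = z0` (strong-focus
#' curvature) by default; the dimensionless pre-factor is fixed to 1.
#'
#' @param WL 1/e amplitude radius (um)
#' @param z0 focus depth (um)
#' @param k wavenumber (rad/um)
#' @param grid a [lateral_grid()]
#' @param R aperture wavefront-curvature radius (um), default `z0`
#' @return complex matrix on `grid`
#' @export
gaussian_aperture <- function(WL, z0, k, grid, R = z0) {
  if (WL <= 0 || z0 <= 0) stop("WL and z0 must be positive")
  if (WL < 2 * max(grid$dx, grid$dy))
    stop("aperture radius WL under-sampled: need WL >= 2 grid spacings")
  r2 <- grid_r2(grid)
  exp(-r2 / WL^2) * exp(-1i * k * r2 / (2 * R))
}

#' Lorentzian aperture field
#'
#' Amplitude `a^2/(a^2 + r^2)` with spherical phase `-k r^2/(2 z0)`.
#' @inheritParams gaussian_aperture
#' @param a half-width (um): amplitude falls to 1/2 at `r = a`
#' @return complex matrix on `grid`
#' @export
lorentzian_aperture <- function(a, z0, k, grid) {
  if (a <= 0 || z0 <= 0) stop("a and z0 must be positive")
  if (a < 2 * max(grid$dx, grid$dy))
    stop("half-width a under-sampled: need a >= 2 grid spacings")
  r2 <- grid_r2(grid)
  (a^2 / (a^2 + r2)) * exp(-1i * k * r2 / (2 * z0))
}

#' Bessel (axicon) aperture field
#'
#' Gaussian amplitude with conical phase: `exp(-r^2/W_amp^2) exp(-i beta r)`.
#' @inheritParams gaussian_aperture
#' @param W_amp Gaussian amplitude radius (um)
#' @param beta axicon radial phase slope (rad/um), `0 <= beta < k`
#' @return complex matrix on `grid`
#' @export
bessel_aperture <- function(W_amp, beta, k, grid) {
  if (W_amp <= 0) stop("W_amp must be positive")
  if (beta < 0) stop("beta must be non-negative")
  if (beta >= k) stop("axicon slope beta >= k puts the cone outside the propagating domain")
  r2 <- grid_r2(grid)
  exp(-r2 / W_amp^2) * exp(-1i * beta * sqrt(r2))
}

#' Resolve a beam spec to its aperture field
#'
#' @param beam a [beam_spec()]
#' @param grid a [lateral_grid()]
#' @param k wavenumber (rad/um)
#' @param with_aberration multiply by the beam's aberration function `Q`
#' @return complex matrix `UL(x, y; k)`
#' @export
aperture_field <- function(beam, grid, k, with_aberration = TRUE) {
  UL <- switch(beam$kind,
    gaussian = gaussian_aperture(beam$WL, beam$z0, k, grid, R = beam$R0 %||% beam$z0),
    lorentzian = lorentzian_aperture(beam$a, beam$z0, k, grid),
    bessel = bessel_aperture(beam$W_amp, beam$beta, k, grid),
    custom = beam$field(grid, k)
  )
  if (with_aberration && !is.null(beam$aberration))
    UL <- UL * aberration_field(beam$aberration, grid)
  UL
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Angular spectrum of an aperture field
#'
#' `g(kx, ky, k)` via the analysis transform of [lateral_spectrum()]. A
#' beam-axis offset `(x0, y0)` would enter only as the linear phase
#' `exp(-i x0 kx - i y0 ky)`, so the spectrum is computed once for the
#' centered beam.
#'
#' @param field complex aperture field on `grid`
#' @param grid a [lateral_grid()]
#' @param check_leakage error if the spectrum has not decayed below
#'   `leak_tol` of its peak at the K-grid edge (under-sampled field)
#' @param leak_tol relative edge-decay threshold
#' @return complex matrix on the K-grid
#' @export
angular_spectrum_of <- function(field, grid, check_leakage = TRUE,
                                leak_tol = 1e-6) {
  g <- lateral_spectrum(field, grid)
  if (check_leakage) {
    edge <- max(abs(g[1, ]), abs(g[grid$n_x, ]), abs(g[, 1]), abs(g[, grid$n_y]))
    if (edge > leak_tol * max(abs(g)))
      stop(sprintf(
        "angular spectrum leaks at the K-grid edge (%.2g of peak > %.2g): field under-sampled",
        edge / max(abs(g)), leak_tol))
  }
  g
}

#' Zernike polynomial on a grid
#'
#' Un-normalized OSA/ANSI double-index Zernike polynomial
#' `Z_n^m(rho, phi)` evaluated on `rho = r/Ra`, zero outside the unit disk.
#' For `m >= 0` the azimuthal factor is `cos(m phi)`, for `m < 0` it is
#' `sin(|m| phi)`; the radial polynomial has unit edge value.
#'
#' @param n radial degree (`n >= |m|`, `n - |m|` even)
#' @param m azimuthal order
#' @param grid a [lateral_grid()]
#' @param Ra normalization radius (um)
#' @return real matrix on `grid`
#' @examples
#' # primary coma Z_3^1 = (3 rho^3 - 2 rho) cos(phi)
#' @export
zernike <- function(n, m, grid, Ra) {
  if (Ra <= 0) stop("Ra must be positive")
  am <- abs(m)
  if (n < am || (n - am) %% 2 != 0)
    stop("invalid Zernike indices: need n >= |m| and n - |m| even")
  x <- matrix(grid$x, grid$n_x, grid$n_y)
  y <- matrix(grid$y, grid$n_x, grid$n_y, byrow = TRUE)
  rho <- sqrt(x^2 + y^2) / Ra
  phi <- atan2(y, x)
  R <- matrix(0, grid$n_x, grid$n_y)
  for (s in 0:((n - am) / 2)) {
    R <- R + (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + am) / 2 - s) * factorial((n - am) / 2 - s)) *
      rho^(n - 2 * s)
  }
  az <- if (m >= 0) cos(m * phi) else sin(am * phi)
  out <- R * az
  out[rho > 1] <- 0
  out
}

#' Aberration function at the aperture
#'
#' Parametric phase aberration `Q(x, y) = exp(-i sum_j A0_j Z_{n_j}^{m_j}(rho, phi))`
#' on a disk of radius `Ra`; `|Q| = 1` everywhere (phase-only). The distorted
#' aperture field is `UL = UL_target * Q`.
#'
#' @param terms list of `list(n =, m =, A0 = )` with amplitudes `A0` in radians
#' @param Ra aperture normalization radius (um)
#' @return object of class `aberration_function`
#' @export
aberration_function <- function(terms, Ra) {
  stopifnot(is.list(terms), length(terms) >= 1, Ra > 0)
  for (t in terms) stopifnot(!is.null(t$n), !is.null(t$m), !is.null(t$A0))
  structure(list(terms = terms, Ra = Ra), class = "aberration_function")
}

## complex Q(x, y) on a grid
aberration_field <- function(ab, grid) {
  phase <- matrix(0, grid$n_x, grid$n_y)
  for (t in ab$terms) phase <- phase + t$A0 * zernike(t$n, t$m, grid, ab$Ra)
  exp(-1i * phase)
}

#' Apply an aberration function to an aperture field
#'
#' Pointwise product `UL * Q`; for phase-only `Q` the amplitude is unchanged.
#' @param field complex aperture field on `grid`
#' @param Q an [aberration_function()] or a complex matrix of matching size
#' @param grid a [lateral_grid()]
#' @return complex matrix
#' @export
apply_aberration <- function(field, Q, grid) {
  Qm <- if (inherits(Q, "aberration_function")) aberration_field(Q, grid) else Q
  if (!all(dim(Qm) == dim(field))) stop("aberration grid does not match the field")
  field * Qm
}

## strip the aberration from a beam spec (the aberration-free target)
beam_without_aberration <- function(beam) {
  beam$aberration <- NULL
  beam
}
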