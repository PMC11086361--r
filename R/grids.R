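#' Centered lateral sampling grid with its conjugate K-grid
#'
#' Defines the equidistant lateral sampling used both for aperture fields
#' (coordinates `x`, `y`) and for beam-scan positions (`x0`, `y0`), together
#' with the conjugate angular-frequency grid (`kx`, `ky`). The beam axis sits
#' at the grid center (`x = y = 0`); K-grid spacings are `2*pi/(n*d)` so that
#' the spatial and spectral representations form an exact discrete transform
#' pair.
#'
#' @param n_x,n_y number of samples in x and y (even, >= 8)
#' @param dx,dy sample spacing in micrometers (> 0)
#' @return an object of class `lateral_grid` with fields `n_x`, `n_y`, `dx`,
#'   `dy`, centered axes `x`, `y`, conjugate axes `kx`, `ky` (rad/um) and
#'   spacings `dkx`, `dky`.
#' @examples
#' g <- lateral_grid(64, 64, 1.5, 1.5)
#' g$dkx  # 2*pi/96
#' @export
lateral_grid <- function(n_x, n_y = n_x, dx = 1, dy = dx) {
  if (dx <= 0 || dy <= 0) stop("grid spacings must be positive")
  if (n_x < 8 || n_y < 8) stop("grid counts must be >= 8")
  if (n_x %% 2 != 0 || n_y %% 2 != 0) stop("grid counts must be even")
  g <- list(
    n_x = as.integer(n_x), n_y = as.integer(n_y), dx = dx, dy = dy,
    x = (seq_len(n_x) - 1 - n_x / 2) * dx,
    y = (seq_len(n_y) - 1 - n_y / 2) * dy,
    kx = (seq_len(n_x) - 1 - n_x / 2) * (2 * pi / (n_x * dx)),
    ky = (seq_len(n_y) - 1 - n_y / 2) * (2 * pi / (n_y * dy)),
    dkx = 2 * pi / (n_x * dx), dky = 2 * pi / (n_y * dy)
  )
  class(g) <- "lateral_grid"
  g
}

#' @export
print.lateral_grid <- function(x, ...) {
  cat(sprintf(
    "<lateral_grid> %d x %d, dx = %g um, dy = %g um, window %g x %g um\n",
    x$n_x, x$n_y, x$dx, x$dy, x$n_x * x$dx, x$n_y * x$dy
  ))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  a$n_x == b$n_x && a$n_y == b$n_y &&
    abs(a$dx - b$dx) < tol && abs(a$dy - b$dy) < tol
}

## --- centered discrete Fourier transforms -----------------------------------
##
## All arrays live in "physical" order: row i <-> x[i], column j <-> y[j],
## origin at index (n/2 + 1). The centered DFT is fftshift(fft(ifftshift(.)));
## for even counts fftshift and ifftshift coincide (a half-period circular
## shift), which is why grids are restricted to even counts.

swap_half <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  m[c((nx / 2 + 1):nx, 1:(nx / 2)), c((ny / 2 + 1):ny, 1:(ny / 2)), drop = FALSE]
}

#' Lateral spatial-to-angular spectrum transform
#'
#' Discrete approximation of `\iint f(x, y) exp(-i (kx x + ky y)) dx dy`
#' on a centered grid (the analysis convention used for aperture fields and
#' for the scan-to-K-space transform of OCT data).
#'
#' @param f complex matrix sampled on `grid` (x along rows)
#' @param grid a [lateral_grid()]
#' @return complex matrix on the conjugate K-grid
#' @seealso [lateral_field()] for the exact inverse
#' @export
lateral_spectrum <- function(f, grid) {
  stopifnot(nrow(f) == grid$n_x, ncol(f) == grid$n_y)
  swap_half(stats::fft(swap_half(f))) * (grid$dx * grid$dy)
}

#' Angular-to-spatial inverse transform
#'
#' Exact inverse of [lateral_spectrum()]:
#' `f(x, y) = (2 pi)^-2 \iint F exp(+i (kx x + ky y)) dkx dky`.
#'
#' @param F complex matrix on the K-grid of `grid`
#' @param grid a [lateral_grid()]
#' @return complex matrix on the spatial grid
#' @export
lateral_field <- function(F, grid) {
  stopifnot(nrow(F) == grid$n_x, ncol(F) == grid$n_y)
  swap_half(stats::fft(swap_half(F), inverse = TRUE)) /
    (grid$n_x * grid$n_y * grid$dx * grid$dy)
}

## \iint F(kx,ky) exp(-i (kx x + ky y)) dkx dky  (plane-wave synthesis onto the
## scan/offset grid; the kernel sign matches the shifted form of the incident-
## field integral, where the beam-axis offset enters as exp(-i k x0)).
k_to_scan <- function(F, grid) {
  swap_half(stats::fft(swap_half(F))) * (grid$dkx * grid$dky)
}

kperp2 <- function(grid) {
  outer(grid$kx^2, grid$ky^2, `+`)
}

#' Source spectrum of the illuminating light
#'
#' Equidistant wavenumber comb `k_n` centered on `k0 = 2*pi/lambda0` with a
#' Gaussian or flat envelope normalized to unit maximum. OCT sources have
#' fractional bandwidths of the order of a few percent; the recorded
#' `fractional_bandwidth` flags the narrowband regime used by the simplified
#' single-wavenumber filtering path.
#'
#' @param lambda0_um central wavelength (um)
#' @param fractional_bandwidth total span `(k_max - k_min)/k0`, in `[0, 0.5)`
#' @param n_k number of spectral lines (>= 1; 1 gives a monochromatic source)
#' @param envelope `"gaussian"` (std = span/6) or `"flat"`
#' @return object of class `source_spectrum` with fields `k` (rad/um), `S`,
#'   `k0`, `dk`, `lambda0_um`, `fractional_bandwidth`, `envelope`.
#' @examples
#' source_spectrum(0.85, 0, 1)$k0     # 2*pi/0.85
#' @export
source_spectrum <- function(lambda0_um, fractional_bandwidth = 0.03,
                            n_k = 32, envelope = c("gaussian", "flat")) {
  envelope <- match.arg(envelope)
  if (lambda0_um <= 0) stop("lambda0_um must be positive")
  if (fractional_bandwidth < 0 || fractional_bandwidth >= 0.5)
    stop("fractional_bandwidth must be in [0, 0.5)")
  if (n_k < 1) stop("n_k must be >= 1")
  k0 <- 2 * pi / lambda0_um
  if (n_k == 1 || fractional_bandwidth == 0) {
    k <- k0
    S <- 1
    dk <- NA_real_
  } else {
    span <- fractional_bandwidth * k0
    dk <- span / (n_k - 1)
    k <- k0 + (seq_len(n_k) - (n_k + 1) / 2) * dk
    S <- if (envelope == "flat") rep(1, n_k) else {
      sig <- span / 6
      exp(-(k - k0)^2 / (2 * sig^2))
    }
    S <- S / max(S)
  }
  out <- list(
    k = k, S = S, k0 = k0, dk = dk, lambda0_um = lambda0_um,
    fractional_bandwidth = fractional_bandwidth, envelope = envelope
  )
  class(out) <- "source_spectrum"
  out
}

#' @export
print.source_spectrum <- function(x, ...) {
  cat(sprintf(
    "<source_spectrum> lambda0 = %g um (k0 = %.4f rad/um), %d line(s), bandwidth %.2f%% (%s)\n",
    x$lambda0_um, x$k0, length(x$k), 100 * x$fractional_bandwidth, x$envelope
  ))
  invisible(x)
}

## amplitude-weighted centroid of the spectral comb
spectrum_centroid <- function(spec) sum(spec$S * spec$k) / sum(spec$S)

## Zero-pad the wavenumber comb symmetrically by an integer factor, keeping the
## line spacing; padded lines carry S = 0. Used for sub-pixel axial peak
## localization and to keep the depth axis a proper conjugate of the comb.
pad_spectrum <- function(spec, pad_factor = 2L) {
  pad_factor <- as.integer(pad_factor)
  if (pad_factor <= 1L || length(spec$k) == 1L) return(spec)
  n <- length(spec$k)
  n_pad <- n * pad_factor
  left <- (n_pad - n) %/% 2
  kmin <- spec$k[1] - left * spec$dk
  k <- kmin + (seq_len(n_pad) - 1) * spec$dk
  S <- numeric(n_pad)
  S[left + seq_len(n)] <- spec$S
  out <- spec
  out$k <- k
  out$S <- S
  out
}

#' Depth axis for reconstructed A-scans
#'
#' @param z depth samples (um), equidistant and increasing
#' @param z_d distance between the aperture and the tissue boundary (um)
#' @return object of class `depth_axis` with `z`, `dz`, `z_d`
#' @export
depth_axis <- function(z, z_d = 0) {
  if (length(z) > 1) {
    dz <- diff(z)
    if (any(dz <= 0)) stop("depth samples must be strictly increasing")
    if (max(abs(dz - dz[1])) > 1e-9 * dz[1]) stop("depth samples must be equidistant")
    dz <- dz[1]
  } else dz <- NA_real_
  structure(list(z = z, dz = dz, z_d = z_d), class = "depth_axis")
}

#' Conjugate depth axis of a source spectrum
#'
#' Builds the depth grid on which the wavenumber-to-depth transform of the
#' double-pass signal (phase `exp(2 i k z)`) is unitary: `n_z` equals the
#' (padded) number of spectral lines and `dz = pi / (n_z * dk)`. The
#' unambiguous depth range is `pi / dk`.
#'
#' @param spec a [source_spectrum()] with at least 2 lines
#' @param pad_factor integer zero-padding factor applied to the comb
#' @param z_min depth of the first sample (um)
#' @param z_d aperture-to-tissue distance (um)
#' @return a [depth_axis()]
#' @export
conjugate_depth_axis <- function(spec, pad_factor = 2L, z_min = 0, z_d = 0) {
  if (length(spec$k) < 2) stop("monochromatic spectrum has no conjugate depth axis")
  n_z <- length(spec$k) * as.integer(pad_factor)
  dz <- pi / (n_z * spec$dk)
  depth_axis(z_min + (seq_len(n_z) - 1) * dz, z_d = z_d)
}
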