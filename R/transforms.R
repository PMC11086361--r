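## High-level transform recipes composing the depth-indexed spectral filter.

## Gaussian beam parameters of the volume's acquisition beam (or stop)
volume_gaussian_params <- function(volume) {
  b <- volume$beam
  if (is.null(b) || b$kind != "gaussian")
    stop("this transform needs Gaussian acquisition-beam metadata")
  if (!is.null(b$aberration))
    stop("beam carries an aberration: use correct_aberrations()")
  b
}

## Analytic (closed-form, paraxial) Gaussian refocusing filter with a
## depth-dependent target waist W0'(z) focused at each depth.
gaussian_refocus_filter <- function(volume, w0_target, alpha) {
  b <- volume_gaussian_params(volume)
  k0 <- volume$spectrum$k0
  z <- volume$depth$z
  ker_i <- gaussian_kernel_stack(b$W0, b$z0, k0, volume$grid, z)
  ker_t <- gaussian_kernel_stack(w0_target, function(zq) zq, k0, volume$grid, z)
  filter_function(ker_i, ker_t, alpha = alpha)
}

## Numeric (arbitrary-beam, full-propagator) kernel of a per-depth refocused
## Gaussian target with constant waist W0.
numeric_target_stack <- function(W0, lambda0, grid, k, depths, z_d = 0,
                                 mode = "full") {
  I <- array(0i, c(grid$n_x, grid$n_y, length(depths)))
  for (q in seq_along(depths)) {
    # a target focused at depth 0 degenerates to a waist at the aperture
    tb <- beam_spec("gaussian", W0 = W0, z0 = max(depths[q], 1e-6),
                    lambda0_um = lambda0)
    ks <- depth_kernel(tb, grid, k, depths[q], z_d = z_d, mode = mode)
    I[, , q] <- ks$I[, , 1]
  }
  structure(list(I = I, k = k, depths = depths, grid = grid,
                 beam = sprintf("gaussian target (W0 = %.3g um, per-depth focus)", W0),
                 type = "numeric", mode = mode),
            class = "kernel_stack")
}

## Kernel-ratio transform with numeric kernels for an arbitrary initial beam
## and a per-depth refocused Gaussian target of constant waist W0_target.
## chain = "narrowband" applies the single-k0 filter; "full" builds a filter
## stack per spectral line and runs the four-transform chain.
kernel_ratio_transform <- function(volume, beam_init, W0_target, alpha,
                                   chain = c("narrowband", "full"),
                                   mode = "full") {
  chain <- match.arg(chain)
  z <- volume$depth$z
  z_d <- volume$depth$z_d
  grid <- volume$grid
  lambda0 <- beam_init$lambda0_um
  make_filter <- function(k) {
    ker_i <- depth_kernel(beam_init, grid, k, z, z_d = z_d, mode = mode)
    ker_t <- numeric_target_stack(W0_target, lambda0, grid, k, z, z_d = z_d,
                                  mode = mode)
    filter_function(ker_i, ker_t, alpha = alpha)
  }
  if (chain == "narrowband")
    apply_filter_narrowband(volume, make_filter(volume$spectrum$k0))
  else
    apply_filter_full(volume, make_filter)
}

#' Conventional digital refocusing
#'
#' Restores the physical-focus lateral resolution at every depth. Three
#' equivalent implementations are exposed:
#' * `"onestep"` - the one-step all-depth phase kernel ([refocus_one_step()]);
#' * `"analytic"` - the generalized filter with closed-form Gaussian kernels
#'   under the waist-conserving constraint `WL'/z0' = WL/z0` (with
#'   `alpha = 0` the filter reduces exactly to the one-step phase kernel);
#' * `"numeric"` - the generalized filter with numerically computed kernels
#'   (full propagator), also usable as the aberration-free reference for
#'   [correct_aberrations()].
#'
#' @param volume an [oct_volume()] acquired with a Gaussian beam
#' @param method implementation path
#' @param alpha relative Tikhonov regularization (filter paths)
#' @param chain `"narrowband"` (single central-wavenumber filtering) or
#'   `"full"` (per-wavenumber filtering), for the `"numeric"` method
#' @return the refocused [oct_volume()]
#' @export
conventional_refocus <- function(volume, method = c("onestep", "analytic", "numeric"),
                                 alpha = 0, chain = "narrowband") {
  method <- match.arg(method)
  if (method == "onestep") return(refocus_one_step(volume))
  b <- volume_gaussian_params(volume)
  if (method == "analytic") {
    filt <- gaussian_refocus_filter(volume, w0_target = b$W0, alpha = alpha)
    return(apply_filter_narrowband(volume, filt))
  }
  kernel_ratio_transform(volume, b, b$W0, alpha, chain = chain, mode = "full")
}

#' Refocusing with a fixed aperture beam radius
#'
#' Shifts the focus to every depth while keeping the beam radius at the
#' aperture invariable (`WL' = WL`), so the recovered focal radius varies
#' with depth: smaller than the physical focus above it (`z0' < z0`), larger
#' below, following `W0'(z) ~ lambda z / (pi WL)` for strong focusing.
#'
#' @param volume an [oct_volume()] acquired with a Gaussian beam
#' @param alpha relative Tikhonov regularization
#' @return the transformed [oct_volume()]
#' @export
refocus_fixed_aperture <- function(volume, alpha = 0) {
  b <- volume_gaussian_params(volume)
  w0_of <- function(z) gaussian_params(b$lambda0_um, max(z, 1e-6), WL = b$WL)$W0
  filt <- gaussian_refocus_filter(volume, w0_target = w0_of, alpha = alpha)
  apply_filter_narrowband(volume, filt)
}

#' Super-refocusing towards a focal radius below the physical focus
#'
#' Phase-and-amplitude filtering towards a target focal radius
#' `W0T = W0 / M < W0` at every depth, equivalent to broadening the beam at
#' the aperture (`WL'(z) = lambda z / (pi W0T)`) while focusing at each
#' depth. The amplitude part amplifies the weak out-of-center angular
#' spectral components, so with noisy data a Tikhonov parameter of the order
#' of the inverse SNR is recommended. `M = 1` degenerates to conventional
#' refocusing. Bounded by the diffraction limit and by the lateral window,
#' which plays the role of the physical lens aperture.
#'
#' @param volume an [oct_volume()] acquired with a Gaussian beam
#' @param M resolution-improvement factor (>= 1) on the focal radius
#' @param alpha relative Tikhonov regularization
#' @param W0_target explicit target focal radius (um), overrides `M`
#' @return the transformed [oct_volume()]
#' @export
super_refocus <- function(volume, M = 4, alpha = 1e-2, W0_target = NULL) {
  b <- volume_gaussian_params(volume)
  if (is.null(W0_target)) {
    stopifnot(M >= 1)
    W0_target <- b$W0 / M
  }
  # effective aperture needed at the deepest plane vs available window
  WL_needed <- b$lambda0_um * max(volume$depth$z) / (pi * W0_target)
  half_win <- min(volume$grid$n_x * volume$grid$dx,
                  volume$grid$n_y * volume$grid$dy) / 2
  if (WL_needed > half_win)
    stop(sprintf(
      "target focal radius %.3g um needs an effective aperture radius %.3g um exceeding the half-window %.3g um",
      W0_target, WL_needed, half_win))
  filt <- gaussian_refocus_filter(volume, w0_target = W0_target, alpha = alpha)
  apply_filter_narrowband(volume, filt)
}

#' Convert a volume between arbitrary beam shapes
#'
#' General application of the kernel-ratio filter with numerically computed
#' kernels (full non-paraxial propagator) for an arbitrary initial/target
#' beam pair, e.g. turning a volume acquired with a focused Lorentzian beam
#' into the volume a non-diverging Bessel beam would have produced.
#'
#' @param volume an [oct_volume()]
#' @param beam_target target [beam_spec()]
#' @param alpha relative Tikhonov regularization
#' @param beam_init initial beam (default: the volume's beam metadata)
#' @param mode propagator mode
#' @param overlap_tol maximal tolerated fraction of target-kernel energy
#'   lying outside the initial kernel's support
#' @return the transformed [oct_volume()]
#' @export
convert_beam <- function(volume, beam_target, alpha = 1e-6,
                         beam_init = volume$beam, mode = "full",
                         overlap_tol = 0.2) {
  if (is.null(beam_init)) stop("no initial beam metadata on the volume")
  k0 <- volume$spectrum$k0
  z <- volume$depth$z
  ker_i <- depth_kernel(beam_init, volume$grid, k0, z, z_d = volume$depth$z_d,
                        mode = mode)
  ker_t <- depth_kernel(beam_target, volume$grid, k0, z, z_d = volume$depth$z_d,
                        mode = mode)
  # target spectral content must be recoverable from the initial passband
  for (q in seq_along(z)) {
    Ii <- abs(ker_i$I[, , q]); It <- abs(ker_t$I[, , q])
    outside <- sum(It[Ii < 1e-9 * max(Ii)]^2) / sum(It^2)
    if (outside > overlap_tol)
      stop(sprintf(
        "target passband at depth %g um lies %.0f%% outside the initial passband: unrecoverable spectrum",
        z[q], 100 * outside))
  }
  apply_filter_narrowband(volume, filter_function(ker_i, ker_t, alpha = alpha))
}

#' Correct known aperture aberrations (double-pass)
#'
#' Simultaneous aberration removal and refocusing for a volume acquired with
#' an aberrated beam `UL = UL_target * Q`. Because the OCT signal is
#' proportional to the *square* of the incident field, the aberration mixes
#' nonlinearly into the data and no aperture phase conjugation (single or
#' double) can undo it; the kernel-ratio filter with the distorted kernel in
#' the denominator handles the double-pass mixing exactly. The aberration
#' function `Q` is assumed known (taken from the volume's beam metadata).
#'
#' @param volume an [oct_volume()] whose beam metadata carries an
#'   [aberration_function()]
#' @param alpha relative Tikhonov regularization
#' @param W0_target target focal radius (um); default: the beam's own waist
#'   (refocused, aberration-free target)
#' @param chain `"narrowband"` (single central-wavenumber filtering, the
#'   computationally cheap default) or `"full"` (per-wavenumber filtering;
#'   removes the residual that the narrowband approximation leaves when the
#'   depth-dependent kernel phases vary across the source band)
#' @return the corrected [oct_volume()]
#' @export
correct_aberrations <- function(volume, alpha = 1e-6, W0_target = NULL,
                                chain = "narrowband") {
  b <- volume$beam
  if (is.null(b) || b$kind != "gaussian")
    stop("aberration correction needs Gaussian acquisition-beam metadata")
  if (is.null(b$aberration))
    stop("volume's beam carries no aberration function")
  if (is.null(W0_target)) W0_target <- b$W0
  kernel_ratio_transform(volume, b, W0_target, alpha, chain = chain,
                         mode = "full")
}

#' Naive conjugate-phase aberration correction (demonstration only)
#'
#' Applies the m-fold conjugate of the aberration phase as a spectral
#' correction (using the focal-plane mapping between aperture position and
#' transverse wavenumber, `x ~ kx z0 / k0`) together with one-step
#' refocusing. For the double-pass geometry neither `m = 1` nor `m = 2`
#' removes the distortion; the residual stays far above the kernel-ratio
#' correction of [correct_aberrations()]. Included as a documented
#' demonstration utility, not a supported transform.
#'
#' @param volume an [oct_volume()] with an aberrated Gaussian beam
#' @param m phase-conjugation multiplicity (1 or 2)
#' @return the (incompletely) corrected [oct_volume()]
#' @export
naive_phase_correction <- function(volume, m = 1) {
  b <- volume$beam
  if (is.null(b$aberration)) stop("volume's beam carries no aberration function")
  k0 <- volume$spectrum$k0
  z0 <- b$z0
  grid <- volume$grid
  # aberration phase resampled onto the K-grid via the lens mapping x ~ kx z0/k0
  kgrid <- grid
  kgrid$x <- grid$kx * z0 / k0
  kgrid$y <- grid$ky * z0 / k0
  phase <- matrix(0, grid$n_x, grid$n_y)
  for (t in b$aberration$terms)
    phase <- phase + t$A0 * zernike(t$n, t$m, kgrid, b$aberration$Ra)
  corr <- exp(1i * m * phase)   # conjugate of Q = exp(-i * phase)
  A <- volume$A
  kp2 <- kperp2(grid)
  for (q in seq_len(dim(A)[3])) {
    kern <- corr * exp(-1i * (z0 - volume$depth$z[q]) * kp2 / (4 * k0))
    A[, , q] <- lateral_field(lateral_spectrum(A[, , q], grid) * kern, grid)
  }
  volume$A <- A
  append_provenance(volume, sprintf("naive_phase_correction(m=%d)", m))
}
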