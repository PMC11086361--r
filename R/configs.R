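## Canonical demonstration configurations. The numbers mirror the package's
## reference simulation conditions: central wavelength 0.85 um, focus depth
## 252 um, scatterer chain spanning 24-480 um, highly focused beam with
## focal-waist radius ~1.9 um (aperture radius 35.9 um), weakly focused beam
## with waist 12.6 um and 12-um scatterer pairs.

## spectrum whose conjugate depth axis (after padding) has spacing dz
chain_spectrum <- function(lambda0_um, n_k, pad_factor, dz) {
  k0 <- 2 * pi / lambda0_um
  dk <- pi / (pad_factor * n_k * dz)
  source_spectrum(lambda0_um, fractional_bandwidth = dk * (n_k - 1) / k0,
                  n_k = n_k, envelope = "gaussian")
}

#' Reference configurations for the demonstration experiments
#'
#' Ready-made [sim_config()]s for the package's canonical experiments:
#'
#' * `config_focused_chain()` - highly focused Gaussian beam
#'   (`lambda0 = 0.85` um, aperture 1/e radius `WL = 35.9` um focused at
#'   `z0 = 252` um, waist ~1.9 um), 256 x 0.75 um scan window (192 um, i.e.
#'   ~3x the out-of-focus beam diameter at the chain ends), depth axis
#'   0-508 um in 4 um steps, paraxial propagator (the model in which the
#'   quoted waist and the one-step refocusing kernel are defined; at this
#'   beam's NA the rigorous propagator widens the focus by several percent).
#'   Pair with [chain_scene()] (defaults put seven scatterers at 24-480 um
#'   with the middle one in focus).
#' * `config_weak_pairs()` - weakly focused Gaussian beam specified by its
#'   waist (`W0 = 12.6` um at 252 um, exact aperture curvature), 192-sample
#'   window for the broader out-of-focus beam. Pair with
#'   [pair_chain_scene()] (12-um pairs).
#' * `config_aberrated_chain()` - the focused-chain beam with a coma
#'   (`Z_3^1`) phase aberration of amplitude `A0` radians over a disk of
#'   radius `Ra` (default twice the aperture radius).
#'
#' The depth spacing is chosen so that all chain depths (multiples of 4 um)
#' fall exactly on depth samples, and the implied fractional bandwidth
#' (~2.6%) sits in the narrowband regime of typical OCT sources.
#'
#' @param n_x lateral samples (even)
#' @param dx scan spacing (um)
#' @param n_k source spectral lines
#' @param pad_factor axial zero-padding factor
#' @param dz depth sampling (um)
#' @param lambda0_um central wavelength (um)
#' @param WL aperture 1/e radius (um)
#' @param W0 focal-waist radius (um)
#' @param z0 focus depth (um)
#' @param propagator_mode `"full"` or `"paraxial"`
#' @param A0_rad coma amplitude (radians)
#' @param Ra_um aberration normalization radius (um)
#' @return a [sim_config()]
#' @name reference_configs
NULL

#' @rdname reference_configs
#' @export
config_focused_chain <- function(n_x = 256, dx = 0.75, n_k = 32,
                                 pad_factor = 4L, dz = 4,
                                 lambda0_um = 0.85, WL = 35.9, z0 = 252,
                                 propagator_mode = "paraxial") {
  grid <- lateral_grid(n_x, n_x, dx, dx)
  spec <- chain_spectrum(lambda0_um, n_k, pad_factor, dz)
  beam <- beam_spec("gaussian", WL = WL, z0 = z0, lambda0_um = lambda0_um)
  sim_config(grid, spec, beam, propagator_mode = propagator_mode,
             pad_factor = pad_factor)
}

#' @rdname reference_configs
#' @export
config_weak_pairs <- function(n_x = 192, dx = 0.75, n_k = 32,
                              pad_factor = 4L, dz = 4,
                              lambda0_um = 0.85, W0 = 12.6, z0 = 252,
                              propagator_mode = "full") {
  grid <- lateral_grid(n_x, n_x, dx, dx)
  spec <- chain_spectrum(lambda0_um, n_k, pad_factor, dz)
  beam <- beam_spec("gaussian", W0 = W0, z0 = z0, lambda0_um = lambda0_um)
  sim_config(grid, spec, beam, propagator_mode = propagator_mode,
             pad_factor = pad_factor)
}

#' @rdname reference_configs
#' @export
config_aberrated_chain <- function(A0_rad = 60, Ra_um = NULL, n_x = 256,
                                   dx = 0.75, n_k = 32, pad_factor = 4L,
                                   dz = 4, lambda0_um = 0.85, WL = 35.9,
                                   z0 = 252, propagator_mode = "full") {
  cfg <- config_focused_chain(n_x, dx, n_k, pad_factor, dz, lambda0_um, WL,
                              z0, propagator_mode)
  if (is.null(Ra_um)) Ra_um <- 2 * cfg$beam$WL
  cfg$beam$aberration <- aberration_function(
    list(list(n = 3, m = 1, A0 = A0_rad)), Ra = Ra_um)
  cfg
}
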