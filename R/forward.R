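#' Angular-spectrum propagator
#'
#' Unit-magnitude spectral phase factor advancing each plane-wave component by
#' the signed axial distance `dz`:
#' full (non-paraxial) mode `exp(i dz sqrt(k^2 - kx^2 - ky^2))` inside the
#' propagating domain `kx^2 + ky^2 <= k^2` and zero outside (evanescent
#' components are excluded, not decayed); paraxial mode
#' `exp(i dz (k - (kx^2 + ky^2)/(2k)))` on the same domain.
#'
#' @param k wavenumber (rad/um)
#' @param dz signed propagation distance (um)
#' @param grid a [lateral_grid()]
#' @param mode `"full"` or `"paraxial"`
#' @return complex matrix on the K-grid (zero outside the propagating mask)
#' @export
propagator <- function(k, dz, grid, mode = c("full", "paraxial")) {
  mode <- match.arg(mode)
  stopifnot(k > 0)
  kp2 <- kperp2(grid)
  mask <- kp2 <= k^2
  h <- matrix(0i, grid$n_x, grid$n_y)
  if (mode == "full") {
    kz <- sqrt(pmax(k^2 - kp2, 0))
    h[mask] <- exp(1i * dz * kz[mask])
  } else {
    ph <- dz * (k - kp2 / (2 * k))
    h[mask] <- exp(1i * ph[mask])
  }
  h
}

#' Simulation configuration
#'
#' Bundles the scan grid, source spectrum, depth axis, beam and propagation
#' options of a forward simulation. If `depth` is omitted it is derived as the
#' conjugate axis of the (padded) spectrum starting at `z_min`.
#'
#' @param grid scan-position [lateral_grid()] (also used for aperture fields)
#' @param spectrum a [source_spectrum()]
#' @param beam a [beam_spec()]
#' @param depth optional [depth_axis()]
#' @param z_d aperture-to-tissue distance (um)
#' @param propagator_mode `"full"` or `"paraxial"`
#' @param pad_factor axial zero-padding factor (sub-pixel peak localization)
#' @param z_min first depth sample when `depth` is derived (um)
#' @return object of class `sim_config`
#' @export
sim_config <- function(grid, spectrum, beam, depth = NULL, z_d = 0,
                       propagator_mode = c("full", "paraxial"),
                       pad_factor = 2L, z_min = 0) {
  propagator_mode <- match.arg(propagator_mode)
  spec_pad <- pad_spectrum(spectrum, pad_factor)
  if (is.null(depth)) {
    if (length(spectrum$k) < 2)
      stop("monochromatic source: supply an explicit depth axis")
    depth <- conjugate_depth_axis(spectrum, pad_factor, z_min = z_min, z_d = z_d)
  }
  structure(
    list(grid = grid, spectrum = spectrum, spectrum_padded = spec_pad,
         beam = beam, depth = depth, z_d = z_d,
         propagator_mode = propagator_mode,
         pad_factor = as.integer(pad_factor)),
    class = "sim_config"
  )
}

#' Validate the scan window against the out-of-focus beam size
#'
#' The lateral window should be at least `factor` (default 3) times the
#' largest out-of-focus beam diameter among the simulated depths, so that the
#' periodic Fourier transforms do not wrap beam tails onto the image. Warns
#' (does not stop) when violated; only Gaussian beams have the closed-form
#' width used here.
#'
#' @param config a [sim_config()]
#' @param factor required window-to-diameter ratio
#' @return invisibly, the computed ratio (NA for non-Gaussian beams)
#' @export
validate_scan_window <- function(config, factor = 3) {
  if (config$beam$kind != "gaussian") return(invisible(NA_real_))
  p <- config$beam$params
  dia <- 2 * max(p$W(range(config$depth$z)))
  win <- min(config$grid$n_x * config$grid$dx, config$grid$n_y * config$grid$dy)
  ratio <- win / dia
  if (ratio < factor)
    warning(sprintf(
      "lateral window (%g um) is only %.2f x the out-of-focus beam diameter (%g um)",
      win, ratio, dia))
  invisible(ratio)
}

#' Incident field at a scatterer depth, over all scan positions
#'
#' Evaluates the propagating-domain integral
#' `Us(x0, y0) = \iint g h exp(i[kx (xs - x0) + ky (ys - y0)]) dkx dky`
#' for every scan position at once: the lateral scatterer offset enters as a
#' linear spectral phase, so one synthesis transform yields the whole scan
#' plane, with no interpolation even for off-grid scatterer positions.
#'
#' @param g angular spectrum of the beam at wavenumber `k` (on `grid`'s K-grid)
#' @param k wavenumber (rad/um)
#' @param scatterer list or one-row scene with `xs`, `ys`, `zs`
#' @param grid scan [lateral_grid()]
#' @param z_d aperture-to-tissue distance (um)
#' @param mode propagator mode
#' @return complex matrix `Us(x0, y0)`
#' @export
incident_field <- function(g, k, scatterer, grid, z_d = 0,
                           mode = c("full", "paraxial")) {
  mode <- match.arg(mode)
  half_x <- grid$n_x * grid$dx / 2
  half_y <- grid$n_y * grid$dy / 2
  if (abs(scatterer$xs) > half_x || abs(scatterer$ys) > half_y)
    stop("scatterer lies outside the lateral scan window")
  h <- propagator(k, scatterer$zs - z_d, grid, mode)
  ramp <- exp(1i * outer(grid$kx * scatterer$xs, grid$ky * scatterer$ys, `+`))
  k_to_scan(g * h * ramp, grid)
}

#' Received double-pass amplitude
#'
#' `Bs = Ks * Us^2`: by the forward/backward symmetry of the double-pass
#' geometry the received amplitude is the scattering coefficient times the
#' square of the incident field, for beams of arbitrary form.
#'
#' @param Us complex incident field (scalar, vector or matrix)
#' @param Ks complex scattering coefficient
#' @return complex of the same shape
#' @export
received_amplitude <- function(Us, Ks) Ks * Us^2

## spectral-domain received amplitudes, one matrix per active spectral line
## (internal work-horse shared by simulate_volume and the factorization check)
received_spectral_planes <- function(scene, config) {
  grid <- config$grid
  spec <- config$spectrum_padded
  active <- which(spec$S > 0)
  B <- vector("list", length(active))
  for (a in seq_along(active)) {
    k <- spec$k[active[a]]
    UL <- aperture_field(config$beam, grid, k)
    g <- lateral_spectrum(UL, grid)
    Bk <- matrix(0i, grid$n_x, grid$n_y)
    h_cache <- list()
    for (s in seq_len(nrow(scene))) {
      key <- sprintf("%.9g", scene$zs[s])
      if (is.null(h_cache[[key]]))
        h_cache[[key]] <- propagator(k, scene$zs[s] - config$z_d, grid,
                                     config$propagator_mode)
      ramp <- exp(1i * outer(grid$kx * scene$xs[s], grid$ky * scene$ys[s], `+`))
      Us <- k_to_scan(g * h_cache[[key]] * ramp, grid)
      Bk <- Bk + received_amplitude(Us, scene$Ks[s])
    }
    B[[a]] <- Bk
  }
  list(B = B, active = active)
}

#' Simulate a 3D OCT volume from a scatterer scene
#'
#' For every spectral line `k_n` with non-zero source amplitude the incident
#' field is computed over the whole scan grid in one synthesis transform per
#' scatterer, squared (double pass), weighted by `Ks`, and summed over
#' scatterers. A-scans are then assembled by the wavenumber-to-depth
#' transform `A(x0, y0, zq) = sum_n S(k_n) B(x0, y0; k_n) exp(-2 i k_n zq)`
#' (the factor 2 reflects the double-pass optical path), evaluated on the
#' conjugate depth axis so the transform chain is exactly invertible.
#'
#' @param scene a scene tibble (see [chain_scene()])
#' @param config a [sim_config()]
#' @return an [oct_volume()]
#' @export
simulate_volume <- function(scene, config) {
  stopifnot(nrow(scene) >= 1)
  zr <- range(config$depth$z)
  if (any(scene$zs < zr[1] - 1e-9) || any(scene$zs > zr[2] + 1e-9))
    warning("scatterer depth outside the unambiguous depth window: image will alias")
  grid <- config$grid
  spec <- config$spectrum_padded
  planes <- received_spectral_planes(scene, config)
  nvox <- grid$n_x * grid$n_y
  Bmat <- matrix(0i, length(planes$active), nvox)
  for (a in seq_along(planes$active))
    Bmat[a, ] <- as.vector(planes$B[[a]])
  kk <- spec$k[planes$active]
  Sn <- spec$S[planes$active]
  E <- exp(-2i * outer(config$depth$z, kk)) * rep(Sn, each = length(config$depth$z))
  A <- array(E %*% Bmat, dim = c(length(config$depth$z), grid$n_x, grid$n_y))
  A <- aperm(A, c(2, 3, 1))
  oct_volume(A, grid, config$depth, spectrum = spec, beam = config$beam,
             provenance = sprintf("simulate_volume(%d scatterers, %s propagator)",
                                  nrow(scene), config$propagator_mode))
}

#' Linearity check of the forward model
#'
#' The A-scan sum over scatterers is linear: the volume of a union of scenes
#' must equal the voxel-wise sum of the per-scene volumes. Returns the maximum
#' absolute deviation relative to the peak amplitude of the union volume.
#'
#' @param scene_a,scene_b scene tibbles on the same configuration
#' @param config a [sim_config()]
#' @return maximum relative deviation (scalar)
#' @export
volume_linearity_check <- function(scene_a, scene_b, config) {
  if (nrow(scene_b) == 0) return(0)
  v_ab <- simulate_volume(rbind(scene_a, scene_b), config)
  v_a <- simulate_volume(scene_a, config)
  v_b <- simulate_volume(scene_b, config)
  max(abs(v_ab$A - (v_a$A + v_b$A))) / max(abs(v_ab$A))
}
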