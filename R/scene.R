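#' Point-scatterer scenes
#'
#' Scenes are tibbles with one row per scatterer: lateral and axial positions
#' `xs`, `ys`, `zs` (um) and the complex scattering coefficient `Ks`
#' (default `1 + 0i`; for narrowband sources and point-like scatterers it is
#' approximately independent of wavenumber and direction).
#'
#' @name scene
NULL

new_scene <- function(xs, ys, zs, Ks) {
  tibble::tibble(xs = as.numeric(xs), ys = as.numeric(ys),
                 zs = as.numeric(zs), Ks = as.complex(Ks))
}

#' Vertical chain of point scatterers
#'
#' `n` scatterers equally spaced in depth on (or parallel to) the beam axis;
#' the canonical test object for depth-dependent focusing.
#'
#' @param n number of scatterers (>= 1)
#' @param z_min,z_max depth span (um); defaults 24-480 um place the middle
#'   scatterer of a 7-chain at 252 um
#' @param x,y lateral position of the chain (um)
#' @param Ks complex scattering coefficient
#' @return a scene tibble
#' @export
chain_scene <- function(n = 7, z_min = 24, z_max = 480, x = 0, y = 0, Ks = 1 + 0i) {
  stopifnot(n >= 1)
  if (n > 1 && z_min >= z_max) stop("need z_min < z_max")
  z <- if (n == 1) (z_min + z_max) / 2 else seq(z_min, z_max, length.out = n)
  new_scene(rep(x, n), rep(y, n), z, rep(Ks, n))
}

#' Chain of laterally separated scatterer pairs
#'
#' Each of `n_pairs` depths carries two scatterers at `x = +/- separation/2`,
#' used to probe lateral two-point resolution.
#'
#' @param n_pairs number of depth positions
#' @param separation lateral pair separation (um)
#' @param z_min,z_max depth span (um)
#' @param Ks complex scattering coefficient
#' @return a scene tibble with `2 * n_pairs` rows
#' @export
pair_chain_scene <- function(n_pairs = 7, separation = 12, z_min = 24,
                             z_max = 480, Ks = 1 + 0i) {
  stopifnot(n_pairs >= 1, separation >= 0)
  base <- chain_scene(n_pairs, z_min, z_max, Ks = Ks)
  left <- base; left$xs <- -separation / 2
  right <- base; right$xs <- separation / 2
  out <- rbind(left, right)
  out[order(out$zs, out$xs), ]
}

#' Uniform random scatterer scene
#'
#' Scatterer count drawn from a Poisson law with mean `density * volume`,
#' positions uniform in the box; reproducible for a fixed seed.
#'
#' @param density_per_um3 scatterer density (um^-3)
#' @param extents list with `x`, `y`, `z` ranges, each `c(min, max)` (um)
#' @param seed integer RNG seed (required)
#' @param random_phase give each `Ks` a uniform random phase
#' @return a scene tibble
#' @export
random_scene <- function(density_per_um3, extents, seed, random_phase = FALSE) {
  stopifnot(density_per_um3 > 0, !missing(seed))
  vol <- prod(vapply(extents[c("x", "y", "z")], function(r) diff(range(r)), 0))
  with_seed(seed, {
    n <- stats::rpois(1, density_per_um3 * vol)
    Ks <- if (random_phase) exp(2i * pi * stats::runif(n)) else rep(1 + 0i, n)
    new_scene(
      stats::runif(n, extents$x[1], extents$x[2]),
      stats::runif(n, extents$y[1], extents$y[2]),
      stats::runif(n, extents$z[1], extents$z[2]),
      Ks
    )
  })
}

## evaluate expr with a local, restored RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Add circular complex Gaussian measurement noise
#'
#' SNR convention (amplitude ratio in dB, referenced to the brightest voxel):
#' `snr_db = 20 log10(max |A| / rms noise amplitude)`, where the RMS noise
#' amplitude is `sqrt(E |n|^2)` of the complex noise. `snr_db = Inf` returns
#' the volume unchanged. Real and imaginary parts are i.i.d. Gaussian
#' (statistically isotropic in the complex plane).
#'
#' @param volume an [oct_volume()]
#' @param snr_db target signal-to-noise ratio (dB); may be `Inf`
#' @param seed integer RNG seed (required for finite SNR)
#' @return the noisy [oct_volume()]
#' @export
add_noise <- function(volume, snr_db, seed) {
  stopifnot(inherits(volume, "oct_volume"))
  if (length(volume$A) == 0) stop("empty volume")
  if (is.infinite(snr_db)) return(volume)
  if (missing(seed)) stop("a seed is required for reproducible noise")
  peak <- max(abs(volume$A))
  sigma <- peak * 10^(-snr_db / 20)  # RMS complex amplitude
  n <- length(volume$A)
  noise <- with_seed(seed, {
    (stats::rnorm(n) + 1i * stats::rnorm(n)) * (sigma / sqrt(2))
  })
  volume$A <- volume$A + array(noise, dim = dim(volume$A))
  append_provenance(volume, sprintf("add_noise(snr_db=%g, seed=%d)", snr_db, as.integer(seed)))
}

#' Write / read a scene as a plain-text table
#'
#' Tab-separated columns `xs ys zs Ks_re Ks_im`, one scatterer per row.
#' @param scene a scene tibble
#' @param path file path
#' @return `read_scene` returns a scene tibble
#' @export
write_scene <- function(scene, path) {
  df <- data.frame(xs = scene$xs, ys = scene$ys, zs = scene$zs,
                   Ks_re = Re(scene$Ks), Ks_im = Im(scene$Ks))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("xs", "ys", "zs", "Ks_re", "Ks_im")
  if (!all(need %in% names(df))) stop("scene table missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  new_scene(df$xs, df$ys, df$zs, complex(real = df$Ks_re, imaginary = df$Ks_im))
}
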