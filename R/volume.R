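#' Complex OCT volume container
#'
#' Holds the complex scan amplitude `A(x0, y0, zq)` on a scan
#' [lateral_grid()] x [depth_axis()], together with the source spectrum and
#' the beam used to acquire or simulate it, and a provenance log of applied
#' transforms.
#'
#' @param A complex array `n_x x n_y x n_z`
#' @param grid scan-position [lateral_grid()]
#' @param depth [depth_axis()]
#' @param spectrum [source_spectrum()] (possibly zero-padded) or NULL
#' @param beam [beam_spec()] metadata or NULL
#' @param provenance character vector of applied operations
#' @return object of class `oct_volume`
#' @export
oct_volume <- function(A, grid, depth, spectrum = NULL, beam = NULL,
                       provenance = character()) {
  stopifnot(length(dim(A)) == 3)
  if (dim(A)[1] != grid$n_x || dim(A)[2] != grid$n_y)
    stop("volume lateral dimensions do not match the grid")
  if (dim(A)[3] != length(depth$z))
    stop("volume depth dimension does not match the depth axis")
  structure(
    list(A = A, grid = grid, depth = depth, spectrum = spectrum,
         beam = beam, provenance = provenance),
    class = "oct_volume"
  )
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$A)
  cat(sprintf(
    "<oct_volume> %d x %d x %d (lateral %g x %g um, depth %g..%g um)\n",
    d[1], d[2], d[3], d[1] * x$grid$dx, d[2] * x$grid$dy,
    min(x$depth$z), max(x$depth$z)
  ))
  if (!is.null(x$beam)) cat("  beam:", format_beam(x$beam), "\n")
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

## index of the depth sample nearest to z (error if far off the axis)
depth_index <- function(volume, z) {
  i <- which.min(abs(volume$depth$z - z))
  if (abs(volume$depth$z[i] - z) > max(volume$depth$dz, 1e-9, na.rm = TRUE))
    warning(sprintf("requested depth %g um is %g um from the nearest sample",
                    z, abs(volume$depth$z[i] - z)))
  i
}

append_provenance <- function(volume, what) {
  volume$provenance <- c(volume$provenance, what)
  volume
}

#' Summary row for an OCT volume
#'
#' One-row tibble with the volume dimensions, physical extents, central
#' wavenumber and number of applied transforms.
#' @param volume an [oct_volume()]
#' @return a tibble
#' @export
volume_summary <- function(volume) {
  d <- dim(volume$A)
  tibble::tibble(
    n_x = d[1], n_y = d[2], n_z = d[3],
    dx_um = volume$grid$dx, dy_um = volume$grid$dy,
    dz_um = volume$depth$dz,
    z_min_um = min(volume$depth$z), z_max_um = max(volume$depth$z),
    k0_rad_um = if (is.null(volume$spectrum)) NA_real_ else volume$spectrum$k0,
    n_transforms = length(volume$provenance),
    peak_amplitude = max(abs(volume$A))
  )
}

#' B-scan or en-face plot of an OCT volume
#'
#' Log-compressed amplitude image of either the x-z cross-section through a
#' given y position (`plane = "bscan"`) or the lateral slice at a given depth
#' (`plane = "enface"`).
#'
#' @param object an [oct_volume()]
#' @param plane `"bscan"` or `"enface"`
#' @param y y position (um) of the B-scan plane
#' @param z depth (um) of the en-face slice
#' @param db_floor dynamic-range floor in dB relative to the volume peak
#' @param ... unused
#' @return a ggplot object
#' @exportS3Method ggplot2::autoplot
autoplot.oct_volume <- function(object, plane = c("bscan", "enface"),
                                y = 0, z = NULL, db_floor = -40, ...) {
  plane <- match.arg(plane)
  amp <- abs(object$A)
  peak <- max(amp)
  if (plane == "bscan") {
    j <- which.min(abs(object$grid$y - y))
    img <- amp[, j, ]
    df <- expand.grid(x = object$grid$x, z = object$depth$z)
    df$db <- pmax(20 * log10(as.vector(img) / peak), db_floor)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z, fill = .data$db)) +
      ggplot2::geom_raster() +
      ggplot2::scale_y_reverse() +
      ggplot2::labs(x = "x (um)", y = "depth z (um)", fill = "dB")
  } else {
    if (is.null(z)) z <- object$depth$z[which.max(apply(amp, 3, max))]
    q <- depth_index(object, z)
    img <- amp[, , q]
    df <- expand.grid(x = object$grid$x, y = object$grid$y)
    df$db <- pmax(20 * log10(as.vector(img) / peak), db_floor)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$db)) +
      ggplot2::geom_raster() +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "x (um)", y = "y (um)", fill = "dB")
  }
  p + ggplot2::scale_fill_viridis_c()
}
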