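#' Lateral 1/e amplitude half-width of a point image
#'
#' Extracts the lateral amplitude profile through the image peak at a given
#' depth and estimates the 1/e half-width with sub-pixel accuracy. The
#' default estimator fits a quadratic to `log |A|` against the squared
#' distance from the (interpolated) peak over samples above `fit_floor` of
#' the peak - exact for Gaussian profiles; `method = "crossing"` instead
#' interpolates the two `peak/e` crossings linearly (useful for non-Gaussian
#' profiles such as Bessel lobes).
#'
#' @param volume an [oct_volume()]
#' @param depth depth of the slice (um)
#' @param axis `"x"` or `"y"` profile direction
#' @param method `"log_quadratic"` or `"crossing"`
#' @param at optional `c(x, y)` (um) near which to search the peak; default:
#'   global slice peak
#' @param fit_floor relative amplitude floor for the quadratic fit
#' @param search_radius half-size (um) of the peak search box around `at`
#' @return half-width in um
#' @export
lateral_width <- function(volume, depth, axis = c("x", "y"),
                          method = c("log_quadratic", "crossing"),
                          at = NULL, fit_floor = 0.2, search_radius = 10) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  q <- depth_index(volume, depth)
  amp <- abs(volume$A[, , q])
  if (max(amp) <= 0) stop("no signal at this depth")
  g <- volume$grid
  if (is.null(at)) {
    pk <- which(amp == max(amp), arr.ind = TRUE)[1, ]
  } else {
    inx <- abs(g$x - at[1]) <= search_radius
    iny <- abs(g$y - at[2]) <= search_radius
    sub <- amp[inx, iny, drop = FALSE]
    loc <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pk <- c(which(inx)[loc[1]], which(iny)[loc[2]])
  }
  if (axis == "x") {
    prof <- amp[, pk[2]]
    coord <- g$x
    ip <- pk[1]
  } else {
    prof <- amp[pk[1], ]
    coord <- g$y
    ip <- pk[2]
  }
  profile_half_width(coord, prof, ip, method, fit_floor)
}

## sub-pixel 1/e half-width of a sampled profile with peak near index ip
profile_half_width <- function(coord, prof, ip, method, fit_floor) {
  n <- length(prof)
  peak_val <- prof[ip]
  if (ip <= 1 || ip >= n) stop("peak at the profile edge: cannot measure width")
  # sub-pixel peak position/value by local quadratic on log-amplitude
  i3 <- (ip - 1):(ip + 1)
  la <- log(pmax(prof[i3], .Machine$double.xmin))
  d <- diff(coord)[1]
  denom <- la[1] - 2 * la[2] + la[3]
  delta <- if (denom < 0) 0.5 * (la[1] - la[3]) / denom else 0
  x_pk <- coord[ip] + delta * d
  log_pk <- la[2] - 0.25 * (la[1] - la[3]) * delta
  if (method == "log_quadratic") {
    keep <- which(prof >= fit_floor * exp(log_pk))
    # restrict to the contiguous run containing the peak (isolate one lobe)
    runs <- split(keep, cumsum(c(1, diff(keep) != 1)))
    keep <- runs[[which(vapply(runs, function(r) ip %in% r, TRUE))]]
    if (length(keep) < 3) stop("too few samples above the fit floor")
    u <- (coord[keep] - x_pk)^2
    fit <- stats::lm.fit(cbind(1, u), log(prof[keep]))
    slope <- unname(fit$coefficients[2])
    if (!is.finite(slope) || slope >= 0) stop("profile is not peaked: cannot fit width")
    sqrt(-1 / slope)
  } else {
    target <- exp(log_pk) / exp(1)
    cross_at <- function(dir) {
      i <- ip
      repeat {
        i2 <- i + dir
        if (i2 < 1 || i2 > n) return(NA_real_)
        if (prof[i2] < target) {
          f <- (prof[i] - target) / (prof[i] - prof[i2])
          return(abs(coord[i] + f * (coord[i2] - coord[i]) - x_pk))
        }
        i <- i2
      }
    }
    w <- mean(c(cross_at(-1), cross_at(1)), na.rm = TRUE)
    if (!is.finite(w)) stop("1/e crossing not found within the window")
    w
  }
}

#' Recovered beam focal radius from an image width
#'
#' The double-pass image of a point scatterer is the square of the incident
#' field, so a Gaussian image profile is narrower than the beam by `sqrt(2)`;
#' the recovered beam radius is `sqrt(2)` times the image 1/e half-width.
#'
#' @inheritParams lateral_width
#' @param ... passed to [lateral_width()]
#' @return recovered beam 1/e radius in um
#' @export
recovered_beam_radius <- function(volume, depth, ...) {
  sqrt(2) * lateral_width(volume, depth, ...)
}

#' Signal-to-noise ratio in dB (amplitude convention)
#'
#' `20 log10(peak |A| in the signal region / RMS |A| in the noise region)`.
#' Regions are axis-aligned boxes given as lists with `x`, `y`, `z` ranges
#' (um); omitted axes span the whole volume. A noise-free region (RMS 0)
#' returns `Inf`.
#'
#' @param volume an [oct_volume()]
#' @param signal_region,noise_region lists of `c(min, max)` ranges
#' @return SNR in dB
#' @export
snr_db <- function(volume, signal_region, noise_region) {
  box <- function(region) {
    g <- volume$grid
    ix <- if (is.null(region$x)) rep(TRUE, g$n_x) else g$x >= region$x[1] & g$x <= region$x[2]
    iy <- if (is.null(region$y)) rep(TRUE, g$n_y) else g$y >= region$y[1] & g$y <= region$y[2]
    iz <- if (is.null(region$z)) rep(TRUE, length(volume$depth$z)) else
      volume$depth$z >= region$z[1] & volume$depth$z <= region$z[2]
    if (!any(ix) || !any(iy) || !any(iz)) stop("empty region")
    abs(volume$A[ix, iy, iz, drop = FALSE])
  }
  s <- max(box(signal_region))
  nr <- sqrt(mean(box(noise_region)^2))
  if (nr == 0) return(Inf)
  20 * log10(s / nr)
}

#' Two-point resolution dip of a scatterer pair
#'
#' Takes the lateral profile along `axis` through the pair at the given
#' depth, locates the two highest local maxima separated by roughly
#' `separation_hint`, and reports the dip
#' `20 log10(mean peak / central minimum)` in dB together with a resolved
#' flag (`dip >= threshold_db`). A coincident (unresolved) pair returns a
#' 0 dB dip.
#'
#' @param volume an [oct_volume()]
#' @param depth depth of the pair (um)
#' @param separation_hint expected pair separation (um)
#' @param axis profile direction
#' @param threshold_db dip threshold for the resolved flag (default 3 dB)
#' @return list with `dip_db`, `resolved`, `peaks` (positions um)
#' @export
pair_dip <- function(volume, depth, separation_hint, axis = c("x", "y"),
                     threshold_db = 3) {
  axis <- match.arg(axis)
  q <- depth_index(volume, depth)
  amp <- abs(volume$A[, , q])
  g <- volume$grid
  if (axis == "x") {
    j <- which.max(apply(amp, 2, max))
    prof <- amp[, j]; coord <- g$x
  } else {
    i <- which.max(apply(amp, 1, max))
    prof <- amp[i, ]; coord <- g$y
  }
  n <- length(prof)
  loc <- which(diff(sign(diff(prof))) < 0) + 1
  loc <- loc[order(prof[loc], decreasing = TRUE)]
  if (length(loc) < 2) {
    # single maximum: coincident/unresolved pair
    return(list(dip_db = 0, resolved = FALSE,
                peaks = coord[which.max(prof)]))
  }
  p1 <- loc[1]
  # second peak: strongest local max at a plausible pair distance from p1
  cand <- loc[-1][abs(abs(coord[loc[-1]] - coord[p1]) - separation_hint) <
                    0.75 * separation_hint]
  if (length(cand) == 0) {
    return(list(dip_db = 0, resolved = FALSE, peaks = coord[p1]))
  }
  p2 <- cand[1]
  lo <- min(p1, p2); hi <- max(p1, p2)
  valley <- min(prof[lo:hi])
  dip <- 20 * log10(mean(prof[c(p1, p2)]) / max(valley, .Machine$double.xmin))
  list(dip_db = dip, resolved = dip >= threshold_db,
       peaks = sort(coord[c(p1, p2)]))
}

#' Point-image metrics at a set of depths
#'
#' Per-depth lateral 1/e image half-width, recovered beam radius
#' (`sqrt(2)` x half-width), Gaussian-equivalent FWHM and peak amplitude in
#' dB relative to the brightest evaluated depth. All metrics are invariant
#' to global complex phase and amplitude rescaling of the volume.
#'
#' @param volume an [oct_volume()]
#' @param depths depths to evaluate (um)
#' @param ... passed to [lateral_width()]
#' @return a tibble with one row per depth
#' @export
metrics_report <- function(volume, depths, ...) {
  rows <- lapply(depths, function(z) {
    q <- depth_index(volume, z)
    w <- lateral_width(volume, z, ...)
    tibble::tibble(
      depth_um = z,
      image_halfwidth_um = w,
      beam_radius_um = sqrt(2) * w,
      fwhm_um = 2 * sqrt(log(2)) * w,
      peak_amplitude = max(abs(volume$A[, , q]))
    )
  })
  out <- do.call(rbind, rows)
  out$peak_db <- 20 * log10(out$peak_amplitude / max(out$peak_amplitude))
  out
}
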