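#' Save / load an OCT volume
#'
#' Lossless persistence of the complex volume together with its grids,
#' spectrum, beam metadata and provenance, using R's native serialization.
#' `load_volume` validates the container schema (class and required fields)
#' and refuses files that do not round-trip to a well-formed volume.
#'
#' @param volume an [oct_volume()]
#' @param path file path (conventionally `.rds`)
#' @return `load_volume` returns the [oct_volume()]
#' @export
save_volume <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  payload <- list(format = "kspaceoct_volume", version = 1L, volume = volume)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_volume
#' @export
load_volume <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read volume container: ", conditionMessage(e)))
  if (!is.list(payload) || !identical(payload$format, "kspaceoct_volume"))
    stop("not a kspaceoct volume container")
  if (!identical(payload$version, 1L))
    stop("unsupported volume container version: ", payload$version)
  v <- payload$volume
  need <- c("A", "grid", "depth")
  miss <- need[!need %in% names(v)]
  if (length(miss))
    stop("volume container missing fields: ", paste(miss, collapse = ", "))
  if (!inherits(v$grid, "lateral_grid") || !inherits(v$depth, "depth_axis"))
    stop("volume container missing axis metadata")
  oct_volume(v$A, v$grid, v$depth, spectrum = v$spectrum, beam = v$beam,
             provenance = v$provenance %||% character())
}

#' Export B-scan / en-face images of a volume
#'
#' Writes a 16-bit grayscale TIFF (linear amplitude, normalized to the
#' volume peak) and an 8-bit PNG (log-compressed with a configurable dB
#' floor; values below the floor map to 0). Requires the `tiff` and `png`
#' packages.
#'
#' @param volume an [oct_volume()]
#' @param plane `"bscan"` (x-z through `y`) or `"enface"` (x-y at depth `z`)
#' @param path output path without extension; `.tif` and `.png` are appended
#' @param y y position for the B-scan plane (um)
#' @param z depth for the en-face plane (um)
#' @param db_floor log-compression floor (dB, negative)
#' @return invisibly, the written paths
#' @export
export_images <- function(volume, plane = c("bscan", "enface"), path,
                          y = 0, z = NULL, db_floor = -40) {
  plane <- match.arg(plane)
  amp <- abs(volume$A)
  peak <- max(amp)
  img <- if (plane == "bscan") {
    j <- which.min(abs(volume$grid$y - y))
    t(amp[, j, ])                      # rows = depth, cols = x
  } else {
    if (is.null(z)) stop("en-face export needs a depth z")
    amp[, , depth_index(volume, z)]
  }
  lin <- img / max(peak, .Machine$double.xmin)
  db <- 20 * log10(pmax(lin, .Machine$double.xmin))
  logimg <- pmax(db - db_floor, 0) / (-db_floor)
  paths <- paste0(path, c(".tif", ".png"))
  if (!requireNamespace("tiff", quietly = TRUE) ||
      !requireNamespace("png", quietly = TRUE))
    stop("export_images needs the 'tiff' and 'png' packages")
  tiff::writeTIFF(lin, paths[1], bits.per.sample = 16)
  png::writePNG(logimg, paths[2])
  invisible(paths)
}

#' Read a run configuration from YAML or JSON
#'
#' Builds the simulation objects from a plain config file. All physical
#' quantities carry explicit unit suffixes in their keys (`*_um`, `*_rad_um`,
#' `*_db`) to prevent unit drift. Top-level sections: `grid`, `spectrum`,
#' `beam`, `scene`, `noise` (optional), `depth` (optional).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file
#' @return list with `config` (a [sim_config()]), `scene`, and `noise`
#'   (list with `snr_db`, `seed`, or NULL)
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::yaml.load_file(path)
  need <- c("grid", "spectrum", "beam", "scene")
  miss <- need[!need %in% names(raw)]
  if (length(miss))
    stop("config missing sections: ", paste(miss, collapse = ", "))
  g <- raw$grid
  grid <- lateral_grid(g$n_x, g$n_y %||% g$n_x, g$dx_um, g$dy_um %||% g$dx_um)
  s <- raw$spectrum
  spec <- source_spectrum(s$lambda0_um, s$fractional_bandwidth %||% 0.03,
                          s$n_k %||% 32, s$envelope %||% "gaussian")
  b <- raw$beam
  ab <- if (!is.null(b$aberration)) {
    terms <- lapply(b$aberration$terms, function(t)
      list(n = t$n, m = t$m, A0 = t$A0_rad))
    aberration_function(terms, Ra = b$aberration$Ra_um)
  }
  beam <- beam_spec(b$kind,
                    WL = b$WL_um, W0 = b$W0_um, z0 = b$z0_um, a = b$a_um,
                    W_amp = b$W_amp_um, beta = b$beta_rad_um,
                    lambda0_um = s$lambda0_um, aberration = ab)
  sc <- raw$scene
  scene <- switch(sc$kind %||% "chain",
    chain = chain_scene(sc$n_scatterers %||% 7, sc$z_min_um %||% 24,
                        sc$z_max_um %||% 480,
                        x = sc$x_um %||% 0, y = sc$y_um %||% 0),
    pair_chain = pair_chain_scene(sc$n_pairs %||% 7, sc$separation_um %||% 12,
                                  sc$z_min_um %||% 24, sc$z_max_um %||% 480),
    table = read_scene(sc$path),
    stop("unknown scene kind: ", sc$kind)
  )
  cfg <- sim_config(grid, spec, beam,
                    z_d = raw$z_d_um %||% 0,
                    propagator_mode = raw$propagator %||% "full",
                    pad_factor = raw$pad_factor %||% 2L,
                    z_min = raw$depth$z_min_um %||% 0)
  noise <- if (!is.null(raw$noise))
    list(snr_db = raw$noise$snr_db, seed = raw$noise$seed)
  list(config = cfg, scene = scene, noise = noise)
}
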