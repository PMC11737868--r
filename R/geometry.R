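#' Reduced two-layer cochlear geometry
#'
#' Builds the reduced 2D fluid domain used throughout the package: a Corti
#' duct (the extracellular fluid space of the organ of Corti) stacked above
#' the scala tympani, separated by the basilar membrane, running from base
#' (x = 0) to apex (x = L). The radial dimension has been collapsed, so each
#' layer is a channel of constant (or tabulated) height. A Greenwood-form
#' place-frequency map ties each place to its characteristic frequency (CF).
#'
#' The default map constants are published gerbil values
#' (CF(x) = A (10^(a (1 - x/L)) - k) with A = 398 Hz, a = 2.2, k = 0.631),
#' giving ~63 kHz at the base and ~147 Hz at the apex of a 12 mm duct. All
#' constants are configurable so other species' maps can be substituted.
#'
#' @param length_m duct length base to apex in meters (gerbil: 0.012)
#' @param corti_height_m height of the Corti fluid layer (m)
#' @param scala_height_m height of the scala tympani layer (m)
#' @param membrane_thickness_m basilar-membrane thickness; the flow model
#'   treats the membrane as a zero-thickness Darcy interface, so this is
#'   metadata only
#' @param pf_map_params list with elements `A_hz`, `a`, `k` of the
#'   Greenwood-form map
#' @param grid list with `nx` (axial cells), `ny_corti`, `ny_scala`
#'   (vertical cells per layer)
#' @return an object of class `cochlear_geometry`
#' @seealso [cf_from_place()], [place_from_cf()], [synthesize_wave()]
#' @export
cochlear_geometry <- function(length_m = 0.012,
                              corti_height_m = 150e-6,
                              scala_height_m = 400e-6,
                              membrane_thickness_m = 0,
                              pf_map_params = list(A_hz = 398, a = 2.2, k = 0.631),
                              grid = list(nx = 240L, ny_corti = 12L, ny_scala = 32L)) {
  check_positive(length_m, "length_m")
  check_positive(corti_height_m, "corti_height_m")
  check_positive(scala_height_m, "scala_height_m")
  check_nonnegative(membrane_thickness_m, "membrane_thickness_m")
  for (f in c("A_hz", "a", "k")) {
    if (is.null(pf_map_params[[f]])) stop_validation(paste0("pf_map_params$", f), "missing")
  }
  check_positive(pf_map_params$A_hz, "pf_map_params$A_hz")
  check_positive(pf_map_params$a, "pf_map_params$a")
  check_nonnegative(pf_map_params$k, "pf_map_params$k")
  if (pf_map_params$k >= 1)
    stop_validation("pf_map_params$k", "must be < 1 so CF stays positive at the apex")
  grid$nx <- as.integer(grid$nx %||% 240L)
  grid$ny_corti <- as.integer(grid$ny_corti %||% 12L)
  grid$ny_scala <- as.integer(grid$ny_scala %||% 24L)
  check_positive(grid$nx, "grid$nx")
  check_positive(grid$ny_corti, "grid$ny_corti")
  check_positive(grid$ny_scala, "grid$ny_scala")

  geom <- structure(
    list(length_m = length_m,
         corti_height_m = corti_height_m,
         scala_height_m = scala_height_m,
         membrane_thickness_m = membrane_thickness_m,
         pf_map_params = pf_map_params[c("A_hz", "a", "k")],
         grid = grid),
    class = "cochlear_geometry")
  # derived grid coordinates (cell centers along x)
  geom$x_centers_m <- (seq_len(grid$nx) - 0.5) * length_m / grid$nx
  geom
}

#' @export
print.cochlear_geometry <- function(x, ...) {
  cat("<cochlear_geometry>\n")
  cat(sprintf("  length: %.3g mm; Corti duct %.0f um over scala tympani %.0f um\n",
              x$length_m * 1e3, x$corti_height_m * 1e6, x$scala_height_m * 1e6))
  cat(sprintf("  CF range: %.3g kHz (base) -> %.3g kHz (apex)\n",
              cf_from_place(x, 0) / 1e3, cf_from_place(x, x$length_m) / 1e3))
  cat(sprintf("  grid: nx = %d, ny = %d (Corti) + %d (scala)\n",
              x$grid$nx, x$grid$ny_corti, x$grid$ny_scala))
  invisible(x)
}

#' Build a geometry from a structured config
#'
#' Accepts a list (e.g. parsed from YAML) or a path to a YAML file with a
#' `geometry` section whose keys mirror the [cochlear_geometry()] arguments.
#' All physical quantities are SI with unit suffixes in the key names.
#'
#' @param config list or path to a YAML file
#' @return a `cochlear_geometry`
#' @export
build_geometry <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  g <- config$geometry %||% config
  cochlear_geometry(
    length_m = g$length_m %||% 0.012,
    corti_height_m = g$corti_height_m %||% 150e-6,
    scala_height_m = g$scala_height_m %||% 400e-6,
    membrane_thickness_m = g$membrane_thickness_m %||% 0,
    pf_map_params = g$pf_map_params %||% list(A_hz = 398, a = 2.2, k = 0.631),
    grid = g$grid %||% list(nx = 240L, ny_corti = 12L, ny_scala = 32L))
}

#' Serialize a geometry to a YAML config
#'
#' Writes a config that [build_geometry()] reads back to an identical
#' geometry.
#'
#' @param geom a `cochlear_geometry`
#' @param path file path; if `NULL`, the YAML text is returned
#' @export
write_geometry <- function(geom, path = NULL) {
  stopifnot(inherits(geom, "cochlear_geometry"))
  cfg <- list(geometry = geom[c("length_m", "corti_height_m", "scala_height_m",
                                "membrane_thickness_m", "pf_map_params", "grid")])
  if (is.null(path)) yaml::as.yaml(cfg) else yaml::write_yaml(cfg, path)
}

#' Place-frequency map
#'
#' `cf_from_place()` maps a place x (meters from the base) to its
#' characteristic frequency; `place_from_cf()` is the exact inverse. The map
#' is strictly decreasing from base to apex (tonotopy).
#'
#' @param geom a `cochlear_geometry`
#' @param x place in meters from the base, in `[0, L]`
#' @return frequency in Hz (`cf_from_place`) or place in meters
#'   (`place_from_cf`); vectorized
#' @export
cf_from_place <- function(geom, x) {
  stopifnot(inherits(geom, "cochlear_geometry"))
  if (any(x < 0 | x > geom$length_m))
    stop("place x outside [0, L]", call. = FALSE)
  p <- geom$pf_map_params
  p$A_hz * (10^(p$a * (1 - x / geom$length_m)) - p$k)
}

#' @param f frequency in Hz, within the map range
#' @rdname cf_from_place
#' @export
place_from_cf <- function(geom, f) {
  stopifnot(inherits(geom, "cochlear_geometry"))
  p <- geom$pf_map_params
  f_min <- cf_from_place(geom, geom$length_m)
  f_max <- cf_from_place(geom, 0)
  if (any(f < f_min | f > f_max))
    stop(sprintf("frequency outside map range [%.4g, %.4g] Hz", f_min, f_max),
         call. = FALSE)
  geom$length_m * (1 - log10(f / p$A_hz + p$k) / p$a)
}

#' Acoustic stimulus description
#'
#' @param kind one of `"tone"`, `"broadband"`, `"silence"`
#' @param frequency_hz tone frequency (tone only)
#' @param band_hz length-2 vector, band edges in Hz (broadband only)
#' @param level_db_spl sound level in dB SPL re 20 uPa (`-Inf` = no sound)
#' @return an object of class `stimulus`
#' @export
stimulus <- function(kind = c("tone", "broadband", "silence"),
                     frequency_hz = NULL, band_hz = NULL, level_db_spl = 80) {
  kind <- match.arg(kind)
  if (!is.numeric(level_db_spl) || length(level_db_spl) != 1L || is.nan(level_db_spl) ||
      level_db_spl == Inf)
    stop_validation("level_db_spl", "must be a single number (or -Inf)")
  if (kind == "tone") {
    check_positive(frequency_hz, "frequency_hz")
    if (length(frequency_hz) != 1L) stop_validation("frequency_hz", "must be scalar")
  }
  if (kind == "broadband") {
    if (is.null(band_hz) || length(band_hz) != 2L || band_hz[1] >= band_hz[2])
      stop_validation("band_hz", "must be increasing length-2 band edges")
  }
  structure(list(kind = kind, frequency_hz = frequency_hz, band_hz = band_hz,
                 level_db_spl = level_db_spl), class = "stimulus")
}
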