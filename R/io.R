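# CSV table I/O for localizations, pairs and spectra. Files carry a
# provenance header as '#' comment lines (tool version, seed, config hash)
# which readers skip; column order on disk is free, extra columns are
# preserved, and rows are written in deterministic (frame, x) order.

LOC_COLUMNS <- c("frame", "x_nm", "y_nm", "sigma_x_nm", "sigma_y_nm",
                 "photons", "background", "uncertainty_nm", "order")
PAIR_COLUMNS <- c("frame", "x0_nm", "y0_nm", "x1_nm", "y1_nm", "d_nm",
                  "lateral_nm", "sigma1_nm", "sigma_excess_nm", "lambda_nm",
                  "label")

provenance_header <- function(seed = NULL, extra = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("specpair")),
                  error = function(e) "dev")
  c(sprintf("# specpair %s", ver),
    if (!is.null(seed)) sprintf("# seed: %s", seed),
    if (!is.null(extra)) paste("#", extra))
}

write_table_with_header <- function(df, path, seed = NULL, extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, extra), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_table_checked <- function(path, mandatory, what) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols))
    stop(what, " file ", path, " is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Write / read a localization table
#'
#' CSV with the column set `frame, x_nm, y_nm, sigma_x_nm, sigma_y_nm,
#' photons, background, uncertainty_nm, order` (a superset-compatible layout
#' for common SMLM table formats). Extra columns are preserved; rows are
#' ordered by frame then x; numeric round trip is exact to well below
#' 1e-6 nm.
#'
#' @param locs Localization data frame.
#' @param path File path.
#' @param seed Optional seed recorded in the provenance header.
#' @return `write_localizations`: the path, invisibly;
#'   `read_localizations`: the data frame.
#' @export
write_localizations <- function(locs, path, seed = NULL) {
  miss <- setdiff(LOC_COLUMNS, names(locs))
  if (length(miss)) stop("localization table lacks column(s): ",
                         paste(miss, collapse = ", "))
  locs <- locs[order(locs$frame, locs$x_nm), , drop = FALSE]
  write_table_with_header(locs, path, seed = seed)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  read_table_checked(path, LOC_COLUMNS, "localization")
}

#' Write / read a spectral-pair table
#'
#' @param pairs Pairs data frame (see [link_orders()]).
#' @inheritParams write_localizations
#' @return `write_pairs`: the path, invisibly; `read_pairs`: the data frame.
#' @export
write_pairs <- function(pairs, path, seed = NULL) {
  miss <- setdiff(PAIR_COLUMNS, names(pairs))
  if (length(miss)) stop("pair table lacks column(s): ",
                         paste(miss, collapse = ", "))
  pairs <- pairs[order(pairs$frame, pairs$x0_nm), , drop = FALSE]
  write_table_with_header(pairs, path, seed = seed)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  read_table_checked(path, setdiff(PAIR_COLUMNS, "label"), "pair")
}

#' Read / write a spectrum or transmission profile as two-column CSV
#'
#' Column 1 is wavelength (nm), column 2 the value (intensity or
#' transmission); a header line is optional on read.
#'
#' @param path File path.
#' @param name,quantum_yield,corrected Spectrum metadata (read only).
#' @return `read_spectrum_csv`: an [emission_spectrum()];
#'   `read_transmission_csv`: a [transmission_profile()].
#' @export
read_spectrum_csv <- function(path, name = basename(path),
                              quantum_yield = 1, corrected = FALSE) {
  df <- read_two_column(path)
  emission_spectrum(df[[1]], df[[2]], name = name,
                    quantum_yield = quantum_yield, corrected = corrected)
}

#' @rdname read_spectrum_csv
#' @export
read_transmission_csv <- function(path) {
  df <- read_two_column(path)
  transmission_profile(df[[1]], df[[2]])
}

#' @rdname read_spectrum_csv
#' @param spectrum An [emission_spectrum()] or [transmission_profile()].
#' @export
write_spectrum_csv <- function(spectrum, path) {
  if (inherits(spectrum, "emission_spectrum")) {
    df <- data.frame(wavelength_nm = spectrum$wavelengths_nm,
                     intensity = spectrum$intensities)
  } else {
    df <- data.frame(wavelength_nm = spectrum$wavelengths_nm,
                     transmission = spectrum$transmission)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_two_column <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- !grepl("^\\s*[0-9.+-]", first)
  df <- utils::read.csv(path, header = has_header, comment.char = "#",
                        stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected two columns in ", path)
  df[, 1:2]
}

#' Load and validate a pipeline configuration
#'
#' JSON file with nested sections `optics`, `noise`, `calibration`,
#' `simulate`, `localize`, `pair`, `classify`, `fret`, plus a global `seed`
#' and a `stages` list. Unknown top-level or section keys are rejected with
#' a message naming them; missing values fall back to package defaults.
#'
#' @param path JSON config path.
#' @return A validated named list with class `pipeline_config`; the
#'   `optics` and `calibration` sections are materialized as
#'   [optical_config()] / [dispersion_calibration()] objects.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- c("optics", "noise", "calibration", "simulate", "localize",
             "pair", "classify", "fret", "seed", "stages", "out_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  check_section <- function(section, allowed) {
    extra <- setdiff(names(cfg[[section]]), allowed)
    if (length(extra))
      stop("unknown key(s) in config section '", section, "': ",
           paste(extra, collapse = ", "))
  }
  check_section("optics", names(formals(optical_config)))
  check_section("noise", setdiff(names(formals(noise_model)), "seed"))
  check_section("calibration", names(formals(dispersion_calibration)))
  check_section("simulate", c("fov_px", "n_frames", "n_emitters", "dye",
                              "photons", "density_per_um2"))
  check_section("localize", c("threshold_factor", "window_px", "model",
                              "min_sep_px"))
  check_section("pair", c("d_window", "lateral_tol_nm"))
  check_section("classify", c("n_components", "bin_nm", "cutoff_nm"))
  check_section("fret", c("bin_nm", "n_states"))
  cfg$optics <- do.call(optical_config, as.list(cfg$optics))
  cfg$calibration <- if (length(cfg$calibration))
    do.call(dispersion_calibration, as.list(cfg$calibration))
  else default_calibration()
  structure(cfg, class = "pipeline_config")
}
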