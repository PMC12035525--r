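#' Specific absorption coefficient tables for the plate model
#'
#' Returns the wavelength-indexed table of per-constituent specific
#' absorption coefficients and the leaf refractive index used by
#' [prospect_forward()]. Three model variants are supported: `"5"`
#' (chlorophyll, carotenoids, water, dry matter), `"5b"` (adds brown
#' pigments) and `"D"` (adds anthocyanins). Shared columns are identical
#' across variants; a variant simply switches constituents on or off.
#'
#' The coefficients bundled here are *synthetic* reference curves: smooth
#' analytic spectra with absorption features placed at the well-known
#' positions (chlorophyll at ~430/662 nm, carotenoids below 550 nm,
#' anthocyanins around 546 nm, liquid-water overtones at 970, 1200, 1450,
#' 1940 and 2500 nm, dry-matter features in the SWIR) and magnitudes chosen
#' so that typical leaf parameter values produce realistic vegetation
#' spectra. They are public-constant stand-ins, not a published calibration;
#' users with a calibrated table can supply their own via
#' [read_coefficient_table()]. Tests of the leaf model therefore rely on
#' invariants (energy conservation, linearity, monotonicity), not on pinned
#' reflectance values tied to a particular calibration.
#'
#' @param variant One of `"D"`, `"5b"`, `"5"`.
#' @return A tibble with columns `wavelength_nm`, `refractive_index`,
#'   `k_cab`, `k_car`, `k_can`, `k_brown`, `k_cw`, `k_cm` on the 1-nm grid.
#'   Constituents absent from a variant have all-zero columns.
#' @export
#' @examples
#' tab <- prospect_coefficients("D")
#' dplyr::glimpse(tab)
prospect_coefficients <- function(variant = c("D", "5b", "5")) {
  variant <- match.arg(variant)
  wl <- as.numeric(spectral_grid())
  g <- function(center, width) exp(-0.5 * ((wl - center) / width)^2)

  # Chlorophyll absorption ends sharply past the red edge (~720 nm).
  red_cut <- 1 / (1 + exp((wl - 715) / 12))
  k_cab <- (0.090 * g(430, 32) + 0.065 * g(662, 26) + 0.018 * g(600, 55)) *
    red_cut
  k_car <- 0.060 * g(420, 26) + 0.130 * g(450, 24) + 0.100 * g(483, 22)
  k_can <- 0.110 * g(546, 33)
  k_brown <- 0.80 * exp(-((wl - 400) / 250)^1.3)
  k_cw <- 2.0 * g(970, 45) + 12 * g(1200, 55) + 65 * g(1450, 65) +
    18 * g(1780, 90) + 130 * g(1940, 85) + 90 * g(2270, 120) +
    160 * g(2600, 180)
  k_cm <- 1.2 + 4 * g(1730, 60) + 9 * g(2100, 80) + 12 * g(2310, 70) +
    18 * g(2500, 150)
  refr <- 1.40 + 0.12 * exp(-(wl - 400) / 700)

  zero <- numeric(length(wl))
  if (variant == "5") {
    k_can <- zero
    k_brown <- zero
  } else if (variant == "5b") {
    k_can <- zero
  }

  tibble::tibble(
    wavelength_nm = wl,
    refractive_index = refr,
    k_cab = k_cab,
    k_car = k_car,
    k_can = k_can,
    k_brown = k_brown,
    k_cw = k_cw,
    k_cm = k_cm
  )
}

# Column order expected in any coefficient table.
coef_columns <- function() {
  c(
    "wavelength_nm", "refractive_index", "k_cab", "k_car", "k_can",
    "k_brown", "k_cw", "k_cm"
  )
}

validate_coefficient_table <- function(table) {
  missing <- setdiff(coef_columns(), names(table))
  if (length(missing) > 0) {
    stop(
      "coefficient table is missing columns: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(table) != n_grid() ||
    !isTRUE(all.equal(as.numeric(table$wavelength_nm), as.numeric(spectral_grid())))) {
    stop("coefficient table must be on the 1-nm 400-2500 nm grid", call. = FALSE)
  }
  kcols <- setdiff(coef_columns(), c("wavelength_nm", "refractive_index"))
  if (any(vapply(table[kcols], function(x) any(x < 0 | !is.finite(x)), logical(1)))) {
    stop("specific absorption coefficients must be finite and >= 0", call. = FALSE)
  }
  if (any(table$refractive_index <= 1)) {
    stop("refractive index must exceed 1", call. = FALSE)
  }
  invisible(table)
}

#' Read or write a coefficient table as delimited text
#'
#' Tables are plain tab-separated text with a header row; wavelengths on
#' grids other than the common 1-nm grid are linearly interpolated on read.
#'
#' @param path File path.
#' @param table A coefficient table (for writing).
#' @return `read_coefficient_table()` returns a validated tibble on the
#'   common grid; `write_coefficient_table()` returns `path` invisibly.
#' @export
read_coefficient_table <- function(path) {
  raw <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  missing <- setdiff(coef_columns(), names(raw))
  if (length(missing) > 0) {
    stop(
      "coefficient file is missing columns: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::tibble(wavelength_nm = as.numeric(spectral_grid()))
  for (col in setdiff(coef_columns(), "wavelength_nm")) {
    out[[col]] <- regrid(raw$wavelength_nm, raw[[col]])
  }
  validate_coefficient_table(out)
  out
}

#' @rdname read_coefficient_table
#' @export
write_coefficient_table <- function(table, path) {
  validate_coefficient_table(table)
  utils::write.table(
    table, path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
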