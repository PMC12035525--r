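#' Read and write spectra tables
#'
#' Spectra are exchanged as delimited text with a `wavelength_nm` column
#' plus one or more value columns (`reflectance`, optionally
#' `transmittance`). On read, rows outside 400--2500 nm are dropped (with
#' a message recording the count) and the remainder is linearly
#' interpolated onto the common 1-nm grid; the source grid and number of
#' dropped rows are kept as attributes.
#'
#' @param path File path.
#' @param x Tibble with `wavelength_nm` and value columns (for writing).
#' @param sep Field separator (default tab).
#' @return `read_spectra()`: a tibble on the common grid with attributes
#'   `source_grid` and `n_dropped`. `write_spectra()`: `path`,
#'   invisibly.
#' @export
read_spectra <- function(path, sep = "\t") {
  raw <- utils::read.delim(path, sep = sep, comment.char = "#", check.names = FALSE)
  if (!"wavelength_nm" %in% names(raw)) {
    stop("spectra file needs a wavelength_nm column", call. = FALSE)
  }
  if (is.unsorted(raw$wavelength_nm, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  vcols <- setdiff(names(raw), "wavelength_nm")
  if (length(vcols) == 0) stop("no value columns found", call. = FALSE)
  inside <- raw$wavelength_nm >= 400 & raw$wavelength_nm <= 2500
  n_dropped <- sum(!inside)
  if (n_dropped > 0) {
    message("dropped ", n_dropped, " rows outside 400-2500 nm")
  }
  kept <- raw[inside, ]
  if (nrow(kept) < 2) stop("too few in-range rows", call. = FALSE)
  out <- tibble::tibble(wavelength_nm = as.numeric(spectral_grid()))
  for (cl in vcols) out[[cl]] <- regrid(kept$wavelength_nm, kept[[cl]])
  attr(out, "source_grid") <- kept$wavelength_nm
  attr(out, "n_dropped") <- n_dropped
  out
}

#' @rdname read_spectra
#' @export
write_spectra <- function(x, path, sep = "\t") {
  if (!"wavelength_nm" %in% names(x)) {
    stop("spectra need a wavelength_nm column", call. = FALSE)
  }
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration with optional blocks `leaf` (and
#' `leaf_liana` / `leaf_tree`), `canopy`, `geometry`, `sampler` and
#' `scene`, applies defaults, and validates all bounds at once: every
#' violation is collected and reported together. Unknown keys are an
#' error in strict mode.
#'
#' @param path YAML file path.
#' @param strict Error on unknown keys.
#' @return A list of class `run_config` with validated blocks and a
#'   `hash` field (digest of the normalized content) for reproducibility
#'   manifests.
#' @export
load_config <- function(path, strict = TRUE) {
  raw <- yaml::read_yaml(path)
  known_blocks <- c(
    "leaf", "leaf_liana", "leaf_tree", "canopy", "geometry",
    "sampler", "scene", "seed"
  )
  problems <- character(0)
  if (strict) {
    extra <- setdiff(names(raw), known_blocks)
    if (length(extra) > 0) {
      problems <- c(problems, paste("unknown block(s):", paste(extra, collapse = ", ")))
    }
  }

  defaults <- list(
    leaf = list(
      N = 1.5, C_ab = 40, C_ar = 10, C_an = 0, C_br = 0,
      C_w = 0.01, C_m = 0.009
    ),
    canopy = list(
      lai = 5.5, omega1 = 27.9, omega2 = 37.1, f2 = 0.66, L = 1, D = 1,
      hot = 0.05, omega_soil = 0.5, Cv = 1, zeta = 0.5
    ),
    geometry = list(tts = 30, tto = 0, psi = 0),
    sampler = list(n_chains = 3, n_iter = 2000, seed = NULL),
    scene = list(
      cluster_area = 2000, prevalence = 0.5, L = 1, grid_size = 1000
    )
  )
  bounds <- list(
    canopy = list(
      lai = c(0, 30), omega1 = c(5, 85), omega2 = c(5, 85), f2 = c(0, 1),
      L = c(0, 1), D = c(0, 1), hot = c(0, 1), omega_soil = c(0, 1)
    ),
    geometry = list(tts = c(0, 89.999), tto = c(0, 89.999), psi = c(0, 360)),
    leaf = list(
      N = c(1, 3.5), C_ab = c(0, 150), C_ar = c(0, 50), C_an = c(0, 20),
      C_br = c(0, 5), C_w = c(0, 0.1), C_m = c(0, 0.05)
    )
  )

  cfg <- list()
  for (blk in names(defaults)) {
    user <- raw[[blk]] %||% list()
    if (strict && length(user) > 0) {
      extra <- setdiff(names(user), names(defaults[[blk]]))
      if (length(extra) > 0) {
        problems <- c(problems, paste0(
          blk, ": unknown key(s): ", paste(extra, collapse = ", ")
        ))
      }
    }
    merged <- utils::modifyList(defaults[[blk]], user[names(user) %in% names(defaults[[blk]])])
    bnd <- bounds[[blk]]
    for (key in names(bnd)) {
      v <- merged[[key]]
      if (!is.null(v) && (v < bnd[[key]][1] || v > bnd[[key]][2])) {
        problems <- c(problems, sprintf(
          "%s$%s = %g outside [%g, %g]", blk, key, v,
          bnd[[key]][1], bnd[[key]][2]
        ))
      }
    }
    cfg[[blk]] <- merged
  }
  for (blk in c("leaf_liana", "leaf_tree")) {
    if (!is.null(raw[[blk]])) {
      merged <- utils::modifyList(defaults$leaf, raw[[blk]])
      cfg[[blk]] <- merged
    }
  }
  cfg$seed <- raw$seed %||% cfg$sampler$seed

  if (length(problems) > 0) {
    stop(
      "invalid configuration:\n  ", paste(problems, collapse = "\n  "),
      call. = FALSE
    )
  }
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "run_config")
}

# Deterministic content hash without external digest dependencies:
# serialize the normalized list to a canonical string and hash with two
# independent polynomial rolling hashes (moduli small enough that all
# arithmetic stays exact in doubles).
config_hash <- function(cfg) {
  cfg$hash <- NULL
  txt <- paste(utils::capture.output(utils::str(cfg, digits.d = 12)), collapse = "\n")
  bytes <- utf8ToInt(txt)
  m1 <- 67108859
  m2 <- 67108879
  h1 <- 17
  h2 <- 59
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% m1
    h2 <- (h2 * 37 + b) %% m2
  }
  sprintf("%08x%08x", h1, h2)
}

#' Write a reproducibility manifest for a run
#'
#' Records the configuration hash, seed and package version next to a
#' run's outputs so that deterministic stages can be reproduced
#' bit-for-bit.
#'
#' @param path Output file (YAML).
#' @param config A `run_config` (or any list with a `hash`).
#' @param seed The seed used.
#' @param extra Optional named list of additional fields.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, extra = list()) {
  manifest <- c(
    list(
      config_hash = config$hash %||% config_hash(config),
      seed = seed,
      package = "lianasignal",
      version = as.character(utils::packageVersion("lianasignal")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    extra
  )
  yaml::write_yaml(manifest, path)
  invisible(path)
}
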