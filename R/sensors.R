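#' Sensor spectral response models
#'
#' A `sensor_model` is a set of spectral bands, each defined by normalized
#' response weights on the common 1-nm grid. Built-in models are boxcar
#' approximations constructed from published band edges:
#'
#' * `landsat5_tm` -- the six reflective Thematic Mapper bands
#'   (450--520, 520--600, 630--690, 760--900, 1550--1750, 2080--2350 nm;
#'   the thermal band is excluded).
#' * `worldview2` -- the eight WV110 multispectral bands
#'   (coastal through NIR2, 400--1040 nm).
#' * `hyperion` -- 10-nm contiguous boxcar bands over 427--2395 nm with
#'   the water-vapour-dominated intervals (1346--1427, 1790--1950,
#'   2365--2500 nm) removed, giving about 170 usable bands.
#'
#' Boxcars are a deliberate simplification: band-ordering conclusions
#' drawn from convolved divergences are insensitive to the exact response
#' shape. Full response tables can be supplied via [load_srf()].
#'
#' @param name Built-in sensor name.
#' @return A list of class `sensor_model` with elements `sensor` (name)
#'   and `bands`, a tibble `band_id`, `center_nm`, and a weights matrix
#'   `weights` (bands x wavelengths) with non-negative rows summing to 1.
#' @export
#' @examples
#' sensor_model("landsat5_tm")$bands
sensor_model <- function(name = c("landsat5_tm", "worldview2", "hyperion")) {
  name <- match.arg(name)
  edges <- switch(name,
    landsat5_tm = data.frame(
      band_id = c("B1", "B2", "B3", "B4", "B5", "B7"),
      lo = c(450, 520, 630, 760, 1550, 2080),
      hi = c(520, 600, 690, 900, 1750, 2350)
    ),
    worldview2 = data.frame(
      band_id = c(
        "coastal", "blue", "green", "yellow", "red", "rededge",
        "nir1", "nir2"
      ),
      lo = c(400, 450, 510, 585, 630, 705, 770, 860),
      hi = c(450, 510, 580, 625, 690, 745, 895, 1040)
    ),
    hyperion = hyperion_edges()
  )
  build_sensor(name, edges)
}

# Contiguous 10-nm Hyperion-like bands with atmospheric water-vapour
# windows removed.
hyperion_edges <- function() {
  lo <- seq(427, 2385, by = 10)
  hi <- lo + 10
  bad <- (lo >= 1346 & lo < 1427) | (lo >= 1790 & lo < 1950) | lo >= 2365
  keep <- !bad
  data.frame(
    band_id = sprintf("H%03d", seq_len(sum(keep))),
    lo = lo[keep], hi = hi[keep]
  )
}

build_sensor <- function(name, edges) {
  wl <- spectral_grid()
  w <- matrix(0, nrow(edges), length(wl))
  for (i in seq_len(nrow(edges))) {
    inb <- wl >= edges$lo[i] & wl <= edges$hi[i]
    w[i, inb] <- 1
  }
  normalize_sensor(name, edges$band_id, w)
}

normalize_sensor <- function(name, band_id, w) {
  rs <- rowSums(w)
  if (any(rs <= 0)) stop("every band needs positive response weight", call. = FALSE)
  if (any(w < 0)) stop("response weights must be >= 0", call. = FALSE)
  w <- w / rs
  centers <- as.numeric(w %*% spectral_grid())
  structure(
    list(
      sensor = name,
      bands = tibble::tibble(band_id = band_id, center_nm = centers),
      weights = w
    ),
    class = "sensor_model"
  )
}

#' Load a sensor model from a response table or by built-in name
#'
#' Response files are delimited text with columns `wavelength_nm`,
#' `band_id`, `weight`; weights are renormalized to sum to 1 per band
#' after mapping onto the common grid.
#'
#' @param x A built-in sensor name or a path to a response file.
#' @return A `sensor_model`.
#' @export
load_srf <- function(x) {
  if (x %in% c("landsat5_tm", "worldview2", "hyperion")) {
    return(sensor_model(x))
  }
  if (!file.exists(x)) {
    stop("unknown sensor name or missing file: ", x, call. = FALSE)
  }
  raw <- utils::read.delim(x, comment.char = "#", check.names = FALSE)
  need <- c("wavelength_nm", "band_id", "weight")
  if (!all(need %in% names(raw))) {
    stop(
      "response table needs columns: ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  ids <- unique(raw$band_id)
  wl <- spectral_grid()
  w <- matrix(0, length(ids), length(wl))
  for (i in seq_along(ids)) {
    sub <- raw[raw$band_id == ids[i], ]
    idx <- match(round(sub$wavelength_nm), wl)
    ok <- !is.na(idx)
    w[i, idx[ok]] <- sub$weight[ok]
  }
  normalize_sensor(basename(x), ids, w)
}

#' Convolve spectra to sensor bands
#'
#' Band means are the response-weighted average of the spectrum. For a
#' [spectral_distribution()], means convolve linearly and variances with
#' squared weights, consistent with independent per-wavelength errors.
#'
#' @param x Either a numeric spectrum on the common grid, a `leaf_optics`
#'   or `canopy_reflectance` tibble (its `reflectance`/`rho` column is
#'   used), or a `spectral_distribution`.
#' @param sensor A `sensor_model`.
#' @return A tibble with `band_id`, `center_nm` and `value` (or `mu`,
#'   `sigma` for distributions).
#' @export
band_convolve <- function(x, sensor) {
  stopifnot(inherits(sensor, "sensor_model"))
  w <- sensor$weights
  if (inherits(x, "spectral_distribution")) {
    mu <- as.numeric(w %*% x$mu)
    sig <- sqrt(as.numeric(w^2 %*% x$sigma^2))
    return(dplyr::mutate(sensor$bands, mu = mu, sigma = sig))
  }
  vec <- spectrum_vector(x)
  dplyr::mutate(sensor$bands, value = as.numeric(w %*% vec))
}

# Coerce supported spectrum containers to a bare vector on the grid.
spectrum_vector <- function(x) {
  if (is.numeric(x)) {
    if (length(x) != n_grid()) {
      stop("spectrum must be on the common 1-nm grid", call. = FALSE)
    }
    return(as.numeric(x))
  }
  if (is.data.frame(x)) {
    col <- intersect(c("rho", "reflectance", "value"), names(x))[1]
    if (is.na(col) || nrow(x) != n_grid()) {
      stop("cannot interpret spectrum input", call. = FALSE)
    }
    return(as.numeric(x[[col]]))
  }
  stop("cannot interpret spectrum input", call. = FALSE)
}
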