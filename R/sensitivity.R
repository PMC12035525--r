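#' Trait-swap sensitivity experiment
#'
#' Quantifies how much each parameter contributes to the liana spectral
#' signal. The baseline model is parameterized with tree traits in the
#' top canopy layer; its divergence from the liana-parameterized
#' reference distribution is `d_base`. For every requested swap set,
#' the named top-layer parameters are switched to their liana values,
#' the model re-run, and the impact reported as
#' `impact = d_base - d_swap`: positive impact means the swap moved the
#' predicted spectral distribution toward the liana signal. Per-
#' wavelength impacts are evaluated the same way at each wavelength
#' separately.
#'
#' Each model configuration defines a Gaussian spectral distribution
#' with mean equal to the predicted reflectance and a constant standard
#' deviation `residual_sd` (the inversion residual).
#'
#' @param tree_traits,liana_traits Named lists of the swappable
#'   parameters: the seven leaf parameters plus `angle` (the top-layer
#'   mean leaf inclination). Defaults come from [trait_defaults()].
#' @param swap_sets List of character vectors naming parameters to swap
#'   together; defaults to all single swaps.
#' @param residual_sd Residual reflectance standard deviation.
#' @param canopy,geom,soil Shared canopy configuration (the top layer's
#'   leaf type and angle are overridden per swap).
#' @param table Coefficient table.
#' @return A tibble of class `trait_swap_result` with one row per swap
#'   set: `swap` (label), `n_swapped`, `impact` (integrated), regional
#'   impacts `impact_vis`, `impact_nir`, `impact_swir`, and the baseline
#'   divergence `d_base` (attribute and column). Per-wavelength impact
#'   curves are in the `curves` attribute.
#' @export
trait_swap_experiment <- function(tree_traits = default_swap_traits("tree"),
                                  liana_traits = default_swap_traits("liana"),
                                  swap_sets = as.list(names(tree_traits)),
                                  residual_sd = 0.01,
                                  canopy = canopy_config(),
                                  geom = view_geometry(),
                                  soil = soil_model(canopy$omega_soil),
                                  table = prospect_coefficients("D")) {
  if (residual_sd <= 0) stop("residual_sd must be > 0", call. = FALSE)
  all_names <- names(tree_traits)
  if (!setequal(all_names, names(liana_traits))) {
    stop("tree and liana trait lists must share names", call. = FALSE)
  }
  bad <- setdiff(unique(unlist(swap_sets)), all_names)
  if (length(bad) > 0) {
    stop(
      "swap of unknown parameter(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }

  tree_leaf_full <- traits_to_leaf_params(tibble::as_tibble(
    tree_traits[setdiff(all_names, "angle")]
  ))
  diffuse <- diffuse_fraction(geom$tts)

  predict_rho <- function(traits) {
    top_leaf <- traits_to_leaf_params(tibble::as_tibble(
      traits[setdiff(all_names, "angle")]
    ))
    cc <- canopy
    cc$omega1 <- traits$angle %||% canopy$omega1
    couple_prosail2(
      top_leaf, tree_leaf_full, cc, geom, soil, table, diffuse
    )$rho
  }

  mu_ref <- predict_rho(liana_traits)
  mu_base <- predict_rho(tree_traits)
  kld_curve <- function(mu) {
    gaussian_kld_pointwise(mu, residual_sd, mu_ref, residual_sd)
  }
  base_curve <- kld_curve(mu_base)
  d_base <- trapz_grid(base_curve)

  wl <- spectral_grid()
  regions <- list(
    vis = wl >= 400 & wl < 700,
    nir = wl >= 700 & wl < 1300,
    swir = wl >= 1300
  )

  rows <- list()
  curves <- list()
  for (s in swap_sets) {
    traits <- tree_traits
    traits[s] <- liana_traits[s]
    curve <- kld_curve(predict_rho(traits))
    impact_curve <- base_curve - curve
    label <- if (length(s) == 0) "(none)" else paste(s, collapse = "+")
    rows[[length(rows) + 1L]] <- tibble::tibble(
      swap = label,
      n_swapped = length(s),
      impact = d_base - trapz_grid(curve),
      impact_vis = sum(impact_curve[regions$vis]),
      impact_nir = sum(impact_curve[regions$nir]),
      impact_swir = sum(impact_curve[regions$swir]),
      d_base = d_base
    )
    curves[[label]] <- tibble::tibble(
      wavelength_nm = as.numeric(wl), swap = label, impact = impact_curve
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "curves") <- dplyr::bind_rows(curves)
  attr(out, "d_base") <- d_base
  class(out) <- c("trait_swap_result", class(out))
  out
}

#' @rdname trait_swap_experiment
#' @param growth_form `"tree"` or `"liana"`.
#' @export
default_swap_traits <- function(growth_form = c("tree", "liana")) {
  growth_form <- match.arg(growth_form)
  cfg <- dplyr::filter(trait_defaults(), .data$growth_form == .env$growth_form)
  stats::setNames(as.list(cfg$mean), cfg$trait)
}

#' Interactive component of a pairwise swap
#'
#' Separates a two-parameter swap impact into its additive part (the sum
#' of the single-parameter impacts) and the interactive remainder:
#' `interaction = impact({a, b}) - impact({a}) - impact({b})`. All three
#' impacts must come from the same experiment (same baseline).
#'
#' @param result A `trait_swap_result` containing the pair and both
#'   singles.
#' @param pair Character vector of the two parameter names.
#' @return One-row tibble with `pair`, `impact_pair`, `additive`,
#'   `interactive` and `sign`.
#' @export
interaction_effect <- function(result, pair) {
  stopifnot(length(pair) == 2)
  lab_pair <- paste(pair, collapse = "+")
  need <- c(lab_pair, pair)
  got <- result$swap
  if (!all(need %in% got)) {
    stop(
      "experiment must contain swaps: ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  if (length(unique(result$d_base)) > 1) {
    stop("impacts come from different baselines", call. = FALSE)
  }
  ip <- result$impact[match(lab_pair, got)]
  i1 <- result$impact[match(pair[1], got)]
  i2 <- result$impact[match(pair[2], got)]
  inter <- ip - i1 - i2
  tibble::tibble(
    pair = lab_pair, impact_pair = ip, additive = i1 + i2,
    interactive = inter, sign = sign(inter)
  )
}

#' Percent relative trait contrast
#'
#' Signed percent difference of the liana value relative to the tree
#' value, `(liana - tree) / tree * 100`.
#'
#' @param liana_value,tree_value Scalars (tree value non-zero).
#' @return Scalar percent.
#' @export
#' @examples
#' summarize_trait_contrast(27.9, 37.1) # about -24.8 (flatter angles)
summarize_trait_contrast <- function(liana_value, tree_value) {
  if (tree_value == 0) stop("tree value must be non-zero", call. = FALSE)
  (liana_value - tree_value) / tree_value * 100
}
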