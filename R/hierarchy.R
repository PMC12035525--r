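#' Hierarchical decomposition of leaf traits
#'
#' Fits the normal hierarchical model
#' `T_ijk = beta0 + beta_i + beta_jk + beta_k + eps` for a trait measured
#' on growth form `i` (liana or tree), species `j` nested in study `k`.
#' Growth forms enter as weakly-informed fixed group means; species-
#' within-study and study effects are exchangeable normal with
#' uninformative hyperpriors on their standard deviations. Sampling is by
#' Gibbs within JAGS. The quantity of interest is the growth-form
#' contrast (liana minus tree) and the fraction of its posterior mass
#' overlapping zero.
#'
#' @param table Tibble with columns `value`, `growth_form` (
#'   `"liana"`/`"tree"`), `species`, `study` (see
#'   [generate_trait_table()]).
#' @param n_iter Post-adaptation iterations per chain.
#' @param n_chains Number of chains.
#' @param seed Integer seed.
#' @return An object of class `trait_hierarchy_fit`: list with `contrast`
#'   (posterior draws of liana minus tree), `overlap_zero` (twice the
#'   smaller tail probability of the contrast), `draws` (tibble of
#'   monitored parameters) and `data_info`.
#' @export
fit_leaf_hierarchy <- function(table, n_iter = 2000, n_chains = 3, seed = 1) {
  need <- c("value", "growth_form", "species", "study")
  if (!all(need %in% names(table))) {
    stop("table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(table$growth_form %in% c("liana", "tree"))) {
    stop("growth_form must be liana or tree", call. = FALSE)
  }
  n_studies <- length(unique(table$study))
  per_gf <- table |>
    dplyr::distinct(.data$growth_form, .data$species) |>
    dplyr::count(.data$growth_form)
  if (nrow(per_gf) < 2 || any(per_gf$n < 2)) {
    stop("need >= 2 species per growth form for identifiability", call. = FALSE)
  }
  use_study <- n_studies >= 2
  if (!use_study) {
    warning("single study: study effect dropped from the model")
  }

  gf <- as.integer(factor(table$growth_form, levels = c("tree", "liana")))
  sp <- as.integer(factor(table$species))
  st <- as.integer(factor(table$study))
  sd_y <- stats::sd(table$value)
  if (sd_y <= 0) sd_y <- abs(mean(table$value)) + 1e-6
  scale_big <- 100 * sd_y

  model_string <- paste0(
    "model {\n",
    "  for (i in 1:n) {\n",
    "    y[i] ~ dnorm(mu[i], tau_res)\n",
    "    mu[i] <- gf_mean[gf[i]] + b_sp[sp[i]]",
    if (use_study) " + b_st[st[i]]" else "", "\n",
    "  }\n",
    "  for (g in 1:2) { gf_mean[g] ~ dnorm(0, ", 1 / scale_big^2, ") }\n",
    "  for (j in 1:n_sp) { b_sp[j] ~ dnorm(0, tau_sp) }\n",
    if (use_study) {
      paste0(
        "  for (k in 1:n_st) { b_st[k] ~ dnorm(0, tau_st) }\n",
        "  sd_st ~ dunif(0, ", scale_big, ")\n",
        "  tau_st <- pow(sd_st, -2)\n"
      )
    } else {
      ""
    },
    "  sd_sp ~ dunif(0, ", scale_big, ")\n",
    "  tau_sp <- pow(sd_sp, -2)\n",
    "  sd_res ~ dunif(0, ", scale_big, ")\n",
    "  tau_res <- pow(sd_res, -2)\n",
    "  contrast <- gf_mean[2] - gf_mean[1]\n",
    "}\n"
  )

  data <- list(
    y = table$value, gf = gf, sp = sp,
    n = nrow(table), n_sp = max(sp)
  )
  if (use_study) {
    data$st <- st
    data$n_st <- max(st)
  }

  set.seed(seed)
  inits <- lapply(seq_len(n_chains), function(i) {
    list(
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = seed + i
    )
  })
  jm <- rjags::jags.model(
    textConnection(model_string),
    data = data, inits = inits, n.chains = n_chains,
    n.adapt = 500, quiet = TRUE
  )
  monitors <- c("gf_mean", "contrast", "sd_sp", "sd_res")
  if (use_study) monitors <- c(monitors, "sd_st")
  samp <- rjags::coda.samples(jm, monitors, n.iter = n_iter, thin = 1)
  draws <- do.call(rbind, lapply(samp, as.matrix))
  contrast <- draws[, "contrast"]
  # Two-sided overlap-with-zero fraction: twice the smaller tail
  # probability, ~0.5 under a null contrast, ~0 for a decisive one.
  overlap <- 2 * min(mean(contrast >= 0), mean(contrast <= 0))

  structure(
    list(
      contrast = contrast,
      overlap_zero = overlap,
      draws = tibble::as_tibble(draws),
      data_info = list(
        n = nrow(table), n_species = max(sp), n_studies = n_studies,
        study_effect = use_study
      ),
      seed = seed
    ),
    class = "trait_hierarchy_fit"
  )
}

#' @export
print.trait_hierarchy_fit <- function(x, ...) {
  cat("trait_hierarchy_fit:", x$data_info$n, "observations,",
    x$data_info$n_species, "species,", x$data_info$n_studies, "studies\n")
  cat(sprintf(
    "growth-form contrast (liana - tree): %.4g (sd %.3g), P(overlap 0) = %.2f\n",
    mean(x$contrast), stats::sd(x$contrast), x$overlap_zero
  ))
  invisible(x)
}

#' Tidy and one-line summaries of a hierarchy fit
#'
#' @param x A `trait_hierarchy_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.trait_hierarchy_fit <- function(x, ...) {
  d <- x$draws
  tibble::tibble(
    term = names(d),
    estimate = vapply(d, stats::median, numeric(1)),
    mean = vapply(d, mean, numeric(1)),
    std.error = vapply(d, stats::sd, numeric(1)),
    conf.low = vapply(d, stats::quantile, numeric(1), 0.025),
    conf.high = vapply(d, stats::quantile, numeric(1), 0.975)
  )
}

#' @rdname tidy.trait_hierarchy_fit
#' @export
glance.trait_hierarchy_fit <- function(x, ...) {
  tibble::tibble(
    contrast = mean(x$contrast),
    contrast_sd = stats::sd(x$contrast),
    overlap_zero = x$overlap_zero,
    n = x$data_info$n,
    n_species = x$data_info$n_species,
    n_studies = x$data_info$n_studies
  )
}
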