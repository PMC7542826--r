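#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a pooled rate posterior
#'
#' @param x A `posterior_rates` tibble from [pool_posterior()].
#' @param mass HPD mass for the interval columns.
#' @param ... Unused.
#' @return One row per rate parameter: `parameter`, `mean`, `median`,
#'   `hpd_low`, `hpd_high` (per-MY units).
#' @export
tidy.posterior_rates <- function(x, mass = 0.95, ...) {
  pars <- setdiff(names(x), c("tree", "generation"))
  purrr::map_dfr(pars, function(p) {
    h <- hpd_interval(x[[p]], mass)
    tibble::tibble(parameter = p, mean = mean(x[[p]]), median = median(x[[p]]),
                   hpd_low = unname(h["low"]), hpd_high = unname(h["high"]))
  })
}

#' @rdname tidy.posterior_rates
#' @export
glance.posterior_rates <- function(x, ...) {
  tibble::tibble(n_draws = nrow(x), n_trees = dplyr::n_distinct(x$tree),
                 samples_per_tree = nrow(x) / dplyr::n_distinct(x$tree))
}

#' Tidy a maximum-likelihood chromosome-model fit
#'
#' @param x A `karyo_ml_fit`.
#' @param ... Unused.
#' @return One row per rate: `term`, `estimate_unit`, `estimate_per_my`.
#' @export
tidy.karyo_ml_fit <- function(x, ...) {
  tibble::tibble(term = names(x$rates_unit),
                 estimate_unit = unname(x$rates_unit),
                 estimate_per_my = unname(x$rates_per_my))
}

#' @rdname tidy.karyo_ml_fit
#' @export
glance.karyo_ml_fit <- function(x, ...) {
  tibble::tibble(log_likelihood = x$log_likelihood, n_tips = x$n_tips,
                 converged = x$converged,
                 include_polyploidy = x$include_polyploidy)
}

#' Tidy an ancestral reconstruction
#'
#' @param x An `ancestral_reconstruction`.
#' @param ... Unused.
#' @return Tibble with `node` (ape numbering), `tip` label where applicable,
#'   `state`, `probability`, and `map_state`.
#' @export
tidy.ancestral_reconstruction <- function(x, ...) {
  ntip <- length(x$tree$tip.label)
  nn <- nrow(x$probs)
  df <- tibble::as_tibble(x$probs)
  df$node <- seq_len(nn)
  df$tip <- c(x$tree$tip.label, rep(NA_character_, nn - ntip))
  df$map_state <- x$map_state
  tidyr::pivot_longer(df, cols = -c("node", "tip", "map_state"),
                      names_to = "state", values_to = "probability")
}

#' Tidy an Mk2 ARD fit
#'
#' @param x An `mk2_fit`.
#' @param ... Unused.
#' @return The pooled per-parameter summary tibble.
#' @export
tidy.mk2_fit <- function(x, ...) x$summary

#' @rdname tidy.mk2_fit
#' @export
glance.mk2_fit <- function(x, ...) {
  tibble::tibble(n_trees = nrow(x$fits),
                 mean_log_lik = mean(x$fits$log_lik),
                 any_boundary = any(x$fits$boundary))
}

#' Posterior density plot of pooled per-MY rates with HPD bars
#'
#' One panel per rate parameter; the bar under each density marks the 95%
#' highest-posterior-density interval.
#'
#' @param object A `posterior_rates` tibble.
#' @param mass HPD mass.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.posterior_rates <- function(object, mass = 0.95, ...) {
  pars <- setdiff(names(object), c("tree", "generation"))
  long <- tidyr::pivot_longer(object[, pars], dplyr::everything(),
                              names_to = "parameter", values_to = "rate")
  hpd <- tidy.posterior_rates(object, mass)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rate)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_segment(data = hpd, ggplot2::aes(
      x = .data$hpd_low, xend = .data$hpd_high, y = 0, yend = 0),
      linewidth = 2, colour = "steelblue") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "rate (per MY)", y = "posterior density")
}

#' Genus-level mean autosome numbers by sex chromosome system
#'
#' Dot plot of per-genus means per SCS class, faceted by order — the visual
#' companion of the fusion/fission classification table.
#'
#' @param object A (classified) genus summary tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_genus_scs <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
                              cols = c("mean_xo", "mean_xy", "mean_multixy"),
                              names_to = "scs", values_to = "mean_autosomes")
  long <- long[!is.na(long$mean_autosomes), , drop = FALSE]
  long$scs <- c(mean_xo = "XO", mean_xy = "XY",
                mean_multixy = "multi-XY")[long$scs]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mean_autosomes,
                                     y = .data$genus, colour = .data$scs)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$order), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "mean haploid autosome number", y = NULL,
                  colour = "SCS")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
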