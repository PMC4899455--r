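#' Precision by treatment boxplot
#'
#' Distribution of per-pot precision under each treatment, pooled across
#' species. Box widths are proportional to the square root of the number of
#' pots. A dashed line at zero marks indifferent root placement.
#'
#' @param precisions Tibble with `treatment` and `precision` columns (e.g.
#'   `report$precisions`).
#' @return A ggplot object.
#' @export
plot_precision_by_treatment <- function(precisions) {
  precisions$treatment <- factor(
    precisions$treatment,
    levels = intersect(c("control", "low", "high"),
                       unique(precisions$treatment))
  )
  ggplot2::ggplot(
    precisions,
    ggplot2::aes(x = .data$treatment, y = .data$precision)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_boxplot(varwidth = TRUE, fill = "grey85") +
    ggplot2::labs(
      x = "Nutrient contrast treatment",
      y = "Precision  log(rich half / poor half)"
    ) +
    ggplot2::theme_minimal()
}

#' Low- vs high-contrast foraging responses
#'
#' Each point is a species; the diagonal marks equal response under both
#' contrasts.
#'
#' @param responses Tibble from [species_responses()].
#' @return A ggplot object.
#' @export
plot_response_by_contrast <- function(responses) {
  ggplot2::ggplot(
    responses,
    ggplot2::aes(x = .data$foraging_low, y = .data$foraging_high)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(-0.5, 0.5), ylim = c(-0.5, 0.5)) +
    ggplot2::labs(
      x = "Foraging (low contrast)", y = "Foraging (high contrast)"
    ) +
    ggplot2::theme_minimal()
}

#' Foraging response against a species trait
#'
#' Boxplots (ordinal/binary traits, widths proportional to sqrt n) or a
#' scatter (continuous traits) of the high-contrast foraging response against
#' one life-history trait.
#'
#' @param responses Tibble from [species_responses()].
#' @param traits Prepared trait table.
#' @param trait Trait column name.
#' @param response Response column (default `"foraging_high"`).
#' @return A ggplot object.
#' @export
plot_response_by_trait <- function(responses, traits, trait,
                                   response = "foraging_high") {
  d <- dplyr::inner_join(responses, traits, by = "species")
  d <- d[complete.cases(d[[trait]], d[[response]]), , drop = FALSE]
  scale <- trait_scales()[[trait]] %||% "continuous"
  p <- ggplot2::ggplot(
    d, ggplot2::aes(x = .data[[trait]], y = .data[[response]])
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50")
  if (scale %in% c("ordinal", "binary")) {
    p <- p + ggplot2::geom_boxplot(
      ggplot2::aes(group = .data[[trait]]),
      varwidth = TRUE, fill = "grey85"
    )
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::labs(x = trait, y = response) + ggplot2::theme_minimal()
}

#' Profile likelihood of Pagel's lambda
#'
#' Plots the profile log-likelihood over lambda in `[0, 1]` for a tip-level
#' variable, with the ML estimate and the 1.92-unit confidence cutoff.
#'
#' @param values Named per-tip values.
#' @param tree Phylogeny.
#' @param n_grid Grid resolution.
#' @return A ggplot object.
#' @export
plot_lambda_profile <- function(values, tree, n_grid = 51) {
  fit <- ml_lambda(values, tree)
  prep <- align_tip_values(values, tree)
  V <- phylo_covariance(prep$tree)
  X <- matrix(1, length(prep$y), 1)
  grid <- seq(0, 1, length.out = n_grid)
  ll <- vapply(
    grid,
    function(l) gls_profile(prep$y, X, lambda_transform(V, l))$logLik,
    numeric(1)
  )
  d <- tibble::tibble(lambda = grid, logLik = ll)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$lambda, y = .data$logLik)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Pagel's lambda", y = "profile log-likelihood") +
    ggplot2::theme_minimal()
  if (fit$identifiable) {
    p <- p +
      ggplot2::geom_vline(xintercept = fit$lambda_hat, colour = "steelblue") +
      ggplot2::geom_hline(
        yintercept = fit$log_likelihood - 1.92,
        linetype = "dashed", colour = "grey50"
      )
  }
  p
}
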