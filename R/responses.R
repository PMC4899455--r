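#' Centered Mann-Whitney effect size
#'
#' The species-level response statistic: the Mann-Whitney U for
#' treated-over-control pairs, divided by `m * n` and centered by subtracting
#' 0.5. Equivalently it is the tie-aware probability of superiority
#' `P(treated > control) + P(tie)/2` minus one half, so it lies in
#' `[-0.5, +0.5]`; positive values mean the treatment shifted precision toward
#' the rich half (foraging), negative values mean rich-patch avoidance. Ties
#' count one half. Computed through the midrank rank-sum identity
#' `U = R_treated - n(n+1)/2`.
#'
#' @param control_values,treated_values Numeric vectors of per-pot precision
#'   for the control and treated group of one species (each nonempty).
#' @return Effect in `[-0.5, 0.5]`.
#' @examples
#' mw_effect(c(1, 2, 3), c(4, 5, 6)) # +0.5, complete separation
#' mw_effect(c(3, 1, 4), c(2, 5)) # 4/6 - 0.5
#' @export
mw_effect <- function(control_values, treated_values) {
  m <- length(control_values)
  n <- length(treated_values)
  if (m < 1 || n < 1) abort("both samples must be nonempty.")
  if (anyNA(control_values) || anyNA(treated_values)) {
    abort("samples must not contain missing values.")
  }
  r <- rank(c(control_values, treated_values)) # midranks
  u <- sum(r[(m + 1):(m + n)]) - n * (n + 1) / 2
  u / (m * n) - 0.5
}

#' Species-level foraging and plasticity responses
#'
#' For each species, the centered Mann-Whitney effect of each treated contrast
#' against that species' control pots: `foraging_low`, `foraging_high` (signed,
#' direction-aware) and their absolute values `plasticity_low`,
#' `plasticity_high` (directionless magnitude of the plastic reaction, which
#' counts rich-patch avoidance as response). A species missing one treated cell
#' gets NA for that contrast; species without control pots are dropped with a
#' warning (no effect is computable).
#'
#' @param precisions Tibble with `species`, `treatment` in
#'   `{control, low, high}`, `precision`.
#' @return Tibble with one row per species: `species`, `m` (control pots),
#'   `n_low`, `n_high`, `foraging_low`, `foraging_high`, `plasticity_low`,
#'   `plasticity_high`.
#' @export
species_responses <- function(precisions) {
  split_sp <- split(precisions, precisions$species)
  no_control <- names(split_sp)[!purrr::map_lgl(
    split_sp, ~ any(.x$treatment == "control")
  )]
  if (length(no_control)) {
    warn(paste0(
      "Species without control pots skipped: ", toString(no_control)
    ))
    split_sp <- split_sp[setdiff(names(split_sp), no_control)]
  }
  purrr::map_dfr(split_sp, function(d) {
    ctrl <- d$precision[d$treatment == "control"]
    eff <- function(tr) {
      x <- d$precision[d$treatment == tr]
      if (length(x) == 0) NA_real_ else mw_effect(ctrl, x)
    }
    f_low <- eff("low")
    f_high <- eff("high")
    tibble::tibble(
      species = d$species[[1]],
      m = length(ctrl),
      n_low = sum(d$treatment == "low"),
      n_high = sum(d$treatment == "high"),
      foraging_low = f_low,
      foraging_high = f_high,
      plasticity_low = abs(f_low),
      plasticity_high = abs(f_high)
    )
  })
}

# Exact null distribution of the signed-rank sum over doubled midranks,
# by convolution over the 2^n equiprobable sign assignments.
signed_rank_null <- function(doubled_ranks) {
  total <- sum(doubled_ranks)
  f <- numeric(total + 1) # index k+1 holds P(V2 = k)
  f[1] <- 1
  for (s in doubled_ranks) {
    g <- f / 2
    g[(s + 1):(total + 1)] <- g[(s + 1):(total + 1)] + f[1:(total + 1 - s)] / 2
    f <- g
  }
  f
}

#' Paired Wilcoxon signed-rank test
#'
#' Species-matched comparison of two per-species summaries (e.g. median
#' precision under control vs under high contrast). Zero differences are
#' dropped before ranking; tied absolute differences get midranks; `V` is the
#' rank sum over positive differences. For `n_pairs <= exact_threshold` the
#' two-sided p-value is exact, from the full null distribution of `V` over all
#' sign assignments (computed by convolution, valid under ties); above the
#' threshold a normal approximation with tie and continuity correction is
#' used. When the same reference sample enters several tests, a Bonferroni
#' factor multiplies the p-value (`p_adjusted = min(1, factor * p_raw)`).
#'
#' @param values_a,values_b Numeric vectors, matched by position (same species
#'   order).
#' @param bonferroni_factor Multiplier for the adjusted p-value (default 1).
#' @param exact_threshold Largest `n_pairs` for which the exact p is used.
#' @return Object of class `paired_wilcoxon`: list with `statistic` (V),
#'   `p_raw`, `p_adjusted`, `n_pairs`, `method`.
#' @examples
#' paired_wilcoxon(c(2, 3, 4), c(1, 1, 1))$p_raw # 0.25, all-positive V = 6
#' @export
paired_wilcoxon <- function(values_a, values_b, bonferroni_factor = 1,
                            exact_threshold = 25) {
  if (length(values_a) != length(values_b)) {
    abort("`values_a` and `values_b` must have equal length (matched pairs).")
  }
  ok <- !is.na(values_a) & !is.na(values_b)
  d <- values_a[ok] - values_b[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warn("All paired differences are zero; degenerate test (V = 0, p = 1).")
    return(new_paired_wilcoxon(0, 1, bonferroni_factor, 0L, "degenerate"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_threshold) {
    s2 <- as.integer(round(2 * r))
    f <- signed_rank_null(s2)
    v2 <- as.integer(round(2 * v))
    p_le <- sum(f[1:(v2 + 1)])
    p_ge <- sum(f[(v2 + 1):length(f)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal-approx"
  }
  new_paired_wilcoxon(v, p, bonferroni_factor, n, method)
}

new_paired_wilcoxon <- function(v, p, factor, n, method) {
  structure(
    list(
      statistic = v, p_raw = p, p_adjusted = min(1, factor * p),
      n_pairs = n, method = method, bonferroni_factor = factor
    ),
    class = "paired_wilcoxon"
  )
}

#' @export
print.paired_wilcoxon <- function(x, ...) {
  cat(sprintf(
    "Paired Wilcoxon signed-rank: V = %g, n = %d, p = %.4g (adjusted %.4g, x%g), %s\n",
    x$statistic, x$n_pairs, x$p_raw, x$p_adjusted, x$bonferroni_factor,
    x$method
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.paired_wilcoxon <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, p.value = x$p_raw, p.adjusted = x$p_adjusted,
    n_pairs = x$n_pairs, method = x$method
  )
}

#' Bootstrap stability of a species response
#'
#' Ordinary (nonparametric) bootstrap of the centered Mann-Whitney effect: in
#' each iteration both the control and the treated sample are resampled with
#' replacement (independently, at their original sizes) and the effect is
#' recomputed. Stability is reported as the middle-half width, the difference
#' between the 0.75 and 0.25 quantiles of the bootstrapped effects (linear
#' interpolation of order statistics, [stats::quantile()] type 7): wide means
#' unstable. Constant inputs give width 0, not an error.
#'
#' @param control_values,treated_values Per-pot precision values (each of
#'   length >= 2).
#' @param n_boot Bootstrap iterations (>= 100; 1,000 is the conventional
#'   default).
#' @param seed Integer seed; deterministic given seed.
#' @return List of class `stability_estimate`: `middle_half_width`, `n_boot`,
#'   `effects` (the bootstrapped values).
#' @export
bootstrap_stability <- function(control_values, treated_values,
                                n_boot = 1000, seed = 1L) {
  m <- length(control_values)
  n <- length(treated_values)
  if (m < 2 || n < 2) abort("need >= 2 pots per group to bootstrap.")
  assert_count(n_boot, "n_boot", min = 100L)
  # each group is a multiset; sorting makes the seeded resample canonical, so
  # the width is exactly invariant under relabeling of pots within a group
  control_values <- sort(control_values)
  treated_values <- sort(treated_values)
  effects <- with_seed(seed, function() {
    vapply(seq_len(n_boot), function(i) {
      mw_effect(
        control_values[sample.int(m, m, replace = TRUE)],
        treated_values[sample.int(n, n, replace = TRUE)]
      )
    }, numeric(1))
  })
  q <- quantile(effects, c(0.25, 0.75), names = FALSE, type = 7)
  structure(
    list(middle_half_width = q[2] - q[1], n_boot = n_boot, effects = effects),
    class = "stability_estimate"
  )
}

#' Per-species bootstrap stability table
#'
#' Applies [bootstrap_stability()] to every species x contrast cell with at
#' least 2 control and 2 treated pots; smaller cells are skipped.
#'
#' @param precisions Tibble with `species`, `treatment`, `precision`.
#' @param n_boot,seed As in [bootstrap_stability()]; each cell gets its own
#'   deterministic subseed.
#' @return Tibble with `species`, `contrast` (`low`/`high`),
#'   `middle_half_width`, `n_boot`.
#' @export
response_stability <- function(precisions, n_boot = 1000, seed = 1L) {
  cells <- tidyr::expand_grid(
    species = sort(unique(precisions$species)),
    contrast = c("low", "high")
  )
  res <- purrr::pmap_dfr(cells, function(species, contrast) {
    ctrl <- precisions$precision[
      precisions$species == species & precisions$treatment == "control"
    ]
    trt <- precisions$precision[
      precisions$species == species & precisions$treatment == contrast
    ]
    if (length(ctrl) < 2 || length(trt) < 2) {
      return(tibble::tibble(
        species = species, contrast = contrast,
        middle_half_width = NA_real_, n_boot = NA_integer_
      ))
    }
    cell_seed <- substream_seed(
      seed + match(contrast, c("low", "high")),
      "bootstrap"
    ) + match(species, sort(unique(precisions$species)))
    bs <- bootstrap_stability(ctrl, trt, n_boot = n_boot, seed = cell_seed)
    tibble::tibble(
      species = species, contrast = contrast,
      middle_half_width = bs$middle_half_width, n_boot = n_boot
    )
  })
  res
}

#' Cross-contrast response correlation
#'
#' Spearman correlation between the low- and high-contrast foraging responses
#' across species. A substantial positive correlation justifies carrying only
#' the high-contrast estimates into trait analyses.
#'
#' @param responses Tibble from [species_responses()].
#' @return One-row association tibble (`trait` = "foraging_low" vs response
#'   "foraging_high").
#' @export
response_cross_correlation <- function(responses) {
  ok <- complete.cases(responses[, c("foraging_low", "foraging_high")])
  if (sum(ok) < 5) {
    abort("need >= 5 species with both contrasts for the cross-correlation.")
  }
  ct <- suppressWarnings(cor.test(
    responses$foraging_low[ok], responses$foraging_high[ok],
    method = "spearman", exact = FALSE
  ))
  tibble::tibble(
    trait = "foraging_low", response_form = "foraging_high",
    method = "spearman", estimate = unname(ct$estimate),
    n_used = sum(ok), p_value = ct$p.value
  )
}
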