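#' Per-pot root placement precision
#'
#' Precision is the natural log of the ratio of root dry mass in the
#' nutrient-rich pot half to that in the poor half,
#' `p = log(mass_rich / mass_poor)`. Zero means indifferent placement; the log
#' removes the linear effect of overall plant size, so `p` captures the
#' size-independent (active) component of the allocation response. Swapping
#' the two halves negates `p` exactly.
#'
#' @param pots Data frame with columns `species`, `treatment`, `mass_rich_g`,
#'   `mass_poor_g`, `pot_id`. Both masses must be strictly positive: pots with
#'   nonpositive or missing half-masses (e.g. roots too small to process) are
#'   an error identifying the offending `pot_id` — there is no defensible fill
#'   value for `log(0)`.
#' @return The input tibble with a `precision` column appended.
#' @examples
#' pots <- tibble::tibble(
#'   species = "a", treatment = "high",
#'   mass_rich_g = c(2, exp(1)), mass_poor_g = c(2, 1), pot_id = c("p1", "p2")
#' )
#' compute_precision(pots)$precision # 0, 1
#' @export
compute_precision <- function(pots) {
  req <- c("species", "treatment", "mass_rich_g", "mass_poor_g", "pot_id")
  missing_cols <- setdiff(req, names(pots))
  if (length(missing_cols)) {
    abort(paste0("`pots` lacks columns: ", toString(missing_cols)))
  }
  bad <- !is.finite(pots$mass_rich_g) | !is.finite(pots$mass_poor_g) |
    pots$mass_rich_g <= 0 | pots$mass_poor_g <= 0
  if (any(bad)) {
    abort(paste0(
      "Nonpositive or missing half-mass in pot(s): ",
      toString(head(pots$pot_id[bad], 10)),
      ". Exclude such pots upstream (see `drop_invalid_pots()`)."
    ))
  }
  dplyr::mutate(
    tibble::as_tibble(pots),
    precision = log(.data$mass_rich_g) - log(.data$mass_poor_g)
  )
}

#' Drop pots with unusable half-masses
#'
#' Filters out records whose half-masses are missing or nonpositive, returning
#' the kept rows and attaching the dropped ones as the `"excluded"` attribute;
#' a warning lists the dropped pot ids. The pipeline never imputes.
#'
#' @param pots Pot records as in [compute_precision()].
#' @return Filtered tibble with attribute `excluded`.
#' @export
drop_invalid_pots <- function(pots) {
  bad <- !is.finite(pots$mass_rich_g) | !is.finite(pots$mass_poor_g) |
    pots$mass_rich_g <= 0 | pots$mass_poor_g <= 0
  if (any(bad)) {
    warn(paste0(
      "Dropping ", sum(bad), " pot(s) with unusable half-masses: ",
      toString(head(pots$pot_id[bad], 10))
    ))
  }
  out <- tibble::as_tibble(pots)[!bad, , drop = FALSE]
  attr(out, "excluded") <- tibble::as_tibble(pots)[bad, , drop = FALSE]
  out
}

#' Randomly orient control pot halves
#'
#' Control pots have no nutrient gradient, so their halves carry no rich/poor
#' meaning — only an arbitrary physical side. To make the control precision
#' distribution symmetric by construction, each control pot's sides are mapped
#' to (first, second) by a seeded fair coin flip: with probability 1/2 the two
#' mass columns are swapped. Deterministic given `seed`; different seeds change
#' per-pot precision only by sign flips.
#'
#' @param pots Data frame of control-treatment pot records only.
#' @param seed Integer seed.
#' @return Tibble of the same shape with halves reoriented.
#' @export
assign_control_halves <- function(pots, seed) {
  if (!all(pots$treatment == "control")) {
    abort("`assign_control_halves()` accepts control-treatment pots only.")
  }
  pots <- tibble::as_tibble(pots)
  flip <- with_seed(seed, function() runif(nrow(pots)) < 0.5)
  rich <- ifelse(flip, pots$mass_poor_g, pots$mass_rich_g)
  poor <- ifelse(flip, pots$mass_rich_g, pots$mass_poor_g)
  pots$mass_rich_g <- rich
  pots$mass_poor_g <- poor
  pots
}

#' Medcouple robust skewness
#'
#' The medcouple is a robust, bounded measure of skewness in `[-1, 1]`: the
#' median of the kernel
#' `h(x_i, x_j) = ((x_j - m) - (m - x_i)) / (x_j - x_i)` over all pairs with
#' `x_i <= m <= x_j` (m the sample median). Pairs of observations tied at the
#' median use the standard sign kernel (-1 / 0 / +1 by within-tie index). It is
#' invariant under location shift and positive scaling. Here it is a
#' diagnostic that motivates median/rank summaries; it gates nothing.
#'
#' The plain O(n^2) kernel enumeration is used; per-cell sample sizes in
#' split-pot designs are small.
#'
#' @param x Numeric vector with at least 3 finite values.
#' @return Medcouple in `[-1, 1]`.
#' @examples
#' compute_medcouple(c(1, 2, 6)) # 0.3, right-skewed
#' @export
compute_medcouple <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) abort("medcouple needs at least 3 finite values.")
  x <- sort(x)
  m <- median(x)
  xl <- x[x <= m]
  xr <- x[x >= m]
  # kernel over the full left x right grid (vectorised O(n^2))
  h <- (outer(xl, xr, function(a, b) (b - m) - (m - a)) /
          outer(xl, xr, function(a, b) b - a))
  # pairs tied at the median (0/0 above): the sign kernel on within-tie
  # positions i, j in 1..k: -1 below the anti-diagonal, 0 on it, +1 above
  k <- sum(x == m)
  if (k > 0) {
    ti <- which(xl == m)
    tj <- which(xr == m)
    h[ti, tj] <- sign(outer(seq_len(k), seq_len(k), `+`) - 1 - k)
  }
  median(h)
}

#' Species-by-treatment median precision
#'
#' Medians summarise each species x treatment cell; balance data are typically
#' skewed (see [compute_medcouple()]), so medians, not means, represent the
#' cell. Cells with no data are simply absent from the output, never zero.
#'
#' @param precisions Tibble with `species`, `treatment`, `precision`.
#' @return Tibble with `species`, `treatment`, `median_precision`, `n_pots`.
#' @export
species_treatment_median <- function(precisions) {
  if (nrow(precisions) == 0) {
    return(tibble::tibble(
      species = character(), treatment = character(),
      median_precision = numeric(), n_pots = integer()
    ))
  }
  precisions |>
    dplyr::group_by(.data$species, .data$treatment) |>
    dplyr::summarise(
      median_precision = median(.data$precision),
      n_pots = dplyr::n(),
      .groups = "drop"
    )
}

#' Medcouple skewness per species-by-treatment cell
#'
#' Diagnostic companion to [species_treatment_median()]: the medcouple of each
#' cell with at least 3 pots (smaller cells get NA).
#'
#' @inheritParams species_treatment_median
#' @return Tibble with `species`, `treatment`, `medcouple`, `n_pots`.
#' @export
cell_medcouple <- function(precisions) {
  precisions |>
    dplyr::group_by(.data$species, .data$treatment) |>
    dplyr::summarise(
      medcouple = if (dplyr::n() >= 3) compute_medcouple(.data$precision) else NA_real_,
      n_pots = dplyr::n(),
      .groups = "drop"
    )
}
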