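# Measurement scale of each standard life-history trait. The scale, not the
# data, decides the correlation method: Spearman for ordinal/binary traits,
# Pearson for continuous ones.
trait_scales <- function() {
  c(
    sla = "continuous", leaf_area = "continuous", height = "continuous",
    lateral_spread = "continuous",
    generative_repro = "ordinal", vegetative_repro = "ordinal",
    shoot_lifespan = "ordinal", clonality = "binary"
  )
}

trait_method <- function(scale) {
  if (scale %in% c("ordinal", "binary")) "spearman" else "pearson"
}

#' Prepare a trait table for analysis
#'
#' Mean leaf area spans orders of magnitude and is log-transformed (natural
#' log) before correlation; all other traits pass through unchanged. Missing
#' cells stay missing. Nonpositive leaf areas cannot be logged and are
#' rejected to missing with a warning.
#'
#' @param traits Tibble with a `species` column and trait columns (see
#'   [trait_scales()] for the recognised set); any cell may be NA.
#' @return Tibble of the same shape with `leaf_area` on the log scale.
#' @export
prepare_traits <- function(traits) {
  traits <- tibble::as_tibble(traits)
  if ("leaf_area" %in% names(traits)) {
    bad <- !is.na(traits$leaf_area) & traits$leaf_area <= 0
    if (any(bad)) {
      warn(paste0(
        sum(bad), " nonpositive leaf_area cell(s) set to missing (cannot log)."
      ))
      traits$leaf_area[bad] <- NA_real_
    }
    traits$leaf_area <- log(traits$leaf_area)
  }
  traits
}

# Spearman rho on midranks with exact permutation p for small n (optional) or
# the t approximation otherwise; Pearson via cor.test.
cor_with_p <- function(x, y, method, exact_permutation = FALSE) {
  n <- length(x)
  if (method == "spearman" && exact_permutation && n <= 10) {
    rx <- rank(x)
    ry <- rank(y)
    obs <- cor(rx, ry)
    perms <- combinat_permutations(n)
    stats <- apply(perms, 1, function(idx) cor(rx, ry[idx]))
    p <- mean(abs(stats) >= abs(obs) - 1e-12)
    return(list(estimate = obs, p_value = p))
  }
  ct <- suppressWarnings(cor.test(
    x, y,
    method = method, exact = if (method == "spearman") FALSE else NULL
  ))
  list(estimate = unname(ct$estimate), p_value = ct$p.value)
}

combinat_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- combinat_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Correlate one species response with one trait
#'
#' Scale-aware bivariate association: Spearman's rho (midranks for ties) for
#' ordinal and binary traits, Pearson's r for continuous ones. Species with a
#' missing value in either variable are excluded pairwise; at least 5 complete
#' pairs are required. Spearman p-values use the t approximation (an exact
#' permutation p is available for n <= 10 via `exact_permutation`).
#'
#' @param responses Tibble from [species_responses()] (must contain `species`
#'   and the `response` column).
#' @param traits Prepared trait table (see [prepare_traits()]).
#' @param trait Name of the trait column.
#' @param response Name of the response column (default `"foraging_high"`).
#' @param exact_permutation Use exact permutation p for Spearman when
#'   n <= 10?
#' @return One-row tibble: `trait`, `response_form`, `method`, `estimate`,
#'   `n_used`, `p_value`.
#' @export
correlate <- function(responses, traits, trait, response = "foraging_high",
                      exact_permutation = FALSE) {
  scales <- trait_scales()
  if (!trait %in% names(traits)) abort(paste0("unknown trait column: ", trait))
  scale <- scales[[trait]] %||% "continuous"
  method <- trait_method(scale)
  d <- dplyr::inner_join(
    responses[, c("species", response)], traits[, c("species", trait)],
    by = "species"
  )
  ok <- complete.cases(d[[response]], d[[trait]])
  if (sum(ok) < 5) {
    abort(paste0(
      "trait '", trait, "': only ", sum(ok),
      " complete pairs (>= 5 required)."
    ))
  }
  res <- cor_with_p(
    d[[trait]][ok], d[[response]][ok], method,
    exact_permutation = exact_permutation
  )
  tibble::tibble(
    trait = trait,
    response_form = sub("_(low|high)$", "", response),
    method = method,
    estimate = res$estimate,
    n_used = sum(ok),
    p_value = res$p_value
  )
}

#' Trait-response association table
#'
#' The full response-by-trait correlation grid: both response forms (signed
#' `foraging` and directionless `plasticity`, high-contrast estimates) against
#' every recognised trait present in the table, with the method chosen by
#' trait scale and pairwise-complete deletion. Lateral spread is defined for
#' clonal species only, so its rows use the clonal subset (this happens
#' naturally through missing-value deletion). Traits with fewer than 5
#' complete pairs yield an NA row rather than an error. Raw p-values are
#' reported (no multiple-testing correction); set `p_adjust = "holm"` to add
#' an adjusted column.
#'
#' @param responses Tibble from [species_responses()].
#' @param traits Prepared trait table.
#' @param p_adjust Optional [stats::p.adjust()] method applied across the
#'   table's cells into a `p_adjusted` column.
#' @return Tibble with one row per response form x trait.
#' @export
association_table <- function(responses, traits, p_adjust = NULL) {
  trait_names <- intersect(names(trait_scales()), names(traits))
  grid <- tidyr::expand_grid(
    response = c("foraging_high", "plasticity_high"),
    trait = trait_names
  )
  out <- purrr::pmap_dfr(grid, function(response, trait) {
    tryCatch(
      correlate(responses, traits, trait, response = response),
      error = function(e) tibble::tibble(
        trait = trait,
        response_form = sub("_(low|high)$", "", response),
        method = trait_method(trait_scales()[[trait]]),
        estimate = NA_real_, n_used = NA_integer_, p_value = NA_real_
      )
    )
  })
  if (!is.null(p_adjust)) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  }
  out
}

#' Pairwise trait collinearity matrix
#'
#' All pairwise correlations among traits, Spearman whenever either trait of a
#' pair is ordinal or binary, Pearson otherwise, each cell on its own
#' pairwise-complete species set. Cells with fewer than 5 complete pairs are
#' unavailable (NA).
#'
#' @param traits Prepared trait table.
#' @return Long tibble with `trait_a`, `trait_b`, `method`, `estimate`,
#'   `n_used`; contains both orders plus the unit diagonal, so
#'   [collinearity_matrix_wide()] can reshape it into a symmetric matrix.
#' @export
trait_collinearity_matrix <- function(traits) {
  scales <- trait_scales()
  trait_names <- intersect(names(scales), names(traits))
  grid <- tidyr::expand_grid(trait_a = trait_names, trait_b = trait_names)
  purrr::pmap_dfr(grid, function(trait_a, trait_b) {
    method <- if (any(scales[c(trait_a, trait_b)] %in% c("ordinal", "binary"))) {
      "spearman"
    } else {
      "pearson"
    }
    x <- traits[[trait_a]]
    y <- traits[[trait_b]]
    ok <- complete.cases(x, y)
    if (trait_a == trait_b) {
      est <- 1
    } else if (sum(ok) < 5 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      est <- NA_real_
    } else if (method == "spearman") {
      est <- cor(rank(x[ok]), rank(y[ok]))
    } else {
      est <- cor(x[ok], y[ok])
    }
    tibble::tibble(
      trait_a = trait_a, trait_b = trait_b, method = method,
      estimate = est, n_used = sum(ok)
    )
  })
}

#' Reshape the collinearity table into a matrix
#'
#' @param collinearity Long tibble from [trait_collinearity_matrix()].
#' @return Numeric matrix with traits as rows and columns.
#' @export
collinearity_matrix_wide <- function(collinearity) {
  wide <- tidyr::pivot_wider(
    collinearity[, c("trait_a", "trait_b", "estimate")],
    names_from = "trait_b", values_from = "estimate"
  )
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$trait_a
  m
}
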