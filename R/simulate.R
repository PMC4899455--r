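#' Simulate an ultrametric pure-birth phylogeny
#'
#' Draws a Yule (pure-birth) tree, the stand-in for a time-calibrated species
#' phylogeny. Tips are labelled `sp01`, `sp02`, ... and the tree is rescaled to
#' unit root-to-tip depth so branch lengths read as fractions of total time.
#'
#' @param n_tips Number of tips (>= 3).
#' @param seed Integer seed; the same `(n_tips, seed)` always yields the same
#'   tree.
#' @return An [ape::phylo] object, rooted and ultrametric.
#' @examples
#' tr <- simulate_tree(10, seed = 1)
#' ape::is.ultrametric(tr)
#' @export
simulate_tree <- function(n_tips, seed) {
  assert_count(n_tips, "n_tips", min = 3L)
  tr <- with_seed(seed, function() ape::rphylo(n_tips, birth = 1, death = 0))
  tr$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr
}

# --- skew-normal machinery -------------------------------------------------
# Standard skew-normal draws via the delta transform: if (u0, u1) are iid
# N(0,1) and d = shape/sqrt(1+shape^2), then d*|u0| + sqrt(1-d^2)*u1 has the
# SN(0, 1, shape) law.
rskewnorm <- function(n, shape) {
  d <- shape / sqrt(1 + shape^2)
  u0 <- rnorm(n)
  u1 <- rnorm(n)
  d * abs(u0) + sqrt(1 - d^2) * u1
}

dskewnorm <- function(x, shape) 2 * stats::dnorm(x) * stats::pnorm(shape * x)

# Median of the standard skew-normal, found numerically so generated precision
# distributions can be median-centered (the pipeline's statistics are all
# median/rank based). Memoised per shape.
.skewnorm_median_cache <- new.env(parent = emptyenv())
skewnorm_median <- function(shape) {
  if (shape == 0) {
    return(0)
  }
  key <- format(shape, digits = 15)
  hit <- .skewnorm_median_cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  cdf <- function(q) {
    integrate(dskewnorm, lower = -Inf, upper = q, shape = shape)$value
  }
  out <- uniroot(function(q) cdf(q) - 0.5, interval = c(-5, 5), tol = 1e-10)$root
  .skewnorm_median_cache[[key]] <- out
  out
}

#' Build a table of species simulation profiles
#'
#' One row per species: `delta` is the foraging strength (shift of median
#' precision per unit treatment contrast), `omega` the within-species precision
#' scale, `gamma` the skew-normal shape of the precision distribution, and
#' `mu_t`, `sigma_t` the log-mean and log-sd of total root dry mass (grams).
#'
#' @param species Character vector of species ids.
#' @param delta,omega,gamma,mu_t,sigma_t Numeric, recycled to one value per
#'   species. `omega` and `sigma_t` must be positive.
#' @return A tibble with one row per species.
#' @export
species_profiles <- function(species, delta = 0, omega = 0.5, gamma = 0,
                             mu_t = 0, sigma_t = 0.5) {
  out <- tibble::tibble(
    species = as.character(species),
    delta = rep_len(delta, length(species)),
    omega = rep_len(omega, length(species)),
    gamma = rep_len(gamma, length(species)),
    mu_t = rep_len(mu_t, length(species)),
    sigma_t = rep_len(sigma_t, length(species))
  )
  if (any(out$omega <= 0)) abort("`omega` must be > 0 for every species.")
  if (any(out$sigma_t <= 0)) abort("`sigma_t` must be > 0 for every species.")
  if (anyDuplicated(out$species)) abort("species ids must be unique.")
  out
}

#' Define a split-pot experiment
#'
#' Bundles species profiles with the design constants: pots per
#' species-by-treatment cell and the contrast coding of the three fertilizer
#' gradient treatments (control 0, low 1, high 2 by default, mirroring the
#' 2:2 / 3:1 / 4:0 dripper ratios of a split-irrigation setup).
#'
#' @param profiles Tibble from [species_profiles()].
#' @param pots_per_cell Pots per species x treatment cell (>= 2).
#' @param contrasts Named numeric vector mapping treatment to contrast level;
#'   must contain `control = 0` and increasing treated levels.
#' @param seed Integer master seed.
#' @return A list of class `experiment_design`.
#' @export
experiment_design <- function(profiles, pots_per_cell,
                              contrasts = c(control = 0, low = 1, high = 2),
                              seed = 1L) {
  assert_count(pots_per_cell, "pots_per_cell", min = 2L)
  if (is.null(names(contrasts)) || !"control" %in% names(contrasts)) {
    abort("`contrasts` must be a named vector including 'control'.")
  }
  if (contrasts[["control"]] != 0) abort("contrast(control) must be 0.")
  treated <- contrasts[setdiff(names(contrasts), "control")]
  if (length(treated) && is.unsorted(treated, strictly = TRUE)) {
    abort("treated contrast levels must be strictly increasing.")
  }
  structure(
    list(
      profiles = profiles,
      pots_per_cell = as.integer(pots_per_cell),
      contrasts = contrasts,
      seed = as.integer(seed)
    ),
    class = "experiment_design"
  )
}

#' Simulate pot-level root mass records
#'
#' For each species x treatment x pot, draws a latent precision
#' `p ~ delta * contrast + omega * SN(gamma)` (the skew-normal is
#' median-centered, so the median of `p` is exactly `delta * contrast`) and a
#' lognormal total root mass `T`, then splits `T` between the two pot halves so
#' that `log(mass_rich / mass_poor) = p` holds exactly:
#' `mass_rich = T * plogis(p)`, `mass_poor = T * plogis(-p)`.
#'
#' For control pots there is no rich or poor half; the two columns are the
#' arbitrarily labelled first and second halves (see
#' [assign_control_halves()]).
#'
#' @param design An [experiment_design()].
#' @return Tibble with columns `species`, `treatment`, `mass_rich_g`,
#'   `mass_poor_g`, `pot_id`, plus the latent `.p` kept for validation.
#' @export
simulate_pots <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  prof <- design$profiles
  cells <- tidyr::expand_grid(
    species = prof$species,
    treatment = names(design$contrasts)
  )
  with_seed(substream_seed(design$seed, "pots"), function() {
    purrr::pmap_dfr(cells, function(species, treatment) {
      row <- prof[prof$species == species, ]
      k <- design$pots_per_cell
      contrast <- design$contrasts[[treatment]]
      z <- rskewnorm(k, row$gamma) - skewnorm_median(row$gamma)
      p <- row$delta * contrast + row$omega * z
      total <- rlnorm(k, meanlog = row$mu_t, sdlog = row$sigma_t)
      tibble::tibble(
        species = species,
        treatment = treatment,
        mass_rich_g = total * stats::plogis(p),
        mass_poor_g = total * stats::plogis(-p),
        pot_id = sprintf("%s_%s_%02d", species, treatment, seq_len(k)),
        .p = p
      )
    })
  })
}

#' Simulate species traits on a phylogeny
#'
#' Latent trait values evolve under Brownian motion with Pagel's-lambda
#' structured covariance: off-diagonal elements of the tree's Brownian
#' covariance are multiplied by `lambda_true` (`0` = star phylogeny /
#' independent species, `1` = full Brownian motion). Latents are mapped to the
#' standard life-history trait scales:
#' \itemize{
#'   \item `sla` (m^2/g), `leaf_area` (m^2), `height` (m), `lateral_spread`
#'     (m): lognormal transforms of latents (always positive);
#'   \item `generative_repro`, `vegetative_repro`: latents cut at their sample
#'     quintiles into the 1..5 ordinal garden-expansion scale;
#'   \item `shoot_lifespan`: two-level ordinal (1/2), median split;
#'   \item `clonality`: binary, median split of its latent;
#'   \item `lateral_spread` is defined for clonal species only (NA otherwise).
#' }
#' `missing_rate` knocks out cells of `sla`, `leaf_area` and
#' `generative_repro` completely at random, emulating database gaps.
#'
#' @param tree Phylogeny whose tips name the species.
#' @param lambda_true Phylogenetic signal in `[0, 1]` used to generate latents.
#' @param seed Integer seed.
#' @param missing_rate Probability a knockout-eligible cell is missing.
#' @param n_extra_continuous Extra generic continuous traits (`cont_1`, ...)
#'   appended, e.g. for signal-recovery experiments.
#' @param keep_latent Keep the raw latent columns (`.latent_<name>`)?
#' @return Tibble, one row per species.
#' @export
simulate_traits <- function(tree, lambda_true = 0, seed = 1L,
                            missing_rate = 0.05, n_extra_continuous = 0L,
                            keep_latent = FALSE) {
  if (!inherits(tree, "phylo")) abort("`tree` must be a phylo object.")
  if (length(tree$tip.label) < 3) abort("`tree` must have >= 3 tips.")
  if (!is.numeric(lambda_true) || lambda_true < 0 || lambda_true > 1) {
    abort("`lambda_true` must lie in [0, 1].")
  }
  n <- length(tree$tip.label)
  V <- lambda_transform(phylo_covariance(tree), lambda_true)
  L <- t(chol(V))
  draw_latent <- function() as.vector(L %*% rnorm(n))

  with_seed(substream_seed(seed, "traits"), function() {
    lat <- list(
      sla = draw_latent(), leaf_area = draw_latent(), height = draw_latent(),
      lateral_spread = draw_latent(), generative_repro = draw_latent(),
      vegetative_repro = draw_latent(), shoot_lifespan = draw_latent(),
      clonality = draw_latent()
    )
    to_ordinal <- function(x, k) {
      cuts <- quantile(x, probs = seq(0, 1, length.out = k + 1))
      as.integer(cut(x, breaks = cuts, include.lowest = TRUE, labels = FALSE))
    }
    clonality <- as.integer(lat$clonality > median(lat$clonality))
    out <- tibble::tibble(
      species = tree$tip.label,
      sla = exp(0.3 * scale_vec(lat$sla) + log(0.02)),
      leaf_area = exp(1.0 * scale_vec(lat$leaf_area) + log(0.001)),
      height = exp(0.6 * scale_vec(lat$height) + log(0.5)),
      lateral_spread = ifelse(
        clonality == 1,
        exp(0.8 * scale_vec(lat$lateral_spread) + log(0.1)), NA_real_
      ),
      generative_repro = to_ordinal(lat$generative_repro, 5L),
      vegetative_repro = to_ordinal(lat$vegetative_repro, 5L),
      shoot_lifespan = as.integer(lat$shoot_lifespan > median(lat$shoot_lifespan)) + 1L,
      clonality = clonality
    )
    for (col in c("sla", "leaf_area", "generative_repro")) {
      gone <- runif(n) < missing_rate
      out[[col]][gone] <- NA
    }
    if (n_extra_continuous > 0) {
      for (j in seq_len(n_extra_continuous)) {
        out[[paste0("cont_", j)]] <- draw_latent()
      }
    }
    if (keep_latent) {
      for (nm in names(lat)) out[[paste0(".latent_", nm)]] <- lat[[nm]]
    }
    out
  })
}

scale_vec <- function(x) {
  s <- sd(x)
  if (s == 0) x - mean(x) else (x - mean(x)) / s
}

#' Simulate a complete split-pot foraging study
#'
#' One call producing the three inputs of the pipeline — pot records, trait
#' table and phylogeny — under a known ground truth. Per-species foraging
#' strengths are `delta_i = delta_mean + delta_sd * z_i +
#' clonality_effect * clonality_i`, so a negative `clonality_effect` builds in
#' the clonal-plants-forage-less coupling with known sign and magnitude.
#'
#' @param n_species Number of species (tree tips).
#' @param pots_per_cell Pots per species x treatment cell.
#' @param delta_mean,delta_sd Mean and between-species sd of the baseline
#'   foraging strength.
#' @param clonality_effect Additive shift of `delta` for clonal species
#'   (negative = clonal species forage less; `0` decouples traits from
#'   responses).
#' @param omega,gamma Precision scale and skewness shape shared by all species.
#' @param mu_t,sigma_t Lognormal parameters of total root mass (grams).
#' @param lambda_true Phylogenetic signal used for trait latents.
#' @param missing_rate Passed to [simulate_traits()].
#' @param seed Master seed; tree, traits, deltas and pots use independent
#'   substreams derived from it.
#' @return List with elements `pots`, `traits`, `tree`, `profiles`, `design`.
#' @examples
#' study <- simulate_study(n_species = 12, pots_per_cell = 4, seed = 42)
#' head(study$pots)
#' @export
simulate_study <- function(n_species = 37, pots_per_cell = 10,
                           delta_mean = 0.5, delta_sd = 0.25,
                           clonality_effect = -0.5,
                           omega = 0.5, gamma = 2,
                           mu_t = 0, sigma_t = 0.5,
                           lambda_true = 0, missing_rate = 0.05,
                           seed = 1L) {
  tree <- simulate_tree(n_species, seed = substream_seed(seed, "tree"))
  traits <- simulate_traits(
    tree,
    lambda_true = lambda_true, seed = seed, missing_rate = missing_rate
  )
  delta <- with_seed(substream_seed(seed, "delta"), function() {
    delta_mean + delta_sd * rnorm(n_species) +
      clonality_effect * traits$clonality
  })
  prof <- species_profiles(
    tree$tip.label,
    delta = delta, omega = omega, gamma = gamma,
    mu_t = mu_t, sigma_t = sigma_t
  )
  design <- experiment_design(prof, pots_per_cell = pots_per_cell, seed = seed)
  pots <- simulate_pots(design)
  list(pots = pots, traits = traits, tree = tree, profiles = prof,
       design = design)
}

#' Write simulated study inputs to disk
#'
#' Writes `pots.csv` (species, treatment, mass_rich_g, mass_poor_g, pot_id),
#' `traits.csv` (empty cell = missing) and `tree.nwk` under `dir`.
#'
#' @param study A list as returned by [simulate_study()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pots <- dplyr::select(study$pots, !dplyr::starts_with("."))
  write.csv(pots, file.path(dir, "pots.csv"), row.names = FALSE, na = "")
  write.csv(study$traits, file.path(dir, "traits.csv"),
            row.names = FALSE, na = "")
  ape::write.tree(study$tree, file.path(dir, "tree.nwk"))
  invisible(dir)
}
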