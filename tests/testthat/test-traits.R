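toy_responses <- function(values, species = sprintf("s%d", seq_along(values))) {
  tibble::tibble(
    species = species, m = 5L, n_low = 5L, n_high = 5L,
    foraging_low = values / 2, foraging_high = values,
    plasticity_low = abs(values / 2), plasticity_high = abs(values)
  )
}

test_that("prepare_traits logs leaf area, preserves missingness, rejects nonpositive", {
  tt <- tibble::tibble(
    species = c("a", "b", "c"),
    leaf_area = c(1, exp(2), NA),
    sla = c(0.01, NA, 0.03)
  )
  out <- prepare_traits(tt)
  expect_equal(out$leaf_area, c(0, 2, NA))
  expect_equal(out$sla, tt$sla) # untouched, missing preserved
  bad <- tibble::tibble(species = "a", leaf_area = -1)
  expect_warning(out2 <- prepare_traits(bad), "nonpositive")
  expect_true(is.na(out2$leaf_area))
})

test_that("correlate picks the method from trait scale and hits the perfect limits", {
  n <- 10
  resp <- toy_responses(seq(-0.4, 0.4, length.out = n))
  traits <- tibble::tibble(
    species = resp$species,
    vegetative_repro = rep(1:5, each = 2), # ordinal, increasing with response
    height = exp(resp$foraging_high) # continuous, monotone but nonlinear
  )
  r1 <- correlate(resp, traits, "vegetative_repro")
  expect_equal(r1$method, "spearman")
  expect_equal(r1$estimate, cor(rank(traits$vegetative_repro),
                                rank(resp$foraging_high)))
  expect_gt(r1$estimate, 0.9)

  # strictly increasing ordinal-free case: rho exactly 1
  traits$generative_repro <- 1:10
  expect_equal(correlate(resp, traits, "generative_repro")$estimate, 1)

  # exactly linear continuous trait: r exactly 1
  traits$sla <- 3 * resp$foraging_high + 2
  r2 <- correlate(resp, traits, "sla")
  expect_equal(r2$method, "pearson")
  expect_equal(r2$estimate, 1)
})

test_that("pairwise deletion matches a hand-computed rank formula on 6 complete pairs", {
  resp <- toy_responses(c(0.1, -0.2, 0.3, 0.05, -0.1, 0.25, 0.4, -0.3),
                        species = letters[1:8])
  traits <- tibble::tibble(
    species = letters[1:8],
    vegetative_repro = c(2, 4, NA, 1, 5, NA, 3, 2)
  )
  res <- correlate(resp, traits, "vegetative_repro")
  expect_equal(res$n_used, 6)
  keep <- !is.na(traits$vegetative_repro)
  rx <- rank(traits$vegetative_repro[keep])
  ry <- rank(resp$foraging_high[keep])
  # hand rank formula with the midrank tie adjustment folded into cor()
  expect_equal(res$estimate, sum((rx - mean(rx)) * (ry - mean(ry))) /
                 sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2)))

  # adding a species with a missing trait cell never changes the coefficient
  resp2 <- dplyr::bind_rows(resp, toy_responses(0.9, species = "zz"))
  traits2 <- dplyr::bind_rows(
    traits, tibble::tibble(species = "zz", vegetative_repro = NA_real_)
  )
  expect_equal(correlate(resp2, traits2, "vegetative_repro")$estimate,
               res$estimate)
  expect_error(correlate(resp[1:4, ], traits[1:4, ], "vegetative_repro"),
               "complete pairs")
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(11)
  resp <- toy_responses(rnorm(12, 0, 0.2))
  traits <- tibble::tibble(species = resp$species, clonality = rep(0:1, 6))
  base <- correlate(resp, traits, "clonality")$estimate
  resp_t <- resp
  resp_t$foraging_high <- exp(3 * resp$foraging_high)
  expect_equal(correlate(resp_t, traits, "clonality")$estimate, base)
})

test_that("binary-trait rho sign matches the group median ordering", {
  set.seed(12)
  for (i in 1:10) {
    clon <- rep(c(0, 1), times = c(6, 6))
    # group-separated, tie-free responses
    vals <- c(rnorm(6, 0.3, 0.05), rnorm(6, -0.1, 0.05))
    resp <- toy_responses(vals)
    traits <- tibble::tibble(species = resp$species, clonality = clon)
    rho <- correlate(resp, traits, "clonality")$estimate
    med_diff <- median(vals[clon == 1]) - median(vals[clon == 0])
    expect_equal(sign(rho), sign(med_diff))
  }
})

test_that("exact permutation Spearman p matches full enumeration at small n", {
  set.seed(13)
  resp <- toy_responses(rnorm(6))
  traits <- tibble::tibble(species = resp$species,
                           vegetative_repro = c(3, 1, 4, 2, 5, 2))
  res <- correlate(resp, traits, "vegetative_repro", exact_permutation = TRUE)
  # oracle: direct enumeration over the 720 permutations
  rx <- rank(traits$vegetative_repro)
  ry <- rank(resp$foraging_high)
  obs <- cor(rx, ry)
  perms <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], perms(v[-i]))
    }))
  }
  all_p <- perms(seq_len(6))
  stats <- apply(all_p, 1, function(idx) cor(rx, ry[idx]))
  expect_equal(res$p_value, mean(abs(stats) >= abs(obs) - 1e-12))
})

test_that("association table covers both forms x all traits, clonal-subset lateral spread", {
  study <- small_study()
  prec <- compute_precision(strip_latent(study$pots))
  resp <- species_responses(prec)
  traits <- prepare_traits(study$traits)
  tab <- association_table(resp, traits)
  expect_equal(nrow(tab), 16)
  expect_setequal(unique(tab$response_form), c("foraging", "plasticity"))
  n_clonal <- sum(traits$clonality == 1 & !is.na(traits$lateral_spread))
  ls_rows <- tab[tab$trait == "lateral_spread", ]
  expect_true(all(is.na(ls_rows$n_used) | ls_rows$n_used == n_clonal))
  # plasticity rows equal foraging rows when all foraging values positive
  resp_pos <- resp
  resp_pos$foraging_high <- abs(resp_pos$foraging_high)
  resp_pos$plasticity_high <- resp_pos$foraging_high
  tab_pos <- association_table(resp_pos, traits)
  f <- tab_pos[tab_pos$response_form == "foraging", ]
  p <- tab_pos[tab_pos$response_form == "plasticity", ]
  expect_equal(f$estimate, p$estimate)
  # optional Holm adjustment
  tab_h <- association_table(resp, traits, p_adjust = "holm")
  expect_true(all(tab_h$p_adjusted >= tab_h$p_value, na.rm = TRUE))
})

test_that("collinearity matrix is symmetric, unit-diagonal, and matches direct formulas", {
  set.seed(14)
  traits <- tibble::tibble(
    species = sprintf("s%d", 1:6),
    sla = rnorm(6), height = rnorm(6), clonality = c(0, 1, 0, 1, 1, 0)
  )
  long <- trait_collinearity_matrix(traits)
  m <- collinearity_matrix_wide(long)
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_equal(m, t(m))
  expect_equal(m["sla", "height"], cor(traits$sla, traits$height))
  expect_equal(m["sla", "clonality"],
               cor(rank(traits$sla), rank(traits$clonality)))
  # duplicated (affinely transformed) trait column: off-diagonal exactly 1
  traits$leaf_area <- 2 * traits$sla + 1
  long2 <- trait_collinearity_matrix(traits)
  m2 <- collinearity_matrix_wide(long2)
  expect_equal(m2["sla", "sla"], 1)
  expect_equal(m2["sla", "leaf_area"], 1)
})
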