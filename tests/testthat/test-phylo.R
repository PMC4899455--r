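test_that("newick reading: hand tree, round trip, generator label set", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  d <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(d, rep(2, 3))
  # round trip preserves pairwise tip distances
  txt <- ape::write.tree(tr)
  tr2 <- read_newick(txt)
  expect_equal(
    ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label],
    ape::cophenetic.phylo(tr2)[tr$tip.label, tr$tip.label]
  )
  sim <- simulate_tree(37, seed = 2)
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(sim, f)
  expect_setequal(read_newick(f)$tip.label, sim$tip.label)
  expect_error(read_newick("(A,B,C);"), "branch length")
})

test_that("phylogenetic covariance reads off shared path lengths", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  V <- phylo_covariance(tr, tips = c("A", "B", "C"))
  expect_equal(unname(diag(V)), c(2, 2, 2))
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "C"], 0)
  expect_equal(V["B", "C"], 0)
  expect_error(phylo_covariance(tr, tips = c("A", "Z")), "Z")

  star <- ape::stree(5, "star")
  star$edge.length <- rep(1, 5)
  expect_equal(phylo_covariance(star), diag(5),
               ignore_attr = TRUE)
  # random Yule tree: PSD
  V2 <- phylo_covariance(simulate_tree(60, seed = 9))
  expect_gte(min(eigen(V2, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
})

test_that("lambda transform scales off-diagonals only", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  V <- phylo_covariance(tr)
  expect_equal(lambda_transform(V, 1), V)
  expect_equal(lambda_transform(V, 0), diag(diag(V)), ignore_attr = TRUE)
  W <- lambda_transform(V, 0.5)
  expect_equal(W["A", "B"], 0.5)
  expect_equal(unname(diag(W)), c(2, 2, 2))
  expect_error(lambda_transform(V, 1.5), "lambda")
})

test_that("lambda likelihood surface: optimizer beats a 51-point grid and CI endpoints sit at the cutoff", {
  tr <- simulate_tree(80, seed = 21)
  V <- phylo_covariance(tr)
  set.seed(22)
  L <- t(chol(lambda_transform(V, 0.7)))
  y <- setNames(as.vector(L %*% rnorm(80)), tr$tip.label)
  fit <- ml_lambda(y, tr)
  X <- matrix(1, 80, 1)
  ll <- function(l) rootforage:::gls_profile(
    unname(y), X, lambda_transform(V, l)
  )$logLik
  grid_ll <- vapply(seq(0, 1, length.out = 51), ll, numeric(1))
  expect_gte(fit$log_likelihood, max(grid_ll) - 1e-6)
  cutoff <- fit$log_likelihood - qchisq(0.95, 1) / 2
  for (e in c(fit$ci_lower, fit$ci_upper)) {
    if (e > 0 && e < 1) expect_equal(ll(e), cutoff, tolerance = 1e-3)
  }
  expect_true(fit$ci_lower <= fit$lambda_hat & fit$lambda_hat <= fit$ci_upper)
})

test_that("lambda fit is invariant to overall branch-length scaling", {
  tr <- simulate_tree(60, seed = 23)
  set.seed(24)
  V <- phylo_covariance(tr)
  L <- t(chol(lambda_transform(V, 0.5)))
  y <- setNames(as.vector(L %*% rnorm(60)), tr$tip.label)
  f1 <- ml_lambda(y, tr)
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 73.5
  f2 <- ml_lambda(y, tr2)
  expect_equal(f1$lambda_hat, f2$lambda_hat, tolerance = 1e-4)
  expect_equal(f1$p_vs_zero, f2$p_vs_zero, tolerance = 1e-6)
})

test_that("star phylogeny is flagged unidentifiable with CI [0, 1]", {
  star <- ape::stree(12, "star")
  star$edge.length <- rep(1, 12)
  set.seed(25)
  fit <- ml_lambda(setNames(rnorm(12), star$tip.label), star)
  expect_false(fit$identifiable)
  expect_equal(c(fit$ci_lower, fit$ci_upper), c(0, 1))
})

test_that("lambda ML agrees with an independent reference implementation", {
  skip_if_not_installed("phytools")
  tr <- simulate_tree(100, seed = 26)
  V <- phylo_covariance(tr)
  set.seed(27)
  L <- t(chol(lambda_transform(V, 0.6)))
  y <- setNames(as.vector(L %*% rnorm(100)), tr$tip.label)
  fit <- ml_lambda(y, tr)
  ref <- phytools::phylosig(tr, y, method = "lambda")
  expect_equal(fit$lambda_hat, ref$lambda, tolerance = 0.02)
  expect_equal(fit$log_likelihood, ref$logL, tolerance = 1e-3)
})

test_that("PGLS: perfect fit, OLS limit, and the two-route GLS identity", {
  tr <- simulate_tree(40, seed = 28)
  set.seed(29)
  d <- tibble::tibble(species = tr$tip.label, x = rnorm(40))
  d$y <- 2 * d$x + 3
  for (mode in c("ml", "fixed_1", "fixed_0")) {
    fit <- pgls_fit(d, y ~ x, tr, lambda_mode = mode)
    expect_equal(tidy(fit)$estimate, c(3, 2), tolerance = 1e-8)
  }
  # lambda = 0 equals OLS (ultrametric tree -> identity covariance)
  d$y <- d$y + rnorm(40)
  f0 <- pgls_fit(d, y ~ x, tr, lambda_mode = "fixed_0")
  ols <- lm(y ~ x, data = d)
  expect_equal(tidy(f0)$estimate, unname(coef(ols)), tolerance = 1e-8)
  expect_equal(tidy(f0)$std.error,
               unname(summary(ols)$coefficients[, 2]), tolerance = 1e-8)

  # whitening route (implementation) vs closed-form normal equations
  set.seed(30)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    trn <- simulate_tree(n, seed = 300 + i)
    dn <- tibble::tibble(species = trn$tip.label, x = rnorm(n),
                         y = rnorm(n))
    lam <- runif(1)
    W <- lambda_transform(phylo_covariance(trn), lam)
    X <- cbind(1, dn$x)
    beta_direct <- solve(t(X) %*% solve(W, X), t(X) %*% solve(W, dn$y))
    prof <- rootforage:::gls_profile(dn$y, X, W)
    expect_equal(unname(prof$beta), as.vector(beta_direct), tolerance = 1e-8)
  }
})

test_that("PGLS t-statistics are invariant to branch-length scaling", {
  tr <- simulate_tree(30, seed = 31)
  set.seed(32)
  d <- tibble::tibble(species = tr$tip.label, x = rnorm(30),
                      y = rnorm(30))
  f1 <- pgls_fit(d, y ~ x, tr, lambda_mode = "ml")
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 0.013
  f2 <- pgls_fit(d, y ~ x, tr2, lambda_mode = "ml")
  expect_equal(tidy(f1)$statistic, tidy(f2)$statistic, tolerance = 1e-5)
  expect_equal(f1$lambda, f2$lambda, tolerance = 1e-4)
})

test_that("phylo association check recovers the clonality coupling and flags sign agreement", {
  study <- simulate_study(n_species = 25, pots_per_cell = 8,
                          clonality_effect = -0.6, lambda_true = 0,
                          missing_rate = 0, seed = 33)
  prec <- compute_precision(strip_latent(study$pots))
  resp <- species_responses(prec)
  traits <- prepare_traits(study$traits)
  chk <- phylo_association_check(resp, traits, study$tree)
  clon <- chk[chk$trait == "clonality" & chk$response_form == "foraging", ]
  expect_lt(clon$slope, 0)
  expect_true(clon$sign_agrees)
  expect_equal(nrow(chk), 16)
})
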