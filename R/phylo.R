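#' Read a phylogeny from Newick
#'
#' Parses a rooted Newick tree, requiring branch lengths (no silent default)
#' and unique tip labels. Zero-length branches are tolerated here; downstream
#' covariance construction collapses them.
#'
#' @param source Path to a Newick file, or a Newick string.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(source) {
  tr <- if (length(source) == 1 && grepl("(", source, fixed = TRUE) &&
              !file.exists(source)) {
    ape::read.tree(text = source)
  } else {
    ape::read.tree(source)
  }
  if (is.null(tr)) abort("could not parse Newick input.")
  if (is.null(tr$edge.length)) {
    abort("Newick tree has no branch lengths; lengths are required.")
  }
  if (anyNA(tr$edge.length) || any(tr$edge.length < 0)) {
    abort("Newick tree has missing or negative branch lengths.")
  }
  if (anyDuplicated(tr$tip.label)) abort("tip labels must be unique.")
  tr
}

#' Brownian phylogenetic covariance matrix
#'
#' Entry (i, j) is the shared path length from the root to the most recent
#' common ancestor of tips i and j; the diagonal holds root-to-tip distances
#' (the tree need not be ultrametric). This is the residual covariance implied
#' by Brownian motion evolution along the tree.
#'
#' @param tree An [ape::phylo] object with branch lengths.
#' @param tips Optional character vector ordering/subsetting the tips; all
#'   must be present in the tree.
#' @return Symmetric positive-semidefinite matrix with tip labels as
#'   dimnames.
#' @export
phylo_covariance <- function(tree, tips = NULL) {
  if (!inherits(tree, "phylo")) abort("`tree` must be a phylo object.")
  if (!is.null(tips)) {
    unknown <- setdiff(tips, tree$tip.label)
    if (length(unknown)) {
      abort(paste0("tip(s) not in tree: ", toString(unknown)))
    }
    if (length(tips) < length(tree$tip.label)) {
      tree <- ape::keep.tip(tree, tips)
    }
  }
  V <- ape::vcv.phylo(tree)
  if (!is.null(tips)) V <- V[tips, tips, drop = FALSE]
  V
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries of the Brownian covariance by
#' `lambda` while leaving the diagonal untouched. `lambda = 1` returns the
#' matrix unchanged (Brownian motion); `lambda = 0` is the star-phylogeny
#' limit (independent species). The result stays positive semidefinite for
#' `lambda` in `[0, 1]`, the search range used throughout this package.
#'
#' @param V Covariance from [phylo_covariance()].
#' @param lambda Signal strength in `[0, 1]`.
#' @return Transformed covariance matrix.
#' @export
lambda_transform <- function(V, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
        lambda < 0 || lambda > 1) {
    abort("`lambda` must be a single value in [0, 1].")
  }
  W <- V * lambda
  diag(W) <- diag(V)
  W
}

# Collapse zero-length terminal/internal branches by nudging them to a tiny
# positive fraction of tree depth; protects chol() from exact singularity
# caused by identical rows.
sanitize_tree <- function(tree) {
  if (any(tree$edge.length == 0)) {
    inform("Zero-length branches collapsed to 1e-8 x tree depth for covariance construction.")
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length[tree$edge.length == 0] <- 1e-8 * max(depth, 1)
  }
  tree
}

# Profiled MVN log-likelihood of y ~ X under covariance sigma^2 * W, with
# beta and sigma^2 maximised analytically (ML, not REML). Returns logLik and
# the profiled estimates.
gls_profile <- function(y, X, W) {
  n <- length(y)
  L <- tryCatch(chol(W), error = function(e) {
    abort(paste0(
      "Transformed phylogenetic covariance is numerically singular (",
      conditionMessage(e),
      "). Collapse zero-length branches or check for duplicated tips."
    ))
  })
  # whiten: solve L' z = v  (W = L'L with R's upper-triangular chol)
  yw <- backsolve(L, y, transpose = TRUE)
  Xw <- backsolve(L, X, transpose = TRUE)
  fit <- stats::lm.fit(Xw, yw)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n
  logdet <- 2 * sum(log(diag(L)))
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdet + n)
  XtWiX <- crossprod(Xw)
  list(
    logLik = ll, beta = beta, sigma2 = sigma2, rss = rss,
    XtWiX = XtWiX, n = n
  )
}

#' Maximum-likelihood Pagel's lambda for a tip-level variable
#'
#' Profiles the multivariate-normal log-likelihood of an intercept-only
#' phylogenetic model over lambda in `[0, 1]` (mean and variance maximised
#' analytically at each lambda), locating the ML estimate by bounded scalar
#' optimisation. The 95% confidence interval is the profile-likelihood set
#' `{lambda : logL >= logL(max) - 1.92}` (chi-square-1 cutoff); likelihood
#' ratio tests against lambda = 0 and lambda = 1 use the boundary-corrected
#' 0.5*chi2_0 + 0.5*chi2_1 mixture. On a star phylogeny lambda does not enter
#' the likelihood; the fit is flagged unidentifiable with CI `[0, 1]`.
#'
#' @param values Named numeric vector (names = tip labels) or unnamed vector
#'   in tip order.
#' @param tree Phylogeny covering those tips.
#' @return Object of class `lambda_fit`: `lambda_hat`, `log_likelihood`,
#'   `ci_lower`, `ci_upper`, `p_vs_zero`, `p_vs_one`, `identifiable`, `n`.
#' @export
ml_lambda <- function(values, tree) {
  prep <- align_tip_values(values, tree)
  y <- prep$y
  n <- length(y)
  if (n < 10) warn("fewer than 10 tips with values; lambda estimate will be imprecise.")
  V <- phylo_covariance(prep$tree)
  X <- matrix(1, n, 1)
  ll_fun <- function(lam) gls_profile(y, X, lambda_transform(V, lam))$logLik

  grid <- seq(0, 1, length.out = 21)
  ll_grid <- vapply(grid, ll_fun, numeric(1))
  if (max(ll_grid) - min(ll_grid) < 1e-8) {
    return(new_lambda_fit(
      NA_real_, ll_grid[[1]], 0, 1, 1, 1,
      identifiable = FALSE, n = n
    ))
  }
  opt <- optimize(ll_fun, interval = c(0, 1), maximum = TRUE, tol = 1e-7)
  cand <- rbind(
    c(opt$maximum, opt$objective),
    cbind(grid, ll_grid)
  )
  best <- cand[which.max(cand[, 2]), ]
  lambda_hat <- best[[1]]
  ll_max <- best[[2]]

  cutoff <- ll_max - stats::qchisq(0.95, df = 1) / 2 # 1.92
  ci_lower <- if (ll_fun(0) >= cutoff) 0 else {
    uniroot(function(l) ll_fun(l) - cutoff, c(0, lambda_hat), tol = 1e-5)$root
  }
  ci_upper <- if (ll_fun(1) >= cutoff) 1 else {
    uniroot(function(l) ll_fun(l) - cutoff, c(lambda_hat, 1), tol = 1e-5)$root
  }
  boundary_lrt_p <- function(ll0) {
    lr <- 2 * (ll_max - ll0)
    if (lr <= 0) 1 else 0.5 * pchisq(lr, df = 1, lower.tail = FALSE)
  }
  new_lambda_fit(
    lambda_hat, ll_max, ci_lower, ci_upper,
    p_vs_zero = boundary_lrt_p(ll_fun(0)),
    p_vs_one = boundary_lrt_p(ll_fun(1)),
    identifiable = TRUE, n = n
  )
}

new_lambda_fit <- function(lambda_hat, ll, lo, hi, p_vs_zero, p_vs_one,
                           identifiable, n) {
  structure(
    list(
      lambda_hat = lambda_hat, log_likelihood = ll,
      ci_lower = lo, ci_upper = hi,
      p_vs_zero = p_vs_zero, p_vs_one = p_vs_one,
      identifiable = identifiable, n = n
    ),
    class = "lambda_fit"
  )
}

#' @export
print.lambda_fit <- function(x, ...) {
  if (!x$identifiable) {
    cat("Pagel's lambda: unidentifiable (star phylogeny), CI [0, 1]\n")
  } else {
    cat(sprintf(
      "Pagel's lambda = %.3f (95%% CI %.3f-%.3f), n = %d\n  LRT vs 0: p = %.4g; vs 1: p = %.4g\n",
      x$lambda_hat, x$ci_lower, x$ci_upper, x$n, x$p_vs_zero, x$p_vs_one
    ))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.lambda_fit <- function(x, ...) {
  tibble::tibble(
    term = "lambda", estimate = x$lambda_hat,
    conf.low = x$ci_lower, conf.high = x$ci_upper,
    p.vs.zero = x$p_vs_zero, p.vs.one = x$p_vs_one
  )
}

#' @exportS3Method generics::glance
glance.lambda_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$log_likelihood, nobs = x$n, identifiable = x$identifiable
  )
}

align_tip_values <- function(values, tree) {
  tree <- sanitize_tree(tree)
  if (!is.null(names(values))) {
    values <- values[!is.na(values)]
    unknown <- setdiff(names(values), tree$tip.label)
    if (length(unknown)) abort(paste0("tip(s) not in tree: ", toString(unknown)))
    keep <- names(values)
    if (length(keep) < 3) abort("need >= 3 tips with data.")
    tree <- ape::keep.tip(tree, keep)
    y <- values[tree$tip.label]
  } else {
    if (length(values) != length(tree$tip.label)) {
      abort("unnamed `values` must match the number of tips.")
    }
    if (anyNA(values)) abort("unnamed `values` must not contain NA; name them to allow pruning.")
    y <- values
  }
  list(y = as.numeric(y), tree = tree)
}

#' Phylogenetic generalized least squares
#'
#' Regression of a tip-level response on tip-level predictors with residual
#' covariance `sigma^2 * V(lambda)` from the phylogeny. `lambda_mode = "ml"`
#' profiles lambda in `[0, 1]` jointly with the regression (maximum
#' likelihood); `"fixed_1"` fixes lambda at 1 (Brownian motion), the
#' conventional parallel check; `"fixed_0"` reduces to ordinary least squares
#' on an ultrametric tree. Species with missing response or predictor are
#' dropped pairwise and the tree pruned to the rest. Coefficient tests are
#' t-based with `n - p` degrees of freedom.
#'
#' @param data Data frame with a `species` column matching tip labels.
#' @param formula Model formula, e.g. `foraging_high ~ clonality`.
#' @param tree Phylogeny.
#' @param lambda_mode One of `"ml"`, `"fixed_1"`, `"fixed_0"`.
#' @return Object of class `pgls_fit` with a coefficient table, `lambda`,
#'   `sigma2`, `log_likelihood`, `n`.
#' @export
pgls_fit <- function(data, formula, tree, lambda_mode = c("ml", "fixed_1", "fixed_0")) {
  lambda_mode <- match.arg(lambda_mode)
  vars <- all.vars(formula)
  d <- data[, c("species", vars)]
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < 5) abort("fewer than 5 complete species for PGLS.")
  tree <- sanitize_tree(tree)
  unknown <- setdiff(d$species, tree$tip.label)
  if (length(unknown)) abort(paste0("species not in tree: ", toString(unknown)))
  tree <- ape::keep.tip(tree, d$species)
  d <- d[match(tree$tip.label, d$species), , drop = FALSE]
  mf <- stats::model.frame(formula, d)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  V <- phylo_covariance(tree)

  fit_at <- function(lam) gls_profile(y, X, lambda_transform(V, lam))
  if (lambda_mode == "ml") {
    opt <- optimize(function(l) fit_at(l)$logLik,
      interval = c(0, 1), maximum = TRUE, tol = 1e-7
    )
    # compare with the boundaries; optimize can miss a boundary maximum
    lls <- c(fit_at(0)$logLik, fit_at(1)$logLik, opt$objective)
    lambda <- c(0, 1, opt$maximum)[which.max(lls)]
  } else {
    lambda <- if (lambda_mode == "fixed_1") 1 else 0
  }
  fit <- fit_at(lambda)
  p <- ncol(X)
  n <- length(y)
  sigma2_unbiased <- fit$rss / (n - p)
  vcov_beta <- sigma2_unbiased * solve(fit$XtWiX)
  se <- sqrt(diag(vcov_beta))
  tstat <- fit$beta / se
  pval <- 2 * pt(-abs(tstat), df = n - p)
  coef_tbl <- tibble::tibble(
    term = colnames(X), estimate = unname(fit$beta),
    std.error = unname(se), statistic = unname(tstat),
    p.value = unname(pval)
  )
  structure(
    list(
      coefficients = coef_tbl, lambda = lambda, lambda_mode = lambda_mode,
      sigma2 = fit$sigma2, log_likelihood = fit$logLik, n = n,
      formula = formula
    ),
    class = "pgls_fit"
  )
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf(
    "PGLS (%s, lambda = %.3f, n = %d): %s\n",
    x$lambda_mode, x$lambda, x$n, deparse(x$formula)
  ))
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pgls_fit <- function(x, ...) x$coefficients

#' @exportS3Method generics::glance
glance.pgls_fit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, sigma2 = x$sigma2, logLik = x$log_likelihood,
    nobs = x$n, lambda_mode = x$lambda_mode
  )
}

#' Phylogenetic check of the trait-response associations
#'
#' One PGLS per trait and response form (response regressed on the single
#' trait), with the slope's sign compared to the corresponding ordinary
#' correlation from [association_table()]: `sign_agrees` flags where the
#' phylogenetic analysis would qualitatively change the story.
#'
#' @param responses Tibble from [species_responses()].
#' @param traits Prepared trait table.
#' @param tree Phylogeny.
#' @param lambda_mode Passed to [pgls_fit()].
#' @param association Optional precomputed [association_table()] (recomputed
#'   if NULL).
#' @return Tibble: `trait`, `response_form`, `slope`, `std.error`, `p_value`,
#'   `lambda`, `n_used`, `ordinary_estimate`, `sign_agrees`.
#' @export
phylo_association_check <- function(responses, traits, tree,
                                    lambda_mode = "ml", association = NULL) {
  if (is.null(association)) association <- association_table(responses, traits)
  data <- dplyr::inner_join(responses, traits, by = "species")
  trait_names <- intersect(names(trait_scales()), names(traits))
  grid <- tidyr::expand_grid(
    response = c("foraging_high", "plasticity_high"),
    trait = trait_names
  )
  purrr::pmap_dfr(grid, function(response, trait) {
    form <- sub("_(low|high)$", "", response)
    ord <- association$estimate[
      association$trait == trait & association$response_form == form
    ]
    ord <- if (length(ord)) ord[[1]] else NA_real_
    fit <- tryCatch(
      pgls_fit(
        data, stats::as.formula(paste(response, "~", trait)),
        tree, lambda_mode = lambda_mode
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(tibble::tibble(
        trait = trait, response_form = form, slope = NA_real_,
        std.error = NA_real_, p_value = NA_real_, lambda = NA_real_,
        n_used = NA_integer_, ordinary_estimate = ord, sign_agrees = NA
      ))
    }
    slope_row <- fit$coefficients[fit$coefficients$term == trait, ]
    tibble::tibble(
      trait = trait, response_form = form,
      slope = slope_row$estimate, std.error = slope_row$std.error,
      p_value = slope_row$p.value, lambda = fit$lambda,
      n_used = fit$n, ordinary_estimate = ord,
      sign_agrees = !is.na(ord) && sign(slope_row$estimate) == sign(ord)
    )
  })
}
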