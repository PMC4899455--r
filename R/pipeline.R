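#' Build a pipeline run configuration
#'
#' Exactly one of `inputs` (paths to pots CSV, traits CSV, Newick tree) or
#' `synthetic` (arguments for [simulate_study()]) must be supplied. The seed
#' governs every random stage (control-half orientation, bootstrap, and the
#' generator when synthetic).
#'
#' @param inputs Named list with `pots`, `traits`, `tree` file paths, or NULL.
#' @param synthetic Named list of [simulate_study()] arguments, or NULL.
#' @param n_boot Bootstrap iterations for stability estimates.
#' @param seed Master seed.
#' @param exact_threshold Largest pair count using the exact signed-rank p.
#' @param out_dir Output directory for artifacts, or NULL to skip writing.
#' @return List of class `run_config`.
#' @export
run_config <- function(inputs = NULL, synthetic = NULL, n_boot = 1000,
                       seed = 1L, exact_threshold = 25, out_dir = NULL) {
  if (is.null(inputs) == is.null(synthetic)) {
    abort("exactly one of `inputs` and `synthetic` must be supplied.")
  }
  if (!is.null(inputs) &&
        !all(c("pots", "traits", "tree") %in% names(inputs))) {
    abort("`inputs` must name `pots`, `traits` and `tree` paths.")
  }
  structure(
    list(
      inputs = inputs, synthetic = synthetic, n_boot = n_boot,
      seed = as.integer(seed), exact_threshold = exact_threshold,
      out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Expects top-level keys matching [run_config()] arguments: either an
#' `inputs` block (`pots`, `traits`, `tree`) or a `synthetic` block of
#' generator arguments, plus optional `n_boot`, `seed`, `exact_threshold`,
#' `out_dir`.
#'
#' @param path YAML file path.
#' @return `run_config` object.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  run_config(
    inputs = cfg$inputs, synthetic = cfg$synthetic,
    n_boot = cfg$n_boot %||% 1000, seed = cfg$seed %||% 1L,
    exact_threshold = cfg$exact_threshold %||% 25,
    out_dir = cfg$out_dir
  )
}

load_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    args <- config$synthetic
    args$seed <- args$seed %||% config$seed
    study <- do.call(simulate_study, args)
    list(
      pots = dplyr::select(study$pots, !dplyr::starts_with(".")),
      traits = study$traits, tree = study$tree, study = study
    )
  } else {
    list(
      pots = tibble::as_tibble(
        read.csv(config$inputs$pots, stringsAsFactors = FALSE)
      ),
      traits = tibble::as_tibble(
        read.csv(config$inputs$traits, stringsAsFactors = FALSE)
      ),
      tree = read_newick(config$inputs$tree),
      study = NULL
    )
  }
}

#' Run the full foraging analysis pipeline
#'
#' Orchestrates: input loading (or synthesis) -> control-half orientation ->
#' per-pot precision -> medcouple diagnostics and cell medians -> paired
#' Wilcoxon treatment tests (control vs low and control vs high, Bonferroni
#' x2 because the control sample is used twice) -> species-level responses
#' and their cross-contrast correlation -> bootstrap stability and its paired
#' comparison across contrasts (raw p) -> trait associations (high-contrast
#' responses, both forms) with the collinearity diagnostic -> Pagel's lambda
#' for foraging and plasticity -> PGLS trait checks (ML lambda, plus fixed
#' lambda = 1 parallel fits). Identical `(inputs, config, seed)` give an
#' identical report. If `out_dir` is set, stage CSVs, a summary JSON, a run
#' log and a MANIFEST (config hash + seed) are written.
#'
#' @param config A [run_config()].
#' @return List of class `run_report`; see the elements documented in
#'   `print.run_report`.
#' @examples
#' cfg <- run_config(
#'   synthetic = list(n_species = 12, pots_per_cell = 4),
#'   n_boot = 100, seed = 7
#' )
#' rep <- run_pipeline(cfg)
#' rep$treatment_tests
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character()
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }

  inp <- load_inputs(config)
  note("inputs: %d pots, %d species in trait table, %d tree tips",
       nrow(inp$pots), nrow(inp$traits), length(inp$tree$tip.label))

  pots <- drop_invalid_pots(inp$pots)
  excluded_pots <- attr(pots, "excluded")
  note("pot screen: %d kept, %d excluded", nrow(pots), nrow(excluded_pots))

  is_ctrl <- pots$treatment == "control"
  ctrl <- assign_control_halves(
    pots[is_ctrl, , drop = FALSE],
    seed = substream_seed(config$seed, "control_halves")
  )
  pots <- dplyr::bind_rows(ctrl, pots[!is_ctrl, , drop = FALSE])
  precisions <- compute_precision(pots)

  skew <- cell_medcouple(precisions)
  note("medcouple diagnostic: median |MC| = %.3f over %d cells",
       median(abs(skew$medcouple), na.rm = TRUE), nrow(skew))

  medians <- species_treatment_median(precisions)
  med_wide <- tidyr::pivot_wider(
    medians[, c("species", "treatment", "median_precision")],
    names_from = "treatment", values_from = "median_precision"
  )
  test_low <- paired_wilcoxon(
    med_wide$low, med_wide$control,
    bonferroni_factor = 2, exact_threshold = config$exact_threshold
  )
  test_high <- paired_wilcoxon(
    med_wide$high, med_wide$control,
    bonferroni_factor = 2, exact_threshold = config$exact_threshold
  )
  treatment_tests <- dplyr::bind_rows(
    dplyr::mutate(tidy(test_low), contrast = "low", .before = 1),
    dplyr::mutate(tidy(test_high), contrast = "high", .before = 1)
  )
  note("treatment tests: low V = %g (adj p = %.3g), high V = %g (adj p = %.3g)",
       test_low$statistic, test_low$p_adjusted,
       test_high$statistic, test_high$p_adjusted)

  responses <- withCallingHandlers(
    species_responses(precisions),
    warning = function(w) {
      log_lines <<- c(log_lines, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  cross_cor <- response_cross_correlation(responses)
  note("cross-contrast correlation: rho = %.3f (p = %.3g, n = %d)",
       cross_cor$estimate, cross_cor$p_value, cross_cor$n_used)

  stability <- response_stability(
    precisions,
    n_boot = config$n_boot, seed = config$seed
  )
  stab_wide <- tidyr::pivot_wider(
    stability[, c("species", "contrast", "middle_half_width")],
    names_from = "contrast", values_from = "middle_half_width"
  )
  stability_test <- paired_wilcoxon(
    stab_wide$low, stab_wide$high,
    bonferroni_factor = 1, exact_threshold = config$exact_threshold
  )
  note("stability comparison (low vs high widths): V = %g, raw p = %.3g",
       stability_test$statistic, stability_test$p_raw)

  traits <- prepare_traits(inp$traits)
  association <- association_table(responses, traits)
  collinearity <- trait_collinearity_matrix(traits)

  resp_named <- function(col) {
    setNames(responses[[col]], responses$species)
  }
  lambda_fits <- list(
    foraging = ml_lambda(resp_named("foraging_high"), inp$tree),
    plasticity = ml_lambda(resp_named("plasticity_high"), inp$tree)
  )
  pgls <- phylo_association_check(
    responses, traits, inp$tree,
    lambda_mode = "ml", association = association
  )
  pgls_bm <- phylo_association_check(
    responses, traits, inp$tree,
    lambda_mode = "fixed_1", association = association
  )

  exclusions <- list(
    pots = excluded_pots,
    species_without_control = setdiff(
      unique(inp$pots$species), unique(responses$species)
    )
  )
  report <- structure(
    list(
      config = config,
      precisions = precisions,
      medcouple = skew,
      medians = medians,
      treatment_tests = treatment_tests,
      responses = responses,
      cross_contrast = cross_cor,
      stability = stability,
      stability_test = stability_test,
      traits = traits,
      association = association,
      collinearity = collinearity,
      lambda = lambda_fits,
      pgls = pgls,
      pgls_bm = pgls_bm,
      exclusions = exclusions,
      log = log_lines
    ),
    class = "run_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Split-pot root foraging analysis\n")
  cat(sprintf("  species: %d, pots: %d\n",
              nrow(x$responses), nrow(x$precisions)))
  cat("  treatment tests (medians, Bonferroni x2):\n")
  print(as.data.frame(x$treatment_tests), digits = 3)
  cat(sprintf("  cross-contrast rho = %.3f (p = %.3g)\n",
              x$cross_contrast$estimate, x$cross_contrast$p_value))
  cat(sprintf("  stability comparison V = %g (raw p = %.3g)\n",
              x$stability_test$statistic, x$stability_test$p_raw))
  lf <- x$lambda$foraging
  if (lf$identifiable) {
    cat(sprintf("  lambda (foraging) = %.3f, CI %.2f-%.2f\n",
                lf$lambda_hat, lf$ci_lower, lf$ci_upper))
  }
  invisible(x)
}

report_summary_list <- function(report) {
  list(
    seed = report$config$seed,
    n_boot = report$config$n_boot,
    n_species = nrow(report$responses),
    n_pots = nrow(report$precisions),
    treatment_tests = report$treatment_tests,
    cross_contrast = report$cross_contrast,
    stability_test = tidy(report$stability_test),
    association = report$association,
    lambda = lapply(report$lambda, function(l) {
      l[c("lambda_hat", "ci_lower", "ci_upper", "p_vs_zero", "p_vs_one",
          "identifiable", "n")]
    }),
    pgls = report$pgls,
    exclusions = list(
      n_pots_excluded = nrow(report$exclusions$pots),
      species_without_control = report$exclusions$species_without_control
    )
  )
}

write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) {
    write.csv(df, file.path(dir, name), row.names = FALSE, na = "")
  }
  wr(dplyr::select(report$precisions, !dplyr::starts_with(".")),
     "precision.csv")
  wr(report$medians, "cell_medians.csv")
  wr(report$responses, "species_responses.csv")
  wr(report$stability, "stability.csv")
  wr(report$association, "association_table.csv")
  wr(report$collinearity, "collinearity.csv")
  wr(report$pgls, "pgls_results.csv")
  jsonlite::write_json(
    lapply(report$lambda, function(l) l[c(
      "lambda_hat", "ci_lower", "ci_upper", "p_vs_zero", "p_vs_one",
      "identifiable", "n"
    )]),
    file.path(dir, "lambda_fits.json"),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  jsonlite::write_json(
    report_summary_list(report), file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, na = "null", dataframe = "rows"
  )
  writeLines(report$log, file.path(dir, "run.log"))
  cfg <- report$config
  cfg$out_dir <- NULL
  writeLines(
    c(
      paste0("seed: ", cfg$seed),
      paste0("config_hash: ", rlang::hash(cfg)),
      paste0("complete: true")
    ),
    file.path(dir, "MANIFEST")
  )
  invisible(dir)
}

#' Render the trait-association table in publication layout
#'
#' Reshapes [association_table()] output into the familiar layout: for each
#' response block (FORAGING, PLASTICITY) three rows — the coefficient (r or
#' rho by trait scale), the pairwise-complete n, and the p-value — with one
#' column per trait. Unavailable cells are blank, never zero.
#'
#' @param report A `run_report`, or an [association_table()] tibble.
#' @return Tibble with columns `block`, `row`, then one column per trait.
#' @export
render_table1 <- function(report) {
  assoc <- if (inherits(report, "run_report")) report$association else report
  trait_order <- intersect(names(trait_scales()), unique(assoc$trait))
  fmt <- function(x, digits) {
    ifelse(is.na(x), "", formatC(x, digits = digits, format = "g"))
  }
  blocks <- purrr::map_dfr(c("foraging", "plasticity"), function(form) {
    a <- assoc[assoc$response_form == form, ]
    a <- a[match(trait_order, a$trait), ]
    rows <- list(
      `r/rho` = fmt(a$estimate, 3),
      n = ifelse(is.na(a$n_used), "", as.character(a$n_used)),
      p = fmt(a$p_value, 3)
    )
    purrr::imap_dfr(rows, function(vals, nm) {
      tibble::as_tibble(c(
        list(block = toupper(form), row = nm),
        setNames(as.list(vals), trait_order)
      ))
    })
  })
  blocks
}
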