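# Orchestration: a single configuration object, the end-to-end run, and
# TSV output with a reproducibility manifest.

#' Pipeline configuration
#'
#' Bundles the simulation and analysis settings. Defaults reproduce the
#' study design: M = 10 mutant alleles per node, 3 replicates, inducer
#' levels 0 / 0.0002 / 0.2 % arabinose, epistasis significance at FDR
#' q < 0.05 (Storey q values) and inducer dependence at two-stage FDR
#' q < 0.1.
#'
#' @param mutants_per_node,n_reps,cv,levels,interactions Passed to
#'   [sim_config()].
#' @param mode Simulation mode, see [generate_dataset()].
#' @param sigma_mode Error-propagation mode, see [expected_G()].
#' @param fdr_method FDR method for epistasis calls; default `"storey"`.
#' @param alpha_epistasis Epistasis significance threshold; default 0.05.
#' @param alpha_dependence Inducer-dependence threshold; default 0.1.
#' @param flat_radius Flat-pattern radius for phenotype classes; default 0.
#' @param seed Integer seed for the whole run.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(mutants_per_node = 10L, n_reps = 3L, cv = 0.10,
                            levels = inducer_levels(), interactions = NULL,
                            mode = c("mechanistic", "multiplicative_null",
                                     "multiplicative_plus_interactions"),
                            sigma_mode = c("as_printed", "sum_of_variances"),
                            fdr_method = c("storey", "bh", "bky"),
                            alpha_epistasis = 0.05, alpha_dependence = 0.1,
                            flat_radius = 0, seed = 1L) {
  mode <- match.arg(mode)
  sigma_mode <- match.arg(sigma_mode)
  fdr_method <- match.arg(fdr_method)
  if (alpha_epistasis <= 0 || alpha_epistasis >= 1 ||
      alpha_dependence <= 0 || alpha_dependence >= 1) {
    stop("significance thresholds must lie in (0, 1)")
  }
  structure(list(
    sim = sim_config(mutants_per_node = mutants_per_node, n_reps = n_reps,
                     cv = cv, levels = levels, interactions = interactions),
    mode = mode, sigma_mode = sigma_mode, fdr_method = fdr_method,
    alpha_epistasis = alpha_epistasis, alpha_dependence = alpha_dependence,
    flat_radius = flat_radius, seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Accepts the scalar fields of [pipeline_config()] plus an optional
#' `interactions` list of `{genotype, inducer_label, delta}` records.
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$interactions)) {
    y$interactions <- dplyr::bind_rows(lapply(y$interactions, tibble::as_tibble))
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  do.call(pipeline_config, y)
}

#' Run the full pipeline
#'
#' Simulates the assay (or takes a provided replicate-level table),
#' summarizes replicates, computes log fold changes, the epistasis table
#' with significance calls and type classes, inducer-dependence profiles
#' with categories and trajectories, per-genotype summaries, and the
#' phenotype projection with the observed-vs-expected diversity
#' comparison. Deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param data Optional tidy replicate-level table (`genotype, order,
#'   inducer_label, replicate, fluorescence`), already normalized to
#'   wild-type-relative units; when `NULL` (default) the dataset is
#'   simulated per `config`.
#' @return List of class `stripepi_run` with elements `data`, `expr`,
#'   `lfc`, `epistasis`, `profiles`, `category_census`,
#'   `genotype_summary`, `points`, `pattern_census`, `diversity`,
#'   `config`.
#' @export
run_all <- function(config = pipeline_config(), data = NULL) {
  sim <- NULL
  if (is.null(data)) {
    sim <- generate_dataset(config$sim, mode = config$mode,
                            seed = config$seed)
    data <- sim$data
  }
  if (!"WT" %in% data$genotype) {
    stop("normalization stage: wild-type reference 'WT' missing from input")
  }
  expr <- summarize_expression(data)
  lfc <- log_fold_changes(data)
  eps <- epistasis_table(lfc, sigma_mode = config$sigma_mode,
                         fdr_method = config$fdr_method,
                         alpha = config$alpha_epistasis,
                         n_expected = config$sim$n_reps)
  eps <- classify_types(eps, lfc)
  profiles <- inducer_dependence(eps, alpha = config$alpha_dependence,
                                 sigma_mode = config$sigma_mode,
                                 n = config$sim$n_reps)
  cats <- category_census(profiles)
  gsum <- summarize_by_genotype(eps, "genotype")
  points <- phenotype_points(expr, lfc, flat_radius = config$flat_radius)
  pattern_census <- points |>
    dplyr::filter(.data$order >= 2L) |>
    dplyr::count(.data$order, .data$source, .data$class)
  diversity <- distance_and_diversity(points)
  structure(list(data = data, expr = expr, lfc = lfc, epistasis = eps,
                 profiles = profiles, category_census = cats,
                 genotype_summary = gsum, points = points,
                 pattern_census = pattern_census, diversity = diversity,
                 sim = sim, config = config),
            class = "stripepi_run")
}

#' Write a pipeline run to TSV files
#'
#' Writes every result table plus a `manifest.yaml` recording the seed,
#' configuration and package version, so a run can be reproduced exactly.
#'
#' @param run A `stripepi_run` from [run_all()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(expression_summary = run$expr,
               log_fold_changes = run$lfc,
               epistasis = run$epistasis,
               inducer_profiles = run$profiles,
               category_census = run$category_census,
               genotype_summaries = run$genotype_summary,
               phenotype_points = run$points,
               pattern_census = run$pattern_census,
               phenotype_distances = run$diversity$distances,
               diversity_tests = run$diversity$tests)
  paths <- character(0)
  for (nm in names(tabs)) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(as.data.frame(tabs[[nm]]), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
  }
  manifest <- list(
    package = "stripepi",
    version = as.character(utils::packageVersion("stripepi")),
    seed = run$config$seed, mode = run$config$mode,
    sigma_mode = run$config$sigma_mode,
    fdr_method = run$config$fdr_method,
    alpha_epistasis = run$config$alpha_epistasis,
    alpha_dependence = run$config$alpha_dependence,
    mutants_per_node = run$config$sim$mutants_per_node,
    n_reps = run$config$sim$n_reps, cv = run$config$sim$cv)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(c(paths, file.path(dir, "manifest.yaml")))
}

#' @export
print.stripepi_run <- function(x, ...) {
  eps <- x$epistasis
  cat("stripepi run (seed ", x$config$seed, ", mode ", x$config$mode, ")\n",
      sep = "")
  for (o in sort(unique(eps$order))) {
    e <- eps[eps$order == o, ]
    cat(sprintf("  order %d: %d tests, %d significant (q < %.2f), %.0f%% negative\n",
                o, nrow(e), sum(e$significant),
                x$config$alpha_epistasis,
                100 * mean(e$epsilon[e$significant] < 0)))
  }
  dep <- x$profiles
  for (o in sort(unique(dep$order))) {
    d <- dep[dep$order == o, ]
    cat(sprintf("  order %d: %d/%d inducer-dependent (q < %.2f)\n",
                o, sum(d$dependent), nrow(d), x$config$alpha_dependence))
  }
  invisible(x)
}
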