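# Synthetic datasets: the full genotype x inducer x replicate assay, either
# from the mechanistic circuit model or from an exact multiplicative null
# (optionally with injected interactions), plus raw plate-reader tables.

#' Default assay inducer levels
#'
#' @return Tibble with columns `inducer_label` (`low`, `medium`, `high`)
#'   and `inducer_pct` (0, 0.0002 and 0.2 % w/v arabinose).
#' @export
inducer_levels <- function() {
  tibble::tibble(inducer_label = c("low", "medium", "high"),
                 inducer_pct = c(0, 2e-4, 0.2))
}

#' The 16-point arabinose gradient
#'
#' The fifteen non-zero assay concentrations plus 0% arabinose.
#'
#' @return Tibble with `inducer_label` (`c01`..`c16`) and `inducer_pct`
#'   in increasing concentration order.
#' @export
arabinose_gradient <- function() {
  pct <- c(0, 0.000012, 0.000025, 0.00005, 0.0001, 0.0002, 0.0004, 0.0008,
           0.0016, 0.00313, 0.00625, 0.0125, 0.025, 0.05, 0.1, 0.2)
  tibble::tibble(inducer_label = sprintf("c%02d", seq_along(pct)),
                 inducer_pct = pct)
}

#' Simulation configuration
#'
#' @param mutants_per_node Mutant alleles per node (M); default 10.
#' @param n_reps Biological replicates per genotype and level; default 3.
#' @param cv Replicate coefficient of variation of the multiplicative
#'   log-normal noise; default 0.10.
#' @param levels Tibble of inducer levels (`inducer_label`,
#'   `inducer_pct`); default [inducer_levels()].
#' @param params [circuit_params()] to simulate from.
#' @param mutant_range Log-uniform multiplier range for drawn mutant
#'   effects (see [draw_mutant_effects()]).
#' @param n_wt_wells Wild-type control wells per replicate plate (>= 3);
#'   the WT reference value of a replicate is their mean.
#' @param n_blank_wells Media-only blank wells per plate (>= 1).
#' @param interactions Optional tibble (`genotype`, `inducer_label`,
#'   `delta`) of interaction terms, in log10 fold-change units, injected on
#'   top of the multiplicative null in
#'   `"multiplicative_plus_interactions"` mode. `inducer_label = "all"`
#'   applies the term at every level.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(mutants_per_node = 10L, n_reps = 3L, cv = 0.10,
                       levels = inducer_levels(), params = circuit_params(),
                       mutant_range = c(1 / 2.5, 2.5),
                       n_wt_wells = 3L, n_blank_wells = 1L,
                       interactions = NULL) {
  stopifnot(mutants_per_node >= 1, n_reps >= 1, cv >= 0,
            all(c("inducer_label", "inducer_pct") %in% names(levels)))
  if (n_wt_wells < 3L) stop("each plate needs at least 3 wild-type wells")
  if (n_blank_wells < 1L) stop("each plate needs at least 1 blank well")
  structure(list(mutants_per_node = as.integer(mutants_per_node),
                 n_reps = as.integer(n_reps), cv = cv,
                 levels = tibble::as_tibble(levels), params = params,
                 mutant_range = mutant_range,
                 n_wt_wells = as.integer(n_wt_wells),
                 n_blank_wells = as.integer(n_blank_wells),
                 interactions = interactions),
            class = "sim_config")
}

# log-normal multiplicative noise with unit mean and the given CV
rnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

effects_for <- function(g, effects) {
  out <- list()
  alleles <- c(sensor = g$sensor, regulator = g$regulator, output = g$output)
  for (nd in nodes()) {
    if (alleles[[nd]] > 0) out <- c(out, effects[[nd]][[alleles[[nd]]]])
  }
  out
}

#' Ground-truth (noiseless) expression for every genotype and level
#'
#' @param config A [sim_config()].
#' @param effects Drawn mutant effects as from [draw_mutant_effects()].
#' @param mode `"mechanistic"`: combinations simulated from the circuit
#'   model with all constituent effects applied; `"multiplicative_null"`:
#'   a combination's expression is exactly the product of its constituent
#'   singles' fold changes times the WT expression;
#'   `"multiplicative_plus_interactions"`: the null plus `10^delta` on the
#'   combinations listed in `config$interactions`.
#' @return Tibble `genotype, order, inducer_label, inducer_pct, truth`.
#' @export
ground_truth <- function(config, effects,
                         mode = c("mechanistic", "multiplicative_null",
                                  "multiplicative_plus_interactions")) {
  mode <- match.arg(mode)
  genotypes <- enumerate_genotypes(config$mutants_per_node)
  lv <- config$levels
  wt_expr <- steady_state(config$params, NULL, lv$inducer_pct)

  # mechanistic expression for every genotype at every level
  mech <- vapply(seq_len(nrow(genotypes)), function(i) {
    steady_state(config$params, effects_for(genotypes[i, ], effects),
                 lv$inducer_pct)
  }, numeric(nrow(lv)))
  mech <- matrix(mech, nrow = nrow(lv)) # levels x genotypes

  truth <- mech
  if (mode != "mechanistic") {
    # fold change of each single mutant relative to WT, per level
    single_idx <- which(genotypes$order == 1L)
    fold <- array(1, dim = c(nrow(lv), 3L, config$mutants_per_node),
                  dimnames = list(NULL, nodes(), NULL))
    for (i in single_idx) {
      nd <- nodes()[which(c(genotypes$sensor[i], genotypes$regulator[i],
                            genotypes$output[i]) > 0)]
      a <- max(genotypes$sensor[i], genotypes$regulator[i], genotypes$output[i])
      fold[, nd, a] <- mech[, i] / wt_expr
    }
    for (i in seq_len(nrow(genotypes))) {
      if (genotypes$order[i] < 2L) next
      f <- rep(1, nrow(lv))
      for (nd in nodes()) {
        a <- genotypes[[nd]][i]
        if (a > 0) f <- f * fold[, nd, a]
      }
      truth[, i] <- wt_expr * f
    }
    if (mode == "multiplicative_plus_interactions") {
      truth <- apply_interactions(truth, genotypes, lv, config$interactions)
    }
  }

  tibble::tibble(
    genotype = rep(genotypes$genotype, each = nrow(lv)),
    order = rep(genotypes$order, each = nrow(lv)),
    inducer_label = rep(lv$inducer_label, times = nrow(genotypes)),
    inducer_pct = rep(lv$inducer_pct, times = nrow(genotypes)),
    truth = as.vector(truth))
}

apply_interactions <- function(truth, genotypes, lv, interactions) {
  if (is.null(interactions) || nrow(interactions) == 0L) return(truth)
  stopifnot(all(c("genotype", "inducer_label", "delta") %in% names(interactions)))
  for (r in seq_len(nrow(interactions))) {
    gi <- match(interactions$genotype[r], genotypes$genotype)
    if (is.na(gi)) stop("unknown genotype in interactions: ",
                        interactions$genotype[r])
    if (genotypes$order[gi] < 2L) {
      stop("interaction deltas apply to combinations only, not ",
           interactions$genotype[r])
    }
    li <- if (interactions$inducer_label[r] == "all") seq_len(nrow(lv)) else
      match(interactions$inducer_label[r], lv$inducer_label)
    if (anyNA(li)) stop("unknown inducer level in interactions: ",
                        interactions$inducer_label[r])
    truth[li, gi] <- truth[li, gi] * 10^interactions$delta[r]
  }
  truth
}

#' Simulate the full assay dataset
#'
#' Draws stripe-retaining mutant alleles, computes noiseless ground-truth
#' expression for every genotype at every inducer level, and adds
#' multiplicative log-normal replicate noise. The wild-type value of a
#' replicate is the mean of `n_wt_wells` simulated control wells, mirroring
#' the plate layout used for normalization.
#'
#' @param config A [sim_config()].
#' @param mode Generation mode; see [ground_truth()].
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return List of class `sim_dataset` with elements `data` (tibble
#'   `genotype, order, inducer_label, inducer_pct, replicate,
#'   fluorescence`), `truth`, `effects`, `mode`, `config`.
#' @export
generate_dataset <- function(config = sim_config(),
                             mode = c("mechanistic", "multiplicative_null",
                                      "multiplicative_plus_interactions"),
                             seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  effects <- draw_mutant_effects(config$params, config$mutants_per_node,
                                 levels = default_check_levels(config),
                                 range = config$mutant_range)
  truth <- ground_truth(config, effects, mode)

  data <- truth[rep(seq_len(nrow(truth)), each = config$n_reps), ]
  data$replicate <- rep_len(seq_len(config$n_reps), nrow(data))
  is_wt <- data$genotype == "WT"
  noise <- numeric(nrow(data))
  noise[!is_wt] <- rnoise(sum(!is_wt), config$cv)
  if (any(is_wt)) {
    # WT reference = mean of the control wells on the replicate plate
    wt_draws <- matrix(rnoise(sum(is_wt) * config$n_wt_wells, config$cv),
                       nrow = sum(is_wt))
    noise[is_wt] <- rowMeans(wt_draws)
  }
  data$fluorescence <- data$truth * noise
  data <- data[, c("genotype", "order", "inducer_label", "inducer_pct",
                   "replicate", "fluorescence")]
  structure(list(data = tibble::as_tibble(data), truth = truth,
                 effects = effects, mode = mode, config = config,
                 seed = seed),
            class = "sim_dataset")
}

# stripe-retention check always uses the three assay concentrations, even
# when the dataset itself is generated over the 16-point gradient
default_check_levels <- function(config) {
  lv <- inducer_levels()
  lv$inducer_pct
}

#' Simulate raw plate-reader tables
#'
#' Produces per-well time series of optical density (logistic growth) and
#' GFP fluorescence (proportional to cell density, rising to a peak and
#' then decaying slowly) for a plate layout with blank and wild-type
#' control wells, suitable as input to the plate-normalization stage. One
#' plate is laid out per replicate and inducer level.
#'
#' @param config A [sim_config()]; `n_wt_wells` and `n_blank_wells` set
#'   the per-plate controls.
#' @param genotypes Character vector of sample genotypes to plate (default
#'   all single mutants); `"WT"` is always present as control wells.
#' @param seed Integer seed.
#' @param times Measurement times in minutes.
#' @param od_offset Optional named vector of growth offsets (added to the
#'   carrying capacity) per genotype, e.g. to exercise the growth-based QC
#'   rule downstream.
#' @return Tibble `plate, well, role, genotype, inducer_label,
#'   inducer_pct, replicate, time_min, od, gfp`.
#' @export
generate_raw_plates <- function(config = sim_config(), genotypes = NULL,
                                seed = 1L, times = seq(0, 300, by = 10),
                                od_offset = NULL) {
  set.seed(seed)
  effects <- draw_mutant_effects(config$params, config$mutants_per_node,
                                 levels = default_check_levels(config),
                                 range = config$mutant_range)
  truth <- ground_truth(config, effects, "mechanistic")
  if (is.null(genotypes)) {
    genotypes <- unique(truth$genotype[truth$order == 1L])
  }
  unknown <- setdiff(genotypes, truth$genotype)
  if (length(unknown)) stop("unknown genotypes: ", paste(unknown, collapse = ", "))

  blank_od <- 0.04; blank_gfp <- 100
  growth_K <- 0.55; growth_r <- 0.035; growth_t0 <- 150
  # fluorescence per OD scaled so raw values sit in a plate-reader-like range
  expr_scale <- 2
  shape <- (1 - exp(-times / 60)) * exp(-pmax(0, times - 180) / 600)

  rows <- list()
  for (rep_i in seq_len(config$n_reps)) {
    for (li in seq_len(nrow(config$levels))) {
      lab <- config$levels$inducer_label[li]
      pct <- config$levels$inducer_pct[li]
      plate <- sprintf("rep%d_%s", rep_i, lab)
      roles <- c(rep("blank", config$n_blank_wells),
                 rep("WT", config$n_wt_wells), rep("sample", length(genotypes)))
      gts <- c(rep(NA_character_, config$n_blank_wells),
               rep("WT", config$n_wt_wells), genotypes)
      for (w in seq_along(roles)) {
        well <- sprintf("%s%02d", LETTERS[(w - 1) %/% 24 + 1], (w - 1) %% 24 + 1)
        if (roles[w] == "blank") {
          od <- blank_od * rnoise(length(times), 0.01)
          gfp <- blank_gfp * rnoise(length(times), 0.01)
        } else {
          K <- growth_K
          if (!is.null(od_offset) && gts[w] %in% names(od_offset)) {
            K <- K + od_offset[[gts[w]]]
          }
          K <- K * rnoise(1L, config$cv / 2)
          cells <- K / (1 + exp(-growth_r * (times - growth_t0)))
          expr <- truth$truth[truth$genotype == gts[w] &
                                truth$inducer_label == lab]
          expr <- expr * rnoise(1L, config$cv)
          od <- blank_od + cells * rnoise(length(times), 0.01)
          gfp <- blank_gfp + expr_scale * expr * cells * shape *
            rnoise(length(times), 0.01)
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          plate = plate, well = well, role = roles[w], genotype = gts[w],
          inducer_label = lab, inducer_pct = pct, replicate = rep_i,
          time_min = times, od = od, gfp = gfp)
      }
    }
  }
  dplyr::bind_rows(rows)
}
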