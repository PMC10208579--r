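# Fixtures are built in code: small simulated datasets and random
# log-fold-change tables exercising the epistasis machinery without a
# full-size simulation.

tiny_config <- function(M = 2L, cv = 0, ...) {
  sim_config(mutants_per_node = M, n_reps = 3L, cv = cv, ...)
}

# A random log-fold-change table for all genotypes at the three levels:
# G values drawn freely, so epistasis is arbitrary but the decomposition
# identity must still hold.
random_lfc <- function(M = 2L, sd_max = 0.1) {
  g <- enumerate_genotypes(M)
  g <- g[g$order >= 1L, ]
  lv <- inducer_levels()$inducer_label
  tibble::tibble(
    genotype = rep(g$genotype, each = length(lv)),
    order = rep(g$order, each = length(lv)),
    inducer_label = rep(lv, times = nrow(g)),
    G = stats::rnorm(nrow(g) * length(lv), 0, 0.5),
    sd = stats::runif(nrow(g) * length(lv), 0.01, sd_max),
    n = 3L)
}

# Replicate-level data in which every genotype's fluorescence is an exact
# fold change of the WT value (no noise), per level.
exact_fold_data <- function(folds, wt_value = c(low = 100, medium = 500, high = 200)) {
  lv <- inducer_levels()
  rows <- list()
  for (g in names(folds)) {
    ord <- if (g == "WT") 0L else parse_genotype(g)$order
    for (li in seq_len(nrow(lv))) {
      lab <- lv$inducer_label[li]
      f <- if (is.null(dim(folds[[g]]))) folds[[g]][[lab]] else folds[[g]][lab]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        genotype = g, order = ord, inducer_label = lab,
        inducer_pct = lv$inducer_pct[li], replicate = 1:3,
        fluorescence = wt_value[[lab]] * f)
    }
  }
  dplyr::bind_rows(rows)
}

# A minimal raw plate table with explicit well values at one time point,
# for hand-checking the correction arithmetic.
manual_plate <- function(samples, wt_corrected = 2000, n_times = 3,
                         blank_gfp = 100, blank_od = 0.05) {
  # choose OD 0.55 for all wells so corrected value = (gfp - 100) / 0.5
  wells <- tibble::tibble(
    role = c("blank", "WT", "WT", "WT", rep("sample", length(samples))),
    genotype = c(NA, "WT", "WT", "WT", names(samples)),
    corrected = c(NA, rep(wt_corrected, 3), unname(samples)))
  wells$well <- sprintf("A%02d", seq_len(nrow(wells)))
  out <- tidyr::crossing(wells, time_min = seq(0, by = 60, length.out = n_times))
  out$plate <- "p1"
  out$inducer_label <- "medium"
  out$replicate <- 1L
  out$od <- ifelse(out$role == "blank", blank_od, 0.55)
  out$gfp <- ifelse(out$role == "blank", blank_gfp,
                    blank_gfp + out$corrected * (0.55 - blank_od))
  out
}
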