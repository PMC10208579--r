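# Classification of epistasis: magnitude / sign / reciprocal sign (RSE),
# positive / negative, the direction group of the constituent singles,
# inducer-dependence categories A-D, sign trajectories, and per-genotype
# summaries.
#
# The type rules formalize the ordering-based definitions used for
# pairwise combinations and extend them to triplets: for each constituent
# single i, the rest of the combination has expected effect
# sum(G_j, j != i); single i's effect is "reversed" in the combined
# background when the combined G sits on the opposite side of G_i from
# that expectation, i.e. sign(G_comb - G_i) != sign(sum_{j != i} G_j).
# No reversal -> magnitude epistasis; some but not all reversed -> sign
# epistasis; all reversed -> RSE. For singles that all raise (lower)
# expression this reduces to: combined above the highest (below the
# lowest) single -> magnitude; between the extremes -> sign; below the
# lowest (above the highest) single -> RSE.

#' Classify the type of an epistatic interaction
#'
#' @param G_singles Numeric vector (length 2 or 3) of the constituent
#'   singles' log10 fold changes relative to WT (WT = 0).
#' @param G_combined Observed log10 fold change of the combination.
#' @param epsilon Epistasis of the combination (sets the positive /
#'   negative sign of the class).
#' @return List with `sign` (`"positive"` / `"negative"` / `"none"`),
#'   `form` (`"magnitude"`, `"sign"`, `"RSE"` or `"none"`),
#'   `direction_group` (`"all_lower"`, `"all_higher"`, `"mixed"`) and
#'   `n_reversed` (how many singles' effects reverse in the combination).
#' @examples
#' classify_type(c(0.3, 0.2), 0.1, -0.4)  # negative RSE
#' @export
classify_type <- function(G_singles, G_combined, epsilon) {
  if (!length(G_singles) %in% 2:3) stop("need 2 or 3 constituent singles")
  dirs <- sign(G_singles)
  direction_group <- if (all(dirs > 0)) "all_higher"
    else if (all(dirs < 0)) "all_lower" else "mixed"
  eps_sign <- if (epsilon > 0) "positive" else if (epsilon < 0) "negative" else "none"
  if (eps_sign == "none") {
    return(list(sign = "none", form = "none",
                direction_group = direction_group, n_reversed = 0L))
  }
  rest <- sum(G_singles) - G_singles
  reversed <- sign(G_combined - G_singles) != sign(rest) &
    sign(G_combined - G_singles) != 0 & sign(rest) != 0
  n_rev <- sum(reversed)
  # RSE demands the combination oppose every single's own direction, which
  # mixed-direction groups cannot satisfy; they cap at sign epistasis
  form <- if (n_rev == 0L) "magnitude"
    else if (n_rev == length(G_singles) && direction_group != "mixed") "RSE"
    else "sign"
  list(sign = eps_sign, form = form, direction_group = direction_group,
       n_reversed = as.integer(n_rev))
}

#' Type classification for a whole epistasis table
#'
#' Applies [classify_type()] to every record of an [epistasis_table()]
#' output, using the singles' log fold changes from `lfc`.
#'
#' @param eps_table Output of [epistasis_table()].
#' @param lfc Log fold-change table containing the singles.
#' @param significant_only Classify only records flagged significant
#'   (default `TRUE`, matching how the study reports type fractions);
#'   non-significant records are kept with `NA` classes.
#' @return `eps_table` with columns `type_sign`, `type_form`,
#'   `direction_group` added.
#' @export
classify_types <- function(eps_table, lfc, significant_only = TRUE) {
  singles <- lfc[lfc$order == 1L, c("genotype", "inducer_label", "G")]
  key <- paste(singles$genotype, singles$inducer_label)
  G_single <- stats::setNames(singles$G, key)
  cons_cache <- lapply(stats::setNames(nm = unique(eps_table$genotype)),
                       constituent_singles)
  n <- nrow(eps_table)
  type_sign <- type_form <- dgrp <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (significant_only && !isTRUE(eps_table$significant[i])) next
    gs <- G_single[paste(cons_cache[[eps_table$genotype[i]]],
                         eps_table$inducer_label[i])]
    cl <- classify_type(unname(gs), eps_table$G_obs[i], eps_table$epsilon[i])
    type_sign[i] <- cl$sign; type_form[i] <- cl$form
    dgrp[i] <- cl$direction_group
  }
  eps_table$type_sign <- type_sign
  eps_table$type_form <- type_form
  eps_table$direction_group <- dgrp
  eps_table
}

#' Propagated uncertainty of an epistasis value
#'
#' Follows the study's printed propagation, `sigma = |epsilon| *
#' sqrt(sigma_obs^2 + sigma_exp^2)` (`"as_printed"`, default; degenerate
#' and equal to 0 when `epsilon = 0`), or the standard root sum of squares
#' (`"sum_of_variances"`).
#'
#' @param epsilon Epistasis value(s).
#' @param sd_obs,sd_exp Standard deviations of the observed and expected
#'   log fold changes.
#' @param sigma_mode `"as_printed"` or `"sum_of_variances"`.
#' @return Numeric vector of propagated sigmas.
#' @export
sigma_epistasis <- function(epsilon, sd_obs, sd_exp,
                            sigma_mode = c("as_printed", "sum_of_variances")) {
  sigma_mode <- match.arg(sigma_mode)
  if (any(c(sd_obs, sd_exp) < 0, na.rm = TRUE)) stop("sigmas must be >= 0")
  rss <- sqrt(sd_obs^2 + sd_exp^2)
  if (sigma_mode == "as_printed") abs(epsilon) * rss else rss
}

#' Inducer-dependence category of an epistasis trajectory
#'
#' Category A: epistasis strictly highest at the medium concentration;
#' B: increasing from low to high; C: decreasing from low to high;
#' D: strictly lowest at medium. Exact ties are broken towards the
#' medium-extremum categories (A, then D) and flagged. The sign
#' trajectory is `always_positive` / `always_negative` when all three
#' point estimates share a sign, otherwise `switching`.
#'
#' @param eps_low,eps_medium,eps_high Epistasis at the three inducer
#'   levels (vectorized).
#' @return Tibble with `category` (`"A"`..`"D"`), `trajectory`, `tie`
#'   (logical).
#' @export
classify_category <- function(eps_low, eps_medium, eps_high) {
  k <- max(length(eps_low), length(eps_medium), length(eps_high))
  eL <- rep_len(eps_low, k); eM <- rep_len(eps_medium, k)
  eH <- rep_len(eps_high, k)
  if (anyNA(c(eL, eM, eH))) stop("epistasis values must be finite at all levels")
  category <- character(k); tie <- logical(k)
  strict_max <- eM > eL & eM > eH
  strict_min <- eM < eL & eM < eH
  category[strict_max] <- "A"
  category[strict_min] <- "D"
  rest <- !strict_max & !strict_min
  category[rest & eL < eH] <- "B"
  category[rest & eL > eH] <- "C"
  # remaining are exact ties: medium equals an extreme, or all equal
  left <- category == ""
  tie[left] <- TRUE
  category[left & eM >= eL & eM >= eH] <- "A"
  category[left & category == ""] <- "D"
  trajectory <- ifelse(eL > 0 & eM > 0 & eH > 0, "always_positive",
                ifelse(eL < 0 & eM < 0 & eH < 0, "always_negative",
                       "switching"))
  tibble::tibble(category = category, trajectory = trajectory, tie = tie)
}

#' Inducer-dependence profiles for all combinations
#'
#' For every combination, spreads epistasis across the three inducer
#' levels, propagates its uncertainty (see [sigma_epistasis()]), runs the
#' three Welch comparisons (low-medium, low-high, medium-high), adjusts
#' them with the two-stage Benjamini-Krieger-Yekutieli procedure within
#' each order's family, and flags a combination inducer-dependent when any
#' of its three comparisons is significant (default q < 0.1). Categories
#' and sign trajectories are assigned to all combinations from the point
#' estimates, with the dependence flag carried alongside.
#'
#' @param eps_table Output of [epistasis_table()] over the three standard
#'   levels.
#' @param alpha Dependence threshold; default 0.1.
#' @param sigma_mode Propagation mode for the per-level epistasis sigma.
#' @param n Replicate count behind each epistasis value; default 3.
#' @return Tibble, one row per combination: `genotype, order, eps_low,
#'   eps_medium, eps_high, sigma_low, sigma_medium, sigma_high, category,
#'   trajectory, tie, p_LM, p_LH, p_MH, q_LM, q_LH, q_MH, dependent`.
#' @export
inducer_dependence <- function(eps_table, alpha = 0.1,
                               sigma_mode = c("as_printed", "sum_of_variances"),
                               n = 3L) {
  sigma_mode <- match.arg(sigma_mode)
  need <- c("genotype", "order", "inducer_label", "epsilon", "sd_obs", "sd_exp")
  if (!all(need %in% names(eps_table))) {
    stop("eps_table is missing columns: ",
         paste(setdiff(need, names(eps_table)), collapse = ", "))
  }
  eps_table$sigma_eps <- sigma_epistasis(eps_table$epsilon, eps_table$sd_obs,
                                         eps_table$sd_exp, sigma_mode)
  wide <- eps_table |>
    dplyr::select("genotype", "order", "inducer_label", "epsilon", "sigma_eps") |>
    tidyr::pivot_wider(names_from = "inducer_label",
                       values_from = c("epsilon", "sigma_eps"))
  need_w <- c("epsilon_low", "epsilon_medium", "epsilon_high")
  if (!all(need_w %in% names(wide))) {
    stop("inducer dependence needs epistasis at the low, medium and high levels")
  }
  complete <- stats::complete.cases(wide[, need_w])
  if (any(!complete)) {
    message(sum(!complete), " combination(s) skipped: missing a level")
    wide <- wide[complete, ]
  }

  pairs <- list(LM = c("low", "medium"), LH = c("low", "high"),
                MH = c("medium", "high"))
  for (nm in names(pairs)) {
    a <- pairs[[nm]][1]; b <- pairs[[nm]][2]
    tt <- t_test_summary(wide[[paste0("epsilon_", a)]],
                         wide[[paste0("sigma_eps_", a)]], n,
                         wide[[paste0("epsilon_", b)]],
                         wide[[paste0("sigma_eps_", b)]], n,
                         variant = "welch")
    wide[[paste0("p_", nm)]] <- tt$p
  }

  # BKY within each order's family, across all three comparisons
  for (col in c("q_LM", "q_LH", "q_MH")) wide[[col]] <- NA_real_
  wide$dependent <- NA
  for (f in unique(wide$order)) {
    idx <- which(wide$order == f)
    p_long <- c(wide$p_LM[idx], wide$p_LH[idx], wide$p_MH[idx])
    adj <- fdr_adjust(p_long, method = "bky", alpha = alpha)
    k <- length(idx)
    wide$q_LM[idx] <- adj$q[seq_len(k)]
    wide$q_LH[idx] <- adj$q[k + seq_len(k)]
    wide$q_MH[idx] <- adj$q[2 * k + seq_len(k)]
    sig <- matrix(adj$significant, ncol = 3L)
    wide$dependent[idx] <- rowSums(sig, na.rm = TRUE) > 0
  }

  cc <- classify_category(wide$epsilon_low, wide$epsilon_medium,
                          wide$epsilon_high)
  out <- dplyr::bind_cols(wide, cc)
  dplyr::rename(out,
                eps_low = "epsilon_low", eps_medium = "epsilon_medium",
                eps_high = "epsilon_high", sigma_low = "sigma_eps_low",
                sigma_medium = "sigma_eps_medium", sigma_high = "sigma_eps_high")
}

#' Census of inducer-dependence categories and sign trajectories
#'
#' @param profiles Output of [inducer_dependence()].
#' @return Tibble of counts and percentages per order x category x
#'   trajectory, percentages within each order.
#' @export
category_census <- function(profiles) {
  profiles |>
    dplyr::count(.data$order, .data$category, .data$trajectory) |>
    dplyr::group_by(.data$order) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Per-genotype (or per-node) epistasis summaries
#'
#' Groups epistasis values by the single-mutant genotype contained in each
#' combination (every combination contributes once per constituent), by
#' node, or by node x inducer level, and reports the mean, SD and
#' coefficient of variation (CoV = SD / mean) of epistasis. At M = 10
#' each genotype has 20 pairwise and 100 triplet combinations, i.e. 60 and
#' 300 epistasis values over the three levels.
#'
#' @param eps_table Output of [epistasis_table()].
#' @param grouping `"genotype"`, `"node"` or `"node_level"`.
#' @return Tibble with the grouping columns, `order`, `n_values`,
#'   `mean_epsilon`, `sd_epsilon`, `cov_epsilon` (`NA` when the mean is
#'   0).
#' @export
summarize_by_genotype <- function(eps_table,
                                  grouping = c("genotype", "node", "node_level")) {
  grouping <- match.arg(grouping)
  cons <- dplyr::bind_rows(lapply(unique(eps_table$genotype), function(g) {
    s <- constituent_singles(g)
    tibble::tibble(genotype = g, single = s,
                   node = sub("-[0-9]+$", "", s))
  }))
  long <- dplyr::inner_join(eps_table, cons, by = "genotype",
                            relationship = "many-to-many")
  grp <- switch(grouping,
                genotype = c("single", "order"),
                node = c("node", "order"),
                node_level = c("node", "inducer_label", "order"))
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(n_values = dplyr::n(),
                     mean_epsilon = mean(.data$epsilon),
                     sd_epsilon = stats::sd(.data$epsilon),
                     .groups = "drop") |>
    dplyr::mutate(cov_epsilon = ifelse(.data$mean_epsilon == 0, NA_real_,
                                       .data$sd_epsilon / .data$mean_epsilon))
}
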