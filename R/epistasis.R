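# The multiplicative-model core. A mutant's effect is its fold change in
# fluorescence relative to the wild type, g = fluor / fluor_WT, worked with
# on the log10 scale, G = log10(g). Under the multiplicative (log-additive)
# null the expected G of a combination is the sum of its constituent
# singles' G; epistasis is the deviation of the observation from that sum,
#
#   epsilon = G_observed - G_expected .
#
# For triplets the expectation can instead be built from the three observed
# pairs (each pair counted once, singles subtracted once to avoid double
# counting), which isolates the exclusive third-order component
# epsilon3 = G_obs(ijk) - [sum G_obs(pairs) - sum G(singles)], and the
# decomposition epsilon(ijk) = epsilon3 + sum of pairwise epsilons holds
# identically.

#' Log10 fold changes relative to the wild type
#'
#' Computes, per genotype and inducer level, the per-replicate
#' `log10(fluorescence / WT)` against the replicate-matched wild-type
#' value (the mean of the WT control wells on the same replicate plate),
#' then the mean, sample SD and count over replicates. Records with
#' non-positive fluorescence are dropped with a message.
#'
#' @param data Tidy replicate-level table (`genotype, order,
#'   inducer_label, replicate, fluorescence`), e.g. the `data` element of
#'   [generate_dataset()] or a normalized well table renamed accordingly.
#' @param wt Genotype string of the reference; default `"WT"`.
#' @return Tibble `genotype, order, inducer_label, G, sd, n` (wild-type
#'   rows excluded; its G is 0 by construction).
#' @export
log_fold_changes <- function(data, wt = "WT") {
  need <- c("genotype", "inducer_label", "replicate", "fluorescence")
  if (!all(need %in% names(data))) {
    stop("data is missing columns: ",
         paste(setdiff(need, names(data)), collapse = ", "))
  }
  wt_tab <- data[data$genotype == wt,
                 c("inducer_label", "replicate", "fluorescence")]
  if (nrow(wt_tab) == 0L) stop("wild-type reference '", wt, "' absent from data")
  names(wt_tab)[3] <- "wt_fluorescence"
  wt_tab <- wt_tab |>
    dplyr::group_by(.data$inducer_label, .data$replicate) |>
    dplyr::summarise(wt_fluorescence = mean(.data$wt_fluorescence),
                     .groups = "drop")

  d <- dplyr::inner_join(data[data$genotype != wt, ], wt_tab,
                         by = c("inducer_label", "replicate"))
  bad <- !is.finite(d$fluorescence) | d$fluorescence <= 0 |
    d$wt_fluorescence <= 0
  if (any(bad)) {
    message(sum(bad), " replicate record(s) with non-positive fluorescence dropped")
    d <- d[!bad, ]
  }
  d$G_rep <- log10(d$fluorescence / d$wt_fluorescence)
  grp <- intersect(c("genotype", "order", "inducer_label", "inducer_pct"),
                   names(d))
  d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(G = mean(.data$G_rep), sd = stats::sd(.data$G_rep),
                     n = dplyr::n(), .groups = "drop")
}

#' Expected log fold change of a combination under the multiplicative null
#'
#' `G_expected` is the sum of the constituent singles' observed log fold
#' changes. Its propagated uncertainty follows the study's printed error
#' propagation, `sigma = |G_expected| * sqrt(sum sigma_i^2)`
#' (`sigma_mode = "as_printed"`, the default), or the standard
#' root-sum-of-squares `sqrt(sum sigma_i^2)`
#' (`sigma_mode = "sum_of_variances"`).
#'
#' @param G Numeric vector (length 2 or 3) of single-mutant log10 fold
#'   changes at one inducer level.
#' @param sd Their replicate standard deviations.
#' @param sigma_mode `"as_printed"` or `"sum_of_variances"`.
#' @return List with `G_expected` and `sigma_expected`.
#' @export
expected_G <- function(G, sd, sigma_mode = c("as_printed", "sum_of_variances")) {
  sigma_mode <- match.arg(sigma_mode)
  if (!length(G) %in% 2:3 || length(sd) != length(G)) {
    stop("need 2 or 3 constituent singles with matching sds")
  }
  Ge <- sum(G)
  rss <- sqrt(sum(sd^2))
  sigma <- if (sigma_mode == "as_printed") abs(Ge) * rss else rss
  list(G_expected = Ge, sigma_expected = sigma)
}

#' Epistasis of a combination
#'
#' @param G_observed,G_expected Observed and expected log10 fold changes
#'   of the combination (vectorized).
#' @return `epsilon = G_observed - G_expected`, in log10 fold-change
#'   units: negative when the combination expresses less than the
#'   multiplicative null predicts.
#' @export
epistasis <- function(G_observed, G_expected) G_observed - G_expected

#' Exclusive third-order epistasis of a triplet
#'
#' Builds the pair-based expectation `G3_expected = sum of the three
#' observed pairwise G minus the sum of the three single G` and the
#' exclusive third-order epistasis `epsilon3 = G_observed(triplet) -
#' G3_expected`, the part of the triplet's epistasis not attributable to
#' its pairs.
#'
#' @param G_triplet Observed log10 fold change of the triplet.
#' @param G_pairs Numeric length-3 vector: observed G of the three
#'   constituent pairs.
#' @param G_singles Numeric length-3 vector: observed G of the three
#'   constituent singles.
#' @return List with `G3_expected`, `epsilon3` and `sum_pairwise_epsilon`
#'   (the three pairwise epistasis terms implied by the same inputs).
#' @export
third_order <- function(G_triplet, G_pairs, G_singles) {
  if (length(G_pairs) != 3L || length(G_singles) != 3L) {
    stop("a triplet has exactly 3 constituent pairs and 3 singles")
  }
  if (anyNA(c(G_triplet, G_pairs, G_singles))) {
    stop("missing constituent record for the triplet decomposition")
  }
  G3 <- sum(G_pairs) - sum(G_singles)
  # each pair's own expectation is the sum of its two singles, so the sum
  # of the three pairwise epsilons is sum(G_pairs) - 2 * sum(G_singles)
  sum_pair_eps <- sum(G_pairs) - 2 * sum(G_singles)
  list(G3_expected = G3, epsilon3 = G_triplet - G3,
       sum_pairwise_epsilon = sum_pair_eps)
}

#' Full epistasis table for all combinations and inducer levels
#'
#' Drives the multiplicative model over every pairwise and triplet
#' combination at every inducer level: expected G from the constituent
#' singles, epsilon, error propagation, a two-sided pooled-variance t test
#' of observed vs expected (summary statistics, replicate n on each side)
#' and FDR adjustment, by default with Storey q values within each order's
#' family of tests. Triplets additionally carry the pair-based expectation
#' and the exclusive third-order epistasis.
#'
#' @param lfc Log fold-change table from [log_fold_changes()] containing
#'   singles and all combinations at all levels.
#' @param sigma_mode Error-propagation mode, see [expected_G()].
#' @param fdr_method `"storey"` (default), `"bh"` or `"bky"`.
#' @param alpha Significance threshold on q; default 0.05.
#' @param fdr_family `"per_order"` (default; pairwise and triplet tests
#'   adjusted separately) or `"pooled"`.
#' @param n_expected Replicate count attributed to the expected side of
#'   the t test; default 3, the study design's replicate number.
#' @return Tibble, one row per combination x level: `genotype, order,
#'   inducer_label, G_obs, sd_obs, n_obs, G_exp, sd_exp, epsilon, t, df,
#'   p, q, significant`, and for order 3 also `G3_exp, epsilon3,
#'   sum_pairwise_epsilon`.
#' @export
epistasis_table <- function(lfc,
                            sigma_mode = c("as_printed", "sum_of_variances"),
                            fdr_method = c("storey", "bh", "bky"),
                            alpha = 0.05,
                            fdr_family = c("per_order", "pooled"),
                            n_expected = 3L) {
  sigma_mode <- match.arg(sigma_mode)
  fdr_method <- match.arg(fdr_method)
  fdr_family <- match.arg(fdr_family)
  if (!"order" %in% names(lfc)) {
    lfc <- dplyr::left_join(lfc, parse_genotype(unique(lfc$genotype))[,
                            c("genotype", "order")], by = "genotype")
  }

  singles <- lfc[lfc$order == 1L, ]
  combos <- lfc[lfc$order >= 2L, ]
  if (nrow(singles) == 0L) stop("no single-mutant records in the table")
  if (nrow(combos) == 0L) stop("no combination records in the table")

  # map each combination to its constituent singles (long form, then join)
  combo_ids <- unique(combos$genotype)
  cons <- dplyr::bind_rows(lapply(combo_ids, function(g) {
    tibble::tibble(genotype = g, single = constituent_singles(g))
  }))
  missing_singles <- setdiff(cons$single, singles$genotype)
  if (length(missing_singles)) {
    stop("missing single-mutant records for: ",
         paste(missing_singles, collapse = ", "))
  }

  long <- dplyr::inner_join(
    tidyr::crossing(cons, inducer_label = unique(combos$inducer_label)),
    singles[, c("genotype", "inducer_label", "G", "sd")],
    by = c(single = "genotype", "inducer_label"))
  exp_tab <- long |>
    dplyr::group_by(.data$genotype, .data$inducer_label) |>
    dplyr::summarise(G_exp = sum(.data$G), rss = sqrt(sum(.data$sd^2)),
                     n_singles = dplyr::n(), .groups = "drop")
  ord_of <- stats::setNames(combos$order[match(combo_ids, combos$genotype)],
                            combo_ids)
  if (any(exp_tab$n_singles != ord_of[exp_tab$genotype])) {
    stop("missing single-mutant records at some inducer levels")
  }
  exp_tab$sd_exp <- if (sigma_mode == "as_printed") {
    abs(exp_tab$G_exp) * exp_tab$rss
  } else {
    exp_tab$rss
  }

  out <- combos |>
    dplyr::select(dplyr::all_of(intersect(
      c("genotype", "order", "inducer_label", "inducer_pct", "G", "sd", "n"),
      names(combos)))) |>
    dplyr::rename(G_obs = "G", sd_obs = "sd", n_obs = "n") |>
    dplyr::inner_join(exp_tab[, c("genotype", "inducer_label", "G_exp", "sd_exp")],
                      by = c("genotype", "inducer_label"))
  out$epsilon <- epistasis(out$G_obs, out$G_exp)

  tt <- t_test_summary(out$G_obs, out$sd_obs, out$n_obs,
                       out$G_exp, out$sd_exp, rep(n_expected, nrow(out)),
                       variant = "pooled")
  out$t <- tt$t; out$df <- tt$df; out$p <- tt$p

  out$q <- NA_real_; out$significant <- NA
  fam <- if (fdr_family == "pooled") rep(1L, nrow(out)) else out$order
  for (f in unique(fam)) {
    idx <- fam == f
    adj <- fdr_adjust(out$p[idx], method = fdr_method, alpha = alpha)
    out$q[idx] <- adj$q
    out$significant[idx] <- adj$significant
  }

  # pair-based expectation and exclusive third-order epistasis
  trip <- out$order == 3L
  out$G3_exp <- NA_real_; out$epsilon3 <- NA_real_
  out$sum_pairwise_epsilon <- NA_real_
  if (any(trip)) {
    pair_eps <- out[out$order == 2L, c("genotype", "inducer_label", "G_obs", "epsilon")]
    trip_cons <- dplyr::bind_rows(lapply(unique(out$genotype[trip]), function(g) {
      s <- constituent_singles(g)
      pairs <- vapply(list(s[c(1, 2)], s[c(1, 3)], s[c(2, 3)]), function(pp) {
        pg <- parse_genotype(pp[1])
        qg <- parse_genotype(pp[2])
        genotype_string(pg$sensor + qg$sensor, pg$regulator + qg$regulator,
                        pg$output + qg$output)
      }, character(1))
      tibble::tibble(genotype = g, pair = pairs)
    }))
    pair_join <- dplyr::inner_join(
      tidyr::crossing(trip_cons, inducer_label = unique(out$inducer_label[trip])),
      pair_eps, by = c(pair = "genotype", "inducer_label"))
    pair_sum <- pair_join |>
      dplyr::group_by(.data$genotype, .data$inducer_label) |>
      dplyr::summarise(G_pairs = sum(.data$G_obs),
                       sum_pairwise_epsilon = sum(.data$epsilon),
                       n_pairs = dplyr::n(), .groups = "drop")
    if (any(pair_sum$n_pairs != 3L)) {
      stop("missing pairwise records for some triplets")
    }
    m <- dplyr::left_join(out[trip, c("genotype", "inducer_label", "G_obs", "G_exp")],
                          pair_sum, by = c("genotype", "inducer_label"))
    # G3_exp = sum(G_pairs) - sum(G_singles); G_exp is the sum of singles
    out$G3_exp[trip] <- m$G_pairs - m$G_exp
    out$epsilon3[trip] <- m$G_obs - out$G3_exp[trip]
    out$sum_pairwise_epsilon[trip] <- m$sum_pairwise_epsilon
  }
  out
}
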