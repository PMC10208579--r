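# Pattern-phenotype space: a genotype's expression at the three assay
# concentrations is projected to (Mx, My) = (G_medium - G_low,
# G_high - G_medium) with G the log10 normalized fluorescence. The
# quadrant then names the pattern: up-then-down (Mx > 0, My < 0) is the
# stripe; the other quadrants are increase, anti-stripe and decrease.
# Distances between patterns are Euclidean in this plane and do not
# depend on whether G is log fluorescence or log fold change versus WT
# (per-level constants cancel in the differences).

#' Project an expression pattern to phenotype coordinates
#'
#' @param G_low,G_medium,G_high Log10 normalized fluorescence at the
#'   three inducer levels (vectorized).
#' @return Tibble with `Mx = G_medium - G_low` and
#'   `My = G_high - G_medium`.
#' @export
project_pattern <- function(G_low, G_medium, G_high) {
  tibble::tibble(Mx = G_medium - G_low, My = G_high - G_medium)
}

#' Classify a phenotype point into a pattern class
#'
#' Quadrant classes: increase (`Mx > 0, My > 0`), anti-stripe
#' (`Mx <= 0, My > 0`), decrease (`Mx <= 0, My <= 0`), stripe
#' (`Mx > 0, My <= 0`); points within `flat_radius` of the origin are
#' `flat`. Boundary points (an axis value exactly 0) follow the half-open
#' convention just given and are flagged.
#'
#' @param Mx,My Phenotype coordinates (vectorized).
#' @param flat_radius Radius below which a pattern counts as flat;
#'   default 0 (strict quadrants).
#' @return Tibble with `class` and logical `boundary`.
#' @export
classify_pattern <- function(Mx, My, flat_radius = 0) {
  if (any(!is.finite(Mx) | !is.finite(My))) stop("coordinates must be finite")
  class <- ifelse(Mx > 0 & My > 0, "increase",
           ifelse(Mx <= 0 & My > 0, "anti_stripe",
           ifelse(Mx <= 0 & My <= 0, "decrease", "stripe")))
  flat <- sqrt(Mx^2 + My^2) <= flat_radius
  class[flat] <- "flat"
  tibble::tibble(class = class, boundary = (Mx == 0 | My == 0) & !flat)
}

#' Observed and expected phenotype points for all genotypes
#'
#' Observed points use each genotype's mean normalized fluorescence;
#' expected points place each combination where the multiplicative null
#' predicts, `G_expected(level) = G_WT(level) + sum of the constituent
#' singles' log fold changes at that level`.
#'
#' @param expr Expression summary table (`genotype, order, inducer_label,
#'   mean`) over the three standard levels, WT included.
#' @param lfc Log fold-change table from [log_fold_changes()] (used for
#'   the expected points of order >= 2 genotypes).
#' @param flat_radius Passed to [classify_pattern()].
#' @return Tibble `genotype, order, source (observed | expected), Mx, My,
#'   class, boundary, distance_to_wt`.
#' @export
phenotype_points <- function(expr, lfc, flat_radius = 0) {
  need <- c("genotype", "order", "inducer_label", "mean")
  if (!all(need %in% names(expr))) {
    stop("expr is missing columns: ",
         paste(setdiff(need, names(expr)), collapse = ", "))
  }
  if (any(expr$mean <= 0)) stop("mean fluorescence must be positive")
  wideG <- expr |>
    dplyr::mutate(G = log10(.data$mean)) |>
    dplyr::select("genotype", "order", "inducer_label", "G") |>
    tidyr::pivot_wider(names_from = "inducer_label", values_from = "G")
  if (!all(c("low", "medium", "high") %in% names(wideG))) {
    stop("expression at the low, medium and high levels is required")
  }

  obs <- dplyr::bind_cols(
    wideG[, c("genotype", "order")],
    project_pattern(wideG$low, wideG$medium, wideG$high))
  obs$source <- "observed"

  # expected points: WT absolute G plus the summed singles' fold changes
  wt <- wideG[wideG$genotype == "WT", ]
  if (nrow(wt) != 1L) stop("WT reference absent from the expression table")
  combos <- wideG$genotype[wideG$order >= 2L]
  lfc_wide <- lfc[lfc$order == 1L, c("genotype", "inducer_label", "G")] |>
    tidyr::pivot_wider(names_from = "inducer_label", values_from = "G")
  exp_rows <- lapply(combos, function(g) {
    s <- constituent_singles(g)
    if (!all(s %in% lfc_wide$genotype)) {
      stop("missing single-mutant log fold changes for ", g)
    }
    sl <- lfc_wide[match(s, lfc_wide$genotype), ]
    tibble::tibble(genotype = g,
                   low = wt$low + sum(sl$low),
                   medium = wt$medium + sum(sl$medium),
                   high = wt$high + sum(sl$high))
  })
  expd <- dplyr::bind_rows(exp_rows)
  if (nrow(expd)) {
    expd <- dplyr::bind_cols(
      expd[, "genotype", drop = FALSE],
      tibble::tibble(order = wideG$order[match(expd$genotype, wideG$genotype)]),
      project_pattern(expd$low, expd$medium, expd$high))
    expd$source <- "expected"
  }

  out <- dplyr::bind_rows(obs, expd)
  out <- dplyr::bind_cols(out, classify_pattern(out$Mx, out$My, flat_radius))
  wt_pt <- obs[obs$genotype == "WT", ]
  out$distance_to_wt <- sqrt((out$Mx - wt_pt$Mx)^2 + (out$My - wt_pt$My)^2)
  out[, c("genotype", "order", "source", "Mx", "My", "class", "boundary",
          "distance_to_wt")]
}

#' Phenotypic diversity: observed vs expected distances to the wild type
#'
#' Pairs each combination's observed and expected phenotype points,
#' compares their Euclidean distances to the WT point with a two-sided
#' Wilcoxon matched-pairs signed-rank test (per order), and also reports
#' the direct displacement `||M_expected - M_observed||` per genotype.
#'
#' @param points Output of [phenotype_points()].
#' @return List with `distances` (tibble `genotype, order, dist_observed,
#'   dist_expected, displacement`) and `tests` (per order: mean observed
#'   and expected distance, Wilcoxon `p`, `degenerate` flag; `p = 1` when
#'   all paired differences are zero).
#' @export
distance_and_diversity <- function(points) {
  combos <- points[points$order >= 2L, ]
  wide <- combos |>
    dplyr::select("genotype", "order", "source", "Mx", "My",
                  "distance_to_wt") |>
    tidyr::pivot_wider(names_from = "source",
                       values_from = c("Mx", "My", "distance_to_wt"))
  unpaired <- !stats::complete.cases(
    wide[, c("distance_to_wt_observed", "distance_to_wt_expected")])
  if (any(unpaired)) {
    message(sum(unpaired), " genotype(s) without both points excluded")
    wide <- wide[!unpaired, ]
  }
  distances <- tibble::tibble(
    genotype = wide$genotype, order = wide$order,
    dist_observed = wide$distance_to_wt_observed,
    dist_expected = wide$distance_to_wt_expected,
    displacement = sqrt((wide$Mx_expected - wide$Mx_observed)^2 +
                          (wide$My_expected - wide$My_observed)^2))
  tests <- lapply(sort(unique(distances$order)), function(o) {
    d <- distances[distances$order == o, ]
    degen <- all(abs(d$dist_observed - d$dist_expected) < 1e-12)
    p <- if (degen) 1 else
      suppressWarnings(stats::wilcox.test(d$dist_observed, d$dist_expected,
                                          paired = TRUE,
                                          alternative = "two.sided")$p.value)
    tibble::tibble(order = o, n = nrow(d),
                   mean_observed = mean(d$dist_observed),
                   mean_expected = mean(d$dist_expected),
                   p = p, degenerate = degen)
  })
  list(distances = distances, tests = dplyr::bind_rows(tests))
}
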