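# Raw plate-reader processing: time-point selection, blank and OD
# correction, wild-type-based plate normalization, growth-based replicate
# QC and replicate summary statistics.

#' Select the analysis time point
#'
#' The analysis time point is when the wild-type network's fluorescence at
#' the medium inducer concentration peaks; all wells are then read at that
#' time. Ties are broken towards the earliest time; a peak on the final
#' time point is flagged as "no peak reached".
#'
#' @param time Numeric vector of measurement times (min).
#' @param fluorescence Wild-type fluorescence at the same times.
#' @return The peak time, with attribute `flag` (`NA`, `"tie"` or
#'   `"no_peak"`).
#' @export
select_timepoint <- function(time, fluorescence) {
  if (length(time) == 0L || length(time) != length(fluorescence)) {
    stop("time and fluorescence must be non-empty vectors of equal length")
  }
  o <- order(time)
  time <- time[o]; fluorescence <- fluorescence[o]
  i <- which.max(fluorescence) # earliest index on ties
  flag <- NA_character_
  if (sum(fluorescence == max(fluorescence)) > 1L) {
    flag <- "tie"
    warning("fluorescence maximum is tied; using the earliest time")
  }
  if (i == length(time) && length(time) > 1L) flag <- "no_peak"
  structure(time[i], flag = flag)
}

#' Blank/OD correction and two-stage wild-type normalization
#'
#' At the chosen time point each well is corrected for media background and
#' cell number: `(gfp - mean blank gfp) / (od - mean blank od)`, blanks
#' taken per plate. Each plate is then scaled so that the mean of its
#' wild-type control wells is 1; a second wild-type re-scaling pass across
#' plates follows (an identity once stage one has run, which makes the
#' normalization idempotent). Wells whose blank-corrected OD is not
#' positive are marked unusable (`NA`).
#'
#' @param plates Raw plate table as from [generate_raw_plates()] (columns
#'   `plate, well, role, genotype, inducer_label, replicate, time_min, od,
#'   gfp`).
#' @param timepoint Time (min) at which to read all wells; see
#'   [select_timepoint()]. The closest measured time is used.
#' @param subtract_blank_od Subtract the plate's blank OD before dividing
#'   (default `TRUE`); set `FALSE` to divide by raw OD.
#' @return Tibble of per-well normalized fluorescence (`plate, well, role,
#'   genotype, inducer_label, inducer_pct, replicate, od, normalized`),
#'   wild-type wells averaging exactly 1 on every plate.
#' @export
correct_and_normalize <- function(plates, timepoint, subtract_blank_od = TRUE) {
  need <- c("plate", "well", "role", "genotype", "inducer_label",
            "replicate", "time_min", "od", "gfp")
  if (!all(need %in% names(plates))) {
    stop("plate table is missing columns: ",
         paste(setdiff(need, names(plates)), collapse = ", "))
  }
  if (!any(plates$role == "blank")) stop("no blank wells on the plates")
  if (!any(plates$role == "WT")) stop("no wild-type control wells on the plates")

  # read every well at the measured time closest to the chosen time point
  at_t <- plates |>
    dplyr::group_by(.data$plate, .data$well) |>
    dplyr::slice_min(abs(.data$time_min - as.numeric(timepoint)),
                     n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()

  at_t <- at_t |>
    dplyr::group_by(.data$plate) |>
    dplyr::mutate(
      blank_gfp = mean(.data$gfp[.data$role == "blank"]),
      blank_od = mean(.data$od[.data$role == "blank"])) |>
    dplyr::ungroup()
  if (anyNA(at_t$blank_gfp)) stop("a plate is missing blank wells")

  denom <- at_t$od - if (subtract_blank_od) at_t$blank_od else 0
  corrected <- ifelse(denom > 0, (at_t$gfp - at_t$blank_gfp) / denom, NA_real_)
  at_t$corrected <- ifelse(at_t$role == "blank", NA_real_, corrected)

  # stage one: scale each plate so its WT wells average 1; stage two:
  # re-scale by the per-plate WT values again (idempotent)
  out <- at_t |>
    dplyr::filter(.data$role != "blank") |>
    dplyr::group_by(.data$plate) |>
    dplyr::mutate(normalized = .data$corrected /
                    mean(.data$corrected[.data$role == "WT"], na.rm = TRUE)) |>
    dplyr::mutate(normalized = .data$normalized /
                    mean(.data$normalized[.data$role == "WT"], na.rm = TRUE)) |>
    dplyr::ungroup()
  cols <- intersect(c("plate", "well", "role", "genotype", "inducer_label",
                      "inducer_pct", "replicate", "od", "normalized"),
                    names(out))
  out[, cols]
}

#' Growth-based replicate QC
#'
#' A replicate of a genotype is excluded when its culture's OD differs by
#' more than `max_od_diff` from the mean OD of the wild-type control wells
#' on the same plate in any assayed condition. Genotypes left with fewer
#' than two surviving replicates are flagged `needs_repeat`. Wild-type
#' control wells are never excluded.
#'
#' @param wells Normalized well table from [correct_and_normalize()].
#' @param max_od_diff Allowed absolute OD deviation from the plate's
#'   wild-type mean; default 0.2.
#' @return List with `wells` (surviving rows) and `qc` (a list with
#'   `excluded` — genotype x replicate with reason — and `surviving` —
#'   per-genotype surviving replicate count and `needs_repeat` flag).
#' @export
qc_filter <- function(wells, max_od_diff = 0.2) {
  wells <- wells |>
    dplyr::group_by(.data$plate) |>
    dplyr::mutate(wt_od = mean(.data$od[.data$role == "WT"])) |>
    dplyr::ungroup()

  # a replicate fails if it deviates in ANY condition
  fails <- wells |>
    dplyr::filter(.data$role == "sample") |>
    dplyr::group_by(.data$genotype, .data$replicate) |>
    dplyr::summarise(max_dev = max(abs(.data$od - .data$wt_od)),
                     .groups = "drop") |>
    dplyr::filter(.data$max_dev > max_od_diff) |>
    dplyr::mutate(reason = sprintf("growth deviation %.3f > %.3f from WT",
                                   .data$max_dev, max_od_diff))

  keep <- wells$role != "sample" |
    !paste(wells$genotype, wells$replicate) %in%
      paste(fails$genotype, fails$replicate)
  all_gt <- unique(wells$genotype[wells$role == "sample"])
  kept_counts <- wells[keep & wells$role == "sample", ] |>
    dplyr::distinct(.data$genotype, .data$replicate) |>
    dplyr::count(.data$genotype, name = "n_replicates")
  surviving <- tibble::tibble(genotype = all_gt) |>
    dplyr::left_join(kept_counts, by = "genotype") |>
    dplyr::mutate(n_replicates = ifelse(is.na(.data$n_replicates), 0L,
                                        .data$n_replicates),
                  needs_repeat = .data$n_replicates < 2L)
  list(wells = wells[keep, setdiff(names(wells), "wt_od")],
       qc = list(excluded = fails[, c("genotype", "replicate", "reason")],
                 surviving = surviving))
}

#' Replicate summary statistics
#'
#' Mean, sample standard deviation (n - 1 denominator) and replicate count
#' of normalized fluorescence per genotype and inducer level. Genotypes
#' with a single surviving replicate get `sd = NA` and are flagged.
#'
#' @param wells Normalized well table (columns `genotype, inducer_label,
#'   replicate, normalized`), e.g. from [qc_filter()], or any tidy
#'   replicate-level table using the column `fluorescence` instead of
#'   `normalized`.
#' @return Tibble `genotype, inducer_label, (inducer_pct,) mean, sd, n,
#'   flag`.
#' @export
summarize_expression <- function(wells) {
  value_col <- if ("normalized" %in% names(wells)) "normalized" else "fluorescence"
  wells$..value <- wells[[value_col]]
  grp <- intersect(c("genotype", "order", "inducer_label", "inducer_pct"),
                   names(wells))
  out <- wells |>
    dplyr::filter(!is.na(.data$..value)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(mean = mean(.data$..value),
                     sd = stats::sd(.data$..value),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(flag = ifelse(.data$n < 2L, "single_replicate", NA_character_))
  out
}

#' Squared correlation between replicate measurement vectors
#'
#' The R^2 of an ordinary least-squares fit of one replicate's values on
#' another's, i.e. the squared Pearson correlation.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return R^2, or `NA` when either vector has zero variance.
#' @export
replicate_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need two vectors of equal length >= 3")
  }
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(NA_real_)
  }
  stats::cor(x, y)^2
}
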