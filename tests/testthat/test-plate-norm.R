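test_that("time-point selection follows the WT peak with deterministic ties", {
  tp <- select_timepoint(c(0, 60, 120, 180), c(0, 10, 30, 20))
  expect_equal(as.numeric(tp), 120)
  expect_true(is.na(attr(tp, "flag")))
  expect_warning(tp2 <- select_timepoint(c(0, 60, 120), c(5, 5, 5)), "tied")
  expect_equal(as.numeric(tp2), 0)
  expect_equal(attr(tp2, "flag"), "tie")
  tp3 <- select_timepoint(c(0, 60, 120), c(1, 2, 3))
  expect_equal(as.numeric(tp3), 120)
  expect_equal(attr(tp3, "flag"), "no_peak")
  expect_error(select_timepoint(numeric(0), numeric(0)), "non-empty")
})

test_that("blank/OD correction and WT scaling follow the documented arithmetic", {
  # corrected value = (600 - 100) / (0.55 - 0.05) = 1000; WT wells at 2000
  # post-correction, so the sample normalizes to 0.5
  pl <- manual_plate(samples = c(s1 = 1000), wt_corrected = 2000)
  nw <- correct_and_normalize(pl, timepoint = 0)
  expect_equal(nw$normalized[nw$role == "sample"], 0.5)
  expect_equal(mean(nw$normalized[nw$role == "WT"]), 1)
  raw_sample <- pl[pl$role == "sample" & pl$time_min == 0, ]
  expect_equal((raw_sample$gfp - 100) / (raw_sample$od - 0.05), 1000)
  # all wells identical to WT -> everything normalizes to exactly 1
  pl2 <- manual_plate(samples = c(a = 2000, b = 2000), wt_corrected = 2000)
  nw2 <- correct_and_normalize(pl2, timepoint = 0)
  expect_equal(nw2$normalized, rep(1, nrow(nw2)))
})

test_that("WT normalization is idempotent and exact on every plate", {
  cfg <- tiny_config(M = 2L, cv = 0.08)
  pl <- generate_raw_plates(cfg, seed = 6)
  nw <- correct_and_normalize(pl, timepoint = 180)
  wt_means <- nw |>
    dplyr::filter(role == "WT") |>
    dplyr::group_by(plate) |>
    dplyr::summarise(m = mean(normalized))
  expect_equal(wt_means$m, rep(1, nrow(wt_means)))
  # re-applying the WT scaling changes nothing
  again <- nw |>
    dplyr::group_by(plate) |>
    dplyr::mutate(re = normalized / mean(normalized[role == "WT"])) |>
    dplyr::ungroup()
  expect_equal(again$re, nw$normalized)
})

test_that("unusable wells (OD at or below blank) are marked missing", {
  pl <- manual_plate(samples = c(dead = 500))
  pl$od[pl$role == "sample"] <- 0.04 # below the 0.05 blank
  nw <- correct_and_normalize(pl, timepoint = 0)
  expect_true(all(is.na(nw$normalized[nw$role == "sample"])))
  expect_error(correct_and_normalize(pl[pl$role != "blank", ], 0), "blank")
})

test_that("growth-based QC applies the 0.2 OD rule per condition", {
  pl <- manual_plate(samples = c(fast = 1000, ok = 1000))
  pl$od[pl$genotype %in% "fast"] <- 0.9 # WT wells sit at 0.55
  nw <- correct_and_normalize(pl, timepoint = 0)
  res <- qc_filter(nw)
  expect_equal(res$qc$excluded$genotype, "fast")
  expect_match(res$qc$excluded$reason, "growth deviation")
  expect_false("fast" %in% res$wells$genotype)
  expect_true("ok" %in% res$wells$genotype)
  # a 0.1 deviation is within the rule
  pl2 <- manual_plate(samples = c(near = 1000))
  pl2$od[pl2$genotype %in% "near"] <- 0.65
  res2 <- qc_filter(correct_and_normalize(pl2, 0))
  expect_equal(nrow(res2$qc$excluded), 0L)
  # WT control wells are never excluded
  expect_equal(sum(res$wells$role == "WT"), 3L)
})

test_that("genotypes left with fewer than two replicates are flagged", {
  cfg <- tiny_config(M = 2L, cv = 0.02)
  pl <- generate_raw_plates(cfg, genotypes = c("sensor-1", "sensor-2"), seed = 8,
                            od_offset = c("sensor-1" = 0.3))
  nw <- correct_and_normalize(pl, timepoint = 180)
  res <- qc_filter(nw)
  surv <- res$qc$surviving
  expect_true(surv$needs_repeat[surv$genotype == "sensor-1"])
  expect_false(surv$needs_repeat[surv$genotype == "sensor-2"])
})

test_that("replicate summaries use the sample SD and flag singletons", {
  w <- tibble::tibble(genotype = "g", inducer_label = "low",
                      replicate = 1:3, normalized = c(1.0, 1.2, 1.4))
  s <- summarize_expression(w)
  expect_equal(s$mean, 1.2)
  expect_equal(s$sd, 0.2)
  expect_equal(s$n, 3L)
  s2 <- summarize_expression(w[1, ])
  expect_true(is.na(s2$sd))
  expect_equal(s2$flag, "single_replicate")
  w$normalized <- 1.1
  expect_equal(summarize_expression(w)$sd, 0)
})

test_that("replicate correlation is the squared least-squares correlation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(replicate_correlation(x, x), 1)
  expect_equal(replicate_correlation(x, 2 * x + 1), 1)
  expect_true(is.na(replicate_correlation(x, rep(2, 5))))
  set.seed(31)
  n <- 2000L
  sig <- rnorm(n)
  noise <- rnorm(n)
  noise <- noise - sig * sum(noise * sig) / sum(sig^2) # orthogonalized
  r2 <- replicate_correlation(sig, noise)
  expect_lt(r2, 1e-3)
  # agrees with the regression R^2 from lm()
  y <- sig + rnorm(n, sd = 0.5)
  expect_equal(replicate_correlation(sig, y),
               summary(stats::lm(y ~ sig))$r.squared, tolerance = 1e-12)
})
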