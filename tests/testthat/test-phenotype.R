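test_that("pattern projection takes level differences of log expression", {
  p <- project_pattern(2.0, 2.5, 2.1)
  expect_equal(p$Mx, 0.5); expect_equal(p$My, -0.4)
  expect_equal(unlist(project_pattern(1, 1, 1)), c(Mx = 0, My = 0))
  # a stripe (medium strictly max) lands in Mx > 0, My < 0
  wt <- log10(steady_state(circuit_params(), NULL, inducer_levels()$inducer_pct))
  pw <- project_pattern(wt[1], wt[2], wt[3])
  expect_gt(pw$Mx, 0); expect_lt(pw$My, 0)
})

test_that("quadrant classification partitions the plane", {
  expect_equal(classify_pattern(0.5, -0.4)$class, "stripe")
  expect_equal(classify_pattern(0.2, 0.3)$class, "increase")
  expect_equal(classify_pattern(-0.2, 0.4)$class, "anti_stripe")
  expect_equal(classify_pattern(-0.2, -0.1)$class, "decrease")
  expect_equal(classify_pattern(0.001, -0.001, flat_radius = 0.01)$class, "flat")
  # boundary points follow the half-open convention and get flagged
  b <- classify_pattern(0, 0.3)
  expect_equal(b$class, "anti_stripe"); expect_true(b$boundary)
  expect_error(classify_pattern(Inf, 0), "finite")
  # every non-boundary point maps to exactly one of the four classes
  set.seed(61)
  Mx <- rnorm(500); My <- rnorm(500)
  cl <- classify_pattern(Mx, My)
  expect_false(any(cl$boundary))
  oracle <- ifelse(Mx > 0 & My > 0, "increase",
            ifelse(Mx < 0 & My > 0, "anti_stripe",
            ifelse(Mx < 0 & My < 0, "decrease", "stripe")))
  expect_equal(cl$class, oracle)
})

test_that("expected points follow the multiplicative null and cancel uniform shifts", {
  # two neutral singles (fold 1 everywhere): the expected pair sits on WT
  folds <- list(WT = c(low = 1, medium = 1, high = 1),
                `sensor-1` = c(low = 1, medium = 1, high = 1),
                `output-1` = c(low = 10, medium = 10, high = 10),
                `sensor-1+output-2` = c(low = 1, medium = 1, high = 1),
                `sensor-2` = c(low = 1, medium = 1, high = 1),
                `output-2` = c(low = 1, medium = 1, high = 1),
                `sensor-2+output-1` = c(low = 5, medium = 5, high = 5))
  d <- exact_fold_data(folds)
  expr <- summarize_expression(d)
  lfc <- log_fold_changes(d)
  pts <- phenotype_points(expr, lfc)
  wt <- pts[pts$genotype == "WT", ]
  neutral_exp <- pts[pts$genotype == "sensor-1+output-2" &
                       pts$source == "expected", ]
  expect_equal(c(neutral_exp$Mx, neutral_exp$My), c(wt$Mx, wt$My))
  # a uniform 10x single shifts all levels equally: expectation still on WT
  shifted_exp <- pts[pts$genotype == "sensor-2+output-1" &
                       pts$source == "expected", ]
  expect_equal(c(shifted_exp$Mx, shifted_exp$My), c(wt$Mx, wt$My))
  expect_equal(shifted_exp$distance_to_wt, 0)
})

test_that("noiseless null simulation puts observed points on expected points", {
  d <- generate_dataset(tiny_config(M = 2L, cv = 0),
                        mode = "multiplicative_null", seed = 19)
  expr <- summarize_expression(d$data)
  lfc <- log_fold_changes(d$data)
  pts <- phenotype_points(expr, lfc)
  wide <- tidyr::pivot_wider(pts[pts$order >= 2, c("genotype", "source", "Mx", "My")],
                             names_from = "source", values_from = c("Mx", "My"))
  expect_equal(wide$Mx_observed, wide$Mx_expected, tolerance = 1e-12)
  expect_equal(wide$My_observed, wide$My_expected, tolerance = 1e-12)
})

test_that("distances to WT are Euclidean and shift-invariant", {
  pts <- tibble::tibble(genotype = c("WT", "g"), order = c(0L, 2L),
                        source = "observed",
                        Mx = c(0, 0.3), My = c(0, -0.4))
  d <- sqrt((pts$Mx - pts$Mx[1])^2 + (pts$My - pts$My[1])^2)
  expect_equal(d[2], 0.5) # the 3-4-5 triangle
  # adding any per-level constant to all genotypes' G leaves distances alone
  set.seed(62)
  G <- matrix(runif(30, 1, 3), ncol = 3,
              dimnames = list(NULL, c("low", "medium", "high")))
  shift <- runif(3, -2, 2)
  p0 <- project_pattern(G[, 1], G[, 2], G[, 3])
  p1 <- project_pattern(G[, 1] + shift[1], G[, 2] + shift[2], G[, 3] + shift[3])
  d0 <- sqrt((p0$Mx - p0$Mx[1])^2 + (p0$My - p0$My[1])^2)
  d1 <- sqrt((p1$Mx - p1$Mx[1])^2 + (p1$My - p1$My[1])^2)
  expect_equal(d0, d1, tolerance = 1e-12)
})

test_that("diversity comparison pairs points and degenerates to p = 1", {
  d <- generate_dataset(tiny_config(M = 2L, cv = 0),
                        mode = "multiplicative_null", seed = 23)
  pts <- phenotype_points(summarize_expression(d$data),
                          log_fold_changes(d$data))
  dv <- distance_and_diversity(pts)
  expect_equal(nrow(dv$distances), 20L) # 12 pairs + 8 triplets
  expect_equal(dv$distances$dist_observed, dv$distances$dist_expected,
               tolerance = 1e-12)
  expect_lt(max(dv$distances$displacement), 1e-12)
  expect_true(all(dv$tests$degenerate))
  expect_equal(dv$tests$p, c(1, 1))
})
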