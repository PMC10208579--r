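# Independent ordering oracle for the pure-direction cases: with all
# singles raising expression, the combination is magnitude epistasis above
# the highest single, sign epistasis between the extremes, and reciprocal
# sign epistasis below the lowest single (mirrored when all singles lower
# expression).
oracle_form <- function(G_singles, G_combined) {
  if (all(G_singles > 0)) {
    if (G_combined > max(G_singles)) "magnitude"
    else if (G_combined < min(G_singles)) "RSE"
    else "sign"
  } else if (all(G_singles < 0)) {
    if (G_combined < min(G_singles)) "magnitude"
    else if (G_combined > max(G_singles)) "RSE"
    else "sign"
  } else NA_character_
}

test_that("type classification matches the worked pairwise cases", {
  # all-higher singles, combination collapsing below both -> negative RSE
  cl <- classify_type(c(0.3, 0.2), 0.1, 0.1 - 0.5)
  expect_equal(cl$sign, "negative")
  expect_equal(cl$form, "RSE")
  expect_equal(cl$direction_group, "all_higher")
  # between the two singles -> sign epistasis
  cl2 <- classify_type(c(0.3, 0.2), 0.25, 0.25 - 0.5)
  expect_equal(cl2$form, "sign")
  expect_equal(cl2$sign, "negative")
  # beyond both singles but either side of the expectation -> magnitude
  cl3 <- classify_type(c(0.3, 0.2), 0.45, 0.45 - 0.5)
  expect_equal(cl3$form, "magnitude")
  expect_equal(cl3$sign, "negative")
  cl4 <- classify_type(c(0.3, 0.2), 0.6, 0.6 - 0.5)
  expect_equal(cl4$form, "magnitude")
  expect_equal(cl4$sign, "positive")
  # zero epistasis has no class
  cl5 <- classify_type(c(0.3, 0.2), 0.5, 0)
  expect_equal(cl5$form, "none")
})

test_that("type classification agrees with the ordering oracle on random cases", {
  set.seed(53)
  for (i in 1:500) {
    k <- sample(2:3, 1)
    dir <- sample(c(-1, 1), 1)
    Gs <- dir * runif(k, 0.05, 1)
    Gc <- runif(1, -1.5, 1.5)
    if (Gc %in% Gs || Gc == sum(Gs)) next
    cl <- classify_type(Gs, Gc, Gc - sum(Gs))
    expect_equal(cl$form, oracle_form(Gs, Gc),
                 label = sprintf("singles=%s combined=%.3f",
                                 paste(round(Gs, 3), collapse = ","), Gc))
    expect_equal(cl$sign, if (Gc > sum(Gs)) "positive" else "negative")
  }
})

test_that("mixed-direction singles never produce RSE", {
  set.seed(54)
  for (i in 1:200) {
    Gs <- c(runif(1, 0.05, 1), -runif(1, 0.05, 1),
            if (runif(1) < 0.5) runif(1, 0.05, 1) else NULL)
    Gc <- runif(1, -2, 2)
    cl <- classify_type(Gs, Gc, Gc - sum(Gs))
    expect_equal(cl$direction_group, "mixed")
    expect_false(identical(cl$form, "RSE"))
  }
})

test_that("epistasis sigma propagation follows both documented modes", {
  expect_equal(sigma_epistasis(2, 0.3, 0.4), 1.0)
  expect_equal(sigma_epistasis(2, 0.3, 0.4, "sum_of_variances"), 0.5)
  expect_equal(sigma_epistasis(0, 0.3, 0.4), 0) # degenerate printed form
  expect_equal(sigma_epistasis(1, 0, 0), 0)
  expect_error(sigma_epistasis(1, -0.1, 0.1), ">= 0")
})

test_that("inducer-dependence categories follow the decision table", {
  cc <- classify_category(-0.1, 0.2, 0.1)
  expect_equal(cc$category, "A"); expect_equal(cc$trajectory, "switching")
  cc <- classify_category(-0.3, -0.2, -0.1)
  expect_equal(cc$category, "B"); expect_equal(cc$trajectory, "always_negative")
  cc <- classify_category(0.3, 0.2, 0.1)
  expect_equal(cc$category, "C"); expect_equal(cc$trajectory, "always_positive")
  cc <- classify_category(0.2, -0.1, 0.3)
  expect_equal(cc$category, "D"); expect_equal(cc$trajectory, "switching")
  # exact ties break towards the medium-extremum categories, flagged
  tie <- classify_category(0.1, 0.1, 0.1)
  expect_true(tie$tie); expect_equal(tie$category, "A")
  expect_error(classify_category(0.1, NA, 0.2), "finite")
})

test_that("every strict ordering of three values maps to exactly one category", {
  set.seed(55)
  eps <- matrix(rnorm(3 * 500), ncol = 3)
  eps <- eps[apply(eps, 1, function(r) !anyDuplicated(r)), ]
  cc <- classify_category(eps[, 1], eps[, 2], eps[, 3])
  expect_false(any(cc$tie))
  expect_true(all(cc$category %in% c("A", "B", "C", "D")))
  # the oracle from the ordering of (low, medium, high)
  oracle <- apply(eps, 1, function(r) {
    if (r[2] > max(r[c(1, 3)])) "A"
    else if (r[2] < min(r[c(1, 3)])) "D"
    else if (r[1] < r[3]) "B" else "C"
  })
  expect_equal(cc$category, oracle)
  # switching trajectory iff signs differ
  expect_equal(cc$trajectory == "switching",
               apply(eps, 1, function(r) length(unique(sign(r))) > 1))
})

test_that("inducer-dependence testing flags separated profiles only", {
  lv <- c("low", "medium", "high")
  base <- tibble::tibble(
    genotype = rep(c("sensor-1+output-1", "sensor-2+output-2"), each = 3),
    order = 2L, inducer_label = rep(lv, 2),
    epsilon = c(0.2, 0.2, 0.2, 0, 0, 5),
    sd_obs = 0.01, sd_exp = 0.01)
  prof <- inducer_dependence(base, alpha = 0.1, sigma_mode = "sum_of_variances")
  flat <- prof[prof$genotype == "sensor-1+output-1", ]
  expect_equal(c(flat$p_LM, flat$p_LH, flat$p_MH), rep(1, 3))
  expect_false(flat$dependent)
  expect_true(prof$dependent[prof$genotype == "sensor-2+output-2"])
})

test_that("per-genotype summaries count combinations correctly", {
  lfc <- random_lfc(M = 2L)
  et <- epistasis_table(lfc)
  gsum <- summarize_by_genotype(et, "genotype")
  # M = 2: each single sits in 2M = 4 pairs and M^2 = 4 triplets,
  # over 3 levels -> 12 values each
  expect_true(all(gsum$n_values[gsum$order == 2] == 12L))
  expect_true(all(gsum$n_values[gsum$order == 3] == 12L))
  expect_equal(sort(unique(gsum$single)),
               sort(enumerate_genotypes(2)$genotype[enumerate_genotypes(2)$order == 1]))
  # constant epsilon -> SD 0, CoV 0
  et2 <- et
  et2$epsilon <- -0.2
  gsum2 <- summarize_by_genotype(et2, "genotype")
  expect_equal(unique(gsum2$mean_epsilon), -0.2)
  expect_equal(unique(gsum2$sd_epsilon), 0)
  expect_equal(unique(gsum2$cov_epsilon), 0)
  # zero mean -> CoV undefined
  et3 <- et
  et3$epsilon <- 0
  gsum3 <- summarize_by_genotype(et3, "node")
  expect_true(all(is.na(gsum3$cov_epsilon)))
  # node x level grouping keeps all three levels
  gsum4 <- summarize_by_genotype(et, "node_level")
  expect_equal(nrow(gsum4), 3L * 3L * 2L)
})
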