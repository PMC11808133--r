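test_that("the Bonferroni threshold is alpha over the number of tests", {
  expect_equal(bonferroni_threshold(0.05, 255), 0.05 / 255)
  expect_lt(abs(bonferroni_threshold(0.05, 255) - 1.96e-4), 5e-7)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 50), 1e-3)
  expect_error(bonferroni_threshold(0.05, 0), "n_variables")
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
})

test_that("the scan finds planted effects and accounts its counts", {
  fx <- strong_pipeline_fixture()
  scan <- fx$scan
  expect_equal(attr(scan, "n_adverse") + attr(scan, "n_protective"),
               attr(scan, "n_significant"))
  expect_equal(attr(scan, "threshold"),
               0.05 / attr(scan, "n_variables"))
  # the two strongest planted effects are recovered with correct direction
  expect_true(scan$significant[scan$variable == "med_cont1"])
  expect_gt(scan$hr[scan$variable == "med_cont1"], 1)
  expect_true(scan$significant[scan$variable == "phy_cont1"])
  expect_lt(scan$hr[scan$variable == "phy_cont1"], 1)
  # results ordered by p
  expect_false(is.unsorted(scan$p[!is.na(scan$p)]))
  expect_error(run_scan(fx$pp$cohort, fx$pp$catalog[0, ]), "no modifiable")
})

test_that("scan results do not depend on variable order", {
  fx <- strong_pipeline_fixture()
  set.seed(1)
  shuffled <- fx$pp$catalog[sample.int(nrow(fx$pp$catalog)), ]
  s2 <- run_scan(fx$pp$cohort, shuffled)
  s1 <- fx$scan
  expect_equal(s2$variable, s1$variable)
  expect_equal(s2$p, s1$p)
})

test_that("per-variable failures are recorded without stopping the scan", {
  sim <- generate_cohort(strong_cfg(n = 800, seed = 19))
  cohort <- sim$cohort
  cohort$dead_col <- 1   # constant
  catalog <- rbind(sim$catalog,
                   data.frame(variable = "dead_col", domain = "lifestyle",
                              type = "continuous", modifiable = TRUE,
                              count_coded = FALSE, n_instances = 1L))
  scan <- run_scan(cohort, catalog)
  row <- scan[scan$variable == "dead_col", ]
  expect_match(row$error, "constant")
  expect_true(is.na(row$p))
  expect_false(row$significant)
  expect_equal(attr(scan, "n_variables"), nrow(catalog))
})

test_that("collinearity filtering drops the weaker of highly correlated pairs", {
  fx <- strong_pipeline_fixture()
  cohort <- fx$pp$cohort
  catalog <- fx$pp$catalog
  # plant exact duplicates of a strong hit
  cohort$dup1 <- cohort$med_cont1
  cohort$dup2 <- cohort$med_cont1
  extra <- data.frame(variable = c("dup1", "dup2"),
                      domain = "medical history", type = "continuous",
                      modifiable = TRUE, count_coded = FALSE,
                      n_instances = 1L, source = c("dup1", "dup2"))
  scan <- run_scan(cohort, rbind(catalog, extra))
  filt <- collinearity_filter(scan, cohort)
  trio <- c("med_cont1", "dup1", "dup2")
  expect_equal(sum(filt$significant[filt$variable %in% trio]), 1)
  expect_equal(sum(filt$dropped_collinear[filt$variable %in% trio]), 2)
  # survivors respect the r-squared bound
  surv <- filt$variable[filt$significant]
  r2 <- cor(as.matrix(cohort[surv]))^2
  diag(r2) <- 0
  expect_lte(max(r2), 0.9)
  # no-op when nothing is over the threshold
  filt2 <- collinearity_filter(fx$scan, fx$pp$cohort)
  expect_length(attr(filt2, "dropped_collinear"), 0)
  expect_equal(filt2$significant, fx$scan$significant)
})

test_that("collinear ties are resolved toward the smaller p-value", {
  # two identical columns, one with an artificially better p
  scan <- data.frame(variable = c("a", "b"), domain = "lifestyle",
                     beta = 0.1, se = 0.01, hr = 1.1, lo = 1, hi = 1.2,
                     p = c(1e-9, 1e-6), ph_p = 0.5, ph_violation = FALSE,
                     fallback = FALSE, error = NA_character_,
                     significant = TRUE, stringsAsFactors = FALSE)
  class(scan) <- c("ewas_scan", "data.frame")
  cohort <- data.frame(a = rnorm(100))
  cohort$b <- cohort$a
  filt <- collinearity_filter(scan, cohort)
  expect_equal(attr(filt, "dropped_collinear"), "b")
  expect_true(filt$significant[filt$variable == "a"])
})

test_that("subgroup scans reuse the full-sample threshold and skip empty strata", {
  fx <- strong_pipeline_fixture()
  cohort <- fx$pp$cohort
  # a constant stratification reproduces the full-sample scan
  sg <- subgroup_scan(cohort, fx$pp$catalog,
                      strata = list(all = rep("everyone", nrow(cohort))))
  one <- sg$scans$all$everyone
  expect_equal(one$p, fx$scan$p[match(one$variable, fx$scan$variable)])
  expect_equal(attr(one, "threshold"), attr(fx$scan, "threshold"))
  # a stratum without events is skipped with a warning
  fac <- ifelse(cohort$event == 1, "with", "without")
  expect_warning(sg2 <- subgroup_scan(cohort, fx$pp$catalog,
                                      strata = list(ev = fac)),
                 "no events")
  expect_named(sg2$scans$ev, "with")
  # age stratification produces a heatmap table over both strata
  sg3 <- subgroup_scan(cohort, fx$pp$catalog,
                       strata = list(age = ifelse(cohort$age >= 65,
                                                  ">=65", "<65")))
  expect_setequal(unique(sg3$heatmap$stratum), c(">=65", "<65"))
  expect_equal(nrow(sg3$heatmap), 2 * nrow(fx$scan))
})
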