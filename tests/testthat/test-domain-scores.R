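fake_scan <- function(df) {
  df$error <- NA_character_
  df$significant <- TRUE
  class(df) <- c("ewas_scan", "data.frame")
  df
}

test_that("orientation complements protective binaries and median-splits others", {
  set.seed(3)
  cohort <- data.frame(smoke = rbinom(200, 1, 0.3),
                       grip = rnorm(200),
                       illness = rbinom(200, 1, 0.4))
  catalog <- data.frame(variable = c("smoke", "grip", "illness"),
                        domain = c("lifestyle", "physical measures",
                                   "medical history"),
                        type = c("binary", "continuous", "binary"),
                        modifiable = TRUE, count_coded = FALSE,
                        n_instances = 1L)
  scan <- fake_scan(data.frame(
    variable = c("smoke", "grip", "illness"),
    domain = catalog$domain,
    hr = c(0.66, 0.98, 1.38), p = c(1e-8, 1e-24, 1e-20)))
  or <- orient_factors(scan, cohort, catalog)
  expect_equal(or$X$smoke, 1L - cohort$smoke)          # protective binary
  med <- median(cohort$grip)
  expect_equal(or$X$grip, as.integer(cohort$grip < med))  # weak grip = risk
  expect_equal(or$X$illness, cohort$illness)           # already adverse
  expect_equal(or$info$rule, c("complement", "below_median", "identity"))
  # oriented factors all associate with hazard in the adverse direction
  expect_true(all(vapply(or$X, function(x) all(x %in% 0:1), TRUE)))
})

test_that("unweighted scores count oriented risk factors", {
  or <- list(info = data.frame(variable = c("a", "b", "c"),
                               domain = "lifestyle"),
             X = data.frame(a = c(1, 0, 1), b = c(0, 0, 1),
                            c = c(1, 0, 1)))
  class(or) <- "oriented_factors"
  expect_equal(unweighted_score(or, "lifestyle"), c(2L, 0L, 3L))
})

test_that("the weighted score is the beta-weighted fraction of risk burden", {
  fx <- strong_scores_fixture()
  for (s in fx$scores) {
    X <- as.matrix(fx$oriented$X[s$members])
    manual <- as.vector(X %*% s$beta) / sum(s$beta)
    expect_equal(s$score, manual, tolerance = 1e-12)
    if (all(s$beta >= 0)) {
      expect_true(all(s$score >= -1e-12 & s$score <= 1 + 1e-12))
      expect_equal(s$score[rowSums(X) == 0],
                   rep(0, sum(rowSums(X) == 0)))
    }
    # rescaling all betas leaves the score unchanged
    expect_equal(as.vector(X %*% (3 * s$beta)) / sum(3 * s$beta), s$score,
                 tolerance = 1e-12)
    # weighted and unweighted scores agree in rank direction
    expect_gt(stats::cor(s$score, s$unweighted, method = "spearman"), 0)
  }
})

test_that("worked weighted-score example: S = sum(X beta) / sum(beta)", {
  X <- rbind(c(1, 1, 1), c(1, 0, 0), c(0, 0, 0))
  beta <- c(0.2, 0.3, 0.5)
  S <- as.vector(X %*% beta) / sum(beta)
  expect_equal(S, c(1.0, 0.2, 0.0))
})

test_that("tertile categorization is deterministic and rank-invariant", {
  lab <- categorize_tertiles(1:9)
  expect_equal(as.vector(table(lab)), c(3, 3, 3))
  expect_equal(as.character(lab[c(1, 4, 7)]),
               c("favorable", "moderate", "unfavorable"))
  # ties at the cut all go to the lower category (the four zeros share
  # the lower cut; the 2/3 quantile falls between them and the ones)
  tied <- c(0, 0, 0, 0, 1, 1)
  lt <- categorize_tertiles(tied)
  expect_equal(as.character(lt),
               rep(c("favorable", "unfavorable"), c(4, 2)))
  # invariant to monotone transforms
  x <- rnorm(100)
  expect_equal(categorize_tertiles(x), categorize_tertiles(exp(x)))
  expect_error(categorize_tertiles(rep(2, 10)), "identical")
})

test_that("the joint five-domain model recovers planted effects", {
  fx <- strong_scores_fixture()
  jm <- joint_domain_model(fx$pp$cohort, fx$scores)
  unf <- jm$terms[grepl("unfavorable", jm$terms$term), ]
  expect_gt(nrow(unf), 0)
  expect_true(all(unf$hr > 1))
  expect_true(all(unf$p < 0.01))
  # unweighted sensitivity keeps the effect directions
  jm2 <- joint_domain_model(fx$pp$cohort, fx$scores, use = "unweighted")
  unf2 <- jm2$terms[grepl("unfavorable", jm2$terms$term), ]
  expect_true(all(unf2$hr > 1))
})

test_that("the nine-group grid uses low/favorable as global reference", {
  fx <- strong_scores_fixture()
  prs <- compute_prs(fx$sim$genotypes, fx$sim$snp_weights)
  keep <- match(fx$pp$cohort$id, fx$sim$cohort$id)
  groups <- prs_tertiles(prs$prs[keep])
  g <- gxe_nine_groups(fx$pp$cohort, groups, fx$scores[["medical history"]])
  expect_equal(nrow(g$grid), 9)
  ref <- g$grid[g$grid$reference, ]
  expect_equal(ref$prs, "low")
  expect_equal(ref$category, "favorable")
  expect_equal(ref$hr, 1)
  expect_equal(sum(g$grid$n), nrow(fx$pp$cohort))
  # risk rises along both axes from the reference
  hi_unf <- g$grid[g$grid$prs == "high" & g$grid$category == "unfavorable", ]
  expect_gt(hi_unf$hr, 1)
  # within-stratum tables contrast favorable/moderate against unfavorable
  expect_setequal(unique(g$within$category), c("favorable", "moderate"))
  expect_true(all(g$within$hr[g$within$category == "favorable"] < 1))
})

test_that("without a PRS effect the grid rows are homogeneous across strata", {
  cfg <- strong_cfg(n = 6000, seed = 23, prs_log_hr = 0,
                    baseline_hazard = 0.03)
  sim <- generate_cohort(cfg)
  scan <- run_scan(sim$cohort, sim$catalog)
  or <- orient_factors(scan, sim$cohort, sim$catalog)
  sc <- suppressWarnings(build_domain_scores(or, sim$cohort))
  prs <- compute_prs(sim$genotypes, sim$snp_weights)
  g <- gxe_nine_groups(sim$cohort, prs_tertiles(prs$prs),
                       sc[["medical history"]])
  # per-category HRs in medium/high PRS lie inside the CI spread of low
  for (cat in c("moderate", "unfavorable")) {
    rows <- g$grid[g$grid$category == cat, ]
    expect_lt(max(rows$hr) / min(rows$hr), 1.8)
  }
})
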