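test_that("polygenic scores standardize to mean 0, SD 1, preserving ranks", {
  p <- compute_prs(matrix(c(0, 1, 2)), 1)
  expect_equal(p$prs, c(-1, 0, 1))
  g <- generate_genotypes(200, 20, seed = 4)
  m <- compute_prs(g$dosages, g$weights)
  expect_equal(mean(m$prs), 0, tolerance = 1e-10)
  expect_equal(stats::sd(m$prs), 1, tolerance = 1e-10)
  expect_equal(order(m$prs), order(m$raw))
  # scale invariance of the standardized score
  m2 <- compute_prs(g$dosages, 2 * g$weights)
  expect_equal(m$prs, m2$prs, tolerance = 1e-12)
  expect_error(compute_prs(g$dosages, rep(0, 20)), "degenerate")
  expect_error(compute_prs(matrix(3, 5, 1), 1), "dosages")
})

test_that("tertile grouping follows the quantile-and-ties convention", {
  expect_equal(as.vector(table(prs_tertiles(1:9))), c(3, 3, 3))
  expect_equal(unname(prs_tertiles(1:9)[c(1, 5, 9)]),
               factor(c("low", "medium", "high"),
                      levels = c("low", "medium", "high"))[1:3])
  expect_equal(as.vector(table(prs_tertiles(1:10))), c(4, 3, 3))
  expect_error(prs_tertiles(rep(1, 10)), "identical")
})

test_that("instrument selection relaxes the threshold when SNPs are scarce", {
  ss <- generate_mr_summary(0.2, 10, seed = 2)
  all_in <- select_instruments(ss)
  expect_equal(nrow(all_in), 10)
  expect_false(attr(all_in, "relaxed"))

  ss2 <- ss
  ss2$p_exposure <- c(1e-9, rep(1e-7, 5), rep(0.5, 4))
  sel <- select_instruments(ss2)
  expect_equal(nrow(sel), 6)
  expect_true(attr(sel, "relaxed"))
  expect_equal(attr(sel, "threshold_used"), 5e-6)

  ss3 <- ss[1, ]
  expect_error(select_instruments(ss3), "insufficient")
})

mk_instruments <- function(ratios, ses) {
  data.frame(beta_exposure = 1, se_exposure = 1e-4,
             p_exposure = 1e-10, beta_outcome = ratios, se_outcome = ses)
}

test_that("IVW equals the closed-form inverse-variance weighted mean", {
  d <- mk_instruments(c(0.4, 0.2), c(0.1, 0.2))
  iv <- mr_ivw(d)
  expect_equal(iv$estimate, (100 * 0.4 + 25 * 0.2) / 125)
  expect_equal(iv$se, 1 / sqrt(125))
  q <- mr_cochran_q(d)
  expect_equal(q$Q, 100 * 0.04^2 + 25 * 0.16^2)
  expect_equal(q$df, 1)
  # homogeneous ratios: estimate is the common value, Q is zero
  h <- mk_instruments(rep(0.3, 4), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(mr_ivw(h)$estimate, 0.3)
  expect_equal(mr_cochran_q(h)$Q, 0)
  # equal weights reduce to the simple mean
  eq <- mk_instruments(c(0.1, 0.3, 0.8), rep(0.2, 3))
  expect_equal(mr_ivw(eq)$estimate, mean(c(0.1, 0.3, 0.8)))
  expect_error(mr_ivw(mk_instruments(0.1, 0.1)), "2 instruments")
  bad <- mk_instruments(c(0.1, 0.2), c(0.1, 0.1))
  bad$beta_exposure[1] <- 0
  expect_error(mr_ivw(bad), "ratio")
})

test_that("IVW matches a direct fixed-effect meta-analysis on random fixtures", {
  for (s in 1:5) {
    set.seed(s)
    k <- sample(3:10, 1)
    d <- data.frame(beta_exposure = runif(k, 0.05, 0.3),
                    se_exposure = runif(k, 0.005, 0.02),
                    p_exposure = 1e-10,
                    beta_outcome = rnorm(k, 0.1, 0.05),
                    se_outcome = runif(k, 0.01, 0.05))
    b <- d$beta_outcome / d$beta_exposure
    w <- (d$beta_exposure / d$se_outcome)^2
    expect_equal(mr_ivw(d)$estimate, sum(w * b) / sum(w), tolerance = 1e-12)
  }
})

test_that("the weighted median sits at the 50% weight crossing", {
  eq <- mk_instruments(c(0.1, 0.5, 0.9), rep(0.2, 3))
  expect_equal(mr_weighted_median(eq)$estimate, 0.5)
  # a dominant instrument pulls the median onto itself
  dom <- data.frame(beta_exposure = 1, se_exposure = 1e-4, p_exposure = 1e-10,
                    beta_outcome = c(0.2, 0.5, 0.9),
                    se_outcome = 1 / sqrt(c(0.98, 0.01, 0.01)))
  est <- mr_weighted_median(dom)$estimate
  expect_lt(abs(est - 0.2), 0.02)
  # duplicating the instrument set leaves the estimate unchanged
  eq2 <- rbind(eq, eq)
  expect_equal(mr_weighted_median(eq2)$estimate,
               mr_weighted_median(eq)$estimate)
  expect_error(mr_weighted_median(eq[1:2, ]), "3 instruments")
  # defining property: the interpolated weighted CDF passes through 1/2
  # at the estimate (checked with stats::approx as the independent
  # interpolation route)
  for (s in 1:10) {
    set.seed(s)
    k <- sample(3:7, 1)
    b <- sort(rnorm(k)); w <- runif(k, 0.1, 2)
    m <- exposcan:::.weighted_median(b, w)
    cw <- cumsum(w / sum(w)) - (w / sum(w)) / 2
    if (m > b[1] && m < b[k])
      expect_equal(stats::approx(b, cw, xout = m)$y, 0.5, tolerance = 1e-9)
    else
      expect_true(m %in% b[c(1, k)])
  }
})

test_that("MR-Egger recovers an exact affine relation and flags pleiotropy", {
  d <- data.frame(beta_exposure = c(0.1, 0.2, 0.3), se_exposure = 1e-4,
                  p_exposure = 1e-10,
                  beta_outcome = 0.5 * c(0.1, 0.2, 0.3) + 0.1,
                  se_outcome = c(0.02, 0.03, 0.04))
  eg <- mr_egger(d)
  expect_equal(eg$estimate, 0.5, tolerance = 1e-10)
  expect_equal(eg$intercept, 0.1, tolerance = 1e-10)
  expect_error(mr_egger(d[1:2, ]), "3 instruments")
  # constant pleiotropy: mean intercept across replicates near the truth
  ints <- vapply(1:30, function(s) {
    ss <- generate_mr_summary(0.2, 30, pleiotropy = 0.05, seed = 400 + s)
    mr_egger(ss)$intercept
  }, numeric(1))
  expect_lt(abs(mean(ints) - 0.05), 0.015)
})

test_that("noiseless instruments make all three estimators agree", {
  ss <- generate_mr_summary(0.25, 12, pleiotropy = 0, noise_scale = 0,
                            seed = 11)
  expect_equal(mr_ivw(ss)$estimate, 0.25, tolerance = 1e-10)
  expect_equal(mr_weighted_median(ss)$estimate, 0.25, tolerance = 1e-10)
  expect_equal(mr_egger(ss)$estimate, 0.25, tolerance = 1e-8)
  expect_equal(mr_cochran_q(ss)$Q, 0, tolerance = 1e-10)
})

test_that("run_mr bundles estimates, heterogeneity and provenance", {
  ss <- generate_mr_summary(0.3, 40, seed = 9)
  res <- run_mr(ss)
  expect_s3_class(res, "mr_result")
  expect_equal(res$n_snp, 40)
  expect_equal(res$cochran_q$df, 39)
  expect_gt(res$ivw$estimate, 0.2)
  expect_lt(abs(res$weighted_median$estimate - res$ivw$estimate), 0.1)
  # deterministic given the seed
  res2 <- run_mr(ss)
  expect_equal(res$weighted_median$se, res2$weighted_median$se)
})
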