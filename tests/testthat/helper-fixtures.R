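# Shared fixtures and independent oracles, built in code at test time.

# Brute-force maximizer of the Cox partial likelihood for a single
# covariate without ties (independent oracle for small datasets).
pl_oracle <- function(time, event, x, interval = c(-5, 5)) {
  stopifnot(!anyDuplicated(time[event == 1]))
  logpl <- function(b) {
    s <- 0
    for (i in which(event == 1)) {
      at_risk <- time >= time[i]
      s <- s + b * x[i] - log(sum(exp(b * x[at_risk])))
    }
    s
  }
  stats::optimize(logpl, interval, maximum = TRUE, tol = 1e-9)$maximum
}

# Three-subject toy dataset whose partial-likelihood score equation has
# the closed-form solution exp(2 beta) = 1/2, i.e. beta = -log(2)/2.
toy3 <- function() data.frame(time = c(1, 2, 3), event = 1, x = c(1, 0, 1))

# Standard "strong effects" generator configuration: two effect-bearing
# variables (one continuous, one binary) in each scoreable domain, a null
# three-level categorical everywhere, and null early-life/environment
# domains.
strong_log_hr <- function() {
  c(ses_cont1 = 0.35, ses_bin2 = 0.35,
    med_cont1 = 0.5,  med_bin2 = 0.4,
    psy_cont1 = 0.45, psy_bin2 = 0.35,
    phy_cont1 = -0.5, phy_bin2 = 0.45,
    lif_cont1 = 0.4,  lif_bin2 = -0.35)
}

strong_cfg <- function(n = 6000, seed = 42, baseline_hazard = 0.02, ...) {
  cohort_config(n = n, baseline_hazard = baseline_hazard,
                true_log_hr = strong_log_hr(), seed = seed, ...)
}

# Cache heavyweight fixtures across test files within one run.
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Moderately sized simulated cohort taken through generation, raw-code
# injection and preprocessing; reused by the scan/score/paf unit tests.
strong_pipeline_fixture <- function() {
  cached("strong_pipeline", {
    sim <- generate_cohort(strong_cfg())
    raw <- inject_raw_codes(sim$cohort, sim$catalog,
                            special_code_rate = 0.02, missing_rate = 0.03,
                            seed = 77)
    pp <- preprocess_cohort(raw, sim$catalog)
    scan <- collinearity_filter(run_scan(pp$cohort, pp$catalog), pp$cohort)
    list(sim = sim, pp = pp, scan = scan)
  })
}

strong_scores_fixture <- function() {
  cached("strong_scores", {
    fx <- strong_pipeline_fixture()
    oriented <- orient_factors(fx$scan, fx$pp$cohort, fx$pp$catalog)
    scores <- suppressWarnings(
      build_domain_scores(oriented, fx$pp$cohort))
    c(fx, list(oriented = oriented, scores = scores))
  })
}

# Piecewise-exponential event times whose hazard ratio for x flips sign at
# t0 — a controlled proportional-hazards violation.
gen_ph_violation <- function(n, b1 = 0.8, b2 = -0.8, t0 = 4, tau = 12,
                             base = 0.08, seed = 1) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  h1 <- base * exp(b1 * x)
  h2 <- base * exp(b2 * x)
  t_a <- rexp(n) / h1
  t <- ifelse(t_a <= t0, t_a, t0 + rexp(n) / h2)
  data.frame(time = pmin(t, tau), event = as.integer(t <= tau), x = x)
}

# Simple proportional-hazards generator (no ties in expectation).
gen_ph_simple <- function(n, beta = 0.3, base = 0.05, tau = 12, seed = 1) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n) / (base * exp(beta * x))
  data.frame(time = pmin(t, tau), event = as.integer(t <= tau), x = x)
}
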