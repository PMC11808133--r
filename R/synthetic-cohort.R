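#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the generator into one validated object. The
#' defaults emulate the structure of a UK-Biobank-style baseline cohort:
#' seven exposure domains holding a mix of continuous, binary and
#' three-level categorical variables, within-domain equicorrelation, a
#' polygenic liability feeding the disease hazard, exponential
#' proportional-hazards event times with administrative censoring at the
#' end of follow-up, and sparse events (a baseline hazard of 6e-4 per
#' person-year gives roughly 0.7% cumulative incidence over 12 years, the
#' order observed for Parkinson's disease in middle-aged cohorts).
#'
#' @param n Number of participants (>= 2).
#' @param vars_per_domain Named integer vector: variables per domain. Names
#'   must be a subset of [exposure_domains()].
#' @param type_cycle Variable types assigned cyclically within each domain;
#'   any combination of `"continuous"`, `"binary"`, `"categorical3"`.
#' @param true_log_hr Named numeric vector of true log hazard ratios, per
#'   standard deviation for continuous variables and per category step for
#'   binary/categorical ones. Variables not named have no effect.
#' @param baseline_hazard Baseline event rate (events/person-year) at the
#'   covariate reference.
#' @param followup Administrative censoring horizon in years.
#' @param censor_rate Target fraction lost to random censoring over the
#'   follow-up window in the absence of events; implemented as an
#'   exponential censoring time with rate `-log(1 - censor_rate)/followup`.
#' @param missing_rate Fraction of variable cells blanked by
#'   [inject_raw_codes()].
#' @param special_code_rate Fraction of variable cells replaced with raw
#'   special codes (-1/-3, or -10 for count-coded variables) by
#'   [inject_raw_codes()].
#' @param rho Within-domain equicorrelation of the latent exposure scale.
#' @param bin_prevalence Prevalence of the "1" level of binary variables.
#' @param n_snps,maf_range,snp_effect_sd Genotype panel: number of SNPs,
#'   minor-allele-frequency range, and SD of per-SNP weights.
#' @param prs_log_hr Log hazard ratio per SD of the standardized polygenic
#'   score.
#' @param age_log_hr,sex_log_hr Log hazard ratios for age (per year,
#'   centred at 55) and male sex.
#' @param n_centers Number of assessment centers (no true effect).
#' @param seed Master seed; all randomness is a pure function of
#'   `(config, seed)` via [child_seed()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n = 10000,
                          vars_per_domain = stats::setNames(rep(3L, 7), exposure_domains()),
                          type_cycle = c("continuous", "binary", "categorical3"),
                          true_log_hr = NULL,
                          baseline_hazard = 6e-4,
                          followup = 12,
                          censor_rate = 0.05,
                          missing_rate = 0.03,
                          special_code_rate = 0.02,
                          rho = 0.2,
                          bin_prevalence = 0.3,
                          n_snps = 100L,
                          maf_range = c(0.05, 0.5),
                          snp_effect_sd = 0.1,
                          prs_log_hr = 0.25,
                          age_log_hr = 0.03,
                          sex_log_hr = 0.3,
                          n_centers = 5L,
                          seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 2)
    stop("invalid config: 'n' must be a single number >= 2")
  if (is.null(names(vars_per_domain)) ||
      !all(names(vars_per_domain) %in% exposure_domains()))
    stop("invalid config: names of 'vars_per_domain' must be exposure domains")
  if (any(vars_per_domain < 0)) stop("invalid config: negative variable count")
  if (!all(type_cycle %in% c("continuous", "binary", "categorical3")))
    stop("invalid config: unknown variable type in 'type_cycle'")
  for (nm in c("censor_rate", "missing_rate", "special_code_rate"))
    .assert_fraction(get(nm), nm)
  if (rho < 0 || rho >= 1) stop("invalid config: 'rho' must be in [0, 1)")
  if (bin_prevalence <= 0 || bin_prevalence >= 1)
    stop("invalid config: 'bin_prevalence' must be in (0, 1)")
  if (baseline_hazard <= 0) stop("invalid config: 'baseline_hazard' must be > 0")
  if (followup <= 0) stop("invalid config: 'followup' must be > 0")
  if (n_snps < 1) stop("invalid config: 'n_snps' must be >= 1")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("invalid config: 'maf_range' must lie within (0, 0.5]")
  cfg <- list(n = as.integer(n), vars_per_domain = vars_per_domain,
              type_cycle = type_cycle, true_log_hr = true_log_hr,
              baseline_hazard = baseline_hazard, followup = followup,
              censor_rate = censor_rate, missing_rate = missing_rate,
              special_code_rate = special_code_rate, rho = rho,
              bin_prevalence = bin_prevalence, n_snps = as.integer(n_snps),
              maf_range = maf_range, snp_effect_sd = snp_effect_sd,
              prs_log_hr = prs_log_hr, age_log_hr = age_log_hr,
              sex_log_hr = sex_log_hr, n_centers = as.integer(n_centers),
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

# Variable catalog implied by a config: names, domains, types.
.build_catalog <- function(config) {
  out <- list()
  for (dom in names(config$vars_per_domain)) {
    nv <- config$vars_per_domain[[dom]]
    if (nv == 0) next
    types <- rep_len(config$type_cycle, nv)
    code <- .domain_codes[[dom]]
    short <- c(continuous = "cont", binary = "bin", categorical3 = "cat")
    vars <- paste0(code, "_", short[types], seq_len(nv))
    first_cont <- which(types == "continuous")[1]
    out[[dom]] <- data.frame(
      variable = vars, domain = dom,
      type = sub("categorical3", "categorical", types),
      modifiable = TRUE,
      count_coded = seq_len(nv) == ifelse(is.na(first_cont), 0L, first_cont),
      n_instances = 1L,
      stringsAsFactors = FALSE)
  }
  cat <- do.call(rbind, out)
  rownames(cat) <- NULL
  cat
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws baseline exposures across the seven domains (equicorrelated within
#' domain on a latent Gaussian scale), adjuster covariates (age, sex,
#' assessment center), a genotype panel with a polygenic score, blood-assay
#' analogues (lymphocyte percentage, neutrophil percentage, total
#' bilirubin) partly driven by disease status, and exponential
#' proportional-hazards event times with administrative plus random
#' censoring. The linear predictor is
#' `sum(true_log_hr * X) + prs_log_hr * PRS + age/sex terms`.
#'
#' The returned `truth` record carries everything needed to test recovery:
#' the full true log-hazard-ratio vector, the standardized polygenic score,
#' the per-participant linear predictor and hazard, and — for every
#' scoreable domain containing at least one non-null variable — the
#' generative population-attributable fraction implied by the generator's
#' own tertile contrast (see Details).
#'
#' @details The generative PAF is computed analytically from the true
#' parameters, independently of the estimation pipeline: oriented binary
#' risk indicators are formed from the true effect signs (median split for
#' continuous/categorical variables, complementation for protective binary
#' ones), combined into a true weighted score with analytic indicator
#' weights, cut into tertiles, and contrasted under the conservative
#' (unfavorable vs rest) and optimistic (unfavorable+moderate vs favorable)
#' exposure definitions. The true hazard ratio of each contrast is the
#' large-n limit of the Cox coefficient — the root of the expected
#' partial-likelihood score under the true individual hazards and the
#' configured censoring — so the recorded PAF is exactly the quantity the
#' estimation pipeline targets as n grows.
#'
#' @param config A [cohort_config()] object.
#' @return A list of class `synthetic_cohort` with elements `cohort`
#'   (data.frame: id, time, event, age, sex, center, variables, assays),
#'   `catalog` (variable metadata), `genotypes`, `snp_weights`, and `truth`.
#' @examples
#' sim <- generate_cohort(cohort_config(n = 500, seed = 7))
#' str(sim$cohort[1:6])
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  n <- config$n
  catalog <- .build_catalog(config)
  if (is.null(catalog)) stop("invalid config: no variables requested")
  blhr <- stats::setNames(rep(0, nrow(catalog)), catalog$variable)
  if (!is.null(config$true_log_hr)) {
    unknown <- setdiff(names(config$true_log_hr), catalog$variable)
    if (length(unknown))
      stop("invalid config: true_log_hr names not in catalog: ",
           paste(unknown, collapse = ", "))
    blhr[names(config$true_log_hr)] <- config$true_log_hr
  }

  set.seed(child_seed(config$seed, "covariates"))
  age <- runif(n, 40, 69)
  sex <- rbinom(n, 1, 0.47)          # 1 = male; cohort ~53% female
  center <- factor(paste0("c", sample.int(config$n_centers, n, replace = TRUE)))

  X <- matrix(0, n, nrow(catalog), dimnames = list(NULL, catalog$variable))
  for (dom in unique(catalog$domain)) {
    vars <- catalog$variable[catalog$domain == dom]
    common <- rnorm(n)
    for (v in vars) {
      z <- sqrt(config$rho) * common + sqrt(1 - config$rho) * rnorm(n)
      ty <- catalog$type[catalog$variable == v]
      X[, v] <- switch(ty,
        continuous  = z,
        binary      = as.integer(z > qnorm(1 - config$bin_prevalence)),
        categorical = as.integer(z > qnorm(0.4)) + as.integer(z > qnorm(0.8)))
    }
  }

  geno <- generate_genotypes(n, config$n_snps, maf_range = config$maf_range,
                             effect_sd = config$snp_effect_sd,
                             seed = child_seed(config$seed, "genotypes"))
  prs <- compute_prs(geno$dosages, geno$weights)$prs

  lp_env <- as.vector(X %*% blhr)
  lp <- lp_env + config$prs_log_hr * prs +
    config$age_log_hr * (age - 55) + config$sex_log_hr * sex
  hazard <- config$baseline_hazard * exp(lp)

  set.seed(child_seed(config$seed, "events"))
  t_event <- rexp(n) / hazard
  if (config$censor_rate > 0) {
    rc <- -log(1 - config$censor_rate) / config$followup
    t_cens <- pmin(rexp(n, rc), config$followup)
  } else t_cens <- rep(config$followup, n)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  set.seed(child_seed(config$seed, "assays"))
  assays <- data.frame(
    lymphocyte_pct  = 30 - 1.5 * event - 0.30 * lp_env + rnorm(n, 0, 5),
    neutrophil_pct  = 55 + 1.5 * event + 0.30 * lp_env + rnorm(n, 0, 5),
    total_bilirubin =  9 + 0.8 * event + 0.15 * lp_env + rnorm(n, 0, 3))

  cohort <- data.frame(id = seq_len(n), time = time, event = event,
                       age = age, sex = sex, center = center,
                       as.data.frame(X), assays, check.names = FALSE)

  truth <- list(true_log_hr = blhr, prs = prs, lp = lp, hazard = hazard,
                generative_paf = .generative_paf(X, catalog, blhr, hazard,
                                                 config$followup,
                                                 config$censor_rate))
  out <- list(cohort = cohort, catalog = catalog,
              genotypes = geno$dosages, snp_weights = geno$weights,
              truth = truth, config = config)
  class(out) <- "synthetic_cohort"
  out
}

# Analytic indicator weight for a median-split of a standard-normal
# exposure with per-SD log hazard ratio b: the log ratio of mean relative
# hazards above vs below the median is log(pnorm(|b|)/pnorm(-|b|)).
.median_split_weight <- function(b) log(pnorm(abs(b)) / pnorm(-abs(b)))

# Large-n limit of the Cox coefficient for binary contrasts under the true
# individual hazards: the root of the expected partial-likelihood score,
#   U(beta) = int_0^tau [ B1(t) - e^b A1(t) / (e^b A1(t) + A0(t)) * B(t) ] dt
# with A_g(t) the expected number at risk and B_g(t) the event intensity
# of arm g (exponential event times, administrative censoring at tau,
# independent exponential random censoring at rate rc). All contrasts are
# evaluated on one time grid so the per-subject survival curves are
# computed once.
.cox_estimand_hr <- function(hazard, contrasts, tau, rc = 0, ngrid = 400) {
  tg <- seq(tau / ngrid, tau, length.out = ngrid)
  M <- vapply(contrasts, as.numeric, numeric(length(hazard)))
  A1 <- B1 <- matrix(0, ngrid, ncol(M))
  Atot <- Btot <- numeric(ngrid)
  for (k in seq_len(ngrid)) {
    s <- exp(-(hazard + rc) * tg[k])
    hs <- hazard * s
    A1[k, ] <- as.vector(crossprod(s, M))
    B1[k, ] <- as.vector(crossprod(hs, M))
    Atot[k] <- sum(s)
    Btot[k] <- sum(hs)
  }
  vapply(seq_len(ncol(M)), function(j) {
    score <- function(b) {
      eb <- exp(b)
      sum(B1[, j] - eb * A1[, j] / (eb * A1[, j] + (Atot - A1[, j])) * Btot)
    }
    exp(stats::uniroot(score, c(-5, 5), tol = 1e-10)$root)
  }, numeric(1))
}

.generative_paf <- function(X, catalog, blhr, hazard, followup,
                            censor_rate = 0) {
  contrasts <- list()
  meta <- list()
  for (dom in intersect(scoreable_domains(), unique(catalog$domain))) {
    vars <- catalog$variable[catalog$domain == dom]
    vars <- vars[blhr[vars] != 0]
    if (!length(vars)) next
    Xo <- matrix(0, nrow(X), length(vars), dimnames = list(NULL, vars))
    w <- numeric(length(vars))
    for (i in seq_along(vars)) {
      v <- vars[i]; b <- blhr[[v]]
      ty <- catalog$type[catalog$variable == v]
      if (ty == "binary") {
        Xo[, i] <- if (b >= 0) X[, v] else 1 - X[, v]
        w[i] <- abs(b)
      } else {
        med <- stats::median(X[, v])
        Xo[, i] <- if (b >= 0) as.integer(X[, v] > med) else as.integer(X[, v] < med)
        w[i] <- if (ty == "continuous") .median_split_weight(b) else abs(b)
      }
    }
    s <- as.vector(Xo %*% w) / sum(w)
    tert <- .tertile_cut(s, c("favorable", "moderate", "unfavorable"))
    for (model in 1:2) {
      exposed <- if (model == 1) tert == "unfavorable" else tert != "favorable"
      if (!any(exposed) || all(exposed)) next
      contrasts[[length(contrasts) + 1L]] <- exposed
      meta[[length(meta) + 1L]] <- list(domain = dom, model = model,
                                        p_pop = mean(exposed))
    }
  }
  if (!length(contrasts)) return(NULL)
  rc <- if (censor_rate > 0) -log(1 - censor_rate) / followup else 0
  hrs <- .cox_estimand_hr(hazard, contrasts, followup, rc = rc)
  out <- do.call(rbind, lapply(seq_along(meta), function(i) data.frame(
    domain = meta[[i]]$domain, model = meta[[i]]$model,
    p_pop = meta[[i]]$p_pop, hr = hrs[i],
    paf = 100 * levin_paf(meta[[i]]$p_pop, hrs[i]),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Generate a genotype dosage matrix with per-SNP weights
#'
#' Independent SNPs with allele dosages drawn `Binomial(2, maf)` and effect
#' weights drawn `Normal(0, effect_sd)`.
#'
#' @param n Number of participants.
#' @param m Number of SNPs (>= 1).
#' @param maf_range Range of minor allele frequencies, within (0, 0.5].
#' @param effect_sd SD of the per-SNP weights.
#' @param seed Seed.
#' @return List with `dosages` (n x m integer matrix, values 0/1/2),
#'   `weights`, and `maf`.
#' @export
generate_genotypes <- function(n, m, maf_range = c(0.05, 0.5),
                               effect_sd = 0.1, seed = 1L) {
  if (m < 1) stop("invalid config: 'm' must be >= 1")
  if (n < 1) stop("invalid config: 'n' must be >= 1")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("invalid config: 'maf_range' must lie within (0, 0.5]")
  set.seed(seed)
  maf <- runif(m, maf_range[1], maf_range[2])
  dosages <- vapply(maf, function(p) rbinom(n, 2L, p), integer(n))
  if (n == 1L) dosages <- matrix(dosages, nrow = 1L)
  colnames(dosages) <- paste0("rs", seq_len(m))
  weights <- stats::setNames(rnorm(m, 0, effect_sd), colnames(dosages))
  list(dosages = dosages, weights = weights, maf = maf)
}

#' Generate a two-sample GWAS summary-statistic table
#'
#' Simulates per-SNP exposure and outcome associations for testing the MR
#' estimators: `beta_outcome = true_effect * beta_exposure + pleiotropy +
#' noise_scale * N(0, se_outcome)`. With `pleiotropy = 0` the IVW estimate
#' is consistent for `true_effect`; with a constant nonzero `pleiotropy`
#' the MR-Egger intercept targets that constant. Exposure betas are drawn
#' strong (|z| between 8 and 15) so they pass genome-wide instrument
#' selection unless `weak_fraction` of them is attenuated below the
#' relaxed threshold.
#'
#' @param true_effect Causal effect of exposure on outcome.
#' @param n_snps Number of instruments (>= 2).
#' @param pleiotropy Constant direct (pleiotropic) effect added to every
#'   SNP's outcome association.
#' @param noise_scale Multiplier on the outcome-side sampling noise; 0
#'   gives noiseless summary statistics.
#' @param weak_fraction Fraction of SNPs rescaled to be weak instruments
#'   (exposure p between the two selection thresholds).
#' @param seed Seed.
#' @return data.frame with columns `snp`, `beta_exposure`, `se_exposure`,
#'   `p_exposure`, `beta_outcome`, `se_outcome`.
#' @export
generate_mr_summary <- function(true_effect, n_snps, pleiotropy = 0,
                                noise_scale = 1, weak_fraction = 0,
                                seed = 1L) {
  if (n_snps < 2) stop("invalid config: 'n_snps' must be >= 2")
  .assert_fraction(weak_fraction, "weak_fraction")
  set.seed(seed)
  # effect alleles oriented to the exposure-increasing allele, the
  # convention MR-Egger's intercept interpretation relies on
  beta_exp <- runif(n_snps, 0.05, 0.3)
  z <- runif(n_snps, 8, 15)
  n_weak <- floor(weak_fraction * n_snps)
  if (n_weak > 0) z[seq_len(n_weak)] <- runif(n_weak, 4.7, 5.3)  # p ~ 1e-6..1e-7
  se_exp <- abs(beta_exp) / z
  p_exp <- 2 * pnorm(-abs(beta_exp) / se_exp)
  se_out <- runif(n_snps, 0.01, 0.05)
  beta_out <- true_effect * beta_exp + pleiotropy +
    noise_scale * rnorm(n_snps, 0, se_out)
  data.frame(snp = paste0("rs", seq_len(n_snps)),
             beta_exposure = beta_exp, se_exposure = se_exp,
             p_exposure = p_exp, beta_outcome = beta_out,
             se_outcome = se_out, stringsAsFactors = FALSE)
}

#' Inject raw special codes and missingness into a clean cohort
#'
#' Emulates raw biobank exports: a fraction of variable cells is replaced
#' by special negative codes — -1 ("do not know") and -3 ("prefer not to
#' answer") anywhere, -10 ("less than one") in count-coded variables — and
#' a further fraction is blanked outright. Altered cells are recorded in a
#' registry attached as attribute `"raw_code_registry"`.
#'
#' @param cohort Cohort data.frame from [generate_cohort()].
#' @param catalog Matching variable catalog.
#' @param special_code_rate,missing_rate Cell-level rates in `[0, 1]`.
#' @param seed Seed.
#' @return The cohort with codes injected; attribute `raw_code_registry`
#'   is a data.frame (row, variable, code, original).
#' @export
inject_raw_codes <- function(cohort, catalog, special_code_rate = 0.02,
                             missing_rate = 0.03, seed = 1L) {
  .assert_fraction(special_code_rate, "special_code_rate")
  .assert_fraction(missing_rate, "missing_rate")
  vars <- .variable_columns(cohort, catalog)
  set.seed(seed)
  reg <- list()
  for (v in vars) {
    base <- sub("\\.\\d+$", "", v)
    count_var <- isTRUE(catalog$count_coded[match(base, catalog$variable)])
    n <- nrow(cohort)
    u <- runif(n)
    hit_code <- u < special_code_rate
    hit_na <- !hit_code & u < special_code_rate + missing_rate
    if (any(hit_code)) {
      codes <- if (count_var) rep(-10, sum(hit_code)) else
        sample(c(-1, -3), sum(hit_code), replace = TRUE)
      reg[[length(reg) + 1L]] <- data.frame(
        row = which(hit_code), variable = v, code = codes,
        original = cohort[[v]][hit_code], stringsAsFactors = FALSE)
      cohort[[v]][hit_code] <- codes
    }
    if (any(hit_na)) cohort[[v]][hit_na] <- NA
  }
  registry <- if (length(reg)) do.call(rbind, reg) else
    data.frame(row = integer(), variable = character(),
               code = numeric(), original = numeric())
  attr(cohort, "raw_code_registry") <- registry
  cohort
}

#' Expand variables into multi-instance measurement columns
#'
#' Replaces each designated variable `v` with instance columns `v.0`,
#' `v.1`, ... holding the underlying value plus independent measurement
#' noise, emulating repeat assessments. [average_instances()] reverses the
#' expansion.
#'
#' @param cohort Cohort data.frame.
#' @param vars Variables to expand.
#' @param n_instances Instances per variable (>= 2).
#' @param noise_sd SD of the per-instance measurement noise.
#' @param seed Seed.
#' @return The cohort with instance columns; attribute `instance_map` maps
#'   base variable to its instance columns.
#' @export
expand_instances <- function(cohort, vars, n_instances = 2L, noise_sd = 0.1,
                             seed = 1L) {
  if (n_instances < 2) stop("'n_instances' must be >= 2")
  missing_vars <- setdiff(vars, names(cohort))
  if (length(missing_vars)) stop("variables not in cohort: ",
                                 paste(missing_vars, collapse = ", "))
  set.seed(seed)
  imap <- list()
  for (v in vars) {
    cols <- paste0(v, ".", seq_len(n_instances) - 1L)
    for (cl in cols) cohort[[cl]] <- cohort[[v]] + rnorm(nrow(cohort), 0, noise_sd)
    cohort[[v]] <- NULL
    imap[[v]] <- cols
  }
  attr(cohort, "instance_map") <- imap
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$cohort), "participants,",
      nrow(x$catalog), "variables in", length(unique(x$catalog$domain)),
      "domains;", sum(x$cohort$event), "events\n")
  if (!is.null(x$truth$generative_paf)) {
    cat("Generative PAFs (%):\n")
    print(x$truth$generative_paf, row.names = FALSE)
  }
  invisible(x)
}
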