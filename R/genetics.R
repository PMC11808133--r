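#' Compute a standardized polygenic risk score
#'
#' The raw score of participant j is `sum_i beta_i * G_ij` over SNP
#' weights beta and allele dosages G; the returned score is standardized
#' by the cohort mean and sample SD (n - 1 denominator), so it has mean 0
#' and SD 1 and is invariant to rescaling all weights by a positive
#' constant.
#'
#' @param genotypes n x m dosage matrix, values in `[0, 2]`.
#' @param weights Numeric vector of m per-SNP weights.
#' @return Object of class `prs_model`: list with `raw`, `mean`, `sd`,
#'   `prs` (standardized), and `weights`.
#' @examples
#' compute_prs(matrix(c(0, 1, 2)), 1)$prs
#' @export
compute_prs <- function(genotypes, weights) {
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) < 2) stop("need at least 2 participants")
  if (ncol(genotypes) < 1) stop("need at least 1 SNP")
  if (length(weights) != ncol(genotypes))
    stop("length(weights) must equal ncol(genotypes)")
  if (any(genotypes < 0 | genotypes > 2))
    stop("dosages must lie in [0, 2]")
  raw <- as.vector(genotypes %*% weights)
  s <- stats::sd(raw)
  if (!is.finite(s) || s < 1e-12)
    stop("degenerate score: all raw polygenic scores identical")
  m <- mean(raw)
  structure(list(raw = raw, mean = m, sd = s, prs = (raw - m) / s,
                 weights = weights),
            class = "prs_model")
}

#' Tertile groups of a polygenic score
#'
#' Cuts at the 1/3 and 2/3 sample quantiles; ties at a cut go to the lower
#' group.
#'
#' @param prs A `prs_model` or numeric vector.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
prs_tertiles <- function(prs) {
  x <- if (inherits(prs, "prs_model")) prs$prs else prs
  .tertile_cut(x, c("low", "medium", "high"))
}

#' Select genetic instruments from GWAS summary statistics
#'
#' Keeps SNPs with exposure p-value below the genome-wide threshold
#' (5e-8); when fewer than `min_snps` survive, the threshold is relaxed to
#' 5e-6 and the relaxation recorded. Fewer than 2 instruments even at the
#' relaxed threshold is an error.
#'
#' @param summary data.frame with columns `beta_exposure`, `se_exposure`,
#'   `p_exposure`, `beta_outcome`, `se_outcome`.
#' @param p1 Primary instrument threshold.
#' @param p2 Relaxed threshold.
#' @param min_snps Minimum instrument count before relaxing.
#' @return The selected rows, with attributes `threshold_used` and
#'   `relaxed`.
#' @export
select_instruments <- function(summary, p1 = 5e-8, p2 = 5e-6, min_snps = 3) {
  req <- c("beta_exposure", "se_exposure", "p_exposure",
           "beta_outcome", "se_outcome")
  missing_cols <- setdiff(req, names(summary))
  if (length(missing_cols))
    stop("summary table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!nrow(summary)) stop("empty summary table")
  keep <- summary$p_exposure < p1
  relaxed <- FALSE
  if (sum(keep) < min_snps) {
    keep <- summary$p_exposure < p2
    relaxed <- TRUE
  }
  if (sum(keep) < 2)
    stop("insufficient instruments: fewer than 2 SNPs pass p < ",
         format(p2))
  structure(summary[keep, , drop = FALSE],
            threshold_used = if (relaxed) p2 else p1, relaxed = relaxed)
}

# Per-SNP Wald ratio estimates with first-order delta-method SEs.
.mr_ratios <- function(d) {
  if (any(d$beta_exposure == 0))
    stop("beta_exposure of 0 gives an undefined ratio estimate")
  if (any(d$se_outcome <= 0) || any(d$se_exposure <= 0))
    stop("standard errors must be positive")
  list(b = d$beta_outcome / d$beta_exposure,
       se = d$se_outcome / abs(d$beta_exposure))
}

.mr_component <- function(method, est, se, p, n, extra = NULL) {
  c(list(method = method, estimate = unname(est), se = unname(se),
         ci_lower = unname(est - 1.96 * se), ci_upper = unname(est + 1.96 * se),
         p = unname(p), n_snp = n), extra)
}

#' Inverse-variance weighted MR estimate
#'
#' Fixed-effect meta-analysis of the per-SNP Wald ratios: with weights
#' `w_k = 1/se_k^2`, the estimate is `sum(w b)/sum(w)` and its SE
#' `1/sqrt(sum(w))`.
#'
#' @param instruments Selected summary-statistic rows (>= 2).
#' @return List (method, estimate, se, ci, p, n_snp).
#' @export
mr_ivw <- function(instruments) {
  if (nrow(instruments) < 2) stop("IVW requires at least 2 instruments")
  r <- .mr_ratios(instruments)
  w <- 1 / r$se^2
  est <- sum(w * r$b) / sum(w)
  se <- 1 / sqrt(sum(w))
  .mr_component("ivw", est, se, 2 * pnorm(-abs(est / se)), nrow(instruments))
}

#' Cochran's Q heterogeneity test for MR instruments
#'
#' `Q = sum w_k (b_k - b_ivw)^2` on K - 1 degrees of freedom against the
#' chi-square upper tail.
#'
#' @param instruments Selected summary-statistic rows (>= 2).
#' @param estimate Pooled estimate; defaults to the IVW estimate.
#' @return List (Q, df, p).
#' @export
mr_cochran_q <- function(instruments, estimate = NULL) {
  if (nrow(instruments) < 2) stop("Cochran's Q requires at least 2 instruments")
  r <- .mr_ratios(instruments)
  w <- 1 / r$se^2
  estimate <- estimate %||% (sum(w * r$b) / sum(w))
  Q <- sum(w * (r$b - estimate)^2)
  df <- nrow(instruments) - 1L
  list(Q = Q, df = df, p = pchisq(Q, df, lower.tail = FALSE))
}

# Weighted median of values b with weights w: the weighted 50th
# percentile, linearly interpolated over the centred cumulative weights
# (sum of weights below + half own weight).
.weighted_median <- function(b, w) {
  ord <- order(b)
  b <- b[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w) - w / 2
  if (0.5 <= cw[1]) return(b[1])
  if (0.5 >= cw[length(cw)]) return(b[length(b)])
  j <- max(which(cw < 0.5))
  b[j] + (b[j + 1] - b[j]) * (0.5 - cw[j]) / (cw[j + 1] - cw[j])
}

#' Weighted-median MR estimate
#'
#' The inverse-variance weighted 50th percentile of the per-SNP ratio
#' estimates — consistent when at least half the weight comes from valid
#' instruments. The SE comes from a parametric bootstrap (resampling
#' exposure and outcome betas from their sampling distributions) with a
#' fixed seed.
#'
#' @param instruments Selected summary-statistic rows (>= 3).
#' @param n_boot Bootstrap draws for the SE.
#' @param seed Bootstrap seed.
#' @return List (method, estimate, se, ci, p, n_snp).
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000, seed = 1L) {
  if (nrow(instruments) < 3)
    stop("weighted median requires at least 3 instruments")
  r <- .mr_ratios(instruments)
  w <- 1 / r$se^2
  est <- .weighted_median(r$b, w)
  set.seed(seed)
  draws <- vapply(seq_len(n_boot), function(i) {
    be <- rnorm(nrow(instruments), instruments$beta_exposure,
                instruments$se_exposure)
    bo <- rnorm(nrow(instruments), instruments$beta_outcome,
                instruments$se_outcome)
    ok <- be != 0
    .weighted_median((bo / be)[ok], (be^2 / instruments$se_outcome^2)[ok])
  }, numeric(1))
  se <- stats::sd(draws)
  .mr_component("weighted_median", est, se, 2 * pnorm(-abs(est / se)),
                nrow(instruments))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with an
#' unconstrained intercept (weights `1/se_outcome^2`), after orienting all
#' exposure betas positive. The slope is the causal estimate; a nonzero
#' intercept indicates directional pleiotropy. Inference uses the t
#' distribution on K - 2 degrees of freedom.
#'
#' @param instruments Selected summary-statistic rows (>= 3).
#' @return List with slope fields (method, estimate, se, ci, p, n_snp) and
#'   `intercept`, `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(instruments) {
  if (nrow(instruments) < 3) stop("MR-Egger requires at least 3 instruments")
  flip <- sign(instruments$beta_exposure)
  flip[flip == 0] <- 1
  bx <- instruments$beta_exposure * flip
  by <- instruments$beta_outcome * flip
  fit <- stats::lm(by ~ bx, weights = 1 / instruments$se_outcome^2)
  cf <- summary(fit)$coefficients
  df <- nrow(instruments) - 2L
  .mr_component("mr_egger", cf["bx", 1], cf["bx", 2],
                2 * pt(-abs(cf["bx", 1] / cf["bx", 2]), df),
                nrow(instruments),
                extra = list(intercept = cf["(Intercept)", 1],
                             intercept_se = cf["(Intercept)", 2],
                             intercept_p = 2 * pt(-abs(cf["(Intercept)", 1] /
                                                         cf["(Intercept)", 2]), df)))
}

#' Run the full two-sample MR analysis
#'
#' Instrument selection with the relaxed-threshold fallback, then IVW,
#' weighted median (when >= 3 instruments), MR-Egger (when >= 3), and
#' Cochran's Q heterogeneity against the IVW estimate.
#'
#' @inheritParams select_instruments
#' @inheritParams mr_weighted_median
#' @return Object of class `mr_result`.
#' @export
run_mr <- function(summary, p1 = 5e-8, p2 = 5e-6, min_snps = 3,
                   n_boot = 1000, seed = 1L) {
  inst <- select_instruments(summary, p1 = p1, p2 = p2, min_snps = min_snps)
  ivw <- mr_ivw(inst)
  out <- list(
    ivw = ivw,
    weighted_median = if (nrow(inst) >= 3)
      mr_weighted_median(inst, n_boot = n_boot, seed = seed) else NULL,
    egger = if (nrow(inst) >= 3) mr_egger(inst) else NULL,
    cochran_q = mr_cochran_q(inst, ivw$estimate),
    n_snp = nrow(inst),
    threshold_used = attr(inst, "threshold_used"),
    relaxed = attr(inst, "relaxed"))
  class(out) <- "mr_result"
  out
}

#' @export
print.mr_result <- function(x, digits = 4, ...) {
  cat("Two-sample MR on", x$n_snp, "instruments (p <",
      format(x$threshold_used), if (x$relaxed) ", relaxed)\n" else ")\n")
  for (m in list(x$ivw, x$weighted_median, x$egger)) {
    if (is.null(m)) next
    cat(sprintf("  %-16s %8.4f (se %.4f, p %.3g)\n",
                m$method, m$estimate, m$se, m$p))
  }
  cat(sprintf("  Cochran Q %.3f on %d df (p %.3g)\n",
              x$cochran_q$Q, x$cochran_q$df, x$cochran_q$p))
  if (!is.null(x$egger))
    cat(sprintf("  Egger intercept %.4f (p %.3g)\n",
                x$egger$intercept, x$egger$intercept_p))
  invisible(x)
}
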