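#' Bonferroni-corrected significance threshold
#'
#' The exposure-wide threshold is the conventional level divided by the
#' number of variables tested; with 255 baseline variables at alpha = 0.05
#' this is 1.96e-4.
#'
#' @param alpha Family-wise level, in (0, 1).
#' @param n_variables Number of tests (>= 1).
#' @return `alpha / n_variables`.
#' @export
bonferroni_threshold <- function(alpha, n_variables) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)")
  if (!is.numeric(n_variables) || n_variables < 1)
    stop("'n_variables' must be >= 1")
  alpha / n_variables
}

#' Exposure-wide association scan
#'
#' Fits one adjusted Cox model per modifiable variable, tests each fit for
#' proportional hazards on its exposure term, refits violating exposures
#' with a time-interaction term (reported at the mean event time), and
#' flags significance at the Bonferroni threshold. Per-variable fitting
#' errors (constant columns, monotone likelihoods) are recorded and the
#' scan continues.
#'
#' @param cohort Preprocessed cohort (numeric, encoded variable columns).
#' @param catalog Variable catalog; modifiable variables present in the
#'   cohort define the scan set.
#' @param adjusters Adjustment covariates.
#' @param alpha Family-wise level before correction.
#' @param n_tests Number of tests used for the Bonferroni threshold;
#'   defaults to the number of scanned variables. Subgroup scans pass the
#'   full-sample count here so all strata share one threshold.
#' @param ph_alpha Level of the per-exposure Schoenfeld PH test.
#' @param ph_fallback Refit PH-violating exposures with a time
#'   interaction? (Disabling skips the refit but still records the flag.)
#' @param tint_max_cuts Episode-splitting resolution of the scan's
#'   time-interaction refits (an event-time quantile grid); coarser than
#'   the standalone [fit_cox_time_interaction()] default because a scan
#'   may refit hundreds of exposures.
#' @return data.frame of class `ewas_scan`, ordered by p (ties by name),
#'   with one row per variable (variable, domain, beta, se, hr, lo, hi, p,
#'   ph_p, ph_violation, fallback, error, significant) and attributes
#'   `threshold`, `n_variables`, `n_significant`, `n_adverse`,
#'   `n_protective`.
#' @export
run_scan <- function(cohort, catalog, adjusters = c("age", "sex", "center"),
                     alpha = 0.05, n_tests = NULL, ph_alpha = 0.05,
                     ph_fallback = TRUE, tint_max_cuts = 20) {
  vars <- .variable_columns(cohort, catalog)
  vars <- vars[catalog$modifiable[match(vars, catalog$variable)]]
  if (!length(vars)) stop("no modifiable variables to scan")
  n_tests <- n_tests %||% length(vars)
  threshold <- bonferroni_threshold(alpha, n_tests)

  proto <- .scan_prototype(cohort, adjusters)
  tint_ctx <- NULL   # built lazily on the first PH violation
  rows <- vector("list", length(vars))
  for (i in seq_along(vars)) {
    v <- vars[i]
    dom <- catalog$domain[match(v, catalog$variable)]
    row <- data.frame(variable = v, domain = dom, beta = NA_real_,
                      se = NA_real_, hr = NA_real_, lo = NA_real_,
                      hi = NA_real_, p = NA_real_, ph_p = NA_real_,
                      ph_violation = FALSE, fallback = FALSE,
                      error = NA_character_, stringsAsFactors = FALSE)
    res <- tryCatch({
      x <- cohort[[v]]
      if (length(unique(x)) < 2L) stop("constant covariate: ", v)
      fit <- .scan_refit(proto, x)
      zp <- survival::cox.zph(fit, transform = "km", global = FALSE)
      ph_p <- zp$table[".expo", "p"]
      if (is.finite(ph_p) && ph_p < ph_alpha && ph_fallback) {
        if (is.null(tint_ctx))
          tint_ctx <- .tint_context(cohort$time, cohort$event,
                                     proto$x[, -1L, drop = FALSE],
                                     max_cuts = tint_max_cuts)
        tr <- .tint_refit(tint_ctx, x)
        list(beta = tr$beta, se = tr$se, hr = tr$hr, lo = tr$lo,
             hi = tr$hi, p = tr$p, ph_p = ph_p, viol = TRUE, fb = TRUE)
      } else {
        b <- fit$coefficients[1L]
        se <- sqrt(fit$var[1L, 1L])
        list(beta = b, se = se, hr = exp(b), lo = exp(b - 1.96 * se),
             hi = exp(b + 1.96 * se), p = 2 * pnorm(-abs(b / se)),
             ph_p = ph_p, viol = is.finite(ph_p) && ph_p < ph_alpha,
             fb = FALSE)
      }
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      row$error <- res
    } else {
      row[c("beta", "se", "hr", "lo", "hi", "p", "ph_p")] <-
        res[c("beta", "se", "hr", "lo", "hi", "p", "ph_p")]
      row$ph_violation <- res$viol
      row$fallback <- res$fb
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p) & out$p < threshold
  out <- out[order(out$p, out$variable), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            threshold = threshold, n_variables = length(vars),
            n_significant = sum(out$significant),
            n_adverse = sum(out$significant & out$hr > 1, na.rm = TRUE),
            n_protective = sum(out$significant & out$hr < 1, na.rm = TRUE),
            class = c("ewas_scan", "data.frame"))
}

#' Drop collinear variables from the significant scan hits
#'
#' Among significant variables whose squared Pearson correlation exceeds
#' the threshold, the member with the larger scan p-value is removed,
#' iterating on the worst remaining pair until no pair exceeds the
#' threshold.
#'
#' @param scan An `ewas_scan`.
#' @param cohort The cohort the scan ran on.
#' @param r2_threshold Squared-correlation cutoff.
#' @return The scan with dropped variables marked `dropped_collinear` and
#'   de-flagged; attribute `dropped_collinear` lists them.
#' @export
collinearity_filter <- function(scan, cohort, r2_threshold = 0.9) {
  sig <- scan$variable[scan$significant]
  dropped <- character(0)
  if (length(sig) >= 2L) {
    r2 <- cor(as.matrix(cohort[sig]))^2
    diag(r2) <- 0
    while (max(r2) > r2_threshold) {
      idx <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
      pair <- rownames(r2)[idx]
      pv <- scan$p[match(pair, scan$variable)]
      drop <- pair[which.max(pv)]       # keep the smaller p-value
      dropped <- c(dropped, drop)
      keep <- setdiff(rownames(r2), drop)
      r2 <- r2[keep, keep, drop = FALSE]
      if (length(keep) < 2L) break
    }
  }
  scan$dropped_collinear <- scan$variable %in% dropped
  scan$significant <- scan$significant & !scan$dropped_collinear
  attr(scan, "dropped_collinear") <- dropped
  attr(scan, "n_significant") <- sum(scan$significant)
  attr(scan, "n_adverse") <- sum(scan$significant & scan$hr > 1, na.rm = TRUE)
  attr(scan, "n_protective") <- sum(scan$significant & scan$hr < 1, na.rm = TRUE)
  scan
}

#' Replicate the scan within subgroups
#'
#' Reruns the exposure-wide scan within each level of one or more
#' stratifying factors (e.g. age >= 65 vs < 65, sex, polygenic-score
#' tertile), keeping the full-sample Bonferroni threshold. Adjusters that
#' are constant within a stratum are dropped for that stratum; strata
#' without events are skipped with a warning, and strata with fewer events
#' than `min_events` are flagged.
#'
#' @param cohort,catalog,adjusters,alpha,ph_alpha,ph_fallback As
#'   [run_scan()].
#' @param strata Named list of stratifying factors (each of length
#'   `nrow(cohort)`), or a single factor.
#' @param min_events Minimum events per stratum before a low-power flag.
#' @return Object of class `subgroup_scan`: list with `scans` (nested by
#'   stratification and level) and `heatmap`, a long table (variable,
#'   stratification, stratum, hr, p, significant) suitable for a heatmap.
#' @export
subgroup_scan <- function(cohort, catalog, strata,
                          adjusters = c("age", "sex", "center"),
                          alpha = 0.05, min_events = 50, ph_alpha = 0.05,
                          ph_fallback = TRUE) {
  if (!is.list(strata)) strata <- list(stratum = strata)
  vars <- .variable_columns(cohort, catalog)
  vars <- vars[catalog$modifiable[match(vars, catalog$variable)]]
  n_tests <- length(vars)
  scans <- list()
  hm <- list()
  for (s in names(strata)) {
    fac <- as.factor(strata[[s]])
    if (length(fac) != nrow(cohort))
      stop("stratum factor '", s, "' does not match the cohort")
    for (lev in levels(fac)) {
      sub <- cohort[!is.na(fac) & fac == lev, , drop = FALSE]
      if (!nrow(sub) || sum(sub$event) == 0) {
        warning("stratum ", s, "=", lev, " has no events; skipped")
        next
      }
      adj <- adjusters[vapply(adjusters, function(a) {
        x <- sub[[a]]
        length(unique(x[!is.na(x)])) > 1L
      }, logical(1))]
      sc <- run_scan(sub, catalog, adjusters = adj, alpha = alpha,
                     n_tests = n_tests, ph_alpha = ph_alpha,
                     ph_fallback = ph_fallback)
      attr(sc, "low_events") <- sum(sub$event) < min_events
      scans[[s]][[lev]] <- sc
      hm[[length(hm) + 1L]] <- data.frame(
        variable = sc$variable, stratification = s, stratum = lev,
        hr = sc$hr, p = sc$p, significant = sc$significant,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(scans = scans,
                 heatmap = if (length(hm)) do.call(rbind, hm) else NULL),
            class = "subgroup_scan")
}

#' @export
print.ewas_scan <- function(x, n = 10, ...) {
  cat("Exposure-wide scan:", attr(x, "n_variables"), "variables, threshold",
      format(attr(x, "threshold"), digits = 3), "\n")
  cat("Significant:", attr(x, "n_significant"),
      sprintf("(%d adverse, %d protective)\n",
              attr(x, "n_adverse"), attr(x, "n_protective")))
  print(utils::head(as.data.frame(x), n), row.names = FALSE)
  invisible(x)
}

#' Manhattan-style plot of an exposure-wide scan
#'
#' @param x An `ewas_scan`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ewas_scan <- function(x, ...) {
  dom <- factor(x$domain, levels = exposure_domains())
  graphics::plot(jitter(as.integer(dom)), -log10(x$p), xaxt = "n",
                 xlab = "domain", ylab = "-log10(p)",
                 pch = ifelse(x$significant, 19, 1), ...)
  graphics::axis(1, at = seq_along(levels(dom)),
                 labels = abbreviate(levels(dom), 8), las = 2, cex.axis = 0.7)
  graphics::abline(h = -log10(attr(x, "threshold")), lty = 2)
  invisible(x)
}
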