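#' Difference-method mediation with bootstrap inference
#'
#' Decomposes the association of an exposure with a continuous outcome
#' into a direct and a mediated component by the difference method: the
#' total effect is the exposure coefficient in the outcome model without
#' the mediator, the direct effect is the same coefficient with the
#' mediator added, and the mediation (indirect) effect is their
#' difference — an identity that holds exactly in every bootstrap draw.
#' Confidence intervals are percentile bootstrap over participants; the
#' two-sided p-value for each effect is twice the smaller tail proportion
#' of draws on either side of zero.
#'
#' When the outcome is a binary disease indicator (the second mediation
#' model set), the same decomposition is applied on a linear probability
#' model, which keeps the difference identity exact.
#'
#' @param data data.frame holding all columns.
#' @param exposure,mediator,outcome Column names.
#' @param covariates Optional adjustment columns (factors allowed).
#' @param n_boot Bootstrap draws (a value below 100 warns).
#' @param seed Bootstrap seed.
#' @return Object of class `mediation_result`: total/direct/mediation
#'   estimates with 95% percentile CIs, the mediation p-value, `n_boot`
#'   and `seed`.
#' @export
mediate <- function(data, exposure, mediator, outcome, covariates = NULL,
                    n_boot = 1000, seed = 1L) {
  if (nrow(data) < 100) stop("mediation requires n >= 100")
  if (n_boot < 100) warning("n_boot < 100 gives unstable intervals")
  y <- data[[outcome]]
  cov_mm <- if (length(covariates))
    stats::model.matrix(stats::reformulate(covariates), data = data)
  else matrix(1, nrow(data), 1)
  Xt <- cbind(cov_mm, expo = data[[exposure]])
  Xd <- cbind(Xt, med = data[[mediator]])
  if (qr(Xd)$rank < ncol(Xd))
    stop("collinear exposure/mediator/covariates: decomposition undefined")
  ie <- ncol(Xt)                      # exposure column index
  point <- c(total = .lm.fit(Xt, y)$coefficients[ie],
             direct = .lm.fit(Xd, y)$coefficients[ie])
  point["mediation"] <- point["total"] - point["direct"]

  set.seed(seed)
  n <- nrow(data)
  draws <- matrix(NA_real_, n_boot, 3,
                  dimnames = list(NULL, c("total", "direct", "mediation")))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    tot <- .lm.fit(Xt[idx, , drop = FALSE], y[idx])$coefficients[ie]
    dir <- .lm.fit(Xd[idx, , drop = FALSE], y[idx])$coefficients[ie]
    draws[b, ] <- c(tot, dir, tot - dir)
  }
  ci <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  pval <- function(d) min(1, 2 * min((1 + sum(d <= 0)) / (length(d) + 1),
                                     (1 + sum(d >= 0)) / (length(d) + 1)))
  structure(list(exposure = exposure, mediator = mediator, outcome = outcome,
                 total = unname(point["total"]), total_ci = ci[, "total"],
                 direct = unname(point["direct"]), direct_ci = ci[, "direct"],
                 mediation = unname(point["mediation"]),
                 mediation_ci = ci[, "mediation"],
                 p = pval(draws[, "mediation"]),
                 n_boot = n_boot, seed = seed, draws = draws),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, digits = 3, ...) {
  fmt <- function(e, ci) sprintf("%.*f [%.*f, %.*f]", digits, e,
                                 digits, ci[1], digits, ci[2])
  cat(x$exposure, "->", x$mediator, "->", x$outcome, "\n")
  cat("  total    ", fmt(x$total, x$total_ci), "\n")
  cat("  direct   ", fmt(x$direct, x$direct_ci), "\n")
  cat("  mediation", fmt(x$mediation, x$mediation_ci),
      sprintf("(p = %.3g)\n", x$p))
  invisible(x)
}

#' Run both mediation model sets over domain scores and blood assays
#'
#' Set 1 treats disease as the intermediary: domain score -> disease ->
#' blood assay (continuous outcome). Set 2 examines assays as potential
#' mediators of the score-disease association: domain score -> assay ->
#' disease, decomposed on a linear probability model. Per-triple failures
#' are logged in the `error` column and the table completed.
#'
#' @param cohort Cohort with an `event` disease indicator and assay
#'   columns.
#' @param scores A `domain_score_set`.
#' @param assays Assay column names.
#' @param covariates Adjustment columns.
#' @param n_boot,seed Bootstrap controls.
#' @return data.frame of class `mediation_table`: one row per (set,
#'   exposure, mediator, outcome) with estimates, CIs and p.
#' @export
run_mediation_sets <- function(cohort, scores,
                               assays = c("lymphocyte_pct", "neutrophil_pct",
                                          "total_bilirubin"),
                               covariates = c("age", "sex", "center"),
                               n_boot = 1000, seed = 1L) {
  missing_cols <- setdiff(assays, names(cohort))
  if (length(missing_cols))
    stop("assay columns absent: ", paste(missing_cols, collapse = ", "))
  d <- cohort
  rows <- list()
  run1 <- function(set, expo, med, out) {
    res <- tryCatch(mediate(d, expo, med, out, covariates = covariates,
                            n_boot = n_boot, seed = seed),
                    error = function(e) conditionMessage(e))
    if (is.character(res))
      data.frame(set = set, exposure = expo, mediator = med, outcome = out,
                 total = NA_real_, total_lo = NA_real_, total_hi = NA_real_,
                 direct = NA_real_, direct_lo = NA_real_, direct_hi = NA_real_,
                 mediation = NA_real_, mediation_lo = NA_real_,
                 mediation_hi = NA_real_, p = NA_real_, error = res,
                 stringsAsFactors = FALSE)
    else
      data.frame(set = set, exposure = expo, mediator = med, outcome = out,
                 total = res$total, total_lo = res$total_ci[1],
                 total_hi = res$total_ci[2], direct = res$direct,
                 direct_lo = res$direct_ci[1], direct_hi = res$direct_ci[2],
                 mediation = res$mediation,
                 mediation_lo = res$mediation_ci[1],
                 mediation_hi = res$mediation_ci[2], p = res$p,
                 error = NA_character_, stringsAsFactors = FALSE)
  }
  for (s in scores) {
    cl <- paste0("score_", gsub("[^a-z]+", "_", s$domain))
    d[[cl]] <- s$score
    for (a in assays) {
      rows[[length(rows) + 1L]] <- run1(1L, cl, "event", a)
      rows[[length(rows) + 1L]] <- run1(2L, cl, a, "event")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mediation_table", "data.frame")
  out
}
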