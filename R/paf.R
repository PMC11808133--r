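#' Levin's population attributable fraction
#'
#' `PAF = P (HR - 1) / (P (HR - 1) + 1)`, the proportional reduction in
#' incidence expected if an exposure with population prevalence `P` and
#' hazard ratio `HR` were removed. Strictly increasing in both arguments
#' (for HR > 1) and zero at HR = 1.
#'
#' @param p_pop Exposure prevalence in `[0, 1]`.
#' @param hr Hazard ratio (> 0).
#' @return The attributable fraction (a plain fraction, not percent).
#' @examples
#' levin_paf(0.3, 1.5)   # 0.15 / 1.15
#' @export
levin_paf <- function(p_pop, hr) {
  if (any(p_pop < 0 | p_pop > 1)) stop("'p_pop' must lie in [0, 1]")
  if (any(hr <= 0)) stop("'hr' must be positive")
  x <- p_pop * (hr - 1)
  if (any(x <= -1)) stop("degenerate protective prevalence: P(HR - 1) <= -1")
  x / (x + 1)
}

#' Per-domain PAF from a tertile contrast
#'
#' Builds the binary exposure for one domain under the chosen
#' counterfactual — Model 1 (conservative): unfavorable vs
#' moderate-or-favorable; Model 2 (optimistic): unfavorable-or-moderate vs
#' favorable — estimates its adjusted hazard ratio by Cox regression, and
#' converts prevalence and HR to a PAF via [levin_paf()].
#'
#' @param cohort Cohort data.frame.
#' @param score A `domain_score` object.
#' @param model Counterfactual model, 1 or 2.
#' @param adjusters Adjustment covariates.
#' @param use `"weighted"` or `"unweighted"` tertile categories.
#' @return List of class `domain_paf`: domain, model, `p_pop`, `hr`,
#'   `paf` (fraction), and the underlying `cox_fit`.
#' @export
domain_paf <- function(cohort, score, model = 1,
                       adjusters = c("age", "sex", "center"),
                       use = c("weighted", "unweighted")) {
  use <- match.arg(use)
  if (!model %in% 1:2) stop("'model' must be 1 or 2")
  cat3 <- if (use == "weighted") score$category else score$unweighted_category
  exposed <- if (model == 1) cat3 == "unfavorable" else cat3 != "favorable"
  if (!any(exposed) || all(exposed))
    stop("degenerate exposure contrast in domain '", score$domain, "'")
  d <- cohort[c("time", "event", adjusters)]
  d$exposed <- as.integer(exposed)
  fit <- fit_cox(d, "exposed", adjusters)
  hr <- fit$terms$hr[fit$terms$term == "exposed"]
  p <- mean(exposed)
  structure(list(domain = score$domain, model = model, p_pop = p, hr = hr,
                 paf = levin_paf(p, hr), fit = fit),
            class = "domain_paf")
}

#' PCA communalities of the domain scores
#'
#' Principal component analysis on the correlation matrix of the
#' standardized domain scores; components with eigenvalue >= 1 (Kaiser
#' rule, inclusive so an exactly-identity correlation keeps everything)
#' are retained, and each domain's communality is the sum of its squared
#' loadings on the retained components — the share of its variance the
#' retained components explain.
#'
#' @param score_matrix Numeric matrix/data.frame, one column per domain.
#' @param eigen_tol Tolerance on the eigenvalue >= 1 retention rule.
#' @return Named vector of communalities in `[0, 1]`.
#' @export
communalities <- function(score_matrix, eigen_tol = 1e-8) {
  S <- as.matrix(score_matrix)
  if (ncol(S) < 2) stop("need at least 2 score columns")
  sds <- apply(S, 2, stats::sd)
  if (any(sds == 0)) stop("constant score column(s): ",
                          paste(colnames(S)[sds == 0], collapse = ", "))
  R <- cor(S)
  e <- eigen(R, symmetric = TRUE)
  keep <- e$values >= 1 - eigen_tol
  if (!any(keep)) keep[1] <- TRUE
  L2 <- sweep(e$vectors[, keep, drop = FALSE]^2, 2, e$values[keep], `*`)
  h <- rowSums(L2)
  stats::setNames(pmin(pmax(h, 0), 1), colnames(S))
}

#' Communality-weighted PAF
#'
#' The per-domain weighted PAF is the unweighted PAF multiplied by the
#' square root of the domain's communality, discounting domains whose
#' variance is poorly shared with the retained principal components.
#'
#' @param unweighted Unweighted PAF (any scale; percent in the reports).
#' @param communality Communality in `[0, 1]`.
#' @return `unweighted * sqrt(communality)`.
#' @export
weighted_paf <- function(unweighted, communality) {
  if (any(communality < 0 | communality > 1))
    stop("'communality' must lie in [0, 1]")
  unweighted * sqrt(communality)
}

#' Overall weighted PAF
#'
#' Per-domain weighted PAFs (percent scale) are each rounded to two
#' decimals and summed; the rounding convention is part of the reporting
#' contract.
#'
#' @param weighted Vector of per-domain weighted PAFs, in percent.
#' @return Their rounded sum.
#' @export
overall_paf <- function(weighted) {
  sum(round(weighted, 2))
}

#' Full per-domain and overall PAF report
#'
#' For each domain and each counterfactual model: exposure prevalence,
#' adjusted HR, unweighted PAF, communality, and communality-weighted PAF
#' (all PAFs in percent), plus the overall weighted PAF per model.
#' Communalities are computed on the weighted domain scores by default
#' (one PCA shared by both models); `communality_on = "indicators"`
#' recomputes them per model on the model-specific binary exposure
#' indicators.
#'
#' @param cohort Cohort data.frame.
#' @param scores A `domain_score_set`.
#' @param adjusters Adjustment covariates.
#' @param communality_on `"scores"` or `"indicators"`.
#' @param use `"weighted"` or `"unweighted"` tertile categories.
#' @return Object of class `paf_report`: list with `table` (domain x
#'   model rows) and `overall` (per model).
#' @export
paf_report <- function(cohort, scores,
                       adjusters = c("age", "sex", "center"),
                       communality_on = c("scores", "indicators"),
                       use = "weighted") {
  communality_on <- match.arg(communality_on)
  doms <- vapply(scores, `[[`, "", "domain")
  score_mat <- vapply(scores, `[[`, numeric(nrow(cohort)), "score")
  colnames(score_mat) <- doms
  comm_scores <- if (communality_on == "scores") communalities(score_mat)
  rows <- list()
  overall <- numeric(0)
  for (model in 1:2) {
    dp <- lapply(scores, function(s) tryCatch(
      domain_paf(cohort, s, model = model, adjusters = adjusters, use = use),
      error = function(e) {
        warning("domain '", s$domain, "', model ", model, ": ",
                conditionMessage(e))
        list(domain = s$domain, model = model, p_pop = NA_real_,
             hr = NA_real_, paf = NA_real_)
      }))
    if (communality_on == "indicators") {
      E <- vapply(dp, function(x) {
        s <- scores[[match(x$domain, doms)]]
        cat3 <- if (use == "weighted") s$category else s$unweighted_category
        as.numeric(if (model == 1) cat3 == "unfavorable" else cat3 != "favorable")
      }, numeric(nrow(cohort)))
      colnames(E) <- doms
      ok <- apply(E, 2, stats::sd) > 0
      comm <- stats::setNames(rep(NA_real_, length(doms)), doms)
      if (sum(ok) >= 2) comm[ok] <- communalities(E[, ok, drop = FALSE])
    } else comm <- comm_scores
    for (x in dp) {
      upaf <- 100 * x$paf
      wpaf <- if (is.na(upaf) || is.na(comm[[x$domain]])) NA_real_
        else weighted_paf(upaf, comm[[x$domain]])
      rows[[length(rows) + 1L]] <- data.frame(
        domain = x$domain, model = model, p_pop = x$p_pop, hr = x$hr,
        unweighted_paf = upaf, communality = comm[[x$domain]],
        weighted_paf = wpaf, stringsAsFactors = FALSE)
    }
    wp <- vapply(rows[vapply(rows, function(r) r$model == model, TRUE)],
                 `[[`, 0, "weighted_paf")
    overall[paste0("model", model)] <- overall_paf(wp[!is.na(wp)])
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, overall = overall,
                 communality_on = communality_on),
            class = "paf_report")
}

#' @export
print.paf_report <- function(x, ...) {
  tab <- x$table
  tab$p_pop <- round(tab$p_pop, 3)
  tab$hr <- round(tab$hr, 3)
  tab[c("unweighted_paf", "communality", "weighted_paf")] <-
    lapply(tab[c("unweighted_paf", "communality", "weighted_paf")], round, 4)
  print(tab, row.names = FALSE)
  cat(sprintf("Overall weighted PAF: model 1 = %.2f%%, model 2 = %.2f%%\n",
              x$overall[["model1"]], x$overall[["model2"]]))
  invisible(x)
}

#' Check the packaged published PAF reference values
#'
#' The package ships a plain-text fixture of published per-domain
#' unweighted PAFs, communalities and weighted PAFs (with overall rows)
#' from a large prospective UK cohort analysis of Parkinson's disease
#' risk factors. This check recomputes every weighted cell from its
#' unweighted PAF and communality via [weighted_paf()], recomputes the
#' overall rows via [overall_paf()], and compares against the stored
#' values.
#'
#' @param path Fixture path; defaults to the packaged
#'   `extdata/paf_reference.csv`.
#' @param tol Comparison tolerance in percentage points.
#' @return data.frame with one row per comparison (domain, model,
#'   expected, recomputed, pass); attribute `all_pass`.
#' @export
paf_reference_check <- function(path = NULL, tol = 0.01) {
  path <- path %||% system.file("extdata", "paf_reference.csv",
                                package = "exposcan", mustWork = TRUE)
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("domain", "model", "unweighted_paf", "communality", "weighted_paf")
  if (!all(req %in% names(ref)) || !nrow(ref))
    stop("malformed reference fixture: expected columns ",
         paste(req, collapse = ", "))
  dom <- ref[ref$domain != "overall", ]
  if (!nrow(dom)) stop("malformed reference fixture: no domain rows")
  out <- data.frame(domain = dom$domain, model = dom$model,
                    expected = dom$weighted_paf,
                    recomputed = round(weighted_paf(dom$unweighted_paf,
                                                    dom$communality / 100), 2),
                    stringsAsFactors = FALSE)
  ov <- ref[ref$domain == "overall", ]
  for (i in seq_len(nrow(ov))) {
    m <- ov$model[i]
    out <- rbind(out, data.frame(
      domain = "overall", model = m, expected = ov$weighted_paf[i],
      recomputed = overall_paf(out$recomputed[out$domain != "overall" &
                                                out$model == m])))
  }
  out$pass <- abs(out$expected - out$recomputed) <= tol + 1e-9
  attr(out, "all_pass") <- all(out$pass)
  out
}
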