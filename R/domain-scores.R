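#' Orient significant scan hits as binary risk indicators
#'
#' Prepares the inputs of the composite domain scores: every significant
#' variable in a scoreable domain becomes a 0/1 indicator pointing in the
#' risk direction. Protective binary factors (HR < 1) are complemented;
#' continuous (and ordinal/categorical-coded) factors are dichotomized at
#' the cohort median on the risk side — above the median when HR > 1,
#' below it when HR < 1. Direction is taken from the hazard-ratio point
#' estimate.
#'
#' @param scan An `ewas_scan` (after [collinearity_filter()] if desired).
#' @param cohort The cohort the scan ran on.
#' @param catalog Variable catalog (for variable types).
#' @param domains Domains eligible for scoring; defaults to the five
#'   scoreable domains.
#' @return Object of class `oriented_factors`: list with `X` (data.frame
#'   of 0/1 indicators) and `info` (variable, domain, hr, p, direction,
#'   rule, cutpoint).
#' @export
orient_factors <- function(scan, cohort, catalog,
                           domains = scoreable_domains()) {
  sel <- scan$significant & is.na(scan$error) & scan$domain %in% domains
  if (!any(sel)) stop("no significant variables in the scoreable domains")
  info <- list()
  X <- list()
  for (i in which(sel)) {
    v <- scan$variable[i]
    hr <- scan$hr[i]
    x <- cohort[[v]]
    ty <- catalog$type[match(v, catalog$variable)]
    is_binary <- ty == "binary" || all(x %in% 0:1)
    if (is_binary) {
      xo <- if (hr < 1) 1L - as.integer(x) else as.integer(x)
      rule <- if (hr < 1) "complement" else "identity"
      cut <- NA_real_
    } else {
      cut <- stats::median(x)
      xo <- if (hr < 1) as.integer(x < cut) else as.integer(x > cut)
      rule <- if (hr < 1) "below_median" else "above_median"
    }
    X[[v]] <- xo
    info[[length(info) + 1L]] <- data.frame(
      variable = v, domain = scan$domain[i], hr = hr, p = scan$p[i],
      direction = if (hr < 1) "protective" else "adverse",
      rule = rule, cutpoint = cut, stringsAsFactors = FALSE)
  }
  structure(list(X = as.data.frame(X, check.names = FALSE),
                 info = do.call(rbind, info)),
            class = "oriented_factors")
}

#' Unweighted domain risk score
#'
#' One point per oriented risk factor the participant carries.
#'
#' @param oriented An `oriented_factors` object.
#' @param domain Domain name.
#' @return Integer vector of row sums over the domain's factors.
#' @export
unweighted_score <- function(oriented, domain) {
  members <- oriented$info$variable[oriented$info$domain == domain]
  if (!length(members)) stop("no oriented factors in domain '", domain, "'")
  as.integer(rowSums(oriented$X[members]))
}

#' Weighted domain risk score
#'
#' Fits the within-domain multivariable Cox model (all of the domain's
#' oriented factors jointly, plus the adjusters) and forms the normalized
#' weighted score `S = sum(X_k beta_k) / sum(beta_k)`, which lies in
#' `[0, 1]` when all beta are nonnegative. Coefficients that come out
#' negative despite orientation (possible under mutual adjustment) are
#' retained with sign and flagged with a warning. Tertiles of both the
#' weighted and unweighted score are attached (favorable / moderate /
#' unfavorable).
#'
#' @inheritParams unweighted_score
#' @param cohort Cohort data.frame.
#' @param adjusters Adjustment covariates for the within-domain fit.
#' @return Object of class `domain_score`: list with `domain`, `members`,
#'   `beta`, `score`, `unweighted`, `category`, `unweighted_category`,
#'   and the within-domain `fit`.
#' @export
weighted_score <- function(oriented, domain, cohort,
                           adjusters = c("age", "sex", "center")) {
  members <- oriented$info$variable[oriented$info$domain == domain]
  if (!length(members)) stop("no oriented factors in domain '", domain, "'")
  d <- cbind(cohort[c("time", "event", adjusters)], oriented$X[members])
  fit <- fit_cox(d, members, adjusters)
  idx <- match(members, fit$terms$term)
  if (anyNA(idx)) idx <- seq_along(members)  # exposure terms come first
  beta <- stats::setNames(fit$terms$beta[idx], members)
  if (any(beta < 0))
    warning("negative within-domain coefficient(s) retained for: ",
            paste(members[beta < 0], collapse = ", "))
  S <- as.vector(as.matrix(oriented$X[members]) %*% beta) / sum(beta)
  unw <- unweighted_score(oriented, domain)
  structure(list(domain = domain, members = members, beta = beta,
                 score = S, unweighted = unw,
                 category = categorize_tertiles(S),
                 unweighted_category = categorize_tertiles(unw),
                 fit = fit),
            class = "domain_score")
}

#' Categorize scores into favorable / moderate / unfavorable tertiles
#'
#' Cuts at the 1/3 and 2/3 sample quantiles; ties at a cut all go to the
#' lower category, so labels are a deterministic function of the score
#' vector. Constant scores are an error.
#'
#' @param scores Numeric vector.
#' @return Factor with levels favorable, moderate, unfavorable.
#' @export
categorize_tertiles <- function(scores) {
  .tertile_cut(scores, c("favorable", "moderate", "unfavorable"))
}

#' Build weighted scores for every scoreable domain
#'
#' @inheritParams weighted_score
#' @return Named list of `domain_score` objects (class
#'   `domain_score_set`), one per domain with oriented factors.
#' @export
build_domain_scores <- function(oriented, cohort,
                                adjusters = c("age", "sex", "center")) {
  doms <- unique(oriented$info$domain)
  out <- lapply(doms, weighted_score, oriented = oriented, cohort = cohort,
                adjusters = adjusters)
  names(out) <- doms
  class(out) <- "domain_score_set"
  out
}

#' Joint Cox model over all domain score categories
#'
#' One Cox model with every domain's tertile category (favorable as the
#' reference) entered together, plus the adjusters — the combined-effect
#' model. Set `use = "unweighted"` for the sensitivity analysis on
#' unweighted scores.
#'
#' @param cohort Cohort data.frame.
#' @param scores A `domain_score_set`.
#' @param adjusters Adjustment covariates.
#' @param use `"weighted"` or `"unweighted"` categories.
#' @return A `cox_fit` whose exposure terms are the domain category
#'   contrasts (moderate and unfavorable vs favorable).
#' @export
joint_domain_model <- function(cohort, scores,
                               adjusters = c("age", "sex", "center"),
                               use = c("weighted", "unweighted")) {
  use <- match.arg(use)
  d <- cohort[c("time", "event", adjusters)]
  cols <- character(0)
  for (s in scores) {
    cl <- paste0("score_", gsub("[^a-z]+", "_", s$domain))
    d[[cl]] <- if (use == "weighted") s$category else s$unweighted_category
    cols <- c(cols, cl)
  }
  fit_cox(d, cols, adjusters)
}

#' Nine-group gene-environment stratification
#'
#' Crosses polygenic-score tertiles (low/medium/high) with a domain's
#' score tertiles (favorable/moderate/unfavorable) into nine groups and
#' fits (a) one model against the global low-PRS/favorable reference and
#' (b) within each PRS stratum, the category contrasts against the
#' unfavorable reference. Genotype measurement batch, when supplied,
#' enters as an additional categorical covariate.
#'
#' @param cohort Cohort data.frame.
#' @param prs_groups Factor of PRS tertiles (`low`, `medium`, `high`), as
#'   from [prs_tertiles()].
#' @param score A `domain_score` object.
#' @param batch Optional genotype batch covariate.
#' @param adjusters Adjustment covariates.
#' @return Object of class `gxe_grid`: list with `grid` (9 rows: prs,
#'   category, n, events, hr, lo, hi, p, reference flag), `within`
#'   (per-PRS-stratum contrasts vs unfavorable), and the underlying fit.
#' @export
gxe_nine_groups <- function(cohort, prs_groups, score, batch = NULL,
                            adjusters = c("age", "sex", "center")) {
  stopifnot(length(prs_groups) == nrow(cohort))
  cat3 <- score$category
  d <- cohort[c("time", "event", adjusters)]
  d$gxe_group <- interaction(prs_groups, cat3, sep = "/", lex.order = TRUE)
  d$gxe_group <- stats::relevel(d$gxe_group, ref = "low/favorable")
  adj <- adjusters
  if (!is.null(batch)) {
    d$batch <- as.factor(batch)
    adj <- c(adj, "batch")
  }
  counts <- table(d$gxe_group)
  empty <- names(counts)[counts == 0]
  if (length(empty)) {
    warning("empty cell(s): ", paste(empty, collapse = ", "))
    d$gxe_group <- droplevels(d$gxe_group)
  }
  fit <- fit_cox(d, "gxe_group", adj)

  lev <- levels(d$gxe_group)
  grid <- data.frame(group = lev, stringsAsFactors = FALSE)
  parts <- strsplit(lev, "/", fixed = TRUE)
  grid$prs <- vapply(parts, `[`, "", 1)
  grid$category <- vapply(parts, `[`, "", 2)
  grid$n <- as.integer(table(d$gxe_group)[lev])
  grid$events <- as.integer(tapply(d$event, d$gxe_group, sum)[lev])
  grid$hr <- 1; grid$lo <- NA_real_; grid$hi <- NA_real_; grid$p <- NA_real_
  grid$reference <- lev == "low/favorable"
  tt <- fit$terms[grepl("^gxe_group", fit$terms$term), ]
  idx <- match(paste0("gxe_group", lev[-1]), tt$term)
  grid[match(lev[-1], grid$group), c("hr", "lo", "hi", "p")] <-
    tt[idx, c("hr", "lo", "hi", "p")]

  within <- list()
  for (g in levels(prs_groups)) {
    sub <- d[prs_groups == g, , drop = FALSE]
    sub$cat <- stats::relevel(factor(cat3[prs_groups == g],
                                     levels = levels(cat3)),
                              ref = "unfavorable")
    adj_s <- adj[vapply(adj, function(a)
      length(unique(sub[[a]])) > 1L, logical(1))]
    wfit <- fit_cox(sub, "cat", adj_s)
    wt <- wfit$terms[grepl("^cat", wfit$terms$term), ]
    within[[g]] <- data.frame(
      prs = g, category = sub("^cat", "", wt$term),
      hr = wt$hr, lo = wt$lo, hi = wt$hi, p = wt$p,
      stringsAsFactors = FALSE)
  }
  structure(list(grid = grid, within = do.call(rbind, within), fit = fit),
            class = "gxe_grid")
}

#' @export
print.gxe_grid <- function(x, digits = 3, ...) {
  cat("PRS x domain-score stratification (reference: low/favorable)\n")
  g <- x$grid
  g[c("hr", "lo", "hi", "p")] <- lapply(g[c("hr", "lo", "hi", "p")],
                                        signif, digits)
  print(g[c("prs", "category", "n", "events", "hr", "lo", "hi", "p")],
        row.names = FALSE)
  invisible(x)
}
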