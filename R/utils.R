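`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exposure domains
#'
#' The seven baseline exposure domains used throughout the package, and the
#' five of them that enter composite risk scores (early-life and
#' local-environment exposures are catalogued and scanned but never scored,
#' mirroring the finding that they carry no scan-significant factors).
#'
#' @return Character vector of domain names.
#' @export
exposure_domains <- function() {
  c("socioeconomic status", "medical history", "psychosocial factors",
    "physical measures", "early life", "local environment", "lifestyle")
}

#' @rdname exposure_domains
#' @export
scoreable_domains <- function() {
  setdiff(exposure_domains(), c("early life", "local environment"))
}

# Short prefixes used for synthetic variable names, one per domain.
.domain_codes <- c(
  "socioeconomic status" = "ses", "medical history" = "med",
  "psychosocial factors" = "psy", "physical measures" = "phy",
  "early life" = "ear", "local environment" = "env", "lifestyle" = "lif")

#' Derive a per-stage child seed from a master seed
#'
#' Stages of the pipeline draw from independent streams derived from one
#' master seed by a fixed counter scheme: `child = master * 64 + offset`,
#' with one reserved offset per named stage. The multiplier keeps streams of
#' different masters disjoint; masters up to 2^24 stay inside the 32-bit
#' integer range.
#'
#' @param seed Master seed (integer).
#' @param stage Stage name; one of the names of the internal offset table.
#' @return An integer seed.
#' @export
child_seed <- function(seed, stage) {
  offsets <- c(covariates = 1L, genotypes = 2L, events = 3L, assays = 4L,
               raw_codes = 5L, instances = 6L, mr_summary = 7L,
               bootstrap = 8L, simulation = 9L)
  if (!stage %in% names(offsets)) stop("unknown seed stage: ", stage)
  seed <- as.integer(seed)
  if (is.na(seed) || abs(seed) > 2^24) stop("master seed must be an integer within +/- 2^24")
  seed * 64L + offsets[[stage]]
}

# Tertile assignment with ties-at-the-cut going to the lower category.
# Cuts are the 1/3 and 2/3 type-7 sample quantiles.
.tertile_cut <- function(x, labels) {
  if (length(x) < 3L) stop("need at least 3 observations for tertiles")
  if (!all(is.finite(x))) stop("tertiles require finite values")
  if (stats::sd(x) == 0) stop("degenerate input: all values identical")
  q <- stats::quantile(x, c(1, 2) / 3, type = 7, names = FALSE)
  g <- 1L + (x > q[1]) + (x > q[2])
  factor(labels[g], levels = labels)
}

# Mode of a vector, ties broken by the smallest value.
.stat_mode <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])  # which.max takes first = smallest
}

.assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("'", name, "' must be a single value in [0, 1]")
  invisible(x)
}

# Variable columns of a cohort = catalog variables actually present.
.variable_columns <- function(cohort, catalog) {
  intersect(catalog$variable, names(cohort))
}
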