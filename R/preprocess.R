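#' Recoding and exclusion rules for raw baseline variables
#'
#' Encodes the variable-processing conventions of UK-Biobank-style exports:
#' meaningful negative codes are mapped to values (-10, "less than one",
#' becomes 0.5 in count-coded variables), non-meaningful codes (-1 "do not
#' know", -3 "prefer not to answer") become missing, and participants or
#' variables with more than 20% missing values are excluded (strict
#' inequality: exactly 20% is retained).
#'
#' @param special_value_map Named numeric vector mapping raw code to
#'   replacement value, applied only to count-coded variables.
#' @param missing_codes Raw codes recoded to missing everywhere.
#' @param variable_missing_threshold,participant_missing_threshold Maximum
#'   tolerated missing fraction, in (0, 1]; exceeding it (strictly) drops
#'   the variable/participant.
#' @return An object of class `recode_rules`.
#' @export
recode_rules <- function(special_value_map = c("-10" = 0.5),
                         missing_codes = c(-1, -3),
                         variable_missing_threshold = 0.20,
                         participant_missing_threshold = 0.20) {
  for (nm in c("variable_missing_threshold", "participant_missing_threshold")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1)
      stop("'", nm, "' must be in (0, 1]")
  }
  if (any(as.numeric(names(special_value_map)) %in% missing_codes))
    stop("special_value_map codes and missing_codes must be disjoint")
  out <- list(special_value_map = special_value_map,
              missing_codes = missing_codes,
              variable_missing_threshold = variable_missing_threshold,
              participant_missing_threshold = participant_missing_threshold)
  class(out) <- "recode_rules"
  out
}

#' Apply participant and variable exclusion criteria
#'
#' Removes, in order and disjointly by first matching criterion:
#' participants with prevalent disease at baseline, participants without
#' genetic data, and participants whose fraction of missing variable values
#' strictly exceeds the participant threshold. Variables whose missing
#' fraction (among retained participants) strictly exceeds the variable
#' threshold are then dropped.
#'
#' @param cohort Cohort data.frame.
#' @param catalog Variable catalog (defines which columns are variables).
#' @param prevalent Logical vector: disease present before baseline.
#' @param has_genetics Logical vector: genetic data available.
#' @param rules A [recode_rules()] object.
#' @return List with `cohort`, `catalog` (dropped variables removed) and
#'   `report`, an `exclusion_report` reconciling the counts.
#' @export
exclude_records <- function(cohort, catalog, prevalent = NULL,
                            has_genetics = NULL, rules = recode_rules()) {
  n <- nrow(cohort)
  prevalent <- prevalent %||% rep(FALSE, n)
  has_genetics <- has_genetics %||% rep(TRUE, n)
  if (length(prevalent) != n || length(has_genetics) != n)
    stop("dimension error: flag vectors must match the number of rows")
  vars <- .variable_columns(cohort, catalog)
  miss_frac <- rowMeans(is.na(cohort[vars]))
  ids <- cohort$id %||% seq_len(n)

  crit <- rep("retained", n)
  crit[miss_frac > rules$participant_missing_threshold] <- "missingness"
  crit[!has_genetics] <- "no_genetics"
  crit[prevalent] <- "prevalent"      # first-matching criterion wins

  keep <- crit == "retained"
  cohort2 <- cohort[keep, , drop = FALSE]

  var_miss <- colMeans(is.na(cohort2[vars]))
  drop_vars <- names(var_miss)[var_miss > rules$variable_missing_threshold]
  cohort2 <- cohort2[, setdiff(names(cohort2), drop_vars), drop = FALSE]
  catalog2 <- catalog[!catalog$variable %in% drop_vars, , drop = FALSE]

  report <- list(
    n_before = n, n_after = nrow(cohort2),
    participants = list(
      prevalent = ids[crit == "prevalent"],
      no_genetics = ids[crit == "no_genetics"],
      missingness = ids[crit == "missingness"]),
    variables_dropped = drop_vars,
    thresholds = list(
      participant = rules$participant_missing_threshold,
      variable = rules$variable_missing_threshold))
  class(report) <- "exclusion_report"
  stopifnot(report$n_before - report$n_after ==
              sum(lengths(report$participants)))
  list(cohort = cohort2, catalog = catalog2, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusions:", x$n_before, "->", x$n_after, "participants\n")
  for (nm in names(x$participants))
    cat(sprintf("  %-12s %d\n", nm, length(x$participants[[nm]])))
  cat("  variables dropped:", length(x$variables_dropped), "\n")
  invisible(x)
}

#' Recode raw special values
#'
#' Applies the special-value map (-10 becomes 0.5 in count-coded
#' variables) and turns the missing codes (-1, -3) into `NA` in every
#' variable column. A mapped special code found in a variable not
#' designated for it raises a warning and is treated as missing. The
#' operation is idempotent.
#'
#' @inheritParams exclude_records
#' @return The recoded cohort.
#' @export
recode_values <- function(cohort, catalog, rules = recode_rules()) {
  vars <- .variable_columns(cohort, catalog)
  # instance columns inherit the designation of their base variable
  inst <- grep("\\.\\d+$", names(cohort), value = TRUE)
  inst <- inst[sub("\\.\\d+$", "", inst) %in% catalog$variable]
  for (v in c(vars, inst)) {
    x <- cohort[[v]]
    if (!is.numeric(x)) next
    x[x %in% rules$missing_codes] <- NA
    base <- sub("\\.\\d+$", "", v)
    count_var <- isTRUE(catalog$count_coded[match(base, catalog$variable)])
    for (code in names(rules$special_value_map)) {
      hit <- !is.na(x) & x == as.numeric(code)
      if (!any(hit)) next
      if (count_var) {
        x[hit] <- rules$special_value_map[[code]]
      } else {
        warning("special code ", code, " in non-designated variable '", v,
                "'; treated as missing")
        x[hit] <- NA
      }
    }
    cohort[[v]] <- x
  }
  cohort
}

#' Average multi-instance measurement columns
#'
#' Collapses instance columns `v.0, v.1, ...` into a single column `v`
#' holding the mean over non-missing instances (a participant with no
#' non-missing instance stays missing, to be handled by imputation).
#'
#' @param cohort Cohort data.frame.
#' @param instance_map Optional named list mapping base variable to
#'   instance columns; derived from the `v.<k>` naming pattern when `NULL`.
#' @return The cohort with instance columns replaced by their means.
#' @export
average_instances <- function(cohort, instance_map = NULL) {
  if (is.null(instance_map)) {
    inst <- grep("\\.\\d+$", names(cohort), value = TRUE)
    if (!length(inst)) return(cohort)
    instance_map <- split(inst, sub("\\.\\d+$", "", inst))
  }
  for (base in names(instance_map)) {
    cols <- instance_map[[base]]
    m <- rowMeans(cohort[cols], na.rm = TRUE)
    m[is.nan(m)] <- NA
    cohort[[base]] <- m       # averaged column appends after the others
    cohort <- cohort[, setdiff(names(cohort), cols), drop = FALSE]
  }
  cohort
}

#' Impute missing variable values
#'
#' Fills categorical/binary/ordinal variables with the mode (ties broken by
#' the smallest coded value) and continuous variables with the median, both
#' computed on the non-missing values of the current (post-exclusion)
#' cohort.
#'
#' @inheritParams exclude_records
#' @return The cohort with no missing values in variable columns.
#' @export
impute_missing <- function(cohort, catalog) {
  vars <- .variable_columns(cohort, catalog)
  for (v in vars) {
    x <- cohort[[v]]
    if (!anyNA(x)) next
    if (all(is.na(x))) stop("cannot impute variable '", v, "': all values missing")
    ty <- catalog$type[match(v, catalog$variable)]
    fill <- if (ty %in% c("categorical", "binary", "ordinal"))
      .stat_mode(x) else stats::median(x, na.rm = TRUE)
    x[is.na(x)] <- fill
    cohort[[v]] <- x
  }
  cohort
}

#' Dummy-encode unordered categorical variables
#'
#' Each k-level unordered categorical variable with k >= 3 becomes k-1
#' binary indicators against the most frequent level (ties broken by the
#' smallest coded value); binary and ordinal variables pass through;
#' constant variables are dropped with a warning. The catalog is rewritten
#' at the encoded-column level with a `source` column recording provenance.
#'
#' @inheritParams exclude_records
#' @return List with the encoded `cohort` and the updated `catalog`.
#' @export
dummy_encode <- function(cohort, catalog) {
  vars <- .variable_columns(cohort, catalog)
  new_rows <- list()
  for (i in seq_len(nrow(catalog))) {
    v <- catalog$variable[i]
    if (!v %in% vars) next
    x <- cohort[[v]]
    lev <- sort(unique(x[!is.na(x)]))
    row <- catalog[i, , drop = FALSE]
    row$source <- v
    if (length(lev) <= 1L) {
      warning("constant variable '", v, "' dropped")
      cohort[[v]] <- NULL
      next
    }
    if (catalog$type[i] != "categorical" || length(lev) == 2L) {
      new_rows[[length(new_rows) + 1L]] <- row
      next
    }
    ref <- .stat_mode(x)
    for (l in setdiff(lev, ref)) {
      nm <- paste0(v, ".", l)
      cohort[[nm]] <- as.integer(x == l)
      r2 <- row
      r2$variable <- nm
      r2$type <- "binary"
      new_rows[[length(new_rows) + 1L]] <- r2
    }
    cohort[[v]] <- NULL
  }
  catalog2 <- do.call(rbind, new_rows)
  rownames(catalog2) <- NULL
  list(cohort = cohort, catalog = catalog2)
}

#' Run the full preprocessing chain
#'
#' Recode special values, average multi-instance columns, apply exclusion
#' criteria, impute remaining missingness, and dummy-encode categoricals —
#' in that order, so that the missingness thresholds act on raw (pre-
#' imputation) missingness.
#'
#' @inheritParams exclude_records
#' @param instance_map Passed to [average_instances()].
#' @return List with `cohort`, `catalog`, and the exclusion `report`.
#' @export
preprocess_cohort <- function(cohort, catalog, rules = recode_rules(),
                              prevalent = NULL, has_genetics = NULL,
                              instance_map = NULL) {
  cohort <- recode_values(cohort, catalog, rules)
  cohort <- average_instances(cohort, instance_map)
  ex <- exclude_records(cohort, catalog, prevalent = prevalent,
                        has_genetics = has_genetics, rules = rules)
  cohort <- impute_missing(ex$cohort, ex$catalog)
  enc <- dummy_encode(cohort, ex$catalog)
  list(cohort = enc$cohort, catalog = enc$catalog, report = ex$report)
}
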