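make_catalog <- function(vars, types, count_coded = rep(FALSE, length(vars))) {
  data.frame(variable = vars, domain = "lifestyle", type = types,
             modifiable = TRUE, count_coded = count_coded, n_instances = 1L,
             stringsAsFactors = FALSE)
}

test_that("special codes are recoded: -10 to 0.5, -1/-3 to missing", {
  cohort <- data.frame(cups = c(-10, 7, -1, 3), mood = c(-3, 2, 1, -1))
  catalog <- make_catalog(c("cups", "mood"), c("continuous", "categorical"),
                          count_coded = c(TRUE, FALSE))
  out <- recode_values(cohort, catalog)
  expect_equal(out$cups, c(0.5, 7, NA, 3))
  expect_equal(out$mood, c(NA, 2, 1, NA))
  # idempotence
  expect_equal(recode_values(out, catalog), out)
  # -10 outside a count-coded variable warns and becomes missing
  bad <- data.frame(cups = c(1, 2), mood = c(-10, 5))
  expect_warning(out2 <- recode_values(bad, catalog), "non-designated")
  expect_equal(out2$mood, c(NA, 5))
})

test_that("exclusion applies the strict 20% rule and reconciles counts", {
  catalog <- make_catalog(paste0("v", 1:10), rep("continuous", 10))
  cohort <- as.data.frame(matrix(1, 6, 10,
                                 dimnames = list(NULL, paste0("v", 1:10))))
  cohort$id <- 1:6
  cohort[1, paste0("v", 1:3)] <- NA    # 30% missing -> excluded
  cohort[2, paste0("v", 1:2)] <- NA    # exactly 20% -> retained
  prevalent <- c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  genetics <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  out <- exclude_records(cohort, catalog, prevalent, genetics)
  expect_setequal(out$cohort$id, c(2, 5, 6))
  expect_equal(out$report$participants$prevalent, 3)
  expect_equal(out$report$participants$no_genetics, 4)
  expect_equal(out$report$participants$missingness, 1)
  expect_equal(out$report$n_before - out$report$n_after, 3)
  # identity when nothing is flagged or missing
  clean <- cohort[5:6, ]
  same <- exclude_records(clean, catalog)
  expect_equal(same$cohort, clean)
  expect_error(exclude_records(cohort, catalog, prevalent[-1], genetics),
               "dimension")
})

test_that("a prevalent case also missing genetics counts once, as prevalent", {
  catalog <- make_catalog("v1", "continuous")
  cohort <- data.frame(id = 1:3, v1 = 1)
  out <- exclude_records(cohort, catalog, prevalent = c(TRUE, FALSE, FALSE),
                         has_genetics = c(FALSE, TRUE, TRUE))
  expect_equal(out$report$participants$prevalent, 1)
  expect_length(out$report$participants$no_genetics, 0)
})

test_that("variables exceeding the missingness threshold are dropped", {
  vars <- letters[1:10]
  catalog <- make_catalog(vars, rep("continuous", 10))
  cohort <- as.data.frame(matrix(1, 10, 10, dimnames = list(NULL, vars)))
  cohort$id <- 1:10
  cohort$a[1:3] <- NA   # 30% missing for 'a'; each row only 10% missing
  out <- exclude_records(cohort, catalog)
  expect_equal(out$report$n_after, 10)         # no participant dropped
  expect_false("a" %in% names(out$cohort))
  expect_true("b" %in% names(out$cohort))
  expect_equal(out$report$variables_dropped, "a")
})

test_that("imputation fills mode for categoricals and median for continuous", {
  catalog <- make_catalog(c("cat", "cont"), c("categorical", "continuous"))
  cohort <- data.frame(cat = c(1, 1, 2, NA), cont = c(1, 2, 9, NA))
  out <- impute_missing(cohort, catalog)
  expect_equal(out$cat[4], 1)      # mode
  expect_equal(out$cont[4], 2)     # median of (1, 2, 9)
  # imputation preserves the observed mode and median
  expect_equal(median(out$cont), median(cohort$cont, na.rm = TRUE))
  # mode ties break to the smallest coded value
  tie <- data.frame(cat = c(2, 2, 1, 1, NA), cont = 1:5)
  expect_equal(impute_missing(tie, catalog)$cat[5], 1)
  # untouched when complete; error when nothing to impute from
  expect_equal(impute_missing(out, catalog), out)
  allna <- data.frame(cat = c(NA, NA), cont = c(1, 2))
  expect_error(impute_missing(allna, catalog), "all values missing")
})

test_that("instance averaging uses the non-missing instances", {
  cohort <- data.frame(id = 1:3, grip.0 = c(10, 10, NA),
                       grip.1 = c(12, NA, NA), other = 1:3)
  out <- average_instances(cohort)
  expect_equal(out$grip, c(11, 10, NA))
  expect_equal(out$other, 1:3)             # single-column variable untouched
  expect_false(any(c("grip.0", "grip.1") %in% names(out)))
})

test_that("dummy coding expands k-level categoricals against the mode", {
  catalog <- make_catalog(c("c3", "bin", "konst"),
                          c("categorical", "binary", "continuous"))
  cohort <- data.frame(c3 = c(0, 0, 1, 2, 0), bin = c(0, 1, 0, 1, 1),
                       konst = rep(5, 5))
  expect_warning(out <- dummy_encode(cohort, catalog), "constant")
  expect_setequal(names(out$cohort), c("c3.1", "c3.2", "bin"))
  expect_equal(out$cohort$c3.1, c(0, 0, 1, 0, 0))
  expect_equal(out$cohort$c3.2, c(0, 0, 0, 1, 0))
  expect_equal(out$catalog$source[out$catalog$variable == "c3.1"], "c3")
  expect_true(all(out$catalog$type %in% c("binary")))
})

test_that("encoded column count equals sum(k - 1) plus pass-through columns", {
  fx <- strong_pipeline_fixture()
  raw_catalog <- fx$sim$catalog
  enc <- fx$pp$catalog
  k3 <- sum(raw_catalog$type == "categorical")
  passthrough <- sum(raw_catalog$type != "categorical")
  expect_equal(nrow(enc), passthrough + 2 * k3)
})

test_that("the full preprocessing chain yields a complete numeric cohort", {
  fx <- strong_pipeline_fixture()
  vars <- .subset2(fx$pp$catalog, "variable")
  expect_false(anyNA(fx$pp$cohort[vars]))
  expect_true(all(vapply(fx$pp$cohort[vars], is.numeric, TRUE)))
})
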