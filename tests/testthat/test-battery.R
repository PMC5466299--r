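# Battery construction, design encoding, and the logistic fit contract.

test_that("the battery reproduces the full model grid", {
  bat_a <- build_battery("A", "a")
  bat_b <- build_battery("A", "b")
  expect_equal(nrow(bat_a), 28L) # 9 univariable + 4 signal + 15 augmented
  expect_equal(nrow(bat_b), 19L) # no univariable block without DCE
  expect_equal(sum(bat_a$role == "univariable"), 9L)
  expect_equal(sum(bat_a$role == "signal"), 4L)
  expect_equal(sum(bat_a$role == "augmented"), 15L)
  expect_equal(nrow(signal1_family(bat_a)), 16L)
  expect_true("Signal1+Shape+ECE+Vmax+dPSA" %in% bat_a$name)
  expect_true(all(signal1_family(bat_b)$name %in% signal1_family(bat_a)$name))
})

test_that("signal-model definitions follow the grid", {
  bat_a <- build_battery("A", "a")
  bat_b <- build_battery("A", "b")
  get <- function(bat, nm, role = "signal") {
    r <- bat[bat$name == nm & bat$role == role, ]
    list(pred = r$predictors[[1]], seqs = r$smax_seqs[[1]])
  }
  expect_equal(get(bat_a, "Signal1")$pred, c("s_max", "s_min_any"))
  expect_equal(get(bat_a, "Signal2")$pred, c("s_max", "s_min_any", "s_dw"))
  expect_equal(get(bat_a, "Signal2")$seqs, c("T2W", "DCE"))
  expect_equal(get(bat_b, "Signal2")$seqs, "T2W")
  expect_equal(get(bat_a, "Signal3")$pred, c("s_t2", "s_dw", "s_dce"))
  expect_equal(get(bat_b, "Signal3")$pred, c("s_t2", "s_dw"))
})

test_that("the b-variant battery never references DCE", {
  bat_b <- build_battery("A", "b")
  expect_false(any(vapply(bat_b$predictors, function(p) "s_dce" %in% p,
                          logical(1))))
  expect_false(any(vapply(bat_b$smax_seqs, function(s) "DCE" %in% s,
                          logical(1))))
})

test_that("ordinal predictors expand to reference-coded indicators", {
  co <- generate_cohort(cohort_params(n_patients = 200, seed = 12))
  spec <- model_spec("smax_only", "s_max")
  enc <- encode_design(co, spec, "A", collapse_threshold = 0)
  expect_equal(sort(unique(compute_smax(co))), 0:3)
  expect_equal(ncol(enc$x), 4L) # intercept + 3 indicators

  enc2 <- encode_design(co, model_spec("smin_only", "s_min_any"), "A")
  expect_equal(ncol(enc2$x), 2L) # intercept + single 0/1 column
  expect_true(all(enc2$x[, 2] %in% c(0, 1)))
})

test_that("levels absent from the data are dropped with a warning", {
  co <- generate_cohort(cohort_params(n_patients = 200, seed = 12))
  co$s_t2[co$s_t2 == 3] <- 2L # remove the 'marked' level on T2W
  co$vol_t2[co$s_t2 == 0] <- NA_real_
  spec <- model_spec("st2_only", "s_t2")
  expect_warning(
    enc <- encode_design(co, spec, "A", collapse_threshold = 0),
    class = "lesionval_dropped_level"
  )
  expect_equal(ncol(enc$x), 3L) # intercept + 2 indicators
  expect_equal(enc$dropped_levels, "s_t2=3")
})

test_that("sparse categorical levels merge toward the reference", {
  co <- generate_cohort(cohort_params(n_patients = 200, seed = 12))
  keep3 <- which(compute_smax(co) == 3)
  drop <- keep3[-(1:2)] # leave only 2 lesions with s_max = 3
  co <- co[setdiff(seq_len(nrow(co)), drop), ]
  enc <- encode_design(co, model_spec("smax_only", "s_max"), "A",
                       collapse_threshold = 3)
  expect_equal(enc$collapsed_levels, "s_max=3")
  expect_equal(ncol(enc$x), 3L) # 3 -> merged into 2
})

test_that("the intercept-only fit recovers the prevalence", {
  co <- generate_cohort(cohort_params(n_patients = 80, seed = 5))
  enc <- encode_design(co, model_spec("null", character(0)), "A")
  fit <- fit_logistic(enc$x, enc$y)
  expect_equal(unique(round(fit$fitted, 12)), round(mean(enc$y), 12))
})

test_that("a single binary predictor recovers the 2x2 log odds ratio", {
  # cells: a = 20 (x=1, y=1), b = 10 (x=1, y=0), c = 5, d = 15
  x1 <- c(rep(1, 30), rep(0, 20))
  y <- c(rep(1, 20), rep(0, 10), rep(1, 5), rep(0, 15))
  fit <- fit_logistic(cbind(1, x = x1), y)
  expect_false(fit$fallback)
  expect_equal(unname(fit$coefficients[2]), log((20 * 15) / (10 * 5)),
               tolerance = 1e-6)
})

test_that("separation triggers the ridge fallback with finite coefficients", {
  x <- cbind(1, sep = c(rep(0, 20), rep(1, 20)))
  y <- c(rep(0, 20), rep(1, 20))
  fit <- fit_logistic(x, y)
  expect_true(fit$fallback)
  expect_true(all(is.finite(fit$coefficients)))
  expect_gt(auc_mw(fit$fitted, y), 0.99)

  expect_error(fit_logistic(cbind(1, x = rnorm(10)), rep(1, 10)),
               class = "lesionval_degenerate")
})

test_that("fitted probabilities are invariant to the reference level", {
  set.seed(42)
  f <- factor(sample(c("l0", "l1", "l2"), 120, replace = TRUE))
  y <- rbinom(120, 1, c(0.2, 0.5, 0.7)[as.integer(f)])
  x1 <- stats::model.matrix(~f)
  x2 <- stats::model.matrix(~stats::relevel(f, "l2"))
  f1 <- fit_logistic(x1, y)
  f2 <- fit_logistic(x2, y)
  expect_equal(f1$fitted, f2$fitted, tolerance = 1e-8)
})

test_that("constant and collinear columns do not change fitted values", {
  set.seed(7)
  x <- cbind(1, a = rnorm(100))
  y <- rbinom(100, 1, plogis(x[, 2]))
  base <- fit_logistic(x, y)
  padded <- fit_logistic(cbind(x, const = 2, dup = x[, 2]), y)
  expect_equal(base$fitted, padded$fitted, tolerance = 1e-8)
  expect_true(length(padded$dropped_terms) >= 1)
})

test_that("apparent AUC of a fitted model is never below chance", {
  for (s in 1:8) {
    rec <- analysis_records(generate_cohort(cohort_params(n_patients = 60,
                                                          seed = 100 + s)))
    fit <- fit_model(rec, model_spec("m", c("s_max", "v_max")), "A")
    y <- label_cspca(rec$gleason_group, rec$epe, "A")
    expect_gte(auc_mw(fit$fitted, as.integer(y)), 0.5 - 1e-12)
  }
})

test_that("the battery manifest is join-able by model name", {
  bat <- build_battery("A", "a")
  path <- withr::local_tempfile(fileext = ".json")
  write_battery_manifest(bat, path)
  manifest <- jsonlite::read_json(path)
  expect_equal(vapply(manifest, `[[`, character(1), "name"), bat$name)
})
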