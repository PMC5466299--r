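# AUC estimator, clustered resampling, and the optimism-corrected bootstrap.

test_that("AUC handles separation, ties, and mixed cases", {
  expect_equal(auc_mw(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(auc_mw(rep(2, 8), rep(c(0, 1), 4)), 0.5)
  s <- c(0.1, 0.4, 0.35, 0.8, 0.4, 0.7)
  y <- c(0, 0, 1, 1, 0, 1)
  expect_equal(auc_mw(s, y), brute_auc(s, y))
  expect_error(auc_mw(1:4, rep(1, 4)), class = "lesionval_degenerate")
})

test_that("AUC equals exhaustive pairwise enumeration on small cohorts", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    scores <- if (i %% 2 == 0) sample(1:4, n, replace = TRUE) else
      round(runif(n), 2)
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    expect_equal(auc_mw(scores, labels), brute_auc(scores, labels),
                 tolerance = 1e-14)
  }
})

test_that("AUC reflection: reversing scores flips the AUC around 0.5", {
  set.seed(99)
  for (i in 1:25) {
    scores <- sample(1:5, 40, replace = TRUE)
    labels <- rbinom(40, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(auc_mw(scores, labels) + auc_mw(-scores, labels), 1)
  }
})

test_that("cluster resampling draws whole patients", {
  one <- tiny_cohort(c("P1", "P1", "P1"), gleason_group = c(0L, 2L, 5L))
  rs <- cluster_resample(one)
  expect_equal(nrow(rs), 3L)
  expect_equal(rs$gleason_group, one$gleason_group)

  co <- generate_cohort(cohort_params(n_patients = 50, seed = 14))
  set.seed(5)
  rs1 <- cluster_resample(co)
  set.seed(5)
  rs2 <- cluster_resample(co)
  expect_identical(rs1, rs2)
  # patient count preserved, copies get distinct synthetic ids
  expect_equal(length(unique(rs1$patient_id)), 50L)
  # every synthetic cluster is an intact copy of a single source patient
  src <- sub("#.*$", "", rs1$patient_id)
  expect_true(all(tapply(src, rs1$patient_id,
                         function(x) length(unique(x))) == 1))

  set.seed(31)
  counts <- replicate(400, nrow(cluster_resample(co)))
  expect_lt(abs(mean(counts) - nrow(co)), 3 * stats::sd(counts) / sqrt(400))
})

test_that("B = 0 returns the apparent AUC as corrected, without an interval", {
  co <- generate_cohort(cohort_params(n_patients = 60, seed = 6))
  spec <- model_spec("m", c("s_max", "s_min_any"))
  v <- validate_model(co, spec, "A", B = 0)
  expect_identical(v$corrected_auc, v$apparent_auc)
  expect_true(is.na(v$ci_low) && is.na(v$ci_high))
  expect_equal(v$n_boot_used, 0L)
})

test_that("validation is invariant to lesion ordering given the seed", {
  co <- generate_cohort(cohort_params(n_patients = 60, seed = 6))
  spec <- model_spec("m", c("s_max", "v_max"))
  v1 <- validate_model(co, spec, "A", B = 60, seed = 42)
  set.seed(777) # permute rows; patient set unchanged
  v2 <- validate_model(co[sample(nrow(co)), ], spec, "A", B = 60, seed = 42)
  expect_equal(tidy(v1), tidy(v2), tolerance = 1e-10)
})

test_that("degenerate replicates are skipped and counted, never imputed", {
  co <- tiny_cohort(rep(c("P1", "P2", "P3"), each = 4),
                    gleason_group = rep(c(3L, 0L, 0L), each = 4),
                    s_dw = rep(c(3L, 1L, 2L), each = 4))
  spec <- model_spec("m", "s_dw")
  v <- validate_model(co, spec, "A", B = 80, seed = 1,
                      collapse_threshold = 0)
  expect_gt(v$n_boot_degenerate, 0)
  expect_equal(v$n_boot_used + v$n_boot_degenerate, 80L)
  expect_equal(nrow(v$boot), v$n_boot_used)

  # a cohort whose every resample is single-class fails loudly
  allpos <- tiny_cohort(c("P1", "P2"), gleason_group = 2L)
  expect_error(validate_model(allpos, spec, "A", B = 10, seed = 1),
               class = "lesionval_degenerate")
})

test_that("optimism is non-negative in expectation for a rich model", {
  spec <- build_battery("A", "a") |>
    dplyr::filter(name == "Signal1+Shape+ECE+Vmax+dPSA")
  opt <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_params(n_patients = 60, seed = 300 + s))
    validate_model(co, spec, "A", B = 60, seed = s)$mean_optimism
  }, double(1))
  expect_gte(mean(opt), -0.01)
})

test_that("the Likert baseline scores lesions without fitting", {
  co <- tiny_cohort(sprintf("P%d", 1:40),
                    gleason_group = rep(c(0L, 2L), 20))
  co$likert <- as.integer(2L + label_cspca(co$gleason_group, co$epe, "A"))
  v <- likert_baseline(co, "A", B = 50, seed = 1)
  expect_equal(v$apparent_auc, 1)
  expect_identical(v$mean_optimism, 0)
  expect_identical(v$corrected_auc, v$apparent_auc)

  flat <- tiny_cohort(sprintf("P%d", 1:40),
                      gleason_group = rep(c(0L, 2L), 20), likert = 3L)
  expect_equal(likert_baseline(flat, "A", B = 0)$apparent_auc, 0.5)
})

test_that("the synthetic Likert AUC matches its large-sample value", {
  big <- generate_cohort(cohort_params(n_patients = 5600, seed = 71))
  y_big <- label_cspca(big$gleason_group, big$epe, "A")
  ref <- auc_mw(big$likert, y_big)

  co <- generate_cohort(cohort_params(n_patients = 300, seed = 72))
  v <- likert_baseline(co, "A", B = 0)
  y <- label_cspca(co$gleason_group, co$epe, "A")
  se <- hanley_se(ref, sum(y), sum(!y))
  expect_lt(abs(v$apparent_auc - ref), 3 * se)
})

test_that("tidy and glance return one-row summaries", {
  co <- generate_cohort(cohort_params(n_patients = 50, seed = 2))
  v <- validate_model(co, model_spec("m", "s_max"), "A", B = 30, seed = 1)
  td <- tidy(v)
  expect_equal(nrow(td), 1L)
  expect_equal(td$corrected_auc, v$apparent_auc - v$mean_optimism)
  expect_identical(glance(v), td)
})
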