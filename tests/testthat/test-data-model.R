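# Lesion-table contract: IO round trip, validation, csPCa labelling,
# prevalence.

test_that("a well-formed table round-trips through CSV unchanged", {
  co <- tiny_cohort(c("P1", "P1", "P2"),
                    s_t2 = c(3L, 2L, 0L), s_dw = c(3L, 1L, 2L),
                    s_dce = c(2L, 0L, 1L),
                    gleason_group = c(5L, 0L, 2L),
                    epe = c(TRUE, FALSE, FALSE),
                    vol = c(2.0, 0.31, 0.7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_lesion_table(co, path)
  back <- read_lesion_table(path)
  expect_equal(as.data.frame(back), as.data.frame(co))
  expect_equal(back$patient_id, co$patient_id) # row order preserved
  expect_equal(length(unique(back$patient_id)), 2L)
})

test_that("validation rejects contract violations with informative errors", {
  co <- tiny_cohort(c("P1", "P2"))

  bad <- co
  bad$likert[2] <- 1L
  expect_error(validate_lesion_table(bad), class = "lesionval_validation_error")
  expect_error(validate_lesion_table(bad), "likert.*row 2")

  bad <- co
  bad$s_dw[1] <- 0L # volume still present
  expect_error(validate_lesion_table(bad), class = "lesionval_validation_error")
  expect_error(validate_lesion_table(bad), "not visible")

  bad <- co
  bad$s_t2 <- bad$s_dw <- bad$s_dce <- 0L
  bad$vol_t2 <- bad$vol_dw <- bad$vol_dce <- NA_real_
  expect_error(validate_lesion_table(bad), "any sequence")

  bad <- co
  bad$epe[1] <- TRUE # still benign
  expect_error(validate_lesion_table(bad), "benign")

  expect_error(validate_lesion_table(co[, setdiff(names(co), "ece_score")]),
               class = "lesionval_schema_error")
  expect_error(validate_lesion_table(co[, setdiff(names(co), "ece_score")]),
               "ece_score")
})

test_that("invalid CSV content fails at read time with the row index", {
  co <- tiny_cohort(c("P1", "P2"))
  co$likert[1] <- 1L
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(co, path, na = "")
  expect_error(read_lesion_table(path), class = "lesionval_validation_error")
})

test_that("csPCa definitions follow the grade-group and EPE rules", {
  # Gleason 9 (4+5) = grade group 5
  expect_true(label_cspca(5L, TRUE, "A"))
  expect_true(label_cspca(5L, TRUE, "B"))
  # benign findings are never csPCa
  for (d in c("A", "B", "C")) expect_false(label_cspca(0L, FALSE, d))
  # grade group 2 with extraprostatic extension
  expect_true(label_cspca(2L, TRUE, "A"))
  expect_false(label_cspca(2L, TRUE, "B"))
  expect_true(label_cspca(2L, TRUE, "C"))
})

test_that("labels under B and C are nested within A on any cohort", {
  co <- generate_cohort(cohort_params(n_patients = 120, seed = 11))
  lab <- add_cspca_labels(co)
  expect_true(all(lab$cspca_b <= lab$cspca_a))
  expect_true(all(lab$cspca_c <= lab$cspca_a))
})

test_that("prevalence counts evaluable lesions and is order-invariant", {
  co <- tiny_cohort(sprintf("P%d", 1:6),
                    gleason_group = c(0L, 2L, 3L, 0L, 0L, 5L),
                    epe = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))
  p <- prevalence(co, definition = "A")
  expect_equal(p$numerator, 3L)
  expect_equal(p$denominator, 6L)
  expect_equal(p$prevalence, 0.5)

  shuffled <- co[c(4, 2, 6, 1, 3, 5), ]
  expect_equal(prevalence(shuffled, definition = "A")$prevalence, 0.5)

  none <- tiny_cohort(c("P1", "P2")) # all benign
  expect_equal(prevalence(none, definition = "A")$prevalence, 0)
  all_pos <- tiny_cohort(c("P1", "P2"), gleason_group = 4L)
  expect_equal(prevalence(all_pos, definition = "A")$prevalence, 1)
})

test_that("excluded lesions are retained in storage but dropped at analysis", {
  co <- tiny_cohort(c("P1", "P2", "P3"), gleason_group = c(2L, 0L, 2L),
                    excluded = c(FALSE, FALSE, TRUE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_lesion_table(co, path)
  expect_equal(nrow(read_lesion_table(path)), 3L)
  p <- prevalence(co, definition = "A")
  expect_equal(p$denominator, 2L)
  expect_equal(p$numerator, 1L)

  all_excluded <- tiny_cohort("P1", excluded = TRUE)
  expect_error(prevalence(all_excluded, definition = "A"),
               class = "lesionval_validation_error")
})

test_that("pooled-reader tables must name the reader at analysis entry", {
  co <- dplyr::bind_rows(
    tiny_cohort(c("P1", "P2"), reader_id = "R1"),
    tiny_cohort(c("P1", "P2"), reader_id = "R2")
  )
  expect_error(analysis_records(co), class = "lesionval_validation_error")
  expect_equal(nrow(analysis_records(co, "R2")), 2L)
})
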