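# Statistical core: Mann-Whitney AUC, patient-clustered bootstrap, Harrell
# optimism correction, and the Likert baseline.
#
# Optimism of a model = E[AUC(fit on bootstrap sample, scored on bootstrap
# sample) - AUC(same fit, scored on original data)], estimated over
# patient-clustered bootstrap replicates; corrected AUC = apparent - mean
# optimism.

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Computes `P(score+ > score-) + 0.5 * P(score+ = score-)` via midranks,
#' which handles ties exactly.
#'
#' @param scores Numeric scores (higher = more suspicious).
#' @param labels 0/1 or logical outcome labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- as.numeric(sum(labels)) # double: counts can overflow integer math
  n_neg <- as.numeric(sum(!labels))
  if (n_pos == 0 || n_neg == 0) {
    abort_degenerate("AUC undefined: one outcome class is absent")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' @inheritParams auc_mw
#' @return A tibble with `threshold`, `fpr`, `tpr`, ordered for plotting.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(scores[labels] >= t), double(1)),
    fpr = vapply(thr, function(t) mean(scores[!labels] >= t), double(1))
  )
}

#' Patient-clustered bootstrap resample
#'
#' Draws `n_patients` patients with replacement; a drawn patient contributes
#' all of their lesions. Replicate copies of a patient receive distinct
#' synthetic cluster identifiers, so within-patient correlation is preserved
#' without merging copies. Uses the current RNG state.
#'
#' @param data A lesion table.
#' @return A lesion table with the same number of patients and a variable
#'   number of lesions.
#' @export
cluster_resample <- function(data) {
  patients <- sort(unique(data$patient_id))
  rows <- split(seq_len(nrow(data)), data$patient_id)
  draw <- sample.int(length(patients), length(patients), replace = TRUE)
  idx <- unlist(rows[draw], use.names = FALSE)
  out <- data[idx, , drop = FALSE]
  copy <- stats::ave(draw, draw, FUN = seq_along)
  out$patient_id <- rep(paste0(patients[draw], "#", copy),
                        lengths(rows[draw]))
  out
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

# shared replicate engine: draws patient-clustered row indices over a fixed
# row->patient map; returns NULL for the caller to mark a degenerate replicate
patient_index_table <- function(patient_id) {
  split(seq_along(patient_id), patient_id)
}

boot_ci <- function(values, center, conf_method) {
  q <- stats::quantile(values, c(0.025, 0.975), names = FALSE, type = 7)
  m <- mean(values)
  if (conf_method == "percentile") {
    c(q[1] - m + center, q[2] - m + center)
  } else { # basic
    c(center - (q[2] - m), center - (q[1] - m))
  }
}

#' Optimism-corrected AUC of one model by patient-clustered bootstrap
#'
#' Implements Harrell's optimism correction with resampling at the patient
#' level. The apparent AUC is the AUC of the full-data fit scored on the full
#' data. For each bootstrap replicate, the model is refit on the resampled
#' cohort; its AUC on the replicate minus its AUC scoring the original cohort
#' is one optimism draw. The corrected AUC is the apparent AUC minus the mean
#' optimism over non-degenerate replicates. The 95% CI is the percentile
#' interval of the replicate out-of-sample AUCs, recentred on the corrected
#' estimate (method switchable to `"basic"`).
#'
#' Replicates whose outcome collapses to a single class are skipped and
#' counted, never imputed.
#'
#' @param data A lesion table (one reader's lesions; see [analysis_records()]).
#' @param spec A one-row battery tibble or model-spec list.
#' @param definition csPCa definition, `"A"`, `"B"` or `"C"`.
#' @param B Number of bootstrap replicates; `B = 0` returns the apparent AUC
#'   as corrected with no interval.
#' @param seed Integer seed for the resampling stream (optional).
#' @param reader Reader to analyse when `data` holds several.
#' @param conf_method `"percentile"` (default) or `"basic"`.
#' @param ... Passed to [encode_design()].
#' @return A `lesion_validation` object; see [tidy.lesion_validation()].
#' @export
validate_model <- function(data, spec, definition = c("A", "B", "C"),
                           B = 1000, seed = NULL, reader = NULL,
                           conf_method = c("percentile", "basic"), ...) {
  definition <- match.arg(definition)
  conf_method <- match.arg(conf_method)
  spec <- as_model_spec(spec)
  rec <- analysis_records(data, reader)
  enc <- encode_design(rec, spec, definition, ...)
  fit0 <- fit_logistic(enc$x, enc$y)
  apparent <- auc_mw(fit0$fitted, enc$y)

  rows <- patient_index_table(rec$patient_id)
  npat <- length(rows)

  boot <- with_seed(seed, {
    res <- matrix(NA_real_, nrow = B, ncol = 2,
                  dimnames = list(NULL, c("auc_boot", "auc_orig")))
    fallbacks <- 0L
    b <- 0L
    while (b < B) {
      b <- b + 1L
      idx <- unlist(rows[sample.int(npat, npat, replace = TRUE)],
                    use.names = FALSE)
      yb <- enc$y[idx]
      if (sum(yb) == 0L || sum(yb) == length(yb)) next # degenerate, stays NA
      fit_b <- fit_logistic(enc$x[idx, , drop = FALSE], yb)
      if (fit_b$fallback) fallbacks <- fallbacks + 1L
      res[b, "auc_boot"] <- auc_mw(fit_b$fitted, yb)
      res[b, "auc_orig"] <- auc_mw(predict_design(fit_b, enc$x), enc$y)
    }
    list(res = res, fallbacks = fallbacks)
  })

  used <- which(!is.na(boot$res[, "auc_boot"]))
  n_degenerate <- B - length(used)
  if (B > 0 && length(used) == 0) {
    rlang::abort("all bootstrap replicates were degenerate (single-class outcome)",
                 class = "lesionval_validation_failure")
  }
  if (B > 0) {
    optimism <- boot$res[used, "auc_boot"] - boot$res[used, "auc_orig"]
    mean_optimism <- mean(optimism)
    corrected <- apparent - mean_optimism
    ci <- boot_ci(boot$res[used, "auc_orig"], corrected, conf_method)
  } else {
    mean_optimism <- 0
    corrected <- apparent
    ci <- c(NA_real_, NA_real_)
  }

  structure(
    list(
      model_name = spec$name,
      seq_variant = spec$seq_variant,
      definition = definition,
      reader = unique(rec$reader_id),
      apparent_auc = apparent,
      mean_optimism = mean_optimism,
      corrected_auc = corrected,
      ci_low = ci[1], ci_high = ci[2],
      n_boot_used = length(used),
      n_boot_degenerate = n_degenerate,
      n_fallback = boot$fallbacks,
      seed = seed,
      conf_method = conf_method,
      boot = tibble::tibble(
        auc_boot = boot$res[used, "auc_boot"],
        auc_orig = boot$res[used, "auc_orig"]
      ),
      fit = fit0
    ),
    class = "lesion_validation"
  )
}

#' Likert score as a diagnostic baseline
#'
#' Uses the reader's 5-level Likert score (2-5 on focal lesions) directly as
#' the diagnostic score. No model is fitted, so the optimism is 0 by
#' construction; the 95% CI is a patient-clustered percentile bootstrap of
#' the AUC itself.
#'
#' @inheritParams validate_model
#' @return A `lesion_validation` object with `model_name = "Likert"`.
#' @export
likert_baseline <- function(data, definition = c("A", "B", "C"),
                            B = 1000, seed = NULL, reader = NULL) {
  definition <- match.arg(definition)
  rec <- analysis_records(data, reader)
  y <- as.integer(label_cspca(rec$gleason_group, rec$epe, definition))
  apparent <- auc_mw(rec$likert, y)

  rows <- patient_index_table(rec$patient_id)
  npat <- length(rows)
  aucs <- with_seed(seed, {
    out <- rep(NA_real_, B)
    for (b in seq_len(B)) {
      idx <- unlist(rows[sample.int(npat, npat, replace = TRUE)],
                    use.names = FALSE)
      yb <- y[idx]
      if (sum(yb) == 0L || sum(yb) == length(yb)) next
      out[b] <- auc_mw(rec$likert[idx], yb)
    }
    out
  })
  used <- which(!is.na(aucs))
  ci <- if (B > 0 && length(used) > 0) {
    stats::quantile(aucs[used], c(0.025, 0.975), names = FALSE)
  } else {
    c(NA_real_, NA_real_)
  }

  structure(
    list(
      model_name = "Likert",
      seq_variant = NA_character_,
      definition = definition,
      reader = unique(rec$reader_id),
      apparent_auc = apparent,
      mean_optimism = 0,
      corrected_auc = apparent,
      ci_low = ci[1], ci_high = ci[2],
      n_boot_used = length(used),
      n_boot_degenerate = B - length(used),
      n_fallback = 0L,
      seed = seed,
      conf_method = "percentile",
      boot = tibble::tibble(auc_boot = aucs[used], auc_orig = aucs[used]),
      fit = NULL
    ),
    class = "lesion_validation"
  )
}

#' @export
print.lesion_validation <- function(x, ...) {
  cat("<lesion_validation> ", x$model_name,
      " (definition ", x$definition, ", reader ", x$reader, ")\n", sep = "")
  cat(sprintf("  apparent AUC %.3f, corrected %.3f [%.3f, %.3f], optimism %.4f\n",
              x$apparent_auc, x$corrected_auc, x$ci_low, x$ci_high,
              x$mean_optimism))
  cat(sprintf("  %d replicates used, %d degenerate\n",
              x$n_boot_used, x$n_boot_degenerate))
  invisible(x)
}

#' Tidy an optimism-corrected validation result
#'
#' @param x A `lesion_validation`.
#' @param ... Unused.
#' @return A one-row tibble: model, definition, reader, sequence variant,
#'   apparent and corrected AUC, optimism, CI bounds, replicate counts.
#' @export
tidy.lesion_validation <- function(x, ...) {
  tibble::tibble(
    model = x$model_name,
    seq_variant = x$seq_variant,
    definition = x$definition,
    reader = x$reader,
    apparent_auc = x$apparent_auc,
    mean_optimism = x$mean_optimism,
    corrected_auc = x$corrected_auc,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    n_boot_used = x$n_boot_used,
    n_boot_degenerate = x$n_boot_degenerate
  )
}

#' @rdname tidy.lesion_validation
#' @export
glance.lesion_validation <- function(x, ...) tidy(x, ...)
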