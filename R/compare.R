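# Paired bootstrap comparison of two models (or a model against the Likert
# baseline). Both models are refit on the same patient-clustered replicates;
# the replicate difference of their original-data AUCs drives the CI and the
# two-sided bootstrap p-value (recentred-null convention).

#' Compare two models by paired clustered bootstrap
#'
#' Fits `spec_a` and `spec_b` on the same patient-clustered bootstrap
#' replicates. The point estimate is the difference of the two
#' optimism-corrected AUCs. Per replicate, the difference of the
#' original-data AUCs of the replicate fits gives the bootstrap distribution;
#' the 95% CI is its percentile interval recentred on the point estimate, and
#' the two-sided p-value is `2 * min(F(0), 1 - F(0))` on that recentred
#' distribution, with ties at zero counted conservatively (so comparing a
#' model with itself gives delta = 0, p = 1 exactly).
#'
#' `spec_b = "likert"` compares against the reader's Likert score, which is
#' used directly as a score (no fitting, zero optimism); its replicate AUC is
#' computed on the replicate so its sampling variability enters the paired
#' difference.
#'
#' @inheritParams validate_model
#' @param spec_a,spec_b Battery rows or model-spec lists; `spec_b` may be the
#'   string `"likert"`.
#' @return A `lesion_comparison` object; see [tidy.lesion_comparison()].
#' @export
compare_models <- function(data, spec_a, spec_b, definition = c("A", "B", "C"),
                           B = 1000, seed = NULL, reader = NULL, ...) {
  definition <- match.arg(definition)
  spec_a <- as_model_spec(spec_a)
  likert_b <- is.character(spec_b) && length(spec_b) == 1 &&
    tolower(spec_b) == "likert"
  if (!likert_b) spec_b <- as_model_spec(spec_b)

  rec <- analysis_records(data, reader)
  enc_a <- encode_design(rec, spec_a, definition, ...)
  y <- enc_a$y
  fit_a0 <- fit_logistic(enc_a$x, y)
  apparent_a <- auc_mw(fit_a0$fitted, y)
  if (likert_b) {
    apparent_b <- auc_mw(rec$likert, y)
  } else {
    enc_b <- encode_design(rec, spec_b, definition, ...)
    fit_b0 <- fit_logistic(enc_b$x, y)
    apparent_b <- auc_mw(fit_b0$fitted, y)
  }

  rows <- patient_index_table(rec$patient_id)
  npat <- length(rows)

  boot <- with_seed(seed, {
    res <- matrix(NA_real_, nrow = B, ncol = 4,
                  dimnames = list(NULL, c("orig_a", "boot_a", "orig_b", "boot_b")))
    for (b in seq_len(B)) {
      idx <- unlist(rows[sample.int(npat, npat, replace = TRUE)],
                    use.names = FALSE)
      yb <- y[idx]
      if (sum(yb) == 0L || sum(yb) == length(yb)) next
      fb_a <- fit_logistic(enc_a$x[idx, , drop = FALSE], yb)
      res[b, "boot_a"] <- auc_mw(fb_a$fitted, yb)
      res[b, "orig_a"] <- auc_mw(predict_design(fb_a, enc_a$x), y)
      if (likert_b) {
        res[b, "boot_b"] <- auc_mw(rec$likert[idx], yb)
        res[b, "orig_b"] <- res[b, "boot_b"]
      } else {
        fb_b <- fit_logistic(enc_b$x[idx, , drop = FALSE], yb)
        res[b, "boot_b"] <- auc_mw(fb_b$fitted, yb)
        res[b, "orig_b"] <- auc_mw(predict_design(fb_b, enc_b$x), y)
      }
    }
    res
  })

  used <- which(!is.na(boot[, "orig_a"]))
  n_degenerate <- B - length(used)
  if (B > 0 && length(used) == 0) {
    rlang::abort("all bootstrap replicates were degenerate (single-class outcome)",
                 class = "lesionval_validation_failure")
  }

  if (B > 0) {
    corrected_a <- apparent_a -
      mean(boot[used, "boot_a"] - boot[used, "orig_a"])
    corrected_b <- if (likert_b) apparent_b else {
      apparent_b - mean(boot[used, "boot_b"] - boot[used, "orig_b"])
    }
    delta <- corrected_a - corrected_b
    d <- boot[used, "orig_a"] - boot[used, "orig_b"]
    dd <- d - mean(d) + delta
    p <- min(1, 2 * min(mean(dd <= 0), mean(dd >= 0)))
    q <- stats::quantile(d, c(0.025, 0.975), names = FALSE, type = 7)
    ci <- q - mean(d) + delta
  } else {
    corrected_a <- apparent_a
    corrected_b <- apparent_b
    delta <- corrected_a - corrected_b
    p <- NA_real_
    ci <- c(NA_real_, NA_real_)
    d <- double(0)
  }

  structure(
    list(
      model_a = spec_a$name,
      model_b = if (likert_b) "Likert" else spec_b$name,
      definition = definition,
      reader = unique(rec$reader_id),
      corrected_a = corrected_a,
      corrected_b = corrected_b,
      delta_auc = delta,
      ci_low = ci[1], ci_high = ci[2],
      p_value = p,
      n_boot_used = length(used),
      n_boot_degenerate = n_degenerate,
      seed = seed,
      boot_delta = d
    ),
    class = "lesion_comparison"
  )
}

#' @export
print.lesion_comparison <- function(x, ...) {
  cat("<lesion_comparison> ", x$model_a, " vs ", x$model_b,
      " (definition ", x$definition, ")\n", sep = "")
  cat(sprintf("  delta AUC %.3f [%.3f, %.3f], p = %.3g\n",
              x$delta_auc, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' Tidy a bootstrap model comparison
#'
#' @param x A `lesion_comparison`.
#' @param ... Unused.
#' @return A one-row tibble with the corrected AUCs, their difference, the
#'   bootstrap CI and p-value.
#' @export
tidy.lesion_comparison <- function(x, ...) {
  tibble::tibble(
    model_a = x$model_a,
    model_b = x$model_b,
    definition = x$definition,
    reader = x$reader,
    corrected_a = x$corrected_a,
    corrected_b = x$corrected_b,
    delta_auc = x$delta_auc,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    p_value = x$p_value,
    n_boot_used = x$n_boot_used,
    n_boot_degenerate = x$n_boot_degenerate
  )
}

#' @rdname tidy.lesion_comparison
#' @export
glance.lesion_comparison <- function(x, ...) tidy(x, ...)
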