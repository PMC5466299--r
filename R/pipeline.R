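# Full study replica: run the battery across readers x definitions x
# sequence-set variants, emit tidy result tables, Likert comparisons, and the
# median-delta-AUC summaries.

#' Configuration of a full study run
#'
#' @param input The cohort: a lesion-table CSV path, a lesion-table data
#'   frame, or [cohort_params()] (the cohort is then generated).
#' @param readers Readers to analyse; default all readers present.
#' @param definitions Subset of `c("A", "B", "C")`.
#' @param seq_variants Subset of `c("a", "b")`.
#' @param B Bootstrap replicates per model cell.
#' @param seed Base seed; per-cell seeds are derived from it deterministically.
#' @param include_likert Add the Likert baseline and best-model-vs-Likert
#'   comparisons.
#' @param conf_method CI method, `"percentile"` or `"basic"`.
#' @param out_dir Optional directory; when given, CSV/JSON outputs and a run
#'   log are written there.
#' @param ... Encoding options passed to [encode_design()].
#' @return A `study_config` list.
#' @export
study_config <- function(input, readers = NULL,
                         definitions = c("A", "B", "C"),
                         seq_variants = c("a", "b"),
                         B = 200, seed = 1, include_likert = TRUE,
                         conf_method = "percentile", out_dir = NULL, ...) {
  definitions <- match.arg(definitions, several.ok = TRUE)
  seq_variants <- match.arg(seq_variants, c("a", "b"), several.ok = TRUE)
  structure(
    list(input = input, readers = readers, definitions = definitions,
         seq_variants = seq_variants, B = B, seed = as.integer(seed),
         include_likert = include_likert, conf_method = conf_method,
         out_dir = out_dir, encode_opts = list(...)),
    class = "study_config"
  )
}

resolve_cohort <- function(input) {
  if (inherits(input, "cohort_params")) {
    generate_cohort(input)
  } else if (is.character(input) && length(input) == 1) {
    read_lesion_table(input)
  } else if (is.data.frame(input)) {
    validate_lesion_table(input)
    tibble::as_tibble(input)
  } else {
    abort_config("input must be a CSV path, a lesion table, or cohort_params()")
  }
}

cell_seed <- function(base, counter) {
  as.integer((as.double(base) * 100003 + counter) %% 2147483647)
}

#' Run the full model-battery study
#'
#' For every (reader, definition, sequence variant, model) cell, computes the
#' optimism-corrected AUC by patient-clustered bootstrap; adds the Likert
#' baseline and a best-model-vs-Likert comparison per (reader, definition);
#' and summarizes, per (reader, definition), the median delta-AUC (with IQR)
#' of the multivariable battery against Signal1a and Signal1b and of the
#' with- vs without-DCE model pairs. Readers are independent strata end to
#' end. A rerun with an identical configuration reproduces every number.
#'
#' @param config A [study_config()].
#' @return A `lesion_study` list: `results` (one row per model cell),
#'   `comparisons`, `summary`, `battery` (the model grids used), `config`,
#'   and `log` (per-cell fit diagnostics). Written as CSV/JSON to
#'   `config$out_dir` when set.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cohort <- resolve_cohort(config$input)
  readers <- config$readers %||% sort(unique(cohort$reader_id))

  battery <- lapply(stats::setNames(config$seq_variants, config$seq_variants),
                    function(v) build_battery(config$definitions[1], v))
  results <- list()
  comparisons <- list()
  log_lines <- character(0)
  counter <- 0L

  for (rd in readers) {
    for (def in config$definitions) {
      for (v in config$seq_variants) {
        bat <- battery[[v]]
        for (i in seq_len(nrow(bat))) {
          counter <- counter + 1L
          spec <- bat[i, ]
          val <- tryCatch(
            rlang::exec(validate_model, cohort, spec, def,
                        B = config$B, seed = cell_seed(config$seed, counter),
                        reader = rd, conf_method = config$conf_method,
                        !!!config$encode_opts),
            error = function(e) {
              rlang::abort(
                sprintf("validation failed at (%s, %s, %s, %s): %s",
                        rd, def, spec$name[[1]], v, conditionMessage(e)),
                class = "lesionval_pipeline_error", parent = e)
            }
          )
          row <- tidy(val)
          row$role <- spec$role[[1]]
          results[[length(results) + 1L]] <- row
          if (val$n_fallback > 0 || val$n_boot_degenerate > 0 ||
              length(val$fit$dropped_terms) > 0) {
            log_lines <- c(log_lines, sprintf(
              "(%s, %s, %s, %s): %d ridge fallbacks, %d degenerate replicates, %d aliased terms",
              rd, def, spec$name[[1]], v, val$n_fallback,
              val$n_boot_degenerate, length(val$fit$dropped_terms)))
          }
        }
      }
      if (config$include_likert) {
        counter <- counter + 1L
        lik <- likert_baseline(cohort, def, B = config$B,
                               seed = cell_seed(config$seed, counter),
                               reader = rd)
        row <- tidy(lik)
        row$role <- "baseline"
        results[[length(results) + 1L]] <- row
      }
    }
  }
  results <- dplyr::bind_rows(results)

  summaries <- list()
  for (rd in readers) {
    for (def in config$definitions) {
      res_cell <- dplyr::filter(results, .data$reader == rd,
                                .data$definition == def)
      fam <- unique(signal1_family(battery[[1]])$name)
      multi <- dplyr::filter(res_cell, .data$role %in% c("signal", "augmented"),
                             .data$model != "S_Max")
      best <- multi[which.max(multi$corrected_auc), ]
      srow <- tibble::tibble(
        reader = rd, definition = def,
        best_model = best$model, best_variant = best$seq_variant,
        best_corrected_auc = best$corrected_auc,
        signal1a_auc = lookup_auc(res_cell, "Signal1", "a"),
        signal1b_auc = lookup_auc(res_cell, "Signal1", "b"),
        likert_auc = if (config$include_likert)
          lookup_auc(res_cell, "Likert", NA) else NA_real_
      )
      aug <- setdiff(fam, "Signal1")
      for (v in config$seq_variants) {
        sd <- summarize_delta(res_cell, pairing = "baseline",
                              baseline = "Signal1", variant = v, models = aug)
        srow[[paste0("median_dauc_vs_signal1", v)]] <- sd$median_delta
        srow[[paste0("iqr_low_vs_signal1", v)]] <- sd$iqr_low
        srow[[paste0("iqr_high_vs_signal1", v)]] <- sd$iqr_high
      }
      if (all(c("a", "b") %in% config$seq_variants)) {
        sd <- summarize_delta(res_cell, pairing = "dce", models = fam)
        srow$median_dauc_dce <- sd$median_delta
        srow$iqr_low_dce <- sd$iqr_low
        srow$iqr_high_dce <- sd$iqr_high
      }
      summaries[[length(summaries) + 1L]] <- srow

      if (config$include_likert) {
        counter <- counter + 1L
        bat <- battery[[best$seq_variant]]
        best_spec <- dplyr::filter(bat, .data$name == best$model,
                                   .data$role %in% c("signal", "augmented"))[1, ]
        cmp <- compare_models(cohort, best_spec, "likert", def,
                              B = config$B,
                              seed = cell_seed(config$seed, counter),
                              reader = rd)
        comparisons[[length(comparisons) + 1L]] <- tidy(cmp)
      }
    }
  }
  summary_tbl <- dplyr::bind_rows(summaries)
  comparisons <- if (length(comparisons)) dplyr::bind_rows(comparisons) else
    tibble::tibble()

  study <- structure(
    list(results = results, comparisons = comparisons,
         summary = summary_tbl, battery = battery,
         config = config, log = log_lines),
    class = "lesion_study"
  )
  if (!is.null(config$out_dir)) write_study(study, config$out_dir)
  study
}

lookup_auc <- function(res, model, variant) {
  rows <- res[res$model == model &
                (is.na(variant) | res$seq_variant %in% variant), ]
  if (nrow(rows) == 0) NA_real_ else rows$corrected_auc[1]
}

#' Median delta-AUC summaries over the multivariable battery
#'
#' Two pairing rules are supported. `"baseline"` pairs every model in
#' `models` (at sequence variant `variant`) against the `baseline` model at
#' the same variant: a positive difference means the multivariable model
#' outperforms the baseline. `"dce"` pairs each model's variant-a and
#' variant-b rows: a positive difference means the model performs better with
#' DCE imaging.
#'
#' @param results Tidy validation rows (columns `model`, `seq_variant`,
#'   `corrected_auc`) for one (reader, definition) stratum.
#' @param pairing `"baseline"` or `"dce"`.
#' @param baseline Baseline model name for `pairing = "baseline"`.
#' @param variant Sequence variant for `pairing = "baseline"`.
#' @param models Model names entering the summary.
#' @return A one-row tibble: `median_delta`, `iqr_low`, `iqr_high`,
#'   `n_models`.
#' @export
summarize_delta <- function(results, pairing = c("baseline", "dce"),
                            baseline = "Signal1", variant = "a",
                            models = NULL) {
  pairing <- match.arg(pairing)
  if (is.null(models)) {
    abort_config("`models` must name the models entering the summary")
  }
  get_auc <- function(model, v) {
    rows <- results[results$model == model & results$seq_variant == v, ]
    if (nrow(rows) == 0) {
      rlang::abort(sprintf("unpaired model: '%s' (variant %s) has no row",
                           model, v),
                   class = "lesionval_pairing_error")
    }
    rows$corrected_auc[1]
  }
  deltas <- if (pairing == "baseline") {
    base_auc <- get_auc(baseline, variant)
    vapply(models, function(m) get_auc(m, variant) - base_auc, double(1))
  } else {
    vapply(models, function(m) get_auc(m, "a") - get_auc(m, "b"), double(1))
  }
  q <- stats::quantile(deltas, c(0.25, 0.75), names = FALSE, type = 7)
  tibble::tibble(
    median_delta = stats::median(deltas),
    iqr_low = q[1], iqr_high = q[2],
    n_models = length(deltas)
  )
}

write_study <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (def in unique(study$results$definition)) {
    readr::write_csv(
      dplyr::filter(study$results, .data$definition == def),
      file.path(out_dir, paste0("validation_", def, ".csv")))
  }
  if (nrow(study$comparisons) > 0) {
    readr::write_csv(study$comparisons, file.path(out_dir, "comparisons.csv"))
  }
  readr::write_csv(study$summary, file.path(out_dir, "summary.csv"))
  for (v in names(study$battery)) {
    write_battery_manifest(study$battery[[v]],
                           file.path(out_dir, paste0("battery_", v, ".json")))
  }
  writeLines(study$log, file.path(out_dir, "run_log.txt"))
  cfg <- study$config
  cfg$input <- if (is.character(cfg$input)) cfg$input else
    paste0("<", class(cfg$input)[1], ">")
  cfg$out_dir <- NULL # environment-specific, not part of the analysis config
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(out_dir)
}

#' @export
print.lesion_study <- function(x, ...) {
  cat("<lesion_study> ", nrow(x$results), " model cells, readers: ",
      paste(unique(x$results$reader), collapse = ", "), "\n", sep = "")
  print(x$summary)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
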