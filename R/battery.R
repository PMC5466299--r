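# The logistic model battery: 9 univariable models, the signal-combination
# models (S_Max, Signal1 = S_Max + S_Min, Signal2 = S_Max* + S_Min* + S_DW,
# Signal3 = per-sequence scores), and Signal1 plus every non-empty subset of
# {Shape, ECE, V_Max, dPSA} — each in an "a" (with DCE) and "b" (without DCE)
# sequence-set variant.

# sequences backing S_Max / S_Min inside the Signal2 model, where DW findings
# are carried separately by S_DW
signal2_sequences <- function(variant = c("a", "b")) {
  variant <- match.arg(variant)
  if (variant == "a") c("T2W", "DCE") else "T2W"
}

new_model_spec <- function(name, predictors, smax_seqs, seq_variant, role) {
  list(name = name, predictors = predictors, smax_seqs = smax_seqs,
       seq_variant = seq_variant, role = role)
}

#' Define a custom model specification
#'
#' Builds a model-spec usable anywhere a battery row is accepted, e.g. for
#' sensitivity analyses with extra covariates or an intercept-only model
#' (`predictors = character(0)`). Predictors named `s_t2`, `s_dw`, `s_dce`,
#' `s_max` and `ece_score` are encoded as ordinal categoricals,
#' `shape_grouped` as a categorical, `s_min_any` as 0/1, and anything else
#' (including arbitrary columns of the lesion table) as a continuous
#' passthrough.
#'
#' @param name Model name.
#' @param predictors Character vector of predictor names.
#' @param smax_seqs Sequences backing `s_max`/`s_min_any` if used.
#' @param seq_variant Sequence-set tag, `"a"` or `"b"`.
#' @return A model-spec list.
#' @export
model_spec <- function(name, predictors, smax_seqs = mri_sequences("a"),
                       seq_variant = "a") {
  check_seqs(smax_seqs)
  new_model_spec(name, predictors, smax_seqs, seq_variant, "custom")
}

as_model_spec <- function(spec) {
  if (is.data.frame(spec)) {
    stopifnot(nrow(spec) == 1)
    spec <- new_model_spec(spec$name[[1]], spec$predictors[[1]],
                           spec$smax_seqs[[1]], spec$seq_variant[[1]],
                           spec$role[[1]])
  }
  stopifnot(is.list(spec), !is.null(spec$name), !is.null(spec$predictors))
  spec
}

battery_tibble <- function(specs) {
  tibble::tibble(
    name = vapply(specs, `[[`, character(1), "name"),
    role = vapply(specs, `[[`, character(1), "role"),
    seq_variant = vapply(specs, `[[`, character(1), "seq_variant"),
    predictors = lapply(specs, `[[`, "predictors"),
    smax_seqs = lapply(specs, `[[`, "smax_seqs")
  )
}

#' Build the logistic model battery
#'
#' Returns the full model grid for one sequence-set variant, in fixed order:
#' for variant `"a"`, 9 univariable models (S_T2, S_DW, S_DCE, S_Max, S_Min,
#' Shape, ECE, V_Max, dPSA), then the signal models S_Max, Signal1, Signal2,
#' Signal3, then Signal1 augmented with every non-empty subset of
#' {Shape, ECE, V_Max, dPSA} (15 models). Variant `"b"` drops DCE everywhere:
#' no univariable block, S_Max/S_Min computed over T2W and DW only, Signal2's
#' starred features over T2W only, Signal3 reduced to S_T2 + S_DW.
#'
#' @param definition csPCa definition the battery is intended for (stored on
#'   the result; the model grid itself is definition-independent).
#' @param seq_variant `"a"` (with DCE) or `"b"` (without DCE).
#' @return A tibble with columns `name`, `role` (`univariable`, `signal`,
#'   `augmented`), `seq_variant`, and list-columns `predictors` and
#'   `smax_seqs` (sequences backing `s_max`/`s_min_any` in that model).
#' @export
build_battery <- function(definition = c("A", "B", "C"),
                          seq_variant = c("a", "b")) {
  definition <- match.arg(definition)
  seq_variant <- match.arg(seq_variant)
  seqs <- mri_sequences(seq_variant)
  s2 <- signal2_sequences(seq_variant)

  specs <- list()
  if (seq_variant == "a") {
    uni <- list(
      S_T2 = "s_t2", S_DW = "s_dw", S_DCE = "s_dce",
      S_Max = "s_max", S_Min = "s_min_any",
      Shape = "shape_grouped", ECE = "ece_score",
      V_Max = "v_max", dPSA = "dpsa"
    )
    for (nm in names(uni)) {
      specs <- c(specs, list(new_model_spec(nm, uni[[nm]], seqs,
                                            seq_variant, "univariable")))
    }
  }
  specs <- c(specs, list(
    new_model_spec("S_Max", "s_max", seqs, seq_variant, "signal"),
    new_model_spec("Signal1", c("s_max", "s_min_any"), seqs,
                   seq_variant, "signal"),
    new_model_spec("Signal2", c("s_max", "s_min_any", "s_dw"), s2,
                   seq_variant, "signal"),
    new_model_spec("Signal3",
                   if (seq_variant == "a") c("s_t2", "s_dw", "s_dce")
                   else c("s_t2", "s_dw"),
                   seqs, seq_variant, "signal")
  ))

  covs <- c(Shape = "shape_grouped", ECE = "ece_score",
            Vmax = "v_max", dPSA = "dpsa")
  for (k in 1:4) {
    for (sub in utils::combn(names(covs), k, simplify = FALSE)) {
      specs <- c(specs, list(new_model_spec(
        paste(c("Signal1", sub), collapse = "+"),
        c("s_max", "s_min_any", unname(covs[sub])),
        seqs, seq_variant, "augmented"
      )))
    }
  }

  out <- battery_tibble(specs)
  attr(out, "definition") <- definition
  out
}

#' The Signal1 model family
#'
#' The 16 models of the multivariable grid built on Signal1: Signal1 itself
#' plus its 15 covariate-augmented variants.
#'
#' @param battery A battery from [build_battery()].
#' @return The matching rows of `battery`.
#' @export
signal1_family <- function(battery) {
  dplyr::filter(battery,
                .data$role == "augmented" | .data$name == "Signal1")
}

#' Write a battery manifest as JSON
#'
#' Emits `name -> (role, seq_variant, predictors, smax_seqs)` so result
#' tables are join-able by model name.
#'
#' @param battery A battery tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_battery_manifest <- function(battery, path) {
  manifest <- lapply(seq_len(nrow(battery)), function(i) {
    list(name = battery$name[[i]], role = battery$role[[i]],
         seq_variant = battery$seq_variant[[i]],
         predictors = battery$predictors[[i]],
         smax_seqs = battery$smax_seqs[[i]])
  })
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# ---- design encoding ------------------------------------------------------

ordinal_predictors <- function() c("s_t2", "s_dw", "s_dce", "s_max", "ece_score")

canonical_levels <- function(predictor, smax_seqs) {
  switch(predictor,
    s_t2 = , s_dw = , s_dce = 0:3,
    s_max = 0:length(smax_seqs),
    ece_score = 1:5,
    NULL
  )
}

# merge factor levels with < threshold observations into the adjacent level
# toward the reference (the previous level in level order)
collapse_sparse_levels <- function(f, threshold) {
  lv <- levels(f)
  cnt <- as.integer(table(f))
  merged <- character(0)
  map <- stats::setNames(lv, lv)
  for (k in rev(seq_along(lv))) {
    if (k == 1) break
    if (cnt[k] > 0 && cnt[k] < threshold) {
      cnt[k - 1] <- cnt[k - 1] + cnt[k]
      cnt[k] <- 0L
      map[map == lv[k]] <- lv[k - 1]
      merged <- c(merged, lv[k])
    }
  }
  list(f = factor(unname(map[as.character(f)]), levels = unique(unname(map[lv]))),
       merged = merged)
}

#' Encode the design matrix for one model specification
#'
#' Ordinal and shape predictors enter as indicator contrasts against the
#' lowest observed level; `s_min_any` is a single 0/1 column; V_Max and dPSA
#' pass through untransformed (optionally log-transformed). Levels of an
#' ordinal predictor that are absent from the data are dropped with a warning;
#' levels with fewer than `collapse_threshold` observations are merged into
#' the adjacent level toward the reference.
#'
#' @param data A single-reader lesion table (analysis rows).
#' @param spec A one-row battery tibble or model-spec list.
#' @param definition csPCa definition used to build the label vector.
#' @param ordinal_coding `"categorical"` (default: indicator contrasts) or
#'   `"linear"` (ordinal scores enter as numeric), a sensitivity switch.
#' @param log_continuous If `TRUE`, V_Max and dPSA enter on the log scale.
#' @param collapse_threshold Minimum observations per categorical level
#'   before it is merged toward the reference; 0 disables collapsing.
#' @return A list with `x` (design matrix including intercept), `y` (0/1
#'   labels), `spec`, and bookkeeping fields `dropped_levels` and
#'   `collapsed_levels`.
#' @export
encode_design <- function(data, spec, definition = c("A", "B", "C"),
                          ordinal_coding = c("categorical", "linear"),
                          log_continuous = FALSE,
                          collapse_threshold = 3) {
  definition <- match.arg(definition)
  ordinal_coding <- match.arg(ordinal_coding)
  spec <- as_model_spec(spec)

  need <- spec$predictors
  if (any(c("s_max", "s_min_any", "v_max", "shape_grouped") %in% need)) {
    data <- augment_features(data, seqs = spec$smax_seqs)
  }
  y <- as.integer(label_cspca(data$gleason_group, data$epe, definition))

  cols <- list()
  dropped <- character(0)
  collapsed <- character(0)
  for (p in need) {
    if (!p %in% names(data)) {
      abort_schema(paste0("predictor not found in data: ", p))
    }
    v <- data[[p]]
    if (p %in% ordinal_predictors() && ordinal_coding == "categorical") {
      canon <- canonical_levels(p, spec$smax_seqs)
      absent <- setdiff(canon, unique(v))
      if (length(absent) > 0) {
        dropped <- c(dropped, paste0(p, "=", absent))
        rlang::warn(paste0("level(s) absent from data dropped for ", p, ": ",
                           paste(absent, collapse = ", ")),
                    class = "lesionval_dropped_level")
      }
      f <- factor(v, levels = intersect(canon, unique(v)))
    } else if (p == "shape_grouped") {
      lv <- intersect(shape_levels(grouped = TRUE), unique(v))
      f <- factor(v, levels = lv)
    } else {
      val <- as.numeric(v)
      if (log_continuous && p %in% c("v_max", "dpsa")) val <- log(val)
      cols[[p]] <- val
      next
    }
    if (collapse_threshold > 0 && nlevels(f) > 1) {
      cs <- collapse_sparse_levels(f, collapse_threshold)
      if (length(cs$merged) > 0) {
        collapsed <- c(collapsed, paste0(p, "=", cs$merged))
      }
      f <- cs$f
    }
    if (nlevels(f) < 2) next # constant predictor contributes no columns
    cols[[p]] <- f
  }

  if (length(cols) == 0) {
    x <- matrix(1, nrow = nrow(data), ncol = 1,
                dimnames = list(NULL, "(Intercept)"))
  } else {
    df <- as.data.frame(cols, optional = TRUE)
    x <- stats::model.matrix(~., data = df)
    rownames(x) <- NULL
  }
  list(x = x, y = y, spec = spec, definition = definition,
       dropped_levels = dropped, collapsed_levels = collapsed)
}
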