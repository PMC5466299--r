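# Derived signal features: S_Max (number of sequences with a marked
# abnormality), S_Min (any sequence on which the lesion is invisible,
# dichotomized 0 vs >= 1), V_Max (largest per-sequence volume), and the
# grouped shape recoding. All pure, row-wise operations.

#' MRI sequence sets
#'
#' Sequence-set variants used throughout the model battery: variant `"a"`
#' uses all three pulse sequences, variant `"b"` drops dynamic
#' contrast-enhanced (DCE) imaging.
#'
#' @param variant `"a"` (T2W, DW, DCE) or `"b"` (T2W, DW).
#' @return Character vector of sequence names.
#' @export
mri_sequences <- function(variant = c("a", "b")) {
  variant <- match.arg(variant)
  if (variant == "a") c("T2W", "DW", "DCE") else c("T2W", "DW")
}

# score / volume columns backing a sequence set
seq_score_cols <- function(seqs) {
  unname(c(T2W = "s_t2", DW = "s_dw", DCE = "s_dce")[seqs])
}
seq_vol_cols <- function(seqs) {
  unname(c(T2W = "vol_t2", DW = "vol_dw", DCE = "vol_dce")[seqs])
}

#' Number of sequences showing a marked signal abnormality (S_Max)
#'
#' @param data A lesion table.
#' @param seqs Sequence set, a subset of `c("T2W", "DW", "DCE")`.
#' @return Integer vector, one count per lesion, in `0..length(seqs)`.
#' @export
compute_smax <- function(data, seqs = mri_sequences("a")) {
  check_seqs(seqs)
  s <- as.matrix(data[seq_score_cols(seqs)])
  as.integer(rowSums(s == 3))
}

#' Any sequence on which the lesion is not visible (S_Min, dichotomized)
#'
#' @inheritParams compute_smax
#' @return Integer vector: 1 if the lesion is invisible (score 0) on at least
#'   one sequence of the set, else 0.
#' @export
compute_smin <- function(data, seqs = mri_sequences("a")) {
  check_seqs(seqs)
  s <- as.matrix(data[seq_score_cols(seqs)])
  as.integer(rowSums(s == 0) > 0)
}

#' Largest per-sequence lesion volume (V_Max)
#'
#' The maximum over the volumes measured on the sequences where the lesion is
#' visible; a lesion invisible on a sequence contributes no volume there.
#'
#' @param data A lesion table.
#' @return Numeric vector of volumes in mL.
#' @export
compute_vmax <- function(data) {
  v <- as.matrix(data[seq_vol_cols(c("T2W", "DW", "DCE"))])
  if (any(rowSums(!is.na(v)) == 0)) {
    rlang::abort("lesion with no measured volume on any sequence",
                 class = "lesionval_feature_error")
  }
  apply(v, 1, max, na.rm = TRUE)
}

#' Grouped shape category
#'
#' Ill-defined areas and linear lesions perpendicular to the capsule are
#' merged into a single category; the other levels pass through, giving the
#' 6-level vocabulary of `shape_levels(grouped = TRUE)`.
#'
#' @param shape Character vector over `shape_levels()`.
#' @return Character vector over the grouped vocabulary.
#' @export
recode_shape <- function(shape) {
  bad <- setdiff(unique(shape), shape_levels())
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown shape level: ", paste(bad, collapse = ", ")),
                 class = "lesionval_feature_error")
  }
  ifelse(shape %in% c("ill_defined", "linear_perpendicular"),
         "ill_defined_or_linear_perp", shape)
}

check_seqs <- function(seqs) {
  if (length(seqs) == 0 || !all(seqs %in% c("T2W", "DW", "DCE"))) {
    rlang::abort("seqs must be a non-empty subset of c('T2W', 'DW', 'DCE')",
                 class = "lesionval_feature_error")
  }
  invisible(seqs)
}

#' Append derived features to a lesion table
#'
#' Adds `s_max`, `s_min_any` (computed over `seqs`), `v_max` and
#' `shape_grouped`. When `tag` is given the sequence-set-dependent columns are
#' suffixed (e.g. `s_max_a`, `s_max_b`), so both variants can coexist.
#'
#' @param data A lesion table.
#' @param seqs Sequence set for `s_max` / `s_min_any`.
#' @param tag Optional suffix naming the sequence set.
#' @return `data` with feature columns appended.
#' @export
augment_features <- function(data, seqs = mri_sequences("a"), tag = NULL) {
  sfx <- if (is.null(tag)) "" else paste0("_", tag)
  data[[paste0("s_max", sfx)]] <- compute_smax(data, seqs)
  data[[paste0("s_min_any", sfx)]] <- compute_smin(data, seqs)
  data$v_max <- compute_vmax(data)
  data$shape_grouped <- recode_shape(data$shape)
  data
}
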