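# Lesion-table data model: column contract, validation, csPCa labelling,
# prevalence. One row per (reader, lesion); the patient is the clustering unit.

#' Canonical lesion-table columns
#'
#' The lesion table has one row per (reader, lesion). Ordinal signal scores
#' take values 0 (not visible) to 3 (marked); per-sequence volumes are in mL
#' and absent (`NA`) when the lesion is not visible on that sequence; `dpsa`
#' is the PSA density in ng/mL/mL, repeated for every lesion of a patient;
#' `gleason_group` is the ISUP grade group (0 = benign, 1-5); `epe` flags
#' lesion-level histological extraprostatic extension.
#'
#' @return Character vector of required column names, in canonical order.
#' @export
lesion_columns <- function() {
  c("patient_id", "reader_id",
    "s_t2", "s_dw", "s_dce",
    "vol_t2", "vol_dw", "vol_dce",
    "shape", "ece_score", "likert", "dpsa",
    "gleason_group", "epe", "excluded")
}

#' Shape vocabulary of the lesion table
#'
#' @param grouped If `TRUE`, return the 6-level grouped vocabulary in which
#'   ill-defined areas and linear lesions perpendicular to the capsule form a
#'   single category (the coding used for modelling).
#' @return Character vector of shape levels.
#' @export
shape_levels <- function(grouped = FALSE) {
  if (grouped) {
    c("not_visible", "ill_defined_or_linear_perp", "linear_parallel",
      "triangular", "nodular_no_mass_effect", "nodular_mass_effect")
  } else {
    c("not_visible", "ill_defined", "linear_perpendicular", "linear_parallel",
      "triangular", "nodular_no_mass_effect", "nodular_mass_effect")
  }
}

abort_schema <- function(msg) rlang::abort(msg, class = "lesionval_schema_error")
abort_validation <- function(msg) rlang::abort(msg, class = "lesionval_validation_error")

#' Validate a lesion table
#'
#' Checks the column contract and the row-level invariants: ordinal fields in
#' range, Likert >= 2 (a focal lesion is by definition at least "likely
#' benign"), volumes absent exactly where the lesion is invisible, at least
#' one sequence showing the lesion, and no extraprostatic extension on benign
#' findings.
#'
#' @param data A data frame with the columns of [lesion_columns()].
#' @return `data` as a tibble, invisibly classed as a validated lesion table.
#' @export
validate_lesion_table <- function(data) {
  missing <- setdiff(lesion_columns(), names(data))
  if (length(missing) > 0) {
    abort_schema(paste0("missing mandatory column(s): ",
                        paste(missing, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)

  bad_rows <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0) {
      abort_validation(sprintf("%s (row %s)", what,
                               paste(utils::head(idx, 5), collapse = ", ")))
    }
  }

  ord_in <- function(x, lo, hi) !is.na(x) & x == floor(x) & x >= lo & x <= hi
  for (col in c("s_t2", "s_dw", "s_dce")) {
    bad_rows(!ord_in(data[[col]], 0, 3),
             sprintf("signal score '%s' outside 0..3", col))
  }
  bad_rows(!ord_in(data$ece_score, 1, 5), "ece_score outside 1..5")
  bad_rows(!ord_in(data$likert, 2, 5),
           "likert outside 2..5 (focal lesions have Likert >= 2)")
  bad_rows(!ord_in(data$gleason_group, 0, 5), "gleason_group outside 0..5")
  bad_rows(is.na(data$dpsa) | data$dpsa <= 0, "dpsa must be > 0")
  bad_rows(!data$shape %in% shape_levels(), "unknown shape level")
  bad_rows(is.na(data$epe), "epe must be TRUE/FALSE")
  bad_rows(is.na(data$excluded), "excluded must be TRUE/FALSE")

  for (seq in c("t2", "dw", "dce")) {
    s <- data[[paste0("s_", seq)]]
    v <- data[[paste0("vol_", seq)]]
    bad_rows(s == 0 & !is.na(v),
             sprintf("volume recorded on %s where the lesion is not visible (s_%s = 0)",
                     toupper(seq), seq))
    bad_rows(!is.na(v) & v < 0, sprintf("negative vol_%s", seq))
  }
  bad_rows(data$s_t2 == 0 & data$s_dw == 0 & data$s_dce == 0,
           "lesion not visible on any sequence")
  bad_rows(data$epe & data$gleason_group == 0,
           "extraprostatic extension flagged on a benign finding")

  invisible(data)
}

#' Read a lesion table from CSV
#'
#' The file must carry a header with exactly the names of [lesion_columns()];
#' per-sequence volumes may be empty where the lesion is invisible. Excluded
#' rows (e.g. DW artefacts) are retained and flagged; they are dropped only
#' at analysis entry.
#'
#' @param path Path to a UTF-8 CSV file.
#' @return A tibble, one row per (reader, lesion), validated.
#' @export
read_lesion_table <- function(path) {
  if (!file.exists(path)) abort_schema(paste0("file not found: ", path))
  data <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      reader_id = readr::col_character(),
      s_t2 = readr::col_integer(),
      s_dw = readr::col_integer(),
      s_dce = readr::col_integer(),
      vol_t2 = readr::col_double(),
      vol_dw = readr::col_double(),
      vol_dce = readr::col_double(),
      shape = readr::col_character(),
      ece_score = readr::col_integer(),
      likert = readr::col_integer(),
      dpsa = readr::col_double(),
      gleason_group = readr::col_integer(),
      epe = readr::col_logical(),
      excluded = readr::col_logical()
    ),
    na = c("", "NA")
  )
  validate_lesion_table(data)
  data
}

#' Write a lesion table to CSV
#'
#' Inverse of [read_lesion_table()]: absent volumes are written as empty
#' strings, so `read_lesion_table(write_lesion_table(x, f))` round-trips.
#'
#' @param data A lesion table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lesion_table <- function(data, path) {
  validate_lesion_table(data)
  readr::write_csv(data[lesion_columns()], path, na = "")
  invisible(path)
}

#' Label lesions as clinically significant cancer
#'
#' Three alternative definitions of clinically significant prostate cancer
#' (csPCa) are supported:
#' \describe{
#'   \item{A}{Gleason >= 7, i.e. ISUP grade group >= 2.}
#'   \item{B}{Gleason >= 7(4+3), i.e. ISUP grade group >= 3.}
#'   \item{C}{ISUP grade group >= 2 with histologically proven extraprostatic
#'     extension (pathological stage >= pT3a).}
#' }
#' On any cohort the positive sets under B and C are subsets of those under A.
#'
#' @param gleason_group Integer ISUP grade group, 0 (benign) to 5.
#' @param epe Logical, lesion-level histological extraprostatic extension.
#' @param definition One of `"A"`, `"B"`, `"C"`.
#' @return Logical vector: `TRUE` where the lesion is csPCa under the
#'   definition.
#' @export
label_cspca <- function(gleason_group, epe, definition = c("A", "B", "C")) {
  definition <- match.arg(definition)
  switch(definition,
    A = gleason_group >= 2,
    B = gleason_group >= 3,
    C = gleason_group >= 2 & epe
  )
}

#' Append csPCa labels to a lesion table
#'
#' Adds `cspca_a`, `cspca_b`, `cspca_c` columns coded 0/1.
#'
#' @param data A lesion table.
#' @return `data` with three label columns appended.
#' @export
add_cspca_labels <- function(data) {
  dplyr::mutate(
    data,
    cspca_a = as.integer(label_cspca(.data$gleason_group, .data$epe, "A")),
    cspca_b = as.integer(label_cspca(.data$gleason_group, .data$epe, "B")),
    cspca_c = as.integer(label_cspca(.data$gleason_group, .data$epe, "C"))
  )
}

#' Restrict a cohort to the analysis set of one reader
#'
#' Analyses never pool readers: the analysis unit is the lesion as described
#' by one reader. Excluded lesions are dropped here (they are retained in
#' storage).
#'
#' @param data A lesion table.
#' @param reader Reader identifier; may be omitted when the table contains a
#'   single reader.
#' @return The non-excluded rows of that reader.
#' @export
analysis_records <- function(data, reader = NULL) {
  readers <- unique(data$reader_id)
  if (is.null(reader)) {
    if (length(readers) > 1) {
      abort_validation(
        "table contains several readers; analyses are single-reader, pass `reader`")
    }
    reader <- readers
  }
  dplyr::filter(data, .data$reader_id == reader, !.data$excluded)
}

#' Prevalence of csPCa in a cohort
#'
#' @param data A lesion table.
#' @param reader Reader identifier (see [analysis_records()]).
#' @param definition csPCa definition, `"A"`, `"B"` or `"C"`.
#' @return A one-row tibble with `reader`, `definition`, `numerator`
#'   (positive lesions), `denominator` (evaluable lesions) and `prevalence`.
#' @export
prevalence <- function(data, reader = NULL, definition = c("A", "B", "C")) {
  definition <- match.arg(definition)
  rec <- analysis_records(data, reader)
  if (nrow(rec) == 0) {
    abort_validation("no evaluable lesions: prevalence is undefined")
  }
  pos <- sum(label_cspca(rec$gleason_group, rec$epe, definition))
  tibble::tibble(
    reader = unique(rec$reader_id),
    definition = definition,
    numerator = pos,
    denominator = nrow(rec),
    prevalence = pos / nrow(rec)
  )
}
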