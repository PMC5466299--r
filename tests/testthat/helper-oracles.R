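# Independent oracles and in-code fixtures shared across tests.

# Exhaustive pairwise AUC: mean over all (positive, negative) pairs of
# 1{pos > neg} + 0.5 * 1{pos == neg}. Quadratic, independent of the midrank
# implementation it checks.
brute_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Hanley-McNeil standard error of an empirical AUC
hanley_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

# Build a small valid lesion table from per-lesion vectors; volumes are
# filled automatically where a sequence shows the lesion.
tiny_cohort <- function(patient_id, s_t2 = 2L, s_dw = 3L, s_dce = 1L,
                        shape = "nodular_no_mass_effect", ece_score = 2L,
                        likert = 4L, dpsa = 0.16, gleason_group = 0L,
                        epe = FALSE, excluded = FALSE, reader_id = "R1",
                        vol = 0.8) {
  n <- length(patient_id)
  d <- tibble::tibble(
    patient_id = as.character(patient_id),
    reader_id = rep_len(reader_id, n),
    s_t2 = as.integer(rep_len(s_t2, n)),
    s_dw = as.integer(rep_len(s_dw, n)),
    s_dce = as.integer(rep_len(s_dce, n)),
    shape = rep_len(shape, n),
    ece_score = as.integer(rep_len(ece_score, n)),
    likert = as.integer(rep_len(likert, n)),
    dpsa = rep_len(dpsa, n),
    gleason_group = as.integer(rep_len(gleason_group, n)),
    epe = rep_len(epe, n),
    excluded = rep_len(excluded, n)
  )
  vol <- rep_len(vol, n)
  d$vol_t2 <- ifelse(d$s_t2 > 0, vol, NA_real_)
  d$vol_dw <- ifelse(d$s_dw > 0, vol, NA_real_)
  d$vol_dce <- ifelse(d$s_dce > 0, vol, NA_real_)
  d[lesionval::lesion_columns()]
}

# Cohort realising a given positive count under one csPCa definition:
# `n_pos` positives, `n_total - n_pos` benign findings, one lesion per
# patient.
counts_cohort <- function(n_pos, n_total, definition = "A", reader = "R1") {
  gg <- c(
    rep(switch(definition, A = 2L, B = 3L, C = 2L), n_pos),
    rep(0L, n_total - n_pos)
  )
  epe <- c(rep(definition == "C", n_pos), rep(FALSE, n_total - n_pos))
  tiny_cohort(sprintf("P%05d", seq_len(n_total)), gleason_group = gg,
              epe = epe, reader_id = reader)
}
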