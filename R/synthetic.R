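# Synthetic cohort generator. Emulates the structure of a prospective
# lesion-level radiologic-pathologic database: lesions clustered within
# patients, class-conditional ordinal signal scores (cumulative-logit),
# lognormal per-sequence volumes with a visibility mask, patient-level PSA
# density, an EPE model on grade and volume, and a Likert score driven by the
# generated features plus noise.

#' Parameters of the synthetic cohort generator
#'
#' Defaults are calibrated to the marginal structure reported for the study
#' population the package emulates: csPCa-A prevalence near 0.45, lesion-level
#' extraprostatic extension near 0.21-0.26, median PSA density 0.16 ng/mL/mL,
#' and a diffusion-weighted sequence carrying the largest signal effect.
#'
#' @param n_patients Number of patients.
#' @param lesions_per_patient Mean of the zero-truncated Poisson number of
#'   lesions described per patient.
#' @param class_probs Probability vector over ISUP grade groups
#'   `c(benign, gg1, gg2, gg3, gg4, gg5)`; must sum to 1.
#' @param epe_logit Coefficients `c(intercept, gg, logvol)` of the logistic
#'   model for lesion-level extraprostatic extension given grade group >= 1;
#'   `logvol` acts on `log(v_max)` centred at `vol_center`.
#' @param score_beta Per-sequence latent class effects of the cumulative-logit
#'   signal-score model, `c(t2, dw, dce)`; higher grade shifts mass toward
#'   "marked". Set to zeros for a null (uninformative) cohort.
#' @param score_cutpoints Shared cutpoints of the cumulative-logit score model
#'   (thresholds for scores >= 1, >= 2, >= 3).
#' @param vol_mu Intercept of the per-sequence lognormal volume model (log-mL).
#' @param vol_beta Grade-group slope of the lognormal volume mean.
#' @param vol_sigma Lognormal volume standard deviation (log scale).
#' @param vol_center Centring constant for `log(v_max)` in `epe_logit`.
#' @param dpsa_meanlog,dpsa_sdlog Patient-level lognormal PSA density
#'   parameters (default median `exp(dpsa_meanlog)` = 0.16 ng/mL/mL).
#' @param ece_beta Coefficients `c(epe, gg)` of the cumulative-logit model for
#'   the 5-level ECE score.
#' @param ece_cutpoints Cutpoints of the ECE score model (scores >= 2..5).
#' @param shape_probs 2 x 6 matrix of shape probabilities (rows: benign,
#'   cancer; columns: the 6 visible shape categories in the order of
#'   `setdiff(shape_levels(), "not_visible")`).
#' @param likert_weights Weights of the latent suspicion score behind the
#'   Likert rating, over `c(s_max, s_min_any, log_vmax, ece, log_dpsa)`.
#' @param likert_cutpoints Cutpoints mapping the latent suspicion score to
#'   Likert 2..5.
#' @param likert_noise_sd Standard deviation of the independent noise added to
#'   the latent suspicion score.
#' @param exclusion_prob Probability that a lesion is flagged excluded (e.g.
#'   DW artefacts).
#' @param seed Integer seed; together with the parameters it fully determines
#'   the generated cohort.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(n_patients = 250,
                          lesions_per_patient = 1.8,
                          class_probs = c(benign = 0.40, gg1 = 0.15,
                                          gg2 = 0.22, gg3 = 0.10,
                                          gg4 = 0.06, gg5 = 0.07),
                          epe_logit = c(intercept = -3.5, gg = 1.05,
                                        logvol = 0.3),
                          score_beta = c(t2 = 0.8, dw = 1.2, dce = 0.7),
                          score_cutpoints = c(0.5, 1.8, 3.2),
                          vol_mu = -1.2,
                          vol_beta = 0.25,
                          vol_sigma = 0.8,
                          vol_center = -0.9,
                          dpsa_meanlog = log(0.16),
                          dpsa_sdlog = 0.54,
                          ece_beta = c(epe = 1.8, gg = 0.3),
                          ece_cutpoints = c(0.8, 2.0, 3.0, 4.0),
                          shape_probs = default_shape_probs(),
                          likert_weights = c(s_max = 0.9, s_min_any = -0.6,
                                             log_vmax = 0.45, ece = 0.35,
                                             log_dpsa = 0.3),
                          likert_cutpoints = c(0.6, 1.7, 2.9),
                          likert_noise_sd = 1.0,
                          exclusion_prob = 0.005,
                          seed = 1L) {
  params <- list(
    n_patients = n_patients,
    lesions_per_patient = lesions_per_patient,
    class_probs = class_probs,
    epe_logit = epe_logit,
    score_beta = score_beta,
    score_cutpoints = score_cutpoints,
    vol_mu = vol_mu, vol_beta = vol_beta, vol_sigma = vol_sigma,
    vol_center = vol_center,
    dpsa_meanlog = dpsa_meanlog, dpsa_sdlog = dpsa_sdlog,
    ece_beta = ece_beta, ece_cutpoints = ece_cutpoints,
    shape_probs = shape_probs,
    likert_weights = likert_weights,
    likert_cutpoints = likert_cutpoints,
    likert_noise_sd = likert_noise_sd,
    exclusion_prob = exclusion_prob,
    seed = as.integer(seed)
  )
  class(params) <- "cohort_params"
  validate_cohort_params(params)
  params
}

default_shape_probs <- function() {
  m <- rbind(
    benign = c(0.35, 0.15, 0.15, 0.15, 0.15, 0.05),
    cancer = c(0.15, 0.05, 0.05, 0.10, 0.40, 0.25)
  )
  colnames(m) <- setdiff(shape_levels(), "not_visible")
  m
}

abort_config <- function(msg) rlang::abort(msg, class = "lesionval_config_error")

validate_cohort_params <- function(p) {
  if (p$n_patients < 0 || p$n_patients != floor(p$n_patients)) {
    abort_config("n_patients must be a non-negative integer")
  }
  if (p$lesions_per_patient <= 1) {
    abort_config("lesions_per_patient must exceed 1 (zero-truncated Poisson mean)")
  }
  if (length(p$class_probs) != 6) {
    abort_config("class_probs must have one entry per grade group (benign, gg1..gg5)")
  }
  if (abs(sum(p$class_probs) - 1) > 1e-12 || any(p$class_probs < 0)) {
    abort_config("class_probs must be a probability vector summing to 1")
  }
  if (any(abs(rowSums(p$shape_probs) - 1) > 1e-12) || any(p$shape_probs < 0)) {
    abort_config("shape_probs rows must sum to 1")
  }
  if (p$vol_sigma <= 0 || p$dpsa_sdlog <= 0 || p$likert_noise_sd < 0) {
    abort_config("scale parameters must be positive")
  }
  if (is.unsorted(p$score_cutpoints, strictly = TRUE) ||
      is.unsorted(p$ece_cutpoints, strictly = TRUE) ||
      is.unsorted(p$likert_cutpoints, strictly = TRUE)) {
    abort_config("cutpoints must be strictly increasing")
  }
  invisible(p)
}

# Zero-truncated Poisson with a given mean: solve for lambda once, draw by
# inverse CDF restricted to x >= 1.
draw_ztpois <- function(n, mean) {
  if (n == 0) return(integer(0))
  lambda <- stats::uniroot(
    function(l) l / (1 - exp(-l)) - mean,
    interval = c(1e-8, mean * 2 + 10), tol = 1e-12
  )$root
  u <- stats::runif(n, stats::dpois(0, lambda), 1)
  stats::qpois(u, lambda)
}

# Cumulative-logit draw: P(S >= k) = plogis(eta - cut[k]); one uniform per
# observation gives the whole ordinal draw.
draw_cumlogit <- function(eta, cutpoints) {
  u <- stats::runif(length(eta))
  out <- integer(length(eta))
  for (k in seq_along(cutpoints)) {
    out <- out + as.integer(u < stats::plogis(eta - cutpoints[k]))
  }
  out
}

#' Generate a synthetic lesion cohort
#'
#' Draws one reader's description of a cohort: patients, their PSA density,
#' a zero-truncated Poisson number of lesions each, lesion grade groups,
#' per-sequence ordinal signal scores and volumes (volumes masked where the
#' score is 0; lesions invisible on all three sequences are redrawn, since a
#' described focal lesion is visible somewhere), lesion-level EPE, ECE score,
#' shape, and a Likert score built from the generated features plus noise.
#' Identical `params` (including `seed`) give an identical cohort.
#'
#' @param params A [cohort_params()] object.
#' @param reader_id Reader tag stored on every row.
#' @return A validated lesion table (tibble) with a `provenance` attribute
#'   recording the seed.
#' @export
generate_cohort <- function(params, reader_id = "R1") {
  validate_cohort_params(params)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(params$seed)

  empty <- tibble::tibble(
    patient_id = character(0), reader_id = character(0),
    s_t2 = integer(0), s_dw = integer(0), s_dce = integer(0),
    vol_t2 = double(0), vol_dw = double(0), vol_dce = double(0),
    shape = character(0), ece_score = integer(0), likert = integer(0),
    dpsa = double(0), gleason_group = integer(0),
    epe = logical(0), excluded = logical(0)
  )
  if (params$n_patients == 0) {
    attr(empty, "provenance") <- sprintf("synthetic seed=%d", params$seed)
    return(empty)
  }

  n_les_pat <- draw_ztpois(params$n_patients, params$lesions_per_patient)
  pat_ids <- sprintf("P%04d", seq_len(params$n_patients))
  dpsa_pat <- stats::rlnorm(params$n_patients, params$dpsa_meanlog,
                            params$dpsa_sdlog)
  n <- sum(n_les_pat)
  pat_of <- rep(seq_len(params$n_patients), n_les_pat)

  gg <- sample(0:5, n, replace = TRUE, prob = params$class_probs)

  # signal scores; redraw lesions invisible on every sequence
  draw_scores <- function(idx) {
    vapply(c("t2", "dw", "dce"), function(seq) {
      draw_cumlogit(params$score_beta[[seq]] * gg[idx], params$score_cutpoints)
    }, integer(length(idx)))
  }
  scores <- matrix(0L, n, 3, dimnames = list(NULL, c("t2", "dw", "dce")))
  scores[] <- draw_scores(seq_len(n))
  repeat {
    invisible_all <- which(rowSums(scores > 0) == 0)
    if (length(invisible_all) == 0) break
    scores[invisible_all, ] <- draw_scores(invisible_all)
  }

  vols <- vapply(c("t2", "dw", "dce"), function(seq) {
    v <- stats::rlnorm(n, params$vol_mu + params$vol_beta * gg,
                       params$vol_sigma)
    v[scores[, seq] == 0] <- NA_real_
    v
  }, double(n))
  v_max <- apply(vols, 1, max, na.rm = TRUE)

  eta_epe <- params$epe_logit[["intercept"]] +
    params$epe_logit[["gg"]] * gg +
    params$epe_logit[["logvol"]] * (log(v_max) - params$vol_center)
  epe <- gg >= 1 & stats::runif(n) < stats::plogis(eta_epe)

  ece <- 1L + draw_cumlogit(
    params$ece_beta[["epe"]] * epe + params$ece_beta[["gg"]] * gg,
    params$ece_cutpoints
  )

  shp_row <- ifelse(gg >= 1, 2L, 1L)
  shape_lv <- colnames(params$shape_probs)
  shape <- vapply(seq_len(n), function(i) {
    sample(shape_lv, 1, prob = params$shape_probs[shp_row[i], ])
  }, character(1))

  s_max <- rowSums(scores == 3)
  s_min_any <- as.integer(rowSums(scores == 0) > 0)
  w <- params$likert_weights
  latent <- w[["s_max"]] * s_max + w[["s_min_any"]] * s_min_any +
    w[["log_vmax"]] * log(v_max) + w[["ece"]] * ece +
    w[["log_dpsa"]] * (log(dpsa_pat[pat_of]) - params$dpsa_meanlog) +
    stats::rnorm(n, 0, params$likert_noise_sd)
  likert <- 2L + draw_cumlogit(latent, params$likert_cutpoints) # via uniform draw
  # draw_cumlogit adds logistic noise on top of `latent`'s own gaussian noise;
  # both are independent of the outcome given the features, as intended.

  excluded <- stats::runif(n) < params$exclusion_prob

  cohort <- tibble::tibble(
    patient_id = pat_ids[pat_of],
    reader_id = reader_id,
    s_t2 = as.integer(scores[, "t2"]),
    s_dw = as.integer(scores[, "dw"]),
    s_dce = as.integer(scores[, "dce"]),
    vol_t2 = vols[, "t2"], vol_dw = vols[, "dw"], vol_dce = vols[, "dce"],
    shape = shape,
    ece_score = as.integer(ece),
    likert = as.integer(likert),
    dpsa = dpsa_pat[pat_of],
    gleason_group = as.integer(gg),
    epe = epe,
    excluded = excluded
  )
  validate_lesion_table(cohort)
  attr(cohort, "provenance") <- sprintf("synthetic seed=%d", params$seed)
  cohort
}

#' Null variant of the generator parameters
#'
#' Returns `params` with every feature model made class-independent: signal
#' scores, volumes, ECE, and shape no longer depend on grade group or EPE, so
#' no feature carries information about the outcome. The outcome model
#' (grade-group probabilities and the EPE model) is unchanged, so the
#' configured prevalences are retained. Useful as a calibration fixture: any
#' feature's out-of-sample AUC is 0.5 by construction.
#'
#' @param params A [cohort_params()] object.
#' @return A `cohort_params` object with nulled feature models.
#' @export
null_params <- function(params = cohort_params()) {
  params$score_beta[] <- 0
  params$vol_beta <- 0
  # the volume slope of the EPE model would leak outcome information into
  # v_max under definition C, so it is nulled too
  params$epe_logit[["logvol"]] <- 0
  params$ece_beta[] <- 0
  params$shape_probs["cancer", ] <- params$shape_probs["benign", ]
  params
}

#' Generate a null cohort
#'
#' Convenience wrapper: [generate_cohort()] under [null_params()].
#'
#' @inheritParams generate_cohort
#' @return A lesion table whose features are independent of the outcome.
#' @export
null_cohort <- function(params = cohort_params(), reader_id = "R1") {
  generate_cohort(null_params(params), reader_id = reader_id)
}
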