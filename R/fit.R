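# Maximum-likelihood logistic fitting on an encoded design, with a small
# ridge fallback when separation or non-convergence is detected. Collinear
# columns are dropped by the QR pivoting inside glm.fit (NA coefficients),
# which leaves fitted probabilities unchanged.

abort_degenerate <- function(msg) {
  rlang::abort(msg, class = "lesionval_degenerate")
}

#' Fit a logistic model on an encoded design
#'
#' Fits by maximum likelihood (`stats::glm.fit`). When the fit does not
#' converge or shows signs of separation (fitted probabilities numerically 0
#' or 1, or extreme coefficients), the model is refit with a small ridge
#' penalty on standardized columns and the `fallback` flag is set.
#'
#' @param x Design matrix including an intercept column.
#' @param y 0/1 label vector; both classes must be present.
#' @param ridge_lambda Ridge penalty used by the fallback, applied to
#'   coefficients of standardized columns.
#' @param coef_limit Absolute coefficient size beyond which the maximum
#'   likelihood fit is treated as separated.
#' @return A `lesion_fit` object: coefficients (NA for aliased columns),
#'   fitted probabilities, `converged` and `fallback` flags, and the names of
#'   aliased (dropped) terms.
#' @export
fit_logistic <- function(x, y, ridge_lambda = 1e-4, coef_limit = 15) {
  if (length(unique(y)) < 2) {
    abort_degenerate("labels contain a single class; logistic fit undefined")
  }
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(x, y, family = stats::binomial()),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  beta <- fit$coefficients
  separated <- !fit$converged || warned ||
    any(abs(beta[!is.na(beta)]) > coef_limit)
  fallback <- FALSE
  if (separated) {
    beta <- ridge_logistic(x, y, lambda = ridge_lambda)
    fallback <- TRUE
  }
  b0 <- beta
  b0[is.na(b0)] <- 0
  structure(
    list(
      coefficients = beta,
      fitted = as.vector(stats::plogis(x %*% b0)),
      converged = fit$converged || fallback,
      fallback = fallback,
      dropped_terms = names(beta)[is.na(beta)]
    ),
    class = "lesion_fit"
  )
}

# IRLS with an L2 penalty on standardized coefficients: penalty
# (lambda/2) * sum((beta_j * sd_j)^2); the intercept is unpenalized.
ridge_logistic <- function(x, y, lambda = 1e-4, max_iter = 100, tol = 1e-10) {
  sds <- apply(x, 2, stats::sd)
  pen <- lambda * sds^2
  pen[sds == 0] <- 0
  if (ncol(x) >= 1) pen[1] <- 0
  # duplicate constant columns would be unpenalized and collinear; give any
  # non-intercept constant column a floor penalty so the system is solvable
  if (ncol(x) > 1) {
    const <- which(sds == 0)
    pen[setdiff(const, 1L)] <- lambda
  }
  beta <- rep(0, ncol(x))
  for (it in seq_len(max_iter)) {
    eta <- as.vector(x %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    a <- crossprod(x, x * w) + diag(pen, ncol(x))
    rhs <- crossprod(x, w * z)
    new_beta <- tryCatch(
      solve(a, rhs),
      error = function(e) solve(a + diag(1e-8, ncol(x)), rhs)
    )
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta
      break
    }
    beta <- new_beta
  }
  stats::setNames(as.vector(beta), colnames(x))
}

# score a (possibly replicate-) fitted model on a design matrix; aliased
# coefficients count as 0
predict_design <- function(fit, x) {
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  as.vector(stats::plogis(x %*% beta))
}

#' Fit one battery model on a cohort
#'
#' Convenience wrapper: encodes the design for `spec` under `definition` and
#' fits the logistic model.
#'
#' @inheritParams encode_design
#' @param ... Passed to [encode_design()].
#' @return A `lesion_fit` with the encoding attached (`$design`).
#' @export
fit_model <- function(data, spec, definition = c("A", "B", "C"), ...) {
  enc <- encode_design(data, spec, definition, ...)
  fit <- fit_logistic(enc$x, enc$y)
  fit$design <- enc
  fit
}

#' @export
print.lesion_fit <- function(x, ...) {
  spec_name <- if (!is.null(x$design)) x$design$spec$name else "(design-level fit)"
  cat("<lesion_fit> ", spec_name, "\n", sep = "")
  cat("  terms: ", length(x$coefficients),
      if (x$fallback) "  [ridge fallback]" else "", "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted lesion model
#'
#' @param x A `lesion_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model term.
#' @export
tidy.lesion_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    aliased = is.na(x$coefficients)
  )
}

#' One-row summary of a fitted lesion model
#'
#' @param x A `lesion_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.lesion_fit <- function(x, ...) {
  tibble::tibble(
    n = length(x$fitted),
    n_terms = length(x$coefficients),
    converged = x$converged,
    fallback = x$fallback
  )
}
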