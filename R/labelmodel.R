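# Generative label model (data programming).
#
# Latent truth y_i in {-1, +1} with class prior pi = P(y = +1). Each
# labeling function j votes independently given y (Naive Bayes):
#
#   P(L_ij = 0     | y) = 1 - beta_j          (abstain; propensity beta_j)
#   P(L_ij = y     | y) = beta_j * alpha_j    (accuracy alpha_j)
#   P(L_ij = -y    | y) = beta_j * (1 - alpha_j)
#
# Parameters are learned from the unlabeled vote matrix by EM with
# closed-form M-steps and add-one smoothing; the per-candidate posteriors
# P(y_i = +1 | row i) are then used directly as probabilistic labels. The
# likelihood is invariant under the label swap (alpha, pi) ->
# (1 - alpha, 1 - pi); since LFs are assumed better than random, the fit is
# canonicalized to mean(alpha) >= 0.5.

new_label_model <- function(alpha, beta, pi, log_lik = numeric(),
                            objective = numeric(), n_iter = 0L,
                            converged = NA) {
  stopifnot(length(alpha) == length(beta))
  structure(
    list(alpha = alpha, beta = beta, pi = pi, log_lik = log_lik,
         objective = objective, n_iter = n_iter, converged = converged),
    class = "gwas_label_model"
  )
}

# log-density of the Beta(2, 2) smoothing priors; the EM below is a MAP-EM
# whose add-one M-steps maximize marginal likelihood times these priors, so
# the `objective` trace (log posterior) is guaranteed non-decreasing, while
# the bare marginal `log_lik` can dip by O(prior strength / n).
log_prior <- function(alpha, beta, pi) {
  sum(stats::dbeta(alpha, 2, 2, log = TRUE)) +
    sum(stats::dbeta(beta, 2, 2, log = TRUE)) +
    stats::dbeta(pi, 2, 2, log = TRUE)
}

#' @export
print.gwas_label_model <- function(x, ...) {
  cat(sprintf(
    "<gwas_label_model: %d LFs, pi = %.3f, %d EM iterations%s>\n",
    length(x$alpha), x$pi, x$n_iter,
    if (isTRUE(x$converged)) " (converged)" else ""
  ))
  cat("  alpha:", paste(sprintf("%.3f", x$alpha), collapse = " "), "\n")
  cat("  beta: ", paste(sprintf("%.3f", x$beta), collapse = " "), "\n")
  invisible(x)
}

check_label_matrix <- function(L) {
  if (!is.matrix(L)) L <- as.matrix(L)
  if (!nrow(L) || !ncol(L)) stop("label matrix is empty")
  if (!all(L %in% c(-1L, 0L, 1L))) {
    stop("label matrix entries must be in {-1, 0, +1}")
  }
  L
}

# log P(row | y) for all rows, given per-LF (alpha, beta); returns an
# n-vector. Abstain factors (1 - beta) are included so the log-likelihood
# is the true marginal, even though they cancel in the posterior ratio.
loglik_given_y <- function(L, alpha, beta, y) {
  agree <- sweep(L == y, 2, log(beta * alpha), `*`)
  disagree <- sweep(L == -y, 2, log(beta * (1 - alpha)), `*`)
  abstain <- sweep(L == 0L, 2, log(1 - beta), `*`)
  rowSums(agree + disagree + abstain)
}

marginal_loglik <- function(L, alpha, beta, pi) {
  lp <- log(pi) + loglik_given_y(L, alpha, beta, +1L)
  lm <- log(1 - pi) + loglik_given_y(L, alpha, beta, -1L)
  mx <- pmax(lp, lm)
  sum(mx + log(exp(lp - mx) + exp(lm - mx)))
}

#' Fit the generative label model by EM
#'
#' Maximizes (locally) the marginal likelihood of the label matrix under
#' the conditionally independent model described above. The M-steps are
#' closed-form with add-one smoothing (Beta(2, 2) priors), so parameters
#' stay strictly inside (0, 1); the EM objective -- marginal log-likelihood
#' plus log-prior, stored as `objective` -- is non-decreasing across
#' iterations (the bare marginal `log_lik` is reported too and can differ
#' from it by at most the prior strength, which vanishes as n grows).
#' The fit is deterministic given the initialization (`seed` is accepted
#' for interface symmetry with stochastic fitters and reserved for random
#' restarts).
#'
#' @param L Label matrix over \{-1, 0, +1\} from [apply_lfs()].
#' @param init Named list with starting values `alpha` (scalar or per-LF,
#'   default 0.7), `beta` (default: empirical coverage), `pi` (default
#'   0.5).
#' @param max_iter,tol EM stops when the log-likelihood improves by less
#'   than `tol` (default 1e-6) or after `max_iter` (default 500)
#'   iterations.
#' @param seed Unused by the deterministic EM; kept in the signature so
#'   callers can treat all fitters uniformly.
#' @return A `gwas_label_model` with `alpha`, `beta`, `pi`, the `log_lik`
#'   and `objective` traces, `n_iter` and `converged`.
#' @examples
#' sim <- simulate_label_matrix(500, alphas = c(0.9, 0.7, 0.8),
#'                              betas = c(0.8, 0.6, 0.7), pi = 0.5, seed = 1)
#' fit_label_model(sim$L)
#' @export
fit_label_model <- function(L, init = list(), max_iter = 500L, tol = 1e-6,
                            seed = NULL) {
  L <- check_label_matrix(L)
  n <- nrow(L)
  m <- ncol(L)
  coverage <- colMeans(L != 0L)
  if (any(coverage == 0)) {
    warning("LF(s) with no votes: accuracy held at initialization for ",
            paste(which(coverage == 0), collapse = ", "))
  }
  alpha <- rep_len(init$alpha %||% 0.7, m)
  beta <- rep_len(init$beta %||% pmin(pmax(coverage, 1 / (n + 2)),
                                      (n + 1) / (n + 2)), m)
  pi <- init$pi %||% 0.5

  n_votes <- colSums(L != 0L)
  ll_trace <- numeric()
  obj_trace <- numeric()
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # E-step: gamma_i = P(y_i = +1 | row i)
    lp <- log(pi) + loglik_given_y(L, alpha, beta, +1L)
    lm <- log(1 - pi) + loglik_given_y(L, alpha, beta, -1L)
    gamma <- 1 / (1 + exp(lm - lp))
    # M-step (add-one smoothing keeps parameters off the boundary)
    pi_new <- (sum(gamma) + 1) / (n + 2)
    beta_new <- (n_votes + 1) / (n + 2)
    correct <- colSums((L == 1L) * gamma + (L == -1L) * (1 - gamma))
    alpha_new <- (correct + 1) / (n_votes + 2)
    alpha_new[n_votes == 0] <- alpha[n_votes == 0]   # hold uninformed LFs
    alpha <- alpha_new
    beta <- beta_new
    pi <- pi_new
    ll <- marginal_loglik(L, alpha, beta, pi)
    ll_trace <- c(ll_trace, ll)
    obj_trace <- c(obj_trace, ll + log_prior(alpha, beta, pi))
    if (it > 1L && abs(obj_trace[it] - obj_trace[it - 1L]) < tol) {
      converged <- TRUE
      break
    }
  }
  # canonicalize the label-swap symmetry: LFs better than random on average
  if (mean(alpha) < 0.5) {
    alpha <- 1 - alpha
    pi <- 1 - pi
  }
  new_label_model(alpha, beta, pi, ll_trace, obj_trace, it, converged)
}

#' Posterior probability of each candidate being correct
#'
#' Computes `P(y_i = +1 | row i)` by Bayes' rule under the model; abstains
#' contribute the same `(1 - beta_j)` factor to both classes and cancel, so
#' an all-abstain row gets the class prior `pi`.
#'
#' @param params A `gwas_label_model` (from [fit_label_model()] or
#'   [label_model_params()]).
#' @param L A label matrix with the same number of columns as `params` has
#'   LFs.
#' @return A numeric vector of posteriors in `[0, 1]`, one per row of `L`.
#' @export
posterior_labels <- function(params, L) {
  stopifnot(inherits(params, "gwas_label_model"))
  L <- check_label_matrix(L)
  if (ncol(L) != length(params$alpha)) {
    stop("label matrix has ", ncol(L), " LFs but the model has ",
         length(params$alpha))
  }
  lp <- log(params$pi) + loglik_given_y(L, params$alpha, params$beta, +1L)
  lm <- log(1 - params$pi) + loglik_given_y(L, params$alpha, params$beta, -1L)
  1 / (1 + exp(lm - lp))
}

#' Accept candidates whose posterior clears a threshold
#'
#' @inheritParams posterior_labels
#' @param threshold Acceptance threshold in (0, 1); strict inequality, so a
#'   posterior exactly at the threshold is rejected.
#' @return A logical vector, one element per row of `L`.
#' @export
predict_labels <- function(params, L, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  posterior_labels(params, L) > threshold
}

#' Construct label-model parameters directly
#'
#' Useful for closed-form checks and for scoring with externally chosen
#' parameters instead of an EM fit.
#'
#' @param alpha,beta Per-LF accuracies and vote propensities in (0, 1).
#' @param pi Class prior `P(y = +1)` in (0, 1).
#' @return A `gwas_label_model`.
#' @export
label_model_params <- function(alpha, beta = rep(0.5, length(alpha)),
                               pi = 0.5) {
  stopifnot(all(alpha > 0 & alpha < 1), all(beta > 0 & beta < 1),
            pi > 0, pi < 1)
  new_label_model(alpha, beta, pi)
}

#' Serialize / restore label-model parameters as JSON
#'
#' @param params A `gwas_label_model`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `label_model_to_json()` returns the JSON string (invisibly when
#'   written to a file); `label_model_from_json()` returns a
#'   `gwas_label_model`.
#' @export
label_model_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "gwas_label_model"))
  js <- jsonlite::toJSON(
    list(alpha = params$alpha, beta = params$beta, pi = params$pi),
    digits = NA
  )
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname label_model_to_json
#' @param json A JSON string or file path produced by
#'   [label_model_to_json()].
#' @export
label_model_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  label_model_params(x$alpha, x$beta, x$pi)
}
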