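# Convergence diagnostics: split potential-scale-reduction factor and
# autocorrelation-based effective sample size, applied to both model
# stages through convergence_report().

#' Split potential scale reduction factor (split R-hat)
#'
#' Each chain is split in half (middle draw dropped when the length is
#' odd); over the resulting `2 * n_chains` half-chains of length `n`,
#' \deqn{\hat{R} = \sqrt{\frac{(n-1)/n \, W + B/n}{W}}}
#' with `W` the mean within-half-chain variance and `B` the between-half-
#' chain variance. Values near 1 indicate the chains agree; the
#' conventional gate is 1.1. Rank normalization is off by default (the
#' classic estimator); enable it to diagnose heavy-tailed targets.
#'
#' @param x A [posterior_draws()] object.
#' @param parameter Parameter label.
#' @param rank_normalize If `TRUE`, draws are replaced by normal scores of
#'   their pooled ranks before the variance decomposition.
#' @return The split-\eqn{\hat{R}} estimate; `NaN` when `W = 0` (all
#'   half-chains constant).
#' @export
split_rhat <- function(x, parameter, rank_normalize = FALSE) {
  m <- extract_draws(x, parameter)
  if (nrow(m) < 2L) stop("need >= 2 iterations per chain", call. = FALSE)
  if (rank_normalize) {
    r <- rank(m, ties.method = "average")
    m[] <- stats::qnorm((r - 3 / 8) / (length(m) + 1 / 4))
  }
  n_half <- nrow(m) %/% 2L
  halves <- cbind(m[seq_len(n_half), , drop = FALSE],
                  m[nrow(m) - n_half + seq_len(n_half), , drop = FALSE])
  w <- mean(apply(halves, 2L, stats::var))
  b <- n_half * stats::var(colMeans(halves))
  if (w == 0) return(NaN)
  sqrt(((n_half - 1) / n_half * w + b / n_half) / w)
}

#' Effective sample size
#'
#' Multi-chain autocorrelation-based ESS: per-lag correlations are combined
#' across chains through the pooled-variance estimator and summed with
#' Geyer's initial positive sequence truncation. Capped at the total number
#' of draws; constant chains return 0 with a warning.
#'
#' @inheritParams split_rhat
#' @return Estimated effective sample size.
#' @export
effective_sample_size <- function(x, parameter) {
  m <- extract_draws(x, parameter)
  n <- nrow(m)
  n_chains <- ncol(m)
  if (n < 4L) stop("need >= 4 iterations per chain", call. = FALSE)

  chain_vars <- apply(m, 2L, stats::var)
  w <- mean(chain_vars)
  if (w == 0 || !is.finite(w)) {
    warning("constant chains: effective sample size reported as 0",
            call. = FALSE)
    return(0)
  }
  b_over_n <- if (n_chains > 1L) stats::var(colMeans(m)) else 0
  var_plus <- (n - 1) / n * w + b_over_n

  max_lag <- n - 1L
  # mean autocovariance across chains at each lag (acf divides by n)
  acov <- sapply(seq_len(n_chains), function(ch) {
    stats::acf(m[, ch], lag.max = max_lag, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  })
  mean_acov <- rowMeans(acov)
  rho <- 1 - (w - mean_acov[-1L]) / var_plus

  # Geyer initial positive sequence on paired sums rho_{2t} + rho_{2t+1}
  ess_sum <- 0
  t <- 1L
  prev_pair <- Inf
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    pair <- min(pair, prev_pair) # enforce monotone decrease
    ess_sum <- ess_sum + pair
    prev_pair <- pair
    t <- t + 2L
  }
  tau <- 1 + 2 * ess_sum
  ess <- n * n_chains / max(tau, 1e-12)
  min(ess, n * n_chains)
}

#' Machine-readable convergence report
#'
#' Computes split-\eqn{\hat{R}} and effective sample size for every
#' parameter and applies the convergence gate: pass when the maximum
#' finite \eqn{\hat{R}} is below `cfg$rhat_threshold`.
#'
#' @param x A [posterior_draws()] object.
#' @param cfg An [mcmc_config()] supplying the gate threshold.
#' @return List with `parameters` (data frame: parameter, rhat, ess),
#'   `max_rhat`, `pass`, and `failed` (labels exceeding the gate).
#'   Serialise with [jsonlite::toJSON()].
#' @export
convergence_report <- function(x, cfg = mcmc_config()) {
  pars <- parameters(x)
  if (length(pars) == 0L) {
    warning("no parameters to diagnose; gate passes vacuously",
            call. = FALSE)
    return(list(parameters = data.frame(parameter = character(),
                                        rhat = numeric(), ess = numeric()),
                max_rhat = NA_real_, pass = TRUE, failed = character()))
  }
  rhat <- vapply(pars, function(p) split_rhat(x, p), numeric(1))
  ess <- vapply(pars, function(p) {
    suppressWarnings(effective_sample_size(x, p))
  }, numeric(1))
  finite <- is.finite(rhat)
  max_rhat <- if (any(finite)) max(rhat[finite]) else NA_real_
  pass <- !any(finite) || max_rhat < cfg$rhat_threshold
  list(
    parameters = data.frame(parameter = pars, rhat = rhat, ess = ess,
                            row.names = NULL),
    max_rhat = max_rhat,
    pass = pass,
    failed = pars[finite & rhat >= cfg$rhat_threshold]
  )
}

#' Write a convergence report as JSON
#'
#' @param report Output of [convergence_report()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_diagnostics_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
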