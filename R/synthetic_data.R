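# Synthetic-data module: rebuilds study-like per-individual datasets from
# printed summary tables, and forward-simulates the two generative stages
# (biofilm as an algae/litter mixture; consumers as trophically enriched
# source mixtures) so recovery of known truth can be tested end to end.

#' Ground truth for the stage-1 (endmember) generative model
#'
#' @param land_uses Character vector of land-use labels.
#' @param delta_A Numeric matrix `[land_use, tracer]` of algal endmembers
#'   (permil).
#' @param phi_T Named numeric, terrestrial fraction of biofilm per land
#'   use, each in `[0, 1]`.
#' @param litter_mean,litter_sd Numeric matrices `[land_use, tracer]`
#'   describing the leaf-litter distribution.
#' @param sigma Named numeric per tracer, biofilm observation noise
#'   (permil, `>= 0`).
#' @return List of class `stage1_truth`.
#' @export
stage1_truth <- function(land_uses, delta_A, phi_T, litter_mean, litter_sd,
                         sigma) {
  tr <- tracer_levels()
  delta_A <- matrix(delta_A, nrow = length(land_uses), ncol = length(tr),
                    dimnames = list(land_uses, tr))
  litter_mean <- matrix(litter_mean, nrow = length(land_uses),
                        ncol = length(tr), dimnames = list(land_uses, tr))
  litter_sd <- matrix(litter_sd, nrow = length(land_uses), ncol = length(tr),
                      dimnames = list(land_uses, tr))
  phi_T <- stats::setNames(rep_len(phi_T, length(land_uses)), land_uses)
  sigma <- stats::setNames(rep_len(sigma, length(tr)), tr)
  if (any(phi_T < 0 | phi_T > 1)) {
    stop("phi_T must lie in [0, 1]", call. = FALSE)
  }
  if (any(sigma < 0) || any(litter_sd < 0)) {
    stop("sigma and litter_sd must be >= 0", call. = FALSE)
  }
  structure(list(land_uses = land_uses, delta_A = delta_A, phi_T = phi_T,
                 litter_mean = litter_mean, litter_sd = litter_sd,
                 sigma = sigma),
            class = "stage1_truth")
}

#' Ground truth for the stage-2 (consumer mixing) generative model
#'
#' @param taxon,guild,land_use Cell labels.
#' @param phi Named numeric over sources, non-negative, summing to 1
#'   (tolerance 1e-9).
#' @param L Trophic level in `[0, 10]`.
#' @param tef Named numeric per tracer: trophic enrichment factor (permil).
#' @param source_mean,source_sd Numeric matrices `[source, tracer]` of
#'   source-signature distributions (permil).
#' @param sigma_c Named numeric per tracer: residual consumer noise
#'   (permil, `>= 0`).
#' @return List of class `stage2_truth`.
#' @export
stage2_truth <- function(phi, L, tef, source_mean, source_sd, sigma_c,
                         taxon = "consumer", guild = "omnivore",
                         land_use = "forest") {
  tr <- tracer_levels()
  sources <- names(phi)
  if (is.null(sources)) stop("phi must be named by source", call. = FALSE)
  if (any(phi < 0) || abs(sum(phi) - 1) > 1e-9) {
    stop("phi must be a simplex (non-negative, summing to 1)", call. = FALSE)
  }
  if (L < 0 || L > 10) stop("L must lie in [0, 10]", call. = FALSE)
  source_mean <- matrix(source_mean, nrow = length(sources),
                        ncol = length(tr), dimnames = list(sources, tr))
  source_sd <- matrix(source_sd, nrow = length(sources), ncol = length(tr),
                      dimnames = list(sources, tr))
  tef <- stats::setNames(rep_len(tef, length(tr)), tr)
  sigma_c <- stats::setNames(rep_len(sigma_c, length(tr)), tr)
  if (any(source_sd < 0) || any(sigma_c < 0)) {
    stop("source_sd and sigma_c must be >= 0", call. = FALSE)
  }
  structure(list(phi = phi, L = L, tef = tef, source_mean = source_mean,
                 source_sd = source_sd, sigma_c = sigma_c, taxon = taxon,
                 guild = guild, land_use = land_use),
            class = "stage2_truth")
}

#' Generate per-individual observations from a summary table
#'
#' For each summary row, draws `n` (or `n_override`) independent normal
#' observations per tracer with the row's mean and sd. Tracers are drawn
#' independently: printed tables report only marginal moments, so no C-N
#' covariance can be emulated.
#'
#' @param rows A `summary_rows` data frame (see [read_summary_table()]).
#' @param n_override Optional integer replacing every row's `n`.
#' @param seed Integer seed; the generator is a pure function of
#'   `(rows, n_override, seed)`.
#' @return An [isotope_dataset()] with provenance `"synthetic:<seed>"`.
#' @export
generate_from_summary <- function(rows, n_override = NULL, seed = 1L) {
  rows <- as_summary_rows(rows)
  set.seed(seed)
  pieces <- lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    n <- if (is.null(n_override)) r$n else as.integer(n_override)
    category <- if (r$category %in% c("biofilm", "leaf_litter")) {
      r$category
    } else {
      paste0("consumer:", r$category)
    }
    data.frame(
      sample_id = sprintf("%s_%s_%03d", gsub("[^A-Za-z0-9]", "", r$category),
                          r$land_use, seq_len(n)),
      category = category,
      guild = if (is.na(r$guild)) NA_character_ else r$guild,
      land_use = r$land_use,
      d13C = stats::rnorm(n, r$d13C_mean, r$d13C_sd),
      d15N = stats::rnorm(n, r$d15N_mean, r$d15N_sd)
    )
  })
  isotope_dataset(do.call(rbind, pieces),
                  provenance = paste0("synthetic:", seed))
}

#' Forward-simulate biofilm and litter under the endmember mixture model
#'
#' Leaf-litter observations are drawn from the litter distribution; biofilm
#' observations from a normal centred on the two-endmember mixture
#' `delta_A * (1 - phi_T) + delta_T * phi_T` with noise `sigma`. By default
#' `delta_T` is the litter distribution mean; with
#' `litter_mode = "draw"` each biofilm observation mixes against a fresh
#' litter draw instead.
#'
#' @param truth A [stage1_truth()].
#' @param n_biofilm,n_litter Observations per land use (`> 0`).
#' @param seed Integer seed.
#' @param litter_mode `"mean"` (default) or `"draw"`.
#' @return An [isotope_dataset()].
#' @export
simulate_stage1 <- function(truth, n_biofilm, n_litter, seed = 1L,
                            litter_mode = c("mean", "draw")) {
  stopifnot(inherits(truth, "stage1_truth"))
  litter_mode <- match.arg(litter_mode)
  if (n_biofilm <= 0 || n_litter <= 0) {
    stop("n_biofilm and n_litter must be positive", call. = FALSE)
  }
  set.seed(seed)
  tr <- tracer_levels()
  pieces <- list()
  for (lu in truth$land_uses) {
    lit <- sapply(tr, function(t) {
      stats::rnorm(n_litter, truth$litter_mean[lu, t], truth$litter_sd[lu, t])
    })
    lit <- matrix(lit, nrow = n_litter, dimnames = list(NULL, tr))
    bio <- sapply(tr, function(t) {
      dT <- if (litter_mode == "mean") {
        truth$litter_mean[lu, t]
      } else {
        stats::rnorm(n_biofilm, truth$litter_mean[lu, t],
                     truth$litter_sd[lu, t])
      }
      mu <- truth$delta_A[lu, t] * (1 - truth$phi_T[lu]) + dT * truth$phi_T[lu]
      stats::rnorm(n_biofilm, mu, truth$sigma[t])
    })
    bio <- matrix(bio, nrow = n_biofilm, dimnames = list(NULL, tr))
    pieces[[paste0(lu, "_lit")]] <- data.frame(
      sample_id = sprintf("litter_%s_%03d", lu, seq_len(n_litter)),
      category = "leaf_litter", guild = NA_character_, land_use = lu,
      d13C = lit[, "d13C"], d15N = lit[, "d15N"])
    pieces[[paste0(lu, "_bio")]] <- data.frame(
      sample_id = sprintf("biofilm_%s_%03d", lu, seq_len(n_biofilm)),
      category = "biofilm", guild = NA_character_, land_use = lu,
      d13C = bio[, "d13C"], d15N = bio[, "d15N"])
  }
  isotope_dataset(do.call(rbind, pieces),
                  provenance = paste0("synthetic:", seed))
}

#' Forward-simulate consumer observations under the mixing model
#'
#' Per observation and tracer: fresh source signatures are drawn from their
#' `(mean, sd)`, combined as `sum_s phi_s * (delta_{t,s} + tef_t * L)`, and
#' residual noise `Normal(0, sigma_c)` is added.
#'
#' @param truth A [stage2_truth()].
#' @param n_consumers Number of consumer observations (`> 0`).
#' @param seed Integer seed.
#' @return An [isotope_dataset()] containing one consumer cell.
#' @export
simulate_stage2 <- function(truth, n_consumers, seed = 1L) {
  stopifnot(inherits(truth, "stage2_truth"))
  if (n_consumers <= 0) stop("n_consumers must be positive", call. = FALSE)
  set.seed(seed)
  tr <- tracer_levels()
  vals <- sapply(tr, function(t) {
    draws <- vapply(seq_len(n_consumers), function(i) {
      sig <- stats::rnorm(nrow(truth$source_mean),
                          truth$source_mean[, t], truth$source_sd[, t])
      sum(truth$phi * (sig + truth$tef[t] * truth$L))
    }, numeric(1))
    draws + stats::rnorm(n_consumers, 0, truth$sigma_c[t])
  })
  vals <- matrix(vals, nrow = n_consumers, dimnames = list(NULL, tr))
  isotope_dataset(
    data.frame(
      sample_id = sprintf("%s_%s_%03d", truth$taxon, truth$land_use,
                          seq_len(n_consumers)),
      category = paste0("consumer:", truth$taxon),
      guild = truth$guild, land_use = truth$land_use,
      d13C = vals[, "d13C"], d15N = vals[, "d15N"]),
    provenance = paste0("synthetic:", seed))
}

#' Rebuild a full synthetic study from the bundled summary table
#'
#' Draws a complete study-like dataset — biofilm, leaf litter and ten
#' consumer taxa across three land uses — with the per-cell sample sizes of
#' the bundled study summary table ([study_summary_table()]).
#'
#' @param seed Integer seed.
#' @return An [isotope_dataset()].
#' @export
make_study_fixture <- function(seed = 1L) {
  generate_from_summary(study_summary_table(), n_override = NULL, seed = seed)
}
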