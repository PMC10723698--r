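# Stage 2: per consumer taxon x land use, apportion the isotopic signal
# among basal sources. Per cell, tracer t and observation i:
#   d_{t,i} ~ Normal( sum_s phi_s * (delta_{t,s} + tef_t * L), sigma_c[t] )
# with phi ~ Dirichlet(1, ..., 1), L ~ Uniform(0, 10), tef_t normal with
# literature TEF priors, latent source signatures delta_{t,s} normal with
# the source-set priors (leaf litter measured; algae from stage 1 — cut
# inference, no feedback), and sigma_c half-normal(0, 3 permil).

#' Source set: ordered basal sources with per-tracer priors
#'
#' @param labels Character vector of source labels (>= 2), in reporting
#'   order. Default order is `c("leaf_litter", "algae")`.
#' @param mean,sd Numeric matrices `[source, tracer]` of prior moments
#'   (permil, `sd > 0`).
#' @return List of class `source_set`.
#' @export
source_set <- function(labels, mean, sd) {
  tr <- tracer_levels()
  if (length(labels) < 2) stop("need >= 2 sources", call. = FALSE)
  mean <- matrix(mean, nrow = length(labels), ncol = length(tr),
                 dimnames = list(labels, tr))
  sd <- matrix(sd, nrow = length(labels), ncol = length(tr),
               dimnames = list(labels, tr))
  if (any(sd <= 0)) stop("source prior sds must be > 0", call. = FALSE)
  structure(list(labels = labels, mean = mean, sd = sd),
            class = "source_set")
}

#' Build per-land-use source sets from litter data and the algal summary
#'
#' Combines measured leaf-litter summaries with the stage-1 algal
#' endmember summaries ([algal_summary()]) into one [source_set()] per
#' land use; optionally appends bulk biofilm as a third source.
#'
#' @param litter_rows,algal_rows `summary_rows` data frames holding
#'   `leaf_litter` and `algae` categories respectively (an entire mixed
#'   table may be passed for either; the relevant category is selected).
#' @param biofilm_rows Optional `summary_rows` with `biofilm` category to
#'   add a third source.
#' @return Named list of [source_set()] objects, one per land use present
#'   in both inputs.
#' @export
build_source_sets <- function(litter_rows, algal_rows, biofilm_rows = NULL) {
  pick <- function(rows, cat) {
    rows <- as.data.frame(rows)
    rows[rows$category == cat, , drop = FALSE]
  }
  lit <- pick(litter_rows, "leaf_litter")
  alg <- pick(algal_rows, "algae")
  bio <- if (!is.null(biofilm_rows)) pick(biofilm_rows, "biofilm")
  lus <- intersect(lit$land_use, alg$land_use)
  if (length(lus) == 0) {
    stop("no common land uses between litter and algal summaries",
         call. = FALSE)
  }
  out <- lapply(stats::setNames(lus, lus), function(lu) {
    rows <- rbind(lit[lit$land_use == lu, ], alg[alg$land_use == lu, ])
    labels <- c("leaf_litter", "algae")
    if (!is.null(bio) && lu %in% bio$land_use) {
      rows <- rbind(rows, bio[bio$land_use == lu, ])
      labels <- c(labels, "biofilm")
    }
    source_set(labels,
               mean = cbind(rows$d13C_mean, rows$d15N_mean),
               sd = cbind(pmax(rows$d13C_sd, 1e-6),
                          pmax(rows$d15N_sd, 1e-6)))
  })
  out
}

#' Trophic enrichment factor prior
#'
#' Defaults are literature per-trophic-step fractionation values:
#' \eqn{\Delta\delta^{13}}C ~ Normal(0.39, 1.14),
#' \eqn{\Delta\delta^{15}}N ~ Normal(3.4, 0.9) (permil).
#'
#' @param d13C_mean,d13C_sd,d15N_mean,d15N_sd Prior moments (sd `> 0`).
#' @return List of class `tef_prior` with named `mean` and `sd` vectors.
#' @export
tef_prior <- function(d13C_mean = 0.39, d13C_sd = 1.14,
                      d15N_mean = 3.4, d15N_sd = 0.9) {
  if (d13C_sd <= 0 || d15N_sd <= 0) stop("prior sd must be > 0", call. = FALSE)
  structure(list(mean = c(d13C = d13C_mean, d15N = d15N_mean),
                 sd = c(d13C = d13C_sd, d15N = d15N_sd)),
            class = "tef_prior")
}

#' Expected consumer signature under the mixing model
#'
#' Per tracer `t`: `sum_s phi_s * (delta_{t,s} + tef_t * L)` — each source
#' signature is shifted by the trophic enrichment accumulated over `L`
#' trophic levels, then mixed by the source proportions.
#'
#' @param sources Numeric matrix `[source, tracer]` of source signatures.
#' @param phi Simplex of source proportions (length `nrow(sources)`).
#' @param tef Named numeric per tracer, trophic enrichment factor.
#' @param L Trophic level.
#' @return Named numeric, expected value per tracer.
#' @export
consumer_expectation <- function(sources, phi, tef, L) {
  sources <- as.matrix(sources)
  if (length(phi) != nrow(sources)) {
    stop("phi length must match the number of sources", call. = FALSE)
  }
  if (length(tef) != ncol(sources)) {
    stop("tef length must match the number of tracers", call. = FALSE)
  }
  if (any(phi < 0) || abs(sum(phi) - 1) > 1e-9) {
    stop("phi must be a simplex", call. = FALSE)
  }
  stats::setNames(as.vector(crossprod(sources, phi)) + tef * L,
                  colnames(sources))
}

#' Stage-2 parameter point
#'
#' @param phi Named simplex over sources.
#' @param L Trophic level in `[0, 10]`.
#' @param tef Named per-tracer trophic enrichment factor (permil).
#' @param delta_src Matrix `[source, tracer]` of latent source signatures.
#' @param sigma_c Named per-tracer residual sd (`> 0`).
#' @return List of class `stage2_params`.
#' @export
stage2_params <- function(phi, L, tef, delta_src, sigma_c) {
  structure(list(phi = phi, L = L, tef = tef, delta_src = delta_src,
                 sigma_c = sigma_c),
            class = "stage2_params")
}

.stage2_cell_data <- function(data, taxon, land_use) {
  obs <- data$observations
  sel <- obs$category == paste0("consumer:", taxon) & obs$land_use == land_use
  obs[sel, , drop = FALSE]
}

#' Stage-2 log posterior density for one consumer cell
#'
#' Log prior (Dirichlet(1,...,1) on `phi`, Uniform(0, 10) on `L`, normal
#' TEF and source-signature priors, half-normal(0, 3) residual scales)
#' plus the normal likelihood of the cell's observations. Off-support
#' points (`phi` off the simplex, `L` outside `[0, 10]`, `sigma_c <= 0`)
#' return `-Inf`.
#'
#' @param params A [stage2_params()] point.
#' @param cell_data Data frame of the cell's observations (columns `d13C`,
#'   `d15N`), all one taxon and land use.
#' @param sources A [source_set()].
#' @param tef A [tef_prior()].
#' @return Scalar log density (unnormalised).
#' @export
stage2_log_posterior <- function(params, cell_data, sources,
                                 tef = tef_prior()) {
  if (nrow(cell_data) == 0) stop("cell_data is empty", call. = FALSE)
  tr <- tracer_levels()
  S <- length(sources$labels)
  phi <- params$phi
  if (length(phi) != S) stop("phi length != number of sources", call. = FALSE)
  if (any(phi < 0) || abs(sum(phi) - 1) > 1e-9) return(-Inf)
  if (params$L < 0 || params$L > 10) return(-Inf)
  sigma_c <- params$sigma_c[tr]
  if (any(sigma_c <= 0)) return(-Inf)

  lp <- lgamma(S) - log(10) # Dirichlet(1,...,1) + U(0,10)
  lp <- lp + sum(stats::dnorm(params$tef[tr], tef$mean[tr], tef$sd[tr],
                              log = TRUE))
  lp <- lp + sum(stats::dnorm(params$delta_src, sources$mean, sources$sd,
                              log = TRUE))
  lp <- lp + sum(log(2) + stats::dnorm(sigma_c, 0, 3, log = TRUE))

  for (t in tr) {
    y <- cell_data[[t]]
    y <- y[!is.na(y)]
    if (length(y) == 0) next
    mu <- sum(phi * (params$delta_src[, t] + params$tef[t] * params$L))
    lp <- lp + sum(stats::dnorm(y, mu, sigma_c[t], log = TRUE))
  }
  unname(lp)
}

# Fit one cell; returns a posterior_draws over labelled parameters.
#
# The Gaussian latents are integrated out of the likelihood analytically:
# writing theta_t = (delta_{t,1:S}, e_t) with e_t = tef_t * L (the
# accumulated enrichment shift) and a = (phi, 1), each observation is
# y_i = a' theta_t + eps_i, and theta_t has a normal prior (e_t | L ~
# Normal(tef_mean * L, (tef_sd * L)^2)). Marginally the cell's
# observations are exchangeable normal with mean a' m_t and covariance
# sigma_c^2 I + (a' D_t a) J, so the sampler only has to walk the
# (S - 1) + 2 + 1 marginal coordinates (phi sticks, sigma_c per tracer,
# L) — a low-dimensional, ridge-free target. The latent theta_t draws
# reported alongside are exact conjugate (Kalman-update) posterior draws
# given each stored (phi, L, sigma_c).
.fit_stage2_cell <- function(y13, y15, sources, tef, cfg) {
  S <- length(sources$labels)
  tr <- tracer_levels()
  specs <- list(param_spec("phi", "simplex", k = S),
                param_spec("L", "interval", lower = 0, upper = 10),
                param_spec("sigma_c[d13C]", "positive"),
                param_spec("sigma_c[d15N]", "positive"))
  tf <- make_transform(specs)
  i_phi <- 1:S
  i_L <- S + 1L
  i_sig <- S + 1L + 1:2

  src_mean <- sources$mean
  src_sd2 <- sources$sd^2
  tef_mean <- tef$mean[tr]
  tef_sd <- tef$sd[tr]
  lgS <- lgamma(S) - log(10)

  stats_t <- list(
    d13C = list(n = length(y13), ybar = mean(y13),
                ss = sum((y13 - mean(y13))^2)),
    d15N = list(n = length(y15), ybar = mean(y15),
                ss = sum((y15 - mean(y15))^2))
  )

  # marginal log likelihood of one tracer given (phi, L, sigma)
  marg_ll <- function(st, mt, vt, e_mean, e_var, phi, sigma) {
    if (st$n == 0) return(0)
    mu0 <- sum(phi * mt) + e_mean
    v <- sum(phi^2 * vt) + e_var
    s2 <- sigma^2
    -0.5 * (st$n * log(2 * pi) + (st$n - 1) * log(s2) + log(s2 + st$n * v) +
              st$ss / s2 + st$n * (st$ybar - mu0)^2 / (s2 + st$n * v))
  }

  log_post_y <- function(y) {
    res <- tf$constrain(y)
    x <- res$x
    phi <- x[i_phi]
    L <- x[i_L]
    sig <- x[i_sig]
    lp <- lgS + sum(log(2) + stats::dnorm(sig, 0, 3, log = TRUE)) +
      marg_ll(stats_t$d13C, src_mean[, 1L], src_sd2[, 1L],
              tef_mean[1L] * L, (tef_sd[1L] * L)^2, phi, sig[1L]) +
      marg_ll(stats_t$d15N, src_mean[, 2L], src_sd2[, 2L],
              tef_mean[2L] * L, (tef_sd[2L] * L)^2, phi, sig[2L])
    lp + res$log_jac
  }

  x0 <- c(rep(1 / S, S), 2, 1.5, 1.5)
  y0 <- tf$unconstrain(x0)
  init <- rep(list(stats::setNames(as.numeric(y0),
                                   unconstrained_names(tf$specs))),
              cfg$chains)

  y_draws <- sample_posterior(log_post_y, init, cfg)
  d <- dim(y_draws)
  flat <- matrix(as.vector(unclass(y_draws)), nrow = d[1] * d[2], ncol = d[3])
  con <- t(apply(flat, 1L, function(y) tf$constrain(y)$x))

  # exact conjugate draws of the latents (delta_src, e) per stored draw,
  # vectorised over draws through the rank-1 Kalman update
  set.seed(cfg$seed + 524287L)
  n_draws <- nrow(con)
  phi_m <- con[, i_phi, drop = FALSE]
  L_v <- con[, i_L]
  latents <- matrix(NA_real_, n_draws, 2L * (S + 1L))
  lat_names <- character(2L * (S + 1L))
  for (ti in 1:2) {
    st <- stats_t[[tr[ti]]]
    prior_mean <- cbind(matrix(src_mean[, ti], n_draws, S, byrow = TRUE),
                        tef_mean[ti] * L_v)
    prior_var <- cbind(matrix(src_sd2[, ti], n_draws, S, byrow = TRUE),
                       (tef_sd[ti] * L_v)^2 + 1e-12)
    a <- cbind(phi_m, 1)
    z <- matrix(stats::rnorm(n_draws * (S + 1L)), n_draws, S + 1L)
    if (st$n > 0) {
      sig2_n <- con[, i_sig[1L] + (ti - 1L)]^2 / st$n
      aDa <- rowSums(a^2 * prior_var)
      gain <- prior_var * a / (sig2_n + aDa) # K = D a / (s2/n + a'Da)
      resid <- st$ybar - rowSums(a * prior_mean)
      post_mean <- prior_mean + gain * resid
      kappa <- aDa / (sig2_n + aDa)
      theta <- 1 - sqrt(1 - kappa)
      sqrt_d <- sqrt(prior_var)
      u <- sqrt_d * a / sqrt(aDa)
      uz <- rowSums(u * z)
      latents[, (ti - 1L) * (S + 1L) + 1:(S + 1L)] <-
        post_mean + sqrt_d * z - theta * uz * sqrt_d * u
    } else {
      latents[, (ti - 1L) * (S + 1L) + 1:(S + 1L)] <-
        prior_mean + sqrt(prior_var) * z
    }
    lat_names[(ti - 1L) * (S + 1L) + 1:(S + 1L)] <-
      c(paste0("delta_src[", sources$labels, ",", tr[ti], "]"),
        paste0("tef[", tr[ti], "]"))
  }
  # e back to tef = e / L
  for (ti in 1:2) {
    col <- (ti - 1L) * (S + 1L) + S + 1L
    latents[, col] <- latents[, col] / L_v
  }

  con <- cbind(con, latents)
  out_names <- c(paste0("phi[", sources$labels, "]"), "L",
                 paste0("sigma_c[", tr, "]"), lat_names)
  colnames(con) <- out_names
  arr <- array(con, dim = c(d[1], d[2], ncol(con)),
               dimnames = list(NULL, NULL, out_names))
  posterior_draws(arr, warmup = cfg$warmup, seed = cfg$seed)
}

#' Fit the stage-2 mixing model to every consumer cell
#'
#' Fits one independent posterior per consumer taxon x land-use cell with
#' at least one observation; empty cells are skipped with a warning and
#' listed in the result. Carbon and nitrogen are fit jointly per cell
#' (shared `phi` and `L`).
#'
#' @param data An [isotope_dataset()] containing consumer observations.
#' @param sources A single [source_set()] applied to every cell, or a
#'   named list of source sets indexed by land use (the usual case: algal
#'   priors differ by land use).
#' @param tef A [tef_prior()].
#' @param cfg An [mcmc_config()]; per-chain seeds are derived from
#'   `cfg$seed` plus a cell offset so cells are independent but
#'   reproducible.
#' @return Object of class `stage2_fit`: list of cells (each with draws,
#'   convergence report and labels), plus metadata.
#' @export
fit_stage2 <- function(data, sources, tef = tef_prior(),
                       cfg = mcmc_config()) {
  stopifnot(inherits(data, "isotope_dataset"))
  obs <- data$observations
  consumers <- obs[startsWith(obs$category, "consumer:"), , drop = FALSE]
  if (nrow(consumers) == 0) stop("no consumer observations", call. = FALSE)
  consumers$taxon <- sub("^consumer:", "", consumers$category)

  cells_idx <- unique(consumers[, c("taxon", "land_use")])
  # stable reporting order: land use, then guild, then first appearance
  lu_rank <- match(cells_idx$land_use, land_use_levels())
  guild <- vapply(seq_len(nrow(cells_idx)), function(i) {
    g <- consumers$guild[consumers$taxon == cells_idx$taxon[i] &
                           consumers$land_use == cells_idx$land_use[i]]
    g[1]
  }, character(1))
  g_rank <- match(guild, guild_levels())
  ord <- order(lu_rank, g_rank, seq_len(nrow(cells_idx)))
  cells_idx <- cells_idx[ord, , drop = FALSE]
  guild <- guild[ord]

  cells <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(cells_idx))) {
    taxon <- cells_idx$taxon[i]
    lu <- cells_idx$land_use[i]
    cell <- consumers[consumers$taxon == taxon & consumers$land_use == lu, ]
    y13 <- cell$d13C[!is.na(cell$d13C)]
    y15 <- cell$d15N[!is.na(cell$d15N)]
    if (length(y13) + length(y15) == 0) {
      warning("cell ", taxon, "/", lu, " has no usable observations; skipped",
              call. = FALSE)
      skipped <- c(skipped, paste0(taxon, "/", lu))
      next
    }
    src <- if (inherits(sources, "source_set")) sources else sources[[lu]]
    if (is.null(src)) {
      stop("no source set for land use ", lu, call. = FALSE)
    }
    cell_cfg <- cfg
    cell_cfg$seed <- cfg$seed + 1000L * (i - 1L)
    draws <- .fit_stage2_cell(y13, y15, src, tef, cell_cfg)
    cells[[paste0(taxon, "/", lu)]] <- list(
      taxon = taxon, guild = guild[i], land_use = lu,
      n_obs = nrow(cell), sources = src$labels, draws = draws,
      convergence = convergence_report(draws, cfg))
  }
  structure(list(cells = cells, cfg = cfg, tef = tef, skipped = skipped),
            class = "stage2_fit")
}

#' @export
print.stage2_fit <- function(x, ...) {
  pass <- vapply(x$cells, function(c) c$convergence$pass, logical(1))
  cat("<stage2_fit> ", length(x$cells), " consumer cells (",
      sum(pass), " passed the convergence gate)\n", sep = "")
  if (length(x$skipped) > 0) {
    cat("  skipped: ", paste(x$skipped, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Grand-mean contribution of one source across consumer cells
#'
#' The unweighted arithmetic mean, over cells, of each cell's posterior
#' mean contribution of the named source — the study-level allochthony
#' statistic when applied to leaf litter.
#'
#' @param x A `stage2_fit`, or a numeric vector of per-cell posterior mean
#'   contributions (e.g. the means column of a printed report).
#' @param source Source label (ignored for numeric input).
#' @return Scalar in `[0, 1]`.
#' @export
allochthony_grand_mean <- function(x, source = "leaf_litter") {
  if (is.numeric(x)) {
    if (length(x) == 0) stop("need >= 1 cell", call. = FALSE)
    return(mean(x))
  }
  stopifnot(inherits(x, "stage2_fit"))
  if (length(x$cells) == 0) stop("need >= 1 cell", call. = FALSE)
  per_cell <- vapply(x$cells, function(cell) {
    lab <- paste0("phi[", source, "]")
    if (!lab %in% parameters(cell$draws)) {
      stop("unknown source label: ", source, call. = FALSE)
    }
    mean(extract_draws(cell$draws, lab, pooled = TRUE))
  }, numeric(1))
  mean(per_cell)
}
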