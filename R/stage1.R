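# Stage 1: estimate the algal isotopic endmember per land use by unmixing
# biofilm into an algal and a terrestrial (leaf litter) component.
#
# Model, per land use j and tracer t:
#   biofilm:  d_P ~ Normal(delta_A[j,t] * (1 - phi_T[j]) +
#                          delta_T[j,t] * phi_T[j], sigma[t])
#   endmember: delta_A[j,t] ~ Normal(delta_f[t] + beta_c[t]*[j = coffee] +
#                                    beta_p[t]*[j = pasture], sigma_delta[t])
#   fractions: phi_T[forest] = phi_f, phi_T[coffee] = phi_f - alpha_c,
#              phi_T[pasture] = phi_f - alpha_p; joint prior truncated to
#              the region where every phi_T lies in [0, 1].
# delta_T is the per-land-use litter sample mean (litter treated as a
# measured source). phi_T is shared across tracers by default (one biofilm
# has one composition); per-tracer fractions sit behind `share_phi = FALSE`.

#' Informative literature prior for the algal endmember
#'
#' Defaults summarise published measurements of algae in tropical streams:
#' \eqn{\delta^{13}}C ~ Normal(-23.72, 4.10),
#' \eqn{\delta^{15}}N ~ Normal(4.10, 3.13) (permil).
#'
#' @param d13C_mean,d13C_sd,d15N_mean,d15N_sd Prior moments (sd `> 0`).
#' @return List of class `algal_prior` with named `mean` and `sd` vectors.
#' @export
algal_prior <- function(d13C_mean = -23.72, d13C_sd = 4.10,
                        d15N_mean = 4.10, d15N_sd = 3.13) {
  if (d13C_sd <= 0 || d15N_sd <= 0) stop("prior sd must be > 0", call. = FALSE)
  structure(list(mean = c(d13C = d13C_mean, d15N = d15N_mean),
                 sd = c(d13C = d13C_sd, d15N = d15N_sd)),
            class = "algal_prior")
}

#' Stage-1 parameter point
#'
#' Collects one value of every stage-1 parameter; used to evaluate
#' [stage1_log_posterior()] and as the sampler initialisation.
#'
#' @param delta_f Named per-tracer forest-baseline algal endmember (permil).
#' @param beta_c,beta_p Named per-tracer land-use offsets on the endmember.
#' @param sigma_delta Named per-tracer endmember scale (`> 0`).
#' @param delta_A Matrix `[land_use, tracer]` of algal endmembers.
#' @param phi_f Forest terrestrial fraction (scalar, or per tracer when
#'   fractions are tracer-specific).
#' @param alpha_c,alpha_p Land-use offsets on the terrestrial fraction.
#' @param sigma Named per-tracer biofilm likelihood sd (`> 0`).
#' @return List of class `stage1_params`.
#' @export
stage1_params <- function(delta_f, beta_c = c(d13C = 0, d15N = 0),
                          beta_p = c(d13C = 0, d15N = 0),
                          sigma_delta = c(d13C = 1, d15N = 1),
                          delta_A, phi_f = 0.5, alpha_c = 0, alpha_p = 0,
                          sigma = c(d13C = 1, d15N = 1)) {
  structure(list(delta_f = delta_f, beta_c = beta_c, beta_p = beta_p,
                 sigma_delta = sigma_delta, delta_A = delta_A,
                 phi_f = phi_f, alpha_c = alpha_c, alpha_p = alpha_p,
                 sigma = sigma),
            class = "stage1_params")
}

# Precompute everything the likelihood needs from a dataset.
.stage1_prepare <- function(data) {
  stopifnot(inherits(data, "isotope_dataset"))
  obs <- data$observations
  tr <- tracer_levels()
  land_uses <- intersect(land_use_levels(), unique(obs$land_use))
  biofilm <- list()
  litter_mean <- matrix(NA_real_, length(land_uses), length(tr),
                        dimnames = list(land_uses, tr))
  litter_sd <- litter_mean
  n_litter <- stats::setNames(integer(length(land_uses)), land_uses)
  for (lu in land_uses) {
    sub <- obs[obs$land_use == lu, , drop = FALSE]
    bio <- sub[sub$category == "biofilm", , drop = FALSE]
    lit <- sub[sub$category == "leaf_litter", , drop = FALSE]
    # sufficient statistics (n, mean, centred SS) per tracer: the normal
    # likelihood only needs these
    biofilm[[lu]] <- lapply(stats::setNames(tr, tr), function(t) {
      v <- bio[[t]]
      v <- v[!is.na(v)]
      if (length(v) == 0) {
        list(n = 0L, ybar = NA_real_, ss = 0)
      } else {
        list(n = length(v), ybar = mean(v), ss = sum((v - mean(v))^2))
      }
    })
    for (t in tr) {
      v <- lit[[t]]
      v <- v[!is.na(v)]
      if (length(v) > 0) {
        litter_mean[lu, t] <- mean(v)
        litter_sd[lu, t] <- if (length(v) > 1) stats::sd(v) else 0
      }
    }
    n_litter[lu] <- nrow(lit)
  }
  list(land_uses = land_uses, biofilm = biofilm, litter_mean = litter_mean,
       litter_sd = litter_sd, n_litter = n_litter)
}

.stage1_lp <- function(params, prep, prior, share_phi = TRUE) {
  tr <- tracer_levels()
  lus <- prep$land_uses
  n_phi <- if (share_phi) 1L else 2L
  phi_f <- rep_len(params$phi_f, n_phi)
  alpha_c <- rep_len(params$alpha_c, n_phi)
  alpha_p <- rep_len(params$alpha_p, n_phi)
  sigma <- params$sigma[tr]
  sigma_delta <- params$sigma_delta[tr]

  if (any(phi_f < 0 | phi_f > 1)) return(-Inf)
  if (any(sigma <= 0) || any(sigma_delta <= 0)) return(-Inf)
  phi_T <- sapply(seq_len(n_phi), function(k) {
    vapply(lus, function(lu) {
      switch(lu, forest = phi_f[k], coffee = phi_f[k] - alpha_c[k],
             pasture = phi_f[k] - alpha_p[k])
    }, numeric(1))
  })
  phi_T <- matrix(phi_T, nrow = length(lus), dimnames = list(lus, NULL))
  if (any(phi_T < 0 | phi_T > 1)) return(-Inf)

  lp <- sum(stats::dnorm(params$delta_f[tr], prior$mean[tr], prior$sd[tr],
                         log = TRUE))
  if ("coffee" %in% lus) {
    lp <- lp + sum(stats::dnorm(params$beta_c[tr], 0, 1, log = TRUE)) +
      sum(stats::dnorm(alpha_c, 0, 1, log = TRUE))
  }
  if ("pasture" %in% lus) {
    lp <- lp + sum(stats::dnorm(params$beta_p[tr], 0, 1, log = TRUE)) +
      sum(stats::dnorm(alpha_p, 0, 1, log = TRUE))
  }
  # phi_f ~ U(0,1): contributes 0. Half-normal scale priors:
  lp <- lp + sum(log(2) + stats::dnorm(sigma, 0, 10, log = TRUE)) +
    sum(log(2) + stats::dnorm(sigma_delta, 0, 5, log = TRUE))

  for (ti in seq_along(tr)) {
    t <- tr[ti]
    k <- if (share_phi) 1L else ti
    for (lu in lus) {
      mu_A <- params$delta_f[t] +
        (lu == "coffee") * params$beta_c[t] +
        (lu == "pasture") * params$beta_p[t]
      dA <- params$delta_A[lu, t]
      lp <- lp + stats::dnorm(dA, mu_A, sigma_delta[t], log = TRUE)
      st <- prep$biofilm[[lu]][[t]]
      if (st$n > 0) {
        mu <- dA * (1 - phi_T[lu, k]) + prep$litter_mean[lu, t] * phi_T[lu, k]
        s2 <- sigma[t]^2
        lp <- lp - 0.5 * (st$n * log(2 * pi * s2) +
                            (st$ss + st$n * (st$ybar - mu)^2) / s2)
      }
    }
  }
  unname(lp)
}

#' Stage-1 log posterior density
#'
#' Log prior plus log likelihood of the endmember model at one parameter
#' point. Parameter values outside the admissible region (any terrestrial
#' fraction outside `[0, 1]`, non-positive scales) return `-Inf`, never an
#' error.
#'
#' @param params A [stage1_params()] point.
#' @param data An [isotope_dataset()] with biofilm and leaf-litter rows for
#'   every land use it contains.
#' @param prior An [algal_prior()].
#' @param share_phi Share the terrestrial fraction across tracers
#'   (default) or give each tracer its own.
#' @return Scalar log density (unnormalised).
#' @export
stage1_log_posterior <- function(params, data, prior = algal_prior(),
                                 share_phi = TRUE) {
  prep <- .stage1_prepare(data)
  missing_lit <- prep$land_uses[!is.finite(prep$litter_mean[, 1])]
  if (length(missing_lit) > 0) {
    stop("no leaf-litter observations for land use(s): ",
         paste(missing_lit, collapse = ", "), call. = FALSE)
  }
  .stage1_lp(params, prep, prior, share_phi = share_phi)
}

#' Fit the stage-1 endmember model
#'
#' Samples the joint posterior of the algal endmembers `delta_A`, the
#' terrestrial fractions `phi_T`, land-use offsets and scales with the
#' adaptive random-walk engine, and gates the result with
#' [convergence_report()]. Land uses lacking biofilm observations abort
#' unless `allow_prior_only = TRUE`, in which case those land uses are
#' dropped from the hierarchical fit and their algal endmember is reported
#' as the exact no-data posterior of the collapsed model — independent
#' draws from the [algal_prior()].
#'
#' @param data An [isotope_dataset()].
#' @param prior An [algal_prior()].
#' @param cfg An [mcmc_config()].
#' @param share_phi Share the terrestrial fraction across tracers.
#' @param allow_prior_only Admit land uses without biofilm data (see
#'   above).
#' @return Object of class `stage1_fit`: posterior draws (including
#'   derived `phi_T[...]` per land use), convergence report, litter
#'   summaries and fit metadata. Non-convergence sets
#'   `convergence$pass = FALSE`; it never fails silently.
#' @export
fit_stage1 <- function(data, prior = algal_prior(), cfg = mcmc_config(),
                       share_phi = TRUE, allow_prior_only = FALSE) {
  prep_all <- .stage1_prepare(data)
  tr <- tracer_levels()

  has_bio <- vapply(prep_all$land_uses, function(lu) {
    any(vapply(prep_all$biofilm[[lu]], function(s) s$n > 0, logical(1)))
  }, logical(1))
  has_lit <- is.finite(prep_all$litter_mean[, 1]) &
    is.finite(prep_all$litter_mean[, 2])
  prior_only <- character(0)
  if (any(!has_bio | !has_lit)) {
    lacking <- prep_all$land_uses[!has_bio | !has_lit]
    if (!allow_prior_only) {
      stop("land use(s) not stage1-ready (need biofilm and leaf litter): ",
           paste(lacking, collapse = ", "), call. = FALSE)
    }
    prior_only <- lacking
  }
  fit_lus <- setdiff(prep_all$land_uses, prior_only)
  if (length(fit_lus) == 0 && length(prior_only) == 0) {
    stop("dataset contains no land uses", call. = FALSE)
  }

  draws <- NULL
  if (length(fit_lus) > 0) {
    J <- length(fit_lus)
    n_phi <- if (share_phi) 1L else 2L
    has_c <- "coffee" %in% fit_lus
    has_p <- "pasture" %in% fit_lus

    # The Gaussian endmember block theta_t = (delta_f, beta_c, beta_p,
    # delta_A[1:J]) per tracer is integrated out analytically: given the
    # fractions and scales, the per-land-use biofilm means are jointly
    # normal, ybar ~ N(w * prior_mean + phi_T * delta_T, (w w') o Sigma_AA
    # + diag(sigma^2 / n)) with w = 1 - phi_T. The sampler therefore only
    # walks (phi_f, alpha_c, alpha_p, sigma_delta, sigma); the block is
    # reconstructed afterwards with exact conjugate (Kalman-update) draws.
    theta_names <- lapply(stats::setNames(tr, tr), function(t) {
      c(paste0("delta_f[", t, "]"),
        if (has_c) paste0("beta_c[", t, "]"),
        if (has_p) paste0("beta_p[", t, "]"),
        paste0("delta_A[", fit_lus, ",", t, "]"))
    })
    m_dim <- length(theta_names[[1]])
    iA <- (m_dim - J + 1L):m_dim # delta_A columns within theta
    Ic <- as.numeric(fit_lus == "coffee")
    Ip <- as.numeric(fit_lus == "pasture")

    base_cov <- function(ps2) {
      # prior covariance of theta without the sigma_delta^2 diagonal
      M <- matrix(0, m_dim, m_dim)
      M[1, 1] <- ps2
      M[1, iA] <- M[iA, 1] <- ps2
      pos <- 2L
      if (has_c) {
        M[pos, pos] <- 1
        M[pos, iA] <- M[iA, pos] <- Ic
        pos <- pos + 1L
      }
      if (has_p) {
        M[pos, pos] <- 1
        M[pos, iA] <- M[iA, pos] <- Ip
      }
      M[iA, iA] <- ps2 + outer(Ic, Ic) + outer(Ip, Ip)
      M
    }
    Sigma_base <- lapply(stats::setNames(tr, tr), function(t) {
      base_cov(prior$sd[t]^2)
    })
    m0 <- lapply(stats::setNames(tr, tr), function(t) {
      v <- numeric(m_dim)
      v[1] <- prior$mean[t]
      v[iA] <- prior$mean[t]
      v
    })

    bstats <- lapply(stats::setNames(tr, tr), function(t) {
      n <- vapply(fit_lus, function(lu) prep_all$biofilm[[lu]][[t]]$n,
                  integer(1))
      list(n = n,
           ybar = vapply(fit_lus, function(lu) {
             prep_all$biofilm[[lu]][[t]]$ybar
           }, numeric(1)),
           ss = vapply(fit_lus, function(lu) {
             prep_all$biofilm[[lu]][[t]]$ss
           }, numeric(1)),
           obs = which(n > 0),
           dT = prep_all$litter_mean[fit_lus, t])
    })

    specs <- list()
    add <- function(s) specs[[length(specs) + 1L]] <<- s
    phi_nms <- if (n_phi == 1L) "phi_f" else paste0("phi_f[", tr, "]")
    ac_nms <- if (n_phi == 1L) "alpha_c" else paste0("alpha_c[", tr, "]")
    ap_nms <- if (n_phi == 1L) "alpha_p" else paste0("alpha_p[", tr, "]")
    for (nm in phi_nms) add(param_spec(nm, "unit"))
    if (has_c) for (nm in ac_nms) add(param_spec(nm, "real"))
    if (has_p) for (nm in ap_nms) add(param_spec(nm, "real"))
    for (t in tr) add(param_spec(paste0("sigma_delta[", t, "]"), "positive"))
    for (t in tr) add(param_spec(paste0("sigma[", t, "]"), "positive"))
    tf <- make_transform(specs)
    i_phi_f <- match(phi_nms, tf$par_names)
    i_ac <- if (has_c) match(ac_nms, tf$par_names)
    i_ap <- if (has_p) match(ap_nms, tf$par_names)
    i_sd <- match(paste0("sigma_delta[", tr, "]"), tf$par_names)
    i_sg <- match(paste0("sigma[", tr, "]"), tf$par_names)

    phi_T_of <- function(x, k) {
      pf <- x[i_phi_f[k]]
      out <- rep(pf, J)
      if (has_c) out[Ic == 1] <- pf - x[i_ac[k]]
      if (has_p) out[Ip == 1] <- pf - x[i_ap[k]]
      out
    }

    # marginal log likelihood of one tracer given fractions and scales
    marg_ll_t <- function(ti, phi_T, sigma, sigma_delta) {
      st <- bstats[[ti]]
      obs <- st$obs
      s2 <- sigma^2
      ll <- sum(-(st$n[obs] - 1) / 2 * log(2 * pi * s2) -
                  0.5 * log(st$n[obs]) - st$ss[obs] / (2 * s2))
      w <- 1 - phi_T[obs]
      SAA <- Sigma_base[[ti]][iA, iA, drop = FALSE][obs, obs, drop = FALSE] +
        diag(sigma_delta^2, length(obs))
      V <- (w %o% w) * SAA + diag(s2 / st$n[obs], length(obs))
      mu <- w * prior$mean[ti] + phi_T[obs] * st$dT[obs]
      r <- st$ybar[obs] - mu
      R <- chol(V)
      z <- backsolve(R, r, transpose = TRUE)
      ll - sum(log(diag(R))) - 0.5 * sum(z^2) -
        length(obs) / 2 * log(2 * pi)
    }

    log_post_y <- function(y) {
      res <- tf$constrain(y)
      x <- res$x
      sigma <- x[i_sg]
      sigma_delta <- x[i_sd]
      lp <- sum(log(2) + stats::dnorm(sigma, 0, 10, log = TRUE)) +
        sum(log(2) + stats::dnorm(sigma_delta, 0, 5, log = TRUE))
      for (ti in 1:2) {
        k <- if (n_phi == 1L) 1L else ti
        phi_T <- phi_T_of(x, k)
        if (any(phi_T < 0 | phi_T > 1)) return(-Inf)
        if (has_c && k == ti) {
          lp <- lp + stats::dnorm(x[i_ac[k]], 0, 1, log = TRUE)
        }
        if (has_p && k == ti) {
          lp <- lp + stats::dnorm(x[i_ap[k]], 0, 1, log = TRUE)
        }
        lp <- lp + marg_ll_t(ti, phi_T, sigma[ti], sigma_delta[ti])
      }
      lp + res$log_jac
    }

    x0 <- numeric(length(tf$par_names))
    x0[i_phi_f] <- 0.5
    x0[i_sd] <- 2
    x0[i_sg] <- 2
    y0 <- tf$unconstrain(x0)
    init <- rep(list(stats::setNames(as.numeric(y0),
                                     unconstrained_names(tf$specs))),
                cfg$chains)

    y_draws <- sample_posterior(log_post_y, init, cfg)

    d <- dim(y_draws)
    flat <- matrix(as.vector(unclass(y_draws)), nrow = d[1] * d[2],
                   ncol = d[3])
    con <- t(apply(flat, 1L, function(y) tf$constrain(y)$x))
    colnames(con) <- tf$par_names

    # exact conjugate reconstruction of the Gaussian endmember block
    set.seed(cfg$seed + 262139L)
    n_draws <- nrow(con)
    theta_draws <- matrix(NA_real_, n_draws, 2L * m_dim)
    for (ti in 1:2) {
      st <- bstats[[ti]]
      obs <- st$obs
      cols <- (ti - 1L) * m_dim + seq_len(m_dim)
      for (i in seq_len(n_draws)) {
        k <- if (n_phi == 1L) 1L else ti
        phi_T <- phi_T_of(con[i, ], k)
        Sigma0 <- Sigma_base[[ti]]
        diag(Sigma0)[iA] <- diag(Sigma0)[iA] + con[i, i_sd[ti]]^2
        z <- stats::rnorm(m_dim)
        if (length(obs) > 0) {
          w <- 1 - phi_T[obs]
          M <- Sigma0[, iA[obs], drop = FALSE] *
            rep(w, each = m_dim) # Sigma0 C'
          V <- (w %o% w) * Sigma0[iA[obs], iA[obs], drop = FALSE] +
            diag(con[i, i_sg[ti]]^2 / st$n[obs], length(obs))
          K <- M %*% solve(V)
          mu <- w * prior$mean[ti] + phi_T[obs] * st$dT[obs]
          m_post <- m0[[ti]] + drop(K %*% (st$ybar[obs] - mu))
          S_post <- Sigma0 - K %*% t(M)
          S_post <- (S_post + t(S_post)) / 2 + diag(1e-10, m_dim)
          theta_draws[i, cols] <- m_post + drop(crossprod(chol(S_post), z))
        } else {
          theta_draws[i, cols] <- m0[[ti]] +
            drop(crossprod(chol(Sigma0 + diag(1e-10, m_dim)), z))
        }
      }
    }
    colnames(theta_draws) <- unlist(theta_names, use.names = FALSE)
    con <- cbind(con, theta_draws)

    # derived terrestrial fractions
    for (k in seq_len(n_phi)) {
      suffix <- if (n_phi == 1L) "" else paste0(",", tr[k])
      for (j in seq_len(J)) {
        val <- con[, i_phi_f[k]]
        if (Ic[j] == 1) val <- val - con[, i_ac[k]]
        if (Ip[j] == 1) val <- val - con[, i_ap[k]]
        con <- cbind(con, val)
        colnames(con)[ncol(con)] <- paste0("phi_T[", fit_lus[j], suffix, "]")
      }
    }
    arr <- array(con, dim = c(d[1], d[2], ncol(con)),
                 dimnames = list(NULL, NULL, colnames(con)))
    draws <- posterior_draws(arr, warmup = cfg$warmup, seed = cfg$seed)
  }

  # prior-only land uses: exact no-data posterior = the algal prior
  if (length(prior_only) > 0) {
    set.seed(cfg$seed + 104729L) # offset stream, still below 2^31
    n_it <- cfg$iterations
    extra <- array(NA_real_,
                   dim = c(n_it, cfg$chains, 2L * length(prior_only)))
    nms <- character(0)
    k <- 0L
    for (lu in prior_only) for (t in tr) {
      k <- k + 1L
      extra[, , k] <- stats::rnorm(n_it * cfg$chains, prior$mean[t],
                                   prior$sd[t])
      nms <- c(nms, paste0("delta_A[", lu, ",", t, "]"))
    }
    dimnames(extra)[[3]] <- nms
    if (is.null(draws)) {
      draws <- posterior_draws(extra, warmup = cfg$warmup, seed = cfg$seed)
    } else {
      both <- array(c(as.vector(unclass(draws)), as.vector(extra)),
                    dim = c(dim(draws)[1], dim(draws)[2],
                            dim(draws)[3] + dim(extra)[3]),
                    dimnames = list(NULL, NULL,
                                    c(parameters(draws), nms)))
      draws <- posterior_draws(both, warmup = cfg$warmup, seed = cfg$seed)
    }
  }

  convergence <- convergence_report(draws, cfg)
  structure(list(draws = draws, convergence = convergence, cfg = cfg,
                 prior = prior, land_uses = prep_all$land_uses,
                 prior_only = prior_only, share_phi = share_phi,
                 litter_mean = prep_all$litter_mean,
                 litter_sd = prep_all$litter_sd),
            class = "stage1_fit")
}

#' @export
print.stage1_fit <- function(x, ...) {
  cat("<stage1_fit> land uses: ", paste(x$land_uses, collapse = ", "),
      if (length(x$prior_only) > 0)
        paste0(" (prior-only: ", paste(x$prior_only, collapse = ", "), ")"),
      "\n  convergence: ", if (x$convergence$pass) "pass" else "FAILED GATE",
      " (max split R-hat ",
      formatC(x$convergence$max_rhat, digits = 3, format = "f"), ")\n",
      sep = "")
  invisible(x)
}

#' Summarise the algal endmember posterior per land use
#'
#' Collapses the stage-1 posterior of `delta_A` to a mean and sd per land
#' use and tracer, in the summary-row layout that feeds stage 2 as the
#' algal source prior.
#'
#' @param fit A `stage1_fit`.
#' @param check_convergence Warn when the convergence gate failed.
#' @return A `summary_rows` data frame with `category = "algae"`; `n` is
#'   the pooled posterior draw count.
#' @export
algal_summary <- function(fit, check_convergence = TRUE) {
  stopifnot(inherits(fit, "stage1_fit"))
  if (check_convergence && !fit$convergence$pass) {
    warning("stage-1 convergence gate failed; summaries may be unreliable",
            call. = FALSE)
  }
  tr <- tracer_levels()
  rows <- lapply(fit$land_uses, function(lu) {
    stats_t <- lapply(stats::setNames(tr, tr), function(t) {
      v <- extract_draws(fit$draws, paste0("delta_A[", lu, ",", t, "]"),
                         pooled = TRUE)
      c(mean = mean(v), sd = stats::sd(v), n = length(v))
    })
    data.frame(category = "algae", guild = NA_character_, land_use = lu,
               d13C_mean = stats_t$d13C[["mean"]],
               d13C_sd = stats_t$d13C[["sd"]],
               d15N_mean = stats_t$d15N[["mean"]],
               d15N_sd = stats_t$d15N[["sd"]],
               n = as.integer(stats_t$d13C[["n"]]))
  })
  as_summary_rows(do.call(rbind, rows))
}
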