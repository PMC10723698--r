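make_forest_data <- function(delta_A = -20, phi_T = 0.7, sigma = 1,
                             litter_mean = -30, n_bio = 200, n_lit = 200,
                             seed = 1) {
  tru <- stage1_truth("forest", delta_A = c(delta_A, 4), phi_T = phi_T,
                      litter_mean = c(litter_mean, -2),
                      litter_sd = c(1, 1), sigma = c(sigma, sigma))
  simulate_stage1(tru, n_bio, n_lit, seed = seed)
}

test_that("the joint density rejects inadmissible regions, never errors", {
  ds <- make_forest_data(n_bio = 5, n_lit = 5)
  base <- stage1_params(
    delta_f = c(d13C = -23.72, d15N = 4.10),
    delta_A = matrix(c(-20, 4), 1, 2,
                     dimnames = list("forest", c("d13C", "d15N"))),
    phi_f = 0.5)
  expect_true(is.finite(stage1_log_posterior(base, ds)))
  off <- base
  off$phi_f <- 1.2
  expect_identical(stage1_log_posterior(off, ds), -Inf)
  neg <- base
  neg$sigma <- c(d13C = -1, d15N = 1)
  expect_identical(stage1_log_posterior(neg, ds), -Inf)
})

test_that("a biofilm observation at its mixture mean contributes the normal peak density", {
  # one biofilm observation exactly at delta_A (1 - phi) + delta_T phi with
  # sigma = 1 adds -log(sqrt(2 pi)) to the log posterior
  litter <- data.frame(sample_id = paste0("l", 1:2),
                       category = "leaf_litter", guild = NA,
                       land_use = "forest", d13C = c(-31, -29),
                       d15N = c(-2, -2))
  bio <- data.frame(sample_id = "b1", category = "biofilm", guild = NA,
                    land_use = "forest", d13C = -25, d15N = NA)
  params <- stage1_params(
    delta_f = c(d13C = -23.72, d15N = 4.10),
    delta_A = matrix(c(-20, 4), 1, 2,
                     dimnames = list("forest", c("d13C", "d15N"))),
    phi_f = 0.5) # mixture mean: -20 * 0.5 + (-30) * 0.5 = -25
  lp_with <- stage1_log_posterior(params, isotope_dataset(rbind(litter, bio)))
  lp_without <- stage1_log_posterior(params, isotope_dataset(litter))
  expect_equal(lp_with - lp_without, -0.5 * log(2 * pi), tolerance = 1e-12)

  # parameter points sharing the mixture mean and scales share the
  # likelihood term
  params2 <- params
  params2$delta_A[1, "d13C"] <- -25
  params2$phi_f <- 0 # mean: -25 * 1 + dT * 0 = -25
  lp2_with <- stage1_log_posterior(params2,
                                   isotope_dataset(rbind(litter, bio)))
  lp2_without <- stage1_log_posterior(params2, isotope_dataset(litter))
  expect_equal(lp2_with - lp2_without, lp_with - lp_without,
               tolerance = 1e-12)
})

test_that("collapsed sampling matches deterministic grid integration on the reduced model", {
  # reduced endmember model: one land use, one tracer, fixed sigma and
  # litter endmember; parameters (delta_A, phi_T)
  set.seed(43)
  dT <- -30
  sigma <- 1
  yb <- rnorm(30, -22 * 0.6 + dT * 0.4, sigma)
  n <- length(yb)
  ybar <- mean(yb)
  pm <- -23.72
  ps <- 4.10

  # oracle: 400 x 400 grid integration of the joint posterior
  dA_g <- seq(pm - 6 * ps, pm + 6 * ps, length.out = 400)
  ph_g <- seq(1 / 800, 1 - 1 / 800, length.out = 400)
  lg <- outer(dA_g, ph_g, function(a, p) {
    mu <- a * (1 - p) + dT * p
    dnorm(a, pm, ps, log = TRUE) - n * (ybar - mu)^2 / (2 * sigma^2)
  })
  w <- exp(lg - max(lg))
  w <- w / sum(w)
  o_mean <- c(dA = sum(rowSums(w) * dA_g), phi = sum(colSums(w) * ph_g))
  o_sd <- c(dA = sqrt(sum(rowSums(w) * dA_g^2) - o_mean[["dA"]]^2),
            phi = sqrt(sum(colSums(w) * ph_g^2) - o_mean[["phi"]]^2))

  # implementation route, as the production fits do it: sample the phi
  # marginal (delta_A integrated out), then reconstruct delta_A with
  # exact conjugate draws
  tf <- allomix:::make_transform(list(allomix:::param_spec("phi", "unit")))
  lp <- function(y) {
    r <- tf$constrain(y)
    p <- r$x[1]
    v <- (1 - p)^2 * ps^2 + sigma^2 / n
    mu <- (1 - p) * pm + p * dT
    dnorm(ybar, mu, sqrt(v), log = TRUE) + r$log_jac
  }
  dr <- sample_posterior(lp, c(phi = 0),
                         mcmc_config(chains = 4, iterations = 5000,
                                     warmup = 1000, seed = 8))
  p_d <- plogis(extract_draws(dr, "phi", pooled = TRUE))
  set.seed(99)
  k_gain <- ps^2 * (1 - p_d) / ((1 - p_d)^2 * ps^2 + sigma^2 / n)
  a_post_mean <- pm + k_gain * (ybar - ((1 - p_d) * pm + p_d * dT))
  a_post_sd <- sqrt(ps^2 - k_gain * (1 - p_d) * ps^2)
  a_d <- rnorm(length(p_d), a_post_mean, a_post_sd)

  expect_lt(abs(mean(p_d) - o_mean[["phi"]]) / o_mean[["phi"]], 0.02)
  expect_lt(abs(sd(p_d) - o_sd[["phi"]]) / o_sd[["phi"]], 0.02)
  expect_lt(abs(mean(a_d) - o_mean[["dA"]]) / abs(o_mean[["dA"]]), 0.02)
  expect_lt(abs(sd(a_d) - o_sd[["dA"]]) / o_sd[["dA"]], 0.02)
})

test_that("fit_stage1 agrees with direct MCMC on the full joint density", {
  # dual route on small forest-only data: collapsed fit vs an adaptive
  # walk over all nine natural-scale parameters through the exported
  # joint density
  ds <- make_forest_data(delta_A = -21, phi_T = 0.5, sigma = 1.5,
                         n_bio = 40, n_lit = 40, seed = 5)
  f1 <- fit_stage1(ds, cfg = mcmc_config(chains = 4, iterations = 3000,
                                         warmup = 1000, seed = 21))
  prep <- allomix:::.stage1_prepare(ds)
  prior <- algal_prior()
  tf <- allomix:::make_transform(list(
    allomix:::param_spec("delta_f[d13C]", "real"),
    allomix:::param_spec("delta_f[d15N]", "real"),
    allomix:::param_spec("sigma_delta[d13C]", "positive"),
    allomix:::param_spec("sigma_delta[d15N]", "positive"),
    allomix:::param_spec("delta_A[d13C]", "real"),
    allomix:::param_spec("delta_A[d15N]", "real"),
    allomix:::param_spec("phi_f", "unit"),
    allomix:::param_spec("sigma[d13C]", "positive"),
    allomix:::param_spec("sigma[d15N]", "positive")))
  lp <- function(y) {
    r <- tf$constrain(y)
    x <- r$x
    p <- stage1_params(
      delta_f = c(d13C = x[1], d15N = x[2]),
      sigma_delta = c(d13C = x[3], d15N = x[4]),
      delta_A = matrix(x[5:6], 1, 2,
                       dimnames = list("forest", c("d13C", "d15N"))),
      phi_f = x[7], sigma = c(d13C = x[8], d15N = x[9]))
    v <- allomix:::.stage1_lp(p, prep, prior)
    if (!is.finite(v)) return(-Inf)
    v + r$log_jac
  }
  y0 <- tf$unconstrain(c(prior$mean[1], prior$mean[2], 2, 2, -25, 2, 0.5,
                         2, 2))
  dr <- sample_posterior(lp, setNames(as.numeric(y0), tf$par_names),
                         mcmc_config(chains = 4, iterations = 8000,
                                     warmup = 3000, seed = 31))
  direct_dA <- extract_draws(dr, "delta_A[d13C]", pooled = TRUE)
  direct_phi <- plogis(extract_draws(dr, "phi_f", pooled = TRUE))
  coll_dA <- extract_draws(f1$draws, "delta_A[forest,d13C]", pooled = TRUE)
  coll_phi <- extract_draws(f1$draws, "phi_T[forest]", pooled = TRUE)
  expect_lt(abs(mean(direct_dA) - mean(coll_dA)), 0.4)
  expect_lt(abs(mean(direct_phi) - mean(coll_phi)), 0.04)
  expect_lt(abs(sd(direct_dA) - sd(coll_dA)) / sd(coll_dA), 0.2)
})

test_that("with no biofilm data the algal posterior returns the prior", {
  litter <- do.call(rbind, lapply(c("forest", "pasture"), function(lu) {
    data.frame(sample_id = paste0("l", lu, 1:5),
               category = "leaf_litter", guild = NA, land_use = lu,
               d13C = rnorm(5, -31, 1), d15N = rnorm(5, -2, 1))
  }))
  bio <- data.frame(sample_id = paste0("b", 1:10), category = "biofilm",
                    guild = NA, land_use = "forest",
                    d13C = rnorm(10, -26, 1), d15N = rnorm(10, 0, 1))
  ds <- isotope_dataset(rbind(litter, bio))
  expect_error(fit_stage1(ds, cfg = quick_cfg()), "stage1-ready")
  f <- fit_stage1(ds, cfg = mcmc_config(chains = 2, iterations = 2500,
                                        warmup = 300, seed = 6),
                  allow_prior_only = TRUE)
  expect_identical(f$prior_only, "pasture")
  prior <- algal_prior()
  v <- extract_draws(f$draws, "delta_A[pasture,d13C]", pooled = TRUE)
  expect_lt(abs(mean(v) - prior$mean["d13C"]), 0.1)
  expect_lt(abs(sd(v) - prior$sd["d13C"]) / prior$sd["d13C"], 0.1)
  set.seed(1)
  ks <- suppressWarnings(
    ks.test(v, rnorm(5000, prior$mean["d13C"], prior$sd["d13C"])))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("terrestrial fraction estimates respect constraints and monotonicity", {
  fits <- lapply(c(-25, -27, -29), function(bio_mean) {
    set.seed(17)
    obs <- rbind(
      data.frame(sample_id = paste0("l", 1:30), category = "leaf_litter",
                 guild = NA, land_use = "forest",
                 d13C = rnorm(30, -30, 1), d15N = rnorm(30, -2, 1)),
      data.frame(sample_id = paste0("b", 1:30), category = "biofilm",
                 guild = NA, land_use = "forest",
                 d13C = rnorm(30, bio_mean, 1), d15N = rnorm(30, 0, 1)))
    fit_stage1(isotope_dataset(obs),
               cfg = mcmc_config(chains = 2, iterations = 600,
                                 warmup = 600, seed = 33))
  })
  phis <- vapply(fits, function(f) {
    mean(extract_draws(f$draws, "phi_T[forest]", pooled = TRUE))
  }, numeric(1))
  # biofilm mean moving toward the litter mean cannot lower the fraction
  expect_true(all(diff(phis) > 0))
  for (f in fits) {
    v <- extract_draws(f$draws, "phi_T[forest]", pooled = TRUE)
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("the study fixture yields a plausible forest algal endmember", {
  ds <- make_study_fixture(seed = 1)
  f <- fit_stage1(ds, cfg = mcmc_config(chains = 2, iterations = 600,
                                        warmup = 600, seed = 13))
  rows <- algal_summary(f, check_convergence = FALSE)
  forest <- rows[rows$land_use == "forest", ]
  # above the forest litter mean and within two prior sds of the
  # literature algal value
  expect_gt(forest$d13C_mean, -32.3)
  expect_lt(abs(forest$d13C_mean - (-23.72)), 2 * 4.10)
  # the summary feeds stage 2 unchanged through the source-set constructor
  srcs <- build_source_sets(study_summary_table(), rows)
  expect_equal(srcs$forest$mean["algae", "d13C"], forest$d13C_mean)
  expect_equal(srcs$forest$sd["algae", "d13C"], forest$d13C_sd)
})

test_that("algal summaries are exact statistics of the stored draws", {
  m <- matrix(c(-24, -26, -24, -26), ncol = 1)
  colnames(m) <- "delta_A[forest,d13C]"
  m2 <- cbind(m, m + 28) # d15N column
  colnames(m2)[2] <- "delta_A[forest,d15N]"
  fake <- structure(list(
    draws = draws_from_matrix(m2), land_uses = "forest",
    convergence = list(pass = TRUE, max_rhat = 1)),
    class = "stage1_fit")
  s <- algal_summary(fake)
  expect_equal(s$d13C_mean, -25)
  expect_equal(s$d13C_sd, sd(c(-24, -26, -24, -26)))
  expect_equal(s$n, 4L)
})
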