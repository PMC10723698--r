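test_that("consumer expectation evaluates the enriched mixture", {
  s <- matrix(c(-32.3, -23.72, -1, 4), 2, 2,
              dimnames = list(c("leaf_litter", "algae"), c("d13C", "d15N")))
  # pure first source, no enrichment: identity
  e0 <- consumer_expectation(s, c(1, 0), c(d13C = 0, d15N = 0), L = 3)
  expect_equal(unname(e0["d13C"]), -32.3)
  # even mixture, carbon enrichment 0.39 over two levels
  e1 <- consumer_expectation(s, c(0.5, 0.5), c(d13C = 0.39, d15N = 0), L = 2)
  expect_equal(unname(e1["d13C"]), -27.23)
  # identical sources: expectation is x + tef * L whatever phi is
  s_eq <- matrix(c(-27, -27, 2, 2), 2, 2,
                 dimnames = list(c("a", "b"), c("d13C", "d15N")))
  for (p in c(0, 0.3, 1)) {
    e <- consumer_expectation(s_eq, c(p, 1 - p), c(d13C = 1, d15N = 3.4), 2)
    expect_equal(unname(e["d13C"]), -25)
    expect_equal(unname(e["d15N"]), 8.8)
  }
  expect_error(consumer_expectation(s, c(0.5, 0.3, 0.2), c(0, 0), 1),
               "match")
  expect_error(consumer_expectation(s, c(0.7, 0.7), c(0, 0), 1), "simplex")
})

test_that("the cell joint density enforces its support", {
  src <- separated_sources()
  cell <- data.frame(d13C = -28, d15N = 3)
  ok <- stage2_params(phi = c(0.6, 0.4), L = 2,
                      tef = c(d13C = 0.39, d15N = 3.4),
                      delta_src = src$mean,
                      sigma_c = c(d13C = 1, d15N = 1))
  expect_true(is.finite(stage2_log_posterior(ok, cell, src)))
  high_L <- ok
  high_L$L <- 11
  expect_identical(stage2_log_posterior(high_L, cell, src), -Inf)
  off_simplex <- ok
  off_simplex$phi <- c(0.5, 0.6)
  expect_identical(stage2_log_posterior(off_simplex, cell, src), -Inf)
  neg_sig <- ok
  neg_sig$sigma_c <- c(d13C = -1, d15N = 1)
  expect_identical(stage2_log_posterior(neg_sig, cell, src), -Inf)
  expect_error(stage2_log_posterior(ok, cell[0, ], src), "empty")
})

test_that("an observation at its expectation contributes the normal peak density", {
  src <- separated_sources()
  params <- stage2_params(phi = c(0.6, 0.4), L = 2,
                          tef = c(d13C = 0.39, d15N = 3.4),
                          delta_src = src$mean,
                          sigma_c = c(d13C = 1, d15N = 1))
  mu <- consumer_expectation(src$mean, params$phi, params$tef, params$L)
  at_mean <- data.frame(d13C = mu[["d13C"]], d15N = NA)
  shifted <- data.frame(d13C = mu[["d13C"]] + 1, d15N = NA)
  lp_peak <- stage2_log_posterior(params, at_mean, src)
  lp_shift <- stage2_log_posterior(params, shifted, src)
  # unit-sd normal: peak density exceeds the 1-sd point by exactly 1/2
  expect_equal(lp_peak - lp_shift, 0.5, tolerance = 1e-12)
  # and equals -log(sqrt(2 pi)) on top of the prior terms
  prior_terms <- lgamma(2) - log(10) +
    sum(dnorm(params$tef, tef_prior()$mean, tef_prior()$sd, log = TRUE)) +
    sum(dnorm(params$delta_src, src$mean, src$sd, log = TRUE)) +
    sum(log(2) + dnorm(params$sigma_c, 0, 3, log = TRUE))
  expect_equal(lp_peak - prior_terms, -0.5 * log(2 * pi), tolerance = 1e-12)
})

test_that("sampler matches 1-D grid integration on the reduced mixing model", {
  # two sources, one tracer, fixed signatures and residual sd: the only
  # parameter is the litter proportion
  set.seed(42)
  d_lit <- -32
  d_alg <- -22
  sig <- 1
  y <- rnorm(20, 0.7 * d_lit + 0.3 * d_alg, sig)
  grid <- seq(1 / 8000, 1 - 1 / 8000, length.out = 4000)
  ll <- vapply(grid, function(p) {
    sum(dnorm(y, p * d_lit + (1 - p) * d_alg, sig, log = TRUE))
  }, numeric(1))
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  oracle <- sum(w * grid)

  tf <- allomix:::make_transform(
    list(allomix:::param_spec("phi", "simplex", k = 2)))
  lp <- function(yv) {
    r <- tf$constrain(yv)
    p <- r$x[1]
    sum(dnorm(y, p * d_lit + (1 - p) * d_alg, sig, log = TRUE)) + r$log_jac
  }
  dr <- sample_posterior(lp, c(phi = 0),
                         mcmc_config(chains = 4, iterations = 4000,
                                     warmup = 1000, seed = 7))
  p_draws <- plogis(extract_draws(dr, "phi", pooled = TRUE))
  expect_lt(abs(mean(p_draws) - oracle), 0.02)
})

test_that("known source proportions are recovered from simulated cells", {
  src <- separated_sources()
  tru <- stage2_truth(phi = c(leaf_litter = 0.8, algae = 0.2), L = 2,
                      tef = c(0.39, 3.4), source_mean = src$mean,
                      source_sd = src$sd, sigma_c = c(0.5, 0.5))
  ds <- simulate_stage2(tru, 50, seed = 2)
  fit <- fit_stage2(ds, src, cfg = mcmc_config(chains = 4,
                                               iterations = 1000,
                                               warmup = 1000, seed = 3))
  cell <- fit$cells[[1]]
  expect_true(cell$convergence$pass)
  phi_mean <- mean(extract_draws(cell$draws, "phi[leaf_litter]",
                                 pooled = TRUE))
  expect_lt(abs(phi_mean - 0.8), 0.15)
})

test_that("posterior mean contributions are monotone in the truth", {
  src <- separated_sources()
  means <- vapply(c(0.1, 0.5, 0.9), function(p) {
    tru <- stage2_truth(phi = c(leaf_litter = p, algae = 1 - p), L = 2,
                        tef = c(0.39, 3.4), source_mean = src$mean,
                        source_sd = src$sd, sigma_c = c(0.5, 0.5))
    ds <- simulate_stage2(tru, 50, seed = 40 + round(100 * p))
    fit <- fit_stage2(ds, src, cfg = quick_cfg(chains = 2, seed = 4))
    mean(extract_draws(fit$cells[[1]]$draws, "phi[leaf_litter]",
                       pooled = TRUE))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("indistinguishable sources return the Dirichlet(1,1) prior", {
  src <- source_set(c("leaf_litter", "algae"),
                    mean = cbind(c(-27, -27), c(2, 2)),
                    sd = matrix(0.05, 2, 2))
  set.seed(9)
  obs <- data.frame(sample_id = paste0("c", 1:20),
                    category = "consumer:Tadpole", guild = "herbivore",
                    land_use = "forest",
                    d13C = rnorm(20, -25, 1.5), d15N = rnorm(20, 7, 1.5))
  fit <- fit_stage2(isotope_dataset(obs), src,
                    cfg = mcmc_config(chains = 4, iterations = 2000,
                                      warmup = 1000, seed = 10))
  v <- extract_draws(fit$cells[[1]]$draws, "phi[leaf_litter]", pooled = TRUE)
  expect_lt(abs(mean(v) - 0.5), 0.05)
  ci <- credible_interval(v)
  expect_lt(abs(ci[1] - 0.025), 0.03)
  expect_lt(abs(ci[2] - 0.975), 0.03)
})

test_that("every stored proportion draw lies on the simplex", {
  src <- separated_sources()
  tru <- stage2_truth(phi = c(leaf_litter = 0.6, algae = 0.4), L = 2,
                      tef = c(0.39, 3.4), source_mean = src$mean,
                      source_sd = src$sd, sigma_c = c(1, 1))
  ds <- simulate_stage2(tru, 15, seed = 5)
  fit <- fit_stage2(ds, src, cfg = quick_cfg(seed = 6))
  p1 <- extract_draws(fit$cells[[1]]$draws, "phi[leaf_litter]", pooled = TRUE)
  p2 <- extract_draws(fit$cells[[1]]$draws, "phi[algae]", pooled = TRUE)
  expect_true(all(p1 >= 0 & p2 >= 0))
  expect_true(all(abs(p1 + p2 - 1) < 1e-9))
})

test_that("permuting source order permutes the proportions", {
  fwd <- separated_sources()
  rev <- source_set(c("algae", "leaf_litter"),
                    mean = fwd$mean[2:1, ], sd = fwd$sd[2:1, ])
  tru <- stage2_truth(phi = c(leaf_litter = 0.7, algae = 0.3), L = 2,
                      tef = c(0.39, 3.4), source_mean = fwd$mean,
                      source_sd = fwd$sd, sigma_c = c(0.8, 0.8))
  ds <- simulate_stage2(tru, 30, seed = 12)
  cfg <- mcmc_config(chains = 4, iterations = 1500, warmup = 1000, seed = 13)
  f_fwd <- fit_stage2(ds, fwd, cfg = cfg)
  f_rev <- fit_stage2(ds, rev, cfg = cfg)
  m_fwd <- allochthony_grand_mean(f_fwd, "leaf_litter")
  m_rev <- allochthony_grand_mean(f_rev, "leaf_litter")
  expect_lt(abs(m_fwd - m_rev), 0.03)
  expect_equal(m_rev,
               1 - allochthony_grand_mean(f_rev, "algae"),
               tolerance = 1e-9)
})

test_that("grand-mean contributions average cells and validate labels", {
  expect_equal(allochthony_grand_mean(c(0.5)), 0.5)
  expect_equal(allochthony_grand_mean(c(0.2, 0.4, 0.9)), 0.5)
  expect_error(allochthony_grand_mean(numeric(0)), ">= 1 cell")
  src <- separated_sources()
  tru <- stage2_truth(phi = c(leaf_litter = 0.6, algae = 0.4), L = 2,
                      tef = c(0.39, 3.4), source_mean = src$mean,
                      source_sd = src$sd, sigma_c = c(1, 1))
  ds <- simulate_stage2(tru, 10, seed = 5)
  fit <- fit_stage2(ds, src, cfg = quick_cfg(seed = 6))
  expect_error(allochthony_grand_mean(fit, "plankton"), "unknown source")
})

test_that("a three-source set samples a uniform Dirichlet correctly", {
  # prior-only target through the stick-breaking transform: the implied
  # marginal means of a Dirichlet(1,1,1) are 1/3 each
  tf <- allomix:::make_transform(
    list(allomix:::param_spec("phi", "simplex", k = 3)))
  lp <- function(y) {
    r <- tf$constrain(y)
    lgamma(3) + r$log_jac
  }
  dr <- sample_posterior(lp, c(stick1 = 0, stick2 = 0),
                         mcmc_config(chains = 4, iterations = 4000,
                                     warmup = 1000, seed = 19))
  d <- dim(dr)
  flat <- matrix(as.vector(unclass(dr)), nrow = d[1] * d[2])
  phis <- t(apply(flat, 1, function(y) tf$constrain(y)$x))
  expect_equal(colMeans(phis), rep(1 / 3, 3), tolerance = 0.02)
  expect_true(all(abs(rowSums(phis) - 1) < 1e-9))
  # and a full three-source cell fit stays on the simplex
  src3 <- source_set(c("leaf_litter", "algae", "biofilm"),
                     mean = cbind(c(-32, -20, -26), c(-1, 4, 1)),
                     sd = matrix(1, 3, 2))
  set.seed(20)
  obs <- data.frame(sample_id = paste0("c", 1:15),
                    category = "consumer:Decapoda", guild = "detritivore",
                    land_use = "forest", d13C = rnorm(15, -27, 1),
                    d15N = rnorm(15, 4, 1))
  f3 <- fit_stage2(isotope_dataset(obs), src3, cfg = quick_cfg(seed = 21))
  p <- sapply(c("phi[leaf_litter]", "phi[algae]", "phi[biofilm]"),
              function(lab) {
                extract_draws(f3$cells[[1]]$draws, lab, pooled = TRUE)
              })
  expect_true(all(p >= 0))
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
})

test_that("cells with no usable observations are skipped with a warning", {
  good <- data.frame(sample_id = paste0("g", 1:5),
                     category = "consumer:Tadpole", guild = "herbivore",
                     land_use = "forest", d13C = rnorm(5, -27),
                     d15N = rnorm(5, 4))
  empty <- data.frame(sample_id = "e1", category = "consumer:Perlidae",
                      guild = "carnivore", land_use = "forest",
                      d13C = NA_real_, d15N = NA_real_)
  ds <- isotope_dataset(rbind(good, empty))
  expect_warning(fit <- fit_stage2(ds, separated_sources(),
                                   cfg = quick_cfg(seed = 2)),
                 "skipped")
  expect_equal(fit$skipped, "Perlidae/forest")
  expect_equal(names(fit$cells), "Tadpole/forest")
})
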