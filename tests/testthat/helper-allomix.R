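# Shared fixtures for the test suite. Everything is generated in code;
# quick_cfg keeps MCMC runs small where only correctness of plumbing (not
# Monte-Carlo precision) is at stake.

quick_cfg <- function(chains = 2L, iterations = 400L, warmup = 400L,
                      seed = 1L) {
  mcmc_config(chains = chains, iterations = iterations, warmup = warmup,
              seed = seed)
}

# two well-separated carbon sources, the workhorse stage-2 setting
separated_sources <- function(sd = 0.5) {
  source_set(c("leaf_litter", "algae"),
             mean = cbind(c(-32, -20), c(-1, 4)),
             sd = matrix(sd, 2, 2))
}

write_obs_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("sample_id,category,guild,land_use,d13C,d15N", lines), path)
  path
}

# build a posterior_draws array from a matrix of pooled draws (one chain)
draws_from_matrix <- function(m, chains = 2L) {
  n <- nrow(m) %/% chains
  arr <- array(NA_real_, dim = c(n, chains, ncol(m)),
               dimnames = list(NULL, NULL, colnames(m)))
  for (ch in seq_len(chains)) {
    arr[, ch, ] <- as.matrix(m[(ch - 1L) * n + seq_len(n), , drop = FALSE])
  }
  posterior_draws(arr)
}

# minimal hand-built stage2_fit with known constant-free draws for one cell
fake_stage2_fit <- function(draw_matrix, taxon = "Tipulidae",
                            guild = "detritivore", land_use = "forest",
                            sources = c("leaf_litter", "algae"),
                            converged = TRUE) {
  draws <- draws_from_matrix(draw_matrix)
  cell <- list(taxon = taxon, guild = guild, land_use = land_use,
               n_obs = 5L, sources = sources, draws = draws,
               convergence = list(pass = converged,
                                  max_rhat = if (converged) 1.0 else 1.5,
                                  parameters = NULL, failed = character(0)))
  structure(list(cells = stats::setNames(list(cell),
                                         paste0(taxon, "/", land_use)),
                 cfg = mcmc_config(seed = 1), tef = tef_prior(),
                 skipped = character(0)),
            class = "stage2_fit")
}
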