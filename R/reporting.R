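# Posterior summarisation and study-style outputs: per-cell contribution
# tables, fractionation-corrected biplot coordinates, and the
# algae-vs-litter overlap diagnostic.

#' Posterior mode via kernel density estimation
#'
#' Location of the maximum of a Gaussian KDE (Silverman's rule-of-thumb
#' bandwidth, 512-point grid spanning the draw range; for proportions the
#' grid is clipped to `[0, 1]`).
#'
#' @param draws Numeric vector of posterior draws (`>= 10`).
#' @param proportion Clip the evaluation grid to `[0, 1]`.
#' @return Scalar mode estimate.
#' @export
posterior_mode <- function(draws, proportion = FALSE) {
  draws <- draws[!is.na(draws)]
  if (length(draws) < 10) stop("need >= 10 draws", call. = FALSE)
  rng <- range(draws)
  if (rng[1] == rng[2]) return(rng[1])
  from <- rng[1]
  to <- rng[2]
  if (proportion) {
    from <- max(0, from)
    to <- min(1, to)
  }
  dens <- stats::density(draws, bw = "nrd0", n = 512, from = from, to = to)
  dens$x[which.max(dens$y)]
}

#' Equal-tailed credible interval
#'
#' Empirical quantiles with linear interpolation (the default quantile
#' definition, type 7).
#'
#' @param draws Numeric vector of posterior draws (`>= 2`).
#' @param lo,hi Tail probabilities, `lo < hi`; defaults give the
#'   2.5–97.5% interval.
#' @return Numeric vector `c(lo, hi)` of interval bounds.
#' @export
credible_interval <- function(draws, lo = 0.025, hi = 0.975) {
  if (lo >= hi) stop("lo must be < hi", call. = FALSE)
  draws <- draws[!is.na(draws)]
  if (length(draws) < 2) stop("need >= 2 draws", call. = FALSE)
  unname(stats::quantile(draws, probs = c(lo, hi), type = 7))
}

#' Study-style contribution table from a stage-2 fit
#'
#' One row per consumer taxon x land use: per-source mode, mean and
#' 2.5–97.5% credible interval of the contribution, the posterior mean
#' trophic level, and the posterior mean trophic enrichment factor per
#' tracer. Rows are grouped by land use, then guild (detritivore,
#' herbivore, omnivore, carnivore), preserving within-group fit order.
#' Values are reported unrounded; round proportions to 3 and delta values
#' to 1 decimal for display.
#'
#' @param fit A `stage2_fit` (see [fit_stage2()]).
#' @return Data frame with one row per cell and a `converged` flag
#'   (non-converged cells are emitted, flagged `FALSE`).
#' @export
build_cell_table <- function(fit) {
  stopifnot(inherits(fit, "stage2_fit"))
  rows <- lapply(fit$cells, function(cell) {
    out <- data.frame(taxon = cell$taxon, guild = cell$guild,
                      land_use = cell$land_use)
    for (s in cell$sources) {
      v <- extract_draws(cell$draws, paste0("phi[", s, "]"), pooled = TRUE)
      ci <- credible_interval(v)
      out[[paste0(s, "_mode")]] <- posterior_mode(v, proportion = TRUE)
      out[[paste0(s, "_mean")]] <- mean(v)
      out[[paste0(s, "_lo")]] <- ci[1]
      out[[paste0(s, "_hi")]] <- ci[2]
    }
    out$trophic_level_mean <-
      mean(extract_draws(cell$draws, "L", pooled = TRUE))
    for (t in tracer_levels()) {
      out[[paste0("tef_", t, "_mean")]] <-
        mean(extract_draws(cell$draws, paste0("tef[", t, "]"), pooled = TRUE))
    }
    out$converged <- cell$convergence$pass
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Fractionation-corrected biplot coordinates
#'
#' Consumer cell means are shifted back down the food chain by the
#' posterior mean trophic enrichment: corrected
#' `delta = mean(delta) - tef_mean * L_mean` per tracer. Resources pass
#' through unchanged. Cells without a posterior are emitted uncorrected
#' and flagged.
#'
#' @param data The [isotope_dataset()] the fit was run on.
#' @param fit A `stage2_fit`.
#' @return Data frame of plotting coordinates: one row per resource
#'   category x land use and per consumer cell, with per-tracer mean, sd
#'   and a `corrected` flag.
#' @export
fractionation_corrected_biplot <- function(data, fit) {
  stopifnot(inherits(data, "isotope_dataset"), inherits(fit, "stage2_fit"))
  obs <- data$observations
  tr <- tracer_levels()

  summarise <- function(sub) {
    c(d13C = mean(sub$d13C, na.rm = TRUE),
      d13C_sd = stats::sd(sub$d13C[!is.na(sub$d13C)]),
      d15N = mean(sub$d15N, na.rm = TRUE),
      d15N_sd = stats::sd(sub$d15N[!is.na(sub$d15N)]))
  }

  rows <- list()
  for (cat in c("biofilm", "leaf_litter")) {
    for (lu in intersect(land_use_levels(), unique(obs$land_use))) {
      sub <- obs[obs$category == cat & obs$land_use == lu, , drop = FALSE]
      if (nrow(sub) == 0) next
      s <- summarise(sub)
      rows[[paste(cat, lu)]] <- data.frame(
        category = cat, taxon = NA_character_, guild = NA_character_,
        land_use = lu, d13C = s[["d13C"]], d13C_sd = s[["d13C_sd"]],
        d15N = s[["d15N"]], d15N_sd = s[["d15N_sd"]], corrected = FALSE)
    }
  }

  consumers <- obs[startsWith(obs$category, "consumer:"), , drop = FALSE]
  consumers$taxon <- sub("^consumer:", "", consumers$category)
  cells_idx <- unique(consumers[, c("taxon", "land_use")])
  for (i in seq_len(nrow(cells_idx))) {
    taxon <- cells_idx$taxon[i]
    lu <- cells_idx$land_use[i]
    sub <- consumers[consumers$taxon == taxon & consumers$land_use == lu, ]
    s <- summarise(sub)
    key <- paste0(taxon, "/", lu)
    cell <- fit$cells[[key]]
    shift <- c(d13C = 0, d15N = 0)
    corrected <- FALSE
    if (!is.null(cell)) {
      L_mean <- mean(extract_draws(cell$draws, "L", pooled = TRUE))
      for (t in tr) {
        tef_mean <- mean(extract_draws(cell$draws, paste0("tef[", t, "]"),
                                       pooled = TRUE))
        shift[t] <- tef_mean * L_mean
      }
      corrected <- TRUE
    } else {
      warning("no posterior for cell ", key, "; emitted uncorrected",
              call. = FALSE)
    }
    rows[[key]] <- data.frame(
      category = "consumer", taxon = taxon, guild = sub$guild[1],
      land_use = lu,
      d13C = s[["d13C"]] - shift[["d13C"]], d13C_sd = s[["d13C_sd"]],
      d15N = s[["d15N"]] - shift[["d15N"]], d15N_sd = s[["d15N_sd"]],
      corrected = corrected)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Overlap between an estimated and a measured resource distribution
#'
#' Overlap coefficient `integral of min(f_a, g_b)` between a Gaussian KDE
#' of posterior draws (e.g. the algal endmember) and a normal density
#' (e.g. measured leaf litter), computed by the trapezoid rule on a shared
#' grid. 1 means identical distributions, 0 disjoint ones.
#'
#' @param a_draws Numeric vector of posterior draws (non-degenerate).
#' @param b_mean,b_sd Moments of the normal comparison density
#'   (`b_sd > 0`).
#' @param n_grid Number of grid points.
#' @return Overlap coefficient in `[0, 1]`.
#' @export
resource_overlap <- function(a_draws, b_mean, b_sd, n_grid = 2048) {
  if (b_sd <= 0) stop("b_sd must be > 0", call. = FALSE)
  a_draws <- a_draws[!is.na(a_draws)]
  if (length(a_draws) < 10 || stats::sd(a_draws) == 0) {
    stop("a_draws must be a non-degenerate sample", call. = FALSE)
  }
  bw <- stats::bw.nrd0(a_draws)
  lo <- min(min(a_draws) - 4 * bw, b_mean - 6 * b_sd)
  hi <- max(max(a_draws) + 4 * bw, b_mean + 6 * b_sd)
  dens <- stats::density(a_draws, bw = bw, n = n_grid, from = lo, to = hi)
  g <- stats::dnorm(dens$x, b_mean, b_sd)
  h <- dens$x[2] - dens$x[1]
  overlap <- sum(pmin(dens$y, g)) * h -
    0.5 * h * (pmin(dens$y[1], g[1]) + pmin(dens$y[n_grid], g[n_grid]))
  min(max(overlap, 0), 1)
}
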