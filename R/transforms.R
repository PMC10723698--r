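# Bijections between constrained model parameters and the unconstrained
# space the sampler walks in. Each spec is a scalar block except "simplex",
# which maps K constrained weights to K-1 stick-breaking logits. Densities
# stated on the constrained scale pick up the log-Jacobian of the inverse
# map so that sampling in y targets the intended posterior.

param_spec <- function(name, type = c("real", "positive", "unit",
                                      "interval", "simplex"),
                       lower = NA_real_, upper = NA_real_, k = NA_integer_) {
  type <- match.arg(type)
  if (type == "interval" && (!is.finite(lower) || !is.finite(upper) ||
                             lower >= upper)) {
    stop("interval spec needs finite lower < upper", call. = FALSE)
  }
  if (type == "simplex" && (is.na(k) || k < 2)) {
    stop("simplex spec needs k >= 2", call. = FALSE)
  }
  list(name = name, type = type, lower = lower, upper = upper,
       k = as.integer(k))
}

spec_n_unconstrained <- function(spec) {
  if (spec$type == "simplex") spec$k - 1L else 1L
}

spec_par_names <- function(spec) {
  if (spec$type == "simplex") paste0(spec$name, "[", seq_len(spec$k), "]")
  else spec$name
}

# Stick-breaking: phi_1 = z_1, phi_k = z_k * prod_{j<k}(1 - z_j),
# phi_K = prod(1 - z_j). Log-Jacobian of phi_{1:K-1} wrt y includes the
# logistic terms and the stick remainders.
.simplex_constrain <- function(y) {
  k <- length(y) + 1L
  z <- stats::plogis(y)
  phi <- numeric(k)
  stick <- 1
  lj <- 0
  for (j in seq_len(k - 1L)) {
    phi[j] <- z[j] * stick
    lj <- lj + log(z[j]) + log1p(-z[j])
    stick <- stick * (1 - z[j])
  }
  phi[k] <- stick
  # det(d phi / d z) = prod_{j=1}^{K-2} (1 - z_j)^(K-1-j)
  if (k > 2L) {
    j <- seq_len(k - 2L)
    lj <- lj + sum((k - 1L - j) * log1p(-z[j]))
  }
  list(x = phi, log_jac = lj)
}

.simplex_unconstrain <- function(phi) {
  k <- length(phi)
  z <- numeric(k - 1L)
  rem <- 1
  for (j in seq_len(k - 1L)) {
    z[j] <- phi[j] / rem
    rem <- rem - phi[j]
  }
  stats::qlogis(pmin(pmax(z, 1e-12), 1 - 1e-12))
}

spec_constrain <- function(spec, y) {
  switch(spec$type,
    real = list(x = y, log_jac = 0),
    positive = list(x = exp(y), log_jac = y),
    unit = {
      z <- stats::plogis(y)
      list(x = z, log_jac = log(z) + log1p(-z))
    },
    interval = {
      z <- stats::plogis(y)
      list(x = spec$lower + (spec$upper - spec$lower) * z,
           log_jac = log(spec$upper - spec$lower) + log(z) + log1p(-z))
    },
    simplex = .simplex_constrain(y)
  )
}

spec_unconstrain <- function(spec, x) {
  switch(spec$type,
    real = x,
    positive = log(x),
    unit = stats::qlogis(pmin(pmax(x, 1e-12), 1 - 1e-12)),
    interval = {
      z <- (x - spec$lower) / (spec$upper - spec$lower)
      stats::qlogis(pmin(pmax(z, 1e-12), 1 - 1e-12))
    },
    simplex = .simplex_unconstrain(x)
  )
}

# Unique labels for the unconstrained coordinates of a spec list (a
# simplex of K weights has K-1 stick coordinates).
unconstrained_names <- function(specs) {
  unlist(lapply(specs, function(s) {
    n <- spec_n_unconstrained(s)
    if (n == 1L) s$name else paste0(s$name, "_stick", seq_len(n))
  }), use.names = FALSE)
}

# Bundle a list of specs into vectorised constrain/unconstrain maps.
make_transform <- function(specs) {
  n_y <- vapply(specs, spec_n_unconstrained, integer(1))
  y_end <- cumsum(n_y)
  y_start <- y_end - n_y + 1L
  par_names <- unlist(lapply(specs, spec_par_names), use.names = FALSE)
  x_len <- vapply(specs, function(s) {
    if (s$type == "simplex") s$k else 1L
  }, integer(1))
  x_end <- cumsum(x_len)
  x_start <- x_end - x_len + 1L

  constrain <- function(y) {
    x <- numeric(sum(x_len))
    lj <- 0
    for (i in seq_along(specs)) {
      res <- spec_constrain(specs[[i]], y[y_start[i]:y_end[i]])
      x[x_start[i]:x_end[i]] <- res$x
      lj <- lj + res$log_jac
    }
    list(x = x, log_jac = lj)
  }
  unconstrain <- function(x) {
    y <- numeric(sum(n_y))
    for (i in seq_along(specs)) {
      y[y_start[i]:y_end[i]] <- spec_unconstrain(specs[[i]],
                                                 x[x_start[i]:x_end[i]])
    }
    y
  }
  list(specs = specs, n_unconstrained = sum(n_y), par_names = par_names,
       constrain = constrain, unconstrain = unconstrain,
       x_index = stats::setNames(
         lapply(seq_along(specs), function(i) x_start[i]:x_end[i]),
         vapply(specs, `[[`, "", "name")))
}
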