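# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no stored data.

# Build an egg-level data frame from cell counts on the grid. Cell k holds
# eggs dead in (t_{k-1}, t_k]; the last cell (n_checkpoints + 1) holds
# right-censored eggs.
eggs_from_cells <- function(counts, grid, mass_id = "X", treatment = "TRT",
                            season = NA_character_) {
  cp <- grid$checkpoints
  n_cp <- length(cp)
  stopifnot(length(counts) == n_cp + 1)
  cell <- rep(seq_along(counts), counts)
  n <- length(cell)
  cens <- cell == n_cp + 1
  k <- pmin(cell, n_cp)
  left <- c(0, cp)[k]
  right <- cp[k]
  left[cens] <- cp[n_cp]
  right[cens] <- NA_real_
  data.frame(mass_id = mass_id, treatment = treatment, season = season,
             egg_id = seq_len(n), genotype = NA_character_,
             interval_left_min = left, interval_right_min = right,
             censored = as.integer(cens), stringsAsFactors = FALSE)
}

# Exhaustive grid search over (mu, sigma) of the interval-censored probit
# likelihood: the brute-force oracle against which the MLE is checked.
probit_grid_oracle <- function(counts, grid, mu_range = c(2.5, 4.5),
                               sigma_range = c(0.02, 1.0), res = 1e-3) {
  b <- log10(grid$checkpoints)
  mus <- seq(mu_range[1], mu_range[2], by = res)
  sigmas <- seq(sigma_range[1], sigma_range[2], by = res)
  occ <- which(counts > 0)
  cnt <- counts[occ]
  best_ll <- -Inf
  best <- c(NA, NA)
  for (s in sigmas) {
    Z <- pnorm(outer(mus, b, function(m, bb) (bb - m) / s))
    P <- cbind(Z[, 1], Z[, -1, drop = FALSE] - Z[, -ncol(Z), drop = FALSE],
               1 - Z[, ncol(Z)])
    ll <- as.vector(log(pmax(P[, occ, drop = FALSE], 1e-300)) %*% cnt)
    i <- which.max(ll)
    if (ll[i] > best_ll) {
      best_ll <- ll[i]
      best <- c(mus[i], s)
    }
  }
  c(mu = best[1], sigma = best[2], loglik = best_ll)
}

# Standard normal quantile by root finding on pnorm: independent of qnorm.
norm_quantile_oracle <- function(p) {
  vapply(p, function(pp)
    uniroot(function(z) pnorm(z) - pp, c(-10, 10), tol = 1e-12)$root,
    numeric(1))
}

# Spearman's rho by the textbook rank formula (no ties).
rank_rho_oracle <- function(x, y) {
  stopifnot(!anyDuplicated(x), !anyDuplicated(y))
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Mann-Whitney U for the first sample by exhaustive pair counting.
u_count_oracle <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# Mendelian offspring distribution by explicit gamete enumeration.
mendel_enum_oracle <- function(p1, p2) {
  gametes <- function(g) strsplit(g, "")[[1]]
  out <- c(SS = 0, ST = 0, TT = 0)
  for (a in gametes(p1)) for (b in gametes(p2)) {
    g <- paste(sort(c(a, b)), collapse = "")
    out[g] <- out[g] + 0.25
  }
  out
}

# A fabricated converged probit fit, for closed-form quantile checks.
fake_probit_fit <- function(mu, sigma, grid) {
  structure(list(mu = mu, sigma = sigma, loglik = 0, converged = TRUE,
                 degenerate = FALSE, bound = NA_character_,
                 bound_minutes = NA_real_, counts = NULL, n_eggs = 0,
                 grid = grid, sigma_floor = 1e-4),
            class = "probit_fit")
}
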