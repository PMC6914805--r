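# Interval-censored probit (log10-time) estimation of lethal times.
#
# The model: latent log10 death times are Normal(mu, sigma); an egg recorded
# dead in (l, r] contributes Phi((log10 r - mu)/sigma) - Phi((log10 l - mu)/sigma)
# (with l = 0 treated as -Inf on the log scale), and a right-censored egg
# contributes 1 - Phi((log10 t_last - mu)/sigma).

# Map egg records of one mass onto grid cells 1..(n_checkpoints + 1); the
# last cell holds right-censored eggs. Validates endpoints against the grid.
interval_cell_counts <- function(eggs, grid) {
  grid <- as_observation_grid(grid)
  cp <- grid$checkpoints
  n_cp <- length(cp)
  need <- c("interval_left_min", "interval_right_min", "censored")
  miss <- setdiff(need, names(eggs))
  if (length(miss))
    stop("egg table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(eggs) == 0) stop("no egg records")
  cens <- eggs$censored == 1
  cell <- integer(nrow(eggs))
  cell[cens] <- n_cp + 1L
  if (any(!cens)) {
    k <- match(eggs$interval_right_min[!cens], cp)
    if (anyNA(k))
      stop("uncensored interval endpoints are not on the observation grid")
    lexp <- c(0, cp)[k]
    if (any(eggs$interval_left_min[!cens] != lexp))
      stop("interval left endpoints do not match the grid cells")
    cell[!cens] <- k
  }
  tabulate(cell, nbins = n_cp + 1L)
}

# Log likelihood for cell counts; b = log10 checkpoint boundaries.
probit_counts_loglik <- function(mu, sigma, counts, b) {
  p <- diff(c(0, pnorm((b - mu) / sigma), 1))
  occ <- counts > 0
  sum(counts[occ] * log(pmax(p[occ], 1e-300)))
}

#' Fit the interval-censored probit model to one egg mass
#'
#' Maximum likelihood estimation of the location `mu` and scale `sigma` of
#' latent log10 death times from interval-censored deaths on the checkpoint
#' grid. The optimiser is a Nelder-Mead search on (mu, log sigma) from
#' moment starting values (interval pseudo-midpoints), polished with BFGS;
#' `sigma` is floored at `sigma_floor` to keep the likelihood finite.
#'
#' Masses in which every egg falls in one boundary class carry no interior
#' information: all dead before the first checkpoint gives only an upper
#' bound on the lethal times, and no deaths at all only a lower bound. Such
#' fits are returned with `degenerate = TRUE` and the bound recorded rather
#' than failing, so extreme masses stay in the cohort. A mass whose deaths
#' all fall in a single interior interval is fitted exactly at that
#' interval's log-midpoint with `sigma` at the floor.
#'
#' @param eggs data frame of one mass's egg records (see
#'   [simulate_egg_mass()] for the columns).
#' @param grid an [make_observation_grid()] object.
#' @param sigma_floor lower bound for the scale, log10 minutes.
#' @return An object of class `probit_fit`: list with `mu`, `sigma`,
#'   `loglik`, `converged`, `degenerate`, `bound` (`NA`, `"upper"` or
#'   `"lower"`), `bound_minutes`, `counts`, `n_eggs`, `grid`.
#' @examples
#' set.seed(7)
#' eggs <- simulate_egg_mass("TT", "TT", 50, "dominant",
#'                           tolerance_model(mu_T = 3.3), make_observation_grid())
#' fit_interval_probit(eggs, make_observation_grid())
#' @export
fit_interval_probit <- function(eggs, grid, sigma_floor = 1e-4) {
  grid <- as_observation_grid(grid)
  counts <- interval_cell_counts(eggs, grid)
  fit_interval_probit_counts(counts, grid, sigma_floor)
}

# Core fitter on cell counts (shared with the mixture machinery and tests).
fit_interval_probit_counts <- function(counts, grid, sigma_floor = 1e-4) {
  grid <- as_observation_grid(grid)
  cp <- grid$checkpoints
  n_cp <- length(cp)
  b <- grid_log10(grid)
  n <- sum(counts)
  if (n == 0) stop("no egg records")
  occupied <- which(counts > 0)

  base <- list(counts = counts, n_eggs = n, grid = grid,
               sigma_floor = sigma_floor)
  if (length(occupied) == 1L) {
    k <- occupied
    if (k == 1L) {
      # every egg dead before the first checkpoint: upper bound only
      return(structure(c(base, list(
        mu = NA_real_, sigma = NA_real_, loglik = 0, converged = FALSE,
        degenerate = TRUE, bound = "upper", bound_minutes = cp[1])),
        class = "probit_fit"))
    }
    if (k == n_cp + 1L) {
      # no deaths observed: lower bound only
      return(structure(c(base, list(
        mu = NA_real_, sigma = NA_real_, loglik = 0, converged = FALSE,
        degenerate = TRUE, bound = "lower", bound_minutes = cp[n_cp])),
        class = "probit_fit"))
    }
    # single interior interval: exact fit at its log-midpoint, zero spread
    return(structure(c(base, list(
      mu = (b[k - 1] + b[k]) / 2, sigma = sigma_floor, loglik = 0,
      converged = TRUE, degenerate = FALSE, bound = NA_character_,
      bound_minutes = NA_real_)), class = "probit_fit"))
  }

  # moment starts from interval pseudo-midpoints
  hb <- mean(diff(b)) / 2
  mids <- c(b[1] - hb, (b[-n_cp] + b[-1]) / 2, b[n_cp] + hb)
  mu0 <- sum(counts * mids) / n
  s0 <- sqrt(sum(counts * (mids - mu0)^2) / n)
  s0 <- max(s0, 0.05)

  nll <- function(th) {
    sig <- max(exp(th[2]), sigma_floor)
    -probit_counts_loglik(th[1], sig, counts, b)
  }
  starts <- list(c(mu0, log(s0)), c(mu0, log(2 * s0)), c(mu0, log(s0 / 2)))
  best <- NULL
  for (st in starts) {
    res <- tryCatch(optim(st, nll, method = "Nelder-Mead",
                          control = list(maxit = 800)),
                    error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop("probit fit failed for all starting values")
  polish <- tryCatch(optim(best$par, nll, method = "BFGS",
                           control = list(maxit = 200)),
                     error = function(e) NULL)
  conv <- best$convergence == 0
  if (!is.null(polish) && polish$value <= best$value) {
    best <- polish
    conv <- polish$convergence == 0
  }

  structure(c(base, list(
    mu = best$par[1], sigma = max(exp(best$par[2]), sigma_floor),
    loglik = -best$value, converged = conv, degenerate = FALSE,
    bound = NA_character_, bound_minutes = NA_real_)),
    class = "probit_fit")
}

#' @export
print.probit_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Interval-censored probit fit: degenerate (", x$bound,
        " bound at ", x$bound_minutes, " min, n = ", x$n_eggs, ")\n", sep = "")
  } else {
    cat(sprintf(
      "Interval-censored probit fit: mu = %.4f, sigma = %.4f (log10 min), n = %d\n",
      x$mu, x$sigma, x$n_eggs))
    cat(sprintf("  loglik = %.3f, LT50 = %.0f min\n", x$loglik, 10^x$mu))
  }
  invisible(x)
}

#' Lethal-time quantile of a fitted probit model
#'
#' The time by which a fraction `p` of eggs is expected to have died:
#' \eqn{10^{\mu + \sigma z_p}} minutes, with \eqn{z_p} the standard normal
#' quantile.
#'
#' @param fit a converged [fit_interval_probit()] object.
#' @param p probability (0 < p < 1); may be a vector.
#' @return Lethal time(s) in minutes.
#' @examples
#' set.seed(7)
#' eggs <- simulate_egg_mass("TT", "TT", 80, "dominant",
#'                           tolerance_model(mu_T = 3.3), make_observation_grid())
#' fit <- fit_interval_probit(eggs, make_observation_grid())
#' lethal_quantile(fit, c(0.25, 0.5, 0.75))
#' @export
lethal_quantile <- function(fit, p) {
  if (!inherits(fit, "probit_fit")) stop("'fit' must be a probit_fit")
  if (fit$degenerate)
    stop("degenerate fit: lethal times are only bounded (", fit$bound,
         " bound at ", fit$bound_minutes, " min); see lethal_times()")
  if (any(p <= 0 | p >= 1)) stop("'p' must lie strictly between 0 and 1")
  10^(fit$mu + fit$sigma * qnorm(p))
}

#' Lethal times LT25, LT50, LT75 of a fitted mass
#'
#' Derives the quartile lethal times from a probit fit and flags estimates
#' falling outside the observation window (see [flag_extrapolated()]). For
#' degenerate fits the three lethal times are reported as the available
#' bound (the first checkpoint when all eggs died before it, the last when
#' none died), with `extrapolated = TRUE` and the bound direction recorded.
#'
#' @param fit a [fit_interval_probit()] object.
#' @return An object of class `lethal_times`: list with `lt25`, `lt50`,
#'   `lt75` (minutes), `extrapolated`, `degenerate`, `bound`.
#' @export
lethal_times <- function(fit) {
  if (!inherits(fit, "probit_fit")) stop("'fit' must be a probit_fit")
  if (fit$degenerate) {
    lt <- rep(fit$bound_minutes, 3)
    out <- list(lt25 = lt[1], lt50 = lt[2], lt75 = lt[3],
                extrapolated = TRUE, degenerate = TRUE, bound = fit$bound)
  } else {
    q <- lethal_quantile(fit, c(0.25, 0.5, 0.75))
    out <- list(lt25 = q[1], lt50 = q[2], lt75 = q[3],
                extrapolated = flag_extrapolated(q[2], fit$grid),
                degenerate = FALSE, bound = NA_character_)
  }
  structure(out, class = "lethal_times")
}

#' @export
print.lethal_times <- function(x, ...) {
  cat(sprintf("LT25 = %.0f, LT50 = %.0f, LT75 = %.0f min%s%s\n",
              x$lt25, x$lt50, x$lt75,
              if (x$extrapolated) " [extrapolated]" else "",
              if (x$degenerate) paste0(" [", x$bound, " bound only]") else ""))
  invisible(x)
}

#' Fit lethal times for every mass of a cohort
#'
#' Splits an egg-level table by `mass_id`, fits the interval-censored probit
#' model per mass and assembles the mass summary table consumed by the
#' classification stage.
#'
#' @param eggs egg-level data frame (one or more masses).
#' @param grid an [make_observation_grid()] object.
#' @param sigma_floor lower bound for the probit scale.
#' @return Data frame with one row per mass: `mass_id`, `treatment`,
#'   `season`, `n_eggs`, `n_censored`, `mu`, `sigma`, `loglik`, `converged`,
#'   `degenerate`, `bound`, `lt25`, `lt50`, `lt75`, `extrapolated`.
#' @examples
#' study <- simulate_study(simulation_config(n_masses = 4, seed = 11))
#' fit_all_masses(study$eggs, study$grid)
#' @export
fit_all_masses <- function(eggs, grid, sigma_floor = 1e-4) {
  grid <- as_observation_grid(grid)
  if (!"mass_id" %in% names(eggs)) stop("egg table lacks a 'mass_id' column")
  ids <- unique(eggs$mass_id)
  rows <- lapply(ids, function(id) {
    m <- eggs[eggs$mass_id == id, , drop = FALSE]
    fit <- fit_interval_probit(m, grid, sigma_floor)
    lt <- lethal_times(fit)
    data.frame(
      mass_id = id,
      treatment = if ("treatment" %in% names(m)) m$treatment[1] else NA,
      season = if ("season" %in% names(m)) m$season[1] else NA,
      n_eggs = nrow(m),
      n_censored = sum(m$censored == 1),
      mu = fit$mu, sigma = fit$sigma, loglik = fit$loglik,
      converged = fit$converged, degenerate = fit$degenerate,
      bound = fit$bound,
      lt25 = lt$lt25, lt50 = lt$lt50, lt75 = lt$lt75,
      extrapolated = lt$extrapolated,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
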