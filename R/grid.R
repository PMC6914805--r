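#' Checkpoint grid of a time-to-death assay
#'
#' Builds the fixed observation schedule on which egg deaths are interval
#' censored. Checkpoints follow a base-10 logarithmic series: checkpoint
#' \eqn{k} (counting from 0) is \eqn{t_0 \cdot 10^{k \cdot step}}, truncated
#' to whole minutes. The default reproduces the seven-point schedule running
#' from 720 to 5719 minutes (12 h to about 95 h) in 0.15 log10 increments:
#' 720, 1017, 1436, 2029, 2866, 4048, 5719.
#'
#' An egg found dead at checkpoint \eqn{t_k} is only known to have died in
#' the interval \eqn{(t_{k-1}, t_k]} (with \eqn{t_0}'s left boundary being
#' the start of exposure); an egg alive at the last checkpoint is right
#' censored.
#'
#' @param t0 first checkpoint, in minutes (> 0).
#' @param step log10 increment between successive checkpoints (> 0).
#' @param n_checkpoints number of checkpoints (>= 1).
#'
#' @return An object of class `observation_grid`: a list with elements
#'   `checkpoints` (whole minutes, strictly increasing), `t0`, `step`,
#'   `n_checkpoints`.
#' @examples
#' make_observation_grid()$checkpoints
#' make_observation_grid(100, 1, 2)$checkpoints  # 100, 1000
#' @export
make_observation_grid <- function(t0 = 720, step = 0.15, n_checkpoints = 7) {
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0) || t0 <= 0)
    stop("'t0' must be a single positive number of minutes")
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) || step <= 0)
    stop("'step' must be a single positive log10 increment")
  if (!is.numeric(n_checkpoints) || length(n_checkpoints) != 1L ||
      n_checkpoints < 1 || n_checkpoints != round(n_checkpoints))
    stop("'n_checkpoints' must be a positive integer")
  k <- seq_len(n_checkpoints) - 1
  # truncate to whole minutes (matches the printed schedule); the small eps
  # guards against representation error for exact products
  cp <- floor(t0 * 10^(step * k) + 1e-9)
  if (any(diff(cp) <= 0))
    stop("checkpoints are not strictly increasing after rounding to whole ",
         "minutes; increase 'step' or 't0'")
  structure(
    list(checkpoints = cp, t0 = t0, step = step,
         n_checkpoints = as.integer(n_checkpoints)),
    class = "observation_grid"
  )
}

#' @export
print.observation_grid <- function(x, ...) {
  cat("Observation grid:", x$n_checkpoints, "checkpoints,",
      "log10 step", x$step, "\n")
  cat("  minutes:", paste(x$checkpoints, collapse = ", "), "\n")
  invisible(x)
}

# log10 checkpoint boundaries (internal)
grid_log10 <- function(grid) log10(grid$checkpoints)

as_observation_grid <- function(grid) {
  if (inherits(grid, "observation_grid")) return(grid)
  if (is.list(grid))
    return(do.call(make_observation_grid, grid))
  stop("'grid' must be an observation_grid or a list of its parameters")
}

#' Flag lethal-time estimates outside the observation window
#'
#' An LT50 below the first checkpoint or above the last one can only be
#' obtained by extrapolating the fitted probit curve beyond the observed
#' death intervals, and is flagged as such.
#'
#' @param lt50 numeric vector of median lethal times, minutes.
#' @param grid an [make_observation_grid()] object.
#' @return logical vector, `TRUE` where the estimate is extrapolated.
#' @examples
#' g <- make_observation_grid()
#' flag_extrapolated(c(500, 2029, 7000), g)  # TRUE FALSE TRUE
#' @export
flag_extrapolated <- function(lt50, grid) {
  grid <- as_observation_grid(grid)
  cp <- grid$checkpoints
  lt50 < cp[1] | lt50 > cp[length(cp)]
}
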