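# Synthetic egg-mass assays: Mendelian genotype draws, log-normal latent
# death times, and censoring onto the checkpoint grid.

#' Simulate one egg mass exposed to a lethal treatment
#'
#' Each egg receives a genotype drawn from the Mendelian offspring
#' distribution of the parental cross, a latent log10 death time drawn from
#' a normal with the genotype's mean (see [genotype_mean_loglt()]) and the
#' model's within-genotype standard deviation, and is then censored onto the
#' observation grid: the egg is recorded dead in the interval
#' \eqn{(t_{k-1}, t_k]} whose right endpoint \eqn{t_k} is the first
#' checkpoint at or after the latent death time, or right censored if it
#' outlives the last checkpoint.
#'
#' Uses the current RNG state; call `set.seed()` beforehand (or use
#' [simulate_study()], which seeds once for a whole cohort).
#'
#' @param parent1,parent2 parental genotypes.
#' @param n_eggs number of eggs exposed (>= 1).
#' @param mode an [inheritance_mode()].
#' @param tolerance a [tolerance_model()].
#' @param grid an [make_observation_grid()] object.
#' @param mass_id,treatment,season labels copied onto every egg record.
#' @return A data frame with one row per egg and columns `mass_id`,
#'   `treatment`, `season`, `egg_id`, `genotype`, `interval_left_min`,
#'   `interval_right_min` (`NA` when censored), `censored` (0/1).
#' @examples
#' set.seed(1)
#' eggs <- simulate_egg_mass("ST", "TT", 20, inheritance_mode("recessive"),
#'                           tolerance_model(), make_observation_grid())
#' table(eggs$censored)
#' @export
simulate_egg_mass <- function(parent1, parent2, n_eggs, mode, tolerance, grid,
                              mass_id = "M1", treatment = "AMD60",
                              season = NA_character_) {
  if (!is.numeric(n_eggs) || length(n_eggs) != 1L || n_eggs < 1 ||
      n_eggs != round(n_eggs))
    stop("'n_eggs' must be a positive integer")
  mode <- as_inheritance_mode(mode)
  tol <- as_tolerance_model(tolerance)
  grid <- as_observation_grid(grid)
  cp <- grid$checkpoints
  n_cp <- length(cp)
  if (n_cp < 1) stop("empty observation grid")

  genotype <- draw_offspring_genotypes(parent1, parent2, n_eggs)
  mu <- genotype_mean_loglt(genotype, mode, tol)
  z <- rnorm(n_eggs, mean = mu, sd = tol$sigma_within)  # latent log10 minutes

  b <- grid_log10(grid)
  # index of the first checkpoint at or after the latent death time;
  # j counts boundaries strictly below z, so cell = j + 1
  j <- findInterval(z, b, left.open = TRUE)
  censored <- j == n_cp
  k <- pmin(j + 1L, n_cp)
  left <- c(0, cp)[k]
  right <- cp[k]
  left[censored] <- cp[n_cp]
  right[censored] <- NA_real_

  data.frame(
    mass_id = mass_id,
    treatment = treatment,
    season = season,
    egg_id = seq_len(n_eggs),
    genotype = genotype,
    interval_left_min = left,
    interval_right_min = right,
    censored = as.integer(censored),
    stringsAsFactors = FALSE
  )
}

#' Configuration of a simulated cohort study
#'
#' Bundles the design of a whole simulated study: number of masses, range of
#' eggs per mass, Hardy-Weinberg allele frequency for parental draws (or an
#' explicit list of crosses), dominance mode, genotype-to-phenotype model,
#' observation grid and seed. The defaults emulate a field study design with
#' 80-120 eggs per mass, four control replicates of five eggs per mass, and
#' parents drawn under Hardy-Weinberg equilibrium.
#'
#' @param n_masses number of egg masses (>= 1).
#' @param eggs_per_mass integer range `c(low, high)` of eggs per mass; each
#'   mass draws its count uniformly on that range.
#' @param allele_freq_T Hardy-Weinberg frequency of the tolerance allele used
#'   to draw parental genotypes; ignored when `crosses` is given.
#' @param crosses optional list (length `n_masses`) of length-2 character
#'   vectors giving each mass's parental genotypes explicitly.
#' @param mode an [inheritance_mode()].
#' @param tolerance a [tolerance_model()].
#' @param grid an [make_observation_grid()] object.
#' @param seed integer seed from which all draws of the study descend.
#' @param treatment,season labels for the cohort.
#' @param n_control_replicates,eggs_per_control control design per mass;
#'   control eggs are recorded as all surviving and used only for
#'   assay-validity bookkeeping.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_masses = 21,
                              eggs_per_mass = c(80, 120),
                              allele_freq_T = 0.5,
                              crosses = NULL,
                              mode = inheritance_mode("incomplete", d = 0.5),
                              tolerance = tolerance_model(),
                              grid = make_observation_grid(),
                              seed = 1L,
                              treatment = "AMD60",
                              season = NA_character_,
                              n_control_replicates = 4,
                              eggs_per_control = 5) {
  if (!is.numeric(n_masses) || length(n_masses) != 1L || n_masses < 1 ||
      n_masses != round(n_masses))
    stop("'n_masses' must be a positive integer")
  if (!is.numeric(eggs_per_mass) || length(eggs_per_mass) != 2L ||
      any(eggs_per_mass < 1) || eggs_per_mass[2] < eggs_per_mass[1] ||
      any(eggs_per_mass != round(eggs_per_mass)))
    stop("'eggs_per_mass' must be an integer range c(low, high) with ",
         "1 <= low <= high")
  if (!is.null(crosses)) {
    if (!is.list(crosses) || length(crosses) != n_masses)
      stop("'crosses' must be a list with one parental pair per mass")
    lapply(crosses, function(x) {
      if (length(x) != 2L) stop("each cross must give two parental genotypes")
      normalize_genotype(x)
    })
  } else {
    hw_genotype_freqs(allele_freq_T)  # validates the frequency
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != round(seed))
    stop("'seed' must be a single integer")
  structure(
    list(n_masses = as.integer(n_masses),
         eggs_per_mass = as.integer(eggs_per_mass),
         allele_freq_T = allele_freq_T,
         crosses = crosses,
         mode = as_inheritance_mode(mode),
         tolerance = as_tolerance_model(tolerance),
         grid = as_observation_grid(grid),
         seed = as.integer(seed),
         treatment = treatment,
         season = season,
         n_control_replicates = n_control_replicates,
         eggs_per_control = eggs_per_control),
    class = "simulation_config"
  )
}

#' Simulate a cohort of egg masses
#'
#' Draws parental genotypes for each mass (under Hardy-Weinberg equilibrium
#' at the configured tolerance-allele frequency, unless explicit crosses are
#' given), simulates every mass with [simulate_egg_mass()], and records the
#' per-mass truth (parents, egg count) together with control bookkeeping.
#' Fully reproducible: the configured seed is set once at the start, so the
#' same configuration always yields byte-identical egg tables.
#'
#' @param config a [simulation_config()].
#' @return An object of class `egg_study`: a list with elements `eggs` (the
#'   egg-level data frame, see [simulate_egg_mass()]), `masses` (per-mass
#'   metadata: parents, egg counts, control survival), `grid`, `config`.
#' @examples
#' study <- simulate_study(simulation_config(n_masses = 3, seed = 42))
#' head(study$eggs)
#' study$masses
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop("'config' must be a simulation_config")
  set.seed(config$seed)
  n <- config$n_masses
  ids <- mass_labels(n)

  if (is.null(config$crosses)) {
    f <- hw_genotype_freqs(config$allele_freq_T)
    parent1 <- sample(names(f), n, replace = TRUE, prob = f)
    parent2 <- sample(names(f), n, replace = TRUE, prob = f)
  } else {
    parent1 <- vapply(config$crosses, function(x) normalize_genotype(x)[1], "")
    parent2 <- vapply(config$crosses, function(x) normalize_genotype(x)[2], "")
  }
  n_eggs <- sample(seq(config$eggs_per_mass[1], config$eggs_per_mass[2]),
                   n, replace = TRUE)

  eggs <- vector("list", n)
  for (i in seq_len(n)) {
    eggs[[i]] <- simulate_egg_mass(parent1[i], parent2[i], n_eggs[i],
                                   config$mode, config$tolerance, config$grid,
                                   mass_id = ids[i],
                                   treatment = config$treatment,
                                   season = config$season)
  }

  masses <- data.frame(
    mass_id = ids,
    treatment = config$treatment,
    season = config$season,
    parent1 = parent1,
    parent2 = parent2,
    n_eggs = n_eggs,
    n_control_eggs = config$n_control_replicates * config$eggs_per_control,
    control_survival = 1,  # controls are generated as all surviving
    stringsAsFactors = FALSE
  )

  structure(list(eggs = do.call(rbind, eggs), masses = masses,
                 grid = config$grid, config = config),
            class = "egg_study")
}

#' @export
print.egg_study <- function(x, ...) {
  cat("Simulated egg-mass study:", nrow(x$masses), "masses,",
      nrow(x$eggs), "eggs,", "treatment", x$config$treatment, "\n")
  invisible(x)
}

# A..Z for small cohorts, zero-padded numeric labels otherwise
mass_labels <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)]
  else sprintf("M%03d", seq_len(n))
}
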