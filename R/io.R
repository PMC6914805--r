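# File formats, configuration and the end-to-end pipeline.
#
# CSV dialect: comma separated, header row, UTF-8, "." decimal; times are
# integer minutes throughout. Right-censored rows carry an empty
# interval_right_min and censored = 1.

EGG_COLUMNS <- c("mass_id", "treatment", "season", "egg_id", "genotype",
                 "interval_left_min", "interval_right_min", "censored")

#' Write an egg-level observation table
#'
#' @param x an `egg_study` (see [simulate_study()]) or an egg-level data
#'   frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_egg_table <- function(x, path) {
  eggs <- if (inherits(x, "egg_study")) x$eggs else x
  for (col in setdiff(EGG_COLUMNS, names(eggs)))
    eggs[[col]] <- NA
  eggs <- eggs[, EGG_COLUMNS]
  write.csv(eggs, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate an egg-level observation table
#'
#' Reads the CSV written by [write_egg_table()] and validates every record
#' against the observation grid: interval endpoints must be grid checkpoints
#' (or 0 for the first interval), left must precede right, and censored
#' records must start at the last checkpoint with an empty right endpoint.
#' Malformed rows are rejected with their line numbers; an empty table is an
#' explicit error rather than an empty cohort.
#'
#' @param path CSV path.
#' @param grid an [make_observation_grid()] object.
#' @return Validated egg-level data frame.
#' @export
read_egg_table <- function(path, grid) {
  grid <- as_observation_grid(grid)
  if (!file.exists(path)) stop("no such file: ", path)
  eggs <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA")),
    error = function(e) stop("cannot read egg table ", path, ": ",
                             conditionMessage(e)))
  required <- c("mass_id", "egg_id", "interval_left_min",
                "interval_right_min", "censored")
  miss <- setdiff(required, names(eggs))
  if (length(miss))
    stop("egg table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(eggs) == 0)
    stop("empty input: ", path, " contains no egg records")
  for (col in c("treatment", "season", "genotype"))
    if (!col %in% names(eggs)) eggs[[col]] <- NA_character_

  cp <- grid$checkpoints
  last <- cp[length(cp)]
  line <- seq_len(nrow(eggs)) + 1L  # data lines, counting the header
  errs <- character()
  flag <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      at <- line[which(bad)]
      shown <- paste(head(at, 10), collapse = ", ")
      more <- if (length(at) > 10) paste0(" (+", length(at) - 10, " more)") else ""
      errs <<- c(errs, paste0(what, " at line(s) ", shown, more))
    }
  }
  flag(!(eggs$censored %in% c(0, 1)), "censored flag must be 0 or 1")
  unc <- eggs$censored %in% 0
  flag(unc & is.na(eggs$interval_right_min),
       "uncensored record lacks interval_right_min")
  flag(unc & !is.na(eggs$interval_right_min) &
         !(eggs$interval_right_min %in% cp),
       "interval_right_min is not a grid checkpoint")
  flag(unc & !(eggs$interval_left_min %in% c(0, cp)),
       "interval_left_min is not 0 or a grid checkpoint")
  flag(unc & !is.na(eggs$interval_right_min) &
         eggs$interval_left_min >= eggs$interval_right_min,
       "interval_left_min is not below interval_right_min")
  cns <- eggs$censored %in% 1
  flag(cns & !is.na(eggs$interval_right_min),
       "censored record must leave interval_right_min empty")
  flag(cns & eggs$interval_left_min != last,
       "censored record must start at the last checkpoint")
  if (length(errs))
    stop("invalid egg table ", path, ":\n  ",
         paste(errs, collapse = "\n  "))
  eggs$interval_left_min <- as.numeric(eggs$interval_left_min)
  eggs$interval_right_min <- as.numeric(eggs$interval_right_min)
  eggs$censored <- as.integer(eggs$censored)
  for (col in c("mass_id", "treatment", "season", "genotype"))
    eggs[[col]] <- as.character(eggs[[col]])
  eggs
}

#' Pipeline configuration
#'
#' Collects everything a full run needs: the observation grid, either a
#' simulation block or an input egg table, classification thresholds, the
#' seed every random draw descends from, and the output directory.
#'
#' @param seed integer seed.
#' @param grid list of [make_observation_grid()] arguments or a grid object.
#' @param simulation optional list of [simulation_config()] arguments
#'   (without `grid`/`seed`, which are taken from the pipeline config).
#' @param input optional path to an egg-level CSV (used when `simulation`
#'   is absent).
#' @param thresholds list: `spread_small`, `spread_large` (percent),
#'   `alpha`, `min_eggs`, `min_weight`, `min_separation_sd`, `sigma_floor`.
#' @param exclude_extrapolated drop extrapolated masses from the
#'   spread-versus-LT50 curve fit.
#' @param rank_modes also run the cohort-level maximum-likelihood mode
#'   comparison.
#' @param outdir optional output directory for the report bundle.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            grid = list(t0 = 720, step = 0.15,
                                        n_checkpoints = 7),
                            simulation = NULL,
                            input = NULL,
                            thresholds = list(),
                            exclude_extrapolated = TRUE,
                            rank_modes = TRUE,
                            outdir = NULL) {
  th <- utils::modifyList(
    list(spread_small = 100, spread_large = 300, alpha = 0.05,
         min_eggs = 20, min_weight = 0.15, min_separation_sd = 2,
         sigma_floor = 1e-4),
    thresholds)
  stopifnot(all(unlist(th[c("spread_small", "spread_large", "alpha",
                            "min_eggs", "min_weight", "min_separation_sd",
                            "sigma_floor")]) > 0))
  if (is.null(simulation) && is.null(input))
    stop("a pipeline needs either a simulation block or an input table")
  structure(list(seed = as.integer(seed), grid = grid,
                 simulation = simulation, input = input, thresholds = th,
                 exclude_extrapolated = isTRUE(exclude_extrapolated),
                 rank_modes = isTRUE(rank_modes), outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  allowed <- names(formals(pipeline_config))
  bad <- setdiff(names(y), allowed)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> lethal-time fitting -> classification ->
#' inheritance evaluation, writing the egg table, mass summary,
#' classification, per-mass inheritance table, hypothesis tally and a
#' key-value report when an output directory is configured. The configured
#' seed is set once at the start, so a config run twice produces
#' byte-identical outputs. Stage failures are propagated with the stage
#' name.
#'
#' @param config a [pipeline_config()] or the path to a YAML config.
#' @param outdir overrides the configured output directory.
#' @return Invisibly, the report bundle: a list with `eggs`, `masses`
#'   (simulation truth, if simulated), `summary`, `classified`,
#'   `spread_fit`, `spearman`, `season_test`, `inheritance`, `tally`,
#'   `ranking`, `config`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    stop("'config' must be a pipeline_config or a YAML path")
  if (is.null(outdir)) outdir <- config$outdir
  th <- config$thresholds

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
  }

  set.seed(config$seed)
  grid <- stage("grid", as_observation_grid(config$grid))

  masses_truth <- NULL
  if (!is.null(config$simulation)) {
    eggs <- stage("simulate", {
      sim_args <- config$simulation
      sim_args$grid <- grid
      sim_args$seed <- config$seed
      study <- simulate_study(do.call(simulation_config, sim_args))
      masses_truth <- study$masses
      study$eggs
    })
  } else {
    eggs <- stage("read", read_egg_table(config$input, grid))
  }

  summary <- stage("fit",
    fit_all_masses(eggs, grid, sigma_floor = th$sigma_floor))
  classified <- stage("classify",
    classify_cohort(summary, spread_small = th$spread_small,
                    spread_large = th$spread_large))
  spread_fit <- stage("classify", tryCatch(
    fit_spread_vs_lt50(classified,
                       exclude_extrapolated = config$exclude_extrapolated,
                       alpha = th$alpha),
    error = function(e) NULL))
  spearman <- stage("classify", tryCatch(
    spearman_lt50_spread(classified), error = function(e) NULL))
  season_test <- stage("classify", {
    seasons <- unique(classified$season[!is.na(classified$season)])
    if (length(seasons) >= 2) {
      a <- classified[classified$season %in% seasons[1], , drop = FALSE]
      b <- classified[classified$season %in% seasons[2], , drop = FALSE]
      list(seasons = seasons[1:2],
           lt50 = compare_seasons(a, b, "lt50"),
           relative_spread = compare_seasons(a, b, "relative_spread"))
    } else NULL
  })
  inheritance <- stage("inherit",
    evaluate_inheritance(eggs, classified, grid,
                         spread_small = th$spread_small,
                         spread_large = th$spread_large,
                         min_eggs = th$min_eggs,
                         min_weight = th$min_weight,
                         min_separation_sd = th$min_separation_sd))
  tally <- stage("inherit", tally_hypothesis_support(inheritance))
  ranking <- if (config$rank_modes)
    stage("inherit", rank_inheritance_modes(eggs, grid)) else NULL

  bundle <- list(eggs = eggs, masses = masses_truth, summary = summary,
                 classified = classified, spread_fit = spread_fit,
                 spearman = spearman, season_test = season_test,
                 inheritance = inheritance, tally = tally,
                 ranking = ranking, config = config)

  if (!is.null(outdir)) stage("report", write_report_bundle(bundle, outdir))
  invisible(bundle)
}

# Write the CSVs and the key-value report of a pipeline run.
write_report_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_egg_table(bundle$eggs, p("eggs.csv"))
  if (!is.null(bundle$masses))
    write.csv(bundle$masses, p("masses_truth.csv"), row.names = FALSE, na = "")
  write.csv(bundle$summary, p("mass_summary.csv"), row.names = FALSE, na = "")
  cls <- bundle$classified
  write.csv(cls[, c("mass_id", "treatment", "season", "lt25", "lt50", "lt75",
                    "relative_spread", "sensitivity_label", "spread_flag_300",
                    "extrapolated", "degenerate", "tolerance_rank")],
            p("classification.csv"), row.names = FALSE, na = "")
  write.csv(bundle$inheritance, p("inheritance.csv"), row.names = FALSE,
            na = "")
  write.csv(bundle$tally, p("hypothesis_support.csv"), row.names = FALSE,
            na = "")

  th <- bundle$config$thresholds
  lines <- c(
    paste0("seed: ", bundle$config$seed),
    paste0("n_masses: ", nrow(bundle$summary)),
    paste0("n_eggs: ", nrow(bundle$eggs)),
    paste0("median_lt50_min: ",
           format(attr(bundle$classified, "median_lt50"), digits = 10)),
    paste0("spread_small_pct: ", th$spread_small),
    paste0("spread_large_pct: ", th$spread_large),
    paste0("exclude_extrapolated: ", bundle$config$exclude_extrapolated)
  )
  if (!is.null(bundle$spread_fit)) {
    sf <- bundle$spread_fit
    lines <- c(lines,
      paste0("spread_lt50_quadratic_coef: ",
             format(sf$quadratic_coef, digits = 10)),
      paste0("spread_lt50_p_one_sided: ",
             format(sf$p_one_sided, digits = 10)),
      paste0("inverted_u: ", sf$inverted_u))
  }
  if (!is.null(bundle$spearman)) {
    lines <- c(lines,
      paste0("spearman_rho: ", format(bundle$spearman$rho, digits = 10)),
      paste0("spearman_p: ", format(bundle$spearman$p, digits = 10)))
  }
  if (!is.null(bundle$season_test)) {
    st <- bundle$season_test
    lines <- c(lines,
      paste0("season_compare: ", paste(st$seasons, collapse = " vs ")),
      paste0("season_lt50_U: ", st$lt50$U),
      paste0("season_lt50_p: ", format(st$lt50$p, digits = 10)),
      paste0("season_spread_U: ", st$relative_spread$U),
      paste0("season_spread_p: ", format(st$relative_spread$p, digits = 10)))
  }
  for (i in seq_len(nrow(bundle$tally))) {
    t_ <- bundle$tally[i, ]
    lines <- c(lines, paste0("support_", t_$treatment, "_", t_$mode, ": ",
                             t_$n_support, "/", t_$n_masses))
  }
  if (!is.null(bundle$ranking)) {
    lines <- c(lines,
      paste0("top_mode: ", attr(bundle$ranking, "top_mode")),
      paste0("mode_bic: ",
             paste(sprintf("%s=%.2f", bundle$ranking$mode,
                           bundle$ranking$bic), collapse = "; ")))
  }
  writeLines(lines, p("report.txt"))
  invisible(outdir)
}
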