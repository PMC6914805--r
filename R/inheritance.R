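# Expected F1 tolerance patterns per dominance mode, recessivity categories,
# hypothesis tallies, and cohort-level maximum-likelihood mode comparison.

#' Expected F1 tolerance pattern of a cross under a dominance mode
#'
#' For a single biallelic locus, maps a (mode, cross) pair onto the expected
#' within-mass pattern of time-to-death frequencies: the Mendelian fraction
#' of phenotypically sensitive eggs, whether the distribution is bimodal
#' (both phenotype classes present under a fully polymorphic mode) or
#' unimodal, and its skew (right-skewed when all offspring are tolerant and
#' survive towards the end of the assay, left-skewed when all are
#' sensitive). Under incomplete dominance with 0 < d < 1 the distribution is
#' unimodal and broad; its reported sensitive fraction is the
#' dominance-weighted value `P(SS) + (1 - d) P(ST)`. Incomplete dominance
#' with d exactly 0 or 1 is the corresponding fully polymorphic mode.
#'
#' @param mode an [inheritance_mode()] (or mode name).
#' @param parent1,parent2 parental genotypes.
#' @return An object of class `pattern_spec`: list with `mode`, `cross`,
#'   `modality`, `skew`, `expected_sensitive_fraction`, `genotype_probs`.
#' @examples
#' expected_pattern("recessive", "ST", "TT")  # bimodal, 50% sensitive
#' expected_pattern("dominant", "TT", "TT")   # unimodal, right skew
#' @export
expected_pattern <- function(mode, parent1, parent2) {
  mode <- as_inheritance_mode(mode)
  off <- cross_offspring_distribution(parent1, parent2)

  eff <- mode
  if (mode$mode == "incomplete" && isTRUE(mode$d == 1))
    eff <- inheritance_mode("dominant")
  if (mode$mode == "incomplete" && isTRUE(mode$d == 0))
    eff <- inheritance_mode("recessive")

  if (eff$mode == "incomplete") {
    frac <- unname(off["SS"] + (1 - eff$d) * off["ST"])
    modality <- "unimodal"
  } else {
    sens <- sensitive_genotypes(eff)
    frac <- unname(sum(off[sens]))
    modality <- if (frac > 0 && frac < 1) "bimodal" else "unimodal"
  }
  skew <- if (frac == 0) "right" else if (frac == 1) "left" else "none"
  structure(list(mode = mode,
                 cross = c(normalize_genotype(parent1),
                           normalize_genotype(parent2)),
                 modality = modality, skew = skew,
                 expected_sensitive_fraction = frac,
                 genotype_probs = off),
            class = "pattern_spec")
}

#' @export
print.pattern_spec <- function(x, ...) {
  cat(sprintf("Expected F1 pattern (%s, %s x %s): %s, skew %s, %.0f%% sensitive\n",
              x$mode$mode, x$cross[1], x$cross[2], x$modality, x$skew,
              100 * x$expected_sensitive_fraction))
  invisible(x)
}

#' Observed fraction of highly sensitive eggs in a mass
#'
#' "Highly sensitive" is defined relative to the cohort: an egg whose death
#' interval lies entirely below the cohort median LT50 (so its recorded
#' death precedes the typical mass's median lethal time).
#'
#' @param eggs data frame of one mass's egg records.
#' @param median_lt50 cohort median LT50, minutes.
#' @return Fraction in \[0, 1\].
#' @export
observed_sensitive_fraction <- function(eggs, median_lt50) {
  mean(eggs$censored == 0 & eggs$interval_right_min <= median_lt50)
}

#' Assign a mass to one of the recessivity categories
#'
#' If tolerance were a fully recessive trait, every mass should fall in one
#' of four categories: (i) all eggs highly sensitive with small relative
#' spread (at least one parent homozygous for the sensitivity-dominant
#' allele); (ii) all eggs highly tolerant with small spread (both parents
#' homozygous tolerant); (iii) roughly half the eggs highly sensitive and
#' half highly tolerant with very large spread (heterozygous x homozygous
#' tolerant cross); (iv) as (iii) but with about three quarters of eggs
#' sensitive (both parents heterozygous). Operationalised with explicit
#' thresholds: small spread < `spread_small`; large spread >=
#' `spread_large`; sensitive-fraction windows \[0.35, 0.65\] for (iii) and
#' (0.65, 0.90\] for (iv) (the windows touch at 0.65; the boundary belongs
#' to (iii) so the categories stay mutually exclusive). Masses matching no
#' category are labelled `"none"`.
#'
#' @param modality `"unimodal"` or `"bimodal"` (see [detect_modality()]).
#' @param sensitivity_label the mass's cohort-relative label (see
#'   [classify_sensitivity()]).
#' @param relative_spread percent (may be `NA` for degenerate masses).
#' @param sensitive_fraction observed fraction of highly sensitive eggs.
#' @param spread_small,spread_large thresholds in percent.
#' @return List with `category` (`"i"`, `"ii"`, `"iii"`, `"iv"`, `"none"`)
#'   and `rationale`.
#' @export
assign_recessivity_category <- function(modality, sensitivity_label,
                                        relative_spread, sensitive_fraction,
                                        spread_small = 100,
                                        spread_large = 300) {
  if (is.na(modality) || is.na(sensitivity_label))
    stop("modality and sensitivity label are required")
  if (is.na(relative_spread)) {
    return(list(category = "none",
                rationale = "degenerate fit: relative spread unavailable"))
  }
  if (modality == "unimodal" && sensitivity_label == "critically_sensitive" &&
      relative_spread < spread_small) {
    return(list(category = "i",
                rationale = "unimodal, critically sensitive, small spread"))
  }
  if (modality == "unimodal" && sensitivity_label == "safely_tolerant" &&
      relative_spread < spread_small) {
    return(list(category = "ii",
                rationale = "unimodal, safely tolerant, small spread"))
  }
  if (modality == "bimodal" && relative_spread >= spread_large &&
      sensitive_fraction >= 0.35 && sensitive_fraction <= 0.65) {
    return(list(category = "iii",
                rationale = "bimodal, ~50% sensitive, very large spread"))
  }
  if (modality == "bimodal" && relative_spread >= spread_large &&
      sensitive_fraction > 0.65 && sensitive_fraction <= 0.90) {
    return(list(category = "iv",
                rationale = "bimodal, ~75% sensitive, large spread"))
  }
  list(category = "none", rationale = "matches no recessivity category")
}

#' Per-mass inheritance diagnostics for a classified cohort
#'
#' Runs the modality detector on every mass, computes its observed fraction
#' of highly sensitive eggs against the cohort median LT50, and assigns the
#' recessivity category.
#'
#' @param eggs egg-level data frame of the cohort.
#' @param classified output of [classify_cohort()] for the same masses.
#' @param grid an [make_observation_grid()] object.
#' @param spread_small,spread_large category thresholds, percent.
#' @param min_eggs,min_weight,min_separation_sd passed to
#'   [detect_modality()].
#' @return Data frame with one row per mass: `mass_id`, `treatment`,
#'   `modality`, `low_power`, `sensitive_fraction`, `relative_spread`,
#'   `sensitivity_label`, `category`, `rationale`.
#' @export
evaluate_inheritance <- function(eggs, classified, grid,
                                 spread_small = 100, spread_large = 300,
                                 min_eggs = 20, min_weight = 0.15,
                                 min_separation_sd = 2) {
  grid <- as_observation_grid(grid)
  med <- attr(classified, "median_lt50")
  if (is.null(med)) med <- median(classified$lt50)
  rows <- lapply(seq_len(nrow(classified)), function(i) {
    id <- classified$mass_id[i]
    m <- eggs[eggs$mass_id == id, , drop = FALSE]
    if (nrow(m) == 0) stop("no eggs found for mass ", id)
    mt <- detect_modality(m, grid, min_eggs = min_eggs,
                          min_weight = min_weight,
                          min_separation_sd = min_separation_sd)
    sf <- observed_sensitive_fraction(m, med)
    cat_ <- assign_recessivity_category(
      mt$modality, classified$sensitivity_label[i],
      classified$relative_spread[i], sf,
      spread_small = spread_small, spread_large = spread_large)
    data.frame(mass_id = id,
               treatment = classified$treatment[i],
               modality = mt$modality,
               low_power = mt$low_power,
               sensitive_fraction = sf,
               relative_spread = classified$relative_spread[i],
               sensitivity_label = classified$sensitivity_label[i],
               category = cat_$category,
               rationale = cat_$rationale,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tally the support for each inheritance hypothesis
#'
#' Applies the pattern logic per treatment cohort: incomplete dominance is
#' supported by every unimodal mass (all unimodal patterns are compatible
#' with some degree of dominance); full recessivity by masses in
#' categories i-iv; full dominance, overdominance and underdominance by
#' categories i-iii (category iv - a bimodal ~3:1 sensitive excess - is a
#' possible outcome of no pattern other than recessivity). A mass may
#' support several hypotheses.
#'
#' @param inheritance per-mass table from [evaluate_inheritance()].
#' @return Data frame with one row per (treatment, mode): `treatment`,
#'   `mode`, `n_support`, `n_masses`, `fraction`; masses uniquely
#'   supporting full recessivity (category iv) are attached as attribute
#'   `full_recessive_only`.
#' @export
tally_hypothesis_support <- function(inheritance) {
  if (!all(c("modality", "category") %in% names(inheritance)))
    stop("'inheritance' must come from evaluate_inheritance()")
  split_by <- if ("treatment" %in% names(inheritance))
    inheritance$treatment else rep("all", nrow(inheritance))
  pieces <- lapply(split(inheritance, split_by), function(d) {
    n <- nrow(d)
    uni <- sum(d$modality == "unimodal")
    rec <- sum(d$category %in% c("i", "ii", "iii", "iv"))
    dom <- sum(d$category %in% c("i", "ii", "iii"))
    data.frame(
      treatment = d$treatment[1],
      mode = c("incomplete", "recessive", "dominant", "overdominant",
               "underdominant"),
      n_support = c(uni, rec, dom, dom, dom),
      n_masses = n,
      fraction = c(uni, rec, dom, dom, dom) / n,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "full_recessive_only") <-
    inheritance$mass_id[inheritance$category == "iv"]
  out
}

# ---- cohort-level maximum-likelihood mode comparison -----------------------

# The six distinct (unordered) parental crosses and their offspring
# distributions; rows: SSxSS, SSxST, SSxTT, STxST, STxTT, TTxTT.
cross_pairs <- function() {
  idx <- rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 2), c(2, 3), c(3, 3))
  list(index = idx,
       offspring = t(apply(idx, 1, function(ij)
         cross_offspring_distribution(GENOTYPES[ij[1]], GENOTYPES[ij[2]]))))
}

# Hardy-Weinberg probabilities of the six unordered crosses at tolerance
# allele frequency p.
cross_hw_weights <- function(p, idx) {
  f <- hw_genotype_freqs(p)
  w <- f[idx[, 1]] * f[idx[, 2]]
  w[idx[, 1] != idx[, 2]] <- 2 * w[idx[, 1] != idx[, 2]]
  unname(w)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Fit one dominance mode to a whole cohort by maximum likelihood
#'
#' Treats each mass as an independent draw from an unknown parental cross
#' under Hardy-Weinberg equilibrium and each egg as an interval-censored
#' draw from its genotype's latent log-normal death time. The mass marginal
#' likelihood sums over the six distinct crosses weighted by their
#' Hardy-Weinberg probabilities. Free parameters: `mu_S`, `mu_T` (> `mu_S`),
#' `sigma_within`, `allele_freq_T`, plus the degree of dominance `d`
#' (incomplete) or the heterozygote displacement `delta` (over/under-
#' dominance). Dominant and recessive are 4-parameter models, the other
#' modes 5-parameter; comparison across modes (see
#' [rank_inheritance_modes()]) uses BIC with the total egg count.
#'
#' @param eggs egg-level data frame of the cohort.
#' @param grid an [make_observation_grid()] object.
#' @param mode mode name: `"dominant"`, `"recessive"`, `"overdominant"`,
#'   `"underdominant"` or `"incomplete"`.
#' @param maxit Nelder-Mead iteration cap per start.
#' @return An object of class `inheritance_fit`: list with `mode`,
#'   `loglik`, `n_par`, `bic`, `n_eggs`, `n_masses`, `estimates` (named
#'   list), `converged`.
#' @export
fit_inheritance_mode <- function(eggs, grid,
                                 mode = c("dominant", "recessive",
                                          "overdominant", "underdominant",
                                          "incomplete"),
                                 maxit = 1500) {
  mode <- match.arg(mode)
  grid <- as_observation_grid(grid)
  b <- grid_log10(grid)
  n_cp <- length(b)

  ids <- unique(eggs$mass_id)
  counts <- t(vapply(ids, function(id)
    interval_cell_counts(eggs[eggs$mass_id == id, , drop = FALSE], grid),
    numeric(n_cp + 1)))
  n_total <- sum(counts)

  cr <- cross_pairs()
  has_extra <- mode %in% c("overdominant", "underdominant", "incomplete")

  geno_means <- function(mu_S, mu_T, extra) {
    het <- switch(mode,
                  dominant = mu_T,
                  recessive = mu_S,
                  incomplete = mu_S + extra * (mu_T - mu_S),
                  overdominant = mu_T + extra,
                  underdominant = mu_S - extra)
    c(mu_S, het, mu_T)
  }

  nll <- function(th) {
    mu_S <- th[1]
    mu_T <- mu_S + exp(th[2])
    sig <- max(exp(th[3]), 1e-3)
    p <- plogis(th[4])
    extra <- if (!has_extra) NULL
             else if (mode == "incomplete") plogis(th[5]) else exp(th[5])
    mu_g <- geno_means(mu_S, mu_T, extra)
    G <- t(vapply(mu_g, component_cell_probs, numeric(n_cp + 1),
                  sigma = sig, b = b))
    P <- cr$offspring %*% G                      # 6 crosses x cells
    logP <- log(pmax(P, 1e-300))
    L <- counts %*% t(logP)                      # masses x crosses
    lw <- log(pmax(cross_hw_weights(p, cr$index), 1e-300))
    -sum(apply(sweep(L, 2, lw, "+"), 1, log_sum_exp))
  }

  # crude per-mass means from interval pseudo-midpoints for the starts
  hb <- mean(diff(b)) / 2
  mids <- c(b[1] - hb, (b[-n_cp] + b[-1]) / 2, b[n_cp] + hb)
  crude <- as.vector(counts %*% mids) / rowSums(counts)
  lo <- min(crude); hi <- max(crude)
  if (hi - lo < 0.3) { lo <- lo - 0.2; hi <- hi + 0.2 }

  extra_start <- if (!has_extra) NULL
                 else if (mode == "incomplete") 0 else log(0.3)
  starts <- list(
    c(lo, log(hi - lo), log(0.2), 0, extra_start),
    c(lo - 0.2, log(hi - lo + 0.4), log(0.3), 0, extra_start),
    c((lo + hi) / 2 - 0.6, log(1.2), log(0.15), 0, extra_start)
  )
  best <- NULL
  for (st in starts) {
    res <- tryCatch(optim(st, nll, method = "Nelder-Mead",
                          control = list(maxit = maxit)),
                    error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop("mode fit failed for all starting values")

  th <- best$par
  est <- list(mu_S = th[1], mu_T = th[1] + exp(th[2]),
              sigma_within = max(exp(th[3]), 1e-3),
              allele_freq_T = plogis(th[4]))
  if (mode == "incomplete") est$d <- plogis(th[5])
  if (mode %in% c("overdominant", "underdominant")) est$delta <- exp(th[5])
  n_par <- 4L + as.integer(has_extra)

  structure(list(mode = mode, loglik = -best$value, n_par = n_par,
                 bic = 2 * best$value + n_par * log(n_total),
                 n_eggs = n_total, n_masses = length(ids),
                 estimates = est, converged = best$convergence == 0),
            class = "inheritance_fit")
}

#' @export
print.inheritance_fit <- function(x, ...) {
  cat(sprintf("Cohort fit, %s mode: loglik = %.2f, BIC = %.2f (%d parameters)\n",
              x$mode, x$loglik, x$bic, x$n_par))
  est <- x$estimates
  cat(sprintf("  mu_S = %.3f, mu_T = %.3f, sigma = %.3f, freq(T) = %.3f%s\n",
              est$mu_S, est$mu_T, est$sigma_within, est$allele_freq_T,
              if (!is.null(est$d)) sprintf(", d = %.3f", est$d)
              else if (!is.null(est$delta)) sprintf(", delta = %.3f", est$delta)
              else ""))
  invisible(x)
}

#' Rank the five dominance modes on a cohort
#'
#' Fits every candidate mode with [fit_inheritance_mode()] and ranks them by
#' BIC; the top-supported mode is the BIC minimiser (ties broken towards the
#' more parsimonious model).
#'
#' @param eggs egg-level data frame of the cohort.
#' @param grid an [make_observation_grid()] object.
#' @param modes candidate mode names.
#' @param maxit passed to [fit_inheritance_mode()].
#' @return Data frame sorted by BIC with columns `mode`, `loglik`, `n_par`,
#'   `bic`, `delta_bic`; the winning mode name is attached as attribute
#'   `top_mode` and the full fits as attribute `fits`.
#' @examples
#' \donttest{
#' study <- simulate_study(simulation_config(n_masses = 6, seed = 9,
#'                                           mode = inheritance_mode("recessive")))
#' rank_inheritance_modes(study$eggs, study$grid)
#' }
#' @export
rank_inheritance_modes <- function(eggs, grid,
                                   modes = c("dominant", "recessive",
                                             "incomplete", "overdominant",
                                             "underdominant"),
                                   maxit = 1500) {
  fits <- lapply(modes, function(m)
    fit_inheritance_mode(eggs, grid, mode = m, maxit = maxit))
  df <- data.frame(
    mode = vapply(fits, `[[`, "", "mode"),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    n_par = vapply(fits, `[[`, 0L, "n_par"),
    bic = vapply(fits, `[[`, 0, "bic"),
    stringsAsFactors = FALSE
  )
  ord <- order(df$bic, df$n_par)
  df <- df[ord, , drop = FALSE]
  df$delta_bic <- df$bic - df$bic[1]
  rownames(df) <- NULL
  attr(df, "top_mode") <- df$mode[1]
  attr(df, "fits") <- setNames(fits, vapply(fits, `[[`, "", "mode"))
  class(df) <- c("mode_ranking", "data.frame")
  df
}

#' @export
print.mode_ranking <- function(x, ...) {
  cat("Inheritance mode ranking (BIC):\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  cat("Top-supported mode:", attr(x, "top_mode"), "\n")
  invisible(x)
}
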