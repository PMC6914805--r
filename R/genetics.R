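# Single-locus, two-allele genetics of tolerance: S = sensitivity allele,
# T = tolerance allele. Genotypes are unordered (TS is normalised to ST).

GENOTYPES <- c("SS", "ST", "TT")

normalize_genotype <- function(g) {
  g <- toupper(as.character(g))
  g[g == "TS"] <- "ST"
  bad <- !(g %in% GENOTYPES)
  if (any(bad))
    stop("invalid genotype(s): ", paste(unique(g[bad]), collapse = ", "),
         " (expected SS, ST or TT)")
  g
}

#' Specify the Mendelian dominance mode of the tolerance allele
#'
#' Describes how the heterozygote's tolerance phenotype relates to the two
#' homozygotes. Under incomplete dominance the heterozygote sits at a
#' position controlled by the degree of dominance `d` of the tolerance
#' allele: `d = 1` reproduces full dominance and `d = 0` full recessivity.
#' Overdominant and underdominant heterozygotes are displaced by `delta`
#' (log10 minutes) above the tolerant or below the sensitive homozygote.
#'
#' @param mode one of `"dominant"`, `"recessive"`, `"overdominant"`,
#'   `"underdominant"`, `"incomplete"`.
#' @param d degree of dominance of tolerance, in \[0, 1\]; used only when
#'   `mode = "incomplete"` (default 0.5).
#' @param delta heterozygote displacement in log10 minutes (> 0); used only
#'   for over/underdominance (default 0.3).
#' @return An object of class `inheritance_mode`.
#' @examples
#' inheritance_mode("incomplete", d = 0.25)
#' inheritance_mode("overdominant")
#' @export
inheritance_mode <- function(mode = c("dominant", "recessive", "overdominant",
                                      "underdominant", "incomplete"),
                             d = NULL, delta = NULL) {
  mode <- match.arg(mode)
  if (mode == "incomplete") {
    if (is.null(d)) d <- 0.5
    if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0 || d > 1)
      stop("degree of dominance 'd' must be a single number in [0, 1]")
  } else if (!is.null(d)) {
    stop("'d' is only meaningful when mode = \"incomplete\"")
  }
  if (mode %in% c("overdominant", "underdominant")) {
    if (is.null(delta)) delta <- 0.3
    if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta <= 0)
      stop("'delta' must be a single positive log10-minute displacement")
  } else if (!is.null(delta)) {
    stop("'delta' is only meaningful for over/underdominance")
  }
  structure(list(mode = mode, d = d, delta = delta),
            class = "inheritance_mode")
}

#' @export
print.inheritance_mode <- function(x, ...) {
  extra <- switch(x$mode,
                  incomplete = paste0(" (d = ", x$d, ")"),
                  overdominant = ,
                  underdominant = paste0(" (delta = ", x$delta, ")"),
                  "")
  cat("Inheritance mode:", x$mode, extra, "\n", sep = "")
  invisible(x)
}

as_inheritance_mode <- function(mode) {
  if (inherits(mode, "inheritance_mode")) return(mode)
  if (is.character(mode) && length(mode) == 1L) return(inheritance_mode(mode))
  if (is.list(mode)) return(do.call(inheritance_mode, mode))
  stop("'mode' must be an inheritance_mode, a mode name, or a parameter list")
}

#' Genotype-to-phenotype model for latent log10 death times
#'
#' Places the two homozygotes on the log10-minute axis and sets the
#' within-genotype spread of latent death times. Together with an
#' [inheritance_mode()] this fixes the mean latent log10 death time of all
#' three genotypes.
#'
#' The defaults put the sensitive homozygote slightly below the first
#' checkpoint of the default observation grid and the tolerant homozygote
#' slightly above the last one, so that the most extreme masses behave like
#' the extrapolated extreme masses seen in real assays while mixed masses
#' span the window.
#'
#' @param mu_S mean log10 death time (log10 minutes) of the sensitive
#'   homozygote SS.
#' @param mu_T mean log10 death time of the tolerant homozygote TT; must
#'   exceed `mu_S`.
#' @param sigma_within within-genotype standard deviation of log10 death
#'   time (>= 0).
#' @return An object of class `tolerance_model`.
#' @examples
#' tolerance_model()
#' @export
tolerance_model <- function(mu_S = 2.6, mu_T = 4.0, sigma_within = 0.2) {
  if (!is.numeric(mu_S) || length(mu_S) != 1L || !is.finite(mu_S))
    stop("'mu_S' must be a single finite number (log10 minutes)")
  if (!is.numeric(mu_T) || length(mu_T) != 1L || !is.finite(mu_T))
    stop("'mu_T' must be a single finite number (log10 minutes)")
  if (mu_T <= mu_S)
    stop("'mu_T' must exceed 'mu_S' (the tolerant genotype survives longer)")
  if (!is.numeric(sigma_within) || length(sigma_within) != 1L ||
      is.na(sigma_within) || sigma_within < 0)
    stop("'sigma_within' must be a single non-negative number")
  structure(list(mu_S = mu_S, mu_T = mu_T, sigma_within = sigma_within),
            class = "tolerance_model")
}

as_tolerance_model <- function(tol) {
  if (inherits(tol, "tolerance_model")) return(tol)
  if (is.list(tol)) return(do.call(tolerance_model, tol))
  stop("'tolerance' must be a tolerance_model or a parameter list")
}

#' Mendelian offspring genotype distribution of a cross
#'
#' Exact segregation probabilities of the three genotypes among offspring of
#' two parents at a single biallelic locus.
#'
#' @param parent1,parent2 parental genotypes (`"SS"`, `"ST"`/`"TS"`, `"TT"`).
#' @return Named numeric vector of probabilities over `SS`, `ST`, `TT`
#'   (non-negative, summing to one).
#' @examples
#' cross_offspring_distribution("ST", "TT")  # 0, 1/2, 1/2
#' cross_offspring_distribution("ST", "ST")  # 1/4, 1/2, 1/4
#' @export
cross_offspring_distribution <- function(parent1, parent2) {
  p1 <- normalize_genotype(parent1)
  p2 <- normalize_genotype(parent2)
  allele_probs <- function(g)
    switch(g,
           SS = c(S = 1,   T = 0),
           ST = c(S = 0.5, T = 0.5),
           TT = c(S = 0,   T = 1))
  a1 <- allele_probs(p1)
  a2 <- allele_probs(p2)
  joint <- outer(a1, a2)
  c(SS = joint["S", "S"],
    ST = joint["S", "T"] + joint["T", "S"],
    TT = joint["T", "T"])
}

#' Draw offspring genotypes from a cross
#'
#' Samples `n` offspring genotypes under exact Mendelian segregation. Uses
#' the current RNG state; call `set.seed()` beforehand for reproducibility.
#'
#' @inheritParams cross_offspring_distribution
#' @param n number of offspring to draw.
#' @return Character vector of genotypes.
#' @examples
#' set.seed(1)
#' table(draw_offspring_genotypes("ST", "ST", 1000))
#' @export
draw_offspring_genotypes <- function(parent1, parent2, n) {
  pr <- cross_offspring_distribution(parent1, parent2)
  sample(names(pr), size = n, replace = TRUE, prob = pr)
}

#' Mean latent log10 death time of a genotype
#'
#' Maps genotypes onto the log10-minute axis given a dominance mode and a
#' genotype-to-phenotype model: SS maps to `mu_S`, TT to `mu_T`, and the
#' heterozygote to `mu_S + d * (mu_T - mu_S)` under incomplete dominance
#' (with `d = 1` for full dominance and `d = 0` for full recessivity), to
#' `mu_T + delta` under overdominance, and to `mu_S - delta` under
#' underdominance.
#'
#' @param genotype character vector of genotypes.
#' @param mode an [inheritance_mode()] (or mode name).
#' @param tolerance a [tolerance_model()].
#' @return Numeric vector of mean log10 death times (log10 minutes).
#' @examples
#' tol <- tolerance_model(mu_S = 3.0, mu_T = 3.6, sigma_within = 0.1)
#' genotype_mean_loglt("ST", inheritance_mode("incomplete", d = 0.5), tol)  # 3.3
#' @export
genotype_mean_loglt <- function(genotype, mode, tolerance) {
  g <- normalize_genotype(genotype)
  mode <- as_inheritance_mode(mode)
  tol <- as_tolerance_model(tolerance)
  het <- switch(mode$mode,
                dominant      = tol$mu_T,
                recessive     = tol$mu_S,
                incomplete    = tol$mu_S + mode$d * (tol$mu_T - tol$mu_S),
                overdominant  = tol$mu_T + mode$delta,
                underdominant = tol$mu_S - mode$delta)
  unname(c(SS = tol$mu_S, ST = het, TT = tol$mu_T)[g])
}

#' Phenotypically sensitive genotypes under a fully polymorphic mode
#'
#' Under the four fully polymorphic modes every genotype is either sensitive
#' or tolerant: with dominant or overdominant tolerance only SS is
#' sensitive; with recessive or underdominant tolerance carrying at least
#' one S allele (SS or ST) makes the egg sensitive. Incomplete dominance
#' with 0 < d < 1 has no binary sensitive class and is rejected.
#'
#' @param mode an [inheritance_mode()] (or mode name).
#' @return Character vector of sensitive genotypes.
#' @examples
#' sensitive_genotypes("recessive")  # "SS" "ST"
#' @export
sensitive_genotypes <- function(mode) {
  mode <- as_inheritance_mode(mode)
  switch(mode$mode,
         dominant = ,
         overdominant = "SS",
         recessive = ,
         underdominant = c("SS", "ST"),
         incomplete = {
           if (isTRUE(mode$d == 1)) "SS"
           else if (isTRUE(mode$d == 0)) c("SS", "ST")
           else stop("the phenotype is not fully polymorphic under ",
                     "incomplete dominance with 0 < d < 1")
         })
}

#' Hardy-Weinberg genotype frequencies
#'
#' @param allele_freq_T frequency of the tolerance allele T, in \[0, 1\].
#' @return Named numeric vector of genotype frequencies over `SS`, `ST`, `TT`.
#' @examples
#' hw_genotype_freqs(0.5)
#' @export
hw_genotype_freqs <- function(allele_freq_T) {
  p <- allele_freq_T
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("'allele_freq_T' must be a single number in [0, 1]")
  c(SS = (1 - p)^2, ST = 2 * p * (1 - p), TT = p^2)
}
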