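# Shared domain types and deterministic demographic algebra.
#
# Stage order is fixed everywhere in the package as
#   (N1, N2, N3, N4, Nimm)
# i.e. first-year, second-year, third-year, fourth-year-and-older
# (the only breeding class), and breeding-age immigrants.

STAGE_NAMES <- c("N1", "N2", "N3", "N4", "Nimm")

#' Study design: years, survey years, age classes
#'
#' Describes the temporal frame of a colony study: the ordered calendar
#' years covered, the (typically sparse) subset of years in which a
#' breeding-pair survey was conducted, and a species label.  Only the
#' 4-and-older class breeds; ages are tracked as classes 1, 2, 3, 4+.
#'
#' @param years integer vector of consecutive calendar years (length >= 3)
#' @param survey_years subset of `years` with breeding-pair counts
#' @param species_label free-text label carried through outputs
#' @return an object of class `study_design`
#' @export
study_design <- function(years, survey_years = years, species_label = "") {
  years <- as.integer(years)
  survey_years <- as.integer(survey_years)
  if (length(years) < 3) stopf("need at least 3 years")
  if (any(diff(years) != 1L)) stopf("years must be consecutive")
  if (!all(survey_years %in% years)) stopf("survey_years must be a subset of years")
  structure(
    list(years = years, survey_years = sort(unique(survey_years)),
         n_years = length(years), age_classes = c("1", "2", "3", "4+"),
         species_label = species_label),
    class = "study_design")
}

#' Vital rates for the female-based five-class life cycle
#'
#' Holds year-indexed first-year apparent survival (`alpha1`), adult
#' apparent survival (`alpha2`), productivity (`f`, chicks fledged per
#' pair; the female-based model uses `f/2`), and the constant
#' immigration-plus-noise rate `omega`.  Scalars are recycled to the
#' requested number of transition years.
#'
#' @param alpha1,alpha2 per-year survival probabilities in (0,1)
#' @param f per-year productivity in (0,1)
#' @param omega nonnegative constant immigration-plus-noise rate
#' @param n_years number of transition years to recycle scalars to
#' @return an object of class `vital_rates`
#' @export
vital_rates <- function(alpha1, alpha2, f, omega, n_years = length(alpha1)) {
  alpha1 <- rep_len(alpha1, n_years)
  alpha2 <- rep_len(alpha2, n_years)
  f <- rep_len(f, n_years)
  check_prob(alpha1, "alpha1")
  check_prob(alpha2, "alpha2")
  check_prob(f, "f")
  if (length(omega) != 1 || !is.finite(omega) || omega < 0)
    stopf("omega must be a single nonnegative number")
  if (any(f / 2 * alpha1 > 1))
    stopf("f/2 * alpha1 exceeds 1: not a valid recruitment probability")
  structure(list(alpha1 = alpha1, alpha2 = alpha2, f = f, omega = omega),
            class = "vital_rates")
}

#' Detection parameters for the encounter-count observation model
#'
#' Availability for detection is a Markov process on presence at the
#' colony: `gamma1[a]` is the probability of being available at `t` given
#' absence at `t - 1` and age class `a` at `t - 1`; `gamma2[a]` the same
#' given presence.  `epsilon` is the mean expected number of encounters
#' per season for the two encounter groups (pre-breeders, ages 1-3, and
#' breeders, 4+).  Individual heterogeneity multiplies `epsilon` by
#' `h_i ~ Gamma(theta, theta)` (mean 1); smaller `theta` means more
#' spread among individuals.
#'
#' @param gamma1,gamma2 length-4 availability probabilities by age class
#' @param epsilon length-2 (pre-breeder, breeder) mean encounter rates,
#'   or a 2 x T matrix for year-varying rates
#' @param theta positive heterogeneity overdispersion parameter
#' @return an object of class `detection_params`
#' @export
detection_params <- function(gamma1, gamma2, epsilon, theta) {
  gamma1 <- rep_len(gamma1, 4L)
  gamma2 <- rep_len(gamma2, 4L)
  check_prob(gamma1, "gamma1")
  check_prob(gamma2, "gamma2")
  if (is.matrix(epsilon)) {
    if (nrow(epsilon) != 2) stopf("epsilon matrix must have 2 rows (groups)")
  } else {
    epsilon <- matrix(rep_len(epsilon, 2L), nrow = 2)
  }
  if (any(!is.finite(epsilon)) || any(epsilon < 0))
    stopf("epsilon must be nonnegative and finite")
  if (length(theta) != 1 || !is.finite(theta) || theta <= 0)
    stopf("theta must be a single positive number")
  structure(list(gamma1 = gamma1, gamma2 = gamma2, epsilon = epsilon,
                 theta = theta),
            class = "detection_params")
}

# epsilon for group g (1 = pre-breeder, 2 = breeder) in (transition-free)
# year t; a 2-column epsilon recycles over years
eps_at <- function(dp, group, t) {
  m <- dp$epsilon
  m[group, ((t - 1L) %% ncol(m)) + 1L]
}

# encounter group from age class: ages 1-3 pre-breeders, 4+ breeders
age_group <- function(age) ifelse(age >= 4L, 2L, 1L)

#' Expected-value projection matrix for one year
#'
#' Builds the 5 x 5 matrix whose product with the stage vector
#' `(N1, N2, N3, N4, Nimm)` gives the expected next-year stage vector
#' under the stochastic state process: recruitment `(f/2) * alpha1` from
#' the breeding classes into N1, survival `alpha2` moving N1->N2, N2->N3
#' and (N3, N4, Nimm)->N4, and immigration at rate `omega` per head of
#' the four resident classes into Nimm.  Immigrants already present
#' graduate into N4, so the (Nimm, Nimm) entry is zero.
#'
#' @param rates a `vital_rates` object; the first year's slice is used
#' @param year which transition year of `rates` to use
#' @return 5 x 5 numeric matrix with dimnames `STAGE_NAMES`
#' @export
build_projection_matrix <- function(rates, year = 1L) {
  stopifnot(inherits(rates, "vital_rates"))
  a1 <- rates$alpha1[year]; a2 <- rates$alpha2[year]
  f <- rates$f[year]; om <- rates$omega
  rec <- f / 2 * a1
  if (rec > 1) stopf("f/2 * alpha1 exceeds 1")
  A <- matrix(0, 5, 5, dimnames = list(STAGE_NAMES, STAGE_NAMES))
  A["N1", c("N4", "Nimm")] <- rec
  A["N2", "N1"] <- a2
  A["N3", "N2"] <- a2
  A["N4", c("N3", "N4", "Nimm")] <- a2
  A["Nimm", c("N1", "N2", "N3", "N4")] <- om
  if (any(A < 0)) stopf("projection matrix has negative entries")
  A
}

#' Stable stage distribution and asymptotic growth rate
#'
#' Normalized leading right eigenvector of a nonnegative projection
#' matrix, together with its dominant eigenvalue.  Used to allocate an
#' initial scalar population size across stages.  Fails explicitly when
#' the two largest eigenvalue moduli are within a relative gap of 1e-8
#' (no strictly dominant eigenvalue).
#'
#' @param A nonnegative square projection matrix
#' @return list with `stable_stage` (proportions summing to 1) and
#'   `lambda` (dominant eigenvalue)
#' @export
stable_stage_distribution <- function(A) {
  if (any(A < 0)) stopf("projection matrix must be nonnegative")
  e <- eigen(A)
  mods <- Mod(e$values)
  ord <- order(mods, decreasing = TRUE)
  if (length(ord) > 1 &&
      (mods[ord[1]] - mods[ord[2]]) <= 1e-8 * mods[ord[1]])
    stopf(paste("no strictly dominant eigenvalue: two largest moduli",
                "%.10g and %.10g are within relative gap 1e-8"),
          mods[ord[1]], mods[ord[2]])
  lambda <- Re(e$values[ord[1]])
  v <- Re(e$vectors[, ord[1]])
  if (sum(v) < 0) v <- -v
  if (any(v < -1e-12)) stopf("leading eigenvector is not nonnegative")
  v <- pmax(v, 0)
  list(stable_stage = v / sum(v), lambda = lambda)
}

#' Realized annual growth rate of a population series
#'
#' The transient growth rate `lambda_t = Ntot_{t+1} / Ntot_t` for each
#' interval.  Intervals with a zero denominator are returned as `NA`
#' (flagged, not dropped), with a warning.
#'
#' @param ntot numeric vector of population sizes (length >= 2)
#' @return numeric vector of length `length(ntot) - 1`
#' @export
realized_growth <- function(ntot) {
  if (length(ntot) < 2) stopf("need at least two population sizes")
  if (any(ntot < 0)) stopf("population sizes must be nonnegative")
  den <- ntot[-length(ntot)]
  lam <- ntot[-1] / den
  if (any(den == 0)) {
    lam[den == 0] <- NA_real_
    warnf("zero population size: %d undefined growth interval(s) set to NA",
          sum(den == 0))
  }
  lam
}

#' Detection probability from an encounter rate
#'
#' With encounters Poisson at rate `epsilon` per season, the probability
#' of at least one encounter is `p = 1 - exp(-epsilon)`.
#'
#' @param epsilon nonnegative encounter rate(s)
#' @return detection probabilities in [0, 1)
#' @export
detection_probability <- function(epsilon) {
  if (any(!is.finite(epsilon)) || any(epsilon < 0))
    stopf("epsilon must be nonnegative and finite")
  -expm1(-epsilon)
}

#' Encounter rate from a detection probability
#'
#' Exact inverse of [detection_probability()]: `epsilon = -log(1 - p)`.
#'
#' @param p detection probabilities in [0, 1)
#' @return nonnegative encounter rates
#' @export
encounter_rate <- function(p) {
  check_prob(p, "p", open = FALSE)
  if (any(p >= 1)) stopf("p must be < 1")
  -log1p(-p)
}

#' Initial stage allocation from a breeding-pair estimate
#'
#' Allocates abundances to N1..N4 proportionally to the stable stage
#' distribution of the projection matrix at the given rates, scaled so
#' that the breeding resident class N4 equals `initial_pairs`.  The
#' immigrant class is excluded from the scaling and is expected to be
#' initialized separately (Poisson around its own mean).
#'
#' @param rates a `vital_rates` object (first-year slice used)
#' @param initial_pairs breeding-pair point estimate for year 1
#' @return named numeric vector over N1..N4 (expected values, not rounded)
#' @export
initial_stage_allocation <- function(rates, initial_pairs) {
  ss <- stable_stage_distribution(build_projection_matrix(rates))$stable_stage
  v <- ss[1:4] / ss[4] * initial_pairs
  names(v) <- STAGE_NAMES[1:4]
  v
}
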