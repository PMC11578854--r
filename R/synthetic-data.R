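# Individual-based generator of the three data streams the IPM consumes:
# breeding-pair survey counts, encounter-count CMR histories, and burrow
# productivity records.  All draws come from the exact distributional
# assumptions of the model, so parameter recovery is a meaningful check.

#' Scenario configuration for the synthetic-data generator
#'
#' Bundles the study design, true demographic and detection parameters,
#' initialization, and marking/monitoring effort.  Defaults describe a
#' reduced-scale scenario sized for routine recovery tests: 15 years,
#' surveys every 4th year, 100 chicks and 40 adults newly marked per
#' year, and 80 monitored burrows per year.  `initial_immigrant_lambda`
#' is the mean of the Poisson draw for first-year immigrants (default
#' 50).
#'
#' @param design a `study_design`
#' @param rates true `vital_rates` (length `n_years - 1`)
#' @param detect true `detection_params`
#' @param initial_total_pairs breeding pairs at the first census
#' @param initial_immigrant_lambda mean number of immigrants in year 1
#' @param chicks_marked_per_year,adults_marked_per_year newly marked
#'   individuals each year (scalar or per-year vector over years
#'   `1..n_years - 1`; birds marked in the final year carry no survival
#'   information and are not generated)
#' @param burrows_per_year monitored burrows (scalar or per-year vector)
#' @param f_monitored optional per-year productivity used for the
#'   monitored-burrow stream; defaults to the population `rates$f`
#' @return an object of class `scenario_config`
#' @export
scenario_config <- function(design,
                            rates,
                            detect,
                            initial_total_pairs = 2000L,
                            initial_immigrant_lambda = 50,
                            chicks_marked_per_year = 100L,
                            adults_marked_per_year = 40L,
                            burrows_per_year = 80L,
                            f_monitored = NULL) {
  stopifnot(inherits(design, "study_design"), inherits(rates, "vital_rates"),
            inherits(detect, "detection_params"))
  Tn <- design$n_years
  if (length(rates$alpha1) != Tn - 1L)
    stopf("rates must have %d transition years, got %d", Tn - 1L,
          length(rates$alpha1))
  cm <- rep_len(as.integer(chicks_marked_per_year), Tn - 1L)
  am <- rep_len(as.integer(adults_marked_per_year), Tn - 1L)
  bb <- rep_len(as.integer(burrows_per_year), Tn)
  if (any(c(cm, am, bb) < 0) || initial_total_pairs < 0 ||
      initial_immigrant_lambda < 0)
    stopf("all counts and rates in the scenario must be nonnegative")
  if (is.null(f_monitored)) f_monitored <- rates$f[c(seq_len(Tn - 1L), Tn - 1L)]
  f_monitored <- rep_len(f_monitored, Tn)
  structure(
    list(design = design, rates = rates, detect = detect,
         initial_total_pairs = as.integer(initial_total_pairs),
         initial_immigrant_lambda = initial_immigrant_lambda,
         chicks_marked_per_year = cm, adults_marked_per_year = am,
         burrows_per_year = bb, f_monitored = f_monitored),
    class = "scenario_config")
}

#' Reduced-scale default scenario
#'
#' Convenience constructor for the default recovery-test scenario:
#' T = 15 years with surveys in years 1, 5, 9, 13, constant true rates,
#' and effort as in [scenario_config()] defaults.  Default parameter
#' values are posterior-mean-scale values typical of a stable auk
#' colony.
#'
#' @param n_years study length
#' @param alpha1,alpha2,f,omega,theta true demographic/heterogeneity values
#' @param epsilon length-2 true mean encounter rates (pre-breeder, breeder)
#' @param gamma1,gamma2 length-4 true availability probabilities
#' @param initial_total_pairs initial breeding pairs
#' @param ... passed on to [scenario_config()]
#' @return a `scenario_config`
#' @export
default_scenario <- function(n_years = 15L,
                             alpha1 = 0.30, alpha2 = 0.85, f = 0.55,
                             omega = 0.08, theta = 39.0,
                             epsilon = c(0.6, 2.5),
                             gamma1 = c(0.05, 0.20, 0.45, 0.65),
                             gamma2 = c(0.30, 0.50, 0.75, 0.90),
                             initial_total_pairs = 2000L, ...) {
  yrs <- seq(1998L, length.out = n_years)
  des <- study_design(yrs, survey_years = yrs[seq(1L, n_years, by = 4L)],
                      species_label = "synthetic-auk")
  rts <- vital_rates(alpha1, alpha2, f, omega, n_years = n_years - 1L)
  det <- detection_params(gamma1, gamma2, epsilon, theta)
  scenario_config(des, rts, det, initial_total_pairs = initial_total_pairs,
                  ...)
}

#' Simulate the latent age-structured population
#'
#' Exact stochastic recursion of the state process: binomial recruitment
#' of first-years from the breeding total at probability `f/2 * alpha1`,
#' binomial survival `alpha2` through the pre-breeder classes and of the
#' breeding total, and Poisson immigration at per-capita rate `omega`
#' applied to the four resident classes.  The breeding total is
#' `Ntot = N4 + Nimm` in every year.  Extinction is permitted and
#' flagged in the result, not an error.
#'
#' @param config a `scenario_config`
#' @return list with integer matrix `N` (5 x T, rows `STAGE_NAMES`),
#'   vector `Ntot`, and logical `extinct`
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  Tn <- config$design$n_years
  r <- config$rates
  N <- matrix(0L, 5, Tn, dimnames = list(STAGE_NAMES, config$design$years))
  init <- initial_stage_allocation(r, config$initial_total_pairs)
  N[1:4, 1] <- rpois(4, init)
  N["Nimm", 1] <- rpois(1, config$initial_immigrant_lambda)
  ntot <- integer(Tn)
  ntot[1] <- N["N4", 1] + N["Nimm", 1]
  for (t in seq_len(Tn - 1L)) {
    N["N1", t + 1] <- rbinom(1, ntot[t], r$f[t] / 2 * r$alpha1[t])
    N["N2", t + 1] <- rbinom(1, N["N1", t], r$alpha2[t])
    N["N3", t + 1] <- rbinom(1, N["N2", t], r$alpha2[t])
    N["N4", t + 1] <- rbinom(1, N["N3", t] + ntot[t], r$alpha2[t])
    N["Nimm", t + 1] <- rpois(1, r$omega * sum(N[1:4, t]))
    ntot[t + 1] <- N["N4", t + 1] + N["Nimm", t + 1]
  }
  list(N = N, Ntot = ntot, extinct = any(colSums(N) == 0L))
}

#' Simulate breeding-pair survey counts
#'
#' Poisson observation of the breeding total in survey years only:
#' `y_t ~ Poisson(Ntot_t)`.
#'
#' @param states result of [simulate_population()]
#' @param design the `study_design`
#' @return data.frame with columns `year`, `pairs`
#' @export
simulate_counts <- function(states, design) {
  idx <- match(design$survey_years, design$years)
  data.frame(year = design$survey_years,
             pairs = rpois(length(idx), states$Ntot[idx]))
}

#' Simulate burrow productivity records
#'
#' Binomial fledging: `J_t ~ Binomial(B_t, f_t)` chicks fledged from
#' `B_t` monitored burrows.
#'
#' @param f_series per-year productivity values
#' @param burrows_per_year scalar or per-year burrow counts
#' @param years calendar years to label rows with
#' @return data.frame with columns `year`, `burrows_monitored`,
#'   `chicks_fledged`
#' @export
simulate_productivity <- function(f_series, burrows_per_year,
                                  years = seq_along(f_series)) {
  B <- rep_len(as.integer(burrows_per_year), length(f_series))
  data.frame(year = years, burrows_monitored = B,
             chicks_fledged = rbinom(length(B), B, f_series))
}

# latent trajectory of one marked individual; returns its encounter
# counts for occasions mark..T (NA once the record ends).  Exposed via
# simulate_encounters().
simulate_one_history <- function(mark, age_mark, Tn, rates, detect) {
  th <- detect$theta
  # marking occasion: alive; counted at least once.  The pair (h, count)
  # is drawn as h ~ Gamma(theta, theta) and then the marking count
  # zero-truncated given h.
  h <- rgamma(1, th, th)
  eps0 <- eps_at(detect, age_group(age_mark), mark)
  cmark <- if (eps0 == 0) 1L else {
    # zero-truncated Poisson via inverse cdf
    u <- runif(1, exp(-eps0 * h), 1)
    qpois(u, eps0 * h)
  }
  ages <- pmin(age_mark + (seq(mark, Tn) - mark), 4L)
  z <- 1L
  k <- if (age_mark == 1L) 0L else 1L  # chicks marked in the nest are absent
  cc <- integer(Tn - mark + 1L)
  cc[1] <- max(cmark, 1L)
  for (j in seq_len(Tn - mark)) {
    t <- mark + j
    age_prev <- ages[j]
    phi <- if (age_prev == 1L) rates$alpha1[t - 1L] else rates$alpha2[t - 1L]
    z <- rbinom(1, 1, phi * z)
    gam <- if (k == 1L) detect$gamma2[age_prev] else detect$gamma1[age_prev]
    k <- rbinom(1, 1, z * gam)
    lam <- k * eps_at(detect, age_group(ages[j + 1L]), t) * h
    cc[j + 1L] <- rpois(1, lam)
  }
  cc
}

#' Simulate encounter-count mark-recapture histories
#'
#' Generates per-individual encounter counts under the zero-inflated
#' gamma-Poisson observation model: a latent alive process with
#' age-constrained apparent survival, a Markov availability process with
#' age-specific return probabilities (`gamma1` from absence, `gamma2`
#' from presence), and Poisson encounter counts at rate
#' `k * epsilon_group * h_i` with individual heterogeneity
#' `h_i ~ Gamma(theta, theta)`.  Chicks are marked in the nest at age
#' class 1 (counted at banding but entering the availability process as
#' absent); adults are marked at the colony at age class 4+ (present).
#' Marking-occasion counts are conditioned to be at least 1.
#'
#' Cohort sizes that exceed the simulated number of available birds
#' (fledged chicks, or twice the breeding total for adults) are
#' truncated with a warning.
#'
#' @param config a `scenario_config`
#' @param states result of [simulate_population()]
#' @return data.frame in long format with columns `individual_id`,
#'   `mark_year`, `age_at_mark`, `year`, `encounter_count` (one row per
#'   individual-season from marking onward)
#' @export
simulate_encounters <- function(config, states) {
  des <- config$design
  Tn <- des$n_years
  rows <- vector("list", 2L * (Tn - 1L))
  id <- 0L
  ri <- 0L
  for (t in seq_len(Tn - 1L)) {
    n_ch <- config$chicks_marked_per_year[t]
    n_ad <- config$adults_marked_per_year[t]
    chicks_avail <- round(states$Ntot[t] * config$rates$f[min(t, Tn - 1L)])
    if (n_ch > chicks_avail) {
      warnf("year %d: only %d chicks fledged; truncating marking cohort from %d",
            des$years[t], chicks_avail, n_ch)
      n_ch <- chicks_avail
    }
    adults_avail <- 2L * states$Ntot[t]
    if (n_ad > adults_avail) {
      warnf("year %d: truncating adult marking cohort from %d to %d",
            des$years[t], n_ad, adults_avail)
      n_ad <- adults_avail
    }
    for (cohort in list(c(n_ch, 1L), c(n_ad, 4L))) {
      n <- cohort[1]; age0 <- cohort[2]
      if (n == 0L) next
      cmat <- t(vapply(seq_len(n), function(i)
        simulate_one_history(t, age0, Tn, config$rates, config$detect),
        numeric(Tn - t + 1L)))
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        individual_id = rep(id + seq_len(n), each = Tn - t + 1L),
        mark_year = des$years[t],
        age_at_mark = age0,
        year = rep(des$years[t:Tn], times = n),
        encounter_count = as.integer(t(cmat)))
      id <- id + n
    }
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  out$individual_id <- sprintf("ind%05d", out$individual_id)
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic scenario on disk
#'
#' Draws one realization of all three data streams and writes a
#' self-describing dataset directory: `counts.csv`, `cmr.csv`,
#' `productivity.csv`, plus `truth.txt` (structured key-value record of
#' every true parameter, the latent trajectory, and the seed) for
#' parameter-recovery tests.  Refuses to overwrite an existing directory
#' unless `overwrite = TRUE`.
#'
#' @param config a `scenario_config`
#' @param dir output directory (created); `NULL` returns the bundle
#'   without writing
#' @param seed integer RNG seed, recorded in the truth file
#' @param overwrite allow writing into an existing directory
#' @return (invisibly, when writing) the bundle: list with `counts`,
#'   `cmr`, `productivity`, `states`, `config`, `seed`
#' @export
generate_scenario <- function(config, dir = NULL, seed = 1L,
                              overwrite = FALSE) {
  set.seed(seed)
  states <- simulate_population(config)
  counts <- simulate_counts(states, config$design)
  prod <- simulate_productivity(config$f_monitored, config$burrows_per_year,
                                config$design$years)
  cmr <- simulate_encounters(config, states)
  bundle <- list(counts = counts, cmr = cmr, productivity = prod,
                 states = states, config = config, seed = seed)
  if (is.null(dir)) return(bundle)
  if (dir.exists(dir) && !overwrite)
    stopf("directory '%s' exists; pass overwrite = TRUE to replace it", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(counts, file.path(dir, "counts.csv"))
  write_cmr(cmr, file.path(dir, "cmr.csv"))
  write_productivity(prod, file.path(dir, "productivity.csv"))
  write_truth(bundle, file.path(dir, "truth.txt"))
  invisible(bundle)
}
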