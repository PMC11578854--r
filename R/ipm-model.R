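# Joint log-posterior of the integrated population model: state-space
# count submodel, encounter-count CMR submodel, binomial productivity
# submodel, random temporal effects, and priors.  These functions give
# an explicit, testable form of the density the MCMC engine samples.

#' Log-probability of a latent population trajectory
#'
#' Sum over transitions of the binomial masses for recruitment and
#' survival and the Poisson mass for immigration.  Impossible
#' transitions (e.g. more second-years than last year's first-years)
#' give `-Inf`.  `method = "normal"` replaces each kernel by its
#' moment-matched normal approximation (useful as a smooth surrogate at
#' large population sizes).
#'
#' @param N 5 x T integer matrix of stage abundances (rows `STAGE_NAMES`)
#' @param rates a `vital_rates` with T - 1 transition years
#' @param method "discrete" (exact) or "normal" (moment-matched)
#' @return log-probability of transitions 1..T-1 given the initial state
#' @export
state_process_logprob <- function(N, rates, method = c("discrete", "normal")) {
  method <- match.arg(method)
  if (nrow(N) != 5) stopf("N must have 5 rows (stages)")
  Tn <- ncol(N)
  if (length(rates$alpha1) != Tn - 1L)
    stopf("rates must have %d transition years", Tn - 1L)
  ntot <- N[4, ] + N[5, ]
  lp <- 0
  dk <- function(x, size, prob) {
    if (method == "discrete") dbinom(x, size, prob, log = TRUE)
    else stats::dnorm(x, size * prob,
                      sqrt(pmax(size * prob * (1 - prob), 1e-12)), log = TRUE)
  }
  dp <- function(x, lam) {
    if (method == "discrete") dpois(x, lam, log = TRUE)
    else stats::dnorm(x, lam, sqrt(pmax(lam, 1e-12)), log = TRUE)
  }
  for (t in seq_len(Tn - 1L)) {
    lp <- lp + dk(N[1, t + 1], ntot[t], rates$f[t] / 2 * rates$alpha1[t]) +
      dk(N[2, t + 1], N[1, t], rates$alpha2[t]) +
      dk(N[3, t + 1], N[2, t], rates$alpha2[t]) +
      dk(N[4, t + 1], N[3, t] + ntot[t], rates$alpha2[t]) +
      dp(N[5, t + 1], rates$omega * sum(N[1:4, t]))
  }
  lp
}

#' Log-likelihood of survey counts given the latent trajectory
#'
#' Poisson observation in survey years only; years without a survey
#' contribute nothing (missing at random).
#'
#' @param counts data.frame (`year`, `pairs`)
#' @param N 5 x T stage matrix with year dimnames, or a list holding it
#' @param design the `study_design`
#' @return log-probability
#' @export
count_loglik <- function(counts, N, design) {
  if (is.list(N) && !is.matrix(N)) N <- N$N
  if (nrow(counts) == 0) return(0)
  idx <- match(counts$year, design$years)
  if (anyNA(idx)) stopf("survey count in a year outside the study design")
  ntot <- N[4, idx] + N[5, idx]
  sum(dpois(counts$pairs, ntot, log = TRUE))
}

#' Log-likelihood of productivity records
#'
#' `J_t ~ Binomial(B_t, f_t)` summed over monitored years.
#'
#' @param productivity data.frame (`year`, `burrows_monitored`,
#'   `chicks_fledged`)
#' @param f_series per-year productivity aligned with `years`
#' @param years calendar years that `f_series` indexes
#' @return log-probability
#' @export
productivity_loglik <- function(productivity, f_series,
                                years = seq_along(f_series)) {
  if (nrow(productivity) == 0) return(0)
  idx <- match(productivity$year, years)
  if (anyNA(idx)) stopf("productivity record in a year without an f value")
  sum(dbinom(productivity$chicks_fledged, productivity$burrows_monitored,
             f_series[idx], log = TRUE))
}

#' Default prior specification
#'
#' Weakly informative defaults for every top-level parameter; all are
#' overridable through `prior` arguments of the fitting functions.
#' Survival year effects are Normal(0, 1) on the logit scale (variance
#' fixed at 1); productivity year effects are Normal(0, sigma_f^2) with
#' sigma_f half-normal(0, 1); probability-scale means are Uniform(0,1);
#' omega is Uniform(0, 0.5); theta has a Gamma(1, 0.05) prior (mean
#' 20); log mean encounter rates are Normal(0, sd 3) with half-normal
#' year-effect scale.
#'
#' @return named list of prior hyperparameters
#' @export
default_priors <- function() {
  list(survival_effect_sd = 1,
       sigma_f_scale = 1,
       omega_upper = 0.5,
       theta_shape = 1, theta_rate = 0.05,
       log_eps_sd = 3,
       sigma_eps_scale = 1,
       imm_init_lambda = 50)
}

#' Log-density of the prior at a parameter configuration
#'
#' Evaluates the prior terms for the logit-scale means, year effects,
#' omega, detection parameters and variance components.  Out-of-support
#' values give `-Inf`.
#'
#' @param pars named list: `mu_alpha1`, `mu_alpha2`, `mu_f`
#'   (probability scale), `eta_alpha1`, `eta_alpha2`, `eta_f` (year
#'   effects), `sigma_f`, `omega`, `gamma1`, `gamma2`, `log_mu_eps`
#'   (length 2), `eta_eps`, `sigma_eps`, `theta`
#' @param priors hyperparameters, see [default_priors()]
#' @return log-density
#' @export
log_prior <- function(pars, priors = default_priors()) {
  lp <- 0
  for (m in c("mu_alpha1", "mu_alpha2", "mu_f")) {
    v <- pars[[m]]
    if (!is.null(v)) { if (v <= 0 || v >= 1) return(-Inf) }
  }
  for (g in c("gamma1", "gamma2")) {
    v <- pars[[g]]
    if (!is.null(v)) { if (any(v < 0 | v > 1)) return(-Inf) }
  }
  if (!is.null(pars$omega)) {
    if (pars$omega < 0 || pars$omega > priors$omega_upper) return(-Inf)
    lp <- lp - log(priors$omega_upper)
  }
  for (e in c("eta_alpha1", "eta_alpha2")) {
    v <- pars[[e]]
    if (!is.null(v))
      lp <- lp + sum(stats::dnorm(v, 0, priors$survival_effect_sd, log = TRUE))
  }
  if (!is.null(pars$sigma_f)) {
    if (pars$sigma_f <= 0) return(-Inf)
    lp <- lp + stats::dnorm(pars$sigma_f, 0, priors$sigma_f_scale, log = TRUE) +
      log(2)
    if (!is.null(pars$eta_f))
      lp <- lp + sum(stats::dnorm(pars$eta_f, 0, pars$sigma_f, log = TRUE))
  }
  if (!is.null(pars$theta)) {
    if (pars$theta <= 0) return(-Inf)
    lp <- lp + stats::dgamma(pars$theta, priors$theta_shape,
                             priors$theta_rate, log = TRUE)
  }
  if (!is.null(pars$log_mu_eps))
    lp <- lp + sum(stats::dnorm(pars$log_mu_eps, 0, priors$log_eps_sd,
                                log = TRUE))
  if (!is.null(pars$sigma_eps)) {
    if (pars$sigma_eps <= 0) return(-Inf)
    lp <- lp + stats::dnorm(pars$sigma_eps, 0, priors$sigma_eps_scale,
                            log = TRUE) + log(2)
    if (!is.null(pars$eta_eps))
      lp <- lp + sum(stats::dnorm(pars$eta_eps, 0, pars$sigma_eps, log = TRUE))
  }
  lp
}

# expand a parameter configuration into vital_rates / detection_params
pars_to_rates <- function(pars, n_trans) {
  a1 <- ilogit(logit(pars$mu_alpha1) + rep_len(pars$eta_alpha1, n_trans))
  a2 <- ilogit(logit(pars$mu_alpha2) + rep_len(pars$eta_alpha2, n_trans))
  f <- ilogit(logit(pars$mu_f) + rep_len(pars$eta_f, n_trans))
  vital_rates(a1, a2, f, pars$omega, n_trans)
}

pars_to_detect <- function(pars, n_years) {
  eta <- rep_len(if (is.null(pars$eta_eps)) 0 else pars$eta_eps, n_years)
  eps <- rbind(exp(pars$log_mu_eps[1] + eta), exp(pars$log_mu_eps[2] + eta))
  detection_params(pars$gamma1, pars$gamma2, eps, pars$theta)
}

#' Joint log-posterior of the integrated model
#'
#' Sum of the state-process term, the three data-stream likelihoods and
#' the prior, under the standard IPM assumption of independent data
#' streams.  Any stream may be `NULL` and then contributes nothing, so
#' single-dataset models are exact special cases.  `-Inf` propagates
#' cleanly from impossible states.
#'
#' @param pars named parameter list (see [log_prior()]); year effects
#'   must have length T - 1 (survival) and T - 1 or T (productivity)
#' @param N 5 x T latent stage matrix
#' @param counts,cmr_histories,productivity data streams (`NULL` to omit)
#' @param design the `study_design`
#' @param priors hyperparameters
#' @param n_quadrature quadrature order for the CMR marginal likelihood
#' @return log-density (unnormalized)
#' @export
joint_log_posterior <- function(pars, N, counts = NULL, cmr_histories = NULL,
                                productivity = NULL, design,
                                priors = default_priors(),
                                n_quadrature = 8L) {
  lp <- log_prior(pars, priors)
  if (!is.finite(lp)) return(-Inf)
  Tn <- design$n_years
  rates <- pars_to_rates(pars, Tn - 1L)
  lp <- lp + state_process_logprob(N, rates)
  if (!is.finite(lp)) return(-Inf)
  if (!is.null(counts)) lp <- lp + count_loglik(counts, N, design)
  if (!is.null(productivity)) {
    f_yr <- ilogit(logit(pars$mu_f) +
                     rep_len(pars$eta_f, Tn)[seq_len(Tn)])
    lp <- lp + productivity_loglik(productivity, f_yr, design$years)
  }
  if (!is.null(cmr_histories) && length(cmr_histories) > 0) {
    detect <- pars_to_detect(pars, Tn)
    lp <- lp + dataset_loglik(cmr_histories, rates, detect, n_quadrature)
  }
  lp
}
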