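# Small scenario builders shared across test files.

# posterior-mean-scale reference parameters for a stable auk colony
ref_rates <- function(n_trans = 1L) {
  vital_rates(alpha1 = 0.30, alpha2 = 0.85, f = 0.55, omega = 0.08,
              n_years = n_trans)
}

ref_detect <- function(theta = 39, n_years = 1L) {
  detection_params(gamma1 = c(0.05, 0.20, 0.45, 0.65),
                   gamma2 = c(0.30, 0.50, 0.75, 0.90),
                   epsilon = c(0.6, 2.5), theta = theta)
}

# a tiny scenario for fast end-to-end checks
tiny_scenario <- function(n_years = 6L, chicks = 15L, adults = 8L,
                          burrows = 40L, pairs = 300L) {
  default_scenario(n_years = n_years, chicks_marked_per_year = chicks,
                   adults_marked_per_year = adults,
                   burrows_per_year = burrows,
                   initial_total_pairs = pairs)
}

# random valid parameters for property-style loops
random_rates <- function(n_trans) {
  vital_rates(runif(n_trans, 0.1, 0.9), runif(n_trans, 0.1, 0.95),
              runif(n_trans, 0.2, 0.9), runif(1, 0, 0.3), n_trans)
}

random_detect <- function(n_years, theta = NULL) {
  if (is.null(theta)) theta <- sample(c(0.5, 16.2, 39, 1e6), 1)
  detection_params(runif(4, 0.05, 0.9), runif(4, 0.1, 0.95),
                   matrix(runif(2 * n_years, 0, 3), 2), theta)
}

random_history <- function(n_years, mean_count = 0.8) {
  m <- sample(seq_len(n_years - 1L), 1)
  list(mark = m,
       age_at_mark = sample(c(1L, 4L), 1),
       counts = c(sample(1:3, 1), rpois(n_years - m, mean_count)))
}

# a minimal ipm_fit-shaped object around a draws matrix, for testing
# posterior utilities without running MCMC
fake_fit <- function(draws, years) {
  half <- seq_len(nrow(draws) %/% 2)
  sl <- coda::mcmc.list(coda::mcmc(draws[half, , drop = FALSE]),
                        coda::mcmc(draws[-half, , drop = FALSE]))
  structure(list(samples = sl,
                 design = study_design(years),
                 streams = character(0), seed = 0L),
            class = "ipm_fit")
}
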