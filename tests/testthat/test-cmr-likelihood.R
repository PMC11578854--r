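# The marginal encounter-history likelihood against closed forms and
# the exhaustive latent-path oracle.

test_that("certain-event histories have log-probability zero", {
  # adult marked at t=1 of T=2 with zero encounter rate: the only
  # possible history is (1, 0)
  rates <- vital_rates(0.3, 0.9, 0.5, 0.05, 1)
  det <- detection_params(rep(0.5, 4), rep(0.9, 4), c(0, 0), theta = 5)
  h <- list(mark = 1L, age_at_mark = 4L, counts = c(1L, 0L))
  expect_lt(abs(individual_loglik(h, rates, det)), 1e-9)
  expect_lt(abs(brute_force_loglik(h, rates, det)), 1e-12)
})

test_that("single-occasion zero count matches the closed-form zero mass", {
  # an always-available survivor not seen once: P(c = 0) = (theta/(theta+eps))^theta
  for (theta in c(0.5, 16.2, 39)) {
    eps <- 1.3
    rates <- vital_rates(0.3, 1 - 1e-12, 0.5, 0.05, 1)
    det <- detection_params(rep(0.5, 4), rep(1 - 1e-12, 4), c(eps, eps),
                            theta = theta)
    h <- list(mark = 1L, age_at_mark = 4L, counts = c(2L, 0L))
    ll <- individual_loglik(h, rates, det, include_marking = FALSE)
    expect_equal(ll, theta * (log(theta) - log(theta + eps)),
                 tolerance = 1e-8)
  }
})

test_that("quadrature equals the exhaustive oracle on random histories", {
  set.seed(301)
  worst <- 0
  for (i in 1:60) {
    Tn <- sample(3:6, 1)
    rates <- random_rates(Tn - 1L)
    det <- random_detect(Tn)
    h <- random_history(Tn)
    l1 <- individual_loglik(h, rates, det)
    l2 <- brute_force_loglik(h, rates, det)
    if (is.finite(l1) || is.finite(l2)) {
      expect_lt(abs(l1 - l2), 1e-6)
      worst <- max(worst, abs(l1 - l2))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("doubling the quadrature order does not move the result", {
  set.seed(302)
  for (i in 1:20) {
    Tn <- sample(4:8, 1)
    rates <- random_rates(Tn - 1L)
    det <- random_detect(Tn)
    h <- random_history(Tn)
    l8 <- individual_loglik(h, rates, det, n_quadrature = 8L)
    l16 <- individual_loglik(h, rates, det, n_quadrature = 16L)
    expect_lt(abs(l8 - l16), 1e-8)
  }
})

test_that("degenerate-heterogeneity limit agrees with a Poisson hidden Markov chain", {
  # independent enumeration with h fixed at 1 (no gamma integral)
  poisson_hmm_loglik <- function(history, rates, det) {
    m <- history$mark; Tn <- m + length(history$counts) - 1L
    ages <- pmin(history$age_at_mark + 0:(Tn - m), 4L)
    Jp <- Tn - m
    tot <- -Inf
    for (s in 0:Jp) {
      phis <- vapply(seq_len(s), function(j) {
        if (ages[j] == 1L) rates$alpha1[m + j - 1L] else rates$alpha2[m + j - 1L]
      }, numeric(1))
      lp_surv <- sum(log(phis))
      if (s < Jp) {
        phn <- if (ages[s + 1L] == 1L) rates$alpha1[m + s] else rates$alpha2[m + s]
        lp_surv <- lp_surv + log(1 - phn)
      }
      cpost <- history$counts[-1]
      if (s < Jp && any(cpost[(s + 1L):Jp] > 0)) next
      for (pth in seq_len(2^s) - 1L) {
        kpath <- if (s > 0) as.integer(intToBits(pth)[seq_len(s)]) else integer(0)
        kprev <- if (history$age_at_mark == 1L) 0L else 1L
        lp <- lp_surv
        for (j in seq_len(s)) {
          g <- if (kprev == 1L) det$gamma2[ages[j]] else det$gamma1[ages[j]]
          lp <- lp + log(if (kpath[j] == 1L) g else 1 - g)
          eps_j <- det$epsilon[if (ages[j + 1L] >= 4L) 2L else 1L,
                               ((m + j - 1L) %% ncol(det$epsilon)) + 1L]
          lam <- if (kpath[j] == 1L) eps_j else 0
          lp <- lp + stats::dpois(cpost[j], lam, log = TRUE)
          kprev <- kpath[j]
        }
        tot <- matrixStats_logsumexp(c(tot, lp))
      }
    }
    tot
  }
  matrixStats_logsumexp <- function(x) {
    m <- max(x); if (!is.finite(m)) return(m); m + log(sum(exp(x - m)))
  }
  set.seed(303)
  for (i in 1:20) {
    Tn <- sample(3:5, 1)
    rates <- random_rates(Tn - 1L)
    det <- random_detect(Tn, theta = 1e8)
    h <- random_history(Tn)
    l1 <- brute_force_loglik(h, rates, det, include_marking = FALSE)
    l2 <- poisson_hmm_loglik(h, rates, det)
    if (is.finite(l1) || is.finite(l2)) expect_lt(abs(l1 - l2), 1e-6)
  }
})

test_that("likelihood is monotone in the intuitive directions", {
  # all-zero post-marking histories become less likely as the
  # encounter rate grows
  Tn <- 5L
  rates <- vital_rates(0.3, 0.85, 0.5, 0.05, Tn - 1L)
  h <- list(mark = 1L, age_at_mark = 4L, counts = c(1L, rep(0L, Tn - 1L)))
  lls <- vapply(c(0.2, 0.5, 1, 2, 4), function(eps) {
    det <- detection_params(rep(0.3, 4), rep(0.7, 4), c(eps, eps), 10)
    individual_loglik(h, rates, det, include_marking = FALSE)
  }, numeric(1))
  expect_true(all(diff(lls) < 0))
  # histories with late encounters become more likely as survival grows
  h2 <- list(mark = 1L, age_at_mark = 4L, counts = c(1L, 0L, 0L, 0L, 2L))
  lls2 <- vapply(c(0.5, 0.7, 0.9), function(a2) {
    r <- vital_rates(0.3, a2, 0.5, 0.05, Tn - 1L)
    det <- detection_params(rep(0.3, 4), rep(0.7, 4), c(1, 1), 10)
    individual_loglik(h2, r, det)
  }, numeric(1))
  expect_true(all(diff(lls2) > 0))
})

test_that("the post-marking likelihood is a proper probability distribution", {
  # sum over all count vectors (with a generous cap) close to 1
  set.seed(304)
  for (i in 1:4) {
    Tn <- 4L
    rates <- random_rates(Tn - 1L)
    det <- random_detect(Tn, theta = sample(c(2, 16.2), 1))
    cmax <- 25L
    age0 <- sample(c(1L, 4L), 1)
    grid <- expand.grid(c1 = 0:cmax, c2 = 0:cmax, c3 = 0:cmax)
    ll <- vapply(seq_len(nrow(grid)), function(r) {
      h <- list(mark = 1L, age_at_mark = age0,
                counts = c(1L, as.integer(grid[r, ])))
      individual_loglik(h, rates, det, include_marking = FALSE)
    }, numeric(1))
    expect_equal(sum(exp(ll)), 1, tolerance = 1e-4)
  }
})

test_that("the marking-occasion term is a normalized zero-truncated mass", {
  for (theta in c(0.5, 39)) {
    eps <- 1.7
    p <- vapply(1:400, function(c0)
      exp(seabirdIPM:::marking_logterm(c0, eps, theta)), numeric(1))
    expect_equal(sum(p), 1, tolerance = 1e-8)
  }
})

test_that("dataset likelihood is additive and order-invariant", {
  Tn <- 5L
  set.seed(305)
  rates <- random_rates(Tn - 1L)
  det <- random_detect(Tn, theta = 16.2)
  h <- random_history(Tn)
  expect_equal(dataset_loglik(list(h, h), rates, det),
               2 * individual_loglik(h, rates, det))
  hs <- replicate(20, random_history(Tn), simplify = FALSE)
  perm <- sample(20)
  expect_equal(dataset_loglik(hs, rates, det),
               dataset_loglik(hs[perm], rates, det))
  expect_warning(z <- dataset_loglik(list(), rates, det), "empty")
  expect_equal(z, 0)
})

test_that("simulated histories get finite likelihood that matches the oracle", {
  # generator and likelihood share one convention: oracle equality on
  # a small simulated dataset
  cfg <- tiny_scenario(n_years = 5L, chicks = 6L, adults = 4L)
  b <- generate_scenario(cfg, NULL, seed = 21)
  hs <- encounter_histories(b$cmr, cfg$design)
  rates <- cfg$rates; det <- cfg$detect
  lls <- vapply(hs, individual_loglik, numeric(1), rates = rates, detect = det)
  expect_true(all(is.finite(lls)))
  oracle <- vapply(hs, brute_force_loglik, numeric(1), rates = rates,
                   detect = det)
  expect_lt(max(abs(lls - oracle)), 1e-6)
})
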