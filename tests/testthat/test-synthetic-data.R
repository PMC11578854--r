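# Moment and invariant checks for each stochastic kernel of the
# generator, plus reproducibility of the on-disk scenario bundle.

test_that("population recursion respects its binomial/Poisson moments", {
  # mean survival ratio N2[t+1]/N1[t] across replicates close to alpha2
  cfg <- default_scenario(n_years = 3L, initial_total_pairs = 2000L)
  set.seed(11)
  n1 <- 0; n2 <- 0
  reps <- 1000L
  for (i in seq_len(reps)) {
    st <- simulate_population(cfg)
    n1 <- n1 + st$N["N1", 2]
    n2 <- n2 + st$N["N2", 3]
  }
  # conditional on N1, N2' ~ Bin(N1, 0.85): aggregate ratio estimator
  se <- sqrt(0.85 * 0.15 / n1)
  expect_lt(abs(n2 / n1 - 0.85), 3 * se)
})

test_that("one-step transition means match the projection matrix", {
  cfg <- default_scenario(n_years = 3L, initial_total_pairs = 3000L)
  A <- build_projection_matrix(cfg$rates)
  set.seed(12)
  reps <- 400L
  obs <- exp <- matrix(0, 5, reps)
  for (i in seq_len(reps)) {
    st <- simulate_population(cfg)
    obs[, i] <- st$N[, 2]
    exp[, i] <- A %*% st$N[, 1]
  }
  d <- rowMeans(obs - exp)
  se <- apply(obs - exp, 1, stats::sd) / sqrt(reps)
  expect_true(all(abs(d) <= 3 * pmax(se, 1e-9) + 1e-9))
})

test_that("near-zero survival drives the population extinct", {
  cfg <- default_scenario(alpha1 = 1e-9, alpha2 = 1e-9, omega = 0,
                          n_years = 8L, initial_total_pairs = 200L)
  set.seed(13)
  st <- simulate_population(cfg)
  expect_true(st$extinct)
  expect_true(all(st$N[, 4:8] == 0))
})

test_that("survey counts are Poisson draws in survey years only", {
  des <- study_design(2001:2008, survey_years = c(2001, 2005))
  st <- list(Ntot = rep(8000L, 8))
  set.seed(14)
  y <- replicate(10000, simulate_counts(st, des)$pairs[1])
  expect_lt(abs(mean(y) - 8000), 3 * sqrt(8000 / 10000))
  one <- simulate_counts(st, des)
  expect_equal(one$year, c(2001, 2005))
  # zero population gives zero counts surely
  st0 <- list(Ntot = rep(0L, 8))
  expect_true(all(simulate_counts(st0, des)$pairs == 0))
})

test_that("fledging counts are binomial in the monitored burrows", {
  set.seed(15)
  expect_true(all(simulate_productivity(rep(1, 5), 80)$chicks_fledged == 80))
  expect_true(all(simulate_productivity(rep(0, 5), 80)$chicks_fledged == 0))
  J <- replicate(10000, simulate_productivity(0.55, 100)$chicks_fledged)
  expect_lt(abs(mean(J) - 55), 3 * sqrt(100 * 0.55 * 0.45 / 10000))
})

test_that("zero encounter rate yields zero post-marking counts", {
  cfg <- default_scenario(n_years = 5L, epsilon = c(0, 0),
                          chicks_marked_per_year = 10L,
                          adults_marked_per_year = 10L)
  set.seed(16)
  st <- simulate_population(cfg)
  cmr <- simulate_encounters(cfg, st)
  post <- cmr[cmr$year > cmr$mark_year, ]
  expect_true(all(post$encounter_count == 0))
  # marking occasion still recorded with count >= 1
  expect_true(all(cmr$encounter_count[cmr$year == cmr$mark_year] >= 1))
})

test_that("encounter counts of available birds follow the gamma-Poisson marginal", {
  # adults in a 2-year design with survival and availability pushed to
  # the boundary: the single post-marking count is marginally
  # negative binomial with size theta and mean epsilon
  theta <- 16.2; eps <- 1
  cfg <- default_scenario(
    n_years = 3L, alpha1 = 0.3, alpha2 = 1 - 1e-12, f = 0.55, omega = 0,
    theta = theta, epsilon = c(eps, eps),
    gamma1 = rep(1 - 1e-12, 4), gamma2 = rep(1 - 1e-12, 4),
    chicks_marked_per_year = 0L, adults_marked_per_year = c(5000L, 0L),
    initial_total_pairs = 4000L)
  set.seed(17)
  st <- simulate_population(cfg)
  cmr <- simulate_encounters(cfg, st)
  cc <- cmr$encounter_count[cmr$year == cmr$mark_year + 1]
  cmax <- 7L
  obs <- tabulate(pmin(cc, cmax) + 1L, nbins = cmax + 1L)
  pexp <- stats::dnbinom(0:(cmax - 1), size = theta, mu = eps)
  pexp <- c(pexp, 1 - sum(pexp))
  chi2 <- sum((obs - length(cc) * pexp)^2 / (length(cc) * pexp))
  expect_lt(chi2, qchisq(0.999, df = cmax))
  # very large theta approaches the pure Poisson variance
  cfg2 <- default_scenario(
    n_years = 3L, alpha2 = 1 - 1e-12, omega = 0, theta = 1e8,
    epsilon = c(eps, eps), gamma1 = rep(1 - 1e-12, 4),
    gamma2 = rep(1 - 1e-12, 4), chicks_marked_per_year = 0L,
    adults_marked_per_year = c(5000L, 0L), initial_total_pairs = 4000L)
  set.seed(18)
  st2 <- simulate_population(cfg2)
  cmr2 <- simulate_encounters(cfg2, st2)
  cc2 <- cmr2$encounter_count[cmr2$year == cmr2$mark_year + 1]
  expect_lt(abs(var(cc2) - eps), 4 * sqrt(2 / length(cc2)) * eps + 0.02)
  expect_gt(var(cc), var(cc2))  # heterogeneity inflates the variance
})

test_that("cohorts larger than the simulated colony are truncated with a warning", {
  cfg <- default_scenario(n_years = 4L, initial_total_pairs = 50L,
                          chicks_marked_per_year = 5000L,
                          adults_marked_per_year = 0L)
  set.seed(19)
  st <- simulate_population(cfg)
  warns <- capture_warnings(cmr <- simulate_encounters(cfg, st))
  expect_true(all(grepl("truncating", warns)) && length(warns) >= 1)
  expect_lt(length(unique(cmr$individual_id)), 5000L * 3L)
})

test_that("scenario bundles are reproducible and refuse accidental overwrite", {
  cfg <- tiny_scenario()
  d1 <- file.path(tempdir(), "scen_a")
  unlink(d1, recursive = TRUE)
  b1 <- generate_scenario(cfg, d1, seed = 5)
  b2 <- generate_scenario(cfg, NULL, seed = 5)
  expect_identical(b1$counts, b2$counts)
  expect_identical(b1$cmr, b2$cmr)
  expect_identical(b1$productivity, b2$productivity)
  expect_error(generate_scenario(cfg, d1, seed = 5), "overwrite")
  # byte-identical files under the same seed
  d2 <- file.path(tempdir(), "scen_b")
  unlink(d2, recursive = TRUE)
  generate_scenario(cfg, d2, seed = 5)
  for (f in c("counts.csv", "cmr.csv", "productivity.csv", "truth.txt")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # truth round-trips through the readers
  sc <- read_scenario(d1)
  expect_equal(sc$truth$alpha1, cfg$rates$alpha1)
  expect_equal(sc$truth$theta, cfg$detect$theta)
  expect_equal(sc$truth$Ntot, b1$states$Ntot)
  expect_identical(sc$counts, b1$counts)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("generated streams satisfy their type invariants on many seeds", {
  cfg <- tiny_scenario()
  for (seed in 1:5) {
    b <- generate_scenario(cfg, NULL, seed = seed)
    expect_true(all(b$counts$year %in% cfg$design$survey_years))
    expect_true(all(b$counts$pairs >= 0))
    expect_true(all(b$productivity$chicks_fledged <=
                      b$productivity$burrows_monitored))
    expect_true(all(b$cmr$encounter_count[b$cmr$year == b$cmr$mark_year] >= 1))
    expect_equal(b$states$Ntot,
                 unname(b$states$N["N4", ] + b$states$N["Nimm", ]))
  }
})
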