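# Model-code assembly, data preparation, posterior utilities, and a
# small determinism/recovery smoke fit.

test_that("model code contains exactly the blocks for the supplied streams", {
  code_all <- ipm_jags_code(c("counts", "cmr", "productivity"), 10L)
  expect_match(code_all, "state-space count submodel")
  expect_match(code_all, "encounter-count CMR submodel")
  expect_match(code_all, "productivity submodel")
  code_cmr <- ipm_jags_code("cmr", 10L)
  expect_no_match(code_cmr, "state-space")
  expect_no_match(code_cmr, "dbin\\(f")
  code_p <- ipm_jags_code("productivity", 10L)
  expect_no_match(code_p, "alpha1")
})

test_that("CMR arrays encode marking, known-alive spans and chick absence", {
  des <- study_design(2001:2006)
  cmr <- data.frame(
    individual_id = c(rep("a", 6), rep("b", 4)),
    mark_year = c(rep(2001, 6), rep(2003, 4)),
    age_at_mark = c(rep(1, 6), rep(5, 4)),
    year = c(2001:2006, 2003:2006),
    encounter_count = c(1, 0, 0, 2, 0, 0, 3, 0, 1, 0))
  arr <- seabirdIPM:::prep_cmr_arrays(cmr, des)
  expect_equal(arr$fi, c(1L, 3L))
  expect_equal(arr$age0, c(1L, 4L))
  # chick enters the availability process absent; adult present
  expect_equal(arr$kdat[1, 1], 0L)
  expect_equal(arr$kdat[2, 3], 1L)
  # known alive through the last encounter
  expect_equal(arr$zdat[1, 1:4], rep(1L, 4))
  expect_true(is.na(arr$zdat[1, 5]))
  # first-year survival applies only to the first chick transition
  expect_equal(arr$usea1[1, 2], 1L)
  expect_equal(sum(arr$usea1), 1L)
  # ages capped at 4+
  expect_equal(arr$age[1, ], c(1L, 2L, 3L, 4L, 4L, 4L))
})

test_that("individuals marked in the final year are dropped with a warning", {
  des <- study_design(2001:2004)
  cmr <- data.frame(individual_id = c("a", "b", "b"),
                    mark_year = c(2004, 2003, 2003),
                    age_at_mark = 4, year = c(2004, 2003, 2004),
                    encounter_count = c(2, 1, 0))
  expect_warning(arr <- seabirdIPM:::prep_cmr_arrays(cmr, des), "final year")
  expect_equal(arr$n, 1L)
})

test_that("posterior summaries match a percentile oracle", {
  set.seed(601)
  nd <- 10000L
  draws <- cbind(stats::rnorm(nd), stats::rnorm(nd, 5, 2))
  colnames(draws) <- c("a", "b")
  fit <- fake_fit(draws, 2000:2002)
  sm <- summarize_fit(fit)
  expect_equal(sm$mean[sm$parameter == "a"], 0, tolerance = 0.05)
  expect_equal(sm$lower[sm$parameter == "a"], -1.96, tolerance = 0.08)
  expect_equal(sm$upper[sm$parameter == "a"], 1.96, tolerance = 0.08)
  # symmetric draws: mean and median agree
  expect_equal(sm$mean[sm$parameter == "b"], sm$median[sm$parameter == "b"],
               tolerance = 0.08)
})

test_that("year masks drop exactly the named years", {
  m <- 5L
  draws <- matrix(stats::rnorm(200 * m), 200, m,
                  dimnames = list(NULL, paste0("alpha1[", 1:m, "]")))
  fit <- fake_fit(draws, 2001:2006)
  sm <- summarize_fit(fit, mask = list(alpha1 = c(2004, 2005)))
  expect_equal(sort(sm$year), c(2001, 2002, 2003))
  p <- series_mean_posterior(fit, "alpha1", drop_years = c(2004, 2005))
  expect_equal(p$draws, rowMeans(draws[, 1:3]))
})

test_that("credible-interval overlap report separates identical and disjoint fits", {
  set.seed(602)
  m <- 4L
  draws <- matrix(stats::rnorm(400 * m, 0.8, 0.02), 400, m,
                  dimnames = list(NULL, paste0("alpha2[", 1:m, "]")))
  f1 <- fake_fit(draws, 2001:2005)
  cmp <- compare_integrated_vs_single(f1, f1, params = "alpha2")
  expect_true(all(cmp$overlap == 1))
  expect_true(all(cmp$mean_diff == 0))
  expect_false(any(cmp$flagged))
  f2 <- fake_fit(draws + 1, 2001:2005)
  cmp2 <- compare_integrated_vs_single(f1, f2, params = "alpha2")
  expect_true(all(cmp2$overlap == 0))
  expect_true(all(cmp2$flagged))
})

test_that("a counts-and-productivity fit keeps the growth identity per draw", {
  cfg <- tiny_scenario(n_years = 6L)
  b <- generate_scenario(cfg, NULL, seed = 47)
  fit <- fit_ipm(b$counts, cmr = NULL, productivity = b$productivity,
                 design = cfg$design,
                 config = fit_config(n_chains = 2L, n_adapt = 300L,
                                     n_burnin = 500L, n_iter = 500L,
                                     seed = 12L))
  lam <- extract_series(fit, "lambda")
  ntot <- extract_series(fit, "Ntot")
  ratio <- ntot[, -1] / pmax(ntot[, -ncol(ntot)], 1)
  expect_equal(unname(lam), unname(ratio), tolerance = 1e-12)
  # draws and metadata round-trip to a run directory
  td <- file.path(tempdir(), "runout")
  unlink(td, recursive = TRUE)
  write_fit(fit, td)
  dr <- read.csv(file.path(td, "draws.csv"), check.names = FALSE)
  expect_true(all(c("chain", "iteration", "omega") %in% names(dr)))
  meta <- readLines(file.path(td, "run-metadata.txt"))
  expect_true(any(grepl("^seed: 12", meta)))
  unlink(td, recursive = TRUE)
})

test_that("a small CMR-only fit is deterministic under a fixed seed", {
  cfg <- tiny_scenario(n_years = 5L, chicks = 12L, adults = 8L)
  b <- generate_scenario(cfg, NULL, seed = 41)
  fc <- fit_config(n_chains = 2L, n_adapt = 150L, n_burnin = 150L,
                   n_iter = 150L, seed = 99L)
  f1 <- fit_cmr_only(b$cmr, cfg$design, fc)
  f2 <- fit_cmr_only(b$cmr, cfg$design, fc)
  expect_equal(draws_matrix(f1), draws_matrix(f2))
  cv <- convergence(f1)
  expect_true(all(c("parameter", "rhat", "ess") %in% names(cv)))
})

test_that("productivity-only fit with a flat prior matches beta-binomial conjugacy", {
  des <- study_design(2001:2003)
  prod <- data.frame(year = 2001, burrows_monitored = 100,
                     chicks_fledged = 55)
  fit <- fit_productivity_only(prod, des,
                               fit_config(n_chains = 2L, n_adapt = 200L,
                                          n_burnin = 200L, n_iter = 2000L,
                                          seed = 5L),
                               hierarchical = FALSE)
  m <- draws_matrix(fit)
  post_mean <- mean(m[, "f[1]"])
  # Beta(56, 46) posterior: mean 56/102
  expect_equal(post_mean, 56 / 102, tolerance = 0.01)
  # unmonitored years keep their flat prior
  expect_equal(mean(m[, "f[2]"]), 0.5, tolerance = 0.03)
})

test_that("an all-failure year concentrates productivity near zero", {
  des <- study_design(2001:2003)
  prod <- data.frame(year = 2001:2002, burrows_monitored = 80,
                     chicks_fledged = c(0, 40))
  fit <- fit_productivity_only(prod, des,
                               fit_config(n_chains = 1L, n_adapt = 200L,
                                          n_burnin = 200L, n_iter = 1000L,
                                          seed = 6L),
                               hierarchical = FALSE)
  m <- draws_matrix(fit)
  expect_lt(mean(m[, "f[1]"]), 0.05)
})
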