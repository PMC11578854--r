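# MCMC fitting of the joint model and the standalone submodels.  The
# sampler is JAGS (via rjags), which samples the discrete latent
# abundances and individual alive/availability states directly; the
# model code is assembled from per-submodel blocks so that the joint
# model and the single-dataset models are literally the same text.

jags_block_rates <- function(Tn) {
  sprintf("
  # demographic rate priors and logit-scale year effects
  mu.a1 ~ dunif(0, 1)
  mu.a2 ~ dunif(0, 1)
  lmu.a1 <- logit(mu.a1)
  lmu.a2 <- logit(mu.a2)
  for (t in 1:%d) {
    eta.a1[t] ~ dnorm(0, tau.surv)
    eta.a2[t] ~ dnorm(0, tau.surv)
    logit(alpha1[t]) <- lmu.a1 + eta.a1[t]
    logit(alpha2[t]) <- lmu.a2 + eta.a2[t]
  }
", Tn - 1L)
}

jags_block_f <- function(Tn, hierarchical = TRUE) {
  if (hierarchical) sprintf("
  mu.f ~ dunif(0, 1)
  lmu.f <- logit(mu.f)
  sigma.f ~ dnorm(0, sigma.f.prior.tau) T(0,)
  tau.f <- pow(sigma.f, -2)
  for (t in 1:%d) {
    eta.f[t] ~ dnorm(0, tau.f)
    logit(f[t]) <- lmu.f + eta.f[t]
  }
", Tn) else sprintf("
  for (t in 1:%d) { f[t] ~ dunif(0, 1) }
", Tn)
}

jags_block_counts <- function(Tn) {
  sprintf("
  # state-space count submodel
  omega ~ dunif(0, omega.upper)
  for (s in 1:4) { N[s, 1] ~ dpois(n.init[s]) }
  N[5, 1] ~ dpois(imm.init.lambda)
  Ntot[1] <- N[4, 1] + N[5, 1]
  for (t in 1:%d) {
    N[1, t + 1] ~ dbin(f[t] / 2 * alpha1[t], Ntot[t])
    N[2, t + 1] ~ dbin(alpha2[t], N[1, t])
    N[3, t + 1] ~ dbin(alpha2[t], N[2, t])
    N[4, t + 1] ~ dbin(alpha2[t], N[3, t] + Ntot[t])
    N[5, t + 1] ~ dpois(omega * (N[1, t] + N[2, t] + N[3, t] + N[4, t]) + 1.0E-10)
    Ntot[t + 1] <- N[4, t + 1] + N[5, t + 1]
    lambda[t] <- Ntot[t + 1] / max(Ntot[t], 1)
  }
  for (s in 1:n.survey) { y[s] ~ dpois(Ntot[survey.idx[s]]) }
", Tn - 1L)
}

jags_block_cmr <- function(Tn) {
  sprintf("
  # encounter-count CMR submodel
  for (a in 1:4) {
    gamma1[a] ~ dunif(0, 1)
    gamma2[a] ~ dunif(0, 1)
  }
  for (g in 1:2) { lmu.eps[g] ~ dnorm(0, lmu.eps.prior.tau) }
  sigma.eps ~ dnorm(0, sigma.eps.prior.tau) T(0,)
  tau.eps <- pow(sigma.eps, -2)
  for (t in 1:%d) {
    eta.eps[t] ~ dnorm(0, tau.eps)
    for (g in 1:2) { log(eps[g, t]) <- lmu.eps[g] + eta.eps[t] }
  }
  theta ~ dgamma(theta.prior.shape, theta.prior.rate)
  for (i in 1:n.ind) {
    h[i] ~ dgamma(theta, theta)
    cmat[i, fi[i]] ~ dpois(eps[grp[i, fi[i]], fi[i]] * h[i]) T(1,)
  }
  for (j in 1:n.post) {
    for (t in (fi[post[j]] + 1):%d) {
      z[post[j], t] ~ dbern(z[post[j], t - 1] *
        (usea1[post[j], t] * alpha1[t - 1] +
         (1 - usea1[post[j], t]) * alpha2[t - 1]))
      k[post[j], t] ~ dbern(z[post[j], t] *
        (k[post[j], t - 1] * gamma2[age[post[j], t - 1]] +
         (1 - k[post[j], t - 1]) * gamma1[age[post[j], t - 1]]))
      cmat[post[j], t] ~ dpois(k[post[j], t] *
        eps[grp[post[j], t], t] * h[post[j]] + 1.0E-10)
    }
  }
", Tn, Tn)
}

jags_block_prod <- function() {
  "
  # productivity submodel
  for (r in 1:n.prod) {
    J[r] ~ dbin(f[prod.idx[r]], B[r])
  }
"
}

#' Assemble JAGS model code for a given combination of data streams
#'
#' @param streams character subset of `c("counts", "cmr", "productivity")`
#' @param n_years study length T
#' @param hierarchical hierarchical year effects on productivity
#' @return a single string of JAGS model code
#' @export
ipm_jags_code <- function(streams, n_years,
                          hierarchical = TRUE) {
  need_rates <- any(c("counts", "cmr") %in% streams)
  need_f <- any(c("counts", "productivity") %in% streams)
  paste0(
    "model {\n",
    "  tau.surv <- pow(surv.effect.sd, -2)\n",
    if (need_rates) jags_block_rates(n_years),
    if (need_f) jags_block_f(n_years, hierarchical),
    if ("counts" %in% streams) jags_block_counts(n_years),
    if ("cmr" %in% streams) jags_block_cmr(n_years),
    if ("productivity" %in% streams) jags_block_prod(),
    "}\n")
}

#' Sampler configuration
#'
#' @param n_chains number of MCMC chains
#' @param n_adapt adaptation iterations
#' @param n_burnin burn-in iterations
#' @param n_iter retained iterations per chain
#' @param thin thinning interval
#' @param seed integer seed; chain seeds are derived from it
#' @param priors prior hyperparameters, see [default_priors()]
#' @param quiet suppress JAGS progress output
#' @return list of class `fit_config`
#' @export
fit_config <- function(n_chains = 3L, n_adapt = 500L, n_burnin = 1000L,
                       n_iter = 1500L, thin = 1L, seed = 1L,
                       priors = default_priors(), quiet = TRUE) {
  structure(list(n_chains = n_chains, n_adapt = n_adapt,
                 n_burnin = n_burnin, n_iter = n_iter, thin = thin,
                 seed = as.integer(seed), priors = priors, quiet = quiet),
            class = "fit_config")
}

# --- data preparation ---------------------------------------------------

prep_cmr_arrays <- function(cmr, design) {
  Tn <- design$n_years
  sp <- split(cmr, cmr$individual_id)
  n <- length(sp)
  cmat <- matrix(NA_integer_, n, Tn)
  fi <- integer(n)
  age0 <- integer(n)
  for (i in seq_along(sp)) {
    d <- sp[[i]][order(sp[[i]]$year), ]
    f0 <- match(d$mark_year[1], design$years)
    if (is.na(f0)) stopf("mark_year outside study years for individual %s",
                         d$individual_id[1])
    fi[i] <- f0
    age0[i] <- min(d$age_at_mark[1], 4L)
    cmat[i, match(d$year, design$years)] <- d$encounter_count
  }
  drop <- fi >= Tn
  if (any(drop)) {
    warnf("dropping %d individual(s) marked in the final year (no post-marking occasions)",
          sum(drop))
    cmat <- cmat[!drop, , drop = FALSE]
    fi <- fi[!drop]; age0 <- age0[!drop]
    n <- length(fi)
  }
  age <- matrix(NA_integer_, n, Tn)
  grp <- matrix(NA_integer_, n, Tn)
  usea1 <- matrix(0L, n, Tn)
  zdat <- matrix(NA_integer_, n, Tn)
  kdat <- matrix(NA_integer_, n, Tn)
  for (i in seq_len(n)) {
    tt <- fi[i]:Tn
    age[i, tt] <- pmin(age0[i] + (tt - fi[i]), 4L)
    grp[i, tt] <- ifelse(age[i, tt] >= 4L, 2L, 1L)
    if (age0[i] == 1L && fi[i] < Tn) usea1[i, fi[i] + 1L] <- 1L
    zdat[i, fi[i]] <- 1L
    kdat[i, fi[i]] <- if (age0[i] == 1L) 0L else 1L
    pos <- which(cmat[i, ] > 0)
    if (length(pos) > 0) {
      last <- max(pos)
      if (last > fi[i]) zdat[i, (fi[i] + 1L):last] <- 1L
      kdat[i, setdiff(pos, fi[i])] <- 1L
    }
  }
  list(cmat = cmat, fi = fi, age0 = age0, age = age, grp = grp,
       usea1 = usea1, zdat = zdat, kdat = kdat, n = n,
       post = which(fi < Tn))
}

# Latent-state initial values.  Individuals start alive through their
# last sighting; afterwards the alive state is forward-simulated at
# plausible survival so chains begin near the dominant mode.  (An
# all-alive initialization points the sampler at a spurious boundary
# mode in which survival tends to one and availability absorbs every
# absence.)
cmr_inits <- function(arr, Tn, a1 = 0.3, a2 = 0.85) {
  zinit <- matrix(NA_integer_, arr$n, Tn)
  kinit <- matrix(NA_integer_, arr$n, Tn)
  for (i in seq_len(arr$n)) {
    f0 <- arr$fi[i]
    pos <- which(!is.na(arr$cmat[i, ]) & arr$cmat[i, ] > 0)
    last <- max(c(f0, pos))
    tt <- setdiff(f0:Tn, f0)
    alive <- 1L
    for (t in tt) {
      if (t <= last) {
        zinit[i, t] <- 1L
      } else {
        if (alive == 1L) {
          p <- if (arr$age0[i] == 1L && t == f0 + 1L) a1 else a2
          alive <- rbinom(1L, 1L, p)
        }
        zinit[i, t] <- alive
      }
      kinit[i, t] <- if (!is.na(arr$cmat[i, t]) && arr$cmat[i, t] > 0) 1L else 0L
    }
  }
  zinit[!is.na(arr$zdat)] <- NA_integer_
  kinit[!is.na(arr$kdat)] <- NA_integer_
  list(z = zinit, k = kinit, h = rep(1, arr$n))
}

# deterministic, support-respecting initial trajectory
n_inits <- function(n_init4, imm_lambda, Tn, a1 = 0.3, a2 = 0.85, f = 0.55,
                    om = 0.08) {
  r <- vital_rates(a1, a2, f, om, 1)
  alloc <- initial_stage_allocation(r, n_init4)
  N <- matrix(0, 5, Tn)
  N[1:4, 1] <- round(alloc)
  N[5, 1] <- round(imm_lambda)
  for (t in seq_len(Tn - 1L)) {
    ntot <- N[4, t] + N[5, t]
    N[1, t + 1] <- round(ntot * f / 2 * a1)
    N[2, t + 1] <- round(N[1, t] * a2)
    N[3, t + 1] <- round(N[2, t] * a2)
    N[4, t + 1] <- round((N[3, t] + ntot) * a2)
    N[5, t + 1] <- round(om * sum(N[1:4, t]))
  }
  N
}

# run one JAGS model; returns mcmc.list plus timings
run_jags <- function(code, data, inits_fun, monitors, config) {
  f <- tempfile(fileext = ".jags")
  writeLines(code, f)
  on.exit(unlink(f))
  t0 <- proc.time()[3]
  load_fun <- if (config$quiet) function(e) suppressMessages(force(e)) else force
  jm <- load_fun(rjags::jags.model(
    f, data = data, inits = inits_fun, n.chains = config$n_chains,
    n.adapt = config$n_adapt, quiet = config$quiet))
  if (config$n_burnin > 0)
    stats::update(jm, config$n_burnin, progress.bar = "none")
  samp <- rjags::coda.samples(jm, monitors, n.iter = config$n_iter,
                              thin = config$thin, progress.bar = "none")
  list(samples = samp, runtime_s = unname(proc.time()[3] - t0))
}

chain_init_base <- function(config, chain) {
  list(.RNG.name = "base::Mersenne-Twister",
       .RNG.seed = (config$seed * 1000L + chain) %% 2147483647L)
}

# --- fitting functions --------------------------------------------------

#' Fit the integrated population model
#'
#' Joint MCMC fit of the state-space count model, the encounter-count
#' CMR model and the binomial productivity model.  Any stream may be
#' `NULL`; the model then reduces exactly to the corresponding
#' sub-model combination (used for the integrated-vs-single
#' comparisons and prior-recovery checks).
#'
#' @param counts data.frame (`year`, `pairs`) or `NULL`
#' @param cmr long-format CMR data.frame or `NULL`
#' @param productivity data.frame (`year`, `burrows_monitored`,
#'   `chicks_fledged`) or `NULL`
#' @param design the `study_design`
#' @param config a [fit_config()]
#' @param initial_pairs point estimate of breeding pairs in year 1 used
#'   for the stable-stage prior allocation of initial abundances;
#'   defaults to the first survey count
#' @return an `ipm_fit` object: mcmc.list samples plus metadata
#' @export
fit_ipm <- function(counts = NULL, cmr = NULL, productivity = NULL,
                    design, config = fit_config(), initial_pairs = NULL) {
  streams <- c("counts", "cmr", "productivity")[
    !c(is.null(counts), is.null(cmr), is.null(productivity))]
  if (length(streams) == 0) stopf("no data streams supplied")
  Tn <- design$n_years
  pr <- config$priors
  data <- list(surv.effect.sd = pr$survival_effect_sd)
  monitors <- character(0)
  if (any(c("counts", "cmr") %in% streams)) {
    monitors <- c(monitors, "alpha1", "alpha2", "mu.a1", "mu.a2")
  }
  if (any(c("counts", "productivity") %in% streams)) {
    data$sigma.f.prior.tau <- 1 / pr$sigma_f_scale^2
    monitors <- c(monitors, "f", "mu.f", "sigma.f")
  }
  if ("counts" %in% streams) {
    if (is.null(initial_pairs)) initial_pairs <- counts$pairs[1]
    data$omega.upper <- pr$omega_upper
    data$imm.init.lambda <- pr$imm_init_lambda
    data$n.init <- unname(initial_stage_allocation(
      vital_rates(0.3, 0.85, 0.55, 0.08, 1), initial_pairs))
    data$y <- counts$pairs
    data$survey.idx <- match(counts$year, design$years)
    if (anyNA(data$survey.idx)) stopf("count year outside study years")
    data$n.survey <- nrow(counts)
    monitors <- c(monitors, "N", "Ntot", "lambda", "omega")
  }
  arr <- NULL
  if ("cmr" %in% streams) {
    arr <- prep_cmr_arrays(cmr, design)
    data <- c(data, list(
      cmat = arr$cmat, fi = arr$fi, age = arr$age, grp = arr$grp,
      usea1 = arr$usea1, z = arr$zdat, k = arr$kdat,
      n.ind = arr$n, post = arr$post, n.post = length(arr$post),
      lmu.eps.prior.tau = 1 / pr$log_eps_sd^2,
      sigma.eps.prior.tau = 1 / pr$sigma_eps_scale^2,
      theta.prior.shape = pr$theta_shape,
      theta.prior.rate = pr$theta_rate))
    monitors <- c(monitors, "gamma1", "gamma2", "eps", "theta", "sigma.eps")
  }
  if ("productivity" %in% streams) {
    data$J <- productivity$chicks_fledged
    data$B <- productivity$burrows_monitored
    data$prod.idx <- match(productivity$year, design$years)
    if (anyNA(data$prod.idx)) stopf("productivity year outside study years")
    data$n.prod <- nrow(productivity)
  }
  code <- ipm_jags_code(streams, Tn)
  cfg <- config
  inits_fun <- local({
    chain_counter <- 0L
    function() {
      chain_counter <<- chain_counter + 1L
      set.seed((cfg$seed * 131L + chain_counter) %% 2147483647L)
      ini <- chain_init_base(cfg, chain_counter)
      u <- function(a, b) a + (b - a) * ((cfg$seed * 7 + chain_counter * 13) %% 97) / 97
      if (any(c("counts", "cmr") %in% streams)) {
        ini$mu.a1 <- u(0.2, 0.5); ini$mu.a2 <- u(0.7, 0.9)
        ini$eta.a1 <- rep(0, Tn - 1L); ini$eta.a2 <- rep(0, Tn - 1L)
      }
      if (any(c("counts", "productivity") %in% streams)) {
        ini$mu.f <- u(0.4, 0.7); ini$sigma.f <- 0.3
        ini$eta.f <- rep(0, Tn)
      }
      if ("counts" %in% streams) {
        ini$omega <- u(0.03, 0.2)
        ini$N <- n_inits(data$n.init[4], data$imm.init.lambda, Tn)
      }
      if ("cmr" %in% streams) {
        ini <- c(ini, cmr_inits(arr, Tn))
        ini$theta <- 20; ini$sigma.eps <- 0.3
        ini$lmu.eps <- c(log(0.5), log(2))
        ini$gamma1 <- rep(0.3, 4); ini$gamma2 <- rep(0.6, 4)
      }
      ini
    }
  })
  run <- run_jags(code, data, inits_fun, unique(monitors), config)
  structure(list(samples = run$samples, design = design,
                 streams = streams, config = config,
                 seed = config$seed, runtime_s = run$runtime_s,
                 model_code = code),
            class = "ipm_fit")
}

#' Fit the CMR submodel alone
#'
#' Survival and detection posteriors from the encounter-count data
#' only, for comparison with the integrated fit.
#'
#' @inheritParams fit_ipm
#' @return an `ipm_fit`
#' @export
fit_cmr_only <- function(cmr, design, config = fit_config()) {
  fit_ipm(counts = NULL, cmr = cmr, productivity = NULL,
          design = design, config = config)
}

#' Fit the productivity submodel alone
#'
#' @inheritParams fit_ipm
#' @param hierarchical if `TRUE` (default), logit-normal year effects
#'   around a common mean; if `FALSE`, independent Uniform(0,1) priors
#'   per monitored year (the conjugate beta-binomial special case)
#' @return an `ipm_fit`
#' @export
fit_productivity_only <- function(productivity, design,
                                  config = fit_config(),
                                  hierarchical = TRUE) {
  Tn <- design$n_years
  data <- list(J = productivity$chicks_fledged,
               B = productivity$burrows_monitored,
               prod.idx = match(productivity$year, design$years),
               n.prod = nrow(productivity),
               surv.effect.sd = config$priors$survival_effect_sd)
  if (anyNA(data$prod.idx)) stopf("productivity year outside study years")
  if (hierarchical)
    data$sigma.f.prior.tau <- 1 / config$priors$sigma_f_scale^2
  code <- paste0("model {\n  tau.surv <- pow(surv.effect.sd, -2)\n",
                 jags_block_f(Tn, hierarchical), jags_block_prod(), "}\n")
  cfg <- config
  inits_fun <- local({
    chain_counter <- 0L
    function() {
      chain_counter <<- chain_counter + 1L
      ini <- chain_init_base(cfg, chain_counter)
      if (hierarchical) { ini$mu.f <- 0.5; ini$sigma.f <- 0.3 }
      ini
    }
  })
  monitors <- if (hierarchical) c("f", "mu.f", "sigma.f") else "f"
  run <- run_jags(code, data, inits_fun, monitors, config)
  structure(list(samples = run$samples, design = design,
                 streams = "productivity", config = config,
                 seed = config$seed, runtime_s = run$runtime_s,
                 model_code = code),
            class = "ipm_fit")
}

# --- posterior utilities ------------------------------------------------

#' Posterior draws as a single matrix
#' @param fit an `ipm_fit`
#' @return draws x parameters numeric matrix
#' @export
draws_matrix <- function(fit) {
  do.call(rbind, lapply(fit$samples, as.matrix))
}

#' Extract the draws of a year-indexed parameter series
#'
#' @param fit an `ipm_fit`
#' @param name base parameter name (e.g. `"alpha1"`, `"Ntot"`)
#' @return draws x years matrix (columns in year order)
#' @export
extract_series <- function(fit, name) {
  m <- draws_matrix(fit)
  cols <- grep(paste0("^", name, "\\["), colnames(m))
  if (length(cols) == 0) stopf("no monitored series '%s'", name)
  idx <- as.integer(sub(".*\\[(\\d+)\\]$", "\\1", colnames(m)[cols]))
  m[, cols[order(idx)], drop = FALSE]
}

#' Extract the draws of the 5 x T latent stage array
#' @param fit an `ipm_fit` that monitored `N`
#' @return draws x 5 x T array
#' @export
extract_stages <- function(fit) {
  m <- draws_matrix(fit)
  cols <- grep("^N\\[", colnames(m), value = TRUE)
  if (length(cols) == 0) stopf("latent stages were not monitored")
  ij <- do.call(rbind, lapply(cols, function(s)
    as.integer(strsplit(sub("^N\\[(\\d+),(\\d+)\\]$", "\\1 \\2", s), " ")[[1]])))
  Tn <- max(ij[, 2])
  out <- array(NA_real_, c(nrow(m), 5, Tn))
  for (q in seq_along(cols)) out[, ij[q, 1], ij[q, 2]] <- m[, cols[q]]
  out
}

#' Convergence diagnostics
#'
#' Split-chain R-hat (Gelman-Rubin) and effective sample size for every
#' monitored scalar, plus an overall pass flag at the package's
#' reproducibility thresholds (R-hat < 1.05, ESS >= 200 on the
#' parameters monitored).
#'
#' @param fit an `ipm_fit`
#' @param rhat_max,ess_min thresholds for the overall flag
#' @return data.frame with `parameter`, `rhat`, `ess`, attribute `ok`
#' @export
convergence <- function(fit, rhat_max = 1.05, ess_min = 200) {
  sl <- fit$samples
  keep <- apply(as.matrix(sl[[1]]), 2, function(x) stats::sd(x) > 0)
  sl2 <- lapply(sl, function(ch) ch[, keep, drop = FALSE])
  class(sl2) <- "mcmc.list"
  gd <- try(coda::gelman.diag(sl2, autoburnin = FALSE,
                              multivariate = FALSE)$psrf[, 1], silent = TRUE)
  if (inherits(gd, "try-error")) gd <- rep(NA_real_, sum(keep))
  ess <- coda::effectiveSize(sl2)
  out <- data.frame(parameter = colnames(as.matrix(sl2[[1]])),
                    rhat = unname(gd), ess = unname(ess))
  attr(out, "ok") <- all(out$rhat < rhat_max, na.rm = TRUE) &&
    all(out$ess >= ess_min, na.rm = TRUE)
  out
}

#' Posterior summary table
#'
#' Mean and equal-tailed 95% credible interval for each monitored
#' parameter.  `mask` excludes named years from year-indexed series
#' (they are dropped from the table, mirroring reporting exclusions for
#' years with insufficient data).
#'
#' @param fit an `ipm_fit`
#' @param params optional character vector of base names to keep
#' @param mask named list: for a series name, calendar years to drop
#' @param level credible level (default 0.95)
#' @return data.frame `parameter`, `year` (NA for scalars), `mean`,
#'   `median`, `lower`, `upper`
#' @export
summarize_fit <- function(fit, params = NULL, mask = NULL, level = 0.95) {
  m <- draws_matrix(fit)
  a <- (1 - level) / 2
  base <- sub("\\[.*$", "", colnames(m))
  if (!is.null(params)) m <- m[, base %in% params, drop = FALSE]
  base <- sub("\\[.*$", "", colnames(m))
  idx1 <- suppressWarnings(
    as.integer(sub("^[^\\[]+\\[(\\d+)\\]$", "\\1", colnames(m))))
  yrs <- fit$design$years[idx1]
  out <- data.frame(parameter = base, year = yrs,
                    mean = colMeans(m),
                    median = apply(m, 2, stats::median),
                    lower = apply(m, 2, quantile, probs = a),
                    upper = apply(m, 2, quantile, probs = 1 - a),
                    row.names = NULL)
  if (!is.null(mask)) {
    for (nm in names(mask)) {
      out <- out[!(out$parameter == nm & out$year %in% mask[[nm]]), ]
    }
  }
  out
}

#' Posterior of the across-year mean of an annual series
#'
#' The scalar "mean rate" reported for a study period is the average of
#' the annual values, computed within each posterior draw.
#'
#' @param fit an `ipm_fit`
#' @param name series name
#' @param drop_years calendar years to exclude from the average
#' @return list with `draws`, `mean`, `lower`, `upper` (95% equal-tailed)
#' @export
series_mean_posterior <- function(fit, name, drop_years = NULL) {
  s <- extract_series(fit, name)
  nyr <- ncol(s)
  yrs <- fit$design$years[seq_len(nyr)]
  keep <- !(yrs %in% drop_years)
  d <- rowMeans(s[, keep, drop = FALSE])
  list(draws = d, mean = mean(d),
       lower = unname(quantile(d, 0.025)), upper = unname(quantile(d, 0.975)))
}

#' Write a fit's draws and metadata to a run directory
#'
#' Stores the posterior draws as a tabular CSV (one row per draw, with
#' chain and iteration columns), the posterior summary as CSV, and a
#' structured key-value metadata file recording the package version,
#' seed, sampler settings, data streams and runtime.
#'
#' @param fit an `ipm_fit`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ms <- lapply(seq_along(fit$samples), function(ch) {
    m <- as.matrix(fit$samples[[ch]])
    data.frame(chain = ch, iteration = seq_len(nrow(m)), m,
               check.names = FALSE)
  })
  write.csv(do.call(rbind, ms), file.path(dir, "draws.csv"),
            row.names = FALSE)
  write.csv(summarize_fit(fit), file.path(dir, "summary.csv"),
            row.names = FALSE)
  cfg <- fit$config
  meta <- c(
    paste0("package_version: ",
           as.character(utils::packageVersion("seabirdIPM"))),
    paste0("seed: ", fit$seed),
    paste0("streams: ", paste(fit$streams, collapse = " ")),
    paste0("n_chains: ", cfg$n_chains),
    paste0("n_adapt: ", cfg$n_adapt),
    paste0("n_burnin: ", cfg$n_burnin),
    paste0("n_iter: ", cfg$n_iter),
    paste0("thin: ", cfg$thin),
    paste0("runtime_s: ", round(fit$runtime_s, 1)))
  writeLines(meta, file.path(dir, "run-metadata.txt"))
  writeLines(fit$model_code, file.path(dir, "model.jags"))
  invisible(dir)
}

#' Compare integrated and single-dataset posteriors
#'
#' For each shared parameter, reports posterior means, the 95% credible
#' intervals, their overlap fraction (intersection length over the
#' narrower interval's length) and the difference of means, flagging
#' parameters whose mean difference exceeds `flag_threshold` times the
#' narrower interval width.
#'
#' @param fit_a,fit_b two `ipm_fit` objects
#' @param params base parameter names to compare (annual series are
#'   compared year by year)
#' @param flag_threshold disagreement flag multiplier (default 1)
#' @return data.frame with one row per compared scalar
#' @export
compare_integrated_vs_single <- function(fit_a, fit_b,
                                         params = c("alpha1", "alpha2"),
                                         flag_threshold = 1) {
  sa <- summarize_fit(fit_a, params = params)
  sb <- summarize_fit(fit_b, params = params)
  key <- function(d) paste(d$parameter, d$year)
  common <- intersect(key(sa), key(sb))
  sa <- sa[match(common, key(sa)), ]
  sb <- sb[match(common, key(sb)), ]
  lo <- pmax(sa$lower, sb$lower)
  hi <- pmin(sa$upper, sb$upper)
  wa <- sa$upper - sa$lower
  wb <- sb$upper - sb$lower
  wmin <- pmin(wa, wb)
  overlap <- pmax(hi - lo, 0) / ifelse(wmin > 0, wmin, 1)
  overlap <- pmin(overlap, 1)
  dd <- data.frame(parameter = sa$parameter, year = sa$year,
                   mean_a = sa$mean, mean_b = sb$mean,
                   mean_diff = sa$mean - sb$mean,
                   overlap = overlap,
                   width_min = wmin)
  dd$flagged <- abs(dd$mean_diff) > flag_threshold * dd$width_min
  dd
}
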