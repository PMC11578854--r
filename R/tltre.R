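# Transient life table response experiment: first-order decomposition
# of the variance of realized population growth (and of its successive
# annual changes) into contributions from the temporal variation and
# covariation of the demographic rates and the stage structure.
#
# The parameter vector per year is
#   (alpha1, alpha2, f, omega, n1, n2, n3, n4, nimm)
# where n* are stage proportions (each class over the all-class total).

TLTRE_PARS <- c("alpha1", "alpha2", "f", "omega",
                "n1", "n2", "n3", "n4", "nimm")

#' Year-by-parameter input table for the transient LTRE
#'
#' @param alpha1,alpha2,f per-year demographic rates (length m years)
#' @param omega scalar or per-year immigration-plus-noise rate
#' @param stages m x 5 matrix (or 5 x m) of stage abundances or
#'   proportions in the order N1, N2, N3, N4, Nimm; rows are
#'   renormalized to proportions
#' @return an object of class `ltre_input`: m x 9 matrix
#' @export
ltre_input <- function(alpha1, alpha2, f, omega, stages) {
  m <- length(alpha1)
  if (length(alpha2) != m || length(f) != m)
    stopf("rate series must have equal length")
  if (is.matrix(stages) && nrow(stages) == 5 && ncol(stages) == m)
    stages <- t(stages)
  if (!is.matrix(stages) || nrow(stages) != m || ncol(stages) != 5)
    stopf("stages must be an m x 5 matrix aligned with the rate series")
  tot <- rowSums(stages)
  if (any(tot <= 0)) stopf("stage totals must be positive in every year")
  props <- stages / tot
  x <- cbind(alpha1, alpha2, f, rep_len(omega, m), props)
  colnames(x) <- TLTRE_PARS
  structure(x, class = c("ltre_input", "matrix"))
}

#' Expected one-step growth of the all-class total
#'
#' The growth function decomposed by the transient LTRE:
#' `lambda(theta) = (f/2) alpha1 (n4 + nimm) + alpha2 (n1+n2+n3+n4+nimm)
#'  + omega (n1+n2+n3+n4)`, the expected next-year all-class total per
#' current head under the state process.  Multilinear in its nine
#' arguments.  Distinct from the breeding-population ratio
#' `Ntot_{t+1}/Ntot_t` reported by [realized_growth()].
#'
#' @param theta named numeric vector over `TLTRE_PARS` (or a row of an
#'   `ltre_input`)
#' @return scalar expected growth rate
#' @export
growth_function <- function(theta) {
  theta <- theta[TLTRE_PARS]
  if (anyNA(theta)) stopf("theta must contain all of: %s",
                          paste(TLTRE_PARS, collapse = ", "))
  pr <- theta[c("n1", "n2", "n3", "n4", "nimm")]
  if (abs(sum(pr) - 1) > 1e-8)
    stopf("stage proportions must sum to 1 (got %.6f)", sum(pr))
  unname(theta["f"] / 2 * theta["alpha1"] * (theta["n4"] + theta["nimm"]) +
           theta["alpha2"] * sum(pr) +
           theta["omega"] * (sum(pr) - theta["nimm"]))
}

#' Sensitivities of the growth function
#'
#' Gradient of [growth_function()] at a parameter point, evaluated both
#' analytically (the function is multilinear, so the partials are
#' exact) and by central finite differences for cross-validation.
#'
#' @param theta named parameter vector (typically the temporal mean)
#' @param method "analytic" (default) or "numeric"
#' @param step finite-difference step (numeric method)
#' @return named gradient vector over `TLTRE_PARS`
#' @export
sensitivities <- function(theta, method = c("analytic", "numeric"),
                          step = 1e-6) {
  method <- match.arg(method)
  theta <- theta[TLTRE_PARS]
  if (method == "analytic") {
    s <- c(alpha1 = unname(theta["f"] / 2 * (theta["n4"] + theta["nimm"])),
           alpha2 = unname(sum(theta[c("n1", "n2", "n3", "n4", "nimm")])),
           f = unname(theta["alpha1"] / 2 * (theta["n4"] + theta["nimm"])),
           omega = unname(sum(theta[c("n1", "n2", "n3", "n4")])),
           n1 = unname(theta["alpha2"] + theta["omega"]),
           n2 = unname(theta["alpha2"] + theta["omega"]),
           n3 = unname(theta["alpha2"] + theta["omega"]),
           n4 = unname(theta["f"] / 2 * theta["alpha1"] + theta["alpha2"] +
                         theta["omega"]),
           nimm = unname(theta["f"] / 2 * theta["alpha1"] + theta["alpha2"]))
    return(s)
  }
  # raw multilinear form, without the proportion-sum check (perturbed
  # points no longer sum to 1)
  g <- function(th)
    th["f"] / 2 * th["alpha1"] * (th["n4"] + th["nimm"]) +
    th["alpha2"] * sum(th[c("n1", "n2", "n3", "n4", "nimm")]) +
    th["omega"] * sum(th[c("n1", "n2", "n3", "n4")])
  vapply(TLTRE_PARS, function(p) {
    up <- theta; up[p] <- up[p] + step
    dn <- theta; dn[p] <- dn[p] - step
    unname((g(up) - g(dn)) / (2 * step))
  }, numeric(1))
}

#' Variance decomposition of realized growth
#'
#' First-order transient LTRE: the contribution of parameter pair
#' (i, j) is `C_ij = cov_t(theta_i, theta_j) s_i s_j` with
#' sensitivities evaluated at the temporal mean.  Per-parameter totals
#' `sum_j C_ij` are split into the own-variance part (`C_ii`) and the
#' summed covariance part, with percentages over the grand total.
#'
#' @param input an `ltre_input` with at least 3 years
#' @return list of class `ltre_result`: `contribution_matrix` (9 x 9),
#'   `table` (per-parameter data.frame with `variance_part`,
#'   `covariance_part`, `total`, `percent`), `total` (sum of all
#'   contributions, the first-order approximation to Var(lambda_t)),
#'   `sens`, `theta_mean`
#' @export
variance_contributions <- function(input) {
  x <- unclass(input)
  if (nrow(x) < 3) stopf("need at least 3 years for a variance decomposition")
  mu <- colMeans(x)
  s <- sensitivities(mu)
  V <- stats::cov(x)
  C <- V * outer(s, s)
  tot <- sum(C)
  own <- diag(C)
  covp <- rowSums(C) - own
  tab <- data.frame(parameter = TLTRE_PARS,
                    variance_part = own,
                    covariance_part = covp,
                    total = own + covp,
                    percent = if (tot != 0) 100 * (own + covp) / tot
                    else rep(0, length(own)),
                    row.names = NULL)
  structure(list(contribution_matrix = C, table = tab, total = tot,
                 sens = s, theta_mean = mu),
            class = "ltre_result")
}

#' Contributions of annual parameter changes to annual growth changes
#'
#' For successive years, the contribution of parameter i to
#' `lambda_{t+1} - lambda_t` is `(theta_{i,t+1} - theta_{i,t}) * s_i`
#' with the sensitivity evaluated at the midpoint of the two years.
#' Row sums approximate the direct change in the growth function.
#'
#' @param input an `ltre_input` with at least 2 years
#' @return (m - 1) x 9 matrix of contributions
#' @export
annual_contributions <- function(input) {
  x <- unclass(input)
  m <- nrow(x)
  if (m < 2) stopf("need at least 2 years")
  out <- matrix(0, m - 1, ncol(x), dimnames = list(NULL, TLTRE_PARS))
  for (t in seq_len(m - 1)) {
    mid <- (x[t, ] + x[t + 1, ]) / 2
    s <- sensitivities(mid)
    out[t, ] <- (x[t + 1, ] - x[t, ]) * s
  }
  out
}

#' Build tLTRE input from a fitted model
#'
#' Extracts the aligned per-year series of demographic rates and stage
#' proportions from an `ipm_fit`.  With `mode = "mean"` the posterior
#' means form one input (the default decomposition); with
#' `mode = "draws"` one input per posterior draw is returned for
#' draw-wise decompositions summarized with credible intervals.
#'
#' @param fit an `ipm_fit` that monitored `alpha1`, `alpha2`, `f` and `N`
#' @param mode "mean" or "draws"
#' @param max_draws cap on the number of draw-wise inputs
#' @return an `ltre_input`, or a list of them for `mode = "draws"`
#' @export
ltre_input_from_fit <- function(fit, mode = c("mean", "draws"),
                                max_draws = 500L) {
  mode <- match.arg(mode)
  a1 <- extract_series(fit, "alpha1")
  a2 <- extract_series(fit, "alpha2")
  ff <- extract_series(fit, "f")
  om <- draws_matrix(fit)[, "omega"]
  Ns <- extract_stages(fit)
  m <- ncol(a1)  # transition years
  if (mode == "mean") {
    st <- t(apply(Ns, c(2, 3), mean))[seq_len(m), ]
    return(ltre_input(colMeans(a1), colMeans(a2), colMeans(ff)[seq_len(m)],
                      mean(om), st))
  }
  nd <- min(nrow(a1), max_draws)
  idx <- round(seq(1, nrow(a1), length.out = nd))
  lapply(idx, function(d)
    ltre_input(a1[d, ], a2[d, ], ff[d, seq_len(m)], om[d],
               t(Ns[d, , ])[seq_len(m), ]))
}

#' Process correlations between annual demographic rates
#'
#' Pearson correlation between the year series of two rates computed
#' within each posterior draw and summarized across draws, separating
#' process correlation from sampling covariation.
#'
#' @param fit an `ipm_fit`
#' @param pairs list of 2-vectors of series names
#' @return data.frame `pair`, `mean`, `lower`, `upper` (95% equal-tailed)
#' @export
process_correlations <- function(fit,
                                 pairs = list(c("alpha2", "f"),
                                              c("alpha2", "alpha1"),
                                              c("alpha1", "f"))) {
  out <- lapply(pairs, function(pp) {
    a <- extract_series(fit, pp[1])
    b <- extract_series(fit, pp[2])
    m <- min(ncol(a), ncol(b))
    r <- vapply(seq_len(nrow(a)),
                function(d) stats::cor(a[d, seq_len(m)], b[d, seq_len(m)]),
                numeric(1))
    data.frame(pair = paste(pp, collapse = "~"), mean = mean(r),
               lower = unname(quantile(r, 0.025, na.rm = TRUE)),
               upper = unname(quantile(r, 0.975, na.rm = TRUE)))
  })
  do.call(rbind, out)
}

#' Tidy export of an `ltre_result`
#' @param result an `ltre_result`
#' @param path optional CSV path
#' @return the per-parameter table (invisibly when writing)
#' @export
ltre_table <- function(result, path = NULL) {
  tab <- result$table
  if (!is.null(path)) {
    write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
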