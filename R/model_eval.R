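# Model comparison and diagnostics: DIC and WAIC from stored pointwise
# log-likelihoods, randomised quantile residuals, simultaneous credible
# bands, effective sample sizes, and effect extraction for reporting.

#' Deviance Information Criterion
#'
#' DIC \eqn{= 2\bar D - D(\hat\theta)} with the plug-in deviance evaluated
#' at the posterior means of the fitted \eqn{\mu_i} and \eqn{\sigma_i}
#' (well defined under the nonlinear scale link); the effective number of
#' parameters is \eqn{p_D = \bar D - D(\hat\theta)}.
#'
#' @param chain A `haz_chain`.
#' @return List with `dic` and `pd`.
#' @export
compute_dic <- function(chain) {
  stopifnot(inherits(chain, "haz_chain"))
  if (is.null(chain$loglik) || nrow(chain$loglik) == 0L)
    stop("chain holds no saved iterations")
  dev_bar <- mean(-2 * rowSums(chain$loglik))
  dev_hat <- -2 * sum(stats::dnorm(chain$y, chain$mu_mean,
                                   chain$sigma_mean, log = TRUE))
  list(dic = 2 * dev_bar - dev_hat, pd = dev_bar - dev_hat)
}

# column-wise log of the mean of exp(ll) with max-shift for stability
.log_col_means_exp <- function(ll) {
  m <- apply(ll, 2L, max)
  m + log(colMeans(exp(sweep(ll, 2L, m))))
}

#' Widely Applicable Information Criterion
#'
#' WAIC \eqn{= -2 \sum_i [\log \mathrm{mean}_t\, p(y_i|\theta_t) -
#' \mathrm{var}_t \log p(y_i|\theta_t)]} with the variance-form penalty
#' (pWAIC2).
#'
#' @param chain A `haz_chain`.
#' @return List with `waic` and `penalty`.
#' @export
compute_waic <- function(chain) {
  stopifnot(inherits(chain, "haz_chain"))
  ll <- chain$loglik
  if (is.null(ll) || nrow(ll) == 0L) stop("chain holds no saved iterations")
  if (nrow(ll) < 2L)
    stop("WAIC needs at least two saved iterations (variance undefined)")
  lppd <- sum(.log_col_means_exp(ll))
  penalty <- sum(apply(ll, 2L, stats::var))
  list(waic = -2 * (lppd - penalty), penalty = penalty)
}

#' Randomised quantile residuals for a Gaussian fit
#'
#' \eqn{r_i = \Phi^{-1}(F(y_i; \mu_i, \sigma_i))}; for a continuous response
#' no randomisation is involved. Under a correctly specified model the
#' residuals are standard normal. Residuals beyond \eqn{\pm 8} (observations
#' essentially infinitely far in the tail) are clipped with a warning.
#'
#' @param y Observed response.
#' @param mu,sigma Fitted means and standard deviations (plug-in posterior
#'   means), `sigma > 0`.
#' @return Numeric residual vector.
#' @export
randomized_quantile_residuals <- function(y, mu, sigma) {
  if (any(sigma <= 0)) stop("'sigma' must be positive")
  r <- stats::qnorm(stats::pnorm(y, mu, sigma))
  out <- !is.finite(r) | abs(r) > 8
  if (any(out)) {
    warning(sum(out), " residual(s) clipped at +/- 8")
    r[out] <- sign(y - mu)[out] * 8
  }
  r
}

#' Simultaneous credible bands for sampled curves
#'
#' Builds, for each requested level, the band
#' \eqn{\hat m(x) \pm q\, \hat s(x)} where \eqn{q} is the empirical level
#' quantile over draws of the maximum (over the grid) standardised absolute
#' deviation from the posterior mean. By construction at least the stated
#' fraction of sampled curves lies entirely inside the band, and the
#' simultaneous band encloses the corresponding pointwise band. Grid points
#' with zero posterior variance contribute the mean only.
#'
#' @param curves Matrix of sampled curves (draws x grid points).
#' @param levels Coverage levels, by default 0.80 and 0.95.
#' @return List with `mean`, `sd` and per-level matrices `lower`/`upper`
#'   (columns named by level), plus the max-statistic quantiles `q`.
#' @export
simultaneous_credible_band <- function(curves, levels = c(0.80, 0.95)) {
  curves <- as.matrix(curves)
  if (nrow(curves) < 100L)
    stop("at least 100 draws are required for simultaneous bands")
  m <- colMeans(curves)
  s <- apply(curves, 2L, stats::sd)
  ok <- s > 0
  if (any(ok)) {
    dev <- abs(sweep(curves[, ok, drop = FALSE], 2L, m[ok])) /
      rep(s[ok], each = nrow(curves))
    maxdev <- apply(dev, 1L, max)
    q <- stats::quantile(maxdev, levels, names = FALSE, type = 1)
  } else {
    q <- rep(0, length(levels))
  }
  lower <- upper <- matrix(m, length(m), length(levels),
                           dimnames = list(NULL, sprintf("%g", levels)))
  for (j in seq_along(levels)) {
    lower[ok, j] <- m[ok] - q[j] * s[ok]
    upper[ok, j] <- m[ok] + q[j] * s[ok]
  }
  list(mean = m, sd = s, lower = lower, upper = upper,
       q = stats::setNames(q, sprintf("%g", levels)))
}

#' Effective sample size by initial monotone sequence truncation
#'
#' Sums lag autocorrelations pairwise (Geyer's initial monotone positive
#' sequence) to estimate the autocorrelation time, and returns
#' `n / tau` bounded to `[1, n]`.
#'
#' @param x Numeric chain.
#' @return Scalar effective sample size.
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0) return(1)
  rho <- drop(stats::acf(x, lag.max = min(n - 2L, 2000L),
                         plot = FALSE)$acf)
  # pair sums Gamma_m = rho_{2m} + rho_{2m+1}, kept while positive and
  # non-increasing
  nmax <- floor((length(rho) - 1L) / 2L)
  gam <- numeric(0)
  prev <- Inf
  for (mth in seq_len(nmax)) {
    g <- rho[2 * mth] + rho[2 * mth + 1]
    if (g <= 0) break
    g <- min(g, prev)
    gam <- c(gam, g)
    prev <- g
  }
  tau <- 1 + 2 * sum(gam)
  min(max(n / tau, 1), n)
}

#' Convergence summary of a chain
#'
#' Effective sample size, posterior mean and standard deviation for every
#' stored coefficient and variance parameter.
#'
#' @param chain A `haz_chain`.
#' @return Data frame with columns `predictor`, `block`, `parameter`,
#'   `mean`, `sd`, `ess`.
#' @export
convergence_summary <- function(chain) {
  stopifnot(inherits(chain, "haz_chain"))
  if (chain$n_saved == 0L) stop("chain holds no saved iterations")
  rows <- list()
  for (side in c("mu", "sigma")) {
    for (lab in names(chain$samples[[side]])) {
      S <- chain$samples[[side]][[lab]]
      nm <- colnames(S)
      if (is.null(nm)) nm <- sprintf("b%02d", seq_len(ncol(S)))
      rows[[length(rows) + 1L]] <- data.frame(
        predictor = side, block = lab, parameter = nm,
        mean = colMeans(S), sd = apply(S, 2L, stats::sd),
        ess = apply(S, 2L, effective_sample_size),
        row.names = NULL)
    }
  }
  V <- chain$variances
  if (!is.null(V) && ncol(V) > 0L)
    rows[[length(rows) + 1L]] <- data.frame(
      predictor = sub(":.*", "", colnames(V)),
      block = sub("^[^:]*:", "", colnames(V)),
      parameter = "variance",
      mean = colMeans(V), sd = apply(V, 2L, stats::sd),
      ess = apply(V, 2L, effective_sample_size), row.names = NULL)
  do.call(rbind, rows)
}

#' Posterior summary of one smooth term on its evaluation grid
#'
#' @param chain A `haz_chain` (must carry its assembled model).
#' @param label Term label.
#' @param predictor `"mu"` or `"sigma"`.
#' @param levels Band levels.
#' @return Data frame: the grid covariates, posterior `mean`, pointwise
#'   equal-tailed bounds (`pw_lo*`/`pw_hi*`) and simultaneous bounds
#'   (`sim_lo*`/`sim_hi*`) per level.
#' @export
extract_term_effect <- function(chain, label, predictor = c("mu", "sigma"),
                                levels = c(0.80, 0.95)) {
  predictor <- match.arg(predictor)
  if (is.null(chain$model)) stop("chain carries no assembled model")
  bl <- chain$model$blocks[[label]]
  if (is.null(bl)) stop("unknown term: ", label)
  S <- chain$samples[[predictor]][[label]]
  if (is.null(S)) stop(sprintf("term '%s' is not in the %s predictor",
                               label, predictor))
  curves <- S %*% t(bl$grid$design)
  band <- simultaneous_credible_band(curves, levels = levels)
  out <- bl$grid$newdata
  out$mean <- band$mean
  for (j in seq_along(levels)) {
    a <- (1 - levels[j]) / 2
    tag <- sprintf("%02.0f", 100 * levels[j])
    out[[paste0("pw_lo", tag)]] <- apply(curves, 2L, stats::quantile,
                                         probs = a)
    out[[paste0("pw_hi", tag)]] <- apply(curves, 2L, stats::quantile,
                                         probs = 1 - a)
    out[[paste0("sim_lo", tag)]] <- band$lower[, j]
    out[[paste0("sim_hi", tag)]] <- band$upper[, j]
  }
  out
}

#' Posterior mean and standard deviation of the spatial effect
#'
#' Returns the per-district posterior mean and standard deviation of the
#' MRF field for one survey wave. The per-wave sum-to-zero constraint makes
#' the posterior-mean effects sum to (numerically) zero across districts;
#' districts without observations still receive prior-smoothed estimates.
#'
#' @param chain A `haz_chain` whose model contains the spatial term.
#' @param wave Survey-wave label.
#' @param predictor `"mu"` or `"sigma"`.
#' @param label Spatial term label (default `"spatial"`).
#' @return Data frame with columns `district`, `wave`, `mean`, `sd`.
#' @export
extract_spatial_effect <- function(chain, wave, predictor = c("mu", "sigma"),
                                   label = "spatial") {
  predictor <- match.arg(predictor)
  if (is.null(chain$model)) stop("chain carries no assembled model")
  bl <- chain$model$blocks[[label]]
  if (is.null(bl) || bl$kind != "mrf")
    stop("model contains no spatial term under label '", label, "'")
  S <- chain$samples[[predictor]][[label]]
  if (is.null(S)) stop(sprintf("spatial term is not in the %s predictor",
                               predictor))
  levels <- bl$grid$newdata
  if (!wave %in% levels$wave)
    stop("wave '", wave, "' not present; available: ",
         paste(unique(levels$wave), collapse = ", "))
  draws <- S %*% t(bl$grid$design)  # draws x (district x wave)
  keep <- levels$wave == wave
  data.frame(district = levels$district[keep], wave = wave,
             mean = colMeans(draws[, keep, drop = FALSE]),
             sd = apply(draws[, keep, drop = FALSE], 2L, stats::sd),
             row.names = NULL)
}

#' Fit summary: information criteria and linear-effect table
#'
#' @param chain A `haz_chain`.
#' @param level Credible level for the linear-effect intervals.
#' @return List with `ic` (one-row data frame: dic, pd, waic, waic_penalty)
#'   and `linear` (per-predictor posterior means and equal-tailed credible
#'   intervals of the fixed effects).
#' @export
summarize_fit <- function(chain, level = 0.95) {
  stopifnot(inherits(chain, "haz_chain"))
  dic <- compute_dic(chain)
  waic <- compute_waic(chain)
  a <- (1 - level) / 2
  lin <- do.call(rbind, lapply(c("mu", "sigma"), function(side) {
    S <- chain$samples[[side]][["(fixed)"]]
    data.frame(predictor = side, covariate = colnames(S),
               mean = colMeans(S),
               lower = apply(S, 2L, stats::quantile, probs = a),
               upper = apply(S, 2L, stats::quantile, probs = 1 - a),
               row.names = NULL)
  }))
  list(ic = data.frame(dic = dic$dic, pd = dic$pd, waic = waic$waic,
                       waic_penalty = waic$penalty),
       linear = lin)
}
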