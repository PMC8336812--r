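# Posterior simulation for the assembled location-scale model.
#
# Mean-side coefficient blocks have Gaussian full conditionals (conjugate
# block Gibbs); scale-side blocks are updated by Metropolis-Hastings with an
# IWLS (iteratively weighted least squares) Gaussian approximation to the
# full conditional as proposal, or an adaptive random walk; every smoothing
# variance gets a conjugate inverse-gamma update. The sweep order is fixed:
# fixed effects, then smooths in specification order (spatial last), then
# variance parameters.

#' Sampler configuration
#'
#' @param seed Integer RNG seed (mandatory; the whole run is reproducible
#'   given the seed).
#' @param iterations Total MCMC iterations.
#' @param burnin Burn-in iterations discarded before saving; any proposal
#'   adaptation is frozen afterwards so the retained chain is valid MCMC.
#' @param thinning Keep every `thinning`-th post-burn-in iteration.
#' @param hyper_a,hyper_b Inverse-gamma shape/scale hyperparameters shared
#'   by all smoothing variances (weakly informative by default).
#' @param proposal Scale-side proposal: `"iwls"` (default) or
#'   `"random-walk"` with scale tuned during burn-in towards an acceptance
#'   rate of roughly 0.23-0.44.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(seed, iterations = 12000L, burnin = 2000L,
                           thinning = 10L, hyper_a = 0.001, hyper_b = 0.001,
                           proposal = c("iwls", "random-walk")) {
  if (missing(seed)) stop("'seed' is required")
  proposal <- match.arg(proposal)
  iterations <- as.integer(iterations); burnin <- as.integer(burnin)
  thinning <- as.integer(thinning)
  if (burnin >= iterations) stop("'burnin' must be smaller than 'iterations'")
  if (burnin < 0L) stop("'burnin' must be >= 0")
  if (thinning < 1L) stop("'thinning' must be >= 1")
  if (hyper_a <= 0 || hyper_b <= 0) stop("hyperparameters must be positive")
  if (floor((iterations - burnin) / thinning) < 1L)
    stop("no iterations would be saved")
  structure(list(seed = as.integer(seed), iterations = iterations,
                 burnin = burnin, thinning = thinning,
                 hyper_a = hyper_a, hyper_b = hyper_b, proposal = proposal),
            class = "sampler_config")
}

.chol_solve <- function(R, b) backsolve(R, backsolve(R, b, transpose = TRUE))

# Cholesky with a tiny diagonal lift as numerical fallback
.safe_chol <- function(P) {
  R <- tryCatch(chol(P), error = function(e) NULL)
  if (is.null(R))
    R <- chol(P + diag(1e-8 * max(diag(P), 1), nrow(P)))
  R
}

#' Gaussian full conditional of a mean-side block
#'
#' For partial residuals \eqn{r} and heteroscedastic noise
#' \eqn{\Sigma = \mathrm{diag}(\sigma_i^2)}, the full conditional of the
#' block coefficients is Normal with precision
#' \eqn{P = B'\Sigma^{-1}B + K/\gamma^2} and mean solving
#' \eqn{P m = B'\Sigma^{-1} r}.
#'
#' @param design Block design matrix `B`.
#' @param partial_residuals Response minus all other contributions.
#' @param sigma Per-observation standard deviations (positive).
#' @param penalty Optional [penalty_matrix()] `K`; `NULL` for a diffuse
#'   (flat) prior.
#' @param gamma2 Smoothing variance \eqn{\gamma^2}; `Inf` gives the flat
#'   prior limit.
#' @return List with `mean`, `precision` and its Cholesky factor `chol`.
#' @export
full_conditional_mu_block <- function(design, partial_residuals, sigma,
                                      penalty = NULL, gamma2 = Inf) {
  if (any(sigma <= 0)) stop("'sigma' must be positive")
  w <- 1 / sigma^2
  P <- crossprod(design * w, design)
  if (!is.null(penalty) && is.finite(gamma2))
    P <- P + penalty$matrix / gamma2
  R <- tryCatch(chol(P), error = function(e)
    stop("singular full-conditional precision (degenerate design)"))
  m <- .chol_solve(R, crossprod(design, w * partial_residuals))
  list(mean = drop(m), precision = P, chol = R)
}

#' Draw a mean-side block from its Gaussian full conditional
#'
#' @inheritParams full_conditional_mu_block
#' @return Numeric coefficient draw.
#' @export
gibbs_update_mu_block <- function(design, partial_residuals, sigma,
                                  penalty = NULL, gamma2 = Inf) {
  fc <- full_conditional_mu_block(design, partial_residuals, sigma,
                                  penalty, gamma2)
  drop(fc$mean + backsolve(fc$chol, stats::rnorm(ncol(design))))
}

# log full conditional of a scale-side block (up to a constant):
# sum_i [ -eta_i - e_i^2 exp(-2 eta_i)/2 ] - beta' K beta / (2 gamma2)
.sigma_logtarget <- function(eta, e2, qform) {
  sum(-eta - 0.5 * e2 * exp(-2 * eta)) - 0.5 * qform
}

# IWLS proposal ingredients at one state: Newton step with observed
# information working weights w = e^2 exp(-2 eta) (so -l''(eta) = 2w),
# giving proposal N(beta + H^-1 g, H^-1) with H = 2 X'WX + K/gamma^2
.iwls_at <- function(X, Kg, beta, eta, e2) {
  w <- e2 * exp(-2 * eta)
  H <- 2 * crossprod(X * w, X)
  if (!is.null(Kg)) H <- H + Kg
  R <- .safe_chol(H)
  g <- drop(crossprod(X, w - 1))
  if (!is.null(Kg)) g <- g - drop(Kg %*% beta)
  list(mean = beta + drop(.chol_solve(R, g)), chol = R,
       logdet = sum(log(diag(R))))
}

# One MH step for a scale-side block. `XtX` may be precomputed (used by the
# random-walk proposal). Returns the new coefficients, the new linear
# predictor and the accept flag. The IWLS proposal is state dependent, so
# the acceptance ratio carries the proposal normalising constants.
.mh_sigma_step <- function(X, XtX, Kg, beta0, offset, e2, proposal, scale) {
  p <- length(beta0)
  eta0 <- offset + drop(X %*% beta0)
  q0 <- if (is.null(Kg)) 0 else drop(crossprod(beta0, Kg %*% beta0))
  lt0 <- .sigma_logtarget(eta0, e2, q0)

  if (proposal == "iwls") {
    pr0 <- .iwls_at(X, Kg, beta0, eta0, e2)
    beta1 <- pr0$mean + drop(backsolve(pr0$chol, stats::rnorm(p)))
  } else {
    H <- 2 * XtX
    if (!is.null(Kg)) H <- H + Kg
    R <- .safe_chol(H)
    beta1 <- beta0 + scale * drop(backsolve(R, stats::rnorm(p)))
  }

  eta1 <- offset + drop(X %*% beta1)
  q1 <- if (is.null(Kg)) 0 else drop(crossprod(beta1, Kg %*% beta1))
  lt1 <- .sigma_logtarget(eta1, e2, q1)
  u <- stats::runif(1)
  if (!is.finite(lt1)) {
    warning("non-finite scale-side log target at proposal; rejected")
    return(list(coefficients = beta0, eta = eta0, accepted = FALSE))
  }
  if (proposal == "iwls") {
    pr1 <- .iwls_at(X, Kg, beta1, eta1, e2)
    lq_fwd <- pr0$logdet - 0.5 * sum((pr0$chol %*% (beta1 - pr0$mean))^2)
    lq_rev <- pr1$logdet - 0.5 * sum((pr1$chol %*% (beta0 - pr1$mean))^2)
    log_alpha <- lt1 - lt0 + lq_rev - lq_fwd
  } else {
    log_alpha <- lt1 - lt0
  }
  if (is.finite(log_alpha) && log(u) < log_alpha)
    list(coefficients = beta1, eta = eta1, accepted = TRUE)
  else
    list(coefficients = beta0, eta = eta0, accepted = FALSE)
}

#' Metropolis-Hastings update of a scale-side block
#'
#' Updates the coefficients of one block of the log-standard-deviation
#' predictor, targeting the full conditional
#' \eqn{\propto \prod_i N(y_i; \mu_i, e^{\eta_i})\times} smoothness prior,
#' where \eqn{\eta_i} is the block contribution plus `offset`.
#'
#' @param design Block design matrix.
#' @param residuals Residual vector \eqn{y - \mu}.
#' @param coefficients Current block coefficients.
#' @param penalty Optional [penalty_matrix()]; `NULL` for a diffuse prior.
#' @param gamma2 Smoothing variance; `Inf` for the diffuse prior.
#' @param offset Contribution of all other scale-side blocks.
#' @param proposal `"iwls"` or `"random-walk"`.
#' @param scale Step scale for the random-walk proposal (0 degenerates to
#'   an always-accepted constant chain).
#' @return List with `coefficients` and logical `accepted`.
#' @export
mh_update_sigma_block <- function(design, residuals, coefficients,
                                  penalty = NULL, gamma2 = Inf, offset = 0,
                                  proposal = c("iwls", "random-walk"),
                                  scale = 1) {
  proposal <- match.arg(proposal)
  if (any(!is.finite(residuals))) stop("residuals must be finite")
  Kg <- if (!is.null(penalty) && is.finite(gamma2))
    penalty$matrix / gamma2 else NULL
  if (length(offset) == 1L) offset <- rep(offset, nrow(design))
  st <- .mh_sigma_step(design, crossprod(design), Kg, coefficients, offset,
                       residuals^2, proposal, scale)
  list(coefficients = st$coefficients, accepted = st$accepted)
}

#' Conjugate update of a smoothing variance
#'
#' Draws \eqn{\gamma^2} from its inverse-gamma full conditional
#' IG\eqn{(a + \mathrm{rank}(K)/2,\; b + \beta'K\beta/2)}.
#'
#' @param coefficients Current block coefficients.
#' @param penalty A [penalty_matrix()] (its stored rank is used).
#' @param hyper_a,hyper_b Inverse-gamma hyperparameters.
#' @return A positive draw of the variance parameter.
#' @export
update_variance_parameter <- function(coefficients, penalty,
                                      hyper_a = 0.001, hyper_b = 0.001) {
  stopifnot(inherits(penalty, "penalty_matrix"))
  q <- drop(crossprod(coefficients, penalty$matrix %*% coefficients))
  if (q < -1e-8 * max(1, sum(coefficients^2)))
    stop("negative penalty quadratic form; penalty matrix corrupted")
  q <- max(q, 0)
  1 / stats::rgamma(1, shape = hyper_a + penalty$rank / 2,
                    rate = hyper_b + q / 2)
}

#' Run the MCMC sampler for an assembled model
#'
#' Systematic-scan sampler: Gibbs draws for every mean-side block (fixed
#' effects first, diffuse prior; then penalised smooths), MH updates for
#' every scale-side block, then inverse-gamma updates of all smoothing
#' variances. Pointwise log-likelihoods, per-block coefficient samples,
#' variance traces and acceptance rates are stored for every saved
#' iteration.
#'
#' @param model A `haz_model` from [assemble_model()].
#' @param config A [sampler_config()].
#' @return An object of class `haz_chain` with elements `samples` (lists
#'   `mu`/`sigma` of draw matrices keyed by block label, fixed effects under
#'   `"(fixed)"`), `variances`, `loglik` (saved draws x observations),
#'   `mu_mean`, `sigma_mean`, `accept`, `y`, `model`, `config`.
#' @export
run_mcmc <- function(model, config) {
  stopifnot(inherits(model, "haz_model"), inherits(config, "sampler_config"))
  set.seed(config$seed)
  y <- model$y
  n <- length(y)

  make_units <- function(side) {
    fixed <- list(list(label = "(fixed)", X = model$fixed[[side]],
                       K = NULL, rank = 0L, penalized = FALSE))
    smooth <- lapply(.side_blocks(model, side), function(bl)
      list(label = bl$label, X = bl$X,
           K = penalty_matrix(bl$K, bl$rank), rank = bl$rank,
           penalized = TRUE))
    c(fixed, unname(smooth))
  }
  mu_units <- make_units("mu")
  sg_units <- make_units("sigma")
  for (k in seq_along(sg_units)) sg_units[[k]]$XtX <- crossprod(sg_units[[k]]$X)

  beta_mu <- lapply(mu_units, function(u) numeric(ncol(u$X)))
  beta_sg <- lapply(sg_units, function(u) numeric(ncol(u$X)))
  beta_mu[[1]][1] <- mean(y)
  beta_sg[[1]][1] <- log(stats::sd(y))
  g2_mu <- rep(10, length(mu_units))
  g2_sg <- rep(10, length(sg_units))

  contrib_mu <- Map(function(u, b) drop(u$X %*% b), mu_units, beta_mu)
  contrib_sg <- Map(function(u, b) drop(u$X %*% b), sg_units, beta_sg)
  eta_mu <- Reduce(`+`, contrib_mu)
  eta_sg <- Reduce(`+`, contrib_sg)

  n_save <- floor((config$iterations - config$burnin) / config$thinning)
  samples <- list(
    mu = lapply(mu_units, function(u)
      matrix(NA_real_, n_save, ncol(u$X),
             dimnames = list(NULL, colnames(u$X)))),
    sigma = lapply(sg_units, function(u)
      matrix(NA_real_, n_save, ncol(u$X),
             dimnames = list(NULL, colnames(u$X)))))
  names(samples$mu) <- vapply(mu_units, `[[`, character(1), "label")
  names(samples$sigma) <- vapply(sg_units, `[[`, character(1), "label")
  mu_pen <- vapply(mu_units, `[[`, logical(1), "penalized")
  sg_pen <- vapply(sg_units, `[[`, logical(1), "penalized")
  var_labels <- c(
    if (any(mu_pen)) paste0("mu:", names(samples$mu)[mu_pen]),
    if (any(sg_pen)) paste0("sigma:", names(samples$sigma)[sg_pen]))
  if (is.null(var_labels)) var_labels <- character(0)
  variances <- matrix(NA_real_, n_save, length(var_labels),
                      dimnames = list(NULL, var_labels))
  loglik <- matrix(NA_real_, n_save, n)
  mu_sum <- numeric(n); sg_sum <- numeric(n)

  # variance parameters are held at their initial value for a short warm-up
  # so the coefficient blocks reach a data-supported state before the
  # smoothing variances adapt; releasing them immediately from a zero start
  # can collapse gamma^2 and freeze a block in an oversmoothed state
  warm <- min(100L, config$burnin %/% 2L)
  rw_scale <- rep(1, length(sg_units))
  acc_adapt <- rep(0L, length(sg_units))   # window counter during burn-in
  acc_post <- rep(0L, length(sg_units))    # post-burn-in acceptance
  n_post <- 0L
  adapt_window <- 50L

  for (it in seq_len(config$iterations)) {
    sigma <- exp(eta_sg)
    # --- mean-side Gibbs sweep -------------------------------------------
    w <- 1 / sigma^2
    for (k in seq_along(mu_units)) {
      u <- mu_units[[k]]
      r <- y - eta_mu + contrib_mu[[k]]
      P <- crossprod(u$X * w, u$X)
      if (u$penalized) P <- P + u$K$matrix / g2_mu[k]
      R <- .safe_chol(P)
      m <- .chol_solve(R, crossprod(u$X, w * r))
      b <- drop(m + backsolve(R, stats::rnorm(ncol(u$X))))
      beta_mu[[k]] <- b
      newc <- drop(u$X %*% b)
      eta_mu <- eta_mu - contrib_mu[[k]] + newc
      contrib_mu[[k]] <- newc
    }
    if (any(!is.finite(eta_mu)))
      stop("divergent chain: non-finite mean predictor at iteration ", it)
    # --- scale-side MH sweep ---------------------------------------------
    e2 <- (y - eta_mu)^2
    if (it == warm + 1L) {
      # re-anchor the scale intercept at its conditional mode once the mean
      # predictor has burnt in; the marginal-sd start is systematically too
      # high once the mean structure absorbs variance, and an IWLS jump
      # across that gap has a vanishing reverse-proposal density
      b <- beta_sg[[1L]]
      b[1L] <- 0.5 * log(mean(e2))
      beta_sg[[1L]] <- b
      newc <- drop(sg_units[[1L]]$X %*% b)
      eta_sg <- eta_sg - contrib_sg[[1L]] + newc
      contrib_sg[[1L]] <- newc
    }
    for (k in seq_along(sg_units)) {
      u <- sg_units[[k]]
      Kg <- if (u$penalized) u$K$matrix / g2_sg[k] else NULL
      offset <- eta_sg - contrib_sg[[k]]
      st <- .mh_sigma_step(u$X, u$XtX, Kg, beta_sg[[k]], offset, e2,
                           config$proposal, rw_scale[k])
      beta_sg[[k]] <- st$coefficients
      newc <- st$eta - offset
      eta_sg <- st$eta
      contrib_sg[[k]] <- newc
      if (st$accepted) {
        if (it <= config$burnin) acc_adapt[k] <- acc_adapt[k] + 1L
        else acc_post[k] <- acc_post[k] + 1L
      }
    }
    if (any(!is.finite(eta_sg)))
      stop("divergent chain: non-finite scale predictor at iteration ", it)
    # random-walk scale tuning, burn-in only (frozen afterwards)
    if (config$proposal == "random-walk" && it <= config$burnin &&
        it %% adapt_window == 0L) {
      rate <- acc_adapt / adapt_window
      rw_scale <- rw_scale * ifelse(rate < 0.23, 0.8,
                                    ifelse(rate > 0.44, 1.25, 1))
      acc_adapt[] <- 0L
    }
    # --- variance parameters ---------------------------------------------
    if (it > warm) {
      for (k in which(mu_pen))
        g2_mu[k] <- update_variance_parameter(beta_mu[[k]], mu_units[[k]]$K,
                                              config$hyper_a, config$hyper_b)
      for (k in which(sg_pen))
        g2_sg[k] <- update_variance_parameter(beta_sg[[k]], sg_units[[k]]$K,
                                              config$hyper_a, config$hyper_b)
    }
    # --- storage ----------------------------------------------------------
    if (it > config$burnin) {
      n_post <- n_post + 1L
      d <- it - config$burnin
      if (d %% config$thinning == 0L) {
        s <- d %/% config$thinning
        if (s <= n_save) {
          for (k in seq_along(mu_units)) samples$mu[[k]][s, ] <- beta_mu[[k]]
          for (k in seq_along(sg_units))
            samples$sigma[[k]][s, ] <- beta_sg[[k]]
          variances[s, ] <- c(g2_mu[mu_pen], g2_sg[sg_pen])
          loglik[s, ] <- stats::dnorm(y, eta_mu, exp(eta_sg), log = TRUE)
          mu_sum <- mu_sum + eta_mu
          sg_sum <- sg_sum + exp(eta_sg)
        }
      }
    }
  }

  accept <- acc_post / max(n_post, 1L)
  names(accept) <- paste0("sigma:", names(samples$sigma))
  structure(
    list(samples = samples, variances = variances, loglik = loglik,
         y = y, mu_mean = mu_sum / n_save, sigma_mean = sg_sum / n_save,
         accept = accept, rw_scale = rw_scale, n_saved = n_save,
         config = config, model = model),
    class = "haz_chain"
  )
}

#' @export
print.haz_chain <- function(x, ...) {
  cat(sprintf(
    "haz_chain: %d saved draws (%d iterations, burn-in %d, thinning %d)\n",
    x$n_saved, x$config$iterations, x$config$burnin, x$config$thinning))
  cat("scale-side acceptance: ",
      paste(sprintf("%s %.2f", names(x$accept), x$accept), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Persist a chain as a directory of delimited trace files
#'
#' Writes one tab-separated trace file per coefficient block, the variance
#' traces, the pointwise log-likelihood matrix and a JSON manifest echoing
#' the configuration, seed and acceptance rates.
#'
#' @param chain A `haz_chain`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
save_chain <- function(chain, dir) {
  stopifnot(inherits(chain, "haz_chain"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(m, f)
    utils::write.table(m, file.path(dir, f), sep = "\t", row.names = FALSE,
                       quote = FALSE)
  slug <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)
  for (side in c("mu", "sigma"))
    for (lab in names(chain$samples[[side]]))
      wr(chain$samples[[side]][[lab]],
         sprintf("trace_%s_%s.tsv", side, slug(lab)))
  wr(chain$variances, "variances.tsv")
  wr(chain$loglik, "loglik.tsv")
  wr(data.frame(y = chain$y, mu_mean = chain$mu_mean,
                sigma_mean = chain$sigma_mean), "fitted.tsv")
  manifest <- list(
    config = unclass(chain$config), n_saved = chain$n_saved,
    accept = as.list(chain$accept),
    blocks = list(mu = names(chain$samples$mu),
                  sigma = names(chain$samples$sigma)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Reload a persisted chain
#'
#' Restores the traces written by [save_chain()] for post-hoc diagnostics
#' (information criteria, effective sample sizes). The assembled model is
#' not part of the serialised form, so curve extraction requires the
#' original `haz_model`.
#'
#' @param dir Directory written by [save_chain()].
#' @return A `haz_chain` with `model = NULL`.
#' @export
load_chain <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  rd <- function(f) as.matrix(utils::read.table(file.path(dir, f),
                                                sep = "\t", header = TRUE,
                                                check.names = FALSE))
  slug <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)
  samples <- list(mu = list(), sigma = list())
  for (side in c("mu", "sigma"))
    for (lab in manifest$blocks[[side]])
      samples[[side]][[lab]] <-
        rd(sprintf("trace_%s_%s.tsv", side, slug(lab)))
  fitted <- utils::read.table(file.path(dir, "fitted.tsv"), sep = "\t",
                              header = TRUE)
  cfg <- manifest$config
  config <- sampler_config(seed = cfg$seed, iterations = cfg$iterations,
                           burnin = cfg$burnin, thinning = cfg$thinning,
                           hyper_a = cfg$hyper_a, hyper_b = cfg$hyper_b,
                           proposal = cfg$proposal)
  structure(
    list(samples = samples, variances = rd("variances.tsv"),
         loglik = unname(rd("loglik.tsv")), y = fitted$y,
         mu_mean = fitted$mu_mean, sigma_mean = fitted$sigma_mean,
         accept = unlist(manifest$accept), n_saved = manifest$n_saved,
         config = config, model = NULL),
    class = "haz_chain"
  )
}
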