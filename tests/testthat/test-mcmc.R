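# Sampler building blocks and end-to-end chain behaviour.

test_that("ridge shrinkage closed form: identity design and penalty", {
  y <- c(1.5, -0.7, 3.2)
  fc <- full_conditional_mu_block(diag(3), y, rep(1, 3),
                                  penalty_matrix(diag(3), 3L), gamma2 = 2)
  expect_equal(fc$mean, y / (1 + 1 / 2))
})

test_that("flat-prior Gibbs draws centre on the GLS estimate", {
  set.seed(11)
  n <- 60
  X <- cbind(1, rnorm(n))
  sigma <- exp(0.4 * runif(n))
  y <- drop(X %*% c(1, 2)) + rnorm(n, 0, sigma)
  w <- 1 / sigma^2
  gls <- solve(crossprod(X * w, X), crossprod(X, w * y))
  fc <- full_conditional_mu_block(X, y, sigma)
  expect_equal(fc$mean, drop(gls))
  draws <- t(replicate(3000, gibbs_update_mu_block(X, y, sigma)))
  se <- sqrt(diag(solve(fc$precision)) / 3000)
  expect_true(all(abs(colMeans(draws) - drop(gls)) < 3.5 * se))
})

test_that("variance updates follow the conjugate inverse-gamma", {
  K <- build_difference_penalty(6L, 2L)
  expect_equal(K$rank, 4L)  # rank n - order enters the shape
  # beta in the null space: quadratic form vanishes, only the rank term
  # remains in the shape (the partially improper prior still carries its
  # (gamma^2)^(-rank/2) normalisation)
  beta0 <- 2 + 3 * (1:6)
  set.seed(12)
  d0 <- replicate(40000, update_variance_parameter(beta0, K, 3, 2))
  expect_equal(mean(d0), 2 / (3 + K$rank / 2 - 1), tolerance = 0.02)
  # general beta: long-run mean matches b*/(a*-1)
  set.seed(13)
  beta <- rnorm(6)
  q <- drop(crossprod(beta, K$matrix %*% beta))
  d1 <- replicate(40000, update_variance_parameter(beta, K, 3, 2))
  expect_equal(mean(d1), (2 + q / 2) / (3 + 2 - 1), tolerance = 0.02)
  expect_error(update_variance_parameter(beta, penalty_matrix(-diag(6), 6L)),
               "corrupted")
})

test_that("zero-step random walk proposals are always accepted", {
  set.seed(14)
  e <- rnorm(50)
  b <- 0.3
  for (i in 1:10) {
    st <- mh_update_sigma_block(matrix(1, 50, 1), e, b,
                                proposal = "random-walk", scale = 0)
    expect_true(st$accepted)
    expect_equal(st$coefficients, b)
  }
})

test_that("Gibbs draws are distributed as their analytic conditional", {
  set.seed(15)
  n <- 30
  X <- cbind(runif(n), runif(n))
  K <- penalty_matrix(crossprod(diff(diag(2))), 1L)
  r <- rnorm(n); sigma <- rep(0.8, n)
  fc <- full_conditional_mu_block(X, r, sigma, K, gamma2 = 0.5)
  draws <- t(replicate(20000, gibbs_update_mu_block(X, r, sigma, K,
                                                    gamma2 = 0.5)))
  V <- solve(fc$precision)
  for (j in 1:2) {
    ks <- suppressWarnings(
      stats::ks.test(draws[, j], "pnorm", fc$mean[j], sqrt(V[j, j])))
    expect_gt(ks$p.value, 1e-4)
  }
})

test_that("same seed reproduces the chain; longer runs extend it", {
  gen <- tiny_survey(seed = 20, n1 = 120, n2 = 180)
  m <- assemble_model(make_model_grid()[[1]], gen$survey, gen$graph)
  c1 <- run_mcmc(m, quick_config(5, iterations = 150, burnin = 50,
                                 thinning = 1))
  c1b <- run_mcmc(m, quick_config(5, iterations = 150, burnin = 50,
                                  thinning = 1))
  expect_identical(c1$samples$mu$education, c1b$samples$mu$education)
  c2 <- run_mcmc(m, quick_config(5, iterations = 250, burnin = 50,
                                 thinning = 1))
  expect_identical(c1$samples$mu$education,
                   c2$samples$mu$education[1:100, ])
})

test_that("intercept-only fit recovers mean and spread of simulated data", {
  set.seed(16)
  dat <- data.frame(haz = rnorm(400, 2, 1.5))
  m <- assemble_model(model_spec(0L, list()), dat, fixed = character(0))
  ch <- run_mcmc(m, quick_config(17, iterations = 1500, burnin = 400,
                                 thinning = 2))
  expect_equal(mean(ch$samples$mu$`(fixed)`), mean(dat$haz),
               tolerance = 0.05)
  expect_equal(mean(exp(ch$samples$sigma$`(fixed)`)), sd(dat$haz),
               tolerance = 0.05)
})

test_that("tuned random-walk acceptance lands in the working range", {
  gen <- tiny_survey(seed = 21, n1 = 150, n2 = 250)
  grid <- make_model_grid()
  m <- assemble_model(grid[[2]], gen$survey, gen$graph)
  ch <- run_mcmc(m, quick_config(9, iterations = 900, burnin = 500,
                                 thinning = 2, proposal = "random-walk"))
  expect_true(all(ch$accept >= 0.1 & ch$accept <= 0.9))
})
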