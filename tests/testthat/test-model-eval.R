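# Information criteria, residuals, bands, effective sample sizes and
# effect extraction.

test_that("a constant chain has pD = 0 and DIC equal to its deviance", {
  set.seed(30)
  y <- rnorm(20)
  ll <- matrix(rep(dnorm(y, 0.2, 1.1, log = TRUE), each = 5), nrow = 5,
               byrow = FALSE)
  ch <- fake_chain(ll, y, rep(0.2, 20), rep(1.1, 20))
  dic <- compute_dic(ch)
  expect_equal(dic$pd, 0)
  expect_equal(dic$dic, -2 * sum(dnorm(y, 0.2, 1.1, log = TRUE)))
  expect_equal(compute_waic(ch)$penalty, 0)
})

test_that("DIC matches the closed form under the conjugate normal-mean posterior", {
  set.seed(31)
  n <- 200; sigma0 <- 1.3
  y <- rnorm(n, 1, sigma0)
  ybar <- mean(y)
  # analytic posterior mu | y ~ N(ybar, sigma0^2/n): pD = 1,
  # DIC = D(ybar) + 2
  draws <- rnorm(6000, ybar, sigma0 / sqrt(n))
  ll <- t(vapply(draws, function(m) dnorm(y, m, sigma0, log = TRUE),
                 numeric(n)))
  ch <- fake_chain(ll, y, rep(ybar, n), rep(sigma0, n))
  dic <- compute_dic(ch)
  dhat <- -2 * sum(dnorm(y, ybar, sigma0, log = TRUE))
  expect_equal(dic$pd, 1, tolerance = 0.1)
  expect_equal(dic$dic, dhat + 2, tolerance = 0.25)
})

test_that("WAIC is stable under thinning and undefined for one draw", {
  set.seed(32)
  n <- 150
  y <- rnorm(n)
  draws <- rnorm(2000, mean(y), 1 / sqrt(n))
  ll <- t(vapply(draws, function(m) dnorm(y, m, 1, log = TRUE), numeric(n)))
  ch <- fake_chain(ll, y, rep(mean(y), n), rep(1, n))
  w_all <- compute_waic(ch)$waic
  w_odd <- compute_waic(fake_chain(ll[seq(1, 2000, 2), ], y,
                                   rep(mean(y), n), rep(1, n)))$waic
  w_head <- compute_waic(fake_chain(ll[1:1000, ], y,
                                    rep(mean(y), n), rep(1, n)))$waic
  expect_equal(w_odd, w_all, tolerance = 0.01)
  expect_equal(w_head, w_all, tolerance = 0.01)
  expect_error(compute_waic(fake_chain(ll[1, , drop = FALSE], y,
                                       rep(mean(y), n), rep(1, n))),
               "two saved")
})

test_that("quantile residuals are standard normal under the truth", {
  set.seed(33)
  n <- 4000
  x <- runif(n)
  mu <- sin(2 * pi * x); sigma <- exp(0.3 * cos(2 * pi * x))
  y <- rnorm(n, mu, sigma)
  r <- randomized_quantile_residuals(y, mu, sigma)
  expect_equal(r[1], qnorm(pnorm(y[1], mu[1], sigma[1])))
  expect_equal(randomized_quantile_residuals(2.5, 2.5, 1), 0)
  expect_gt(stats::ks.test(r, "pnorm")$p.value, 0.01)
  # scale misspecified by a factor two doubles the residual spread
  r2 <- randomized_quantile_residuals(y, mu, sigma / 2)
  expect_equal(sd(r2), 2, tolerance = 0.1)
  expect_warning(randomized_quantile_residuals(100, 0, 1), "clipped")
})

test_that("simultaneous bands enclose pointwise bands and the sampled curves", {
  set.seed(34)
  nd <- 500; ng <- 60
  curves <- matrix(rnorm(nd * ng), nd, ng) %*% chol(
    outer(1:ng, 1:ng, function(i, j) 0.9^abs(i - j)))
  band <- simultaneous_credible_band(curves)
  a <- apply(curves, 2, quantile, probs = 0.025)
  b <- apply(curves, 2, quantile, probs = 0.975)
  expect_true(all(band$lower[, "0.95"] <= a + 1e-12))
  expect_true(all(band$upper[, "0.95"] >= b - 1e-12))
  expect_true(all(band$lower[, "0.95"] <= band$lower[, "0.8"]))
  inside <- vapply(seq_len(nd), function(t)
    all(curves[t, ] >= band$lower[, "0.95"] &
          curves[t, ] <= band$upper[, "0.95"]), logical(1))
  expect_gte(mean(inside), 0.95)
  # degenerate draws: zero-width band
  flat <- matrix(1.7, 200, 10)
  bf <- simultaneous_credible_band(flat)
  expect_equal(bf$lower[, "0.95"], rep(1.7, 10))
  expect_equal(bf$upper[, "0.95"], rep(1.7, 10))
  expect_error(simultaneous_credible_band(curves[1:50, ]), "100 draws")
})

test_that("effective sample size matches closed forms", {
  set.seed(35)
  n <- 20000
  expect_gt(effective_sample_size(rnorm(n)), 0.75 * n)
  expect_equal(effective_sample_size(rep(3, 100)), 1)
  rho <- 0.5
  x <- as.numeric(stats::arima.sim(list(ar = rho), n))
  expect_equal(effective_sample_size(x), n * (1 - rho) / (1 + rho),
               tolerance = 0.15)
})

test_that("spatial effects satisfy the per-wave constraint and cover empty districts", {
  lat <- generate_lattice_districts(3L)
  set.seed(36)
  field <- as.numeric(scale(lat$layout$row)) * 0.8
  n_per <- 30L
  d <- rep(lat$layout$district, each = n_per)
  y <- -1 + field[match(d, lat$layout$district)] + rnorm(length(d))
  dat <- data.frame(haz = y, district_id = d)
  # drop one district from the data entirely
  dat <- dat[dat$district_id != "d005", ]
  spec <- model_spec(0L, list(term_spec("spatial", "mrf", "district_id")))
  m <- assemble_model(spec, dat, lat$graph, fixed = character(0))
  ch <- run_mcmc(m, quick_config(37, iterations = 700, burnin = 200,
                                 thinning = 5))
  sp <- extract_spatial_effect(ch, "all")
  expect_equal(nrow(sp), 9L)
  expect_lt(abs(sum(sp$mean)), 1e-8)
  miss <- sp[sp$district == "d005", ]
  expect_true(is.finite(miss$mean) && miss$sd > 0)
  expect_error(extract_spatial_effect(ch, "2099"), "not present")
})

test_that("convergence summaries cover every block and variance", {
  dat <- spline_toy(38, n = 300L)
  m <- assemble_model(locscale_spline_spec(), dat, fixed = character(0))
  ch <- run_mcmc(m, quick_config(39, iterations = 500, burnin = 100,
                                 thinning = 2))
  cs <- convergence_summary(ch)
  expect_true(all(c("mu", "sigma") %in% cs$predictor))
  expect_true(all(cs$ess >= 1 & cs$ess <= ch$n_saved))
  expect_true("variance" %in% cs$parameter)
  fs <- summarize_fit(ch)
  expect_named(fs$ic, c("dic", "pd", "waic", "waic_penalty"))
  expect_true(all(fs$linear$lower <= fs$linear$mean &
                    fs$linear$mean <= fs$linear$upper))
})
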