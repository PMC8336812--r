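# Synthetic survey generator: geography, calibration, wealth index,
# determinism and qualitative effect recovery.

test_that("lattice districts have rook adjacency and full connectivity", {
  lat <- generate_lattice_districts(4L)
  expect_length(lat$graph$nodes, 16L)
  expect_equal(nrow(lat$graph$edges), 24L)   # 2 * side * (side - 1)
  deg <- lat$graph$degree
  corner <- lat$layout$district[lat$layout$row %in% c(1, 4) &
                                  lat$layout$col %in% c(1, 4)]
  interior <- lat$layout$district[lat$layout$row %in% 2:3 &
                                    lat$layout$col %in% 2:3]
  expect_true(all(deg[corner] == 2L))
  expect_true(all(deg[interior] == 4L))
  expect_equal(build_mrf_penalty(lat$graph)$rank, 15L)  # connected
  expect_error(generate_lattice_districts(1L), ">= 2")
})

test_that("the generator is deterministic given its seed", {
  g1 <- tiny_survey(seed = 5, n1 = 150, n2 = 200)
  g2 <- tiny_survey(seed = 5, n1 = 150, n2 = 200)
  expect_identical(g1$survey, g2$survey)
  g3 <- tiny_survey(seed = 6, n1 = 150, n2 = 200)
  expect_false(identical(g1$survey$haz, g3$survey$haz))
})

test_that("directly drawn covariate moments converge to their targets", {
  gen <- generate_survey(synthetic_config(
    seed = 40, n_children = c(`2013/14` = 10000L), lattice_side = 4L))
  s <- gen$survey
  tgt <- list(age_months = 29.84, mother_bmi = 22.57,
              mother_education_years = 7.81, mother_age_birth = 24.08,
              household_size = 6.60, birth_order = 2.88,
              vaccinations = 7.45)
  for (v in names(tgt)) {
    se <- sd(s[[v]]) / sqrt(nrow(s))
    expect_lt(abs(mean(s[[v]]) - tgt[[v]]), 3 * se + 0.08)
  }
  # invariants of the survey table
  expect_true(all(is.finite(s$haz)))
  expect_true(all(s$birth_order >= 1 & s$vaccinations >= 0))
  expect_true(all(s$mother_education_years <= 25))
  expect_equal(length(unique(paste(s$psu_id, s$district_id))),
               length(unique(s$psu_id)))  # each PSU in exactly one district
  # PSU coordinates stay within the district cell plus displacement slack
  lay <- gen$layout
  i <- match(s$district_id, lay$district)
  expect_true(all(s$psu_x >= (lay$col[i] - 1) * 50 - 10 &
                    s$psu_x <= lay$col[i] * 50 + 10))
})

test_that("the asset index is a sign-oriented standardised first component", {
  set.seed(41)
  a <- rbinom(300, 1, 0.4)
  perf <- data.frame(radio = a, tv = a)  # perfectly correlated pair
  s <- asset_index_pca(perf, orient_by = "radio")
  expect_equal(abs(cor(s, a + a)), 1, tolerance = 1e-10)
  assets <- data.frame(
    electricity = rbinom(300, 1, 0.3), radio = rbinom(300, 1, 0.6),
    tv = rbinom(300, 1, 0.4), car = rbinom(300, 1, 0.1))
  sc <- asset_index_pca(assets, orient_by = "electricity")
  expect_lt(abs(mean(sc)), 1e-10)
  expect_equal(sd(sc), 1, tolerance = 1e-10)
  # owning everything scores at least as high as owning nothing
  rich <- which(rowSums(assets) == 4)[1]
  poor <- which(rowSums(assets) == 0)[1]
  expect_gte(sc[rich], sc[poor])
  expect_error(asset_index_pca(data.frame(a = rep(1, 10), b = rep(0, 10))),
               "constant")
  expect_warning(
    asset_index_pca(cbind(assets, fixed = 1), orient_by = "electricity"),
    "constant")
})

test_that("regional mean deviations centre every region", {
  set.seed(42)
  x <- rnorm(120)
  reg <- sample(c("north", "south", "east"), 120, replace = TRUE)
  d <- regional_mean_deviation(x, reg)
  for (r in unique(reg)) expect_lt(abs(mean(d[reg == r])), 1e-12)
  one <- regional_mean_deviation(x, rep("all", 120))
  expect_equal(one, x - mean(x))
  expect_error(regional_mean_deviation(x, reg[-1]), "length")
})

test_that("ground truth record reproduces the response construction", {
  gen <- tiny_survey(seed = 43, n1 = 200, n2 = 300)
  tr <- gen$truth
  expect_equal(nrow(tr$components_mu), nrow(gen$survey))
  # per-wave centring: systematic part of each wave averages to the target
  for (wv in unique(gen$survey$wave)) {
    sel <- gen$survey$wave == wv
    expect_equal(mean(tr$mu[sel]),
                 tr$intercepts$mu[tr$intercepts$wave == wv])
    expect_equal(mean(tr$eta_sigma[sel]),
                 tr$intercepts$sigma[tr$intercepts$wave == wv])
  }
  # the log1p population-density transform is what the truth library uses
  lib <- default_truth_library()
  expect_equal(tr$components_mu$popdens,
               lib$mu$popdens(gen$survey$pop_density))
})

test_that("fitting recovers the rising-above-eight-years education effect", {
  gen <- generate_survey(synthetic_config(
    seed = 44, n_children = c(`2013/14` = 2500L), lattice_side = 3L))
  spec <- model_spec(0L, list(
    term_spec("education", "spline1d", "mother_education_years",
              in_mu = TRUE, in_sigma = TRUE),
    term_spec("vaccinations", "spline1d", "vaccinations",
              in_mu = TRUE, in_sigma = FALSE)))
  m <- assemble_model(spec, gen$survey, fixed = c("gender", "residence"))
  ch <- run_mcmc(m, quick_config(45, iterations = 800, burnin = 300,
                                 thinning = 5))
  eff <- extract_term_effect(ch, "education")
  gx <- eff$mother_education_years
  above <- which(gx > 8.5)
  slope <- diff(eff$mean[above])
  expect_gte(mean(slope > 0), 0.9)
  # and the curve is nearly flat below eight years
  below <- which(gx < 7.5)
  expect_lt(max(eff$mean[below]) - min(eff$mean[below]), 0.35)
})
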