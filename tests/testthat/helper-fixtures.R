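# Shared fixtures: all inputs are generated in code at test time.

# small two-wave synthetic survey on a toy lattice
tiny_survey <- function(seed = 1, n1 = 300, n2 = 500, side = 3L, psu = 4L) {
  generate_survey(synthetic_config(
    seed = seed, n_children = c(`2007` = n1, `2013/14` = n2),
    lattice_side = side, psu_per_district = psu))
}

quick_config <- function(seed, iterations = 600L, burnin = 200L,
                         thinning = 4L, ...) {
  sampler_config(seed = seed, iterations = iterations, burnin = burnin,
                 thinning = thinning, ...)
}

# heteroscedastic single-smooth toy: mu(x) = sin(2 pi x),
# log sigma(x) = 0.3 cos(2 pi x)
spline_toy <- function(seed, n = 2000L) {
  set.seed(seed)
  x <- stats::runif(n)
  data.frame(haz = stats::rnorm(n, sin(2 * pi * x),
                                exp(0.3 * cos(2 * pi * x))),
             x = x)
}

locscale_spline_spec <- function() {
  model_spec(0L, list(term_spec("sx", "spline1d", "x",
                                in_mu = TRUE, in_sigma = TRUE)))
}

# minimal hand-built chain object for testing the information criteria in
# isolation from the sampler
fake_chain <- function(loglik, y, mu_mean, sigma_mean) {
  structure(list(loglik = loglik, y = y, mu_mean = mu_mean,
                 sigma_mean = sigma_mean, n_saved = nrow(loglik),
                 samples = NULL, model = NULL),
            class = "haz_chain")
}

# total variation distance between two discrete probability vectors
tv_dist <- function(p, q) 0.5 * sum(abs(p - q))
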