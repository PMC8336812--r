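# Synthetic DHS-like survey generator with known ground truth: covariate
# marginals calibrated to published survey-wave moments, cluster (PSU)
# structure with confidentiality displacement of coordinates, a latent
# smooth spatial field over a toy district lattice, known non-linear
# covariate effects on the mean and heteroscedastic noise with known
# effects on the log standard deviation. Also provides the asset-index
# construction (first principal component of household asset indicators).

# per-wave calibration targets: response mean, covariate means/sds and
# proportions as published for the two survey waves, plus the scale
# intercept on the log-sd scale
.wave_moments <- function() {
  list(
    `2007` = list(
      n = 7936L, haz_mean = -1.59, male = 0.4962, urban = 0.3873,
      age = c(29.14, 17.03), bf = c(16.22, 7.04), birth_order = c(2.99, 2.38),
      vacc = c(5.64, 2.40), mother_age = c(24.30, 6.82), bmi = c(22.35, 3.42),
      education = c(7.18, 3.53), household = c(6.27, 2.49),
      malaria = c(0.26, 0.11), popdens = c(260.07, 831.22),
      drought = c(-0.59, 0.66), sigma_intercept = 0.28),
    `2013/14` = list(
      n = 17916L, haz_mean = -1.47, male = 0.5008, urban = 0.4301,
      age = c(29.84, 17.20), bf = c(15.69, 7.11), birth_order = c(2.88, 2.37),
      vacc = c(7.45, 2.17), mother_age = c(24.08, 6.94), bmi = c(22.57, 3.75),
      education = c(7.81, 3.64), household = c(6.60, 2.77),
      malaria = c(0.20, 0.12), popdens = c(321.87, 1098.58),
      drought = c(0.37, 0.91), sigma_intercept = 0.23)
  )
}

#' Default library of true covariate effects
#'
#' The known functions generating the synthetic response: effects on the
#' mean predictor (`mu`, keyed by covariate group) and on the log standard
#' deviation (`sigma`). The shapes mimic the qualitative patterns the model
#' is meant to detect — an education effect flat below eight years and
#' rising above, a saturating maternal-BMI effect, a linearly increasing
#' vaccination effect, a malaria effect declining above incidence 0.3, and
#' declining response variation with maternal education — and serve as test
#' fixtures with known truth, not as substantive claims.
#'
#' @return Nested list of functions.
#' @export
default_truth_library <- function() {
  list(
    mu = list(
      asset = function(a) 0.15 * a,
      education = function(e) 0.06 * pmax(e - 8, 0),
      household = function(h) -0.02 * (h - 6),
      bmi = function(b) 0.25 * tanh((b - 22) / 6),
      vacc = function(v) 0.03 * v,
      drought = function(d) -0.05 * d,
      malaria = function(m) -0.8 * pmax(m - 0.3, 0),
      popdens = function(p) 0.05 * (log1p(p) - 5),
      age_bf = function(a, b) -0.9 * stats::plogis((a - 15) / 7) -
        0.01 * b * stats::plogis((a - 30) / 6),
      bo_ma = function(bo, ma) 0.3 * exp(-((ma - 30) / 10)^2) - 0.03 * bo
    ),
    sigma = list(
      education = function(e) -0.03 * pmax(e - 8, 0),
      vacc = function(v) -0.02 * (v - 7),
      spatial = function(f) 0.4 * f
    )
  )
}

#' Configuration of the synthetic survey generator
#'
#' @param seed Integer RNG seed (mandatory).
#' @param n_children Named integer vector, children per survey wave.
#'   Defaults to the published wave sizes (7,936 and 17,916).
#' @param lattice_side Side length of the toy district lattice
#'   (`lattice_side^2` districts, rook adjacency).
#' @param psu_per_district Primary sampling units per district.
#' @param moments Per-wave calibration targets; defaults to the published
#'   wave-level descriptive moments.
#' @param effects True-effect library, see [default_truth_library()].
#' @param spatial_amplitude Standard deviation of the latent district field
#'   on the z-score scale.
#' @param wealth_correlation Latent correlation tying maternal education,
#'   household wealth and urban residence together.
#' @param gps_displacement Apply DHS-style confidentiality displacement to
#'   PSU coordinates (up to 2 km urban, 5 km rural, 10 km for 1% of rural
#'   PSUs).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             n_children = NULL,
                             lattice_side = 6L,
                             psu_per_district = 20L,
                             moments = .wave_moments(),
                             effects = default_truth_library(),
                             spatial_amplitude = 0.3,
                             wealth_correlation = 0.4,
                             gps_displacement = TRUE) {
  if (missing(seed)) stop("'seed' is required")
  lattice_side <- as.integer(lattice_side)
  if (lattice_side < 2L) stop("'lattice_side' must be >= 2")
  if (is.null(n_children)) {
    n_children <- vapply(moments, function(m) as.integer(m$n), integer(1))
  } else {
    nm <- names(n_children)
    n_children <- as.integer(n_children)
    names(n_children) <- if (is.null(nm))
      names(moments)[seq_along(n_children)] else nm
    if (!all(names(n_children) %in% names(moments)))
      stop("'n_children' names must match moment-target waves")
    moments <- moments[names(n_children)]
  }
  if (any(n_children < 1L)) stop("'n_children' must be positive")
  for (m in moments) {
    sds <- c(m$age[2], m$bf[2], m$vacc[2], m$mother_age[2], m$bmi[2],
             m$education[2], m$household[2], m$malaria[2], m$popdens[2],
             m$drought[2], m$birth_order[2])
    if (any(sds <= 0)) stop("all moment-target standard deviations must be positive")
  }
  if (spatial_amplitude < 0) stop("'spatial_amplitude' must be >= 0")
  if (abs(wealth_correlation) >= 1) stop("'wealth_correlation' must be in (-1, 1)")
  structure(list(seed = as.integer(seed), n_children = n_children,
                 lattice_side = lattice_side,
                 psu_per_district = as.integer(psu_per_district),
                 moments = moments, effects = effects,
                 spatial_amplitude = spatial_amplitude,
                 wealth_correlation = wealth_correlation,
                 gps_displacement = isTRUE(gps_displacement)),
            class = "synthetic_config")
}

#' Generate a toy district geography on a square lattice
#'
#' `side^2` districts on a regular grid with rook adjacency
#' (2 * side * (side - 1) edges) and unit-square polygons (50 km cells) for
#' choropleth export.
#'
#' @param side Lattice side length, at least 2.
#' @return List with `graph` (a [district_graph()]), `layout` (district,
#'   row, col) and `polygons` (district, xmin, ymin, xmax, ymax, in km).
#' @export
generate_lattice_districts <- function(side) {
  side <- as.integer(side)
  if (side < 2L) stop("'side' must be >= 2")
  cell <- 50  # km
  layout <- expand.grid(row = seq_len(side), col = seq_len(side),
                        KEEP.OUT.ATTRS = FALSE)
  layout <- layout[order(layout$row, layout$col), ]
  layout$district <- sprintf("d%03d", seq_len(side^2))
  idx <- function(r, c) (r - 1L) * side + c
  edges <- NULL
  for (r in seq_len(side)) for (cc in seq_len(side)) {
    if (cc < side) edges <- rbind(edges, c(idx(r, cc), idx(r, cc + 1L)))
    if (r < side) edges <- rbind(edges, c(idx(r, cc), idx(r + 1L, cc)))
  }
  graph <- district_graph(layout$district,
                          cbind(layout$district[edges[, 1]],
                                layout$district[edges[, 2]]))
  polygons <- data.frame(district = layout$district,
                         xmin = (layout$col - 1) * cell,
                         ymin = (layout$row - 1) * cell,
                         xmax = layout$col * cell,
                         ymax = layout$row * cell)
  list(graph = graph, layout = layout[, c("district", "row", "col")],
       polygons = polygons)
}

# smooth north-south district field plus an east-west ripple, standardised
# to mean zero / unit sd over districts
.lattice_field <- function(layout) {
  side <- max(layout$row)
  raw <- (layout$row - (side + 1) / 2) / side +
    0.4 * cos(pi * (layout$col - 1) / max(side - 1, 1))
  as.numeric(scale(raw))
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic DHS-like child survey with known ground truth
#'
#' Draws per-wave child records whose covariate marginals match the
#' configured moment targets, assigns children to districts and PSUs on a
#' toy lattice with optional GPS displacement, constructs a household asset
#' index by PCA over simulated asset indicators, and builds the response
#' as wave intercept + centred true covariate effects + latent district
#' field + heteroscedastic Gaussian noise. Within each wave the combined
#' systematic effects are mean-centred (mirroring the sum-to-zero
#' identifiability of the fitted model), so the expected wave mean of the
#' z-score equals the configured target.
#'
#' @param config A [synthetic_config()].
#' @return List of class `haz_synthetic` with `survey` (child-level data
#'   frame), `truth` (per-row true predictors and per-component
#'   contributions, district fields, intercepts), `graph`, `polygons` and
#'   `assets` (household asset indicator table).
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  lat <- generate_lattice_districts(config$lattice_side)
  graph <- lat$graph
  S <- length(graph$nodes)
  field0 <- .lattice_field(lat$layout)
  field <- list(`1` = config$spatial_amplitude * field0,
                `2` = 0.8 * config$spatial_amplitude * field0)
  waves <- names(config$n_children)
  lib <- config$effects
  rho <- config$wealth_correlation

  per_wave <- vector("list", length(waves))
  for (wix in seq_along(waves)) {
    wv <- waves[wix]
    m <- config$moments[[wv]]
    n <- config$n_children[[wv]]
    district <- sample(graph$nodes, n, replace = TRUE)
    psu_local <- sample.int(config$psu_per_district, n, replace = TRUE)
    psu_id <- sprintf("%s.%s.p%02d", wv, district, psu_local)

    # PSU-level environment: urban flag, remote-sensed covariates
    psus <- unique(psu_id)
    np <- length(psus)
    p_urban <- stats::rbinom(np, 1L, m$urban)
    cv2 <- (m$popdens[2] / m$popdens[1])^2
    s2 <- log(1 + cv2)
    p_popdens <- exp(stats::rnorm(np, log(m$popdens[1]) - s2 / 2, sqrt(s2))) *
      (1 + 0.5 * p_urban) / (1 + 0.5 * m$urban)
    p_malaria <- .clamp(stats::rnorm(np, m$malaria[1], m$malaria[2]),
                        0.001, 0.99)
    p_drought <- stats::rnorm(np, m$drought[1], m$drought[2])
    pix <- match(psu_id, psus)
    urban <- p_urban[pix]

    # latent household wealth, correlated with urban residence
    p_u <- m$urban
    z_w <- rho * (urban - p_u) / sqrt(p_u * (1 - p_u)) +
      sqrt(1 - rho^2) * stats::rnorm(n)
    education <- .clamp(m$education[1] +
                          m$education[2] * (rho * z_w +
                                            sqrt(1 - rho^2) * stats::rnorm(n)),
                        0, 25)

    age <- stats::runif(n, 0, 2 * m$age[1])
    z_a <- (age - m$age[1]) / m$age[2]
    bf <- .clamp(m$bf[1] + m$bf[2] * (0.6 * z_a + 0.8 * stats::rnorm(n)),
                 0, age)
    birth_order <- 1L + stats::rpois(n, m$birth_order[1] - 1)
    household <- 1L + stats::rpois(n, m$household[1] - 1)
    vacc <- pmin(stats::rpois(n, m$vacc[1]), 14L)
    mother_age <- .clamp(stats::rnorm(n, m$mother_age[1], m$mother_age[2]),
                         10, 60)
    bmi <- .clamp(stats::rnorm(n, m$bmi[1], m$bmi[2]), 13, 60)
    gender <- ifelse(stats::rbinom(n, 1L, m$male) == 1L, "boy", "girl")

    per_wave[[wix]] <- data.frame(
      wave = wv, district_id = district, psu_id = psu_id,
      gender = gender, residence = ifelse(urban == 1L, "urban", "rural"),
      age_months = age, breastfeeding_months = bf,
      birth_order = birth_order, vaccinations = vacc,
      mother_age_birth = mother_age, mother_bmi = bmi,
      mother_education_years = education, household_size = household,
      malaria_incidence = p_malaria[pix], drought_index = p_drought[pix],
      pop_density = p_popdens[pix], z_wealth = z_w,
      stringsAsFactors = FALSE)
  }
  dat <- do.call(rbind, per_wave)
  nall <- nrow(dat)

  # household asset indicators driven by latent wealth; one household per
  # child record (household size is carried as a covariate)
  alpha <- c(electricity = -1.2, radio = 0.4, tv = -0.8, fridge = -1.6,
             bicycle = 0.2, motorcycle = -2.2, car = -2.6,
             improved_water = -0.2)
  assets <- as.data.frame(lapply(alpha, function(a)
    stats::rbinom(nall, 1L, stats::plogis(a + 1.2 * dat$z_wealth))))
  dat$asset_index <- asset_index_pca(assets, orient_by = "electricity")
  dat$asset_index_dev <- regional_mean_deviation(dat$asset_index,
                                                 dat$district_id)

  # PSU coordinates on the 50 km lattice cells, with confidentiality
  # displacement (km): rural up to 5, urban up to 2, 1% of rural up to 10
  psu_tab <- unique(dat[, c("psu_id", "district_id", "residence")])
  drow <- match(psu_tab$district_id, lat$layout$district)
  base_x <- (lat$layout$col[drow] - 1) * 50 + stats::runif(nrow(psu_tab), 0, 50)
  base_y <- (lat$layout$row[drow] - 1) * 50 + stats::runif(nrow(psu_tab), 0, 50)
  if (config$gps_displacement) {
    rmax <- ifelse(psu_tab$residence == "urban", 2, 5)
    rural <- psu_tab$residence == "rural"
    far <- rural & stats::runif(nrow(psu_tab)) < 0.01
    rmax[far] <- 10
    r <- stats::runif(nrow(psu_tab), 0, rmax)
    theta <- stats::runif(nrow(psu_tab), 0, 2 * pi)
    base_x <- base_x + r * cos(theta)
    base_y <- base_y + r * sin(theta)
  }
  prow <- match(dat$psu_id, psu_tab$psu_id)
  dat$psu_x <- base_x[prow]
  dat$psu_y <- base_y[prow]

  # true systematic effects on the mean ...
  comp <- data.frame(
    asset = lib$mu$asset(dat$asset_index_dev),
    education = lib$mu$education(dat$mother_education_years),
    household = lib$mu$household(dat$household_size),
    bmi = lib$mu$bmi(dat$mother_bmi),
    vacc = lib$mu$vacc(dat$vaccinations),
    drought = lib$mu$drought(dat$drought_index),
    malaria = lib$mu$malaria(dat$malaria_incidence),
    popdens = lib$mu$popdens(dat$pop_density),
    age_bf = lib$mu$age_bf(dat$age_months, dat$breastfeeding_months),
    bo_ma = lib$mu$bo_ma(dat$birth_order, dat$mother_age_birth))
  didx <- match(dat$district_id, lat$layout$district)
  comp$spatial <- ifelse(dat$wave == waves[1], field[["1"]][didx],
                         field[["2"]][didx])
  # ... and on the log standard deviation (a spatial component mirrors the
  # regional variation of the response spread)
  comp_sg <- data.frame(
    education = lib$sigma$education(dat$mother_education_years),
    vacc = lib$sigma$vacc(dat$vaccinations),
    spatial = lib$sigma$spatial(comp$spatial))

  eff_mu <- rowSums(comp)
  eff_sg <- rowSums(comp_sg)
  true_mu <- numeric(nall)
  true_eta_sigma <- numeric(nall)
  intercepts <- data.frame(wave = waves, mu = NA_real_, sigma = NA_real_)
  for (wix in seq_along(waves)) {
    wv <- waves[wix]
    m <- config$moments[[wv]]
    sel <- dat$wave == wv
    true_mu[sel] <- m$haz_mean + eff_mu[sel] - mean(eff_mu[sel])
    true_eta_sigma[sel] <- m$sigma_intercept + eff_sg[sel] -
      mean(eff_sg[sel])
    intercepts$mu[wix] <- m$haz_mean
    intercepts$sigma[wix] <- m$sigma_intercept
  }
  dat$haz <- stats::rnorm(nall, true_mu, exp(true_eta_sigma))
  dat$z_wealth <- NULL

  fields <- data.frame(
    district = rep(lat$layout$district, times = length(waves)),
    wave = rep(waves, each = S),
    value = c(field[["1"]], field[["2"]])[seq_len(S * length(waves))])

  structure(
    list(survey = dat,
         truth = list(mu = true_mu, eta_sigma = true_eta_sigma,
                      components_mu = comp, components_sigma = comp_sg,
                      field = fields, intercepts = intercepts,
                      effects = lib),
         graph = graph, polygons = lat$polygons, layout = lat$layout,
         assets = assets),
    class = "haz_synthetic"
  )
}

#' @export
print.haz_synthetic <- function(x, ...) {
  cat(sprintf("synthetic survey: %d children, %d districts, waves: %s\n",
              nrow(x$survey), length(x$graph$nodes),
              paste(unique(x$survey$wave), collapse = ", ")))
  invisible(x)
}

#' Household wealth index by principal components
#'
#' First principal component of the standardised asset-indicator matrix,
#' sign-oriented so that a designated wealth-positive indicator loads
#' positively, and standardised to mean zero and unit standard deviation.
#'
#' @param assets Data frame of binary/ordinal asset indicators, one row per
#'   household. Indicators constant across all households are dropped.
#' @param orient_by Column name used to fix the sign of the index; defaults
#'   to the first non-constant indicator.
#' @return Numeric score vector.
#' @export
asset_index_pca <- function(assets, orient_by = NULL) {
  assets <- as.data.frame(assets)
  if (nrow(assets) < 2L) stop("at least two households are required")
  keep <- vapply(assets, function(x) stats::sd(x) > 0, logical(1))
  if (!any(keep)) stop("all asset indicators are constant")
  dropped <- names(assets)[!keep]
  if (length(dropped) > 0L)
    warning("dropping constant indicator(s): ",
            paste(dropped, collapse = ", "))
  A <- scale(as.matrix(assets[keep]))
  score <- stats::prcomp(A, center = FALSE, scale. = FALSE)$x[, 1L]
  if (is.null(orient_by)) orient_by <- names(assets)[keep][1L]
  if (!orient_by %in% names(assets)[keep])
    stop("'orient_by' must name a non-constant indicator")
  s <- sign(stats::cov(score, assets[[orient_by]]))
  if (s != 0) score <- s * score
  as.numeric(scale(score))
}

#' Deviation of a score from its regional mean
#'
#' @param score Numeric vector (e.g. the asset index).
#' @param region Region identifier per observation.
#' @return `score` minus its region mean; every region mean of the output
#'   is zero.
#' @export
regional_mean_deviation <- function(score, region) {
  if (length(score) != length(region)) stop("length mismatch")
  if (anyNA(region)) stop("missing region identifiers")
  score - stats::ave(score, region)
}
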