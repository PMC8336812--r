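# Declarative model specification and assembly of the two structured additive
# predictors eta_mu and eta_sigma: mu = eta_mu (identity link) and
# sigma = exp(eta_sigma) (log link) for a Gaussian response.

#' Specify one additive term
#'
#' @param label Term label, used to key coefficient blocks and outputs.
#' @param kind One of `"spline1d"`, `"tensor2d"`, `"mrf"`.
#' @param covariates Covariate name(s): one for `spline1d`, two for
#'   `tensor2d`, the district identifier column for `mrf`.
#' @param in_mu,in_sigma Whether the term enters the mean and/or the
#'   log-standard-deviation predictor. At least one must be `TRUE`.
#' @param degree,penalty_order B-spline degree and random-walk order.
#' @param n_intervals Interior intervals per (marginal) basis. Defaults to
#'   20 for univariate smooths and 8 per margin for tensor surfaces.
#' @param transform Optional name of a transform applied to the covariate at
#'   assembly time (currently `"log1p"`).
#' @return An object of class `haz_term`.
#' @export
term_spec <- function(label, kind = c("spline1d", "tensor2d", "mrf"),
                      covariates, in_mu = TRUE, in_sigma = FALSE,
                      degree = 3L, n_intervals = NULL, penalty_order = 2L,
                      transform = NULL) {
  kind <- match.arg(kind)
  covariates <- as.character(covariates)
  need <- switch(kind, spline1d = 1L, tensor2d = 2L, mrf = 1L)
  if (length(covariates) != need)
    stop(sprintf("term '%s' (%s) needs %d covariate(s)", label, kind, need))
  if (!in_mu && !in_sigma)
    stop(sprintf("term '%s' enters neither predictor", label))
  if (is.null(n_intervals))
    n_intervals <- if (kind == "tensor2d") 8L else 20L
  if (!is.null(transform) && !transform %in% "log1p")
    stop("unknown covariate transform: ", transform)
  structure(
    list(label = label, kind = kind, covariates = covariates,
         in_mu = isTRUE(in_mu), in_sigma = isTRUE(in_sigma),
         degree = as.integer(degree), n_intervals = as.integer(n_intervals),
         penalty_order = as.integer(penalty_order), transform = transform),
    class = "haz_term"
  )
}

#' Specify a full two-predictor model
#'
#' @param model_id Integer model identifier (1-6 for the standard grid).
#' @param terms List of [term_spec()] objects.
#' @param sigma_modelled If `FALSE` the standard deviation is constant
#'   (intercept-only scale predictor) and all `in_sigma` flags are ignored.
#' @param response Name of the response column (height-for-age z-score).
#' @return An object of class `haz_model_spec`.
#' @export
model_spec <- function(model_id, terms, sigma_modelled = TRUE,
                       response = "haz") {
  stopifnot(all(vapply(terms, inherits, logical(1), "haz_term")))
  labels <- vapply(terms, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicated term labels")
  if (!sigma_modelled)
    terms <- lapply(terms, function(tm) { tm$in_sigma <- FALSE; tm })
  for (tm in terms)
    if (tm$kind == "tensor2d" && tm$in_sigma)
      stop("tensor-product terms are not allowed in the scale predictor")
  structure(list(model_id = as.integer(model_id), terms = terms,
                 sigma_modelled = isTRUE(sigma_modelled),
                 response = response),
            class = "haz_model_spec")
}

#' @export
print.haz_model_spec <- function(x, ...) {
  lab <- vapply(x$terms, `[[`, character(1), "label")
  insg <- vapply(x$terms, `[[`, logical(1), "in_sigma")
  cat(sprintf("model %d: %d smooth terms; sigma %s\n", x$model_id,
              length(lab),
              if (x$sigma_modelled) "modelled" else "constant"))
  cat("  eta_mu   : ", paste(lab, collapse = ", "), "\n", sep = "")
  cat("  eta_sigma: ",
      if (x$sigma_modelled) paste(lab[insg], collapse = ", ") else "(intercept)",
      "\n", sep = "")
  invisible(x)
}

# the canonical term library over the survey column dictionary; sigma_ok
# marks terms allowed in the scale predictor (the two interaction surfaces
# are excluded there because their chains mix poorly)
.grid_terms <- function() {
  list(
    asset    = term_spec("asset_index", "spline1d", "asset_index_dev"),
    bo_ma    = term_spec("birth_order:mother_age", "tensor2d",
                         c("birth_order", "mother_age_birth")),
    age_bf   = term_spec("child_age:breastfeeding", "tensor2d",
                         c("age_months", "breastfeeding_months")),
    edu      = term_spec("education", "spline1d", "mother_education_years"),
    hh       = term_spec("household_size", "spline1d", "household_size"),
    bmi      = term_spec("mother_bmi", "spline1d", "mother_bmi"),
    vacc     = term_spec("vaccinations", "spline1d", "vaccinations"),
    drought  = term_spec("drought", "spline1d", "drought_index"),
    malaria  = term_spec("malaria", "spline1d", "malaria_incidence"),
    popdens  = term_spec("pop_density", "spline1d", "pop_density",
                         transform = "log1p"),
    spatial  = term_spec("spatial", "mrf", "district_id")
  )
}

#' The six-model comparison grid
#'
#' Builds the standard grid of six model specifications compared by DIC and
#' WAIC:
#' * Model 1 — all smooth terms in the mean predictor, constant sigma;
#' * Model 2 — socio-economic smooths plus the spatial term, both predictors;
#' * Model 3 — remote-sensed smooths plus the spatial term, both predictors;
#' * Model 4 — linear/categorical terms only, both predictors;
#' * Model 5 — the full model: all terms in the mean predictor, all but the
#'   two interaction surfaces in the scale predictor;
#' * Model 6 — Model 5 without the population-density term.
#'
#' The two tensor-product interaction surfaces never enter the scale
#' predictor.
#'
#' @return List of six [model_spec()] objects.
#' @export
make_model_grid <- function() {
  lib <- .grid_terms()
  socio  <- c("asset", "bo_ma", "age_bf", "edu", "hh", "bmi", "vacc")
  remote <- c("drought", "malaria", "popdens")
  sigma_ok <- function(nm) !nm %in% c("bo_ma", "age_bf")
  build <- function(id, include, sigma_modelled = TRUE) {
    terms <- lapply(include, function(nm) {
      tm <- lib[[nm]]
      tm$in_sigma <- sigma_modelled && sigma_ok(nm)
      tm
    })
    model_spec(id, terms, sigma_modelled = sigma_modelled)
  }
  list(
    build(1L, c(socio, remote, "spatial"), sigma_modelled = FALSE),
    build(2L, c(socio, "spatial")),
    build(3L, c(remote, "spatial")),
    model_spec(4L, list(), sigma_modelled = TRUE),
    build(5L, c(socio, remote, "spatial")),
    build(6L, c(socio, setdiff(remote, "popdens"), "spatial"))
  )
}

.apply_transform <- function(x, transform) {
  if (is.null(transform)) return(x)
  switch(transform, log1p = log1p(x))
}

# spline definition adapted to the data: boundary from the observed range and
# interval count reduced on covariates with few distinct values so the basis
# stays full rank; the penalty order is reduced alongside if needed
.adapt_def <- function(covariate, x, degree, n_intervals, penalty_order) {
  nd <- length(unique(x))
  if (nd < 2L) stop(sprintf("covariate '%s' is constant", covariate))
  n_intervals <- min(n_intervals, nd - 1L)
  penalty_order <- min(penalty_order, max(1L, n_intervals - 1L))
  degree <- min(degree, max(1L, nd - 1L))
  spline_basis_def(covariate, degree = degree, n_intervals = n_intervals,
                   boundary = range(x), penalty_order = penalty_order)
}

.build_block <- function(tm, data, graph, waves) {
  if (tm$kind == "spline1d") {
    x <- .apply_transform(data[[tm$covariates]], tm$transform)
    def <- .adapt_def(tm$covariates, x, tm$degree, tm$n_intervals,
                      tm$penalty_order)
    B <- build_bspline_basis(x, def)
    K <- build_difference_penalty(ncol(B), def$penalty_order)
    con <- apply_sum_to_zero_constraint(B, K)
    grid_x <- seq(def$boundary[1], def$boundary[2], length.out = 100L)
    Xg <- build_bspline_basis(grid_x, def) %*% con$transform
    grid <- list(newdata = data.frame(x = grid_x), design = Xg)
    names(grid$newdata) <- tm$covariates
  } else if (tm$kind == "tensor2d") {
    x1 <- data[[tm$covariates[1]]]
    x2 <- data[[tm$covariates[2]]]
    def1 <- .adapt_def(tm$covariates[1], x1, tm$degree, tm$n_intervals,
                       tm$penalty_order)
    def2 <- .adapt_def(tm$covariates[2], x2, tm$degree, tm$n_intervals,
                       tm$penalty_order)
    tb <- build_tensor_basis(x1, x2, def1, def2)
    con <- apply_sum_to_zero_constraint(tb$design, tb$penalty)
    g1 <- seq(def1$boundary[1], def1$boundary[2], length.out = 15L)
    g2 <- seq(def2$boundary[1], def2$boundary[2], length.out = 15L)
    nd <- expand.grid(x1 = g1, x2 = g2, KEEP.OUT.ATTRS = FALSE)
    Xg <- build_tensor_basis(nd$x1, nd$x2, def1, def2)$design %*% con$transform
    names(nd) <- tm$covariates
    grid <- list(newdata = nd, design = Xg)
  } else { # mrf, one field per survey wave sharing one variance parameter
    if (is.null(graph)) stop("spatial term requires a district graph")
    S <- length(graph$nodes)
    W <- length(waves)
    d <- data[[tm$covariates]]
    wv <- if (W > 1L) as.character(data$wave) else rep(waves, nrow(data))
    Kw <- build_mrf_penalty(graph)
    X <- matrix(0, nrow(data), S * W)
    levels <- data.frame(district = rep(graph$nodes, times = W),
                         wave = rep(waves, each = S),
                         stringsAsFactors = FALSE)
    col <- (match(wv, waves) - 1L) * S + match(d, graph$nodes)
    X[cbind(seq_len(nrow(data)), col)] <- 1
    colnames(X) <- paste(levels$district, levels$wave, sep = "@")
    Kfull <- kronecker(diag(W), Kw$matrix)
    # per-wave unweighted sum-to-zero over district coefficients, so
    # districts without observations remain estimable
    C <- kronecker(diag(W), matrix(1, 1L, S))
    con <- apply_sum_to_zero_constraint(
      X, penalty_matrix(Kfull, rank = W * Kw$rank), constraint = C)
    grid <- list(newdata = levels, design = diag(S * W) %*% con$transform)
  }
  list(label = tm$label, kind = tm$kind, covariates = tm$covariates,
       in_mu = tm$in_mu, in_sigma = tm$in_sigma,
       X = con$design, K = con$penalty$matrix, rank = con$penalty$rank,
       transform = con$transform, grid = grid)
}

#' Assemble a model for a survey table
#'
#' Builds the response vector, the effect-coded fixed-effect designs of both
#' predictors, and one constrained smooth block (design, penalty, rank,
#' back-transform, evaluation grid) per term and predictor. Rows with
#' missing values in any used column are dropped (complete-case analysis;
#' the count is reported via a message).
#'
#' @param spec A [model_spec()].
#' @param data Survey table (one row per child).
#' @param graph A [district_graph()]; required when the model has a spatial
#'   term. Districts occurring in the data must be graph nodes.
#' @param fixed Categorical covariates entering both predictors linearly via
#'   effect coding (besides the intercept). Defaults to gender, residence
#'   and survey wave; use `character(0)` for intercept-only fixed effects.
#' @param references Named character vector of reference levels for the
#'   effect coding; unnamed covariates default to the last sorted level.
#' @return An object of class `haz_model`.
#' @export
assemble_model <- function(spec, data, graph = NULL,
                           fixed = c("gender", "residence", "wave"),
                           references = c(gender = "girl",
                                          residence = "rural")) {
  stopifnot(inherits(spec, "haz_model_spec"))
  data <- as.data.frame(data)
  has_spatial <- any(vapply(spec$terms, function(tm) tm$kind == "mrf",
                            logical(1)))
  used <- unique(c(spec$response, fixed,
                   unlist(lapply(spec$terms, `[[`, "covariates")),
                   if (has_spatial && "wave" %in% names(data)) "wave"))
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols) > 0L)
    stop("columns absent from data: ", paste(missing_cols, collapse = ", "))
  for (cl in used)
    if (all(is.na(data[[cl]]))) stop("column '", cl, "' is entirely missing")
  cc <- stats::complete.cases(data[used])
  dropped <- sum(!cc)
  if (dropped > 0L)
    message(sprintf("dropping %d incomplete row(s); n = %d", dropped,
                    sum(cc)))
  data <- data[cc, , drop = FALSE]
  if (nrow(data) == 0L) stop("no complete rows")

  if (has_spatial) {
    if (is.null(graph)) stop("model has a spatial term but no graph given")
    dcol <- spec$terms[[which(vapply(spec$terms, function(tm)
      tm$kind == "mrf", logical(1)))[1]]]$covariates
    unknown <- setdiff(unique(as.character(data[[dcol]])), graph$nodes)
    if (length(unknown) > 0L)
      stop("districts not in graph: ", paste(unknown, collapse = ", "))
  }
  waves <- if ("wave" %in% names(data))
    sort(unique(as.character(data$wave))) else "all"

  fixed_design <- function(cols) {
    X <- matrix(1, nrow(data), 1L, dimnames = list(NULL, "(Intercept)"))
    for (cl in cols) {
      v <- as.character(data[[cl]])
      if (length(unique(v)) < 2L) next  # constant within this sample
      ref <- if (cl %in% names(references)) references[[cl]] else NULL
      M <- effect_code(v, reference = ref)
      colnames(M) <- paste(cl, colnames(M), sep = "_")
      X <- cbind(X, M)
    }
    X
  }
  X_fix <- fixed_design(fixed)
  X_fix_sigma <- if (spec$sigma_modelled) X_fix else
    matrix(1, nrow(data), 1L, dimnames = list(NULL, "(Intercept)"))

  blocks <- lapply(spec$terms, .build_block, data = data, graph = graph,
                   waves = waves)
  names(blocks) <- vapply(blocks, `[[`, character(1), "label")

  structure(
    list(y = as.numeric(data[[spec$response]]), n = nrow(data),
         data = data, spec = spec, graph = graph, waves = waves,
         fixed = list(mu = X_fix, sigma = X_fix_sigma),
         blocks = blocks, dropped = dropped),
    class = "haz_model"
  )
}

#' @export
print.haz_model <- function(x, ...) {
  cat(sprintf("assembled model %d: n = %d, %d smooth block(s), sigma %s\n",
              x$spec$model_id, x$n, length(x$blocks),
              if (x$spec$sigma_modelled) "modelled" else "constant"))
  invisible(x)
}

# labels of the update units of one predictor side, fixed effects first,
# then the smooths in specification order (spatial term last in the grid)
.side_blocks <- function(model, side) {
  flag <- if (side == "mu") "in_mu" else "in_sigma"
  keep <- vapply(model$blocks, `[[`, logical(1), flag)
  model$blocks[keep]
}

#' Evaluate both predictors for given coefficients
#'
#' Computes \eqn{\mu = \eta_\mu} and \eqn{\sigma = \exp(\eta_\sigma)} from a
#' coefficient set structured like the sampler output: a list with elements
#' `mu` and `sigma`, each a named list holding the fixed-effect vector under
#' `"(fixed)"` and one constrained coefficient vector per smooth block label.
#'
#' @param object A `haz_model` from [assemble_model()].
#' @param coefficients Coefficient list as described above.
#' @param ... Unused.
#' @return List with numeric vectors `mu` and `sigma` (strictly positive).
#' @export
predict.haz_model <- function(object, coefficients, ...) {
  eta <- function(side) {
    X0 <- object$fixed[[side]]
    cf <- coefficients[[side]]
    b0 <- cf[["(fixed)"]]
    if (is.null(b0) || length(b0) != ncol(X0))
      stop("fixed-effect coefficient dimension mismatch for ", side)
    out <- drop(X0 %*% b0)
    for (bl in .side_blocks(object, side)) {
      b <- cf[[bl$label]]
      if (is.null(b) || length(b) != ncol(bl$X))
        stop(sprintf("coefficient dimension mismatch for '%s' (%s)",
                     bl$label, side))
      out <- out + drop(bl$X %*% b)
    }
    out
  }
  list(mu = eta("mu"), sigma = exp(eta("sigma")))
}
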