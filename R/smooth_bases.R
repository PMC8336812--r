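# Design matrices, penalty matrices and identifiability machinery for the
# structured additive terms: penalised B-splines (P-splines), tensor-product
# interaction surfaces, Markov random field (MRF) spatial effects, sum-to-zero
# constraints and effect coding of categorical covariates.

#' Define a penalised B-spline basis
#'
#' Describes the univariate B-spline basis underlying a smooth term: the
#' polynomial degree, the number of equidistant interior intervals spanning
#' the boundary range, and the order of the random-walk (difference) penalty
#' that acts as smoothness prior on the basis coefficients.
#'
#' @param covariate Name of the covariate (used in labels and error messages).
#' @param degree Polynomial degree of the B-spline pieces; cubic by default.
#' @param n_intervals Number of equidistant interior intervals over the
#'   boundary range. The basis has `n_intervals + degree` functions.
#' @param boundary Numeric `c(low, high)`, the range covered by the basis.
#'   May be `NULL` at definition time and filled in from data later.
#' @param penalty_order Order of the random-walk difference penalty (1 or 2).
#' @return An object of class `spline_basis_def`.
#' @seealso [build_bspline_basis()], [build_difference_penalty()]
#' @export
spline_basis_def <- function(covariate, degree = 3L, n_intervals = 20L,
                             boundary = NULL, penalty_order = 2L) {
  stopifnot(is.character(covariate), length(covariate) == 1L)
  degree <- as.integer(degree)
  n_intervals <- as.integer(n_intervals)
  penalty_order <- as.integer(penalty_order)
  if (degree < 1L) stop("'degree' must be >= 1")
  if (penalty_order < 1L) stop("'penalty_order' must be >= 1")
  if (n_intervals < penalty_order + 1L)
    stop("'n_intervals' must be at least penalty_order + 1")
  if (!is.null(boundary)) {
    boundary <- as.numeric(boundary)
    if (length(boundary) != 2L || anyNA(boundary) || boundary[1] >= boundary[2])
      stop("'boundary' must be c(low, high) with low < high")
  }
  structure(
    list(covariate = covariate, degree = degree, n_intervals = n_intervals,
         boundary = boundary, penalty_order = penalty_order),
    class = "spline_basis_def"
  )
}

#' Penalty matrix container
#'
#' A symmetric positive semidefinite penalty matrix together with its rank,
#' i.e. the dimension of the penalised subspace. The null space is spanned by
#' polynomial sequences of degree below the difference order (spline case) or
#' by per-component constant vectors (MRF case).
#'
#' @param matrix Symmetric psd matrix.
#' @param rank Rank of the matrix (dimension minus null-space dimension).
#' @return An object of class `penalty_matrix` with elements `matrix`, `rank`
#'   and `null_dim`.
#' @export
penalty_matrix <- function(matrix, rank) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stop("penalty must be square")
  if (max(abs(matrix - t(matrix))) > 1e-8 * max(1, max(abs(matrix))))
    stop("penalty must be symmetric")
  matrix <- (matrix + t(matrix)) / 2
  rank <- as.integer(rank)
  if (rank < 0L || rank > nrow(matrix)) stop("invalid penalty rank")
  structure(list(matrix = matrix, rank = rank,
                 null_dim = nrow(matrix) - rank),
            class = "penalty_matrix")
}

# equidistant knot grid extending the boundary by `degree` interval widths on
# each side, as needed for a full B-spline basis on [low, high]
.knot_grid <- function(def) {
  lo <- def$boundary[1]; hi <- def$boundary[2]
  h <- (hi - lo) / def$n_intervals
  # interior knots hit the boundary exactly so observations at the range
  # limits stay representable
  c(lo - h * (def$degree:1),
    seq(lo, hi, length.out = def$n_intervals + 1L),
    hi + h * (1:def$degree))
}

#' Build a B-spline design matrix
#'
#' Evaluates the B-spline basis described by `def` at the observations `x`.
#' Every row of the result sums to one (partition of unity) and all entries
#' lie in \eqn{[0, 1]}; the matrix has `n_intervals + degree` columns.
#'
#' @param x Numeric vector of observations, all within the basis boundary.
#' @param def A [spline_basis_def()]; if its boundary is `NULL` the observed
#'   range of `x` is used.
#' @return Design matrix with `length(x)` rows.
#' @export
build_bspline_basis <- function(x, def) {
  stopifnot(inherits(def, "spline_basis_def"))
  x <- as.numeric(x)
  if (anyNA(x)) stop(sprintf("missing values in '%s'", def$covariate))
  if (is.null(def$boundary)) def$boundary <- range(x)
  lo <- def$boundary[1]; hi <- def$boundary[2]
  if (any(x < lo | x > hi))
    stop(sprintf("values of '%s' outside basis boundary [%g, %g]",
                 def$covariate, lo, hi))
  knots <- .knot_grid(def)
  B <- splines::splineDesign(knots, x, ord = def$degree + 1L)
  colnames(B) <- sprintf("%s.b%02d", def$covariate, seq_len(ncol(B)))
  B
}

#' Build a random-walk difference penalty
#'
#' Returns \eqn{K = D_d' D_d} for the order-`order` difference operator
#' \eqn{D_d}, the precision (up to the variance parameter) of a random-walk
#' prior on spline coefficients. `K` has rank `n_basis - order` and
#' annihilates polynomial sequences of degree below `order`.
#'
#' @param n_basis Number of basis coefficients.
#' @param order Random-walk order, `1 <= order < n_basis`.
#' @return A [penalty_matrix()].
#' @export
build_difference_penalty <- function(n_basis, order = 2L) {
  n_basis <- as.integer(n_basis); order <- as.integer(order)
  if (order < 1L) stop("'order' must be >= 1")
  if (order >= n_basis) stop("'order' must be smaller than 'n_basis'")
  D <- diff(diag(n_basis), differences = order)
  penalty_matrix(crossprod(D), rank = n_basis - order)
}

#' Build a tensor-product basis for a two-dimensional interaction surface
#'
#' The design is the row-wise tensor product of the two marginal B-spline
#' bases (so rows still sum to one); the penalty is the Kronecker sum
#' \eqn{K_1 \otimes I + I \otimes K_2} of the marginal difference penalties,
#' with a single shared variance parameter attached downstream.
#'
#' @param x1,x2 Covariate vectors of equal length.
#' @param def1,def2 Marginal [spline_basis_def()]s.
#' @return List with elements `design` (matrix with
#'   `ncol(B1) * ncol(B2)` columns) and `penalty` (a [penalty_matrix()]).
#' @export
build_tensor_basis <- function(x1, x2, def1, def2) {
  if (length(x1) != length(x2))
    stop("'x1' and 'x2' must have the same length")
  B1 <- build_bspline_basis(x1, def1)
  B2 <- build_bspline_basis(x2, def2)
  p1 <- ncol(B1); p2 <- ncol(B2)
  # column (j1-1)*p2 + j2 holds B1[, j1] * B2[, j2]
  B <- B1[, rep(seq_len(p1), each = p2), drop = FALSE] *
       B2[, rep(seq_len(p2), times = p1), drop = FALSE]
  colnames(B) <- paste(colnames(B1)[rep(seq_len(p1), each = p2)],
                       colnames(B2)[rep(seq_len(p2), times = p1)], sep = ":")
  K1 <- build_difference_penalty(p1, def1$penalty_order)
  K2 <- build_difference_penalty(p2, def2$penalty_order)
  K <- kronecker(K1$matrix, diag(p2)) + kronecker(diag(p1), K2$matrix)
  # null(K1 (+) K2) = null(K1) (x) null(K2) for psd marginals
  rank <- p1 * p2 - K1$null_dim * K2$null_dim
  list(design = B, penalty = penalty_matrix(K, rank = rank))
}

#' Create a district adjacency graph
#'
#' @param nodes Character vector of district labels (the node universe; may
#'   include districts that appear in no edge, i.e. islands).
#' @param edges Two-column matrix or data frame of undirected neighbour
#'   pairs referring to `nodes`. Duplicated and reversed pairs are collapsed.
#' @return An object of class `district_graph` with elements `nodes`, `edges`
#'   (two-column character matrix), `degree` (named integer vector
#'   \eqn{N_s}) and `islands`.
#' @export
district_graph <- function(nodes, edges) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicated node labels")
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  } else {
    if (ncol(edges) != 2L) stop("'edges' must have two columns")
    storage.mode(edges) <- "character"
  }
  if (nrow(edges) > 0L) {
    bad <- !(edges %in% nodes)
    if (any(bad))
      stop("edges reference unknown nodes: ",
           paste(unique(edges[bad]), collapse = ", "))
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    key <- apply(edges, 1L, function(e) paste(sort(e), collapse = "\r"))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  deg <- integer(length(nodes)); names(deg) <- nodes
  if (nrow(edges) > 0L) {
    tab <- table(factor(c(edges[, 1], edges[, 2]), levels = nodes))
    deg[] <- as.integer(tab)
  }
  structure(list(nodes = nodes, edges = edges, degree = deg,
                 islands = nodes[deg == 0L]),
            class = "district_graph")
}

#' @export
print.district_graph <- function(x, ...) {
  cat(sprintf("district graph: %d nodes, %d edges, %d island(s)\n",
              length(x$nodes), nrow(x$edges), length(x$islands)))
  invisible(x)
}

#' Build the Markov random field penalty of a district graph
#'
#' Returns the graph Laplacian \eqn{K = \mathrm{diag}(N_s) - A}, the
#' precision structure of the intrinsic MRF prior: conditional on its
#' neighbours, the effect of district \eqn{s} is Normal with mean the
#' neighbour average and variance \eqn{\tau^2 / N_s}. Row sums are zero;
#' islands contribute zero rows and are governed only by the sum-to-zero
#' constraint and the variance parameter (a warning is issued).
#'
#' @param graph A [district_graph()].
#' @return A [penalty_matrix()] with dimnames equal to the node labels.
#' @export
build_mrf_penalty <- function(graph) {
  stopifnot(inherits(graph, "district_graph"))
  n <- length(graph$nodes)
  A <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges) > 0L) {
    idx <- cbind(match(graph$edges[, 1], graph$nodes),
                 match(graph$edges[, 2], graph$nodes))
    A[idx] <- 1
    A[idx[, 2:1, drop = FALSE]] <- 1
  }
  K <- diag(graph$degree, n) - A
  dimnames(K) <- list(graph$nodes, graph$nodes)
  if (length(graph$islands) > 0L)
    warning("district graph has island(s): ",
            paste(graph$islands, collapse = ", "),
            "; their effects are identified by the sum-to-zero constraint only")
  penalty_matrix(K, rank = n - .n_components(graph))
}

# number of connected components (islands count singly)
.n_components <- function(graph) {
  n <- length(graph$nodes)
  if (n == 0L) return(0L)
  comp <- integer(n)
  adj <- vector("list", n)
  if (nrow(graph$edges) > 0L) {
    i <- match(graph$edges[, 1], graph$nodes)
    j <- match(graph$edges[, 2], graph$nodes)
    for (k in seq_along(i)) {
      adj[[i[k]]] <- c(adj[[i[k]]], j[k])
      adj[[j[k]]] <- c(adj[[j[k]]], i[k])
    }
  }
  nc <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    nc <- nc + 1L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (comp[v] != 0L) next
      comp[v] <- nc
      queue <- c(queue, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }
  nc
}

#' Apply a sum-to-zero (identifiability) constraint to a smooth block
#'
#' Reparametrises a design/penalty pair so that the fitted contribution is
#' orthogonal to the constraint directions, by default the observed column
#' sums (so fitted values sum to zero over the sample for any coefficient
#' vector). The returned `transform` maps constrained coefficients back to
#' the original basis; the penalty rank deficiency shrinks by the number of
#' constrained directions lying in its null space.
#'
#' @param design Design matrix (columns = basis coefficients).
#' @param penalty A [penalty_matrix()] of matching dimension.
#' @param constraint Optional constraint matrix with one row per linear
#'   constraint on the coefficients; defaults to `colSums(design)`.
#' @return List with `design` (constrained), `penalty` (constrained, with
#'   recomputed rank) and `transform` (matrix `Z` with
#'   `beta_original = Z %*% beta_constrained`).
#' @export
apply_sum_to_zero_constraint <- function(design, penalty, constraint = NULL) {
  stopifnot(inherits(penalty, "penalty_matrix"))
  p <- ncol(design)
  if (p != nrow(penalty$matrix))
    stop("design column count must equal penalty dimension")
  if (is.null(constraint)) constraint <- matrix(colSums(design), nrow = 1L)
  constraint <- as.matrix(constraint)
  if (ncol(constraint) != p) stop("constraint dimension mismatch")
  qrC <- qr(t(constraint))
  k <- qrC$rank
  if (k >= p) stop("constraint removes all coefficients")
  Z <- qr.Q(qrC, complete = TRUE)[, (k + 1L):p, drop = FALSE]
  Xc <- design %*% Z
  Kc <- crossprod(Z, penalty$matrix %*% Z)
  Kc <- (Kc + t(Kc)) / 2
  ev <- eigen(Kc, symmetric = TRUE, only.values = TRUE)$values
  tol <- max(abs(ev), 0) * 1e-9
  rank <- sum(ev > tol)
  list(design = Xc, penalty = penalty_matrix(Kc, rank = rank), transform = Z)
}

#' Effect-code a categorical covariate
#'
#' Codes an `L`-level factor into `L - 1` columns: the column for a
#' non-reference level takes +1 on rows at that level, -1 on rows at the
#' reference level and 0 otherwise, so coefficients express deviations from
#' an overall level and columns sum to zero on balanced samples.
#'
#' @param f Character or factor vector with at least two observed levels.
#' @param reference Reference level; defaults to the last observed level in
#'   sorted order.
#' @return Numeric matrix with one column per non-reference level, named by
#'   level.
#' @export
effect_code <- function(f, reference = NULL) {
  f <- as.character(f)
  if (anyNA(f)) stop("missing values in categorical covariate")
  levs <- sort(unique(f))
  if (length(levs) < 2L)
    stop("categorical covariate has a single observed level")
  if (is.null(reference)) reference <- levs[length(levs)]
  if (!reference %in% levs)
    stop(sprintf("reference level '%s' not present in data", reference))
  keep <- setdiff(levs, reference)
  M <- matrix(0, length(f), length(keep), dimnames = list(NULL, keep))
  for (lv in keep) M[f == lv, lv] <- 1
  M[f == reference, ] <- -1
  M
}

#' Read a district graph from edge-list and node files
#'
#' The edge file is whitespace-delimited with a header line and two columns
#' (`from`, `to`); the node file holds the full node universe, one label per
#' line below a header, so islands are representable.
#'
#' @param edge_file,node_file Paths.
#' @return A [district_graph()].
#' @export
read_district_graph <- function(edge_file, node_file) {
  nodes <- utils::read.table(node_file, header = TRUE,
                             colClasses = "character")[[1L]]
  edges <- utils::read.table(edge_file, header = TRUE,
                             colClasses = "character")
  district_graph(nodes, edges)
}

#' Write a district graph to edge-list and node files
#'
#' @param graph A [district_graph()].
#' @param edge_file,node_file Paths.
#' @return Invisibly, the graph.
#' @export
write_district_graph <- function(graph, edge_file, node_file) {
  stopifnot(inherits(graph, "district_graph"))
  utils::write.table(data.frame(node = graph$nodes), node_file,
                     row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(from = graph$edges[, 1],
                                to = graph$edges[, 2]),
                     edge_file, row.names = FALSE, quote = FALSE)
  invisible(graph)
}
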