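# Basis construction, penalties, constraints and coding.

test_that("B-spline designs form a partition of unity with the right size", {
  set.seed(1)
  for (case in list(list(deg = 3L, ni = 10L), list(deg = 2L, ni = 7L),
                    list(deg = 1L, ni = 4L))) {
    x <- runif(200)
    def <- spline_basis_def("x", degree = case$deg, n_intervals = case$ni,
                            boundary = c(0, 1))
    B <- build_bspline_basis(x, def)
    expect_equal(ncol(B), case$ni + case$deg)
    expect_lt(max(abs(rowSums(B) - 1)), 1e-12)
    expect_true(all(B >= 0 & B <= 1))
  }
  # boundary values stay representable
  def <- spline_basis_def("x", boundary = c(0, 1))
  B <- build_bspline_basis(c(0, 1), def)
  expect_lt(max(abs(rowSums(B) - 1)), 1e-12)
})

test_that("linear B-spline at a knot reproduces the hand-computed row", {
  def <- spline_basis_def("x", degree = 1L, n_intervals = 2L,
                          boundary = c(0, 1), penalty_order = 1L)
  B <- build_bspline_basis(0.5, def)
  expect_equal(unname(drop(B)), c(0, 1, 0))
})

test_that("out-of-range observations raise an error naming the covariate", {
  def <- spline_basis_def("mother_bmi", boundary = c(10, 40))
  expect_error(build_bspline_basis(c(15, 45), def), "mother_bmi")
})

test_that("difference penalties have the stated matrix, rank and null space", {
  K1 <- build_difference_penalty(4L, 1L)
  expect_equal(K1$matrix,
               matrix(c(1, -1, 0, 0,
                        -1, 2, -1, 0,
                        0, -1, 2, -1,
                        0, 0, -1, 1), 4, 4, byrow = TRUE))
  expect_equal(K1$rank, 3L)
  for (n in c(5L, 9L)) {
    expect_lt(max(abs(build_difference_penalty(n, 1L)$matrix %*% rep(1, n))),
              1e-12)
    K2 <- build_difference_penalty(n, 2L)
    expect_lt(max(abs(K2$matrix %*% seq_len(n))), 1e-12)
    expect_equal(K2$rank, n - 2L)
  }
  expect_error(build_difference_penalty(3L, 3L), "smaller")
})

test_that("tensor bases have product dimension, unit rows and the Kronecker-sum penalty", {
  set.seed(2)
  x1 <- runif(150); x2 <- runif(150)
  d13 <- spline_basis_def("a", degree = 3L, n_intervals = 10L,
                          boundary = c(0, 1))
  tb <- build_tensor_basis(x1, x2, d13, d13)
  expect_equal(ncol(tb$design), 169L)
  expect_lt(max(abs(rowSums(tb$design) - 1)), 1e-12)
  expect_error(build_tensor_basis(runif(3), runif(4), d13, d13), "length")

  # element-by-element assembly of K1 (x) I + I (x) K2 on 3x3 marginals
  dm <- spline_basis_def("m", degree = 1L, n_intervals = 2L,
                         boundary = c(0, 1), penalty_order = 1L)
  tb3 <- build_tensor_basis(x1, x2, dm, dm)
  K1 <- build_difference_penalty(3L, 1L)$matrix
  K2 <- K1
  oracle <- matrix(0, 9, 9)
  for (j1 in 1:3) for (j2 in 1:3) for (k1 in 1:3) for (k2 in 1:3) {
    r <- (j1 - 1) * 3 + j2; cc <- (k1 - 1) * 3 + k2
    oracle[r, cc] <- K1[j1, k1] * (j2 == k2) + (j1 == k1) * K2[j2, k2]
  }
  expect_equal(tb3$penalty$matrix, oracle)
})

test_that("MRF penalty is the graph Laplacian with the neighbour-average conditional", {
  g <- district_graph(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  K <- build_mrf_penalty(g)
  expect_equal(unname(K$matrix),
               matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3, 3, byrow = TRUE))
  expect_equal(K$rank, 2L)
  # conditional mean of a node with neighbours holding 2 and 4 is 3
  beta <- c(a = NA, b = 2, c = 4)
  star <- district_graph(c("a", "b", "c"),
                         rbind(c("a", "b"), c("a", "c")))
  Ks <- build_mrf_penalty(star)$matrix
  expect_equal(drop(-Ks["a", c("b", "c")] %*% beta[c("b", "c")] /
                      Ks["a", "a"]), 3)

  # brute-force conditioning of a proper approximation on a 5-node graph
  g5 <- district_graph(letters[1:5],
                       rbind(c("a", "b"), c("b", "c"), c("c", "d"),
                             c("d", "e"), c("b", "d")))
  K5 <- build_mrf_penalty(g5)$matrix
  expect_lt(max(abs(rowSums(K5))), 1e-12)
  tau2 <- 1.7
  Sig <- solve((K5 + 1e-9 * diag(5)) / tau2)
  x <- c(0.3, -1.2, 0.7, 2.1, -0.5)
  for (s in 1:5) {
    nb <- which(K5[s, ] < 0)
    w <- solve(Sig[-s, -s], x[-s])
    cond_mean <- drop(Sig[s, -s] %*% w)
    cond_var <- Sig[s, s] - drop(Sig[s, -s] %*% solve(Sig[-s, -s], Sig[-s, s]))
    expect_equal(cond_mean, mean(x[nb]), tolerance = 1e-4)
    expect_equal(cond_var, tau2 / length(nb), tolerance = 1e-4)
  }
})

test_that("island districts yield zero penalty rows and a warning", {
  g <- district_graph(c("a", "b", "lonely"), rbind(c("a", "b")))
  expect_equal(g$islands, "lonely")
  expect_warning(K <- build_mrf_penalty(g), "lonely")
  expect_equal(unname(K$matrix["lonely", ]), c(0, 0, 0))
  expect_equal(K$rank, 1L)  # 3 nodes, 2 components
})

test_that("sum-to-zero constraint centres fits, is idempotent and updates rank", {
  set.seed(3)
  X <- build_bspline_basis(runif(80), spline_basis_def("x", boundary = c(0, 1)))
  K <- build_difference_penalty(ncol(X), 2L)
  con <- apply_sum_to_zero_constraint(X, K)
  for (i in 1:5) {
    b <- rnorm(ncol(con$design))
    expect_lt(abs(sum(con$design %*% b)), 1e-10)
  }
  # projector onto the constrained space is idempotent
  P <- con$transform %*% t(con$transform)
  expect_equal(P %*% P, P, tolerance = 1e-10)
  # RW2 null space {constant, linear}: the constant is constrained out
  expect_equal(con$penalty$null_dim, 1L)
  # constant-column design: constrained contribution is identically zero
  Xc <- matrix(1, 40, 3)
  conc <- apply_sum_to_zero_constraint(
    Xc, penalty_matrix(diag(3), 3L))
  b <- rnorm(ncol(conc$design))
  expect_lt(max(abs(conc$design %*% b)), 1e-10)
})

test_that("effect coding uses +1/-1/0 with sensible errors", {
  M <- effect_code(c("boy", "girl", "boy"), reference = "girl")
  expect_equal(colnames(M), "boy")
  expect_equal(unname(drop(M)), c(1, -1, 1))
  # balanced three-level factor: columns sum to zero
  f <- rep(c("a", "b", "c"), each = 4)
  M3 <- effect_code(f)
  expect_equal(ncol(M3), 2L)
  expect_equal(unname(colSums(M3)), c(0, 0))
  expect_error(effect_code(rep("only", 5)), "single")
  expect_error(effect_code(c("a", "b"), reference = "z"), "not present")
})

test_that("district graphs round-trip through edge-list and node files", {
  g <- district_graph(c("n1", "n2", "n3", "iso"),
                      rbind(c("n1", "n2"), c("n2", "n3"), c("n2", "n1")))
  expect_equal(nrow(g$edges), 2L)  # duplicate collapsed
  expect_equal(unname(g$degree), c(1L, 2L, 1L, 0L))
  ef <- tempfile(); nf <- tempfile()
  write_district_graph(g, ef, nf)
  g2 <- read_district_graph(ef, nf)
  expect_equal(g2$nodes, g$nodes)
  expect_equal(sort(paste(g2$edges[, 1], g2$edges[, 2])),
               sort(paste(g$edges[, 1], g$edges[, 2])))
  expect_equal(g2$islands, "iso")
  expect_error(district_graph(c("a"), rbind(c("a", "a"))), "self-loops")
  expect_error(district_graph(c("a", "b"), rbind(c("a", "zz"))), "unknown")
})
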