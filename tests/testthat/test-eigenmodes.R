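test_that("Laplacian has the degree-minus-adjacency form with zero row sums", {
  A <- matrix(c(0, 2, 2, 0), 2)
  L <- build_laplacian(A)
  expect_equal(L, matrix(c(2, -2, -2, 2), 2))
  expect_equal(eigendecompose(L)$values, c(0, 4))

  expect_equal(build_laplacian(matrix(0, 3, 3)), matrix(0, 3, 3))

  # 3-node unit path: analytic spectrum {0, 1, 3}
  P <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  expect_equal(eigendecompose(build_laplacian(P))$values, c(0, 1, 3))

  expect_error(build_laplacian(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("Laplacian agrees with igraph on a random weighted graph", {
  skip_if_not_installed("igraph")
  set.seed(3)
  A <- matrix(runif(49), 7); A <- A * t(A); diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  Lg <- as.matrix(igraph::laplacian_matrix(g))
  expect_equal(unname(build_laplacian(A)), unname(Lg), tolerance = 1e-12)
})

test_that("Laplacian invariants hold on random synthetic connectomes", {
  gen <- generate_connectome(small_params(), seed = 5)
  L <- build_laplacian(gen$connectome)
  expect_lt(max(abs(rowSums(L))), 1e-9 * max(abs(L)))
  es <- eigendecompose(L)
  expect_gt(min(es$values), -1e-9 * max(es$values))
  # reconstruction Q diag(lambda) Q'
  recon <- es$vectors %*% (es$values * t(es$vectors))
  expect_lt(max(abs(recon - L)), 1e-8 * max(abs(L)))
  # orthonormality
  expect_lt(max(abs(crossprod(es$vectors) - diag(nrow(L)))), 1e-9)
})

test_that("zero eigenvalues count connected components", {
  gen <- generate_connectome(small_params(), seed = 2)
  es <- eigendecompose(build_laplacian(gen$connectome))
  scale <- max(es$values)
  expect_equal(sum(abs(es$values) <= 1e-9 * scale), 1L)

  # block-diagonal two-component graph: exactly two zeros
  A1 <- matrix(c(0, 1, 1, 0), 2)
  A <- rbind(cbind(A1, matrix(0, 2, 2)), cbind(matrix(0, 2, 2), A1))
  es2 <- eigendecompose(build_laplacian(A))
  expect_equal(sum(abs(es2$values) <= 1e-9 * max(es2$values)), 2L)

  # complete 4-graph: {0, 4, 4, 4} with a degenerate subspace
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  expect_equal(eigendecompose(build_laplacian(K4))$values, c(0, 4, 4, 4))
})

test_that("eigenmode matching finds index, sign and rank offset", {
  gen <- generate_connectome(small_params(), seed = 4)
  es <- eigendecompose(build_laplacian(gen$connectome))

  m <- match_eigenmode(es$vectors[, 3], es, 3)
  expect_equal(m$matched_index, 3L)
  expect_equal(m$sign, 1)
  expect_equal(m$inner_product, 1, tolerance = 1e-12)
  expect_equal(m$step_offset, 0)

  flipped <- es
  flipped$vectors[, 3] <- -flipped$vectors[, 3]
  m <- match_eigenmode(es$vectors[, 3], flipped, 3)
  expect_equal(m$matched_index, 3L)
  expect_equal(m$sign, -1)

  swapped <- es
  swapped$vectors[, 3:4] <- swapped$vectors[, 4:3]
  swapped$values[3:4] <- swapped$values[4:3]
  m <- match_eigenmode(es$vectors[, 3], swapped, 3)
  expect_equal(m$matched_index, 4L)
  expect_equal(m$step_offset, 1)

  # orthogonal reference triggers the no-match warning
  ref <- rep(0, length(es$values)); ref[1] <- 1
  ref <- ref - es$vectors %*% crossprod(es$vectors, ref)  # project out all
  expect_warning(match_eigenmode(as.numeric(ref), es, 2, window = Inf),
                 "orthogonal")
})

test_that("angle variance is minimized over matching and sign", {
  gen <- generate_connectome(small_params(), seed = 4)
  es <- eigendecompose(build_laplacian(gen$connectome))
  v <- es$vectors[, 2]

  expect_equal(angle_variance(v, list(es), 2)$angles[[1]], 0, tolerance = 1e-6)
  neg <- es; neg$vectors <- -neg$vectors
  expect_equal(angle_variance(v, list(neg), 2)$angles[[1]], 0, tolerance = 1e-6)

  # candidate orthogonal to the reference: 90 degrees
  orth <- es
  orth$vectors <- es$vectors[, c(1, 3, 2, 4:ncol(es$vectors))]
  expect_equal(suppressWarnings(
    angle_variance(v, list(orth), 2, window = 0)$angles[[1]]), 90)

  expect_error(angle_variance(v[-1], list(es), 2), "dimension")
})

test_that("spectrum normalization divides by the mean eigenvalue", {
  expect_equal(normalize_spectrum(c(0, 2, 4)), c(0, 1, 2))
  expect_equal(normalize_spectrum(rep(3, 5)), rep(1, 5))
  set.seed(9)
  v <- c(0, sort(runif(10)))
  expect_equal(mean(normalize_spectrum(v)), 1)
  expect_error(normalize_spectrum(c(0, 0, 0)), "all-zero")
  # excluding the zero mode normalizes by the nonzero mean
  expect_equal(normalize_spectrum(c(0, 2, 4), exclude_zero = TRUE),
               c(0, 2, 4) / 3)
})

test_that("network diffusion follows the spectral solution and conserves mass", {
  # 2-node unit edge: x1(t) = 1/2 + 1/2 exp(-2 beta t)
  L <- build_laplacian(matrix(c(0, 1, 1, 0), 2))
  x0 <- c(1, 0)
  expect_equal(solve_network_diffusion(L, x0, beta = 1, t = 0), x0)
  expect_equal(solve_network_diffusion(L, x0, beta = 1, t = log(2) / 2),
               c(0.75, 0.25))
  expect_equal(solve_network_diffusion(L, x0, beta = 1, t = 50),
               c(0.5, 0.5))

  gen <- generate_connectome(small_params(), seed = 6)
  L <- build_laplacian(gen$connectome)
  set.seed(1)
  x0 <- runif(nrow(L))
  for (tt in c(0.1, 1, 10)) {
    xt <- solve_network_diffusion(L, x0, beta = 0.7, t = tt)
    expect_equal(sum(xt), sum(x0), tolerance = 1e-9)
  }
  # long-time limit is uniform at mean(x0) on a connected graph
  expect_equal(solve_network_diffusion(L, x0, t = 1e6),
               rep(mean(x0), length(x0)), tolerance = 1e-6)
  expect_error(solve_network_diffusion(L, x0, beta = 0, t = 1), "beta")
  expect_error(solve_network_diffusion(L, x0, t = -1), "t must")
})

test_that("single eigenmode projections decay at their characteristic rate", {
  gen <- generate_connectome(small_params(), seed = 8)
  es <- eigendecompose(build_laplacian(gen$connectome))
  beta <- 0.5
  for (i in c(2, 5, 10)) {
    x0 <- es$vectors[, i]
    for (tt in c(0.05, 0.2)) {
      xt <- solve_network_diffusion(es, x0, beta = beta, t = tt)
      proj <- sum(es$vectors[, i] * xt)
      expect_equal(proj, exp(-beta * es$values[i] * tt), tolerance = 1e-9)
    }
  }
})

test_that("eigensystem export writes eigenvalue and eigenvector tables", {
  sys2 <- two_node_system(weight = 3)
  es <- eigendecompose(build_laplacian(sys2$connectome))
  paths <- write_eigensystem(es, file.path(tempdir(), "es2"),
                             node_ids = sys2$connectome$node_ids)
  vals <- read.delim(paths[["eigenvalues"]])
  expect_equal(vals$eigenvalue, c(0, 6))  # {0, 2w}
  vecs <- read.delim(paths[["eigenvectors"]])
  expect_equal(vecs$node_id, c("a", "b"))
})
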