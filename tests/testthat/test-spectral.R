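test_that("eigendecomposition is sorted, sign-fixed and reconstructs", {
  expect_equal(eigenDecompose(diag(3))$values, rep(1, 3))
  e2 <- eigenDecompose(matrix(c(0, 1, 1, 0), 2))
  expect_equal(e2$values, c(1, -1))

  set.seed(2)
  M <- matrix(rnorm(25), 5); M <- (M + t(M)) / 2
  e <- eigenDecompose(M)
  expect_lte(max(abs(M - e$vectors %*% diag(e$values) %*% t(e$vectors))),
             1e-8)
  expect_equal(crossprod(e$vectors), diag(5), tolerance = 1e-8)
  for (j in 1:5)
    expect_gt(e$vectors[which.max(abs(e$vectors[, j])), j], 0)

  expect_error(eigenDecompose(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("knee-point estimate solves the staircase example", {
  ev <- c(1, 1, seq(0.9, 0.1, by = -0.1))
  fit <- estimateNumClusters(ev)
  expect_identical(fit$k, 2L)
  expect_equal(fit$slope, -0.1)
  expect_equal(fit$plateau, 2L)
  expect_equal(fit$kRaw, 2, tolerance = 1e-10)
})

test_that("the near-1 plateau floors the cluster count", {
  # three exact connected components: three eigenvalues at 1
  blocks <- list(matrix(1, 2, 2), matrix(1, 2, 2), matrix(1, 3, 3))
  A <- matrix(0, 7, 7)
  A[1:2, 1:2] <- blocks[[1]]; A[3:4, 3:4] <- blocks[[2]]
  A[5:7, 5:7] <- blocks[[3]]
  g <- new("CommunityGraph", similarity = A, sigma = 1, sizes = rep(1L, 7))
  vals <- eigenDecompose(normalizeAdjacency(g))$values
  fit <- estimateNumClusters(vals)
  expect_gte(fit$k, 3L)

  # no decay at all: fall back to the plateau length
  flat <- rep(1, 6)
  expect_identical(estimateNumClusters(flat)$k, 6L)
})

test_that("spectral embedding has unit or zero row norms", {
  V <- cbind(c(2, 0, 0), c(0, 1, 0), c(0, 0, 0))
  emb <- spectralEmbed(V, 1)
  expect_equal(emb[, 1], c(1, 0, 0))
  emb2 <- spectralEmbed(V, 3)
  expect_true(all(abs(sqrt(rowSums(emb2^2)) - c(1, 1, 0)) < 1e-12))
})

test_that("block structure collapses same-block rows after embedding", {
  A <- matrix(0, 6, 6)
  A[1:2, 1:2] <- 1; A[3:4, 3:4] <- 1; A[5:6, 5:6] <- 1
  g <- new("CommunityGraph", similarity = A, sigma = 1, sizes = rep(1L, 6))
  e <- eigenDecompose(normalizeAdjacency(g))
  emb <- spectralEmbed(e$vectors, 3)
  for (block in list(1:2, 3:4, 5:6))
    expect_lt(max(dist(emb[block, ])), 1e-8)
})

test_that("k-means separates well-separated direction groups", {
  set.seed(6)
  emb <- rbind(matrix(rep(c(1, 0), each = 10), ncol = 2),
               matrix(rep(c(-1, 0), each = 10), ncol = 2))
  labs <- kmeansCluster(emb, 2, seed = 1)
  expect_identical(length(unique(labs[1:10])), 1L)
  expect_identical(length(unique(labs[11:20])), 1L)
  expect_false(labs[1] == labs[11])

  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  rows <- dirs[rep(1:3, each = 20), ] + matrix(rnorm(180, sd = 0.02), 60)
  truth <- rep(1:3, each = 20)
  labs3 <- kmeansCluster(rows, 3, seed = 2)
  expect_equal(fMeasure(truth, labs3), 1)

  # identical rows force the distinct-row guard down to a single cluster
  same <- matrix(1, 5, 2)
  expect_warning(labs1 <- kmeansCluster(same, 3, seed = 1), "distinct")
  expect_identical(labs1, rep(1L, 5))
})

test_that("k-means labels are rotation invariant up to permutation", {
  set.seed(14)
  base <- rbind(matrix(rnorm(40, mean = 3, sd = 0.1), ncol = 2),
                matrix(rnorm(40, mean = -3, sd = 0.1), ncol = 2))
  theta <- 0.7
  Q <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  l1 <- kmeansCluster(base, 2, seed = 5)
  l2 <- kmeansCluster(base %*% Q, 2, seed = 5)
  expect_equal(fMeasure(l1, l2), 1)
})

test_that("spectral clustering composes with override and theorem cases", {
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 0.9; A[4:6, 4:6] <- 0.8
  diag(A) <- 1
  g <- new("CommunityGraph", similarity = A, sigma = 1, sizes = rep(1L, 6))
  ng <- normalizeAdjacency(g)

  res <- spectralCluster(ng, seed = 3)
  expect_identical(numClusters(res), 2L)
  expect_identical(length(unique(clusterLabels(res)[1:3])), 1L)
  expect_identical(length(unique(clusterLabels(res)[4:6])), 1L)
  expect_false(clusterLabels(res)[1] == clusterLabels(res)[4])

  set.seed(9)
  B <- matrix(runif(36, 0.1, 1), 6); B <- (B + t(B)) / 2
  gB <- new("CommunityGraph", similarity = B, sigma = 1, sizes = rep(1L, 6))
  res4 <- spectralCluster(normalizeAdjacency(gB), kOverride = 4, seed = 3)
  expect_identical(numClusters(res4), 4L)
})
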