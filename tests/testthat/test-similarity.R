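test_that("heat kernel hits its closed-form anchor points", {
  sigma <- 1.7
  expect_equal(heatKernel(0, sigma), 1)
  expect_equal(heatKernel(sigma * sqrt(2), sigma), exp(-1))
  expect_equal(heatKernel(2 * sigma, sigma), exp(-2))
  d <- seq(0, 5, by = 0.25)
  expect_true(all(diff(heatKernel(d, sigma)) < 0))
})

test_that("community similarity equals explicit pair sums", {
  data <- rbind(c(0, 0), c(1, 0), c(0, 1))
  # two-member vs singleton at sigma 1: e^-0.5 + e^-1
  expect_equal(communitySimilarity(c(1L, 2L), 3L, data, 1),
               exp(-0.5) + exp(-1))

  # singletons at distance D reduce to the kernel itself
  expect_equal(communitySimilarity(1L, 2L, data, 0.8), heatKernel(1, 0.8))

  # coincident points: every term is 1
  co <- matrix(1, nrow = 5, ncol = 2)
  expect_equal(communitySimilarity(1:3, 4:5, co, 2), 6)
})

test_that("similarity matrix matches the double-loop oracle on small toys", {
  set.seed(13)
  for (rep in 1:4) {
    nCom <- sample(3:6, 1)
    sizes <- sample(1:4, nCom, replace = TRUE)
    n <- sum(sizes)
    data <- matrix(runif(n * 2, 0, 4), ncol = 2)
    memb <- rep(seq_len(nCom), sizes)
    comms <- unname(split(seq_len(n), memb))
    reps <- vapply(comms, `[`, integer(1), 1L)
    sampling <- new("FaithfulSampling",
                    communities = comms,
                    representatives = reps,
                    membership = memb,
                    h = 10, hTrace = 10, iterations = 1L,
                    converged = TRUE, singletonFallback = FALSE)
    sigma <- runif(1, 0.5, 2)
    S <- similarityMatrix(buildSimilarityMatrix(sampling, data, sigma))
    expect_equal(S, bruteForceSimilarityMatrix(comms, data, sigma),
                 tolerance = 1e-12)
  }
})

test_that("similarity diagonal counts ordered pairs including i = j", {
  data <- rbind(c(0, 0), c(3, 0))
  sampling <- new("FaithfulSampling",
                  communities = list(c(1L, 2L)), representatives = 1L,
                  membership = c(1L, 1L), h = 5, hTrace = 5,
                  iterations = 1L, converged = TRUE,
                  singletonFallback = FALSE)
  S <- similarityMatrix(buildSimilarityMatrix(sampling, data, 1))
  expect_equal(dim(S), c(1L, 1L))
  expect_equal(S[1, 1], 2 + 2 * heatKernel(3, 1))
})

test_that("normalization is scale invariant with unit spectral radius", {
  A <- matrix(c(0, 2, 2, 0), 2)
  g <- new("CommunityGraph", similarity = A, sigma = 1, sizes = c(1L, 1L))
  ng <- normalizeAdjacency(g)
  expect_equal(ng@matrix, matrix(c(0, 1, 1, 0), 2))
  expect_equal(sort(eigen(ng@matrix)$values), c(-1, 1))

  set.seed(21)
  A0 <- matrix(runif(16, 0.1, 2), 4)
  A0 <- (A0 + t(A0)) / 2
  g0 <- new("CommunityGraph", similarity = A0, sigma = 1, sizes = rep(1L, 4))
  g3 <- new("CommunityGraph", similarity = 3 * A0, sigma = 1,
            sizes = rep(1L, 4))
  expect_equal(normalizeAdjacency(g0)@matrix, normalizeAdjacency(g3)@matrix)

  e <- eigenDecompose(normalizeAdjacency(g0))
  expect_equal(e$values[1], 1, tolerance = 1e-10)
  # leading eigenvector proportional to sqrt of the degrees
  v <- e$vectors[, 1]
  sd <- sqrt(normalizeAdjacency(g0)@degree)
  expect_equal(v, sd / sqrt(sum(sd^2)), tolerance = 1e-8)
})

test_that("eigenvalue-1 multiplicity counts disconnected blocks", {
  set.seed(5)
  blockA <- matrix(runif(9, 0.5, 1), 3); blockA <- (blockA + t(blockA)) / 2
  blockB <- matrix(runif(4, 0.5, 1), 2); blockB <- (blockB + t(blockB)) / 2
  A <- matrix(0, 5, 5)
  A[1:3, 1:3] <- blockA
  A[4:5, 4:5] <- blockB
  g <- new("CommunityGraph", similarity = A, sigma = 1, sizes = rep(1L, 5))
  vals <- eigenDecompose(normalizeAdjacency(g))$values
  expect_equal(sum(vals > 1 - 1e-8), 2L)
})
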