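test_that("initial radius follows the bounding-box closed form", {
  unitSquare <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  expect_equal(initialRadius(unitSquare, 4), 0.25)

  square2 <- rbind(c(0, 0), c(2, 2))
  # hypothetical m below the validated minimum checked via the formula at m=2
  expect_equal(initialRadius(square2, 2), 0.5 * sqrt(4 / 2))

  cube <- rbind(c(0, 0, 0), c(1, 1, 1))
  expect_equal(initialRadius(cube, 8), 0.25)

  expect_error(initialRadius(rbind(c(1, 1), c(1, 1)), 4), "degenerate")
})

test_that("one faithful pass registers every event within L1 radius", {
  expect_equal(faithfulSample(matrix(c(3, 4), 1), h = 1, 1L)$communities,
               list(1L))

  two <- rbind(c(0, 0), c(1, 2))      # L1 distance 3
  res <- faithfulSample(two, h = 1, pickOrder = c(2L, 1L))
  expect_length(res$communities, 2L)
  expect_equal(lengths(res$communities), c(1L, 1L))

  collinear <- matrix(c(0, 1, 2), ncol = 1)
  res <- faithfulSample(collinear, h = 1.5, pickOrder = c(1L, 2L, 3L))
  expect_equal(res$communities, list(c(1L, 2L), 3L))
  expect_equal(res$representatives, c(1L, 3L))
})

test_that("faithful sampling partitions events and respects the radius", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    d <- sample(1:3, 1)
    data <- matrix(rnorm(n * d), ncol = d)
    h <- runif(1, 0.2, 1.5)
    res <- faithfulSample(data, h, sample.int(n))

    expect_equal(sum(lengths(res$communities)), n)
    expect_false(any(duplicated(unlist(res$communities))))
    for (c in seq_along(res$communities)) {
      members <- res$communities[[c]]
      expect_true(res$representatives[c] %in% members)
      repRow <- data[res$representatives[c], ]
      l1 <- apply(data[members, , drop = FALSE], 1L,
                  function(x) sum(abs(x - repRow)))
      expect_lte(max(l1), h)
    }
  }
})

test_that("a larger radius never produces more communities", {
  set.seed(77)
  data <- matrix(rnorm(400), ncol = 2)
  order <- sample.int(200)
  hs <- sort(runif(6, 0.1, 2))
  counts <- vapply(hs, function(h)
    length(faithfulSample(data, h, order)$communities), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("adaptive sampling converges on a uniform grid", {
  grid <- as.matrix(expand.grid(x = seq(0, 1, length.out = 100),
                                y = seq(0, 1, length.out = 100)))
  res <- adaptiveSample(grid, m = 1000L, seed = 9L)
  expect_true(res@converged)
  expect_gte(nCommunities(res), 500L)
  expect_lte(nCommunities(res), 1000L)
  expect_equal(length(res@hTrace), res@iterations)
  expect_equal(sum(communitySizes(res)), nrow(grid))
})

test_that("tiny inputs short-circuit to flagged singleton communities", {
  data <- matrix(rnorm(20), ncol = 2)     # n = 10 < m/2 = 50
  res <- adaptiveSample(data, m = 100L, seed = 1L)
  expect_true(res@singletonFallback)
  expect_false(res@converged)
  expect_identical(nCommunities(res), 10L)
  expect_identical(membership(res), 1:10)
})

test_that("uniform sampling honours count and seed contracts", {
  data <- matrix(rnorm(60), ncol = 2)
  expect_setequal(uniformSample(data, 30, seed = 4), 1:30)
  expect_length(uniformSample(data, 1, seed = 4), 1L)
  expect_identical(uniformSample(data, 10, seed = 7),
                   uniformSample(data, 10, seed = 7))
  expect_error(uniformSample(data, 31, seed = 1), "between 1")
})

test_that("nearest-representative labels match a brute-force scan", {
  data <- rbind(c(0, 0), c(5, 5), c(1, 1), c(4, 4), c(2.5, 2.5))
  reps <- c(1L, 2L)
  labs <- nearestRepresentativeLabels(data, reps, c(10L, 20L))
  # exhaustive scan with the tie (event 5 equidistant) going to the first rep
  expected <- integer(5)
  for (e in 1:5) {
    d <- sqrt(rowSums((data[reps, , drop = FALSE] -
                       rep(data[e, ], each = 2))^2))
    expected[e] <- c(10L, 20L)[which.min(d)]
  }
  expect_identical(labs, expected)
  expect_identical(labs[5], 10L)

  # coincident event takes its representative's label; single rep labels all
  expect_identical(nearestRepresentativeLabels(data, 2L, 7L),
                   rep(7L, 5))
})
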