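test_that("objective intermediates match hand evaluation on two points", {
  X <- matrix(c(1, 5, -2, 0), 2, 2)
  y <- c(0, 1)
  bd <- nca_objective(c(0, 0), X, y, sigma = 1, lambda = 0)
  expect_equal(bd$d_w, matrix(0, 2, 2))
  expect_equal(bd$p_ij[1, 2], 1)
  expect_equal(bd$p_ij[2, 1], 1)
  expect_equal(bd$l_i, c(1, 1))
  expect_equal(bd$objective, 1)
})

test_that("weighted distance follows the squared-weight L1 form", {
  X <- rbind(c(1, 0), c(0, 2))
  bd <- nca_objective(c(2, 1), X, c(0, 0), sigma = 1, lambda = 0)
  expect_equal(bd$d_w[1, 2], 2^2 * 1 + 1^2 * 2) # = 6
})

test_that("neighbour probabilities are a proper distribution for any weights", {
  set.seed(8)
  for (i in 1:5) {
    X <- matrix(rnorm(7 * 4), 7)
    bd <- nca_objective(runif(4, 0, 2), X, rnorm(7), sigma = runif(1, 0.5, 3))
    expect_equal(rowSums(bd$p_ij), rep(1, 7), tolerance = 1e-12)
    expect_true(all(bd$p_ij >= 0))
  }
})

test_that("objective matches the brute-force pairwise oracle to 1e-12", {
  set.seed(5)
  for (n in c(4, 8)) {
    X <- matrix(rnorm(n * 3), n)
    y <- rnorm(n)
    w <- runif(3, 0, 1.5)
    expect_equal(nca_objective(w, X, y, sigma = 1.3, lambda = 0.07)$objective,
                 nca_bruteforce(w, X, y, sigma = 1.3, lambda = 0.07),
                 tolerance = 1e-12)
  }
})

test_that("analytic gradient matches central finite differences", {
  set.seed(6)
  X <- matrix(rnorm(6 * 3), 6)
  y <- rnorm(6)
  w <- runif(3, 0.5, 1.5)
  g <- nca_gradient(w, X, y, sigma = 1, lambda = 0.1)
  h <- 1e-5
  fd <- vapply(1:3, function(r) {
    wp <- w; wp[r] <- w[r] + h
    wm <- w; wm[r] <- w[r] - h
    (nca_objective(wp, X, y, 1, 0.1)$objective -
       nca_objective(wm, X, y, 1, 0.1)$objective) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-8)), 1e-5)
})

test_that("penalty term contributes 2*lambda*w; duplicated rows zero the loss gradient", {
  X <- rbind(c(1, 2), c(1, 2), c(1, 2), c(1, 2))
  y <- c(0, 1, 0, 1)
  w <- c(0.7, -0.3)
  # all pairwise distances vanish, so only the penalty derivative remains
  expect_equal(nca_gradient(w, X, y, sigma = 1, lambda = 1), 2 * w)
  # at w = 0 the loss term is stationary by symmetry
  set.seed(3)
  X2 <- matrix(rnorm(10), 5, 2)
  expect_equal(nca_gradient(rep(0, 2), X2, rnorm(5), 1, 0), c(0, 0))
})

test_that("pure-noise responses shrink every weight at the default penalty", {
  set.seed(12)
  ok <- 0
  for (s in 1:10) {
    X <- matrix(rnorm(100 * 5), 100)
    y <- rnorm(100)
    m <- fit_nca(X, y, seed = s)
    if (max(abs(m$w)) < 0.1) ok <- ok + 1
  }
  expect_gte(ok, 8)
})

test_that("informative features beat decoys under the 1% rule at the defaults", {
  set.seed(1)
  n <- 300
  X <- matrix(rnorm(n * 10), n)
  colnames(X) <- paste0("f", 1:10)
  y <- 3 * X[, 1] - 2 * X[, 2] + rnorm(n, 0, 0.3)
  ok <- 0
  for (s in 1:10) {
    sel <- select_features(fit_nca(X, y, seed = s))
    if (all(c(1, 2) %in% sel) && !any(3:10 %in% sel)) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("feature rescaling changes neither selection nor the optimum", {
  set.seed(2)
  n <- 120
  X <- matrix(rnorm(n * 5), n)
  y <- 2 * X[, 1] - X[, 3] + rnorm(n, 0, 0.2)
  m1 <- fit_nca(X, y, seed = 4)
  X10 <- X
  X10[, 1] <- X10[, 1] * 10
  m2 <- fit_nca(X10, y, seed = 4)
  expect_equal(select_features(m1), select_features(m2))
  expect_equal(m1$objective, m2$objective, tolerance = 1e-6)
})

test_that("the 1%-of-maximum selection rule on squared weights", {
  m <- structure(list(w2 = c(0.8, 0.02, 0.004)), class = "nca_model")
  expect_equal(select_features(m), c(1L, 2L)) # threshold 0.008
  expect_equal(select_features(structure(list(w2 = 1), class = "nca_model")), 1L)
  m3 <- structure(list(w2 = rep(0.5, 4)), class = "nca_model")
  expect_equal(select_features(m3), 1:4)
  expect_error(select_features(structure(list(w2 = c(0, 0)),
                                         class = "nca_model")), "zero")
})

test_that("degenerate inputs are rejected", {
  expect_error(nca_objective(1, matrix(1, 1, 1), 1), "2 points")
  expect_error(fit_nca(matrix(1, 1, 1), 1), "2 points")
})

test_that("tidy/glance expose weights and fit summary", {
  set.seed(9)
  X <- matrix(rnorm(40 * 3), 40)
  colnames(X) <- c("a", "b", "c")
  m <- fit_nca(X, X[, 1] + rnorm(40, 0, 0.1), seed = 1)
  td <- tidy(m)
  expect_named(td, c("feature", "weight", "weight_sq", "selected"))
  expect_equal(td$feature, c("a", "b", "c"))
  gl <- glance(m)
  expect_true(all(c("objective", "lambda", "converged") %in% names(gl)))
})
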