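test_that("full-rank eigenpairs reconstruct the sample covariance", {
  set.seed(21)
  X <- random_binary_matrix(300, 10)
  m <- estimate_background_model(X, k = 10)
  S_rec <- m$eigenvectors %*% diag(m$eigenvalues, m$k) %*% t(m$eigenvectors)
  expect_lt(max(abs(S_rec - cov(X))), 1e-8)
  expect_equal(m$mu, colMeans(X))
})

test_that("independent Bernoulli columns give eigenvalues near p(1-p)", {
  set.seed(22)
  X <- random_binary_matrix(5000, 10, p = 0.3)
  m <- estimate_background_model(X, k = 10)
  expect_true(all(abs(m$eigenvalues - 0.21) < 0.04))
  # cross-check against a dense eigensolver on the raw covariance
  expect_equal(m$eigenvalues, eigen(cov(X), symmetric = TRUE)$values,
               tolerance = 1e-10)
})

test_that("variance explained lies in (0,1] and is non-decreasing in k", {
  set.seed(23)
  sim <- simulate_correlated_annotations(n_annotations = 40,
                                         n_variants = 800, seed = 23)
  ve <- vapply(c(1, 5, 10, 20, 40), function(k) {
    estimate_background_model(sim, k = k)$variance_explained
  }, numeric(1))
  expect_true(all(ve > 0 & ve <= 1 + 1e-12))
  expect_true(all(diff(ve) >= -1e-12))
})

test_that("degenerate and invalid inputs are rejected", {
  X <- matrix(1, nrow = 50, ncol = 4)
  expect_error(estimate_background_model(X, k = 2), "degenerate")
  expect_error(estimate_background_model(random_binary_matrix(50, 4), k = 0),
               "k must be")
  expect_error(estimate_background_model(random_binary_matrix(10, 4), k = 30),
               "k\\+1")
})

test_that("whitening: x = mu maps to zero; quadratic form matches the dense oracle", {
  set.seed(24)
  X <- random_binary_matrix(200, 8)
  m <- estimate_background_model(X, k = 8)
  expect_equal(whiten(m$mu, m), rep(0, 8))
  oracle <- dense_oracle(X, k = 8)
  for (i in 1:20) {
    x <- rbinom(8, 1, 0.5)
    w <- runif(8, 0.5, 4)
    if (sum((x - m$mu)^2) == 0) next
    z <- whiten(x, m, w)
    expect_equal(sum(z^2), oracle$mahalanobis(x, w)^2, tolerance = 1e-8)
  }
})

test_that("whitening dimension mismatch errors; missing entries impute to mu", {
  set.seed(25)
  X <- random_binary_matrix(100, 6)
  m <- estimate_background_model(X, k = 6)
  expect_error(whiten(rep(1, 5), m), "length")
  x <- c(1, NA, 0, NA, 1, 0)
  x_imp <- x; x_imp[is.na(x)] <- m$mu[is.na(x)]
  expect_equal(whiten(x, m), whiten(x_imp, m))
})

test_that("Mahalanobis reduces to Euclidean distance under identity covariance", {
  m <- background_model(mu = c(0, 0), eigenvalues = c(1, 1),
                        eigenvectors = diag(2))
  expect_equal(mahalanobis_score(c(3, 4), m), 5)
  expect_equal(mahalanobis_score(c(0, 0), m), 0)
})

test_that("cosine: self-angle is 1, constructed orthogonal vector gives 0", {
  m <- background_model(mu = c(0, 0), eigenvalues = c(1, 1),
                        eigenvectors = diag(2))
  expect_equal(cosine_to_ones(c(1, 1), m), 1)
  expect_equal(cosine_to_ones(c(1, -1), m), 0)   # (1,-1) _|_ (1,1)
  expect_error(cosine_to_ones(c(0, 0), m), "undefined")
})

test_that("score, cosine and Mahalanobis match the dense-oracle formulas on random instances", {
  set.seed(26)
  for (rep in 1:20) {
    n <- sample(50:200, 1)
    d <- sample(5:20, 1)
    X <- random_binary_matrix(n, d, p = runif(1, 0.2, 0.6))
    k <- sample(2:d, 1)
    m <- estimate_background_model(X, k = k)
    k <- m$k  # near-zero eigenvalues may have been dropped
    oracle <- dense_oracle(X, k = k)
    w <- if (rep %% 2) rep(1, d) else runif(d, 0.5, 4)
    x <- rbinom(d, 1, 0.5)
    if (oracle$mahalanobis(x, w) < 1e-6) next
    expect_equal(mahalanobis_score(x, m, w), oracle$mahalanobis(x, w),
                 tolerance = 1e-8)
    expect_equal(cosine_to_ones(x, m, w), oracle$cosine(x, w),
                 tolerance = 1e-8)
    expect_equal(pines_score(x, m, w), oracle$score(x, w), tolerance = 1e-8)
  }
})

test_that("all-1 vector attains score 0; every score is non-negative", {
  set.seed(27)
  for (rep in 1:5) {
    X <- random_binary_matrix(300, 12, p = 0.35)
    m <- estimate_background_model(X, k = sample(3:12, 1))
    w <- if (rep %% 2) NULL else runif(12, 0.2, 5)
    expect_lt(pines_score(rep(1, 12), m, w), 1e-6)
    sc <- score_matrix(X, m, w)
    ok <- !sc$undefined
    expect_true(all(sc$raw_score[ok] >= 0))
    one_row <- rowSums(X == 1) == 12
    expect_true(all(sc$raw_score[ok & !one_row] >
                      pines_score(rep(1, 12), m, w)))
  }
})

test_that("scaling W by c > 0 scales scores by 1/c^2 and preserves rankings", {
  set.seed(28)
  X <- random_binary_matrix(400, 10, p = 0.3)
  m <- estimate_background_model(X, k = 10)
  sc1 <- score_matrix(X, m, rep(1, 10))
  for (c_ in c(0.5, 2, 7)) {
    sc2 <- score_matrix(X, m, rep(c_, 10))
    expect_equal(sc2$raw_score, sc1$raw_score / c_^2, tolerance = 1e-10)
    expect_equal(order(sc2$raw_score), order(sc1$raw_score))
  }
})

test_that("permuting annotation columns (with mu, W permuted) leaves scores unchanged", {
  set.seed(29)
  X <- random_binary_matrix(300, 9, p = 0.4)
  w <- runif(9, 0.5, 3)
  m <- estimate_background_model(X, k = 6)
  perm <- sample(9)
  m_p <- estimate_background_model(X[, perm], k = 6)
  for (i in 1:10) {
    x <- rbinom(9, 1, 0.5)
    if (sum((x - m$mu)^2) == 0) next
    expect_equal(pines_score(x[perm], m_p, w[perm]), pines_score(x, m, w),
                 tolerance = 1e-8)
  }
})

test_that("background model round-trips through its archive", {
  set.seed(30)
  X <- random_binary_matrix(100, 6)
  m <- estimate_background_model(X, k = 4)
  f <- withr::local_tempfile(fileext = ".rds")
  write_background_model(m, f)
  expect_true(file.exists(paste0(f, ".yaml")))
  m2 <- read_background_model(f)
  expect_equal(m2$eigenvalues, m$eigenvalues)
  x <- rbinom(6, 1, 0.5)
  expect_equal(pines_score(x, m2), pines_score(x, m))
})
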