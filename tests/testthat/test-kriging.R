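test_that("the Gaussian correlation matches hand-evaluated cases", {
  x <- c(0.3, -1.2)
  expect_equal(krig_correlation(x, x, c(1, 1)), 1)
  expect_equal(krig_correlation(0, 1, 1), exp(-1))
  expect_equal(krig_correlation(c(0, 0), c(1, 1), c(0.5, 0.5)), exp(-1))
  expect_equal(krig_correlation(c(0, 2), c(1, 0), c(2, 0.25)), exp(-(2 + 1)))
  expect_error(krig_correlation(1:2, 1:3, c(1, 1)), class = "waterkrig_dimension_error")
  expect_error(krig_correlation(1, 2, -1), class = "waterkrig_domain_error")
})

test_that("correlation matrix factorization is exact and guarded", {
  X <- matrix(seq(0, 4), ncol = 1)
  fac <- krig_correlation_matrix(X, theta = 1e6)
  expect_equal(fac$R, diag(5) + diag(fac$nugget, 5), tolerance = 1e-12)

  # duplicated rows with no nugget available -> conditioning error
  Xdup <- matrix(c(1, 1), ncol = 1)
  expect_error(krig_correlation_matrix(Xdup, theta = 1, nugget = 0, nugget_max = 0),
               class = "waterkrig_conditioning_error")
  # escalation rescues it and is flagged
  fac2 <- krig_correlation_matrix(Xdup, theta = 1, nugget = 1e-16, nugget_max = 1e-6)
  expect_true(fac2$escalated)

  withr::with_seed(12, {
    X5 <- matrix(runif(10), 5, 2)
    fac5 <- krig_correlation_matrix(X5, theta = c(0.8, 1.7))
    expect_equal(fac5$log_det, log(det(fac5$R)), tolerance = 1e-8)
  })
})

test_that("concentrated likelihood collapses correctly in limiting cases", {
  X <- matrix(seq_len(6), ncol = 1)
  y_const <- rep(3.5, 6)
  lk <- krig_likelihood(X, y_const, theta = 1)
  expect_equal(lk$mu_hat, 3.5, tolerance = 1e-8)
  expect_equal(lk$sigma2_hat, 0, tolerance = 1e-10)
  expect_true(is.finite(lk$L))  # sigma2 floored before the log

  withr::with_seed(3, {
    y <- rnorm(6)
    lk2 <- krig_likelihood(X, y, theta = 1e8)  # R -> identity
    expect_equal(lk2$mu_hat, mean(y), tolerance = 1e-6)
    expect_equal(lk2$sigma2_hat, mean((y - mean(y))^2), tolerance = 1e-6)
  })
})

test_that("likelihood, weights and predictions match the dense oracle", {
  withr::with_seed(21, {
    for (rep in 1:8) {
      n <- sample(2:8, 1); d <- sample(1:4, 1)
      X <- matrix(runif(n * d, 0, 3), n, d)
      y <- rnorm(n)
      theta <- 10^runif(d, -2, 1)
      Xq <- matrix(runif(3 * d, 0, 3), 3, d)
      # both routes use the same (generous) nugget so the comparison probes the
      # formulas, not the conditioning of a nearly singular R
      oracle <- dense_krig_oracle(X, y, theta, nugget = 1e-6, Xq = Xq)

      lk <- krig_likelihood(X, y, theta, nugget = 1e-6)
      expect_equal(lk$L, oracle$L, tolerance = 1e-8)
      expect_equal(lk$mu_hat, oracle$mu_hat, tolerance = 1e-8)
      expect_equal(lk$sigma2_hat, oracle$sigma2_hat, tolerance = 1e-8)

      df <- as.data.frame(X); names(df) <- paste0("f", seq_len(d)); df$value <- y
      m <- krig_fit(df, theta = theta, control = krig_control(nugget = 1e-6))
      expect_equal(m$weights, oracle$weights, tolerance = 1e-8)
      dq <- as.data.frame(Xq); names(dq) <- paste0("f", seq_len(d))
      expect_equal(predict(m, dq), oracle$pred, tolerance = 1e-8)
    }
  })
})

test_that("prediction interpolates training points and reverts to the mean far away", {
  withr::with_seed(5, {
    d <- data.frame(x1 = runif(12, 0, 2), x2 = runif(12, 0, 2))
    d$value <- cos(2 * d$x1) + 0.5 * d$x2
    m <- krig_fit(d, control = krig_control(particles = 8, iterations = 20, seed = 2))
    expect_lt(max(abs(predict(m, d) - d$value) / pmax(abs(d$value), 1)), 1e-6)
    far <- data.frame(x1 = 1e4, x2 = -1e4)
    expect_equal(predict(m, far), m$mu_hat, tolerance = 1e-10)
    expect_error(predict(m, matrix(1, 1, 5)), class = "waterkrig_dimension_error")
  })
})

test_that("the predictor is shift invariant and scale equivariant at fixed theta", {
  withr::with_seed(9, {
    d <- data.frame(x = runif(10, 0, 3))
    d$value <- sin(d$x)
    theta <- 2
    q <- data.frame(x = runif(20, 0, 3))
    base <- predict(krig_fit(d, theta = theta), q)
    d_shift <- d; d_shift$value <- d$value + 7.5
    expect_equal(predict(krig_fit(d_shift, theta = theta), q), base + 7.5,
                 tolerance = 1e-8)
    d_scale <- d; d_scale$value <- d$value * -3.2
    expect_equal(predict(krig_fit(d_scale, theta = theta), q), base * -3.2,
                 tolerance = 1e-8)
  })
})

test_that("degenerate training sets are rejected; zero response gives zero weights", {
  expect_error(krig_fit(data.frame(x = 1, value = 2)), class = "waterkrig_domain_error")
  m <- krig_fit(data.frame(x = c(0, 1), value = c(0, 0)), theta = 1)
  expect_equal(m$weights, c(0, 0))
  expect_equal(m$mu_hat, 0)
})

test_that("hyperparameter search is deterministic and beats a dense grid scan", {
  withr::with_seed(14, {
    X <- matrix(runif(40, 0, 3), 20, 2)
    y <- sin(X[, 1]) + 0.3 * X[, 2]^2
  })
  ctrl <- krig_control(particles = 15, iterations = 40, seed = 77)
  o1 <- krig_optimize(X, y, ctrl)
  o2 <- krig_optimize(X, y, ctrl)
  expect_identical(o1$theta, o2$theta)
  expect_identical(o1$L, o2$L)

  # 50 x 50 log-grid oracle
  grid <- as.matrix(expand.grid(g1 = seq(-6, 3, length.out = 50),
                                g2 = seq(-6, 3, length.out = 50)))
  best_grid <- max(apply(grid, 1, function(g) krig_likelihood(X, y, 10^g)$L))
  expect_gte(o1$L, best_grid - 1e-8)

  # DE route agrees on the same problem
  ode <- krig_optimize(X, y, krig_control(method = "de", particles = 15,
                                          iterations = 40, seed = 77))
  expect_gte(ode$L, best_grid - 1e-2)
})

test_that("enlarging a nested training set does not hurt test error at fixed theta", {
  theta <- c(4, 4)
  mse_gain <- vapply(1:10, function(s) {
    withr::with_seed(1000 + s, {
      X <- matrix(runif(120, 0, 2), 60, 2)
      y <- sin(2 * X[, 1]) * cos(X[, 2])
      q <- matrix(runif(200, 0, 2), 100, 2)
      yq <- sin(2 * q[, 1]) * cos(q[, 2])
    })
    df <- data.frame(x1 = X[, 1], x2 = X[, 2], value = y)
    dq <- data.frame(x1 = q[, 1], x2 = q[, 2])
    m_small <- krig_fit(df[1:30, ], theta = theta)
    m_big <- krig_fit(df, theta = theta)
    mean((predict(m_small, dq) - yq)^2) - mean((predict(m_big, dq) - yq)^2)
  }, 0)
  expect_gt(mean(mse_gain), 0)            # more data helps on average
  expect_gt(mean(mse_gain >= 0), 0.8)     # and in (nearly) every replicate
})

test_that("model artifacts round-trip bit-identically and are validated", {
  withr::with_seed(2, {
    d <- data.frame(a = runif(9), b = runif(9))
    d$value <- d$a * 2 - d$b
  })
  m <- krig_fit(d, control = krig_control(particles = 6, iterations = 10, seed = 4))
  q <- d[1:4, c("a", "b")]
  p <- withr::local_tempfile(fileext = ".json")
  write_krig(m, p)
  m2 <- read_krig(p)
  expect_identical(predict(m2, q), predict(m, q))

  art <- jsonlite::read_json(p)
  art$version <- "9.9"
  p2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(art, p2, digits = NA, auto_unbox = TRUE)
  expect_error(read_krig(p2), class = "waterkrig_artifact_error")

  art2 <- jsonlite::read_json(p)
  art2$weights <- NULL
  jsonlite::write_json(art2, p2, digits = NA, auto_unbox = TRUE)
  expect_error(read_krig(p2), class = "waterkrig_artifact_error")
})
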