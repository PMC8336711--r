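test_that("initial state has one prior hypothesis with belief 1", {
  st <- drex_init(drex_params(D = 1, M = 5))
  expect_equal(st$beliefs, 1)
  expect_equal(st$t, 0L)
  st2 <- drex_init(drex_params(D = 2, M = 5))
  expect_length(st2$stats[[1]]$su, 1L) # pair statistics present
  expect_identical(st, drex_init(drex_params(D = 1, M = 5)))
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(drex_params(D = 3), class = "drexr_error_parameter")
  expect_error(drex_params(M = 0), class = "drexr_error_parameter")
  expect_error(drex_params(N = -1), class = "drexr_error_parameter")
  expect_error(drex_params(hazard = 0), class = "drexr_error_parameter")
})

test_that("posterior predictive matches NIG quadrature oracle", {
  p <- drex_params(D = 1, M = 10, N = 0)
  st <- drex_init(p)
  data <- c(0.3, -0.2, 0.8, 1.1)
  for (v in data) st <- drex_step(st, v)$state
  for (xq in c(-1, 0, 0.5, 2)) {
    pr <- drex_predict(st, xq)
    i <- which(pr$clen == length(data))
    expect_equal(pr$p[i, 1], nig_predictive_quadrature(xq, data),
                 tolerance = 1e-6)
    # marginal is the belief-weighted mixture
    expect_equal(pr$marginal, sum(pr$p[, 1] * pr$beliefs),
                 tolerance = 1e-12)
  }
})

test_that("predictive is centered for symmetric history and flattens with N", {
  p <- drex_params(D = 1, M = 4, N = 0)
  st <- drex_init(p)
  for (v in c(0, 0, 0, 0)) st <- drex_step(st, v)$state
  d_plus <- drex_predict(st, 0.7)$marginal
  d_minus <- drex_predict(st, -0.7)$marginal
  expect_equal(d_plus, d_minus, tolerance = 1e-12)
  expect_gt(drex_predict(st, 0)$marginal, d_plus)

  # large observation noise dominates: surprisal contrast collapses
  for (N in c(0, 100)) {
    pN <- drex_params(D = 1, M = 4, N = N)
    sN <- drex_init(pN)
    for (v in c(0, 0, 0, 0)) sN <- drex_step(sN, v)$state
    gap <- drex_predict(sN, 0)$surprisal - drex_predict(sN, 3)$surprisal
    if (N == 0) gap0 <- gap else expect_lt(abs(gap), abs(gap0) / 10)
  }
})

test_that("surprisal_from_density is -log with a guarded domain", {
  expect_equal(surprisal_from_density(1), 0)
  expect_equal(surprisal_from_density(exp(-2)), 2)
  expect_equal(surprisal_from_density(dnorm(0)), -log(1 / sqrt(2 * pi)))
  expect_error(surprisal_from_density(0), class = "drexr_error_domain")
  expect_error(surprisal_from_density(-1), class = "drexr_error_domain")
})

test_that("belief update renormalizes and shifts mass at an outlier", {
  p <- drex_params(D = 1, M = 10, N = 0, hazard = 1 / 60)
  st <- drex_init(p)
  for (v in c(0, 0, 0, 0)) {
    st <- drex_step(st, v)$state
    expect_equal(sum(st$beliefs), 1, tolerance = 1e-9)
  }
  b_before_newest <- st$beliefs[1]
  st <- drex_step(st, 10)$state
  expect_equal(sum(st$beliefs), 1, tolerance = 1e-9)
  # newest-context hypothesis gains mass at the outlier
  expect_gt(st$beliefs[1], 0.5)
  expect_gt(st$beliefs[1], b_before_newest)
  expect_error(drex_step(st, NaN), class = "drexr_error_input")
})

test_that("recursive beliefs equal exhaustive changepoint enumeration", {
  h <- 1 / 60
  p <- drex_params(D = 1, M = 10, N = 0, hazard = h)
  set.seed(42)
  seqs <- list(
    c(0.1, -0.4),
    rnorm(5),
    c(rnorm(4, 0, 0.4), rnorm(4, 3, 2)),
    rnorm(8),
    c(0, 0, 0, 0, 10, 10, 10, 10)
  )
  for (x in seqs) {
    tr <- run_drex(x, p, keep_beliefs = TRUE)
    bl <- attr(tr, "beliefs")
    ob <- oracle_beliefs(x, h)
    for (t in seq_along(x)) {
      expect_equal(bl[[t]], ob[[t]], tolerance = 1e-8)
    }
  }
})

test_that("M = 1 reduces to the stationary conjugate model", {
  p <- drex_params(D = 1, M = 1, N = 0, hazard = 1e-9)
  st <- drex_init(p)
  data <- c(0.4, -0.1, 0.9, 0.2)
  for (v in data) {
    st <- drex_step(st, v)$state
    expect_length(st$beliefs, 1L)
    expect_equal(st$beliefs, 1)
  }
  pr <- drex_predict(st, 0.3)
  # closed-form stationary posterior predictive (Student-t)
  n <- length(data); k0 <- 1; m0 <- 0; a0 <- 0.5; b0 <- 0.5
  kn <- k0 + n; mn <- (k0 * m0 + sum(data)) / kn; an <- a0 + n / 2
  bn <- b0 + sum((data - mean(data))^2) / 2 +
    k0 * n * (mean(data) - m0)^2 / (2 * kn)
  s <- sqrt(bn * (kn + 1) / (an * kn))
  expect_equal(pr$marginal,
               (1 - 1e-9) * dt((0.3 - mn) / s, 2 * an) / s +
                 1e-9 * pr$p[which(pr$clen == 0), 1],
               tolerance = 1e-9)
})

test_that("hypothesis count never exceeds M and merging conserves mass", {
  p <- drex_params(D = 1, M = 3, N = 0)
  st <- drex_init(p)
  set.seed(1)
  for (v in rnorm(20)) {
    st <- drex_step(st, v)$state
    expect_lte(length(st$beliefs), 3L)
    expect_equal(sum(st$beliefs), 1, tolerance = 1e-9)
  }
})

test_that("Jensen-Shannon divergence has its defining properties", {
  expect_equal(js_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(js_divergence(c(1, 0), c(0, 1)), log(2))
  p <- c(0.5, 0.5); q <- c(0.9, 0.1)
  expect_equal(js_divergence(p, q), js_direct(p, q), tolerance = 1e-12)
  set.seed(99)
  for (i in 1:200) {
    k <- sample(2:8, 1)
    a <- rand_simplex(k); b <- rand_simplex(k)
    d <- js_divergence(a, b)
    expect_equal(d, js_divergence(b, a), tolerance = 1e-12)
    expect_gte(d, 0)
    expect_lte(d, log(2) + 1e-9)
  }
  expect_error(js_divergence(c(0.7, 0.7), c(0.5, 0.5)),
               class = "drexr_error_contract")
})

test_that("a variance step yields maximal belief change near the change", {
  set.seed(33)
  hits <- 0L
  for (r in 1:10) {
    x <- c(rnorm(30, 0, 0.3), rnorm(30, 0, 3))
    tr <- run_drex(x, drex_params(D = 1, M = 10))
    tm <- which.max(tr$belief_change)
    if (tm >= 31 && tm <= 36) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("constant input keeps belief change near zero after burn-in", {
  tr <- run_drex(rep(1, 40) + 1e-6 * sin(1:40), drex_params(D = 1, M = 8))
  expect_lt(max(tr$belief_change[10:40]), 0.05)
})

test_that("detection thresholds behave at their extremes and on ties", {
  tr <- c(0, 0.1, 0.5, 0.2)
  expect_true(detect_change(tr, 0)$detected)
  expect_false(detect_change(tr, log(2) + 0.01)$detected)
  expect_equal(detect_change(tr, 0.3)$time, 3L)
  expect_equal(detect_change(c(0, 0.4, 0.4, 0.1), 0.2)$time, 2L)
  # detection is non-increasing in the threshold
  set.seed(8)
  x <- c(rnorm(30, 0, 0.5), rnorm(30, 0, 2))
  trc <- run_drex(x, drex_params(M = 8))
  taus <- seq(0, 0.7, by = 0.05)
  det <- vapply(taus, function(tt) detect_change(trc, tt)$detected,
                logical(1))
  expect_true(all(diff(det) <= 0))
})

test_that("D = 2 tracks lag-1 dependence that D = 1 misses", {
  # alternating sequence: strongly negatively autocorrelated, unit variance
  set.seed(21)
  x1 <- rep(c(-1, 1), 20) + rnorm(40, 0, 0.1)      # predictable under D=2
  x2 <- sample(x1)                                  # same marginal, shuffled
  p2 <- drex_params(D = 2, M = 6, N = 0)
  s_alt <- mean(run_drex(x1, p2)$surprisal[20:40])
  s_shuf <- mean(run_drex(x2, p2)$surprisal[20:40])
  expect_lt(s_alt, s_shuf)
  # D = 1 sees the two as equally surprising
  p1 <- drex_params(D = 1, M = 6, N = 0)
  s1_alt <- mean(run_drex(x1, p1)$surprisal[20:40])
  s1_shuf <- mean(run_drex(x2, p1)$surprisal[20:40])
  expect_lt(abs(s1_alt - s1_shuf), abs(s_alt - s_shuf))
})

test_that("traces have aligned lengths and bounded belief change", {
  set.seed(3)
  x <- rnorm(50)
  tr <- run_drex(x, drex_params(M = 5))
  expect_equal(nrow(tr), 50L)
  expect_true(all(tr$belief_change >= 0))
  expect_true(all(tr$belief_change <= log(2) + 1e-9))
  expect_equal(tr$belief_change[1], 0)
})
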