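# Shared small experiment for fitting tests (built once per test file run).
small_experiment <- local({
  co <- design_conditions("nsp")
  co$n_reps <- 10L
  build_experiment(co, seed = 123)
})

test_that("simulated listeners respect threshold extremes and determinism", {
  p <- drex_params(M = 6, N = 0.1)
  rec0 <- simulate_listener(small_experiment, "Late_D11_MAX", p, tau = 0)
  expect_true(all(rec0$detected))
  rec_inf <- simulate_listener(small_experiment, "Late_D11_MAX", p,
                               tau = log(2) + 0.01)
  expect_false(any(rec_inf$detected))
  rec_a <- simulate_listener(small_experiment, "Late_D22_MAX", p, tau = 0.2)
  rec_b <- simulate_listener(small_experiment, "Late_D22_MAX", p, tau = 0.2)
  expect_identical(rec_a, rec_b)
  # control false-alarm rate at tau = 0 is 1
  rates <- detection_rates(rec0)
  expect_equal(rates$rate[rates$condition == "control"], 1)
})

test_that("detection rates are per-condition proportions, order-invariant", {
  rec <- tibble::tibble(
    condition = rep(c("a", "b"), each = 50),
    detected = c(rep(c(TRUE, FALSE), 25), rep(TRUE, 50))
  )
  r <- detection_rates(rec)
  expect_equal(r$rate[r$condition == "a"], 0.5)
  expect_equal(r$rate[r$condition == "b"], 1.0)
  r2 <- detection_rates(rec[sample(nrow(rec)), ])
  expect_equal(r, r2)
  expect_error(detection_rates(rec, conditions = c("a", "b", "c")),
               class = "drexr_error_undefined_rate")
})

test_that("d-prime has closed-form values and survives extreme rates", {
  expect_equal(dprime(0.5, 0.5, 50, 50), 0)
  expect_equal(dprime(0.8, 0.2, 1000, 1000), 2 * qnorm(0.8),
               tolerance = 1e-12)
  expect_equal(dprime(0.8, 0.2, 1000, 1000), 1.683242, tolerance = 1e-6)
  d_extreme <- dprime(1, 0, 50, 50)
  expect_true(is.finite(d_extreme))
  expect_equal(d_extreme, qnorm(1 - 1 / 100) - qnorm(1 / 100))
  expect_error(dprime(0.5, 0.5, 0, 10), class = "drexr_error_parameter")
})

test_that("hinge loss matches hand-computed cases", {
  # saturated: all signals beyond the margin on the listener's side
  expect_equal(hinge_loss(c(0.5, 0.5, 0.01), 0.2,
                          c(TRUE, TRUE, FALSE), margin = 0.05), 0)
  # boundary: every signal exactly at threshold
  expect_equal(hinge_loss(rep(0.3, 4), 0.3, c(TRUE, FALSE, TRUE, FALSE),
                          margin = 0.05), 0.05)
  # hand-computed 3-trial case, margin 0.1, tau 0.2:
  #  trial 1: detected, delta 0.25 -> max(0, 0.1 - 0.05) = 0.05
  #  trial 2: not detected, delta 0.35 -> max(0, 0.1 + 0.15) = 0.25
  #  trial 3: detected, delta 0.05 -> max(0, 0.1 + 0.15) = 0.25
  expect_equal(hinge_loss(c(0.25, 0.35, 0.05), 0.2,
                          c(TRUE, FALSE, TRUE), margin = 0.1),
               mean(c(0.05, 0.25, 0.25)))
  expect_error(hinge_loss(1:3, 0.1, c(TRUE, FALSE)),
               class = "drexr_error_contract")
})

test_that("grid fit is self-consistent and recovers in-grid parameters", {
  grid <- grid_spec(M = c(2L, 6L, 12L), N = c(0.03, 0.3, 3),
                    tau = c(0.1, 0.25, 0.4))
  truth <- drex_params(M = 6L, N = 0.3)
  listener <- simulate_listener(small_experiment, "Late_D11_MAX",
                                truth, tau = 0.25)
  fit <- fit_listener(listener, small_experiment, "Late_D11_MAX", grid)
  expect_s3_class(fit, "drex_fit")
  # the generating grid point reproduces the listener, so the minimum is 0
  expect_equal(fit$mse, 0)
  expect_equal(fit$rates$model, fit$rates$listener)
  expect_true(fit$M_f1 %in% grid$M && fit$tau %in% grid$tau)
  # loss coherence: saturated signals give zero hinge loss as well
  sat <- abs(fit$trials$max_delta - fit$tau) > fit$margin
  expect_equal(hinge_loss(fit$trials$max_delta[sat], fit$tau,
                          fit$trials$listener_detected[sat]), 0)
  td <- tidy(fit)
  expect_setequal(td$parameter, c("M", "M", "N", "N", "tau"))
  expect_true(all(td$value[td$parameter == "M"] %in% grid$M))
  gl <- glance(fit)
  expect_equal(gl$mse, 0)
  expect_equal(gl$variant, "Late_D11_MAX")
  expect_error(fit_listener(listener, small_experiment, "Late_D11_MAX",
                            list(M = 2)), class = "drexr_error_parameter")
})

test_that("early-stage and wAVG fits run on reduced grids", {
  grid <- grid_spec(M = c(4L, 8L), N = c(0.1, 1), tau = c(0.05, 0.15, 0.3),
                    w = c(0.25, 0.5, 0.75))
  p <- drex_params(M = 8L, N = 0.1)
  listener <- simulate_listener(small_experiment, "Early_D11_MIN", p,
                                tau = 0.15)
  fit <- fit_listener(listener, small_experiment, "Early_D11_MIN", grid)
  expect_equal(fit$mse, 0)
  expect_equal(fit$M_f1, fit$M_f2) # shared memory bound
  lw <- simulate_listener(small_experiment, "Late_D11_wAVG", p,
                          tau = 0.15, w = 0.75)
  fw <- fit_listener(lw, small_experiment, "Late_D11_wAVG", grid)
  expect_false(is.na(fw$w))
  expect_equal(fw$mse, 0)
})

test_that("cross-validation is reproducible and self-recovers", {
  grid <- grid_spec(M = c(2L, 6L), N = c(0.1, 1), tau = c(0.1, 0.25, 0.4))
  truth <- drex_params(M = 6L, N = 0.1)
  listener <- simulate_listener(small_experiment, "Late_D11_MAX",
                                truth, tau = 0.25)
  cv <- cross_validate(listener, small_experiment, "Late_D11_MAX", grid,
                       n_iter = 3, seed = 9)
  cv2 <- cross_validate(listener, small_experiment, "Late_D11_MAX", grid,
                        n_iter = 3, seed = 9)
  expect_identical(cv$per_iteration, cv2$per_iteration)
  # in-grid listener: held-out model d' tracks listener d'
  expect_equal(cv$summary$d_prime_model, cv$summary$d_prime_listener,
               tolerance = 0.35)
  expect_error(cross_validate(listener[listener$trial < 3, ],
                              small_experiment, "Late_D11_MAX", grid),
               class = "drexr_error_input")
  # fewer than 2 trials in a condition cannot be split
  tiny_co <- design_conditions("nsp")
  tiny_co$n_reps <- 1L
  tiny_ex <- build_experiment(tiny_co, seed = 2)
  tiny_beh <- simulate_listener(tiny_ex, "Late_D11_MAX", truth, tau = 0.25)
  expect_error(cross_validate(tiny_beh, tiny_ex, "Late_D11_MAX", grid),
               class = "drexr_error_parameter")
})

test_that("performance regression recovers exact and null relations", {
  set.seed(60)
  n <- 40
  df <- tibble::tibble(M_f1 = sample(2:20, n, TRUE),
                       M_f2 = sample(2:20, n, TRUE),
                       N_f1 = runif(n, 0.01, 10),
                       N_f2 = runif(n, 0.01, 10))
  # exactly linear in memory: R^2 = 1
  df$d_prime <- 0.1 * df$M_f1 + 0.05 * df$M_f2
  r <- suppressWarnings(regress_performance(df)) # noiseless fit warns
  expect_equal(r$r_squared, 1, tolerance = 1e-9)
  expect_equal(r$coefficients$estimate[r$coefficients$term == "M_f1"],
               0.1, tolerance = 1e-9)
  # independent of parameters: R^2 near 0
  df$d_prime <- rnorm(n)
  expect_lt(regress_performance(df)$r_squared, 0.3)
  # closed-form least squares on a 5-point hand case
  hand <- tibble::tibble(x = c(1, 2, 3, 4, 5),
                         d_prime = c(1.1, 1.9, 3.2, 3.8, 5.1))
  rh <- regress_performance(hand, predictors = "x")
  X <- cbind(1, hand$x)
  beta <- solve(t(X) %*% X, t(X) %*% hand$d_prime)
  expect_equal(rh$coefficients$estimate, as.numeric(beta),
               tolerance = 1e-10)
  # rank-deficient design errors
  df$N_f2 <- df$N_f1
  expect_error(regress_performance(df), class = "drexr_error_singular")
})

test_that("data from Late_D22_MAX is best fit by Late_D22_MAX", {
  # listeners simulated from the late/D2/MAX model should be assigned the
  # lowest hinge loss by that same variant among structurally different
  # competitors, for most listeners
  ex <- build_experiment("nsp", seed = 99)
  grid <- grid_spec(M = c(4L, 10L), N = c(0.1, 1),
                    tau = c(0.15, 0.25, 0.35))
  variants <- c("Late_D22_MAX", "Early_D22_MIN", "Late_D11_MAX",
                "Early_D11_MAX")
  set.seed(17)
  truths <- lapply(1:20, function(l) {
    list(M = sample(grid$M, 2, TRUE), N = sample(grid$N, 2, TRUE),
         tau = sample(grid$tau, 1))
  })
  behaviors <- lapply(truths, function(tr) {
    simulate_listener(ex, "Late_D22_MAX",
                      drex_params(D = 2, M = tr$M[1], N = tr$N[1]),
                      drex_params(D = 2, M = tr$M[2], N = tr$N[2]),
                      tau = tr$tau)
  })
  hinges <- sapply(variants, function(v) {
    vapply(fit_listeners(behaviors, ex, v, grid),
           function(f) f$hinge, numeric(1))
  })
  best <- variants[apply(hinges, 1, which.min)]
  expect_gte(mean(best == "Late_D22_MAX"), 0.8)
})

test_that("lapses flip responses at the requested rate", {
  p <- drex_params(M = 6, N = 0.1)
  clean <- simulate_listener(small_experiment, "Late_D11_MAX", p, tau = 0.2)
  noisy <- simulate_listener(small_experiment, "Late_D11_MAX", p, tau = 0.2,
                             lapse = 0.5, seed = 4)
  expect_gt(mean(clean$detected != noisy$detected), 0.2)
  expect_lt(mean(clean$detected != noisy$detected), 0.8)
})
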