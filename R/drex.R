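#' Model parameters for the sequential Bayesian predictor
#'
#' The predictor treats the observed sequence as Gaussian with unknown
#' parameters that change at unknown times. It maintains up to `M` context
#' hypotheses (candidate spans since the most recent change), each with
#' conjugate sufficient statistics, and a belief (posterior probability)
#' per hypothesis, updated with a constant per-step change prior (`hazard`).
#'
#' @param D Temporal-dependence order: 1 (univariate Gaussian; mean and
#'   variance) or 2 (bivariate over adjacent pairs; additionally the lag-1
#'   covariance, with prediction the conditional given the previous value).
#' @param M Memory bound: maximum number of context hypotheses (`>= 1`).
#' @param N Observation-noise variance added to the predictive variance
#'   (seed units squared, `>= 0`); a floor on prediction uncertainty.
#' @param hazard Per-step prior probability of a statistical change,
#'   in (0, 1). Default `1/60` (one expected change per 60-tone melody).
#' @param prior_mean Prior mean on the seed scale (default 0).
#' @param prior_scale Prior scale (SD) on the seed scale (default 1).
#' @param prior_n Prior pseudo-count for the conjugate prior (default 1).
#' @param tau Detection threshold on the maximal belief change (nats).
#'
#' @return A list of class `drex_params`.
#' @examples
#' drex_params(D = 2, M = 8, N = 0.1)
#' @export
drex_params <- function(D = 1L, M = 10L, N = 0, hazard = 1 / 60,
                        prior_mean = 0, prior_scale = 1, prior_n = 1,
                        tau = 0.1) {
  if (!D %in% c(1L, 2L)) {
    rlang::abort("`D` must be 1 or 2.", class = "drexr_error_parameter")
  }
  if (M < 1) rlang::abort("`M` must be >= 1.", class = "drexr_error_parameter")
  if (N < 0) rlang::abort("`N` must be >= 0.", class = "drexr_error_parameter")
  if (hazard <= 0 || hazard >= 1) {
    rlang::abort("`hazard` must be in (0, 1).", class = "drexr_error_parameter")
  }
  if (prior_scale <= 0 || prior_n <= 0) {
    rlang::abort("prior hyperparameters must be positive.",
                 class = "drexr_error_parameter")
  }
  structure(list(D = as.integer(D), M = as.integer(M), N = N,
                 hazard = hazard, prior_mean = prior_mean,
                 prior_scale = prior_scale, prior_n = prior_n, tau = tau),
            class = "drex_params")
}

# ---------------------------------------------------------------------------
# Internal engine. A single code path serves the single-feature model
# (F = 1) and early-integration multifeature models (F = 2, with a combine
# function applied to per-hypothesis predictive densities across features).
#
# Hypothesis order: index 1 = newest (shortest context), last = oldest.
# ---------------------------------------------------------------------------

.engine_spec <- function(D, N, M, hazard, prior_mean, prior_scale, prior_n,
                         combine = NULL) {
  list(F = length(D), D = as.integer(D), N = N, M = as.integer(M),
       hazard = hazard,
       prior = list(m0 = prior_mean, k0 = prior_n, nu0 = prior_n,
                    s0sq = prior_scale^2),
       combine = combine)
}

.stats_empty <- function(D) {
  if (D == 1L) {
    list(n = numeric(0), sx = numeric(0), sxx = numeric(0))
  } else {
    list(m = numeric(0), su = numeric(0), sv = numeric(0),
         suu = numeric(0), suv = numeric(0), svv = numeric(0))
  }
}

.stats_newborn <- function(st, D, x) {
  if (D == 1L) {
    list(n = c(1, st$n), sx = c(x, st$sx), sxx = c(x^2, st$sxx))
  } else {
    # context starts at x: no within-context pair yet
    list(m = c(0, st$m), su = c(0, st$su), sv = c(0, st$sv),
         suu = c(0, st$suu), suv = c(0, st$suv), svv = c(0, st$svv))
  }
}

.stats_grow <- function(st, D, x, x_prev) {
  if (D == 1L) {
    list(n = st$n + 1, sx = st$sx + x, sxx = st$sxx + x^2)
  } else {
    list(m = st$m + 1, su = st$su + x_prev, sv = st$sv + x,
         suu = st$suu + x_prev^2, suv = st$suv + x_prev * x,
         svv = st$svv + x^2)
  }
}

.stats_drop <- function(st, i) lapply(st, function(v) v[-i])

# Student-t density with location/scale
.dt_ls <- function(x, df, loc, scale) {
  stats::dt((x - loc) / scale, df) / scale
}

# D = 1 posterior predictive (Normal-Inverse-Gamma conjugacy), vectorized
# over hypotheses. Zero-count rows give the prior predictive.
.pred_d1 <- function(st, x, prior, N) {
  n <- st$n
  k0 <- prior$k0; m0 <- prior$m0
  a0 <- prior$nu0 / 2; b0 <- prior$nu0 * prior$s0sq / 2
  xbar <- ifelse(n > 0, st$sx / pmax(n, 1), 0)
  ss <- pmax(st$sxx - n * xbar^2, 0)
  kn <- k0 + n
  mn <- (k0 * m0 + st$sx) / kn
  an <- a0 + n / 2
  bn <- b0 + ss / 2 + k0 * n * (xbar - m0)^2 / (2 * kn)
  df <- 2 * an
  s2 <- bn * (kn + 1) / (an * kn) + N
  .dt_ls(x, df, mn, sqrt(s2))
}

# D = 2 posterior predictive (Normal-Inverse-Wishart over adjacent pairs),
# vectorized. `has_prev` flags hypotheses whose context contains the
# previous observation; for those the prediction is the conditional of the
# bivariate posterior predictive given x_prev, otherwise its first-margin.
.pred_d2 <- function(st, x, x_prev, has_prev, prior, N) {
  m <- st$m
  k0 <- prior$k0; m0 <- prior$m0
  nu0 <- prior$nu0 + 2           # proper NIW needs nu0 > d - 1
  psi0 <- prior$s0sq
  ubar <- ifelse(m > 0, st$su / pmax(m, 1), 0)
  vbar <- ifelse(m > 0, st$sv / pmax(m, 1), 0)
  Suu <- pmax(st$suu - m * ubar^2, 0)
  Svv <- pmax(st$svv - m * vbar^2, 0)
  Suv <- st$suv - m * ubar * vbar
  kn <- k0 + m
  nun <- nu0 + m
  mn1 <- (k0 * m0 + st$su) / kn
  mn2 <- (k0 * m0 + st$sv) / kn
  w <- k0 * m / kn
  P11 <- psi0 + Suu + w * (ubar - m0)^2
  P22 <- psi0 + Svv + w * (vbar - m0)^2
  P12 <- Suv + w * (ubar - m0) * (vbar - m0)
  df0 <- nun - 1
  cc <- (kn + 1) / (kn * df0)
  S11 <- cc * P11
  S22 <- cc * P22
  S12 <- cc * P12
  out <- numeric(length(m))
  if (any(has_prev)) {
    i <- has_prev
    loc <- mn2[i] + S12[i] / S11[i] * (x_prev - mn1[i])
    d1 <- (x_prev - mn1[i])^2 / S11[i]
    dfc <- df0[i] + 1
    s2 <- (df0[i] + d1) / dfc * (S22[i] - S12[i]^2 / S11[i]) + N
    out[i] <- .dt_ls(x, dfc, loc, sqrt(s2))
  }
  if (any(!has_prev)) {
    i <- !has_prev
    out[i] <- .dt_ls(x, df0[i], mn1[i], sqrt(S11[i] + N))
  }
  out
}

.pred_feature <- function(st, f, spec, x, x_prev, clen) {
  if (spec$D[f] == 1L) {
    .pred_d1(st, x, spec$prior, spec$N[f])
  } else {
    .pred_d2(st, x, x_prev, has_prev = clen >= 1L, spec$prior, spec$N[f])
  }
}

#' Initialize the predictor state
#'
#' Returns the state before any observation: a single context hypothesis
#' carrying the prior statistics with belief exactly 1.
#'
#' @param params A [drex_params()] object (or an internal engine spec).
#' @return A list of class `drex_state` with elements `t`, `beliefs`,
#'   `clen` (context lengths), per-feature sufficient statistics, and the
#'   previous observation.
#' @export
drex_init <- function(params) {
  spec <- if (inherits(params, "drex_params")) {
    .engine_spec(params$D, params$N, params$M, params$hazard,
                 params$prior_mean, params$prior_scale, params$prior_n)
  } else {
    params
  }
  stats <- lapply(seq_len(spec$F), function(f) {
    st <- .stats_empty(spec$D[f])
    # one empty (prior) hypothesis
    lapply(st, function(v) c(v, 0))
  })
  structure(list(t = 0L, beliefs = 1, clen = 0L, stats = stats,
                 x_prev = rep(NA_real_, spec$F), spec = spec),
            class = "drex_state")
}

#' One-step predictive distribution of the current state
#'
#' Propagates the beliefs through the change prior (a virtual new context
#' with mass `hazard` is added and existing hypotheses are scaled by
#' `1 - hazard`), evaluates each hypothesis's posterior-predictive density
#' at `x`, and returns the per-hypothesis densities together with the
#' belief-weighted marginal. The marginal equals `sum(p_i * b_i)` over the
#' propagated hypothesis set.
#'
#' @param state A `drex_state` from [drex_init()] or [drex_step()].
#' @param x The next observation (one value per feature).
#' @return A list with `p` (matrix, hypotheses x features), `beliefs`
#'   (hazard-propagated), `marginal` (per feature) and `surprisal`
#'   (per feature, nats).
#' @export
drex_predict <- function(state, x) {
  spec <- state$spec
  if (length(x) != spec$F || any(!is.finite(x))) {
    rlang::abort("`x` must be a finite value per feature.",
                 class = "drexr_error_input")
  }
  if (state$t == 0L) {
    b_ext <- 1
    clen_ext <- 0L
    stats_ext <- state$stats
  } else {
    h <- spec$hazard
    b_ext <- c(h, (1 - h) * state$beliefs)
    clen_ext <- c(0L, state$clen)
    stats_ext <- lapply(seq_len(spec$F), function(f) {
      st <- state$stats[[f]]
      lapply(st, function(v) c(0, v))
    })
  }
  p <- vapply(seq_len(spec$F), function(f) {
    .pred_feature(stats_ext[[f]], f, spec, x[f], state$x_prev[f], clen_ext)
  }, numeric(length(b_ext)))
  p <- matrix(p, nrow = length(b_ext), ncol = spec$F)
  marginal <- as.numeric(b_ext %*% p)
  list(p = p, beliefs = b_ext, clen = clen_ext, marginal = marginal,
       surprisal = -log(marginal))
}

#' Advance the predictor by one observation
#'
#' Performs the predict-update cycle for one new observation: evaluates
#' per-hypothesis predictive densities, reweights beliefs under the change
#' prior, spawns a new context hypothesis, updates all sufficient
#' statistics with the observation, enforces the memory bound `M` by
#' merging the two oldest hypotheses (the oldest absorbs belief mass and
#' keeps its statistics), and computes the belief change (Jensen-Shannon
#' divergence between aligned beliefs before and after, in nats).
#'
#' @param state A `drex_state`.
#' @param x The new observation (one value per feature).
#' @return A list with the new `state`, `surprisal` (per feature, nats)
#'   and `delta` (belief change, nats).
#' @export
drex_step <- function(state, x) {
  spec <- state$spec
  if (length(x) != spec$F || any(!is.finite(x))) {
    rlang::abort("`x` must be a finite value per feature.",
                 class = "drexr_error_input")
  }
  h <- spec$hazard
  b_old <- state$beliefs

  if (state$t == 0L) {
    # first observation: single (prior) context absorbs it; no change yet
    p0 <- vapply(seq_len(spec$F), function(f) {
      .pred_feature(state$stats[[f]], f, spec, x[f], NA_real_, 0L)
    }, numeric(1))
    stats <- lapply(seq_len(spec$F), function(f) {
      st <- .stats_empty(spec$D[f])
      .stats_newborn(st, spec$D[f], x[f])
    })
    new_state <- structure(list(t = 1L, beliefs = 1, clen = 1L,
                                stats = stats, x_prev = x, spec = spec),
                           class = "drex_state")
    return(list(state = new_state, surprisal = -log(p0), delta = 0))
  }

  k <- length(b_old)
  p <- vapply(seq_len(spec$F), function(f) {
    .pred_feature(state$stats[[f]], f, spec, x[f], state$x_prev[f],
                  state$clen)
  }, numeric(k))
  p <- matrix(p, nrow = k, ncol = spec$F)
  p0 <- vapply(seq_len(spec$F), function(f) {
    st0 <- lapply(.stats_empty(spec$D[f]), function(v) c(v, 0))
    .pred_feature(st0, f, spec, x[f], state$x_prev[f], 0L)
  }, numeric(1))

  # evidence: combined across features for shared-context models
  ev <- if (is.null(spec$combine)) p[, 1L] else apply(p, 1L, spec$combine)
  ev0 <- if (is.null(spec$combine)) p0[1L] else spec$combine(p0)

  marginal <- as.numeric((1 - h) * (b_old %*% p)) + h * p0

  w <- c(h * ev0, (1 - h) * b_old * ev)
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0) {
    # catastrophic underflow: the observation is inconsistent with every
    # hypothesis; attribute it to a fresh context
    w <- c(1, rep(0, k))
    tot <- 1
  }
  b_new <- w / tot
  clen_new <- c(1L, state$clen + 1L)
  stats_new <- lapply(seq_len(spec$F), function(f) {
    st <- .stats_grow(state$stats[[f]], spec$D[f], x[f], state$x_prev[f])
    .stats_newborn(st, spec$D[f], x[f])
  })

  before <- c(0, b_old)
  if (length(b_new) > spec$M) {
    kk <- length(b_new)
    b_new <- c(b_new[seq_len(kk - 2L)], b_new[kk - 1L] + b_new[kk])
    before <- c(before[seq_len(kk - 2L)], before[kk - 1L] + before[kk])
    clen_new <- c(clen_new[seq_len(kk - 2L)], clen_new[kk])
    stats_new <- lapply(stats_new, .stats_drop, i = kk - 1L)
  }
  delta <- js_divergence(before, b_new)

  new_state <- structure(list(t = state$t + 1L, beliefs = b_new,
                              clen = clen_new, stats = stats_new,
                              x_prev = x, spec = spec),
                         class = "drex_state")
  list(state = new_state, surprisal = -log(marginal), delta = delta)
}

#' Run the predictor over a full sequence
#'
#' Iterates predict / update over a sequence on the seed scale and returns
#' the per-tone trace of surprisal (nats) and belief change (nats).
#'
#' @param x Numeric sequence (length `>= 2`), or a data frame with columns
#'   `tone` and `seed_value` for a single feature.
#' @param params A [drex_params()] object.
#' @param keep_beliefs Keep the belief history as an attribute (list of
#'   numeric vectors)? Default `FALSE`.
#' @return A tibble of class `drex_trace` with columns `tone`, `surprisal`,
#'   `belief_change`.
#' @examples
#' tr <- run_drex(c(rnorm(30, 0, 0.3), rnorm(30, 0, 3)), drex_params(M = 8))
#' tr[which.max(tr$belief_change), ]
#' @export
run_drex <- function(x, params, keep_beliefs = FALSE) {
  if (is.data.frame(x)) x <- x$seed_value
  if (length(x) < 2L) {
    rlang::abort("`x` must have length >= 2.", class = "drexr_error_input")
  }
  if (any(!is.finite(x))) {
    rlang::abort("`x` must be finite.", class = "drexr_error_input")
  }
  st <- drex_init(params)
  n <- length(x)
  surprisal <- numeric(n)
  delta <- numeric(n)
  beliefs <- if (keep_beliefs) vector("list", n) else NULL
  for (t in seq_len(n)) {
    step <- drex_step(st, x[t])
    st <- step$state
    surprisal[t] <- step$surprisal[1L]
    delta[t] <- step$delta
    if (keep_beliefs) beliefs[[t]] <- st$beliefs
  }
  out <- tibble::tibble(tone = seq_len(n), surprisal = surprisal,
                        belief_change = delta)
  if (keep_beliefs) attr(out, "beliefs") <- beliefs
  attr(out, "params") <- params
  class(out) <- c("drex_trace", class(out))
  out
}

#' Surprisal of a predictive density value
#'
#' @param density Positive predictive density evaluated at the observation.
#' @return `-log(density)` in nats. May be negative for densities above 1.
#' @examples
#' surprisal_from_density(exp(-2))
#' @export
surprisal_from_density <- function(density) {
  if (any(!is.finite(density)) || any(density <= 0)) {
    rlang::abort("`density` must be positive.", class = "drexr_error_domain")
  }
  -log(density)
}

#' Jensen-Shannon divergence between two belief distributions
#'
#' `0.5 * KL(p || m) + 0.5 * KL(q || m)` with `m = (p + q) / 2`, natural
#' logarithm. Symmetric, bounded in `[0, log(2)]`, zero iff `p == q`.
#'
#' @param p,q Probability vectors of equal length summing to 1.
#' @return The divergence in nats.
#' @examples
#' js_divergence(c(0.5, 0.5), c(0.9, 0.1))
#' @export
js_divergence <- function(p, q) {
  if (length(p) != length(q)) {
    rlang::abort("`p` and `q` must have equal length.",
                 class = "drexr_error_contract")
  }
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6 ||
      any(p < -1e-12) || any(q < -1e-12)) {
    rlang::abort("`p` and `q` must be normalized probability vectors.",
                 class = "drexr_error_contract")
  }
  m <- (p + q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log(a[i] / m[i]))
  }
  max(0, (kl(p) + kl(q)) / 2)
}

#' Threshold change detection on a belief-change trace
#'
#' A change is reported when the maximal belief change reaches the
#' detection threshold `tau`; the detection time is the earliest tone at
#' which the maximum is attained.
#'
#' @param trace A `drex_trace` / joint-trace tibble (column `belief_change`
#'   or `delta_combined`), or a numeric belief-change vector.
#' @param tau Nonnegative detection threshold (nats).
#' @return A one-row tibble: `detected` (logical), `time` (tone index of
#'   the maximum), `max_delta`.
#' @examples
#' detect_change(c(0, 0.1, 0.5, 0.2), tau = 0.3)
#' @export
detect_change <- function(trace, tau) {
  delta <- if (is.data.frame(trace)) {
    if ("delta_combined" %in% names(trace)) trace$delta_combined
    else trace$belief_change
  } else {
    trace
  }
  if (length(delta) == 0L) {
    rlang::abort("empty trace.", class = "drexr_error_input")
  }
  i <- which.max(delta)
  tibble::tibble(detected = delta[i] >= tau, time = as.integer(i),
                 max_delta = delta[i])
}
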