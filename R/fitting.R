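#' Grid specification for parameter fitting
#'
#' Candidate values for the grid search over memory bound `M`, observation
#' noise `N`, detection threshold `tau`, and (for `wAVG` variants) the
#' convex feature weight `w`. Defaults are a desk-scale grid: `M` even
#' values 2-20, `N` log-spaced over `[0.01, 10]`, `tau` linear over
#' `(0, 0.7]`, `w` on an 11-point grid in `[0, 1]`.
#'
#' @param M Integer candidates for the memory bound (per feature for late
#'   integration, shared for early).
#' @param N Positive candidates for the observation-noise variance.
#' @param tau Nonnegative candidates for the detection threshold (nats).
#' @param w Candidates in `[0, 1]` for the `wAVG` weight.
#' @return A list of class `drex_grid`.
#' @export
grid_spec <- function(M = seq(2L, 20L, by = 2L),
                      N = 10^seq(-2, 1, length.out = 10),
                      tau = seq(0.07, 0.7, length.out = 10),
                      w = seq(0, 1, by = 0.1)) {
  if (length(M) == 0L || length(N) == 0L || length(tau) == 0L) {
    rlang::abort("grid lists must be nonempty.",
                 class = "drexr_error_parameter")
  }
  if (any(N <= 0) || any(tau < 0) || any(w < 0 | w > 1)) {
    rlang::abort("invalid grid values (need N > 0, tau >= 0, w in [0, 1]).",
                 class = "drexr_error_parameter")
  }
  structure(list(M = as.integer(M), N = as.numeric(N),
                 tau = as.numeric(tau), w = as.numeric(w)),
            class = "drex_grid")
}

#' Which conditions of a design contain a statistical change?
#'
#' @param conditions A condition table from [design_conditions()].
#' @return A tibble with `condition` and logical `is_change`.
#' @export
condition_changes <- function(conditions) {
  tibble::tibble(
    condition = conditions$condition,
    is_change = conditions$beta_pre_1 != conditions$beta_post_1 |
      conditions$beta_pre_2 != conditions$beta_post_2
  )
}

# Per-trial seed tracks of an experiment, feature order = design order.
.experiment_tracks <- function(experiment) {
  conds <- attr(experiment, "conditions")
  f1 <- conds$feature_1[1]; f2 <- conds$feature_2[1]
  trials <- sort(unique(experiment$trial))
  e1 <- experiment[experiment$feature == f1, ]
  e2 <- experiment[experiment$feature == f2, ]
  tone_count <- attr(experiment, "tone_count")
  x1 <- matrix(e1$seed_value[order(e1$trial, e1$tone)], nrow = tone_count)
  x2 <- matrix(e2$seed_value[order(e2$trial, e2$tone)], nrow = tone_count)
  cond_by_trial <- e1$condition[e1$tone == 1][order(e1$trial[e1$tone == 1])]
  list(trials = trials, x1 = x1, x2 = x2, condition = cond_by_trial)
}

#' Simulate a listener's responses with a model variant
#'
#' Runs the variant on every stimulus of the experiment and converts the
#' maximal combined belief change into a yes/no change response with
#' threshold `tau`. An optional lapse rate flips each response
#' independently, emulating attentional lapses.
#'
#' @param experiment An experiment tibble from [build_experiment()].
#' @param variant Variant name or row of [drex_variants()].
#' @param params_f1,params_f2 [drex_params()] per feature (see
#'   [run_variant()]).
#' @param tau Detection threshold (defaults to `params_f1$tau`).
#' @param w Convex weight for `wAVG` variants.
#' @param lapse Probability of flipping each response (default 0).
#' @param seed Seed for the lapse noise.
#' @return A tibble with one row per trial: `trial`, `condition`,
#'   `detected`, `max_delta`, `detect_time`.
#' @export
simulate_listener <- function(experiment, variant, params_f1,
                              params_f2 = params_f1, tau = NULL, w = NULL,
                              lapse = 0, seed = NULL) {
  cfg <- parse_variant(variant)
  tau <- tau %||% params_f1$tau
  tk <- .experiment_tracks(experiment)
  n <- length(tk$trials)
  max_delta <- numeric(n)
  dtime <- integer(n)
  for (i in seq_len(n)) {
    tr <- run_variant(list(tk$x1[, i], tk$x2[, i]), cfg, params_f1,
                      params_f2, w = w)
    j <- which.max(tr$delta_combined)
    max_delta[i] <- tr$delta_combined[j]
    dtime[i] <- j
  }
  detected <- max_delta >= tau
  if (lapse > 0) {
    if (!is.null(seed)) {
      old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
      set.seed(as.integer(seed))
    }
    flip <- stats::runif(n) < lapse
    detected[flip] <- !detected[flip]
  }
  tibble::tibble(trial = tk$trials, condition = tk$condition,
                 detected = detected, max_delta = max_delta,
                 detect_time = as.integer(dtime))
}

#' Per-condition detection rates
#'
#' @param records A behavioral table with columns `condition` and
#'   `detected`.
#' @param conditions Optional vector of condition labels that must all be
#'   present (a condition with zero trials is an error).
#' @return A tibble with `condition`, `n`, `rate`.
#' @export
detection_rates <- function(records, conditions = NULL) {
  out <- records |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n = dplyr::n(), rate = mean(.data$detected),
                     .groups = "drop")
  if (!is.null(conditions)) {
    missing <- setdiff(conditions, out$condition)
    if (length(missing) > 0L) {
      rlang::abort(paste0("no trials for condition(s): ",
                          paste(missing, collapse = ", ")),
                   class = "drexr_error_undefined_rate")
    }
    out <- out[match(conditions, out$condition), ]
  }
  out
}

#' Detection sensitivity d-prime with extreme-rate correction
#'
#' `qnorm(hit) - qnorm(fa)` after clamping both rates to
#' `[1/(2n), 1 - 1/(2n)]` with the respective trial counts, so perfect or
#' zero rates give finite values.
#'
#' @param hit_rate,fa_rate Hit and false-alarm probabilities in `[0, 1]`.
#' @param n_signal,n_noise Trial counts behind each rate (`>= 1`).
#' @return d-prime (unitless).
#' @examples
#' dprime(0.8, 0.2, 50, 50)
#' @export
dprime <- function(hit_rate, fa_rate, n_signal, n_noise) {
  if (n_signal < 1 || n_noise < 1) {
    rlang::abort("trial counts must be >= 1.",
                 class = "drexr_error_parameter")
  }
  clamp <- function(r, n) pmin(pmax(r, 1 / (2 * n)), 1 - 1 / (2 * n))
  stats::qnorm(clamp(hit_rate, n_signal)) -
    stats::qnorm(clamp(fa_rate, n_noise))
}

#' Overall performance summary of a behavioral table
#'
#' Pools all change conditions for the hit rate and all no-change
#' (control) conditions for the false-alarm rate, and computes corrected
#' d-prime.
#'
#' @param records Behavioral table (`condition`, `detected`).
#' @param conditions Condition design table (to classify change vs
#'   control), as from [design_conditions()].
#' @return One-row tibble: `hit_rate`, `fa_rate`, `n_signal`, `n_noise`,
#'   `d_prime`.
#' @export
performance_summary <- function(records, conditions) {
  ch <- condition_changes(conditions)
  sig <- records$condition %in% ch$condition[ch$is_change]
  n_signal <- sum(sig); n_noise <- sum(!sig)
  if (n_signal == 0L || n_noise == 0L) {
    rlang::abort("need at least one change and one control trial.",
                 class = "drexr_error_undefined_rate")
  }
  hit <- mean(records$detected[sig])
  fa <- mean(records$detected[!sig])
  tibble::tibble(hit_rate = hit, fa_rate = fa, n_signal = n_signal,
                 n_noise = n_noise,
                 d_prime = dprime(hit, fa, n_signal, n_noise))
}

#' Modified hinge loss against listener responses
#'
#' Mean over trials of `max(0, margin - y * (max_delta - tau))`, where
#' `y = +1` when the listener reported a change and `-1` otherwise. The
#' loss penalizes model decision signals on the wrong side of the
#' threshold and correct signals within `margin` of it, rewarding
#' decisions far from threshold. Ground truth is the listener's response,
#' not the stimulus.
#'
#' @param max_delta Per-trial maximal combined belief change (nats).
#' @param tau Detection threshold (nats).
#' @param detected Logical listener responses, aligned with `max_delta`.
#' @param margin Hinge margin in belief-change units (default 0.05).
#' @return Mean hinge loss (nonnegative).
#' @export
hinge_loss <- function(max_delta, tau, detected, margin = 0.05) {
  if (length(max_delta) != length(detected)) {
    rlang::abort("`max_delta` and `detected` must be aligned.",
                 class = "drexr_error_contract")
  }
  y <- ifelse(detected, 1, -1)
  mean(pmax(0, margin - y * (max_delta - tau)))
}

# --- grid-search internals --------------------------------------------------

# Belief-change traces for every (M, N) grid cell of one feature.
.feature_cache <- function(x, D, grid, base) {
  combos <- expand.grid(Ni = seq_along(grid$N), Mi = seq_along(grid$M),
                        KEEP.OUT.ATTRS = FALSE)
  n_trials <- ncol(x)
  lapply(seq_len(nrow(combos)), function(k) {
    p <- base
    p$D <- D
    p$M <- grid$M[combos$Mi[k]]
    p$N <- grid$N[combos$Ni[k]]
    d <- vapply(seq_len(n_trials),
                function(i) run_drex(x[, i], p)$belief_change,
                numeric(nrow(x)))
    list(Mi = combos$Mi[k], Ni = combos$Ni[k], delta = d,
         max = apply(d, 2L, max))
  })
}

# Per-trial max combined delta for every early-integration grid cell.
.early_cache <- function(x1, x2, cfg, grid, base, w_values) {
  combos <- expand.grid(wi = seq_along(w_values),
                        N2i = seq_along(grid$N), N1i = seq_along(grid$N),
                        Mi = seq_along(grid$M), KEEP.OUT.ATTRS = FALSE)
  n_trials <- ncol(x1)
  lapply(seq_len(nrow(combos)), function(k) {
    p1 <- base
    p1$M <- grid$M[combos$Mi[k]]
    p1$N <- grid$N[combos$N1i[k]]
    p2 <- base
    p2$N <- grid$N[combos$N2i[k]]
    w <- w_values[combos$wi[k]]
    mx <- vapply(seq_len(n_trials), function(i) {
      tr <- run_variant(list(x1[, i], x2[, i]), cfg, p1, p2, w = w)
      max(tr$delta_combined)
    }, numeric(1))
    list(Mi = combos$Mi[k], N1i = combos$N1i[k], N2i = combos$N2i[k],
         wi = combos$wi[k], max = mx)
  })
}

.col_max <- function(m) do.call(pmax, asplit(m, 1L))

# Exhaustive search over the cached grid. `use` indexes the trials used
# for fitting; listener detection rates are computed on those trials.
.fit_from_cache <- function(cache, cfg, grid, condition, detected, use,
                            margin) {
  cond_use <- condition[use]
  det_use <- detected[use]
  cond_levels <- unique(condition)
  listener_rates <- vapply(cond_levels,
                           function(cl) mean(det_use[cond_use == cl]),
                           numeric(1))
  group <- match(cond_use, cond_levels)
  n_per <- tabulate(group, nbins = length(cond_levels))
  n_tau <- length(grid$tau)

  best <- list(mse = Inf, hinge = Inf)
  score <- function(mx, ids) {
    # detection-rate MSE for every tau at once
    det <- outer(mx[use], grid$tau, ">=")
    rates <- rowsum(det + 0, group) / n_per
    mse <- colMeans((rates - listener_rates)^2)
    lo <- min(mse)
    if (lo > best$mse + 1e-12) return(invisible())
    # exact MSE ties (within and across grid cells) are broken by the
    # hinge loss, preferring decision signals far from the threshold
    cand <- which(mse <= lo + 1e-12)
    hinges <- vapply(cand, function(ti) {
      hinge_loss(mx[use], grid$tau[ti], det_use, margin)
    }, numeric(1))
    ti <- cand[which.min(hinges)]
    hg <- min(hinges)
    if (lo < best$mse - 1e-12 ||
        (lo <= best$mse + 1e-12 && hg < best$hinge - 1e-12)) {
      best <<- c(list(mse = mse[ti], hinge = hg, tau_i = ti,
                      max_delta = mx), ids)
    }
    invisible()
  }

  if (cfg$stage == "late") {
    is_wavg <- cfg$operator == "wAVG"
    w_values <- if (is_wavg) grid$w else NA_real_
    for (c1 in cache$f1) {
      for (c2 in cache$f2) {
        for (wi in seq_along(w_values)) {
          mx <- switch(cfg$operator,
            MAX  = pmax(c1$max, c2$max),
            MIN  = .col_max(pmin(c1$delta, c2$delta)),
            AVG  = .col_max((c1$delta + c2$delta) / 2),
            wAVG = .col_max(w_values[wi] * c1$delta +
                              (1 - w_values[wi]) * c2$delta)
          )
          score(mx, list(M1i = c1$Mi, N1i = c1$Ni, M2i = c2$Mi,
                         N2i = c2$Ni, wi = if (is_wavg) wi else NA))
        }
      }
    }
  } else {
    for (ce in cache$early) {
      score(ce$max, list(M1i = ce$Mi, N1i = ce$N1i, M2i = ce$Mi,
                         N2i = ce$N2i, wi = ce$wi))
    }
  }

  tau <- grid$tau[best$tau_i]
  hinge <- best$hinge
  list(
    M_f1 = grid$M[best$M1i], N_f1 = grid$N[best$N1i],
    M_f2 = grid$M[best$M2i], N_f2 = grid$N[best$N2i],
    tau = tau,
    w = if (cfg$operator == "wAVG") grid$w[best$wi] else NA_real_,
    mse = best$mse, hinge = hinge, max_delta = best$max_delta,
    listener_rates = tibble::tibble(condition = cond_levels,
                                    listener = unname(listener_rates))
  )
}

.build_cache <- function(tracks, cfg, grid, base) {
  if (cfg$stage == "late") {
    list(f1 = .feature_cache(tracks$x1, cfg$d_f1, grid, base),
         f2 = .feature_cache(tracks$x2, cfg$d_f2, grid, base))
  } else {
    wv <- if (cfg$operator == "wAVG") grid$w else NA_real_
    list(early = .early_cache(tracks$x1, tracks$x2, cfg, grid, base, wv))
  }
}

#' Fit model parameters to a listener by exhaustive grid search
#'
#' For every grid cell, the model's per-condition detection rate is
#' compared with the listener's; the parameters minimizing the mean
#' squared error across conditions are selected (ties broken by
#' first-encountered grid order: feature-1 memory, feature-1 noise,
#' feature-2 memory, feature-2 noise, weight, threshold). A hinge loss
#' against the listener's trial-by-trial responses is reported at the
#' selected parameters. Late-integration variants fit two memory and two
#' noise parameters; early-integration variants share one memory bound.
#'
#' @param behavior Behavioral table aligned with the experiment by
#'   `trial`: columns `trial`, `condition`, `detected`.
#' @param experiment The stimulus experiment the listener heard
#'   ([build_experiment()]).
#' @param variant Variant name or row of [drex_variants()].
#' @param grid A [grid_spec()].
#' @param margin Hinge-loss margin (default 0.05).
#' @param base_params Baseline [drex_params()] supplying hazard and prior
#'   hyperparameters.
#' @return An object of class `drex_fit`: fitted `M_f1`, `N_f1`, `M_f2`,
#'   `N_f2`, `tau`, `w`, losses `mse` and `hinge`, per-condition rates,
#'   and the per-trial `max_delta` at the optimum. Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
fit_listener <- function(behavior, experiment, variant, grid = grid_spec(),
                         margin = 0.05, base_params = drex_params()) {
  fit_listeners(list(behavior), experiment, variant, grid, margin,
                base_params)[[1]]
}

#' @rdname fit_listener
#' @param behaviors A list of behavioral tables, one per listener; all
#'   listeners heard the same experiment, so the model traces are computed
#'   once and reused across listeners.
#' @return `fit_listeners()` returns a list of `drex_fit` objects (named
#'   like `behaviors`).
#' @export
fit_listeners <- function(behaviors, experiment, variant,
                          grid = grid_spec(), margin = 0.05,
                          base_params = drex_params()) {
  cfg <- parse_variant(variant)
  if (!inherits(grid, "drex_grid")) {
    rlang::abort("`grid` must be a grid_spec().",
                 class = "drexr_error_parameter")
  }
  tk <- .experiment_tracks(experiment)
  cache <- .build_cache(tk, cfg, grid, base_params)
  lapply(behaviors, function(behavior) {
    ord <- match(tk$trials, behavior$trial)
    if (any(is.na(ord))) {
      rlang::abort("`behavior` must contain every experiment trial.",
                   class = "drexr_error_input")
    }
    detected <- behavior$detected[ord]
    fit <- .fit_from_cache(cache, cfg, grid, tk$condition, detected,
                           use = seq_along(tk$trials), margin = margin)
    model_rates <- detection_rates(
      tibble::tibble(condition = tk$condition,
                     detected = fit$max_delta >= fit$tau))
    rates <- dplyr::left_join(fit$listener_rates, model_rates,
                              by = "condition")
    names(rates)[names(rates) == "rate"] <- "model"
    structure(list(
      variant = cfg$name, stage = cfg$stage, operator = cfg$operator,
      M_f1 = fit$M_f1, N_f1 = fit$N_f1, M_f2 = fit$M_f2, N_f2 = fit$N_f2,
      tau = fit$tau, w = fit$w, mse = fit$mse, hinge = fit$hinge,
      margin = margin, rates = rates,
      trials = tibble::tibble(trial = tk$trials, condition = tk$condition,
                              max_delta = fit$max_delta,
                              listener_detected = detected,
                              model_detected = fit$max_delta >= fit$tau),
      grid = grid, n_trials = length(tk$trials)
    ), class = "drex_fit")
  })
}

#' @export
print.drex_fit <- function(x, ...) {
  cat("<drex_fit> variant", x$variant, "\n")
  cat(sprintf("  M = (%d, %d)  N = (%.4g, %.4g)  tau = %.3f%s\n",
              x$M_f1, x$M_f2, x$N_f1, x$N_f2, x$tau,
              if (!is.na(x$w)) sprintf("  w = %.2f", x$w) else ""))
  cat(sprintf("  detection-rate MSE = %.5f   hinge loss = %.5f  (%d trials)\n",
              x$mse, x$hinge, x$n_trials))
  invisible(x)
}

#' Cross-validated fit / evaluation split
#'
#' Repeats `n_iter` times: fit the model on a random half of trials
#' (stratified by condition) and evaluate detection sensitivity on the
#' held-out half, for both the fitted model and the listener.
#'
#' @inheritParams fit_listener
#' @param n_iter Number of random partitions (default 10).
#' @param seed Seed for the partitions.
#' @return A list of class `drex_cv`: `per_iteration` tibble
#'   (`iteration`, `d_prime_model`, `d_prime_listener`, `mse`, `hinge`)
#'   and their means in `summary`.
#' @export
cross_validate <- function(behavior, experiment, variant,
                           grid = grid_spec(), n_iter = 10L, seed = 1L,
                           margin = 0.05, base_params = drex_params()) {
  cfg <- parse_variant(variant)
  tk <- .experiment_tracks(experiment)
  ord <- match(tk$trials, behavior$trial)
  if (any(is.na(ord))) {
    rlang::abort("`behavior` must contain every experiment trial.",
                 class = "drexr_error_input")
  }
  detected <- behavior$detected[ord]
  conds <- attr(experiment, "conditions")
  per_cond <- split(seq_along(tk$trials), tk$condition)
  if (any(lengths(per_cond) < 2L)) {
    rlang::abort("need >= 2 trials per condition for cross-validation.",
                 class = "drexr_error_parameter")
  }
  cache <- .build_cache(tk, cfg, grid, base_params)
  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  res <- purrr::map_dfr(seq_len(n_iter), function(it) {
    train <- sort(unlist(lapply(per_cond, function(ix) {
      sample(ix, floor(length(ix) / 2))
    }), use.names = FALSE))
    test <- setdiff(seq_along(tk$trials), train)
    fit <- .fit_from_cache(cache, cfg, grid, tk$condition, detected,
                           use = train, margin = margin)
    model_rec <- tibble::tibble(condition = tk$condition[test],
                                detected = fit$max_delta[test] >= fit$tau)
    listener_rec <- tibble::tibble(condition = tk$condition[test],
                                   detected = detected[test])
    tibble::tibble(
      iteration = it,
      d_prime_model = performance_summary(model_rec, conds)$d_prime,
      d_prime_listener = performance_summary(listener_rec, conds)$d_prime,
      mse = fit$mse,
      hinge = hinge_loss(fit$max_delta[test], fit$tau, detected[test],
                         margin)
    )
  })
  structure(list(per_iteration = res,
                 summary = tibble::tibble(
                   d_prime_model = mean(res$d_prime_model),
                   d_prime_listener = mean(res$d_prime_listener),
                   mse = mean(res$mse), hinge = mean(res$hinge),
                   n_iter = n_iter)),
            class = "drex_cv")
}

#' Regress listener performance on fitted model parameters
#'
#' Ordinary least squares of a performance measure (typically d-prime) on
#' fitted perceptual parameters across listeners, as used to relate
#' individual differences to memory and noise parameters.
#'
#' @param data A data frame with one row per listener.
#' @param response Name of the performance column (default `"d_prime"`).
#' @param predictors Character vector of parameter columns (default the
#'   four perceptual parameters `M_f1`, `M_f2`, `N_f1`, `N_f2`).
#' @return A list with `coefficients` (tibble: `term`, `estimate`,
#'   `std_error`, `p_value`), `r_squared`, `n`, and the underlying `lm`
#'   fit.
#' @export
regress_performance <- function(data, response = "d_prime",
                                predictors = c("M_f1", "M_f2",
                                               "N_f1", "N_f2")) {
  if (nrow(data) < length(predictors) + 2L) {
    rlang::abort("need at least 2 more rows than predictors.",
                 class = "drexr_error_parameter")
  }
  X <- as.matrix(data[, predictors, drop = FALSE])
  if (qr(cbind(1, X))$rank < length(predictors) + 1L) {
    rlang::abort("design matrix is rank deficient.",
                 class = "drexr_error_singular")
  }
  fml <- stats::reformulate(predictors, response)
  fit <- stats::lm(fml, data = data)
  sm <- summary(fit)
  co <- sm$coefficients
  list(coefficients = tibble::tibble(term = rownames(co),
                                     estimate = unname(co[, 1]),
                                     std_error = unname(co[, 2]),
                                     p_value = unname(co[, 4])),
       r_squared = sm$r.squared, n = nrow(data), fit = fit)
}
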