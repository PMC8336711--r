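#' Enumerate the 32 multifeature model variants
#'
#' Variants cross the statistics order for each feature (`D` = 1 or 2), the
#' integration stage (early: predictions are combined across features
#' before the shared context-belief update; late: the belief-change signal
#' is computed per feature and combined before the decision), and the
#' integration operator (AVG, wAVG, MIN, MAX). Names follow the pattern
#' `stage_DXX_operator`, e.g. `Late_D22_MAX` = late integration, `D = 2`
#' for both features, maximum operator.
#'
#' @return A tibble with 32 rows: `name`, `stage`, `d_f1`, `d_f2`,
#'   `operator`.
#' @examples
#' drex_variants()
#' @export
drex_variants <- function() {
  grid <- expand.grid(operator = c("AVG", "wAVG", "MIN", "MAX"),
                      d_f2 = 1:2, d_f1 = 1:2,
                      stage = c("early", "late"),
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  out <- tibble::as_tibble(grid[, c("stage", "d_f1", "d_f2", "operator")])
  out$name <- paste0(ifelse(out$stage == "early", "Early", "Late"),
                     "_D", out$d_f1, out$d_f2, "_", out$operator)
  out[, c("name", "stage", "d_f1", "d_f2", "operator")]
}

#' Parse a variant name into its configuration
#'
#' @param name A variant name such as `"Late_D22_MAX"`, or a one-row data
#'   frame from [drex_variants()].
#' @return A one-row tibble with `name`, `stage`, `d_f1`, `d_f2`,
#'   `operator`.
#' @export
parse_variant <- function(name) {
  if (is.data.frame(name)) {
    stopifnot(nrow(name) == 1L)
    return(tibble::as_tibble(name))
  }
  m <- regmatches(name,
                  regexec("^(Early|Late)_D([12])([12])_(AVG|wAVG|MIN|MAX)$",
                          name))[[1]]
  if (length(m) == 0L) {
    rlang::abort(paste0("not a valid variant name: ", name),
                 class = "drexr_error_parameter")
  }
  tibble::tibble(name = name,
                 stage = tolower(m[2]),
                 d_f1 = as.integer(m[3]), d_f2 = as.integer(m[4]),
                 operator = m[5])
}

#' Combine two values with an integration operator
#'
#' AVG is the arithmetic mean, wAVG the convex combination
#' `w * a + (1 - w) * b`, MIN and MAX the elementwise extremes. Vectorized
#' over `a` and `b`.
#'
#' @param a,b Numeric values (per-feature evidence or belief-change
#'   signals).
#' @param operator One of `"AVG"`, `"wAVG"`, `"MIN"`, `"MAX"`.
#' @param w Convex weight in `[0, 1]`; required for `wAVG`.
#' @return Combined numeric values.
#' @examples
#' combine_features(0.2, 0.8, "AVG")
#' @export
combine_features <- function(a, b, operator = c("AVG", "wAVG", "MIN", "MAX"),
                             w = NULL) {
  operator <- match.arg(operator)
  if (operator == "wAVG") {
    if (is.null(w) || length(w) != 1L || is.na(w) || w < 0 || w > 1) {
      rlang::abort("`wAVG` requires a weight `w` in [0, 1].",
                   class = "drexr_error_parameter")
    }
  }
  switch(operator,
    AVG  = (a + b) / 2,
    wAVG = w * a + (1 - w) * b,
    MIN  = pmin(a, b),
    MAX  = pmax(a, b)
  )
}

.combiner_fn <- function(operator, w = NULL) {
  switch(operator,
    AVG  = function(v) (v[1L] + v[2L]) / 2,
    wAVG = function(v) w * v[1L] + (1 - w) * v[2L],
    MIN  = function(v) min(v),
    MAX  = function(v) max(v)
  )
}

# Extract per-feature seed matrices (tone x 1) from a stimulus tibble in
# the feature order of the condition design (pitch first).
.stimulus_tracks <- function(stimulus) {
  feats <- unique(stimulus$feature)
  if (length(feats) != 2L) {
    rlang::abort("stimulus must contain exactly two features.",
                 class = "drexr_error_input")
  }
  lapply(feats, function(f) stimulus$seed_value[stimulus$feature == f])
}

#' Run a multifeature model variant on one stimulus
#'
#' Late-stage variants run two independent single-feature models (each
#' with its own `M` and `N`) and combine the two belief-change traces
#' elementwise with the operator. Early-stage variants share one set of
#' context hypotheses and beliefs across features: within each hypothesis
#' separate per-feature statistics are kept, per-hypothesis per-feature
#' predictive densities are combined by the operator into a single
#' evidence value for the shared belief update, and a single shared
#' belief-change trace results. Per-feature surprisals are retained in
#' both stages; overall surprisal is their sum.
#'
#' @param stimulus A per-tone tibble from [build_stimulus()], a trial
#'   subset of [build_experiment()], or a list of two numeric seed tracks.
#' @param variant A variant name or a row of [drex_variants()]; its `D`
#'   settings override those in the params.
#' @param params_f1,params_f2 [drex_params()] for each feature. For early
#'   integration the shared memory bound, hazard and prior are taken from
#'   `params_f1`; `N` stays per feature.
#' @param w Convex weight for the `wAVG` operator.
#' @return A tibble of class `drex_joint_trace` with columns `tone`,
#'   `surprisal_f1`, `surprisal_f2`, `surprisal_total`, `delta_f1`,
#'   `delta_f2` (`NA` for early variants), `delta_combined`.
#' @examples
#' stim <- build_stimulus(design_conditions("nsp")[1, ], seed = 1)
#' tr <- run_variant(stim, "Late_D11_MAX", drex_params(M = 6))
#' tr[29:34, ]
#' @export
run_variant <- function(stimulus, variant, params_f1,
                        params_f2 = params_f1, w = NULL) {
  cfg <- parse_variant(variant)
  if (cfg$operator == "wAVG" && (is.null(w) || w < 0 || w > 1)) {
    rlang::abort("`wAVG` requires a weight `w` in [0, 1].",
                 class = "drexr_error_parameter")
  }
  tracks <- if (is.list(stimulus) && !is.data.frame(stimulus)) stimulus
            else .stimulus_tracks(stimulus)
  x1 <- tracks[[1]]; x2 <- tracks[[2]]
  if (length(x1) != length(x2)) {
    rlang::abort("feature tracks must have equal length.",
                 class = "drexr_error_input")
  }

  if (cfg$stage == "late") {
    p1 <- params_f1; p1$D <- cfg$d_f1
    p2 <- params_f2; p2$D <- cfg$d_f2
    t1 <- run_drex(x1, p1)
    t2 <- run_drex(x2, p2)
    out <- tibble::tibble(
      tone = t1$tone,
      surprisal_f1 = t1$surprisal,
      surprisal_f2 = t2$surprisal,
      surprisal_total = t1$surprisal + t2$surprisal,
      delta_f1 = t1$belief_change,
      delta_f2 = t2$belief_change,
      delta_combined = combine_features(t1$belief_change, t2$belief_change,
                                        cfg$operator, w)
    )
  } else {
    spec <- .engine_spec(D = c(cfg$d_f1, cfg$d_f2),
                         N = c(params_f1$N, params_f2$N),
                         M = params_f1$M, hazard = params_f1$hazard,
                         prior_mean = params_f1$prior_mean,
                         prior_scale = params_f1$prior_scale,
                         prior_n = params_f1$prior_n,
                         combine = .combiner_fn(cfg$operator, w))
    st <- drex_init(spec)
    n <- length(x1)
    s1 <- s2 <- dlt <- numeric(n)
    for (t in seq_len(n)) {
      step <- drex_step(st, c(x1[t], x2[t]))
      st <- step$state
      s1[t] <- step$surprisal[1L]
      s2[t] <- step$surprisal[2L]
      dlt[t] <- step$delta
    }
    out <- tibble::tibble(
      tone = seq_len(n),
      surprisal_f1 = s1, surprisal_f2 = s2, surprisal_total = s1 + s2,
      delta_f1 = NA_real_, delta_f2 = NA_real_,
      delta_combined = dlt
    )
  }
  attr(out, "variant") <- cfg$name
  class(out) <- c("drex_joint_trace", class(out))
  out
}

#' Overall surprisal: elementwise sum across features
#'
#' @param s1 A joint-trace tibble (columns `surprisal_f1`, `surprisal_f2`)
#'   or a numeric per-feature surprisal sequence.
#' @param s2 Second per-feature surprisal sequence when `s1` is numeric.
#' @return Numeric sequence of overall surprisal (nats).
#' @export
overall_surprisal <- function(s1, s2 = NULL) {
  if (is.data.frame(s1)) {
    return(s1$surprisal_f1 + s1$surprisal_f2)
  }
  if (length(s1) != length(s2)) {
    rlang::abort("per-feature surprisals must have equal length.",
                 class = "drexr_error_contract")
  }
  s1 + s2
}

#' Model change-detection response for a joint trace
#'
#' Applies the detection threshold to the combined belief-change trace;
#' the detection time is the earliest tone attaining the maximum.
#'
#' @param trace A `drex_joint_trace` (or any table with `delta_combined`).
#' @param tau Nonnegative detection threshold (nats).
#' @return One-row tibble: `detected`, `time`, `max_delta`.
#' @export
model_response <- function(trace, tau) {
  detect_change(trace, tau)
}
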