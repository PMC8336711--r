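#' Stimulus condition tables for the four experiment designs
#'
#' Returns the per-condition entropy design of one of the four built-in
#' experiments. Each stimulus is a 60-tone melody whose two features follow
#' independent random-fractal contours; at the midpoint, one or both
#' features may switch to high entropy (`beta = 0`). Designs:
#'
#' * `"sp"` / `"tp"`: psychophysics designs (pitch + spatial, pitch +
#'   timbre), 8 conditions x 25 repetitions, tones at 10 Hz. Five change
#'   conditions (both features change; one feature changes while the other
#'   stays at low or mid entropy) and three no-change controls (low/low,
#'   low/mid, mid/low).
#' * `"nsp"` / `"ntp"`: EEG designs, 4 conditions x 50 repetitions, tones at
#'   8.6 Hz. Both-change, each single-change (nonchanging feature at low
#'   entropy), and a no-change control.
#'
#' Entropy levels are low (`beta = 2.5`), mid (`beta = 2`) and high
#' (`beta = 0`). Entropy only ever increases at the change.
#'
#' @param design One of `"sp"`, `"tp"`, `"nsp"`, `"ntp"`.
#' @return A tibble with one row per condition: `condition`, `feature_1`,
#'   `feature_2`, `beta_pre_1`, `beta_post_1`, `beta_pre_2`, `beta_post_2`,
#'   `n_reps`, plus attributes `onset_rate` (Hz) and `tone_count`.
#' @examples
#' design_conditions("nsp")
#' @export
design_conditions <- function(design = c("sp", "tp", "nsp", "ntp")) {
  design <- match.arg(design)
  f2 <- if (design %in% c("sp", "nsp")) "spatial" else "timbre"
  lo <- 2.5; mid <- 2; hi <- 0
  if (design %in% c("nsp", "ntp")) {
    out <- tibble::tibble(
      condition   = c("both", "pitch", f2, "control"),
      feature_1   = "pitch",
      feature_2   = f2,
      beta_pre_1  = c(lo, lo, lo, lo),
      beta_post_1 = c(hi, hi, lo, lo),
      beta_pre_2  = c(lo, lo, lo, lo),
      beta_post_2 = c(hi, lo, hi, lo),
      n_reps      = 50L
    )
    attr(out, "onset_rate") <- 8.6
  } else {
    out <- tibble::tibble(
      condition = c("both",
                    "pitch_low", "pitch_mid",
                    paste0(f2, "_low"), paste0(f2, "_mid"),
                    "control_low_low", "control_low_mid", "control_mid_low"),
      feature_1   = "pitch",
      feature_2   = f2,
      beta_pre_1  = c(lo, lo, lo,  lo, lo,  lo, lo, mid),
      beta_post_1 = c(hi, hi, hi,  lo, lo,  lo, lo, mid),
      beta_pre_2  = c(lo, lo, mid, lo, mid, lo, mid, lo),
      beta_post_2 = c(hi, lo, mid, hi, hi,  lo, mid, lo),
      n_reps      = 25L
    )
    attr(out, "onset_rate") <- 10
  }
  attr(out, "tone_count") <- 60L
  attr(out, "design") <- design
  out
}

#' Inter-onset interval for a tone presentation rate
#'
#' @param rate_hz Presentation rate in Hz.
#' @return Interval between tone onsets in milliseconds.
#' @examples
#' onset_interval_ms(8.6) # ~116 ms
#' @export
onset_interval_ms <- function(rate_hz) {
  if (!is.numeric(rate_hz) || any(rate_hz <= 0)) {
    rlang::abort("`rate_hz` must be positive.", class = "drexr_error_parameter")
  }
  1000 / rate_hz
}

#' Build one multifeature stimulus
#'
#' Assembles a per-tone table for a single melody: each feature follows a
#' standardized, bounded fractal seed, mapped to its physical scale. For a
#' changing feature, the track is a pre-change segment (length
#' `tone_count/2`, at `beta_pre`) followed by an independent post-change
#' segment (at `beta_post`); each segment is generated and standardized
#' separately, with no continuity constraint at the join. Nonchanging
#' features use one full-length seed. The first changed tone is
#' `tone_count/2 + 1`.
#'
#' @param condition A one-row data frame as returned by
#'   [design_conditions()] (columns `condition`, `feature_1`, `feature_2`,
#'   `beta_pre_*`, `beta_post_*`).
#' @param tone_count Even number of tones (default 60).
#' @param seed Integer seed; per-feature and per-segment substreams are
#'   derived from it deterministically.
#' @return A tibble of `tone_count * 2` rows with columns `tone`, `feature`,
#'   `seed_value`, `physical_value`, and attributes `condition`,
#'   `changepoint` (first changed tone, or `NA` for controls).
#' @examples
#' cond <- design_conditions("nsp")[1, ]
#' stim <- build_stimulus(cond, seed = 1)
#' head(stim)
#' @export
build_stimulus <- function(condition, tone_count = 60L, seed = NULL) {
  stopifnot(is.data.frame(condition), nrow(condition) == 1L)
  if (tone_count %% 2L != 0L || tone_count < 4L) {
    rlang::abort("`tone_count` must be an even integer >= 4.",
                 class = "drexr_error_parameter")
  }
  tone_count <- as.integer(tone_count)
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  sub_seeds <- sample.int(2147483646L, 4L)
  feats <- c(condition$feature_1, condition$feature_2)
  pre  <- c(condition$beta_pre_1,  condition$beta_pre_2)
  post <- c(condition$beta_post_1, condition$beta_post_2)
  half <- tone_count %/% 2L

  tracks <- purrr::map(1:2, function(k) {
    if (pre[k] == post[k]) {
      generate_fractal(pre[k], tone_count, seed = sub_seeds[2 * k - 1])
    } else {
      c(generate_fractal(pre[k],  half, seed = sub_seeds[2 * k - 1]),
        generate_fractal(post[k], half, seed = sub_seeds[2 * k]))
    }
  })
  changes <- pre != post
  out <- tibble::tibble(
    tone = rep(seq_len(tone_count), times = 2L),
    feature = rep(feats, each = tone_count),
    seed_value = c(tracks[[1]], tracks[[2]]),
    physical_value = c(map_to_feature(tracks[[1]], feats[1]),
                       map_to_feature(tracks[[2]], feats[2]))
  )
  attr(out, "condition") <- condition$condition
  attr(out, "changepoint") <- if (any(changes)) half + 1L else NA_integer_
  attr(out, "changed_features") <- feats[changes]
  class(out) <- c("drex_stimulus", class(out))
  out
}

#' Build a full randomized experiment of stimuli
#'
#' Expands a condition table by its repetition counts, draws an independent
#' fractal seed per stimulus and per feature, and returns the trials in a
#' seeded random presentation order.
#'
#' @param conditions A condition tibble from [design_conditions()], or a
#'   design name (`"sp"`, `"tp"`, `"nsp"`, `"ntp"`).
#' @param seed Integer experiment seed; all per-trial randomness is derived
#'   from it, so identical seeds give identical experiments.
#' @param tone_count Even number of tones per melody (default from the
#'   condition table, 60).
#' @return A long tibble with one row per trial x tone x feature:
#'   `trial`, `condition`, `changepoint`, `tone`, `feature`, `seed_value`,
#'   `physical_value`. Attributes: `conditions`, `onset_rate`, `tone_count`.
#' @examples
#' ex <- build_experiment("nsp", seed = 1)
#' dplyr::n_distinct(ex$trial)
#' @export
build_experiment <- function(conditions, seed = 1L, tone_count = NULL) {
  if (is.character(conditions)) conditions <- design_conditions(conditions)
  if (!is.data.frame(conditions) || nrow(conditions) == 0L) {
    rlang::abort("`conditions` must be a nonempty condition table.",
                 class = "drexr_error_parameter")
  }
  if (is.null(tone_count)) {
    tone_count <- attr(conditions, "tone_count") %||% 60L
  }
  n_reps <- if ("n_reps" %in% names(conditions)) conditions$n_reps else
    rep(1L, nrow(conditions))
  if (any(n_reps < 0)) {
    rlang::abort("repetition counts must be >= 0.",
                 class = "drexr_error_parameter")
  }
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))

  idx <- rep(seq_len(nrow(conditions)), times = n_reps)
  n_trials <- length(idx)
  if (n_trials == 0L) {
    out <- tibble::tibble(trial = integer(), condition = character(),
                          changepoint = integer(), tone = integer(),
                          feature = character(), seed_value = double(),
                          physical_value = double())
  } else {
    order <- sample.int(n_trials)
    idx <- idx[order]
    trial_seeds <- sample.int(2147483646L, n_trials)
    out <- purrr::map2_dfr(seq_len(n_trials), idx, function(tr, ci) {
      st <- build_stimulus(conditions[ci, ], tone_count = tone_count,
                           seed = trial_seeds[tr])
      tibble::tibble(trial = tr,
                     condition = attr(st, "condition"),
                     changepoint = attr(st, "changepoint"),
                     tone = st$tone, feature = st$feature,
                     seed_value = st$seed_value,
                     physical_value = st$physical_value)
    })
  }
  attr(out, "conditions") <- conditions
  attr(out, "onset_rate") <- attr(conditions, "onset_rate")
  attr(out, "tone_count") <- as.integer(tone_count)
  class(out) <- c("drex_experiment", class(out))
  out
}

#' Write / read an experiment as plain-text files
#'
#' Serializes the per-tone table as CSV and the design metadata (conditions,
#' tone count, onset rate, changepoints) as JSON.
#'
#' @param experiment A tibble from [build_experiment()].
#' @param dir Output directory (created if needed).
#' @return `write_experiment()` returns `dir` invisibly; `read_experiment()`
#'   returns the experiment tibble.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(experiment),
                   file.path(dir, "stimuli.csv"), row.names = FALSE)
  meta <- list(
    conditions = as.data.frame(attr(experiment, "conditions")),
    onset_rate = attr(experiment, "onset_rate"),
    tone_count = attr(experiment, "tone_count")
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_experiment
#' @export
read_experiment <- function(dir) {
  tab <- tibble::as_tibble(utils::read.csv(file.path(dir, "stimuli.csv")))
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  conds <- tibble::as_tibble(meta$conditions)
  attr(conds, "onset_rate") <- meta$onset_rate
  attr(conds, "tone_count") <- meta$tone_count
  attr(tab, "conditions") <- conds
  attr(tab, "onset_rate") <- meta$onset_rate
  attr(tab, "tone_count") <- meta$tone_count
  class(tab) <- c("drex_experiment", class(tab))
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
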