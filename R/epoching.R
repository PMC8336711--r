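#' Epoch analysis specification
#'
#' Windows (ms relative to tone onset) and sampling rate used by the
#' epoch-alignment utilities. Defaults: epochs from -1000 to 1500 ms, an
#' early analysis window at 80-150 ms (frontocentral-negativity latency)
#' and a late window at 300-800 ms (centroparietal-positivity latency),
#' with baseline windows at -152 to -82 ms and -630 to -130 ms.
#'
#' @param window Epoch extent `(start, end)` in ms.
#' @param rate Sampling rate in Hz.
#' @param early,late Analysis windows in ms.
#' @param baseline_early,baseline_late Baseline windows in ms.
#' @return A list of class `epoch_spec`.
#' @export
epoch_spec <- function(window = c(-1000, 1500), rate = 256,
                       early = c(80, 150), late = c(300, 800),
                       baseline_early = c(-152, -82),
                       baseline_late = c(-630, -130)) {
  stopifnot(window[1] < window[2], rate > 0)
  wins <- list(early, late, baseline_early, baseline_late)
  ok <- vapply(wins, function(w) w[1] < w[2] && w[1] >= window[1] &&
                 w[2] <= window[2], logical(1))
  if (!all(ok)) {
    rlang::abort("analysis/baseline windows must lie within the epoch.",
                 class = "drexr_error_parameter")
  }
  structure(list(window = window, rate = rate, early = early, late = late,
                 baseline_early = baseline_early,
                 baseline_late = baseline_late),
            class = "epoch_spec")
}

#' Flag model-defined alignment events
#'
#' Pools overall surprisal across all tones of a subject's trials and
#' flags tones above the `100 - percentile` and below the `percentile`
#' pooled percentiles as high- and low-surprisal events, plus the single
#' tone of maximal combined belief change per trial. A tone qualifying as
#' both high-surprisal and maximal belief change is assigned to the
#' latter only, keeping the event sets disjoint. Ties at the thresholds
#' are resolved by stable `(trial, tone)` order.
#'
#' @param traces A tibble with columns `trial`, `tone`,
#'   `surprisal_total` and `delta_combined` (e.g. row-bound joint traces
#'   with a `trial` column).
#' @param percentile Tail percentage in `(0, 50)` (default 5).
#' @return A tibble `trial`, `tone`, `event` with event one of
#'   `"high_surprisal"`, `"low_surprisal"`, `"max_belief_change"`.
#' @export
flag_events <- function(traces, percentile = 5) {
  if (!is.data.frame(traces) || nrow(traces) == 0L) {
    rlang::abort("`traces` must be a nonempty data frame.",
                 class = "drexr_error_input")
  }
  if (percentile <= 0 || percentile >= 50) {
    rlang::abort("`percentile` must be in (0, 50).",
                 class = "drexr_error_parameter")
  }
  tr <- traces[order(traces$trial, traces$tone), ]
  n <- nrow(tr)
  n_sel <- ceiling(n * percentile / 100)
  lo_idx <- order(tr$surprisal_total, tr$trial, tr$tone)[seq_len(n_sel)]
  hi_idx <- order(-tr$surprisal_total, tr$trial, tr$tone)[seq_len(n_sel)]
  hi_idx <- setdiff(hi_idx, lo_idx)
  maxd <- max_belief_change_event(tr)
  maxd_key <- paste(maxd$trial, maxd$tone)
  hi_key <- paste(tr$trial[hi_idx], tr$tone[hi_idx])
  hi_idx <- hi_idx[!hi_key %in% maxd_key]
  out <- dplyr::bind_rows(
    tibble::tibble(trial = tr$trial[hi_idx], tone = tr$tone[hi_idx],
                   event = "high_surprisal"),
    tibble::tibble(trial = tr$trial[lo_idx], tone = tr$tone[lo_idx],
                   event = "low_surprisal"),
    tibble::tibble(trial = maxd$trial, tone = maxd$tone,
                   event = "max_belief_change")
  )
  out[order(out$trial, out$tone), ]
}

#' Tone of maximal belief change per trial
#'
#' @param traces Tibble with columns `trial`, `tone`, `delta_combined`
#'   (or `belief_change`); one row per trial is returned, at the earliest
#'   tone attaining the per-trial maximum.
#' @return Tibble `trial`, `tone`, `delta`.
#' @export
max_belief_change_event <- function(traces) {
  delta <- if ("delta_combined" %in% names(traces)) traces$delta_combined
           else traces$belief_change
  if (is.null(delta) || length(delta) == 0L) {
    rlang::abort("`traces` must contain a belief-change column.",
                 class = "drexr_error_input")
  }
  df <- tibble::tibble(trial = traces$trial, tone = traces$tone,
                       delta = delta)
  df <- df[order(df$trial, df$tone), ]
  df |>
    dplyr::group_by(.data$trial) |>
    dplyr::slice(which.max(.data$delta)) |>
    dplyr::ungroup()
}

#' Equal-occupancy binning of response magnitude by surprisal
#'
#' Rank-based binning: epochs are assigned to `n_bins` bins of equal
#' occupancy (sizes differ by at most one) in order of surprisal, and the
#' mean surprisal and mean response magnitude are reported per bin.
#'
#' @param surprisal Per-epoch overall surprisal (nats).
#' @param magnitude Per-epoch response magnitude (e.g. microvolts or dB).
#' @param n_bins Number of bins (default 40; must not exceed the number
#'   of epochs).
#' @return A tibble `bin`, `n`, `mean_surprisal`, `mean_magnitude` of
#'   class `drex_binned`.
#' @export
bin_by_surprisal <- function(surprisal, magnitude, n_bins = 40L) {
  n <- length(surprisal)
  if (length(magnitude) != n) {
    rlang::abort("`surprisal` and `magnitude` must be aligned.",
                 class = "drexr_error_contract")
  }
  if (n_bins > n || n_bins < 1L) {
    rlang::abort("`n_bins` must be between 1 and the number of epochs.",
                 class = "drexr_error_parameter")
  }
  ord <- order(surprisal)
  bin <- integer(n)
  bin[ord] <- .equal_chunks(n, n_bins)
  out <- tibble::tibble(surprisal = surprisal, magnitude = magnitude,
                        bin = bin) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_surprisal = mean(.data$surprisal),
                     mean_magnitude = mean(.data$magnitude),
                     .groups = "drop")
  attr(out, "assignments") <- bin
  class(out) <- c("drex_binned", class(out))
  out
}

# n items into k consecutive chunks with sizes differing by <= 1
.equal_chunks <- function(n, k) {
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(k), times = sizes)
}

#' Equal-occupancy binning in a two-feature surprisal space
#'
#' Splits the 2-D space spanned by the per-feature surprisals into
#' `n_bins` cells of equal occupancy by recursive median bifurcation:
#' at each level the epochs of a cell are split at the median rank along
#' one dimension, alternating dimensions between levels, until `n_bins`
#' (a power of two) cells remain.
#'
#' @param surprisal_f1,surprisal_f2 Per-epoch surprisal along each
#'   feature (nats).
#' @param magnitude Per-epoch response magnitude.
#' @param n_bins Number of cells; must be a power of two (default 128).
#' @return A tibble `bin`, `n`, `mean_surprisal_f1`, `mean_surprisal_f2`,
#'   `mean_magnitude` of class `drex_binned2`.
#' @export
bin_by_surprisal2 <- function(surprisal_f1, surprisal_f2, magnitude,
                              n_bins = 128L) {
  n <- length(magnitude)
  if (length(surprisal_f1) != n || length(surprisal_f2) != n) {
    rlang::abort("inputs must be aligned.", class = "drexr_error_contract")
  }
  if (n_bins < 1L || bitwAnd(n_bins, n_bins - 1L) != 0L) {
    rlang::abort("`n_bins` must be a power of two.",
                 class = "drexr_error_parameter")
  }
  if (n_bins > n) {
    rlang::abort("`n_bins` must not exceed the number of epochs.",
                 class = "drexr_error_parameter")
  }
  depth <- as.integer(round(log2(n_bins)))
  bin <- rep(1L, n)
  s <- list(surprisal_f1, surprisal_f2)
  if (depth > 0) {
    for (level in seq_len(depth)) {
      dim_k <- s[[(level - 1L) %% 2L + 1L]]
      new_bin <- bin
      for (cell in unique(bin)) {
        ix <- which(bin == cell)
        ord <- ix[order(dim_k[ix])]
        half <- .equal_chunks(length(ix), 2L)
        new_bin[ord] <- 2L * (cell - 1L) + half
      }
      bin <- new_bin
    }
  }
  out <- tibble::tibble(s1 = surprisal_f1, s2 = surprisal_f2,
                        magnitude = magnitude, bin = bin) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_surprisal_f1 = mean(.data$s1),
                     mean_surprisal_f2 = mean(.data$s2),
                     mean_magnitude = mean(.data$magnitude),
                     .groups = "drop")
  attr(out, "assignments") <- bin
  class(out) <- c("drex_binned2", class(out))
  out
}

#' Reject high-power epochs
#'
#' Computes the mean squared amplitude of each epoch (over channels and
#' samples) and removes epochs whose power exceeds the mean by more than
#' `k` standard deviations. With zero spread across epochs nothing is
#' removed.
#'
#' @param epochs A 3-D array `(epoch, channel, time)` or a matrix
#'   `(epoch, time)`.
#' @param k Rejection threshold in SD units (default 2, `> 0`).
#' @return The retained epochs (same layout), with the kept indices in
#'   attribute `"kept"`.
#' @export
reject_epochs <- function(epochs, k = 2) {
  if (k <= 0) rlang::abort("`k` must be > 0.",
                           class = "drexr_error_parameter")
  dims <- dim(epochs)
  if (is.null(dims) || !length(dims) %in% 2:3) {
    rlang::abort("`epochs` must be a matrix or 3-D array.",
                 class = "drexr_error_input")
  }
  n <- dims[1]
  if (n < 3L) {
    rlang::abort("need at least 3 epochs.", class = "drexr_error_input")
  }
  power <- apply(epochs, 1L, function(e) mean(e^2))
  s <- stats::sd(power)
  keep <- if (!is.finite(s) || s == 0) rep(TRUE, n)
          else power <= mean(power) + k * s
  out <- if (length(dims) == 3L) epochs[keep, , , drop = FALSE]
         else epochs[keep, , drop = FALSE]
  attr(out, "kept") <- which(keep)
  out
}

#' Baseline-relative rms magnitude of a window, in decibels
#'
#' `20 * log10(rms(window) / rms(baseline))` of a channel-averaged epoch
#' series. Sample times are `t0 + (0:(n-1)) * 1000 / rate` ms; windows
#' are half-open `[start, end)`.
#'
#' @param epoch Channel-averaged numeric series.
#' @param window,baseline `(start, end)` in ms relative to the alignment
#'   event.
#' @param rate Sampling rate (Hz).
#' @param t0 Time of the first sample (ms, default -1000).
#' @return Magnitude in dB.
#' @examples
#' window_rms_db(rep(c(1, 10), each = 100), c(50, 80), c(-80, -50),
#'               rate = 1000, t0 = -100)
#' @export
window_rms_db <- function(epoch, window, baseline, rate, t0 = -1000) {
  times <- t0 + (seq_along(epoch) - 1L) * 1000 / rate
  pick <- function(w) {
    ix <- times >= w[1] & times < w[2]
    if (!any(ix)) {
      rlang::abort("window contains no samples.",
                   class = "drexr_error_parameter")
    }
    sqrt(mean(epoch[ix]^2))
  }
  r_w <- pick(window)
  r_b <- pick(baseline)
  if (r_b == 0) {
    rlang::abort("baseline rms is zero.", class = "drexr_error_domain")
  }
  20 * log10(r_w / r_b)
}

#' Synthesize multichannel epochs with a surprisal-scaled response
#'
#' Test-bench signal generator: each epoch contains a template deflection
#' (half-cosine bump spanning the early analysis window) whose amplitude
#' is `gain * surprisal`, identical across channels, plus independent
#' Gaussian noise. Supports end-to-end checks of binning, rejection and
#' regression utilities; it emulates an evoked response proportional to
#' surprisal and none of the richer structure of recorded signals.
#'
#' @param surprisal Per-epoch surprisal values driving the response.
#' @param gain Response amplitude per unit surprisal (`>= 0`).
#' @param noise_sd Gaussian noise SD (`>= 0`).
#' @param spec An [epoch_spec()].
#' @param n_channels Number of channels (default 4).
#' @param seed Optional seed.
#' @return A 3-D array `(epoch, channel, time)` with attribute `"times"`
#'   (ms).
#' @export
synth_epochs <- function(surprisal, gain = 1, noise_sd = 0,
                         spec = epoch_spec(), n_channels = 4L,
                         seed = NULL) {
  if (gain < 0 || noise_sd < 0) {
    rlang::abort("`gain` and `noise_sd` must be >= 0.",
                 class = "drexr_error_parameter")
  }
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  times <- seq(spec$window[1], spec$window[2] - 1000 / spec$rate,
               by = 1000 / spec$rate)
  n_t <- length(times)
  w <- spec$early
  bump <- ifelse(times >= w[1] & times < w[2],
                 sin(pi * (times - w[1]) / (w[2] - w[1])), 0)
  n_e <- length(surprisal)
  out <- array(stats::rnorm(n_e * n_channels * n_t, 0, noise_sd),
               dim = c(n_e, n_channels, n_t))
  signal <- outer(gain * surprisal, bump)  # epoch x time
  for (ch in seq_len(n_channels)) out[, ch, ] <- out[, ch, ] + signal
  attr(out, "times") <- times
  out
}
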