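#' Generate a random-fractal (1/f^beta) seed sequence
#'
#' Synthesizes a stochastic sequence whose expected power spectrum falls off
#' as `1/f^beta`, by inverse-FFT spectral synthesis: one-sided amplitudes
#' proportional to `f^(-beta/2)` over FFT bins `1..floor(n/2)`, zero DC
#' amplitude, independent uniform random phases, conjugate-symmetric
#' spectrum. The real part of the inverse transform is then standardized to
#' zero mean and unit variance and bounded to `[-bound, bound]`.
#'
#' `beta` parameterizes the entropy of the sequence: `beta = 0` is white
#' noise (maximal entropy), larger `beta` gives smoother, more predictable
#' contours. The seed regimes used throughout the package are low entropy
#' (`beta = 2.5`), mid entropy (`beta = 2`) and high entropy (`beta = 0`).
#'
#' @param beta Nonnegative spectral exponent (log-log slope of the power
#'   spectrum, unitless).
#' @param n Sequence length in tones (`>= 2`).
#' @param seed Optional integer seed for reproducibility. When `NULL`, the
#'   current RNG state is used.
#' @param bound Symmetric bound applied after standardization (seed units,
#'   default 3).
#'
#' @return A numeric vector of length `n`, standardized and bounded.
#' @seealso [standardize_and_bound()], [map_to_feature()], [estimate_slope()]
#' @examples
#' x <- generate_fractal(2.5, 60, seed = 1)
#' range(x)
#' @export
generate_fractal <- function(beta, n, seed = NULL, bound = 3) {
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta < 0) {
    rlang::abort("`beta` must be a single nonnegative number.",
                 class = "drexr_error_parameter")
  }
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 2) {
    rlang::abort("`n` must be a single integer >= 2.",
                 class = "drexr_error_parameter")
  }
  n <- as.integer(n)
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  half <- n %/% 2L
  freq <- seq_len(half)
  amp <- freq^(-beta / 2)
  phase <- stats::runif(half, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  # Nyquist bin of an even-length FFT must be real for a real signal
  if (n %% 2L == 0L) spec[half] <- complex(real = amp[half] * cos(phase[half]),
                                           imaginary = 0)
  full <- complex(length.out = n)
  full[1L] <- 0 + 0i
  full[1L + freq] <- spec
  if (n %% 2L == 0L) {
    if (half > 1L) full[n:(half + 2L)] <- Conj(spec[1:(half - 1L)])
  } else {
    full[n:(half + 1L)] <- Conj(spec)
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  standardize_and_bound(x, bound = bound)
}

#' Standardize a sequence and bound it
#'
#' Centers to zero mean and scales to unit variance, then clips values to
#' `[-bound, bound]`. Clipping (rather than resampling) keeps the operation
#' deterministic; the physical feature ranges correspond exactly to seed
#' values at the default bound of 3.
#'
#' @param x Numeric vector, length `>= 2`, nonconstant.
#' @param bound Symmetric clip bound (default 3).
#' @return Numeric vector of the same length; mean 0 and SD 1 before
#'   clipping.
#' @examples
#' standardize_and_bound(c(1, 2, 3))
#' @export
standardize_and_bound <- function(x, bound = 3) {
  if (!is.numeric(x) || length(x) < 2L) {
    rlang::abort("`x` must be a numeric vector of length >= 2.",
                 class = "drexr_error_parameter")
  }
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    rlang::abort("`x` has zero variance; cannot standardize.",
                 class = "drexr_error_zero_variance")
  }
  z <- (x - mean(x)) / s
  pmin(pmax(z, -bound), bound)
}

#' Feature mappings from seed units to physical units
#'
#' Maps a standardized, bounded seed sequence to physical feature values:
#' * `pitch`: fundamental frequency `350 * 2^(3 x / 12)` Hz
#'   (3 semitones per seed unit around 350 Hz);
#' * `spatial`: azimuth `15 * y` degrees;
#' * `timbre`: spectral centroid `1200 * 2^(3 z / 12)` Hz.
#'
#' With seeds bounded in `[-3, 3]` the ranges are 208-589 Hz (pitch),
#' -45 to 45 degrees (spatial) and 714-2018 Hz (timbre), to the nearest
#' unit.
#'
#' @param seed Numeric seed vector in `[-3, 3]` (seed units).
#' @param feature One of `"pitch"`, `"spatial"`, `"timbre"`.
#' @return Numeric vector of physical values (Hz or degrees).
#' @examples
#' map_to_feature(c(-3, 0, 3), "pitch")
#' @export
map_to_feature <- function(seed, feature = c("pitch", "spatial", "timbre")) {
  feature <- tryCatch(match.arg(feature), error = function(e) {
    rlang::abort("`feature` must be one of 'pitch', 'spatial', 'timbre'.",
                 class = "drexr_error_parameter")
  })
  switch(feature,
    pitch   = 350 * 2^(3 * seed / 12),
    spatial = 15 * seed,
    timbre  = 1200 * 2^(3 * seed / 12)
  )
}

#' Inverse of the feature mapping (physical units to seed units)
#'
#' @param physical Numeric vector of physical values (Hz or degrees).
#' @param feature One of `"pitch"`, `"spatial"`, `"timbre"`.
#' @return Numeric vector on the seed scale.
#' @export
map_from_feature <- function(physical, feature = c("pitch", "spatial", "timbre")) {
  feature <- match.arg(feature)
  switch(feature,
    pitch   = 12 * log2(physical / 350) / 3,
    spatial = physical / 15,
    timbre  = 12 * log2(physical / 1200) / 3
  )
}

#' Estimate the spectral exponent of a sequence
#'
#' Least-squares fit of log power versus log frequency on the periodogram
#' (FFT bins `1..floor(n/2)`, DC excluded). Returns the estimated `beta`,
#' i.e. the negative of the fitted slope. Used as an independent check that
#' generated fractal seeds have the requested spectral exponent.
#'
#' @param x Numeric sequence.
#' @return Estimated spectral exponent (unitless).
#' @examples
#' estimate_slope(generate_fractal(2, 1024, seed = 2))
#' @export
estimate_slope <- function(x) {
  n <- length(x)
  half <- n %/% 2L
  po <- Mod(stats::fft(x))^2 / n
  f <- seq_len(half)
  pw <- po[1L + f]
  keep <- pw > 0
  fit <- stats::lm.fit(cbind(1, log(f[keep])), log(pw[keep]))
  -unname(fit$coefficients[2L])
}

# RNG bookkeeping: save/restore the global .Random.seed so seeded helpers
# do not disturb the caller's stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
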