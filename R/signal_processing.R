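#' Filter specification for zero-lag Butterworth filtering
#'
#' Describes a one-pass Butterworth design that is applied forward and
#' backward ("zero-lag") over a series. `order` is the order of the
#' underlying one-pass filter, matching common gait-lab usage: a "zero-lag
#' second-order" filter is a 2nd-order design applied twice, giving an
#' effective 4th-order magnitude response with no phase distortion.
#'
#' @param kind Either `"lowpass"` or `"highpass"`.
#' @param order Order of the one-pass Butterworth design (>= 1).
#' @param cutoff Cutoff frequency in Hz; must be below the Nyquist frequency
#'   at application time.
#' @param zero_lag Apply the filter forward and backward (default `TRUE`).
#'
#' @return An object of class `filter_spec`.
#' @export
#' @examples
#' filter_spec("lowpass", order = 2, cutoff = 8)
filter_spec <- function(kind = c("lowpass", "highpass"), order = 2L,
                        cutoff, zero_lag = TRUE) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(order), order >= 1, is.numeric(cutoff), cutoff > 0)
  structure(
    list(kind = kind, order = as.integer(order), cutoff = cutoff,
         zero_lag = isTRUE(zero_lag)),
    class = "filter_spec"
  )
}

# Steady-state initial filter state for unit step input scaled later
# (transposed direct-form-II), so that forward-backward filtering of a
# constant is exact and endpoint transients are suppressed.
lfilter_zi <- function(b, a) {
  n <- length(a)
  if (n == 1L) return(numeric(0))
  a <- a / a[1]; b <- b / a[1]
  if (length(b) < n) b <- c(b, rep(0, n - length(b)))
  # companion matrix of a
  comp <- matrix(0, n - 1L, n - 1L)
  comp[1L, ] <- -a[-1L] / a[1L]
  if (n > 2L) comp[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  iminusa <- diag(n - 1L) - t(comp)
  bb <- b[-1L] - a[-1L] * b[1L]
  solve(iminusa, bb)
}

# single forward pass with initial state z (transposed direct form II)
df2t_filter <- function(b, a, x, z) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  y <- numeric(length(x))
  z <- c(z, 0)
  for (m in seq_along(x)) {
    xm <- x[m]
    y[m] <- b[1] * xm + z[1]
    if (n > 1L) {
      for (i in 1:(n - 1L)) {
        z[i] <- b[i + 1L] * xm + z[i + 1L] - a[i + 1L] * y[m]
      }
    }
  }
  y
}

#' Zero-lag Butterworth filtering
#'
#' Applies a Butterworth filter forward and backward over the series so the
#' net phase shift is zero. Endpoint transients are suppressed by odd
#' (point-reflected) edge padding of `3 * (order + 1)` samples combined with
#' steady-state initial conditions, so a constant input is returned exactly.
#'
#' @param x Numeric series.
#' @param fs Sampling frequency in Hz.
#' @param spec A [filter_spec()].
#'
#' @return Filtered series, same length as `x`.
#' @export
#' @examples
#' x <- sin(2 * pi * 1 * seq(0, 2, by = 0.01))
#' y <- butterworth_zero_lag(x, fs = 100, filter_spec("lowpass", 2, 8))
butterworth_zero_lag <- function(x, fs, spec) {
  stopifnot(inherits(spec, "filter_spec"), is.numeric(x), fs > 0)
  nyq <- fs / 2
  if (spec$cutoff >= nyq) {
    stop(sprintf("cutoff %.3g Hz must be below the Nyquist frequency %.3g Hz",
                 spec$cutoff, nyq))
  }
  bf <- signal::butter(spec$order, spec$cutoff / nyq,
                       type = if (spec$kind == "lowpass") "low" else "high")
  b <- bf$b; a <- bf$a
  if (!spec$zero_lag) {
    zi <- lfilter_zi(b, a)
    return(df2t_filter(b, a, x, zi * x[1]))
  }
  padlen <- 3L * (spec$order + 1L)
  if (length(x) <= padlen) {
    stop(sprintf("series length %d must exceed the edge padding length %d",
                 length(x), padlen))
  }
  zi <- lfilter_zi(b, a)
  # odd reflection about the end points
  pre <- 2 * x[1] - x[(padlen + 1L):2L]
  post <- 2 * x[length(x)] - x[(length(x) - 1L):(length(x) - padlen)]
  ext <- c(pre, x, post)
  y <- df2t_filter(b, a, ext, zi * ext[1])
  y <- rev(df2t_filter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + length(x))]
}

#' EMG envelope extraction
#'
#' Standard surface-EMG conditioning chain: zero-lag 4th-order Butterworth
#' high-pass at 30 Hz, full-wave rectification, then zero-lag 4th-order
#' Butterworth low-pass at 6 Hz. The result is clamped at zero (the low-pass
#' can undershoot slightly) and is *not* peak-normalised; see
#' [normalise_emg()].
#'
#' @param raw Raw EMG series (arbitrary units).
#' @param fs Sampling frequency in Hz; must exceed 60 Hz so the 30 Hz
#'   high-pass cutoff is below Nyquist.
#' @param hp_cutoff,lp_cutoff High/low-pass cutoffs in Hz.
#' @param order One-pass filter order (applied forward-backward).
#'
#' @return Non-negative envelope series, same length as `raw`.
#' @export
process_emg <- function(raw, fs, hp_cutoff = 30, lp_cutoff = 6, order = 4L) {
  if (fs <= 2 * hp_cutoff) {
    stop(sprintf("fs = %.3g Hz too low for a %.3g Hz high-pass (need fs > %.3g)",
                 fs, hp_cutoff, 2 * hp_cutoff))
  }
  hp <- butterworth_zero_lag(raw, fs, filter_spec("highpass", order, hp_cutoff))
  rect <- abs(hp)
  env <- butterworth_zero_lag(rect, fs, filter_spec("lowpass", order, lp_cutoff))
  pmax(env, 0)
}

#' Per-subject peak normalisation of EMG envelopes
#'
#' Each channel is divided by its peak value across *all* of the subject's
#' trials, so the per-channel maximum over the whole set equals 1 and
#' within-trial shapes are preserved up to one scalar per channel.
#'
#' @param envelopes A list of trials; each trial is a named list (or data
#'   frame) of per-channel envelope series. Channel names must agree across
#'   trials.
#'
#' @return A list of the same shape with normalised envelopes.
#' @export
normalise_emg <- function(envelopes) {
  stopifnot(is.list(envelopes), length(envelopes) >= 1)
  channels <- names(envelopes[[1]])
  peaks <- vapply(channels, function(ch) {
    max(vapply(envelopes, function(tr) max(tr[[ch]]), numeric(1)))
  }, numeric(1))
  dead <- channels[peaks <= 0]
  if (length(dead) > 0) {
    stop("all-zero EMG channel(s): ", paste(dead, collapse = ", "))
  }
  lapply(envelopes, function(tr) {
    out <- tr
    for (ch in channels) out[[ch]] <- tr[[ch]] / peaks[[ch]]
    out
  })
}

#' Frame-by-frame differentiation
#'
#' Central differences at interior samples, first-order one-sided differences
#' at the two endpoints (via [pracma::gradient()]).
#'
#' @param x Numeric series of length >= 3.
#' @param fs Sampling frequency in Hz.
#'
#' @return Derivative series, same length as `x`.
#' @export
differentiate <- function(x, fs) {
  if (length(x) < 3L) stop("differentiate needs at least 3 samples")
  pracma::gradient(x, 1 / fs)
}

#' Time-normalise a stance-phase series to 100 samples
#'
#' Linear interpolation onto a uniform phase grid; 0% and 100% of stance
#' correspond to the first (heel strike) and last (toe-off) input samples,
#' which are preserved exactly.
#'
#' @param x Numeric series of length >= 2.
#' @param n Number of output samples (default 100).
#'
#' @return Series of length `n`.
#' @export
resample_stance <- function(x, n = 100L) {
  if (length(x) < 2L) stop("resample_stance needs at least 2 samples")
  stats::approx(seq(0, 1, length.out = length(x)),
                x, xout = seq(0, 1, length.out = n))$y
}
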