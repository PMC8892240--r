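#' Canonical EEG frequency bands
#'
#' The five rhythm-defined EEG bands: delta 1-3 Hz (sleep waves), theta
#' 4-7 Hz, alpha 8-13 Hz (relaxation), beta 14-30 Hz (waking reasoning),
#' gamma 30-100 Hz (high-level processing).
#'
#' @return A data frame with columns `name`, `low`, `high` (Hz), sorted by
#'   lower edge.
#' @examples
#' default_bands()
#' @export
default_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    low  = c(1, 4, 8, 14, 30),
    high = c(3, 7, 13, 30, 100),
    stringsAsFactors = FALSE
  )
}

#' Define a frequency band
#'
#' @param name band label.
#' @param low,high band edges in Hz, `0 < low < high`.
#' @return One-row data frame compatible with [default_bands()].
#' @export
band_spec <- function(name, low, high) {
  if (!(is.numeric(low) && is.numeric(high) && low > 0 && high > low))
    stop("band edges must satisfy 0 < low < high")
  data.frame(name = as.character(name), low = low, high = high,
             stringsAsFactors = FALSE)
}

#' A set of labelled signal epochs
#'
#' @param epochs list of `channels x samples` numeric matrices, all with
#'   the same channel count.
#' @param rate sampling rate in Hz.
#' @param labels integer class label per epoch.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, rate, labels) {
  if (!is.list(epochs) || length(epochs) < 1L)
    stop("`epochs` must be a non-empty list of channels x samples matrices")
  epochs <- lapply(epochs, as.matrix)
  nch <- vapply(epochs, nrow, integer(1))
  if (any(nch != nch[1])) stop("all epochs must have the same channel count")
  if (!is.numeric(rate) || rate <= 0) stop("`rate` must be a positive sampling rate")
  if (length(labels) != length(epochs)) stop("one label per epoch is required")
  structure(list(epochs = epochs, rate = rate, labels = as.integer(labels),
                 channels = nch[1]),
            class = "epoch_set")
}

#' Slice a continuous recording into fixed-length epochs
#'
#' Cuts a `channels x samples` recording into windows of `window_s`
#' seconds taken every `step_s` seconds (overlapping when
#' `step_s < window_s`), all inheriting the recording's label. Mirrors the
#' common segmentation protocols for emotion EEG (e.g. 5-s segments, or
#' 4-s windows with 2-s overlap).
#'
#' @param x `channels x samples` numeric matrix.
#' @param rate sampling rate in Hz.
#' @param label integer class label for the recording.
#' @param window_s window length in seconds.
#' @param step_s hop between window starts in seconds; defaults to
#'   `window_s` (no overlap).
#' @return An [epoch_set()].
#' @export
slice_epochs <- function(x, rate, label, window_s, step_s = window_s) {
  x <- as.matrix(x)
  win <- as.integer(round(window_s * rate))
  hop <- as.integer(round(step_s * rate))
  if (win < 1L || hop < 1L) stop("window and step must cover at least one sample")
  if (ncol(x) < win) stop("recording shorter than one window")
  starts <- seq(1L, ncol(x) - win + 1L, by = hop)
  epoch_set(lapply(starts, function(s) x[, s:(s + win - 1L), drop = FALSE]),
            rate = rate, labels = rep(as.integer(label), length(starts)))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass of the
#' given order, so the output has no group delay and the effective
#' magnitude response is the square of the one-pass response.
#'
#' @param x numeric signal vector.
#' @param rate sampling rate in Hz.
#' @param band one-row band data frame ([band_spec()]) or a list with
#'   `low`/`high` in Hz; `high` must be below the Nyquist rate.
#' @param order Butterworth order of the one-pass filter.
#' @return Filtered signal, same length as `x`.
#' @export
bandpass <- function(x, rate, band, order = 4L) {
  low <- band$low[1]; high <- band$high[1]
  if (high >= rate / 2)
    stop(sprintf("band edge %g Hz is at or above the Nyquist rate %g Hz",
                 high, rate / 2))
  bf <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, as.numeric(x)))
}

# Welch PSD of one channel: Hann-windowed overlapping segments, averaged
# one-sided periodograms. Returns freq grid (Hz) and density (power/Hz)
# such that sum(psd) * df ~ mean power of the signal.
welch_psd <- function(x, rate, window_s = 1.0, overlap = 0.5) {
  x <- as.numeric(x)
  nwin <- as.integer(round(window_s * rate))
  if (nwin < 2L) stop("window too short: fewer than two samples")
  if (length(x) < nwin)
    stop(sprintf(
      "epoch (%d samples) shorter than one window (%d samples); use a smaller window_s",
      length(x), nwin))
  hop <- max(1L, as.integer(round(nwin * (1 - overlap))))
  starts <- seq(1L, length(x) - nwin + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / nwin)   # periodic Hann
  u <- sum(w^2)                                         # window power norm
  nfreq <- nwin %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1L)] * w
    px <- abs(stats::fft(seg))[seq_len(nfreq)]^2 / (u * rate)
    # one-sided: double everything except DC (and Nyquist when nwin even)
    scale2 <- rep(2, nfreq)
    scale2[1] <- 1
    if (nwin %% 2L == 0L) scale2[nfreq] <- 1
    acc <- acc + px * scale2
  }
  list(freq = (seq_len(nfreq) - 1L) * rate / nwin,
       psd = acc / length(starts),
       df = rate / nwin)
}

#' Per-channel Welch band power of an epoch
#'
#' Estimates each channel's power spectral density by Welch's method
#' (Hann window, overlapping segments, averaged periodograms) and
#' integrates it over the band, yielding one nonnegative power value per
#' channel.
#'
#' @param epoch `channels x samples` numeric matrix.
#' @param rate sampling rate in Hz.
#' @param band one-row band data frame or list with `low`/`high` in Hz.
#' @param window_s Welch segment length in seconds.
#' @param overlap fractional segment overlap in \[0, 1).
#' @param log_power take `log(power + 1e-12)` of the band integrals.
#' @return Numeric vector, one band-power value per channel.
#' @export
welch_psd_features <- function(epoch, rate, band, window_s = 1.0,
                               overlap = 0.5, log_power = FALSE) {
  epoch <- as.matrix(epoch)
  pow <- apply(epoch, 1L, function(ch) {
    sp <- welch_psd(ch, rate, window_s = window_s, overlap = overlap)
    keep <- sp$freq >= band$low[1] & sp$freq <= band$high[1]
    sum(sp$psd[keep]) * sp$df
  })
  if (log_power) pow <- log(pow + 1e-12)
  as.numeric(pow)
}

#' Band-power feature extraction for a set of epochs
#'
#' Computes per-channel Welch band power for every epoch and band,
#' assembling one `channels x epochs` feature matrix per band: the
#' "one PSD value per channel per band" representation. Column `j` of
#' every band matrix comes from epoch `j`; labels are carried through.
#'
#' @param epochs an [epoch_set()].
#' @param bands band table as from [default_bands()]; every `high` must be
#'   below the Nyquist rate.
#' @inheritParams welch_psd_features
#' @return A [multiband_dataset()] with `M = nrow(bands)` bands and
#'   `d = channels` features.
#' @examples
#' set.seed(1)
#' eps <- lapply(1:6, function(i) matrix(rnorm(4 * 256), 4, 256))
#' es <- epoch_set(eps, rate = 128, labels = rep(1:2, 3))
#' extract_multiband(es, default_bands()[1:4, ])
#' @export
extract_multiband <- function(epochs, bands = default_bands(), window_s = 1.0,
                              overlap = 0.5, log_power = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (any(bands$high >= epochs$rate / 2))
    stop("band edges must be below the Nyquist rate of the epochs")
  Z <- lapply(seq_len(nrow(bands)), function(b) {
    vapply(epochs$epochs, welch_psd_features, numeric(epochs$channels),
           rate = epochs$rate, band = bands[b, ], window_s = window_s,
           overlap = overlap, log_power = log_power)
  })
  Z <- lapply(Z, function(m) matrix(m, nrow = epochs$channels))
  multiband_dataset(Z, labels = epochs$labels, band_names = bands$name)
}
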