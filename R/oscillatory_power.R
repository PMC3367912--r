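# Epoching, EOG artifact rejection, sustained Hanning-taper FFT power,
# frequency-band averaging, evoked-response subtraction, 3-cycle adaptive
# sliding-window time-frequency power, and 10*log10 normalizations.

#' Canonical analysis windows and frequency bands
#'
#' The sustained (between-pair) window runs from 2 s to 250 ms before pair
#' onset (length 1.75 s); the time-frequency window runs from 0.75 s before
#' to 1.75 s after pair onset (length 2.5 s). Bands: theta 4-6, alpha 7-13,
#' beta 14-34, gamma 35-80 Hz.
#'
#' @return \code{sustained_window()}/\code{tfr_window()}: numeric
#'   \code{c(start_s, end_s)} relative to pair onset. \code{band_definitions()}:
#'   data frame with columns name, low_hz, high_hz.
#' @export
sustained_window <- function() c(-2.0, -0.25)

#' @rdname sustained_window
#' @export
tfr_window <- function() c(-0.75, 1.75)

#' @rdname sustained_window
#' @export
band_definitions <- function() {
  data.frame(name = c("theta", "alpha", "beta", "gamma"),
             low_hz = c(4, 7, 14, 35), high_hz = c(6, 13, 34, 80),
             stringsAsFactors = FALSE)
}

#' Segment a continuous recording into stimulus-locked epochs
#'
#' Sample indices are taken as \code{floor(time * rate)}; every epoch has the
#' same length \code{round((end - start) * rate)} samples. Trials whose
#' window would fall outside the recording are dropped (with a message).
#'
#' @param series channels x samples matrix, or a vector (single channel).
#' @param schedule \code{event_schedule}.
#' @param window \code{c(start_s, end_s)} relative to pair onset.
#' @param condition condition label to select, or NULL for all pairs.
#' @param fs sampling rate (Hz).
#' @return object of class \code{epoch_set}: \code{data} (trials x channels
#'   x samples array), \code{window}, \code{condition}, \code{onsets},
#'   \code{event_index} (row of the schedule's event table), \code{fs},
#'   \code{kept}, \code{rejected}.
#' @export
segment_epochs <- function(series, schedule, window, condition = NULL, fs) {
  if (window[1] >= window[2]) config_error("epoch window start must precede end")
  if (diff(window) > schedule$params$inter_pair_s)
    config_error("epoch window (%.2f s) longer than the inter-pair interval (%.2f s)",
                 diff(window), schedule$params$inter_pair_s)
  x <- if (is.matrix(series)) series else matrix(series, nrow = 1)
  ev <- schedule$events
  rows <- if (is.null(condition)) seq_len(nrow(ev)) else which(ev$condition == condition)
  n_win <- round(diff(window) * fs)
  starts <- floor((ev$onset_s[rows] + window[1]) * fs) + 1L
  ok <- starts >= 1L & (starts + n_win - 1L) <= ncol(x)
  if (any(!ok))
    message(sprintf("segment_epochs: dropped %d trial(s) outside the recording", sum(!ok)))
  rows <- rows[ok]; starts <- starts[ok]
  dat <- array(0, c(length(rows), nrow(x), n_win))
  for (i in seq_along(rows)) dat[i, , ] <- x[, starts[i] + seq_len(n_win) - 1L, drop = FALSE]
  structure(list(data = dat, window = window, condition = condition,
                 onsets = ev$onset_s[rows], event_index = rows, fs = fs,
                 kept = seq_along(rows), rejected = integer(0)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("epoch_set: %d trials (%d kept) x %d channels x %d samples, window [%g, %g] s%s\n",
              dim(x$data)[1], length(x$kept), dim(x$data)[2], dim(x$data)[3],
              x$window[1], x$window[2],
              if (is.null(x$condition)) "" else paste0(", ", x$condition)))
  invisible(x)
}

#' Reject epochs by EOG peak-to-peak amplitude
#'
#' A trial is kept iff the peak-to-peak EOG amplitude within its epoch is at
#' most \code{threshold_uv}; only strictly larger amplitudes are discarded
#' (an epoch at exactly the threshold is kept).
#'
#' @param epochs \code{epoch_set} of sensor (or source) data.
#' @param eog_epochs \code{epoch_set} of the EOG channel, aligned trial for
#'   trial with \code{epochs}.
#' @param threshold_uv rejection threshold in microvolts (default 100).
#' @return \code{epochs} with updated \code{kept}/\code{rejected}.
#' @export
reject_artifacts <- function(epochs, eog_epochs, threshold_uv = 100) {
  if (dim(epochs$data)[1] != dim(eog_epochs$data)[1])
    data_error("EOG epochs (%d trials) not aligned with data epochs (%d trials)",
               dim(eog_epochs$data)[1], dim(epochs$data)[1])
  pp <- apply(eog_epochs$data[, 1, , drop = FALSE], 1, function(v) max(v) - min(v))
  reject <- which(pp > threshold_uv)
  epochs$rejected <- sort(union(epochs$rejected, reject))
  epochs$kept <- setdiff(seq_len(dim(epochs$data)[1]), epochs$rejected)
  epochs$eog_peak_to_peak <- pp
  epochs
}

hanning_taper <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

# One-sided power spectral density of one tapered segment. Scaling:
# |FFT|^2 / (fs * sum(w^2)), doubled for 0 < f < Nyquist, so that
# sum(psd) * (fs/N) == sum((x*w)^2) / sum(w^2) exactly (Parseval).
taper_psd <- function(x, fs, taper = hanning_taper(length(x))) {
  n <- length(x)
  X <- stats::fft(x * taper)
  n_keep <- floor(n / 2) + 1L
  p <- Mod(X[seq_len(n_keep)])^2 / (fs * sum(taper^2))
  dbl <- rep(2, n_keep)
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[n_keep] <- 1
  list(freq = (seq_len(n_keep) - 1) * fs / n, psd = p * dbl)
}

#' Sustained spectral power via Hanning-tapered FFT
#'
#' Each kept trial is demeaned, multiplied by a Hanning taper spanning the
#' whole epoch, Fourier transformed, and converted to one-sided power
#' spectral density with taper-power correction; trials are then averaged.
#' Frequency bins are the natural FFT bins of the window (no zero padding),
#' restricted to \code{freq_range}.
#'
#' @param epochs \code{epoch_set} (uses kept trials only).
#' @param freq_range \code{c(low, high)} in Hz; default c(4, 80).
#' @return object of class \code{power_estimate}: \code{values} (elements x
#'   frequencies), \code{freqs_hz}, \code{normalization = "raw"},
#'   \code{n_trials}.
#' @export
sustained_power <- function(epochs, freq_range = c(4, 80)) {
  if (length(epochs$kept) < 1) estimation_error("no kept trials for power estimation")
  nchan <- dim(epochs$data)[2]; nsamp <- dim(epochs$data)[3]
  w <- hanning_taper(nsamp)
  full <- taper_psd(numeric(nsamp), fs = epochs$fs, taper = w)$freq
  sel <- which(full >= freq_range[1] & full <= freq_range[2])
  dbl <- rep(2, length(full)); dbl[1] <- 1
  if (nsamp %% 2 == 0) dbl[length(full)] <- 1
  scale <- dbl[sel] / (epochs$fs * sum(w^2))
  vals <- matrix(0, nchan, length(sel))
  for (tr in epochs$kept) {
    Xm <- matrix(epochs$data[tr, , ], nrow = nchan)   # channels x samples
    Xm <- (Xm - rowMeans(Xm)) * rep(w, each = nchan)
    Y <- stats::mvfft(t(Xm))                          # samples x channels
    vals <- vals + t(Mod(Y[sel, , drop = FALSE])^2) * rep(scale, each = nchan)
  }
  vals <- vals / length(epochs$kept)
  structure(list(values = vals, freqs_hz = full[sel], times_s = NULL,
                 normalization = "raw", n_trials = length(epochs$kept)),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  dims <- if (is.null(x$times_s))
    sprintf("%d elements x %d freqs", nrow(x$values), length(x$freqs_hz))
  else
    sprintf("%d elements x %d freqs x %d times", dim(x$values)[1],
            length(x$freqs_hz), length(x$times_s))
  cat(sprintf("power_estimate (%s): %s, %d trials\n", x$normalization, dims,
              x$n_trials))
  invisible(x)
}

#' Average power over a frequency band
#'
#' Mean of power values over bins whose center frequency f satisfies
#' \code{low <= f <= high}.
#'
#' @param power \code{power_estimate} (sustained, elements x frequencies).
#' @param band \code{c(low_hz, high_hz)}, or a row of [band_definitions()].
#' @return numeric vector, one value per element.
#' @export
band_average <- function(power, band) {
  if (is.data.frame(band) || is.list(band)) band <- c(band$low_hz, band$high_hz)
  sel <- power$freqs_hz >= band[1] & power$freqs_hz <= band[2]
  if (!any(sel)) config_error("no frequency bins inside band [%g, %g] Hz", band[1], band[2])
  if (is.null(x_times <- power$times_s)) {
    rowMeans(power$values[, sel, drop = FALSE])
  } else {
    apply(power$values[, sel, , drop = FALSE], c(1, 3), mean)
  }
}

#' Subtract the trial-averaged evoked response
#'
#' Removes the mean waveform over kept trials from every kept trial so the
#' remaining power reflects induced (non-phase-locked) activity; the new
#' trial average is zero to numerical precision.
#'
#' @param epochs \code{epoch_set} with >= 2 kept trials.
#' @return \code{epoch_set} with the evoked response removed.
#' @export
subtract_evoked <- function(epochs) {
  if (length(epochs$kept) < 2)
    estimation_error("evoked subtraction requires >= 2 kept trials")
  avg <- apply(epochs$data[epochs$kept, , , drop = FALSE], c(2, 3), mean)
  for (tr in epochs$kept) epochs$data[tr, , ] <- epochs$data[tr, , ] - avg
  epochs$evoked_subtracted <- TRUE
  epochs
}

#' Defined center span of the adaptive time-frequency window
#'
#' At frequency f the 3-cycle window has length n_cycles/f, so power is
#' defined only for centers at least n_cycles/(2f) away from both epoch
#' edges.
#'
#' @param f frequency (Hz).
#' @param window epoch window \code{c(start_s, end_s)}.
#' @param n_cycles cycles per window (default 3).
#' @return \code{c(first_center_s, last_center_s)}.
#' @export
tfr_defined_span <- function(f, window = tfr_window(), n_cycles = 3) {
  half <- n_cycles / (2 * f)
  c(window[1] + half, window[2] - half)
}

#' Time-frequency power with an adaptive 3-cycle Hanning window
#'
#' At each frequency f, power is estimated from Hanning-tapered segments of
#' length n_cycles/f (rounded to the nearest sample, ties up) slid across
#' the epoch on a common center grid; cells whose window does not fit inside
#' the epoch are NA. Kept trials are demeaned at the epoch level before
#' windowing and power is averaged over trials.
#'
#' @param epochs \code{epoch_set}.
#' @param freqs frequencies of interest (Hz).
#' @param n_cycles cycles per window (default 3).
#' @param stride_s center step (default 0.05 s).
#' @return \code{power_estimate} with \code{values} elements x frequencies x
#'   times and \code{times_s} the center grid.
#' @export
tfr_power <- function(epochs, freqs, n_cycles = 3, stride_s = 0.05) {
  if (length(epochs$kept) < 1) estimation_error("no kept trials")
  win <- epochs$window; fs <- epochs$fs
  nchan <- dim(epochs$data)[2]; nsamp <- dim(epochs$data)[3]
  if (max(n_cycles / freqs) > diff(win))
    config_error("window of %g cycles at %g Hz (%.2f s) exceeds the epoch length %.2f s",
                 n_cycles, min(freqs), max(n_cycles / freqs), diff(win))
  times <- seq(win[1], win[2], by = stride_s)
  eps <- 0.5 / fs
  dat <- epochs$data[epochs$kept, , , drop = FALSE]
  for (tr in seq_len(dim(dat)[1])) for (ch in seq_len(nchan))
    dat[tr, ch, ] <- dat[tr, ch, ] - mean(dat[tr, ch, ])
  vals <- array(NA_real_, c(nchan, length(freqs), length(times)))
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    wlen <- as.integer(round_half_up(n_cycles / f * fs))
    wlen <- min(wlen, nsamp)
    span <- tfr_defined_span(f, win, n_cycles)
    defined <- which(times >= span[1] - eps & times <= span[2] + eps)
    if (!length(defined)) next
    w <- hanning_taper(wlen)
    carrier <- w * exp(-2i * pi * f * (seq_len(wlen) - 1) / fs)
    scale <- 2 / (fs * sum(w^2))
    for (ti in defined) {
      ci <- as.integer(round_half_up((times[ti] - win[1]) * fs)) + 1L
      i0 <- ci - wlen %/% 2L
      i0 <- max(1L, min(i0, nsamp - wlen + 1L))
      seg <- i0 + seq_len(wlen) - 1L
      for (ch in seq_len(nchan)) {
        M <- matrix(dat[, ch, seg], nrow = dim(dat)[1])
        vals[ch, fi, ti] <- mean(Mod(M %*% carrier)^2) * scale
      }
    }
  }
  structure(list(values = vals, freqs_hz = freqs, times_s = times,
                 normalization = "raw", n_trials = length(epochs$kept),
                 window = win, n_cycles = n_cycles),
            class = "power_estimate")
}

#' Decibel normalization of power estimates
#'
#' \code{10 * log10(power / reference)}. For a time-frequency estimate with
#' \code{reference = "baseline"}, the reference is the per-element,
#' per-frequency mean over defined cells with center time earlier than
#' \code{baseline_end_s} (default -0.1 s, i.e. pre-stimulus). For sustained
#' estimates, \code{reference} is a matching \code{power_estimate} (e.g. the
#' Passive condition) or a positive scalar.
#'
#' @param power \code{power_estimate} with raw values.
#' @param reference "baseline", a \code{power_estimate}, or a positive
#'   scalar.
#' @param baseline_end_s end of the baseline period (TFR only).
#' @return \code{power_estimate} in dB (\code{normalization} set to
#'   \code{"db_vs_baseline"} or \code{"db_vs_reference"}).
#' @export
db_normalize <- function(power, reference = "baseline", baseline_end_s = -0.1) {
  v <- power$values
  if (identical(reference, "baseline")) {
    if (is.null(power$times_s))
      config_error("baseline normalization requires a time-frequency estimate")
    base_t <- power$times_s < baseline_end_s
    ref <- apply(v[, , base_t, drop = FALSE], c(1, 2), mean, na.rm = TRUE)
    bad <- which(!is.na(ref) & ref <= 0, arr.ind = TRUE)
    if (nrow(bad <- as.matrix(bad)))
      numerical_error("nonpositive baseline reference at element %d, frequency %g Hz",
                      bad[1, 1], power$freqs_hz[bad[1, 2]])
    power$values <- 10 * log10(sweep(v, c(1, 2), ref, "/"))
    power$normalization <- "db_vs_baseline"
  } else {
    ref <- if (inherits(reference, "power_estimate")) reference$values else reference
    if (any(ref <= 0, na.rm = TRUE)) {
      bad <- which(ref <= 0)[1]
      numerical_error("nonpositive reference at element %d", bad)
    }
    power$values <- 10 * log10(v / ref)
    power$normalization <- "db_vs_reference"
  }
  power
}
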