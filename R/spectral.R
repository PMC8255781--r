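# Filter-bank + Hilbert spectral pipeline. All FIR filtering is zero-phase:
# linear-phase (odd-length, symmetric) kernels applied by FFT convolution
# with reflection padding, compensating the (taps-1)/2 group delay.

#' Downsample a recording with anti-alias filtering
#'
#' Applies a Blackman-window low-pass FIR (cutoff at 40% of the target
#' sampling rate, i.e. 80 Hz for the default 200 Hz, with the stopband
#' reaching the new Nyquist) before keeping every `fs/target_fs`-th sample.
#'
#' @param x An `eeg_recording` (all channels are downsampled) or a numeric
#'   vector.
#' @param target_fs Target sampling rate, Hz; `fs` must be an integer
#'   multiple of it.
#' @param fs Source sampling rate; required when `x` is a bare vector.
#' @return Object of the same type as `x` at `target_fs`.
#' @export
downsample <- function(x, target_fs = 200, fs = NULL) {
  if (inherits(x, "eeg_recording")) {
    rec <- x
    rec$channels <- lapply(rec$channels, downsample, target_fs = target_fs,
                           fs = rec$fs)
    rec$fs <- target_fs
    return(rec)
  }
  if (is.null(fs)) stopf("fs required for vector input")
  factor <- fs / target_fs
  if (abs(factor - round(factor)) > 1e-9) {
    stopf("fs (%g) is not an integer multiple of target_fs (%g)", fs, target_fs)
  }
  factor <- round(factor)
  if (factor == 1) return(x)
  n_taps <- 301L
  h <- signal::fir1(n_taps - 1L, 0.8 * target_fs / fs,
                    type = "low", window = signal::blackman(n_taps))
  y <- fir_zerophase(x, h)
  y[seq(1, length(y), by = factor)]
}

#' Build the narrowband FIR filter bank
#'
#' Linear-phase Hamming-window bandpass kernels, one per filter-bank
#' channel, designed at the analysis rate. 401 taps (2 s of support at
#' 200 Hz) gives a transition width narrow enough for the 1.6-Hz passbands
#' at the low end of the bank.
#'
#' @param spec Channel layout from [filterbank_spec()].
#' @param fs Analysis sampling rate, Hz.
#' @param n_taps Kernel length (odd).
#' @return A `filterbank` list: `kernels` (list of numeric vectors),
#'   `spec`, `fs`, `n_taps`.
#' @export
build_filterbank <- function(spec = filterbank_spec(), fs = 200,
                             n_taps = 401L) {
  if (n_taps %% 2 == 0) stopf("n_taps must be odd for zero-phase filtering")
  if (any(spec$hi >= fs / 2)) {
    stopf("high cutoff %.1f Hz >= Nyquist (%.1f Hz)", max(spec$hi), fs / 2)
  }
  kernels <- lapply(seq_len(nrow(spec)), function(i) {
    as.numeric(signal::fir1(n_taps - 1L,
                            c(spec$lo[i], spec$hi[i]) / (fs / 2),
                            type = "pass"))
  })
  structure(list(kernels = kernels, spec = spec, fs = fs, n_taps = n_taps),
            class = "filterbank")
}

# Zero-phase FIR by FFT convolution with reflection padding.
fir_zerophase <- function(x, h) {
  n <- length(x)
  L <- length(h)
  npad <- (L - 1) %/% 2
  if (n <= npad + 1) stopf("signal shorter than filter half-length")
  xe <- c(x[(npad + 1):2], x, x[(n - 1):(n - npad)])
  nfft <- stats::nextn(length(xe) + L - 1, c(2, 3, 5))
  conv <- Re(stats::fft(stats::fft(c(xe, numeric(nfft - length(xe)))) *
                        stats::fft(c(h, numeric(nfft - L))),
                        inverse = TRUE)) / nfft
  conv[L:(L - 1 + n)]
}

#' Instantaneous power via the Hilbert envelope
#'
#' Squared magnitude of the analytic signal (FFT construction): for a
#' narrowband signal `A(t) sin(2 pi f t)` this recovers `A(t)^2`.
#'
#' @param x Finite numeric vector.
#' @return Non-negative power series, same length as `x`.
#' @export
hilbert_power <- function(x) {
  if (any(!is.finite(x))) stopf("non-finite input to hilbert_power")
  n <- length(x)
  X <- stats::fft(x)
  mult <- numeric(n)
  if (n %% 2 == 0) {
    mult[c(1, n / 2 + 1)] <- 1
    mult[2:(n / 2)] <- 2
  } else {
    mult[1] <- 1
    mult[2:((n + 1) / 2)] <- 2
  }
  a <- stats::fft(X * mult, inverse = TRUE) / n
  Mod(a)^2
}

#' Per-epoch median power with artifact exclusion
#'
#' Medians are robust against brief high-amplitude excursions inside an
#' epoch; flagged epochs keep their row (indexing is preserved) but are
#' dropped from `kept`.
#'
#' @param power Numeric power series at `fs`.
#' @param fs Sampling rate, Hz.
#' @param epoch_len Epoch length, s.
#' @param mask Optional [artifact_mask()] with exactly as many entries as
#'   there are whole epochs in `power`.
#' @return List with `median` (one value per epoch) and `kept` (logical).
#' @export
epoch_median_power <- function(power, fs, epoch_len = 4, mask = NULL) {
  spp <- round(epoch_len * fs)
  n_epochs <- length(power) %/% spp
  if (n_epochs < 1) stopf("power series shorter than one epoch")
  m <- matrix(power[seq_len(n_epochs * spp)], nrow = spp)
  med <- apply(m, 2, stats::median)
  kept <- rep(TRUE, n_epochs)
  if (!is.null(mask)) {
    if (nrow(mask) != n_epochs) {
      stopf("mask has %d epochs but power series has %d", nrow(mask), n_epochs)
    }
    kept <- !mask$is_artifact
  }
  list(median = med, kept = kept)
}

#' Threshold-based artifact detector using EEG and EMG
#'
#' An epoch is flagged when the EEG's peak absolute deviation from its
#' global median exceeds `k_eeg` robust SDs (median absolute deviation
#' scaled to the normal), or when the epoch EMG RMS exceeds `k_emg` times
#' the median epoch RMS. The EMG channel captures movement artifacts whose
#' EEG expression is equivocal.
#'
#' @param eeg,emg Equal-length numeric channels.
#' @param fs Sampling rate, Hz.
#' @param epoch_len Epoch length, s.
#' @param k_eeg,k_emg Detection thresholds (robust SD multiples).
#' @return An [artifact_mask()].
#' @export
detect_artifacts <- function(eeg, emg, fs, epoch_len = 4,
                             k_eeg = 6, k_emg = 6) {
  if (length(eeg) != length(emg)) stopf("eeg and emg must have equal length")
  spp <- round(epoch_len * fs)
  n_epochs <- length(eeg) %/% spp
  if (n_epochs < 1) return(artifact_mask(logical(0)))
  idx <- seq_len(n_epochs * spp)
  eeg_dev <- abs(eeg[idx] - stats::median(eeg))
  sd_eeg <- stats::mad(eeg)
  em <- matrix(eeg_dev, nrow = spp)
  eeg_peak <- apply(em, 2, max)
  mm <- matrix(emg[idx]^2, nrow = spp)
  emg_rms <- sqrt(colMeans(mm))
  base_rms <- stats::median(emg_rms)
  flag_eeg <- if (sd_eeg > 0) eeg_peak > k_eeg * sd_eeg else rep(FALSE, n_epochs)
  flag_emg <- if (base_rms > 0) emg_rms > k_emg * base_rms else rep(FALSE, n_epochs)
  artifact_mask(flag_eeg | flag_emg)
}

#' Filter-bank epoch power matrix
#'
#' The full spectral chain for one channel: for each of the 70 filter-bank
#' channels, zero-phase bandpass filtering, analytic-signal power, and 4-s
#' epoch medians. Filtering and Hilbert transform are fused in the
#' frequency domain (one forward FFT of the padded signal, one inverse FFT
#' per channel).
#'
#' @param recording An `eeg_recording` at the bank's sampling rate.
#' @param bank A [build_filterbank()] result.
#' @param mask Optional [artifact_mask()]; flagged epochs are excluded from
#'   `kept` (and thereby from every downstream band statistic).
#' @param channel Channel to analyze.
#' @return An `epoch_power` object: `values` (epochs x channels matrix of
#'   median power), `centers`, `kept`, `epoch_len`, `fs`.
#' @export
compute_epoch_power <- function(recording, bank = build_filterbank(),
                                mask = NULL, channel = "eeg_frontal") {
  stopifnot(inherits(recording, "eeg_recording"), inherits(bank, "filterbank"))
  if (abs(recording$fs - bank$fs) > 1e-9) {
    stopf("recording at %g Hz but filter bank designed for %g Hz; downsample first",
          recording$fs, bank$fs)
  }
  x <- recording$channels[[channel]]
  if (is.null(x)) stopf("channel '%s' not present", channel)
  if (any(!is.finite(x))) stopf("non-finite samples in channel '%s'", channel)
  n <- length(x)
  L <- bank$n_taps
  npad <- (L - 1) %/% 2
  spp <- round(4 * bank$fs)
  n_epochs <- n %/% spp
  if (n_epochs < 1) stopf("recording shorter than one 4-s epoch")

  xe <- c(x[(npad + 1):2], x, x[(n - 1):(n - npad)])
  nfft <- stats::nextn(length(xe) + L - 1, c(2, 3, 5))
  X <- stats::fft(c(xe, numeric(nfft - length(xe))))
  amult <- numeric(nfft)
  amult[c(1, nfft / 2 + 1)] <- 1
  amult[2:(nfft / 2)] <- 2
  Xa <- X * amult

  values <- matrix(NA_real_, n_epochs, nrow(bank$spec))
  keep_idx <- seq_len(n_epochs * spp)
  for (i in seq_along(bank$kernels)) {
    H <- stats::fft(c(bank$kernels[[i]], numeric(nfft - L)))
    a <- stats::fft(Xa * H, inverse = TRUE) / nfft
    pw <- Mod(a[L:(L - 1 + n)])^2
    values[, i] <- apply(matrix(pw[keep_idx], nrow = spp), 2, stats::median)
  }

  kept <- rep(TRUE, n_epochs)
  if (!is.null(mask)) {
    if (nrow(mask) < n_epochs) {
      stopf("mask covers %d epochs but recording has %d", nrow(mask), n_epochs)
    }
    kept <- !mask$is_artifact[seq_len(n_epochs)]
  }
  structure(list(values = values, centers = bank$spec$center, kept = kept,
                 epoch_len = 4, fs = bank$fs),
            class = "epoch_power")
}
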