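#' Classical EEG frequency band definitions
#'
#' The seven bands used throughout the pipeline, with half-open ranges
#' `[lo, hi)` in Hz: delta 1-4, theta 4-8, alpha 8-12, sigma 10-15,
#' beta 12-30, gamma1 30-50, gamma2 50-100. Sigma intentionally overlaps
#' alpha and beta (the sleep-spindle band straddles the alpha/beta edge),
#' so a filter-bank channel may contribute to two bands.
#'
#' @return A data.frame with columns `band` (ordered factor), `lo`, `hi`.
#' @export
band_definitions <- function() {
  data.frame(
    band = factor(BAND_LABELS, levels = BAND_LABELS),
    lo = c(1, 4, 8, 10, 12, 30, 50),
    hi = c(4, 8, 12, 15, 30, 50, 100)
  )
}

BAND_LABELS <- c("delta", "theta", "alpha", "sigma", "beta", "gamma1", "gamma2")

#' Filter-bank channel layout
#'
#' The narrowband filter bank: 70 bandpass channels whose low cutoffs run
#' from 1.0 to 97.6 Hz in 1.4-Hz steps and whose high cutoffs run from 2.6
#' to 99.2 Hz, i.e. constant 1.6-Hz widths with adjacent passbands
#' overlapping by 0.2 Hz. Channel centers are `(lo + hi) / 2`.
#'
#' @param low_start First low cutoff (Hz).
#' @param step Spacing between consecutive low cutoffs (Hz).
#' @param width Passband width `hi - lo` (Hz).
#' @param n_channels Number of channels.
#' @return A data.frame with columns `channel` (1-based), `lo`, `hi`, `center`.
#' @export
filterbank_spec <- function(low_start = 1.0, step = 1.4, width = 1.6,
                            n_channels = 70L) {
  stopifnot(low_start > 0, step > 0, width > 0, n_channels >= 1)
  lo <- low_start + step * (seq_len(n_channels) - 1)
  data.frame(
    channel = seq_len(n_channels),
    lo = lo,
    hi = lo + width,
    center = lo + width / 2
  )
}

#' Band membership of filter-bank channels
#'
#' A channel belongs to every band whose half-open range `[lo, hi)` contains
#' the channel's center frequency. With the default bank (centers
#' 1.8 + 1.4k Hz) no center ever falls exactly on a band edge, but
#' membership is by center so the rule is well defined for any bank.
#'
#' @param bank A data.frame from [filterbank_spec()].
#' @param bands A data.frame from [band_definitions()].
#' @return Named list mapping band label to integer channel indices.
#' @export
band_channel_members <- function(bank = filterbank_spec(),
                                 bands = band_definitions()) {
  members <- lapply(seq_len(nrow(bands)), function(i) {
    which(bank$center >= bands$lo[i] & bank$center < bands$hi[i])
  })
  names(members) <- as.character(bands$band)
  empty <- vapply(members, length, integer(1)) == 0
  if (any(empty)) {
    stopf("band(s) with no member channels: %s",
          paste(names(members)[empty], collapse = ", "))
  }
  members
}
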