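# Band aggregation, time binning, and the two normalization schemes.
# Binned tables are long data.frames with one row per (keys x band x bin):
# columns `band`, `bin_start_min`, `value`, `n_epochs`, plus any metadata
# key columns (subject, genotype, treatment, ...). All grouped operations
# are keyed on whatever metadata columns are present.

KEY_COLS <- c("subject", "genotype", "treatment", "session")

group_keys <- function(df) intersect(KEY_COLS, names(df))

split_by_keys <- function(df, extra = character(0)) {
  keys <- c(group_keys(df), extra)
  if (!length(keys)) return(list(df))
  split(df, df[keys], drop = TRUE)
}

#' Aggregate filter-bank channels into the seven bands
#'
#' A band's per-epoch value is the unweighted mean of the filter-bank
#' channels whose center frequency lies in the band's half-open range.
#' Channels in the alpha/sigma and sigma/beta overlaps contribute to both
#' bands.
#'
#' @param epm An `epoch_power` object from [compute_epoch_power()].
#' @param bands Band table from [band_definitions()].
#' @return data.frame with `epoch_index` (0-based), `kept`, and one column
#'   per band.
#' @export
aggregate_bands <- function(epm, bands = band_definitions()) {
  stopifnot(inherits(epm, "epoch_power"))
  bank <- data.frame(center = epm$centers)
  members <- lapply(seq_len(nrow(bands)), function(i) {
    which(bank$center >= bands$lo[i] & bank$center < bands$hi[i])
  })
  names(members) <- as.character(bands$band)
  if (any(vapply(members, length, integer(1)) == 0)) {
    stopf("band with no member channels")
  }
  out <- data.frame(epoch_index = seq_len(nrow(epm$values)) - 1L,
                    kept = epm$kept)
  for (b in names(members)) {
    out[[b]] <- rowMeans(epm$values[, members[[b]], drop = FALSE])
  }
  out
}

#' Average per-epoch band power into time bins
#'
#' @param band_epochs Output of [aggregate_bands()].
#' @param bin_width_s Bin width in seconds; must be a multiple of the 4-s
#'   epoch length (3600 for baseline 1-h bins, 600 for treatment 10-min
#'   bins).
#' @param anchor_s Time origin in seconds from recording start (0 for
#'   baselines; the injection time for treatment sessions, so pretreatment
#'   bins get negative `bin_start_min`).
#' @param meta Optional named list of key columns (subject, genotype,
#'   treatment) replicated onto every row.
#' @return Long data.frame: keys, `band`, `bin_start_min`, `value`
#'   (mean over kept epochs; `NA` for fully masked bins), `n_epochs`.
#' @export
bin_time <- function(band_epochs, bin_width_s = 3600, anchor_s = 0,
                     meta = NULL) {
  if (bin_width_s %% 4 != 0) stopf("bin_width_s must be a multiple of 4 s")
  t_epoch <- band_epochs$epoch_index * 4
  bin <- floor((t_epoch - anchor_s) / bin_width_s)
  bin_levels <- seq(min(bin), max(bin))
  rows <- lapply(BAND_LABELS, function(b) {
    vals <- vapply(bin_levels, function(k) {
      sel <- bin == k & band_epochs$kept
      if (!any(sel)) return(c(NA_real_, 0))
      c(mean(band_epochs[[b]][sel]), sum(sel))
    }, numeric(2))
    data.frame(band = b, bin_start_min = bin_levels * bin_width_s / 60,
               value = vals[1, ], n_epochs = as.integer(vals[2, ]))
  })
  out <- do.call(rbind, rows)
  if (!is.null(meta)) {
    for (k in rev(names(meta))) out <- cbind(stats::setNames(
      data.frame(rep(meta[[k]], nrow(out))), k), out)
  }
  out$band <- factor(out$band, levels = BAND_LABELS)
  rownames(out) <- NULL
  out
}

#' Normalize band power to the total power per time bin
#'
#' Each band's value is divided by the sum of all seven band values in the
#' same bin (and same session), so normalized rows sum to 1 per bin. Bins
#' with zero or missing total are emitted as missing with a warning.
#'
#' @param binned Long binned table from [bin_time()].
#' @return Same shape, values as fractions of total band power.
#' @export
normalize_baseline <- function(binned) {
  parts <- split_by_keys(binned, extra = "bin_start_min")
  out <- lapply(parts, function(d) {
    tot <- sum(d$value)
    if (!is.finite(tot) || tot <= 0) {
      warnf("bin at %g min has zero or missing total power; emitted as missing",
            d$bin_start_min[1])
      d$value <- NA_real_
    } else {
      d$value <- d$value / tot
    }
    d
  })
  res <- do.call(rbind, out)
  res <- res[order(res$band, res$bin_start_min), ]
  rownames(res) <- NULL
  res
}

#' Normalize each band to its pretreatment mean
#'
#' Divides every bin of a band by that band's epoch-weighted mean over the
#' pretreatment window (bins with `bin_start_min < 0`), per session. The
#' pretreatment mean of the output is 1 by construction.
#'
#' @param binned Long binned table from [bin_time()] anchored at the
#'   injection time.
#' @return Same shape, values as ratios to the pretreatment mean.
#' @export
normalize_pretreatment <- function(binned) {
  parts <- split_by_keys(binned, extra = "band")
  out <- lapply(parts, function(d) {
    pre <- d$bin_start_min < 0 & !is.na(d$value) & d$n_epochs > 0
    if (!any(pre)) stopf("no kept pretreatment bins for band %s", d$band[1])
    ref <- sum(d$value[pre] * d$n_epochs[pre]) / sum(d$n_epochs[pre])
    if (!is.finite(ref) || ref <= 0) {
      stopf("zero pretreatment mean for band %s", d$band[1])
    }
    d$value <- d$value / ref
    d
  })
  res <- do.call(rbind, out)
  res <- res[order(res$band, res$bin_start_min), ]
  rownames(res) <- NULL
  res
}

#' Epoch-weighted mean band power over an analysis window
#'
#' @param binned Long binned table.
#' @param window Two-element numeric `c(from, to)` in minutes since
#'   injection, half-open `[from, to)`. The conventional windows are acute
#'   `c(0, 120)` and subacute `c(120, 300)`.
#' @return data.frame with keys, `band` and `value` (the epoch-weighted
#'   window mean; `NA` when the window holds no kept bins).
#' @export
window_mean <- function(binned, window = c(0, 120)) {
  stopifnot(length(window) == 2, window[1] < window[2])
  parts <- split_by_keys(binned, extra = "band")
  out <- lapply(parts, function(d) {
    sel <- d$bin_start_min >= window[1] & d$bin_start_min < window[2] &
      !is.na(d$value) & d$n_epochs > 0
    keys <- d[1, setdiff(names(d), c("bin_start_min", "value", "n_epochs")),
              drop = FALSE]
    keys$value <- if (any(sel)) {
      sum(d$value[sel] * d$n_epochs[sel]) / sum(d$n_epochs[sel])
    } else NA_real_
    keys
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
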