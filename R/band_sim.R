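#' Summary-level synthetic band-power study
#'
#' Draws per-time-bin band powers directly from the same effect model as the
#' signal-level generator — per-band baseline power, squared genotype
#' amplitude scaling, squared drug/stress amplitude gains averaged over each
#' bin, a per-subject log-normal amplitude random effect, and multiplicative
#' log-normal bin noise — without synthesizing raw EEG. This is the
#' generator's fast mode for Monte-Carlo calibration and power studies of
#' the rank statistics; the signal-level mode ([make_study()]) validates
#' that the spectral pipeline reproduces the same band structure.
#'
#' @param design data.frame with columns `subject`, `genotype` and
#'   optionally `treatment` (one row per session).
#' @param seed Master seed.
#' @param n_pre_bins,n_post_bins Number of pre-/post-injection bins.
#' @param bin_width_min Bin width, minutes.
#' @param base_power Named per-band baseline power (amplitude-squared
#'   units); defaults emulate a murine 1/f-weighted band profile.
#' @param genotype_scales Named list of per-genotype named band *amplitude*
#'   multipliers (power scales as their square).
#' @param drug_profiles Named list mapping treatment label to
#'   [drug_profile()]; unlisted treatments get [drug_profile_null()].
#' @param subject_sd SD of per-subject log-amplitude random effect.
#' @param bin_sd SD of per-bin log-power measurement noise.
#' @param n_epochs_per_bin Nominal kept-epoch count recorded per bin.
#' @return Long data.frame: `subject`, `genotype`, `treatment`, `band`,
#'   `bin_start_min` (negative for pretreatment bins), `value`, `n_epochs`.
#' @export
simulate_band_study <- function(design, seed = 1L, n_pre_bins = 6L,
                                n_post_bins = 12L, bin_width_min = 10,
                                base_power = NULL,
                                genotype_scales = list(),
                                drug_profiles = list(),
                                subject_sd = 0.2, bin_sd = 0.15,
                                n_epochs_per_bin = 150L) {
  stopifnot(all(c("subject", "genotype") %in% names(design)))
  if (is.null(design$treatment)) design$treatment <- "none"
  if (is.null(base_power)) {
    base_power <- c(delta = 800, theta = 300, alpha = 70, sigma = 35,
                    beta = 30, gamma1 = 8, gamma2 = 5)
  }
  stopifnot(all(BAND_LABELS %in% names(base_power)))
  key <- paste(design$subject, design$treatment)
  if (anyDuplicated(key)) stopf("duplicate subject/session keys")

  subjects <- unique(design$subject)
  subj_eff <- vapply(subjects, function(s) {
    with_seed(derive_seed(seed, "subject_effect", s),
              exp(stats::rnorm(1, 0, subject_sd)))
  }, numeric(1))
  names(subj_eff) <- subjects

  bins <- (seq_len(n_pre_bins + n_post_bins) - 1L - n_pre_bins) * bin_width_min
  # mean squared gain over a bin, on a 0.5-min grid
  mean_sq_gain <- function(profile, band, bin_start) {
    if (bin_start < 0) return(1)
    tt <- seq(bin_start, bin_start + bin_width_min, by = 0.5)
    mean(drug_gain(profile, band, tt)^2)
  }

  rows <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    s <- as.character(design$subject[i])
    g <- as.character(design$genotype[i])
    tr <- as.character(design$treatment[i])
    profile <- drug_profiles[[tr]] %||% drug_profile_null()
    gs <- genotype_scales[[g]] %||% numeric(0)
    noise <- with_seed(derive_seed(seed, s, tr, "bins"),
                       matrix(stats::rnorm(length(bins) * 7, 0, bin_sd),
                              length(bins), 7))
    vals <- matrix(0, length(bins), 7, dimnames = list(NULL, BAND_LABELS))
    for (b in seq_along(BAND_LABELS)) {
      band <- BAND_LABELS[b]
      gsc <- unname(gs[band]); if (is.na(gsc) || !length(gsc)) gsc <- 1
      gain2 <- vapply(bins, mean_sq_gain, numeric(1),
                      profile = profile, band = band)
      vals[, b] <- base_power[[band]] * gsc^2 * subj_eff[[s]]^2 *
        gain2 * exp(noise[, b])
    }
    rows[[i]] <- data.frame(
      subject = s, genotype = g, treatment = tr,
      band = rep(BAND_LABELS, each = length(bins)),
      bin_start_min = rep(bins, times = 7),
      value = as.vector(vals),
      n_epochs = n_epochs_per_bin)
  }
  out <- do.call(rbind, rows)
  out$band <- factor(out$band, levels = BAND_LABELS)
  rownames(out) <- NULL
  out
}
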