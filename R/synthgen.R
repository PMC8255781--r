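#' Oscillator specification for the synthetic EEG generator
#'
#' Each oscillator contributes a band-limited stochastic rhythm: white noise
#' spectrally confined to `center_freq +/- bandwidth/2`, scaled so its RMS
#' equals `amplitude / sqrt(2)` (the RMS of a sinusoid of that amplitude).
#' Band-limited noise rather than a pure tone is used so the synthetic bands
#' have realistic spectral spread at the band edges.
#'
#' @param center_freq Center frequency, Hz.
#' @param bandwidth Full bandwidth, Hz.
#' @param amplitude Peak-equivalent amplitude, uV.
#' @param band Band label; one of delta, theta, alpha, sigma, beta,
#'   gamma1, gamma2. Must contain `center_freq`.
#' @return An `oscillator_spec` list.
#' @export
oscillator_spec <- function(center_freq, bandwidth, amplitude, band) {
  band <- match.arg(band, BAND_LABELS)
  if (center_freq <= 0) stopf("center_freq must be > 0")
  if (bandwidth <= 0) stopf("bandwidth must be > 0")
  if (amplitude < 0) stopf("amplitude must be >= 0")
  bd <- band_definitions()
  rng <- bd[bd$band == band, ]
  if (center_freq < rng$lo || center_freq >= rng$hi) {
    stopf("center_freq %.2f Hz outside %s band [%g, %g)",
          center_freq, band, rng$lo, rng$hi)
  }
  structure(list(center_freq = center_freq, bandwidth = bandwidth,
                 amplitude = amplitude, band = band),
            class = "oscillator_spec")
}

#' Default oscillator set
#'
#' One oscillator per band with amplitudes decreasing roughly as 1/f,
#' emulating the murine cortical EEG spectrum (strong slow-wave delta,
#' prominent theta, weak fast gamma).
#'
#' @return List of [oscillator_spec()] objects.
#' @export
default_oscillators <- function() {
  list(
    oscillator_spec(2.5, 2.0, 40, "delta"),
    oscillator_spec(6.0, 3.0, 25, "theta"),
    oscillator_spec(10.0, 3.0, 12, "alpha"),
    oscillator_spec(12.5, 3.0, 8, "sigma"),
    oscillator_spec(20.0, 10.0, 8, "beta"),
    oscillator_spec(40.0, 15.0, 4, "gamma1"),
    oscillator_spec(70.0, 30.0, 3, "gamma2")
  )
}

#' Drug-effect time-course profile
#'
#' Describes a drug's per-band multiplicative *amplitude* gain trajectory as
#' a function of time since injection, plus an injection-stress transient
#' shared by all treatments (including vehicle). The trajectory ramps
#' linearly from 1 at `onset_min` to the peak gain at `peak_min`, holds the
#' peak until `offset_min`, then decays exponentially back toward 1 with a
#' 30-min time constant.
#' The stress transient multiplies every band by `stress_gains[band]` at the
#' moment of injection, relaxing to 1 with time constant `stress_tau_min`
#' (so it is maximal within the first 10-min bin).
#'
#' Gains act on amplitude; spectral power scales as gain squared.
#'
#' @param band_gains Named numeric vector of peak amplitude gains, names in
#'   the band vocabulary. Bands not named have trajectory gain 1.
#' @param onset_min,peak_min,offset_min Trajectory timing, minutes.
#' @param stress_gains Named numeric vector of instantaneous-injection
#'   amplitude gains (default: none).
#' @param stress_tau_min Stress-transient decay constant, minutes.
#' @param label Free-text profile label.
#' @return A `drug_profile` list.
#' @export
drug_profile <- function(band_gains = numeric(0), onset_min = 5,
                         peak_min = 30, offset_min = 150,
                         stress_gains = numeric(0), stress_tau_min = 10,
                         label = "custom") {
  if (length(band_gains) && (is.null(names(band_gains)) ||
      !all(names(band_gains) %in% BAND_LABELS))) {
    stopf("band_gains must be named with band labels")
  }
  if (length(stress_gains) && !all(names(stress_gains) %in% BAND_LABELS)) {
    stopf("stress_gains must be named with band labels")
  }
  if (any(c(band_gains, stress_gains) <= 0)) stopf("all gains must be > 0")
  if (!(onset_min <= peak_min && peak_min < offset_min)) {
    stopf("need onset_min <= peak_min < offset_min")
  }
  structure(list(band_gains = band_gains, onset_min = onset_min,
                 peak_min = peak_min, offset_min = offset_min,
                 stress_gains = stress_gains,
                 stress_tau_min = stress_tau_min, label = label),
            class = "drug_profile")
}

#' @rdname drug_profile
#' @export
drug_profile_null <- function() drug_profile(label = "null")

# Injection-stress amplitude gains shared by all active profiles:
# suppression of delta..beta, increment of the gamma bands, as seen after
# vehicle injection.
.stress_defaults <- function() {
  c(delta = 0.8, theta = 0.8, alpha = 0.85, sigma = 0.85, beta = 0.85,
    gamma1 = 1.25, gamma2 = 1.15)
}

#' @rdname drug_profile
#' @export
drug_profile_saline <- function() {
  drug_profile(stress_gains = .stress_defaults(), label = "SAL")
}

#' @rdname drug_profile
#' @param delta_gain,theta_gain Peak amplitude gains for the THIP-like
#'   delta/theta power increment.
#' @export
drug_profile_thip <- function(delta_gain = 2.0, theta_gain = 1.5) {
  drug_profile(band_gains = c(delta = delta_gain, theta = theta_gain),
               onset_min = 5, peak_min = 30, offset_min = 120,
               stress_gains = .stress_defaults(), label = "THIP")
}

#' @rdname drug_profile
#' @param suppression Amplitude gain applied to every band except gamma1
#'   for the stimulant-like broadband suppression.
#' @export
drug_profile_4mmc <- function(suppression = 0.75) {
  gains <- rep(suppression, 6)
  names(gains) <- setdiff(BAND_LABELS, "gamma1")
  drug_profile(band_gains = gains, onset_min = 2, peak_min = 15,
               offset_min = 120, stress_gains = .stress_defaults(),
               label = "4-MMC")
}

#' Evaluate a drug profile's amplitude gain
#'
#' @param profile A [drug_profile()].
#' @param band Band label.
#' @param t_min Time since injection, minutes (vectorized, must be >= 0).
#' @return Dimensionless amplitude gain(s), continuous in `t_min`,
#'   tending to 1 as `t_min` grows.
#' @export
drug_gain <- function(profile, band, t_min) {
  stopifnot(inherits(profile, "drug_profile"))
  if (!band %in% BAND_LABELS) stopf("unknown band label '%s'", band)
  if (any(t_min < 0)) stopf("t_min must be >= 0")
  g <- rep(1, length(t_min))
  peak <- unname(profile$band_gains[band])
  if (!is.na(peak) && length(peak)) {
    shape <- ifelse(
      t_min <= profile$onset_min, 0,
      ifelse(t_min <= profile$peak_min,
             (t_min - profile$onset_min) /
               max(profile$peak_min - profile$onset_min, .Machine$double.eps),
             ifelse(t_min <= profile$offset_min, 1,
                    exp(-(t_min - profile$offset_min) / 30))))
    g <- 1 + (peak - 1) * shape
  }
  s <- unname(profile$stress_gains[band])
  if (!is.na(s) && length(s)) {
    g <- g * exp(log(s) * exp(-t_min / profile$stress_tau_min))
  }
  g
}

#' Generator specification
#'
#' Full description of one synthetic recording: oscillators, 1/f background,
#' genotype scaling, drug profile, artifacts and RNG seed. The defaults
#' mirror the study's recording conditions (two EEG channels plus EMG at
#' 1000 Hz; sporadic movement artifacts with EMG coincidence).
#'
#' @param duration Recording length, seconds (integer).
#' @param fs Sampling rate, Hz.
#' @param oscillators List of [oscillator_spec()].
#' @param noise_exponent Spectral slope `a` of the 1/f^a background.
#' @param noise_floor RMS amplitude of the background, uV.
#' @param genotype_scale Named per-band amplitude multipliers (e.g. the
#'   knockout's elevated delta); unnamed bands scale by 1.
#' @param drug A [drug_profile()] or `NULL`.
#' @param injection_time Seconds from recording start, or `NULL`.
#' @param artifact_rate Expected artifact events per hour.
#' @param emg_rms Baseline EMG RMS, uV.
#' @param light_onset,light_offset Zeitgeber lights-on/off, hours.
#' @param seed Integer; fully determines the output.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(duration, fs = 1000, oscillators = default_oscillators(),
                           noise_exponent = 1, noise_floor = 10,
                           genotype_scale = numeric(0), drug = NULL,
                           injection_time = NULL, artifact_rate = 0,
                           emg_rms = 5, light_onset = 0, light_offset = 12,
                           seed = 1L) {
  if (!is.numeric(duration) || duration <= 0) stopf("duration must be > 0")
  if (!is.numeric(fs) || fs <= 0) stopf("fs must be > 0")
  if (artifact_rate < 0) stopf("artifact_rate must be >= 0")
  if (length(genotype_scale) && !all(names(genotype_scale) %in% BAND_LABELS)) {
    stopf("genotype_scale must be named with band labels")
  }
  if (!is.null(drug) && !inherits(drug, "drug_profile")) {
    stopf("drug must be a drug_profile or NULL")
  }
  if (!is.null(drug) && is.null(injection_time)) {
    stopf("a drug profile requires injection_time")
  }
  structure(list(duration = duration, fs = fs, oscillators = oscillators,
                 noise_exponent = noise_exponent, noise_floor = noise_floor,
                 genotype_scale = genotype_scale, drug = drug,
                 injection_time = injection_time,
                 artifact_rate = artifact_rate, emg_rms = emg_rms,
                 light_onset = light_onset, light_offset = light_offset,
                 seed = seed),
            class = "generator_spec")
}

# White noise spectrally confined to [lo, hi] Hz, scaled to unit RMS.
band_limited_noise <- function(n, fs, lo, hi) {
  nfft <- stats::nextn(n, c(2, 3, 5))
  x <- stats::rnorm(nfft)
  X <- stats::fft(x)
  f <- seq(0, nfft - 1) / nfft * fs
  f <- pmin(f, fs - f)  # two-sided frequency axis folded to [0, fs/2]
  X[f < lo | f > hi] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / nfft
  y <- y[seq_len(n)]
  r <- sqrt(mean(y^2))
  if (r == 0) rep(0, n) else y / r
}

# 1/f^a background noise with the requested RMS.
one_over_f_noise <- function(n, fs, a, rms) {
  if (rms <= 0) return(rep(0, n))
  nfft <- stats::nextn(n, c(2, 3, 5))
  x <- stats::rnorm(nfft)
  X <- stats::fft(x)
  f <- seq(0, nfft - 1) / nfft * fs
  f <- pmin(f, fs - f)
  shape <- ifelse(f > 0, f^(-a / 2), 0)
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / nfft
  y <- y[seq_len(n)]
  y / sqrt(mean(y^2)) * rms
}

# One EEG channel: sum of gain-modulated band-limited oscillators + 1/f
# background. `t` in seconds; gains are evaluated in minutes since injection.
synth_eeg_channel <- function(spec, n, t) {
  eeg <- numeric(n)
  for (osc in spec$oscillators) {
    wave <- band_limited_noise(n, spec$fs, osc$center_freq - osc$bandwidth / 2,
                               osc$center_freq + osc$bandwidth / 2)
    amp <- osc$amplitude / sqrt(2)
    gscale <- unname(spec$genotype_scale[osc$band])
    if (!is.na(gscale) && length(gscale)) amp <- amp * gscale
    gain <- rep(1, n)
    if (!is.null(spec$drug)) {
      post <- t >= spec$injection_time
      if (any(post)) {
        gain[post] <- drug_gain(spec$drug, osc$band,
                                (t[post] - spec$injection_time) / 60)
      }
    }
    eeg <- eeg + amp * gain * wave
  }
  eeg + one_over_f_noise(n, spec$fs, spec$noise_exponent, spec$noise_floor)
}

#' Generate one synthetic EEG/EMG recording with ground-truth artifact mask
#'
#' @param spec A [generator_spec()].
#' @return A list with elements `recording` (an `eeg_recording`: channels
#'   `eeg_frontal`, `eeg_parietal`, `emg`; `fs`; `t0`; `meta`) and `mask`
#'   (an `artifact_mask` covering every whole 4-s epoch, with the injected
#'   event log in `attr(mask, "events")`).
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- round(spec$duration * spec$fs)
  with_seed(spec$seed, {
    t <- seq_len(n) / spec$fs
    eeg1 <- synth_eeg_channel(spec, n, t)
    eeg2 <- 0.9 * synth_eeg_channel(spec, n, t)
    emg <- stats::rnorm(n, sd = spec$emg_rms)

    n_epochs <- floor(spec$duration / 4)
    events <- data.frame(onset_s = numeric(0), duration_s = numeric(0))
    is_artifact <- rep(FALSE, n_epochs)
    n_ev <- stats::rpois(1, spec$artifact_rate * spec$duration / 3600)
    if (n_ev > 0) {
      dur <- rep(0.5, n_ev)
      onset <- stats::runif(n_ev, 0, spec$duration - dur)
      events <- data.frame(onset_s = sort(onset), duration_s = dur)
      sd_bg <- stats::sd(eeg1)
      for (i in seq_len(n_ev)) {
        idx <- which(t >= events$onset_s[i] &
                     t < events$onset_s[i] + events$duration_s[i])
        burst <- 10 * sd_bg *
          sin(pi * seq_along(idx) / length(idx))^2 *
          sign(stats::rnorm(length(idx)))
        eeg1[idx] <- eeg1[idx] + burst
        eeg2[idx] <- eeg2[idx] + burst
        emg[idx] <- emg[idx] + 10 * spec$emg_rms *
          sin(pi * seq_along(idx) / length(idx))^2 * stats::rnorm(length(idx))
        ep <- floor(events$onset_s[i] / 4):
          floor((events$onset_s[i] + events$duration_s[i] - 1e-9) / 4)
        ep <- ep[ep < n_epochs]
        is_artifact[ep + 1] <- TRUE
      }
    }

    recording <- structure(
      list(channels = list(eeg_frontal = eeg1, eeg_parietal = eeg2, emg = emg),
           fs = spec$fs, t0 = 0,
           meta = list(subject = NA_character_, genotype = NA_character_,
                       treatment = NA_character_,
                       injection_time_s = spec$injection_time %||% NA_real_)),
      class = "eeg_recording")
    mask <- artifact_mask(is_artifact)
    attr(mask, "events") <- events
    list(recording = recording, mask = mask)
  })
}

#' Construct an artifact mask
#'
#' @param is_artifact Logical vector, one entry per 4-s epoch (epoch 0 first).
#' @return An `artifact_mask` data.frame with 0-based `epoch_index` and
#'   `is_artifact`, epoch length fixed at 4 s.
#' @export
artifact_mask <- function(is_artifact) {
  structure(data.frame(epoch_index = seq_along(is_artifact) - 1L,
                       is_artifact = as.logical(is_artifact)),
            epoch_len = 4,
            class = c("artifact_mask", "data.frame"))
}

#' Generate a full synthetic study
#'
#' One 24-h baseline recording per subject plus one pretreatment + post-
#' treatment session per design row, with a per-subject log-normal amplitude
#' random effect (SD 0.2 on the log scale) drawn once per subject. Default
#' durations mirror the study sessions (24-h baseline; 1-h pretreatment and
#' 5-h post-treatment at 1000 Hz); pass smaller values for quick simulations.
#'
#' @param design data.frame with columns `subject`, `genotype`, `treatment`
#'   (one row per treatment session).
#' @param seed Master seed; per-recording streams are derived with
#'   [derive_seed()] from (subject, session), so each recording is stable.
#' @param fs Sampling rate, Hz.
#' @param baseline_duration,pre_duration,post_duration Seconds.
#' @param genotype_scales Named list: per-genotype named band amplitude
#'   multipliers (e.g. `list(KO = c(delta = 1.3))`).
#' @param drug_profiles Named list mapping treatment label to
#'   [drug_profile()]; treatments not listed get [drug_profile_saline()].
#' @param artifact_rate Events per hour.
#' @param subject_sd SD of the per-subject log-amplitude random effect.
#' @param include_baseline Generate the 24-h baselines?
#' @param ... Further arguments passed to [generator_spec()].
#' @return A `synthetic_study` list: `design`, `subject_effects`,
#'   `baselines` (named by subject), `sessions` (list of
#'   `list(recording, mask, subject, genotype, treatment)`).
#' @export
make_study <- function(design, seed = 1L, fs = 1000,
                       baseline_duration = 86400, pre_duration = 3600,
                       post_duration = 18000,
                       genotype_scales = list(),
                       drug_profiles = list(),
                       artifact_rate = 5, subject_sd = 0.2,
                       include_baseline = TRUE, ...) {
  stopifnot(all(c("subject", "genotype", "treatment") %in% names(design)))
  key <- paste(design$subject, design$treatment)
  if (anyDuplicated(key)) {
    stopf("duplicate subject/session keys: %s",
          paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  subjects <- unique(design$subject)
  subj_eff <- vapply(subjects, function(s) {
    with_seed(derive_seed(seed, "subject_effect", s),
              exp(stats::rnorm(1, 0, subject_sd)))
  }, numeric(1))
  names(subj_eff) <- subjects

  scale_osc <- function(mult) {
    lapply(default_oscillators(), function(o) {
      o$amplitude <- o$amplitude * mult
      o
    })
  }
  gscale_for <- function(genotype) {
    gs <- genotype_scales[[as.character(genotype)]]
    if (is.null(gs)) numeric(0) else gs
  }
  profile_for <- function(treatment) {
    p <- drug_profiles[[as.character(treatment)]]
    if (is.null(p)) drug_profile_saline() else p
  }

  baselines <- list()
  if (include_baseline) {
    for (s in subjects) {
      g <- design$genotype[match(s, design$subject)]
      sp <- generator_spec(duration = baseline_duration, fs = fs,
                           oscillators = scale_osc(subj_eff[[s]]),
                           genotype_scale = gscale_for(g),
                           artifact_rate = artifact_rate,
                           seed = derive_seed(seed, s, "baseline"), ...)
      out <- generate_recording(sp)
      out$recording$meta$subject <- as.character(s)
      out$recording$meta$genotype <- as.character(g)
      out$recording$meta$treatment <- "baseline"
      baselines[[as.character(s)]] <- out
    }
  }

  sessions <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    s <- design$subject[i]
    sp <- generator_spec(duration = pre_duration + post_duration, fs = fs,
                         oscillators = scale_osc(subj_eff[[as.character(s)]]),
                         genotype_scale = gscale_for(design$genotype[i]),
                         drug = profile_for(design$treatment[i]),
                         injection_time = pre_duration,
                         artifact_rate = artifact_rate,
                         seed = derive_seed(seed, s, design$treatment[i]), ...)
    out <- generate_recording(sp)
    out$recording$meta$subject <- as.character(s)
    out$recording$meta$genotype <- as.character(design$genotype[i])
    out$recording$meta$treatment <- as.character(design$treatment[i])
    sessions[[i]] <- c(out, list(subject = as.character(s),
                                 genotype = as.character(design$genotype[i]),
                                 treatment = as.character(design$treatment[i])))
  }
  structure(list(design = design, subject_effects = subj_eff,
                 baselines = baselines, sessions = sessions),
            class = "synthetic_study")
}
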