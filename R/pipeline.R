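# End-to-end orchestration: raw recordings -> band tables -> rank tests,
# mirroring the two study arms (24-h baseline; pretreatment + post-
# treatment pharmaco-EEG session), plus report rendering.

#' Process one recording into a binned band-power table
#'
#' Downsamples to the filter bank's analysis rate if needed, obtains an
#' artifact mask (supplied, or from [detect_artifacts()]), runs the
#' filter-bank/Hilbert/epoch-median chain, aggregates to bands and bins in
#' time. Baseline mode bins from recording start and normalizes to total
#' band power per bin; treatment mode bins from the injection time and
#' normalizes each band to its pretreatment mean.
#'
#' @param recording An `eeg_recording`.
#' @param mode `"baseline"` or `"treatment"`.
#' @param mask Optional [artifact_mask()] (4-s epochs at the analysis
#'   rate); when `NULL` the automatic detector is used.
#' @param bank Filter bank from [build_filterbank()].
#' @param channel Analysis channel (frontal EEG by default).
#' @param bin_width_s Bin width; defaults to 3600 s (baseline) or 600 s
#'   (treatment).
#' @param normalize Apply the mode's normalization (set `FALSE` for raw
#'   band power, e.g. for pretreatment stability checks).
#' @return Long binned band table (see [bin_time()]) with the recording's
#'   metadata as key columns.
#' @export
process_session <- function(recording, mode = c("baseline", "treatment"),
                            mask = NULL, bank = build_filterbank(),
                            channel = "eeg_frontal", bin_width_s = NULL,
                            normalize = TRUE) {
  mode <- match.arg(mode)
  if (is.null(bin_width_s)) bin_width_s <- if (mode == "baseline") 3600 else 600
  if (recording$fs != bank$fs) {
    recording <- downsample(recording, target_fs = bank$fs)
  }
  if (is.null(mask)) {
    mask <- detect_artifacts(recording$channels[[channel]],
                             recording$channels$emg, recording$fs)
  }
  epm <- compute_epoch_power(recording, bank, mask, channel)
  be <- aggregate_bands(epm)
  anchor <- if (mode == "treatment") {
    inj <- recording$meta$injection_time_s
    if (is.null(inj) || is.na(inj)) stopf("treatment mode requires injection time")
    inj
  } else 0
  meta <- recording$meta[c("subject", "genotype", "treatment")]
  binned <- bin_time(be, bin_width_s = bin_width_s, anchor_s = anchor,
                     meta = meta)
  if (!normalize) return(binned)
  if (mode == "baseline") normalize_baseline(binned)
  else normalize_pretreatment(binned)
}

#' Process a whole synthetic or loaded study into one band table
#'
#' @param study A `synthetic_study` from [make_study()] (or a list with the
#'   same shape holding loaded recordings).
#' @param mode `"baseline"` (uses `study$baselines`) or `"treatment"`
#'   (uses `study$sessions`).
#' @param use_truth_masks Use the generator's ground-truth masks instead of
#'   the automatic detector. Masks are defined on 4-s epochs of the raw
#'   recording, which coincide with analysis-rate epochs.
#' @param ... Passed to [process_session()].
#' @return Long band table over all subjects/sessions.
#' @export
collect_study_bands <- function(study, mode = c("baseline", "treatment"),
                                use_truth_masks = TRUE, ...) {
  mode <- match.arg(mode)
  recs <- if (mode == "baseline") study$baselines else study$sessions
  if (!length(recs)) stopf("study has no %s recordings", mode)
  tabs <- lapply(recs, function(r) {
    process_session(r$recording, mode = mode,
                    mask = if (use_truth_masks) r$mask else NULL, ...)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

apply_band_family <- function(tests) {
  m <- length(unique(tests$band))
  tests$p_corrected <- bonferroni(tests$p_raw, m)
  tests
}

#' Baseline analysis: per-band genotype tests on 24-h normalized power
#'
#' For each band, an F1-LD-F1 layout (genotype x 1-h time bins) on the
#' total-power-normalized values: genotype main effect, time and
#' genotype:time, as WTS and ATS, Bonferroni-corrected across the seven
#' bands; plus Bonferroni-corrected per-hour genotype comparisons per band.
#' Subjects missing from a band's table are simply absent from that test;
#' `n` always reports the units actually used.
#'
#' @param bands Long normalized baseline band table (from
#'   [collect_study_bands()] or files) with `subject`, `genotype`, `band`,
#'   `bin_start_min`, `value`.
#' @return List: `tests` (all effects x bands), `posthoc` (per-band
#'   per-hour comparisons), `band_table` (the input, for plotting).
#' @export
run_baseline <- function(bands) {
  tests <- do.call(rbind, lapply(levels(droplevels(factor(bands$band))),
    function(b) {
      d <- bands[bands$band == b & is.finite(bands$value), ]
      ld <- long_dataset(d, "F1_LD_F1", subject = "subject",
                         time = "bin_start_min", groups = "genotype")
      ft <- fit_design(ld)
      ft$band <- b
      ft
    }))
  tests <- do.call(rbind, lapply(split(tests,
    list(tests$effect, tests$statistic_type), drop = TRUE),
    apply_band_family))
  rownames(tests) <- NULL
  posthoc <- lapply(split(bands, bands$band, drop = TRUE), posthoc_timepoints)
  list(tests = tests, posthoc = posthoc, band_table = bands)
}

#' Treatment analysis: F2-LD-F1 tests and post-hoc comparisons
#'
#' For each band and analysis window (acute 0-2 h, subacute 2-5 h by
#' default), fits treatment x genotype x time on the pretreatment-
#' normalized 10-min series, with (subject, treatment-session) as the
#' independent unit. Adds pairwise treatment-vs-reference rank comparisons
#' of window means per genotype (Bonferroni family = comparisons per band)
#' and per-bin genotype post-hocs per treatment.
#'
#' @param bands Long pretreatment-normalized band table with `subject`,
#'   `genotype`, `treatment`, `band`, `bin_start_min`, `value`, `n_epochs`.
#' @param windows Named list of `c(from, to)` windows in minutes.
#' @param reference Reference treatment label for pairwise comparisons
#'   (vehicle), or `NULL` to skip.
#' @return List: `tests`, `pairwise`, `posthoc` (per band x treatment),
#'   `band_table`.
#' @export
run_treatment <- function(bands,
                          windows = list(acute = c(0, 120),
                                         subacute = c(120, 300)),
                          reference = "SAL") {
  bands$unit <- paste(bands$subject, bands$treatment, sep = ":")
  band_levels <- levels(droplevels(factor(bands$band)))

  tests <- do.call(rbind, lapply(names(windows), function(w) {
    win <- windows[[w]]
    sub <- bands[bands$bin_start_min >= win[1] & bands$bin_start_min < win[2] &
                 is.finite(bands$value), ]
    do.call(rbind, lapply(band_levels, function(b) {
      d <- sub[sub$band == b, ]
      ld <- long_dataset(d, "F2_LD_F1", subject = "unit",
                         time = "bin_start_min",
                         groups = c("treatment", "genotype"))
      ft <- fit_design(ld)
      ft$band <- b
      ft$window <- w
      ft
    }))
  }))
  tests <- do.call(rbind, lapply(split(tests,
    list(tests$effect, tests$statistic_type, tests$window), drop = TRUE),
    apply_band_family))
  rownames(tests) <- NULL

  pairwise <- NULL
  if (!is.null(reference) && reference %in% bands$treatment) {
    others <- setdiff(unique(bands$treatment), reference)
    pairwise <- do.call(rbind, lapply(names(windows), function(w) {
      wm <- window_mean(bands, windows[[w]])
      do.call(rbind, lapply(band_levels, function(b) {
        do.call(rbind, lapply(unique(wm$genotype), function(g) {
          rows <- lapply(others, function(tr) {
            x <- wm$value[wm$band == b & wm$genotype == g &
                          wm$treatment == reference]
            y <- wm$value[wm$band == b & wm$genotype == g &
                          wm$treatment == tr]
            if (length(x) < 2 || length(y) < 2) return(NULL)
            wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
            data.frame(window = w, band = b, genotype = g,
                       comparison = paste(reference, "vs", tr),
                       statistic = unname(wt$statistic),
                       p_raw = wt$p.value)
          })
          out <- do.call(rbind, rows)
          if (!is.null(out)) out$p_corrected <- bonferroni(out$p_raw, nrow(out))
          out
        }))
      }))
    }))
    if (!is.null(pairwise)) {
      pairwise$tier <- significance_tier(pairwise$p_corrected)
      rownames(pairwise) <- NULL
    }
  }

  posthoc <- lapply(split(bands, list(bands$band, bands$treatment),
                          drop = TRUE, sep = " x "),
                    function(d) {
                      if (length(unique(d$genotype)) != 2) return(NULL)
                      posthoc_timepoints(d[d$bin_start_min >= 0, ])
                    })
  list(tests = tests, pairwise = pairwise, posthoc = posthoc,
       band_table = bands)
}

#' Cross-session stability of pretreatment baselines
#'
#' Tests whether the raw pretreatment band power used for normalization
#' drifts across a subject's sessions: per band, an F1-LD-F1 layout with
#' the session's treatment label as the whole-plot factor over
#' (subject, session) units and pretreatment bins as time. Subjects with a
#' single session are excluded.
#'
#' @param bands Long *raw* (unnormalized) band table restricted to
#'   pretreatment bins, with `subject`, `treatment`, `band`,
#'   `bin_start_min`, `value`.
#' @return data.frame of per-band test results, or an empty data.frame
#'   with a warning when fewer than two sessions exist.
#' @export
check_pretreatment_stability <- function(bands) {
  bands <- bands[bands$bin_start_min < 0 & is.finite(bands$value), ]
  n_sessions <- tapply(bands$treatment, bands$subject,
                       function(x) length(unique(x)))
  keep <- names(n_sessions)[n_sessions >= 2]
  dropped <- setdiff(names(n_sessions), keep)
  if (length(dropped)) {
    warnf("subject(s) with a single session excluded: %s",
          paste(dropped, collapse = ", "))
  }
  bands <- bands[bands$subject %in% keep, ]
  if (!nrow(bands) || length(unique(bands$treatment)) < 2) {
    warnf("fewer than two sessions available; no stability test computed")
    return(data.frame())
  }
  bands$unit <- paste(bands$subject, bands$treatment, sep = ":")
  out <- do.call(rbind, lapply(unique(as.character(bands$band)), function(b) {
    d <- bands[bands$band == b, ]
    ld <- long_dataset(d, "F1_LD_F1", subject = "unit",
                       time = "bin_start_min", groups = "treatment")
    rows <- rbind(wald_type_statistic(ld, "treatment"),
                  anova_type_statistic(ld, "treatment"))
    rows$band <- b
    rows
  }))
  rownames(out) <- NULL
  out
}

#' Standard error of the mean
#'
#' @param x Numeric vector (NAs removed).
#' @return `sd(x)/sqrt(n)`.
#' @export
sem <- function(x) {
  x <- x[is.finite(x)]
  stats::sd(x) / sqrt(length(x))
}

#' Render time-course figures with significance underlays
#'
#' Per-band line plots of group mean +/- SEM over time bins, with
#' three-tier significance markers from per-bin post-hoc results and
#' optional light/dark shading, plus a pairwise comparison-matrix plot
#' when pairwise results are present.
#'
#' @param results Output of [run_baseline()] or [run_treatment()].
#' @param group Grouping column for the line plots.
#' @param dark_period Optional `c(from, to)` minutes shaded as lights-off.
#' @return Named list of ggplot objects (`timecourse`, and `matrix` when
#'   pairwise comparisons exist).
#' @export
render_report <- function(results, group = "genotype", dark_period = NULL) {
  bands <- results$band_table
  bands <- bands[is.finite(bands$value), ]
  agg <- do.call(rbind, lapply(
    split(bands, list(bands$band, bands$bin_start_min, bands[[group]]),
          drop = TRUE),
    function(d) data.frame(band = d$band[1], bin_start_min = d$bin_start_min[1],
                           group = d[[group]][1], mean = mean(d$value),
                           sem = sem(d$value))))
  tier_df <- NULL
  if (length(results$posthoc)) {
    tier_df <- do.call(rbind, lapply(names(results$posthoc), function(b) {
      ph <- results$posthoc[[b]]
      if (is.null(ph) || !nrow(ph)) return(NULL)
      sig <- ph[ph$tier != "", , drop = FALSE]
      if (!nrow(sig)) return(NULL)
      data.frame(band = b, bin_start_min = sig$time, tier = sig$tier)
    }))
  }
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = bin_start_min, y = mean,
                                         color = group)) +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - sem, ymax = mean + sem),
                           width = 0) +
    ggplot2::facet_wrap(~band, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "normalized power", color = group) +
    ggplot2::theme_minimal()
  if (!is.null(dark_period)) {
    p <- p + ggplot2::annotate("rect", xmin = dark_period[1],
                               xmax = dark_period[2], ymin = -Inf, ymax = Inf,
                               alpha = 0.1, fill = "grey20")
  }
  if (!is.null(tier_df) && nrow(tier_df)) {
    tier_df$color <- c(`*` = "grey50", `**` = "blue",
                       `***` = "red")[tier_df$tier]
    p <- p + ggplot2::geom_point(data = tier_df,
                                 ggplot2::aes(x = bin_start_min, y = -Inf),
                                 color = tier_df$color, shape = 15,
                                 inherit.aes = FALSE)
  }
  out <- list(timecourse = p)
  if (!is.null(results$pairwise) && nrow(results$pairwise)) {
    pw <- results$pairwise
    out$matrix <- ggplot2::ggplot(pw, ggplot2::aes(x = band, y = comparison,
                                                   fill = -log10(p_corrected))) +
      ggplot2::geom_tile() +
      ggplot2::geom_text(ggplot2::aes(label = tier)) +
      ggplot2::facet_grid(genotype ~ window) +
      ggplot2::scale_fill_gradient(low = "white", high = "red") +
      ggplot2::theme_minimal()
  }
  out
}

#' Read a study configuration file
#'
#' YAML (or JSON) configuration with paths, windows and options; windows
#' must be ordered and disjoint and referenced files must exist.
#'
#' @param path Config file path.
#' @return Named list of configuration values.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stopf("config not found: %s", path)
  cfg <- if (grepl("\\.json$", path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) stopf("jsonlite needed")
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) stopf("yaml needed")
    yaml::read_yaml(path)
  }
  if (!is.null(cfg$windows)) {
    w <- cfg$windows
    ends <- vapply(w, `[`, numeric(1), 2)
    starts <- vapply(w, `[`, numeric(1), 1)
    o <- order(starts)
    if (any(starts[o][-1] < ends[o][-length(ends)])) {
      stopf("analysis windows must be disjoint and ordered")
    }
  }
  for (f in intersect(c("design", "recordings", "masks"), names(cfg))) {
    missing <- cfg[[f]][!file.exists(unlist(cfg[[f]]))]
    if (length(missing)) {
      stopf("config references missing file(s): %s",
            paste(missing, collapse = ", "))
    }
  }
  cfg
}
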