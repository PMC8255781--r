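# Generator contracts: determinism, spectral content, drug gains,
# artifact ground truth, study assembly.

test_that("generator specs validate their inputs", {
  expect_error(generator_spec(duration = -5), "duration")
  expect_error(generator_spec(duration = 10, fs = 0), "fs")
  expect_error(generator_spec(duration = 10, artifact_rate = -1), "artifact_rate")
  expect_error(oscillator_spec(2.5, 1, 10, "theta"), "outside")
  expect_error(oscillator_spec(-1, 1, 10, "delta"), "center_freq")
  expect_error(generator_spec(duration = 10, drug = drug_profile_thip()),
               "injection_time")
})

test_that("identical specs and seeds give bit-identical recordings", {
  sp <- generator_spec(duration = 60, fs = 200, artifact_rate = 20, seed = 5)
  a <- generate_recording(sp)
  b <- generate_recording(sp)
  expect_identical(a$recording$channels, b$recording$channels)
  expect_identical(a$mask$is_artifact, b$mask$is_artifact)
  sp2 <- generator_spec(duration = 60, fs = 200, artifact_rate = 20, seed = 6)
  c <- generate_recording(sp2)
  expect_false(identical(a$recording$channels$eeg_frontal,
                         c$recording$channels$eeg_frontal))
})

test_that("a single delta oscillator dominates the delta band", {
  sp <- generator_spec(duration = 40, fs = 200,
                       oscillators = list(oscillator_spec(2.5, 1, 20, "delta")),
                       noise_floor = 0, seed = 2)
  out <- generate_recording(sp)
  ep <- compute_epoch_power(out$recording, default_bank())
  peak <- ep$centers[which.max(colMeans(ep$values))]
  expect_gte(peak, 1)
  expect_lt(peak, 4)
  # spectral fidelity: >= 90% of filter-bank power in delta-centered channels
  in_delta <- ep$centers >= 1 & ep$centers < 4
  expect_gte(sum(colMeans(ep$values)[in_delta]) / sum(colMeans(ep$values)),
             0.9)
})

test_that("doubling oscillator amplitude quadruples band epoch power", {
  mk <- function(amp) {
    sp <- generator_spec(duration = 40, fs = 200,
                         oscillators = list(oscillator_spec(6, 2, amp, "theta")),
                         noise_floor = 0, seed = 9)
    out <- generate_recording(sp)
    ep <- compute_epoch_power(out$recording, default_bank())
    bt <- aggregate_bands(ep)
    mean(bt$theta)
  }
  expect_equal(mk(20) / mk(10), 4, tolerance = 0.01)
})

test_that("artifact events are counted, large, and covered by the mask", {
  sp <- generator_spec(duration = 7200, fs = 200, artifact_rate = 10,
                       seed = 21)
  out <- generate_recording(sp)
  events <- attr(out$mask, "events")
  # ~20 expected events (Poisson); allow wide but informative bounds
  expect_gte(nrow(events), 10)
  expect_lte(nrow(events), 32)
  eeg <- out$recording$channels$eeg_frontal
  sp0 <- generator_spec(duration = 7200, fs = 200, artifact_rate = 0,
                        seed = 21)
  bg_sd <- sd(generate_recording(sp0)$recording$channels$eeg_frontal)
  for (i in seq_len(nrow(events))) {
    idx <- round(events$onset_s[i] * 200):round((events$onset_s[i] +
                                                 events$duration_s[i]) * 200)
    expect_gte(max(abs(eeg[idx])), 5 * bg_sd)
    # ground truth: every event covered by >= 1 flagged epoch
    eps <- floor(events$onset_s[i] / 4):
      floor((events$onset_s[i] + events$duration_s[i] - 1e-9) / 4)
    eps <- eps[eps < nrow(out$mask)]
    expect_true(any(out$mask$is_artifact[eps + 1]))
  }
})

test_that("drug gains follow the profile and default to 1", {
  null <- drug_profile_null()
  expect_equal(drug_gain(null, "delta", c(0, 5, 500)), c(1, 1, 1))
  thip <- drug_profile(band_gains = c(delta = 2.0), peak_min = 30,
                       offset_min = 120)
  expect_equal(drug_gain(thip, "delta", 30), 2.0)
  expect_equal(drug_gain(thip, "theta", 30), 1.0)  # unspecified band
  expect_error(drug_gain(thip, "omega", 10), "unknown band")
  expect_error(drug_gain(thip, "delta", -5), "t_min")
  # continuity and return to 1
  tt <- seq(0, 600, by = 0.5)
  g <- drug_gain(thip, "delta", tt)
  expect_lt(max(abs(diff(g))), 0.05)
  expect_equal(g[length(g)], 1, tolerance = 1e-4)
  # 4-MMC-like suppression plateau readable back from the profile
  mmc <- drug_profile_4mmc(suppression = 0.6)
  expect_equal(drug_gain(drug_profile(band_gains = c(beta = 0.6),
                                      onset_min = 2, peak_min = 15,
                                      offset_min = 120), "beta", 60), 0.6)
  expect_lt(drug_gain(mmc, "beta", 60), 1)
  expect_equal(drug_gain(mmc, "gamma1", 60), 1, tolerance = 0.01)
})

test_that("stress transient peaks in the first 10-min bin", {
  sal <- drug_profile_saline()
  for (b in c("delta", "beta", "gamma1")) {
    g <- drug_gain(sal, b, seq(0, 120, by = 1))
    dev <- abs(log(g))
    expect_equal(which.max(dev), 1)  # maximal at injection
    expect_gt(mean(dev[1:10]), mean(dev[11:20]))
  }
})

test_that("make_study assembles the right recordings deterministically", {
  des <- small_design(1, 1, treatments = c("SAL", "THIP"))
  st <- make_study(des, seed = 4, fs = 200, baseline_duration = 60,
                   pre_duration = 20, post_duration = 40, artifact_rate = 0)
  expect_length(st$baselines, 2)
  expect_length(st$sessions, 4)
  st2 <- make_study(des, seed = 4, fs = 200, baseline_duration = 60,
                    pre_duration = 20, post_duration = 40, artifact_rate = 0)
  expect_identical(st$sessions[[1]]$recording$channels,
                   st2$sessions[[1]]$recording$channels)
  dup <- rbind(des, des[1, ])
  expect_error(make_study(dup, seed = 1, fs = 200, baseline_duration = 60,
                          pre_duration = 20, post_duration = 40),
               "duplicate")
})

test_that("summary-level band study is deterministic and null-exchangeable", {
  des <- small_design(4, 4)
  a <- simulate_band_study(des, seed = 3)
  b <- simulate_band_study(des, seed = 3)
  expect_identical(a, b)
  expect_setequal(unique(as.character(a$band)), band_definitions()$band)
  expect_true(all(a$value > 0))
  # no drug, no genotype scaling: pre and post bins share distribution
  expect_equal(mean(a$value[a$bin_start_min < 0 & a$band == "delta"]),
               mean(a$value[a$bin_start_min >= 0 & a$band == "delta"]),
               tolerance = 0.15)
})

test_that("derived seeds are stable and within integer range", {
  s1 <- derive_seed(42, "m1", "SAL")
  expect_identical(s1, derive_seed(42, "m1", "SAL"))
  expect_false(s1 == derive_seed(42, "m1", "THIP"))
  expect_false(s1 == derive_seed(43, "m1", "SAL"))
  expect_true(s1 >= 0 && s1 < 2^31)
})
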