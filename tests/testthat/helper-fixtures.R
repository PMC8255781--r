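# Shared fixture builders. Everything is generated in code at test time.

make_sine_recording <- function(freq, duration = 40, fs = 200, amplitude = 1,
                                subject = "s1") {
  t <- seq_len(duration * fs) / fs
  structure(list(
    channels = list(eeg_frontal = amplitude * sin(2 * pi * freq * t),
                    eeg_parietal = amplitude * sin(2 * pi * freq * t),
                    emg = rep(0, length(t))),
    fs = fs, t0 = 0,
    meta = list(subject = subject, genotype = "WT", treatment = "none",
                injection_time_s = NA_real_)),
    class = "eeg_recording")
}

# Small study design used across tests: 4 KO + 4 WT subjects.
small_design <- function(n_ko = 4, n_wt = 4,
                         treatments = NULL) {
  subjects <- paste0("m", seq_len(n_ko + n_wt))
  genotype <- rep(c("KO", "WT"), c(n_ko, n_wt))
  if (is.null(treatments)) {
    data.frame(subject = subjects, genotype = genotype)
  } else {
    d <- expand.grid(subject = subjects, treatment = treatments,
                     stringsAsFactors = FALSE)
    d$genotype <- genotype[match(d$subject, subjects)]
    d
  }
}

# Null longitudinal dataset (8+9 units, 4 time levels, exchangeable values)
with_null_dataset <- function(seed) {
  d <- expand.grid(unit = paste0("u", 1:17), time = 1:4)
  d$group <- rep(c("A", "B"), c(8, 9))[match(d$unit, paste0("u", 1:17))]
  set.seed(seed)
  subj <- rnorm(17)
  d$value <- subj[match(d$unit, paste0("u", 1:17))] + rnorm(nrow(d))
  d
}

# The cached default filter bank (design is deterministic; building it
# once keeps the suite fast).
default_bank <- local({
  bank <- NULL
  function() {
    if (is.null(bank)) bank <<- build_filterbank()
    bank
  }
})
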