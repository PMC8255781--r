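# Rank machinery: midranks, relative effects, WTS/ATS vs the independent
# brute-force oracle, Bonferroni, post-hoc comparisons, invariances.

test_that("midranks handle distinct values, ties and degenerate input", {
  expect_equal(midranks(c(3, 1, 2)), c(3, 1, 2))
  expect_equal(midranks(c(1, 1, 2, 2)), c(1.5, 1.5, 3.5, 3.5))
  expect_equal(midranks(rep(7, 5)), rep(3, 5))
  x <- rnorm(30)
  expect_equal(sum(midranks(x)), 30 * 31 / 2)
  expect_error(midranks(numeric(0)), "empty")
  expect_error(midranks(c(1, NA)), "finite")
})

test_that("relative effects match hand-computed values", {
  d <- data.frame(subject = c("a", "b", "c", "d"),
                  group = c("A", "A", "B", "B"), time = 1,
                  value = c(1, 2, 3, 4))
  ld <- long_dataset(d, "F1_LD_F1", groups = "group")
  re <- relative_effects(ld)
  expect_equal(re$p_hat[re$group == "A"], 0.25)
  expect_equal(re$p_hat[re$group == "B"], 0.75)
  # identical distributions -> 0.5 each (midranks across duplicated values)
  d2 <- d
  d2$value <- c(1, 2, 1, 2)
  re2 <- relative_effects(long_dataset(d2, "F1_LD_F1", groups = "group"))
  expect_equal(re2$p_hat, c(0.5, 0.5))
})

test_that("observation-weighted mean relative effect is exactly 0.5", {
  set.seed(31)
  for (i in 1:5) {
    d <- expand.grid(subject = paste0("u", 1:10), time = 1:3)
    d$group <- rep(c("A", "B"), each = 5)[match(d$subject, paste0("u", 1:10))]
    d$value <- rnorm(nrow(d), sd = sample(1:3, 1))
    re <- relative_effects(long_dataset(d, "F1_LD_F1", groups = "group"))
    expect_equal(sum(re$p_hat * re$n) / sum(re$n), 0.5, tolerance = 1e-12)
    expect_true(all(re$p_hat > 0 & re$p_hat < 1))
  }
})

test_that("WTS and ATS match the brute-force matrix oracle on fixtures", {
  # five fixed datasets: F1 complete, F1 with ties, F1 with a missing
  # observation, F2 complete, F2 unbalanced
  set.seed(1234)
  fixtures <- list()
  f1 <- expand.grid(unit = paste0("u", 1:8), time = 1:3)
  f1$A <- rep(c("g1", "g2"), each = 4)[match(f1$unit, paste0("u", 1:8))]
  f1$value <- round(rnorm(nrow(f1)), 2)
  fixtures$f1_complete <- f1
  f1t <- f1; f1t$value <- round(f1t$value * 2) / 2
  fixtures$f1_ties <- f1t
  fixtures$f1_missing <- f1[-c(3, 17), ]
  f2 <- expand.grid(unit = paste0("u", 1:12), time = 1:3)
  i <- as.integer(sub("u", "", f2$unit))
  f2$A <- ifelse(i <= 6, "t1", "t2")
  f2$B <- ifelse(i %% 2 == 0, "wt", "ko")
  f2$value <- round(rnorm(nrow(f2)), 2)
  fixtures$f2_complete <- f2
  f2u <- f2[f2$unit != "u1", ]
  fixtures$f2_unbalanced <- f2u

  for (nm in names(fixtures)) {
    df <- fixtures[[nm]]
    two_way <- "B" %in% names(df)
    groups <- if (two_way) c("A", "B") else "A"
    ld <- long_dataset(df, if (two_way) "F2_LD_F1" else "F1_LD_F1",
                       subject = "unit", groups = groups, time = "time")
    effects <- if (two_way) {
      list(c("A"), c("B"), c("A", "B"), c("time"), c("A", "time"),
           c("A", "B", "time"))
    } else {
      list(c("A"), c("time"), c("A", "time"))
    }
    for (inv in effects) {
      eff <- paste(inv, collapse = ":")
      w <- wald_type_statistic(ld, eff)
      a <- anova_type_statistic(ld, eff)
      ow <- oracle_wts(df, inv)
      oa <- oracle_ats(df, inv)
      expect_equal(w$statistic, ow$statistic, tolerance = 1e-10,
                   info = paste(nm, eff, "WTS"))
      expect_equal(w$df, ow$df, info = paste(nm, eff, "WTS df"))
      expect_equal(a$statistic, oa$statistic, tolerance = 1e-10,
                   info = paste(nm, eff, "ATS"))
      expect_equal(a$df, oa$df, tolerance = 1e-10,
                   info = paste(nm, eff, "ATS df"))
      expect_equal(a$p_raw, oa$p, tolerance = 1e-10,
                   info = paste(nm, eff, "ATS p"))
    }
  }
})

test_that("statistics are invariant under group relabeling and monotone transforms", {
  set.seed(77)
  d <- expand.grid(unit = paste0("u", 1:10), time = 1:4)
  d$group <- rep(c("A", "B"), each = 5)[match(d$unit, paste0("u", 1:10))]
  d$value <- rnorm(nrow(d))
  ld <- long_dataset(d, "F1_LD_F1", subject = "unit", groups = "group")
  w1 <- wald_type_statistic(ld, "group")
  a1 <- anova_type_statistic(ld, "group:time")
  # swap labels
  d2 <- d
  d2$group <- ifelse(d$group == "A", "B", "A")
  ld2 <- long_dataset(d2, "F1_LD_F1", subject = "unit", groups = "group")
  expect_equal(wald_type_statistic(ld2, "group")$statistic, w1$statistic,
               tolerance = 1e-12)
  # strictly monotone transform leaves ranks, hence statistics, unchanged
  d3 <- d
  d3$value <- exp(3 * d$value) - 5
  ld3 <- long_dataset(d3, "F1_LD_F1", subject = "unit", groups = "group")
  expect_equal(wald_type_statistic(ld3, "group")$statistic, w1$statistic,
               tolerance = 1e-12)
  expect_equal(anova_type_statistic(ld3, "group:time")$statistic,
               a1$statistic, tolerance = 1e-12)
})

test_that("WTS null rejection rate is near nominal (liberal band allowed)", {
  rej <- vapply(1:200, function(s) {
    d <- with_null_dataset(s)
    ld <- long_dataset(d, "F1_LD_F1", subject = "unit", groups = "group")
    wald_type_statistic(ld, "group")$p_raw < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.10)
})

test_that("ATS null rejection rate is within the calibrated band", {
  rej <- vapply(1:200, function(s) {
    d <- with_null_dataset(s)
    ld <- long_dataset(d, "F1_LD_F1", subject = "unit", groups = "group")
    anova_type_statistic(ld, "group")$p_raw < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.025)
  expect_lte(mean(rej), 0.085)
})

test_that("missing data is tracked, never silently imputed", {
  d <- expand.grid(unit = paste0("u", 1:8), time = 1:3)
  d$group <- rep(c("A", "B"), each = 4)[match(d$unit, paste0("u", 1:8))]
  set.seed(5)
  d$value <- rnorm(nrow(d))
  ld_full <- long_dataset(d, "F1_LD_F1", subject = "unit", groups = "group")
  # whole-subject deletion changes reported n
  d_sub <- d[d$unit != "u1", ]
  ld_sub <- long_dataset(d_sub, "F1_LD_F1", subject = "unit", groups = "group")
  expect_equal(wald_type_statistic(ld_full, "group")$n, 8)
  expect_equal(wald_type_statistic(ld_sub, "group")$n, 7)
  # single-cell deletion: available-case estimates, result still finite
  d_cell <- d[-2, ]
  ld_cell <- long_dataset(d_cell, "F1_LD_F1", subject = "unit",
                          groups = "group")
  r <- anova_type_statistic(ld_cell, "group:time")
  expect_true(is.finite(r$statistic))
  # an entirely empty cell is dropped and named
  d_empty <- d[!(d$group == "A" & d$time == 2), ]
  ld_empty <- long_dataset(d_empty, "F1_LD_F1", subject = "unit",
                           groups = "group")
  r2 <- wald_type_statistic(ld_empty, "group")
  expect_match(r2$note, "dropped")
  # NA values are dropped and counted, not imputed
  d_na <- d
  d_na$value[4] <- NA
  ld_na <- long_dataset(d_na, "F1_LD_F1", subject = "unit", groups = "group")
  expect_equal(attr(ld_na, "n_missing"), 1)
})

test_that("degenerate designs error informatively", {
  d <- data.frame(unit = c("u1", "u2", "u3"), group = c("A", "A", "B"),
                  time = 1, value = c(1, 2, 3))
  ld <- long_dataset(d, "F1_LD_F1", subject = "unit", groups = "group")
  expect_error(wald_type_statistic(ld, "group"), "fewer than 2")
  expect_error(long_dataset(d, "F1_LD_F1", subject = "unit",
                            groups = c("group", "other")), "1 whole-plot")
  # unit assigned to two groups
  d2 <- data.frame(unit = c("u1", "u1", "u2", "u2"),
                   group = c("A", "B", "B", "B"), time = c(1, 1, 1, 2),
                   value = 1:4)
  expect_error(long_dataset(d2, "F1_LD_F1", subject = "unit",
                            groups = "group"), "more than one")
})

test_that("single time level reduces to the one-time group test", {
  set.seed(8)
  d <- data.frame(unit = paste0("u", 1:10),
                  group = rep(c("A", "B"), each = 5), time = 1,
                  value = rnorm(10))
  ld <- long_dataset(d, "F1_LD_F1", subject = "unit", groups = "group")
  ft <- fit_design(ld)
  expect_setequal(unique(ft$effect), "group")
  expect_equal(ft$statistic[ft$statistic_type == "WTS"],
               wald_type_statistic(ld, "group")$statistic)
})

test_that("fit_design enumerates the factorial effects", {
  set.seed(9)
  d <- expand.grid(unit = paste0("u", 1:12), time = 1:2)
  i <- as.integer(sub("u", "", d$unit))
  d$treatment <- ifelse(i <= 6, "SAL", "THIP")
  d$genotype <- ifelse(i %% 2 == 0, "WT", "KO")
  d$value <- rnorm(nrow(d))
  ld <- long_dataset(d, "F2_LD_F1", subject = "unit",
                     groups = c("treatment", "genotype"))
  ft <- fit_design(ld)
  expect_setequal(unique(ft$effect),
                  c("treatment", "genotype", "treatment:genotype", "time",
                    "treatment:time", "genotype:time",
                    "treatment:genotype:time"))
  expect_setequal(unique(ft$statistic_type), c("WTS", "ATS"))
  expect_true(all(is.finite(ft$p_raw)))
})

test_that("bonferroni correction multiplies, caps at 1 and preserves order", {
  expect_equal(bonferroni(0.01, 7), 0.07)
  expect_equal(bonferroni(0.3, 7), 1.0)
  expect_equal(bonferroni(0, 100), 0)
  p <- c(0.001, 0.01, 0.2, 0.9)
  pc <- bonferroni(p, 5)
  expect_true(all(pc >= p))
  expect_false(is.unsorted(pc))
  expect_error(bonferroni(1.2, 3), "\\[0, 1\\]")
  expect_error(bonferroni(0.5, 0), "m")
})

test_that("per-bin post-hocs correct within the tested family", {
  set.seed(12)
  d <- expand.grid(subject = paste0("u", 1:17), bin_start_min = seq(0, 110, 10))
  d$genotype <- rep(c("KO", "WT"), c(8, 9))[match(d$subject, paste0("u", 1:17))]
  d$value <- rnorm(nrow(d))
  # inject a huge difference confined to bins 30-50
  shift <- d$bin_start_min %in% c(30, 40, 50) & d$genotype == "KO"
  d$value[shift] <- d$value[shift] + 10
  ph <- posthoc_timepoints(d)
  expect_equal(nrow(ph), 12)
  expect_equal(ph$p_corrected, pmin(1, ph$p_raw * 12))
  sig <- ph$time[ph$p_corrected < 0.05]
  expect_true(all(c(30, 40, 50) %in% sig))
  expect_lte(length(setdiff(sig, c(30, 40, 50))), 1)
  # tier mapping
  expect_equal(significance_tier(c(0.2, 0.01, 5e-4, 5e-5)),
               c("", "*", "**", "***"))
})
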