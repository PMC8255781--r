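# Rank-based nonparametric tests for longitudinal factorial designs:
# relative treatment effects, Wald-type (WTS) and ANOVA-type (ATS)
# statistics for one or two whole-plot factors crossed with a repeated
# time factor (the F1-LD-F1 and F2-LD-F1 layouts). Observations are ranked
# globally with midranks; subjects (or subject-sessions) are the
# independent units; missing cells are handled by available-case
# estimation, never silently imputed.

#' Midranks
#'
#' Ranks with tied values receiving the mean of the rank positions they
#' cover, so ranks always sum to N(N+1)/2.
#'
#' @param x Numeric vector of finite values.
#' @return Numeric vector of midranks.
#' @export
midranks <- function(x) {
  if (length(x) == 0) stopf("empty input to midranks")
  if (any(!is.finite(x))) stopf("midranks requires finite values")
  rank(x, ties.method = "average")
}

#' Assemble a longitudinal dataset for rank-based testing
#'
#' @param df data.frame in long format.
#' @param design_type `"F1_LD_F1"` (one whole-plot factor x time) or
#'   `"F2_LD_F1"` (two whole-plot factors x time).
#' @param subject Column naming the independent unit (for crossover studies
#'   analyzed with F2-LD-F1, a subject-session identifier).
#' @param value,time Value and time-level columns.
#' @param groups Character vector of one (F1) or two (F2) whole-plot factor
#'   columns.
#' @return A `long_dataset` data.frame with standardized columns and the
#'   design metadata in attributes. Rows with missing values are dropped
#'   but counted (attribute `n_missing`).
#' @export
long_dataset <- function(df, design_type = c("F1_LD_F1", "F2_LD_F1"),
                         subject = "subject", value = "value",
                         time = "time", groups = "group") {
  design_type <- match.arg(design_type)
  n_groups <- if (design_type == "F1_LD_F1") 1L else 2L
  if (length(groups) != n_groups) {
    stopf("%s requires %d whole-plot factor(s), got %d",
          design_type, n_groups, length(groups))
  }
  missing_cols <- setdiff(c(subject, value, time, groups), names(df))
  if (length(missing_cols)) {
    stopf("missing factor/column(s): %s", paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(unit = as.character(df[[subject]]),
                    value = as.numeric(df[[value]]))
  out$time <- factor(df[[time]], levels = sort(unique(df[[time]])))
  out$A <- factor(as.character(df[[groups[1]]]))
  if (n_groups == 2L) out$B <- factor(as.character(df[[groups[2]]]))
  drop <- !is.finite(out$value)
  n_missing <- sum(drop)
  out <- out[!drop, , drop = FALSE]
  if (!nrow(out)) stopf("no finite observations")
  grp_cols <- c("A", if (n_groups == 2L) "B")
  per_unit <- unique(out[, c("unit", grp_cols), drop = FALSE])
  if (anyDuplicated(per_unit$unit)) {
    stopf("unit(s) with more than one whole-plot assignment: %s",
          paste(unique(per_unit$unit[duplicated(per_unit$unit)]),
                collapse = ", "))
  }
  structure(out, design_type = design_type, n_missing = n_missing,
            factor_labels = c(groups, "time"),
            class = c("long_dataset", "data.frame"))
}

# Shared rank machinery: global midranks, per-cell relative effects, and
# the available-case covariance of the cell mean-rank vector.
rank_core <- function(data) {
  stopifnot(inherits(data, "long_dataset"))
  two_way <- attr(data, "design_type") == "F2_LD_F1"
  a_lev <- levels(data$A)
  b_lev <- if (two_way) levels(data$B) else "."
  t_lev <- levels(data$time)
  na <- length(a_lev); nb <- length(b_lev); nt <- length(t_lev)
  n_cells <- na * nb * nt

  N <- nrow(data)
  r <- midranks(data$value) / N
  ai <- as.integer(data$A)
  bi <- if (two_way) as.integer(data$B) else rep(1L, N)
  ti <- as.integer(data$time)
  cell <- ((ai - 1L) * nb + (bi - 1L)) * nt + ti  # time varies fastest

  units <- unique(data$unit)
  U <- matrix(NA_real_, length(units), n_cells,
              dimnames = list(units, NULL))
  for (i in seq_len(N)) {
    u <- data$unit[i]
    U[u, cell[i]] <- if (is.na(U[u, cell[i]])) r[i] else
      (U[u, cell[i]] + r[i]) / 2  # average replicate obs within a cell
  }

  obs_n <- colSums(!is.na(U))
  p_hat <- vapply(seq_len(n_cells), function(s) {
    sel <- cell == s
    if (!any(sel)) return(NA_real_)
    mean(r[sel]) - 0.5 / N
  }, numeric(1))

  # group combo of each unit
  unit_combo <- integer(length(units))
  for (k in seq_along(units)) {
    row <- which(data$unit == units[k])[1]
    unit_combo[k] <- (ai[row] - 1L) * nb + bi[row]
  }

  Sigma <- matrix(0, n_cells, n_cells)
  for (g in seq_len(na * nb)) {
    cells_g <- ((g - 1L) * nt + 1L):(g * nt)
    rows_g <- which(unit_combo == g)
    if (!length(rows_g)) next
    Ug <- U[rows_g, cells_g, drop = FALSE]
    has_any <- colSums(!is.na(Ug)) > 0
    if (length(rows_g) < 2 && any(has_any)) {
      combo_lab <- paste(a_lev[(g - 1L) %/% nb + 1L],
                         if (two_way) b_lev[(g - 1L) %% nb + 1L])
      stopf("covariance not estimable: fewer than 2 units in group %s",
            trimws(combo_lab))
    }
    S <- suppressWarnings(stats::cov(Ug, use = "pairwise.complete.obs"))
    S[!is.finite(S)] <- 0
    npair <- crossprod(!is.na(Ug))
    ns <- colSums(!is.na(Ug))
    denom <- outer(ns, ns)
    scale <- ifelse(denom > 0, npair / denom, 0)
    B <- S * scale
    # pairwise-complete covariance need not be PSD; project onto the PSD
    # cone (no-op for complete data) so trace normalizations stay valid
    eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
    if (any(eg$values < 0)) {
      B <- eg$vectors %*% (pmax(eg$values, 0) * t(eg$vectors))
    }
    Sigma[cells_g, cells_g] <- B
  }

  cell_grid <- expand.grid(time = t_lev, B = b_lev, A = a_lev,
                           stringsAsFactors = FALSE)[, c("A", "B", "time")]
  combo_cells <- lapply(seq_len(na * nb), function(g) {
    ((g - 1L) * nt + 1L):(g * nt)
  })
  combo_n <- vapply(seq_len(na * nb), function(g) {
    sum(unit_combo == g)
  }, integer(1))
  list(p_hat = p_hat, Sigma = Sigma, N = N, n_units = length(units),
       dims = c(A = na, B = nb, time = nt), two_way = two_way,
       cell_grid = cell_grid, obs_n = obs_n,
       combo_cells = combo_cells, combo_n = combo_n,
       factor_labels = attr(data, "factor_labels"))
}

#' Relative treatment effects
#'
#' The rank-based effect-size estimand per design cell:
#' `p_hat = (mean midrank - 0.5) / N`, a probability-scale quantity in
#' (0, 1) whose observation-weighted mean over all cells is 0.5.
#'
#' @param data A [long_dataset()].
#' @return data.frame with the whole-plot factor(s), `time`, `p_hat` and
#'   `n` (observations per cell; empty cells give `NA` with a warning).
#' @export
relative_effects <- function(data) {
  core <- rank_core(data)
  out <- core$cell_grid
  labs <- core$factor_labels
  names(out)[1] <- labs[1]
  if (core$two_way) names(out)[2] <- labs[2] else out$B <- NULL
  out$p_hat <- core$p_hat
  out$n <- core$obs_n
  if (any(is.na(out$p_hat))) {
    warnf("%d empty cell(s): relative effects reported as missing",
          sum(is.na(out$p_hat)))
  }
  out
}

centering_mat <- function(k) diag(k) - matrix(1 / k, k, k)
mean_row <- function(k) matrix(1 / k, 1, k)

# Kronecker contrast for an effect named by its involved factors, e.g.
# "treatment:time". Factors absent from the effect are averaged out.
build_contrast <- function(core, effect) {
  labs <- core$factor_labels  # (A[, B], time) labels
  involved <- strsplit(effect, ":", fixed = TRUE)[[1]]
  internal <- c("A", if (core$two_way) "B", "time")
  lab_map <- stats::setNames(internal, labs)
  unknown <- setdiff(involved, labs)
  if (length(unknown)) stopf("unknown factor(s): %s", paste(unknown, collapse = ", "))
  inv_internal <- unname(lab_map[involved])
  dims <- core$dims[c("A", if (core$two_way) "B", "time")]
  mats <- lapply(names(dims), function(f) {
    if (f %in% inv_internal) centering_mat(dims[[f]]) else mean_row(dims[[f]])
  })
  Reduce(kronecker, mats)
}

rank_test <- function(data, effect, type = c("ats", "wts")) {
  type <- match.arg(type)
  core <- rank_core(data)
  C <- build_contrast(core, effect)
  obs <- which(!is.na(core$p_hat))
  dropped <- setdiff(seq_along(core$p_hat), obs)
  note <- NA_character_
  if (length(dropped)) {
    cg <- core$cell_grid[dropped, , drop = FALSE]
    note <- paste("empty cells dropped:",
                  paste(apply(cg, 1, paste, collapse = "/"), collapse = ", "))
    C <- C[, obs, drop = FALSE]
  }
  p <- core$p_hat[obs]
  S <- core$Sigma[obs, obs, drop = FALSE]
  df0 <- NA_real_
  if (type == "wts") {
    CS <- C %*% S %*% t(C)
    df <- mat_rank(CS)
    if (df == 0) stopf("degenerate contrast for effect '%s'", effect)
    stat <- drop(t(C %*% p) %*% pinv(CS) %*% (C %*% p))
    pval <- stats::pchisq(stat, df, lower.tail = FALSE)
  } else {
    Tm <- t(C) %*% pinv(C %*% t(C)) %*% C
    TS <- Tm %*% S
    tr1 <- sum(diag(TS))
    if (tr1 <= 0) stopf("degenerate covariance for effect '%s'", effect)
    stat <- drop(t(p) %*% Tm %*% p) / tr1
    df <- tr1^2 / sum(diag(TS %*% TS))
    # Purely whole-plot effects get a Box/Satterthwaite denominator df
    # (an F reference), the standard small-sample calibration for
    # between-subject contrasts; effects involving the repeated time
    # factor use the chi-square_f / f reference.
    time_lab <- core$factor_labels[length(core$factor_labels)]
    whole_plot <- !time_lab %in% strsplit(effect, ":", fixed = TRUE)[[1]]
    if (whole_plot) {
      denom <- 0
      for (g in seq_along(core$combo_cells)) {
        cg <- match(intersect(core$combo_cells[[g]], obs), obs)
        if (!length(cg) || core$combo_n[g] < 2) next
        c_g <- sum(diag(Tm[cg, cg, drop = FALSE] %*%
                        S[cg, cg, drop = FALSE]))
        denom <- denom + c_g^2 / (core$combo_n[g] - 1)
      }
      df0 <- if (denom > 0) tr1^2 / denom else Inf
      pval <- stats::pf(stat, df, df0, lower.tail = FALSE)
    } else {
      df0 <- Inf
      pval <- stats::pchisq(df * stat, df, lower.tail = FALSE)
    }
  }
  data.frame(effect = effect, statistic_type = toupper(type),
             statistic = stat, df = df, df0 = df0, p_raw = pval,
             p_corrected = NA_real_, n = core$n_units, note = note)
}

#' Wald-type statistic for a rank-based longitudinal design
#'
#' Quadratic form of the contrasted relative effects against the empirical
#' covariance of subject-level rank vectors, referred to a chi-square
#' distribution with the contrast rank as degrees of freedom.
#'
#' @param data A [long_dataset()].
#' @param effect Effect label built from the design's factor names joined
#'   by `:`, e.g. `"genotype"`, `"time"`, `"treatment:genotype"`.
#' @return One-row data.frame: `effect`, `statistic_type`, `statistic`,
#'   `df`, `p_raw`, `p_corrected` (`NA` until a family is applied), `n`,
#'   `note`.
#' @export
wald_type_statistic <- function(data, effect) rank_test(data, effect, "wts")

#' ANOVA-type statistic for a rank-based longitudinal design
#'
#' The trace-normalized quadratic form with Box-type approximation for the
#' numerator degrees of freedom. Effects involving the repeated time factor
#' are referred to the scaled chi-square (chi-square_f / f) distribution;
#' purely whole-plot effects additionally get a Satterthwaite denominator
#' df and an F(f, f0) reference, the standard small-sample calibration for
#' between-subject contrasts. Better calibrated than the Wald-type
#' statistic at small group sizes.
#'
#' @inheritParams wald_type_statistic
#' @return One-row data.frame as in [wald_type_statistic()]; `df` is the
#'   Box-approximated (real-valued) numerator df and `df0` the denominator
#'   df (`Inf` for effects involving time, `NA` for WTS rows).
#' @export
anova_type_statistic <- function(data, effect) rank_test(data, effect, "ats")

#' Fit all main effects and interactions of a longitudinal design
#'
#' F1-LD-F1 yields group, time and group:time; F2-LD-F1 yields both
#' whole-plot mains, their interaction, time, and all time interactions.
#' Each effect is computed as both WTS and ATS. With a single time level
#' the time effects are absent and the group tests reduce to the one-time
#' statistics.
#'
#' @param data A [long_dataset()].
#' @return data.frame of test results, one row per effect x statistic.
#' @export
fit_design <- function(data) {
  labs <- attr(data, "factor_labels")
  two_way <- attr(data, "design_type") == "F2_LD_F1"
  g <- labs[-length(labs)]
  has_time <- nlevels(data$time) > 1
  effects <- if (!two_way) {
    c(g[1], if (has_time) c("time", paste0(g[1], ":time")))
  } else {
    c(g[1], g[2], paste0(g[1], ":", g[2]),
      if (has_time) c("time", paste0(g[1], ":time"), paste0(g[2], ":time"),
                      paste0(g[1], ":", g[2], ":time")))
  }
  rows <- lapply(effects, function(e) {
    rbind(wald_type_statistic(data, e), anova_type_statistic(data, e))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bonferroni correction
#'
#' `p_c = min(1, m * p)`: order-preserving, never decreasing, capped at 1.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param m Family size (>= 1).
#' @return Corrected p-values.
#' @export
bonferroni <- function(p, m) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  if (m < 1) stopf("family size m must be >= 1")
  pmin(1, m * p)
}

#' Per-time-bin two-group rank comparisons with Bonferroni correction
#'
#' For each time level, the two groups are compared with a rank-sum test
#' (normal approximation, midranks for ties); p-values are Bonferroni-
#' corrected with family size equal to the number of time bins actually
#' tested, and assigned the three-tier severity convention
#' (`*` p < 0.05, `**` p < 0.001, `***` p < 0.0001).
#'
#' @param df data.frame with the comparison data.
#' @param group Column with exactly two group levels.
#' @param time,value Time-bin and value columns.
#' @param min_n Minimum group size per bin; smaller bins are skipped with a
#'   warning.
#' @return data.frame: `time`, `n1`, `n2`, `statistic` (rank-sum W),
#'   `p_raw`, `p_corrected`, `tier`.
#' @export
posthoc_timepoints <- function(df, group = "genotype", time = "bin_start_min",
                               value = "value", min_n = 2L) {
  g <- factor(as.character(df[[group]]))
  if (nlevels(g) != 2) stopf("posthoc_timepoints requires exactly 2 groups")
  tl <- sort(unique(df[[time]]))
  rows <- lapply(tl, function(tb) {
    sel <- df[[time]] == tb & is.finite(df[[value]])
    x <- df[[value]][sel & g == levels(g)[1]]
    y <- df[[value]][sel & g == levels(g)[2]]
    if (length(x) < min_n || length(y) < min_n) {
      warnf("time bin %s skipped: fewer than %d observations per group",
            format(tb), min_n)
      return(NULL)
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    data.frame(time = tb, n1 = length(x), n2 = length(y),
               statistic = unname(wt$statistic), p_raw = wt$p.value)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) {
    return(data.frame(time = numeric(0), n1 = integer(0), n2 = integer(0),
                      statistic = numeric(0), p_raw = numeric(0),
                      p_corrected = numeric(0), tier = character(0)))
  }
  out$p_corrected <- bonferroni(out$p_raw, nrow(out))
  out$tier <- significance_tier(out$p_corrected)
  rownames(out) <- NULL
  out
}

#' Three-tier significance labels
#'
#' @param p Corrected p-values.
#' @param thresholds Severity cutoffs, most severe last.
#' @return Character vector: `""` (not significant), `"*"` (p < 0.05),
#'   `"**"` (p < 0.001), `"***"` (p < 0.0001).
#' @export
significance_tier <- function(p, thresholds = c(0.05, 0.001, 0.0001)) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    strrep("*", sum(pi < thresholds))
  }, character(1))
}
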