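# Independent brute-force oracle for the rank-based longitudinal tests.
# Deliberately naive: explicit loops, no shared code with the package
# internals, MASS::ginv for generalized inverses. Operates on a long
# data.frame with columns unit, A (and optionally B), time, value.

oracle_midranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

# Per-cell relative effects and covariance of the cell mean rank vector,
# assembled observation by observation.
oracle_core <- function(df) {
  two_way <- "B" %in% names(df)
  a_lev <- sort(unique(as.character(df$A)))
  b_lev <- if (two_way) sort(unique(as.character(df$B))) else "."
  t_lev <- sort(unique(df$time))
  cells <- expand.grid(time = t_lev, B = b_lev, A = a_lev,
                       stringsAsFactors = FALSE)[, c("A", "B", "time")]
  n_cells <- nrow(cells)
  N <- nrow(df)
  r <- oracle_midranks(df$value)

  cell_of <- function(i) {
    ok <- cells$A == as.character(df$A[i]) & cells$time == df$time[i]
    if (two_way) ok <- ok & cells$B == as.character(df$B[i])
    which(ok)
  }
  p_hat <- rep(NA_real_, n_cells)
  for (s in seq_len(n_cells)) {
    sel <- vapply(seq_len(N), function(i) cell_of(i) == s, logical(1))
    if (any(sel)) p_hat[s] <- (mean(r[sel]) - 0.5) / N
  }

  units <- unique(df$unit)
  U <- matrix(NA_real_, length(units), n_cells)
  for (i in seq_len(N)) {
    k <- which(units == df$unit[i])
    s <- cell_of(i)
    U[k, s] <- if (is.na(U[k, s])) r[i] / N else (U[k, s] + r[i] / N) / 2
  }
  combo <- character(length(units))
  for (k in seq_along(units)) {
    i <- which(df$unit == units[k])[1]
    combo[k] <- paste(df$A[i], if (two_way) df$B[i] else ".")
  }
  Sigma <- matrix(0, n_cells, n_cells)
  for (g in unique(combo)) {
    rows <- which(combo == g)
    cellsel <- which(paste(cells$A, cells$B) == g)
    Bg <- matrix(0, length(cellsel), length(cellsel))
    for (s in cellsel) for (s2 in cellsel) {
      ok <- rows[!is.na(U[rows, s]) & !is.na(U[rows, s2])]
      if (length(ok) < 2) next
      # means over the pairwise-complete units (the standard pairwise
      # covariance definition)
      mus <- mean(U[ok, s])
      mus2 <- mean(U[ok, s2])
      covv <- sum((U[ok, s] - mus) * (U[ok, s2] - mus2)) / (length(ok) - 1)
      ns <- sum(!is.na(U[rows, s])); ns2 <- sum(!is.na(U[rows, s2]))
      Bg[match(s, cellsel), match(s2, cellsel)] <- covv * length(ok) / (ns * ns2)
    }
    # PSD projection of the block, mirroring the estimator's definition
    eg <- eigen((Bg + t(Bg)) / 2, symmetric = TRUE)
    Bg <- eg$vectors %*% diag(pmax(eg$values, 0), nrow(Bg)) %*% t(eg$vectors)
    Sigma[cellsel, cellsel] <- Bg
  }
  list(p_hat = p_hat, Sigma = Sigma, cells = cells, two_way = two_way,
       a_lev = a_lev, b_lev = b_lev, t_lev = t_lev)
}

# Projection-style hypothesis matrix assembled entry by entry.
oracle_tmat <- function(core, involved) {
  cells <- core$cells
  n_cells <- nrow(cells)
  Tm <- matrix(0, n_cells, n_cells)
  fac_term <- function(fac, lev, li, lj) {
    k <- length(lev)
    if (fac %in% involved) (li == lj) - 1 / k else 1 / k
  }
  for (i in seq_len(n_cells)) for (j in seq_len(n_cells)) {
    v <- fac_term("A", core$a_lev, cells$A[i], cells$A[j]) *
      fac_term("time", core$t_lev, cells$time[i], cells$time[j])
    if (core$two_way) {
      v <- v * fac_term("B", core$b_lev, cells$B[i], cells$B[j])
    }
    Tm[i, j] <- v
  }
  Tm
}

oracle_wts <- function(df, involved) {
  core <- oracle_core(df)
  Tm <- oracle_tmat(core, involved)
  obs <- which(!is.na(core$p_hat))
  Tm <- Tm[, obs, drop = FALSE]
  Tm <- Tm[rowSums(abs(Tm)) > 1e-14, , drop = FALSE]
  p <- core$p_hat[obs]
  S <- core$Sigma[obs, obs]
  mid <- MASS::ginv(Tm %*% S %*% t(Tm))
  stat <- drop(t(Tm %*% p) %*% mid %*% (Tm %*% p))
  df_ <- qr(Tm %*% S %*% t(Tm), tol = 1e-9)$rank
  list(statistic = stat, df = df_,
       p = pchisq(stat, df_, lower.tail = FALSE))
}

oracle_ats <- function(df, involved) {
  core <- oracle_core(df)
  Tm0 <- oracle_tmat(core, involved)
  obs <- which(!is.na(core$p_hat))
  C <- Tm0[rowSums(abs(Tm0)) > 1e-14, obs, drop = FALSE]
  Tm <- t(C) %*% MASS::ginv(C %*% t(C)) %*% C
  p <- core$p_hat[obs]
  S <- core$Sigma[obs, obs]
  tr1 <- sum(diag(Tm %*% S))
  stat <- drop(t(p) %*% Tm %*% p) / tr1
  f <- tr1^2 / sum(diag(Tm %*% S %*% Tm %*% S))
  if (!"time" %in% involved) {
    # Satterthwaite denominator df over group combos, by explicit loops
    cells <- core$cells[obs, , drop = FALSE]
    combos <- unique(paste(cells$A, cells$B))
    denom <- 0
    for (g in combos) {
      sel <- which(paste(cells$A, cells$B) == g)
      n_g <- length(unique(df$unit[paste(df$A,
        if (core$two_way) df$B else ".") == g]))
      if (n_g < 2) next
      c_g <- sum(diag(Tm[sel, sel, drop = FALSE] %*% S[sel, sel, drop = FALSE]))
      denom <- denom + c_g^2 / (n_g - 1)
    }
    f0 <- if (denom > 0) tr1^2 / denom else Inf
    list(statistic = stat, df = f, df0 = f0,
         p = pf(stat, f, f0, lower.tail = FALSE))
  } else {
    list(statistic = stat, df = f, df0 = Inf,
         p = pchisq(f * stat, f, lower.tail = FALSE))
  }
}
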