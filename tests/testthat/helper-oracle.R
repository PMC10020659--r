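# Straight-line brute-force TOPSIS oracle, written independently of the
# package implementation: explicit loops only, no shared code. Used to
# cross-check every stage of run_topsis on small matrices.

oracle_interval <- function(x, lo, hi) {
  mn <- x[1]; mx <- x[1]
  for (v in x) {
    if (v < mn) mn <- v
    if (v > mx) mx <- v
  }
  M <- lo - mn
  if (mx - hi > M) M <- mx - hi
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    v <- x[i]
    if (v >= lo && v <= hi) {
      out[i] <- 1
    } else if (v < lo) {
      out[i] <- 1 - (lo - v) / M
    } else {
      out[i] <- 1 - (v - hi) / M
    }
  }
  out
}

oracle_topsis <- function(values, directions, weights,
                          interval_low = NULL, interval_high = NULL) {
  n <- nrow(values)
  m <- ncol(values)
  v <- values
  dir <- directions
  for (j in seq_len(m)) {
    if (dir[j] == "interval") {
      v[, j] <- oracle_interval(v[, j], interval_low[j], interval_high[j])
      dir[j] <- "benefit"
    }
  }
  r <- matrix(0, n, m)
  for (j in seq_len(m)) {
    s <- 0
    for (i in seq_len(n)) s <- s + v[i, j]^2
    for (i in seq_len(n)) r[i, j] <- v[i, j] / sqrt(s)
  }
  wsum <- 0
  for (j in seq_len(m)) wsum <- wsum + weights[j]
  w <- numeric(m)
  for (j in seq_len(m)) w[j] <- weights[j] / wsum
  for (j in seq_len(m)) for (i in seq_len(n)) r[i, j] <- r[i, j] * w[j]
  pos <- numeric(m); neg <- numeric(m)
  for (j in seq_len(m)) {
    cmax <- r[1, j]; cmin <- r[1, j]
    for (i in seq_len(n)) {
      if (r[i, j] > cmax) cmax <- r[i, j]
      if (r[i, j] < cmin) cmin <- r[i, j]
    }
    if (dir[j] == "cost") {
      pos[j] <- cmin; neg[j] <- cmax
    } else {
      pos[j] <- cmax; neg[j] <- cmin
    }
  }
  d_plus <- numeric(n); d_minus <- numeric(n); ci <- numeric(n)
  for (i in seq_len(n)) {
    sp <- 0; sn <- 0
    for (j in seq_len(m)) {
      sp <- sp + (r[i, j] - pos[j])^2
      sn <- sn + (r[i, j] - neg[j])^2
    }
    d_plus[i] <- sqrt(sp)
    d_minus[i] <- sqrt(sn)
    ci[i] <- d_minus[i] / (d_plus[i] + d_minus[i])
  }
  rk <- integer(n)
  for (i in seq_len(n)) {
    better <- 0L
    for (j in seq_len(n)) {
      if (ci[j] > ci[i]) better <- better + 1L
      if (j < i && ci[j] == ci[i]) better <- better + 1L
    }
    rk[i] <- better + 1L
  }
  list(d_plus = d_plus, d_minus = d_minus, closeness = ci, rank = rk)
}

# Random decision-matrix case for the oracle comparison: up to 5 treatments
# and 5 indicators, mixed directions, positive values, random weights.
random_topsis_case <- function(seed) {
  set.seed(seed)
  n <- sample(2:5, 1)
  m <- sample(1:5, 1)
  values <- matrix(runif(n * m, 0.5, 10), n, m)
  directions <- sample(c("benefit", "cost", "interval"), m, replace = TRUE)
  lo <- rep(NA_real_, m)
  hi <- rep(NA_real_, m)
  for (j in which(directions == "interval")) {
    # bounds placed so at least some values fall outside the optimum range
    lo[j] <- runif(1, 2, 6)
    hi[j] <- lo[j] + runif(1, 0, 2)
  }
  weights <- runif(m, 0.1, 1)
  list(values = values, directions = directions, weights = weights,
       interval_low = lo, interval_high = hi)
}

case_to_dm <- function(case) {
  ind <- indicator_set(paste0("ind", seq_along(case$directions)),
                       case$directions, case$weights,
                       case$interval_low, case$interval_high)
  decision_matrix(case$values, ind)
}
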