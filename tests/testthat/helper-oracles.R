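# Independent oracles and fixture builders, kept deliberately separate from
# the package's own code paths.

# Closed-form expected proportion asleep, re-derived from the generative
# model description: mesor + damped cosine with (for LL) a period that
# lengthens by drift h per elapsed day, clipped to [0, 1].
oracle_prop_asleep <- function(hours, condition, baseline, amplitude0,
                               decay, phase0, tau, drift = 0) {
  tau_t <- if (condition == "LL") tau + drift * hours / 24 else tau
  A <- if (condition == "LD") amplitude0 else amplitude0 * (1 - decay)^(hours / 24)
  p <- baseline + A * cos(2 * pi * (hours - phase0) / tau_t)
  pmin(pmax(p, 0), 1)
}

# Dense brute-force period scan: closed-form least squares via the normal
# equations at each candidate period, picking the best-fitting period.
oracle_period_scan <- function(hours, y, grid = seq(20, 28, by = 0.01)) {
  rss <- vapply(grid, function(P) {
    X <- cbind(1, sin(2 * pi * hours / P), cos(2 * pi * hours / P))
    b <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% b)^2)
  }, numeric(1))
  grid[which.min(rss)]
}

# Exact two-sided rank-sum p by bitmask enumeration over group labelings
# (independent of the package's combn-based path).
oracle_wilcoxon_exact <- function(a, b) {
  n1 <- length(a); N <- n1 + length(b)
  r <- rank(c(a, b))
  mu <- n1 * (N + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  hits <- 0L; total <- 0L
  for (mask in 0:(2^N - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(N - 1))) > 0)
    if (length(idx) != n1) next
    total <- total + 1L
    if (abs(sum(r[idx]) - mu) >= obs - 1e-9) hits <- hits + 1L
  }
  hits / total
}

# Build a minimal valid observation frame from per-cage vectors.
make_cage <- function(cage_id, condition, replicate_index, hours, n_alive,
                      n_sleeping, contacts = 0L, lower = 0L) {
  data.frame(cage_id = cage_id, condition = condition,
             replicate_index = replicate_index, hour = hours,
             n_alive = n_alive, n_sleeping = n_sleeping,
             n_disturbance_contacts = contacts, n_sleeping_lower = lower,
             stringsAsFactors = FALSE)
}

# A sleep_series object from raw vectors, bypassing ingestion.
make_series <- function(hours, pct, condition = "LL", replicate_index = 1L,
                        cage_id = paste0(condition, "_", replicate_index)) {
  s <- list(cage_id = cage_id, condition = condition,
            replicate_index = as.integer(replicate_index), hours = hours,
            percent_asleep = pct, percent_alive = rep(100, length(hours)),
            extinct = FALSE)
  class(s) <- "sleep_series"
  s
}

# Survival fixture: cages whose % alive at t_end are the given values
# (per-mille resolution via n_alive(0) = 1000).
make_survival_records <- function(pct_by_condition, t_end = 2) {
  rows <- list()
  for (cc in names(pct_by_condition)) {
    for (i in seq_along(pct_by_condition[[cc]])) {
      final <- round(10 * pct_by_condition[[cc]][i])
      rows[[paste0(cc, i)]] <- make_cage(
        paste0(cc, "_", i), cc, i, hours = 0:(t_end - 1),
        n_alive = c(1000L, rep(final, t_end - 1)),
        n_sleeping = 0L)
    }
  }
  do.call(rbind, rows)
}

null_sim_config <- function(seed) {
  # all arms generatively identical: condition-specific effects switched off
  sim_config(tau_ll = 24, tau_dd = 24, tau_ld = 24, drift_ll = 0,
             amplitude_decay = 0, p_lower_ll = 0.5,
             disturb_rate_ll_late = 0.31, seed = seed)
}
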