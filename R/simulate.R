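#' Simulation configuration for a caged bee sleep experiment
#'
#' Builds and validates the full set of generative parameters for the synthetic
#' experiment generator. Defaults reproduce the study conditions: 3 cages per
#' lighting condition, 23 bees per cage, 120 hourly observations, an entrained
#' 24 h period under the light:dark (LD) control, a free-running 24 h period in
#' constant dark (DD), and a lengthening free-running period in constant light
#' (LL) that drifts by `drift_ll` hours per elapsed day.
#'
#' The expected proportion asleep at hour `t` is
#' \deqn{p(t) = baseline + A(t) \cos(2\pi (t - phase_0)/\tau_{eff}(t)),}
#' clipped to \[0, 1\], where \eqn{\tau_{eff}(t) = \tau + drift_{ll} \cdot t/24}
#' under LL (constant \eqn{\tau} otherwise) and the amplitude
#' \eqn{A(t) = A_0 (1 - decay)^{t/24}} damps in the two constant conditions
#' (free-running rhythms weaken without a zeitgeber) but not under LD.
#'
#' @param n_cages_per_condition Cages (replicates) per lighting condition.
#' @param n_bees Bees per cage at hour 0.
#' @param duration Experiment length in hours; observations at hours
#'   `0, ..., duration - 1`.
#' @param tau_ld,tau_dd,tau_ll Circadian period (h) in each condition.
#' @param drift_ll Period lengthening per elapsed day under constant light
#'   (h/day); applied only to LL.
#' @param amplitude0 Peak-to-midline amplitude of the proportion-asleep
#'   oscillation, in \[0, 0.5\].
#' @param baseline Mesor (rhythm-adjusted mean) proportion asleep, in \[0, 1\].
#' @param amplitude_decay Fractional amplitude loss per day under LL and DD,
#'   in \[0, 1).
#' @param phase0 Acrophase (hour of maximal sleep) at experiment onset.
#' @param mortality_hazard Per-bee per-hour death probability, in \[0, 1).
#' @param disturb_rate_base Expected disturbance contacts per sleeping bee per
#'   scored 5-minute window.
#' @param disturb_rate_ll_late Elevated contact rate under LL from `onset_hour`
#'   onward.
#' @param onset_hour Hour at which the elevated LL contact rate begins.
#' @param p_lower_ld_dark Probability a sleeping bee occupies the lower cage
#'   half under LD or DD (no light gradient to avoid).
#' @param p_lower_ll Same probability under LL (light avoidance).
#' @param seed Master integer seed; cage-level sub-seeds are derived from it
#'   (see [simulate_experiment()]).
#'
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$tau_ll
#' @export
sim_config <- function(n_cages_per_condition = 3,
                       n_bees = 23,
                       duration = 120,
                       tau_ld = 24.0,
                       tau_dd = 24.0,
                       tau_ll = 24.5,
                       drift_ll = 0.25,
                       amplitude0 = 0.25,
                       baseline = 0.35,
                       amplitude_decay = 0.10,
                       phase0 = 18,
                       mortality_hazard = 0.001,
                       disturb_rate_base = 0.31,
                       disturb_rate_ll_late = 1.09,
                       onset_hour = 90,
                       p_lower_ld_dark = 0.5,
                       p_lower_ll = 0.8,
                       seed = 1L) {
  cfg <- list(
    n_cages_per_condition = as.integer(n_cages_per_condition),
    n_bees = as.integer(n_bees),
    duration = as.integer(duration),
    tau_ld = tau_ld, tau_dd = tau_dd, tau_ll = tau_ll,
    drift_ll = drift_ll,
    amplitude0 = amplitude0, baseline = baseline,
    amplitude_decay = amplitude_decay, phase0 = phase0,
    mortality_hazard = mortality_hazard,
    disturb_rate_base = disturb_rate_base,
    disturb_rate_ll_late = disturb_rate_ll_late,
    onset_hour = onset_hour,
    p_lower_ld_dark = p_lower_ld_dark, p_lower_ll = p_lower_ll,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_cages_per_condition >= 1,
    cfg$duration >= 1,
    cfg$amplitude0 >= 0, cfg$amplitude0 <= 0.5,
    cfg$baseline >= 0, cfg$baseline <= 1,
    cfg$amplitude_decay >= 0, cfg$amplitude_decay < 1,
    cfg$mortality_hazard >= 0, cfg$mortality_hazard < 1,
    cfg$disturb_rate_base >= 0, cfg$disturb_rate_ll_late >= 0,
    cfg$p_lower_ld_dark >= 0, cfg$p_lower_ld_dark <= 1,
    cfg$p_lower_ll >= 0, cfg$p_lower_ll <= 1
  )
  if (cfg$n_bees <= 0) stop("n_bees must be positive")
  if (cfg$baseline + cfg$amplitude0 > 1 || cfg$baseline - cfg$amplitude0 < 0)
    stop("baseline +/- amplitude0 must stay within [0, 1]")
  taus <- c(LD = cfg$tau_ld, DD = cfg$tau_dd, LL = cfg$tau_ll)
  out_of_range <- taus < 20 | taus > 26
  if (any(out_of_range))
    warning("period(s) outside the free-running range 20-26 h: ",
            paste(names(taus)[out_of_range], collapse = ", "))
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Bee sleep simulation configuration\n")
  cat(sprintf("  %d cages/condition, %d bees/cage, %d h\n",
              x$n_cages_per_condition, x$n_bees, x$duration))
  cat(sprintf("  tau: LD %.2f, DD %.2f, LL %.2f (+%.2f h/day drift)\n",
              x$tau_ld, x$tau_dd, x$tau_ll, x$drift_ll))
  cat(sprintf("  mesor %.2f, amplitude %.2f (decay %.2f/day LL+DD), acrophase %.1f h\n",
              x$baseline, x$amplitude0, x$amplitude_decay, x$phase0))
  cat(sprintf("  mortality %.4g/bee/h; contacts %.2f -> %.2f (LL, >= %g h)\n",
              x$mortality_hazard, x$disturb_rate_base,
              x$disturb_rate_ll_late, x$onset_hour))
  invisible(x)
}

condition_tau <- function(cfg, condition) {
  switch(condition, LD = cfg$tau_ld, DD = cfg$tau_dd, LL = cfg$tau_ll,
         stop("invalid condition label: ", condition))
}

#' Expected proportion asleep under the generative model
#'
#' Evaluates the deterministic mean curve \eqn{p(t)} used by
#' [simulate_cage()] for a given condition, before binomial sampling.
#'
#' @param cfg A [sim_config()] object.
#' @param condition One of `"LL"`, `"DD"`, `"LD"`.
#' @param hours Numeric vector of hours from onset.
#' @return Numeric vector of expected proportions asleep, clipped to \[0, 1\].
#' @export
expected_prop_asleep <- function(cfg, condition, hours) {
  condition <- match.arg(condition, c("LL", "DD", "LD"))
  tau0 <- condition_tau(cfg, condition)
  tau_eff <- if (condition == "LL") tau0 + cfg$drift_ll * hours / 24 else
    rep(tau0, length(hours))
  amp <- if (condition == "LD") rep(cfg$amplitude0, length(hours)) else
    cfg$amplitude0 * (1 - cfg$amplitude_decay)^(hours / 24)
  p <- cfg$baseline + amp * cos(2 * pi * (hours - cfg$phase0) / tau_eff)
  pmin(pmax(p, 0), 1)
}

condition_p_lower <- function(cfg, condition) {
  if (condition == "LL") cfg$p_lower_ll else cfg$p_lower_ld_dark
}

#' Simulate one cage of hourly sleep observations
#'
#' Draws a complete hourly observation series for a single cage. Per hour:
#' deaths are binomial at `mortality_hazard` per alive bee, sleepers are
#' binomial over alive bees at the expected proportion from
#' [expected_prop_asleep()], disturbance contacts are Poisson with mean
#' `n_sleeping * rate` (the rate switches to `disturb_rate_ll_late` under LL at
#' `onset_hour`), and the count of sleepers in the lower cage half is binomial
#' over sleepers at the condition's lower-half probability. Identical seed and
#' configuration give bit-identical output.
#'
#' @param cfg A [sim_config()] object.
#' @param condition `"LL"`, `"DD"` or `"LD"`.
#' @param replicate_index 1-based replicate number within the condition.
#' @param seed Integer seed for this cage.
#' @return A data frame of observation records, one row per hour, with columns
#'   `cage_id`, `condition`, `replicate_index`, `hour`, `n_alive`,
#'   `n_sleeping`, `n_disturbance_contacts`, `n_sleeping_lower`.
#' @examples
#' obs <- simulate_cage(sim_config(), "LD", 1, seed = 7)
#' head(obs)
#' @export
simulate_cage <- function(cfg, condition, replicate_index, seed) {
  condition <- match.arg(condition, c("LL", "DD", "LD"))
  validate_sim_config(unclass(cfg))
  set.seed(as.integer(seed))
  hours <- seq_len(cfg$duration) - 1L
  p <- expected_prop_asleep(cfg, condition, hours)

  n_alive <- integer(cfg$duration)
  alive <- cfg$n_bees
  for (t in seq_along(hours)) {
    if (hours[t] > 0 && alive > 0)
      alive <- alive - stats::rbinom(1, alive, cfg$mortality_hazard)
    n_alive[t] <- alive
  }
  n_sleeping <- stats::rbinom(cfg$duration, n_alive, p)
  rate <- ifelse(condition == "LL" & hours >= cfg$onset_hour,
                 cfg$disturb_rate_ll_late, cfg$disturb_rate_base)
  n_contacts <- stats::rpois(cfg$duration, n_sleeping * rate)
  n_lower <- stats::rbinom(cfg$duration, n_sleeping,
                           condition_p_lower(cfg, condition))

  data.frame(
    cage_id = paste0(condition, "_", replicate_index),
    condition = condition,
    replicate_index = as.integer(replicate_index),
    hour = hours,
    n_alive = n_alive,
    n_sleeping = n_sleeping,
    n_disturbance_contacts = n_contacts,
    n_sleeping_lower = n_lower,
    stringsAsFactors = FALSE
  )
}

# Fixed per-condition seed strides: adding a condition never reshuffles
# sub-seeds of existing cages.
.condition_stride <- c(LD = 10000L, DD = 20000L, LL = 30000L)

#' Derive the sub-seed for one cage from the master seed
#'
#' `seed + stride(condition) + replicate_index`, with strides LD = 10000,
#' DD = 20000, LL = 30000. Documented so external tools can reproduce any
#' single cage.
#'
#' @inheritParams simulate_cage
#' @param seed Master seed.
#' @return Integer sub-seed.
#' @export
cage_seed <- function(seed, condition, replicate_index) {
  as.integer(seed) + .condition_stride[[condition]] + as.integer(replicate_index)
}

#' Simulate a full three-condition experiment
#'
#' Runs [simulate_cage()] for `n_cages_per_condition` replicates of each of
#' LL, DD and LD, with per-cage sub-seeds from [cage_seed()].
#'
#' @param cfg A [sim_config()] object.
#' @return A data frame of observation records for all cages (rows ordered by
#'   condition LD, DD, LL, then replicate, then hour).
#' @examples
#' obs <- simulate_experiment(sim_config(seed = 1))
#' nrow(obs)  # 9 cages x 120 hours
#' @export
simulate_experiment <- function(cfg) {
  validate_sim_config(unclass(cfg))
  out <- list()
  for (condition in c("LD", "DD", "LL")) {
    for (r in seq_len(cfg$n_cages_per_condition)) {
      out[[paste0(condition, r)]] <-
        simulate_cage(cfg, condition, r, cage_seed(cfg$seed, condition, r))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write observation records to the canonical CSV
#'
#' Header: `cage_id,condition,replicate_index,hour,n_alive,n_sleeping,`
#' `n_disturbance_contacts,n_sleeping_lower`.
#'
#' @param records Observation data frame, as from [simulate_experiment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(records, path) {
  utils::write.csv(records[, observation_columns()], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a simulation configuration from a YAML file
#'
#' Keys are the arguments of [sim_config()]; missing keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(sim_config, vals)
}
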