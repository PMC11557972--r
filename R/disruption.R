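#' Fold ratio between two positive means
#'
#' Scale-invariant ratio `a / b`, the package's convention for "x-fold"
#' statements (e.g. mean light level at the cage top over the bottom, or mean
#' contacts per sleeper in light over dark). Returns `NA` with a warning when
#' the denominator is zero.
#'
#' @param a,b Positive scalars (means).
#' @return `a / b`, or `NA_real_` if `b == 0`.
#' @export
fold_ratio <- function(a, b) {
  if (b == 0) {
    warning("fold ratio undefined: zero denominator")
    return(NA_real_)
  }
  a / b
}

#' Compare light levels between the top and bottom of the cage
#'
#' Two-sample pooled-variance t-test (df = n1 + n2 - 2) of photon flux between
#' the `top` and `bottom` positions, plus the top/bottom fold ratio of the
#' means. The pooled-variance form matches the reported t with 28 df for 15
#' measurements per position.
#'
#' @param measurements Data frame with columns `position` (`top`/`bottom`) and
#'   `photon_flux` (see [read_light_measurements()]).
#' @return A list with `t`, `df`, `p_value`, `mean_top`, `mean_bottom`,
#'   `fold_ratio`, and `method`.
#' @export
compare_light_levels <- function(measurements) {
  top <- measurements$photon_flux[measurements$position == "top"]
  bottom <- measurements$photon_flux[measurements$position == "bottom"]
  if (length(top) < 2 || length(bottom) < 2)
    stop("need at least 2 measurements per position")
  tt <- stats::t.test(top, bottom, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       mean_top = mean(top), mean_bottom = mean(bottom),
       fold_ratio = fold_ratio(mean(top), mean(bottom)),
       method = "two-sample t, pooled variance")
}

#' Disturbance-contact rates per sleeping bee, by condition
#'
#' For each cage-hour cell in the analysis window with at least one sleeper,
#' the contact rate is `n_disturbance_contacts / n_sleeping` (contacts per
#' sleeping bee per scored 5-minute window); cells without sleepers contribute
#' no rate observation. Reports mean and SD per condition and the fold ratio
#' between the first two conditions present (LL over DD when both occur).
#'
#' @param records Validated observation data frame.
#' @param window Analysis window in hours, half-open; default `c(90, 120)`,
#'   the interval where light/dark contact rates diverge.
#' @return A list with `summary` (data frame: condition,
#'   `mean_contacts_per_sleeper`, `sd_contacts`, `n_cells`, window bounds) and
#'   `fold_ratio` (LL mean over DD mean where both exist, else `NA`).
#' @export
disturbance_summary <- function(records, window = c(90, 120)) {
  records <- validate_observations(records)
  sel <- records$hour >= window[1] & records$hour < window[2]
  if (!any(sel)) stop("empty analysis window [", window[1], ", ", window[2], ")")
  d <- records[sel & records$n_sleeping > 0, , drop = FALSE]
  conds <- sort(unique(records$condition[sel]))
  rows <- lapply(conds, function(cc) {
    r <- d[d$condition == cc, , drop = FALSE]
    rate <- if (nrow(r)) r$n_disturbance_contacts / r$n_sleeping else numeric(0)
    data.frame(condition = cc,
               mean_contacts_per_sleeper = if (length(rate)) mean(rate) else NA_real_,
               sd_contacts = if (length(rate) > 1) stats::sd(rate) else NA_real_,
               n_cells = length(rate),
               window_start = window[1], window_end = window[2],
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  fr <- NA_real_
  if (all(c("LL", "DD") %in% summary$condition)) {
    m_ll <- summary$mean_contacts_per_sleeper[summary$condition == "LL"]
    m_dd <- summary$mean_contacts_per_sleeper[summary$condition == "DD"]
    if (is.finite(m_ll) && is.finite(m_dd) && m_dd > 0)
      fr <- fold_ratio(m_ll, m_dd)
  }
  list(summary = summary, fold_ratio = fr)
}

#' Proportion of sleepers in the lower cage half, per cage
#'
#' `prop_lower = sum(n_sleeping_lower) / sum(n_sleeping)` per cage over the
#' analysis window. Cages with no sleepers in the window get an `NA` sentinel.
#' Group-level inference on this response is delegated to
#' [rm_mixed_model()] with `response = "prop_lower"`.
#'
#' @param records Validated observation data frame.
#' @param window Analysis window; default `c(90, 120)`.
#' @return Data frame with `cage_id`, `condition`, `replicate_index`,
#'   `prop_lower`, `n_sleeper_hours`.
#' @export
position_preference <- function(records, window = c(90, 120)) {
  records <- validate_observations(records)
  sel <- records$hour >= window[1] & records$hour < window[2]
  if (!any(sel)) stop("empty analysis window")
  d <- records[sel, , drop = FALSE]
  cages <- unique(d$cage_id)
  rows <- lapply(cages, function(cage) {
    r <- d[d$cage_id == cage, , drop = FALSE]
    tot <- sum(r$n_sleeping)
    data.frame(cage_id = cage, condition = r$condition[1],
               replicate_index = r$replicate_index[1],
               prop_lower = if (tot > 0) sum(r$n_sleeping_lower) / tot else NA_real_,
               n_sleeper_hours = tot, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
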