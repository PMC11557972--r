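observation_columns <- function() {
  c("cage_id", "condition", "replicate_index", "hour", "n_alive",
    "n_sleeping", "n_disturbance_contacts", "n_sleeping_lower")
}

#' Read and validate an observation CSV
#'
#' Reads the canonical long-format observation table (one row per cage-hour)
#' and enforces every record invariant: counts consistent
#' (`0 <= n_sleeping_lower <= n_sleeping <= n_alive`), non-increasing `n_alive`
#' within each cage, and a complete, duplicate-free hour grid per cage. All
#' violations are collected and reported together with their row numbers.
#'
#' @param path CSV file path with header
#'   `cage_id,condition,replicate_index,hour,n_alive,n_sleeping,`
#'   `n_disturbance_contacts,n_sleeping_lower`.
#' @return A validated observation data frame, rows ordered by cage then hour.
#' @export
read_observations <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_observations(records)
}

#' Validate observation records
#'
#' @param records Observation data frame (see [read_observations()]).
#' @return The records, ordered by cage then hour, invisibly validated.
#' @export
validate_observations <- function(records) {
  missing_cols <- setdiff(observation_columns(), names(records))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  bad_cond <- !records$condition %in% c("LL", "DD", "LD")
  problems <- character()
  note <- function(rows, what) {
    if (length(rows))
      problems <<- c(problems, paste0(what, " (rows ",
                                      paste(rows, collapse = ", "), ")"))
  }
  note(which(bad_cond), "invalid condition label")
  counts <- c("hour", "n_alive", "n_sleeping", "n_disturbance_contacts",
              "n_sleeping_lower")
  for (col in counts)
    note(which(!is.finite(records[[col]]) | records[[col]] < 0 |
                 records[[col]] != round(records[[col]])),
         paste0("non-count value in ", col))
  note(which(records$n_sleeping > records$n_alive),
       "n_sleeping exceeds n_alive")
  note(which(records$n_sleeping_lower > records$n_sleeping),
       "n_sleeping_lower exceeds n_sleeping")

  for (cage in unique(records$cage_id)) {
    idx <- which(records$cage_id == cage)
    idx <- idx[order(records$hour[idx])]
    h <- records$hour[idx]
    dup <- duplicated(h)
    note(idx[dup], paste0("duplicate (cage, hour) in cage ", cage))
    grid <- seq(min(h), max(h))
    if (!all(grid %in% h))
      problems <- c(problems,
                    paste0("incomplete grid in cage ", cage, ": missing hour(s) ",
                           paste(setdiff(grid, h), collapse = ", ")))
    drop <- diff(records$n_alive[idx[!dup]])
    note(idx[!dup][which(drop > 0) + 1L],
         paste0("n_alive increases over time in cage ", cage))
  }
  if (length(problems))
    stop("observation validation failed:\n  ",
         paste(problems, collapse = "\n  "))
  records[order(records$cage_id, records$hour), , drop = FALSE]
}

#' Convert observation records to per-cage sleep series
#'
#' Computes `percent_asleep = 100 * n_sleeping / n_alive` per hour (0 when the
#' cage is extinct, flagged) and `percent_alive = 100 * n_alive / n_alive(0)`,
#' grouped per cage.
#'
#' @param records Validated observation data frame.
#' @return A named list of `sleep_series` objects, one per cage. Each holds
#'   `cage_id`, `condition`, `replicate_index`, `hours`, `percent_asleep`,
#'   `percent_alive`, and `extinct` (TRUE if `n_alive` reached 0).
#' @export
to_sleep_series <- function(records) {
  records <- validate_observations(records)
  cages <- unique(records$cage_id)
  out <- lapply(cages, function(cage) {
    d <- records[records$cage_id == cage, , drop = FALSE]
    d <- d[order(d$hour), , drop = FALSE]
    extinct <- any(d$n_alive == 0)
    pa <- ifelse(d$n_alive > 0, 100 * d$n_sleeping / d$n_alive, 0)
    s <- list(
      cage_id = cage,
      condition = d$condition[1],
      replicate_index = d$replicate_index[1],
      hours = d$hour,
      percent_asleep = pa,
      percent_alive = 100 * d$n_alive / d$n_alive[1],
      extinct = extinct
    )
    class(s) <- "sleep_series"
    s
  })
  names(out) <- cages
  out
}

#' @export
print.sleep_series <- function(x, ...) {
  cat(sprintf("Sleep series: cage %s (%s, replicate %d), %d hours\n",
              x$cage_id, x$condition, x$replicate_index, length(x$hours)))
  cat(sprintf("  %% asleep: median %.1f, range %.1f-%.1f;  %% alive at end: %.1f%s\n",
              stats::median(x$percent_asleep), min(x$percent_asleep),
              max(x$percent_asleep), utils::tail(x$percent_alive, 1),
              if (x$extinct) "  [extinct]" else ""))
  invisible(x)
}

#' @export
as.data.frame.sleep_series <- function(x, ...) {
  data.frame(cage_id = x$cage_id, condition = x$condition,
             replicate_index = x$replicate_index, hour = x$hours,
             percent_asleep = x$percent_asleep,
             percent_alive = x$percent_alive, stringsAsFactors = FALSE)
}

#' Log-transform sleep proportions with a zero-admitting offset
#'
#' Returns `log(p + offset)`. The default offset is `1 / (2 * max(n_alive))`
#' (half a minimal count increment) so zero proportions remain finite; pass
#' `offset = 0` for the plain log.
#'
#' @param p Numeric vector of proportions in \[0, 1\], or an observation data
#'   frame, in which case `n_sleeping / n_alive` is transformed.
#' @param offset Additive offset; defaults to `1 / (2 * 23)` for numeric input
#'   and `1 / (2 * max(n_alive))` for records.
#' @return Numeric vector `log(p + offset)`.
#' @export
log_transform_proportion <- function(p, offset = NULL) {
  if (is.data.frame(p)) {
    if (is.null(offset)) offset <- 1 / (2 * max(p$n_alive))
    p <- ifelse(p$n_alive > 0, p$n_sleeping / p$n_alive, 0)
  } else if (is.null(offset)) {
    offset <- 1 / (2 * 23)
  }
  if (any(p < 0)) stop("proportions must be non-negative")
  log(p + offset)
}

#' Read light measurements (position, photon_flux)
#'
#' @param path CSV with columns `position` (`top`/`bottom`) and `photon_flux`
#'   (µmol/m²/s, non-negative).
#' @return Validated data frame.
#' @export
read_light_measurements <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("position", "photon_flux") %in% names(d)))
    stop("light CSV must have columns position, photon_flux")
  if (!all(d$position %in% c("top", "bottom")))
    stop("position must be 'top' or 'bottom'")
  if (any(!is.finite(d$photon_flux) | d$photon_flux < 0))
    stop("photon_flux must be finite and non-negative")
  d
}
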