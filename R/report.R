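#' Pipeline configuration
#'
#' Bundles input source, analysis windows, period grid, output directory and
#' seed for [run_pipeline()].
#'
#' @param input Path to an observation CSV, or `NULL` to simulate.
#' @param sim A [sim_config()] used when `input` is `NULL`.
#' @param out_dir Output directory (created if absent).
#' @param crossover_h Hour after which the treatment-by-time sleep model is
#'   refit (the observed divergence point); default 79.
#' @param disrupt_window Disruptor analysis window; default `c(90, 120)`.
#' @param day4_window Day-4 alignment window; default `c(72, 96)`.
#' @param end_h End of experiment for the survival test; default 120.
#' @param grid Candidate period grid; default `seq(20, 28, by = 0.05)`.
#' @param seed Seed recorded in the manifest (the simulation seed comes from
#'   `sim`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, sim = sim_config(),
                            out_dir = "apisomnia-out",
                            crossover_h = 79, disrupt_window = c(90, 120),
                            day4_window = c(72, 96), end_h = 120,
                            grid = seq(20, 28, by = 0.05), seed = sim$seed) {
  if (crossover_h >= end_h) stop("crossover_h must be below end_h")
  cfg <- list(input = input, sim = sim, out_dir = out_dir,
              crossover_h = crossover_h, disrupt_window = disrupt_window,
              day4_window = day4_window, end_h = end_h, grid = grid,
              seed = seed)
  class(cfg) <- "pipeline_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full sleep-rhythm analysis pipeline
#'
#' Simulates or loads observations, then writes to `out_dir`:
#' `observations.csv`, `rhythm.csv` (one period fit per cage),
#' `alignment.csv` (day-4 AUC and peak distance per LL/DD cage vs its LD
#' control), `disrupt.csv` (contact rates and position preference),
#' `stats.csv` (mixed-model and nonparametric test results), sleep-curve and
#' alignment figures (PNG), and `manifest.json` recording inputs, windows,
#' seed and package version. Re-running with the same manifest inputs
#' reproduces all CSVs byte-identically.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- stage("input", {
    if (is.null(config$input)) simulate_experiment(config$sim)
    else read_observations(config$input)
  })
  if (config$day4_window[2] > max(records$hour) + 1)
    stop("pipeline stage 'validate-windows' failed: day-4 window [",
         config$day4_window[1], ", ", config$day4_window[2],
         ") extends beyond the data (last hour ", max(records$hour), ")",
         call. = FALSE)
  write_observations(records, file.path(config$out_dir, "observations.csv"))

  series <- stage("series", to_sleep_series(records))

  rhythm <- stage("rhythm", {
    do.call(rbind, lapply(series, function(s) {
      f <- estimate_period(s, grid = config$grid)
      data.frame(cage_id = s$cage_id, condition = s$condition,
                 replicate_index = s$replicate_index, tau = f$tau,
                 beta_sin = f$beta_sin, beta_cos = f$beta_cos,
                 amplitude = f$amplitude, phase = f$phase,
                 arrhythmic = f$arrhythmic, stringsAsFactors = FALSE)
    }))
  })
  utils::write.csv(rhythm, file.path(config$out_dir, "rhythm.csv"),
                   row.names = FALSE, quote = FALSE)

  alignment <- stage("alignment", align_to_control(series, config$day4_window))
  utils::write.csv(alignment, file.path(config$out_dir, "alignment.csv"),
                   row.names = FALSE, quote = FALSE)

  disrupt <- stage("disruption", {
    ds <- disturbance_summary(records, config$disrupt_window)
    pp <- position_preference(records, config$disrupt_window)
    merged <- merge(pp, ds$summary, by = "condition", all.x = TRUE)
    attr(merged, "fold_ratio") <- ds$fold_ratio
    merged
  })
  utils::write.csv(disrupt, file.path(config$out_dir, "disrupt.csv"),
                   row.names = FALSE, quote = FALSE)

  stats_rows <- stage("stats", {
    rows <- list()
    add <- function(analysis, tab) {
      rows[[length(rows) + 1]] <<- cbind(analysis = analysis, tab)
    }
    m_full <- rm_mixed_model(records, response = "log_prop_asleep")
    add("sleep_full", m_full$anova)
    m_late <- rm_mixed_model(records, c(config$crossover_h, config$end_h),
                             response = "log_prop_asleep")
    add("sleep_post_crossover", m_late$anova)
    surv <- kruskal_wallis_survival(records, config$end_h)
    add("survival", data.frame(term = "condition",
                               F = surv$statistic_value, df1 = surv$df,
                               df2 = NA_real_, p = surv$p_value))
    wil <- wilcoxon_rank_sum(
      alignment$abs_auc_day4[alignment$condition == "LL"],
      alignment$abs_auc_day4[alignment$condition == "DD"])
    add("abs_auc_LL_vs_DD", data.frame(term = "group",
                                       F = wil$statistic_value, df1 = NA_real_,
                                       df2 = NA_real_, p = wil$p_value))
    do.call(rbind, rows)
  })
  utils::write.csv(stats_rows, file.path(config$out_dir, "stats.csv"),
                   row.names = FALSE, quote = FALSE)

  fig <- file.path(config$out_dir, "sleep_curves.png")
  arrays <- stage("figures", {
    grDevices::png(fig, width = 900, height = 540)
    on.exit(grDevices::dev.off())
    plot_sleep_curves(series, day4_window = config$day4_window)
  })

  manifest <- list(
    input = if (is.null(config$input)) "simulated" else config$input,
    seed = config$seed,
    sim = if (is.null(config$input)) unclass(config$sim) else NULL,
    windows = list(crossover_h = config$crossover_h,
                   disrupt = config$disrupt_window,
                   day4 = config$day4_window, end_h = config$end_h),
    grid = range(config$grid),
    package_version = as.character(utils::packageVersion("apisomnia"))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(records = records, series = series, rhythm = rhythm,
                 alignment = alignment, disrupt = disrupt,
                 stats = stats_rows, figure = fig, arrays = arrays,
                 out_dir = config$out_dir))
}

#' Plot per-condition sleep curves with median and MAD band
#'
#' For each condition draws the across-cage median percent asleep per hour
#' with a +/- 1 MAD band (plain median absolute deviation, no consistency
#' scaling), line width proportional to the median percent of bees surviving,
#' and the day-4 window shaded. Conditions with no series are skipped with a
#' warning.
#'
#' @param series_list List of `sleep_series` objects.
#' @param day4_window Shaded window; default `c(72, 96)`.
#' @param colors Named condition colors.
#' @return Invisibly, the plotted arrays per condition (hours, median, mad,
#'   pct_surviving) — the same arrays a caller would write to CSV.
#' @export
plot_sleep_curves <- function(series_list, day4_window = c(72, 96),
                              colors = c(LL = "#E69F00", DD = "#0072B2",
                                         LD = "#009E73")) {
  conds <- vapply(series_list, `[[`, character(1), "condition")
  arrays <- list()
  for (cc in c("LD", "DD", "LL")) {
    ss <- series_list[conds == cc]
    if (!length(ss)) {
      warning("no series for condition ", cc, "; skipped")
      next
    }
    hours <- ss[[1]]$hours
    mat <- sapply(ss, `[[`, "percent_asleep")
    surv <- sapply(ss, `[[`, "percent_alive")
    med <- apply(as.matrix(mat), 1, stats::median)
    mad_ <- apply(as.matrix(mat), 1, function(v) stats::median(abs(v - stats::median(v))))
    arrays[[cc]] <- list(hours = hours, median = med, mad = mad_,
                         pct_surviving = apply(as.matrix(surv), 1, stats::median))
  }
  if (!length(arrays)) return(invisible(arrays))
  all_h <- range(unlist(lapply(arrays, `[[`, "hours")))
  plot(NA, xlim = all_h, ylim = c(0, 100), xlab = "Hours from onset",
       ylab = "% of bees asleep", main = "Sleep curves by lighting condition")
  graphics::rect(day4_window[1], 0, day4_window[2], 100,
                 col = grDevices::adjustcolor("grey", 0.3), border = NA)
  for (cc in names(arrays)) {
    a <- arrays[[cc]]
    col <- colors[[cc]]
    graphics::polygon(c(a$hours, rev(a$hours)),
                      c(a$median + a$mad, rev(a$median - a$mad)),
                      col = grDevices::adjustcolor(col, 0.25), border = NA)
    # line width tracks the surviving fraction, segment by segment
    for (i in seq_len(length(a$hours) - 1))
      graphics::segments(a$hours[i], a$median[i], a$hours[i + 1],
                         a$median[i + 1], col = col,
                         lwd = 0.5 + 2.5 * a$pct_surviving[i] / 100)
  }
  graphics::legend("topright", legend = names(arrays),
                   col = colors[names(arrays)], lwd = 2, bty = "n")
  invisible(arrays)
}
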