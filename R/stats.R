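#' Repeated-measures mixed model for cage-level sleep responses
#'
#' Fits `response ~ treatment + time + treatment:time` with a random intercept
#' for cage (cages have unique ids, so the intercept is implicitly nested
#' within treatment) by REML, and reports an F test per fixed term with
#' Satterthwaite denominator degrees of freedom (the approximation used is
#' recorded in the output). Responses:
#' \describe{
#'   \item{`log_prop_asleep`}{`log(n_sleeping/n_alive + offset)` per cage-hour,
#'     offset `1/(2 * max(n_alive))` so zero counts stay finite.}
#'   \item{`prop_lower`}{`n_sleeping_lower/n_sleeping`, cells with sleepers.}
#'   \item{`contacts`}{`n_disturbance_contacts/n_sleeping`, cells with
#'     sleepers.}
#' }
#'
#' A response with zero variance or a singular fit (zero cage variance) is
#' flagged in the result rather than raising an error.
#'
#' @param records Validated observation data frame (any subset of conditions).
#' @param window Half-open analysis window in hours; default the whole series.
#' @param response One of `"log_prop_asleep"`, `"prop_lower"`, `"contacts"`.
#' @return A list with `anova` (data frame: term, F, df1, df2, p),
#'   `cage_variance_share`, `singular`, `ddf_method`, `n_obs`, and the fitted
#'   `model` (or `NULL` for a degenerate response).
#' @export
rm_mixed_model <- function(records, window = NULL,
                           response = c("log_prop_asleep", "prop_lower",
                                        "contacts")) {
  response <- match.arg(response)
  records <- validate_observations(records)
  if (!is.null(window)) {
    records <- records[records$hour >= window[1] & records$hour < window[2], ,
                       drop = FALSE]
    if (!nrow(records)) stop("empty analysis window")
  }
  if (length(unique(records$condition)) < 2)
    stop("need at least 2 treatments")
  if (min(table(unique(records[c("cage_id", "condition")])$condition)) < 2)
    stop("need at least 2 cages per treatment")

  if (response == "log_prop_asleep") {
    d <- records[records$n_alive > 0, , drop = FALSE]
    d$y <- log_transform_proportion(d)
  } else {
    d <- records[records$n_sleeping > 0, , drop = FALSE]
    d$y <- if (response == "prop_lower")
      d$n_sleeping_lower / d$n_sleeping else
      d$n_disturbance_contacts / d$n_sleeping
  }
  d$treatment <- factor(d$condition)
  d$time <- d$hour
  d$cage <- factor(d$cage_id)

  terms <- c("treatment", "time", "treatment:time")
  if (stats::sd(d$y) == 0) {
    tab <- data.frame(term = terms, F = 0, df1 = NA_real_, df2 = NA_real_,
                      p = NA_real_, stringsAsFactors = FALSE)
    return(list(anova = tab, cage_variance_share = 0, singular = TRUE,
                ddf_method = "none (constant response)", n_obs = nrow(d),
                model = NULL))
  }

  m <- lmerTest::lmer(y ~ treatment * time + (1 | cage), data = d, REML = TRUE)
  a <- tryCatch(stats::anova(m, type = 3, ddf = "Satterthwaite"),
                error = function(e) NULL)
  ddf_method <- "Satterthwaite"
  if (is.null(a) || any(!is.finite(a$`Pr(>F)`))) {
    # fall back to residual denominator df when Satterthwaite degenerates
    a <- stats::anova(m, ddf = "lme4")
    a$DenDF <- nrow(d) - length(lme4::fixef(m))
    a$`Pr(>F)` <- stats::pf(a$`F value`, a$NumDF, a$DenDF, lower.tail = FALSE)
    ddf_method <- "residual"
  }
  vc <- as.data.frame(lme4::VarCorr(m))
  cage_var <- vc$vcov[vc$grp == "cage"]
  share <- cage_var / sum(vc$vcov)
  tab <- data.frame(term = rownames(a), F = a$`F value`, df1 = a$NumDF,
                    df2 = a$DenDF, p = a$`Pr(>F)`, stringsAsFactors = FALSE,
                    row.names = NULL)
  list(anova = tab, cage_variance_share = share,
       singular = lme4::isSingular(m), ddf_method = ddf_method,
       n_obs = nrow(d), model = m)
}

#' Wilcoxon rank-sum test with an exact small-sample path
#'
#' Two-sided rank-sum test. For combined n <= 12 the p-value is computed by
#' full enumeration of all `choose(n1+n2, n1)` group labelings of the pooled
#' midranks (valid with ties): `p = P(|W - mu| >= |W_obs - mu|)` where `W` is
#' the rank sum of the first sample and `mu = n1 (n1+n2+1)/2`. Larger samples
#' use the normal approximation with tie correction and a 0.5 continuity
#' correction. The path taken is recorded in the result.
#'
#' @param a,b Numeric samples (non-empty).
#' @param exact Force the exact (`TRUE`) or approximate (`FALSE`) path;
#'   default `NULL` switches on combined n <= 12.
#' @return A list with `statistic_name` (`"W"`, the rank sum of `a`),
#'   `statistic_value`, `p_value`, `method`, and `n` (c(n1, n2)).
#' @export
wilcoxon_rank_sum <- function(a, b, exact = NULL) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  if (is.null(exact)) exact <- N <= 12
  if (exact) {
    combos <- utils::combn(N, n1)
    sums <- colSums(matrix(r[combos], nrow = n1))
    p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal approximation, tie-corrected, continuity-corrected"
  }
  list(statistic_name = "W", statistic_value = W, p_value = p,
       method = method, n = c(n1, n2))
}

#' Kruskal-Wallis comparison of survival at the end of the experiment
#'
#' Computes the percentage of bees still alive at `t_end` per cage
#' (`100 * n_alive(last hour) / n_alive(0)`) and compares conditions with a
#' tie-corrected Kruskal-Wallis test (chi-square reference, df = groups - 1).
#' When every cage has the same survival (complete ties) the statistic is 0
#' and p = 1.
#'
#' @param records Validated observation data frame.
#' @param t_end End of experiment in hours from onset; the last observed hour
#'   before `t_end` is used. Default 120.
#' @return A list with `statistic_name` (`"H"`), `statistic_value`, `df`,
#'   `p_value`, `method`, and `per_cage` (data frame with `cage_id`,
#'   `condition`, `replicate_index`, `pct_alive`).
#' @export
kruskal_wallis_survival <- function(records, t_end = 120) {
  records <- validate_observations(records)
  if (max(records$hour) < t_end - 1)
    stop("t_end = ", t_end, " h is beyond the data (last hour ",
         max(records$hour), ")")
  if (length(unique(records$condition)) < 2)
    stop("need at least 2 conditions")
  cages <- unique(records$cage_id)
  per_cage <- do.call(rbind, lapply(cages, function(cage) {
    d <- records[records$cage_id == cage, , drop = FALSE]
    d <- d[order(d$hour), , drop = FALSE]
    last <- max(which(d$hour < t_end))
    data.frame(cage_id = cage, condition = d$condition[1],
               replicate_index = d$replicate_index[1],
               pct_alive = 100 * d$n_alive[last] / d$n_alive[1],
               stringsAsFactors = FALSE)
  }))
  g <- factor(per_cage$condition)
  if (stats::sd(per_cage$pct_alive) == 0) {
    return(list(statistic_name = "H", statistic_value = 0,
                df = nlevels(g) - 1, p_value = 1,
                method = "Kruskal-Wallis (complete ties)",
                per_cage = per_cage))
  }
  kt <- stats::kruskal.test(per_cage$pct_alive, g)
  list(statistic_name = "H", statistic_value = unname(kt$statistic),
       df = unname(kt$parameter), p_value = kt$p.value,
       method = "Kruskal-Wallis, tie-corrected", per_cage = per_cage)
}
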