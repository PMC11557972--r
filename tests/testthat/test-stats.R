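test_that("rank-sum exact path reproduces enumeration on canonical cases", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(wilcoxon_rank_sum(c(2, 5, 9), c(2, 5, 9))$p_value, 1.0)
  expect_equal(wilcoxon_rank_sum(1, 2)$p_value, 1.0)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
  expect_match(wilcoxon_rank_sum(1:3, 4:6)$method, "exact")
})

test_that("exact p agrees with independent enumeration and wilcox.test", {
  set.seed(55)
  for (i in 1:12) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    a <- sample(1:8, n1, replace = i %% 2 == 0)  # half the cases have ties
    b <- sample(1:8, n2, replace = i %% 2 == 0)
    p_pkg <- wilcoxon_rank_sum(a, b)$p_value
    expect_equal(p_pkg, oracle_wilcoxon_exact(a, b), tolerance = 1e-12)
    if (!anyDuplicated(c(a, b)))
      expect_equal(p_pkg,
                   suppressWarnings(wilcox.test(a, b, exact = TRUE)$p.value),
                   tolerance = 1e-12)
  }
})

test_that("exact and approximate paths agree at the switchover size", {
  set.seed(77)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(6)  # combined n = 12, no ties
    p_exact <- wilcoxon_rank_sum(a, b, exact = TRUE)$p_value
    p_approx <- wilcoxon_rank_sum(a, b, exact = FALSE)$p_value
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("survival comparison matches the hand-rank Kruskal-Wallis formula", {
  rec <- make_survival_records(list(LD = c(10, 20, 30), DD = c(40, 50, 60),
                                    LL = c(70, 80, 90)))
  res <- kruskal_wallis_survival(rec, t_end = 2)
  expect_equal(res$statistic_value, 7.2)
  expect_equal(res$df, 2)
  expect_equal(sort(res$per_cage$pct_alive),
               seq(10, 90, by = 10))

  # complete ties: everyone survives
  rec <- make_survival_records(list(LD = c(100, 100, 100),
                                    DD = c(100, 100, 100),
                                    LL = c(100, 100, 100)))
  res <- kruskal_wallis_survival(rec, t_end = 2)
  expect_equal(res$statistic_value, 0)
  expect_equal(res$p_value, 1)

  expect_error(kruskal_wallis_survival(rec, t_end = 500), "beyond the data")
})

test_that("survival test is invariant under monotone transforms of survival", {
  r1 <- make_survival_records(list(LD = c(10, 20, 30), DD = c(40, 50, 60),
                                   LL = c(70, 80, 90)))
  # a strictly monotone remapping of the same rank order
  r2 <- make_survival_records(list(LD = c(0.1, 0.4, 0.9),
                                   DD = c(1.6, 2.5, 3.6),
                                   LL = c(4.9, 6.4, 8.1)))
  expect_equal(kruskal_wallis_survival(r1, 2)$statistic_value,
               kruskal_wallis_survival(r2, 2)$statistic_value)
})

test_that("mixed model detects a strong injected treatment-by-time interaction", {
  hits <- 0
  for (s in 1:20) {
    set.seed(700 + s)
    rows <- list()
    for (cc in c("LL", "DD")) for (i in 1:3) {
      slope <- if (cc == "LL") -0.0015 else 0
      p <- pmax(0.02, 0.35 + slope * (0:119))
      rows[[paste0(cc, i)]] <- make_cage(
        paste0(cc, "_", i), cc, i, 0:119, n_alive = 23L,
        n_sleeping = rbinom(120, 23, p))
    }
    rec <- do.call(rbind, rows)
    fit <- rm_mixed_model(rec, response = "log_prop_asleep")
    p_int <- fit$anova$p[fit$anova$term == "treatment:time"]
    if (is.finite(p_int) && p_int < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("constant responses are flagged singular with zero F", {
  rec <- rbind(
    make_cage("LL_1", "LL", 1, 0:59, 10L, 5L), make_cage("LL_2", "LL", 2, 0:59, 10L, 5L),
    make_cage("DD_1", "DD", 1, 0:59, 10L, 5L), make_cage("DD_2", "DD", 2, 0:59, 10L, 5L))
  fit <- rm_mixed_model(rec, response = "log_prop_asleep")
  expect_true(fit$singular)
  expect_true(all(fit$anova$F == 0))
  expect_equal(fit$cage_variance_share, 0)
})

test_that("mixed-model fixed effects are invariant to cage relabeling", {
  obs <- simulate_experiment(sim_config(seed = 13))
  f1 <- rm_mixed_model(obs, c(79, 120), "log_prop_asleep")
  relabeled <- obs
  relabeled$cage_id <- paste0("cage", as.integer(factor(obs$cage_id,
    levels = sample(unique(obs$cage_id)))))
  f2 <- rm_mixed_model(relabeled, c(79, 120), "log_prop_asleep")
  expect_equal(f1$anova$F, f2$anova$F, tolerance = 1e-6)
  expect_equal(f1$ddf_method, "Satterthwaite")
})

test_that("mixed model reports window and response contracts", {
  obs <- simulate_experiment(sim_config(seed = 14))
  fit <- rm_mixed_model(obs, c(90, 120), "contacts")
  expect_setequal(fit$anova$term, c("treatment", "time", "treatment:time"))
  expect_true(all(fit$anova$p >= 0 & fit$anova$p <= 1, na.rm = TRUE))
  expect_gte(fit$cage_variance_share, 0)
  expect_error(rm_mixed_model(obs, c(500, 600)), "empty")
  one_cage <- obs[obs$cage_id %in% c("LL_1", "DD_1"), ]
  expect_error(rm_mixed_model(one_cage), "2 cages")
})
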