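test_that("tumor volume follows the caliper formula and is asymmetric", {
  expect_equal(tumor_volume(10, 5), 261.7)
  expect_equal(tumor_volume(5, 10), 130.85)
  expect_equal(tumor_volume(0, 7), 0)
  expect_equal(tumor_volume(c(10, 5), c(5, 10)), c(261.7, 130.85))
  expect_error(tumor_volume(-1, 5), ">= 0")
})

test_that("trajectory classification applies the four thresholds", {
  tr <- function(v) data.frame(day = seq_along(v) * 7, volume_mm3 = v)

  cls <- classify_trajectory(tr(c(300, 80, 600)))
  expect_equal(cls$final_status, "recurrent")
  expect_equal(cls$recurrence_day, 21)
  expect_equal(cls$complete_regression_day, 14)
  expect_true(cls$complete_regression)

  cls2 <- classify_trajectory(tr(c(300, 120, 130)))
  expect_equal(cls2$final_status, "stable_disease")
  expect_false(cls2$recurrence)

  # never regressed below 150
  cls3 <- classify_trajectory(tr(c(300, 260, 600)))
  expect_equal(cls3$final_status, "non_regressed")
  expect_false(cls3$recurrence)   # growth without regression is not recurrence

  # ends below 100: complete regression
  cls4 <- classify_trajectory(tr(c(300, 120, 90, 60)))
  expect_equal(cls4$final_status, "complete_regression")

  # strict inequalities: exactly 150 is not regression, exactly 500 not recurrence
  cls5 <- classify_trajectory(tr(c(300, 150, 500)))
  expect_equal(cls5$final_status, "non_regressed")
  expect_true(is.na(cls5$regression_day))

  # caliper columns accepted
  cal <- data.frame(day = c(0, 7), length_mm = c(10, 12), width_mm = c(5, 9))
  expect_equal(classify_trajectory(cal)$final_status, "non_regressed")

  expect_error(classify_trajectory(tr(c(300))), "at least 2")
  expect_error(classify_trajectory(data.frame(day = numeric(),
                                              volume_mm3 = numeric())),
               "empty")
})

test_that("raising the recurrence threshold never adds recurrent animals", {
  sim <- simulate_xenograft_trajectories(traj_sim_config(n_animals = 15,
                                                         noise_cv = 0.1,
                                                         seed = 14))
  counts <- sapply(c(400, 500, 700), function(thr) {
    cls <- classify_trajectories(sim$trajectories,
                                 thresholds = c(initial = 300,
                                                regression = 150,
                                                complete = 100,
                                                recurrence = thr))
    sum(cls$final_status == "recurrent")
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("classifier recovers generator truth", {
  sim0 <- simulate_xenograft_trajectories(traj_sim_config(n_animals = 25,
                                                          noise_cv = 0,
                                                          seed = 3))
  cls0 <- classify_trajectories(sim0$trajectories)
  truth0 <- sim0$truth$recurrent[match(cls0$animal_id, sim0$truth$animal_id)]
  expect_equal(mean((cls0$final_status == "recurrent") == truth0), 1)

  agree <- vapply(1:10, function(s) {
    sim <- simulate_xenograft_trajectories(traj_sim_config(n_animals = 25,
                                                           noise_cv = 0.1,
                                                           seed = s))
    cls <- classify_trajectories(sim$trajectories)
    truth <- sim$truth$recurrent[match(cls$animal_id, sim$truth$animal_id)]
    mean((cls$final_status == "recurrent") == truth)
  }, numeric(1))
  expect_gte(mean(agree), 0.95)
})

test_that("interval summary tracks absorbing recurrence and current volume", {
  traj <- rbind(
    data.frame(animal_id = "rec", arm = "a", day = c(0, 28, 56),
               volume_mm3 = c(300, 80, 600)),
    data.frame(animal_id = "cr", arm = "a", day = c(0, 28, 56),
               volume_mm3 = c(300, 60, 50)),
    data.frame(animal_id = "sd", arm = "a", day = c(0, 28, 56),
               volume_mm3 = c(300, 120, 200)),
    data.frame(animal_id = "dip", arm = "a", day = c(0, 28, 56),
               volume_mm3 = c(300, 90, 300)))
  cls <- classify_trajectories(traj)
  summ <- interval_status_summary(cls, traj, interval = 28, horizon_weeks = 8)
  w4 <- summ[summ$day == 28, ]
  expect_equal(w4$frac_complete_regression, 3 / 4)  # rec, cr, dip all < 100
  expect_equal(w4$frac_recurrent, 0)
  w8 <- summ[summ$day == 56, ]
  expect_equal(w8$frac_recurrent, 1 / 4)
  expect_equal(w8$frac_complete_regression, 1 / 4)  # only cr still < 100
  expect_equal(w8$frac_stable_disease, 2 / 4)
  # fractions always sum to 1
  ok <- with(summ, frac_complete_regression + frac_stable_disease +
                     frac_recurrent)
  expect_true(all(abs(ok - 1) < 1e-12))

  # single animal below 100 throughout
  solo <- data.frame(animal_id = "s", arm = "a", day = c(0, 28),
                     volume_mm3 = c(90, 80))
  scls <- classify_trajectories(solo)
  ssumm <- interval_status_summary(scls, solo, interval = 28,
                                   horizon_weeks = 8)
  expect_true(all(ssumm$frac_complete_regression == 1))
})

test_that("censored animals leave denominators after their censoring day", {
  traj <- rbind(
    data.frame(animal_id = "c1", arm = "a", day = c(0, 28),
               volume_mm3 = c(300, 120), censored_day = 30),
    data.frame(animal_id = "ok", arm = "a", day = c(0, 28, 56, 84),
               volume_mm3 = c(300, 80, 600, 700), censored_day = NA))
  cls <- classify_trajectories(traj)
  expect_true(cls$censored[cls$animal_id == "c1"])
  summ <- interval_status_summary(cls, traj, interval = 28, horizon_weeks = 12)
  expect_equal(summ$n[summ$day == 28], 2L)
  expect_equal(summ$n[summ$day == 56], 1L)
  # censored animal excluded from the contingency table
  tab <- recurrence_contingency(cls, "a", "a")
  expect_equal(sum(tab), 2)
})

test_that("Fisher's exact test matches enumeration and is symmetric", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_two_sided, 1)
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 4), 2))$p_two_sided, 1)

  m <- matrix(c(12, 3, 4, 11), 2)
  res <- fisher_exact(m)
  expect_equal(res$p_two_sided, fisher_oracle(12, 4, 3, 11), tolerance = 1e-12)
  expect_equal(res$odds_ratio, (12 * 11) / (4 * 3))
  expect_equal(fisher_exact(m[2:1, ])$p_two_sided, res$p_two_sided)
  expect_equal(fisher_exact(m[, 2:1])$p_two_sided, res$p_two_sided)

  # matches the established implementation too
  expect_equal(res$p_two_sided, fisher.test(m)$p.value, tolerance = 1e-10)

  # all tables with margins <= 10
  for (m1 in 0:10) for (n1 in 0:10) for (k in 0:(m1 + n1)) {
    for (a in max(0, k - n1):min(k, m1)) {
      tab <- matrix(c(a, k - a, m1 - a, n1 - k + a), 2)
      expect_equal(fisher_exact(tab)$p_two_sided,
                   fisher_oracle(a, m1 - a, k - a, n1 - k + a),
                   tolerance = 1e-12)
    }
  }
})

test_that("planted arm difference is detected by Fisher's exact test", {
  hits <- 0
  for (s in 1:10) {
    sim <- simulate_xenograft_trajectories(
      traj_sim_config(n_animals = 40, arms = c("hi", "lo"),
                      recurrence_prob = c(hi = 0.70, lo = 0.30),
                      noise_cv = 0.1, seed = s))
    cls <- classify_trajectories(sim$trajectories)
    tab <- recurrence_contingency(cls, "hi", "lo")
    hits <- hits + (fisher_exact(tab)$p_two_sided < 0.05)
  }
  expect_gte(hits, 6)
})

test_that("Welch t matches its formula and reduces to the pooled t", {
  a <- c(1, 2, 3); b <- c(4, 5, 6, 7)
  res <- welch_t(a, b)
  se2 <- var(a) / 3 + var(b) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 4)^2 / 3)
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$df, df_hand, tolerance = 1e-10)
  expect_equal(res$p_two_sided, 2 * pt(-abs(t_hand), df_hand),
               tolerance = 1e-10)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_two_sided, 1)

  # equal variances and n: numerically equal to the pooled t
  set.seed(71)
  x <- rnorm(10); y <- rnorm(10)
  y <- (y - mean(y)) / sd(y) * sd(x) + mean(y)  # force equal variance
  expect_equal(welch_t(x, y)$t,
               unname(t.test(x, y, var.equal = TRUE)$statistic),
               tolerance = 1e-10)
})

test_that("Pearson correlation handles exact and degenerate inputs", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 3)$r, 1)
  expect_error(pearson_r(1:5, rep(2, 5)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  set.seed(81)
  x <- rnorm(30); y <- rnorm(30)
  res <- pearson_r(x, y)
  r <- cor(x, y)
  tstat <- r * sqrt(28 / (1 - r^2))
  expect_equal(res$p_two_sided, 2 * pt(-abs(tstat), 28), tolerance = 1e-12)
})

test_that("null Pearson rejection rate is calibrated", {
  rej <- 0
  for (s in 1:400) {
    set.seed(s + 4000)
    rej <- rej + (pearson_r(rnorm(20), rnorm(20))$p_two_sided < 0.05)
  }
  expect_gte(rej / 400, 0.025)
  expect_lte(rej / 400, 0.075)
})
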