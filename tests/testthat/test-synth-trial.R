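test_that("default configuration reproduces the trial's arm sizes", {
  tab <- generate_trial(sim_config())
  expect_equal(unname(table(tab$arm)[c("no_feedback", "nontailored", "tailored")]),
               c(343, 338, 331), ignore_attr = TRUE)
  expect_equal(nrow(tab), 1012)
})

test_that("a fixed seed reproduces the table exactly", {
  cfg <- small_config(seed = 42)
  t1 <- generate_trial(cfg)
  t2 <- generate_trial(cfg)
  expect_identical(t1, t2)
  m1 <- apply_missingness(t1, cfg)
  m2 <- apply_missingness(t2, cfg)
  expect_identical(m1, m2)
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(arm_sizes = c(1, 10, 10)), "arm_sizes")
  expect_error(sim_config(followup_days = 0), "followup_days")
  expect_error(sim_config(miss_rate_overall = 1), "miss_rate_overall")
  expect_error(sim_config(miss_rate_variable = -0.1), "miss_rate_variable")
  expect_error(sim_config(cost_sd = rep(0, 7)), "cost_sd")
})

test_that("generated tables respect their domain invariants", {
  tab <- generate_trial(small_config(seed = 5))
  for (v in c("phq_t0", "phq_t2", "phq_t3"))
    expect_true(all(tab[[v]] >= 0 & tab[[v]] <= 27))
  for (v in c("vas_t0", "vas_t3"))
    expect_true(all(tab[[v]] >= 0 & tab[[v]] <= 100))
  expect_true(all(tab$eq5d_t0 >= -0.661 & tab$eq5d_t0 <= 1))
  expect_true(all(tab$eq5d_t3 >= -0.661 & tab$eq5d_t3 <= 1))
  expect_true(all(tab$day_t2 > 0 & tab$day_t2 < tab$day_t3))
  q_cols <- grep("^q_(pre|post)_", names(tab), value = TRUE)
  expect_true(all(as.matrix(tab[, q_cols]) >= 0))
  expect_true(all(tab$absence_pre >= 0 & tab$absence_post >= 0))
})

test_that("under a null configuration arm differences are centred at zero", {
  cfg <- sim_config(
    arm_sizes = c(no_feedback = 2000, nontailored = 2000, tailored = 2000),
    true_cost_shift = c(nontailored = 0, tailored = 0),
    true_qaly_shift = c(nontailored = 0, tailored = 0),
    phq_arm_drift = c(nontailored = 0, tailored = 0), seed = 11)
  an <- prepare_analysis(generate_trial(cfg))
  for (arm in c("nontailored", "tailored")) {
    for (v in c("cost_total", "qaly")) {
      x1 <- an[[v]][an$arm == arm]
      x0 <- an[[v]][an$arm == "no_feedback"]
      # analytic Monte-Carlo SE of a difference in means
      se <- sqrt(var(x1) / length(x1) + var(x0) / length(x0))
      expect_lt(abs(mean(x1) - mean(x0)), 3 * se)
    }
  }
})

test_that("follow-up total costs are right-skewed (SD exceeds mean)", {
  an <- prepare_analysis(generate_trial(sim_config(seed = 2)))
  expect_gt(sd(an$cost_total), mean(an$cost_total))
})

test_that("zero missingness rates leave the table unchanged", {
  cfg <- small_config(seed = 3, miss_rate_overall = 0, miss_rate_variable = 0)
  tab <- generate_trial(cfg)
  expect_identical(apply_missingness(tab, cfg), tab)
})

test_that("realised missingness matches its targets", {
  cfg <- sim_config(seed = 8)
  tab <- apply_missingness(generate_trial(cfg), cfg)
  data_cols <- setdiff(names(tab), c("in_base", "in_primary", "in_extended"))
  overall <- mean(is.na(tab[, data_cols]))
  expect_gte(overall, 0.033)
  expect_lte(overall, 0.053)
  eligible <- c("scid", "phq_t2", "phq_t3", "eq5d_t0", "eq5d_t3",
                "vas_t0", "vas_t3", "absence_pre", "absence_post",
                grep("^q_post_", names(tab), value = TRUE))
  per_var <- vapply(tab[, eligible], function(x) mean(is.na(x)), numeric(1))
  expect_lt(abs(mean(per_var) - 0.09), 0.01)
  # protected columns stay complete
  for (v in c("id", "arm", "age", "gender", "phq_t0"))
    expect_false(anyNA(tab[[v]]))
})

test_that("missingness is MAR: independent of the masked value given covariates", {
  cfg <- sim_config(
    arm_sizes = c(no_feedback = 2000, nontailored = 2000, tailored = 2000),
    seed = 13)
  complete <- generate_trial(cfg)
  masked <- apply_missingness(complete, cfg)
  fit <- glm(is.na(masked$eq5d_t3) ~ complete$eq5d_t3 + complete$age +
               complete$gender + complete$arm, family = binomial())
  z <- coef(summary(fit))["complete$eq5d_t3", "z value"]
  expect_lt(abs(z), 3)
})

test_that("true_values echoes the configured ground truth", {
  tv0 <- true_values(sim_config(true_cost_shift = c(nontailored = 0, tailored = 0),
                                true_qaly_shift = c(nontailored = 0, tailored = 0)))
  expect_equal(tv0$delta_cost, c(0, 0))
  expect_equal(tv0$delta_qaly, c(0, 0))
  tv <- true_values(sim_config(true_cost_shift = c(nontailored = 0, tailored = -600),
                               true_qaly_shift = c(nontailored = 0, tailored = -0.006)))
  expect_equal(tv$delta_cost[tv$arm == "tailored"], -600)
  expect_equal(tv$delta_qaly[tv$arm == "tailored"], -0.006)
})

test_that("trial tables round-trip through delimited text with metadata", {
  cfg <- small_config(seed = 9)
  tab <- apply_missingness(generate_trial(cfg), cfg)
  path <- tempfile(fileext = ".tsv")
  write_trial_table(tab, path)
  back <- read_trial_table(path)
  expect_equal(levels(back$arm), levels(tab$arm))
  expect_identical(is.na(back$eq5d_t3), is.na(tab$eq5d_t3))
  expect_equal(back$absence_post, tab$absence_post, tolerance = 1e-8)
  expect_identical(back$in_primary, tab$in_primary)
})
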