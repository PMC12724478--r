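arms3 <- c("no_feedback", "nontailored", "tailored")

test_that("incremental differences vanish for identical arm records", {
  tab <- means_table(arms3[1:2], cost = c(4000, 4000), effect = c(0.35, 0.35),
                     jitter = 10)
  inc <- incremental(tab, c("nontailored", "no_feedback"))
  expect_equal(inc$delta_cost$point, 0)
  expect_equal(inc$delta_effect$point, 0)
})

test_that("incremental reproduces the published arm-mean differences", {
  fm <- followup_means()
  tab <- means_table(arms3, cost = unlist(fm["total", arms3]),
                     effect = unlist(fm["qaly", arms3]), jitter = 50)
  inc_nt <- incremental(tab, c("nontailored", "no_feedback"))
  expect_equal(inc_nt$delta_cost$point, 372)
  expect_equal(round(inc_nt$delta_effect$point, 3), -0.002)
  inc_t <- incremental(tab, c("tailored", "no_feedback"))
  expect_equal(inc_t$delta_cost$point, -597)
  expect_equal(round(inc_t$delta_effect$point, 3), -0.006)
  expect_error(incremental(tab, c("placebo", "no_feedback")), "absent")
})

test_that("incremental cost is recovered within 2 SEs on synthetic data", {
  cfg <- sim_config(
    arm_sizes = c(no_feedback = 340, nontailored = 340, tailored = 340),
    true_cost_shift = c(nontailored = 0, tailored = -600),
    true_qaly_shift = c(nontailored = 0, tailored = -0.006), seed = 17)
  an <- prepare_analysis(generate_trial(cfg))
  inc <- incremental(an, c("tailored", "no_feedback"))
  expect_lt(abs(inc$delta_cost$point - (-600)), 2 * inc$delta_cost$se)
})

test_that("dominance classification matches the sign-table oracle", {
  # independent oracle: enumerate the 9 sign combinations
  sign_oracle <- function(dc, de) {
    if (dc < 0 && de > 0) return("dominant")
    if (dc > 0 && de < 0) return("dominated")
    if (de == 0) return("undefined-ratio")
    "ratio"
  }
  vals <- c(-1, 0, 1)
  for (dc in vals) for (de in vals) {
    r <- icer(dc * 500, de * 0.01)
    expect_equal(r$label, sign_oracle(dc * 500, de * 0.01),
                 info = sprintf("dc=%g de=%g", dc, de))
    if (r$label == "ratio") expect_equal(r$icer, (dc * 500) / (de * 0.01))
    else expect_true(is.na(r$icer))
  }
  expect_equal(icer(372, -0.002)$label, "dominated")
  expect_equal(icer(-100, 0.01)$label, "dominant")
  sw <- icer(-597, -0.006)
  expect_equal(sw$quadrant, "SW")
  expect_equal(sw$icer, 99500)
  expect_match(sw$note, "lower cost, lower effect")
})

test_that("net benefit is wtp times effect minus cost", {
  expect_equal(net_benefit(3000, 0.35, 10000), 500)
  expect_equal(net_benefit(1234, 0.4, 0), -1234)
  expect_equal(net_benefit(0, 1, 50000), 50000)
  expect_error(net_benefit(0, 1, -1), ">= 0")
})

test_that("the net-benefit regression slope is the arm-mean difference", {
  nb <- c(90, 110, 150, 170)           # means 100 vs 160
  is_ig <- c(FALSE, FALSE, TRUE, TRUE)
  f <- nbr_fit(nb, is_ig)
  expect_equal(f$coef, 60)
  # identical to lm on a treatment dummy
  lmfit <- summary(lm(nb ~ is_ig))
  expect_equal(f$coef, unname(coef(lmfit)[2, 1]))
  expect_equal(f$se, unname(coef(lmfit)[2, 2]))
  expect_error(nbr_fit(nb, rep(TRUE, 4)), "both arms")
})

test_that("NBR slope decomposes as wtp * dE - dC for any wtp", {
  set.seed(19)
  n <- 200
  cost <- rgamma(n, 0.5, scale = 8000)
  eff <- rnorm(n, 0.36, 0.1)
  is_ig <- rep(c(TRUE, FALSE), n / 2)
  d_e <- mean(eff[is_ig]) - mean(eff[!is_ig])
  d_c <- mean(cost[is_ig]) - mean(cost[!is_ig])
  for (lambda in seq(0, 160000, by = 10000)) {
    f <- nbr_fit(net_benefit(cost, eff, lambda), is_ig)
    expect_equal(f$coef, lambda * d_e - d_c, tolerance = 1e-9)
  }
})

test_that("the base CEAC grid has 17 points from 0 to 160,000", {
  tab <- prepare_analysis(generate_trial(small_config(seed = 23)))
  cc <- ceac(tab, c("tailored", "no_feedback"))
  expect_equal(nrow(cc), 17)
  expect_equal(cc$wtp, seq(0, 160000, by = 10000))
  expect_true(all(cc$prob >= 0 & cc$prob <= 1))
  expect_error(ceac(tab, c("tailored", "no_feedback"), wtp_grid = c(2, 1)),
               "increasing")
})

test_that("CEAC at wtp 0 equals the probability of cost saving", {
  tab <- prepare_analysis(generate_trial(small_config(seed = 29)))
  cc <- ceac(tab, c("tailored", "no_feedback"))
  # independent route: one-sided exceedance of the negated cost difference
  s_ig <- tab$cost_total[tab$arm == "tailored"]
  s_cg <- tab$cost_total[tab$arm == "no_feedback"]
  f <- nbr_fit(-c(s_ig, s_cg), rep(c(TRUE, FALSE), c(length(s_ig), length(s_cg))))
  expect_equal(cc$prob[1], f$p_exceed, tolerance = 1e-12)
})

test_that("pooling a complete dataset reproduces the single-dataset CEAC", {
  cfg <- small_config(seed = 31, miss_rate_overall = 0, miss_rate_variable = 0)
  tab <- generate_trial(cfg)
  imps <- prepare_analysis(impute_chained(tab, m = 10, iterations = 1, seed = 1))
  pooled <- ceac(imps, c("tailored", "no_feedback"))
  single <- ceac(prepare_analysis(tab), c("tailored", "no_feedback"))
  expect_equal(pooled$prob, single$prob)
})

test_that("scenario dispatch selects measure, perspective and grid", {
  s1 <- scenario_spec("S1")
  expect_equal(s1$effect_col, "qaly_vas")
  expect_equal(s1$perspective, "societal")
  s3 <- scenario_spec("S3")
  expect_equal(s3$perspective, "payer")
  s5 <- scenario_spec("S5")
  expect_equal(s5$effect_col, "dfd")
  expect_equal(s5$wtp_grid, seq(0, 200, by = 10))
  expect_equal(s5$wtp_anchor, 15)
  expect_error(scenario_spec("S9"))

  imps <- prepare_analysis(impute_chained(
    generate_trial(small_config(seed = 37)), m = 1, iterations = 1, seed = 1))
  res <- run_scenario(imps, "S3")
  expect_named(res$results, c("nontailored_vs_no_feedback",
                              "tailored_vs_no_feedback",
                              "tailored_vs_nontailored"))
  # payer deltas are computed on the informal-care/indirect-free totals
  t1 <- imps$imputations[[1]]
  dc_payer <- mean(t1$cost_total_payer[t1$arm == "tailored"]) -
    mean(t1$cost_total_payer[t1$arm == "no_feedback"])
  expect_equal(res$results$tailored_vs_no_feedback$incremental$delta_cost$point,
               dc_payer)
  res5 <- run_scenario(imps, "S5")
  expect_equal(nrow(res5$results[[1]]$ceac), 21)
})

test_that("subgroup curves exist per level and age splits into terciles", {
  cfg <- sim_config(
    arm_sizes = c(no_feedback = 338, nontailored = 337, tailored = 337),
    seed = 41, miss_rate_overall = 0, miss_rate_variable = 0)
  imps <- prepare_analysis(impute_chained(generate_trial(cfg), m = 1,
                                          iterations = 1, seed = 1))
  by_gender <- subgroup_ceac(imps, "gender",
                             comparisons = default_comparisons()[2])
  expect_true(all(c("woman", "man") %in% names(by_gender)))
  tab <- imps$imputations[[1]]
  terc <- trialcea:::.age_terciles(tab$age)
  expect_lte(diff(range(table(terc))), 1)
  expect_equal(sum(table(terc)), nrow(tab))
  # terciles are ordered: everyone in T1 is no older than everyone in T3
  expect_lte(max(tab$age[terc == "age_T1"]), min(tab$age[terc == "age_T3"]))
  by_age <- subgroup_ceac(imps, "age", comparisons = default_comparisons()[2])
  expect_named(by_age, c("age_T1", "age_T2", "age_T3"))
  expect_error(subgroup_ceac(imps, "shoe_size"), "unknown grouping")
})

test_that("balance tests: identical arms give t = 0, p = 1; rows = vars x pairs", {
  base <- data.frame(age = rnorm(30), phq_t0 = rpois(30, 14))
  tab <- rbind(base, base, base)
  tab$arm <- rep(arms3, each = 30)
  bal <- baseline_balance(tab, vars = c("age", "phq_t0"))
  expect_equal(nrow(bal), 2 * 3)
  expect_true(all(abs(bal$statistic) < 1e-12))
  expect_true(all(bal$p == 1))
  tab5 <- generate_trial(small_config(seed = 43))
  bal5 <- baseline_balance(tab5, vars = c("age", "gender", "phq_t0",
                                          "eq5d_t0", "vas_t0"))
  expect_equal(nrow(bal5), 5 * 3)
})

test_that("balance tests hold their nominal type-I error rate", {
  set.seed(47)
  reps <- 1000
  p <- numeric(reps)
  for (i in 1:reps) {
    tab <- data.frame(arm = rep(c("a", "b"), each = 25), y = rnorm(50))
    p[i] <- baseline_balance(tab, vars = "y")$p
  }
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})
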