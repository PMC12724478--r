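test_that("value-set scoring honours floor and ceiling", {
  vs <- synthetic_de_value_set()
  expect_equal(score_eq5d(c(1, 1, 1, 1, 1), vs), 1)
  expect_equal(score_eq5d(c(5, 5, 5, 5, 5), vs), -0.661)
  expect_equal(vs$floor, -0.661)
  # scores never leave [floor, ceiling]
  set.seed(1)
  profs <- matrix(sample(1:5, 500, replace = TRUE), ncol = 5)
  idx <- score_eq5d(profs, vs)
  expect_true(all(idx >= vs$floor - 1e-12 & idx <= vs$ceiling + 1e-12))
})

test_that("additive toy set scores by per-level decrements", {
  vs <- toy_value_set(0.1)
  expect_equal(score_eq5d(c(2, 1, 1, 1, 1), vs), 0.9)
  expect_equal(score_eq5d(c(2, 2, 1, 1, 1), vs), 0.8)
})

test_that("lookup-form value sets reject absent profiles and bad levels", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(profile = c("11111", "21111"), index = c(1, 0.9)),
            path, row.names = FALSE)
  vs <- read_value_set(path)
  expect_equal(score_eq5d(c(2, 1, 1, 1, 1), vs), 0.9)
  expect_error(score_eq5d(c(3, 1, 1, 1, 1), vs), "absent")
  expect_error(score_eq5d(c(6, 1, 1, 1, 1), vs), "1..5")
  expect_error(score_eq5d(c(0, 1, 1, 1), vs), "5 dimension levels")
})

test_that("QALYs follow the linear-trend closed form", {
  expect_equal(qaly_index(1, 1, 180), 0.5)
  expect_equal(qaly_index(0.6, 0.8, 180), 0.35)
  expect_equal(qaly_index(0.6, 0.8, 360), 0.325)
  expect_error(qaly_index(0.5, 0.5, 0), "delta_days")
  expect_warning(qaly_index(0.5, 0.5, 400), "outside")
})

test_that("at a 180-day interval the QALY is the mean index times 0.5", {
  set.seed(7)
  n <- 1e4
  i0 <- runif(n, -0.661, 1)
  i3 <- runif(n, -0.661, 1)
  expect_equal(qaly_index(i0, i3, rep(180, n)), (i0 + i3) / 2 * 0.5)
  # linearity in each index argument
  a <- runif(1); b <- runif(1)
  expect_equal(qaly_index(a * i0 + b, i3, rep(140, n)),
               a * qaly_index(i0, i3, rep(140, n)) +
                 b * qaly_index(1, i3, rep(140, n)) -
                 (a + b - 1) * qaly_index(0, i3, rep(140, n)))
})

test_that("VAS QALYs are the index formula on VAS/100", {
  expect_equal(qaly_vas(50, 50, 180), 0.25)
  expect_equal(qaly_vas(0, 100, 180), 0.25)
  expect_equal(qaly_vas(100, 100, 360), 0.5)
  expect_error(qaly_vas(101, 50, 180), "\\[0, 100\\]")
  expect_error(qaly_vas(50, -1, 180), "\\[0, 100\\]")
})

test_that("PHQ-9 severity bands follow the standard cut points", {
  expect_equal(as.character(phq_severity_band(3)), "minimal")
  expect_equal(as.character(phq_severity_band(10)), "moderate")
  expect_equal(as.character(phq_severity_band(27)), "severe")
  expect_equal(as.character(phq_severity_band(c(4, 5, 9, 14, 15, 19, 20))),
               c("minimal", "mild", "mild", "moderate", "moderately severe",
                 "moderately severe", "severe"))
  expect_error(phq_severity_band(-1), "\\[0, 27\\]")
  expect_error(phq_severity_band(28), "\\[0, 27\\]")
})

test_that("depression-free days handle the all-below and all-above cases", {
  expect_equal(depression_free_days(c(4, 4, 4), c(30, 180)), 180)
  expect_equal(depression_free_days(c(20, 20, 20), c(30, 180)), 0)
  # first segment crosses the threshold at day 15
  expect_equal(depression_free_days(c(10, 0, 0), c(30, 180)), 165)
  expect_error(depression_free_days(c(5, 5, 5), c(180, 30)), "increasing")
  expect_error(depression_free_days(c(28, 5, 5), c(30, 180)), "\\[0, 27\\]")
  expect_true(is.na(depression_free_days(c(NA, 5, 5), c(30, 180))))
})

test_that("exact DFD agrees with a fine-grid oracle on random trajectories", {
  set.seed(42)
  worst <- 0
  for (i in 1:1000) {
    s <- runif(3, 0, 27)
    d2 <- runif(1, 10, 120)
    d3 <- d2 + runif(1, 20, 150)
    exact <- depression_free_days(s, c(d2, d3))
    approx_val <- dfd_grid_oracle(s, c(d2, d3))
    worst <- max(worst, abs(exact - approx_val))
  }
  expect_lt(worst, 0.5)
})

test_that("DFD is monotone nonincreasing in any single score", {
  set.seed(9)
  for (i in 1:50) {
    s <- runif(3, 0, 26)
    off <- sort(runif(2, 10, 200))
    base <- depression_free_days(s, off)
    for (j in 1:3) {
      s2 <- s
      s2[j] <- s2[j] + runif(1, 0, 27 - s2[j])
      expect_lte(depression_free_days(s2, off), base + 1e-9)
    }
  }
})

test_that("graded DFD credit bounds the binary count from above", {
  set.seed(10)
  for (i in 1:100) {
    s <- runif(3, 0, 27)
    off <- sort(runif(2, 10, 200)); off <- c(off[1], off[1] + off[2])
    b <- depression_free_days(s, off, rule = "binary", threshold = 5)
    g <- depression_free_days(s, off, rule = "graded", lower = 5, upper = 10)
    expect_gte(g, b - 1e-9)
    expect_lte(g, 180 + 1e-9)
  }
})

test_that("compute_outcomes assembles the per-participant outcome set", {
  tab <- generate_trial(small_config(seed = 4))
  out <- compute_outcomes(tab)
  expect_equal(nrow(out), nrow(tab))
  expect_true(all(out$dfd >= 0 & out$dfd <= 180))
  expect_true(all(out$qaly <= 0.5 + 1e-6))
  expect_s3_class(out$severity_t3, "factor")
  expect_true(all(levels(out$severity_t3) ==
    c("minimal", "mild", "moderate", "moderately severe", "severe")))
})
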