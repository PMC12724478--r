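# shared fixtures: small configs and toy inputs, all built in code

small_config <- function(seed = 1, ...) {
  sim_config(arm_sizes = c(no_feedback = 120, nontailored = 120, tailored = 120),
             seed = seed, ...)
}

# toy additive value set: 0.1 decrement per level above 1 in any dimension
toy_value_set <- function(per_level = 0.1) {
  path <- tempfile(fileext = ".csv")
  dims <- c("mobility", "self_care", "usual_activities",
            "pain_discomfort", "anxiety_depression")
  tab <- expand.grid(dimension = dims, level = 2:5, stringsAsFactors = FALSE)
  tab$decrement <- (tab$level - 1) * per_level
  write.csv(tab, path, row.names = FALSE)
  read_value_set(path)
}

synthetic_de_value_set <- function() {
  read_value_set(system.file("extdata", "value_set_synthetic_de.csv",
                             package = "trialcea"))
}

# published arm-level follow-up summary (means per arm) used for the
# printed-arithmetic checks
followup_means <- function() {
  tab <- read.csv(system.file("extdata", "trial_followup_means.csv",
                              package = "trialcea"))
  rownames(tab) <- tab$row
  tab
}

# analysis table with explicit per-arm constant cost/effect values, so arm
# means are exact; two rows per arm satisfy the regression preconditions
means_table <- function(arms, cost, effect, jitter = 0) {
  data.frame(
    arm = factor(rep(arms, each = 2), levels = arms),
    cost_total = rep(cost, each = 2) + rep(c(-jitter, jitter), length(arms)),
    qaly = rep(effect, each = 2)
  )
}

# independent fine-grid oracle for depression-free days: midpoint sampling
# of the piecewise-linear trajectory (last score carried forward past T3)
dfd_grid_oracle <- function(scores, offsets, threshold = 5, horizon = 180,
                            n_grid = 1e4) {
  t <- (seq_len(n_grid) - 0.5) * horizon / n_grid
  x <- c(0, offsets)
  interp <- approx(x, scores, xout = pmin(t, max(x)))$y
  interp[t > max(x)] <- scores[3]   # last score carried forward
  sum(interp < threshold) * horizon / n_grid
}
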