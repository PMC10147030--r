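test_that("growth rate is the percent height increase, sign preserved", {
  expect_equal(growth_rate(100, 120), 20)
  expect_equal(growth_rate(150, 150), 0)
  expect_equal(growth_rate(80, 60), -25)
  expect_error(growth_rate(0, 50), class = "nupeval_validation_error")

  # growth_rate(a, a * (1 + r/100)) recovers r for any a > 0, r >= -100
  set.seed(11)
  a <- runif(50, 0.1, 400)
  r <- runif(50, -100, 300)
  expect_equal(growth_rate(a, a * (1 + r / 100)), r, tolerance = 1e-9)
})

test_that("one-way ANOVA matches the hand sums-of-squares decomposition", {
  groups <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  res <- oneway_anova(make_onedate_trial(groups), "acc", 18)
  expect_equal(res$F, 3.0)
  expect_identical(c(res$df_between, res$df_within), c(2L, 6L))
  expect_equal(res$ss_between, 6)
  expect_equal(res$ss_within, 6)

  set.seed(42)
  for (i in 1:20) {
    k <- sample(3:4, 1)
    groups <- lapply(seq_len(k), function(j) runif(sample(2:6, 1), 10, 200))
    res <- oneway_anova(make_onedate_trial(groups), "acc", 18)
    orc <- oracle_oneway(groups)
    expect_equal(res$F, orc$F, tolerance = 1e-9)
    expect_equal(res$p_value, orc$p, tolerance = 1e-9)
    # SS identity: total = between + within, to 1e-9 relative
    expect_equal(res$ss_between + res$ss_within, orc$sst,
                 tolerance = 1e-9)
  }
})

test_that("F statistics are invariant to location shift and positive rescaling", {
  set.seed(7)
  groups <- lapply(1:3, function(i) runif(5, 50, 150) + 10 * i)
  base <- oneway_anova(make_onedate_trial(groups), "acc", 18)
  shifted <- oneway_anova(make_onedate_trial(lapply(groups, `+`, 50)), "acc", 18)
  scaled <- oneway_anova(make_onedate_trial(lapply(groups, `*`, 2.7)), "acc", 18)
  expect_equal(shifted$F, base$F, tolerance = 1e-9)
  expect_equal(shifted$p_value, base$p_value, tolerance = 1e-9)
  expect_equal(scaled$F, base$F, tolerance = 1e-9)
})

test_that("zero within-group variance is flagged degenerate, not an error", {
  d <- make_onedate_trial(list(c(5, 5, 5), c(5, 5, 5), c(5, 5, 5)))
  res <- oneway_anova(d, "acc", 18)
  expect_true(res$degenerate)
  expect_true(is.na(res$F))
  tk <- tukey_hsd(d, "acc", 18)
  expect_true(tk$degenerate)
  expect_true(all(is.na(tk$pairs$significant)))
})

test_that("Tukey HSD flags exactly the separated pairs and is symmetric", {
  base <- c(-0.1, -0.05, 0, 0.05, 0.1) + 5
  d <- make_onedate_trial(list(base, base + 0.1, base + 10))
  tk <- tukey_hsd(d, "acc", 18)
  far <- tk$pairs$treatment_a == "trt3" | tk$pairs$treatment_b == "trt3"
  expect_identical(tk$pairs$significant, far)

  # relabelling the groups negates the mean difference, keeps significance
  d2 <- make_onedate_trial(list(base + 10, base + 0.1, base))
  tk2 <- tukey_hsd(d2, "acc", 18)
  pair13 <- tk$pairs$treatment_a == "trt3" & tk$pairs$treatment_b == "trt1"
  expect_equal(tk2$pairs$mean_diff[pair13], -tk$pairs$mean_diff[pair13])
  expect_identical(sum(tk2$pairs$significant), sum(tk$pairs$significant))
})

test_that("Tukey HSD agrees with the brute-force studentized-range oracle", {
  set.seed(99)
  for (i in 1:25) {
    groups <- lapply(1:3, function(j)
      rnorm(sample(2:5, 1), mean = sample(0:6, 1) * 2, sd = 1) + 50)
    tk <- tukey_hsd(make_onedate_trial(groups), "acc", 18)
    orc <- oracle_tukey(groups)
    impl <- tk$pairs[order(tk$pairs$treatment_b, tk$pairs$treatment_a), ]
    orc <- orc[order(orc$i, orc$j), ]
    expect_equal(impl$adj_p, orc$adj_p, tolerance = 1e-6)
    expect_identical(impl$significant, orc$significant)
    expect_equal(impl$mean_diff, orc$diff, tolerance = 1e-9)
  }
})

test_that("repeated-measures decomposition matches brute-force SS on a toy grid", {
  # 2 treatments x 2 times x 2 replicates
  df <- expand.grid(treatment = c("A", "B"), replicate = 1:2,
                    months_after_planting = c(15, 18))
  df$species <- "s"; df$accession <- "acc"
  df$height_cm <- c(10, 20, 12, 24, 15, 28, 18, 33)
  d <- trial_dataset(df)
  res <- repeated_measures_anova(d, "acc", 2)

  odf <- data.frame(treatment = df$treatment,
                    subject = paste(df$treatment, df$replicate),
                    time = df$months_after_planting, y = df$height_cm)
  orc <- oracle_rm_ss(odf)
  expect_equal(res$treatment$ss_between, orc$ss_treat, tolerance = 1e-9)
  expect_equal(res$treatment$ss_within, orc$ss_subj_within, tolerance = 1e-9)
  expect_equal(res$time$ss_between, orc$ss_time, tolerance = 1e-9)
  expect_equal(res$interaction$ss_between, orc$ss_inter, tolerance = 1e-9)
  expect_equal(res$time$ss_within, orc$ss_err, tolerance = 1e-9)
})

test_that("duplicating every replicate doubles each SS component exactly", {
  cfg <- trial_sim_config(seed = 5, timepoints_months = c(15, 18))
  d <- simulate_trial(cfg)
  d2 <- as.data.frame(d)
  dup <- d2; dup$replicate <- dup$replicate + max(d2$replicate)
  dd <- trial_dataset(rbind(d2, dup))
  r1 <- repeated_measures_anova(d, "SYN-01", 2)
  r2 <- repeated_measures_anova(dd, "SYN-01", 2)
  for (comp in c("treatment", "time", "interaction")) {
    expect_equal(r2[[comp]]$ss_between, 2 * r1[[comp]]$ss_between,
                 tolerance = 1e-9)
    expect_equal(r2[[comp]]$ss_within, 2 * r1[[comp]]$ss_within,
                 tolerance = 1e-9)
  }
})

test_that("with no treatment effect the treatment F follows its null; time F is large", {
  f_treat <- f_time <- numeric(100)
  for (i in 1:100) {
    cfg <- trial_sim_config(
      seed = 1000 + i, timepoints_months = c(3, 6, 9, 12),
      monthly_growth_cm = c(control = 10, conventional = 10, organic = 10),
      replicate_sd_cm = 4, measurement_sd_cm = 4)
    res <- repeated_measures_anova(simulate_trial(cfg), "SYN-01", 1)
    f_treat[i] <- res$treatment$F
    f_time[i] <- res$time$F
  }
  null_median <- qf(0.5, 2, 12)
  expect_lt(abs(median(f_treat) - null_median), 0.3)
  expect_gt(median(f_time), 50)
})

test_that("unbalanced grids error by default and can be excluded listwise", {
  cfg <- trial_sim_config(seed = 3, timepoints_months = c(15, 18))
  d <- as.data.frame(simulate_trial(cfg))
  drop <- d$treatment == "control" & d$replicate == 1 &
    d$months_after_planting == 18
  d_unbal <- trial_dataset(d[!drop, ])
  err <- expect_error(repeated_measures_anova(d_unbal, "SYN-01", 2),
                      class = "nupeval_validation_error")
  expect_match(conditionMessage(err), "exclude")
  res <- repeated_measures_anova(d_unbal, "SYN-01", 2, incomplete = "exclude")
  expect_identical(res$n_subjects, 14L)
})

test_that("trial summaries use nearest-date matching and record fruit onset", {
  df <- expand.grid(replicate = 1:2, treatment = c("a", "b"),
                    months_after_planting = c(6.5, 17.8))
  df$species <- "s"; df$accession <- "g1"
  df$height_cm <- ifelse(df$months_after_planting < 10, 100, 145)
  df$fruiting <- df$months_after_planting > 10  # season 2 fruiting
  st <- summarize_trial(trial_dataset(df))
  expect_equal(unique(st$summaries$matched_month_6), 6.5)
  expect_equal(unique(st$summaries$matched_month_18), 17.8)
  expect_equal(unique(st$summaries$growth_rate_pct), 45)
  expect_identical(unique(st$summaries$fruit_onset_season), 2L)

  # a genotype never fruiting yields NA onset, which scores 0 on the rubric
  df$fruiting <- FALSE
  ri <- rubric_inputs_from_trial(trial_dataset(df))
  expect_true(is.na(ri$fruit_onset_season))
  expect_identical(score_value(default_scales()$fruit_onset,
                               ri$fruit_onset_season), 0L)

  # no measurement within one month of a required timepoint -> missing cell
  df2 <- df[df$months_after_planting < 10, ]
  st2 <- summarize_trial(trial_dataset(df2))
  expect_true(all(is.na(st2$summaries$matched_month_18)))
  expect_true(all(is.na(st2$summaries$growth_rate_pct)))
})

test_that("best-treatment table picks the tallest regime per genotype", {
  df <- expand.grid(replicate = 1:2, treatment = c("control", "organic"),
                    months_after_planting = c(6, 18))
  df$species <- "s"; df$accession <- "g1"
  df$height_cm <- with(df, ifelse(months_after_planting == 6, 100,
                                  ifelse(treatment == "organic", 200, 150)))
  st <- summarize_trial(trial_dataset(df))
  expect_identical(st$best_treatment$treatment, "organic")
  expect_equal(st$best_treatment$height_18m_cm, 200)
})
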