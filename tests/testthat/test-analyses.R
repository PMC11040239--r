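test_that("control scoring implements the 5-of-9 rule with its boundary", {
  ctl <- controls_with_scores(c(p_all = 9, p_four = 4, p_five = 5, p_zero = 0))
  res <- score_controls_and_exclude(ctl)
  sc <- setNames(res$scores$score, res$scores$participant_id)
  expect_equal(sc[["p_all"]], 9L)
  expect_equal(sc[["p_four"]], 4L)
  expect_setequal(res$included, c("p_all", "p_five"))  # 5 in, 4 out, "less than five"
  # malformed control sets are named
  expect_error(score_controls_and_exclude(ctl[-1, ]), "p_all")
})

test_that("the sampling matrix conserves the three choices per participant", {
  rows <- build_sampling_matrix(tiny_records())
  expect_equal(rows$times_sampled + rows$times_not_sampled, rep(3L, 12))
  expect_true(all(tapply(rows$times_sampled, rows$participant_id, sum) == 3))
  # sampled once -> (1, 2); never -> (0, 3); thrice -> (3, 0)
  expect_equal(rows$times_not_sampled[rows$times_sampled == 1], c(2L, 2L, 2L))
  p2 <- rows[rows$participant_id == "p2", ]
  expect_equal(sort(p2$times_sampled), c(0L, 0L, 0L, 0L, 0L, 3L))
  expect_equal(p2$times_not_sampled[p2$times_sampled == 3L], 0L)
  bad <- tiny_records()
  bad$times_sampled[1] <- 2L
  expect_error(build_sampling_matrix(bad), "p1")
})

test_that("chance_corrected_response reproduces hand-computed values", {
  # hand evaluation of (u_s/min(u_a,3) - u_a/6)/2 + 0.5:
  # 2 unknown, both sampled: (2/2 - 2/6)/2 + 0.5
  expect_equal(chance_corrected_response(c(0, 0, 1, 1, 1, 1), sampled = c(1, 2, 3)),
               (2 / 2 - 2 / 6) / 2 + 0.5)   # 0.8333...
  expect_equal(round(chance_corrected_response(c(0, 0, 1, 1, 1, 1), c(1, 2, 3)), 4),
               0.8333)
  # 3 unknown, none sampled: (0/3 - 3/6)/2 + 0.5 = 0.25
  expect_equal(chance_corrected_response(c(0, 0, 0, 1, 1, 1), sampled = c(4, 5, 6)),
               0.25)
  # 5 unknown, 3 sampled, cap active: (3/3 - 5/6)/2 + 0.5
  expect_equal(round(chance_corrected_response(c(0, 0, 0, 0, 0, 1), c(1, 2, 3)), 4),
               0.5833)
})

test_that("chance_corrected_response stays in (0,1), is antisymmetric, signals exclusions", {
  # enumerate all informative judgement profiles x all 3-subsets of 6 objects
  subsets <- combn(6, 3)
  for (u_avail in 1:5) {
    judgements <- c(rep(0, u_avail), rep(1, 6 - u_avail))
    for (j in seq_len(ncol(subsets))) {
      r <- chance_corrected_response(judgements, subsets[, j])
      expect_true(r > 0 && r < 1)
    }
    if (u_avail <= 3) {
      # extremes: sampling all unknowns vs none of them. Closed form derived
      # by hand: r_hi = (1 - u_a/6)/2 + 1/2, r_lo = (0 - u_a/6)/2 + 1/2, so
      # r_hi + r_lo = 3/2 - u_a/6 -- exactly 1 (mirror symmetry) only at
      # u_a = 3, where the availability proportion is 1/2
      r_hi <- chance_corrected_response(judgements, seq_len(u_avail))
      r_lo <- chance_corrected_response(judgements, 4:6)
      expect_equal(r_hi + r_lo, 3 / 2 - u_avail / 6, tolerance = 1e-12)
      if (u_avail == 3) expect_equal(r_hi, 1 - r_lo, tolerance = 1e-12)
    }
  }
  expect_error(chance_corrected_response(rep(1, 6), 1:3), class = "uds_exclusion")
  expect_error(chance_corrected_response(rep(0, 6), 1:3), class = "uds_exclusion")
})

test_that("overall accuracy model recovers a strong group and flags separation", {
  dat <- sim_group(n = 50, w = 0, seed = 31, p_learn = 1, p_correct_learned = 0.8,
                   sampling_boost = 0, sd_participant = 0.3, sd_object = 0.2)
  rep <- run_overall_accuracy(dat$records, "adult")
  expect_lt(abs(rep$fits$accuracy$estimates[["(Intercept)"]] - logit(0.8)), 0.45)
  expect_lt(rep$tests$chance_wald$p_value, 0.001)
  expect_equal(rep$chance_link, logit(1 / 6))
  # complete separation: all answers correct
  sat <- dat$records
  sat$test_correct <- 1L
  rep2 <- run_overall_accuracy(sat, "adult")
  expect_length(rep2$tests, 0)
  expect_match(rep2$notes, "separation")
})

test_that("confidence-accuracy analysis recovers calibration and reports the LRT", {
  dat <- sim_group(n = 120, w = 0, seed = 32, p_learn = 0.6,
                   p_sure_given_correct = 0.9, p_sure_given_incorrect = 0.5,
                   sd_participant = 0.3, sd_object = 0.2)
  rep <- run_confidence_accuracy(dat$records, "adult")
  expect_lt(rep$tests$lrt$p_value, 0.05)
  expect_lt(abs(rep$fitted_probs[["correct"]] - 0.9), 0.05)
  expect_lt(abs(rep$fitted_probs[["incorrect"]] - 0.5), 0.05)
  # constant rating is reported, not fitted
  flat <- dat$records
  flat$confidence_rating <- 1L
  rep2 <- run_confidence_accuracy(flat, "adult")
  expect_match(rep2$notes, "constant")
  expect_length(rep2$fits, 0)
})

test_that("bootstrap intervals for fitted confidence probabilities are ordered and cover the estimate", {
  dat <- sim_group(n = 40, w = 0, seed = 33, sd_participant = 0.3, sd_object = 0.2)
  rep <- run_confidence_accuracy(dat$records, "adult", include_random_slopes = FALSE,
                                 n_boot = 60, seed = 8)
  ci <- rep$intervals$fitted
  expect_equal(dim(ci), c(2L, 2L))
  expect_true(all(ci[, "lower"] <= ci[, "upper"]))
  expect_true(rep$fitted_probs[["incorrect"]] >= ci[1, "lower"] - 0.1 &&
                rep$fitted_probs[["incorrect"]] <= ci[1, "upper"] + 0.1)
})

test_that("sampling-benefit predictor is z-standardized over the analysis subset", {
  dat <- sim_group(n = 40, w = 0.5, seed = 34, p_learn = 0.5)
  for (mode in c("preregistered", "posthoc")) {
    rep <- run_sampling_accuracy(dat$records, "adult", mode)
    fitdat <- rep$fits$accuracy$model@frame
    z <- tapply(fitdat$prop_unknown_sampled_z, fitdat$participant_id, unique)
    expect_lt(abs(mean(z)), 1e-10)
    expect_lt(abs(sd(z) - 1), 1e-10)
    expect_equal(rep$n_included + rep$n_removed, 40L)
  }
})

test_that("posthoc mode removes zero-unknown participants and counts them", {
  dat <- sim_group(n = 40, w = 0, seed = 35, p_learn = 0.9,
                   judge_known_given_learned = 1, judge_known_given_unlearned = 0.4)
  rec <- dat$records
  u_avail <- tapply(rec$knowledge_judgement == 0, rec$participant_id, sum)
  n_zero <- sum(u_avail == 0)
  expect_gt(n_zero, 0)  # this config reliably produces all-known participants
  rep <- run_sampling_accuracy(rec, "adult", "posthoc")
  expect_equal(rep$n_removed, n_zero)
  fitdat <- rep$fits$accuracy$model@frame
  expect_false(any(names(u_avail)[u_avail == 0] %in% fitdat$participant_id))
})

test_that("interaction analysis separates shared and judgement-specific boosts", {
  # boost applies to every sampled object: main effect, no interaction
  dat <- sim_group(n = 120, w = 0, seed = 36, p_learn = 0.5,
                   p_correct_learned = 0.55, p_correct_unlearned_base = 0.25,
                   sampling_boost = 1.2, sd_participant = 0.3, sd_object = 0.2)
  rep <- run_sampling_interaction(dat$records, "adult")
  expect_lt(rep$tests$sampling_lrt$p_value, 0.05)
  expect_lt(rep$tests$sampling_wald_reduced$p_value, 0.05)
  expect_gt(rep$fits$reduced$estimates[["times_sampled"]], 0)
  # boost only for unlearned objects: interaction should surface
  dat2 <- sim_group(n = 150, w = 0, seed = 37, p_learn = 0.5,
                    judge_known_given_learned = 0.95, judge_known_given_unlearned = 0.05,
                    p_correct_learned = 0.85, p_correct_unlearned_base = 0.2,
                    sampling_boost = 2.5, boost_unlearned_only = TRUE,
                    sd_participant = 0.3, sd_object = 0.2)
  rep2 <- run_sampling_interaction(dat2$records, "adult")
  expect_lt(rep2$tests$interaction_wald$p_value, 0.05)
  # constant sampling counts are refused gracefully
  const <- dat$records
  const$times_sampled <- 0L
  expect_match(run_sampling_interaction(const, "adult")$notes, "constant")
  # fitted cell grid covers sampling 0-3 x judgement 0/1
  expect_equal(nrow(rep$fitted_cells), 8L)
  expect_true(all(rep$fitted_cells$fitted_prob > 0 & rep$fitted_cells$fitted_prob < 1))
})

test_that("chance-corrected beta analysis is null-calibrated and detects preference", {
  # null: w = 0. The statistic's chance expectation is 0.5 only for
  # participants with >= 3 unknown objects; for u_a in {1, 2} the
  # hypergeometric expectation of u_s (3 draws of 6) gives E[r] = 2/3 and
  # 7/12 (hand-derived: E[u_s] = u_a/2, so r = (1/2 - u_a/6)/2 + 1/2).
  dat0 <- sim_group(n = 400, w = 0, seed = 38, p_learn = 0.5)
  rep0 <- run_chance_corrected_beta(dat0$records, "adult")
  cc <- rep0$responses
  rec0 <- dat0$records
  u_a <- tapply(rec0$knowledge_judgement == 0, rec0$participant_id, sum)
  u_a <- u_a[cc$participant_id[!cc$excluded]]
  expected <- ifelse(u_a >= 3, 0.5, (1 / 2 - u_a / 6) / 2 + 0.5)
  resid <- cc$response[!cc$excluded] - expected
  expect_lt(abs(mean(resid)), 3 * sd(resid) / sqrt(length(resid)))
  # and exactly 0.5 in expectation on the u_a >= 3 subset
  sub <- cc$response[!cc$excluded][u_a >= 3]
  expect_lt(abs(mean(sub) - 0.5), 3 * sd(sub) / sqrt(length(sub)))
  expect_equal(rep0$n_included + rep0$n_removed, 400L)
  # strong preference: intercept significantly above 0
  dat1 <- sim_group(n = 60, w = 1.5, seed = 39, p_learn = 0.5)
  rep1 <- run_chance_corrected_beta(dat1$records, "adult")
  expect_gt(rep1$fits$beta$estimates[["(Intercept)"]], 0)
  expect_lt(rep1$tests$chance_wald$p_value, 0.05)
  expect_error(run_chance_corrected_beta(dat1$records[1:12, ], "adult"), ">= 5")
})
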