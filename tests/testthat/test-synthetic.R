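test_that("cohort truth generation matches its generative parameters", {
  p <- cohort_params(n_participants = 10000L, seed = 5)
  truth <- generate_truth(p)
  n_part <- length(unique(truth$participant_id))
  expect_equal(n_part, 10000L)
  # realized participant prevalence within 3 binomial SE of 0.074
  part_pos <- tapply(truth$true_label == "positive", truth$participant_id, any)
  se <- sqrt(0.074 * (1 - 0.074) / 10000)
  expect_lt(abs(mean(part_pos) - 0.074), 3 * se)
  # mean images per participant near 3.1
  expect_lt(abs(nrow(truth) / n_part - 3.1), 3 * sqrt(2.1 / 10000))
  # participant truth is the OR of image truth
  expect_equal(as.vector(part_pos[truth$participant_id]),
               truth$participant_true_label == "positive")
  # determinism
  expect_identical(truth, generate_truth(p))
  none <- generate_truth(cohort_params(n_participants = 500L,
                                       participant_prevalence = 0, seed = 1))
  expect_true(all(none$true_label == "negative"))
  expect_error(cohort_params(images_mean = 0.5), "images_mean")
  expect_error(cohort_params(participant_prevalence = 1.2), "participant_prevalence")
})

test_that("perfect graders reproduce the truth with no arbitration", {
  perfect <- list(primary1 = c(sensitivity = 1, specificity = 1),
                  primary2 = c(sensitivity = 1, specificity = 1),
                  arbiter = c(sensitivity = 1, specificity = 1))
  p <- cohort_params(n_participants = 2000L, grader_profiles = perfect, seed = 8)
  co <- simulate_grading(generate_truth(p), p)
  g <- co$gradable
  expect_equal(co$human_label[g], co$true_label[g])
  expect_false(any(co$label_provenance[g] == "arbiter"))
  expect_true(all(is.na(co$human_label[!g])))
})

test_that("two-stage label quality matches the closed-form workflow composition", {
  profiles <- list(primary1 = c(sensitivity = 0.85, specificity = 0.99),
                   primary2 = c(sensitivity = 0.85, specificity = 0.99),
                   arbiter = c(sensitivity = 1, specificity = 1))
  p <- cohort_params(n_participants = 60000L, grader_profiles = profiles,
                     ungradable_rate = 0, seed = 12)
  co <- simulate_grading(generate_truth(p), p)
  pos <- co$true_label == "positive"
  # analytic probability of a positive final label, per truth class
  p_pos_given_pos <- two_stage_positive_prob(0.85, 0.85, 1, 0.15)
  p_pos_given_neg <- two_stage_positive_prob(0.01, 0.01, 0, 0.15)
  obs_pos <- mean(co$human_label[pos] == "positive")
  obs_neg <- mean(co$human_label[!pos] == "positive")
  expect_lt(abs(obs_pos - p_pos_given_pos),
            3 * sqrt(p_pos_given_pos * (1 - p_pos_given_pos) / sum(pos)))
  expect_lt(abs(obs_neg - p_pos_given_neg),
            3 * sqrt(p_pos_given_neg * (1 - p_pos_given_neg) / sum(!pos)))
})

test_that("a full negative-regrade fraction double-reads every image", {
  p <- cohort_params(n_participants = 1000L, negative_regrade_fraction = 1,
                     seed = 4)
  co <- simulate_grading(generate_truth(p), p)
  g <- co$gradable
  expect_true(all(co$label_provenance[g] %in% c("primary2", "arbiter")))
})

test_that("two-stage grading improves label accuracy over one stage at screening prevalence", {
  for (sens in c(0.7, 0.85, 0.95)) {
    for (spec in c(0.85, 0.95, 0.99)) {
      prof <- c(sensitivity = sens, specificity = spec)
      p <- cohort_params(n_participants = 15000L,
                         grader_profiles = list(primary1 = prof, primary2 = prof,
                                                arbiter = prof),
                         ungradable_rate = 0, seed = 100 + round(100 * sens + spec))
      truth <- generate_truth(p)
      two <- simulate_grading(truth, p)
      acc_two <- mean(two$human_label == two$true_label)
      # single-grader workflow: stage 1 alone; expected accuracy in closed form
      pos <- truth$true_label == "positive"
      acc_one <- mean(pos) * sens + mean(!pos) * spec
      expect_gte(acc_two + 3 * sqrt(acc_two * (1 - acc_two) / nrow(truth)), acc_one)
    }
  }
})

test_that("simulated classifier attains its operating point and score contract", {
  p <- cohort_params(n_participants = 17000L, ungradable_rate = 0, seed = 21)
  co <- simulate_classifier(generate_truth(p), p)
  pos <- co$true_label == "positive"
  sens_obs <- mean(co$classifier_label[pos] == "positive")
  spec_obs <- mean(co$classifier_label[!pos] == "negative")
  expect_lt(abs(sens_obs - 0.925), 3 * sqrt(0.925 * 0.075 / sum(pos)))
  expect_lt(abs(spec_obs - 0.985), 3 * sqrt(0.985 * 0.015 / sum(!pos)))
  # label consistent with the score at the 0.5 threshold
  expect_equal(co$classifier_label == "positive", co$classifier_score >= 0.5)
  # perfect operating point -> AUROC 1
  pp <- cohort_params(n_participants = 2000L, classifier_sensitivity = 1,
                      classifier_specificity = 1, ungradable_rate = 0, seed = 2)
  cop <- simulate_classifier(generate_truth(pp), pp)
  expect_equal(compute_auroc(cop$classifier_score, cop$true_label), 1)
  # symmetric operating point -> sens ~ spec
  ps <- cohort_params(n_participants = 20000L, classifier_sensitivity = 0.9,
                      classifier_specificity = 0.9, ungradable_rate = 0, seed = 3)
  cos <- simulate_classifier(generate_truth(ps), ps)
  pos <- cos$true_label == "positive"
  expect_lt(abs(mean(cos$classifier_label[pos] == "positive") -
                mean(cos$classifier_label[!pos] == "negative")), 0.02)
})

test_that("the truth oracle returns truth by default and composes reader errors", {
  p <- cohort_params(n_participants = 3000L, seed = 31)
  co <- simulate_cohort(p)
  v <- truth_oracle(co)
  expect_equal(v$final_verdict, co$true_label)
  perfect <- list(reader1 = c(sensitivity = 1, specificity = 1),
                  reader2 = c(sensitivity = 1, specificity = 1),
                  arbiter = c(sensitivity = 1, specificity = 1))
  expect_equal(truth_oracle(co, perfect, seed = 2)$final_verdict, co$true_label)
  # imperfect readers: verdict-positive rate per class matches the analytic
  # two-reader + arbiter composition q^2 + 2q(1-q)q_arb
  prof <- list(reader1 = c(sensitivity = 0.9, specificity = 0.95),
               reader2 = c(sensitivity = 0.9, specificity = 0.95),
               arbiter = c(sensitivity = 0.98, specificity = 0.99))
  big <- simulate_cohort(cohort_params(n_participants = 30000L,
                                       ungradable_rate = 0, seed = 32))
  vv <- truth_oracle(big, prof, seed = 3)
  pos <- big$true_label == "positive"
  comp <- function(q, qa) q^2 + 2 * q * (1 - q) * qa
  exp_pos <- comp(0.9, 0.98)
  exp_neg <- comp(0.05, 0.01)
  obs_pos <- mean(vv$final_verdict[pos] == "positive")
  obs_neg <- mean(vv$final_verdict[!pos] == "positive")
  expect_lt(abs(obs_pos - exp_pos), 3 * sqrt(exp_pos * (1 - exp_pos) / sum(pos)))
  expect_lt(abs(obs_neg - exp_neg), 3 * sqrt(exp_neg * (1 - exp_neg) / sum(!pos)))
  expect_error(truth_oracle(big[, c("image_id", "human_label")]), "hidden truth")
})

test_that("cohort simulation is a pure function of parameters and seed", {
  p <- cohort_params(n_participants = 1500L, seed = 99)
  expect_identical(simulate_cohort(p), simulate_cohort(p))
  p2 <- cohort_params(n_participants = 1500L, seed = 100)
  expect_false(identical(simulate_cohort(p)$human_label,
                         simulate_cohort(p2)$human_label))
})

test_that("a large default cohort supports a faithful end-to-end audit", {
  # single large-cohort spot check (~200k images); the replicated recovery
  # property lives in the acceptance suite at a smaller per-replicate size
  p <- cohort_params(n_participants = 65000L, seed = 2024)
  co <- simulate_cohort(p)
  expect_gt(nrow(co), 180000)
  g <- co[co$gradable, ]
  truth <- g$true_label
  names(truth) <- g$image_id
  strata <- discrepancy_strata(g, level = "image")
  for (nm in c("fn", "fp")) {
    s <- strata[[nm]]
    samp <- draw_sample(s, fraction = if (nm == "fn") 0.10 else 0.05, seed = 7)
    samp <- ingest_verdicts(samp, data.frame(
      unit_id = samp$sampled_ids,
      final_verdict = unname(truth[samp$sampled_ids]),
      stringsAsFactors = FALSE))
    est <- estimate_error_rate(samp)
    stratum_rate <- mean(truth[s$unit_ids] != s$human_label)
    expect_gte(stratum_rate, est$ci_low)
    expect_lte(stratum_rate, est$ci_high)
  }
})

test_that("difficulty effect induces correlated grader and classifier errors", {
  base <- cohort_params(n_participants = 25000L, ungradable_rate = 0,
                        difficulty_sd = 2, seed = 55)
  co <- simulate_cohort(base)
  grader_err <- co$human_label != co$true_label
  cls_err <- co$classifier_label != co$true_label
  # among truth-negative images, errors co-occur more than independence predicts
  neg <- co$true_label == "negative"
  p_joint <- mean(grader_err[neg] & cls_err[neg])
  p_indep <- mean(grader_err[neg]) * mean(cls_err[neg])
  expect_gt(p_joint, p_indep)
  # labels remain consistent with scores relative to the threshold
  expect_equal(co$classifier_label == "positive", co$classifier_score >= 0.5)
})
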