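#' Parameters of a synthetic screening cohort
#'
#' Bundles every generative knob of the simulated screening program:
#' participants contributing a small number of fundus images, referable
#' disease nested within participants, a two-stage human grading workflow
#' with per-grader operating points, and a classifier with a configurable
#' operating point emitting continuous scores.
#'
#' Defaults emulate the scale ratios and label quality of a large
#' real-world program: ~3.1 images per participant, 7.4% truly referable
#' participants with 84% of a referable participant's images showing
#' referable disease (image prevalence ~6.2%), 10% ungradable images, a
#' classifier at sensitivity 0.925 / specificity 0.985, and primary graders
#' at 0.91/0.91 with a 0.98/0.998 arbiter and 15% of stage-1 negatives
#' re-read — a workflow whose final labels run at ~92% sensitivity with a
#' ~0.9% wrong-positive rate, i.e. an overall label-error rate near 1.3%.
#'
#' @param n_participants number of participants (>= 1).
#' @param images_mean mean images per participant (>= 1); counts are drawn
#'   as `1 + Poisson(images_mean - 1)`.
#' @param participant_prevalence probability a participant carries referable
#'   disease.
#' @param image_positive_rate probability each image of a referable
#'   participant shows referable disease (no positive images occur in
#'   non-referable participants).
#' @param grader_profiles list with elements `primary1`, `primary2`,
#'   `arbiter`, each a named vector `c(sensitivity =, specificity =)`.
#' @param negative_regrade_fraction fraction of stage-1 negatives re-read by
#'   the second primary grader (stage-1 positives are always re-read).
#' @param classifier_sensitivity,classifier_specificity classifier operating
#'   point at the 0.5 score threshold.
#' @param ungradable_rate probability an image fails quality control.
#' @param difficulty_sd standard deviation of an optional per-image
#'   "difficulty" effect on the logit of every grader's error probability
#'   (and of the classifier's); 0 (default) makes all errors independent.
#' @param seed integer master seed.
#' @return an object of class `cohort_params`.
#' @export
cohort_params <- function(n_participants = 20000L,
                          images_mean = 3.1,
                          participant_prevalence = 0.074,
                          image_positive_rate = 0.84,
                          grader_profiles = list(
                            primary1 = c(sensitivity = 0.91, specificity = 0.91),
                            primary2 = c(sensitivity = 0.91, specificity = 0.91),
                            arbiter = c(sensitivity = 0.98, specificity = 0.998)
                          ),
                          negative_regrade_fraction = 0.15,
                          classifier_sensitivity = 0.925,
                          classifier_specificity = 0.985,
                          ungradable_rate = 0.10,
                          difficulty_sd = 0,
                          seed = 1L) {
  if (n_participants < 1) stop("n_participants must be >= 1", call. = FALSE)
  if (images_mean < 1) stop("images_mean must be >= 1 (every participant contributes an image)",
                            call. = FALSE)
  stopifnot_probability(participant_prevalence, "participant_prevalence")
  stopifnot_probability(image_positive_rate, "image_positive_rate")
  stopifnot_probability(negative_regrade_fraction, "negative_regrade_fraction")
  stopifnot_probability(classifier_sensitivity, "classifier_sensitivity")
  stopifnot_probability(classifier_specificity, "classifier_specificity")
  stopifnot_probability(ungradable_rate, "ungradable_rate")
  if (difficulty_sd < 0) stop("difficulty_sd must be >= 0", call. = FALSE)
  for (g in c("primary1", "primary2", "arbiter")) {
    prof <- grader_profiles[[g]]
    if (is.null(prof) || !all(c("sensitivity", "specificity") %in% names(prof))) {
      stop(sprintf("grader_profiles$%s must provide sensitivity and specificity", g),
           call. = FALSE)
    }
    stopifnot_probability(prof[["sensitivity"]], paste0(g, " sensitivity"))
    stopifnot_probability(prof[["specificity"]], paste0(g, " specificity"))
  }
  structure(list(
    n_participants = as.integer(n_participants), images_mean = images_mean,
    participant_prevalence = participant_prevalence,
    image_positive_rate = image_positive_rate,
    grader_profiles = grader_profiles,
    negative_regrade_fraction = negative_regrade_fraction,
    classifier_sensitivity = classifier_sensitivity,
    classifier_specificity = classifier_specificity,
    ungradable_rate = ungradable_rate,
    difficulty_sd = difficulty_sd,
    seed = as.integer(seed)
  ), class = "cohort_params")
}

# One grader's (or reader's) binary calls given image truth, optionally
# modulated by a per-image difficulty shift on the logit of the error
# probability. Exact when difficulty_sd = 0 (perfect graders stay perfect).
rater_calls <- function(truth_pos, profile, z = NULL) {
  err <- ifelse(truth_pos, 1 - profile[["sensitivity"]], 1 - profile[["specificity"]])
  if (!is.null(z)) {
    clamped <- pmin(pmax(err, 1e-12), 1 - 1e-12)
    adj <- stats::plogis(stats::qlogis(clamped) + z)
    adj[err == 0] <- 0
    adj[err == 1] <- 1
    err <- adj
  }
  wrong <- stats::runif(length(truth_pos)) < err
  xor(truth_pos, wrong)  # TRUE = calls positive
}

#' Generate cohort ground truth
#'
#' Draws participants, their image counts, the hidden true referable status
#' of every image, and gradability flags. A participant's true status is the
#' OR of their images' true status.
#'
#' @param params a [cohort_params()] object.
#' @param seed seed (defaults to `params$seed`).
#' @return data frame with `image_id`, `participant_id`, `gradable`
#'   (logical), `true_label`, `participant_true_label`.
#' @export
generate_truth <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "cohort_params"))
  with_seed(seed, {
    n_img <- 1L + stats::rpois(params$n_participants, params$images_mean - 1)
    at_risk <- stats::runif(params$n_participants) < params$participant_prevalence
    pid <- sprintf("P%07d", seq_len(params$n_participants))
    participant_of <- rep.int(seq_len(params$n_participants), n_img)
    img_seq <- sequence(n_img)
    total <- length(participant_of)
    true_pos <- at_risk[participant_of] &
      stats::runif(total) < params$image_positive_rate
    gradable <- stats::runif(total) >= params$ungradable_rate
    part_pos <- tapply(true_pos, participant_of, any)
    data.frame(
      image_id = paste0(pid[participant_of], "_I", img_seq),
      participant_id = pid[participant_of],
      gradable = gradable,
      true_label = ifelse(true_pos, POSITIVE, NEGATIVE),
      participant_true_label = ifelse(part_pos[participant_of], POSITIVE, NEGATIVE),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate the two-stage human grading workflow
#'
#' Stage 1: a primary grader labels every gradable image by flipping the
#' truth with probability `1 - sensitivity` (positives) or
#' `1 - specificity` (negatives). Stage 2: all stage-1 positives plus a
#' seeded random fraction of stage-1 negatives are re-read by a second
#' primary grader; any disagreement goes to an arbiter whose call is final.
#'
#' @param cohort output of [generate_truth()].
#' @param params a [cohort_params()] object.
#' @param seed seed (defaults to `params$seed + 1`).
#' @return the cohort with `human_label` (`NA` for ungradable images) and
#'   `label_provenance` (`"primary1"`, `"primary2"` or `"arbiter"`).
#' @export
simulate_grading <- function(cohort, params, seed = params$seed + 1L) {
  stopifnot(inherits(params, "cohort_params"))
  g <- cohort$gradable
  truth_pos <- cohort$true_label == POSITIVE & g
  n <- nrow(cohort)
  with_seed(seed, {
    z <- if (params$difficulty_sd > 0) stats::rnorm(n, 0, params$difficulty_sd) else NULL
    s1 <- rater_calls(truth_pos, params$grader_profiles$primary1, z)
    reviewed <- g & (s1 | stats::runif(n) < params$negative_regrade_fraction)
    s2 <- rater_calls(truth_pos, params$grader_profiles$primary2, z)
    arb <- rater_calls(truth_pos, params$grader_profiles$arbiter, z)
    final <- s1
    agree <- reviewed & (s2 == s1)
    disagree <- reviewed & (s2 != s1)
    final[disagree] <- arb[disagree]
    provenance <- rep("primary1", n)
    provenance[agree] <- "primary2"
    provenance[disagree] <- "arbiter"
    cohort$human_label <- ifelse(final, POSITIVE, NEGATIVE)
    cohort$human_label[!g] <- NA_character_
    cohort$label_provenance <- provenance
    cohort$label_provenance[!g] <- NA_character_
    cohort
  })
}

# Class-conditional score family: positives ~ Beta(a, 1), negatives
# ~ Beta(1, b), with a and b solved so that P(score >= 0.5 | positive) =
# sensitivity and P(score >= 0.5 | negative) = 1 - specificity exactly.
# Degenerate operating points (0 or 1) fall back to uniforms on one side of
# the threshold.
score_shapes <- function(sens, spec) {
  list(a = if (sens > 0 && sens < 1) log(1 - sens) / log(0.5) else NA_real_,
       b = if (spec > 0 && spec < 1) log(1 - spec) / log(0.5) else NA_real_)
}

draw_scores <- function(truth_pos, sens, spec) {
  n <- length(truth_pos)
  sh <- score_shapes(sens, spec)
  score <- numeric(n)
  npos <- sum(truth_pos); nneg <- n - npos
  score[truth_pos] <- if (is.na(sh$a)) {
    if (sens >= 1) stats::runif(npos, 0.5, 1) else stats::runif(npos, 0, 0.5)
  } else stats::rbeta(npos, sh$a, 1)
  score[!truth_pos] <- if (is.na(sh$b)) {
    if (spec >= 1) stats::runif(nneg, 0, 0.5) else stats::runif(nneg, 0.5, 1)
  } else stats::rbeta(nneg, 1, sh$b)
  score
}

#' Simulate the classifier's scores and labels
#'
#' Scores are drawn from two class-conditional beta distributions calibrated
#' so that thresholding at 0.5 attains the requested sensitivity and
#' specificity in expectation; the binary label is `score >= 0.5`. With a
#' non-zero `difficulty_sd` the label is instead drawn by flipping the truth
#' with a difficulty-modulated error probability (shared with the graders'
#' difficulty effect) and the score is drawn from the calibrated family
#' truncated to the side of the threshold matching the label.
#'
#' @param cohort output of [generate_truth()] (grading columns optional).
#' @param params a [cohort_params()] object.
#' @param seed seed (defaults to `params$seed + 2`).
#' @return the cohort with `classifier_score` and `classifier_label`
#'   (`NA` for ungradable images).
#' @export
simulate_classifier <- function(cohort, params, seed = params$seed + 2L) {
  stopifnot(inherits(params, "cohort_params"))
  g <- cohort$gradable
  truth_pos <- cohort$true_label == POSITIVE
  n <- nrow(cohort)
  sens <- params$classifier_sensitivity
  spec <- params$classifier_specificity
  with_seed(seed, {
    if (params$difficulty_sd > 0) {
      z <- stats::rnorm(n, 0, params$difficulty_sd)
      called_pos <- rater_calls(truth_pos, c(sensitivity = sens, specificity = spec), z)
      sh <- score_shapes(sens, spec)
      a <- ifelse(truth_pos, if (is.na(sh$a)) 1 else sh$a, 1)
      b <- ifelse(truth_pos, 1, if (is.na(sh$b)) 1 else sh$b)
      p_mid <- stats::pbeta(0.5, a, b)
      u <- stats::runif(n)
      q <- ifelse(called_pos, p_mid + u * (1 - p_mid), u * p_mid)
      score <- stats::qbeta(q, a, b)
    } else {
      score <- draw_scores(truth_pos, sens, spec)
      called_pos <- score >= 0.5
    }
    cohort$classifier_score <- ifelse(g, score, NA_real_)
    cohort$classifier_label <- ifelse(g, ifelse(called_pos, POSITIVE, NEGATIVE),
                                      NA_character_)
    cohort
  })
}

#' Generate a complete synthetic screening cohort
#'
#' Chains [generate_truth()], [simulate_grading()] and
#' [simulate_classifier()] under seeds derived from `params$seed`; a pure
#' function of its arguments.
#'
#' @param params a [cohort_params()] object.
#' @return data frame with ids, gradability, human label and provenance,
#'   classifier score/label, and the hidden truth columns `true_label` and
#'   `participant_true_label`.
#' @export
simulate_cohort <- function(params) {
  cohort <- generate_truth(params)
  cohort <- simulate_grading(cohort, params)
  simulate_classifier(cohort, params)
}

#' Adjudication verdicts from the hidden truth
#'
#' Stands in for the masked expert adjudication panel: by default the final
#' verdict for every image equals the hidden true status. Supplying
#' `adjudicator_profiles` (named vectors as in [cohort_params()], elements
#' `reader1`, `reader2`, `arbiter`) instead corrupts the verdicts through a
#' two-reader-plus-arbiter workflow.
#'
#' @param cohort a cohort carrying `true_label`.
#' @param adjudicator_profiles optional list of reader operating points.
#' @param seed seed for the corrupted workflow.
#' @return verdict table: `image_id`, `final_verdict` (plus `reader1`,
#'   `reader2` when profiles are supplied).
#' @export
truth_oracle <- function(cohort, adjudicator_profiles = NULL, seed = 1L) {
  if (!"true_label" %in% names(cohort)) {
    stop("cohort does not carry hidden truth ('true_label')", call. = FALSE)
  }
  if (is.null(adjudicator_profiles)) {
    return(data.frame(image_id = cohort$image_id,
                      final_verdict = cohort$true_label,
                      stringsAsFactors = FALSE))
  }
  for (r in c("reader1", "reader2", "arbiter")) {
    if (is.null(adjudicator_profiles[[r]])) {
      stop(sprintf("adjudicator_profiles must provide '%s'", r), call. = FALSE)
    }
  }
  truth_pos <- cohort$true_label == POSITIVE
  with_seed(seed, {
    r1 <- rater_calls(truth_pos, adjudicator_profiles$reader1)
    r2 <- rater_calls(truth_pos, adjudicator_profiles$reader2)
    arb <- rater_calls(truth_pos, adjudicator_profiles$arbiter)
    final <- ifelse(r1 == r2, r1, arb)
    data.frame(image_id = cohort$image_id,
               reader1 = ifelse(r1, POSITIVE, NEGATIVE),
               reader2 = ifelse(r2, POSITIVE, NEGATIVE),
               final_verdict = ifelse(final, POSITIVE, NEGATIVE),
               stringsAsFactors = FALSE)
  })
}
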