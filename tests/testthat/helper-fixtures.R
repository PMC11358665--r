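# Published screening-program counts used as worked-example inputs.
image_counts <- function() {
  list(tp = 36401, fp = 57886, tn = 632457, fn = 9339,
       k_fn = 560, n_fn = 880, k_fp = 140, n_fp = 2710)
}
participant_counts <- function() {
  list(tp = 15236, fp = 33878, tn = 186648, fn = 2062,
       k_fn = 128, n_fn = 195, k_fp = 85, n_fp = 1657)
}

# Independent oracle: AUROC by exhaustive enumeration of all
# positive/negative pairs, ties counting 1/2.
brute_auroc <- function(scores, labels) {
  pos <- scores[labels == "positive"]
  neg <- scores[labels == "negative"]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Independent oracle: confusion cells by an explicit double loop.
brute_confusion <- function(cls, hum) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(cls)) {
    if (cls[i] == "positive" && hum[i] == "positive") tp <- tp + 1L
    if (cls[i] == "positive" && hum[i] == "negative") fp <- fp + 1L
    if (cls[i] == "negative" && hum[i] == "negative") tn <- tn + 1L
    if (cls[i] == "negative" && hum[i] == "positive") fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Closed-form probability that the two-stage workflow emits a positive
# label, given per-rater probabilities of calling positive (q1, q2 primaries,
# q3 arbiter) and the negative re-grade fraction r. Derived by enumerating
# the workflow paths: stage-1 positives are always re-read (agree -> stand,
# disagree -> arbiter); stage-1 negatives are re-read with probability r.
two_stage_positive_prob <- function(q1, q2, q3, r) {
  q1 * (q2 + (1 - q2) * q3) + (1 - q1) * r * q2 * q3
}

# Small record table with known structure for aggregation/IO tests.
toy_records <- function() {
  data.frame(
    image_id = sprintf("img%02d", 1:9),
    participant_id = c("A", "A", "A", "B", "B", "C", "C", "C", "D"),
    gradable = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    human_label = c("negative", "positive", "negative",
                    "negative", "negative",
                    "positive", "negative", "negative",
                    "positive"),
    classifier_score = c(0.1, 0.9, 0.2, 0.3, 0.4, 0.05, 0.6, 0.7, 0.8),
    stringsAsFactors = FALSE
  )
}
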