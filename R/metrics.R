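#' Binarize a 5-level diabetic retinopathy grade
#'
#' NHS screening grades are collapsed to the referable/non-referable
#' dichotomy: R2 (preproliferative), R3s (static proliferative) and R3a
#' (active proliferative) are referable ("positive"); R0 (no DR) and R1
#' (background DR) are non-referable ("negative").
#'
#' @param grade character vector of grades among `R0`, `R1`, `R2`, `R3s`,
#'   `R3a`. `NA` is preserved.
#' @return character vector of `"positive"`/`"negative"`.
#' @examples
#' binarize_grade(c("R0", "R1", "R2", "R3s", "R3a"))
#' @export
binarize_grade <- function(grade) {
  if (is.factor(grade)) grade <- as.character(grade)
  valid <- c("R0", "R1", "R2", "R3s", "R3a")
  bad <- !is.na(grade) & !grade %in% valid
  if (any(bad)) {
    stop(sprintf("unknown DR grade(s): %s (expected one of %s)",
                 paste(unique(grade[bad]), collapse = ", "),
                 paste(valid, collapse = ", ")), call. = FALSE)
  }
  out <- ifelse(grade %in% c("R2", "R3s", "R3a"), POSITIVE, NEGATIVE)
  out[is.na(grade)] <- NA_character_
  out
}

#' Aggregate image-level records to participant level
#'
#' A participant is positive (for the human label and for the classifier
#' independently) if at least one of their gradable images is positive.
#' Participants without any gradable image are excluded and counted.
#'
#' @param records data frame with columns `participant_id`, `gradable`
#'   (logical), `human_label`, `classifier_label` (binary labels in any
#'   encoding accepted by [as_binary_label()]).
#' @return data frame with one row per retained participant:
#'   `participant_id`, `human_label`, `classifier_label`, `n_images`,
#'   `n_gradable`. The number of excluded participants (all images
#'   ungradable) is attached as attribute `n_excluded` and reported via
#'   `message()`.
#' @export
aggregate_participants <- function(records) {
  required <- c("participant_id", "gradable", "human_label", "classifier_label")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("records is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0L) {
    warning("aggregate_participants(): empty input, returning empty output")
    out <- data.frame(participant_id = character(), human_label = character(),
                      classifier_label = character(), n_images = integer(),
                      n_gradable = integer(), stringsAsFactors = FALSE)
    attr(out, "n_excluded") <- 0L
    return(out)
  }
  gradable <- as.logical(records$gradable)
  human <- as_binary_label(records$human_label, "human_label")
  cls <- as_binary_label(records$classifier_label, "classifier_label")

  pid <- as.character(records$participant_id)
  n_images <- tapply(pid, pid, length)
  g_split <- split(gradable, pid)
  h_split <- split(human == POSITIVE, pid)
  c_split <- split(cls == POSITIVE, pid)

  ids <- names(g_split)
  n_gradable <- vapply(g_split, sum, integer(1))
  keep <- n_gradable > 0L
  n_excluded <- sum(!keep)
  if (n_excluded > 0L) {
    message(sprintf("aggregate_participants(): excluded %d participant(s) with no gradable image",
                    n_excluded))
  }
  or_over_gradable <- function(lab, grd) any(lab[grd], na.rm = FALSE)
  human_pos <- mapply(or_over_gradable, h_split, g_split)
  cls_pos <- mapply(or_over_gradable, c_split, g_split)

  out <- data.frame(
    participant_id = ids[keep],
    human_label = ifelse(human_pos[keep], POSITIVE, NEGATIVE),
    classifier_label = ifelse(cls_pos[keep], POSITIVE, NEGATIVE),
    n_images = as.integer(n_images[keep]),
    n_gradable = as.integer(n_gradable[keep]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Confusion-matrix counts
#'
#' Container for the four cells of a binary confusion matrix, oriented so
#' that "positive" always means referable disease and FN/FP are defined
#' against the human label (FN = classifier negative & label positive,
#' FP = classifier positive & label negative). Cells may be real-valued:
#' corrected matrices carry fractional expected counts internally.
#'
#' @param tp,fp,tn,fn non-negative cell counts.
#' @param level `"image"` or `"participant"`.
#' @return an object of class `confusion_counts` with elements `tp`, `fp`,
#'   `tn`, `fn`, `level`, plus derived `n`, `label_positive`,
#'   `label_negative`, `pred_positive`, `pred_negative`.
#' @export
confusion_counts <- function(tp, fp, tn, fn, level = c("image", "participant")) {
  level <- match.arg(level)
  cells <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop("confusion cells must be finite and non-negative", call. = FALSE)
  }
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn, level = level,
    n = tp + fp + tn + fn,
    label_positive = tp + fn, label_negative = tn + fp,
    pred_positive = tp + fp, pred_negative = tn + fn
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts (%s level, n = %s)\n", x$level, format(x$n)))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2,
              dimnames = list(classifier = c("positive", "negative"),
                              label = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Tally a confusion matrix from paired binary labels
#'
#' @param classifier_label,human_label equal-length vectors of binary labels.
#' @param level `"image"` or `"participant"`.
#' @param unit_id optional unit identifiers used in error messages.
#' @return a [confusion_counts()] object.
#' @export
build_confusion <- function(classifier_label, human_label,
                            level = c("image", "participant"),
                            unit_id = NULL) {
  level <- match.arg(level)
  cls <- as_binary_label(classifier_label, "classifier_label")
  hum <- as_binary_label(human_label, "human_label")
  if (length(cls) != length(hum)) {
    stop("classifier and human label vectors differ in length", call. = FALSE)
  }
  bad <- which(is.na(cls) | is.na(hum))
  if (length(bad)) {
    ids <- if (is.null(unit_id)) paste("row", bad) else unit_id[bad]
    stop("missing label(s) for unit(s): ",
         paste(utils::head(ids, 10L), collapse = ", "),
         if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L),
         call. = FALSE)
  }
  confusion_counts(
    tp = sum(cls == POSITIVE & hum == POSITIVE),
    fp = sum(cls == POSITIVE & hum == NEGATIVE),
    tn = sum(cls == NEGATIVE & hum == NEGATIVE),
    fn = sum(cls == NEGATIVE & hum == POSITIVE),
    level = level
  )
}

#' Diagnostic performance metrics from a confusion matrix
#'
#' Sensitivity (recall), specificity, precision, accuracy and the F1-score.
#' A metric whose denominator is zero is reported as `NA` with a warning,
#' never as 0 or 1.
#'
#' @param cm a [confusion_counts()] object.
#' @param auroc optional area under the ROC curve (see [compute_auroc()]),
#'   carried alongside the threshold metrics.
#' @return an object of class `metrics_set`.
#' @export
compute_metrics <- function(cm, auroc = NA_real_) {
  stopifnot(inherits(cm, "confusion_counts"))
  safe_ratio <- function(num, den, what) {
    if (den <= 0) {
      warning(sprintf("%s undefined (zero denominator); reported as NA", what),
              call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  sens <- safe_ratio(cm$tp, cm$tp + cm$fn, "sensitivity")
  spec <- safe_ratio(cm$tn, cm$tn + cm$fp, "specificity")
  prec <- safe_ratio(cm$tp, cm$tp + cm$fp, "precision")
  acc <- safe_ratio(cm$tp + cm$tn, cm$n, "accuracy")
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens <= 0) {
    NA_real_
  } else {
    2 * prec * sens / (prec + sens)
  }
  structure(list(accuracy = acc, precision = prec, sensitivity = sens,
                 specificity = spec, f1 = f1, auroc = auroc, level = cm$level),
            class = "metrics_set")
}

#' @export
print.metrics_set <- function(x, ...) {
  cat(sprintf("Diagnostic metrics (%s level)\n", x$level))
  vals <- c(accuracy = x$accuracy, precision = x$precision,
            sensitivity = x$sensitivity, specificity = x$specificity,
            f1 = x$f1)
  for (nm in names(vals)) {
    cat(sprintf("  %-12s %s%%\n", nm,
                ifelse(is.na(vals[[nm]]), "NA",
                       format(round_half_up(100 * vals[[nm]], 1), nsmall = 1))))
  }
  if (!is.na(x$auroc)) cat(sprintf("  %-12s %.3f\n", "AUROC", x$auroc))
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Equals the probability that a random positive unit scores higher than a
#' random negative unit, with ties contributing 1/2 — the Mann-Whitney U
#' statistic normalised by `n_pos * n_neg`, computed from midranks.
#'
#' @param scores numeric vector of classifier scores.
#' @param labels binary labels, same length.
#' @return AUROC in \[0, 1\].
#' @export
compute_auroc <- function(scores, labels) {
  lab <- as_binary_label(labels, "labels")
  if (length(scores) != length(lab)) stop("scores and labels differ in length", call. = FALSE)
  keep <- !is.na(scores) & !is.na(lab)
  scores <- scores[keep]; lab <- lab[keep]
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  pos <- lab == POSITIVE
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUROC is undefined: need at least one positive and one negative label",
         call. = FALSE)
  }
  r <- rank(scores)  # midranks handle ties
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
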