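#' Read and validate an image-record table
#'
#' Reads the delimited-text (CSV, header required, UTF-8) per-image schema:
#' one row per image with columns `image_id`, `participant_id`, `gradable`,
#' a human label (`human_grade` in R0..R3a, or `human_label`), and a
#' classifier output (`classifier_score` in \[0, 1\] and/or
#' `classifier_label`). When only `human_grade` is present the binary label
#' is derived with [binarize_grade()]; when only `classifier_score` is
#' present the binary prediction is `score >= threshold`.
#'
#' @param path CSV path (or a data frame already in memory, validated the
#'   same way).
#' @param threshold score threshold for deriving `classifier_label`
#'   (default 0.5).
#' @return validated data frame with columns `image_id`, `participant_id`,
#'   `gradable` (logical), `human_label`, `classifier_score` (possibly
#'   `NA`), `classifier_label`.
#' @export
read_image_records <- function(path, threshold = 0.5) {
  stopifnot_probability(threshold, "threshold")
  records <- if (is.data.frame(path)) path else {
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  }
  if (nrow(records) == 0L) stop("input contains no records", call. = FALSE)
  required <- c("image_id", "participant_id", "gradable")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records$image_id <- as.character(records$image_id)
  records$participant_id <- as.character(records$participant_id)
  dup <- unique(records$image_id[duplicated(records$image_id)])
  if (length(dup)) {
    stop("duplicate image_id(s): ", paste(utils::head(dup, 10L), collapse = ", "),
         call. = FALSE)
  }
  records$gradable <- as.logical(records$gradable)
  if (anyNA(records$gradable)) {
    stop("column 'gradable' must be logical (TRUE/FALSE) with no missing values; rows: ",
         paste(utils::head(which(is.na(records$gradable)), 10L), collapse = ", "),
         call. = FALSE)
  }

  if ("human_label" %in% names(records)) {
    records$human_label <- as_binary_label(records$human_label, "human_label")
  } else if ("human_grade" %in% names(records)) {
    records$human_label <- binarize_grade(records$human_grade)
  } else {
    stop("need a 'human_grade' or 'human_label' column", call. = FALSE)
  }

  has_score <- "classifier_score" %in% names(records)
  has_label <- "classifier_label" %in% names(records)
  if (!has_score && !has_label) {
    stop("need a 'classifier_score' and/or 'classifier_label' column", call. = FALSE)
  }
  if (has_score) {
    s <- records$classifier_score
    bad <- which(!is.na(s) & (s < 0 | s > 1))
    if (length(bad)) {
      stop("classifier_score outside [0, 1]; rows: ",
           paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
    }
  } else {
    records$classifier_score <- NA_real_
  }
  if (has_label) {
    records$classifier_label <- as_binary_label(records$classifier_label,
                                                "classifier_label")
    derive <- is.na(records$classifier_label) & !is.na(records$classifier_score)
    records$classifier_label[derive] <-
      ifelse(records$classifier_score[derive] >= threshold, POSITIVE, NEGATIVE)
  } else {
    records$classifier_label <- ifelse(is.na(records$classifier_score), NA_character_,
                                       ifelse(records$classifier_score >= threshold,
                                              POSITIVE, NEGATIVE))
  }

  g <- records$gradable
  bad_h <- which(g & is.na(records$human_label))
  if (length(bad_h)) {
    stop("gradable record(s) without a human label; rows: ",
         paste(utils::head(bad_h, 10L), collapse = ", "), call. = FALSE)
  }
  bad_c <- which(g & is.na(records$classifier_label))
  if (length(bad_c)) {
    stop("gradable record(s) without classifier score or label; rows: ",
         paste(utils::head(bad_c, 10L), collapse = ", "), call. = FALSE)
  }
  records
}

#' Read an adjudication verdict table
#'
#' CSV with a unit id column (`unit_id`, `image_id` or `participant_id`) and
#' `final_verdict` in positive/negative; optional `reader1`/`reader2`
#' columns pass through (used only for disagreement logging).
#'
#' @param path CSV path.
#' @return validated verdict data frame.
#' @export
read_verdicts <- function(path) {
  v <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  id_col <- intersect(c("unit_id", "image_id", "participant_id"), names(v))[1]
  if (is.na(id_col) || !"final_verdict" %in% names(v)) {
    stop("verdict table needs a unit id column and 'final_verdict'", call. = FALSE)
  }
  v[[id_col]] <- as.character(v[[id_col]])
  v$final_verdict <- as_binary_label(v$final_verdict, "final_verdict")
  v
}

#' Export a sample manifest for hand-off to adjudicators
#'
#' @param sample an `adjudication_sample`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_sample_manifest <- function(sample, path) {
  stopifnot(inherits(sample, "adjudication_sample"))
  utils::write.csv(
    data.frame(unit_id = sample$sampled_ids, stratum = sample$stratum,
               level = sample$level, human_label = sample$human_label,
               seed = sample$seed, stringsAsFactors = FALSE),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Emits the public per-image CSV (the schema read back by
#' [read_image_records()]) and a hidden-truth sidecar CSV intended for
#' testing only.
#'
#' @param cohort output of [simulate_cohort()].
#' @param path public cohort CSV path.
#' @param truth_path sidecar CSV path (`NULL` to skip).
#' @return named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, path, truth_path = NULL) {
  public_cols <- c("image_id", "participant_id", "gradable",
                   "human_label", "classifier_score", "classifier_label")
  utils::write.csv(cohort[, public_cols], path, row.names = FALSE, quote = FALSE)
  written <- c(cohort = path)
  if (!is.null(truth_path)) {
    truth_cols <- intersect(c("image_id", "participant_id", "true_label",
                              "participant_true_label", "label_provenance"),
                            names(cohort))
    utils::write.csv(cohort[, truth_cols], truth_path, row.names = FALSE,
                     quote = FALSE)
    written <- c(written, truth = truth_path)
  }
  invisible(written)
}
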