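#' Discrepancy (and concordant) strata of a labelled data set
#'
#' Partitions units into the four confusion cells and returns the requested
#' cells as sampling strata. The two discrepancy strata drive label-error
#' estimation: `FN_stratum` holds classifier-negative/label-positive units,
#' `FP_stratum` classifier-positive/label-negative units. Concordant cells
#' (`TP_stratum`, `TN_stratum`) can also be requested for spot checks.
#'
#' @param records data frame with `human_label`, `classifier_label` and a
#'   unit id column (`image_id` or `participant_id`, picked by `level`).
#' @param level `"image"` or `"participant"`.
#' @param cells which confusion cells to return, subset of
#'   `c("fn", "fp", "tp", "tn")`.
#' @return named list of `discrepancy_stratum` objects (`name`, `unit_ids`,
#'   `size`, `human_label`, `level`).
#' @export
discrepancy_strata <- function(records, level = c("image", "participant"),
                               cells = c("fn", "fp")) {
  level <- match.arg(level)
  cells <- match.arg(cells, c("fn", "fp", "tp", "tn"), several.ok = TRUE)
  id_col <- paste0(level, "_id")
  if (!id_col %in% names(records)) {
    stop(sprintf("records must carry a '%s' column at the %s level", id_col, level),
         call. = FALSE)
  }
  ids <- as.character(records[[id_col]])
  if (anyDuplicated(ids)) stop("unit ids must be unique within a data set", call. = FALSE)
  cls <- as_binary_label(records$classifier_label, "classifier_label")
  hum <- as_binary_label(records$human_label, "human_label")
  pick <- list(
    fn = cls == NEGATIVE & hum == POSITIVE,
    fp = cls == POSITIVE & hum == NEGATIVE,
    tp = cls == POSITIVE & hum == POSITIVE,
    tn = cls == NEGATIVE & hum == NEGATIVE
  )
  human_of <- c(fn = POSITIVE, fp = NEGATIVE, tp = POSITIVE, tn = NEGATIVE)
  out <- lapply(cells, function(cell) {
    uid <- ids[pick[[cell]]]
    structure(list(name = paste0(toupper(cell), "_stratum"),
                   unit_ids = uid, size = length(uid),
                   human_label = human_of[[cell]], level = level),
              class = "discrepancy_stratum")
  })
  names(out) <- cells
  out
}

#' Construct a sampling stratum directly
#'
#' @param name stratum name, conventionally `"FN_stratum"` or `"FP_stratum"`.
#' @param unit_ids unique unit identifiers.
#' @param human_label the (single) human label shared by the stratum's units.
#' @param level `"image"` or `"participant"`.
#' @return a `discrepancy_stratum` object.
#' @export
new_stratum <- function(name, unit_ids,
                        human_label = if (grepl("^FN|^TP", name)) POSITIVE else NEGATIVE,
                        level = "image") {
  unit_ids <- as.character(unit_ids)
  if (anyDuplicated(unit_ids)) stop("stratum unit ids must be unique", call. = FALSE)
  structure(list(name = name, unit_ids = unit_ids, size = length(unit_ids),
                 human_label = as_binary_label(human_label, "human_label"),
                 level = level),
            class = "discrepancy_stratum")
}

#' Draw a reproducible adjudication sample from a stratum
#'
#' Uniform sampling without replacement. Fractional requests use the ceiling
#' rule (`n = ceiling(fraction * size)`). Sampling is applied to the sorted
#' unit ids so the draw is invariant to the input row order.
#'
#' @param stratum a `discrepancy_stratum`.
#' @param fraction sampling fraction in (0, 1\]; give either this or `count`.
#' @param count absolute sample size.
#' @param seed integer seed; recorded in the sample object.
#' @return an `adjudication_sample` with verdicts pending
#'   (`k_overturned = NA`).
#' @export
draw_sample <- function(stratum, fraction = NULL, count = NULL, seed = 1L) {
  stopifnot(inherits(stratum, "discrepancy_stratum"))
  if (is.null(fraction) == is.null(count)) {
    stop("give exactly one of 'fraction' or 'count'", call. = FALSE)
  }
  n <- if (!is.null(fraction)) {
    stopifnot_probability(fraction, "fraction")
    if (fraction <= 0) stop("fraction must be positive", call. = FALSE)
    as.integer(ceiling(fraction * stratum$size))
  } else {
    as.integer(count)
  }
  if (n < 1L) stop("requested sample size must be at least 1", call. = FALSE)
  if (n > stratum$size) {
    stop(sprintf(
      "requested %d units but %s holds only %d; adjudicate the full stratum (census) instead",
      n, stratum$name, stratum$size), call. = FALSE)
  }
  ids <- sort(stratum$unit_ids)
  sampled <- with_seed(seed, sample(ids, n))
  structure(list(stratum = stratum$name, human_label = stratum$human_label,
                 level = stratum$level, stratum_size = stratum$size,
                 sampled_ids = sampled, n = n, k_overturned = NA_integer_,
                 seed = as.integer(seed)),
            class = "adjudication_sample")
}

#' @export
print.adjudication_sample <- function(x, ...) {
  cat(sprintf("Adjudication sample: %d of %d units from %s (%s level, seed %d)\n",
              x$n, x$stratum_size, x$stratum, x$level, x$seed))
  if (!is.na(x$k_overturned)) {
    cat(sprintf("  verdicts ingested: %d of %d labels overturned (%.1f%%)\n",
                x$k_overturned, x$n, 100 * x$k_overturned / x$n))
  } else {
    cat("  verdicts pending\n")
  }
  invisible(x)
}

#' Ingest adjudication verdicts into a sample
#'
#' Matches one final binary verdict to every sampled unit and counts the
#' overturned labels: units whose final verdict contradicts the stratum's
#' human label (and hence agrees with the classifier).
#'
#' @param sample an `adjudication_sample` from [draw_sample()].
#' @param verdicts data frame with a unit id column (`unit_id`, `image_id`
#'   or `participant_id`) and `final_verdict` (binary label). Extra rows for
#'   units outside the sample are rejected; `reader1`/`reader2` columns, if
#'   present, are only used to report the disagreement count.
#' @return the sample with `k_overturned` filled in.
#' @export
ingest_verdicts <- function(sample, verdicts) {
  stopifnot(inherits(sample, "adjudication_sample"))
  id_col <- intersect(c("unit_id", "image_id", "participant_id"), names(verdicts))[1]
  if (is.na(id_col)) {
    stop("verdict table needs a 'unit_id', 'image_id' or 'participant_id' column",
         call. = FALSE)
  }
  if (!"final_verdict" %in% names(verdicts)) {
    stop("verdict table needs a 'final_verdict' column", call. = FALSE)
  }
  ids <- as.character(verdicts[[id_col]])
  foreign <- setdiff(ids, sample$sampled_ids)
  if (length(foreign)) {
    stop("verdict table contains unit(s) not in the sample: ",
         paste(utils::head(foreign, 10L), collapse = ", "), call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate verdict(s) for unit(s): ",
         paste(utils::head(dup, 10L), collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(sample$sampled_ids, ids)
  if (length(absent)) {
    stop("missing verdict(s) for sampled unit(s): ",
         paste(utils::head(absent, 10L), collapse = ", "), call. = FALSE)
  }
  verdict <- as_binary_label(verdicts$final_verdict, "final_verdict")
  if (anyNA(verdict)) stop("final_verdict must not be missing", call. = FALSE)
  if (all(c("reader1", "reader2") %in% names(verdicts))) {
    r1 <- as_binary_label(verdicts$reader1, "reader1")
    r2 <- as_binary_label(verdicts$reader2, "reader2")
    message(sprintf("ingest_verdicts(): %d of %d verdicts required arbitration",
                    sum(r1 != r2, na.rm = TRUE), length(verdict)))
  }
  sample$k_overturned <- sum(verdict != sample$human_label)
  sample
}

#' Estimate a stratum label-error rate
#'
#' The proportion of adjudicated units whose human label was overturned,
#' with a binomial interval. Tagged `fnr` for the FN stratum and `fpr` for
#' the FP stratum (label-error rates, not classifier error rates).
#'
#' @param sample a completed `adjudication_sample` (verdicts ingested).
#' @param conf_level confidence level.
#' @param method interval method, see [binomial_interval()].
#' @return a `rate_estimate`.
#' @export
estimate_error_rate <- function(sample, conf_level = 0.95,
                                method = "clopper_pearson") {
  stopifnot(inherits(sample, "adjudication_sample"))
  if (is.na(sample$k_overturned)) {
    stop("verdicts have not been ingested for this sample", call. = FALSE)
  }
  tag <- switch(sample$stratum, FN_stratum = "fnr", FP_stratum = "fpr",
                paste0(tolower(sub("_stratum$", "", sample$stratum)), "_error_rate"))
  binomial_interval(sample$k_overturned, sample$n, conf_level = conf_level,
                    method = method, rate_name = tag)
}

#' Subsample-size stability analysis
#'
#' Repeatedly draws seeded subsamples of each requested size, adjudicates
#' them against an oracle verdict table, and summarises the distribution of
#' the estimated error rate per size — used to judge how small an
#' adjudication sample can be while still representing the stratum.
#'
#' @param stratum a `discrepancy_stratum`.
#' @param sizes integer vector of sample sizes (each <= stratum size).
#' @param replicates number of subsamples per size (>= 2).
#' @param seed master seed; replicate seeds are derived from it.
#' @param oracle verdict table covering every stratum unit (columns as in
#'   [ingest_verdicts()]).
#' @return data frame with one row per size: `size`, `replicates`, `mean`,
#'   `sd`, and the 2.5/25/50/75/97.5 percentiles of the estimated rate.
#' @export
stability_analysis <- function(stratum, sizes, replicates, seed, oracle) {
  stopifnot(inherits(stratum, "discrepancy_stratum"))
  if (replicates < 2) stop("replicates must be >= 2", call. = FALSE)
  if (any(sizes < 1) || any(sizes > stratum$size)) {
    stop("every size must be between 1 and the stratum size", call. = FALSE)
  }
  id_col <- intersect(c("unit_id", "image_id", "participant_id"), names(oracle))[1]
  if (is.na(id_col) || !"final_verdict" %in% names(oracle)) {
    stop("oracle must be a verdict table with a unit id and 'final_verdict'",
         call. = FALSE)
  }
  oracle_ids <- as.character(oracle[[id_col]])
  absent <- setdiff(stratum$unit_ids, oracle_ids)
  if (length(absent)) {
    stop("oracle is missing true status for unit(s): ",
         paste(utils::head(absent, 10L), collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_along(sizes), function(i) {
    size <- sizes[i]
    est <- vapply(seq_len(replicates), function(j) {
      s <- draw_sample(stratum, count = size,
                       seed = seed + (i - 1L) * replicates + j)
      idx <- match(s$sampled_ids, oracle_ids)
      s <- ingest_verdicts(s, data.frame(unit_id = s$sampled_ids,
                                         final_verdict = oracle$final_verdict[idx],
                                         stringsAsFactors = FALSE))
      s$k_overturned / s$n
    }, numeric(1))
    q <- stats::quantile(est, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
    data.frame(size = size, replicates = replicates,
               mean = mean(est), sd = stats::sd(est),
               q2.5 = q[1], q25 = q[2], median = q[3], q75 = q[4], q97.5 = q[5])
  })
  do.call(rbind, rows)
}
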