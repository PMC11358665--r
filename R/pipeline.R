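SCHEMA_VERSION <- "1.0"

#' Evaluate a classifier against the (pre-correction) human labels
#'
#' Confusion counts and diagnostic metrics at the image level (gradable
#' images only; AUROC when scores are available) and/or the participant
#' level (labels aggregated by [aggregate_participants()]).
#'
#' @param input path to a per-image CSV or a data frame, validated by
#'   [read_image_records()].
#' @param level `"image"`, `"participant"` or `"both"`.
#' @param threshold score threshold passed to [read_image_records()].
#' @param out_dir optional directory; when given, a JSON report and a CSV
#'   metric summary are written there.
#' @return a list of class `evaluation_report` with elements
#'   `schema_version`, and per level `confusion` and `metrics`.
#' @export
run_evaluate <- function(input, level = c("both", "image", "participant"),
                         threshold = 0.5, out_dir = NULL) {
  level <- match.arg(level)
  records <- read_image_records(input, threshold = threshold)
  report <- list(schema_version = SCHEMA_VERSION, threshold = threshold)
  g <- records$gradable
  if (level %in% c("both", "image")) {
    cm <- build_confusion(records$classifier_label[g], records$human_label[g],
                          level = "image", unit_id = records$image_id[g])
    auroc <- if (any(!is.na(records$classifier_score[g]))) {
      compute_auroc(records$classifier_score[g], records$human_label[g])
    } else NA_real_
    report$image <- list(confusion = cm, metrics = compute_metrics(cm, auroc = auroc))
  }
  if (level %in% c("both", "participant")) {
    parts <- aggregate_participants(records)
    cm <- build_confusion(parts$classifier_label, parts$human_label,
                          level = "participant", unit_id = parts$participant_id)
    report$participant <- list(confusion = cm, metrics = compute_metrics(cm),
                               n_excluded = attr(parts, "n_excluded"))
  }
  class(report) <- "evaluation_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report_json(report, file.path(out_dir, "evaluation.json"))
    write_metrics_csv(report, file.path(out_dir, "evaluation.csv"))
  }
  report
}

#' Draw the FN- and FP-stratum adjudication samples
#'
#' @param records validated per-image records (or participant-level pairs).
#' @param level `"image"` or `"participant"`; participant-level strata are
#'   built from aggregated labels.
#' @param fn_fraction,fp_fraction sampling fractions for the two strata
#'   (ceiling rule; realized sizes are recorded and used downstream).
#' @param seed master seed; the FP draw uses `seed + 1`.
#' @return list with `strata` and pending `fn_sample`, `fp_sample`.
#' @export
draw_audit_samples <- function(records, level = c("image", "participant"),
                               fn_fraction = 0.10, fp_fraction = 0.05,
                               seed = 1L) {
  level <- match.arg(level)
  units <- if (level == "participant" && !"participant_label_pair" %in% names(records)) {
    if ("image_id" %in% names(records)) aggregate_participants(records) else records
  } else {
    records[records$gradable, , drop = FALSE]
  }
  strata <- discrepancy_strata(units, level = level)
  list(strata = strata,
       fn_sample = draw_sample(strata$fn, fraction = fn_fraction, seed = seed),
       fp_sample = draw_sample(strata$fp, fraction = fp_fraction, seed = seed + 1L))
}

#' Full label-error audit from per-unit records and verdicts
#'
#' Orchestrates the audit: evaluate against the raw labels, draw the two
#' discrepancy-stratum samples, ingest the adjudication verdicts, estimate
#' the stratum error rates, correct the labels and re-estimate the metrics,
#' and (when a laboratory operating point is supplied) report the gap
#' analysis. Verdict tables may cover more units than sampled (e.g. a full
#' truth sidecar); they are subset to the sampled ids.
#'
#' @param input path or data frame of per-image records.
#' @param verdicts verdict table (data frame or CSV path) covering at least
#'   every sampled unit at the requested level.
#' @param level `"image"` or `"participant"`.
#' @param fn_fraction,fp_fraction stratum sampling fractions.
#' @param seed master seed (sampling and bootstrap).
#' @param conf_level,ci_method interval settings, see [binomial_interval()].
#' @param lab_sensitivity,lab_specificity optional laboratory reference
#'   operating point for the gap analysis.
#' @param bootstrap_replicates replicates for [propagate_uncertainty()].
#' @param out_dir optional output directory (JSON report, CSV summary and
#'   sample manifests).
#' @return a `label_audit_report` list, see [audit_from_counts()].
#' @export
run_audit <- function(input, verdicts, level = c("image", "participant"),
                      fn_fraction = 0.10, fp_fraction = 0.05, seed = 1L,
                      conf_level = 0.95, ci_method = "clopper_pearson",
                      lab_sensitivity = NULL, lab_specificity = NULL,
                      bootstrap_replicates = 1000L, out_dir = NULL) {
  level <- match.arg(level)
  records <- read_image_records(input)
  if (is.character(verdicts)) verdicts <- read_verdicts(verdicts)

  units <- if (level == "participant") aggregate_participants(records)
           else records[records$gradable, , drop = FALSE]
  id_col <- paste0(level, "_id")
  cm <- build_confusion(units$classifier_label, units$human_label,
                        level = level, unit_id = units[[id_col]])
  strata <- discrepancy_strata(units, level = level)
  fn_sample <- draw_sample(strata$fn, fraction = fn_fraction, seed = seed)
  fp_sample <- draw_sample(strata$fp, fraction = fp_fraction, seed = seed + 1L)

  vid_col <- intersect(c("unit_id", "image_id", "participant_id"), names(verdicts))[1]
  take <- function(sample) {
    idx <- match(sample$sampled_ids, as.character(verdicts[[vid_col]]))
    if (anyNA(idx)) {
      stop("verdict table is missing sampled unit(s): ",
           paste(utils::head(sample$sampled_ids[is.na(idx)], 10L), collapse = ", "),
           call. = FALSE)
    }
    ingest_verdicts(sample, data.frame(unit_id = sample$sampled_ids,
                                       final_verdict = verdicts$final_verdict[idx],
                                       stringsAsFactors = FALSE))
  }
  fn_sample <- take(fn_sample)
  fp_sample <- take(fp_sample)

  report <- build_audit_report(
    cm = cm,
    fnr = estimate_error_rate(fn_sample, conf_level, ci_method),
    fpr = estimate_error_rate(fp_sample, conf_level, ci_method),
    lab_sensitivity = lab_sensitivity, lab_specificity = lab_specificity,
    bootstrap_replicates = bootstrap_replicates, seed = seed,
    conf_level = conf_level,
    seeds = list(fn_sample = fn_sample$seed, fp_sample = fp_sample$seed,
                 bootstrap = as.integer(seed)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_sample_manifest(fn_sample, file.path(out_dir, "fn_sample_manifest.csv"))
    write_sample_manifest(fp_sample, file.path(out_dir, "fp_sample_manifest.csv"))
    write_report_json(report, file.path(out_dir, "audit.json"))
    write_audit_csv(report, file.path(out_dir, "audit_summary.csv"))
  }
  report
}

#' Label-error audit from the eight printed integers (cells-only mode)
#'
#' The whole correction is identified by the four confusion cells and the
#' two adjudicated counts, so a published audit can be reproduced without
#' any per-image table: supply `tp, fp, tn, fn` and the overturned/sampled
#' counts of each stratum.
#'
#' @param tp,fp,tn,fn pre-correction confusion cells (positive = referable).
#' @param k_fn,n_fn overturned and sampled counts in the FN stratum.
#' @param k_fp,n_fp overturned and sampled counts in the FP stratum.
#' @param level `"image"` or `"participant"`.
#' @param conf_level,ci_method interval settings.
#' @param lab_sensitivity,lab_specificity optional laboratory operating
#'   point for the gap analysis.
#' @param bootstrap_replicates,seed uncertainty-propagation settings.
#' @param out_dir optional output directory.
#' @return a list of class `label_audit_report`: pre-correction `confusion`
#'   and `metrics`, stratum `error_rates`, the `correction`
#'   ([correct_labels()]), propagated `uncertainty`, `gap` (or `NULL`),
#'   pre/post `comparisons` (chi-square on sensitivity, specificity,
#'   accuracy), and the seeds/method tags.
#' @export
audit_from_counts <- function(tp, fp, tn, fn, k_fn, n_fn, k_fp, n_fp,
                              level = c("image", "participant"),
                              conf_level = 0.95, ci_method = "clopper_pearson",
                              lab_sensitivity = NULL, lab_specificity = NULL,
                              bootstrap_replicates = 1000L, seed = 1L,
                              out_dir = NULL) {
  level <- match.arg(level)
  cm <- confusion_counts(tp, fp, tn, fn, level = level)
  report <- build_audit_report(
    cm = cm,
    fnr = binomial_interval(k_fn, n_fn, conf_level, ci_method, rate_name = "fnr"),
    fpr = binomial_interval(k_fp, n_fp, conf_level, ci_method, rate_name = "fpr"),
    lab_sensitivity = lab_sensitivity, lab_specificity = lab_specificity,
    bootstrap_replicates = bootstrap_replicates, seed = seed,
    conf_level = conf_level,
    seeds = list(bootstrap = as.integer(seed)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report_json(report, file.path(out_dir, "audit.json"))
    write_audit_csv(report, file.path(out_dir, "audit_summary.csv"))
  }
  report
}

build_audit_report <- function(cm, fnr, fpr, lab_sensitivity, lab_specificity,
                               bootstrap_replicates, seed, conf_level, seeds) {
  pre_metrics <- compute_metrics(cm)
  correction <- correct_labels(cm, fnr, fpr)
  unc <- propagate_uncertainty(cm, fnr, fpr, method = "bootstrap",
                               replicates = bootstrap_replicates, seed = seed,
                               conf_level = conf_level)
  correction$overall_error_rate <- unc$overall_error_rate
  post_cm <- correction$corrected_cm
  comparisons <- list(
    sensitivity = compare_proportions(cm$tp, cm$label_positive,
                                      post_cm$tp, post_cm$label_positive),
    specificity = compare_proportions(cm$tn, cm$label_negative,
                                      post_cm$tn, post_cm$label_negative),
    accuracy = compare_proportions(cm$tp + cm$tn, cm$n,
                                   post_cm$tp + post_cm$tn, post_cm$n)
  )
  gap <- if (!is.null(lab_sensitivity) && !is.null(lab_specificity)) {
    gap_analysis(pre_metrics, correction$corrected_metrics,
                 lab_sensitivity, lab_specificity)
  } else NULL
  structure(list(
    schema_version = SCHEMA_VERSION, level = cm$level,
    pre = list(confusion = cm, metrics = pre_metrics),
    error_rates = list(fnr = fnr, fpr = fpr),
    correction = correction, uncertainty = unc,
    gap = gap, comparisons = comparisons,
    continuity_correction = FALSE, seeds = seeds
  ), class = "label_audit_report")
}

#' @export
print.label_audit_report <- function(x, ...) {
  cat(sprintf("=== Label-error audit (%s level) ===\n", x$level))
  cat("\n-- Pre-correction --\n")
  print(x$pre$metrics)
  cat("\n-- Stratum label-error rates --\n")
  print(x$error_rates$fnr); print(x$error_rates$fpr)
  cat("\n-- Correction --\n")
  print(x$correction)
  if (!is.null(x$gap)) { cat("\n"); print(x$gap) }
  invisible(x)
}

#' Generate a synthetic cohort run directory
#'
#' Writes the public cohort CSV, the hidden-truth sidecar, a JSON echo of
#' the generative parameters and a run manifest. Byte-identical on rerun
#' with the same parameters.
#'
#' @param params a [cohort_params()] object.
#' @param out_dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
run_simulate <- function(params, out_dir) {
  stopifnot(inherits(params, "cohort_params"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(params)
  paths <- write_cohort(cohort, file.path(out_dir, "cohort.csv"),
                        file.path(out_dir, "cohort_truth.csv"))
  params_path <- file.path(out_dir, "params.json")
  jsonlite::write_json(unclass(params), params_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(schema_version = SCHEMA_VERSION,
                            seed = params$seed,
                            n_images = nrow(cohort),
                            n_participants = params$n_participants,
                            files = basename(c(paths, params = params_path))),
                       manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, params = params_path, manifest = manifest_path))
}

#' Write a report as structured JSON
#'
#' @param report any report list produced by this package.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}

metrics_column <- function(cm, metrics) {
  pct <- function(x) if (is.na(x)) NA_real_ else round_half_up(100 * x, 1)
  c(positive_labels = round_half_up(cm$label_positive),
    negative_labels = round_half_up(cm$label_negative),
    tp = round_half_up(cm$tp), fp = round_half_up(cm$fp),
    tn = round_half_up(cm$tn), fn = round_half_up(cm$fn),
    accuracy_pct = pct(metrics$accuracy),
    precision_pct = pct(metrics$precision),
    sensitivity_pct = pct(metrics$sensitivity),
    specificity_pct = pct(metrics$specificity),
    f1_pct = pct(metrics$f1))
}

#' Write the audit summary CSV (pre/post metric table)
#'
#' @param report a `label_audit_report`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_audit_csv <- function(report, path) {
  pre <- metrics_column(report$pre$confusion, report$pre$metrics)
  post <- metrics_column(report$correction$corrected_cm,
                         report$correction$corrected_metrics)
  utils::write.csv(data.frame(quantity = names(pre), precorrection = unname(pre),
                              postcorrection = unname(post),
                              stringsAsFactors = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the evaluation metric summary CSV
#'
#' @param report an `evaluation_report` from [run_evaluate()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_metrics_csv <- function(report, path) {
  cols <- list()
  for (lv in c("image", "participant")) {
    if (!is.null(report[[lv]])) {
      cols[[lv]] <- metrics_column(report[[lv]]$confusion, report[[lv]]$metrics)
    }
  }
  df <- data.frame(quantity = names(cols[[1]]), stringsAsFactors = FALSE)
  for (lv in names(cols)) df[[lv]] <- unname(cols[[lv]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
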