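# End-to-end orchestration: synth -> extract -> cross-validate, with a
# self-describing output directory (config echo + package version +
# seed) and a JSON-lines audit log so fold disjointness and feature
# drop lists are machine-checkable. The command-line entry point in
# inst/cli/pacdetect.R is a thin optparse wrapper over these functions.

.log_jsonl <- function(path, event, ...) {
  rec <- c(list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                event = event), list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
      sep = "", file = path, append = TRUE)
}

.echo_config <- function(dir, cfg_list) {
  jsonlite::write_json(
    c(list(package = "pacdetect",
           version = as.character(utils::packageVersion("pacdetect"))),
      cfg_list),
    file.path(dir, "run_config.json"), auto_unbox = TRUE, digits = NA)
}

#' Generate a synthetic cohort on disk
#'
#' @param out_dir output directory (one record fixture set per
#'   patient).
#' @param n_patients cohort size.
#' @param seed master seed.
#' @param n_beats beats per record.
#' @return invisible vector of record base paths.
#' @export
run_synth <- function(out_dir, n_patients = 20L, seed = 1L,
                      n_beats = 300L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(n_patients, seed = seed, n_beats = n_beats)
  paths <- vapply(cohort, function(g) write_fixture(g, out_dir), "")
  .echo_config(out_dir, list(stage = "synth", n_patients = n_patients,
                             seed = seed, n_beats = n_beats))
  invisible(paths)
}

#' Extract the feature matrix from a directory of records
#'
#' Every record found in `records_dir` (CSV-with-sidecar or WFDB; the
#' CSV form is preferred when both exist) is preprocessed and turned
#' into per-beat feature vectors. Records that are too short are warned
#' about and skipped; the run continues.
#'
#' @param records_dir directory of record fixtures.
#' @param out_csv output CSV path (`NULL` = no file, return only).
#' @param cfg a [preprocess_config].
#' @param morph_cfg a [morph_config].
#' @param log_path optional JSON-lines audit log.
#' @return the pooled feature data.frame, invisibly when `out_csv` is
#'   given.
#' @export
run_extract <- function(records_dir, out_csv = NULL,
                        cfg = preprocess_config(),
                        morph_cfg = morph_config(), log_path = NULL) {
  bases <- unique(c(
    sub("\\.json$", "", list.files(records_dir, "\\.json$",
                                   full.names = TRUE)),
    sub("\\.hea$", "", list.files(records_dir, "\\.hea$",
                                  full.names = TRUE))))
  bases <- bases[file.exists(paste0(bases, ".csv")) |
                   file.exists(paste0(bases, ".hea"))]
  if (length(bases) == 0L) stop(sprintf("no records found in %s", records_dir))
  out <- list()
  for (b in sort(bases)) {
    rec <- if (file.exists(paste0(b, ".csv"))) {
      read_record(paste0(b, ".csv"))
    } else {
      read_record(b)
    }
    ann_path <- if (file.exists(paste0(b, ".atr.csv"))) {
      paste0(b, ".atr.csv")
    } else paste0(b, ".atr")
    ann <- read_annotations(ann_path, rec)
    pp <- preprocess_record(rec, ann, cfg)
    feat <- tryCatch(
      assemble_features(pp$record, pp$annotations, morph_cfg),
      warning = function(w) {
        message(sprintf("skipping %s: %s", basename(b), conditionMessage(w)))
        NULL
      })
    if (is.null(feat) || nrow(feat) == 0L) next
    message(sprintf("extracted %s: %d beats -> %d feature rows",
                    basename(b), nrow(ann), nrow(feat)))
    if (!is.null(log_path)) {
      .log_jsonl(log_path, "extract", record = basename(b),
                 n_beats = nrow(ann), n_rows = nrow(feat))
    }
    out[[length(out) + 1L]] <- feat
  }
  features <- do.call(rbind, out)
  if (!is.null(out_csv)) {
    write_features_csv(features, out_csv)
    return(invisible(features))
  }
  features
}

#' Cross-validate a feature matrix and write a report
#'
#' Delegates to [cross_validate()] and writes `metrics.json`,
#' `predictions.csv`, `confusion.csv`, `importances.csv`, per-fold
#' prediction CSVs, an `audit.jsonl` log and the config echo into
#' `out_dir`.
#'
#' @param features feature data.frame or path to a features CSV.
#' @param out_dir report directory.
#' @param mode `"multiclass"` or `"binary"`.
#' @param k folds.
#' @param seed master seed.
#' @param cap per-class training cap.
#' @return the `cv_result`, invisibly.
#' @export
run_cv <- function(features, out_dir, mode = c("multiclass", "binary"),
                   k = 10L, seed = 20210616L, cap = 10000L) {
  mode <- match.arg(mode)
  if (is.character(features)) features <- read_features_csv(features)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- cross_validate(features, k = k, cfg = rf_config(seed = seed),
                        mode = mode, cap = cap)
  log_path <- file.path(out_dir, "audit.jsonl")
  if (file.exists(log_path)) file.remove(log_path)
  for (a in res$audit) {
    .log_jsonl(log_path, "fold", fold = a$fold, disjoint = a$disjoint,
               n_train = a$n_train, n_test = a$n_test,
               n_features = a$n_features, dropped_var = a$dropped_var,
               dropped_corr = a$dropped_corr,
               train_patients = a$train_patients,
               test_patients = a$test_patients)
  }
  jsonlite::write_json(
    list(mode = mode, k = k,
         beat_wise = list(
           per_class = res$beat_metrics$per_class,
           confusion_pct = as.data.frame(res$beat_metrics$confusion_pct)),
         patient_wise = res$patient_metrics),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  write.csv(res$predictions, file.path(out_dir, "predictions.csv"),
            row.names = FALSE)
  for (f in sort(unique(res$predictions$fold))) {
    write.csv(res$predictions[res$predictions$fold == f, , drop = FALSE],
              file.path(out_dir, sprintf("predictions_fold%02d.csv", f)),
              row.names = FALSE)
  }
  write.csv(as.data.frame(res$beat_metrics$confusion_pct),
            file.path(out_dir, "confusion.csv"), row.names = FALSE)
  write.csv(res$importances, file.path(out_dir, "importances.csv"),
            row.names = FALSE)
  .echo_config(out_dir, list(stage = "cv", mode = mode, k = k, seed = seed,
                             cap = cap))
  invisible(res)
}

#' Run the whole pipeline (synth -> extract -> cv)
#'
#' Reproduces the package's parameter-recovery check in one call:
#' generate a heterogeneous synthetic cohort, extract features, run
#' patient-wise cross-validation and write the report.
#'
#' @param out_dir output directory (`records/`, `features.csv`,
#'   `report/`).
#' @param n_patients,n_beats cohort shape.
#' @param k folds.
#' @param mode classifier mode.
#' @param seed master seed.
#' @param dry_run if `TRUE`, print the resolved stage plan and do
#'   nothing.
#' @return the `cv_result`, invisibly (`NULL` for a dry run).
#' @export
run_all <- function(out_dir, n_patients = 20L, n_beats = 300L, k = 2L,
                    mode = "multiclass", seed = 1L, dry_run = FALSE) {
  plan <- sprintf(
    "synth(n_patients=%d, n_beats=%d, seed=%d) -> extract -> cv(mode=%s, k=%d)",
    n_patients, n_beats, seed, mode, k)
  if (dry_run) {
    cat("plan:", plan, "\n")
    return(invisible(NULL))
  }
  message("running: ", plan)
  rec_dir <- file.path(out_dir, "records")
  run_synth(rec_dir, n_patients = n_patients, seed = seed,
            n_beats = n_beats)
  features <- run_extract(rec_dir, file.path(out_dir, "features.csv"))
  res <- run_cv(features, file.path(out_dir, "report"), mode = mode,
                k = k, seed = derive_seed(seed, "cv"))
  .echo_config(out_dir, list(stage = "all", n_patients = n_patients,
                             n_beats = n_beats, k = k, mode = mode,
                             seed = seed))
  invisible(res)
}
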