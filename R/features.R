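# Per-beat feature matrix assembly and conditioning.
#
# Fixed pipeline order (part of the contract): physiological clipping
# of RR/dRR-bearing features -> imputation of missing HRV windows with
# training-fold column means -> variance pruning (< 0.05, computed
# before z-scoring where the threshold has its stated meaning) ->
# Pearson dependence pruning (|r| > 0.95, later feature of the pair
# dropped) -> z-score with training-fold parameters.

#' All canonical feature names (42 HRV + 72 raw + 72 W4 = 186)
#' @export
feature_names_all <- function() {
  c(hrv_feature_names(), morph_feature_names("raw"), morph_feature_names("w4"))
}

#' Physiological clip bounds for RR/dRR features
#'
#' RR is bounded below by the cardiac refractory period (250 ms) and
#' above by twice the RR of an extreme 35 bpm bradycardia (the longest
#' post-ectopic pause): 2 x 60000/35 = 3428.6 ms. dRR bounds are
#' derived symmetrically as +-(RR_max - RR_min).
#'
#' @return list with `rr_min`, `rr_max`, `drr_min`, `drr_max` (ms).
#' @export
clip_bounds <- function() {
  rr_min <- 250
  rr_max <- round(2 * 60000 / 35, 1)  # 3428.6 ms
  list(rr_min = rr_min, rr_max = rr_max,
       drr_min = -(rr_max - rr_min), drr_max = rr_max - rr_min)
}

# Feature-name sets the clip applies to: interval-valued features only
# (beat-local RR/dRR and window mean RR); spreads, pNNx and morphology
# are untouched.
.clip_rr_features <- function(nms) {
  nms[grepl("^hrv_rr_", nms) | grepl("^hrv_win.*_meanrr$", nms)]
}
.clip_drr_features <- function(nms) {
  nms[grepl("^hrv_drr_", nms)]
}

#' Assemble the per-beat feature matrix of one record
#'
#' The record must already be preprocessed (fs 250). All beats provide
#' RR timing and template context; feature vectors are emitted only for
#' beats with index in `[41, n - 40]` (1-based; the first and last 40
#' beats are trimmed) and a label in {N, S, V}. The W4 morphology block
#' is computed on the scale-4 wavelet detail of both leads.
#'
#' @param record a preprocessed [ecg_record] (fs 250, >= 2 leads).
#' @param annotations data.frame with `sample` (0-based) and `label`.
#' @param morph_cfg a [morph_config].
#' @return data.frame: `patient_id`, `beat_sample`, `label`, then the
#'   186 canonical feature columns. Empty (with a warning) if the
#'   record has 80 beats or fewer.
#' @export
assemble_features <- function(record, annotations, morph_cfg = morph_config()) {
  stopifnot(inherits(record, "ecg_record"))
  if (record$fs != 250) stop("assemble_features expects a preprocessed record (fs 250)")
  n <- nrow(annotations)
  empty <- data.frame(patient_id = character(0), beat_sample = numeric(0),
                      label = character(0))
  if (n <= 80L) {
    warning(sprintf("record %s has %d beats (<= 80): no feature vectors",
                    record$patient_id, n))
    for (nm in feature_names_all()) empty[[nm]] <- numeric(0)
    return(empty)
  }
  eval_idx <- seq.int(41L, n - 40L)
  eval_idx <- eval_idx[annotations$label[eval_idx] %in% PAC_CLASSES]
  if (length(eval_idx) == 0L) {
    for (nm in feature_names_all()) empty[[nm]] <- numeric(0)
    return(empty)
  }
  series <- compute_rr_series(annotations$sample, record$fs)
  hrv <- hrv_matrix(series, eval_idx)
  sig <- record$signal[, 1:2, drop = FALSE]
  w4 <- apply(sig, 2L, w4_transform, fs = record$fs)
  raw_m <- beat_morph_features(sig, annotations$sample, eval_idx,
                               fs = record$fs, cfg = morph_cfg,
                               version = "raw")
  w4_m <- beat_morph_features(w4, annotations$sample, eval_idx,
                              fs = record$fs, cfg = morph_cfg,
                              version = "w4")
  out <- data.frame(patient_id = record$patient_id,
                    beat_sample = annotations$sample[eval_idx],
                    label = annotations$label[eval_idx],
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(cbind(hrv, raw_m, w4_m)))
}

#' Clip RR/dRR-bearing features to physiological bounds
#'
#' @param mat data.frame or matrix with canonical feature columns.
#' @param bounds a [clip_bounds] list.
#' @return same shape, out-of-range interval values replaced by the
#'   nearest bound.
#' @export
clip_features <- function(mat, bounds = clip_bounds()) {
  nms <- colnames(mat)
  for (f in .clip_rr_features(nms)) {
    mat[, f] <- pmin(pmax(mat[, f], bounds$rr_min), bounds$rr_max)
  }
  for (f in .clip_drr_features(nms)) {
    mat[, f] <- pmin(pmax(mat[, f], bounds$drr_min), bounds$drr_max)
  }
  mat
}

#' Prune features by variance and pairwise Pearson dependence
#'
#' Fitted on training beats only. First drops features with variance
#' below `var_min` (computed after clipping, before z-scoring); then,
#' scanning feature pairs in canonical order, drops the later feature
#' of any pair with `|r| > corr_max`. Deterministic.
#'
#' @param train numeric matrix/data.frame of training features (no
#'   missing values).
#' @param corr_max Pearson threshold (default 0.95).
#' @param var_min variance threshold (default 0.05).
#' @return list with `keep` (character), `dropped_var`, `dropped_corr`.
#' @export
prune_features <- function(train, corr_max = 0.95, var_min = 0.05) {
  x <- as.matrix(train)
  v <- apply(x, 2L, var)
  dropped_var <- colnames(x)[v < var_min]
  keep <- colnames(x)[v >= var_min]
  if (length(keep) == 0L) stop("prune_features: all features dropped")
  r <- abs(cor(x[, keep, drop = FALSE]))
  dropped_corr <- character(0)
  alive <- rep(TRUE, length(keep))
  for (a in seq_along(keep)) {
    if (!alive[a]) next
    for (b in seq_along(keep)) {
      if (b <= a || !alive[b]) next
      if (!is.na(r[a, b]) && r[a, b] > corr_max) {
        alive[b] <- FALSE
        dropped_corr <- c(dropped_corr, keep[b])
      }
    }
  }
  list(keep = keep[alive], dropped_var = dropped_var,
       dropped_corr = dropped_corr)
}

#' Fit / apply the z-score transform
#'
#' @param train numeric matrix of training features (columns already
#'   pruned; no constant columns).
#' @return `zscore_fit`: list with `mean`, `sd`, `features`.
#' @export
zscore_fit <- function(train) {
  x <- as.matrix(train)
  mu <- colMeans(x)
  sdev <- apply(x, 2L, sd)
  if (any(sdev <= 0)) {
    stop("zscore_fit: constant column reached the z-score stage")
  }
  list(mean = mu, sd = sdev, features = colnames(x))
}

#' @rdname zscore_fit
#' @param fit a `zscore_fit` result.
#' @param mat matrix/data.frame containing at least `fit$features`.
#' @export
zscore_apply <- function(fit, mat) {
  x <- as.matrix(mat)[, fit$features, drop = FALSE]
  sweep(sweep(x, 2L, fit$mean, "-"), 2L, fit$sd, "/")
}

#' Fit the full feature conditioning on training beats
#'
#' clip -> impute (training column means) -> variance prune ->
#' correlation prune -> z-score fit. The returned transform depends
#' only on the training beats; apply it to any fold with
#' [apply_feature_transform()].
#'
#' @param train_df feature data.frame (metadata columns tolerated).
#' @param corr_max,var_min pruning thresholds.
#' @param bounds clip bounds.
#' @return a `feature_transform` list.
#' @export
fit_feature_transform <- function(train_df, corr_max = 0.95, var_min = 0.05,
                                  bounds = clip_bounds()) {
  x <- train_df[, intersect(feature_names_all(), colnames(train_df)),
                drop = FALSE]
  x <- clip_features(x, bounds)
  impute <- colMeans(as.matrix(x), na.rm = TRUE)
  impute[is.nan(impute)] <- 0
  for (j in seq_along(x)) {
    miss <- is.na(x[[j]])
    if (any(miss)) x[[j]][miss] <- impute[[j]]
  }
  pr <- prune_features(x, corr_max = corr_max, var_min = var_min)
  zs <- zscore_fit(as.matrix(x)[, pr$keep, drop = FALSE])
  structure(list(bounds = bounds, impute = impute, keep = pr$keep,
                 dropped_var = pr$dropped_var,
                 dropped_corr = pr$dropped_corr, zscore = zs,
                 corr_max = corr_max, var_min = var_min),
            class = "feature_transform")
}

#' @rdname fit_feature_transform
#' @param transform a fitted `feature_transform`.
#' @param df feature data.frame to transform.
#' @return numeric matrix (rows as in `df`, columns `transform$keep`),
#'   z-scored with training parameters.
#' @export
apply_feature_transform <- function(transform, df) {
  x <- df[, names(transform$impute), drop = FALSE]
  x <- clip_features(x, transform$bounds)
  for (j in seq_along(x)) {
    miss <- is.na(x[[j]])
    if (any(miss)) x[[j]][miss] <- transform$impute[[j]]
  }
  zscore_apply(transform$zscore, as.matrix(x)[, transform$keep, drop = FALSE])
}

#' Serialize / load a fitted feature transform (JSON sidecar)
#' @param transform a `feature_transform`.
#' @param path output JSON path.
#' @export
write_feature_transform <- function(transform, path) {
  tr <- unclass(transform)
  tr$impute <- as.list(tr$impute)          # keep names as JSON keys
  tr$zscore$mean <- as.list(tr$zscore$mean)
  tr$zscore$sd <- as.list(tr$zscore$sd)
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_transform
#' @export
read_feature_transform <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$impute <- unlist(tr$impute)
  tr$zscore$mean <- unlist(tr$zscore$mean)
  tr$zscore$sd <- unlist(tr$zscore$sd)
  tr$zscore$features <- unlist(tr$zscore$features)
  tr$keep <- unlist(tr$keep)
  tr$bounds <- lapply(tr$bounds, as.numeric)
  structure(tr, class = "feature_transform")
}

#' Write / read the feature matrix as CSV (bit-exact roundtrip)
#' @param df feature data.frame.
#' @param path CSV path.
#' @export
write_features_csv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  for (j in which(num)) out[[j]] <- sprintf("%.17g", df[[j]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  hdr <- names(read.csv(path, nrows = 1L, check.names = FALSE))
  cls <- ifelse(hdr %in% c("patient_id", "label"), "character", "numeric")
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = stats::setNames(cls, hdr))
}
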