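# R surface of the template morphology module. The heavy lifting
# (alignment, template construction, the per-beat feature sweep) is in
# src/morph.cpp.

#' Fixed segment windows around the R peak
#'
#' Window bounds in ms relative to the R peak (t = 0): whole beat
#' \[-300, 250\], P wave \[-300, 40\], PR interval \[-288, 0\], QRS
#' complex \[-70, 60\]. Sample offsets are `round(ms * fs / 1000)` with
#' ties away from zero. No delineation is performed: the windows
#' capture intra-patient variability of the approximate ECG regions.
#'
#' @param kind one of `"beat"`, `"p"`, `"pr"`, `"qrs"`.
#' @param fs sampling rate, Hz (pipeline value: 250).
#' @return list with `kind`, `window_ms`, `off_lo`, `off_hi`, `len`.
#' @export
segment_spec <- function(kind = c("beat", "p", "pr", "qrs"), fs = 250) {
  kind <- match.arg(kind)
  ms <- switch(kind,
               beat = c(-300, 250),
               p = c(-300, 40),
               pr = c(-288, 0),
               qrs = c(-70, 60))
  off <- as.integer(round_half_away(ms * fs / 1000))
  list(kind = kind, window_ms = ms, off_lo = off[1L], off_hi = off[2L],
       len = off[2L] - off[1L] + 1L)
}

#' @rdname segment_spec
#' @export
segment_kinds <- function() c("beat", "p", "pr", "qrs")

#' Morphology engine defaults
#'
#' `max_lag` is the alignment search range (+-40 ms = +-10 samples at
#' 250 Hz: larger than plausible fiducial jitter, smaller than the
#' inter-beat spacing); `ncc_min` the outlier-exclusion threshold on
#' the alignment NCC against the provisional median reference.
#'
#' @param neighborhoods template context sizes (beats, symmetric
#'   around — and always excluding — the beat of study).
#' @param max_lag alignment search half-range in samples.
#' @param ncc_min outlier NCC threshold for template construction.
#' @return a `morph_config` list.
#' @export
morph_config <- function(neighborhoods = c(80L, 20L, 4L), max_lag = 10L,
                         ncc_min = 0.8) {
  stopifnot(all(neighborhoods >= 2L), max_lag >= 0L,
            ncc_min >= -1, ncc_min <= 1)
  structure(list(neighborhoods = as.integer(neighborhoods),
                 max_lag = as.integer(max_lag), ncc_min = ncc_min),
            class = "morph_config")
}

#' Extract a fixed window around an R peak
#'
#' @param lead numeric sample vector.
#' @param r_sample 0-based R-peak sample index.
#' @param spec a [segment_spec].
#' @return waveform of length `spec$len`.
#' @export
extract_segment <- function(lead, r_sample, spec) {
  lo <- r_sample + spec$off_lo
  hi <- r_sample + spec$off_hi
  if (lo < 0 || hi >= length(lead)) {
    stop(sprintf("segment window [%d, %d] out of record (n = %d)",
                 lo, hi, length(lead)))
  }
  lead[(lo + 1L):(hi + 1L)]
}

#' Align a waveform to a reference by maximum NCC
#'
#' Searches lags in `[-max_lag, max_lag]` for the maximum normalized
#' (zero-mean, unit-energy) cross-correlation over the overlapping
#' parts; ties go to the smallest `|lag|`, then to the negative lag.
#' Positive lag means the waveform lags the reference. Zero-variance
#' overlaps score 0.
#'
#' @param x,ref equal-length numeric waveforms.
#' @param max_lag search half-range in samples.
#' @return list with `lag` (integer) and `ncc` in \[-1, 1\].
#' @export
align_lag <- function(x, ref, max_lag = 10L) {
  .align_lag_cpp(as.numeric(x), as.numeric(ref), as.integer(max_lag))
}

#' Build an intra-patient template from neighbor segments
#'
#' Provisional reference = element-wise median of the input segments;
#' each segment is aligned to it by [align_lag()]; segments whose
#' alignment NCC falls below `ncc_min` are excluded; the retained
#' aligned segments are averaged element-wise. If exclusion would leave
#' fewer than 2 segments, the 2 highest-NCC segments are kept (floor
#' rule). Samples shifted beyond the overlap are filled with the
#' reference value.
#'
#' @param beats numeric matrix, one segment per column.
#' @param ncc_min outlier threshold.
#' @param max_lag alignment search half-range.
#' @return list with `mean_wave`, `per_sample_sd` (n-1 denominator),
#'   `median_sd` (median over samples) and `n_used`.
#' @export
build_template <- function(beats, ncc_min = 0.8, max_lag = 10L) {
  beats <- as.matrix(beats)
  if (ncol(beats) < 2L) stop("build_template: need at least 2 beats")
  .build_template_cpp(beats, ncc_min, as.integer(max_lag))
}

#' Symmetric template neighborhoods of a beat
#'
#' @param i 1-based beat index.
#' @param n_beats total beat count.
#' @param sizes neighborhood sizes.
#' @return named list of 1-based index vectors, excluding `i` itself.
#' @export
neighborhoods <- function(i, n_beats, sizes = c(80L, 20L, 4L)) {
  if (i < 41L || i > n_beats - 40L) {
    stop("neighborhoods: beat index inside the 40-beat trim zone")
  }
  out <- lapply(sizes, function(k) {
    half <- k %/% 2L
    j <- (i - half):(i + half)
    j[j != i & j >= 1L & j <= n_beats]
  })
  names(out) <- as.character(sizes)
  out
}

#' Canonical morphology feature names for one signal version
#'
#' Pattern `morph_{ver}_{beat|p|pr|qrs}_{t80|t20|t4}_L{1|2}_{xcorr|lag|medsd}`,
#' ordered segment-slowest / stat-fastest (72 names).
#'
#' @param version `"raw"` or `"w4"`.
#' @param cfg a [morph_config].
#' @export
morph_feature_names <- function(version = c("raw", "w4"),
                                cfg = morph_config()) {
  version <- match.arg(version)
  nm <- character(0)
  for (seg in segment_kinds()) {
    for (t in cfg$neighborhoods) {
      for (L in 1:2) {
        nm <- c(nm, paste0("morph_", version, "_", seg, "_t", t, "_L", L,
                           "_", c("xcorr", "lag", "medsd")))
      }
    }
  }
  nm
}

#' Morphology features for a set of beats (one signal version)
#'
#' For each evaluated beat: 4 segments x 3 neighborhoods x 2 leads,
#' each scored against a template rebuilt from the neighbors (the beat
#' itself never enters its own template), yielding (max NCC, lag,
#' template median sd) = 72 values per beat. Neighbors of any class are
#' eligible; neighbors whose window would fall off the record are
#' skipped.
#'
#' @param signal n x 2 (or more) numeric matrix; first two leads used.
#' @param r_samples 0-based R-peak samples of all beats.
#' @param eval_idx 1-based indices of the beats to evaluate.
#' @param fs sampling rate (250).
#' @param cfg a [morph_config].
#' @param version label used for the column names.
#' @return numeric matrix `length(eval_idx)` x 72 with canonical names.
#' @export
beat_morph_features <- function(signal, r_samples, eval_idx, fs = 250,
                                cfg = morph_config(),
                                version = c("raw", "w4")) {
  version <- match.arg(version)
  specs <- lapply(segment_kinds(), segment_spec, fs = fs)
  m <- .morph_features_cpp(
    as.matrix(signal), as.integer(r_samples),
    as.integer(eval_idx - 1L),
    vapply(specs, `[[`, 0L, "off_lo"), vapply(specs, `[[`, 0L, "off_hi"),
    cfg$neighborhoods, cfg$max_lag, cfg$ncc_min)
  colnames(m) <- morph_feature_names(version, cfg)
  m
}
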