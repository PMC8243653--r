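# Per-beat heart-rate-variability features.
#
# RR_n is the interval ending at beat n's R peak; dRR_n = RR_{n+1} -
# RR_n. Every annotated R peak contributes to RR timing regardless of
# class (an R peak exists physically even for EXCLUDED beats). Each
# beat gets 6 beat-local values plus 9 statistics over each of four
# time windows: 1 and 5 minutes preceding the beat, 2 and 10 minutes
# centered on it (42 values; see the methods vignette for the 41-vs-42
# enumeration note).

#' Window specifications for HRV statistics
#'
#' @return data.frame with columns `name`, `kind`, `minutes`.
#' @export
hrv_window_specs <- function() {
  data.frame(
    name = c("1p", "5p", "2c", "10c"),
    kind = c("preceding", "preceding", "centered", "centered"),
    minutes = c(1, 5, 2, 10),
    stringsAsFactors = FALSE
  )
}

#' Canonical HRV feature names (42)
#' @export
hrv_feature_names <- function() {
  local <- c("hrv_rr_i", "hrv_rr_im1", "hrv_rr_ip1",
             "hrv_drr_i", "hrv_drr_im1", "hrv_drr_ip1")
  stats <- c("meanrr", "sdrr", "sddrr", "pnn10", "pnn20", "pnn30",
             "pnn40", "pnn50", "rmssd")
  wins <- hrv_window_specs()$name
  c(local, as.vector(t(outer(wins, stats,
                             function(w, s) paste0("hrv_win", w, "_", s)))))
}

#' Build the RR/dRR series of a record
#'
#' @param samples 0-based R-peak sample indices (all beats, sorted).
#' @param fs sampling rate, Hz.
#' @return list of class `rr_series`: `rr` (ms, `rr[k]` spans beats k
#'   to k+1, 1-based), `drr` (ms, `drr[k] = rr[k+1] - rr[k]`),
#'   `end_time` (ms, time of the R peak ending each RR), `beat_time`
#'   (ms per beat), `n_beats`.
#' @export
compute_rr_series <- function(samples, fs) {
  samples <- as.numeric(samples)
  if (is.unsorted(samples, strictly = TRUE)) {
    stop("annotation samples must be strictly increasing")
  }
  bt <- samples * 1000 / fs
  if (length(samples) < 2L) {
    return(structure(list(rr = numeric(0), drr = numeric(0),
                          end_time = numeric(0), beat_time = bt,
                          n_beats = length(samples)),
                     class = "rr_series"))
  }
  rr <- diff(bt)
  structure(list(rr = rr, drr = diff(rr), end_time = bt[-1L],
                 beat_time = bt, n_beats = length(samples)),
            class = "rr_series")
}

#' Beat-local RR/dRR features
#'
#' Returns `(RR_i, RR_{i-1}, RR_{i+1}, dRR_i, dRR_{i-1}, dRR_{i+1})` in
#' ms, where RR_i ends at beat `i`'s R peak. Requires both neighbors'
#' context (`i >= 3` and `i <= n_beats - 2`, 1-based), which the
#' 40-beat trim guarantees in the pipeline.
#'
#' @param series an `rr_series`.
#' @param i 1-based beat index.
#' @export
beat_local_features <- function(series, i) {
  n <- series$n_beats
  if (i < 3L || i > n - 2L) {
    stop("beat_local_features: beat index lacks neighbor context")
  }
  c(hrv_rr_i = series$rr[i - 1L],
    hrv_rr_im1 = series$rr[i - 2L],
    hrv_rr_ip1 = series$rr[i],
    hrv_drr_i = series$drr[i - 1L],
    hrv_drr_im1 = series$drr[i - 2L],
    hrv_drr_ip1 = series$drr[i])
}

# Core window statistics on an RR subsequence (>= 3 entries).
.rr_stats <- function(rr) {
  d <- diff(rr)
  pnn <- vapply(c(10, 20, 30, 40, 50),
                function(x) 100 * mean(abs(d) > x), 0)
  c(meanrr = mean(rr), sdrr = sd(rr), sddrr = sd(d),
    pnn10 = pnn[1], pnn20 = pnn[2], pnn30 = pnn[3], pnn40 = pnn[4],
    pnn50 = pnn[5], rmssd = sqrt(mean(d^2)))
}

#' Windowed HRV statistics for one beat
#'
#' The window holds the RR entries whose ending R-peak time lies in
#' `[t_i - d, t_i)` for a preceding window of duration `d`, or in
#' `[t_i - d/2, t_i + d/2]` for a centered one. Statistics: mean and sd
#' of RR, sd of dRR, pNN10..pNN50 (percent of successive RR differences
#' strictly greater than the threshold) and RMSSD. Windows with fewer
#' than 3 RR entries return all-`NA` (imputed at model time).
#'
#' @param series an `rr_series`.
#' @param i 1-based beat index.
#' @param kind `"preceding"` or `"centered"`.
#' @param minutes window duration.
#' @return named numeric of length 9.
#' @export
window_stats <- function(series, i, kind = c("preceding", "centered"),
                         minutes) {
  kind <- match.arg(kind)
  ti <- series$beat_time[i]
  d <- minutes * 60000
  et <- series$end_time
  sel <- if (kind == "preceding") {
    et >= ti - d & et < ti
  } else {
    et >= ti - d / 2 & et <= ti + d / 2
  }
  rr <- series$rr[sel]
  if (length(rr) < 3L) {
    return(stats::setNames(rep(NA_real_, 9L),
                           names(.rr_stats(c(1, 2, 3)))))
  }
  .rr_stats(rr)
}

#' Full HRV feature block for one beat
#'
#' @param series an `rr_series`.
#' @param i 1-based beat index.
#' @return named numeric of length 42 in canonical
#'   [hrv_feature_names()] order.
#' @export
beat_hrv_vector <- function(series, i) {
  specs <- hrv_window_specs()
  out <- beat_local_features(series, i)
  for (r in seq_len(nrow(specs))) {
    ws <- window_stats(series, i, specs$kind[r], specs$minutes[r])
    names(ws) <- paste0("hrv_win", specs$name[r], "_", names(ws))
    out <- c(out, ws)
  }
  out
}

# Batched HRV block for many beats (matrix eval x 42).
hrv_matrix <- function(series, eval_idx) {
  nm <- hrv_feature_names()
  out <- matrix(NA_real_, length(eval_idx), length(nm),
                dimnames = list(NULL, nm))
  for (r in seq_along(eval_idx)) {
    out[r, ] <- beat_hrv_vector(series, eval_idx[r])
  }
  out
}
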