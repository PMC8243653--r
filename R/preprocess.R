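# Sampling-rate homogenization and denoising.
#
# Chain (in this order): resample to 250 Hz -> subtract a baseline
# wander estimate obtained from two cascaded median filters (200 ms and
# 600 ms) -> linear-phase FIR low-pass at 35 Hz with group-delay
# compensation, so R-peak sample indices stay valid throughout.

#' Preprocessing configuration
#'
#' @param target_fs internal sampling rate, Hz. All downstream feature
#'   extraction is calibrated to 250 Hz.
#' @param median_ms lengths of the two cascaded median filters, ms. The
#'   first (short) window flattens QRS complexes, the second smooths the
#'   remainder into a baseline wander estimate.
#' @param lp_cutoff low-pass passband edge, Hz.
#' @param lp_stop low-pass stopband edge, Hz.
#' @param lp_atten_db minimum stopband attenuation, dB.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(target_fs = 250, median_ms = c(200, 600),
                              lp_cutoff = 35, lp_stop = 45,
                              lp_atten_db = 40) {
  stopifnot(length(median_ms) == 2L, median_ms[1] < median_ms[2],
            lp_cutoff < lp_stop, lp_stop < target_fs / 2, target_fs > 0)
  structure(list(target_fs = target_fs, median_ms = median_ms,
                 lp_cutoff = lp_cutoff, lp_stop = lp_stop,
                 lp_atten_db = lp_atten_db),
            class = "preprocess_config")
}

# Kaiser-window linear-phase FIR low-pass. Even order (odd tap count)
# so the group delay is an integer number of samples; DC gain
# normalized to exactly 1. The half-band edge sits midway between
# passband and stopband edges.
fir_lowpass_design <- function(fs, cutoff, stop, atten_db) {
  if (stop >= fs / 2 || cutoff >= stop || cutoff <= 0) {
    stop("unmeetable low-pass specification")
  }
  A <- atten_db
  beta <- if (A > 50) {
    0.1102 * (A - 8.7)
  } else if (A >= 21) {
    0.5842 * (A - 21)^0.4 + 0.07886 * (A - 21)
  } else 0
  dw <- 2 * pi * (stop - cutoff) / fs
  N <- ceiling((A - 8) / (2.285 * dw))
  if (N %% 2L == 1L) N <- N + 1L       # even order -> integer delay
  m <- (0:N) - N / 2
  fc <- (cutoff + stop) / 2 / fs       # normalized, cycles/sample
  h <- ifelse(m == 0, 2 * fc, sin(2 * pi * fc * m) / (pi * m))
  w <- besselI(beta * sqrt(pmax(0, 1 - (2 * m / N)^2)), 0) / besselI(beta, 0)
  h <- h * w
  h / sum(h)
}

# Apply a symmetric FIR with mirror-extension edges and integer
# group-delay compensation: output[i] lines up with input[i].
apply_fir <- function(x, h) {
  d <- (length(h) - 1L) %/% 2L
  xp <- mirror_pad(x, d)
  y <- conv_full(xp, h)
  y[(2L * d + 1L):(2L * d + length(x))]
}

#' Resample a record to a target rate
#'
#' Cubic-spline interpolation onto the new time grid; when
#' downsampling, an anti-alias low-pass at 0.45 of the target Nyquist
#' is applied first. Returns the resampled record together with an
#' index map for annotation samples (round-half-away-from-zero, clamped
#' to the record).
#'
#' @param record an [ecg_record].
#' @param target_fs target rate, Hz.
#' @return list with `record` (resampled) and `map` (function taking
#'   0-based sample indices at the old rate to the new rate).
#' @export
resample_record <- function(record, target_fs) {
  if (!is.numeric(target_fs) || length(target_fs) != 1L || target_fs <= 0) {
    stop("target_fs must be a positive scalar")
  }
  if (record$fs == target_fs) {
    return(list(record = record, map = function(s) s))
  }
  ratio <- target_fs / record$fs
  n_out <- round(record$n_samples * ratio)
  t_new <- (seq_len(n_out) - 1L) / target_fs
  sig <- record$signal
  if (target_fs < record$fs) {
    aa <- fir_lowpass_design(record$fs, 0.40 * target_fs, 0.50 * target_fs, 60)
    sig <- apply(sig, 2L, apply_fir, h = aa)
  }
  t_old <- (seq_len(record$n_samples) - 1L) / record$fs
  out <- vapply(seq_len(ncol(sig)), function(j) {
    splinefun(t_old, sig[, j], method = "fmm")(t_new)
  }, numeric(n_out))
  new_rec <- ecg_record(out, fs = target_fs, patient_id = record$patient_id)
  map <- function(s) pmin(pmax(round_half_away(s * ratio), 0), n_out - 1L)
  list(record = new_rec, map = map)
}

# Nearest odd sample count for a window duration.
.odd_win <- function(ms, fs) {
  w <- round(ms * fs / 1000)
  if (w %% 2L == 0L) w <- w + 1L
  as.integer(max(w, 1L))
}

#' Estimate baseline wander with cascaded median filters
#'
#' Two running medians (window durations from `cfg$median_ms`,
#' converted to the nearest odd sample count: 51 and 151 samples at
#' 250 Hz). Edges use shrinking symmetric windows. Adding a constant to
#' the input adds the same constant to the estimate.
#'
#' @param lead numeric sample vector.
#' @param fs sampling rate, Hz.
#' @param cfg a [preprocess_config].
#' @return baseline estimate, same length as `lead`.
#' @export
estimate_baseline <- function(lead, fs, cfg = preprocess_config()) {
  if (length(lead) == 0L) stop("estimate_baseline: empty lead")
  w1 <- .odd_win(cfg$median_ms[1], fs)
  w2 <- .odd_win(cfg$median_ms[2], fs)
  b <- runmed(lead, k = min(w1, length(lead) - (1 - length(lead) %% 2L)),
              endrule = "median")
  as.vector(runmed(b, k = min(w2, length(b) - (1 - length(b) %% 2L)),
                   endrule = "median"))
}

#' @rdname estimate_baseline
#' @export
remove_baseline <- function(lead, fs, cfg = preprocess_config()) {
  lead - estimate_baseline(lead, fs, cfg)
}

#' Low-pass filter a lead at 35 Hz
#'
#' Linear-phase FIR (Kaiser design meeting the configured band edges
#' and attenuation), applied with integer group-delay compensation so
#' the output stays time-aligned with the input.
#'
#' @inheritParams estimate_baseline
#' @export
lowpass_filter <- function(lead, fs, cfg = preprocess_config()) {
  if (fs != cfg$target_fs) {
    stop(sprintf("lowpass_filter expects fs == %g (resample first)",
                 cfg$target_fs))
  }
  h <- fir_lowpass_design(fs, cfg$lp_cutoff, cfg$lp_stop, cfg$lp_atten_db)
  apply_fir(lead, h)
}

#' Run the full preprocessing chain on a record
#'
#' Resample to `cfg$target_fs`, remove the median-filter baseline
#' estimate, low-pass at `cfg$lp_cutoff`; annotation samples are
#' remapped to the new rate. Both leads are processed identically.
#'
#' @param record an [ecg_record].
#' @param annotations data.frame with a 0-based `sample` column (may be
#'   `NULL`).
#' @param cfg a [preprocess_config].
#' @return list with `record` and `annotations`.
#' @export
preprocess_record <- function(record, annotations = NULL,
                              cfg = preprocess_config()) {
  rs <- resample_record(record, cfg$target_fs)
  rec <- rs$record
  sig <- apply(rec$signal, 2L, function(x) {
    lowpass_filter(remove_baseline(x, rec$fs, cfg), rec$fs, cfg)
  })
  out <- ecg_record(sig, fs = rec$fs, patient_id = rec$patient_id)
  if (!is.null(annotations) && nrow(annotations) > 0L) {
    annotations$sample <- rs$map(annotations$sample)
  }
  list(record = out, annotations = annotations)
}
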