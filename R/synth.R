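# Annotated synthetic two-lead ECG generator.
#
# Beats are sum-of-Gaussians P-QRS-T kernels placed on a planned rhythm
# with respiratory RR modulation, Gaussian noise and sinusoidal
# baseline wander. PACs (label S) are premature with a perturbed P wave
# (attenuated / shifted / inverted — an ectopic atrial focus) and a
# non-compensatory pause; ventricular beats (label V) have no P wave, a
# wide inverted main deflection with inverted T, and a full
# compensatory pause. Transparent ground truth for every pipeline knob;
# not a physiologically faithful dynamical model (see the methods
# vignette for what a green test does and does not establish).

#' Synthetic record configuration
#'
#' Defaults are the package's stated test world: 250 Hz, 300 beats,
#' mean RR 800 ms (sd 40 ms), 30 ms respiratory modulation at 0.25 Hz,
#' 10% PACs and 10% ventricular beats, PAC prematurity 0.25 of the
#' local RR, PAC P wave at half amplitude, shifted -40 ms and inverted,
#' ventricular QRS 2.5x wide at 1.4x amplitude, noise sd 0.02 mV,
#' 0.1 mV baseline wander at 0.3 Hz.
#'
#' @param fs sampling rate, Hz.
#' @param n_beats beats per record.
#' @param mean_rr,sd_rr base RR distribution, ms.
#' @param resp_amp,resp_freq respiratory RR modulation (ms, Hz).
#' @param pac_rate,pvc_rate ectopic rates in \[0,1\] (isolated pattern).
#' @param pac_prematurity RR shortening fraction for premature beats.
#' @param pac_p_amp,pac_p_shift_ms,pac_p_invert PAC P-wave perturbation.
#' @param pvc_qrs_width_factor,pvc_amp_factor ventricular QRS shape.
#' @param pattern `"isolated"`, `"bigeminy"`, `"trigeminy"` or
#'   `"atrial_run"`.
#' @param run_len run length for `"atrial_run"`.
#' @param noise_sd additive Gaussian noise, mV.
#' @param wander_amp,wander_freq baseline wander (mV, Hz).
#' @param p_amp,r_amp,lead2_gain kernel amplitude knobs (per-patient
#'   variability).
#' @param seed integer seed; generation is deterministic given it.
#' @return a `synth_config` list.
#' @export
synth_config <- function(fs = 250, n_beats = 300L, mean_rr = 800,
                         sd_rr = 40, resp_amp = 30, resp_freq = 0.25,
                         pac_rate = 0.10, pvc_rate = 0.10,
                         pac_prematurity = 0.25, pac_p_amp = 0.5,
                         pac_p_shift_ms = -40, pac_p_invert = TRUE,
                         pvc_qrs_width_factor = 2.5, pvc_amp_factor = 1.4,
                         pattern = c("isolated", "bigeminy", "trigeminy",
                                     "atrial_run"),
                         run_len = 4L, noise_sd = 0.02, wander_amp = 0.1,
                         wander_freq = 0.3, p_amp = 0.15, r_amp = 1.0,
                         lead2_gain = 0.7, seed = 1L) {
  pattern <- match.arg(pattern)
  stopifnot(fs > 0, pac_rate >= 0, pvc_rate >= 0, pac_rate + pvc_rate < 1)
  structure(as.list(environment()), class = "synth_config")
}

# Gaussian bump over a millisecond grid.
.bump <- function(t, a, mu, sd) a * exp(-((t - mu)^2) / (2 * sd^2))

#' Beat waveform kernel
#'
#' @param kind `"N"`, `"S"` or `"V"`.
#' @param cfg a [synth_config].
#' @param lead 1 or 2 (lead 2 is a scaled, slightly widened copy).
#' @return list with integer sample `offsets` (relative to the R peak)
#'   and `values` (mV).
#' @export
beat_waveform <- function(kind = c("N", "S", "V"), cfg = synth_config(),
                          lead = 1L) {
  kind <- match.arg(kind)
  off <- seq.int(round(-350 * cfg$fs / 1000), round(400 * cfg$fs / 1000))
  t <- off * 1000 / cfg$fs
  wid <- if (lead == 2L) 1.1 else 1.0
  g <- if (lead == 2L) cfg$lead2_gain else 1.0
  v <- numeric(length(t))
  if (kind != "V") {
    pa <- cfg$p_amp
    pmu <- -160
    psd <- 22 * wid
    if (kind == "S") {
      pa <- pa * cfg$pac_p_amp * (if (cfg$pac_p_invert) -1 else 1)
      pmu <- pmu + cfg$pac_p_shift_ms
    }
    v <- v + .bump(t, pa, pmu, psd)
    v <- v + .bump(t, -0.10 * cfg$r_amp, -22, 7 * wid)   # Q
    v <- v + .bump(t, cfg$r_amp, 0, 9 * wid)             # R
    v <- v + .bump(t, -0.18 * cfg$r_amp, 25, 9 * wid)    # S wave
    v <- v + .bump(t, 0.35 * cfg$r_amp, 220, 45 * wid)   # T
  } else {
    wf <- cfg$pvc_qrs_width_factor
    af <- cfg$pvc_amp_factor
    v <- v + .bump(t, -af * cfg$r_amp, 0, 9 * wf * wid)  # wide inverted R
    v <- v + .bump(t, 0.45 * cfg$r_amp, 70, 30 * wid)    # opposing hump
    v <- v + .bump(t, -0.40 * cfg$r_amp, 250, 55 * wid)  # inverted T
  }
  list(offsets = off, values = v * g)
}

#' Plan beat times and labels
#'
#' Label sequence per `cfg$pattern`; beat times with Gaussian RR noise
#' and respiratory modulation. Premature beats shorten their RR by
#' `pac_prematurity`; after a PAC the next interval is stretched by
#' half the stolen time (non-compensatory pause, total < 2 RR); after a
#' ventricular beat the next R falls so the couplet spans exactly
#' `2 * mean_rr` (full compensatory pause).
#'
#' @param cfg a [synth_config]. Uses the current RNG state (seeded by
#'   [generate_record()]).
#' @return data.frame `time_ms`, `label`, strictly increasing.
#' @export
rhythm_plan <- function(cfg = synth_config()) {
  n <- cfg$n_beats
  labels <- rep("N", n)
  if (cfg$pattern == "isolated") {
    u <- runif(n)
    labels[u < cfg$pac_rate] <- "S"
    labels[u >= cfg$pac_rate & u < cfg$pac_rate + cfg$pvc_rate] <- "V"
    labels[1:2] <- "N"
    labels[n] <- "N"
  } else if (cfg$pattern == "bigeminy") {
    labels[seq(2L, n, by = 2L)] <- "S"
  } else if (cfg$pattern == "trigeminy") {
    labels[seq(3L, n, by = 3L)] <- "S"
  } else { # atrial_run
    i <- 3L
    while (i <= n - cfg$run_len) {
      if (runif(1) < cfg$pac_rate / cfg$run_len) {
        labels[i:(i + cfg$run_len - 1L)] <- "S"
        i <- i + cfg$run_len + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  t <- numeric(n)
  t[1] <- 1000
  carry <- 0
  force_next <- NA_real_
  for (i in 2:n) {
    base <- cfg$mean_rr + cfg$sd_rr * rnorm(1) +
      cfg$resp_amp * sin(2 * pi * cfg$resp_freq * t[i - 1] / 1000)
    if (labels[i] == "S") {
      rr <- base * (1 - cfg$pac_prematurity)
      carry <- 0.5 * cfg$pac_prematurity * cfg$mean_rr
      force_next <- NA_real_
    } else if (labels[i] == "V") {
      rr <- base * (1 - cfg$pac_prematurity)
      force_next <- 2 * cfg$mean_rr - rr  # full compensatory pause
      carry <- 0
    } else if (!is.na(force_next)) {
      rr <- force_next
      force_next <- NA_real_
      carry <- 0
    } else {
      rr <- base + carry
      carry <- 0
    }
    t[i] <- t[i - 1] + rr
  }
  if (any(diff(t) < 300)) {
    stop("rhythm_plan: beats closer than 300 ms (mean_rr too small)")
  }
  data.frame(time_ms = t, label = labels, stringsAsFactors = FALSE)
}

#' Generate an annotated synthetic record
#'
#' @param cfg a [synth_config].
#' @param patient_id identifier stored in the record.
#' @return list: `record` (an [ecg_record]), `truth` (data.frame
#'   `sample`, `label`), `annotations` (data.frame `sample`, `symbol`,
#'   `label` — PhysioNet symbols N/A/V), `plan`.
#' @export
generate_record <- function(cfg = synth_config(), patient_id = "synth01") {
  with_seed(cfg$seed, {
    plan <- rhythm_plan(cfg)
    r <- round(plan$time_ms * cfg$fs / 1000)
    n <- max(r) + round(cfg$fs * 1.0)
    kernels <- lapply(c(N = "N", S = "S", V = "V"), function(k) {
      lapply(1:2, function(L) beat_waveform(k, cfg, lead = L))
    })
    sig <- matrix(0, n, 2L)
    for (b in seq_along(r)) {
      kk <- kernels[[plan$label[b]]]
      for (L in 1:2) {
        idx <- r[b] + kk[[L]]$offsets + 1L
        ok <- idx >= 1L & idx <= n
        sig[idx[ok], L] <- sig[idx[ok], L] + kk[[L]]$values[ok]
      }
    }
    tt <- (seq_len(n) - 1) / cfg$fs
    for (L in 1:2) {
      phase <- runif(1, 0, 2 * pi)
      sig[, L] <- sig[, L] +
        cfg$wander_amp * sin(2 * pi * cfg$wander_freq * tt + phase) +
        rnorm(n, sd = cfg$noise_sd)
    }
    record <- ecg_record(sig, fs = cfg$fs, patient_id = patient_id)
    truth <- data.frame(sample = r, label = plan$label,
                        stringsAsFactors = FALSE)
    ann <- data.frame(sample = r,
                      symbol = c(N = "N", S = "A", V = "V")[plan$label],
                      label = plan$label, stringsAsFactors = FALSE)
    rownames(ann) <- NULL
    list(record = record, truth = truth, annotations = ann, plan = plan)
  })
}

#' Write a synthetic record to disk as fixtures
#'
#' Emits the WFDB pair (`.hea`/`.dat`, format 16), the CSV fallback
#' (`.csv` + `.json` sidecar), annotations in both MIT (`.atr`) and CSV
#' (`.atr.csv`) form, and the ground truth (`_truth.csv`).
#'
#' @param gen result of [generate_record()].
#' @param dir output directory.
#' @return the record base path, invisibly.
#' @export
write_fixture <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, gen$record$patient_id)
  write_record(gen$record, base, format = "wfdb")
  write_record(gen$record, base, format = "csv")
  write_annotations(gen$annotations, base, format = "wfdb")
  write_annotations(gen$annotations, base, format = "csv")
  write.csv(gen$truth, paste0(base, "_truth.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(base)
}

#' Generate a heterogeneous synthetic cohort
#'
#' Per-patient kernel and rhythm randomization (mean RR, RR noise, R/P
#' amplitudes, lead-2 gain, ectopic rates) emulates inter-patient
#' variability; a fixed share of patients carries bigeminy, trigeminy
#' and atrial-run patterns (indices `n-5..n-4`, `n-3..n-2`, `n-1..n`),
#' the rest isolated ectopy.
#'
#' @param n_patients cohort size.
#' @param seed master seed (per-patient seeds are derived from it).
#' @param n_beats beats per record.
#' @return list of [generate_record()] results, one per patient.
#' @export
generate_cohort <- function(n_patients = 20L, seed = 1L, n_beats = 300L) {
  patterns <- rep("isolated", n_patients)
  if (n_patients >= 8L) {
    patterns[n_patients - (5:4)] <- "bigeminy"
    patterns[n_patients - (3:2)] <- "trigeminy"
    patterns[n_patients - (1:0)] <- "atrial_run"
  }
  lapply(seq_len(n_patients), function(p) {
    ps <- derive_seed(seed, paste0("patient", p))
    knobs <- with_seed(ps, list(
      mean_rr = runif(1, 650, 1000), sd_rr = runif(1, 25, 60),
      r_amp = runif(1, 0.8, 1.3), p_amp = runif(1, 0.10, 0.18),
      lead2_gain = runif(1, 0.5, 0.9),
      pac_rate = runif(1, 0.06, 0.14), pvc_rate = runif(1, 0.06, 0.14)))
    cfg <- synth_config(
      n_beats = n_beats, mean_rr = knobs$mean_rr, sd_rr = knobs$sd_rr,
      r_amp = knobs$r_amp, p_amp = knobs$p_amp,
      lead2_gain = knobs$lead2_gain,
      pac_rate = knobs$pac_rate,
      pvc_rate = if (patterns[p] == "isolated") knobs$pvc_rate else 0.0,
      pattern = patterns[p],
      seed = derive_seed(ps, "record"))
    generate_record(cfg, patient_id = sprintf("synth%02d", p))
  })
}
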