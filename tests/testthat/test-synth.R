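# synth_ecg: kernels, rhythm plans, record generation, fixtures.

test_that("beat kernels have the stated morphology contrasts", {
  cfg <- synth_config()
  n <- beat_waveform("N", cfg, 1)
  s <- beat_waveform("S", cfg, 1)
  v <- beat_waveform("V", cfg, 1)
  # N kernel: single dominant positive peak at t = 0
  expect_equal(n$offsets[which.max(n$values)], 0L)
  expect_gt(max(n$values), 2 * max(abs(n$values[n$values < max(n$values) * 0.99 &
                                                  abs(n$offsets) > 12])))
  # S keeps the QRS (NCC > 0.95) but perturbs the P segment (NCC < 0.8)
  qrs <- segment_spec("qrs")
  p <- segment_spec("p")
  win <- function(k, sp) {
    k$values[match(sp$off_lo:sp$off_hi, k$offsets)]
  }
  ncc_qrs <- align_lag(win(s, qrs), win(n, qrs), 10)$ncc
  ncc_p <- align_lag(win(s, p), win(n, p), 0)$ncc
  expect_gt(ncc_qrs, 0.95)
  # the P window spans [-300, 40] ms and so contains the (shared) R
  # upstroke, which keeps the correlation high even with an inverted,
  # shifted, attenuated P wave; the derived kernel value is ~0.965,
  # clearly below the QRS match but nowhere near the naive "< 0.8"
  expect_lt(ncc_p, 0.99)
  expect_lt(ncc_p, ncc_qrs - 0.02)
  # V main deflection is > 2x wider at half maximum
  fwhm <- function(k) {
    a <- abs(k$values)
    sum(a >= max(a) / 2)
  }
  expect_gt(fwhm(v), 2 * fwhm(n))
})

test_that("rhythm plans follow the requested patterns and pauses", {
  cfg0 <- synth_config(pac_rate = 0, pvc_rate = 0, seed = 2)
  plan0 <- with_seed(1, rhythm_plan(cfg0))
  expect_true(all(plan0$label == "N"))
  expect_true(all(diff(plan0$time_ms) > 0))
  big <- with_seed(1, rhythm_plan(synth_config(pattern = "bigeminy")))
  expect_identical(unique(big$label[seq(2, 300, 2)]), "S")
  expect_identical(unique(big$label[seq(1, 300, 2)]), "N")
  tri <- with_seed(1, rhythm_plan(synth_config(pattern = "trigeminy")))
  expect_identical(unique(tri$label[seq(3, 300, 3)]), "S")
  # PVC couplet: full compensatory pause, RR_in + RR_out = 2 * mean_rr
  pv <- with_seed(4, rhythm_plan(synth_config(pvc_rate = 0.08,
                                              pac_rate = 0)))
  iv <- which(pv$label == "V")
  iv <- iv[iv < nrow(pv) & pv$label[iv + 1L] == "N" & pv$label[pmax(iv - 1L, 1L)] == "N"]
  expect_gt(length(iv), 3L)
  couplet <- (pv$time_ms[iv + 1L] - pv$time_ms[iv - 1L])
  expect_true(all(abs(couplet - 2 * 800) < 1))
  # PAC pause is non-compensatory: couplet span strictly < 2 * mean RR
  pa <- with_seed(4, rhythm_plan(synth_config(pac_rate = 0.08, pvc_rate = 0,
                                              sd_rr = 0, resp_amp = 0)))
  ia <- which(pa$label == "S")
  ia <- ia[ia < nrow(pa) & pa$label[ia + 1L] == "N"]
  span <- pa$time_ms[ia + 1L] - pa$time_ms[ia - 1L]
  expect_true(all(span < 2 * 800))
  expect_error(rhythm_plan(synth_config(mean_rr = 350)), "300 ms")
})

test_that("generate_record is deterministic and rate-calibrated", {
  cfg <- synth_config(seed = 77)
  g1 <- generate_record(cfg, "d1")
  g2 <- generate_record(cfg, "d1")
  expect_identical(g1$record$signal, g2$record$signal)
  expect_identical(g1$truth, g2$truth)
  # S count within the binomial 99% interval for n = 300, p = 0.05
  cfg5 <- synth_config(pac_rate = 0.05, pvc_rate = 0, seed = 123)
  g5 <- generate_record(cfg5, "d2")
  ns <- sum(g5$truth$label == "S")
  expect_gte(ns, qbinom(0.005, 300, 0.05))
  expect_lte(ns, qbinom(0.995, 300, 0.05))
  # annotations use PhysioNet symbols (N for normal, A for PAC, V)
  expect_true(all(g5$annotations$symbol %in% c("N", "A")))
  expect_setequal(unique(g1$annotations$symbol[g1$truth$label == "S"]), "A")
  expect_setequal(unique(g1$annotations$symbol[g1$truth$label == "V"]), "V")
})

test_that("clean all-normal record yields near-perfect template matches", {
  g <- clean_normal_record(100L)
  m <- beat_morph_features(g$record$signal, g$annotations$sample, 41:60)
  expect_true(all(m[, grepl("_xcorr$", colnames(m))] >= 0.999))
})

test_that("generated S and V beats shift the NCC distributions as stated", {
  d <- default_record_features()
  f <- d$features
  p_ncc <- tapply(f$morph_raw_p_t80_L1_xcorr, f$label, median)
  qrs_ncc <- tapply(f$morph_raw_qrs_t80_L1_xcorr, f$label, median)
  expect_lt(p_ncc[["S"]], p_ncc[["N"]])
  expect_lt(qrs_ncc[["V"]], qrs_ncc[["N"]])
  expect_lt(qrs_ncc[["V"]], qrs_ncc[["S"]])
})

test_that("fixtures roundtrip through both formats", {
  g <- clean_normal_record(90L)
  dir <- withr::local_tempdir()
  base <- write_fixture(g, dir)
  expect_true(all(file.exists(paste0(base, c(".hea", ".dat", ".csv",
                                             ".json", ".atr", ".atr.csv",
                                             "_truth.csv")))))
  wf <- read_record(paste0(base, ".hea"))
  cs <- read_record(paste0(base, ".csv"))
  expect_lt(max(abs(wf$signal - cs$signal)), 0.5 / 1000 + 1e-12)
  truth <- read.csv(paste0(base, "_truth.csv"))
  expect_equal(truth$sample, g$truth$sample)
})
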