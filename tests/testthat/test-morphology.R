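# morphology_templates: segments, alignment, template construction,
# per-beat features.

test_that("segment windows resolve to the documented sample offsets", {
  p <- segment_spec("p")
  expect_equal(c(p$off_lo, p$off_hi, p$len), c(-75, 10, 86))
  pr <- segment_spec("pr")
  expect_equal(c(pr$off_lo, pr$off_hi, pr$len), c(-72, 0, 73))
  beat <- segment_spec("beat")
  expect_equal(c(beat$off_lo, beat$off_hi), c(-75, 63))  # 62.5 -> 63
  qrs <- segment_spec("qrs")
  expect_equal(c(qrs$off_lo, qrs$off_hi), c(-18, 15))    # -17.5 -> -18
  lead <- sin(1:1000 / 9)
  seg <- extract_segment(lead, 500, p)
  expect_equal(seg, lead[(500 - 75 + 1):(500 + 10 + 1)])
  expect_error(extract_segment(lead, 10, beat), "out of record")
})

test_that("align_lag: identity, shift recovery, sign flip, degenerate", {
  ref <- sin(seq(0, 6 * pi, length.out = 120))
  expect_equal(align_lag(ref, ref, 10), list(lag = 0L, ncc = 1))
  # x[n] = ref[n + 3]: recovered at lag -3 with ncc ~ 1
  x <- c(ref[4:120], ref[1:3] * 0)
  al <- align_lag(x, ref, 10)
  expect_equal(al$lag, -3L)
  expect_gt(al$ncc, 0.99)
  # pure sign flip on a ramp: every lag ties at -1, tie rules give lag 0
  ramp <- seq(-1, 1, length.out = 80)
  expect_equal(align_lag(-ramp, ramp, 10), list(lag = 0L, ncc = -1))
  # zero-variance input scores 0 at lag 0
  expect_equal(align_lag(rep(2, 50), ref[1:50], 10),
               list(lag = 0L, ncc = 0))
  # bounds hold across random cases
  set.seed(21)
  for (case in 1:50) {
    a <- rnorm(60)
    b <- rnorm(60)
    v <- align_lag(a, b, 10)
    expect_gte(v$ncc, -1 - 1e-12)
    expect_lte(v$ncc, 1 + 1e-12)
    expect_true(abs(v$lag) <= 10)
  }
})

test_that("ncc is invariant to positive scaling and translation", {
  set.seed(22)
  x <- rnorm(100)
  ref <- rnorm(100)
  base <- align_lag(x, ref, 8)
  expect_equal(align_lag(3.7 * x + 2, ref, 8), base)
  scaled_shift <- align_lag(2 * ref + 5, ref, 8)
  expect_equal(scaled_shift, list(lag = 0L, ncc = 1))
})

test_that("build_template: degeneracy, outlier exclusion, floor rule", {
  wave <- sin(seq(0, 4 * pi, length.out = 90))
  b_same <- matrix(rep(wave, 12), ncol = 12)
  tp <- build_template(b_same)
  expect_equal(tp$n_used, 12L)
  expect_equal(tp$mean_wave, wave)
  expect_equal(max(tp$per_sample_sd), 0)
  expect_equal(tp$median_sd, 0)
  # 9 identical + 1 inverted at threshold 0.8: inverted excluded,
  # template unchanged
  b_out <- cbind(matrix(rep(wave, 9), ncol = 9), -wave)
  tp2 <- build_template(b_out, ncc_min = 0.8)
  expect_equal(tp2$n_used, 9L)
  expect_equal(tp2$mean_wave, wave)
  # oracle equivalence: hand-pruned set with exclusion disabled
  tp3 <- build_template(b_out[, 1:9], ncc_min = -2)
  expect_equal(tp2$mean_wave, tp3$mean_wave)
  expect_equal(tp2$per_sample_sd, tp3$per_sample_sd)
  # floor rule: 2 beats kept regardless of threshold
  two <- cbind(wave, -wave)
  tp4 <- build_template(two, ncc_min = 0.99)
  expect_equal(tp4$n_used, 2L)
  expect_error(build_template(matrix(wave, ncol = 1)), "at least 2")
})

test_that("templates are translation-equivariant", {
  set.seed(23)
  b <- matrix(rnorm(80 * 10), 80, 10) + sin(1:80 / 6)
  t0 <- build_template(b)
  t1 <- build_template(b + 3.25)
  expect_equal(t1$mean_wave, t0$mean_wave + 3.25)
  expect_equal(t1$per_sample_sd, t0$per_sample_sd)
  al0 <- align_lag(b[, 1], t0$mean_wave, 10)
  al1 <- align_lag(b[, 1] + 3.25, t1$mean_wave, 10)
  expect_equal(al0, al1)
})

test_that("neighborhoods are symmetric, exclude self, honor the trim", {
  nb <- neighborhoods(41L, 200L)
  expect_equal(nb[["80"]], c(1:40, 42:81))
  expect_equal(nb[["4"]], c(39L, 40L, 42L, 43L))
  nb2 <- neighborhoods(100L, 200L)
  expect_equal(nb2[["20"]], c(90:99, 101:110))
  expect_false(100L %in% unlist(nb2))
  expect_error(neighborhoods(10L, 200L), "trim")
})

test_that("identical-beat record: all xcorr 1, lag 0, medsd 0; 72 values", {
  g <- clean_normal_record(100L)
  m <- beat_morph_features(g$record$signal, g$annotations$sample,
                           eval_idx = 45:50)
  expect_equal(ncol(m), 72L)
  expect_identical(colnames(m), morph_feature_names("raw"))
  expect_true(all(m[, grepl("_xcorr$", colnames(m))] > 0.9999))
  expect_true(all(m[, grepl("_lag$", colnames(m))] == 0))
  expect_lt(max(m[, grepl("_medsd$", colnames(m))]), 1e-9)
})

test_that("a ventricular beat scores lower QRS xcorr than in an all-N record", {
  # same rhythm/seed, one config with a PVC pattern injected manually:
  # replace the middle beat's kernel by comparing two generated records
  g_clean <- clean_normal_record(120L, seed = 9L)
  cfg <- synth_config(n_beats = 120L, pac_rate = 0, pvc_rate = 0,
                      sd_rr = 0, resp_amp = 0, noise_sd = 0,
                      wander_amp = 0, seed = 9L)
  g_pvc <- generate_record(cfg, "pvc01")
  mid <- 60L
  kern <- lapply(1:2, function(L) beat_waveform("V", cfg, L))
  sig <- g_pvc$record$signal
  r <- g_pvc$annotations$sample[mid]
  nkern <- lapply(1:2, function(L) beat_waveform("N", cfg, L))
  for (L in 1:2) {
    idx <- r + kern[[L]]$offsets + 1L
    sig[idx, L] <- sig[idx, L] - nkern[[L]]$values + kern[[L]]$values
  }
  m_clean <- beat_morph_features(g_clean$record$signal,
                                 g_clean$annotations$sample, mid)
  m_pvc <- beat_morph_features(sig, g_pvc$annotations$sample, mid)
  expect_lt(m_pvc[1, "morph_raw_qrs_t80_L1_xcorr"],
            m_clean[1, "morph_raw_qrs_t80_L1_xcorr"] - 0.2)
})
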