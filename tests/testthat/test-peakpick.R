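test_that("smoothing/baseline identity and closed-form configurations", {
  run <- one_peak_run()
  out <- smooth_and_baseline(run, window = 1L, baseline_quantile = 0)
  expect_equal(eic_matrix(out)$mat, eic_matrix(run)$mat, tolerance = 1e-12)
  ## constant signal minus its rolling median is zero
  des <- quiet_design(baseline_level = 5)
  flat <- simulate_run(list(), des, "s1", "g", "room_air", jitter = FALSE)
  out2 <- smooth_and_baseline(flat, window = 1L, baseline_quantile = 0.5)
  expect_true(all(abs(eic_matrix(out2)$mat) < 1e-9))
  ## a constant offset b under a peak is removed from the apex height
  b <- 500
  des3 <- quiet_design(baseline_level = b)
  run3 <- simulate_run(list(toluene_like(3)), des3, "s1", "g", "mother",
                       jitter = FALSE)
  out3 <- smooth_and_baseline(run3, window = 1L, baseline_quantile = 0.25,
                              baseline_window = 801L)
  apex0 <- max(eic_matrix(run3)$mat[, match(91L, eic_matrix(run3)$mz)])
  apex1 <- max(eic_matrix(out3)$mat[, match(91L, eic_matrix(out3)$mz)])
  expect_equal(apex0 - apex1, b, tolerance = 0.02 * b)
  expect_error(smooth_and_baseline(run, window = 4L), "odd")
})

test_that("matched filter finds a noiseless peak at the oracle apex", {
  run <- one_peak_run(rt = 3, abundance = 1e5)
  feats <- detect_peaks(run, fwhm = 0.05, snr_threshold = 5,
                        mz_range = c(38, 150))
  f91 <- feats[feats$mz == 91, ]
  expect_equal(nrow(f91), 1L)
  expect_equal(f91$rt, oracle_apex(run, 91), tolerance = 0.005 + 1e-9)
  expect_equal(f91$maxo, 1e5, tolerance = 0.01 * 1e5)
  expect_true(f91$rt_lo <= f91$rt && f91$rt <= f91$rt_hi)
  ## every planted fragment found at its unit mass
  expect_setequal(feats$mz, c(39, 65, 91, 92))
})

test_that("two peaks six sigma apart resolve into two features", {
  des <- quiet_design()
  cmps <- list(toluene_like(3), toluene_like(3 + 6 * 0.02))
  run <- simulate_run(cmps, des, "s1", "g", "mother", jitter = FALSE)
  feats <- detect_peaks(run, fwhm = 0.05, snr_threshold = 5,
                        mz_range = c(91, 91))
  expect_equal(nrow(feats), 2L)
  ## oracle: distinct local maxima of the raw EIC above half height
  e <- eic_matrix(run, c(91, 91))
  lm_idx <- which(diff(sign(diff(e$mat[, 1]))) == -2) + 1L
  lm_idx <- lm_idx[e$mat[lm_idx, 1] > max(e$mat[, 1]) / 2]
  expect_equal(sort(feats$rt), sort(e$rt[lm_idx]), tolerance = 0.005)
})

test_that("pure noise rarely produces features at SNR 10", {
  des <- quiet_design(noise_sd = 30, baseline_level = 0, mz_hi = 60)
  hits <- 0L
  set.seed(99)
  for (i in 1:20) {
    run <- simulate_run(list(), des, "s1", "g", "room_air", jitter = FALSE)
    feats <- detect_peaks(run, fwhm = 0.05, snr_threshold = 10,
                          mz_range = c(38, 60))
    hits <- hits + (nrow(feats) > 0L)
  }
  expect_lte(hits, 1L)
})

test_that("detection recall: ions at 20x the noise floor are all found", {
  des <- quiet_design(noise_sd = 25, baseline_level = 50, mz_hi = 150)
  set.seed(7)
  run <- simulate_run(list(toluene_like(3, abundance = 25 * 20 / 0.12)),
                      des, "s1", "g", "mother", jitter = FALSE)
  ## weakest planted ion (rel 120) has height 500 = 20x noise sd
  sm <- smooth_and_baseline(run)
  feats <- detect_peaks(sm, fwhm = 0.05, snr_threshold = 5,
                        mz_range = c(38, 150))
  for (ion in c(39, 65, 91, 92)) {
    fi <- feats[feats$mz == ion, ]
    expect_gte(nrow(fi), 1L)
    expect_lte(min(abs(fi$rt - 3)), 2 * des$scan_interval)
  }
})

test_that("alignment removes an injected constant shift", {
  des <- quiet_design(noise_sd = 10, baseline_level = 20, seed = 3)
  lib <- make_library(8, seed = 3, mz_range = c(38, 140), rt_span = c(2, 8))
  runs <- lapply(1:3, function(i)
    simulate_run(lib$compounds, des, sprintf("s%d", i), "g", "mother",
                 jitter = FALSE))
  names(runs) <- sprintf("s%d", 1:3)
  ## shift the third sample's clock by +0.30 min
  runs$s3$rt <- runs$s3$rt + 0.30
  feats <- lapply(runs, detect_peaks, fwhm = 0.05, snr_threshold = 5,
                  mz_range = c(38, 140))
  al <- align_retention_times(feats)
  ## residual shift on anchor groups < 0.01 min
  regrouped <- group_features(al$features, rt_bw = 2 / 60, minfrac = 1,
                              samples = names(runs))
  dev <- regrouped$members$rt -
    stats::setNames(regrouped$groups$rt_median,
                    regrouped$groups$group_feature_id)[
                      regrouped$members$group_feature_id]
  expect_lt(max(abs(dev[regrouped$members$sample_id == "s3"])), 0.01)
  ## anchor-group retention variance never increases
  pre <- group_features(feats, rt_bw = 0.5, minfrac = 1, samples = names(runs))
  var_of <- function(gr) vapply(gr$groups$group_feature_id, function(id)
    stats::var(gr$members$rt[gr$members$group_feature_id == id]), numeric(1))
  expect_lte(mean(var_of(regrouped)), mean(var_of(pre)) + 1e-12)
})

test_that("alignment degenerates to the identity warp", {
  f <- detect_peaks(one_peak_run(), fwhm = 0.05, snr_threshold = 5,
                    mz_range = c(38, 150))
  expect_warning(al <- align_retention_times(list(s1 = f)), "fewer than 2")
  expect_equal(al$features$s1$rt, f$rt)
  ## already-aligned samples stay put
  runs <- lapply(1:3, function(i) one_peak_run(sample_id = sprintf("s%d", i)))
  feats <- lapply(runs, detect_peaks, fwhm = 0.05, snr_threshold = 5,
                  mz_range = c(38, 150))
  names(feats) <- sprintf("s%d", 1:3)
  al <- align_retention_times(feats)
  for (s in names(feats))
    expect_lt(max(abs(al$features[[s]]$rt - feats[[s]]$rt)), 1e-6)
})

test_that("grouping matches the exhaustive single-linkage oracle", {
  mk <- function(rt, sample, mz = 91L) data.frame(
    feature_id = sprintf("%s_%0.3f", sample, rt), sample_id = sample,
    mz = mz, rt = rt, rt_lo = rt - 0.02, rt_hi = rt + 0.02, maxo = 100,
    stringsAsFactors = FALSE)
  ## identical peak in 3 samples -> one group of 3
  f <- rbind(mk(10, "a"), mk(10, "b"), mk(10, "c"))
  g <- group_features(f, rt_bw = 2 / 60, minfrac = 0.5)
  expect_equal(nrow(g$groups), 1L)
  expect_equal(nrow(g$members), 3L)
  ## two clusters 10 bandwidths apart
  f2 <- rbind(mk(10, "a"), mk(10, "b"), mk(10 + 10 * 2 / 60, "a"),
              mk(10 + 10 * 2 / 60, "b"))
  g2 <- group_features(f2, rt_bw = 2 / 60, minfrac = 0.5)
  expect_equal(nrow(g2$groups), 2L)
  ## randomized <= 10-point instances against the dendrogram cut
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(2:10, 1)
    rts <- round(stats::runif(n, 0, 1), 3)
    rts <- rts + seq_len(n) * 1e-6  # break exact ties
    f3 <- do.call(rbind, lapply(seq_len(n), function(i)
      mk(rts[i], sprintf("s%d", i))))
    g3 <- group_features(f3, rt_bw = 0.07, minfrac = 0)
    oracle <- oracle_cluster(rts, 0.07)
    got <- vapply(seq_len(n), function(i) {
      m <- g3$members[g3$members$feature_id == f3$feature_id[i], ]
      m$group_feature_id[1]
    }, character(1))
    expect_equal(length(unique(got)), length(unique(oracle)))
    expect_true(all(tapply(got, oracle, function(x) length(unique(x))) == 1))
  }
  ## singletons below the support fraction are dropped
  f4 <- rbind(mk(10, "a"), mk(10, "b"), mk(20, "c"))
  g4 <- group_features(f4, rt_bw = 2 / 60, minfrac = 0.5)
  expect_equal(nrow(g4$groups), 1L)
  expect_false(20 %in% round(g4$groups$rt_median))
})

test_that("gap filling reads the raw window and never alters members", {
  des <- quiet_design(seed = 2)
  runs <- list(s1 = one_peak_run(sample_id = "s1"),
               s2 = one_peak_run(sample_id = "s2"),
               s3 = simulate_run(list(), des, "s3", "g", "mother",
                                 jitter = FALSE))
  feats <- lapply(runs, detect_peaks, fwhm = 0.05, snr_threshold = 5,
                  mz_range = c(38, 150))
  g <- group_features(feats, rt_bw = 2 / 60, minfrac = 0.5,
                      samples = names(runs))
  fm <- fill_missing(g, runs)
  expect_false(any(is.na(fm$values)))
  ## members kept verbatim
  for (i in seq_len(nrow(g$members))) {
    m <- g$members[i, ]
    expect_equal(fm$values[m$group_feature_id, m$sample_id], m$maxo)
    expect_false(fm$filled[m$group_feature_id, m$sample_id])
  }
  ## s3 is flat zero there
  expect_true(all(fm$filled[, "s3"]))
  expect_true(all(fm$values[, "s3"] == 0))
})

test_that("gap filling recovers a planted sub-threshold peak", {
  des <- quiet_design(seed = 2)
  h <- 1e5
  runs <- list(s1 = one_peak_run(abundance = h, sample_id = "s1"),
               s2 = one_peak_run(abundance = h, sample_id = "s2"),
               s3 = one_peak_run(abundance = h / 1e4, sample_id = "s3"))
  feats <- lapply(runs, detect_peaks, fwhm = 0.05, snr_threshold = 5,
                  mz_range = c(91, 91))
  ## drop s3's detection to force a gap over the real (weak) peak
  feats$s3 <- feats$s3[0, ]
  g <- group_features(feats, rt_bw = 2 / 60, minfrac = 0.5,
                      samples = names(runs))
  fm <- fill_missing(g, runs)
  expect_true(fm$filled["FT00001", "s3"])
  expect_equal(fm$values["FT00001", "s3"], h / 1e4,
               tolerance = 0.05 * h / 1e4)
})
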