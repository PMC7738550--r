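test_that("match factor endpoints and hand-computed weighted cosine", {
  s <- c(`91` = 1000, `92` = 500)
  expect_equal(match_factor(s, s), 100)
  expect_equal(match_factor(s, s * 0.37), 100)  # proportional spectra
  expect_equal(match_factor(c(`91` = 1000), c(`45` = 1000)), 0)
  ## brute-force arithmetic oracle for {91:1000} vs {91:1000, 65:200}
  q <- c(`91` = 1000); e <- c(`65` = 200, `91` = 1000)
  wq <- c(0, 91 * sqrt(1000))
  we <- c(65 * sqrt(200), 91 * sqrt(1000))
  oracle <- 100 * sum(wq * we) / sqrt(sum(wq^2) * sum(we^2))
  expect_equal(match_factor(q, e), oracle, tolerance = 1e-12)
  expect_equal(match_factor(q, e), match_factor(e, q))
  expect_error(match_factor(q, numeric(0)), "empty")
  ## identity property over random spectra
  set.seed(31)
  for (rep in 1:20) {
    sp <- stats::setNames(stats::runif(8, 1, 1000), sample(38:400, 8))
    expect_equal(match_factor(sp, sp), 100, tolerance = 1e-9)
  }
})

test_that("retention indices interpolate linearly between alkane anchors", {
  anchors <- data.frame(label = sprintf("C%d", 7:30), rt = alkane_rt_truth(7:30),
                        ri = 100 * (7:30))
  ## anchor identity, exact
  for (i in seq_len(nrow(anchors)))
    expect_identical(as.numeric(compute_ri(anchors$rt[i], anchors)),
                     anchors$ri[i])
  ## midway between C10 and C11 -> 1050
  mid <- mean(anchors$rt[anchors$label %in% c("C10", "C11")])
  expect_equal(as.numeric(compute_ri(mid, anchors)), 1050)
  ## extrapolation is flagged
  lo <- compute_ri(anchors$rt[1] - 1, anchors)
  expect_true(attr(lo, "extrapolated"))
  inb <- compute_ri(mean(anchors$rt[2:3]), anchors)
  expect_false(attr(inb, "extrapolated"))
  ## monotone in rt
  rts <- seq(min(anchors$rt) - 1, max(anchors$rt) + 1, length.out = 50)
  expect_true(all(diff(as.numeric(compute_ri(rts, anchors))) > 0))
  expect_error(compute_ri(5, anchors[1, , drop = FALSE]), "anchors")
})

test_that("RI error is the percent disagreement relative to the entry", {
  expect_equal(ri_error(1000, 1000), 0)
  expect_equal(ri_error(1100, 1000), 10)
  expect_equal(ri_error(800, 1000), 20)
  expect_error(ri_error(1000, 0), "RI")
})

test_that("candidate extraction applies floor, window and cap", {
  base <- c(`91` = 1000, `92` = 500, `65` = 200)
  ## entries engineered to give a descending MF ladder
  perturb <- function(eps) {
    s <- base; s[["65"]] <- s[["65"]] + eps; rescale_1000(s)
  }
  lib <- structure(list(entries = list(
    list(name = "exact", spectrum = base, retention_index = NA, molecular_weight = NA),
    list(name = "close", spectrum = perturb(400), retention_index = NA, molecular_weight = NA),
    list(name = "far", spectrum = c(`45` = 1000, `57` = 800),
         retention_index = NA, molecular_weight = NA))),
    class = "spectral_library")
  cand <- candidate_entries(base, lib, mf_floor = 80, mf_window = 5)
  mf <- vapply(lib$entries, function(e) match_factor(base, e$spectrum),
               numeric(1))
  expect_equal(cand$name,
               c("exact", "close")[order(-mf[1:2])][mf[order(-mf[1:2])] >
                                                      max(mf) - 5 &
                                                      sort(mf[1:2],
                                                           TRUE) > 80])
  expect_false("far" %in% cand$name)
  ## nothing clears the floor -> empty
  none <- candidate_entries(c(`45` = 1000), structure(list(entries = list(
    list(name = "x", spectrum = base, retention_index = NA,
         molecular_weight = NA))), class = "spectral_library"))
  expect_equal(nrow(none), 0L)
  ## more qualifying entries than the cap -> truncated to 450
  big <- structure(list(entries = replicate(500, list(
    name = "dup", spectrum = base, retention_index = NA,
    molecular_weight = NA), simplify = FALSE)), class = "spectral_library")
  expect_equal(nrow(candidate_entries(base, big)), 450L)
})

test_that("best-entry selection prioritises RI error, then match factor", {
  cand <- data.frame(entry = 1:2, name = c("low_ri_err", "high_mf"),
                     match_factor = c(92, 95), ri_entry = c(1000, 1000),
                     ri_error = c(3, 18), stringsAsFactors = FALSE)
  best <- select_best(cand)
  expect_equal(best$entry_name, "low_ri_err")
  expect_equal(best$rank_basis, "ri_and_mf")
  ## all RI errors above 20 -> fall back to the match factor
  cand2 <- transform(cand, ri_error = c(25, 30))
  best2 <- select_best(cand2)
  expect_equal(best2$entry_name, "high_mf")
  expect_equal(best2$rank_basis, "mf_only")
  ## single candidate without RI
  cand3 <- data.frame(entry = 1, name = "only", match_factor = 90,
                      ri_entry = NA, ri_error = NA, stringsAsFactors = FALSE)
  expect_equal(select_best(cand3)$rank_basis, "mf_only")
  ## an RI error of exactly 20 is kept ("greater than 20% discarded")
  cand4 <- transform(cand, ri_error = c(20, 25))
  expect_equal(select_best(cand4)$rank_basis, "ri_and_mf")
  ## empty candidates -> explicit null identification
  none <- select_best(cand[0, ])
  expect_true(is.na(none$entry_name))
})

test_that("alkane anchoring runs its six filters on a synthetic ladder", {
  span <- c(1.2, 8.5)
  lad <- alkane_ladder(carbons = 7:12, span = span)
  rts <- vapply(lad$compounds, `[[`, numeric(1), "rt_mean")
  mk_cmp <- function(id, rt, spec) list(compound_id = id, sample_id = "s1",
                                        rt = rt, spectrum = spec, area = 1,
                                        segment = 1L, sigma = 0.02)
  cmps <- lapply(seq_along(lad$compounds), function(i)
    mk_cmp(sprintf("D%d", i), rts[i], lad$compounds[[i]]$spectrum))
  ## a decoy with an alkane-like spectrum but no molecular ion
  dec_spec <- lad$compounds[[2]]$spectrum
  dec_spec <- dec_spec[names(dec_spec) != "114"]  # strip C8's M+ (114)
  cmps <- c(cmps, list(mk_cmp("decoy", rts[2] + 0.2, rescale_1000(dec_spec))))
  ## feature groups confirming each alkane's molecular ion at its RT
  g <- structure(list(groups = data.frame(
    group_feature_id = sprintf("F%d", 7:12), mz = 14L * (7:12) + 2L,
    rt_median = rts, rt_lo = rts - 0.05, rt_hi = rts + 0.05,
    n_samples = 1L, stringsAsFactors = FALSE),
    members = data.frame(), samples = "s1"), class = "feature_groups")
  res <- anchor_alkanes(cmps, g, alkane_ladder(carbons = 7:24)$library)
  expect_equal(res$anchors$carbon, 7:12)
  expect_equal(res$anchors$ri, 100 * (7:12))
  expect_equal(res$anchors$rt, rts, tolerance = 1e-9)
  expect_true(any(res$diagnostics$removed_by == "molecular_ion" &
                    res$diagnostics$compound_id == "decoy"))
  ## cross-approach confirmation: remove C9 feature -> C9 anchor vanishes
  g2 <- g; g2$groups <- g2$groups[g2$groups$mz != 14L * 9L + 2L, ]
  res2 <- anchor_alkanes(cmps[1:6], g2, alkane_ladder(carbons = 7:24)$library)
  expect_false(9 %in% res2$anchors$carbon)
  ## planted RT outlier on the carbon line is removed by the MAD filter
  cmps3 <- cmps[1:6]
  cmps3[[3]]$rt <- rts[3] + 1.5   # C9 way off the line
  g3 <- g; g3$groups$rt_median[3] <- rts[3] + 1.5
  res3 <- anchor_alkanes(cmps3, g3, alkane_ladder(carbons = 7:24)$library)
  expect_false(9 %in% res3$anchors$carbon)
  expect_equal(sort(res3$anchors$carbon), setdiff(7:12, 9))
  ## fewer than two surviving anchors is an error
  expect_error(anchor_alkanes(cmps[1], g, alkane_ladder(carbons = 7:24)$library),
               "anchor")
})

test_that("lowest-RT rule picks the earliest confirmed compound per alkane", {
  span <- c(1.2, 8.5)
  lad <- alkane_ladder(carbons = 7:10, span = span)
  rts <- vapply(lad$compounds, `[[`, numeric(1), "rt_mean")
  mk_cmp <- function(id, rt, spec) list(compound_id = id, sample_id = "s1",
                                        rt = rt, spectrum = spec, area = 1,
                                        segment = 1L, sigma = 0.02)
  cmps <- lapply(seq_along(lad$compounds), function(i)
    mk_cmp(sprintf("D%d", i), rts[i], lad$compounds[[i]]$spectrum))
  ## a later twin of C8 (same spectrum) must lose to the earlier one
  cmps <- c(cmps, list(mk_cmp("late_twin", rts[2] + 0.04,
                              lad$compounds[[2]]$spectrum)))
  g <- structure(list(groups = data.frame(
    group_feature_id = c(sprintf("F%d", 7:10), "Ftwin"),
    mz = c(14L * (7:10) + 2L, 14L * 8L + 2L),
    rt_median = c(rts, rts[2] + 0.04),
    rt_lo = 0, rt_hi = 10, n_samples = 1L, stringsAsFactors = FALSE),
    members = data.frame(), samples = "s1"), class = "feature_groups")
  res <- anchor_alkanes(cmps, g, alkane_ladder(carbons = 7:24)$library)
  a8 <- res$anchors[res$anchors$carbon == 8, ]
  expect_equal(a8$rt, rts[2], tolerance = 1e-9)
})

test_that("identify_compounds ties the pieces together", {
  lib <- make_library(5, seed = 13, mz_range = c(38, 200),
                      rt_span = c(2, 8), alkane_span = c(1.2, 8.5))
  anchors <- data.frame(label = sprintf("C%d", 7:30),
                        rt = alkane_rt_truth(7:30, c(1.2, 8.5)),
                        ri = 100 * (7:30))
  al <- mk_aligned_identify <- structure(list(
    compounds = lapply(seq_along(lib$compounds), function(i) list(
      aligned_id = sprintf("AC%d", i), rt = lib$compounds[[i]]$rt_mean,
      spectrum = lib$compounds[[i]]$spectrum,
      areas = c(s1 = 1), rts = 1, recovered = character(0), segment = 1L,
      sigma = 0.02)),
    shifts = c(s1 = 0)), class = "aligned_compounds")
  id <- identify_compounds(al, lib$library, anchors = anchors)
  expect_equal(nrow(id), 5L)
  expect_equal(id$entry_name,
               vapply(lib$compounds, `[[`, character(1), "name"))
  expect_true(all(id$match_factor > 99.9))
  expect_true(all(id$ri_error < 20))
})
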