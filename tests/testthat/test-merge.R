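mk_aligned <- function(...) {
  cmps <- list(...)
  structure(list(compounds = cmps,
                 shifts = stats::setNames(
                   numeric(0), character(0))),
            class = "aligned_compounds")
}

mk_cmp <- function(id, rt, spec, areas = c(s1 = 1)) {
  list(aligned_id = id, rt = rt, spectrum = rescale_1000(spec),
       areas = areas, rts = rt, recovered = character(0), segment = 2L,
       sigma = 0.02)
}

mk_groups <- function(df) {
  structure(list(groups = df,
                 members = data.frame(group_feature_id = character(0),
                                      sample_id = character(0),
                                      feature_id = character(0),
                                      rt = numeric(0), maxo = numeric(0)),
                 samples = "s1"),
            class = "feature_groups")
}

test_that("feature-ion matching enforces m/z identity and the 0.05 min rule", {
  g <- mk_groups(data.frame(
    group_feature_id = c("F91", "F92", "F93"), mz = c(91L, 92L, 93L),
    rt_median = c(10.02, 10.06, 10.01), rt_lo = 9.9, rt_hi = 10.2,
    n_samples = 3L, stringsAsFactors = FALSE))
  al <- mk_aligned(mk_cmp("AC1", 10.00, c(`91` = 1000, `92` = 400)))
  m <- match_features_to_ions(g, al, rt_tol = 0.05)
  expect_equal(m$group_feature_id, "F91")       # 91 matches at 0.02
  expect_false("F92" %in% m$group_feature_id)    # 0.06 exceeds the window
  expect_false("F93" %in% m$group_feature_id)    # 93 absent from spectrum
  ## boundary: exactly 0.05 is inside
  g2 <- mk_groups(data.frame(group_feature_id = "F91", mz = 91L,
                             rt_median = 10.05, rt_lo = 9.9, rt_hi = 10.2,
                             n_samples = 1L, stringsAsFactors = FALSE))
  expect_equal(nrow(match_features_to_ions(g2, al)), 1L)
  ## nearest feature wins within one compound
  g3 <- mk_groups(data.frame(
    group_feature_id = c("Fa", "Fb"), mz = 91L, rt_median = c(10.01, 10.04),
    rt_lo = 9.9, rt_hi = 10.2, n_samples = 1L, stringsAsFactors = FALSE))
  m3 <- match_features_to_ions(g3, al)
  expect_equal(m3$group_feature_id, "Fa")
})

test_that("the three-step relative-intensity protocol is verbatim arithmetic", {
  fm <- feature_matrix(
    features = data.frame(feature_id = c("A", "B", "C"), mz = 91:93,
                          rt_median = 10, stringsAsFactors = FALSE),
    values = matrix(c(300, 100, 150, 50, 75, 25), 3, 2, byrow = TRUE,
                    dimnames = list(c("A", "B", "C"), c("s1", "s2"))))
  ## averages: A 200, B 100, C 50
  rel <- relative_intensities(c("A", "B", "C"), fm)
  expect_equal(rel, c(A = 1000, B = 500, C = 250))
  expect_equal(relative_intensities("B", fm), c(B = 1000))
  ## ties: both receive 1000 by the formula
  fm2 <- feature_matrix(
    features = data.frame(feature_id = c("A", "B"), mz = 91:92,
                          rt_median = 10, stringsAsFactors = FALSE),
    values = matrix(7, 2, 2, dimnames = list(c("A", "B"), c("s1", "s2"))))
  expect_equal(relative_intensities(c("A", "B"), fm2), c(A = 1000, B = 1000))
})

test_that("spectrum vectors span 412 half-open positions and unit norm", {
  v <- vectorize_spectrum(c(`91` = 1000))
  expect_length(v$values, 412L)
  expect_true(v$normalized)
  expect_equal(which(v$values > 0), 91 - 38 + 1)
  expect_equal(sqrt(sum(v$values^2)), 1, tolerance = 1e-12)
  ## empty spectrum: all-zero, flagged
  v0 <- vectorize_spectrum(stats::setNames(numeric(0), character(0)))
  expect_false(v0$normalized)
  expect_true(all(v0$values == 0))
  ## m/z 450 is outside the half-open range, 38 inside
  expect_warning(v2 <- vectorize_spectrum(c(`38` = 10, `450` = 10)), "range")
  expect_equal(which(v2$values > 0), 1L)
  expect_error(vectorize_spectrum(c(`91` = 1), mz_lo = 100, mz_hi = 100),
               "mz_lo")
})

test_that("spectral dot product has the documented geometry", {
  v <- vectorize_spectrum(c(`91` = 1000, `92` = 500))
  expect_equal(spectral_dot(v, v), 1, tolerance = 1e-12)
  a <- vectorize_spectrum(c(`91` = 1000))
  b <- vectorize_spectrum(c(`92` = 1000))
  expect_equal(spectral_dot(a, b), 0)
  ## hand computation: {91:1000} vs {91:1000, 92:500} -> 2/sqrt(5)
  c1 <- vectorize_spectrum(c(`91` = 1000, `92` = 500))
  expect_equal(spectral_dot(a, c1), 2 / sqrt(5), tolerance = 1e-12)
  expect_error(spectral_dot(a, vectorize_spectrum(c(`91` = 1), 38, 400)),
               "bounds")
  ## properties over random spectra: symmetry, scale invariance,
  ## identity iff proportional
  set.seed(21)
  for (rep in 1:25) {
    s1 <- stats::setNames(stats::runif(6, 1, 1000), sample(38:449, 6))
    s2 <- stats::setNames(stats::runif(6, 1, 1000), sample(38:449, 6))
    v1 <- vectorize_spectrum(s1); v2 <- vectorize_spectrum(s2)
    expect_equal(spectral_dot(v1, v2), spectral_dot(v2, v1))
    expect_equal(spectral_dot(vectorize_spectrum(s1 * 7.3), v2),
                 spectral_dot(v1, v2), tolerance = 1e-12)
    expect_equal(spectral_dot(v1, vectorize_spectrum(s1 * 0.21)), 1,
                 tolerance = 1e-9)
    if (!setequal(names(s1), names(s2)))
      expect_lt(spectral_dot(v1, v2), 1)
  }
})

test_that("compound matching keeps only best matches above 0.7", {
  spec_a <- c(`91` = 1000, `92` = 500)
  spec_b <- c(`45` = 1000, `57` = 300)
  al <- mk_aligned(mk_cmp("ACa", 10, spec_a), mk_cmp("ACb", 20, spec_b))
  ions <- data.frame(aligned_id = c("ACa", "ACb"), mz = c(91L, 45L),
                     group_feature_id = c("F1", "F2"),
                     delta_rt = 0, stringsAsFactors = FALSE)
  fs <- match_compounds(list(CL1 = spec_a), c(CL1 = 10), al, ions)
  expect_equal(fs$filtered_compounds, "ACa")
  expect_equal(fs$filtered_features, "F1")
  expect_true(all(fs$matches$dot >= 0 & fs$matches$dot <= 1))
  ## a best dot at or below 0.7 is not selected ("higher than 0.7")
  mixed <- c(`91` = 1000, `45` = 979)  # dot vs spec_a just below 0.7
  stopifnot(abs(sum(vectorize_spectrum(mixed)$values *
                      vectorize_spectrum(spec_a)$values)) < 0.7)
  fs2 <- match_compounds(list(CL1 = mixed), c(CL1 = 10),
                         mk_aligned(mk_cmp("ACc", 10, spec_a)), ions[0, ])
  expect_length(fs2$filtered_compounds, 0L)
  ## second-best everywhere is excluded even with a high dot
  near_a <- c(`91` = 1000, `92` = 480)
  al3 <- mk_aligned(mk_cmp("AC1", 10, spec_a), mk_cmp("AC2", 10, near_a))
  fs3 <- match_compounds(list(CL1 = spec_a), c(CL1 = 10), al3, ions[0, ])
  expect_equal(fs3$filtered_compounds, "AC1")
  best <- fs3$matches[fs3$matches$is_best_for_clique, ]
  expect_equal(best$aligned_id, "AC1")
})

test_that("duplicate detection applies all three criteria", {
  spec <- c(`91` = 1000, `92` = 500)
  near <- c(`91` = 1000, `92` = 450)
  mk_dup <- function(id, rt, spec, areas = NULL, size = NULL)
    c(list(id = id, rt = rt, spectrum = spec),
      if (!is.null(areas)) list(areas = areas),
      if (!is.null(size)) list(size = size))
  ar1 <- c(s1 = 10, s2 = 50, s3 = 90, s4 = 20)
  ## planted split: dot ~0.999, 0.03 min apart, correlated areas -> flagged
  d <- detect_duplicates(list(
    mk_dup("A", 10.00, spec, areas = ar1),
    mk_dup("B", 10.03, near, areas = ar1 * 1.1)))
  expect_equal(nrow(d$pairs), 1L)
  expect_length(d$deduplicated, 1L)
  expect_equal(d$deduplicated, "B")  # larger total area survives
  ## retention rule: 0.2 min apart is not a duplicate
  d2 <- detect_duplicates(list(mk_dup("A", 10.0, spec, areas = ar1),
                               mk_dup("B", 10.2, near, areas = ar1)))
  expect_equal(nrow(d2$pairs), 0L)
  ## Pearson rule on the deconvolved side
  d3 <- detect_duplicates(list(
    mk_dup("A", 10.00, spec, areas = c(s1 = 10, s2 = 50, s3 = 90, s4 = 20)),
    mk_dup("B", 10.02, near, areas = c(s1 = 80, s2 = 20, s3 = 30, s4 = 70))))
  expect_equal(nrow(d3$pairs), 0L)
  ## clique side: no areas, retention + dot suffice; larger size survives
  d4 <- detect_duplicates(list(mk_dup("A", 10.00, spec, size = 5),
                               mk_dup("B", 10.02, near, size = 9)))
  expect_equal(nrow(d4$pairs), 1L)
  expect_equal(d4$deduplicated, "B")
  ## fewer than two compounds: empty report
  expect_equal(nrow(detect_duplicates(list(mk_dup("A", 1, spec)))$pairs), 0L)
})

test_that("normalization follows the printed log-ratio formula per subset", {
  fm <- feature_matrix(
    features = data.frame(feature_id = "F", mz = 91L, rt_median = 10,
                          stringsAsFactors = FALSE),
    values = matrix(c(100, 9900), 1, 2,
                    dimnames = list("F", c("s1", "s2"))))
  norm <- normalize_matrix(fm)
  ## log10(100) / log10(10000) * 1000 = 2/4 * 1000
  expect_equal(unname(norm$values["F", "s1"]), 500)
  ## single-sample subset: exactly 1000
  fm1 <- feature_matrix(
    features = fm$features,
    values = matrix(123.4, 1, 1, dimnames = list("F", "s1")))
  expect_equal(unname(normalize_matrix(fm1)$values["F", "s1"]), 1000)
  ## a raw value of 1 maps to 0
  fm2 <- feature_matrix(
    features = fm$features,
    values = matrix(c(1, 9999), 1, 2, dimnames = list("F", c("s1", "s2"))))
  expect_equal(unname(normalize_matrix(fm2)$values["F", "s1"]), 0)
  ## non-positive denominator drops the feature with a warning
  fm3 <- feature_matrix(
    features = fm$features,
    values = matrix(c(0.2, 0.3), 1, 2, dimnames = list("F", c("s1", "s2"))))
  expect_warning(norm3 <- normalize_matrix(fm3), "dropped")
  expect_equal(nrow(norm3$values), 0L)
  ## alternative denominator readings stay available
  expect_silent(normalize_matrix(fm, denominator = "mean"))
  expect_silent(normalize_matrix(fm, denominator = "sum_of_logs"))
})
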