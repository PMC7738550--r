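# Shared fixtures: a compressed three-ramp program keeps unit tests fast
# (same scan spacing and peak widths as the full-length program).

short_program <- function() temperature_program(boundaries = c(2, 6), end = 9)

quiet_design <- function(noise_sd = 0, baseline_level = 0, seed = 1,
                         mz_hi = 150, rt_jitter_sd = 0, ...) {
  cohort_design(noise_sd = noise_sd, baseline_level = baseline_level,
                seed = seed, ramp_program = short_program(),
                scan_mz_range = c(35, mz_hi), rt_jitter_sd = rt_jitter_sd,
                ...)
}

toluene_like <- function(rt = 3, abundance = 1e5, sigma = 0.02) {
  true_compound("toluene-like",
                c(`39` = 120, `65` = 200, `91` = 1000, `92` = 500),
                rt_mean = rt, peak_sigma = sigma,
                abundance_by_sample = c(default = abundance))
}

one_peak_run <- function(rt = 3, abundance = 1e5, design = quiet_design(),
                         sample_id = "s1", group_id = "group1") {
  simulate_run(list(toluene_like(rt, abundance)), design, sample_id,
               group_id, "mother", jitter = FALSE)
}

# Brute-force apex oracle: scan of maximum raw intensity of one unit-mass EIC.
oracle_apex <- function(run, mz) {
  e <- eic_matrix(run)
  col <- match(as.integer(mz), e$mz)
  e$rt[which.max(e$mat[, col])]
}

# Exhaustive 1-D clustering oracle: single-linkage dendrogram cut at h.
oracle_cluster <- function(rt, h) {
  if (length(rt) == 1L) return(1L)
  stats::cutree(stats::hclust(stats::dist(rt), method = "single"), h = h)
}

# The full-scale synthetic study (built once; several acceptance checks and
# the recovery test share it).
.study_cache <- new.env(parent = emptyenv())

acceptance_study <- function() {
  if (is.null(.study_cache$study)) {
    .study_cache$study <- demo_pipeline(seed = 1, out_dir = file.path(
      tempdir(), "vocpipe_acceptance"), quiet = TRUE)
  }
  .study_cache$study
}

msp_text <- function(...) {
  path <- tempfile(fileext = ".msp")
  writeLines(c(...), path)
  path
}
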