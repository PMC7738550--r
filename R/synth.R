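#' Synthetic breath-like GC/MS cohorts with known ground truth
#'
#' The generator emulates the data the pipeline is built for: Gaussian
#' compound elution over a three-ramp temperature program, unit-mass EI
#' fragment spectra, a constant baseline plus additive detector noise,
#' a systematic between-group retention-time shift (the column-change
#' effect), two ubiquitous sampling-bag artifacts present in every breath
#' sample, and standards runs (C7-C30 n-alkane ladder, VOC mix).
#'
#' @name synth
NULL

## Ground-truth alkane retention grid: linear in carbon number, which makes
## the retention-index mapping exact and the anchor regression well-posed.
alkane_rt_truth <- function(n, span = c(1.5, 44.7), carbons = c(7, 30)) {
  span[1] + (span[2] - span[1]) * (n - carbons[1]) / (carbons[2] - carbons[1])
}

ri_from_rt_truth <- function(rt, span = c(1.5, 44.7), carbons = c(7, 30)) {
  100 * (carbons[1] + (carbons[2] - carbons[1]) * (rt - span[1]) /
           (span[2] - span[1]))
}

#' True (planted) compound
#'
#' @param name compound name.
#' @param spectrum named numeric, integer m/z -> relative intensity; rescaled
#'   so the base peak is 1000.
#' @param rt_mean apex retention time, minutes.
#' @param peak_sigma Gaussian elution sigma, minutes (> 0).
#' @param abundance_by_sample named numeric of per-sample apex heights of the
#'   base peak (abundance units); may be empty and filled by the cohort
#'   simulator.
#' @return object of class `true_compound`.
#' @export
true_compound <- function(name, spectrum, rt_mean, peak_sigma = 0.02,
                          abundance_by_sample = numeric(0)) {
  if (peak_sigma <= 0) stop("peak_sigma must be > 0", call. = FALSE)
  spectrum <- rescale_1000(spectrum)
  structure(list(name = name, spectrum = spectrum, rt_mean = rt_mean,
                 peak_sigma = peak_sigma,
                 abundance_by_sample = abundance_by_sample),
            class = "true_compound")
}

#' Ubiquitous sampling-bag artifact compounds
#'
#' N,N-dimethylacetamide and phenol, the well-documented Tedlar-bag
#' contaminants, with fixed EI-like unit-mass spectra. They are planted in
#' every non-standard run of a synthetic cohort.
#'
#' @param peak_sigma elution sigma, minutes.
#' @return list of two [true_compound()]s.
#' @export
artifact_compounds <- function(peak_sigma = 0.02) {
  dma <- true_compound(
    "N,N-dimethylacetamide",
    c(`43` = 420, `44` = 1000, `45` = 160, `72` = 310, `87` = 520),
    rt_mean = 14.5, peak_sigma = peak_sigma)
  phenol <- true_compound(
    "phenol",
    c(`39` = 240, `40` = 90, `47` = 60, `55` = 70, `65` = 220, `66` = 280,
      `94` = 1000, `95` = 70),
    rt_mean = 20.3, peak_sigma = peak_sigma)
  list(dma, phenol)
}

## Alkane fragment series for CnH2n+2: 43/57/71/... with decaying intensity,
## base peak 57, molecular ion 14n+2 kept at low relative intensity.
alkane_spectrum <- function(n_carbon) {
  mw <- 14L * n_carbon + 2L
  frag <- seq(43L, mw - 15L, by = 14L)
  ## base peak 57, geometric decay up the series, faint high-mass fragments
  rel <- pmax(1000 * 0.64^(seq_along(frag) - 2), 2)
  rel[1] <- 900
  spec <- stats::setNames(as.numeric(rel), frag)
  spec[as.character(mw)] <- 40
  rescale_1000(spec)
}

#' Synthetic n-alkane ladder
#'
#' Library entries (RI = 100 x carbon number, molecular weight 14n + 2) and
#' matching planted compounds at the ground-truth retention grid.
#'
#' @param carbons integer vector of carbon numbers (default 7:30, the C7-C30
#'   commercial ladder).
#' @param peak_sigma elution sigma, minutes.
#' @param abundance apex height of each alkane's base peak.
#' @param span retention times of C7 and C30 on the simulated program,
#'   minutes; the grid is linear in carbon number between them.
#' @return list with `library` (a `spectral_library`) and `compounds`
#'   (list of [true_compound()]).
#' @export
alkane_ladder <- function(carbons = 7:30, peak_sigma = 0.02,
                          abundance = 5e4, span = c(1.5, 44.7)) {
  entries <- lapply(carbons, function(n) list(
    name = sprintf("n-alkane C%d", n),
    spectrum = alkane_spectrum(n),
    retention_index = 100 * n,
    molecular_weight = 14L * n + 2L))
  compounds <- lapply(carbons, function(n)
    true_compound(sprintf("n-alkane C%d", n), alkane_spectrum(n),
                  rt_mean = alkane_rt_truth(n, span), peak_sigma = peak_sigma,
                  abundance_by_sample = c(default = abundance)))
  list(library = structure(list(entries = entries), class = "spectral_library"),
       compounds = compounds)
}

#' Generate a random EI spectral library with ground truth
#'
#' Each compound receives 5-25 unit-mass fragment ions inside `mz_range`, a
#' base peak of 1000, its largest ion recorded as the molecular ion
#' (`molecular_weight`), a ground-truth retention time on the simulated
#' program and the corresponding ground-truth retention index. Deterministic
#' for a fixed seed.
#'
#' @param n_compounds number of compounds (>= 1).
#' @param seed integer RNG seed.
#' @param mz_range inclusive m/z bounds for fragment ions.
#' @param rt_span retention window the compounds elute in, minutes.
#' @param peak_sigma elution sigma, minutes.
#' @param alkane_span retention times of C7 and C30 on the same program (the
#'   grid ground-truth retention indices are computed against); must match
#'   the ladder the cohort carries.
#' @return list with `library` (a `spectral_library`) and `compounds`
#'   (list of [true_compound()]), in matching order.
#' @export
make_library <- function(n_compounds, seed = 1L, mz_range = c(38, 450),
                         rt_span = c(2.5, 44), peak_sigma = 0.02,
                         alkane_span = c(1.5, 44.7)) {
  if (n_compounds < 1) stop("n_compounds must be >= 1", call. = FALSE)
  with_seed(seed, {
    entries <- vector("list", n_compounds)
    compounds <- vector("list", n_compounds)
    rts <- sort(stats::runif(n_compounds, rt_span[1], rt_span[2]))
    for (i in seq_len(n_compounds)) {
      n_ions <- sample(5:25, 1L)
      n_ions <- min(n_ions, mz_range[2] - mz_range[1] + 1L)
      mzs <- sort(sample(seq.int(mz_range[1], mz_range[2]), n_ions))
      rel <- stats::runif(n_ions, 10, 800)
      rel[sample(n_ions, 1L)] <- 1000
      rel[n_ions] <- max(rel[n_ions], 60)  # visible molecular ion
      spec <- rescale_1000(stats::setNames(rel, mzs))
      name <- sprintf("synthetic compound %03d", i)
      entries[[i]] <- list(name = name, spectrum = spec,
                           retention_index = ri_from_rt_truth(rts[i],
                                                              alkane_span),
                           molecular_weight = as.integer(mzs[n_ions]))
      compounds[[i]] <- true_compound(name, spec, rt_mean = rts[i],
                                      peak_sigma = peak_sigma)
    }
    list(library = structure(list(entries = entries),
                             class = "spectral_library"),
         compounds = compounds)
  })
}

#' Cohort design for the synthetic generator
#'
#' Defaults describe the emulated study conditions: two groups analysed on
#' different columns of the same model (a constant +0.3 min shift for the
#' second group plus small per-compound jitter), three subsets per group
#' (mothers, children, room air) preprocessed separately, a constant
#' baseline with additive Gaussian detector noise, ubiquitous bag artifacts,
#' and standards runs.
#'
#' @param n_mothers,n_children,n_room_air samples per group and subset.
#' @param groups named numeric: group id -> retention-time shift in minutes.
#' @param noise_sd additive noise standard deviation, abundance units.
#' @param baseline_level constant baseline, abundance units.
#' @param artifacts list of [true_compound()] present in every breath and
#'   room-air run.
#' @param include_alkane_ladder,include_voc_standard add standards runs per
#'   group.
#' @param seed integer seed; a fixed seed gives a bitwise-identical cohort.
#' @param scan_interval scan spacing, minutes.
#' @param scan_mz_range acquisition m/z range (unit masses).
#' @param rt_jitter_sd per-compound, per-sample retention jitter sd, minutes
#'   (emulating the intragroup retention variation that makes alignment
#'   necessary and occasionally splits a compound's features across groups,
#'   the known source of duplicate entries).
#' @param abundance_meanlog,abundance_sdlog log-normal apex-height
#'   distribution across samples.
#' @param panel_fraction fraction of library compounds present in each
#'   subset's panel (panels overlap partially).
#' @param ladder_carbons carbon numbers of the planted alkane ladder.
#' @param alkane_span retention times of C7 and C30, minutes (see
#'   [alkane_ladder()]).
#' @param ramp_program a [temperature_program()].
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(n_mothers = 3, n_children = 3, n_room_air = 2,
                          groups = c(group1 = 0, group2 = 0.3),
                          noise_sd = 50, baseline_level = 100,
                          artifacts = artifact_compounds(),
                          include_alkane_ladder = TRUE,
                          include_voc_standard = TRUE,
                          seed = 1L,
                          scan_interval = 0.005,
                          scan_mz_range = c(35, 450),
                          rt_jitter_sd = 0.02,
                          abundance_meanlog = log(5e4),
                          abundance_sdlog = 0.5,
                          panel_fraction = 0.8,
                          ladder_carbons = 7:30,
                          alkane_span = c(1.5, 44.7),
                          ramp_program = temperature_program()) {
  if (any(c(n_mothers, n_children, n_room_air) < 0))
    stop("sample counts must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(n_mothers = n_mothers, n_children = n_children,
                 n_room_air = n_room_air, groups = groups,
                 noise_sd = noise_sd, baseline_level = baseline_level,
                 artifacts = artifacts,
                 include_alkane_ladder = include_alkane_ladder,
                 include_voc_standard = include_voc_standard,
                 seed = as.integer(seed), scan_interval = scan_interval,
                 scan_mz_range = scan_mz_range, rt_jitter_sd = rt_jitter_sd,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 panel_fraction = panel_fraction,
                 ladder_carbons = ladder_carbons,
                 alkane_span = alkane_span,
                 ramp_program = ramp_program),
            class = "cohort_design")
}

#' Simulate one run
#'
#' Scans are placed at a fixed interval over the temperature program. Each
#' compound contributes `abundance * rel_int(mz)/1000 *
#' exp(-(t - mu)^2 / (2 sigma^2))` to its fragment channels, with
#' `mu = rt_mean + group shift (+ jitter if requested)`; a constant baseline
#' and additive Gaussian noise (truncated at zero) complete the signal.
#'
#' @param compounds list of [true_compound()]; may be empty.
#' @param design a [cohort_design()].
#' @param sample_id,group_id,subset run metadata; `group_id` selects the
#'   retention shift from `design$groups` (unknown ids shift by 0).
#' @param jitter logical; add per-compound retention jitter
#'   (sd `design$rt_jitter_sd`). Jitter and noise are drawn from the current
#'   RNG stream.
#' @return a [raw_run()] with attribute `truth`: data.frame of planted
#'   compounds (name, rt_apex, abundance, base-peak m/z).
#' @export
simulate_run <- function(compounds, design, sample_id, group_id, subset,
                         jitter = TRUE) {
  prog <- design$ramp_program
  span <- range(prog$segments)
  rt <- seq(span[1] + design$scan_interval, span[2],
            by = design$scan_interval)
  mz <- seq.int(design$scan_mz_range[1], design$scan_mz_range[2])
  shift <- if (group_id %in% names(design$groups))
    design$groups[[group_id]] else 0
  mat <- matrix(design$baseline_level, nrow = length(rt), ncol = length(mz))
  if (design$noise_sd > 0)
    mat <- mat + matrix(stats::rnorm(length(mat), 0, design$noise_sd),
                        nrow = nrow(mat))
  truth <- data.frame(sample_id = character(0), name = character(0),
                      rt_apex = numeric(0), abundance = numeric(0),
                      base_mz = integer(0), stringsAsFactors = FALSE)
  for (cmp in compounds) {
    ab <- cmp$abundance_by_sample
    a <- if (sample_id %in% names(ab)) ab[[sample_id]]
         else if ("default" %in% names(ab)) ab[["default"]]
         else stats::rlnorm(1, design$abundance_meanlog, design$abundance_sdlog)
    jit <- if (jitter && design$rt_jitter_sd > 0)
      stats::rnorm(1, 0, design$rt_jitter_sd) else 0
    mu <- cmp$rt_mean + shift + jit
    cols <- match(as.integer(names(cmp$spectrum)), mz)
    ok <- !is.na(cols)
    if (!any(ok)) next
    win <- which(rt >= mu - 5 * cmp$peak_sigma & rt <= mu + 5 * cmp$peak_sigma)
    if (length(win))
      mat[win, cols[ok]] <- mat[win, cols[ok]] +
        outer(a * gauss_profile(rt[win], mu, cmp$peak_sigma),
              unname(cmp$spectrum[ok]) / 1000)
    truth <- rbind(truth, data.frame(
      sample_id = sample_id, name = cmp$name, rt_apex = mu, abundance = a,
      base_mz = as.integer(names(cmp$spectrum))[which.max(cmp$spectrum)],
      stringsAsFactors = FALSE))
  }
  mat[mat < 0] <- 0
  run <- raw_run(sample_id, group_id, subset, rt = rt, mz = mz,
                 intensity = mat, ramp_program = prog)
  attr(run, "truth") <- truth
  run
}

#' Simulate a full cohort
#'
#' Builds all runs of a [cohort_design()]: per group, `n_mothers` mother
#' runs, `n_children` child runs, `n_room_air` room-air runs, plus optional
#' standards (alkane ladder, VOC mix). Each subset carries a partially
#' overlapping panel of library compounds; the artifacts appear in every
#' non-standard run. Reproducible for a fixed `design$seed`.
#'
#' @param design a [cohort_design()].
#' @param library the list returned by [make_library()] (`library` +
#'   `compounds`).
#' @return list with `runs` (named list of [raw_run()]), `truth` (data.frame
#'   over all runs), `panels` (subset -> compound names), `alkane_rt`
#'   (ground-truth ladder grid) and `manifest` (per-run metadata).
#' @export
simulate_cohort <- function(design, library) {
  compounds <- library$compounds
  with_seed(design$seed, {
    non_artifact <- compounds
    n_pick <- max(1L, ceiling(design$panel_fraction * length(non_artifact)))
    subsets <- c("mother", "child", "room_air")
    panels <- lapply(subsets, function(s)
      sort(sample(seq_along(non_artifact), n_pick)))
    names(panels) <- subsets

    manifest <- data.frame(sample_id = character(0), group_id = character(0),
                           subset = character(0), stringsAsFactors = FALSE)
    for (g in names(design$groups)) {
      add <- function(n, subset, tag) if (n > 0)
        data.frame(sample_id = sprintf("%s_%s_%02d", g, tag, seq_len(n)),
                   group_id = g, subset = subset, stringsAsFactors = FALSE)
      manifest <- rbind(manifest,
                        add(design$n_mothers, "mother", "mother"),
                        add(design$n_children, "child", "child"),
                        add(design$n_room_air, "room_air", "air"))
    }

    ## fixed per-sample abundances so the truth table is complete up front
    for (i in seq_along(compounds)) {
      ab <- stats::rlnorm(nrow(manifest), design$abundance_meanlog,
                          design$abundance_sdlog)
      names(ab) <- manifest$sample_id
      compounds[[i]]$abundance_by_sample <- ab
    }
    artifacts <- design$artifacts
    for (i in seq_along(artifacts)) {
      ab <- stats::rlnorm(nrow(manifest), design$abundance_meanlog,
                          design$abundance_sdlog)
      names(ab) <- manifest$sample_id
      artifacts[[i]]$abundance_by_sample <- ab
    }

    runs <- list(); truth <- NULL
    for (i in seq_len(nrow(manifest))) {
      row <- manifest[i, ]
      panel <- compounds[panels[[row$subset]]]
      run <- simulate_run(c(panel, artifacts), design, row$sample_id,
                          row$group_id, row$subset)
      runs[[row$sample_id]] <- run
      truth <- rbind(truth, cbind(attr(run, "truth"),
                                  group_id = row$group_id,
                                  subset = row$subset))
    }

    ladder <- alkane_ladder(carbons = design$ladder_carbons,
                            span = design$alkane_span)
    std_manifest <- NULL
    for (g in names(design$groups)) {
      if (design$include_alkane_ladder) {
        sid <- sprintf("%s_alkane_ladder", g)
        run <- simulate_run(ladder$compounds, design, sid, g, "standard",
                            jitter = FALSE)
        runs[[sid]] <- run
        truth <- rbind(truth, cbind(attr(run, "truth"), group_id = g,
                                    subset = "standard"))
        std_manifest <- rbind(std_manifest, data.frame(
          sample_id = sid, group_id = g, subset = "standard",
          stringsAsFactors = FALSE))
      }
      if (design$include_voc_standard && length(compounds)) {
        sid <- sprintf("%s_voc_standard", g)
        idx <- seq_len(min(10L, length(compounds)))
        voc <- lapply(compounds[idx], function(cmp) {
          cmp$abundance_by_sample <- c(default = 5e4); cmp
        })
        run <- simulate_run(voc, design, sid, g, "standard", jitter = FALSE)
        runs[[sid]] <- run
        truth <- rbind(truth, cbind(attr(run, "truth"), group_id = g,
                                    subset = "standard"))
        std_manifest <- rbind(std_manifest, data.frame(
          sample_id = sid, group_id = g, subset = "standard",
          stringsAsFactors = FALSE))
      }
    }
    manifest <- rbind(manifest, std_manifest)
    alk_n <- design$ladder_carbons
    list(runs = runs, truth = truth,
         panels = lapply(panels, function(ix)
           vapply(compounds[ix], `[[`, character(1), "name")),
         alkane_rt = data.frame(carbon = alk_n,
                                rt = alkane_rt_truth(alk_n,
                                                     design$alkane_span),
                                ri = 100 * alk_n),
         manifest = manifest)
  })
}

#' Write a cohort's ground truth as CSV
#'
#' @param cohort result of [simulate_cohort()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(cohort, path) {
  utils::write.csv(cohort$truth, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
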