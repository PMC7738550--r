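#' Pipeline configuration
#'
#' All module thresholds with their defaults, the input manifest, library and
#' anchor sources, and the output directory. Values passed as named lists are
#' merged over the defaults.
#'
#' @param manifest data.frame with `path`, `sample_id`, `group_id`, `subset`,
#'   or `NULL` when runs are passed to [run_pipeline()] directly.
#' @param library a `spectral_library` object, or a path to an MSP file.
#' @param alkane_library alkane-only `spectral_library` (or MSP path) for
#'   retention anchoring; entries must carry molecular weights.
#' @param anchors `"auto-alkane"` (build anchors from the standard runs via
#'   [anchor_alkanes()]), a path to a CSV with columns `label`, `rt`, `ri`,
#'   or a data.frame of the same shape.
#' @param out_dir output directory for the tabular results.
#' @param identification logical; match compounds against the library.
#' @param peakpick,cliques,deconv,merge,identify named lists of module
#'   parameters (see Details in the package vignette).
#' @param seed integer seed recorded with the run.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest = NULL, library = NULL,
                            alkane_library = NULL, anchors = "auto-alkane",
                            out_dir = NULL, identification = !is.null(library),
                            peakpick = list(), cliques = list(),
                            deconv = list(), merge = list(),
                            identify = list(), seed = 1L) {
  defaults <- list(
    peakpick = list(smooth_window = 5L, baseline_quantile = 0.25,
                    baseline_window = 401L, fwhm = 0.05, snr = 5,
                    rt_bw = 2 / 60, minfrac = 0.5, mz_range = c(38L, 450L)),
    cliques = list(rt_tol = 0.05, min_cosine = 0.8),
    deconv = list(noise_threshold = 300, peak_sigma = 0.02, min_ions = 4L,
                  cor_gate = 0.9, rt_tol = 0.05, min_spectral_dot = 0.7,
                  boundaries = NULL),
    merge = list(rt_tol = 0.05, dot_threshold = 0.7, dup_dot = 0.8,
                 dup_rt_tol = 0.05, dup_pearson = 0.75, mz_lo = 38L,
                 mz_hi = 450L, normalization = "sum",
                 exclude_features = character(0)),
    identify = list(mf_floor = 80, mf_window = 5, cap = 450L,
                    ri_error_max = 20, alkane_mf_floor = 95, mf_points = 5))
  cfg <- list(manifest = manifest, library = library,
              alkane_library = alkane_library, anchors = anchors,
              out_dir = out_dir, identification = identification,
              peakpick = utils::modifyList(defaults$peakpick, peakpick),
              cliques = utils::modifyList(defaults$cliques, cliques),
              deconv = utils::modifyList(defaults$deconv, deconv),
              merge = utils::modifyList(defaults$merge, merge),
              identify = utils::modifyList(defaults$identify, identify),
              seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys mirror the arguments of
#'   [pipeline_config()]; `manifest` may be a path to a CSV with columns
#'   `path`, `sample_id`, `group_id`, `subset`.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.character(y$manifest))
    y$manifest <- utils::read.csv(y$manifest, stringsAsFactors = FALSE)
  if (!is.null(y$manifest) && !is.data.frame(y$manifest))
    y$manifest <- do.call(rbind, lapply(y$manifest, function(r)
      data.frame(r, stringsAsFactors = FALSE)))
  do.call(pipeline_config, y)
}

resolve_library <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "spectral_library")) return(x)
  read_msp_library(x)
}

resolve_anchors <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.character(x) && x != "auto-alkane")
    return(utils::read.csv(x, stringsAsFactors = FALSE))
  NULL  # auto-alkane: computed per group from the standard runs
}

serialize_spectrum <- function(spec) {
  paste(sprintf("%s:%.6g", names(spec), unname(spec)), collapse = ";")
}

#' Run the full preprocessing workflow
#'
#' Executes, per group and subset (subsets are preprocessed separately and
#' groups never pooled), the peak-picking route (smoothing and baseline
#' correction, matched-filter detection, retention alignment, cross-sample
#' grouping, gap filling, similarity-network pseudo-compounds) and the
#' deconvolution route (ramp segmentation, deconvolution, compound alignment,
#' missing-compound recovery), then merges the two routes by spectral dot
#' product, flags duplicates, normalizes the filtered feature matrix and,
#' when a library is configured, identifies the filtered compounds. All
#' tables are written to `config$out_dir` with a machine-readable run
#' summary.
#'
#' @param config a [pipeline_config()].
#' @param runs named list of [raw_run()]s; when `NULL` they are read from the
#'   config manifest.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with per-(group, subset) results (`blocks`),
#'   per-group anchors, the identification table and the run `summary`
#'   data.frame.
#' @export
run_pipeline <- function(config, runs = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  library_obj <- resolve_library(config$library)
  if (isTRUE(config$identification) && is.null(library_obj))
    stop("identification is enabled but no spectral library is configured",
         call. = FALSE)
  alkane_lib <- resolve_library(config$alkane_library)
  fixed_anchors <- resolve_anchors(config$anchors)
  if (is.null(runs)) {
    if (is.null(config$manifest))
      stop("no runs given and no manifest configured", call. = FALSE)
    runs <- list()
    for (i in seq_len(nrow(config$manifest))) {
      m <- config$manifest[i, ]
      runs[[m$sample_id]] <- read_raw_run(m$path, m$sample_id, m$group_id,
                                          m$subset)
    }
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  emit <- function(name, df) {
    if (!is.null(out_dir))
      utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
  }

  groups_of <- vapply(runs, `[[`, character(1), "group_id")
  subset_of <- vapply(runs, `[[`, character(1), "subset")
  blocks <- list(); summary_rows <- list(); ident_all <- NULL
  anchors_by_group <- list()
  pp <- config$peakpick; cq <- config$cliques; dv <- config$deconv
  mg <- config$merge; idf <- config$identify

  deconv_run <- function(run) {
    segs <- segment_run(run, dv$boundaries)
    unlist(lapply(segs, deconvolve, noise_threshold = dv$noise_threshold,
                  peak_sigma = dv$peak_sigma, min_ions = dv$min_ions,
                  cor_gate = dv$cor_gate, mz_range = pp$mz_range),
           recursive = FALSE)
  }
  peakpick_block <- function(rs) {
    sm <- lapply(rs, smooth_and_baseline, window = pp$smooth_window,
                 baseline_quantile = pp$baseline_quantile,
                 baseline_window = pp$baseline_window)
    feats <- lapply(sm, detect_peaks, fwhm = pp$fwhm, snr_threshold = pp$snr,
                    mz_range = pp$mz_range)
    al <- if (length(feats) >= 2L)
      align_retention_times(feats, rt_bw = pp$rt_bw,
                            max_anchor_spread = 2 * pp$fwhm)
    else suppressWarnings(align_retention_times(feats))
    warped <- lapply(names(sm), function(s) warp_run(sm[[s]], al$warps[[s]]))
    names(warped) <- names(sm)
    list(features = al$features, warps = al$warps, warped = warped)
  }

  for (g in unique(groups_of)) {
    ## retention anchors for this group
    anchors <- fixed_anchors
    std <- runs[groups_of == g & subset_of == "standard"]
    if (is.null(anchors) && isTRUE(config$identification) &&
        !is.null(alkane_lib) && length(std)) {
      say("[%s] building alkane anchors from %d standard run(s)", g,
          length(std))
      res <- tryCatch({
        ## standards runs (ladder vs VOC mix) share no compounds, so the
        ## cross-run alignment inside the block legitimately finds no
        ## anchors and falls back to identity warps
        pb <- suppressWarnings(peakpick_block(std))
        std_feats <- do.call(rbind, pb$features)
        std_groups <- group_features(std_feats, rt_bw = pp$rt_bw,
                                     minfrac = 0, samples = names(std))
        dcs <- unlist(lapply(pb$warped, deconv_run), recursive = FALSE)
        anchor_alkanes(dcs, std_groups, alkane_lib,
                       alkane_mf_floor = idf$alkane_mf_floor,
                       mf_points = idf$mf_points, rt_tol = mg$rt_tol)
      }, error = function(e) {
        warning(sprintf("group %s: alkane anchoring failed (%s); falling back to match factor only",
                        g, conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (!is.null(res)) {
        anchors <- res$anchors
        emit(sprintf("%s_anchors", g), anchors)
      }
    }
    anchors_by_group[[g]] <- anchors

    for (sb in c("mother", "child", "room_air")) {
      rs <- runs[groups_of == g & subset_of == sb]
      if (!length(rs)) next
      key <- sprintf("%s_%s", g, sb)
      say("[%s] approach 1: peak picking on %d run(s)", key, length(rs))
      t0 <- proc.time()[["elapsed"]]
      pb <- peakpick_block(rs)
      fgroups <- group_features(pb$features, rt_bw = pp$rt_bw,
                                minfrac = pp$minfrac, samples = names(rs))
      fmat <- fill_missing(fgroups, pb$warped)
      cliq <- annotate_all_samples(pb$features, fgroups, pb$warped,
                                   rt_tol = cq$rt_tol,
                                   min_cosine = cq$min_cosine)
      say("[%s] approach 2: deconvolution", key)
      dcs <- unlist(lapply(pb$warped, deconv_run), recursive = FALSE)
      ali <- align_compounds(dcs, rt_tol = dv$rt_tol,
                             min_spectral_dot = dv$min_spectral_dot)
      ali <- recover_missing(ali, pb$warped)

      say("[%s] connecting the two approaches", key)
      ## clique relative-intensity spectra keyed by unit m/z
      mz_of <- stats::setNames(fgroups$groups$mz,
                               fgroups$groups$group_feature_id)
      clique_spectra <- list(); clique_rt <- numeric(0); clique_size <- numeric(0)
      for (i in seq_len(nrow(cliq$compounds))) {
        cid <- cliq$compounds$clique_id[i]
        mem <- cliq$members$group_feature_id[cliq$members$clique_id == cid]
        rel <- relative_intensities(mem, fmat)
        spec <- tapply(rel, as.integer(mz_of[mem]), max)
        clique_spectra[[cid]] <- stats::setNames(as.numeric(spec),
                                                 names(spec))
        clique_rt[cid] <- cliq$compounds$rt[i]
        clique_size[cid] <- sum(rowMeans(
          fmat$values[match(mem, fmat$features$feature_id), , drop = FALSE]))
      }
      ionm <- match_features_to_ions(fgroups, ali, rt_tol = mg$rt_tol)
      fs <- if (length(clique_spectra) && length(ali$compounds))
        match_compounds(clique_spectra, clique_rt, ali, ionm,
                        dot_threshold = mg$dot_threshold,
                        mz_lo = mg$mz_lo, mz_hi = mg$mz_hi)
      else suppressWarnings(match_compounds(clique_spectra, clique_rt, ali,
                                            ionm))
      ## duplicate reports: each approach raw, then the filtered list
      as_dup <- function(ids, spectra, rts, sizes = NULL, areas = NULL)
        lapply(seq_along(ids), function(i) {
          c(list(id = ids[i], rt = rts[[i]], spectrum = spectra[[i]]),
            if (!is.null(sizes)) list(size = sizes[[i]]),
            if (!is.null(areas)) list(areas = areas[[i]]))
        })
      dup_clique <- detect_duplicates(
        as_dup(names(clique_spectra), clique_spectra, clique_rt,
               sizes = clique_size),
        dot_min = mg$dup_dot, rt_tol = mg$dup_rt_tol,
        mz_lo = mg$mz_lo, mz_hi = mg$mz_hi)
      d_ids <- vapply(ali$compounds, `[[`, character(1), "aligned_id")
      dup_deconv <- detect_duplicates(
        as_dup(d_ids, lapply(ali$compounds, `[[`, "spectrum"),
               lapply(ali$compounds, `[[`, "rt"),
               areas = lapply(ali$compounds, `[[`, "areas")),
        dot_min = mg$dup_dot, rt_tol = mg$dup_rt_tol,
        pearson_min = mg$dup_pearson, mz_lo = mg$mz_lo, mz_hi = mg$mz_hi)
      keep_f <- fs$filtered_compounds
      dup_filtered <- detect_duplicates(
        as_dup(d_ids[d_ids %in% keep_f],
               lapply(ali$compounds[d_ids %in% keep_f], `[[`, "spectrum"),
               lapply(ali$compounds[d_ids %in% keep_f], `[[`, "rt"),
               areas = lapply(ali$compounds[d_ids %in% keep_f], `[[`, "areas")),
        dot_min = mg$dup_dot, rt_tol = mg$dup_rt_tol,
        pearson_min = mg$dup_pearson, mz_lo = mg$mz_lo, mz_hi = mg$mz_hi)

      ## normalized matrix over the filtered features (minus exclusions)
      keep_feats <- setdiff(fs$filtered_features, mg$exclude_features)
      idx <- match(keep_feats, fmat$features$feature_id)
      idx <- idx[!is.na(idx)]
      norm <- if (length(idx)) {
        suppressWarnings(normalize_matrix(
          feature_matrix(fmat$features[idx, , drop = FALSE],
                         fmat$values[idx, , drop = FALSE],
                         fmat$filled[idx, , drop = FALSE]),
          denominator = mg$normalization))
      } else NULL

      ident <- NULL
      if (isTRUE(config$identification) && length(keep_f)) {
        say("[%s] identification of %d filtered compound(s)", key,
            length(keep_f))
        ident <- identify_compounds(ali, library_obj,
                                    anchors = anchors_by_group[[g]],
                                    mf_floor = idf$mf_floor,
                                    mf_window = idf$mf_window,
                                    cap = idf$cap,
                                    ri_error_max = idf$ri_error_max,
                                    ids = keep_f)
        if (nrow(ident)) {
          ident <- cbind(group_id = g, subset = sb, ident)
          ident_all <- rbind(ident_all, ident)
        }
      }
      elapsed <- proc.time()[["elapsed"]] - t0
      say("[%s] done in %.1f s", key, elapsed)

      ## tabular outputs
      emit(sprintf("%s_feature_matrix", key), {
        df <- data.frame(feature_id = fmat$features$feature_id,
                         mz = fmat$features$mz,
                         rt_median = fmat$features$rt_median)
        cbind(df, as.data.frame(fmat$values, optional = TRUE))
      })
      emit(sprintf("%s_clique_table", key), within(cliq$compounds, {
        members <- vapply(clique_id, function(ci) paste(
          cliq$members$group_feature_id[cliq$members$clique_id == ci],
          collapse = ";"), character(1))
      }))
      emit(sprintf("%s_compound_table", key), do.call(rbind, lapply(
        ali$compounds, function(cmp) data.frame(
          aligned_id = cmp$aligned_id, rt = cmp$rt, segment = cmp$segment,
          spectrum = serialize_spectrum(cmp$spectrum),
          n_samples = length(cmp$areas),
          recovered = paste(cmp$recovered, collapse = ";"),
          total_area = sum(cmp$areas), stringsAsFactors = FALSE))))
      emit(sprintf("%s_match_results", key), fs$matches)
      if (!is.null(norm))
        write_feature_matrix(norm, file.path(
          out_dir %||% tempdir(), sprintf("%s_filtered_normalized_matrix.csv",
                                          key)))
      dup_report <- rbind(
        if (nrow(dup_clique$pairs)) cbind(list_name = "clique", dup_clique$pairs),
        if (nrow(dup_deconv$pairs)) cbind(list_name = "deconv", dup_deconv$pairs),
        if (nrow(dup_filtered$pairs)) cbind(list_name = "filtered",
                                            dup_filtered$pairs))
      emit(sprintf("%s_duplicate_report", key),
           dup_report %||% data.frame(list_name = character(0)))
      if (!is.null(ident)) emit(sprintf("%s_identification", key), ident)

      dup_frac <- function(d, n) if (n >= 2) nrow(d$pairs) / choose(n, 2) else 0
      summary_rows[[key]] <- data.frame(
        group_id = g, subset = sb, n_runs = length(rs),
        n_features = sum(vapply(pb$features, nrow, integer(1))),
        n_feature_groups = nrow(fgroups$groups),
        n_clique_compounds = nrow(cliq$compounds),
        n_deconv_compounds = length(ali$compounds),
        n_filtered_compounds = length(fs$filtered_compounds),
        n_filtered_features = length(fs$filtered_features),
        dup_frac_clique = dup_frac(dup_clique, length(clique_spectra)),
        dup_frac_deconv = dup_frac(dup_deconv, length(ali$compounds)),
        dup_frac_filtered = dup_frac(dup_filtered,
                                     length(fs$filtered_compounds)),
        elapsed_s = elapsed, stringsAsFactors = FALSE)
      blocks[[key]] <- list(
        group_id = g, subset = sb, features = pb$features,
        feature_groups = fgroups, feature_matrix = fmat, cliques = cliq,
        clique_spectra = clique_spectra, aligned = ali, ion_matches = ionm,
        filtered = fs, duplicates = list(clique = dup_clique,
                                         deconv = dup_deconv,
                                         filtered = dup_filtered),
        normalized = norm, identification = ident)
    }
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(seed = config$seed, summary = summary,
           anchors = anchors_by_group),
      file.path(out_dir, "run_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(blocks = blocks, anchors = anchors_by_group,
                 identification = ident_all, summary = summary,
                 config = config))
}

#' Demonstration pipeline on a synthetic cohort
#'
#' Builds a seeded synthetic cohort (two groups of 3 mothers + 3 children +
#' 2 room-air samples, an alkane ladder and a VOC standard per group, 18
#' library compounds plus the 2 ubiquitous artifacts), runs the full
#' workflow and prints the run summary.
#'
#' @param seed integer seed for the cohort.
#' @param out_dir output directory (default: a session temporary directory).
#' @param n_compounds number of library compounds to plant.
#' @param design a [cohort_design()]; the default uses `seed`.
#' @param quiet suppress progress messages.
#' @return (invisibly) list with `result` ([run_pipeline()] output), `cohort`
#'   (the synthetic truth) and `library`.
#' @export
demo_pipeline <- function(seed = 1L, out_dir = file.path(tempdir(), "vocpipe_demo"),
                          n_compounds = 18L, design = NULL, quiet = FALSE) {
  lib <- make_library(n_compounds, seed = seed)
  if (is.null(design)) design <- cohort_design(seed = seed)
  cohort <- simulate_cohort(design, lib)
  ## the search library also carries the artifacts and the alkanes, as a
  ## real reference library would
  artifact_entries <- lapply(design$artifacts, function(a) list(
    name = a$name, spectrum = a$spectrum,
    retention_index = ri_from_rt_truth(a$rt_mean, design$alkane_span),
    molecular_weight = max(as.integer(names(a$spectrum)))))
  full_lib <- structure(list(entries = c(lib$library$entries,
                                         artifact_entries,
                                         alkane_ladder()$library$entries)),
                        class = "spectral_library")
  alk <- alkane_ladder(carbons = 7:24)$library
  cfg <- pipeline_config(library = full_lib, alkane_library = alk,
                         out_dir = out_dir, seed = seed)
  res <- run_pipeline(cfg, runs = cohort$runs, quiet = quiet)
  if (!quiet) {
    cat("\nRun summary:\n")
    print(res$summary, digits = 3)
  }
  invisible(list(result = res, cohort = cohort, library = lib))
}
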