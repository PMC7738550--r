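#' Split a run at the temperature-ramp boundaries
#'
#' The three ramp segments are preprocessed independently. Scans exactly on a
#' boundary belong to the earlier segment (closed right edge).
#'
#' @param run a [raw_run()].
#' @param boundaries the two inner segment boundaries, minutes; default taken
#'   from the run's temperature program.
#' @return list of three [raw_run()]s, each with attribute `segment` (1-3).
#' @export
segment_run <- function(run, boundaries = NULL) {
  if (is.null(boundaries))
    boundaries <- run$ramp_program$segments[1:2, "end_rt"]
  b <- sort(as.numeric(boundaries))
  span <- range(run$rt)
  if (any(b <= span[1]) || any(b >= span[2]))
    stopf("segment boundary outside the run's retention span (%.2f-%.2f min)",
          span[1], span[2])
  ## boundary scans go to the earlier segment (closed right edge); the
  ## epsilon keeps grid round-off from flipping a boundary scan
  eps <- 1e-9
  seg_of <- 1L + (run$rt > b[1] + eps) + (run$rt > b[2] + eps)
  out <- lapply(1:3, function(k) {
    idx <- which(seg_of == k)
    if (!length(idx))
      stopf("segment %d is empty: run ends at %.2f min", k, span[2])
    sub <- if (is.null(run$scans))
      raw_run(run$sample_id, run$group_id, run$subset, rt = run$rt[idx],
              mz = run$mz, intensity = run$intensity[idx, , drop = FALSE],
              ramp_program = run$ramp_program)
    else
      raw_run(run$sample_id, run$group_id, run$subset, rt = run$rt[idx],
              scans = run$scans[idx], ramp_program = run$ramp_program)
    attr(sub, "segment") <- k
    sub
  })
  out
}

#' Spectral deconvolution of one segment
#'
#' Two stages. Compound detection (the local-covariance stage): intensities
#' below `noise_threshold` are floored to zero (the automatic denoising /
#' baseline handling), each EIC is lightly smoothed and its local maxima
#' collected; apex retention times that cluster within one `peak_sigma`
#' and involve at least `min_ions` distinct ions announce a candidate
#' compound at the cluster's median apex. Spectrum extraction: an EIC joins a
#' candidate when its profile correlation with the candidate's Gaussian
#' elution model (centred at the candidate apex, sigma `peak_sigma`) is at
#' least `cor_gate` over the ion's support; each member ion's apex
#' contribution is then solved by non-negative least squares of its EIC
#' against the elution models of all overlapping candidates, which unmixes
#' co-eluting compounds. The spectrum is rescaled to base peak 1000 and the
#' compound area is the elution-model area times the summed ion loadings.
#' Candidates retaining fewer than `min_ions` member ions are dropped.
#'
#' @param run a segment [raw_run()] (see [segment_run()]).
#' @param noise_threshold abundance floor applied before detection.
#' @param peak_sigma expected Gaussian elution sigma, minutes.
#' @param min_ions minimum number of member ions of a real compound.
#' @param cor_gate minimum EIC/model profile correlation for membership.
#' @param mz_range unit-mass bounds considered.
#' @return list of deconvolved compounds, each a list with `compound_id`,
#'   `sample_id`, `rt`, `spectrum` (named numeric, base peak 1000), `area`,
#'   `segment`, `sigma`.
#' @export
deconvolve <- function(run, noise_threshold = 300, peak_sigma = 0.02,
                       min_ions = 4L, cor_gate = 0.9, mz_range = c(38, 450)) {
  segment <- attr(run, "segment") %||% NA_integer_
  if (length(run$rt) < 5L) return(list())
  eics <- eic_matrix(run, mz_range)
  mat <- eics$mat
  mat[mat < noise_threshold] <- 0
  rt <- eics$rt
  dt <- stats::median(diff(rt))
  if (max(mat) <= 0) return(list())
  sm_win <- max(3L, 2L * floor((peak_sigma / dt) / 2) + 1L)
  ## per-ion apexes of the floored, lightly smoothed EICs
  apex_rt <- numeric(0); apex_ion <- integer(0)
  for (j in which(colSums(mat) > 0)) {
    y <- moving_average(mat[, j], sm_win)
    am <- local_maxima(y)
    am <- am[y[am] > 0]
    if (length(am)) {
      apex_rt <- c(apex_rt, rt[am])
      apex_ion <- c(apex_ion, rep(j, length(am)))
    }
  }
  if (!length(apex_rt)) return(list())
  ord <- order(apex_rt)
  apex_rt <- apex_rt[ord]; apex_ion <- apex_ion[ord]
  cl <- cumsum(c(1L, as.integer(diff(apex_rt) > peak_sigma)))
  n <- length(rt)
  ## per-candidate width from the dominant ion's full width at half maximum,
  ## so peaks broader or narrower than the nominal sigma keep their ions
  est_sigma <- function(i, j) {
    y <- moving_average(mat[, j], sm_win)
    hm <- y[i] / 2
    lo <- i; while (lo > 1L && y[lo - 1L] > hm) lo <- lo - 1L
    hi <- i; while (hi < n && y[hi + 1L] > hm) hi <- hi + 1L
    s <- (rt[hi] - rt[lo]) / 2.3548
    min(max(s, 0.6 * peak_sigma), 3 * peak_sigma)
  }
  cand <- list()
  for (c_id in unique(cl)) {
    sel <- cl == c_id
    if (length(unique(apex_ion[sel])) < min_ions) next
    i <- which.min(abs(rt - stats::median(apex_rt[sel])))
    ions <- unique(apex_ion[sel])
    j_star <- ions[which.max(mat[i, ions])]
    sig <- est_sigma(i, j_star)
    half <- max(3L, ceiling(4 * sig / dt))
    lo <- max(1L, as.integer(i - half)); hi <- min(n, as.integer(i + half))
    cand[[length(cand) + 1L]] <- list(
      apex = i, lo = lo, hi = hi, sigma = sig,
      model = gauss_profile(rt, rt[i], sig) *
        (seq_len(n) >= lo & seq_len(n) <= hi))
  }
  if (!length(cand)) return(list())
  ## chains of candidates with overlapping windows are unmixed jointly
  n_c <- length(cand)
  chain_id <- integer(n_c); cur <- 0L
  for (k in seq_len(n_c)) {
    if (k == 1L || cand[[k]]$lo > cand[[k - 1L]]$hi) cur <- cur + 1L
    chain_id[k] <- cur
  }
  loadings <- matrix(0, nrow = ncol(mat), ncol = n_c)
  gated <- matrix(FALSE, nrow = ncol(mat), ncol = n_c)
  for (ch in unique(chain_id)) {
    ks <- which(chain_id == ch)
    lo <- min(vapply(cand[ks], `[[`, integer(1), "lo"))
    hi <- max(vapply(cand[ks], `[[`, integer(1), "hi"))
    rows <- lo:hi
    models <- vapply(cand[ks], function(c) c$model[rows],
                     numeric(length(rows)))
    models <- matrix(models, ncol = length(ks))
    active <- which(colSums(mat[rows, , drop = FALSE]) > 0)
    for (j in active) {
      y <- mat[rows, j]
      cors <- vapply(seq_along(ks), function(q) {
        ## correlate over the ion's support inside the model window, so a
        ## threshold-truncated weak ion is judged on its visible profile
        w <- which(models[, q] > 1e-3 & y > 0)
        if (length(w) < 5L || stats::sd(y[w]) == 0) return(0)
        suppressWarnings(stats::cor(y[w], models[w, q]))
      }, numeric(1))
      ok <- which(!is.na(cors) & cors >= cor_gate)
      if (!length(ok)) next
      gated[j, ks[ok]] <- TRUE
      if (length(ok) == 1L) {
        m <- models[, ok]
        loadings[j, ks[ok]] <- max(0, sum(y * m) / sum(m * m))
      } else {
        fit <- pracma::lsqnonneg(models[, ok, drop = FALSE], y)
        loadings[j, ks[ok]] <- fit$x
      }
    }
  }
  out <- list(); idx <- 0L
  for (k in seq_len(n_c)) {
    member <- which(gated[, k] & loadings[, k] > 0)
    if (length(member) < min_ions) next
    idx <- idx + 1L
    spec <- rescale_1000(stats::setNames(loadings[member, k],
                                         eics$mz[member]))
    area <- sum(cand[[k]]$model) * dt * sum(loadings[member, k])
    out[[idx]] <- list(
      compound_id = sprintf("%s_D%03d", run$sample_id, idx),
      sample_id = run$sample_id, rt = rt[cand[[k]]$apex],
      spectrum = spec, area = area, segment = segment,
      sigma = cand[[k]]$sigma)
  }
  out
}

## cosine similarity of two named spectra over the union of their ions
spec_cosine <- function(a, b) {
  ions <- union(names(a), names(b))
  va <- stats::setNames(rep(0, length(ions)), ions); va[names(a)] <- a
  vb <- stats::setNames(rep(0, length(ions)), ions); vb[names(b)] <- b
  cosine_sim(va, vb)
}

#' Align deconvolved compounds across samples
#'
#' Greedy clustering by descending area: a compound joins an existing
#' aligned cluster iff its retention time (after per-sample median-shift
#' correction) is within `rt_tol` of the cluster and its spectrum dot with
#' the cluster consensus is at least `min_spectral_dot`; otherwise it seeds a
#' new cluster. One member per sample per cluster. The per-sample shifts are
#' estimated by a first greedy pass at a wide tolerance. The consensus
#' spectrum is the area-weighted mean rescaled to base peak 1000.
#'
#' @param compounds list of deconvolved compounds ([deconvolve()]), pooled
#'   over samples.
#' @param rt_tol retention tolerance after shift correction, minutes.
#' @param min_spectral_dot minimum spectral cosine to join a cluster.
#' @param coarse_tol tolerance of the shift-estimation pass, minutes.
#' @return object of class `aligned_compounds`: list with `compounds` (list
#'   of aligned compounds: `aligned_id`, `rt`, `spectrum`, `areas`, `rts`,
#'   `recovered`, `segment`, `sigma`) and `shifts` (named numeric per
#'   sample).
#' @export
align_compounds <- function(compounds, rt_tol = 0.05, min_spectral_dot = 0.7,
                            coarse_tol = 0.2) {
  samples <- unique(vapply(compounds, `[[`, character(1), "sample_id"))
  shifts <- stats::setNames(rep(0, length(samples)), samples)
  if (!length(compounds))
    return(structure(list(compounds = list(), shifts = shifts),
                     class = "aligned_compounds"))
  greedy <- function(shift, tol) {
    ord <- order(-vapply(compounds, `[[`, numeric(1), "area"))
    clusters <- list()
    for (i in ord) {
      cmp <- compounds[[i]]
      rt_c <- cmp$rt - shift[[cmp$sample_id]]
      joined <- FALSE
      for (k in seq_along(clusters)) {
        cl <- clusters[[k]]
        if (cmp$sample_id %in% cl$samples) next
        if (abs(rt_c - cl$rt) > tol) next
        if (spec_cosine(cmp$spectrum, cl$spectrum) < min_spectral_dot) next
        cl$members <- c(cl$members, i)
        cl$samples <- c(cl$samples, cmp$sample_id)
        cl$rts <- c(cl$rts, rt_c)
        cl$rt <- stats::median(cl$rts)
        clusters[[k]] <- cl
        joined <- TRUE
        break
      }
      if (!joined)
        clusters[[length(clusters) + 1L]] <- list(
          members = i, samples = cmp$sample_id, rts = rt_c, rt = rt_c,
          spectrum = cmp$spectrum)
    }
    clusters
  }
  if (length(samples) > 1L) {
    pass1 <- greedy(shifts, coarse_tol)
    dev <- lapply(samples, function(s) numeric(0))
    names(dev) <- samples
    for (cl in pass1) {
      if (length(cl$members) < 2L) next
      med <- stats::median(cl$rts)
      for (q in seq_along(cl$members))
        dev[[cl$samples[q]]] <- c(dev[[cl$samples[q]]], cl$rts[q] - med)
    }
    for (s in samples)
      if (length(dev[[s]])) shifts[[s]] <- stats::median(dev[[s]])
  }
  clusters <- greedy(shifts, rt_tol)
  out <- vector("list", length(clusters))
  ord <- order(vapply(clusters, `[[`, numeric(1), "rt"))
  for (q in seq_along(ord)) {
    cl <- clusters[[ord[q]]]
    mem <- compounds[cl$members]
    areas <- vapply(mem, `[[`, numeric(1), "area")
    names(areas) <- cl$samples
    ions <- sort(unique(as.integer(unlist(lapply(mem, function(m)
      names(m$spectrum))))))
    acc <- stats::setNames(rep(0, length(ions)), ions)
    for (j in seq_along(mem))
      acc[names(mem[[j]]$spectrum)] <- acc[names(mem[[j]]$spectrum)] +
        areas[j] * mem[[j]]$spectrum
    rts <- cl$rts
    names(rts) <- cl$samples
    out[[q]] <- list(
      aligned_id = sprintf("AC%04d", q),
      rt = stats::median(cl$rts),
      spectrum = rescale_1000(acc / sum(areas)),
      areas = areas, rts = rts, recovered = character(0),
      segment = mem[[1]]$segment, sigma = mem[[1]]$sigma)
  }
  structure(list(compounds = out, shifts = shifts),
            class = "aligned_compounds")
}

#' @export
print.aligned_compounds <- function(x, ...) {
  cat(sprintf("<aligned_compounds> %d compounds over %d samples\n",
              length(x$compounds), length(x$shifts)))
  invisible(x)
}

#' Recover missing compounds from the raw signal
#'
#' For every aligned compound absent from a sample, the sample's EICs of the
#' compound's `top_k` most intense ions are integrated over the consensus
#' retention window (shifted into the sample's own retention coordinates) and
#' scaled up by the consensus spectrum weight of the remaining ions; the
#' result is recorded as that sample's area and flagged as recovered.
#' Existing areas are never altered.
#'
#' @param aligned an `aligned_compounds` object ([align_compounds()]).
#' @param runs named list of [raw_run()]s covering the samples to recover in.
#' @param top_k number of ions integrated.
#' @return the `aligned_compounds` with recovered areas filled in.
#' @export
recover_missing <- function(aligned, runs, top_k = 3L) {
  samples <- names(runs)
  eics <- NULL  # computed lazily: only when something is missing
  for (q in seq_along(aligned$compounds)) {
    cmp <- aligned$compounds[[q]]
    missing <- setdiff(samples, names(cmp$areas))
    if (!length(missing)) next
    if (is.null(eics)) eics <- lapply(runs, eic_matrix)
    spec <- cmp$spectrum
    top <- names(sort(spec, decreasing = TRUE))[seq_len(min(top_k, length(spec)))]
    scale_up <- sum(spec) / sum(spec[top])
    for (s in missing) {
      sh <- if (s %in% names(aligned$shifts)) aligned$shifts[[s]] else 0
      e <- eics[[s]]
      rows <- which(e$rt >= cmp$rt + sh - 3 * cmp$sigma &
                      e$rt <= cmp$rt + sh + 3 * cmp$sigma)
      area <- 0
      if (length(rows) >= 2L) {
        dt <- stats::median(diff(e$rt[rows]))
        for (ion in top) {
          col <- match(as.integer(ion), e$mz)
          if (!is.na(col)) area <- area + sum(e$mat[rows, col]) * dt
        }
      }
      cmp$areas[[s]] <- area * scale_up
      cmp$recovered <- c(cmp$recovered, s)
    }
    aligned$compounds[[q]] <- cmp
  }
  aligned
}
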