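#' Smoothing and baseline correction
#'
#' Per-EIC moving-average smoothing followed by subtraction of a rolling
#' low-quantile baseline, clipped at zero. Retention times are unchanged.
#' The run is unit-mass binned on output (the representation every later
#' stage uses). A `baseline_quantile` of 0 disables baseline subtraction, so
#' `window = 1, baseline_quantile = 0` is the identity configuration.
#'
#' @param run a [raw_run()].
#' @param window odd moving-average width, scans.
#' @param baseline_quantile quantile of the rolling window taken as baseline
#'   (0 disables).
#' @param baseline_window rolling-baseline width, scans.
#' @return a unit-mass binned [raw_run()].
#' @export
smooth_and_baseline <- function(run, window = 5L, baseline_quantile = 0.25,
                                baseline_window = 401L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be odd and >= 1", call. = FALSE)
  eics <- eic_matrix(run)
  mat <- moving_average_mat(eics$mat, window)
  if (baseline_quantile > 0) {
    for (j in seq_len(ncol(mat))) {
      base <- rolling_quantile(mat[, j], baseline_window, baseline_quantile)
      mat[, j] <- mat[, j] - base
    }
    mat[mat < 0] <- 0
  }
  run_from_eics(run, list(rt = eics$rt, mz = eics$mz, mat = mat))
}

#' Matched-filter peak detection
#'
#' For each unit-mass EIC, the signal is convolved with a zero-area Gaussian
#' second-derivative (Mexican-hat) kernel of the given full width at half
#' maximum. Local maxima of the filter response above `snr_threshold` times
#' a robust per-EIC noise estimate (1.4826 x MAD of the response) become
#' features; the integration window is set where the response crosses zero
#' around the apex, and the feature intensity is the maximum raw intensity in
#' that window (the "maxo" convention). Overlapping peaks separate wherever
#' the filter response has two distinct maxima.
#'
#' @param run a [raw_run()] (typically the output of [smooth_and_baseline()]).
#' @param fwhm expected chromatographic peak full width at half maximum,
#'   minutes.
#' @param snr_threshold signal-to-noise ratio required of the filter response.
#' @param mz_range inclusive unit-mass bounds to scan.
#' @return data.frame of features: `feature_id`, `sample_id`, `mz`, `rt`,
#'   `rt_lo`, `rt_hi`, `maxo`.
#' @export
detect_peaks <- function(run, fwhm = 0.05, snr_threshold = 5,
                         mz_range = c(38, 450)) {
  if (fwhm <= 0) stop("fwhm must be > 0", call. = FALSE)
  empty <- data.frame(feature_id = character(0), sample_id = character(0),
                      mz = integer(0), rt = numeric(0), rt_lo = numeric(0),
                      rt_hi = numeric(0), maxo = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(run$rt) < 3L) return(empty)
  eics <- eic_matrix(run, mz_range)
  rt <- eics$rt
  dt <- stats::median(diff(rt))
  sig_sc <- max(1, (fwhm / 2.3548) / dt)
  half <- max(4L, ceiling(4 * sig_sc))
  tt <- seq(-half, half)
  kern <- (1 - (tt / sig_sc)^2) * exp(-tt^2 / (2 * sig_sc^2))
  kern <- kern - mean(kern)
  resp <- stats::filter(eics$mat, kern, sides = 2)
  resp <- matrix(as.numeric(resp), nrow = nrow(eics$mat))
  resp[is.na(resp)] <- 0

  out <- vector("list", ncol(resp))
  for (j in seq_len(ncol(resp))) {
    r <- resp[, j]
    peak_max <- max(r)
    if (peak_max <= 0) next
    noise <- mad_noise(r)
    thr <- max(snr_threshold * noise, 1e-6 * peak_max)
    apex <- local_maxima(r)
    apex <- apex[r[apex] > thr]
    if (!length(apex)) next
    raw <- eics$mat[, j]
    rows <- lapply(apex, function(i) {
      lo <- i; while (lo > 1L && r[lo - 1L] > 0) lo <- lo - 1L
      hi <- i; while (hi < length(r) && r[hi + 1L] > 0) hi <- hi + 1L
      mx <- max(raw[lo:hi])
      if (mx <= 0) return(NULL)
      data.frame(mz = eics$mz[j], rt = rt[i], rt_lo = rt[lo], rt_hi = rt[hi],
                 maxo = mx, stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) out[[j]] <- do.call(rbind, rows)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  feats <- do.call(rbind, out)
  feats <- feats[order(feats$rt, feats$mz), , drop = FALSE]
  data.frame(feature_id = sprintf("%s_F%04d", run$sample_id,
                                  seq_len(nrow(feats))),
             sample_id = run$sample_id, feats,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Retention-time alignment across samples
#'
#' Two-pass correction. A coarse pass clusters features generously
#' (`coarse_bw`), keeps clusters covering at least `anchor_min_frac` of the
#' samples and removes each sample's median retention deviation — the gross
#' between-run shift. A fine pass then re-clusters the coarsely corrected
#' features at bandwidth `rt_bw` and keeps as anchors the well-behaved groups:
#' same unit m/z, present in at least `anchor_min_frac` of the samples and
#' residual retention spread no larger than `max_anchor_spread`. For every
#' sample a smooth deviation curve (loess when enough anchors exist,
#' otherwise linear or constant) of total deviation against retention time is
#' fitted and inverted, so anchor medians are left in place. With fewer than
#' two samples the warp is the identity and a warning is raised.
#'
#' @param runs_features named list: sample id -> feature data.frame (from
#'   [detect_peaks()]).
#' @param rt_bw fine clustering bandwidth, minutes.
#' @param anchor_min_frac minimum fraction of samples an anchor group must
#'   cover.
#' @param max_anchor_spread maximum residual retention spread of an anchor
#'   group, minutes (2 x fwhm by convention).
#' @param coarse_bw bandwidth of the coarse pass, minutes; must exceed the
#'   largest between-run shift to be corrected.
#' @return list with `features` (the input with corrected `rt`, `rt_lo`,
#'   `rt_hi`), `warps` (named list of functions: original rt -> corrected rt)
#'   and `anchors` (the anchor table, in coarse-corrected coordinates).
#' @export
align_retention_times <- function(runs_features, rt_bw = 2 / 60,
                                  anchor_min_frac = 0.9,
                                  max_anchor_spread = 0.1,
                                  coarse_bw = 0.5) {
  samples <- names(runs_features)
  identity_out <- function() {
    warps <- stats::setNames(rep(list(identity), length(samples)), samples)
    list(features = runs_features, warps = warps, anchors = NULL)
  }
  if (length(samples) < 2L) {
    warning("fewer than 2 samples: alignment skipped (identity warp)",
            call. = FALSE)
    return(identity_out())
  }
  pooled <- do.call(rbind, runs_features)
  rownames(pooled) <- NULL

  ## coarse pass: per-sample median shift
  coarse_groups <- group_features(pooled, rt_bw = coarse_bw,
                                  minfrac = anchor_min_frac, samples = samples)
  coarse <- stats::setNames(rep(0, length(samples)), samples)
  if (nrow(coarse_groups$groups)) {
    mem <- coarse_groups$members
    med <- stats::setNames(coarse_groups$groups$rt_median,
                           coarse_groups$groups$group_feature_id)
    mem$dev <- mem$rt - med[mem$group_feature_id]
    agg <- tapply(mem$dev, mem$sample_id, stats::median)
    coarse[names(agg)] <- as.numeric(agg)
  }

  ## fine pass on coarsely corrected retention times
  corrected_pool <- pooled
  corrected_pool$rt <- pooled$rt - coarse[pooled$sample_id]
  fine <- group_features(corrected_pool, rt_bw = rt_bw,
                         minfrac = anchor_min_frac, samples = samples)
  g <- fine$groups
  if (nrow(g)) {
    spread <- vapply(g$group_feature_id, function(id)
      diff(range(fine$members$rt[fine$members$group_feature_id == id])),
      numeric(1))
    anchors <- g[spread <= max_anchor_spread, , drop = FALSE]
  } else anchors <- g
  if (!nrow(anchors)) {
    warning("no anchor groups found: alignment skipped (identity warp)",
            call. = FALSE)
    return(identity_out())
  }
  mem <- fine$members[fine$members$group_feature_id %in%
                        anchors$group_feature_id, , drop = FALSE]
  med <- stats::setNames(anchors$rt_median, anchors$group_feature_id)
  ## total deviation of the ORIGINAL rt from the anchor median
  mem$rt_orig <- mem$rt + coarse[mem$sample_id]
  mem$dev <- mem$rt_orig - med[mem$group_feature_id]

  span <- range(pooled$rt)
  grid <- seq(span[1] - 1, span[2] + 1, length.out = 257L)
  warps <- list()
  for (s in samples) {
    d <- mem[mem$sample_id == s, , drop = FALSE]
    dev_hat <- if (nrow(d) >= 10L && diff(range(d$rt_orig)) > 1e-8) {
      fit <- tryCatch(
        stats::loess(dev ~ rt_orig, data = d, span = 0.75, degree = 1L,
                     control = stats::loess.control(surface = "direct")),
        error = function(e) stats::lm(dev ~ rt_orig, data = d))
      stats::predict(fit, data.frame(
        rt_orig = pmin(pmax(grid, min(d$rt_orig)), max(d$rt_orig))))
    } else if (nrow(d) >= 2L && diff(range(d$rt_orig)) > 1e-8) {
      fit <- stats::lm(dev ~ rt_orig, data = d)
      stats::predict(fit, data.frame(
        rt_orig = pmin(pmax(grid, min(d$rt_orig)), max(d$rt_orig))))
    } else if (nrow(d) >= 1L) {
      rep(stats::median(d$dev), length(grid))
    } else rep(coarse[[s]], length(grid))
    dev_fun <- stats::approxfun(grid, dev_hat, rule = 2L)
    warps[[s]] <- local({
      f <- dev_fun
      function(rt) rt - f(rt)
    })
  }
  corrected <- lapply(samples, function(s) {
    f <- runs_features[[s]]
    w <- warps[[s]]
    f$rt <- w(f$rt); f$rt_lo <- w(f$rt_lo); f$rt_hi <- w(f$rt_hi)
    f
  })
  names(corrected) <- samples
  list(features = corrected, warps = warps, anchors = anchors)
}

#' Apply a retention warp to a raw run
#'
#' @param run a [raw_run()].
#' @param warp function mapping original rt (minutes) to corrected rt.
#' @return the run with corrected scan retention times.
#' @export
warp_run <- function(run, warp) {
  rt <- warp(run$rt)
  if (any(diff(rt) <= 0)) rt <- cummax(rt + seq_along(rt) * 1e-12)
  run$rt <- rt
  run
}

#' Group features across samples
#'
#' Within each unit m/z, retention times are clustered by single-linkage with
#' cut height `rt_bw` (consecutive sorted RTs further apart than the
#' bandwidth start a new cluster). Clusters covering at least `minfrac` of
#' the samples become feature groups; each sample contributes at most one
#' member (nearest to the cluster median wins).
#'
#' @param features data.frame of aligned features (rbind over samples) or a
#'   named list of per-sample data.frames.
#' @param rt_bw clustering bandwidth, minutes.
#' @param minfrac minimum fraction of samples with a member.
#' @param samples character vector of all sample ids (defaults to those seen
#'   in `features`; pass explicitly when some samples detected nothing).
#' @return object of class `feature_groups`: list with `groups`
#'   (data.frame: `group_feature_id`, `mz`, `rt_median`, `rt_lo`, `rt_hi`,
#'   `n_samples`) and `members` (data.frame linking groups to features).
#' @export
group_features <- function(features, rt_bw = 2 / 60, minfrac = 0.5,
                           samples = NULL) {
  if (is.list(features) && !is.data.frame(features))
    features <- do.call(rbind, features)
  if (is.null(samples)) samples <- unique(features$sample_id)
  need <- minfrac * length(samples)
  groups <- list(); members <- list(); k <- 0L
  for (m in sort(unique(features$mz))) {
    f <- features[features$mz == m, , drop = FALSE]
    f <- f[order(f$rt), , drop = FALSE]
    cl <- cumsum(c(1L, as.integer(diff(f$rt) > rt_bw)))
    for (c_id in unique(cl)) {
      fc <- f[cl == c_id, , drop = FALSE]
      ## one member per sample: nearest to the cluster median
      med <- stats::median(fc$rt)
      fc <- fc[order(abs(fc$rt - med)), , drop = FALSE]
      fc <- fc[!duplicated(fc$sample_id), , drop = FALSE]
      if (length(unique(fc$sample_id)) < need) next
      k <- k + 1L
      gid <- sprintf("FT%05d", k)
      groups[[k]] <- data.frame(
        group_feature_id = gid, mz = m, rt_median = stats::median(fc$rt),
        rt_lo = stats::median(fc$rt_lo), rt_hi = stats::median(fc$rt_hi),
        n_samples = length(unique(fc$sample_id)), stringsAsFactors = FALSE)
      members[[k]] <- data.frame(
        group_feature_id = gid, sample_id = fc$sample_id,
        feature_id = fc$feature_id, rt = fc$rt, maxo = fc$maxo,
        stringsAsFactors = FALSE)
    }
  }
  if (!k) {
    return(structure(list(
      groups = data.frame(group_feature_id = character(0), mz = integer(0),
                          rt_median = numeric(0), rt_lo = numeric(0),
                          rt_hi = numeric(0), n_samples = integer(0),
                          stringsAsFactors = FALSE),
      members = data.frame(group_feature_id = character(0),
                           sample_id = character(0), feature_id = character(0),
                           rt = numeric(0), maxo = numeric(0),
                           stringsAsFactors = FALSE),
      samples = samples), class = "feature_groups"))
  }
  g <- do.call(rbind, groups)
  ord <- order(g$rt_median, g$mz)
  structure(list(groups = g[ord, , drop = FALSE],
                 members = do.call(rbind, members),
                 samples = samples),
            class = "feature_groups")
}

#' @export
print.feature_groups <- function(x, ...) {
  cat(sprintf("<feature_groups> %d groups over %d samples\n",
              nrow(x$groups), length(x$samples)))
  invisible(x)
}

#' Fill missing feature values from the raw signal
#'
#' For every (group, sample) pair without a detected member, the raw
#' (retention-corrected) EIC of the group's m/z is read between the group's
#' integration envelope and its maximum intensity recorded (the maxo
#' convention), flagged as filled. Existing member values are never altered.
#'
#' @param groups a `feature_groups` object ([group_features()]).
#' @param runs named list of [raw_run()]s, retention-corrected (see
#'   [warp_run()]); names define the matrix column order.
#' @return a [feature_matrix()] with no missing cells.
#' @export
fill_missing <- function(groups, runs) {
  samples <- names(runs)
  g <- groups$groups
  vals <- matrix(NA_real_, nrow = nrow(g), ncol = length(samples),
                 dimnames = list(g$group_feature_id, samples))
  for (i in seq_len(nrow(groups$members))) {
    m <- groups$members[i, ]
    vals[m$group_feature_id, m$sample_id] <- m$maxo
  }
  filled <- is.na(vals)
  if (any(filled)) {
    eics <- lapply(runs, eic_matrix)
    for (s in samples) {
      miss <- which(is.na(vals[, s]))
      if (!length(miss)) next
      e <- eics[[s]]
      for (i in miss) {
        col <- match(g$mz[i], e$mz)
        if (is.na(col)) { vals[i, s] <- 0; next }
        rows <- which(e$rt >= g$rt_lo[i] & e$rt <= g$rt_hi[i])
        vals[i, s] <- if (length(rows)) max(e$mat[rows, col]) else 0
      }
    }
  }
  feature_matrix(
    features = data.frame(feature_id = g$group_feature_id, mz = g$mz,
                          rt_median = g$rt_median, stringsAsFactors = FALSE),
    values = vals, filled = filled)
}
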