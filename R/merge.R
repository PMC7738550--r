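#' Match features to compound ions
#'
#' A peak-picked feature and an ion of a deconvolved compound are the same
#' signal iff they share the unit m/z and their retention times agree within
#' `rt_tol`. A feature may match ions of several compounds; within one
#' compound each ion takes at most one feature (nearest retention time wins).
#'
#' @param groups a `feature_groups` object ([group_features()]).
#' @param aligned an `aligned_compounds` object ([align_compounds()]).
#' @param rt_tol retention tolerance, minutes.
#' @return data.frame: `aligned_id`, `mz` (the ion), `group_feature_id`,
#'   `delta_rt`.
#' @export
match_features_to_ions <- function(groups, aligned, rt_tol = 0.05) {
  g <- groups$groups
  out <- list()
  for (cmp in aligned$compounds) {
    ions <- as.integer(names(cmp$spectrum))
    for (ion in ions) {
      cand <- which(g$mz == ion &
                      abs(g$rt_median - cmp$rt) <= rt_tol + 1e-9)
      if (!length(cand)) next
      best <- cand[which.min(abs(g$rt_median[cand] - cmp$rt))]
      out[[length(out) + 1L]] <- data.frame(
        aligned_id = cmp$aligned_id, mz = ion,
        group_feature_id = g$group_feature_id[best],
        delta_rt = g$rt_median[best] - cmp$rt, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(aligned_id = character(0), mz = integer(0),
                      group_feature_id = character(0), delta_rt = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Relative intensities of a clique compound's features
#'
#' The three-step protocol: (1) average each member feature's intensity
#' across the whole set of samples; (2) assign 1000 to the feature with the
#' highest average (the base peak); (3) scale the rest as
#' `average / max average * 1000`. Ties for the base peak all receive 1000
#' (the formula applied verbatim); a zero-average member floors to 0.
#'
#' @param clique_members character vector of `group_feature_id`s forming one
#'   clique compound.
#' @param matrix a [feature_matrix()] containing those features.
#' @return named numeric: `group_feature_id` -> relative intensity in
#'   \[0, 1000\].
#' @export
relative_intensities <- function(clique_members, matrix) {
  idx <- match(clique_members, matrix$features$feature_id)
  if (anyNA(idx))
    stopf("clique member(s) missing from the feature matrix: %s",
          paste(clique_members[is.na(idx)], collapse = ", "))
  avg <- rowMeans(matrix$values[idx, , drop = FALSE])
  top <- max(avg)
  if (top <= 0) return(stats::setNames(rep(0, length(avg)), clique_members))
  stats::setNames(avg / top * 1000, clique_members)
}

#' Fixed-length spectrum vector over the comparison range
#'
#' Positions cover the half-open integer range `[mz_lo, mz_hi)` — 412
#' positions for the default m/z 38-450 comparison range. In-range ions are
#' copied (out-of-range ions dropped with a warning), absent positions are 0,
#' and the vector is scaled to unit Euclidean norm so the dot product of two
#' vectors lies in \[0, 1\]. An all-zero spectrum stays all-zero and is
#' flagged.
#'
#' @param spectrum named numeric: integer m/z -> relative intensity.
#' @param mz_lo,mz_hi integer bounds of the comparison range.
#' @return object of class `spectrum_vector`: list with `values` (length
#'   `mz_hi - mz_lo`), `mz_lo`, `mz_hi`, `normalized`.
#' @export
vectorize_spectrum <- function(spectrum, mz_lo = 38L, mz_hi = 450L) {
  mz_lo <- as.integer(mz_lo); mz_hi <- as.integer(mz_hi)
  if (mz_lo >= mz_hi) stop("mz_lo must be < mz_hi", call. = FALSE)
  len <- mz_hi - mz_lo
  values <- numeric(len)
  if (length(spectrum)) {
    mz <- as.integer(names(spectrum))
    inr <- mz >= mz_lo & mz < mz_hi
    if (any(!inr))
      warnf("%d ion(s) outside the m/z [%d, %d) comparison range dropped",
            sum(!inr), mz_lo, mz_hi)
    values[mz[inr] - mz_lo + 1L] <- as.numeric(spectrum[inr])
  }
  nrm <- sqrt(sum(values^2))
  normalized <- nrm > 0
  if (normalized) values <- values / nrm
  structure(list(values = values, mz_lo = mz_lo, mz_hi = mz_hi,
                 normalized = normalized),
            class = "spectrum_vector")
}

#' Spectral dot product
#'
#' Sum of elementwise products of two unit-norm spectrum vectors over the
#' same comparison range: the cosine similarity, in \[0, 1\] for non-negative
#' spectra. 1 means identical relative-intensity patterns, 0 disjoint ion
#' sets.
#'
#' @param a,b `spectrum_vector`s with identical bounds.
#' @return numeric in \[0, 1\].
#' @export
spectral_dot <- function(a, b) {
  if (a$mz_lo != b$mz_lo || a$mz_hi != b$mz_hi)
    stop("spectrum vectors have mismatched m/z bounds", call. = FALSE)
  min(1, max(0, sum(a$values * b$values)))
}

#' Cross-validate the two approaches and filter
#'
#' Every clique compound (its relative-intensity spectrum over the comparison
#' range) is compared by dot product with every deconvolved compound. The
#' deconvolved compounds that are the best match of at least one clique
#' compound with a dot product above `dot_threshold` become the filtered
#' compounds; the features previously matched to any filtered compound
#' ([match_features_to_ions()]) become the filtered features (the second
#' filter). Arg-max ties break by smaller retention gap, then by id.
#'
#' @param clique_spectra named list: `clique_id` -> relative-intensity
#'   spectrum (named numeric, `group_feature_id` is not needed here — names
#'   are integer m/z).
#' @param clique_rt named numeric: `clique_id` -> retention time.
#' @param aligned an `aligned_compounds` object.
#' @param ion_matches result of [match_features_to_ions()].
#' @param dot_threshold minimum best-match dot product.
#' @param mz_lo,mz_hi comparison range bounds.
#' @return object of class `filtered_set`: list with `matches` (data.frame
#'   `clique_id`, `aligned_id`, `dot`, `is_best_for_clique`),
#'   `filtered_compounds`, `filtered_features` and `feature_to_compound`
#'   (data.frame `group_feature_id`, `aligned_id`).
#' @export
match_compounds <- function(clique_spectra, clique_rt, aligned, ion_matches,
                            dot_threshold = 0.7, mz_lo = 38L, mz_hi = 450L) {
  empty <- structure(list(
    matches = data.frame(clique_id = character(0), aligned_id = character(0),
                         dot = numeric(0), is_best_for_clique = logical(0),
                         stringsAsFactors = FALSE),
    filtered_compounds = character(0), filtered_features = character(0),
    feature_to_compound = data.frame(group_feature_id = character(0),
                                     aligned_id = character(0),
                                     stringsAsFactors = FALSE)),
    class = "filtered_set")
  if (!length(clique_spectra) || !length(aligned$compounds)) {
    warning("empty compound list on one side: nothing to match", call. = FALSE)
    return(empty)
  }
  cvec <- lapply(clique_spectra, vectorize_spectrum, mz_lo = mz_lo,
                 mz_hi = mz_hi)
  dvec <- lapply(aligned$compounds, function(cmp)
    vectorize_spectrum(cmp$spectrum, mz_lo, mz_hi))
  d_ids <- vapply(aligned$compounds, `[[`, character(1), "aligned_id")
  d_rt <- vapply(aligned$compounds, `[[`, numeric(1), "rt")
  rows <- list()
  best_of <- character(0)
  for (cid in names(cvec)) {
    dots <- vapply(dvec, spectral_dot, numeric(1), a = cvec[[cid]])
    top <- max(dots)
    cand <- which(dots == top)
    if (length(cand) > 1L) {
      gap <- abs(d_rt[cand] - clique_rt[[cid]])
      cand <- cand[order(gap, d_ids[cand])]
    }
    best <- cand[1]
    rows[[cid]] <- data.frame(clique_id = cid, aligned_id = d_ids,
                              dot = dots,
                              is_best_for_clique = seq_along(dots) == best,
                              stringsAsFactors = FALSE)
    if (top > dot_threshold) best_of <- c(best_of, d_ids[best])
  }
  matches <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  filtered_compounds <- sort(unique(best_of))
  f2c <- ion_matches[ion_matches$aligned_id %in% filtered_compounds,
                     c("group_feature_id", "aligned_id"), drop = FALSE]
  f2c <- unique(f2c)
  structure(list(matches = matches,
                 filtered_compounds = filtered_compounds,
                 filtered_features = sort(unique(f2c$group_feature_id)),
                 feature_to_compound = f2c),
            class = "filtered_set")
}

#' @export
print.filtered_set <- function(x, ...) {
  cat(sprintf("<filtered_set> %d filtered compounds, %d filtered features\n",
              length(x$filtered_compounds), length(x$filtered_features)))
  invisible(x)
}

#' Detect possible duplicate compounds
#'
#' Two compounds are a possible duplication iff their spectra's dot product
#' exceeds `dot_min`, their retention times agree within `rt_tol`, and — for
#' deconvolved compounds, which carry per-sample areas — their areas
#' correlate (Pearson above `pearson_min`). The deduplicated list keeps, per
#' flagged pair, the member with the larger total area (deconvolved side) or
#' larger summed average intensity (clique side).
#'
#' @param compounds data.frame-like list of compounds to compare: a list of
#'   lists with `id`, `rt`, `spectrum`, and either `areas` (named numeric;
#'   triggers the Pearson criterion) or `size` (clique side ranking value).
#' @param dot_min minimum dot product.
#' @param rt_tol retention tolerance, minutes.
#' @param pearson_min minimum Pearson correlation of per-sample areas
#'   (deconvolved side only).
#' @param mz_lo,mz_hi comparison range bounds.
#' @return list with `pairs` (data.frame `id_a`, `id_b`, `dot`, `delta_rt`,
#'   `area_pearson`) and `deduplicated` (character ids kept).
#' @export
detect_duplicates <- function(compounds, dot_min = 0.8, rt_tol = 0.05,
                              pearson_min = 0.75, mz_lo = 38L, mz_hi = 450L) {
  ids <- vapply(compounds, `[[`, character(1), "id")
  n <- length(compounds)
  pairs <- data.frame(id_a = character(0), id_b = character(0),
                      dot = numeric(0), delta_rt = numeric(0),
                      area_pearson = numeric(0), stringsAsFactors = FALSE)
  if (n < 2L)
    return(list(pairs = pairs, deduplicated = ids))
  vecs <- lapply(compounds, function(c)
    vectorize_spectrum(c$spectrum, mz_lo, mz_hi))
  rts <- vapply(compounds, `[[`, numeric(1), "rt")
  rank_val <- vapply(compounds, function(c) {
    if (!is.null(c$areas)) sum(c$areas) else c$size %||% 0
  }, numeric(1))
  drop <- rep(FALSE, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    drt <- abs(rts[i] - rts[j])
    if (drt > rt_tol + 1e-9) next
    dp <- spectral_dot(vecs[[i]], vecs[[j]])
    if (dp <= dot_min) next
    pear <- NA_real_
    if (!is.null(compounds[[i]]$areas) && !is.null(compounds[[j]]$areas)) {
      shared <- intersect(names(compounds[[i]]$areas),
                          names(compounds[[j]]$areas))
      if (length(shared) >= 3L) {
        a <- compounds[[i]]$areas[shared]; b <- compounds[[j]]$areas[shared]
        pear <- if (stats::sd(a) > 0 && stats::sd(b) > 0)
          stats::cor(a, b) else NA_real_
      }
      if (is.na(pear) || pear <= pearson_min) next
    }
    pairs <- rbind(pairs, data.frame(
      id_a = ids[i], id_b = ids[j], dot = dp, delta_rt = drt,
      area_pearson = pear, stringsAsFactors = FALSE))
    loser <- if (rank_val[i] >= rank_val[j]) j else i
    drop[loser] <- TRUE
  }
  list(pairs = pairs, deduplicated = ids[!drop])
}

#' Normalize the filtered feature matrix
#'
#' Within each subset's samples, the normalized value of feature f in sample
#' s is `log10(value(f, s)) / log10(D(f)) * 1000`, with the denominator `D`
#' the feature's intensity across all the subset's samples: the sum of the
#' values (default), their mean, or the sum of their logs (`denominator`).
#' Zeros are floored to 1 abundance unit before taking logs; features whose
#' denominator is not positive (intensity sum at or below 1) are dropped with
#' a warning.
#'
#' @param matrix a [feature_matrix()] (typically restricted to filtered
#'   features).
#' @param denominator one of `"sum"`, `"mean"`, `"sum_of_logs"`.
#' @return a [feature_matrix()] of normalized values.
#' @export
normalize_matrix <- function(matrix,
                             denominator = c("sum", "mean", "sum_of_logs")) {
  denominator <- match.arg(denominator)
  v <- matrix$values
  if (any(v <= 0)) v[v <= 0] <- 1
  den <- switch(denominator,
                sum = log10(rowSums(v)),
                mean = log10(rowMeans(v)),
                sum_of_logs = rowSums(log10(v)))
  ok <- den > 0
  if (any(!ok))
    warnf("%d feature(s) dropped: non-positive normalization denominator",
          sum(!ok))
  out <- log10(v[ok, , drop = FALSE]) / den[ok] * 1000
  feature_matrix(features = matrix$features[ok, , drop = FALSE],
                 values = out,
                 filled = matrix$filled[ok, , drop = FALSE])
}
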