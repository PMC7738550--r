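#' Match factor between two EI spectra
#'
#' 100 times the weighted cosine similarity of the two spectra over the union
#' of their ions, with the conventional library-search weighting
#' `m^1 * intensity^0.5`. Identical (proportional) spectra score 100,
#' disjoint ion sets 0; the score is symmetric.
#'
#' @param query,entry named numeric spectra (names integer m/z).
#' @return percent in \[0, 100\].
#' @export
match_factor <- function(query, entry) {
  if (!length(query) || !length(entry))
    stop("match factor undefined for an empty spectrum", call. = FALSE)
  ions <- sort(unique(as.integer(c(names(query), names(entry)))))
  wq <- we <- numeric(length(ions))
  iq <- match(as.integer(names(query)), ions)
  ie <- match(as.integer(names(entry)), ions)
  wq[iq] <- ions[iq] * sqrt(as.numeric(query))
  we[ie] <- ions[ie] * sqrt(as.numeric(entry))
  100 * min(1, cosine_sim(wq, we))
}

#' Retention index by piecewise-linear interpolation
#'
#' The van den Dool & Kratz convention for temperature-programmed GC:
#' `RI = ri_k + (ri_{k+1} - ri_k) * (rt - rt_k) / (rt_{k+1} - rt_k)` for the
#' bracketing anchor pair; outside the anchor span the terminal pair is
#' extrapolated and the result flagged (attribute `extrapolated`).
#'
#' @param rt query retention time, minutes.
#' @param anchors data.frame with `rt` and `ri`, strictly increasing in both.
#' @return dimensionless retention index (with attribute `extrapolated`).
#' @export
compute_ri <- function(rt, anchors) {
  if (is.null(anchors) || nrow(anchors) < 2L)
    stop("need at least 2 retention-index anchors", call. = FALSE)
  anchors <- anchors[order(anchors$rt), , drop = FALSE]
  if (any(diff(anchors$rt) <= 0) || any(diff(anchors$ri) <= 0))
    stop("anchor rt and ri must be strictly increasing", call. = FALSE)
  n <- nrow(anchors)
  k <- findInterval(rt, anchors$rt, rightmost.closed = TRUE)
  extrapolated <- k < 1L | rt > anchors$rt[n]
  k <- pmin(pmax(k, 1L), n - 1L)
  ri <- anchors$ri[k] + (anchors$ri[k + 1L] - anchors$ri[k]) *
    (rt - anchors$rt[k]) / (anchors$rt[k + 1L] - anchors$rt[k])
  attr(ri, "extrapolated") <- extrapolated
  ri
}

#' Retention-index error
#'
#' Percent disagreement of a query RI with a library entry's RI, relative to
#' the entry: `100 * |ri_query - ri_entry| / ri_entry`.
#'
#' @param ri_query,ri_entry retention indices.
#' @return percent.
#' @export
ri_error <- function(ri_query, ri_entry) {
  if (any(ri_entry <= 0)) stop("entry RI must be > 0", call. = FALSE)
  100 * abs(ri_query - ri_entry) / ri_entry
}

#' Candidate library entries for a query spectrum
#'
#' Entries with a match factor above `mf_floor` and within `mf_window` of the
#' best match factor, ordered by descending match factor and truncated to
#' `cap` entries. Empty when nothing clears the floor.
#'
#' @param query named numeric spectrum.
#' @param library a `spectral_library` ([read_msp_library()]).
#' @param mf_floor minimum match factor, percent (exclusive).
#' @param mf_window retained band below the best match factor, percent.
#' @param cap maximum number of entries returned.
#' @return data.frame: `entry`, `name`, `match_factor`, `ri_entry`.
#' @export
candidate_entries <- function(query, library, mf_floor = 80, mf_window = 5,
                              cap = 450L) {
  if (!length(library$entries)) stop("empty spectral library", call. = FALSE)
  mf <- vapply(library$entries, function(e) match_factor(query, e$spectrum),
               numeric(1))
  keep <- which(mf > mf_floor & mf >= max(mf) - mf_window)
  keep <- keep[order(-mf[keep])]
  if (length(keep) > cap) keep <- keep[seq_len(cap)]
  data.frame(
    entry = keep,
    name = vapply(library$entries[keep], `[[`, character(1), "name"),
    match_factor = mf[keep],
    ri_entry = vapply(library$entries[keep], function(e)
      as.numeric(e$retention_index %||% NA_real_), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Select the best library entry
#'
#' Among candidates with an RI error at or below `ri_error_max`, the entry
#' with the lowest RI error wins (match factor breaks ties). If no candidate
#' has a qualifying RI error — including when RI is unavailable on either
#' side — the highest match factor wins and the ranking basis is recorded as
#' `mf_only`.
#'
#' @param candidates data.frame from [candidate_entries()], optionally with a
#'   `ri_error` column (`NA` where unavailable).
#' @param ri_error_max maximum acceptable RI error, percent.
#' @return list (`identification`): `entry_name`, `match_factor`, `ri_error`
#'   (`NA` if unused/absent), `rank_basis` (`"ri_and_mf"` or `"mf_only"`), or
#'   `NULL`-object with `entry_name = NA` when `candidates` is empty.
#' @export
select_best <- function(candidates, ri_error_max = 20) {
  if (is.null(candidates) || !nrow(candidates))
    return(list(entry_name = NA_character_, match_factor = NA_real_,
                ri_error = NA_real_, rank_basis = NA_character_))
  rie <- if ("ri_error" %in% names(candidates)) candidates$ri_error
         else rep(NA_real_, nrow(candidates))
  ok <- which(!is.na(rie) & rie <= ri_error_max)
  if (length(ok)) {
    best <- ok[order(rie[ok], -candidates$match_factor[ok])][1]
    list(entry_name = candidates$name[best],
         match_factor = candidates$match_factor[best],
         ri_error = rie[best], rank_basis = "ri_and_mf")
  } else {
    best <- which.max(candidates$match_factor)
    list(entry_name = candidates$name[best],
         match_factor = candidates$match_factor[best],
         ri_error = NA_real_, rank_basis = "mf_only")
  }
}

#' Identify compounds against an MSP library
#'
#' Runs [candidate_entries()], computes each candidate's RI error when both
#' the query RI (from `anchors` via [compute_ri()]) and the entry RI exist,
#' and applies [select_best()].
#'
#' @param aligned an `aligned_compounds` object; each compound's consensus
#'   spectrum is the query.
#' @param library a `spectral_library`.
#' @param anchors data.frame with `rt`, `ri`, or `NULL` for match-factor-only
#'   identification.
#' @param mf_floor,mf_window,cap,ri_error_max see [candidate_entries()] and
#'   [select_best()].
#' @param ids restrict to these `aligned_id`s (default all).
#' @return data.frame: `aligned_id`, `rt`, `ri_query`, `entry_name`,
#'   `match_factor`, `ri_error`, `rank_basis`.
#' @export
identify_compounds <- function(aligned, library, anchors = NULL,
                               mf_floor = 80, mf_window = 5, cap = 450L,
                               ri_error_max = 20, ids = NULL) {
  out <- list()
  for (cmp in aligned$compounds) {
    if (!is.null(ids) && !(cmp$aligned_id %in% ids)) next
    ri_q <- if (!is.null(anchors) && nrow(anchors) >= 2L)
      as.numeric(compute_ri(cmp$rt, anchors)) else NA_real_
    cand <- candidate_entries(cmp$spectrum, library, mf_floor, mf_window, cap)
    if (nrow(cand))
      cand$ri_error <- ifelse(!is.na(ri_q) & !is.na(cand$ri_entry),
                              ri_error(ri_q, cand$ri_entry), NA_real_)
    best <- select_best(cand, ri_error_max)
    out[[length(out) + 1L]] <- data.frame(
      aligned_id = cmp$aligned_id, rt = cmp$rt, ri_query = ri_q,
      entry_name = best$entry_name, match_factor = best$match_factor,
      ri_error = best$ri_error, rank_basis = best$rank_basis,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(aligned_id = character(0), rt = numeric(0),
                      ri_query = numeric(0), entry_name = character(0),
                      match_factor = numeric(0), ri_error = numeric(0),
                      rank_basis = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Build retention-index anchors from n-alkanes in samples
#'
#' The six-filter anchoring procedure. Against a library restricted to
#' n-alkane entries (C7-C24 by default; names must allow the carbon number
#' and molecular weight to be read off the entry): (1) keep deconvolved
#' compounds whose match factor against any alkane entry exceeds
#' `alkane_mf_floor`; (2) per alkane, keep compounds within `mf_points` match
#' factor points of that alkane's best; (3) drop combinations whose
#' deconvolved spectrum lacks the alkane's molecular ion; (4) cross-approach
#' confirmation — require a detected feature with m/z equal to the alkane's
#' molecular weight within `rt_tol` of the compound; (5) per alkane keep the
#' lowest-RT compound (higher match factor breaks ties); (6) remove outliers
#' from the RT-vs-carbon-number line (residuals beyond 3 x MAD of a linear
#' fit). Each surviving alkane contributes one anchor with RI = 100 x carbon
#' number.
#'
#' @param compounds list of deconvolved compounds ([deconvolve()]) or an
#'   `aligned_compounds` object, from the anchor samples.
#' @param groups a `feature_groups` object from the same samples.
#' @param alkane_library a `spectral_library` of n-alkane entries carrying
#'   `molecular_weight`; carbon number is derived as (MW - 2) / 14.
#' @param alkane_mf_floor match-factor floor, percent (exclusive).
#' @param mf_points per-alkane match-factor band, points.
#' @param rt_tol cross-approach retention tolerance, minutes.
#' @return list with `anchors` (data.frame `label`, `carbon`, `rt`, `ri`) and
#'   `diagnostics` (data.frame of all combinations and the filter that
#'   removed them, `kept` flag).
#' @export
anchor_alkanes <- function(compounds, groups, alkane_library,
                           alkane_mf_floor = 95, mf_points = 5,
                           rt_tol = 0.05) {
  if (inherits(compounds, "aligned_compounds")) {
    cmps <- lapply(compounds$compounds, function(c)
      list(id = c$aligned_id, rt = c$rt, spectrum = c$spectrum))
  } else {
    cmps <- lapply(compounds, function(c)
      list(id = c$compound_id, rt = c$rt, spectrum = c$spectrum))
  }
  entries <- alkane_library$entries
  mw <- vapply(entries, function(e) as.numeric(e$molecular_weight %||% NA),
               numeric(1))
  if (anyNA(mw))
    stop("alkane library entries must carry molecular_weight", call. = FALSE)
  carbon <- as.integer(round((mw - 2) / 14))
  ## match-factor matrix: compounds x alkane entries
  mf <- matrix(0, nrow = length(cmps), ncol = length(entries))
  for (i in seq_along(cmps)) for (j in seq_along(entries))
    mf[i, j] <- match_factor(cmps[[i]]$spectrum, entries[[j]]$spectrum)

  ## filter 1: overall spectral gate
  alkane_like <- which(apply(mf, 1L, max) > alkane_mf_floor)
  combos <- list()
  if (length(alkane_like)) {
    ## filter 2: per alkane, the band within mf_points of that alkane's best
    for (j in seq_along(entries)) {
      band <- mf[alkane_like, j] >= max(mf[alkane_like, j]) - mf_points
      for (i in alkane_like[band])
        combos[[length(combos) + 1L]] <- list(i = i, j = j)
    }
  }
  g <- groups$groups
  keep <- logical(length(combos)); removed <- character(length(combos))
  for (k in seq_along(combos)) {
    i <- combos[[k]]$i; j <- combos[[k]]$j
    cmp <- cmps[[i]]
    ## filter 3: molecular ion present in the deconvolved spectrum
    if (!(as.character(as.integer(mw[j])) %in% names(cmp$spectrum))) {
      removed[k] <- "molecular_ion"; next
    }
    ## filter 4: a feature at the molecular weight within rt_tol
    hit <- any(g$mz == as.integer(mw[j]) &
                 abs(g$rt_median - cmp$rt) <= rt_tol)
    if (!hit) { removed[k] <- "feature_confirmation"; next }
    keep[k] <- TRUE
  }
  diagnostics <- data.frame(
    compound_id = vapply(combos, function(c) cmps[[c$i]]$id, character(1)),
    alkane = vapply(combos, function(c) entries[[c$j]]$name, character(1)),
    carbon = vapply(combos, function(c) carbon[c$j], integer(1)),
    rt = vapply(combos, function(c) cmps[[c$i]]$rt, numeric(1)),
    match_factor = vapply(combos, function(c) mf[c$i, c$j], numeric(1)),
    removed_by = removed, kept = keep, stringsAsFactors = FALSE)

  ## filter 5: lowest-RT compound per alkane (MF breaks ties)
  surv <- diagnostics[diagnostics$kept, , drop = FALSE]
  picks <- NULL
  for (cn in sort(unique(surv$carbon))) {
    s <- surv[surv$carbon == cn, , drop = FALSE]
    s <- s[order(s$rt, -s$match_factor), , drop = FALSE]
    picks <- rbind(picks, s[1, , drop = FALSE])
  }
  ## filter 6: outliers off the RT ~ carbon line
  if (!is.null(picks) && nrow(picks) >= 3L) {
    fit <- stats::lm(rt ~ carbon, data = picks)
    res <- stats::residuals(fit)
    scale <- stats::mad(res)
    ## a scale below numeric noise (sub-microminute) means no real scatter
    if (scale > 1e-6) {
      out <- abs(res) > 3 * scale
      if (any(out)) {
        drop_ids <- paste(picks$compound_id[out], picks$alkane[out])
        diagnostics$removed_by[paste(diagnostics$compound_id,
                                     diagnostics$alkane) %in% drop_ids] <-
          "rt_outlier"
        diagnostics$kept[paste(diagnostics$compound_id,
                               diagnostics$alkane) %in% drop_ids] <- FALSE
        picks <- picks[!out, , drop = FALSE]
      }
    }
  }
  if (is.null(picks) || nrow(picks) < 2L)
    stop("fewer than 2 alkane anchors survive; identification must fall back to match factor only",
         call. = FALSE)
  anchors <- data.frame(label = sprintf("C%d", picks$carbon),
                        carbon = picks$carbon, rt = picks$rt,
                        ri = 100 * picks$carbon, stringsAsFactors = FALSE)
  anchors <- anchors[order(anchors$rt), , drop = FALSE]
  rownames(anchors) <- NULL
  list(anchors = anchors, diagnostics = diagnostics)
}
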