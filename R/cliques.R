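#' Feature-similarity network of one sample
#'
#' Nodes are the sample's features; two features are connected iff they
#' co-elute (apex retention times within `rt_tol`) and their raw EIC shapes
#' over the union of their integration windows have cosine similarity at
#' least `min_cosine`. Fragments of one compound share the compound's elution
#' profile, so their cosine approaches 1; profiles a few sigma apart fall
#' below the gate.
#'
#' @param features data.frame of one sample's features ([detect_peaks()]).
#' @param run that sample's [raw_run()] (retention-corrected if the features
#'   are).
#' @param rt_tol co-elution tolerance, minutes.
#' @param min_cosine minimum EIC-shape cosine for an edge.
#' @return object of class `similarity_network`: list with `nodes` (feature
#'   ids) and `edges` (data.frame `from`, `to`, `weight`).
#' @export
build_similarity_network <- function(features, run, rt_tol = 0.05,
                                     min_cosine = 0.8) {
  nodes <- features$feature_id
  edges <- data.frame(from = character(0), to = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  net <- function() structure(list(nodes = nodes, edges = edges),
                              class = "similarity_network")
  n <- nrow(features)
  if (n < 2L) return(net())
  eics <- eic_matrix(run)
  ord <- order(features$rt)
  f <- features[ord, , drop = FALSE]
  cols <- match(f$mz, eics$mz)
  out <- list()
  for (i in seq_len(n - 1L)) {
    j <- i + 1L
    while (j <= n && f$rt[j] - f$rt[i] <= rt_tol) {
      if (!is.na(cols[i]) && !is.na(cols[j])) {
        lo <- min(f$rt_lo[i], f$rt_lo[j]); hi <- max(f$rt_hi[i], f$rt_hi[j])
        rows <- which(eics$rt >= lo & eics$rt <= hi)
        if (length(rows) >= 3L) {
          w <- cosine_sim(eics$mat[rows, cols[i]], eics$mat[rows, cols[j]])
          if (w >= min_cosine)
            out[[length(out) + 1L]] <- data.frame(
              from = f$feature_id[i], to = f$feature_id[j], weight = w,
              stringsAsFactors = FALSE)
        }
      }
      j <- j + 1L
    }
  }
  if (length(out)) edges <- do.call(rbind, out)
  net()
}

#' Per-sample pseudo-compound groups from the similarity network
#'
#' Connected components of the network (edges below the construction gate
#' were never added), each component one per-sample pseudo-compound. Every
#' feature belongs to exactly one group; isolated features form singletons.
#' Deterministic: groups ordered by their first node, nodes in input order.
#'
#' @param network a `similarity_network` ([build_similarity_network()]).
#' @return list of character vectors of feature ids (a partition of the
#'   network's nodes).
#' @export
find_cliques <- function(network) {
  nodes <- network$nodes
  if (!length(nodes)) return(list())
  if (!nrow(network$edges)) return(lapply(nodes, identity))
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  comp <- igraph::components(g)$membership[nodes]
  split(nodes, comp)[unique(as.character(comp))]
}

#' Cohort-level clique compounds
#'
#' Runs the similarity-network grouping sample by sample, lifts the
#' per-sample cliques onto the cross-sample feature groups and reconciles
#' them by majority vote: two feature groups belong to the same clique
#' compound iff they are co-clustered in more than half of the samples where
#' both are detected. The clique compound's support is the mean co-clustering
#' fraction over its member pairs (1 for singletons).
#'
#' @param aligned_features named list: sample id -> aligned feature
#'   data.frame.
#' @param groups a `feature_groups` object ([group_features()]).
#' @param runs named list of retention-corrected [raw_run()]s.
#' @param rt_tol,min_cosine passed to [build_similarity_network()].
#' @return object of class `clique_compounds`: list with `compounds`
#'   (data.frame `clique_id`, `rt`, `support`, `n_members`) and `members`
#'   (data.frame `clique_id`, `group_feature_id`).
#' @export
annotate_all_samples <- function(aligned_features, groups, runs,
                                 rt_tol = 0.05, min_cosine = 0.8) {
  empty <- structure(list(
    compounds = data.frame(clique_id = character(0), rt = numeric(0),
                           support = numeric(0), n_members = integer(0),
                           stringsAsFactors = FALSE),
    members = data.frame(clique_id = character(0),
                         group_feature_id = character(0),
                         stringsAsFactors = FALSE)),
    class = "clique_compounds")
  samples <- names(aligned_features)
  if (!length(samples) || !nrow(groups$groups)) return(empty)
  f2g <- stats::setNames(groups$members$group_feature_id,
                         groups$members$feature_id)
  gids <- groups$groups$group_feature_id
  gi <- stats::setNames(seq_along(gids), gids)
  n_g <- length(gids)
  present <- matrix(FALSE, nrow = n_g, ncol = length(samples),
                    dimnames = list(gids, samples))
  n_co <- matrix(0L, n_g, n_g)
  for (s in samples) {
    feats <- aligned_features[[s]]
    feats <- feats[feats$feature_id %in% names(f2g), , drop = FALSE]
    if (!nrow(feats)) next
    feats <- feats[order(feats$feature_id), , drop = FALSE]
    feats <- feats[!duplicated(f2g[feats$feature_id]), , drop = FALSE]
    present[unique(f2g[feats$feature_id]), s] <- TRUE
    net <- build_similarity_network(feats, runs[[s]], rt_tol, min_cosine)
    for (cl in find_cliques(net)) {
      gidx <- unique(gi[f2g[cl]])
      if (length(gidx) >= 2L)
        n_co[gidx, gidx] <- n_co[gidx, gidx] + 1L
    }
  }
  diag(n_co) <- 0L
  pm <- present * 1L
  n_both <- pm %*% t(pm)
  frac <- ifelse(n_both > 0, n_co / pmax(n_both, 1L), 0)
  adj <- frac > 0.5
  seen <- gids[rowSums(present) > 0]
  if (!length(seen)) return(empty)
  pair <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (!nrow(pair)) {
    parts <- lapply(seen, identity)
  } else {
    edges <- data.frame(from = gids[pair[, 1]], to = gids[pair[, 2]],
                        stringsAsFactors = FALSE)
    edges <- edges[edges$from %in% seen & edges$to %in% seen, , drop = FALSE]
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = seen))
    memb <- igraph::components(g)$membership[seen]
    parts <- split(seen, memb)[unique(as.character(memb))]
  }
  rt_of <- stats::setNames(groups$groups$rt_median, gids)
  comp <- NULL; mem <- NULL
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    cid <- sprintf("CC%04d", i)
    supp <- if (length(p) < 2L) 1 else {
      idx <- gi[p]
      mean(frac[cbind(rep(idx, each = length(idx)),
                      rep(idx, length(idx)))][
        as.vector(upper.tri(matrix(0, length(idx), length(idx))))])
    }
    comp <- rbind(comp, data.frame(
      clique_id = cid, rt = stats::median(rt_of[p]), support = supp,
      n_members = length(p), stringsAsFactors = FALSE))
    mem <- rbind(mem, data.frame(clique_id = cid, group_feature_id = p,
                                 stringsAsFactors = FALSE, row.names = NULL))
  }
  structure(list(compounds = comp, members = mem), class = "clique_compounds")
}

#' @export
print.clique_compounds <- function(x, ...) {
  cat(sprintf("<clique_compounds> %d compounds (%d member features)\n",
              nrow(x$compounds), nrow(x$members)))
  invisible(x)
}
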