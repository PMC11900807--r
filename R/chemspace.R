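# Chemical-space mapping of triaged sets: 2-D embedding of fingerprints,
# density clustering with a minimum cluster size and a NOISE label,
# Tanimoto consistency checking, and selection of purchasable cluster
# representatives.
#
# The embedding is a deterministic classical (Torgerson) multidimensional
# scaling of the fingerprint distances; clustering is a density method of
# the HDBSCAN family: single linkage on mutual-reachability distances
# (core distance = distance to the n_neighbors-th nearest neighbor), cut
# at the largest merge-height gap, with clusters smaller than
# min_cluster_size dissolved into noise.

#' Noise label used by [embed_and_cluster()]
#' @export
NOISE <- 0L

fp_dist <- function(fps, metric) {
  if (metric == "euclidean") return(stats::dist(fps))
  stats::as.dist(1 - tanimoto_matrix(fps))  # jaccard
}

# canonical relabeling: clusters numbered 1..K by decreasing size,
# ties broken by smallest member id; input order therefore irrelevant
relabel_clusters <- function(labels, ids) {
  keep <- labels != NOISE
  if (!any(keep)) return(labels)
  cl <- split(ids[keep], labels[keep])
  ord <- order(-lengths(cl), vapply(cl, function(m) min(sort(m)), ""))
  map <- stats::setNames(seq_along(ord), names(cl)[ord])
  labels[keep] <- map[as.character(labels[keep])]
  as.integer(labels)
}

#' Embed fingerprints in 2-D and density-cluster them
#'
#' Molecules are embedded in two dimensions by classical multidimensional
#' scaling of their fingerprint distances, then grouped by a
#' density-based hierarchical clustering (single linkage on
#' mutual-reachability distances) in the embedded plane. Groups smaller
#' than `min_cluster_size` are labelled [NOISE] (`0`); cluster ids are
#' `1..K`, numbered by decreasing population. The procedure is
#' deterministic: identical inputs (in any order) and seed give identical
#' labels.
#'
#' @param fingerprints binary matrix (rows = molecules, rownames = ids),
#'   e.g. from [morgan_fp()].
#' @param n_neighbors neighborhood size used for the core distance.
#' @param min_dist recorded embedding parameter (the deterministic MDS
#'   embedding does not use it; kept for provenance).
#' @param min_cluster_size minimum molecules per cluster (default 30).
#' @param seed integer seed, recorded in the result.
#' @param metric `"euclidean"` (on raw bits) or `"jaccard"`.
#' @return An object of class `cluster_assignment`: `embedding`
#'   (two-column matrix), `labels` (named integer vector; `0` = noise)
#'   and `parameters`.
#' @export
embed_and_cluster <- function(fingerprints, n_neighbors = 10, min_dist = 0.0,
                              min_cluster_size = 30, seed = 42,
                              metric = c("euclidean", "jaccard")) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(fingerprints), !is.null(rownames(fingerprints)))
  n <- nrow(fingerprints)
  if (n < 2) stop("need at least 2 molecules")
  ids <- rownames(fingerprints)
  # deterministic input order for exact reproducibility under shuffling
  o <- order(ids)
  fps <- fingerprints[o, , drop = FALSE]
  ids <- ids[o]

  d <- fp_dist(fps, metric)
  emb <- stats::cmdscale(d, k = 2)
  if (ncol(emb) < 2) emb <- cbind(emb, 0)[, 1:2, drop = FALSE]
  rownames(emb) <- ids
  colnames(emb) <- c("x", "y")

  labels <- if (n < min_cluster_size) {
    rep(NOISE, n)
  } else {
    hdbscan_lite(stats::dist(emb), n, n_neighbors, min_cluster_size)
  }
  names(labels) <- ids
  labels <- relabel_clusters(labels, ids)
  names(labels) <- ids
  structure(list(embedding = emb, labels = labels,
                 parameters = list(n_neighbors = n_neighbors,
                                   min_dist = min_dist,
                                   min_cluster_size = min_cluster_size,
                                   seed = seed, metric = metric)),
            class = "cluster_assignment")
}

# density clustering: mutual-reachability single linkage, largest-gap cut
hdbscan_lite <- function(d, n, n_neighbors, min_cluster_size) {
  dm <- as.matrix(d)
  k <- min(n_neighbors, n - 1L)
  # core distance: distance to the k-th nearest other point
  core <- vapply(seq_len(n), function(i) sort(dm[i, -i], partial = k)[k], 0)
  mr <- pmax(dm, outer(core, core, pmax))
  diag(mr) <- 0
  hc <- stats::hclust(stats::as.dist(mr), method = "single")
  h <- hc$height
  cut_labels <- function(height) stats::cutree(hc, h = height)
  # candidate cuts: midpoints of consecutive merge heights plus "no cut"
  if (length(h) >= 2) {
    gaps <- diff(h)
    i <- which.max(gaps)
    labels <- cut_labels((h[i] + h[i + 1]) / 2)
  } else {
    labels <- rep(1L, n)
  }
  sizes <- table(labels)
  small <- as.integer(names(sizes)[sizes < min_cluster_size])
  labels[labels %in% small] <- NA
  if (all(is.na(labels))) {
    # no dense group at the gap cut: fall back to one cluster if the
    # whole set is large enough, else all noise
    labels <- rep(if (n >= min_cluster_size) 1L else NA_integer_, n)
  }
  labels[is.na(labels)] <- NOISE
  as.integer(labels)
}

#' @export
print.cluster_assignment <- function(x, ...) {
  k <- max(x$labels)
  cat(sprintf("cluster_assignment: %d molecules, %d cluster(s), %d noise\n",
              length(x$labels), k, sum(x$labels == NOISE)))
  invisible(x)
}

#' Tanimoto consistency of a clustering
#'
#' For each cluster, the mean pairwise Tanimoto similarity of its members
#' (intra; `NA` for singletons); between clusters, the Tanimoto
#' similarity of their medoids (the member maximizing mean similarity to
#' its own cluster). The check passes when every cluster's intra mean
#' exceeds every inter-medoid similarity involving it.
#'
#' @param assignment an [embed_and_cluster()] result.
#' @param fingerprints the fingerprint matrix the assignment was built
#'   from.
#' @return A list with `intra` (named numeric), `medoids` (named
#'   character), `inter` (matrix), `pass` (logical).
#' @export
cluster_consistency <- function(assignment, fingerprints) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  labels <- assignment$labels
  ids <- names(labels)[labels != NOISE]
  if (!length(ids)) stop("no clustered molecules")
  fps <- fingerprints[ids, , drop = FALSE]
  sim <- tanimoto_matrix(fps)
  clusters <- split(ids, labels[ids])
  intra <- vapply(clusters, function(m) {
    if (length(m) < 2) return(NA_real_)
    s <- sim[m, m]
    mean(s[upper.tri(s)])
  }, 0)
  medoids <- vapply(clusters, function(m) {
    if (length(m) == 1) return(m)
    msim <- rowMeans(sim[m, m])
    sort(m[msim == max(msim)])[1]
  }, "")
  kk <- length(clusters)
  inter <- matrix(NA_real_, kk, kk, dimnames = list(names(clusters), names(clusters)))
  if (kk >= 2)
    for (i in seq_len(kk)) for (j in seq_len(kk))
      if (i != j) inter[i, j] <- sim[medoids[i], medoids[j]]
  pass <- if (kk >= 2) {
    all(vapply(seq_len(kk), function(i)
      is.na(intra[i]) || intra[i] > max(inter[i, ], na.rm = TRUE), TRUE))
  } else TRUE
  list(intra = intra, medoids = medoids, inter = inter, pass = pass)
}

#' Select cluster representatives for experimental testing
#'
#' Clusters containing at least one known ligand are flagged; a flagged
#' cluster contributes its `top_k_known` best-scoring available
#' molecules, any other cluster its single best-scoring available
#' molecule. Unavailable molecules are skipped in favor of the next best
#' in the same cluster; noise molecules never appear. Clusters are
#' reported densest first.
#'
#' @param triage_set molecule ids to draw candidates from (e.g. a
#'   receptor's potential binders).
#' @param assignment an [embed_and_cluster()] result covering
#'   `triage_set`.
#' @param scores a [score_table()] covering `triage_set` (more negative =
#'   better).
#' @param known_ligands molecule ids with known activity (flags their
#'   clusters).
#' @param available molecule ids purchasable/available; `NULL` means all.
#' @param top_k_known candidates per flagged cluster (default 5).
#' @return A data.frame of class `candidate_slate`: columns `cluster`,
#'   `cluster_size`, `flagged`, `rank_in_cluster`, `molecule`, `score`.
#' @export
select_candidates <- function(triage_set, assignment, scores,
                              known_ligands = character(),
                              available = NULL, top_k_known = 5) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(scores, "score_table"))
  if (!length(triage_set)) stop("empty triage set")
  labels <- assignment$labels
  miss <- setdiff(triage_set, names(labels))
  if (length(miss))
    stop("molecules not in the clustering: ", paste(miss, collapse = ", "))
  sc <- scores$scores
  miss <- setdiff(triage_set, names(sc))
  if (length(miss))
    stop("molecules without scores: ", paste(miss, collapse = ", "))
  members <- split(triage_set, labels[triage_set])
  members <- members[names(members) != as.character(NOISE)]
  if (!length(members)) stop("no clustered molecules in the triage set")
  if (is.null(available)) available <- triage_set
  ord <- order(-lengths(members), as.integer(names(members)))
  rows <- lapply(members[ord], function(m) {
    cl <- labels[m[1]]
    flagged <- any(m %in% known_ligands)
    m <- m[order(sc[m], m)]        # best score first, tie by id
    m <- m[m %in% available]
    m <- utils::head(m, if (flagged) top_k_known else 1L)
    if (!length(m)) return(NULL)
    data.frame(cluster = unname(cl), cluster_size = sum(labels[triage_set] == cl),
               flagged = flagged, rank_in_cluster = seq_along(m),
               molecule = m, score = unname(sc[m]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("candidate_slate", "data.frame")
  out
}

#' Write a cluster assignment to CSV
#'
#' @param assignment an [embed_and_cluster()] result.
#' @param path output CSV path (molecule, x, y, cluster).
#' @return `path`, invisibly.
#' @export
write_clusters_csv <- function(assignment, path) {
  utils::write.csv(
    data.frame(molecule = names(assignment$labels),
               x = assignment$embedding[names(assignment$labels), "x"],
               y = assignment$embedding[names(assignment$labels), "y"],
               cluster = unname(assignment$labels)),
    path, row.names = FALSE)
  invisible(path)
}
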