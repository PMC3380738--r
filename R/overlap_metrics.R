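# Per-cluster overlap statistics for a (non-unique) collection of clusters.
#
# For cluster c_i in a set of n clusters, an overlap is a non-empty
# intersection V(c_i) ∩ V(c_j), j != i; equal intersections with different
# partners count separately (multiset semantics). From the multiset O(c_i):
#   S_overlap = mean overlap size        = sum |o| / |O|
#   R_overlap = S_overlap / |V(c_i)|                       ("overlap rate")
#   Cov       = |union of O| / |V(c_i)|                    ("overlap coverage")
#   Cons      = R_overlap / Cov                            ("consistency")
# A cluster with no overlaps gets 0 for all four, which also lets it pass
# through refinement untouched.

#' Overlaps of one cluster with the rest of a cluster set
#'
#' Returns the multiset of non-empty intersections between the target
#' cluster and every *other* cluster of the set (by position, so a
#' duplicated cluster overlaps its twin fully).
#'
#' @param clusters a [cluster_set].
#' @param i position of the target cluster in `clusters`.
#' @return list of character vectors, one per overlapping partner, named by
#'   partner label.
#' @export
cluster_overlaps <- function(clusters, i) {
  stopifnot(inherits(clusters, "cluster_set"))
  i <- as.integer(i)
  if (i < 1L || i > length(clusters)) {
    stop(sprintf("no cluster at position %d", i), call. = FALSE)
  }
  target <- clusters[[i]]
  out <- lapply(seq_along(clusters)[-i],
                function(j) intersect(clusters[[j]], target))
  names(out) <- names(clusters)[-i]
  out[lengths(out) > 0L]
}

#' Overlap profile of one cluster
#'
#' Computes the overlap statistics of the cluster at position `i`: the
#' average overlap size, the overlap rate (average overlap size relative to
#' cluster size), the overlap coverage (fraction of members appearing in at
#' least one overlap) and the overlapping consistency (rate divided by
#' coverage, a uniformity measure in \[0, 1\]).
#'
#' @inheritParams cluster_overlaps
#' @return a one-row data frame with columns `label`, `size`, `n_overlaps`,
#'   `s_overlap`, `r_overlap`, `coverage`, `consistency`.
#' @export
overlap_profile <- function(clusters, i) {
  ov <- cluster_overlaps(clusters, i)
  target <- clusters[[i]]
  size <- length(target)
  if (length(ov) == 0L) {
    s <- r <- cov <- cons <- 0
  } else {
    s <- mean(lengths(ov))
    r <- s / size
    cov <- length(unique(unlist(ov))) / size
    cons <- r / cov
  }
  data.frame(label = names(clusters)[i], size = size,
             n_overlaps = length(ov), s_overlap = s, r_overlap = r,
             coverage = cov, consistency = cons,
             stringsAsFactors = FALSE)
}

#' Overlap profiles of every cluster in a set
#'
#' @param clusters a [cluster_set].
#' @return data frame with one row per cluster (columns as
#'   [overlap_profile()]), in cluster order.
#' @export
overlap_profiles <- function(clusters) {
  stopifnot(inherits(clusters, "cluster_set"))
  do.call(rbind, lapply(seq_along(clusters),
                        function(i) overlap_profile(clusters, i)))
}

#' Average overlap rate of a cluster set
#'
#' Arithmetic mean of the per-cluster overlap rate; clusters with no
#' overlaps contribute 0. An average overlap rate of 0.2 means that on
#' average 20% of the members of each cluster are involved in overlapping.
#'
#' @param clusters a non-empty [cluster_set].
#' @return a number in \[0, 1\].
#' @export
average_overlap_rate <- function(clusters) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (length(clusters) == 0L) stop("empty cluster set", call. = FALSE)
  mean(overlap_profiles(clusters)$r_overlap)
}
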