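# f-measure scoring of predicted clusters against a gold-standard complex
# catalog, plus the descriptive summaries used to compare cluster sets
# before and after refinement.

#' f-measure between a cluster and a complex
#'
#' Recall is the fraction of the complex recovered (`|c ∩ p| / |p|`),
#' precision the fraction of the cluster that is genuine (`|c ∩ p| / |c|`),
#' and f their harmonic mean — size-unbiased, 1 exactly when the two sets
#' coincide, 0 when they are disjoint.
#'
#' @param cluster non-empty character vector of cluster members.
#' @param complex non-empty character vector of complex members.
#' @return list with `recall`, `precision`, `f`.
#' @export
f_score <- function(cluster, complex) {
  cluster <- unique(as.character(cluster))
  complex <- unique(as.character(complex))
  if (length(cluster) == 0L || length(complex) == 0L) {
    stop("both sets must be non-empty", call. = FALSE)
  }
  common <- length(intersect(cluster, complex))
  recall <- common / length(complex)
  precision <- common / length(cluster)
  f <- if (recall + precision > 0) {
    2 * recall * precision / (recall + precision)
  } else 0
  list(recall = recall, precision = precision, f = f)
}

#' Best-matching complex for a cluster
#'
#' Scans the catalog for the complex with the highest f-score against the
#' cluster; ties are broken by catalog order (first wins). A cluster
#' intersecting no complex gets f = 0 and no matched complex.
#'
#' @param cluster non-empty character vector of cluster members.
#' @param catalog a non-empty [complex_catalog].
#' @return one-row data frame: `complex_name` (`NA` if no overlap with any
#'   complex), `recall`, `precision`, `f`.
#' @export
best_match <- function(cluster, catalog) {
  stopifnot(inherits(catalog, "complex_catalog"))
  if (length(catalog) == 0L) stop("empty catalog", call. = FALSE)
  best <- list(recall = 0, precision = 0, f = 0)
  best_name <- NA_character_
  for (k in seq_along(catalog)) {
    sc <- f_score(cluster, catalog[[k]])
    if (sc$f > best$f) {
      best <- sc
      best_name <- names(catalog)[k]
    }
  }
  data.frame(complex_name = best_name, recall = best$recall,
             precision = best$precision, f = best$f,
             stringsAsFactors = FALSE)
}

#' Best-match f-scores of every cluster in a set
#'
#' @param clusters a [cluster_set].
#' @param catalog a [complex_catalog].
#' @return data frame with one row per cluster: `label`, `size`,
#'   `complex_name`, `recall`, `precision`, `f`.
#' @export
score_clusters <- function(clusters, catalog) {
  stopifnot(inherits(clusters, "cluster_set"))
  rows <- lapply(seq_along(clusters), function(i) {
    cbind(data.frame(label = names(clusters)[i], size = length(clusters[[i]]),
                     stringsAsFactors = FALSE),
          best_match(clusters[[i]], catalog))
  })
  do.call(rbind, rows)
}

#' Average best-match f-score with a five-number summary
#'
#' The accuracy measure for a whole cluster set: the mean best-match
#' f-score over *all* clusters (passthroughs and singletons included unless
#' filtered with `min_size`), together with the five-number summary used in
#' before/after box-plot comparisons.
#'
#' @param clusters a non-empty [cluster_set].
#' @param catalog a non-empty [complex_catalog].
#' @param min_size drop clusters smaller than this before scoring
#'   (default 1 = keep everything).
#' @param qtype quantile convention passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return list with `mean_f`, `min`, `q1`, `median`, `q3`, `max`, `n`, and
#'   the per-cluster `scores` data frame.
#' @export
average_f <- function(clusters, catalog, min_size = 1L, qtype = 7) {
  stopifnot(inherits(clusters, "cluster_set"))
  keep <- lengths(clusters) >= min_size
  if (!any(keep)) stop("no clusters left after size filtering", call. = FALSE)
  scores <- score_clusters(clusters[keep], catalog)
  q <- stats::quantile(scores$f, probs = c(0, 0.25, 0.5, 0.75, 1),
                       type = qtype, names = FALSE)
  list(mean_f = mean(scores$f), min = q[1], q1 = q[2], median = q[3],
       q3 = q[4], max = q[5], n = nrow(scores), scores = scores)
}

#' Protein occurrence distribution across clusters
#'
#' Counts, for each multiplicity k, how many distinct proteins appear in
#' exactly k clusters of the set — the histogram used to characterise how
#' strongly a clustering overlaps.
#'
#' @param clusters a non-empty [cluster_set].
#' @return data frame with columns `occurrences` (k) and `n_proteins`; the
#'   identity `sum(k * n_proteins) == sum(cluster sizes)` always holds.
#' @export
occurrence_distribution <- function(clusters) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (length(clusters) == 0L) stop("empty cluster set", call. = FALSE)
  occ <- table(unlist(lapply(clusters, unique)))
  tab <- table(as.integer(occ))
  data.frame(occurrences = as.integer(names(tab)),
             n_proteins = as.integer(tab))
}
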