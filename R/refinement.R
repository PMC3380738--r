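# Consensus-threshold refinement of overlapping clusters.
#
# Strongly overlapping clusters often describe the same underlying protein
# complex. The refinement pass walks the input collection once; each
# cluster whose overlap coverage and consistency clear the minCov/minCons
# gates is merged with all of its overlap partners, and a per-vertex
# consensus counter (how many of the merged clusters contain the vertex)
# is thresholded at count * minCss. minCss = 1 keeps only vertices common
# to all merged clusters (the intersection); minCss = 0 keeps the union;
# intermediate values interpolate between the two.

#' Refine a cluster set by merging its overlaps
#'
#' One pass of consensus-threshold overlap refinement. For each cluster `g`
#' of the input, in order:
#'
#' * if `Cov(g) < min_cov` or `Cons(g) < min_cons` (both computed on the
#'   *original* input set), `g` is passed through unchanged;
#' * otherwise `g` is merged with every cluster it overlaps (partners found
#'   against the original `g`, not re-grown as the merge proceeds); each
#'   vertex of the merged set carries a consensus counter — the number of
#'   merged clusters containing it — and vertices with counter strictly
#'   below `count * min_css`, where `count` is the number of clusters
#'   merged, are removed;
#' * the result enters the output unless a member-identical cluster is
#'   already there (redundancy check; subset containment is *not* treated
#'   as redundant).
#'
#' Every input cluster takes its own turn as a seed, including
#' ones already absorbed as partners; the redundancy check deduplicates
#' identical outcomes.
#'
#' @param clusters a non-empty [cluster_set] of preliminary clusters.
#' @param min_cov minimum overlap coverage for a cluster to be refined, in
#'   \[0, 1\]. Below it the cluster passes through unchanged.
#' @param min_cons minimum overlapping consistency, in \[0, 1\]; same role.
#' @param min_css minimum consensus fraction in \[0, 1\]: a vertex survives
#'   the merge if it appears in at least `min_css` of the merged clusters.
#'   1 = intersection, 0 = union.
#' @return an object of class `overlap_refinement` with components
#'   `refined` (a [cluster_set]), `audit` (one data-frame row per input
#'   cluster: `label`, `action` in `passthrough`/`merged`/
#'   `dropped-redundant`/`dropped-empty`, `n_partners`, `size_before`,
#'   `size_after`), `seed_results` (each input cluster's post-merge,
#'   post-filter member set, before the redundancy check) and `params`. A
#'   `dropped-empty` row arises only when a
#'   high consensus threshold empties the merge, which is possible once
#'   three or more clusters overlap pairwise without a common member.
#' @examples
#' cs <- cluster_set(list(c("A", "B", "C"), c("B", "C", "D")))
#' refine_overlaps(cs, min_css = 1)$refined  # the intersection {B, C}
#' refine_overlaps(cs, min_css = 0)$refined  # the union {A, B, C, D}
#' @export
refine_overlaps <- function(clusters, min_cov = 0, min_cons = 0,
                            min_css = 0.5) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (length(clusters) == 0L) stop("empty cluster set", call. = FALSE)
  for (p in c(min_cov = min_cov, min_cons = min_cons, min_css = min_css)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      stop("refinement thresholds must be single numbers in [0, 1]",
           call. = FALSE)
    }
  }
  prof <- overlap_profiles(clusters)
  refined <- list()
  refined_labs <- character(0)
  seen_keys <- character(0)
  audit <- vector("list", length(clusters))
  seed_results <- vector("list", length(clusters))
  for (i in seq_along(clusters)) {
    gmem <- clusters[[i]]
    lab <- names(clusters)[i]
    if (prof$coverage[i] < min_cov || prof$consistency[i] < min_cons) {
      action <- "passthrough"
      partners <- integer(0)
      result <- gmem
    } else {
      # overlap partners found against the original g, frozen before merging
      partners <- refine_partner_positions(clusters, i)
      counter <- stats::setNames(rep(1L, length(gmem)), gmem)
      count <- 1L
      merged <- gmem
      for (j in partners) {
        pm <- clusters[[j]]
        new <- setdiff(pm, names(counter))
        counter[new] <- 0L
        counter[pm] <- counter[pm] + 1L
        merged <- union(merged, pm)
        count <- count + 1L
      }
      # strict "<": vertices exactly at the consensus threshold survive
      result <- sort(merged[counter[merged] >= count * min_css -
                              sqrt(.Machine$double.eps)])
      action <- "merged"
    }
    seed_results[[i]] <- result
    key <- paste(result, collapse = "\r")
    if (length(result) == 0L) {
      # a high consensus threshold can empty the merge (the common
      # intersection of 3+ pairwise-overlapping clusters may be empty);
      # an empty cluster is not representable and is discarded
      action <- "dropped-empty"
    } else if (key %in% seen_keys) {
      action <- "dropped-redundant"
    } else {
      seen_keys <- c(seen_keys, key)
      refined[[length(refined) + 1L]] <- result
      refined_labs <- c(refined_labs, lab)
    }
    audit[[i]] <- data.frame(
      label = lab, action = action, n_partners = length(partners),
      size_before = length(gmem), size_after = length(result),
      stringsAsFactors = FALSE)
  }
  structure(list(refined = cluster_set(refined, refined_labs),
                 audit = do.call(rbind, audit),
                 seed_results = stats::setNames(seed_results, names(clusters)),
                 params = c(min_cov = min_cov, min_cons = min_cons,
                            min_css = min_css)),
            class = "overlap_refinement")
}

# positions of the clusters sharing at least one member with cluster i
refine_partner_positions <- function(clusters, i) {
  target <- clusters[[i]]
  js <- seq_along(clusters)[-i]
  js[vapply(js, function(j) length(intersect(clusters[[j]], target)) > 0L, NA)]
}

#' @export
print.overlap_refinement <- function(x, ...) {
  tab <- table(factor(x$audit$action,
                      levels = c("merged", "passthrough", "dropped-redundant",
                                 "dropped-empty")))
  cat(sprintf(
    "Overlap refinement (min_cov=%.2g, min_cons=%.2g, min_css=%.2g)\n",
    x$params["min_cov"], x$params["min_cons"], x$params["min_css"]))
  cat(sprintf("  %d clusters in -> %d out (%d merged, %d passthrough, %d redundant dropped, %d emptied)\n",
              nrow(x$audit), length(x$refined), tab[["merged"]],
              tab[["passthrough"]], tab[["dropped-redundant"]],
              tab[["dropped-empty"]]))
  invisible(x)
}

#' @export
summary.overlap_refinement <- function(object, ...) {
  print(object)
  cat("\nPer-cluster audit:\n")
  print(object$audit, row.names = FALSE)
  invisible(object$audit)
}

#' Two-stage refinement threshold selection
#'
#' The parameter-selection protocol for the refinement thresholds, driven
#' by mean best-match f-score against a gold-standard catalog. Stage 1
#' sweeps `min_css` with `min_cov` and `min_cons` tied over a coarse grid
#' and fixes `min_css` at its best value; stage 2 then sweeps `min_cov`
#' and `min_cons` independently over \[0, 1\] at that `min_css`. The
#' returned refinement uses the winning combination (ties resolved toward
#' the first grid point, so the outcome is deterministic).
#'
#' @param clusters a [cluster_set] of preliminary clusters.
#' @param catalog a [complex_catalog] used for scoring.
#' @param cov_cons stage-1 tied values of `min_cov` = `min_cons`.
#' @param css stage-1 grid of `min_css` values.
#' @param cov,cons stage-2 grids, swept independently.
#' @return list with `best` (named vector `min_cov`, `min_cons`,
#'   `min_css`), `mean_f` (the score at `best`), `refinement` (the full
#'   [refine_overlaps()] result at `best`), `refined` (its [cluster_set]),
#'   and the `stage1` / `stage2` sweep tables.
#' @export
select_refinement_params <- function(clusters, catalog,
                                     cov_cons = seq(0.1, 0.6, by = 0.1),
                                     css = seq(0, 1, by = 0.1),
                                     cov = seq(0, 1, by = 0.1),
                                     cons = seq(0, 1, by = 0.1)) {
  stage1 <- sweep_refinement(clusters, catalog, cov_cons = cov_cons,
                             css = css)
  css_best <- stage1$min_css[which.max(stage1$mean_f)]
  grid <- expand.grid(min_cov = cov, min_cons = cons,
                      KEEP.OUT.ATTRS = FALSE)
  grid$mean_f <- mapply(function(cv, cn) {
    average_f(refine_overlaps(clusters, cv, cn, css_best)$refined,
              catalog)$mean_f
  }, grid$min_cov, grid$min_cons)
  k <- which.max(grid$mean_f)
  best <- c(min_cov = grid$min_cov[k], min_cons = grid$min_cons[k],
            min_css = css_best)
  refinement <- refine_overlaps(clusters, grid$min_cov[k], grid$min_cons[k],
                                css_best)
  list(best = best, mean_f = grid$mean_f[k], refinement = refinement,
       refined = refinement$refined, stage1 = stage1, stage2 = grid)
}

#' Parameter sweep over refinement thresholds
#'
#' Runs [refine_overlaps()] over a grid of thresholds and reports, for each
#' setting, the number of refined clusters and (when a catalog is given)
#' the mean best-match f-score — the tables behind accuracy-vs-minCss
#' surface plots.
#'
#' @param clusters a [cluster_set].
#' @param catalog optional [complex_catalog] for f-measure scoring.
#' @param cov_cons values used for both `min_cov` and `min_cons` (the two
#'   gates are swept in lockstep).
#' @param css values of `min_css`.
#' @return data frame with columns `min_cov`, `min_cons`, `min_css`,
#'   `n_clusters` and, with a catalog, `mean_f`.
#' @export
sweep_refinement <- function(clusters, catalog = NULL,
                             cov_cons = seq(0.1, 0.6, by = 0.1),
                             css = seq(0, 1, by = 0.1)) {
  grid <- expand.grid(cov_cons = cov_cons, css = css,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    ref <- refine_overlaps(clusters, min_cov = grid$cov_cons[k],
                           min_cons = grid$cov_cons[k],
                           min_css = grid$css[k])
    row <- data.frame(min_cov = grid$cov_cons[k],
                      min_cons = grid$cov_cons[k],
                      min_css = grid$css[k],
                      n_clusters = length(ref$refined))
    if (!is.null(catalog)) {
      row$mean_f <- average_f(ref$refined, catalog)$mean_f
    }
    row
  })
  do.call(rbind, rows)
}
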