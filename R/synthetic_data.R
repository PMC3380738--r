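# Planted-complex benchmark generator.
#
# Emulates the shape of a curated yeast interactome plus complex catalog:
# a set of planted complexes (dense modules, some sharing members), a
# sprinkle of background proteins, and a "preliminary clustering" obtained
# by fragmenting and contaminating the true complexes — the overlap
# patterns that refinement is designed to repair. Everything is
# reproducible from one integer seed, so the full pipeline is testable
# without any database download.

#' Generate a planted-complex interaction network and its catalog
#'
#' Draws `n_complexes` complexes with sizes uniform in `size_range` over
#' disjoint fresh proteins; a `share_fraction` subset of complexes then
#' borrows 1-2 member proteins from another complex, creating genuine
#' membership overlap. Edges are placed independently with probability
#' `p_in` inside each complex and `p_out` between any other pair; proteins
#' left with no edge at all are absent from the network (an edge list
#' cannot represent isolated vertices). `n_background` proteins belong to
#' no complex and only pick up background edges.
#'
#' @param n_complexes number of planted complexes.
#' @param size_range integer pair, inclusive bounds on drawn complex sizes
#'   (minimum 3, so every noiseless complex contains a triangle).
#' @param share_fraction fraction of complexes in \[0, 1) that share
#'   borrowed proteins with another complex.
#' @param p_in within-complex edge probability in (0, 1]; must exceed
#'   `p_out`.
#' @param p_out background edge probability in \[0, 1).
#' @param n_background proteins in no complex.
#' @param seed integer seed; fixed seed means identical output.
#' @return list with `network` (an [igraph::graph]), `catalog` (a
#'   [complex_catalog]) and `universe` (all generated protein ids, whether
#'   or not they acquired edges).
#' @export
generate_planted <- function(n_complexes = 20, size_range = c(4, 10),
                             share_fraction = 0.3, p_in = 0.9,
                             p_out = 0.02, n_background = 20, seed = 1L) {
  if (length(size_range) != 2L || size_range[1] < 3L ||
      size_range[2] < size_range[1]) {
    stop("'size_range' must be an increasing pair with minimum >= 3",
         call. = FALSE)
  }
  if (!(p_in > 0 && p_in <= 1)) stop("'p_in' must be in (0, 1]", call. = FALSE)
  if (!(p_out >= 0 && p_out < 1)) stop("'p_out' must be in [0, 1)", call. = FALSE)
  if (p_in <= p_out) stop("'p_in' must exceed 'p_out'", call. = FALSE)
  if (share_fraction < 0 || share_fraction >= 1) {
    stop("'share_fraction' must be in [0, 1)", call. = FALSE)
  }
  if (n_complexes < 1L) stop("need at least one complex", call. = FALSE)
  rng <- local_rng(seed)
  rng$eval({
    sizes <- sample(seq(size_range[1], size_range[2]), n_complexes,
                    replace = TRUE)
    ids <- sprintf("P%04d", seq_len(sum(sizes) + n_background))
    stops <- cumsum(sizes)
    complexes <- lapply(seq_len(n_complexes), function(k) {
      ids[(stops[k] - sizes[k] + 1L):stops[k]]
    })
    background <- if (n_background > 0L) ids[(stops[n_complexes] + 1L):length(ids)]
                  else character(0)
    # membership sharing: selected complexes absorb 1-2 proteins of another
    n_share <- round(share_fraction * n_complexes)
    if (n_share > 0L && n_complexes > 1L) {
      takers <- sample(seq_len(n_complexes), n_share)
      for (k in takers) {
        donor <- sample(setdiff(seq_len(n_complexes), k), 1L)
        n_borrow <- min(sample(1:2, 1L), length(complexes[[donor]]))
        borrowed <- sample(complexes[[donor]], n_borrow)
        complexes[[k]] <- sort(union(complexes[[k]], borrowed))
      }
    }
    # within-complex edges at p_in
    edges <- list()
    for (m in complexes) {
      pr <- t(utils::combn(m, 2L))
      keep <- stats::runif(nrow(pr)) < p_in
      edges[[length(edges) + 1L]] <- pr[keep, , drop = FALSE]
    }
    # background edges at p_out over every pair not inside a common complex
    if (p_out > 0 && length(ids) > 1L) {
      in_common <- new.env(hash = TRUE)
      for (m in complexes) {
        pr <- t(utils::combn(m, 2L))
        for (r in seq_len(nrow(pr))) {
          assign(paste(sort(pr[r, ]), collapse = "\r"), TRUE, envir = in_common)
        }
      }
      allpr <- t(utils::combn(ids, 2L))
      keys <- paste(pmin(allpr[, 1], allpr[, 2]),
                    pmax(allpr[, 1], allpr[, 2]), sep = "\r")
      outside <- !vapply(keys, exists, NA, envir = in_common, inherits = FALSE)
      cand <- allpr[outside, , drop = FALSE]
      keep <- stats::runif(nrow(cand)) < p_out
      edges[[length(edges) + 1L]] <- cand[keep, , drop = FALSE]
    }
    pairs <- do.call(rbind, edges)
    if (is.null(pairs) || nrow(pairs) == 0L) {
      stop("generated network has no edges; raise p_in or sizes", call. = FALSE)
    }
    list(network = interaction_network(pairs),
         catalog = complex_catalog(complexes,
                                   sprintf("cpx-%03d", seq_len(n_complexes))),
         universe = ids)
  })
}

#' Degrade a catalog into a fragmented preliminary clustering
#'
#' Emulates the output of an imperfect clusterer run on the network behind
#' a catalog: each complex is either emitted whole or, with probability
#' `split_prob`, broken into 2-3 overlapping fragments that all retain a
#' common core of half the complex (rounded up) and split the remaining
#' members among themselves — the pattern where one complex surfaces as
#' several partial, mutually overlapping clusters. Each emitted cluster
#' then gains up to `noise_per_cluster` extraneous proteins drawn from
#' `universe`; no identifiers outside `universe` are ever invented.
#'
#' @param catalog a [complex_catalog].
#' @param split_prob probability in \[0, 1\] that a complex is fragmented.
#' @param noise_per_cluster maximum number of extraneous proteins added to
#'   each emitted cluster (the actual number is drawn uniformly from
#'   `0:noise_per_cluster`).
#' @param seed integer seed.
#' @param universe character vector of allowed protein ids; defaults to the
#'   union of catalog members.
#' @return a [cluster_set]; labels record the source complex and fragment
#'   number.
#' @export
degrade_catalog <- function(catalog, split_prob = 0.6, noise_per_cluster = 1L,
                            seed = 1L, universe = NULL) {
  stopifnot(inherits(catalog, "complex_catalog"))
  if (split_prob < 0 || split_prob > 1) {
    stop("'split_prob' must be in [0, 1]", call. = FALSE)
  }
  if (is.null(universe)) universe <- sort(unique(unlist(catalog)))
  universe <- as.character(universe)
  rng <- local_rng(seed)
  rng$eval({
    out <- list()
    labs <- character(0)
    for (k in seq_along(catalog)) {
      m <- catalog[[k]]
      frags <- if (stats::runif(1) < split_prob && length(m) >= 2L) {
        split_complex(m)
      } else {
        list(m)
      }
      for (fi in seq_along(frags)) {
        fm <- frags[[fi]]
        if (noise_per_cluster > 0L) {
          pool <- setdiff(universe, fm)
          n_noise <- min(sample.int(noise_per_cluster + 1L, 1L) - 1L,
                         length(pool))
          if (n_noise > 0L) fm <- c(fm, sample(pool, n_noise))
        }
        out[[length(out) + 1L]] <- fm
        labs <- c(labs, sprintf("%s/frag-%d", names(catalog)[k], fi))
      }
    }
    cluster_set(out, labs)
  })
}

# 2-3 overlapping fragments: common core of ceil(half), remainder split
split_complex <- function(m) {
  m <- sample(m)  # randomise which members form the core
  core_n <- ceiling(length(m) / 2)
  core <- m[seq_len(core_n)]
  rest <- m[-seq_len(core_n)]
  k <- min(sample(2:3, 1L), max(2L, length(rest)))
  if (length(rest) == 0L) {
    return(list(core, core))
  }
  part <- sort(rep_len(seq_len(k), length(rest)))
  lapply(seq_len(k), function(i) c(core, rest[part == i]))
}
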