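# Independent brute-force oracles, coded directly from the definitions and
# kept free of the package's internals: the package is exercised through
# its exported API only, and results are compared against these.

# --- adjacency-matrix entropy oracle ----------------------------------------

oracle_adjmat <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g)) > 0
}

oracle_entropy <- function(adj, members) {
  h <- 0
  for (v in rownames(adj)) {
    nb <- colnames(adj)[adj[v, ]]
    if (length(nb) == 0L) next
    p <- sum(nb %in% members) / length(nb)
    if (p > 0 && p < 1) h <- h - p * log2(p) - (1 - p) * log2(1 - p)
  }
  h
}

oracle_local_min <- function(adj, members, protect = character(0)) {
  h <- oracle_entropy(adj, members)
  for (v in setdiff(members, protect)) {
    if (oracle_entropy(adj, setdiff(members, v)) < h - 1e-12) return(FALSE)
  }
  outside <- setdiff(rownames(adj), members)
  boundary <- outside[vapply(outside,
                             function(v) any(adj[v, members]), NA)]
  for (v in boundary) {
    if (oracle_entropy(adj, c(members, v)) < h - 1e-12) return(FALSE)
  }
  TRUE
}

# --- exhaustive triangle oracle ---------------------------------------------

oracle_triangles <- function(g) {
  adj <- oracle_adjmat(g)
  vs <- sort(rownames(adj))
  if (length(vs) < 3L) return(list())
  out <- list()
  trip <- utils::combn(vs, 3L)
  for (k in seq_len(ncol(trip))) {
    t3 <- trip[, k]
    if (adj[t3[1], t3[2]] && adj[t3[1], t3[3]] && adj[t3[2], t3[3]]) {
      out[[length(out) + 1L]] <- t3
    }
  }
  out
}

# --- replay oracle for the triangle-seeded clusterer ------------------------
# re-states the procedure from scratch: lexicographic triangle seeds,
# add-all-boundary rounds, greedy lexicographic removal among the vertices
# just added (strict decrease, repeated passes), stop when a round's
# additions are all removed, skip triangles contained in an earlier output

oracle_triangle_clustering <- function(g) {
  adj <- oracle_adjmat(g)
  tris <- oracle_triangles(g)
  out <- list()
  for (tri in tris) {
    if (any(vapply(out, function(m) all(tri %in% m), NA))) next
    members <- tri
    repeat {
      outside <- setdiff(rownames(adj), members)
      added <- sort(outside[vapply(outside,
                                   function(v) any(adj[v, members]), NA)])
      if (length(added) == 0L) break
      members <- c(members, added)
      repeat {
        changed <- FALSE
        for (v in sort(intersect(members, added))) {
          if (oracle_entropy(adj, setdiff(members, v)) <
              oracle_entropy(adj, members) - 1e-12) {
            members <- setdiff(members, v)
            changed <- TRUE
          }
        }
        if (!changed) break
      }
      if (length(intersect(members, added)) == 0L) break
    }
    out[[length(out) + 1L]] <- sort(members)
  }
  out
}

# --- overlap-metric oracles (definition-level loops) ------------------------

oracle_overlaps <- function(clusters, i) {
  out <- list()
  for (j in seq_along(clusters)) {
    if (j == i) next
    o <- intersect(clusters[[i]], clusters[[j]])
    if (length(o) > 0L) out[[length(out) + 1L]] <- o
  }
  out
}

oracle_profile <- function(clusters, i) {
  ov <- oracle_overlaps(clusters, i)
  n_v <- length(clusters[[i]])
  if (length(ov) == 0L) {
    return(c(s = 0, r = 0, cov = 0, cons = 0))
  }
  s <- sum(vapply(ov, length, 0L)) / length(ov)
  r <- s / n_v
  cov <- length(unique(unlist(ov))) / n_v
  c(s = s, r = r, cov = cov, cons = r / cov)
}

oracle_avg_rate <- function(clusters) {
  mean(vapply(seq_along(clusters),
              function(i) oracle_profile(clusters, i)[["r"]], 0))
}

# --- refinement oracle: line-by-line transliteration ------------------------

oracle_refine <- function(clusters, min_cov, min_cons, min_css) {
  s_prime <- list()
  for (i in seq_along(clusters)) {
    g <- clusters[[i]]
    prof <- oracle_profile(clusters, i)
    if (prof[["cov"]] < min_cov || prof[["cons"]] < min_cons) {
      result <- sort(g)
    } else {
      value <- integer(0)
      for (v in g) value[v] <- 1L
      count <- 1L
      for (j in seq_along(clusters)) {
        if (j == i || length(intersect(clusters[[j]], clusters[[i]])) == 0L) next
        for (v in clusters[[j]]) {
          value[v] <- if (is.na(value[v])) 1L else value[v] + 1L
        }
        g <- union(g, clusters[[j]])
        count <- count + 1L
      }
      result <- sort(g[value[g] >= count * min_css - 1e-9])
    }
    if (length(result) > 0L &&
        !any(vapply(s_prime, identical, NA, y = result))) {
      s_prime[[length(s_prime) + 1L]] <- result
    }
  }
  s_prime
}

# --- evaluation oracles ------------------------------------------------------

oracle_f <- function(a, b) {
  common <- length(intersect(a, b))
  if (common == 0L) return(0)
  r <- common / length(b)
  p <- common / length(a)
  2 * r * p / (r + p)
}

oracle_mean_best_f <- function(clusters, complexes) {
  mean(vapply(clusters, function(cl) {
    max(vapply(complexes, function(px) oracle_f(cl, px), 0))
  }, 0))
}

# --- random instance generators ---------------------------------------------

random_cluster_list <- function(max_clusters = 6, max_proteins = 12) {
  universe <- sprintf("p%02d", seq_len(sample(4:max_proteins, 1L)))
  n <- sample(2:max_clusters, 1L)
  lapply(seq_len(n), function(i) {
    sort(sample(universe, sample(seq_len(min(5L, length(universe))), 1L)))
  })
}

random_graph_edges <- function(max_n = 8, p = 0.4) {
  n <- sample(3:max_n, 1L)
  vs <- sprintf("v%d", seq_len(n))
  pairs <- t(utils::combn(vs, 2L))
  el <- pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
  # edge lists cannot carry isolated vertices: attach leftovers somewhere
  for (v in setdiff(vs, unique(as.vector(el)))) {
    el <- rbind(el, c(v, sample(setdiff(vs, v), 1L)))
  }
  el
}
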