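edge_key <- function(g) {
  e <- igraph::as_edgelist(g)
  sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
}

test_that("generation is deterministic under a fixed seed", {
  a <- generate_planted(n_complexes = 6, seed = 99)
  b <- generate_planted(n_complexes = 6, seed = 99)
  expect_identical(edge_key(a$network), edge_key(b$network))
  expect_identical(unclass(a$catalog), unclass(b$catalog))
  expect_identical(a$universe, b$universe)

  d1 <- degrade_catalog(a$catalog, 0.7, 2L, seed = 5, universe = a$universe)
  d2 <- degrade_catalog(b$catalog, 0.7, 2L, seed = 5, universe = b$universe)
  expect_identical(unclass(d1), unclass(d2))
})

test_that("noiseless disjoint limit: cliques, and clustering recovers them perfectly", {
  gen <- generate_planted(n_complexes = 5, size_range = c(4, 6),
                          share_fraction = 0, p_in = 1, p_out = 0,
                          n_background = 0, seed = 7)
  cs <- cluster_entropy_triangle(gen$network)
  res <- average_f(cs, gen$catalog)
  expect_equal(res$mean_f, 1)
  expect_equal(res$n, length(gen$catalog))
})

test_that("with no background edges every planted complex is a maximal clique", {
  for (s in 1:5) {
    gen <- generate_planted(n_complexes = 6, size_range = c(4, 8),
                            share_fraction = 0.5, p_in = 1, p_out = 0,
                            n_background = 0, seed = s)
    expect_lte(length(gen$universe), 60)
    mc <- lapply(igraph::max_cliques(gen$network, min = 2),
                 function(v) sort(igraph::V(gen$network)$name[as.integer(v)]))
    keys <- vapply(mc, paste, "", collapse = "|")
    for (m in gen$catalog) {
      expect_true(paste(sort(m), collapse = "|") %in% keys)
    }
  }
})

test_that("edge probabilities are honoured empirically", {
  gen <- generate_planted(n_complexes = 12, size_range = c(8, 12),
                          share_fraction = 0, p_in = 0.8, p_out = 0.05,
                          n_background = 40, seed = 21)
  g <- gen$network
  adj <- oracle_adjmat(g)
  inside <- 0; inside_n <- 0
  pair_in_complex <- new.env(hash = TRUE)
  for (m in gen$catalog) {
    pr <- t(utils::combn(m, 2))
    for (k in seq_len(nrow(pr))) {
      key <- paste(sort(pr[k, ]), collapse = "|")
      if (!exists(key, pair_in_complex, inherits = FALSE)) {
        assign(key, TRUE, pair_in_complex)
        inside_n <- inside_n + 1
        both <- pr[k, 1] %in% rownames(adj) && pr[k, 2] %in% rownames(adj)
        inside <- inside + (both && adj[pr[k, 1], pr[k, 2]])
      }
    }
  }
  expect_lt(abs(inside / inside_n - 0.8), 0.05)

  allpr <- t(utils::combn(gen$universe, 2))
  keys <- paste(pmin(allpr[, 1], allpr[, 2]), pmax(allpr[, 1], allpr[, 2]),
                sep = "|")
  bg <- allpr[!vapply(keys, exists, NA, envir = pair_in_complex,
                      inherits = FALSE), , drop = FALSE]
  hit <- vapply(seq_len(nrow(bg)), function(k) {
    bg[k, 1] %in% rownames(adj) && bg[k, 2] %in% rownames(adj) &&
      adj[bg[k, 1], bg[k, 2]]
  }, NA)
  expect_lt(abs(mean(hit) - 0.05), 0.015)
})

test_that("degradation identity limit returns the catalog itself", {
  gen <- generate_planted(n_complexes = 5, seed = 3)
  deg <- degrade_catalog(gen$catalog, split_prob = 0, noise_per_cluster = 0L,
                         seed = 4)
  expect_equal(lapply(unclass(deg), identity), lapply(unclass(gen$catalog), identity),
               ignore_attr = TRUE)
})

test_that("forced fragmentation yields overlapping fragments covering the complex", {
  cat1 <- complex_catalog(list(sprintf("q%d", 1:8)), "only")
  for (s in 1:20) {
    deg <- degrade_catalog(cat1, split_prob = 1, noise_per_cluster = 0L,
                           seed = s)
    expect_gte(length(deg), 2)
    expect_setequal(sort(unique(unlist(deg))), sprintf("q%d", 1:8))
    pairs <- utils::combn(seq_along(deg), 2)
    for (k in seq_len(ncol(pairs))) {
      expect_gt(length(intersect(deg[[pairs[1, k]]], deg[[pairs[2, k]]])), 0)
    }
    # the common core spans at least half the complex
    expect_gte(length(Reduce(intersect, unclass(deg))), 4)
  }
})

test_that("degradation never invents identifiers outside the universe", {
  gen <- generate_planted(n_complexes = 8, seed = 11)
  for (s in 1:10) {
    deg <- degrade_catalog(gen$catalog, 0.8, 3L, seed = s,
                           universe = gen$universe)
    expect_true(all(unlist(deg) %in% gen$universe))
  }
})

test_that("generator rejects inconsistent parameters", {
  expect_error(generate_planted(size_range = c(2, 5)), "size_range")
  expect_error(generate_planted(p_in = 0.1, p_out = 0.5), "exceed")
  expect_error(generate_planted(share_fraction = 1), "share_fraction")
  expect_error(generate_planted(p_out = 1), "p_out")
})
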