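prp19 <- function() {
  read_cluster_file(system.file("extdata", "prp19_clusters.txt",
                                package = "overclust", mustWork = TRUE))
}

refined_sets <- function(ref) lapply(unclass(ref$refined), identity)

test_that("worked example: the three overlapping clusters collapse to their core", {
  ref <- refine_overlaps(prp19(), min_cov = 0, min_cons = 0, min_css = 0.7)
  expect_length(ref$refined, 1)
  expect_setequal(ref$refined[[1]],
                  c("YLL036C", "YDR416W", "YGR129W", "YLR117C"))
  expect_equal(sum(ref$audit$action == "dropped-redundant"), 2)
})

test_that("consensus limits: min_css 1 gives the intersection, 0 the union", {
  s3 <- read_cluster_file(system.file("extdata", "set3p_clusters.txt",
                                      package = "overclust", mustWork = TRUE))
  inter <- refine_overlaps(s3, min_css = 1)$refined
  expect_length(inter, 1)
  expect_setequal(inter[[1]], c("YGL194C", "YKR029C"))

  uni <- refine_overlaps(s3, min_css = 0)$refined
  expect_length(uni, 1)
  expect_setequal(uni[[1]], sort(unique(unlist(s3))))
})

test_that("low coverage or consistency means passthrough, members untouched", {
  # coverage of first cluster is 0.3 < gate 0.5
  cs <- cluster_set(list(sprintf("m%02d", 1:10),
                         c("m01", "m02", "m03", "x1", "x2")))
  ref <- refine_overlaps(cs, min_cov = 0.5, min_cons = 0, min_css = 0.5)
  expect_equal(ref$audit$action[1], "passthrough")
  expect_identical(ref$refined[[1]], cs[[1]])
})

test_that("parameters and input are validated", {
  cs <- cluster_set(list(c("A", "B")))
  expect_error(refine_overlaps(cs, min_css = 1.5), "\\[0, 1\\]")
  expect_error(refine_overlaps(cs, min_cov = -0.1), "\\[0, 1\\]")
  expect_error(refine_overlaps(cluster_set(list()), min_css = 0.5), "empty")
})

test_that("a cluster with no overlap partners survives every setting", {
  cs <- cluster_set(list(c("A", "B"), c("B", "C"), c("x1", "x2", "x3")))
  for (css in c(0, 0.3, 0.7, 1)) {
    ref <- refine_overlaps(cs, min_css = css)
    expect_true(any(vapply(refined_sets(ref),
                           identical, NA, y = c("x1", "x2", "x3"))))
  }
})

test_that("limit behaviour holds on random sets: union at 0, intersection at 1", {
  set.seed(83)
  for (rep in 1:100) {
    cl <- random_cluster_list()
    cs <- cluster_set(cl)
    ref0 <- refine_overlaps(cs, 0, 0, 0)
    ref1 <- refine_overlaps(cs, 0, 0, 1)
    for (i in seq_along(cl)) {
      js <- which(vapply(seq_along(cl), function(j) {
        j != i && length(intersect(cl[[j]], cl[[i]])) > 0
      }, NA))
      group <- c(list(cl[[i]]), cl[js])
      # per-seed expected outcomes
      expect_true(any(vapply(refined_sets(ref0), identical, NA,
                             y = sort(Reduce(union, group)))))
      inter <- sort(Reduce(intersect, group))
      if (length(inter) > 0) {
        expect_true(any(vapply(refined_sets(ref1), identical, NA, y = inter)))
      }
    }
  }
})

test_that("per-seed output shrinks monotonically as min_css rises", {
  set.seed(89)
  for (rep in 1:50) {
    cl <- random_cluster_list()
    cs <- cluster_set(cl)
    css_grid <- c(0, 0.25, 0.5, 0.75, 1)
    # follow each seed's own merge outcome through increasing css
    per_seed <- lapply(css_grid, function(css) {
      refine_overlaps(cs, 0, 0, css)$seed_results
    })
    for (i in seq_along(cl)) {
      for (k in seq_along(css_grid)[-1]) {
        expect_true(all(per_seed[[k]][[i]] %in% per_seed[[k - 1]][[i]]))
      }
    }
  }
})

test_that("refined sets contain no duplicate member sets", {
  set.seed(97)
  for (rep in 1:100) {
    cs <- cluster_set(random_cluster_list())
    for (css in c(0, 0.5, 1)) {
      sets <- refined_sets(refine_overlaps(cs, 0, 0, css))
      keys <- vapply(sets, paste, "", collapse = "|")
      expect_false(anyDuplicated(keys) > 0)
    }
  }
})

test_that("raising the gates never decreases the passthrough count", {
  set.seed(101)
  for (rep in 1:50) {
    cs <- cluster_set(random_cluster_list())
    counts <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(gate) {
      sum(refine_overlaps(cs, gate, gate, 0.5)$audit$action == "passthrough")
    }, 0)
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("refinement agrees with the pseudocode transliteration oracle", {
  set.seed(103)
  for (rep in 1:300) {
    cl <- random_cluster_list(max_clusters = 8, max_proteins = 15)
    cs <- cluster_set(cl)
    params <- c(sample(c(0, 0.25, 0.5, 0.75, 1), 2, TRUE),
                sample(seq(0, 1, 0.1), 1))
    got <- refined_sets(refine_overlaps(cs, params[1], params[2], params[3]))
    want <- oracle_refine(cl, params[1], params[2], params[3])
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("every source cluster maps to exactly one audit record", {
  set.seed(107)
  for (rep in 1:20) {
    cs <- cluster_set(random_cluster_list())
    ref <- refine_overlaps(cs, 0.2, 0.2, 0.6)
    expect_equal(ref$audit$label, names(cs))
    expect_true(all(ref$audit$action %in%
                      c("passthrough", "merged", "dropped-redundant",
                        "dropped-empty")))
  }
})
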