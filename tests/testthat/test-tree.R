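test_that("two classes give a single split with two leaves", {
  ds <- two_class_dataset()
  tree <- build_tree(ds)
  expect_s3_class(tree, "dtsvm_tree")
  root <- tree$nodes[[tree$root]]
  expect_false(root$leaf)
  expect_true(tree$nodes[[root$left]]$leaf)
  expect_true(tree$nodes[[root$right]]$leaf)
  expect_equal(tree_to_text(tree), "(A,B);")
})

test_that("the least separable pair merges first, the most separable splits the root", {
  # 1-D centers 5, 6 and 100: A and B are the hard pair, C is far away
  set.seed(11)
  x <- c(rnorm(30, 5), rnorm(30, 6), rnorm(30, 100))
  ds <- labeled_dataset(
    matrix(x, ncol = 1, dimnames = list(NULL, "mass")),
    rep(c("A", "B", "C"), each = 30)
  )
  tree <- build_tree(ds)
  expect_equal(tree$merges$left[1], "A")
  expect_equal(tree$merges$right[1], "B")
  root <- tree$nodes[[tree$root]]
  expect_setequal(
    list(tree$nodes[[root$left]]$labels, tree$nodes[[root$right]]$labels),
    list(c("A", "B"), "C")
  )
  # the root corresponds to the final, most separable merge
  expect_equal(root$merge_icsf, tree$merges$icsf[nrow(tree$merges)])
})

test_that("every recorded merge had the minimal separability among all pairs", {
  # exhaustive oracle over <= 5 classes: replay the merge sequence and
  # verify the argmin at every step by direct recomputation
  cohort <- centers_dataset(
    list(A = c(5, 5), B = c(7, 5), C = c(5, 11), D = c(20, 20), E = c(21, 20)),
    n = 20, seed = 13
  )
  tree <- build_tree(cohort, standardize = FALSE)
  partition <- as.list(sort(unique(cohort$labels)))
  for (step in seq_len(nrow(tree$merges))) {
    stats_by_group <- lapply(partition, function(g) {
      group_stats(cohort$features[cohort$labels %in% g, , drop = FALSE])
    })
    k <- length(partition)
    pair_vals <- c()
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        pair_vals <- c(pair_vals, icsf(stats_by_group[[i]], stats_by_group[[j]]))
      }
    }
    expect_equal(tree$merges$icsf[step], min(pair_vals), tolerance = 1e-12)
    ids <- vapply(partition, function(g) paste(sort(g), collapse = "+"), "")
    li <- match(tree$merges$left[step], ids)
    ri <- match(tree$merges$right[step], ids)
    expect_false(is.na(li) || is.na(ri))
    partition[[li]] <- sort(c(partition[[li]], partition[[ri]]))
    partition[ri] <- NULL
  }
  expect_equal(length(partition), 1)
})

test_that("a 23-species tree has 22 classifier nodes and a leaf per species", {
  cohort <- small_cohort(n_per_class = 40, seed = 5)
  tree <- build_tree(cohort)
  leaves <- names(tree$nodes)[vapply(tree$nodes, `[[`, TRUE, "leaf")]
  internal <- setdiff(names(tree$nodes), leaves)
  expect_equal(length(leaves), 23)
  expect_equal(length(internal), 22)
  expect_setequal(leaves, LETTERS[1:23])
  # children of every internal node are disjoint and union to the node set
  for (id in internal) {
    nd <- tree$nodes[[id]]
    l <- tree$nodes[[nd$left]]$labels
    r <- tree$nodes[[nd$right]]$labels
    expect_equal(length(intersect(l, r)), 0)
    expect_setequal(c(l, r), nd$labels)
  }
  # adding body length may change the topology but not the structure
  tree4 <- build_tree(small_cohort(canonical_features(), 40, seed = 5))
  expect_equal(sum(!vapply(tree4$nodes, `[[`, TRUE, "leaf")), 22)
})

test_that("tree construction is deterministic", {
  cohort <- small_cohort(n_per_class = 15, seed = 21)
  expect_identical(build_tree(cohort)$merges, build_tree(cohort)$merges)
})

test_that("degenerate inputs are refused", {
  ds <- two_class_dataset()
  only_a <- labeled_dataset(
    ds$features[ds$labels == "A", , drop = FALSE],
    ds$labels[ds$labels == "A"]
  )
  expect_error(build_tree(only_a), "at least 2 species")

  # two classes occupying identical single points are inseparable
  x <- matrix(c(1, 1, 1, 1), ncol = 1, dimnames = list(NULL, "mass"))
  twins <- labeled_dataset(x, c("A", "A", "B", "B"))
  expect_error(build_tree(twins, standardize = FALSE), "degenerate")
})

test_that("newick rendering round-trips the topology", {
  skip_if_not_installed("ape")
  cohort <- small_cohort(n_per_class = 25, seed = 17)
  tree <- build_tree(cohort)
  text <- tree_to_text(tree)
  # every species appears exactly once
  for (lab in LETTERS[1:23]) {
    expect_equal(lengths(regmatches(text, gregexpr(lab, text, fixed = TRUE))), 1)
  }
  phylo <- ape::read.tree(text = text)
  expect_setequal(phylo$tip.label, LETTERS[1:23])
  # clades of the parsed tree match the label sets of the internal nodes
  clades <- lapply(
    ape::prop.part(phylo),
    function(idx) sort(phylo$tip.label[idx])
  )
  node_sets <- lapply(
    Filter(function(nd) !nd$leaf, tree$nodes),
    function(nd) sort(nd$labels)
  )
  # prop.part omits nothing for a rooted binary tree except trivial tips
  expect_true(all(vapply(
    node_sets,
    function(s) any(vapply(clades, identical, TRUE, s)), TRUE
  )))
})

test_that("JSON serialization carries the full structure", {
  ds <- two_class_dataset()
  tree <- build_tree(ds)
  parsed <- jsonlite::fromJSON(tree_to_json(tree), simplifyVector = FALSE)
  expect_equal(parsed$root, "A+B")
  expect_equal(parsed$feature_names[[1]], "mass")
  ids <- vapply(parsed$nodes, `[[`, "", "id")
  expect_setequal(ids, c("A", "B", "A+B"))
})
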