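#' Build the separability-driven binary classification tree
#'
#' Converts the N-species problem into N-1 two-class problems arranged in
#' a binary tree. Construction is agglomerative: starting from one group
#' per species, the pair of groups with the *smallest* separability factor
#' (the hardest pair to tell apart) is merged, group statistics are
#' recomputed from the pooled samples, and merging repeats until one group
#' remains. Read top-down, the resulting tree places the final -- most
#' separable -- split at the root, so the easiest decisions are made
#' first and errors on hard pairs cannot contaminate the rest of the
#' cascade.
#'
#' Ties on the minimal separability are broken deterministically in favor
#' of the pair whose combined sorted label string sorts first.
#'
#' @param training_set A [labeled_dataset()] with >= 2 species, each with
#'   >= 2 samples.
#' @param standardize Fit z-score scaling on the training set and build
#'   the tree in standardized feature space (default TRUE). The scaling
#'   is stored in the tree and reused for prediction.
#' @return A `dtsvm_tree`: list with `nodes` (keyed by group id), `root`,
#'   `feature_names`, `scaling` (or NULL), and `merges`, the merge
#'   sequence as a data frame (`left`, `right`, `icsf`).
#' @export
#' @examples
#' stats <- load_species_stats()
#' cohort <- generate_cohort(stats, n_per_class = 50, seed = 1)
#' halves <- split_train_test(cohort, seed = 2)
#' tree <- build_tree(halves$train)
#' tree
build_tree <- function(training_set, standardize = TRUE) {
  stopifnot(inherits(training_set, "labeled_dataset"))
  labs <- sort(unique(training_set$labels))
  if (length(labs) < 2) {
    stop("tree construction needs at least 2 species", call. = FALSE)
  }
  counts <- table(training_set$labels)
  if (any(counts < 2)) {
    stop(
      "species with fewer than 2 training samples: ",
      paste(names(counts)[counts < 2], collapse = ", "),
      call. = FALSE
    )
  }
  scaling <- NULL
  ds <- training_set
  if (standardize) {
    std <- standardize(training_set)
    ds <- std$dataset
    scaling <- std$scaling
  }

  nodes <- stats::setNames(
    lapply(labs, function(l) {
      list(id = l, labels = l, leaf = TRUE)
    }),
    labs
  )
  groups <- as.list(labs)
  merges <- data.frame(
    left = character(0), right = character(0), icsf = numeric(0),
    stringsAsFactors = FALSE
  )

  while (length(groups) > 1) {
    gs <- lapply(groups, function(g) {
      group_stats(ds$features[ds$labels %in% g, , drop = FALSE])
    })
    k <- length(groups)
    best <- NULL
    best_val <- Inf
    best_key <- NULL
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        v <- icsf(gs[[i]], gs[[j]])
        key <- paste(sort(c(groups[[i]], groups[[j]])), collapse = "")
        if (v < best_val || (v == best_val && key < best_key)) {
          best <- c(i, j)
          best_val <- v
          best_key <- key
        }
      }
    }
    id_i <- group_id(groups[[best[1]]])
    id_j <- group_id(groups[[best[2]]])
    left <- min(id_i, id_j)
    right <- max(id_i, id_j)
    merged <- sort(c(groups[[best[1]]], groups[[best[2]]]))
    nodes[[group_id(merged)]] <- list(
      id = group_id(merged), labels = merged, leaf = FALSE,
      left = left, right = right, merge_icsf = best_val
    )
    merges <- rbind(merges, data.frame(
      left = left, right = right, icsf = best_val,
      stringsAsFactors = FALSE
    ))
    groups[[best[1]]] <- merged
    groups[best[2]] <- NULL
  }

  structure(
    list(
      nodes = nodes,
      root = group_id(labs),
      feature_names = training_set$feature_names,
      scaling = scaling,
      merges = merges
    ),
    class = "dtsvm_tree"
  )
}

n_internal_nodes <- function(tree) {
  sum(!vapply(tree$nodes, `[[`, TRUE, "leaf"))
}

tree_leaves <- function(tree) {
  names(tree$nodes)[vapply(tree$nodes, `[[`, TRUE, "leaf")]
}

#' Render a classification tree as a newick string
#'
#' One leaf per species; internal nodes optionally carry their merge
#' separability value as a node label. The string parses back (e.g. with
#' `ape::read.tree`) to the same topology.
#'
#' @param tree A `dtsvm_tree` or trained `dtsvm` model.
#' @param include_icsf Write merge separability values as internal node
#'   labels.
#' @return A single newick string, terminated by ";".
#' @export
#' @examples
#' ds <- labeled_dataset(
#'   matrix(c(0, 0.1, 5, 5.2), ncol = 1,
#'     dimnames = list(NULL, "mass")
#'   ),
#'   c("A", "A", "B", "B")
#' )
#' tree_to_text(build_tree(ds))
tree_to_text <- function(tree, include_icsf = FALSE) {
  if (inherits(tree, "dtsvm")) tree <- tree$tree
  stopifnot(inherits(tree, "dtsvm_tree"))
  render <- function(id) {
    nd <- tree$nodes[[id]]
    if (nd$leaf) {
      return(nd$labels)
    }
    lab <- if (include_icsf) format(nd$merge_icsf, digits = 6) else ""
    paste0("(", render(nd$left), ",", render(nd$right), ")", lab)
  }
  paste0(render(tree$root), ";")
}

#' Serialize a classification tree to JSON
#'
#' Structural information only (node ids, children, label sets, merge
#' separability values); trained SVM parameters are not included.
#'
#' @param tree A `dtsvm_tree` or trained `dtsvm` model.
#' @return A JSON string.
#' @export
tree_to_json <- function(tree) {
  if (inherits(tree, "dtsvm")) tree <- tree$tree
  stopifnot(inherits(tree, "dtsvm_tree"))
  nodes <- lapply(unname(tree$nodes), function(nd) {
    out <- list(
      id = nd$id,
      labels = as.list(nd$labels),
      leaf = nd$leaf
    )
    if (!nd$leaf) {
      out$left <- nd$left
      out$right <- nd$right
      out$merge_icsf <- nd$merge_icsf
    }
    out
  })
  jsonlite::toJSON(
    list(
      root = tree$root,
      feature_names = tree$feature_names,
      nodes = nodes
    ),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
}

#' @export
print.dtsvm_tree <- function(x, ...) {
  leaves <- tree_leaves(x)
  cat(
    "Separability-driven binary classification tree\n",
    " ", length(leaves), " species, ", n_internal_nodes(x),
    " binary classifier nodes\n",
    sep = ""
  )
  cat("  features:", paste(x$feature_names, collapse = ", "), "\n")
  cat(
    "  root split: {", x$nodes[[x$root]]$left, "} vs {",
    x$nodes[[x$root]]$right, "}  (separability ",
    format(x$nodes[[x$root]]$merge_icsf, digits = 4), ")\n",
    sep = ""
  )
  invisible(x)
}
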