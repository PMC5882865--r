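#' Train the SVM cascade of a classification tree
#'
#' Fits one two-class SVM per internal tree node. Each node's classifier
#' is trained on the training samples of the species in that node's label
#' set, relabeled by the side (left/right subtree) their species falls
#' on. Training is performed in the tree's standardized feature space.
#'
#' The radial-basis kernel is used throughout. The defaults
#' (`cost = 100`, `gamma = 2` on standardized features) were chosen by a
#' coarse grid sweep (see [tune_dtsvm()]) as the smallest values whose
#' test accuracy on full-size synthetic cohorts is indistinguishable from
#' the Bayes-optimal rates of the generating distribution; see the
#' package vignette. Inverse-frequency class weighting is available for
#' the strongly unbalanced (1-species-vs-many) nodes but is off by
#' default -- balanced cohorts gain nothing from it at the boundary.
#'
#' @param tree A `dtsvm_tree` from [build_tree()].
#' @param training_set The [labeled_dataset()] to train on (raw feature
#'   scale; the tree's stored scaling is applied internally).
#' @param cost SVM regularization parameter C.
#' @param gamma RBF kernel width; `NULL` uses `1 / n_features`.
#' @param class_weights Inverse-frequency sample weighting per node.
#' @return A trained `dtsvm` model.
#' @export
train_dtsvm <- function(tree, training_set, cost = 100, gamma = 2,
                        class_weights = FALSE) {
  stopifnot(
    inherits(tree, "dtsvm_tree"),
    inherits(training_set, "labeled_dataset")
  )
  if (!identical(tree$feature_names, training_set$feature_names)) {
    stop("training set features do not match the tree's feature set",
      call. = FALSE
    )
  }
  missing <- setdiff(tree_leaves(tree), unique(training_set$labels))
  if (length(missing) > 0) {
    stop(
      "species in the tree but absent from the training data: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  ds <- if (is.null(tree$scaling)) {
    training_set
  } else {
    apply_scaling(training_set, tree$scaling)
  }
  if (is.null(gamma)) {
    gamma <- 1 / length(tree$feature_names)
  }
  fits <- list()
  for (id in names(tree$nodes)) {
    nd <- tree$nodes[[id]]
    if (nd$leaf) next
    in_node <- ds$labels %in% nd$labels
    left_labels <- tree$nodes[[nd$left]]$labels
    side <- factor(
      ifelse(ds$labels[in_node] %in% left_labels, "left", "right"),
      levels = c("left", "right")
    )
    if (any(table(side) == 0)) {
      stop(
        "node ", id, " has training samples on only one side; ",
        "tree and training data do not match",
        call. = FALSE
      )
    }
    args <- list(
      x = ds$features[in_node, , drop = FALSE],
      y = side,
      kernel = "radial",
      cost = cost,
      gamma = gamma,
      scale = FALSE
    )
    if (class_weights) {
      w <- 1 / table(side)
      args$class.weights <- w / mean(w)
    }
    fits[[id]] <- do.call(e1071::svm, args)
  }
  structure(
    list(
      tree = tree,
      fits = fits,
      hyperparameters = list(
        kernel = "radial", cost = cost, gamma = gamma,
        class_weights = class_weights
      )
    ),
    class = "dtsvm"
  )
}

#' Predict species by cascading through the classifier tree
#'
#' Each sample enters at the root and is passed left or right by the
#' node's SVM until it reaches a leaf; the leaf's species is the
#' prediction. The tree's stored scaling is applied to the input first.
#'
#' @param object A trained `dtsvm` model.
#' @param newdata A [labeled_dataset()] or numeric matrix whose columns
#'   are the model's features.
#' @param ... Unused.
#' @return Character vector of predicted species labels, one per row.
#' @export
predict.dtsvm <- function(object, newdata, ...) {
  tree <- object$tree
  x <- if (inherits(newdata, "labeled_dataset")) {
    if (!identical(newdata$feature_names, tree$feature_names)) {
      stop("newdata features do not match the model's feature set",
        call. = FALSE
      )
    }
    newdata$features
  } else {
    newdata <- as.matrix(newdata)
    if (ncol(newdata) != length(tree$feature_names)) {
      stop(
        "newdata has ", ncol(newdata), " columns; model expects ",
        length(tree$feature_names),
        call. = FALSE
      )
    }
    colnames(newdata) <- tree$feature_names
    newdata
  }
  if (!is.null(tree$scaling)) {
    x <- apply_scaling(
      labeled_dataset(x, rep("x", nrow(x)), tree$feature_names),
      tree$scaling
    )$features
  }
  out <- character(nrow(x))
  route <- function(id, idx) {
    if (length(idx) == 0) {
      return(invisible())
    }
    nd <- tree$nodes[[id]]
    if (nd$leaf) {
      out[idx] <<- nd$labels
      return(invisible())
    }
    side <- predict(object$fits[[id]], x[idx, , drop = FALSE])
    route(nd$left, idx[side == "left"])
    route(nd$right, idx[side == "right"])
  }
  route(tree$root, seq_len(nrow(x)))
  out
}

#' @export
print.dtsvm <- function(x, ...) {
  cat("Trained decision-tree SVM\n")
  print(x$tree)
  hp <- x$hyperparameters
  cat(
    "  node SVMs: ", length(x$fits), " (", hp$kernel,
    " kernel, cost ", hp$cost, ", gamma ", format(hp$gamma, digits = 4),
    if (hp$class_weights) ", class-weighted" else "", ")\n",
    sep = ""
  )
  invisible(x)
}

#' Score predictions against true species labels
#'
#' Per-species identification accuracy is recall: the fraction of a
#' species' test samples routed to the correct leaf. The mean accuracy is
#' the unweighted mean over species, matching balanced test cohorts.
#'
#' @param predictions Character vector of predicted labels.
#' @param truth Character vector of true labels, same length.
#' @param metadata Optional list recorded verbatim in the report
#'   (experiment configuration, seeds, ...).
#' @return A `dtsvm_eval` object: `per_species_accuracy` (named vector),
#'   `mean_accuracy`, `confusion` (truth in rows), `metadata`.
#' @export
evaluate_predictions <- function(predictions, truth, metadata = list()) {
  if (length(predictions) != length(truth)) {
    stop("predictions and truth differ in length", call. = FALSE)
  }
  known <- sort(unique(as.character(truth)))
  bad <- setdiff(unique(as.character(predictions)), known)
  if (length(bad) > 0) {
    stop(
      "predictions contain label(s) absent from the truth set: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  confusion <- table(
    truth = factor(truth, levels = known),
    predicted = factor(predictions, levels = known)
  )
  per_species <- diag(confusion) / rowSums(confusion)
  structure(
    list(
      per_species_accuracy = per_species,
      mean_accuracy = mean(per_species),
      confusion = confusion,
      metadata = metadata
    ),
    class = "dtsvm_eval"
  )
}

#' @export
print.dtsvm_eval <- function(x, ...) {
  cat(
    "Identification accuracy over", length(x$per_species_accuracy),
    "species\n"
  )
  print(round(x$per_species_accuracy, 2))
  cat("Mean:", format(round(x$mean_accuracy, 2), nsmall = 2), "\n")
  invisible(x)
}

#' Accuracy table of one or more evaluations
#'
#' Lays evaluations out like the published accuracy tables: one row per
#' species plus a final unweighted mean row, one column per evaluation.
#'
#' @param ... Named `dtsvm_eval` objects (or a single list of them).
#' @param digits Rounding for presentation; `NULL` keeps full precision.
#' @return A data frame with a `label` column and one accuracy column per
#'   evaluation.
#' @export
accuracy_table <- function(..., digits = 2) {
  evals <- list(...)
  if (length(evals) == 1 && !inherits(evals[[1]], "dtsvm_eval")) {
    evals <- evals[[1]]
  }
  stopifnot(all(vapply(evals, inherits, TRUE, "dtsvm_eval")))
  if (is.null(names(evals)) || any(names(evals) == "")) {
    names(evals) <- paste0("accuracy_", seq_along(evals))
  }
  labels <- sort(unique(unlist(lapply(evals, function(e) {
    names(e$per_species_accuracy)
  }))))
  out <- data.frame(label = c(labels, "mean"), stringsAsFactors = FALSE)
  for (nm in names(evals)) {
    acc <- evals[[nm]]$per_species_accuracy[labels]
    vals <- c(unname(acc), evals[[nm]]$mean_accuracy)
    out[[nm]] <- if (is.null(digits)) vals else round(vals, digits)
  }
  out
}
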