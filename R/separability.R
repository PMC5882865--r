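#' Standardize features to zero mean and unit variance
#'
#' Raw features differ by orders of magnitude (masses reach hundreds of
#' mg while the length-to-width ratio stays below ~13), which would let
#' mass dominate both the Euclidean distances in the separability factor
#' and the SVM kernel. Scaling is therefore fitted on the training cohort
#' and reapplied, unchanged, to any test data.
#'
#' @param dataset A [labeled_dataset()].
#' @return List with `dataset` (the standardized copy) and `scaling`, a
#'   `dtsvm_scaling` object holding the per-feature center and scale.
#' @seealso [apply_scaling()]
#' @export
standardize <- function(dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  center <- colMeans(dataset$features)
  scale <- apply(dataset$features, 2, stats::sd)
  zero <- which(scale == 0 | !is.finite(scale))
  if (length(zero) > 0) {
    stop(
      "zero-variance feature(s): ",
      paste(dataset$feature_names[zero], collapse = ", "),
      call. = FALSE
    )
  }
  scaling <- structure(
    list(
      center = center, scale = scale,
      feature_names = dataset$feature_names
    ),
    class = "dtsvm_scaling"
  )
  list(dataset = apply_scaling(dataset, scaling), scaling = scaling)
}

#' Apply stored scaling parameters to a dataset
#'
#' @param dataset A [labeled_dataset()] with the same feature set the
#'   scaling was fitted on.
#' @param scaling A `dtsvm_scaling` object from [standardize()].
#' @return The rescaled [labeled_dataset()].
#' @export
apply_scaling <- function(dataset, scaling) {
  stopifnot(inherits(dataset, "labeled_dataset"), inherits(scaling, "dtsvm_scaling"))
  if (!identical(dataset$feature_names, scaling$feature_names)) {
    stop(
      "dataset features (", paste(dataset$feature_names, collapse = ", "),
      ") do not match scaling features (",
      paste(scaling$feature_names, collapse = ", "), ")",
      call. = FALSE
    )
  }
  z <- sweep(dataset$features, 2, scaling$center, "-")
  z <- sweep(z, 2, scaling$scale, "/")
  labeled_dataset(z, dataset$labels, dataset$feature_names)
}

#' Center and scalar spread of a class group
#'
#' The center is the arithmetic mean vector (the one-cluster K-means
#' solution). The spread is a single rotation-invariant scalar compatible
#' with Euclidean inter-center distances: sigma^2 is the total scatter
#' about the center, i.e. the trace of the group's covariance matrix (sum
#' of per-feature sample variances, n-1 normalization).
#'
#' @param x Numeric matrix of the group's samples (rows).
#' @return List with `center` (numeric vector) and `sigma` (scalar >= 0).
#' @export
#' @examples
#' group_stats(rbind(c(0, 0), c(2, 0)))
group_stats <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0) {
    stop("cannot compute statistics of an empty group", call. = FALSE)
  }
  center <- colMeans(x)
  sigma <- if (nrow(x) == 1) {
    0
  } else {
    sqrt(sum(apply(x, 2, stats::var)))
  }
  list(center = center, sigma = sigma)
}

#' Inter-class separability factor of two groups
#'
#' The Euclidean distance between the group centers divided by the sum of
#' the two scalar spreads. Large values mean the groups are easy to tell
#' apart; the factor is symmetric in its arguments and invariant under a
#' common rescaling of all features.
#'
#' @param group_i,group_j Lists with `center` and `sigma`, as returned by
#'   [group_stats()].
#' @return Non-negative separability value; `Inf` for two degenerate
#'   (zero-spread) groups with distinct centers.
#' @export
#' @examples
#' icsf(list(center = c(0, 0), sigma = 1), list(center = c(3, 4), sigma = 1.5))
icsf <- function(group_i, group_j) {
  d <- sqrt(sum((group_i$center - group_j$center)^2))
  s <- group_i$sigma + group_j$sigma
  if (s == 0) {
    if (d == 0) {
      stop(
        "identical degenerate classes: zero spread and coincident centers",
        call. = FALSE
      )
    }
    return(Inf)
  }
  d / s
}

#' Pairwise separability matrix over a class partition
#'
#' Computes the separability factor for every pair of groups in a
#' partition of the species labels, recomputing each group's center and
#' spread from the pooled samples of its member species.
#'
#' @param dataset A [labeled_dataset()].
#' @param grouping List of character vectors partitioning the labels;
#'   defaults to one singleton group per species.
#' @return A `separability_matrix` object: list with `groups` and the
#'   symmetric `values` matrix (diagonal `NA`).
#' @export
separability_matrix <- function(dataset, grouping = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (is.null(grouping)) {
    grouping <- as.list(sort(unique(dataset$labels)))
  }
  members <- unlist(grouping, use.names = FALSE)
  if (anyDuplicated(members) || !setequal(members, unique(dataset$labels))) {
    stop("grouping must partition the dataset's species labels", call. = FALSE)
  }
  gs <- lapply(grouping, function(g) {
    group_stats(dataset$features[dataset$labels %in% g, , drop = FALSE])
  })
  k <- length(grouping)
  values <- matrix(NA_real_, k, k)
  ids <- vapply(grouping, group_id, "")
  dimnames(values) <- list(ids, ids)
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        values[i, j] <- values[j, i] <- icsf(gs[[i]], gs[[j]])
      }
    }
  }
  structure(
    list(groups = grouping, group_stats = gs, values = values),
    class = "separability_matrix"
  )
}

#' @export
print.separability_matrix <- function(x, digits = 3, ...) {
  cat(
    "Inter-class separability matrix over", length(x$groups),
    "group(s)\n"
  )
  print(round(x$values, digits))
  invisible(x)
}
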