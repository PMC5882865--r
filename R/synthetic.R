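#' Generate a synthetic cohort from per-species statistics
#'
#' Rebuilds a full labeled dataset from summary statistics alone, emulating
#' the sample-extension step used to train the classifier: each species is
#' extended to `n_per_class` samples drawn from a normal distribution with
#' that species' per-feature mean and standard deviation.
#'
#' Per-species covariances of the original specimens are not part of the
#' published statistics, so features are drawn independently by default
#' (diagonal covariance). Users holding raw specimen data can supply a
#' per-species correlation matrix through `correlations` to restore the
#' full multivariate normal.
#'
#' Draws that land at or below zero are redrawn (not clipped), keeping
#' masses, frequencies, ratios and lengths strictly positive without
#' creating a point mass at zero. With `truncate_to_range = TRUE` draws
#' outside a species' observed min--max range are likewise redrawn;
#' flagged suspect ranges are ignored by the truncation.
#'
#' @param stats A `species_stats` table from [load_species_stats()].
#' @param features Features to generate, a subset of
#'   [canonical_features()]; defaults to the three radar-retrievable ones.
#' @param n_per_class Samples generated per species (default 5000).
#' @param seed Integer seed for reproducible generation, or NULL.
#' @param truncate_to_range Redraw samples outside the observed range.
#' @param correlations Optional named list mapping species labels to
#'   feature correlation matrices (dimnames = feature names).
#' @return A [labeled_dataset()] with `n_per_class` rows per species,
#'   ordered by species label.
#' @export
#' @examples
#' stats <- load_species_stats()
#' cohort <- generate_cohort(stats, n_per_class = 100, seed = 1)
#' table(cohort$labels)[1:4]
generate_cohort <- function(stats,
                            features = canonical_features()[1:3],
                            n_per_class = 5000,
                            seed = NULL,
                            truncate_to_range = FALSE,
                            correlations = NULL) {
  stopifnot(inherits(stats, "data.frame"), n_per_class >= 2)
  features <- check_features(features)
  for (f in features) {
    for (part in c("_mean", "_sd")) {
      if (!paste0(f, part) %in% names(stats)) {
        stop(
          "statistics table lacks ", paste0(f, part),
          " needed to generate feature ", f,
          call. = FALSE
        )
      }
    }
  }
  labels <- sort(stats$label)
  with_rng_seed(seed, {
    blocks <- lapply(labels, function(lab) {
      row <- stats[stats$label == lab, , drop = FALSE]
      mu <- vapply(features, function(f) row[[paste0(f, "_mean")]], 0)
      sdv <- vapply(features, function(f) row[[paste0(f, "_sd")]], 0)
      lo <- rep(-Inf, length(features))
      hi <- rep(Inf, length(features))
      if (truncate_to_range) {
        suspect <- isTRUE(row$mass_range_suspect)
        for (j in seq_along(features)) {
          if (features[j] == "mass" && suspect) next
          lo[j] <- row[[paste0(features[j], "_min")]]
          hi[j] <- row[[paste0(features[j], "_max")]]
        }
      }
      corr <- correlations[[lab]]
      if (is.null(corr)) {
        x <- vapply(seq_along(features), function(j) {
          draw_truncated_normal(
            n_per_class, mu[j], sdv[j],
            max(lo[j], 0), hi[j]
          )
        }, numeric(n_per_class))
      } else {
        x <- draw_correlated(
          n_per_class, mu, sdv, corr, features,
          pmax(lo, 0), hi
        )
      }
      colnames(x) <- features
      x
    })
    labeled_dataset(
      do.call(rbind, blocks),
      rep(labels, each = n_per_class),
      features
    )
  })
}

# Normal draws with rejection of values outside (lo, hi]; lo = 0 encodes
# the positivity constraint (values must be strictly > 0).
draw_truncated_normal <- function(n, mu, sdv, lo, hi, max_iter = 1000L) {
  x <- stats::rnorm(n, mu, sdv)
  for (i in seq_len(max_iter)) {
    bad <- x <= lo | x > hi | (lo <= 0 & x <= 0)
    if (!any(bad)) {
      return(x)
    }
    x[bad] <- stats::rnorm(sum(bad), mu, sdv)
  }
  stop(
    "could not draw positive in-range samples for mean ", mu,
    ", sd ", sdv, "; acceptance region too small",
    call. = FALSE
  )
}

draw_correlated <- function(n, mu, sdv, corr, features, lo, hi,
                            max_iter = 1000L) {
  if (!is.matrix(corr) || any(dim(corr) != length(features))) {
    stop("correlation matrix must be ", length(features), "x",
      length(features),
      call. = FALSE
    )
  }
  if (!is.null(dimnames(corr))) {
    corr <- corr[features, features]
  }
  sigma <- diag(sdv, length(sdv)) %*% corr %*% diag(sdv, length(sdv))
  x <- MASS::mvrnorm(n, mu, sigma)
  if (n == 1) x <- matrix(x, nrow = 1)
  for (i in seq_len(max_iter)) {
    bad <- rowSums(
      sweep(x, 2, lo, "<=") | sweep(x, 2, hi, ">")
    ) > 0
    if (!any(bad)) {
      return(x)
    }
    redraw <- MASS::mvrnorm(sum(bad), mu, sigma)
    x[bad, ] <- if (sum(bad) == 1) matrix(redraw, nrow = 1) else redraw
  }
  stop("could not draw positive in-range correlated samples", call. = FALSE)
}

#' Split a cohort into training and testing halves
#'
#' Stratified 50/50 split: within every species, half the samples (the
#' extra one, for odd counts) go to training and the rest to testing, so
#' balanced cohorts stay balanced on both sides.
#'
#' @param dataset A [labeled_dataset()]; every species needs >= 2 samples.
#' @param seed Integer seed driving the per-class shuffle, or NULL.
#' @param train_fraction Fraction assigned to training (default 0.5).
#' @return List with elements `train` and `test`, both [labeled_dataset()]s.
#' @export
split_train_test <- function(dataset, seed = NULL, train_fraction = 0.5) {
  stopifnot(
    inherits(dataset, "labeled_dataset"),
    train_fraction > 0, train_fraction < 1
  )
  counts <- table(dataset$labels)
  if (any(counts < 2)) {
    stop(
      "species with fewer than 2 samples cannot be split: ",
      paste(names(counts)[counts < 2], collapse = ", "),
      call. = FALSE
    )
  }
  with_rng_seed(seed, {
    train_idx <- unlist(
      lapply(sort(unique(dataset$labels)), function(lab) {
        idx <- which(dataset$labels == lab)
        sample(idx, ceiling(length(idx) * train_fraction))
      }),
      use.names = FALSE
    )
  })
  train_idx <- sort(train_idx)
  list(
    train = subset_dataset(dataset, train_idx),
    test = subset_dataset(dataset, setdiff(seq_len(n_samples(dataset)), train_idx))
  )
}
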