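# Fixtures built in code: minimal statistics tables and toy datasets.

# A statistics table in the same layout as the bundled one, for a few
# artificial species. means/sds are named lists: label -> numeric vector
# over the four canonical features.
toy_stats <- function(means, sds) {
  labs <- names(means)
  st <- data.frame(
    label = labs,
    species = paste("species", labs),
    family = "Toyidae",
    order = "Toyoptera",
    quantity = 10L,
    stringsAsFactors = FALSE
  )
  for (j in seq_along(canonical_features())) {
    f <- canonical_features()[j]
    mu <- vapply(means, `[`, 0, j)
    sdv <- vapply(sds, `[`, 0, j)
    st[[paste0(f, "_mean")]] <- mu
    st[[paste0(f, "_sd")]] <- sdv
    st[[paste0(f, "_min")]] <- mu - 4 * sdv
    st[[paste0(f, "_max")]] <- mu + 4 * sdv
  }
  st$mass_range_suspect <- FALSE
  st
}

# Two well-separated species on a single feature.
two_class_dataset <- function(n = 20, gap = 10, sd = 0.3, seed = 7) {
  set.seed(seed)
  x <- c(rnorm(n, 5, sd), rnorm(n, 5 + gap, sd))
  labeled_dataset(
    matrix(x, ncol = 1, dimnames = list(NULL, "mass")),
    rep(c("A", "B"), each = n)
  )
}

# Small multi-species 2-D dataset with given centers (list label -> c(x, y)).
centers_dataset <- function(centers, n = 30, sd = 1, seed = 7) {
  set.seed(seed)
  blocks <- lapply(names(centers), function(lab) {
    cbind(
      rnorm(n, centers[[lab]][1], sd),
      rnorm(n, centers[[lab]][2], sd)
    )
  })
  x <- do.call(rbind, blocks)
  colnames(x) <- c("mass", "wingbeat_frequency")
  labeled_dataset(x, rep(names(centers), each = n))
}

# A reduced-size real cohort shared by several structural tests.
small_cohort <- function(features = canonical_features()[1:3],
                         n_per_class = 40, seed = 5) {
  generate_cohort(
    load_species_stats(),
    features = features, n_per_class = n_per_class, seed = seed
  )
}
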