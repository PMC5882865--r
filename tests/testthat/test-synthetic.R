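test_that("cohort generation conserves counts and label order", {
  cohort <- small_cohort(n_per_class = 40)
  expect_equal(nrow(cohort$features), 23 * 40)
  counts <- table(cohort$labels)
  expect_true(all(counts == 40))
  expect_equal(cohort$labels, rep(LETTERS[1:23], each = 40))
  expect_true(all(cohort$features > 0))
})

test_that("per-species sample moments recover the input statistics", {
  st <- load_species_stats()
  n <- 5000
  cohort <- generate_cohort(st,
    features = canonical_features(),
    n_per_class = n, seed = 31
  )
  for (lab in st$label) {
    rows <- cohort$labels == lab
    for (f in canonical_features()) {
      mu <- st[[paste0(f, "_mean")]][st$label == lab]
      sdv <- st[[paste0(f, "_sd")]][st$label == lab]
      xm <- mean(cohort$features[rows, f])
      xs <- sd(cohort$features[rows, f])
      expect_lt(abs(xm - mu), 4 * sdv / sqrt(n) + 1e-9)
      expect_lt(abs(xs - sdv), 4 * sdv / sqrt(2 * n) + 1e-9)
    }
  }
})

test_that("a large cohort reproduces the hummingbird hawk-moth's wingbeat mean", {
  st <- load_species_stats()
  cohort <- generate_cohort(
    st[st$label == "S", ],
    features = "wingbeat_frequency", n_per_class = 1e5, seed = 9
  )
  expect_lt(abs(mean(cohort$features[, 1]) - 233.40), 0.5)
})

test_that("generation is reproducible under a fixed seed", {
  a <- small_cohort(n_per_class = 10, seed = 3)
  b <- small_cohort(n_per_class = 10, seed = 3)
  c <- small_cohort(n_per_class = 10, seed = 4)
  expect_identical(a$features, b$features)
  expect_false(identical(a$features, c$features))
})

test_that("zero-variance statistics give degenerate identical samples", {
  st <- toy_stats(
    means = list(A = c(10, 40, 3, 12)),
    sds = list(A = c(0, 0, 0, 0))
  )
  cohort <- generate_cohort(st, canonical_features(), n_per_class = 2, seed = 1)
  expect_equal(unname(cohort$features[1, ]), c(10, 40, 3, 12))
  expect_equal(cohort$features[1, ], cohort$features[2, ])
})

test_that("generation validates the requested features", {
  st <- load_species_stats()
  st$body_length_mean <- NULL
  expect_error(
    generate_cohort(st, canonical_features(), n_per_class = 5),
    "body_length"
  )
})

test_that("independent features are uncorrelated, supplied correlations are honored", {
  st <- toy_stats(
    means = list(A = c(100, 50, 5, 20)),
    sds = list(A = c(10, 5, 0.5, 2))
  )
  n <- 5000
  ind <- generate_cohort(st, canonical_features(), n_per_class = n, seed = 2)
  cors <- cor(ind$features)
  expect_true(all(abs(cors[upper.tri(cors)]) < 4 / sqrt(n)))

  rho <- diag(4)
  dimnames(rho) <- list(canonical_features(), canonical_features())
  rho["mass", "body_length"] <- rho["body_length", "mass"] <- 0.8
  dep <- generate_cohort(st, canonical_features(),
    n_per_class = n,
    seed = 2, correlations = list(A = rho)
  )
  expect_lt(abs(cor(dep$features[, "mass"], dep$features[, "body_length"]) - 0.8), 0.05)
})

test_that("range truncation keeps samples inside the printed range", {
  st <- load_species_stats()
  row <- st[st$label == "G", ]
  cohort <- generate_cohort(row,
    features = "wingbeat_frequency",
    n_per_class = 2000, seed = 6, truncate_to_range = TRUE
  )
  expect_true(all(cohort$features >= row$wingbeat_frequency_min))
  expect_true(all(cohort$features <= row$wingbeat_frequency_max))
})

test_that("train/test splitting is an exact stratified partition", {
  cohort <- small_cohort(n_per_class = 40, seed = 8)
  halves <- split_train_test(cohort, seed = 9)
  expect_true(all(table(halves$train$labels) == 20))
  expect_true(all(table(halves$test$labels) == 20))

  # union equals the input, intersection is empty (rows as tuples)
  key <- function(ds) {
    vals <- apply(ds$features, 1, function(r) {
      paste(sprintf("%.17g", r), collapse = "|")
    })
    paste(ds$labels, vals, sep = "|")
  }
  all_keys <- c(key(halves$train), key(halves$test))
  expect_setequal(all_keys, key(cohort))
  expect_equal(length(intersect(key(halves$train), key(halves$test))), 0)
})

test_that("odd class counts favor the training half", {
  x <- matrix(1:5, ncol = 1, dimnames = list(NULL, "mass"))
  ds <- labeled_dataset(x, c("A", "A", "A", "A", "A"))
  halves <- split_train_test(ds, seed = 1)
  expect_equal(nrow(halves$train$features), 3)
  expect_equal(nrow(halves$test$features), 2)

  two <- labeled_dataset(x[1:2, , drop = FALSE], c("A", "A"))
  halves <- split_train_test(two, seed = 1)
  expect_equal(nrow(halves$train$features), 1)
  expect_equal(nrow(halves$test$features), 1)

  one <- labeled_dataset(x[1, , drop = FALSE], "A")
  expect_error(split_train_test(one, seed = 1), "fewer than 2")
})

test_that("splitting stratifies identically however the rows are ordered", {
  cohort <- small_cohort(n_per_class = 11, seed = 2)
  set.seed(99)
  perm <- sample(nrow(cohort$features))
  shuffled <- labeled_dataset(
    cohort$features[perm, , drop = FALSE],
    cohort$labels[perm],
    cohort$feature_names
  )
  a <- split_train_test(cohort, seed = 5)
  b <- split_train_test(shuffled, seed = 5)
  expect_equal(table(a$train$labels), table(b$train$labels))
  expect_equal(table(a$test$labels), table(b$test$labels))
})
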