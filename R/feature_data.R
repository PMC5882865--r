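#' Canonical radar-observable features
#'
#' The four physical features used throughout the package, in their fixed
#' canonical order: body mass (mg), wingbeat frequency (Hz), body
#' length-to-width ratio (unitless) and body length (mm). The first three
#' are retrievable by current entomological radar; body length is the
#' optional fourth variable used to probe the value of an extra dimension.
#'
#' @return Character vector of the four feature names in canonical order.
#' @seealso [feature_units()]
#' @export
#' @examples
#' canonical_features()
canonical_features <- function() {
  c("mass", "wingbeat_frequency", "length_to_width_ratio", "body_length")
}

#' Units of the canonical features
#'
#' @return Named character vector mapping each canonical feature to its unit.
#' @export
feature_units <- function() {
  c(
    mass = "mg",
    wingbeat_frequency = "Hz",
    length_to_width_ratio = "",
    body_length = "mm"
  )
}

check_features <- function(features) {
  if (length(features) == 0) {
    stop("at least one feature must be requested", call. = FALSE)
  }
  unknown <- setdiff(features, canonical_features())
  if (length(unknown) > 0) {
    stop(
      "unknown feature(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  # enforce canonical order regardless of how the user listed them
  intersect(canonical_features(), features)
}

#' Load per-species summary statistics
#'
#' Reads a table of per-species morphometric summary statistics: for every
#' species a label, taxonomic annotation, specimen count, and the mean,
#' standard deviation and observed min--max range of each canonical
#' feature. The bundled `"beihuang"` table describes the 23 migratory
#' species trapped by searchlight on Beihuang Island (Bohai Gulf, China);
#' its statistics are the sole input the cohort generator needs.
#'
#' Three of the printed mass ranges in the source table are internally
#' inconsistent (inverted or incompatible with the printed mean). They are
#' stored exactly as printed and flagged in the `mass_range_suspect`
#' column; flagged range cells are excluded from the range-containment
#' validation, and ranges play no role in default cohort generation.
#'
#' @param source `"beihuang"` for the bundled table, or the path of a CSV
#'   file with the same columns.
#' @return A `species_stats` data frame, one row per species, with columns
#'   `label`, `species`, `family`, `order`, `quantity` and, for each
#'   canonical feature `f`, `f_min`, `f_max`, `f_mean`, `f_sd`.
#' @export
#' @examples
#' stats <- load_species_stats()
#' stats[stats$label == "S", c("wingbeat_frequency_min", "wingbeat_frequency_max")]
load_species_stats <- function(source = "beihuang") {
  path <- if (identical(source, "beihuang")) {
    system.file("extdata", "beihuang_species_stats.csv",
      package = "dtsvm", mustWork = TRUE
    )
  } else {
    source
  }
  if (!file.exists(path)) {
    stop("species statistics file not found: ", path, call. = FALSE)
  }
  st <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_species_stats(st)
  class(st) <- c("species_stats", "data.frame")
  st
}

validate_species_stats <- function(st) {
  required <- c(
    "label", "quantity",
    as.vector(outer(canonical_features(), c("_min", "_max", "_mean", "_sd"),
      paste0
    ))
  )
  missing <- setdiff(required, names(st))
  if (length(missing) > 0) {
    stop(
      "species statistics table lacks column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(st$label)) {
    stop(
      "duplicate species label(s): ",
      paste(unique(st$label[duplicated(st$label)]), collapse = ", "),
      call. = FALSE
    )
  }
  if (!"mass_range_suspect" %in% names(st)) {
    st$mass_range_suspect <- FALSE
  }
  for (f in canonical_features()) {
    for (part in c("_min", "_max", "_mean", "_sd")) {
      col <- paste0(f, part)
      v <- st[[col]]
      bad <- which(!is.finite(v))
      if (length(bad) > 0) {
        stop(
          "non-finite value in column ", col, ", row ", bad[1],
          " (label ", st$label[bad[1]], ")",
          call. = FALSE
        )
      }
    }
    sd_bad <- which(st[[paste0(f, "_sd")]] < 0)
    if (length(sd_bad) > 0) {
      stop(
        "negative standard deviation for ", f, ", label ",
        st$label[sd_bad[1]],
        call. = FALSE
      )
    }
    suspect <- if (f == "mass") st$mass_range_suspect else FALSE
    lo <- st[[paste0(f, "_min")]]
    hi <- st[[paste0(f, "_max")]]
    mu <- st[[paste0(f, "_mean")]]
    bad <- which(!suspect & (lo > hi | mu < lo | mu > hi))
    if (length(bad) > 0) {
      stop(
        "mean outside printed range for ", f, ", label ",
        st$label[bad[1]],
        call. = FALSE
      )
    }
  }
  quantity <- st$quantity
  if (any(!is.finite(quantity) | quantity < 1)) {
    stop("specimen quantities must be positive integers", call. = FALSE)
  }
  invisible(st)
}

#' @export
print.species_stats <- function(x, ...) {
  cat(
    "Per-species feature statistics:", nrow(x), "species,",
    sum(x$quantity), "trapped specimens\n"
  )
  cols <- intersect(
    c("label", "species", "quantity", paste0(canonical_features(), "_mean")),
    names(x)
  )
  print.data.frame(x[, cols], row.names = FALSE)
  invisible(x)
}

#' Construct a labeled feature dataset
#'
#' The universal currency of the pipeline: a numeric feature matrix plus a
#' species label per row. Columns follow the canonical feature order.
#'
#' @param features Numeric matrix, one row per sample.
#' @param labels Character vector of species labels, one per row.
#' @param feature_names Names of the matrix columns, a subset of
#'   [canonical_features()] in canonical order.
#' @return A `labeled_dataset` object.
#' @export
labeled_dataset <- function(features, labels, feature_names = colnames(features)) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.character(labels)
  if (anyDuplicated(feature_names)) {
    stop("duplicated feature names", call. = FALSE)
  }
  if (ncol(features) != length(feature_names)) {
    stop(
      "feature matrix has ", ncol(features), " columns but ",
      length(feature_names), " feature names were given",
      call. = FALSE
    )
  }
  ordered <- check_features(feature_names)
  if (!identical(ordered, as.character(feature_names))) {
    features <- features[, match(ordered, feature_names), drop = FALSE]
  }
  feature_names <- ordered
  if (nrow(features) != length(labels)) {
    stop(
      "feature matrix has ", nrow(features), " rows but ",
      length(labels), " labels were given",
      call. = FALSE
    )
  }
  if (anyNA(features) || any(!is.finite(features))) {
    stop("feature matrix contains missing or non-finite values", call. = FALSE)
  }
  colnames(features) <- feature_names
  structure(
    list(features = features, labels = labels, feature_names = feature_names),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(
    "Labeled feature dataset:", nrow(x$features), "samples,",
    length(unique(x$labels)), "species\n"
  )
  cat("  features:", paste(x$feature_names, collapse = ", "), "\n")
  tab <- table(x$labels)
  cat(
    "  samples per species:",
    if (length(unique(tab)) == 1) unique(tab) else paste(range(tab), collapse = "-"),
    "\n"
  )
  invisible(x)
}

n_samples <- function(dataset) nrow(dataset$features)

subset_dataset <- function(dataset, idx) {
  labeled_dataset(
    dataset$features[idx, , drop = FALSE],
    dataset$labels[idx],
    dataset$feature_names
  )
}

#' Read a labeled feature table from CSV
#'
#' The file must have a header with a `species` column and one column per
#' requested feature. Columns are reordered to the canonical feature order.
#'
#' @param path CSV file path.
#' @param feature_names Features to read; defaults to every canonical
#'   feature present in the file.
#' @return A [labeled_dataset()].
#' @export
read_dataset <- function(path, feature_names = NULL) {
  if (!file.exists(path)) {
    stop("dataset file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"species" %in% names(df)) {
    stop("dataset file lacks the 'species' label column", call. = FALSE)
  }
  if (is.null(feature_names)) {
    feature_names <- intersect(canonical_features(), names(df))
  }
  feature_names <- check_features(feature_names)
  missing <- setdiff(feature_names, names(df))
  if (length(missing) > 0) {
    stop(
      "dataset file lacks feature column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  for (f in feature_names) {
    v <- suppressWarnings(as.numeric(df[[f]]))
    bad <- which(is.na(v) & !is.na(df[[f]]) | is.na(df[[f]]))
    if (length(bad) > 0) {
      stop(
        "non-numeric value in column ", f, ", data row ", bad[1],
        call. = FALSE
      )
    }
    df[[f]] <- v
  }
  labeled_dataset(
    as.matrix(df[, feature_names, drop = FALSE]),
    df$species,
    feature_names
  )
}

#' Write a labeled feature table to CSV
#'
#' Values are written at full precision so that
#' `read_dataset(write_dataset(x))` restores `x` exactly.
#'
#' @param dataset A [labeled_dataset()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  df <- data.frame(
    species = dataset$labels,
    stringsAsFactors = FALSE
  )
  for (f in dataset$feature_names) {
    df[[f]] <- dataset$features[, f]
  }
  if (nrow(df) == 0) {
    # keep the header so the empty set round-trips
    df <- df[0, c("species", dataset$feature_names), drop = FALSE]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
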