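#' Define a measurement-error scenario
#'
#' Radar retrieval of insect features is imprecise: wingbeat frequency
#' carries additive noise (in Hz) while mass, length-to-width ratio and
#' body length carry relative errors summarized by their root mean square
#' percent error (RMSPE). A scenario bundles one additive noise standard
#' deviation with a set of per-feature RMSPE levels.
#'
#' Errors are Gaussian: the wingbeat column receives `x + e`,
#' `e ~ N(0, wingbeat_sd)`; an RMSPE-governed column receives
#' `x * (1 + e)`, `e ~ N(0, rmspe)`, whose realized root mean square
#' relative deviation converges to the nominal RMSPE.
#'
#' @param case_label Name of the scenario.
#' @param wingbeat_sd Additive noise standard deviation in Hz (>= 0).
#' @param rmspe Named numeric vector of RMSPE fractions in \[0, 1), names
#'   among `mass`, `length_to_width_ratio`, `body_length`.
#' @return An `error_spec` object.
#' @seealso [builtin_error_cases()], [apply_errors()]
#' @export
#' @examples
#' error_spec("custom", wingbeat_sd = 1, rmspe = c(mass = 0.25))
error_spec <- function(case_label, wingbeat_sd = 0, rmspe = numeric(0)) {
  stopifnot(
    is.character(case_label), length(case_label) == 1,
    is.numeric(wingbeat_sd), length(wingbeat_sd) == 1, wingbeat_sd >= 0
  )
  rmspe <- unlist(rmspe)
  if (length(rmspe) > 0) {
    allowed <- setdiff(canonical_features(), "wingbeat_frequency")
    bad <- setdiff(names(rmspe), allowed)
    if (is.null(names(rmspe)) || length(bad) > 0) {
      stop(
        "rmspe must be named with features among: ",
        paste(allowed, collapse = ", "),
        call. = FALSE
      )
    }
    if (any(rmspe < 0 | rmspe >= 1)) {
      stop("rmspe values must lie in [0, 1)", call. = FALSE)
    }
  }
  structure(
    list(
      case_label = case_label,
      wingbeat_sd = wingbeat_sd,
      rmspe = rmspe
    ),
    class = "error_spec"
  )
}

#' @export
print.error_spec <- function(x, ...) {
  cat("Measurement-error scenario '", x$case_label, "'\n", sep = "")
  cat("  wingbeat frequency: additive sd", x$wingbeat_sd, "Hz\n")
  if (length(x$rmspe) > 0) {
    cat(
      "  RMSPE:",
      paste0(names(x$rmspe), " ", 100 * x$rmspe, "%", collapse = ", "),
      "\n"
    )
  }
  invisible(x)
}

#' The four built-in measurement-precision scenarios
#'
#' Case I mirrors current radar retrieval precision (1 Hz wingbeat noise,
#' 40% RMSPE on mass and length-to-width ratio); Cases II and III tighten
#' both RMSPEs to 20% and 10%; Case IV keeps 10% and adds body length at
#' 10% RMSPE as a fourth measured feature.
#'
#' @return Named list of four [error_spec()] objects (`I` ... `IV`).
#' @export
#' @examples
#' builtin_error_cases()$I
builtin_error_cases <- function() {
  list(
    I = error_spec("I",
      wingbeat_sd = 1,
      rmspe = c(mass = 0.40, length_to_width_ratio = 0.40)
    ),
    II = error_spec("II",
      wingbeat_sd = 1,
      rmspe = c(mass = 0.20, length_to_width_ratio = 0.20)
    ),
    III = error_spec("III",
      wingbeat_sd = 1,
      rmspe = c(mass = 0.10, length_to_width_ratio = 0.10)
    ),
    IV = error_spec("IV",
      wingbeat_sd = 1,
      rmspe = c(
        mass = 0.10, length_to_width_ratio = 0.10,
        body_length = 0.10
      )
    )
  )
}

#' Inject measurement errors into a cohort
#'
#' Perturbs the feature columns of a dataset according to an error
#' scenario; labels are untouched. Perturbations that would drive a value
#' non-positive (additive) or flip its sign (multiplicative factor
#' `1 + e <= 0`) are redrawn rather than clipped, preserving physical
#' positivity without a point mass.
#'
#' Noise is drawn from an independent sub-stream per species (keyed on
#' the seed and the label), so injecting errors into a per-species subset
#' of a cohort yields exactly the rows of the noised full cohort.
#'
#' @param dataset A [labeled_dataset()].
#' @param spec An [error_spec()]. Every feature named in `spec$rmspe`
#'   must be present in the dataset.
#' @param seed Integer seed, or NULL.
#' @return The perturbed [labeled_dataset()].
#' @export
apply_errors <- function(dataset, spec, seed = NULL) {
  stopifnot(
    inherits(dataset, "labeled_dataset"),
    inherits(spec, "error_spec")
  )
  absent <- setdiff(names(spec$rmspe), dataset$feature_names)
  if (length(absent) > 0) {
    stop(
      "error scenario names feature(s) absent from the dataset: ",
      paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  x <- dataset$features
  for (lab in sort(unique(dataset$labels))) {
    rows <- which(dataset$labels == lab)
    sub_seed <- if (is.null(seed)) {
      NULL
    } else {
      (as.numeric(seed) * 131 + sum(utf8ToInt(lab))) %% 2147483647
    }
    x[rows, ] <- with_rng_seed(sub_seed, {
      perturb_block(
        x[rows, , drop = FALSE], dataset$feature_names, spec
      )
    })
  }
  labeled_dataset(x, dataset$labels, dataset$feature_names)
}

perturb_block <- function(x, feature_names, spec, max_iter = 1000L) {
  n <- nrow(x)
  if (n == 0) {
    return(x)
  }
  if (spec$wingbeat_sd > 0 && "wingbeat_frequency" %in% feature_names) {
    j <- match("wingbeat_frequency", feature_names)
    noisy <- x[, j] + stats::rnorm(n, 0, spec$wingbeat_sd)
    for (it in seq_len(max_iter)) {
      bad <- noisy <= 0
      if (!any(bad)) break
      noisy[bad] <- x[bad, j] + stats::rnorm(sum(bad), 0, spec$wingbeat_sd)
    }
    x[, j] <- noisy
  }
  for (f in intersect(feature_names, names(spec$rmspe))) {
    level <- spec$rmspe[[f]]
    if (level == 0) next
    eps <- stats::rnorm(n, 0, level)
    for (it in seq_len(max_iter)) {
      bad <- eps <= -1
      if (!any(bad)) break
      eps[bad] <- stats::rnorm(sum(bad), 0, level)
    }
    j <- match(f, feature_names)
    x[, j] <- x[, j] * (1 + eps)
  }
  x
}
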