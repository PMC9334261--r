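#' Read a TEM inter-domain distance table
#'
#' Reads a CSV of measured backstop-cylinder distances with header
#' `distance_nm` and an optional `label` column (device variant, e.g.
#' `"ss97"`). Values must be non-negative numbers in nm.
#'
#' @param path Path to a UTF-8 CSV file with `.` as decimal separator.
#'
#' @return A tibble with columns `distance_nm` (and `label` if present);
#'   attribute `source = "measured"`.
#' @export
read_distance_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("No such file: %s", path), call. = FALSE)
  raw <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character())),
    error = function(e) stop(sprintf("Cannot parse '%s' as CSV: %s", path,
                                     conditionMessage(e)), call. = FALSE)
  )
  if (nrow(raw) == 0) {
    stop(sprintf("Distance table '%s' is empty.", path), call. = FALSE)
  }
  if (!"distance_nm" %in% names(raw)) {
    stop(sprintf("Distance table '%s' is missing the required `distance_nm` column.",
                 path), call. = FALSE)
  }
  values <- suppressWarnings(as.numeric(raw$distance_nm))
  bad <- which(is.na(values))
  if (length(bad) > 0) {
    stop(sprintf("Non-numeric `distance_nm` value in row %d of '%s': \"%s\".",
                 bad[1], path, raw$distance_nm[bad[1]]), call. = FALSE)
  }
  neg <- which(values < 0)
  if (length(neg) > 0) {
    stop(sprintf("Negative distance in row %d of '%s' (%g nm); distances must be non-negative.",
                 neg[1], path, values[neg[1]]), call. = FALSE)
  }
  out <- tibble::tibble(distance_nm = values)
  if ("label" %in% names(raw)) out$label <- raw$label
  attr(out, "source") <- "measured"
  out
}

#' Write a distance table to CSV
#'
#' Full-precision CSV writer, the inverse of [read_distance_table()].
#'
#' @param sample A data frame with a `distance_nm` column.
#' @param path Output path.
#'
#' @return `path`, invisibly.
#' @export
write_distance_table <- function(sample, path) {
  stopifnot(is.data.frame(sample), "distance_nm" %in% names(sample))
  keep <- intersect(c("distance_nm", "label"), names(sample))
  readr::write_csv(sample[keep], path)
  invisible(path)
}

#' Map measured distance r to actuation distance d
#'
#' The TEM-measured backstop-cylinder distance `r` correlates directly with
#' the actuation distance `d` at the piston tip; the default map is the
#' identity. Any geometric offset is an explicit affine parameter, applied
#' elementwise as `d = slope * r + intercept` and floored at 0.
#'
#' @param sample A data frame with a `distance_nm` column.
#' @param slope Positive multiplier (default 1).
#' @param intercept Additive offset in nm (default 0).
#'
#' @return The input with `distance_nm` transformed.
#' @export
r_to_d <- function(sample, slope = 1, intercept = 0) {
  stopifnot(is.data.frame(sample), "distance_nm" %in% names(sample))
  if (slope <= 0) stop("`slope` must be positive.", call. = FALSE)
  dplyr::mutate(sample, distance_nm = pmax(0, slope * .data$distance_nm + intercept))
}

#' Summary statistics and density histogram of a distance sample
#'
#' Mean, unbiased (n-1) standard deviation, 5/50/95% quantiles, and a density
#' histogram (integrating to 1) of a distance sample. For a single
#' measurement the sd is reported as `NA` (undefined).
#'
#' @param sample A data frame with a `distance_nm` column, or a numeric
#'   vector of distances (nm).
#' @param bin_width Histogram bin width in nm (default 2, comparable to the
#'   TEM histograms).
#'
#' @return An `ensemble_summary` (see [boltzmann_moments()]) with
#'   `source = "sample"` and the raw values retained for distribution
#'   comparisons.
#' @examples
#' summarize_distances(gen_tem_distances(500, seed = 1))
#' @export
summarize_distances <- function(sample, bin_width = 2) {
  values <- if (is.data.frame(sample)) {
    stopifnot("distance_nm" %in% names(sample))
    sample$distance_nm
  } else {
    as.numeric(sample)
  }
  if (length(values) < 1) stop("Need at least one distance.", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("Distances must be finite and non-negative.", call. = FALSE)
  }
  n <- length(values)
  qs <- stats::quantile(values, c(0.05, 0.5, 0.95), names = FALSE)
  .new_ensemble_summary(
    mean = mean(values),
    sd = if (n >= 2) stats::sd(values) else NA_real_,
    quantiles = c(q05 = qs[1], q50 = qs[2], q95 = qs[3]),
    histogram = .histogram_from_values(values, bin_width),
    source = "sample", n = n, values = values
  )
}

#' Compare a distance sample to a model ensemble
#'
#' Descriptive comparison of a measured (or simulated) distance sample with a
#' model ensemble summary: difference of means, ratio of standard deviations,
#' and the Kolmogorov-Smirnov statistic (statistic only; the ensemble is a
#' model, so no p-value headline is reported). If both carry raw values the
#' two-sample statistic is used; against a quadrature summary the sample is
#' compared to the quadrature CDF.
#'
#' @param sample A data frame with `distance_nm`, or an `ensemble_summary`
#'   with retained values.
#' @param model_summary An `ensemble_summary` from [boltzmann_moments()] or
#'   [summarize_distances()].
#'
#' @return A one-row tibble: `mean_diff_nm`, `sd_ratio`, `ks_statistic`.
#' @export
compare_to_model <- function(sample, model_summary) {
  stopifnot(inherits(model_summary, "ensemble_summary"))
  s <- if (inherits(sample, "ensemble_summary")) sample else summarize_distances(sample)
  if (is.null(s$values)) {
    stop("`sample` must carry raw values (a distance table or sample summary).",
         call. = FALSE)
  }
  ks <- if (!is.null(model_summary$values)) {
    unname(suppressWarnings(
      stats::ks.test(s$values, model_summary$values)
    )$statistic)
  } else if (!is.null(model_summary$cdf)) {
    unname(suppressWarnings(
      stats::ks.test(s$values, model_summary$cdf)
    )$statistic)
  } else {
    NA_real_
  }
  tibble::tibble(
    mean_diff_nm = s$mean - model_summary$mean,
    sd_ratio = s$sd / model_summary$sd,
    ks_statistic = ks
  )
}
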