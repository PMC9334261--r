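#' Fit a bead calibration line in log space
#'
#' Ordinary least squares of log(molecules per bead) on log(mean fluorescence
#' intensity), the standard quantification-bead procedure: populations with
#' defined fluorophore numbers are measured on the cytometer and the
#' regression converts sample MFI into molecules per cell.
#'
#' @param beads A data frame with columns `mfi` (fluorescence units, > 0) and
#'   `molecules_per_bead` (> 0); at least two distinct MFI values.
#' @param base Logarithm base for the regression space (default 10, the
#'   conventional choice).
#'
#' @return An object of class `bead_calibration` with `slope`, `intercept`
#'   (both in log-base space), `r_squared`, and the underlying `lm` fit.
#' @examples
#' beads <- data.frame(mfi = c(1e2, 1e3, 1e4), molecules_per_bead = c(1e2, 1e3, 1e4))
#' fit_bead_calibration(beads) # slope 1, intercept 0, r^2 = 1
#' @export
fit_bead_calibration <- function(beads, base = 10) {
  stopifnot(is.data.frame(beads))
  if (!all(c("mfi", "molecules_per_bead") %in% names(beads))) {
    stop("`beads` needs columns `mfi` and `molecules_per_bead`.", call. = FALSE)
  }
  if (any(beads$mfi <= 0) || any(beads$molecules_per_bead <= 0)) {
    stop("Bead MFIs and molecule counts must be positive.", call. = FALSE)
  }
  if (nrow(beads) < 2 || length(unique(beads$mfi)) < 2) {
    stop("At least two bead populations with distinct MFI are required to fit a calibration line.",
         call. = FALSE)
  }
  df <- data.frame(
    log_mfi = log(beads$mfi, base = base),
    log_molecules = log(beads$molecules_per_bead, base = base)
  )
  fit <- stats::lm(log_molecules ~ log_mfi, data = df)
  # manual r^2: summary.lm warns on exact (noise-free) calibration lines
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((df$log_molecules - mean(df$log_molecules))^2)
  structure(
    list(
      slope = unname(stats::coef(fit)[["log_mfi"]]),
      intercept = unname(stats::coef(fit)[["(Intercept)"]]),
      r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
      base = base,
      n = nrow(beads),
      fit = fit
    ),
    class = "bead_calibration"
  )
}

#' @export
print.bead_calibration <- function(x, ...) {
  cat(sprintf(
    "<bead_calibration> log%g(molecules) = %.4f x log%g(MFI) + %.4f (r^2 = %.4f, n = %d)\n",
    x$base, x$slope, x$base, x$intercept, x$r_squared, x$n
  ))
  invisible(x)
}

#' Molecules per cell from sample MFI
#'
#' Applies a fitted bead calibration line to a background-corrected sample
#' MFI: `molecules = base^(slope * log(mfi - background) + intercept)`.
#'
#' @param line A [fit_bead_calibration()] result.
#' @param sample_mfi Sample mean fluorescence intensity (one or more values).
#' @param background_mfi Baseline autofluorescence MFI subtracted before
#'   conversion (default 0); must be below every `sample_mfi`.
#'
#' @return Estimated molecules per cell, same length as `sample_mfi`.
#' @export
count_from_mfi <- function(line, sample_mfi, background_mfi = 0) {
  stopifnot(inherits(line, "bead_calibration"))
  if (any(background_mfi < 0)) {
    stop("`background_mfi` must be non-negative.", call. = FALSE)
  }
  if (any(sample_mfi <= background_mfi)) {
    stop("`sample_mfi` must exceed `background_mfi`: no signal above background.",
         call. = FALSE)
  }
  net <- sample_mfi - background_mfi
  line$base^(line$slope * log(net, base = line$base) + line$intercept)
}

#' Background-subtracted time-resolved FRET ratio per condition
#'
#' Reduces plate-reader donor/acceptor intensities to the assay response
#' `R(A/D) - R0`: the scaled acceptor/donor ratio of each well, averaged per
#' condition, minus the mean ratio of the antibody-only background wells.
#' The scale factor (default 1e4) follows the convention that puts the
#' response on the order of 1e4 units. The response is invariant to
#' multiplying both intensities of a well by a common factor.
#'
#' @param plate A data frame with columns `condition`, `donor_620`,
#'   `acceptor_665` and optionally `well`.
#' @param scale Ratio scale factor (default 1e4).
#' @param background Condition label of the antibody-only background wells
#'   (default `"background"`).
#'
#' @return A tibble with one row per non-background condition: `condition`,
#'   `response` (mean scaled ratio minus background), `sd` (over replicate
#'   wells), `n_wells`.
#' @export
lret_ratio <- function(plate, scale = 1e4, background = "background") {
  stopifnot(is.data.frame(plate))
  needed <- c("condition", "donor_620", "acceptor_665")
  if (!all(needed %in% names(plate))) {
    stop("`plate` needs columns `condition`, `donor_620`, `acceptor_665`.",
         call. = FALSE)
  }
  bad <- which(!is.finite(plate$donor_620) | plate$donor_620 <= 0)
  if (length(bad) > 0) {
    id <- if ("well" %in% names(plate)) plate$well[bad[1]] else sprintf("row %d", bad[1])
    stop(sprintf("Non-positive donor intensity in well %s; ratio undefined.", id),
         call. = FALSE)
  }
  if (any(!is.finite(plate$acceptor_665) | plate$acceptor_665 <= 0)) {
    stop("Acceptor intensities must be positive.", call. = FALSE)
  }
  if (!any(plate$condition == background)) {
    stop(sprintf("No background wells: no condition labelled \"%s\".", background),
         call. = FALSE)
  }
  if (all(plate$condition == background)) {
    stop("Plate contains only background wells.", call. = FALSE)
  }
  ratios <- dplyr::mutate(plate, r_ad = scale * .data$acceptor_665 / .data$donor_620)
  r0 <- mean(ratios$r_ad[ratios$condition == background])
  ratios |>
    dplyr::filter(.data$condition != background) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      response = mean(.data$r_ad) - r0,
      sd = stats::sd(.data$r_ad),
      n_wells = dplyr::n(),
      .groups = "drop"
    )
}

#' Two-state idealization of a single-channel current trace
#'
#' Threshold-with-hysteresis idealization of a planar-bilayer current trace
#' into closed and open states:
#' 1. initial closed/open levels from a 2-means split of the current values;
#' 2. state assignment by walking the trace with switching thresholds at the
#'    level midpoint plus/minus a quarter of the level separation;
#' 3. dwells shorter than `min_dwell` samples merged into their neighbours;
#' 4. per-state mean and sd recomputed from the final assignment.
#' A trace whose level separation is below twice the pooled within-level sd
#' is reported as single-state with no transitions.
#'
#' @param trace A data frame with columns `time_s` (uniformly sampled) and
#'   `current_pA`; at least 100 samples.
#' @param min_dwell Minimum dwell length in samples (default 5).
#'
#' @return An object of class `trace_segmentation`: `data` (the trace with a
#'   `state` column), `states` (per-state mean, sd, sample count, occupancy),
#'   `n_transitions`, `dwells` (per-dwell state and duration), `single_state`,
#'   and the switching `thresholds`.
#' @examples
#' tr <- gen_trace(duration_s = 5, seed = 1)
#' segment_trace(tr)
#' @export
segment_trace <- function(trace, min_dwell = 5) {
  stopifnot(is.data.frame(trace))
  if (!all(c("time_s", "current_pA") %in% names(trace))) {
    stop("`trace` needs columns `time_s` and `current_pA`.", call. = FALSE)
  }
  i <- trace$current_pA
  t <- trace$time_s
  n <- length(i)
  if (n < 100) stop("Trace too short: at least 100 samples are required.", call. = FALSE)
  if (any(!is.finite(i)) || any(!is.finite(t))) {
    stop("Trace values must be finite.", call. = FALSE)
  }
  dts <- diff(t)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 1e-6 * max(dt, 1e-12))) {
    stop("Trace must be uniformly sampled.", call. = FALSE)
  }

  single_state_result <- function() {
    states <- factor(rep("closed", n), levels = c("closed", "open"))
    structure(
      list(
        data = tibble::tibble(time_s = t, current_pA = i, state = states),
        states = tibble::tibble(
          state = "closed", mean_pA = mean(i), sd_pA = stats::sd(i),
          n_samples = n, occupancy = 1
        ),
        n_transitions = 0L,
        dwells = tibble::tibble(state = "closed", n_samples = n,
                                duration_s = n * dt),
        single_state = TRUE,
        thresholds = c(lower = NA_real_, upper = NA_real_),
        min_dwell = min_dwell
      ),
      class = "trace_segmentation"
    )
  }
  if (diff(range(i)) == 0) return(single_state_result())

  # 2-means split seeded at the 10/90% quantiles: deterministic in 1-D
  centers <- matrix(stats::quantile(i, c(0.1, 0.9), names = FALSE), ncol = 1)
  if (centers[1] == centers[2]) centers[2] <- centers[2] + 1e-9
  km <- stats::kmeans(i, centers = centers)
  lo_cl <- which.min(km$centers)
  level_closed <- min(km$centers)
  level_open <- max(km$centers)
  sep <- level_open - level_closed
  # within-state noise sd, estimated robustly from first differences so the
  # estimate is not inflated by the level separation itself
  pooled_sd <- stats::mad(diff(i)) / sqrt(2)
  if (sep < 2 * pooled_sd) return(single_state_result())

  mid <- (level_closed + level_open) / 2
  thr_up <- mid + sep / 4   # closed -> open crossing
  thr_dn <- mid - sep / 4   # open -> closed crossing
  st <- integer(n)          # 1 = closed, 2 = open
  st[1] <- if (abs(i[1] - level_closed) <= abs(i[1] - level_open)) 1L else 2L
  for (k in 2:n) {
    st[k] <- st[k - 1]
    if (st[k - 1] == 1L && i[k] > thr_up) st[k] <- 2L
    if (st[k - 1] == 2L && i[k] < thr_dn) st[k] <- 1L
  }

  # merge dwells shorter than min_dwell into their neighbours (shortest first)
  repeat {
    runs <- rle(st)
    if (length(runs$lengths) <= 1) break
    short <- which(runs$lengths < min_dwell)
    if (length(short) == 0) break
    j <- short[which.min(runs$lengths[short])]
    runs$values[j] <- 3L - runs$values[j]
    st <- inverse.rle(runs)
  }

  runs <- rle(st)
  labels <- c("closed", "open")
  states_f <- factor(labels[st], levels = labels)
  per_state <- tibble::tibble(
    state = labels,
    mean_pA = c(mean(i[st == 1L]), mean(i[st == 2L])),
    sd_pA = c(if (sum(st == 1L) >= 2) stats::sd(i[st == 1L]) else NA_real_,
              if (sum(st == 2L) >= 2) stats::sd(i[st == 2L]) else NA_real_),
    n_samples = c(sum(st == 1L), sum(st == 2L)),
    occupancy = c(mean(st == 1L), mean(st == 2L))
  )
  per_state <- per_state[per_state$n_samples > 0, ]
  structure(
    list(
      data = tibble::tibble(time_s = t, current_pA = i, state = states_f),
      states = per_state,
      n_transitions = length(runs$lengths) - 1L,
      dwells = tibble::tibble(
        state = labels[runs$values],
        n_samples = runs$lengths,
        duration_s = runs$lengths * dt
      ),
      single_state = length(unique(st)) == 1L,
      thresholds = c(lower = thr_dn, upper = thr_up),
      min_dwell = min_dwell
    ),
    class = "trace_segmentation"
  )
}

#' @export
print.trace_segmentation <- function(x, ...) {
  if (x$single_state) {
    cat(sprintf("<trace_segmentation> single state: mean %.2f pA (%d samples)\n",
                x$states$mean_pA[1], x$states$n_samples[1]))
  } else {
    cat(sprintf(
      "<trace_segmentation> closed %.2f pA / open %.2f pA; %d transitions over %d samples\n",
      x$states$mean_pA[x$states$state == "closed"],
      x$states$mean_pA[x$states$state == "open"],
      x$n_transitions, nrow(x$data)
    ))
  }
  invisible(x)
}
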