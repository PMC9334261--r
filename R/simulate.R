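.generator_meta <- function(fun, args, element = NULL) {
  meta <- list(
    generator = fun,
    args = args,
    package = "nanowinch",
    version = as.character(utils::packageVersion("nanowinch"))
  )
  if (!is.null(element)) meta$element <- element
  meta
}

#' Shipped default TEM distance parameters per device variant
#'
#' Documented generator defaults mirroring the reported mean actuation
#' distances of the six device variants: single-stranded 97/60/30-nt
#' connectors (17.7, 14.0, 9.3 nm) and hybridized 30/60/97-bp connectors
#' (10.7, 19.0, 31.3 nm). The common sd of 5 nm is a fixture convention
#' matching the visual spread of the measured histograms; per-variant SDs
#' were not reported.
#'
#' @return A tibble with columns `label`, `strandedness`, `n_units`,
#'   `mean_nm`, `sd_nm`.
#' @export
tem_defaults <- function() {
  tibble::tibble(
    label = c("ss97", "ss60", "ss30", "ds30", "ds60", "ds97"),
    strandedness = c("single", "single", "single", "double", "double", "double"),
    n_units = c(97, 60, 30, 30, 60, 97),
    mean_nm = c(17.7, 14.0, 9.3, 10.7, 19.0, 31.3),
    sd_nm = rep(5, 6)
  )
}

#' Simulate a TEM inter-domain distance sample
#'
#' Draws distances from a normal distribution truncated at zero (measured
#' distance distributions are unimodal and bounded below), reproducible by
#' seed. Defaults are the ss97 variant parameters; see [tem_defaults()] for
#' the other variants.
#'
#' @param n Number of particles; at least 1.
#' @param mean Target mean in nm (> 0); default 17.7 (ss97 variant).
#' @param sd Target sd in nm (> 0); default 5 (fixture convention).
#' @param seed Integer RNG seed; required.
#' @param label Variant label stored alongside the values.
#'
#' @return A tibble with columns `distance_nm`, `label`; attributes
#'   `source = "synthetic"` and `generator` (seed and parameters).
#' @examples
#' summarize_distances(gen_tem_distances(500, seed = 1))
#' @export
gen_tem_distances <- function(n, mean = 17.7, sd = 5, seed, label = "ss97") {
  if (missing(seed)) stop("`seed` is required for reproducible generation.", call. = FALSE)
  if (n < 1) stop("`n` must be at least 1.", call. = FALSE)
  if (mean <= 0 || sd <= 0) stop("`mean` and `sd` must be positive.", call. = FALSE)
  values <- withr::with_seed(seed, {
    p0 <- stats::pnorm(0, mean, sd)
    stats::qnorm(stats::runif(n, p0, 1), mean, sd)
  })
  out <- tibble::tibble(distance_nm = values, label = label)
  attr(out, "source") <- "synthetic"
  attr(out, "generator") <- .generator_meta(
    "gen_tem_distances",
    list(n = n, mean = mean, sd = sd, seed = seed, label = label)
  )
  out
}

#' Simulate a bead calibration experiment
#'
#' Emulates a quantification-bead run: populations with defined molecule
#' counts lying on a log-log calibration line, measured with lognormal MFI
#' noise, plus replicate cell-sample MFIs whose configured true count
#' defaults to the reported per-cell mean of 9,200 devices.
#'
#' @param populations Molecules per bead for each population (default five
#'   populations spanning 1e2-1e6); at least 2.
#' @param slope,intercept Calibration line in log10 space (defaults 1, 0).
#' @param cv Coefficient of variation of the lognormal MFI noise
#'   (default 0.05).
#' @param true_count Configured true molecules per cell (default 9200).
#' @param n_cell_replicates Replicate cell measurements (default 3).
#' @param seed Integer RNG seed; required.
#'
#' @return An object of class `bead_sim`: `beads` (tibble `mfi`,
#'   `molecules_per_bead`), `cell_mfi` (replicate MFIs), `true_count`,
#'   and the generator parameters.
#' @examples
#' sim <- gen_bead_table(seed = 1)
#' line <- fit_bead_calibration(sim$beads)
#' mean(count_from_mfi(line, sim$cell_mfi))
#' @export
gen_bead_table <- function(populations = 10^(2:6), slope = 1, intercept = 0,
                           cv = 0.05, true_count = 9200, n_cell_replicates = 3,
                           seed) {
  if (missing(seed)) stop("`seed` is required for reproducible generation.", call. = FALSE)
  if (length(populations) < 2) {
    stop("At least two bead populations are required.", call. = FALSE)
  }
  if (any(populations <= 0) || true_count <= 0) {
    stop("Molecule counts must be positive.", call. = FALSE)
  }
  if (cv < 0) stop("`cv` must be non-negative.", call. = FALSE)
  sdlog <- sqrt(log(1 + cv^2))
  mfi_true <- 10^((log10(populations) - intercept) / slope)
  cell_mfi_true <- 10^((log10(true_count) - intercept) / slope)
  noise <- withr::with_seed(seed, {
    list(
      beads = stats::rlnorm(length(populations), meanlog = 0, sdlog = sdlog),
      cell = stats::rlnorm(n_cell_replicates, meanlog = 0, sdlog = sdlog)
    )
  })
  beads <- tibble::tibble(
    mfi = mfi_true * noise$beads,
    molecules_per_bead = populations
  )
  attr(beads, "generator") <- .generator_meta(
    "gen_bead_table",
    list(populations = populations, slope = slope, intercept = intercept,
         cv = cv, true_count = true_count, n_cell_replicates = n_cell_replicates,
         seed = seed),
    element = "beads"
  )
  structure(
    list(
      beads = beads,
      cell_mfi = cell_mfi_true * noise$cell,
      true_count = true_count,
      slope = slope, intercept = intercept, cv = cv, seed = seed
    ),
    class = "bead_sim"
  )
}

#' Simulate a time-resolved FRET plate
#'
#' Generates donor/acceptor intensity wells for one or more conditions plus
#' antibody-only background wells, with a configurable true background-
#' subtracted response. The default true response is the reported
#' cRGD-functionalized device value of 1.23e4. Donor intensities sit at a
#' fixed scale; acceptor intensities are set so the expected scaled ratio
#' minus background equals `true_response`; both intensities then receive
#' multiplicative lognormal noise.
#'
#' @param true_response Configured true `R(A/D) - R0` (default 1.23e4).
#' @param r0 Background scaled ratio of the antibody-only wells
#'   (default 0.5e4, the order of the low-control responses).
#' @param cv Coefficient of variation of the intensity noise (default 0.1).
#' @param wells_per_condition Replicate wells per condition (default 3).
#' @param conditions Condition label(s) (default `"cRGD_nanowinch"`).
#' @param donor Donor intensity scale (default 1e4 counts).
#' @param scale Ratio scale factor (default 1e4, as in [lret_ratio()]).
#' @param seed Integer RNG seed; required.
#'
#' @return A tibble with columns `well`, `condition`, `donor_620`,
#'   `acceptor_665`, including `"background"` wells; `generator` attribute.
#' @examples
#' lret_ratio(gen_plate(seed = 1))
#' @export
gen_plate <- function(true_response = 1.23e4, r0 = 0.5e4, cv = 0.1,
                      wells_per_condition = 3, conditions = "cRGD_nanowinch",
                      donor = 1e4, scale = 1e4, seed) {
  if (missing(seed)) stop("`seed` is required for reproducible generation.", call. = FALSE)
  if (wells_per_condition < 1) stop("Need at least one well per condition.", call. = FALSE)
  if (r0 <= 0 || donor <= 0 || scale <= 0) {
    stop("`r0`, `donor` and `scale` must be positive.", call. = FALSE)
  }
  if (any(conditions == "background")) {
    stop("\"background\" is reserved for the antibody-only wells.", call. = FALSE)
  }
  all_conditions <- c("background", conditions)
  ratio_true <- c(r0, rep(true_response + r0, length(conditions)))
  df <- tibble::tibble(
    condition = rep(all_conditions, each = wells_per_condition),
    ratio_true = rep(ratio_true, each = wells_per_condition)
  )
  n <- nrow(df)
  sdlog <- sqrt(log(1 + cv^2))
  noise <- withr::with_seed(seed, {
    list(d = stats::rlnorm(n, 0, sdlog), a = stats::rlnorm(n, 0, sdlog))
  })
  out <- tibble::tibble(
    well = sprintf("W%02d", seq_len(n)),
    condition = df$condition,
    donor_620 = donor * noise$d,
    acceptor_665 = donor * df$ratio_true / scale * noise$a
  )
  attr(out, "generator") <- .generator_meta(
    "gen_plate",
    list(true_response = true_response, r0 = r0, cv = cv,
         wells_per_condition = wells_per_condition, conditions = conditions,
         donor = donor, scale = scale, seed = seed)
  )
  out
}

#' Simulate a two-state single-channel current trace
#'
#' Continuous-time two-state Markov chain (closed/open) sampled uniformly
#' with additive Gaussian noise, emulating a planar-bilayer recording of a
#' mechanically gated channel. Defaults follow the reported conductance
#' levels: closed 4 pA, open 16 pA, noise sd 4 pA. Dwell-time means default
#' to 1 s per state (transitions on the seconds scale).
#'
#' @param duration_s Trace duration in seconds (default 60).
#' @param rate_hz Sampling rate in Hz (default 1000).
#' @param closed_pA,open_pA State current levels (defaults 4 and 16 pA).
#' @param noise_sd Gaussian noise sd in pA (default 4).
#' @param dwell_means_s Named numeric `c(closed = , open = )` mean dwell
#'   times in seconds (default 1 s each).
#' @param seed Integer RNG seed; required.
#'
#' @return A tibble with columns `time_s`, `current_pA`; attributes
#'   `state_true` (the noiseless state of each sample) and `generator`.
#' @examples
#' tr <- gen_trace(duration_s = 10, seed = 1)
#' segment_trace(tr)
#' @export
gen_trace <- function(duration_s = 60, rate_hz = 1000, closed_pA = 4,
                      open_pA = 16, noise_sd = 4,
                      dwell_means_s = c(closed = 1, open = 1), seed) {
  if (missing(seed)) stop("`seed` is required for reproducible generation.", call. = FALSE)
  if (duration_s <= 0 || rate_hz <= 0) {
    stop("`duration_s` and `rate_hz` must be positive.", call. = FALSE)
  }
  if (open_pA <= closed_pA) stop("`open_pA` must exceed `closed_pA`.", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative.", call. = FALSE)
  if (!all(c("closed", "open") %in% names(dwell_means_s)) ||
      any(dwell_means_s[c("closed", "open")] <= 0)) {
    stop("`dwell_means_s` must give positive `closed` and `open` mean dwells.",
         call. = FALSE)
  }
  n <- floor(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  sim <- withr::with_seed(seed, {
    # alternate exponential dwells starting closed until the trace is covered
    jumps <- numeric(0)
    states <- integer(0)
    elapsed <- 0
    state <- 1L # 1 = closed, 2 = open
    while (elapsed <= duration_s) {
      dwell <- stats::rexp(1, rate = 1 / dwell_means_s[[c("closed", "open")[state]]])
      jumps <- c(jumps, elapsed)
      states <- c(states, state)
      elapsed <- elapsed + dwell
      state <- 3L - state
    }
    st <- states[findInterval(t, jumps)]
    list(state = st, noise = stats::rnorm(n, 0, noise_sd))
  })
  level <- c(closed_pA, open_pA)[sim$state]
  out <- tibble::tibble(time_s = t, current_pA = level + sim$noise)
  attr(out, "state_true") <- factor(c("closed", "open")[sim$state],
                                    levels = c("closed", "open"))
  attr(out, "generator") <- .generator_meta(
    "gen_trace",
    list(duration_s = duration_s, rate_hz = rate_hz, closed_pA = closed_pA,
         open_pA = open_pA, noise_sd = noise_sd,
         dwell_means_s = as.list(dwell_means_s), seed = seed)
  )
  out
}

#' Write a generated table with its metadata sidecar
#'
#' Writes a generated data frame to CSV together with a JSON sidecar
#' recording the generator, its arguments (including the seed) and the
#' package version, so the file can be regenerated byte-identically with
#' [regenerate()].
#'
#' @param x A generated tibble carrying a `generator` attribute
#'   (from [gen_tem_distances()], [gen_plate()], [gen_trace()], or the
#'   `beads` element of [gen_bead_table()]).
#' @param path Output CSV path; the sidecar is written to
#'   `paste0(path, ".meta.json")`.
#'
#' @return `path`, invisibly.
#' @export
write_generated <- function(x, path) {
  meta <- attr(x, "generator")
  if (is.null(meta)) {
    stop("`x` carries no generator metadata; only generated tables can be written with a sidecar.",
         call. = FALSE)
  }
  stopifnot(is.data.frame(x))
  readr::write_csv(as.data.frame(x), path)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Regenerate a table from its metadata sidecar
#'
#' Re-runs the generator recorded in a sidecar written by
#' [write_generated()]; with the stored seed the result is identical to the
#' original.
#'
#' @param sidecar_path Path to a `.meta.json` sidecar.
#'
#' @return The regenerated tibble.
#' @export
regenerate <- function(sidecar_path) {
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(meta$generator) || is.null(meta$args)) {
    stop("Sidecar does not record a generator and its arguments.", call. = FALSE)
  }
  fun <- getExportedValue("nanowinch", meta$generator)
  args <- meta$args
  if (meta$generator == "gen_trace" && !is.null(args$dwell_means_s)) {
    args$dwell_means_s <- unlist(args$dwell_means_s)
  }
  obj <- do.call(fun, args)
  if (!is.null(meta$element)) obj <- obj[[meta$element]]
  obj
}
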