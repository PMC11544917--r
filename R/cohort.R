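#' Synthetic cohort configuration
#'
#' Describes how a synthetic nocturnal CGM cohort is drawn: how many one-night
#' segments, which archetypes in what proportions, the noise model, and the
#' missingness (sensor-gap) model. Each segment is an archetype mean curve
#' plus a segment-level offset (between-night/between-patient level shift,
#' `N(0, offset_sigma)`) plus stationary AR(1) noise (`phi`, innovation sd
#' `noise_sigma`), clipped to the sensor range. Gaps are injected as missing
#' readings: isolated single-reading dropouts at rate `gap_rate_single` per
#' slot, plus (with probability `gap_rate_long` per segment) one long outage
#' of 3-6 consecutive readings.
#'
#' @param n_patients number of one-night segments to draw (one per patient).
#' @param archetypes list of [archetype_spec()]; defaults to the full
#'   six-shape catalogue.
#' @param archetype_mix mixing proportions over `archetypes`; nonnegative,
#'   summing to 1 (within 1e-9). Default uniform.
#' @param noise_phi AR(1) coefficient in \[0, 1).
#' @param noise_sigma AR(1) innovation sd, mmol/L.
#' @param offset_sigma sd of the per-segment level offset, mmol/L.
#' @param gap_rate_single per-slot probability of an isolated missing reading.
#' @param gap_rate_long per-segment probability of one 3-6 reading outage.
#' @param seed integer RNG seed; identical configs generate identical cohorts.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          archetypes = default_archetypes(),
                          archetype_mix = NULL,
                          noise_phi = 0.8,
                          noise_sigma = 0.3,
                          offset_sigma = 0.5,
                          gap_rate_single = 0.02,
                          gap_rate_long = 0.05,
                          seed = 1L) {
  if (is.null(archetype_mix)) {
    archetype_mix <- rep(1 / length(archetypes), length(archetypes))
  }
  if (length(archetype_mix) != length(archetypes)) {
    stop_glucluster("archetype_mix length must match archetypes", "config_error")
  }
  if (any(archetype_mix < 0) || abs(sum(archetype_mix) - 1) > 1e-9) {
    stop_glucluster("archetype_mix must be nonnegative and sum to 1",
                    "config_error")
  }
  if (noise_phi < 0 || noise_phi >= 1) {
    stop_glucluster("noise_phi must lie in [0, 1)", "config_error")
  }
  structure(
    list(n_patients = as.integer(n_patients), archetypes = archetypes,
         archetype_mix = as.numeric(archetype_mix),
         noise_phi = as.numeric(noise_phi),
         noise_sigma = as.numeric(noise_sigma),
         offset_sigma = as.numeric(offset_sigma),
         gap_rate_single = as.numeric(gap_rate_single),
         gap_rate_long = as.numeric(gap_rate_long),
         seed = as.integer(seed)),
    class = "cohort_config")
}

#' Generate a synthetic nocturnal CGM cohort
#'
#' Draws `config$n_patients` one-night 72-reading glucose segments around the
#' configured archetype curves (see [cohort_config()] for the noise and gap
#' model). Missing readings are stored as 0 with the parallel `missing` mask
#' set, mirroring raw CGM exports in which zeros encode dropouts.
#'
#' @param config a [cohort_config()].
#' @param length readings per segment (default 72).
#' @return An object of class `cgm_cohort`: a list with `values` (n x length
#'   matrix, mmol/L, 0 at missing), `missing` (n x length logical matrix),
#'   `archetype_id` (true pattern label per segment), `patient_id`,
#'   `night_index`, and the `config`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(8, seed = 42))
#' dim(coh$values)
#' table(coh$archetype_id)
generate_cohort <- function(config, length = SEGMENT_LENGTH) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  if (n == 0L) stop_glucluster("cohort must contain at least one patient",
                               "empty_cohort_error")
  L <- as.integer(length)
  set.seed(config$seed)

  ids <- vapply(config$archetypes, function(a) a$id, integer(1))
  which_arch <- sample(seq_along(ids), n, replace = TRUE,
                       prob = config$archetype_mix)
  curves <- vapply(config$archetypes, archetype_curve, numeric(L), length = L)

  values <- matrix(0, n, L)
  missing <- matrix(FALSE, n, L)
  for (i in seq_len(n)) {
    offset <- stats::rnorm(1L, 0, config$offset_sigma)
    # stationary AR(1): start from the marginal distribution
    marg_sd <- config$noise_sigma / sqrt(1 - config$noise_phi^2)
    eps <- numeric(L)
    eps[1] <- stats::rnorm(1L, 0, marg_sd)
    innov <- stats::rnorm(L - 1L, 0, config$noise_sigma)
    for (t in 2:L) eps[t] <- config$noise_phi * eps[t - 1L] + innov[t - 1L]
    values[i, ] <- clip_sensor(curves[, which_arch[i]] + offset + eps)

    gap <- stats::runif(L) < config$gap_rate_single
    if (stats::runif(1L) < config$gap_rate_long) {
      len <- sample(3:6, 1L)
      start <- sample(seq_len(L - len + 1L), 1L)
      gap[start:(start + len - 1L)] <- TRUE
    }
    missing[i, ] <- gap
  }
  values[missing] <- 0

  structure(
    list(values = values, missing = missing,
         archetype_id = ids[which_arch],
         patient_id = sprintf("P%04d", seq_len(n)),
         night_index = rep(1L, n),
         config = config),
    class = "cgm_cohort")
}

#' @export
print.cgm_cohort <- function(x, ...) {
  cat(sprintf("Synthetic CGM cohort: %d segments x %d readings (5-min)\n",
              nrow(x$values), ncol(x$values)))
  cat("Archetype counts:\n")
  print(table(x$archetype_id))
  cat(sprintf("Missing readings: %.1f%%\n", 100 * mean(x$missing)))
  invisible(x)
}

#' Write a cohort as long-format CGM CSV plus a label sidecar
#'
#' The long file has one row per reading:
#' `patient_id,night_index,timestamp,glucose_mmol_l`, timestamps ISO-8601 on
#' the 5-min grid starting at 00:00; missing readings have an empty glucose
#' field. The sidecar holds the true archetype labels:
#' `patient_id,night_index,archetype_id`.
#'
#' @param cohort a `cgm_cohort`.
#' @param path output CSV path for the readings.
#' @param labels_path output path for the label sidecar (default
#'   `<path>` with `_labels` inserted before the extension).
#' @param start_date calendar date of the first night.
#' @return Invisibly, `c(path, labels_path)`.
#' @export
write_cohort_csv <- function(cohort, path, labels_path = NULL,
                             start_date = as.Date("2024-01-01")) {
  stopifnot(inherits(cohort, "cgm_cohort"))
  if (is.null(labels_path)) {
    labels_path <- sub("(\\.[^.]+)?$", "_labels\\1", path)
  }
  n <- nrow(cohort$values); L <- ncol(cohort$values)
  slots <- seq(0, by = SAMPLING_MINUTES * 60, length.out = L)
  ts0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  times <- rep(ts0 + (cohort$night_index - 1L) * 86400, each = L) +
    rep(slots, times = n)
  vals <- as.vector(t(cohort$values))     # patient-major order
  miss <- as.vector(t(cohort$missing))
  rows <- data.frame(
    patient_id = rep(cohort$patient_id, each = L),
    night_index = rep(cohort$night_index, each = L),
    timestamp = format(times, "%Y-%m-%dT%H:%M:%S"),
    glucose_mmol_l = ifelse(miss, NA, sprintf("%.6f", vals)))
  utils::write.csv(rows, path, row.names = FALSE, na = "", quote = FALSE)
  utils::write.csv(
    data.frame(patient_id = cohort$patient_id,
               night_index = cohort$night_index,
               archetype_id = cohort$archetype_id),
    labels_path, row.names = FALSE, quote = FALSE)
  invisible(c(path, labels_path))
}

#' Read long-format CGM records
#'
#' Reads the CSV dialect written by [write_cohort_csv()] (or any file with
#' columns `patient_id`, `timestamp`, `glucose_mmol_l`, optionally
#' `night_index`); empty glucose fields become missing readings.
#'
#' @param path CSV path.
#' @return data.frame with `patient_id`, `time` (POSIXct, UTC) and
#'   `glucose` (numeric, `NA` = missing), sorted by patient then time.
#' @export
read_cgm_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(glucose_mmol_l = "character"))
  g <- suppressWarnings(as.numeric(df$glucose_mmol_l))
  out <- data.frame(patient_id = as.character(df$patient_id),
                    time = as.POSIXct(df$timestamp, tz = "UTC",
                                      format = "%Y-%m-%dT%H:%M:%S"),
                    glucose = g)
  out[order(out$patient_id, out$time), , drop = FALSE]
}
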