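#' Nocturnal glucose archetype specification
#'
#' An archetype is a noiseless mean curve describing one recurring pattern of
#' nocturnal glucose dynamics: stable profiles at target or elevated levels,
#' monotone downward/upward trends, a hypoglycemic dip with partial recovery,
#' and a stable low (hypoglycemic) profile. Synthetic cohorts are drawn around
#' these curves, so every generated segment carries a known pattern label.
#'
#' @param id small integer identifying the archetype.
#' @param shape one of `"stable_target"`, `"stable_elevated"`,
#'   `"downward_trend"`, `"upward_trend"`, `"hypo_dip"`, `"hypo_low_stable"`.
#' @param start_level,end_level glucose (mmol/L) at the start/end of the night;
#'   both must lie inside the sensor range \[2.2, 22.2\].
#' @param dip_time_index 0-based index in \[0, 71\] at which a `hypo_dip`
#'   reaches its nadir (`NA` for other shapes).
#' @param dip_depth nadir glucose (mmol/L) for `hypo_dip` (`NA` otherwise).
#' @return An object of class `archetype_spec`.
#' @seealso [archetype_curve()], [default_archetypes()]
#' @export
archetype_spec <- function(id, shape, start_level, end_level = start_level,
                           dip_time_index = NA_integer_, dip_depth = NA_real_) {
  shapes <- c("stable_target", "stable_elevated", "downward_trend",
              "upward_trend", "hypo_dip", "hypo_low_stable")
  if (!is.character(shape) || length(shape) != 1L || !shape %in% shapes) {
    stop_glucluster(
      sprintf("unknown archetype shape %s", deparse(shape)), "config_error")
  }
  for (lev in c(start_level, end_level)) {
    if (lev < SENSOR_RANGE[1] || lev > SENSOR_RANGE[2]) {
      stop_glucluster("archetype levels must lie in the sensor range",
                      "config_error")
    }
  }
  if (shape == "hypo_dip") {
    if (is.na(dip_time_index) || is.na(dip_depth)) {
      stop_glucluster("hypo_dip requires dip_time_index and dip_depth",
                      "config_error")
    }
    if (dip_time_index < 0L || dip_time_index > SEGMENT_LENGTH - 1L) {
      stop_glucluster("dip_time_index must lie in [0, 71]", "config_error")
    }
  }
  structure(
    list(id = as.integer(id), shape = shape,
         start_level = as.numeric(start_level),
         end_level = as.numeric(end_level),
         dip_time_index = as.integer(dip_time_index),
         dip_depth = as.numeric(dip_depth)),
    class = "archetype_spec")
}

#' Default archetype catalogue
#'
#' Six patterns spanning the taxonomy seen in clustered nocturnal CGM data:
#' stable at target, stable elevated, downward trend, upward trend, a
#' mid-night hypoglycemic dip with partial recovery, and a stable low profile.
#' The first four never fall below 4.4 mmol/L; the last two spend at least
#' three consecutive readings below the 3.9 mmol/L hypoglycemia threshold.
#'
#' @param shapes optional character vector restricting which of the six shapes
#'   are returned (in catalogue order).
#' @return A list of [archetype_spec()] objects.
#' @export
default_archetypes <- function(shapes = NULL) {
  cat6 <- list(
    archetype_spec(1L, "stable_target",   6.5),
    archetype_spec(2L, "stable_elevated", 12.0),
    archetype_spec(3L, "downward_trend",  11.0, 5.5),
    archetype_spec(4L, "upward_trend",     6.0, 11.5),
    archetype_spec(5L, "hypo_dip",         7.0, 5.5,
                   dip_time_index = 36L, dip_depth = 3.2),
    archetype_spec(6L, "hypo_low_stable",  3.5))
  if (is.null(shapes)) return(cat6)
  keep <- vapply(cat6, function(a) a$shape %in% shapes, logical(1))
  cat6[keep]
}

#' Noiseless archetype mean curve
#'
#' Evaluates the deterministic glucose curve of an archetype on an
#' equally-spaced grid of `length` five-minute readings. Stable shapes are
#' constant at `start_level`; trend shapes interpolate linearly from
#' `start_level` to `end_level`; `hypo_dip` follows a smooth (half-cosine)
#' descent from `start_level` to `dip_depth` at `dip_time_index`, then a
#' half-cosine partial recovery toward `end_level`. Values are clipped to the
#' sensor range \[2.2, 22.2\] mmol/L.
#'
#' @param spec an [archetype_spec()].
#' @param length number of readings (>= 4); 72 for a full night.
#' @return Numeric vector of `length` glucose values (mmol/L).
#' @export
#' @examples
#' archetype_curve(archetype_spec(1, "downward_trend", 10, 5), length = 6)
archetype_curve <- function(spec, length = SEGMENT_LENGTH) {
  stopifnot(inherits(spec, "archetype_spec"))
  if (length < 4L) stop_glucluster("length must be >= 4", "config_error")
  n <- as.integer(length)
  curve <- switch(
    spec$shape,
    stable_target = ,
    stable_elevated = ,
    hypo_low_stable = rep(spec$start_level, n),
    downward_trend = ,
    upward_trend = seq(spec$start_level, spec$end_level, length.out = n),
    hypo_dip = {
      # dip index is specified on the 72-slot grid; rescale when length differs
      nadir <- if (n == SEGMENT_LENGTH) spec$dip_time_index else
        as.integer(round(spec$dip_time_index * (n - 1L) / (SEGMENT_LENGTH - 1L)))
      nadir <- max(1L, min(n - 2L, nadir))
      idx <- seq_len(n) - 1L
      out <- numeric(n)
      down <- idx <= nadir
      out[down] <- spec$dip_depth + (spec$start_level - spec$dip_depth) *
        (1 + cos(pi * idx[down] / nadir)) / 2
      out[!down] <- spec$dip_depth + (spec$end_level - spec$dip_depth) *
        (1 - cos(pi * (idx[!down] - nadir) / (n - 1L - nadir))) / 2
      out
    })
  clip_sensor(curve)
}
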