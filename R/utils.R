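#' @keywords internal
"_PACKAGE"

# Detectable CGM sensor range, mmol/L (40-400 mg/dL)
SENSOR_RANGE <- c(2.2, 22.2)

# Hypoglycemia threshold (mmol/L) and persistence (consecutive 5-min readings)
NH_THRESHOLD <- 3.9
NH_MIN_RUN <- 3L

# Segment geometry: 72 five-minute slots covering 00:00-05:59
SEGMENT_LENGTH <- 72L
SAMPLING_MINUTES <- 5L

`%||%` <- function(a, b) if (is.null(a)) b else a

clip_sensor <- function(x, range = SENSOR_RANGE) {
  pmin(pmax(x, range[1]), range[2])
}

#' Runs of TRUE values in a logical vector
#'
#' @param mask logical vector.
#' @return data.frame with columns `start`, `end`, `length`, one row per
#'   maximal run of `TRUE`.
#' @keywords internal
true_runs <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

stop_glucluster <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "glucluster_error")))
}
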