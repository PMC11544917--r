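#' One night's CGM segment
#'
#' A fixed-length (72-reading) nocturnal glucose vector with its missingness
#' mask. Missing readings are stored as 0 with the mask set; after imputation
#' and filtering no missing entries remain.
#'
#' @param values numeric glucose vector (mmol/L), length 72 by default.
#' @param missing_mask logical vector, same length; `TRUE` = missing.
#' @param patient_id,night_index identifiers.
#' @param nh_label optional logical nocturnal-hypoglycemia label.
#' @return An object of class `nocturnal_segment`.
#' @export
nocturnal_segment <- function(values, missing_mask = rep(FALSE, length(values)),
                              patient_id = "P0001", night_index = 1L,
                              nh_label = NA) {
  if (length(values) != length(missing_mask)) {
    stop_glucluster("values and missing_mask lengths differ", "shape_error")
  }
  values <- as.numeric(values)
  values[missing_mask] <- 0
  structure(
    list(patient_id = as.character(patient_id),
         night_index = as.integer(night_index),
         values = values, missing_mask = as.logical(missing_mask),
         nh_label = nh_label),
    class = "nocturnal_segment")
}

#' @export
print.nocturnal_segment <- function(x, ...) {
  cat(sprintf("Nocturnal segment %s/night %d: %d readings, %d missing, NH=%s\n",
              x$patient_id, x$night_index, length(x$values),
              sum(x$missing_mask), format(x$nh_label)))
  invisible(x)
}

#' Panel of equal-length nocturnal segments
#'
#' Stacks complete (imputed) segments into an n x L matrix with per-segment
#' metadata and, after [split_dataset()], a train/validation/test role.
#'
#' @param segments list of complete `nocturnal_segment` objects.
#' @param roles optional factor/character of roles per segment
#'   (`train`, `validation`, `test`).
#' @return An object of class `segment_set`: `values` (n x L matrix),
#'   `patient_id`, `night_index`, `nh_label`, `role`, `series_length`.
#' @export
as_segment_set <- function(segments, roles = NULL) {
  if (length(segments) == 0L) {
    stop_glucluster("no segments supplied", "size_error")
  }
  lens <- vapply(segments, function(s) length(s$values), integer(1))
  if (length(unique(lens)) != 1L) {
    stop_glucluster("segments have differing lengths", "shape_error")
  }
  if (any(vapply(segments, function(s) any(s$missing_mask), logical(1)))) {
    stop_glucluster("segment_set requires imputed (complete) segments",
                    "precondition_error")
  }
  values <- do.call(rbind, lapply(segments, `[[`, "values"))
  role <- if (is.null(roles)) rep(NA_character_, length(segments))
          else as.character(roles)
  structure(
    list(values = values,
         patient_id = vapply(segments, `[[`, character(1), "patient_id"),
         night_index = vapply(segments, `[[`, integer(1), "night_index"),
         nh_label = vapply(segments, function(s) isTRUE(s$nh_label), logical(1)),
         role = role, series_length = unique(lens)),
    class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("Segment set: %d segments x %d readings; NH-positive: %d\n",
              nrow(x$values), x$series_length, sum(x$nh_label)))
  if (!all(is.na(x$role))) print(table(role = x$role))
  invisible(x)
}

#' Subset a segment set by role
#'
#' @param set a `segment_set`.
#' @param role one of `"train"`, `"validation"`, `"test"`.
#' @return The matrix of series (rows) carrying that role.
#' @export
role_matrix <- function(set, role) {
  stopifnot(inherits(set, "segment_set"))
  set$values[which(set$role == role), , drop = FALSE]
}

#' Write a segment set as a wide segment-matrix CSV
#'
#' Columns: `patient_id,night_index,nh_label,role,g00,...,g71`.
#'
#' @param set a `segment_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments_csv <- function(set, path) {
  stopifnot(inherits(set, "segment_set"))
  m <- as.data.frame(set$values)
  names(m) <- sprintf("g%02d", seq_len(set$series_length) - 1L)
  df <- cbind(data.frame(patient_id = set$patient_id,
                         night_index = set$night_index,
                         nh_label = set$nh_label, role = set$role), m)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wide segment-matrix CSV written by [write_segments_csv()]
#'
#' @param path CSV path.
#' @return A `segment_set`.
#' @export
read_segments_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  gcols <- grep("^g[0-9]+$", names(df), value = TRUE)
  values <- as.matrix(df[, gcols])
  dimnames(values) <- NULL
  structure(
    list(values = values, patient_id = as.character(df$patient_id),
         night_index = as.integer(df$night_index),
         nh_label = as.logical(df$nh_label),
         role = if ("role" %in% names(df)) as.character(df$role)
                else rep(NA_character_, nrow(df)),
         series_length = length(gcols)),
    class = "segment_set")
}
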