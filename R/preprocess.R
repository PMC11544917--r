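#' Extract nocturnal segments from raw CGM records
#'
#' Slices each patient's record into per-night candidate segments covering the
#' 00:00-05:59 window at 5-minute resolution (72 slots; slot index =
#' minutes-since-midnight / 5). A night belongs to the calendar date of its
#' 00:00 start. Slots with no reading are marked missing; nights with no
#' in-window reading at all are skipped.
#'
#' @param records data.frame with `patient_id`, `time` (POSIXct) and
#'   `glucose` (mmol/L, `NA` = missing), e.g. from [read_cgm_csv()];
#'   timestamps must be strictly increasing within a patient.
#' @param window_start,window_end window bounds as minutes since midnight
#'   (defaults 0 and 360).
#' @param interval sampling interval in minutes (must be 5).
#' @return List of [nocturnal_segment()] objects.
#' @export
extract_nocturnal_segments <- function(records, window_start = 0L,
                                       window_end = 360L,
                                       interval = SAMPLING_MINUTES) {
  stopifnot(all(c("patient_id", "time", "glucose") %in% names(records)))
  if (interval != SAMPLING_MINUTES || (window_end - window_start) != 360L) {
    stop_glucluster("window must span 6 h at 5-min sampling", "config_error")
  }
  n_slots <- as.integer((window_end - window_start) / interval)
  out <- list()
  for (pid in unique(records$patient_id)) {
    rec <- records[records$patient_id == pid, , drop = FALSE]
    if (is.unsorted(as.numeric(rec$time), strictly = TRUE)) {
      stop_glucluster(sprintf("timestamps for %s are not strictly increasing",
                              pid), "data_error")
    }
    lt <- as.POSIXlt(rec$time, tz = "UTC")
    mins <- lt$hour * 60L + lt$min
    inwin <- mins >= window_start & mins < window_end
    if (!any(inwin)) next
    rec <- rec[inwin, , drop = FALSE]
    mins <- mins[inwin]
    night <- format(as.Date(as.POSIXlt(rec$time, tz = "UTC")))
    for (d in unique(night)) {
      sel <- night == d
      slot <- (mins[sel] - window_start) %/% interval + 1L
      vals <- rep(0, n_slots)
      mask <- rep(TRUE, n_slots)
      g <- rec$glucose[sel]
      ok <- !is.na(g)
      # first reading wins if two fall into one slot
      first <- !duplicated(slot) & ok
      vals[slot[first]] <- g[first]
      mask[slot[first]] <- FALSE
      out[[length(out) + 1L]] <- nocturnal_segment(
        vals, mask, patient_id = pid,
        night_index = as.integer(as.Date(d) - as.Date(night[1])) + 1L)
    }
  }
  out
}

#' Impute single and double gaps by the left/right-neighbor mean
#'
#' Every run of one or two consecutive missing readings is replaced by the
#' arithmetic mean of the nearest non-missing reading to its left and the
#' nearest to its right (both entries of a double gap receive the same mean).
#' Non-missing readings are never altered. Gaps of length three or more, and
#' gaps touching the segment boundary (no neighbor on one side), are not
#' imputable: the former must be rejected by [filter_segment()] first, the
#' latter raise a `boundary_gap_error`.
#'
#' @param segment a [nocturnal_segment()].
#' @return The segment with short gaps filled and the mask cleared.
#' @export
#' @examples
#' s <- nocturnal_segment(c(5, 0, 6, 7), c(FALSE, TRUE, FALSE, FALSE))
#' impute_short_gaps(s)$values   # 5.0 5.5 6.0 7.0
impute_short_gaps <- function(segment) {
  stopifnot(inherits(segment, "nocturnal_segment"))
  mask <- segment$missing_mask
  if (!any(mask)) return(segment)
  runs <- true_runs(mask)
  if (any(runs$length >= 3L)) {
    stop_glucluster("segment has a gap of >= 3 consecutive readings; reject it",
                    "precondition_error")
  }
  vals <- segment$values
  n <- length(vals)
  for (i in seq_len(nrow(runs))) {
    if (runs$start[i] == 1L || runs$end[i] == n) {
      stop_glucluster("short gap at the segment boundary has no neighbor pair",
                      "boundary_gap_error")
    }
    fill <- (vals[runs$start[i] - 1L] + vals[runs$end[i] + 1L]) / 2
    vals[runs$start[i]:runs$end[i]] <- fill
  }
  segment$values <- vals
  segment$missing_mask <- rep(FALSE, n)
  segment
}

#' Keep/reject decision for a raw (pre-imputation) segment
#'
#' Rejection rules, checked in order of precedence:
#' \describe{
#'   \item{LONG_GAP}{any run of 3 or more consecutive missing readings;}
#'   \item{TOO_SPARSE}{strictly more than 10\% missing readings
#'     (for 72 slots: 8 or more);}
#'   \item{BOUNDARY_GAP}{a 1-2 reading gap touching the first or last slot,
#'     which the left/right-mean rule cannot fill.}
#' }
#'
#' @param segment a [nocturnal_segment()] before imputation.
#' @return List with `keep` (logical) and `reason` (`"OK"`, `"LONG_GAP"`,
#'   `"TOO_SPARSE"` or `"BOUNDARY_GAP"`).
#' @export
filter_segment <- function(segment) {
  stopifnot(inherits(segment, "nocturnal_segment"))
  mask <- segment$missing_mask
  n <- length(mask)
  if (any(mask)) {
    runs <- true_runs(mask)
    if (any(runs$length >= 3L)) {
      return(list(keep = FALSE, reason = "LONG_GAP"))
    }
    if (sum(mask) / n > 0.10) {
      return(list(keep = FALSE, reason = "TOO_SPARSE"))
    }
    if (runs$start[1] == 1L || runs$end[nrow(runs)] == n) {
      return(list(keep = FALSE, reason = "BOUNDARY_GAP"))
    }
  }
  list(keep = TRUE, reason = "OK")
}

#' Label a segment for nocturnal hypoglycemia
#'
#' A night is NH-positive when interstitial glucose stays strictly below
#' `threshold` for at least `min_run` consecutive readings — with 5-minute
#' sampling, `min_run = 3` covers the conventional "persisted at least
#' 15 minutes" definition (readings at t, t+5, t+10).
#'
#' @param segment a complete (imputed) [nocturnal_segment()], or a bare
#'   numeric glucose vector.
#' @param threshold hypoglycemia threshold, mmol/L (default 3.9).
#' @param min_run minimum run of consecutive sub-threshold readings
#'   (default 3; use 4 for the stricter reading of 15-min persistence).
#' @return Logical NH label.
#' @export
label_nocturnal_hypoglycemia <- function(segment, threshold = NH_THRESHOLD,
                                         min_run = NH_MIN_RUN) {
  vals <- if (inherits(segment, "nocturnal_segment")) {
    if (any(segment$missing_mask)) {
      stop_glucluster("segment must be imputed before NH labeling",
                      "precondition_error")
    }
    segment$values
  } else as.numeric(segment)
  runs <- true_runs(vals < threshold)
  nrow(runs) > 0L && any(runs$length >= min_run)
}

#' Split segments into train/validation/test, stratified by NH status
#'
#' NH-positive and NH-negative segments are pooled separately; each pool is
#' shuffled under the seed and allocated contiguously with largest-remainder
#' rounding of `n * ratio`, so role sizes depend only on the pool sizes, not
#' on the seed.
#'
#' @param segments list of complete, NH-labeled [nocturnal_segment()]s.
#' @param ratios train/validation/test proportions, summing to 1
#'   (default `c(0.7, 0.1, 0.2)`).
#' @param seed integer RNG seed.
#' @return A [as_segment_set()] with the `role` field assigned.
#' @export
split_dataset <- function(segments, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  if (any(ratios < 0) || abs(sum(ratios) - 1) > 1e-9) {
    stop_glucluster("ratios must be nonnegative and sum to 1", "config_error")
  }
  roles <- c("train", "validation", "test")
  if (length(segments) < sum(ratios > 0)) {
    stop_glucluster("fewer segments than nonzero ratio groups", "size_error")
  }
  nh <- vapply(segments, function(s) isTRUE(s$nh_label), logical(1))
  role <- rep(NA_character_, length(segments))
  set.seed(seed)
  for (grp in list(which(!nh), which(nh))) {
    n <- length(grp)
    if (n == 0L) next
    counts <- largest_remainder(n, ratios)
    perm <- grp[sample.int(n)]
    role[perm] <- rep(roles, times = counts)
  }
  as_segment_set(segments, roles = role)
}

# largest-remainder apportionment of n into round(n * ratio) counts
largest_remainder <- function(n, ratios) {
  exact <- n * ratios
  counts <- floor(exact)
  short <- n - sum(counts)
  if (short > 0L) {
    extra <- order(exact - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

#' Preprocess a cohort end to end
#'
#' Applies [filter_segment()], [impute_short_gaps()],
#' [label_nocturnal_hypoglycemia()] and [split_dataset()] to a list of raw
#' segments (or a `cgm_cohort`), returning the split panels per NH group plus
#' a rejection tally.
#'
#' @param segments list of raw [nocturnal_segment()]s, or a `cgm_cohort`.
#' @param nh_threshold,nh_min_run NH labeling parameters.
#' @param ratios split proportions.
#' @param seed split seed.
#' @return List with `sets` (named list `no_NH` / `NH` of `segment_set`,
#'   present when non-empty), `counts` (kept/rejected tally by reason), and
#'   `kept` (the labeled kept segments).
#' @export
preprocess_cohort <- function(segments, nh_threshold = NH_THRESHOLD,
                              nh_min_run = NH_MIN_RUN,
                              ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  if (inherits(segments, "cgm_cohort")) {
    coh <- segments
    segments <- lapply(seq_len(nrow(coh$values)), function(i) {
      nocturnal_segment(coh$values[i, ], coh$missing[i, ],
                        patient_id = coh$patient_id[i],
                        night_index = coh$night_index[i])
    })
  }
  decisions <- lapply(segments, filter_segment)
  reasons <- vapply(decisions, `[[`, character(1), "reason")
  kept <- segments[reasons == "OK"]
  kept <- lapply(kept, impute_short_gaps)
  kept <- lapply(kept, function(s) {
    s$nh_label <- label_nocturnal_hypoglycemia(s, nh_threshold, nh_min_run)
    s
  })
  counts <- table(factor(reasons,
                         levels = c("OK", "LONG_GAP", "TOO_SPARSE",
                                    "BOUNDARY_GAP")))
  nh <- vapply(kept, `[[`, logical(1), "nh_label")
  sets <- list()
  if (any(!nh)) sets$no_NH <- split_dataset(kept[!nh], ratios, seed)
  if (any(nh)) sets$NH <- split_dataset(kept[nh], ratios, seed + 1L)
  list(sets = sets, counts = counts, kept = kept)
}
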