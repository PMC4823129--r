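# The four in situ hybridization markers used by the risk model, with the
# scoring system each one uses:
#   additive  -- intensity (0-3) + percentage category (0-2), final score 0-5
#   intensity -- four-tier intensity alone, final score 0-3
#   percent   -- percentage of stained cells, 0-100
.MARKERS <- data.frame(
  marker    = c("miR-145", "miR-31", "miR-92a", "miR-10b"),
  system    = c("additive", "additive", "intensity", "percent"),
  threshold = c(4, 3, 0.5, 20),
  # "positive" side of the threshold: ">" strict (negative iff score <= thr),
  # ">=" inclusive (high iff score >= thr, used for the percent marker)
  direction = c(">", ">", ">", ">="),
  max_score = c(5, 5, 3, 100),
  stringsAsFactors = FALSE
)

#' Marker scoring systems
#'
#' Returns the scoring-system table for the four in situ hybridization (ISH)
#' miRNA markers: the scoring system each uses, its positivity threshold and
#' the attainable score range.
#'
#' @return A data frame with columns `marker`, `system`, `threshold`,
#'   `direction` and `max_score`.
#' @export
#' @examples
#' marker_systems()
marker_systems <- function() .MARKERS

.marker_row <- function(marker) {
  i <- match(marker, .MARKERS$marker)
  if (is.na(i)) {
    stop("unknown marker '", marker, "'; expected one of ",
         paste(.MARKERS$marker, collapse = ", "), call. = FALSE)
  }
  .MARKERS[i, ]
}

#' Additive ISH score from intensity and percentage categories
#'
#' Combines the chromogenic intensity score (0 = no signal, 1 = weak,
#' 2 = intermediate, 3 = strong) with the stained-percentage category
#' (0 = 0%, 1 = <30%, 2 = >30%) into the additive final score 0--5 used
#' for miR-145 and miR-31.
#'
#' @param intensity Integer 0--3, chromogenic intensity.
#' @param percentage_category Integer 0--2, stained-percentage category.
#' @return Integer final score, `intensity + percentage_category`, in 0--5.
#' @export
#' @examples
#' score_additive_marker(3, 2)  # 5, the maximal score
score_additive_marker <- function(intensity, percentage_category) {
  if (!is.numeric(intensity) || any(!is.finite(intensity)) ||
      any(intensity != as.integer(intensity)) ||
      any(intensity < 0 | intensity > 3)) {
    stop("intensity must be an integer in 0..3", call. = FALSE)
  }
  if (!is.numeric(percentage_category) || any(!is.finite(percentage_category)) ||
      any(percentage_category != as.integer(percentage_category)) ||
      any(percentage_category < 0 | percentage_category > 2)) {
    stop("percentage_category must be an integer in 0..2", call. = FALSE)
  }
  as.integer(intensity + percentage_category)
}

#' Binary marker call from a final score
#'
#' Applies the marker-specific positivity rule to a (possibly rater-averaged,
#' hence non-integer) final score.  miR-145 is positive for score > 4,
#' miR-31 for score > 3, miR-92a for score > 0.5, and miR-10b is "high"
#' for >= 20% of cells stained.  Scores on the boundary fall on the
#' negative/low side except for miR-10b, whose threshold is inclusive.
#'
#' @param marker One of `"miR-145"`, `"miR-31"`, `"miR-92a"`, `"miR-10b"`.
#' @param final_score Numeric score within the marker's range.
#' @return `"positive"` or `"negative"` (for miR-10b: `"high"` or `"low"`).
#' @export
#' @examples
#' call_marker("miR-145", 4)    # "negative": boundary falls on negative side
#' call_marker("miR-31", 3.5)   # "positive": averaged two-rater score
#' call_marker("miR-10b", 20)   # "high": percent threshold is inclusive
call_marker <- function(marker, final_score) {
  row <- .marker_row(marker)
  if (!is.numeric(final_score) || length(final_score) != 1L ||
      !is.finite(final_score)) {
    stop("final_score must be a single finite number", call. = FALSE)
  }
  if (final_score < 0 || final_score > row$max_score) {
    stop("final_score ", final_score, " outside range [0, ", row$max_score,
         "] for marker ", marker, call. = FALSE)
  }
  pos <- if (row$direction == ">=") final_score >= row$threshold
         else final_score > row$threshold
  if (row$system == "percent") {
    if (pos) "high" else "low"
  } else {
    if (pos) "positive" else "negative"
  }
}

#' Aggregate multiple raters' readings into one marker call
#'
#' Computes each rater's final score under the marker's scoring system,
#' averages the final scores arithmetically across raters, and applies
#' [call_marker()] to the mean.  Averaging acts on composite final scores,
#' not on intensity and percentage separately.
#'
#' @param readings A data frame of readings for a single marker with columns
#'   `marker`, `rater_id`, and -- depending on the scoring system --
#'   `intensity`, `percentage_category` or `percent_stained`.
#' @return A list with elements `marker`, `final_score` (rater mean) and
#'   `call`.
#' @export
#' @examples
#' r <- data.frame(marker = "miR-31", rater_id = c("A", "B"),
#'                 intensity = c(3, 2), percentage_category = c(1, 1))
#' aggregate_raters(r)  # mean score 3.5 -> positive
aggregate_raters <- function(readings) {
  if (!is.data.frame(readings) || nrow(readings) == 0L) {
    stop("readings must be a non-empty data frame", call. = FALSE)
  }
  marker <- unique(readings$marker)
  if (length(marker) != 1L) {
    stop("readings mix markers: ", paste(marker, collapse = ", "),
         call. = FALSE)
  }
  row <- .marker_row(marker)
  per_rater <- switch(row$system,
    additive = score_additive_marker(readings$intensity,
                                     readings$percentage_category),
    intensity = {
      x <- readings$intensity
      if (any(!is.finite(x)) || any(x < 0 | x > 3)) {
        stop("intensity must lie in 0..3", call. = FALSE)
      }
      x
    },
    percent = {
      x <- readings$percent_stained
      if (any(!is.finite(x)) || any(x < 0 | x > 100)) {
        stop("percent_stained must lie in 0..100", call. = FALSE)
      }
      x
    }
  )
  final <- mean(per_rater)
  list(marker = marker, final_score = final,
       call = call_marker(marker, final))
}

#' Relative expression by the 2^-ddCt method
#'
#' Computes the fold change of a target miRNA relative to an endogenous
#' reference (e.g. U6 snRNA) and a calibrator sample:
#' `2^-((Ct_target,sample - Ct_ref,sample) - (Ct_target,cal - Ct_ref,cal))`.
#'
#' @param ct_target_sample,ct_reference_sample Cycle thresholds in the sample.
#' @param ct_target_calibrator,ct_reference_calibrator Cycle thresholds in
#'   the calibrator.
#' @return Positive fold change; 1 means no change relative to calibrator.
#' @export
#' @examples
#' fold_change_ddct(25, 20, 24, 20)  # ddCt = 1 -> 0.5
fold_change_ddct <- function(ct_target_sample, ct_reference_sample,
                             ct_target_calibrator, ct_reference_calibrator) {
  cts <- c(ct_target_sample, ct_reference_sample,
           ct_target_calibrator, ct_reference_calibrator)
  if (!is.numeric(cts) || length(cts) != 4L || any(!is.finite(cts))) {
    stop("all four Ct values must be finite numbers", call. = FALSE)
  }
  ddct <- (ct_target_sample - ct_reference_sample) -
    (ct_target_calibrator - ct_reference_calibrator)
  2^(-ddct)
}

#' Score a table of raw ISH readings into per-patient marker calls
#'
#' Groups a readings table by patient and marker, averages final scores
#' across all raters and tissue cores (the resolution of the two cores per
#' patient is not specified by the scoring systems; all readings for a
#' patient/marker are pooled into the mean, and multi-core patients are
#' counted in a message), and emits one binary call per patient and marker.
#'
#' @param readings Data frame with columns `patient_id`, `marker`,
#'   `rater_id`, optionally `core_id`, and the scoring columns `intensity`,
#'   `percentage_category`, `percent_stained` as required per marker.
#' @param quiet Suppress the multi-core pooling message.
#' @return Data frame with columns `patient_id`, `marker`, `final_score`,
#'   `call`.
#' @export
score_markers <- function(readings, quiet = FALSE) {
  if (!is.data.frame(readings) || nrow(readings) == 0L) {
    stop("readings must be a non-empty data frame", call. = FALSE)
  }
  need <- c("patient_id", "marker", "rater_id")
  miss <- setdiff(need, names(readings))
  if (length(miss)) {
    stop("readings lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if ("core_id" %in% names(readings) && !quiet) {
    ncores <- tapply(readings$core_id,
                     paste(readings$patient_id, readings$marker),
                     function(x) length(unique(x)))
    if (any(ncores > 1L)) {
      message("pooling readings across ", max(ncores),
              " tissue cores per patient/marker (mean of all final scores)")
    }
  }
  keys <- unique(readings[c("patient_id", "marker")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- readings[readings$patient_id == keys$patient_id[i] &
                      readings$marker == keys$marker[i], , drop = FALSE]
    agg <- aggregate_raters(sub)
    data.frame(patient_id = keys$patient_id[i], marker = agg$marker,
               final_score = agg$final_score, call = agg$call,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read a raw ISH readings table from delimited text
#'
#' @param path File path.
#' @param sep Field delimiter, default tab.
#' @param na Missing-value token(s); the default accepts both the empty
#'   string and the literal `NA` written by [write.table()].
#' @return Data frame of readings.
#' @export
read_ish_readings <- function(path, sep = "\t", na = c("", "NA")) {
  utils::read.table(path, header = TRUE, sep = sep, na.strings = na,
                    stringsAsFactors = FALSE, comment.char = "#")
}

#' Write a per-patient marker-call table as delimited text
#'
#' @param calls Data frame as returned by [score_markers()].
#' @param path File path.
#' @param sep Field delimiter, default tab.
#' @export
write_marker_calls <- function(calls, path, sep = "\t") {
  utils::write.table(calls, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
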