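## Domain containers and tabular readers/writers.
##
## Spike events and trial protocols travel as plain data frames with a class
## attribute; all times are seconds from trial start, half-open trial window
## [0, duration). Files are TSV with a header and 6-decimal second precision.

EVENT_TYPES <- c("simple", "complex")
LATERAL_ALLOWED <- c(330, 660, 990)
MODES <- c("pc", "mli", "gc", "thermal")

#' Construct a validated spike-event table
#'
#' A `spike_events` object is a data frame with columns `unit_id`,
#' `trial_id`, `event_type` (`"simple"` or `"complex"`) and `time_s`
#' (seconds from trial start). Rows are sorted by unit, trial, time and
#' validated: times must be non-negative (unless the table is marked as
#' aligned to light onset, in which case pre-stimulus times are negative)
#' and strictly increasing within each (unit, trial, event type) train.
#'
#' @param x data frame with the four columns above.
#' @param aligned logical; `TRUE` when times are referenced to light onset
#'   rather than trial start (see [align_to_light()]).
#' @return A `spike_events` data frame.
#' @examples
#' ev <- spike_events(data.frame(
#'   unit_id = "u1", trial_id = "t1",
#'   event_type = c("simple", "simple", "complex"),
#'   time_s = c(0.01, 0.03, 0.02)))
#' nrow(ev)
#' @export
spike_events <- function(x, aligned = FALSE) {
  required <- c("unit_id", "trial_id", "event_type", "time_s")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("spike event table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.data.frame(x)[required]
  x$unit_id <- as.character(x$unit_id)
  x$trial_id <- as.character(x$trial_id)
  x$event_type <- as.character(x$event_type)
  x$time_s <- as.numeric(x$time_s)
  bad_type <- setdiff(unique(x$event_type), EVENT_TYPES)
  if (length(bad_type) > 0) {
    stop("invalid event_type value(s): ", paste(bad_type, collapse = ", "),
         " (allowed: ", paste(EVENT_TYPES, collapse = ", "), ")",
         call. = FALSE)
  }
  if (anyNA(x$time_s)) stop("non-numeric or missing time_s", call. = FALSE)
  if (!aligned && any(x$time_s < 0)) {
    stop("negative spike times in an unaligned event table", call. = FALSE)
  }
  x <- x[order(x$unit_id, x$trial_id, x$time_s, x$event_type), , drop = FALSE]
  rownames(x) <- NULL
  key <- interaction(x$unit_id, x$trial_id, x$event_type, drop = TRUE)
  for (k in levels(key)) {
    tt <- x$time_s[key == k]
    if (length(tt) > 1 && any(diff(tt) <= 0)) {
      row <- x[key == k, ][1, ]
      stop(sprintf(
        "non-monotone spike times within unit '%s', trial '%s' (%s train)",
        row$unit_id, row$trial_id, row$event_type), call. = FALSE)
    }
  }
  structure(x, class = c("spike_events", "data.frame"), aligned = aligned)
}

#' @export
print.spike_events <- function(x, ...) {
  cat(sprintf("<spike_events> %d events, %d unit(s), %d trial(s)%s\n",
              nrow(x), length(unique(x$unit_id)),
              length(unique(x$trial_id)),
              if (isTRUE(attr(x, "aligned"))) ", aligned to light onset" else ""))
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

is_aligned <- function(events) isTRUE(attr(events, "aligned"))

#' Construct a validated light-protocol table
#'
#' One row per trial: stimulus epoch, laser power at the source and at the
#' fiber tip, and the fiber position relative to the recorded cell
#' (`fiber_depth_um` negative when the tip sits above the cell;
#' `lateral_um` a multiple of the 330 um guide-tube spacing).
#'
#' @param x data frame with columns `trial_id`, `trial_duration_s`,
#'   `light_on_s`, `light_off_s`, `laser_power_mw`, `tip_power_mw`,
#'   `fiber_depth_um`, `lateral_um`, `mode`.
#' @return A `light_protocol` data frame.
#' @export
light_protocol <- function(x) {
  required <- c("trial_id", "trial_duration_s", "light_on_s", "light_off_s",
                "laser_power_mw", "tip_power_mw", "fiber_depth_um",
                "lateral_um", "mode")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("protocol table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.data.frame(x)[required]
  x$trial_id <- as.character(x$trial_id)
  x$mode <- as.character(x$mode)
  num_cols <- setdiff(required, c("trial_id", "mode"))
  for (cc in num_cols) x[[cc]] <- as.numeric(x[[cc]])
  if (anyDuplicated(x$trial_id)) stop("duplicate trial_id in protocol", call. = FALSE)
  bad_mode <- setdiff(unique(x$mode), MODES)
  if (length(bad_mode) > 0) {
    stop("invalid mode value(s): ", paste(bad_mode, collapse = ", "), call. = FALSE)
  }
  ok_epoch <- x$light_on_s >= 0 & x$light_on_s < x$light_off_s &
    x$light_off_s <= x$trial_duration_s
  if (!all(ok_epoch)) {
    stop("protocol requires 0 <= light_on < light_off <= trial_duration (trial ",
         x$trial_id[which(!ok_epoch)[1]], ")", call. = FALSE)
  }
  if (!all(x$lateral_um %in% LATERAL_ALLOWED)) {
    stop("lateral_um must be one of ", paste(LATERAL_ALLOWED, collapse = ", "),
         call. = FALSE)
  }
  if (any(x$tip_power_mw > x$laser_power_mw)) {
    stop("tip_power_mw cannot exceed laser_power_mw", call. = FALSE)
  }
  x <- x[order(x$trial_id), , drop = FALSE]
  rownames(x) <- NULL
  structure(x, class = c("light_protocol", "data.frame"))
}

#' Read / write spike-event tables
#'
#' TSV with header columns `unit_id`, `trial_id`, `event_type`, `time_s`.
#' `write_events()` emits rows sorted by unit, trial, time with times
#' printed at 6-decimal second precision, so `read_events(write_events(x))`
#' round-trips exactly for tables already at that precision.
#'
#' @param path file path.
#' @return `read_events()` returns a validated [spike_events()] table.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  spike_events(df)
}

#' @rdname read_events
#' @param events a [spike_events()] table.
#' @export
write_events <- function(events, path) {
  events <- spike_events(events, aligned = is_aligned(events))
  out <- as.data.frame(events)
  out$time_s <- sprintf("%.6f", out$time_s)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read / write trial-protocol tables
#'
#' TSV with the columns of [light_protocol()]; seconds at 6-decimal
#' precision, powers and positions as printed.
#'
#' @param path file path.
#' @return `read_protocol()` returns a validated [light_protocol()] table.
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  light_protocol(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' @rdname read_protocol
#' @param protocol a [light_protocol()] table.
#' @export
write_protocol <- function(protocol, path) {
  protocol <- light_protocol(protocol)
  out <- as.data.frame(protocol)
  for (cc in c("trial_duration_s", "light_on_s", "light_off_s")) {
    out[[cc]] <- sprintf("%.6f", out[[cc]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Re-reference spike times to light onset
#'
#' Subtracts each trial's `light_on_s` from its spike times, so time 0 is
#' light onset and pre-stimulus times are negative. A spike exactly at
#' light onset maps to 0 and belongs to the light-on epoch (closed-left
#' convention). Aligning an already-aligned table is an error.
#'
#' @param events a [spike_events()] table.
#' @param protocol a [light_protocol()] table covering every trial in
#'   `events`.
#' @return A [spike_events()] table with `aligned = TRUE`.
#' @export
align_to_light <- function(events, protocol) {
  if (is_aligned(events)) {
    stop("events are already aligned to light onset", call. = FALSE)
  }
  protocol <- light_protocol(protocol)
  idx <- match(events$trial_id, protocol$trial_id)
  if (anyNA(idx)) {
    stop("trial_id not found in protocol: ",
         paste(unique(events$trial_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  out <- as.data.frame(events)
  out$time_s <- out$time_s - protocol$light_on_s[idx]
  spike_events(out, aligned = TRUE)
}
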