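# Session container: one recording = tracking + events + spikes + units +
# LFP + config (+ optional ground truth for synthetic sessions).

SCHEMA_VERSION <- "1"

EVENT_TYPES <- c("trigger_beam", "reward_port", "reward_delivered",
                 "light_pulse_on")

#' Construct a session object
#'
#' A session bundles everything recorded in one run of the linear-track task:
#' video tracking of the head and tail-base markers, task events (beam breaks,
#' reward deliveries, light pulses), sorted single-unit spike times, unit
#' metadata, and the LFP trace. All timestamps are seconds from a common zero.
#'
#' @param tracking tibble with columns `frame_time_s`, `head_x`, `head_y`,
#'   `tail_x`, `tail_y`, `valid`.
#' @param events tibble with columns `time_s`, `event_type`, `payload`.
#' @param spikes tibble with columns `unit_id`, `time_s`.
#' @param units tibble with one row per unit (waveform features etc.).
#' @param lfp list with `samples` (numeric, microvolt), `rate_hz`, `site_id`.
#' @param config list of generation/acquisition parameters.
#' @param truth optional ground-truth list (synthetic sessions only).
#' @param meta list of session metadata; must include `hemisphere`
#'   (`"left"` or `"right"`) and `arena` geometry.
#' @return an object of class `ephys_session`.
#' @export
new_session <- function(tracking, events, spikes, units, lfp = NULL,
                        config = list(), truth = NULL, meta = list()) {
  meta$schema_version <- SCHEMA_VERSION
  structure(
    list(tracking = as_tibble(tracking), events = as_tibble(events),
         spikes = as_tibble(spikes), units = as_tibble(units),
         lfp = lfp, config = config, truth = truth, meta = meta),
    class = "ephys_session")
}

#' @export
print.ephys_session <- function(x, ...) {
  dur <- if (nrow(x$tracking)) max(x$tracking$frame_time_s) else 0
  cat(sprintf("<ephys_session> %.1f s, %d frames, %d units, %d spikes\n",
              dur, nrow(x$tracking), nrow(x$units), nrow(x$spikes)))
  if (!is.null(x$lfp))
    cat(sprintf("  LFP: %d samples @ %g Hz\n",
                length(x$lfp$samples), x$lfp$rate_hz))
  if (!is.null(x$truth)) cat("  ground truth attached\n")
  invisible(x)
}

#' Write a session to a directory
#'
#' Tables go to CSV, the LFP to little-endian float32 (`lfp.bin` +
#' `lfp_meta.json`), config and ground truth to JSON.
#'
#' @param session an `ephys_session`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(session$tracking, file.path(dir, "tracking.csv"), row.names = FALSE)
  write.csv(session$events, file.path(dir, "events.csv"), row.names = FALSE)
  write.csv(session$spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  units <- session$units
  # flatten list-columns (waveforms) for CSV round-tripping
  listcols <- names(units)[vapply(units, is.list, logical(1))]
  for (lc in listcols) {
    units[[lc]] <- vapply(units[[lc]], function(v)
      paste(signif(v, 7), collapse = ";"), character(1))
  }
  write.csv(units, file.path(dir, "units.csv"), row.names = FALSE)
  if (!is.null(session$lfp)) {
    con <- file(file.path(dir, "lfp.bin"), "wb")
    writeBin(as.numeric(session$lfp$samples), con, size = 4,
             endian = "little")
    close(con)
    jsonlite::write_json(
      list(rate_hz = session$lfp$rate_hz,
           site_id = session$lfp$site_id %||% "site1",
           dtype = "float32", endian = "little"),
      file.path(dir, "lfp_meta.json"), auto_unbox = TRUE)
  }
  jsonlite::write_json(c(session$config,
                         list(meta = session$meta)),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(session$truth))
    jsonlite::write_json(session$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session from a directory
#'
#' @param dir directory written by [write_session()].
#' @return an `ephys_session`.
#' @export
read_session <- function(dir) {
  rd <- function(f) as_tibble(read.csv(file.path(dir, f)))
  tracking <- rd("tracking.csv")
  events <- rd("events.csv")
  spikes <- rd("spikes.csv")
  units <- rd("units.csv")
  for (lc in intersect(c("mean_waveform"), names(units))) {
    units[[lc]] <- lapply(strsplit(units[[lc]], ";"), as.numeric)
  }
  lfp <- NULL
  if (file.exists(file.path(dir, "lfp.bin"))) {
    m <- jsonlite::read_json(file.path(dir, "lfp_meta.json"),
                             simplifyVector = TRUE)
    n <- file.info(file.path(dir, "lfp.bin"))$size / 4
    con <- file(file.path(dir, "lfp.bin"), "rb")
    samples <- readBin(con, numeric(), n = n, size = 4, endian = "little")
    close(con)
    lfp <- list(samples = samples, rate_hz = m$rate_hz, site_id = m$site_id)
  }
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  meta <- cfg$meta %||% list()
  cfg$meta <- NULL
  truth <- if (file.exists(file.path(dir, "truth.json")))
    jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  new_session(tracking, events, spikes, units, lfp, cfg, truth, meta)
}

#' Validate a session container
#'
#' Schema and invariant checks. Fatal problems (missing columns, unknown
#' event types) are reported as errors; repairable ones (unsorted spike
#' times) as warnings, with the repair applied to the returned session.
#'
#' @param session an `ephys_session`.
#' @return a list with `report` (tibble: level, message) and `session`
#'   (possibly repaired).
#' @export
validate_session <- function(session) {
  rep <- list()
  note <- function(level, msg) rep[[length(rep) + 1]] <<- tibble(
    level = level, message = msg)
  need <- list(
    tracking = c("frame_time_s", "head_x", "head_y", "tail_x", "tail_y",
                 "valid"),
    events = c("time_s", "event_type"),
    spikes = c("unit_id", "time_s"))
  for (tab in names(need)) {
    missing <- setdiff(need[[tab]], names(session[[tab]]))
    if (length(missing))
      note("error", sprintf("%s.csv missing column(s): %s", tab,
                            paste(missing, collapse = ", ")))
  }
  if (nrow(session$events)) {
    bad <- setdiff(unique(session$events$event_type), EVENT_TYPES)
    if (length(bad))
      note("error", sprintf("unknown event_type: %s",
                            paste(bad, collapse = ", ")))
  }
  ft <- session$tracking$frame_time_s
  if (length(ft) > 1 && any(diff(ft) <= 0))
    note("error", "tracking frame times are not strictly increasing")
  if (nrow(session$spikes) > 1) {
    st <- session$spikes |>
      dplyr::group_by(.data$unit_id) |>
      dplyr::summarise(sorted = !is.unsorted(.data$time_s))
    if (any(!st$sorted)) {
      note("warning", "spike times not sorted within unit; sorting applied")
      session$spikes <- dplyr::arrange(session$spikes, .data$unit_id,
                                       .data$time_s)
    }
  }
  report <- if (length(rep)) dplyr::bind_rows(rep) else
    tibble(level = character(), message = character())
  list(report = report, session = session)
}
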