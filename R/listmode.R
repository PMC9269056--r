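# List-mode containers, event filters (energy window, LOR angle allowance)
# and the list-mode file format.

LM_MAGIC <- "PLANARPETLM"
LM_VERSION <- 1L
EVENT_COLS <- c("x1", "y1", "x2", "y2", "e1", "e2", "t", "label")

empty_events <- function() {
  data.frame(x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric(),
             e1 = numeric(), e2 = numeric(), t = numeric(),
             label = character())
}

#' List-mode coincidence set
#'
#' Container for an acquisition: one row per coincidence with the endpoint
#' coordinates on head A (z = +sep/2) and head B (z = -sep/2) in mm, the two
#' observed photon energies in keV, the event time in seconds from
#' acquisition start, and a ground-truth label (`"true"`, `"scatter"` or
#' `"random"`).
#'
#' @param events data frame with columns `x1, y1, x2, y2, e1, e2, t, label`,
#'   time-ordered.
#' @param windows the [acquisition_windows()] in force.
#' @param geom the [build_detector()] geometry.
#' @param duration acquisition duration in seconds.
#' @param meta named list of frame metadata (start time, activity,
#'   concentration, seeds).
#' @return An object of class `listmode_set`.
#' @export
listmode_set <- function(events, windows, geom, duration, meta = list()) {
  stopifnot(all(EVENT_COLS %in% names(events)))
  if (is.unsorted(events$t)) stop_validation("events must be time-ordered")
  structure(list(events = events[, EVENT_COLS, drop = FALSE],
                 windows = windows, geom = geom,
                 duration = duration, meta = meta),
            class = "listmode_set")
}

#' @export
print.listmode_set <- function(x, ...) {
  tab <- table(factor(x$events$label, c("true", "scatter", "random")))
  cat(sprintf("listmode_set: %d events in %.4g s (%d true, %d scatter, %d random)\n",
              nrow(x$events), x$duration, tab[1], tab[2], tab[3]))
  if (!is.null(x$meta$concentration_kbq_ml))
    cat(sprintf("  concentration: %.4g kBq/mL\n", x$meta$concentration_kbq_ml))
  invisible(x)
}

#' Number of events and event rate
#'
#' @param set a [listmode_set()].
#' @return `n_events`: event count; `event_rate`: events per second.
#' @export
n_events <- function(set) nrow(set$events)

#' @rdname n_events
#' @export
event_rate <- function(set) nrow(set$events) / set$duration

#' Energy-window filter
#'
#' Keeps events whose two photon energies both lie in `[low, high]` keV.
#' Order is preserved and surviving records are unaltered.
#'
#' @param set a [listmode_set()].
#' @param low,high window bounds in keV.
#' @return The filtered [listmode_set()].
#' @export
apply_energy_window <- function(set, low = 350, high = 700) {
  if (low >= high) stop_domain("low must be < high")
  ev <- set$events
  keep <- ev$e1 >= low & ev$e1 <= high & ev$e2 >= low & ev$e2 <= high
  set$events <- ev[keep, , drop = FALSE]
  rownames(set$events) <- NULL
  set$windows$energy_low <- max(set$windows$energy_low, low)
  set$windows$energy_high <- min(set$windows$energy_high, high)
  set
}

#' LOR angle-allowance filter
#'
#' Discards oblique lines of response: an event is kept when the transverse
#' displacement between its two endpoints does not exceed `allowance` mm.
#' The default metric is the Euclidean displacement
#' `sqrt((x1-x2)^2 + (y1-y2)^2)`; `mode = "per_axis"` instead requires
#' `|x1-x2| <= allowance` and `|y1-y2| <= allowance` separately.
#'
#' @param set a [listmode_set()].
#' @param allowance maximum endpoint displacement in mm (>= 0).
#' @param mode `"radial"` (default) or `"per_axis"`.
#' @return The filtered [listmode_set()].
#' @export
apply_angle_allowance <- function(set, allowance,
                                  mode = c("radial", "per_axis")) {
  if (allowance < 0) stop_domain("allowance must be >= 0")
  mode <- match.arg(mode)
  ev <- set$events
  dx <- ev$x1 - ev$x2
  dy <- ev$y1 - ev$y2
  keep <- if (mode == "radial") sqrt(dx^2 + dy^2) <= allowance
          else abs(dx) <= allowance & abs(dy) <= allowance
  set$events <- ev[keep, , drop = FALSE]
  rownames(set$events) <- NULL
  set$meta$angle_allowance_mm <- allowance
  set$meta$angle_allowance_mode <- mode
  set
}

lm_error <- function(class, ...) {
  stop(errorCondition(paste0(...),
                      class = c(class, "planarpet_io_error", "error")))
}

#' Write / read the list-mode binary format
#'
#' The format is a versioned header (magic string, format version, JSON
#' metadata carrying the geometry, windows, duration and frame metadata)
#' followed by the event table as little-endian doubles plus integer label
#' codes. Writing then reading reproduces every field bit-exactly.
#'
#' @param set a [listmode_set()].
#' @param path file path.
#' @return `write_listmode` returns `path` invisibly; `read_listmode`
#'   returns the [listmode_set()].
#' @export
write_listmode <- function(set, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- list(
    version = LM_VERSION,
    n_events = nrow(set$events),
    duration = set$duration,
    windows = unclass(set$windows),
    geometry = unclass(set$geom),
    meta = set$meta)
  hjson <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA,
                                      null = "null"))
  writeBin(charToRaw(LM_MAGIC), con)
  writeBin(length(hjson), con, size = 4L, endian = "little")
  writeBin(hjson, con)
  ev <- set$events
  num <- as.numeric(t(as.matrix(ev[, EVENT_COLS[1:7]])))
  writeBin(num, con, size = 8L, endian = "little")
  codes <- match(ev$label, c("true", "scatter", "random"))
  if (anyNA(codes)) lm_error("planarpet_integrity_error",
                             "unknown truth label in event table")
  writeBin(as.integer(codes), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_listmode
#' @export
read_listmode <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", nchar(LM_MAGIC)))
  if (!identical(magic, LM_MAGIC))
    lm_error("planarpet_format_error", "not a planarpet list-mode file: ", path)
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(hlen) != 1L || is.na(hlen) || hlen <= 0)
    lm_error("planarpet_truncated_error", "truncated header in ", path)
  hraw <- readBin(con, "raw", hlen)
  if (length(hraw) != hlen)
    lm_error("planarpet_truncated_error", "truncated header in ", path)
  header <- jsonlite::fromJSON(rawToChar(hraw), simplifyVector = TRUE)
  if (!identical(as.integer(header$version), LM_VERSION))
    lm_error("planarpet_version_error", "unsupported list-mode version: ",
             header$version)
  n <- as.integer(header$n_events)
  num <- readBin(con, "numeric", n * 7L, size = 8L, endian = "little")
  codes <- readBin(con, "integer", n, size = 4L, endian = "little")
  if (length(num) != n * 7L || length(codes) != n)
    lm_error("planarpet_truncated_error", "truncated event records in ", path)
  if (n > 0 && (anyNA(codes) || any(codes < 1L | codes > 3L)))
    lm_error("planarpet_integrity_error", "invalid label codes in ", path)
  m <- matrix(num, ncol = 7L, byrow = TRUE,
              dimnames = list(NULL, EVENT_COLS[1:7]))
  ev <- as.data.frame(m)
  ev$label <- c("true", "scatter", "random")[codes]
  if (n == 0) ev <- empty_events()
  geom <- do.call(build_detector, header$geometry[
    setdiff(names(header$geometry), c("head_size_x", "head_size_y"))])
  win <- do.call(acquisition_windows, header$windows)
  meta <- header$meta
  listmode_set(ev, win, geom, header$duration,
               meta = if (is.null(meta)) list() else meta)
}

#' CSV export / import of a list-mode set
#'
#' Writes the event table to plain CSV plus a JSON sidecar (`<path>.meta.json`)
#' carrying the acquisition metadata. Round-tripping preserves fields to the
#' printed precision (15 significant digits).
#'
#' @param set a [listmode_set()].
#' @param path CSV file path.
#' @return `export_listmode_csv` returns `path` invisibly;
#'   `import_listmode_csv` the [listmode_set()].
#' @export
export_listmode_csv <- function(set, path) {
  ev <- set$events
  for (cc in EVENT_COLS[1:7]) ev[[cc]] <- formatC(ev[[cc]], digits = 15,
                                                  format = "g")
  write.csv(ev, path, row.names = FALSE, quote = FALSE)
  meta <- list(version = LM_VERSION, duration = set$duration,
               windows = unclass(set$windows), geometry = unclass(set$geom),
               meta = set$meta)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             paste0(path, ".meta.json"))
  invisible(path)
}

#' @rdname export_listmode_csv
#' @export
import_listmode_csv <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path))
    lm_error("planarpet_format_error", "missing metadata sidecar ", meta_path)
  header <- jsonlite::fromJSON(meta_path, simplifyVector = TRUE)
  ev <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(rep("numeric", 7), "character"))
  if (nrow(ev) == 0) ev <- empty_events()
  geom <- do.call(build_detector, header$geometry[
    setdiff(names(header$geometry), c("head_size_x", "head_size_y"))])
  win <- do.call(acquisition_windows, header$windows)
  meta <- header$meta
  listmode_set(ev, win, geom, header$duration,
               meta = if (is.null(meta)) list() else meta)
}
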