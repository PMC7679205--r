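# Core data model: home schema, sensor event logs, day segmentation,
# pain/pain-free day labeling.

#' The 13 daily-activity classes, in canonical order
#'
#' Activity vocabulary used throughout the package: every labeled sensor
#' event carries exactly one of these classes, and the activity-wise hourly
#' series follow this order.
#'
#' @return Character vector of length 13.
#' @export
activity_vocabulary <- function() {
  c("Bathe", "Bed-Toilet Transition", "Cook", "Eat", "Enter Home",
    "Leave Home", "Personal Hygiene", "Relax", "Sleep", "Take Medicine",
    "Wash Dishes", "Work", "Other Activity")
}

#' The 36 canonical in-home location names, in canonical order
#'
#' The marker schema is defined over a fixed set of 36 locations so that
#' marker vectors from different homes are comparable; homes lacking a
#' location simply produce all-zero series for it.
#'
#' @return Character vector of length 36.
#' @export
location_vocabulary <- function() {
  c("bed", "bedroom", "bedroom_closet", "guest_bedroom",
    "toilet", "bathroom_sink", "shower", "bathtub", "medicine_cabinet",
    "hallway", "hallway_night",
    "kitchen", "stove", "fridge", "kitchen_sink", "pantry", "dining_table",
    "living_room", "recliner", "sofa", "tv_area",
    "office", "desk", "bookshelf",
    "laundry", "utility", "garage", "basement", "stairs",
    "sunroom", "porch", "entryway", "workshop",
    "front_door", "back_door", "garage_door")
}

#' Construct a home schema
#'
#' A home schema maps each physical sensor to one named location with planar
#' coordinates (meters), and fixes the location and activity vocabularies
#' that define the behavior-marker layout.
#'
#' @param sensors data.frame with columns `sensor_id`, `sensor_type`
#'   (`"PIR"` or `"DOOR"`), `location`, `x`, `y`.
#' @param locations ordered character vector of location names; defaults to
#'   the canonical 36-entry vocabulary.
#' @param activities ordered character vector of activity classes; defaults
#'   to the canonical 13-entry vocabulary.
#' @return An object of class `home_schema`.
#' @export
home_schema <- function(sensors,
                        locations = location_vocabulary(),
                        activities = activity_vocabulary()) {
  stopifnot(is.data.frame(sensors),
            all(c("sensor_id", "sensor_type", "location", "x", "y") %in%
                  names(sensors)))
  sensors$sensor_id <- as.character(sensors$sensor_id)
  sensors$location <- as.character(sensors$location)
  if (anyDuplicated(sensors$sensor_id))
    stop("duplicate sensor_id in schema")
  if (!all(sensors$sensor_type %in% c("PIR", "DOOR")))
    stop("sensor_type must be PIR or DOOR")
  if (!all(sensors$location %in% locations))
    stop("schema error: sensor location not in location vocabulary: ",
         paste(setdiff(sensors$location, locations), collapse = ", "))
  if (length(locations) != 36L)
    stop("location vocabulary must have exactly 36 entries")
  if (length(activities) != 13L)
    stop("activity vocabulary must have exactly 13 entries")
  if (any(!is.finite(sensors$x)) || any(!is.finite(sensors$y)))
    stop("schema error: sensor coordinates must be finite")
  structure(list(sensors = sensors,
                 locations = locations,
                 activities = activities),
            class = "home_schema")
}

#' Canonical single-occupant home schema
#'
#' One PIR sensor per in-home location and one magnetic contact sensor per
#' door, laid out on a plausible single-floor plan. This is the schema the
#' synthetic generator emits and the marker extractor assumes by default.
#'
#' @return A `home_schema`.
#' @export
canonical_home_schema <- function() {
  locs <- location_vocabulary()
  # approximate single-floor plan, meters from the south-west corner
  xy <- matrix(c(
    2.0, 9.0,   # bed
    3.5, 8.5,   # bedroom
    4.8, 9.5,   # bedroom_closet
    7.5, 9.0,   # guest_bedroom
    1.0, 6.5,   # toilet
    2.2, 6.0,   # bathroom_sink
    1.0, 5.2,   # shower
    2.0, 5.0,   # bathtub
    2.8, 6.5,   # medicine_cabinet
    4.5, 6.5,   # hallway
    4.5, 7.8,   # hallway_night
    8.0, 6.5,   # kitchen
    9.0, 7.0,   # stove
    9.5, 6.0,   # fridge
    8.5, 5.5,   # kitchen_sink
    10.2, 6.8,  # pantry
    7.0, 4.5,   # dining_table
    4.0, 2.5,   # living_room
    3.0, 1.5,   # recliner
    5.0, 1.5,   # sofa
    4.0, 0.8,   # tv_area
    9.5, 2.5,   # office
    10.0, 1.8,  # desk
    10.5, 3.0,  # bookshelf
    11.5, 5.0,  # laundry
    11.5, 6.0,  # utility
    13.0, 2.0,  # garage
    12.5, 8.5,  # basement
    6.0, 5.5,   # stairs
    0.5, 2.5,   # sunroom
    1.5, 0.2,   # porch
    6.5, 0.5,   # entryway
    13.5, 4.0,  # workshop
    6.5, 0.0,   # front_door
    8.5, 9.8,   # back_door
    12.5, 1.0), # garage_door
    ncol = 2, byrow = TRUE)
  is_door <- grepl("_door$", locs)
  ids <- character(length(locs))
  ids[!is_door] <- sprintf("M%03d", seq_len(sum(!is_door)))
  ids[is_door] <- sprintf("D%03d", seq_len(sum(is_door)))
  home_schema(data.frame(sensor_id = ids,
                         sensor_type = ifelse(is_door, "DOOR", "PIR"),
                         location = locs,
                         x = xy[, 1], y = xy[, 2],
                         stringsAsFactors = FALSE))
}

#' @export
print.home_schema <- function(x, ...) {
  cat("home_schema:", nrow(x$sensors), "sensors,",
      length(x$locations), "locations,",
      length(x$activities), "activity classes\n")
  invisible(x)
}

#' Write / read a home schema as YAML
#'
#' @param schema a `home_schema`.
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return `read_home_schema` returns a `home_schema`.
#' @export
write_home_schema <- function(schema, path) {
  rows <- lapply(seq_len(nrow(schema$sensors)), function(i)
    as.list(schema$sensors[i, ]))
  obj <- list(sensors = rows,
              location_vocabulary = schema$locations,
              activity_vocabulary = schema$activities)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' @rdname write_home_schema
#' @export
read_home_schema <- function(path) {
  obj <- if (grepl("\\.json$", path)) jsonlite::read_json(path) else
    yaml::read_yaml(path)
  sens <- do.call(rbind, lapply(obj$sensors, function(s)
    data.frame(sensor_id = s$sensor_id, sensor_type = s$sensor_type,
               location = s$location, x = as.numeric(s$x),
               y = as.numeric(s$y), stringsAsFactors = FALSE)))
  home_schema(sens,
              locations = unlist(obj$location_vocabulary),
              activities = unlist(obj$activity_vocabulary))
}

# internal: construct an event_log data.frame from parallel vectors
new_event_log <- function(timestamp, sensor_id, sensor_type, state,
                          activity = NA_character_) {
  df <- data.frame(timestamp = timestamp,
                   sensor_id = as.character(sensor_id),
                   sensor_type = as.character(sensor_type),
                   state = as.character(state),
                   activity = as.character(activity),
                   stringsAsFactors = FALSE)
  class(df) <- c("event_log", "data.frame")
  df
}

#' An empty event log
#' @param schema unused; present for interface symmetry.
#' @return An `event_log` with zero rows.
#' @export
empty_event_log <- function(schema = NULL) {
  new_event_log(as.POSIXct(character(), tz = "UTC"),
                character(), character(), character(), character())
}

#' Read an ambient sensor event log
#'
#' Accepts two dialects: whitespace-delimited lines
#' `YYYY-MM-DD HH:MM:SS.ffffff sensor_id state [activity label]`
#' (the activity label, which may contain spaces, is everything after the
#' state), or CSV with header `timestamp,sensor_id,sensor_type,state,activity`.
#' States are canonicalized (trimmed, upper-cased) to `ON`/`OFF`. Timestamps
#' are parsed as naive local time and stored in UTC; sub-second precision is
#' preserved to the microsecond.
#'
#' @param path path to the log file.
#' @param schema a `home_schema`; events from sensors absent from the schema
#'   are rejected.
#' @return An `event_log` (data.frame with columns `timestamp`, `sensor_id`,
#'   `sensor_type`, `state`, `activity`) in nondecreasing timestamp order.
#' @export
read_event_log <- function(path, schema) {
  stopifnot(inherits(schema, "home_schema"))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) return(empty_event_log())

  is_csv <- grepl("^\\s*timestamp\\s*,", lines[1])
  if (is_csv) {
    df <- utils::read.csv(text = lines, stringsAsFactors = FALSE,
                          colClasses = "character")
    need <- c("timestamp", "sensor_id", "state")
    if (!all(need %in% names(df)))
      stop("parse error: CSV header missing columns: ",
           paste(setdiff(need, names(df)), collapse = ", "))
    ts_chr <- df$timestamp
    sensor <- trimws(df$sensor_id)
    state <- df$state
    act <- if ("activity" %in% names(df)) df$activity else
      rep(NA_character_, nrow(df))
    lineno <- lineno[-1][seq_len(nrow(df))]
  } else {
    m <- regmatches(lines, regexec(
      "^\\s*(\\S+)\\s+(\\S+)\\s+(\\S+)\\s+(\\S+)(?:\\s+(.*\\S))?\\s*$",
      lines))
    bad <- which(vapply(m, length, 1L) == 0L)
    if (length(bad))
      stop("parse error at line ", lineno[bad[1]], ": malformed event line")
    m <- do.call(rbind, m)
    ts_chr <- paste(m[, 2], m[, 3])
    sensor <- m[, 4]
    state <- m[, 5]
    act <- m[, 6]
    act[act == ""] <- NA_character_
  }

  state <- toupper(trimws(state))
  badst <- which(!state %in% c("ON", "OFF"))
  if (length(badst))
    stop("parse error at line ", lineno[badst[1]],
         ": state must be ON or OFF, got \"", state[badst[1]], "\"")
  ts <- as.POSIXct(ts_chr, tz = "UTC", format = "%Y-%m-%d %H:%M:%OS")
  badts <- which(is.na(ts))
  if (length(badts))
    stop("parse error at line ", lineno[badts[1]],
         ": unparseable timestamp \"", ts_chr[badts[1]], "\"")

  unknown <- which(!sensor %in% schema$sensors$sensor_id)
  if (length(unknown))
    stop("schema error at line ", lineno[unknown[1]],
         ": sensor not in schema: ", sensor[unknown[1]])
  act <- ifelse(is.na(act), NA_character_, trimws(act))
  act[!is.na(act) & !nzchar(act)] <- NA_character_
  bada <- which(!is.na(act) & !act %in% schema$activities)
  if (length(bada))
    stop("parse error at line ", lineno[bada[1]],
         ": unknown activity label \"", act[bada[1]], "\"")

  stype <- schema$sensors$sensor_type[match(sensor, schema$sensors$sensor_id)]
  log <- new_event_log(ts, sensor, stype, state, act)
  ord <- order(log$timestamp)
  log <- log[ord, , drop = FALSE]
  rownames(log) <- NULL
  class(log) <- c("event_log", "data.frame")
  message(sprintf("read_event_log: parsed %d events from %s",
                  nrow(log), path))
  log
}

#' Write an event log
#'
#' @param log an `event_log`.
#' @param path output path.
#' @param format `"text"` (canonical whitespace-delimited dialect) or
#'   `"csv"`.
#' @export
write_event_log <- function(log, path, format = c("text", "csv")) {
  format <- match.arg(format)
  ts <- format(log$timestamp, "%Y-%m-%d %H:%M:%OS6", tz = "UTC")
  if (format == "csv") {
    df <- data.frame(timestamp = ts, sensor_id = log$sensor_id,
                     sensor_type = log$sensor_type, state = log$state,
                     activity = ifelse(is.na(log$activity), "",
                                       log$activity))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    act <- ifelse(is.na(log$activity), "", paste0(" ", log$activity))
    writeLines(paste0(ts, " ", log$sensor_id, " ", log$state, act), path)
  }
  invisible(path)
}

#' Construct one participant-day of events
#'
#' @param participant_id participant identifier.
#' @param date calendar day (`Date`).
#' @param events an `event_log` whose events all fall within
#'   `[date 00:00, date+1 00:00)`.
#' @param label `"pain"`, `"pain_free"` or `"unlabeled"`.
#' @param event_id identifier of the associated pain event (for pain days
#'   and their matched controls), or `NA`.
#' @return A `day_segment`.
#' @export
day_segment <- function(participant_id, date, events,
                        label = "unlabeled", event_id = NA_character_) {
  date <- as.Date(date)
  stopifnot(label %in% c("pain", "pain_free", "unlabeled"))
  if (nrow(events)) {
    d0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
    if (any(events$timestamp < d0) ||
        any(events$timestamp >= d0 + 86400))
      stop("day_segment: events outside [00:00, 24:00) of ", date)
  }
  structure(list(participant_id = participant_id, date = date,
                 events = events, label = label, event_id = event_id),
            class = "day_segment")
}

#' @export
print.day_segment <- function(x, ...) {
  cat(sprintf("day_segment %s %s: %d events, label=%s\n",
              x$participant_id, format(x$date), nrow(x$events), x$label))
  invisible(x)
}

#' Segment an event log into calendar days
#'
#' Splits a time-sorted log at local midnights (half-open day windows
#' `[00:00, 24:00)`). Every calendar day spanned by the log is emitted, so
#' days without any events appear as empty segments.
#'
#' @param log an `event_log`, sorted by timestamp.
#' @param participant_id identifier carried into the segments.
#' @return List of `day_segment`, one per day from the first to the last
#'   day of the log (empty list for an empty log).
#' @export
segment_days <- function(log, participant_id = "P") {
  if (nrow(log) == 0L) return(list())
  if (is.unsorted(as.numeric(log$timestamp)))
    stop("ordering error: event log is not sorted by timestamp")
  day <- as.Date(log$timestamp, tz = "UTC")
  span <- seq(min(day), max(day), by = "day")
  idx <- split(seq_len(nrow(log)), factor(as.character(day),
                                          levels = as.character(span)))
  lapply(seq_along(span), function(i) {
    ev <- log[idx[[i]], , drop = FALSE]
    rownames(ev) <- NULL
    class(ev) <- c("event_log", "data.frame")
    day_segment(participant_id, span[i], ev)
  })
}

# internal: does calendar day d overlap interval [start, end)?
day_overlaps <- function(d, start, end) {
  d0 <- as.POSIXct(paste(as.Date(d), "00:00:00"), tz = "UTC")
  start < d0 + 86400 & end > d0
}

#' Label days as pain, pain-free, or unlabeled
#'
#' A day is labeled `pain` iff it overlaps any pain-event interval of its
#' participant. Days falling inside a declared normal week that overlap no
#' pain event are candidate `pain_free` days; per participant, exactly as
#' many pain-free days as pain days are retained (the balanced-design rule),
#' choosing the candidates nearest in time to a pain day, ties going to the
#' earlier date. All remaining days are `unlabeled`. Each labeled day
#' records the pain event it belongs to (pain days) or was matched to
#' (controls), which downstream cross-validation uses as the grouping unit.
#'
#' @param segments list of `day_segment`.
#' @param pain_events data.frame with columns `participant_id`, `start`,
#'   `end` (POSIXct), `type`; an `event_id` column is added if missing.
#' @param normal_weeks data.frame with columns `participant_id`, `start`,
#'   `end` (Dates, inclusive).
#' @return The segments, relabeled.
#' @export
label_days <- function(segments, pain_events, normal_weeks) {
  if (is.null(pain_events$event_id))
    pain_events$event_id <- sprintf("E%03d", seq_len(nrow(pain_events)))
  if (nrow(pain_events)) {
    bad <- !(pain_events$start < pain_events$end)
    if (any(bad)) stop("pain event with start >= end")
    # a pain event may not overlap a declared normal week
    for (i in seq_len(nrow(pain_events))) {
      nw <- normal_weeks[normal_weeks$participant_id ==
                           pain_events$participant_id[i], , drop = FALSE]
      for (j in seq_len(nrow(nw))) {
        w0 <- as.POSIXct(paste(as.Date(nw$start[j]), "00:00:00"), tz = "UTC")
        w1 <- as.POSIXct(paste(as.Date(nw$end[j]) + 1, "00:00:00"),
                         tz = "UTC")
        if (pain_events$start[i] < w1 && pain_events$end[i] > w0)
          stop("consistency error: pain event ", pain_events$event_id[i],
               " overlaps a declared normal week")
      }
    }
  }

  pid <- vapply(segments, function(s) s$participant_id, "")
  dates <- as.Date(vapply(segments, function(s) as.character(s$date), ""))
  label <- rep("unlabeled", length(segments))
  evid <- rep(NA_character_, length(segments))

  for (p in unique(pid)) {
    rows <- which(pid == p)
    pe <- pain_events[pain_events$participant_id == p, , drop = FALSE]
    nw <- normal_weeks[normal_weeks$participant_id == p, , drop = FALSE]
    # pain days: overlap rule
    for (r in rows) {
      for (i in seq_len(nrow(pe))) {
        if (day_overlaps(dates[r], pe$start[i], pe$end[i])) {
          label[r] <- "pain"
          if (is.na(evid[r])) evid[r] <- pe$event_id[i]
        }
      }
    }
    pain_rows <- rows[label[rows] == "pain"]
    n_pain <- length(pain_rows)
    # candidates: inside a normal week, not pain
    in_nw <- rep(FALSE, length(rows))
    for (j in seq_len(nrow(nw)))
      in_nw <- in_nw | (dates[rows] >= as.Date(nw$start[j]) &
                          dates[rows] <= as.Date(nw$end[j]))
    cand <- rows[in_nw & label[rows] != "pain"]
    if (n_pain > 0L && length(cand)) {
      pd <- as.numeric(dates[pain_rows])
      dist <- vapply(as.numeric(dates[cand]),
                     function(d) min(abs(d - pd)), 0)
      ord <- order(dist, as.numeric(dates[cand]))
      keep <- cand[ord][seq_len(min(n_pain, length(cand)))]
      label[keep] <- "pain_free"
      # matched controls inherit the event of their nearest pain day
      for (r in keep) {
        nearest <- pain_rows[which.min(abs(as.numeric(dates[r]) - pd))]
        evid[r] <- evid[nearest]
      }
      if (length(keep) < n_pain)
        warning("participant ", p, ": only ", length(keep),
                " pain-free candidates for ", n_pain, " pain days")
    }
  }
  mapply(function(s, l, e) { s$label <- l; s$event_id <- e; s },
         segments, label, evid, SIMPLIFY = FALSE)
}

#' Read / write a pain-event table
#'
#' CSV with columns `participant_id,start,end,type` (and optionally
#' `event_id`); `type` is `acute` or `flare`.
#'
#' @param path file path.
#' @return data.frame with POSIXct `start`/`end`.
#' @export
read_pain_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$start <- as.POSIXct(df$start, tz = "UTC",
                         format = "%Y-%m-%d %H:%M:%OS")
  df$end <- as.POSIXct(df$end, tz = "UTC", format = "%Y-%m-%d %H:%M:%OS")
  stopifnot(all(df$type %in% c("acute", "flare")), all(df$start < df$end))
  df
}

#' @rdname read_pain_events
#' @param events pain-event data.frame.
#' @export
write_pain_events <- function(events, path) {
  out <- events
  out$start <- format(out$start, "%Y-%m-%d %H:%M:%OS6", tz = "UTC")
  out$end <- format(out$end, "%Y-%m-%d %H:%M:%OS6", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
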