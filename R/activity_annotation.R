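# Activity annotation: a deterministic rule-based labeler (stand-in for a
# trained activity-recognition model), visitor detection from
# near-simultaneous distant ON pairs, and room-to-room traversal timing.

# location -> default activity mapping used by the rule labeler
.location_rules <- function() {
  c(bed = "Sleep", bedroom = "Relax", bedroom_closet = "Other Activity",
    guest_bedroom = "Other Activity",
    toilet = "Personal Hygiene", bathroom_sink = "Personal Hygiene",
    shower = "Bathe", bathtub = "Bathe",
    medicine_cabinet = "Take Medicine",
    hallway = "Other Activity", hallway_night = "Other Activity",
    kitchen = "Cook", stove = "Cook", fridge = "Cook",
    kitchen_sink = "Wash Dishes", pantry = "Cook",
    dining_table = "Eat",
    living_room = "Relax", recliner = "Relax", sofa = "Relax",
    tv_area = "Relax",
    office = "Work", desk = "Work", bookshelf = "Work",
    laundry = "Other Activity", utility = "Other Activity",
    garage = "Other Activity", basement = "Other Activity",
    stairs = "Other Activity", sunroom = "Relax",
    porch = "Other Activity", entryway = "Other Activity",
    workshop = "Work",
    front_door = "Other Activity", back_door = "Other Activity",
    garage_door = "Other Activity")
}

#' Label events with daily activities by deterministic rules
#'
#' A transparent stand-in for a trained activity-recognition model: each
#' event gets exactly one of the 13 activity classes from its location,
#' time of day, and local context. Base rule: location-typical activity
#' (bed -> Sleep, stove -> Cook, recliner -> Relax, ...). Context rules:
#' a toilet-area event at night within 10 minutes of a bed event becomes
#' Bed-Toilet Transition; a door event followed by at least 15 minutes of
#' indoor PIR silence becomes Leave Home, one ending such a silent spell
#' becomes Enter Home. Unmatched events fall through to Other Activity,
#' so labeling is total.
#'
#' @param log an `event_log`, time-sorted.
#' @param schema a `home_schema` mapping every sensor to a location.
#' @return The log with its `activity` column replaced by rule labels.
#' @export
label_activities_rules <- function(log, schema) {
  stopifnot(inherits(schema, "home_schema"))
  if (nrow(log) == 0L) return(log)
  loc <- schema$sensors$location[match(log$sensor_id,
                                       schema$sensors$sensor_id)]
  if (anyNA(loc)) stop("schema error: sensor not in schema")
  rules <- .location_rules()
  lab <- unname(rules[loc])
  lab[is.na(lab)] <- "Other Activity"

  hrs <- as.numeric(format(log$timestamp, "%H", tz = "UTC")) +
    as.numeric(format(log$timestamp, "%M", tz = "UTC")) / 60
  night <- hrs >= 21 | hrs < 9
  tnum <- as.numeric(log$timestamp)

  # bed at any hour -> Sleep (base rule); night toilet-area events within
  # 10 min of a preceding bed event -> Bed-Toilet Transition
  bed_times <- sort(tnum[loc == "bed"])
  if (length(bed_times)) {
    cand <- which(loc %in% c("toilet", "hallway_night") & night)
    prev <- findInterval(tnum[cand], bed_times)
    ok <- prev > 0 & tnum[cand] - bed_times[pmax(prev, 1L)] <= 600
    lab[cand[ok]] <- "Bed-Toilet Transition"
  }

  # door events bordering home-wide PIR silence -> Leave/Enter Home
  is_door <- log$sensor_type == "DOOR"
  pir_on <- which(!is_door & log$state == "ON")
  pir_times <- tnum[pir_on]
  for (i in which(is_door & log$state == "ON")) {
    nxt <- pir_times[pir_times > tnum[i] + 1]
    gap_after <- if (length(nxt)) min(nxt) - tnum[i] else Inf
    prv <- pir_times[pir_times < tnum[i] - 1]
    gap_before <- if (length(prv)) tnum[i] - max(prv) else Inf
    if (gap_after >= 900 && gap_after >= gap_before) lab[i] <- "Leave Home"
    else if (gap_before >= 900) lab[i] <- "Enter Home"
  }
  # an OFF event inherits the label of its sensor's preceding ON
  for (idx in split(seq_len(nrow(log)), log$sensor_id)) {
    last <- NA_character_
    for (i in idx) {
      if (log$state[i] == "ON") last <- lab[i]
      else if (!is.na(last)) lab[i] <- last
    }
  }
  log$activity <- lab
  log
}

#' Detect visitor intervals from concurrent distant ON events
#'
#' Two bodies moving in the home show up as pairs of ON events fired
#' nearly simultaneously by sensors too far apart for one person to
#' trigger both. A concurrency hit is a pair of ON events separated by
#' less than `max_gap` seconds from sensors more than `min_distance`
#' meters apart (Euclidean, from the schema coordinates); hits within 10
#' minutes of each other merge into one visitor interval.
#'
#' @param log an `event_log`, time-sorted.
#' @param schema a `home_schema` with sensor coordinates.
#' @param max_gap maximum time between paired ON events, seconds.
#' @param min_distance minimum sensor separation, meters.
#' @return data.frame with POSIXct columns `start`, `end` (zero rows when
#'   no visitors are detected).
#' @export
detect_visitors <- function(log, schema, max_gap = 0.01,
                            min_distance = 3.0) {
  stopifnot(inherits(schema, "home_schema"))
  s <- schema$sensors
  if (any(!is.finite(s$x)) || any(!is.finite(s$y)))
    stop("schema error: missing sensor coordinates")
  on <- log[log$state == "ON", , drop = FALSE]
  empty <- data.frame(start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"))
  if (nrow(on) < 2) return(empty)
  tnum <- as.numeric(on$timestamp)
  si <- match(on$sensor_id, s$sensor_id)
  hits <- numeric(0)
  # events are sorted; only a short forward window can be concurrent
  j <- 1L
  for (i in seq_len(nrow(on) - 1L)) {
    k <- i + 1L
    while (k <= nrow(on) && tnum[k] - tnum[i] < max_gap) {
      d <- sqrt((s$x[si[i]] - s$x[si[k]])^2 +
                  (s$y[si[i]] - s$y[si[k]])^2)
      if (d > min_distance) hits <- c(hits, tnum[i])
      k <- k + 1L
    }
  }
  if (!length(hits)) return(empty)
  hits <- sort(unique(hits))
  brk <- c(0, which(diff(hits) > 600), length(hits))
  out <- do.call(rbind, lapply(seq_len(length(brk) - 1L), function(b) {
    h <- hits[(brk[b] + 1L):brk[b + 1L]]
    data.frame(start = min(h), end = max(h))
  }))
  out$start <- as.POSIXct(out$start, tz = "UTC",
                          origin = "1970-01-01")
  out$end <- as.POSIXct(out$end, tz = "UTC", origin = "1970-01-01")
  out
}

#' Time to move between two locations
#'
#' For each maximal run of consecutive ON events at `from_location`, if
#' the first subsequent ON at `to_location` arrives within `window`
#' seconds (before any further `from_location` event), the time difference
#' is emitted. With `"bed"` and `"toilet"` this measures nocturnal
#' bed-to-toilet traversal time, a proxy for walking speed.
#'
#' @param log an `event_log`, time-sorted.
#' @param from_location,to_location location names from the schema.
#' @param schema a `home_schema`.
#' @param window maximum traversal time considered, seconds.
#' @return Numeric vector of traversal durations (seconds), possibly
#'   empty.
#' @export
traversal_time <- function(log, from_location, to_location,
                           schema = canonical_home_schema(),
                           window = 900) {
  if (!from_location %in% schema$locations ||
      !to_location %in% schema$locations)
    stop("schema error: unknown location")
  loc <- schema$sensors$location[match(log$sensor_id,
                                       schema$sensors$sensor_id)]
  on <- which(log$state == "ON" & loc %in% c(from_location, to_location))
  if (!length(on)) return(numeric(0))
  l <- loc[on]
  t <- as.numeric(log$timestamp[on])
  out <- numeric(0)
  i <- 1L
  n <- length(on)
  while (i <= n) {
    if (l[i] == from_location) {
      # extend the run of from_location events
      while (i < n && l[i + 1L] == from_location) i <- i + 1L
      if (i < n && l[i + 1L] == to_location &&
          t[i + 1L] - t[i] <= window && t[i + 1L] > t[i])
        out <- c(out, t[i + 1L] - t[i])
    }
    i <- i + 1L
  }
  out
}
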