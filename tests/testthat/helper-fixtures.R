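# shared fixtures: tiny hand-built logs and day segments

.schema <- canonical_home_schema()

# build an event_log from hour-of-day offsets on a given date
mk_log <- function(hours, locations, states = "ON", date = "2021-03-01",
                   activity = NA_character_, schema = .schema) {
  n <- length(hours)
  states <- rep_len(states, n)
  activity <- rep_len(activity, n)
  sid <- schema$sensors$sensor_id[match(locations, schema$sensors$location)]
  styp <- schema$sensors$sensor_type[match(locations,
                                           schema$sensors$location)]
  d0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  df <- data.frame(timestamp = d0 + hours * 3600, sensor_id = sid,
                   sensor_type = styp, state = states,
                   activity = activity, stringsAsFactors = FALSE)
  df <- df[order(df$timestamp), ]
  rownames(df) <- NULL
  class(df) <- c("event_log", "data.frame")
  df
}

mk_day <- function(hours, locations, activity, date = "2021-03-01",
                   label = "unlabeled", schema = .schema) {
  day_segment("P001", as.Date(date),
              mk_log(hours, locations, "ON", date, activity, schema),
              label = label)
}

empty_day <- function(date = "2021-03-01", label = "unlabeled") {
  day_segment("P001", as.Date(date), empty_event_log(), label = label)
}

# a small feature_matrix built from raw pieces (for model tests)
mk_feature_matrix <- function(X, y, groups) {
  df <- as.data.frame(X, check.names = FALSE)
  df$participant_id <- "P001"
  df$date <- as.character(seq(as.Date("2021-01-01"), by = "day",
                              length.out = nrow(X)))
  df$label <- y
  df$event_id <- groups
  feature_matrix(df)
}
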