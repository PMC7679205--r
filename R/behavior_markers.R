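# Behavior markers: hourly activity series, the 11 statistical measures,
# schedule regularity, circadian rhythm strength, and the per-day marker
# vector (550 statistical entries + 2 regularity + 1 circadian).

#' Names of the 11 statistical measures, in canonical order
#' @return Character vector of length 11.
#' @export
measure_names <- function() {
  c("mean", "median", "sd", "max", "min", "zero_crossings",
    "mean_crossings", "iqr", "skewness", "kurtosis", "energy")
}

#' Stream identifiers of the 50 hourly series, in canonical order
#' @param schema a `home_schema`.
#' @return Character vector of length 50: `"overall"`, then `"loc:<name>"`
#'   for the 36 locations, then `"act:<name>"` for the 13 activities.
#' @export
stream_ids <- function(schema = canonical_home_schema()) {
  c("overall", paste0("loc:", schema$locations),
    paste0("act:", schema$activities))
}

#' Names of the 550 statistical markers, in canonical order
#' @param schema a `home_schema`.
#' @return Character vector of length 550 (`"<stream>.<measure>"`).
#' @export
marker_names <- function(schema = canonical_home_schema()) {
  as.vector(t(outer(stream_ids(schema), measure_names(), paste, sep = ".")))
}

#' Hourly ON-event series for one day
#'
#' Counts ON events per hour of the day into 50 series: overall, one per
#' canonical location, one per activity class. Only ON events are counted
#' (each ON firing is one motion detection); locations without events give
#' all-zero series, and the overall series equals the elementwise sum of
#' the 36 location series.
#'
#' @param day a `day_segment` whose events are activity-labeled.
#' @param schema a `home_schema`.
#' @return A 50 x 24 numeric matrix, rownames the stream ids.
#' @export
build_hourly_series <- function(day, schema = canonical_home_schema()) {
  ids <- stream_ids(schema)
  M <- matrix(0, nrow = 50, ncol = 24, dimnames = list(ids, NULL))
  ev <- day$events
  on <- ev[ev$state == "ON", , drop = FALSE]
  if (nrow(on) == 0L) return(M)
  if (anyNA(on$activity))
    stop("labeling error: day contains unlabeled ON events")
  loc <- schema$sensors$location[match(on$sensor_id,
                                       schema$sensors$sensor_id)]
  if (anyNA(loc)) stop("schema error: sensor not in schema")
  li <- match(loc, schema$locations)
  ai <- match(on$activity, schema$activities)
  if (anyNA(ai))
    stop("labeling error: activity label outside the 13-class vocabulary")
  hr <- as.integer(format(on$timestamp, "%H", tz = "UTC"))
  lc <- tabulate((li - 1L) * 24L + hr + 1L, nbins = 36L * 24L)
  ac <- tabulate((ai - 1L) * 24L + hr + 1L, nbins = 13L * 24L)
  M[2:37, ] <- matrix(lc, nrow = 36, byrow = TRUE)
  M[38:50, ] <- matrix(ac, nrow = 13, byrow = TRUE)
  M[1, ] <- colSums(M[2:37, , drop = FALSE])
  M
}

#' The 11 statistical measures of a length-24 hourly series
#'
#' Conventions: population standard deviation; IQR from
#' linearly-interpolated quantiles (Q3 - Q1); skewness m3/m2^1.5 and
#' excess kurtosis m4/m2^2 - 3, both defined as 0 when the series has zero
#' variance; zero crossings count transitions between zero and nonzero
#' values across consecutive hours; mean crossings count sign changes of
#' (value - mean), values exactly at the mean inheriting the previous
#' sign; signal energy is the sum of squared values.
#'
#' @param v numeric vector of length 24 (one hourly series).
#' @return Named numeric vector of length 11.
#' @export
stat_measures <- function(v) {
  if (length(v) != 24L || !is.numeric(v))
    stop("shape error: expected a numeric series of length 24")
  m <- mean(v)
  d <- v - m
  m2 <- mean(d^2)
  nz <- v != 0
  zc <- sum(nz[-1] != nz[-length(v)])
  s <- sign(d)
  s_nz <- s[s != 0]
  mc <- if (length(s_nz) < 2) 0L else sum(diff(s_nz) != 0)
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
  c(mean = m,
    median = stats::median(v),
    sd = sqrt(m2),
    max = max(v),
    min = min(v),
    zero_crossings = as.numeric(zc),
    mean_crossings = as.numeric(mc),
    iqr = q[2] - q[1],
    skewness = if (m2 > 0) mean(d^3) / m2^1.5 else 0,
    kurtosis = if (m2 > 0) mean(d^4) / m2^2 - 3 else 0,
    energy = sum(v^2))
}

# hour x category ON-count matrix for one day (locations or activities)
.hour_category_counts <- function(day, stream_kind, schema) {
  ev <- day$events
  on <- ev[ev$state == "ON", , drop = FALSE]
  K <- if (stream_kind == "location") 36L else 13L
  M <- matrix(0, nrow = 24, ncol = K)
  if (nrow(on) == 0L) return(M)
  if (stream_kind == "location") {
    loc <- schema$sensors$location[match(on$sensor_id,
                                         schema$sensors$sensor_id)]
    ci <- match(loc, schema$locations)
  } else {
    if (anyNA(on$activity))
      stop("labeling error: day contains unlabeled ON events")
    ci <- match(on$activity, schema$activities)
  }
  hr <- as.integer(format(on$timestamp, "%H", tz = "UTC"))
  cnt <- tabulate((ci - 1L) * 24L + hr + 1L, nbins = K * 24L)
  matrix(cnt, nrow = 24, byrow = FALSE)
}

#' Daily schedule regularity
#'
#' For every day and hour, the ON events of that hour define a categorical
#' distribution over the location (or activity) vocabulary. The schedule
#' difference is the mean, over all day pairs and all 24 hours, of the
#' total-variation distance between the two days' hour-h distributions;
#' two empty hours are at distance 0, an empty paired with a non-empty
#' hour at distance 1. Regularity is 1 minus that mean: 1 for identical
#' days, 0 for maximally divergent ones.
#'
#' @param days list of at least two `day_segment`.
#' @param stream_kind `"location"` or `"activity"`.
#' @param schema a `home_schema`.
#' @return Scalar in `[0, 1]`.
#' @export
regularity <- function(days, stream_kind = c("location", "activity"),
                       schema = canonical_home_schema()) {
  stream_kind <- match.arg(stream_kind)
  if (length(days) < 2L)
    stop("insufficient data: regularity needs at least 2 days")
  P <- lapply(days, function(d) {
    M <- .hour_category_counts(d, stream_kind, schema)
    tot <- rowSums(M)
    M <- M / ifelse(tot > 0, tot, 1)
    attr(M, "empty") <- tot == 0
    M
  })
  W <- length(days)
  tot_d <- 0
  n_pairs <- 0L
  for (a in seq_len(W - 1L)) for (b in (a + 1L):W) {
    ea <- attr(P[[a]], "empty"); eb <- attr(P[[b]], "empty")
    tv <- 0.5 * rowSums(abs(P[[a]] - P[[b]]))
    tv[ea & eb] <- 0
    tv[xor(ea, eb)] <- 1
    tot_d <- tot_d + sum(tv)
    n_pairs <- n_pairs + 1L
  }
  1 - tot_d / (n_pairs * 24)
}

#' Circadian rhythm strength
#'
#' Concatenates the overall hourly activity series of W whole days into N
#' = 24 W samples, mean-centers it, and computes the periodogram P(k) =
#' |DFT(k)|^2 for k = 1..floor(N/2). The strength is the fraction of
#' spectral power at the 24-hour component, P(W) / sum(P); a constant
#' series (zero total power) returns 0. A pure 24-hour cosine gives 1.
#'
#' @param days list of at least two `day_segment`, or a numeric vector of
#'   hourly samples whose length is a multiple of 24 (at least 48).
#' @param schema a `home_schema` (ignored for numeric input).
#' @return Scalar in `[0, 1]`.
#' @export
circadian_strength <- function(days, schema = canonical_home_schema()) {
  if (is.numeric(days)) {
    x <- days
    if (length(x) < 48L || length(x) %% 24L != 0L)
      stop("insufficient data: need >= 2 whole days of hourly samples")
  } else {
    if (length(days) < 2L)
      stop("insufficient data: circadian strength needs at least 2 days")
    x <- unlist(lapply(days, function(d) {
      ev <- d$events
      on <- ev[ev$state == "ON", , drop = FALSE]
      if (nrow(on) == 0L) return(numeric(24))
      hr <- as.integer(format(on$timestamp, "%H", tz = "UTC"))
      tabulate(hr + 1L, nbins = 24L)
    }))
  }
  W <- length(x) %/% 24L
  x <- x - mean(x)
  P <- Mod(stats::fft(x))^2
  k <- seq_len(length(x) %/% 2L)
  Pk <- P[k + 1L]
  tot <- sum(Pk)
  if (tot <= 0) return(0)
  Pk[W] / tot
}

#' Extract the full marker vector for one day
#'
#' Applies the 11 statistical measures to each of the day's 50 hourly
#' series (550 markers in a fixed name order), then appends schedule
#' regularity over locations and over activities and the circadian rhythm
#' strength, all computed over the surrounding context window (normally
#' the 7 days centered on the day, clipped at record edges). With fewer
#' than 2 context days the regularity markers default to 1 and circadian
#' strength to 0.
#'
#' @param day a `day_segment`.
#' @param context list of `day_segment` forming the window around `day`.
#' @param schema a `home_schema`.
#' @return An object of class `marker_vector`: list with `participant_id`,
#'   `date`, `label`, `event_id`, and `markers`, a named numeric vector of
#'   length 553.
#' @export
extract_markers <- function(day, context = list(day),
                            schema = canonical_home_schema()) {
  M <- build_hourly_series(day, schema)
  stat <- as.vector(apply(M, 1L, stat_measures))
  names(stat) <- marker_names(schema)
  if (length(context) >= 2L) {
    reg_loc <- regularity(context, "location", schema)
    reg_act <- regularity(context, "activity", schema)
    circ <- circadian_strength(context, schema)
  } else {
    reg_loc <- 1; reg_act <- 1; circ <- 0
  }
  extra <- c(regularity_location = reg_loc,
             regularity_activity = reg_act,
             circadian_strength = circ)
  structure(list(participant_id = day$participant_id, date = day$date,
                 label = day$label, event_id = day$event_id,
                 markers = c(stat, extra)),
            class = "marker_vector")
}

#' @export
print.marker_vector <- function(x, ...) {
  cat(sprintf("marker_vector %s %s (%s): %d markers\n",
              x$participant_id, format(x$date), x$label,
              length(x$markers)))
  invisible(x)
}

#' Build the per-day feature matrix for a labeled day sequence
#'
#' Extracts the 553-marker vector for each selected day of one
#' participant's (time-ordered) day list, using the 7-day window centered
#' on each day (clipped at the record edges) as regularity/circadian
#' context.
#'
#' @param days time-ordered list of `day_segment` for one participant.
#' @param schema a `home_schema`.
#' @param labeled_only keep only days labeled pain or pain-free.
#' @return data.frame with columns `participant_id`, `date`, `label`,
#'   `event_id` and the 553 marker columns (names unaltered).
#' @export
build_feature_rows <- function(days, schema = canonical_home_schema(),
                               labeled_only = TRUE) {
  sel <- seq_along(days)
  if (labeled_only)
    sel <- sel[vapply(days, function(d)
      d$label %in% c("pain", "pain_free"), TRUE)]
  if (!length(sel)) return(NULL)
  rows <- lapply(sel, function(i) {
    ctx <- days[max(1L, i - 3L):min(length(days), i + 3L)]
    mv <- extract_markers(days[[i]], ctx, schema)
    cbind(data.frame(participant_id = mv$participant_id,
                     date = as.character(mv$date), label = mv$label,
                     event_id = mv$event_id, stringsAsFactors = FALSE),
          as.data.frame(t(mv$markers), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Feature matrix for a whole synthetic cohort
#'
#' Labels every day (pain / pain-free / unlabeled) from the cohort's pain
#' events and normal weeks, then extracts marker vectors for the labeled
#' days of every participant.
#'
#' @param cohort a `cohort` from [generate_cohort()].
#' @return data.frame as in [build_feature_rows()], all participants
#'   stacked.
#' @export
cohort_feature_matrix <- function(cohort) {
  out <- lapply(names(cohort$days), function(p) {
    labeled <- label_days(cohort$days[[p]], cohort$pain_events,
                          cohort$normal_weeks)
    build_feature_rows(labeled, cohort$schema)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write / read a feature matrix as TSV
#' @param features feature data.frame.
#' @param path file path.
#' @return `read_feature_matrix` returns the data.frame.
#' @export
write_feature_matrix <- function(features, path) {
  utils::write.table(features, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
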