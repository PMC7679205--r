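# Synthetic single-occupant smart-home generator: a fixed daily routine
# template with stochastic bout timing and Poisson ON-event emission,
# plus pain perturbations that move behavior along six themes (sleep,
# walking, grooming, out-of-home time, visitors, overall activity).

# duration distributions for pain events, frozen so that the truncated
# means match the study conditions (acute mean 6.8 d on [0.25, 14];
# flare mean 6.6 d on [2, 8])
.acute_meanlog <- 1.898313
.acute_sdlog <- 0.5
.flare_mu <- 7.49267
.flare_sd <- 1.5

#' Sample pain-event durations
#'
#' Acute events draw from a log-normal distribution truncated to
#' `[0.25, 14]` days (mean 6.8); flares from a normal distribution
#' truncated to `[2, 8]` days (mean 6.6). Sampling uses inverse-CDF
#' truncation, so it is exact and vectorized.
#'
#' @param type `"acute"` or `"flare"`.
#' @param n number of durations.
#' @return Numeric vector of durations in days.
#' @export
sample_event_duration <- function(type = c("acute", "flare"), n = 1L) {
  type <- match.arg(type)
  u <- stats::runif(n)
  if (type == "acute") {
    lo <- stats::plnorm(0.25, .acute_meanlog, .acute_sdlog)
    hi <- stats::plnorm(14, .acute_meanlog, .acute_sdlog)
    stats::qlnorm(lo + u * (hi - lo), .acute_meanlog, .acute_sdlog)
  } else {
    lo <- stats::pnorm(2, .flare_mu, .flare_sd)
    hi <- stats::pnorm(8, .flare_mu, .flare_sd)
    stats::qnorm(lo + u * (hi - lo), .flare_mu, .flare_sd)
  }
}

# the fixed daily bout template: times in hours, durations in minutes,
# rates in ON events per minute (pre-scaling weights)
.default_schedule <- function() {
  sc <- function(name, act, loc, start, ssd, dur, dsd, rate,
                 grooming = FALSE, chair = FALSE)
    data.frame(name = name, activity = act, location = loc,
               start_mean = start, start_sd = ssd, dur_mean = dur,
               dur_sd = dsd, rate = rate, grooming = grooming,
               chair = chair, stringsAsFactors = FALSE)
  rbind(
    sc("wake_hygiene", "Personal Hygiene", "bathroom_sink", 6.80, 0.25, 15, 4, 2.0, grooming = TRUE),
    sc("meds_am", "Take Medicine", "medicine_cabinet", 7.10, 0.20, 3, 1, 2.0),
    sc("cook_breakfast", "Cook", "stove", 7.30, 0.25, 25, 6, 2.5),
    sc("eat_breakfast", "Eat", "dining_table", 7.80, 0.25, 25, 6, 1.5),
    sc("dishes_am", "Wash Dishes", "kitchen_sink", 8.30, 0.25, 10, 3, 2.0),
    sc("bathe", "Bathe", "shower", 8.60, 0.25, 20, 5, 1.5, grooming = TRUE),
    sc("relax_am", "Relax", "recliner", 9.20, 0.35, 90, 20, 0.6, chair = TRUE),
    sc("work", "Work", "desk", 10.80, 0.35, 60, 15, 1.5),
    sc("cook_lunch", "Cook", "kitchen", 11.90, 0.25, 20, 5, 2.5),
    sc("eat_lunch", "Eat", "dining_table", 12.30, 0.25, 25, 6, 1.5),
    sc("dishes_noon", "Wash Dishes", "kitchen_sink", 12.80, 0.25, 8, 3, 2.0),
    sc("relax_pm", "Relax", "sofa", 15.00, 0.45, 60, 15, 1.2),
    sc("cook_dinner", "Cook", "stove", 17.20, 0.25, 35, 8, 2.5),
    sc("eat_dinner", "Eat", "dining_table", 17.90, 0.25, 30, 6, 1.5),
    sc("dishes_pm", "Wash Dishes", "kitchen_sink", 18.50, 0.25, 10, 3, 2.0),
    sc("relax_eve", "Relax", "recliner", 19.00, 0.35, 150, 25, 0.6, chair = TRUE),
    sc("hygiene_pm", "Personal Hygiene", "bathroom_sink", 21.60, 0.25, 15, 4, 2.0, grooming = TRUE),
    sc("relax_bedroom", "Relax", "bedroom", 22.00, 0.25, 40, 10, 1.0))
}

# expected unscaled rate-driven ON events per day, via a minute-grid
# mean-field pass over the nominal template (bouts at their mean times,
# background during waking hours, out-of-home suppression spread over its
# placement window)
.expected_unit_events <- function(sched, wake, bedtime, sleep_rate,
                                  background_rate, nap_prob, nap_dur,
                                  oo_mean_minutes, oo_window) {
  grid <- seq(0, 24, by = 1 / 60)[-1]  # minute grid midpoints (hours)
  dens <- numeric(length(grid))
  awake <- grid > wake & grid < bedtime
  dens[awake] <- dens[awake] + background_rate
  dens[!awake] <- dens[!awake] + sleep_rate
  for (i in seq_len(nrow(sched))) {
    cov <- grid >= sched$start_mean[i] &
      grid < sched$start_mean[i] + sched$dur_mean[i] / 60
    dens[cov] <- dens[cov] + sched$rate[i]
  }
  # nap expectation (early afternoon)
  cov <- grid >= 14 & grid < 14 + nap_dur / 60
  dens[cov] <- dens[cov] + nap_prob * 0.25
  # out-of-home suppression probability, uniform over its window
  p_oo <- numeric(length(grid))
  in_win <- grid >= oo_window[1] & grid <= oo_window[2]
  p_oo[in_win] <- oo_mean_minutes / (diff(oo_window) * 60)
  sum(dens * (1 - p_oo))  # minutes x rate/min
}

#' Construct a routine profile for the synthetic generator
#'
#' The profile encodes one older adult's habitual day: a fixed bout
#' template (sleep, hygiene, meals, relaxing in a favorite recliner, desk
#' work) with truncated-normal start/duration jitter, low-rate background
#' wandering, nightly bed-to-toilet transitions, occasional out-of-home
#' errands and visitors, and a per-day log-normal activity-level factor.
#' PIR emission rates are scaled so that the expected number of ON events
#' per day matches `daily_event_rate_target` (default 2,000/day, i.e.
#' roughly 60,000 per 30-day month).
#'
#' @param daily_event_rate_target expected ON events per day.
#' @param out_of_home_prob probabilities of 0, 1, 2 out-of-home bouts per
#'   day.
#' @param night_transition_mean mean nightly bed-toilet transition count.
#' @param traversal_mean_seconds mean routine bed-to-toilet traversal time.
#' @param visitor_probability per-day probability of a visitor.
#' @param nap_probability per-day probability of an afternoon nap.
#' @param day_factor_sdlog sd (log scale) of the per-day activity factor;
#'   the factor has mean 1.
#' @param background_rate waking-hours background wandering rate (ON/min,
#'   pre-scaling).
#' @param sleep_rate in-bed micro-movement rate (ON/min, pre-scaling).
#' @return An object of class `routine_profile`.
#' @export
routine_profile <- function(daily_event_rate_target = 2000,
                            out_of_home_prob = c(0.25, 0.5, 0.25),
                            night_transition_mean = 0.7,
                            traversal_mean_seconds = 45,
                            visitor_probability = 0.08,
                            nap_probability = 0.15,
                            day_factor_sdlog = 0.10,
                            background_rate = 0.5,
                            sleep_rate = 0.25) {
  stopifnot(daily_event_rate_target >= 0, length(out_of_home_prob) == 3,
            all(out_of_home_prob >= 0), night_transition_mean >= 0,
            visitor_probability >= 0, visitor_probability <= 1)
  sched <- .default_schedule()
  oo_window <- c(9.5, 18)
  oo_mean_minutes <- sum(out_of_home_prob * 0:2) * 90
  unit <- .expected_unit_events(sched, wake = 6.75, bedtime = 22.75,
                                sleep_rate = sleep_rate,
                                background_rate = background_rate,
                                nap_prob = nap_probability, nap_dur = 50,
                                oo_mean_minutes = oo_mean_minutes,
                                oo_window = oo_window)
  # structural (unscaled) events: door firings, transition sequences,
  # visitor pairs -- small, subtracted from the target before scaling
  structural <- sum(out_of_home_prob * 0:2) * 2 +
    night_transition_mean * 5.2 + visitor_probability * 32
  # the mean-field pass ignores bout-overlap truncation (later bouts cut
  # earlier ones); the frozen correction restores the realized daily mean
  # to the target (one-time Monte-Carlo calibration of the template)
  correction <- 1.1112
  scale <- correction * max(0, daily_event_rate_target - structural) / unit
  structure(list(schedule = sched,
                 daily_event_rate_target = daily_event_rate_target,
                 rate_scale = scale,
                 out_of_home_prob = out_of_home_prob / sum(out_of_home_prob),
                 oo_window = oo_window,
                 night_transition_mean = night_transition_mean,
                 traversal_mean_seconds = traversal_mean_seconds,
                 visitor_probability = visitor_probability,
                 nap_probability = nap_probability,
                 day_factor_sdlog = day_factor_sdlog,
                 background_rate = background_rate,
                 sleep_rate = sleep_rate),
            class = "routine_profile")
}

#' Construct a pain perturbation
#'
#' Encodes how a pain event reshapes daily behavior, one parameter per
#' theme: overall activity is damped, nightly bed-toilet transitions become
#' more frequent and slower, favorite-chair time grows, out-of-home bouts
#' become rarer, grooming bouts are skipped, sleep shifts, naps and
#' visitors become more likely. With all multipliers at 1, additive terms
#' at 0 and probabilities at `NA` (inherit the routine baseline), a
#' perturbed day is distributionally identical to a routine day.
#'
#' @param type `"acute"` or `"flare"` (selects the duration distribution).
#' @param activity_rate_multiplier multiplies the PIR emission rate of
#'   every locomotor bout and of background wandering; stationary
#'   micro-movement (in the favorite chair, in bed) is exempt, so chair
#'   event counts rise with chair time while overall activity falls.
#' @param extra_bed_toilet_transitions_per_night added nightly transitions.
#' @param transition_duration_multiplier multiplies bed-to-toilet traversal
#'   times.
#' @param favorite_chair_added_minutes extra recliner minutes per day.
#' @param out_of_home_probability_multiplier thins out-of-home bouts.
#' @param grooming_skip_probability probability each grooming bout is
#'   skipped.
#' @param sleep_shift_minutes extra minutes in bed (later wake, earlier
#'   bedtime).
#' @param nap_probability pain-day nap probability (`NA` = baseline).
#' @param visitor_burst_probability pain-day visitor probability (`NA` =
#'   baseline).
#' @return An object of class `pain_perturbation`.
#' @export
pain_perturbation <- function(type = c("acute", "flare"),
                              activity_rate_multiplier = 0.6,
                              extra_bed_toilet_transitions_per_night = 2,
                              transition_duration_multiplier = 1.8,
                              favorite_chair_added_minutes = 120,
                              out_of_home_probability_multiplier = 0.3,
                              grooming_skip_probability = 0.2,
                              sleep_shift_minutes = 30,
                              nap_probability = 0.5,
                              visitor_burst_probability = 0.3) {
  type <- match.arg(type)
  stopifnot(activity_rate_multiplier > 0,
            transition_duration_multiplier > 0,
            out_of_home_probability_multiplier > 0,
            grooming_skip_probability >= 0, grooming_skip_probability <= 1,
            is.na(nap_probability) ||
              (nap_probability >= 0 && nap_probability <= 1),
            is.na(visitor_burst_probability) ||
              (visitor_burst_probability >= 0 &&
                 visitor_burst_probability <= 1))
  structure(list(type = type,
                 activity_rate_multiplier = activity_rate_multiplier,
                 extra_bed_toilet_transitions_per_night =
                   extra_bed_toilet_transitions_per_night,
                 transition_duration_multiplier =
                   transition_duration_multiplier,
                 favorite_chair_added_minutes = favorite_chair_added_minutes,
                 out_of_home_probability_multiplier =
                   out_of_home_probability_multiplier,
                 grooming_skip_probability = grooming_skip_probability,
                 sleep_shift_minutes = sleep_shift_minutes,
                 nap_probability = nap_probability,
                 visitor_burst_probability = visitor_burst_probability),
            class = "pain_perturbation")
}

#' A perturbation with no effect
#'
#' All multipliers 1, additive terms 0, probabilities inherited from the
#' routine profile; days simulated under it are distributionally identical
#' to routine days. Used for null-effect checks.
#'
#' @param type `"acute"` or `"flare"`.
#' @return A `pain_perturbation`.
#' @export
neutral_perturbation <- function(type = "acute") {
  pain_perturbation(type = type,
                    activity_rate_multiplier = 1,
                    extra_bed_toilet_transitions_per_night = 0,
                    transition_duration_multiplier = 1,
                    favorite_chair_added_minutes = 0,
                    out_of_home_probability_multiplier = 1,
                    grooming_skip_probability = 0,
                    sleep_shift_minutes = 0,
                    nap_probability = NA,
                    visitor_burst_probability = NA)
}

# truncated-normal draw, vectorized over n
.rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  u <- stats::runif(n)
  a <- stats::pnorm(lo, mean, sd)
  b <- stats::pnorm(hi, mean, sd)
  stats::qnorm(a + u * (b - a), mean, sd)
}

# precomputed distant PIR pairs for visitor simulation
.distant_pairs <- function(schema, min_distance = 4) {
  s <- schema$sensors[schema$sensors$sensor_type == "PIR", , drop = FALSE]
  d <- as.matrix(stats::dist(s[, c("x", "y")]))
  idx <- which(d > min_distance & upper.tri(d), arr.ind = TRUE)
  cbind(s$location[idx[, 1]], s$location[idx[, 2]])
}

#' Simulate one day of sensor events
#'
#' Samples a realization of the routine template: bout start times and
#' durations (truncated normal), Poisson ON-event emission within each
#' bout, background wandering, nightly bed-toilet transition sequences,
#' out-of-home bouts (door firings, indoor PIR silence), optional visitors
#' (near-simultaneous ON pairs from distant sensors), and an OFF event
#' 1-5 s after each ON. Every event carries its ground-truth activity
#' label. Pass a `pain_perturbation` to simulate a pain day.
#'
#' @param profile a `routine_profile`.
#' @param date calendar day of the simulated events.
#' @param participant_id identifier carried into the segment.
#' @param perturb `NULL` for a routine day, or a `pain_perturbation`.
#' @param schema home schema (sensor map); defaults to the canonical one.
#' @param seed optional integer seed (restores determinism regardless of
#'   the current RNG state).
#' @return A `day_segment` with ground-truth labeled events.
#' @export
simulate_day <- function(profile, date = as.Date("2021-03-01"),
                         participant_id = "P001", perturb = NULL,
                         schema = canonical_home_schema(), seed = NULL) {
  stopifnot(inherits(profile, "routine_profile"))
  if (!is.null(seed)) set.seed(seed)
  date <- as.Date(date)
  sens_of <- function(loc) schema$sensors$sensor_id[
    match(loc, schema$sensors$location)]

  p <- perturb
  mult <- if (is.null(p)) 1 else p$activity_rate_multiplier
  f_day <- stats::rlnorm(1, -profile$day_factor_sdlog^2 / 2,
                         profile$day_factor_sdlog)
  emit_scale <- profile$rate_scale * f_day

  # sleep shift is taken on the wake side: pain keeps the person in bed
  # later in the morning, leaving the evening routine in place
  shift_h <- if (is.null(p)) 0 else p$sleep_shift_minutes / 60
  wake <- .rtnorm(1, 6.75 + shift_h, 0.3, 5.0, 10.0)
  bedtime <- .rtnorm(1, 22.75, 0.3, 21.0, 23.9)

  # --- sample the bout table -------------------------------------------
  sched <- profile$schedule
  start <- .rtnorm(nrow(sched), sched$start_mean, sched$start_sd,
                   sched$start_mean - 1.5, sched$start_mean + 1.5)
  dur <- pmax(3, stats::rnorm(nrow(sched), sched$dur_mean, sched$dur_sd))
  # morning bouts track the actual wake time
  morning <- sched$start_mean < 9
  start[morning] <- start[morning] + (wake - 6.75)
  keep <- rep(TRUE, nrow(sched))
  if (!is.null(p) && p$grooming_skip_probability > 0)
    keep[sched$grooming] <- stats::runif(sum(sched$grooming)) >=
      p$grooming_skip_probability
  bouts <- data.frame(start = start, end = start + dur / 60,
                      rate = sched$rate, activity = sched$activity,
                      location = sched$location, chair = sched$chair,
                      stationary = sched$chair,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  # optional afternoon nap
  nap_p <- if (!is.null(p) && !is.na(p$nap_probability)) p$nap_probability
           else profile$nap_probability
  if (stats::runif(1) < nap_p) {
    ns <- .rtnorm(1, 14, 0.5, 13, 15.5)
    bouts <- rbind(bouts, data.frame(
      start = ns, end = ns + pmax(20, stats::rnorm(1, 50, 10)) / 60,
      rate = 0.25, activity = "Sleep", location = "bed", chair = FALSE,
      stationary = TRUE))
  }
  # sleep blocks bracket the day
  bouts <- rbind(bouts,
                 data.frame(start = 0, end = wake,
                            rate = profile$sleep_rate, activity = "Sleep",
                            location = "bed", chair = FALSE,
                            stationary = TRUE),
                 data.frame(start = bedtime, end = 24,
                            rate = profile$sleep_rate, activity = "Sleep",
                            location = "bed", chair = FALSE,
                            stationary = TRUE))
  bouts <- bouts[order(bouts$start), , drop = FALSE]
  # later bouts truncate earlier ones
  if (nrow(bouts) > 1)
    bouts$end[-nrow(bouts)] <- pmin(bouts$end[-nrow(bouts)],
                                    bouts$start[-1])
  bouts <- bouts[bouts$end > bouts$start, , drop = FALSE]
  bouts$end <- pmin(bouts$end, 24)

  # extra favorite-chair time fills the unscheduled early afternoon
  # (displacing only background wandering), capped by the next bout
  if (!is.null(p) && p$favorite_chair_added_minutes > 0) {
    cs <- .rtnorm(1, 13.0, 0.3, 12.5, 14)
    ce <- cs + pmax(20, stats::rnorm(1, p$favorite_chair_added_minutes,
                                     15)) / 60
    nxt <- bouts$start[bouts$start > cs]
    if (length(nxt)) ce <- min(ce, min(nxt))
    bouts <- rbind(bouts, data.frame(
      start = cs, end = ce, rate = 0.6, activity = "Relax",
      location = "recliner", chair = TRUE, stationary = TRUE))
  }

  # background wandering while awake
  bouts <- rbind(bouts, data.frame(
    start = wake, end = bedtime, rate = profile$background_rate,
    activity = "Other Activity", location = "hallway", chair = FALSE,
    stationary = FALSE))

  # --- out-of-home bouts ------------------------------------------------
  n_oo <- sample(0:2, 1, prob = profile$out_of_home_prob)
  if (!is.null(p) && n_oo > 0)
    n_oo <- sum(stats::runif(n_oo) < p$out_of_home_probability_multiplier)
  oo <- NULL
  if (n_oo > 0) {
    os <- sort(stats::runif(n_oo, profile$oo_window[1],
                            profile$oo_window[2] - 0.5))
    od <- .rtnorm(n_oo, 90, 30, 20, 180) / 60
    oe <- pmin(os + od, profile$oo_window[2] + 1)
    if (n_oo == 2 && oe[1] > os[2]) { # merge overlapping errands
      os <- os[1]; oe <- max(oe)
    }
    oo <- cbind(os[seq_along(oe)], oe)
  }

  # --- emit rate-driven ON events --------------------------------------
  # pain damps locomotor activity; stationary micro-movement in the
  # favorite chair keeps firing at its usual rate. The damping is
  # heterogeneous across bouts (different activities are hit differently
  # on different days): per-bout log-normal jitter whose spread scales
  # with the effect size, so a neutral multiplier stays exactly neutral.
  het <- 1.5 * abs(log(mult))
  bout_mult <- ifelse(bouts$stationary, 1,
                      pmin(1, mult * stats::rlnorm(nrow(bouts), 0, het)))
  n_ev <- stats::rpois(nrow(bouts),
                       bouts$rate * emit_scale * bout_mult *
                         (bouts$end - bouts$start) * 60)
  t_on <- unlist(mapply(function(s, e, n) stats::runif(n, s, e),
                        bouts$start, bouts$end, n_ev, SIMPLIFY = FALSE))
  loc_on <- rep(bouts$location, n_ev)
  act_on <- rep(bouts$activity, n_ev)
  # suppress indoor PIR events while out of home
  if (!is.null(oo) && length(t_on)) {
    supp <- rep(FALSE, length(t_on))
    for (i in seq_len(nrow(oo)))
      supp <- supp | (t_on >= oo[i, 1] & t_on < oo[i, 2])
    t_on <- t_on[!supp]; loc_on <- loc_on[!supp]; act_on <- act_on[!supp]
  }

  # door events at each departure / return
  if (!is.null(oo)) {
    t_on <- c(t_on, oo[, 1], oo[, 2])
    loc_on <- c(loc_on, rep("front_door", 2 * nrow(oo)))
    act_on <- c(act_on, rep("Leave Home", nrow(oo)),
                rep("Enter Home", nrow(oo)))
  }

  # --- nightly bed-toilet transitions ----------------------------------
  tdm <- if (is.null(p)) 1 else p$transition_duration_multiplier
  n_tr <- stats::rpois(1, profile$night_transition_mean) +
    if (is.null(p)) 0L else p$extra_bed_toilet_transitions_per_night
  if (n_tr > 0 && wake > 1) {
    tt <- stats::runif(n_tr, 0.3, wake - 0.4)
    for (t0 in tt) {
      gap <- stats::rlnorm(1, log(profile$traversal_mean_seconds), 0.3) *
        tdm / 3600
      # out of bed for the whole excursion: drop in-bed micro-movement
      # events that would otherwise fire mid-transition
      out_win <- t_on > t0 & t_on < t0 + gap + 6 / 60 & loc_on == "bed"
      if (any(out_win)) {
        t_on <- t_on[!out_win]; loc_on <- loc_on[!out_win]
        act_on <- act_on[!out_win]
      }
      t_on <- c(t_on, t0); loc_on <- c(loc_on, "bed")
      act_on <- c(act_on, "Sleep")
      if (stats::runif(1) < 0.7) {
        t_on <- c(t_on, t0 + gap * 0.5)
        loc_on <- c(loc_on, "hallway_night")
        act_on <- c(act_on, "Bed-Toilet Transition")
      }
      n_toi <- 1L + stats::rpois(1, 1.5)
      dwell <- pmax(1, stats::rnorm(1, 4, 1)) / 60
      t_on <- c(t_on, t0 + gap, t0 + gap + stats::runif(n_toi - 1) * dwell)
      loc_on <- c(loc_on, rep("toilet", n_toi))
      act_on <- c(act_on, rep("Bed-Toilet Transition", n_toi))
      t_on <- c(t_on, t0 + gap + dwell + 30 / 3600)
      loc_on <- c(loc_on, "bed"); act_on <- c(act_on, "Sleep")
    }
  }

  # --- visitors ---------------------------------------------------------
  vis_p <- if (!is.null(p) && !is.na(p$visitor_burst_probability))
    p$visitor_burst_probability else profile$visitor_probability
  if (stats::runif(1) < vis_p) {
    vstart <- stats::runif(1, 10, 17)
    vdur <- stats::runif(1, 20, 60) / 60
    pairs <- .distant_pairs(schema)
    n_hits <- max(2L, stats::rpois(1, vdur * 60 / 2.5))
    ht <- sort(stats::runif(n_hits, vstart, vstart + vdur))
    pi <- sample(nrow(pairs), n_hits, replace = TRUE)
    dt <- stats::runif(n_hits, 0, 0.008) / 3600
    t_on <- c(t_on, ht, ht + dt)
    loc_on <- c(loc_on, pairs[pi, 1], pairs[pi, 2])
    act_on <- c(act_on, rep("Other Activity", 2 * n_hits))
  }

  # --- assemble, add OFF events, clip to the day ------------------------
  ok <- t_on >= 0 & t_on < 24
  t_on <- t_on[ok]; loc_on <- loc_on[ok]; act_on <- act_on[ok]
  sid <- sens_of(loc_on)
  styp <- ifelse(grepl("_door$", loc_on), "DOOR", "PIR")
  t_off <- t_on + stats::runif(length(t_on), 1, 5) / 3600
  keep_off <- t_off < 24
  ts <- c(t_on, t_off[keep_off])
  d0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  ev <- new_event_log(
    timestamp = d0 + round(ts * 3600, 6),
    sensor_id = c(sid, sid[keep_off]),
    sensor_type = c(styp, styp[keep_off]),
    state = c(rep("ON", length(t_on)), rep("OFF", sum(keep_off))),
    activity = c(act_on, act_on[keep_off]))
  ev <- ev[order(ev$timestamp), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("event_log", "data.frame")
  day_segment(participant_id, date, ev)
}

#' Inject a pain event into a simulated day sequence
#'
#' Days overlapping `[start, start + duration)` are regenerated under the
#' perturbation; the sampled duration comes from the perturbation type's
#' distribution. Under a neutral perturbation the regenerated days are
#' distributionally identical to routine days.
#'
#' @param days list of `day_segment` (consecutive calendar days).
#' @param perturbation a `pain_perturbation`.
#' @param start event start (POSIXct or coercible).
#' @param profile the `routine_profile` that generated `days`.
#' @param schema home schema.
#' @param seed optional integer seed.
#' @return List with `days` (the modified sequence) and `record` (a
#'   one-row pain-event data.frame).
#' @export
inject_pain_event <- function(days, perturbation, start,
                              profile = routine_profile(),
                              schema = canonical_home_schema(),
                              seed = NULL) {
  stopifnot(inherits(perturbation, "pain_perturbation"), length(days) > 0)
  if (!is.null(seed)) set.seed(seed)
  start <- as.POSIXct(start, tz = "UTC")
  dates <- as.Date(vapply(days, function(d) as.character(d$date), ""))
  span0 <- as.POSIXct(paste(min(dates), "00:00:00"), tz = "UTC")
  span1 <- as.POSIXct(paste(max(dates) + 1, "00:00:00"), tz = "UTC")
  if (start < span0 || start >= span1)
    stop("span error: event start outside the simulated span")
  dur <- sample_event_duration(perturbation$type, 1L)
  end <- start + dur * 86400
  if (end > span1)
    stop("span error: event extends past the simulated span")
  pid <- days[[1]]$participant_id
  for (i in seq_along(days)) {
    if (day_overlaps(dates[i], start, end))
      days[[i]] <- simulate_day(profile, dates[i], pid,
                                perturb = perturbation, schema = schema)
  }
  record <- data.frame(participant_id = pid, start = start, end = end,
                       type = perturbation$type,
                       stringsAsFactors = FALSE)
  list(days = days, record = record)
}

#' Construct a cohort specification
#'
#' Defaults emulate the study conditions: 11 single-occupant homes, 27
#' pain events of which 8 are acute (30%) and 19 flares (70%), every
#' participant experiencing at least one event.
#'
#' @param n_participants number of homes.
#' @param monitoring_days monitored days per participant.
#' @param n_pain_events total pain events across the cohort.
#' @param acute_fraction fraction of events that are acute.
#' @param master_seed integer master seed; the whole cohort is reproducible
#'   from it.
#' @param start_date first monitored day.
#' @param profile `routine_profile` shared by the cohort.
#' @param acute_perturbation,flare_perturbation effect parameters for the
#'   two event types.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 11L,
                        monitoring_days = 180L,
                        n_pain_events = 27L,
                        acute_fraction = 8 / 27,
                        master_seed = 1L,
                        start_date = as.Date("2021-01-01"),
                        profile = routine_profile(),
                        acute_perturbation = pain_perturbation("acute"),
                        flare_perturbation = pain_perturbation("flare")) {
  stopifnot(n_participants >= 1, acute_fraction >= 0, acute_fraction <= 1,
            n_pain_events == 0 || n_pain_events >= n_participants)
  structure(list(n_participants = as.integer(n_participants),
                 monitoring_days = as.integer(monitoring_days),
                 n_pain_events = as.integer(n_pain_events),
                 acute_fraction = acute_fraction,
                 master_seed = as.integer(master_seed),
                 start_date = as.Date(start_date),
                 profile = profile,
                 acute_perturbation = acute_perturbation,
                 flare_perturbation = flare_perturbation),
            class = "cohort_spec")
}

# deterministic per-participant sub-seed below 2^31
.sub_seed <- function(master, i) {
  (as.numeric(master) * 7919 + i * 104729) %% 2147483647
}

#' Generate a synthetic cohort
#'
#' Allocates the requested pain events across participants (each gets at
#' least one; types drawn to match `acute_fraction`), places them
#' disjointly inside each monitoring span with buffer gaps, simulates
#' every day (routine or perturbed), and declares as normal weeks all
#' 7-day blocks at least 2 days clear of any pain event.
#'
#' @param spec a `cohort_spec`.
#' @param schema home schema shared by the cohort.
#' @return An object of class `cohort`: list with `days` (per-participant
#'   lists of `day_segment`), `pain_events`, `normal_weeks`, `spec`,
#'   `schema`.
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            schema = canonical_home_schema()) {
  stopifnot(inherits(spec, "cohort_spec"))
  P <- spec$n_participants
  D <- spec$monitoring_days
  pids <- sprintf("P%03d", seq_len(P))

  # allocate event counts and types
  set.seed(spec$master_seed %% 2147483647)
  counts <- rep(spec$n_pain_events %/% P, P)
  extra <- spec$n_pain_events %% P
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  n_acute <- round(spec$acute_fraction * spec$n_pain_events)
  types <- rep("flare", spec$n_pain_events)
  if (spec$n_pain_events > 0 && n_acute > 0)
    types[sample(spec$n_pain_events, n_acute)] <- "acute"

  all_events <- list()
  all_weeks <- list()
  days_by_p <- vector("list", P)
  names(days_by_p) <- pids
  ev_i <- 0L
  for (i in seq_len(P)) {
    set.seed(.sub_seed(spec$master_seed, i))
    k <- counts[i]
    # place events in equal blocks of the monitoring span, buffered
    starts <- ends <- as.POSIXct(character(), tz = "UTC")
    etype <- character()
    if (k > 0) {
      block <- (D - 10) / k
      for (j in seq_len(k)) {
        ev_i_local <- ev_i + j
        ty <- types[ev_i_local]
        dur <- sample_event_duration(ty, 1L)
        lo <- 5 + (j - 1) * block
        hi <- 5 + j * block - dur - 3
        if (hi <= lo)
          stop("placement error: monitoring span too short for ",
               "requested events")
        sday <- stats::runif(1, lo, hi)
        s <- as.POSIXct(paste(spec$start_date, "00:00:00"), tz = "UTC") +
          sday * 86400
        starts <- c(starts, s)
        ends <- c(ends, s + dur * 86400)
        etype <- c(etype, ty)
      }
    }
    pe <- data.frame(event_id = sprintf("E%03d", ev_i + seq_len(k)),
                     participant_id = rep(pids[i], k),
                     start = starts, end = ends, type = etype,
                     stringsAsFactors = FALSE)
    ev_i <- ev_i + k
    all_events[[i]] <- pe

    # normal weeks: 7-day blocks >= 2 days clear of every event
    wk_start <- seq(spec$start_date, spec$start_date + D - 7, by = 7)
    ok <- vapply(wk_start, function(w) {
      w0 <- as.POSIXct(paste(w - 2, "00:00:00"), tz = "UTC")
      w1 <- as.POSIXct(paste(w + 9, "00:00:00"), tz = "UTC")
      !any(pe$start < w1 & pe$end > w0)
    }, TRUE)
    all_weeks[[i]] <- data.frame(participant_id = pids[i],
                                 start = wk_start[ok],
                                 end = wk_start[ok] + 6)

    # simulate every monitored day
    dates <- seq(spec$start_date, by = "day", length.out = D)
    perturb_of <- lapply(dates, function(d) {
      hit <- which(day_overlaps(d, pe$start, pe$end))
      if (length(hit) == 0) NULL
      else if (pe$type[hit[1]] == "acute") spec$acute_perturbation
      else spec$flare_perturbation
    })
    days_by_p[[i]] <- lapply(seq_along(dates), function(j)
      simulate_day(spec$profile, dates[j], pids[i],
                   perturb = perturb_of[[j]], schema = schema))
  }
  pain_events <- do.call(rbind, all_events)
  normal_weeks <- do.call(rbind, all_weeks)
  structure(list(days = days_by_p, pain_events = pain_events,
                 normal_weeks = normal_weeks, spec = spec,
                 schema = schema),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d participants x %d days, %d pain events (%d acute)\n",
              length(x$days), x$spec$monitoring_days,
              nrow(x$pain_events), sum(x$pain_events$type == "acute")))
  invisible(x)
}

#' Flatten one participant's days into a single event log
#'
#' @param cohort a `cohort`.
#' @param participant_id participant to extract.
#' @return An `event_log`.
#' @export
cohort_event_log <- function(cohort, participant_id) {
  days <- cohort$days[[participant_id]]
  if (is.null(days)) stop("unknown participant: ", participant_id)
  logs <- lapply(days, function(d) d$events)
  out <- do.call(rbind, logs)
  rownames(out) <- NULL
  class(out) <- c("event_log", "data.frame")
  out
}
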