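.drug_ids <- c("anti_mir155_np", "cisplatin", "atezolizumab", "pembrolizumab")

#' A single dose event
#'
#' @param drug One of `"anti_mir155_np"`, `"cisplatin"`, `"atezolizumab"`,
#'   `"pembrolizumab"`.
#' @param dose_mg_kg Dose in mg/kg body weight (>= 0).
#' @param time_day Time in days from treatment start (>= 0).
#' @return A `dose_event` object.
#' @export
dose_event <- function(drug, dose_mg_kg, time_day) {
  drug <- match.arg(drug, .drug_ids)
  if (!is.numeric(dose_mg_kg) || dose_mg_kg < 0)
    stop("dose_event: 'dose_mg_kg' must be >= 0", call. = FALSE)
  if (!is.numeric(time_day) || time_day < 0)
    stop("dose_event: 'time_day' must be >= 0", call. = FALSE)
  structure(list(drug = drug, dose_mg_kg = as.numeric(dose_mg_kg),
                 time_day = as.numeric(time_day)),
            class = "dose_event")
}

#' A dosing regimen
#'
#' An ordered set of dose events plus the timing frame: `treatment_start` is
#' measured in days from tumor inception (mouse: inoculation; human: the
#' single founding cell), event times in days from treatment start, and
#' `follow_up_end` (days from treatment start) closes the observation window.
#'
#' @param events List of [dose_event()]s (may be empty for a control arm).
#' @param treatment_start Days from tumor inception to first possible dose.
#' @param follow_up_end Days from treatment start to the end of follow-up;
#'   must not precede the last dose.
#' @return A `regimen` object with events sorted by time.
#' @export
regimen <- function(events = list(), treatment_start, follow_up_end) {
  if (!is.list(events) ||
      (length(events) && !all(vapply(events, inherits, logical(1),
                                     "dose_event"))))
    stop("regimen: 'events' must be a list of dose_event objects",
         call. = FALSE)
  if (treatment_start < 0)
    stop("regimen: 'treatment_start' must be >= 0", call. = FALSE)
  if (length(events)) {
    tms <- vapply(events, `[[`, numeric(1), "time_day")
    events <- events[order(tms)]
    if (follow_up_end < max(tms))
      stop("regimen: 'follow_up_end' precedes the last dose event",
           call. = FALSE)
  }
  structure(list(events = events,
                 treatment_start = as.numeric(treatment_start),
                 follow_up_end = as.numeric(follow_up_end)),
            class = "regimen")
}

#' Build an evenly spaced schedule for one drug
#'
#' Convenience constructor for the standard clinical schedules: `QW` (every
#' 7 days), `Q2W` (14), `Q3W` (21), and `BIW` (twice weekly, every 3.5 days).
#'
#' @param drug Drug id (see [dose_event()]).
#' @param dose_mg_kg Per-dose amount, mg/kg.
#' @param schedule One of `"QW"`, `"Q2W"`, `"Q3W"`, `"BIW"`, or a numeric
#'   interval in days.
#' @param n_cycles Number of doses.
#' @param start_day First dose time, days from treatment start (default 0).
#' @return List of [dose_event()]s.
#' @export
schedule_events <- function(drug, dose_mg_kg, schedule, n_cycles,
                            start_day = 0) {
  interval <- if (is.numeric(schedule)) schedule else
    switch(match.arg(schedule, c("QW", "Q2W", "Q3W", "BIW")),
           QW = 7, Q2W = 14, Q3W = 21, BIW = 3.5)
  if (n_cycles < 1) stop("schedule_events: 'n_cycles' must be >= 1",
                         call. = FALSE)
  lapply(seq_len(n_cycles) - 1L, function(i)
    dose_event(drug, dose_mg_kg, start_day + i * interval))
}

#' Merge event lists from several drugs into one regimen
#'
#' @param ... Lists of [dose_event()]s (e.g. from [schedule_events()]).
#' @inheritParams regimen
#' @return A `regimen`.
#' @export
combine_regimen <- function(..., treatment_start, follow_up_end) {
  regimen(do.call(c, list(...)), treatment_start = treatment_start,
          follow_up_end = follow_up_end)
}

#' Reference preclinical regimens
#'
#' The five treatment arms (plus control) of the pooled preclinical
#' calibration design, on the xenograft timeline: inoculation at day 0,
#' treatment from day 7 for four weeks, end of treatment at day 35.
#' Anti-miR-155 is given at 0.2 mg/kg (4,000 ng in a 20 g mouse) twice
#' weekly; cisplatin at 8 mg/kg once weekly; atezolizumab at 10 mg/kg and
#' pembrolizumab at 5 mg/kg twice weekly.
#'
#' @param arms Character vector of arms to return; default all.
#' @return Named list of `regimen` objects.
#' @export
preclinical_regimens <- function(arms = c("control", "anti_mir155",
                                          "cisplatin", "combination",
                                          "atezolizumab", "pembrolizumab")) {
  arms <- match.arg(arms, several.ok = TRUE)
  ts <- 7; fu <- 28  # treatment days 7..35 post-inoculation
  build <- list(
    control = function() regimen(list(), ts, fu),
    anti_mir155 = function() regimen(
      schedule_events("anti_mir155_np", 0.2, "BIW", 8), ts, fu),
    cisplatin = function() regimen(
      schedule_events("cisplatin", 8, "QW", 4), ts, fu),
    combination = function() combine_regimen(
      schedule_events("anti_mir155_np", 0.2, "BIW", 8),
      schedule_events("cisplatin", 8, "QW", 4),
      treatment_start = ts, follow_up_end = fu),
    atezolizumab = function() regimen(
      schedule_events("atezolizumab", 10, "BIW", 8), ts, fu),
    pembrolizumab = function() regimen(
      schedule_events("pembrolizumab", 5, "BIW", 8), ts, fu)
  )
  stats::setNames(lapply(arms, function(a) build[[a]]()), arms)
}

#' End-of-treatment time of a regimen
#'
#' Defined as the last dose time plus one inter-dose interval (or the
#' follow-up end for control arms), capped at `follow_up_end`; in days from
#' treatment start.
#'
#' @param reg A `regimen`.
#' @return Numeric scalar, days from treatment start.
#' @export
end_of_treatment <- function(reg) {
  if (!length(reg$events)) return(reg$follow_up_end)
  tms <- sort(unique(vapply(reg$events, `[[`, numeric(1), "time_day")))
  gap <- if (length(tms) > 1) stats::median(diff(tms)) else reg$follow_up_end
  min(max(tms) + gap, reg$follow_up_end)
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("<regimen> %d dose events, start day %.3g post-inception, follow-up %.3g d\n",
              length(x$events), x$treatment_start, x$follow_up_end))
  if (length(x$events)) {
    df <- regimen_table(x)
    agg <- stats::aggregate(dose_mg_kg ~ drug, df, function(d)
      sprintf("%d x %.3g mg/kg", length(d), d[1]))
    for (i in seq_len(nrow(agg)))
      cat("  ", agg$drug[i], ": ", agg$dose_mg_kg[i], "\n", sep = "")
  }
  invisible(x)
}

#' Tabulate a regimen's dose events
#' @param reg A `regimen`.
#' @return data.frame with columns `drug`, `dose_mg_kg`, `time_day`.
#' @export
regimen_table <- function(reg) {
  if (!length(reg$events))
    return(data.frame(drug = character(), dose_mg_kg = numeric(),
                      time_day = numeric()))
  data.frame(
    drug = vapply(reg$events, `[[`, character(1), "drug"),
    dose_mg_kg = vapply(reg$events, `[[`, numeric(1), "dose_mg_kg"),
    time_day = vapply(reg$events, `[[`, numeric(1), "time_day"))
}
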