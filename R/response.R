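#' Tumor growth inhibition
#'
#' TGI at time `t` relative to a paired control arm sharing the same
#' provenance (initial volume and treatment start):
#' `TGI(t) = 100 * [(V_ctrl(t) - V0) - (V_trt(t) - V0)] / (V_ctrl(t) - V0)`,
#' where `V0` is the shared volume at treatment start. Defined only when the
#' control arm has grown (`V_ctrl(t) > V0`); 0% for a treatment identical to
#' control and 100% for a tumor pinned at its baseline volume.
#'
#' @param treated,control `trajectory` objects covering `t` and sharing the
#'   same treatment start and baseline volume.
#' @param t_day Assessment time, days from treatment start.
#' @return TGI in percent (<= 100; can be negative if the treated arm
#'   outgrows control).
#' @export
tumor_growth_inhibition <- function(treated, control, t_day) {
  reg_t <- attr(treated, "regimen"); reg_c <- attr(control, "regimen")
  if (abs(reg_t$treatment_start - reg_c$treatment_start) > 1e-9)
    stop("tumor_growth_inhibition: arms have different treatment starts",
         call. = FALSE)
  ts <- reg_c$treatment_start
  v0_c <- trajectory_at(control, "volume", ts)
  v0_t <- trajectory_at(treated, "volume", ts)
  if (abs(v0_c - v0_t) > 1e-6 * max(v0_c, v0_t))
    stop("tumor_growth_inhibition: arms do not share a baseline volume",
         call. = FALSE)
  t_abs <- ts + t_day
  if (t_abs > max(control$time) + 1e-9 || t_abs > max(treated$time) + 1e-9)
    stop("tumor_growth_inhibition: trajectories do not cover t", call. = FALSE)
  vc <- trajectory_at(control, "volume", t_abs)
  vt <- trajectory_at(treated, "volume", t_abs)
  denom <- vc - v0_c
  if (denom <= 0)
    stop("tumor_growth_inhibition: control arm has not grown at t; ",
         "TGI undefined", call. = FALSE)
  100 * (denom - (vt - v0_c)) / denom
}

#' Spherical tumor diameter from volume
#'
#' `d = (6 V / pi)^(1/3)`, assuming a spherical lesion.
#'
#' @param volume_cm3 Volume(s) in cm^3, >= 0.
#' @return Diameter(s) in cm.
#' @export
diameter_from_volume <- function(volume_cm3) {
  if (any(volume_cm3 < 0))
    stop("diameter_from_volume: volume must be >= 0", call. = FALSE)
  (6 * volume_cm3 / pi)^(1 / 3)
}

#' Spherical tumor volume from diameter
#' @param diameter_cm Diameter(s) in cm, >= 0.
#' @return Volume(s) in cm^3.
#' @export
volume_from_diameter <- function(diameter_cm) {
  if (any(diameter_cm < 0))
    stop("volume_from_diameter: diameter must be >= 0", call. = FALSE)
  pi / 6 * diameter_cm^3
}

#' RECIST 1.1 category stream for a single-lesion trajectory
#'
#' Assessments follow RECIST 1.1 with a nadir-based reference: the reference
#' diameter is the smaller of the baseline (treatment-start) diameter and the
#' smallest diameter recorded since treatment start. Progressive disease (PD)
#' requires both a >= 20% increase over the nadir and an absolute increase of
#' >= 0.5 cm; partial response (PR) is a >= 30% decrease from baseline;
#' complete response (CR) is a diameter below the detectability floor
#' (0.1 cm); otherwise stable disease (SD).
#'
#' @param traj A `trajectory` whose regimen defines the treatment start.
#' @param assessment_days Assessment times in days from treatment start
#'   (default: every trajectory grid point from treatment start onward).
#' @return data.frame with `time_day` (days from treatment start),
#'   `diameter_cm`, `nadir_cm`, `category` (factor CR/PR/SD/PD).
#' @export
recist_stream <- function(traj, assessment_days = NULL) {
  reg <- attr(traj, "regimen")
  ts <- reg$treatment_start
  if (is.null(assessment_days)) {
    assessment_days <- traj$time[traj$time >= ts - 1e-9] - ts
  }
  if (!length(assessment_days))
    stop("recist_stream: empty assessment grid", call. = FALSE)
  assessment_days <- sort(unique(assessment_days))
  d <- diameter_from_volume(trajectory_at(traj, "volume", ts + assessment_days))
  baseline <- diameter_from_volume(trajectory_at(traj, "volume", ts))
  nadir <- pmin(baseline, cummin(d))
  cat_of <- function(di, na) {
    if (di < 0.1) "CR"
    else if (di >= na * 1.2 && di - na >= 0.5) "PD"
    else if (di <= baseline * 0.7) "PR"
    else "SD"
  }
  category <- factor(mapply(cat_of, d, nadir),
                     levels = c("CR", "PR", "SD", "PD"))
  data.frame(time_day = assessment_days, diameter_cm = d, nadir_cm = nadir,
             category = category)
}

#' Time to progression (RECIST 1.1)
#'
#' First assessment time classified as progressive disease, converted to
#' months (30.44 days/month); censored at the end of follow-up if no
#' progression occurs.
#'
#' @inheritParams recist_stream
#' @param follow_up_end_day End of follow-up, days from treatment start
#'   (default: the regimen's).
#' @return List with `ttp_months`, `event` (TRUE if progression observed),
#'   and the assessment `stream`.
#' @export
time_to_progression <- function(traj, assessment_days = NULL,
                                follow_up_end_day = NULL) {
  reg <- attr(traj, "regimen")
  if (is.null(follow_up_end_day)) follow_up_end_day <- reg$follow_up_end
  stream <- recist_stream(traj, assessment_days)
  stream <- stream[stream$time_day <= follow_up_end_day + 1e-9, , drop = FALSE]
  hit <- which(stream$category == "PD")
  if (length(hit)) {
    list(ttp_months = stream$time_day[hit[1]] / 30.44, event = TRUE,
         stream = stream)
  } else {
    list(ttp_months = follow_up_end_day / 30.44, event = FALSE,
         stream = stream)
  }
}

#' Best overall response of an assessment stream
#' @param stream Output of [recist_stream()] (or the `stream` element of
#'   [time_to_progression()]).
#' @return Single category: the best (CR > PR > SD) category attained before
#'   the first PD, or `"PD"` if progression is the first assessment.
#' @export
best_response <- function(stream) {
  cats <- as.character(stream$category)
  pd <- which(cats == "PD")
  pre <- if (length(pd)) cats[seq_len(pd[1] - 1)] else cats
  if (!length(pre)) return("PD")
  for (c in c("CR", "PR", "SD")) if (c %in% pre) return(c)
  "PD"
}

#' Percent change in diameter from the RECIST reference
#'
#' Diameter change at time `t` relative to the nadir-based RECIST reference
#' (baseline or smallest post-baseline diameter, whichever is smaller), the
#' endpoint used for the modified Hill dose-response characterization.
#'
#' @inheritParams recist_stream
#' @param t_day Assessment time, days from treatment start.
#' @return Percent change (positive = growth beyond the reference).
#' @export
diameter_change_percent <- function(traj, t_day) {
  stream <- recist_stream(traj)
  stream <- stream[stream$time_day <= t_day + 1e-9, , drop = FALSE]
  last <- stream[nrow(stream), ]
  100 * (last$diameter_cm - last$nadir_cm) / last$nadir_cm
}
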