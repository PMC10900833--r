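#' Build one of the five simulated KRT schedules
#'
#' The five settings are: (1) thrice-weekly (Mon/Wed/Fri) 4-h hemodialysis
#' (HD) at dialysate flow Qd 300 mL/min; (2) daily 4-h HD at Qd 300; (3) daily
#' sequential therapy, 4-h HD at Qd 300 immediately followed by 20-h
#' ultrafiltration (UF) at Quf 5 mL/min; (4) daily 9-h prolonged intermittent
#' KRT (PIKRT) at Qd 100; (5) continuous daily 24-h extended PIKRT at Qd 50.
#'
#' Clock convention: for settings 1-3, 4-early and 5 the simulation origin
#' t = 0 is the start of the first KRT session and sessions recur at the same
#' clock time each day (each week for setting 1). The first dose is anchored
#' at the end of the first HD session (settings 1-3), at PIKRT start
#' (4-early), or at t = 0 for setting 5. For setting 4-late the origin is the
#' first dose and the first PIKRT session starts 15 h later. One week of
#' therapy is simulated from the first dose, so the session timeline extends
#' to `dose_anchor + 168` h and setting 1 sees the following Monday's HD.
#'
#' @param setting Integer 1-5.
#' @param variant `"early"` or `"late"`, meaningful only for setting 4
#'   (first dose at PIKRT start vs 15 h before PIKRT); `"none"` otherwise.
#' @return An object of class `krt_schedule`: a list with `name`, `setting`,
#'   `variant`, `dose_anchor` (h), `horizon` (h), and `sessions`, a tibble
#'   with columns `start`, `end` (h), `modality` (`"HD"`/`"UF"`) and
#'   `effluent_rate` (mL/min).
#' @examples
#' krt_schedule(3)
#' krt_schedule(4, "late")$sessions
#' @export
krt_schedule <- function(setting, variant = c("none", "early", "late")) {
  variant <- match.arg(variant)
  if (!setting %in% 1:5) stop("unknown KRT setting: ", setting)
  if (setting == 4 && variant == "none")
    stop("setting 4 requires variant 'early' or 'late'")
  if (setting != 4 && variant != "none")
    stop("variant is only meaningful for setting 4")

  anchor <- if (setting %in% 1:3) 4 else 0
  horizon <- anchor + 168

  day_starts <- function(first = 0) seq(first, horizon, by = 24)
  sess <- switch(as.character(setting),
    `1` = {
      starts <- as.vector(outer(c(0, 48, 96), seq(0, horizon, by = 168), `+`))
      tibble::tibble(start = sort(starts), duration = 4,
                     modality = "HD", effluent_rate = 300)
    },
    `2` = tibble::tibble(start = day_starts(), duration = 4,
                         modality = "HD", effluent_rate = 300),
    `3` = {
      hd <- tibble::tibble(start = day_starts(), duration = 4,
                           modality = "HD", effluent_rate = 300)
      uf <- tibble::tibble(start = day_starts() + 4, duration = 20,
                           modality = "UF", effluent_rate = 5)
      dplyr::arrange(dplyr::bind_rows(hd, uf), start)
    },
    `4` = tibble::tibble(start = day_starts(if (variant == "late") 15 else 0),
                         duration = 9, modality = "HD", effluent_rate = 100),
    `5` = tibble::tibble(start = day_starts(), duration = 24,
                         modality = "HD", effluent_rate = 50))

  sess$end <- pmin(sess$start + sess$duration, horizon)
  sess <- sess[sess$start < horizon & sess$end > sess$start,
               c("start", "end", "modality", "effluent_rate")]

  name <- switch(as.character(setting),
    `1` = "thrice-weekly 4-h HD (Qd 300)",
    `2` = "daily 4-h HD (Qd 300)",
    `3` = "sequential 4-h HD (Qd 300) + 20-h UF (Quf 5)",
    `4` = paste0(variant, " 9-h PIKRT (Qd 100)"),
    `5` = "extended 24-h PIKRT (Qd 50)")
  structure(list(name = name, setting = setting, variant = variant,
                 dose_anchor = anchor, horizon = horizon, sessions = sess),
            class = "krt_schedule")
}

#' @export
print.krt_schedule <- function(x, ...) {
  cat(sprintf("<krt_schedule> setting %d%s: %s\n", x$setting,
              if (x$variant != "none") paste0("-", x$variant) else "", x$name))
  cat(sprintf("  first dose at t = %g h; %d sessions over %g h\n",
              x$dose_anchor, nrow(x$sessions), x$horizon))
  invisible(x)
}

#' @method tidy krt_schedule
#' @export
tidy.krt_schedule <- function(x, ...) {
  dplyr::mutate(x$sessions, setting = x$setting, variant = x$variant,
                .before = 1)
}

#' Transmembrane clearance from an extraction coefficient and effluent flow
#'
#' Dialytic clearance is the saturation coefficient times the dialysate flow
#' rate (`CL_HD = SA * Qd`); ultrafiltration clearance is the sieving
#' coefficient times the ultrafiltrate flow rate (`CL_UF = SC * Quf`).
#'
#' @param coef Saturation or sieving coefficient in \[0, 1\] (vectorized).
#' @param effluent_rate Qd or Quf in mL/min (>= 0).
#' @return Clearance in mL/min.
#' @examples
#' transmembrane_clearance(0.31, 300) # 93 mL/min
#' @export
transmembrane_clearance <- function(coef, effluent_rate) {
  stopifnot(all(coef >= 0 & coef <= 1), all(effluent_rate >= 0))
  coef * effluent_rate
}

# mL/min -> L/h
ML_MIN_TO_L_H <- 0.06

# Extraction coefficient of `patient` (one-row data frame or list) that
# applies to a session row: SA matched to the session's Qd for HD, SC for UF.
session_coef <- function(patient, modality, effluent_rate) {
  if (modality == "UF") return(patient$sc)
  col <- paste0("sa_", format(effluent_rate))
  if (is.null(patient[[col]]))
    stop("patient has no saturation coefficient for Qd ", effluent_rate)
  patient[[col]]
}

#' Piecewise-constant total clearance of one patient under a schedule
#'
#' Inside a session total clearance is `cl_nr + coef * effluent_rate` (SA for
#' HD, SC for UF); between sessions it is `cl_nr` alone (anuric patients).
#' Breakpoints fall exactly at session boundaries.
#'
#' @param patient One cohort row (see [sample_cohort()]).
#' @param schedule A [krt_schedule()].
#' @return A tibble with columns `t0`, `t1` (h) and `clearance` (mL/min)
#'   covering `[0, schedule$horizon]`.
#' @export
clearance_timeline <- function(patient, schedule) {
  stopifnot(inherits(schedule, "krt_schedule"))
  sess <- schedule$sessions
  bp <- sort(unique(c(0, sess$start, sess$end, schedule$horizon)))
  out <- tibble::tibble(t0 = bp[-length(bp)], t1 = bp[-1])
  mid <- (out$t0 + out$t1) / 2
  cl <- rep(patient$cl_nr, nrow(out))
  for (i in seq_len(nrow(sess))) {
    on <- mid >= sess$start[i] & mid < sess$end[i]
    if (any(on)) {
      coef <- session_coef(patient, sess$modality[i], sess$effluent_rate[i])
      cl[on] <- cl[on] +
        transmembrane_clearance(coef, sess$effluent_rate[i])
    }
  }
  out$clearance <- cl
  out
}
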