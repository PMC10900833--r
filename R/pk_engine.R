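#' Define a dosing regimen
#'
#' @param maintenance_dose Maintenance dose in mg (> 0). For
#'   piperacillin/tazobactam regimens this is the combination product dose
#'   (e.g. 4500 mg = 4 g piperacillin + 0.5 g tazobactam); the split is
#'   applied at evaluation time via the drug's companion dose fraction.
#' @param interval Dosing interval in hours, one of 6, 8, 12, 24.
#' @param infusion_duration Infusion length in hours; the study uses 0.5-h
#'   intermittent and 4-h extended infusions. Must be shorter than the
#'   interval.
#' @param loading_dose Optional first dose in mg replacing the first
#'   maintenance dose.
#' @param label Display string; composed from the doses if omitted.
#' @return An object of class `krt_regimen`.
#' @examples
#' regimen(1000, 24, loading_dose = 2000) # "2 g LD, 1 g q24h"
#' @export
regimen <- function(maintenance_dose, interval, infusion_duration = 0.5,
                    loading_dose = NULL, label = NULL) {
  stopifnot(maintenance_dose > 0, interval %in% c(6, 8, 12, 24),
            infusion_duration > 0, infusion_duration < interval)
  if (!is.null(loading_dose)) stopifnot(loading_dose > 0)
  fmt_g <- function(mg) paste0(format(mg / 1000), " g")
  if (is.null(label)) {
    label <- paste0(if (!is.null(loading_dose))
      paste0(fmt_g(loading_dose), " LD, ") else "",
      fmt_g(maintenance_dose), " q", interval, "h",
      if (infusion_duration > 0.5) " (ext inf)" else "")
  }
  structure(list(loading_dose = loading_dose,
                 maintenance_dose = maintenance_dose,
                 interval = interval, infusion_duration = infusion_duration,
                 label = label),
            class = "krt_regimen")
}

#' @export
print.krt_regimen <- function(x, ...) {
  cat("<krt_regimen>", x$label,
      sprintf("(%.2g-h infusion)\n", x$infusion_duration))
  invisible(x)
}

# Average dose over the simulated week, mg/day (loading dose amortized).
daily_dose <- function(regimen) {
  n_doses <- 168 %/% regimen$interval
  total <- n_doses * regimen$maintenance_dose
  if (!is.null(regimen$loading_dose))
    total <- total - regimen$maintenance_dose + regimen$loading_dose
  total / 7
}

#' Expand a regimen into dose events on a schedule's clock
#'
#' The first dose (the loading dose if present) starts at the schedule's dose
#' anchor: the end of the first HD session for settings 1-3, PIKRT start for
#' setting 4-early, 15 h before the first PIKRT session for 4-late (t = 0 on
#' that schedule's clock), and t = 0 for setting 5. Maintenance doses follow
#' at `anchor + k * interval` for one week; dose times are fixed clock times
#' and are not moved relative to sessions.
#'
#' @param regimen A [regimen()].
#' @param schedule A [krt_schedule()].
#' @param horizon Simulation end in hours (default: the schedule's horizon,
#'   one week after the first dose). An infusion running past the horizon is
#'   truncated with a warning.
#' @return A tibble with columns `start`, `duration` (h), `dose` (mg),
#'   `rate` (mg/h) and `which` (`"loading"`/`"maintenance"`).
#' @export
build_dose_events <- function(regimen, schedule, horizon = schedule$horizon) {
  stopifnot(inherits(regimen, "krt_regimen"), inherits(schedule, "krt_schedule"))
  anchor <- schedule$dose_anchor
  n_doses <- 168 %/% regimen$interval # all valid intervals divide the week
  starts <- anchor + regimen$interval * seq_len(n_doses) - regimen$interval
  starts <- starts[starts < horizon]
  dose <- rep(regimen$maintenance_dose, length(starts))
  which <- rep("maintenance", length(starts))
  if (!is.null(regimen$loading_dose)) {
    dose[1] <- regimen$loading_dose
    which[1] <- "loading"
  }
  ev <- tibble::tibble(start = starts, duration = regimen$infusion_duration,
                       dose = dose, which = which)
  over <- ev$start + ev$duration > horizon
  if (any(over)) {
    warning("truncating ", sum(over), " infusion(s) at the simulation horizon")
    ev$duration[over] <- horizon - ev$start[over]
    ev$dose[over] <- ev$dose[over] *
      ev$duration[over] / regimen$infusion_duration
  }
  ev$rate <- ev$dose / ev$duration
  ev[ev$duration > 0, c("start", "duration", "dose", "rate", "which")]
}

#' One-compartment step with constant infusion rate and elimination
#'
#' Advances the concentration of a one-compartment, first-order model by `dt`
#' hours under a constant zero-order input `r0` and elimination rate constant
#' `ke`: `c(dt) = c0 * exp(-ke dt) + r0/(ke Vd) * (1 - exp(-ke dt))`, with the
#' analytic limit `c0 + r0 dt / Vd` when `ke = 0`. All arguments are
#' vectorized.
#'
#' @param c0 Concentration at segment start (mg/L).
#' @param ke Elimination rate constant (1/h, >= 0).
#' @param r0 Infusion rate (mg/h, >= 0).
#' @param vd Volume of distribution (L, > 0).
#' @param dt Step length (h, >= 0).
#' @return Concentration after `dt` (mg/L).
#' @examples
#' segment_step(0, 0, 2000, 20, 0.5) # 50 mg/L: no elimination, dose / Vd
#' @export
segment_step <- function(c0, ke, r0, vd, dt) {
  stopifnot(all(vd > 0), all(dt >= 0), all(ke >= 0))
  n <- max(length(c0), length(ke), length(r0), length(vd), length(dt))
  c0 <- rep_len(c0, n); ke <- rep_len(ke, n); r0 <- rep_len(r0, n)
  vd <- rep_len(vd, n); dt <- rep_len(dt, n)
  out <- numeric(n)
  z <- ke == 0
  out[z] <- c0[z] + r0[z] * dt[z] / vd[z]
  if (any(!z)) {
    e <- exp(-ke[!z] * dt[!z])
    out[!z] <- c0[!z] * e + r0[!z] / (ke[!z] * vd[!z]) * (1 - e)
  }
  out
}

# Per-segment "on" coefficient bookkeeping: for each inter-breakpoint segment
# find the session covering it (sessions never overlap) and return the column
# of the cohort table holding the applicable extraction coefficient plus the
# session effluent rate ("" and 0 off-KRT).
segment_session_info <- function(bp, sessions) {
  m <- length(bp) - 1
  mid <- (bp[-1] + bp[-(m + 1)]) / 2
  coef_col <- character(m)
  rate <- numeric(m)
  for (i in seq_len(nrow(sessions))) {
    on <- mid > sessions$start[i] & mid < sessions$end[i]
    coef_col[on] <- if (sessions$modality[i] == "UF") "sc"
                    else paste0("sa_", format(sessions$effluent_rate[i]))
    rate[on] <- sessions$effluent_rate[i]
  }
  list(coef_col = coef_col, rate = rate)
}

#' Simulate one week of concentration-time profiles for a whole cohort
#'
#' Event-driven, piecewise-analytic solution of the one-compartment model for
#' every patient at once. Breakpoints are the union of dose starts/stops,
#' session starts/stops, and the day boundaries `first dose + 24 d`; within a
#' segment the elimination rate constant `ke = (CL_NR + coef * effluent) / Vd`
#' and infusion rate are constant and the closed-form [segment_step()] is
#' applied. The simulated state is total plasma concentration; free
#' concentration is `fu * total` per patient.
#'
#' @param cohort A [sample_cohort()] tibble (or any data frame with the same
#'   columns).
#' @param schedule A [krt_schedule()].
#' @param regimen A [regimen()].
#' @return An object of class `cohort_profiles`: breakpoint times, an
#'   `n x (m+1)` matrix of total concentrations at breakpoints, per-segment
#'   elimination rate constants, infusion rates, and the patient covariates
#'   needed to query it (`vd`, `fu`, `id`).
#' @examples
#' lib <- krt_drug_library()
#' cohort <- sample_cohort(lib$meropenem, n = 50, seed = 7)
#' prof <- simulate_cohort(cohort, krt_schedule(2), regimen(500, 12))
#' dim(prof$conc)
#' @export
simulate_cohort <- function(cohort, schedule, regimen) {
  stopifnot(inherits(schedule, "krt_schedule"), inherits(regimen, "krt_regimen"))
  events <- build_dose_events(regimen, schedule)
  t_first <- if (nrow(events)) events$start[1] else schedule$dose_anchor
  horizon <- schedule$horizon
  sess <- schedule$sessions
  bp <- sort(unique(c(0, horizon, events$start, events$start + events$duration,
                      sess$start, sess$end, t_first + 24 * (0:7))))
  bp <- bp[bp >= 0 & bp <= horizon]
  m <- length(bp) - 1
  mid <- (bp[-1] + bp[-(m + 1)]) / 2

  r0 <- numeric(m)
  for (i in seq_len(nrow(events))) {
    on <- mid > events$start[i] & mid < events$start[i] + events$duration[i]
    r0[on] <- r0[on] + events$rate[i]
  }

  info <- segment_session_info(bp, sess)
  n <- nrow(cohort)
  vd <- cohort$vd
  ke_off <- cohort$cl_nr * ML_MIN_TO_L_H / vd
  # n x m elimination-rate matrix; only a handful of distinct columns
  ke <- matrix(ke_off, n, m)
  for (j in which(info$coef_col != "")) {
    coef <- cohort[[info$coef_col[j]]]
    ke[, j] <- (cohort$cl_nr + coef * info$rate[j]) * ML_MIN_TO_L_H / vd
  }

  conc <- matrix(0, n, m + 1)
  for (j in seq_len(m)) {
    conc[, j + 1] <- segment_step(conc[, j], ke[, j], r0[j], vd, bp[j + 1] - bp[j])
  }

  structure(list(breakpoints = bp, conc = conc, ke = ke, r0 = r0,
                 vd = vd, fu = cohort$fu, id = cohort$id,
                 t_first_dose = t_first, drug = attr(cohort, "drug"),
                 schedule = schedule, regimen = regimen),
            class = "cohort_profiles")
}

#' @export
print.cohort_profiles <- function(x, ...) {
  cat(sprintf("<cohort_profiles> %s, %s, %s\n",
              x$drug %||% "drug", x$schedule$name, x$regimen$label))
  cat(sprintf("  %d patients, %d segments over [0, %g] h; first dose t = %g h\n",
              nrow(x$conc), length(x$r0), max(x$breakpoints), x$t_first_dose))
  invisible(x)
}

#' Simulate one patient's concentration-time profile
#'
#' Single-patient wrapper around [simulate_cohort()].
#'
#' @inheritParams simulate_cohort
#' @param patient One cohort row.
#' @return An object of class `conc_profile` with a `segments` tibble
#'   (`t0`, `t1`, `ke`, `r0`, `c0`), `vd`, `fu` and `t_first_dose`.
#' @export
simulate_profile <- function(patient, schedule, regimen) {
  cp <- simulate_cohort(patient[1, , drop = FALSE], schedule, regimen)
  m <- length(cp$r0)
  structure(list(
    segments = tibble::tibble(t0 = cp$breakpoints[-(m + 1)],
                              t1 = cp$breakpoints[-1],
                              ke = cp$ke[1, ], r0 = cp$r0,
                              c0 = cp$conc[1, -(m + 1)]),
    final_conc = cp$conc[1, m + 1],
    vd = cp$vd[1], fu = cp$fu[1], t_first_dose = cp$t_first_dose,
    drug = cp$drug, schedule = cp$schedule, regimen = cp$regimen),
    class = "conc_profile")
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("<conc_profile> %d segments over [0, %g] h, Vd %.1f L, fu %.2f\n",
              nrow(x$segments), max(x$segments$t1), x$vd, x$fu))
  invisible(x)
}

#' Query a concentration profile at arbitrary times
#'
#' @param profile A [simulate_profile()] result.
#' @param t Vector of times in hours within the simulated span.
#' @param scale `"total"` (model state) or `"free"` (`fu * total`).
#' @return Concentrations (mg/L) at `t`.
#' @export
conc_at <- function(profile, t, scale = c("total", "free")) {
  scale <- match.arg(scale)
  seg <- profile$segments
  stopifnot(all(t >= seg$t0[1]), all(t <= seg$t1[nrow(seg)] + 1e-9))
  j <- findInterval(t, seg$t0, rightmost.closed = FALSE)
  out <- segment_step(seg$c0[j], seg$ke[j], seg$r0[j], profile$vd, t - seg$t0[j])
  if (scale == "free") out <- out * profile$fu
  out
}

#' Export a profile as a concentration table
#'
#' @param x A `conc_profile`.
#' @param by Sampling resolution in hours.
#' @param ... Unused.
#' @return A tibble with `time`, `total`, `free` (mg/L).
#' @method tidy conc_profile
#' @export
tidy.conc_profile <- function(x, by = 0.1, ...) {
  t <- seq(x$segments$t0[1], max(x$segments$t1), by = by)
  total <- conc_at(x, t)
  tibble::tibble(time = t, total = total, free = total * x$fu)
}
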