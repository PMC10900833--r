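#' Define a pharmacodynamic target
#'
#' A PD target is a threshold concentration together with the required
#' fraction of each 24-h day that the free concentration must spend above it.
#' For the study drugs the threshold is the breakpoint MIC or four times the
#' MIC; for tazobactam it is a fixed 4 mg/L free-concentration threshold.
#'
#' @param threshold_conc Threshold in mg/L (> 0).
#' @param required_fraction Required fraction of each day above the threshold
#'   (0.40 for carbapenems, 0.50 for piperacillin and tazobactam, 0.60 for
#'   cephalosporins).
#' @param uses_free Compare the free (unbound) concentration (default) or the
#'   total concentration against the threshold.
#' @param label Display string.
#' @return An object of class `pd_target`.
#' @export
pd_target <- function(threshold_conc, required_fraction, uses_free = TRUE,
                      label = NULL) {
  stopifnot(threshold_conc > 0, required_fraction > 0, required_fraction <= 1)
  if (is.null(label))
    label <- sprintf("%.0f%% fT>%g mg/L", 100 * required_fraction, threshold_conc)
  structure(list(threshold_conc = threshold_conc,
                 required_fraction = required_fraction,
                 uses_free = uses_free, label = label),
            class = "pd_target")
}

#' @export
print.pd_target <- function(x, ...) {
  cat("<pd_target>", x$label, if (x$uses_free) "(free)" else "(total)", "\n")
  invisible(x)
}

#' @param drug A `drug_model` with a breakpoint MIC (or, for tazobactam, a
#'   fixed threshold concentration).
#' @param mic_multiplier 1 for fT>MIC, 4 for the aggressive fT>MICx4 target.
#' @rdname pd_target
#' @export
efficacy_target <- function(drug, mic_multiplier = 1) {
  stopifnot(inherits(drug, "drug_model"))
  if (!is.na(drug$threshold_conc))
    return(pd_target(drug$threshold_conc, drug$ft_fraction,
                     label = sprintf("%.0f%% fT>threshold %g mg/L",
                                     100 * drug$ft_fraction, drug$threshold_conc)))
  stopifnot(mic_multiplier %in% drug$mic_multiplier_targets)
  pd_target(drug$mic * mic_multiplier, drug$ft_fraction,
            label = sprintf("%.0f%% fT>MIC%s", 100 * drug$ft_fraction,
                            if (mic_multiplier > 1)
                              paste0("x", mic_multiplier) else ""))
}

# Exact time above threshold within one monotone segment.
# c(t) = css + (c0 - css) exp(-ke t) approaches css monotonically, so a
# segment has at most one crossing; the crossing time is closed-form.
seg_time_above <- function(c0, c1, ke, r0, vd, dt, thr) {
  out <- numeric(length(c0))
  above0 <- c0 > thr
  above1 <- c1 > thr
  out[above0 & above1] <- dt
  cross <- xor(above0, above1)
  if (any(cross)) {
    kc <- ke[cross]
    tstar <- numeric(sum(cross))
    pos <- kc > 0
    if (any(pos)) {
      css <- r0 / (kc[pos] * vd[cross][pos])
      tstar[pos] <- log((c0[cross][pos] - css) / (thr[cross][pos] - css)) / kc[pos]
    }
    if (any(!pos)) # ke = 0 with r0 > 0: linear rise
      tstar[!pos] <- (thr[cross][!pos] - c0[cross][!pos]) * vd[cross][!pos] / r0
    tstar <- pmin(pmax(tstar, 0), dt)
    out[cross] <- ifelse(above0[cross], tstar, dt - tstar)
  }
  out
}

# Hours above a per-patient total-scale threshold within [ta, tb] for every
# patient of a cohort_profiles object.
cohort_time_above <- function(profiles, thr, window) {
  bp <- profiles$breakpoints
  n <- length(profiles$vd)
  thr <- rep_len(thr, n)
  total <- numeric(n)
  for (j in seq_along(profiles$r0)) {
    s0 <- max(bp[j], window[1])
    s1 <- min(bp[j + 1], window[2])
    if (s1 <= s0) next
    kej <- profiles$ke[, j]
    c_s0 <- segment_step(profiles$conc[, j], kej, profiles$r0[j],
                         profiles$vd, s0 - bp[j])
    c_s1 <- segment_step(profiles$conc[, j], kej, profiles$r0[j],
                         profiles$vd, s1 - bp[j])
    total <- total + seg_time_above(c_s0, c_s1, kej, profiles$r0[j],
                                    profiles$vd, s1 - s0, thr)
  }
  total
}

#' Exact time spent above a threshold concentration
#'
#' Computes the time a profile spends above a threshold within a window,
#' segment by segment with closed-form crossing times (no time grid). Within
#' a segment the concentration approaches its segment steady state
#' monotonically, so at most one crossing per segment exists.
#'
#' @param profile A [simulate_profile()] result.
#' @param threshold Threshold concentration (mg/L, > 0).
#' @param window Two-element vector `c(ta, tb)` in hours within the simulated
#'   span.
#' @param scale `"free"` compares `fu * total` (the PD convention);
#'   `"total"` compares the model state (the toxicity convention).
#' @return Hours above the threshold, in `[0, tb - ta]`.
#' @examples
#' lib <- krt_drug_library()
#' p <- sample_cohort(lib$meropenem, 1, seed = 3)
#' prof <- simulate_profile(p, krt_schedule(5), regimen(1000, 12))
#' time_above(prof, 2, window = c(0, 24))
#' @export
time_above <- function(profile, threshold, window, scale = c("free", "total")) {
  scale <- match.arg(scale)
  stopifnot(inherits(profile, "conc_profile"), threshold > 0,
            length(window) == 2, window[1] < window[2])
  seg <- profile$segments
  cp <- list(breakpoints = c(seg$t0, seg$t1[nrow(seg)]),
             conc = matrix(seg$c0, 1), ke = matrix(seg$ke, 1), r0 = seg$r0,
             vd = profile$vd)
  thr <- if (scale == "free") threshold / profile$fu else threshold
  cohort_time_above(cp, thr, window)
}

#' Per-day target attainment for every patient
#'
#' Day `d` is the window `[24 (d-1), 24 d]` hours after the first dose; a
#' patient attains the target on a day when the free (or total, per the
#' target) concentration exceeds the threshold for at least
#' `required_fraction` of that day (non-strict).
#'
#' @param profiles A [simulate_cohort()] result spanning one week of therapy.
#' @param target A [pd_target()] or [efficacy_target()].
#' @param days Days to evaluate (default 1:7).
#' @return A tibble with columns `id`, `day`, `hours_above`, `fraction`,
#'   `attained`.
#' @export
daily_attainment <- function(profiles, target, days = 1:7) {
  stopifnot(inherits(profiles, "cohort_profiles"), inherits(target, "pd_target"))
  thr <- if (target$uses_free) target$threshold_conc / profiles$fu
         else rep_len(target$threshold_conc, length(profiles$fu))
  t0 <- profiles$t_first_dose
  purrr::map_dfr(days, function(d) {
    h <- cohort_time_above(profiles, thr, t0 + c(24 * (d - 1), 24 * d))
    tibble::tibble(id = profiles$id, day = d, hours_above = h,
                   fraction = h / 24,
                   attained = h / 24 >= target$required_fraction)
  })
}

#' Cohort probability of target attainment by day
#'
#' @param attainment A [daily_attainment()] (or [combo_attainment()]) tibble.
#' @return A tibble of class `pta_table` with columns `day`, `n`, `pta`
#'   (percent of the cohort attaining the target that day). The weekly
#'   minimum is attached as attribute `weekly_min` and reported by
#'   [glance.pta_table()].
#' @export
pta <- function(attainment) {
  stopifnot(nrow(attainment) > 0)
  out <- dplyr::summarise(dplyr::group_by(attainment, .data$day),
                          n = dplyr::n(),
                          pta = 100 * mean(.data$attained), .groups = "drop")
  attr(out, "weekly_min") <- min(out$pta)
  class(out) <- c("pta_table", class(out))
  out
}

#' @param x A `pta_table`.
#' @param ... Unused.
#' @rdname pta
#' @method glance pta_table
#' @export
glance.pta_table <- function(x, ...) {
  tibble::tibble(weekly_min_pta = attr(x, "weekly_min"),
                 day1_pta = x$pta[x$day == min(x$day)],
                 n = x$n[1])
}

#' End-of-day toxicity-threshold exceedance probability
#'
#' For each day, the share of the cohort whose concentration at the end of
#' the day (the instant `24 d` hours after the first dose) is at or above the
#' drug's neurotoxicity threshold. Thresholds are total plasma concentrations
#' by default; `scale = "free"` compares `fu * total` instead (an alternative
#' reading for the piperacillin threshold).
#'
#' @param profiles A [simulate_cohort()] result.
#' @param threshold Toxicity threshold (mg/L).
#' @param scale `"total"` (default) or `"free"`.
#' @param days Days to evaluate (default 1:7).
#' @return A tibble with columns `day`, `n`, `toxicity` (percent).
#' @export
toxicity_probability <- function(profiles, threshold, scale = c("total", "free"),
                                 days = 1:7) {
  scale <- match.arg(scale)
  stopifnot(inherits(profiles, "cohort_profiles"), threshold > 0)
  bp <- profiles$breakpoints
  purrr::map_dfr(days, function(d) {
    t_end <- profiles$t_first_dose + 24 * d
    j <- which(abs(bp - t_end) < 1e-9)
    stopifnot(length(j) == 1) # day boundaries are breakpoints by construction
    conc <- profiles$conc[, j]
    if (scale == "free") conc <- conc * profiles$fu
    tibble::tibble(day = d, n = length(conc),
                   toxicity = 100 * mean(conc >= threshold))
  })
}

#' Joint attainment of the piperacillin and tazobactam targets
#'
#' A piperacillin/tazobactam regimen attains its target on a day only if the
#' piperacillin efficacy target and the tazobactam threshold target (50%
#' fT > 4 mg/L free) are both attained by the same patient on that day.
#'
#' @param pip_attain,tazo_attain [daily_attainment()] tibbles for the two
#'   components over the same cohort indices and days.
#' @return A tibble with `id`, `day`, per-component attainment flags, and the
#'   joint `attained`.
#' @export
combo_attainment <- function(pip_attain, tazo_attain) {
  stopifnot(nrow(pip_attain) == nrow(tazo_attain))
  joined <- dplyr::inner_join(
    dplyr::select(pip_attain, "id", "day", pip_attained = "attained"),
    dplyr::select(tazo_attain, "id", "day", tazo_attained = "attained"),
    by = c("id", "day"))
  stopifnot(nrow(joined) == nrow(pip_attain)) # same cohort required
  dplyr::mutate(joined, attained = .data$pip_attained & .data$tazo_attained)
}
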