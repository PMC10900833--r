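#' Evaluate one dosing regimen for a drug, KRT setting and PD target
#'
#' Simulates the whole cohort under the regimen, assembles per-day PTA and
#' toxicity-exceedance tables, and computes the average daily dose (total mg
#' over the week / 7, loading dose amortized). For setting 4 both the early
#' and late PIKRT variants are evaluated and reported together, since a
#' recommended dose must work regardless of when the dose falls relative to
#' the session. For piperacillin the regimen dose is the combination product
#' dose: piperacillin receives 8/9 and tazobactam 1/9 of it, tazobactam is
#' simulated as an independently parameterized companion drug, and a day
#' counts as attained only when both component targets are attained
#' ([combo_attainment()]).
#'
#' @param drug A `drug_model`.
#' @param setting KRT setting 1-5 (see [krt_schedule()]).
#' @param regimen A [regimen()]; dose in mg of product.
#' @param cohort A [sample_cohort()] cohort for `drug`.
#' @param mic_multiplier 1 (fT>MIC) or 4 (fT>MICx4).
#' @param companion_cohort Cohort for the companion drug; sampled
#'   automatically from the cohort's seed when the drug has a companion and
#'   none is given.
#' @param toxicity_scale `"total"` (default) or `"free"`; the free scale is
#'   an alternative reading of the piperacillin threshold.
#' @param max_daily_dose Conventional daily-dose cap in mg/day used for the
#'   `exceeds_max_daily` flag (NA = no cap).
#' @return An object of class `regimen_report` with a `by_day` tibble
#'   (`variant`, `day`, `pta`, `toxicity`), the average `daily_dose`, the
#'   weekly floor PTA across variants, and advisory flags.
#' @export
evaluate_regimen <- function(drug, setting, regimen, cohort,
                             mic_multiplier = 1, companion_cohort = NULL,
                             toxicity_scale = c("total", "free"),
                             max_daily_dose = NA) {
  toxicity_scale <- match.arg(toxicity_scale)
  stopifnot(inherits(drug, "drug_model"), inherits(regimen, "krt_regimen"))
  target <- efficacy_target(drug, mic_multiplier)
  has_companion <- !is.null(drug$companion)
  if (has_companion && is.null(companion_cohort)) {
    seed <- attr(cohort, "seed") %||% 1L
    companion_cohort <- sample_cohort(drug$companion, nrow(cohort),
                                      substream_seed(seed, "companion"))
  }
  variants <- if (setting == 4) c("early", "late") else "none"

  by_day <- purrr::map_dfr(variants, function(v) {
    sched <- krt_schedule(setting, v)
    if (has_companion) {
      frac <- drug$companion_dose_frac
      scale_reg <- function(f) regimen(
        regimen$maintenance_dose * f, regimen$interval,
        regimen$infusion_duration,
        if (!is.null(regimen$loading_dose)) regimen$loading_dose * f,
        label = regimen$label)
      prof <- simulate_cohort(cohort, sched, scale_reg(1 - frac))
      prof_c <- simulate_cohort(companion_cohort, sched, scale_reg(frac))
      att <- combo_attainment(
        daily_attainment(prof, target),
        daily_attainment(prof_c, efficacy_target(drug$companion)))
    } else {
      prof <- simulate_cohort(cohort, sched, regimen)
      att <- daily_attainment(prof, target)
    }
    p <- pta(att)
    tox <- if (!is.na(drug$toxicity_threshold))
      toxicity_probability(prof, drug$toxicity_threshold, toxicity_scale)$toxicity
    else rep(NA_real_, nrow(p))
    tibble::tibble(variant = v, day = p$day, pta = p$pta, toxicity = tox)
  })

  floor_pta <- min(by_day$pta)
  day1_pta <- min(by_day$pta[by_day$day == 1])
  days27_floor <- min(by_day$pta[by_day$day > 1])
  dd <- daily_dose(regimen)
  structure(list(
    drug = drug$name, setting = setting, regimen = regimen,
    target = target, mic_multiplier = mic_multiplier,
    by_day = by_day, daily_dose = dd,
    floor_pta = floor_pta, day1_pta = day1_pta, days27_floor = days27_floor,
    n = nrow(cohort),
    flags = list(
      day1_shortfall = day1_pta < 90 && days27_floor >= 85,
      exceeds_max_daily = !is.na(max_daily_dose) && dd > max_daily_dose,
      toxicity_concern = any(by_day$toxicity >= 50, na.rm = TRUE))),
    class = "regimen_report")
}

#' @export
print.regimen_report <- function(x, ...) {
  cat(sprintf("<regimen_report> %s, setting %d, %s: %s\n",
              x$drug, x$setting, x$target$label, x$regimen$label))
  cat(sprintf("  daily dose %.0f mg/day; weekly floor PTA %.1f%% (day 1 %.1f%%)\n",
              x$daily_dose, x$floor_pta, x$day1_pta))
  flg <- names(Filter(isTRUE, x$flags))
  if (length(flg)) cat("  flags:", paste(flg, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy and summarize a regimen report
#'
#' @param x A [evaluate_regimen()] report.
#' @param ... Unused.
#' @return `tidy()` returns the per-day PTA/toxicity tibble with identifying
#'   columns; `glance()` a one-row summary.
#' @method tidy regimen_report
#' @export
tidy.regimen_report <- function(x, ...) {
  dplyr::mutate(x$by_day, drug = x$drug, setting = x$setting,
                regimen = x$regimen$label, target = x$target$label,
                .before = 1)
}

#' @rdname tidy.regimen_report
#' @method glance regimen_report
#' @export
glance.regimen_report <- function(x, ...) {
  tibble::tibble(drug = x$drug, setting = x$setting,
                 regimen = x$regimen$label, target = x$target$label,
                 daily_dose = x$daily_dose, floor_pta = x$floor_pta,
                 day1_pta = x$day1_pta, days27_floor = x$days27_floor,
                 max_toxicity = if (all(is.na(x$by_day$toxicity))) NA_real_
                                else max(x$by_day$toxicity),
                 n = x$n,
                 day1_shortfall = x$flags$day1_shortfall,
                 exceeds_max_daily = x$flags$exceeds_max_daily,
                 toxicity_concern = x$flags$toxicity_concern)
}

#' Optimal-regimen selection rule
#'
#' A regimen is optimal when it attains the PD target in at least `pta_floor`
#' percent of the cohort on every day of the week with the smallest average
#' daily dose (ties broken toward fewer administrations per day). When no
#' candidate does so within the conventional daily-dose cap, regimens whose
#' days 2-7 stay within `approx_band` of the floor are accepted with a
#' relaxed day-1 requirement (`day1_relaxation_floor`), and, if a cap makes
#' even that unreachable, with no day-1 requirement at all.
#'
#' @param pta_floor Required PTA, percent (default 90).
#' @param day1_relaxation_floor Minimum acceptable day-1 PTA when day 1 alone
#'   misses the floor (default 75).
#' @param approx_band How far below `pta_floor` days 2-7 may fall and still
#'   count as "approximately attained", in percentage points (default 2.5).
#' @param max_daily_dose Named vector of per-drug conventional daily-dose
#'   caps in mg/day; only cefepime's 6 g/day cap is established, other drugs
#'   are uncapped unless configured.
#' @return An object of class `selection_rule`.
#' @export
selection_rule <- function(pta_floor = 90, day1_relaxation_floor = 75,
                           approx_band = 2.5,
                           max_daily_dose = c(cefepime = 6000)) {
  stopifnot(day1_relaxation_floor < pta_floor)
  structure(list(pta_floor = pta_floor,
                 day1_relaxation_floor = day1_relaxation_floor,
                 approx_band = approx_band,
                 max_daily_dose = max_daily_dose),
            class = "selection_rule")
}

#' Select the optimal regimen among evaluated candidates
#'
#' @param reports A list of [evaluate_regimen()] reports sharing drug,
#'   setting and target.
#' @param rule A [selection_rule()].
#' @return The selected `regimen_report`, with a `rationale` element naming
#'   the rule branch that fired.
#' @export
select_optimal <- function(reports, rule = selection_rule()) {
  stopifnot(length(reports) > 0)
  g <- purrr::map_dfr(reports, glance.regimen_report)
  stopifnot(length(unique(g$drug)) == 1, length(unique(g$setting)) == 1,
            length(unique(g$target)) == 1)
  cap <- rule$max_daily_dose[g$drug[1]]
  cap <- if (is.na(cap)) Inf else unname(cap)
  intervals <- purrr::map_dbl(reports, ~ .x$regimen$interval)

  pick <- function(idx) {
    ord <- order(g$daily_dose[idx], -intervals[idx])
    idx[ord][1]
  }
  under_cap <- g$daily_dose <= cap
  approx_floor <- rule$pta_floor - rule$approx_band

  primary <- which(g$floor_pta >= rule$pta_floor & under_cap)
  relaxed <- which(g$days27_floor >= approx_floor &
                   g$day1_pta >= rule$day1_relaxation_floor & under_cap)
  capped <- which(g$days27_floor >= approx_floor & under_cap)

  if (length(primary)) {
    sel <- pick(primary)
    rationale <- sprintf("PTA >= %g%% on every day with the smallest daily dose",
                         rule$pta_floor)
  } else if (length(relaxed)) {
    sel <- pick(relaxed)
    rationale <- sprintf(
      "days 2-7 PTA ~%g%% with day-1 PTA %.1f%% accepted (>= %g%% relaxation floor); no candidate met the floor on day 1 within the %s cap",
      rule$pta_floor, g$day1_pta[sel], rule$day1_relaxation_floor,
      if (is.finite(cap)) paste0(cap / 1000, " g/day") else "uncapped")
  } else if (length(capped) && is.finite(cap)) {
    sel <- pick(capped)
    rationale <- sprintf(
      "days 2-7 PTA ~%g%%; day-1 PTA %.1f%% accepted because reaching the floor on day 1 would exceed the maximal conventional dose (%g g/day)",
      rule$pta_floor, g$day1_pta[sel], cap / 1000)
  } else {
    stop("no candidate regimen satisfies the selection rule")
  }
  out <- reports[[sel]]
  out$rationale <- rationale
  out
}

#' Default candidate regimen grids
#'
#' A reconstruction of the candidate dose/interval grids evaluated per drug:
#' conventional unit doses at intervals 6/8/12/24 h, with and without a
#' loading dose of twice (or here, for cefepime's aggressive target, three
#' times) the unit dose. Doses are combination product doses for
#' piperacillin/tazobactam.
#'
#' @param drug_name One of the five study drugs.
#' @param infusion_duration 0.5 (intermittent) or 4 (extended) hours.
#' @return A list of [regimen()] objects.
#' @export
default_candidates <- function(drug_name, infusion_duration = 0.5) {
  grid <- switch(drug_name,
    cefepime = list(c(1000, 24, 2000), c(1000, 12, NA), c(1000, 12, 2000),
                    c(2000, 12, 3000), c(1000, 6, 2000), c(1000, 6, 3000),
                    c(2000, 8, NA), c(2000, 12, NA)),
    ceftazidime = list(c(1000, 24, NA), c(1000, 12, NA), c(1000, 8, 2000),
                       c(2000, 8, NA), c(2000, 12, NA)),
    imipenem = list(c(500, 12, NA), c(500, 8, NA), c(750, 8, NA),
                    c(1000, 8, NA), c(750, 6, NA)),
    meropenem = list(c(500, 24, NA), c(500, 12, NA), c(500, 12, 1000),
                     c(500, 8, NA), c(1000, 12, NA)),
    piperacillin = list(c(2250, 12, NA), c(3375, 12, NA), c(4500, 12, NA),
                        c(4500, 8, NA), c(3375, 8, NA), c(3375, 6, NA),
                        c(4500, 6, NA), c(3000, 8, NA), c(4000, 6, NA)),
    stop("no default candidate grid for drug: ", drug_name))
  purrr::map(grid, function(x)
    regimen(x[1], x[2], infusion_duration,
            loading_dose = if (!is.na(x[3])) x[3]))
}
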