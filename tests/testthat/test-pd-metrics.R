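# A profile that is exactly constant after its single infusion: no
# elimination route at all (cl_nr = 0, all extraction coefficients 0).
flat_profile <- function(dose = 1000, vd = 20, fu = 1) {
  p <- make_patient(vd = vd, fu = fu, cl_nr = 0, sa_300 = 0, sa_100 = 0,
                    sa_50 = 0, sc = 0)
  simulate_profile(p, krt_schedule(2), regimen(dose, 24))
}

test_that("time above threshold handles always-above and never-above", {
  # with no elimination the daily 1 g doses step the plateau up by 50 mg/L;
  # within day 1 (after the 0.5-h infusion ending at 4.5) it sits at 50
  prof <- flat_profile(dose = 1000, vd = 20)
  expect_equal(time_above(prof, 8, c(5, 27)), 22)
  expect_equal(time_above(prof, 60, c(5, 27)), 0)
  # bounded by the window length and additive over disjoint windows
  expect_equal(time_above(prof, 8, c(5, 16)) + time_above(prof, 8, c(16, 27)),
               time_above(prof, 8, c(5, 27)))
  expect_lte(time_above(prof, 8, c(0, 168)), 168)
})

test_that("time above threshold is exact against a dense-grid oracle", {
  lib <- krt_drug_library()
  set.seed(314)
  drugs <- names(lib)[1:5]
  schedules <- list(krt_schedule(1), krt_schedule(2), krt_schedule(3),
                    krt_schedule(4, "early"), krt_schedule(4, "late"),
                    krt_schedule(5))
  for (i in 1:60) {
    d <- lib[[sample(drugs, 1)]]
    co <- sample_cohort(d, 1, seed = 1000 + i)
    reg <- regimen(sample(c(500, 1000, 2000, 4000), 1),
                   sample(c(6, 8, 12, 24), 1),
                   infusion_duration = sample(c(0.5, 4), 1))
    sched <- schedules[[sample(length(schedules), 1)]]
    prof <- simulate_profile(co, sched, reg)
    day <- sample(0:6, 1)
    win <- prof$t_first_dose + 24 * day + c(0, 24)
    thr <- stats::runif(1, 1, 80)
    expect_equal(time_above(prof, thr, win, scale = "free"),
                 dense_time_above(prof, thr, win, scale = "free"),
                 tolerance = 2e-3 / 24) # testthat tolerance is relative
  }
})

test_that("time above is monotone non-increasing in the threshold", {
  lib <- krt_drug_library()
  co <- sample_cohort(lib$cefepime, 1, seed = 77)
  prof <- simulate_profile(co, krt_schedule(2), regimen(2000, 12))
  win <- c(4, 28)
  thrs <- c(2, 8, 16, 32, 64)
  h <- vapply(thrs, function(th) time_above(prof, th, win), numeric(1))
  expect_true(all(diff(h) <= 1e-12))
  expect_true(all(h >= 0 & h <= 24))
})

test_that("daily attainment applies the required fraction per day", {
  # constant free concentration just above 4x MIC: every day attained
  p <- make_patient(vd = 20, cl_nr = 0, sa_300 = 0, sa_100 = 0, sa_50 = 0,
                    sc = 0)
  co <- p
  cohort_prof <- simulate_cohort(co, krt_schedule(2), regimen(33 * 20, 24))
  lib <- krt_drug_library()
  att <- daily_attainment(cohort_prof, efficacy_target(lib$cefepime, 4))
  expect_equal(nrow(att), 7)
  expect_true(all(att$attained))
  expect_true(all(att$fraction >= 0 & att$fraction <= 1))

  # threshold composition: cefepime 8/32, piperacillin 16/64
  expect_equal(efficacy_target(lib$cefepime, 1)$threshold_conc, 8)
  expect_equal(efficacy_target(lib$cefepime, 4)$threshold_conc, 32)
  expect_equal(efficacy_target(lib$cefepime, 4)$required_fraction, 0.60)
  expect_equal(efficacy_target(lib$piperacillin, 1)$threshold_conc, 16)
  expect_equal(efficacy_target(lib$piperacillin, 4)$threshold_conc, 64)

  # attainment comparison is non-strict: exactly the required fraction passes
  expect_true(att$fraction[1] >= 0.60)
})

test_that("PTA summarises the cohort by day with its weekly minimum", {
  att <- tibble::tibble(id = rep(1:4, each = 2), day = rep(1:2, 4),
                        attained = c(TRUE, TRUE, TRUE, FALSE,
                                     TRUE, TRUE, FALSE, FALSE))
  p <- pta(att)
  expect_equal(p$pta, c(75, 50))
  expect_equal(attr(p, "weekly_min"), 50)
  g <- glance(p)
  expect_equal(g$weekly_min_pta, 50)
  expect_equal(g$day1_pta, 75)
  expect_error(pta(att[0, ]))
})

test_that("PTA is monotone in MIC multiplier and dose; toxicity in dose", {
  lib <- krt_drug_library()
  co <- sample_cohort(lib$cefepime, 400, seed = 21)
  for (sched in list(krt_schedule(2), krt_schedule(4, "early"))) {
    ptas <- list(); tox <- list()
    for (dose in c(500, 1000, 2000)) {
      prof <- simulate_cohort(co, sched, regimen(dose, 8))
      ptas[[as.character(dose)]] <- vapply(c(1, 4), function(m)
        pta(daily_attainment(prof, efficacy_target(lib$cefepime, m)))$pta,
        numeric(7))
      tox[[as.character(dose)]] <-
        toxicity_probability(prof, lib$cefepime$toxicity_threshold)$toxicity
    }
    for (d in 1:3) # fT>MICx4 PTA never exceeds fT>MIC PTA on any day
      expect_true(all(ptas[[d]][, 2] <= ptas[[d]][, 1]))
    # dose escalation never lowers PTA or toxicity on any day
    expect_true(all(ptas[["1000"]] >= ptas[["500"]]))
    expect_true(all(ptas[["2000"]] >= ptas[["1000"]]))
    expect_true(all(tox[["1000"]] >= tox[["500"]]))
    expect_true(all(tox[["2000"]] >= tox[["1000"]]))
  }
})

test_that("with fu = 1 free and total metrics coincide", {
  lib <- krt_drug_library()
  co <- sample_cohort(lib$meropenem, 30, seed = 31)
  co$fu <- rep(1, nrow(co))
  prof <- simulate_cohort(co, krt_schedule(5), regimen(1000, 12))
  free_t <- daily_attainment(prof, pd_target(2, 0.4, uses_free = TRUE))
  tot_t <- daily_attainment(prof, pd_target(2, 0.4, uses_free = FALSE))
  expect_equal(free_t$hours_above, tot_t$hours_above)
})

test_that("end-of-day toxicity uses the instantaneous trough, at-or-above", {
  # no elimination: the end-of-day-d concentration is exactly 50 d mg/L
  # (d doses of 1 g into 20 L; the day-d+1 dose starts at that instant but
  # has not yet been infused)
  p <- make_patient(vd = 20, cl_nr = 0, sa_300 = 0, sa_100 = 0, sa_50 = 0,
                    sc = 0)
  prof <- simulate_cohort(p, krt_schedule(2), regimen(1000, 24))
  expect_equal(toxicity_probability(prof, 50)$toxicity, rep(100, 7))
  expect_equal(toxicity_probability(prof, 50.0001)$toxicity,
               c(0, rep(100, 6))) # day-1 trough is exactly 50: non-strict
  expect_equal(toxicity_probability(prof, 350.0001)$toxicity, rep(0, 7))
  # free scale compares fu * total (free trough on day d is 25 d mg/L)
  p2 <- p; p2$fu <- 0.5
  prof2 <- simulate_cohort(p2, krt_schedule(2), regimen(1000, 24))
  expect_equal(toxicity_probability(prof2, 30, scale = "free")$toxicity,
               c(0, rep(100, 6)))
  expect_equal(toxicity_probability(prof2, 25, scale = "free")$toxicity,
               rep(100, 7))
})

test_that("combination attainment requires both components on the same day", {
  pip <- tibble::tibble(id = c(1, 1, 2, 2), day = c(1, 2, 1, 2),
                        attained = c(TRUE, TRUE, TRUE, FALSE))
  tz <- tibble::tibble(id = c(1, 1, 2, 2), day = c(1, 2, 1, 2),
                       attained = c(TRUE, FALSE, TRUE, TRUE))
  both <- combo_attainment(pip, tz)
  expect_equal(both$attained, c(TRUE, FALSE, TRUE, FALSE))
  expect_error(combo_attainment(pip, tz[1:3, ]))
})
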