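# Minimal hand-built report for exercising the selection rule without
# running simulations.
fake_report <- function(daily_dose, interval, pta_by_day,
                        drug = "drugA", setting = 2) {
  by_day <- tibble::tibble(variant = "none", day = 1:7, pta = pta_by_day,
                           toxicity = NA_real_)
  structure(list(drug = drug, setting = setting,
                 regimen = regimen(daily_dose * 7 / (168 / interval), interval,
                                   label = paste0(daily_dose, "@q", interval)),
                 target = pd_target(8, 0.6, label = "tgt"),
                 mic_multiplier = 1, by_day = by_day, daily_dose = daily_dose,
                 floor_pta = min(pta_by_day), day1_pta = pta_by_day[1],
                 days27_floor = min(pta_by_day[-1]), n = 5000,
                 flags = list(day1_shortfall = FALSE, exceeds_max_daily = FALSE,
                              toxicity_concern = FALSE)),
            class = "regimen_report")
}

test_that("selection picks the smallest compliant daily dose", {
  r1 <- fake_report(4000, 12, rep(95, 7))
  r2 <- fake_report(2000, 12, rep(92, 7))
  r3 <- fake_report(1000, 12, c(85, rep(95, 6))) # fails the floor on day 1
  best <- select_optimal(list(r1, r2, r3))
  expect_equal(best$daily_dose, 2000)
  expect_match(best$rationale, "smallest daily dose")
})

test_that("equal daily doses tie-break toward fewer administrations per day", {
  q6 <- fake_report(13500, 6, rep(93, 7))  # 3.375 g q6h
  q8 <- fake_report(13500, 8, rep(93, 7))  # 4.5 g q8h
  best <- select_optimal(list(q6, q8))
  expect_equal(best$regimen$interval, 8)
})

test_that("day-1 relaxation accepts near-miss day 1 when nothing passes fully", {
  r1 <- fake_report(2000, 12, c(78, rep(91, 6)))
  r2 <- fake_report(4000, 12, c(82, rep(93, 6)))
  best <- select_optimal(list(r1, r2))
  expect_equal(best$daily_dose, 2000)
  expect_match(best$rationale, "relaxation")
  # below the 75% relaxation floor and uncapped: rule is unsatisfiable
  r3 <- fake_report(2000, 12, c(60, rep(91, 6)))
  expect_error(select_optimal(list(r3)), "no candidate")
})

test_that("the daily-dose cap branch admits low day-1 PTA for capped drugs", {
  # cefepime capped at 6 g/day: a 63%-day-1 regimen under the cap wins over
  # an over-cap regimen that would fix day 1
  under <- fake_report(4000, 6, c(63, rep(90, 6)), drug = "cefepime")
  over <- fake_report(8000, 6, rep(95, 7), drug = "cefepime")
  best <- select_optimal(list(under, over))
  expect_equal(best$daily_dose, 4000)
  expect_match(best$rationale, "maximal conventional dose")
})

test_that("the selected regimen is never dominated by another candidate", {
  set.seed(5)
  for (rep_i in 1:20) {
    n <- 5
    reports <- purrr::map(1:n, function(i)
      fake_report(sample(seq(1000, 8000, 500), 1), sample(c(6, 8, 12, 24), 1),
                  pmin(100, stats::runif(7, 80, 100))))
    best <- tryCatch(select_optimal(reports), error = function(e) NULL)
    if (is.null(best)) next
    for (r in reports) {
      dominates <- r$daily_dose < best$daily_dose &&
        all(r$by_day$pta >= best$by_day$pta) && r$floor_pta >= 90
      expect_false(dominates)
    }
  }
})

test_that("evaluate_regimen assembles PTA and toxicity per day", {
  lib <- krt_drug_library()
  co <- sample_cohort(lib$meropenem, 200, seed = 9)
  rep1 <- evaluate_regimen(lib$meropenem, 2, regimen(500, 12), co)
  expect_s3_class(rep1, "regimen_report")
  expect_equal(nrow(rep1$by_day), 7)
  expect_true(all(rep1$by_day$pta >= 0 & rep1$by_day$pta <= 100))
  expect_true(all(rep1$by_day$toxicity >= 0 & rep1$by_day$toxicity <= 100))
  expect_equal(rep1$daily_dose, 1000)
  td <- tidy(rep1)
  expect_named(td, c("drug", "setting", "regimen", "target", "variant",
                     "day", "pta", "toxicity"))
  expect_equal(nrow(glance(rep1)), 1)
})

test_that("setting 4 evaluates both early and late variants", {
  lib <- krt_drug_library()
  co <- sample_cohort(lib$cefepime, 300, seed = 13)
  rep4 <- evaluate_regimen(lib$cefepime, 4, regimen(1000, 12), co)
  expect_setequal(unique(rep4$by_day$variant), c("early", "late"))
  expect_equal(nrow(rep4$by_day), 14)
  # dose timing relative to PIKRT changes day-1 toxicity markedly
  d1 <- rep4$by_day[rep4$by_day$day == 1, ]
  expect_gt(d1$toxicity[d1$variant == "early"],
            d1$toxicity[d1$variant == "late"])
  # the floor aggregates over both variants
  expect_equal(rep4$floor_pta, min(rep4$by_day$pta))
})

test_that("piperacillin evaluation applies the 8:1 split and joint target", {
  lib <- krt_drug_library()
  co <- sample_cohort(lib$piperacillin, 300, seed = 17)
  repc <- evaluate_regimen(lib$piperacillin, 2, regimen(4500, 12), co)
  expect_equal(nrow(repc$by_day), 7)
  # joint attainment can only be harder than piperacillin alone: compare
  # against an artificial evaluation with the companion target removed
  solo <- lib$piperacillin
  solo$companion <- NULL
  prof <- simulate_cohort(co, krt_schedule(2), regimen(4000, 12))
  solo_pta <- pta(daily_attainment(prof, efficacy_target(solo, 1)))
  expect_true(all(repc$by_day$pta <= solo_pta$pta + 1e-9))
})

test_that("aggressive targets never select a smaller daily dose", {
  lib <- krt_drug_library()
  co <- sample_cohort(lib$meropenem, 300, seed = 23)
  cands <- default_candidates("meropenem")
  sel <- purrr::map(c(1, 4), function(m) {
    reports <- purrr::map(cands, function(r)
      evaluate_regimen(lib$meropenem, 2, r, co, mic_multiplier = m))
    select_optimal(reports)
  })
  expect_gte(sel[[2]]$daily_dose, sel[[1]]$daily_dose)
})
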