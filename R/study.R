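#' Assemble a study configuration
#'
#' @param drugs Character vector of study drugs (default: all five;
#'   tazobactam is simulated implicitly as piperacillin's companion).
#' @param settings KRT settings to simulate (default 1:5).
#' @param targets `"mic"`, `"micx4"`, or both.
#' @param n Cohort size (default 5000).
#' @param seed Master seed; each (drug, setting) pair draws from its own
#'   deterministic substream, so adding a scenario never perturbs another's
#'   draws.
#' @param infusion_duration 0.5-h intermittent (default) or 4-h extended
#'   infusions.
#' @param out_dir Output directory for the CSV tables.
#' @param toxicity_scale `"total"` (default) or `"free"` for the piperacillin
#'   threshold reading.
#' @param drug_library Optional path to a YAML drug-library override
#'   ([read_drug_library()]).
#' @return A list of class `study_config`.
#' @export
study_config <- function(drugs = c("cefepime", "ceftazidime", "imipenem",
                                   "meropenem", "piperacillin"),
                         settings = 1:5, targets = c("mic", "micx4"),
                         n = 5000, seed = 1L, infusion_duration = 0.5,
                         out_dir = "krtdose-study",
                         toxicity_scale = c("total", "free"),
                         drug_library = NULL) {
  toxicity_scale <- match.arg(toxicity_scale)
  stopifnot(n >= 1, all(settings %in% 1:5),
            all(targets %in% c("mic", "micx4")))
  lib_names <- names(krt_drug_library())
  stopifnot(all(drugs %in% lib_names))
  structure(list(drugs = drugs, settings = settings, targets = targets,
                 n = n, seed = as.integer(seed),
                 infusion_duration = infusion_duration, out_dir = out_dir,
                 toxicity_scale = toxicity_scale, drug_library = drug_library),
            class = "study_config")
}

#' Run a full dosing study and write its table artifacts
#'
#' For every drug x setting x target combination: samples a cohort from the
#' (drug, setting) seed substream, evaluates every candidate regimen
#' ([default_candidates()]), applies the optimal-dose selection rule, and
#' writes three CSV tables plus a run manifest to `config$out_dir`:
#' `pta_by_day.csv` (per regimen per day, with toxicity columns),
#' `toxicity_by_day.csv` (optimal regimens only, day 1-7 wide layout), and
#' `optimal_regimens.csv`. Percentages are reported to one decimal place.
#' Identical config and seed reproduce byte-identical CSVs.
#'
#' @param config A [study_config()] or path to a YAML file with its fields.
#' @param rule A [selection_rule()].
#' @return Invisibly, a list with the three tables and the manifest.
#' @export
run_study <- function(config, rule = selection_rule()) {
  if (is.character(config)) config <- do.call(study_config, yaml::read_yaml(config))
  stopifnot(inherits(config, "study_config"))
  lib <- if (!is.null(config$drug_library))
    read_drug_library(config$drug_library) else krt_drug_library()

  combos <- tidyr::expand_grid(drug = config$drugs, setting = config$settings)
  results <- purrr::pmap(combos, function(drug, setting) {
    d <- lib[[drug]]
    seed <- substream_seed(config$seed, paste(drug, setting))
    cohort <- sample_cohort(d, config$n, seed)
    purrr::map(config$targets, function(tg) {
      mult <- if (tg == "micx4") 4 else 1
      cands <- default_candidates(drug, config$infusion_duration)
      reports <- purrr::map(cands, function(r)
        evaluate_regimen(d, setting, r, cohort, mic_multiplier = mult,
                         toxicity_scale = config$toxicity_scale,
                         max_daily_dose =
                           rule$max_daily_dose[drug] %|NA|% NA))
      best <- tryCatch(select_optimal(reports, rule), error = function(e) NULL)
      list(reports = reports, optimal = best, target = tg)
    })
  })
  results <- purrr::flatten(results)

  pta_tbl <- purrr::map_dfr(results, function(res)
    purrr::map_dfr(res$reports, tidy.regimen_report)) |>
    dplyr::mutate(pta = round(.data$pta, 1), toxicity = round(.data$toxicity, 1))

  optimal_tbl <- purrr::map_dfr(results, function(res) {
    if (is.null(res$optimal)) return(tibble::tibble())
    dplyr::mutate(glance.regimen_report(res$optimal),
                  rationale = res$optimal$rationale)
  })

  tox_wide <- purrr::map_dfr(results, function(res) {
    if (is.null(res$optimal)) return(tibble::tibble())
    tidy.regimen_report(res$optimal) |>
      dplyr::mutate(toxicity = round(.data$toxicity, 1)) |>
      dplyr::select("drug", "setting", "variant", "target", "regimen",
                    "day", "toxicity") |>
      tidyr::pivot_wider(names_from = "day", values_from = "toxicity",
                         names_prefix = "day_")
  })

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(pta_tbl, file.path(config$out_dir, "pta_by_day.csv"),
                   row.names = FALSE)
  utils::write.csv(optimal_tbl, file.path(config$out_dir, "optimal_regimens.csv"),
                   row.names = FALSE)
  utils::write.csv(tox_wide, file.path(config$out_dir, "toxicity_by_day.csv"),
                   row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("krtdose")),
    seed = config$seed, n = config$n,
    drugs = config$drugs, settings = config$settings,
    targets = config$targets, infusion_duration = config$infusion_duration,
    toxicity_scale = config$toxicity_scale)
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  invisible(list(pta = pta_tbl, optimal = optimal_tbl, toxicity = tox_wide,
                 manifest = manifest))
}

# NA-coalescing helper for named-vector lookups that may miss.
`%|NA|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x
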