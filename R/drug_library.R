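#' Parameter specification: arithmetic moments plus truncation range
#'
#' A `param_spec` holds the arithmetic mean and standard deviation of a PK
#' parameter in its native units, together with the truncation range inside
#' which virtual-patient values must fall. Cohort sampling moment-matches a
#' log-normal to `(mean, sd)` and rejection-resamples into `[low, high]`.
#'
#' @param mean Arithmetic mean (native units), must be positive.
#' @param sd Arithmetic standard deviation (same units), must be >= 0.
#' @param low,high Truncation bounds; `low < high` and `low <= mean <= high`.
#'   `low = 0` imposes no lower truncation (the log-normal has support on
#'   positive reals); `high = Inf` imposes no upper truncation.
#'
#' @return An object of class `param_spec`.
#' @examples
#' param_spec(0.45, 0.25, 0.25, 1.11) # cefepime Vd, L/kg
#' @export
param_spec <- function(mean, sd, low = 0, high = Inf) {
  stopifnot(is.numeric(mean), length(mean) == 1, mean > 0)
  stopifnot(is.numeric(sd), length(sd) == 1, sd >= 0)
  stopifnot(low < high, low <= mean, mean <= high)
  structure(list(mean = mean, sd = sd, low = low, high = high),
            class = "param_spec")
}

#' @export
print.param_spec <- function(x, ...) {
  cat(sprintf("<param_spec> %g ± %g [%g, %g]\n", x$mean, x$sd, x$low, x$high))
  invisible(x)
}

new_drug_model <- function(name, vd_per_kg, fu, cl_nr, sa_by_qd, sc_uf,
                           mic = NA_real_, ft_fraction = NA_real_,
                           threshold_conc = NA_real_,
                           toxicity_threshold = NA_real_,
                           companion = NULL, companion_dose_frac = NA_real_) {
  stopifnot(ft_fraction %in% c(0.40, 0.50, 0.60) || is.na(ft_fraction))
  structure(
    list(name = name, vd_per_kg = vd_per_kg, fu = fu, cl_nr = cl_nr,
         sa_by_qd = sa_by_qd, sc_uf = sc_uf, mic = mic,
         mic_multiplier_targets = c(1, 4), ft_fraction = ft_fraction,
         threshold_conc = threshold_conc,
         toxicity_threshold = toxicity_threshold,
         companion = companion, companion_dose_frac = companion_dose_frac),
    class = "drug_model")
}

#' @export
print.drug_model <- function(x, ...) {
  cat(sprintf("<drug_model> %s\n", x$name))
  cat(sprintf("  Vd %g L/kg, fu %g, CL_NR %g mL/min (means)\n",
              x$vd_per_kg$mean, x$fu$mean, x$cl_nr$mean))
  if (!is.na(x$mic))
    cat(sprintf("  MIC %g mg/L, target %g fT>MIC per day\n", x$mic, x$ft_fraction))
  if (!is.na(x$threshold_conc))
    cat(sprintf("  threshold %g mg/L free, target %g fT>threshold\n",
                x$threshold_conc, x$ft_fraction))
  if (!is.na(x$toxicity_threshold))
    cat(sprintf("  neurotoxicity threshold %g mg/L total\n", x$toxicity_threshold))
  if (!is.null(x$companion))
    cat(sprintf("  companion: %s at %s of the product dose\n",
                x$companion$name, format(x$companion_dose_frac)))
  invisible(x)
}

# Shared body-weight distribution for the critically-ill KRT population (kg).
body_weight_spec <- function() param_spec(88, 26, 40, 177)

#' Built-in beta-lactam drug library
#'
#' Returns the PK parameter distributions (volume of distribution per kg,
#' unbound fraction, non-renal clearance, saturation coefficients at dialysate
#' flows of 300/100/50 mL/min, sieving coefficient at ultrafiltrate flow
#' 5 mL/min), the Pseudomonas aeruginosa breakpoint MIC, the per-day fT>MIC
#' target fraction, and the total-concentration neurotoxicity threshold for
#' each study drug. Tazobactam carries a fixed free-concentration target
#' (4 mg/L, 50% of each day) and is attached as piperacillin's companion at an
#' 8:1 product dose ratio (4.5 g = 4 g piperacillin + 0.5 g tazobactam).
#'
#' All distributions are arithmetic mean +/- SD with a truncation range;
#' fractions (fu, SA, SC) are bounded to \[0, 1\].
#'
#' @return A named list of six [drug_model][param_spec] objects:
#'   cefepime, ceftazidime, imipenem, meropenem, piperacillin, tazobactam.
#' @examples
#' lib <- krt_drug_library()
#' lib$piperacillin$sa_by_qd[["300"]]$mean # 0.31
#' @export
krt_drug_library <- function() {
  tazo <- new_drug_model(
    name = "tazobactam",
    vd_per_kg = param_spec(0.5, 0.37, 0.11, 2.13),
    fu = param_spec(0.74, 0.27, 0, 1),
    cl_nr = param_spec(38.3, 66.2, 0, 381.0),
    sa_by_qd = list(`300` = param_spec(0.33, 0.07, 0, 1),
                    `100` = param_spec(0.51, 0.10, 0, 1),
                    `50`  = param_spec(0.63, 0.13, 0, 1)),
    sc_uf = param_spec(1.0, 0.20, 0, 1),
    ft_fraction = 0.50,
    threshold_conc = 4)

  lib <- list(
    cefepime = new_drug_model(
      name = "cefepime",
      vd_per_kg = param_spec(0.45, 0.25, 0.25, 1.11),
      fu = param_spec(0.79, 0.09, 0, 1),
      cl_nr = param_spec(24.6, 19.4, 0, 66.8),
      sa_by_qd = list(`300` = param_spec(0.45, 0.09, 0, 1),
                      `100` = param_spec(0.68, 0.14, 0, 1),
                      `50`  = param_spec(0.75, 0.15, 0, 1)),
      sc_uf = param_spec(0.82, 0.16, 0, 1),
      mic = 8, ft_fraction = 0.60, toxicity_threshold = 20),
    ceftazidime = new_drug_model(
      name = "ceftazidime",
      vd_per_kg = param_spec(0.29, 0.20, 0.17, 1.10),
      fu = param_spec(0.86, 0.08, 0, 1),
      cl_nr = param_spec(20.8, 7, 10.1, 37.7),
      sa_by_qd = list(`300` = param_spec(0.34, 0.06, 0, 1),
                      `100` = param_spec(0.58, 0.11, 0, 1),
                      `50`  = param_spec(0.73, 0.15, 0, 1)),
      sc_uf = param_spec(1.0, 0.20, 0, 1),
      mic = 8, ft_fraction = 0.60, toxicity_threshold = 64),
    imipenem = new_drug_model(
      name = "imipenem",
      vd_per_kg = param_spec(0.36, 0.15, 0.11, 0.75),
      fu = param_spec(0.80, 0.16, 0, 1),
      cl_nr = param_spec(89.2, 31.9, 27.1, 160.0),
      sa_by_qd = list(`300` = param_spec(0.34, 0.07, 0, 1),
                      `100` = param_spec(0.63, 0.12, 0, 1),
                      `50`  = param_spec(0.82, 0.16, 0, 1)),
      sc_uf = param_spec(0.82, 0.16, 0, 1),
      mic = 2, ft_fraction = 0.40, toxicity_threshold = 16),
    meropenem = new_drug_model(
      name = "meropenem",
      vd_per_kg = param_spec(0.39, 0.18, 0.08, 1.07),
      fu = param_spec(0.98, 0.16, 0, 1),
      cl_nr = param_spec(38.3, 25.6, 0, 104.8),
      sa_by_qd = list(`300` = param_spec(0.37, 0.07, 0, 1),
                      `100` = param_spec(0.65, 0.13, 0, 1),
                      `50`  = param_spec(0.83, 0.16, 0, 1)),
      sc_uf = param_spec(0.98, 0.2, 0, 1),
      mic = 2, ft_fraction = 0.40, toxicity_threshold = 64),
    piperacillin = new_drug_model(
      name = "piperacillin",
      vd_per_kg = param_spec(0.4, 0.21, 0.12, 1.72),
      fu = param_spec(0.81, 0.10, 0, 1),
      cl_nr = param_spec(45.7, 38.3, 0, 192.0),
      sa_by_qd = list(`300` = param_spec(0.31, 0.06, 0, 1),
                      `100` = param_spec(0.46, 0.09, 0, 1),
                      `50`  = param_spec(0.55, 0.11, 0, 1)),
      sc_uf = param_spec(0.87, 0.17, 0, 1),
      mic = 16, ft_fraction = 0.50, toxicity_threshold = 157,
      companion = tazo, companion_dose_frac = 1 / 9),
    tazobactam = tazo)
  lib
}

#' Tidy a drug model or the whole library into a parameter table
#'
#' @param x A `drug_model`, or a named list of them as returned by
#'   [krt_drug_library()].
#' @param ... Unused.
#' @return A tibble with one row per (drug, parameter): columns `drug`,
#'   `parameter`, `mean`, `sd`, `low`, `high`, `units`.
#' @method tidy drug_model
#' @export
tidy.drug_model <- function(x, ...) {
  specs <- list(
    body_weight = c(body_weight_spec(), units = "kg"),
    vd_per_kg = c(x$vd_per_kg, units = "L/kg"),
    fu = c(x$fu, units = "fraction"),
    cl_nr = c(x$cl_nr, units = "mL/min"),
    sa_qd300 = c(x$sa_by_qd[["300"]], units = "fraction"),
    sa_qd100 = c(x$sa_by_qd[["100"]], units = "fraction"),
    sa_qd50 = c(x$sa_by_qd[["50"]], units = "fraction"),
    sc_quf5 = c(x$sc_uf, units = "fraction"))
  purrr::imap_dfr(specs, function(s, nm)
    tibble::tibble(drug = x$name, parameter = nm, mean = s$mean, sd = s$sd,
                   low = s$low, high = s$high, units = s$units))
}

#' @rdname tidy.drug_model
#' @export
tidy_drug_library <- function(x = krt_drug_library(), ...) {
  purrr::map_dfr(x, tidy.drug_model)
}

#' Read a drug library from a YAML or JSON-like config file
#'
#' The file holds one entry per drug with the same field names as the built-in
#' library; each distribution is a list with `mean`, `sd`, `low`, `high`.
#' Missing drugs fall back to the built-in definitions, so a config can
#' override a single parameter set.
#'
#' @param path Path to a YAML file.
#' @return A named list of `drug_model` objects.
#' @seealso [write_drug_library()] for the round-trip companion.
#' @export
read_drug_library <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- krt_drug_library()
  as_spec <- function(s) param_spec(s$mean, s$sd, s$low %||% 0, s$high %||% Inf)
  out <- base
  for (nm in names(raw)) {
    d <- raw[[nm]]
    out[[nm]] <- new_drug_model(
      name = nm,
      vd_per_kg = as_spec(d$vd_per_kg), fu = as_spec(d$fu),
      cl_nr = as_spec(d$cl_nr),
      sa_by_qd = purrr::map(d$sa_by_qd, as_spec),
      sc_uf = as_spec(d$sc_uf),
      mic = d$mic %||% NA_real_,
      ft_fraction = d$ft_fraction %||% NA_real_,
      threshold_conc = d$threshold_conc %||% NA_real_,
      toxicity_threshold = d$toxicity_threshold %||% NA_real_)
  }
  # re-link piperacillin's companion in case either drug was overridden
  if (!is.null(out$piperacillin) && !is.null(out$tazobactam)) {
    out$piperacillin$companion <- out$tazobactam
    out$piperacillin$companion_dose_frac <- 1 / 9
  }
  out
}

#' @param lib A drug library (named list of `drug_model`).
#' @rdname read_drug_library
#' @export
write_drug_library <- function(lib, path) {
  de_spec <- function(s) list(mean = s$mean, sd = s$sd, low = s$low,
                              high = if (is.finite(s$high)) s$high else NULL)
  raw <- purrr::map(lib, function(d) {
    out <- list(vd_per_kg = de_spec(d$vd_per_kg), fu = de_spec(d$fu),
                cl_nr = de_spec(d$cl_nr),
                sa_by_qd = purrr::map(d$sa_by_qd, de_spec),
                sc_uf = de_spec(d$sc_uf))
    if (!is.na(d$mic)) out$mic <- d$mic
    if (!is.na(d$ft_fraction)) out$ft_fraction <- d$ft_fraction
    if (!is.na(d$threshold_conc)) out$threshold_conc <- d$threshold_conc
    if (!is.na(d$toxicity_threshold)) out$toxicity_threshold <- d$toxicity_threshold
    out
  })
  yaml::write_yaml(raw, path)
  invisible(path)
}
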