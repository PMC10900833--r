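#' Draw from a moment-matched truncated log-normal
#'
#' All PK parameters are assumed log-Gaussian. The underlying normal
#' parameters are moment-matched to the arithmetic `(mean, sd)` of the spec:
#' `sigma^2 = log(1 + (sd/mean)^2)`, `mu = log(mean) - sigma^2/2`. Draws
#' outside `[low, high]` are rejected and redrawn, so no probability mass
#' piles up at the bounds; the post-truncation moments therefore deviate
#' slightly from the nominal `(mean, sd)` when the range is tight. With
#' `sd = 0` the sampler degenerates to the constant `mean`.
#'
#' @param spec A [param_spec()].
#' @param n Number of draws (>= 1).
#' @return Numeric vector of `n` values, all inside `[spec$low, spec$high]`.
#'   Uses the current RNG state; seed control belongs to the caller (see
#'   [sample_cohort()]).
#' @examples
#' set.seed(1)
#' x <- sample_truncated_lognormal(param_spec(0.45, 0.25, 0.25, 1.11), 1000)
#' range(x) # within [0.25, 1.11]
#' @export
sample_truncated_lognormal <- function(spec, n) {
  stopifnot(inherits(spec, "param_spec"), n >= 1)
  if (spec$sd == 0) return(rep(spec$mean, n))
  sigma2 <- log(1 + (spec$sd / spec$mean)^2)
  mu <- log(spec$mean) - sigma2 / 2
  sigma <- sqrt(sigma2)
  lo <- if (spec$low > 0) spec$low else 0
  accept_p <- stats::plnorm(spec$high, mu, sigma) - stats::plnorm(lo, mu, sigma)
  if (accept_p < 1e-6)
    stop("truncation window [", lo, ", ", spec$high,
         "] has negligible probability under the moment-matched log-normal; ",
         "check the parameter spec for internal consistency")
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) / accept_p * 1.1) + 16
    x <- stats::rlnorm(m, mu, sigma)
    out <- c(out, x[x >= lo & x <= spec$high])
  }
  out[seq_len(n)]
}

#' Sample a virtual-patient cohort for one drug
#'
#' Draws `n` independent virtual patients: body weight, volume of distribution
#' per kg, unbound fraction, non-renal clearance, the saturation coefficient
#' at each dialysate flow rate, and the sieving coefficient, each from its
#' truncated log-normal spec. Parameters are sampled independently (no
#' correlation structure). Patients are anuric adults: non-renal clearance is
#' the only elimination route between KRT sessions.
#'
#' @param drug A `drug_model` from [krt_drug_library()].
#' @param n Cohort size (default 5000, the study cohort).
#' @param seed Integer seed; the same `(drug, n, seed)` reproduces the cohort
#'   bit for bit. The global RNG state is left untouched.
#' @return A tibble of class `krt_cohort` with one row per patient and columns
#'   `id`, `body_weight` (kg), `vd_per_kg` (L/kg), `vd` (L), `fu`, `cl_nr`
#'   (mL/min), `sa_300`, `sa_100`, `sa_50`, `sc` (all coefficients in
#'   \[0, 1\]). Attributes `drug` and `seed` record provenance.
#' @examples
#' lib <- krt_drug_library()
#' cohort <- sample_cohort(lib$cefepime, n = 100, seed = 1)
#' summary(cohort$vd)
#' @export
sample_cohort <- function(drug, n = 5000, seed = 1L) {
  stopifnot(inherits(drug, "drug_model"), n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  out <- tibble::tibble(
    id = seq_len(n),
    body_weight = sample_truncated_lognormal(body_weight_spec(), n),
    vd_per_kg = sample_truncated_lognormal(drug$vd_per_kg, n),
    fu = sample_truncated_lognormal(drug$fu, n),
    cl_nr = sample_truncated_lognormal(drug$cl_nr, n),
    sa_300 = sample_truncated_lognormal(drug$sa_by_qd[["300"]], n),
    sa_100 = sample_truncated_lognormal(drug$sa_by_qd[["100"]], n),
    sa_50 = sample_truncated_lognormal(drug$sa_by_qd[["50"]], n),
    sc = sample_truncated_lognormal(drug$sc_uf, n))
  out$vd <- out$vd_per_kg * out$body_weight
  out <- out[, c("id", "body_weight", "vd_per_kg", "vd", "fu", "cl_nr",
                 "sa_300", "sa_100", "sa_50", "sc")]
  attr(out, "drug") <- drug$name
  attr(out, "seed") <- seed
  class(out) <- c("krt_cohort", class(out))
  out
}

# Deterministic per-(drug, setting, ...) sub-seed so adding one scenario to a
# study never perturbs the draws of another. Kept below 2^31 - 1.
substream_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}
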