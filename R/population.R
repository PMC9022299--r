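#' Sample a virtual patient cohort
#'
#' Realizes the inter-individual variability structure of the population
#' model at a fixed creatinine clearance: independent lognormal random
#' effects on clearance and central volume,
#' \deqn{CL_i = TVCL(CrCl) e^{\eta_1}, \quad \eta_1 \sim N(0, \omega_{CL}^2)}
#' \deqn{V_{1,i} = V_{1,pop} e^{\eta_2}, \quad \eta_2 \sim N(0, \omega_{V1}^2)}
#' with \code{Q} and \code{V2} fixed at their population values (no IIV was
#' reported for them). Reported IIV percentages are used directly as
#' log-scale SDs (\code{omega = IIV\% / 100}).
#'
#' With \code{seed = NULL} the draw consumes the current R random stream
#' (Mersenne-Twister); with a seed, the stream is set locally and restored,
#' so repeated calls with the same seed are bitwise identical.
#'
#' @param pop \code{\link{pop_params}}.
#' @param crcl Creatinine clearance (mL/min), a single value per cohort.
#' @param n Number of subjects, >= 1.
#' @param seed Optional integer seed for a reproducible cohort.
#' @return \code{\link{individual_params}} with \code{n} rows.
#' @examples
#' cohort <- sample_individuals(pop_params(), crcl = 160, n = 5, seed = 7)
#' @export
sample_individuals <- function(pop, crcl, n, seed = NULL) {
  if (length(crcl) != 1L) stop("crcl must be a single value")
  if (n < 1) stop("n must be >= 1")
  tvcl <- typical_clearance(crcl, pop)
  draw <- function() {
    eta1 <- stats::rnorm(n, 0, pop$omega_cl)
    eta2 <- stats::rnorm(n, 0, pop$omega_v1)
    individual_params(cl = tvcl * exp(eta1), v1 = pop$v1_pop * exp(eta2),
                      q = pop$q_pop, v2 = pop$v2_pop)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Apply proportional residual error to concentrations
#'
#' Observation-level noise \code{conc * (1 + eps)}, \code{eps ~ N(0,
#' sigma_prop^2)}, truncated below at zero. Draws come from the current R
#' random stream; seed the stream (or the calling scenario) for
#' reproducibility. Excluded from attainment computations by default, where
#' targets are evaluated on individual-predicted troughs.
#'
#' @param conc Concentrations (mg/L), >= 0.
#' @param sigma_prop Proportional error SD (dimensionless).
#' @return Perturbed concentrations, same length.
#' @export
apply_residual_error <- function(conc, sigma_prop) {
  if (any(conc < 0)) stop("concentrations must be >= 0")
  if (sigma_prop < 0) stop("sigma_prop must be >= 0")
  if (sigma_prop == 0) return(conc)
  pmax(0, conc * (1 + stats::rnorm(length(conc), 0, sigma_prop)))
}

#' Simulation scenario
#'
#' One cell of the simulation study: a creatinine-clearance value, a dosing
#' regimen, a cohort size and a seed. Study defaults are 1000 virtual
#' subjects at CrCl 160, 200 or 240 mL/min.
#'
#' @param crcl Creatinine clearance (mL/min), > 0.
#' @param regimen A \code{\link{regimen}}.
#' @param n_subjects Cohort size, >= 1.
#' @param seed Optional integer seed.
#' @return An object of class \code{"lev_scenario"}.
#' @export
scenario <- function(crcl, regimen, n_subjects = 1000L, seed = NULL) {
  if (!is.finite(crcl) || crcl <= 0) stop("crcl must be > 0")
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (!inherits(regimen, "lev_regimen")) stop("regimen must be a lev_regimen")
  structure(list(crcl = crcl, regimen = regimen,
                 n_subjects = as.integer(n_subjects), seed = seed),
            class = "lev_scenario")
}
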