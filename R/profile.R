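#' Typical-subject concentration-time profile, with and without loading dose
#'
#' Concentration-time course for the typical subject at a given creatinine
#' clearance, starting treatment from a drug-free state, under the plain
#' maintenance regimen and (optionally) the same regimen preceded by a
#' loading infusion. Intended for assessing how long extended or continuous
#' infusions take to reach the therapeutic floor and how a loading dose
#' shortens that time.
#'
#' @param crcl Creatinine clearance (mL/min).
#' @param reg Maintenance \code{\link{regimen}} (without loading fields).
#' @param pop \code{\link{pop_params}}.
#' @param hours Simulation horizon (h), > 0.
#' @param step Output time step (h).
#' @param loading_dose_mg Optional loading dose (mg) for the comparison
#'   column.
#' @param loading_tinf_h Loading infusion duration (h).
#' @param target Concentration (mg/L) whose first attainment time is
#'   reported per column.
#' @return Data frame with columns \code{time}, \code{conc} and (with a
#'   loading dose) \code{conc_loading}; attribute \code{"time_to_target"} is
#'   a named vector of first times to \code{target} (h, \code{Inf} = never).
#' @examples
#' pr <- conc_profile(200, continuous_infusion(3000), hours = 36,
#'                    loading_dose_mg = 1500, loading_tinf_h = 0.5)
#' attr(pr, "time_to_target")
#' @export
conc_profile <- function(crcl, reg, pop = pop_params(), hours = 48,
                         step = 0.1, loading_dose_mg = NULL,
                         loading_tinf_h = 0.5, target = 12) {
  if (hours <= 0) stop("hours must be > 0")
  ind <- individual_params(cl = typical_clearance(crcl, pop),
                           v1 = pop$v1_pop, q = pop$q_pop, v2 = pop$v2_pop)
  tt <- seq(0, hours, by = step)
  n_doses <- as.integer(ceiling(hours / reg$tau_h)) + 1L
  out <- data.frame(time = tt, conc = time_course(ind, reg, tt, n_doses))
  ttt <- c(no_loading = time_to_target(ind, reg, target))
  if (!is.null(loading_dose_mg)) {
    reg_ld <- regimen(reg$dose_mg, reg$tau_h, reg$tinf_h,
                      loading_dose_mg = loading_dose_mg,
                      loading_tinf_h = loading_tinf_h)
    out$conc_loading <- time_course(ind, reg_ld, tt, n_doses)
    ttt <- c(ttt, loading = time_to_target(ind, reg_ld, target))
  }
  attr(out, "time_to_target") <- ttt
  out
}
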