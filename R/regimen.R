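#' Intravenous dosing regimen
#'
#' Describes repeated intravenous infusion dosing: a maintenance dose given
#' every \code{tau_h} hours, infused over \code{tinf_h} hours, optionally
#' preceded by a loading infusion. Continuous infusion is encoded as
#' \code{tinf_h == tau_h == 24} with \code{dose_mg} the total daily dose.
#'
#' When a loading dose is present the loading infusion starts at time 0 and
#' the first maintenance infusion starts one dosing interval later, at
#' \code{t = tau_h}.
#'
#' @param dose_mg Maintenance dose per administration (mg).
#' @param tau_h Dosing interval (h).
#' @param tinf_h Infusion duration (h); must satisfy \code{0 < tinf_h <= tau_h}.
#' @param loading_dose_mg Optional loading dose (mg).
#' @param loading_tinf_h Loading infusion duration (h); required with
#'   \code{loading_dose_mg}.
#' @return An object of class \code{"lev_regimen"}.
#' @examples
#' regimen(1500, tau_h = 8, tinf_h = 4)         # extended infusion
#' continuous_infusion(4500)                     # 4500 mg/day CI
#' regimen(1000, 8, 0.5, loading_dose_mg = 1500, loading_tinf_h = 0.5)
#' @export
regimen <- function(dose_mg, tau_h, tinf_h, loading_dose_mg = NULL,
                    loading_tinf_h = NULL) {
  if (!is.finite(dose_mg) || dose_mg < 0) stop("dose_mg must be >= 0")
  if (!is.finite(tau_h) || tau_h <= 0) stop("tau_h must be > 0")
  if (!is.finite(tinf_h) || tinf_h <= 0 || tinf_h > tau_h)
    stop("tinf_h must satisfy 0 < tinf_h <= tau_h")
  if (is.null(loading_dose_mg) != is.null(loading_tinf_h))
    stop("loading_dose_mg and loading_tinf_h must be given together")
  if (!is.null(loading_dose_mg)) {
    if (!is.finite(loading_dose_mg) || loading_dose_mg < 0)
      stop("loading_dose_mg must be >= 0")
    if (!is.finite(loading_tinf_h) || loading_tinf_h <= 0 ||
        loading_tinf_h > tau_h)
      stop("loading_tinf_h must satisfy 0 < loading_tinf_h <= tau_h")
  }
  structure(list(dose_mg = dose_mg, tau_h = tau_h, tinf_h = tinf_h,
                 loading_dose_mg = loading_dose_mg,
                 loading_tinf_h = loading_tinf_h),
            class = "lev_regimen")
}

#' @rdname regimen
#' @param daily_dose_mg Total daily dose (mg) administered at constant rate.
#' @export
continuous_infusion <- function(daily_dose_mg) {
  regimen(dose_mg = daily_dose_mg, tau_h = 24, tinf_h = 24)
}

#' @rdname regimen
#' @param reg A \code{"lev_regimen"}.
#' @export
is_continuous <- function(reg) {
  reg$tinf_h == reg$tau_h
}

#' @rdname regimen
#' @export
infusion_rate <- function(reg) {
  reg$dose_mg / reg$tinf_h
}

#' @export
print.lev_regimen <- function(x, ...) {
  if (is_continuous(x)) {
    cat(sprintf("Continuous infusion: %g mg over %g h (%.4g mg/h)\n",
                x$dose_mg, x$tau_h, infusion_rate(x)))
  } else {
    cat(sprintf("Intermittent infusion: %g mg q%gh over %g h (%.4g mg/h)\n",
                x$dose_mg, x$tau_h, x$tinf_h, infusion_rate(x)))
  }
  if (!is.null(x$loading_dose_mg))
    cat(sprintf("  loading dose: %g mg over %g h at t = 0\n",
                x$loading_dose_mg, x$loading_tinf_h))
  invisible(x)
}
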