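#' Population pharmacokinetic parameters for intravenous levetiracetam
#'
#' Container for the fixed effects, inter-individual variabilities (IIV) and
#' residual-error magnitude of the published two-compartment population model
#' developed in critically ill patients. Defaults are the published estimates;
#' any field can be overridden for sensitivity analyses.
#'
#' The typical-value clearance model is
#' \deqn{CL (L/h) = \theta_{nr} + (CrCl / CrCl_{ref})^{\theta_r}}
#' where \eqn{\theta_{nr}} is the non-renal clearance component and CrCl the
#' creatinine clearance in mL/min. \code{clearance_model = "power_only"}
#' selects the alternative reading \eqn{CL = (CrCl/CrCl_{ref})^{\theta_r}}
#' (the non-renal component cancelled); it is retained purely so that the two
#' readings can be discriminated against the published attainment grid.
#'
#' Reported IIV percentages are interpreted as 100 times the standard
#' deviation of the log-scale random effect, applied exponentially
#' (\code{CL_i = TVCL * exp(eta)}); see \code{\link{sample_individuals}}.
#'
#' @param theta_nr Non-renal clearance component (L/h).
#' @param theta_r Exponent on normalized creatinine clearance (dimensionless).
#' @param v1_pop Central volume of distribution (L).
#' @param q_pop Intercompartmental clearance (L/h).
#' @param v2_pop Peripheral volume of distribution (L).
#' @param omega_cl SD of the log-scale random effect on clearance
#'   (dimensionless; reported IIV\% / 100).
#' @param omega_v1 SD of the log-scale random effect on central volume.
#' @param sigma_prop Proportional residual-error SD (dimensionless).
#' @param crcl_ref Covariate normalization constant (mL/min).
#' @param clearance_model Typical-clearance covariate model; see Details.
#' @return An object of class \code{"lev_pop"}: a named list of the above.
#' @examples
#' pop <- pop_params()
#' typical_clearance(c(120, 160, 200, 240), pop)
#' @export
pop_params <- function(theta_nr = 3.5, theta_r = 2.5, v1_pop = 20.7,
                       q_pop = 31.9, v2_pop = 33.5, omega_cl = 0.327,
                       omega_v1 = 0.561, sigma_prop = 0.223, crcl_ref = 120,
                       clearance_model = c("nonrenal_plus_power", "power_only")) {
  clearance_model <- match.arg(clearance_model)
  pos <- c(theta_nr = theta_nr, theta_r = theta_r, v1_pop = v1_pop,
           q_pop = q_pop, v2_pop = v2_pop, crcl_ref = crcl_ref)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("structural parameters must be strictly positive and finite")
  nneg <- c(omega_cl = omega_cl, omega_v1 = omega_v1, sigma_prop = sigma_prop)
  if (any(!is.finite(nneg)) || any(nneg < 0))
    stop("variability parameters must be non-negative and finite")
  structure(list(theta_nr = theta_nr, theta_r = theta_r, v1_pop = v1_pop,
                 q_pop = q_pop, v2_pop = v2_pop, omega_cl = omega_cl,
                 omega_v1 = omega_v1, sigma_prop = sigma_prop,
                 crcl_ref = crcl_ref, clearance_model = clearance_model),
            class = "lev_pop")
}

#' @export
print.lev_pop <- function(x, ...) {
  cat("Population PK parameters (two-compartment, IV infusion)\n")
  cat(sprintf("  CL model: %s (theta_nr = %g L/h, theta_r = %g, CrCl ref = %g mL/min)\n",
              x$clearance_model, x$theta_nr, x$theta_r, x$crcl_ref))
  cat(sprintf("  V1 = %g L, Q = %g L/h, V2 = %g L\n", x$v1_pop, x$q_pop, x$v2_pop))
  cat(sprintf("  omega_CL = %g, omega_V1 = %g, sigma_prop = %g\n",
              x$omega_cl, x$omega_v1, x$sigma_prop))
  invisible(x)
}

#' Individual pharmacokinetic parameters
#'
#' One row per virtual subject. Arguments are recycled to a common length, so
#' a single typical subject or a whole simulated cohort can be represented.
#'
#' @param cl Total clearance (L/h).
#' @param v1 Central volume (L).
#' @param q Intercompartmental clearance (L/h).
#' @param v2 Peripheral volume (L).
#' @return A data frame of class \code{"lev_individuals"} with columns
#'   \code{cl}, \code{v1}, \code{q}, \code{v2}.
#' @examples
#' individual_params(cl = 4.5, v1 = 20.7, q = 31.9, v2 = 33.5)
#' @export
individual_params <- function(cl, v1, q, v2) {
  n <- max(length(cl), length(v1), length(q), length(v2))
  ind <- data.frame(cl = rep_len(cl, n), v1 = rep_len(v1, n),
                    q = rep_len(q, n), v2 = rep_len(v2, n))
  if (any(!is.finite(as.matrix(ind))) || any(as.matrix(ind) <= 0))
    stop("individual parameters must be strictly positive and finite")
  class(ind) <- c("lev_individuals", "data.frame")
  ind
}
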