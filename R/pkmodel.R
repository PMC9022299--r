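#' Typical-value clearance from creatinine clearance
#'
#' Covariate model for levetiracetam clearance. Under the default model the
#' typical value is \code{theta_nr + (crcl / crcl_ref)^theta_r}: a non-renal
#' component plus a power function of normalized creatinine clearance, so
#' that clearance equals \code{theta_nr} in the anephric limit and rises
#' steeply through the augmented-renal-clearance range.
#'
#' @param crcl Creatinine clearance (mL/min); vectorized, must be >= 0.
#' @param pop A \code{\link{pop_params}} object.
#' @return Typical clearance (L/h), same length as \code{crcl}.
#' @examples
#' typical_clearance(240)  # 3.5 + 2^2.5
#' @export
typical_clearance <- function(crcl, pop = pop_params()) {
  if (any(!is.finite(crcl)) || any(crcl < 0))
    stop("crcl must be finite and >= 0")
  renal <- (crcl / pop$crcl_ref)^pop$theta_r
  switch(pop$clearance_model,
         nonrenal_plus_power = pop$theta_nr + renal,
         power_only = renal)
}

#' Two-compartment disposition constants
#'
#' Reparameterizes clearances and volumes into micro rate constants and the
#' hybrid exponential rates of the biexponential disposition function, plus
#' the per-exponential central-compartment amplitudes \code{a1}, \code{a2}
#' (mg/L per mg/h) of the constant-rate infusion solution
#' \deqn{C(t) = R_0 \sum_i a_i (1 - e^{-\lambda_i t}).}
#'
#' For strictly positive parameters the discriminant is positive, so
#' \code{lambda1 > lambda2 > 0} always; a numerical guard nudges
#' \code{lambda2} by \code{1e-9 * lambda1} in the (unreachable for realistic
#' parameters) near-repeated-root case so the amplitudes stay finite.
#'
#' @param ind A \code{\link{individual_params}} data frame (any number of rows).
#' @return A data frame with columns \code{cl}, \code{v1}, \code{k10},
#'   \code{k12}, \code{k21}, \code{lambda1}, \code{lambda2}, \code{a1},
#'   \code{a2}, one row per subject.
#' @export
derive_disposition <- function(ind) {
  if (any(as.matrix(ind[c("cl", "v1", "q", "v2")]) <= 0))
    stop("all individual parameters must be strictly positive")
  k10 <- ind$cl / ind$v1
  k12 <- ind$q / ind$v1
  k21 <- ind$q / ind$v2
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  lambda1 <- (s + disc) / 2
  lambda2 <- (s - disc) / 2
  near <- (lambda1 - lambda2) < 1e-9 * lambda1
  if (any(near)) lambda2[near] <- lambda2[near] - 1e-9 * lambda1[near]
  a1 <- (k21 - lambda1) / (lambda1 * (lambda2 - lambda1)) / ind$v1
  a2 <- (k21 - lambda2) / (lambda2 * (lambda1 - lambda2)) / ind$v1
  data.frame(cl = ind$cl, v1 = ind$v1, k10 = k10, k12 = k12, k21 = k21,
             lambda1 = lambda1, lambda2 = lambda2, a1 = a1, a2 = a2)
}

# Single-infusion central concentration at times t (h) after infusion start.
# Valid for all t: 0 before the dose, rising biexponential during the
# infusion, biexponential decay after. Recycles subject rows against t.
.conc_single <- function(dc, rate, tinf, t) {
  ti <- pmin(t, tinf)                     # portion of t spent infusing
  out <- rate * (dc$a1 * (-expm1(-dc$lambda1 * ti)) * exp(-dc$lambda1 * (t - ti)) +
                 dc$a2 * (-expm1(-dc$lambda2 * ti)) * exp(-dc$lambda2 * (t - ti)))
  out[t <= 0] <- 0
  out
}

# Steady-state concentration at t in [0, tau] (t = tau is the instant just
# before the next infusion starts). Current dose enters via .conc_single;
# all earlier doses collapse into per-exponential geometric tails with
# accumulation factors 1 / (1 - exp(-lambda * tau)).
.css_raw <- function(dc, reg, t) {
  rate <- infusion_rate(reg)
  b1 <- -expm1(-dc$lambda1 * reg$tinf_h)
  b2 <- -expm1(-dc$lambda2 * reg$tinf_h)
  tail <- rate *
    (dc$a1 * b1 * exp(-dc$lambda1 * (t + reg$tau_h - reg$tinf_h)) /
       (-expm1(-dc$lambda1 * reg$tau_h)) +
     dc$a2 * b2 * exp(-dc$lambda2 * (t + reg$tau_h - reg$tinf_h)) /
       (-expm1(-dc$lambda2 * reg$tau_h)))
  .conc_single(dc, rate, reg$tinf_h, t) + tail
}

#' Steady-state concentration within a dosing interval
#'
#' Closed-form steady-state central concentration under repeated infusion
#' dosing, with \code{t = 0} the start of an infusion. Computed as the
#' current-dose biexponential solution plus the geometric accumulation of all
#' earlier doses, applied per exponential. For the continuous-infusion
#' encoding the expression collapses analytically to the plateau
#' \code{infusion_rate(reg) / cl} at every \code{t}.
#'
#' Either \code{ind} has one row and \code{t} is a vector (a profile), or
#' \code{t} is a scalar and \code{ind} holds a cohort (one value per subject).
#'
#' @param ind \code{\link{individual_params}}.
#' @param reg \code{\link{regimen}} (any loading dose is irrelevant at steady
#'   state and ignored here).
#' @param t Time since the start of a steady-state infusion (h), in
#'   \code{[0, tau_h)}.
#' @return Concentration(s), mg/L.
#' @examples
#' ind <- individual_params(4.5, 20.7, 31.9, 33.5)
#' steady_state_concentration(ind, continuous_infusion(3000), 10)  # 125/4.5
#' @export
steady_state_concentration <- function(ind, reg, t) {
  if (any(!is.finite(t)) || any(t < 0) || any(t >= reg$tau_h))
    stop("t must lie within one steady-state dosing interval [0, tau_h)")
  .css_raw(derive_disposition(ind), reg, t)
}

#' Steady-state trough concentration
#'
#' Concentration at the end of a steady-state dosing interval, immediately
#' before the next infusion starts (\code{t = tau_h^-}). For the
#' continuous-infusion encoding this is the plateau,
#' \code{infusion_rate(reg) / cl}, returned exactly.
#'
#' @inheritParams steady_state_concentration
#' @return Trough concentration per subject (mg/L).
#' @examples
#' ind <- individual_params(typical_clearance(240), 20.7, 31.9, 33.5)
#' steady_state_trough(ind, continuous_infusion(4500))  # 187.5 / 9.157
#' @export
steady_state_trough <- function(ind, reg) {
  if (is_continuous(reg)) return(infusion_rate(reg) / ind$cl)
  .css_raw(derive_disposition(ind), reg, reg$tau_h)
}

# Dose schedule implied by a regimen: start time, infusion duration and rate
# of each administration. With a loading dose, it is administration 1 and the
# first maintenance dose follows at t = tau_h.
.dose_schedule <- function(reg, n_doses) {
  if (n_doses < 1) stop("n_doses must be >= 1")
  if (!is.null(reg$loading_dose_mg)) {
    start <- reg$tau_h * seq_len(n_doses - 1)
    data.frame(start = c(0, start),
               tinf = c(reg$loading_tinf_h, rep(reg$tinf_h, n_doses - 1)),
               rate = c(reg$loading_dose_mg / reg$loading_tinf_h,
                        rep(infusion_rate(reg), n_doses - 1)))
  } else {
    data.frame(start = reg$tau_h * (seq_len(n_doses) - 1),
               tinf = rep(reg$tinf_h, n_doses),
               rate = rep(infusion_rate(reg), n_doses))
  }
}

.superpose <- function(dc, schedule, t) {
  conc <- numeric(length(t))
  for (j in seq_len(nrow(schedule)))
    conc <- conc + .conc_single(dc, schedule$rate[j], schedule$tinf[j],
                                t - schedule$start[j])
  conc
}

#' Concentration-time course under a finite number of doses
#'
#' Finite superposition of single-infusion solutions for one subject,
#' starting from a drug-free state at \code{t = 0}. Supports an optional
#' loading infusion at \code{t = 0} (counted as the first of the
#' \code{n_doses} administrations), with maintenance dosing from
#' \code{t = tau_h} on. Converges to \code{\link{steady_state_concentration}}
#' as \code{n_doses} grows.
#'
#' @param ind One-row \code{\link{individual_params}}.
#' @param reg \code{\link{regimen}}.
#' @param t_grid Non-decreasing times (h), >= 0.
#' @param n_doses Total number of administrations, >= 1.
#' @return Concentrations at \code{t_grid} (mg/L).
#' @export
time_course <- function(ind, reg, t_grid, n_doses = 1L) {
  if (nrow(ind) != 1L) stop("time_course expects a single subject")
  if (any(!is.finite(t_grid)) || any(t_grid < 0)) stop("times must be >= 0")
  if (is.unsorted(t_grid)) stop("t_grid must be non-decreasing")
  .superpose(derive_disposition(ind), .dose_schedule(reg, n_doses), t_grid)
}

#' Time to reach a target concentration
#'
#' Earliest time at which the repeated-dosing concentration-time course
#' (including any loading dose) first reaches \code{target}. Each dosing
#' interval is scanned on a fine grid of the closed-form finite superposition
#' and the crossing is refined by root bisection; intervals are marched until
#' the profile has converged to steady state. Returns \code{Inf} ("never") if
#' the steady-state envelope never reaches the target.
#'
#' @param ind One-row \code{\link{individual_params}}.
#' @param reg \code{\link{regimen}}.
#' @param target Target concentration (mg/L), > 0.
#' @return Time (h), or \code{Inf} if the target is never reached.
#' @examples
#' ind <- individual_params(typical_clearance(200), 20.7, 31.9, 33.5)
#' time_to_target(ind, continuous_infusion(3000), 12)
#' @export
time_to_target <- function(ind, reg, target) {
  if (!is.finite(target) || target <= 0) stop("target must be > 0")
  if (nrow(ind) != 1L) stop("time_to_target expects a single subject")
  dc <- derive_disposition(ind)
  has_loading <- !is.null(reg$loading_dose_mg) && reg$loading_dose_mg > 0
  if (reg$dose_mg <= 0 && !has_loading) return(Inf)

  tg <- sort(unique(c(seq(0, reg$tau_h, length.out = 801), reg$tinf_h)))
  ss_max <- if (reg$dose_mg > 0) max(.css_raw(dc, reg, tg)) else 0
  n_ss <- max(3, ceiling(10 * log(2) / dc$lambda2 / reg$tau_h))
  n_max <- if (ss_max >= target) 4L * n_ss else n_ss

  schedule <- .dose_schedule(reg, n_max)
  f <- function(t) .superpose(dc, schedule, t) - target
  grid_n <- 401L
  for (k in seq_len(n_max) - 1L) {
    tt <- seq(k * reg$tau_h, (k + 1) * reg$tau_h, length.out = grid_n)
    fv <- f(tt)
    hit <- which(fv >= 0)
    if (length(hit)) {
      i <- hit[1L]
      if (i == 1L) return(tt[1L])
      return(stats::uniroot(f, lower = tt[i - 1L], upper = tt[i],
                            tol = 1e-9)$root)
    }
  }
  Inf
}

#' Numerical-integration oracle for the two-compartment infusion model
#'
#' Solves the two-compartment mass-balance system (central amount:
#' input rate \eqn{- (k_{10}+k_{12}) A_1 + k_{21} A_2}; peripheral:
#' \eqn{k_{12} A_1 - k_{21} A_2}; concentration \eqn{A_1 / V_1}) with
#' \code{deSolve::lsoda} at tight tolerances, integrating piecewise between
#' infusion on/off breakpoints so the discontinuous input rate never crosses
#' an integration step. Same dosing schedule conventions as
#' \code{\link{time_course}}. Intended as an independent verification path
#' for the closed-form solutions.
#'
#' @inheritParams time_course
#' @param amounts If \code{TRUE}, also return compartment amounts.
#' @return Concentrations at \code{t_grid} (mg/L), or if
#'   \code{amounts = TRUE} a data frame with \code{time}, \code{conc},
#'   \code{a1}, \code{a2}.
#' @export
ode_oracle <- function(ind, reg, t_grid, n_doses = 1L, amounts = FALSE) {
  if (nrow(ind) != 1L) stop("ode_oracle expects a single subject")
  if (any(!is.finite(t_grid)) || any(t_grid < 0)) stop("times must be >= 0")
  if (is.unsorted(t_grid)) stop("t_grid must be non-decreasing")
  dc <- derive_disposition(ind)
  sched <- .dose_schedule(reg, n_doses)
  rhs <- function(t, y, parms) {
    list(c(parms$rate - (dc$k10 + dc$k12) * y[1] + dc$k21 * y[2],
           dc$k12 * y[1] - dc$k21 * y[2]))
  }
  brk <- sort(unique(c(0, sched$start, sched$start + sched$tinf,
                       max(t_grid), t_grid)))
  brk <- brk[brk <= max(t_grid) | brk %in% t_grid]
  y <- c(0, 0)
  res_t <- numeric(0); res_y <- NULL
  if (brk[1] %in% t_grid) { res_t <- brk[1]; res_y <- rbind(res_y, y) }
  for (i in seq_len(length(brk) - 1L)) {
    t0 <- brk[i]; t1 <- brk[i + 1L]
    if (t1 <= t0) next
    active <- sched$start <= t0 + 1e-12 & t0 < sched$start + sched$tinf - 1e-12
    rate <- sum(sched$rate[active])
    inner <- t_grid[t_grid > t0 & t_grid <= t1]
    times <- sort(unique(c(t0, inner, t1)))
    sol <- deSolve::lsoda(y, times, rhs, parms = list(rate = rate),
                          rtol = 1e-11, atol = 1e-12)
    if (attr(sol, "istate")[1] < 0) stop("ODE integration failed")
    keep <- sol[, 1] %in% inner
    if (any(keep)) {
      res_t <- c(res_t, sol[keep, 1])
      res_y <- rbind(res_y, unname(sol[keep, 2:3, drop = FALSE]))
    }
    y <- unname(sol[nrow(sol), 2:3])
  }
  ord <- match(t_grid, res_t)
  conc <- unname(res_y[ord, 1]) / ind$v1
  if (!amounts) return(conc)
  data.frame(time = t_grid, conc = conc,
             a1 = res_y[ord, 1], a2 = res_y[ord, 2])
}
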