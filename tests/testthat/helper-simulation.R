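# shared fixtures: typical subjects and randomized parameter/regimen draws
typical_subject <- function(crcl, pop = pop_params()) {
  individual_params(cl = typical_clearance(crcl, pop), v1 = pop$v1_pop,
                    q = pop$q_pop, v2 = pop$v2_pop)
}

random_subject <- function() {
  individual_params(cl = runif(1, 1, 15), v1 = runif(1, 5, 60),
                    q = runif(1, 5, 60), v2 = runif(1, 10, 80))
}

random_regimen <- function(force_ci = FALSE) {
  tau <- sample(c(6, 8, 12, 24), 1)
  tinf <- if (force_ci || runif(1) < 0.2) tau else runif(1, 0.25, tau - 0.1)
  regimen(dose_mg = runif(1, 250, 4000), tau_h = tau, tinf_h = tinf)
}
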