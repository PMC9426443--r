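## Calibration of the growth scenario: find the light availability at which
## the wild type achieves a target normalized biomass over the simulated
## horizon (e.g. one doubling per day), by bisection on the photoperiod
## photon availability. Growth is monotone in light on the fixture, so
## bisection is well posed.

#' Calibrate light availability for a target diel growth
#'
#' Bisects the photoperiod light availability until the final normalized
#' biomass of the simulated wild type hits `target` within `tol`. The flux
#' ceiling `u_max` is recalibrated from the light-harvesting rule at every
#' trial. Component producibility (a Boolean pattern unchanged by jointly
#' rescaling light and the flux ceiling) is precomputed once at the upper
#' bracket and reused across trials.
#'
#' @param bundle a scenario bundle (see [diel_scenario()]); its
#'   environment's light availability is ignored.
#' @param target target final normalized mass (default 2: one doubling).
#' @param hours,dt simulation horizon and timestep.
#' @param bracket initial light bracket, mmol photons/gDW/h.
#' @param tol relative tolerance on the achieved target.
#' @param max_iter bisection iteration cap.
#' @return list: `light_availability`, `achieved` (final normalized mass at
#'   the calibrated light), `iterations`, `simulation` (the final run).
#' @export
calibrate_light_for_target <- function(bundle, target = 2, hours = 24,
                                       dt = 0.1, bracket = c(0.5, 60),
                                       tol = 0.005, max_iter = 20) {
  env_at <- function(L) {
    e <- bundle$env
    e$light_availability <- L
    e
  }
  frac <- build_fraction_ctx(bundle$fits)
  poss <- production_possibilities(
    bundle$dmodel, bundle$fits, env_at(bracket[2]),
    calibrate_umax(bundle$light_rule, frac, bracket[2]))
  run_at <- function(L) {
    simulate_diel(bundle$dmodel, bundle$fits, env_at(L), bundle$setpoints,
                  hours = hours, dt = dt, light_rule = bundle$light_rule,
                  possibilities = poss)
  }
  final_of <- function(sim) sim$trajectory$normalized[nrow(sim$trajectory)]
  lo <- bracket[1]; hi <- bracket[2]
  f_hi <- final_of(run_at(hi))
  if (f_hi < target) {
    stop("target unreachable within the light bracket (achieved ",
         format(f_hi, digits = 4), " at ", hi, ")", call. = FALSE)
  }
  sim <- NULL; mid <- hi; achieved <- f_hi
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    sim <- run_at(mid)
    achieved <- final_of(sim)
    if (abs(achieved - target) <= tol * target) break
    if (achieved > target) hi <- mid else lo <- mid
  }
  list(light_availability = mid, achieved = achieved, iterations = it,
       simulation = sim)
}
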