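## Diel simulation: march the transcript-constrained, biomass-decoupled
## model through the day/night cycle in fixed timesteps. Each step
## (1) rebinds every GPR-mapped reaction from the fitted curves,
## (2) updates the PI controllers from the current composition,
## (3) satisfies maintenance ATP (catabolizing stored components at night
##     when the medium cannot), (4) runs the iterative production-expansion
## LP, and (5) advances component masses by forward Euler.

#' Describe a diel growth environment
#'
#' @param light_availability maximum light uptake, mmol photons/gDW/h,
#'   during the photoperiod (square-wave schedule).
#' @param day_hours length of the light phase (default 12 of 24).
#' @param medium named vector of maximum uptake rates (mmol/gDW/h) by
#'   exchange reaction id; exchanges not listed allow secretion only.
#' @param ngam non-growth-associated maintenance ATP demand,
#'   mmol ATP/gDW/h (> 0).
#' @param ngam_reaction id of the maintenance ATP hydrolysis reaction.
#' @param light_exchange id of the photon exchange reaction.
#' @param energy_exchanges exchanges counted as energy inputs (closed when
#'   testing production from an internal component); defaults to the light
#'   exchange plus any acetate exchange in the medium.
#' @return object of class `diel_environment`.
#' @export
diel_environment <- function(light_availability, day_hours = 12,
                             medium = c(), ngam = 0.8,
                             ngam_reaction = "NGAM",
                             light_exchange = "EX_photon",
                             energy_exchanges = NULL) {
  stopifnot(light_availability >= 0, ngam > 0)
  if (is.null(energy_exchanges)) {
    energy_exchanges <- c(light_exchange,
                          grep("^EX_ac", names(medium), value = TRUE))
  }
  structure(list(light_availability = light_availability,
                 day_hours = day_hours, medium = medium, ngam = ngam,
                 ngam_reaction = ngam_reaction,
                 light_exchange = light_exchange,
                 energy_exchanges = energy_exchanges),
            class = "diel_environment")
}

light_at <- function(env, t) {
  if ((t %% 24) < env$day_hours) env$light_availability else 0
}

## ---- simulation preparation ---------------------------------------------

prepare_sim <- function(dmodel, fits, env, u_max) {
  model <- dmodel$model
  rules <- lapply(model$reactions$gpr, function(g) {
    if (nzchar(g)) parse_gpr(g) else NULL
  })
  frac <- build_fraction_ctx(fits)
  rx <- model$reactions
  base_lb <- rx$lb; base_ub <- rx$ub
  ## medium: uptake allowed only for listed exchanges
  exch <- which(is_exchange(model))
  for (j in exch) {
    id <- rx$id[j]
    if (id %in% dmodel$components$syn_id || id %in% dmodel$components$deg_id ||
        id %in% dmodel$dump$rxn_id) next
    up <- env$medium[id]
    base_lb[j] <- if (!is.na(up)) -abs(up) else 0
  }
  ngam_j <- rxn_index(model, env$ngam_reaction)
  light_j <- rxn_index(model, env$light_exchange)
  comp <- dmodel$components
  list(model = model, rules = rules, frac = frac, u_max = u_max,
       base_lb = base_lb, base_ub = base_ub,
       ngam_j = ngam_j, light_j = light_j,
       syn_j = rxn_index(model, comp$syn_id),
       deg_j = rxn_index(model, comp$deg_id),
       dump_j = rxn_index(model, dmodel$dump$rxn_id),
       dump_mw = dmodel$dump$mw,
       comp = comp, env = env)
}

## lb/ub at diel time t: transcript caps, light schedule, NGAM demand;
## degradation and dump sinks closed (opened selectively by the caller)
sim_bounds <- function(prep, t) {
  lb <- prep$base_lb; ub <- prep$base_ub
  for (j in seq_along(prep$rules)) {
    rule <- prep$rules[[j]]
    if (is.null(rule)) next
    v <- rule_fraction(rule, prep$frac, t)
    cap <- prep$u_max * min(1, v)
    ub[j] <- min(ub[j], cap)
    if (lb[j] < 0) lb[j] <- max(lb[j], -cap)
  }
  lb[prep$light_j] <- -light_at(prep$env, t)
  lb[prep$ngam_j] <- prep$env$ngam
  ub[prep$ngam_j] <- max(prep$env$ngam, ub[prep$ngam_j])
  lb[prep$deg_j] <- 0; ub[prep$deg_j] <- 0
  lb[prep$dump_j] <- 0; ub[prep$dump_j] <- 0
  list(lb = lb, ub = ub)
}

## open degradation (and matching dump sinks) for the given components,
## capped by the mass available over this timestep
open_degradation <- function(prep, bounds, comps, masses, total_mass, dt) {
  for (k in comps) {
    i <- match(k, prep$comp$component)
    cap <- masses[k] / (total_mass * dt)
    bounds$ub[prep$deg_j[i]] <- max(cap, 0)
    mets <- prep$comp$metabolites[[i]]
    dump_rows <- match(paste0("DUMP_", mets), prep$model$reactions$id)
    bounds$ub[dump_rows] <- 1000
  }
  bounds
}

feasible <- function(prep, bounds) {
  res <- lp_solve(rep(0, ncol(prep$model$S)), prep$model$S,
                  rep(0, nrow(prep$model$S)), bounds$lb, bounds$ub)
  res$status == "optimal"
}

solve_sim_lp <- function(prep, bounds, obj, maximize = TRUE) {
  lp_solve(obj, prep$model$S, rep(0, nrow(prep$model$S)),
           bounds$lb, bounds$ub, maximize = maximize)
}

#' Precompute component producibility per time and energy source
#'
#' For every grid time and energy source (the medium, or each biomass
#' component as catabolic substrate with energy exchanges closed), records
#' whether each component's synthesis can carry positive flux under the
#' transcript bounds of that time.
#'
#' @param dmodel a `decoupled_model`.
#' @param fits fitted transcript curves.
#' @param env a `diel_environment`.
#' @param u_max global flux ceiling.
#' @param grid evaluation times (default hourly over the diel cycle).
#' @return tibble `t`, `source` ("medium" or a component name), `component`,
#'   `producible`.
#' @export
production_possibilities <- function(dmodel, fits, env, u_max,
                                     grid = 0:23) {
  prep <- prepare_sim(dmodel, fits, env, u_max)
  n <- ncol(prep$model$S)
  sources <- c("medium", prep$comp$component)
  purrr::map_dfr(grid, function(t) {
    b0 <- sim_bounds(prep, t)
    b0$lb[prep$ngam_j] <- 0          # producibility, not maintenance
    purrr::map_dfr(sources, function(src) {
      b <- b0
      if (src != "medium") {
        i <- match(src, prep$comp$component)
        ej <- unique(c(match(prep$env$energy_exchanges,
                             prep$model$reactions$id), prep$light_j))
        ej <- ej[!is.na(ej)]
        b$lb[ej] <- pmax(b$lb[ej], 0)   # no external energy inputs
        b$ub[prep$deg_j[i]] <- 1000
        mets <- prep$comp$metabolites[[i]]
        b$ub[match(paste0("DUMP_", mets), prep$model$reactions$id)] <- 1000
      }
      ## a component trivially "re-produced" from its own degradation does
      ## not count as producible
      test_idx <- which(prep$comp$component != src)
      ## fast path: if every tested synthesis can carry flux simultaneously
      ## (max-min over them is positive), all are producible in one solve
      k <- length(test_idx)
      syn <- prep$syn_j[test_idx]
      Amm <- cbind(rbind(prep$model$S, matrix(0, k, n)), 0)
      for (r in seq_len(k)) {
        Amm[nrow(prep$model$S) + r, syn[r]] <- 1
        Amm[nrow(prep$model$S) + r, n + 1] <- -1
      }
      ## rows: syn_r - s - slack_r = 0, slack >= 0
      Amm <- cbind(Amm, rbind(matrix(0, nrow(prep$model$S), k), diag(-1, k)))
      mm <- lp_solve(c(rep(0, n), 1, rep(0, k)), Amm,
                     rep(0, nrow(prep$model$S) + k),
                     c(b$lb, 0, rep(0, k)), c(b$ub, 1e6, rep(1e6, k)))
      producible <- rep(FALSE, length(prep$syn_j))
      if (mm$status == "optimal" && mm$x[n + 1] > 1e-8) {
        producible[test_idx] <- TRUE
      } else {
        ## if even the summed synthesis cannot carry flux, nothing can
        obj_sum <- rep(0, n); obj_sum[syn] <- 1
        sm <- solve_sim_lp(prep, b, obj_sum)
        if (sm$status != "optimal" || sm$objective <= 1e-8) {
          producible[test_idx] <- FALSE
        } else {
          producible[test_idx] <- vapply(test_idx, function(ci) {
            obj <- rep(0, n); obj[prep$syn_j[ci]] <- 1
            res <- solve_sim_lp(prep, b, obj)
            res$status == "optimal" && res$objective > 1e-8
          }, logical(1))
        }
      }
      tibble::tibble(t = t, source = src,
                     component = prep$comp$component,
                     producible = producible)
    })
  })
}

## ---- per-step phases -----------------------------------------------------

## returns list(bounds, by_medium, opened, died). Components opened only to
## survive (consumption error <= 0) are capped at the minimal degradation
## the maintenance solve needs, so the production phase cannot raid them;
## components above their setpoints stay open to their availability cap.
ngam_phase <- function(prep, bounds, state, priority_full, e_cons, dt) {
  if (feasible(prep, bounds)) {
    return(list(bounds = bounds, by_medium = TRUE, opened = character(0),
                died = FALSE))
  }
  opened <- character(0)
  for (k in priority_full) {
    if (state$masses[k] <= 1e-12) next
    opened <- c(opened, k)
    bounds2 <- open_degradation(prep, bounds, opened, state$masses,
                                state$total, dt)
    if (feasible(prep, bounds2)) {
      ## minimal degradation meeting maintenance
      n <- ncol(prep$model$S)
      obj <- rep(0, n); obj[prep$deg_j] <- 1
      mindeg <- solve_sim_lp(prep, bounds2, obj, maximize = FALSE)
      if (mindeg$status == "optimal") {
        emergency <- opened[e_cons[opened] <= 0]
        for (ke in emergency) {
          i <- match(ke, prep$comp$component)
          bounds2$ub[prep$deg_j[i]] <- mindeg$x[prep$deg_j[i]] + 1e-9
        }
      }
      return(list(bounds = bounds2, by_medium = FALSE, opened = opened,
                  died = FALSE))
    }
  }
  list(bounds = bounds, by_medium = FALSE, opened = opened, died = TRUE)
}

## iterative production-expansion LP.
##
## Components are produced at the controller-set ratios: with weights w_k,
## maximize the common scale s subject to syn_k = base_k + w_k s. When a
## limitation is hit, the limiting components (those whose synthesis cannot
## individually rise above the achieved flux) are frozen, and the remaining
## ones are expanded again at their ratios, until nothing improves. A final
## minimal-degradation solve removes futile catabolic flux.
produce_step <- function(prep, bounds, weights, tol = 1e-6) {
  n <- ncol(prep$model$S)
  m <- nrow(prep$model$S)
  active <- names(weights)[weights > 0]
  if (length(active) == 0) {
    obj <- rep(0, n); obj[prep$deg_j] <- 1; obj[prep$dump_j] <- 1e-3
    return(solve_sim_lp(prep, bounds, obj, maximize = FALSE))
  }
  ci_all <- match(active, prep$comp$component)
  syn_i <- prep$syn_j[ci_all]; deg_i <- prep$deg_j[ci_all]
  w <- unname(weights[active])
  fixed <- logical(length(active))
  base <- rep(0, length(active))
  ## ratio and pin constraints act on NET production syn_k - deg_k: the
  ## synthesis/degradation pair of a component is a futile cycle the LP
  ## must not exploit to fake production
  net_rows <- function(which_k) {
    R <- matrix(0, length(which_k), n)
    for (r in seq_along(which_k)) {
      R[r, syn_i[which_k[r]]] <- 1
      R[r, deg_i[which_k[r]]] <- -1
    }
    R
  }
  solve_with_rows <- function(extra_A, extra_b, obj, maximize = TRUE,
                              extra_cols = NULL) {
    A <- rbind(prep$model$S, extra_A)
    b <- c(rep(0, m), extra_b)
    lo <- bounds$lb; hi <- bounds$ub
    if (!is.null(extra_cols)) {
      A <- cbind(A, extra_cols$col)
      lo <- c(lo, extra_cols$lb); hi <- c(hi, extra_cols$ub)
      obj <- c(obj, extra_cols$obj)
    }
    lp_solve(obj, A, b, lo, hi, maximize = maximize)
  }
  for (round in seq_len(length(active))) {
    unfixed <- which(!fixed)
    if (!length(unfixed)) break
    ## expand: max s with net_k = base_k + w_k s (unfixed), net_j = base_j
    R <- net_rows(seq_along(active))
    scol <- c(rep(0, m), ifelse(seq_along(active) %in% unfixed, -w, 0))
    res <- solve_with_rows(R, base, rep(0, n), maximize = TRUE,
                           extra_cols = list(col = scol, lb = 0, ub = 1e6,
                                             obj = 1))
    if (res$status == "optimal" && res$x[n + 1] > tol) {
      base[unfixed] <- base[unfixed] + w[unfixed] * res$x[n + 1]
    }
    ## quick collective check: with every unfixed net held at >= base, can
    ## the sum still rise? If not, no single component can, and all are
    ## limiting at once (the typical energy-limited case).
    obj_sum <- rep(0, n)
    obj_sum[syn_i[unfixed]] <- 1; obj_sum[deg_i[unfixed]] <- -1
    sum_probe <- local({
      A <- rbind(prep$model$S, net_rows(setdiff(seq_along(active), unfixed)))
      b <- c(rep(0, m), base[setdiff(seq_along(active), unfixed)])
      lo <- bounds$lb; hi <- bounds$ub
      ## nets >= base via slack columns: net_k - slack_k = base_k
      k <- length(unfixed)
      A2 <- rbind(A, matrix(0, k, n))
      for (r in seq_len(k)) {
        A2[nrow(A) + r, syn_i[unfixed[r]]] <- 1
        A2[nrow(A) + r, deg_i[unfixed[r]]] <- -1
      }
      Acols <- rbind(matrix(0, nrow(A), k), diag(-1, k))
      lp_solve(c(obj_sum, rep(0, k)), cbind(A2, Acols),
               c(b, base[unfixed]), c(lo, rep(0, k)),
               c(hi, rep(1e6, k)))
    })
    sum_gain <- if (sum_probe$status == "optimal") {
      sum_probe$objective - sum(base[unfixed])
    } else 0
    if (sum_gain <= tol * (1 + sum(abs(base[unfixed])))) {
      fixed[] <- TRUE
      break
    }
    ## probe each unfixed component for individual net headroom
    newly <- FALSE
    for (ci in unfixed) {
      others <- setdiff(seq_along(active), ci)
      obj2 <- rep(0, n)
      obj2[syn_i[ci]] <- 1; obj2[deg_i[ci]] <- -1
      probe <- if (length(others)) {
        solve_with_rows(net_rows(others), base[others], obj2)
      } else {
        solve_with_rows(matrix(0, 0, n), numeric(0), obj2)
      }
      gain <- if (probe$status == "optimal") probe$objective - base[ci] else 0
      if (gain <= tol * (1 + abs(base[ci]))) {
        fixed[ci] <- TRUE
        newly <- TRUE
      }
    }
    if (!newly) fixed[] <- TRUE   # nothing limiting: ratios fully expanded
  }
  ## final: net productions pinned at achieved values, minimal
  ## degradation and dumping (removes futile cycles and spare catabolism)
  obj <- rep(0, n); obj[prep$deg_j] <- 1; obj[prep$dump_j] <- 1e-3
  res <- solve_with_rows(net_rows(seq_along(active)), base, obj,
                         maximize = FALSE)
  if (res$status != "optimal") {
    res <- solve_with_rows(net_rows(seq_along(active)), base * 0.999, obj,
                           maximize = FALSE)
  }
  if (res$status != "optimal") {
    res <- solve_sim_lp(prep, bounds, rep(0, n))
  }
  res
}

#' Advance the simulation state by one Euler step
#'
#' Component masses change by `(synthesis - degradation) * total_mass * dt`
#' (synthesis/degradation fluxes are in g component per gDW per h by
#' construction of the decoupled model); dumped mass -- degraded metabolites
#' leaving through dump sinks -- accumulates in a ledger. Masses are clamped
#' at zero, with an error if the overshoot exceeds tolerance.
#'
#' @param state simulation state (`t`, `masses`, `total`, `dumped`).
#' @param fluxes named flux vector of the step's final LP solution.
#' @param prep internal simulation context (from the simulator).
#' @param dt timestep (h).
#' @return updated state, with step accounting in `state$step` (`produced`,
#'   `consumed`, `dumped` in g).
#' @keywords internal
advance_state <- function(state, fluxes, prep, dt) {
  syn <- fluxes[prep$syn_j]; deg <- fluxes[prep$deg_j]
  dump <- fluxes[prep$dump_j]
  M <- state$total
  dm <- (syn - deg) * M * dt
  newm <- state$masses + stats::setNames(dm, prep$comp$component)
  if (any(newm < -1e-6)) {
    stop("component mass went negative beyond tolerance: ",
         paste(names(newm)[newm < -1e-6], collapse = ", "), call. = FALSE)
  }
  newm <- pmax(newm, 0)
  dumped_g <- sum(dump * prep$dump_mw / 1000) * M * dt
  produced_g <- sum(syn) * M * dt
  consumed_total_g <- sum(deg) * M * dt
  state$masses <- newm
  state$total <- sum(newm)
  state$dumped <- state$dumped + dumped_g
  state$t <- state$t + dt
  state$step <- list(produced = produced_g,
                     consumed = consumed_total_g - dumped_g,
                     dumped = dumped_g)
  state
}

## ---- main loop -----------------------------------------------------------

#' Simulate diel growth of a transcript-constrained decoupled model
#'
#' Marches the model through the day/night cycle. Every timestep the
#' transcript curves rebound all GPR-mapped reactions, the PI controllers
#' are updated from the current composition, maintenance ATP is satisfied
#' (from the medium if possible, otherwise by catabolizing stored
#' components in consumption-priority order, each only as far as needed),
#' the weighted iterative production LP runs, and component masses advance
#' by forward Euler. If maintenance cannot be met even with every component
#' opened for catabolism, the cell dies and the trajectory is truncated
#' with status `"died"`.
#'
#' @param dmodel a `decoupled_model` from [split_biomass()].
#' @param fits fitted transcript curves (`diel_fits`).
#' @param env a `diel_environment`.
#' @param setpoints diel composition setpoint table (`time`, `component`,
#'   `fraction`).
#' @param hours simulated duration (h).
#' @param dt timestep (h), default 0.1 (ten steps per hour).
#' @param u_max global flux ceiling; default calibrated from the light
#'   reaction's GPR via [calibrate_umax()].
#' @param light_rule GPR string of the light-harvesting reaction used for
#'   `u_max` calibration (required when `u_max` is `NULL`).
#' @param controllers controller state (default [new_controller_state()]).
#' @param initial_mass starting total biomass (g).
#' @param possibilities optional precomputed [production_possibilities()]
#'   table (computed on an hourly grid if omitted).
#' @param store_fluxes keep each step's flux vector (list column).
#' @return object of class `diel_simulation`: list with `trajectory`
#'   (tibble: `t`, `status`, per-component masses, `total`, `normalized`,
#'   `produced`, `consumed`, `dumped`, `dumped_cum`, `ngam_source`),
#'   `status` (`"completed"` or `"died"`), `final` state and call
#'   parameters.
#' @export
simulate_diel <- function(dmodel, fits, env, setpoints, hours = 24, dt = 0.1,
                          u_max = NULL, light_rule = NULL,
                          controllers = new_controller_state(
                            dmodel$components$component),
                          initial_mass = 1,
                          possibilities = NULL,
                          store_fluxes = FALSE) {
  stopifnot(dt > 0, hours > 0)
  if (is.null(u_max)) {
    if (is.null(light_rule)) {
      stop("supply u_max or light_rule for calibration", call. = FALSE)
    }
    u_max <- calibrate_umax(light_rule, build_fraction_ctx(fits),
                            env$light_availability)
  }
  prep <- prepare_sim(dmodel, fits, env, u_max)
  spf_raw <- setpoint_fn(setpoints)
  comps <- prep$comp$component
  if (is.null(possibilities)) {
    possibilities <- production_possibilities(dmodel, fits, env, u_max)
  }
  ## a component that cannot be produced from any source at any time cannot
  ## be part of this genotype's composition (e.g. starch in a starchless
  ## knockout): start it at zero, drop it from the setpoints, and
  ## renormalize the remaining setpoints so the composition target is
  ## attainable
  ever <- dplyr::summarise(dplyr::group_by(possibilities, .data$component),
                           ever = any(.data$producible), .groups = "drop")
  never_made <- ever$component[!ever$ever]
  spf <- if (length(never_made)) {
    function(t) {
      sp <- spf_raw(t)[comps]
      tot <- sum(sp)
      sp[comps %in% never_made] <- 0
      s2 <- sum(sp)
      if (s2 > 0) sp <- sp * (tot / s2)
      sp
    }
  } else {
    function(t) spf_raw(t)[comps]
  }
  sp0 <- spf(0)
  if (sum(sp0) <= 0) stop("no producible biomass component", call. = FALSE)
  masses0 <- sp0 / sum(sp0) * initial_mass
  state <- list(t = 0, masses = stats::setNames(masses0, comps),
                total = initial_mass, dumped = 0)
  n_steps <- ceiling(hours / dt - 1e-9)
  rows <- vector("list", n_steps)
  fluxes_list <- if (store_fluxes) vector("list", n_steps) else NULL
  status <- "completed"
  for (s in seq_len(n_steps)) {
    t <- state$t
    bounds <- sim_bounds(prep, t %% 24)
    actual <- state$masses / state$total
    sp <- spf(t)[comps]
    controllers <- update_controllers(controllers, actual, sp, dt)
    e_cons <- stats::setNames(controllers$e_cons, controllers$component)
    e_prod <- stats::setNames(controllers$e_prod, controllers$component)
    ## maintenance phase
    pri <- consumption_priority(e_cons, ngam_unmet = FALSE)
    pri_full <- consumption_priority(e_cons, ngam_unmet = TRUE)
    ng <- ngam_phase(prep, bounds, state,
                     unique(c(pri, pri_full)), e_cons, dt)
    if (ng$died) {
      status <- "died"
      rows[[s]] <- snapshot_row(state, comps, t, "died", "none",
                                c(produced = 0, consumed = 0, dumped = 0))
      rows <- rows[seq_len(s)]
      break
    }
    bounds <- ng$bounds
    ## production phase: energy sources are the medium (if maintenance came
    ## from it) plus components already opened / above setpoint
    extra_sources <- if (ng$by_medium) {
      names(e_cons)[e_cons > 0 & state$masses[names(e_cons)] > 1e-12]
    } else {
      setdiff(names(e_cons)[e_cons > 0 & state$masses[names(e_cons)] > 1e-12],
              ng$opened)
    }
    if (length(extra_sources)) {
      bounds <- open_degradation(prep, bounds, extra_sources, state$masses,
                                 state$total, dt)
    }
    th <- floor(t %% 24)
    act_sources <- c(if (ng$by_medium) "medium", ng$opened, extra_sources)
    poss <- possibilities[possibilities$t == th &
                            possibilities$source %in% act_sources, ]
    producible <- unique(poss$component[poss$producible])
    w <- objective_weights(e_prod, producible)
    sol <- produce_step(prep, bounds, w)
    if (sol$status != "optimal") {
      ## fall back to plain maintenance solution
      sol <- solve_sim_lp(prep, bounds, rep(0, ncol(prep$model$S)))
    }
    state <- advance_state(state, sol$x, prep, dt)
    rows[[s]] <- snapshot_row(state, comps, state$t,
                              "alive",
                              if (ng$by_medium) "medium"
                              else paste(ng$opened, collapse = "+"),
                              unlist(state$step))
    if (store_fluxes) {
      fluxes_list[[s]] <- stats::setNames(sol$x, prep$model$reactions$id)
    }
  }
  traj <- dplyr::bind_rows(rows)
  traj$normalized <- traj$total / initial_mass
  out <- list(trajectory = traj, status = status,
              final = state, u_max = u_max, dt = dt, hours = hours,
              controllers = controllers,
              fluxes = fluxes_list)
  class(out) <- "diel_simulation"
  out
}

snapshot_row <- function(state, comps, t, status, ngam_source, step) {
  row <- tibble::tibble(t = t, status = status, total = state$total,
                        dumped_cum = state$dumped,
                        produced = unname(step["produced"]),
                        consumed = unname(step["consumed"]),
                        dumped = unname(step["dumped"]),
                        ngam_source = ngam_source)
  for (k in comps) row[[paste0("mass_", k)]] <- unname(state$masses[k])
  row
}

#' @export
print.diel_simulation <- function(x, ...) {
  fin <- x$trajectory[nrow(x$trajectory), ]
  cat("<diel_simulation> ", x$hours, " h at dt = ", x$dt, " h; status: ",
      x$status, "\n  final normalized mass: ",
      format(fin$normalized, digits = 5), "\n", sep = "")
  invisible(x)
}
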