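## Decoupled biomass: the single biomass formation equation is split into
## ten component pools, each with its own synthesis and degradation
## pseudo-reaction, so components can be produced (or consumed) at different
## times of day. Dual proportional-integral controllers per component track
## diel composition setpoints and produce the error terms that set
## production goals and consumption priorities.

#' The ten biomass component pool names
#'
#' Canonical order; used for deterministic tie-breaking throughout.
#'
#' @return character vector of length 10.
#' @export
biomass_components <- function() {
  c("carotenoid", "chlorophyll_a", "chlorophyll_b", "protein", "lipid",
    "lipid_droplet", "carbohydrate", "nucleotide", "redox", "starch")
}

#' Partition lipid species into bulk lipid and lipid droplet
#'
#' Triacylglycerides with measured tail compositions form the lipid-droplet
#' pool, which can rise and fall independently (the nitrogen-stress
#' phenotype); all other lipid species stay in the bulk lipid pool, which
#' includes nitrogen-containing lipids and is therefore constrained under
#' nitrogen limitation.
#'
#' @param lipid_metabolites ids of all lipid species in the biomass
#'   equation.
#' @param measured_tags ids of TAG species with measured tails (duplicates
#'   are removed).
#' @return tibble `metabolite`, `component` (`"lipid"` or
#'   `"lipid_droplet"`); flagged via attribute `empty_droplet` when no TAG
#'   is listed.
#' @export
split_lipids <- function(lipid_metabolites, measured_tags) {
  measured_tags <- unique(measured_tags)
  out <- tibble::tibble(
    metabolite = unique(lipid_metabolites),
    component = ifelse(unique(lipid_metabolites) %in% measured_tags,
                       "lipid_droplet", "lipid"))
  if (!any(out$component == "lipid_droplet")) {
    attr(out, "empty_droplet") <- TRUE
  }
  out
}

#' Split the biomass equation into component synthesis/degradation pools
#'
#' The model's biomass reaction is disabled and replaced by one synthesis
#' pseudo-reaction per component (consuming that component's metabolites,
#' scaled so that unit flux forms 1 g of component per gDW per h) and one
#' degradation pseudo-reaction (the exact reverse, returning the metabolites
#' to the network; closed by default). Per-metabolite dump sinks (closed by
#' default) let degraded species that no catabolic pathway can consume leave
#' the cell, with the lost mass tracked by the simulator. Summing the
#' component syntheses at the original mass fractions reproduces the
#' original biomass equation exactly.
#'
#' @param model a `metabolic_model` whose metabolites carry formulas.
#' @param component_map data frame `metabolite`, `component` assigning every
#'   consumed biomass metabolite to exactly one of [biomass_components()].
#' @param biomass_reaction id of the biomass reaction (default: the reaction
#'   with nonzero objective coefficient).
#' @return list of class `decoupled_model`: `model` (expanded), `components`
#'   (tibble `component`, `mass_fraction`, `syn_id`, `deg_id`,
#'   `metabolites` list column), `dump` (tibble `metabolite`, `rxn_id`,
#'   `mw`), `biomass_reaction`.
#' @export
split_biomass <- function(model, component_map, biomass_reaction = NULL) {
  if (is.null(biomass_reaction)) {
    cand <- model$reactions$id[model$reactions$objective != 0]
    if (length(cand) != 1) {
      stop("cannot identify a unique biomass reaction; pass biomass_reaction",
           call. = FALSE)
    }
    biomass_reaction <- cand
  }
  j <- rxn_index(model, biomass_reaction)
  coef <- model$S[, j]
  consumed <- names(coef)[coef < 0]
  component_map <- tibble::as_tibble(component_map)
  stopifnot(all(c("metabolite", "component") %in% names(component_map)))
  bad_comp <- setdiff(component_map$component, biomass_components())
  if (length(bad_comp)) {
    stop("unknown component(s): ", paste(bad_comp, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(component_map$metabolite, consumed)
  if (length(extra)) {
    stop("mapped metabolite(s) not consumed by the biomass equation: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  unassigned <- setdiff(consumed, component_map$metabolite)
  if (length(unassigned)) {
    stop("biomass metabolite(s) not assigned to any component: ",
         paste(unassigned, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(component_map$metabolite)) {
    stop("each biomass metabolite must map to exactly one component",
         call. = FALSE)
  }
  mw <- stats::setNames(formula_weight(model$metabolites$formula),
                        model$metabolites$id)
  if (any(mw[consumed] <= 0)) {
    stop("biomass metabolites need formulas to compute component masses",
         call. = FALSE)
  }
  comps <- unique(component_map$component)
  comp_tbl <- purrr::map_dfr(comps, function(k) {
    mets <- component_map$metabolite[component_map$component == k]
    fk <- sum(-coef[mets] * mw[mets] / 1000)   # g of component per gDW
    tibble::tibble(component = k, mass_fraction = fk,
                   syn_id = paste0("SYNC_", k), deg_id = paste0("DEGC_", k),
                   metabolites = list(mets))
  })
  comp_tbl <- comp_tbl[order(match(comp_tbl$component, biomass_components())), ]

  mets_all <- unique(component_map$metabolite)
  new_rxns <- dplyr::bind_rows(
    tibble::tibble(id = comp_tbl$syn_id,
                   name = paste("synthesis of", comp_tbl$component),
                   lb = 0, ub = 1000, gpr = "", objective = 0),
    tibble::tibble(id = comp_tbl$deg_id,
                   name = paste("degradation of", comp_tbl$component),
                   lb = 0, ub = 0, gpr = "", objective = 0),
    tibble::tibble(id = paste0("DUMP_", mets_all),
                   name = paste("dump sink for", mets_all),
                   lb = 0, ub = 0, gpr = "", objective = 0))
  Sadd <- matrix(0, nrow(model$S), nrow(new_rxns),
                 dimnames = list(rownames(model$S), new_rxns$id))
  for (r in seq_len(nrow(comp_tbl))) {
    mets <- comp_tbl$metabolites[[r]]
    fk <- comp_tbl$mass_fraction[r]
    Sadd[mets, comp_tbl$syn_id[r]] <- coef[mets] / fk      # consumes (neg)
    Sadd[mets, comp_tbl$deg_id[r]] <- -coef[mets] / fk     # returns (pos)
  }
  for (m in mets_all) Sadd[m, paste0("DUMP_", m)] <- -1
  rx <- model$reactions
  rx$lb[j] <- 0; rx$ub[j] <- 0; rx$objective[j] <- 0     # biomass disabled
  new_model <- metabolic_model(paste0(model$id, "_decoupled"),
                               model$metabolites,
                               dplyr::bind_rows(rx, new_rxns),
                               cbind(model$S, Sadd),
                               genes = model$genes)
  structure(list(model = new_model, components = comp_tbl,
                 dump = tibble::tibble(metabolite = mets_all,
                                       rxn_id = paste0("DUMP_", mets_all),
                                       mw = unname(mw[mets_all])),
                 biomass_reaction = biomass_reaction),
            class = "decoupled_model")
}

#' @export
print.decoupled_model <- function(x, ...) {
  cat("<decoupled_model> ", x$model$id, ": ", nrow(x$components),
      " components\n", sep = "")
  invisible(x)
}

## ---- diel setpoints ------------------------------------------------------

#' Periodic piecewise-linear setpoint interpolator
#'
#' @param setpoints data frame `time`, `component`, `fraction` covering
#'   \[0, 24\]; fractions must be nonnegative and sum to at most 1 at each
#'   tabulated time.
#' @return function `(t) -> named fraction vector` (24-periodic).
#' @export
setpoint_fn <- function(setpoints) {
  sp <- tibble::as_tibble(setpoints)
  stopifnot(all(c("time", "component", "fraction") %in% names(sp)))
  if (any(sp$fraction < 0)) stop("setpoint fractions must be >= 0", call. = FALSE)
  sums <- dplyr::summarise(dplyr::group_by(sp, .data$time),
                           s = sum(.data$fraction), .groups = "drop")
  if (any(sums$s > 1 + 1e-9)) {
    stop("setpoint fractions sum to more than 1 at t = ",
         sums$time[which.max(sums$s)], call. = FALSE)
  }
  comps <- unique(sp$component)
  funs <- lapply(comps, function(k) {
    d <- sp[sp$component == k, ]
    d <- d[order(d$time), ]
    tt <- d$time; ff <- d$fraction
    ## periodic extension so interpolation wraps across midnight
    tt2 <- c(tt[length(tt)] - 24, tt, tt[1] + 24)
    ff2 <- c(ff[length(ff)], ff, ff[1])
    stats::approxfun(tt2, ff2, ties = mean)
  })
  names(funs) <- comps
  function(t) {
    tt <- t %% 24
    vapply(funs, function(f) f(tt), numeric(1))
  }
}

## ---- PI controllers ------------------------------------------------------

#' Initialize per-component PI controller state
#'
#' One pair of proportional-integral controllers per biomass component: the
#' production controller pushes a component up when it sits below its
#' setpoint, the consumption controller marks components that have been
#' above their setpoints for some time as preferred catabolic substrates.
#' The integral term is clamped to an anti-windup box of
#' `windup_factor` x the current setpoint.
#'
#' @param components component names.
#' @param kp proportional gain (1/h scale).
#' @param ki integral gain (1/h^2 scale).
#' @param windup_factor anti-windup clamp as a multiple of the setpoint.
#' @return tibble controller state.
#' @export
new_controller_state <- function(components = biomass_components(),
                                 kp = 1, ki = 0.1, windup_factor = 10) {
  tibble::tibble(component = components, kp = kp, ki = ki,
                 windup_factor = windup_factor, integral = 0,
                 e_prod = 0, e_cons = 0)
}

#' Update PI controllers with the current composition
#'
#' For each component with setpoint `sp` and actual mass fraction `x`:
#' the integral accumulates `(sp - x) dt` (clamped to the anti-windup box),
#' the production error is `kp (sp - x) + ki I`, and the consumption error
#' is its negative, `kp (x - sp) + ki (-I)` -- rising when a component has
#' persistently exceeded its setpoint.
#'
#' @param state controller tibble from [new_controller_state()].
#' @param actual named vector of actual mass fractions.
#' @param setpoints named vector of setpoint fractions.
#' @param dt timestep (h).
#' @return updated controller tibble.
#' @export
update_controllers <- function(state, actual, setpoints, dt) {
  stopifnot(dt > 0)
  sp <- setpoints[state$component]
  x <- actual[state$component]
  err <- unname(sp - x)
  lim <- state$windup_factor * pmax(unname(sp), 1e-6)
  state$integral <- pmin(pmax(state$integral + err * dt, -lim), lim)
  state$e_prod <- state$kp * err + state$ki * state$integral
  state$e_cons <- -state$kp * err - state$ki * state$integral
  state
}

#' Normalized production objective weights from production errors
#'
#' Weights are proportional to the positive production errors over the
#' producible components. When no producible component has positive error,
#' the fallback depends on why: components sitting essentially *at* their
#' setpoints (|error| below `zero_tol`) share uniform weights, so a cell
#' that is perfectly on-target keeps growing; components clearly above
#' their setpoints (error strongly negative) get no weight, so the cell
#' does not manufacture surplus it would have to discard.
#'
#' @param e_prod named production errors.
#' @param producible names of components producible this timestep.
#' @param zero_tol tolerance below which an error counts as zero.
#' @return named weights summing to 1 over a subset of `producible` (empty
#'   if nothing should be produced).
#' @export
objective_weights <- function(e_prod, producible = names(e_prod),
                              zero_tol = 1e-9) {
  if (length(producible) == 0) return(stats::setNames(numeric(0), character(0)))
  e <- pmax(e_prod[producible], 0)
  if (sum(e) > 0) return(e / sum(e))
  near0 <- producible[abs(e_prod[producible]) <= zero_tol]
  if (length(near0) == 0) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(rep(1 / length(near0), length(near0)), near0)
}

#' Order components for catabolism by consumption error
#'
#' Components with positive consumption error are consumed first, in
#' descending error order (ties broken by the canonical component order).
#' Components at or below their setpoints are excluded unless maintenance
#' ATP is still unmet, in which case the full descending list is returned
#' with an emergency flag and starch promoted among ties (the designated
#' storage pool).
#'
#' @param e_cons named consumption errors.
#' @param ngam_unmet logical; is maintenance ATP still unmet?
#' @return character vector of component names (attribute `emergency` set
#'   when the fallback list is included).
#' @export
consumption_priority <- function(e_cons, ngam_unmet = FALSE) {
  canon <- match(names(e_cons), biomass_components())
  pos <- names(e_cons)[e_cons > 0]
  pos <- pos[order(-e_cons[pos], canon[match(pos, names(e_cons))])]
  if (!ngam_unmet) return(pos)
  rest <- setdiff(names(e_cons), pos)
  starch_first <- ifelse(rest == "starch", 0L, 1L)
  rest <- rest[order(-e_cons[rest], starch_first,
                     canon[match(rest, names(e_cons))])]
  out <- c(pos, rest)
  attr(out, "emergency") <- length(rest) > 0
  out
}
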