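## Flux balance analysis over the package's LP core.

#' Flux balance analysis
#'
#' Solves `max c'v` subject to `S v = 0` and `lb <= v <= ub` over the
#' model's stoichiometric matrix.
#'
#' @param model a `metabolic_model`.
#' @param objective objective specification: `NULL` (use the model's
#'   objective coefficients), a reaction id, or a named numeric vector of
#'   coefficients by reaction id.
#' @param lb,ub optional bound vectors overriding the model bounds
#'   (full-length, in reaction order).
#' @param maximize logical.
#' @return list of class `flux_solution`: `status`, `objective`, `fluxes`
#'   (named numeric over reactions).
#' @export
#' @examples
#' toy <- build_toy_model()
#' sol <- fba(toy$model, objective = "BIOMASS")
#' sol$status
fba <- function(model, objective = NULL, lb = NULL, ub = NULL,
                maximize = TRUE) {
  rx <- model$reactions
  obj <- rep(0, nrow(rx))
  if (is.null(objective)) {
    obj <- rx$objective
  } else if (is.character(objective)) {
    obj[rxn_index(model, objective)] <- 1
  } else if (is.numeric(objective) && !is.null(names(objective))) {
    obj[rxn_index(model, names(objective))] <- unname(objective)
  } else {
    stop("objective must be NULL, a reaction id, or a named numeric vector",
         call. = FALSE)
  }
  lb <- lb %||% rx$lb
  ub <- ub %||% rx$ub
  res <- lp_solve(obj, model$S, rep(0, nrow(model$S)), lb, ub,
                  maximize = maximize)
  structure(list(status = res$status,
                 objective = res$objective,
                 fluxes = stats::setNames(res$x, rx$id)),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status,
      "  objective: ", format(x$objective, digits = 6), "\n", sep = "")
  invisible(x)
}
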