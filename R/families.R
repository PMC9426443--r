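## Parametric expression families for diel transcript profiles.
##
## All families are defined on a 24-h diel frame: time enters as t mod 24,
## hours since light onset. Each family is a list with
##   name      identifier used throughout the package
##   n_params  number of free parameters (enters the AICc penalty)
##   par_names names of the stored parameter slots (fixed layout; may include
##             one non-free context slot, e.g. the spike width of the
##             Kronecker-delta family, so that curve databases round-trip)
##   eval      function(params, t) -> raw (unclamped) model value

DIEL_PERIOD <- 24

#' Names of the candidate expression families, in canonical order
#'
#' The fixed ordering is load-bearing: fit tables, Akaike-weight vectors and
#' similarity fit-vectors all use this order, and ties in model selection are
#' broken towards the earlier (simpler) family.
#'
#' @return character vector of the eight family names.
#' @export
expression_families <- function() {
  c("constant", "one_term_cosine", "two_term_cosine", "hat",
    "fixed_decay", "variable_decay", "kronecker_delta",
    "cosine_multiplicative")
}

tmod <- function(t) t %% DIEL_PERIOD

## indicator for a wrap-around window [on, off) on the diel circle
in_window <- function(t, on, off) {
  tt <- tmod(t); on <- tmod(on); off <- tmod(off)
  if (isTRUE(all.equal(on, off))) rep(FALSE, length(tt))
  else if (on < off) tt >= on & tt < off
  else tt >= on | tt < off
}

family_defs <- local({
  w1 <- 2 * pi / DIEL_PERIOD
  list(
    constant = list(
      name = "constant", n_params = 1L, par_names = "c",
      eval = function(p, t) rep(p[["c"]], length(t))
    ),
    one_term_cosine = list(
      name = "one_term_cosine", n_params = 3L, par_names = c("c", "A", "phi"),
      eval = function(p, t) p[["c"]] + p[["A"]] * cos(w1 * (t - p[["phi"]]))
    ),
    two_term_cosine = list(
      name = "two_term_cosine", n_params = 5L,
      par_names = c("c", "A1", "phi1", "A2", "phi2"),
      eval = function(p, t) {
        p[["c"]] + p[["A1"]] * cos(w1 * (t - p[["phi1"]])) +
          p[["A2"]] * cos(2 * w1 * (t - p[["phi2"]]))
      }
    ),
    hat = list(
      name = "hat", n_params = 4L, par_names = c("c", "A", "t_on", "t_off"),
      eval = function(p, t) {
        p[["c"]] + p[["A"]] * as.numeric(in_window(t, p[["t_on"]], p[["t_off"]]))
      }
    ),
    fixed_decay = list(
      name = "fixed_decay", n_params = 2L, par_names = c("c", "A"),
      tau0 = 4,
      eval = function(p, t) p[["c"]] + p[["A"]] * exp(-tmod(t) / 4)
    ),
    variable_decay = list(
      name = "variable_decay", n_params = 3L, par_names = c("c", "A", "tau"),
      eval = function(p, t) p[["c"]] + p[["A"]] * exp(-tmod(t) / p[["tau"]])
    ),
    kronecker_delta = list(
      name = "kronecker_delta", n_params = 3L,
      par_names = c("c", "A", "t0", "width"),   # width is context, not free
      eval = function(p, t) {
        p[["c"]] + p[["A"]] *
          as.numeric(in_window(t, p[["t0"]], p[["t0"]] + p[["width"]]))
      }
    ),
    cosine_multiplicative = list(
      name = "cosine_multiplicative", n_params = 4L,
      par_names = c("c", "A", "phi", "g"),
      eval = function(p, t) {
        (p[["c"]] + p[["A"]] * cos(w1 * (t - p[["phi"]]))) * exp(p[["g"]] * tmod(t))
      }
    )
  )
})

get_family <- function(name) {
  fam <- family_defs[[name]]
  if (is.null(fam)) {
    stop("unknown expression family: '", name, "'", call. = FALSE)
  }
  fam
}

#' Evaluate one expression family at given times
#'
#' Raw model values; negative values are permitted here (clamping to
#' nonnegative expression happens only when curves are queried for
#' downstream use, see [query_curve()]).
#'
#' @param family family name, one of [expression_families()].
#' @param params named numeric vector of parameters (see the family's
#'   `par_names`; `kronecker_delta` additionally uses a `width` slot).
#' @param t numeric times in hours; evaluated modulo 24.
#' @return numeric vector of model values.
#' @export
#' @examples
#' eval_family("one_term_cosine", c(c = 100, A = 50, phi = 6), t = c(0, 6, 12))
eval_family <- function(family, params, t) {
  fam <- get_family(family)
  p <- as.list(params)
  missing <- setdiff(setdiff(fam$par_names, "width"), names(p))
  if (length(missing)) {
    stop("family '", family, "' needs parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (family == "kronecker_delta" && is.null(p$width)) p$width <- 2
  fam$eval(p, t)
}
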