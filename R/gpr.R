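## Gene-protein-reaction Boolean rules and transcript-driven flux bounds.
##
## A reaction catalysed by an enzyme complex (genes joined by AND) is limited
## by its least-expressed subunit: the combined flux fraction is the minimum
## of the member fractions. Isozymes (OR) act in parallel: fractions add.
## The combined fraction, capped at 1, scales a global flux ceiling u_max
## into the reaction's time-varying upper bound.

gpr_tokenize <- function(s) {
  s <- gsub("&&|&", " and ", s)
  s <- gsub("\\|\\||\\|", " or ", s)
  s <- gsub("\\(", " ( ", s)
  s <- gsub("\\)", " ) ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Parse a gene-protein-reaction rule string
#'
#' Accepts `and`/`or` (case-insensitive; `&`/`|` synonyms) with parentheses;
#' AND binds tighter than OR. The empty string denotes an unmapped reaction.
#'
#' @param rule_string GPR text, e.g. `"a or (b and c)"`.
#' @return object of class `gpr_rule`: a Boolean expression tree with node
#'   types `or`, `and`, `gene`, or `empty` for unmapped reactions.
#' @export
#' @examples
#' r <- parse_gpr("a or (b and c)")
#' format(r)
parse_gpr <- function(rule_string) {
  if (is.null(rule_string) || is.na(rule_string) || !nzchar(trimws(rule_string))) {
    return(structure(list(type = "empty"), class = "gpr_rule"))
  }
  toks <- gpr_tokenize(rule_string)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  is_kw <- function(t, kw) !is.na(t) && tolower(t) == kw

  parse_expr <- function() {
    left <- parse_term()
    kids <- list(left)
    while (is_kw(peek(), "or")) {
      take()
      kids <- c(kids, list(parse_term()))
    }
    if (length(kids) == 1) kids[[1]] else list(type = "or", children = kids)
  }
  parse_term <- function() {
    left <- parse_factor()
    kids <- list(left)
    while (is_kw(peek(), "and")) {
      take()
      kids <- c(kids, list(parse_factor()))
    }
    if (length(kids) == 1) kids[[1]] else list(type = "and", children = kids)
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("GPR parse error: unexpected end of rule at position ",
                       pos, call. = FALSE)
    if (t == "(") {
      take()
      inner <- parse_expr()
      if (!identical(peek(), ")")) {
        stop("GPR parse error: unbalanced parentheses at token ", pos,
             call. = FALSE)
      }
      take()
      inner
    } else if (t == ")") {
      stop("GPR parse error: unbalanced parentheses at token ", pos,
           call. = FALSE)
    } else if (tolower(t) %in% c("and", "or")) {
      stop("GPR parse error: unexpected operator '", t, "' at token ", pos,
           call. = FALSE)
    } else {
      take()
      list(type = "gene", gene = t)
    }
  }
  tree <- parse_expr()
  if (pos <= length(toks)) {
    stop("GPR parse error: trailing input at token ", pos,
         if (identical(peek(), ")")) " (unbalanced parentheses)" else "",
         call. = FALSE)
  }
  structure(tree, class = "gpr_rule")
}

#' @export
format.gpr_rule <- function(x, ...) {
  dep <- function(node, parent = "") {
    switch(node$type,
      empty = "",
      gene = node$gene,
      and = {
        s <- paste(vapply(node$children, dep, character(1), parent = "and"),
                   collapse = " and ")
        if (parent == "") s else s
      },
      or = {
        s <- paste(vapply(node$children, dep, character(1), parent = "or"),
                   collapse = " or ")
        if (parent == "and") paste0("(", s, ")") else s
      })
  }
  dep(unclass(x))
}

#' @export
print.gpr_rule <- function(x, ...) {
  cat("<gpr_rule> ", if (x$type == "empty") "(unmapped)" else format(x), "\n",
      sep = "")
  invisible(x)
}

#' Genes referenced by a GPR rule
#'
#' @param rule a `gpr_rule` (or rule string).
#' @return character vector of gene identifiers.
#' @export
gpr_genes <- function(rule) {
  if (is.character(rule)) rule <- parse_gpr(rule)
  walk <- function(node) {
    switch(node$type,
      empty = character(0),
      gene = node$gene,
      unlist(lapply(node$children, walk)))
  }
  unique(walk(unclass(rule)))
}

gpr_genes_from_string <- function(s) {
  toks <- gpr_tokenize(s)
  toks[!(tolower(toks) %in% c("and", "or", "(", ")"))]
}

#' Normalized expression fraction of a gene at a diel time
#'
#' The best-fit curve value divided by its maximum over the diel cycle,
#' giving a fraction in \[0, 1\] that peaks at 1 at the transcript's diel
#' maximum. An all-zero curve yields fraction 0 at every time (flagged).
#'
#' @param fits a `diel_fits` table.
#' @param gene gene identifier.
#' @param t time(s) in hours.
#' @param grid_dt grid resolution used to locate the diel maximum.
#' @return numeric fraction(s) in \[0, 1\].
#' @export
normalized_fraction <- function(fits, gene, t, grid_dt = 0.05) {
  f <- curve_evaluator(fits, gene)
  peak <- max(f(seq(0, 24 - grid_dt, by = grid_dt)))
  if (peak <= 0) {
    out <- rep(0, length(t))
    attr(out, "all_zero") <- TRUE
    return(out)
  }
  pmin(f(t) / peak, 1)
}

## precompute per-gene fraction closures for fast repeated evaluation;
## returns function(gene, t) -> fraction, with missing-gene policy = 1
build_fraction_ctx <- function(fits, genes = NULL, grid_dt = 0.05) {
  if (is.null(genes)) genes <- unique(fits$gene_id)
  grid <- seq(0, 24 - grid_dt, by = grid_dt)
  tab <- new.env(parent = emptyenv())
  for (g in genes) {
    f <- curve_evaluator(fits, g)
    peak <- max(f(grid))
    assign(g, list(f = f, peak = peak), envir = tab)
  }
  warned <- new.env(parent = emptyenv())
  function(gene, t) {
    e <- get0(gene, envir = tab)
    if (is.null(e)) {
      if (is.null(get0(gene, envir = warned))) {
        warning("gene '", gene,
                "' has no transcript curve; treating as unconstrained",
                call. = FALSE)
        assign(gene, TRUE, envir = warned)
      }
      return(rep(1, length(t)))
    }
    if (e$peak <= 0) return(rep(0, length(t)))
    pmin(e$f(t) / e$peak, 1)
  }
}

#' Combined flux fraction of a GPR rule at a diel time
#'
#' AND nodes take the minimum of their children's fractions (complex
#' limited by its scarcest subunit); OR nodes take the sum (isozymes act in
#' parallel). Sums are not capped inside the tree -- capping at 1 happens
#' only at the bound stage, see [bound_at()].
#'
#' @param rule a `gpr_rule` or rule string.
#' @param frac function `(gene, t) -> fraction`, e.g. from a fitted curve
#'   set; genes without curves contribute fraction 1 (unconstrained, with a
#'   warning).
#' @param t time in hours (scalar or vector).
#' @return numeric combined fraction (may exceed 1 before capping);
#'   `NA` for unmapped (empty) rules.
#' @export
rule_fraction <- function(rule, frac, t) {
  if (is.character(rule)) rule <- parse_gpr(rule)
  evalnode <- function(node) {
    switch(node$type,
      empty = rep(NA_real_, length(t)),
      gene = frac(node$gene, t),
      and = do.call(pmin, lapply(node$children, evalnode)),
      or = Reduce(`+`, lapply(node$children, evalnode)))
  }
  evalnode(unclass(rule))
}

#' Time-varying flux bounds from a combined fraction
#'
#' Upper bound `u = u_max * min(1, v)`; the lower bound is `-u` for
#' reversible reactions and 0 otherwise.
#'
#' @param v combined flux fraction(s) (>= 0, possibly > 1 pre-cap).
#' @param u_max global flux ceiling (mmol/gDW/h).
#' @param reversible logical.
#' @return tibble with columns `lb`, `ub`.
#' @export
bound_at <- function(v, u_max, reversible = FALSE) {
  stopifnot(u_max > 0)
  ub <- u_max * pmin(1, v)
  tibble::tibble(lb = if (reversible) -ub else rep(0, length(ub)), ub = ub)
}

#' Calibrate the global flux ceiling against light availability
#'
#' The ceiling `u_max` is set so that the maximum light uptake allowed by
#' the transcript constraints over the diel cycle equals the light available
#' in the environment: `u_max = light_availability / max_t min(1,
#' v_light(t))`.
#'
#' @param light_rule GPR rule (or string) of the light-harvesting reaction.
#' @param frac fraction function `(gene, t) -> value` (see
#'   [build_fraction_ctx]); typically built from fitted curves.
#' @param light_availability maximum environmental light,
#'   mmol photons/gDW/h (> 0).
#' @param grid_dt diel grid used to locate the peak fraction.
#' @return `u_max` (mmol/gDW/h).
#' @export
calibrate_umax <- function(light_rule, frac, light_availability,
                           grid_dt = 0.05) {
  if (light_availability <= 0) {
    stop("light availability must be positive to calibrate u_max",
         call. = FALSE)
  }
  grid <- seq(0, 24 - grid_dt, by = grid_dt)
  v <- pmin(1, rule_fraction(light_rule, frac, grid))
  peak <- max(v)
  if (!is.finite(peak) || peak <= 0) {
    stop("light reaction has zero peak expression fraction; cannot calibrate",
         call. = FALSE)
  }
  light_availability / peak
}

#' Bound schedule for all GPR-mapped reactions over a diel grid
#'
#' @param model a `metabolic_model`.
#' @param fits a `diel_fits` table.
#' @param u_max global flux ceiling.
#' @param times evaluation times (hours).
#' @return tibble `reaction`, `t`, `lb`, `ub` (reactions without GPR are
#'   omitted: they keep their model-default bounds).
#' @export
bound_schedule <- function(model, fits, u_max, times = seq(0, 23.9, by = 0.1)) {
  frac <- build_fraction_ctx(fits)
  mapped <- which(nzchar(model$reactions$gpr))
  purrr::map_dfr(mapped, function(j) {
    rule <- parse_gpr(model$reactions$gpr[j])
    v <- rule_fraction(rule, frac, times)
    bb <- bound_at(v, u_max, reversible = model$reactions$lb[j] < 0)
    tibble::tibble(reaction = model$reactions$id[j], t = times,
                   lb = bb$lb, ub = bb$ub)
  })
}

## lb/ub vectors for the whole model at one time point (simulator hot path)
bounds_at_time <- function(model, rules, frac, u_max, t) {
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  for (j in seq_along(rules)) {
    rule <- rules[[j]]
    if (is.null(rule)) next
    v <- rule_fraction(rule, frac, t)
    if (is.na(v)) next
    cap <- u_max * min(1, v)
    ub[j] <- min(ub[j], cap)
    if (lb[j] < 0) lb[j] <- max(lb[j], -cap)
  }
  list(lb = lb, ub = ub)
}

#' Zero out transcript curves to simulate complete gene knockouts
#'
#' The named genes' fitted curves are replaced by the zero function; every
#' GPR fraction that references them recomputes accordingly (an AND with a
#' knocked-out gene drops to 0; an OR loses that summand).
#'
#' @param fits a `diel_fits` table.
#' @param gene_ids genes to knock out (must exist in the curve set).
#' @return modified `diel_fits` table.
#' @export
knockout_curves <- function(fits, gene_ids) {
  known <- unique(fits$gene_id)
  unknown <- setdiff(gene_ids, known)
  if (length(unknown)) {
    stop("unknown gene(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  ko <- fits$gene_id %in% gene_ids
  out <- fits
  out$best[ko] <- out$family[ko] == "constant"
  out$weight[ko] <- as.numeric(out$best[ko])
  out$params[ko] <- purrr::map2(out$family[ko], out$params[ko], function(f, p) {
    if (f == "constant") c(c = 0) else p
  })
  attr_names <- c("period", "families")
  for (a in attr_names) attr(out, a) <- attr(fits, a)
  out
}
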