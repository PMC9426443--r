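## Constraint-based model container and format readers (COBRA-JSON, SBML).

#' Construct a constraint-based metabolic model
#'
#' A light container for stoichiometric models: a metabolite table, a
#' reaction table (bounds, gene-protein-reaction rule strings, objective
#' coefficients) and a dense stoichiometric matrix (metabolites x
#' reactions). Sized for reduced/synthetic models of up to a few thousand
#' reactions.
#'
#' @param id model identifier.
#' @param metabolites tibble with columns `id`, and optionally `name`,
#'   `formula`, `compartment`.
#' @param reactions tibble with columns `id`, `lb`, `ub`, and optionally
#'   `name`, `gpr` (GPR string, "" = unmapped), `objective`.
#' @param S stoichiometric matrix, rows in metabolite order, columns in
#'   reaction order.
#' @param genes character vector of gene identifiers (default: collected
#'   from the GPR strings).
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, S, genes = NULL) {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  if (!"gpr" %in% names(reactions)) reactions$gpr <- ""
  if (!"objective" %in% names(reactions)) reactions$objective <- 0
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"formula" %in% names(metabolites)) metabolites$formula <- NA_character_
  S <- as.matrix(S)
  stopifnot(nrow(S) == nrow(metabolites), ncol(S) == nrow(reactions))
  dimnames(S) <- list(metabolites$id, reactions$id)
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(reactions$gpr, gpr_genes_from_string))))
  }
  structure(list(id = id, metabolites = metabolites, reactions = reactions,
                 S = S, genes = genes),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n",
      "  metabolites: ", nrow(x$metabolites),
      "  reactions: ", nrow(x$reactions),
      "  genes: ", length(x$genes), "\n", sep = "")
  invisible(x)
}

rxn_index <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (anyNA(i)) {
    stop("unknown reaction(s): ", paste(id[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  i
}

#' Identify exchange reactions
#'
#' Single-metabolite (boundary) reactions, the conventional shape of
#' exchanges, demands and sinks.
#'
#' @param model a `metabolic_model`.
#' @return logical vector over reactions.
#' @export
is_exchange <- function(model) {
  colSums(model$S != 0) == 1
}

## ---- COBRA JSON ----------------------------------------------------------

#' Read a model in COBRA-JSON format
#'
#' @param path path to a COBRA-style JSON file.
#' @return a `metabolic_model`.
#' @export
read_cobra_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path)
  mets <- purrr::map_dfr(obj$metabolites, function(m) {
    tibble::tibble(id = m$id, name = m$name %||% m$id,
                   formula = m$formula %||% NA_character_,
                   compartment = m$compartment %||% NA_character_)
  })
  rxns <- purrr::map_dfr(obj$reactions, function(r) {
    tibble::tibble(id = r$id, name = r$name %||% r$id,
                   lb = as.numeric(r$lower_bound %||% -1000),
                   ub = as.numeric(r$upper_bound %||% 1000),
                   gpr = r$gene_reaction_rule %||% "",
                   objective = as.numeric(r$objective_coefficient %||% 0))
  })
  S <- matrix(0, nrow(mets), nrow(rxns), dimnames = list(mets$id, rxns$id))
  for (j in seq_along(obj$reactions)) {
    st <- obj$reactions[[j]]$metabolites
    for (m in names(st)) {
      if (!m %in% mets$id) stop("reaction ", rxns$id[j],
                                " references unknown metabolite ", m,
                                call. = FALSE)
      S[m, j] <- as.numeric(st[[m]])
    }
  }
  genes <- purrr::map_chr(obj$genes %||% list(), "id")
  metabolic_model(obj$id %||% basename(path), mets, rxns, S,
                  genes = if (length(genes)) genes else NULL)
}

#' Write a model in COBRA-JSON format
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cobra_json <- function(model, path) {
  mets <- purrr::map(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment %||% "c")
    if (!is.na(m$formula)) out$formula <- m$formula
    out
  })
  rxns <- purrr::map(seq_len(nrow(model$reactions)), function(j) {
    r <- model$reactions[j, ]
    coefs <- model$S[, j]
    coefs <- coefs[coefs != 0]
    list(id = r$id, name = r$name,
         metabolites = as.list(coefs),
         lower_bound = r$lb, upper_bound = r$ub,
         gene_reaction_rule = r$gpr,
         objective_coefficient = r$objective)
  })
  genes <- purrr::map(model$genes, function(g) list(id = g, name = g))
  jsonlite::write_json(list(id = model$id, metabolites = mets,
                            reactions = rxns, genes = genes),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## ---- SBML (level 3 + fbc) ------------------------------------------------

#' Read a model from SBML (core + fbc subset)
#'
#' Minimal SBML reader covering the constructs constraint-based models use:
#' species, reactions with reactant/product stoichiometries, reversibility,
#' flux bounds (fbc bound parameters when present, otherwise the
#' reversibility flag with a default magnitude), and fbc gene-product
#' associations converted to GPR strings.
#'
#' @param path path to an SBML file.
#' @param default_bound magnitude used when no fbc bounds are present.
#' @return a `metabolic_model`.
#' @export
read_sbml <- function(path, default_bound = 1000) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  ## fbc-prefixed elements keep their namespace prefix after stripping the
  ## default namespace, so match by local name and attribute suffix
  ln <- function(name) sprintf("*[local-name()='%s']", name)
  attr1 <- function(node, name) {
    a <- unlist(xml2::xml_attrs(node))
    hit <- grep(paste0("(^|:)", name, "$"), names(a))
    if (length(hit)) unname(a[hit[1]]) else NA_character_
  }
  attrs <- function(nodes, name) {
    vapply(nodes, attr1, character(1), name = name)
  }
  model_node <- xml2::xml_find_first(doc, paste0(".//", ln("model")))
  params <- xml2::xml_find_all(doc, sprintf(".//%s/%s", ln("listOfParameters"),
                                            ln("parameter")))
  pvals <- stats::setNames(as.numeric(attrs(params, "value")),
                           attrs(params, "id"))
  sp <- xml2::xml_find_all(doc, sprintf(".//%s/%s", ln("listOfSpecies"),
                                        ln("species")))
  mets <- tibble::tibble(
    id = attrs(sp, "id"),
    name = dplyr::coalesce(attrs(sp, "name"), attrs(sp, "id")),
    formula = attrs(sp, "chemicalFormula"),
    compartment = attrs(sp, "compartment"))
  boundary <- attrs(sp, "boundaryCondition") %in% "true"
  rx <- xml2::xml_find_all(doc, sprintf(".//%s/%s", ln("listOfReactions"),
                                        ln("reaction")))
  parse_gpa <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      attr1(node, "geneProduct")
    } else if (nm %in% c("and", "or")) {
      kids <- xml2::xml_children(node)
      parts <- vapply(kids, parse_gpa, character(1))
      paste0("(", paste(parts, collapse = paste0(" ", nm, " ")), ")")
    } else {
      ""
    }
  }
  rxns <- purrr::map_dfr(rx, function(r) {
    rev <- !(attr1(r, "reversible") %in% "false")
    lbp <- attr1(r, "lowerFluxBound")
    ubp <- attr1(r, "upperFluxBound")
    lb <- if (!is.na(lbp) && lbp %in% names(pvals)) pvals[[lbp]] else
      if (rev) -default_bound else 0
    ub <- if (!is.na(ubp) && ubp %in% names(pvals)) pvals[[ubp]] else default_bound
    gpa <- xml2::xml_find_first(
      r, sprintf("./%s/*", ln("geneProductAssociation")))
    gpr <- if (inherits(gpa, "xml_missing")) "" else parse_gpa(gpa)
    tibble::tibble(id = attr1(r, "id"),
                   name = dplyr::coalesce(attr1(r, "name"), attr1(r, "id")),
                   lb = lb, ub = ub, gpr = gpr, objective = 0)
  })
  keep <- !boundary
  S <- matrix(0, sum(keep), nrow(rxns),
              dimnames = list(mets$id[keep], rxns$id))
  for (j in seq_along(rx)) {
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(
        rx[[j]], sprintf("./%s/%s", ln(side), ln("speciesReference")))
      if (!length(refs)) next
      sgn <- if (side == "listOfReactants") -1 else 1
      ids <- attrs(refs, "species")
      sto <- as.numeric(attrs(refs, "stoichiometry"))
      sto[is.na(sto)] <- 1
      for (k in seq_along(ids)) {
        if (ids[k] %in% rownames(S)) S[ids[k], j] <- S[ids[k], j] + sgn * sto[k]
      }
    }
  }
  gp <- xml2::xml_find_all(doc, sprintf(".//%s/%s", ln("listOfGeneProducts"),
                                        ln("geneProduct")))
  genes <- attrs(gp, "id")
  metabolic_model(attr1(model_node, "id") %||% basename(path),
                  mets[keep, ], rxns, S,
                  genes = if (length(genes)) genes else NULL)
}

## ---- elemental balance ---------------------------------------------------

parse_formula <- function(f) {
  if (is.na(f) || !nzchar(f)) return(numeric(0))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", f)[[1]]
  parts <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", f))[[1]]
  el <- sub("^([A-Z][a-z]?).*$", "\\1", parts)
  ct <- suppressWarnings(as.numeric(sub("^[A-Z][a-z]?", "", parts)))
  ct[is.na(ct)] <- 1
  tapply(ct, el, sum)
}

#' Check elemental balance of every non-exchange reaction
#'
#' @param model a `metabolic_model` with metabolite formulas.
#' @param tol imbalance tolerance per element.
#' @return tibble with one row per unbalanced internal reaction
#'   (`reaction`, `element`, `imbalance`); zero rows means balanced.
#' @export
check_mass_balance <- function(model, tol = 1e-6) {
  exch <- is_exchange(model)
  forms <- lapply(model$metabolites$formula, parse_formula)
  els <- sort(unique(unlist(lapply(forms, names))))
  E <- matrix(0, length(els), nrow(model$metabolites),
              dimnames = list(els, model$metabolites$id))
  for (i in seq_along(forms)) E[names(forms[[i]]), i] <- forms[[i]]
  imb <- E %*% model$S          # elements x reactions
  out <- tibble::as_tibble(as.table(imb), .name_repair = "minimal")
  names(out) <- c("element", "reaction", "imbalance")
  dplyr::filter(out, abs(.data$imbalance) > tol,
                !.data$reaction %in% model$reactions$id[exch])
}

#' Compute the molecular weight of a formula (g/mol)
#'
#' @param formula chemical formula string, e.g. `"C6H12O6"`.
#' @return numeric weight.
#' @export
formula_weight <- function(formula) {
  aw <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, P = 30.974,
          S = 32.06, Mg = 24.305, Fe = 55.845)
  vapply(formula, function(f) {
    v <- parse_formula(f)
    if (!length(v)) return(0)
    unknown <- setdiff(names(v), names(aw))
    if (length(unknown)) stop("no atomic weight for element(s): ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    sum(v * aw[names(v)])
  }, numeric(1), USE.NAMES = FALSE)
}
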