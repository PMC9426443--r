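## Expression-table IO and synthetic diel transcriptome generation.

## canonical column layout: gene_id, time (hours since light onset), fpkm
normalize_expression_columns <- function(df) {
  nm <- names(df)
  ren <- c(time_h = "time", value = "fpkm", FPKM = "fpkm")
  for (old in names(ren)) {
    if (old %in% nm && !(ren[[old]] %in% nm)) {
      names(df)[names(df) == old] <- ren[[old]]
    }
  }
  need <- c("gene_id", "time", "fpkm")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("expression table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df[, need])
}

#' Read a delimited transcript time-series table
#'
#' Expects columns `gene_id`, `time` (or `time_h`; hours since light onset)
#' and `fpkm` (or `value`). Rows are sorted by time within gene; duplicate
#' (gene, time) rows are averaged with a warning, since replicate-bearing
#' designs are common in diel experiments. Gzip-compressed files are read
#' transparently.
#'
#' @param path file path (TSV or CSV; `.gz` accepted).
#' @param delim field delimiter; `NULL` (default) guesses from the file
#'   extension (`.csv` -> comma, otherwise tab).
#' @return tibble with columns `gene_id`, `time`, `fpkm`.
#' @export
read_expression_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  }
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  df <- normalize_expression_columns(df)
  bad <- which(df$fpkm < 0)
  if (length(bad)) {
    stop("negative FPKM at row ", bad[1], " (gene '", df$gene_id[bad[1]],
         "')", call. = FALSE)
  }
  dups <- dplyr::count(df, .data$gene_id, .data$time)
  if (any(dups$n > 1)) {
    warning("duplicate (gene, time) measurements averaged", call. = FALSE)
    df <- dplyr::summarise(dplyr::group_by(df, .data$gene_id, .data$time),
                           fpkm = mean(.data$fpkm), .groups = "drop")
  }
  dplyr::arrange(df, .data$gene_id, .data$time)
}

#' Write an expression table to a delimited file
#'
#' @param expression data frame with columns `gene_id`, `time`, `fpkm`.
#' @param path output path (`.csv` writes comma-separated, otherwise tab).
#' @return the input, invisibly.
#' @export
write_expression_table <- function(expression, path) {
  df <- normalize_expression_columns(expression)
  delim <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  readr::write_delim(df, path, delim = delim)
  invisible(expression)
}

#' Specification for a synthetic diel transcriptome
#'
#' Describes the study conditions the generator emulates: 2-h sampling over
#' a 24-h light/dark cycle, expression shapes drawn from the eight candidate
#' families, nonnegative FPKM with multiplicative lognormal noise.
#'
#' @param n_genes number of genes to generate.
#' @param shape_mix named numeric vector of proportions over the eight
#'   family names (need not be normalized; must be nonnegative, nonzero sum).
#'   The default mirrors diel transcriptomes of photosynthetic microbes, in
#'   which the large majority of transcripts cycle: 60% cyclic shapes
#'   (one- and two-term cosine, hat), 10% cyclic with an exponential
#'   envelope, 8% light-onset spikes, and 22% non-periodic (constant plus
#'   decays).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   noise (0 = noiseless).
#' @param sampling_times sampling grid in hours (default 0, 2, ..., 24,
#'   thirteen points emulating 2-h diel sampling).
#' @param seed integer seed.
#' @return an object of class `transcriptome_spec`.
#' @export
synthetic_transcriptome_spec <- function(n_genes = 100,
                                         shape_mix = NULL,
                                         noise_cv = 0.05,
                                         sampling_times = seq(0, 24, by = 2),
                                         seed = 1) {
  fams <- expression_families()
  if (is.null(shape_mix)) {
    shape_mix <- c(constant = 0.07, one_term_cosine = 0.30,
                   two_term_cosine = 0.20, hat = 0.12, fixed_decay = 0.05,
                   variable_decay = 0.08, kronecker_delta = 0.08,
                   cosine_multiplicative = 0.10)
  }
  if (length(shape_mix) == 0 || sum(shape_mix) <= 0) {
    stop("shape_mix must contain positive proportions", call. = FALSE)
  }
  if (!all(names(shape_mix) %in% fams)) {
    stop("unknown family in shape_mix: ",
         paste(setdiff(names(shape_mix), fams), collapse = ", "),
         call. = FALSE)
  }
  if (any(shape_mix < 0)) stop("shape_mix proportions must be >= 0", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 shape_mix = shape_mix / sum(shape_mix),
                 noise_cv = noise_cv,
                 sampling_times = sampling_times,
                 seed = as.integer(seed)),
            class = "transcriptome_spec")
}

## draw plausible diel parameters for one gene of a given family
draw_family_params <- function(family, sampling_times) {
  base <- stats::runif(1, 20, 200)       # mesor scale, FPKM
  amp <- base * stats::runif(1, 0.3, 0.9)
  switch(family,
    constant = c(c = base),
    one_term_cosine = c(c = base, A = amp, phi = stats::runif(1, 0, 24)),
    two_term_cosine = {
      ## keep A1 + A2 below the mesor so the planted curve never clips at 0
      a1 <- base * stats::runif(1, 0.3, 0.6)
      c(c = base, A1 = a1, phi1 = stats::runif(1, 0, 24),
        A2 = a1 * stats::runif(1, 0.3, 0.6), phi2 = stats::runif(1, 0, 12))
    },
    hat = {
      on <- stats::runif(1, 0, 24)
      c(c = base, A = amp, t_on = on, t_off = (on + stats::runif(1, 4, 12)) %% 24)
    },
    fixed_decay = c(c = base, A = amp * sample(c(-1, 1), 1)),
    variable_decay = {
      ## keep the decay constant away from the fixed-decay value (4 h), so
      ## the planted family is identifiable from its nested sibling
      tau <- sample(c(stats::runif(1, 1, 2.5), stats::runif(1, 6, 12)), 1)
      c(c = base, A = amp * sample(c(-1, 1), 1), tau = tau)
    },
    kronecker_delta = {
      width <- min(diff(sort(unique(sampling_times %% 24))))
      c(c = base, A = amp * 3, t0 = sample(sampling_times[-length(sampling_times)], 1),
        width = width)
    },
    cosine_multiplicative = {
      ## an envelope rate near zero degenerates to the plain cosine; draw
      ## it large enough to change the envelope at least ~2.5x over a day
      g <- sample(c(-1, 1), 1) * stats::runif(1, 0.04, 0.1)
      c(c = base, A = amp, phi = stats::runif(1, 0, 24), g = g)
    },
    stop("unknown family: ", family, call. = FALSE)
  )
}

#' Generate a synthetic diel transcriptome with ground-truth labels
#'
#' Each gene is drawn from one of the eight parametric families with
#' recorded true family and parameters; multiplicative lognormal noise with
#' the requested coefficient of variation is applied and values are clamped
#' at zero. Deterministic under the spec's seed.
#'
#' @param spec a [synthetic_transcriptome_spec()].
#' @return list with `expression` (tibble `gene_id`, `time`, `fpkm`) and
#'   `truth` (tibble `gene_id`, `family`, `params` list column).
#' @export
#' @examples
#' out <- generate_synthetic_transcriptome(
#'   synthetic_transcriptome_spec(n_genes = 5, noise_cv = 0, seed = 7))
#' dplyr::count(out$truth, family)
generate_synthetic_transcriptome <- function(spec) {
  stopifnot(inherits(spec, "transcriptome_spec"))
  withr::with_seed(spec$seed, {
    fams <- sample(names(spec$shape_mix), spec$n_genes, replace = TRUE,
                   prob = spec$shape_mix)
    ids <- sprintf("g%04d", seq_len(spec$n_genes))
    ## lognormal with unit mean and cv = noise_cv
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    rows <- purrr::map(seq_len(spec$n_genes), function(i) {
      pars <- draw_family_params(fams[i], spec$sampling_times)
      mu <- pmax(eval_family(fams[i], pars, spec$sampling_times), 0)
      noise <- if (spec$noise_cv > 0) {
        exp(stats::rnorm(length(mu), -sdlog^2 / 2, sdlog))
      } else rep(1, length(mu))
      list(expr = tibble::tibble(gene_id = ids[i], time = spec$sampling_times,
                                 fpkm = pmax(mu * noise, 0)),
           truth = tibble::tibble(gene_id = ids[i], family = fams[i],
                                  params = list(pars)))
    })
    list(expression = purrr::map_dfr(rows, "expr"),
         truth = purrr::map_dfr(rows, "truth"))
  })
}

## ---- curve database (JSON) round-trip ------------------------------------

#' Write a fitted-curve database to JSON
#'
#' Serializes a `diel_fits` table (per gene and family: parameters, RSS,
#' AICc, Akaike weight, best flag) losslessly to a JSON file.
#'
#' @param fits a `diel_fits` table from [fit_transcriptome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curve_database <- function(fits, path) {
  recs <- purrr::map(split(fits, fits$gene_id), function(df) {
    list(fits = purrr::map(seq_len(nrow(df)), function(i) {
      list(family = df$family[i],
           params = as.list(df$params[[i]]),
           n_params = df$n_params[i], rss = df$rss[i], aicc = df$aicc[i],
           n_obs = df$n_obs[i], weight = df$weight[i], best = df$best[i])
    }))
  })
  jsonlite::write_json(list(period = attr(fits, "period") %||% 24,
                            genes = recs),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a fitted-curve database from JSON
#'
#' @param path path to a file written by [write_curve_database()].
#' @return a `diel_fits` tibble.
#' @export
read_curve_database <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path)
  genes <- obj$genes
  if (length(genes) == 0) {
    out <- tibble::tibble(gene_id = character(), family = character(),
                          params = list(), n_params = integer(),
                          rss = numeric(), aicc = numeric(),
                          n_obs = integer(), weight = numeric(),
                          best = logical())
  } else {
    out <- purrr::map_dfr(names(genes), function(g) {
      purrr::map_dfr(genes[[g]]$fits, function(f) {
        if (!f$family %in% expression_families()) {
          stop("unknown family tag '", f$family, "' in curve database",
               call. = FALSE)
        }
        tibble::tibble(gene_id = g, family = f$family,
                       params = list(unlist(f$params)),
                       n_params = as.integer(f$n_params),
                       rss = null_na(f$rss), aicc = null_inf(f$aicc),
                       n_obs = as.integer(f$n_obs),
                       weight = null_na(f$weight),
                       best = isTRUE(f$best))
      })
    })
  }
  class(out) <- c("diel_fits", class(out))
  attr(out, "period") <- obj$period %||% 24
  attr(out, "families") <- expression_families()
  out
}

null_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
null_inf <- function(x) {
  if (is.null(x)) return(Inf)
  if (is.character(x)) return(as.numeric(x))  # "Inf" round-trips as string
  as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
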