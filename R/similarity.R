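## Transcript-expression similarity: weight-scaled parameter vectors scored
## by distance x angle, or shape-only integral dissimilarity of the fitted
## curves; Ward clustering and blockwise heatmap assembly.

## fixed slot layout over all families (canonical order); the kronecker
## width context slot is included so layout is stable across datasets
family_slot_names <- function() {
  unlist(lapply(expression_families(), function(f) {
    paste(f, family_defs[[f]]$par_names, sep = ".")
  }))
}

#' Turn a gene's fitted-model ensemble into a fixed-layout vector
#'
#' For every candidate family, the Akaike weight of that family multiplies
#' its fitted parameter values; the per-family blocks are concatenated in
#' canonical family order. The resulting vector encodes both which shapes
#' fit a transcript and with what parameters, so that Euclidean distance and
#' angle between two vectors measure expression-profile similarity.
#' Zero-weight or failed families contribute zero blocks.
#'
#' @param fits a `diel_fits` table.
#' @param genes genes to vectorize (default all).
#' @return numeric matrix, one row per gene, columns named
#'   `family.parameter`.
#' @export
fit_vectors <- function(fits, genes = NULL) {
  slots <- family_slot_names()
  if (is.null(genes)) genes <- unique(fits$gene_id)
  out <- matrix(0, nrow = length(genes), ncol = length(slots),
                dimnames = list(genes, slots))
  for (g in genes) {
    df <- fits[fits$gene_id == g, ]
    if (nrow(df) == 0) stop("gene '", g, "' not in fit table", call. = FALSE)
    for (i in seq_len(nrow(df))) {
      fam <- df$family[i]
      pars <- df$params[[i]]
      w <- df$weight[i]
      if (is.null(pars) || !is.finite(w)) next
      full <- family_defs[[fam]]$par_names
      vals <- stats::setNames(rep(0, length(full)), full)
      vals[names(pars)[names(pars) %in% full]] <- pars[names(pars) %in% full]
      out[g, paste(fam, full, sep = ".")] <- w * vals
    }
  }
  out
}

#' Score a pair of fit vectors (distance x angle)
#'
#' The distance value maps Euclidean distance `d` into \[0, 1\] via
#' `min(1 - log(d)/log(dm), 1)` with `dm` the maximum pairwise distance of
#' the dataset (natural logarithm); it is 1 for negligible distances
#' (`d <= 1`, including d = 0) and 0 at `d = dm`. The score multiplies this
#' by the cosine of the angle between the vectors, so a pair can approach
#' the maximum score of 1 only when aligned in direction and of similar
#' magnitude. If `dm <= 1` the log mapping loses monotonicity, so all
#' distances are rescaled by `exp(1)/dm` first (flagged via attribute).
#'
#' @param u,v numeric vectors (same length, nonzero).
#' @param dm maximum pairwise distance of the dataset (> 0).
#' @return one-row tibble: `d`, `cos_theta`, `distance_value`, `score`.
#' @export
#' @examples
#' score_pair(c(1, 0), c(0.5, 0), dm = 10)
score_pair <- function(u, v, dm) {
  stopifnot(length(u) == length(v), dm > 0)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("zero fit vector: the angle between vectors is undefined",
         call. = FALSE)
  }
  d <- sqrt(sum((u - v)^2))
  rescaled <- dm <= 1
  if (rescaled) {
    d <- d * exp(1) / dm
    dm <- exp(1)
  }
  cos_theta <- min(max(sum(u * v) / (nu * nv), -1), 1)
  dv <- if (d <= 1) 1 else min(1 - log(d) / log(dm), 1)
  dv <- max(dv, 0)
  out <- tibble::tibble(d = d, cos_theta = cos_theta, distance_value = dv,
                        score = cos_theta * dv)
  attr(out, "rescaled") <- rescaled
  out
}

#' Shape-only dissimilarity between two fitted curves
#'
#' Both best-fit curves are sampled on \[0, 24) at interval `dt`, min-max
#' normalized independently (so any positive affine transform of a curve
#' leaves its normalized shape unchanged) and compared by mean absolute
#' difference, giving a symmetric dissimilarity in \[0, 1\]. A flat curve
#' (max == min) has no shape and is mapped to the constant 0.5, flagged via
#' the `degenerate` attribute.
#'
#' @param fits a `diel_fits` table.
#' @param gene1,gene2 gene identifiers.
#' @param dt sampling interval in hours; must divide 24 evenly.
#' @return numeric dissimilarity in \[0, 1\].
#' @export
integral_dissimilarity <- function(fits, gene1, gene2, dt = 0.1) {
  if (abs(24 / dt - round(24 / dt)) > 1e-9) {
    stop("dt must divide 24 evenly", call. = FALSE)
  }
  ts <- seq(0, 24 - dt, by = dt)
  f1 <- curve_evaluator(fits, gene1)(ts)
  f2 <- curve_evaluator(fits, gene2)(ts)
  n1 <- minmax_norm(f1); n2 <- minmax_norm(f2)
  out <- mean(abs(n1$x - n2$x))
  attr(out, "degenerate") <- n1$flat || n2$flat
  out
}

minmax_norm <- function(x) {
  r <- range(x)
  if (diff(r) < 1e-12) list(x = rep(0.5, length(x)), flat = TRUE)
  else list(x = (x - r[1]) / diff(r), flat = FALSE)
}

#' Pairwise similarity or dissimilarity matrix over all fitted genes
#'
#' For `method = "score"`, fit vectors are compared with [score_pair()]
#' (the maximum pairwise distance `dm` is computed once over the dataset);
#' entries are similarity scores with unit diagonal. For
#' `method = "integral"`, entries are shape-only dissimilarities with zero
#' diagonal; this is the method used for clustering.
#'
#' @param fits a `diel_fits` table with at least 2 genes.
#' @param method `"score"` or `"integral"`.
#' @param dt sampling interval for the integral method.
#' @return symmetric matrix of class `similarity_matrix` with attributes
#'   `method` and (for score) `dm`.
#' @export
pairwise_matrix <- function(fits, method = c("integral", "score"), dt = 0.1) {
  method <- match.arg(method)
  genes <- unique(fits$gene_id)
  n <- length(genes)
  if (n < 2) stop("need at least 2 genes", call. = FALSE)
  M <- matrix(0, n, n, dimnames = list(genes, genes))
  if (method == "score") {
    V <- fit_vectors(fits, genes)
    D <- as.matrix(stats::dist(V))
    dm <- max(D)
    if (dm <= 0) dm <- 1   # all-identical dataset; every score is 1
    diag(M) <- 1
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
      s <- score_pair(V[i, ], V[j, ], dm)$score
      M[i, j] <- s; M[j, i] <- s
    }
    attr(M, "dm") <- dm
  } else {
    ts <- seq(0, 24 - dt, by = dt)
    curves <- vapply(genes, function(g) curve_evaluator(fits, g)(ts),
                     numeric(length(ts)))
    normed <- apply(curves, 2, function(x) minmax_norm(x)$x)
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
      v <- mean(abs(normed[, i] - normed[, j]))
      M[i, j] <- v; M[j, i] <- v
    }
  }
  class(M) <- c("similarity_matrix", class(M))
  attr(M, "method") <- method
  M
}

#' Write / read a pairwise matrix as long-form TSV
#'
#' @param mat a `similarity_matrix`.
#' @param path output path.
#' @return `path` invisibly (write); a `similarity_matrix` (read).
#' @export
write_pairwise_tsv <- function(mat, path) {
  df <- tibble::as_tibble(as.table(unclass(mat)), .name_repair = "minimal")
  names(df) <- c("gene_a", "gene_b", "value")
  df$method <- attr(mat, "method")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_pairwise_tsv
#' @export
read_pairwise_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  genes <- unique(df$gene_a)
  M <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  M[cbind(match(df$gene_a, genes), match(df$gene_b, genes))] <- df$value
  class(M) <- c("similarity_matrix", class(M))
  attr(M, "method") <- df$method[1]
  M
}

#' Cluster genes from a pairwise matrix with the Ward criterion
#'
#' Score matrices are converted to dissimilarity as `1 - S`; integral
#' matrices are used as-is. Following the behaviour of the reference
#' hierarchical-clustering implementation when handed a square matrix, the
#' rows of the dissimilarity matrix are treated as feature vectors and
#' clustered by Ward linkage on their Euclidean distances; the dendrogram is
#' truncated at `n_leaves` leaves.
#'
#' @param mat a `similarity_matrix`.
#' @param n_leaves number of leaves to cut the dendrogram into.
#' @return list of class `diel_clustering`: `hclust` (the tree), `leaves`
#'   (tibble `gene_id`, `leaf`), `order` (genes in dendrogram order).
#' @export
cluster_expression <- function(mat, n_leaves) {
  genes <- rownames(mat)
  if (n_leaves > length(genes)) {
    stop("n_leaves exceeds the number of genes", call. = FALSE)
  }
  D <- unclass(mat)
  if (attr(mat, "method") == "score") D <- 1 - D
  hc <- stats::hclust(stats::dist(D), method = "ward.D2")
  cut <- stats::cutree(hc, k = n_leaves)
  structure(list(hclust = hc,
                 leaves = tibble::tibble(gene_id = genes, leaf = unname(cut)),
                 order = genes[hc$order]),
            class = "diel_clustering")
}

#' Assemble a clustered similarity heatmap with a model-weight sidebar
#'
#' Renders the pairwise matrix in dendrogram leaf order as a square heat
#' map. Tile data are assembled blockwise, one leaf at a time, so memory
#' stays bounded in the number of genes per leaf. A per-gene stacked bar of
#' the eight Akaike weights is appended on the right: a gene whose column is
#' dominated by one colour is best fit by that family. Optionally highlights
#' named genes.
#'
#' @param mat a `similarity_matrix`.
#' @param clustering a `diel_clustering` from [cluster_expression()].
#' @param fits the `diel_fits` table (for the weight sidebar).
#' @param out_path output PNG path.
#' @param highlight optional gene ids to mark on the axis.
#' @param width,height device size in inches.
#' @return `out_path`, invisibly.
#' @export
assemble_heatmap <- function(mat, clustering, fits, out_path,
                             highlight = NULL, width = 8, height = 7) {
  ord <- clustering$order
  leaf_of <- stats::setNames(clustering$leaves$leaf, clustering$leaves$gene_id)
  ## blockwise tile assembly: one leaf's rows at a time
  blocks <- purrr::map(split(ord, leaf_of[ord]), function(rows) {
    tibble::tibble(gene_a = rep(rows, each = length(ord)),
                   gene_b = rep(ord, times = length(rows)),
                   value = as.vector(t(unclass(mat)[rows, ord, drop = FALSE])))
  })
  tiles <- dplyr::bind_rows(blocks)
  tiles$gene_a <- factor(tiles$gene_a, levels = ord)
  tiles$gene_b <- factor(tiles$gene_b, levels = ord)
  lab <- if (attr(mat, "method") == "score") "score" else "dissimilarity"
  p_main <- ggplot2::ggplot(tiles, ggplot2::aes(x = .data$gene_b,
                                                y = .data$gene_a,
                                                fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::scale_y_discrete(limits = rev(ord), labels = function(l) {
      ifelse(l %in% highlight, paste0("* ", l), l)
    }) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.title = ggplot2::element_blank(),
                   axis.text.y = if (length(ord) > 40 && is.null(highlight))
                     ggplot2::element_blank() else ggplot2::element_text())
  wts <- fits[fits$gene_id %in% ord, c("gene_id", "family", "weight")]
  wts$gene_id <- factor(wts$gene_id, levels = rev(ord))
  wts$family <- factor(wts$family, levels = expression_families())
  p_side <- ggplot2::ggplot(wts, ggplot2::aes(y = .data$gene_id,
                                              x = .data$weight,
                                              fill = .data$family)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_brewer(palette = "Set2", name = "family") +
    ggplot2::theme_void(base_size = 8)
  if (requireNamespace("patchwork", quietly = TRUE)) {
    p <- patchwork::wrap_plots(p_main, p_side, widths = c(5, 1))
  } else {
    p <- p_main
  }
  ggplot2::ggsave(out_path, p, width = width, height = height, dpi = 120)
  invisible(out_path)
}
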