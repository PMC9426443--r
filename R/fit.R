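## Curve fitting: each transcript series is fitted by all eight candidate
## families, families are compared by small-sample-corrected AIC, and the
## per-gene result is an Akaike-weighted ensemble queryable at any time.

#' Corrected Akaike information criterion from a least-squares fit
#'
#' `AICc = n log(rss/n) + 2k + 2k(k+1)/(n - k - 1)`, the standard
#' least-squares form with the small-sample correction term. When
#' `n_obs <= k_params + 1` the correction denominator is nonpositive and the
#' criterion is undefined; `Inf` is returned as a sentinel so that such fits
#' lose every model comparison. The residual sum of squares is floored at
#' 1e-30 so that exact interpolation (rss = 0, possible on noise-free data)
#' yields a finite criterion in which the parameter penalty still
#' discriminates between families.
#'
#' @param rss residual sum of squares (>= 0).
#' @param n_obs number of observations.
#' @param k_params number of free parameters.
#' @return numeric AICc value (possibly `Inf`).
#' @export
#' @examples
#' aicc(13, 13, 2)  # 13*log(1) + 4 + 12/10 = 5.2
aicc <- function(rss, n_obs, k_params) {
  if (rss < 0) stop("rss must be nonnegative", call. = FALSE)
  if (n_obs - k_params - 1 <= 0) return(Inf)
  rss_eff <- max(rss, 1e-30)
  n_obs * log(rss_eff / n_obs) + 2 * k_params +
    2 * k_params * (k_params + 1) / (n_obs - k_params - 1)
}

#' Akaike weights over a set of candidate-model AICc values
#'
#' With `delta_i = AICc_i - min(AICc)`, the weight of model i is
#' `exp(-delta_i/2)` normalized over the candidate set. Weights are
#' nonnegative, sum to one, and are invariant to adding a constant to all
#' AICc values. Models with infinite AICc (unfittable) receive weight zero.
#'
#' @param aiccs numeric vector of AICc values (at least one finite).
#' @return numeric vector of weights summing to 1, same names as input.
#' @export
#' @examples
#' akaike_weights(c(10, 12))  # approx (0.731, 0.269)
akaike_weights <- function(aiccs) {
  if (!any(is.finite(aiccs))) {
    stop("all candidate models have infinite AICc; series is unfittable",
         call. = FALSE)
  }
  delta <- aiccs - min(aiccs[is.finite(aiccs)])
  w <- ifelse(is.finite(delta), exp(-delta / 2), 0)
  w / sum(w)
}

## ---- per-family least-squares fitting ------------------------------------

## linear LS through QR; returns list(coef, rss)
lin_ls <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  list(coef = fit$coefficients, rss = rss)
}

w1 <- 2 * pi / 24

fit_constant <- function(t, y, ...) {
  cbar <- mean(y)
  list(params = c(c = cbar), rss = sum((y - cbar)^2))
}

fit_one_term_cosine <- function(t, y, ...) {
  ls <- lin_ls(cbind(1, cos(w1 * t), sin(w1 * t)), y)
  a <- ls$coef[2]; b <- ls$coef[3]
  list(params = c(c = unname(ls$coef[1]), A = unname(sqrt(a^2 + b^2)),
                  phi = unname((atan2(b, a) / w1) %% 24)),
       rss = ls$rss)
}

fit_two_term_cosine <- function(t, y, ...) {
  X <- cbind(1, cos(w1 * t), sin(w1 * t), cos(2 * w1 * t), sin(2 * w1 * t))
  ls <- lin_ls(X, y)
  a1 <- ls$coef[2]; b1 <- ls$coef[3]; a2 <- ls$coef[4]; b2 <- ls$coef[5]
  list(params = c(c = unname(ls$coef[1]),
                  A1 = unname(sqrt(a1^2 + b1^2)),
                  phi1 = unname((atan2(b1, a1) / w1) %% 24),
                  A2 = unname(sqrt(a2^2 + b2^2)),
                  phi2 = unname((atan2(b2, a2) / (2 * w1)) %% 12)),
       rss = ls$rss)
}

fit_hat <- function(t, y, ...) {
  tt <- t %% 24
  ord <- order(tt)
  ts <- tt[ord]
  edges <- unique(c((ts[-length(ts)] + ts[-1]) / 2,
                    (ts[length(ts)] + ts[1] + 24) / 2 %% 24))
  best <- NULL
  for (on in edges) for (off in edges) {
    if (isTRUE(all.equal(on, off))) next
    inside <- in_window(tt, on, off)
    if (!any(inside) || all(inside)) next
    ci <- mean(y[!inside]); ai <- mean(y[inside]) - ci
    rss <- sum((y - (ci + ai * inside))^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(params = c(c = ci, A = ai, t_on = on, t_off = off), rss = rss)
    }
  }
  if (is.null(best)) {           # degenerate grid; fall back to constant shape
    cbar <- mean(y)
    best <- list(params = c(c = cbar, A = 0, t_on = 0, t_off = 12),
                 rss = sum((y - cbar)^2))
  }
  best
}

fit_fixed_decay <- function(t, y, ...) {
  ls <- lin_ls(cbind(1, exp(-(t %% 24) / 4)), y)
  list(params = c(c = unname(ls$coef[1]), A = unname(ls$coef[2])), rss = ls$rss)
}

## residual profile over the 1-D nonlinear parameter with inner linear solve
profile_fit <- function(t, y, basis_fn, starts, lower, upper) {
  obj <- function(par) lin_ls(basis_fn(par), y)$rss
  cands <- c(starts,
             stats::optimize(obj, lower = lower, upper = upper)$minimum)
  refined <- vapply(cands, function(s) {
    res <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) list(par = s, value = obj(s)))
    c(res$par, res$value)
  }, numeric(2))
  best <- which.min(refined[2, ])
  par <- refined[1, best]
  list(par = par, ls = lin_ls(basis_fn(par), y))
}

fit_variable_decay <- function(t, y, n_restarts = 100, rng = NULL, ...) {
  starts <- if (n_restarts > 1) stats::runif(n_restarts - 1, 0.1, 24) else numeric(0)
  pf <- profile_fit(t, y, function(tau) cbind(1, exp(-(t %% 24) / tau)),
                    starts, lower = 0.1, upper = 24)
  list(params = c(c = unname(pf$ls$coef[1]), A = unname(pf$ls$coef[2]),
                  tau = unname(pf$par)),
       rss = pf$ls$rss)
}

fit_kronecker_delta <- function(t, y, ...) {
  tt <- t %% 24
  width <- if (length(tt) > 1) min(diff(sort(unique(tt)))) else 2
  best <- NULL
  for (i in seq_along(tt)) {
    inside <- in_window(tt, tt[i], tt[i] + width)
    if (all(inside) || !any(inside)) next
    ci <- mean(y[!inside]); ai <- mean(y[inside]) - ci
    rss <- sum((y - (ci + ai * inside))^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(params = c(c = ci, A = ai, t0 = tt[i], width = width),
                   rss = rss)
    }
  }
  if (is.null(best)) {
    cbar <- mean(y)
    best <- list(params = c(c = cbar, A = 0, t0 = 0, width = width),
                 rss = sum((y - cbar)^2))
  }
  best
}

fit_cosine_multiplicative <- function(t, y, n_restarts = 100, ...) {
  tt <- t %% 24
  basis <- function(g) {
    e <- exp(g * tt)
    cbind(e, cos(w1 * tt) * e, sin(w1 * tt) * e)
  }
  starts <- if (n_restarts > 1) stats::runif(n_restarts - 1, -0.3, 0.3) else numeric(0)
  pf <- profile_fit(t, y, basis, starts, lower = -0.3, upper = 0.3)
  a <- pf$ls$coef[2]; b <- pf$ls$coef[3]
  params <- c(c = unname(pf$ls$coef[1]), A = unname(sqrt(a^2 + b^2)),
              phi = unname((atan2(b, a) / w1) %% 24), g = unname(pf$par))
  ## polish all four parameters jointly from the profiled solution
  resid_fn <- function(p) {
    (p[1] + p[2] * cos(w1 * (tt - p[3]))) * exp(p[4] * tt) - y
  }
  pol <- tryCatch(
    minpack.lm::nls.lm(par = unname(params), fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (!is.null(pol) && sum(pol$fvec^2) < lin_ls(basis(pf$par), y)$rss - 1e-12) {
    p <- pol$par
    params <- c(c = p[1], A = p[2], phi = p[3] %% 24, g = p[4])
    rss <- sum(pol$fvec^2)
  } else {
    rss <- pf$ls$rss
  }
  list(params = params, rss = rss)
}

family_fitters <- list(
  constant = fit_constant,
  one_term_cosine = fit_one_term_cosine,
  two_term_cosine = fit_two_term_cosine,
  hat = fit_hat,
  fixed_decay = fit_fixed_decay,
  variable_decay = fit_variable_decay,
  kronecker_delta = fit_kronecker_delta,
  cosine_multiplicative = fit_cosine_multiplicative
)

## deterministic per-string hash for reproducible per-gene RNG streams,
## independent of gene order in the input
str_seed <- function(s, base_seed, salt = 0L) {
  h <- 5381
  for (k in utf8ToInt(s)) h <- (h * 33 + k) %% 2147483629
  as.integer((h + base_seed * 7919 + salt * 104729) %% 2147483629)
}

#' Fit one expression family to a transcript series
#'
#' Least-squares fit of a single candidate family. Families that are linear
#' in their parameters (possibly after profiling a single nonlinear
#' parameter) are solved in closed form; the nonlinear profile parameter is
#' additionally multi-started from `n_restarts` random initial values and
#' the lowest-AICc solution kept, so the result is deterministic under a
#' fixed seed.
#'
#' @param series data frame with columns `time` and `fpkm` for one gene.
#' @param family family name, one of [expression_families()].
#' @param n_restarts number of randomized restarts for nonlinear families.
#' @param seed integer seed for the restart stream.
#' @return one-row tibble: `family`, `params` (list column of named numeric
#'   vectors), `n_params`, `rss`, `aicc`, `n_obs`.
#' @export
fit_family <- function(series, family, n_restarts = 100, seed = 1) {
  stopifnot(n_restarts >= 1)
  fam <- get_family(family)
  t <- series$time; y <- series$fpkm
  fit <- tryCatch({
    res <- withr::with_seed(
      str_seed(family, seed),
      family_fitters[[family]](t, y, n_restarts = n_restarts)
    )
    res
  }, error = function(e) NULL)
  if (is.null(fit)) {
    return(tibble::tibble(family = family, params = list(NULL),
                          n_params = fam$n_params, rss = NA_real_,
                          aicc = Inf, n_obs = length(y)))
  }
  tibble::tibble(family = family, params = list(fit$params),
                 n_params = fam$n_params, rss = fit$rss,
                 aicc = aicc(fit$rss, length(y), fam$n_params),
                 n_obs = length(y))
}

validate_series <- function(series, gene = "<series>") {
  if (nrow(series) < 4) {
    stop("series for gene '", gene, "' has fewer than 4 time points",
         call. = FALSE)
  }
  if (any(series$fpkm < 0)) {
    stop("negative FPKM in series for gene '", gene, "'", call. = FALSE)
  }
  if (is.unsorted(series$time, strictly = TRUE)) {
    stop("times for gene '", gene, "' must be strictly increasing",
         call. = FALSE)
  }
  invisible(series)
}

fit_gene <- function(series, gene_id, families = expression_families(),
                     n_restarts = 100, seed = 1) {
  validate_series(series, gene_id)
  fits <- purrr::map_dfr(families, function(fam) {
    fit_family(series, fam, n_restarts = n_restarts,
               seed = str_seed(gene_id, seed))
  })
  fits$weight <- akaike_weights(fits$aicc)
  ## best family: lowest AICc; exact ties resolved to fewest parameters,
  ## then canonical family order
  ord <- order(fits$aicc, fits$n_params, match(fits$family, families))
  fits$best <- seq_len(nrow(fits)) == ord[1]
  tibble::tibble(gene_id = gene_id, fits)
}

#' Fit every transcript in an expression table to all candidate families
#'
#' The workhorse of the curve-fitting stage: for each gene, all eight
#' candidate families are fitted, ranked by AICc, and assigned Akaike
#' weights. Results are independent of gene order (each gene gets an RNG
#' stream derived from its identifier) and genes whose series cannot be
#' fitted are returned as flagged rows rather than aborting the batch.
#'
#' @param expression data frame with columns `gene_id`, `time`, `fpkm`.
#' @param families candidate family names (default all eight).
#' @param n_restarts randomized restarts per nonlinear family.
#' @param seed integer seed.
#' @return a `diel_fits` tibble with one row per gene x family:
#'   `gene_id`, `family`, `params`, `n_params`, `rss`, `aicc`, `n_obs`,
#'   `weight`, `best`.
#' @export
#' @examples
#' expr <- generate_synthetic_transcriptome(synthetic_transcriptome_spec(
#'   n_genes = 3, noise_cv = 0, seed = 1))$expression
#' fits <- fit_transcriptome(expr, n_restarts = 3)
#' dplyr::filter(fits, best)
fit_transcriptome <- function(expression, families = expression_families(),
                              n_restarts = 100, seed = 1) {
  stopifnot(is.data.frame(expression))
  if (nrow(expression) == 0) stop("empty expression table", call. = FALSE)
  expression <- normalize_expression_columns(expression)
  genes <- sort(unique(expression$gene_id))
  out <- purrr::map_dfr(genes, function(g) {
    ser <- dplyr::arrange(dplyr::filter(expression, .data$gene_id == g), .data$time)
    tryCatch(
      fit_gene(ser, g, families = families, n_restarts = n_restarts, seed = seed),
      error = function(e) {
        tibble::tibble(gene_id = g, family = families, params = list(NULL),
                       n_params = vapply(families, function(f) get_family(f)$n_params, 1L),
                       rss = NA_real_, aicc = Inf, n_obs = nrow(ser),
                       weight = NA_real_, best = FALSE)
      })
  })
  class(out) <- c("diel_fits", class(out))
  attr(out, "period") <- DIEL_PERIOD
  attr(out, "families") <- families
  out
}

#' Query fitted expression curves at arbitrary diel times
#'
#' Evaluates the best-family curve of each requested gene at the requested
#' times. Times are taken modulo 24 h and raw model values are clamped at
#' zero, so the returned expression is 24-periodic and nonnegative --
#' the properties required for downstream flux bounds.
#'
#' @param fits a `diel_fits` table from [fit_transcriptome()].
#' @param genes gene identifiers to query (default: all fitted genes).
#' @param t numeric vector of times (hours).
#' @return tibble with columns `gene_id`, `time`, `value`.
#' @export
query_curve <- function(fits, genes = NULL, t) {
  best <- dplyr::filter(fits, .data$best)
  if (!is.null(genes)) {
    missing <- setdiff(genes, best$gene_id)
    if (length(missing)) {
      stop("unknown gene(s): ", paste(missing, collapse = ", "), call. = FALSE)
    }
    best <- dplyr::filter(best, .data$gene_id %in% genes)
  }
  purrr::map_dfr(seq_len(nrow(best)), function(i) {
    v <- eval_family(best$family[i], best$params[[i]], t %% DIEL_PERIOD)
    tibble::tibble(gene_id = best$gene_id[i], time = t, value = pmax(v, 0))
  })
}

## fast internal evaluator: returns function(t) for one gene (clamped)
curve_evaluator <- function(fits, gene) {
  row <- dplyr::filter(fits, .data$gene_id == gene, .data$best)
  if (nrow(row) == 0) stop("no fit for gene '", gene, "'", call. = FALSE)
  fam <- row$family[[1]]; par <- row$params[[1]]
  function(t) pmax(eval_family(fam, par, t %% DIEL_PERIOD), 0)
}
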