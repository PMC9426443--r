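test_that("aicc matches its closed form and guards its domain", {
  # 13 log(13/13) + 2*2 + 2*2*3/(13-3) = 5.2
  expect_equal(aicc(13, 13, 2), 5.2)
  expect_equal(aicc(13, 13, 2),
               13 * log(13 / 13) + 4 + 12 / 10)
  expect_identical(aicc(1, 4, 3), Inf)     # n = k + 1
  expect_error(aicc(-1, 10, 2), "nonnegative")
  # strictly increasing in rss at fixed n, k
  expect_gt(aicc(26, 13, 2), aicc(13, 13, 2))
})

test_that("akaike weights follow the exponential rule and normalize", {
  expect_equal(akaike_weights(c(7, 7)), c(0.5, 0.5))
  w <- akaike_weights(c(10, 12))          # delta = (0, 2)
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(w, 4), c(0.7311, 0.2689))
  # invariance to adding a constant; infinite entries get zero weight
  set.seed(4)
  for (i in 1:20) {
    a <- rnorm(8, sd = 5)
    a[sample(8, 2)] <- Inf
    w1 <- akaike_weights(a)
    w2 <- akaike_weights(a + 100)
    expect_equal(sum(w1), 1, tolerance = 1e-12)
    expect_true(all(w1 >= 0 & w1 <= 1))
    expect_equal(w1, w2, tolerance = 1e-9)
    expect_true(all(w1[!is.finite(a)] == 0))
  }
  expect_error(akaike_weights(c(Inf, Inf)), "unfittable")
})

test_that("noise-free data from each family is recovered near-exactly", {
  spec_times <- seq(0, 24, by = 2)
  set.seed(21)
  for (fam in expression_families()) {
    mix <- stats::setNames(1, fam)
    out <- generate_synthetic_transcriptome(synthetic_transcriptome_spec(
      n_genes = 4, shape_mix = mix, noise_cv = 0, seed = 17))
    for (i in seq_len(4)) {
      g <- out$truth$gene_id[i]
      ser <- out$expression[out$expression$gene_id == g,
                            c("time", "fpkm")]
      fit <- fit_family(ser, fam, n_restarts = 5, seed = 2)
      tot <- sum((ser$fpkm - mean(ser$fpkm))^2)
      expect_lte(fit$rss, 1e-6 * max(tot, 1),
                 label = paste(fam, "rss"))
    }
  }
})

test_that("one-term cosine parameters are recovered from noiseless data", {
  ts <- seq(0, 24, by = 2)
  ser <- make_series(ts, 100 + 50 * cos(2 * pi * (ts - 6) / 24))
  fit <- fit_family(ser, "one_term_cosine", n_restarts = 3, seed = 1)
  p <- fit$params[[1]]
  expect_equal(unname(p["c"]), 100, tolerance = 1e-3)
  expect_equal(unname(p["A"]), 50, tolerance = 1e-3)
  expect_equal(unname(p["phi"]), 6, tolerance = 1e-3)
})

test_that("constant family fits the sample mean", {
  ser <- make_series(c(0, 4, 8, 12), c(2, 4, 6, 8))
  fit <- fit_family(ser, "constant", n_restarts = 1)
  expect_equal(unname(fit$params[[1]]["c"]), 5)
  expect_equal(fit$rss, sum((c(2, 4, 6, 8) - 5)^2))
  flat <- make_series(c(0, 4, 8, 12), rep(7, 4))
  expect_equal(fit_family(flat, "constant")$rss, 0)
})

test_that("more restarts can only improve (or tie) the selected AICc", {
  set.seed(8)
  ts <- seq(0, 24, by = 2)
  y <- (80 + 40 * cos(2 * pi * (ts - 3) / 24)) * exp(0.05 * ts)
  ser <- make_series(ts, y * exp(rnorm(13, 0, 0.05)))
  f1 <- fit_family(ser, "cosine_multiplicative", n_restarts = 1, seed = 5)
  f100 <- fit_family(ser, "cosine_multiplicative", n_restarts = 100, seed = 5)
  expect_lte(f100$aicc, f1$aicc + 1e-9)
})

test_that("fit_transcriptome validates input and flags bad genes", {
  expect_error(fit_transcriptome(tibble::tibble(gene_id = character(),
                                                time = numeric(),
                                                fpkm = numeric())),
               "empty")
  # a 3-point series is below the minimum and must be flagged, not fatal
  expr <- dplyr::bind_rows(
    tibble::tibble(gene_id = "ok", time = seq(0, 24, 2),
                   fpkm = 50 + 10 * cos(2 * pi * seq(0, 24, 2) / 24)),
    tibble::tibble(gene_id = "short", time = c(0, 2, 4), fpkm = c(1, 2, 3)))
  fits <- fit_transcriptome(expr, n_restarts = 2, seed = 1)
  expect_true(all(is.infinite(fits$aicc[fits$gene_id == "short"])))
  expect_true(any(fits$best[fits$gene_id == "ok"]))
})

test_that("fit results are independent of gene order", {
  out <- generate_synthetic_transcriptome(
    synthetic_transcriptome_spec(n_genes = 6, noise_cv = 0.05, seed = 12))
  expr <- out$expression
  rev_expr <- dplyr::arrange(expr, dplyr::desc(gene_id), time)
  f1 <- fit_transcriptome(expr, n_restarts = 4, seed = 7)
  f2 <- fit_transcriptome(rev_expr, n_restarts = 4, seed = 7)
  expect_equal(tibble::as_tibble(f1), tibble::as_tibble(f2))
})

test_that("model selection sharpens as noise vanishes", {
  rate_at <- function(cv) {
    out <- generate_synthetic_transcriptome(
      synthetic_transcriptome_spec(n_genes = 40, noise_cv = cv, seed = 31))
    fits <- fit_transcriptome(out$expression, n_restarts = 8, seed = 31)
    cmp <- dplyr::inner_join(glance(fits), out$truth, by = "gene_id")
    mean(cmp$best_family == cmp$family)
  }
  r0 <- rate_at(0)
  r2 <- rate_at(0.02)
  expect_equal(r0, 1)
  expect_gte(r2, 0.85)
})

test_that("query_curve is 24-periodic, nonnegative, and clamps troughs", {
  curves <- tibble::tibble(
    gene_id = c("flat", "deep"),
    family = c("constant", "one_term_cosine"),
    params = list(c(c = 100), c(c = 10, A = 20, phi = 0)))
  fits <- analytic_fits(curves)
  q <- query_curve(fits, "flat", c(0, 5.5, 23))
  expect_true(all(q$value == 100))
  # trough of c=10, A=20 sits at raw -10 -> clamped to 0
  trough <- query_curve(fits, "deep", 12)
  expect_equal(trough$value, 0)
  ts <- runif(20, 0, 24)
  q1 <- query_curve(fits, "deep", ts)
  q2 <- query_curve(fits, "deep", ts + 24)
  expect_equal(q1$value, q2$value, tolerance = 1e-12)
  expect_true(all(q1$value >= 0))
  expect_error(query_curve(fits, "nope", 0), "unknown gene")
})
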