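test_that("expression tables round-trip and validate", {
  tbl <- tidyr::expand_grid(gene_id = c("a", "b", "c"),
                            time = seq(0, 24, by = 2))
  tbl$fpkm <- runif(nrow(tbl), 1, 100)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(tbl, path)
  back <- read_expression_table(path)
  expect_equal(nrow(back), 3 * 13)
  expect_equal(sort(unique(back$gene_id)), c("a", "b", "c"))
  expect_equal(back$fpkm[back$gene_id == "b"],
               tbl$fpkm[tbl$gene_id == "b"])

  neg <- tbl; neg$fpkm[5] <- -1
  path2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(neg, path2)
  expect_error(read_expression_table(path2), "negative FPKM")

  expect_error(read_expression_table(tempfile()), "not found")
})

test_that("duplicate (gene, time) rows are averaged with a warning", {
  tbl <- tibble::tibble(gene_id = c("a", "a", "a", "a", "a"),
                        time = c(0, 0, 2, 4, 6),
                        fpkm = c(10, 20, 5, 7, 9))
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tbl, path)
  expect_warning(back <- read_expression_table(path), "averaged")
  # hand average: (10 + 20) / 2 = 15 at t = 0
  expect_equal(back$fpkm[back$time == 0], 15)
  expect_equal(nrow(back), 4)
})

test_that("alternative column names time_h / value are accepted", {
  tbl <- tibble::tibble(gene_id = "a", time_h = c(0, 2, 4, 6),
                        value = c(1, 2, 3, 4))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tbl, path)
  back <- read_expression_table(path)
  expect_named(back, c("gene_id", "time", "fpkm"))
})

test_that("synthetic transcriptome: zero noise reproduces family curves", {
  spec <- synthetic_transcriptome_spec(n_genes = 30, noise_cv = 0, seed = 1)
  out <- generate_synthetic_transcriptome(spec)
  for (i in seq_len(nrow(out$truth))) {
    g <- out$truth$gene_id[i]
    expected <- pmax(eval_family(out$truth$family[i], out$truth$params[[i]],
                                 spec$sampling_times), 0)
    expect_equal(out$expression$fpkm[out$expression$gene_id == g], expected,
                 tolerance = 1e-12)
  }
})

test_that("synthetic transcriptome is deterministic and respects shape_mix", {
  spec <- synthetic_transcriptome_spec(n_genes = 20, noise_cv = 0.1, seed = 9)
  a <- generate_synthetic_transcriptome(spec)
  b <- generate_synthetic_transcriptome(spec)
  expect_identical(a$expression, b$expression)
  expect_identical(a$truth$family, b$truth$family)

  flat <- generate_synthetic_transcriptome(synthetic_transcriptome_spec(
    n_genes = 10, shape_mix = c(constant = 1), noise_cv = 0, seed = 2))
  vars <- tapply(flat$expression$fpkm, flat$expression$gene_id, var)
  expect_true(all(vars == 0))

  expect_error(synthetic_transcriptome_spec(shape_mix = numeric(0)),
               "positive")
  expect_error(synthetic_transcriptome_spec(shape_mix = c(bogus = 1)),
               "unknown family")
  expect_error(synthetic_transcriptome_spec(noise_cv = -1), "noise_cv")
})

test_that("curve database round-trips losslessly", {
  fits <- small_fit_fixture()$fits
  path <- withr::local_tempfile(fileext = ".json")
  write_curve_database(fits, path)
  back <- read_curve_database(path)
  expect_equal(nrow(back), nrow(fits))
  ord <- order(back$gene_id, back$family)
  ord0 <- order(fits$gene_id, fits$family)
  expect_equal(back$family[ord], fits$family[ord0])
  expect_equal(back$aicc[ord], fits$aicc[ord0], tolerance = 1e-12)
  expect_equal(back$weight[ord], fits$weight[ord0], tolerance = 1e-12)
  expect_equal(back$best[ord], fits$best[ord0])
  for (k in seq_along(ord)) {
    expect_equal(back$params[[ord[k]]], fits$params[[ord0[k]]],
                 tolerance = 1e-12)
  }
})

test_that("curve database rejects unknown family tags, allows empty", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(period = 24, genes = list(
    gX = list(fits = list(list(family = "mystery", params = list(c = 1),
                               n_params = 1, rss = 0, aicc = 0, n_obs = 13,
                               weight = 1, best = TRUE))))),
    path, auto_unbox = TRUE)
  expect_error(read_curve_database(path), "unknown family")

  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(period = 24, genes = list()), path2,
                       auto_unbox = TRUE)
  empty <- read_curve_database(path2)
  expect_equal(nrow(empty), 0)
})
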