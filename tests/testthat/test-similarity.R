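test_that("fit vectors have fixed layout with weight-scaled parameters", {
  curves <- tibble::tibble(gene_id = c("a", "b"),
                           family = c("constant", "constant"),
                           params = list(c(c = 5), c(c = 5)))
  fits <- analytic_fits(curves)
  V <- fit_vectors(fits)
  expect_equal(ncol(V), sum(c(1, 3, 5, 4, 2, 3, 4, 4)))
  expect_equal(unname(V["a", "constant.c"]), 5)   # weight 1 x param 5
  expect_true(all(V["a", colnames(V) != "constant.c"] == 0))
  expect_equal(V["a", ], V["b", ])                # identical ensembles
})

test_that("score pairs follow the distance-value and angle rules", {
  u <- c(3, 0, 0); v <- c(0, 4, 0)
  # self-comparison: d = 0 -> distance value 1, cos 1, score 1
  self <- score_pair(u, u, dm = 50)
  expect_equal(self$score, 1)
  expect_equal(self$distance_value, 1)
  # d == dm -> score 0 regardless of angle
  at_dm <- score_pair(u, v, dm = 5)
  expect_equal(at_dm$d, 5)
  expect_equal(at_dm$distance_value, 0)
  expect_equal(at_dm$score, 0)
  # orthogonal at small distance: cos 0 -> score 0
  w <- c(0, 0.6, 0)
  orth <- score_pair(c(0.8, 0, 0), w, dm = 50)
  expect_equal(orth$cos_theta, 0)
  expect_equal(orth$score, 0)
  # aligned pair at d = sqrt(dm): log d = log(dm)/2 -> distance value 0.5
  dm <- 100
  a <- c(20, 0); b <- c(20 + sqrt(dm), 0)
  half <- score_pair(a, b, dm = dm)
  expect_equal(half$cos_theta, 1)
  expect_equal(half$distance_value, 0.5)
  expect_equal(half$score, 0.5)
  expect_error(score_pair(c(0, 0, 0), u, 10), "zero fit vector")
})

test_that("scores stay in [-1, 1] and are symmetric for random pairs", {
  set.seed(14)
  V <- matrix(rnorm(20 * 6, sd = 4), 20)
  D <- as.matrix(dist(V))
  dm <- max(D)
  for (k in 1:40) {
    ij <- sample(20, 2)
    s1 <- score_pair(V[ij[1], ], V[ij[2], ], dm)
    s2 <- score_pair(V[ij[2], ], V[ij[1], ], dm)
    expect_gte(s1$score, -1); expect_lte(s1$score, 1)
    expect_equal(s1$score, s2$score, tolerance = 1e-12)
  }
  # distance value is nonincreasing in d on [1, dm]
  ds <- seq(1, dm, length.out = 30)
  dv <- sapply(ds, function(d) {
    score_pair(c(1, 0), c(1 + d, 0), dm)$distance_value
  })
  expect_true(all(diff(dv) <= 1e-12))
})

test_that("integral dissimilarity is shape-only, bounded and symmetric", {
  curves <- tibble::tibble(
    gene_id = c("base", "affine", "anti", "flat"),
    family = c("one_term_cosine", "one_term_cosine", "one_term_cosine",
               "constant"),
    params = list(c(c = 100, A = 30, phi = 6),
                  c(c = 207, A = 60, phi = 6),     # 2x + 7 of base
                  c(c = 100, A = 30, phi = 18),    # antiphase complement
                  c(c = 50)))
  fits <- analytic_fits(curves)
  expect_equal(integral_dissimilarity(fits, "base", "base"), 0,
               ignore_attr = TRUE)
  expect_equal(integral_dissimilarity(fits, "base", "affine"), 0,
               tolerance = 1e-9, ignore_attr = TRUE)
  anti <- integral_dissimilarity(fits, "base", "anti")
  expect_gt(anti, 0.4)
  ab <- integral_dissimilarity(fits, "base", "anti")
  ba <- integral_dissimilarity(fits, "anti", "base")
  expect_equal(as.numeric(ab), as.numeric(ba))
  fl <- integral_dissimilarity(fits, "base", "flat")
  expect_true(attr(fl, "degenerate"))
  expect_error(integral_dissimilarity(fits, "base", "anti", dt = 0.7),
               "divide")
})

test_that("a normalized square wave and its complement differ by exactly 1", {
  curves <- tibble::tibble(
    gene_id = c("sq", "sqc"),
    family = c("hat", "hat"),
    params = list(c(c = 0, A = 10, t_on = 0, t_off = 12),
                  c(c = 10, A = -10, t_on = 0, t_off = 12)))
  fits <- analytic_fits(curves)
  # |x - (1 - x)| = 1 on alternating 0/1 plateaus
  expect_equal(as.numeric(integral_dissimilarity(fits, "sq", "sqc")), 1)
})

test_that("pairwise matrices are symmetric with the right diagonal", {
  fits <- small_fit_fixture()$fits
  for (method in c("score", "integral")) {
    M <- pairwise_matrix(fits, method = method, dt = 0.5)
    expect_equal(unclass(M), t(unclass(M)), ignore_attr = TRUE)
    expect_equal(unname(diag(M)),
                 rep(if (method == "score") 1 else 0, nrow(M)))
    if (method == "score") expect_true(all(M >= -1 & M <= 1))
    else expect_true(all(M >= 0 & M <= 1))
  }
  # long-form TSV round-trip
  M <- pairwise_matrix(fits, method = "integral", dt = 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pairwise_tsv(M, path)
  back <- read_pairwise_tsv(path)
  expect_equal(unclass(back), unclass(M), tolerance = 1e-9,
               ignore_attr = TRUE)
})

planted_cluster_fits <- function() {
  set.seed(77)
  rows <- list()
  for (i in 1:20) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene_id = sprintf("cos%02d", i), family = "one_term_cosine",
      params = list(c(c = runif(1, 80, 120), A = runif(1, 30, 60),
                      phi = 6 + runif(1, -0.8, 0.8))))
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene_id = sprintf("dec%02d", i), family = "variable_decay",
      params = list(c(c = runif(1, 10, 30), A = runif(1, 50, 90),
                      tau = runif(1, 2, 3))))
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene_id = sprintf("nightcos%02d", i), family = "one_term_cosine",
      params = list(c(c = runif(1, 80, 120), A = runif(1, 30, 60),
                      phi = 18 + runif(1, -0.8, 0.8))))
  }
  analytic_fits(dplyr::bind_rows(rows))
}

test_that("Ward clustering recovers planted expression groups", {
  fits <- planted_cluster_fits()
  M <- pairwise_matrix(fits, method = "integral", dt = 0.5)
  cl <- cluster_expression(M, n_leaves = 3)
  truth <- sub("[0-9]+$", "", cl$leaves$gene_id)
  purity <- sum(apply(table(truth, cl$leaves$leaf), 2, max)) /
    nrow(cl$leaves)
  expect_gte(purity, 0.95)
  # identical genes merge at height zero before anything else
  two <- analytic_fits(tibble::tibble(
    gene_id = c("t1", "t2", "o1"),
    family = c("constant", "constant", "one_term_cosine"),
    params = list(c(c = 5), c(c = 5), c(c = 50, A = 20, phi = 3))))
  M2 <- pairwise_matrix(two, method = "integral", dt = 0.5)
  cl2 <- cluster_expression(M2, n_leaves = 2)
  expect_equal(cl2$hclust$height[1], 0)
  expect_equal(sort(cl2$leaves$leaf[cl2$leaves$gene_id %in% c("t1", "t2")]),
               rep(cl2$leaves$leaf[1], 2))
  # n_leaves = n_genes puts every gene in its own leaf
  cl3 <- cluster_expression(M2, n_leaves = 3)
  expect_equal(length(unique(cl3$leaves$leaf)), 3)
  expect_error(cluster_expression(M2, n_leaves = 10), "exceeds")
})

test_that("heatmap assembly writes an image file", {
  fits <- small_fit_fixture()$fits
  M <- pairwise_matrix(fits, method = "integral", dt = 0.5)
  cl <- cluster_expression(M, n_leaves = 3)
  path <- withr::local_tempfile(fileext = ".png")
  assemble_heatmap(M, cl, fits, path, highlight = rownames(M)[1])
  expect_true(file.exists(path))
  expect_gt(file.size(path), 1000)
})
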