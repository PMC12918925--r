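test_that("ANOVA F statistic matches hand arithmetic and separation conventions", {
  # groups [1,2,3] and [3,4,5]: grand mean 3, SSB = 6 (df 1), SSW = 4 (df 4)
  x <- matrix(c(1, 2, 3, 3, 4, 5), ncol = 1)
  labs <- rep(c("a", "b"), each = 3)
  sel <- anova_select(x, labs, n_genes = 1)
  expect_equal(sel, 1L)
  # recompute the F value through the implementation by comparing orderings
  x3 <- cbind(g_sep = c(0, 0, 1, 1),        # SSW = 0, SSB > 0 -> F = Inf
              g_mid = c(1, 2, 3, 4),        # ordinary finite F
              g_const = c(2, 2, 2, 2))      # SSB = SSW = 0 -> F = 0
  sel3 <- anova_select(x3, c("a", "a", "b", "b"), n_genes = 3)
  expect_equal(sel3, c(1L, 2L, 3L))         # descending-F order
  expect_error(anova_select(x3, rep("a", 4), 2), "at least 2")
})

test_that("anova_select agrees with stats::aov on random data", {
  set.seed(8)
  x <- matrix(rnorm(40 * 6), 40, 6)
  labs <- sample(c("u", "v", "w"), 40, TRUE)
  f_oracle <- apply(x, 2, function(g)
    summary(aov(g ~ factor(labs)))[[1]]$`F value`[1])
  sel <- anova_select(x, labs, n_genes = 6)
  expect_equal(sel, order(f_oracle, decreasing = TRUE))
})

test_that("standardize centers/scales per gene and reuses training stats", {
  st <- standardize(matrix(c(1, 2, 3), 3, 1))
  expect_equal(unname(st$x[, 1]), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)
  # reapplying stored stats reproduces the fit output
  x <- matrix(rnorm(50), 10, 5)
  st2 <- standardize(x)
  expect_equal(standardize(x, stats = st2$stats)$x, st2$x)
  # constant column: centered to 0, flagged
  st3 <- standardize(cbind(c(1, 1, 1), c(1, 2, 3)))
  expect_equal(unname(st3$x[, 1]), c(0, 0, 0))
  expect_identical(unname(st3$stats$zero_variance), c(TRUE, FALSE))
})

test_that("pca_project is deterministic, consistent between fit and apply, and ranks variance", {
  set.seed(4)
  x <- matrix(rnorm(200), 40, 5)
  p1 <- pca_project(x, n_pcs = 3)
  p2 <- pca_project(x, n_pcs = 3)
  expect_identical(p1$scores, p2$scores)
  # applying the model to training data reproduces fit scores
  expect_equal(pca_project(x, model = p1$model)$scores, p1$scores,
               tolerance = 1e-9)
  expect_true(all(diff(p1$model$explained_variance) <= 1e-9))
  # rank-1 data: PC1 explains everything
  r1 <- outer(rnorm(30), rnorm(4))
  pr <- pca_project(r1, n_pcs = 2)
  expect_gt(pr$model$explained_variance[1] /
              sum(pr$model$explained_variance), 1 - 1e-9)
  # explained variances match eigenvalues of the covariance (oracle)
  ev <- eigen(cov(x), symmetric = TRUE)$values
  expect_equal(p1$model$explained_variance, ev[1:3], tolerance = 1e-9)
  expect_error(pca_project(x, n_pcs = 10), NA)  # clamped with a message
})

test_that("classifier separates constructed blobs and is deterministic", {
  set.seed(5)
  x <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 6), 50, 2))
  y <- rep(c("lo", "hi"), each = 50)
  m <- train_classifier(x, y)
  expect_equal(mean(predict_labels(m, x) == y), 1.0)
  expect_identical(predict_labels(m, x), predict_labels(m, x))
  expect_error(train_classifier(x, rep("one", 100)), "2 classes")
})

test_that("pipeline achieves near-perfect macro F1 on separable types and chance under shuffling", {
  suppressMessages({
    f1s <- vapply(1:2, function(s) {
      bs <- benchmark_suite(50 + s)
      d <- bs$three_type_separable$data$datasets$ref
      cfg <- denoise_config(min_cells_per_type = 50, n_genes = 250,
                            n_pcs = 30, seed = s)
      run_tissue_pipeline(d, cfg)$macro_f1
    }, numeric(1))
    expect_true(all(f1s >= 0.95))
    bs <- benchmark_suite(53)
    d <- bs$three_type_separable$data$datasets$ref
    set.seed(99)
    d$meta$cell_type <- sample(d$meta$cell_type)
    rep_null <- run_tissue_pipeline(d, denoise_config(min_cells_per_type = 50,
                                                      n_genes = 250,
                                                      n_pcs = 30, seed = 1))
    expect_lt(abs(rep_null$macro_f1 - 1 / 3), 0.15)
  })
})

test_that("types below the cell-count threshold are excluded", {
  suppressMessages({
    bs <- benchmark_suite(54)
    d <- bs$three_type_separable$data$datasets$ref
    labs <- meta_column(d, "cell_type")
    keep <- c(which(labs != "gamma"), which(labs == "gamma")[1:99])
    d2 <- subset_cells(d, keep)
    rep <- run_tissue_pipeline(d2, denoise_config(min_cells_per_type = 100,
                                                  n_genes = 250, n_pcs = 30,
                                                  seed = 1))
    expect_identical(rep$excluded_types, "gamma")
    expect_equal(rep$n_types, 2)
  })
})

test_that("no information leaks from test data into fitted statistics", {
  suppressMessages({
    bs <- benchmark_suite(55)
    d <- bs$three_type_separable$data$datasets$ref
    cfg <- denoise_config(min_cells_per_type = 50, n_genes = 250, n_pcs = 30,
                          seed = 2)
    labs <- meta_column(d, "cell_type")
    z <- normalize_matrix(d)$z
    sp <- stratified_split(labs, train_frac = 1 - cfg$test_frac,
                           seed = cfg$seed)
    # fit the chain with the real test set, then with the test rows replaced
    # by unrelated data: every fitted statistic must be identical
    fit1 <- lincell:::fit_predict_chain(z, labs, sp$train, sp$test, cfg)
    z2 <- z
    set.seed(1000)
    z2[sp$test, ] <- z[sample(sp$train, length(sp$test), replace = TRUE), ]
    fit2 <- lincell:::fit_predict_chain(z2, labs, sp$train, sp$test, cfg)
    expect_identical(fit1$selection, fit2$selection)
    expect_identical(fit1$standardization, fit2$standardization)
    expect_identical(fit1$pca$rotation, fit2$pca$rotation)
  })
})

test_that("per-fold macro F1 is bit-reproducible under a fixed seed", {
  suppressMessages({
    bs <- benchmark_suite(56)
    d <- bs$three_type_separable$data$datasets$ref
    cfg <- denoise_config(min_cells_per_type = 50, n_genes = 250, n_pcs = 30,
                          n_folds = 3, seed = 7)
    r1 <- run_tissue_pipeline(d, cfg)
    r2 <- run_tissue_pipeline(d, cfg)
    expect_identical(r1$per_fold_macro_f1, r2$per_fold_macro_f1)
    expect_equal(r1$macro_f1, mean(r1$per_type_f1), tolerance = 1e-9)
  })
})
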