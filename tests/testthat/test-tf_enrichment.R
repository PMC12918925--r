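make_nm_z <- function(z) {
  dimnames(z) <- list(paste0("c", seq_len(nrow(z))),
                      paste0("g", seq_len(ncol(z))))
  structure(list(z = z, gene_ids = colnames(z), cell_ids = rownames(z),
                 meta = NULL), class = "NormalizedMatrix")
}

test_that("PMI with zero pseudocount equals the log frequency ratio", {
  # gene observed in 8/10 TF-high cells vs 40/100 overall -> ln 2
  N <- 100
  ztf <- c(rep(1, 10), rep(-1, 90))           # top decile = first 10 cells
  on <- c(rep(1, 8), rep(-1, 2), rep(1, 32), rep(-1, 58))
  nm <- make_nm_z(cbind(ztf, on))
  pmi <- pmi_score(nm, "g1", "g2", high_q = 0.90, pseudocount = 0)
  expect_equal(pmi, log(2), tolerance = 1e-12)
  # identical frequency in H and overall -> PMI = 0
  on2 <- rep(c(1, -1), 50)
  nm2 <- make_nm_z(cbind(ztf, on2))
  expect_equal(pmi_score(nm2, "g1", "g2", pseudocount = 0), 0,
               tolerance = 1e-12)
  # never observed in H: finite negative with smoothing
  on3 <- c(rep(-1, 10), rep(1, 40), rep(-1, 50))
  nm3 <- make_nm_z(cbind(ztf, on3))
  p3 <- pmi_score(nm3, "g1", "g2", pseudocount = 0.5)
  expect_true(is.finite(p3) && p3 < 0)
  expect_error(pmi_score(nm3, "gX", "g2"), "absent")
})

test_that("PMI with pseudocount 0 matches direct counting on random small matrices", {
  for (seed in 1:20) {
    set.seed(seed)
    z <- matrix(rnorm(60 * 2), 60, 2)
    nm <- make_nm_z(z)
    H <- z[, 1] > quantile(z[, 1], 0.9)
    on <- z[, 2] > 0
    if (sum(on[H]) == 0 || sum(on) == 0) next
    oracle <- log((sum(on & H) / sum(H)) / (sum(on) / length(on)))
    expect_equal(pmi_score(nm, "g1", "g2", pseudocount = 0), oracle,
                 tolerance = 1e-12)
  }
})

test_that("permutation z is invariant to cell order and flags degenerate nulls", {
  set.seed(30)
  z <- matrix(rnorm(400), 200, 2)
  nm <- make_nm_z(z)
  r1 <- null_z(nm, "g1", "g2", n_perm = 200, seed = 3)
  perm <- sample(200)
  nm_p <- make_nm_z(z[perm, ])
  nm_p$cell_ids <- nm$cell_ids[perm]
  rownames(nm_p$z) <- nm_p$cell_ids
  r2 <- null_z(nm_p, "g1", "g2", n_perm = 200, seed = 3)
  expect_equal(r1$z, r2$z, tolerance = 1e-12)
  # constant gene (always on): null s.d. 0 -> flagged, p = 1
  z3 <- cbind(rnorm(200), rep(5, 200))
  r3 <- null_z(make_nm_z(z3), "g1", "g2", n_perm = 100, seed = 1)
  expect_true(r3$degenerate)
  expect_equal(r3$p, 1)
  expect_error(null_z(nm, "g1", "g2", n_perm = 10), ">= 100")
})

test_that("BH selection in the screen matches the hand example and the brute-force oracle", {
  # p = [0.001, 0.01, 0.02, 0.8] at alpha 0.05 -> 3 significant
  expect_identical(bh_bruteforce(c(0.001, 0.01, 0.02, 0.8), 0.05),
                   c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(p.adjust(c(0.001, 0.01, 0.02, 0.8), "BH") <= 0.05,
                   c(TRUE, TRUE, TRUE, FALSE))
  # fuzz: step-up oracle vs p.adjust route used by the screen
  set.seed(77)
  for (i in 1:1000) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(1:3, 1)
    alpha <- runif(1, 0.01, 0.2)
    expect_identical(p.adjust(p, "BH") <= alpha, bh_bruteforce(p, alpha))
  }
})

test_that("type-I error is calibrated under synthetic independence", {
  suppressMessages({
    cfg <- synthetic_config(n_genes = 250,
                            cell_types = data.frame(name = "cell",
                                                    n_cells = 500),
                            dropout_rate = 0.05, seed = 71)
    nm <- normalize_matrix(generate_synthetic(cfg)$datasets$ref)
    tab <- enrichment_screen(nm, paste0("g", 1:10), paste0("g", 11:30),
                             alpha = 0.05, n_perm = 200, seed = 2)
    expect_equal(nrow(tab), 200)
    expect_lt(abs(mean(tab$p < 0.05) - 0.05), 0.04)
    expect_lte(mean(tab$q <= 0.05), 0.07)
  })
})

test_that("planted TF-target edges are recovered with controlled FDR", {
  suppressMessages({
    stats <- lapply(1:3, function(s) {
      d <- benchmark_suite(72 + s)$tf_screen$data
      nm <- normalize_matrix(d$datasets$ref)
      ref <- do.call(rbind, lapply(d$truth$tf_edges, function(e)
        data.frame(tf = paste0("g", e$tf), gene = paste0("g", e$targets))))
      tab <- enrichment_screen(nm, paste0("g", 1:10), paste0("g", 11:30),
                               alpha = 0.05, reference = ref, n_perm = 200,
                               seed = s)
      truth_keys <- paste(ref$tf, ref$gene)
      keys <- paste(tab$tf, tab$gene)
      sig <- tab$significant
      # validation summary: significant calls enriched over background
      expect_gt(attr(tab, "validated_rate_significant"),
                attr(tab, "validated_rate_background"))
      c(power = mean(truth_keys %in% keys[sig]),
        fdr = if (any(sig)) mean(!(keys[sig] %in% truth_keys)) else 0)
    })
    stats <- do.call(rbind, stats)
    expect_gte(mean(stats[, "power"]), 0.7)
    expect_lte(mean(stats[, "fdr"]), 0.10)           # 2 * alpha, seed-averaged
  })
})

test_that("a strongly coupled TF-target pair scores z > 3 in at least 90% of seeds", {
  suppressMessages({
    zs <- vapply(1:10, function(s) {
      cfg <- synthetic_config(
        n_genes = 300, cell_types = data.frame(name = "cell", n_cells = 500),
        dropout_rate = 0.05,
        tf_edges = list(list(tf = 1, targets = 2, coupling = 2.5)),
        seed = 900 + s)
      nm <- normalize_matrix(generate_synthetic(cfg)$datasets$ref)
      null_z(nm, "g1", "g2", n_perm = 200, seed = s)$z
    }, numeric(1))
    expect_gte(mean(zs > 3), 0.9)
  })
})

test_that("screen edge cases: all p near 1 yields nothing significant", {
  set.seed(41)
  z <- matrix(rnorm(300 * 4), 300, 4)
  nm <- make_nm_z(z)
  tab <- enrichment_screen(nm, c("g1", "g2"), c("g3", "g4"), alpha = 1e-6,
                           n_perm = 100, seed = 1)
  expect_false(any(tab$significant))
  expect_error(enrichment_screen(nm, character(0), "g3"), "empty")
})
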