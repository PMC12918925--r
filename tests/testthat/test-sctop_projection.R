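make_nm <- function(z, gene_ids = NULL, cell_ids = NULL) {
  gene_ids <- gene_ids %||% paste0("g", seq_len(ncol(z)))
  cell_ids <- cell_ids %||% paste0("c", seq_len(nrow(z)))
  dimnames(z) <- list(cell_ids, gene_ids)
  structure(list(z = z, gene_ids = gene_ids, cell_ids = cell_ids,
                 meta = NULL),
            class = "NormalizedMatrix")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

find_omap_public <- function(omaps, from, to) {
  for (om in omaps) {
    if (om$source_species == from && om$target_species == to) return(om)
  }
  stop("not found")
}

make_basis <- function(B, labels, gene_ids = NULL) {
  gene_ids <- gene_ids %||% paste0("g", seq_len(nrow(B)))
  structure(list(B = B, type_labels = labels, gene_ids = gene_ids,
                 source_tag = ""), class = "ReferenceBasis")
}

test_that("build_basis averages normalized rows per label", {
  z <- matrix(c(1, 0, 1,
                0, 1, 1,
                2, 2, 0), 3, 3, byrow = TRUE)
  nm <- make_nm(z)
  b <- build_basis(nm, labels = c("A", "A", "B"))
  expect_equal(unname(b$B[, "A"]), c(0.5, 0.5, 1))
  expect_equal(unname(b$B[, "B"]), c(2, 2, 0))
  # identical rows, same label: the column is that row
  b2 <- build_basis(make_nm(z[c(3, 3), ]), labels = c("B", "B"))
  expect_equal(unname(b2$B[, 1]), c(2, 2, 0))
})

test_that("build_basis drops under-sized labels with a warning, errors when none remain", {
  z <- matrix(rnorm(12), 4, 3)
  nm <- make_nm(z)
  expect_warning(b <- build_basis(nm, labels = c("A", "A", "B", "C"),
                                  min_cells = 2), "C")
  expect_identical(b$type_labels, "A")
  expect_error(suppressWarnings(
    build_basis(nm, labels = letters[1:4], min_cells = 2)), "no labels")
})

test_that("projection reproduces orthogonal identities", {
  B <- diag(3)
  basis <- make_basis(B, c("t1", "t2", "t3"))
  pr <- project(basis, make_nm(matrix(c(0, 1, 0), 1)))
  expect_equal(unname(pr$coefficients[1, ]), c(0, 1, 0), tolerance = 1e-12)
  expect_identical(pr$predicted_label, "t2")
  # vector orthogonal to every column -> zero coefficients, zero margin
  B2 <- matrix(c(1, 0, 0, 0, 1, 0), 3, 2)
  pr2 <- project(make_basis(B2, c("a", "b")),
                 make_nm(matrix(c(0, 0, 5), 1)))
  expect_equal(unname(pr2$coefficients[1, ]), c(0, 0), tolerance = 1e-12)
  expect_equal(pr2$margin, 0, tolerance = 1e-12)
})

test_that("projection solves the hand-worked non-orthogonal system", {
  # B = [[1,0],[1,1],[0,1]], x = [1,1,0]: B'B = [[2,1],[1,2]], B'x = [2,1]
  # => a = [1, 0]
  B <- matrix(c(1, 1, 0, 0, 1, 1), 3, 2)
  pr <- project(make_basis(B, c("t1", "t2")),
                make_nm(matrix(c(1, 1, 0), 1)))
  expect_equal(unname(pr$coefficients[1, ]), c(1, 0), tolerance = 1e-12)
  expect_identical(pr$predicted_label, "t1")
})

test_that("coefficients equal the generic least-squares solution on random instances", {
  for (i in 1:200) {
    set.seed(i)
    G <- sample(3:8, 1); K <- sample(2:3, 1)
    B <- matrix(rnorm(G * K), G, K)
    x <- rnorm(G)
    a_oracle <- qr.coef(qr(B), x)          # independent least-squares route
    pr <- project(make_basis(B, paste0("t", 1:K)),
                  make_nm(matrix(x, 1)))
    expect_equal(unname(pr$coefficients[1, ]), unname(a_oracle),
                 tolerance = 1e-10)
  }
})

test_that("project is idempotent on well-conditioned basis columns", {
  set.seed(42)
  B <- matrix(rnorm(30), 10, 3)
  basis <- make_basis(B, c("a", "b", "c"))
  pr <- project(basis, make_nm(t(B)))
  expect_equal(unname(pr$coefficients), diag(3), tolerance = 1e-9)
})

test_that("gene-axis rescaling changes non-orthogonal coefficients (counterexample)", {
  # a shared invertible diagonal rescaling preserves coefficients only for
  # orthogonal columns; with non-orthogonal columns it must not in general
  B <- matrix(c(1, 1, 0, 0, 1, 1), 3, 2)
  x <- c(1, 0.5, 2)
  D <- diag(c(3, 1, 0.2))
  a1 <- project(make_basis(B, c("a", "b")), make_nm(matrix(x, 1)))$coefficients
  a2 <- project(make_basis(D %*% B, c("a", "b")),
                make_nm(matrix(as.numeric(D %*% x), 1)))$coefficients
  expect_gt(max(abs(a1 - a2)), 1e-3)
})

test_that("project guards against singular Gram matrices and missing genes", {
  B <- cbind(c(1, 1, 0), c(2, 2, 0))     # collinear columns
  expect_error(project(make_basis(B, c("a", "b")),
                       make_nm(matrix(rnorm(3), 1))), "ill-conditioned")
  basis <- make_basis(diag(3), c("a", "b", "c"), gene_ids = c("g1", "g2", "gX"))
  expect_error(project(basis, make_nm(matrix(rnorm(3), 1))), "absent")
})

test_that("self-transfer on separable synthetic types is perfect and labels outside the basis are excluded", {
  suppressMessages({
    bs <- benchmark_suite(11)
    d <- bs$three_type_separable$data$datasets$ref
    res <- classify_transfer(d, d)
    expect_equal(res$macro_f1, 1.0)
    expect_equal(res$n_excluded, 0)
    # remove one label from the source: those target cells are excluded
    keep <- meta_column(d, "cell_type") != "gamma"
    res2 <- classify_transfer(subset_cells(d, keep), d)
    expect_equal(res2$n_excluded, sum(!keep))
    expect_setequal(res2$shared_labels, c("alpha", "beta"))
  })
})

test_that("two species at divergence 0 transfer as well as self-transfer", {
  suppressMessages({
    cfg <- synthetic_config(
      n_genes = 300,
      cell_types = data.frame(name = c("alpha", "beta", "gamma"),
                              n_cells = c(80, 80, 80)),
      species = data.frame(name = c("ref", "twin"), divergence = c(0, 0)),
      program_strength = 2.5, seed = 21)
    sim <- generate_synthetic(cfg)
    om <- find_omap_public(sim$omaps, "twin", "ref")
    cross <- classify_transfer(sim$datasets$ref, sim$datasets$twin, omap = om)
    self <- classify_transfer(sim$datasets$ref, sim$datasets$ref)
    expect_lt(abs(cross$macro_f1 - self$macro_f1), 0.05)
  })
})
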