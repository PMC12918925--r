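#' Configuration for the denoising classification pipeline
#'
#' Defaults follow the atlas-scale protocol: keep cell types with at least
#' 100 cells, hold out 20 percent, select the 20000 genes varying most across
#' cell types by one-way ANOVA, standardize gene-wise on training statistics,
#' project onto the 220 most variable principal components, and evaluate a
#' ridge-regularized multinomial logistic classifier with five-fold
#' cross-validation. For desk-scale inputs \code{n_genes}/\code{n_pcs} are
#' clamped to the available dimensions (with a message).
#'
#' @param min_cells_per_type,test_frac,n_genes,n_pcs,n_folds,seed see above.
#' @param lambda ridge penalty of the logistic classifier (fixed, not tuned).
#' @param per_cell_standardize standardize rows instead of columns (the
#'   literal per-cell reading; column-wise is the default because it is the
#'   variant that makes "most variable components" meaningful).
#' @return list of class \code{DenoiseConfig}.
#' @export
denoise_config <- function(min_cells_per_type = 100, test_frac = 0.2,
                           n_genes = 20000, n_pcs = 220, n_folds = 5,
                           seed = 0, lambda = 1e-2,
                           per_cell_standardize = FALSE) {
  stopifnot(test_frac > 0, test_frac < 1, n_pcs <= n_genes, n_folds >= 2,
            lambda > 0)
  structure(list(min_cells_per_type = min_cells_per_type,
                 test_frac = test_frac, n_genes = n_genes, n_pcs = n_pcs,
                 n_folds = n_folds, seed = seed, lambda = lambda,
                 per_cell_standardize = per_cell_standardize),
            class = "DenoiseConfig")
}

#' ANOVA-based gene selection
#'
#' One-way ANOVA F statistic per gene across label groups,
#' F = (SSB/(k-1)) / (SSW/(n-k)); returns the indices of the \code{n_genes}
#' largest in descending-F order. Conventions: SSW = 0 with SSB > 0 gives
#' F = +Inf (perfect separation, ranked first); SSB = SSW = 0 (constant gene)
#' gives F = 0.
#'
#' @param nm \code{NormalizedMatrix} or plain numeric matrix (cells x genes).
#' @param labels per-cell character labels, at least 2 groups of >= 2 cells.
#' @param n_genes number of genes to keep (clamped to available).
#' @return integer vector of column indices, descending F.
#' @export
anova_select <- function(nm, labels, n_genes) {
  x <- if (inherits(nm, "NormalizedMatrix")) nm$z else as.matrix(nm)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(x))
  groups <- sort(unique(labels))
  k <- length(groups)
  if (k < 2) stop("ANOVA needs at least 2 label groups")
  n <- nrow(x)
  gsize <- as.numeric(table(labels)[groups])
  gm <- rowsum(x, group = labels) / gsize          # k x genes group means
  grand <- colMeans(x)
  ssb <- colSums(gsize * (gm - rep(grand, each = k))^2)
  tot <- colSums(x^2) - n * grand^2
  ssw <- pmax(tot - ssb, 0)
  f <- rep(0, ncol(x))
  pos_w <- ssw > 1e-12
  f[pos_w] <- (ssb[pos_w] / (k - 1)) / (ssw[pos_w] / (n - k))
  f[!pos_w & ssb > 1e-12] <- Inf
  n_keep <- min(n_genes, ncol(x))
  if (n_keep < n_genes) message("anova_select: clamping n_genes to ", n_keep)
  order(f, decreasing = TRUE)[seq_len(n_keep)]
}

#' Gene-wise standardization with reusable training statistics
#'
#' Centers and scales each column by its (population) mean and s.d.;
#' zero-variance columns are centered and scaled by 1, and flagged. When
#' \code{stats} is supplied (from a previous fit) it is applied as-is —
#' the mechanism that keeps test data out of every fitted statistic.
#'
#' @param x numeric matrix (cells x genes).
#' @param stats \code{NULL} to fit, or the \code{stats} element of a previous
#'   result to apply.
#' @return list(x = standardized matrix, stats = list(means, sds,
#'   zero_variance)).
#' @export
standardize <- function(x, stats = NULL) {
  x <- as.matrix(x)
  if (is.null(stats)) {
    means <- colMeans(x)
    sds <- sqrt(colMeans(sweep(x, 2, means)^2))  # population s.d.
    zv <- sds < 1e-12
    sds[zv] <- 1
    stats <- list(means = means, sds = sds, zero_variance = zv)
  } else {
    if (length(stats$means) != ncol(x)) stop("stats dimensions do not match x")
  }
  out <- sweep(sweep(x, 2, stats$means), 2, stats$sds, "/")
  list(x = out, stats = stats)
}

#' Fit or apply a PCA projection
#'
#' Fitting: principal axes of the (column-centered) input by descending
#' explained variance, computed by SVD, with a deterministic sign convention
#' (the largest-magnitude loading of each axis is positive). Applying: rows
#' of new data are centered with the stored means and projected onto the
#' stored axes — fitted axes never see test data.
#'
#' @param x numeric matrix (cells x features).
#' @param n_pcs number of components (clamped to \code{min(rows - 1, cols)}
#'   when fitting, with a message).
#' @param model \code{NULL} to fit, or a previously fitted model to apply.
#' @return list(scores = cells x n_pcs matrix, model = list(center, rotation,
#'   explained_variance)).
#' @export
pca_project <- function(x, n_pcs = NULL, model = NULL) {
  x <- as.matrix(x)
  if (is.null(model)) {
    max_pcs <- min(nrow(x) - 1L, ncol(x))
    if (is.null(n_pcs)) n_pcs <- max_pcs
    if (n_pcs > max_pcs) {
      message("pca_project: clamping n_pcs to ", max_pcs)
      n_pcs <- max_pcs
    }
    if (n_pcs < 1) stop("n_pcs must be >= 1")
    center <- colMeans(x)
    xc <- sweep(x, 2, center)
    sv <- svd(xc, nu = 0, nv = n_pcs)
    rot <- sv$v
    for (j in seq_len(ncol(rot))) {          # deterministic sign convention
      i <- which.max(abs(rot[, j]))
      if (rot[i, j] < 0) rot[, j] <- -rot[, j]
    }
    model <- list(center = center, rotation = rot,
                  explained_variance = (sv$d[seq_len(n_pcs)]^2) / (nrow(x) - 1))
    scores <- xc %*% rot
  } else {
    if (length(model$center) != ncol(x)) stop("model dimensions do not match x")
    scores <- sweep(x, 2, model$center) %*% model$rotation
  }
  list(scores = scores, model = model)
}

#' Train a ridge-penalized multinomial logistic classifier
#'
#' A thin deterministic wrapper around \pkg{glmnet} at a single fixed
#' penalty. The penalty is a documented default, not tuned per dataset.
#'
#' @param scores numeric matrix (cells x features, >= 2 features).
#' @param labels per-cell labels, >= 2 classes.
#' @param lambda ridge penalty.
#' @param weights optional per-observation weights.
#' @return object of class \code{lincell_classifier} with a
#'   \code{predict_labels} method.
#' @export
train_classifier <- function(scores, labels, lambda = 1e-2, weights = NULL) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  fam <- if (length(classes) == 2) "binomial" else "multinomial"
  fit <- glmnet::glmnet(scores, factor(labels, levels = classes),
                        family = fam, alpha = 0,
                        lambda = c(10 * lambda, lambda),
                        weights = weights, standardize = FALSE)
  structure(list(fit = fit, lambda = lambda, classes = classes),
            class = "lincell_classifier")
}

#' Predict class labels from a trained classifier
#' @param model \code{lincell_classifier}.
#' @param scores feature matrix.
#' @return character vector of labels.
#' @export
predict_labels <- function(model, scores) {
  as.character(stats::predict(model$fit, newx = as.matrix(scores),
                              s = model$lambda, type = "class")[, 1])
}

#' Stratified fold assignment
#' @param labels class labels
#' @param n_folds number of folds
#' @param seed RNG seed
#' @return integer fold id per observation
#' @export
stratified_folds <- function(labels, n_folds, seed = 0) {
  set.seed(seed)
  labels <- as.character(labels)
  fold <- integer(length(labels))
  for (L in sort(unique(labels))) {
    idx <- sample(which(labels == L))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# Fit the full denoising chain on training cells and predict on test cells.
# Selection, standardization and PCA are all fitted on training data only.
fit_predict_chain <- function(z, labels, train, test, cfg) {
  sel <- anova_select(z[train, , drop = FALSE], labels[train], cfg$n_genes)
  ztr <- z[train, sel, drop = FALSE]
  zte <- z[test, sel, drop = FALSE]
  if (cfg$per_cell_standardize) {
    ztr <- t(scale(t(ztr))); zte <- t(scale(t(zte)))
    ztr[is.na(ztr)] <- 0; zte[is.na(zte)] <- 0
    st <- list(stats = NULL)
  } else {
    st <- standardize(ztr)
    ztr <- st$x
    zte <- standardize(zte, stats = st$stats)$x
  }
  pc <- pca_project(ztr, n_pcs = cfg$n_pcs)
  str_scores <- pc$scores
  ste_scores <- pca_project(zte, model = pc$model)$scores
  model <- train_classifier(str_scores, labels[train], lambda = cfg$lambda)
  list(pred = predict_labels(model, ste_scores),
       selection = sel, standardization = st$stats, pca = pc$model,
       model = model)
}

#' Run the denoising classification pipeline on one tissue
#'
#' Filters cell types below \code{min_cells_per_type}; splits cells into
#' stratified train/test sets; normalizes each cell to itself; on training
#' cells only, selects genes by ANOVA, fits gene-wise standardization and the
#' PCA projection; trains the logistic classifier; and reports held-out macro
#' F1 plus a five-fold cross-validated macro F1 in which the entire chain is
#' refit inside each fold.
#'
#' @param em \code{\link{expression_matrix}} with \code{meta$cell_type}.
#' @param cfg \code{\link{denoise_config}}.
#' @return object of class \code{ClassifierReport}: \code{per_type_f1},
#'   \code{macro_f1} (held-out test), \code{per_fold_macro_f1},
#'   \code{cv_macro_f1} (their mean), \code{n_cells}, \code{n_types},
#'   \code{excluded_types}.
#' @export
run_tissue_pipeline <- function(em, cfg = denoise_config()) {
  labels <- meta_column(em, "cell_type")
  tab <- table(labels)
  keep_types <- names(tab)[tab >= cfg$min_cells_per_type]
  excluded <- setdiff(names(tab), keep_types)
  if (length(excluded) > 0) {
    message("excluding ", length(excluded), " cell types below ",
            cfg$min_cells_per_type, " cells: ",
            paste(excluded, collapse = ", "))
  }
  if (length(keep_types) < 2) stop("fewer than 2 cell types pass the filter")
  keep <- labels %in% keep_types & rowSums(em$counts) > 0
  em <- subset_cells(em, keep)
  labels <- labels[keep]
  z <- normalize_matrix(em)$z
  sp <- stratified_split(labels, train_frac = 1 - cfg$test_frac,
                         seed = cfg$seed)
  res <- fit_predict_chain(z, labels, sp$train, sp$test, cfg)
  pt <- per_class_f1(labels[sp$test], res$pred, labels = keep_types)
  fold <- stratified_folds(labels, cfg$n_folds, seed = cfg$seed + 1L)
  per_fold <- vapply(seq_len(cfg$n_folds), function(f) {
    te <- which(fold == f); tr <- which(fold != f)
    pred <- fit_predict_chain(z, labels, tr, te, cfg)$pred
    macro_f1(labels[te], pred, labels = keep_types)
  }, numeric(1))
  structure(list(per_type_f1 = pt, macro_f1 = mean(pt),
                 per_fold_macro_f1 = per_fold, cv_macro_f1 = mean(per_fold),
                 n_cells = length(labels), n_types = length(keep_types),
                 excluded_types = excluded,
                 fitted = res[c("selection", "standardization", "pca")]),
            class = "ClassifierReport")
}

#' @export
print.ClassifierReport <- function(x, ...) {
  cat("ClassifierReport:", x$n_cells, "cells,", x$n_types, "types\n")
  cat("  held-out macro F1:", round(x$macro_f1, 4), "\n")
  cat("  CV macro F1:", round(x$cv_macro_f1, 4), " (folds: ",
      paste(round(x$per_fold_macro_f1, 3), collapse = ", "), ")\n", sep = "")
  invisible(x)
}
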