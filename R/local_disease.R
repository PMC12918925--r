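#' Configuration for the cluster-local disease pipeline
#'
#' Cells are clustered (without any knowledge of health status) by Leiden
#' community detection on a k-nearest-neighbor graph in PCA space, aiming for
#' roughly \code{target_clusters} transcriptionally coherent regions; a
#' separate infected/uninfected logistic classifier is then trained inside
#' each cluster.
#'
#' @param target_clusters desired number of clusters (the resolution grid is
#'   scanned and the resolution whose cluster count is closest wins; ties go
#'   to the lower resolution).
#' @param knn_k neighbors for the cell-cell graph.
#' @param resolution_grid increasing positive resolutions to scan.
#' @param n_pcs PCA dimensionality for the embedding.
#' @param seed RNG seed (clustering and splits).
#' @param min_cluster_size clusters below this get a constant
#'   majority-class model instead of a fitted classifier.
#' @return list of class \code{LocalDiseaseConfig}.
#' @export
local_disease_config <- function(target_clusters = 15, knn_k = 15,
                                 resolution_grid = c(0.05, 0.1, 0.2, 0.4, 0.8,
                                                     1.2, 1.6, 2.0),
                                 n_pcs = 50, seed = 0, min_cluster_size = 10) {
  stopifnot(target_clusters >= 2, length(resolution_grid) > 0,
            !is.unsorted(resolution_grid, strictly = TRUE))
  structure(list(target_clusters = target_clusters, knn_k = knn_k,
                 resolution_grid = resolution_grid, n_pcs = n_pcs,
                 seed = seed, min_cluster_size = min_cluster_size),
            class = "LocalDiseaseConfig")
}

# Symmetric ("union") kNN graph on Euclidean distances.
knn_graph <- function(x, k) {
  n <- nrow(x)
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(x))
  edges <- matrix(0L, nrow = 0, ncol = 2)
  nbr <- t(apply(d, 1L, function(row) order(row)[2:(k + 1L)]))
  from <- rep(seq_len(n), k)
  to <- as.integer(nbr)
  und <- cbind(pmin(from, to), pmax(from, to))
  und <- unique(und)
  g <- igraph::graph_from_edgelist(und, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- d[und]
  g
}

#' Leiden clustering of cells in a low-dimensional embedding
#'
#' Builds a symmetric k-nearest-neighbor graph on the rows of \code{scores}
#' (Euclidean), runs Leiden community detection (modularity objective) over
#' the resolution grid, and keeps the resolution whose cluster count is
#' closest to \code{target_clusters} (ties to the lower resolution).
#' Deterministic under \code{cfg$seed}.
#'
#' @param scores numeric matrix (cells x dims), e.g. PCA scores.
#' @param cfg \code{\link{local_disease_config}}.
#' @return integer cluster labels (1-based), with attributes
#'   \code{resolution} and \code{n_clusters}.
#' @export
leiden_cluster <- function(scores, cfg = local_disease_config()) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < cfg$target_clusters) stop("fewer cells than target_clusters")
  if (max(stats::dist(utils::head(scores, min(n, 200)))) == 0 &&
      all(scores == rep(scores[1, ], each = n))) {
    return(structure(rep(1L, n), resolution = NA_real_, n_clusters = 1L))
  }
  g <- knn_graph(scores, cfg$knn_k)
  comp <- igraph::components(g)
  if (comp$no > cfg$target_clusters) {
    message("kNN graph has ", comp$no, " components (> target_clusters); ",
            "proceeding")
  }
  best <- NULL
  for (i in seq_along(cfg$resolution_grid)) {
    r <- cfg$resolution_grid[i]
    set.seed(cfg$seed + i)
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = r, n_iterations = 5)
    memb <- igraph::membership(cl)
    nc <- length(unique(memb))
    gap <- abs(nc - cfg$target_clusters)
    if (is.null(best) || gap < best$gap) {   # strict: ties keep lower resolution
      best <- list(memb = memb, gap = gap, r = r, nc = nc)
    }
  }
  structure(as.integer(best$memb), resolution = best$r,
            n_clusters = best$nc)
}

#' Fit one infected/uninfected classifier per cluster
#'
#' Within each cluster with both disease classes and at least
#' \code{min_cluster_size} cells, fits a ridge logistic model with
#' class-weighted loss (inverse class frequency) to counter the strong
#' per-cluster class imbalance. Degenerate clusters (one class, or too small)
#' get a flagged constant model predicting the majority class.
#'
#' @param scores feature matrix (cells x dims).
#' @param clusters integer cluster labels.
#' @param disease per-cell labels with exactly 2 levels.
#' @param lambda ridge penalty.
#' @param min_cluster_size see above.
#' @return named list of per-cluster models, each either
#'   \code{lincell_classifier} or \code{list(constant = <label>)}.
#' @export
fit_local_classifiers <- function(scores, clusters, disease, lambda = 1e-2,
                                  min_cluster_size = 10) {
  disease <- as.character(disease)
  models <- list()
  for (cl in sort(unique(clusters))) {
    idx <- which(clusters == cl)
    y <- disease[idx]
    tab <- table(y)
    if (length(tab) < 2 || length(idx) < min_cluster_size ||
        min(tab) < 2) {
      models[[as.character(cl)]] <- list(constant = names(tab)[which.max(tab)],
                                         flagged = TRUE, n = length(idx))
      next
    }
    w <- as.numeric(1 / tab[y]); w <- w / mean(w)
    models[[as.character(cl)]] <- train_classifier(
      scores[idx, , drop = FALSE], y, lambda = lambda, weights = w)
  }
  models
}

predict_local <- function(models, scores, clusters) {
  pred <- character(nrow(scores))
  for (cl in unique(clusters)) {
    idx <- which(clusters == cl)
    m <- models[[as.character(cl)]]
    if (is.null(m)) stop("no model for cluster ", cl)
    pred[idx] <- if (!is.null(m$constant)) m$constant else
      predict_labels(m, scores[idx, , drop = FALSE])
  }
  pred
}

#' Run the cluster-local disease-state pipeline
#'
#' Normalize each cell to itself; ANOVA gene selection grouped by
#' \code{cell_type} metadata when available (never by disease state, so
#' selection cannot leak the outcome); standardize; PCA; Leiden clustering of
#' all cells (clusters are computed before disease labels are used anywhere);
#' per-cluster stratified train/test split; class-weighted local logistic
#' classifiers; pooled held-out predictions scored by macro F1 over the two
#' disease classes. A single global classifier on the same features and the
#' same split is fitted for comparison.
#'
#' @param em \code{\link{expression_matrix}} with \code{meta$disease_state}
#'   (exactly 2 levels).
#' @param cfg \code{\link{local_disease_config}}.
#' @param dcfg \code{\link{denoise_config}} for the shared preprocessing
#'   (its \code{min_cells_per_type} is not applied here).
#' @return object of class \code{DiseaseReport}: \code{per_cluster}
#'   (data.frame), \code{macro_f1} (pooled local), \code{global_macro_f1},
#'   \code{predictions} (data.frame of cell, cluster, truth, local, global),
#'   \code{n_clusters}, \code{resolution}.
#' @export
run_disease_pipeline <- function(em, cfg = local_disease_config(),
                                 dcfg = denoise_config(seed = cfg$seed)) {
  disease <- meta_column(em, "disease_state")
  lev <- sort(unique(disease))
  if (length(lev) != 2) {
    stop("disease_state must have exactly 2 levels, found: ",
         paste(lev, collapse = ", "))
  }
  ok <- rowSums(em$counts) > 0
  em <- subset_cells(em, ok); disease <- disease[ok]
  z <- normalize_matrix(em)$z
  if (!is.null(em$meta) && "cell_type" %in% names(em$meta)) {
    sel <- anova_select(z, meta_column(em, "cell_type"), dcfg$n_genes)
    z <- z[, sel, drop = FALSE]
  }
  z <- standardize(z)$x
  scores <- pca_project(z, n_pcs = min(cfg$n_pcs, nrow(z) - 1L, ncol(z)))$scores
  clusters <- leiden_cluster(scores, cfg)        # disease labels unused so far
  strat <- paste(clusters, disease)
  sp <- stratified_split(strat, train_frac = 1 - dcfg$test_frac,
                         seed = cfg$seed)
  models <- fit_local_classifiers(scores[sp$train, , drop = FALSE],
                                  clusters[sp$train], disease[sp$train],
                                  lambda = dcfg$lambda,
                                  min_cluster_size = cfg$min_cluster_size)
  local_pred <- predict_local(models, scores[sp$test, , drop = FALSE],
                              clusters[sp$test])
  tabg <- table(disease[sp$train])
  wg <- as.numeric(1 / tabg[disease[sp$train]]); wg <- wg / mean(wg)
  global_model <- train_classifier(scores[sp$train, , drop = FALSE],
                                   disease[sp$train], lambda = dcfg$lambda,
                                   weights = wg)
  global_pred <- predict_labels(global_model, scores[sp$test, , drop = FALSE])
  truth <- disease[sp$test]
  per_cluster <- do.call(rbind, lapply(sort(unique(clusters)), function(cl) {
    idx <- clusters[sp$test] == cl
    f1s <- if (any(idx)) per_class_f1(truth[idx], local_pred[idx], labels = lev)
           else c(NA_real_, NA_real_)
    data.frame(cluster = cl,
               n_cells = sum(clusters == cl),
               n_test = sum(idx),
               n_class1 = sum(disease[clusters == cl] == lev[1]),
               n_class2 = sum(disease[clusters == cl] == lev[2]),
               f1_1 = f1s[1], f1_2 = f1s[2],
               constant_model = !is.null(models[[as.character(cl)]]$constant))
  }))
  names(per_cluster)[names(per_cluster) == "f1_1"] <- paste0("f1_", lev[1])
  names(per_cluster)[names(per_cluster) == "f1_2"] <- paste0("f1_", lev[2])
  structure(list(
    per_cluster = per_cluster,
    macro_f1 = macro_f1(truth, local_pred, labels = lev),
    global_macro_f1 = macro_f1(truth, global_pred, labels = lev),
    predictions = data.frame(cell = em$cell_ids[sp$test],
                             cluster = clusters[sp$test], truth = truth,
                             local = local_pred, global = global_pred),
    n_clusters = attr(clusters, "n_clusters"),
    resolution = attr(clusters, "resolution")),
    class = "DiseaseReport")
}

#' @export
print.DiseaseReport <- function(x, ...) {
  cat("DiseaseReport:", x$n_clusters, "clusters (resolution ",
      x$resolution, ")\n", sep = "")
  cat("  pooled local macro F1:", round(x$macro_f1, 4), "\n")
  cat("  global macro F1:      ", round(x$global_macro_f1, 4), "\n")
  invisible(x)
}
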