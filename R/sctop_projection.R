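#' Build a pseudo-bulk reference basis
#'
#' Each cell type of interest becomes one basis vector: the mean of the
#' normalized expression rows of all cells carrying that label. Averaging
#' after rank normalization suppresses per-cell noise while preserving the
#' type's characteristic rank profile. The number of retained types must stay
#' below the number of genes so the types span a proper linear subspace of
#' gene expression space.
#'
#' @param nm \code{\link{normalize_matrix}} output.
#' @param labels per-cell character labels (defaults to \code{meta$cell_type}).
#' @param min_cells drop labels with fewer cells than this (with a warning).
#' @param source_tag free-text provenance tag stored on the basis.
#' @return object of class \code{ReferenceBasis}: \code{B} (genes x K),
#'   \code{type_labels}, \code{gene_ids}, \code{source_tag},
#'   \code{n_cells_per_type}.
#' @export
build_basis <- function(nm, labels = NULL, min_cells = 1, source_tag = "") {
  if (is.null(labels)) {
    if (is.null(nm$meta) || is.null(nm$meta$cell_type)) {
      stop("labels not given and meta$cell_type missing")
    }
    labels <- as.character(nm$meta$cell_type)
  }
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(nm$z))
  counts_per <- table(labels)
  keep <- names(counts_per)[counts_per >= min_cells]
  dropped <- setdiff(names(counts_per), keep)
  if (length(dropped) > 0) {
    warning("dropping labels below min_cells = ", min_cells, ": ",
            paste(dropped, collapse = ", "))
  }
  if (length(keep) == 0) stop("no labels retained after min_cells filter")
  keep <- sort(keep)
  B <- vapply(keep, function(L) colMeans(nm$z[labels == L, , drop = FALSE]),
              numeric(ncol(nm$z)))
  if (length(keep) >= ncol(nm$z)) {
    stop("number of retained cell types (", length(keep),
         ") must be less than the number of genes (", ncol(nm$z), ")")
  }
  structure(list(B = B, type_labels = keep, gene_ids = nm$gene_ids,
                 source_tag = source_tag,
                 n_cells_per_type = as.integer(counts_per[keep])),
            class = "ReferenceBasis")
}

#' @export
print.ReferenceBasis <- function(x, ...) {
  cat("ReferenceBasis:", length(x$type_labels), "cell types x",
      length(x$gene_ids), "genes",
      if (nzchar(x$source_tag)) paste0("(", x$source_tag, ")") else "", "\n")
  invisible(x)
}

#' Non-orthogonal projection of cells onto a reference basis
#'
#' For each normalized cell vector x the projection coefficients a solve the
#' Gram (normal-equation) system
#' \deqn{(B^\top B)\, a = B^\top x,}
#' i.e. the least-squares decomposition of x over the (generally
#' non-orthogonal) basis columns. Each cell is labeled with the type of its
#' largest coefficient; ties break to the first label in basis order and are
#' reported.
#'
#' Gene handling: normalized columns are aligned to the basis gene order.
#' Target genes absent from the basis are dropped; basis genes absent from
#' the target are an error — rank z-scores have no natural value for an
#' unmeasured gene, so zero-filling would silently distort projections.
#'
#' @param basis \code{\link{build_basis}} output.
#' @param nm \code{\link{normalize_matrix}} output.
#' @param cond_threshold error if the Gram matrix condition number exceeds
#'   this (near-collinear basis columns; prune closely related types).
#' @return object of class \code{ProjectionResult}: \code{coefficients}
#'   (cells x K), \code{predicted_label}, \code{margin} (largest minus
#'   second-largest coefficient; 0 when K = 1).
#' @export
project <- function(basis, nm, cond_threshold = 1e8) {
  missing_genes <- setdiff(basis$gene_ids, nm$gene_ids)
  if (length(missing_genes) > 0) {
    stop(length(missing_genes), " basis genes absent from the target ",
         "(e.g. ", paste(utils::head(missing_genes, 5), collapse = ", "),
         "); restrict the basis or harmonize gene sets first")
  }
  extra <- length(setdiff(nm$gene_ids, basis$gene_ids))
  if (extra > 0) message("dropping ", extra, " target genes not in the basis")
  K <- length(basis$type_labels)
  if (length(basis$gene_ids) < K) stop("fewer shared genes than basis types")
  Z <- nm$z[, basis$gene_ids, drop = FALSE]
  B <- basis$B
  G <- crossprod(B)
  d <- svd(G, nu = 0, nv = 0)$d
  cond <- if (min(d) <= 0) Inf else max(d) / min(d)
  if (!is.finite(cond) || cond > cond_threshold) {
    stop("Gram matrix is ill-conditioned (condition number ",
         format(cond, digits = 3), " > ", format(cond_threshold),
         "); prune near-collinear basis columns")
  }
  A <- t(solve(G, crossprod(B, t(Z))))   # cells x K
  colnames(A) <- basis$type_labels
  top <- apply(A, 1L, function(a) {
    o <- order(a, decreasing = TRUE)
    c(o[1], if (length(a) > 1) a[o[1]] - a[o[2]] else 0)
  })
  winner <- as.integer(top[1, ])
  n_tie <- sum(apply(A, 1L, function(a) sum(a == max(a)) > 1))
  if (n_tie > 0) message(n_tie, " cells had tied top coefficients; ",
                         "first label in basis order used")
  structure(list(coefficients = A,
                 predicted_label = basis$type_labels[winner],
                 margin = as.numeric(top[2, ]),
                 cell_ids = nm$cell_ids),
            class = "ProjectionResult")
}

#' @export
print.ProjectionResult <- function(x, ...) {
  cat("ProjectionResult:", nrow(x$coefficients), "cells,",
      ncol(x$coefficients), "types\n")
  print(utils::head(table(x$predicted_label)))
  invisible(x)
}

#' Cross-dataset (or cross-species) projection classification
#'
#' Builds a pseudo-bulk basis from the labeled source dataset and classifies
#' every target cell by its largest projection coefficient. When the datasets
#' come from different species an ortholog map (target-species gene IDs to
#' source-species gene IDs) is applied first. Both sides are restricted to
#' the common gene set *before* normalization, so ranks are computed over the
#' genes actually shared.
#'
#' @param source,target \code{\link{expression_matrix}} objects with
#'   \code{meta$cell_type} (target labels are needed only for scoring).
#' @param omap optional \code{\link{ortholog_map}} from target gene IDs to
#'   source gene IDs; required when gene sets differ by species.
#' @param min_cells passed to \code{\link{build_basis}}.
#' @param cond_threshold passed to \code{\link{project}}.
#' @return list with \code{projection} (\code{ProjectionResult} over all
#'   target cells), \code{macro_f1} (over labels shared by source and
#'   target), \code{shared_labels}, \code{n_scored}, \code{n_excluded}.
#' @export
classify_transfer <- function(source, target, omap = NULL, min_cells = 1,
                              cond_threshold = 1e8) {
  src_labels <- meta_column(source, "cell_type")
  tgt_labels <- meta_column(target, "cell_type")
  if (!is.null(omap)) target <- harmonize(target, omap)
  common <- intersect(source$gene_ids, target$gene_ids)
  if (length(common) == 0) stop("no shared genes between source and target")
  src <- source; tgt <- target
  src$counts <- src$counts[, common, drop = FALSE]; src$gene_ids <- common
  tgt$counts <- tgt$counts[, common, drop = FALSE]; tgt$gene_ids <- common
  nonzero_src <- rowSums(src$counts) > 0
  nonzero_tgt <- rowSums(tgt$counts) > 0
  if (!all(nonzero_src)) { src <- subset_cells(src, nonzero_src); src_labels <- src_labels[nonzero_src] }
  if (!all(nonzero_tgt)) { tgt <- subset_cells(tgt, nonzero_tgt); tgt_labels <- tgt_labels[nonzero_tgt] }
  nm_src <- normalize_matrix(src)
  nm_tgt <- normalize_matrix(tgt)
  basis <- build_basis(nm_src, labels = src_labels, min_cells = min_cells)
  pr <- project(basis, nm_tgt, cond_threshold = cond_threshold)
  shared <- intersect(basis$type_labels, unique(tgt_labels))
  if (length(shared) == 0) stop("source and target share no cell-type labels")
  scored <- tgt_labels %in% shared
  n_excl <- sum(!scored)
  if (n_excl > 0) message(n_excl, " target cells with labels outside the ",
                          "basis excluded from scoring")
  f1 <- macro_f1(tgt_labels[scored], pr$predicted_label[scored], labels = shared)
  list(projection = pr, macro_f1 = f1, shared_labels = shared,
       n_scored = sum(scored), n_excluded = n_excl)
}
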