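#' Rank-based per-cell normalization
#'
#' Each cell is normalized to itself: counts are replaced by z-scores that
#' encode only the within-cell rank ordering of genes. With G genes, a gene
#' whose average rank is r receives
#' \deqn{z = \Phi^{-1}\!\left(\frac{r}{G+1}\right)}
#' where ties share the average rank (van der Waerden scores). A gene at the
#' 50th within-cell percentile therefore scores z = 0, one at the 84th
#' percentile z = qnorm(0.84) = 0.994 (about 1). Because rank/(G+1) never
#' reaches 0 or 1, z is always finite without clipping.
#'
#' No information flows between cells, which is what makes this normalization
#' insensitive to per-cell scaling (library size) and to batch-level
#' monotone distortions.
#'
#' @param counts non-negative integral numeric vector, length G >= 2, with at
#'   least one nonzero entry.
#' @return numeric vector of length G of finite z-scores; equal counts map to
#'   equal z.
#' @examples
#' normalize_cell(c(0, 1, 2, 3, 4))
#' @export
normalize_cell <- function(counts) {
  counts <- as.numeric(counts)
  G <- length(counts)
  if (G < 2) stop("need at least 2 genes")
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integral-valued")
  }
  if (all(counts == 0)) stop("all-zero cell carries no rank information")
  r <- rank(counts, ties.method = "average")
  stats::qnorm(r / (G + 1))
}

#' Normalize every cell of an expression matrix
#'
#' Applies \code{\link{normalize_cell}} row-wise. Cells are processed
#' independently; permuting or subsetting cells never changes any cell's
#' z-scores.
#'
#' @param em \code{\link{expression_matrix}} (or a plain counts matrix,
#'   cells x genes).
#' @return object of class \code{NormalizedMatrix}: list with \code{z}
#'   (cells x genes), \code{gene_ids}, \code{cell_ids}, \code{meta}.
#' @export
normalize_matrix <- function(em) {
  if (inherits(em, "ExpressionMatrix")) {
    counts <- em$counts
    gene_ids <- em$gene_ids; cell_ids <- em$cell_ids; meta <- em$meta
  } else {
    counts <- as.matrix(em)
    gene_ids <- colnames(counts) %||% paste0("g", seq_len(ncol(counts)))
    cell_ids <- rownames(counts) %||% paste0("c", seq_len(nrow(counts)))
    meta <- NULL
  }
  zero_cells <- rowSums(counts) == 0
  if (any(zero_cells)) {
    stop("all-zero cells present: ",
         paste(utils::head(cell_ids[zero_cells], 10), collapse = ", "))
  }
  G <- ncol(counts)
  z <- t(apply(counts, 1L, function(x) rank(x, ties.method = "average")))
  z <- stats::qnorm(z / (G + 1))
  dimnames(z) <- list(cell_ids, gene_ids)
  structure(list(z = z, gene_ids = gene_ids, cell_ids = cell_ids, meta = meta),
            class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat("NormalizedMatrix:", nrow(x$z), "cells x", ncol(x$z), "genes\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
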