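#' Construct an expression matrix
#'
#' The universal input container: a cells x genes matrix of raw mRNA counts
#' together with gene/cell identifiers and optional per-cell metadata
#' (columns such as \code{cell_type}, \code{species}, \code{donor},
#' \code{batch}, \code{disease_state}).
#'
#' Counts must be non-negative and integral-valued (integers, or doubles whose
#' values are whole numbers). Pre-normalized input is rejected on purpose:
#' every downstream step assumes raw counts.
#'
#' @param counts numeric matrix (cells x genes) or a \pkg{Matrix} sparse
#'   matrix; coerced to a dense base matrix.
#' @param gene_ids character vector of unique gene identifiers (columns).
#' @param cell_ids character vector of unique cell identifiers (rows).
#' @param meta optional data.frame with one row per cell.
#' @return an object of class \code{ExpressionMatrix}: a list with elements
#'   \code{counts}, \code{gene_ids}, \code{cell_ids}, \code{meta}.
#' @export
expression_matrix <- function(counts, gene_ids, cell_ids, meta = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(counts) != length(cell_ids) || ncol(counts) != length(gene_ids)) {
    stop("counts must be (n_cells x n_genes) = (", length(cell_ids), " x ",
         length(gene_ids), "), got (", nrow(counts), " x ", ncol(counts), ")")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene IDs: ",
         paste(utils::head(unique(gene_ids[duplicated(gene_ids)]), 5), collapse = ", "))
  }
  if (anyDuplicated(cell_ids)) {
    stop("duplicate cell IDs: ",
         paste(utils::head(unique(cell_ids[duplicated(cell_ids)]), 5), collapse = ", "))
  }
  if (anyNA(counts)) stop("counts contain NA")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integral-valued raw counts (found non-integer entries)")
  }
  if (!is.null(meta)) {
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    if (nrow(meta) != length(cell_ids)) {
      stop("meta must have one row per cell (", length(cell_ids), "), got ", nrow(meta))
    }
    rownames(meta) <- cell_ids
  }
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 meta = meta),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", length(x$cell_ids), "cells x", length(x$gene_ids),
      "genes\n")
  if (!is.null(x$meta)) cat("  meta columns:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' Fetch a required metadata column, failing fast if absent
#' @param em ExpressionMatrix
#' @param column metadata column name
#' @return character vector, one value per cell
#' @export
meta_column <- function(em, column) {
  if (is.null(em$meta) || !column %in% names(em$meta)) {
    stop("required metadata column '", column, "' is missing")
  }
  as.character(em$meta[[column]])
}

#' Read an expression matrix from disk
#'
#' Supported format: \code{mtx_dir} — a directory holding a cell-major
#' MatrixMarket file \code{matrix.mtx} (rows = cells), sidecars
#' \code{genes.tsv} and \code{cells.tsv} (one ID per line), and optionally
#' \code{meta.csv} (one row per cell). The AnnData \code{h5ad} layout is part
#' of the interchange contract but requires HDF5 bindings; when they are not
#' available the call fails with an informative error.
#'
#' @param path directory (mtx_dir) or file (h5ad) path.
#' @param format one of \code{"mtx_dir"}, \code{"h5ad"}.
#' @return \code{\link{expression_matrix}} with genes/cells in file order.
#' @export
read_expression <- function(path, format = c("mtx_dir", "h5ad")) {
  format <- match.arg(format)
  if (format == "h5ad") {
    stop("h5ad input requires HDF5 bindings which are not available in this ",
         "installation; convert to mtx_dir (see write_expression)")
  }
  if (!dir.exists(path)) stop("mtx_dir path does not exist: ", path)
  mtx <- file.path(path, "matrix.mtx")
  gf <- file.path(path, "genes.tsv")
  cf <- file.path(path, "cells.tsv")
  for (f in c(mtx, gf, cf)) {
    if (!file.exists(f)) stop("mtx_dir is missing component: ", basename(f))
  }
  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) stop("malformed MatrixMarket file matrix.mtx: ",
                                         conditionMessage(e)))
  genes <- readLines(gf)
  cells <- readLines(cf)
  meta <- NULL
  mf <- file.path(path, "meta.csv")
  if (file.exists(mf)) {
    meta <- utils::read.csv(mf, stringsAsFactors = FALSE,
                            colClasses = "character")
  }
  expression_matrix(as.matrix(m), gene_ids = genes, cell_ids = cells, meta = meta)
}

#' Write an expression matrix as an mtx_dir
#'
#' Round-trips exactly with \code{\link{read_expression}}: counts bit-exact,
#' metadata value-exact (metadata is written as character).
#'
#' @param em ExpressionMatrix
#' @param path output directory (created if needed).
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(em, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(em$counts, sparse = TRUE),
                  file.path(path, "matrix.mtx"))
  writeLines(em$gene_ids, file.path(path, "genes.tsv"))
  writeLines(em$cell_ids, file.path(path, "cells.tsv"))
  if (!is.null(em$meta)) {
    utils::write.csv(em$meta, file.path(path, "meta.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Construct a one-to-one ortholog map
#'
#' @param pairs two-column data.frame or matrix: source gene ID, target gene ID.
#' @param source_species,target_species species tags.
#' @param collapse how to enforce one-to-one-ness; \code{"drop_ambiguous"}
#'   removes every row whose source OR target gene participates in more than
#'   one pair.
#' @return object of class \code{OrthologMap} with character vectors
#'   \code{source_gene}, \code{target_gene} (parallel, injective).
#' @export
ortholog_map <- function(pairs, source_species = "source",
                         target_species = "target",
                         collapse = "drop_ambiguous") {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2) stop("ortholog pairs need two columns (source, target)")
  src <- as.character(pairs[[1]])
  tgt <- as.character(pairs[[2]])
  if (length(src) > 0) {                # exact duplicate rows collapse
    keep <- !duplicated(paste(src, tgt, sep = "\r"))
    src <- src[keep]; tgt <- tgt[keep]
  }
  if (collapse == "drop_ambiguous") {
    ok <- !(src %in% src[duplicated(src)]) & !(tgt %in% tgt[duplicated(tgt)])
    n_drop <- sum(!ok)
    if (n_drop > 0) message("dropped ", n_drop, " ambiguous ortholog pairs")
    src <- src[ok]; tgt <- tgt[ok]
  } else {
    stop("unknown collapse mode: ", collapse)
  }
  if (length(src) == 0) warning("ortholog map is empty")
  stopifnot(!anyDuplicated(src), !anyDuplicated(tgt))
  structure(list(source_gene = src, target_gene = tgt,
                 source_species = source_species,
                 target_species = target_species),
            class = "OrthologMap")
}

#' @export
print.OrthologMap <- function(x, ...) {
  cat("OrthologMap:", x$source_species, "->", x$target_species, "(",
      length(x$source_gene), "pairs )\n")
  invisible(x)
}

#' Read an ortholog map from CSV
#'
#' The CSV must have columns \code{source_gene} and \code{target_gene};
#' optional columns \code{source_species}, \code{target_species} override the
#' arguments.
#'
#' @inheritParams ortholog_map
#' @param path CSV path.
#' @return \code{OrthologMap}
#' @export
read_ortholog_map <- function(path, source_species = "source",
                              target_species = "target",
                              collapse = "drop_ambiguous") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("source_gene", "target_gene")
  if (!all(need %in% names(df))) {
    stop("ortholog CSV must have columns: ", paste(need, collapse = ", "))
  }
  if ("source_species" %in% names(df) && nrow(df) > 0) {
    source_species <- df$source_species[1]
  }
  if ("target_species" %in% names(df) && nrow(df) > 0) {
    target_species <- df$target_species[1]
  }
  ortholog_map(df[need], source_species, target_species, collapse)
}

#' Invert a one-to-one ortholog map
#' @param omap OrthologMap
#' @return OrthologMap with source and target swapped
#' @export
invert_ortholog_map <- function(omap) {
  structure(list(source_gene = omap$target_gene,
                 target_gene = omap$source_gene,
                 source_species = omap$target_species,
                 target_species = omap$source_species),
            class = "OrthologMap")
}

#' Construct an evolutionary distance table
#'
#' One divergence value (millions of years from a stated reference species)
#' per species; the reference itself must be present with distance 0.
#'
#' @param species character vector.
#' @param mya non-negative numeric, same length.
#' @param reference reference species name.
#' @return object of class \code{DistanceTable}.
#' @export
distance_table <- function(species, mya, reference) {
  species <- as.character(species)
  mya <- as.numeric(mya)
  if (length(species) != length(mya)) stop("species and mya lengths differ")
  if (anyDuplicated(species)) stop("duplicate species in distance table")
  if (any(mya < 0)) stop("mya must be non-negative")
  if (!reference %in% species) stop("reference species '", reference, "' absent")
  if (mya[match(reference, species)] != 0) {
    stop("reference species must have mya = 0")
  }
  structure(list(species = species, mya = stats::setNames(mya, species),
                 reference = reference),
            class = "DistanceTable")
}

#' Read a distance table from CSV (columns species, mya)
#' @param path CSV path
#' @param reference reference species name
#' @return \code{DistanceTable}
#' @export
read_distance_table <- function(path, reference) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "mya") %in% names(df))) {
    stop("distance CSV must have columns species, mya")
  }
  distance_table(df$species, df$mya, reference)
}

#' Subset an ExpressionMatrix by cell index
#' @param em ExpressionMatrix
#' @param idx integer or logical index over cells
#' @return ExpressionMatrix
#' @export
subset_cells <- function(em, idx) {
  expression_matrix(em$counts[idx, , drop = FALSE],
                    gene_ids = em$gene_ids,
                    cell_ids = em$cell_ids[idx],
                    meta = if (is.null(em$meta)) NULL else em$meta[idx, , drop = FALSE])
}
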