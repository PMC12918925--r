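#' Cosine similarity of two vectors
#' @param u,v numeric vectors of equal length, both with positive norm.
#' @return value in [-1, 1]
#' @export
cosine <- function(u, v) {
  if (length(u) != length(v)) stop("vector lengths differ")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine undefined for a zero vector")
  s <- sum(u * v) / (nu * nv)
  max(-1, min(1, s))
}

new_similarity_matrix <- function(S, labels) {
  dimnames(S) <- list(labels, labels)
  stopifnot(max(abs(S - t(S))) < 1e-9, max(abs(diag(S) - 1)) < 1e-9)
  structure(list(labels = labels, S = S), class = "SimilarityMatrix")
}

#' @export
print.SimilarityMatrix <- function(x, ...) {
  cat("SimilarityMatrix over", length(x$labels), "labels\n")
  print(round(x$S, 3))
  invisible(x)
}

#' Pairwise cosine similarity between cell-type pseudo-bulk vectors
#'
#' Builds a pseudo-bulk vector per label (mean of normalized rows, as in
#' \code{\link{build_basis}}) and returns all pairwise cosine similarities.
#' Within a developmental lineage, successive stages are expected to be more
#' similar than distant stages.
#'
#' @param nm \code{\link{normalize_matrix}} output.
#' @param labels per-cell character labels (defaults to \code{meta$cell_type}).
#' @return object of class \code{SimilarityMatrix}: symmetric, unit diagonal.
#' @export
celltype_similarity <- function(nm, labels = NULL) {
  if (is.null(labels)) {
    if (is.null(nm$meta) || is.null(nm$meta$cell_type)) {
      stop("labels not given and meta$cell_type missing")
    }
    labels <- as.character(nm$meta$cell_type)
  }
  labels <- as.character(labels)
  uniq <- sort(unique(labels))
  if (length(uniq) < 2) stop("need at least 2 labels")
  P <- vapply(uniq, function(L) colMeans(nm$z[labels == L, , drop = FALSE]),
              numeric(ncol(nm$z)))
  S <- outer(seq_along(uniq), seq_along(uniq),
             Vectorize(function(i, j) cosine(P[, i], P[, j])))
  diag(S) <- 1
  S <- (S + t(S)) / 2
  new_similarity_matrix(S, uniq)
}

#' Species-level cosine similarity over shared cell types and orthologs
#'
#' For each species: restrict to the cell types shared by all species (so
#' composition is equalized), harmonize genes onto the reference namespace,
#' keep only orthologs present in every species, normalize, and average all
#' retained cells into one representative species-level vector. Returns all
#' pairwise cosine similarities; similarity is expected to decay with
#' evolutionary distance.
#'
#' @param datasets named list of \code{\link{expression_matrix}} objects with
#'   \code{meta$cell_type}.
#' @param omaps as in \code{\link{transfer_experiment}}; maps from each
#'   species' genes onto the reference species' genes.
#' @param reference species whose gene namespace anchors the common
#'   coordinate system (default: first dataset).
#' @param shared_types_only restrict to cell types present in every species
#'   (an error names any species missing a shared type when this is set and
#'   no type survives).
#' @return \code{SimilarityMatrix} over species.
#' @export
species_similarity <- function(datasets, omaps = list(), reference = NULL,
                               shared_types_only = TRUE) {
  species <- names(datasets)
  if (length(species) < 2) stop("need at least 2 species")
  if (is.null(reference)) reference <- species[1]
  types_per <- lapply(datasets, function(d) unique(meta_column(d, "cell_type")))
  shared <- Reduce(intersect, types_per)
  if (shared_types_only) {
    if (length(shared) == 0) {
      miss <- vapply(species, function(s)
        paste(setdiff(unique(unlist(types_per)), types_per[[s]]), collapse = ","),
        character(1))
      stop("no cell types shared by all species; missing per species: ",
           paste(paste0(species, ":[", miss, "]"), collapse = " "))
    }
  }
  harmonized <- lapply(species, function(s) {
    d <- datasets[[s]]
    if (shared_types_only) {
      keep <- meta_column(d, "cell_type") %in% shared
      d <- subset_cells(d, keep)
    }
    # datasets already sharing the reference namespace need no map
    om <- tryCatch(find_omap(omaps, from = s, to = reference),
                   error = function(e) NULL)
    if (!is.null(om)) d <- harmonize(d, om)
    d
  })
  names(harmonized) <- species
  common_genes <- Reduce(intersect, lapply(harmonized, function(d) d$gene_ids))
  if (length(common_genes) == 0) stop("empty common ortholog set")
  vectors <- vapply(harmonized, function(d) {
    d$counts <- d$counts[, common_genes, drop = FALSE]
    d$gene_ids <- common_genes
    ok <- rowSums(d$counts) > 0
    nm <- normalize_matrix(subset_cells(d, ok))
    colMeans(nm$z)
  }, numeric(length(common_genes)))
  S <- outer(seq_along(species), seq_along(species),
             Vectorize(function(i, j) cosine(vectors[, i], vectors[, j])))
  diag(S) <- 1
  S <- (S + t(S)) / 2
  new_similarity_matrix(S, species)
}

#' Spearman correlation between similarity to a reference and divergence time
#'
#' Correlates the cosine similarity of every non-reference species to the
#' reference with its evolutionary distance (millions of years). A strong
#' negative value indicates that similarity decays monotonically with
#' divergence.
#'
#' @param sim \code{SimilarityMatrix} over species.
#' @param dist \code{\link{distance_table}}.
#' @param reference reference species (must be a label of \code{sim}).
#' @return list with \code{spearman_r} and \code{pairs} (data.frame of
#'   species, similarity, mya).
#' @export
distance_correlation <- function(sim, dist, reference) {
  if (!reference %in% sim$labels) stop("reference not in similarity matrix")
  others <- setdiff(sim$labels, reference)
  if (length(others) < 3) stop("need at least 3 non-reference species")
  if (!all(others %in% dist$species)) {
    stop("species missing from distance table: ",
         paste(setdiff(others, dist$species), collapse = ", "))
  }
  s <- sim$S[reference, others]
  m <- dist$mya[others]
  if (stats::sd(s) == 0 || stats::sd(m) == 0) {
    stop("degenerate input: similarities or distances are constant")
  }
  r <- stats::cor(s, m, method = "spearman")
  list(spearman_r = r,
       pairs = data.frame(species = others, similarity = as.numeric(s),
                          mya = as.numeric(m), row.names = NULL))
}
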