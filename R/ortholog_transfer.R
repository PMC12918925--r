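#' Harmonize a dataset onto another species' gene namespace
#'
#' Restricts the matrix to genes present in the ortholog map and renames them
#' to their counterparts in the map's target species, giving all datasets a
#' common gene coordinate system. Counts of unmapped genes are discarded (the
#' step is inherently lossy) and the number dropped is reported.
#'
#' @param em \code{\link{expression_matrix}} whose gene IDs live in the map's
#'   source-species namespace.
#' @param omap \code{\link{ortholog_map}}.
#' @return ExpressionMatrix with renamed, duplicate-free genes.
#' @export
harmonize <- function(em, omap) {
  idx <- match(em$gene_ids, omap$source_gene)
  keep <- !is.na(idx)
  if (!any(keep)) stop("no genes of the dataset appear in the ortholog map")
  n_drop <- sum(!keep)
  if (n_drop > 0) message("harmonize: dropping ", n_drop, " unmapped genes")
  new_ids <- omap$target_gene[idx[keep]]
  stopifnot(!anyDuplicated(new_ids))  # guaranteed by the map's injectivity
  expression_matrix(em$counts[, keep, drop = FALSE],
                    gene_ids = new_ids, cell_ids = em$cell_ids, meta = em$meta)
}

#' Macro-averaged F1 score
#'
#' Unweighted mean over the given labels of per-class F1 = 2PR/(P+R).
#' A class with no true and no predicted instances has undefined F1; by
#' convention it contributes 0 (and is reported), which penalizes absent
#' classes consistently.
#'
#' @param y_true,y_pred character vectors of equal length.
#' @param labels label set to average over; defaults to the union of observed
#'   labels.
#' @return macro F1 in [0, 1].
#' @export
macro_f1 <- function(y_true, y_pred, labels = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred lengths differ")
  if (is.null(labels)) labels <- sort(unique(c(y_true, y_pred)))
  if (length(labels) == 0) stop("empty label set")
  f1 <- vapply(labels, function(L) {
    tp <- sum(y_true == L & y_pred == L)
    fp <- sum(y_true != L & y_pred == L)
    fn <- sum(y_true == L & y_pred != L)
    if (tp + fp + fn == 0) return(0)      # absent class convention
    if (tp == 0) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
  n_absent <- sum(!(labels %in% y_true) & !(labels %in% y_pred))
  if (n_absent > 0) message(n_absent, " classes absent from truth and ",
                            "predictions contribute F1 = 0")
  mean(f1)
}

#' Per-class F1 scores
#' @inheritParams macro_f1
#' @return named numeric vector of per-class F1 (absent classes 0)
#' @export
per_class_f1 <- function(y_true, y_pred, labels = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (is.null(labels)) labels <- sort(unique(c(y_true, y_pred)))
  vapply(labels, function(L) {
    tp <- sum(y_true == L & y_pred == L)
    fp <- sum(y_true != L & y_pred == L)
    fn <- sum(y_true == L & y_pred != L)
    if (tp == 0) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
}

#' Stratified train/test split indices
#' @param labels per-observation class labels
#' @param train_frac fraction assigned to training, per class
#' @param seed RNG seed
#' @return list(train = integer indices, test = integer indices)
#' @export
stratified_split <- function(labels, train_frac = 0.8, seed = 0) {
  stopifnot(train_frac > 0, train_frac < 1)
  set.seed(seed)
  labels <- as.character(labels)
  train <- integer(0)
  for (L in sort(unique(labels))) {
    idx <- which(labels == L)
    n_tr <- max(1L, round(train_frac * length(idx)))
    if (n_tr >= length(idx)) n_tr <- length(idx) - 1L  # keep >= 1 test cell
    if (n_tr < 1L) n_tr <- 1L
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' All-pairs cross-species transfer experiment
#'
#' Entry (i, j) of the returned matrix is the macro F1 obtained when a
#' pseudo-bulk basis built from species i classifies the cells of species j.
#' Off-diagonal entries use all cells of both species after harmonizing j's
#' genes onto i's namespace; the diagonal uses a stratified held-out split
#' (never train-on-test). Pairs with no shared cell-type labels get NA.
#'
#' @param datasets named list of \code{\link{expression_matrix}} objects
#'   (names = species), each with \code{meta$cell_type}.
#' @param omaps list of \code{\link{ortholog_map}} objects covering, for each
#'   ordered pair with differing gene namespaces, a map from the target
#'   species' genes to the basis species' genes (inverses are derived
#'   automatically; maps through a common reference are composed if needed).
#' @param split_frac training fraction for the diagonal.
#' @param seed RNG seed for the diagonal splits.
#' @return object of class \code{TransferMatrix}: \code{species},
#'   \code{f1} (S x S, NA = missing).
#' @export
transfer_experiment <- function(datasets, omaps = list(), split_frac = 0.8,
                                seed = 0) {
  species <- names(datasets)
  if (is.null(species) || any(!nzchar(species))) stop("datasets must be named by species")
  S <- length(species)
  f1 <- matrix(NA_real_, S, S, dimnames = list(train = species, test = species))
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      if (i == j) {
        labs <- meta_column(datasets[[i]], "cell_type")
        sp <- stratified_split(labs, train_frac = split_frac,
                               seed = seed + i)
        res <- try(classify_transfer(subset_cells(datasets[[i]], sp$train),
                                     subset_cells(datasets[[i]], sp$test)),
                   silent = TRUE)
      } else {
        om <- find_omap(omaps, from = species[j], to = species[i])
        res <- try(classify_transfer(datasets[[i]], datasets[[j]], omap = om),
                   silent = TRUE)
      }
      if (inherits(res, "try-error")) {
        message("transfer ", species[i], " -> ", species[j], " missing: ",
                attr(res, "condition")$message)
      } else {
        f1[i, j] <- res$macro_f1
      }
    }
  }
  structure(list(species = species, f1 = f1), class = "TransferMatrix")
}

#' @export
print.TransferMatrix <- function(x, ...) {
  cat("TransferMatrix (train rows x test cols):\n")
  print(round(x$f1, 3))
  invisible(x)
}

# Locate (or derive by inversion / composition through a shared species) a map
# from species `from` gene IDs to species `to` gene IDs. Identity if from == to.
find_omap <- function(omaps, from, to) {
  if (from == to) return(NULL)
  for (om in omaps) {
    if (om$source_species == from && om$target_species == to) return(om)
  }
  for (om in omaps) {
    if (om$source_species == to && om$target_species == from) {
      return(invert_ortholog_map(om))
    }
  }
  # compose from -> ref -> to
  for (om1 in omaps) {
    a <- if (om1$source_species == from) om1 else
      if (om1$target_species == from) invert_ortholog_map(om1) else next
    for (om2 in omaps) {
      b <- if (om2$source_species == a$target_species && om2$target_species == to) om2 else
        if (om2$target_species == a$target_species && om2$source_species == to)
          invert_ortholog_map(om2) else next
      idx <- match(a$target_gene, b$source_gene)
      keep <- !is.na(idx)
      if (!any(keep)) next
      return(structure(list(source_gene = a$source_gene[keep],
                            target_gene = b$target_gene[idx[keep]],
                            source_species = from, target_species = to),
                       class = "OrthologMap"))
    }
  }
  stop("no ortholog map available from ", from, " to ", to)
}
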