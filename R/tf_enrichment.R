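#' PMI-inspired TF-gene enrichment score
#'
#' Cells with high TF activity are those whose normalized TF score exceeds
#' the \code{high_q} quantile of that gene across cells; a gene is "observed"
#' in a cell when its normalized score exceeds \code{on_thresh} (above the
#' within-cell median by default). The score compares the gene's detection
#' frequency among TF-high cells with its marginal detection frequency:
#' \deqn{\mathrm{PMI} = \log\frac{n_{on,H} + c}{|H| + 2c}
#'       - \log\frac{n_{on,\cdot} + c}{N + 2c}}
#' with pseudocount c keeping the score finite. Positive values mean the gene
#' is conditionally enriched among TF-high cells; the statistic measures
#' conditional co-expression, not causal regulation.
#'
#' @param nm \code{\link{normalize_matrix}} output.
#' @param tf,gene gene IDs present in \code{nm}.
#' @param high_q TF-high quantile (default 0.90).
#' @param on_thresh detection threshold on normalized scores (default 0).
#' @param pseudocount Laplace-style smoothing (default 0.5; use 0 for exact
#'   frequency ratios).
#' @return numeric PMI score.
#' @export
pmi_score <- function(nm, tf, gene, high_q = 0.90, on_thresh = 0,
                      pseudocount = 0.5) {
  for (g in c(tf, gene)) {
    if (!g %in% nm$gene_ids) stop("gene absent from matrix: ", g)
  }
  ztf <- nm$z[, tf]
  H <- ztf > stats::quantile(ztf, high_q)
  if (!any(H)) stop("empty TF-high set (quantile too extreme or TF constant)")
  on <- nm$z[, gene] > on_thresh
  pmi_from_counts(sum(on[H]), sum(H), sum(on), length(on), pseudocount)
}

pmi_from_counts <- function(n_on_H, n_H, n_on_all, N, pseudocount) {
  log((n_on_H + pseudocount) / (n_H + 2 * pseudocount)) -
    log((n_on_all + pseudocount) / (N + 2 * pseudocount))
}

#' Permutation null Z-score for a PMI pair
#'
#' The null keeps the sizes fixed and permutes which cells form the TF-high
#' set uniformly at random \code{n_perm} times; the observed PMI is reduced
#' to z = (observed - null mean)/null s.d. and a two-sided p-value from the
#' standard normal tail of that calibrated z. A degenerate null (s.d. 0,
#' e.g. a gene observed in every cell) yields z = 0, p = 1, flagged.
#'
#' Permutations are drawn after sorting cell IDs, so the result is invariant
#' to the order cells arrive in.
#'
#' @inheritParams pmi_score
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return list(z, p, pmi, degenerate)
#' @export
null_z <- function(nm, tf, gene, n_perm = 200, seed = 0, high_q = 0.90,
                   on_thresh = 0, pseudocount = 0.5) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  ord <- order(nm$cell_ids)
  ztf <- nm$z[ord, tf]
  on <- nm$z[ord, gene] > on_thresh
  H <- ztf > stats::quantile(ztf, high_q)
  if (!any(H)) stop("empty TF-high set")
  m <- sum(H); N <- length(on); n_on_all <- sum(on)
  obs <- pmi_from_counts(sum(on[H]), m, n_on_all, N, pseudocount)
  set.seed(seed)
  null_vals <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(N, m)
    pmi_from_counts(sum(on[idx]), m, n_on_all, N, pseudocount)
  }, numeric(1))
  s <- stats::sd(null_vals)
  if (!is.finite(s) || s == 0) {
    return(list(z = 0, p = 1, pmi = obs, degenerate = TRUE))
  }
  z <- (obs - mean(null_vals)) / s
  list(z = z, p = 2 * stats::pnorm(-abs(z)), pmi = obs, degenerate = FALSE)
}

#' Screen all TF-gene pairs with FDR control
#'
#' Computes the PMI score and permutation z/p for every (tf, gene) pair,
#' applies Benjamini-Hochberg correction across all pairs at level
#' \code{alpha}, and (optionally) flags pairs present in an independent
#' interaction reference, reporting the validated fraction among significant
#' calls against the background validation rate.
#'
#' @inheritParams null_z
#' @param tfs,genes character vectors of gene IDs (pairs with tf == gene are
#'   skipped).
#' @param alpha FDR level.
#' @param reference optional data.frame with columns \code{tf}, \code{gene}.
#' @return data.frame of class \code{EnrichmentTable} with columns tf, gene,
#'   pmi, z, p, q, significant, validated; attributes
#'   \code{validated_rate_significant}, \code{validated_rate_background}.
#' @export
enrichment_screen <- function(nm, tfs, genes, alpha = 0.05, reference = NULL,
                              n_perm = 200, seed = 0, high_q = 0.90,
                              on_thresh = 0, pseudocount = 0.5) {
  if (length(tfs) == 0 || length(genes) == 0) stop("empty TF or gene list")
  pairs <- expand.grid(tf = tfs, gene = genes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$tf != pairs$gene, , drop = FALSE]
  res <- mapply(function(tf, g, i) {
    r <- null_z(nm, tf, g, n_perm = n_perm, seed = seed + i,
                high_q = high_q, on_thresh = on_thresh,
                pseudocount = pseudocount)
    c(r$pmi, r$z, r$p)
  }, pairs$tf, pairs$gene, seq_len(nrow(pairs)))
  out <- data.frame(tf = pairs$tf, gene = pairs$gene,
                    pmi = res[1, ], z = res[2, ], p = res[3, ],
                    row.names = NULL)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q <= alpha
  if (!is.null(reference)) {
    ref_keys <- paste(reference$tf, reference$gene)
    out$validated <- paste(out$tf, out$gene) %in% ref_keys
    attr(out, "validated_rate_significant") <-
      if (any(out$significant)) mean(out$validated[out$significant]) else NA_real_
    attr(out, "validated_rate_background") <- mean(out$validated)
  } else {
    out$validated <- NA
  }
  class(out) <- c("EnrichmentTable", "data.frame")
  out
}
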