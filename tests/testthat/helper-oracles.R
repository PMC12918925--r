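# Independent oracles used across test files. These deliberately use
# different algorithms / primitives than the implementation they check.

# Tiny deterministic expression matrix: 4 cells x 5 genes, two labels.
tiny_em <- function() {
  counts <- matrix(c(5, 0, 2, 1, 9,
                     4, 1, 3, 0, 8,
                     0, 7, 1, 6, 2,
                     1, 8, 0, 5, 3), nrow = 4, byrow = TRUE)
  expression_matrix(counts,
                    gene_ids = paste0("g", 1:5),
                    cell_ids = paste0("c", 1:4),
                    meta = data.frame(cell_type = c("A", "A", "B", "B")))
}

# Floyd-Warshall all-pairs shortest paths on a weighted adjacency matrix
# (Inf = no edge). O(n^3); only for small n.
fw_shortest_paths <- function(adj) {
  n <- nrow(adj)
  D <- adj
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# Weighted adjacency of the union kNN graph, built independently of the
# package (plain loops over sorted distances).
union_knn_adjacency <- function(points, k) {
  d <- as.matrix(dist(points))
  n <- nrow(d)
  adj <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    nbr <- order(d[i, ])[2:(k + 1)]
    adj[i, nbr] <- d[i, nbr]
    adj[nbr, i] <- d[i, nbr]
  }
  adj
}

# Benjamini-Hochberg step-up by direct enumeration of all thresholds.
bh_bruteforce <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  passing <- which(ps <= alpha * seq_len(m) / m)
  k <- if (length(passing) == 0) 0 else max(passing)
  sig <- logical(m)
  if (k > 0) sig[o[seq_len(k)]] <- TRUE
  sig
}

# Spearman rank correlation from first principles (average ranks + Pearson
# on ranks), independent of stats::cor(method = "spearman").
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Pairwise planted divergence between two species under independent Brownian
# drift from a common program.
pairwise_divergence <- function(di, dj) sqrt(di^2 + dj^2)

# Mean over matrix rows of Spearman(off-diagonal F1, pairwise divergence);
# rows where F1 is constant (undefined correlation) are skipped.
ladder_row_spearman <- function(tm, divergences) {
  S <- length(tm$species)
  vals <- vapply(seq_len(S), function(i) {
    j <- setdiff(seq_len(S), i)
    f1 <- tm$f1[i, j]
    dv <- pairwise_divergence(divergences[i], divergences[j])
    if (sd(f1, na.rm = TRUE) == 0 || anyNA(f1)) return(NA_real_)
    cor(f1, dv, method = "spearman")
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}
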