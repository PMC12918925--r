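#' Generate a swiss-roll point cloud
#'
#' The classical curved-manifold control: a 2-D strip rolled into 3-D,
#' \code{(t cos t, h, t sin t)} with \code{t ~ U(1.5*pi, 4.5*pi)} and height
#' \code{h ~ U(0, 21)}, plus isotropic Gaussian noise. The intrinsic
#' coordinates are (arc length along the spiral, h); a faithful nonlinear
#' embedding recovers them up to isometry, while any linear projection
#' cannot.
#'
#' @param n number of points (>= 10).
#' @param noise_sd s.d. of added Gaussian noise.
#' @param seed RNG seed.
#' @return list(points = n x 3, intrinsic = n x 2).
#' @export
swiss_roll <- function(n, noise_sd = 0, seed = 0) {
  if (n < 10) stop("n must be >= 10")
  set.seed(seed)
  t <- stats::runif(n, 1.5 * pi, 4.5 * pi)
  h <- stats::runif(n, 0, 21)
  pts <- cbind(t * cos(t), h, t * sin(t)) +
    matrix(stats::rnorm(3 * n, sd = noise_sd), n, 3)
  arc <- function(u) (u * sqrt(1 + u^2) + asinh(u)) / 2   # integral of sqrt(1+u^2)
  list(points = pts, intrinsic = cbind(arc(t) - arc(1.5 * pi), h))
}

#' Geodesic distances on a symmetric k-nearest-neighbor graph
#'
#' Builds the union kNN graph (an edge exists when either endpoint is among
#' the other's k Euclidean nearest neighbors), weights edges by Euclidean
#' length, and returns all-pairs shortest-path distances. Pairs in different
#' connected components are NA; disconnection is reported, not fatal.
#'
#' @param points numeric matrix (n x d).
#' @param k neighbors (1 <= k < n).
#' @return list(D_geo = n x n matrix with NA across components,
#'   component = integer component labels).
#' @export
geodesic_distances <- function(points, k) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(k >= 1, n > k)
  g <- knn_graph(points, k)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    message("kNN graph split into ", comp$no, " components; cross-component ",
            "distances are NA")
  }
  D <- igraph::distances(g, weights = igraph::E(g)$weight)
  D[is.infinite(D)] <- NA_real_
  list(D_geo = D, component = as.integer(comp$membership))
}

#' Geodesic-versus-Euclidean linearity diagnostic
#'
#' For each k, Pearson correlation between graph-geodesic and straight-line
#' Euclidean distances over (up to \code{max_pairs}) sampled pairs inside the
#' largest connected component. On data occupying a nearly linear region the
#' two distances agree and the correlation approaches 1; on a strongly curved
#' manifold (e.g. the swiss roll at small k) geodesics are much longer than
#' chords and the correlation drops.
#'
#' @param points numeric matrix (n x d), n >= 50.
#' @param k_values integer vector of neighborhood sizes to scan.
#' @param max_pairs cap on sampled pairs per k.
#' @param seed RNG seed for pair sampling.
#' @return object of class \code{GeometryReport}: \code{k_values},
#'   \code{pearson_by_k} (NA when no pairs survive),
#'   \code{largest_component_frac_by_k}, \code{n_points}.
#' @export
linearity_score <- function(points, k_values = c(5, 10, 20, 40),
                            max_pairs = 200000, seed = 0) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 50) stop("need at least 50 points")
  d_euc <- as.matrix(stats::dist(points))
  pearson <- numeric(length(k_values))
  frac <- numeric(length(k_values))
  for (i in seq_along(k_values)) {
    gd <- geodesic_distances(points, k_values[i])
    comp_sizes <- table(gd$component)
    main <- as.integer(names(comp_sizes)[which.max(comp_sizes)])
    in_main <- which(gd$component == main)
    frac[i] <- length(in_main) / n
    m <- length(in_main)
    if (m < 2) { pearson[i] <- NA_real_; next }
    set.seed(seed + i)
    n_all <- m * (m - 1) / 2
    if (n_all <= max_pairs) {
      idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    } else {
      a <- sample.int(m, max_pairs, replace = TRUE)
      b <- sample.int(m, max_pairs, replace = TRUE)
      keep <- a != b
      idx <- cbind(pmin(a, b), pmax(a, b))[keep, , drop = FALSE]
    }
    geo <- gd$D_geo[cbind(in_main[idx[, 1]], in_main[idx[, 2]])]
    euc <- d_euc[cbind(in_main[idx[, 1]], in_main[idx[, 2]])]
    ok <- !is.na(geo)
    pearson[i] <- if (sum(ok) >= 3 && stats::sd(geo[ok]) > 0 &&
                      stats::sd(euc[ok]) > 0)
      stats::cor(geo[ok], euc[ok]) else NA_real_
  }
  structure(list(k_values = k_values, pearson_by_k = pearson,
                 largest_component_frac_by_k = frac, n_points = n),
            class = "GeometryReport")
}

#' @export
print.GeometryReport <- function(x, ...) {
  cat("GeometryReport over", x$n_points, "points\n")
  print(data.frame(k = x$k_values, pearson = round(x$pearson_by_k, 4),
                   largest_component_frac =
                     round(x$largest_component_frac_by_k, 3)))
  invisible(x)
}

#' Two-dimensional embedding by PCA or Isomap
#'
#' \code{pca}: scores on the top-2 principal axes (a rigid-ish linear view).
#' \code{isomap}: classical multidimensional scaling of the graph-geodesic
#' distances of the largest connected component (points outside it get NA
#' rows and the restriction is reported).
#'
#' @param points numeric matrix (n x d), n >= 3.
#' @param method \code{"pca"} or \code{"isomap"}.
#' @param k neighbors for the geodesic graph (isomap only).
#' @return n x 2 numeric matrix.
#' @export
embed_2d <- function(points, method = c("pca", "isomap"), k = 10) {
  method <- match.arg(method)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3) stop("need at least 3 points")
  if (method == "pca") {
    return(pca_project(points, n_pcs = 2)$scores)
  }
  gd <- geodesic_distances(points, k)
  comp_sizes <- table(gd$component)
  main <- as.integer(names(comp_sizes)[which.max(comp_sizes)])
  in_main <- which(gd$component == main)
  if (length(in_main) < n) {
    message("isomap: embedding largest component only (",
            length(in_main), "/", n, " points)")
  }
  D <- gd$D_geo[in_main, in_main]
  Y <- stats::cmdscale(stats::as.dist(D), k = 2)
  out <- matrix(NA_real_, n, 2)
  out[in_main, seq_len(ncol(Y))] <- Y
  out
}
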