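#' Internal cluster validity indices
#'
#' Computes the five internal validity indices used by the clustering demo
#' app for a given labeling of a numeric data matrix:
#' \describe{
#'   \item{`calinski_harabasz`}{between-cluster over within-cluster
#'     dispersion, `(B/(k-1)) / (W/(n-k))`; higher is better.}
#'   \item{`silhouette`}{mean silhouette width over all points (via
#'     \pkg{cluster}); points in singleton clusters contribute width 0, the
#'     usual convention; higher is better.}
#'   \item{`davies_bouldin`}{mean over clusters of the worst
#'     `(S_i + S_j) / d(c_i, c_j)` ratio, with `S_i` the mean distance to
#'     the centroid; lower is better.}
#'   \item{`gap`}{gap statistic: `mean(log(W*_b)) - log(W)` where the `B`
#'     reference datasets are drawn uniformly over the per-feature bounding
#'     box of the data and clustered by k-means at the same `k`; higher is
#'     better.}
#'   \item{`s_dbw`}{intra-cluster scatter plus inter-cluster density
#'     (density at cluster-pair midpoints relative to the cluster centers,
#'     radius = average cluster standard deviation); lower is better.}
#' }
#' Indices that require at least two non-empty clusters are `NA` for a
#' single-cluster labeling.
#'
#' @param data Numeric matrix or data frame (rows = observations).
#' @param labels Cluster labels, one per row (any atomic type; `NA`s
#'   excluded).
#' @param B Number of uniform reference datasets for the gap statistic.
#' @param seed Seed for the gap references.
#' @return Named list with the five indices.
#' @export
cluster_quality_metrics <- function(data, labels, B = 10L, seed = 0L) {
  x <- as.matrix(data)
  storage.mode(x) <- "double"
  keep <- !is.na(labels)
  x <- x[keep, , drop = FALSE]
  lab <- as.integer(factor(labels[keep]))
  n <- nrow(x)
  k <- length(unique(lab))
  na_all <- list(calinski_harabasz = NA_real_, silhouette = NA_real_,
                 davies_bouldin = NA_real_, gap = NA_real_, s_dbw = NA_real_)
  if (n < 2L || k < 2L || k >= n) {
    if (k >= 1L && n >= 1L) na_all$gap <- gap_statistic(x, lab, B, seed)
    # all-singleton labelings: every point's silhouette is 0 by convention
    if (k == n && n >= 2L) na_all$silhouette <- 0
    return(na_all)
  }

  centers <- centroids(x, lab)
  grand <- colMeans(x)
  sizes <- tabulate(lab, nbins = k)
  wss <- within_ss(x, lab, centers)
  bss <- sum(sizes * rowSums(sweep(centers, 2L, grand)^2))

  ch <- (bss / (k - 1)) / (wss / (n - k))

  d <- stats::dist(x)
  sil <- mean(cluster::silhouette(lab, d)[, "sil_width"])

  db <- davies_bouldin(x, lab, centers)
  gap <- gap_statistic(x, lab, B, seed, wss = wss)
  sdbw <- s_dbw_index(x, lab, centers)

  list(calinski_harabasz = ch, silhouette = sil, davies_bouldin = db,
       gap = gap, s_dbw = sdbw)
}

centroids <- function(x, lab) {
  k <- max(lab)
  m <- vapply(seq_len(k), function(i) colMeans(x[lab == i, , drop = FALSE]),
              numeric(ncol(x)))
  # vapply returns a d x k matrix (or a length-k vector when d = 1)
  matrix(m, nrow = k, ncol = ncol(x), byrow = TRUE)
}

within_ss <- function(x, lab, centers) {
  sum(vapply(seq_len(max(lab)), function(i) {
    xi <- x[lab == i, , drop = FALSE]
    sum(sweep(xi, 2L, centers[i, ])^2)
  }, numeric(1)))
}

davies_bouldin <- function(x, lab, centers) {
  k <- max(lab)
  s <- vapply(seq_len(k), function(i) {
    xi <- x[lab == i, , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2L, centers[i, ])^2)))
  }, numeric(1))
  dc <- as.matrix(stats::dist(centers))
  mean(vapply(seq_len(k), function(i) {
    r <- (s[i] + s[-i]) / dc[i, -i]
    max(r[is.finite(r)], -Inf)
  }, numeric(1)))
}

gap_statistic <- function(x, lab, B, seed, wss = NULL) {
  k <- length(unique(lab))
  n <- nrow(x)
  if (is.null(wss)) {
    centers <- centroids(x, lab)
    wss <- within_ss(x, lab, centers)
  }
  if (wss <= 0) wss <- .Machine$double.eps
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  with_seed(seed, {
    ref <- vapply(seq_len(B), function(b) {
      xr <- matrix(stats::runif(n * ncol(x)), n) *
        rep(hi - lo, each = n) + rep(lo, each = n)
      if (k >= 2L && k < n) {
        km <- suppressWarnings(stats::kmeans(xr, centers = k, nstart = 1L,
                                             iter.max = 20L))
        max(km$tot.withinss, .Machine$double.eps)
      } else {
        sum(sweep(xr, 2L, colMeans(xr))^2)
      }
    }, numeric(1))
    mean(log(ref)) - log(wss)
  })
}

# S_Dbw (scatter + inter-cluster density). Density counts points of a
# cluster pair within the average cluster standard deviation of a probe
# point; a pair with an empty denominator contributes 0.
s_dbw_index <- function(x, lab, centers) {
  k <- max(lab)
  var0 <- function(m) {
    v <- apply(m, 2L, stats::var)
    v[is.na(v)] <- 0  # singleton clusters have zero scatter
    v
  }
  sigma_all <- var0(x)
  sigma_i <- lapply(seq_len(k), function(i) var0(x[lab == i, , drop = FALSE]))
  nrm <- function(v) sqrt(sum(v^2))
  scat <- mean(vapply(sigma_i, nrm, numeric(1))) / max(nrm(sigma_all),
                                                       .Machine$double.eps)
  stdev <- sqrt(mean(vapply(sigma_i, nrm, numeric(1))))
  dens <- function(u, members) {
    if (stdev <= 0) return(sum(rowSums(sweep(x[members, , drop = FALSE],
                                             2L, u)^2) == 0))
    sum(sqrt(rowSums(sweep(x[members, , drop = FALSE], 2L, u)^2)) <= stdev)
  }
  total <- 0
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    members <- which(lab %in% c(i, j))
    dij <- dens((centers[i, ] + centers[j, ]) / 2, members)
    denom <- max(dens(centers[i, ], members), dens(centers[j, ], members))
    total <- total + if (denom > 0) dij / denom else 0
  }
  dens_bw <- 2 * total / (k * (k - 1))
  scat + dens_bw
}
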