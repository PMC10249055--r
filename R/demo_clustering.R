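#' Generate the binary paintings-style feature table
#'
#' A seeded stand-in for a catalogue of 403 paintings annotated with 67
#' binary scene features. Rows are assigned to a handful of latent themes
#' (seascape, mountain, forest, winter, cabin); each theme plants a block
#' of co-occurring features (high on-probability inside the block, low
#' outside), and a few near-universal features (trees and the like) are on
#' for most rows regardless of theme. The planted blocks make clusterings
#' of the table non-trivial while the theme labels stay hidden.
#'
#' @param seed Seed; the same seed reproduces the table exactly.
#' @param n_rows,n_features Table shape (defaults 403 x 67).
#' @param n_themes Number of planted feature blocks (>= 3).
#' @return Data frame: `painting_id` plus `n_features` 0/1 columns named
#'   `feat_01` ... . The hidden theme assignment is attached as attribute
#'   `"theme"` for diagnostics, not as a column.
#' @export
generate_paintings_like <- function(seed = 0L, n_rows = 403L,
                                    n_features = 67L, n_themes = 5L) {
  stopifnot(n_themes >= 3L, n_features >= 2L * n_themes)
  with_seed(mix_seed(seed, 1L), {
    theme <- sample.int(n_themes, n_rows, replace = TRUE)
    n_common <- 4L
    block_size <- (n_features - n_common) %/% n_themes
    p <- matrix(0.05, n_rows, n_features)
    for (t in seq_len(n_themes)) {
      cols <- n_common + (t - 1L) * block_size + seq_len(block_size)
      p[theme == t, cols] <- 0.7
    }
    # leftover columns after the last full block stay background noise
    p[, seq_len(n_common)] <- 0.8
    m <- matrix(as.integer(stats::runif(n_rows * n_features) < p),
                n_rows, n_features)
    colnames(m) <- sprintf("feat_%02d", seq_len(n_features))
    out <- data.frame(painting_id = sprintf("p%03d", seq_len(n_rows)), m,
                      check.names = FALSE, stringsAsFactors = FALSE)
    attr(out, "theme") <- theme
    out
  })
}

# Plain DBSCAN (Euclidean, region queries against a precomputed distance
# matrix; adequate at the few-hundred-row scale of the demo). Noise points
# get label 0, clusters 1..k.
dbscan_labels <- function(x, eps, min_pts) {
  n <- nrow(x)
  dm <- as.matrix(stats::dist(x))
  labels <- rep(NA_integer_, n)  # NA = unvisited, 0 = noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i])) next
    nb <- which(dm[i, ] <= eps)
    if (length(nb) < min_pts) { labels[i] <- 0L; next }
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb, i)
    while (length(queue)) {
      j <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(labels[j]) && labels[j] == 0L) labels[j] <- cl
      if (!is.na(labels[j])) next
      labels[j] <- cl
      nb_j <- which(dm[j, ] <= eps)
      if (length(nb_j) >= min_pts)
        queue <- c(queue, setdiff(nb_j, which(!is.na(labels))))
    }
  }
  labels
}

cluster_feature_columns <- function(input, features = NULL) {
  if (!is.null(features)) return(features)
  num <- names(input)[vapply(input, is.numeric, TRUE)]
  # embedding columns appended by dimred_app are for display, not clustering
  setdiff(num, grep("^(pca|mds|tsne)[12]$", num, value = TRUE))
}

#' Run one clustering configuration
#'
#' The run function of the clustering demo app: clusters the numeric
#' feature columns of `input` with the requested method and emits the two
#' output tables of the app contract, `cluster_ids` (one `cluster_id` row
#' per input row; ids consecutive from 0, noise points from DBSCAN keep id
#' 0 of their own) and `quality_criteria` (a single row holding the five
#' validity indices, the model's self-reported derived output). Methods may
#' converge to fewer distinct ids than the requested `k`. If `input`
#' carries 2-D embedding columns (`tsne1`/`tsne2`, `mds1`/`mds2` or
#' `pca1`/`pca2`), the run image reuses them; otherwise it projects the
#' features by PCA.
#'
#' @param input Data frame with numeric/binary feature columns.
#' @param values Named list of parameter values (see
#'   [clustering_demo_app()] for the manifest).
#' @param features Optional explicit feature column names.
#' @return `list(tables = list(cluster_ids, quality_criteria), image = fn)`.
#' @export
clustering_run <- function(input, values, features = NULL) {
  cols <- cluster_feature_columns(input, features)
  x <- as.matrix(input[cols])
  storage.mode(x) <- "double"
  n <- nrow(x)
  k <- as.integer(values$k)
  seed <- as.integer(values$seed %||% 0L)

  if (nrow(unique(x)) == 1L) {
    warning("degenerate input: all rows identical; single cluster")
    lab <- rep(0L, n)
  } else {
    lab <- with_seed(mix_seed(seed, 2L), switch(values$method,
      kmeans = stats::kmeans(x, centers = k, nstart = 2L, iter.max = 30L,
                             algorithm = values$algorithm)$cluster,
      hierarchical = {
        hm <- c(ward = "ward.D2", complete = "complete", average = "average",
                single = "single", median = "median",
                centroid = "centroid")[[values$agglomeration]]
        stats::cutree(stats::hclust(stats::dist(x), method = hm), k = k)
      },
      spectral = {
        kp <- if (values$kernel %in% c("rbfdot", "laplacedot"))
          list(sigma = 1 / max(stats::median(stats::dist(x))^2,
                               .Machine$double.eps))
        else list()
        as.integer(kernlab::specc(x, centers = k, kernel = values$kernel,
                                  kpar = kp))
      },
      dbscan = dbscan_labels(x, eps = values$eps, min_pts = values$min_pts),
      abort("unknown clustering method '", values$method, "'")))
    # consecutive ids from 0 in order of first appearance (noise stays 0)
    if (values$method != "dbscan")
      lab <- as.integer(factor(lab, levels = unique(lab))) - 1L
  }

  qm <- cluster_quality_metrics(x, lab, B = as.integer(values$gap_B %||% 10L),
                                seed = mix_seed(seed, 3L))
  cluster_ids <- data.frame(cluster_id = lab)
  quality <- as.data.frame(qm)

  emb_cols <- NULL
  for (cand in list(c("tsne1", "tsne2"), c("mds1", "mds2"),
                    c("pca1", "pca2")))
    if (all(cand %in% names(input))) { emb_cols <- cand; break }
  emb <- if (!is.null(emb_cols)) cbind(input[[emb_cols[1]]],
                                       input[[emb_cols[2]]])
         else embed_2d(x, "pca")
  image_fn <- function(path = NULL) {
    pal <- grDevices::hcl.colors(max(2L, length(unique(lab))), "Dark 3")
    col <- pal[lab - min(lab) + 1L]
    graphics::plot(emb[, 1L], emb[, 2L], col = col, pch = 19, cex = 0.7,
                   xlab = "dim 1", ylab = "dim 2",
                   main = paste0(values$method, " (k=", k, ")"))
    for (g in unique(lab)) {
      pts <- emb[lab == g, , drop = FALSE]
      if (nrow(pts) >= 3L) {
        hull <- grDevices::chull(pts)
        graphics::polygon(pts[hull, 1L], pts[hull, 2L], border =
                            pal[g - min(lab) + 1L], lty = 2)
      }
    }
  }
  list(tables = list(cluster_ids = cluster_ids, quality_criteria = quality),
       image = image_fn)
}

#' The clustering demo app
#'
#' Bundles [clustering_run()] with its manifest: four clustering methods
#' (k-means, spectral, hierarchical, DBSCAN), the cluster count `k` in
#' `[2, 20]`, the k-means `algorithm`, the hierarchical `agglomeration`
#' linkage (ward, complete, average, single, median, centroid), the
#' spectral `kernel`, the DBSCAN `eps`/`min_pts`, the gap-statistic
#' reference count `gap_B`, and an explicit `seed` so sessions are
#' reproducible end to end. Emits the `cluster_ids` and `quality_criteria`
#' tables plus a 2-D embedding image per run.
#'
#' @param features Optional explicit feature column names for clustering.
#' @return A [ps_app()].
#' @export
clustering_demo_app <- function(features = NULL) {
  manifest <- ps_manifest(
    "clustering",
    list(
      ps_param("method", "categorical", "kmeans",
               items = c("kmeans", "spectral", "hierarchical", "dbscan")),
      ps_param("k", "integer", 4, min = 2, max = 20,
               info = "number of clusters (ignored by dbscan)"),
      ps_param("algorithm", "categorical", "Hartigan-Wong",
               items = c("Hartigan-Wong", "Lloyd", "MacQueen"),
               depends_on = "method"),
      ps_param("agglomeration", "categorical", "ward",
               items = c("ward", "complete", "average", "single", "median",
                         "centroid"), depends_on = "method"),
      ps_param("kernel", "categorical", "rbfdot",
               items = c("rbfdot", "laplacedot", "polydot", "vanilladot"),
               depends_on = "method"),
      ps_param("eps", "double", 2.5, min = 0.1, max = 20),
      ps_param("min_pts", "integer", 5, min = 1, max = 50),
      ps_param("gap_B", "integer", 10, min = 1, max = 50,
               info = "reference datasets for the gap statistic"),
      ps_param("seed", "integer", 0, min = 0, max = 1e9)
    ),
    output_tables = c("cluster_ids", "quality_criteria"),
    emits_image = TRUE)
  ps_app(manifest, function(input, values)
    clustering_run(input, values, features = features))
}
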