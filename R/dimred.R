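# Shared 2-D embedding backend for the dimred derivation pass and the
# DimRed demo app. PCA via prcomp, metric MDS via cmdscale on Euclidean
# distances, t-SNE via Rtsne (exact, seeded).
embed_2d <- function(mat, method = c("pca", "mds", "tsne"), seed = 0L,
                     perplexity = NULL) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  n <- nrow(mat)
  if (n < 2L) abort("embedding requires at least 2 rows")
  if (method == "pca") {
    # constant columns carry no information; prcomp scales only centers
    pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
    k <- ncol(pc$x)
    out <- cbind(pc$x[, 1L],
                 if (k >= 2L) pc$x[, 2L] else rep(0, n))
  } else if (method == "mds") {
    d <- stats::dist(mat)
    out <- stats::cmdscale(d, k = 2L)
    if (ncol(out) < 2L) out <- cbind(out, rep(0, n))
  } else {
    # default perplexity 30, capped so 3 * perplexity < n
    perp <- perplexity %||% 30
    perp <- max(1, min(perp, (n - 1) / 3))
    out <- with_seed(seed,
      Rtsne::Rtsne(mat, dims = 2L, perplexity = perp,
                   check_duplicates = FALSE, pca = TRUE, theta = 0.0,
                   max_iter = 500L, verbose = FALSE)$Y)
  }
  colnames(out) <- NULL
  unname(out[, 1:2, drop = FALSE])
}

#' Append 2-D projections of selected columns to a data table
#'
#' The dimensionality-reduction demo app: computes a two-dimensional
#' projection of the selected numeric columns per requested method and
#' appends the coordinates as new columns (`pca1`/`pca2`, `mds1`/`mds2`,
#' `tsne1`/`tsne2`), e.g., six new columns when all three methods are
#' requested. Typically run once on an input table before a clustering
#' sweep so every run's image can reuse the same embedding.
#'
#' @param table A data frame.
#' @param columns Character vector of numeric columns to project; `NULL`
#'   selects all numeric columns.
#' @param methods Subset of `c("pca", "mds", "tsne")`.
#' @param seed Seed for the stochastic methods.
#' @param perplexity Optional t-SNE perplexity (default 30, capped at
#'   `(n - 1) / 3`).
#' @return `table` with `2 * length(methods)` appended columns.
#' @export
dimred_app <- function(table, columns = NULL,
                       methods = c("pca", "mds", "tsne"), seed = 0L,
                       perplexity = NULL) {
  stopifnot(is.data.frame(table))
  methods <- match.arg(methods, several.ok = TRUE)
  cols <- columns %||% names(table)[vapply(table, is.numeric, TRUE)]
  bad <- setdiff(cols, names(table))
  if (length(bad))
    abort("table has no column(s): ", paste(bad, collapse = ", "))
  mat <- as.matrix(table[cols])
  if (!is.numeric(mat)) abort("selected columns must be numeric")
  if (nrow(mat) < 3L) abort("dimred_app requires at least 3 rows")
  for (m in methods) {
    emb <- embed_2d(mat, m, seed = seed, perplexity = perplexity)
    table[[paste0(m, "1")]] <- emb[, 1L]
    table[[paste0(m, "2")]] <- emb[, 2L]
  }
  table
}
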