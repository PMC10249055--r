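#' Declare a run filter
#'
#' The headless counterpart of histogram brushing: a numeric filter keeps
#' runs whose column value lies in the closed interval `[lo, hi]`, a
#' categorical filter keeps runs whose value is in `values`. Filters
#' compose by conjunction in [apply_filters()].
#'
#' @param column Runs-table column name.
#' @param lo,hi Closed interval bounds (numeric filter).
#' @param values Kept category values (categorical filter; non-empty).
#' @return A `ps_filter` object.
#' @export
ps_filter <- function(column, lo = NULL, hi = NULL, values = NULL) {
  numeric_f <- !is.null(lo) || !is.null(hi)
  if (numeric_f && !is.null(values))
    abort("give either an interval or a value set, not both")
  if (numeric_f) {
    lo <- lo %||% -Inf; hi <- hi %||% Inf
    if (lo > hi) abort("filter on '", column, "': lo > hi")
  } else if (is.null(values) || length(values) == 0L) {
    abort("filter on '", column, "': value set must be non-empty")
  }
  structure(list(column = column, lo = lo, hi = hi, values = values),
            class = "ps_filter")
}

#' Filter runs by conjunction of predicates
#'
#' @param runs_info A runs-table data frame (or a `ps_runs` handle).
#' @param filters List of [ps_filter()] objects (a single filter is
#'   accepted); the empty list keeps all runs.
#' @param drop_missing Drop runs with a missing value in any filtered
#'   column (they cannot satisfy a predicate); the number dropped is
#'   reported via `message()`.
#' @return The kept run ids, in increasing `run_id` order.
#' @export
apply_filters <- function(runs_info, filters = list(), drop_missing = TRUE) {
  if (inherits(runs_info, "ps_runs")) runs_info <- runs_info$runs_info
  if (inherits(filters, "ps_filter")) filters <- list(filters)
  keep <- rep(TRUE, nrow(runs_info))
  n_missing <- 0L
  for (f in filters) {
    if (!f$column %in% names(runs_info))
      abort("unknown column '", f$column, "'; available: ",
            paste(names(runs_info), collapse = ", "))
    x <- runs_info[[f$column]]
    miss <- is.na(x)
    n_missing <- n_missing + sum(miss & keep)
    ok <- if (!is.null(f$values)) as.character(x) %in% as.character(f$values)
          else x >= f$lo & x <= f$hi
    keep <- keep & !miss & ok
  }
  if (n_missing > 0L)
    message(n_missing, " run(s) dropped for missing values in filtered ",
            "columns")
  sort(runs_info$run_id[keep])
}

#' Histogram summary of one runs-table column
#'
#' Numeric columns are binned (Sturges' rule by default, matching the
#' distribution-view bar plots); categorical columns get one bar per value.
#'
#' @param runs_info Runs-table data frame or `ps_runs` handle.
#' @param column Column name.
#' @param bins Number of bins for numeric columns (`NULL` = Sturges).
#' @return A list with `column`, `type`, `counts` (named for categorical
#'   columns), `breaks` (numeric only) and `n_missing`. Counts sum to the
#'   number of non-missing rows.
#' @export
ps_histogram <- function(runs_info, column, bins = NULL) {
  if (inherits(runs_info, "ps_runs")) runs_info <- runs_info$runs_info
  if (!column %in% names(runs_info))
    abort("unknown column '", column, "'; available: ",
          paste(names(runs_info), collapse = ", "))
  x <- runs_info[[column]]
  n_missing <- sum(is.na(x))
  x <- x[!is.na(x)]
  if (!length(x)) {
    warning("column '", column, "' has no non-missing values")
    return(list(column = column, type = "empty", counts = integer(),
                breaks = NULL, n_missing = n_missing))
  }
  if (is.numeric(x)) {
    nb <- bins %||% grDevices::nclass.Sturges(x)
    if (min(x) == max(x)) {
      # constant column: a single bin holding every run
      return(list(column = column, type = "numeric",
                  counts = stats::setNames(length(x), format(min(x))),
                  breaks = c(min(x), max(x)), n_missing = n_missing))
    }
    breaks <- seq(min(x), max(x), length.out = nb + 1L)
    h <- graphics::hist(x, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE, right = TRUE)
    list(column = column, type = "numeric", counts = h$counts,
         breaks = h$breaks, n_missing = n_missing)
  } else {
    tb <- table(as.character(x))
    list(column = column, type = "categorical",
         counts = stats::setNames(as.integer(tb), names(tb)),
         breaks = NULL, n_missing = n_missing)
  }
}

#' Pareto frontier of runs
#'
#' A run is on the frontier iff no other run is at least as good on every
#' axis and strictly better on at least one (weak dominance with strict
#' improvement); exact ties on all axes keep both runs. Runs with a missing
#' value on any axis are excluded before the dominance test.
#'
#' @param runs_info Runs-table data frame or `ps_runs` handle.
#' @param axes Named character vector or list mapping column name to
#'   direction, e.g. `c(fp = "minimize", tp = "maximize")`; at least two
#'   axes.
#' @return Run ids of the non-dominated runs (increasing order).
#' @export
pareto_front <- function(runs_info, axes) {
  if (inherits(runs_info, "ps_runs")) runs_info <- runs_info$runs_info
  axes <- unlist(axes)
  if (length(axes) < 2L) abort("pareto_front requires at least 2 axes")
  if (!all(axes %in% c("minimize", "maximize")))
    abort("axis directions must be 'minimize' or 'maximize'")
  missing_cols <- setdiff(names(axes), names(runs_info))
  if (length(missing_cols))
    abort("unknown column(s): ", paste(missing_cols, collapse = ", "))
  # orient every axis to "larger is better"
  m <- sapply(names(axes), function(cn) {
    x <- as.numeric(runs_info[[cn]])
    if (axes[[cn]] == "minimize") -x else x
  })
  m <- matrix(m, ncol = length(axes))
  ok <- stats::complete.cases(m)
  ids <- runs_info$run_id[ok]
  m <- m[ok, , drop = FALSE]
  n <- nrow(m)
  if (n == 0L) return(integer())
  # lexicographic descending sort: a dominating point always precedes the
  # point it dominates, so only earlier points need checking
  ord <- do.call(order, c(lapply(seq_len(ncol(m)), function(j) m[, j]),
                          list(decreasing = TRUE)))
  m <- m[ord, , drop = FALSE]
  ids <- ids[ord]
  nondom <- logical(n)
  for (i in seq_len(n)) {
    if (i == 1L) { nondom[1L] <- TRUE; next }
    prev <- m[seq_len(i - 1L), , drop = FALSE]
    ge <- prev >= matrix(m[i, ], i - 1L, ncol(m), byrow = TRUE)
    gt <- prev > matrix(m[i, ], i - 1L, ncol(m), byrow = TRUE)
    dominated <- any(rowSums(ge) == ncol(m) & rowSums(gt) > 0L)
    nondom[i] <- !dominated
  }
  sort(ids[nondom])
}

#' Default orientation registry for the cluster validity indices
#'
#' Maps each metric consumed by [normalized_mean_quality()] to whether a
#' higher value indicates a better clustering: Calinski-Harabasz,
#' silhouette and the gap statistic reward separation (higher is better);
#' Davies-Bouldin and S_Dbw are dispersion ratios (lower is better).
#' Override any entry by passing a modified copy.
#'
#' @return Named logical vector, `TRUE` = higher is better.
#' @export
metric_direction_registry <- function() {
  c(calinski_harabasz = TRUE, silhouette = TRUE, davies_bouldin = FALSE,
    gap = TRUE, s_dbw = FALSE)
}

#' Mean normalized quality aggregate
#'
#' Each metric column is min-max normalized to `[0, 1]` over the
#' non-missing runs, inverted when its registry entry says lower is better,
#' and the per-run mean across metrics is returned as one aggregate column.
#' A constant metric column carries no ranking information and is set to
#' 0.5 everywhere (with a warning).
#'
#' @param runs_info Runs-table data frame or `ps_runs` handle.
#' @param metric_columns Character vector of numeric metric columns.
#' @param registry Named logical vector mapping every metric column to
#'   higher-is-better; defaults to [metric_direction_registry()].
#' @param name Name of the aggregate column.
#' @return `runs_info` with the aggregate column appended.
#' @export
normalized_mean_quality <- function(runs_info, metric_columns,
                                    registry = metric_direction_registry(),
                                    name = "mean_normalized_quality") {
  if (inherits(runs_info, "ps_runs")) runs_info <- runs_info$runs_info
  missing_cols <- setdiff(metric_columns, names(runs_info))
  if (length(missing_cols))
    abort("unknown metric column(s): ", paste(missing_cols, collapse = ", "))
  unreg <- setdiff(metric_columns, names(registry))
  if (length(unreg))
    abort("metric(s) not in the direction registry: ",
          paste(unreg, collapse = ", "))
  norm <- sapply(metric_columns, function(cn) {
    x <- as.numeric(runs_info[[cn]])
    rng <- range(x, na.rm = TRUE)
    if (!is.finite(rng[1L]) || rng[1L] == rng[2L]) {
      warning("metric '", cn, "' is constant; normalized to 0.5")
      v <- ifelse(is.na(x), NA_real_, 0.5)
    } else {
      v <- (x - rng[1L]) / (rng[2L] - rng[1L])
    }
    if (!registry[[cn]]) v <- 1 - v
    v
  })
  runs_info[[name]] <- rowMeans(matrix(norm, ncol = length(metric_columns)),
                                na.rm = FALSE)
  runs_info
}

#' Convert confusion counts to ROC rates in percent
#'
#' Helper for reading ground-truth comparison counts as rates: with the
#' class totals known (e.g., 69 true-DE and 23 null spike-ins), a run with
#' 60 true positives and 1 false positive has TPR 87% and FPR 4%.
#'
#' @param tp,fp Per-run true/false positive counts (vectors).
#' @param n_positive,n_negative Ground-truth class totals.
#' @param digits Rounding for the returned percentages (default whole
#'   percent).
#' @return Data frame with columns `tpr_percent`, `fpr_percent`.
#' @export
roc_rates <- function(tp, fp, n_positive, n_negative, digits = 0) {
  data.frame(tpr_percent = round(100 * tp / n_positive, digits),
             fpr_percent = round(100 * fp / n_negative, digits))
}

#' Export a static exploration report
#'
#' Replaces the interactive exploration views with a directory of static
#' artifacts: per-column histograms, configured scatter plots (any two
#' columns, optionally colored by a third, with seeded render-time jitter
#' for categorical axes), the filtered runs table, the Pareto front table,
#' thumbnails of selected runs' images, and a single `index.html`.
#'
#' @param rd A `ps_runs` handle.
#' @param out_dir Report directory (created if needed).
#' @param filters Optional list of [ps_filter()]s applied first.
#' @param scatters List of scatter configs, each
#'   `list(x = , y = , color = NULL, jitter = FALSE)`.
#' @param histogram_columns Columns to summarize as histograms (default:
#'   all runs-table columns except `run_id`).
#' @param pareto Optional axes spec as in [pareto_front()].
#' @param selected_ids Run ids whose images are copied as thumbnails; a
#'   missing image produces a placeholder entry with a warning.
#' @param seed Seed for render-time jitter.
#' @return `out_dir`, invisibly. The report's tables: `runs.txt` (filtered
#'   runs table) and `pareto.txt` when a Pareto spec is given.
#' @export
export_report <- function(rd, out_dir, filters = list(), scatters = list(),
                          histogram_columns = NULL, pareto = NULL,
                          selected_ids = integer(), seed = 0L) {
  stopifnot(inherits(rd, "ps_runs"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- apply_filters(rd$runs_info, filters)
  ri <- rd$runs_info[rd$runs_info$run_id %in% ids, , drop = FALSE]
  write_tsv(ri, file.path(out_dir, "runs.txt"))
  items <- character()

  hist_cols <- histogram_columns %||% setdiff(names(ri), "run_id")
  for (cn in hist_cols) {
    if (nrow(ri) == 0L) break
    fp <- file.path(out_dir, paste0("hist_", gsub("[^A-Za-z0-9_]", "_", cn),
                                    ".png"))
    h <- suppressWarnings(ps_histogram(ri, cn))
    grDevices::png(fp, width = 480, height = 360)
    if (h$type == "numeric" && length(h$counts) > 1L)
      graphics::hist(ri[[cn]][!is.na(ri[[cn]])], breaks = h$breaks,
                     main = cn, xlab = cn, col = "grey70")
    else
      graphics::barplot(h$counts, main = cn, col = "grey70", las = 2)
    grDevices::dev.off()
    items <- c(items, basename(fp))
  }

  jit <- function(x, do) {
    if (!do) return(x)
    with_seed(seed, x + stats::runif(length(x), -0.2, 0.2))
  }
  for (sc in scatters) {
    need <- c(sc$x, sc$y, sc$color)
    miss <- setdiff(need, names(ri))
    if (length(miss))
      abort("scatter references missing column(s): ",
            paste(miss, collapse = ", "))
    if (nrow(ri) == 0L) break
    fp <- file.path(out_dir, paste0(
      "scatter_", gsub("[^A-Za-z0-9_]", "_", paste(sc$x, sc$y, sep = "_")),
      ".png"))
    xs <- ri[[sc$x]]; ys <- ri[[sc$y]]
    xn <- if (is.numeric(xs)) xs else as.integer(factor(xs))
    yn <- if (is.numeric(ys)) ys else as.integer(factor(ys))
    do_jit <- isTRUE(sc$jitter)
    col <- "grey30"; leg <- NULL
    if (!is.null(sc$color)) {
      cf <- factor(ri[[sc$color]])
      pal <- grDevices::hcl.colors(max(2L, nlevels(cf)), "Dark 3")
      col <- pal[as.integer(cf)]
      leg <- list(levels = levels(cf), pal = pal[seq_len(nlevels(cf))])
    }
    grDevices::png(fp, width = 540, height = 480)
    graphics::plot(jit(xn, do_jit && !is.numeric(xs)),
                   jit(yn, do_jit && !is.numeric(ys)),
                   xlab = sc$x, ylab = sc$y, col = col, pch = 19,
                   xlim = sc$xlim %||% NULL, ylim = sc$ylim %||% NULL,
                   main = paste(sc$y, "vs", sc$x))
    if (!is.null(leg))
      graphics::legend("topright", legend = leg$levels, col = leg$pal,
                       pch = 19, cex = 0.8, title = sc$color)
    grDevices::dev.off()
    items <- c(items, basename(fp))
  }

  if (!is.null(pareto)) {
    pf <- if (nrow(ri)) pareto_front(ri, pareto) else integer()
    write_tsv(ri[ri$run_id %in% pf, , drop = FALSE],
              file.path(out_dir, "pareto.txt"))
    items <- c(items, "pareto.txt")
  }

  for (id in selected_ids) {
    src <- run_image_path(rd, id)
    dst <- file.path(out_dir, paste0("run_", id, ".png"))
    if (is.na(src)) {
      warning("no image for run ", id, "; writing placeholder")
      grDevices::png(dst, width = 200, height = 200)
      graphics::plot.new()
      graphics::text(0.5, 0.5, paste("run", id, "\n(no image)"))
      grDevices::dev.off()
    } else {
      file.copy(src, dst, overwrite = TRUE)
    }
    items <- c(items, basename(dst))
  }

  html <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
            "<title>psweep report</title></head><body>",
            paste0("<h1>psweep report</h1><p>", nrow(ri),
                   " run records after filtering.</p>"),
            "<p><a href='runs.txt'>runs.txt</a></p>",
            vapply(items, function(it) {
              if (grepl("\\.png$", it))
                paste0("<div><h3>", it, "</h3><img src='", it, "'></div>")
              else paste0("<p><a href='", it, "'>", it, "</a></p>")
            }, ""),
            "</body></html>")
  writeLines(html, file.path(out_dir, "index.html"))
  invisible(out_dir)
}
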