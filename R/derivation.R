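#' Declare a derivation pass
#'
#' A derivation pass maps each run's raw output table to one or more
#' scalar/categorical values that are appended to the runs table as named
#' columns. Available methods:
#' \describe{
#'   \item{aggregates}{`mean`, `sum`, `median`, `min`, `max` over a numeric
#'     column; appends `<fn>_<column>`.}
#'   \item{`n_class_labels`}{number of distinct labels in a column; appends
#'     `Num(<table>)`.}
#'   \item{`mode_class_labels`}{most frequent label; appends
#'     `mode_<column>`.}
#'   \item{`count_per_class_label`}{per-label occurrence counts; appends one
#'     `n(<column> = <label>)` column per label observed in any run
#'     (zero-filled where a run lacks the label).}
#'   \item{`gt_comparison`}{cross-tabulates a boolean prediction column
#'     against a `{TRUE, FALSE, NA}` ground-truth column of the session
#'     input; appends the six `n(<pred> = <P> & <gt> = <G>)` count columns.}
#'   \item{`dimred_pca` / `dimred_mds` / `dimred_tsne`}{flattens each run's
#'     selected numeric columns into one feature vector, embeds the
#'     runs-by-features matrix in 2-D, and appends `<method>1(<table>)`,
#'     `<method>2(<table>)`.}
#'   \item{`take_first_row`}{appends the first row of the table under the
#'     table's own column names (the hook by which models self-report
#'     custom derived output).}
#'   \item{`none`}{no-op, for directories whose runs table already carries
#'     derived columns.}
#' }
#'
#' @param method Method name (see above).
#' @param table Output table name the pass reads.
#' @param columns Selected column name(s); `NULL` selects all numeric
#'   columns for dimred methods and the single column of one-column tables.
#' @param gt_column Input-table ground-truth column (`gt_comparison` only).
#' @param options Method-specific settings (e.g., `seed`, `perplexity` for
#'   `dimred_tsne`).
#' @return A `ps_pass` object.
#' @export
derivation_pass <- function(method, table = NULL, columns = NULL,
                            gt_column = NULL, options = list()) {
  methods <- c("mean", "sum", "median", "min", "max", "n_class_labels",
               "mode_class_labels", "count_per_class_label", "gt_comparison",
               "dimred_pca", "dimred_mds", "dimred_tsne", "take_first_row",
               "none")
  if (!method %in% methods)
    abort("unknown derivation method '", method, "'")
  if (method == "none") {
    if (!is.null(table) || !is.null(columns) || !is.null(gt_column))
      abort("method 'none' takes no table or columns")
  } else if (is.null(table)) {
    abort("method '", method, "' requires an output table name")
  }
  if (method == "gt_comparison" &&
      (is.null(columns) || length(columns) != 1L || is.null(gt_column)))
    abort("gt_comparison requires one prediction column and one gt_column")
  structure(list(method = method, table = table, columns = columns,
                 gt_column = gt_column, options = options),
            class = "ps_pass")
}

pass_signature <- function(pass) {
  paste(pass$method, pass$table %||% "", paste(pass$columns, collapse = ","),
        pass$gt_column %||% "", sep = "|")
}

ok_run_ids <- function(rd) {
  ri <- rd$runs_info
  ids <- ri$run_id
  if ("status" %in% names(ri)) ids[ri$status == "ok"] else ids
}

# Read the pass's table for every ok run once; NULL for missing/failed.
collect_tables <- function(rd, table) {
  ids <- rd$runs_info$run_id
  ok <- ids %in% ok_run_ids(rd)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    if (!ok[[i]]) next
    fp <- file.path(rd$path, "runs", paste0(table, "_", ids[[i]], ".txt"))
    if (file.exists(fp)) out[[i]] <- read_tsv(fp)
  }
  names(out) <- as.character(ids)
  out
}

pick_column <- function(tab, column, table, method) {
  if (is.null(tab)) return(NULL)
  if (is.null(column)) {
    if (ncol(tab) != 1L)
      abort("method '", method, "' on table '", table,
            "': column must be named when the table has ", ncol(tab),
            " columns")
    return(tab[[1L]])
  }
  if (!column %in% names(tab))
    abort("table '", table, "' has no column '", column, "'")
  tab[[column]]
}

derive_columns <- function(rd, pass, tabs = NULL) {
  method <- pass$method
  if (method == "none")
    return(list(labels = character(), values = NULL))
  if (is.null(tabs)) tabs <- collect_tables(rd, pass$table)
  switch(method,
    mean = , sum = , median = , min = , max =
      derive_aggregate_cols(rd, pass, tabs),
    n_class_labels = , mode_class_labels = , count_per_class_label =
      derive_label_cols(rd, pass, tabs),
    gt_comparison = derive_gt_cols(rd, pass, tabs),
    dimred_pca = , dimred_mds = , dimred_tsne =
      derive_dimred_cols(rd, pass, tabs),
    take_first_row = derive_first_row_cols(rd, pass, tabs))
}

derive_aggregate_cols <- function(rd, pass, tabs) {
  fn <- match.fun(pass$method)
  vals <- vapply(seq_along(tabs), function(i) {
    x <- pick_column(tabs[[i]], pass$columns, pass$table, pass$method)
    if (is.null(x)) return(NA_real_)
    if (!is.numeric(x))
      abort("run ", names(tabs)[[i]], ": column '", pass$columns,
            "' of table '", pass$table, "' is not numeric",
            class = "psweep_type_error")
    as.numeric(fn(x))
  }, numeric(1))
  lab <- paste0(pass$method, "_", pass$columns %||%
                  names(tabs[[which(!vapply(tabs, is.null, TRUE))[1L]]])[1L])
  list(labels = lab, values = stats::setNames(list(vals), lab))
}

derive_label_cols <- function(rd, pass, tabs) {
  cols <- lapply(tabs, function(t)
    pick_column(t, pass$columns, pass$table, pass$method))
  colname <- pass$columns %||% "value"
  if (pass$method == "n_class_labels") {
    lab <- paste0("Num(", pass$table, ")")
    vals <- vapply(cols, function(x) {
      if (is.null(x) || length(x) == 0L) NA_real_
      else as.numeric(length(unique(x[!is.na(x)])))
    }, numeric(1))
    return(list(labels = lab, values = stats::setNames(list(vals), lab)))
  }
  if (pass$method == "mode_class_labels") {
    lab <- paste0("mode_", colname)
    vals <- vapply(cols, function(x) {
      if (is.null(x) || length(x) == 0L) return(NA_character_)
      tb <- table(x)
      names(tb)[which.max(tb)]
    }, character(1))
    return(list(labels = lab, values = stats::setNames(list(vals), lab)))
  }
  # count_per_class_label: label universe is the union over all runs so the
  # runs table stays rectangular; absent labels count 0, missing runs NA.
  universe <- sort(unique(unlist(lapply(cols, function(x)
    as.character(x[!is.na(x)])))))
  labs <- paste0("n(", colname, " = ", universe, ")")
  values <- lapply(universe, function(lv) {
    vapply(cols, function(x) {
      if (is.null(x)) NA_real_ else as.numeric(sum(as.character(x) == lv,
                                                   na.rm = TRUE))
    }, numeric(1))
  })
  list(labels = labs, values = stats::setNames(values, labs))
}

# "NA" as a truth category is a first-class level, printed literally in the
# derived column names.
gt_levels <- c("TRUE", "FALSE", "NA")

derive_gt_cols <- function(rd, pass, tabs) {
  if (is.null(rd$input))
    abort("gt_comparison requires the session input table (input.txt)")
  if (!pass$gt_column %in% names(rd$input))
    abort("input table has no ground-truth column '", pass$gt_column, "'")
  gt <- rd$input[[pass$gt_column]]
  gt_chr <- ifelse(is.na(gt), "NA", ifelse(as.logical(gt), "TRUE", "FALSE"))
  pred_name <- pass$columns
  grid <- expand.grid(P = c("TRUE", "FALSE"), G = gt_levels,
                      stringsAsFactors = FALSE)
  labs <- paste0("n(", pred_name, " = ", grid$P, " & ", pass$gt_column,
                 " = ", grid$G, ")")
  values <- stats::setNames(rep(list(rep(NA_real_, length(tabs))), nrow(grid)),
                            labs)
  for (i in seq_along(tabs)) {
    x <- pick_column(tabs[[i]], pred_name, pass$table, "gt_comparison")
    if (is.null(x)) next
    if (length(x) != length(gt))
      abort("run ", names(tabs)[[i]], ": table '", pass$table, "' has ",
            length(x), " rows but the input ground truth has ", length(gt))
    px <- ifelse(as.logical(x), "TRUE", "FALSE")
    for (j in seq_len(nrow(grid)))
      values[[j]][[i]] <- sum(px == grid$P[[j]] & gt_chr == grid$G[[j]])
  }
  list(labels = labs, values = values)
}

derive_dimred_cols <- function(rd, pass, tabs) {
  method <- sub("^dimred_", "", pass$method)
  have <- which(!vapply(tabs, is.null, TRUE))
  if (length(have) < 2L)
    abort("dimred derivation requires at least 2 complete runs")
  feats <- lapply(tabs[have], function(t) {
    cols <- pass$columns %||%
      names(t)[vapply(t, is.numeric, TRUE)]
    bad <- setdiff(cols, names(t))
    if (length(bad)) abort("table '", pass$table, "' has no column(s) ",
                           paste(bad, collapse = ", "))
    as.numeric(unlist(t[cols], use.names = FALSE))
  })
  lens <- lengths(feats)
  if (length(unique(lens)) != 1L)
    abort("dimred derivation: runs have unequal flattened lengths (",
          paste(sort(unique(lens)), collapse = " vs "), ")")
  mat <- do.call(rbind, feats)
  emb <- embed_2d(mat, method,
                  seed = pass$options$seed %||% 0L,
                  perplexity = pass$options$perplexity)
  labs <- paste0(method, 1:2, "(", pass$table, ")")
  v1 <- rep(NA_real_, length(tabs)); v2 <- v1
  v1[have] <- emb[, 1L]; v2[have] <- emb[, 2L]
  list(labels = labs, values = stats::setNames(list(v1, v2), labs))
}

derive_first_row_cols <- function(rd, pass, tabs) {
  have <- which(!vapply(tabs, is.null, TRUE))
  if (!length(have)) abort("take_first_row: no run has table '", pass$table,
                           "'")
  labs <- names(tabs[[have[[1L]]]])
  values <- lapply(labs, function(cn) {
    sapply(tabs, function(t) {
      if (is.null(t) || nrow(t) == 0L || !cn %in% names(t)) NA
      else t[[cn]][[1L]]
    })
  })
  list(labels = labs, values = stats::setNames(values, labs))
}

#' Apply derivation passes to a runs directory
#'
#' Computes each pass over every run's output and appends the resulting
#' columns to the runs table, in pass order. Re-running a pass replaces the
#' columns it produced earlier (recorded in `derived_columns.json`) rather
#' than duplicating them; parameter columns are never overwritten.
#' `runsInfo.txt` is rewritten atomically; files under `runs/` are never
#' modified.
#'
#' @param rd A `ps_runs` handle from [load_runs_directory()].
#' @param passes A list of [derivation_pass()] objects (or a single one).
#' @param quiet Suppress the appended-column message.
#' @return The updated `ps_runs` handle (with refreshed `runs_info`).
#' @export
apply_passes <- function(rd, passes, quiet = TRUE) {
  if (inherits(passes, "ps_pass")) passes <- list(passes)
  stopifnot(all(vapply(passes, inherits, TRUE, "ps_pass")))
  prov_path <- file.path(rd$path, "derived_columns.json")
  prov <- if (file.exists(prov_path)) read_json_file(prov_path) else list()
  param_cols <- if (!is.null(rd$param_info)) rd$param_info$name else character()
  reserved <- c("run_id", param_cols, "status", "duration_seconds")

  ri <- rd$runs_info
  for (pass in passes) {
    if (pass$method == "none") next
    if (!is.null(rd$manifest) && length(rd$manifest$output_tables) &&
        !pass$table %in% rd$manifest$output_tables)
      abort("pass reads undeclared table '", pass$table, "'; declared: ",
            paste(rd$manifest$output_tables, collapse = ", "))
    sig <- pass_signature(pass)
    old <- unlist(prov[[sig]])
    if (length(old)) ri <- ri[, !(names(ri) %in% old), drop = FALSE]
    dc <- derive_columns(rd, pass)
    clash <- intersect(dc$labels, reserved)
    if (length(clash))
      abort("derived column(s) would overwrite parameter columns: ",
            paste(clash, collapse = ", "))
    ri <- ri[, !(names(ri) %in% dc$labels), drop = FALSE]
    for (lab in dc$labels) ri[[lab]] <- dc$values[[lab]]
    prov[[sig]] <- as.list(dc$labels)
    if (!quiet)
      message("pass ", pass$method, ": appended ",
              paste(dc$labels, collapse = ", "))
  }
  write_tsv_atomic(ri, runs_info_path(rd$path))
  write_json_file(prov, prov_path)
  write_json_file(lapply(passes, unclass),
                  file.path(rd$path, "derivation_plan.json"))
  rd$runs_info <- read_tsv(runs_info_path(rd$path))
  rd
}

#' Read a derivation plan from JSON
#'
#' The plan format is a JSON array of pass objects with fields `method`,
#' `table`, `columns`, `gt_column`, `options`, as written by
#' [apply_passes()] to `derivation_plan.json`.
#'
#' @param path JSON file path.
#' @return List of [derivation_pass()] objects.
#' @export
read_derivation_plan <- function(path) {
  doc <- read_json_file(path)
  lapply(doc, function(d)
    derivation_pass(d$method, table = d$table,
                    columns = if (!is.null(d$columns)) unlist(d$columns),
                    gt_column = d$gt_column,
                    options = d$options %||% list()))
}
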