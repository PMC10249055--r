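#' Define a model app
#'
#' A model app couples a manifest to a run function. The run function
#' receives the session input table and one parameter combination (a named
#' list) and must return a list with:
#' \describe{
#'   \item{`tables`}{named list of data frames, one per declared output
#'     table;}
#'   \item{`image`}{(only if the manifest declares `emits_image`) a
#'     function that draws the run's image; the session runner opens a PNG
#'     device at `images/<id>.png` before calling it and closes it after;}
#'   \item{`records`}{optional data frame of per-run records; when present,
#'     each of its rows becomes one row of `runsInfo.txt` (sharing the
#'     run's parameter values), which is how apps that checkpoint a single
#'     training run at several epochs report one record per checkpoint.}
#' }
#'
#' @param manifest A [ps_manifest()].
#' @param run `function(input, values) -> list(tables = , image = , records = )`.
#' @param record_columns Optional character vector naming the columns of the
#'   `records` data frame (fixes the runsInfo header up front).
#' @return A `ps_app` object.
#' @export
ps_app <- function(manifest, run, record_columns = NULL) {
  stopifnot(inherits(manifest, "ps_manifest"), is.function(run))
  structure(list(manifest = manifest, run = run,
                 record_columns = record_columns),
            class = "ps_app")
}

#' Draw one parameter combination
#'
#' Uniform random sampling: integer ranges are drawn uniformly on the
#' closed integer interval `[lo, hi]`, doubles uniformly on `[lo, hi]`,
#' boolean/categorical parameters uniformly over the enabled set, and
#' constants are passed through. Draw `i` is a pure function of
#' `(spec$seed, i)`, so streams are reproducible and resumable.
#'
#' @param spec A validated sampling spec.
#' @param draw_index Zero-based draw counter within the session.
#' @return Named list of concrete parameter values.
#' @export
sample_combination <- function(spec, draw_index) {
  stopifnot(draw_index >= 0)
  with_seed(mix_seed(spec$seed, draw_index), {
    vals <- lapply(spec$directives, function(d) {
      switch(d$mode,
        constant = d$value,
        numeric_range = {
          if (is_integer_directive(spec, d))
            d$lo + floor(stats::runif(1) * (d$hi - d$lo + 1))
          else stats::runif(1, d$lo, d$hi)
        },
        boolean_set = ,
        categorical_set = d$enabled[[
          1L + floor(stats::runif(1) * length(d$enabled))]])
    })
    names(vals) <- names(spec$directives)
    vals
  })
}

# A spec does not carry kinds; treat whole-numbered bounds on both ends as
# an integer range only when the stored directive says so. Specs built via
# set_range() against a manifest keep kind in the manifest, so run_session
# resolves kinds there; standalone use falls back to bound inspection.
is_integer_directive <- function(spec, d) {
  kind <- attr(spec, "kinds")[[d$parameter]]
  if (!is.null(kind)) return(kind == "integer")
  d$lo == round(d$lo) && d$hi == round(d$hi) &&
    !is.null(attr(d, "integer")) && isTRUE(attr(d, "integer"))
}

bind_kinds <- function(manifest, spec) {
  attr(spec, "kinds") <- vapply(manifest$parameters, `[[`, "", "kind")
  spec
}

runs_info_path <- function(dir) file.path(dir, "runsInfo.txt")

# Serialize one parameter value for a runsInfo/paramInfo cell.
fmt_value <- function(v) {
  if (is.logical(v)) return(if (v) "TRUE" else "FALSE")
  if (is.numeric(v)) return(format(v, digits = 15, scientific = FALSE,
                                   trim = TRUE))
  as.character(v)
}

#' Execute a sampling session into a runs directory
#'
#' Draws `spec$n_runs` parameter combinations, executes the app for each,
#' and persists everything in the standard session layout: `input.txt` (the
#' input table), `paramInfo.txt` (parameter name and type), `runsInfo.txt`
#' (one row per run record: run id, parameter values, status, duration),
#' `runs/` (one TSV per declared output table per run, named
#' `<Table>_<id>.txt`) and `images/` (`<id>.png` per run for image-emitting
#' apps). Run ids are sequential integers from 0. A run whose app raises an
#' error is recorded with status `"failed"` and the session continues.
#' `runsInfo.txt` is appended record-by-record, so an interrupted session
#' remains loadable and resumable.
#'
#' @param app A [ps_app()].
#' @param input Input data frame handed to every run.
#' @param spec A sampling spec with `out_dir` set.
#' @param quiet Suppress progress messages.
#' @return A `ps_runs` handle for the written directory (see
#'   [load_runs_directory()]).
#' @export
run_session <- function(app, input, spec, quiet = TRUE) {
  manifest <- app$manifest
  validate_sampling_spec(manifest, spec)
  if (is.null(spec$out_dir)) abort("spec$out_dir is not set")
  dir <- spec$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "runs"), showWarnings = FALSE)
  if (manifest$emits_image)
    dir.create(file.path(dir, "images"), showWarnings = FALSE)

  write_tsv(input, file.path(dir, "input.txt"))
  param_info <- data.frame(
    name = names(manifest$parameters),
    type = vapply(manifest$parameters, `[[`, "", "kind"),
    stringsAsFactors = FALSE)
  write_tsv(param_info, file.path(dir, "paramInfo.txt"))
  write_manifest(manifest, file.path(dir, "manifest.json"))
  spec$n_drawn <- 0L
  write_sampling_spec(spec, file.path(dir, "sampling_spec.json"))

  execute_draws(app, input, spec, dir, first_draw = 0L, next_id = 0L,
                quiet = quiet)
  load_runs_directory(dir)
}

execute_draws <- function(app, input, spec, dir, first_draw, next_id,
                          quiet = TRUE) {
  manifest <- app$manifest
  spec <- bind_kinds(manifest, spec)
  info_path <- runs_info_path(dir)
  header_written <- file.exists(info_path) && file.size(info_path) > 0
  rid <- next_id
  for (i in seq_len(spec$n_runs - first_draw) - 1L) {
    draw <- first_draw + i
    values <- sample_combination(spec, draw)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(app$run(input, values), error = function(e) e)
    elapsed <- proc.time()[["elapsed"]] - t0
    failed <- inherits(res, "error")
    if (failed && !quiet)
      message("run ", rid, " failed: ", conditionMessage(res))

    if (!failed) {
      for (tn in manifest$output_tables)
        write_tsv(res$tables[[tn]],
                  file.path(dir, "runs", paste0(tn, "_", rid, ".txt")))
      if (manifest$emits_image && is.function(res$image)) {
        img <- file.path(dir, "images", paste0(rid, ".png"))
        grDevices::png(img, width = 480, height = 480)
        ok <- tryCatch({ res$image(img); TRUE }, error = function(e) FALSE)
        grDevices::dev.off()
        if (!ok) unlink(img)
      }
    }

    base <- data.frame(run_id = rid, stringsAsFactors = FALSE)
    for (pn in names(values)) base[[pn]] <- fmt_value(values[[pn]])
    base$status <- if (failed) "failed" else (res$status %||% "ok")
    base$duration_seconds <- round(elapsed, 4)
    records <- if (!failed && is.data.frame(res$records)) res$records
    if (!is.null(records) && nrow(records) > 0L) {
      rows <- base[rep(1L, nrow(records)), , drop = FALSE]
      rows$run_id <- rid + seq_len(nrow(records)) - 1L
      rows <- cbind(rows, records, stringsAsFactors = FALSE)
      rid <- rid + nrow(records)
    } else {
      if (!is.null(app$record_columns))
        for (cn in app$record_columns) base[[cn]] <- NA
      rows <- base
      rid <- rid + 1L
    }
    utils::write.table(rows, info_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = !header_written,
                       append = header_written, na = "NA",
                       fileEncoding = "UTF-8")
    header_written <- TRUE
    spec$n_drawn <- draw + 1L
    write_sampling_spec(spec, file.path(dir, "sampling_spec.json"))
    if (!quiet && (draw + 1L) %% 100L == 0L)
      message("completed ", draw + 1L, " / ", spec$n_runs, " draws")
  }
  invisible(rid)
}

#' Resume a sampling session
#'
#' Appends `additional_runs` further draws to an existing session. Because
#' every draw is keyed by `(seed, draw_index)`, the union of an interrupted
#' session and its resumption is identical to one uninterrupted session of
#' the same total length. New run ids continue from the maximum existing id
#' plus one; previously written files are untouched.
#'
#' @param app The [ps_app()] that produced the session.
#' @param dir Session directory path.
#' @param additional_runs Number of further draws (0 is a no-op).
#' @param quiet Suppress progress messages.
#' @return A refreshed `ps_runs` handle.
#' @export
resume_session <- function(app, dir, additional_runs, quiet = TRUE) {
  spec_path <- file.path(dir, "sampling_spec.json")
  if (!file.exists(spec_path))
    abort("cannot resume: '", spec_path, "' is missing")
  spec <- read_sampling_spec(spec_path)
  spec$out_dir <- dir
  rd <- load_runs_directory(dir)
  input <- rd$input
  n_drawn <- spec$n_drawn %||% nrow(rd$runs_info)
  next_id <- if (nrow(rd$runs_info)) max(rd$runs_info$run_id) + 1L else 0L
  spec$n_runs <- n_drawn + as.integer(additional_runs)
  if (additional_runs > 0L)
    execute_draws(app, input, spec, dir, first_draw = n_drawn,
                  next_id = next_id, quiet = quiet)
  load_runs_directory(dir)
}

#' Load a runs directory
#'
#' Accepts any directory in the standard session layout, including one
#' produced by an external tool: only `runsInfo.txt` is mandatory;
#' `input.txt`, `paramInfo.txt`, `sampling_spec.json` and per-run files are
#' picked up when present and flagged when not.
#'
#' @param path Directory path.
#' @return A `ps_runs` handle: a list with `path`, `runs_info` (data frame),
#'   `param_info`, `input`, `spec`, and `manifest` (the latter four `NULL`
#'   when absent). Per-run outputs are read lazily via [run_table()] and
#'   [run_image_path()].
#' @export
load_runs_directory <- function(path) {
  if (!dir.exists(path)) abort("no such directory: '", path, "'")
  info <- runs_info_path(path)
  if (!file.exists(info))
    abort("not a runs directory: missing '", info, "'")
  runs_info <- read_tsv(info)
  if (!"run_id" %in% names(runs_info))
    abort("runsInfo.txt has no 'run_id' column")
  maybe <- function(f, reader = read_tsv) {
    fp <- file.path(path, f)
    if (file.exists(fp)) reader(fp) else NULL
  }
  structure(list(
    path = path,
    runs_info = runs_info,
    param_info = maybe("paramInfo.txt"),
    input = maybe("input.txt"),
    spec = maybe("sampling_spec.json", read_sampling_spec),
    manifest = maybe("manifest.json", parse_manifest)
  ), class = "ps_runs")
}

#' @export
print.ps_runs <- function(x, ...) {
  cat("<ps_runs> ", x$path, "\n  ", nrow(x$runs_info), " run records, ",
      ncol(x$runs_info), " columns\n", sep = "")
  invisible(x)
}

#' Access one run's output table or image
#'
#' @param rd A `ps_runs` handle.
#' @param table Declared output table name.
#' @param run_id Integer run id.
#' @return `run_table()` returns the run's table as a data frame, or `NULL`
#'   with a warning when the file is missing (a missing individual run file
#'   is not fatal). `run_image_path()` returns the image path or `NA`.
#' @export
run_table <- function(rd, table, run_id) {
  fp <- file.path(rd$path, "runs", paste0(table, "_", run_id, ".txt"))
  if (!file.exists(fp)) {
    warning("missing run file: ", fp)
    return(NULL)
  }
  read_tsv(fp)
}

#' @rdname run_table
#' @export
run_image_path <- function(rd, run_id) {
  fp <- file.path(rd$path, "images", paste0(run_id, ".png"))
  if (file.exists(fp)) fp else NA_character_
}
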