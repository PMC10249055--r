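#' Declare one model parameter
#'
#' A parameter declaration carries everything needed to build both a
#' single-run default configuration and a sampling range: the value kind,
#' the default, numeric bounds for numeric kinds, and the item list for
#' categorical kinds.
#'
#' @param name Identifier, unique within a manifest.
#' @param kind One of `"integer"`, `"double"`, `"boolean"`, `"categorical"`,
#'   `"string"`, `"filename"`, `"output"`.
#' @param default Default value of the matching kind.
#' @param label Display text; defaults to `name`.
#' @param min,max Inclusive bounds (numeric kinds only); must bracket the
#'   default.
#' @param items Ordered vector of legal values (categorical only); pairwise
#'   distinct and containing the default.
#' @param info Optional free-text description.
#' @param depends_on Optional name of a controlling parameter. Retained for
#'   provenance only; sampling does not enforce dependencies.
#' @return A `ps_param` object.
#' @export
ps_param <- function(name, kind, default, label = name, min = NULL,
                     max = NULL, items = NULL, info = NULL,
                     depends_on = NULL) {
  kinds <- c("integer", "double", "boolean", "categorical", "string",
             "filename", "output")
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    abort("parameter 'name' must be a non-empty string")
  if (!kind %in% kinds)
    abort("parameter '", name, "': unknown kind '", kind, "'")
  p <- structure(list(name = name, label = label, kind = kind,
                      default = default, min = min, max = max,
                      items = items, info = info, depends_on = depends_on),
                 class = "ps_param")
  validate_param(p)
  p
}

validate_param <- function(p) {
  n <- p$name
  if (p$kind %in% c("integer", "double")) {
    if (is.null(p$min) || is.null(p$max))
      abort("parameter '", n, "': numeric kinds require min and max")
    if (!is.numeric(p$default) || length(p$default) != 1L)
      abort("parameter '", n, "': default must be a single number")
    if (p$kind == "integer" &&
        (p$default != round(p$default) || p$min != round(p$min) ||
         p$max != round(p$max)))
      abort("parameter '", n, "': integer kind requires whole-number ",
            "default/min/max")
    if (!(p$min <= p$default && p$default <= p$max))
      abort("parameter '", n, "': default ", p$default,
            " outside bounds [", p$min, ", ", p$max, "]")
  } else if (p$kind == "boolean") {
    if (!is.logical(p$default) || length(p$default) != 1L || is.na(p$default))
      abort("parameter '", n, "': boolean default must be TRUE or FALSE")
  } else if (p$kind == "categorical") {
    if (length(p$items) == 0L)
      abort("parameter '", n, "': categorical kind requires items")
    if (anyDuplicated(p$items))
      abort("parameter '", n, "': items must be pairwise distinct")
    if (!p$default %in% p$items)
      abort("parameter '", n, "': default '", p$default,
            "' is not among items")
  } else {
    if (!is.character(p$default) || length(p$default) != 1L)
      abort("parameter '", n, "': default must be a single string")
  }
  invisible(p)
}

#' Declare a model app manifest
#'
#' The manifest is the schema from which default configurations, sampling
#' specifications and the on-disk `paramInfo.txt` are all derived.
#'
#' @param app_name Name of the app.
#' @param parameters List of [ps_param()] declarations (at least one; names
#'   unique).
#' @param output_tables Character vector of declared output table names
#'   (pairwise distinct).
#' @param emits_image Does each run produce an image under `images/`?
#' @return A `ps_manifest` object.
#' @export
ps_manifest <- function(app_name, parameters, output_tables = character(),
                        emits_image = FALSE) {
  if (length(parameters) == 0L)
    abort("manifest '", app_name, "': at least one parameter is required")
  if (!all(vapply(parameters, inherits, TRUE, "ps_param")))
    abort("manifest '", app_name, "': parameters must be ps_param objects")
  nm <- vapply(parameters, `[[`, "", "name")
  if (anyDuplicated(nm))
    abort("manifest '", app_name, "': duplicate parameter name '",
          nm[duplicated(nm)][1L], "'")
  if (anyDuplicated(output_tables))
    abort("manifest '", app_name, "': output table names must be distinct")
  names(parameters) <- nm
  structure(list(app_name = app_name, parameters = parameters,
                 output_tables = as.character(output_tables),
                 emits_image = isTRUE(emits_image)),
            class = "ps_manifest")
}

#' @export
print.ps_manifest <- function(x, ...) {
  cat("<ps_manifest> ", x$app_name, "\n", sep = "")
  for (p in x$parameters) {
    rng <- switch(p$kind,
      integer = , double = paste0(" [", p$min, ", ", p$max, "]"),
      categorical = paste0(" {", paste(p$items, collapse = ", "), "}"),
      "")
    cat("  ", format(p$name, width = 18), p$kind, rng,
        " default=", format(p$default), "\n", sep = "")
  }
  if (length(x$output_tables))
    cat("  tables: ", paste(x$output_tables, collapse = ", "), "\n", sep = "")
  cat("  emits_image: ", x$emits_image, "\n", sep = "")
  invisible(x)
}

manifest_to_list <- function(m) {
  list(app_name = m$app_name,
       parameters = lapply(unname(m$parameters), function(p) {
         Filter(Negate(is.null),
                list(name = p$name, label = p$label, type = p$kind,
                     default = p$default, min = p$min, max = p$max,
                     items = as.list(p$items), info = p$info,
                     depends_on = p$depends_on))
       }),
       output_tables = as.list(m$output_tables),
       emits_image = m$emits_image)
}

#' Write a manifest to a JSON file
#' @param manifest A [ps_manifest()] object.
#' @param path Destination file.
#' @export
write_manifest <- function(manifest, path) {
  write_json_file(manifest_to_list(manifest), path)
}

#' Parse a manifest from a JSON document
#'
#' @param path Path to a JSON manifest file, or a JSON string.
#' @return A validated [ps_manifest()] object; malformed documents and
#'   invariant violations (e.g., a default outside its bounds) raise errors
#'   naming the offending field.
#' @export
parse_manifest <- function(path) {
  doc <- tryCatch(
    if (file.exists(path)) read_json_file(path)
    else jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE),
    error = function(e) abort("malformed manifest document: ",
                              conditionMessage(e), class = "psweep_parse_error"))
  for (f in c("app_name", "parameters"))
    if (is.null(doc[[f]]))
      abort("manifest document missing field '", f, "'",
            class = "psweep_parse_error")
  params <- lapply(doc$parameters, function(q) {
    if (is.null(q$name) || is.null(q$type))
      abort("manifest parameter entry missing 'name' or 'type'",
            class = "psweep_parse_error")
    default <- q$default
    if (identical(q$type, "boolean")) default <- as.logical(default)
    if (identical(q$type, "integer")) default <- as.numeric(default)
    ps_param(q$name, q$type, default,
             label = q$label %||% q$name,
             min = q$min, max = q$max,
             items = if (!is.null(q$items)) unlist(q$items),
             info = q$info, depends_on = q$depends_on)
  })
  ps_manifest(doc$app_name, params,
              output_tables = unlist(doc$output_tables) %||% character(),
              emits_image = isTRUE(doc$emits_image))
}

# ---- sampling directives and specs ------------------------------------

directive <- function(parameter, mode, value = NULL, lo = NULL, hi = NULL,
                      enabled = NULL) {
  structure(list(parameter = parameter, mode = mode, value = value,
                 lo = lo, hi = hi, enabled = enabled),
            class = "ps_directive")
}

#' Default (all-constant) sampling specification
#'
#' Every directive starts as `constant` at the manifest default, mirroring a
#' freshly opened sampling view: nothing varies until a range or item set is
#' enabled explicitly.
#'
#' @param manifest A [ps_manifest()].
#' @param n_runs Number of parameter combinations to draw.
#' @param seed Session seed; every draw is keyed by `(seed, draw_index)`.
#' @param out_dir Session output directory.
#' @return A `ps_sampling_spec` object.
#' @export
default_sampling_spec <- function(manifest, n_runs = 1L, seed = 0L,
                                  out_dir = NULL) {
  dirs <- lapply(manifest$parameters, function(p)
    directive(p$name, "constant", value = p$default))
  names(dirs) <- names(manifest$parameters)
  spec <- structure(list(app_name = manifest$app_name, directives = dirs,
                         n_runs = as.integer(n_runs), seed = as.integer(seed),
                         out_dir = out_dir),
                    class = "ps_sampling_spec")
  attr(spec, "kinds") <- vapply(manifest$parameters, `[[`, "", "kind")
  spec
}

#' Enable sampling for one parameter of a spec
#'
#' `set_range()` samples a numeric parameter uniformly on the closed
#' interval `[lo, hi]`; `set_enabled()` samples a boolean or categorical
#' parameter uniformly over the enabled subset; `set_constant()` pins any
#' parameter back to a fixed value.
#'
#' @param spec A sampling spec from [default_sampling_spec()].
#' @param parameter Parameter name.
#' @param lo,hi Closed-interval bounds (within the manifest bounds).
#' @param items For boolean parameters a logical vector, for categorical a
#'   subset of the manifest items; non-empty.
#' @param value Constant value.
#' @return The updated spec.
#' @export
set_range <- function(spec, parameter, lo, hi) {
  check_has_param(spec, parameter)
  spec$directives[[parameter]] <- directive(parameter, "numeric_range",
                                            lo = lo, hi = hi)
  spec
}

#' @rdname set_range
#' @export
set_enabled <- function(spec, parameter, items) {
  check_has_param(spec, parameter)
  mode <- if (is.logical(items)) "boolean_set" else "categorical_set"
  spec$directives[[parameter]] <- directive(parameter, mode, enabled = items)
  spec
}

#' @rdname set_range
#' @export
set_constant <- function(spec, parameter, value) {
  check_has_param(spec, parameter)
  spec$directives[[parameter]] <- directive(parameter, "constant",
                                            value = value)
  spec
}

#' Sampling spec that varies every samplable parameter
#'
#' Convenience for full sweeps: numeric parameters get their whole manifest
#' range, booleans both values, categoricals all items; string, filename
#' and output parameters (and any name in `except`) stay constant at their
#' defaults.
#'
#' @inheritParams default_sampling_spec
#' @param except Parameter names to hold constant (e.g., `"seed"`).
#' @return A `ps_sampling_spec`.
#' @export
full_sampling_spec <- function(manifest, n_runs = 1L, seed = 0L,
                               out_dir = NULL, except = "seed") {
  spec <- default_sampling_spec(manifest, n_runs = n_runs, seed = seed,
                                out_dir = out_dir)
  for (p in manifest$parameters) {
    if (p$name %in% except) next
    spec <- switch(p$kind,
      integer = , double = set_range(spec, p$name, p$min, p$max),
      boolean = set_enabled(spec, p$name, c(TRUE, FALSE)),
      categorical = set_enabled(spec, p$name, p$items),
      spec)
  }
  spec
}

check_has_param <- function(spec, parameter) {
  if (!parameter %in% names(spec$directives))
    abort("unknown parameter '", parameter, "'; spec has: ",
          paste(names(spec$directives), collapse = ", "))
}

#' Validate a sampling spec against its manifest
#'
#' Checks that there is exactly one directive per manifest parameter, that
#' numeric ranges sit inside the manifest bounds with `lo <= hi`, that
#' enabled sets are non-empty subsets of the legal values, and that string,
#' filename and output parameters are held constant.
#'
#' @param manifest A [ps_manifest()].
#' @param spec A `ps_sampling_spec`.
#' @return The spec, invisibly, if valid; otherwise an error.
#' @export
validate_sampling_spec <- function(manifest, spec) {
  pn <- names(manifest$parameters)
  if (!setequal(names(spec$directives), pn) ||
      length(spec$directives) != length(pn))
    abort("spec must have exactly one directive per manifest parameter")
  if (spec$n_runs < 1L) abort("n_runs must be >= 1")
  for (d in spec$directives) {
    p <- manifest$parameters[[d$parameter]]
    switch(d$mode,
      constant = {
        # a constant must itself be a legal value
        tmp <- p; tmp$default <- d$value
        validate_param(tmp)
      },
      numeric_range = {
        if (!p$kind %in% c("integer", "double"))
          abort("parameter '", p$name, "' (", p$kind,
                ") admits only constant directives")
        if (is.null(d$lo) || is.null(d$hi) || d$lo > d$hi)
          abort("parameter '", p$name, "': range requires lo <= hi")
        if (d$lo < p$min || d$hi > p$max)
          abort("parameter '", p$name, "': range [", d$lo, ", ", d$hi,
                "] outside manifest bounds [", p$min, ", ", p$max, "]")
      },
      boolean_set = {
        if (p$kind != "boolean")
          abort("parameter '", p$name, "': boolean_set on non-boolean kind")
        if (length(d$enabled) == 0L || !is.logical(d$enabled) ||
            anyNA(d$enabled))
          abort("parameter '", p$name, "': enabled set must be a non-empty ",
                "subset of {TRUE, FALSE}")
      },
      categorical_set = {
        if (p$kind != "categorical")
          abort("parameter '", p$name, "': categorical_set on non-categorical ",
                "kind")
        if (length(d$enabled) == 0L)
          abort("parameter '", p$name, "': enabled set must be non-empty")
        if (!all(d$enabled %in% p$items))
          abort("parameter '", p$name, "': enabled values outside items: ",
                paste(setdiff(d$enabled, p$items), collapse = ", "))
      },
      abort("parameter '", d$parameter, "': unknown directive mode '",
            d$mode, "'"))
  }
  invisible(spec)
}

spec_to_list <- function(spec) {
  list(app_name = spec$app_name,
       n_runs = spec$n_runs, seed = spec$seed,
       n_drawn = spec$n_drawn %||% NULL,
       kinds = as.list(attr(spec, "kinds")),
       directives = lapply(unname(spec$directives), function(d)
         Filter(Negate(is.null),
                list(parameter = d$parameter, mode = d$mode, value = d$value,
                     lo = d$lo, hi = d$hi, enabled = as.list(d$enabled)))))
}

#' Write / read a sampling spec as JSON
#'
#' A copy of the spec is written beside each session (`sampling_spec.json`)
#' so that sessions are reproducible and resumable.
#'
#' @param spec A `ps_sampling_spec`.
#' @param path JSON file path.
#' @export
write_sampling_spec <- function(spec, path) {
  write_json_file(spec_to_list(spec), path)
}

#' @rdname write_sampling_spec
#' @export
read_sampling_spec <- function(path) {
  doc <- read_json_file(path)
  dirs <- lapply(doc$directives, function(d) {
    enabled <- if (!is.null(d$enabled)) unlist(d$enabled)
    if (identical(d$mode, "boolean_set")) enabled <- as.logical(enabled)
    directive(d$parameter, d$mode, value = d$value, lo = d$lo, hi = d$hi,
              enabled = enabled)
  })
  names(dirs) <- vapply(dirs, `[[`, "", "parameter")
  spec <- structure(list(app_name = doc$app_name, directives = dirs,
                         n_runs = as.integer(doc$n_runs),
                         seed = as.integer(doc$seed),
                         out_dir = NULL),
                    class = "ps_sampling_spec")
  if (!is.null(doc$n_drawn)) spec$n_drawn <- as.integer(doc$n_drawn)
  if (!is.null(doc$kinds))
    attr(spec, "kinds") <- unlist(doc$kinds)
  spec
}
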