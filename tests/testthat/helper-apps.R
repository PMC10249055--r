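# Shared fixtures, all built in code.

# Toy two-table app: TableA has a numeric column A1 and a label column A2,
# TableB is a single row. Output is a deterministic function of the
# parameter values, so sessions are reproducible without app-side state.
toy_manifest <- function() {
  ps_manifest("toy", list(
    ps_param("k", "integer", 4, min = 2, max = 20),
    ps_param("rate", "double", 0.5, min = 0, max = 1),
    ps_param("method", "categorical", "a", items = c("a", "b", "c")),
    ps_param("flag", "boolean", TRUE),
    ps_param("tag", "string", "x")),
    output_tables = c("TableA", "TableB"), emits_image = FALSE)
}

toy_app <- function(n_rows = 7L) {
  ps_app(toy_manifest(), function(input, values) {
    set.seed(values$k * 1000L + round(values$rate * 100))
    list(tables = list(
      TableA = data.frame(A1 = round(stats::rnorm(n_rows, values$k), 6),
                          A2 = sample(c("x", "y"), n_rows, replace = TRUE)),
      TableB = data.frame(B1 = values$k, B2 = values$method,
                          B3 = values$rate)))
  })
}

toy_input <- function(n = 7L) {
  data.frame(id = seq_len(n),
             GT = rep(c(TRUE, FALSE, NA), length.out = n))
}

# Boolean-prediction app over the toy input, for ground-truth comparison.
pred_manifest <- function() {
  ps_manifest("pred", list(
    ps_param("cut", "double", 0.5, min = 0, max = 1)),
    output_tables = "calls", emits_image = FALSE)
}

pred_app <- function() {
  ps_app(pred_manifest(), function(input, values) {
    set.seed(round(values$cut * 1e6))
    list(tables = list(
      calls = data.frame(isDE = stats::runif(nrow(input)) < values$cut)))
  })
}

# Well-separated Gaussian blobs for clustering checks.
make_blobs <- function(k = 3L, n_per = 30L, sep = 10, sd = 0.5, d = 2L,
                       seed = 1L) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(k * d), k, d) * 0 +
    sep * matrix(seq_len(k), k, d)
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(stats::rnorm(n_per * d, sd = sd), n_per, d) +
      matrix(centers[i, ], n_per, d, byrow = TRUE)))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}

run_toy_session <- function(n_runs = 10L, seed = 42L, app = toy_app(),
                            input = toy_input(), vary = TRUE) {
  spec <- default_sampling_spec(app$manifest, n_runs = n_runs, seed = seed,
                                out_dir = withr::local_tempdir(
                                  .local_envir = parent.frame()))
  if (vary && "k" %in% names(spec$directives)) {
    spec <- set_range(spec, "k", 2, 19)
    spec <- set_enabled(spec, "method", c("a", "b", "c"))
  }
  if (vary && "cut" %in% names(spec$directives))
    spec <- set_range(spec, "cut", 0, 1)
  run_session(app, input, spec)
}
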