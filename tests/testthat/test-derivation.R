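# Independent streaming oracle for the numeric aggregates: recompute from
# the run files with explicit loops (median by sort-and-pick-middle).
oracle_aggregate <- function(rd, table, column, fn_name) {
  vapply(rd$runs_info$run_id, function(id) {
    x <- suppressWarnings(run_table(rd, table, id))[[column]]
    if (is.null(x)) return(NA_real_)
    switch(fn_name,
      mean = sum(x) / length(x),
      sum = { s <- 0; for (v in x) s <- s + v; s },
      median = {
        s <- sort(x); n <- length(s)
        if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
      },
      min = { m <- Inf; for (v in x) if (v < m) m <- v; m },
      max = { m <- -Inf; for (v in x) if (v > m) m <- v; m })
  }, numeric(1))
}

test_that("numeric aggregates match a brute-force oracle and use paper naming", {
  rd <- run_toy_session(n_runs = 10, seed = 101)
  for (fn in c("mean", "sum", "median", "min", "max")) {
    rd <- apply_passes(rd, derivation_pass(fn, "TableA", "A1"))
    lab <- paste0(fn, "_A1")
    expect_true(lab %in% names(rd$runs_info))
    expect_equal(rd$runs_info[[lab]], oracle_aggregate(rd, "TableA", "A1", fn),
                 tolerance = 1e-12)
  }
})

test_that("aggregating a single-row table gives the value for every function", {
  m <- ps_manifest("one", list(ps_param("v", "double", 3, min = 0, max = 9)),
                   output_tables = "t")
  app <- ps_app(m, function(input, values)
    list(tables = list(t = data.frame(x = values$v))))
  spec <- set_range(default_sampling_spec(m, n_runs = 5, seed = 2,
                                          out_dir = withr::local_tempdir()),
                    "v", 0, 9)
  rd <- run_session(app, data.frame(a = 1), spec)
  for (fn in c("mean", "sum", "median", "min", "max"))
    rd <- apply_passes(rd, derivation_pass(fn, "t", "x"))
  for (fn in c("sum", "median", "min", "max"))
    expect_equal(rd$runs_info[[paste0(fn, "_x")]], rd$runs_info$mean_x)
})

test_that("aggregate on a non-numeric column raises a typed error naming the run", {
  rd <- run_toy_session(n_runs = 3, seed = 5)
  expect_error(apply_passes(rd, derivation_pass("mean", "TableA", "A2")),
               class = "psweep_type_error")
  expect_error(apply_passes(rd, derivation_pass("mean", "TableA", "A2")),
               "run 0")
})

test_that("class-label statistics: counts, mode and label histogram columns", {
  rd <- run_toy_session(n_runs = 8, seed = 31)
  rd <- apply_passes(rd, list(
    derivation_pass("n_class_labels", "TableA", "A2"),
    derivation_pass("mode_class_labels", "TableA", "A2"),
    derivation_pass("count_per_class_label", "TableA", "A2")))
  expect_true(all(c("Num(TableA)", "mode_A2", "n(A2 = x)", "n(A2 = y)")
                  %in% names(rd$runs_info)))
  for (i in seq_len(nrow(rd$runs_info))) {
    id <- rd$runs_info$run_id[i]
    a2 <- run_table(rd, "TableA", id)$A2
    expect_identical(rd$runs_info$`Num(TableA)`[i], length(unique(a2)))
    expect_identical(rd$runs_info$`n(A2 = x)`[i], sum(a2 == "x"))
    expect_identical(rd$runs_info$`n(A2 = y)`[i], sum(a2 == "y"))
    # per-run label counts sum to the run's row count
    expect_identical(rd$runs_info$`n(A2 = x)`[i] + rd$runs_info$`n(A2 = y)`[i],
                     length(a2))
    tab <- table(a2)
    expect_identical(rd$runs_info$mode_A2[i], names(tab)[which.max(tab)])
  }
})

test_that("a constant label column has one class and is its own mode", {
  m <- ps_manifest("const", list(ps_param("n", "integer", 5, min = 5,
                                          max = 5)),
                   output_tables = "t")
  app <- ps_app(m, function(input, values)
    list(tables = list(t = data.frame(lab = rep("only", values$n)))))
  rd <- run_session(app, data.frame(a = 1),
                    default_sampling_spec(m, n_runs = 3, seed = 1,
                                          out_dir = withr::local_tempdir()))
  rd <- apply_passes(rd, list(
    derivation_pass("n_class_labels", "t", "lab"),
    derivation_pass("mode_class_labels", "t", "lab")))
  expect_identical(rd$runs_info$`Num(t)`, rep(1L, 3))
  expect_identical(rd$runs_info$mode_lab, rep("only", 3))
})

test_that("ground-truth comparison emits six conserving count columns", {
  input <- data.frame(id = 1:200,
                      GT = sample(c(TRUE, FALSE, NA), 200, replace = TRUE))
  app <- pred_app()
  spec <- set_range(default_sampling_spec(app$manifest, n_runs = 50,
                                          seed = 17,
                                          out_dir = withr::local_tempdir()),
                    "cut", 0, 1)
  rd <- run_session(app, input, spec)
  rd <- apply_passes(rd, derivation_pass("gt_comparison", "calls",
                                         columns = "isDE",
                                         gt_column = "GT"))
  labs <- c("n(isDE = TRUE & GT = TRUE)", "n(isDE = FALSE & GT = TRUE)",
            "n(isDE = TRUE & GT = FALSE)", "n(isDE = FALSE & GT = FALSE)",
            "n(isDE = TRUE & GT = NA)", "n(isDE = FALSE & GT = NA)")
  expect_true(all(labs %in% names(rd$runs_info)))
  # nested-loop cross-tab oracle, every run
  for (i in seq_len(nrow(rd$runs_info))) {
    id <- rd$runs_info$run_id[i]
    pred <- run_table(rd, "calls", id)$isDE
    counts <- stats::setNames(numeric(6), labs)
    for (g in seq_along(pred)) {
      gchr <- if (is.na(input$GT[g])) "NA" else as.character(input$GT[g])
      key <- paste0("n(isDE = ", pred[g], " & GT = ", gchr, ")")
      counts[key] <- counts[key] + 1
    }
    for (lab in labs)
      expect_identical(rd$runs_info[[lab]][i], as.integer(counts[[lab]]))
    expect_identical(sum(unlist(rd$runs_info[i, labs])), 200L)
  }
})

test_that("degenerate ground-truth comparison puts all mass in one cell", {
  input <- data.frame(GT = rep(NA, 10))
  m <- ps_manifest("allf", list(ps_param("z", "integer", 1, min = 1,
                                         max = 1)),
                   output_tables = "calls")
  app <- ps_app(m, function(input, values)
    list(tables = list(calls = data.frame(isDE = rep(FALSE, 10)))))
  rd <- run_session(app, input,
                    default_sampling_spec(m, n_runs = 2, seed = 1,
                                          out_dir = withr::local_tempdir()))
  rd <- apply_passes(rd, derivation_pass("gt_comparison", "calls",
                                         columns = "isDE", gt_column = "GT"))
  expect_identical(rd$runs_info$`n(isDE = FALSE & GT = NA)`, c(10L, 10L))
  others <- grep("^n\\(isDE", names(rd$runs_info), value = TRUE)
  others <- setdiff(others, "n(isDE = FALSE & GT = NA)")
  expect_true(all(as.matrix(rd$runs_info[others]) == 0L))
})

test_that("gt comparison rejects row-count mismatches", {
  input <- data.frame(GT = c(TRUE, FALSE, NA))
  m <- ps_manifest("mism", list(ps_param("z", "integer", 1, min = 1,
                                         max = 1)),
                   output_tables = "calls")
  app <- ps_app(m, function(input, values)
    list(tables = list(calls = data.frame(isDE = c(TRUE, FALSE)))))
  rd <- run_session(app, input,
                    default_sampling_spec(m, n_runs = 1, seed = 1,
                                          out_dir = withr::local_tempdir()))
  expect_error(apply_passes(rd, derivation_pass("gt_comparison", "calls",
                                                columns = "isDE",
                                                gt_column = "GT")),
               "rows")
})

test_that("take_first_row appends the table's own columns", {
  rd <- run_toy_session(n_runs = 6, seed = 51)
  rd <- apply_passes(rd, derivation_pass("take_first_row", "TableB"))
  expect_true(all(c("B1", "B2", "B3") %in% names(rd$runs_info)))
  for (i in seq_len(6)) {
    b <- run_table(rd, "TableB", rd$runs_info$run_id[i])
    expect_equal(rd$runs_info$B1[i], b$B1[1])
    expect_equal(rd$runs_info$B2[i], b$B2[1])
  }
})

test_that("dimred passes embed runs into two named columns", {
  rd <- run_toy_session(n_runs = 10, seed = 61)
  rd <- apply_passes(rd, derivation_pass("dimred_pca", "TableA",
                                         columns = "A1"))
  expect_true(all(c("pca1(TableA)", "pca2(TableA)") %in% names(rd$runs_info)))
  expect_identical(sum(!is.na(rd$runs_info$`pca1(TableA)`)), 10L)
  # pca on runs whose feature vectors have rank 2 preserves pairwise
  # distances up to rotation
  feats <- t(vapply(rd$runs_info$run_id, function(id)
    run_table(rd, "TableA", id)$A1, numeric(7)))
  basis <- matrix(stats::rnorm(14), 2, 7)
  low <- feats[, 1:2] %*% basis  # exact rank-2 matrix
  m <- ps_manifest("r2", list(ps_param("i", "integer", 1, min = 1,
                                       max = 10)),
                   output_tables = "t")
  app <- ps_app(m, function(input, values)
    list(tables = list(t = data.frame(t(low[values$i, ])))))
  spec <- set_range(default_sampling_spec(m, n_runs = 30, seed = 3,
                                          out_dir = withr::local_tempdir()),
                    "i", 1, 10)
  rd2 <- run_session(app, data.frame(a = 1), spec)
  rd2 <- apply_passes(rd2, derivation_pass("dimred_pca", "t"))
  emb <- cbind(rd2$runs_info$`pca1(t)`, rd2$runs_info$`pca2(t)`)
  rows <- t(vapply(rd2$runs_info$run_id, function(id)
    as.numeric(run_table(rd2, "t", id)[1, ]), numeric(7)))
  expect_equal(as.numeric(dist(emb)), as.numeric(dist(rows)),
               tolerance = 1e-8)
  # duplicate runs (same i drawn twice) share embedding coordinates
  dup <- duplicated(rd2$runs_info$i)
  if (any(dup)) {
    i1 <- which(dup)[1]
    i0 <- which(rd2$runs_info$i == rd2$runs_info$i[i1])[1]
    expect_equal(emb[i1, ], emb[i0, ], tolerance = 1e-10)
  }
})

test_that("applying passes is idempotent and never touches run files", {
  rd <- run_toy_session(n_runs = 6, seed = 71)
  passes <- list(derivation_pass("mean", "TableA", "A1"),
                 derivation_pass("count_per_class_label", "TableA", "A2"),
                 derivation_pass("take_first_row", "TableB"))
  before <- lapply(list.files(file.path(rd$path, "runs"), full.names = TRUE),
                   readLines)
  rd1 <- apply_passes(rd, passes)
  rd2 <- apply_passes(rd1, passes)
  expect_identical(rd2$runs_info, rd1$runs_info)
  after <- lapply(list.files(file.path(rd$path, "runs"), full.names = TRUE),
                  readLines)
  expect_identical(after, before)
  # the documented three-pass example adds 1 + 2 + 3 columns
  base_cols <- ncol(rd$runs_info)
  expect_identical(ncol(rd1$runs_info), base_cols + 6L)
})

test_that("derived columns may not overwrite parameter columns", {
  m <- ps_manifest("clash", list(ps_param("B1", "integer", 1, min = 1,
                                          max = 5)),
                   output_tables = "TableB")
  app <- ps_app(m, function(input, values)
    list(tables = list(TableB = data.frame(B1 = 9, B2 = "q"))))
  rd <- run_session(app, data.frame(a = 1),
                    default_sampling_spec(m, n_runs = 2, seed = 1,
                                          out_dir = withr::local_tempdir()))
  expect_error(apply_passes(rd, derivation_pass("take_first_row", "TableB")),
               "parameter columns")
})

test_that("failed runs propagate missing values through derivation", {
  m <- ps_manifest("flaky", list(ps_param("k", "integer", 4, min = 2,
                                          max = 20)),
                   output_tables = "t")
  app <- ps_app(m, function(input, values) {
    if (values$k > 10) stop("boom")
    list(tables = list(t = data.frame(x = rep(values$k, 3))))
  })
  spec <- set_range(default_sampling_spec(m, n_runs = 15, seed = 8,
                                          out_dir = withr::local_tempdir()),
                    "k", 2, 19)
  rd <- run_session(app, data.frame(a = 1), spec)
  rd <- apply_passes(rd, derivation_pass("mean", "t", "x"))
  failed <- rd$runs_info$status == "failed"
  expect_true(any(failed))
  expect_true(all(is.na(rd$runs_info$mean_x[failed])))
  expect_true(all(!is.na(rd$runs_info$mean_x[!failed])))
})
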