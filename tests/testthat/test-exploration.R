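test_that("filters conjoin, match a row-by-row oracle, and commute", {
  set.seed(9)
  for (trial in 1:100) {
    n <- sample(20:60, 1)
    ri <- data.frame(run_id = 0:(n - 1),
                     a = round(stats::runif(n, 0, 10), 2),
                     g = sample(c("u", "v", "w"), n, replace = TRUE))
    lo <- stats::runif(1, 0, 5); hi <- lo + stats::runif(1, 0, 5)
    vals <- sample(c("u", "v", "w"), sample(1:3, 1))
    fs <- list(ps_filter("a", lo = lo, hi = hi),
               ps_filter("g", values = vals))
    got <- apply_filters(ri, fs)
    oracle <- integer()
    for (i in seq_len(n))
      if (ri$a[i] >= lo && ri$a[i] <= hi && ri$g[i] %in% vals)
        oracle <- c(oracle, ri$run_id[i])
    expect_identical(got, oracle)
    expect_identical(apply_filters(ri, rev(fs)), got)
  }
})

test_that("the empty filter list keeps every run; unknown columns are named", {
  ri <- data.frame(run_id = 0:4, x = 1:5)
  expect_identical(apply_filters(ri, list()), 0:4)
  expect_error(apply_filters(ri, ps_filter("nope", lo = 0)),
               "available")
  expect_error(ps_filter("x", values = character()), "non-empty")
  expect_error(ps_filter("x", lo = 2, hi = 1), "lo > hi")
})

test_that("categorical filtering isolates one method's runs", {
  ri <- data.frame(run_id = 0:9,
                   method = rep(c("kmeans", "hierarchical"), 5))
  ids <- apply_filters(ri, ps_filter("method", values = "hierarchical"))
  expect_identical(ids, ri$run_id[ri$method == "hierarchical"])
})

test_that("histograms count every non-missing run once", {
  set.seed(4)
  ri <- data.frame(run_id = 0:99, x = c(stats::rnorm(97), NA, NA, NA),
                   g = sample(c("single", "median", "centroid"), 100,
                              replace = TRUE))
  h <- ps_histogram(ri, "x")
  expect_identical(sum(h$counts), 97L)
  expect_identical(h$n_missing, 3L)
  hg <- ps_histogram(ri, "g")
  expect_identical(sum(hg$counts), 100L)
  expect_setequal(names(hg$counts), c("single", "median", "centroid"))
  # independent counting oracle per category
  for (lv in names(hg$counts))
    expect_identical(hg$counts[[lv]], sum(ri$g == lv))
  hc <- ps_histogram(data.frame(run_id = 0:9, k = rep(7, 10)), "k")
  expect_identical(sum(hc$counts), 10L)
  expect_length(hc$counts, 1L)
  expect_warning(ps_histogram(data.frame(run_id = 1, x = NA_real_), "x"),
                 "no non-missing")
})

# O(n^2) pairwise-dominance oracle, independent of the implementation.
pareto_oracle <- function(df, axes) {
  m <- sapply(names(axes), function(cn)
    if (axes[[cn]] == "minimize") -df[[cn]] else df[[cn]])
  m <- matrix(m, ncol = length(axes))
  keep <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    dominated <- FALSE
    for (j in seq_len(nrow(m))) {
      if (i == j) next
      if (all(m[j, ] >= m[i, ]) && any(m[j, ] > m[i, ])) {
        dominated <- TRUE
        break
      }
    }
    keep[i] <- !dominated
  }
  sort(df$run_id[keep])
}

test_that("pareto front: base cases and corrected dominance example", {
  one <- data.frame(run_id = 0L, fp = 0.3, tp = 0.5)
  expect_identical(pareto_front(one, c(fp = "minimize", tp = "maximize")),
                   0L)
  # (0,1) dominates both (1,0) and (1,1): front is {(0,1)} alone
  pts <- data.frame(run_id = 0:2, fp = c(0, 1, 1), tp = c(1, 0, 1))
  expect_identical(pareto_front(pts, c(fp = "minimize", tp = "maximize")),
                   0L)
  # exact duplicates of a frontier point are all kept
  dup <- data.frame(run_id = 0:2, fp = c(0, 0, 1), tp = c(1, 1, 0.5))
  expect_identical(pareto_front(dup, c(fp = "minimize", tp = "maximize")),
                   c(0L, 1L))
})

test_that("pareto front equals the O(n^2) oracle and is idempotent", {
  set.seed(12)
  for (trial in 1:5) {
    n <- 500
    df <- data.frame(run_id = 0:(n - 1),
                     fp = round(stats::runif(n, 0, 23)),
                     tp = round(stats::runif(n, 0, 69)))
    axes <- c(fp = "minimize", tp = "maximize")
    front <- pareto_front(df, axes)
    expect_identical(front, pareto_oracle(df, axes))
    sub <- df[df$run_id %in% front, ]
    expect_identical(pareto_front(sub, axes), front)
    # witness: every non-front point is dominated by some front point
    fm <- sub
    for (id in setdiff(df$run_id, front)) {
      p <- df[df$run_id == id, ]
      expect_true(any(fm$fp <= p$fp & fm$tp >= p$tp &
                        (fm$fp < p$fp | fm$tp > p$tp)),
                  info = paste("run", id, "has no dominating witness"))
    }
  }
  # three axes
  set.seed(13)
  df3 <- data.frame(run_id = 0:199, a = stats::runif(200),
                    b = stats::runif(200), c = stats::runif(200))
  axes3 <- c(a = "minimize", b = "maximize", c = "maximize")
  expect_identical(pareto_front(df3, axes3), pareto_oracle(df3, axes3))
})

test_that("normalized mean quality: hand-computed example and invariances", {
  ri <- data.frame(run_id = 0:2,
                   calinski_harabasz = c(10, 20, 30),
                   davies_bouldin = c(2, 1, 3))
  out <- normalized_mean_quality(ri, c("calinski_harabasz",
                                       "davies_bouldin"))
  # by hand: ch -> (0, .5, 1); db -> (.5, 1, 0) after inversion
  expect_equal(out$mean_normalized_quality, c(0.25, 0.75, 0.5))
  expect_true(all(out$mean_normalized_quality >= 0 &
                    out$mean_normalized_quality <= 1))
  # invariant under positive affine rescaling of an input metric
  ri2 <- ri
  ri2$calinski_harabasz <- 100 * ri2$calinski_harabasz + 7
  out2 <- normalized_mean_quality(ri2, c("calinski_harabasz",
                                         "davies_bouldin"))
  expect_equal(out2$mean_normalized_quality, out$mean_normalized_quality)
  # constant metrics normalize to 0.5
  ri3 <- data.frame(run_id = 0:2, silhouette = c(0.4, 0.4, 0.4),
                    gap = c(1, 2, 3))
  expect_warning(out3 <- normalized_mean_quality(ri3, c("silhouette",
                                                        "gap")),
                 "constant")
  expect_equal(out3$mean_normalized_quality, (0.5 + c(0, 0.5, 1)) / 2)
  expect_error(normalized_mean_quality(ri, c("calinski_harabasz", "zzz")),
               "unknown metric")
  expect_error(
    normalized_mean_quality(ri, "calinski_harabasz",
                            registry = c(other = TRUE)),
    "not in the direction registry")
})

test_that("roc_rates reproduces count-to-percent arithmetic", {
  r <- roc_rates(tp = 60, fp = 1, n_positive = 69, n_negative = 23)
  expect_equal(r$tpr_percent, 87)
  expect_equal(r$fpr_percent, 4)
})

test_that("export_report writes tables and plots consistent with filters", {
  rd <- run_toy_session(n_runs = 15, seed = 88)
  rd <- apply_passes(rd, derivation_pass("mean", "TableA", "A1"))
  out <- withr::local_tempdir()
  suppressWarnings(export_report(rd, out,
                filters = list(ps_filter("method", values = c("a", "b"))),
                scatters = list(list(x = "k", y = "mean_A1",
                                     color = "method")),
                pareto = c(k = "minimize", mean_A1 = "maximize"),
                selected_ids = c(0, 999)))
  expect_true(file.exists(file.path(out, "index.html")))
  rep_runs <- utils::read.delim(file.path(out, "runs.txt"),
                                check.names = FALSE)
  kept <- apply_filters(rd$runs_info,
                        ps_filter("method", values = c("a", "b")))
  expect_identical(nrow(rep_runs), length(kept))
  expect_true(file.exists(file.path(out, "pareto.txt")))
  expect_true(any(grepl("^scatter_", list.files(out))))
  # run 999 has no image: a placeholder is still produced
  expect_true(file.exists(file.path(out, "run_999.png")))
  # an empty filter result still yields a valid report
  out2 <- withr::local_tempdir()
  export_report(rd, out2, filters = list(ps_filter("k", lo = 100, hi = 200)))
  expect_true(file.exists(file.path(out2, "index.html")))
  expect_identical(nrow(utils::read.delim(file.path(out2, "runs.txt"))), 0L)
})
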