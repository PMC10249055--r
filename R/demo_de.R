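#' Generate a spike-in RNA-seq benchmark count table
#'
#' Emulates a two-condition bulk RNA-seq benchmark with embedded
#' ground-truth: a count table of `n_genes` rows by 10 samples (5
#' biological replicates per condition) in which 92 rows are synthetic
#' spike-in genes of known between-condition abundance ratio. 23 spike-ins
#' (25%) have ratio 1 and are true negatives (`GT_DE = FALSE`); the other
#' 69 (75%) have ratio 0.5, 0.67 or 2 (23 each) and are true positives
#' (`GT_DE = TRUE`). All non-spike-in genes have `GT_DE = NA`: their DE
#' status is unknown, like the biological background of a real benchmark.
#'
#' Counts are negative binomial. Gene-wise baseline means are log-normal,
#' per-gene dispersions gamma-distributed, and a configurable fraction of
#' background genes carries nuisance differential expression so the
#' background is not a pure null.
#'
#' @param seed Seed; identical seeds give identical tables.
#' @param config Optional overrides: `n_genes` (21716), `n_spike` (92),
#'   `n_null_spike` (23), `de_ratios` (`c(0.5, 0.67, 2)`), `reps` (5 per
#'   condition), `meanlog`/`sdlog` (log-normal baseline mean, 3 / 1.8),
#'   `spike_meanlog` (5), `disp_shape`/`disp_rate` (gamma dispersion, 2 /
#'   20), `disp_floor` (0.01), `nuisance_fraction` (0.1),
#'   `nuisance_lfc_sd` (0.8, natural log).
#' @return Data frame: `gene_id`, `cond1_1..cond1_5`, `cond2_1..cond2_5`
#'   (non-negative integer counts), `GT_DE` (logical with `NA`),
#'   `spike_ratio` (0.5 / 0.67 / 1 / 2, `NA` for non-spike-ins).
#' @export
generate_seqc_like <- function(seed = 0L, config = list()) {
  cfg <- utils::modifyList(list(
    n_genes = 21716L, n_spike = 92L, n_null_spike = 23L,
    de_ratios = c(0.5, 0.67, 2), reps = 5L,
    meanlog = 3, sdlog = 1.8, spike_meanlog = 5,
    disp_shape = 2, disp_rate = 20, disp_floor = 0.01,
    nuisance_fraction = 0.1, nuisance_lfc_sd = 0.8), config)
  n <- cfg$n_genes
  ns <- cfg$n_spike
  n_de_spike <- ns - cfg$n_null_spike
  stopifnot(n >= ns, n_de_spike %% length(cfg$de_ratios) == 0L)

  with_seed(mix_seed(seed, 7L), {
    spike_rows <- sort(sample.int(n, ns))
    ratio <- rep(NA_real_, n)
    ratio[spike_rows[seq_len(cfg$n_null_spike)]] <- 1
    de_rows <- spike_rows[-seq_len(cfg$n_null_spike)]
    ratio[de_rows] <- rep(cfg$de_ratios,
                          each = n_de_spike / length(cfg$de_ratios))

    mu1 <- stats::rlnorm(n, cfg$meanlog, cfg$sdlog)
    mu1[spike_rows] <- stats::rlnorm(ns, cfg$spike_meanlog, cfg$sdlog)
    fold <- rep(1, n)
    fold[!is.na(ratio)] <- ratio[!is.na(ratio)]
    bg <- which(is.na(ratio))
    nuis <- sample(bg, round(cfg$nuisance_fraction * length(bg)))
    fold[nuis] <- exp(stats::rnorm(length(nuis), 0, cfg$nuisance_lfc_sd))
    mu2 <- mu1 * fold

    disp <- pmax(stats::rgamma(n, cfg$disp_shape, cfg$disp_rate),
                 cfg$disp_floor)
    counts <- matrix(0L, n, 2L * cfg$reps)
    for (j in seq_len(cfg$reps)) {
      counts[, j] <- stats::rnbinom(n, mu = mu1, size = 1 / disp)
      counts[, cfg$reps + j] <- stats::rnbinom(n, mu = mu2, size = 1 / disp)
    }
    colnames(counts) <- c(paste0("cond1_", seq_len(cfg$reps)),
                          paste0("cond2_", seq_len(cfg$reps)))

    gene_id <- sprintf("gene_%05d", seq_len(n))
    gene_id[spike_rows] <- sprintf("spike_%03d", seq_len(ns))
    gt <- rep(NA, n)
    gt[spike_rows] <- ratio[spike_rows] != 1
    data.frame(gene_id = gene_id, counts, GT_DE = gt, spike_ratio = ratio,
               check.names = FALSE, stringsAsFactors = FALSE)
  })
}

de_count_columns <- function(input) {
  g1 <- grep("^cond1_", names(input), value = TRUE)
  g2 <- grep("^cond2_", names(input), value = TRUE)
  if (length(g1) < 2L || length(g2) < 2L)
    abort("DE caller requires >= 2 replicate columns per condition ",
          "(cond1_* / cond2_*)")
  list(g1 = g1, g2 = g2)
}

#' Call differential expression with explicit sensitivity controls
#'
#' A transparent DE caller whose parameters expose the sensitivity /
#' specificity trade-off: genes whose counts-per-million stay below
#' `cpm_cutoff` in every sample are excluded (DE = 0); remaining genes are
#' scored by a two-group log-ratio statistic whose variance combines the
#' negative-binomial mean-variance relation with a method-of-moments
#' dispersion (either one `common` value or `per-gene`); p-values are
#' referred to a Student t reference with `n1 + n2 - 2` degrees of freedom,
#' adjusted by the chosen multiple-testing method, and a gene is labelled
#' `DE = +1` (up in condition 2) or `-1` (down) when its adjusted p-value
#' falls below `fdr_threshold`.
#'
#' @param input Count table as produced by [generate_seqc_like()] (count
#'   columns `cond1_*` / `cond2_*`; extra columns ignored).
#' @param values Parameter list: `normalization` (`"total-count"` or
#'   `"median-of-ratios"`), `dispersion` (`"common"` or `"per-gene"`),
#'   `cpm_cutoff` in `[0, 10]`, `p_adjust` (`"BH"`, `"holm"`,
#'   `"bonferroni"`, `"none"`), `fdr_threshold` in `(0, 1)`.
#' @return `list(tables = list(de_calls = data.frame(gene_id, DE, isDE)))`
#'   with `DE` in `{-1, 0, +1}` and `isDE == (DE != 0)`.
#' @export
de_caller_run <- function(input, values) {
  cols <- de_count_columns(input)
  k1 <- as.matrix(input[cols$g1]); k2 <- as.matrix(input[cols$g2])
  storage.mode(k1) <- "double"; storage.mode(k2) <- "double"
  counts <- cbind(k1, k2)
  if (any(counts < 0) || any(counts != round(counts)))
    abort("counts must be non-negative integers")
  n1 <- ncol(k1); n2 <- ncol(k2)
  libsize <- colSums(counts)

  sf <- switch(values$normalization,
    "total-count" = libsize / mean(libsize),
    "median-of-ratios" = {
      lg <- rowMeans(log(counts))
      ok <- is.finite(lg)
      if (!any(ok)) abort("median-of-ratios undefined: no gene has all ",
                          "counts positive")
      apply(counts[ok, , drop = FALSE], 2L,
            function(col) stats::median(exp(log(col) - lg[ok])))
    },
    abort("unknown normalization '", values$normalization, "'"))

  cpm <- sweep(counts, 2L, libsize, "/") * 1e6
  tested <- apply(cpm >= values$cpm_cutoff, 1L, any)
  de <- integer(nrow(counts))
  if (!any(tested)) {
    warning("all genes fall below the CPM cutoff; no gene tested")
  } else {
    x <- sweep(counts[tested, , drop = FALSE], 2L, sf, "/")
    x1 <- x[, seq_len(n1), drop = FALSE]
    x2 <- x[, n1 + seq_len(n2), drop = FALSE]
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    v1 <- apply(x1, 1L, stats::var); v2 <- apply(x2, 1L, stats::var)

    # Method-of-moments NB dispersion from both groups. Per-gene estimates
    # are deliberately left untruncated: phi_g = (v - m)/m^2 makes the
    # modeled variance m + phi m^2 coincide with the sample variance, which
    # keeps the test's type-I rate close to nominal at few replicates
    # (truncating at zero inflates the variance and makes it conservative).
    # The shared common-dispersion value is truncated, as a negative common
    # dispersion is meaningless.
    phi_hat <- function(m, v) ifelse(m > 0, (v - m) / m^2, NA)
    phi_g <- rowMeans(cbind(phi_hat(m1, v1), phi_hat(m2, v2)), na.rm = TRUE)
    phi_g[!is.finite(phi_g)] <- 0
    phi <- switch(values$dispersion,
      "per-gene" = phi_g,
      "common" = rep(stats::median(pmax(phi_g, 0), na.rm = TRUE),
                     length(phi_g)),
      abort("unknown dispersion mode '", values$dispersion, "'"))

    c0 <- 0.5
    lfc <- log(m2 + c0) - log(m1 + c0)
    var_mean <- function(m, n) pmax((m + phi * m^2) / n, 0)
    se2 <- var_mean(m1, n1) / (m1 + c0)^2 + var_mean(m2, n2) / (m2 + c0)^2
    z <- lfc / sqrt(pmax(se2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(z), df = n1 + n2 - 2)
    padj <- stats::p.adjust(p, method = values$p_adjust)
    de[tested] <- ifelse(padj < values$fdr_threshold, sign(lfc), 0)
  }
  out <- data.frame(gene_id = input$gene_id %||% seq_len(nrow(counts)),
                    DE = as.integer(de), isDE = de != 0L,
                    stringsAsFactors = FALSE)
  list(tables = list(de_calls = out))
}

#' The differential-expression demo app
#'
#' Bundles [de_caller_run()] with its manifest: normalization method,
#' dispersion mode, CPM cutoff in `[0, 10]`, p-value adjustment method
#' (BH, holm, bonferroni, none) and FDR threshold in `(0, 1)`. Emits one
#' `de_calls` table per run.
#'
#' @return A [ps_app()].
#' @export
de_demo_app <- function() {
  manifest <- ps_manifest(
    "de_caller",
    list(
      ps_param("normalization", "categorical", "median-of-ratios",
               items = c("total-count", "median-of-ratios")),
      ps_param("dispersion", "categorical", "per-gene",
               items = c("common", "per-gene")),
      ps_param("cpm_cutoff", "double", 1, min = 0, max = 10),
      ps_param("p_adjust", "categorical", "BH",
               items = c("BH", "holm", "bonferroni", "none")),
      ps_param("fdr_threshold", "double", 0.05, min = 0.001, max = 0.999)
    ),
    output_tables = "de_calls",
    emits_image = FALSE)
  ps_app(manifest, de_caller_run)
}
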