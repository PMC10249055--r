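playground_features <- c("x1", "x2", "x1sq", "x2sq", "x1x2", "sin_x1",
                         "sin_x2")

#' Generate a 2-D classification dataset in the playground style
#'
#' Four classic shapes on the `[-5, 5]` square, 200 points split exactly
#' 100/100 between the labels `-1` and `+1`:
#' \describe{
#'   \item{`gauss`}{two Gaussian blobs at `(2, 2)` / `(-2, -2)`; the noise
#'     level widens the blob standard deviation linearly from 0.5 (noise 0)
#'     to 4 (noise 50).}
#'   \item{`circle`}{positives on an inner disk (radius up to 2.5),
#'     negatives on an outer annulus (radius 3.5 to 5).}
#'   \item{`xor`}{uniform points pushed 0.3 away from the axes, labelled by
#'     the quadrant product `sign(x1 * x2)`.}
#'   \item{`spiral`}{two interleaved Archimedean arms (angle proportional
#'     to radius, 1.75 turns, half a turn apart), labelled by arm.}
#' }
#' For `circle`, `xor` and `spiral` the noise level `v` perturbs the point
#' used for labelling by a uniform offset of `v`% of the domain half-width
#' per coordinate, so labels flip near class boundaries while stored
#' coordinates stay clean (class overlap grows with noise). The seven
#' standard feature transforms are emitted alongside the raw coordinates.
#'
#' @param shape One of `"gauss"`, `"circle"`, `"xor"`, `"spiral"`.
#' @param noise Noise level in `[0, 50]`.
#' @param seed Seed.
#' @param n Total number of points (even; half per label).
#' @return Data frame with columns `x1`, `x2`, `x1sq`, `x2sq`, `x1x2`,
#'   `sin_x1`, `sin_x2`, `label` (`-1`/`+1`).
#' @export
generate_playground_dataset <- function(shape, noise = 0, seed = 0L,
                                        n = 200L) {
  shapes <- c("gauss", "circle", "xor", "spiral")
  if (!is.character(shape) || length(shape) != 1L || !shape %in% shapes)
    abort("shape must be one of: ", paste(shapes, collapse = ", "))
  if (!is.numeric(noise) || length(noise) != 1L || noise < 0 || noise > 50)
    abort("noise must be a number in [0, 50]")
  stopifnot(n %% 2L == 0L)
  R <- 5
  half <- n %/% 2L
  with_seed(mix_seed(seed, 11L), {
    pts <- switch(shape,
      gauss = {
        sd <- 0.5 + 3.5 * noise / 50
        data.frame(
          x1 = c(stats::rnorm(half, 2, sd), stats::rnorm(half, -2, sd)),
          x2 = c(stats::rnorm(half, 2, sd), stats::rnorm(half, -2, sd)),
          label = rep(c(1, -1), each = half))
      },
      spiral = {
        one_arm <- function(delta, label) {
          i <- seq_len(half) - 1L
          r <- i / half * R
          t <- 1.75 * i / half * 2 * pi + delta
          data.frame(x1 = r * sin(t) + stats::runif(half, -R, R) * noise / 100,
                     x2 = r * cos(t) + stats::runif(half, -R, R) * noise / 100,
                     label = label)
        }
        rbind(one_arm(0, 1), one_arm(pi, -1))
      },
      # circle and xor: draw candidates, label at a noise-perturbed probe
      # position, and fill the two label quotas by rejection
      circle = sample_balanced(half, function() {
        inside <- stats::runif(1) < 0.5
        r <- if (inside) stats::runif(1, 0, R * 0.5)
             else stats::runif(1, R * 0.7, R)
        a <- stats::runif(1, 0, 2 * pi)
        x <- c(r * sin(a), r * cos(a))
        probe <- x + stats::runif(2, -R, R) * noise / 100
        list(x = x, label = if (sqrt(sum(probe^2)) < R * 0.5) 1 else -1)
      }),
      xor = sample_balanced(half, function() {
        x <- stats::runif(2, -R, R)
        x <- x + sign(x) * 0.3
        probe <- x + stats::runif(2, -R, R) * noise / 100
        list(x = x, label = if (prod(probe) >= 0) 1 else -1)
      }))
    pts$label <- as.integer(pts$label)
    data.frame(x1 = pts$x1, x2 = pts$x2,
               x1sq = pts$x1^2, x2sq = pts$x2^2, x1x2 = pts$x1 * pts$x2,
               sin_x1 = sin(pts$x1), sin_x2 = sin(pts$x2),
               label = pts$label)
  })
}

sample_balanced <- function(half, draw1) {
  got <- c(`-1` = 0L, `1` = 0L)
  xs <- matrix(NA_real_, 2L * half, 2L)
  labs <- integer(2L * half)
  filled <- 0L
  guard <- 0L
  while (filled < 2L * half) {
    guard <- guard + 1L
    if (guard > 2e5L) abort("balanced sampling did not converge")
    d <- draw1()
    key <- as.character(d$label)
    if (got[[key]] >= half) next
    got[[key]] <- got[[key]] + 1L
    filled <- filled + 1L
    xs[filled, ] <- d$x
    labs[[filled]] <- d$label
  }
  data.frame(x1 = xs[, 1L], x2 = xs[, 2L], label = labs)
}

activation_funs <- list(
  linear = list(f = function(x) x, df = function(a) 1),
  relu = list(f = function(x) pmax(x, 0), df = function(a) (a > 0) * 1),
  sigmoid = list(f = function(x) 1 / (1 + exp(-x)),
                 df = function(a) a * (1 - a)),
  tanh = list(f = base::tanh, df = function(a) 1 - a^2))

#' Train a small fully connected network with checkpointed metrics
#'
#' Mini-batch gradient descent on the squared-error loss
#' `0.5 * mean((f(x) - y)^2)` with targets `y` in `{-1, +1}` and a tanh
#' output unit; classification thresholds the output at 0. Hidden layers
#' share one activation (`linear` is the identity, so a linear-activation
#' network of any depth has an affine decision boundary). Weights start uniform on
#' `(-0.5, 0.5)`, seeded. L1/L2 penalties act on the weights only. At each
#' checkpoint epoch the train/test loss, TPR, FPR, cumulative training
#' time and mean per-epoch time are recorded; a training run whose loss
#' turns non-finite stops early and is flagged `diverged`, keeping one
#' record per checkpoint with missing metrics (sessions mark the run's
#' records with status `"failed"`).
#'
#' @param dataset A [generate_playground_dataset()] table.
#' @param hyper Named list: `n_layers` (0-6), `n_neurons` (1-8),
#'   `features` (character subset of the seven feature names),
#'   `train_ratio`, `batch_size`, `learning_rate`, `activation`,
#'   `regularization` (`"none"`, `"L1"`, `"L2"`), `reg_rate`, `seed`.
#' @param checkpoints Increasing vector of epoch counts at which metrics
#'   are recorded.
#' @return `list(records = <one row per checkpoint>, predictions =
#'   data.frame(pred_label), weights = final weight list, split = logical
#'   train-membership vector)`.
#' @export
mlp_train <- function(dataset, hyper, checkpoints = c(50, 100, 200, 400)) {
  feats <- hyper$features
  if (length(feats) == 0L) abort("at least one input feature is required")
  bad <- setdiff(feats, playground_features)
  if (length(bad)) abort("unknown feature(s): ", paste(bad, collapse = ", "))
  checkpoints <- sort(unique(as.integer(checkpoints)))
  X <- as.matrix(dataset[feats])
  y <- dataset$label
  n <- nrow(X)
  act <- activation_funs[[hyper$activation]]
  if (is.null(act)) abort("unknown activation '", hyper$activation, "'")
  lr <- as.numeric(hyper$learning_rate)
  lambda <- as.numeric(hyper$reg_rate %||% 0)
  reg <- hyper$regularization %||% "none"
  seed <- as.integer(hyper$seed %||% 0L)

  n_train <- max(1L, min(n - 1L, round(as.numeric(hyper$train_ratio) * n)))
  sizes <- c(ncol(X), rep(as.integer(hyper$n_neurons),
                          as.integer(hyper$n_layers)), 1L)
  state <- with_seed(mix_seed(seed, 13L), {
    train_idx <- sample.int(n, n_train)
    W <- lapply(seq_len(length(sizes) - 1L), function(l)
      matrix(stats::runif(sizes[l] * sizes[l + 1L], -0.5, 0.5),
             sizes[l], sizes[l + 1L]))
    b <- lapply(seq_len(length(sizes) - 1L), function(l)
      stats::runif(sizes[l + 1L], -0.5, 0.5))
    list(train_idx = train_idx, W = W, b = b)
  })
  W <- state$W; b <- state$b
  train_idx <- state$train_idx
  is_train <- seq_len(n) %in% train_idx
  Xtr <- X[train_idx, , drop = FALSE]; ytr <- y[train_idx]
  Xte <- X[-train_idx, , drop = FALSE]; yte <- y[-train_idx]
  L <- length(W)

  # hidden layers use the chosen activation; the output unit is tanh, so
  # predictions live in (-1, 1) like the targets and the loss is bounded
  forward <- function(xm) {
    a <- list(xm)
    for (l in seq_len(L)) {
      z <- a[[l]] %*% W[[l]] + matrix(b[[l]], nrow(xm), length(b[[l]]),
                                      byrow = TRUE)
      a[[l + 1L]] <- if (l < L) act$f(z) else tanh(z)
    }
    a
  }
  data_loss <- function(xm, yv) {
    if (!nrow(xm)) return(NA_real_)
    pred <- forward(xm)[[L + 1L]][, 1L]
    0.5 * mean((pred - yv)^2)
  }
  rates <- function(xm, yv) {
    if (!nrow(xm)) return(c(NA_real_, NA_real_))
    pred <- forward(xm)[[L + 1L]][, 1L] > 0
    c(tpr = if (any(yv > 0)) mean(pred[yv > 0]) else NA_real_,
      fpr = if (any(yv < 0)) mean(pred[yv < 0]) else NA_real_)
  }

  bs <- max(1L, min(as.integer(hyper$batch_size), n_train))
  records <- NULL
  t_start <- proc.time()[["elapsed"]]
  epoch_stream <- mix_seed(seed, 17L)
  max_epoch <- max(checkpoints)
  for (epoch in seq_len(max_epoch)) {
    ord <- with_seed(mix_seed(epoch_stream, epoch), sample.int(n_train))
    for (start in seq(1L, n_train, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n_train)]
      a <- forward(Xtr[idx, , drop = FALSE])
      m <- length(idx)
      delta <- (a[[L + 1L]] - ytr[idx]) * (1 - a[[L + 1L]]^2) / m
      for (l in rev(seq_len(L))) {
        gW <- crossprod(a[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L)
          delta <- (delta %*% t(W[[l]])) * act$df(a[[l]])
        pen <- switch(reg, none = 0, L1 = lambda * sign(W[[l]]),
                      L2 = lambda * W[[l]])
        W[[l]] <- W[[l]] - lr * (gW + pen)
        b[[l]] <- b[[l]] - lr * gb
      }
    }
    if (epoch %in% checkpoints) {
      tl <- data_loss(Xtr, ytr)
      if (!is.finite(tl)) { diverged <- TRUE; break }
      el <- proc.time()[["elapsed"]] - t_start
      rtr <- rates(Xtr, ytr); rte <- rates(Xte, yte)
      records <- rbind(records, data.frame(
        epoch = epoch, train_loss = tl, test_loss = data_loss(Xte, yte),
        train_tpr = rtr[[1L]], train_fpr = rtr[[2L]],
        test_tpr = rte[[1L]], test_fpr = rte[[2L]],
        total_time = round(el, 4),
        mean_time = round(el / epoch, 6)))
    }
  }
  diverged <- exists("diverged", inherits = FALSE) && isTRUE(diverged)
  # a diverged run keeps one record per checkpoint, metrics missing
  missing_cp <- checkpoints[!checkpoints %in% records$epoch]
  if (diverged && length(missing_cp))
    records <- rbind(records, data.frame(
      epoch = missing_cp, train_loss = NA_real_, test_loss = NA_real_,
      train_tpr = NA_real_, train_fpr = NA_real_, test_tpr = NA_real_,
      test_fpr = NA_real_, total_time = NA_real_, mean_time = NA_real_))
  pred <- forward(X)[[L + 1L]][, 1L]
  pred <- ifelse(is.finite(pred), ifelse(pred > 0, 1L, -1L), NA_integer_)
  list(records = records, diverged = diverged,
       predictions = data.frame(pred_label = pred),
       weights = list(W = W, b = b), split = is_train)
}

mlp_decision_image <- function(dataset, weights, hyper, split) {
  act <- activation_funs[[hyper$activation]]
  grid <- expand.grid(x1 = seq(-6, 6, length.out = 60),
                      x2 = seq(-6, 6, length.out = 60))
  gd <- data.frame(x1 = grid$x1, x2 = grid$x2, x1sq = grid$x1^2,
                   x2sq = grid$x2^2, x1x2 = grid$x1 * grid$x2,
                   sin_x1 = sin(grid$x1), sin_x2 = sin(grid$x2))
  a <- as.matrix(gd[hyper$features])
  W <- weights$W; b <- weights$b
  for (l in seq_along(W)) {
    z <- a %*% W[[l]] + matrix(b[[l]], nrow(a), length(b[[l]]), byrow = TRUE)
    a <- if (l < length(W)) act$f(z) else z
  }
  z <- matrix(a[, 1L], 60, 60)
  function(path = NULL) {
    graphics::image(seq(-6, 6, length.out = 60), seq(-6, 6, length.out = 60),
                    z > 0, col = c("#ffe0b2", "#bbdefb"), xlab = "x1",
                    ylab = "x2", main = "decision surface")
    graphics::points(dataset$x1, dataset$x2,
                     col = ifelse(dataset$label > 0, "#1565c0", "#ef6c00"),
                     pch = 21, bg = ifelse(split, "white", "black"),
                     cex = 0.8)
  }
}

#' The multilayer-perceptron demo app
#'
#' Wraps [mlp_train()] as a sampleable app over the playground
#' hyperparameters: hidden layer count 0-6, neurons per layer 1-8, seven
#' independent feature toggles, train/test split ratio, batch size 1-30,
#' learning rate and regularization rate from the playground's discrete
#' menus, activation (`linear`, `relu`, `sigmoid`, `tanh`) and
#' regularization (`none`, `L1`, `L2`). One *training run* per sampled
#' combination is checkpointed at the `checkpoints` epochs, and every
#' checkpoint becomes its own record (row) of the runs table via the
#' app-record mechanism, with `epoch` as a recorded column; the run's
#' predicted-labels table and optional decision-surface image are stored
#' under the combination's first record id.
#'
#' @param checkpoints Epochs at which metrics are recorded (default
#'   `c(50, 100, 200, 400)`).
#' @param emit_images Render a decision-surface image per combination
#'   (default `FALSE`; bulk sweeps get large otherwise).
#' @return A [ps_app()].
#' @export
mlp_demo_app <- function(checkpoints = c(50, 100, 200, 400),
                         emit_images = FALSE) {
  lr_items <- c("0.00001", "0.0001", "0.001", "0.003", "0.01", "0.03",
                "0.1", "0.3", "1", "3", "10")
  rr_items <- c("0", "0.001", "0.003", "0.01", "0.03", "0.1", "0.3", "1",
                "3")
  params <- c(
    list(ps_param("n_layers", "integer", 1, min = 0, max = 6),
         ps_param("n_neurons", "integer", 4, min = 1, max = 8)),
    lapply(playground_features, function(f)
      ps_param(paste0("use_", f), "boolean",
               default = f %in% c("x1", "x2"))),
    list(
      ps_param("train_ratio", "double", 0.5, min = 0.1, max = 0.9),
      ps_param("batch_size", "integer", 10, min = 1, max = 30),
      ps_param("learning_rate", "categorical", "0.03", items = lr_items),
      ps_param("activation", "categorical", "tanh",
               items = c("linear", "relu", "sigmoid", "tanh")),
      ps_param("regularization", "categorical", "none",
               items = c("none", "L1", "L2")),
      ps_param("reg_rate", "categorical", "0", items = rr_items),
      ps_param("seed", "integer", 0, min = 0, max = 1e9)))
  manifest <- ps_manifest("mlp", params, output_tables = "predictions",
                          emits_image = emit_images)
  record_cols <- c("epoch", "train_loss", "test_loss", "train_tpr",
                   "train_fpr", "test_tpr", "test_fpr", "total_time",
                   "mean_time")
  run <- function(input, values) {
    feats <- playground_features[vapply(playground_features, function(f)
      isTRUE(as.logical(values[[paste0("use_", f)]])), TRUE)]
    if (length(feats) == 0L) {
      # an empty feature set cannot be trained; keep the one-record-per-
      # checkpoint contract with missing metrics and a failed status
      return(list(
        tables = list(predictions = data.frame(
          pred_label = rep(NA_integer_, nrow(input)))),
        records = data.frame(
          epoch = sort(unique(as.integer(checkpoints))),
          train_loss = NA_real_, test_loss = NA_real_, train_tpr = NA_real_,
          train_fpr = NA_real_, test_tpr = NA_real_, test_fpr = NA_real_,
          total_time = NA_real_, mean_time = NA_real_),
        status = "failed"))
    }
    hyper <- list(
      n_layers = values$n_layers, n_neurons = values$n_neurons,
      features = feats, train_ratio = values$train_ratio,
      batch_size = values$batch_size,
      learning_rate = as.numeric(values$learning_rate),
      activation = values$activation,
      regularization = values$regularization,
      reg_rate = as.numeric(values$reg_rate), seed = values$seed)
    fit <- mlp_train(input, hyper, checkpoints)
    out <- list(tables = list(predictions = fit$predictions),
                records = fit$records,
                status = if (fit$diverged) "failed" else "ok")
    if (emit_images)
      out$image <- mlp_decision_image(input, fit$weights, hyper, fit$split)
    out
  }
  ps_app(manifest, run, record_columns = record_cols)
}
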