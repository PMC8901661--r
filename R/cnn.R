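# A compact convolutional network for spectrogram classification,
# implemented with im2col matrix multiplication: three 3x3 conv blocks
# (ReLU + 2x2 max-pool) feeding a fully connected hidden layer and a
# softmax output. Trained with minibatch SGD + momentum, a stepped
# learning-rate schedule and best-validation-accuracy checkpointing.

#' Training configuration for the spectrogram classifier
#'
#' Defaults follow the study protocol: 20 epochs, minibatch 32, initial
#' learning rate 0.001 with a drop factor of 10^-0.5 (every
#' `lrDropPeriod` epochs), a stratified random 70/30 train/validation
#' split per trial, and 10 repeated trials.
#'
#' @param task "valence" (binary) or "context" (multi-class).
#' @param backbone "small_cnn" (the bundled 3-conv-block network).
#'   "resnet50_transfer" is accepted for interface compatibility but
#'   requires pretrained weights that are not bundled, and errors.
#' @param epochs,batch,lr,lrDropFactor,lrDropPeriod optimizer settings.
#' @param split train fraction in (0, 1).
#' @param nTrials repeated trials for the metric summary.
#' @param momentum SGD momentum.
#' @param hidden width of the fully connected hidden layer.
#' @param convFilters filters per conv block.
#' @param rngSeed integer seed; trial t uses `rngSeed + t`.
#' @return list of class `TrainConfig`.
#' @export
trainConfig <- function(task = c("valence", "context"),
                        backbone = c("small_cnn", "resnet50_transfer"),
                        epochs = 20L, batch = 32L, lr = 0.001,
                        lrDropFactor = 10^-0.5, lrDropPeriod = 10L,
                        split = 0.7, nTrials = 10L, momentum = 0.9,
                        hidden = 64L, convFilters = c(8L, 16L, 32L),
                        rngSeed = 1L) {
  task <- match.arg(task)
  backbone <- match.arg(backbone)
  stopifnot(split > 0, split < 1, epochs >= 1, batch >= 1, nTrials >= 1,
            length(convFilters) == 3L)
  out <- list(task = task, backbone = backbone, epochs = as.integer(epochs),
              batch = as.integer(batch), lr = lr,
              lrDropFactor = lrDropFactor,
              lrDropPeriod = as.integer(lrDropPeriod), split = split,
              nTrials = as.integer(nTrials), momentum = momentum,
              hidden = as.integer(hidden),
              convFilters = as.integer(convFilters),
              rngSeed = as.integer(rngSeed))
  class(out) <- "TrainConfig"
  out
}

# ---- conv plumbing -------------------------------------------------------

# im2col index block for 3x3/pad-1 convolution over an (H, W, C, N)
# array: linear indices into the zero-padded array for each of the 9
# offsets, one column block per (offset, channel).
.convIndices <- function(H, W, N) {
  H2 <- H + 2L; W2 <- W + 2L
  i <- rep.int(seq_len(H), W * N)
  j <- rep.int(rep(seq_len(W), each = H), N)
  n <- rep(seq_len(N), each = H * W)
  # top-left corner of each 3x3 patch in padded coordinates
  base <- i + (j - 1L) * H2
  list(base = base, n = n, H2 = H2, W2 = W2)
}

.convForward <- function(x, Wmat, b, geom) {
  d <- dim(x); H <- d[1L]; W <- d[2L]; C <- d[3L]; N <- d[4L]
  H2 <- geom$H2; W2 <- geom$W2
  xp <- array(0, c(H2, W2, C, N))
  xp[2:(H + 1L), 2:(W + 1L), , ] <- x
  planeC <- H2 * W2
  planeN <- planeC * C
  npos <- length(geom$base)
  cols <- matrix(0, npos, 9L * C)
  baseN <- geom$base + (geom$n - 1L) * planeN
  k <- 0L
  for (c in seq_len(C)) {
    off_c <- (c - 1L) * planeC
    for (dj in 0:2) for (di in 0:2) {
      k <- k + 1L
      cols[, k] <- xp[baseN + off_c + di + dj * H2]
    }
  }
  outMat <- cols %*% Wmat
  outMat <- sweep(outMat, 2L, b, "+")
  F <- length(b)
  out <- aperm(array(outMat, c(H, W, N, F)), c(1L, 2L, 4L, 3L))
  list(out = out, cols = cols)
}

.convBackward <- function(dout, cols, Wmat, xdim, geom) {
  H <- xdim[1L]; W <- xdim[2L]; C <- xdim[3L]; N <- xdim[4L]
  F <- ncol(Wmat)
  dmat <- matrix(aperm(dout, c(1L, 2L, 4L, 3L)), ncol = F)
  dW <- crossprod(cols, dmat)
  db <- colSums(dmat)
  dcols <- dmat %*% t(Wmat)
  H2 <- geom$H2; W2 <- geom$W2
  planeC <- H2 * W2
  planeN <- planeC * C
  dxp <- numeric(planeN * N)
  baseN <- geom$base + (geom$n - 1L) * planeN
  k <- 0L
  for (c in seq_len(C)) {
    off_c <- (c - 1L) * planeC
    for (dj in 0:2) for (di in 0:2) {
      k <- k + 1L
      idx <- baseN + off_c + di + dj * H2
      dxp[idx] <- dxp[idx] + dcols[, k]
    }
  }
  dxp <- array(dxp, c(H2, W2, C, N))
  list(dx = dxp[2:(H + 1L), 2:(W + 1L), , , drop = FALSE], dW = dW,
       db = db)
}

.poolForward <- function(x) {
  d <- dim(x); H <- d[1L]; W <- d[2L]
  io <- seq(1L, H, 2L); jo <- seq(1L, W, 2L)
  s <- list(x[io, jo, , , drop = FALSE], x[io + 1L, jo, , , drop = FALSE],
            x[io, jo + 1L, , , drop = FALSE],
            x[io + 1L, jo + 1L, , , drop = FALSE])
  out <- pmax(s[[1L]], s[[2L]], s[[3L]], s[[4L]])
  # first slab attaining the max wins (deterministic tie-break)
  w <- array(1L, dim(out))
  w[s[[1L]] < out & s[[2L]] >= out] <- 2L
  w[s[[1L]] < out & s[[2L]] < out & s[[3L]] >= out] <- 3L
  w[s[[1L]] < out & s[[2L]] < out & s[[3L]] < out] <- 4L
  list(out = out, argmax = w)
}

.poolBackward <- function(dout, argmax, xdim) {
  dx <- array(0, xdim)
  H <- xdim[1L]; W <- xdim[2L]
  io <- seq(1L, H, 2L); jo <- seq(1L, W, 2L)
  for (k in 1:4) {
    mask <- argmax == k
    di <- (k - 1L) %% 2L; dj <- (k - 1L) %/% 2L
    slab <- array(0, dim(dout))
    slab[mask] <- dout[mask]
    dx[io + di, jo + dj, , ] <- slab
  }
  dx
}

# ---- network -------------------------------------------------------------

.heInit <- function(nin, n) rnorm(n, 0, sqrt(2 / nin))

.cnnInit <- function(inputSize, nClasses, cfg) {
  f <- cfg$convFilters
  H <- inputSize[1L]; W <- inputSize[2L]
  stopifnot(H %% 8L == 0L, W %% 8L == 0L)
  flat <- (H %/% 8L) * (W %/% 8L) * f[3L]
  list(
    W1 = matrix(.heInit(9, 9 * f[1L]), 9, f[1L]), b1 = numeric(f[1L]),
    W2 = matrix(.heInit(9 * f[1L], 9 * f[1L] * f[2L]), 9 * f[1L], f[2L]),
    b2 = numeric(f[2L]),
    W3 = matrix(.heInit(9 * f[2L], 9 * f[2L] * f[3L]), 9 * f[2L], f[3L]),
    b3 = numeric(f[3L]),
    W4 = matrix(.heInit(flat, flat * cfg$hidden), cfg$hidden, flat),
    b4 = numeric(cfg$hidden),
    W5 = matrix(.heInit(cfg$hidden, cfg$hidden * nClasses), nClasses,
                cfg$hidden),
    b5 = numeric(nClasses)
  )
}

# forward pass; returns softmax probabilities (and, if wanted, the cache
# for backprop and the hidden fully connected activations)
.cnnForward <- function(params, x, cache = FALSE) {
  d <- dim(x)
  if (length(d) == 3L) x <- array(x, c(d[1L], d[2L], 1L, d[3L]))
  d <- dim(x); N <- d[4L]
  g1 <- .convIndices(d[1L], d[2L], N)
  c1 <- .convForward(x, params$W1, params$b1, g1)
  r1 <- pmax(c1$out, 0)
  p1 <- .poolForward(r1)
  d1 <- dim(p1$out)
  g2 <- .convIndices(d1[1L], d1[2L], N)
  c2 <- .convForward(p1$out, params$W2, params$b2, g2)
  r2 <- pmax(c2$out, 0)
  p2 <- .poolForward(r2)
  d2 <- dim(p2$out)
  g3 <- .convIndices(d2[1L], d2[2L], N)
  c3 <- .convForward(p2$out, params$W3, params$b3, g3)
  r3 <- pmax(c3$out, 0)
  p3 <- .poolForward(r3)
  flat <- matrix(p3$out, ncol = N)   # (H/8*W/8*F3) x N
  h <- pmax(params$W4 %*% flat + params$b4, 0)
  logits <- params$W5 %*% h + params$b5
  m <- apply(logits, 2L, max)
  e <- exp(sweep(logits, 2L, m))
  probs <- sweep(e, 2L, colSums(e), "/")
  if (!cache) return(list(probs = probs, hidden = h))
  list(probs = probs, hidden = h,
       cache = list(x = x, g1 = g1, c1 = c1, r1 = r1, p1 = p1, g2 = g2,
                    c2 = c2, r2 = r2, p2 = p2, g3 = g3, c3 = c3, r3 = r3,
                    p3 = p3, flat = flat, h = h))
}

.cnnBackward <- function(params, fw, yIdx) {
  ca <- fw$cache
  N <- ncol(fw$probs)
  dlogits <- fw$probs
  dlogits[cbind(yIdx, seq_len(N))] <-
    dlogits[cbind(yIdx, seq_len(N))] - 1
  dlogits <- dlogits / N
  g <- list()
  g$W5 <- dlogits %*% t(ca$h); g$b5 <- rowSums(dlogits)
  dh <- t(params$W5) %*% dlogits
  dh[ca$h <= 0] <- 0
  g$W4 <- dh %*% t(ca$flat); g$b4 <- rowSums(dh)
  dflat <- t(params$W4) %*% dh
  dp3 <- array(dflat, dim(ca$p3$out))
  dr3 <- .poolBackward(dp3, ca$p3$argmax, dim(ca$r3))
  dr3[ca$r3 <= 0] <- 0
  bk3 <- .convBackward(dr3, ca$c3$cols, params$W3, dim(ca$p2$out), ca$g3)
  g$W3 <- bk3$dW; g$b3 <- bk3$db
  dp2 <- bk3$dx
  dr2 <- .poolBackward(dp2, ca$p2$argmax, dim(ca$r2))
  dr2[ca$r2 <= 0] <- 0
  bk2 <- .convBackward(dr2, ca$c2$cols, params$W2, dim(ca$p1$out), ca$g2)
  g$W2 <- bk2$dW; g$b2 <- bk2$db
  dp1 <- bk2$dx
  dr1 <- .poolBackward(dp1, ca$p1$argmax, dim(ca$r1))
  dr1[ca$r1 <= 0] <- 0
  bk1 <- .convBackward(dr1, ca$c1$cols, params$W1, dim(ca$x), ca$g1)
  g$W1 <- bk1$dW; g$b1 <- bk1$db
  g
}

# ---- metrics -------------------------------------------------------------

#' Classification metrics from labels
#'
#' Accuracy, precision, recall and F1. For binary problems with a
#' designated `positive` class the binary formulas are used; otherwise
#' per-class one-vs-rest metrics are averaged weighted by class support
#' in `truth`.
#'
#' @param truth,pred character vectors of labels.
#' @param positive positive class label for the binary case, or NULL for
#'   weighted multi-class averaging.
#' @return named numeric: accuracy, precision, recall, f1.
#' @export
classificationMetrics <- function(truth, pred, positive = NULL) {
  stopifnot(length(truth) == length(pred))
  acc <- mean(truth == pred)
  prf <- function(pos) {
    tp <- sum(truth == pos & pred == pos)
    fp <- sum(truth != pos & pred == pos)
    fn <- sum(truth == pos & pred != pos)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(p, r, f)
  }
  if (!is.null(positive)) {
    m <- prf(positive)
  } else {
    lev <- sort(unique(truth))
    w <- as.numeric(table(base::factor(truth, levels = lev)))
    w <- w / sum(w)
    ms <- vapply(lev, prf, numeric(3))
    m <- as.numeric(ms %*% w)
  }
  c(accuracy = acc, precision = m[1L], recall = m[2L], f1 = m[3L])
}

# stratified split: for each class, round(split * n_class) indices into
# the training set (at least 1 per class in each half)
.stratifiedSplit <- function(labels, split) {
  train <- integer()
  for (lev in unique(labels)) {
    idx <- which(labels == lev)
    if (length(idx) < 2L)
      stop("class ", lev, " has fewer than 2 examples; stratified ",
           "splitting cannot place it in both halves")
    ntr <- min(max(round(split * length(idx)), 1L), length(idx) - 1L)
    train <- c(train, sample(idx, ntr))
  }
  sort(train)
}

# ---- training ------------------------------------------------------------

#' Train the spectrogram classifier over repeated trials
#'
#' For each trial the data are split stratified 70/30 (per `cfg$split`),
#' the network is trained with minibatch SGD + momentum and the stepped
#' learning-rate schedule, validation accuracy is measured after every
#' epoch, and the best-validation checkpoint is kept. Per-trial metrics
#' (accuracy, precision, recall, F1 on the validation split, from the
#' best checkpoint) are returned with the final trial's model.
#'
#' Valence metrics use the binary formulas treating positive-valence
#' labels as the positive class; context metrics are weighted averages
#' across classes.
#'
#' @param images array (rows, cols, n) from [spectrogramTensor()].
#' @param labels character vector of length n.
#' @param cfg a [trainConfig()].
#' @param verbose print per-epoch progress.
#' @return list with `model` (class `cnnModel`), `trials` (data.frame of
#'   per-trial metrics) and `summary` (from [summarizeTrials()] when
#'   `nTrials >= 2`).
#' @export
trainClassifier <- function(images, labels, cfg = trainConfig(),
                            verbose = FALSE) {
  stopifnot(inherits(cfg, "TrainConfig"),
            length(dim(images)) == 3L,
            dim(images)[3L] == length(labels))
  if (cfg$backbone == "resnet50_transfer")
    stop("the resnet50_transfer backbone requires pretrained weights ",
         "that are not bundled; use backbone = 'small_cnn'")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need >= 2 classes")
  positive <- if (cfg$task == "valence" && "positive" %in% classes)
    "positive" else NULL
  trials <- vector("list", cfg$nTrials)
  model <- NULL
  for (trial in seq_len(cfg$nTrials)) {
    set.seed(cfg$rngSeed + trial)
    tr <- .stratifiedSplit(labels, cfg$split)
    va <- setdiff(seq_along(labels), tr)
    fitted <- .trainOnce(images, labels, classes, tr, va, cfg, verbose)
    pred <- .cnnPredictLabels(fitted$params, images[, , va, drop = FALSE],
                              classes)
    m <- classificationMetrics(labels[va], pred, positive)
    trials[[trial]] <- data.frame(trial = trial, t(m))
    model <- list(backbone = cfg$backbone, params = fitted$params,
                  classes = classes, task = cfg$task, cfg = cfg,
                  inputSize = dim(images)[1:2],
                  bestValAccuracy = fitted$bestAcc)
    class(model) <- "cnnModel"
    if (verbose)
      message(sprintf("trial %d: val accuracy %.3f", trial, m["accuracy"]))
  }
  trials <- do.call(rbind, trials)
  summary <- if (cfg$nTrials >= 2L) summarizeTrials(trials) else NULL
  list(model = model, trials = trials, summary = summary)
}

.cnnPredictLabels <- function(params, images, classes) {
  n <- dim(images)[3L]
  # bounded-memory prediction in chunks
  out <- character(n)
  for (s in seq(1L, n, by = 128L)) {
    e <- min(s + 127L, n)
    probs <- .cnnForward(params, images[, , s:e, drop = FALSE])$probs
    out[s:e] <- classes[max.col(t(probs), ties.method = "first")]
  }
  out
}

.trainOnce <- function(images, labels, classes, tr, va, cfg, verbose) {
  yIdx <- match(labels, classes)
  params <- .cnnInit(dim(images)[1:2], length(classes), cfg)
  vel <- lapply(params, function(p) p * 0)
  best <- params
  bestAcc <- -Inf
  lr <- cfg$lr
  for (epoch in seq_len(cfg$epochs)) {
    if (epoch > 1L && (epoch - 1L) %% cfg$lrDropPeriod == 0L)
      lr <- lr * cfg$lrDropFactor
    ord <- sample(tr)
    for (s in seq(1L, length(ord), by = cfg$batch)) {
      bidx <- ord[s:min(s + cfg$batch - 1L, length(ord))]
      if (length(bidx) < 2L) next
      fw <- .cnnForward(params, images[, , bidx, drop = FALSE],
                        cache = TRUE)
      grads <- .cnnBackward(params, fw, yIdx[bidx])
      for (nm in names(params)) {
        vel[[nm]] <- cfg$momentum * vel[[nm]] - lr * grads[[nm]]
        params[[nm]] <- params[[nm]] + vel[[nm]]
      }
    }
    pred <- .cnnPredictLabels(params, images[, , va, drop = FALSE],
                              classes)
    acc <- mean(pred == labels[va])
    if (acc >= bestAcc) {   # >=: prefer the later, equally good epoch
      bestAcc <- acc
      best <- params
    }
    if (verbose)
      message(sprintf("  epoch %d: lr %.2g val acc %.3f", epoch, lr, acc))
  }
  list(params = best, bestAcc = bestAcc)
}

#' Predict labels for new spectrogram images
#'
#' @param model a `cnnModel` from [trainClassifier()].
#' @param images array (rows, cols, n).
#' @return character vector of predicted labels.
#' @export
predictCalls <- function(model, images) {
  stopifnot(inherits(model, "cnnModel"))
  .cnnPredictLabels(model$params, images, model$classes)
}

#' Penultimate-layer activations of the classifier
#'
#' Returns the activations of the last fully connected hidden layer (the
#' layer feeding the softmax output), one row per input image — the
#' representation inspected by [embedActivations()].
#'
#' @param model a `cnnModel`.
#' @param images array (rows, cols, n).
#' @return numeric matrix (n x hidden width).
#' @export
extractActivations <- function(model, images) {
  stopifnot(inherits(model, "cnnModel"))
  n <- dim(images)[3L]
  out <- matrix(0, n, length(model$params$b4))
  for (s in seq(1L, n, by = 128L)) {
    e <- min(s + 127L, n)
    h <- .cnnForward(model$params, images[, , s:e, drop = FALSE])$hidden
    out[s:e, ] <- t(h)
  }
  out
}

#' Summarize per-trial metrics as mean and standard error
#'
#' @param trials data.frame with columns accuracy, precision, recall, f1
#'   (one row per trial; >= 2 trials).
#' @return data.frame with one row per metric: `mean` and `uncertainty`
#'   (standard error of the mean across trials).
#' @export
summarizeTrials <- function(trials) {
  cols <- c("accuracy", "precision", "recall", "f1")
  stopifnot(all(cols %in% names(trials)), nrow(trials) >= 2L)
  data.frame(
    metric = cols,
    mean = vapply(cols, function(cc) mean(trials[[cc]]), numeric(1)),
    uncertainty = vapply(cols, function(cc)
      sd(trials[[cc]]) / sqrt(nrow(trials)), numeric(1)),
    row.names = NULL
  )
}
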