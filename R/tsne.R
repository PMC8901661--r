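# Exact t-distributed stochastic neighbor embedding (O(n^2)), used to
# map classifier activations to 2-D. Sized for the package's use case
# (hundreds to a few thousand points).

# row-wise binary search for the Gaussian bandwidths matching the target
# perplexity; D2 is the squared distance matrix
.tsnePerplexity <- function(D2, perplexity, tol = 1e-5) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sumP <- sum(p)
      if (sumP < 1e-300) sumP <- 1e-300
      H <- log(sumP) + beta * sum(di * p) / sumP
      if (abs(H - logU) < tol) break
      if (H > logU) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- p / sum(p)
  }
  P
}

#' Exact t-SNE to two dimensions
#'
#' Standard t-SNE: input similarities from a perplexity-calibrated
#' Gaussian kernel (symmetrized), Student-t similarities in the map,
#' gradient descent with momentum and early exaggeration. Deterministic
#' given `seed`.
#'
#' @param X numeric matrix (n x d).
#' @param perplexity effective neighborhood size; must be < n (n >= 3 x
#'   perplexity is recommended).
#' @param seed integer seed for the random initialization.
#' @param maxIter gradient-descent iterations.
#' @param eta learning rate.
#' @return n x 2 matrix of embedding coordinates.
#' @export
tsneEmbed <- function(X, perplexity = 30, seed = 1L, maxIter = 400L,
                      eta = 200) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (perplexity >= n) stop("perplexity must be smaller than n")
  set.seed(seed)
  D2 <- as.matrix(dist(X))^2
  # degenerate input: all points identical -> coincident embedding
  if (max(D2) < 1e-24) return(matrix(0, n, 2))
  P <- .tsnePerplexity(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- matrix(rnorm(n * 2, 0, 1e-4), n, 2)
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  momentum <- 0.5
  exag <- 12
  Pe <- P * exag
  for (iter in seq_len(maxIter)) {
    if (iter == 101L) { Pe <- P; momentum <- 0.8 }
    num <- 1 / (1 + as.matrix(dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- dY + Y
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  Y
}

#' Embed classifier activations with t-SNE
#'
#' Projects penultimate-layer activations (from [extractActivations()])
#' to 2-D. Default perplexities follow the study settings: 50 for the
#' valence map and 20 for the context map.
#'
#' @param activations numeric matrix (n x d).
#' @param labels data.frame with per-point `valence` and `context`
#'   columns (and optionally `call_id`).
#' @param perplexity t-SNE perplexity (< n).
#' @param seed integer seed.
#' @param ... passed to [tsneEmbed()].
#' @return an [EmbeddingResult-class].
#' @export
embedActivations <- function(activations, labels, perplexity = 50,
                             seed = 1L, ...) {
  act <- as.matrix(activations)
  stopifnot(nrow(act) == nrow(labels))
  coords <- tsneEmbed(act, perplexity = perplexity, seed = seed, ...)
  colnames(coords) <- c("x", "y")
  new("EmbeddingResult", coords = coords,
      labels = as.data.frame(labels), perplexity = perplexity,
      seed = as.integer(seed))
}

#' Write an embedding to CSV and render the labelled scatter
#'
#' The CSV has columns call_id (when present), x, y, valence, context.
#' The scatter marks negative-valence calls as triangles and positive
#' ones as circles, coloured by context.
#'
#' @param embedding an [EmbeddingResult-class].
#' @param csvPath,pngPath output paths (either may be NULL to skip).
#' @return the coordinate data.frame, invisibly.
#' @export
writeEmbedding <- function(embedding, csvPath = NULL, pngPath = NULL) {
  stopifnot(is(embedding, "EmbeddingResult"))
  df <- cbind(embedding@labels,
              x = embedding@coords[, 1L], y = embedding@coords[, 2L])
  front <- intersect(c("call_id", "x", "y", "valence", "context"),
                     names(df))
  df <- df[, c(front, setdiff(names(df), front))]
  if (!is.null(csvPath)) write.csv(df, csvPath, row.names = FALSE)
  if (!is.null(pngPath)) {
    png(pngPath, width = 900, height = 700)
    pch <- ifelse(df$valence == "negative", 17, 19)
    colIdx <- as.integer(base::factor(df$context))
    plot(df$x, df$y, pch = pch, col = colIdx,
         xlab = "t-SNE 1", ylab = "t-SNE 2",
         main = sprintf("t-SNE of activations (perplexity %g)",
                        embedding@perplexity))
    legend("topright", legend = c("negative", "positive"),
           pch = c(17, 19), bty = "n")
    dev.off()
  }
  invisible(df)
}
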