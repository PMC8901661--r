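# Internal numerical helpers.

# dB re full scale of a linear amplitude, floored so silence is finite.
.ampToDb <- function(a, floor_db = -70) {
  pmax(20 * log10(pmax(a, 0) + 1e-300), floor_db)
}

# Turning-point (zigzag) decomposition of a contour with hysteresis:
# returns alternating indices of prominent troughs and peaks, where a
# reversal only counts once the contour has moved by >= prominence dB away
# from the last extremum. Returns a data.frame with columns idx and type
# ("peak"/"trough"), strictly alternating.
.turningPoints <- function(y, prominence) {
  n <- length(y)
  if (n < 2L) return(data.frame(idx = integer(), type = character()))
  pts_idx <- integer()
  pts_type <- character()
  # candidate extremum since the last confirmed turning point
  cand_idx <- 1L
  direction <- 0L  # +1 rising since candidate trough, -1 falling since peak
  for (i in 2:n) {
    if (direction >= 0L) {
      # tracking a candidate trough at cand_idx, looking for a rise
      if (y[i] < y[cand_idx]) cand_idx <- i
      if (y[i] - y[cand_idx] >= prominence) {
        pts_idx <- c(pts_idx, cand_idx)
        pts_type <- c(pts_type, "trough")
        cand_idx <- i
        direction <- -1L
      }
    } else {
      # tracking a candidate peak at cand_idx, looking for a fall
      if (y[i] > y[cand_idx]) cand_idx <- i
      if (y[cand_idx] - y[i] >= prominence) {
        pts_idx <- c(pts_idx, cand_idx)
        pts_type <- c(pts_type, "peak")
        cand_idx <- i
        direction <- 1L
      }
    }
    if (direction == 0L) {
      # undecided start: pick first direction that exceeds prominence
      if (y[i] - y[cand_idx] >= prominence) {
        pts_idx <- c(pts_idx, cand_idx); pts_type <- c(pts_type, "trough")
        cand_idx <- i; direction <- -1L
      } else if (y[cand_idx] - y[i] >= prominence) {
        pts_idx <- c(pts_idx, cand_idx); pts_type <- c(pts_type, "peak")
        cand_idx <- i; direction <- 1L
      }
    }
  }
  # close the final candidate extremum so a trailing trough terminates the
  # last peak's cycle
  if (length(pts_type)) {
    lastType <- tail(pts_type, 1L)
    finType <- if (lastType == "peak") "trough" else "peak"
    pts_idx <- c(pts_idx, cand_idx)
    pts_type <- c(pts_type, finType)
  }
  data.frame(idx = pts_idx, type = pts_type, stringsAsFactors = FALSE)
}

# Bilinear resize of a numeric matrix to out_dim = c(rows, cols).
.resizeBilinear <- function(m, out_dim) {
  nr <- nrow(m); nc <- ncol(m)
  or <- out_dim[1L]; oc <- out_dim[2L]
  # map output pixel centres onto input pixel-centre coordinates
  ri <- if (nr == 1L || or == 1L) rep((nr + 1) / 2, or)
        else seq(1, nr, length.out = or)
  ci <- if (nc == 1L || oc == 1L) rep((nc + 1) / 2, oc)
        else seq(1, nc, length.out = oc)
  r0 <- pmax(pmin(floor(ri), nr - 1L), 1L)
  c0 <- pmax(pmin(floor(ci), nc - 1L), 1L)
  fr <- ri - r0; fc <- ci - c0
  r1 <- pmin(r0 + 1L, nr); c1 <- pmin(c0 + 1L, nc)
  a <- m[r0, c0, drop = FALSE]; b <- m[r0, c1, drop = FALSE]
  d <- m[r1, c0, drop = FALSE]; e <- m[r1, c1, drop = FALSE]
  wr <- matrix(fr, or, oc); wc <- matrix(fc, or, oc, byrow = TRUE)
  a * (1 - wr) * (1 - wc) + b * (1 - wr) * wc +
    d * wr * (1 - wc) + e * wr * wc
}

# Centered moving mean of x^2 over a window of w samples (edge-truncated).
.movMeanSq <- function(x, w) {
  n <- length(x)
  cs <- c(0, cumsum(x^2))
  half <- w %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Centered moving mean over a window of w samples (edge-truncated).
.movMean <- function(x, w) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  half <- w %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Draw an integer sub-seed from the current RNG stream (keeps derived seeds
# within 32-bit integer range).
.subSeed <- function() as.integer(floor(runif(1) * 2^31 - 1))
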