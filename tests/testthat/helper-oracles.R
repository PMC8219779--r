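# Independent brute-force oracles used to check the vectorized
# implementations. These are deliberately written as plain scalar loops.

# Per-node scalar evaluation of a fully-connected forward pass.
oracle_forward <- function(layers, hidden_act, input) {
  y <- input
  for (k in seq_along(layers)) {
    W <- layers[[k]]$W; b <- layers[[k]]$b
    x <- numeric(length(b))
    for (j in seq_along(b)) {
      s <- b[j]
      for (i in seq_along(y)) s <- s + W[i, j] * y[i]
      x[j] <- s
    }
    if (k < length(layers)) {
      y <- if (hidden_act == "relu") pmax(x, 0) else 2 / (1 + exp(-x)) - 1
    } else {
      y <- 1 / (1 + exp(-x))
    }
  }
  y
}

# Quadruple-loop zero-padded 3x3 convolution with bias and RELU.
oracle_conv <- function(map, kernel, bias) {
  H <- nrow(map); W <- ncol(map)
  out <- matrix(0, H, W)
  for (r in 1:H) for (c in 1:W) {
    s <- bias
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      v <- if (rr >= 1 && rr <= H && cc >= 1 && cc <= W) map[rr, cc] else 0
      s <- s + kernel[dr + 2, dc + 2] * v
    }
    out[r, c] <- max(s, 0)
  }
  out
}

# Exhaustive 4x4 window maximum.
oracle_maxpool <- function(map) {
  h <- nrow(map) / 4; w <- ncol(map) / 4
  out <- matrix(0, h, w)
  for (r in 1:h) for (c in 1:w)
    out[r, c] <- max(map[(4 * r - 3):(4 * r), (4 * c - 3):(4 * c)])
  out
}

# Pairwise concordance AUC with ties counting one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (n in neg)
    s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# Brute-force threshold sweep: J at every distinct score with the strict
# score > threshold rule.
oracle_youden <- function(scores, labels) {
  cand <- sort(unique(scores))
  J <- sapply(cand, function(t)
    mean(scores[labels == 1] > t) + mean(scores[labels == 0] <= t) - 1)
  list(cand = cand, J = J,
       best = cand[which(J == max(J))[1]], maxJ = max(J))
}

# Brute-force block mean for integer block sizes.
oracle_blockmean <- function(m, res) {
  f <- nrow(m) / res
  out <- matrix(0, res, res)
  for (r in 1:res) for (c in 1:res)
    out[r, c] <- mean(m[((r - 1) * f + 1):(r * f), ((c - 1) * f + 1):(c * f)])
  out
}

# Brute-force pixel -> box map: box index (row-major, 1-based) of a 0-based
# pixel coordinate under boundary k = round(k * side / 7), half-open.
oracle_pixel_box <- function(row0, col0, side) {
  b <- floor(0:7 * side / 7 + 0.5)
  r <- max(which(b <= row0)) - 1
  c <- max(which(b <= col0)) - 1
  r * 7 + c + 1
}

# Small learnable fixture shared by trainer tests.
make_tiny_task <- function(n_images, seed = 11, image_size = 98) {
  ds <- generate_dataset(synth_config(n_images = n_images,
                                      image_size = image_size, seed = seed))
  prep_dataset(ds, 20)
}
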