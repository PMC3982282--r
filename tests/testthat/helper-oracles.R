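# Independent brute-force oracles. These deliberately share no code with the
# package's computational paths: convolution by direct summation, medians by
# per-pixel sorting, nearest-edge distances by all-pairs scan, clustering
# optima by exhaustive enumeration.

# direct-sum true convolution with symmetric padding; the quadruple loop in
# conv2_oracle_slow is the definition, conv2_oracle is the same sum with the
# inner two loops collapsed to a flipped-window product for speed
conv2_oracle_slow <- function(image, kernel) {
  s <- nrow(kernel); r <- (s - 1L) %/% 2L
  h <- nrow(image); w <- ncol(image)
  p <- pad_sym_oracle(image, r)
  out <- matrix(if (is.complex(kernel)) 0i else 0, h, w)
  for (i in 1:h) for (j in 1:w)
    for (di in -r:r) for (dj in -r:r)
      out[i, j] <- out[i, j] +
        kernel[r + 1L + di, r + 1L + dj] * p[r + i - di, r + j - dj]
  out
}

conv2_oracle <- function(image, kernel) {
  s <- nrow(kernel); r <- (s - 1L) %/% 2L
  h <- nrow(image); w <- ncol(image)
  p <- pad_sym_oracle(image, r)
  kf <- kernel[s:1, s:1]                      # flip for convolution
  out <- matrix(if (is.complex(kernel)) 0i else 0, h, w)
  for (i in 1:h) for (j in 1:w)
    out[i, j] <- sum(kf * p[i:(i + 2L * r), j:(j + 2L * r)])
  out
}

pad_sym_oracle <- function(x, r) {
  if (r == 0L) return(x)
  h <- nrow(x); w <- ncol(x)
  x[c(r:1, 1:h, h:(h - r + 1L)), c(r:1, 1:w, w:(w - r + 1L)), drop = FALSE]
}

# per-pixel sorted-window median with symmetric padding
median_oracle <- function(image, window) {
  r <- (window - 1L) %/% 2L
  p <- pad_sym_oracle(image, r)
  out <- image
  for (i in seq_len(nrow(image))) for (j in seq_len(ncol(image))) {
    win <- p[i:(i + 2L * r), j:(j + 2L * r)]
    out[i, j] <- sort(as.numeric(win))[(window * window + 1L) %/% 2L]
  }
  out
}

# 3x3 gradient magnitude by plain correlation loops
gradient_oracle <- function(image, operator) {
  c2 <- if (operator == "sobel") 2 else 1
  kx <- matrix(c(-1, -c2, -1, 0, 0, 0, 1, c2, 1), 3, 3)
  ky <- t(kx)
  p <- pad_sym_oracle(image, 1L)
  gx <- gy <- image * 0
  for (i in seq_len(nrow(image))) for (j in seq_len(ncol(image))) {
    win <- p[i:(i + 2L), j:(j + 2L)]
    gx[i, j] <- sum(kx * win)
    gy[i, j] <- sum(ky * win)
  }
  sqrt(gx^2 + gy^2)
}

# globally optimal 2-cluster MSE cost by enumerating all 2-partitions
best_two_partition_cost <- function(v) {
  n <- length(v)
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    a <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    cost <- sum((v[a] - mean(v[a]))^2) + sum((v[!a] - mean(v[!a]))^2)
    if (cost < best) best <- cost
  }
  best
}

# independently coded fuzzy c-means fixed-point iteration (loops over points
# and clusters), run from a given membership matrix to tight tolerance
fcm_oracle <- function(v, u, m, tol = 1e-10, max_iter = 2000L) {
  n <- length(v); k <- ncol(u)
  centers <- rep(NA_real_, k)
  for (it in seq_len(max_iter)) {
    new_centers <- numeric(k)
    for (i in 1:k) {
      num <- den <- 0
      for (j in 1:n) {
        wj <- u[j, i]^m
        num <- num + wj * v[j]; den <- den + wj
      }
      new_centers[i] <- num / den
    }
    for (j in 1:n) {
      d <- abs(v[j] - new_centers)
      if (any(d == 0)) {
        u[j, ] <- (d == 0) / sum(d == 0)
      } else {
        for (i in 1:k)
          u[j, i] <- 1 / sum((d[i] / d)^(2 / (m - 1)))
      }
    }
    if (!anyNA(centers) && max(abs(new_centers - centers)) < tol) break
    centers <- new_centers
  }
  list(centers = centers, u = u)
}

# all-pairs nearest-truth-pixel distances for every detected pixel
nearest_distance_oracle <- function(truth, detected) {
  tp <- which(truth == 1L, arr.ind = TRUE)
  dp <- which(detected == 1L, arr.ind = TRUE)
  apply(dp, 1L, function(q)
    sqrt(min((tp[, 1L] - q[1L])^2 + (tp[, 2L] - q[2L])^2)))
}

# reference FOM evaluated straight from its definition
fom_oracle <- function(truth, detected, alpha = 1 / 9) {
  nd <- sum(detected)
  if (nd == 0L) return(0)
  l <- nearest_distance_oracle(truth, detected)
  sum(1 / (1 + alpha * l^2)) / max(sum(truth), nd)
}

# small random binary map with at least one foreground pixel
random_edge_map <- function(h, w, p = 0.1) {
  m <- matrix(rbinom(h * w, 1L, p), h, w)
  if (sum(m) == 0L) m[sample(h, 1L), sample(w, 1L)] <- 1L
  m
}
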