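# Independent brute-force oracles used across the suite.

# direct-summation convolution with edge reflection (the package's kernel
# semantics, re-derived by explicit loops)
oracle_conv <- function(x, w) {
  n <- length(x)
  h <- (length(w) - 1L) %/% 2L
  out <- numeric(n)
  for (t in seq_len(n)) {
    acc <- 0
    for (k in -h:h) {
      j <- t + k
      if (j < 1L) j <- min(n, 2L - j)
      if (j > n) j <- max(1L, 2L * n - j)
      acc <- acc + w[k + h + 1L] * x[j]
    }
    out[t] <- acc
  }
  out
}

oracle_gauss_kernel <- function(n) {
  h <- max(1L, floor(n / 2))
  k <- -h:h
  g <- exp(-k^2 / (2 * (n / 4)^2))
  g / sum(g)
}

oracle_dog_kernel <- function(n) {
  h <- max(1L, floor(n / 2))
  k <- -h:h
  g <- exp(-k^2 / (2 * (n / 4)^2))
  w <- k * g
  w / sum(k * w)
}

# exhaustive Viterbi: enumerate all 2^T orientation paths with the model's
# scoring (stay/flip log-probabilities, emission -beta*E, step energy)
oracle_enumerate_paths <- function(E, params, step_D = NULL) {
  Tn <- nrow(E)
  if (is.null(step_D)) step_D <- matrix(0, Tn - 1L, 2L,
                                        dimnames = list(NULL, c("same", "cross")))
  lstay <- log(params$stay_prob); lflip <- log(1 - params$stay_prob)
  b <- params$beta; ad2 <- params$alpha[3L]
  best <- -Inf; best_path <- NULL
  for (m in 0:(2^Tn - 1L)) {
    path <- as.integer(intToBits(m)[1:Tn]) + 1L
    sc <- -b * E[1L, path[1L]]
    for (i in 2:Tn) {
      if (path[i] == path[i - 1L]) {
        sc <- sc + lstay - b * ad2 * step_D[i - 1L, "same"]
      } else {
        sc <- sc + lflip - b * ad2 * step_D[i - 1L, "cross"]
      }
      sc <- sc - b * E[i, path[i]]
    }
    if (sc > best + 1e-12) { best <- unname(sc); best_path <- path }
  }
  list(path = c("first", "last")[best_path], score = best)
}

# polygon simplicity by pairwise segment intersection
oracle_polygon_simple <- function(poly) {
  n <- nrow(poly)
  segs <- cbind(poly, poly[c(2:n, 1L), ])
  ccw <- function(ax, ay, bx, by, cx, cy) (cy - ay) * (bx - ax) - (by - ay) * (cx - ax)
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j == i || j == i %% n + 1L || i == j %% n + 1L) next
      a <- segs[i, 1:2]; b <- segs[i, 3:4]; c <- segs[j, 1:2]; d <- segs[j, 3:4]
      d1 <- ccw(a[1], a[2], b[1], b[2], c[1], c[2])
      d2 <- ccw(a[1], a[2], b[1], b[2], d[1], d[2])
      d3 <- ccw(c[1], c[2], d[1], d[2], a[1], a[2])
      d4 <- ccw(c[1], c[2], d[1], d[2], b[1], b[2])
      if (d1 * d2 < 0 && d3 * d4 < 0) return(FALSE)
    }
  }
  TRUE
}

# two-sample G-test statistic over shared categories
oracle_gtest_2sample <- function(c1, c2) {
  tot <- c1 + c2
  keep <- tot > 0
  c1 <- c1[keep]; c2 <- c2[keep]
  n1 <- sum(c1); n2 <- sum(c2)
  e1 <- (c1 + c2) * n1 / (n1 + n2)
  e2 <- (c1 + c2) * n2 / (n1 + n2)
  g <- 0
  for (i in seq_along(c1)) {
    if (c1[i] > 0) g <- g + 2 * c1[i] * log(c1[i] / e1[i])
    if (c2[i] > 0) g <- g + 2 * c2[i] * log(c2[i] / e2[i])
  }
  g
}

# straight synthetic track translating along its own axis
straight_moving_track <- function(n = 120, dt = 0.1, speed = 0.5, L = 4) {
  tt <- (0:(n - 1L)) * dt
  sx <- outer(tt * speed, seq(0, L, length.out = 11L), `+`)
  sy <- matrix(0, n, 11L)
  larva_track("straight", tt, sx, sy)
}

make_simple_ethogram <- function(id, actions, dt = 0.1, t0 = 0) {
  ethogram(id, t0 + (seq_along(actions) - 1L) * dt, actions)
}
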