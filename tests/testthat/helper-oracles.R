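# Independent brute-force oracles.  These deliberately avoid the vectorised
# linear-algebra formulations used by the package: plain loops over pairs
# and grid searches over geometry, so that agreement is informative.

nodf_oracle <- function(b) {
  n <- nrow(b); m <- ncol(b)
  tot <- 0
  if (m >= 2) for (k in 1:(m - 1)) for (l in (k + 1):m) {
    fk <- sum(b[, k] != 0); fl <- sum(b[, l] != 0)
    if (fk > fl && fl > 0)
      tot <- tot + 100 * sum(b[, k] != 0 & b[, l] != 0) / fl
  }
  if (n >= 2) for (k in 1:(n - 1)) for (l in (k + 1):n) {
    fk <- sum(b[k, ] != 0); fl <- sum(b[l, ] != 0)
    if (fk > fl && fl > 0)
      tot <- tot + 100 * sum(b[k, ] != 0 & b[l, ] != 0) / fl
  }
  npairs <- n * (n - 1) / 2 + m * (m - 1) / 2
  if (npairs == 0) 0 else tot / npairs
}

jdm_oracle <- function(b) {
  n <- nrow(b); m <- ncol(b)
  obs <- 0; expct <- 0
  if (n >= 2) for (a in 1:(n - 1)) for (bb in (a + 1):n) {
    obs <- obs + sum(b[a, ] != 0 & b[bb, ] != 0)
    expct <- expct + sum(b[a, ] != 0) * sum(b[bb, ] != 0) / m
  }
  if (m >= 2) for (a in 1:(m - 1)) for (bb in (a + 1):m) {
    obs <- obs + sum(b[, a] != 0 & b[, bb] != 0)
    expct <- expct + sum(b[, a] != 0) * sum(b[, bb] != 0) / n
  }
  obs / expct
}

# temperature of an arrangement as given: Simpson-free trapezoid area,
# bisection for the isocline exponent, grid search for each crossing
temperature_oracle <- function(b) {
  n <- nrow(b); m <- ncol(b)
  F <- sum(b != 0); p <- F / (n * m)
  if (p >= 1) return(0)
  area <- function(a) {
    xs <- seq(0, 1, length.out = 10001)
    ys <- (1 - xs^a)^(1 / a)
    sum((ys[-1] + ys[-length(ys)]) / 2) * (xs[2] - xs[1])
  }
  lo <- log(0.02); hi <- log(2000)
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (area(exp(mid)) < p) lo <- mid else hi <- mid
  }
  a <- exp((lo + hi) / 2)
  tot <- 0
  for (i in 1:n) for (j in 1:m) {
    x <- (j - 0.5) / m; y <- (i - 0.5) / n
    inside <- x^a + y^a <= 1
    pres <- b[i, j] != 0
    if (pres == inside) next
    tlo <- -min(x, y); thi <- min(1 - x, 1 - y)
    ts <- seq(tlo, thi, length.out = 20001)
    g <- (x + ts)^a + (y + ts)^a - 1
    k <- which(diff(sign(g)) != 0)[1]
    tstar <- ts[k] - g[k] * (ts[k + 1] - ts[k]) / (g[k + 1] - g[k])
    tot <- tot + (abs(tstar) / (thi - tlo))^2
  }
  100 * tot / (0.04145 * n * m)
}

# a matrix is perfectly nested if every pair of rows (and columns) is
# subset-comparable
is_perfectly_nested <- function(b) {
  b <- b != 0
  comparable <- function(u, v) all(u >= v) || all(v >= u)
  n <- nrow(b); m <- ncol(b)
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (!comparable(b[i, ], b[j, ])) return(FALSE)
  if (m >= 2) for (i in 1:(m - 1)) for (j in (i + 1):m)
    if (!comparable(b[, i], b[, j])) return(FALSE)
  TRUE
}

# all binary matrices of a given shape, as a list (used exhaustively for
# small shapes only)
all_binary_matrices <- function(n, m) {
  cells <- n * m
  lapply(0:(2^cells - 1), function(code) {
    bits <- as.integer(intToBits(code))[1:cells]
    matrix(bits, n, m)
  })
}

rand_binary <- function(n, m, fill, labels = TRUE) {
  x <- matrix(0, n, m)
  x[sample.int(n * m, fill)] <- 1
  as_biadjacency(x)
}

rand_weighted <- function(n, m, fill, wmax = 9) {
  x <- matrix(0, n, m)
  x[sample.int(n * m, fill)] <- sample.int(wmax, fill, replace = TRUE)
  as_biadjacency(x)
}

# strip + sort + score without going through the package pipeline more than
# necessary: used where a test needs the *arrangement* the package chose
sorted_binary <- function(m) {
  degree_sort(strip_empty(binarise(m)), use_weights = FALSE)$matrix
}
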