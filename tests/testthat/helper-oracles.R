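# Independent brute-force oracles used to validate the vectorised
# implementation.  These are deliberately written as plain loops over the
# defining formulas and share no code with the package internals.

# Direct evaluation of each window feature from its defining formula.
oracle_feature <- function(name, s, fs = 1000, eps = 0,
                           low = c(20, 250), high = c(250, 500)) {
  w <- length(s)
  pspec <- function() {
    sp <- stats::fft(s)
    half <- floor(w / 2)
    list(f = (0:half) * fs / w, p = Mod(sp[1:(half + 1)])^2)
  }
  switch(name,
    RMS = sqrt(sum(s^2) / w),
    MAV = sum(abs(s)) / w,
    WL = { a <- 0; for (i in 1:(w - 1)) a <- a + abs(s[i + 1] - s[i]); a },
    ZC = {
      n <- 0
      for (i in 1:(w - 1))
        if (s[i] * s[i + 1] < 0 && abs(s[i] - s[i + 1]) >= eps) n <- n + 1
      n
    },
    DASDV = {
      a <- 0; for (i in 1:(w - 1)) a <- a + (s[i + 1] - s[i])^2
      sqrt(a / (w - 1))
    },
    LOG = exp(sum(s) / w),
    SSI = sum(s^2),
    TM3 = abs(sum(s^3) / w),
    TM4 = abs(sum(s^4) / w),
    TM5 = abs(sum(s^5) / w),
    FR = {
      ps <- pspec()
      lo <- sum(ps$p[ps$f >= low[1] & ps$f < low[2]])
      hi <- sum(ps$p[ps$f >= high[1] & ps$f < high[2]])
      lo / hi
    },
    IEMG = sum(abs(s)),
    MFMN = { ps <- pspec(); sum(ps$f * ps$p) / sum(ps$p) },
    MFMD = {
      ps <- pspec()
      tot <- sum(ps$p); acc <- 0
      for (k in seq_along(ps$p)) {
        acc <- acc + ps$p[k]
        if (acc >= tot / 2) return(ps$f[k])
      }
    })
}

# Brute-force enumeration of sliding-window offsets.
oracle_window_offsets <- function(n_samples, w, tau) {
  offs <- integer(0)
  s <- 0
  while (s + w <= n_samples) {
    offs <- c(offs, s)
    s <- s + tau
  }
  offs
}

# Brute-force segmentation: scan all factor pairs.
oracle_segmentation <- function(w) {
  best <- NULL
  for (n in 1:w) {
    if (w %% n == 0) {
      l <- w / n
      if (n <= l && (is.null(best) || abs(n - l) < best$dif))
        best <- list(n = n, l = l, dif = abs(n - l))
    }
  }
  best
}

# Triple-loop dynamic routing oracle: u (I x Din), W (I, J, Din, Dout).
# Follows the agreement-update recurrence literally, element by element.
oracle_routing <- function(u, W, iterations = 3, kind = "e_squash") {
  I <- dim(W)[1]; J <- dim(W)[2]; Din <- dim(W)[3]; Dout <- dim(W)[4]
  uhat <- array(0, c(I, J, Dout))
  for (i in 1:I) for (j in 1:J) for (d in 1:Dout) {
    acc <- 0
    for (k in 1:Din) acc <- acc + W[i, j, k, d] * u[i, k]
    uhat[i, j, d] <- acc
  }
  sq <- function(s) {
    r <- sqrt(sum(s^2))
    if (r < 1e-12) return(s * 0)
    g <- switch(kind,
      squash = r^2 / (1 + r^2),
      hsquash = (r / 4)^2 / (1 + (r / 4)^2),
      strict_squash = 0.69 * r^2 * 2^(-0.6 * r - 1.115),
      squash_4 = r^2 / (0.5 + r^2),
      e_squash = 1 - exp(-r^2))
    g * s / r
  }
  b <- matrix(0, I, J)
  v <- matrix(0, J, Dout)
  for (t in 1:iterations) {
    cc <- matrix(0, I, J)
    for (i in 1:I) {
      den <- 0
      for (k in 1:J) den <- den + exp(b[i, k])
      for (j in 1:J) cc[i, j] <- exp(b[i, j]) / den
    }
    for (j in 1:J) {
      s <- numeric(Dout)
      for (i in 1:I) for (d in 1:Dout)
        s[d] <- s[d] + cc[i, j] * uhat[i, j, d]
      v[j, ] <- sq(s)
    }
    if (t < iterations)
      for (i in 1:I) for (j in 1:J) {
        agree <- 0
        for (d in 1:Dout) agree <- agree + uhat[i, j, d] * v[j, d]
        b[i, j] <- b[i, j] + agree
      }
  }
  list(v = v, c = cc, b = b)
}

# Elementwise outer-product feature map.
oracle_outer_map <- function(f, alpha = 0.5, beta = 0.5) {
  n <- length(f)
  F <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    F[i, j] <- 1 / (1 + exp(-(alpha * f[i]) * (beta * f[j])))
  F
}

# A small random test window (channels x w).
random_window <- function(channels = 16, w = 300, seed = NULL,
                          label = "HC") {
  if (!is.null(seed)) set.seed(seed)
  list(data = matrix(stats::rnorm(channels * w), channels, w),
       fs = 1000, label = label)
}
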