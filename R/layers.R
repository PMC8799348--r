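# Low-level neural building blocks.
#
# Activations live in one of two equivalent memory layouts:
#   "flat": (B, C*npos) matrix, element (b, (c-1)*npos + p)
#   "map":  (B*npos, C) matrix, row (p-1)*B + b
# Both describe the same column-major buffer, so `dim<-` converts for free;
# spatial positions p run column-major over the (H, W) grid.

# Precompute the im2col gather plan of a 2D cross-correlation.
# IDX[p, k] is the flat input index (1..H*W*C, or H*W*C+1 for zero padding)
# of patch element k at output position p.
conv_plan <- function(H, W, C, kh, kw, stride = 1L, pad = 0L) {
  Ho <- (H + 2L * pad - kh) %/% stride + 1L
  Wo <- (W + 2L * pad - kw) %/% stride + 1L
  stopifnot(Ho >= 1L, Wo >= 1L)
  len <- H * W * C
  patch <- kh * kw * C
  npos <- Ho * Wo
  ro <- rep(seq_len(Ho), times = Wo)           # output row, p fastest
  co <- rep(seq_len(Wo), each = Ho)
  kr <- rep(seq_len(kh), times = kw * C)
  kc <- rep(rep(seq_len(kw), each = kh), times = C)
  cc <- rep(seq_len(C), each = kh * kw)
  ri <- outer((ro - 1L) * stride - pad, kr, `+`)  # (npos, patch) 1-based rows
  ci <- outer((co - 1L) * stride - pad, kc, `+`)
  flat <- (rep(cc, each = npos) - 1L) * (H * W) + (ci - 1L) * H + ri
  oob <- ri < 1L | ri > H | ci < 1L | ci > W
  flat[oob] <- len + 1L
  dim(flat) <- c(npos, patch)
  list(H = H, W = W, C = C, Ho = Ho, Wo = Wo, npos = npos,
       patch = patch, len = len, idx = flat)
}

# Forward cross-correlation.  x: (B, len) flat input.  K: (patch, Cout).
# Returns out (B*npos, Cout) in map layout plus the im2col matrix for the
# backward pass.
conv_forward <- function(x, plan, K, bias) {
  B <- nrow(x)
  xa <- cbind(x, 0)
  P <- xa[, as.vector(plan$idx), drop = FALSE]
  dim(P) <- c(B * plan$npos, plan$patch)
  out <- P %*% K
  out <- sweep(out, 2L, bias, `+`)
  list(out = out, P = P)
}

# Backward cross-correlation: upstream d_out (B*npos, Cout).
conv_backward <- function(d_out, P, K, plan, B) {
  dK <- crossprod(P, d_out)
  db <- colSums(d_out)
  dP <- d_out %*% t(K)
  dxa <- matrix(0, B, plan$len + 1L)
  for (k in seq_len(plan$patch)) {
    cols <- plan$idx[, k]
    dcol <- dP[, k]
    dim(dcol) <- c(B, plan$npos)
    dxa[, cols] <- dxa[, cols] + dcol
  }
  list(dx = dxa[, seq_len(plan$len), drop = FALSE], dK = dK, db = db)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

relu_backward <- function(pre, d_out) {
  d_out * (pre > 0)
}

# He-style variance-scaled initialisation for a (fan_in, fan_out) kernel.
init_kernel <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)),
         fan_in, fan_out)
}

# flat (B, C*npos) <-> map (B*npos, C) conversion by relabelling dims.
as_map <- function(x, npos, C) {
  dim(x) <- c(nrow(x) * npos, C)
  x
}

as_flat <- function(x, B, npos, C) {
  dim(x) <- c(B, npos * C)
  x
}
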