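#' Width profiles of the network
#'
#' The default ("paper") profile uses 256-channel convolutions throughout,
#' giving 7*7*32 = 1568 primary capsules of dimension 8 and 5 action
#' capsules of dimension 16.  The "test" profile shrinks every convolution
#' to 32 channels (196 primary capsules) so that training runs in minutes on
#' one CPU; "tiny" (8 channels, 49 primary capsules) is meant for gradient
#' checks.  All profiles keep the 7x7 spatial grid, the capsule dimensions
#' and the five action capsules.
#'
#' @param width_profile `"paper"`, `"test"` or `"tiny"`, or a positive
#'   integer number of convolution channels (a multiple of 8).
#' @param n_class Number of gesture classes / action capsules.
#' @param n_channels Number of sEMG electrode channels.
#' @param routing_iters Dynamic-routing iterations.
#' @return A list of architecture constants.
#' @export
fficaps_profile <- function(width_profile = "test", n_class = 5L,
                            n_channels = 16L, routing_iters = 3L) {
  C <- if (is.numeric(width_profile)) as.integer(width_profile)
       else switch(match.arg(width_profile, c("paper", "test", "tiny")),
                   paper = 256L, test = 32L, tiny = 8L)
  if (C %% 8L != 0L || C < 8L)
    stop("convolution width must be a positive multiple of the capsule dim 8")
  if (routing_iters < 1L) stop("routing_iters must be >= 1")
  list(C = C, caps_dim = 8L, action_dim = 16L, n_class = as.integer(n_class),
       n_channels = as.integer(n_channels),
       routing_iters = as.integer(routing_iters),
       n_primary = 7L * 7L * (C %/% 8L))
}

#' Initialise network weights
#'
#' Convolution kernels use variance-scaled normal initialisation with zero
#' biases; the per-pair capsule transformation matrices are drawn from
#' N(0, 0.05^2).
#'
#' @param profile An [fficaps_profile()].
#' @param seed Optional integer seed for reproducible initialisation.
#' @return A list of parameter tensors (class `"fficaps_weights"`).
#' @export
fficaps_init <- function(profile = fficaps_profile(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  C <- profile$C; nc <- profile$n_channels
  plans <- list(
    s = conv_plan(15L, 20L, nc, 3L, 8L, stride = 2L, pad = 0L),
    f = conv_plan(15L, 15L, nc, 3L, 3L, stride = 2L, pad = 0L),
    k3 = conv_plan(7L, 7L, C, 3L, 3L, stride = 1L, pad = 1L),
    k5 = conv_plan(7L, 7L, C, 5L, 5L, stride = 1L, pad = 2L))
  stopifnot(plans$s$Ho == 7L, plans$s$Wo == 7L,
            plans$f$Ho == 7L, plans$f$Wo == 7L)
  JD <- profile$n_class * profile$action_dim
  params <- list(
    Ks = init_kernel(plans$s$patch, C), bs = numeric(C),
    Kf = init_kernel(plans$f$patch, C), bf = numeric(C),
    Kmix = init_kernel(2L * C, C), bmix = numeric(C),
    K3 = init_kernel(plans$k3$patch, C), b3 = numeric(C),
    K5 = init_kernel(plans$k5$patch, C), b5 = numeric(C),
    Kb = init_kernel(3L * C, C), bb = numeric(C),
    Wc = array(stats::rnorm(8L * JD * profile$n_primary, sd = 0.05),
               dim = c(8L, JD, profile$n_primary)))
  structure(list(params = params, plans = plans, profile = profile),
            class = "fficaps_weights")
}

#' Convolutional fusion front-end
#'
#' Applies the two fusion branches to one batch of fused inputs: a stride-2
#' valid convolution with 3x8 kernels over the 16 x 15 x 20 segment arrays
#' and with 3x3 kernels over the 16 x 15 x 15 feature-map arrays, channel
#' concatenation of the two 7x7 maps, and a 1x1 mixing convolution back to
#' the base width — yielding the 7 x 7 x C capsule-network input.
#'
#' @param input A fused input from [build_fused_input()], or a list of them
#'   (a batch).
#' @param weights An [fficaps_init()] weight set.
#' @return A 3D array `7 x 7 x C` for a single input, or `B x 49 x C` for a
#'   batch.
#' @export
fusion_frontend <- function(input, weights) {
  batch <- !is.null(input$feature_map) || inherits(input, "fused_input")
  inputs <- if (batch) list(input) else input
  X <- .stack_fused(inputs)
  fw <- .frontend_forward(weights$params, weights$plans, X$f, X$s,
                          keep = FALSE)
  B <- length(inputs)
  out <- fw$mix  # (B*49, C) map layout
  C <- ncol(out)
  if (B == 1L) {
    arr <- array(out, dim = c(7L, 7L, C))
    return(arr)
  }
  arr <- array(as_flat(out, B, 49L, C), dim = c(B, 49L, C))
  arr
}

# Stack a list of fused inputs into flat (B, len) matrices for both branches.
.stack_fused <- function(inputs) {
  B <- length(inputs)
  nf <- length(inputs[[1L]]$feature_map)
  ns <- length(inputs[[1L]]$semg_matrix)
  Xf <- matrix(0, B, nf); Xs <- matrix(0, B, ns)
  for (b in seq_len(B)) {
    Xf[b, ] <- as.vector(inputs[[b]]$feature_map)   # (15,15,nc): p fastest
    Xs[b, ] <- as.vector(inputs[[b]]$semg_matrix)
  }
  list(f = Xf, s = Xs)
}

# ---- forward passes -------------------------------------------------------

.frontend_forward <- function(params, plans, Xf, Xs, keep = TRUE) {
  B <- nrow(Xf)
  cs <- conv_forward(Xs, plans$s, params$Ks, params$bs)
  cf <- conv_forward(Xf, plans$f, params$Kf, params$bf)
  zs <- relu(cs$out); zf <- relu(cf$out)
  cat1 <- cbind(zs, zf)                       # (B*49, 2C)
  mix_pre <- sweep(cat1 %*% params$Kmix, 2L, params$bmix, `+`)
  mix <- relu(mix_pre)
  out <- list(mix = mix, B = B)
  if (keep)
    out <- c(out, list(cs = cs, cf = cf, zs_pre = cs$out, zf_pre = cf$out,
                       cat1 = cat1, mix_pre = mix_pre))
  out
}

#' Multilevel convolution block
#'
#' Concatenates a padded 3x3 convolution, a padded 5x5 convolution and the
#' block input along channels (7x7 spatial size preserved; 3C channels),
#' then reduces back to C channels with a 1x1 bottleneck convolution.
#'
#' @param input A `7 x 7 x C` array (single map) as produced by
#'   [fusion_frontend()].
#' @param weights An [fficaps_init()] weight set.
#' @param return_intermediates Also return the pre-bottleneck concatenation.
#' @return A `7 x 7 x C` array, or a list with elements `out` and `concat`
#'   when `return_intermediates = TRUE`.
#' @export
multilevel_conv <- function(input, weights, return_intermediates = FALSE) {
  C <- weights$profile$C
  stopifnot(length(dim(input)) == 3L, dim(input)[1] == 7L,
            dim(input)[2] == 7L, dim(input)[3] == C)
  x <- matrix(as.vector(input), nrow = 1L)     # (1, 49*C) flat
  ml <- .mlconv_forward(weights$params, weights$plans, x, B = 1L,
                        keep = FALSE)
  out <- array(ml$bot, dim = c(7L, 7L, C))
  if (return_intermediates)
    list(out = out, concat = array(ml$cat2, dim = c(7L, 7L, 3L * C)))
  else out
}

.mlconv_forward <- function(params, plans, x_flat, B, keep = TRUE) {
  C <- ncol(params$Kb)
  c3 <- conv_forward(x_flat, plans$k3, params$K3, params$b3)
  c5 <- conv_forward(x_flat, plans$k5, params$K5, params$b5)
  z3 <- relu(c3$out); z5 <- relu(c5$out)
  xmap <- x_flat
  dim(xmap) <- c(B * 49L, C)
  cat2 <- cbind(z3, z5, xmap)                  # (B*49, 3C)
  bot_pre <- sweep(cat2 %*% params$Kb, 2L, params$bb, `+`)
  bot <- relu(bot_pre)
  out <- list(bot = bot, cat2 = cat2, B = B)
  if (keep)
    out <- c(out, list(c3 = c3, c5 = c5, z3_pre = c3$out, z5_pre = c5$out,
                       bot_pre = bot_pre))
  out
}

#' Reshape a convolutional map into squashed primary capsules
#'
#' Groups the C channels of a 7x7 map into C/8 groups of 8, giving
#' `49 * C/8` primary capsules of dimension 8, and applies the selected
#' squash to each capsule.
#'
#' @param map A `7 x 7 x C` array with C divisible by 8.
#' @param kind Squash kind, see [apply_squash()].
#' @return A `n_primary x 8` matrix of squashed capsule vectors.
#' @export
to_primary_caps <- function(map, kind = "e_squash") {
  d <- dim(map)
  stopifnot(length(d) == 3L)
  C <- d[3]
  if (C %% 8L != 0L) stop("channel count must be divisible by the capsule dim 8")
  m <- matrix(as.vector(map), nrow = d[1] * d[2], ncol = C)  # (49, C)
  u <- .caps_reshape(m, B = 1L)
  .squash_rows(u, kind)$v
}

# (B*49, C) map -> (B*49*G, 8) capsule rows, capsule index i = (g-1)*49 + p,
# batch fastest within capsule.
.caps_reshape <- function(m, B) {
  C <- ncol(m)
  G <- C %/% 8L
  blocks <- lapply(seq_len(G), function(g)
    m[, ((g - 1L) * 8L + 1L):(g * 8L), drop = FALSE])
  do.call(rbind, blocks)
}

.caps_unreshape <- function(u, B, C) {
  G <- C %/% 8L
  n <- nrow(u) %/% G
  m <- matrix(0, n, C)
  for (g in seq_len(G))
    m[, ((g - 1L) * 8L + 1L):(g * 8L)] <- u[((g - 1L) * n + 1L):(g * n), ,
                                            drop = FALSE]
  m
}

# ---- dynamic routing ------------------------------------------------------

# Batched routing forward.  uhat: (B*I, J*D) with batch fastest in rows and
# d fastest within j in columns.  Returns final action capsules plus the
# full per-iteration cache needed for the backward pass.
.routing_forward <- function(uhat, B, I, J, D, iters, kind) {
  grp <- rep(seq_len(B), times = I)
  blog <- matrix(0, B * I, J)
  c_list <- vector("list", iters)
  S_list <- vector("list", iters)   # each (B, D, J)
  V_list <- vector("list", iters)
  sq_list <- vector("list", iters)  # per iteration: list over j of squash cache
  for (t in seq_len(iters)) {
    cm <- .softmax_rows(blog)
    S <- array(0, dim = c(B, D, J))
    V <- array(0, dim = c(B, D, J))
    sqc <- vector("list", J)
    for (j in seq_len(J)) {
      jc <- ((j - 1L) * D + 1L):(j * D)
      Sj <- rowsum(uhat[, jc, drop = FALSE] * cm[, j], grp, reorder = TRUE)
      sq <- .squash_rows(Sj, kind)
      S[, , j] <- Sj
      V[, , j] <- sq$v
      sqc[[j]] <- sq
      if (t < iters)
        blog[, j] <- blog[, j] +
          rowSums(uhat[, jc, drop = FALSE] * sq$v[grp, , drop = FALSE])
    }
    c_list[[t]] <- cm; S_list[[t]] <- S; V_list[[t]] <- V; sq_list[[t]] <- sqc
  }
  list(V = V_list[[iters]], c_list = c_list, S_list = S_list,
       V_list = V_list, sq_list = sq_list, blog = blog, grp = grp,
       B = B, I = I, J = J, D = D, iters = iters, kind = kind)
}

# Batched routing backward: dV (B, D, J) upstream on the final action
# capsules; returns duhat (B*I, J*D).
.routing_backward <- function(uhat, rt, dV) {
  B <- rt$B; I <- rt$I; J <- rt$J; D <- rt$D
  grp <- rt$grp; kind <- rt$kind; iters <- rt$iters
  duhat <- matrix(0, B * I, J * D)
  G <- NULL                                   # dL/db_{t-1}, (B*I, J)
  dVt <- dV
  for (t in iters:1) {
    if (t < iters) {
      # b_t = b_{t-1} + uhat . v_t contributed gradient G to v_t and uhat
      dVt <- array(0, dim = c(B, D, J))
      for (j in seq_len(J)) {
        jc <- ((j - 1L) * D + 1L):(j * D)
        dVt[, , j] <- rowsum(uhat[, jc, drop = FALSE] * G[, j], grp,
                             reorder = TRUE)
        duhat[, jc] <- duhat[, jc] +
          rt$V_list[[t]][, , j][grp, , drop = FALSE] * G[, j]
      }
    }
    cm <- rt$c_list[[t]]
    dc <- matrix(0, B * I, J)
    for (j in seq_len(J)) {
      jc <- ((j - 1L) * D + 1L):(j * D)
      dSj <- .squash_rows_backward(rt$S_list[[t]][, , j], rt$sq_list[[t]][[j]],
                                   dVt[, , j], kind)
      dc[, j] <- rowSums(uhat[, jc, drop = FALSE] * dSj[grp, , drop = FALSE])
      duhat[, jc] <- duhat[, jc] + dSj[grp, , drop = FALSE] * cm[, j]
    }
    sm <- cm * (dc - rowSums(dc * cm))
    G <- if (t == iters) sm else sm + G
  }
  duhat
}

.softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}

#' Dynamic routing-by-agreement
#'
#' Routes primary capsules to action capsules: logits `b` start at 0, and
#' each iteration computes coupling coefficients `c = softmax(b)` over
#' action capsules, weighted prediction sums `s_j`, squashed outputs `v_j`,
#' and an agreement update `b_ij <- b_ij + uhat_ij . v_j` (skipped after the
#' final iteration).  Coupling rows always sum to 1.
#'
#' @param primary A `I x 8` matrix of (already squashed) primary capsule
#'   vectors.
#' @param W A 4D transformation array `I x J x 8 x D_out` giving the
#'   per-pair matrices `W_ij`.
#' @param iterations Number of routing iterations (>= 1; default 3).
#' @param kind Squash kind used inside routing.
#' @return A list with `action` (a `J x D_out` matrix of action capsules)
#'   and `state` (list with logits `b`, couplings `c`, weighted sums `s`,
#'   outputs `v`).
#' @export
dynamic_routing <- function(primary, W, iterations = 3L, kind = "e_squash") {
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L)
    stop("'iterations' must be a positive integer")
  dW <- dim(W)
  stopifnot(length(dW) == 4L, nrow(primary) == dW[1],
            ncol(primary) == dW[3])
  I <- dW[1]; J <- dW[2]; D <- dW[4]
  uhat <- matrix(0, I, J * D)
  for (i in seq_len(I)) {
    # (8, J*D) with d fastest within j
    Wi <- matrix(aperm(array(W[i, , , ], dim = dW[2:4]), c(2L, 3L, 1L)),
                 nrow = dW[3])
    uhat[i, ] <- as.vector(primary[i, , drop = FALSE] %*% Wi)
  }
  rt <- .routing_forward(uhat, B = 1L, I = I, J = J, D = D,
                         iters = iterations, kind = kind)
  action <- matrix(0, J, D)
  s_mat <- matrix(0, J, D)
  for (j in seq_len(J)) {
    action[j, ] <- rt$V_list[[iterations]][1L, , j]
    s_mat[j, ] <- rt$S_list[[iterations]][1L, , j]
  }
  list(action = action,
       state = list(b = rt$blog, c = rt$c_list[[iterations]],
                    s = s_mat, v = action))
}

#' Margin loss for action capsule lengths
#'
#' `sum_k T_k max(0, m_plus - ||v_k||)^2 + lambda (1 - T_k)
#' max(0, ||v_k|| - m_minus)^2`, averaged over samples when `lengths` is a
#' matrix.
#'
#' @param lengths Numeric vector of action capsule lengths, or a
#'   `B x n_class` matrix (one row per sample).
#' @param true_label Integer class in `1..n_class` (vector of length B for a
#'   matrix input).
#' @param m_plus,m_minus,lambda_down Margin hyperparameters (defaults 0.9,
#'   0.1, 0.5).
#' @return A single numeric loss value.
#' @export
margin_loss <- function(lengths, true_label, m_plus = 0.9, m_minus = 0.1,
                        lambda_down = 0.5) {
  if (!is.matrix(lengths)) lengths <- matrix(lengths, nrow = 1L)
  .margin_loss_grad(lengths, as.integer(true_label), m_plus, m_minus,
                    lambda_down)$loss
}

.margin_loss_grad <- function(len, labels, m_plus = 0.9, m_minus = 0.1,
                              lambda_down = 0.5) {
  B <- nrow(len); J <- ncol(len)
  Tk <- matrix(0, B, J)
  Tk[cbind(seq_len(B), labels)] <- 1
  pos <- pmax(0, m_plus - len)
  neg <- pmax(0, len - m_minus)
  loss <- sum(Tk * pos^2 + lambda_down * (1 - Tk) * neg^2) / B
  dlen <- (Tk * (-2 * pos) + lambda_down * (1 - Tk) * 2 * neg) / B
  list(loss = loss, dlen = dlen)
}

#' Predict the gesture from action capsules
#'
#' The predicted class is the action capsule with the largest length; ties
#' break toward the lowest index.
#'
#' @param action A `J x D` matrix of action capsule vectors, or a numeric
#'   vector of J capsule lengths.
#' @return Integer class index in `1..J`.
#' @export
predict_capsules <- function(action) {
  lens <- if (is.matrix(action)) sqrt(rowSums(action^2)) else as.numeric(action)
  which.max(lens)
}

# ---- full network ---------------------------------------------------------

# Full forward pass over a batch.  Xf, Xs flat (B, len) matrices.
# Returns capsule lengths (B, J) plus cache when keep = TRUE.
.ff_forward <- function(model, Xf, Xs, keep = TRUE) {
  p <- model$params; plans <- model$plans; prof <- model$profile
  kind <- model$kind
  B <- nrow(Xf); C <- prof$C
  fe <- .frontend_forward(p, plans, Xf, Xs, keep = keep)
  mix_flat <- as_flat(fe$mix, B, 49L, C)
  ml <- .mlconv_forward(p, plans, mix_flat, B, keep = keep)
  u_pre <- .caps_reshape(ml$bot, B)            # (B*49*G, 8)
  usq <- .squash_rows(u_pre, kind)
  u <- usq$v
  I <- prof$n_primary; J <- prof$n_class; D <- prof$action_dim
  uhat <- matrix(0, B * I, J * D)
  for (i in seq_len(I)) {
    ri <- ((i - 1L) * B + 1L):(i * B)
    uhat[ri, ] <- u[ri, , drop = FALSE] %*% p$Wc[, , i]
  }
  rt <- .routing_forward(uhat, B, I, J, D, prof$routing_iters, kind)
  len <- matrix(0, B, J)
  for (j in seq_len(J)) len[, j] <- sqrt(rowSums(rt$V[, , j, drop = FALSE]^2))
  out <- list(lengths = len, rt = rt)
  if (keep)
    out <- c(out, list(fe = fe, ml = ml, u_pre = u_pre, usq = usq, u = u,
                       uhat = uhat, B = B))
  out
}

# Full backward pass: dlen (B, J) upstream.  Returns gradient list matching
# model$params.
.ff_backward <- function(model, cache, dlen) {
  p <- model$params; plans <- model$plans; prof <- model$profile
  kind <- model$kind
  B <- cache$B; C <- prof$C
  I <- prof$n_primary; J <- prof$n_class; D <- prof$action_dim
  rt <- cache$rt
  # lengths -> final action capsules
  dV <- array(0, dim = c(B, D, J))
  for (j in seq_len(J)) {
    lj <- pmax(cache$lengths[, j], 1e-12)
    dV[, , j] <- rt$V[, , j] * (dlen[, j] / lj)
  }
  duhat <- .routing_backward(cache$uhat, rt, dV)
  du <- matrix(0, nrow(cache$u), 8L)
  dWc <- array(0, dim = dim(p$Wc))
  for (i in seq_len(I)) {
    ri <- ((i - 1L) * B + 1L):(i * B)
    du[ri, ] <- duhat[ri, , drop = FALSE] %*% t(p$Wc[, , i])
    dWc[, , i] <- crossprod(cache$u[ri, , drop = FALSE],
                            duhat[ri, , drop = FALSE])
  }
  du_pre <- .squash_rows_backward(cache$u_pre, cache$usq, du, kind)
  dbot <- .caps_unreshape(du_pre, B, C)
  # bottleneck
  ml <- cache$ml
  dbot_pre <- relu_backward(ml$bot_pre, dbot)
  dKb <- crossprod(ml$cat2, dbot_pre)
  dbb <- colSums(dbot_pre)
  dcat2 <- dbot_pre %*% t(p$Kb)
  dz3 <- relu_backward(ml$z3_pre, dcat2[, 1:C, drop = FALSE])
  dz5 <- relu_backward(ml$z5_pre, dcat2[, (C + 1L):(2L * C), drop = FALSE])
  dmix_map <- dcat2[, (2L * C + 1L):(3L * C), drop = FALSE]
  cb3 <- conv_backward(dz3, ml$c3$P, p$K3, plans$k3, B)
  cb5 <- conv_backward(dz5, ml$c5$P, p$K5, plans$k5, B)
  dmix <- dmix_map + as_map(cb3$dx + cb5$dx, 49L, C)
  # mixing conv
  fe <- cache$fe
  dmix_pre <- relu_backward(fe$mix_pre, dmix)
  dKmix <- crossprod(fe$cat1, dmix_pre)
  dbmix <- colSums(dmix_pre)
  dcat1 <- dmix_pre %*% t(p$Kmix)
  dzs <- relu_backward(fe$zs_pre, dcat1[, 1:C, drop = FALSE])
  dzf <- relu_backward(fe$zf_pre, dcat1[, (C + 1L):(2L * C), drop = FALSE])
  cbs <- conv_backward(dzs, fe$cs$P, p$Ks, plans$s, B)
  cbf <- conv_backward(dzf, fe$cf$P, p$Kf, plans$f, B)
  list(Ks = cbs$dK, bs = cbs$db, Kf = cbf$dK, bf = cbf$db,
       Kmix = dKmix, bmix = dbmix, K3 = cb3$dK, b3 = cb3$db,
       K5 = cb5$dK, b5 = cb5$db, Kb = dKb, bb = dbb, Wc = dWc)
}
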