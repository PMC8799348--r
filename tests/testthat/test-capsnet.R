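kinds <- c("squash", "hsquash", "strict_squash", "squash_4", "e_squash")

test_that("squash kinds evaluate their closed forms and preserve direction", {
  expect_equal(squash_length(1, "squash"), 0.5)
  expect_equal(squash_length(1, "squash_4"), 2 / 3)
  expect_equal(squash_length(4, "hsquash"), 0.5)
  expect_equal(squash_length(1, "e_squash"), 1 - exp(-1))
  for (k in kinds) {
    expect_identical(apply_squash(c(0, 0, 0), k), c(0, 0, 0))
    set.seed(17)
    s <- rnorm(8) * 3
    v <- apply_squash(s, k)
    # direction preserved
    expect_equal(v / sqrt(sum(v^2)), s / sqrt(sum(s^2)), tolerance = 1e-9)
    expect_equal(sqrt(sum(v^2)), squash_length(sqrt(sum(s^2)), k),
                 tolerance = 1e-12)
  }
})

test_that("squash lengths are monotone, bounded, and e-Squash dominates", {
  x <- seq(0, 25, by = 0.01)
  xs <- x[x <= 5]   # strict upper bound checked where it is representable
  for (k in setdiff(kinds, "strict_squash")) {
    g <- squash_length(x, k)
    expect_true(all(g >= 0 & g <= 1), label = k)
    expect_true(all(squash_length(xs, k) < 1), label = k)
    expect_true(all(diff(g) >= -1e-12), label = paste(k, "monotone"))
  }
  # e-Squash rises at least as fast as the original squash everywhere
  expect_true(all(squash_length(x, "e_squash") >=
                    squash_length(x, "squash") - 1e-12))
})

test_that("matrix squash equals row-by-row vector squash", {
  set.seed(23)
  m <- matrix(rnorm(40), 5, 8)
  for (k in kinds) {
    got <- apply_squash(m, k)
    want <- t(apply(m, 1, apply_squash, kind = k))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("multilevel convolution keeps the 7x7 grid and concatenates 3C channels", {
  wt <- fficaps_init(fficaps_profile("tiny"), seed = 4)
  x <- array(runif(7 * 7 * 8), c(7, 7, 8))
  ml <- multilevel_conv(x, wt, return_intermediates = TRUE)
  expect_identical(dim(ml$out), c(7L, 7L, 8L))
  expect_identical(dim(ml$concat), c(7L, 7L, 24L))
  # the block input is stacked unchanged as the last C channels
  expect_equal(ml$concat[, , 17:24], x)
  # zero input, zero biases -> zero output
  z <- multilevel_conv(array(0, c(7, 7, 8)), wt)
  expect_equal(z, array(0, c(7, 7, 8)))
})

test_that("primary capsule reshaping counts and squashes capsules", {
  wt <- fficaps_init(fficaps_profile("tiny"), seed = 5)
  map <- array(rnorm(7 * 7 * 8), c(7, 7, 8))
  u <- to_primary_caps(map, "e_squash")
  expect_identical(dim(u), c(49L, 8L))   # 7*7*(8/8) capsules of dim 8
  expect_true(all(sqrt(rowSums(u^2)) < 1))
  expect_equal(to_primary_caps(array(0, c(7, 7, 16)), "squash"),
               matrix(0, 98, 8))
  expect_error(to_primary_caps(array(0, c(7, 7, 12)), "squash"))
  # paper-width capsule count: 7*7*(256/8) = 1568
  big <- array(0, c(7, 7, 256))
  expect_identical(nrow(to_primary_caps(big, "squash")), 1568L)
})

test_that("routing couplings are uniform at initialisation and rows sum to 1", {
  set.seed(41)
  I <- 6L; J <- 5L
  u <- matrix(rnorm(I * 8), I, 8)
  W <- array(rnorm(I * J * 8 * 16, sd = 0.3), c(I, J, 8, 16))
  r1 <- dynamic_routing(u, W, iterations = 1, kind = "e_squash")
  expect_equal(r1$state$c, matrix(0.2, I, J))
  for (it in 1:3) {
    r <- dynamic_routing(u, W, iterations = it, kind = "e_squash")
    expect_equal(rowSums(r$state$c), rep(1, I), tolerance = 1e-9)
    expect_identical(dim(r$action), c(J, 16L))
  }
  expect_error(dynamic_routing(u, W, iterations = 0))
})

test_that("vectorised routing matches the triple-loop oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    I <- 4; J <- 2; Din <- 2; Dout <- 3
    u <- matrix(rnorm(I * Din), I, Din)
    W <- array(rnorm(I * J * Din * Dout, sd = 0.7), c(I, J, Din, Dout))
    kind <- kinds[(seed %% 5) + 1]
    got <- dynamic_routing(u, W, iterations = 3, kind = kind)
    want <- oracle_routing(u, W, iterations = 3, kind = kind)
    expect_equal(got$action, want$v, tolerance = 1e-6,
                 label = sprintf("seed %d (%s)", seed, kind))
    expect_equal(got$state$c, want$c, tolerance = 1e-6)
  }
})

test_that("routing is equivariant to primary capsule permutation", {
  set.seed(77)
  I <- 8; J <- 3
  u <- matrix(rnorm(I * 8), I, 8)
  W <- array(rnorm(I * J * 8 * 16, sd = 0.3), c(I, J, 8, 16))
  perm <- sample(I)
  a <- dynamic_routing(u, W, 3, "squash")
  b <- dynamic_routing(u[perm, ], W[perm, , , ], 3, "squash")
  expect_equal(a$action, b$action, tolerance = 1e-10)
})

test_that("batched routing agrees with per-sample routing", {
  set.seed(55)
  B <- 3; I <- 5; J <- 4; D <- 6
  uhat_list <- lapply(1:B, function(b) matrix(rnorm(I * J * D), I, J * D))
  uhat <- matrix(0, B * I, J * D)
  for (i in 1:I) for (b in 1:B)
    uhat[(i - 1) * B + b, ] <- uhat_list[[b]][i, ]
  rt <- fficaps:::.routing_forward(uhat, B, I, J, D, iters = 3,
                                   kind = "e_squash")
  for (b in 1:B) {
    rt1 <- fficaps:::.routing_forward(uhat_list[[b]], 1L, I, J, D,
                                      iters = 3, kind = "e_squash")
    for (j in 1:J)
      expect_equal(rt$V[b, , j], rt1$V[1, , j], tolerance = 1e-12)
  }
})

test_that("margin loss reproduces hand-derived values", {
  expect_equal(margin_loss(c(0.95, 0.05, 0.05, 0.05, 0.05), 1), 0)
  expect_equal(margin_loss(numeric(5), 1), 0.81)
  expect_equal(margin_loss(c(0.95, 0.2, 0.2, 0.2, 0.2), 1), 0.02)
  # batch mean
  len <- rbind(c(0.95, 0.05, 0.05, 0.05, 0.05), numeric(5))
  expect_equal(margin_loss(len, c(1, 2)), 0.405)
})

test_that("margin loss gradient matches finite differences", {
  set.seed(9)
  len <- matrix(runif(10, 0.05, 0.95), 2, 5)
  lab <- c(2L, 4L)
  lg <- fficaps:::.margin_loss_grad(len, lab)
  h <- 1e-6
  for (i in seq_along(len)) {
    lp <- len; lp[i] <- lp[i] + h
    lm <- len; lm[i] <- lm[i] - h
    fd <- (margin_loss(lp, lab) - margin_loss(lm, lab)) / (2 * h)
    expect_equal(lg$dlen[i], fd, tolerance = 1e-5)
  }
})

test_that("prediction takes the longest capsule with low-index ties", {
  expect_identical(predict_capsules(c(0.1, 0.8, 0.2, 0.1, 0.1)), 2L)
  expect_identical(predict_capsules(rep(0.3, 5)), 1L)
  set.seed(13)
  act <- matrix(rnorm(5 * 16), 5, 16)
  lens <- sqrt(rowSums(act^2))
  expect_identical(predict_capsules(act), which.max(lens))
  perm <- c(3L, 1L, 5L, 2L, 4L)
  expect_identical(perm[predict_capsules(act[perm, ])],
                   predict_capsules(act))
})

test_that("full forward yields 5 lengths in [0,1) and is deterministic", {
  win <- random_window(16, 300, seed = 61)
  fi <- build_fused_input(win)
  wt <- fficaps_init(fficaps_profile("tiny"), seed = 6)
  model <- list(params = wt$params, plans = wt$plans, profile = wt$profile,
                kind = "e_squash")
  X <- fficaps:::.stack_fused(list(fi))
  f1 <- fficaps:::.ff_forward(model, X$f, X$s, keep = FALSE)
  f2 <- fficaps:::.ff_forward(model, X$f, X$s, keep = FALSE)
  expect_identical(dim(f1$lengths), c(1L, 5L))
  expect_true(all(f1$lengths >= 0 & f1$lengths < 1))
  expect_identical(f1$lengths, f2$lengths)
})
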