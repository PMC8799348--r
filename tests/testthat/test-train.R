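# Training tests run at the "tiny" width profile on small datasets so the
# whole file stays in the tens of seconds.

test_that("training is deterministic per seed and the loss decreases", {
  ds <- generate_experiment("displacement", n_train = 40, n_test = 20,
                            seed = 3)
  f1 <- fficaps(ds, width_profile = "tiny", epochs = 3, batch_size = 8,
                seed = 4)
  f2 <- fficaps(ds, width_profile = "tiny", epochs = 3, batch_size = 8,
                seed = 4)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
  expect_lt(f1$history$loss[3], f1$history$loss[1])
})

test_that("a linearly separable two-class toy problem trains to 100%", {
  ds <- generate_experiment("displacement", n_train = 30, n_test = 10,
                            shift = 0, n_gestures = 2, separation = 2,
                            noise_sd = 0.02, seed = 6)
  fit <- fficaps(ds, width_profile = "tiny", epochs = 20, batch_size = 8,
                 seed = 6)
  tr <- ds$split == "train"
  pred <- predict(fit, ds$windows[tr])
  expect_equal(mean(pred == ds$labels[tr]), 1)
})

test_that("invalid fitting configurations are rejected", {
  ds <- generate_experiment("displacement", n_train = 10, n_test = 5,
                            seed = 3)
  expect_error(fficaps(ds, epochs = 0))
  expect_error(fficaps(ds, batch_size = 0))
  expect_error(fficaps(ds, squash = "not_a_squash"))
  expect_error(fficaps(ds, width_profile = "mystery"))
  expect_error(fficaps(ds, routing_iters = 0))
})

test_that("evaluation agrees with a brute-force recount", {
  ds <- generate_experiment("displacement", n_train = 40, n_test = 20,
                            seed = 8)
  fit <- fficaps(ds, width_profile = "tiny", epochs = 4, batch_size = 8,
                 seed = 8)
  ev <- evaluate_fficaps(fit, ds)
  te <- ds$split == "test"
  pred <- predict(fit, ds$windows[te])
  truth <- ds$labels[te]
  # brute-force recount of (prediction, label) pairs
  n_ok <- 0
  for (i in seq_along(pred)) if (pred[i] == truth[i]) n_ok <- n_ok + 1
  expect_equal(ev$overall, 100 * n_ok / length(pred))
  # per-class accuracies recount
  for (g in levels(truth)) {
    sel <- truth == g
    expect_equal(unname(ev$per_gesture[g]),
                 100 * mean(pred[sel] == g))
  }
  # confusion row sums equal per-class test counts
  expect_equal(unname(rowSums(ev$confusion)),
               unname(as.vector(table(truth))))
  # overall equals count-weighted mean of per-class accuracies
  wts <- as.vector(table(truth))
  expect_equal(ev$overall,
               sum(ev$per_gesture * wts, na.rm = TRUE) / sum(wts))
})

test_that("capsule lengths and class predictions are consistent", {
  ds <- generate_experiment("displacement", n_train = 20, n_test = 10,
                            seed = 12)
  fit <- fficaps(ds, width_profile = "tiny", epochs = 2, batch_size = 8,
                 seed = 12)
  te <- ds$split == "test"
  lens <- predict(fit, ds$windows[te], type = "lengths")
  cls <- predict(fit, ds$windows[te])
  expect_identical(dim(lens), c(10L, 5L))
  expect_true(all(lens >= 0 & lens < 1))
  expect_identical(as.integer(cls),
                   unname(apply(lens, 1, which.max)))
})

test_that("model checkpoints round-trip and predict identically", {
  ds <- generate_experiment("displacement", n_train = 20, n_test = 10,
                            seed = 14)
  fit <- fficaps(ds, width_profile = "tiny", epochs = 2, batch_size = 8,
                 seed = 14)
  f <- tempfile(fileext = ".rds")
  save_fficaps(fit, f)
  back <- load_fficaps(f)
  te <- ds$split == "test"
  expect_identical(predict(back, ds$windows[te], type = "lengths"),
                   predict(fit, ds$windows[te], type = "lengths"))
  unlink(f)
})

test_that("S3 surface: print, summary, coef, plot", {
  ds <- generate_experiment("displacement", n_train = 10, n_test = 5,
                            seed = 15)
  fit <- fficaps(ds, width_profile = "tiny", epochs = 1, batch_size = 4,
                 seed = 15)
  expect_output(print(fit), "capsule network")
  expect_output(print(summary(fit)), "parameters")
  expect_named(coef(fit),
               c("Ks", "bs", "Kf", "bf", "Kmix", "bmix", "K3", "b3",
                 "K5", "b5", "Kb", "bb", "Wc"))
  pdf(NULL)
  expect_invisible(plot(fit))
  dev.off()
})

test_that("the ablation driver tabulates one row per squash kind", {
  tab <- ablate_squash("displacement", kinds = c("squash", "e_squash"),
                       repeats = 2, seed = 21, epochs = 1,
                       width_profile = "tiny", n_train = 10, n_test = 5,
                       batch_size = 4)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$squash, c("squash", "e_squash"))
  expect_true(all(is.finite(tab$overall_mean)))
  expect_true(all(tab$overall_mean >= 0 & tab$overall_mean <= 100))
})
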