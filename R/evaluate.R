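#' Evaluate a fitted model on a test set
#'
#' @param object A fitted [fficaps()] model.
#' @param dataset An `semg_dataset`; windows with `split == "test"` are
#'   used (all windows when there is no split).
#' @return A list with `per_gesture` (accuracy per true class, percent),
#'   `overall` (percent), and `confusion` (counts, true classes in rows).
#' @export
evaluate_fficaps <- function(object, dataset) {
  te <- if (is.null(dataset$split)) rep(TRUE, length(dataset$windows))
        else dataset$split == "test"
  if (!any(te)) stop("dataset has no test split")
  truth <- factor(as.character(dataset$labels[te]), levels = object$levels)
  pred <- predict(object, dataset$windows[te])
  confusion <- table(truth = truth, predicted = pred)
  per <- 100 * diag(confusion) / rowSums(confusion)
  per[rowSums(confusion) == 0] <- NA_real_
  list(per_gesture = per, overall = 100 * mean(pred == truth),
       confusion = confusion)
}

#' Run a full synthetic experiment with seeded replicates
#'
#' Generates the scenario dataset, trains the network and evaluates it on
#' the test split, once per replicate seed; accuracies are reported as
#' mean and standard deviation over replicates, mirroring the usual
#' mean +/- std layout of gesture-recognition result tables.
#'
#' @param scenario `"displacement"` or `"cross_subject"`.
#' @param squash Squash kind.
#' @param repeats Number of independently seeded replicate runs.
#' @param seed Base seed; replicate r uses `seed + r - 1`.
#' @param epochs,batch_size,width_profile,lr Passed to [fficaps()].  The
#'   default batch size is 32 for the displacement scenario and 16 for
#'   cross-subject.
#' @param ... Further arguments to [generate_experiment()] (e.g. `shift`,
#'   `separation`, `noise_sd`, `n_train`, `n_test`).
#' @param verbose Print per-replicate progress.
#' @return A list of class `"fficaps_report"`: `per_gesture_mean`,
#'   `per_gesture_sd`, `overall_mean`, `overall_sd` (all percent),
#'   `overall` (per-replicate vector), `confusion` (last replicate),
#'   `history` (last replicate), and the run configuration.
#' @export
run_experiment <- function(scenario = c("displacement", "cross_subject"),
                           squash = "e_squash", repeats = 3L, seed = 1L,
                           epochs = 30L,
                           batch_size = NULL, width_profile = "test",
                           lr = 1e-3, ..., verbose = FALSE) {
  scenario <- match.arg(scenario)
  if (is.null(batch_size))
    batch_size <- if (scenario == "displacement") 32L else 16L
  per <- NULL; overall <- numeric(repeats)
  confusion <- NULL; history <- NULL
  for (r in seq_len(repeats)) {
    s <- seed + r - 1L
    ds <- generate_experiment(scenario, seed = s, ...)
    fit <- fficaps(ds, squash = squash, width_profile = width_profile,
                   epochs = epochs, batch_size = batch_size, lr = lr,
                   seed = s, verbose = verbose)
    ev <- evaluate_fficaps(fit, ds)
    per <- rbind(per, ev$per_gesture)
    overall[r] <- ev$overall
    confusion <- ev$confusion
    history <- fit$history
    if (verbose)
      message(sprintf("replicate %d/%d (seed %d): overall %.2f%%",
                      r, repeats, s, ev$overall))
  }
  structure(list(
    scenario = scenario, squash = squash, repeats = repeats, seed = seed,
    per_gesture_mean = colMeans(per),
    per_gesture_sd = apply(per, 2L, stats::sd),
    overall_mean = mean(overall),
    overall_sd = stats::sd(overall),
    overall = overall, confusion = confusion, history = history),
    class = "fficaps_report")
}

#' @export
print.fficaps_report <- function(x, ...) {
  cat(sprintf("FFiCAPS synthetic experiment: %s scenario, %s, %d replicates\n",
              x$scenario, x$squash, x$repeats))
  fmt <- function(m, s) sprintf("%.2f +/- %.2f", m,
                                ifelse(is.na(s), 0, s))
  tab <- data.frame(gesture = names(x$per_gesture_mean),
                    accuracy = fmt(x$per_gesture_mean, x$per_gesture_sd))
  print(tab, row.names = FALSE)
  cat(sprintf("overall accuracy (%%): %s\n",
              fmt(x$overall_mean, x$overall_sd)))
  invisible(x)
}

#' Squash-function ablation
#'
#' Repeats [run_experiment()] for every squash kind and tabulates the
#' overall accuracies.
#'
#' @inheritParams run_experiment
#' @param kinds Squash kinds to compare (default all five).
#' @return A data frame with one row per squash kind: `squash`,
#'   `overall_mean`, `overall_sd` (percent).
#' @export
ablate_squash <- function(scenario = "displacement",
                          kinds = c("squash", "hsquash", "strict_squash",
                                    "squash_4", "e_squash"),
                          repeats = 3L, seed = 1L, ..., verbose = FALSE) {
  rows <- lapply(kinds, function(k) {
    rep_ <- run_experiment(scenario, squash = k, repeats = repeats,
                           seed = seed, ..., verbose = verbose)
    data.frame(squash = k, overall_mean = rep_$overall_mean,
               overall_sd = rep_$overall_sd)
  })
  do.call(rbind, rows)
}
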