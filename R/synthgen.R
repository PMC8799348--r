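#' Gesture names used by the synthetic generator
#'
#' Hand closed, hand open, radial flexion, wrist extension, wrist flexion.
#'
#' @return Character vector of length 5.
#' @export
gesture_names <- function() c("HC", "HO", "RF", "WE", "WF")

#' Generate gesture activation templates
#'
#' Each gesture is modelled as a smooth bump of muscle activation centred on
#' a distinct group of electrode channels on the 16-channel ring.
#' `separation` scales how far the per-gesture envelopes differ: at 0 all
#' envelopes collapse onto the shared baseline; larger values push the
#' gesture-specific bumps apart.
#'
#' @param n_gestures Number of gestures (>= 2; default 5).
#' @param n_channels Number of electrode channels (default 16).
#' @param separation Nonnegative scale of between-gesture envelope distance
#'   (default 1).
#' @param band Pass-band in Hz of the synthetic signals.
#' @param seed Optional integer seed.
#' @return List of templates, each a list with `gesture`, `envelope`
#'   (length `n_channels`, nonnegative) and `band`.
#' @export
make_templates <- function(n_gestures = 5L, n_channels = 16L,
                           separation = 1, band = c(20, 500), seed = NULL) {
  stopifnot(n_gestures >= 2L, n_channels >= 2L, separation >= 0)
  if (!is.null(seed)) set.seed(seed)
  nms <- if (n_gestures == 5L) gesture_names()
         else paste0("G", seq_len(n_gestures))
  baseline <- 0.15
  centers <- (seq_len(n_gestures) - 1L) * n_channels / n_gestures
  width <- n_channels / 4
  # small seeded jitter so no two gestures share an exact envelope shape
  jitter <- stats::runif(n_gestures, -0.3, 0.3)
  lapply(seq_len(n_gestures), function(g) {
    ch <- seq_len(n_channels) - 1L
    d <- pmin(abs(ch - centers[g] - jitter[g]),
              n_channels - abs(ch - centers[g] - jitter[g]))  # ring distance
    env <- baseline + separation * exp(-(d / width)^2 * 4)
    list(gesture = nms[g], envelope = env, band = band)
  })
}

#' Subject profile for the synthetic generator
#'
#' Subjects differ by multiplicative per-channel gains (log-normal,
#' sigma 0.2, emulating electrode/skin impedance variability), an integer
#' circular channel displacement (armband rotation between wearings), and
#' an additive white-noise floor.
#'
#' @param n_channels Number of channels.
#' @param shift Integer circular channel displacement in `0..n_channels-1`.
#' @param noise_sd Additive white-noise standard deviation.
#' @param gain_sigma Log-normal sigma of the per-channel gains.
#' @param seed Optional integer seed.
#' @return A list with `gains`, `shift`, `noise_sd`.
#' @export
subject_profile <- function(n_channels = 16L, shift = 0L, noise_sd = 0.1,
                            gain_sigma = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  shift <- as.integer(shift) %% n_channels
  list(gains = stats::rlnorm(n_channels, 0, gain_sigma),
       shift = shift, noise_sd = noise_sd)
}

# Band-limited unit-variance Gaussian noise via spectral masking: white
# noise is transformed, bins outside [low, high] Hz are zeroed, and the
# signal is transformed back and re-standardised.
.bandlimited_noise <- function(n, fs, band) {
  x <- stats::rnorm(n)
  sp <- stats::fft(x)
  freqs <- (seq_len(n) - 1L) * fs / n
  freqs <- pmin(freqs, fs - freqs)             # two-sided bin frequency
  sp[freqs < band[1] | freqs > band[2]] <- 0
  y <- Re(stats::fft(sp, inverse = TRUE)) / n
  sdv <- stats::sd(y)
  if (sdv > 0) y / sdv else y
}

#' Synthesize one sEMG window
#'
#' Channel `c` carries `envelope[(c - shift) mod n] * gains[c]` times
#' band-limited (20-500 Hz by default) Gaussian noise, plus `noise_sd`
#' times white measurement noise; 300 samples at 1000 Hz by default.
#'
#' @param template A template from [make_templates()].
#' @param subject A [subject_profile()].
#' @param fs Sampling rate in Hz.
#' @param w Window length in samples.
#' @param seed Optional integer seed (bit-identical windows per seed).
#' @return A window: list with `data` (channels x w), `fs`, `label`.
#' @export
synthesize_window <- function(template, subject, fs = 1000, w = 300L,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nc <- length(template$envelope)
  data <- matrix(0, nc, w)
  for (ch in seq_len(nc)) {
    src <- ((ch - 1L - subject$shift) %% nc) + 1L
    amp <- template$envelope[src] * subject$gains[ch]
    data[ch, ] <- amp * .bandlimited_noise(w, fs, template$band) +
      subject$noise_sd * stats::rnorm(w)
  }
  list(data = data, fs = fs, label = template$gesture)
}

#' Generate a synthetic gesture-recognition experiment
#'
#' Two scenarios mirror the two evaluation protocols:
#' * `displacement`: train windows are recorded at channel shift 0 and test
#'   windows at shift `shift` of the same subject, emulating the armband
#'   being re-worn in a rotated position between sessions.
#' * `cross_subject`: train windows come from `subject_count - 1` subjects
#'   and test windows from a held-out subject with a distinct gain profile.
#'
#' Classes are exactly balanced in both splits.
#'
#' @param scenario `"displacement"` or `"cross_subject"`.
#' @param n_train,n_test Total train/test window counts (multiples of the
#'   class count; defaults 600/200 = 120/40 windows per class).
#' @param shift Test-time channel displacement (displacement scenario).
#' @param subject_count Number of subjects (cross-subject scenario).
#' @param separation Envelope separation, see [make_templates()].
#' @param noise_sd Additive noise level.
#' @param n_gestures,n_channels,fs,w Geometry of the dataset.
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @return A list of class `"semg_dataset"`: `windows`, `labels` (factor),
#'   `split` (`"train"`/`"test"`), `templates`, `config`, `seed`.
#' @export
generate_experiment <- function(scenario = c("displacement", "cross_subject"),
                                n_train = 600L, n_test = 200L, shift = 1L,
                                subject_count = 4L, separation = 1,
                                noise_sd = 0.1, n_gestures = 5L,
                                n_channels = 16L, fs = 1000, w = 300L,
                                seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(n_train >= 1L, n_test >= 1L)
  if (n_train %% n_gestures || n_test %% n_gestures)
    stop("train and test sizes must be multiples of the class count")
  set.seed(seed)
  templates <- make_templates(n_gestures, n_channels, separation)
  if (scenario == "displacement") {
    base <- subject_profile(n_channels, shift = 0L, noise_sd = noise_sd)
    train_subjects <- list(base)
    test_subject <- base
    test_subject$shift <- as.integer(shift) %% n_channels
  } else {
    stopifnot(subject_count >= 2L)
    subjects <- lapply(seq_len(subject_count), function(s)
      subject_profile(n_channels, shift = 0L, noise_sd = noise_sd))
    train_subjects <- subjects[-subject_count]
    test_subject <- subjects[[subject_count]]
  }
  synth_split <- function(n_total, subjects) {
    per_class <- n_total %/% n_gestures
    wins <- vector("list", n_total)
    k <- 0L
    for (g in seq_len(n_gestures)) {
      for (r in seq_len(per_class)) {
        k <- k + 1L
        subj <- subjects[[((r - 1L) %% length(subjects)) + 1L]]
        wins[[k]] <- synthesize_window(templates[[g]], subj, fs, w)
      }
    }
    wins
  }
  train <- synth_split(n_train, train_subjects)
  test <- synth_split(n_test, list(test_subject))
  windows <- c(train, test)
  labels <- factor(vapply(windows, `[[`, character(1L), "label"),
                   levels = vapply(templates, `[[`, character(1L), "gesture"))
  structure(list(
    windows = windows, labels = labels,
    split = rep(c("train", "test"), c(n_train, n_test)),
    templates = templates,
    config = list(scenario = scenario, n_train = n_train, n_test = n_test,
                  shift = shift, subject_count = subject_count,
                  separation = separation, noise_sd = noise_sd,
                  n_gestures = n_gestures, n_channels = n_channels,
                  fs = fs, w = w),
    seed = seed), class = "semg_dataset")
}

#' @export
print.semg_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic sEMG dataset (%s): %d train + %d test windows, %d classes, seed %d\n",
    x$config$scenario, x$config$n_train, x$config$n_test,
    nlevels(x$labels), x$seed))
  invisible(x)
}

#' Save / load a dataset container
#'
#' Serialises the dataset (windows, labels, split, seed and config echo) to
#' an RDS container.
#'
#' @param dataset A `semg_dataset`.
#' @param path File path.
#' @return `path` (save) or the dataset (load).
#' @export
save_dataset <- function(dataset, path) {
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) readRDS(path)

#' Nearest-template baseline classifier
#'
#' Classifies windows by the Euclidean distance between their per-channel
#' RMS profile and each gesture's envelope (both scaled to unit norm).  A
#' deliberately simple reference used to sanity-check the generator: labels
#' must be recoverable from the raw signal when envelopes are well
#' separated.
#'
#' @param windows List of windows.
#' @param templates Templates from [make_templates()].
#' @return Integer vector of predicted class indices.
#' @export
nearest_template_classify <- function(windows, templates) {
  env <- vapply(templates, `[[`, numeric(length(templates[[1L]]$envelope)),
                "envelope")
  env <- sweep(env, 2L, sqrt(colSums(env^2)), `/`)
  vapply(windows, function(wdw) {
    prof <- sqrt(rowMeans(wdw$data^2))
    prof <- prof / sqrt(sum(prof^2))
    which.min(colSums((env - prof)^2))
  }, integer(1L))
}
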