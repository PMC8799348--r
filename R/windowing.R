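#' Construct an sEMG recording buffer
#'
#' A recording buffer holds a continuous multi-channel surface-EMG recording
#' as a channels-by-samples matrix together with its sampling rate and an
#' optional gesture label.
#'
#' @param data Numeric matrix, channels in rows, samples in columns
#'   (microvolt-scale arbitrary units).
#' @param fs Sampling rate in Hz.
#' @param label Optional gesture identifier attached to the whole recording.
#' @return An object of class `"semg_recording"`.
#' @export
semg_recording <- function(data, fs = 1000, label = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || nrow(data) < 1L || ncol(data) < 1L)
    stop("'data' must be a non-empty numeric channels x samples matrix")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive sampling rate in Hz")
  structure(list(data = data, fs = fs, label = label),
            class = "semg_recording")
}

#' @export
print.semg_recording <- function(x, ...) {
  cat(sprintf("sEMG recording: %d channels x %d samples @ %g Hz%s\n",
              nrow(x$data), ncol(x$data), x$fs,
              if (is.null(x$label)) "" else paste0(", label ", x$label)))
  invisible(x)
}

#' Read a recording from delimited text
#'
#' Expects one row per sample and one column per channel (the usual export
#' layout of acquisition software); the returned buffer is transposed to
#' channels x samples.
#'
#' @param path Path to a delimited text file.
#' @param fs Sampling rate in Hz.
#' @param label Optional gesture identifier.
#' @param sep Field separator (default tab).
#' @param header Whether the file has a header line.
#' @return A [semg_recording()].
#' @export
read_recording <- function(path, fs = 1000, label = NULL, sep = "\t",
                           header = FALSE) {
  m <- as.matrix(utils::read.table(path, sep = sep, header = header))
  storage.mode(m) <- "double"
  semg_recording(t(m), fs = fs, label = label)
}

#' Write a recording to delimited text (samples in rows, channels in columns)
#'
#' @param rec A [semg_recording()].
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_recording <- function(rec, path, sep = "\t") {
  stopifnot(inherits(rec, "semg_recording"))
  utils::write.table(t(rec$data), path, sep = sep, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Sliding-window analysis of a continuous recording
#'
#' Cuts a recording into overlapping windows of `w` samples advanced by
#' `tau` samples.  Offsets are 0-based and windows are half-open
#' `[start, start + w)`; trailing samples shorter than a full window are
#' dropped.  Every window inherits the buffer's label.
#'
#' @param buffer A [semg_recording()].
#' @param w Window length in samples (default 300).
#' @param tau Increment interval in samples (default 50).
#' @return A list of windows, each a list with elements `data`
#'   (channels x `w` matrix), `fs`, `label` and `start` (0-based offset).
#' @export
slide_windows <- function(buffer, w = 300L, tau = 50L) {
  stopifnot(inherits(buffer, "semg_recording"))
  w <- as.integer(w); tau <- as.integer(tau)
  if (is.na(w) || w < 1L) stop("window length 'w' must be a positive integer")
  if (is.na(tau) || tau < 1L || tau > w)
    stop("increment 'tau' must satisfy 1 <= tau <= w")
  ns <- ncol(buffer$data)
  if (ns < w) return(list())
  starts <- seq.int(0L, ns - w, by = tau)
  lapply(starts, function(s) {
    list(data = buffer$data[, (s + 1L):(s + w), drop = FALSE],
         fs = buffer$fs, label = buffer$label, start = s)
  })
}

#' Solve the window segmentation plan
#'
#' Finds the factor pair `n * l = w` minimising `|n - l|`; when two mirrored
#' pairs tie the one with `n <= l` is returned, so a 300-sample window
#' segments into 15 rows of 20 samples.
#'
#' @param w Window length in samples.
#' @return A list with integer elements `n` (segment count), `l` (segment
#'   length) and `dif = |n - l|`.
#' @export
solve_segmentation <- function(w) {
  w <- as.integer(w)
  if (is.na(w) || w < 1L) stop("'w' must be a positive integer")
  divs <- which(w %% seq_len(w) == 0L)
  # candidates with n <= l resolve the mirror tie toward n <= l
  n <- divs[divs * divs <= w]
  l <- w %/% n
  best <- which.min(l - n)
  list(n = n[best], l = l[best], dif = l[best] - n[best])
}

#' Stack a window channel into its segment matrix
#'
#' Cuts a length-`w` single-channel signal into `n` consecutive segments of
#' `l` samples and stacks them as rows, giving the n x l signal matrix fed
#' to the fusion front-end.  Row-wise flattening recovers the input exactly.
#'
#' @param channel_signal Numeric vector of length `plan$n * plan$l`.
#' @param plan A segmentation plan from [solve_segmentation()].
#' @return An `n x l` numeric matrix.
#' @export
stack_segments <- function(channel_signal, plan) {
  if (length(channel_signal) != plan$n * plan$l)
    stop(sprintf("signal length %d does not match plan %d x %d",
                 length(channel_signal), plan$n, plan$l))
  matrix(channel_signal, nrow = plan$n, ncol = plan$l, byrow = TRUE)
}
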