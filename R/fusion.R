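#' Fusion configuration
#'
#' @param alpha,beta Conversion parameters of the outer-product feature map
#'   (both 0.5).
#' @return A list of class `"fusion_config"`.
#' @export
fusion_config <- function(alpha = 0.5, beta = 0.5) {
  stopifnot(alpha > 0, beta > 0)
  structure(list(alpha = alpha, beta = beta), class = "fusion_config")
}

#' Outer-product feature map
#'
#' Transforms a per-channel feature vector `f` (length 15, leading 1) into
#' a symmetric 15 x 15 abstract feature map
#' `F[i, j] = sigmoid(alpha * beta * f[i] * f[j])`, i.e. the outer product
#' of the scaled vector with itself passed through the sigmoid so every
#' entry lies in (0, 1).
#'
#' @param f Feature vector from [build_feature_vector()].
#' @param config A [fusion_config()].
#' @return A symmetric `length(f) x length(f)` matrix with entries in (0, 1).
#' @export
outer_feature_map <- function(f, config = fusion_config()) {
  f <- as.numeric(f)
  theta <- config$alpha * config$beta * tcrossprod(f)
  1 / (1 + exp(-theta))
}

#' Min-Max normalisation of a matrix
#'
#' Maps the minimum to 0 and the maximum to 1, affinely in between.  A
#' constant matrix maps to all zeros.
#'
#' @param x Numeric matrix (or array) with finite entries.
#' @return Normalised object of the same shape.
#' @export
minmax_normalize <- function(x) {
  lo <- min(x); hi <- max(x)
  if (!is.finite(lo) || !is.finite(hi)) stop("input must be finite")
  if (hi == lo) return(x * 0)
  (x - lo) / (hi - lo)
}

#' Build the fused network input for one window
#'
#' For each electrode channel of a w = 300 sample window this computes the
#' 15-entry feature vector, its 15 x 15 outer-product feature map, and the
#' 15 x 20 stacked segment matrix, Min-Max normalises each per-channel
#' matrix independently, and stacks channels as the depth dimension.
#'
#' @param window A window (list with `data` channels x 300, `fs`, `label`).
#' @param spectral A [spectral_config()].
#' @param fusion A [fusion_config()].
#' @return An object of class `"fused_input"`: list with `feature_map`
#'   (15 x 15 x channels array), `semg_matrix` (15 x 20 x channels array),
#'   `channels` and `label`.
#' @export
build_fused_input <- function(window, spectral = spectral_config(),
                              fusion = fusion_config()) {
  x <- window$data
  w <- ncol(x)
  if (w != 300L)
    stop(sprintf("window length %d: the fusion front-end expects w = 300", w))
  plan <- solve_segmentation(w)
  nf <- 1L + length(feature_names())
  nc <- nrow(x)
  fm <- array(0, dim = c(nf, nf, nc))
  sm <- array(0, dim = c(plan$n, plan$l, nc))
  for (ch in seq_len(nc)) {
    f <- build_feature_vector(x[ch, ], spectral)
    fm[, , ch] <- minmax_normalize(outer_feature_map(f, fusion))
    sm[, , ch] <- minmax_normalize(stack_segments(x[ch, ], plan))
  }
  structure(list(feature_map = fm, semg_matrix = sm, channels = nc,
                 label = window$label),
            class = "fused_input")
}

#' Featurize a list of windows into fused inputs
#'
#' @param windows List of windows (from [slide_windows()] or the synthetic
#'   generator).
#' @param spectral A [spectral_config()].
#' @param fusion A [fusion_config()].
#' @return List of [build_fused_input()] objects.
#' @export
featurize_windows <- function(windows, spectral = spectral_config(),
                              fusion = fusion_config()) {
  lapply(windows, build_fused_input, spectral = spectral, fusion = fusion)
}
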