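#' Squash activation family for capsule vectors
#'
#' A squash function rescales a capsule vector `s` to `g(||s||) * s/||s||`,
#' keeping its direction while compressing its length so that length can be
#' read as an existence probability.  Supported kinds and their length maps
#' g(x):
#'
#' * `squash`: `x^2 / (1 + x^2)` (the original capsule nonlinearity)
#' * `hsquash`: `(x/4)^2 / (1 + (x/4)^2)`
#' * `strict_squash`: `0.69 x^2 * 2^(-0.6 x - 1.115)`
#' * `squash_4`: `x^2 / (0.5 + x^2)`
#' * `e_squash`: `1 - exp(-x^2)`, which tracks the original squash for small
#'   lengths but rises faster once the length grows, sharpening the model's
#'   response to capsule length changes
#'
#' The zero vector maps exactly to the zero vector.  All kinds except
#' `strict_squash` have length strictly below 1.
#'
#' @param s Numeric vector, or a matrix whose rows are capsule vectors.
#' @param kind One of `"squash"`, `"hsquash"`, `"strict_squash"`,
#'   `"squash_4"`, `"e_squash"`.
#' @return Object of the same shape as `s`.
#' @export
apply_squash <- function(s, kind = c("squash", "hsquash", "strict_squash",
                                     "squash_4", "e_squash")) {
  kind <- match.arg(kind)
  if (is.matrix(s)) return(.squash_rows(s, kind)$v)
  v <- .squash_rows(matrix(s, nrow = 1L), kind)$v
  drop(v)
}

#' Squash length map
#'
#' The scalar length compression `g(x)` applied by [apply_squash()] to a
#' capsule of length `x`.
#'
#' @param x Nonnegative numeric vector of capsule lengths.
#' @param kind Squash kind, see [apply_squash()].
#' @return Numeric vector of squashed lengths.
#' @export
squash_length <- function(x, kind = c("squash", "hsquash", "strict_squash",
                                      "squash_4", "e_squash")) {
  kind <- match.arg(kind)
  switch(kind,
    squash = x^2 / (1 + x^2),
    hsquash = x^2 / (16 + x^2),
    strict_squash = 0.69 * x^2 * 2^(-0.6 * x - 1.115),
    squash_4 = x^2 / (0.5 + x^2),
    e_squash = 1 - exp(-x^2))
}

# derivative g'(x) of the length map
.squash_length_grad <- function(x, kind) {
  switch(kind,
    squash = 2 * x / (1 + x^2)^2,
    hsquash = 32 * x / (16 + x^2)^2,
    strict_squash = 0.69 * 2^(-0.6 * x - 1.115) * (2 * x - 0.6 * log(2) * x^2),
    squash_4 = x / (0.5 + x^2)^2,
    e_squash = 2 * x * exp(-x^2))
}

# Row-wise squash with cached quantities for the backward pass.
# Returns v = h(r) * s with h(r) = g(r)/r, plus r and h.
.squash_rows <- function(s, kind) {
  r <- sqrt(rowSums(s * s))
  rg <- pmax(r, 1e-12)            # numerical guard; exact zero rows give 0
  h <- squash_length(rg, kind) / rg
  list(v = s * h, r = rg, h = h)
}

# VJP of row-wise squash: given cached forward and upstream dv, return ds.
# dv/ds = h I + (g'(r) - h)/r * (s s^T)/r  (per row)
.squash_rows_backward <- function(s, cache, dv, kind) {
  r <- cache$r
  h <- cache$h
  gp <- .squash_length_grad(r, kind)
  sdotdv <- rowSums(s * dv)
  dv * h + s * ((gp - h) / (r * r) * sdotdv)
}
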