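# Internal numerical helpers shared across modules.

#' Row-wise softmax
#'
#' @param y numeric matrix (rows = timesteps, cols = classes) or vector.
#' @return matrix (or vector) of probabilities; rows sum to 1.
#' @keywords internal
#' @noRd
softmax_rows <- function(y) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
  m <- apply(y, 1L, max)
  e <- exp(y - m)
  e / rowSums(e)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# round-half-up, used everywhere a continuous delay is discretized so the
# convention does not depend on R's round-half-to-even
round_half_up <- function(x) floor(x + 0.5)

#' Shift the rows of a matrix down by `u` steps, zero-filling the top.
#' Row t of the result is row t - u of `m` (zero when t - u < 1).
#' @noRd
shift_rows <- function(m, u) {
  if (u == 0L) return(m)
  Tn <- nrow(m)
  out <- matrix(0, Tn, ncol(m))
  if (u < Tn) out[(u + 1L):Tn, ] <- m[1L:(Tn - u), , drop = FALSE]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  invisible(x)
}
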