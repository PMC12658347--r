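# Low-level array operations on feature maps.
#
# Internal layout is (C, H, W, B): channel-first within a sample, batch last,
# so that matrix(x, C) exposes the (C, H*W*B) channel matrix without copying
# and per-channel broadcasting recycles along the first axis. The exported
# operation wrappers present the conventional (B, C, H, W) axis order.

#' Convert a (B, C, H, W) array to internal (C, H, W, B) layout
#' @param x numeric 4-d array, dims (B, C, H, W)
#' @return array with dims (C, H, W, B)
#' @keywords internal
as_chwb <- function(x) {
  stopifnot(length(dim(x)) == 4L)
  aperm(x, c(2L, 3L, 4L, 1L))
}

#' Convert internal (C, H, W, B) layout back to (B, C, H, W)
#' @param x numeric 4-d array, dims (C, H, W, B)
#' @return array with dims (B, C, H, W)
#' @keywords internal
as_bchw <- function(x) {
  stopifnot(length(dim(x)) == 4L)
  aperm(x, c(4L, 1L, 2L, 3L))
}

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(x)
}

# Zero-pad the spatial axes of a (C, H, W, B) array by p on every side.
pad_hw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + 2L * p, d[3] + 2L * p, d[4]))
  out[, (p + 1L):(p + d[2]), (p + 1L):(p + d[3]), ] <- x
  out
}

crop_hw <- function(x, p, H, W) {
  if (p == 0L) return(x)
  x[, (p + 1L):(p + H), (p + 1L):(p + W), , drop = FALSE]
}

# Partition a (C, H, W, B) array into non-overlapping k x k blocks and expose
# them as a (C*k*k, Ho*Wo*B) matrix (the patch matrix of a kernel = stride
# convolution). Column-major order throughout; exact inverse is unblockify().
blockify <- function(x, k) {
  d <- dim(x)
  C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  Ho <- H %/% k; Wo <- W %/% k
  dim(x) <- c(C, k, Ho, k, Wo, B)
  x <- aperm(x, c(1L, 2L, 4L, 3L, 5L, 6L))
  dim(x) <- c(C * k * k, Ho * Wo * B)
  x
}

unblockify <- function(p, C, Ho, Wo, k, B) {
  dim(p) <- c(C, k, k, Ho, Wo, B)
  p <- aperm(p, c(1L, 2L, 4L, 3L, 5L, 6L))
  dim(p) <- c(C, Ho * k, Wo * k, B)
  p
}

# Row-wise softmax of a matrix, numerically stabilised.
softmax_rows <- function(s) {
  m <- apply(s, 1L, max)
  e <- exp(s - m)
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

gelu_fun <- function(x) x * stats::pnorm(x)

gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)
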