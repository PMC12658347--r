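# Residual depthwise-separable convolution block.
#
# Z = X + ReLU(BN(Conv1x1(ReLU(BN(DWConv7x7(X))))))
#
# The 7x7 depthwise convolution gathers spatial context over a wide receptive
# field at one filter per channel; the 1x1 convolution mixes channels. Stride
# is 1 and the depthwise padding is 3, so the block is shape preserving, which
# the residual addition requires. Channel changes never happen inside the
# block; they belong to the stage-transition down/upsamplers.

#' Create a residual depthwise-separable CNN block
#'
#' @param channels number of input (= output) channels.
#' @param dw_kernel depthwise kernel size; fixed default 7.
#' @return a `dermseg_module` of class `cnn_block`.
#' @export
cnn_block <- function(channels, dw_kernel = 7L) {
  stopifnot(channels >= 1L, dw_kernel %% 2L == 1L)
  new_module("cnn_block",
             children = list(
               dw = dwconv(channels, dw_kernel),
               bn1 = batchnorm(channels),
               act1 = relu(),
               pw = conv1x1(channels, channels),
               bn2 = batchnorm(channels),
               act2 = relu()),
             meta = list(C = channels, k = dw_kernel))
}

#' @export
mod_forward.cnn_block <- function(m, x, training = FALSE) {
  ch <- m$children
  h <- mod_forward(ch$dw, x, training)
  h <- mod_forward(ch$bn1, h, training)
  h <- mod_forward(ch$act1, h, training)
  h <- mod_forward(ch$pw, h, training)
  h <- mod_forward(ch$bn2, h, training)
  h <- mod_forward(ch$act2, h, training)
  x + h
}

#' @export
mod_backward.cnn_block <- function(m, dout) {
  ch <- m$children
  d <- mod_backward(ch$act2, dout)
  d <- mod_backward(ch$bn2, d)
  d <- mod_backward(ch$pw, d)
  d <- mod_backward(ch$act1, d)
  d <- mod_backward(ch$bn1, d)
  d <- mod_backward(ch$dw, d)
  dout + d
}

#' Apply a residual depthwise-separable CNN block to a feature map
#'
#' Functional wrapper around [cnn_block()] used at the package surface and in
#' tests: takes and returns a feature map in `(B, C, H, W)` axis order. In
#' evaluation mode the normalisation layers use their stored running
#' statistics, so the output is deterministic given input and parameters.
#'
#' @param x numeric 4-d array `(B, C, H, W)` with finite entries.
#' @param block a module created by [cnn_block()].
#' @param training logical; use batch statistics and cache for backprop.
#' @return array of the same shape as `x`.
#' @export
cnn_block_forward <- function(x, block, training = FALSE) {
  stopifnot(inherits(block, "cnn_block"))
  check_finite(x)
  if (dim(x)[2] != block$meta$C) {
    stop(sprintf("channel mismatch: input has %d channels, block expects %d",
                 dim(x)[2], block$meta$C), call. = FALSE)
  }
  as_bchw(mod_forward(block, as_chwb(x), training))
}
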