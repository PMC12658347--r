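# Wavelet-attention refinement of the highest-resolution skip connection.
#
# The encoder skip feature is decomposed with a single-level orthonormal Haar
# DWT into four half-resolution sub-bands (ll, lh, hl, hh). The decoder
# feature, average-pooled to the same size, gates each sub-band through its
# own attention gate (1x1 conv embeddings, ReLU, 1x1 conv to a single channel,
# sigmoid, broadcast over channels). The gated sub-bands are recombined by the
# inverse transform. The orthonormal basis makes dwt2/idwt2 exact inverses and
# conserves energy, so the module can only attenuate sub-band content, never
# amplify it.

#' Single-level 2-D orthonormal Haar wavelet decomposition
#'
#' Applied independently per channel. For a 2x2 block `a b / c d` (rows of the
#' image), the sub-band coefficients are `ll = (a+b+c+d)/2`,
#' `lh = (a-b+c-d)/2`, `hl = (a+b-c-d)/2`, `hh = (a-b-c+d)/2`.
#'
#' @param x feature map `(B, C, H, W)` with even H and W.
#' @return `list(ll, lh, hl, hh)` of arrays `(B, C, H/2, W/2)`.
#' @export
dwt2 <- function(x) {
  xi <- as_chwb(x)
  s <- dwt2_chwb(xi)
  lapply(s, as_bchw)
}

#' Inverse of [dwt2()]
#'
#' @param s list with elements `ll`, `lh`, `hl`, `hh` of identical shape
#'   `(B, C, H/2, W/2)`.
#' @return feature map `(B, C, H, W)`.
#' @export
idwt2 <- function(s) {
  dims <- lapply(s[c("ll", "lh", "hl", "hh")], dim)
  if (length(unique(dims)) != 1L) {
    stop("sub-band shape mismatch", call. = FALSE)
  }
  as_bchw(idwt2_chwb(lapply(s[c("ll", "lh", "hl", "hh")], as_chwb)))
}

# internal (C, H, W, B) versions; the 4x4 block transform matrix is symmetric
# orthogonal, so each is the adjoint (= backward pass) of the other.
dwt2_chwb <- function(x) {
  d <- dim(x)
  if (d[2] %% 2L != 0L || d[3] %% 2L != 0L) {
    stop(sprintf("wavelet decomposition requires even spatial dims, got %dx%d",
                 d[2], d[3]), call. = FALSE)
  }
  oy <- seq.int(1L, d[2], 2L); ey <- oy + 1L
  ox <- seq.int(1L, d[3], 2L); ex <- ox + 1L
  a <- x[, oy, ox, , drop = FALSE]   # row r,   col c
  b <- x[, oy, ex, , drop = FALSE]   # row r,   col c+1
  cc <- x[, ey, ox, , drop = FALSE]  # row r+1, col c
  dd <- x[, ey, ex, , drop = FALSE]  # row r+1, col c+1
  list(ll = (a + b + cc + dd) / 2,
       lh = (a - b + cc - dd) / 2,
       hl = (a + b - cc - dd) / 2,
       hh = (a - b - cc + dd) / 2)
}

idwt2_chwb <- function(s) {
  d <- dim(s$ll)
  out <- array(0, c(d[1], 2L * d[2], 2L * d[3], d[4]))
  oy <- seq.int(1L, 2L * d[2], 2L); ey <- oy + 1L
  ox <- seq.int(1L, 2L * d[3], 2L); ex <- ox + 1L
  out[, oy, ox, ] <- (s$ll + s$lh + s$hl + s$hh) / 2
  out[, oy, ex, ] <- (s$ll - s$lh + s$hl - s$hh) / 2
  out[, ey, ox, ] <- (s$ll + s$lh - s$hl - s$hh) / 2
  out[, ey, ex, ] <- (s$ll - s$lh - s$hl + s$hh) / 2
  out
}

#' 2x2 average pooling of the decoder guidance feature
#'
#' @param x feature map `(B, C, H, W)` with even H and W.
#' @return array `(B, C, H/2, W/2)`.
#' @export
pool_guidance <- function(x) {
  m <- avgpool2()
  as_bchw(mod_forward(m, as_chwb(x)))
}

# one attention gate: alpha = sigma(Wpsi(ReLU(Wx x + Wg g))), single channel
warm_gate <- function(C, f_int) {
  new_module("warm_gate",
             children = list(wx = conv1x1(C, f_int, bias = FALSE),
                             wg = conv1x1(C, f_int, bias = TRUE),
                             act = relu(),
                             wpsi = conv1x1(f_int, 1L, bias = TRUE)),
             meta = list(C = C, f_int = f_int))
}

gate_forward <- function(m, xsub, g, training = FALSE) {
  ch <- m$children
  s <- mod_forward(ch$wx, xsub, training) + mod_forward(ch$wg, g, training)
  r <- mod_forward(ch$act, s, training)
  alpha <- sigmoid(mod_forward(ch$wpsi, r, training))      # (1, H2, W2, B)
  al <- alpha[rep(1L, dim(xsub)[1]), , , , drop = FALSE]   # broadcast over C
  m$cache$alpha <- alpha
  m$cache$al <- al
  m$cache$xsub <- xsub
  xsub * al
}

gate_backward <- function(m, dout) {
  ch <- m$children
  C <- dim(m$cache$xsub)[1]
  dxsub_direct <- dout * m$cache$al
  dal <- dout * m$cache$xsub
  dalpha <- array(colSums(matrix(dal, C)), dim(m$cache$alpha))
  dpsi <- dalpha * m$cache$alpha * (1 - m$cache$alpha)
  dr <- mod_backward(ch$wpsi, dpsi)
  ds <- mod_backward(ch$act, dr)
  dxsub <- dxsub_direct + mod_backward(ch$wx, ds)
  dg <- mod_backward(ch$wg, ds)
  list(dxsub = dxsub, dg = dg)
}

#' Apply one decoder-guided attention gate to a wavelet sub-band
#'
#' Computes `alpha = sigma(Wpsi(ReLU(Wx xsub + Wg g)))`, a single-channel map
#' in (0, 1), and returns `xsub * alpha` broadcast over channels.
#'
#' @param x_sub sub-band `(B, C, H/2, W/2)`.
#' @param g pooled decoder guidance of identical shape.
#' @param gate a gate module from [warm_module()] (element of
#'   `warm$children`), or NULL to create a fresh one.
#' @return `list(refined, alpha)` with `alpha` of shape `(B, 1, H/2, W/2)`.
#' @export
attention_gate <- function(x_sub, g, gate = NULL) {
  if (!identical(dim(x_sub), dim(g))) {
    stop("sub-band and guidance shapes differ", call. = FALSE)
  }
  if (is.null(gate)) gate <- warm_gate(dim(x_sub)[2], max(dim(x_sub)[2] %/% 2L, 1L))
  out <- gate_forward(gate, as_chwb(x_sub), as_chwb(g))
  list(refined = as_bchw(out), alpha = as_bchw(gate$cache$alpha))
}

#' Create a wavelet-attention refinement module
#'
#' @param channels channels C of the encoder and decoder features.
#' @param gate_width embedding width of the gate 1x1 convolutions. The
#'   shipped network default is calibrated so the module's parameter count
#'   matches its printed budget; standing alone, `max(C/2, 1)` is a sensible
#'   choice.
#' @return a `dermseg_module` of class `warm_mod` with one independent gate
#'   per sub-band.
#' @export
warm_module <- function(channels, gate_width = max(channels %/% 2L, 1L)) {
  new_module("warm_mod",
             children = list(gate_ll = warm_gate(channels, gate_width),
                             gate_lh = warm_gate(channels, gate_width),
                             gate_hl = warm_gate(channels, gate_width),
                             gate_hh = warm_gate(channels, gate_width)),
             meta = list(C = channels, f_int = gate_width))
}

warm_forward_chwb <- function(m, x_enc, x_dec, training = FALSE) {
  if (!identical(dim(x_enc), dim(x_dec))) {
    stop("encoder and decoder features must share shape", call. = FALSE)
  }
  s <- dwt2_chwb(x_enc)
  pool <- avgpool2()
  g <- mod_forward(pool, x_dec, training)
  m$cache$pool <- pool
  ref <- list(ll = gate_forward(m$children$gate_ll, s$ll, g, training),
              lh = gate_forward(m$children$gate_lh, s$lh, g, training),
              hl = gate_forward(m$children$gate_hl, s$hl, g, training),
              hh = gate_forward(m$children$gate_hh, s$hh, g, training))
  idwt2_chwb(ref)
}

warm_backward_chwb <- function(m, dout) {
  ds <- dwt2_chwb(dout)                     # adjoint of idwt2
  dg <- 0
  dsub <- list()
  for (nm in c("ll", "lh", "hl", "hh")) {
    gb <- gate_backward(m$children[[paste0("gate_", nm)]], ds[[nm]])
    dsub[[nm]] <- gb$dxsub
    dg <- dg + gb$dg
  }
  dx_enc <- idwt2_chwb(dsub)                # adjoint of dwt2
  dx_dec <- mod_backward(m$cache$pool, dg)
  list(dx_enc = dx_enc, dx_dec = dx_dec)
}

#' Refine an encoder skip feature with decoder-guided wavelet gating
#'
#' @param x_enc encoder feature `(B, C, H, W)`, H and W even.
#' @param x_dec decoder feature of identical shape.
#' @param warm a module from [warm_module()].
#' @param training logical.
#' @return refined feature map of the same shape as `x_enc`.
#' @export
warm_forward <- function(x_enc, x_dec, warm, training = FALSE) {
  stopifnot(inherits(warm, "warm_mod"))
  as_bchw(warm_forward_chwb(warm, as_chwb(x_enc), as_chwb(x_dec), training))
}
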