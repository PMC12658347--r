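# Multi-scale query attention block (MSQFormer).
#
# Full-resolution queries attend to key/value pairs convolutionally compressed
# at strides 2, 4 and 8. Each path gets h/2 heads of dimension d = C/h, so the
# query projection emits 3C/2 features (the only reading under which the
# concatenated path outputs have width 3C/2 and project back to C). Values are
# locally enhanced with a residual 3x3 depthwise convolution on their spatial
# grid before attention. The block is residual attention only: no
# feed-forward sub-layer and no positional encoding.
#
# Attention score memory per path is N x M_i with M_i = HW / s_i^2, i.e.
# strictly below the N^2 of full self-attention for every s_i >= 2.

msq_strides <- c(2L, 4L, 8L)

#' Configure a multi-scale query attention block
#'
#' @param channels feature channels C; must be divisible by `heads`.
#' @param heads total head count h (even); each of the three key/value paths
#'   receives h/2 heads of dimension d = C/h.
#' @param dropout_rate dropout applied after the output projection.
#' @param single_scale if TRUE keep only the stride-2 path (ablation).
#' @return a `dermseg_module` of class `msq_block`.
#' @export
msq_block <- function(channels, heads, dropout_rate = 0, single_scale = FALSE) {
  if (heads < 2L || heads %% 2L != 0L) {
    stop("head count must be an even integer >= 2, got ", heads, call. = FALSE)
  }
  if (channels %% heads != 0L) {
    stop(sprintf("channels (%d) not divisible by heads (%d)", channels, heads),
         call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  }
  strides <- if (single_scale) msq_strides[1L] else msq_strides
  np <- length(strides)
  ck <- channels %/% 2L                     # per-path K (or V) width = h/2 * d
  ch <- list(ln_q = layernorm(channels),
             lin_q = linear(channels, np * ck),
             lin_out = linear(np * ck, channels),
             drop = dropout(dropout_rate))
  for (p in seq_len(np)) {
    s <- strides[p]
    ch[[paste0("conv", p)]] <- convks(channels, channels, s)
    ch[[paste0("ln", p)]] <- layernorm(channels)
    ch[[paste0("gelu", p)]] <- gelu()
    ch[[paste0("kv", p)]] <- linear(channels, 2L * ck)
    ch[[paste0("dwv", p)]] <- dwconv(ck, 3L)
  }
  new_module("msq_block", children = ch,
             meta = list(C = channels, heads = heads, d = channels %/% heads,
                         h2 = heads %/% 2L, ck = ck, strides = strides,
                         dropout = dropout_rate, single_scale = single_scale))
}

check_msq_dims <- function(H, W) {
  if (H %% 8L != 0L) stop("height ", H, " not divisible by 8", call. = FALSE)
  if (W %% 8L != 0L) stop("width ", W, " not divisible by 8", call. = FALSE)
}

#' @export
mod_forward.msq_block <- function(m, x, training = FALSE) {
  mt <- m$meta; ch <- m$children
  d4 <- dim(x)
  C <- d4[1]; H <- d4[2]; W <- d4[3]; B <- d4[4]
  check_msq_dims(H, W)
  N <- H * W
  dh <- mt$d; h2 <- mt$h2; ck <- mt$ck
  isq <- 1 / sqrt(dh)

  xt <- x; dim(xt) <- c(C, N, B)
  qf <- mod_forward(ch$lin_q, mod_forward(ch$ln_q, xt, training), training)

  np <- length(mt$strides)
  o <- array(0, c(np * ck, N, B))
  att <- vector("list", np)
  score_products <- numeric(np)
  for (p in seq_len(np)) {
    s <- mt$strides[p]
    Fi <- mod_forward(ch[[paste0("conv", p)]], x, training)
    ds <- dim(Fi); Hs <- ds[2]; Ws <- ds[3]; Mi <- Hs * Ws
    dim(Fi) <- c(C, Mi, B)
    kv <- mod_forward(ch[[paste0("kv", p)]],
                      mod_forward(ch[[paste0("gelu", p)]],
                                  mod_forward(ch[[paste0("ln", p)]], Fi, training),
                                  training), training)
    K <- kv[seq_len(ck), , , drop = FALSE]
    V <- kv[ck + seq_len(ck), , , drop = FALSE]
    Vg <- V; dim(Vg) <- c(ck, Hs, Ws, B)
    Vd <- mod_forward(ch[[paste0("dwv", p)]], Vg, training)
    dim(Vd) <- c(ck, Mi, B)
    Vt <- V + Vd
    score_products[p] <- N * Mi
    pc <- if (training) vector("list", B) else NULL
    qoff <- (p - 1L) * ck
    for (b in seq_len(B)) {
      hb <- if (training) vector("list", h2) else NULL
      for (j in seq_len(h2)) {
        rows <- (j - 1L) * dh + seq_len(dh)
        Qh <- t(matrix(qf[qoff + rows, , b], dh, N))   # (N, d)
        Kh <- t(matrix(K[rows, , b], dh, Mi))          # (M, d)
        Vh <- t(matrix(Vt[rows, , b], dh, Mi))
        A <- softmax_rows(tcrossprod(Qh, Kh) * isq)
        Z <- A %*% Vh
        o[qoff + rows, , b] <- t(Z)
        if (training) hb[[j]] <- list(A = A, Qh = Qh, Kh = Kh, Vh = Vh)
      }
      if (training) pc[[b]] <- hb
    }
    if (training) {
      att[[p]] <- list(heads = pc, Mi = Mi, Hs = Hs, Ws = Ws)
    } else {
      att[[p]] <- list(Mi = Mi, Hs = Hs, Ws = Ws)
    }
  }
  ot <- mod_forward(ch$drop, mod_forward(ch$lin_out, o, training), training)
  dim(ot) <- d4
  m$cache <- list(d4 = d4, att = att, score_products = score_products,
                  training = training)
  x + ot
}

#' @export
mod_backward.msq_block <- function(m, dout) {
  mt <- m$meta; ch <- m$children
  cm <- m$cache
  stopifnot(isTRUE(cm$training))
  d4 <- cm$d4
  C <- d4[1]; H <- d4[2]; W <- d4[3]; B <- d4[4]
  N <- H * W
  dh <- mt$d; h2 <- mt$h2; ck <- mt$ck
  isq <- 1 / sqrt(dh)

  dot <- dout; dim(dot) <- c(C, N, B)
  do_ <- mod_backward(ch$lin_out, mod_backward(ch$drop, dot))   # (np*ck, N, B)

  dx <- dout                                   # residual branch
  dqf <- array(0, c(length(mt$strides) * ck, N, B))
  for (p in seq_along(mt$strides)) {
    pa <- cm$att[[p]]
    Mi <- pa$Mi; Hs <- pa$Hs; Ws <- pa$Ws
    qoff <- (p - 1L) * ck
    dK <- array(0, c(ck, Mi, B))
    dVt <- array(0, c(ck, Mi, B))
    for (b in seq_len(B)) {
      for (j in seq_len(h2)) {
        rows <- (j - 1L) * dh + seq_len(dh)
        hc <- pa$heads[[b]][[j]]
        dZ <- t(matrix(do_[qoff + rows, , b], dh))       # (N, d)
        A <- hc$A
        dV <- crossprod(A, dZ)                           # (M, d)
        dA <- tcrossprod(dZ, hc$Vh)                      # (N, M)
        dS <- A * (dA - rowSums(A * dA))
        dQ <- (dS %*% hc$Kh) * isq
        dKh <- crossprod(dS, hc$Qh) * isq
        dqf[qoff + rows, , b] <- t(dQ)
        dK[rows, , b] <- t(dKh)
        dVt[rows, , b] <- t(dV)
      }
    }
    # value enhancement: Vt = V + DW(V)
    dVg <- dVt; dim(dVg) <- c(ck, Hs, Ws, B)
    dV_dw <- mod_backward(ch[[paste0("dwv", p)]], dVg)
    dim(dV_dw) <- c(ck, Mi, B)
    dV_tot <- dVt + dV_dw
    dkv <- array(0, c(2L * ck, Mi, B))
    dkv[seq_len(ck), , ] <- dK
    dkv[ck + seq_len(ck), , ] <- dV_tot
    dFi <- mod_backward(ch[[paste0("ln", p)]],
                        mod_backward(ch[[paste0("gelu", p)]],
                                     mod_backward(ch[[paste0("kv", p)]], dkv)))
    dim(dFi) <- c(C, Hs, Ws, B)
    dx <- dx + mod_backward(ch[[paste0("conv", p)]], dFi)
  }
  dxt <- mod_backward(ch$ln_q, mod_backward(ch$lin_q, dqf))
  dim(dxt) <- d4
  dx + dxt
}

# ---- functional surface ------------------------------------------------------

# internal: (h*d, N, B) token rows -> (B, h, N, d)
tok_to_spec <- function(tok, h, d) {
  dd <- dim(tok)
  arr <- array(tok, c(d, h, dd[2], dd[3]))
  aperm(arr, c(4L, 2L, 3L, 1L))
}

spec_to_tok <- function(arr) {
  # (B, h, N, d) -> (h*d, N, B)
  a <- aperm(arr, c(4L, 2L, 3L, 1L))
  dim(a) <- c(dim(arr)[4] * dim(arr)[2], dim(arr)[3], dim(arr)[1])
  a
}

#' Project feature-map pixels to full-resolution query tokens
#'
#' Flattens the `(B, C, H, W)` input to N = H*W tokens (column-major over the
#' spatial grid), layer-normalises, and linearly projects to the query tensor:
#' three per-path groups of h/2 heads each (h/2 x 3 heads total, head
#' dimension d = C/h).
#'
#' @param x feature map `(B, C, H, W)`.
#' @param block an [msq_block()].
#' @return query tokens, array `(B, 3h/2, N, d)` (or `(B, h/2, N, d)` for a
#'   single-scale block).
#' @export
project_queries <- function(x, block) {
  stopifnot(inherits(block, "msq_block"))
  mt <- block$meta
  xi <- as_chwb(x)
  d4 <- dim(xi)
  if (d4[1] != mt$C) {
    stop(sprintf("channel mismatch: input has %d channels, block expects %d",
                 d4[1], mt$C), call. = FALSE)
  }
  dim(xi) <- c(mt$C, d4[2] * d4[3], d4[4])
  qf <- mod_forward(block$children$lin_q,
                    mod_forward(block$children$ln_q, xi))
  tok_to_spec(qf, length(mt$strides) * mt$h2, mt$d)
}

#' Compute multi-scale key/value token pairs
#'
#' Each path compresses the input with a kernel = stride convolution (strides
#' 2, 4, 8; no padding), flattens to M_i = HW/s_i^2 tokens, applies
#' LayerNorm, GELU and a linear map to 2 * (h/2 * d) features, and splits the
#' result into keys and values.
#'
#' @param x feature map `(B, C, H, W)`; H and W must be divisible by 8.
#' @param block an [msq_block()].
#' @return list with one element per path, each `list(K =, V =)` of arrays
#'   `(B, h/2, M_i, d)`.
#' @export
multiscale_kv <- function(x, block) {
  stopifnot(inherits(block, "msq_block"))
  mt <- block$meta
  xi <- as_chwb(x)
  check_msq_dims(dim(xi)[2], dim(xi)[3])
  out <- vector("list", length(mt$strides))
  for (p in seq_along(mt$strides)) {
    ch <- block$children
    Fi <- mod_forward(ch[[paste0("conv", p)]], xi)
    ds <- dim(Fi)
    dim(Fi) <- c(mt$C, ds[2] * ds[3], ds[4])
    kv <- mod_forward(ch[[paste0("kv", p)]],
                      mod_forward(ch[[paste0("gelu", p)]],
                                  mod_forward(ch[[paste0("ln", p)]], Fi)))
    K <- kv[seq_len(mt$ck), , , drop = FALSE]
    V <- kv[mt$ck + seq_len(mt$ck), , , drop = FALSE]
    out[[p]] <- list(K = tok_to_spec(K, mt$h2, mt$d),
                     V = tok_to_spec(V, mt$h2, mt$d))
  }
  out
}

#' Enhance value tokens with a residual 3x3 depthwise convolution
#'
#' The value tokens are laid back on their `path_shape` spatial grid, passed
#' through a zero-padded 3x3 depthwise convolution, and added to themselves.
#'
#' @param v value tokens `(B, h/2, M_i, d)`.
#' @param path_shape integer pair `(H/s_i, W/s_i)`; its product must be M_i.
#' @param block an [msq_block()].
#' @param path which path's enhancement convolution to use (1..3).
#' @return array of the same shape as `v`.
#' @export
enhance_values <- function(v, path_shape, block, path = 1L) {
  stopifnot(inherits(block, "msq_block"))
  mt <- block$meta
  dd <- dim(v)
  if (prod(path_shape) != dd[3]) {
    stop(sprintf("path_shape %dx%d incompatible with %d tokens",
                 path_shape[1], path_shape[2], dd[3]), call. = FALSE)
  }
  tok <- spec_to_tok(v)                       # (ck, M, B)
  dim(tok) <- c(mt$ck, path_shape[1], path_shape[2], dd[1])
  dv <- mod_forward(block$children[[paste0("dwv", path)]], tok)
  dim(dv) <- c(mt$ck, dd[3], dd[1])
  tok2 <- spec_to_tok(v) + dv
  tok_to_spec(tok2, mt$h2, mt$d)
}

#' Scaled dot-product attention between query and compressed key/value tokens
#'
#' @param q queries `(B, heads, N, d)`.
#' @param k keys `(B, heads, M, d)`.
#' @param v values `(B, heads, M, d)`.
#' @return `list(weights, z)`: attention weights `(B, heads, N, M)` with rows
#'   summing to one, and the contextualised tokens `(B, heads, N, d)`.
#' @export
scaled_attention <- function(q, k, v) {
  dq <- dim(q); dk <- dim(k)
  if (dq[4] != dk[4]) {
    stop(sprintf("head_dim mismatch: queries %d, keys %d", dq[4], dk[4]),
         call. = FALSE)
  }
  isq <- 1 / sqrt(dq[4])
  wts <- array(0, c(dq[1], dq[2], dq[3], dk[3]))
  z <- array(0, dq)
  for (b in seq_len(dq[1])) for (j in seq_len(dq[2])) {
    Qh <- matrix(q[b, j, , ], dq[3])
    Kh <- matrix(k[b, j, , ], dk[3])
    Vh <- matrix(v[b, j, , ], dk[3])
    A <- softmax_rows(tcrossprod(Qh, Kh) * isq)
    wts[b, j, , ] <- A
    z[b, j, , ] <- A %*% Vh
  }
  list(weights = wts, z = z)
}

#' Concatenate per-path attention outputs and project back to the feature map
#'
#' @param z_list list of per-path token tensors `(B, h/2, N, d)` sharing B, N
#'   and d.
#' @param block an [msq_block()].
#' @param hw spatial size `(H, W)` with `H*W = N`, used to restore the map.
#' @param training propagate dropout in training mode.
#' @return feature map `(B, C, H, W)`.
#' @export
fuse_paths <- function(z_list, block, hw, training = FALSE) {
  stopifnot(inherits(block, "msq_block"))
  mt <- block$meta
  ns <- vapply(z_list, function(z) dim(z)[3], 0)
  if (length(unique(ns)) != 1L) {
    stop("token-count mismatch across paths: ", paste(ns, collapse = ", "),
         call. = FALSE)
  }
  toks <- lapply(z_list, spec_to_tok)
  o <- array(0, c(length(toks) * mt$ck, dim(toks[[1]])[2], dim(toks[[1]])[3]))
  for (p in seq_along(toks)) {
    o[(p - 1L) * mt$ck + seq_len(mt$ck), , ] <- toks[[p]]
  }
  ot <- mod_forward(block$children$drop,
                    mod_forward(block$children$lin_out, o, training), training)
  dim(ot) <- c(mt$C, hw[1], hw[2], dim(ot)[3])
  as_bchw(ot)
}

#' Apply a full multi-scale query attention block
#'
#' Residual wrapper over the query/key-value/attention/fusion pipeline:
#' `out = x + O(x)`.
#'
#' @param x feature map `(B, C, H, W)`; H, W divisible by 8.
#' @param block an [msq_block()].
#' @param training logical.
#' @return array of the same shape as `x`.
#' @export
msqformer_block <- function(x, block, training = FALSE) {
  stopifnot(inherits(block, "msq_block"))
  as_bchw(mod_forward(block, as_chwb(x), training))
}
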