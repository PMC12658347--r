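# Minimal neural-network module framework.
#
# A module is an environment holding parameters (`par`), accumulated gradients
# (`gr`), non-trainable buffers (`buf`), child modules (`children`) and a
# forward cache (`cache`). Forward and backward passes dispatch on the module
# class via S3. Gradients accumulate across backward calls until zero_grads().
#
# All spatial tensors use the internal (C, H, W, B) layout; token tensors use
# (C, N, B) with N = H*W in column-major spatial order.

new_module <- function(kind, par = list(), buf = list(), children = list(),
                       meta = list()) {
  m <- new.env(parent = emptyenv())
  m$kind <- kind
  m$par <- par
  m$gr <- lapply(par, function(p) array(0, dim(p) %||% length(p)))
  m$buf <- buf
  m$children <- children
  m$cache <- list()
  m$meta <- meta
  class(m) <- c(kind, "dermseg_module")
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dermseg_module <- function(x, ...) {
  cat(sprintf("<%s> %s parameters\n", x$kind,
              format(count_params(x), big.mark = ",")))
  invisible(x)
}

#' Run a module's forward pass
#'
#' Generic over all network modules. Spatial tensors use the internal
#' `(C, H, W, B)` layout; the exported operation wrappers (e.g.
#' [cnn_block_forward()], [msqformer_block()], [forward()]) convert from the
#' conventional `(B, C, H, W)` order.
#'
#' @param m a `dermseg_module`.
#' @param x input array.
#' @param training logical; cache intermediates for [mod_backward()] and use
#'   batch statistics in normalisation layers.
#' @return output array.
#' @export
mod_forward <- function(m, x, training = FALSE) UseMethod("mod_forward")

#' Run a module's backward pass
#'
#' Accumulates parameter gradients into the module tree (see [zero_grads()])
#' and returns the gradient with respect to the module input. Requires a
#' preceding [mod_forward()] call with `training = TRUE`.
#'
#' @param m a `dermseg_module`.
#' @param dout gradient of the loss w.r.t. the module output.
#' @return gradient w.r.t. the module input.
#' @export
mod_backward <- function(m, dout) UseMethod("mod_backward")

#' Collect references to every trainable tensor of a module tree
#'
#' @param m a `dermseg_module`.
#' @param path name prefix for the returned paths.
#' @return list of `list(mod, name, path)` references.
#' @export
param_refs <- function(m, path = m$kind) {
  refs <- list()
  for (nm in names(m$par)) {
    refs[[length(refs) + 1L]] <- list(mod = m, name = nm,
                                      path = paste(path, nm, sep = "/"))
  }
  for (cn in names(m$children)) {
    refs <- c(refs, param_refs(m$children[[cn]], paste(path, cn, sep = "/")))
  }
  refs
}

#' Total number of trainable parameters of a module tree
#' @param m a `dermseg_module`.
#' @return integer count.
#' @export
count_params <- function(m) {
  sum(vapply(param_refs(m), function(r) length(r$mod$par[[r$name]]), 0))
}

#' Reset accumulated gradients of a module tree to zero
#' @param m a `dermseg_module`.
#' @return the module, invisibly.
#' @export
zero_grads <- function(m) {
  for (nm in names(m$gr)) m$gr[[nm]][] <- 0
  for (ch in m$children) zero_grads(ch)
  invisible(m)
}

# Deep copy of the parameter tree (used for checkpoints).
param_state <- function(m) {
  st <- list(par = m$par, buf = m$buf)
  st$children <- lapply(m$children, param_state)
  st
}

load_param_state <- function(m, st) {
  stopifnot(identical(names(m$par), names(st$par)))
  m$par <- st$par
  m$buf <- st$buf
  for (nm in names(m$children)) load_param_state(m$children[[nm]], st$children[[nm]])
  invisible(m)
}

acc_grad <- function(m, name, g) {
  m$gr[[name]] <- m$gr[[name]] + g
  invisible(NULL)
}

# ---- weight initialisation ---------------------------------------------------

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

# ---- 1x1 convolution (channel mixing) ---------------------------------------

conv1x1 <- function(cin, cout, bias = TRUE) {
  par <- list(weight = he_init(c(cout, cin), cin))
  if (bias) par$bias <- numeric(cout)
  new_module("conv1x1", par, meta = list(cin = cin, cout = cout))
}

#' @export
mod_forward.conv1x1 <- function(m, x, training = FALSE) {
  d <- dim(x)
  xm <- matrix(x, d[1])
  y <- m$par$weight %*% xm
  if (!is.null(m$par$bias)) y <- y + m$par$bias
  m$cache <- list(xm = xm, d = d)
  array(y, c(m$meta$cout, d[-1]))
}

#' @export
mod_backward.conv1x1 <- function(m, dout) {
  d <- m$cache$d
  dm <- matrix(dout, m$meta$cout)
  acc_grad(m, "weight", dm %*% t(m$cache$xm))
  if (!is.null(m$par$bias)) acc_grad(m, "bias", rowSums(dm))
  array(crossprod(m$par$weight, dm), d)
}

# ---- depthwise convolution (stride 1, "same" zero padding) ------------------

dwconv <- function(C, k, pad = (k - 1L) %/% 2L, bias = TRUE) {
  par <- list(weight = he_init(c(C, k, k), k * k))
  if (bias) par$bias <- numeric(C)
  new_module("dwconv", par, meta = list(C = C, k = k, pad = pad))
}

#' @export
mod_forward.dwconv <- function(m, x, training = FALSE) {
  d <- dim(x); k <- m$meta$k; p <- m$meta$pad
  H <- d[2]; W <- d[3]
  xp <- pad_hw(x, p)
  out <- array(0, d)
  Wt <- m$par$weight
  for (dy in seq_len(k)) for (dx in seq_len(k)) {
    out <- out + xp[, dy:(dy + H - 1L), dx:(dx + W - 1L), , drop = FALSE] *
      Wt[, dy, dx]
  }
  if (!is.null(m$par$bias)) out <- out + m$par$bias
  m$cache <- list(xp = xp, d = d)
  out
}

#' @export
mod_backward.dwconv <- function(m, dout) {
  d <- m$cache$d; k <- m$meta$k; p <- m$meta$pad
  C <- d[1]; H <- d[2]; W <- d[3]
  xp <- m$cache$xp
  dxp <- array(0, dim(xp))
  dW <- array(0, dim(m$par$weight))
  Wt <- m$par$weight
  for (dy in seq_len(k)) for (dx in seq_len(k)) {
    ys <- dy:(dy + H - 1L); xs <- dx:(dx + W - 1L)
    sl <- xp[, ys, xs, , drop = FALSE]
    dW[, dy, dx] <- rowSums(matrix(sl * dout, C))
    dxp[, ys, xs, ] <- dxp[, ys, xs, , drop = FALSE] + dout * Wt[, dy, dx]
  }
  acc_grad(m, "weight", dW)
  if (!is.null(m$par$bias)) acc_grad(m, "bias", rowSums(matrix(dout, C)))
  crop_hw(dxp, p, H, W)
}

# ---- dense k x k convolution with stride (the stem) -------------------------

convdense <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  par <- list(weight = he_init(c(cout, cin, k, k), cin * k * k),
              bias = numeric(cout))
  new_module("convdense", par,
             meta = list(cin = cin, cout = cout, k = k, s = stride, pad = pad))
}

#' @export
mod_forward.convdense <- function(m, x, training = FALSE) {
  d <- dim(x); k <- m$meta$k; s <- m$meta$s; p <- m$meta$pad
  H <- d[2]; W <- d[3]; B <- d[4]
  Ho <- (H + 2L * p - k) %/% s + 1L
  Wo <- (W + 2L * p - k) %/% s + 1L
  xp <- pad_hw(x, p)
  y <- matrix(0, m$meta$cout, Ho * Wo * B)
  for (dy in seq_len(k)) for (dx in seq_len(k)) {
    sl <- xp[, seq.int(dy, by = s, length.out = Ho),
             seq.int(dx, by = s, length.out = Wo), , drop = FALSE]
    y <- y + m$par$weight[, , dy, dx] %*% matrix(sl, m$meta$cin)
  }
  y <- y + m$par$bias
  m$cache <- list(xp = xp, d = d, Ho = Ho, Wo = Wo)
  array(y, c(m$meta$cout, Ho, Wo, B))
}

#' @export
mod_backward.convdense <- function(m, dout) {
  cm <- m$cache; k <- m$meta$k; s <- m$meta$s; p <- m$meta$pad
  d <- cm$d; Ho <- cm$Ho; Wo <- cm$Wo
  dm <- matrix(dout, m$meta$cout)
  dxp <- array(0, dim(cm$xp))
  dW <- array(0, dim(m$par$weight))
  for (dy in seq_len(k)) for (dx in seq_len(k)) {
    ys <- seq.int(dy, by = s, length.out = Ho)
    xs <- seq.int(dx, by = s, length.out = Wo)
    sl <- matrix(cm$xp[, ys, xs, , drop = FALSE], m$meta$cin)
    dW[, , dy, dx] <- dm %*% t(sl)
    dsl <- crossprod(m$par$weight[, , dy, dx], dm)
    dxp[, ys, xs, ] <- dxp[, ys, xs, , drop = FALSE] +
      array(dsl, c(m$meta$cin, Ho, Wo, d[4]))
  }
  acc_grad(m, "weight", dW)
  acc_grad(m, "bias", rowSums(dm))
  crop_hw(dxp, p, d[2], d[3])
}

# ---- kernel = stride convolution (non-overlapping; KV compression and
# ---- 2x downsamplers) -------------------------------------------------------

convks <- function(cin, cout, k) {
  par <- list(weight = he_init(c(cout, cin * k * k), cin * k * k),
              bias = numeric(cout))
  new_module("convks", par, meta = list(cin = cin, cout = cout, k = k))
}

#' @export
mod_forward.convks <- function(m, x, training = FALSE) {
  d <- dim(x); k <- m$meta$k
  Ho <- d[2] %/% k; Wo <- d[3] %/% k
  pmat <- blockify(x, k)
  y <- m$par$weight %*% pmat + m$par$bias
  m$cache <- list(pmat = pmat, d = d, Ho = Ho, Wo = Wo)
  array(y, c(m$meta$cout, Ho, Wo, d[4]))
}

#' @export
mod_backward.convks <- function(m, dout) {
  cm <- m$cache; k <- m$meta$k
  dm <- matrix(dout, m$meta$cout)
  acc_grad(m, "weight", dm %*% t(cm$pmat))
  acc_grad(m, "bias", rowSums(dm))
  dp <- crossprod(m$par$weight, dm)
  unblockify(dp, m$meta$cin, cm$Ho, cm$Wo, k, cm$d[4])
}

# ---- 2x2 stride-2 transposed convolution (upsamplers) -----------------------

tconv2 <- function(cin, cout) {
  par <- list(weight = he_init(c(cout * 4L, cin), cin),
              bias = numeric(cout))
  new_module("tconv2", par, meta = list(cin = cin, cout = cout))
}

#' @export
mod_forward.tconv2 <- function(m, x, training = FALSE) {
  d <- dim(x)
  xm <- matrix(x, d[1])
  p <- m$par$weight %*% xm
  out <- unblockify(p, m$meta$cout, d[2], d[3], 2L, d[4])
  out <- out + m$par$bias
  m$cache <- list(xm = xm, d = d)
  out
}

#' @export
mod_backward.tconv2 <- function(m, dout) {
  d <- m$cache$d
  acc_grad(m, "bias", rowSums(matrix(dout, m$meta$cout)))
  dp <- blockify(dout, 2L)
  acc_grad(m, "weight", dp %*% t(m$cache$xm))
  array(crossprod(m$par$weight, dp), d)
}

# ---- batch normalisation over (H, W, B) per channel -------------------------

batchnorm <- function(C, momentum = 0.1, eps = 1e-5) {
  new_module("batchnorm",
             par = list(gamma = rep(1, C), beta = numeric(C)),
             buf = list(running_mean = numeric(C), running_var = rep(1, C)),
             meta = list(C = C, momentum = momentum, eps = eps))
}

#' @export
mod_forward.batchnorm <- function(m, x, training = FALSE) {
  C <- m$meta$C; eps <- m$meta$eps
  if (training) {
    xm <- matrix(x, C)
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu * mu
    mom <- m$meta$momentum
    m$buf$running_mean <- (1 - mom) * m$buf$running_mean + mom * mu
    m$buf$running_var <- (1 - mom) * m$buf$running_var + mom * v
  } else {
    mu <- m$buf$running_mean
    v <- m$buf$running_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (x - mu) * inv
  y <- xhat * m$par$gamma + m$par$beta
  m$cache <- list(xhat = xhat, inv = inv, training = training)
  y
}

#' @export
mod_backward.batchnorm <- function(m, dout) {
  C <- m$meta$C
  xhat <- m$cache$xhat
  acc_grad(m, "gamma", rowSums(matrix(dout * xhat, C)))
  acc_grad(m, "beta", rowSums(matrix(dout, C)))
  dxhat <- dout * m$par$gamma
  if (m$cache$training) {
    mu_d <- rowMeans(matrix(dxhat, C))
    mu_dx <- rowMeans(matrix(dxhat * xhat, C))
    (dxhat - mu_d - xhat * mu_dx) * m$cache$inv
  } else {
    dxhat * m$cache$inv
  }
}

# ---- layer normalisation over channels of a (C, N, B) token tensor ----------

layernorm <- function(C, eps = 1e-5) {
  new_module("layernorm",
             par = list(gamma = rep(1, C), beta = numeric(C)),
             meta = list(C = C, eps = eps))
}

#' @export
mod_forward.layernorm <- function(m, x, training = FALSE) {
  C <- m$meta$C
  d <- dim(x)
  xm <- matrix(x, C)
  mu <- colMeans(xm)
  v <- colMeans(xm * xm) - mu * mu
  inv <- 1 / sqrt(v + m$meta$eps)
  xhat <- (xm - rep(mu, each = C)) * rep(inv, each = C)
  y <- xhat * m$par$gamma + m$par$beta
  m$cache <- list(xhat = xhat, inv = inv, d = d)
  array(y, d)
}

#' @export
mod_backward.layernorm <- function(m, dout) {
  C <- m$meta$C
  xhat <- m$cache$xhat
  dm <- matrix(dout, C)
  acc_grad(m, "gamma", rowSums(dm * xhat))
  acc_grad(m, "beta", rowSums(dm))
  dxhat <- dm * m$par$gamma
  mu_d <- colMeans(dxhat)
  mu_dx <- colMeans(dxhat * xhat)
  dx <- (dxhat - rep(mu_d, each = C) - xhat * rep(mu_dx, each = C)) *
    rep(m$cache$inv, each = C)
  array(dx, m$cache$d)
}

# ---- token-wise linear map on (C, N, B) -------------------------------------

linear <- function(cin, cout, bias = TRUE) {
  par <- list(weight = he_init(c(cout, cin), cin))
  if (bias) par$bias <- numeric(cout)
  m <- new_module("linearmod", par, meta = list(cin = cin, cout = cout))
  m
}

#' @export
mod_forward.linearmod <- function(m, x, training = FALSE) {
  d <- dim(x)
  xm <- matrix(x, d[1])
  y <- m$par$weight %*% xm
  if (!is.null(m$par$bias)) y <- y + m$par$bias
  m$cache <- list(xm = xm, d = d)
  array(y, c(m$meta$cout, d[-1]))
}

#' @export
mod_backward.linearmod <- function(m, dout) {
  dm <- matrix(dout, m$meta$cout)
  acc_grad(m, "weight", dm %*% t(m$cache$xm))
  if (!is.null(m$par$bias)) acc_grad(m, "bias", rowSums(dm))
  array(crossprod(m$par$weight, dm), m$cache$d)
}

# ---- activations ------------------------------------------------------------

relu <- function() new_module("relumod")

#' @export
mod_forward.relumod <- function(m, x, training = FALSE) {
  m$cache <- list(pos = x > 0)
  x * m$cache$pos
}

#' @export
mod_backward.relumod <- function(m, dout) dout * m$cache$pos

gelu <- function() new_module("gelumod")

#' @export
mod_forward.gelumod <- function(m, x, training = FALSE) {
  m$cache <- list(x = x)
  gelu_fun(x)
}

#' @export
mod_backward.gelumod <- function(m, dout) dout * gelu_grad(m$cache$x)

# ---- dropout ----------------------------------------------------------------

dropout <- function(rate = 0) new_module("dropoutmod", meta = list(rate = rate))

#' @export
mod_forward.dropoutmod <- function(m, x, training = FALSE) {
  if (!training || m$meta$rate <= 0) {
    m$cache <- list(mask = NULL)
    return(x)
  }
  keep <- 1 - m$meta$rate
  mask <- (array(stats::runif(length(x)), dim(x)) < keep) / keep
  m$cache <- list(mask = mask)
  x * mask
}

#' @export
mod_backward.dropoutmod <- function(m, dout) {
  if (is.null(m$cache$mask)) dout else dout * m$cache$mask
}

# ---- 2x2 average pooling ----------------------------------------------------

avgpool2 <- function() new_module("avgpool2")

#' @export
mod_forward.avgpool2 <- function(m, x, training = FALSE) {
  d <- dim(x)
  if (d[2] %% 2L != 0L || d[3] %% 2L != 0L) {
    stop("average pooling requires even spatial dims, got ",
         d[2], "x", d[3], call. = FALSE)
  }
  oy <- seq.int(1L, d[2], 2L); ey <- oy + 1L
  ox <- seq.int(1L, d[3], 2L); ex <- ox + 1L
  m$cache <- list(d = d)
  (x[, oy, ox, , drop = FALSE] + x[, ey, ox, , drop = FALSE] +
     x[, oy, ex, , drop = FALSE] + x[, ey, ex, , drop = FALSE]) / 4
}

#' @export
mod_backward.avgpool2 <- function(m, dout) {
  d <- m$cache$d
  dx <- array(0, d)
  oy <- seq.int(1L, d[2], 2L); ey <- oy + 1L
  ox <- seq.int(1L, d[3], 2L); ex <- ox + 1L
  q <- dout / 4
  dx[, oy, ox, ] <- q; dx[, ey, ox, ] <- q
  dx[, oy, ex, ] <- q; dx[, ey, ex, ] <- q
  dx
}
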