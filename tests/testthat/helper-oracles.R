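# Independent reference implementations used as oracles. Everything here is
# written with explicit elementwise loops against the documented weight
# layouts, deliberately avoiding the package's vectorised code paths.

# token order: column-major over the (H, W) grid, H fastest
tok_rc <- function(n, H) c((n - 1) %% H + 1, (n - 1) %/% H + 1)

naive_ln <- function(v, gamma, beta, eps = 1e-5) {
  mu <- mean(v)
  va <- mean((v - mu)^2)
  gamma * (v - mu) / sqrt(va + eps) + beta
}

naive_linear <- function(v, W, b) {
  out <- numeric(nrow(W))
  for (i in seq_len(nrow(W))) out[i] <- sum(W[i, ] * v) + (if (is.null(b)) 0 else b[i])
  out
}

# kernel = stride convolution on a per-sample (C, H, W) array; weight rows
# index the (C, r_h, r_w) patch layout with C fastest
naive_convks <- function(xs, W, b, k) {
  C <- dim(xs)[1]; H <- dim(xs)[2]; Wd <- dim(xs)[3]
  Ho <- H %/% k; Wo <- Wd %/% k
  cout <- nrow(W)
  out <- array(0, c(cout, Ho, Wo))
  for (bi in seq_len(Ho)) for (bj in seq_len(Wo)) for (co in seq_len(cout)) {
    acc <- b[co]
    for (dy in seq_len(k)) for (dx in seq_len(k)) for (ci in seq_len(C)) {
      w_idx <- ci + C * ((dy - 1) + k * (dx - 1))
      acc <- acc + W[co, w_idx] * xs[ci, (bi - 1) * k + dy, (bj - 1) * k + dx]
    }
    out[co, bi, bj] <- acc
  }
  out
}

# depthwise 3x3, zero padding 1, on a (C, H, W) grid; weight (C, 3, 3)
naive_dw3 <- function(xs, W, b) {
  C <- dim(xs)[1]; H <- dim(xs)[2]; Wd <- dim(xs)[3]
  out <- array(0, dim(xs))
  for (c in seq_len(C)) for (i in seq_len(H)) for (j in seq_len(Wd)) {
    acc <- b[c]
    for (dy in 1:3) for (dx in 1:3) {
      y <- i + dy - 2; x <- j + dx - 2
      if (y >= 1 && y <= H && x >= 1 && x <= Wd) {
        acc <- acc + W[c, dy, dx] * xs[c, y, x]
      }
    }
    out[c, i, j] <- acc
  }
  out
}

naive_softmax <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

# dense re-implementation of the whole multi-scale query attention block for
# one sample in (B = 1, C, H, W) order, evaluation mode, dropout inactive
naive_msq_forward <- function(x, block) {
  mt <- block$meta
  ch <- block$children
  C <- dim(x)[2]; H <- dim(x)[3]; W <- dim(x)[4]
  N <- H * W
  dh <- mt$d; h2 <- mt$h2; ck <- mt$ck
  np <- length(mt$strides)

  xs <- array(x[1, , , ], c(C, H, W))
  toks <- matrix(0, N, C)
  for (n in seq_len(N)) {
    rc <- tok_rc(n, H)
    toks[n, ] <- xs[, rc[1], rc[2]]
  }
  qf <- matrix(0, N, np * ck)
  for (n in seq_len(N)) {
    v <- naive_ln(toks[n, ], ch$ln_q$par$gamma, ch$ln_q$par$beta)
    qf[n, ] <- naive_linear(v, ch$lin_q$par$weight, ch$lin_q$par$bias)
  }
  zc <- matrix(0, N, np * ck)
  for (p in seq_len(np)) {
    s <- mt$strides[p]
    cv <- ch[[paste0("conv", p)]]
    Fi <- naive_convks(xs, cv$par$weight, cv$par$bias, s)
    Hs <- dim(Fi)[2]; Ws <- dim(Fi)[3]; Mi <- Hs * Ws
    kv <- matrix(0, Mi, 2 * ck)
    for (m in seq_len(Mi)) {
      rc <- tok_rc(m, Hs)
      v <- naive_ln(Fi[, rc[1], rc[2]],
                    ch[[paste0("ln", p)]]$par$gamma,
                    ch[[paste0("ln", p)]]$par$beta)
      v <- v * pnorm(v)                                  # GELU
      kv[m, ] <- naive_linear(v, ch[[paste0("kv", p)]]$par$weight,
                              ch[[paste0("kv", p)]]$par$bias)
    }
    K <- kv[, seq_len(ck), drop = FALSE]
    V <- kv[, ck + seq_len(ck), drop = FALSE]
    vg <- array(0, c(ck, Hs, Ws))
    for (m in seq_len(Mi)) {
      rc <- tok_rc(m, Hs)
      vg[, rc[1], rc[2]] <- V[m, ]
    }
    dwm <- ch[[paste0("dwv", p)]]
    ve <- naive_dw3(vg, dwm$par$weight, dwm$par$bias)
    Vt <- V
    for (m in seq_len(Mi)) {
      rc <- tok_rc(m, Hs)
      Vt[m, ] <- V[m, ] + ve[, rc[1], rc[2]]
    }
    for (j in seq_len(h2)) {
      cols <- (j - 1) * dh + seq_len(dh)
      qcols <- (p - 1) * ck + cols
      for (n in seq_len(N)) {
        scores <- numeric(Mi)
        for (m in seq_len(Mi)) {
          scores[m] <- sum(qf[n, qcols] * K[m, cols]) / sqrt(dh)
        }
        a <- naive_softmax(scores)
        for (k in seq_len(dh)) {
          zc[n, (p - 1) * ck + cols[k]] <- sum(a * Vt[, cols[k]])
        }
      }
    }
  }
  out <- array(0, c(1, C, H, W))
  for (n in seq_len(N)) {
    o <- naive_linear(zc[n, ], ch$lin_out$par$weight, ch$lin_out$par$bias)
    rc <- tok_rc(n, H)
    out[1, , rc[1], rc[2]] <- xs[, rc[1], rc[2]] + o
  }
  out
}

# flood fill: number of 4-connected foreground components of a 0/1 matrix
count_components <- function(mask) {
  m <- mask > 0
  seen <- matrix(FALSE, nrow(m), ncol(m))
  comps <- 0L
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (m[i, j] && !seen[i, j]) {
      comps <- comps + 1L
      stack <- list(c(i, j))
      seen[i, j] <- TRUE
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nrow(m) && q[2] >= 1 && q[2] <= ncol(m) &&
              m[q[1], q[2]] && !seen[q[1], q[2]]) {
            seen[q[1], q[2]] <- TRUE
            stack[[length(stack) + 1L]] <- q
          }
        }
      }
    }
  }
  comps
}

# brute-force HD95: explicit boundary scan, all-pairs distances, and a
# hand-written linear-interpolation 95th percentile
naive_hd95 <- function(a, b) {
  bdry <- function(m) {
    pts <- list()
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      if (m[i, j] > 0) {
        bg <- FALSE
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          y <- i + d[1]; x <- j + d[2]
          if (y < 1 || y > nrow(m) || x < 1 || x > ncol(m) || m[y, x] == 0) {
            bg <- TRUE
          }
        }
        if (bg) pts[[length(pts) + 1L]] <- c(i, j)
      }
    }
    do.call(rbind, pts)
  }
  pa <- bdry(a); pb <- bdry(b)
  dmin <- function(from, to) {
    apply(from, 1, function(p) {
      min(sqrt((to[, 1] - p[1])^2 + (to[, 2] - p[2])^2))
    })
  }
  pooled <- sort(c(dmin(pa, pb), dmin(pb, pa)))
  h <- (length(pooled) - 1) * 0.95 + 1
  lo <- floor(h)
  if (lo >= length(pooled)) return(pooled[length(pooled)])
  pooled[lo] + (h - lo) * (pooled[lo + 1] - pooled[lo])
}

# tiny network configuration used across tests (3 stages, 64x64-capable)
tiny_model_config <- function(input_size = 64L) {
  model_config(input_size = input_size, stage_channels = c(8L, 16L, 32L),
               enc_blocks = c(1L, 1L, 1L), dec_blocks = c(1L, 1L),
               heads = c(2L, 2L, 4L), gate_width = 4L)
}

# smallest legal configuration (2 stages, 32x32)
micro_model_config <- function(...) {
  model_config(input_size = 32L, stage_channels = c(4L, 8L),
               enc_blocks = c(1L, 1L), dec_blocks = c(1L),
               heads = c(2L, 2L), gate_width = 3L, ...)
}

rand_arr <- function(...) {
  d <- c(...)
  array(stats::rnorm(prod(d)), d)
}
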