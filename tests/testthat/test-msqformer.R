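test_that("query projection produces three per-path head groups at full resolution", {
  set.seed(21)
  blk <- msq_block(8, 4)
  x <- rand_arr(1, 8, 4, 4)
  q <- project_queries(x, blk)
  expect_identical(dim(q), c(1L, 6L, 16L, 2L))   # 3 paths x h/2 heads, N, d
  # constant input: every token identical after any token-wise map
  qc <- project_queries(array(0.7, c(1, 8, 4, 4)), blk)
  tok_spread <- apply(qc, c(1, 2, 4), function(v) diff(range(v)))
  expect_lt(max(tok_spread), 1e-10)
})

test_that("configuration errors are caught", {
  expect_error(msq_block(8, 3), "even")
  expect_error(msq_block(9, 2), "not divisible")
  expect_error(msq_block(8, 2, dropout_rate = 1), "dropout")
})

test_that("multi-scale key/value compression yields M_i = HW / s_i^2 tokens", {
  set.seed(22)
  blk <- msq_block(8, 2)
  x <- rand_arr(1, 8, 32, 32)
  kv <- multiscale_kv(x, blk)
  expect_identical(vapply(kv, function(p) dim(p$K)[3], 0L), c(256L, 64L, 16L))
  expect_identical(dim(kv[[1]]$K), c(1L, 1L, 256L, 4L))
  expect_identical(dim(kv[[3]]$V), c(1L, 1L, 16L, 4L))
  expect_error(multiscale_kv(rand_arr(1, 8, 12, 32), blk), "12")
})

test_that("key/value tokens match the explicit block-sum oracle", {
  set.seed(23)
  blk <- msq_block(4, 2)
  x <- rand_arr(1, 4, 8, 8)
  kv <- multiscale_kv(x, blk)
  xs <- array(x[1, , , ], c(4, 8, 8))
  for (p in 1:3) {
    s <- c(2L, 4L, 8L)[p]
    cv <- blk$children[[paste0("conv", p)]]
    Fi <- naive_convks(xs, cv$par$weight, cv$par$bias, s)
    Hs <- dim(Fi)[2]
    for (m in seq_len(Hs * dim(Fi)[3])) {
      rc <- tok_rc(m, Hs)
      v <- naive_ln(Fi[, rc[1], rc[2]],
                    blk$children[[paste0("ln", p)]]$par$gamma,
                    blk$children[[paste0("ln", p)]]$par$beta)
      v <- v * pnorm(v)
      kvv <- naive_linear(v, blk$children[[paste0("kv", p)]]$par$weight,
                          blk$children[[paste0("kv", p)]]$par$bias)
      expect_equal(as.numeric(kv[[p]]$K[1, 1, m, ]), kvv[1:2], tolerance = 1e-10)
      expect_equal(as.numeric(kv[[p]]$V[1, 1, m, ]), kvv[3:4], tolerance = 1e-10)
    }
  }
})

test_that("value enhancement is a residual depthwise convolution", {
  set.seed(24)
  blk <- msq_block(4, 2)
  v <- rand_arr(1, 1, 16, 2)
  blk$children$dwv1$par$weight[] <- 0
  blk$children$dwv1$par$bias[] <- 0
  expect_equal(enhance_values(v, c(4, 4), blk, 1), v, tolerance = 1e-12)
  expect_identical(dim(enhance_values(v, c(4, 4), blk, 1)), dim(v))
  expect_error(enhance_values(v, c(3, 4), blk, 1), "incompatible")
  # constant value field with an averaging kernel: interior tokens double,
  # boundary tokens gain less because of the zero padding
  blk$children$dwv2$par$weight[] <- 1 / 9
  blk$children$dwv2$par$bias[] <- 0
  vc <- array(1, c(1, 1, 9, 2))
  ve <- enhance_values(vc, c(3, 3), blk, 2)
  grid <- matrix(ve[1, 1, , 1], 3, 3)        # token grid, column-major
  expect_equal(grid[2, 2], 2.0, tolerance = 1e-12)           # interior: 1 + 1
  expect_equal(grid[1, 1], 1 + 4 / 9, tolerance = 1e-12)     # corner
  expect_equal(grid[1, 2], 1 + 6 / 9, tolerance = 1e-12)     # edge
})

test_that("scaled attention normalises rows and matches hand evaluation", {
  set.seed(25)
  # M = 1: weights are all ones, output broadcasts the single value
  q <- rand_arr(1, 2, 5, 3)
  k <- rand_arr(1, 2, 1, 3)
  v <- rand_arr(1, 2, 1, 3)
  sa <- scaled_attention(q, k, v)
  expect_equal(max(abs(sa$weights - 1)), 0, tolerance = 1e-12)
  for (n in 1:5) expect_equal(sa$z[1, , n, ], v[1, , 1, ], tolerance = 1e-12)
  # random case: every row sums to one
  q <- rand_arr(2, 3, 7, 4); k <- rand_arr(2, 3, 5, 4); v <- rand_arr(2, 3, 5, 4)
  sa <- scaled_attention(q, k, v)
  expect_lt(max(abs(apply(sa$weights, 1:3, sum) - 1)), 1e-5)
  # hand case: N = 3, M = 2, d = 1, Q = (0,1,2), K = (0, ln 3), V = (1, 5)
  q <- array(c(0, 1, 2), c(1, 1, 3, 1))
  k <- array(c(0, log(3)), c(1, 1, 2, 1))
  v <- array(c(1, 5), c(1, 1, 2, 1))
  sa <- scaled_attention(q, k, v)
  expect_equal(as.numeric(sa$weights[1, 1, 2, ]), c(1 / 4, 3 / 4),
               tolerance = 1e-12)
  expect_equal(sa$z[1, 1, 2, 1], 4.0, tolerance = 1e-12)
  expect_error(scaled_attention(q, array(0, c(1, 1, 2, 2)), v), "head_dim")
})

test_that("path fusion concatenates to 3C/2 and projects back to C", {
  set.seed(26)
  blk <- msq_block(8, 2)
  expect_identical(dim(blk$children$lin_out$par$weight), c(8L, 12L))
  z <- replicate(3, rand_arr(1, 1, 16, 4), simplify = FALSE)
  blk$children$lin_out$par$weight[] <- 0
  blk$children$lin_out$par$bias[] <- 0
  out <- fuse_paths(z, blk, c(4, 4))
  expect_identical(dim(out), c(1L, 8L, 4L, 4L))
  expect_equal(max(abs(out)), 0)
  z[[2]] <- rand_arr(1, 1, 9, 4)
  expect_error(fuse_paths(z, blk, c(4, 4)), "token-count mismatch")
})

test_that("the full block is residual: zero output projection gives identity", {
  set.seed(27)
  blk <- msq_block(8, 2)
  blk$children$lin_out$par$weight[] <- 0
  blk$children$lin_out$par$bias[] <- 0
  x <- rand_arr(2, 8, 16, 16)
  expect_equal(msqformer_block(x, blk), x, tolerance = 1e-12)
})

test_that("the block matches the dense naive oracle and its score memory is sub-quadratic", {
  set.seed(28)
  for (cfg in list(c(C = 4, h = 2, H = 8, W = 8))) {
    blk <- msq_block(cfg["C"], cfg["h"])
    x <- rand_arr(1, cfg["C"], cfg["H"], cfg["W"])
    got <- msqformer_block(x, blk)
    expect_identical(dim(got), dim(x))
    want <- naive_msq_forward(x, blk)
    expect_lt(max(abs(got - want)), 1e-5)
    N <- cfg["H"] * cfg["W"]
    sp <- blk$cache$score_products
    expect_equal(sum(sp), as.numeric(N * (N / 4 + N / 16 + N / 64)))
    expect_lt(sum(sp), N^2)
  }
})

test_that("single-scale ablation keeps only the stride-2 path", {
  set.seed(29)
  blk <- msq_block(8, 2, single_scale = TRUE)
  expect_identical(dim(blk$children$lin_q$par$weight), c(4L, 8L))
  expect_null(blk$children$conv2)
  x <- rand_arr(1, 8, 8, 8)
  expect_identical(dim(msqformer_block(x, blk)), dim(x))
})

test_that("with token-wise convolutions the block is equivariant to stride-8 circular shifts", {
  set.seed(30)
  blk <- msq_block(4, 2)
  # degenerate configuration: value enhancement reduced to a token-wise map
  for (p in 1:3) {
    dwv <- blk$children[[paste0("dwv", p)]]
    dwv$par$weight[] <- 0
    dwv$par$weight[, 2, 2] <- rnorm(dim(dwv$par$weight)[1])
  }
  x <- rand_arr(1, 4, 16, 16)
  sh <- function(a, s) a[, , c((s + 1):16, 1:s), c((s + 1):16, 1:s), drop = FALSE]
  y <- msqformer_block(x, blk)
  ys <- msqformer_block(sh(x, 8), blk)
  expect_lt(max(abs(ys - sh(y, 8))), 1e-8)
})

test_that("block gradients match finite differences", {
  set.seed(31)
  blk <- msq_block(4, 2)
  xi <- dermseg:::as_chwb(rand_arr(1, 4, 8, 8))
  y <- mod_forward(blk, xi, training = TRUE)
  r <- array(rnorm(length(y)), dim(y))
  zero_grads(blk)
  mod_forward(blk, xi, training = TRUE)
  dx <- mod_backward(blk, r)
  eps <- 1e-5
  for (i in sample(length(xi), 5)) {
    xp <- xi; xp[i] <- xp[i] + eps
    xm <- xi; xm[i] <- xm[i] - eps
    num <- (sum(mod_forward(blk, xp, TRUE) * r) -
              sum(mod_forward(blk, xm, TRUE) * r)) / (2 * eps)
    expect_equal(dx[i], num, tolerance = 1e-4)
  }
})
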