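test_that("the Haar decomposition matches hand-computed coefficients", {
  # constant input: low-pass doubles, high-pass vanishes
  x <- array(3, c(1, 2, 4, 4))
  s <- dwt2(x)
  expect_equal(max(abs(s$ll - 6)), 0, tolerance = 1e-12)
  for (nm in c("lh", "hl", "hh")) expect_equal(max(abs(s[[nm]])), 0)
  # 2x2 block (rows) [[1,2],[3,4]]
  x <- array(0, c(1, 1, 2, 2))
  x[1, 1, 1, ] <- c(1, 2)
  x[1, 1, 2, ] <- c(3, 4)
  s <- dwt2(x)
  expect_equal(as.numeric(s$ll), 5)
  expect_equal(as.numeric(s$hl), -2)
  expect_equal(as.numeric(s$lh), -1)
  # hh = (1 - 2 - 3 + 4)/2; the block is a bilinear ramp with no diagonal
  # component, and energy conservation (25 + 1 + 4 + 0 = 30) confirms it
  expect_equal(as.numeric(s$hh), 0)
  # shapes
  s <- dwt2(rand_arr(2, 8, 64, 64))
  for (nm in names(s)) expect_identical(dim(s[[nm]]), c(2L, 8L, 32L, 32L))
  expect_error(dwt2(rand_arr(1, 1, 5, 4)), "even")
})

test_that("the wavelet transform reconstructs perfectly and conserves energy", {
  set.seed(41)
  for (i in 1:20) {
    x <- rand_arr(1, 3, 8, 8)
    s <- dwt2(x)
    expect_lt(max(abs(idwt2(s) - x)), 1e-5)
    e_sub <- sum(s$ll^2) + sum(s$lh^2) + sum(s$hl^2) + sum(s$hh^2)
    expect_lt(abs(e_sub - sum(x^2)) / sum(x^2), 1e-4)
  }
  z <- lapply(dwt2(rand_arr(1, 1, 4, 4)), function(a) a * 0)
  expect_equal(max(abs(idwt2(z))), 0)
  # ll = 2c alone inverts to the constant c
  cst <- list(ll = array(2 * 1.5, c(1, 1, 2, 2)),
              lh = array(0, c(1, 1, 2, 2)),
              hl = array(0, c(1, 1, 2, 2)),
              hh = array(0, c(1, 1, 2, 2)))
  expect_equal(max(abs(idwt2(cst) - 1.5)), 0, tolerance = 1e-12)
  cst$hh <- array(0, c(1, 1, 3, 2))
  expect_error(idwt2(cst), "shape mismatch")
})

test_that("guidance pooling averages 2x2 neighbourhoods", {
  expect_equal(pool_guidance(array(0.4, c(1, 4, 16, 16))),
               array(0.4, c(1, 4, 8, 8)), tolerance = 1e-12)
  x <- array(0, c(1, 1, 2, 2))
  x[1, 1, , ] <- matrix(c(0, 2, 4, 6), 2, 2)
  expect_equal(as.numeric(pool_guidance(x)), 3)
  expect_error(pool_guidance(rand_arr(1, 1, 5, 4)), "even")
})

test_that("attention gates squash to (0,1) and reproduce the scalar hand case", {
  set.seed(42)
  gate <- dermseg:::warm_gate(3, 2)
  xs <- rand_arr(2, 3, 4, 4)
  g <- rand_arr(2, 3, 4, 4)
  # zeroed psi map: alpha = sigmoid(0) = 0.5 everywhere
  gate$children$wpsi$par$weight[] <- 0
  gate$children$wpsi$par$bias[] <- 0
  out <- attention_gate(xs, g, gate)
  expect_equal(out$refined, 0.5 * xs, tolerance = 1e-12)
  # bounds for arbitrary weights
  gate2 <- dermseg:::warm_gate(3, 2)
  out2 <- attention_gate(xs, g, gate2)
  expect_true(all(out2$alpha > 0 & out2$alpha < 1))
  expect_identical(dim(out2$alpha), c(2L, 1L, 4L, 4L))
  # scalar case: all weights 1, x = g = 1 -> alpha = sigmoid(relu(2))
  gate3 <- dermseg:::warm_gate(1, 1)
  for (nm in c("wx", "wg", "wpsi")) {
    gate3$children[[nm]]$par$weight[] <- 1
    if (!is.null(gate3$children[[nm]]$par$bias)) gate3$children[[nm]]$par$bias[] <- 0
  }
  o3 <- attention_gate(array(1, c(1, 1, 1, 1)), array(1, c(1, 1, 1, 1)), gate3)
  expect_equal(as.numeric(o3$refined), 1 / (1 + exp(-2)), tolerance = 1e-10)
  expect_error(attention_gate(xs, rand_arr(2, 3, 4, 2), gate), "shapes differ")
})

test_that("saturated gates make the module pass-through or annihilating", {
  set.seed(43)
  w <- warm_module(4, 3)
  xe <- rand_arr(1, 4, 8, 8)
  xd <- rand_arr(1, 4, 8, 8)
  for (g in w$children) g$children$wpsi$par$bias[] <- 30
  expect_equal(warm_forward(xe, xd, w), xe, tolerance = 1e-6)
  for (g in w$children) g$children$wpsi$par$bias[] <- -30
  expect_lt(max(abs(warm_forward(xe, xd, w))), 1e-6)
})

test_that("gating never amplifies sub-band magnitudes", {
  set.seed(44)
  w <- warm_module(4, 3)
  xe <- rand_arr(2, 4, 8, 8)
  xd <- rand_arr(2, 4, 8, 8)
  s <- dwt2(xe)
  g <- pool_guidance(xd)
  for (nm in c("ll", "lh", "hl", "hh")) {
    ref <- attention_gate(s[[nm]], g, w$children[[paste0("gate_", nm)]])$refined
    expect_true(all(abs(ref) <= abs(s[[nm]]) + 1e-12))
  }
})

test_that("the composed module matches its sub-operation chain", {
  set.seed(45)
  w <- warm_module(3, 2)
  xe <- rand_arr(1, 3, 8, 8)
  xd <- rand_arr(1, 3, 8, 8)
  got <- warm_forward(xe, xd, w)
  expect_identical(dim(got), dim(xe))
  s <- dwt2(xe)
  g <- pool_guidance(xd)
  ref <- list()
  for (nm in c("ll", "lh", "hl", "hh")) {
    ref[[nm]] <- attention_gate(s[[nm]], g, w$children[[paste0("gate_", nm)]])$refined
  }
  expect_lt(max(abs(got - idwt2(ref))), 1e-10)
  expect_error(warm_forward(xe, rand_arr(1, 3, 8, 4), w), "share shape")
})

test_that("warm gradients match finite differences", {
  set.seed(46)
  w <- warm_module(2, 2)
  xe <- dermseg:::as_chwb(rand_arr(1, 2, 4, 4))
  xd <- dermseg:::as_chwb(rand_arr(1, 2, 4, 4))
  y <- dermseg:::warm_forward_chwb(w, xe, xd, TRUE)
  r <- array(rnorm(length(y)), dim(y))
  zero_grads(w)
  dermseg:::warm_forward_chwb(w, xe, xd, TRUE)
  gb <- dermseg:::warm_backward_chwb(w, r)
  eps <- 1e-5
  for (i in sample(length(xe), 4)) {
    xp <- xe; xp[i] <- xp[i] + eps
    xm <- xe; xm[i] <- xm[i] - eps
    num <- (sum(dermseg:::warm_forward_chwb(w, xp, xd, TRUE) * r) -
              sum(dermseg:::warm_forward_chwb(w, xm, xd, TRUE) * r)) / (2 * eps)
    expect_equal(gb$dx_enc[i], num, tolerance = 1e-4)
  }
  for (i in sample(length(xd), 4)) {
    xp <- xd; xp[i] <- xp[i] + eps
    xm <- xd; xm[i] <- xm[i] - eps
    num <- (sum(dermseg:::warm_forward_chwb(w, xe, xp, TRUE) * r) -
              sum(dermseg:::warm_forward_chwb(w, xe, xm, TRUE) * r)) / (2 * eps)
    expect_equal(gb$dx_dec[i], num, tolerance = 1e-4)
  }
})
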