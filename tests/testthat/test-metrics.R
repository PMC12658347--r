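test_that("confusion counts are exact", {
  g <- matrix(0L, 10, 10); g[3:6, 3:6] <- 1L
  c1 <- confusion(g, g)
  expect_identical(c(c1$TP, c1$TN, c1$FP, c1$FN), c(16L, 84L, 0L, 0L))
  c2 <- confusion(1L - g, g)
  expect_identical(c(c2$TP, c2$TN), c(0L, 0L))
  # shifted squares: compare against an explicit pixel loop
  p <- matrix(0L, 10, 10); p[5:8, 5:8] <- 1L
  c3 <- confusion(p, g)
  tp <- tn <- fp <- fn <- 0L
  for (i in 1:10) for (j in 1:10) {
    if (p[i, j] == 1 && g[i, j] == 1) tp <- tp + 1L
    if (p[i, j] == 0 && g[i, j] == 0) tn <- tn + 1L
    if (p[i, j] == 1 && g[i, j] == 0) fp <- fp + 1L
    if (p[i, j] == 0 && g[i, j] == 1) fn <- fn + 1L
  }
  expect_identical(c(c3$TP, c3$TN, c3$FP, c3$FN), c(tp, tn, fp, fn))
  expect_error(confusion(p, g[1:5, ]), "shapes differ")
  expect_error(confusion(p * 2L, g), "only 0 and 1")
})

make_conf <- function(TP, TN, FP, FN) {
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN, k = 1L),
            class = "dermseg_confusion")
}

test_that("rate metrics reproduce hand-computed contingency values exactly", {
  # perfect prediction
  m <- compute_metrics(make_conf(10, 90, 0, 0))
  for (nm in c("mIoU", "DSC", "Acc", "Sen", "Spe")) expect_equal(m[[nm]], 1)
  # the worked four-count example
  m <- compute_metrics(make_conf(6, 90, 2, 2))
  expect_equal(m$DSC, 12 / 16)
  expect_equal(m$mIoU, (6 / 10 + 90 / 94) / 2)
  expect_equal(m$Acc, 0.96)
  expect_equal(m$Sen, 0.75)
  expect_equal(m$Spe, 90 / 92)
  # complement prediction: everything collapses to zero
  m <- compute_metrics(make_conf(0, 0, 90, 10))
  for (nm in c("mIoU", "DSC", "Acc", "Sen", "Spe")) expect_equal(m[[nm]], 0)
  # both masks empty: absent-class convention gives ones
  m <- compute_metrics(make_conf(0, 100, 0, 0))
  for (nm in c("mIoU", "DSC", "Sen", "Spe")) expect_equal(m[[nm]], 1)
  # empty prediction, non-empty truth
  m <- compute_metrics(make_conf(0, 90, 0, 10))
  expect_equal(m$Sen, 0); expect_equal(m$DSC, 0)
  expect_equal(m$mIoU, 0.45); expect_equal(m$Spe, 1)
  # all-lesion prediction over a 40% lesion
  m <- compute_metrics(make_conf(40, 0, 60, 0))
  expect_equal(m$DSC, 80 / 140)
  expect_equal(m$mIoU, 0.2)
  expect_equal(m$Sen, 1); expect_equal(m$Spe, 0); expect_equal(m$Acc, 0.4)
})

test_that("metrics agree with a per-pixel re-derivation on random masks", {
  set.seed(61)
  for (i in 1:100) {
    p <- matrix(rbinom(144, 1, 0.4), 12, 12)
    g <- matrix(rbinom(144, 1, 0.4), 12, 12)
    m <- compute_metrics(confusion(p, g))
    tp <- sum(p * g); fp <- sum(p * (1 - g))
    fn <- sum((1 - p) * g); tn <- sum((1 - p) * (1 - g))
    expect_identical(m$confusion$TP, as.integer(tp))
    if (tp + fp + fn > 0) {
      expect_equal(m$DSC, 2 * tp / (2 * tp + fp + fn))
      expect_equal(m$mIoU, (tp / (tp + fp + fn) + tn / (tn + fp + fn)) / 2)
    }
  }
})

test_that("growing false positives never improves the rate metrics", {
  base <- compute_metrics(make_conf(30, 60, 5, 5))
  worse <- compute_metrics(make_conf(30, 55, 10, 5))
  for (nm in c("Spe", "Acc", "DSC", "mIoU")) expect_lte(worse[[nm]], base[[nm]])
  # and DSC always dominates the lesion IoU
  for (cfg in list(c(6, 90, 2, 2), c(30, 60, 5, 5), c(1, 9, 3, 2))) {
    m <- compute_metrics(do.call(make_conf, as.list(cfg)))
    iou_fg <- cfg[1] / (cfg[1] + cfg[3] + cfg[4])
    expect_gte(m$DSC, iou_fg)
  }
})

test_that("hd95 matches trivial cases, the brute-force oracle, and is symmetric", {
  g <- matrix(0L, 20, 20); g[6:12, 6:12] <- 1L
  expect_equal(hd95(g, g), 0)
  a <- matrix(0L, 20, 20); a[3, 4] <- 1L
  b <- matrix(0L, 20, 20); b[3, 9] <- 1L
  expect_equal(hd95(a, b), 5)
  # square versus its 1-pixel dilation
  d <- matrix(0L, 20, 20); d[5:13, 5:13] <- 1L
  expect_equal(hd95(g, d), naive_hd95(g, d))
  expect_equal(hd95(d, g), hd95(g, d))
  set.seed(62)
  for (i in 1:5) {
    p <- matrix(0L, 20, 20)
    q <- matrix(0L, 20, 20)
    p[sample(400, 30)] <- 1L
    q[sample(400, 30)] <- 1L
    expect_equal(hd95(p, q), naive_hd95(p, q))
    expect_equal(hd95(p, q), hd95(q, p))
  }
  # empty-mask policies
  e <- matrix(0L, 20, 20)
  expect_equal(hd95(e, e), 0)
  expect_equal(hd95(e, g), sqrt(2) * 20)       # image-diagonal sentinel
})

test_that("the combined loss matches hand evaluation and has finite gradients", {
  # perfect-fit limit
  g <- matrix(c(1, 0, 1, 0), 2, 2)
  z <- (2 * g - 1) * 40
  expect_lt(combined_loss(z, g), 1e-10)
  # zero logits, two pixels with half the mask on
  g2 <- matrix(c(1, 0), 1, 2)
  l <- combined_loss(matrix(0, 1, 2), g2)
  expect_equal(l, log(2) + (1 - (2 * 0.5 + 1) / (1 + 1 + 1)), tolerance = 1e-12)
  expect_equal(l, log(2) + 1 / 3, tolerance = 1e-12)
  # smoothness and gradient correctness on random logits
  set.seed(63)
  z <- matrix(runif(36, -10, 10), 6, 6)
  gm <- matrix(rbinom(36, 1, 0.5), 6, 6)
  expect_true(is.finite(combined_loss(z, gm)))
  gr <- dermseg:::combined_loss_grad(z, gm)
  expect_true(all(is.finite(gr)))
  eps <- 1e-6
  for (i in sample(36, 5)) {
    zp <- z; zp[i] <- zp[i] + eps
    zm <- z; zm[i] <- zm[i] - eps
    num <- (combined_loss(zp, gm) - combined_loss(zm, gm)) / (2 * eps)
    expect_equal(gr[i], num, tolerance = 1e-5)
  }
  expect_error(combined_loss(z, gm * 3), "only 0 and 1")
})
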