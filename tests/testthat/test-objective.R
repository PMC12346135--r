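# Loss functions and the polynomial learning-rate schedule.

onehot_probs <- function(mask, K) {
  p <- array(0, c(dim(mask), K, 1))
  for (c in seq_len(K)) p[, , c, 1] <- mask == (c - 1L)
  p
}

test_that("dice loss vanishes for one-hot perfect predictions", {
  set.seed(1)
  mask <- matrix(sample(0:2, 36, replace = TRUE), 6, 6)
  p <- onehot_probs(mask, 3L)
  expect_lt(dice_loss(p, mask), 1e-5)
  # all-background with matching one-hot: smoothing keeps empty classes at 0/0 -> 1
  bg <- matrix(0L, 4, 4)
  expect_lt(dice_loss(onehot_probs(bg, 2L), bg), 1e-5)
})

test_that("dice loss of a uniform prediction matches the hand-derived form", {
  mask <- matrix(c(0, 0, 1, 1,
                   0, 1, 1, 0,
                   0, 0, 0, 1,
                   1, 0, 0, 0), 4, 4, byrow = TRUE)
  p <- array(0.5, c(4, 4, 2, 1))
  # per class: (2 * 0.5 * |t_c| + s) / (0.5 * N + |t_c| + s), N = 16
  s <- 1e-5
  n1 <- sum(mask == 1)
  expected <- 1 - mean(c((2 * 0.5 * (16 - n1) + s) / (8 + (16 - n1) + s),
                         (2 * 0.5 * n1 + s) / (8 + n1 + s)))
  expect_equal(dice_loss(p, mask), expected, tolerance = 1e-12)
})

test_that("dice loss is symmetric under joint class relabeling", {
  set.seed(2)
  mask <- matrix(sample(0:2, 64, replace = TRUE), 8, 8)
  p <- array(runif(8 * 8 * 3), c(8, 8, 3, 1))
  tot <- p[, , 1, ] + p[, , 2, ] + p[, , 3, ]
  for (c in 1:3) p[, , c, 1] <- p[, , c, 1] / tot
  perm <- c(2L, 0L, 1L)  # class relabeling 0->2, 1->0, 2->1
  mask_p <- matrix(perm[mask + 1L], 8, 8)
  p_p <- p[, , order(perm) , , drop = FALSE]
  expect_equal(dice_loss(p, mask), dice_loss(p_p, mask_p), tolerance = 1e-12)
})

test_that("cross-entropy hits its closed forms", {
  mask <- matrix(sample(0:3, 16, replace = TRUE), 4, 4)
  # near-perfect logits -> ~0
  z <- array(-50, c(4, 4, 4, 1))
  for (c in 1:4) z[, , c, 1][mask == c - 1] <- 50
  expect_lt(cross_entropy_loss(z, mask), 1e-8)
  # uniform logits over K=4 -> ln 4 per pixel
  expect_equal(cross_entropy_loss(array(0, c(4, 4, 4, 1)), mask), log(4),
               tolerance = 1e-12)
  # one pixel with probability 0.25 on its class -> -ln 0.25
  p <- array(c(0.25, 0.3, 0.25, 0.2), c(1, 1, 4, 1))
  expect_equal(cross_entropy_loss(p, matrix(0L, 1, 1), from_logits = FALSE),
               -log(0.25), tolerance = 1e-12)
  expect_error(cross_entropy_loss(z, mask + 10L), "out of range")
})

test_that("combined loss is lambda * dice + cross-entropy", {
  set.seed(3)
  mask <- matrix(sample(0:1, 64, replace = TRUE), 8, 8)
  z <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1))
  p <- sonoseg:::ad_softmax_c(NULL, z)
  d <- dice_loss(p, mask)
  ce <- cross_entropy_loss(z, mask)
  expect_equal(combined_loss(z, mask, loss_config(lambda_dice = 0.5)),
               0.5 * d + ce, tolerance = 1e-12)
  # lambda = 0 degenerates to cross-entropy alone
  expect_equal(combined_loss(z, mask, loss_config(lambda_dice = 0)), ce,
               tolerance = 1e-12)
  # perfect prediction -> ~0
  zp <- array(-50, c(8, 8, 2, 1))
  for (c in 1:2) zp[, , c, 1][mask == c - 1] <- 50
  expect_lt(combined_loss(zp, mask), 1e-5)
})

test_that("combined-loss gradient matches central differences on a toy case", {
  set.seed(4)
  mask <- matrix(sample(0:1, 16, replace = TRUE), 4, 4)
  z <- array(rnorm(4 * 4 * 2, sd = 0.5), c(4, 4, 2, 1))
  ctx <- sonoseg:::new_ctx(TRUE)
  zn <- sonoseg:::.nd(ctx, z)
  L <- sonoseg:::ad_seg_loss(ctx, zn, array(mask, c(4, 4, 1)))
  sonoseg:::run_backward(ctx, L$total)
  g <- zn$grad
  f <- function(zz) combined_loss(zz, mask)
  eps <- 1e-5
  for (i in sample(length(z), 8)) {
    zp <- z; zp[i] <- zp[i] + eps
    zm <- z; zm[i] <- zm[i] - eps
    num <- (f(zp) - f(zm)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-4)
  }
})

test_that("model parameter gradients match central differences", {
  # end-to-end check through conv, batch-norm, pooling, attention and the
  # transposed conv on a tiny network; 32x32 input keeps the bottleneck at
  # 2x2 so no batch-norm reduces over a single element (which would park
  # activations exactly on the ReLU kink)
  m <- build_model(tiny_config(), seed = 8)
  set.seed(81)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  tg <- array(sample(0:1, 32 * 32, replace = TRUE), c(32, 32, 1))
  # finite differences must probe the same function the tape records, i.e.
  # the training-mode forward (batch-norm on batch statistics)
  loss_at <- function() {
    ctx <- sonoseg:::new_ctx(TRUE)
    z <- sonoseg:::net_forward(ctx, m, x, logits = TRUE)
    sonoseg:::ad_seg_loss(ctx, z, tg)$value
  }
  ctx <- sonoseg:::new_ctx(TRUE)
  z <- sonoseg:::net_forward(ctx, m, x, logits = TRUE)
  L <- sonoseg:::ad_seg_loss(ctx, z, tg)
  sonoseg:::run_backward(ctx, L$total)
  ps <- model_parameters(m)
  eps <- 1e-5
  set.seed(82)
  picks <- sample(names(ps), 6)
  for (nm in picks) {
    p <- ps[[nm]]
    i <- sample(length(p$value), 1)
    v0 <- p$value[i]
    p$value[i] <- v0 + eps; fp <- loss_at()
    p$value[i] <- v0 - eps; fm <- loss_at()
    p$value[i] <- v0
    num <- (fp - fm) / (2 * eps)
    expect_equal(p$grad[i], num, tolerance = 5e-3)
  }
})

test_that("polynomial decay matches its closed form and is monotone", {
  expect_identical(poly_lr(schedule_state(iter = 0L)), 0.01)
  expect_identical(poly_lr(schedule_state(iter = 30000L)), 0)
  expect_equal(poly_lr(schedule_state(iter = 15000L)), 0.01 * 0.5^0.9,
               tolerance = 1e-12)
  expect_equal(poly_lr(schedule_state(iter = 15000L)), 0.0053588673, tolerance = 1e-8)
  lrs <- vapply(seq(0, 30000, by = 500), function(tc) poly_lr(schedule_state(iter = tc)),
                numeric(1))
  expect_true(all(diff(lrs) < 0))
  expect_error(poly_lr(schedule_state(iter = 30001L)), "max_iter")
})
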