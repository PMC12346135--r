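# Building-block contracts: shapes, channel bookkeeping, closed-form
# degenerate cases and gate/attention properties.

set_zero_weights <- function(m) {
  for (p in module_parameters(m)) p$value[] <- 0
  invisible(m)
}

test_that("stem block lifts channels to the base width and preserves space", {
  set.seed(1)
  stem <- with_seed(1, stem_block(1L, 16L))
  x <- array(runif(48 * 40), c(48, 40, 1, 1))
  y <- block_forward(stem, x)
  expect_identical(dim(y), c(48L, 40L, 16L, 1L))
  expect_true(all(is.finite(y)))
  # four conv units, as declared
  expect_length(stem$children, 4L)
  expect_true(all(vapply(stem$children, function(u) u$kind == "cba", logical(1))))
  # all-zero input through fresh batch-norm stays finite
  y0 <- block_forward(stem, array(0, c(32, 32, 1, 1)))
  expect_true(all(is.finite(y0)))
})

test_that("stem parameter count matches the closed-form layer formula", {
  stem <- with_seed(1, stem_block(1L, 16L))
  # per conv: k^2 * cin * cout weights + cout biases; per norm: 2 * cout
  cin <- c(1, 16, 16, 16)
  expected <- sum(9 * cin * 16 + 16 + 2 * 16)
  expect_identical(count_parameters(stem), expected)
})

test_that("encoder block doubles channels at every width", {
  for (C in c(8L, 32L)) {
    blk <- with_seed(2, encoder_block(C, groups = 4L))
    x <- array(rnorm(12 * 12 * C), c(12, 12, C, 1))
    y <- block_forward(blk, x)
    expect_identical(dim(y), c(12L, 12L, 2L * C, 1L))
  }
  expect_error(encoder_block(6L, groups = 4L), "divisible")
})

test_that("zero-weight conv blocks give spatially constant outputs", {
  blk <- with_seed(3, encoder_block(8L, groups = 4L))
  set_zero_weights(blk)
  # restore batch-norm scale so the (constant) biases pass through
  for (u in blk$children) u$children$bn$params$gamma$value[] <- 1
  x <- array(rnorm(10 * 10 * 8), c(10, 10, 8, 1))
  y <- block_forward(blk, x)
  for (c in seq_len(dim(y)[3])) {
    expect_lt(diff(range(y[, , c, 1])), 1e-12)
  }
})

test_that("2x2 max pooling halves space and matches the tile-wise oracle", {
  set.seed(4)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3, 1))
  y <- downsample(x)
  expect_identical(dim(y), c(4L, 4L, 3L, 1L))
  for (c in 1:3) expect_equal(y[, , c, 1], bf_pool2(x[, , c, 1]))
  # constant input -> constant output of the same value
  expect_true(all(downsample(array(2.5, c(6, 6, 1, 1))) == 2.5))
  expect_error(downsample(array(0, c(5, 6, 1, 1))), "even")
})

test_that("transposed-conv upsampling doubles space, halves channels", {
  up <- with_seed(5, upsample_halve(32L))
  x <- array(rnorm(8 * 8 * 32), c(8, 8, 32, 1))
  y <- block_forward(up, x)
  expect_identical(dim(y), c(16L, 16L, 16L, 1L))
  expect_error(upsample_halve(7L), "even")
})

test_that("transposed conv matches a hand-rolled oracle on a tiny grid", {
  up <- upsample_halve(2L)
  # constant kernel 1/4, zero bias, 2x2 input
  up$children$up$params$w$value[] <- 0.25
  up$children$up$params$b$value[] <- 0
  x <- array(c(1, 2, 3, 4, 5, 6, 7, 8), c(2, 2, 2, 1))
  y <- block_forward(up, x)
  # each output 2x2 tile is input * 0.25 summed over the 2 input channels
  ref <- matrix(0, 4, 4)
  for (i in 1:2) for (j in 1:2) {
    ref[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)] <- 0.25 * (x[i, j, 1, 1] + x[i, j, 2, 1])
  }
  expect_equal(y[, , 1, 1], ref, tolerance = 1e-12)
  # constant input maps to constant output
  yc <- block_forward(up, array(3, c(4, 4, 2, 1)))
  expect_lt(diff(range(yc)), 1e-12)
})

test_that("pixel attention gate matches channels and strictly contracts", {
  gate <- with_seed(6, pixel_attention(8L, 3L))
  X <- array(rnorm(16 * 16 * 8), c(16, 16, 8, 1))
  Y <- array(rnorm(16 * 16 * 3), c(16, 16, 3, 1))
  out <- block_forward(gate, X, Y)
  expect_identical(dim(out), dim(X))
  # gate in (0,1): |out| <= |X| with strict inequality off zeros
  for (rep in 1:20) {
    g2 <- with_seed(rep, pixel_attention(4L, 2L))
    X2 <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
    Y2 <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1))
    o2 <- block_forward(g2, X2, Y2)
    expect_true(all(abs(o2) <= abs(X2)))
    expect_true(all(abs(o2)[X2 != 0] < abs(X2)[X2 != 0]))
  }
  expect_error(block_forward(gate, X, array(0, c(8, 8, 3, 1))), "spatial")
})

test_that("pixel attention saturates to 0 or X at extreme gate bias", {
  gate <- with_seed(7, pixel_attention(4L, 4L))
  X <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  Y <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  gate$children$a3$children$bn$params$beta$value[] <- -50
  expect_equal(max(abs(block_forward(gate, X, Y))), 0, tolerance = 1e-15)
  gate$children$a3$children$bn$params$beta$value[] <- 50
  expect_equal(block_forward(gate, X, Y), X, tolerance = 1e-12)
})

test_that("bottleneck attention is width-neutral and expands branches 3x", {
  C <- 16L
  attn <- with_seed(8, branch_attention(C, heads = 4L))
  x <- array(rnorm(8 * 8 * C), c(8, 8, C, 1))
  y <- block_forward(attn, x)
  expect_identical(dim(y), dim(x))
  for (b in c("b1", "b2", "b3")) {
    expect_identical(attn$children[[b]]$cout, 3L * C)
  }
  expect_identical(attn$children$fuse$cin, 3L * C)
  expect_error(branch_attention(6L, heads = 4L), "divisible")
})

test_that("attention weight rows sum to 1 for every head and branch", {
  attn <- with_seed(9, branch_attention(8L, heads = 4L))
  x <- array(rnorm(4 * 4 * 8), c(4, 4, 8, 1))
  ws <- attention_weights(attn, x)
  expect_length(ws, 3L)
  for (branch in ws) for (A in branch) {
    expect_true(all(A >= 0))
    expect_equal(unname(rowSums(A)), rep(1, nrow(A)), tolerance = 1e-12)
  }
})

test_that("single-token attention reduces to the V pass-through closed form", {
  C <- 8L
  attn <- with_seed(10, branch_attention(C, heads = 4L))
  x <- array(rnorm(C), c(1, 1, C, 1))
  y <- block_forward(attn, x)
  # with one token the softmax weight is 1, so each branch returns its V
  # slice; the block is conv -> split -> take V -> concat -> 1x1 conv
  cat3 <- array(0, c(1, 1, 3 * C, 1))
  for (i in 1:3) {
    conv <- attn$children[[c("b1", "b2", "b3")[i]]]
    qkv <- sonoseg:::ad_conv2d(NULL, x, conv)
    cat3[, , (i - 1) * C + seq_len(C), ] <- qkv[, , 2 * C + seq_len(C), , drop = FALSE]
  }
  ref <- sonoseg:::ad_conv2d(NULL, cat3, attn$children$fuse)
  expect_equal(y, ref, tolerance = 1e-12)
})

test_that("segmentation head emits a per-pixel probability simplex", {
  head <- with_seed(11, segmentation_head(16L, 4L))
  x <- array(rnorm(32 * 32 * 16), c(32, 32, 16, 1))
  p <- block_forward(head, x)
  expect_identical(dim(p), c(32L, 32L, 4L, 1L))
  expect_true(all(p >= 0))
  expect_equal(apply(p, c(1, 2, 4), sum), array(1, c(32, 32, 1)), tolerance = 1e-10)
  # zero weights -> uniform 1/K
  set_zero_weights(head)
  p0 <- block_forward(head, x)
  expect_equal(max(abs(p0 - 0.25)), 0, tolerance = 1e-12)
})
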