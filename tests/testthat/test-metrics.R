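# Evaluation metrics against hand-computed values and brute-force oracles.

test_that("DSC and IOU match hand-counted toy masks and conventions", {
  A <- matrix(FALSE, 3, 4); A[1, 1:2] <- TRUE
  B <- matrix(FALSE, 3, 4); B[1, 2:3] <- TRUE
  expect_equal(dsc(A, B), 0.5)            # 2*1 / (2+2)
  expect_equal(iou(A, B), 1 / 3)          # 1 / 3
  expect_equal(dsc(A, A), 1)
  expect_equal(iou(A, A), 1)
  D <- matrix(FALSE, 3, 4); D[3, 4] <- TRUE
  expect_equal(dsc(A, D), 0)
  # empty-mask conventions
  E <- matrix(FALSE, 3, 4)
  expect_equal(dsc(E, E), 1)
  expect_equal(iou(E, E), 1)
  expect_equal(dsc(A, E), 0)
})

test_that("IOU = DSC / (2 - DSC) identically", {
  set.seed(1)
  for (i in 1:50) {
    A <- random_mask(12)
    B <- random_mask(12)
    d <- dsc(A, B)
    expect_equal(iou(A, B), d / (2 - d), tolerance = 1e-12)
  }
})

test_that("surface pixels follow the 4-neighbor boundary definition", {
  M <- matrix(FALSE, 5, 5); M[3, 3] <- TRUE
  expect_equal(surface_pixels(M), which(M, arr.ind = TRUE))
  # filled 3x3 square: 8 border pixels, center excluded
  S <- matrix(FALSE, 5, 5); S[2:4, 2:4] <- TRUE
  sp <- surface_pixels(S)
  expect_equal(nrow(sp), 8)
  expect_false(any(sp[, 1] == 3 & sp[, 2] == 3))
  # 1-pixel line: every pixel is surface
  L <- matrix(FALSE, 5, 5); L[2, ] <- TRUE
  expect_equal(nrow(surface_pixels(L)), 5)
  # mask touching the array border is surface there
  Fl <- matrix(TRUE, 3, 3)
  expect_equal(nrow(surface_pixels(Fl)), 8)
  expect_error(surface_pixels(matrix(FALSE, 3, 3)), "empty")
})

test_that("HD95 reproduces the 3-4-5 triangle in both modes", {
  A <- matrix(FALSE, 6, 6); A[1, 1] <- TRUE
  B <- matrix(FALSE, 6, 6); B[4, 5] <- TRUE   # offset (3, 4): distance 5
  expect_equal(hd95(A, B, mode = "literal"), 4.75)
  expect_equal(hd95(A, B, mode = "percentile"), 5)
  expect_equal(hd95(A, A), 0)
  expect_equal(hd95(A, A, mode = "literal"), 0)
})

test_that("ASD matches the two-pixel hand computation", {
  A <- matrix(FALSE, 3, 4); A[1, 1] <- TRUE
  B <- matrix(FALSE, 3, 4); B[1, 3] <- TRUE
  expect_equal(asd(A, B), 2)               # (2 + 2) / (1 + 1)
  expect_equal(asd(A, A), 0)
})

test_that("distance metrics agree with the brute-force pairwise oracle", {
  set.seed(2)
  for (i in 1:25) {
    A <- random_mask(sample(8:32, 1))
    B <- random_mask(nrow(A))
    expect_equal(hd95(A, B), bf_hd95(A, B), tolerance = 1e-9)
    expect_equal(asd(A, B), bf_asd(A, B), tolerance = 1e-9)
  }
})

test_that("metrics are symmetric, translation invariant and spacing-aware", {
  set.seed(3)
  for (i in 1:10) {
    A <- random_mask(16); B <- random_mask(16)
    expect_equal(dsc(A, B), dsc(B, A))
    expect_equal(iou(A, B), iou(B, A))
    expect_equal(hd95(A, B), hd95(B, A), tolerance = 1e-12)
    expect_equal(asd(A, B), asd(B, A), tolerance = 1e-12)
  }
  # joint translation leaves all four unchanged
  A <- matrix(FALSE, 20, 20); A[4:7, 5:9] <- TRUE
  B <- matrix(FALSE, 20, 20); B[5:9, 6:8] <- TRUE
  sh <- function(M, dy, dx) {
    out <- matrix(FALSE, nrow(M), ncol(M))
    idx <- which(M, arr.ind = TRUE)
    out[cbind(idx[, 1] + dy, idx[, 2] + dx)] <- TRUE
    out
  }
  for (f in list(dsc, iou, hd95, asd)) {
    expect_equal(f(sh(A, 3, 2), sh(B, 3, 2)), f(A, B), tolerance = 1e-12)
  }
  # spacing scales distance metrics linearly, overlap metrics not at all
  s <- 2.5
  expect_equal(hd95(A, B, spacing = c(s, s)), s * hd95(A, B), tolerance = 1e-12)
  expect_equal(asd(A, B, spacing = c(s, s)), s * asd(A, B), tolerance = 1e-12)
  # anisotropic spacing against the oracle
  expect_equal(asd(A, B, spacing = c(0.5, 2)), bf_asd(A, B, c(0.5, 2)),
               tolerance = 1e-9)
})

test_that("evaluate_case reproduces the frozen 8x8 toy-pair values", {
  # pred: 3x3 square at rows/cols 2..4; truth: same square shifted by (1,1);
  # expected values computed by independent enumeration and frozen
  pred <- matrix(0L, 8, 8); pred[2:4, 2:4] <- 1L
  truth <- matrix(0L, 8, 8); truth[3:5, 3:5] <- 1L
  r <- evaluate_case(pred, truth)
  expect_equal(r$dsc_pct, 100 * 8 / 18, tolerance = 1e-9)
  expect_equal(r$iou_pct, 100 * 4 / 14, tolerance = 1e-9)
  expect_equal(r$hd95, sqrt(2), tolerance = 1e-9)
  expect_equal(r$asd, 0.80177669, tolerance = 1e-7)
  expect_false(r$undefined)
})

test_that("evaluate_case handles multi-class maps and empty classes", {
  set.seed(4)
  truth <- matrix(0L, 16, 16)
  truth[3:8, 3:8] <- 1L; truth[10:14, 10:14] <- 2L; truth[2, 12:15] <- 3L
  r <- evaluate_case(truth, truth)
  expect_equal(r$dsc_pct, rep(100, 3))
  expect_equal(r$iou_pct, rep(100, 3))
  expect_equal(r$hd95, rep(0, 3))
  expect_equal(r$asd, rep(0, 3))
  # truth lacks class 2, prediction has it: distances undefined, DSC 0
  truth2 <- truth; truth2[truth2 == 2L] <- 0L
  r2 <- evaluate_case(truth, truth2, classes = 1:3)
  expect_true(r2$undefined[r2$class == 2])
  expect_true(is.na(r2$hd95[r2$class == 2]))
  expect_equal(r2$dsc_pct[r2$class == 2], 0)
  # IOU <= DSC row-wise where defined
  expect_true(all(r2$iou_pct <= r2$dsc_pct + 1e-9))
})

test_that("evaluate_cases summarizes with exclusion counts and violin layout", {
  pred <- matrix(0L, 8, 8); pred[2:4, 2:4] <- 1L
  truth <- matrix(0L, 8, 8); truth[3:5, 3:5] <- 1L
  empty <- matrix(0L, 8, 8)
  rp <- evaluate_cases(list(pred, empty), list(truth, truth), classes = 1L)
  expect_equal(nrow(rp$per_case), 2)
  expect_equal(rp$summary$n_excluded, 1)
  expect_equal(rp$summary$hd95, sqrt(2), tolerance = 1e-9)  # defined case only
  v <- violin_data(rp$per_case, method = "ours")
  expect_equal(nrow(v), 8)
  expect_setequal(unique(v$metric), c("dsc_pct", "iou_pct", "hd95", "asd"))
})

test_that("paired t-test follows the textbook formula and the conventions", {
  set.seed(5)
  x <- rnorm(10, 1, 0.3)
  d <- rnorm(10, 0.5, 1)
  y <- x - d
  tstat <- mean(d) / (sd(d) / sqrt(10))
  p_oracle <- 2 * pt(-abs(tstat), df = 9)
  expect_equal(paired_ttest(x, y), p_oracle, tolerance = 1e-9)
  expect_equal(paired_ttest(x, x), 1)
  expect_error(paired_ttest(x, x + 1), "constant")
})

test_that("masks round-trip through PNG exactly", {
  set.seed(6)
  m <- matrix(sample(0:3, 64 * 64, replace = TRUE), 64, 64)
  path <- tempfile(fileext = ".png")
  write_mask_png(m, path)
  expect_identical(read_mask_png(path), m)
})
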