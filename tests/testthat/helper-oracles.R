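# Independent brute-force oracles used to cross-check the optimized paths.
# These deliberately avoid the package's own implementations.

# tile-wise 2x2 max pooling by direct enumeration
bf_pool2 <- function(m) {
  H <- nrow(m) / 2; W <- ncol(m) / 2
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    out[i, j] <- max(m[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  }
  out
}

# surface pixels by per-pixel neighbor enumeration
bf_surface <- function(M) {
  H <- nrow(M); W <- ncol(M)
  out <- NULL
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!M[i, j]) next
    nb <- c(if (i > 1) M[i - 1, j] else FALSE,
            if (i < H) M[i + 1, j] else FALSE,
            if (j > 1) M[i, j - 1] else FALSE,
            if (j < W) M[i, j + 1] else FALSE)
    if (i == 1 || i == H || j == 1 || j == W || !all(nb)) out <- rbind(out, c(i, j))
  }
  out
}

bf_directed_dists <- function(P, Q, spacing = c(1, 1)) {
  apply(P, 1, function(p) {
    min(sqrt(((Q[, 1] - p[1]) * spacing[1])^2 + ((Q[, 2] - p[2]) * spacing[2])^2))
  })
}

bf_hd95 <- function(A, B, spacing = c(1, 1)) {
  SA <- bf_surface(A); SB <- bf_surface(B)
  d <- c(bf_directed_dists(SA, SB, spacing), bf_directed_dists(SB, SA, spacing))
  unname(quantile(d, 0.95, type = 7))
}

bf_asd <- function(A, B, spacing = c(1, 1)) {
  SA <- bf_surface(A); SB <- bf_surface(B)
  dab <- bf_directed_dists(SA, SB, spacing)
  dba <- bf_directed_dists(SB, SA, spacing)
  (sum(dab) + sum(dba)) / (length(dab) + length(dba))
}

# random blob-ish binary mask with at least one pixel
random_mask <- function(n = 16, p = 0.2) {
  m <- matrix(runif(n * n) < p, n, n)
  if (!any(m)) m[sample(n, 1), sample(n, 1)] <- TRUE
  m
}

# small-width model configuration used throughout the tests
tiny_config <- function(num_classes = 2, ...) {
  model_config(base_channels = 4L, num_classes = num_classes, ...)
}

# in-memory phantom samples for training tests
phantom_samples <- function(n, size = 64, seed = 100, task = "capsule") {
  sp <- phantom_spec(size = size, seed = seed, task = task)
  lapply(seq_len(n), function(i) {
    spi <- sp
    spi$seed <- sp$seed + i - 1L
    s <- generate_phantom(spi)
    list(image = s$image, mask = s$mask)
  })
}

# Make every convolution kernel left-right symmetric in place (the column
# axis of (k, k, cin_g, cout) conv weights and (2, 2, cout, cin) transposed
# conv weights), so the network becomes exactly flip-equivariant.
symmetrize_kernels <- function(model) {
  ps <- model_parameters(model)
  for (nm in names(ps)) {
    p <- ps[[nm]]
    d <- dim(p$value)
    if (length(d) == 4L) {
      p$value <- (p$value + p$value[, d[2]:1, , , drop = FALSE]) / 2
    }
  }
  invisible(model)
}
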