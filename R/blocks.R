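# Network building blocks.
#
# All blocks preserve spatial size (every convolution uses zero "same"
# padding); only downsample() and the transposed-convolution upsampler change
# it.  Feature maps are channel-last arrays (H, W, C, N); a matrix or an
# (H, W, C) array is promoted to a single-image batch.

#' Promote an image or feature map to a 4-D (H, W, C, N) array
#'
#' @param x matrix (H, W), array (H, W, C) or array (H, W, C, N)
#' @return 4-D numeric array
#' @export
as_feature_map <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  else if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  else if (length(dim(x)) != 4L) stop("expected a 2-D image or a 3-D/4-D feature map")
  if (!all(is.finite(x))) stop("feature map contains non-finite values")
  x
}

#' Stem convolution block
#'
#' Four (3x3 convolution, batch-norm, ReLU) units; the first maps the input
#' channels to `base_channels`, the remaining three operate at
#' `base_channels`.  Used at the top encoder stage to lift a 1-channel image
#' to the network width.
#'
#' @param in_channels input channel count (1 for grayscale)
#' @param base_channels output width of the block
#' @return a module; apply it with [block_forward()]
#' @export
stem_block <- function(in_channels = 1L, base_channels = 16L) {
  m <- new_module("stem", cin = in_channels, cout = base_channels)
  m$children <- list(
    c1 = conv_bn_act(in_channels, base_channels, 3L),
    c2 = conv_bn_act(base_channels, base_channels, 3L),
    c3 = conv_bn_act(base_channels, base_channels, 3L),
    c4 = conv_bn_act(base_channels, base_channels, 3L)
  )
  m
}

fwd_stem <- function(ctx, m, x) {
  h <- fwd_cba(ctx, m$children$c1, x)
  h <- fwd_cba(ctx, m$children$c2, h)
  h <- fwd_cba(ctx, m$children$c3, h)
  fwd_cba(ctx, m$children$c4, h)
}

#' Encoder convolution block
#'
#' Depth-wise 3x3 convolution (C -> C), group 3x3 convolution (C -> 2C, where
#' the channel doubling happens), then two plain 3x3 convolutions at 2C; each
#' convolution is followed by batch-norm and ReLU.
#'
#' @param channels input width C; output width is 2C
#' @param groups group count of the group convolution
#' @return a module
#' @export
encoder_block <- function(channels, groups = 4L) {
  C <- as.integer(channels)
  if (C %% groups != 0) stop("encoder block: channels must be divisible by groups")
  m <- new_module("encoder", cin = C, cout = 2L * C)
  m$children <- list(
    dw = conv_bn_act(C, C, 3L, groups = C),
    gc = conv_bn_act(C, 2L * C, 3L, groups = groups),
    c1 = conv_bn_act(2L * C, 2L * C, 3L),
    c2 = conv_bn_act(2L * C, 2L * C, 3L)
  )
  m
}

fwd_encoder <- function(ctx, m, x) {
  h <- fwd_cba(ctx, m$children$dw, x)
  h <- fwd_cba(ctx, m$children$gc, h)
  h <- fwd_cba(ctx, m$children$c1, h)
  fwd_cba(ctx, m$children$c2, h)
}

#' Decoder convolution block
#'
#' Depth-wise 3x3 (C -> C), group 3x3 (C -> C), point-wise 1x1 (C -> C/2),
#' each followed by batch-norm and ReLU.  The point-wise convolution carries
#' the channel halving so that concatenated (skip + upsampled) features exit
#' at the stage width.
#'
#' @param channels input width C (must be even); output width is C/2
#' @param groups group count of the group convolution
#' @return a module
#' @export
decoder_block <- function(channels, groups = 4L) {
  C <- as.integer(channels)
  if (C %% 2L != 0) stop("decoder block: channels must be even")
  if (C %% groups != 0) stop("decoder block: channels must be divisible by groups")
  m <- new_module("decoder", cin = C, cout = C %/% 2L)
  m$children <- list(
    dw = conv_bn_act(C, C, 3L, groups = C),
    gc = conv_bn_act(C, C, 3L, groups = groups),
    pw = conv_bn_act(C, C %/% 2L, 1L)
  )
  m
}

fwd_decoder <- function(ctx, m, x) {
  h <- fwd_cba(ctx, m$children$dw, x)
  h <- fwd_cba(ctx, m$children$gc, h)
  fwd_cba(ctx, m$children$pw, h)
}

#' Multi-convolution pixel-wise attention gate
#'
#' From the guidance stream Y a gate in (0, 1) is computed by a 3x3
#' convolution (matching Y's channels to X's), two 7x7 convolutions, each
#' with batch-norm, ReLU on the first two and sigmoid on the last; the gate
#' multiplies the primary stream X elementwise.
#'
#' @param channels_x width of the gated stream X (and of the output)
#' @param channels_y width of the guidance stream Y
#' @return a module; apply with `block_forward(m, x, y)`
#' @export
pixel_attention <- function(channels_x, channels_y) {
  m <- new_module("pixgate", cx = as.integer(channels_x), cy = as.integer(channels_y))
  m$children <- list(
    a1 = conv_bn_act(channels_y, channels_x, 3L),
    a2 = conv_bn_act(channels_x, channels_x, 7L),
    a3 = conv_bn_act(channels_x, channels_x, 7L, act = "sigmoid")
  )
  m
}

fwd_pixgate <- function(ctx, m, x, y) {
  dx <- dim(.val(x)); dy <- dim(.val(y))
  if (dx[1] != dy[1] || dx[2] != dy[2]) {
    stop("pixel attention: X and Y must share spatial size")
  }
  g <- fwd_cba(ctx, m$children$a1, y)
  g <- fwd_cba(ctx, m$children$a2, g)
  g <- fwd_cba(ctx, m$children$a3, g)
  ad_mul(ctx, g, x)
}

#' Triple-branch multi-head self-attention bottleneck
#'
#' Three parallel branches expand the input C -> 3C with 3x3 / 5x5 / 7x7
#' convolutions; each 3C map is split channel-wise into Q, K, V, run through
#' multi-head self-attention over the flattened spatial tokens, and the three
#' C-channel branch outputs are concatenated and fused back to C by a 1x1
#' convolution, so the block is width-neutral.
#'
#' @param channels input/output width C (must be divisible by `heads`)
#' @param heads number of attention heads per branch
#' @param kernels integer triple of branch kernel sizes (odd)
#' @param scale attention score normalizer: `"sqrt_d"` divides scores by the
#'   square root of the per-head key dimension (default), `"d"` by the
#'   per-head dimension itself, `"input_3c"` by three times the block input
#'   channels
#' @return a module
#' @export
branch_attention <- function(channels, heads = 4L, kernels = c(3L, 5L, 7L),
                             scale = c("sqrt_d", "d", "input_3c")) {
  scale <- match.arg(scale)
  C <- as.integer(channels)
  if (C %% heads != 0) stop("branch attention: channels must be divisible by heads")
  if (any(kernels %% 2 != 1)) stop("branch attention: kernels must be odd")
  m <- new_module("triattn", C = C, heads = as.integer(heads),
                  kernels = as.integer(kernels), scale = scale)
  m$children <- list(
    b1 = layer_conv(C, 3L * C, kernels[1]),
    b2 = layer_conv(C, 3L * C, kernels[2]),
    b3 = layer_conv(C, 3L * C, kernels[3]),
    fuse = layer_conv(3L * C, C, 1L)
  )
  m
}

attn_scale_value <- function(C, heads, scale) {
  switch(scale,
         sqrt_d = sqrt(C / heads),
         d = C / heads,
         input_3c = 3 * C)
}

fwd_triattn <- function(ctx, m, x) {
  sc <- attn_scale_value(m$C, m$heads, m$scale)
  o1 <- ad_mhsa(ctx, ad_conv2d(ctx, x, m$children$b1), m$heads, sc)
  o2 <- ad_mhsa(ctx, ad_conv2d(ctx, x, m$children$b2), m$heads, sc)
  o3 <- ad_mhsa(ctx, ad_conv2d(ctx, x, m$children$b3), m$heads, sc)
  cat3 <- ad_concat_c(ctx, ad_concat_c(ctx, o1, o2), o3)
  ad_conv2d(ctx, cat3, m$children$fuse)
}

#' Attention weight matrices of the bottleneck, for inspection
#'
#' Runs the three branches in inference mode and returns, per branch and per
#' head, the row-stochastic token-by-token attention matrix.
#'
#' @param m a [branch_attention()] module
#' @param x input feature map
#' @return list of branches, each a list of head matrices (tokens x tokens)
#' @export
attention_weights <- function(m, x) {
  x <- as_feature_map(x)
  sc <- attn_scale_value(m$C, m$heads, m$scale)
  C <- m$C; dh <- C / m$heads
  lapply(m$children[c("b1", "b2", "b3")], function(conv) {
    qkv <- ad_conv2d(NULL, x, conv)
    d <- dim(qkv); HW <- d[1] * d[2]
    X <- matrix(qkv[, , , 1], HW, 3L * C)
    lapply(seq_len(m$heads), function(h) {
      cols <- (h - 1L) * dh + seq_len(dh)
      S <- tcrossprod(X[, cols, drop = FALSE], X[, C + cols, drop = FALSE]) / sc
      S <- S - apply(S, 1L, max)
      E <- exp(S)
      E / rowSums(E)
    })
  })
}

#' Segmentation head
#'
#' A 1x1 convolution to `num_classes` channels followed by a per-pixel
#' softmax, so every pixel carries a probability simplex over classes.
#'
#' @param channels input width (the final decoder width)
#' @param num_classes number of classes
#' @return a module
#' @export
segmentation_head <- function(channels, num_classes) {
  m <- new_module("head", cin = as.integer(channels), cout = as.integer(num_classes))
  m$children <- list(conv = layer_conv(channels, num_classes, 1L))
  m
}

fwd_head <- function(ctx, m, x, logits = FALSE) {
  z <- ad_conv2d(ctx, x, m$children$conv)
  if (logits) z else ad_softmax_c(ctx, z)
}

#' Upsampling stage: transposed convolution, 2x2 kernel, stride 2
#'
#' Doubles the spatial size while halving the channel count.
#'
#' @param channels input width C (must be even); output width is C/2
#' @return a module
#' @export
upsample_halve <- function(channels) {
  C <- as.integer(channels)
  if (C %% 2L != 0) stop("upsample: channels must be even")
  m <- new_module("upsample", cin = C, cout = C %/% 2L)
  m$children <- list(up = layer_convt2(C, C %/% 2L))
  m
}

fwd_upsample <- function(ctx, m, x) ad_convt2(ctx, x, m$children$up)

#' 2x2 max-pooling downsample
#'
#' Halves height and width; channels unchanged.  Spatial size must be even.
#'
#' @param x a feature map
#' @return pooled feature map
#' @export
downsample <- function(x) {
  x <- as_feature_map(x)
  maxpool2_fwd_cpp(x)$out
}

#' Apply a block to a feature map
#'
#' Inference-mode application of any block constructed by this package
#' ([stem_block()], [encoder_block()], [decoder_block()],
#' [pixel_attention()], [branch_attention()], [segmentation_head()],
#' [upsample_halve()]).  Batch-norm layers use their running statistics.
#'
#' @param m a module
#' @param x primary input feature map
#' @param y guidance input (pixel attention only)
#' @return output feature map (H, W, C_out, N)
#' @export
block_forward <- function(m, x, y = NULL) {
  x <- as_feature_map(x)
  switch(m$kind,
         stem = fwd_stem(NULL, m, x),
         encoder = fwd_encoder(NULL, m, x),
         decoder = fwd_decoder(NULL, m, x),
         pixgate = fwd_pixgate(NULL, m, x, as_feature_map(y)),
         triattn = fwd_triattn(NULL, m, x),
         head = fwd_head(NULL, m, x),
         upsample = fwd_upsample(NULL, m, x),
         cba = fwd_cba(NULL, m, x),
         stop("no forward rule for module kind ", m$kind))
}
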