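# Full network assembly: U-shaped encoder-decoder with pixel-wise attention
# gates at every stage and a triple-branch multi-head self-attention block at
# the bottleneck.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the generator, evaluates `expr`, and restores the previous RNG
#' state, so seeded helpers do not disturb the caller's random stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Network configuration
#'
#' Hyperparameters of the segmentation network.  Defaults reproduce the
#' reference configuration: 1-channel input, width 16 at the top stage
#' (doubling per encoder stage to 256 at the bottleneck), five stages (stem
#' plus four encoder blocks, hence four skip connections and four 2x2
#' poolings), four attention heads and four convolution groups, branch
#' kernels 3/5/7.
#'
#' @param in_channels image channels (1 for grayscale)
#' @param num_classes output classes (2 for capsule-only, 4 for internal
#'   structures)
#' @param base_channels width after the stem block
#' @param stages total encoder stages including the stem (`stages - 1`
#'   encoder blocks, poolings and skip connections)
#' @param heads attention heads per bottleneck branch
#' @param groups group count of all group convolutions
#' @param branch_kernels odd kernel-size triple of the bottleneck branches
#' @param pixel_gates enable the pixel-wise attention gates (ablation switch)
#' @param bottleneck_attention enable the bottleneck self-attention
#'   (ablation switch)
#' @param attention_scale score normalizer, see [branch_attention()]
#' @return object of class `sg_config`
#' @export
model_config <- function(in_channels = 1L, num_classes = 2L, base_channels = 16L,
                         stages = 5L, heads = 4L, groups = 4L,
                         branch_kernels = c(3L, 5L, 7L),
                         pixel_gates = TRUE, bottleneck_attention = TRUE,
                         attention_scale = c("sqrt_d", "d", "input_3c")) {
  attention_scale <- match.arg(attention_scale)
  cfg <- list(in_channels = as.integer(in_channels),
              num_classes = as.integer(num_classes),
              base_channels = as.integer(base_channels),
              stages = as.integer(stages),
              heads = as.integer(heads),
              groups = as.integer(groups),
              branch_kernels = as.integer(branch_kernels),
              pixel_gates = isTRUE(pixel_gates),
              bottleneck_attention = isTRUE(bottleneck_attention),
              attention_scale = attention_scale)
  if (cfg$stages < 2L) stop("config: need at least a stem and one encoder stage")
  if (cfg$base_channels %% cfg$groups != 0) {
    stop("config: base_channels must be divisible by groups")
  }
  if (cfg$base_channels %% cfg$heads != 0) {
    stop("config: base_channels must be divisible by heads")
  }
  if (length(cfg$branch_kernels) != 3L || any(cfg$branch_kernels %% 2L != 1L)) {
    stop("config: branch_kernels must be three odd integers")
  }
  if (cfg$num_classes < 2L) stop("config: num_classes must be at least 2")
  class(cfg) <- "sg_config"
  cfg
}

#' Build the segmentation network
#'
#' Assembles stem, encoder stages (each: pixel-attention gate feeding the
#' skip connection, 2x2 max pooling, encoder block), the self-attention
#' bottleneck, decoder stages (transposed-convolution upsampling, skip
#' concatenation, decoder block, pixel-attention gate) and the softmax
#' segmentation head.  Convolutions are Kaiming-initialized from `seed`.
#'
#' @param cfg a [model_config()]
#' @param seed integer seed for parameter initialization
#' @return object of class `sg_model`
#' @export
build_model <- function(cfg = model_config(), seed = 1L) {
  stopifnot(inherits(cfg, "sg_config"))
  ne <- cfg$stages - 1L   # encoder blocks = poolings = skips
  cb <- cfg$base_channels
  with_seed(seed, {
    model <- new_module("model", cfg = cfg, seed = as.integer(seed), n_enc = ne)
    ch <- list(stem = stem_block(cfg$in_channels, cb))
    enc_w_in <- cb * 2L^(seq_len(ne) - 1L)    # encoder block input widths
    for (i in seq_len(ne)) {
      # gate i sits before pooling i: X = previous block output, Y = that
      # block's own input (the pre-block features)
      cy <- if (i == 1L) cfg$in_channels else cb * 2L^(i - 2L)
      if (cfg$pixel_gates) {
        ch[[paste0("egate", i)]] <- pixel_attention(enc_w_in[i], cy)
      }
      ch[[paste0("enc", i)]] <- encoder_block(enc_w_in[i], cfg$groups)
    }
    cbot <- cb * 2L^ne
    if (cfg$bottleneck_attention) {
      ch$bottleneck <- branch_attention(cbot, cfg$heads, cfg$branch_kernels,
                                        cfg$attention_scale)
    }
    for (i in seq.int(ne, 1L)) {
      cin <- cb * 2L^i
      ch[[paste0("up", i)]] <- upsample_halve(cin)
      ch[[paste0("dec", i)]] <- decoder_block(cin, cfg$groups)
      if (cfg$pixel_gates) {
        ch[[paste0("dgate", i)]] <- pixel_attention(cin %/% 2L, cin)
      }
    }
    ch$head <- segmentation_head(cb, cfg$num_classes)
    model$children <- ch
    model
  })
}

# Shared forward over the assembled graph.  Returns the head output; with
# logits = TRUE the pre-softmax scores (used by the training objective).
net_forward <- function(ctx, model, x, logits = FALSE) {
  cfg <- model$cfg
  ne <- model$n_enc
  ch <- model$children
  d <- dim(.val(x))
  div <- 2L^ne
  if (d[1] %% div != 0 || d[2] %% div != 0) {
    stop("input spatial size (", d[1], "x", d[2], ") must be divisible by ",
         div, " (", ne, " successive 2x2 poolings)")
  }
  if (d[3] != cfg$in_channels) stop("input has ", d[3], " channels, expected ", cfg$in_channels)
  cur <- fwd_stem(ctx, ch$stem, x)
  stage_in <- x
  skips <- vector("list", ne)
  for (i in seq_len(ne)) {
    skips[[i]] <- if (cfg$pixel_gates) {
      fwd_pixgate(ctx, ch[[paste0("egate", i)]], cur, stage_in)
    } else cur
    pooled <- ad_maxpool2(ctx, skips[[i]])
    cur <- fwd_encoder(ctx, ch[[paste0("enc", i)]], pooled)
    stage_in <- pooled
  }
  if (cfg$bottleneck_attention) cur <- fwd_triattn(ctx, ch$bottleneck, cur)
  for (i in seq.int(ne, 1L)) {
    up <- fwd_upsample(ctx, ch[[paste0("up", i)]], cur)
    cat <- ad_concat_c(ctx, skips[[i]], up)
    dec <- fwd_decoder(ctx, ch[[paste0("dec", i)]], cat)
    cur <- if (cfg$pixel_gates) {
      fwd_pixgate(ctx, ch[[paste0("dgate", i)]], dec, cat)
    } else dec
  }
  fwd_head(ctx, ch$head, cur, logits = logits)
}

#' Forward pass
#'
#' Maps an image (or batch) to per-pixel class probabilities.  In inference
#' mode (the default) batch-norm layers use running statistics and the
#' result is deterministic.
#'
#' @param model a built model
#' @param image matrix (H, W), array (H, W, C) or batch (H, W, C, N); spatial
#'   size must be divisible by `2^(stages-1)` (16 for the default depth)
#' @param logits return pre-softmax scores instead of probabilities
#' @return array (H, W, num_classes, N)
#' @export
model_forward <- function(model, image, logits = FALSE) {
  stopifnot(inherits(model, "sg_model"))
  net_forward(NULL, model, as_feature_map(image), logits = logits)
}

#' Parameters of a model
#'
#' @param model a built model
#' @return named list of parameter environments
#' @export
model_parameters <- function(model) module_parameters(model)

#' Architecture bookkeeping summary
#'
#' Walks the assembled graph and reports the stage widths and counts used by
#' the channel/shape contracts.
#'
#' @param model a built model
#' @param input_size spatial size used to report per-stage resolutions
#' @return list with encoder/decoder widths, bottleneck width and spatial
#'   size, skip-connection count, stem convolution count, branch expansion
#'   factor and parameter count
#' @export
model_summary <- function(model, input_size = 512L) {
  cfg <- model$cfg
  ne <- model$n_enc
  cb <- cfg$base_channels
  enc_widths <- as.integer(cb * 2L^(0:ne))
  stem_convs <- sum(vapply(model$children$stem$children,
                           function(u) identical(u$kind, "cba"), logical(1)))
  bexp <- if (cfg$bottleneck_attention) {
    bt <- model$children$bottleneck
    bt$children$b1$cout / bt$children$b1$cin
  } else NA_real_
  list(
    encoder_widths = enc_widths,
    decoder_widths = rev(enc_widths[-length(enc_widths)]),
    bottleneck_channels = as.integer(cb * 2L^ne),
    bottleneck_size = as.integer(input_size / 2L^ne),
    skip_connections = ne,
    skip_widths = as.integer(enc_widths[seq_len(ne)]),
    stem_conv_layers = stem_convs,
    branch_expansion = bexp,
    n_parameters = count_parameters(model)
  )
}

#' @export
print.sg_model <- function(x, ...) {
  s <- model_summary(x)
  cat("<segmentation network>\n")
  cat("  classes:", x$cfg$num_classes,
      " stages:", x$cfg$stages,
      " base width:", x$cfg$base_channels, "\n")
  cat("  encoder widths:", paste(s$encoder_widths, collapse = "-"), "\n")
  cat("  skip connections:", s$skip_connections, "\n")
  cat("  pixel gates:", x$cfg$pixel_gates,
      " bottleneck attention:", x$cfg$bottleneck_attention, "\n")
  cat("  parameters:", format(s$n_parameters, big.mark = ","), "\n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the configuration, the initialization seed, all
#' parameter values and the batch-norm running statistics, so a reloaded
#' model reproduces inference bitwise.
#'
#' @param model a built model
#' @param path file path (conventionally `.rds`)
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored model
#' @export
save_checkpoint <- function(model, path) {
  ps <- model_parameters(model)
  bns <- bn_layers(model)
  saveRDS(list(cfg = model$cfg, seed = model$seed,
               params = lapply(ps, function(p) p$value),
               bn = lapply(bns, function(b) list(mean = b$running_mean,
                                                 var = b$running_var))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  st <- readRDS(path)
  model <- build_model(st$cfg, seed = st$seed)
  set_model_state(model, st$params, st$bn)
  model
}

# Overwrite parameter values / running stats in place (also used to restore
# the best validation checkpoint during training).
set_model_state <- function(model, params, bn) {
  ps <- model_parameters(model)
  stopifnot(identical(names(ps), names(params)))
  for (nm in names(ps)) ps[[nm]]$value <- params[[nm]]
  bns <- bn_layers(model)
  stopifnot(identical(names(bns), names(bn)))
  for (nm in names(bns)) {
    bns[[nm]]$running_mean <- bn[[nm]]$mean
    bns[[nm]]$running_var <- bn[[nm]]$var
  }
  invisible(model)
}

get_model_state <- function(model) {
  list(params = lapply(model_parameters(model), function(p) p$value),
       bn = lapply(bn_layers(model), function(b) list(mean = b$running_mean,
                                                      var = b$running_var)))
}
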