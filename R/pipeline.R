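# Data pipeline: preprocessing, augmentation, dataset splitting, the SGD
# training loop with validation-based model selection, and prediction.

#' Training configuration
#'
#' Defaults follow the reference protocol: SGD with momentum 0.9 and weight
#' decay 1e-4, batch size 4, 30000 iterations, polynomial learning-rate
#' decay from 0.01 with power 0.9, 512x512 input crops.  Scale
#' `max_iterations`, `batch_size` and `crop_size` down for CPU-sized
#' experiments.
#'
#' @param batch_size samples per iteration
#' @param max_iterations total SGD iterations
#' @param lr_initial initial learning rate
#' @param lr_power polynomial decay exponent
#' @param momentum SGD momentum
#' @param weight_decay L2 penalty
#' @param crop_size square input size (multiple of 16)
#' @param seed seed controlling batch order and augmentation draws
#' @param val_interval iterations between validation passes
#' @param augment an [augmentation_config()], or NULL to disable
#' @param loss a [loss_config()]
#' @return object of class `sg_train_config`
#' @export
train_config <- function(batch_size = 4L, max_iterations = 30000L,
                         lr_initial = 0.01, lr_power = 0.9,
                         momentum = 0.9, weight_decay = 1e-4,
                         crop_size = 512L, seed = 1L, val_interval = 250L,
                         augment = augmentation_config(), loss = loss_config()) {
  stopifnot(batch_size >= 1, max_iterations >= 1, lr_initial > 0,
            crop_size %% 16 == 0, val_interval >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 max_iterations = as.integer(max_iterations),
                 lr_initial = lr_initial, lr_power = lr_power,
                 momentum = momentum, weight_decay = weight_decay,
                 crop_size = as.integer(crop_size), seed = as.integer(seed),
                 val_interval = as.integer(val_interval),
                 augment = augment, loss = loss),
            class = "sg_train_config")
}

#' Augmentation configuration
#'
#' Geometric transforms (rotation, flips) are applied identically to image
#' and mask (nearest-neighbor for the mask); photometric transforms
#' (Gaussian noise, brightness/contrast jitter) touch only the image.
#'
#' @param rotation_deg maximum absolute rotation in degrees
#' @param hflip_prob,vflip_prob flip probabilities
#' @param noise_sigma_range range of the additive Gaussian noise standard
#'   deviation (intensity units)
#' @param jitter brightness/contrast jitter factor (uniform in
#'   `[1 - jitter, 1 + jitter]`)
#' @return object of class `sg_augment_config`
#' @export
augmentation_config <- function(rotation_deg = 25, hflip_prob = 0.5,
                                vflip_prob = 0.5, noise_sigma_range = c(0, 0.05),
                                jitter = 0.2) {
  stopifnot(hflip_prob >= 0, hflip_prob <= 1, vflip_prob >= 0, vflip_prob <= 1)
  structure(list(rotation_deg = rotation_deg, hflip_prob = hflip_prob,
                 vflip_prob = vflip_prob, noise_sigma_range = noise_sigma_range,
                 jitter = jitter),
            class = "sg_augment_config")
}

#' Preprocess a grayscale image for the network
#'
#' Center-crops images larger than `crop_size` and zero-pads smaller ones
#' (original pixels centered), then min-max normalizes intensities to
#' `[0, 1]`; a constant image maps to all zeros.
#'
#' @param image numeric matrix
#' @param crop_size target square side (multiple of 16)
#' @return `crop_size` x `crop_size` matrix in `[0, 1]`
#' @export
preprocess_image <- function(image, crop_size = 512L) {
  if (!is.matrix(image)) stop("preprocess: expected a 2-D grayscale image")
  out <- crop_or_pad(image, crop_size)
  rng <- range(out)
  if (rng[2] > rng[1]) (out - rng[1]) / (rng[2] - rng[1]) else out * 0
}

#' Center-crop or zero-pad a matrix to a square size
#'
#' @param m matrix
#' @param size target side
#' @param fill pad value
#' @return `size` x `size` matrix
#' @export
crop_or_pad <- function(m, size, fill = 0) {
  take <- function(n) {
    # index window of length min(n, size) centered in the source
    off <- max(0L, (n - size) %/% 2L)
    seq.int(off + 1L, off + min(n, size))
  }
  put <- function(n) {
    off <- max(0L, (size - n) %/% 2L)
    seq.int(off + 1L, off + min(n, size))
  }
  out <- matrix(fill, size, size)
  out[put(nrow(m)), put(ncol(m))] <- m[take(nrow(m)), take(ncol(m))]
  out
}

# Rotate by `deg` about the center; bilinear for images, nearest for masks.
# Out-of-bounds samples fall back to `fill`.
rotate_image <- function(m, deg, method = c("bilinear", "nearest"), fill = 0) {
  method <- match.arg(method)
  if (deg %% 360 == 0) return(m)
  H <- nrow(m); W <- ncol(m)
  th <- deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  g <- expand.grid(r = seq_len(H), c = seq_len(W))
  # inverse map: source coordinates of each output pixel
  dy <- g$r - cy; dx <- g$c - cx
  sy <- cy + dy * cos(th) - dx * sin(th)
  sx <- cx + dy * sin(th) + dx * cos(th)
  if (method == "nearest") {
    ry <- round(sy); rx <- round(sx)
    ok <- ry >= 1 & ry <= H & rx >= 1 & rx <= W
    v <- rep(fill, length(sy))
    v[ok] <- m[cbind(ry[ok], rx[ok])]
  } else {
    y0 <- floor(sy); x0 <- floor(sx)
    fy <- sy - y0; fx <- sx - x0
    at <- function(yy, xx) {
      ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
      out <- rep(fill, length(yy))
      out[ok] <- m[cbind(yy[ok], xx[ok])]
      out
    }
    v <- at(y0, x0) * (1 - fy) * (1 - fx) + at(y0 + 1, x0) * fy * (1 - fx) +
      at(y0, x0 + 1) * (1 - fy) * fx + at(y0 + 1, x0 + 1) * fy * fx
  }
  matrix(v, H, W)
}

#' Jointly augment an image/mask pair
#'
#' Draws one random transform from `cfg` using the current RNG state:
#' rotation (uniform within the range), horizontal/vertical flips, additive
#' Gaussian noise and brightness/contrast jitter.  The geometric part is
#' shared by image and mask; intensities are clipped to `[0, 1]`.
#'
#' @param image numeric matrix in `[0, 1]`
#' @param mask integer label matrix of the same shape
#' @param cfg an [augmentation_config()]
#' @return list with `image` and `mask`
#' @export
augment_pair <- function(image, mask, cfg = augmentation_config()) {
  stopifnot(identical(dim(image), dim(mask)))
  deg <- if (cfg$rotation_deg > 0) stats::runif(1, -cfg$rotation_deg, cfg$rotation_deg) else 0
  if (deg != 0) {
    image <- rotate_image(image, deg, "bilinear", fill = 0)
    mask <- rotate_image(mask, deg, "nearest", fill = 0L)
  }
  if (stats::runif(1) < cfg$hflip_prob) {
    image <- image[, ncol(image):1]
    mask <- mask[, ncol(mask):1]
  }
  if (stats::runif(1) < cfg$vflip_prob) {
    image <- image[nrow(image):1, ]
    mask <- mask[nrow(mask):1, ]
  }
  sig <- stats::runif(1, cfg$noise_sigma_range[1], cfg$noise_sigma_range[2])
  if (sig > 0) image <- image + matrix(stats::rnorm(length(image), 0, sig), nrow(image))
  if (cfg$jitter > 0) {
    contrast <- stats::runif(1, 1 - cfg$jitter, 1 + cfg$jitter)
    brightness <- stats::runif(1, -cfg$jitter, cfg$jitter)
    image <- (image - 0.5) * contrast + 0.5 + brightness
  }
  list(image = pmin(pmax(image, 0), 1), mask = mask)
}

#' Split a dataset manifest into train/validation/test
#'
#' Subjects missing any required foreground class are excluded first, then
#' the remainder is shuffled with `seed` and partitioned by `counts`.
#'
#' @param manifest data.frame with at least `image` and `mask` columns
#' @param counts integer triple (train, validation, test); must sum to the
#'   number of subjects after exclusion
#' @param seed split seed (logged in the result; there is no default on
#'   purpose)
#' @param required_classes foreground labels that must all be present in a
#'   subject's mask; `NULL` disables exclusion.  Masks are read from
#'   `manifest$mask` when exclusion is requested.
#' @return object of class `sg_split`: list of the three manifests plus the
#'   seed and exclusion count
#' @export
split_dataset <- function(manifest, counts, seed, required_classes = NULL) {
  stopifnot(is.data.frame(manifest), length(counts) == 3)
  keep <- rep(TRUE, nrow(manifest))
  if (!is.null(required_classes)) {
    keep <- vapply(seq_len(nrow(manifest)), function(i) {
      m <- read_mask_png(manifest$mask[i])
      all(required_classes %in% unique(as.vector(m)))
    }, logical(1))
  }
  kept <- manifest[keep, , drop = FALSE]
  if (sum(counts) != nrow(kept)) {
    stop("counts (", sum(counts), ") must sum to the ", nrow(kept),
         " subjects available after exclusion")
  }
  idx <- with_seed(seed, sample.int(nrow(kept)))
  bounds <- cumsum(counts)
  structure(list(
    train = kept[idx[seq_len(bounds[1])], , drop = FALSE],
    val = kept[idx[seq.int(bounds[1] + 1L, bounds[2])], , drop = FALSE],
    test = kept[idx[seq.int(bounds[2] + 1L, bounds[3])], , drop = FALSE],
    seed = as.integer(seed), n_excluded = sum(!keep)
  ), class = "sg_split")
}

# Load manifest rows into memory as a list of image/mask samples.
load_samples <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i) {
    list(image = read_image_png(manifest$image[i]),
         mask = read_mask_png(manifest$mask[i]))
  })
}

# Mean foreground DSC of model predictions over a sample list.
validation_dsc <- function(model, samples, num_classes) {
  scores <- vapply(samples, function(s) {
    pred <- predict_mask(model, s$image)
    fg <- seq_len(num_classes - 1L)
    mean(vapply(fg, function(k) dsc(pred == k, s$mask == k), numeric(1)))
  }, numeric(1))
  mean(scores)
}

#' Train the segmentation network
#'
#' SGD with momentum and per-iteration polynomial learning-rate decay over
#' `cfg$max_iterations` iterations.  Samples cycle in seeded shuffled order;
#' each draw is augmented when augmentation is enabled.  Every
#' `cfg$val_interval` iterations (and at the end) the mean foreground DSC on
#' the validation samples is computed and the parameter state with the
#' highest validation DSC is retained; the returned model carries that best
#' state.  Training aborts with a diagnostic if the loss turns non-finite.
#'
#' @param model a [build_model()] network (modified in place)
#' @param train_samples,val_samples lists of `list(image, mask)` samples
#'   (e.g. from [load_samples()] or [generate_phantom()]); images must
#'   already have the network input size.  `val_samples` may be `NULL` to
#'   skip model selection.
#' @param cfg a [train_config()]
#' @return list: `model` (best-validation state), `history` (per-iteration
#'   data.frame: iter, lr, loss, dice, ce), `val_history` (iter, dsc),
#'   `best` (iter and dsc of the selected checkpoint)
#' @export
train_model <- function(model, train_samples, val_samples = NULL,
                        cfg = train_config()) {
  stopifnot(inherits(model, "sg_model"), inherits(cfg, "sg_train_config"),
            length(train_samples) >= 1)
  K <- model$cfg$num_classes
  lcfg <- cfg$loss
  n <- length(train_samples)
  history <- vector("list", cfg$max_iterations)
  val_history <- list()
  best <- list(dsc = -Inf, iter = NA_integer_, state = NULL)
  params <- model_parameters(model)
  with_seed(cfg$seed, {
    order_pool <- sample.int(n)
    pool_pos <- 0L
    next_sample <- function() {
      pool_pos <<- pool_pos + 1L
      if (pool_pos > n) {
        order_pool <<- sample.int(n)
        pool_pos <<- 1L
      }
      train_samples[[order_pool[pool_pos]]]
    }
    for (it in seq_len(cfg$max_iterations)) {
      lr <- poly_lr(schedule_state(cfg$lr_initial, it - 1L, cfg$max_iterations,
                                   cfg$lr_power))
      imgs <- vector("list", cfg$batch_size)
      msks <- vector("list", cfg$batch_size)
      for (bidx in seq_len(cfg$batch_size)) {
        s <- next_sample()
        if (!is.null(cfg$augment)) {
          s <- augment_pair(s$image, s$mask, cfg$augment)
        }
        imgs[[bidx]] <- s$image
        msks[[bidx]] <- s$mask
      }
      H <- nrow(imgs[[1]]); W <- ncol(imgs[[1]])
      xb <- array(unlist(imgs), c(H, W, 1L, cfg$batch_size))
      tb <- array(as.integer(unlist(msks)), c(H, W, cfg$batch_size))
      ctx <- new_ctx(TRUE)
      z <- net_forward(ctx, model, xb, logits = TRUE)
      L <- ad_seg_loss(ctx, z, tb, lambda = lcfg$lambda_dice,
                       smooth = lcfg$smooth,
                       include_background = lcfg$include_background,
                       class_weights = lcfg$class_weights)
      if (!is.finite(L$value)) {
        stop("non-finite loss at iteration ", it,
             " (lr = ", signif(lr, 4), ", dice = ", signif(L$dice, 4),
             ", ce = ", signif(L$ce, 4), ")")
      }
      run_backward(ctx, L$total)
      sgd_step(params, lr, cfg$momentum, cfg$weight_decay)
      history[[it]] <- data.frame(iter = it, lr = lr, loss = L$value,
                                  dice = L$dice, ce = L$ce)
      if (!is.null(val_samples) &&
          (it %% cfg$val_interval == 0L || it == cfg$max_iterations)) {
        vd <- validation_dsc(model, val_samples, K)
        val_history[[length(val_history) + 1L]] <- data.frame(iter = it, dsc = vd)
        if (vd > best$dsc) {
          best <- list(dsc = vd, iter = it, state = get_model_state(model))
        }
      }
    }
  })
  if (!is.null(best$state)) {
    set_model_state(model, best$state$params, best$state$bn)
  }
  list(model = model,
       history = do.call(rbind, history),
       val_history = if (length(val_history)) do.call(rbind, val_history) else NULL,
       best = list(iter = best$iter, dsc = best$dsc))
}

#' Predict a label mask for one image
#'
#' Runs the network in inference mode and takes the per-pixel argmax of the
#' class probabilities.
#'
#' @param model a trained model (or a checkpoint path)
#' @param image numeric matrix with side divisible by 16 (preprocess first
#'   otherwise)
#' @return integer label matrix
#' @export
predict_mask <- function(model, image) {
  if (is.character(model)) model <- load_checkpoint(model)
  p <- model_forward(model, image)
  K <- dim(p)[3]
  lab <- p[, , 1, 1]
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (c in 2:K) {
    better <- p[, , c, 1] > lab
    lab[better] <- p[, , c, 1][better]
    out[better] <- c - 1L
  }
  out
}

#' Predict masks for a set of images and write them next to the inputs
#'
#' @param model a trained model or checkpoint path
#' @param image_paths character vector of grayscale PNG paths
#' @param out_dir output directory for the predicted masks (same file names)
#' @return character vector of written mask paths
#' @export
predict_masks <- function(model, image_paths, out_dir) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  vapply(image_paths, function(p) {
    m <- predict_mask(model, read_image_png(p))
    out <- file.path(out_dir, basename(p))
    write_mask_png(m, out)
    out
  }, character(1), USE.NAMES = FALSE)
}

#' Read a YAML experiment configuration
#'
#' Maps the `model`, `train`, `augment` and `loss` sections of a YAML file
#' onto [model_config()], [train_config()], [augmentation_config()] and
#' [loss_config()].
#'
#' @param path YAML file
#' @return list with `model` and `train` configuration objects
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  mc <- do.call(model_config, y$model %||% list())
  aug <- if (isFALSE(y$augment)) NULL else do.call(augmentation_config, y$augment %||% list())
  lc <- do.call(loss_config, y$loss %||% list())
  tc <- do.call(train_config, c(y$train %||% list(),
                                list(augment = aug, loss = lc)))
  list(model = mc, train = tc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
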