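# Synthetic kidney phantoms: B-mode-ultrasound-like grayscale images with
# paired label masks, so the network, losses, metrics and pipeline are all
# testable without clinical data.
#
# Geometry: a rotated outer ellipse (the capsule) encloses a bright
# concentric central ellipse (central echo complex, CEC), several dark lobes
# arranged in the annulus between them (medulla), and the remaining interior
# (cortex).  Echogenicity ordering mirrors renal sonographic appearance:
# CEC brightest, cortex intermediate, medulla darkest, background low.
# The piecewise-constant map is Gaussian-blurred and corrupted by
# unit-mean multiplicative gamma speckle.

#' Phantom specification
#'
#' @param size image side in pixels; must be a multiple of 16 so phantoms
#'   feed the default-depth network directly
#' @param seed integer seed; phantoms are a pure function of (spec, seed)
#' @param task `"capsule"` (2-class mask: background / capsule) or
#'   `"internal"` (4-class mask: background / CEC / medulla / cortex)
#' @param speckle_strength standard deviation of the unit-mean multiplicative
#'   gamma speckle, in `[0, 1]`; 0 disables speckle
#' @param blur_sigma Gaussian blur standard deviation in pixels; 0 disables
#'   blurring
#' @param center_jitter maximum center offset as a fraction of `size`
#' @param axis_range outer-ellipse semi-axis range as fractions of `size`
#'   (major sampled from the upper half, minor from the lower)
#' @param rotation_range rotation range in degrees
#' @param n_lobes_range integer range of medulla lobe counts
#' @return object of class `sg_phantom_spec`
#' @export
phantom_spec <- function(size = 256L, seed = 1L, task = c("internal", "capsule"),
                         speckle_strength = 0.4, blur_sigma = 1.5,
                         center_jitter = 0.05, axis_range = c(0.22, 0.40),
                         rotation_range = c(-30, 30), n_lobes_range = c(4L, 8L)) {
  task <- match.arg(task)
  size <- as.integer(size)
  if (size %% 16L != 0) stop("phantom size must be a multiple of 16")
  if (speckle_strength < 0 || speckle_strength > 1) {
    stop("speckle_strength must lie in [0, 1]")
  }
  if (diff(axis_range) <= 0 || diff(range(n_lobes_range)) < 0) {
    stop("degenerate geometry ranges")
  }
  structure(list(size = size, seed = as.integer(seed), task = task,
                 speckle_strength = speckle_strength, blur_sigma = blur_sigma,
                 center_jitter = center_jitter, axis_range = axis_range,
                 rotation_range = rotation_range,
                 n_lobes_range = as.integer(n_lobes_range)),
            class = "sg_phantom_spec")
}

# Separable Gaussian blur via the package's own convolution kernel.
blur_gaussian <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  g1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  g1 <- g1 / sum(g1)
  k2 <- outer(g1, g1)
  x <- array(img, c(nrow(img), ncol(img), 1L, 1L))
  w <- array(k2, c(2L * r + 1L, 2L * r + 1L, 1L, 1L))
  out <- conv2d_fwd_cpp(x, w, 0, 1L)
  matrix(out, nrow(img), ncol(img))
}

# Region masks for one sampled geometry; NULL if a class came out empty.
.phantom_geometry <- function(spec) {
  n <- spec$size
  cx <- n / 2 + stats::runif(1, -1, 1) * spec$center_jitter * n
  cy <- n / 2 + stats::runif(1, -1, 1) * spec$center_jitter * n
  a <- stats::runif(1, mean(spec$axis_range), spec$axis_range[2]) * n  # major
  b <- stats::runif(1, spec$axis_range[1], mean(spec$axis_range)) * n  # minor
  th <- stats::runif(1, spec$rotation_range[1], spec$rotation_range[2]) * pi / 180
  s_cec <- stats::runif(1, 0.35, 0.45)        # CEC scale of the outer axes
  nl <- sample(seq.int(spec$n_lobes_range[1], spec$n_lobes_range[2]), 1)
  ang0 <- stats::runif(1, 0, 2 * pi)
  lobe_r <- stats::runif(nl, 0.60, 0.72)      # radial position (normalized)
  lobe_s <- stats::runif(nl, 0.10, 0.14)      # lobe size (normalized)
  ij <- expand.grid(row = seq_len(n), col = seq_len(n))
  # coordinates in the ellipse frame, normalized by the semi-axes
  dx <- ij$col - cx
  dy <- ij$row - cy
  u <- (dx * cos(th) + dy * sin(th)) / a
  v <- (-dx * sin(th) + dy * cos(th)) / b
  r2 <- u^2 + v^2
  capsule <- matrix(r2 <= 1, n, n)
  cec <- matrix(r2 <= s_cec^2, n, n)
  medulla <- matrix(FALSE, n, n)
  for (k in seq_len(nl)) {
    phi <- ang0 + 2 * pi * (k - 1) / nl
    lu <- lobe_r[k] * cos(phi)
    lv <- lobe_r[k] * sin(phi)
    lobe <- (u - lu)^2 + (v - lv)^2 <= lobe_s[k]^2
    medulla <- medulla | matrix(lobe, n, n)
  }
  # keep the nesting constructive: lobes clipped to the annulus between the
  # CEC and a margin inside the capsule rim
  medulla <- medulla & matrix(r2 <= 0.92^2, n, n) & !cec
  cortex <- capsule & !cec & !medulla
  if (!any(cec) || !any(medulla) || !any(cortex)) return(NULL)
  list(capsule = capsule, cec = cec, medulla = medulla, cortex = cortex)
}

#' Generate one phantom sample
#'
#' Deterministic in `(spec, spec$seed)`: repeated calls return identical
#' image and mask.  With `speckle_strength = 0` and `blur_sigma = 0` the
#' image equals the piecewise-constant echogenicity map exactly.
#'
#' @param spec a [phantom_spec()]
#' @return list with `image` (matrix in `[0, 1]`), `mask` (integer matrix;
#'   capsule task: 0/1; internal task: 0 background, 1 CEC, 2 medulla,
#'   3 cortex), and `spec`
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "sg_phantom_spec"))
  with_seed(spec$seed, {
    geo <- NULL
    for (try in seq_len(100)) {
      geo <- .phantom_geometry(spec)
      if (!is.null(geo)) break
    }
    if (is.null(geo)) stop("phantom geometry sampling failed after 100 retries")
    levels <- c(background = 0.15, cec = 0.75, medulla = 0.25, cortex = 0.45)
    img <- matrix(levels["background"], spec$size, spec$size)
    img[geo$cortex] <- levels["cortex"]
    img[geo$medulla] <- levels["medulla"]
    img[geo$cec] <- levels["cec"]
    img <- blur_gaussian(img, spec$blur_sigma)
    if (spec$speckle_strength > 0) {
      shape <- 1 / spec$speckle_strength^2
      noise <- matrix(stats::rgamma(length(img), shape = shape, scale = 1 / shape),
                      spec$size, spec$size)
      img <- img * noise
    }
    img <- pmin(pmax(img, 0), 1)
    mask <- matrix(0L, spec$size, spec$size)
    if (spec$task == "capsule") {
      mask[geo$capsule] <- 1L
    } else {
      mask[geo$cec] <- 1L
      mask[geo$medulla] <- 2L
      mask[geo$cortex] <- 3L
    }
    list(image = img, mask = mask, spec = spec)
  })
}

#' Class vocabulary of a phantom task
#'
#' @param task `"capsule"` or `"internal"`
#' @return named integer vector of labels
#' @export
phantom_classes <- function(task = c("internal", "capsule")) {
  task <- match.arg(task)
  if (task == "capsule") c(background = 0L, capsule = 1L)
  else c(background = 0L, cec = 1L, medulla = 2L, cortex = 3L)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` image/mask PNG pairs plus a CSV manifest.  Sample `i` is
#' generated from seed `spec$seed + i - 1`, so the dataset is reproducible
#' file-by-file.
#'
#' @param n number of samples (>= 1)
#' @param spec a [phantom_spec()]; its seed is the base seed
#' @param out_dir output directory (created if missing)
#' @return the manifest data.frame (columns `image`, `mask`, `seed`, `task`),
#'   also written to `manifest.csv` in `out_dir`
#' @export
generate_dataset <- function(n, spec = phantom_spec(), out_dir) {
  stopifnot(n >= 1)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  rows <- lapply(seq_len(n), function(i) {
    sp <- spec
    sp$seed <- spec$seed + i - 1L
    s <- generate_phantom(sp)
    img_path <- file.path(out_dir, sprintf("img_%04d.png", i))
    msk_path <- file.path(out_dir, sprintf("msk_%04d.png", i))
    write_image_png(s$image, img_path)
    write_mask_png(s$mask, msk_path)
    data.frame(image = img_path, mask = msk_path, seed = sp$seed,
               task = spec$task, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}
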