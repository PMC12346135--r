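# Segmentation evaluation: overlap metrics (DSC, IOU), surface-distance
# metrics (HD95, ASD) and the paired t-test used for per-case method
# comparison.
#
# Masks are logical or 0/1 matrices for the binary metrics; evaluate_case()
# handles multi-class integer label maps by per-class binarization.
# Distances are Euclidean in pixel units unless a physical pixel spacing is
# supplied.

.as_binary_mask <- function(m) {
  if (is.logical(m)) {
    storage.mode(m) <- "logical"
  } else {
    if (!all(m %in% c(0, 1))) stop("binary mask must contain only 0/1 (or logical) values")
    m <- m != 0
  }
  if (!is.matrix(m)) stop("mask must be a matrix")
  m
}

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`.  If both masks are empty the value is 1
#' by convention (perfect agreement on absence); if exactly one is empty the
#' value is 0.
#'
#' @param A,B binary masks (logical or 0/1 matrices) of equal shape
#' @return value in `[0, 1]`
#' @export
dsc <- function(A, B) {
  A <- .as_binary_mask(A); B <- .as_binary_mask(B)
  stopifnot(identical(dim(A), dim(B)))
  sa <- sum(A); sb <- sum(B)
  if (sa + sb == 0) return(1)
  2 * sum(A & B) / (sa + sb)
}

#' Intersection over union
#'
#' `|A intersect B| / |A union B|`; identically equal to `DSC / (2 - DSC)`.
#' Empty-mask convention as in [dsc()].
#'
#' @inheritParams dsc
#' @return value in `[0, 1]`
#' @export
iou <- function(A, B) {
  A <- .as_binary_mask(A); B <- .as_binary_mask(B)
  stopifnot(identical(dim(A), dim(B)))
  u <- sum(A | B)
  if (u == 0) return(1)
  sum(A & B) / u
}

#' Surface pixels of a binary mask
#'
#' Pixels belonging to the mask with at least one 4-neighbor outside it;
#' pixels on the array border count as surface.
#'
#' @param M binary mask
#' @return two-column matrix of (row, col) coordinates, one row per surface
#'   pixel
#' @export
surface_pixels <- function(M) {
  M <- .as_binary_mask(M)
  if (!any(M)) stop("surface_pixels: mask is empty")
  H <- nrow(M); W <- ncol(M)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- M
  core <- pad[2:(H + 1), 2:(W + 1), drop = FALSE]
  interior <- core &
    pad[1:H, 2:(W + 1), drop = FALSE] & pad[3:(H + 2), 2:(W + 1), drop = FALSE] &
    pad[2:(H + 1), 1:W, drop = FALSE] & pad[2:(H + 1), 3:(W + 2), drop = FALSE]
  which(core & !interior, arr.ind = TRUE)
}

.surface_dists <- function(A, B, spacing) {
  SA <- surface_pixels(A)
  SB <- surface_pixels(B)
  sa <- sweep(SA, 2, spacing, `*`)
  sb <- sweep(SB, 2, spacing, `*`)
  list(ab = min_dists_cpp(sa, sb), ba = min_dists_cpp(sb, sa))
}

#' 95% Hausdorff distance between mask surfaces
#'
#' In the default `"percentile"` mode, the 95th percentile (linear
#' interpolation between order statistics) of the pooled directed
#' surface-to-surface distances in both directions -- the standard HD95.
#' The `"literal"` mode instead returns `0.95 * max(h(A,B), h(B,A))`, i.e.
#' 95% of the exact bidirectional Hausdorff distance.
#'
#' @param A,B non-empty binary masks of equal shape
#' @param mode `"percentile"` (default) or `"literal"`
#' @param spacing physical pixel size per axis (row, col); distances are
#'   reported in the same units
#' @return distance (`>= 0`), or `NA_real_` with attribute `undefined = TRUE`
#'   if either mask is empty
#' @export
hd95 <- function(A, B, mode = c("percentile", "literal"), spacing = c(1, 1)) {
  mode <- match.arg(mode)
  A <- .as_binary_mask(A); B <- .as_binary_mask(B)
  stopifnot(identical(dim(A), dim(B)))
  if (!any(A) || !any(B)) {
    return(structure(NA_real_, undefined = TRUE))
  }
  d <- .surface_dists(A, B, spacing)
  if (mode == "percentile") {
    unname(stats::quantile(c(d$ab, d$ba), 0.95, type = 7))
  } else {
    0.95 * max(max(d$ab), max(d$ba))
  }
}

#' Average surface distance
#'
#' Symmetric mean of all directed nearest-surface distances:
#' `(sum d(a, S(B)) + sum d(b, S(A))) / (|S(A)| + |S(B)|)`.
#'
#' @inheritParams hd95
#' @return distance (`>= 0`), `NA_real_` (attribute `undefined`) on empty
#'   masks
#' @export
asd <- function(A, B, spacing = c(1, 1)) {
  A <- .as_binary_mask(A); B <- .as_binary_mask(B)
  stopifnot(identical(dim(A), dim(B)))
  if (!any(A) || !any(B)) {
    return(structure(NA_real_, undefined = TRUE))
  }
  d <- .surface_dists(A, B, spacing)
  (sum(d$ab) + sum(d$ba)) / (length(d$ab) + length(d$ba))
}

#' Evaluate one predicted label map against ground truth
#'
#' Binarizes each requested foreground class and computes DSC and IOU (as
#' percentages) plus HD95 and ASD.  Distance metrics are undefined (NA) when
#' either mask is empty for a class; the `undefined` column flags such rows
#' so they can be excluded from means with an exclusion count.
#'
#' @param pred,truth integer label maps of equal shape
#' @param classes integer vector of foreground class labels to evaluate
#'   (default: all nonzero labels present in `truth`)
#' @param class_names optional names for the report rows
#' @param spacing physical pixel size per axis
#' @param hd95_mode passed to [hd95()]
#' @return data.frame with one row per class: `class`, `dsc_pct`, `iou_pct`,
#'   `hd95`, `asd`, `undefined`
#' @export
evaluate_case <- function(pred, truth, classes = NULL, class_names = NULL,
                          spacing = c(1, 1), hd95_mode = "percentile") {
  stopifnot(identical(dim(pred), dim(truth)))
  if (is.null(classes)) classes <- sort(setdiff(unique(as.vector(truth)), 0))
  if (length(classes) == 0) stop("no foreground classes to evaluate")
  known <- union(unique(as.vector(truth)), unique(as.vector(pred)))
  if (!all(classes %in% known) && !all(classes >= 0)) stop("unknown class id")
  rows <- lapply(seq_along(classes), function(i) {
    k <- classes[i]
    P <- pred == k
    Tm <- truth == k
    h <- hd95(P, Tm, mode = hd95_mode, spacing = spacing)
    a <- asd(P, Tm, spacing = spacing)
    data.frame(class = k,
               dsc_pct = 100 * dsc(P, Tm),
               iou_pct = 100 * iou(P, Tm),
               hd95 = as.numeric(h),
               asd = as.numeric(a),
               undefined = isTRUE(attr(h, "undefined")))
  })
  out <- do.call(rbind, rows)
  if (!is.null(class_names)) out$name <- class_names
  out
}

#' Evaluate a directory (or list) of prediction/truth mask pairs
#'
#' @param preds,truths lists of integer label maps, or character vectors of
#'   PNG file paths (read with [read_mask_png()]); paired by position
#' @param classes foreground classes (default: union of nonzero labels in
#'   the truths)
#' @param spacing,hd95_mode passed through to the per-case metrics
#' @return list with `per_case` (long data.frame: case, class, metrics) and
#'   `summary` (per-class means of defined values plus the exclusion count
#'   for the distance metrics)
#' @export
evaluate_cases <- function(preds, truths, classes = NULL,
                           spacing = c(1, 1), hd95_mode = "percentile") {
  if (is.character(preds)) preds <- lapply(preds, read_mask_png)
  if (is.character(truths)) truths <- lapply(truths, read_mask_png)
  stopifnot(length(preds) == length(truths), length(preds) >= 1)
  if (is.null(classes)) {
    classes <- sort(unique(unlist(lapply(truths, function(t) setdiff(unique(as.vector(t)), 0)))))
  }
  per <- do.call(rbind, lapply(seq_along(preds), function(i) {
    r <- evaluate_case(preds[[i]], truths[[i]], classes = classes,
                       spacing = spacing, hd95_mode = hd95_mode)
    cbind(case = i, r)
  }))
  summ <- do.call(rbind, lapply(split(per, per$class), function(g) {
    data.frame(class = g$class[1],
               dsc_pct = mean(g$dsc_pct),
               iou_pct = mean(g$iou_pct),
               hd95 = mean(g$hd95[!g$undefined]),
               asd = mean(g$asd[!g$undefined]),
               n_cases = nrow(g),
               n_excluded = sum(g$undefined))
  }))
  rownames(summ) <- NULL
  list(per_case = per, summary = summ)
}

#' Long-format per-case table for distribution (violin) plots
#'
#' Reshapes the per-case report into (case, class, metric, value) rows,
#' the layout used to plot per-method metric distributions.
#'
#' @param per_case the `per_case` element of [evaluate_cases()]
#' @param method optional method label column
#' @return long data.frame
#' @export
violin_data <- function(per_case, method = NULL) {
  metrics <- c("dsc_pct", "iou_pct", "hd95", "asd")
  out <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(case = per_case$case, class = per_case$class,
               metric = m, value = per_case[[m]])
  }))
  if (!is.null(method)) out$method <- method
  out
}

#' Two-sided paired t-test on per-case metric vectors
#'
#' Used to compare two methods case by case.  If every paired difference is
#' exactly zero the p-value is 1 by convention; a nonzero constant
#' difference (zero variance) is an error because the statistic is
#' undefined.
#'
#' @param x,y numeric vectors of equal length (>= 2), paired by case
#' @return two-sided p-value
#' @export
paired_ttest <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(1)
    stop("paired t-test undefined: differences are a nonzero constant")
  }
  stats::t.test(x, y, paired = TRUE)$p.value
}

#' Read / write integer label masks as 8-bit grayscale PNG
#'
#' Label values are stored directly as gray levels (0..255), so masks
#' round-trip exactly.
#'
#' @param path PNG file path
#' @return `read_mask_png`: integer matrix; `write_mask_png`: `path`,
#'   invisibly
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  storage.mode(m) <- "double"
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' @rdname read_mask_png
#' @param mask integer matrix of class labels (0..255)
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(all(mask >= 0), all(mask <= 255))
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Read / write a grayscale image as PNG
#'
#' @param path PNG file path
#' @return `read_image_png`: numeric matrix in `[0, 1]`
#' @export
read_image_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m
}

#' @rdname read_image_png
#' @param image numeric matrix in `[0, 1]`
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
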