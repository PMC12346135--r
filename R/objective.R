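# Training objective (soft Dice + cross-entropy) and the polynomial
# learning-rate schedule.

#' Loss configuration
#'
#' @param lambda_dice weight of the Dice term in the combined loss
#'   (reference setting 0.5)
#' @param smooth additive smoothing of the soft-Dice ratio; keeps the term
#'   defined when a class is absent from both prediction mass and target
#' @param include_background include class 0 in the Dice average
#' @param class_weights optional per-class cross-entropy weights
#' @return object of class `sg_loss_config`
#' @export
loss_config <- function(lambda_dice = 0.5, smooth = 1e-5,
                        include_background = TRUE, class_weights = NULL) {
  stopifnot(lambda_dice >= 0, smooth > 0)
  structure(list(lambda_dice = lambda_dice, smooth = smooth,
                 include_background = isTRUE(include_background),
                 class_weights = class_weights),
            class = "sg_loss_config")
}

# Canonicalize probability maps and integer targets for the plain losses.
.loss_inputs <- function(probs, target) {
  probs <- as_feature_map(probs)
  K <- dim(probs)[3]
  tg <- as.integer(target)
  if (length(tg) * K != length(probs)) stop("probs and target shapes do not match")
  if (any(tg < 0L | tg >= K)) stop("target class index out of range (0..", K - 1, ")")
  list(p = probs, t = array(tg, dim(probs)[c(1, 2, 4)]), K = K)
}

#' Soft Dice loss
#'
#' `1 - mean_c (2 * sum(p_c * t_c) + s) / (sum(p_c) + sum(t_c) + s)` over the
#' included classes, with the target one-hot encoded.  Batches are pooled
#' into the per-class sums.
#'
#' @param probs per-pixel class probabilities (H, W, K) or (H, W, K, N)
#' @param target integer class map (H, W) or (H, W, N), values in 0..K-1
#' @param smooth smoothing constant
#' @param include_background include class 0 in the class average
#' @return scalar loss in `[0, 1)` up to smoothing effects
#' @export
dice_loss <- function(probs, target, smooth = 1e-5, include_background = TRUE) {
  z <- .loss_inputs(probs, target)
  incl <- if (include_background) seq_len(z$K) else seq.int(2L, z$K)
  dc <- vapply(incl, function(c) {
    pc <- z$p[, , c, ]
    tc <- as.vector(z$t == (c - 1L))
    (2 * sum(pc * tc) + smooth) / (sum(pc) + sum(tc) + smooth)
  }, numeric(1))
  1 - mean(dc)
}

#' Cross-entropy loss
#'
#' Mean per-pixel negative log-likelihood of the true class.  By default the
#' input is pre-softmax scores and the log-softmax is taken internally for
#' numerical stability; set `from_logits = FALSE` to pass probabilities.
#'
#' @param scores (H, W, K[, N]) logits (default) or probabilities
#' @param target integer class map, values in 0..K-1
#' @param from_logits whether `scores` are pre-softmax
#' @param class_weights optional per-class weights (normalized by the total
#'   weight present, so a uniform vector reproduces the unweighted mean)
#' @return scalar loss
#' @export
cross_entropy_loss <- function(scores, target, from_logits = TRUE,
                               class_weights = NULL) {
  z <- .loss_inputs(scores, target)
  K <- z$K
  if (from_logits) {
    mx <- z$p[, , 1, ]
    if (K > 1) for (c in 2:K) mx <- pmax(mx, z$p[, , c, ])
    s <- array(0, dim(mx))
    for (c in seq_len(K)) s <- s + exp(z$p[, , c, ] - mx)
    lse <- mx + log(s)
  }
  lp <- array(0, dim(z$t))
  for (c in seq_len(K)) {
    sel <- z$t == (c - 1L)
    sc <- z$p[, , c, ]
    lp[sel] <- if (from_logits) sc[sel] - lse[sel] else log(sc[sel])
  }
  if (is.null(class_weights)) return(-mean(lp))
  w <- array(class_weights[z$t + 1L], dim(z$t))
  -sum(w * lp) / sum(w)
}

#' Combined segmentation loss
#'
#' `lambda * Dice + cross-entropy`, the training objective.
#'
#' @param scores logits (default) or probabilities, see `from_logits`
#' @param target integer class map
#' @param cfg a [loss_config()]
#' @param from_logits whether `scores` are pre-softmax
#' @return scalar loss
#' @export
combined_loss <- function(scores, target, cfg = loss_config(),
                          from_logits = TRUE) {
  stopifnot(inherits(cfg, "sg_loss_config"))
  scores <- as_feature_map(scores)
  probs <- if (from_logits) ad_softmax_c(NULL, scores) else scores
  cfg$lambda_dice * dice_loss(probs, target, cfg$smooth, cfg$include_background) +
    cross_entropy_loss(scores, target, from_logits = from_logits,
                       class_weights = cfg$class_weights)
}

#' Schedule state for polynomial learning-rate decay
#'
#' @param lr_initial initial learning rate (reference setting 0.01)
#' @param iter current iteration, 0-based
#' @param max_iter total training iterations (reference setting 30000)
#' @param power decay exponent (reference setting 0.9)
#' @return object of class `sg_schedule`
#' @export
schedule_state <- function(lr_initial = 0.01, iter = 0L, max_iter = 30000L,
                           power = 0.9) {
  stopifnot(lr_initial > 0, max_iter >= 1)
  structure(list(lr_initial = lr_initial, iter = as.integer(iter),
                 max_iter = as.integer(max_iter), power = power),
            class = "sg_schedule")
}

#' Polynomial learning-rate decay
#'
#' `lr = lr_initial * (1 - iter / max_iter) ^ power`; equals `lr_initial` at
#' iteration 0 and decays monotonically to exactly 0 at `max_iter`.
#'
#' @param s a [schedule_state()], or the current iteration if the remaining
#'   arguments are given
#' @param lr_initial,max_iter,power scalar alternative to passing a state
#' @return learning rate for the given iteration
#' @export
poly_lr <- function(s, lr_initial = 0.01, max_iter = 30000L, power = 0.9) {
  if (!inherits(s, "sg_schedule")) {
    s <- schedule_state(lr_initial, s, max_iter, power)
  }
  if (s$iter < 0L || s$iter > s$max_iter) {
    stop("schedule: iteration must lie in [0, max_iter]")
  }
  s$lr_initial * (1 - s$iter / s$max_iter)^s$power
}
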