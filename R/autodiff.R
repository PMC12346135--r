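# Minimal reverse-mode automatic differentiation over channel-last
# (H, W, C, N) arrays.
#
# A forward pass in training mode records nodes on a tape (creation order is
# a topological order because evaluation is eager); run_backward() walks the
# tape in reverse and accumulates gradients into parameter environments.
# In inference mode (ctx NULL or training = FALSE) every op returns a plain
# array and nothing is recorded.

new_ctx <- function(training = TRUE) {
  e <- new.env(parent = emptyenv())
  e$training <- isTRUE(training)
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

.recording <- function(ctx) !is.null(ctx) && isTRUE(ctx$training)

.val <- function(x) if (is.environment(x)) x$value else x

.nd <- function(ctx, value, parents = list(), bw = NULL) {
  if (!.recording(ctx)) return(value)
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$bw <- bw
  ctx$n <- ctx$n + 1L
  if (ctx$n > length(ctx$nodes)) {
    ctx$nodes <- c(ctx$nodes, vector("list", length(ctx$nodes)))
  }
  ctx$nodes[[ctx$n]] <- nd
  nd
}

.param <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$mom <- NULL
  class(e) <- "sg_param"
  e
}

#' Accumulate gradients of a scalar loss node into its parameters
#'
#' Walks the recorded tape in reverse, calling each node's backward function
#' and summing gradients into every parameter environment encountered.
#' Intermediate activations are released as soon as their node has been
#' processed.
#'
#' @param ctx a recording context created by the training loop
#' @param loss the scalar loss node returned by the loss primitive
#' @keywords internal
run_backward <- function(ctx, loss) {
  stopifnot(is.environment(loss))
  loss$grad <- 1
  for (i in seq.int(ctx$n, 1L)) {
    nd <- ctx$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$bw)) next
    gs <- nd$bw(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      gj <- gs[[j]]
      if (is.environment(p) && !is.null(gj)) {
        p$grad <- if (is.null(p$grad)) gj else p$grad + gj
      }
    }
    nd$grad <- NULL
    nd$value <- NULL
    ctx$nodes[i] <- list(NULL)
  }
  invisible(NULL)
}

# ---- primitive ops ---------------------------------------------------------

ad_conv2d <- function(ctx, x, layer) {
  xv <- .val(x)
  out <- conv2d_fwd_cpp(xv, layer$params$w$value, layer$params$b$value, layer$groups)
  .nd(ctx, out, parents = list(x, layer$params$w, layer$params$b),
      bw = function(g) {
        r <- conv2d_bwd_cpp(xv, layer$params$w$value, g, layer$groups)
        list(r$gx, r$gw, r$gb)
      })
}

ad_convt2 <- function(ctx, x, layer) {
  xv <- .val(x)
  out <- convt2_fwd_cpp(xv, layer$params$w$value, layer$params$b$value)
  .nd(ctx, out, parents = list(x, layer$params$w, layer$params$b),
      bw = function(g) {
        r <- convt2_bwd_cpp(xv, layer$params$w$value, g)
        list(r$gx, r$gw, r$gb)
      })
}

ad_maxpool2 <- function(ctx, x) {
  xv <- .val(x)
  r <- maxpool2_fwd_cpp(xv)
  H <- dim(xv)[1]; W <- dim(xv)[2]
  .nd(ctx, r$out, parents = list(x),
      bw = function(g) list(maxpool2_bwd_cpp(r$idx, g, H, W)))
}

ad_relu <- function(ctx, x) {
  xv <- .val(x)
  v <- xv
  v[v < 0] <- 0
  .nd(ctx, v, parents = list(x), bw = function(g) list(g * (xv > 0)))
}

ad_sigmoid <- function(ctx, x) {
  xv <- .val(x)
  v <- 1 / (1 + exp(-xv))
  .nd(ctx, v, parents = list(x), bw = function(g) list(g * v * (1 - v)))
}

ad_mul <- function(ctx, a, b) {
  av <- .val(a); bv <- .val(b)
  .nd(ctx, av * bv, parents = list(a, b),
      bw = function(g) list(g * bv, g * av))
}

ad_concat_c <- function(ctx, a, b) {
  av <- .val(a); bv <- .val(b)
  da <- dim(av); db <- dim(bv)
  ca <- da[3]; cb <- db[3]
  v <- array(0, c(da[1], da[2], ca + cb, da[4]))
  v[, , seq_len(ca), ] <- av
  v[, , ca + seq_len(cb), ] <- bv
  .nd(ctx, v, parents = list(a, b),
      bw = function(g) list(g[, , seq_len(ca), , drop = FALSE],
                            g[, , ca + seq_len(cb), , drop = FALSE]))
}

# Batch normalization over the (H, W, N) axes per channel.  The layer
# environment carries the affine parameters and running statistics; running
# statistics are updated in place during a recording pass.
ad_bn <- function(ctx, x, layer) {
  xv <- .val(x)
  d <- dim(xv)
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]; M <- HW * N
  gamma <- layer$params$gamma$value
  beta <- layer$params$beta$value
  if (.recording(ctx)) {
    m2 <- matrix(xv, nrow = HW)
    mu <- rowSums(matrix(colSums(m2), C, N)) / M
    mu2 <- rowSums(matrix(colSums(m2 * m2), C, N)) / M
    va <- pmax(mu2 - mu * mu, 0)
    invstd <- 1 / sqrt(va + layer$eps)
    xhat <- (xv - rep(mu, each = HW)) * rep(invstd, each = HW)
    v <- xhat * rep(gamma, each = HW) + rep(beta, each = HW)
    mom <- layer$momentum
    layer$running_mean <- (1 - mom) * layer$running_mean + mom * mu
    ub <- if (M > 1) M / (M - 1) else 1
    layer$running_var <- (1 - mom) * layer$running_var + mom * va * ub
    .nd(ctx, v, parents = list(x, layer$params$gamma, layer$params$beta),
        bw = function(g) {
          gm <- matrix(g, nrow = HW)
          sg <- rowSums(matrix(colSums(gm), C, N))
          sgx <- rowSums(matrix(colSums(gm * matrix(xhat, nrow = HW)), C, N))
          gx <- rep(gamma * invstd, each = HW) *
            (g - rep(sg / M, each = HW) - xhat * rep(sgx / M, each = HW))
          list(gx, sgx, sg)
        })
  } else {
    invstd <- 1 / sqrt(layer$running_var + layer$eps)
    sc <- gamma * invstd
    sh <- beta - layer$running_mean * sc
    xv * rep(sc, each = HW) + rep(sh, each = HW)
  }
}

# Softmax across the channel axis (dim 3).
ad_softmax_c <- function(ctx, x) {
  xv <- .val(x)
  d <- dim(xv); C <- d[3]
  mx <- xv[, , 1, ]
  if (C > 1) for (c in 2:C) mx <- pmax(mx, xv[, , c, ])
  e <- xv
  for (c in seq_len(C)) e[, , c, ] <- exp(xv[, , c, ] - mx)
  s <- e[, , 1, ]
  if (C > 1) for (c in 2:C) s <- s + e[, , c, ]
  p <- e
  for (c in seq_len(C)) p[, , c, ] <- e[, , c, ] / s
  .nd(ctx, p, parents = list(x),
      bw = function(g) {
        tot <- p[, , 1, ] * g[, , 1, ]
        if (C > 1) for (c in 2:C) tot <- tot + p[, , c, ] * g[, , c, ]
        gx <- g
        for (c in seq_len(C)) gx[, , c, ] <- p[, , c, ] * (g[, , c, ] - tot)
        gx
      })
}

# Multi-head self-attention over flattened spatial tokens.  `qkv` holds the
# query/key/value planes stacked along channels (3C total); scores for each
# head are divided by `scale` before the row-wise softmax.
ad_mhsa <- function(ctx, qkv, heads, scale) {
  v <- .val(qkv)
  d <- dim(v)
  HW <- d[1] * d[2]; C <- d[3] / 3L; N <- d[4]
  if (C %% heads != 0) stop("attention: channels must be divisible by heads")
  if (HW < 1) stop("attention: token count is zero")
  dh <- C / heads
  out <- array(0, c(d[1], d[2], C, N))
  cache <- vector("list", N)
  rec <- .recording(ctx)
  for (n in seq_len(N)) {
    X <- matrix(v[, , , n], HW, 3L * C)
    Q <- X[, seq_len(C), drop = FALSE]
    K <- X[, C + seq_len(C), drop = FALSE]
    V <- X[, 2L * C + seq_len(C), drop = FALSE]
    On <- matrix(0, HW, C)
    As <- if (rec) vector("list", heads) else NULL
    for (h in seq_len(heads)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / scale
      S <- S - apply(S, 1L, max)
      E <- exp(S)
      A <- E / rowSums(E)
      On[, cols] <- A %*% V[, cols, drop = FALSE]
      if (rec) As[[h]] <- A
    }
    out[, , , n] <- array(On, c(d[1], d[2], C))
    if (rec) cache[[n]] <- list(Q = Q, K = K, V = V, A = As)
  }
  .nd(ctx, out, parents = list(qkv),
      bw = function(g) {
        gqkv <- array(0, d)
        for (n in seq_len(N)) {
          cc <- cache[[n]]
          GO <- matrix(g[, , , n], HW, C)
          gX <- matrix(0, HW, 3L * C)
          for (h in seq_len(heads)) {
            cols <- (h - 1L) * dh + seq_len(dh)
            A <- cc$A[[h]]
            Vh <- cc$V[, cols, drop = FALSE]
            GOh <- GO[, cols, drop = FALSE]
            gA <- tcrossprod(GOh, Vh)
            gV <- crossprod(A, GOh)
            gS <- A * (gA - rowSums(gA * A))
            gX[, cols] <- (gS %*% cc$K[, cols, drop = FALSE]) / scale
            gX[, C + cols] <- crossprod(gS, cc$Q[, cols, drop = FALSE]) / scale
            gX[, 2L * C + cols] <- gV
          }
          gqkv[, , , n] <- array(gX, c(d[1], d[2], 3L * C))
        }
        list(gqkv)
      })
}

# Combined soft-Dice + cross-entropy training objective, taken from logits
# for numerical stability.  Returns the scalar node plus the two component
# values for logging.
ad_seg_loss <- function(ctx, logits, target, lambda = 0.5, smooth = 1e-5,
                        include_background = TRUE, class_weights = NULL) {
  zv <- .val(logits)
  d <- dim(zv)
  H <- d[1]; W <- d[2]; K <- d[3]; N <- d[4]
  tg <- as.integer(target)
  if (any(tg < 0L) || any(tg >= K)) stop("target class index out of range")
  npix <- H * W * N
  # stable softmax + log-softmax over channels
  mx <- zv[, , 1, ]
  if (K > 1) for (c in 2:K) mx <- pmax(mx, zv[, , c, ])
  e <- zv
  for (c in seq_len(K)) e[, , c, ] <- exp(zv[, , c, ] - mx)
  s <- e[, , 1, ]
  if (K > 1) for (c in 2:K) s <- s + e[, , c, ]
  p <- e
  for (c in seq_len(K)) p[, , c, ] <- e[, , c, ] / s
  logs <- log(s)
  tarr <- array(tg, c(H, W, N))
  onehot <- array(0, d)
  for (c in seq_len(K)) onehot[, , c, ] <- (tarr == (c - 1L))
  # cross-entropy
  lp_true <- array(0, c(H, W, N))
  for (c in seq_len(K)) {
    sel <- tarr == (c - 1L)
    zc <- zv[, , c, ]
    lp_true[sel] <- zc[sel] - mx[sel] - logs[sel]
  }
  if (is.null(class_weights)) {
    wpix <- rep(1 / npix, npix)
    ce <- -sum(lp_true) / npix
  } else {
    wp <- class_weights[tg + 1L]
    wpix <- wp / sum(wp)
    ce <- -sum(wpix * as.vector(lp_true))
  }
  # soft Dice aggregated over the batch
  incl <- if (include_background) seq_len(K) else seq.int(2L, K)
  Ic <- Pc <- Tc <- numeric(K)
  for (c in seq_len(K)) {
    Ic[c] <- sum(p[, , c, ] * onehot[, , c, ])
    Pc[c] <- sum(p[, , c, ])
    Tc[c] <- sum(onehot[, , c, ])
  }
  dice_c <- (2 * Ic[incl] + smooth) / (Pc[incl] + Tc[incl] + smooth)
  dloss <- 1 - mean(dice_c)
  total <- lambda * dloss + ce
  node <- .nd(ctx, total, parents = list(logits),
              bw = function(g) {
                # d(dice)/dp then chain through softmax; CE closed form
                gp <- array(0, d)
                kk <- length(incl)
                for (c in incl) {
                  denom <- Pc[c] + Tc[c] + smooth
                  gp[, , c, ] <- -(2 * onehot[, , c, ] * denom -
                                     (2 * Ic[c] + smooth)) / (denom^2) / kk
                }
                tot <- p[, , 1, ] * gp[, , 1, ]
                if (K > 1) for (c in 2:K) tot <- tot + p[, , c, ] * gp[, , c, ]
                gz <- gp
                for (c in seq_len(K)) {
                  gz[, , c, ] <- lambda * p[, , c, ] * (gp[, , c, ] - tot) +
                    (p[, , c, ] - onehot[, , c, ]) * wpix
                }
                list(g * gz)
              })
  list(total = node, value = total, dice = dloss, ce = ce)
}

#' One SGD-with-momentum update
#'
#' Applies the classical momentum update `v <- mu * v + (g + wd * w)`,
#' `w <- w - lr * v` to every parameter that received a gradient, then clears
#' the gradients.
#'
#' @param params list of parameter environments (from [model_parameters()])
#' @param lr learning rate for this step
#' @param momentum momentum coefficient (reference setting 0.9)
#' @param weight_decay L2 penalty coefficient (reference setting 1e-4)
#' @keywords internal
sgd_step <- function(params, lr, momentum = 0.9, weight_decay = 1e-4) {
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad + weight_decay * p$value
    p$mom <- if (is.null(p$mom)) g else momentum * p$mom + g
    p$value <- p$value - lr * p$mom
    p$grad <- NULL
  }
  invisible(NULL)
}
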