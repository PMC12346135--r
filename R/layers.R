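# Parameterized layers.  A layer/module is an environment carrying
#   kind     - layer type tag
#   params   - named list of parameter environments (value/grad/mom)
#   children - named list of sub-modules
# plus whatever hyperparameters the op needs.  Mutable state (batch-norm
# running statistics) lives directly in the environment.

new_module <- function(.kind, ...) {
  e <- new.env(parent = emptyenv())
  e$kind <- .kind
  e$params <- list()
  e$children <- list()
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(paste0("sg_", .kind), "sg_module")
  e
}

# Kaiming fan-in initialization for a grouped convolution.
layer_conv <- function(cin, cout, k, groups = 1L) {
  if (cin %% groups != 0 || cout %% groups != 0) {
    stop("conv: channels (", cin, "->", cout, ") must be divisible by groups (", groups, ")")
  }
  if (k %% 2 != 1) stop("conv: kernel size must be odd for size-preserving padding")
  fan_in <- k * k * cin / groups
  m <- new_module("conv", k = k, cin = cin, cout = cout, groups = as.integer(groups))
  m$params <- list(
    w = .param(array(stats::rnorm(k * k * (cin / groups) * cout, sd = sqrt(2 / fan_in)),
                     c(k, k, cin / groups, cout))),
    b = .param(numeric(cout))
  )
  m
}

# Transposed convolution, 2x2 kernel, stride 2: doubles H, W.
layer_convt2 <- function(cin, cout) {
  m <- new_module("convt2", cin = cin, cout = cout)
  m$params <- list(
    w = .param(array(stats::rnorm(4 * cout * cin, sd = sqrt(2 / cin)), c(2, 2, cout, cin))),
    b = .param(numeric(cout))
  )
  m
}

layer_bn <- function(C, eps = 1e-5, momentum = 0.1) {
  m <- new_module("bn", eps = eps, momentum = momentum,
                  running_mean = numeric(C), running_var = rep(1, C))
  m$params <- list(gamma = .param(rep(1, C)), beta = .param(numeric(C)))
  m
}

# conv -> batch-norm -> activation unit, the repeating motif of every block
conv_bn_act <- function(cin, cout, k, groups = 1L, act = "relu") {
  m <- new_module("cba", act = act)
  m$children <- list(conv = layer_conv(cin, cout, k, groups), bn = layer_bn(cout))
  m
}

fwd_cba <- function(ctx, m, x) {
  h <- ad_conv2d(ctx, x, m$children$conv)
  h <- ad_bn(ctx, h, m$children$bn)
  switch(m$act,
         relu = ad_relu(ctx, h),
         sigmoid = ad_sigmoid(ctx, h),
         none = h)
}

#' Enumerate the parameters of a module tree
#'
#' @param m a module (a block, or a whole model)
#' @param prefix name prefix used during recursion
#' @return named list of parameter environments; names encode the position in
#'   the module tree (e.g. `stem.c1.conv.w`)
#' @export
module_parameters <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$params)) {
    out[[paste0(prefix, nm)]] <- m$params[[nm]]
  }
  for (nm in names(m$children)) {
    out <- c(out, module_parameters(m$children[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

#' Count scalar parameters of a module or model
#'
#' @param m a module or model
#' @return integer, total number of trainable scalars (batch-norm affine
#'   terms included, running statistics excluded)
#' @export
count_parameters <- function(m) {
  sum(vapply(module_parameters(m), function(p) length(p$value), numeric(1)))
}

# Walk all batch-norm layers of a module tree (used for checkpointing and
# for resetting running statistics).
bn_layers <- function(m, prefix = "") {
  out <- list()
  if (identical(m$kind, "bn")) out[[prefix]] <- m
  for (nm in names(m$children)) {
    out <- c(out, bn_layers(m$children[[nm]], paste0(prefix, nm, ".")))
  }
  out
}
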