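# Minimal define-and-run network core. Feature tensors are column-major R
# arrays laid out (H, W, C, N); every layer is an environment exposing
# forward(x, training) / backward(dy) plus its trainable parameters, with the
# caches required by backward kept on the layer between the two calls.

new_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$m <- NULL
  p$v <- NULL
  p
}

#' @noRd
collect_params <- function(mod) {
  out <- if (is.null(mod$params)) list() else mod$params
  for (ch in mod$children) out <- c(out, collect_params(ch))
  out
}

#' Count trainable parameters of a network or block
#'
#' @param mod a `"gsn_network"` (or any internal module, or a fitted
#'   `"gsn_hvnet"` model).
#' @return total number of trainable scalar parameters.
#' @export
n_parameters <- function(mod) {
  if (inherits(mod, "gsn_hvnet")) mod <- mod$network
  sum(vapply(collect_params(mod), function(p) length(p$value), numeric(1)))
}

zero_grads <- function(params) {
  for (p in params) {
    p$grad <- if (is.null(dim(p$value))) numeric(length(p$value))
    else array(0, dim = dim(p$value))
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Kaiming-normal initialised convolution (cross-correlation); bias-free, the
# normalization layers carry the shift.
nn_conv <- function(in_ch, out_ch, k, stride = 1L, pad = as.integer(k %/% 2),
                    groups = 1L) {
  stopifnot(in_ch %% groups == 0, out_ch %% groups == 0)
  self <- new.env(parent = emptyenv())
  fan_in <- k * k * in_ch / groups
  self$w <- new_param(array(stats::rnorm(k * k * (in_ch %/% groups) * out_ch,
                                         sd = sqrt(2 / fan_in)),
                            dim = c(k, k, in_ch %/% groups, out_ch)))
  self$stride <- as.integer(stride)
  self$pad <- as.integer(pad)
  self$groups <- as.integer(groups)
  self$params <- list(self$w)
  self$children <- list()
  self$forward <- function(x, training = TRUE) {
    if (training) self$x <- x
    conv2d_fw(x, self$w$value, self$stride, self$pad, self$groups)
  }
  self$backward <- function(dy) {
    g <- conv2d_bw(self$x, self$w$value, dy, self$stride, self$pad, self$groups)
    self$w$grad <- self$w$grad + g$dw
    self$x <- NULL
    g$dx
  }
  self
}

nn_relu <- function() {
  self <- new.env(parent = emptyenv())
  self$params <- list()
  self$children <- list()
  self$forward <- function(x, training = TRUE) {
    y <- x
    y[y < 0] <- 0
    if (training) self$y <- y
    y
  }
  self$backward <- function(dy) {
    dy[self$y <= 0] <- 0
    self$y <- NULL
    dy
  }
  self
}

nn_tanh <- function() {
  self <- new.env(parent = emptyenv())
  self$params <- list()
  self$children <- list()
  self$forward <- function(x, training = TRUE) {
    y <- tanh(x)
    if (training) self$y <- y
    y
  }
  self$backward <- function(dy) {
    dx <- dy * (1 - self$y^2)
    self$y <- NULL
    dx
  }
  self
}

# Channel-wise softmax over the third array dimension.
softmax_channels <- function(x) {
  d <- dim(x)
  C <- d[3]
  m <- x[, , 1, , drop = FALSE]
  if (C > 1) for (cc in 2:C) m <- pmax(m, x[, , cc, , drop = FALSE])
  e <- exp(x - m[, , rep(1L, C), , drop = FALSE])
  s <- e[, , 1, , drop = FALSE]
  if (C > 1) for (cc in 2:C) s <- s + e[, , cc, , drop = FALSE]
  e / s[, , rep(1L, C), , drop = FALSE]
}

nn_softmax <- function() {
  self <- new.env(parent = emptyenv())
  self$params <- list()
  self$children <- list()
  self$forward <- function(x, training = TRUE) {
    y <- softmax_channels(x)
    if (training) self$y <- y
    y
  }
  self$backward <- function(dy) {
    y <- self$y
    C <- dim(y)[3]
    s <- (y * dy)[, , 1, , drop = FALSE]
    if (C > 1) for (cc in 2:C) s <- s + (y * dy)[, , cc, , drop = FALSE]
    dx <- y * (dy - s[, , rep(1L, C), , drop = FALSE])
    self$y <- NULL
    dx
  }
  self
}

# Nearest-neighbour x2 upsampling.
nn_upsample2 <- function() {
  self <- new.env(parent = emptyenv())
  self$params <- list()
  self$children <- list()
  self$forward <- function(x, training = TRUE) {
    d <- dim(x)
    if (training) self$din <- d
    x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
      drop = FALSE]
  }
  self$backward <- function(dy) {
    d <- self$din
    ro <- seq(1L, 2L * d[1], 2L); re <- ro + 1L
    co <- seq(1L, 2L * d[2], 2L); ce <- co + 1L
    dy[ro, co, , , drop = FALSE] + dy[re, co, , , drop = FALSE] +
      dy[ro, ce, , , drop = FALSE] + dy[re, ce, , , drop = FALSE]
  }
  self
}

nn_seq <- function(...) {
  self <- new.env(parent = emptyenv())
  self$params <- list()
  self$children <- list(...)
  self$forward <- function(x, training = TRUE) {
    for (ch in self$children) x <- ch$forward(x, training)
    x
  }
  self$backward <- function(dy) {
    for (ch in rev(self$children)) dy <- ch$backward(dy)
    dy
  }
  self
}

cat_channels <- function(xs) cat_ch(xs)

split_channels <- function(dy, Cs) split_ch(dy, as.integer(Cs))

# Adam with decoupled weight decay; state lives on the parameter objects.
adam_step <- function(params, step, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  for (p in params) {
    if (is.null(p$m)) {
      p$m <- p$grad * 0
      p$v <- p$grad * 0
    }
    p$m <- beta1 * p$m + (1 - beta1) * p$grad
    p$v <- beta2 * p$v + (1 - beta2) * p$grad^2
    mhat <- p$m / (1 - beta1^step)
    vhat <- p$v / (1 - beta2^step)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps) -
      lr * weight_decay * p$value
  }
  invisible(NULL)
}
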