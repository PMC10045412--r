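# Joint training loss: L = L_NSS + L_HV + L_NC with
#   L_NSS = la * BCE(q) + lb * Dice(q)
#   L_HV  = lc * MSE(p, Gamma) + ld * MSGE(p, Gamma)   (Sobel gradients)
#   L_NC  = le * BCE(r) + lf * Dice(r)
# BCE is applied channel-wise to the softmax outputs; Dice uses the
# foreground nuclei channel for NSS and all channels for NC; MSGE compares
# Sobel derivatives of prediction and target over the ground-truth nuclei
# pixels only.

#' Loss weights for the joint objective
#'
#' @param lambda_a,lambda_b weights of the NSS branch BCE and Dice terms.
#' @param lambda_c,lambda_d weights of the HV branch MSE and MSGE terms.
#' @param lambda_e,lambda_f weights of the NC branch BCE and Dice terms.
#'   Defaults `(1, 1, 1, 1, 2, 1)`.
#' @param epsilon Dice smoothing constant guarding zero denominators
#'   (default `1e-4`).
#' @return list of class `"loss_weights"`.
#' @export
loss_weights <- function(lambda_a = 1, lambda_b = 1, lambda_c = 1,
                         lambda_d = 1, lambda_e = 2, lambda_f = 1,
                         epsilon = 1e-4) {
  w <- list(lambda_a = lambda_a, lambda_b = lambda_b, lambda_c = lambda_c,
            lambda_d = lambda_d, lambda_e = lambda_e, lambda_f = lambda_f,
            epsilon = epsilon)
  stopifnot(all(unlist(w[1:6]) >= 0), epsilon > 0)
  structure(w, class = "loss_weights")
}

BCE_CLAMP <- 1e-7

#' Binary cross-entropy loss
#'
#' Mean over all pixels (and channels) of
#' `-[X log Y + (1 - X) log(1 - Y)]`, with `Y` clamped away from 0 and 1.
#'
#' @param Y predicted probabilities, any array shape.
#' @param X ground-truth values in `[0, 1]` of the same shape.
#' @return non-negative scalar.
#' @examples
#' bce_loss(matrix(0.5, 4, 4), matrix(rbinom(16, 1, 0.5), 4, 4))  # log(2)
#' @export
bce_loss <- function(Y, X) {
  if (!identical(dim(Y) %||% length(Y), dim(X) %||% length(X)))
    stop("shape mismatch between Y and X")
  Yc <- pmin(pmax(Y, BCE_CLAMP), 1 - BCE_CLAMP)
  -mean(X * log(Yc) + (1 - X) * log(1 - Yc))
}

bce_grad <- function(Y, X) {
  Yc <- pmin(pmax(Y, BCE_CLAMP), 1 - BCE_CLAMP)
  g <- (-X / Yc + (1 - X) / (1 - Yc)) / length(Y)
  g[Y < BCE_CLAMP | Y > 1 - BCE_CLAMP] <- 0
  g
}

#' Dice loss
#'
#' `1 - (2 * sum(Y X) + eps) / (sum(Y) + sum(X) + eps)`. The smoothing
#' constant makes the loss 0 (not undefined) when both inputs are empty.
#'
#' @param Y prediction in `[0, 1]`, any array shape.
#' @param X ground truth of the same shape.
#' @param epsilon smoothing constant (default `1e-4`).
#' @return scalar in `[0, 1]`.
#' @export
dice_loss <- function(Y, X, epsilon = 1e-4) {
  if (!identical(dim(Y) %||% length(Y), dim(X) %||% length(X)))
    stop("shape mismatch between Y and X")
  1 - (2 * sum(Y * X) + epsilon) / (sum(Y) + sum(X) + epsilon)
}

dice_grad <- function(Y, X, epsilon = 1e-4) {
  S <- sum(Y * X); D <- sum(Y) + sum(X) + epsilon
  -(2 * X * D - (2 * S + epsilon)) / D^2
}

# 5x5 (or 3x3) Sobel kernels: smoothing x derivative separable product,
# normalized so the response to a unit ramp is 1 (i.e. the filter estimates
# the derivative itself, keeping the gradient loss on the scale of squared
# slopes).
sobel_kernels <- function(ksize = 5L) {
  if (ksize == 3L) {
    sm <- c(1, 2, 1); dv <- c(-1, 0, 1)
  } else if (ksize == 5L) {
    sm <- c(1, 4, 6, 4, 1); dv <- c(-1, -2, 0, 2, 1)
  } else stop("sobel_ksize must be 3 or 5")
  half <- ksize %/% 2
  norm <- sum(sm) * sum(dv * seq(-half, half))
  list(kx = outer(sm, dv) / norm, ky = outer(dv, sm) / norm)  # kx: d/dx
}

# Cross-correlate each (H, W [, N]) plane with a small kernel, same padding.
filter2d <- function(x, kern) {
  d <- dim(x)
  if (length(d) == 2) d <- c(d, 1L)
  xx <- array(x, dim = c(d[1], d[2], 1L, d[3]))
  w <- array(kern, dim = c(nrow(kern), ncol(kern), 1L, 1L))
  y <- conv2d_fw(xx, w, 1L, as.integer(nrow(kern) %/% 2), 1L)
  array(y, dim = dim(x))
}

# Adjoint of filter2d (correlation with the 180-degree rotated kernel).
filter2d_adj <- function(x, kern) {
  filter2d(x, kern[rev(seq_len(nrow(kern))), rev(seq_len(ncol(kern)))])
}

#' Mean squared error of the HV regression
#'
#' @param p predicted HV map, `H x W x 2` (optionally batched `H x W x 2 x N`).
#' @param gamma ground-truth HV map of the same shape.
#' @return scalar mean squared difference over all pixels and channels.
#' @export
hv_mse_loss <- function(p, gamma) {
  if (!identical(dim(p), dim(gamma))) stop("shape mismatch")
  mean((p - gamma)^2)
}

#' Mean squared gradient error of the HV regression
#'
#' Compares Sobel derivatives instead of raw values: the horizontal Sobel
#' response of the horizontal channel difference and the vertical response of
#' the vertical channel difference, averaged over the ground-truth nuclei
#' pixels. Constant offsets between `p` and `gamma` vanish here, so this term
#' specifically penalizes distorted within-instance ramps — the structure the
#' watershed separation depends on.
#'
#' @param p,gamma HV maps `H x W x 2` (optionally `H x W x 2 x N`).
#' @param mask binary nuclei mask `H x W` (`H x W x N`); an empty mask gives 0.
#' @param sobel_ksize Sobel kernel size (3 or 5).
#' @return non-negative scalar.
#' @export
hv_msge_loss <- function(p, gamma, mask, sobel_ksize = 5L) {
  if (!identical(dim(p), dim(gamma))) stop("shape mismatch")
  m <- sum(mask)
  if (m == 0) return(0)
  kk <- sobel_kernels(sobel_ksize)
  d <- p - gamma
  dh <- hv_channel(d, 1L)
  dv <- hv_channel(d, 2L)
  gx <- filter2d(dh, kk$kx)
  gy <- filter2d(dv, kk$ky)
  sum(mask * gx^2) / m + sum(mask * gy^2) / m
}

# extract one HV channel keeping the (H, W [, N]) shape of the mask
hv_channel <- function(d, ch) {
  nd <- length(dim(d))
  if (nd == 3) return(d[, , ch])
  out <- d[, , ch, , drop = FALSE]
  dim(out) <- dim(d)[c(1, 2, 4)]
  out
}

# Gradient of hv_msge_loss w.r.t. p; returns an array shaped like p.
hv_msge_grad <- function(p, gamma, mask, sobel_ksize = 5L) {
  g <- p * 0
  m <- sum(mask)
  if (m == 0) return(g)
  kk <- sobel_kernels(sobel_ksize)
  d <- p - gamma
  dh <- hv_channel(d, 1L)
  dv <- hv_channel(d, 2L)
  gx <- filter2d(dh, kk$kx)
  gy <- filter2d(dv, kk$ky)
  ah <- filter2d_adj(mask * gx, kk$kx) * (2 / m)
  av <- filter2d_adj(mask * gy, kk$ky) * (2 / m)
  if (length(dim(p)) == 3) {
    g[, , 1] <- ah; g[, , 2] <- av
  } else {
    g[, , 1, ] <- ah; g[, , 2, ] <- av
  }
  g
}

#' Joint multi-task loss
#'
#' Weighted sum of the six loss components with a per-term breakdown. `q` is
#' evaluated channel-wise as a 2-channel (background, foreground) problem for
#' BCE and on the foreground channel for Dice; `r` uses all `K + 1` channels
#' for both.
#'
#' @param outputs list with `q` (foreground probability, `H x W [x N]`), `p`
#'   (HV map `H x W x 2 [x N]`), and optionally `r` (type probabilities
#'   `H x W x (K+1) [x N]`), as returned by [network_forward()].
#' @param targets list with `mask` (binary `H x W [x N]`), `hv`
#'   (`H x W x 2 [x N]`), and optionally `types` (one-hot
#'   `H x W x (K+1) [x N]`).
#' @param w a [loss_weights()].
#' @param sobel_ksize Sobel kernel size for the MSGE term.
#' @return list with `total` and `terms` (named per-component values).
#' @export
joint_loss <- function(outputs, targets, w = loss_weights(), sobel_ksize = 5L) {
  stopifnot(inherits(w, "loss_weights"))
  q <- outputs$q; mask <- targets$mask
  q2 <- c(1 - q, q); x2 <- c(1 - mask, mask)
  terms <- c(
    bce_nss = bce_loss(q2, x2),
    dice_nss = dice_loss(q, mask, w$epsilon),
    mse_hv = hv_mse_loss(outputs$p, targets$hv),
    msge_hv = hv_msge_loss(outputs$p, targets$hv, mask, sobel_ksize)
  )
  if (!is.null(outputs$r)) {
    terms <- c(terms,
               bce_nc = bce_loss(outputs$r, targets$types),
               dice_nc = dice_loss(outputs$r, targets$types, w$epsilon))
  }
  lam <- c(w$lambda_a, w$lambda_b, w$lambda_c, w$lambda_d, w$lambda_e,
           w$lambda_f)[seq_along(terms)]
  list(total = sum(lam * terms), terms = terms)
}

# Loss + gradients w.r.t. the raw branch outputs (full softmax arrays for
# nss/nc, tanh array for hv); used by the training loop.
joint_loss_backward <- function(outs, targets, w, sobel_ksize = 5L) {
  nss <- outs$nss                       # (H, W, 2, N)
  X2 <- targets$mask2                   # (H, W, 2, N) one-hot bg/fg
  fg <- nss[, , 2, , drop = FALSE]
  fgx <- X2[, , 2, , drop = FALSE]

  l_bce_q <- bce_loss(nss, X2)
  l_dice_q <- dice_loss(fg, fgx, w$epsilon)
  dnss <- w$lambda_a * bce_grad(nss, X2)
  dnss[, , 2, ] <- dnss[, , 2, ] +
    as.vector(w$lambda_b * dice_grad(fg, fgx, w$epsilon))

  mask <- targets$mask                  # (H, W, N)
  l_mse <- hv_mse_loss(outs$hv, targets$hv)
  l_msge <- hv_msge_loss(outs$hv, targets$hv, mask, sobel_ksize)
  dhv <- w$lambda_c * 2 * (outs$hv - targets$hv) / length(outs$hv) +
    w$lambda_d * hv_msge_grad(outs$hv, targets$hv, mask, sobel_ksize)

  terms <- c(bce_nss = l_bce_q, dice_nss = l_dice_q, mse_hv = l_mse,
             msge_hv = l_msge)
  douts <- list(nss = dnss, hv = dhv)
  if (!is.null(outs$nc)) {
    l_bce_r <- bce_loss(outs$nc, targets$types)
    l_dice_r <- dice_loss(outs$nc, targets$types, w$epsilon)
    douts$nc <- w$lambda_e * bce_grad(outs$nc, targets$types) +
      w$lambda_f * dice_grad(outs$nc, targets$types, w$epsilon)
    terms <- c(terms, bce_nc = l_bce_r, dice_nc = l_dice_r)
  }
  lam <- c(w$lambda_a, w$lambda_b, w$lambda_c, w$lambda_d, w$lambda_e,
           w$lambda_f)[seq_along(terms)]
  list(total = sum(lam * terms), terms = terms, douts = douts)
}
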