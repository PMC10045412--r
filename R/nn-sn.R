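# Switchable normalization (SN). Each layer learns softmax-weighted convex
# mixtures of the instance (IN), layer (LN), and batch (BN) first and second
# moments, then applies a single affine normalization:
#   y = gamma * (x - sum_k w_k mu_k) / sqrt(sum_k w'_k s2_k + eps) + beta,
# k in {IN, LN, BN}. Because the mixture can lean on IN/LN statistics, the
# layer stays stable when the minibatch is as small as a single patch.
#
# Implementation note: every pooled statistic is constant within one
# (channel, sample) block, so the whole layer reduces to per-(c, n) affine
# tables applied by the compiled cn_affine kernels; the backward pass needs
# only the per-block sums of dy and dy * x.

softmax3 <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# broadcast a per-sample (length N) / per-channel (length C) vector to a
# C x N table
tab_ln <- function(v, C, N) matrix(rep(v, each = C), C, N)
tab_bn <- function(v, C, N) matrix(v, C, N)

nn_sn <- function(C, eps = 1e-5, momentum = 0.9) {
  self <- new.env(parent = emptyenv())
  self$gamma <- new_param(rep(1, C))
  self$beta <- new_param(rep(0, C))
  self$mean_logits <- new_param(rep(0, 3))
  self$var_logits <- new_param(rep(0, 3))
  self$run_mean <- rep(0, C)
  self$run_var <- rep(1, C)
  self$eps <- eps
  self$momentum <- momentum
  self$params <- list(self$gamma, self$beta, self$mean_logits, self$var_logits)
  self$children <- list()

  self$forward <- function(x, training = TRUE) {
    d <- dim(x)
    HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
    ss <- cn_sums_sq(x)
    mu_in <- ss$s1 / HW
    e2_in <- ss$s2 / HW
    mu_ln <- colMeans(mu_in); e2_ln <- colMeans(e2_in)
    s2_in <- e2_in - mu_in^2
    s2_ln <- e2_ln - mu_ln^2
    if (training) {
      mu_bn <- rowMeans(mu_in)
      s2_bn <- rowMeans(e2_in) - mu_bn^2
      self$run_mean <- self$momentum * self$run_mean + (1 - self$momentum) * mu_bn
      self$run_var <- self$momentum * self$run_var + (1 - self$momentum) * s2_bn
    } else {
      mu_bn <- self$run_mean
      s2_bn <- self$run_var
    }
    w <- softmax3(self$mean_logits$value)
    wp <- softmax3(self$var_logits$value)
    Mcn <- w[1] * mu_in + tab_ln(w[2] * mu_ln, C, N) + tab_bn(w[3] * mu_bn, C, N)
    Vcn <- wp[1] * s2_in + tab_ln(wp[2] * s2_ln, C, N) +
      tab_bn(wp[3] * s2_bn, C, N)
    inv_cn <- 1 / sqrt(Vcn + self$eps)
    g <- self$gamma$value
    y <- cn_affine(x, g * inv_cn, self$beta$value - g * inv_cn * Mcn)
    if (training)
      self$cache <- list(x = x, Mcn = Mcn, inv_cn = inv_cn, d = d,
                         mu_in = mu_in, mu_ln = mu_ln, mu_bn = mu_bn,
                         s2_in = s2_in, s2_ln = s2_ln, s2_bn = s2_bn,
                         w = w, wp = wp)
    y
  }

  self$backward <- function(dy) {
    cc <- self$cache
    d <- cc$d
    HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
    g <- self$gamma$value
    inv <- cc$inv_cn
    sp <- cn_sums_prod(dy, cc$x)
    S_dy <- sp$sa
    Sc_dy <- sp$sab - cc$Mcn * S_dy  # sum of dy * (x - M) per (c, n)

    self$gamma$grad <- self$gamma$grad + rowSums(inv * Sc_dy)
    self$beta$grad <- self$beta$grad + rowSums(S_dy)

    # pooled means of dL/d(mean) and dL/d(variance); constants per (c, n)
    dm_cn <- -(g * inv) * S_dy / HW
    dv_cn <- -0.5 * g * inv^3 * Sc_dy / HW
    dm_ln <- colMeans(dm_cn); dm_bn <- rowMeans(dm_cn)
    dv_ln <- colMeans(dv_cn); dv_bn <- rowMeans(dv_cn)

    w <- cc$w; wp <- cc$wp
    A <- w[1] * dm_cn + tab_ln(w[2] * dm_ln, C, N) + tab_bn(w[3] * dm_bn, C, N)
    B <- 2 * (wp[1] * dv_cn + tab_ln(wp[2] * dv_ln, C, N) +
                tab_bn(wp[3] * dv_bn, C, N))
    D <- -2 * (wp[1] * cc$mu_in * dv_cn +
                 tab_ln(wp[2] * cc$mu_ln * dv_ln, C, N) +
                 tab_bn(wp[3] * cc$mu_bn * dv_bn, C, N))
    dx <- cn_affine2(dy, g * inv, cc$x, B, A + D)

    dlw <- HW * c(sum(dm_cn * cc$mu_in),
                  sum(colSums(dm_cn) * cc$mu_ln),
                  sum(rowSums(dm_cn) * cc$mu_bn))
    dlwp <- HW * c(sum(dv_cn * cc$s2_in),
                   sum(colSums(dv_cn) * cc$s2_ln),
                   sum(rowSums(dv_cn) * cc$s2_bn))
    self$mean_logits$grad <- self$mean_logits$grad + w * (dlw - sum(w * dlw))
    self$var_logits$grad <- self$var_logits$grad + wp * (dlwp - sum(wp * dlwp))

    self$cache <- NULL
    dx
  }
  self
}

#' Switchable normalization forward pass
#'
#' Normalizes a feature tensor with a learned convex mixture of instance
#' (per channel and sample), layer (per sample), and batch (per channel)
#' statistics. Mixture weights are softmax transforms of two logit triplets,
#' one for the means and one for the variances, so a layer can interpolate
#' between IN, LN, and BN behaviour; this keeps normalization stable for
#' batch sizes as small as 1.
#'
#' @param x numeric array of features, laid out `(H, W, C, N)`.
#' @param gamma,beta per-channel scale and shift (length `C`).
#' @param mean_logits,var_logits length-3 logits ordered (IN, LN, BN);
#'   their softmax gives the mixture weights for the means and variances.
#' @param eps variance floor added before the square root.
#' @param training logical; if `FALSE`, batch statistics are taken from
#'   `running_mean`/`running_var` instead of the minibatch.
#' @param running_mean,running_var per-channel moments used for the BN
#'   component in inference mode.
#' @return array of the same dimensions as `x`.
#' @examples
#' x <- array(rnorm(2 * 3 * 4 * 4), dim = c(4, 4, 3, 2))
#' y <- sn_forward(x, gamma = rep(1, 3), beta = rep(0, 3))
#' dim(y)
#' @export
sn_forward <- function(x, gamma, beta, mean_logits = c(0, 0, 0),
                       var_logits = c(0, 0, 0), eps = 1e-5, training = TRUE,
                       running_mean = NULL, running_var = NULL) {
  stopifnot(length(dim(x)) == 4, length(mean_logits) == 3,
            length(var_logits) == 3, eps > 0)
  C <- dim(x)[3]
  stopifnot(length(gamma) == C, length(beta) == C)
  layer <- nn_sn(C, eps = eps)
  layer$gamma$value <- gamma
  layer$beta$value <- beta
  layer$mean_logits$value <- mean_logits
  layer$var_logits$value <- var_logits
  if (!training) {
    if (is.null(running_mean) || is.null(running_var))
      stop("inference mode needs running_mean and running_var")
    layer$run_mean <- running_mean
    layer$run_var <- running_var
  }
  layer$forward(x, training = training)
}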