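# Building blocks: Ghost-Block-SN (GBS), Residual-Ghost-SN (RGS),
# Residual-Ghost-Module (RGM), Dense-Ghost-SN (DGS), Dense-Ghost-Module
# (DGM), and the Conv-SN-ReLU (CSR) stem.

#' Ghost convolution block configuration
#'
#' A ghost block produces `out_channels / ratio` "intrinsic" feature maps with
#' an ordinary (default 1x1 point-wise) convolution and expands them to the
#' full width with a cheap depthwise convolution, so most output channels cost
#' only `cheap_kernel^2` weights each instead of `in_channels` multiplies.
#'
#' @param in_channels,out_channels input/output channel counts.
#' @param ratio integer `s >= 2`; fraction of channels produced by the primary
#'   convolution is `out_channels / s`. Must divide `out_channels`.
#' @param primary_kernel kernel size of the ordinary convolution (default 1).
#' @param cheap_kernel kernel size of the depthwise expansion (default 3).
#' @return a list of class `"ghost_config"`.
#' @seealso [ghost_param_count()]
#' @export
ghost_config <- function(in_channels, out_channels, ratio = 2L,
                         primary_kernel = 1L, cheap_kernel = 3L) {
  stopifnot(in_channels >= 1, out_channels >= 1, ratio >= 2)
  if (out_channels %% ratio != 0)
    stop("out_channels must be divisible by ratio")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 ratio = as.integer(ratio),
                 primary_kernel = as.integer(primary_kernel),
                 cheap_kernel = as.integer(cheap_kernel)),
            class = "ghost_config")
}

#' Ghost block convolution weight count
#'
#' Closed form `C*O/s * k_p^2 + (s-1)/s * O * k_c^2` for the convolution
#' weights of a ghost block (bias-free), against `C * O * k_p^2` for the
#' ordinary convolution it replaces.
#'
#' @param cfg a [ghost_config()].
#' @return named numeric vector with elements `ghost` and `ordinary`.
#' @examples
#' ghost_param_count(ghost_config(64, 128))
#' @export
ghost_param_count <- function(cfg) {
  stopifnot(inherits(cfg, "ghost_config"))
  intrinsic <- cfg$out_channels %/% cfg$ratio
  c(ghost = cfg$in_channels * intrinsic * cfg$primary_kernel^2 +
      (cfg$out_channels - intrinsic) * cfg$cheap_kernel^2,
    ordinary = cfg$in_channels * cfg$out_channels * cfg$primary_kernel^2)
}

# Ghost-Block-SN. Primary conv -> cheap depthwise expansion -> concat -> SN
# (-> ReLU). The cheap conv maps each intrinsic channel to (ratio - 1) ghost
# channels via a grouped depthwise convolution.
nn_gbs <- function(cfg, relu = TRUE) {
  intrinsic <- cfg$out_channels %/% cfg$ratio
  ghost <- cfg$out_channels - intrinsic
  self <- new.env(parent = emptyenv())
  self$cfg <- cfg
  self$intrinsic <- intrinsic
  self$primary <- nn_conv(cfg$in_channels, intrinsic, cfg$primary_kernel)
  self$cheap <- nn_conv(intrinsic, ghost, cfg$cheap_kernel, groups = intrinsic)
  self$sn <- nn_sn(cfg$out_channels)
  self$relu <- if (relu) nn_relu() else NULL
  self$params <- list()
  self$children <- c(list(self$primary, self$cheap, self$sn),
                     if (relu) list(self$relu))
  self$forward <- function(x, training = TRUE) {
    a <- self$primary$forward(x, training)
    b <- self$cheap$forward(a, training)
    y <- self$sn$forward(cat_channels(list(a, b)), training)
    if (!is.null(self$relu)) y <- self$relu$forward(y, training)
    y
  }
  self$backward <- function(dy) {
    if (!is.null(self$relu)) dy <- self$relu$backward(dy)
    dcat <- self$sn$backward(dy)
    parts <- split_channels(dcat, c(self$intrinsic, dim(dcat)[3] - self$intrinsic))
    da <- parts[[1]] + self$cheap$backward(parts[[2]])
    self$primary$backward(da)
  }
  self
}

# Residual-Ghost-SN: a bottleneck of two point-wise ghost blocks around a
# 3x3 depthwise stage that carries the stride, with an identity (or
# 1x1-projected) shortcut; ReLU after the addition (ResNet convention).
nn_rgs <- function(in_ch, out_ch, stride = 1L, ratio = 2L) {
  mid <- max(2L, 2L * (out_ch %/% 4L))
  self <- new.env(parent = emptyenv())
  self$gbs1 <- nn_gbs(ghost_config(in_ch, mid, ratio), relu = TRUE)
  self$dw <- nn_conv(mid, mid, 3L, stride = stride, groups = mid)
  self$dw_sn <- nn_sn(mid)
  self$dw_relu <- nn_relu()
  self$gbs2 <- nn_gbs(ghost_config(mid, out_ch, ratio), relu = FALSE)
  self$project <- stride != 1L || in_ch != out_ch
  if (self$project) {
    self$proj <- nn_conv(in_ch, out_ch, 1L, stride = stride, pad = 0L)
    self$proj_sn <- nn_sn(out_ch)
  }
  self$out_relu <- nn_relu()
  self$params <- list()
  self$children <- c(list(self$gbs1, self$dw, self$dw_sn, self$dw_relu,
                          self$gbs2, self$out_relu),
                     if (self$project) list(self$proj, self$proj_sn))
  self$forward <- function(x, training = TRUE) {
    h <- self$gbs1$forward(x, training)
    h <- self$dw_relu$forward(
      self$dw_sn$forward(self$dw$forward(h, training), training), training)
    h <- self$gbs2$forward(h, training)
    s <- if (self$project)
      self$proj_sn$forward(self$proj$forward(x, training), training)
    else x
    self$out_relu$forward(h + s, training)
  }
  self$backward <- function(dy) {
    dsum <- self$out_relu$backward(dy)
    dh <- self$gbs2$backward(dsum)
    dh <- self$dw$backward(self$dw_sn$backward(self$dw_relu$backward(dh)))
    dx <- self$gbs1$backward(dh)
    if (self$project)
      dx <- dx + self$proj$backward(self$proj_sn$backward(dsum))
    else dx <- dx + dsum
    dx
  }
  self
}

# Residual-Ghost-Module: a stack of RGS; the first block carries the module's
# stride and channel change.
nn_rgm <- function(in_ch, out_ch, n_rgs, stride = 1L) {
  blocks <- vector("list", n_rgs)
  blocks[[1]] <- nn_rgs(in_ch, out_ch, stride = stride)
  if (n_rgs > 1)
    for (i in 2:n_rgs) blocks[[i]] <- nn_rgs(out_ch, out_ch, stride = 1L)
  do.call(nn_seq, blocks)
}

# Conv-SN-ReLU.
nn_csr <- function(in_ch, out_ch, k = 3L, stride = 1L) {
  nn_seq(nn_conv(in_ch, out_ch, k, stride = stride), nn_sn(out_ch), nn_relu())
}

# Dense-Ghost-SN: one ghost block emitting `growth` channels; the dense
# concatenation wiring lives in the module below.
nn_dgs <- function(in_ch, growth) {
  nn_gbs(ghost_config(in_ch, growth), relu = TRUE)
}

# Dense-Ghost-Module: each DGS consumes the module input concatenated with
# every previous DGS output; module output is the concatenation of all of
# them (in + n * growth channels).
nn_dgm <- function(in_ch, n, growth) {
  self <- new.env(parent = emptyenv())
  self$in_ch <- as.integer(in_ch)
  self$n <- as.integer(n)
  self$growth <- as.integer(growth)
  self$dgs <- lapply(seq_len(n), function(t)
    nn_dgs(in_ch + (t - 1L) * growth, growth))
  self$params <- list()
  self$children <- self$dgs
  self$forward <- function(x, training = TRUE) {
    feats <- list(x)
    for (t in seq_len(self$n)) {
      inp <- if (t == 1) x else cat_channels(feats)
      feats[[t + 1L]] <- self$dgs[[t]]$forward(inp, training)
    }
    cat_channels(feats)
  }
  self$backward <- function(dy) {
    sizes <- c(self$in_ch, rep(self$growth, self$n))
    dacc <- split_channels(dy, sizes)
    for (t in rev(seq_len(self$n))) {
      dcat <- self$dgs[[t]]$backward(dacc[[t + 1L]])
      if (t == 1) {
        dacc[[1]] <- dacc[[1]] + dcat
      } else {
        parts <- split_channels(dcat, sizes[seq_len(t)])
        for (i in seq_len(t)) dacc[[i]] <- dacc[[i]] + parts[[i]]
      }
    }
    dacc[[1]]
  }
  self
}
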