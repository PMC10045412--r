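# Encoder-decoder assembly. Encoder: CSR stem -> 4 RGMs (1, 2, 3, 1 RGS;
# strides 1, 2, 2, 2, so x8 down) -> 1x1 bottleneck conv. Decoder: three
# structurally identical branches (NSS, HV, NC), each three x2 nearest-
# neighbour upsampling steps with skip concatenations from the encoder
# stages; a Dense-Ghost-Module with 8 DGS follows the first upsampling and
# one with 4 DGS the second.

#' Network stage specification
#'
#' Structural hyper-parameters of the encoder-decoder: how many
#' Residual-Ghost-SN blocks each encoder stage stacks, the stage widths, the
#' number of Dense-Ghost-SN blocks in the two decoder dense modules, and the
#' dense growth rate.
#'
#' @param rgs_counts integer(4); RGS per encoder stage.
#' @param stage_channels integer(4); channels of the four encoder stages.
#' @param dgm_counts integer(2); DGS in the first and second decoder DGM.
#' @param growth dense growth rate (channels emitted per DGS).
#' @return a list of class `"stage_spec"`.
#' @export
stage_spec <- function(rgs_counts = c(1L, 2L, 3L, 1L),
                       stage_channels = c(64L, 128L, 256L, 512L),
                       dgm_counts = c(8L, 4L), growth = 32L) {
  stopifnot(length(rgs_counts) == 4, all(rgs_counts >= 1),
            length(stage_channels) == 4, all(stage_channels %% 2 == 0),
            length(dgm_counts) == 2, all(dgm_counts >= 1),
            growth %% 2 == 0, growth >= 2)
  structure(list(rgs_counts = as.integer(rgs_counts),
                 stage_channels = as.integer(stage_channels),
                 dgm_counts = as.integer(dgm_counts),
                 growth = as.integer(growth)),
            class = "stage_spec")
}

# One decoder branch; head_act is "softmax" or "tanh".
nn_branch <- function(spec, out_ch, head_act) {
  ch <- spec$stage_channels
  g <- spec$growth
  nd <- spec$dgm_counts
  self <- new.env(parent = emptyenv())
  self$up1 <- nn_upsample2()
  self$uc1 <- nn_csr(ch[4], ch[3], 3L)
  self$dgm1 <- nn_dgm(2L * ch[3], nd[1], g)
  self$tr1 <- nn_csr(2L * ch[3] + nd[1] * g, ch[3], 1L)
  self$up2 <- nn_upsample2()
  self$uc2 <- nn_csr(ch[3], ch[2], 3L)
  self$dgm2 <- nn_dgm(2L * ch[2], nd[2], g)
  self$tr2 <- nn_csr(2L * ch[2] + nd[2] * g, ch[2], 1L)
  self$up3 <- nn_upsample2()
  self$uc3 <- nn_csr(ch[2], ch[1], 3L)
  self$fuse <- nn_csr(2L * ch[1], ch[1], 3L)
  self$head <- nn_conv(ch[1], out_ch, 1L, pad = 0L)
  self$act <- if (head_act == "softmax") nn_softmax() else nn_tanh()
  self$ch <- ch
  self$params <- list()
  self$children <- list(self$up1, self$uc1, self$dgm1, self$tr1, self$up2,
                        self$uc2, self$dgm2, self$tr2, self$up3, self$uc3,
                        self$fuse, self$head, self$act)
  self$forward <- function(d0, skips, training = TRUE) {
    a <- self$uc1$forward(self$up1$forward(d0, training), training)
    a <- self$tr1$forward(
      self$dgm1$forward(cat_channels(list(a, skips[[3]])), training), training)
    a <- self$uc2$forward(self$up2$forward(a, training), training)
    a <- self$tr2$forward(
      self$dgm2$forward(cat_channels(list(a, skips[[2]])), training), training)
    a <- self$uc3$forward(self$up3$forward(a, training), training)
    a <- self$fuse$forward(cat_channels(list(a, skips[[1]])), training)
    self$act$forward(self$head$forward(a, training), training)
  }
  self$backward <- function(dy) {
    ch <- self$ch
    da <- self$head$backward(self$act$backward(dy))
    parts <- split_channels(self$fuse$backward(da), c(ch[1], ch[1]))
    dskip1 <- parts[[2]]
    da <- self$up3$backward(self$uc3$backward(parts[[1]]))
    parts <- split_channels(self$dgm2$backward(self$tr2$backward(da)),
                            c(ch[2], ch[2]))
    dskip2 <- parts[[2]]
    da <- self$up2$backward(self$uc2$backward(parts[[1]]))
    parts <- split_channels(self$dgm1$backward(self$tr1$backward(da)),
                            c(ch[3], ch[3]))
    dskip3 <- parts[[2]]
    dd0 <- self$up1$backward(self$uc1$backward(parts[[1]]))
    list(dd0 = dd0, dskips = list(dskip1, dskip2, dskip3))
  }
  self
}

#' Build the nuclei segmentation/classification network
#'
#' Assembles the multi-task encoder-decoder. The encoder is a Conv-SN-ReLU
#' stem followed by four Residual-Ghost-Modules stacking 1, 2, 3, and 1
#' Residual-Ghost-SN blocks (strides 1, 2, 2, 2) and a 1x1 bottleneck
#' convolution. Each decoder branch upsamples x2 three times with skip
#' concatenations from the first three encoder stages and Dense-Ghost-Modules
#' of 8 and 4 blocks after the first and second upsampling. The NSS branch
#' ends in a 2-channel softmax (nuclei probability), the HV branch in a
#' 2-channel tanh (bounded signed distances), and the optional NC branch in a
#' `(n_types + 1)`-channel softmax.
#'
#' @param n_types number of nucleus classes (background excluded).
#' @param spec a [stage_spec()].
#' @param with_classification include the NC branch? When `FALSE` the network
#'   is the segmentation-only variant with two output heads.
#' @param in_channels image channels (3 for RGB).
#' @return an object of class `"gsn_network"`: an environment with
#'   `forward`/`backward` closures and the parameter tree. Use
#'   [network_forward()] for a plain functional interface and
#'   [n_parameters()] via `attr` or `summary` of a fitted model for sizes.
#' @export
gsn_network <- function(n_types = 3L, spec = stage_spec(),
                        with_classification = TRUE, in_channels = 3L) {
  stopifnot(n_types >= 1)
  ch <- spec$stage_channels
  self <- new.env(parent = emptyenv())
  self$spec <- spec
  self$n_types <- as.integer(n_types)
  self$with_classification <- isTRUE(with_classification)
  self$csr <- nn_csr(in_channels, ch[1], 3L)
  self$rgm1 <- nn_rgm(ch[1], ch[1], spec$rgs_counts[1], stride = 1L)
  self$rgm2 <- nn_rgm(ch[1], ch[2], spec$rgs_counts[2], stride = 2L)
  self$rgm3 <- nn_rgm(ch[2], ch[3], spec$rgs_counts[3], stride = 2L)
  self$rgm4 <- nn_rgm(ch[3], ch[4], spec$rgs_counts[4], stride = 2L)
  self$bottleneck <- nn_conv(ch[4], ch[4], 1L, pad = 0L)
  self$branches <- list(nss = nn_branch(spec, 2L, "softmax"),
                        hv = nn_branch(spec, 2L, "tanh"))
  if (self$with_classification)
    self$branches$nc <- nn_branch(spec, n_types + 1L, "softmax")
  self$params <- list()
  self$children <- c(list(self$csr, self$rgm1, self$rgm2, self$rgm3,
                          self$rgm4, self$bottleneck), self$branches)

  self$forward <- function(x, training = TRUE) {
    d <- dim(x)
    if (d[1] %% 8 != 0 || d[2] %% 8 != 0)
      stop("input height and width must be divisible by 8")
    s1 <- self$rgm1$forward(self$csr$forward(x, training), training)
    s2 <- self$rgm2$forward(s1, training)
    s3 <- self$rgm3$forward(s2, training)
    d0 <- self$bottleneck$forward(self$rgm4$forward(s3, training), training)
    skips <- list(s1, s2, s3)
    out <- lapply(self$branches, function(b) b$forward(d0, skips, training))
    out
  }

  # douts: named list of gradients w.r.t. each branch output.
  self$backward <- function(douts) {
    dd0 <- NULL
    dskips <- NULL
    for (nm in names(self$branches)) {
      g <- self$branches[[nm]]$backward(douts[[nm]])
      if (is.null(dd0)) {
        dd0 <- g$dd0
        dskips <- g$dskips
      } else {
        dd0 <- dd0 + g$dd0
        for (i in 1:3) dskips[[i]] <- dskips[[i]] + g$dskips[[i]]
      }
    }
    de4 <- self$bottleneck$backward(dd0)
    ds3 <- self$rgm4$backward(de4) + dskips[[3]]
    ds2 <- self$rgm3$backward(ds3) + dskips[[2]]
    ds1 <- self$rgm2$backward(ds2) + dskips[[1]]
    self$csr$backward(self$rgm1$backward(ds1))
  }
  class(self) <- c("gsn_network", "environment")
  self
}

#' Run the network on image patches
#'
#' Functional forward pass. In inference mode (`training = FALSE`) the
#' batch-normalization component of every switchable-normalization layer uses
#' its running moments, so repeated calls on the same input are identical.
#'
#' @param net a `"gsn_network"` (or a fitted `"gsn_hvnet"` model, whose
#'   network is used).
#' @param images numeric array `(H, W, 3)` or `(H, W, 3, N)` with values in
#'   `[0, 1]`; `H` and `W` must be divisible by 8.
#' @param training logical; training mode uses minibatch statistics.
#' @return list with elements `q` (`H x W x N` foreground nuclei probability),
#'   `p` (`H x W x 2 x N` HV regression, in `[-1, 1]`), and — when the network
#'   has a classification branch — `r` (`H x W x (K+1) x N` type
#'   probabilities, channel 1 = background).
#' @export
network_forward <- function(net, images, training = FALSE) {
  if (inherits(net, "gsn_hvnet")) net <- net$network
  stopifnot(inherits(net, "gsn_network"))
  if (length(dim(images)) == 3) dim(images) <- c(dim(images), 1L)
  out <- net$forward(images, training = training)
  res <- list(q = out$nss[, , 2, , drop = TRUE], p = out$hv)
  if (!is.null(out$nc)) res$r <- out$nc
  res
}
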