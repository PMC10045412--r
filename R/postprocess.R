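# From network outputs (q, p) to instances: Sobel gradient magnitude of the
# HV map -> marker = high-probability pixels minus high-gradient boundary
# band -> binary energy landscape -> marker-controlled watershed restricted
# to the thresholded foreground; then per-instance majority vote over the NC
# probabilities.

#' Post-processing parameters
#'
#' @param h threshold on the nuclei probability map `q` (foreground =
#'   `q > h`).
#' @param k threshold on the HV gradient map `Sm`; pixels with `Sm > k` form
#'   the boundary band suppressed from the markers.
#' @param min_object_px marker components smaller than this are discarded as
#'   speckle before seeding the watershed.
#' @param sobel_ksize Sobel kernel size used for the gradient map (3 or 5).
#' @param hv_blur box-blur size applied to the HV map before the gradient
#'   map (odd; 1 disables). Denoises regression noise in predicted maps so
#'   the boundary band does not drown in it; the instance-boundary jumps
#'   survive the averaging.
#' @param continuous_energy if `TRUE`, the energy landscape carries the
#'   continuous `q` values inside the foreground instead of the binary
#'   indicator.
#' @return list of class `"postprocess_params"`.
#' @export
postprocess_params <- function(h = 0.5, k = 0.4, min_object_px = 10L,
                               sobel_ksize = 5L, hv_blur = 5L,
                               continuous_energy = FALSE) {
  stopifnot(h > 0, h < 1, k > 0, k < 1, min_object_px >= 0,
            hv_blur >= 1, hv_blur %% 2 == 1)
  structure(list(h = h, k = k, min_object_px = as.integer(min_object_px),
                 sobel_ksize = as.integer(sobel_ksize),
                 hv_blur = as.integer(hv_blur),
                 continuous_energy = isTRUE(continuous_energy)),
            class = "postprocess_params")
}

# edge-replicated box blur of one plane
box_blur <- function(m, k) {
  if (k <= 1) return(m)
  half <- k %/% 2
  ri <- c(rep(1L, half), seq_len(nrow(m)), rep(nrow(m), half))
  ci <- c(rep(1L, half), seq_len(ncol(m)), rep(ncol(m), half))
  xx <- m[ri, ci]
  dim(xx) <- c(dim(xx), 1L, 1L)
  y <- conv2d_fw(xx, array(1 / (k * k), c(k, k, 1L, 1L)), 1L, 0L, 1L)
  matrix(y, nrow(m), ncol(m))
}

#' HV gradient map
#'
#' Pixel-wise maximum of the processed horizontal Sobel response of the
#' horizontal HV channel and vertical response of the vertical channel.
#' Within an instance each HV channel ramps upward, so its signed derivative
#' is positive; crossing into the next instance (or out of the nucleus on the
#' ascending side) the value drops sharply, so instance boundaries are the
#' strong negative derivatives. Each signed derivative is therefore min-max
#' rescaled to `[0, 1]` per image and inverted, putting the boundary jumps
#' near 1 and the smooth interior ramps near 0, and giving the threshold `k`
#' a fixed scale. A constant channel (zero derivative range) contributes 0.
#'
#' @param p HV map `H x W x 2` (channel 1 horizontal, channel 2 vertical).
#' @param sobel_ksize Sobel kernel size.
#' @return matrix `H x W` with values in `[0, 1]`; high along the lines where
#'   adjacent instances meet.
#' @export
hv_gradient_map <- function(p, sobel_ksize = 5L) {
  stopifnot(length(dim(p)) == 3, dim(p)[3] == 2)
  kk <- sobel_kernels(sobel_ksize)
  half <- sobel_ksize %/% 2
  # edge-replicated padding: the patch border must not masquerade as an
  # instance boundary
  pad_rep <- function(m) {
    ri <- c(rep(1L, half), seq_len(nrow(m)), rep(nrow(m), half))
    ci <- c(rep(1L, half), seq_len(ncol(m)), rep(ncol(m), half))
    m[ri, ci]
  }
  deriv <- function(m, kern) {
    xx <- pad_rep(m)
    dim(xx) <- c(dim(xx), 1L, 1L)
    y <- conv2d_fw(xx, array(kern, dim = c(sobel_ksize, sobel_ksize, 1L, 1L)),
                   1L, 0L, 1L)
    matrix(y, nrow(m), ncol(m))
  }
  boundary_response <- function(x) {
    r <- range(x)
    if (r[2] > r[1]) 1 - (x - r[1]) / (r[2] - r[1]) else x * 0
  }
  gx <- boundary_response(deriv(p[, , 1], kk$kx))
  gy <- boundary_response(deriv(p[, , 2], kk$ky))
  pmax(gx, gy)
}

#' Watershed marker
#'
#' `M = relu(tau(q, h) - tau(Sm, k))`: pixels confidently inside nuclei but
#' outside the high-gradient boundary band. Connected components of `M` seed
#' the watershed, one per nucleus when `h` and `k` are chosen sensibly.
#'
#' @param q nuclei probability map in `[0, 1]`.
#' @param Sm gradient map from [hv_gradient_map()].
#' @param h,k thresholds in `(0, 1)`.
#' @return binary 0/1 matrix.
#' @export
compute_marker <- function(q, Sm, h, k) {
  stopifnot(identical(dim(q), dim(Sm)))
  pmax((q > h) - (Sm > k), 0)
}

#' Energy landscape
#'
#' `E = (1 - tau(Sm, k)) * tau(q, h)`: 1 on confident interior pixels, 0 on
#' the boundary band and the background. The watershed floods `-E`, i.e.
#' interior first, boundary band last.
#'
#' @inheritParams compute_marker
#' @return 0/1 matrix.
#' @export
energy_landscape <- function(q, Sm, h, k) {
  stopifnot(identical(dim(q), dim(Sm)))
  (1 - (Sm > k)) * (q > h)
}

#' Instance segmentation from network outputs
#'
#' Runs the full post-processing chain: gradient map, marker extraction with
#' small-object removal, energy landscape, and a marker-controlled watershed
#' (8-connected, deterministic raster-order tie-break) restricted to the
#' thresholded foreground. Every foreground pixel is assigned to exactly one
#' instance; labels are consecutive from 1.
#'
#' @param q nuclei probability matrix `H x W`.
#' @param p HV map `H x W x 2`.
#' @param params a [postprocess_params()].
#' @return integer instance matrix (0 = background). With no markers, an
#'   empty map is returned with a warning.
#' @export
instance_segment <- function(q, p, params = postprocess_params()) {
  stopifnot(inherits(params, "postprocess_params"))
  if (params$hv_blur > 1) {
    p[, , 1] <- box_blur(p[, , 1], params$hv_blur)
    p[, , 2] <- box_blur(p[, , 2], params$hv_blur)
  }
  Sm <- hv_gradient_map(p, params$sobel_ksize)
  fg <- matrix(as.integer(q > params$h), nrow(q))
  M <- compute_marker(q, Sm, params$h, params$k)
  # 4-connected marker components: a single-pixel diagonal gap in the
  # boundary band must not fuse two nucleus cores
  markers <- cc_label(matrix(as.integer(M > 0), nrow(q)), 4L)
  if (max(markers) > 0 && params$min_object_px > 0) {
    sz <- tabulate(markers[markers > 0], nbins = max(markers))
    keep <- which(sz >= params$min_object_px)
    relab <- integer(max(markers))
    relab[keep] <- seq_along(keep)
    markers[markers > 0] <- relab[markers[markers > 0]]
  }
  if (max(markers) == 0 && any(fg > 0)) {
    # the HV gradient band can swallow every core when the HV prediction is
    # still noisy; fall back to plain connected components of the foreground
    # so the segmentation degrades to blob detection instead of emptiness
    markers <- cc_label(fg, 4L)
    if (params$min_object_px > 0 && max(markers) > 0) {
      sz <- tabulate(markers[markers > 0], nbins = max(markers))
      keep <- which(sz >= params$min_object_px)
      relab <- integer(max(markers))
      relab[keep] <- seq_along(keep)
      markers[markers > 0] <- relab[markers[markers > 0]]
    }
  }
  if (max(markers) == 0) {
    warning("no watershed markers found; returning an empty instance map")
    return(matrix(0L, nrow(q), ncol(q)))
  }
  E <- if (params$continuous_energy)
    (1 - (Sm > params$k)) * q * (q > params$h)
  else energy_landscape(q, Sm, params$h, params$k)
  # Flood in ascending (1 - E); within an altitude level, pixels with lower
  # HV gradient flood first so basins meet on the Sm ridge (the true
  # interface), with raster order as the final deterministic tie-break.
  marker_watershed((1 - E) + Sm, markers, fg)
}

#' Assign a type to each segmented instance
#'
#' Per instance, each member pixel votes for its argmax type over the
#' non-background channels of `r`; the instance takes the majority type
#' (ties broken toward the lowest class index) with the winning vote
#' fraction as confidence.
#'
#' @param instances integer instance matrix.
#' @param r type probability array `H x W x (K + 1)` (channel 1 =
#'   background).
#' @return list of class `"instance_prediction"` with `instances`, `types`
#'   (integer vector indexed by instance label), and `confidence`.
#' @export
assign_types <- function(instances, r) {
  stopifnot(length(dim(r)) == 3, dim(r)[3] >= 2,
            identical(dim(instances), dim(r)[1:2]))
  K <- dim(r)[3] - 1L
  n <- max(instances, 0L)
  pos <- which(instances > 0)
  rm <- matrix(r, ncol = K + 1L)
  pixel_type <- max.col(rm[pos, 1L + seq_len(K), drop = FALSE],
                        ties.method = "first")
  types <- integer(n)
  conf <- numeric(n)
  votes <- split(pixel_type, instances[pos])
  for (lv in names(votes)) {
    l <- as.integer(lv)
    tab <- tabulate(votes[[lv]], nbins = K)
    types[l] <- which.max(tab)
    conf[l] <- max(tab) / length(votes[[lv]])
  }
  structure(list(instances = instances, types = types, confidence = conf),
            class = "instance_prediction")
}
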