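# Training targets derived from the instance/type rasters: binary nuclei
# mask, per-instance-normalized HV distance map, and per-pixel type one-hot.

#' Horizontal/vertical distance map of an instance raster
#'
#' For each instance, every member pixel receives its signed horizontal and
#' vertical offset from the instance's unweighted mass center (x = column,
#' y = row, 0-based), normalized per instance and axis by the maximum
#' absolute offset so the values span `[-1, 1]`. Background is 0. The two
#' channels are the regression target of the HV branch; their spatial
#' gradients peak between touching instances, which is what the watershed
#' post-processing exploits.
#'
#' @param instances integer matrix, 0 = background, positive labels =
#'   distinct nuclei.
#' @return numeric array `H x W x 2`; channel 1 horizontal, channel 2
#'   vertical, values in `[-1, 1]`.
#' @examples
#' m <- matrix(0L, 5, 5); m[3, 2:4] <- 1L
#' compute_hv_map(m)[3, , 1]  # -1 0 1 across the bar
#' @export
compute_hv_map <- function(instances) {
  stopifnot(is.matrix(instances))
  H <- nrow(instances); W <- ncol(instances)
  hv <- array(0, dim = c(H, W, 2))
  pos <- which(instances > 0)
  if (!length(pos)) return(hv)
  hh <- hv[, , 1]; vv <- hv[, , 2]
  for (idx in split(pos, instances[pos])) {
    x <- (idx - 1L) %/% H  # 0-based column
    y <- (idx - 1L) %% H   # 0-based row
    dx <- x - mean(x)
    dy <- y - mean(y)
    mx <- max(abs(dx)); my <- max(abs(dy))
    hh[idx] <- if (mx > 0) dx / mx else 0
    vv[idx] <- if (my > 0) dy / my else 0
  }
  hv[, , 1] <- hh; hv[, , 2] <- vv
  hv
}

#' Binary nuclei mask from an instance raster
#'
#' @param instances integer instance matrix.
#' @return numeric 0/1 matrix of the same shape.
#' @export
binarize_instances <- function(instances) {
  stopifnot(is.matrix(instances))
  (instances > 0) * 1
}

#' Per-pixel one-hot type target
#'
#' @param types integer matrix with values in `0..n_types` (0 = background).
#' @param n_types number of nucleus classes.
#' @return numeric array `H x W x (n_types + 1)`; channel 1 is background,
#'   channel `k + 1` is type `k`. Channels sum to 1 at every pixel.
#' @export
type_target <- function(types, n_types) {
  stopifnot(is.matrix(types), n_types >= 1)
  if (any(types < 0 | types > n_types))
    stop("type values must lie in 0..n_types")
  out <- array(0, dim = c(nrow(types), ncol(types), n_types + 1L))
  for (k in 0:n_types) out[, , k + 1L] <- (types == k) * 1
  out
}

# Stack the three targets for a patch (used by the training loop).
patch_targets <- function(patch, n_types) {
  list(mask = binarize_instances(patch$instances),
       hv = compute_hv_map(patch$instances),
       types = type_target(patch$types, n_types))
}
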