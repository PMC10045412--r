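# Synthetic H&E-like patches of overlapping elliptical nuclei with instance,
# type, and (derivable) HV ground truth. The generator is the package's test
# bed: pink stroma-like background, darker purple-ish nuclei with a
# type-dependent hue, per-nucleus intensity jitter, and global Gaussian
# noise. Where nuclei overlap, each pixel belongs to the nucleus whose
# normalized ellipse distance is smallest, so contact regions are split
# along the mid-line as annotators of single-raster ground truths do and
# every pixel has exactly one owner.

#' Synthetic dataset configuration
#'
#' @param image_size patch side in pixels (square, >= 32).
#' @param n_images number of patches to generate.
#' @param n_types number of nucleus classes (default 3, emulating a
#'   three-class typing scheme plus background).
#' @param nuclei_per_image integer range `c(min, max)` of nuclei per patch.
#'   The default density (3-6 nuclei on an 80 px patch) matches what a
#'   40x-magnification H&E field of that size typically holds.
#' @param radius_range range of ellipse semi-axes in pixels (default 5-10,
#'   i.e. nucleus diameters of 10-20 px as at 40x); the maximum must stay
#'   below `image_size / 4`.
#' @param overlap_prob probability that a nucleus is seeded adjacent to an
#'   existing one, producing touching/overlapping pairs.
#' @param noise_sd standard deviation of the additive Gaussian image noise,
#'   in `[0, 1]` intensity units.
#' @param seed integer seed; the full dataset is a pure function of the
#'   configuration including this seed.
#' @return a list of class `"synth_config"`.
#' @export
synth_config <- function(image_size = 80L, n_images = 16L, n_types = 3L,
                         nuclei_per_image = c(3L, 6L),
                         radius_range = c(5, 10), overlap_prob = 0.5,
                         noise_sd = 0.03, seed = 1L) {
  stopifnot(image_size >= 32, n_images >= 1, n_types >= 1,
            length(nuclei_per_image) == 2, length(radius_range) == 2,
            overlap_prob >= 0, overlap_prob <= 1, noise_sd >= 0)
  if (nuclei_per_image[1] > nuclei_per_image[2])
    stop("nuclei_per_image must be an increasing range")
  if (radius_range[1] > radius_range[2] || radius_range[1] <= 1)
    stop("radius_range must be an increasing range with min > 1")
  if (radius_range[2] >= image_size / 4)
    stop("maximum radius must be below image_size / 4")
  structure(list(image_size = as.integer(image_size),
                 n_images = as.integer(n_images),
                 n_types = as.integer(n_types),
                 nuclei_per_image = as.integer(nuclei_per_image),
                 radius_range = as.numeric(radius_range),
                 overlap_prob = overlap_prob, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Mean stain color per nucleus type; types cycle through three purple/blue/
# red-shifted tones and darken on further cycles.
type_color <- function(type) {
  base <- list(c(0.36, 0.26, 0.58), c(0.26, 0.34, 0.64), c(0.52, 0.26, 0.46))
  tone <- base[[((type - 1) %% 3) + 1]]
  pmax(tone - 0.08 * ((type - 1) %/% 3), 0.05)
}

bg_color <- c(0.87, 0.75, 0.83)

# Squared normalized ellipse distance field: <= 1 inside the ellipse.
ellipse_dist <- function(S, cx, cy, a, b, theta) {
  dx <- matrix(rep(seq_len(S), each = S), S, S) - cx   # column index = x
  dy <- matrix(rep(seq_len(S), times = S), S, S) - cy  # row index = y
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  u * u + v * v
}

ellipse_mask <- function(S, cx, cy, a, b, theta) {
  ellipse_dist(S, cx, cy, a, b, theta) <= 1
}

# TRUE when every positive label in `lab` forms one 8-connected region of at
# least min_px pixels.
labels_intact <- function(lab, labels, min_px) {
  for (l in labels) {
    m <- lab == l
    n <- sum(m)
    if (n < min_px) return(FALSE)
    cc <- cc_label(matrix(as.integer(m), nrow(lab)), 8L)
    if (max(cc) != 1L) return(FALSE)
  }
  TRUE
}

generate_one_patch <- function(cfg, image_seed) {
  set.seed(image_seed)
  S <- cfg$image_size
  rmin <- cfg$radius_range[1]; rmax <- cfg$radius_range[2]
  n <- if (cfg$nuclei_per_image[1] == cfg$nuclei_per_image[2])
    cfg$nuclei_per_image[1]
  else sample(cfg$nuclei_per_image[1]:cfg$nuclei_per_image[2], 1L)
  min_px <- 8L

  lab <- matrix(0L, S, S)
  dist_own <- matrix(Inf, S, S)      # ellipse distance of each pixel's owner
  centers <- matrix(NA_real_, n, 2)  # (cx, cy)
  shapes <- matrix(NA_real_, n, 3)   # (a, b, theta)
  sizes <- numeric(n)
  inst_type <- integer(n)
  # radius of an ellipse (a, b, theta) along absolute direction phi
  reff <- function(a, b, theta, phi) {
    psi <- phi - theta
    a * b / sqrt((b * cos(psi))^2 + (a * sin(psi))^2)
  }

  for (j in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(80L)) {
      a <- stats::runif(1, rmin, rmax)
      b <- stats::runif(1, rmin, rmax)
      theta <- stats::runif(1, 0, pi)
      r <- max(a, b)
      near <- j > 1 && stats::runif(1) < cfg$overlap_prob && try <= 50L
      if (near) {
        # seed adjacent to an existing nucleus: center distance just at (or
        # slightly inside) the sum of the two effective radii along the
        # seeding direction, so the pair touches or overlaps shallowly
        e <- sample.int(j - 1L, 1L)
        ang <- stats::runif(1, 0, 2 * pi)
        d <- (reff(shapes[e, 1], shapes[e, 2], shapes[e, 3], ang) +
                reff(a, b, theta, ang + pi)) * stats::runif(1, 0.9, 1.02)
        cx <- centers[e, 1] + d * cos(ang)
        cy <- centers[e, 2] + d * sin(ang)
      } else {
        cx <- stats::runif(1, 1 + r, S - r)
        cy <- stats::runif(1, 1 + r, S - r)
      }
      if (cx < 1 + rmin / 2 || cx > S - rmin / 2 ||
          cy < 1 + rmin / 2 || cy > S - rmin / 2) next
      dj <- ellipse_dist(S, cx, cy, a, b, theta)
      # contested pixels go to the nucleus whose (normalized) center is
      # nearer, splitting contact regions the way annotators of single-raster
      # ground truths do, so both instances stay convex-ish
      mask <- dj <= 1 & dj < dist_own
      if (sum(mask) < min_px) next
      lab2 <- lab
      lab2[mask] <- j
      affected <- setdiff(unique(lab[mask]), 0L)
      if (labels_intact(lab2, c(affected, j), min_px)) {
        lab <- lab2
        dist_own[mask] <- dj[mask]
        centers[j, ] <- c(cx, cy)
        shapes[j, ] <- c(a, b, theta)
        sizes[j] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place nucleus ", j,
                      "; radius_range too large for image_size")
    inst_type[j] <- sample.int(cfg$n_types, 1L)
  }

  types <- matrix(0L, S, S)
  img <- array(rep(bg_color, each = S * S), dim = c(S, S, 3))
  for (j in seq_len(n)) {
    idx <- lab == j
    types[idx] <- inst_type[j]
    col <- pmin(pmax(type_color(inst_type[j]) + stats::rnorm(3, 0, 0.05), 0), 1)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[idx] <- col[ch]
      img[, , ch] <- plane
    }
  }
  if (cfg$noise_sd > 0)
    img <- img + stats::rnorm(length(img), 0, cfg$noise_sd)
  img <- pmin(pmax(img, 0), 1)

  structure(list(image = img, instances = lab, types = types),
            class = "labeled_patch")
}

#' Generate a synthetic nuclei dataset
#'
#' Renders `n_images` patches of overlapping elliptical nuclei. Instance
#' labels are consecutive `1..N` per patch, every instance is one 8-connected
#' region carrying a single type drawn uniformly from `1..n_types`, and
#' overlap regions are split between the touching nuclei by normalized
#' ellipse distance (each pixel has exactly one owner, and both instances
#' stay convex-ish as in manually annotated single-raster ground truths).
#' The RNG stream is split per image index, so patch `i` can be
#' regenerated in isolation and the whole dataset is a pure function of the
#' configuration.
#'
#' @param cfg a [synth_config()].
#' @return list of patches (class `"nuclei_dataset"`); each patch is a list
#'   with `image` (`H x W x 3` in `[0, 1]`), `instances` (integer matrix,
#'   0 = background), and `types` (integer matrix in `0..n_types`).
#' @examples
#' ds <- generate_nuclei_dataset(synth_config(n_images = 2, seed = 7))
#' table(ds[[1]]$instances > 0, ds[[1]]$types > 0)
#' @export
generate_nuclei_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  patches <- lapply(seq_len(cfg$n_images), function(i)
    generate_one_patch(cfg, image_seed = (cfg$seed + 7919L * i) %% 2147483647L))
  structure(patches, class = "nuclei_dataset", config = cfg)
}

# Count 8-adjacent pixel pairs carrying two distinct positive labels.
count_touching_pairs <- function(instances) {
  H <- nrow(instances); W <- ncol(instances)
  shifts <- list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  total <- 0L
  for (s in shifts) {
    r1 <- seq_len(H - abs(s[1])); c1 <- seq_len(W - abs(s[2]))
    r2 <- r1 + abs(s[1])
    c2 <- if (s[2] >= 0) c1 + s[2] else c1 - s[2]
    a <- instances[r1, if (s[2] < 0) c2 else c1, drop = FALSE]
    b <- instances[r2, if (s[2] < 0) c1 else c2, drop = FALSE]
    total <- total + sum(a > 0 & b > 0 & a != b)
  }
  total
}

# Inverse-mapped affine warp about the patch center; bilinear for the image,
# nearest-neighbour for the label rasters. Out-of-range pixels fall back to
# the background color estimate / label 0.
affine_warp <- function(patch, A) {
  S <- nrow(patch$instances)
  ctr <- (S + 1) / 2
  Ainv <- solve(A)
  gx <- matrix(rep(seq_len(S), each = S), S, S) - ctr  # x = column
  gy <- matrix(rep(seq_len(S), times = S), S, S) - ctr # y = row
  sx <- Ainv[1, 1] * gx + Ainv[1, 2] * gy + ctr
  sy <- Ainv[2, 1] * gx + Ainv[2, 2] * gy + ctr

  nx <- round(sx); ny <- round(sy)
  inside <- nx >= 1 & nx <= S & ny >= 1 & ny <= S
  nxc <- pmin(pmax(nx, 1), S); nyc <- pmin(pmax(ny, 1), S)
  nn_idx <- cbind(as.vector(nyc), as.vector(nxc))

  inst <- matrix(0L, S, S)
  inst[as.vector(inside)] <- patch$instances[nn_idx][as.vector(inside)]
  typ <- matrix(0L, S, S)
  typ[as.vector(inside)] <- patch$types[nn_idx][as.vector(inside)]

  bgest <- vapply(1:3, function(ch) {
    pl <- patch$image[, , ch]
    stats::median(pl[patch$instances == 0])
  }, numeric(1))
  x0 <- pmin(pmax(floor(sx), 1), S); x1 <- pmin(x0 + 1, S)
  y0 <- pmin(pmax(floor(sy), 1), S); y1 <- pmin(y0 + 1, S)
  fx <- pmin(pmax(sx - x0, 0), 1); fy <- pmin(pmax(sy - y0, 0), 1)
  img <- array(0, dim = c(S, S, 3))
  for (ch in 1:3) {
    pl <- patch$image[, , ch]
    v <- (1 - fx) * (1 - fy) * pl[cbind(as.vector(y0), as.vector(x0))] +
      fx * (1 - fy) * pl[cbind(as.vector(y0), as.vector(x1))] +
      (1 - fx) * fy * pl[cbind(as.vector(y1), as.vector(x0))] +
      fx * fy * pl[cbind(as.vector(y1), as.vector(x1))]
    v[!inside] <- bgest[ch]
    img[, , ch] <- v
  }
  structure(list(image = img, instances = inst, types = typ),
            class = "labeled_patch")
}

#' Augment a labeled patch
#'
#' Applies the requested augmentations in order. Geometric operations (zoom,
#' shear, rotate, flips) transform image and label rasters identically, with
#' nearest-neighbour interpolation for labels so instances stay
#' integer-labeled; the output keeps the input size (out-of-range pixels
#' become background). `channel_shift` is photometric only.
#'
#' @param patch a `"labeled_patch"`.
#' @param ops character vector drawn from `zoom`, `channel_shift`, `shear`,
#'   `rotate`, `hflip`, `vflip`.
#' @param seed integer seed for the sampled magnitudes.
#' @param params optional fixed magnitudes overriding the sampled ones:
#'   `zoom` (scale factor), `shear` (x-shear coefficient), `rotate` (degrees,
#'   counter-clockwise), `channel_shift` (length-3 additive offsets).
#' @return the augmented `"labeled_patch"`.
#' @examples
#' ds <- generate_nuclei_dataset(synth_config(n_images = 1, seed = 3))
#' aug <- augment_patch(ds[[1]], c("rotate", "hflip"), seed = 2,
#'                      params = list(rotate = 90))
#' @export
augment_patch <- function(patch, ops, seed = 1L, params = list()) {
  known <- c("zoom", "channel_shift", "shear", "rotate", "hflip", "vflip")
  bad <- setdiff(ops, known)
  if (length(bad)) stop("unknown augmentation op: ", paste(bad, collapse = ", "))
  set.seed(seed)
  rot_mat <- function(deg) {
    a <- deg * pi / 180
    matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  }
  for (op in ops) {
    patch <- switch(op,
      hflip = structure(list(image = patch$image[, ncol(patch$instances):1, ,
                                                 drop = FALSE],
                             instances = patch$instances[, ncol(patch$instances):1],
                             types = patch$types[, ncol(patch$types):1]),
                        class = "labeled_patch"),
      vflip = structure(list(image = patch$image[nrow(patch$instances):1, , ,
                                                 drop = FALSE],
                             instances = patch$instances[nrow(patch$instances):1, ],
                             types = patch$types[nrow(patch$types):1, ]),
                        class = "labeled_patch"),
      zoom = affine_warp(patch, diag(2) *
                           (params$zoom %||% stats::runif(1, 0.8, 1.25))),
      shear = affine_warp(patch, matrix(c(1, 0,
                                          params$shear %||%
                                            stats::runif(1, -0.2, 0.2), 1),
                                        2, 2)),
      rotate = affine_warp(patch, rot_mat(params$rotate %||%
                                            stats::runif(1, 0, 360))),
      channel_shift = {
        off <- params$channel_shift %||% stats::runif(3, -0.1, 0.1)
        img <- patch$image
        for (ch in 1:3) img[, , ch] <- pmin(pmax(img[, , ch] + off[ch], 0), 1)
        structure(list(image = img, instances = patch$instances,
                       types = patch$types), class = "labeled_patch")
      })
  }
  patch
}
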