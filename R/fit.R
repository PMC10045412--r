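# Model fitting and the S3 surface: gsn_hvnet() trains the multi-task
# network on labeled patches and returns a fitted model with
# print/summary/coef/predict/plot methods.

#' Fit the multi-task nuclei segmentation/classification network
#'
#' Trains the encoder-decoder on labeled patches with Adam and the joint
#' loss `L = la*BCE(q) + lb*Dice(q) + lc*MSE(p) + ld*MSGE(p) + le*BCE(r) +
#' lf*Dice(r)`. Following common practice for nuclei segmentation training,
#' the training set is enlarged each epoch with randomly augmented copies of
#' every patch (random combinations of zooming, channel shifting, shearing,
#' rotating, and flips); targets are recomputed from the warped label
#' rasters. Weights use Kaiming-normal initialization and convolutions carry
#' no bias (the normalization layers provide the shift).
#'
#' @param patches a `"nuclei_dataset"` (see [generate_nuclei_dataset()]) or
#'   list of patches, each with `image` (`H x W x 3` in `[0, 1]`),
#'   `instances`, and `types` matrices. `H`, `W` must be divisible by 8.
#' @param n_types number of nucleus classes.
#' @param spec a [stage_spec()] fixing the architecture widths.
#' @param with_classification include the NC branch? If `FALSE` the model
#'   only segments.
#' @param epochs training epochs.
#' @param batch_size minibatch size; the switchable normalization keeps
#'   training stable down to `batch_size = 1`.
#' @param lr Adam learning rate.
#' @param weight_decay decoupled weight decay coefficient.
#' @param weights a [loss_weights()].
#' @param post default [postprocess_params()] stored for [predict.gsn_hvnet()].
#' @param augment_copies augmented copies of each patch added per epoch
#'   (0 disables augmentation).
#' @param calibrate_post after training, tune the watershed threshold `k` on
#'   a validation subset of the training patches (the gradient-band scale
#'   depends on how sharp the trained HV maps are, so the appropriate `k` is
#'   a property of the fit; the chosen value is stored in the returned
#'   model's `post`).
#' @param seed integer seed governing initialization, shuffling, and
#'   augmentation.
#' @param verbose print a per-epoch loss summary?
#' @param log_file optional path; per-step loss breakdowns are appended as
#'   JSON lines.
#' @return an object of class `"gsn_hvnet"` with elements `network`, `spec`,
#'   `n_types`, `history` (per-step loss terms), `post`, `weights`, and
#'   `seed`.
#' @seealso [predict.gsn_hvnet()], [evaluate_instances()]
#' @export
gsn_hvnet <- function(patches, n_types = 3L, spec = stage_spec(),
                      with_classification = TRUE, epochs = 10L,
                      batch_size = 4L, lr = 1e-4, weight_decay = 0.1,
                      weights = loss_weights(), post = postprocess_params(),
                      augment_copies = 3L, calibrate_post = TRUE, seed = 1L,
                      verbose = TRUE, log_file = NULL) {
  stopifnot(length(patches) >= 1, epochs >= 1, batch_size >= 1, lr > 0)
  d1 <- dim(patches[[1]]$image)
  if (d1[1] %% 8 != 0 || d1[2] %% 8 != 0)
    stop("patch height and width must be divisible by 8")

  set.seed(seed)
  net <- gsn_network(n_types = n_types, spec = spec,
                     with_classification = with_classification,
                     in_channels = d1[3])
  params <- collect_params(net)

  aug_ops <- c("zoom", "channel_shift", "shear", "rotate", "hflip", "vflip")
  history <- list()
  step <- 0L
  n_base <- length(patches)

  for (epoch in seq_len(epochs)) {
    pool <- patches
    if (augment_copies > 0) {
      for (cp in seq_len(augment_copies)) {
        for (i in seq_len(n_base)) {
          ops <- aug_ops[stats::runif(length(aug_ops)) < 0.5]
          if (!length(ops)) ops <- sample(aug_ops, 1L)
          aseed <- (seed + 1009L * epoch + 131L * i + 7919L * cp) %% 2147483647L
          pool[[length(pool) + 1L]] <- augment_patch(patches[[i]], ops, aseed)
        }
      }
    }
    ord <- sample.int(length(pool))
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    epoch_loss <- numeric(0)
    for (bi in batches) {
      step <- step + 1L
      bt <- assemble_batch(pool[bi], n_types, with_classification)
      outs <- net$forward(bt$x, training = TRUE)
      lb <- joint_loss_backward(outs, bt, weights)
      if (!is.finite(lb$total))
        stop("non-finite loss at step ", step,
             " (terms: ", paste(signif(lb$terms, 4), collapse = ", "), ")")
      zero_grads(params)
      net$backward(lb$douts)
      adam_step(params, step, lr = lr, weight_decay = weight_decay)
      rec <- c(step = step, epoch = epoch, lb$terms, total = lb$total)
      history[[step]] <- rec
      if (!is.null(log_file))
        cat(jsonlite::toJSON(as.list(rec), auto_unbox = TRUE, digits = NA),
            "\n", sep = "", file = log_file, append = TRUE)
      epoch_loss <- c(epoch_loss, lb$total)
    }
    if (verbose)
      message(sprintf("epoch %d/%d  joint loss %.4f  (%d steps)",
                      epoch, epochs, mean(epoch_loss), length(batches)))
  }

  history <- as.data.frame(do.call(rbind, history))
  if (calibrate_post) {
    post <- calibrate_k(net, patches, post, verbose = verbose)
    if (verbose)
      message(sprintf("calibrated watershed threshold k = %.2f", post$k))
  }
  structure(list(network = net, spec = spec, n_types = as.integer(n_types),
                 with_classification = isTRUE(with_classification),
                 history = history, weights = weights, post = post,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, weight_decay = weight_decay, seed = as.integer(seed),
                 call = match.call()),
            class = "gsn_hvnet")
}

# Choose the gradient-band threshold k on a validation subset of the
# training patches: run inference once, sweep a k grid through the watershed,
# and keep the value maximizing detection F1 (AJI as tiebreak weight).
# h and k are dataset-calibrated quantities, not universal constants.
calibrate_k <- function(net, patches, post, n_val = 20L,
                        grid = seq(0.35, 0.6, by = 0.05), verbose = TRUE) {
  idx <- utils::tail(seq_along(patches), min(n_val, length(patches)))
  val <- patches[idx]
  d <- dim(val[[1]]$image)
  x <- array(0, dim = c(d[1], d[2], d[3], length(val)))
  for (i in seq_along(val)) x[, , , i] <- val[[i]]$image
  maps <- network_forward(net, x, training = FALSE)
  qs <- array(maps$q, dim = c(d[1], d[2], length(val)))
  best <- post
  best_score <- -Inf
  for (k in grid) {
    pk <- post
    pk$k <- k
    score <- mean(vapply(seq_along(val), function(i) {
      seg <- suppressWarnings(instance_segment(qs[, , i], maps$p[, , , i], pk))
      rep <- evaluate_instances(val[[i]]$instances, NULL, seg)
      rep$fd + 0.5 * rep$aji
    }, numeric(1)))
    if (score > best_score + 1e-9) {
      best_score <- score
      best <- pk
    }
  }
  best
}

# Stack patches into batch tensors plus all loss targets.
assemble_batch <- function(plist, n_types, with_classification) {
  B <- length(plist)
  d <- dim(plist[[1]]$image)
  x <- array(0, dim = c(d[1], d[2], d[3], B))
  mask <- array(0, dim = c(d[1], d[2], B))
  mask2 <- array(0, dim = c(d[1], d[2], 2L, B))
  hv <- array(0, dim = c(d[1], d[2], 2L, B))
  types <- if (with_classification)
    array(0, dim = c(d[1], d[2], n_types + 1L, B)) else NULL
  for (b in seq_len(B)) {
    p <- plist[[b]]
    x[, , , b] <- p$image
    m <- binarize_instances(p$instances)
    mask[, , b] <- m
    mask2[, , 1, b] <- 1 - m
    mask2[, , 2, b] <- m
    hv[, , , b] <- compute_hv_map(p$instances)
    if (with_classification) types[, , , b] <- type_target(p$types, n_types)
  }
  list(x = x, mask = mask, mask2 = mask2, hv = hv, types = types)
}

#' @export
print.gsn_hvnet <- function(x, ...) {
  cat("Multi-task nuclei segmentation",
      if (x$with_classification) "and classification", "network\n")
  cat(sprintf("  stages: RGS counts (%s), channels (%s); DGM (%s), growth %d\n",
              paste(x$spec$rgs_counts, collapse = ","),
              paste(x$spec$stage_channels, collapse = ","),
              paste(x$spec$dgm_counts, collapse = ","), x$spec$growth))
  cat(sprintf("  trainable parameters: %s\n",
              format(n_parameters(x$network), big.mark = ",")))
  if (nrow(x$history))
    cat(sprintf("  trained %d epochs (%d steps); joint loss %.4f -> %.4f\n",
                x$epochs, nrow(x$history), x$history$total[1],
                mean(utils::tail(x$history$total, 10))))
  invisible(x)
}

#' @export
summary.gsn_hvnet <- function(object, ...) {
  print(object)
  h <- object$history
  if (nrow(h)) {
    cat("\nFinal loss terms (mean of last 10 steps):\n")
    terms <- setdiff(names(h), c("step", "epoch", "total"))
    for (t in terms)
      cat(sprintf("  %-10s %.5f\n", t, mean(utils::tail(h[[t]], 10))))
  }
  invisible(object)
}

#' @export
coef.gsn_hvnet <- function(object, ...) {
  ps <- collect_params(object$network)
  unlist(lapply(ps, function(p) as.numeric(p$value)))
}

#' @export
plot.gsn_hvnet <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) stop("model has no training history")
  graphics::plot(h$step, h$total, type = "l", xlab = "step",
                 ylab = "joint loss", main = "Training loss", ...)
  invisible(x)
}

#' Predict instances (or raw maps) for new image patches
#'
#' Runs the network in inference mode and, for `type = "instances"`, the
#' marker-controlled watershed post-processing plus per-instance type voting.
#'
#' @param object a fitted `"gsn_hvnet"`.
#' @param images one patch (`H x W x 3` array), a list of patches or
#'   `"labeled_patch"` objects, or a batched `H x W x 3 x N` array.
#' @param type `"instances"` for segmented (and typed) instances,
#'   `"maps"` for the raw network outputs.
#' @param post a [postprocess_params()]; defaults to the one stored in the
#'   model.
#' @param ... unused.
#' @return for `"maps"`, the [network_forward()] output. For
#'   `"instances"`, a list of `"instance_prediction"` objects (one per
#'   image); segmentation-only models return plain instance matrices.
#' @export
predict.gsn_hvnet <- function(object, images, type = c("instances", "maps"),
                              post = object$post, ...) {
  type <- match.arg(type)
  imgs <- if (is.list(images) && !is.null(images$image)) list(images$image)
  else if (is.list(images)) lapply(images, function(p)
    if (is.list(p)) p$image else p)
  else if (length(dim(images)) == 3) list(images)
  else lapply(seq_len(dim(images)[4]), function(i) images[, , , i])
  d <- dim(imgs[[1]])
  x <- array(0, dim = c(d[1], d[2], d[3], length(imgs)))
  for (i in seq_along(imgs)) x[, , , i] <- imgs[[i]]
  maps <- network_forward(object$network, x, training = FALSE)
  if (type == "maps") return(maps)
  N <- length(imgs)
  qs <- array(maps$q, dim = c(d[1], d[2], N))
  out <- vector("list", N)
  for (i in seq_len(N)) {
    inst <- instance_segment(qs[, , i], maps$p[, , , i], post)
    out[[i]] <- if (!is.null(maps$r))
      assign_types(inst, maps$r[, , , i]) else inst
  }
  if (N == 1) out[[1]] else out
}
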