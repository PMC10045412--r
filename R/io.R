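# Disk formats: 8-bit PNG for images, 16-bit single-channel TIFF for
# instance/type rasters (bit-exact integer round trip), 32-bit float TIFF
# for cached HV maps, JSON manifests, RDS checkpoints.

#' Write a labeled dataset to a directory
#'
#' Each patch is stored as `image_%04d.png` (8-bit RGB),
#' `instances_%04d.tif`, and `types_%04d.tif` (16-bit grayscale, label 0 =
#' background), with a `manifest.json` listing the files and, when present,
#' the generating [synth_config()].
#'
#' @param dataset a `"nuclei_dataset"` or list of patches.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_patch_dir <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (i in seq_along(dataset)) {
    p <- dataset[[i]]
    fi <- sprintf("image_%04d.png", i)
    fn <- sprintf("instances_%04d.tif", i)
    ft <- sprintf("types_%04d.tif", i)
    png::writePNG(p$image, file.path(dir, fi))
    write_label_tiff(p$instances, file.path(dir, fn))
    write_label_tiff(p$types, file.path(dir, ft))
    entries[[i]] <- list(image = fi, instances = fn, types = ft)
  }
  cfg <- attr(dataset, "config")
  manifest <- list(n_images = length(dataset), files = entries)
  if (!is.null(cfg)) manifest$config <- unclass(cfg)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a labeled dataset written by [write_patch_dir()]
#'
#' @param dir directory containing `manifest.json`.
#' @return a `"nuclei_dataset"` list of patches.
#' @export
read_patch_dir <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  patches <- lapply(manifest$files, function(e) {
    structure(list(image = png::readPNG(file.path(dir, e$image)),
                   instances = read_label_tiff(file.path(dir, e$instances)),
                   types = read_label_tiff(file.path(dir, e$types))),
              class = "labeled_patch")
  })
  cfg <- manifest$config
  if (!is.null(cfg)) cfg <- lapply(cfg, unlist)
  structure(patches, class = "nuclei_dataset",
            config = if (!is.null(cfg)) do.call(synth_config, cfg))
}

#' Write / read an integer label raster as 16-bit TIFF
#'
#' Labels survive the round trip bit-exactly (range 0..65535).
#'
#' @param labels integer matrix.
#' @param path file path.
#' @return [read_label_tiff()] returns the integer matrix.
#' @export
write_label_tiff <- function(labels, path) {
  stopifnot(all(labels >= 0), all(labels <= 65535))
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write / read an HV map as 32-bit float TIFF
#'
#' The `[-1, 1]` signed distances are stored affinely mapped to `[0, 1]`
#' (32-bit float samples) and mapped back on read.
#'
#' @param hv `H x W x 2` numeric array in `[-1, 1]`.
#' @param path file path.
#' @return [read_hv_tiff()] returns the array.
#' @export
write_hv_tiff <- function(hv, path) {
  stopifnot(length(dim(hv)) == 3, dim(hv)[3] == 2,
            all(hv >= -1), all(hv <= 1))
  tiff::writeTIFF((hv + 1) / 2, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_hv_tiff
#' @export
read_hv_tiff <- function(path) {
  # libtiff notes that the 2nd sample of a grayscale TIFF is an extra
  # channel; that is exactly what we wrote, so silence the advisory
  m <- suppressWarnings(tiff::readTIFF(path))
  array(m * 2 - 1, dim = dim(m))
}

#' Write instance predictions to disk
#'
#' The instance map goes to a 16-bit TIFF and the per-instance attributes
#' (label, type, confidence, centroid, area) to a JSON sidecar.
#'
#' @param pred an `"instance_prediction"` or plain instance matrix.
#' @param stem output path without extension.
#' @return the two file paths, invisibly.
#' @export
write_instance_prediction <- function(pred, stem) {
  inst <- if (inherits(pred, "instance_prediction")) pred$instances else pred
  fmap <- paste0(stem, ".tif")
  fjson <- paste0(stem, ".json")
  write_label_tiff(inst, fmap)
  n <- max(inst, 0L)
  H <- nrow(inst)
  rows <- lapply(seq_len(n), function(l) {
    idx <- which(inst == l)
    rec <- list(label = l, area = length(idx),
                centroid = c(mean((idx - 1L) %/% H), mean((idx - 1L) %% H)))
    if (inherits(pred, "instance_prediction")) {
      rec$type <- pred$types[l]
      rec$confidence <- pred$confidence[l]
    }
    rec
  })
  jsonlite::write_json(rows, fjson, auto_unbox = TRUE, digits = NA)
  invisible(c(fmap, fjson))
}

# Run closures with the global RNG state preserved.
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  expr
}

# Flatten all module state (parameter values and SN running moments) in the
# deterministic construction order.
collect_state <- function(net) {
  vals <- lapply(collect_params(net), function(p) p$value)
  runs <- list()
  walk <- function(mod) {
    if (!is.null(mod$run_mean))
      runs[[length(runs) + 1L]] <<- list(mean = mod$run_mean,
                                         var = mod$run_var)
    for (ch in mod$children) walk(ch)
  }
  walk(net)
  list(params = vals, running = runs)
}

assign_state <- function(net, state) {
  ps <- collect_params(net)
  stopifnot(length(ps) == length(state$params))
  for (i in seq_along(ps)) ps[[i]]$value <- state$params[[i]]
  i <- 0L
  walk <- function(mod) {
    if (!is.null(mod$run_mean)) {
      i <<- i + 1L
      mod$run_mean <- state$running[[i]]$mean
      mod$run_var <- state$running[[i]]$var
    }
    for (ch in mod$children) walk(ch)
  }
  walk(net)
  invisible(net)
}

#' Save / load a fitted model
#'
#' The checkpoint stores the architecture description and all weights and
#' normalization running moments; loading rebuilds the network and restores
#' the state.
#'
#' @param model a fitted `"gsn_hvnet"`.
#' @param path checkpoint file path (RDS).
#' @return [load_gsn_hvnet()] returns the restored `"gsn_hvnet"`.
#' @export
save_gsn_hvnet <- function(model, path) {
  stopifnot(inherits(model, "gsn_hvnet"))
  saveRDS(list(spec = model$spec, n_types = model$n_types,
               with_classification = model$with_classification,
               state = collect_state(model$network),
               history = model$history, weights = model$weights,
               post = model$post, epochs = model$epochs,
               batch_size = model$batch_size, lr = model$lr,
               weight_decay = model$weight_decay, seed = model$seed),
          path)
  invisible(path)
}

#' @rdname save_gsn_hvnet
#' @export
load_gsn_hvnet <- function(path) {
  ck <- readRDS(path)
  net <- with_preserved_rng({
    set.seed(0L)
    gsn_network(n_types = ck$n_types, spec = ck$spec,
                with_classification = ck$with_classification)
  })
  assign_state(net, ck$state)
  structure(list(network = net, spec = ck$spec, n_types = ck$n_types,
                 with_classification = ck$with_classification,
                 history = ck$history, weights = ck$weights, post = ck$post,
                 epochs = ck$epochs, batch_size = ck$batch_size, lr = ck$lr,
                 weight_decay = ck$weight_decay, seed = ck$seed,
                 call = NULL),
            class = "gsn_hvnet")
}
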