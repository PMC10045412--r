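test_that("generation is a pure function of the configuration", {
  cfg <- synth_config(n_images = 3, seed = 5)
  d1 <- generate_nuclei_dataset(cfg)
  d2 <- generate_nuclei_dataset(cfg)
  expect_identical(d1[[2]]$image, d2[[2]]$image)
  expect_identical(d1[[2]]$instances, d2[[2]]$instances)
  expect_identical(d1[[2]]$types, d2[[2]]$types)
  d3 <- generate_nuclei_dataset(synth_config(n_images = 3, seed = 6))
  expect_false(identical(d1[[1]]$instances, d3[[1]]$instances))
})

test_that("patches honour the configured nucleus count and label structure", {
  ds <- generate_nuclei_dataset(synth_config(n_images = 10, seed = 2,
                                             nuclei_per_image = c(5, 5)))
  for (p in ds) {
    labs <- sort(unique(p$instances[p$instances > 0]))
    expect_identical(labs, 1:5)
    # exactly one type per instance, none on background
    expect_true(all((p$instances > 0) == (p$types > 0)))
    for (l in labs) {
      expect_length(unique(p$types[p$instances == l]), 1)
      expect_equal(count_components(p$instances == l), 1)
    }
    expect_true(all(p$types %in% 0:3))
    expect_true(all(p$image >= 0 & p$image <= 1))
  }
})

test_that("overlap seeding produces touching instance pairs", {
  ds <- generate_nuclei_dataset(synth_config(n_images = 50, seed = 3,
                                             overlap_prob = 0.9,
                                             nuclei_per_image = c(8, 12)))
  frac <- mean(vapply(ds, function(p) has_touching_pair(p$instances),
                      logical(1)))
  expect_gte(frac, 0.8)
})

test_that("nuclei pixel coverage grows with the configured count", {
  cov <- vapply(list(c(2, 3), c(5, 6), c(8, 9)), function(np) {
    ds <- generate_nuclei_dataset(synth_config(n_images = 12, seed = 4,
                                               nuclei_per_image = np))
    mean(vapply(ds, function(p) mean(p$instances > 0), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(cov) > 0))
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(nuclei_per_image = c(6, 3)), "increasing")
  expect_error(synth_config(radius_range = c(5, 25)), "radius")
  expect_error(synth_config(image_size = 16), "image_size")
  expect_error(synth_config(overlap_prob = 1.4))
})

test_that("flips are involutions and photometric ops leave labels alone", {
  p <- generate_nuclei_dataset(synth_config(n_images = 1, seed = 9))[[1]]
  twice <- augment_patch(augment_patch(p, "hflip", 1), "hflip", 1)
  expect_identical(twice$instances, p$instances)
  expect_equal(twice$image, p$image)
  twice_v <- augment_patch(augment_patch(p, "vflip", 1), "vflip", 1)
  expect_identical(twice_v$instances, p$instances)

  shifted <- augment_patch(p, "channel_shift", 3)
  expect_identical(shifted$instances, p$instances)
  expect_identical(shifted$types, p$types)
  expect_false(identical(shifted$image, p$image))
})

test_that("exact 90-degree rotation permutes pixels without loss", {
  p <- generate_nuclei_dataset(synth_config(n_images = 1, seed = 10))[[1]]
  rot <- augment_patch(p, "rotate", 1, params = list(rotate = 90))
  expect_identical(sort(tabulate(rot$instances[rot$instances > 0])),
                   sort(tabulate(p$instances[p$instances > 0])))
})

test_that("geometric augmentation keeps rasters integer and sized", {
  p <- generate_nuclei_dataset(synth_config(n_images = 1, seed = 11))[[1]]
  for (op in c("zoom", "shear", "rotate")) {
    a <- augment_patch(p, op, 7)
    expect_identical(dim(a$instances), dim(p$instances))
    expect_identical(dim(a$image), dim(p$image))
    expect_true(is.integer(a$instances))
    expect_true(all(a$instances >= 0))
  }
  expect_error(augment_patch(p, "warp", 1), "unknown augmentation")
})
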