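# Two axis-aligned touching ellipses used by several cases.
touching_pair <- function(S = 48) {
  xs <- matrix(rep(seq_len(S), each = S), S, S)
  ys <- matrix(rep(seq_len(S), times = S), S, S)
  m <- matrix(0L, S, S)
  m[((xs - 17) / 8)^2 + ((ys - 24) / 7)^2 <= 1] <- 1L
  m[(m == 0L) & ((xs - 31) / 7)^2 + ((ys - 24) / 8)^2 <= 1] <- 2L
  m
}

test_that("gradient map peaks on the shared boundary", {
  m <- touching_pair()
  hv <- compute_hv_map(m)
  Sm <- hv_gradient_map(hv)
  expect_true(all(Sm >= 0 & Sm <= 1))
  # the shared vertical boundary band attains the maximal response, while
  # the instance interiors stay low
  contact <- Sm[20:28, 23:26]
  expect_gte(max(contact), max(Sm) - 1e-9)
  expect_lt(max(Sm[22:26, 12:15]), 0.5)   # interior of the left nucleus

  flat <- hv_gradient_map(array(0.25, c(16, 16, 2)))
  expect_true(all(flat == 0))
})

test_that("marker arithmetic follows the threshold rules", {
  S <- 16
  expect_true(all(compute_marker(matrix(1, S, S), matrix(0, S, S),
                                 0.5, 0.3) == 1))
  expect_true(all(compute_marker(matrix(1, S, S), matrix(1, S, S),
                                 0.5, 0.3) == 0))
  m <- touching_pair()
  hv <- compute_hv_map(m)
  M <- compute_marker(binarize_instances(m), hv_gradient_map(hv), 0.5, 0.3)
  # the boundary band splits the foreground into exactly two marker cores
  expect_equal(count_components(M, eight = FALSE), 2)
})

test_that("the energy landscape is binary and properly gated", {
  set.seed(71)
  q <- matrix(runif(100), 10, 10)
  Sm <- matrix(runif(100), 10, 10)
  E <- energy_landscape(q, Sm, 0.5, 0.3)
  expect_true(all(E %in% c(0, 1)))
  expect_true(all(E[q <= 0.5] == 0))
  expect_true(all(E[Sm > 0.3] == 0))
})

test_that("ideal inputs segment blobs and touching pairs exactly", {
  # single blob
  S <- 40
  xs <- matrix(rep(seq_len(S), each = S), S, S)
  ys <- matrix(rep(seq_len(S), times = S), S, S)
  blob <- matrix(0L, S, S)
  blob[((xs - 20) / 8)^2 + ((ys - 20) / 6)^2 <= 1] <- 1L
  seg <- instance_segment(binarize_instances(blob), compute_hv_map(blob))
  expect_equal(max(seg), 1)
  expect_identical(seg > 0, blob > 0)

  # touching pair
  m <- touching_pair()
  seg2 <- instance_segment(binarize_instances(m), compute_hv_map(m))
  expect_equal(max(seg2), 2)
  expect_gte(aji(m, seg2), 0.9)
  # every foreground pixel is assigned, labels consecutive
  expect_identical(seg2 > 0, m > 0)
  expect_identical(sort(unique(seg2[seg2 > 0])), 1:2)

  # no foreground at all
  expect_warning(
    empty <- instance_segment(matrix(0, 16, 16), array(0, c(16, 16, 2))),
    "no watershed markers")
  expect_true(all(empty == 0))
})

test_that("raising k never removes marker components", {
  m <- touching_pair()
  hv <- compute_hv_map(m)
  Sm <- hv_gradient_map(hv)
  q <- binarize_instances(m)
  n_mark <- vapply(seq(0.15, 0.85, by = 0.1), function(k)
    count_components(compute_marker(q, Sm, 0.5, k), eight = FALSE),
    numeric(1))
  expect_true(all(diff(n_mark) >= 0))
})

test_that("resegmenting an ideal reconstruction is stable", {
  m <- touching_pair()
  seg <- instance_segment(binarize_instances(m), compute_hv_map(m))
  seg2 <- instance_segment(binarize_instances(seg), compute_hv_map(seg))
  expect_equal(max(seg2), max(seg))
})

test_that("instance types come from per-pixel majority votes", {
  m <- matrix(0L, 10, 10)
  m[2:6, 2:6] <- 1L
  r <- array(0, c(10, 10, 4))
  r[, , 1] <- 1
  # certain class 2 inside the instance
  for (i in 2:6) for (j in 2:6) r[i, j, ] <- c(0, 0, 1, 0)
  pred <- assign_types(m, r)
  expect_s3_class(pred, "instance_prediction")
  expect_equal(pred$types, 2L)
  expect_equal(pred$confidence, 1)

  # 60/40 split between classes 1 and 3 (25 px: 15 vs 10)
  px <- which(m == 1L)
  r2 <- array(0, c(10, 10, 4)); r2[, , 1] <- 1
  rm <- matrix(r2, ncol = 4)
  rm[px[1:15], ] <- rep(c(0, 1, 0, 0), each = 15)
  rm[px[16:25], ] <- rep(c(0, 0, 0, 1), each = 10)
  pred2 <- assign_types(m, array(rm, c(10, 10, 4)))
  expect_equal(pred2$types, 1L)
  expect_equal(pred2$confidence, 0.6)

  # exact tie between classes 2 and 3 resolves to the lower index
  m2 <- matrix(0L, 4, 4); m2[1:2, 1:2] <- 1L
  r3 <- array(0, c(4, 4, 4)); r3[, , 1] <- 1
  rm3 <- matrix(r3, ncol = 4)
  px2 <- which(m2 == 1L)
  rm3[px2[1:2], ] <- rep(c(0, 0, 1, 0), each = 2)
  rm3[px2[3:4], ] <- rep(c(0, 0, 0, 1), each = 2)
  pred3 <- assign_types(m2, array(rm3, c(4, 4, 4)))
  expect_equal(pred3$types, 2L)
})
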