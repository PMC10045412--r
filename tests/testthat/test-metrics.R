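test_that("dice coefficient handles edge and hand-counted cases", {
  m <- matrix(0, 6, 6); m[2:3, 2:4] <- 1
  expect_equal(dice_coef(m, m), 1)
  expect_equal(dice_coef(matrix(0, 3, 3), matrix(0, 3, 3)), 1)
  A <- matrix(0, 4, 4); A[1, 1:2] <- 1
  B <- matrix(0, 4, 4); B[1, 2:3] <- 1
  expect_equal(dice_coef(A, B), 0.5)
  C <- matrix(0, 4, 4); C[4, 4] <- 1
  expect_equal(dice_coef(A, C), 0)
  expect_error(dice_coef(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("AJI reproduces hand-enumerated cases", {
  gt <- matrix(0L, 6, 6); gt[2:3, 2:3] <- 1L           # 4 px
  pr <- matrix(0L, 6, 6); pr[3:4, 2:3] <- 1L           # 4 px, 2 shared
  expect_equal(aji(gt, pr), 1 / 3)
  expect_equal(aji(gt, gt), 1)

  # exact match plus one spurious 5-px prediction
  gt2 <- matrix(0L, 8, 8); gt2[2:3, 2:6] <- 1L         # 10 px
  pr2 <- gt2
  pr2[6, 1:5] <- 2L
  expect_equal(aji(gt2, pr2), 10 / 15)

  z <- matrix(0L, 4, 4)
  expect_equal(aji(z, z), 1)
  expect_equal(aji(z, gt[1:4, 1:4]), 0)
})

test_that("panoptic quality applies the IoU > 0.5 matching rule", {
  gt <- matrix(0L, 10, 10); gt[1:2, 1:5] <- 1L         # 10 px
  pr <- matrix(0L, 10, 10); pr[1:2, 2:5] <- 1L         # 8 px, inter 8
  # IoU = 8/10 = 0.8 -> matched
  pq <- panoptic_quality(gt, pr)
  expect_equal(unname(pq["dq"]), 1)
  expect_equal(unname(pq["sq"]), 0.8)
  expect_equal(unname(pq["pq"]), 0.8)

  pr2 <- matrix(0L, 10, 10); pr2[1:2, 4:9] <- 1L       # inter 4, union 18
  # IoU = 4/18 < 0.5 -> unmatched
  pq2 <- panoptic_quality(gt, pr2)
  expect_equal(unname(pq2["dq"]), 0)
  expect_equal(unname(pq2["pq"]), 0)

  expect_message(pq3 <- panoptic_quality(matrix(0L, 4, 4), matrix(0L, 4, 4)),
                 "empty")
  expect_equal(unname(pq3), c(1, 1, 1))
})

test_that("detection F1 counts matches, misses, and spurious predictions", {
  gt <- matrix(0L, 12, 12)
  gt[1:3, 1:3] <- 1L; gt[5:7, 5:7] <- 2L; gt[9:11, 9:11] <- 3L
  pr <- gt
  pr[gt == 3L] <- 0L               # miss one
  pr[1:2, 9:11] <- 4L              # add a spurious one
  pr[pr == 4L] <- 3L
  m <- match_instances(gt, pr)
  expect_equal(nrow(m$pairs), 2)
  expect_equal(detection_f1(m), 2 * 2 / (4 + 1 + 1))
  expect_equal(detection_f1(match_instances(gt, matrix(0L, 12, 12))), 0)
  expect_equal(detection_f1(match_instances(gt, gt)), 1)
})

test_that("classification score folds detection errors into the F-measure", {
  gt <- matrix(0L, 12, 12)
  gt[1:3, 1:3] <- 1L; gt[5:7, 5:7] <- 2L; gt[9:11, 9:11] <- 3L
  gt_types <- c(1L, 1L, 2L)
  # predict the two type-1 nuclei correctly, miss the third entirely
  pr <- gt; pr[gt == 3L] <- 0L
  pred <- structure(list(instances = pr, types = c(1L, 1L),
                         confidence = c(1, 1)),
                    class = "instance_prediction")
  # TPc = 2, TNc = 0, FNd = 1 -> 4 / 5
  expect_equal(classification_score(gt, gt_types, pred, 1), 0.8)
  # for type 2: TNc = 2, FNd = 1 -> 4 / 5
  expect_equal(classification_score(gt, gt_types, pred, 2), 0.8)

  perfect <- structure(list(instances = gt, types = gt_types,
                            confidence = rep(1, 3)),
                       class = "instance_prediction")
  for (t in 1:2)
    expect_equal(classification_score(gt, gt_types, perfect, t), 1)

  empty <- structure(list(instances = matrix(0L, 12, 12), types = integer(0),
                          confidence = numeric(0)),
                     class = "instance_prediction")
  expect_message(
    s <- classification_score(matrix(0L, 12, 12), integer(0), empty, 1),
    "no instances")
  expect_equal(s, 1)
})

test_that("metrics agree with exhaustive oracles on random maps", {
  set.seed(81)
  for (rep in 1:40) {
    gt <- random_instance_map()
    pr <- random_instance_map()
    expect_equal(aji(gt, pr), aji_oracle(gt, pr), tolerance = 1e-12)
    expect_equal(panoptic_quality(gt, pr), pq_oracle(gt, pr),
                 tolerance = 1e-12)
    expect_equal(dice_coef(binarize_instances(gt), binarize_instances(pr)),
                 dice_oracle(gt, pr), tolerance = 1e-12)
  }
})

test_that("metrics are invariant to label permutation and pq <= dq, sq", {
  set.seed(82)
  for (rep in 1:10) {
    gt <- random_instance_map()
    pr <- random_instance_map()
    relab <- function(m) {
      labs <- sort(unique(m[m > 0]))
      if (!length(labs)) return(m)
      p <- sample(labs)
      m2 <- m
      m2[m > 0] <- p[match(m[m > 0], labs)]
      m2
    }
    expect_equal(aji(gt, relab(pr)), aji(gt, pr))
    pq1 <- panoptic_quality(gt, pr)
    expect_equal(panoptic_quality(relab(gt), relab(pr)), pq1)
    expect_lte(pq1["pq"], pq1["dq"] + 1e-15)
    expect_lte(pq1["pq"], pq1["sq"] + 1e-15)
    expect_equal(unname(pq1["pq"]), unname(pq1["dq"] * pq1["sq"]),
                 tolerance = 1e-12)
  }
})
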