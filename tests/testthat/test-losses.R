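test_that("binary cross-entropy matches its closed forms", {
  set.seed(61)
  X <- matrix(rbinom(16, 1, 0.5), 4, 4)
  expect_lt(bce_loss(pmin(pmax(X, 1e-7), 1 - 1e-7), X), 1e-5)
  expect_equal(bce_loss(matrix(0.5, 4, 4), X), log(2), tolerance = 1e-12)

  # hand-summed reference on a random 2-class case
  Y <- array(runif(4 * 4 * 2, 0.05, 0.95), c(4, 4, 2))
  X2 <- array(0, c(4, 4, 2))
  X2[, , 1] <- X
  X2[, , 2] <- 1 - X
  acc <- 0
  for (i in 1:4) for (j in 1:4) for (k in 1:2)
    acc <- acc - (X2[i, j, k] * log(Y[i, j, k]) +
                    (1 - X2[i, j, k]) * log(1 - Y[i, j, k]))
  expect_equal(bce_loss(Y, X2), acc / 32, tolerance = 1e-12)
  expect_error(bce_loss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("dice loss follows the smoothed formula", {
  m <- matrix(0, 10, 10)
  m[2:6, 3:12 %% 10 + 1] <- 1
  m <- (m > 0) * 1
  expect_equal(dice_loss(m, m), 0, tolerance = 1e-6)

  A <- matrix(0, 5, 5); A[1:2, 1:5] <- 1   # 10 px
  B <- matrix(0, 5, 5); B[4:5, 1:5] <- 1   # disjoint 10 px
  expect_equal(dice_loss(A, B), 1 - 1e-4 / (20 + 1e-4), tolerance = 1e-12)

  z <- matrix(0, 4, 4)
  expect_equal(dice_loss(z, z), 0)

  # invariance under a shared spatial permutation
  set.seed(62)
  Y <- matrix(runif(25), 5, 5); X <- matrix(rbinom(25, 1, 0.4), 5, 5)
  p <- sample(25)
  expect_equal(dice_loss(matrix(Y[p], 5), matrix(X[p], 5)), dice_loss(Y, X))
})

test_that("HV regression losses vanish where they should", {
  set.seed(63)
  m <- matrix(0L, 12, 12); m[4:8, 3:9] <- 1L
  gam <- compute_hv_map(m)
  mask <- binarize_instances(m)
  expect_equal(hv_mse_loss(gam, gam), 0)
  expect_equal(hv_msge_loss(gam, gam, mask), 0)

  p <- gam + 0.3
  expect_equal(hv_mse_loss(p, gam), 0.09, tolerance = 1e-12)
  expect_equal(hv_msge_loss(p, gam, mask), 0, tolerance = 1e-12)
  expect_equal(hv_msge_loss(p, gam, matrix(0, 12, 12)), 0)
})

test_that("gradient loss matches a hand-computed correlation", {
  # 5-pixel horizontal bar; prediction flat, target the HV ramp
  m <- matrix(0L, 9, 9); m[5, 3:7] <- 1L
  gam <- compute_hv_map(m)
  p <- gam * 0
  mask <- binarize_instances(m)
  kk <- gsnuclei:::sobel_kernels(5L)
  d <- p - gam
  ref_gx <- matrix(0, 9, 9)
  for (i in 1:9) for (j in 1:9) {
    acc <- 0
    for (a in -2:2) for (b in -2:2) {
      ii <- i + a; jj <- j + b
      v <- if (ii >= 1 && ii <= 9 && jj >= 1 && jj <= 9) d[ii, jj, 1] else 0
      acc <- acc + kk$kx[a + 3, b + 3] * v
    }
    ref_gx[i, j] <- acc
  }
  ref <- sum(mask * ref_gx^2) / sum(mask)  # vertical channel difference is 0
  expect_equal(hv_msge_loss(p, gam, mask), ref, tolerance = 1e-12)
})

test_that("the joint loss is the weighted sum of its parts", {
  set.seed(64)
  ds <- generate_nuclei_dataset(synth_config(n_images = 1, seed = 65))
  tg <- gsnuclei:::patch_targets(ds[[1]], 3)
  # perfect predictions
  perfect <- list(q = tg$mask, p = tg$hv, r = tg$types)
  jl <- joint_loss(perfect, tg)
  expect_lte(jl$total, 1e-4)

  # a noisy prediction decomposes componentwise
  noisy <- list(q = pmin(pmax(tg$mask + runif(length(tg$mask), -0.3, 0.3),
                              1e-6), 1 - 1e-6),
                p = pmin(pmax(tg$hv + rnorm(length(tg$hv), 0, 0.1), -1), 1),
                r = tg$types * 0 + 1 / 4)
  w <- loss_weights()
  jl <- joint_loss(noisy, tg, w)
  q2 <- c(1 - noisy$q, noisy$q); x2 <- c(1 - tg$mask, tg$mask)
  manual <- 1 * bce_loss(q2, x2) +
    1 * dice_loss(noisy$q, tg$mask) +
    1 * hv_mse_loss(noisy$p, tg$hv) +
    1 * hv_msge_loss(noisy$p, tg$hv, tg$mask) +
    2 * bce_loss(noisy$r, tg$types) +
    1 * dice_loss(noisy$r, tg$types)
  expect_equal(jl$total, manual, tolerance = 1e-12)

  # zeroing the HV and NC weights leaves the NSS loss alone
  w0 <- loss_weights(lambda_c = 0, lambda_d = 0, lambda_e = 0, lambda_f = 0)
  jl0 <- joint_loss(noisy, tg, w0)
  expect_equal(jl0$total,
               bce_loss(q2, x2) + dice_loss(noisy$q, tg$mask),
               tolerance = 1e-12)
  expect_true(all(jl$terms >= 0))
})

test_that("analytic loss gradients agree with finite differences", {
  set.seed(66)
  ns <- asNamespace("gsnuclei")
  H <- 6; W <- 6; N <- 1
  m <- matrix(0L, H, W); m[2:4, 2:5] <- 1L
  mask <- array(binarize_instances(m), c(H, W, N))
  mask2 <- array(0, c(H, W, 2, N))
  mask2[, , 1, ] <- 1 - mask; mask2[, , 2, ] <- mask
  hv <- array(compute_hv_map(m), c(H, W, 2, N))
  types <- array(type_target(matrix(ifelse(m > 0, 2L, 0L), H), 2),
                 c(H, W, 3, N))
  tg <- list(mask = mask, mask2 = mask2, hv = hv, types = types)
  outs <- list(nss = array(runif(H * W * 2 * N, 0.1, 0.9), c(H, W, 2, N)),
               hv = array(runif(H * W * 2 * N, -0.9, 0.9), c(H, W, 2, N)),
               nc = array(runif(H * W * 3 * N, 0.1, 0.9), c(H, W, 3, N)))
  w <- loss_weights()
  lb <- ns$joint_loss_backward(outs, tg, w)
  for (head in c("nss", "hv", "nc")) {
    x0 <- outs[[head]]
    idx <- sample(length(x0), 12)
    for (i in idx) {
      op <- outs; om <- outs
      xp <- x0; xp[i] <- xp[i] + 1e-6
      xm <- x0; xm[i] <- xm[i] - 1e-6
      op[[head]] <- xp; om[[head]] <- xm
      num <- (ns$joint_loss_backward(op, tg, w)$total -
                ns$joint_loss_backward(om, tg, w)$total) / 2e-6
      expect_equal(lb$douts[[head]][i], num, tolerance = 1e-4)
    }
  }
})
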