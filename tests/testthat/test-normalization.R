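# Reference statistics computed with direct loops/apply calls, independent
# of the package's pooled-table implementation.
ref_stats <- function(x) {
  C <- dim(x)[3]; N <- dim(x)[4]
  mu_in <- array(0, c(C, N)); v_in <- array(0, c(C, N))
  for (c in seq_len(C)) for (n in seq_len(N)) {
    v <- as.vector(x[, , c, n])
    mu_in[c, n] <- mean(v); v_in[c, n] <- mean((v - mean(v))^2)
  }
  mu_ln <- vapply(seq_len(N), function(n) mean(x[, , , n]), numeric(1))
  v_ln <- vapply(seq_len(N), function(n) mean((x[, , , n] - mu_ln[n])^2),
                 numeric(1))
  mu_bn <- vapply(seq_len(C), function(c) mean(x[, , c, ]), numeric(1))
  v_bn <- vapply(seq_len(C), function(c) mean((x[, , c, ] - mu_bn[c])^2),
                 numeric(1))
  list(mu_in = mu_in, v_in = v_in, mu_ln = mu_ln, v_ln = v_ln,
       mu_bn = mu_bn, v_bn = v_bn)
}

test_that("one-hot mixture logits collapse to BN, IN, and LN", {
  set.seed(31)
  x <- array(rnorm(6 * 5 * 3 * 4), c(6, 5, 3, 4))
  st <- ref_stats(x)
  eps <- 1e-5
  C <- 3; N <- 4
  gam <- runif(C, 0.5, 1.5); bet <- rnorm(C)

  # BN
  y <- sn_forward(x, gam, bet, mean_logits = c(-20, -20, 20),
                  var_logits = c(-20, -20, 20))
  ref <- array(0, dim(x))
  for (c in seq_len(C))
    ref[, , c, ] <- gam[c] * (x[, , c, ] - st$mu_bn[c]) /
      sqrt(st$v_bn[c] + eps) + bet[c]
  expect_lt(max(abs(y - ref)), 1e-5)

  # IN
  y <- sn_forward(x, gam, bet, mean_logits = c(20, -20, -20),
                  var_logits = c(20, -20, -20))
  ref <- array(0, dim(x))
  for (c in seq_len(C)) for (n in seq_len(N))
    ref[, , c, n] <- gam[c] * (x[, , c, n] - st$mu_in[c, n]) /
      sqrt(st$v_in[c, n] + eps) + bet[c]
  expect_lt(max(abs(y - ref)), 1e-5)

  # LN
  y <- sn_forward(x, gam, bet, mean_logits = c(-20, 20, -20),
                  var_logits = c(-20, 20, -20))
  ref <- array(0, dim(x))
  for (c in seq_len(C)) for (n in seq_len(N))
    ref[, , c, n] <- gam[c] * (x[, , c, n] - st$mu_ln[n]) /
      sqrt(st$v_ln[n] + eps) + bet[c]
  expect_lt(max(abs(y - ref)), 1e-5)
})

test_that("equal logits average the three statistics", {
  set.seed(32)
  x <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  st <- ref_stats(x)
  y <- sn_forward(x, rep(1, 3), rep(0, 3))
  ref <- array(0, dim(x))
  for (c in 1:3) for (n in 1:2) {
    m <- (st$mu_in[c, n] + st$mu_ln[n] + st$mu_bn[c]) / 3
    v <- (st$v_in[c, n] + st$v_ln[n] + st$v_bn[c]) / 3
    ref[, , c, n] <- (x[, , c, n] - m) / sqrt(v + 1e-5)
  }
  expect_lt(max(abs(y - ref)), 1e-10)
})

test_that("a constant input normalizes to zero", {
  x <- array(2.5, c(4, 4, 2, 3))
  y <- sn_forward(x, rep(1, 2), rep(0, 2))
  expect_lt(max(abs(y)), 1e-6)
})

test_that("output is invariant to shifting all mean logits", {
  set.seed(33)
  x <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  y1 <- sn_forward(x, rep(1, 3), rep(0, 3), mean_logits = c(0.3, -0.2, 0.5))
  y2 <- sn_forward(x, rep(1, 3), rep(0, 3),
                   mean_logits = c(0.3, -0.2, 0.5) + 7)
  expect_equal(y1, y2, tolerance = 1e-12)
})

test_that("batch size one stays finite with usable gradients", {
  set.seed(34)
  ly <- gsnuclei:::nn_sn(4)
  gsnuclei:::zero_grads(ly$params)
  x <- array(rnorm(8 * 8 * 4 * 1), c(8, 8, 4, 1))
  y <- ly$forward(x, training = TRUE)
  expect_true(all(is.finite(y)))
  dx <- ly$backward(array(rnorm(length(y)), dim(y)))
  expect_true(all(is.finite(dx)))
  expect_true(all(vapply(ly$params, function(p) all(is.finite(p$grad)),
                         logical(1))))
})

test_that("layer gradients match finite differences", {
  set.seed(35)
  ly <- gsnuclei:::nn_sn(3)
  ly$gamma$value <- runif(3, 0.5, 1.5)
  ly$mean_logits$value <- rnorm(3, 0, 0.4)
  ly$var_logits$value <- rnorm(3, 0, 0.4)
  gsnuclei:::zero_grads(ly$params)
  x <- array(rnorm(4 * 3 * 3 * 2), c(4, 3, 3, 2))
  loss_dir <- array(rnorm(length(x)), dim(x))
  y <- ly$forward(x, training = TRUE)
  dx <- ly$backward(loss_dir)
  f <- function(xx) sum(sn_forward(array(xx, dim(x)), ly$gamma$value,
                                   ly$beta$value, ly$mean_logits$value,
                                   ly$var_logits$value) * loss_dir)
  num <- vapply(seq_along(x), function(i) {
    xp <- as.numeric(x); xm <- as.numeric(x)
    xp[i] <- xp[i] + 1e-5; xm[i] <- xm[i] - 1e-5
    (f(xp) - f(xm)) / 2e-5
  }, numeric(1))
  expect_lt(max(abs(dx - num)), 1e-6)
})

test_that("inference mode uses the running batch moments", {
  set.seed(36)
  x <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  rm <- c(0.2, -0.1); rv <- c(1.2, 0.8)
  y <- sn_forward(x, rep(1, 2), rep(0, 2),
                  mean_logits = c(-20, -20, 20), var_logits = c(-20, -20, 20),
                  training = FALSE, running_mean = rm, running_var = rv)
  ref <- array(0, dim(x))
  for (c in 1:2) ref[, , c, ] <- (x[, , c, ] - rm[c]) / sqrt(rv[c] + 1e-5)
  expect_lt(max(abs(y - ref)), 1e-5)
})
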