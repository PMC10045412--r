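# Shared fixtures and independent oracles for the test suite. Everything in
# here is deliberately naive (double loops, exhaustive enumeration) so it
# cannot share a bug with the package implementations it checks.

# random instance map: up to n_max elliptical-ish blobs, possibly overlapping
random_instance_map <- function(S = 48, n_max = 6) {
  m <- matrix(0L, S, S)
  n <- sample.int(n_max, 1)
  for (l in seq_len(n)) {
    cx <- runif(1, 8, S - 8); cy <- runif(1, 8, S - 8)
    a <- runif(1, 3, 8); b <- runif(1, 3, 8)
    xs <- matrix(rep(seq_len(S), each = S), S, S)
    ys <- matrix(rep(seq_len(S), times = S), S, S)
    m[((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1] <- l
  }
  # relabel to consecutive labels (overlap can erase one entirely)
  labs <- sort(unique(m[m > 0]))
  matrix(as.integer(match(m, c(0L, labs)) - 1L), S, S)
}

# exhaustive intersection/area tables by double loop over label pairs
overlap_brute <- function(gt, pred) {
  gl <- sort(unique(gt[gt > 0])); pl <- sort(unique(pred[pred > 0]))
  inter <- matrix(0, length(gl), length(pl))
  if (length(gl) && length(pl))
    for (i in seq_along(gl)) for (j in seq_along(pl))
      inter[i, j] <- sum(gt == gl[i] & pred == pl[j])
  list(gl = gl, pl = pl, inter = inter,
       ag = vapply(gl, function(l) sum(gt == l), numeric(1)),
       ap = vapply(pl, function(l) sum(pred == l), numeric(1)))
}

aji_oracle <- function(gt, pred) {
  ov <- overlap_brute(gt, pred)
  if (!length(ov$gl)) return(if (!length(ov$pl)) 1 else 0)
  used <- rep(FALSE, length(ov$pl))
  num <- 0; den <- 0
  for (i in seq_along(ov$gl)) {
    best <- 0; bestj <- 0
    for (j in seq_along(ov$pl)) {
      if (used[j] || ov$inter[i, j] == 0) next
      jac <- ov$inter[i, j] / (ov$ag[i] + ov$ap[j] - ov$inter[i, j])
      if (jac > best) { best <- jac; bestj <- j }
    }
    if (bestj == 0) {
      den <- den + ov$ag[i]
    } else {
      used[bestj] <- TRUE
      num <- num + ov$inter[i, bestj]
      den <- den + ov$ag[i] + ov$ap[bestj] - ov$inter[i, bestj]
    }
  }
  den <- den + sum(ov$ap[!used])
  if (den == 0) 1 else num / den
}

pq_oracle <- function(gt, pred) {
  ov <- overlap_brute(gt, pred)
  tp <- 0; sum_iou <- 0
  if (length(ov$gl) && length(ov$pl))
    for (i in seq_along(ov$gl)) for (j in seq_along(ov$pl)) {
      iou <- ov$inter[i, j] / (ov$ag[i] + ov$ap[j] - ov$inter[i, j])
      if (iou > 0.5) { tp <- tp + 1; sum_iou <- sum_iou + iou }
    }
  fp <- length(ov$pl) - tp
  fn <- length(ov$gl) - tp
  if (tp + fp + fn == 0) return(c(dq = 1, sq = 1, pq = 1))
  dq <- tp / (tp + fp / 2 + fn / 2)
  sq <- if (tp > 0) sum_iou / tp else 0
  c(dq = dq, sq = sq, pq = dq * sq)
}

dice_oracle <- function(X, Y) {
  sx <- sum(X > 0); sy <- sum(Y > 0)
  if (sx + sy == 0) return(1)
  2 * sum(X > 0 & Y > 0) / (sx + sy)
}

# independent connected-component counter (queue-based BFS in plain R)
count_components <- function(mask, eight = TRUE) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  offs <- if (eight) rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                           c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  ncomp <- 0
  for (start in which(mask > 0)) {
    si <- (start - 1) %% H + 1; sj <- (start - 1) %/% H + 1
    if (seen[si, sj]) next
    ncomp <- ncomp + 1
    queue <- list(c(si, sj)); seen[si, sj] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        qi <- p[1] + offs[k, 1]; qj <- p[2] + offs[k, 2]
        if (qi >= 1 && qi <= H && qj >= 1 && qj <= W &&
            mask[qi, qj] > 0 && !seen[qi, qj]) {
          seen[qi, qj] <- TRUE
          queue[[length(queue) + 1]] <- c(qi, qj)
        }
      }
    }
  }
  ncomp
}

# does any 8-adjacent pixel pair carry two distinct positive labels?
has_touching_pair <- function(m) {
  H <- nrow(m); W <- ncol(m)
  for (s in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    r1 <- seq_len(H - abs(s[1])); c1 <- seq_len(W - abs(s[2]))
    a <- m[r1, if (s[2] < 0) c1 + 1 else c1, drop = FALSE]
    b <- m[r1 + s[1], if (s[2] < 0) c1 else c1 + s[2], drop = FALSE]
    if (any(a > 0 & b > 0 & a != b)) return(TRUE)
  }
  FALSE
}

# tiny architecture used by structural / speed-sensitive tests
tiny_spec <- function() stage_spec(stage_channels = c(4L, 8L, 12L, 16L),
                                   growth = 4L)

small_spec <- function() stage_spec(stage_channels = c(8L, 16L, 24L, 32L),
                                    growth = 8L)
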