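# Independent explicit-loop oracles used to check the vectorized / compiled
# implementation. Everything here is deliberately written as plain nested
# loops, sharing no code with the package internals.

# 1-based mirror (symmetric, edge duplicated) reflection into 1..n
reflect1 <- function(i, n) {
  if (n == 1L) return(1L)
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

# ring weight by direct summation of the defining series
oracle_ring_weight <- function(d, s) {
  total <- 0
  for (v in max(d, 1):s) total <- total + 1 / ((2 * v + 1)^2 * s)
  total
}

# profile-weighted squared patch distance, 2D, explicit loops
oracle_patch_dist <- function(img, k, l, s) {
  n1 <- nrow(img); n2 <- ncol(img)
  acc <- 0
  for (dy in -s:s) for (dx in -s:s) {
    w <- oracle_ring_weight(max(abs(dx), abs(dy)), s)
    a <- img[reflect1(k[1] + dx, n1), reflect1(k[2] + dy, n2)]
    b <- img[reflect1(l[1] + dx, n1), reflect1(l[2] + dy, n2)]
    acc <- acc + w * (a - b)^2
  }
  acc
}

# dense similarity weights + nonlocal mean by brute force (2D)
oracle_nlm <- function(img, s, u, h) {
  n1 <- nrow(img); n2 <- ncol(img)
  S <- vector("list", n1 * n2)
  xbar <- matrix(0, n1, n2)
  for (kc in seq_len(n2)) for (kr in seq_len(n1)) {
    rows <- max(1, kr - u):min(n1, kr + u)
    cols <- max(1, kc - u):min(n2, kc + u)
    d <- numeric(0); ind <- integer(0)
    for (lc in cols) for (lr in rows) {
      d <- c(d, oracle_patch_dist(img, c(kr, kc), c(lr, lc), s))
      ind <- c(ind, (lc - 1L) * n1 + lr)
    }
    w <- exp(-d / h)
    w <- w / sum(w)
    k <- (kc - 1L) * n1 + kr
    S[[k]] <- stats::setNames(w, ind)
    xbar[kr, kc] <- sum(w * img[ind])
  }
  list(S = S, xbar = xbar)
}

# windowed kernel-weighted sum by explicit loops (2D)
oracle_lws <- function(field, kw) {
  rho <- (nrow(kw) - 1L) / 2L
  n1 <- nrow(field); n2 <- ncol(field)
  out <- matrix(0, n1, n2)
  for (j in seq_len(n2)) for (i in seq_len(n1)) {
    acc <- 0
    for (dy in -rho:rho) for (dx in -rho:rho)
      acc <- acc + kw[dx + rho + 1L, dy + rho + 1L] *
        field[reflect1(i + dx, n1), reflect1(j + dy, n2)]
    out[i, j] <- acc
  }
  out
}

# direct transcription of the joint membership update: per-pixel brackets
# sum_r K(r-k)||x_k - b_r v_i||^2 + beta_k sum_r K(r-k)||xbar_k - b_r v_i||^2
# - a_k, power -1/(m-1), normalized; same clamp/crisp convention as
# documented (brackets <= 1e-12 -> crisp, ties split equally)
oracle_update_u <- function(img, v, b, kw, m, xbar, beta, ak) {
  n1 <- nrow(img); n2 <- ncol(img)
  rho <- (nrow(kw) - 1L) / 2L
  C <- length(v)
  U <- array(0, dim = c(n1, n2, C))
  for (j in seq_len(n2)) for (i in seq_len(n1)) {
    br <- numeric(C)
    for (ci in seq_len(C)) {
      loc <- 0; nl <- 0
      for (dy in -rho:rho) for (dx in -rho:rho) {
        K <- kw[dx + rho + 1L, dy + rho + 1L]
        brv <- b[reflect1(i + dx, n1), reflect1(j + dy, n2)] * v[ci]
        loc <- loc + K * (img[i, j] - brv)^2
        nl <- nl + K * (xbar[i, j] - brv)^2
      }
      br[ci] <- loc + beta[i, j] * nl - ak[i, j]
    }
    if (min(br) <= 1e-12) {
      hit <- br <= 1e-12
      U[i, j, ] <- hit / sum(hit)
    } else {
      e <- br^(-1 / (m - 1))
      U[i, j, ] <- e / sum(e)
    }
  }
  U
}

# direct transcription of the prototype update
oracle_update_v <- function(img, U, b, kw, m, xbar, beta) {
  n1 <- nrow(img); n2 <- ncol(img)
  rho <- (nrow(kw) - 1L) / 2L
  C <- dim(U)[3]
  v <- numeric(C)
  for (ci in seq_len(C)) {
    num <- 0; den <- 0
    for (j in seq_len(n2)) for (i in seq_len(n1)) {
      for (dy in -rho:rho) for (dx in -rho:rho) {
        K <- kw[dx + rho + 1L, dy + rho + 1L]
        br <- b[reflect1(i + dx, n1), reflect1(j + dy, n2)]
        num <- num + K * br * (img[i, j] + beta[i, j] * xbar[i, j]) * U[i, j, ci]^m
        den <- den + K * br^2 * (1 + beta[i, j]) * U[i, j, ci]^m
      }
    }
    v[ci] <- num / den
  }
  v
}

# direct transcription of the bias update (stationarity of the objective in
# b_r: the window sum runs over the pixels r whose windows contain k)
oracle_update_b <- function(img, U, v, kw, m, xbar, beta) {
  n1 <- nrow(img); n2 <- ncol(img)
  rho <- (nrow(kw) - 1L) / 2L
  C <- dim(U)[3]
  B <- matrix(0, n1, n2)
  for (j in seq_len(n2)) for (i in seq_len(n1)) {
    num <- 0; den <- 0
    for (dy in -rho:rho) for (dx in -rho:rho) {
      K <- kw[dx + rho + 1L, dy + rho + 1L]
      r1 <- reflect1(i + dx, n1); r2 <- reflect1(j + dy, n2)
      for (ci in seq_len(C)) {
        num <- num + K * v[ci] * U[r1, r2, ci]^m *
          (img[r1, r2] + beta[r1, r2] * xbar[r1, r2])
        den <- den + K * v[ci]^2 * U[r1, r2, ci]^m * (1 + beta[r1, r2])
      }
    }
    B[i, j] <- num / den
  }
  B
}

# single BCFCM update step transcribed directly: neighbourhood term over the
# 3x3 window minus the centre, mirror-padded
oracle_bcfcm_step <- function(img, v, m, alpha) {
  n1 <- nrow(img); n2 <- ncol(img)
  C <- length(v)
  nbr <- function(i, j) {
    out <- numeric(0)
    for (dy in -1:1) for (dx in -1:1)
      if (dx != 0L || dy != 0L)
        out <- c(out, img[reflect1(i + dx, n1), reflect1(j + dy, n2)])
    out
  }
  U <- array(0, dim = c(n1, n2, C))
  for (j in seq_len(n2)) for (i in seq_len(n1)) {
    xr <- nbr(i, j)
    d <- vapply(v, function(vi)
      (img[i, j] - vi)^2 + alpha / length(xr) * sum((xr - vi)^2), numeric(1))
    if (min(d) <= 1e-12) {
      hit <- d <= 1e-12
      U[i, j, ] <- hit / sum(hit)
    } else {
      e <- d^(-1 / (m - 1))
      U[i, j, ] <- e / sum(e)
    }
  }
  vNew <- numeric(C)
  for (ci in seq_len(C)) {
    num <- 0; den <- 0
    for (j in seq_len(n2)) for (i in seq_len(n1)) {
      num <- num + U[i, j, ci]^m *
        (img[i, j] + alpha / 8 * sum(nbr(i, j)))
      den <- den + U[i, j, ci]^m
    }
    vNew[ci] <- num / ((1 + alpha) * den)
  }
  list(u = U, v = vNew)
}

# single GIFP_FCM update step transcribed directly
oracle_gifp_step <- function(img, v, m, alpha) {
  x <- as.vector(img)
  C <- length(v)
  D <- sapply(v, function(vi) (x - vi)^2)
  a <- alpha * apply(D, 1, min)
  U <- matrix(0, length(x), C)
  for (k in seq_along(x)) {
    br <- D[k, ] - a[k]
    if (min(br) <= 1e-12) {
      hit <- br <= 1e-12
      U[k, ] <- hit / sum(hit)
    } else {
      e <- br^(-1 / (m - 1))
      U[k, ] <- e / sum(e)
    }
  }
  vNew <- colSums(U^m * x) / colSums(U^m)
  list(u = U, v = vNew)
}

# exhaustive label matching oracle for 3 classes
oracle_match3 <- function(pred, truth) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  best <- NULL; bestScore <- -1
  for (p in perms) {
    score <- sum(p[pred] == truth & pred > 0 & truth > 0)
    if (score > bestScore) { bestScore <- score; best <- p }
  }
  as.integer(best)
}

# a small smooth strictly positive field for oracle states
smooth_test_bias <- function(n1, n2, amp = 0.15) {
  outer(seq_len(n1), seq_len(n2), function(i, j)
    1 + amp * sin(i / n1 * pi) * cos(j / n2 * pi * 0.5))
}
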