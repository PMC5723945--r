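# Brute-force nested-loop oracles for the convolution-based operations.
# These deliberately share no code with the package internals: every sum is
# written as an explicit double loop over pixels and kernel offsets.

oracle_local_entropy <- function(img, r, window = "square", offset = 1) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- c()
    for (di in -r:r) for (dj in -r:r) {
      if (window == "disk" && sqrt(di^2 + dj^2) > r) next
      y <- i + di; x <- j + dj
      if (y >= 1 && y <= nr && x >= 1 && x <= nc) vals <- c(vals, img[y, x] + offset)
    }
    s <- sum(vals)
    if (s == 0) { out[i, j] <- 0; next }
    p <- vals / s
    p <- p[p > 0]
    out[i, j] <- -sum(p * log(p)) / log(max(length(vals), 2))
  }
  out
}

# sum_y K(x-y) f(y) at pixel (i, j), clipping at the image border
oracle_conv_at <- function(f, K, r, i, j) {
  nr <- nrow(f); nc <- ncol(f)
  acc <- 0
  for (di in -r:r) for (dj in -r:r) {
    y <- i + di; x <- j + dj
    if (y >= 1 && y <= nr && x >= 1 && x <= nc)
      acc <- acc + K[di + r + 1, dj + r + 1] * f[y, x]
  }
  acc
}

oracle_force_maps <- function(img, E, st, kern, p) {
  K <- kern$weights; r <- kern$radius
  nr <- nrow(img); nc <- ncol(img)
  mk <- function(i) {
    s <- st$sigma_sq[i]; ci <- st$c[i]
    out <- matrix(0, nr, nc)
    for (x1 in seq_len(nr)) for (x2 in seq_len(nc)) {
      acc <- 0
      for (d1 in -r:r) for (d2 in -r:r) {
        y1 <- x1 + d1; y2 <- x2 + d2
        if (y1 >= 1 && y1 <= nr && y2 >= 1 && y2 <= nc)
          acc <- acc + K[d1 + r + 1, d2 + r + 1] *
            (log(sqrt(2 * pi * s)) + (img[y1, y2] - st$bias[x1, x2] * ci)^2 / (2 * s))
      }
      out[x1, x2] <- E[x1, x2] * acc
    }
    out
  }
  list(e1 = mk(1), e2 = mk(2))
}

oracle_memberships <- function(phi, eps) {
  m1 <- 0.5 * (1 + (2 / pi) * atan(phi / eps))
  list(m1, 1 - m1)
}

oracle_update_c <- function(img, E, bias, phi, kern, p) {
  K <- kern$weights; r <- kern$radius
  M <- oracle_memberships(phi, p$epsilon)
  sapply(1:2, function(i) {
    num <- 0; den <- 0
    for (x1 in seq_len(nrow(img))) for (x2 in seq_len(ncol(img))) {
      kim <- oracle_conv_at(img * M[[i]], K, r, x1, x2)
      km <- oracle_conv_at(M[[i]], K, r, x1, x2)
      num <- num + E[x1, x2] * bias[x1, x2] * kim
      den <- den + E[x1, x2] * bias[x1, x2]^2 * km
    }
    num / den
  })
}

oracle_update_bias <- function(img, phi, cc, ss, kern, p) {
  K <- kern$weights; r <- kern$radius
  M <- oracle_memberships(phi, p$epsilon)
  lam <- c(p$lambda1, p$lambda2)
  wn <- lam[1] * M[[1]] * cc[1] / ss[1] + lam[2] * M[[2]] * cc[2] / ss[2]
  wd <- lam[1] * M[[1]] * cc[1]^2 / ss[1] + lam[2] * M[[2]] * cc[2]^2 / ss[2]
  out <- matrix(0, nrow(img), ncol(img))
  for (x1 in seq_len(nrow(img))) for (x2 in seq_len(ncol(img)))
    out[x1, x2] <- oracle_conv_at(img * wn, K, r, x1, x2) /
      oracle_conv_at(wd, K, r, x1, x2)
  pmax(out, p$bias_floor)
}

oracle_update_sigma <- function(img, E, bias, phi, cc, kern, p) {
  K <- kern$weights; r <- kern$radius
  M <- oracle_memberships(phi, p$epsilon)
  nr <- nrow(img); nc <- ncol(img)
  sapply(1:2, function(i) {
    num <- 0; den <- 0
    for (x1 in seq_len(nr)) for (x2 in seq_len(nc)) {
      for (d1 in -r:r) for (d2 in -r:r) {
        y1 <- x1 + d1; y2 <- x2 + d2
        if (y1 >= 1 && y1 <= nr && y2 >= 1 && y2 <= nc) {
          kv <- K[d1 + r + 1, d2 + r + 1]
          num <- num + E[x1, x2] * kv *
            (img[y1, y2] - cc[i] * bias[x1, x2])^2 * M[[i]][y1, y2]
          den <- den + E[x1, x2] * kv * M[[i]][y1, y2]
        }
      }
    }
    num / den
  })
}

oracle_data_energy <- function(img, E, st, kern, p) {
  K <- kern$weights; r <- kern$radius
  M <- oracle_memberships(st$phi, p$epsilon)
  lam <- c(p$lambda1, p$lambda2)
  nr <- nrow(img); nc <- ncol(img)
  total <- 0
  for (i in 1:2) {
    s <- st$sigma_sq[i]; ci <- st$c[i]
    for (x1 in seq_len(nr)) for (x2 in seq_len(nc)) {
      acc <- 0
      for (d1 in -r:r) for (d2 in -r:r) {
        y1 <- x1 + d1; y2 <- x2 + d2
        if (y1 >= 1 && y1 <= nr && y2 >= 1 && y2 <= nc)
          acc <- acc + K[d1 + r + 1, d2 + r + 1] * M[[i]][y1, y2] *
            (log(sqrt(2 * pi * s)) + (img[y1, y2] - st$bias[x1, x2] * ci)^2 / (2 * s))
      }
      total <- total + lam[i] * E[x1, x2] * acc
    }
  }
  total
}

# independently coded explicit-loop version of the evolution stencil
oracle_evolve_phi <- function(phi, e1, e2, p) {
  nr <- nrow(phi); nc <- ncol(phi)
  at <- function(m, i, j) m[min(max(i, 1), nr), min(max(j, 1), nc)]
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    gx[i, j] <- (at(phi, i + 1, j) - at(phi, i - 1, j)) / 2
    gy[i, j] <- (at(phi, i, j + 1) - at(phi, i, j - 1)) / 2
  }
  mag <- sqrt(gx^2 + gy^2 + p$grad_stab)
  nx <- gx / mag; ny <- gy / mag
  out <- phi
  for (i in 1:nr) for (j in 1:nc) {
    kap <- (at(nx, i + 1, j) - at(nx, i - 1, j)) / 2 +
      (at(ny, i, j + 1) - at(ny, i, j - 1)) / 2
    lap <- at(phi, i + 1, j) + at(phi, i - 1, j) +
      at(phi, i, j + 1) + at(phi, i, j - 1) - 4 * phi[i, j]
    dd <- (1 / pi) * p$epsilon / (p$epsilon^2 + phi[i, j]^2)
    out[i, j] <- phi[i, j] + p$dt *
      (-dd * (p$lambda1 * e1[i, j] - p$lambda2 * e2[i, j]) +
         p$nu * dd * kap + p$mu * (lap - kap))
  }
  out
}

# random small test instance with a fixed seed
rand_instance <- function(seed, n = 8, sigma = 1.5, radius = 3) {
  set.seed(seed)
  img <- matrix(runif(n * n, 0, 255), n, n)
  st <- list(phi = matrix(runif(n * n, -3, 3), n, n),
             c = sort(runif(2, 20, 220)),
             sigma_sq = runif(2, 100, 3000),
             bias = matrix(runif(n * n, 0.6, 1.4), n, n))
  list(img = img, st = st,
       E = local_entropy(img, 2, offset = 0),
       kern = make_kernel(sigma, radius),
       p = model_params(kernel_sigma = sigma, radius_r = radius))
}
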