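# Independent brute-force oracles: plain-loop reimplementations of every
# quality metric, kept deliberately naive (per-pixel loops, no shared code
# with the package's vectorized/C++ paths).

oracle_sobel <- function(img) {
  H <- nrow(img); W <- ncol(img)
  cl <- function(i, lo, hi) min(max(i, lo), hi)
  gx <- gy <- matrix(0, H, W)
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3)      # [di+2, dj+2]
  ky <- t(kx)
  for (i in 1:H) for (j in 1:W) {
    sx <- 0; sy <- 0
    for (di in -1:1) for (dj in -1:1) {
      v <- img[cl(i + di, 1, H), cl(j + dj, 1, W)]
      sx <- sx + kx[di + 2, dj + 2] * v
      sy <- sy + ky[di + 2, dj + 2] * v
    }
    gx[i, j] <- sx; gy[i, j] <- sy
  }
  list(gx = gx, gy = gy)
}

oracle_tenengrad <- function(img) {
  g <- oracle_sobel(img)
  H <- nrow(img); W <- ncol(img)
  acc <- 0; n <- 0
  for (i in 2:(H - 1)) for (j in 2:(W - 1)) {
    acc <- acc + g$gx[i, j]^2 + g$gy[i, j]^2
    n <- n + 1
  }
  acc / n
}

oracle_psnr <- function(ref, test, max_val = 1) {
  mse <- 0
  for (i in seq_along(ref)) mse <- mse + (ref[i] - test[i])^2
  mse <- mse / length(ref)
  if (mse == 0) Inf else 10 * log10(max_val^2 / mse)
}

oracle_pcc <- function(j, k) {
  jb <- sum(j) / length(j); kb <- sum(k) / length(k)
  num <- 0; dj2 <- 0; dk2 <- 0
  for (i in seq_along(j)) {
    num <- num + (j[i] - jb) * (k[i] - kb)
    dj2 <- dj2 + (j[i] - jb)^2
    dk2 <- dk2 + (k[i] - kb)^2
  }
  if (dj2 == 0 || dk2 == 0) return(NA_real_)
  num / sqrt(dj2 * dk2)
}

oracle_mse <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  s / length(a)
}

# Naive Canny following the documented algorithm: Gaussian smoothing
# (radius ceil(3 sigma), replicate padding), Sobel, max-normalized
# magnitude, 4-sector non-max suppression, hysteresis by repeated growth.
oracle_canny <- function(img, params) {
  H <- nrow(img); W <- ncol(img)
  cl <- function(i, lo, hi) min(max(i, lo), hi)
  sm <- img
  if (params$gaussian_sigma > 0) {
    r <- max(1, ceiling(3 * params$gaussian_sigma))
    k <- exp(-((-r:r)^2) / (2 * params$gaussian_sigma^2))
    k <- k / sum(k)
    tmp <- matrix(0, H, W)
    for (i in 1:H) for (j in 1:W) {
      s <- 0
      for (t in -r:r) s <- s + k[t + r + 1] * img[cl(i + t, 1, H), j]
      tmp[i, j] <- s
    }
    for (i in 1:H) for (j in 1:W) {
      s <- 0
      for (t in -r:r) s <- s + k[t + r + 1] * tmp[i, cl(j + t, 1, W)]
      sm[i, j] <- s
    }
  }
  g <- oracle_sobel(sm)
  mag <- sqrt(g$gx^2 + g$gy^2)
  if (max(mag) == 0) return(matrix(FALSE, H, W))
  mag <- mag / max(mag)
  keep <- matrix(FALSE, H, W)
  for (i in 1:H) for (j in 1:W) {
    a <- atan2(g$gy[i, j], g$gx[i, j])
    if (a < 0) a <- a + pi
    s <- floor((a + pi / 8) / (pi / 4)) %% 4
    d <- switch(as.character(s), "0" = c(0, 1), "1" = c(1, 1),
                "2" = c(1, 0), "3" = c(1, -1))
    nb <- function(di, dj) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > H || jj < 1 || jj > W) 0 else mag[ii, jj]
    }
    keep[i, j] <- mag[i, j] >= nb(d[1], d[2]) && mag[i, j] >= nb(-d[1], -d[2])
  }
  strong <- keep & (mag >= params$high)
  weak <- keep & (mag >= params$low)
  out <- strong
  repeat {
    grown <- out
    for (i in 1:H) for (j in 1:W) {
      if (!weak[i, j] || out[i, j]) next
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W && out[ii, jj]) {
          grown[i, j] <- TRUE
        }
      }
    }
    if (identical(grown, out)) break
    out <- grown
  }
  out
}

oracle_edge_pcc <- function(J, K, params) {
  mask <- oracle_canny(J, params)
  if (params$dilation_radius_px > 0) {
    H <- nrow(mask); W <- ncol(mask)
    r <- params$dilation_radius_px
    out <- matrix(FALSE, H, W)
    for (i in 1:H) for (j in 1:W) {
      if (!mask[i, j]) next
      for (di in -floor(r):floor(r)) for (dj in -floor(r):floor(r)) {
        if (di^2 + dj^2 > r^2 + 1e-9) next
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) out[ii, jj] <- TRUE
      }
    }
    mask <- out
  }
  if (sum(mask) < 2) return(NA_real_)
  oracle_pcc(J[mask], K[mask])
}

# Brute-force pairwise dilation-intersection contact oracle.
oracle_contacts <- function(mask, radius) {
  ids <- sort(unique(mask[mask > 0]))
  H <- nrow(mask); W <- ncol(mask)
  contact <- matrix(FALSE, H, W)
  if (length(ids) < 2) return(contact)
  dil <- lapply(ids, function(k) {
    m <- mask == k
    if (radius <= 0) return(m)
    out <- matrix(FALSE, H, W)
    for (i in 1:H) for (j in 1:W) {
      if (!m[i, j]) next
      for (di in -floor(radius):floor(radius)) {
        for (dj in -floor(radius):floor(radius)) {
          if (di^2 + dj^2 > radius^2 + 1e-9) next
          ii <- i + di; jj <- j + dj
          if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) out[ii, jj] <- TRUE
        }
      }
    }
    out
  })
  for (a in seq_along(ids)) for (b in seq_along(ids)) {
    if (b <= a) next
    contact <- contact | (dil[[a]] & dil[[b]])
  }
  contact
}

rel_err <- function(a, b) {
  if (is.na(a) && is.na(b)) return(0)
  if (is.infinite(a) && is.infinite(b) && sign(a) == sign(b)) return(0)
  abs(a - b) / max(abs(b), 1e-300)
}
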