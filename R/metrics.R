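# Image-quality evaluation: Tenenbaum gradient (sharpness), PSNR, Pearson
# correlation over all pixels or restricted to Canny edge pixels, and MSE.
#
# Conventions (documented, since the field uses several):
#  * Tenengrad is the MEAN of Gx^2 + Gy^2 over the valid interior (1-px
#    border excluded), so scores are comparable across image sizes.
#  * PCC of a constant image is undefined and reported as NA, never 0.
#  * The Canny edge mask for edge-restricted PCC is computed on the
#    REFERENCE image only, so competing restorations are scored on the same
#    pixel support.

#' Tenenbaum gradient (Tenengrad) sharpness score
#'
#' Mean over interior pixels of `Gx^2 + Gy^2`, `Gx`/`Gy` the 3x3 Sobel
#' responses.  Invariant to additive intensity offsets; higher = sharper.
#'
#' @param image Numeric matrix, at least 3x3.
#' @return Non-negative scalar.
#' @export
tenengrad <- function(image) {
  if (!is_image(image) || any(dim(image) < 3)) {
    stop("image must be a numeric matrix of size >= 3x3", call. = FALSE)
  }
  g <- sobel_cpp(image)
  H <- nrow(image); W <- ncol(image)
  i <- 2:(H - 1); j <- 2:(W - 1)
  mean(g$gx[i, j]^2 + g$gy[i, j]^2)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(max_val^2 / MSE)` in decibels; identical images give `Inf`.
#'
#' @param reference,test Equal-sized numeric matrices.
#' @param max_val Peak signal value (default 1 for float images).
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(reference, test, max_val = 1) {
  stopifnot(is_image(reference), is_image(test), max_val > 0)
  if (!identical(dim(reference), dim(test))) {
    stop("reference and test must have the same shape", call. = FALSE)
  }
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_val^2 / mse)
}

#' Pearson correlation of two images
#'
#' `sum((J-Jbar)(K-Kbar)) / sqrt(sum((J-Jbar)^2) * sum((K-Kbar)^2))` over
#' flattened pixels.  Returns `NA` (undefined) when either image is
#' constant.
#'
#' @param J,K Equal-sized numeric matrices (>= 2 pixels).
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
pcc <- function(J, K) {
  stopifnot(is_image(J), is_image(K))
  if (!identical(dim(J), dim(K))) stop("J and K must have the same shape",
                                       call. = FALSE)
  if (length(J) < 2) stop("need at least 2 pixels", call. = FALSE)
  pcc_vec(as.vector(J), as.vector(K))
}

pcc_vec <- function(j, k) {
  dj <- j - mean(j)
  dk <- k - mean(k)
  den <- sqrt(sum(dj^2) * sum(dk^2))
  if (den == 0) return(NA_real_)
  sum(dj * dk) / den
}

#' Canny edge-detection parameters
#'
#' @param gaussian_sigma Pre-smoothing sd in px (default 1).
#' @param low,high Hysteresis thresholds on the max-normalized gradient
#'   magnitude in `[0, 1]` (defaults 0.1, 0.2; `low < high`).
#' @param dilation_radius_px Radius by which the edge mask is dilated before
#'   use (default 1).
#' @return An object of class `"edge_params"`.
#' @export
edge_params <- function(gaussian_sigma = 1, low = 0.1, high = 0.2,
                        dilation_radius_px = 1) {
  if (low >= high) stop("low must be < high", call. = FALSE)
  if (dilation_radius_px < 0) stop("dilation radius must be >= 0", call. = FALSE)
  structure(list(gaussian_sigma = gaussian_sigma, low = low, high = high,
                 dilation_radius_px = dilation_radius_px),
            class = "edge_params")
}

#' Canny edge mask
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, and hysteresis thresholding on the
#' max-normalized magnitude.
#'
#' @param image Numeric matrix.
#' @param params An [edge_params()].
#' @return Logical matrix of edge pixels.
#' @export
canny_edges <- function(image, params = edge_params()) {
  stopifnot(is_image(image), inherits(params, "edge_params"))
  sm <- image
  if (params$gaussian_sigma > 0) {
    r <- max(1, ceiling(3 * params$gaussian_sigma))
    k <- exp(-((-r:r)^2) / (2 * params$gaussian_sigma^2))
    sm <- conv2_sep_cpp(image, k / sum(k))
  }
  g <- sobel_cpp(sm)
  mag <- sqrt(g$gx^2 + g$gy^2)
  mmax <- max(mag)
  if (mmax == 0) return(matrix(FALSE, nrow(image), ncol(image)))
  mag <- mag / mmax
  # quantize gradient direction into 4 sectors and compare with the two
  # neighbors along it
  ang <- atan2(g$gy, g$gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- floor((ang + pi / 8) / (pi / 4)) %% 4  # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  H <- nrow(mag); W <- ncol(mag)
  shift <- function(m, di, dj) {
    out <- matrix(0, H, W)
    si <- max(1, 1 + di):min(H, H + di)
    sj <- max(1, 1 + dj):min(W, W + dj)
    out[si, sj] <- m[si - di, sj - dj]
    out
  }
  n1 <- matrix(0, H, W); n2 <- matrix(0, H, W)
  dirs <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  for (s in 0:3) {
    d <- dirs[[as.character(s)]]
    sel <- sector == s
    n1[sel] <- shift(mag, d[1], d[2])[sel]
    n2[sel] <- shift(mag, -d[1], -d[2])[sel]
  }
  keep <- mag >= n1 & mag >= n2
  strong <- keep & mag >= params$high
  weak <- keep & mag >= params$low
  # hysteresis: strong pixels seed connected weak components (8-connected)
  lab <- label_components_cpp(weak, 8L)
  good <- unique(lab[strong])
  good <- good[good > 0]
  weak & matrix(lab %in% good, H, W)
}

# Binary dilation by a Euclidean disk of radius r (r = 0 is the identity).
dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(FALSE, H, W)
  r <- floor(radius)
  for (di in -r:r) for (dj in -r:r) {
    if (di^2 + dj^2 > radius^2 + 1e-9) next
    si <- max(1, 1 + di):min(H, H + di)
    sj <- max(1, 1 + dj):min(W, W + dj)
    out[si, sj] <- out[si, sj] | mask[si - di, sj - dj]
  }
  out
}

#' Edge-restricted Pearson correlation
#'
#' PCC over the pixels of the Canny edge mask of the REFERENCE image `J`
#' (optionally dilated).  `NA` when the mask is empty or either image is
#' constant over it.
#'
#' @inheritParams pcc
#' @param params An [edge_params()].
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
edge_pcc <- function(J, K, params = edge_params()) {
  stopifnot(is_image(J), is_image(K))
  if (!identical(dim(J), dim(K))) stop("J and K must have the same shape",
                                       call. = FALSE)
  mask <- dilate_mask(canny_edges(J, params), params$dilation_radius_px)
  if (sum(mask) < 2) return(NA_real_)
  pcc_vec(J[mask], K[mask])
}

#' Full metric report for one image pair
#'
#' @inheritParams pcc
#' @param params An [edge_params()] for the edge-restricted PCC.
#' @return A list with `tenengrad` (of `K`, the test image), `psnr_db`,
#'   `pcc`, `edge_pcc` and `mse`.
#' @export
metric_report <- function(J, K, params = edge_params()) {
  list(tenengrad = tenengrad(K), psnr_db = psnr(J, K), pcc = pcc(J, K),
       edge_pcc = edge_pcc(J, K, params), mse = mean((J - K)^2))
}

#' Evaluate aligned sets of image pairs
#'
#' @param reference_set,test_set Equal-length lists of equal-sized images.
#' @param params An [edge_params()].
#' @return A list with `per_pair` (data frame, one row per pair, including
#'   the reference's own Tenengrad) and `summary` (median and IQR per
#'   metric, with the count of undefined values excluded).
#' @export
evaluate_pairs <- function(reference_set, test_set, params = edge_params()) {
  if (length(reference_set) != length(test_set)) {
    stop("reference and test sets must have equal length", call. = FALSE)
  }
  n <- length(reference_set)
  per <- data.frame(
    pair = seq_len(n), tenengrad_ref = numeric(n), tenengrad_test = numeric(n),
    psnr_db = numeric(n), pcc = numeric(n), edge_pcc = numeric(n),
    mse = numeric(n)
  )
  for (i in seq_len(n)) {
    J <- reference_set[[i]]; K <- test_set[[i]]
    r <- metric_report(J, K, params)
    per$tenengrad_ref[i] <- tenengrad(J)
    per$tenengrad_test[i] <- r$tenengrad
    per$psnr_db[i] <- r$psnr_db
    per$pcc[i] <- r$pcc
    per$edge_pcc[i] <- r$edge_pcc
    per$mse[i] <- r$mse
  }
  metrics <- c("tenengrad_test", "psnr_db", "pcc", "edge_pcc", "mse")
  summ <- do.call(rbind, lapply(metrics, function(m) {
    v <- per[[m]]
    ok <- is.finite(v) | (m == "psnr_db" & is.infinite(v) & v > 0)
    vv <- v[is.finite(v)]
    data.frame(metric = m,
               median = if (length(vv)) median(vv) else
                 if (any(ok)) Inf else NA_real_,
               iqr = if (length(vv) > 1) diff(quantile(vv, c(.25, .75),
                                                       names = FALSE)) else 0,
               n_excluded = sum(!ok))
  }))
  if (n == 0) summ <- summ[0, , drop = FALSE]
  list(per_pair = per, summary = summ)
}
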