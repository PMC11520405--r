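# Downstream analysis: classical cell segmentation, contact-region
# detection and fidelity scoring.
#
# The production segmenter in the assay this package emulates is a MaskRCNN
# trained on thousands of annotated microscopy images; its weights cannot be
# shipped, so a deterministic classical pipeline (well-border suppression,
# Otsu threshold on the darker cell bodies, hole filling, minimum-area
# filter, watershed split on the distance transform) stands in.  It is
# adequate for simulator imagery and reproduces the failure mechanism of
# interest: defocus blur thickens apparent boundaries, inflating instance
# areas and creating false cell-cell contacts.

#' Segmentation parameters
#'
#' @param margin_frac Fraction of the image side excluded on each edge so
#'   the dark well border is not segmented as foreground (default 0.15).
#' @param smooth_sigma Gaussian pre-smoothing sd in px.
#' @param threshold `"otsu"` or a fixed numeric threshold; foreground is
#'   darker than the threshold (cell bodies are dark in this modality).
#' @param min_area_px Instances below this area are dropped.
#' @param marker_min_dist Minimum interior distance (px) for a watershed
#'   marker.
#' @param min_contrast Minimum separation between the mean intensities
#'   below/above the threshold; below it the image is treated as empty
#'   (guards Otsu against splitting pure background noise).
#' @return An object of class `"segment_params"`.
#' @export
segment_params <- function(margin_frac = 0.15, smooth_sigma = 1,
                           threshold = "otsu", min_area_px = 20L,
                           marker_min_dist = 2.5, min_contrast = 0.03) {
  structure(list(margin_frac = margin_frac, smooth_sigma = smooth_sigma,
                 threshold = threshold, min_area_px = as.integer(min_area_px),
                 marker_min_dist = marker_min_dist,
                 min_contrast = min_contrast),
            class = "segment_params")
}

#' Otsu threshold of a numeric vector/matrix
#'
#' @param x Numeric values in `[0, 1]`.
#' @param n_bins Histogram resolution.
#' @return Threshold scalar.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.vector(x)
  h <- tabulate(pmin(pmax(floor(v * n_bins) + 1, 1), n_bins), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(n_bins) - 0.5) / n_bins)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  which.max(sigma_b) / n_bins
}

#' Segment cells in a nanowell image
#'
#' @param image Grayscale image in `[0, 1]`.
#' @param params A [segment_params()].
#' @return An object of class `"label_mask"`: an integer matrix (0 =
#'   background, k = instance k, labels contiguous from 1) with a vector of
#'   per-instance pixel areas in `attr(, "areas")`.
#' @export
segment_cells <- function(image, params = segment_params()) {
  check_image01(image)
  H <- nrow(image); W <- ncol(image)
  sm <- image
  if (params$smooth_sigma > 0) {
    r <- max(1, ceiling(3 * params$smooth_sigma))
    k <- exp(-((-r:r)^2) / (2 * params$smooth_sigma^2))
    sm <- conv2_sep_cpp(image, k / sum(k))
  }
  mi <- max(1L, round(params$margin_frac * H))
  mj <- max(1L, round(params$margin_frac * W))
  interior <- matrix(FALSE, H, W)
  interior[(mi + 1):(H - mi), (mj + 1):(W - mj)] <- TRUE
  thr <- if (identical(params$threshold, "otsu")) {
    otsu_threshold(sm[interior])
  } else {
    params$threshold
  }
  vals <- sm[interior]
  lo <- vals[vals < thr]
  hi <- vals[vals >= thr]
  if (!length(lo) || !length(hi) ||
      mean(hi) - mean(lo) < params$min_contrast) {
    out <- matrix(0L, H, W)
    attr(out, "areas") <- integer(0)
    class(out) <- c("label_mask", class(out))
    return(out)
  }
  fg <- sm < thr & interior
  # fill holes: background components not connected to the image border
  bg_lab <- label_components_cpp(!fg, 4L)
  border_labels <- unique(c(bg_lab[1, ], bg_lab[H, ], bg_lab[, 1], bg_lab[, W]))
  fg <- fg | !(matrix(bg_lab %in% border_labels, H, W))
  # minimum-area filter
  lab0 <- label_components_cpp(fg, 8L)
  if (max(lab0) > 0) {
    areas0 <- tabulate(lab0[lab0 > 0], max(lab0))
    fg <- fg & matrix(!(lab0 %in% which(areas0 < params$min_area_px)), H, W) &
      lab0 > 0
  }
  if (!any(fg)) {
    out <- matrix(0L, H, W)
    attr(out, "areas") <- integer(0)
    class(out) <- c("label_mask", class(out))
    return(out)
  }
  # watershed split on the chamfer distance transform
  dist <- chamfer_dt_cpp(fg)
  mx <- dist
  shift_max <- function(m, di, dj) {
    out <- matrix(-Inf, H, W)
    si <- max(1, 1 + di):min(H, H + di)
    sj <- max(1, 1 + dj):min(W, W + dj)
    out[si, sj] <- m[si - di, sj - dj]
    out
  }
  for (di in -2:2) for (dj in -2:2) {
    if (di == 0 && dj == 0) next
    mx <- pmax(mx, shift_max(dist, di, dj))
  }
  peaks <- fg & dist >= mx & dist >= params$marker_min_dist
  if (!any(peaks)) peaks <- fg & dist == max(dist[fg])
  markers <- label_components_cpp(peaks, 8L)
  lab <- watershed_cpp(dist, markers, fg)
  # relabel contiguously in scan order
  ids <- sort(unique(lab[lab > 0]))
  out <- matrix(match(lab, ids, nomatch = 0L), H, W)
  # merge then re-check min area (watershed can carve small basins)
  areas <- tabulate(out[out > 0], length(ids))
  keep <- which(areas >= params$min_area_px)
  out <- matrix(match(out, keep, nomatch = 0L), H, W)
  attr(out, "areas") <- as.integer(areas[keep])
  class(out) <- c("label_mask", class(out))
  out
}

#' Detect cell-cell contact regions
#'
#' Each instance support is dilated by a Euclidean disk of radius
#' `touch_radius_px`; contact pixels are those covered by at least two
#' distinct dilated instances.  With radius 0 the supports are used as-is,
#' so disjoint hard masks yield no contact; radius 1 (the default) captures
#' boundary adjacency.  Invariant under instance relabeling.
#'
#' @param mask A `"label_mask"` (or plain integer matrix).
#' @param touch_radius_px Dilation radius (>= 0, default 1).
#' @return An object of class `"contact_mask"`: a logical matrix with the
#'   contributing instance pairs in `attr(, "pairs")`.
#' @export
detect_contacts <- function(mask, touch_radius_px = 1) {
  stopifnot(is.matrix(mask))
  ids <- sort(unique(mask[mask > 0]))
  H <- nrow(mask); W <- ncol(mask)
  contact <- matrix(FALSE, H, W)
  pairs <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  if (length(ids) >= 2) {
    dil <- lapply(ids, function(k) dilate_mask(mask == k, touch_radius_px))
    for (a in seq_along(ids)) {
      for (b in seq_along(ids)) {
        if (b <= a) next
        inter <- dil[[a]] & dil[[b]]
        if (any(inter)) {
          contact <- contact | inter
          pairs <- rbind(pairs, c(ids[a], ids[b]))
        }
      }
    }
  }
  structure(contact, pairs = pairs, class = c("contact_mask", "matrix"))
}

#' Contact-mask fidelity against a reference
#'
#' Pearson correlation and mean squared error of two binary contact masks;
#' PCC is `NA` when either mask is constant (e.g. both empty).
#'
#' @param reference,test Equal-sized logical/0-1 matrices.
#' @return A list with `pcc` and `mse`.
#' @export
contact_fidelity <- function(reference, test) {
  ref <- matrix(as.numeric(reference), nrow(reference))
  tst <- matrix(as.numeric(test), nrow(test))
  if (!identical(dim(ref), dim(tst))) {
    stop("contact masks must have the same shape", call. = FALSE)
  }
  list(pcc = pcc(ref, tst), mse = mean((ref - tst)^2))
}

#' Cell-count error over aligned frame sequences
#'
#' @param reference_masks,test_masks Equal-length lists of `"label_mask"`s
#'   (or plain numeric instance counts).
#' @return A list with `per_frame` absolute count differences, their `sum`
#'   and `mean`.
#' @export
count_error <- function(reference_masks, test_masks) {
  if (length(reference_masks) != length(test_masks)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  n_of <- function(x) {
    if (is.matrix(x)) length(unique(x[x > 0])) else as.numeric(x)
  }
  per <- mapply(function(r, t) abs(n_of(r) - n_of(t)),
                reference_masks, test_masks)
  per <- as.numeric(per)
  list(per_frame = per, sum = sum(per), mean = mean(per))
}
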