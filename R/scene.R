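# Synthetic nanowell scene rendering and parametric defocus.
#
# The simulator emulates label-free (phase-contrast-like) imaging of square
# PDMS nanowells, 50 um edge length, holding a few cells or beads.  Cells
# appear as darker bodies with a thin bright halo rim; beads as bright disks
# with a dark rim.  Defocus is modeled as a parametric blur whose kernel
# width grows linearly with the axial offset |dz|, followed by contrast loss
# toward the image mean and fresh acquisition noise.

#' Scene specification for the nanowell simulator
#'
#' @param image_size_px Side of the square output image, in pixels.
#' @param pixel_pitch_um Microns per pixel.  The default (0.325) makes a
#'   50 um well span ~154 px; coarser pitches give desk-scale images.
#' @param well_edge_um Well edge length in microns (default 50).
#' @param n_cells Number of objects to place (>= 0).
#' @param object_kind One of `"round_cell"`, `"elongated_cell"`, `"bead"`.
#' @param radius_um_range Length-2 numeric, min/max object radius in microns.
#' @param intensity_fg,intensity_bg Object interior / background intensity
#'   in `[0, 1]`.
#' @param noise_sigma Additive Gaussian acquisition-noise sd.
#' @param halo_strength Amplitude of the bright phase-contrast-like rim in
#'   `[0, 1]`.
#' @return An object of class `"scene_spec"`.
#' @export
scene_spec <- function(image_size_px = 160L, pixel_pitch_um = 0.325,
                       well_edge_um = 50, n_cells = 2L,
                       object_kind = c("round_cell", "elongated_cell", "bead"),
                       radius_um_range = c(4, 6), intensity_fg = 0.25,
                       intensity_bg = 0.55, noise_sigma = 0.01,
                       halo_strength = 0.5) {
  object_kind <- match.arg(object_kind)
  spec <- structure(list(
    image_size_px = as.integer(image_size_px),
    pixel_pitch_um = pixel_pitch_um, well_edge_um = well_edge_um,
    n_cells = as.integer(n_cells), object_kind = object_kind,
    radius_um_range = radius_um_range, intensity_fg = intensity_fg,
    intensity_bg = intensity_bg, noise_sigma = noise_sigma,
    halo_strength = halo_strength
  ), class = "scene_spec")
  validate_scene_spec(spec)
}

validate_scene_spec <- function(spec) {
  with(spec, {
    if (image_size_px < 8) stop("image_size_px too small", call. = FALSE)
    if (well_edge_um / pixel_pitch_um > image_size_px) {
      stop("well does not fit inside the image: well_edge_um / pixel_pitch_um",
           " must be <= image_size_px", call. = FALSE)
    }
    if (length(radius_um_range) != 2 || any(radius_um_range <= 0) ||
        diff(radius_um_range) < 0) {
      stop("radius_um_range must be positive and ordered", call. = FALSE)
    }
    ints <- c(intensity_fg, intensity_bg, halo_strength)
    if (any(ints < 0 | ints > 1)) stop("intensities must lie in [0, 1]", call. = FALSE)
    if (n_cells < 0) stop("n_cells must be >= 0", call. = FALSE)
    if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  })
  spec
}

#' Parametric defocus model
#'
#' Axial offsets map to blur width as `sigma = sigma_per_um * |dz|`, the
#' classical small-defocus approximation with a Gaussian (or flat disk) PSF.
#' `dz = 0` is the identity transform.
#'
#' @param sigma_per_um Blur-kernel scale in px per micron of `|dz|` (> 0).
#' @param psf_family `"gaussian"` or `"disk"`.
#' @param contrast_decay_per_um Fractional contrast lost per micron of
#'   `|dz|`; the remaining contrast is clamped at 20% of the original.
#' @return An object of class `"defocus_model"`.
#' @export
defocus_model <- function(sigma_per_um = 0.4,
                          psf_family = c("gaussian", "disk"),
                          contrast_decay_per_um = 0.05) {
  psf_family <- match.arg(psf_family)
  if (sigma_per_um <= 0) stop("sigma_per_um must be > 0", call. = FALSE)
  if (contrast_decay_per_um < 0) stop("contrast_decay_per_um must be >= 0",
                                      call. = FALSE)
  structure(list(sigma_per_um = sigma_per_um, psf_family = psf_family,
                 contrast_decay_per_um = contrast_decay_per_um),
            class = "defocus_model")
}

#' Blur width for an axial offset
#'
#' @param delta_z_um Signed axial offset in microns.
#' @param model A [defocus_model()].
#' @return Blur sigma in pixels; even in `delta_z_um`, zero at 0.
#' @export
defocus_sigma <- function(delta_z_um, model) {
  stopifnot(inherits(model, "defocus_model"))
  model$sigma_per_um * abs(delta_z_um)
}

# Sample an object layout (centers, radii, orientation) inside the well by
# rejection sampling; uses the ambient RNG stream.
sample_layout <- function(spec) {
  px <- spec$well_edge_um / spec$pixel_pitch_um
  ctr <- (spec$image_size_px + 1) / 2
  he <- px / 2
  n <- spec$n_cells
  out <- vector("list", n)
  if (n == 0) return(out)
  max_tries <- 200L * n
  tries <- 0L
  placed <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("failed to place ", n, " non-overlapping objects after ",
           max_tries, " tries; reduce n_cells or radii", call. = FALSE)
    }
    r <- runif(1, spec$radius_um_range[1], spec$radius_um_range[2]) /
      spec$pixel_pitch_um
    obj <- list(r = r, kind = spec$object_kind, a = r, b = r, theta = 0)
    if (spec$object_kind == "elongated_cell") {
      # wall-adherent: elongate along a randomly chosen wall, axis ratio <= 3
      f <- runif(1, 1.1, sqrt(3))
      obj$a <- r * f
      obj$b <- r / f
      side <- sample.int(4L, 1)
      along <- runif(1, -he + obj$a + 3, he - obj$a - 3)
      offw <- he - obj$b - 2.5
      if (side == 1L) { obj$cx <- ctr + along; obj$cy <- ctr - offw; obj$theta <- 0 }
      if (side == 2L) { obj$cx <- ctr + along; obj$cy <- ctr + offw; obj$theta <- 0 }
      if (side == 3L) { obj$cx <- ctr - offw; obj$cy <- ctr + along; obj$theta <- pi / 2 }
      if (side == 4L) { obj$cx <- ctr + offw; obj$cy <- ctr + along; obj$theta <- pi / 2 }
    } else {
      marg <- r + 3.5
      obj$cx <- runif(1, ctr - he + marg, ctr + he - marg)
      obj$cy <- runif(1, ctr - he + marg, ctr + he - marg)
    }
    ok <- TRUE
    if (placed > 0) {
      for (p in out[seq_len(placed)]) {
        gap <- sqrt((p$cx - obj$cx)^2 + (p$cy - obj$cy)^2)
        if (gap < max(p$a, p$b) + max(obj$a, obj$b) + 3) { ok <- FALSE; break }
      }
    }
    if (ok) {
      placed <- placed + 1L
      out[[placed]] <- obj
    }
  }
  out
}

# Deterministic rendering of a layout (no RNG except the noise draw, which
# the caller seeds).
render_layout <- function(spec, layout, add_noise = TRUE) {
  n <- spec$image_size_px
  px <- spec$well_edge_um / spec$pixel_pitch_um
  ctr <- (n + 1) / 2
  he <- px / 2
  X <- matrix(rep(seq_len(n), each = n), n)   # column index (x)
  Y <- matrix(rep(seq_len(n), times = n), n)  # row index (y)
  img <- matrix(spec$intensity_bg, n, n)
  # dark well border, ~1.5 px wide Gaussian profile on the square outline
  dsq <- pmax(abs(X - ctr), abs(Y - ctr)) - he
  bw <- exp(-(dsq / 1.2)^2)
  img <- img * (1 - bw) + 0.22 * bw
  masks <- vector("list", length(layout))
  for (i in seq_along(layout)) {
    o <- layout[[i]]
    xr <- (X - o$cx) * cos(o$theta) + (Y - o$cy) * sin(o$theta)
    yr <- -(X - o$cx) * sin(o$theta) + (Y - o$cy) * cos(o$theta)
    if (o$a == o$b) {
      s <- sqrt((X - o$cx)^2 + (Y - o$cy)^2) - o$r
    } else {
      q <- sqrt((xr / o$a)^2 + (yr / o$b)^2)
      s <- (q - 1) * o$b  # approximate signed distance to the ellipse
    }
    cov <- pmin(pmax(0.5 - s, 0), 1)  # anti-aliased body coverage
    if (o$kind == "bead") {
      img <- img * (1 - cov) + 0.82 * cov
      rim <- exp(-((s - 0.3) / 0.8)^2)
      img <- img - 0.5 * spec$halo_strength * rim * img
    } else {
      img <- img * (1 - cov) + spec$intensity_fg * cov
      rim <- exp(-((s - 0.9) / 0.8)^2)
      img <- img + spec$halo_strength * rim * (0.95 - img)
    }
    masks[[i]] <- s <= 0
  }
  if (add_noise && spec$noise_sigma > 0) {
    img <- img + matrix(rnorm(n * n, sd = spec$noise_sigma), n)
  }
  list(image = clip01(img), masks = masks)
}

#' Render a synthetic nanowell scene
#'
#' @param spec A [scene_spec()].
#' @param seed Integer seed; the render is a pure function of
#'   `(spec, seed)`.
#' @return A list with `image` (matrix in `[0, 1]`), `masks` (list of
#'   per-object logical matrices) and `layout` (object centers/radii, used
#'   by [simulate_video()]).
#' @export
render_scene <- function(spec, seed) {
  validate_scene_spec(spec)
  with_seed(seed, {
    layout <- sample_layout(spec)
    out <- render_layout(spec, layout)
    out$layout <- layout
    out
  })
}

#' Apply parametric defocus blur to an image
#'
#' Convolves with the PSF of width [defocus_sigma()], scales contrast toward
#' the image mean by `contrast_decay_per_um * |dz|` (clamped so at least 20%
#' of the original contrast survives), adds fresh acquisition noise, and
#' clips to `[0, 1]`.  `dz = 0` with `noise_sigma = 0` returns the input
#' exactly.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param delta_z_um Signed axial offset in microns.
#' @param model A [defocus_model()].
#' @param seed Optional seed for the noise draw.
#' @param noise_sigma Acquisition-noise sd (default 0.01; set 0 to disable).
#' @return Degraded image, same size, in `[0, 1]`.
#' @export
apply_defocus <- function(image, delta_z_um, model, seed = NULL,
                          noise_sigma = 0.01) {
  check_image01(image)
  stopifnot(inherits(model, "defocus_model"))
  sigma <- defocus_sigma(delta_z_um, model)
  if (sigma == 0 && noise_sigma == 0) return(image)
  out <- image
  if (sigma > 0) {
    if (model$psf_family == "gaussian") {
      r <- ceiling(3 * sigma)
      if (2 * r + 1 > min(dim(image))) {
        stop("PSF kernel (", 2 * r + 1, " px) larger than image", call. = FALSE)
      }
      k <- exp(-((-r:r)^2) / (2 * sigma^2))
      out <- conv2_sep_cpp(out, k / sum(k))
    } else {
      r <- max(1, round(sigma))
      if (2 * r + 1 > min(dim(image))) {
        stop("PSF kernel (", 2 * r + 1, " px) larger than image", call. = FALSE)
      }
      off <- expand.grid(a = -r:r, b = -r:r)
      ker <- matrix(as.numeric(off$a^2 + off$b^2 <= r^2 + 0.25), 2 * r + 1)
      out <- conv2_cpp(out, ker / sum(ker))
    }
    ctr <- max(0.2, 1 - model$contrast_decay_per_um * abs(delta_z_um))
    m <- mean(out)
    out <- m + (out - m) * ctr
  }
  if (noise_sigma > 0) {
    out <- with_seed(seed, out + matrix(rnorm(length(out), sd = noise_sigma),
                                        nrow(out)))
  }
  clip01(out)
}
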