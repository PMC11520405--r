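# Desk-scale fixtures shared across test files.  The desk world: 64x64 px
# at 1 um/px (a 50 um well spans 50 px), 2 round cells of radius 4-6 um,
# Gaussian defocus PSF with sigma = 0.4 px/um and 5%/um contrast decay.

desk_scene <- function(n_cells = 2L, ...) {
  scene_spec(image_size_px = 64L, pixel_pitch_um = 1.0, n_cells = n_cells,
             radius_um_range = c(4, 6), noise_sigma = 0.01, ...)
}

desk_defocus <- function(...) defocus_model(...)

# A tiny net/schedule for fast contract tests (not for quality claims).
tiny_schedule <- function() make_schedule(6L)
tiny_denoiser <- function() denoiser_spec(base_channels = 4L, n_layers = 2L)

random_image <- function(h = 8, w = h) matrix(runif(h * w), h, w)
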