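# Time-lapse simulation: cells perform a bounded random walk inside the
# well while intermittent OOF "bursts" (a stage/autofocus excursion lasting
# a few frames at a constant axial offset) corrupt the observed frames.

#' Video specification
#'
#' @param n_frames Number of frames (>= 1).
#' @param motion_step_px Per-frame sd of the cell displacement (px).
#' @param oof_event_rate Probability that a new defocus burst starts at a
#'   frame when none is active, in `[0, 1]`.
#' @param oof_burst_len_frames Length-2 integer range of burst durations.
#' @param burst_delta_z_um Positive offsets from which a burst's `|dz|` is
#'   drawn (sign random); default `c(5, 10)`.
#' @return An object of class `"video_spec"`.
#' @export
video_spec <- function(n_frames = 37L, motion_step_px = 1.0,
                       oof_event_rate = 0.05,
                       oof_burst_len_frames = c(2L, 4L),
                       burst_delta_z_um = c(5, 10)) {
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  if (oof_event_rate < 0 || oof_event_rate > 1) {
    stop("oof_event_rate must lie in [0, 1]", call. = FALSE)
  }
  if (any(oof_burst_len_frames < 1) || diff(oof_burst_len_frames) < 0) {
    stop("oof_burst_len_frames must be an ordered range >= 1", call. = FALSE)
  }
  structure(list(n_frames = as.integer(n_frames),
                 motion_step_px = motion_step_px,
                 oof_event_rate = oof_event_rate,
                 oof_burst_len_frames = as.integer(oof_burst_len_frames),
                 burst_delta_z_um = burst_delta_z_um),
            class = "video_spec")
}

# Burst process for the axial offset trace; runs on the ambient RNG stream.
sample_z_trace <- function(video) {
  z <- numeric(video$n_frames)
  remaining <- 0L
  current <- 0
  for (i in seq_len(video$n_frames)) {
    if (remaining == 0L && runif(1) < video$oof_event_rate) {
      remaining <- if (video$oof_burst_len_frames[1] ==
                       video$oof_burst_len_frames[2]) {
        video$oof_burst_len_frames[1]
      } else {
        sample(seq(video$oof_burst_len_frames[1],
                   video$oof_burst_len_frames[2]), 1)
      }
      current <- sample(c(-1, 1), 1) *
        if (length(video$burst_delta_z_um) == 1) video$burst_delta_z_um else
          sample(video$burst_delta_z_um, 1)
    }
    if (remaining > 0L) {
      z[i] <- current
      remaining <- remaining - 1L
    }
  }
  z
}

#' Simulate a nanowell time-lapse video
#'
#' Cells random-walk inside the well with reflecting walls; the observed
#' frame is the in-focus render degraded by [apply_defocus()] at the frame's
#' axial offset (`z_trace`, 0 outside bursts).
#'
#' @param scene A [scene_spec()].
#' @param video A [video_spec()].
#' @param model A [defocus_model()].
#' @param seed Integer seed.
#' @return A list with `in_focus` (list of frames), `observed` (list of
#'   frames), `masks` (per-frame list of per-object masks) and `z_trace`.
#' @export
simulate_video <- function(scene, video, model, seed = 1L) {
  validate_scene_spec(scene)
  stopifnot(inherits(video, "video_spec"), inherits(model, "defocus_model"))
  px <- scene$well_edge_um / scene$pixel_pitch_um
  ctr <- (scene$image_size_px + 1) / 2
  he <- px / 2
  state <- with_seed(seed, {
    layout <- sample_layout(scene)
    z <- sample_z_trace(video)
    steps <- if (length(layout)) {
      array(rnorm(2 * length(layout) * video$n_frames,
                  sd = video$motion_step_px),
            dim = c(length(layout), 2, video$n_frames))
    } else {
      array(0, dim = c(0, 2, video$n_frames))
    }
    list(layout = layout, z = z, steps = steps)
  })
  layout <- state$layout
  reflect <- function(v, lo, hi) {
    # reflect into [lo, hi]
    while (v < lo || v > hi) {
      if (v < lo) v <- lo + (lo - v)
      if (v > hi) v <- hi - (v - hi)
    }
    v
  }
  in_focus <- observed <- masks <- vector("list", video$n_frames)
  for (f in seq_len(video$n_frames)) {
    if (f > 1 && length(layout)) {
      for (i in seq_along(layout)) {
        o <- layout[[i]]
        marg <- max(o$a, o$b) + 3
        o$cx <- reflect(o$cx + state$steps[i, 1, f], ctr - he + marg,
                        ctr + he - marg)
        o$cy <- reflect(o$cy + state$steps[i, 2, f], ctr - he + marg,
                        ctr + he - marg)
        layout[[i]] <- o
      }
    }
    # ground-truth frames are rendered noise-free; the single acquisition
    # noise draw happens in apply_defocus (also for in-focus frames, dz = 0)
    fr <- render_layout(scene, layout, add_noise = FALSE)
    in_focus[[f]] <- fr$image
    masks[[f]] <- fr$masks
    observed[[f]] <- apply_defocus(fr$image, state$z[f], model,
                                   seed = sub_seed(seed, 20000 + f),
                                   noise_sigma = scene$noise_sigma)
  }
  list(in_focus = in_focus, observed = observed, masks = masks,
       z_trace = state$z)
}
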