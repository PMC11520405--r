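# Two-step selective restoration workflow: assess every video with the
# focus classifier, restore only the frames flagged OOF, and account for
# usable-video yield before and after.  A video is unusable ("flagged")
# when STRICTLY more than 5% of its frames are OOF.

#' Assess a video's focus state
#'
#' Runs [predict_frame()] on every frame; the video is flagged when the OOF
#' fraction is strictly greater than `threshold` ("more than 5%": a video
#' at exactly the threshold is NOT flagged).
#'
#' @param frames List of grayscale frames in `[0, 1]`.
#' @param classifier A `"focus_classifier"`, or (as a test-harness hook) a
#'   function mapping one frame to an OOF score in `[0, 1]` (labeled OOF at
#'   score >= 0.5).
#' @param threshold Flagging threshold on the OOF frame fraction
#'   (default 0.05).
#' @return An object of class `"video_assessment"`: `n_frames`,
#'   `oof_frame_indices`, `oof_fraction`, `flagged`, `scores`.
#' @export
assess_video <- function(frames, classifier, threshold = 0.05) {
  if (length(frames) == 0) stop("empty frame sequence", call. = FALSE)
  pred <- if (is.function(classifier)) {
    score <- vapply(frames, classifier, numeric(1))
    data.frame(score = score,
               label = ifelse(score >= 0.5, "oof", "in_focus"))
  } else {
    predict_frame(classifier, frames)
  }
  idx <- which(pred$label == "oof")
  frac <- length(idx) / length(frames)
  structure(list(n_frames = length(frames), oof_frame_indices = idx,
                 oof_fraction = frac, flagged = frac > threshold,
                 threshold = threshold, scores = pred$score),
            class = "video_assessment")
}

#' Oracle restorer (test harness)
#'
#' Replaces each flagged frame with the stored ground-truth frame instead
#' of running a model; used to validate yield accounting independently of
#' restoration quality.
#'
#' @param truth_frames List of ground-truth frames, aligned with the video.
#' @return An object of class `"oracle_restorer"`.
#' @export
oracle_restorer <- function(truth_frames) {
  structure(list(truth = truth_frames), class = "oracle_restorer")
}

restore_one_frame <- function(restorer, frame, index, K, seed) {
  if (inherits(restorer, "oracle_restorer")) {
    return(restorer$truth[[index]])
  }
  if (inherits(restorer, "focus_ddpm")) {
    return(restore_averaged(restorer, frame, K = K,
                            seed = sub_seed(seed, index))$mean_image)
  }
  if (inherits(restorer, "focus_regressor")) {
    return(predict_regression(restorer, frame))
  }
  stop("unknown restorer type", call. = FALSE)
}

#' Selectively restore the OOF frames of a video
#'
#' Frames at `assessment$oof_frame_indices` are replaced by the restorer's
#' output (for a diffusion model, the K-sample mean image); every other
#' frame is returned bit-identical.
#'
#' @param frames List of frames the assessment was computed from.
#' @param assessment A `"video_assessment"`.
#' @param restorer A `"focus_ddpm"`, `"focus_regressor"` or
#'   [oracle_restorer()].
#' @param K Samples per frame for diffusion restoration (default 5).
#' @param seed Integer seed (sub-seeded per frame).
#' @return List of frames, same length.
#' @export
restore_video <- function(frames, assessment, restorer, K = 5L, seed = 1L) {
  stopifnot(inherits(assessment, "video_assessment"))
  if (assessment$n_frames != length(frames)) {
    stop("assessment does not match the frame sequence", call. = FALSE)
  }
  if (length(assessment$oof_frame_indices) &&
      max(assessment$oof_frame_indices) > length(frames)) {
    stop("OOF frame index out of range", call. = FALSE)
  }
  out <- frames
  for (i in assessment$oof_frame_indices) {
    out[[i]] <- restore_one_frame(restorer, frames[[i]], i, K, seed)
  }
  out
}

#' Usable-video yield before and after selective restoration
#'
#' Assesses every video, restores the OOF frames of flagged videos, then
#' re-assesses the restored videos.  By default re-assessment runs the SAME
#' classifier on the restored frames; `reassess = "assume_in_focus"` scores
#' restored frames as in-focus by fiat (ablation switch, since either
#' reading of post-restoration accounting is defensible).
#'
#' @param videos List of videos; each is a list with `frames` (and, for an
#'   [oracle_restorer()] built per video from ground truth, `truth`).
#' @param classifier A `"focus_classifier"`.
#' @param restorer A restorer (see [restore_video()]), or the string
#'   `"oracle"` to substitute each video's own `truth` frames.
#' @param threshold Flagging threshold (default 0.05).
#' @param K Samples per restored frame for diffusion restoration.
#' @param seed Integer seed.
#' @param reassess `"classifier"` (default) or `"assume_in_focus"`.
#' @return An object of class `"yield_report"`: `n_videos`,
#'   `n_flagged_before`, `n_flagged_after`, per-video fractions, and
#'   `recovered_fraction` (`NA` when nothing was flagged).
#' @export
yield_report <- function(videos, classifier, restorer, threshold = 0.05,
                         K = 5L, seed = 1L,
                         reassess = c("classifier", "assume_in_focus")) {
  reassess <- match.arg(reassess)
  stopifnot(length(videos) >= 1)
  n <- length(videos)
  before <- after <- numeric(n)
  flagged_before <- flagged_after <- logical(n)
  for (v in seq_len(n)) {
    frames <- videos[[v]]$frames
    a <- assess_video(frames, classifier, threshold)
    before[v] <- a$oof_fraction
    flagged_before[v] <- a$flagged
    if (!a$flagged) {
      after[v] <- a$oof_fraction
      flagged_after[v] <- a$flagged
      next
    }
    rest <- if (identical(restorer, "oracle")) {
      oracle_restorer(videos[[v]]$truth)
    } else {
      restorer
    }
    restored <- restore_video(frames, a, rest, K = K,
                              seed = sub_seed(seed, v))
    if (reassess == "classifier") {
      a2 <- assess_video(restored, classifier, threshold)
    } else {
      keep <- setdiff(seq_along(frames), a$oof_frame_indices)
      n_oof <- if (length(keep)) {
        length(assess_video(frames[keep], classifier, threshold)$oof_frame_indices)
      } else 0L
      frac <- n_oof / length(frames)
      a2 <- list(oof_fraction = frac, flagged = frac > threshold)
    }
    after[v] <- a2$oof_fraction
    flagged_after[v] <- a2$flagged
  }
  nb <- sum(flagged_before); na <- sum(flagged_after)
  structure(list(n_videos = n, n_flagged_before = nb, n_flagged_after = na,
                 fraction_before = before, fraction_after = after,
                 flagged_before = flagged_before,
                 flagged_after = flagged_after,
                 recovered_fraction = if (nb > 0) (nb - na) / nb else NA_real_),
            class = "yield_report")
}

#' @export
print.yield_report <- function(x, ...) {
  cat("Usable-video yield report\n")
  cat(sprintf("  videos:         %d\n", x$n_videos))
  cat(sprintf("  flagged before: %d (%.1f%%)\n", x$n_flagged_before,
              100 * x$n_flagged_before / x$n_videos))
  cat(sprintf("  flagged after:  %d (%.1f%%)\n", x$n_flagged_after,
              100 * x$n_flagged_after / x$n_videos))
  if (!is.na(x$recovered_fraction)) {
    cat(sprintf("  recovered:      %.0f%% of flagged videos\n",
                100 * x$recovered_fraction))
  }
  invisible(x)
}
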