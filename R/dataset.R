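# Paired in-focus/OOF dataset construction, on-disk layout and validation.
#
# Mirrors how the training corpus for the restoration model is assembled:
# for every nanowell an in-focus frame plus one frame re-imaged at an OOF
# plane (offset drawn from the configured set, random sign), with a fraction
# of identity pairs (OOF slot holds an exact copy of the in-focus frame, 25%
# by default) so the restorer also learns to leave sharp input alone.

manifest_cols <- c("pair_id", "in_focus_path", "oof_path", "delta_z_um",
                   "is_identity", "focus_label", "split", "seed")

#' Generate a paired in-focus/OOF dataset
#'
#' @param spec A [scene_spec()].
#' @param model A [defocus_model()].
#' @param n_pairs Number of pairs (> 0).
#' @param identity_fraction Fraction of identity pairs in `[0, 1)`;
#'   default 0.25.
#' @param offsets_um Positive offsets (microns) from which `|dz|` of
#'   non-identity pairs is drawn; the sign is random.  Default 10.
#' @param seed Integer seed.
#' @param split_fractions Named numeric summing to 1; pairs are assigned to
#'   splits at random in these proportions (default 4:1 train/val).
#' @return An object of class `"focus_dataset"`: a list with `pairs` (each
#'   holding `in_focus`, `oof`, `delta_z_um`, `is_identity`, `masks`) and
#'   `manifest` (data frame, one row per pair).
#' @export
make_pair_dataset <- function(spec, model, n_pairs, identity_fraction = 0.25,
                              offsets_um = 10, seed = 1L,
                              split_fractions = c(train = 0.8, val = 0.2)) {
  if (n_pairs <= 0) stop("n_pairs must be > 0", call. = FALSE)
  if (identity_fraction < 0 || identity_fraction >= 1) {
    stop("identity_fraction must lie in [0, 1)", call. = FALSE)
  }
  if (length(offsets_um) == 0 || any(offsets_um <= 0)) {
    stop("offsets_um must be a non-empty set of positive offsets", call. = FALSE)
  }
  n_id <- round(n_pairs * identity_fraction)
  with_seed(seed, {
    id_idx <- sample.int(n_pairs, n_id)
    non_id <- setdiff(seq_len(n_pairs), id_idx)
    dz <- numeric(n_pairs)
    if (length(non_id)) {
      dz[non_id] <- sample(c(-1, 1), length(non_id), replace = TRUE) *
        sample(rep(offsets_um, 2), length(non_id), replace = TRUE)
    }
    splits <- sample(rep(names(split_fractions),
                         times = round(split_fractions * n_pairs) +
                           c(n_pairs - sum(round(split_fractions * n_pairs)),
                             rep(0, length(split_fractions) - 1))))
  })
  pairs <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    s_scene <- sub_seed(seed, i)
    sc <- render_scene(spec, s_scene)
    is_id <- i %in% id_idx
    oof <- if (is_id) {
      sc$image
    } else {
      apply_defocus(sc$image, dz[i], model, seed = sub_seed(seed, n_pairs + i),
                    noise_sigma = spec$noise_sigma)
    }
    pairs[[i]] <- structure(list(
      in_focus = sc$image, oof = oof, delta_z_um = dz[i],
      is_identity = is_id, masks = sc$masks
    ), class = "frame_pair")
  }
  manifest <- data.frame(
    pair_id = sprintf("pair_%05d", seq_len(n_pairs)),
    in_focus_path = NA_character_, oof_path = NA_character_,
    delta_z_um = dz,
    is_identity = seq_len(n_pairs) %in% id_idx,
    focus_label = ifelse(abs(dz) > 0, "oof", "in_focus"),
    split = splits, seed = seed,
    stringsAsFactors = FALSE
  )
  structure(list(pairs = pairs, manifest = manifest, spec = spec,
                 model = model), class = "focus_dataset")
}

#' Validate a dataset manifest
#'
#' Checks label/offset consistency (`focus_label == "oof"` iff `|dz| > 0`
#' and not an identity pair) and, when paths are present, file existence.
#' Errors name the first offending record.
#'
#' @param manifest A manifest data frame.
#' @param dir Optional directory against which relative paths are resolved.
#' @return The manifest, invisibly.
#' @export
validate_manifest <- function(manifest, dir = NULL) {
  stopifnot(all(manifest_cols %in% names(manifest)))
  want <- abs(manifest$delta_z_um) > 0 & !manifest$is_identity
  bad <- which((manifest$focus_label == "oof") != want)
  if (length(bad)) {
    stop("manifest record ", manifest$pair_id[bad[1]],
         ": focus_label inconsistent with delta_z_um/is_identity",
         call. = FALSE)
  }
  bad_id <- which(manifest$is_identity & manifest$delta_z_um != 0)
  if (length(bad_id)) {
    stop("manifest record ", manifest$pair_id[bad_id[1]],
         ": identity pair with non-zero delta_z_um", call. = FALSE)
  }
  if (!is.null(dir) && nrow(manifest)) {
    paths <- c(file.path(dir, manifest$in_focus_path),
               file.path(dir, manifest$oof_path))
    miss <- paths[!file.exists(paths)]
    if (length(miss)) stop("missing image file: ", miss[1], call. = FALSE)
  }
  invisible(manifest)
}

#' Write a dataset to disk
#'
#' Images go to 16-bit TIFF, the manifest to `manifest.csv` with paths
#' relative to `out_dir`.
#'
#' @param dataset A `"focus_dataset"` from [make_pair_dataset()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest with populated paths, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "focus_dataset"))
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  man <- dataset$manifest
  for (i in seq_along(dataset$pairs)) {
    p <- dataset$pairs[[i]]
    man$in_focus_path[i] <- file.path("images", paste0(man$pair_id[i], "_if.tif"))
    man$oof_path[i] <- file.path("images", paste0(man$pair_id[i], "_oof.tif"))
    write_tiff(p$in_focus, file.path(out_dir, man$in_focus_path[i]))
    write_tiff(p$oof, file.path(out_dir, man$oof_path[i]))
  }
  write.csv(man, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read a dataset from disk
#'
#' Validates the manifest (see [validate_manifest()]) before loading pixel
#' data; identity pairs are additionally checked for exact equality of the
#' two images.
#'
#' @param dir Directory written by [write_dataset()].
#' @return A `"focus_dataset"` (without ground-truth masks, which are not
#'   serialized).
#' @export
read_dataset <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  validate_manifest(man, dir = dir)
  pairs <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    in_f <- read_image(file.path(dir, man$in_focus_path[i]))
    oof <- read_image(file.path(dir, man$oof_path[i]))
    if (man$is_identity[i] && !identical(dim(in_f), dim(oof))) {
      stop("manifest record ", man$pair_id[i], ": image shape mismatch",
           call. = FALSE)
    }
    pairs[[i]] <- structure(list(in_focus = in_f, oof = oof,
                                 delta_z_um = man$delta_z_um[i],
                                 is_identity = man$is_identity[i],
                                 masks = NULL), class = "frame_pair")
  }
  structure(list(pairs = pairs, manifest = man, spec = NULL, model = NULL),
            class = "focus_dataset")
}

#' Generate a labeled single-frame set for classifier training
#'
#' Draws `n` independent scenes; a fraction is re-imaged out of focus
#' (offset from `offsets_um`, random sign), the rest stay in focus.  The
#' default OOF share follows the 21:20 OOF:in-focus composition of the
#' classifier corpus.
#'
#' @param spec A [scene_spec()].
#' @param model A [defocus_model()].
#' @param n Number of frames.
#' @param oof_fraction Fraction of OOF frames (default 21/41).
#' @param offsets_um Positive offsets for OOF frames (default 10).
#' @param seed Integer seed.
#' @return A list with `images` (list of matrices), `labels` (character,
#'   `"in_focus"`/`"oof"`) and `delta_z_um`.
#' @export
make_frame_set <- function(spec, model, n, oof_fraction = 21 / 41,
                           offsets_um = 10, seed = 1L) {
  stopifnot(n >= 1, oof_fraction >= 0, oof_fraction <= 1)
  n_oof <- round(n * oof_fraction)
  with_seed(seed, {
    oof_idx <- sample.int(n, n_oof)
    dz <- numeric(n)
    dz[oof_idx] <- sample(c(-1, 1), n_oof, replace = TRUE) *
      sample(rep(offsets_um, 2), n_oof, replace = TRUE)
  })
  images <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- render_scene(spec, sub_seed(seed, i))
    images[[i]] <- if (dz[i] == 0) sc$image else {
      apply_defocus(sc$image, dz[i], model, seed = sub_seed(seed, n + i),
                    noise_sigma = spec$noise_sigma)
    }
  }
  list(images = images,
       labels = ifelse(dz != 0, "oof", "in_focus"),
       delta_z_um = dz)
}
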