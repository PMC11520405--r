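# In-focus / out-of-focus frame classifier.
#
# One small configurable CNN (conv 3x3 + ReLU + 2x2 average-pool blocks,
# global average pooling, linear head) trained with Adam on cross-entropy,
# standing in for the published off-the-shelf architecture comparison (whose
# accuracy spread was <= 1%, so architecture is not the scientific content
# here).  Images are z-scored with per-dataset statistics rather than
# ImageNet moments, which do not exist for synthetic grayscale data.

#' Classifier configuration
#'
#' Defaults follow the training protocol of the published workflow:
#' learning rate 1e-4, L2 weight decay 1e-5, batch size 50, 100 training
#' iterations.  "Iterations" is interpreted as full passes over the data
#' (epochs); the protocol wording is ambiguous between epochs and optimizer
#' steps, and this choice is documented rather than inferred.
#'
#' @param input_size_px Model input side; frames are bilinearly resized.
#' @param conv_widths Channel counts of the conv blocks.
#' @param learning_rate,weight_decay,batch_size,n_iterations Optimizer
#'   settings.
#' @param rotation_degrees_max,contrast_jitter,brightness_jitter
#'   Augmentation bounds: rotation angle uniform in +/- max degrees,
#'   multiplicative contrast in `1 +/- contrast_jitter`, additive brightness
#'   in `+/- brightness_jitter`.
#' @param threshold Decision threshold on the OOF score (default 0.5).
#' @return An object of class `"classifier_config"`.
#' @export
classifier_config <- function(input_size_px = 64L, conv_widths = c(8L, 16L, 32L),
                              learning_rate = 1e-4, weight_decay = 1e-5,
                              batch_size = 50L, n_iterations = 100L,
                              rotation_degrees_max = 15,
                              contrast_jitter = 0.1, brightness_jitter = 0.1,
                              threshold = 0.5) {
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  if (n_iterations < 0) stop("n_iterations must be >= 0", call. = FALSE)
  structure(list(input_size_px = as.integer(input_size_px),
                 conv_widths = as.integer(conv_widths),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 n_iterations = as.integer(n_iterations),
                 rotation_degrees_max = rotation_degrees_max,
                 contrast_jitter = contrast_jitter,
                 brightness_jitter = brightness_jitter,
                 threshold = threshold),
            class = "classifier_config")
}

# Bilinear resize to size x size (no-op if already there).
resize_bilinear <- function(image, size) {
  H <- nrow(image); W <- ncol(image)
  if (H == size && W == size) return(image)
  yi <- (seq_len(size) - 0.5) * H / size + 0.5
  xi <- (seq_len(size) - 0.5) * W / size + 0.5
  y0 <- pmin(pmax(floor(yi), 1), H); y1 <- pmin(y0 + 1, H)
  x0 <- pmin(pmax(floor(xi), 1), W); x1 <- pmin(x0 + 1, W)
  fy <- pmin(pmax(yi - y0, 0), 1); fx <- pmin(pmax(xi - x0, 0), 1)
  a <- image[y0, x0] * outer(1 - fy, 1 - fx) +
    image[y1, x0] * outer(fy, 1 - fx) +
    image[y0, x1] * outer(1 - fy, fx) +
    image[y1, x1] * outer(fy, fx)
  a
}

# Bilinear rotation about the image center; out-of-support pixels take the
# image mean.
rotate_bilinear <- function(image, degrees) {
  if (degrees %% 360 == 0) return(image)
  H <- nrow(image); W <- ncol(image)
  th <- degrees * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  Y <- matrix(rep(seq_len(H), times = W), H)
  X <- matrix(rep(seq_len(W), each = H), H)
  ys <- cy + (Y - cy) * cos(th) - (X - cx) * sin(th)
  xs <- cx + (Y - cy) * sin(th) + (X - cx) * cos(th)
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  fill <- mean(image)
  gv <- function(yy, xx) {
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    v <- matrix(fill, H, W)
    v[ok] <- image[cbind(yy[ok], xx[ok])]
    v
  }
  gv(y0, x0) * (1 - fy) * (1 - fx) + gv(y0 + 1, x0) * fy * (1 - fx) +
    gv(y0, x0 + 1) * (1 - fy) * fx + gv(y0 + 1, x0 + 1) * fy * fx
}

#' Random training augmentation
#'
#' Rotation (uniform in the configured range), multiplicative contrast
#' jitter about the image mean and additive brightness jitter, clipped to
#' `[0, 1]`.  All jitters zero gives the identity.  Augmentation never
#' changes the focus label.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param config A [classifier_config()].
#' @param seed Optional seed.
#' @return Augmented image.
#' @export
augment_image <- function(image, config, seed = NULL) {
  check_image01(image)
  with_seed(seed, {
    out <- image
    if (config$rotation_degrees_max > 0) {
      ang <- runif(1, -config$rotation_degrees_max, config$rotation_degrees_max)
      out <- rotate_bilinear(out, ang)
    }
    if (config$contrast_jitter > 0) {
      g <- runif(1, 1 - config$contrast_jitter, 1 + config$contrast_jitter)
      m <- mean(out)
      out <- m + (out - m) * g
    }
    if (config$brightness_jitter > 0) {
      out <- out + runif(1, -config$brightness_jitter, config$brightness_jitter)
    }
    clip01(out)
  })
}

# He-initialized conv stack + head for the classifier; runs on the ambient
# RNG stream.
init_classifier_net <- function(config) {
  widths <- config$conv_widths
  c_in <- 1L
  layers <- list()
  for (w in widths) {
    fan_in <- c_in * 9
    layers[[length(layers) + 1]] <- list(
      W = matrix(rnorm(w * fan_in, sd = sqrt(2 / fan_in)), w, fan_in),
      b = numeric(w), dilation = 1L, act = "relu", pool = TRUE
    )
    c_in <- w
  }
  head <- list(w = rnorm(c_in, sd = sqrt(1 / c_in)), b = 0)
  list(params = layers, head = head)
}

prep_frames <- function(images, config, norm) {
  n <- length(images)
  X <- array(0, dim = c(config$input_size_px, config$input_size_px, n))
  for (i in seq_len(n)) {
    X[, , i] <- (resize_bilinear(images[[i]], config$input_size_px) -
                   norm$mean) / norm$sd
  }
  X
}

#' Train the focus classifier
#'
#' @param images List of grayscale frames in `[0, 1]`.
#' @param labels Character/factor vector with levels `"in_focus"`, `"oof"`;
#'   both classes must be present.
#' @param config A [classifier_config()].
#' @param seed Integer seed (weight init, shuffling, augmentation).
#' @param augment Apply random augmentation each epoch (default TRUE).
#' @return An object of class `"focus_classifier"` holding the weights,
#'   config, per-dataset normalization and the per-step training loss
#'   history.
#' @export
train_classifier <- function(images, labels, config = classifier_config(),
                             seed = 1L, augment = TRUE) {
  labels <- as.character(labels)
  stopifnot(length(images) == length(labels))
  if (length(unique(labels)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  y <- as.numeric(labels == "oof")
  norm <- dataset_norm(images)
  net <- with_seed(seed, init_classifier_net(config))
  adam <- list()
  losses <- numeric(0)
  if (config$n_iterations > 0) {
    for (ep in seq_len(config$n_iterations)) {
      ep_seed <- sub_seed(seed, 1000 + ep)
      imgs <- if (augment) {
        with_seed(ep_seed, lapply(images, function(im) augment_image(im, config)))
      } else {
        images
      }
      X <- prep_frames(imgs, config, norm)
      res <- cls_train_cpp(net$params, net$head, adam, X, y,
                           config$learning_rate, config$weight_decay,
                           config$batch_size, 1L, sub_seed(seed, 2000 + ep))
      net$params <- res$params
      net$head <- res$head
      adam <- res$adam
      losses <- c(losses, res$losses)
    }
  }
  structure(list(params = net$params, head = net$head, config = config,
                 norm = norm, history = losses),
            class = "focus_classifier")
}

dataset_norm <- function(images) {
  v <- unlist(lapply(images, as.vector))
  s <- sd(v)
  list(mean = mean(v), sd = if (is.na(s) || s == 0) 1 else s)
}

#' Predict the focus state of frames
#'
#' @param model A `"focus_classifier"`.
#' @param images A single frame or a list of frames.
#' @return A data frame with `score` (probability of OOF) and `label`
#'   (`"oof"` when `score >= threshold`).
#' @export
predict_frame <- function(model, images) {
  stopifnot(inherits(model, "focus_classifier"))
  if (is.matrix(images)) images <- list(images)
  X <- prep_frames(images, model$config, model$norm)
  score <- as.numeric(cls_predict_cpp(model$params, model$head, X))
  data.frame(score = score,
             label = ifelse(score >= model$config$threshold, "oof", "in_focus"),
             stringsAsFactors = FALSE)
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Takes `round(cv_fraction * n)` items (label-stratified, default 75% as in
#' the published protocol), partitions them into `k` label-stratified folds
#' and trains/validates `k` models.
#'
#' @param images,labels As in [train_classifier()].
#' @param config A [classifier_config()].
#' @param k Number of folds (>= 2, default 5).
#' @param cv_fraction Fraction of items entering the CV pool (default 0.75).
#' @param seed Integer seed.
#' @return An object of class `"cv_report"`: per-fold accuracies, their mean
#'   and sd, and fold assignments.
#' @export
cross_validate <- function(images, labels, config = classifier_config(),
                           k = 5L, cv_fraction = 0.75, seed = 1L) {
  labels <- as.character(labels)
  stopifnot(length(images) == length(labels))
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (length(unique(labels)) < 2) {
    stop("cross-validation needs both classes", call. = FALSE)
  }
  n_pool <- round(cv_fraction * length(images))
  if (n_pool < k) stop("fewer items than folds", call. = FALSE)
  # label-stratified pool selection and fold assignment
  assign_folds <- with_seed(seed, {
    pool <- unlist(lapply(split(seq_along(labels), labels), function(idx) {
      take <- round(length(idx) * cv_fraction)
      sample(idx, take)
    }))
    # adjust to exactly n_pool items (rounding per class can drift by 1)
    if (length(pool) > n_pool) pool <- sample(pool, n_pool)
    if (length(pool) < n_pool) {
      pool <- c(pool, sample(setdiff(seq_along(labels), pool),
                             n_pool - length(pool)))
    }
    folds <- integer(length(labels))
    # assign folds cyclically with a running offset across classes so fold
    # sizes stay within 1 globally while remaining label-stratified
    offset <- 0L
    for (lv in unique(labels)) {
      idx <- sample(pool[labels[pool] == lv])
      folds[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- offset + length(idx)
    }
    folds
  })
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- which(assign_folds > 0 & assign_folds != f)
    va <- which(assign_folds == f)
    m <- train_classifier(images[tr], labels[tr], config,
                          seed = sub_seed(seed, 3000 + f))
    pred <- predict_frame(m, images[va])
    acc[f] <- mean(pred$label == labels[va])
  }
  structure(list(fold_accuracy = acc, mean_accuracy = mean(acc),
                 sd_accuracy = sd(acc), folds = assign_folds, k = k,
                 n_pool = sum(assign_folds > 0)),
            class = "cv_report")
}
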