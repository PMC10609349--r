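# Per-frame particle segmentation: a classical smoothing/threshold/morphology
# chain and a lightweight trainable multiscale pixel classifier, both
# evaluated by intersection over union against ground-truth masks.

#' Classical segmentation parameters
#'
#' @param smooth_sigma Gaussian pre-smoothing sigma in pixels (0 disables).
#' @param threshold_method `"otsu"` (data-driven, contrast-shift invariant)
#'   or `"fixed"`.
#' @param fixed_threshold Grayscale cut used when `threshold_method="fixed"`.
#' @param open_radius,close_radius Disc radii (px) of the morphological
#'   opening and closing that remove speckle and seal boundary gaps.
#' @param min_component_px Connected components smaller than this many pixels
#'   are discarded.
#' @return Object of class `segmentation_params`.
#' @export
segmentation_params <- function(smooth_sigma = 1,
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = 0.5,
                                open_radius = 2L, close_radius = 2L,
                                min_component_px = 30L) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(smooth_sigma >= 0, open_radius >= 0, close_radius >= 0,
            min_component_px >= 1)
  structure(list(smooth_sigma = smooth_sigma,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 open_radius = as.integer(open_radius),
                 close_radius = as.integer(close_radius),
                 min_component_px = as.integer(min_component_px)),
            class = "segmentation_params")
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2L * radius + 1L, shape = "disc")
}

drop_small_components <- function(bw, min_px) {
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  lab <- as.matrix(EBImage::imageData(lab))
  if (max(lab) == 0) return(matrix(FALSE, nrow(bw), ncol(bw)))
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(bw), ncol(bw))
}

#' Segment one SEM frame with the classical chain
#'
#' Gaussian smooth, threshold (Otsu on the smoothed image's own range, so the
#' result is invariant to adding a constant to the frame), morphological open
#' then close with disc structuring elements, and removal of connected
#' components below `min_component_px`. All surviving components are
#' returned; choosing among them is the tracker's job. An empty mask is a
#' valid result (e.g. a blank frame).
#'
#' @param frame Numeric matrix, nominally in `[0, 1]`.
#' @param params A [segmentation_params()] object.
#' @return Logical mask matrix of the frame's dimensions.
#' @export
segment_frame_classical <- function(frame, params = segmentation_params()) {
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("frame must be a 2-D numeric matrix")
  if (any(!is.finite(frame))) stop("frame contains non-finite values")
  sm <- frame
  if (params$smooth_sigma > 0)
    sm <- as.matrix(EBImage::gblur(EBImage::Image(frame),
                                   params$smooth_sigma))
  if (params$threshold_method == "otsu") {
    rng <- range(sm)
    if (diff(rng) < 1e-9)
      return(matrix(FALSE, nrow(frame), ncol(frame)))
    th <- EBImage::otsu(EBImage::Image(sm), range = rng)
  } else {
    th <- params$fixed_threshold
  }
  bw <- sm > th
  if (params$open_radius > 0)
    bw <- as.matrix(EBImage::opening(EBImage::Image(bw * 1),
                                     disc_brush(params$open_radius))) > 0.5
  if (params$close_radius > 0)
    bw <- as.matrix(EBImage::closing(EBImage::Image(bw * 1),
                                     disc_brush(params$close_radius))) > 0.5
  drop_small_components(bw, params$min_component_px)
}

#' Segment every frame of a video
#'
#' @param video A `synthetic_video` or a list of frame matrices.
#' @param params A [segmentation_params()] for `method = "classical"`.
#' @param method `"classical"` or `"model"`.
#' @param model A trained [train_segmenter()] model when `method = "model"`.
#' @return List of logical masks, one per frame.
#' @export
segment_video <- function(video, params = segmentation_params(),
                          method = c("classical", "model"), model = NULL) {
  method <- match.arg(method)
  frames <- if (inherits(video, "synthetic_video")) video$frames else video
  if (method == "classical")
    lapply(frames, segment_frame_classical, params = params)
  else {
    if (is.null(model)) stop("method='model' requires a trained model")
    lapply(frames, segment_frame_model, model = model)
  }
}

#' Intersection over union of two masks
#'
#' `|A & B| / |A | B|`; by convention 1 when both masks are empty (the masks
#' agree there is no particle).
#'
#' @param a,b Logical mask matrices of identical dimensions.
#' @return Fraction in `[0, 1]`.
#' @export
iou <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask dimensions differ")
  a <- a > 0; b <- b > 0
  uni <- sum(a | b)
  if (uni == 0) return(1)
  sum(a & b) / uni
}

#' Configuration of the trainable segmenter
#'
#' The trainable model is a multiscale pixel classifier: per-pixel logistic
#' regression on the raw intensity plus Gaussian-smoothed intensity and local
#' standard deviation at several scales — a compact, CPU-trainable stand-in
#' for an encoder-decoder network that sees the image at multiple scales.
#'
#' @param feature_sigmas Gaussian scales (px) of the feature bank.
#' @param samples_per_frame Pixels sampled per training frame (balanced
#'   between foreground and background where possible).
#' @param epochs Maximum iteratively-reweighted-least-squares iterations; 0
#'   returns an untrained (all-zero) model, flagged.
#' @param prob_cut Foreground probability cut for inference (default 0.5).
#' @param min_component_px Post-inference small-component filter, mirroring
#'   the classical chain.
#' @param seed Seed for pixel sampling.
#' @return Object of class `seg_model_config`.
#' @export
seg_model_config <- function(feature_sigmas = c(1, 2, 4, 8),
                             samples_per_frame = 1500L, epochs = 30L,
                             prob_cut = 0.5, min_component_px = 30L,
                             seed = 1L) {
  stopifnot(all(feature_sigmas > 0), samples_per_frame >= 10L, epochs >= 0L,
            prob_cut > 0, prob_cut < 1)
  structure(list(feature_sigmas = feature_sigmas,
                 samples_per_frame = as.integer(samples_per_frame),
                 epochs = as.integer(epochs), prob_cut = prob_cut,
                 min_component_px = as.integer(min_component_px),
                 seed = as.integer(seed)),
            class = "seg_model_config")
}

pixel_features <- function(frame, sigmas) {
  n <- length(frame)
  feats <- matrix(0, n, 1L + 2L * length(sigmas))
  feats[, 1L] <- as.vector(frame)
  img <- EBImage::Image(frame)
  for (i in seq_along(sigmas)) {
    bl <- as.matrix(EBImage::gblur(img, sigmas[i]))
    bl2 <- as.matrix(EBImage::gblur(EBImage::Image(frame^2), sigmas[i]))
    feats[, 2L * i] <- as.vector(bl)
    feats[, 2L * i + 1L] <- as.vector(sqrt(pmax(bl2 - bl^2, 0)))
  }
  feats
}

#' Train the multiscale pixel-classifier segmenter
#'
#' Samples labelled pixels from (frame, truth mask) pairs and fits a
#' regularized logistic regression on the multiscale feature bank. Training
#' is seeded and takes seconds on one CPU.
#'
#' @param pairs List of `list(frame =, mask =)` training pairs (at least 8).
#' @param config A [seg_model_config()].
#' @return Object of class `seg_model` with elements `coef`, `config`,
#'   `dim` (training frame geometry) and `trained`.
#' @export
train_segmenter <- function(pairs, config = seg_model_config()) {
  if (length(pairs) == 0L) stop("empty training set")
  if (length(pairs) < 8L) stop("need at least 8 training pairs")
  dims <- unique(lapply(pairs, function(p) dim(p$frame)))
  if (length(dims) != 1L) stop("training frames must share one geometry")
  nfeat <- 1L + 2L * length(config$feature_sigmas)
  if (config$epochs == 0L) {
    warning("epochs = 0: returning an untrained model")
    return(structure(list(coef = rep(0, nfeat + 1L), config = config,
                          dim = dims[[1L]], trained = FALSE),
                     class = "seg_model"))
  }
  with_seed(config$seed, {
    xs <- list(); ys <- list()
    for (p in pairs) {
      stopifnot(identical(dim(p$frame), dim(p$mask)))
      feats <- pixel_features(p$frame, config$feature_sigmas)
      lab <- as.vector(p$mask > 0)
      fg <- which(lab); bg <- which(!lab)
      n_fg <- min(length(fg), config$samples_per_frame %/% 2L)
      n_bg <- min(length(bg), config$samples_per_frame - n_fg)
      sel <- c(if (n_fg > 0) sample(fg, n_fg), sample(bg, n_bg))
      xs[[length(xs) + 1L]] <- feats[sel, , drop = FALSE]
      ys[[length(ys) + 1L]] <- lab[sel]
    }
    X <- cbind(1, do.call(rbind, xs))
    y <- as.numeric(unlist(ys))
    fit <- suppressWarnings(stats::glm.fit(
      X, y, family = stats::binomial(),
      control = list(maxit = config$epochs)))
    beta <- fit$coefficients
    beta[!is.finite(beta)] <- 0
    if (any(!is.finite(fit$fitted.values)))
      stop("non-finite values in segmenter training; aborting")
    structure(list(coef = beta, config = config, dim = dims[[1L]],
                   trained = TRUE),
              class = "seg_model")
  })
}

#' Segment a frame with a trained model
#'
#' Computes the feature bank, applies the logistic classifier, thresholds the
#' foreground probability at `prob_cut`, and drops components below
#' `min_component_px` (mirroring the classical chain so comparisons stay
#' symmetric). Inference is deterministic.
#'
#' @param frame Numeric matrix with the model's training geometry.
#' @param model A [train_segmenter()] model.
#' @return Logical mask matrix.
#' @export
segment_frame_model <- function(frame, model) {
  stopifnot(inherits(model, "seg_model"))
  if (!identical(dim(frame), model$dim))
    stop("frame geometry differs from the model's training geometry")
  feats <- cbind(1, pixel_features(frame, model$config$feature_sigmas))
  prob <- stats::plogis(drop(feats %*% model$coef))
  bw <- matrix(prob > model$config$prob_cut, nrow(frame), ncol(frame))
  if (!any(bw)) return(bw)
  drop_small_components(bw, model$config$min_component_px)
}

#' Mean IoU of predicted masks against truth
#'
#' @param pred,truth Lists of masks of equal length.
#' @return Mean per-frame IoU.
#' @export
mean_iou <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  mean(mapply(iou, pred, truth))
}
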