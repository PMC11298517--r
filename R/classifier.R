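# Trainable pixel classification: random forest on the multiscale 2D
# feature bank, trained from sparse slice annotations, applied
# slice-wise to whole volumes, with background-subtraction
# postprocessing of the probability maps.

.pick_channel <- function(volume, channel) {
  if (inherits(volume, "multichannel_volume")) {
    if (!channel %in% names(volume$channels))
      stop("channel ", channel, " not present in volume (has: ",
           paste(names(volume$channels), collapse = ", "), ")", call. = FALSE)
    volume$channels[[channel]]
  } else {
    as_stack3d(volume)
  }
}

# feature matrix of one slice: rows = pixels (column-major), cols = features
.slice_feature_matrix <- function(sl, config) {
  fb <- compute_feature_bank(sl, config)
  matrix(fb, ncol = dim(fb)[3],
         dimnames = list(NULL, dimnames(fb)[[3]]))
}

#' Train a pixel classifier from sparse annotations
#'
#' Computes the multiscale feature bank on every annotated slice, turns
#' labeled pixels into training rows and fits a probability random
#' forest. The canonical design is five annotated slices from each of
#' two samples, four classes (background, lumen, low_AF, high_AF), on
#' the 785 nm channel at 20 um.
#'
#' @param volumes list of `multichannel_volume` (or bare 3D arrays);
#'   one entry per training sample.
#' @param annotations list of `region_label_volume` matching `volumes`;
#'   code 0 = unlabeled, annotations are sparse on a few slices.
#' @param channel excitation channel used for features (default
#'   `"785"`).
#' @param config a [feature_bank_config()].
#' @param n_trees number of trees (default 200).
#' @param seed integer seed recorded in the model; the whole chain is
#'   deterministic under it.
#' @return an object of class `pixel_classifier` with the fitted model,
#'   class names, feature config and training provenance.
#' @export
train_classifier <- function(volumes, annotations, channel = "785",
                             config = feature_bank_config(),
                             n_trees = 200L, seed = 1L) {
  if (inherits(volumes, "multichannel_volume") || is.array(volumes))
    volumes <- list(volumes)
  if (inherits(annotations, "region_label_volume"))
    annotations <- list(annotations)
  stopifnot(length(volumes) == length(annotations))
  class_names <- annotations[[1]]$class_names
  X_list <- list(); y_list <- list(); n_slices <- 0L
  for (i in seq_along(volumes)) {
    vol <- .pick_channel(volumes[[i]], channel)
    lab <- annotations[[i]]$labels
    if (!identical(dim(vol), dim(lab)))
      stop("annotation shape does not match volume ", i, call. = FALSE)
    zs <- which(apply(lab > 0, 1, any))
    for (z in zs) {
      n_slices <- n_slices + 1L
      lz <- lab[z, , ]
      sel <- which(lz > 0)
      Xz <- .slice_feature_matrix(vol[z, , ], config)
      X_list[[length(X_list) + 1L]] <- Xz[sel, , drop = FALSE]
      y_list[[length(y_list) + 1L]] <- lz[sel]
    }
  }
  if (n_slices == 0L) stop("no annotated slices found", call. = FALSE)
  X <- do.call(rbind, X_list)
  y_code <- unlist(y_list)
  y <- factor(class_names[as.character(y_code)],
              levels = unname(class_names))
  counts <- table(factor(y, levels = unname(class_names)))
  if (any(counts == 0))
    stop("class(es) with zero labeled pixels: ",
         paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  if (sum(counts > 0) < 2L)
    stop("need at least two annotated classes", call. = FALSE)
  fit <- ranger::ranger(x = X, y = y,
                        num.trees = as.integer(n_trees),
                        mtry = floor(sqrt(ncol(X))),
                        probability = TRUE,
                        seed = as.integer(seed),
                        num.threads = 1L)
  pred <- predict(fit, data = X, num.threads = 1L)$predictions
  train_acc <- mean(colnames(pred)[max.col(pred, ties.method = "first")] == y)
  structure(list(model = fit,
                 class_names = class_names,
                 channel = channel,
                 config = config,
                 n_trees = as.integer(n_trees),
                 seed = as.integer(seed),
                 training_accuracy = train_acc,
                 provenance = list(
                   n_annotated_slices = n_slices,
                   n_source_volumes = length(volumes),
                   n_labeled_pixels = as.list(counts))),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("<pixel_classifier> %d trees | channel %s nm | %d features | classes: %s\n",
              x$n_trees, x$channel, length(x$config$feature_names),
              paste(unname(x$class_names), collapse = ", ")))
  cat(sprintf("  trained on %d slices from %d volume(s); training accuracy %.4f\n",
              x$provenance$n_annotated_slices, x$provenance$n_source_volumes,
              x$training_accuracy))
  invisible(x)
}

#' Predict per-class probability maps for a volume
#'
#' Applies the classifier slice by slice (features are computed and
#' discarded per slice, keeping memory bounded) and returns the forest's
#' per-voxel class probabilities.
#'
#' @param classifier a [train_classifier()] result.
#' @param volume a `multichannel_volume` containing the training
#'   channel, or a bare 3D array.
#' @return an object of class `probability_map_set` at stage `"raw"`:
#'   per-class 3D probability arrays summing to 1 at every voxel.
#' @export
predict_probabilities <- function(classifier, volume) {
  stopifnot(inherits(classifier, "pixel_classifier"))
  vol <- .pick_channel(volume, classifier$channel)
  d <- dim(vol)
  cls <- unname(classifier$class_names)
  P <- lapply(cls, function(k) array(0, dim = d))
  names(P) <- cls
  for (z in seq_len(d[1])) {
    Xz <- .slice_feature_matrix(vol[z, , ], classifier$config)
    pr <- predict(classifier$model, data = Xz, num.threads = 1L)$predictions
    for (k in cls) P[[k]][z, , ] <- pr[, k]
  }
  structure(list(P = P, stage = "raw", class_names = classifier$class_names),
            class = "probability_map_set")
}

#' @export
print.probability_map_set <- function(x, ...) {
  d <- dim(x$P[[1]])
  cat(sprintf("<probability_map_set> stage %s | %d classes | %d x %d x %d\n",
              x$stage, length(x$P), d[1], d[2], d[3]))
  invisible(x)
}

#' Background-subtraction postprocessing of probability maps
#'
#' Subtracts the background-class probability from every other class
#' map (clipped at zero), and replaces the background map by its
#' inversion `1 - P[background]` — the organ gross-structure map. This
#' is the postprocessing that turns raw classifier output into the
#' definitive display channels.
#'
#' @param maps a `probability_map_set` at stage `"raw"`.
#' @param background_class class name of the background map.
#' @return a `probability_map_set` at stage `"background_subtracted"`,
#'   all values in \[0, 1\].
#' @export
postprocess_background_subtraction <- function(maps,
                                               background_class = "background") {
  stopifnot(inherits(maps, "probability_map_set"))
  if (maps$stage != "raw")
    stop("postprocessing applies to stage 'raw' maps", call. = FALSE)
  if (!background_class %in% names(maps$P))
    stop("missing background class '", background_class, "'", call. = FALSE)
  bg <- maps$P[[background_class]]
  out <- maps
  for (k in names(maps$P)) {
    out$P[[k]] <- if (k == background_class) 1 - bg
                  else pmax(maps$P[[k]] - bg, 0)
  }
  out$stage <- "background_subtracted"
  out
}

#' Threshold a probability map into a binary mask, or argmax-label all
#' classes
#'
#' @param maps a `probability_map_set`.
#' @param class class to threshold; if `NULL`, returns the argmax label
#'   volume over all classes (every voxel assigned to exactly one
#'   class; ties resolved to the first class in order).
#' @param threshold probability threshold in (0, 1) for the binary
#'   mode.
#' @return a `region_label_volume`: binary (code 1 = class) in
#'   threshold mode, or the full label volume in argmax mode.
#' @export
probability_to_mask <- function(maps, class = NULL, threshold = 0.5) {
  stopifnot(inherits(maps, "probability_map_set"))
  cls <- names(maps$P)
  if (is.null(class)) {
    d <- dim(maps$P[[1]])
    flat <- vapply(cls, function(k) as.vector(maps$P[[k]]),
                   numeric(prod(d)))
    lab <- array(max.col(flat, ties.method = "first"), dim = d)
    return(region_label_volume(lab, stats::setNames(cls, seq_along(cls))))
  }
  if (!class %in% cls) stop("unknown class: ", class, call. = FALSE)
  if (!(threshold > 0 && threshold < 1))
    stop("threshold must be in (0, 1)", call. = FALSE)
  mask <- maps$P[[class]] >= threshold
  region_label_volume(array(as.integer(mask), dim = dim(mask)),
                      stats::setNames(class, "1"))
}

#' Per-class DICE evaluation of a predicted segmentation
#'
#' Compares predicted and reference label volumes class by class (by
#' class name) via [dice()], reporting the macro average. A class empty
#' in both volumes scores 1 and is flagged.
#'
#' @param pred,truth `region_label_volume` objects of identical shape.
#' @return data.frame with columns `class`, `dice`, `flagged`; macro
#'   average in attribute `"macro_dice"`.
#' @export
evaluate_segmentation <- function(pred, truth) {
  stopifnot(inherits(pred, "region_label_volume"),
            inherits(truth, "region_label_volume"))
  if (!identical(dim(pred$labels), dim(truth$labels)))
    stop("shape mismatch between prediction and truth", call. = FALSE)
  classes <- unname(truth$class_names)
  if (length(intersect(unname(pred$class_names), classes)) == 0L)
    stop("class-name mismatch: no shared classes between prediction and truth",
         call. = FALSE)
  res <- lapply(classes, function(k) {
    pm <- if (k %in% pred$class_names) class_mask(pred, k)
          else array(FALSE, dim = dim(pred$labels))
    tm <- class_mask(truth, k)
    empty_both <- sum(pm) + sum(tm) == 0
    d <- if (empty_both) 1 else dice(pm, tm)
    data.frame(class = k, dice = d, flagged = empty_both)
  })
  out <- do.call(rbind, res)
  attr(out, "macro_dice") <- mean(out$dice)
  out
}
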