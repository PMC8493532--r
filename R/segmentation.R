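# Segmentation training on generated pairs and label-free checkpoint
# selection by mask simplicity.

#' Segmentation training configuration
#'
#' @param epochs training epochs (default 30).
#' @param lr Adam learning rate.
#' @param levels,base U-Net depth and base channel count (the same
#'   architecture family as the transform generator; levels must divide the
#'   image size).
#' @param classes task legend of the labels (including background).
#' @param seed RNG seed (weight init and shuffling).
#' @return a list of settings.
#' @export
seg_config <- function(epochs = 30L, lr = 1e-3, levels = 3L, base = 8L,
                       classes = task_legend(), seed = 0L) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (!"background" %in% names(classes))
    stop("classes must include background")
  as.list(environment())
}

#' Train the U-Net segmenter on image/label pairs
#'
#' Cross-entropy training of a U-Net on rendered (or transformed) pairs;
#' one checkpoint is kept per epoch so that checkpoint selection can scan
#' the whole trajectory.
#'
#' @param pairs list of `pseudo_pair` (images in `[0,1]`, labels in the
#'   configured classes).
#' @param config a [seg_config()] list.
#' @return a `seg_training`: `checkpoints` (one `seg_checkpoint` per
#'   epoch), `losses` (mean per-epoch cross-entropy), `config`.
#' @export
train_segmenter <- function(pairs, config = seg_config()) {
  if (!length(pairs)) stop("need at least one training pair")
  codes <- sort(unique(unlist(lapply(pairs, function(p) unique(as.vector(p$label))))))
  if (!all(codes %in% config$classes))
    stop("label code(s) ", paste(setdiff(codes, config$classes), collapse = ", "),
         " absent from configured classes")
  class_codes <- sort(unique(as.integer(config$classes)))
  K <- length(class_codes)
  H <- nrow(pairs[[1]]$image); W <- ncol(pairs[[1]]$image)
  set.seed(as.integer(config$seed))
  net <- unet_new(1L, K, levels = config$levels, base = config$base,
                  final = "logits")
  st <- adam_state()
  checkpoints <- vector("list", config$epochs)
  losses <- numeric(config$epochs)
  xs <- lapply(pairs, function(p) array(p$image, c(H, W, 1L)))
  ys <- lapply(pairs, function(p) matrix(match(p$label, class_codes) - 1L, H, W))
  for (e in seq_len(config$epochs)) {
    ord <- sample(length(pairs))
    el <- 0
    for (i in ord) {
      r <- unet_forward(net, xs[[i]], want_cache = TRUE)
      l <- ce_loss(r$out, ys[[i]])
      bk <- unet_backward(net, r$cache, l$dlogits)
      a <- adam_step(net, bk$grads, st, lr = config$lr)
      net <- a$net; st <- a$state
      el <- el + l$loss
    }
    losses[e] <- el / length(pairs)
    checkpoints[[e]] <- structure(list(net = net, epoch = e,
                                       class_codes = class_codes,
                                       classes = config$classes),
                                  class = "seg_checkpoint")
  }
  structure(list(checkpoints = checkpoints, losses = losses, config = config),
            class = "seg_training")
}

#' Predict a segmentation mask
#'
#' Pixel-wise argmax over class logits.
#'
#' @param checkpoint a `seg_checkpoint`.
#' @param image H x W matrix in `[0,1]`, H and W divisible by
#'   `2^levels` of the trained network.
#' @return integer class-code raster (H x W) with the task legend attached.
#' @export
predict_mask <- function(checkpoint, image) {
  H <- nrow(image); W <- ncol(image)
  lv <- checkpoint$net$levels
  if (H %% 2^lv != 0 || W %% 2^lv != 0)
    stop("image geometry ", H, "x", W, " incompatible with network (needs ",
         "divisibility by ", 2^lv, ")")
  logits <- unet_forward(checkpoint$net, array(image, c(H, W, 1L)))
  idx <- apply(logits, c(1, 2), which.max)
  out <- matrix(checkpoint$class_codes[idx], H, W)
  attr(out, "task_legend") <- checkpoint$classes
  out
}

#' Select a checkpoint by mask simplicity on unlabeled images
#'
#' Predicts every selection image with every checkpoint, computes the
#' simplicity of the predicted structure mask (empty prediction counts as
#' 0), and returns the checkpoint with the highest median simplicity. The
#' selection set needs no labels — simplicity depends only on the network
#' output — so real, unannotated images can steer the choice toward
#' checkpoints that generalize. Ties go to the later epoch.
#'
#' @param checkpoints list of `seg_checkpoint` (e.g. from
#'   [train_segmenter()]).
#' @param selection_images list of H x W image matrices (no labels).
#' @param structure structure whose mask drives selection (default
#'   `lv_endo`); with `structure = "all"`, the mean of per-structure median
#'   simplicities.
#' @param predict_fn prediction function `(checkpoint, image) -> raster`
#'   (default [predict_mask()]).
#' @return the selected checkpoint, with attributes `scores` (per
#'   checkpoint median simplicity) and `epoch`.
#' @export
select_by_simplicity <- function(checkpoints, selection_images,
                                 structure = "lv_endo",
                                 predict_fn = predict_mask) {
  if (!length(checkpoints)) stop("need at least one checkpoint")
  if (!length(selection_images)) stop("need at least one selection image")
  score_one <- function(ck) {
    per_img <- vapply(selection_images, function(im) {
      pred <- predict_fn(ck, im)
      lg <- attr(pred, "task_legend")
      structs <- if (identical(structure, "all")) {
        setdiff(names(lg), "background")
      } else structure
      sp <- vapply(structs, function(s) {
        msk <- task_structure_mask(pred, s, legend = lg)
        if (!any(msk)) 0 else simplicity(msk)
      }, numeric(1))
      mean(sp)
    }, numeric(1))
    stats::median(per_img)
  }
  scores <- vapply(checkpoints, score_one, numeric(1))
  if (all(scores == 0))
    stop("all predictions empty for structure '", structure, "' at epochs ",
         paste(vapply(checkpoints, function(c) c$epoch, numeric(1)),
               collapse = ", "))
  best <- max(which(scores == max(scores)))  # tie -> later epoch
  out <- checkpoints[[best]]
  attr(out, "scores") <- scores
  out
}

#' Dice of a trained checkpoint on labeled pairs (convenience)
#'
#' @param checkpoint a `seg_checkpoint`.
#' @param pairs list of `pseudo_pair`.
#' @param structure structure name.
#' @return per-pair Dice vector.
#' @export
evaluate_checkpoint <- function(checkpoint, pairs, structure = "lv_endo") {
  vapply(pairs, function(p) {
    pred <- predict_mask(checkpoint, p$image)
    dice(task_structure_mask(pred, structure, attr(pred, "task_legend")),
         task_structure_mask(p$label, structure, p$task_legend_map))
  }, numeric(1))
}
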