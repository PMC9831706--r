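#' Per-class binary cross-entropy loss
#'
#' `L = -sum_i [ y_i log p_i + (1 - y_i) log(1 - p_i) ]`, summed over the C
#' class outputs and averaged over the batch. Probabilities are clamped to
#' `[1e-7, 1 - 1e-7]` before the logs.
#'
#' @param probs B x C matrix of per-class probabilities in (0, 1)
#'   (sigmoid outputs).
#' @param one_hot B x C 0/1 matrix of targets.
#' @return scalar loss, non-negative.
#' @export
bce_loss <- function(probs, one_hot) {
  probs <- as.matrix(probs); one_hot <- as.matrix(one_hot)
  if (!all(dim(probs) == dim(one_hot))) {
    stop(sprintf("probs (%d x %d) and one_hot (%d x %d) shapes differ",
                 nrow(probs), ncol(probs), nrow(one_hot), ncol(one_hot)),
         call. = FALSE)
  }
  if (any(is.na(probs))) stop("NaN in probabilities", call. = FALSE)
  eps <- 1e-7
  p <- pmin(pmax(probs, eps), 1 - eps)
  mean(rowSums(-(one_hot * log(p) + (1 - one_hot) * log(1 - p))))
}

one_hot_encode <- function(labels, n_classes) {
  B <- length(labels)
  m <- matrix(0, B, n_classes)
  m[cbind(seq_len(B), labels + 1L)] <- 1
  m
}

#' Horizontal / vertical image flips
#'
#' @param image H x W x C array.
#' @return flipped array.
#' @export
flip_horizontal <- function(image) image[, rev(seq_len(dim(image)[2])), , drop = FALSE]

#' @rdname flip_horizontal
#' @export
flip_vertical <- function(image) image[rev(seq_len(dim(image)[1])), , , drop = FALSE]

# triangle-wave reflection of real coordinates into [1, n]
reflect_coord <- function(x, n) {
  if (n == 1L) return(rep(1, length(x)))
  period <- 2 * (n - 1)
  j <- (x - 1) %% period
  ifelse(j > (n - 1), period - j, j) + 1
}

#' Rotate an image about its center with reflection padding
#'
#' Bilinear resampling; source coordinates that fall outside the frame are
#' mirrored back in, so rotation never introduces out-of-gamut fill values.
#' A 0-degree rotation is pixel-identical.
#'
#' @param image H x W x C array.
#' @param angle_deg rotation angle in degrees (counter-clockwise).
#' @return rotated array of the same shape.
#' @export
rotate_reflect <- function(image, angle_deg) {
  if (angle_deg == 0) return(image)
  d <- dim(image)
  H <- d[1]; W <- d[2]
  th <- angle_deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r <- matrix(seq_len(H), H, W) - cy
  c <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  # inverse rotation of output coords into source space
  sr <- reflect_coord(cos(th) * r - sin(th) * c + cy, H)
  sc <- reflect_coord(sin(th) * r + cos(th) * c + cx, W)
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  r0 <- pmin(pmax(r0, 1), H); c0 <- pmin(pmax(c0, 1), W)
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  out <- image
  for (ch in seq_len(d[3])) {
    img <- image[, , ch]
    v00 <- img[cbind(as.vector(r0), as.vector(c0))]
    v01 <- img[cbind(as.vector(r0), as.vector(c1))]
    v10 <- img[cbind(as.vector(r1), as.vector(c0))]
    v11 <- img[cbind(as.vector(r1), as.vector(c1))]
    v <- v00 * (1 - fr) * (1 - fc) + v01 * (1 - fr) * fc +
      v10 * fr * (1 - fc) + v11 * fr * fc
    out[, , ch] <- matrix(v, H, W)
  }
  out
}

#' Training-time augmentation
#'
#' Independently applies a horizontal flip (p = 0.5), a vertical flip
#' (p = 0.5), and a rotation by a uniform angle in [-15, +15] degrees with
#' reflection padding. Deterministic given the seed.
#'
#' @param image H x W x C array in `[0, 1]`.
#' @param seed integer seed.
#' @return augmented image, same shape.
#' @export
augment_fundus <- function(image, seed) {
  with_seed(seed, {
    if (stats::runif(1) < 0.5) image <- flip_horizontal(image)
    if (stats::runif(1) < 0.5) image <- flip_vertical(image)
    rotate_reflect(image, stats::runif(1, -15, 15))
  })
}

#' Resize an image
#'
#' Bilinear resize to `size x size` (used for deterministic eval-time
#' resizing and for loading images whose resolution differs from the model
#' input size).
#'
#' @param image H x W x C array.
#' @param size target side length.
#' @return size x size x C array.
#' @export
resize_image <- function(image, size) {
  d <- dim(image)
  if (d[1] == size && d[2] == size) return(image)
  out <- EBImage::resize(image, w = size, h = size)
  array(out, c(size, size, d[3]))
}

#' Training configuration
#'
#' Defaults are the reference recipe: SGD with momentum 0.9 and weight decay
#' 5e-4, 20 epochs, batch size 32, backbone learning rate 1e-3 and
#' classifier learning rate 1e-2.
#'
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr_backbone learning rate for all feature-extraction parameters.
#' @param lr_classifier learning rate for the CSRA classifier matrix.
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay coefficient.
#' @param seed master seed for initialization, shuffling and augmentation.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping; `Inf` (default) disables early stopping.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 20L, batch_size = 32L, lr_backbone = 1e-3,
                         lr_classifier = 1e-2, momentum = 0.9,
                         weight_decay = 5e-4, seed = 0L,
                         early_stop_patience = Inf) {
  if (lr_backbone < 0 || lr_classifier < 0) {
    stop("learning rates must be non-negative", call. = FALSE)
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_backbone = lr_backbone, lr_classifier = lr_classifier,
                 momentum = momentum, weight_decay = weight_decay,
                 seed = as.integer(seed),
                 early_stop_patience = early_stop_patience),
            class = "train_config")
}

#' Desk-scale training preset
#'
#' The reference recipe with the minibatch size scaled down to the small
#' synthetic corpora the desk-scale encoder preset is trained on: batch 8
#' keeps the number of SGD updates per epoch meaningful on a few hundred
#' images (the full-scale recipe's batch of 32 against several thousand
#' images corresponds to hundreds of updates per epoch). All rates,
#' momentum and weight decay are unchanged.
#'
#' @param ... overrides passed to [train_config()].
#' @export
tiny_train_config <- function(...) {
  args <- utils::modifyList(list(batch_size = 8L), list(...))
  do.call(train_config, args)
}

# recursive SGD-with-momentum step on a params-shaped nested list
sgd_step <- function(p, g, v, lr, momentum, weight_decay) {
  if (is.list(p)) {
    keys <- if (is.null(names(p))) seq_along(p) else names(p)
    for (k in keys) {
      res <- sgd_step(p[[k]], g[[k]], v[[k]], lr, momentum, weight_decay)
      p[[k]] <- res$p; v[[k]] <- res$v
    }
    list(p = p, v = v)
  } else {
    v <- momentum * v + g + weight_decay * p
    list(p = p - lr * v, v = v)
  }
}

# forward a batch, returning loss, per-sample caches and sigmoid probs
forward_batch <- function(model, images, labels, keep_cache = FALSE) {
  B <- length(images)
  C <- model$n_classes
  probs <- matrix(0, B, C)
  logits <- matrix(0, B, C)
  caches <- if (keep_cache) vector("list", B) else NULL
  for (b in seq_len(B)) {
    fw <- model_forward(model, images[[b]], keep_cache = keep_cache)
    probs[b, ] <- fw$sigmoid
    logits[b, ] <- fw$logits
    if (keep_cache) caches[[b]] <- fw$cache
  }
  y <- one_hot_encode(labels, C)
  list(loss = bce_loss(probs, y), probs = probs, logits = logits,
       one_hot = y, caches = caches)
}

# accumulate parameter gradients over a batch (d loss / d logits through
# the per-class sigmoid BCE: (sigma(logit) - y) / B)
batch_gradients <- function(model, fw) {
  B <- nrow(fw$probs)
  dlogit_mat <- (fw$probs - fw$one_hot) / B
  total <- NULL
  for (b in seq_len(B)) {
    g <- model_backward(model, fw$caches[[b]], dlogit_mat[b, ])
    total <- if (is.null(total)) g else params_map2(total, g, `+`)
  }
  total
}

#' Train the grading model
#'
#' SGD with momentum on per-class sigmoid BCE, with two parameter groups
#' (feature-extraction block at `lr_backbone`, CSRA classifier at
#' `lr_classifier`), per-image flip/rotation augmentation at train time,
#' and a per-epoch train/validation loss log. The checkpoint with the
#' lowest validation loss is kept as `best_model`.
#'
#' @param data list with `train` and `val` elements, each a list with
#'   `images` (list of arrays) and `labels` (0-based integer vector); see
#'   [load_split()].
#' @param model_config `encoder_config`.
#' @param cfg `train_config`.
#' @param n_classes number of grades.
#' @param lambda CSRA residual weight.
#' @param n_csra_heads CSRA head count.
#' @param verbose print per-epoch losses.
#' @return list of class `train_result`: `best_model`, `final_model`,
#'   `log` (data.frame epoch/train_loss/val_loss), `best_epoch`.
#' @export
train_grader <- function(data, model_config, cfg = train_config(),
                         n_classes = 6L, lambda = 0.3, n_csra_heads = 2L,
                         verbose = FALSE) {
  if (length(data$train$images) == 0L) stop("empty training set", call. = FALSE)
  if (length(unique(data$train$labels)) < 2L) {
    stop("training labels must cover at least 2 classes", call. = FALSE)
  }
  model <- init_model(model_config, n_classes, lambda = lambda,
                      n_csra_heads = n_csra_heads, seed = cfg$seed)
  vel <- params_zero(model$params)
  n <- length(data$train$images)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric())
  best <- list(loss = Inf, model = model, epoch = 0L)
  stale <- 0L
  set.seed(cfg$seed)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    epoch_loss <- 0; n_batches <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      aug_seeds <- sample.int(.Machine$integer.max, length(idx))
      imgs <- lapply(seq_along(idx), function(j) {
        augment_fundus(data$train$images[[idx[j]]], aug_seeds[j])
      })
      fw <- forward_batch(model, imgs, data$train$labels[idx],
                          keep_cache = TRUE)
      grads <- batch_gradients(model, fw)
      upd_bb <- sgd_step(model$params[setdiff(names(model$params), "m")],
                         grads[setdiff(names(grads), "m")],
                         vel[setdiff(names(vel), "m")],
                         cfg$lr_backbone, cfg$momentum, cfg$weight_decay)
      upd_cl <- sgd_step(model$params["m"], grads["m"], vel["m"],
                         cfg$lr_classifier, cfg$momentum, cfg$weight_decay)
      model$params <- c(upd_bb$p, upd_cl$p)
      vel <- c(upd_bb$v, upd_cl$v)
      epoch_loss <- epoch_loss + fw$loss
      n_batches <- n_batches + 1L
    }
    train_loss <- epoch_loss / n_batches
    val_loss <- if (length(data$val$images)) {
      forward_batch(model, data$val$images, data$val$labels)$loss
    } else NA_real_
    log <- rbind(log, data.frame(epoch = epoch, train_loss = train_loss,
                                 val_loss = val_loss))
    if (verbose) {
      message(sprintf("epoch %d: train %.4f val %.4f", epoch, train_loss,
                      val_loss))
    }
    track <- if (is.na(val_loss)) train_loss else val_loss
    if (track < best$loss) {
      best <- list(loss = track, model = model, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= cfg$early_stop_patience) break
    }
  }
  structure(list(best_model = best$model, final_model = model, log = log,
                 best_epoch = best$epoch),
            class = "train_result")
}

#' Evaluate a model on a labeled image set
#'
#' Deterministic: no augmentation, plain resize only. Emits per-image
#' softmax probabilities, the confusion matrix, and the full metric report
#' including per-class one-vs-rest AUC.
#'
#' @param model `dr_model`.
#' @param images list of H x W x 3 arrays.
#' @param labels 0-based integer labels.
#' @return list of class `eval_result`: `probs` (n x C), `predicted`,
#'   `labels`, `cm` (`confusion_matrix`), `report` (`metrics_report`).
#' @export
evaluate_grader <- function(model, images, labels) {
  C <- model$n_classes
  if (any(labels >= C)) {
    stop(sprintf("label %d exceeds model class count %d",
                 max(labels), C), call. = FALSE)
  }
  n <- length(images)
  probs <- matrix(0, n, C)
  predicted <- integer(n)
  for (i in seq_len(n)) {
    img <- resize_image(images[[i]], model$config$image_size)
    fw <- model_forward(model, img)
    probs[i, ] <- fw$probs
    predicted[i] <- fw$predicted
  }
  cm <- confusion_matrix(labels, predicted, C)
  auc <- ovr_auc(probs, labels)
  structure(list(probs = probs, predicted = predicted, labels = labels,
                 cm = cm, report = metrics_report(cm, auc = auc)),
            class = "eval_result")
}

#' Collapse grades to the binary screening task
#'
#' Screening mode distinguishes grade 0 (no DR) from any DR (grades >= 1).
#'
#' @param labels integer grade vector.
#' @return 0/1 integer vector.
#' @export
binarize_labels <- function(labels) as.integer(labels > 0L)
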