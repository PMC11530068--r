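#' Model configuration for the soft-label CNN regressor
#'
#' Defaults mirror the study schedule: batch size 16, 10 epochs,
#' learning rate 7e-5 for epochs 1-4 then 3e-5 for the remainder, and
#' augmentation by multiples-of-90-degree rotation plus independent
#' horizontal/vertical flips. The `tiny_cnn` backbone is a
#' sub-100k-parameter network for desk-scale work; `paper_backbone`
#' selects an EfficientNet-B3-shaped architecture when an implementation
#' is available.
#'
#' @param backbone `"tiny_cnn"` or `"paper_backbone"`.
#' @param input_size `(H, W, C)` network input.
#' @param lr_schedule list of `list(epochs = <integer vector>, rate =
#'   <numeric>)` entries covering every epoch.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param augmentation list with `rotation_degrees` (90 enables the four
#'   right-angle rotations, 0 disables), `horizontal_flip`,
#'   `vertical_flip` logicals.
#' @param seed integer seed governing initialization, shuffling and
#'   augmentation draws.
#' @param average_final_weights average the network weights over the
#'   final learning-rate stage (Polyak/SWA-style) and use the average as
#'   the trained model; reduces run-to-run variance on small datasets.
#' @return object of class `mixshape_model_config`.
#' @export
model_config <- function(backbone = c("tiny_cnn", "paper_backbone"),
                         input_size = c(300, 300, 3),
                         lr_schedule = list(list(epochs = 1:4, rate = 7e-5),
                                            list(epochs = 5:10, rate = 3e-5)),
                         batch_size = 16, epochs = 10,
                         augmentation = list(rotation_degrees = 90,
                                             horizontal_flip = TRUE,
                                             vertical_flip = TRUE),
                         seed = 1L, average_final_weights = FALSE) {
  backbone <- match.arg(backbone)
  stopifnot(length(input_size) == 3, batch_size >= 1, epochs >= 1)
  structure(list(backbone = backbone, input_size = as.integer(input_size),
                 lr_schedule = lr_schedule, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), augmentation = augmentation,
                 seed = as.integer(seed),
                 average_final_weights = isTRUE(average_final_weights)),
            class = "mixshape_model_config")
}

lr_for_epoch <- function(config, epoch) {
  for (entry in config$lr_schedule)
    if (epoch %in% entry$epochs) return(entry$rate)
  utils::tail(config$lr_schedule, 1)[[1]]$rate
}

#' Build an (untrained) soft-label CNN regression model
#'
#' The network ends in a 3-unit softmax head (PARENTAL, RESISTANT,
#' CONTROL); weights are freshly He-initialized from the config seed —
#' no pretrained weights are used.
#'
#' @param config a [model_config()].
#' @return object of class `mixshape_model`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "mixshape_model_config"))
  if (config$backbone == "paper_backbone")
    stop("no EfficientNet-B3 implementation is configured in this ",
         "installation; use backbone = 'tiny_cnn'")
  d <- config$input_size
  if (d[1] < 24 || d[2] < 24)
    stop("input_size ", paste(d, collapse = "x"),
         " too small for the tiny_cnn backbone (needs >= 24x24)")
  net <- nn_build_tiny(d)
  net <- nn_init(net, config$seed)
  structure(list(net = net, config = config, fold_id = NA_integer_,
                 log = NULL, trained = FALSE),
            class = "mixshape_model")
}

#' @export
print.mixshape_model <- function(x, ...) {
  cat("<mixshape_model> backbone=", x$config$backbone,
      " input=", paste(x$config$input_size, collapse = "x"),
      " params=", nn_param_count(x$net),
      " trained=", x$trained, "\n", sep = "")
  invisible(x)
}

#' Number of trainable parameters of a model
#' @param model a `mixshape_model`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) nn_param_count(model$net)

# one of the 8 dihedral transforms of an (H, W, C) array:
# rotate by k * 90 degrees clockwise, then optional flips
dihedral_transform <- function(img, k = 0L, hflip = FALSE, vflip = FALSE) {
  d <- dim(img)
  if (length(d) == 2) img <- array(img, c(d, 1L))
  k <- k %% 4L
  if (k > 0 && dim(img)[1] != dim(img)[2])
    stop("rotation requires square spatial dimensions")
  for (r in seq_len(k)) {
    # clockwise 90: out[i, j] = in[H - j + 1, i]
    H <- dim(img)[1]
    img <- aperm(img, c(2, 1, 3))[, H:1, , drop = FALSE]
  }
  if (hflip) img <- img[, dim(img)[2]:1, , drop = FALSE]   # mirror columns
  if (vflip) img <- img[dim(img)[1]:1, , , drop = FALSE]   # mirror rows
  if (length(d) == 2) img <- img[, , 1]
  img
}

#' Randomly augment an image
#'
#' Applies a uniformly drawn multiple-of-90-degree rotation (when
#' `rotation_degrees = 90`) and independent Bernoulli(1/2) horizontal
#' and vertical flips. The label is unchanged by contract. An all-off
#' spec is the identity.
#'
#' @param image `(H, W, C)` array (square spatial dims when rotating).
#' @param spec augmentation list as in [model_config()].
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return augmented image array.
#' @export
augment <- function(image, spec, seed = NULL) {
  if (isTRUE(spec$rotation_degrees == 90) && dim(image)[1] != dim(image)[2])
    stop("rotation requires square spatial dimensions")
  draw <- function() {
    k <- if (isTRUE(spec$rotation_degrees == 90))
      sample.int(4L, 1L) - 1L else 0L
    hf <- isTRUE(spec$horizontal_flip) && stats::runif(1) < 0.5
    vf <- isTRUE(spec$vertical_flip) && stats::runif(1) < 0.5
    dihedral_transform(image, k, hf, vf)
  }
  if (is.null(seed)) draw() else with_seed_ms(seed, draw())
}

# permutation vector realizing a dihedral transform on flattened images
dihedral_perm <- function(dim3, k, hf, vf) {
  ref <- array(seq_len(prod(dim3)), dim3)
  as.integer(dihedral_transform(ref, k, hf, vf))
}

records_to_matrix <- function(records, input_size) {
  D <- prod(input_size)
  X <- matrix(0, D, length(records))
  for (i in seq_along(records)) {
    img <- records[[i]]$image
    if (!all(dim(img) == input_size))
      stop("record ", i, " has dims ", paste(dim(img), collapse = "x"),
           "; expected ", paste(input_size, collapse = "x"),
           " (preprocess records first)")
    X[, i] <- as.numeric(img)
  }
  X
}

labels_to_matrix <- function(records) {
  vapply(records, function(r) as.numeric(r$label), numeric(3))
}

#' Train one cross-validation fold model
#'
#' Minimizes the mean squared Euclidean distance between the softmax
#' output and the simplex label with Adam under the config's
#' learning-rate schedule, shuffling and augmenting per epoch. Logs
#' per-epoch training and validation loss. Deterministic given the
#' config seed.
#'
#' @param model an untrained (or warm) `mixshape_model`.
#' @param train_records,val_records preprocessed records at the model's
#'   input size; `val_records` may be empty.
#' @param fold_id integer recorded on the model.
#' @return the trained `mixshape_model` with `$log` (data.frame of
#'   epoch, lr, train_loss, val_loss).
#' @export
train_fold <- function(model, train_records, val_records = list(),
                       fold_id = NA_integer_) {
  stopifnot(inherits(model, "mixshape_model"))
  if (length(train_records) == 0) stop("empty training set")
  config <- model$config
  d <- config$input_size
  X <- records_to_matrix(train_records, d)
  Y <- labels_to_matrix(train_records)
  has_val <- length(val_records) > 0
  if (has_val) {
    Xv <- records_to_matrix(val_records, d)
    Yv <- labels_to_matrix(val_records)
  }
  aug <- config$augmentation
  use_rot <- isTRUE(aug$rotation_degrees == 90)
  if (use_rot && d[1] != d[2])
    stop("rotation augmentation requires square input")
  # precompute the 16 flattened-index permutations (4 rots x hf x vf)
  perms <- list()
  for (k in 0:3) for (hf in 0:1) for (vf in 0:1)
    perms[[paste(k, hf, vf)]] <- dihedral_perm(d, k, hf == 1, vf == 1)
  net <- model$net
  st <- adam_init(net)
  n <- ncol(X)
  log <- NULL
  # Polyak averaging window: the epochs of the final schedule stage
  swa_epochs <- if (isTRUE(config$average_final_weights))
    utils::tail(config$lr_schedule, 1)[[1]]$epochs else integer(0)
  swa_sum <- NULL; swa_n <- 0L
  with_seed_ms(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- lr_for_epoch(config, epoch)
      ord <- sample.int(n)
      ks <- if (use_rot) sample.int(4L, n, replace = TRUE) - 1L
            else integer(n)
      hfs <- if (isTRUE(aug$horizontal_flip))
        stats::runif(n) < 0.5 else logical(n)
      vfs <- if (isTRUE(aug$vertical_flip))
        stats::runif(n) < 0.5 else logical(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        bidx <- ord[start:min(start + config$batch_size - 1L, n)]
        Xb <- X[, bidx, drop = FALSE]
        for (bi in seq_along(bidx)) {
          s <- bidx[bi]
          pm <- perms[[paste(ks[s], as.integer(hfs[s]), as.integer(vfs[s]))]]
          Xb[, bi] <- Xb[pm, bi]
        }
        fw <- nn_forward(net, Xb)
        ls <- nn_mse_softmax(fw$logits, Y[, bidx, drop = FALSE])
        if (!is.finite(ls$loss))
          stop("training loss is not finite at epoch ", epoch,
               " (lr = ", lr, "); reduce the learning rate")
        bw <- nn_backward(net, fw$caches, ls$dlogits)
        up <- adam_step(net, bw$grads, st, lr)
        net <- up$net; st <- up$state
        ep_loss <- ep_loss + ls$loss; nb <- nb + 1L
      }
      if (epoch %in% swa_epochs) {
        if (is.null(swa_sum)) swa_sum <- lapply(net$layers, function(ly)
          if (!is.null(ly$W)) list(W = ly$W, b = ly$b) else NULL)
        else for (li in seq_along(net$layers)) {
          if (is.null(swa_sum[[li]])) next
          swa_sum[[li]]$W <- swa_sum[[li]]$W + net$layers[[li]]$W
          swa_sum[[li]]$b <- swa_sum[[li]]$b + net$layers[[li]]$b
        }
        swa_n <- swa_n + 1L
      }
      val_loss <- if (has_val)
        nn_mse_softmax(nn_forward(net, Xv)$logits, Yv)$loss else NA_real_
      log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                   train_loss = ep_loss / nb,
                                   val_loss = val_loss))
    }
  })
  if (swa_n > 0) for (li in seq_along(net$layers)) {
    if (is.null(swa_sum[[li]])) next
    net$layers[[li]]$W <- swa_sum[[li]]$W / swa_n
    net$layers[[li]]$b <- swa_sum[[li]]$b / swa_n
  }
  model$net <- net
  model$log <- log
  model$fold_id <- fold_id
  model$trained <- TRUE
  model
}

#' Predict soft labels for a set of records
#'
#' Batched, order-preserving, deterministic (no augmentation at
#' inference). Rows are valid simplex points.
#'
#' @param model a `mixshape_model`.
#' @param records preprocessed records.
#' @param batch_size inference batch size.
#' @return numeric matrix `(n, 3)` with columns PARENTAL, RESISTANT,
#'   CONTROL.
#' @export
predict_soft <- function(model, records, batch_size = 64L) {
  stopifnot(inherits(model, "mixshape_model"))
  X <- records_to_matrix(records, model$config$input_size)
  n <- ncol(X)
  out <- matrix(0, n, 3, dimnames = list(NULL, CLASS_NAMES))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    P <- nn_softmax(nn_forward(model$net, X[, idx, drop = FALSE])$logits)
    out[idx, ] <- t(P)
  }
  out
}

#' Save / load a model (weights, config, log)
#' @param model a `mixshape_model`.
#' @param path file path (`.rds`).
#' @return `load_model` returns the restored model; predictions are
#'   bit-equivalent to the saved model's.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "mixshape_model"))
  m
}

#' Grad-CAM saliency heatmap
#'
#' Standard gradient-weighted class activation mapping on the last
#' convolutional feature map: channel weights are the spatial means of
#' the target-logit gradients, the weighted feature-map sum is
#' rectified, bilinearly upsampled to the input size, and normalized to
#' `[0, 1]` by its maximum (an all-zero rectified map stays all zero).
#'
#' @param model a `mixshape_model` (tiny_cnn exposes its last conv map).
#' @param record one preprocessed [image_record()].
#' @param target_class class name or index 1..3 whose logit is explained.
#' @return numeric matrix `(H, W)` in `[0, 1]`.
#' @export
grad_cam <- function(model, record, target_class) {
  stopifnot(inherits(model, "mixshape_model"))
  if (is.character(target_class))
    target_class <- match(target_class, CLASS_NAMES)
  stopifnot(target_class %in% 1:3)
  net <- model$net
  if (is.null(net$feature_layer))
    stop("model exposes no convolutional feature map")
  X <- records_to_matrix(list(record), model$config$input_size)
  fw <- nn_forward(net, X)
  dlog <- matrix(0, 3, 1)
  dlog[target_class, 1] <- 1
  bw <- nn_backward(net, fw$caches, dlog, stop_layer = net$feature_layer)
  fd <- net$feature_dim
  A <- array(fw$caches[[net$feature_layer]]$out[, 1], fd)
  G <- array(bw$d_feature[, 1], fd)
  alpha <- apply(G, 3, mean)
  cam <- matrix(0, fd[1], fd[2])
  for (ch in seq_len(fd[3])) cam <- cam + alpha[ch] * A[, , ch]
  cam <- pmax(cam, 0)
  H <- model$config$input_size[1]; W <- model$config$input_size[2]
  cam <- resize_bilinear(cam, H, W)
  mx <- max(cam)
  if (mx > 0) cam <- cam / mx
  cam
}
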