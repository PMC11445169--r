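#' Training configuration for the droplet classifier
#'
#' Defaults follow the published recipe: categorical cross-entropy
#' minimized by plain mini-batch stochastic gradient descent at learning
#' rate 0.001 for 6 epochs with batches of 160 images, and a stratified
#' 95/5 train/validation split. Momentum, gradient reduction and
#' architecture depth are exposed; nothing else is tuned silently.
#'
#' @param epochs Number of passes over the training set.
#' @param batch_size Mini-batch size.
#' @param learning_rate SGD learning rate.
#' @param validation_fraction Fraction held out for validation (in (0,1)).
#' @param n_classes Number of classes (3).
#' @param input_side Input image side in pixels (55).
#' @param arch_depth `"small"` for the compact residual network used at
#'   desk scale, or `"50"` for the 50-layer bottleneck residual network
#'   (stages 3-4-6-3, grayscale input replicated to 3 channels).
#' @param seed Integer seed controlling weight initialization and epoch
#'   shuffling.
#' @param momentum SGD momentum (default 0: plain SGD).
#' @param grad_reduction `"sum"` to sum per-example gradients over the
#'   mini-batch (classical SGD; the effective step grows with the batch
#'   size) or `"mean"` to average them.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(epochs = 6, batch_size = 160,
                         learning_rate = 0.001,
                         validation_fraction = 0.05,
                         n_classes = 3, input_side = 55,
                         arch_depth = c("small", "50"),
                         seed = 1, momentum = 0,
                         grad_reduction = c("sum", "mean")) {
  arch_depth <- match.arg(as.character(arch_depth), c("small", "50"))
  grad_reduction <- match.arg(grad_reduction)
  stopifnot(epochs >= 1, batch_size >= 1,
            validation_fraction > 0, validation_fraction < 1,
            learning_rate > 0, momentum >= 0, momentum < 1)
  if (arch_depth == "50" && input_side < 32)
    stop("train_config(): the depth-50 architecture requires input_side >= 32")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 validation_fraction = validation_fraction,
                 n_classes = as.integer(n_classes),
                 input_side = as.integer(input_side),
                 arch_depth = arch_depth,
                 seed = as.integer(seed),
                 momentum = momentum,
                 grad_reduction = grad_reduction),
            class = "train_config")
}

# conv unit descriptor with He-initialized weights (draws from the current
# RNG stream; callers fix the seed)
conv_unit <- function(k, stride, pad, cin, cout, relu) {
  fan_in <- cin * k * k
  list(type = "conv", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), cin = as.integer(cin), cout = as.integer(cout),
       relu = relu,
       W = matrix(rnorm(cout * fan_in, 0, sqrt(2 / fan_in)), cout, fan_in),
       b = numeric(cout))
}

res_unit <- function(convs, proj = NULL) {
  list(type = "res", convs = convs, proj = proj)
}

pool_unit <- function(size = 2, stride = 2, pad = 0) {
  list(type = "maxpool", size = as.integer(size), stride = as.integer(stride),
       pad = as.integer(pad))
}

dense_unit <- function(nfeat, nclass) {
  list(type = "dense",
       W = matrix(rnorm(nclass * nfeat, 0, sqrt(2 / nfeat)), nclass, nfeat),
       b = numeric(nclass))
}

arch_small <- function(n_classes) {
  list(
    conv_unit(3, 1, 1, 1, 8, TRUE),
    pool_unit(),
    res_unit(list(conv_unit(3, 1, 1, 8, 8, TRUE),
                  conv_unit(3, 1, 1, 8, 8, FALSE))),
    pool_unit(),
    res_unit(list(conv_unit(3, 1, 1, 8, 16, TRUE),
                  conv_unit(3, 1, 1, 16, 16, FALSE)),
             proj = conv_unit(1, 1, 0, 8, 16, FALSE)),
    pool_unit(),
    list(type = "gap"),
    dense_unit(16, n_classes))
}

arch_resnet50 <- function(n_classes) {
  widths <- c(64, 128, 256, 512)
  blocks <- c(3, 4, 6, 3)
  units <- list(conv_unit(7, 2, 3, 3, 64, TRUE), pool_unit(3, 2, 1))
  cin <- 64
  for (s in seq_along(widths)) {
    w <- widths[s]
    for (b in seq_len(blocks[s])) {
      stride <- if (s > 1 && b == 1) 2L else 1L
      proj <- if (cin != 4 * w || stride > 1)
        conv_unit(1, stride, 0, cin, 4 * w, FALSE) else NULL
      units <- c(units, list(res_unit(list(
        conv_unit(1, 1, 0, cin, w, TRUE),
        conv_unit(3, stride, 1, w, w, TRUE),
        conv_unit(1, 1, 0, w, 4 * w, FALSE)), proj = proj)))
      cin <- 4L * w
    }
  }
  c(units, list(list(type = "gap"), dense_unit(2048, n_classes)))
}

#' Build an untrained residual-network droplet classifier
#'
#' The `"small"` variant is a compact residual network (a stem
#' convolution, two residual blocks -- the second with a 1x1 projection
#' skip -- interleaved with max pooling, global average pooling and a
#' 3-way softmax head) suited to desk-scale training on a CPU. The `"50"`
#' variant is the 50-layer bottleneck residual network (stages 3-4-6-3)
#' with the grayscale input replicated to 3 channels; it shares the exact
#' I/O contract. Initial weights are He-scaled Gaussians drawn
#' deterministically from the config seed.
#'
#' @param cfg A [train_config()].
#' @return An object of class `"droplet_classifier"`.
#' @export
build_classifier <- function(cfg = train_config()) {
  stopifnot(inherits(cfg, "train_config"))
  net <- withr::with_seed(cfg$seed, {
    if (cfg$arch_depth == "small") arch_small(cfg$n_classes)
    else arch_resnet50(cfg$n_classes)
  })
  structure(list(net = net, cfg = cfg,
                 input_channels = if (cfg$arch_depth == "small") 1L else 3L,
                 trained = FALSE, history = NULL),
            class = "droplet_classifier")
}

#' @export
print.droplet_classifier <- function(x, ...) {
  cat(sprintf("<droplet_classifier depth=%s, input %dx%d, %s>\n",
              x$cfg$arch_depth, x$cfg$input_side, x$cfg$input_side,
              if (x$trained) "trained" else "untrained"))
  if (!is.null(x$history)) {
    h <- x$history[nrow(x$history), ]
    cat(sprintf("  final epoch: train acc %.3f, val acc %.3f\n",
                h$train_acc, h$val_acc))
  }
  invisible(x)
}

# coerce (n, s, s) array / list of matrices / single matrix to (s, s, n)
as_input_cube <- function(images, side) {
  if (is.matrix(images)) images <- list(images)
  if (is.list(images)) {
    images <- lapply(images, as_image_matrix)
    arr <- array(0, c(length(images), side, side))
    for (i in seq_along(images)) {
      if (!all(dim(images[[i]]) == side))
        stop("image ", i, " has side ", nrow(images[[i]]),
             "; the model expects ", side, " (no silent resize)")
      arr[i, , ] <- images[[i]]
    }
    images <- arr
  }
  stopifnot(is.array(images), length(dim(images)) == 3)
  if (dim(images)[2] != side || dim(images)[3] != side)
    stop("input images are ", dim(images)[2], "x", dim(images)[3],
         "; the model expects ", side, "x", side, " (no silent resize)")
  aperm(images, c(2, 3, 1))
}

# intensity scaling applied before the first convolution: maps the 16-bit
# range to [0, 8]. The gain is part of the architecture: preprocessed
# droplet images are sparse (thin bright contours on a zero background),
# and this scale puts globally pooled activations at order one, which the
# fixed published learning rate expects.
scale_input <- function(cube) cube / 8192

#' Train the droplet classifier
#'
#' Stratified seeded split into training (95% by default) and validation
#' sets, then minimization of categorical cross-entropy by mini-batch SGD
#' at the configured learning rate for the configured number of epochs.
#' Training requires every class present in the training split and warns
#' on class imbalance (optionally down-sampling to balance).
#'
#' @param x Preprocessed images: an array of shape `(n, side, side)` or a
#'   list of `side x side` matrices.
#' @param y Integer labels in `{0, 1, 2}`, one per image.
#' @param cfg A [train_config()].
#' @param model Optional [build_classifier()] output to continue from;
#'   built fresh from `cfg` when `NULL`.
#' @param downsample If `TRUE`, an imbalanced class distribution is
#'   down-sampled to the minority class size instead of only warned about.
#' @return A trained `"droplet_classifier"` with a `history` data.frame
#'   (per-epoch train/validation loss and accuracy).
#' @export
train_classifier <- function(x, y, cfg = train_config(), model = NULL,
                             downsample = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  y <- as.integer(y)
  if (!all(y %in% 0:(cfg$n_classes - 1)))
    stop("train_classifier(): labels must be in 0..", cfg$n_classes - 1)
  X <- as_input_cube(x, cfg$input_side)
  n <- dim(X)[3]
  stopifnot(length(y) == n)
  counts <- tabulate(y + 1L, nbins = cfg$n_classes)
  if (any(counts == 0L))
    stop("train_classifier(): class(es) ",
         paste(which(counts == 0L) - 1L, collapse = ", "),
         " have no examples")
  keep <- seq_len(n)
  if (length(unique(counts)) > 1L) {
    if (downsample) {
      keep <- withr::with_seed(cfg$seed, unlist(lapply(
        0:(cfg$n_classes - 1),
        function(k) sample(which(y == k), min(counts)))))
      keep <- sort(keep)
      warning("train_classifier(): imbalanced classes down-sampled to ",
              min(counts), " per class")
    } else {
      warning("train_classifier(): class counts are imbalanced (",
              paste(counts, collapse = ", "),
              "); the published recipe trains on balanced classes")
    }
  }
  y <- y[keep]
  X <- X[, , keep, drop = FALSE]
  n <- length(y)

  if (is.null(model)) model <- build_classifier(cfg)
  stopifnot(inherits(model, "droplet_classifier"))

  split <- withr::with_seed(cfg$seed + 1L, {
    val_idx <- unlist(lapply(0:(cfg$n_classes - 1), function(k) {
      idx <- which(y == k)
      nv <- max(1L, round(cfg$validation_fraction * length(idx)))
      sample(idx, nv)
    }))
    train_idx <- setdiff(seq_len(n), val_idx)
    orders <- vapply(seq_len(cfg$epochs),
                     function(e) sample(length(train_idx)),
                     integer(length(train_idx)))
    list(val_idx = val_idx, train_idx = train_idx, orders = orders)
  })
  ytr <- y[split$train_idx]
  if (!all(0:(cfg$n_classes - 1) %in% ytr))
    stop("train_classifier(): a class is missing from the training split")

  Xtr <- scale_input(X[, , split$train_idx, drop = FALSE])
  Xva <- scale_input(X[, , split$val_idx, drop = FALSE])
  fit <- cpp_net_train(model$net, Xtr, ytr, Xva, y[split$val_idx],
                       model$input_channels, cfg$epochs, cfg$batch_size,
                       cfg$learning_rate, cfg$momentum, cfg$grad_reduction,
                       matrix(as.integer(split$orders),
                              nrow(split$orders), ncol(split$orders)))
  model$net <- fit$net
  model$trained <- TRUE
  model$history <- fit$history
  model$cfg <- cfg
  model
}

#' Predict droplet classes
#'
#' Runs the classifier on preprocessed images and returns one prediction
#' per image, in input order: the argmax label, the confidence on a 0-100
#' scale (100 x the maximum softmax probability) and the full probability
#' vector. Inference is deterministic given fixed weights; inputs of the
#' wrong spatial size are an error, never silently resized.
#'
#' @param object A `"droplet_classifier"`.
#' @param images Array `(n, side, side)`, list of matrices, or one matrix.
#' @param ... Unused.
#' @return Data.frame `label, confidence, p0, p1, p2`.
#' @export
predict.droplet_classifier <- function(object, images, ...) {
  X <- scale_input(as_input_cube(images, object$cfg$input_side))
  probs <- cpp_net_predict(object$net, X, object$input_channels)
  lab <- max.col(probs, ties.method = "first") - 1L
  out <- data.frame(label = lab, confidence = 100 * apply(probs, 1, max))
  colnames(probs) <- paste0("p", 0:(ncol(probs) - 1))
  cbind(out, as.data.frame(probs))
}

#' Filter predictions by confidence
#'
#' Keeps predictions whose confidence (0-100) is at least `threshold` and
#' reports the retained fraction. Retention is non-increasing in the
#' threshold; a threshold of 100 keeps only predictions with confidence
#' exactly 100.
#'
#' @param preds Data.frame with a `confidence` column (as returned by
#'   [predict.droplet_classifier()]).
#' @param threshold Confidence threshold in `[0, 100]`.
#' @return List with `retained` (the kept rows) and `retention_fraction`.
#' @export
filter_by_confidence <- function(preds, threshold) {
  stopifnot(is.data.frame(preds), "confidence" %in% names(preds),
            threshold >= 0, threshold <= 100)
  keep <- preds$confidence >= threshold
  list(retained = preds[keep, , drop = FALSE],
       retention_fraction = if (nrow(preds)) mean(keep) else NA_real_)
}

#' Save / load a trained classifier
#'
#' Writes the weights (`weights.rds`) together with a JSON sidecar
#' (`config.json`) recording the training configuration, and reads them
#' back.
#'
#' @param model A `"droplet_classifier"`.
#' @param dir Directory to write to / read from.
#' @return `save_classifier()` returns `dir` invisibly;
#'   `load_classifier()` returns the model.
#' @export
save_classifier <- function(model, dir) {
  stopifnot(inherits(model, "droplet_classifier"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  saveRDS(model[c("net", "input_channels", "trained", "history")],
          file.path(dir, "weights.rds"))
  jsonlite::write_json(unclass(model$cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(dir) {
  payload <- readRDS(file.path(dir, "weights.rds"))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  cfg <- do.call(train_config, cfg[setdiff(names(cfg), character(0))])
  structure(c(payload, list(cfg = cfg)), class = "droplet_classifier")
}
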