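#' Simulate a labeled droplet set in memory
#'
#' Renders a balanced set of synthetic droplets (Empty / Single /
#' Multiple, the Multiple class drawing 2-4 cells uniformly) with
#' per-image seeds derived from the master seed, optionally running the
#' preprocessing pipeline on each image. This is the in-memory counterpart
#' of [generate_dataset()] and the workhorse of training experiments.
#'
#' @param n_per_class Images per class.
#' @param config_template A [scene_config()].
#' @param seed Master integer seed.
#' @param preprocess_cfg A [preprocess_config()] to apply, or `NULL` to
#'   return raw [droplet_image] objects.
#' @return List with `x` (array `(n, side, side)` if preprocessed, else a
#'   list of [droplet_image]), `y` (integer labels) and `n_cells`.
#' @export
simulate_labeled_set <- function(n_per_class,
                                 config_template = scene_config(beadline = TRUE),
                                 seed = 1,
                                 preprocess_cfg = NULL) {
  stopifnot(n_per_class >= 1)
  n_total <- 3L * as.integer(n_per_class)
  withr::with_seed(as.integer(seed), {
    seeds <- sample.int(.Machine$integer.max - 1L, n_total)
    multi_counts <- sample(2:4, n_per_class, replace = TRUE)
  })
  y <- rep(0:2, each = n_per_class)
  n_cells <- c(rep(0L, n_per_class), rep(1L, n_per_class), multi_counts)
  if (is.null(preprocess_cfg)) {
    x <- vector("list", n_total)
  } else {
    x <- array(0, c(n_total, preprocess_cfg$target_side,
                    preprocess_cfg$target_side))
  }
  for (i in seq_len(n_total)) {
    cfg <- config_template
    cfg$n_cells <- as.integer(n_cells[i])
    cfg$seed <- seeds[i]
    img <- render_droplet(cfg)$image
    if (is.null(preprocess_cfg)) x[[i]] <- img
    else x[i, , ] <- preprocess_droplet(img$pixels, preprocess_cfg)
  }
  list(x = x, y = y, n_cells = as.integer(n_cells))
}

#' Hyper-parameter sweep over dataset size, epochs or batch size
#'
#' Trains one model (or several replicates) per parameter value on
#' synthetic droplets and evaluates each on a fixed held-out set, mirroring
#' the way training hyper-parameters are explored before fixing the final
#' recipe.
#'
#' @param param One of `"dataset_size"`, `"epochs"`, `"batch_size"`.
#' @param values Numeric vector of parameter values to try (non-empty).
#' @param n_replicates Models trained per value.
#' @param scene A [scene_config()] template for the synthetic data.
#' @param preprocess_cfg A [preprocess_config()].
#' @param base_train_cfg A [train_config()]; the swept field is overridden.
#' @param n_train_per_class Training images per class (used unless
#'   sweeping `dataset_size`).
#' @param n_eval_per_class Held-out evaluation images per class.
#' @param seed Master seed for data generation and training.
#' @return Data.frame with one row per (value, replicate):
#'   `param, value, replicate, overall_accuracy, acc_empty, acc_single,
#'   acc_multiple`.
#' @export
sweep_parameter <- function(param = c("dataset_size", "epochs", "batch_size"),
                            values, n_replicates = 1,
                            scene = scene_config(beadline = TRUE),
                            preprocess_cfg = preprocess_config(),
                            base_train_cfg = train_config(),
                            n_train_per_class = 200,
                            n_eval_per_class = 100,
                            seed = 1) {
  param <- match.arg(param)
  stopifnot(length(values) >= 1, n_replicates >= 1)
  eval_set <- simulate_labeled_set(n_eval_per_class, scene,
                                   seed = seed + 9000L,
                                   preprocess_cfg = preprocess_cfg)
  rows <- list()
  for (vi in seq_along(values)) {
    v <- values[vi]
    npc <- if (param == "dataset_size") as.integer(v) else n_train_per_class
    train_set <- simulate_labeled_set(npc, scene, seed = seed + 17L * vi,
                                      preprocess_cfg = preprocess_cfg)
    for (rep_i in seq_len(n_replicates)) {
      cfg <- base_train_cfg
      if (param == "epochs") cfg$epochs <- as.integer(v)
      if (param == "batch_size") cfg$batch_size <- as.integer(v)
      cfg$seed <- as.integer(seed + 1000L + 31L * vi + rep_i)
      model <- train_classifier(train_set$x, train_set$y, cfg)
      preds <- predict(model, eval_set$x)
      rep_score <- score_predictions(preds$label, eval_set$y)
      rows[[length(rows) + 1L]] <- data.frame(
        param = param, value = v, replicate = rep_i,
        overall_accuracy = rep_score$overall_accuracy,
        acc_empty = rep_score$per_class_accuracy[1],
        acc_single = rep_score$per_class_accuracy[2],
        acc_multiple = rep_score$per_class_accuracy[3])
    }
  }
  do.call(rbind, rows)
}
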