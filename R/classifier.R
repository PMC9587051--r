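# Pluggable softmax image classifier with the transfer-learning training
# schedule: a backbone produces a feature vector per 224x224x3 input and a
# multinomial softmax head is trained on top with minibatch RMSprop (or Adam
# or SGD with momentum), per-epoch shuffling and a piecewise step-decay
# learning rate.
#
# Deep zoo backbones (resnet50, vgg19, inceptionv3, mobilenetv2) are
# recognised names whose pretrained feature extractor must be registered by
# the user via `register_backbone()`; their internals are deliberately not
# re-implemented. The bundled desk-scale backbone, `smallcnn`, is a small
# convolutional network: a stride-2 average-pooling layer, a bank of seeded
# fixed zero-mean convolution filters with ReLU, spatial average pooling on a
# 4x4 grid and per-map statistics, concatenated with a 16-bin intensity
# histogram. Only the softmax head is trained — the same frozen-features /
# retrained-head structure transfer learning uses on the large backbones.

ZOO_BACKBONES <- c("resnet50", "vgg19", "inceptionv3", "mobilenetv2")
VALID_BACKBONES <- c(ZOO_BACKBONES, "smallcnn")

.backbone_registry <- new.env(parent = emptyenv())

#' Register a feature extractor for a zoo backbone
#'
#' Plugs a pretrained backbone into the pipeline. The extractor receives one
#' 224 x 224 x 3 array in `[0,1]` and must return a fixed-length numeric
#' feature vector; the softmax head is then trained on those features.
#'
#' @param name One of `"resnet50"`, `"vgg19"`, `"inceptionv3"`,
#'   `"mobilenetv2"`.
#' @param extractor `function(img) -> numeric`.
#' @return Invisibly, `name`.
#' @export
register_backbone <- function(name, extractor) {
  name <- match.arg(name, ZOO_BACKBONES)
  stopifnot(is.function(extractor))
  assign(name, extractor, envir = .backbone_registry)
  invisible(name)
}

#' Training configuration
#'
#' Hyperparameters of the softmax-head training schedule. The defaults for
#' deep zoo backbones are the fine-tuning settings (initial learning rate
#' 1e-5, minibatch 80, RMSprop with squared-gradient decay 0.99, 3 epochs,
#' shuffling every epoch, piecewise learning-rate drop factor 0.1 every
#' epoch). `smallcnn` trains a fresh head from scratch rather than fine-tuning
#' pretrained weights, so its backbone defaults use a larger initial rate
#' (0.1) and a smaller minibatch (20) under the same schedule.
#'
#' @param backbone One of `"resnet50"`, `"vgg19"`, `"inceptionv3"`,
#'   `"mobilenetv2"`, `"smallcnn"`.
#' @param n_stages Number of output classes (>= 2; default 4).
#' @param classes Class labels; defaults to the canonical stages when
#'   `n_stages = 4`.
#' @param initial_lr Initial learning rate `lr0`.
#' @param minibatch Minibatch size.
#' @param optimizer `"rmsprop"` (default), `"adam"` or `"sgdm"`.
#' @param squared_gradient_decay RMSprop squared-gradient moving-average
#'   coefficient (default 0.99).
#' @param epochs Training epochs (default 3).
#' @param shuffle_every_epoch Reshuffle minibatches each epoch.
#' @param lr_drop Step-decay drop factor in `(0, 1]` (default 0.1).
#' @param epochs_drop Epochs between decay steps (default 1).
#' @param lr_floor Minimum learning rate clamp (default 0).
#' @param quadrisect Train/predict on image quadrants (default `TRUE`).
#' @param n_augment Augmented copies of each training sample added to the
#'   datastore (default 0; quadrisection already quadruples the data).
#' @param seed Integer seed for filters, shuffling and initialisation.
#' @return A `training_config` list.
#' @export
training_config <- function(backbone = "smallcnn", n_stages = 4,
                            classes = NULL,
                            initial_lr = NULL, minibatch = NULL,
                            optimizer = c("rmsprop", "adam", "sgdm"),
                            squared_gradient_decay = 0.99, epochs = 3,
                            shuffle_every_epoch = TRUE, lr_drop = 0.1,
                            epochs_drop = 1, lr_floor = 0,
                            quadrisect = TRUE, n_augment = 0, seed = 1) {
  if (!backbone %in% VALID_BACKBONES) {
    stopf("unknown backbone '%s'; valid backbones: %s", backbone,
          paste(VALID_BACKBONES, collapse = ", "))
  }
  optimizer <- match.arg(optimizer)
  if (lr_drop <= 0 || lr_drop > 1) stopf("lr_drop must lie in (0, 1]")
  if (epochs < 1) stopf("epochs must be >= 1")
  if (lr_floor < 0) stopf("lr_floor must be >= 0")
  if (is.null(classes)) {
    classes <- if (n_stages == 4) canonical_stages()
               else if (n_stages == 3) c("diestrus+metestrus", "proestrus", "estrus")
               else paste0("stage", seq_len(n_stages))
  }
  if (length(classes) != n_stages) stopf("length(classes) must equal n_stages")
  if (n_stages < 2) stopf("n_stages must be >= 2")
  desk <- backbone == "smallcnn"
  structure(list(backbone = backbone, n_stages = n_stages, classes = classes,
                 initial_lr = initial_lr %||% (if (desk) 0.1 else 1e-5),
                 minibatch = minibatch %||% (if (desk) 20 else 80),
                 optimizer = optimizer,
                 squared_gradient_decay = squared_gradient_decay,
                 epochs = epochs, shuffle_every_epoch = shuffle_every_epoch,
                 lr_drop = lr_drop, epochs_drop = epochs_drop,
                 lr_floor = lr_floor, quadrisect = quadrisect,
                 n_augment = n_augment, seed = seed),
            class = "training_config")
}

#' Piecewise step-decay learning rate
#'
#' `lr(epoch) = max(lr_floor, lr0 * lr_drop ^ floor(epoch / epochs_drop))`,
#' with epoch indexed from 0 so the first epoch trains at the initial rate.
#' Non-increasing in `epoch`.
#'
#' @param epoch Integer epoch index (>= 0).
#' @param cfg A [training_config()].
#' @return Learning rate.
#' @export
step_decay_lr <- function(epoch, cfg) {
  if (any(epoch < 0)) stopf("epoch must be >= 0")
  pmax(cfg$lr_floor, cfg$initial_lr * cfg$lr_drop ^ floor(epoch / cfg$epochs_drop))
}

# --- smallcnn feature stage -------------------------------------------------

make_smallcnn_filters <- function(seed, n_filters = 8, size = 9) {
  with_seed(seed, {
    lapply(seq_len(n_filters), function(i) {
      f <- matrix(rnorm(size * size), size, size)
      f <- f - mean(f)        # zero mean: respond to structure, not level
      f / sqrt(sum(f^2))
    })
  })
}

# Average-pool a matrix by an integer factor.
avg_pool <- function(x, factor) {
  h <- nrow(x) %/% factor * factor
  w <- ncol(x) %/% factor * factor
  x <- x[seq_len(h), seq_len(w)]
  xr <- rowsum(x, rep(seq_len(h %/% factor), each = factor))
  t(rowsum(t(xr), rep(seq_len(w %/% factor), each = factor))) / factor^2
}

smallcnn_features <- function(img224, filters) {
  x <- img224[, , 1]                      # channels are identical grayscale
  x <- avg_pool(x, 2)                     # stride-2 pooling: 112 x 112
  feats <- unlist(lapply(filters, function(f) {
    resp <- EBImage::filter2(x, f, boundary = "replicate")
    resp <- pmax(resp, 0)                 # ReLU
    grid <- avg_pool(resp, nrow(resp) %/% 4)[1:4, 1:4]
    c(as.vector(grid), stats::sd(resp), max(resp))
  }))
  hist16 <- tabulate(pmin(pmax(floor(x * 16), 0), 15) + 1L, nbins = 16) / length(x)
  c(feats, hist16)
}

#' Build an untrained classifier
#'
#' Replaces the backbone's classification head with an `n_stages`-way softmax
#' head. For zoo backbones the convolutional feature extractor must have been
#' supplied via [register_backbone()]; `smallcnn` is self-contained.
#'
#' @param cfg A [training_config()].
#' @return An untrained `estrous_model`.
#' @export
build_model <- function(cfg = training_config()) {
  stopifnot(inherits(cfg, "training_config"))
  filters <- if (cfg$backbone == "smallcnn") {
    make_smallcnn_filters(cfg$seed)
  } else NULL
  structure(list(backbone = cfg$backbone, n_stages = cfg$n_stages,
                 classes = cfg$classes, config = cfg, filters = filters,
                 weights = NULL, feature_mean = NULL, feature_sd = NULL,
                 history = NULL, trained = FALSE),
            class = "estrous_model")
}

#' @export
print.estrous_model <- function(x, ...) {
  cat(sprintf("<estrous_model> backbone=%s, %d stages (%s), %s\n",
              x$backbone, x$n_stages, paste(x$classes, collapse = ", "),
              if (x$trained) sprintf("trained (%d epochs)", nrow(x$history))
              else "untrained"))
  invisible(x)
}

model_features <- function(model, img224) {
  if (model$backbone == "smallcnn") return(smallcnn_features(img224, model$filters))
  extractor <- get0(model$backbone, envir = .backbone_registry)
  if (is.null(extractor)) {
    stopf(paste("backbone '%s' has no registered feature extractor;",
                "pretrained weights are not bundled — register one with",
                "register_backbone()"), model$backbone)
  }
  extractor(img224)
}

# Preprocessing chain shared by training and inference:
# grayscale -> luminance peak alignment -> 3 channels -> [quadrisect] ->
# 224x224x3 resize. Returns a list of one or four input arrays.
preprocess_for_model <- function(img, quadrisect = TRUE) {
  g <- rgb_to_gray(img)
  g <- normalize_luminance(g)
  g3 <- to_three_channel_gray(g)
  pieces <- if (quadrisect) quadrisect(g3) else list(g3)
  lapply(pieces, resize_to_input)
}

manifest_features <- function(model, m, quadrisect, augment_params_list = NULL) {
  feats <- list()
  labels <- character(0)
  groups <- integer(0)
  for (i in seq_len(nrow(m))) {
    img <- load_image(m$image_path[i])
    variants <- list(img)
    if (!is.null(augment_params_list)) {
      for (ap in augment_params_list) {
        ap$seed <- (ap$seed %||% 0) + i  # per-image deterministic draw
        variants <- c(variants, list(augment(img, ap)))
      }
    }
    for (v in variants) {
      for (piece in preprocess_for_model(v, quadrisect)) {
        feats[[length(feats) + 1]] <- model_features(model, piece)
        labels <- c(labels, m$stage[i])
        groups <- c(groups, i)
      }
    }
  }
  list(x = do.call(rbind, feats), y = labels, group = groups)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Aggregate per-piece softmax rows back to per-image predictions (quadrant
# probabilities are averaged before the argmax).
aggregate_predictions <- function(P, group, classes) {
  groups <- unique(group)
  pred <- vapply(groups, function(g) {
    pm <- colMeans(P[group == g, , drop = FALSE])
    classes[which.max(pm)]
  }, character(1))
  list(group = groups, pred = pred)
}

#' Train a classifier on a dataset split
#'
#' Extracts backbone features for every training image (after the standard
#' preprocessing chain, with quadrisection and optional augmentation
#' expanding the datastore), standardizes them, and trains the softmax head
#' with the configured optimizer and step-decay schedule, reshuffling
#' minibatches every epoch. Validation accuracy is recorded per epoch when a
#' validation partition is present.
#'
#' @param model An untrained model from [build_model()].
#' @param split A [split_dataset()] result (or a list with at least `$train`;
#'   `$validation` may be empty).
#' @param cfg Optional [training_config()] override; defaults to the config
#'   the model was built with.
#' @return A trained `estrous_model` with a `history` data.frame (per-epoch
#'   `loss` and `val_accuracy`).
#' @export
train <- function(model, split, cfg = NULL) {
  stopifnot(inherits(model, "estrous_model"))
  cfg <- cfg %||% model$config
  if (cfg$epochs < 1) stopf("epochs must be >= 1")
  m <- split$train
  if (is.null(m) || nrow(m) == 0) stopf("training partition is empty")
  present <- unique(m$stage)
  missing_cls <- setdiff(model$classes, present)
  if (model$n_stages == 4 && length(missing_cls)) {
    stopf("stage(s) absent from training data: %s",
          paste(missing_cls, collapse = ", "))
  }
  aug <- if (cfg$n_augment > 0) {
    lapply(seq_len(cfg$n_augment), function(j)
      augment_params(seed = cfg$seed * 1000 + j))
  } else NULL
  tr <- with_seed(cfg$seed, manifest_features(model, m, cfg$quadrisect, aug))
  mu <- colMeans(tr$x)
  sdv <- apply(tr$x, 2, stats::sd)
  sdv[sdv < 1e-8] <- 1
  Xs <- sweep(sweep(tr$x, 2, mu), 2, sdv, "/")
  Y <- outer(tr$y, model$classes, "==") * 1
  val <- NULL
  if (!is.null(split$validation) && nrow(split$validation) > 0) {
    val <- with_seed(cfg$seed + 1L,
                     manifest_features(model, split$validation, cfg$quadrisect))
    val$xs <- sweep(sweep(val$x, 2, mu), 2, sdv, "/")
  }
  # train epoch by epoch so validation accuracy is recorded along the way
  history <- data.frame(epoch = seq_len(cfg$epochs), loss = NA_real_,
                        learning_rate = step_decay_lr(seq_len(cfg$epochs) - 1, cfg),
                        val_accuracy = NA_real_)
  Wcur <- NULL
  with_seed(cfg$seed + 2L, {
    for (e in seq_len(cfg$epochs)) {
      one <- cfg
      one$initial_lr <- step_decay_lr(e - 1, cfg)
      st <- train_softmax_head_continue(Xs, Y, one, Wcur)
      Wcur <- st$W
      history$loss[e] <- st$losses[1]
      if (!is.null(val)) {
        P <- softmax_rows(cbind(1, val$xs) %*% Wcur)
        agg <- aggregate_predictions(P, val$group, model$classes)
        truth <- val$y[!duplicated(val$group)]
        history$val_accuracy[e] <- mean(agg$pred == truth)
      }
    }
  })
  model$weights <- Wcur
  model$feature_mean <- mu
  model$feature_sd <- sdv
  model$history <- history
  model$config <- cfg
  model$trained <- TRUE
  ec_log("train: backbone=%s n=%d samples, %d epochs, final loss %.4f",
         model$backbone, nrow(Xs), cfg$epochs, history$loss[cfg$epochs])
  model
}

# One epoch of head training continuing from W0 (state-light continuation:
# the squared-gradient accumulator restarts each epoch).
train_softmax_head_continue <- function(X, Y, cfg, W0 = NULL) {
  n <- nrow(X); p <- ncol(X); k <- ncol(Y)
  W <- W0 %||% matrix(0, p + 1, k)
  V <- matrix(0, p + 1, k)
  M <- matrix(0, p + 1, k)
  Xb <- cbind(1, X)
  lr <- cfg$initial_lr
  idx <- if (cfg$shuffle_every_epoch) sample.int(n) else seq_len(n)
  batch_starts <- seq(1, n, by = cfg$minibatch)
  epoch_loss <- 0
  step <- 0
  for (b in batch_starts) {
    rows <- idx[b:min(b + cfg$minibatch - 1, n)]
    Xm <- Xb[rows, , drop = FALSE]
    Ym <- Y[rows, , drop = FALSE]
    P <- softmax_rows(Xm %*% W)
    G <- crossprod(Xm, P - Ym) / length(rows)
    step <- step + 1
    if (cfg$optimizer == "rmsprop") {
      rho <- cfg$squared_gradient_decay
      V <- rho * V + (1 - rho) * G^2
      W <- W - lr * G / (sqrt(V) + 1e-8)
    } else if (cfg$optimizer == "adam") {
      M <- 0.9 * M + 0.1 * G
      V <- 0.999 * V + 0.001 * G^2
      W <- W - lr * (M / (1 - 0.9^step)) / (sqrt(V / (1 - 0.999^step)) + 1e-8)
    } else {
      V <- 0.9 * V + G
      W <- W - lr * V
    }
    epoch_loss <- epoch_loss + -sum(Ym * log(pmax(P, 1e-12))) / length(rows)
  }
  list(W = W, losses = epoch_loss / length(batch_starts))
}

#' Per-stage softmax probabilities for one image
#'
#' Applies the standard preprocessing chain (luminance alignment, 3-channel
#' grayscale, optional quadrisection, 224 x 224 x 3 resize), extracts
#' backbone features, and evaluates the trained softmax head. With
#' `aggregate_quadrants` the four quadrant softmax vectors are averaged and
#' renormalized; with `FALSE` the whole image is classified in one pass.
#'
#' @param model A trained `estrous_model`.
#' @param record A single-row manifest, an image path, or an image array.
#' @param aggregate_quadrants Average quadrant predictions (default taken
#'   from the model's config).
#' @return A named probability vector summing to 1 (class
#'   `stage_probabilities`).
#' @export
predict_probabilities <- function(model, record, aggregate_quadrants = NULL) {
  if (!isTRUE(model$trained)) stopf("model is not trained")
  quad <- aggregate_quadrants %||% model$config$quadrisect
  img <- if (is.character(record)) load_image(record)
         else if (is.data.frame(record)) load_image(record$image_path[1])
         else record
  pieces <- preprocess_for_model(img, quad)
  P <- t(vapply(pieces, function(piece) {
    f <- model_features(model, piece)
    fs <- (f - model$feature_mean) / model$feature_sd
    z <- c(1, fs) %*% model$weights
    as.vector(softmax_rows(z))
  }, numeric(model$n_stages)))
  p <- colMeans(P)
  p <- p / sum(p)
  structure(stats::setNames(p, model$classes), class = "stage_probabilities")
}

#' Classify every record of a manifest
#'
#' @param model A trained `estrous_model`.
#' @param m An `estrous_manifest`.
#' @param aggregate_quadrants See [predict_probabilities()].
#' @return A list of `estrous_result` objects (one per record).
#' @export
classify_manifest <- function(model, m, aggregate_quadrants = NULL) {
  lapply(seq_len(nrow(m)), function(i) {
    p <- predict_probabilities(model, m[i, , drop = FALSE], aggregate_quadrants)
    classification_result(p, image_path = m$image_path[i])
  })
}
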