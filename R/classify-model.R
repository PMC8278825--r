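# Desk-scale classification stage: a backbone-agnostic feature extractor
# feeding a seeded multilayer-perceptron head with the two dropout(0.75)
# layers and a softmax output of 2 (diet or size task) or 4 (joint task)
# units, trained with Adam on cross-entropy.
#
# The production-scale equivalent uses a large pretrained convolutional
# backbone; here the backbone is any function mapping an image matrix to a
# fixed-length feature vector, with a default that block-average-pools the
# image and appends simple texture summaries. This keeps the full pipeline
# trainable in minutes on one CPU while preserving the head architecture
# and every interface around it.

#' Default pooling backbone
#'
#' Block-average-pools the image to a `grid` of cells and appends global
#' summaries (mean, standard deviation, mean absolute horizontal and
#' vertical gradient), giving a fixed-length descriptor of intensity and
#' texture.
#'
#' @param image numeric matrix.
#' @param grid integer (rows, cols) of the pooling grid.
#' @return numeric feature vector of length `prod(grid) + 4`.
#' @export
backbone_pool <- function(image, grid = c(6, 8)) {
  h <- nrow(image); w <- ncol(image)
  ri <- ceiling(seq_len(h) / h * grid[1])
  ci <- ceiling(seq_len(w) / w * grid[2])
  cell <- (ci[col(image)] - 1) * grid[1] + ri[row(image)]
  pooled <- as.vector(tapply(as.vector(image), cell, mean))
  gx <- if (w > 1) mean(abs(image[, -1, drop = FALSE] - image[, -w, drop = FALSE])) else 0
  gy <- if (h > 1) mean(abs(image[-1, , drop = FALSE] - image[-h, , drop = FALSE])) else 0
  c(pooled, mean(image), stats::sd(as.vector(image)), gx, gy)
}

#' Classifier configuration
#'
#' @param task `"diet"` (CON vs HF), `"size"` (AGA vs SGA) or `"joint"`
#'   (all four classes).
#' @param backbone feature extractor: the string `"pool"` (default,
#'   [backbone_pool()]) or any function `image -> numeric vector`, e.g. a
#'   wrapper around a pretrained network.
#' @param hidden integer widths of the two dense layers of the head.
#' @param dropout dropout rate of the two dropout layers (default 0.75).
#' @param epochs,batch_size,learning_rate,seed training hyperparameters
#'   (Adam optimizer).
#' @param augment apply random flip/rotation augmentation to training
#'   images (one of the 4 variants sampled per image per epoch).
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(task = c("diet", "size", "joint"),
                              backbone = "pool", hidden = c(32, 16),
                              dropout = 0.75, epochs = 10, batch_size = 32,
                              learning_rate = 1e-3, seed = 1L,
                              augment = FALSE) {
  task <- match.arg(task)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)", call. = FALSE)
  if (epochs < 1 || batch_size < 1 || learning_rate <= 0) {
    stop("epochs, batch_size >= 1 and learning_rate > 0 required", call. = FALSE)
  }
  structure(list(task = task, backbone = backbone, hidden = hidden,
                 dropout = dropout, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 augment = isTRUE(augment)),
            class = "classifier_config")
}

task_labels <- function(items, task) {
  switch(task,
         diet = items$diet,
         size = items$size,
         joint = items$class)
}

task_classes <- function(task) {
  switch(task,
         diet = c("CON", "HF"),
         size = c("AGA", "SGA"),
         joint = TISSUE_CLASSES)
}

backbone_fn <- function(backbone) {
  if (is.function(backbone)) return(backbone)
  if (identical(backbone, "pool")) return(backbone_pool)
  stop("unknown backbone: ", backbone, call. = FALSE)
}

# ---- MLP head ----------------------------------------------------------

mlp_init <- function(n_in, hidden, n_out, seed) {
  dims <- c(n_in, hidden, n_out)
  with_seed(seed, {
    lapply(seq_len(length(dims) - 1), function(i) {
      list(W = matrix(stats::rnorm(dims[i] * dims[i + 1],
                                   sd = sqrt(2 / dims[i])),
                      dims[i], dims[i + 1]),
           b = rep(0, dims[i + 1]))
    })
  })
}

# Forward pass. In training mode, inverted dropout (keep-prob scaling at
# train time) follows each hidden activation, so evaluation is a plain
# deterministic pass. Returns activations for backprop.
mlp_forward <- function(layers, X, dropout = 0, training = FALSE) {
  L <- length(layers)
  acts <- vector("list", L + 1)
  masks <- vector("list", L)
  acts[[1]] <- X
  for (i in seq_len(L)) {
    Z <- acts[[i]] %*% layers[[i]]$W +
      matrix(layers[[i]]$b, nrow(acts[[i]]), length(layers[[i]]$b), byrow = TRUE)
    if (i < L) {
      A <- pmax(Z, 0)
      if (training && dropout > 0) {
        m <- matrix(stats::runif(length(A)) >= dropout, nrow(A), ncol(A))
        A <- A * m / (1 - dropout)
        masks[[i]] <- m
      }
      acts[[i + 1]] <- A
    } else {
      Z <- Z - apply(Z, 1, max)
      P <- exp(Z)
      acts[[i + 1]] <- P / rowSums(P)
    }
  }
  list(acts = acts, masks = masks)
}

mlp_backward <- function(layers, fwd, Y, dropout) {
  L <- length(layers)
  n <- nrow(Y)
  grads <- vector("list", L)
  delta <- (fwd$acts[[L + 1]] - Y) / n
  for (i in L:1) {
    grads[[i]] <- list(W = t(fwd$acts[[i]]) %*% delta, b = colSums(delta))
    if (i > 1) {
      delta <- delta %*% t(layers[[i]]$W)
      delta <- delta * (fwd$acts[[i]] > 0)
      if (!is.null(fwd$masks[[i - 1]])) {
        delta <- delta * fwd$masks[[i - 1]] / (1 - dropout)
      }
    }
  }
  grads
}

cross_entropy <- function(P, Y) {
  -mean(log(pmax(rowSums(P * Y), 1e-12)))
}

#' Train the classification head on a split dataset
#'
#' Extracts backbone features for the train and validation splits,
#' standardizes them with train-split statistics, and optimizes the
#' two-dropout-layer softmax head by minibatch Adam on cross-entropy.
#' Every epoch the train and validation splits are re-evaluated in
#' deterministic (dropout-off) mode to record the learning curves. Fully
#' seeded: identical dataset and config reproduce identical weights and
#' history.
#'
#' @param dataset a `labeled_dataset` with a `split` column (see
#'   [split_dataset()]) and `images` holding either [phase_map()] objects
#'   or plain matrices.
#' @param config a [classifier_config()].
#' @return object of class `picslim_classifier`: the trained layers plus
#'   feature scaling, class set, the slide ids seen in training or
#'   validation, and `history` (data.frame of per-epoch train/val accuracy
#'   and loss).
#' @export
train_classifier <- function(dataset, config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  items <- dataset$items
  if (is.null(items$split)) stop("dataset has no split; call split_dataset()", call. = FALSE)
  tr <- which(items$split == "train")
  va <- which(items$split == "val")
  if (!length(tr)) stop("empty training split", call. = FALSE)
  if (!length(va)) stop("empty validation split", call. = FALSE)
  bb <- backbone_fn(config$backbone)
  get_img <- function(i) {
    im <- dataset$images[[i]]
    if (inherits(im, "phase_map")) im$phi else im
  }
  feats_of <- function(idx, variant = 1L) {
    variant <- rep_len(variant, length(idx))
    t(vapply(seq_along(idx), function(k) {
      img <- get_img(idx[k])
      if (variant[k] > 1L) img <- augmentation_variants(img)[[variant[k]]]
      bb(img)
    }, numeric(length(bb(get_img(idx[1]))))))
  }
  classes <- task_classes(config$task)
  y_all <- task_labels(items, config$task)
  onehot <- function(lab) {
    Y <- matrix(0, length(lab), length(classes))
    Y[cbind(seq_along(lab), match(lab, classes))] <- 1
    Y
  }
  # with augmentation on, precompute the 4 variants' features once and
  # sample a variant per image per epoch (cheap stand-in for on-the-fly
  # augmentation)
  n_var <- if (config$augment) 4L else 1L
  Xtr_var <- lapply(seq_len(n_var), function(v) {
    feats_of(tr, rep(v, length(tr)))
  })
  mu <- colMeans(Xtr_var[[1]])
  sdv <- pmax(apply(Xtr_var[[1]], 2, stats::sd), 1e-8)
  scale_X <- function(X) sweep(sweep(X, 2, mu), 2, sdv, "/")
  Xtr_var <- lapply(Xtr_var, scale_X)
  Xva <- scale_X(feats_of(va))
  Ytr <- onehot(y_all[tr]); Yva <- onehot(y_all[va])

  layers <- mlp_init(ncol(Xva), config$hidden, length(classes),
                     derive_seed(config$seed, 1L))
  mstate <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  vstate <- mstate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t_step <- 0
  history <- data.frame(epoch = integer(), train_acc = numeric(),
                        train_loss = numeric(), val_acc = numeric(),
                        val_loss = numeric())
  eval_split <- function(X, Y) {
    P <- mlp_forward(layers, X)$acts[[length(layers) + 1]]
    list(acc = mean(max.col(P) == max.col(Y)), loss = cross_entropy(P, Y))
  }
  for (ep in seq_len(config$epochs)) {
    ep_seed <- derive_seed(config$seed, 2L, ep)
    with_seed(ep_seed, {
      ord <- sample.int(length(tr))
      variant <- if (config$augment) sample.int(4L, length(tr), replace = TRUE)
                 else rep(1L, length(tr))
      for (start in seq(1, length(tr), by = config$batch_size)) {
        bidx <- ord[start:min(start + config$batch_size - 1, length(tr))]
        Xb <- do.call(rbind, lapply(bidx, function(k) {
          Xtr_var[[variant[k]]][k, , drop = FALSE]
        }))
        fwd <- mlp_forward(layers, Xb, dropout = config$dropout, training = TRUE)
        grads <- mlp_backward(layers, fwd, Ytr[bidx, , drop = FALSE],
                              config$dropout)
        t_step <- t_step + 1
        for (i in seq_along(layers)) {
          for (p in c("W", "b")) {
            g <- grads[[i]][[p]]
            mstate[[i]][[p]] <- b1 * mstate[[i]][[p]] + (1 - b1) * g
            vstate[[i]][[p]] <- b2 * vstate[[i]][[p]] + (1 - b2) * g^2
            mhat <- mstate[[i]][[p]] / (1 - b1^t_step)
            vhat <- vstate[[i]][[p]] / (1 - b2^t_step)
            layers[[i]][[p]] <- layers[[i]][[p]] -
              config$learning_rate * mhat / (sqrt(vhat) + eps)
          }
        }
      }
    })
    etr <- eval_split(Xtr_var[[1]], Ytr)
    eva <- eval_split(Xva, Yva)
    history <- rbind(history, data.frame(
      epoch = ep, train_acc = etr$acc, train_loss = etr$loss,
      val_acc = eva$acc, val_loss = eva$loss))
  }
  structure(list(layers = layers, config = config, classes = classes,
                 feat_mean = mu, feat_sd = sdv,
                 train_slides = unique(items$slide[items$split %in% c("train", "val")]),
                 history = history),
            class = "picslim_classifier")
}

#' @export
print.picslim_classifier <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf("<picslim_classifier> task %s, %d classes, %d epochs, val acc %.3f\n",
              x$config$task, length(x$classes), nrow(x$history), h$val_acc))
  invisible(x)
}

#' Predict class labels or probabilities
#'
#' @param object a trained `picslim_classifier`.
#' @param images list of [phase_map()] objects or matrices.
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @return character vector of labels or a probability matrix.
#' @export
predict.picslim_classifier <- function(object, images, type = c("class", "prob"),
                                       ...) {
  type <- match.arg(type)
  bb <- backbone_fn(object$config$backbone)
  X <- t(vapply(images, function(im) {
    bb(if (inherits(im, "phase_map")) im$phi else im)
  }, numeric(length(object$feat_mean))))
  X <- sweep(sweep(X, 2, object$feat_mean), 2, object$feat_sd, "/")
  P <- mlp_forward(object$layers, X)$acts[[length(object$layers) + 1]]
  colnames(P) <- object$classes
  if (type == "prob") P else object$classes[max.col(P)]
}

#' Evaluate a trained classifier on a dataset split
#'
#' @param model a trained `picslim_classifier`.
#' @param dataset the `labeled_dataset` (with `split` when `split` is
#'   named).
#' @param split which split to evaluate (`"test"` default; `"all"` uses
#'   every item).
#' @return list with `accuracy`, `mean_loss` (cross-entropy) and
#'   `confusion` (a [confusion_matrix()]).
#' @export
evaluate <- function(model, dataset, split = "test") {
  stopifnot(inherits(model, "picslim_classifier"))
  items <- dataset$items
  idx <- if (identical(split, "all")) seq_len(nrow(items)) else {
    if (is.null(items$split)) stop("dataset has no split", call. = FALSE)
    which(items$split == split)
  }
  if (!length(idx)) stop("no items in split ", split, call. = FALSE)
  truth <- task_labels(items[idx, , drop = FALSE], model$config$task)
  if (any(!truth %in% model$classes)) {
    stop("dataset labels do not match the model's task classes", call. = FALSE)
  }
  P <- predict(model, dataset$images[idx], type = "prob")
  pred <- model$classes[max.col(P)]
  Y <- matrix(0, length(idx), length(model$classes))
  Y[cbind(seq_along(idx), match(truth, model$classes))] <- 1
  list(accuracy = mean(pred == truth),
       mean_loss = cross_entropy(P, Y),
       confusion = confusion_matrix(truth, pred, labels = model$classes))
}

#' Evaluate a held-out slide never seen in training
#'
#' Restricts the dataset to one source slide, verifies the slide leaked
#' into neither the training nor the validation split of the model, and
#' reports the three true-positive rates (both factors, diet alone, size
#' alone) from the model's joint four-class predictions.
#'
#' @param model a trained `picslim_classifier` with `task = "joint"`.
#' @param dataset a `labeled_dataset` containing the slide's images.
#' @param slide the held-out slide id.
#' @return named numeric vector `c(joint =, diet =, size =)`.
#' @export
evaluate_holdout_slide <- function(model, dataset, slide) {
  stopifnot(inherits(model, "picslim_classifier"))
  if (model$config$task != "joint") {
    stop("held-out-slide evaluation needs a joint (four-class) model",
         call. = FALSE)
  }
  if (slide %in% model$train_slides) {
    stop("slide ", slide, " leaked into training/validation", call. = FALSE)
  }
  idx <- which(dataset$items$slide == slide)
  if (!length(idx)) stop("slide ", slide, " not present in dataset", call. = FALSE)
  pred <- predict(model, dataset$images[idx])
  holdout_rates(dataset$items$class[idx], pred)
}
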