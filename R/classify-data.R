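# Dataset splitting, augmentation and evaluation containers for the
# classification stage.

#' Split a labeled dataset into train / validation / test
#'
#' Reproducible random assignment of `n_train + n_val + n_test` items;
#' any remaining items are marked `"unused"`. With `stratify = TRUE` the
#' class proportions within each split are balanced as evenly as the
#' requested counts allow (each class contributes `floor(n_s / K)` items
#' plus a deterministic share of the remainder).
#'
#' @param dataset a `labeled_dataset` (see [generate_labeled_dataset()]),
#'   or any list with an `items` data.frame carrying a `class` column.
#' @param n_train,n_val,n_test split sizes; their sum must not exceed the
#'   number of items.
#' @param seed integer seed.
#' @param stratify balance classes within each split.
#' @return the dataset with a `split` column added to `items`, one of
#'   `"train"`, `"val"`, `"test"`, `"unused"`.
#' @export
#' @examples
#' ds <- list(items = data.frame(id = 1:10, class = rep(c("a", "b"), 5)))
#' table(split_dataset(ds, 6, 2, 2, seed = 1)$items$split)
split_dataset <- function(dataset, n_train, n_val, n_test, seed = 1L,
                          stratify = FALSE) {
  items <- dataset$items
  n <- nrow(items)
  sizes <- c(train = n_train, val = n_val, test = n_test)
  if (any(sizes < 0) || sum(sizes) > n) {
    stop(sprintf("split sizes %d+%d+%d exceed the %d available items",
                 n_train, n_val, n_test, n), call. = FALSE)
  }
  split <- rep("unused", n)
  if (!stratify) {
    ord <- with_seed(seed, sample.int(n))
    labels <- rep(names(sizes), sizes)
    split[ord[seq_along(labels)]] <- labels
  } else {
    classes <- sort(unique(items$class))
    K <- length(classes)
    # per-class quotas: floor share plus a remainder rotated across
    # classes between splits, so no class is over-drawn when totals fit
    off <- 0
    quotas <- lapply(sizes, function(ns) {
      r <- ns %% K
      extra <- rep(0L, K)
      if (r > 0) extra[(off + seq_len(r) - 1) %% K + 1] <- 1L
      off <<- off + r
      rep(ns %/% K, K) + extra
    })
    for (ci in seq_along(classes)) {
      idx <- which(items$class == classes[ci])
      idx <- with_seed(derive_seed(seed, 7L, ci), idx[sample.int(length(idx))])
      want <- c(train = quotas$train[ci], val = quotas$val[ci],
                test = quotas$test[ci])
      if (sum(want) > length(idx)) {
        stop(sprintf("class %s has %d items, %d requested", classes[ci],
                     length(idx), sum(want)), call. = FALSE)
      }
      labels <- rep(names(want), want)
      split[idx[seq_along(labels)]] <- labels
    }
  }
  dataset$items$split <- split
  dataset
}

#' Apply a fixed set of augmentation operations
#'
#' Deterministic building block: applies exactly the named operations.
#' `flip_x` mirrors along the x axis (reverses columns), `flip_y` mirrors
#' along the y axis (reverses rows), `rot180` rotates by 180 degrees
#' (equal to `flip_x` then `flip_y`). All three preserve the frame shape
#' and permute pixels, so pixel histograms are invariant.
#'
#' @param image numeric matrix.
#' @param ops character vector, subset of
#'   `c("rot180", "flip_x", "flip_y")`, applied in the given order.
#' @return transformed matrix.
#' @export
apply_augmentation <- function(image, ops = character()) {
  stopifnot(all(ops %in% c("rot180", "flip_x", "flip_y")))
  for (op in ops) {
    image <- switch(op,
      flip_x = image[, rev(seq_len(ncol(image))), drop = FALSE],
      flip_y = image[rev(seq_len(nrow(image))), , drop = FALSE],
      rot180 = image[rev(seq_len(nrow(image))), rev(seq_len(ncol(image))),
                     drop = FALSE])
  }
  image
}

#' Random training augmentation
#'
#' Applies each available operation independently with probability 1/2.
#' Because `rot180 = flip_x o flip_y`, the group generated by the three
#' operations on a rectangular frame has 4 distinct elements (identity,
#' the two flips, and the rotation); 90-degree rotations are excluded so
#' non-square frames keep their shape.
#'
#' @param image numeric matrix.
#' @param ops operations eligible for sampling.
#' @param seed integer seed.
#' @return augmented matrix.
#' @export
augment <- function(image, ops = c("rot180", "flip_x", "flip_y"), seed = 1L) {
  stopifnot(all(ops %in% c("rot180", "flip_x", "flip_y")))
  chosen <- with_seed(seed, ops[stats::runif(length(ops)) < 0.5])
  apply_augmentation(image, chosen)
}

#' All distinct augmented variants of an image
#'
#' @param image numeric matrix.
#' @return list of the 4 variants reachable by `{rot180, flip_x, flip_y}`
#'   (identity, flip_x, flip_y, rot180); duplicates are not removed, the
#'   four are distinct for a generic asymmetric image.
#' @export
augmentation_variants <- function(image) {
  list(identity = image,
       flip_x = apply_augmentation(image, "flip_x"),
       flip_y = apply_augmentation(image, "flip_y"),
       rot180 = apply_augmentation(image, "rot180"))
}

#' Confusion matrix with row percentages
#'
#' Rows are true classes, columns predicted classes; `row_percent`
#' normalizes each nonempty row to sum to 100.
#'
#' @param true,predicted character vectors of class labels.
#' @param labels ordered class names; defaults to the sorted union.
#' @return object of class `confusion_matrix`: list with `labels`,
#'   integer `counts` and `row_percent`.
#' @export
confusion_matrix <- function(true, predicted,
                             labels = sort(union(true, predicted))) {
  if (length(true) != length(predicted)) {
    stop("true and predicted must have equal length", call. = FALSE)
  }
  counts <- table(factor(true, levels = labels),
                  factor(predicted, levels = labels))
  counts <- matrix(as.integer(counts), length(labels), length(labels),
                   dimnames = list(true = labels, predicted = labels))
  rs <- rowSums(counts)
  row_percent <- counts * 0
  nz <- rs > 0
  row_percent[nz, ] <- 100 * counts[nz, , drop = FALSE] / rs[nz]
  structure(list(labels = labels, counts = counts, row_percent = row_percent),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> row-normalized percentages (rows = true):\n")
  print(round(x$row_percent, 1))
  invisible(x)
}

#' Held-out-slide true-positive rates from joint predictions
#'
#' Given true and predicted four-class labels (`SIZE_DIET` strings), the
#' three rates reported for a held-out slide: the fraction of frames with
#' both factors correct, with the diet factor correct, and with the size
#' factor correct. Joint correctness implies each marginal, so
#' `joint <= min(diet, size)`.
#'
#' @param true,predicted character vectors of joint class labels such as
#'   `"SGA_HF"`.
#' @return named numeric vector `c(joint =, diet =, size =)`.
#' @export
holdout_rates <- function(true, predicted) {
  if (length(true) != length(predicted) || !length(true)) {
    stop("true and predicted must be equal-length, non-empty", call. = FALSE)
  }
  split_lab <- function(x) do.call(rbind, strsplit(x, "_"))
  t <- split_lab(true); p <- split_lab(predicted)
  c(joint = mean(true == predicted),
    diet = mean(t[, 2] == p[, 2]),
    size = mean(t[, 1] == p[, 1]))
}
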