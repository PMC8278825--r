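make_items <- function(n_per_class, slides_per_class = 2) {
  classes <- c("AGA_CON", "AGA_HF", "SGA_CON", "SGA_HF")
  items <- do.call(rbind, lapply(classes, function(cl) {
    parts <- strsplit(cl, "_")[[1]]
    data.frame(id = paste0(cl, "_", seq_len(n_per_class)), size = parts[1],
               diet = parts[2], class = cl,
               slide = paste0(cl, "_s", (seq_len(n_per_class) - 1) %% slides_per_class + 1),
               stringsAsFactors = FALSE)
  }))
  list(items = items)
}

test_that("dataset splits are exact, reproducible and disjoint", {
  ds <- make_items(25)   # 100 items
  sp <- split_dataset(ds, 60, 20, 20, seed = 1)
  expect_equal(as.vector(table(factor(sp$items$split,
                                      c("train", "val", "test")))),
               c(60L, 20L, 20L))
  sp2 <- split_dataset(ds, 60, 20, 20, seed = 1)
  expect_identical(sp$items$split, sp2$items$split)
  sp3 <- split_dataset(ds, 60, 20, 20, seed = 2)
  expect_false(identical(sp$items$split, sp3$items$split))
  expect_error(split_dataset(ds, 90, 20, 20, seed = 1), "exceed")
})

test_that("stratified splits balance the four classes exactly when divisible", {
  ds <- make_items(100)   # balanced 400
  sp <- split_dataset(ds, 200, 100, 100, seed = 3, stratify = TRUE)
  tab <- table(sp$items$class, sp$items$split)
  expect_true(all(tab[, "train"] == 50))
  expect_true(all(tab[, "val"] == 25))
  expect_true(all(tab[, "test"] == 25))
})

test_that("augmentations are shape-preserving pixel permutations", {
  img <- matrix(1:6, 2, 3)
  expect_identical(apply_augmentation(apply_augmentation(img, "flip_x"), "flip_x"), img)
  expect_identical(apply_augmentation(apply_augmentation(img, "flip_y"), "flip_y"), img)
  expect_identical(apply_augmentation(img, c("flip_x", "flip_y")),
                   apply_augmentation(img, "rot180"))
  set.seed(8)
  big <- matrix(runif(35), 5, 7)
  for (op in c("rot180", "flip_x", "flip_y")) {
    out <- apply_augmentation(big, op)
    expect_equal(dim(out), dim(big))
    expect_equal(sort(as.vector(out)), sort(as.vector(big)))
  }
  # random augmentation draws only group elements
  out <- augment(big, seed = 4)
  variants <- augmentation_variants(big)
  expect_true(any(vapply(variants, identical, logical(1), out)))
})

test_that("an asymmetric frame has exactly four distinct augmented variants", {
  img <- matrix(1:6, 2, 3)
  variants <- augmentation_variants(img)
  keys <- vapply(variants, function(v) paste(v, collapse = ","), character(1))
  expect_length(unique(keys), 4)
  # closure: composing any two generators stays inside the variant set
  ops <- c("rot180", "flip_x", "flip_y")
  for (o1 in ops) for (o2 in ops) {
    out <- apply_augmentation(img, c(o1, o2))
    expect_true(any(vapply(variants, identical, logical(1), out)))
  }
})

test_that("confusion matrices count predictions with row percentages", {
  cm <- confusion_matrix(c("a", "a", "b", "b"), c("a", "b", "b", "b"))
  expect_equal(sum(cm$counts), 4)
  expect_equal(unname(rowSums(cm$row_percent)), c(100, 100), tolerance = 1e-9)
  expect_equal(unname(cm$counts["a", ]), c(1L, 1L))
  # perfect predictor: diagonal
  p <- confusion_matrix(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(unname(diag(p$counts)), rep(1L, 3))
  expect_equal(sum(p$counts) - sum(diag(p$counts)), 0)
  # fixed-class predictor on a balanced 4-class set: one nonzero column
  truth <- rep(c("AGA_CON", "AGA_HF", "SGA_CON", "SGA_HF"), each = 5)
  cmf <- confusion_matrix(truth, rep("SGA_CON", 20))
  expect_equal(mean(truth == "SGA_CON"), 0.25)
  expect_equal(unname(colSums(cmf$counts)), c(0L, 0L, 20L, 0L))
  expect_error(confusion_matrix(c("a", "b"), "a"), "equal length")
})

test_that("held-out rates decompose joint and marginal correctness", {
  expect_equal(holdout_rates(rep("SGA_HF", 4), rep("SGA_HF", 4)),
               c(joint = 1, diet = 1, size = 1))
  # always Control-SGA on a Diet-SGA slide
  expect_equal(holdout_rates(rep("SGA_HF", 10), rep("SGA_CON", 10)),
               c(joint = 0, diet = 0, size = 1))
  # joint <= min(diet, size) for arbitrary prediction vectors
  classes <- c("AGA_CON", "AGA_HF", "SGA_CON", "SGA_HF")
  set.seed(13)
  for (i in 1:10) {
    truth <- sample(classes, 30, replace = TRUE)
    pred <- sample(classes, 30, replace = TRUE)
    r <- holdout_rates(truth, pred)
    expect_lte(r["joint"], min(r["diet"], r["size"]))
  }
})

test_that("training is seeded, records history and can overfit one batch", {
  p <- tiny_params(diet_effect = 2, seed = 31)
  ds <- generate_labeled_dataset(p, n_per_class = 12, seed = 31)
  ds <- split_dataset(ds, 32, 8, 8, seed = 32, stratify = TRUE)
  cfg <- classifier_config(task = "diet", epochs = 3, seed = 33)
  m1 <- train_classifier(ds, cfg)
  m2 <- train_classifier(ds, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$layers, m2$layers)
  expect_equal(nrow(m1$history), 3)
  expect_true(all(m1$history$train_acc >= 0 & m1$history$train_acc <= 1))
  expect_true(all(is.finite(m1$history$val_loss)))
  # one-batch overfit: 8 images memorized
  dsb <- generate_labeled_dataset(tiny_params(seed = 35), n_per_class = 3, seed = 35)
  dsb$items$split <- c(rep("train", 8), rep("val", 4))
  mb <- train_classifier(dsb, classifier_config(task = "joint", epochs = 200,
                                                batch_size = 8,
                                                learning_rate = 0.01, seed = 36))
  expect_equal(tail(mb$history$train_acc, 1), 1.0)
  expect_error(train_classifier(list(items = ds$items[0, ], images = list()),
                                cfg), "split")
})

test_that("evaluation reports accuracy, loss and a consistent confusion matrix", {
  p <- tiny_params(diet_effect = 2.5, seed = 41)
  ds <- generate_labeled_dataset(p, n_per_class = 15, seed = 41)
  ds <- split_dataset(ds, 40, 10, 10, seed = 42, stratify = TRUE)
  m <- train_classifier(ds, classifier_config(task = "diet", epochs = 6, seed = 43))
  ev <- evaluate(m, ds, "test")
  expect_gte(ev$accuracy, 0)
  expect_lte(ev$accuracy, 1)
  expect_equal(sum(ev$confusion$counts), 10)
  expect_equal(ev$accuracy,
               sum(diag(ev$confusion$counts)) / sum(ev$confusion$counts))
  rp <- rowSums(ev$confusion$row_percent)
  expect_true(all(abs(rp[rowSums(ev$confusion$counts) > 0] - 100) < 1e-9))
  expect_error(evaluate(m, ds, "nope"), "no items")
})

test_that("held-out slide evaluation rejects leaked slides", {
  p <- tiny_params(diet_effect = 2, size_effect = 2, seed = 51)
  ds <- generate_labeled_dataset(p, n_per_class = 10, seed = 51,
                                 slides_per_class = 2)
  holdout <- "SGA_HF_s2"
  ds$items$split <- ifelse(ds$items$slide == holdout, "unused",
                           rep(c("train", "train", "train", "val"),
                               length.out = nrow(ds$items)))
  m <- train_classifier(ds, classifier_config(task = "joint", epochs = 4, seed = 52))
  r <- evaluate_holdout_slide(m, ds, holdout)
  expect_named(r, c("joint", "diet", "size"))
  expect_lte(r["joint"], min(r["diet"], r["size"]))
  expect_error(evaluate_holdout_slide(m, ds, "AGA_CON_s1"), "leaked")
  expect_error(evaluate_holdout_slide(m, ds, "NO_SUCH"), "not present")
  dm <- train_classifier(ds, classifier_config(task = "diet", epochs = 2, seed = 53))
  expect_error(evaluate_holdout_slide(dm, ds, holdout), "joint")
})
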