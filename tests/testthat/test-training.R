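test_that("balanced inverse-frequency class weights match hand arithmetic", {
  w <- class_weights(c(ARR = 96, CHF = 30, NSR = 36))
  expect_equal(w, c(ARR = 0.5625, CHF = 1.8, NSR = 1.5))
  expect_equal(class_weights(c(A = 10, B = 10, C = 10)),
               c(A = 1, B = 1, C = 1))
  expect_error(class_weights(c(A = 5)), "at least two")
  expect_error(class_weights(c(A = 5, B = 0)), "> 0")
})

test_that("stratified split preserves class proportions with round-to-nearest", {
  manifest <- tibble::tibble(
    record_id = sprintf("r%03d", 1:162),
    label = rep(c("ARR", "CHF", "NSR"), times = c(96, 30, 36)))
  sp <- stratified_split(manifest, 0.7, seed = 1)
  lab <- function(ids) table(factor(manifest$label[match(ids, manifest$record_id)],
                                    levels = ecg_classes()))
  expect_equal(as.integer(lab(sp$test)), c(29L, 9L, 11L))
  expect_equal(as.integer(lab(sp$train)), c(67L, 21L, 25L))
  # disjoint + exhaustive
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), manifest$record_id)
  # determinism
  expect_identical(stratified_split(manifest, 0.7, seed = 1), sp)
  expect_false(identical(stratified_split(manifest, 0.7, seed = 2), sp))
})

test_that("half split of a 2-per-class toy gives one train and one test each", {
  manifest <- tibble::tibble(record_id = sprintf("r%d", 1:6),
                             label = rep(ecg_classes(), each = 2))
  sp <- stratified_split(manifest, 0.5, seed = 3)
  expect_length(sp$train, 3)
  expect_length(sp$test, 3)
  single <- tibble::tibble(record_id = c("a", "b", "c"),
                           label = c("ARR", "ARR", "CHF"))
  expect_error(stratified_split(single, 0.5, seed = 1), "fewer than 2")
})

test_that("stratified k-fold partitions each class evenly", {
  manifest <- tibble::tibble(
    record_id = sprintf("r%03d", 1:162),
    label = rep(c("ARR", "CHF", "NSR"), times = c(96, 30, 36)))
  folds <- stratified_kfold(manifest, k = 5, seed = 2)
  expect_length(folds, 5)
  test_ids <- unlist(lapply(folds, `[[`, "test"))
  expect_equal(sort(test_ids), sort(manifest$record_id))  # exhaustive, no dups
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    counts <- table(factor(manifest$label[match(f$test, manifest$record_id)],
                           levels = ecg_classes()))
    expect_equal(as.integer(counts[["CHF"]]), 6L)  # 30 / 5 exactly
    expect_true(all(abs(counts - c(96, 30, 36) / 5) <= 1))
  }
  expect_error(stratified_kfold(manifest[1:100, ], k = 40, seed = 1), "fewer than k")
})

test_that("leave-one-out on a balanced toy yields singleton test folds", {
  manifest <- tibble::tibble(record_id = sprintf("r%d", 1:6),
                             label = rep(ecg_classes(), each = 2))
  folds <- stratified_kfold(manifest, k = 2, seed = 1)
  expect_true(all(vapply(folds, function(f) length(f$test), 0L) == 3L))
})

test_that("head training is seeded-deterministic and records its history", {
  imgs <- toy_images(9)
  m <- toy_model(alpha = 0.6)
  f <- compute_branch_features(m, imgs)
  cfg <- train_config(epochs = 20, batch_size = 4, seed = 7)
  m1 <- train_model(m, f, cfg)
  m2 <- train_model(m, f, cfg)
  expect_length(m1$history, 20)
  expect_equal(m1$history[20], m2$history[20], tolerance = 1e-6)
  expect_identical(m1$head, m2$head)
  expect_error(train_config(epochs = 0), "epochs")
})

test_that("class weighting reduces to unweighted loss on balanced data", {
  imgs <- toy_images(6)  # 2 per class
  m <- toy_model()
  f <- compute_branch_features(m, imgs)
  cfg_w <- train_config(epochs = 5, batch_size = 6, seed = 3, class_weighting = TRUE)
  cfg_u <- train_config(epochs = 5, batch_size = 6, seed = 3, class_weighting = FALSE)
  m_w <- train_model(m, f, cfg_w)
  m_u <- train_model(m, f, cfg_u)
  expect_equal(m_w$history, m_u$history, tolerance = 1e-12)
})

test_that("evaluation computes trace-over-total accuracy and per-class metrics", {
  # perfect diagonal
  ev <- ecgblend:::eval_result(rep(ecg_classes(), each = 10),
                               rep(ecg_classes(), each = 10))
  expect_equal(ev$accuracy, 1)
  # hand-built confusion [[5,5,0],[0,10,0],[0,0,10]]
  truth <- rep(ecg_classes(), each = 10)
  pred <- c(rep("ARR", 5), rep("CHF", 5), rep("CHF", 10), rep("NSR", 10))
  ev <- ecgblend:::eval_result(truth, pred)
  expect_equal(ev$accuracy, 25 / 30)
  expect_equal(ev$confusion["ARR", "CHF"], 5L)
  # accuracy invariant: equals brute-force recount
  expect_equal(ev$accuracy, mean(pred == truth))
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / sum(ev$confusion))
  g <- glance(ev)
  expect_equal(g$accuracy, 25 / 30)
  td <- tidy(ev)
  expect_equal(td$recall[td$class == "ARR"], 0.5)
  expect_error(ecgblend:::eval_result(character(0), character(0)), "empty")
})
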