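test_that("deep and shallow variants differ by one conv+pool stage", {
  sh <- build_network(architecture_spec("shallow", base_filters = 8,
                                        dense_width = 32), 3, seed = 1)
  dp <- build_network(architecture_spec("deep", base_filters = 8,
                                        dense_width = 32), 3, seed = 1)
  expect_equal(dp$arch$n_conv, sh$arch$n_conv + 1)
  expect_equal(sum(dp$arch$pool_after), sum(sh$arch$pool_after) + 1)
  ## the deep head sees twice the filter count of the shallow head
  last_f <- function(net) nrow(net$weights$convW[[net$arch$n_conv]])
  expect_equal(last_f(dp), 2 * last_f(sh))
  expect_error(build_network(architecture_spec(), 1), ">= 2")
})

test_that("softmax outputs are probabilities for any input", {
  net <- build_network(architecture_spec("shallow", base_filters = 4,
                                         dense_width = 16,
                                         input_size = 32L), 2, seed = 2)
  imgs <- replicate(5, matrix(runif(32 * 32), 32, 32), simplify = FALSE)
  lg <- network_logits(net, imgs)
  expect_equal(dim(lg), c(5L, 2L))
  p <- apply_temperature(lg, 1)
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
})

test_that("front-block filter shapes match whether pretrained or analytic", {
  spec_a <- architecture_spec("deep", base_filters = 8, dense_width = 16,
                              input_size = 32L)
  fw <- list(W1 = matrix(0.1, 8, 9), b1 = rep(0, 8),
             W2 = matrix(0.1, 8, 72), b2 = rep(0, 8))
  spec_b <- architecture_spec("deep", base_filters = 8, dense_width = 16,
                              input_size = 32L, front_weights = fw)
  na <- build_network(spec_a, 2, seed = 1)
  nb <- build_network(spec_b, 2, seed = 1)
  for (i in seq_along(na$weights$convW)) {
    expect_equal(dim(na$weights$convW[[i]]), dim(nb$weights$convW[[i]]))
  }
  expect_equal(nb$weights$convW[[1]], fw$W1)
})

test_that("training is reproducible, freezes the front, and tracks history", {
  ds <- toy_two_class(16, seed = 3)
  sp <- split_dataset(ds, seed = 4)
  spec <- architecture_spec("shallow", base_filters = 4, dense_width = 16)
  net <- build_network(spec, 2, seed = 5)

  m0 <- train_node(net, sp$train, sp$validation, epochs = 0)
  expect_equal(nrow(m0$history), 0)
  expect_identical(m0$weights, net$weights)

  m1 <- train_node(net, sp$train, sp$validation, epochs = 2, seed = 6,
                   augment = NULL)
  m2 <- train_node(net, sp$train, sp$validation, epochs = 2, seed = 6,
                   augment = NULL)
  expect_identical(m1$weights, m2$weights)
  expect_equal(m1$history$val_loss, m2$history$val_loss)
  expect_equal(nrow(m1$history), 2)
  ## frozen front is bit-identical before and after training
  expect_identical(m1$weights$convW[[1]], net$weights$convW[[1]])
  expect_identical(m1$weights$convW[[2]], net$weights$convW[[2]])
  ## trained layers moved
  expect_false(identical(m1$weights$convW[[3]], net$weights$convW[[3]]))
})

test_that("a separable two-class problem is learned to high accuracy", {
  ds <- toy_two_class(40, seed = 7)
  sp <- split_dataset(ds, seed = 8)
  net <- build_network(architecture_spec("shallow", base_filters = 8,
                                         dense_width = 32, dropout = 0.25),
                       2, seed = 9)
  m <- train_node(net, sp$train, sp$validation, epochs = 5, seed = 10,
                  lr = 3e-3, augment = NULL)
  lg <- network_logits(m, sp$test)
  acc <- mean(m$class_order[max.col(lg)] == sp$test$labels)
  expect_gte(acc, 0.95)
})

test_that("hierarchy training covers every node with balanced subsets", {
  cfg <- tiny_taxonomy()
  tree <- build_hierarchy(cfg)
  specs <- list(
    t1 = morphotype_spec("aporate", size_px = c(50, 2), base_intensity = .9),
    a1 = morphotype_spec("triporate", size_px = c(20, 2)),
    a2 = morphotype_spec("vesiculate", size_px = c(30, 2)),
    b1 = morphotype_spec("npp", size_px = c(25, 3), base_intensity = .4),
    b2 = morphotype_spec("tricolpate", size_px = c(36, 2))
  )
  ds <- generate_dataset(specs, c(t1 = 12, a1 = 12, a2 = 8, b1 = 12,
                                  b2 = 12), seed = 11)
  sp <- split_dataset(ds, seed = 12)
  models <- train_hierarchy(tree, sp,
                            spec = architecture_spec(base_filters = 4,
                                                     dense_width = 8),
                            epochs = 1, augment = NULL, seed = 13)
  expect_named(models, names(tree$nodes))
  ## the root's training subset was balanced to its smallest pooled class
  expect_s3_class(models[["root"]], "node_model")
  expect_equal(models[["a"]]$class_order, c("a1", "a2"))

  ## class present in the tree but absent from the data: hard error
  ds2 <- ds[ds$labels != "b2"]
  sp2 <- split_dataset(ds2, seed = 12)
  expect_error(train_hierarchy(tree, sp2,
                               spec = architecture_spec(base_filters = 4,
                                                        dense_width = 8),
                               epochs = 1, seed = 13), "b2")
})

test_that("single-node trees train to a one-model map", {
  cfg <- list(nodes = list(list(
    id = "only", name = "Only", level = 1, epochs = 1, fallback = "Unknown",
    architecture = "shallow",
    outputs = list(list(label = "disc"), list(label = "ring")))))
  tree <- build_hierarchy(cfg)
  ds <- toy_two_class(10, seed = 14)
  ds <- image_set(ds$images,
                  ifelse(ds$labels == "disc", "disc", "ring"))
  sp <- split_dataset(ds, seed = 15)
  models <- train_hierarchy(tree, sp,
                            spec = architecture_spec(base_filters = 4,
                                                     dense_width = 8),
                            epochs = 1, augment = NULL, seed = 16)
  expect_length(models, 1)
  expect_equal(models[["only"]]$node_id, "only")
})
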