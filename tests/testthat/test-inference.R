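# Routing semantics are exercised with stub models that emit prescribed
# confidences, so thresholds and fallbacks are tested independently of any
# trained weights.

test_that("abstention at the root yields the unknown label", {
  tree <- build_hierarchy(tiny_taxonomy())
  models <- default_tree_stubs(tree, conf = 0.99)
  ## root emits max confidence 0.65 -> under tau = 0.7
  models[["root"]] <- const_stub("root", c("t1", "mixA", "mixB"),
                                 c(0.65, 0.2, 0.15))
  pred <- classify_image(tree, models, matrix(0.5, 8, 8))
  expect_equal(pred$final_label, "Unknown")
  expect_true(pred$abstained)
  expect_equal(pred$abstention_level, 1L)
})

test_that("abstention below the root yields the parent-class label", {
  tree <- build_hierarchy(default_taxonomy())
  models <- default_tree_stubs(tree, conf = 0.99)
  ## route Main -> Tricolpate -> Acer confidently, then stall at the Acer
  ## node with max confidence 0.60: the image must still count as Acer
  models[["main"]] <- const_stub(
    "main", vapply(tree$nodes[["main"]]$outputs, `[[`, character(1), "label"),
    c(0.002, 0.002, 0.002, 0.002, 0.99, 0.002))
  models[["tricolpate"]] <- const_stub("tricolpate", c("Quercus", "Acer"),
                                       c(0.05, 0.95))
  models[["acer"]] <- const_stub("acer", c("Acer rubrum", "Acer saccharum"),
                                 c(0.60, 0.40))
  pred <- classify_image(tree, models, matrix(0.5, 8, 8))
  expect_equal(pred$final_label, "Acer")
  expect_true(pred$abstained)
  expect_equal(pred$abstention_level, 3L)
  expect_equal(pred$path$node, c("main", "tricolpate", "acer"))
})

test_that("tau = 0 never abstains and always reaches a terminal", {
  tree <- build_hierarchy(tiny_taxonomy())
  models <- default_tree_stubs(tree, conf = 0.4)   # low confidence everywhere
  terms <- terminal_labels(tree)
  cls <- classify_set(tree, models, blank_images(10),
                      threshold_policy(tau = 0))
  expect_true(all(cls$labels %in% terms))
  expect_equal(under_threshold_rate(cls), 0)
})

test_that("counts are conserved over the enumerated label set", {
  tree <- build_hierarchy(tiny_taxonomy())
  set.seed(5)
  ## random confidences per image: conservation must hold regardless
  models <- list()
  for (id in names(tree$nodes)) {
    classes <- vapply(tree$nodes[[id]]$outputs, `[[`, character(1), "label")
    models[[id]] <- local({
      k <- length(classes)
      stub_model(id, classes, function(n) {
        p <- matrix(stats::rexp(n * k), n, k)
        p / rowSums(p)
      })
    })
  }
  items <- blank_images(40)
  cls <- classify_set(tree, models, items, threshold_policy(0.7))
  expect_equal(sum(cls$counts), 40)
  expect_named(cls$counts, enumerate_labels(tree))
})

test_that("raising tau never decreases the unknown-plus-fallback total", {
  tree <- build_hierarchy(tiny_taxonomy())
  set.seed(11)
  n_img <- 30
  ## per-image, per-node confidences fixed by image identity: image i is a
  ## constant matrix of value i/100, and each stub looks its row up by that
  ## value, so the prediction set is frozen across tau
  items <- image_set(lapply(seq_len(n_img),
                            function(i) matrix(i / 100, 8, 8)),
                     rep("?", n_img), classes = "?")
  models <- list()
  for (id in names(tree$nodes)) {
    classes <- vapply(tree$nodes[[id]]$outputs, `[[`, character(1), "label")
    conf <- matrix(stats::rexp(n_img * length(classes)), n_img)
    conf <- conf / rowSums(conf)
    local({
      cc <- conf
      models[[id]] <<- stub_model(id, classes, NULL)
      models[[id]]$logit_fun <<- function(images) {
        rows <- vapply(images, function(m) round(m[1, 1] * 100), numeric(1))
        log(pmax(cc[rows, , drop = FALSE], 1e-12))
      }
    })
  }
  nonterminal <- setdiff(enumerate_labels(tree), terminal_labels(tree))
  totals <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9, 0.99), function(tau) {
    cls <- classify_set(tree, models, items, threshold_policy(tau))
    sum(cls$counts[nonterminal])
  }, numeric(1))
  expect_true(all(diff(totals) >= 0))
})

test_that("threshold comparison is strict below by default", {
  tree <- build_hierarchy(tiny_taxonomy())
  models <- default_tree_stubs(tree)
  models[["root"]] <- const_stub("root", c("t1", "mixA", "mixB"),
                                 c(0.7, 0.2, 0.1))
  ## exactly at tau: classifies (only falling strictly under abstains)
  pred <- classify_image(tree, models, matrix(0, 4, 4),
                         threshold_policy(0.7, strict = TRUE))
  expect_false(pred$abstained)
  pred2 <- classify_image(tree, models, matrix(0, 4, 4),
                          threshold_policy(0.7, strict = FALSE))
  expect_true(pred2$abstained)
})

test_that("degenerate inputs are handled loudly", {
  tree <- build_hierarchy(tiny_taxonomy())
  models <- default_tree_stubs(tree)
  expect_error(classify_set(tree, models[-1], blank_images(2)), "missing")
  expect_warning(z <- classify_set(tree, models,
                                   image_set(list(), character(0))), "empty")
  expect_equal(sum(z$counts), 0)
})

test_that("classified sequences assemble a conserving counts table", {
  tree <- build_hierarchy(tiny_taxonomy())
  models <- default_tree_stubs(tree, conf = 0.99)
  samples <- list(blank_images(12), blank_images(12))
  counts <- classify_sequence(tree, models, samples, depths = c(5, 10),
                              marker_class = "t1")
  labs <- enumerate_labels(tree)
  expect_equal(unname(rowSums(counts[, labs])), c(12, 12))
  expect_equal(counts$marker_count, counts$t1)
  expect_equal(counts$depth_cm, c(5, 10))
})
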