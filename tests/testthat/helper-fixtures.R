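# Shared in-code fixtures: tiny taxonomies, stub models that drive the
# router with prescribed confidences, and small rendered datasets.

## a 2-level, 3-node tree: root -> {t1, mixA -> {a1, a2}, mixB -> {b1, b2}}
tiny_taxonomy <- function() {
  list(
    unknown_label = "Unknown",
    nodes = list(
      list(id = "root", name = "Root", level = 1, architecture = "deep",
           epochs = 1, fallback = "Unknown",
           outputs = list(list(label = "t1"),
                          list(label = "mixA", child = "a"),
                          list(label = "mixB", child = "b"))),
      list(id = "a", name = "A", level = 2, architecture = "shallow",
           epochs = 1, fallback = "mixA",
           outputs = list(list(label = "a1"), list(label = "a2"))),
      list(id = "b", name = "B", level = 2, architecture = "shallow",
           epochs = 1, fallback = "mixB",
           outputs = list(list(label = "b1"), list(label = "b2")))
    )
  )
}

## stub node model: emits fixed calibrated confidences per image index.
## conf_fun(n) must return an n x K probability matrix.
stub_model <- function(node_id, classes, conf_fun) {
  force(node_id); force(classes); force(conf_fun)
  structure(list(node_id = node_id, class_order = classes, temperature = 1,
                 logit_fun = function(images) {
                   p <- conf_fun(length(images))
                   log(pmax(p, 1e-12))
                 },
                 history = data.frame()),
            class = "node_model")
}

## constant-confidence stub: every image gets the same probability row
const_stub <- function(node_id, classes, probs) {
  force(probs)
  stub_model(node_id, classes,
             function(n) matrix(probs, n, length(probs), byrow = TRUE))
}

blank_images <- function(n, size = 8L) {
  image_set(replicate(n, matrix(0.5, size, size), simplify = FALSE),
            rep("?", n), classes = "?")
}

## stub models for the full default tree: route every image to its true
## terminal with a given confidence at each node (used by routing tests)
default_tree_stubs <- function(tree, conf = 0.99) {
  models <- list()
  for (id in names(tree$nodes)) {
    classes <- vapply(tree$nodes[[id]]$outputs, `[[`, character(1), "label")
    p <- rep((1 - conf) / (length(classes) - 1), length(classes))
    p[1] <- conf
    models[[id]] <- const_stub(id, classes, p)
  }
  models
}

## a quickly separable two-class set: large bright discs vs small dim rings
toy_two_class <- function(n_per_class = 30, seed = 1) {
  specs <- list(
    disc = morphotype_spec("aporate", size_px = c(48, 2),
                           base_intensity = 0.9, texture_amp = 0.02),
    ring = morphotype_spec("npp", size_px = c(20, 2),
                           base_intensity = 0.4, texture_amp = 0.05)
  )
  generate_dataset(specs, n_per_class, seed = seed)
}
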