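# Per-node network construction and training.
#
# Every node of the hierarchy carries one small VGG-style network: a frozen
# transfer front block (conv, conv, maxpool), a trained common core of two
# conv-conv-pool blocks with filters doubling after each pool, an optional
# extra conv+pool stage (the deep variant, doubling the head's input filter
# count), and a dropout -> flatten -> dense -> softmax head. The numeric
# engine lives in compiled code; training is bit-reproducible given a seed.

#' Architecture specification for a node network
#'
#' @param variant `"shallow"` or `"deep"`. The deep variant appends one
#'   convolutional layer and one max-pooling layer to the shared core,
#'   doubling the filter count entering the fully connected head.
#' @param base_filters Filters in the front block (the core doubles them
#'   after each pooling stage). Default 64.
#' @param dense_width Width of the fully connected hidden layer. Default 256.
#' @param dropout Dropout rate of the head (default 0.5).
#' @param input_size Input image side (default 128; grayscale, 1 channel).
#' @param front_weights Optional list with `W1, b1, W2, b2` giving
#'   externally pretrained front-block convolution weights (e.g. the first
#'   block of a large published image network) with shapes
#'   `f x 9`, `f`, `f x 9f`, `f`. When `NULL` the front block is randomly
#'   initialized with identical shapes. In either case it is frozen.
#' @return An `architecture_spec` object.
#' @export
architecture_spec <- function(variant = c("deep", "shallow"),
                              base_filters = 64, dense_width = 256,
                              dropout = 0.5, input_size = 128L,
                              front_weights = NULL) {
  variant <- match.arg(variant)
  stopifnot(base_filters >= 8 || base_filters >= 2,  # >=2 for toy tests
            dropout >= 0, dropout < 1, input_size %% 16 == 0)
  structure(list(variant = variant, base_filters = as.integer(base_filters),
                 dense_width = as.integer(dense_width), dropout = dropout,
                 input_size = as.integer(input_size),
                 front_weights = front_weights),
            class = "architecture_spec")
}

## conv layer plan: (in, out, pooled?) per conv, front first
conv_plan <- function(spec) {
  f <- spec$base_filters
  plan <- list(
    list(f_in = 1L, f_out = f,      pool = FALSE),  # front (frozen)
    list(f_in = f,  f_out = f,      pool = TRUE),   # front (frozen)
    list(f_in = f,  f_out = f,      pool = FALSE),  # core block 1
    list(f_in = f,  f_out = f,      pool = TRUE),
    list(f_in = f,  f_out = 2L * f, pool = FALSE),  # core block 2
    list(f_in = 2L * f, f_out = 2L * f, pool = TRUE)
  )
  if (spec$variant == "deep") {
    plan <- c(plan, list(list(f_in = 2L * f, f_out = 4L * f, pool = TRUE)))
  }
  plan
}

#' Build an untrained node network
#'
#' Initializes all weights (He-normal) from `seed`. The front block is
#' frozen: training never updates it, so its weights are bit-identical
#' before and after [train_node()].
#'
#' @param spec An [architecture_spec()].
#' @param n_classes Number of softmax outputs (>= 2).
#' @param seed Integer seed for weight initialization.
#' @return A `node_network` object.
#' @export
build_network <- function(spec, n_classes, seed = 1L) {
  stopifnot(inherits(spec, "architecture_spec"))
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  local_seed(seed)
  plan <- conv_plan(spec)
  he <- function(nrow, ncol) {
    matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / ncol)), nrow, ncol)
  }
  convW <- lapply(plan, function(p) he(p$f_out, 9L * p$f_in))
  convB <- lapply(plan, function(p) numeric(p$f_out))
  if (!is.null(spec$front_weights)) {
    fw <- spec$front_weights
    stopifnot(all(dim(fw$W1) == dim(convW[[1]])),
              all(dim(fw$W2) == dim(convW[[2]])))
    convW[[1]] <- fw$W1; convB[[1]] <- as.numeric(fw$b1)
    convW[[2]] <- fw$W2; convB[[2]] <- as.numeric(fw$b2)
  } else {
    ## analytic frozen front: a fixed bank of oriented-derivative /
    ## smoothing / centre-surround filters (the features the first block of
    ## a large pretrained image network converges to), signed pairs so the
    ## ReLU keeps both polarities; the second conv passes each map through.
    fb <- front_filter_bank(spec$base_filters)
    convW[[1]] <- fb
    w2 <- matrix(0, spec$base_filters, 9L * spec$base_filters)
    for (o in seq_len(spec$base_filters)) w2[o, (o - 1L) * 9L + 5L] <- 1
    convW[[2]] <- w2
  }
  n_pool <- sum(vapply(plan, `[[`, logical(1), "pool"))
  side <- spec$input_size / 2^n_pool
  flat <- as.integer(side^2 * plan[[length(plan)]]$f_out)
  weights <- list(
    convW = convW, convB = convB,
    W1 = he(spec$dense_width, flat), b1 = numeric(spec$dense_width),
    W2 = he(n_classes, spec$dense_width), b2 = numeric(n_classes)
  )
  arch <- list(n_conv = length(plan), n_frozen = 2L,
               pool_after = vapply(plan, `[[`, logical(1), "pool"),
               dense_width = spec$dense_width, n_classes = as.integer(n_classes))
  structure(list(spec = spec, arch = arch, weights = weights,
                 n_classes = as.integer(n_classes)),
            class = "node_network")
}

## fixed 3x3 filter bank for the frozen front block. Rows (filters) cycle
## through: Gaussian smooth, +/- horizontal and vertical derivatives,
## +/- Laplacian (centre-surround), +/- diagonal derivatives.
front_filter_bank <- function(n_filters) {
  g  <- c(1, 2, 1, 2, 4, 2, 1, 2, 1) / 16
  sx <- c(-1, -2, -1, 0, 0, 0, 1, 2, 1) / 4
  sy <- c(-1, 0, 1, -2, 0, 2, -1, 0, 1) / 4
  lp <- c(0, -1, 0, -1, 4, -1, 0, -1, 0) / 4
  d1 <- c(-2, -1, 0, -1, 0, 1, 0, 1, 2) / 4
  d2 <- c(0, 1, 2, -1, 0, 1, -2, -1, 0) / 4
  bank <- unname(rbind(g, sx, -sx, sy, -sy, lp, -lp, d1, -d1, d2, -d2))
  bank[rep(seq_len(nrow(bank)), length.out = n_filters), , drop = FALSE]
}

#' @export
print.node_network <- function(x, ...) {
  cat("<node_network> ", x$spec$variant, ", ", x$arch$n_conv,
      " conv layers (2 frozen), ", x$n_classes, " classes\n", sep = "")
  invisible(x)
}

images_to_cube <- function(images) {
  if (inherits(images, "image_set")) images <- images$images
  if (is.matrix(images)) images <- list(images)
  array(unlist(images, use.names = FALSE),
        dim = c(dim(images[[1]]), length(images)))
}

#' Raw (uncalibrated) logits of a network on a batch of images
#'
#' A model carrying a `logit_fun` field (a function of an image list
#' returning an n x K matrix) is evaluated through it instead of the
#' compiled network — the hook routing tests use to drive the hierarchy
#' with prescribed confidences.
#'
#' @param network A `node_network` or trained `node_model`.
#' @param images An `image_set`, list of matrices, or single matrix.
#' @return n x K matrix of logits.
#' @export
network_logits <- function(network, images) {
  if (inherits(images, "image_set")) images <- images$images
  if (is.matrix(images)) images <- list(images)
  if (!is.null(network$logit_fun)) {
    out <- network$logit_fun(images)
    stopifnot(nrow(out) == length(images))
    return(out)
  }
  cpp_cnn_logits(network$weights, images_to_cube(images), network$arch)
}

#' Train one node network
#'
#' Minibatch Adam on softmax cross-entropy. Each epoch the training stream
#' is re-augmented (rotation/shear/brightness; see [augment_batch()]) and
#' reshuffled; validation images pass through untransformed. The weights
#' with the best validation accuracy (validation loss breaking ties) are
#' retained. With `epochs = 0` the
#' untrained network is returned with an empty history.
#'
#' @param network A `node_network` from [build_network()].
#' @param train An `image_set` (balanced upstream; see [balance_classes()]).
#' @param validation An `image_set`, disjoint from `train`.
#' @param epochs Number of epochs.
#' @param batch Minibatch size (default 32).
#' @param lr Adam learning rate (default 1e-3).
#' @param lr_decay Multiplicative per-epoch learning-rate decay (default
#'   0.85; 1 = constant rate). Damps the late-epoch oscillation typical of
#'   Adam on small balanced sets.
#' @param augment An [augmentation_config()] or `NULL` for none.
#' @param seed Integer seed; a fixed seed reproduces the run exactly.
#' @param classes Output label order; defaults to sorted unique train labels.
#' @param node_id Optional node identifier stored on the model.
#' @param restarts Number of independent training runs (fresh weight
#'   initialization and stream seeds); the run with the best validation
#'   accuracy is kept. Default 1.
#' @param verbose Print per-epoch losses.
#' @return A `node_model`: weights, class order, calibration temperature
#'   (`temperature = 1` until calibrated), and a `history` data frame with
#'   per-epoch train loss, validation loss and validation accuracy.
#' @export
train_node <- function(network, train, validation, epochs, batch = 32L,
                       lr = 1e-3, lr_decay = 0.85,
                       augment = augmentation_config(),
                       seed = 1L, classes = NULL, node_id = NULL,
                       restarts = 1L, verbose = FALSE) {
  stopifnot(inherits(network, "node_network"), inherits(train, "image_set"))
  if (restarts > 1L) {
    runs <- lapply(seq_len(restarts), function(r) {
      net_r <- if (r == 1L) network else {
        build_network(network$spec, network$n_classes,
                      seed = seed + 7919L * (r - 1L))
      }
      train_node(net_r, train, validation, epochs = epochs, batch = batch,
                 lr = lr, lr_decay = lr_decay, augment = augment,
                 seed = seed + 104729L * (r - 1L), classes = classes,
                 node_id = node_id, restarts = 1L, verbose = verbose)
    })
    scores <- vapply(runs, function(m) {
      if (nrow(m$history)) max(m$history$val_acc) else -1
    }, numeric(1))
    return(runs[[which.max(scores)]])
  }
  if (is.null(classes)) classes <- sort(unique(train$labels))
  if (length(classes) != network$n_classes) {
    stop("network has ", network$n_classes, " outputs but ", length(classes),
         " classes supplied", call. = FALSE)
  }
  missing_cl <- setdiff(classes, unique(train$labels))
  if (length(missing_cl)) {
    stop("class(es) with no training data: ",
         paste(missing_cl, collapse = ", "), call. = FALSE)
  }
  y <- as.integer(factor(train$labels, levels = classes)) - 1L
  yval <- as.integer(factor(validation$labels, levels = classes)) - 1L
  Xval <- images_to_cube(validation)

  model <- structure(list(node_id = node_id, spec = network$spec,
                          arch = network$arch, weights = network$weights,
                          class_order = classes, temperature = 1,
                          history = data.frame()),
                     class = "node_model")
  if (epochs == 0) return(model)

  local_seed(seed)
  n <- length(train)
  weights <- network$weights
  n_tr <- network$arch$n_conv - network$arch$n_frozen
  zeros_like <- function(x) {
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else matrix(0, length(x), 1)
  }
  shapes <- c(unlist(lapply(seq_len(n_tr), function(t) {
    i <- network$arch$n_frozen + t
    list(weights$convW[[i]], weights$convB[[i]])
  }), recursive = FALSE), list(weights$W1, weights$b1, weights$W2, weights$b2))
  adam <- list(m = lapply(shapes, zeros_like), v = lapply(shapes, zeros_like),
               t = 0L)

  best <- list(val_loss = Inf, val_acc = -1, weights = weights)
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ep_seed <- sample.int(.Machine$integer.max - 1L, 2L)
    tr_images <- if (is.null(augment)) train else {
      augment_batch(train, augment, seed = ep_seed[1])
    }
    X <- images_to_cube(tr_images)
    ord <- sample.int(n) - 1L
    res <- cpp_cnn_epoch(weights, adam, X, y, network$arch, ord,
                         as.integer(batch), lr * lr_decay^(ep - 1),
                         network$spec$dropout,
                         as.integer(ep_seed[2] %% .Machine$integer.max))
    weights <- res$weights
    adam <- res$adam
    vl <- cpp_cnn_logits(weights, Xval, network$arch)
    vp <- softmax_rows(vl)
    val_loss <- mean(-log(pmax(vp[cbind(seq_len(nrow(vp)), yval + 1L)], 1e-12)))
    val_acc <- mean(max.col(vp) == yval + 1L)
    hist[[ep]] <- data.frame(epoch = ep, train_loss = res$loss,
                             val_loss = val_loss, val_acc = val_acc)
    if (verbose) {
      message(sprintf("  epoch %d/%d  train %.4f  val %.4f  acc %.3f",
                      ep, epochs, res$loss, val_loss, val_acc))
    }
    ## checkpoint rule: best validation accuracy, validation loss as the
    ## tiebreak (accuracy is what the assembled hierarchy is scored on)
    if (val_acc > best$val_acc ||
        (val_acc == best$val_acc && val_loss < best$val_loss)) {
      best <- list(val_loss = val_loss, val_acc = val_acc, weights = weights)
    }
  }
  model$weights <- best$weights
  model$history <- do.call(rbind, hist)
  model
}

#' @export
print.node_model <- function(x, ...) {
  cat("<node_model> ", x$node_id %||% "(anonymous)", ": ",
      length(x$class_order), " classes, T = ", signif(x$temperature, 4), sep = "")
  if (nrow(x$history)) {
    cat(", best val loss ", signif(min(x$history$val_loss), 4), sep = "")
  }
  cat("\n")
  invisible(x)
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

## terminal labels covered by each output slot of a node
slot_label_map <- function(tree, node_id) {
  nd <- tree$nodes[[node_id]]
  out <- list()
  for (slot in nd$outputs) {
    covered <- if (is.null(slot$child)) slot$label else {
      sub <- character(0)
      walk <- function(id) {
        for (s in tree$nodes[[id]]$outputs) {
          if (is.null(s$child)) sub <<- c(sub, s$label) else walk(s$child)
        }
      }
      walk(slot$child)
      sub
    }
    out[[slot$label]] <- covered
  }
  out
}

## relabel a terminal-labelled set to one node's output classes, dropping
## images not under this node
node_subset <- function(tree, node_id, items) {
  map <- slot_label_map(tree, node_id)
  lab <- rep(NA_character_, length(items))
  for (slot_label in names(map)) {
    lab[items$labels %in% map[[slot_label]]] <- slot_label
  }
  keep <- which(!is.na(lab))
  image_set(items$images[keep], lab[keep], classes = names(map))
}

#' Train every node of a hierarchy
#'
#' Each node trains on its own subset of the data: images of all terminal
#' classes under an output slot are pooled and relabelled to that slot's
#' class, the node's training set is balanced to its least populated output
#' class, and the node's own epoch count (from the taxonomy, or the
#' `epochs` override) is used. Labels in `data` must be terminal labels of
#' `tree` (aliases are resolved first).
#'
#' @param tree A `hierarchy_tree`.
#' @param data Named list with `train` and `validation` `image_set`s
#'   (e.g. from [split_dataset()]).
#' @param spec An [architecture_spec()]; its `variant` is overridden
#'   per node by the taxonomy's architecture field.
#' @param epochs Optional override: a single count, or a named vector by
#'   node id. Defaults to each node's taxonomy epoch count.
#' @param batch,lr,augment Passed to [train_node()].
#' @param restarts Independent training runs per node (scalar or named
#'   vector by node id); the best-validation run is kept.
#' @param seed Integer seed (per-node seeds are derived from it).
#' @param verbose Print progress.
#' @return Named list of `node_model`s, one per node id.
#' @export
train_hierarchy <- function(tree, data, spec = architecture_spec(),
                            epochs = NULL, batch = 32L, lr = 1e-3,
                            lr_decay = 0.95,
                            augment = augmentation_config(), seed = 1L,
                            restarts = 1L, verbose = FALSE) {
  stopifnot(inherits(tree, "hierarchy_tree"))
  train <- data$train
  validation <- data$validation
  train$labels <- resolve_aliases(train$labels, tree)
  validation$labels <- resolve_aliases(validation$labels, tree)
  terms <- terminal_labels(tree)
  missing_cl <- setdiff(terms, unique(train$labels))
  if (length(missing_cl)) {
    stop("terminal class(es) in the tree but absent from the data: ",
         paste(missing_cl, collapse = ", "), call. = FALSE)
  }
  local_seed(seed)
  node_seeds <- sample.int(.Machine$integer.max - 1L,
                           2L * length(tree$nodes))
  models <- list()
  for (i in seq_along(tree$nodes)) {
    id <- names(tree$nodes)[i]
    nd <- tree$nodes[[id]]
    tr <- balance_classes(node_subset(tree, id, train),
                          seed = node_seeds[2L * i - 1L])
    va <- node_subset(tree, id, validation)
    ep <- if (is.null(epochs)) nd$epochs
          else if (!is.null(names(epochs))) {
            if (id %in% names(epochs)) as.integer(epochs[[id]]) else nd$epochs
          } else as.integer(epochs)
    nspec <- spec
    nspec$variant <- nd$architecture
    net <- build_network(nspec, n_classes = length(nd$outputs),
                         seed = node_seeds[2L * i])
    if (verbose) {
      message("training node '", id, "' (", nd$architecture, ", ",
              length(tr), " images, ", ep, " epochs)")
    }
    rs <- if (!is.null(names(restarts))) {
      if (id %in% names(restarts)) as.integer(restarts[[id]]) else 1L
    } else as.integer(restarts)
    models[[id]] <- train_node(net, tr, va, epochs = ep, batch = batch,
                               lr = lr, lr_decay = lr_decay,
                               augment = augment,
                               seed = node_seeds[2L * i],
                               classes = names(slot_label_map(tree, id)),
                               node_id = id, restarts = rs,
                               verbose = verbose)
  }
  models
}
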