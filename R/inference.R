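# Top-down routing through the calibrated hierarchy with abstention.
#
# An image enters the root node. At each node the calibrated probabilities
# are computed; if the maximum falls strictly below the threshold the image
# abstains — to the unknown label at the root, to the node's fallback label
# (the parent taxon) deeper down. Otherwise the image takes the argmax slot:
# a terminal label ends the path, a descend slot continues at the child.

#' Abstention threshold policy
#'
#' @param tau Confidence threshold in `(0,1)`, default 0.7. A prediction
#'   strictly below `tau` abstains ("fell under the threshold"); a
#'   prediction exactly at `tau` classifies. Set `strict = FALSE` to abstain
#'   at `<= tau` instead.
#' @param strict Use strict inequality (default `TRUE`).
#' @return A `threshold_policy` object.
#' @export
threshold_policy <- function(tau = 0.7, strict = TRUE) {
  stopifnot(tau >= 0, tau < 1)
  structure(list(tau = tau, strict = strict), class = "threshold_policy")
}

below_threshold <- function(p, policy) {
  if (policy$strict) p < policy$tau else p <= policy$tau
}

#' Classify one image through the hierarchy
#'
#' @param tree A `hierarchy_tree`.
#' @param models Named list of calibrated `node_model`s covering every node.
#' @param image 128x128 numeric matrix (normalized; see
#'   [normalize_image()]).
#' @param policy A [threshold_policy()].
#' @return A `prediction` object: `final_label`, `abstained`,
#'   `abstention_level` (`NA` if none), `confidence` (minimum calibrated
#'   confidence along the path, for audit), and `path` (data frame of node,
#'   chosen output, confidence).
#' @export
classify_image <- function(tree, models, image, policy = threshold_policy()) {
  missing_m <- setdiff(names(tree$nodes), names(models))
  if (length(missing_m)) {
    stop("missing node model(s): ", paste(missing_m, collapse = ", "),
         call. = FALSE)
  }
  classify_batch(tree, models, image_set(list(image), "?", classes = "?"),
                 policy)[[1]]
}

## vectorized routing: batches all images at one node per call
classify_batch <- function(tree, models, items, policy) {
  n <- length(items)
  preds <- vector("list", n)
  state <- data.frame(idx = seq_len(n))
  route <- function(node_id, idx, paths) {
    m <- models[[node_id]]
    logits <- network_logits(m, items$images[idx])
    probs <- apply_temperature(logits, m$temperature)
    if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1)
    colnames(probs) <- m$class_order
    top <- max.col(probs, ties.method = "first")
    conf <- probs[cbind(seq_along(idx), top)]
    lab <- m$class_order[top]
    nd <- tree$nodes[[node_id]]
    level <- nd$level
    for (k in seq_along(idx)) {
      i <- idx[k]
      step <- data.frame(node = node_id, output = lab[k],
                         confidence = conf[k])
      paths_i <- rbind(paths[[k]], step)
      if (below_threshold(conf[k], policy)) {
        final <- if (level == 1L) tree$unknown_label else nd$fallback
        preds[[i]] <<- new_prediction(final, TRUE, level, paths_i)
      } else {
        slot <- nd$outputs[[top[k]]]
        if (is.null(slot$child)) {
          preds[[i]] <<- new_prediction(slot$label, FALSE, NA_integer_,
                                        paths_i)
        }
        ## descend handled below in batch
      }
    }
    ## batch-descend per child
    for (ci in seq_along(nd$outputs)) {
      slot <- nd$outputs[[ci]]
      if (is.null(slot$child)) next
      go <- which(top == ci & !below_threshold(conf, policy))
      if (!length(go)) next
      sub_paths <- lapply(go, function(k) {
        rbind(paths[[k]], data.frame(node = node_id, output = lab[k],
                                     confidence = conf[k]))
      })
      route(slot$child, idx[go], sub_paths)
    }
  }
  route(tree$root, seq_len(n), rep(list(NULL), n))
  preds
}

new_prediction <- function(final_label, abstained, level, path) {
  structure(list(final_label = final_label, abstained = abstained,
                 abstention_level = if (abstained) level else NA_integer_,
                 confidence = min(path$confidence), path = path),
            class = "prediction")
}

#' @export
print.prediction <- function(x, ...) {
  cat("<prediction> ", x$final_label,
      if (x$abstained) paste0(" (abstained at level ", x$abstention_level, ")"),
      sprintf("  [min path confidence %.3f]\n", x$confidence), sep = "")
  invisible(x)
}

#' Classify an image set and tally a counts row
#'
#' Routes every image through the hierarchy and tallies final labels over
#' [enumerate_labels()]. Conservation holds by construction: every image
#' contributes exactly one count to exactly one label.
#'
#' @param tree A `hierarchy_tree`.
#' @param models Named list of calibrated `node_model`s.
#' @param items An `image_set` (labels, if any, are ignored).
#' @param policy A [threshold_policy()].
#' @return A `classified_set`: list with `predictions` (list of
#'   `prediction`), `labels` (character vector of final labels), `counts`
#'   (named integer vector over [enumerate_labels()]) and
#'   `under_threshold` (fraction abstained).
#' @export
classify_set <- function(tree, models, items, policy = threshold_policy()) {
  missing_m <- setdiff(names(tree$nodes), names(models))
  if (length(missing_m)) {
    stop("missing node model(s): ", paste(missing_m, collapse = ", "),
         call. = FALSE)
  }
  labs <- enumerate_labels(tree)
  if (length(items) == 0) {
    warning("empty image set: returning a zero counts row")
    return(structure(list(predictions = list(), labels = character(0),
                          counts = stats::setNames(integer(length(labs)), labs),
                          under_threshold = NA_real_),
                     class = "classified_set"))
  }
  preds <- classify_batch(tree, models, items, policy)
  labels <- vapply(preds, `[[`, character(1), "final_label")
  counts <- table(factor(labels, levels = labs))
  structure(list(predictions = preds, labels = labels,
                 counts = stats::setNames(as.integer(counts), labs),
                 under_threshold = mean(vapply(preds, `[[`, logical(1),
                                               "abstained"))),
            class = "classified_set")
}

#' @export
print.classified_set <- function(x, ...) {
  cat("<classified_set> ", length(x$predictions), " images, ",
      sprintf("%.1f%% under threshold\n", 100 * x$under_threshold), sep = "")
  print(x$counts[x$counts > 0])
  invisible(x)
}

#' Classify a whole fossil sequence into a counts table
#'
#' Applies [classify_set()] to each per-depth sample and assembles the
#' counts table consumed by the stratigraphic statistics (percentages,
#' concentration, influx, zonation). The exotic-marker count column is the
#' tally of the marker class.
#'
#' @param tree,models,policy As in [classify_set()].
#' @param samples List of `image_set`s, one per depth.
#' @param depths Numeric depths (cm), one per sample.
#' @param marker_class Label of the exotic marker (default `"Eucalyptus"`).
#' @param volume_cm3 Sample volume(s), recycled.
#' @return A counts data frame (`sample_id`, `depth_cm`, one column per
#'   label of [enumerate_labels()], `marker_count`, `volume_cm3`).
#' @export
classify_sequence <- function(tree, models, samples, depths,
                              policy = threshold_policy(),
                              marker_class = "Eucalyptus", volume_cm3 = 1) {
  stopifnot(length(samples) == length(depths))
  rows <- lapply(samples, function(s) classify_set(tree, models, s, policy))
  counts <- do.call(rbind, lapply(rows, `[[`, "counts"))
  out <- data.frame(sample_id = sprintf("S%03d", seq_along(samples)),
                    depth_cm = depths, check.names = FALSE)
  out <- cbind(out, as.data.frame(counts, check.names = FALSE))
  out$marker_count <- if (marker_class %in% colnames(counts)) {
    as.integer(counts[, marker_class])
  } else 0L
  out$volume_cm3 <- rep_len(volume_cm3, nrow(out))
  attr(out, "under_threshold") <- vapply(rows, `[[`, numeric(1),
                                         "under_threshold")
  out
}
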