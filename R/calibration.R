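# Confidence calibration by temperature scaling.
#
# A single scalar T > 0 divides a node's logits before the softmax. T is
# fitted on the validation split by minimizing negative log-likelihood;
# since z/T is monotone in z for T > 0, the argmax — and hence every
# accuracy metric — is unchanged.

#' Temperature-scaled softmax
#'
#' @param logits Numeric vector (one item) or n x K matrix.
#' @param temperature Scalar `T > 0`.
#' @return Probabilities with the same shape; rows sum to 1.
#' @export
#' @examples
#' apply_temperature(c(2, 0), 2)   # ~ (0.731, 0.269)
apply_temperature <- function(logits, temperature) {
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  if (is.matrix(logits)) softmax_rows(logits / temperature)
  else as.vector(softmax_rows(matrix(logits / temperature, 1)))
}

#' Mean negative log-likelihood of predicted probabilities
#'
#' @param probabilities n x K matrix; each row sums to 1.
#' @param labels True labels: integer column indices (1-based) or a factor/
#'   character vector matching `colnames(probabilities)`.
#' @return Mean of `-log p(true class)`; `Inf` (with a warning) if any true
#'   class has zero probability.
#' @export
negative_log_likelihood <- function(probabilities, labels) {
  probabilities <- as.matrix(probabilities)
  idx <- label_index(labels, probabilities)
  p <- probabilities[cbind(seq_len(nrow(probabilities)), idx)]
  if (any(p <= 0)) {
    warning("zero probability at a true label; NLL is infinite")
    return(Inf)
  }
  mean(-log(p))
}

label_index <- function(labels, probabilities) {
  if (is.numeric(labels)) return(as.integer(labels))
  cn <- colnames(probabilities)
  if (is.null(cn)) stop("character labels need column names on the ",
                        "probability matrix", call. = FALSE)
  idx <- match(as.character(labels), cn)
  if (anyNA(idx)) stop("label not among probability columns: ",
                       paste(unique(labels[is.na(idx)]), collapse = ", "),
                       call. = FALSE)
  idx
}

#' Fit a calibration temperature on validation logits
#'
#' Minimizes the validation NLL of `softmax(logits / T)` over `T` by
#' golden-section search on `log T` in `[log lower, log upper]`
#' (tolerance 1e-4). Accuracy is untouched: scaling preserves each row's
#' argmax.
#'
#' @param logits n x K validation logit matrix.
#' @param labels True labels (indices or characters; see
#'   [negative_log_likelihood()]).
#' @param lower,upper Search range for `T` (defaults 0.01 and 100).
#' @return A `calibration_result`: list with `temperature`, `nll_before`,
#'   `nll_after`, `n`.
#' @export
fit_temperature <- function(logits, labels, lower = 1e-2, upper = 1e2) {
  logits <- as.matrix(logits)
  if (nrow(logits) < 2) stop("need at least 2 validation items", call. = FALSE)
  idx <- label_index(labels, logits)
  if (length(unique(idx)) < 2) {
    stop("degenerate validation set: only one class represented",
         call. = FALSE)
  }
  nll_at <- function(logT) {
    negative_log_likelihood(softmax_rows(logits / exp(logT)), idx)
  }
  opt <- stats::optimize(nll_at, interval = log(c(lower, upper)), tol = 1e-4)
  temperature <- exp(opt$minimum)
  nll_before <- nll_at(0)
  nll_after <- opt$objective
  if (nll_before < nll_after) {   # T = 1 was already optimal within tol
    temperature <- 1
    nll_after <- nll_before
  }
  structure(list(temperature = temperature, nll_before = nll_before,
                 nll_after = nll_after, n = nrow(logits)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> T = %.4g, NLL %.4g -> %.4g (n = %d)\n",
              x$temperature, x$nll_before, x$nll_after, x$n))
  invisible(x)
}

#' Calibrate every node model on the validation split
#'
#' Computes each node's validation logits on its own subset of the
#' validation images (relabelled to the node's output classes) and fits its
#' temperature. Only the validation split is ever used for calibration.
#'
#' @param models Named list of `node_model`s from [train_hierarchy()].
#' @param tree The `hierarchy_tree` the models belong to.
#' @param validation An `image_set` with terminal labels.
#' @return List with `models` (temperatures set) and `results` (data frame:
#'   node, temperature, nll_before, nll_after, n).
#' @export
calibrate_hierarchy <- function(models, tree, validation) {
  validation$labels <- resolve_aliases(validation$labels, tree)
  rows <- list()
  for (id in names(models)) {
    sub <- node_subset(tree, id, validation)
    logits <- network_logits(models[[id]], sub)
    colnames(logits) <- models[[id]]$class_order
    res <- fit_temperature(logits, sub$labels)
    models[[id]]$temperature <- res$temperature
    rows[[id]] <- data.frame(node = id, temperature = res$temperature,
                             nll_before = res$nll_before,
                             nll_after = res$nll_after, n = res$n)
  }
  list(models = models, results = do.call(rbind, c(rows, make.row.names = FALSE)))
}
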