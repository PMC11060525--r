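# Evaluation surfaces: confusion matrices, average per-class accuracy,
# abstention rates, and per-class agreement regressions between two
# prediction sets (e.g. network counts vs analyst counts per sample).

#' Confusion matrix and average per-class accuracy
#'
#' APC (average per-class accuracy) is the macro-average of per-class
#' recall, i.e. the mean of the diagonal of the row-normalized confusion
#' matrix. Classes with no true items are excluded from the mean and
#' reported in `empty_classes`.
#'
#' @param predicted,truth Character vectors (same length), or a
#'   `classified_set` plus its true labels.
#' @param labels Label order; defaults to the sorted union.
#' @return A `confusion_apc` object: `counts` (K x K integer matrix, rows =
#'   truth), `normalized` (row-normalized), `per_class_recall`, `apc`
#'   (in [0,1]) and `empty_classes`.
#' @export
confusion_and_apc <- function(predicted, truth, labels = NULL) {
  if (inherits(predicted, "classified_set")) predicted <- predicted$labels
  if (is.null(labels)) labels <- sort(union(unique(predicted), unique(truth)))
  miss <- setdiff(unique(truth), labels)
  if (length(miss)) {
    stop("truth label(s) absent from label order: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  pf <- factor(predicted, levels = labels)
  tf <- factor(truth, levels = labels)
  counts <- table(truth = tf, predicted = pf)
  rs <- rowSums(counts)
  normalized <- counts / ifelse(rs == 0, 1, rs)
  recall <- ifelse(rs == 0, NA_real_, diag(counts) / rs)
  structure(list(counts = unclass(counts), normalized = unclass(normalized),
                 per_class_recall = stats::setNames(recall, labels),
                 apc = mean(recall, na.rm = TRUE),
                 empty_classes = labels[rs == 0]),
            class = "confusion_apc")
}

#' @export
print.confusion_apc <- function(x, ...) {
  cat(sprintf("<confusion_apc> APC = %.1f%% over %d classes",
              100 * x$apc, sum(!is.na(x$per_class_recall))))
  if (length(x$empty_classes)) {
    cat(" (", length(x$empty_classes), " empty classes excluded)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Fraction of predictions that abstained
#'
#' @param predictions A `classified_set` or a list of `prediction` objects.
#' @return Fraction in `[0,1]`.
#' @export
under_threshold_rate <- function(predictions) {
  if (inherits(predictions, "classified_set")) {
    predictions <- predictions$predictions
  }
  mean(vapply(predictions, `[[`, logical(1), "abstained"))
}

#' Per-class agreement regression between two proportion series
#'
#' For each class, ordinary least squares with intercept of the predicted
#' per-sample proportion on the reference proportion, with a two-sided
#' t-test of slope = 0, the fit's R-squared and the residual RMSE
#' (`rmse = "residual"`, the default) or the root-mean-square of the
#' pairwise series differences (`rmse = "difference"`).
#'
#' A zero-variance reference series cannot support a slope test; such
#' classes are returned with `fitted = FALSE` and `NA` statistics rather
#' than propagating NaN.
#'
#' @param reference,predicted Data frames or matrices of per-sample
#'   proportions (rows = samples, columns = classes; column names must
#'   match).
#' @param rmse `"residual"` or `"difference"`.
#' @return Data frame with one row per class: `class`, `n`, `slope`,
#'   `intercept`, `p_value`, `r_squared`, `rmse`, `fitted`.
#' @export
class_agreement_regression <- function(reference, predicted,
                                       rmse = c("residual", "difference")) {
  rmse <- match.arg(rmse)
  reference <- as.data.frame(reference)
  predicted <- as.data.frame(predicted)
  classes <- intersect(names(reference), names(predicted))
  if (!length(classes)) stop("no shared class columns", call. = FALSE)
  rows <- lapply(classes, function(cl) {
    x <- reference[[cl]]
    y <- predicted[[cl]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3 || stats::var(x) == 0) {
      return(data.frame(class = cl, n = n, slope = NA_real_,
                        intercept = NA_real_, p_value = NA_real_,
                        r_squared = NA_real_, rmse = NA_real_,
                        fitted = FALSE))
    }
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)
    rmse_val <- if (rmse == "residual") {
      sqrt(mean(stats::residuals(fit)^2))
    } else {
      sqrt(mean((y - x)^2))
    }
    data.frame(class = cl, n = n,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               p_value = sm$coefficients[2, 4],
               r_squared = sm$r.squared,
               rmse = rmse_val, fitted = TRUE)
  })
  do.call(rbind, rows)
}

#' Per-sample class proportions from a counts table
#'
#' Converts a counts data frame (one row per sample) into proportions. By
#' default every classified object — including non-pollen palynomorphs and
#' unknowns — enters the denominator; pass `denominator` to restrict it.
#'
#' @param counts Counts data frame (see [classify_sequence()]).
#' @param classes Class columns to report (default: all columns that are
#'   not `sample_id`, `depth_cm`, `age_calBP`, `marker_count`,
#'   `volume_cm3`).
#' @param denominator Columns summed per sample as the denominator
#'   (default `classes`).
#' @return Data frame of proportions, same id columns.
#' @export
count_proportions <- function(counts, classes = NULL, denominator = NULL) {
  meta <- intersect(c("sample_id", "depth_cm", "age_calBP", "marker_count",
                      "volume_cm3"), names(counts))
  if (is.null(classes)) classes <- setdiff(names(counts), meta)
  if (is.null(denominator)) denominator <- classes
  denom <- rowSums(counts[, denominator, drop = FALSE])
  out <- counts[, intersect(meta, c("sample_id", "depth_cm", "age_calBP")),
                drop = FALSE]
  props <- counts[, classes, drop = FALSE] / ifelse(denom == 0, NA, denom)
  cbind(out, props)
}
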