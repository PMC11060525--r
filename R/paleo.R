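# Stratigraphic pollen statistics: exotic-marker concentration and influx,
# percentage diagrams, age-depth interpolation, stratigraphically
# constrained incremental sum-of-squares zonation (CONISS) and broken-stick
# selection of the number of significant zones.

#' Pollen concentration from an exotic marker
#'
#' A known dose of exotic marker grains is added per unit sediment volume;
#' the ratio of counted pollen to counted marker grains scales the dose to
#' a concentration:
#' `concentration = pollen_count * marker_added / (marker_count * volume)`.
#'
#' @param pollen_count Counted pollen grains (vectorized).
#' @param marker_count Counted exotic-marker grains.
#' @param marker_added Marker grains added per cm^3 of sediment (e.g. a
#'   Eucalyptus spike of 15319 grains/cm^3).
#' @param volume_cm3 Sample volume in cm^3 (default 1).
#' @return Grains per cm^3. Samples with `marker_count = 0` yield `NA` with
#'   a warning (undefined concentration), never a silent infinity.
#' @export
#' @examples
#' concentration(200, 100, 15319)  # 30638 grains/cm3
concentration <- function(pollen_count, marker_count, marker_added,
                          volume_cm3 = 1) {
  stopifnot(all(pollen_count >= 0, na.rm = TRUE),
            all(marker_count >= 0, na.rm = TRUE), marker_added > 0,
            all(volume_cm3 > 0))
  bad <- !is.na(marker_count) & marker_count == 0
  if (any(bad)) {
    warning(sum(bad), " sample(s) with zero marker count: ",
            "concentration undefined (NA)")
  }
  out <- pollen_count * marker_added / (marker_count * volume_cm3)
  out[bad] <- NA_real_
  out
}

#' Age-depth model from dated control points
#'
#' Piecewise-linear interpolation by default; `kind = "monotone"` uses a
#' monotone Hermite cubic. Ages must be nondecreasing with depth.
#'
#' @param control_points Data frame with columns `depth_cm` and `age_calBP`
#'   (at least 2 rows).
#' @param kind `"linear"` or `"monotone"`.
#' @return An `age_depth_model` object.
#' @export
age_depth_model <- function(control_points, kind = c("linear", "monotone")) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(control_points),
            all(c("depth_cm", "age_calBP") %in% names(control_points)),
            nrow(control_points) >= 2)
  cp <- control_points[order(control_points$depth_cm), ]
  if (anyDuplicated(cp$depth_cm)) stop("duplicate control depths", call. = FALSE)
  if (is.unsorted(cp$age_calBP)) {
    stop("ages must be nondecreasing with depth", call. = FALSE)
  }
  structure(list(control_points = cp, kind = kind),
            class = "age_depth_model")
}

#' Interpolated age and deposition time at a depth
#'
#' @param model An [age_depth_model()].
#' @param depth Depths in cm (vectorized).
#' @param extrapolate Allow depths outside the control range (linearly
#'   extended); otherwise such depths raise an error.
#' @return Data frame with `depth_cm`, `age_calBP` and `deposition_yr_cm`
#'   (the local slope of age against depth, in years per cm). A zero local
#'   slope is degenerate for influx computation and is flagged with a
#'   warning.
#' @export
age_and_deposition <- function(model, depth, extrapolate = FALSE) {
  stopifnot(inherits(model, "age_depth_model"))
  cp <- model$control_points
  rng <- range(cp$depth_cm)
  outside <- depth < rng[1] | depth > rng[2]
  if (any(outside) && !extrapolate) {
    stop("depth(s) outside the dated range [", rng[1], ", ", rng[2],
         "] cm; set extrapolate = TRUE to extend linearly", call. = FALSE)
  }
  if (model$kind == "linear") {
    seg <- findInterval(depth, cp$depth_cm, all.inside = TRUE)
    slope <- (cp$age_calBP[seg + 1] - cp$age_calBP[seg]) /
      (cp$depth_cm[seg + 1] - cp$depth_cm[seg])
    age <- cp$age_calBP[seg] + slope * (depth - cp$depth_cm[seg])
  } else {
    f <- stats::splinefun(cp$depth_cm, cp$age_calBP, method = "monoH.FC")
    age <- f(depth)
    slope <- f(depth, deriv = 1)
    if (any(outside)) {  # linear extension beyond the knots
      age[outside] <- stats::approx(cp$depth_cm, cp$age_calBP, depth[outside],
                                    rule = 2)$y
    }
  }
  if (any(slope == 0)) {
    warning("zero deposition slope at ", sum(slope == 0),
            " depth(s): influx undefined there")
  }
  data.frame(depth_cm = depth, age_calBP = age, deposition_yr_cm = slope)
}

#' Pollen influx from concentration and deposition time
#'
#' @param concentration Grains per cm^3.
#' @param deposition_yr_cm Deposition time in years per cm (> 0).
#' @return Grains per cm^2 per year.
#' @export
#' @examples
#' influx(10000, 12.4)  # ~806.45 grains/cm2/yr
influx <- function(concentration, deposition_yr_cm) {
  if (any(deposition_yr_cm <= 0, na.rm = TRUE)) {
    stop("deposition time must be positive", call. = FALSE)
  }
  concentration / deposition_yr_cm
}

#' Pollen-sum policy
#'
#' Declares which classes form the percentage denominator (the pollen sum).
#' The conventional default excludes non-pollen palynomorphs, unknowns,
#' intermediate fallback mixes beyond their own right, and the exotic
#' marker; here the exclusion list is explicit and fully configurable.
#'
#' @param exclude Classes excluded from the pollen sum (default:
#'   NPP/minerals, the unknown label and the Eucalyptus marker).
#' @param include Optional explicit inclusion list; if given, `exclude` is
#'   ignored.
#' @return A `pollen_sum_policy` object.
#' @export
pollen_sum_policy <- function(exclude = c("NPP/Minerals", "Unknown",
                                          "Eucalyptus"),
                              include = NULL) {
  structure(list(exclude = exclude, include = include),
            class = "pollen_sum_policy")
}

#' Percentage abundances under a pollen-sum policy
#'
#' Per sample, each included class's count is divided by the pollen sum
#' (the summed counts of the policy classes). Excluded columns (NPPs,
#' unknowns, the marker) are additionally reported against the total
#' object count as `<class>_of_total`.
#'
#' @param counts Counts data frame (`sample_id`, `depth_cm`, class
#'   columns, `marker_count`, `volume_cm3`; see [classify_sequence()]).
#' @param policy A [pollen_sum_policy()].
#' @return Data frame: id columns, `pollen_sum`, one proportion column per
#'   policy class (rows sum to 1), and `_of_total` columns for excluded
#'   classes. Samples with a zero pollen sum are flagged with a warning and
#'   yield `NA` proportions.
#' @export
percentages <- function(counts, policy = pollen_sum_policy()) {
  meta <- intersect(c("sample_id", "depth_cm", "age_calBP", "marker_count",
                      "volume_cm3"), names(counts))
  cls <- setdiff(names(counts), meta)
  sum_classes <- if (!is.null(policy$include)) {
    missing_cl <- setdiff(policy$include, cls)
    if (length(missing_cl)) stop("policy names unknown class(es): ",
                                 paste(missing_cl, collapse = ", "),
                                 call. = FALSE)
    policy$include
  } else setdiff(cls, policy$exclude)
  if (!length(sum_classes)) stop("empty pollen sum", call. = FALSE)
  psum <- rowSums(counts[, sum_classes, drop = FALSE])
  if (any(psum == 0)) warning(sum(psum == 0), " sample(s) with zero pollen sum")
  out <- counts[, intersect(meta, c("sample_id", "depth_cm", "age_calBP")),
                drop = FALSE]
  out$pollen_sum <- psum
  props <- counts[, sum_classes, drop = FALSE] / ifelse(psum == 0, NA, psum)
  out <- cbind(out, props)
  total <- rowSums(counts[, cls, drop = FALSE])
  for (ex in intersect(setdiff(cls, sum_classes), cls)) {
    if (any(counts[[ex]] > 0) || ex %in% policy$exclude) {
      out[[paste0(ex, "_of_total")]] <- counts[[ex]] / total
    }
  }
  out
}

#' Stratigraphically constrained incremental sum-of-squares clustering
#'
#' Agglomerative clustering of stratigraphically ordered samples in which
#' only adjacent clusters may merge (CONISS). The dispersion of a cluster
#' is the sum over its members and variables of squared deviations from
#' the cluster mean; at each step the adjacent pair whose fusion least
#' increases total within-cluster dispersion is merged (ties broken by the
#' uppermost pair). The default transform takes square roots of row
#' proportions, i.e. distances are chord-like; `"none"` clusters the matrix
#' as given and `"standardize"` scales columns to unit variance.
#'
#' @param x Numeric matrix or data frame, rows = samples in stratigraphic
#'   order, columns = classes.
#' @param depths Sample depths (cm), strictly monotone; default row index.
#' @param transform `"sqrt"`, `"none"` or `"standardize"`.
#' @return A `zonation` object: `merges` data frame (`step`, `boundary` —
#'   the index of the sample boundary removed, `cost`, `cumulative`),
#'   `total_dispersion`, `n`, `depths`, plus `k` and `boundaries` once
#'   [broken_stick_zones()] has been applied.
#' @export
coniss <- function(x, depths = NULL, transform = c("sqrt", "none",
                                                   "standardize")) {
  transform <- match.arg(transform)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  if (is.null(depths)) depths <- seq_len(n)
  if (length(depths) != n || is.unsorted(depths, strictly = TRUE) &&
      is.unsorted(rev(depths), strictly = TRUE)) {
    stop("depths must be strictly monotone and match the rows", call. = FALSE)
  }
  x <- switch(transform,
    sqrt = sqrt(x / ifelse(rowSums(x) == 0, 1, rowSums(x))),
    standardize = scale(x),
    none = x)
  ## cluster bookkeeping: per cluster, n, column sums, sum of squares
  cl_n <- rep(1, n)
  cl_sum <- x
  cl_ss <- rowSums(x^2)
  disp <- function(i) cl_ss[i] - sum(cl_sum[i, ]^2) / cl_n[i]
  right <- seq_len(n)           # cluster id of right end sample
  alive <- seq_len(n)           # clusters in stratigraphic order
  merges <- data.frame(step = integer(0), boundary = integer(0),
                       cost = numeric(0), cumulative = numeric(0))
  cum <- 0
  for (step in seq_len(n - 1)) {
    m <- length(alive)
    costs <- vapply(seq_len(m - 1), function(j) {
      a <- alive[j]; b <- alive[j + 1]
      merged_ss <- cl_ss[a] + cl_ss[b]
      merged_sum2 <- sum((cl_sum[a, ] + cl_sum[b, ])^2)
      merged_disp <- merged_ss - merged_sum2 / (cl_n[a] + cl_n[b])
      merged_disp - disp(a) - disp(b)
    }, numeric(1))
    j <- which.min(costs)
    a <- alive[j]; b <- alive[j + 1]
    cum <- cum + costs[j]
    merges <- rbind(merges, data.frame(step = step, boundary = right[a],
                                       cost = costs[j], cumulative = cum))
    cl_n[a] <- cl_n[a] + cl_n[b]
    cl_sum[a, ] <- cl_sum[a, ] + cl_sum[b, ]
    cl_ss[a] <- cl_ss[a] + cl_ss[b]
    right[a] <- right[b]
    alive <- alive[-(j + 1)]
  }
  structure(list(merges = merges, total_dispersion = cum, n = n,
                 depths = depths, transform = transform),
            class = "zonation")
}

#' @export
print.zonation <- function(x, ...) {
  cat("<zonation> ", x$n, " samples, total dispersion ",
      signif(x$total_dispersion, 5), "\n", sep = "")
  if (!is.null(x$k)) {
    cat("  selected k = ", x$k, " zones; boundaries at depth(s) ",
        paste(signif(x$boundary_depths, 5), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Broken-stick expectations for m pieces
#'
#' `E_j = (1/m) * sum(1/i, i = j..m)`: the expected fraction of a unit
#' stick's length in its j-th longest piece when broken at random into `m`
#' pieces. Expectations sum to 1 and strictly decrease.
#'
#' @param m Number of pieces.
#' @return Numeric vector of length `m`.
#' @export
#' @examples
#' broken_stick_expectation(2)  # 0.75 0.25
broken_stick_expectation <- function(m) {
  stopifnot(m >= 1)
  vapply(seq_len(m), function(j) sum(1 / (j:m)) / m, numeric(1))
}

#' Select the number of significant zones by the broken-stick rule
#'
#' Splits are the merges read in reverse: the j-th split divides j clusters
#' into j + 1 and explains a fraction `cost / total_dispersion` of the
#' total dispersion. Each observed fraction is compared with the
#' broken-stick expectation for `m = n - 1` pieces; `k` is 1 plus the
#' number of leading splits whose observed fraction exceeds expectation.
#'
#' @param zonation A `zonation` from [coniss()] (or its `merges` data
#'   frame together with `n`).
#' @param n Number of samples (taken from the zonation if omitted).
#' @return The `zonation` augmented with `k`, `boundaries` (sample boundary
#'   indices), `boundary_depths` (midpoints between adjacent samples of
#'   different zones) and `splits` (data frame: `split`, `observed`,
#'   `expected`, `significant`).
#' @export
broken_stick_zones <- function(zonation, n = NULL) {
  if (is.data.frame(zonation)) {
    if (is.null(n)) stop("supply n with a bare merge table", call. = FALSE)
    zonation <- structure(list(merges = zonation,
                               total_dispersion = max(zonation$cumulative),
                               n = n, depths = seq_len(n)),
                          class = "zonation")
  }
  n <- zonation$n
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  m <- n - 1
  expected <- broken_stick_expectation(m)
  td <- zonation$total_dispersion
  ## split j undoes merge (n - j): last merge first
  observed <- rev(zonation$merges$cost) / if (td > 0) td else 1
  significant <- observed > expected
  lead <- which(!significant)
  k <- if (length(lead)) lead[1] else m + 1L
  zonation$splits <- data.frame(split = seq_len(m), observed = observed,
                                expected = expected,
                                significant = significant)
  zonation$k <- as.integer(k)
  zb <- zone_boundaries(zonation, k)
  zonation$boundaries <- zb$boundaries
  zonation$boundary_depths <- zb$boundary_depths
  zonation
}

#' Zone boundaries for a given cluster count
#'
#' Cutting the merge sequence after `n - k` merges leaves `k` contiguous
#' zones; the boundaries are the sample boundaries never removed, placed
#' at depth midpoints between the adjacent samples of different zones.
#'
#' @param zonation A `zonation` from [coniss()].
#' @param k Number of zones, `1 <= k <= n`.
#' @return List with `boundaries` (indices `i` meaning "between sample i
#'   and i + 1", increasing) and `boundary_depths` (midpoint depths).
#' @export
zone_boundaries <- function(zonation, k) {
  stopifnot(inherits(zonation, "zonation"))
  n <- zonation$n
  if (k < 1 || k > n) stop("k must be in [1, ", n, "]", call. = FALSE)
  removed <- zonation$merges$boundary[seq_len(n - k)]
  kept <- sort(setdiff(seq_len(n - 1), removed))
  d <- zonation$depths
  list(boundaries = kept,
       boundary_depths = (d[kept] + d[kept + 1]) / 2)
}

#' Zone membership of each sample for a given k
#' @param zonation A `zonation`.
#' @param k Number of zones.
#' @return Integer vector of zone ids (1 = top of the sequence).
#' @export
zone_membership <- function(zonation, k) {
  b <- zone_boundaries(zonation, k)$boundaries
  findInterval(seq_len(zonation$n), b + 1L) + 1L
}

#' Assemble the full diagram table for a classified sequence
#'
#' Joins percentages, concentration and influx into one tidy long-format
#' table (sample x class), the shape a plotting layer or export consumes.
#'
#' @param counts Counts data frame (see [classify_sequence()]).
#' @param marker_added Marker grains added per cm^3.
#' @param age_model Optional [age_depth_model()] for ages and influx.
#' @param policy A [pollen_sum_policy()].
#' @return Long data frame: `sample_id`, `depth_cm`, (`age_calBP`),
#'   `class`, `count`, `percent`, `concentration`, (`influx`).
#' @export
diagram_table <- function(counts, marker_added, age_model = NULL,
                          policy = pollen_sum_policy()) {
  meta <- intersect(c("sample_id", "depth_cm", "age_calBP", "marker_count",
                      "volume_cm3"), names(counts))
  cls <- setdiff(names(counts), meta)
  pct <- percentages(counts, policy)
  sum_classes <- intersect(names(pct), cls)
  dep <- NULL
  if (!is.null(age_model)) {
    dep <- age_and_deposition(age_model, counts$depth_cm, extrapolate = TRUE)
  }
  rows <- lapply(sum_classes, function(cl) {
    conc <- concentration(counts[[cl]], counts$marker_count, marker_added,
                          counts$volume_cm3 %||% 1)
    out <- data.frame(sample_id = counts$sample_id,
                      depth_cm = counts$depth_cm, class = cl,
                      count = counts[[cl]], percent = 100 * pct[[cl]],
                      concentration = conc)
    if (!is.null(dep)) {
      out$age_calBP <- dep$age_calBP
      out$influx <- influx(conc, dep$deposition_yr_cm)
    }
    out
  })
  do.call(rbind, rows)
}

#' Minimal percentage-diagram renderer
#'
#' A reference renderer: one horizontal panel per class, abundance against
#' depth, optional zone boundaries, optional visual-only exaggeration of
#' sparse curves (stored values are never modified).
#'
#' @param pct Output of [percentages()].
#' @param zonation Optional `zonation` with `k` set.
#' @param classes Classes to draw (default: all proportion columns).
#' @param exaggerate Visual multiplication factor drawn as a lighter fill
#'   (default 1 = off).
#' @return Invisibly, the matrix drawn.
#' @export
plot_diagram <- function(pct, zonation = NULL, classes = NULL,
                         exaggerate = 1) {
  meta <- intersect(c("sample_id", "depth_cm", "age_calBP", "pollen_sum"),
                    names(pct))
  if (is.null(classes)) {
    classes <- setdiff(names(pct), c(meta, grep("_of_total$", names(pct),
                                                value = TRUE)))
  }
  depths <- pct$depth_cm
  op <- graphics::par(mfrow = c(1, length(classes)),
                      mar = c(4, 0.4, 3, 0.4), oma = c(0, 4, 0, 0))
  on.exit(graphics::par(op))
  for (cl in classes) {
    v <- 100 * pct[[cl]]
    xmax <- max(v * exaggerate, 5, na.rm = TRUE)
    graphics::plot(v, depths, type = "n", xlim = c(0, xmax),
                   ylim = rev(range(depths)), xlab = "%", ylab = "",
                   yaxt = if (cl == classes[1]) "s" else "n", main = cl,
                   cex.main = 0.7)
    if (exaggerate > 1) {
      graphics::polygon(c(0, v * exaggerate, 0),
                        c(depths[1], depths, depths[length(depths)]),
                        col = "grey90", border = NA)
    }
    graphics::polygon(c(0, v, 0),
                      c(depths[1], depths, depths[length(depths)]),
                      col = "grey40", border = "black")
    if (!is.null(zonation) && !is.null(zonation$boundary_depths)) {
      graphics::abline(h = zonation$boundary_depths, lty = 2)
    }
  }
  graphics::mtext("depth (cm)", side = 2, outer = TRUE, line = 2.5)
  invisible(pct)
}
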