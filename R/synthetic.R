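# Procedural generation of labelled grain images.
#
# Images follow the dark-field convention: bright object on a near-black
# background, 128x128 pixels, intensities in [0,1]. Each renderer draws a
# parametric 2-D morphotype (body ellipse, air sacs, pores, furrows) plus a
# procedural exine texture, and logs its ground-truth geometry (centre,
# radii, pore centres, saccus boxes) so tests can assert construction
# without any vision code.

#' Morphotype specification
#'
#' Describes one grain class as parametric geometry. All dispersion
#' parameters are standard deviations of per-grain draws.
#'
#' @param morphotype One of `"aporate"`, `"vesiculate"`, `"triporate"`,
#'   `"stephanoporate"`, `"tricolpate"`, `"npp"`.
#' @param size_px Length-2 numeric `c(mean, sd)`: grain diameter in pixels.
#' @param eccentricity Body ellipse eccentricity in `[0, 0.8]` (0 = circle).
#' @param saccus_ratio Saccus diameter relative to body diameter
#'   (vesiculate only).
#' @param pore_count Number of pores, 3 for triporate, 4 or 5 for
#'   stephanoporate.
#' @param pore_prominence Intensity contrast of pores in `[0,1]`.
#' @param furrow_count Number of colpi (tricolpate only).
#' @param furrow_depth Intensity drop of furrows in `[0,1]`.
#' @param texture_freq Spatial frequency of the exine texture (cycles per
#'   grain radius).
#' @param texture_amp Texture amplitude in intensity units.
#' @param base_intensity Mean body intensity in `(0,1]`.
#' @return A `morphotype_spec` object.
#' @export
morphotype_spec <- function(morphotype,
                            size_px = c(32, 3),
                            eccentricity = 0.15,
                            saccus_ratio = 0.5,
                            pore_count = 3,
                            pore_prominence = 0.5,
                            furrow_count = 3,
                            furrow_depth = 0.5,
                            texture_freq = 6,
                            texture_amp = 0.08,
                            base_intensity = 0.75) {
  morphotype <- match.arg(morphotype, c("aporate", "vesiculate", "triporate",
                                        "stephanoporate", "tricolpate", "npp"))
  stopifnot(length(size_px) == 2, size_px[1] > 0, size_px[2] >= 0,
            eccentricity >= 0, eccentricity <= 0.9,
            saccus_ratio > 0,
            pore_prominence >= 0, furrow_depth >= 0,
            texture_freq >= 0, texture_amp >= 0,
            base_intensity > 0, base_intensity <= 1)
  if (morphotype %in% c("triporate", "stephanoporate") &&
      !pore_count %in% 3:5) {
    stop("pore_count must be 3, 4 or 5", call. = FALSE)
  }
  structure(list(
    morphotype = morphotype, size_px = size_px, eccentricity = eccentricity,
    saccus_ratio = saccus_ratio, pore_count = as.integer(pore_count),
    pore_prominence = pore_prominence, furrow_count = as.integer(furrow_count),
    furrow_depth = furrow_depth, texture_freq = texture_freq,
    texture_amp = texture_amp, base_intensity = base_intensity
  ), class = "morphotype_spec")
}

#' Render one grain image
#'
#' Draws a single grain on a dark background. Deterministic: the same
#' `(spec, seed)` pair always yields a bit-identical image. The ground-truth
#' geometry (centre, semi-axes, orientation, pore centres, saccus centres,
#' furrow angles) is attached as the `"geometry"` attribute.
#'
#' @param spec A [morphotype_spec()].
#' @param seed Integer seed for the per-grain parameter draws.
#' @param size Canvas side in pixels (default 128).
#' @return A `size`x`size` numeric matrix in `[0,1]` with attribute
#'   `"geometry"`.
#' @export
render_grain <- function(spec, seed, size = 128L) {
  stopifnot(inherits(spec, "morphotype_spec"))
  if (spec$size_px[1] >= size) {
    stop("grain size (", spec$size_px[1], "px) exceeds canvas (", size, "px)",
         call. = FALSE)
  }
  local_seed(seed)
  n <- size
  ## per-grain draws
  diam <- max(6, stats::rnorm(1, spec$size_px[1], spec$size_px[2]))
  diam <- min(diam, 0.9 * n)
  r <- diam / 2
  margin <- if (spec$morphotype == "vesiculate") {
    r * (0.75 + 1.6 * spec$saccus_ratio)
  } else r
  margin <- min(margin * 1.1, n / 2 - 1)
  cx <- n / 2 + stats::runif(1, -1, 1) * max(0, n / 2 - margin - 2) * 0.35
  cy <- n / 2 + stats::runif(1, -1, 1) * max(0, n / 2 - margin - 2) * 0.35
  theta <- stats::runif(1, 0, pi)
  ecc <- spec$eccentricity
  a <- r
  b <- r * sqrt(1 - ecc^2)
  ## random low-order texture phases
  tex_phase <- stats::runif(2, 0, 2 * pi)
  base <- spec$base_intensity * stats::runif(1, 0.92, 1.05)

  xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index
  ct <- cos(theta); st <- sin(theta)
  u <- (xs - cx) * ct + (ys - cy) * st
  v <- -(xs - cx) * st + (ys - cy) * ct

  img <- matrix(0.02, n, n)
  geom <- list(center = c(cx, cy), semi_axes = c(a, b), orientation = theta,
               diameter = diam, morphotype = spec$morphotype)

  soft_disc <- function(d2, edge = 1.2) pmin(1, pmax(0, (1 - sqrt(d2)) / (edge / r) + 1))

  if (spec$morphotype == "npp") {
    ## non-pollen palynomorphs are a mixture: air bubbles (large rings) and
    ## jagged mineral fragments (harmonically modulated blobs)
    if (stats::runif(1) < 0.5) {
      rad <- sqrt(u^2 + v^2)
      ring <- exp(-((rad - r) / (0.06 * r + 1))^2)
      img <- clamp01(img + base * 1.3 * ring)  # hollow: interior stays dark
      geom$npp_kind <- "bubble"
      geom$ring_radius <- r
    } else {
      amp <- stats::runif(3, 0.1, 0.35)
      ph <- stats::runif(3, 0, 2 * pi)
      ang <- atan2(v, u)
      rad <- sqrt(u^2 + v^2)
      rmod <- r * (1 + amp[1] * cos(2 * ang + ph[1]) +
                     amp[2] * cos(3 * ang + ph[2]) +
                     amp[3] * cos(5 * ang + ph[3]))
      inside <- rad <= rmod
      tex <- spec$texture_amp * sin(spec$texture_freq * u / r + tex_phase[1]) *
        sin(spec$texture_freq * v / r + tex_phase[2])
      img[inside] <- pmin(1, pmax(0, base * 0.85 + tex[inside]))
      geom$npp_kind <- "mineral"
      geom$harmonics <- list(amp = amp, phase = ph)
    }
  } else {
    d2 <- (u / a)^2 + (v / b)^2
    if (spec$morphotype == "triporate") {
      ## triporates are triangular-aspidate in polar view: the outline
      ## bulges at the three pore positions
      pore_ang0 <- stats::runif(1, 0, 2 * pi)
      angm <- atan2(v / b, u / a)
      bulge <- 1 + 0.14 * cos(3 * (angm - pore_ang0))
      d2 <- d2 / bulge^2
    }
    inside <- d2 <= 1
    ## radial profile: bright rim (exine), slightly dimmer interior
    rim <- exp(-((sqrt(d2) - 0.92) / 0.06)^2)
    ## aporate grains show a markedly thickened smooth exine rim
    rim_gain <- if (spec$morphotype == "aporate") 0.45 else 0.18
    tex <- spec$texture_amp * sin(spec$texture_freq * u / r + tex_phase[1]) *
      cos(spec$texture_freq * v / r + tex_phase[2])
    body <- base * (0.82 + 0.10 * (1 - d2)) + rim_gain * base * rim + tex
    if (spec$morphotype == "aporate") {
      ## central protruding papilla, the hallmark of juniper-type grains
      body <- body + 0.45 * base * exp(-d2 / 0.04)
    }
    img[inside] <- pmin(1, pmax(0, body[inside]))

    if (spec$morphotype == "vesiculate") {
      ## two air sacs flanking the body along its major axis
      rs <- r * spec$saccus_ratio
      off <- a * 0.75 + rs * 0.6   # bladders protrude beyond the body
      sac_centers <- matrix(NA_real_, 2, 2)
      for (k in 1:2) {
        sgn <- if (k == 1) -1 else 1
        scx <- cx + sgn * off * ct
        scy <- cy + sgn * off * st
        sac_centers[k, ] <- c(scx, scy)
        sd2 <- ((xs - scx)^2 + (ys - scy)^2) / rs^2
        sin_s <- sd2 <= 1
        srim <- exp(-((sqrt(sd2) - 0.88) / 0.1)^2)
        ## sacci are reticulate: brighter than the body shadow, with a
        ## crisp rim and a honeycomb shimmer
        shim <- 0.08 * sin(9 * (xs - scx) / rs) * sin(9 * (ys - scy) / rs)
        sac <- base * (0.72 + 0.10 * (1 - sd2)) + 0.3 * base * srim + shim
        img[sin_s] <- pmin(1, pmax(img[sin_s], sac[sin_s]))
      }
      geom$saccus_centers <- sac_centers
      geom$saccus_radius <- rs
    }

    if (spec$morphotype %in% c("triporate", "stephanoporate")) {
      k <- spec$pore_count
      ang0 <- if (spec$morphotype == "triporate") pore_ang0 else {
        stats::runif(1, 0, 2 * pi)
      }
      angs <- ang0 + 2 * pi * (seq_len(k) - 1) / k
      pr <- max(3, 0.22 * r)
      bulge_r <- if (spec$morphotype == "triporate") 1.14 else 1
      centers <- matrix(NA_real_, k, 2)
      for (i in seq_len(k)) {
        px <- cx + bulge_r * (a * cos(angs[i]) * ct - b * sin(angs[i]) * st)
        py <- cy + bulge_r * (a * cos(angs[i]) * st + b * sin(angs[i]) * ct)
        centers[i, ] <- c(px, py)
        pd2 <- ((xs - px)^2 + (ys - py)^2) / pr^2
        pin <- pd2 <= 1.4
        ## pores: dark aperture inside a bright protruding collar
        pore <- spec$pore_prominence *
          (1.1 * exp(-((sqrt(pd2) - 0.85) / 0.22)^2) - 1.0 * (pd2 < 0.45))
        img[pin] <- pmin(1, pmax(0, img[pin] + pore[pin]))
      }
      if (spec$morphotype == "stephanoporate") {
        ## arci: the thickened curved bands running between pores that
        ## identify Alnus grains; thickened exine scatters more light, so
        ## under dark-field they read as bright arcs
        rad_e <- sqrt(d2)
        arc <- inside & (abs(rad_e - 0.62) < 0.14)
        img[arc] <- pmin(1, img[arc] + 0.55 * base *
                           exp(-((rad_e[arc] - 0.62) / 0.08)^2))
      }
      geom$pore_centers <- centers
      geom$pore_angles <- angs %% (2 * pi)
      geom$pore_radius <- pr
    }

    if (spec$morphotype == "tricolpate") {
      k <- spec$furrow_count
      ang0 <- stats::runif(1, 0, pi)
      angs <- ang0 + pi * (seq_len(k) - 1) / k
      w <- max(1.8, 0.13 * r)
      for (i in seq_len(k)) {
        ## a furrow is a dark band through the grain centre at angle angs[i],
        ## flanked by brighter thickened margins
        dist <- abs(-u * sin(angs[i] - theta) + v * cos(angs[i] - theta))
        band <- inside & (dist < 2.2 * w)
        drop <- spec$furrow_depth * base *
          (1.1 * exp(-(dist / w)^2) - 0.5 * exp(-((dist - 1.6 * w) / (0.5 * w))^2))
        img[band] <- pmin(1, pmax(0, img[band] - drop[band]))
      }
      geom$furrow_angles <- angs %% pi
      geom$furrow_width <- w
    }
  }

  attr(img, "geometry") <- geom
  img
}

#' Taphonomic degradation configuration
#'
#' Parameters of the fresh-to-fossil degradation dial: folding (a darkened
#' crease band), debris occlusion, clumping (a partial second object),
#' defocus blur and sensor speckle. All probabilities in `[0,1]`; an
#' all-zero config makes [degrade()] the identity. The shipped presets are
#' illustrative of fossil material in general, not calibrated to any one
#' sediment record.
#'
#' @param fold_prob,fold_darkening Probability of a fold; intensity drop of
#'   the crease band.
#' @param occlusion_prob,occlusion_area Probability of a debris patch; patch
#'   area as a fraction of the grain bounding box, in `[0,1)`.
#' @param blur_sigma Length-2 range of Gaussian blur sigma (pixels).
#' @param speckle_sd Standard deviation of additive Gaussian noise.
#' @param clump_prob Probability of an overlapping partial neighbour grain.
#' @return A `taphonomy_config` object.
#' @export
taphonomy_config <- function(fold_prob = 0, fold_darkening = 0.4,
                             occlusion_prob = 0, occlusion_area = 0.15,
                             blur_sigma = c(0, 0), speckle_sd = 0,
                             clump_prob = 0) {
  stopifnot(fold_prob >= 0, fold_prob <= 1, occlusion_prob >= 0,
            occlusion_prob <= 1, clump_prob >= 0, clump_prob <= 1,
            occlusion_area >= 0, occlusion_area < 1,
            length(blur_sigma) == 2, all(blur_sigma >= 0),
            speckle_sd >= 0, fold_darkening >= 0)
  structure(list(fold_prob = fold_prob, fold_darkening = fold_darkening,
                 occlusion_prob = occlusion_prob,
                 occlusion_area = occlusion_area,
                 blur_sigma = as.numeric(blur_sigma),
                 speckle_sd = speckle_sd, clump_prob = clump_prob),
            class = "taphonomy_config")
}

#' Moderate degradation preset (illustrative)
#' @return A [taphonomy_config()].
#' @export
taphonomy_fossil <- function() {
  taphonomy_config(fold_prob = 0.3, fold_darkening = 0.4,
                   occlusion_prob = 0.3, occlusion_area = 0.12,
                   blur_sigma = c(0.5, 1.5), speckle_sd = 0.03,
                   clump_prob = 0.15)
}

#' Apply taphonomic degradation to a grain image
#'
#' @param image Numeric matrix in `[0,1]`.
#' @param config A [taphonomy_config()]. A config with all probabilities,
#'   blur and noise at zero returns `image` unchanged.
#' @param seed Integer seed.
#' @return Degraded image in `[0,1]`; applied events are logged in the
#'   `"taphonomy"` attribute.
#' @export
degrade <- function(image, config, seed) {
  stopifnot(inherits(config, "taphonomy_config"))
  if (config$fold_prob == 0 && config$occlusion_prob == 0 &&
      config$clump_prob == 0 && all(config$blur_sigma == 0) &&
      config$speckle_sd == 0) {
    return(image)
  }
  local_seed(seed)
  n <- nrow(image)
  geom <- attr(image, "geometry")
  img <- image
  log <- list()

  xs <- matrix(rep(seq_len(n), each = n), n, n)
  ys <- matrix(rep(seq_len(n), times = n), n, n)

  ## grain bounding box (fallback: bright-pixel bbox)
  if (!is.null(geom)) {
    cx <- geom$center[1]; cy <- geom$center[2]; rr <- geom$diameter / 2
  } else {
    bright <- which(image > 0.2, arr.ind = TRUE)
    if (nrow(bright) == 0) bright <- cbind(n / 2, n / 2)
    cy <- mean(bright[, 1]); cx <- mean(bright[, 2])
    rr <- max(4, max(abs(bright[, 1] - cy), abs(bright[, 2] - cx)))
  }

  if (stats::runif(1) < config$fold_prob) {
    ang <- stats::runif(1, 0, pi)
    off <- stats::runif(1, -0.4, 0.4) * rr
    dist <- (xs - cx) * cos(ang) + (ys - cy) * sin(ang) - off
    w <- stats::runif(1, 0.08, 0.2) * rr + 1
    band <- abs(dist) < w
    img[band] <- img[band] * (1 - config$fold_darkening * exp(-(dist[band] / w)^2))
    ## bright crease line at the band edge
    edge <- abs(abs(dist) - w) < 0.8
    img[edge] <- pmin(1, img[edge] + 0.1)
    log$fold <- list(angle = ang, offset = off, width = w)
  }

  if (stats::runif(1) < config$occlusion_prob) {
    ## one debris patch covering ~occlusion_area of the grain bounding box
    side <- 2 * rr
    pr <- sqrt(config$occlusion_area * side^2 / pi)
    px <- cx + stats::runif(1, -0.6, 0.6) * rr
    py <- cy + stats::runif(1, -0.6, 0.6) * rr
    pd2 <- ((xs - px)^2 + (ys - py)^2) / pr^2
    pin <- pd2 <= 1
    shade <- stats::runif(1, 0.15, 0.5)
    img[pin] <- img[pin] * (1 - 0.85 * pmax(0, 1 - pd2[pin])) + shade * pmax(0, 1 - pd2[pin])
    log$occlusion <- list(center = c(px, py), radius = pr,
                          area_fraction = config$occlusion_area)
  }

  if (stats::runif(1) < config$clump_prob) {
    ang <- stats::runif(1, 0, 2 * pi)
    ncx <- cx + cos(ang) * rr * 1.6
    ncy <- cy + sin(ang) * rr * 1.6
    nr <- rr * stats::runif(1, 0.5, 0.9)
    nd2 <- ((xs - ncx)^2 + (ys - ncy)^2) / nr^2
    pin <- nd2 <= 1
    img[pin] <- pmax(img[pin], 0.5 * (0.8 + 0.2 * (1 - nd2[pin])))
    log$clump <- list(center = c(ncx, ncy), radius = nr)
  }

  if (any(config$blur_sigma > 0)) {
    sigma <- stats::runif(1, config$blur_sigma[1], config$blur_sigma[2])
    if (sigma > 0.05) img <- EBImage::imageData(EBImage::gblur(img, sigma = sigma))
    log$blur_sigma <- sigma
  }

  if (config$speckle_sd > 0) {
    img <- img + matrix(stats::rnorm(n * n, 0, config$speckle_sd), n, n)
    log$speckle_sd <- config$speckle_sd
  }

  img <- clamp01(img)
  attr(img, "geometry") <- geom
  attr(img, "taphonomy") <- log
  img
}

#' Default class specifications
#'
#' One [morphotype_spec()] per terminal class of [default_taxonomy()].
#' Classes of the same gross morphotype are separated by size, saccus ratio,
#' pore count/prominence, furrow geometry and texture so that the class
#' signal is recoverable from pixels.
#'
#' @return Named list of `morphotype_spec` objects (14 classes).
#' @export
default_class_specs <- function() {
  list(
    "Juniperus/Thuja" = morphotype_spec("aporate", size_px = c(30, 2.5),
      eccentricity = 0.08, texture_freq = 3, texture_amp = 0.02,
      base_intensity = 0.58),
    "Abies balsamea" = morphotype_spec("vesiculate", size_px = c(56, 3.5),
      eccentricity = 0.30, saccus_ratio = 0.50, texture_freq = 7,
      texture_amp = 0.07, base_intensity = 0.78),
    "Picea" = morphotype_spec("vesiculate", size_px = c(46, 3),
      eccentricity = 0.22, saccus_ratio = 0.40, texture_freq = 10,
      texture_amp = 0.10, base_intensity = 0.70),
    "Pinus banksiana" = morphotype_spec("vesiculate", size_px = c(27, 2),
      eccentricity = 0.18, saccus_ratio = 0.90, texture_freq = 5,
      texture_amp = 0.05, base_intensity = 0.90),
    "Pinus strobus" = morphotype_spec("vesiculate", size_px = c(35, 2.5),
      eccentricity = 0.12, saccus_ratio = 1.05, texture_freq = 13,
      texture_amp = 0.10, base_intensity = 0.82),
    "Betula" = morphotype_spec("triporate", size_px = c(23, 2),
      eccentricity = 0.10, pore_count = 3, pore_prominence = 0.80,
      texture_freq = 4, texture_amp = 0.03, base_intensity = 0.85),
    "Corylus cornuta" = morphotype_spec("triporate", size_px = c(34, 2.5),
      eccentricity = 0.22, pore_count = 3, pore_prominence = 0.55,
      texture_freq = 9, texture_amp = 0.20, base_intensity = 0.45),
    "Eucalyptus" = morphotype_spec("triporate", size_px = c(17, 1.5),
      eccentricity = 0.35, pore_count = 3, pore_prominence = 0.85,
      texture_freq = 14, texture_amp = 0.12, base_intensity = 0.85),
    "Alnus crispa" = morphotype_spec("stephanoporate", size_px = c(20, 1.5),
      eccentricity = 0.10, pore_count = 4, pore_prominence = 0.85,
      texture_freq = 6, texture_amp = 0.06, base_intensity = 0.55),
    "Alnus rugosa" = morphotype_spec("stephanoporate", size_px = c(28, 2),
      eccentricity = 0.10, pore_count = 5, pore_prominence = 0.85,
      texture_freq = 6, texture_amp = 0.06, base_intensity = 0.68),
    "Quercus" = morphotype_spec("tricolpate", size_px = c(26, 2),
      eccentricity = 0.28, furrow_count = 3, furrow_depth = 0.35,
      texture_freq = 12, texture_amp = 0.13, base_intensity = 0.64),
    "Acer rubrum" = morphotype_spec("tricolpate", size_px = c(32, 2.5),
      eccentricity = 0.12, furrow_count = 3, furrow_depth = 0.75,
      texture_freq = 5, texture_amp = 0.05, base_intensity = 0.80),
    "Acer saccharum" = morphotype_spec("tricolpate", size_px = c(42, 3),
      eccentricity = 0.18, furrow_count = 3, furrow_depth = 0.60,
      texture_freq = 8, texture_amp = 0.09, base_intensity = 0.70),
    "NPP/Minerals" = morphotype_spec("npp", size_px = c(28, 6),
      texture_freq = 3, texture_amp = 0.12, base_intensity = 0.42)
  )
}

#' Labelled image set constructor
#' @param images List of equal-sized numeric matrices in `[0,1]`.
#' @param labels Character vector, one label per image.
#' @param classes Declared class list (defaults to the sorted unique labels).
#' @param provenance Optional list (seed, spec hash, ...).
#' @return An `image_set` object.
#' @export
image_set <- function(images, labels, classes = sort(unique(labels)),
                      provenance = list()) {
  stopifnot(length(images) == length(labels))
  if (length(images)) {
    dims <- vapply(images, dim, integer(2))
    if (any(dims != dims[, 1])) stop("all images must share one shape",
                                     call. = FALSE)
    if (!all(labels %in% classes)) {
      stop("labels outside the declared class list: ",
           paste(setdiff(labels, classes), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(images = images, labels = labels, classes = classes,
                 provenance = provenance), class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  cat("<image_set> ", length(x$images), " images",
      if (length(x$images)) paste0(" (", paste(dim(x$images[[1]]), collapse = "x"), ")"),
      ", ", length(x$classes), " classes\n", sep = "")
  print(table(factor(x$labels, levels = x$classes)))
  invisible(x)
}

#' @export
length.image_set <- function(x) length(x$images)

#' Subset an image set
#' @param x An `image_set`.
#' @param i Index vector.
#' @param ... Unused.
#' @return An `image_set`.
#' @export
`[.image_set` <- function(x, i, ...) {
  image_set(x$images[i], x$labels[i], classes = x$classes,
            provenance = x$provenance)
}

#' Concatenate image sets
#' @param ... `image_set` objects with a common image shape.
#' @return An `image_set`.
#' @export
c.image_set <- function(...) {
  sets <- list(...)
  image_set(do.call(c, lapply(sets, `[[`, "images")),
            do.call(c, lapply(sets, `[[`, "labels")),
            classes = sort(unique(unlist(lapply(sets, `[[`, "classes")))))
}

#' Generate a labelled dataset of rendered grains
#'
#' @param class_specs Named list of [morphotype_spec()] (name = class label).
#' @param n_per_class Images per class (scalar or named vector).
#' @param taphonomy Optional [taphonomy_config()] applied to every image.
#' @param seed Integer seed; the output is a pure function of
#'   `(class_specs, n_per_class, taphonomy, seed)`.
#' @param size Canvas side (default 128).
#' @return An `image_set` with `n_per_class` images per class.
#' @export
generate_dataset <- function(class_specs, n_per_class, taphonomy = NULL,
                             seed = 1L, size = 128L) {
  if (length(class_specs) == 0) stop("empty class map", call. = FALSE)
  stopifnot(all(n_per_class >= 1))
  classes <- names(class_specs)
  if (length(n_per_class) == 1L) {
    n_per_class <- stats::setNames(rep(n_per_class, length(classes)), classes)
  }
  local_seed(seed)
  total <- sum(n_per_class[classes])
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * total)
  images <- vector("list", total)
  labels <- character(total)
  k <- 0L
  for (cl in classes) {
    for (i in seq_len(n_per_class[[cl]])) {
      k <- k + 1L
      img <- render_grain(class_specs[[cl]], seeds[2L * k - 1L], size = size)
      if (!is.null(taphonomy)) img <- degrade(img, taphonomy, seeds[2L * k])
      images[[k]] <- img
      labels[k] <- cl
    }
  }
  image_set(images, labels, classes = classes,
            provenance = list(seed = seed, n_per_class = as.list(n_per_class)))
}

#' Generate a synthetic fossil sequence with ground truth
#'
#' Emulates a sediment-core image dataset: for each depth, `n_objects`
#' microscope objects are drawn — each is an exotic-marker grain
#' (Eucalyptus) with probability `marker_dose`, otherwise a grain from the
#' per-depth composition — rendered, degraded, and tallied into a
#' ground-truth counts table, so end-to-end diagram recovery is checkable
#' against the generating truth.
#'
#' @param composition Data frame with column `depth_cm` plus one column per
#'   class giving per-depth proportions (each row sums to 1 over the class
#'   columns).
#' @param n_objects Objects rendered per sample.
#' @param marker_dose Probability that an object is an exotic-marker grain.
#' @param taphonomy Optional [taphonomy_config()].
#' @param seed Integer seed.
#' @param class_specs Named spec list (default [default_class_specs()]);
#'   must cover the composition columns and `"Eucalyptus"`.
#' @param marker_class Marker class label (default `"Eucalyptus"`).
#' @param size Canvas side.
#' @return List with `samples` (list of `image_set`, one per depth) and
#'   `truth` (counts data frame: `sample_id`, `depth_cm`, one column per
#'   class, `marker_count`, `volume_cm3`).
#' @export
generate_fossil_sequence <- function(composition, n_objects = 100,
                                     marker_dose = 0.1, taphonomy = NULL,
                                     seed = 1L,
                                     class_specs = default_class_specs(),
                                     marker_class = "Eucalyptus",
                                     size = 128L) {
  stopifnot(is.data.frame(composition), "depth_cm" %in% names(composition))
  cls <- setdiff(names(composition), c("depth_cm", "sample_id"))
  if (!all(cls %in% names(class_specs))) {
    stop("composition classes missing from class_specs: ",
         paste(setdiff(cls, names(class_specs)), collapse = ", "),
         call. = FALSE)
  }
  props <- as.matrix(composition[, cls, drop = FALSE])
  if (any(props < 0)) stop("negative proportions", call. = FALSE)
  if (any(abs(rowSums(props) - 1) > 1e-6)) {
    stop("per-depth proportions must sum to 1", call. = FALSE)
  }
  local_seed(seed)
  n_dep <- nrow(composition)
  all_classes <- union(cls, marker_class)
  samples <- vector("list", n_dep)
  counts <- matrix(0L, n_dep, length(all_classes),
                   dimnames = list(NULL, all_classes))
  marker_count <- integer(n_dep)
  for (d in seq_len(n_dep)) {
    is_marker <- stats::runif(n_objects) < marker_dose
    lab <- character(n_objects)
    lab[is_marker] <- marker_class
    n_rest <- sum(!is_marker)
    if (n_rest > 0) {
      lab[!is_marker] <- sample(cls, n_rest, replace = TRUE, prob = props[d, ])
    }
    seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_objects)
    imgs <- vector("list", n_objects)
    for (i in seq_len(n_objects)) {
      img <- render_grain(class_specs[[lab[i]]], seeds[2L * i - 1L], size = size)
      if (!is.null(taphonomy)) img <- degrade(img, taphonomy, seeds[2L * i])
      imgs[[i]] <- img
    }
    samples[[d]] <- image_set(imgs, lab, classes = all_classes)
    tab <- table(factor(lab, levels = all_classes))
    counts[d, ] <- as.integer(tab)
    marker_count[d] <- sum(is_marker)
  }
  truth <- data.frame(sample_id = sprintf("S%03d", seq_len(n_dep)),
                      depth_cm = composition$depth_cm,
                      check.names = FALSE)
  truth <- cbind(truth, as.data.frame(counts, check.names = FALSE))
  truth$marker_count <- marker_count
  truth$volume_cm3 <- 1
  list(samples = samples, truth = truth)
}

#' Nearest-centroid pixel baseline
#'
#' A deliberately trivial classifier: class centroids in raw pixel space,
#' assignment by minimal Euclidean distance. Used as a separability probe —
#' if this baseline cannot beat chance on clean renders, no network should
#' be blamed for failing.
#'
#' @param train,test `image_set` objects.
#' @return Accuracy on `test` (fraction correct).
#' @export
centroid_baseline <- function(train, test) {
  classes <- sort(unique(train$labels))
  X <- t(vapply(train$images, as.vector, numeric(length(train$images[[1]]))))
  centroids <- t(vapply(classes, function(cl) {
    colMeans(X[train$labels == cl, , drop = FALSE])
  }, numeric(ncol(X))))
  Xt <- t(vapply(test$images, as.vector, numeric(length(test$images[[1]]))))
  d <- outer(rowSums(Xt^2), rowSums(centroids^2), "+") - 2 * Xt %*% t(centroids)
  pred <- classes[max.col(-d)]
  mean(pred == test$labels)
}

## clamp to [0,1] without disturbing dim attributes (pmin/pmax drop them)
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

## seed the RNG for the calling function, restoring the caller's RNG state
## when that function exits (so generators are pure in (args, seed))
local_seed <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed %% (.Machine$integer.max - 1L)))
  restore <- if (is.null(old)) {
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  } else {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  }
  do.call(on.exit, list(restore, add = TRUE), envir = envir)
  invisible(NULL)
}
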