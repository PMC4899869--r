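#' Detection parameters
#'
#' Controls the automated spot/cell detection pipeline. Defaults suit
#' cell-scale fluorescent blobs a few pixels across; they are deliberately
#' explicit and never adapted silently to the image.
#'
#' @param smoothing_sigma Gaussian blur scale in pixels (>= 0; 0 disables).
#' @param threshold_mode `"otsu"` (computed on in-mask pixels only, so
#'   bright excluded regions such as autofluorescent epithelium cannot skew
#'   the threshold) or `"absolute"`.
#' @param threshold_value intensity cutoff, required iff mode is
#'   `"absolute"`.
#' @param min_area,max_area object area gates in pixels.
#' @param split_touching if `TRUE`, components larger than `2 * min_area`
#'   are split by local-maximum-seeded watershed on the smoothed intensity.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(smoothing_sigma = 2, threshold_mode = c("otsu", "absolute"),
                             threshold_value = NULL, min_area = 20,
                             max_area = 2000, split_touching = FALSE) {
  threshold_mode <- match.arg(threshold_mode)
  if (smoothing_sigma < 0)
    stop_nncoloc("nncoloc_schema", "smoothing_sigma must be >= 0")
  if (!(min_area > 0 && min_area <= max_area))
    stop_nncoloc("nncoloc_schema", "need 0 < min_area <= max_area")
  if (threshold_mode == "absolute" &&
      (is.null(threshold_value) || !is.finite(threshold_value)))
    stop_nncoloc("nncoloc_schema",
                 "absolute threshold mode requires a finite threshold_value")
  structure(list(smoothing_sigma = smoothing_sigma,
                 threshold_mode = threshold_mode,
                 threshold_value = threshold_value,
                 min_area = min_area, max_area = max_area,
                 split_touching = isTRUE(split_touching)),
            class = "detection_params")
}

# Otsu threshold on a vector of intensities (256-bin histogram, maximum
# between-class variance; returns the bin upper edge). Hand-rolled because
# it must run on in-mask pixels only, not a full rectangular image.
otsu_threshold <- function(v, n_bins = 256L) {
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, edges, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  edges[k + 1L]
}

weighted_centroid <- function(rows, cols, w) {
  c(x = sum(w * (cols - 1)) / sum(w), y = sum(w * (rows - 1)) / sum(w))
}

#' Detect cells in a marker channel
#'
#' Minimal auditable pipeline for fluorescent cell-scale blobs:
#' (1) Gaussian smooth; (2) zero pixels outside `mask$valid`; (3) binarize
#' by Otsu's method on in-mask intensities or an absolute cutoff;
#' (4) label 8-connected components; (5) drop components outside
#' `[min_area, max_area]`; (6) optionally split merged components, first by
#' watershed seeded at local maxima of the smoothed intensity, then by
#' flux-conserving weighted k-means for blobs whose integrated intensity
#' accounts for several cells but shows no resolvable dip (doublets closer
#' than the two-point resolution limit); (7) emit the intensity-weighted
#' centroid of each surviving component. Deterministic: identical inputs
#' give identical points in labeling scan order.
#'
#' @param image a [channel_image].
#' @param mask a [region_mask] of the same shape.
#' @param params a [detection_params].
#' @return A [point_set] with `provenance = "detected"`.
#' @export
detect_cells <- function(image, mask, params = detection_params()) {
  if (!inherits(image, "channel_image"))
    stop_nncoloc("nncoloc_schema", "image must be a channel_image")
  if (!inherits(mask, "region_mask"))
    stop_nncoloc("nncoloc_schema", "mask must be a region_mask")
  if (!all(dim(image$pixels) == dim(mask$valid)))
    stop_nncoloc("nncoloc_shape_mismatch", "image and mask shapes differ")
  if (!inherits(params, "detection_params"))
    stop_nncoloc("nncoloc_schema", "params must be detection_params")

  sm <- if (params$smoothing_sigma > 0)
    EBImage::gblur(image$pixels, sigma = params$smoothing_sigma)
  else image$pixels
  sm[!mask$valid] <- 0

  inmask <- sm[mask$valid]
  thr <- if (params$threshold_mode == "otsu") {
    if (diff(range(inmask)) == 0)
      stop_nncoloc("nncoloc_degenerate_image",
                   "in-mask image is constant; Otsu threshold undefined")
    otsu_threshold(inmask)
  } else params$threshold_value

  binary <- sm > thr & mask$valid
  empty <- point_set(numeric(0), numeric(0),
                     cell_class = image$channel_name,
                     sample_id = image$sample_id, provenance = "detected")
  if (!any(binary)) return(empty)

  lab <- cpp_label8(binary)
  n_lab <- max(lab)
  areas <- tabulate(lab[lab > 0L], n_lab)
  keep <- which(areas >= params$min_area & areas <= params$max_area)
  if (!length(keep)) return(empty)

  pix <- which(lab > 0L, arr.ind = TRUE)
  pix_lab <- lab[pix]
  # single-cell flux scale for declumping: the median integrated intensity
  # over detected objects is robust to a minority of merged doublets
  fluxes <- vapply(keep, function(k) {
    sel <- pix_lab == k
    sum(sm[pix[sel, , drop = FALSE]])
  }, numeric(1))
  unit_flux <- stats::median(fluxes)
  xs <- numeric(0); ys <- numeric(0)
  for (k in keep) {
    sel <- pix_lab == k
    rows <- pix[sel, 1]; cols <- pix[sel, 2]
    if (params$split_touching && areas[k] > 2 * params$min_area) {
      sub <- split_component(sm, rows, cols, params, unit_flux)
      for (s in sub) {
        cen <- weighted_centroid(s$rows, s$cols, sm[cbind(s$rows, s$cols)])
        xs <- c(xs, cen["x"]); ys <- c(ys, cen["y"])
      }
    } else if (params$split_touching &&
               flux_multiplicity(sum(sm[cbind(rows, cols)]), unit_flux) > 1) {
      for (s in flux_split(rows, cols, sm[cbind(rows, cols)],
                           flux_multiplicity(sum(sm[cbind(rows, cols)]),
                                             unit_flux))) {
        cen <- weighted_centroid(s$rows, s$cols, sm[cbind(s$rows, s$cols)])
        xs <- c(xs, cen["x"]); ys <- c(ys, cen["y"])
      }
    } else {
      cen <- weighted_centroid(rows, cols, sm[cbind(rows, cols)])
      xs <- c(xs, cen["x"]); ys <- c(ys, cen["y"])
    }
  }
  # a concave component's centroid can fall on an excluded pixel; snap such
  # points to the component's brightest pixel so output honours the mask
  for (i in seq_along(xs)) {
    ri <- round(ys[i]) + 1; ci <- round(xs[i]) + 1
    if (!mask$valid[ri, ci]) {
      near <- which(binary, arr.ind = TRUE)
      d2 <- (near[, 2] - 1 - xs[i])^2 + (near[, 1] - 1 - ys[i])^2
      b <- which.min(d2)
      xs[i] <- near[b, 2] - 1; ys[i] <- near[b, 1] - 1
    }
  }
  point_set(xs, ys, cell_class = image$channel_name,
            sample_id = image$sample_id, provenance = "detected",
            shape = dim(image$pixels))
}

# integer number of cells a blob's integrated intensity accounts for
flux_multiplicity <- function(flux, unit_flux) {
  if (!is.finite(unit_flux) || unit_flux <= 0) return(1L)
  max(1L, min(4L, as.integer(round(flux / unit_flux))))
}

# Deterministic weighted k-means split of one pixel cloud into m objects:
# centers start spread along the principal axis, then standard Lloyd
# iterations with intensity weights. No RNG involved.
flux_split <- function(rows, cols, w, m) {
  x <- cols - 1; y <- rows - 1
  cx <- sum(w * x) / sum(w); cy <- sum(w * y) / sum(w)
  dx <- x - cx; dy <- y - cy
  ang <- 0.5 * atan2(2 * sum(w * dx * dy),
                     sum(w * dx * dx) - sum(w * dy * dy))
  proj <- dx * cos(ang) + dy * sin(ang)
  qs <- stats::quantile(proj, probs = (seq_len(m) - 0.5) / m,
                        names = FALSE, type = 1)
  cen <- cbind(cx + qs * cos(ang), cy + qs * sin(ang))
  assign <- rep(1L, length(x))
  for (it in 1:25) {
    d2 <- vapply(seq_len(m), function(j)
      (x - cen[j, 1])^2 + (y - cen[j, 2])^2, numeric(length(x)))
    new_assign <- max.col(-d2, ties.method = "first")
    if (all(new_assign == assign) && it > 1) break
    assign <- new_assign
    for (j in seq_len(m)) {
      sel <- assign == j
      if (any(sel)) cen[j, ] <- c(sum(w[sel] * x[sel]) / sum(w[sel]),
                                  sum(w[sel] * y[sel]) / sum(w[sel]))
    }
  }
  lapply(unique(assign), function(j)
    list(rows = rows[assign == j], cols = cols[assign == j]))
}

# Split of one oversized component: watershed on the smoothed intensity
# seeded at local maxima (EBImage) separates cells with an intensity dip;
# sub-objects whose integrated intensity still accounts for several cells
# (doublets merged below the dip-resolution limit) are then divided by
# flux-conserving weighted k-means. Falls back to the unsplit component if
# nothing survives the area gate.
split_component <- function(sm, rows, cols, params, unit_flux = NA_real_) {
  r0 <- min(rows); r1 <- max(rows); c0 <- min(cols); c1 <- max(cols)
  sub <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
  sub[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- sm[cbind(rows, cols)]
  tol <- 0.015 * max(sub)
  w <- EBImage::watershed(sub, tolerance = tol, ext = 1L)
  out <- list()
  for (l in seq_len(max(w))) {
    idx <- which(w == l, arr.ind = TRUE)
    if (nrow(idx) < params$min_area) next
    obj <- list(rows = idx[, 1] + r0 - 1L, cols = idx[, 2] + c0 - 1L)
    ww <- sm[cbind(obj$rows, obj$cols)]
    mlt <- flux_multiplicity(sum(ww), unit_flux)
    if (mlt > 1L)
      out <- c(out, flux_split(obj$rows, obj$cols, ww, mlt))
    else out[[length(out) + 1L]] <- obj
  }
  if (!length(out)) out <- list(list(rows = rows, cols = cols))
  out
}
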