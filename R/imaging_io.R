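#' Construct a single-channel image
#'
#' The elementary raster container: one marker channel of one sample. Pixels
#' are addressed by a 0-based continuous coordinate system in which `x` is
#' the column index and `y` the row index; the center of pixel `(row i,
#' col j)` is at `(x = j, y = i)`. All distances downstream are computed in
#' pixel units; `pixel_size` (microns per pixel edge) converts to physical
#' units for reporting only.
#'
#' @param pixels numeric matrix of non-negative finite intensities.
#' @param channel_name marker label, e.g. `"CD45"`, `"GFP"`, `"p16"`.
#' @param pixel_size microns per pixel edge; default 1.
#' @param sample_id opaque sample identifier.
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, channel_name, pixel_size = 1.0,
                          sample_id = NA_character_) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop_nncoloc("nncoloc_bad_image", "image must have >= 1 row and column")
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop_nncoloc("nncoloc_bad_image", "intensities must be finite and >= 0")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop_nncoloc("nncoloc_bad_image", "pixel_size must be a positive scalar")
  structure(list(pixels = pixels, channel_name = as.character(channel_name),
                 pixel_size = pixel_size, sample_id = sample_id),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s  %d x %d px  (%.3g um/px)  sample %s\n",
              x$channel_name, nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              x$sample_id))
  invisible(x)
}

#' Construct a region mask
#'
#' Defines the valid analysis region (interstitial stroma) and the named
#' excluded regions (epithelium, hair follicles, muscle, background). Random
#' placement in the Monte-Carlo null and cell detection both honour `valid`.
#'
#' @param valid logical matrix; `TRUE` = pixel available for analysis.
#' @param excluded named list of logical matrices, same shape as `valid`,
#'   each disjoint from `valid`.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(valid, excluded = list()) {
  valid <- as.matrix(valid)
  if (!is.logical(valid)) valid <- valid != 0
  if (!any(valid))
    stop_nncoloc("nncoloc_empty_valid", "valid region contains no pixel")
  for (nm in names(excluded)) {
    ex <- excluded[[nm]]
    if (!all(dim(ex) == dim(valid)))
      stop_nncoloc("nncoloc_shape_mismatch",
                   sprintf("excluded region '%s' shape differs from valid", nm))
    if (any(ex & valid))
      stop_nncoloc("nncoloc_mask_overlap",
                   sprintf("excluded region '%s' overlaps valid region", nm))
    excluded[[nm]] <- ex != 0
  }
  structure(list(valid = valid, excluded = excluded), class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %d x %d px, %d valid (%.1f%%), excluded: %s\n",
              nrow(x$valid), ncol(x$valid), sum(x$valid),
              100 * mean(x$valid),
              if (length(x$excluded)) paste(names(x$excluded), collapse = ", ")
              else "none"))
  invisible(x)
}

#' Construct a point set
#'
#' Planar cell coordinates for one cell class in one sample, in the 0-based
#' `x = column`, `y = row` pixel coordinate convention. Duplicates are
#' permitted (two detections can coincide); the set may be empty.
#'
#' @param x,y numeric coordinate vectors of equal length.
#' @param cell_class marker label of the class.
#' @param sample_id opaque sample identifier.
#' @param provenance one of `"manual"`, `"detected"`, `"simulated"`.
#' @param shape optional `c(nrow, ncol)` raster shape to validate bounds
#'   against (points must satisfy `-0.5 <= x <= ncol - 0.5`, same for y).
#' @return A `point_set`, a data frame with columns `x`, `y`.
#' @export
point_set <- function(x, y, cell_class = NA_character_,
                      sample_id = NA_character_,
                      provenance = c("manual", "detected", "simulated"),
                      shape = NULL) {
  provenance <- match.arg(provenance)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop_nncoloc("nncoloc_schema", "x and y must have equal length")
  if (length(x) && (!all(is.finite(x)) || !all(is.finite(y))))
    stop_nncoloc("nncoloc_schema", "coordinates must be finite")
  if (!is.null(shape) && length(x)) {
    if (any(x < -0.5 | x > shape[2] - 0.5 | y < -0.5 | y > shape[1] - 0.5))
      stop_nncoloc("nncoloc_out_of_bounds",
                   "point outside the raster bounds of its sample")
  }
  structure(data.frame(x = x, y = y),
            cell_class = cell_class, sample_id = sample_id,
            provenance = provenance,
            class = c("point_set", "data.frame"))
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set> %d points, class %s, sample %s, provenance %s\n",
              nrow(x), attr(x, "cell_class"), attr(x, "sample_id"),
              attr(x, "provenance")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Read one channel from a (possibly multi-page) TIFF
#'
#' Channel-to-page mapping is declared in `channel_map`, never inferred from
#' TIFF metadata (acquisition software writes unreliable channel tags).
#'
#' @param path TIFF file, one page per channel.
#' @param channel_name channel to extract.
#' @param channel_map named integer vector mapping channel names to 1-based
#'   page numbers; defaults to page 1 for a single-page file.
#' @param pixel_size microns per pixel; default 1.
#' @param sample_id sample identifier; defaults to the file name.
#' @return A [channel_image].
#' @export
read_image <- function(path, channel_name, channel_map = NULL,
                       pixel_size = 1.0, sample_id = NULL) {
  if (!file.exists(path))
    stop_nncoloc("nncoloc_missing_file", paste("no such file:", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop_nncoloc("nncoloc_unreadable",
                                   paste("cannot read TIFF:", conditionMessage(e))))
  if (is.null(channel_map)) {
    if (length(pages) != 1L)
      stop_nncoloc("nncoloc_bad_channel",
                   "multi-page TIFF requires an explicit channel_map")
    page <- 1L
  } else {
    if (!channel_name %in% names(channel_map))
      stop_nncoloc("nncoloc_bad_channel",
                   sprintf("channel '%s' not present in channel map (%s)",
                           channel_name,
                           paste(names(channel_map), collapse = ", ")))
    page <- channel_map[[channel_name]]
    if (page < 1L || page > length(pages))
      stop_nncoloc("nncoloc_bad_channel",
                   sprintf("channel '%s' maps to page %d but file has %d page(s)",
                           channel_name, page, length(pages)))
  }
  px <- pages[[page]]
  if (length(dim(px)) == 3L) px <- px[, , 1L]  # collapse grey-stored-as-RGB
  channel_image(px, channel_name, pixel_size = pixel_size,
                sample_id = if (is.null(sample_id)) basename(path) else sample_id)
}

#' Write a channel image (or list of them) as a TIFF
#'
#' @param images a [channel_image] or list of them (one page each).
#' @param path output path.
#' @param bits bits per sample (8, 16 or 32); integer data up to
#'   `2^bits - 1` round-trips exactly through [read_image()].
#' @export
write_image <- function(images, path, bits = 16L) {
  if (inherits(images, "channel_image")) images <- list(images)
  scale <- 2^bits - 1
  pages <- lapply(images, function(im) im$pixels / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

# Even-odd ray-casting point-in-polygon test, vectorized over query points.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    if (yi != yj) {
      cross <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, cross)
    }
    j <- i
  }
  inside
}

seg_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

check_simple_polygon <- function(vx, vy, name) {
  n <- length(vx)
  if (n < 3L)
    stop_nncoloc("nncoloc_bad_polygon",
                 sprintf("polygon '%s' has fewer than 3 vertices", name))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1L || (i == 1L && j == n)) next
      if (seg_intersect(c(vx[i], vy[i]), c(vx[i %% n + 1L], vy[i %% n + 1L]),
                        c(vx[j], vy[j]), c(vx[j %% n + 1L], vy[j %% n + 1L])))
        stop_nncoloc("nncoloc_self_intersecting",
                     sprintf("polygon '%s' is self-intersecting", name))
    }
  }
}

# Rasterize one polygon onto shape = c(nrow, ncol): pixel (i, j) is in the
# polygon iff its center (x = j, y = i, 0-based) is inside (even-odd rule).
rasterize_polygon <- function(vertices, shape, name = "region") {
  v <- do.call(rbind, lapply(vertices, as.numeric))
  check_simple_polygon(v[, 1], v[, 2], name)
  cx <- rep(seq_len(shape[2]) - 1L, each = shape[1])   # x = col, column-major
  cy <- rep(seq_len(shape[1]) - 1L, times = shape[2])  # y = row
  matrix(points_in_polygon(cx, cy, v[, 1], v[, 2]), shape[1], shape[2])
}

#' Read a region mask from a raster file or polygon JSON
#'
#' Accepts either a binary raster (TIFF or PNG; any nonzero pixel = valid
#' stroma) or a JSON document of named excluded polygons with an optional
#' enclosing tissue polygon:
#' `{"regions": [{"name": "epithelium", "vertices": [[x, y], ...]}, ...],
#'   "tissue": [[x, y], ...]}`.
#' Polygons are rasterized by the pixel-center rule; the valid region is the
#' tissue polygon (or the whole frame) minus the union of excluded regions.
#'
#' @param path raster or JSON file (dispatch on extension: .json vs raster).
#' @param shape required raster shape `c(nrow, ncol)`; checked against
#'   raster input, used to rasterize polygons.
#' @return A [region_mask].
#' @export
read_mask <- function(path, shape) {
  if (!file.exists(path))
    stop_nncoloc("nncoloc_missing_file", paste("no such file:", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    doc <- jsonlite::read_json(path)
    tissue <- if (!is.null(doc$tissue))
      rasterize_polygon(doc$tissue, shape, "tissue")
    else matrix(TRUE, shape[1], shape[2])
    excluded <- list()
    acc <- matrix(FALSE, shape[1], shape[2])
    for (reg in doc$regions) {
      r <- rasterize_polygon(reg$vertices, shape, reg$name)
      excluded[[reg$name]] <- r
      acc <- acc | r
    }
    valid <- tissue & !acc
    if (!is.null(doc$tissue)) excluded[["background"]] <- !tissue & !acc
    excluded <- lapply(excluded, function(e) e & !valid)
    if (!any(valid))
      stop_nncoloc("nncoloc_empty_valid",
                   "valid region empty after applying exclusions")
    region_mask(valid, excluded)
  } else {
    raster <- if (ext == "png") png::readPNG(path)
    else tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(raster)) == 3L) raster <- raster[, , 1L]
    if (!all(dim(raster) == shape))
      stop_nncoloc("nncoloc_shape_mismatch",
                   sprintf("mask is %d x %d but expected %d x %d",
                           nrow(raster), ncol(raster), shape[1], shape[2]))
    valid <- raster != 0
    if (!any(valid))
      stop_nncoloc("nncoloc_empty_valid", "raster mask has no valid pixel")
    region_mask(valid, excluded = list(background = !valid))
  }
}

#' Write a region mask as a binary TIFF (valid = 1)
#' @param mask a [region_mask].
#' @param path output TIFF path.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(mask$valid * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read manually annotated cell coordinates from CSV
#'
#' The human-sample workflow: an annotator clicks cell positions and exports
#' a table with header columns `x, y` (pixel coordinates) and optionally
#' `cell_class`, `sample_id`.
#'
#' @param path CSV file.
#' @param shape optional raster shape `c(nrow, ncol)` for bounds validation.
#' @return A [point_set] with `provenance = "manual"`.
#' @export
read_points <- function(path, shape = NULL) {
  if (!file.exists(path))
    stop_nncoloc("nncoloc_missing_file", paste("no such file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(df)))
    stop_nncoloc("nncoloc_schema",
                 sprintf("points CSV must have columns x, y (found: %s)",
                         paste(names(df), collapse = ", ")))
  if (!is.numeric(df$x) || !is.numeric(df$y))
    stop_nncoloc("nncoloc_schema", "columns x and y must be numeric")
  point_set(df$x, df$y,
            cell_class = if ("cell_class" %in% names(df) && nrow(df))
              df$cell_class[1] else NA_character_,
            sample_id = if ("sample_id" %in% names(df) && nrow(df))
              df$sample_id[1] else NA_character_,
            provenance = "manual", shape = shape)
}

#' Write a point set to CSV
#' @param points a [point_set].
#' @param path output CSV path.
#' @export
write_points <- function(points, path) {
  df <- as.data.frame(points)
  # 17 significant digits: doubles survive the text round-trip bit-exactly
  df$x <- sprintf("%.17g", df$x)
  df$y <- sprintf("%.17g", df$y)
  df$cell_class <- attr(points, "cell_class")
  df$sample_id <- attr(points, "sample_id")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Atomic write: serialize to a sibling temp file, then rename into place,
# so a failed run never leaves a truncated result document.
write_json_atomic <- function(x, path, digits = I(17)) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json.tmp")
  ok <- tryCatch({
    suppressWarnings(jsonlite::write_json(x, tmp, auto_unbox = TRUE,
                                          digits = digits,
                                          null = "null", na = "null"))
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.rename(tmp, path)) {
    if (file.exists(tmp)) unlink(tmp)
    stop_nncoloc("nncoloc_io", paste("cannot write result to", path))
  }
  invisible(path)
}

#' Write an analysis result or cohort summary to JSON
#'
#' Serializes every field plus the configuration echo, seed and package
#' version; doubles are written at 17 significant digits so
#' [read_result()] recovers them losslessly.
#'
#' @param x an `nn_assoc` (per-sample result) or `group_summary` object.
#' @param path output JSON path (written atomically).
#' @export
write_result <- function(x, path) {
  if (inherits(x, "nn_assoc")) {
    doc <- list(
      type = "nn_assoc",
      sample_id = x$sample_id,
      mode = x$observed$mode,
      observed = list(distances = x$observed$distances,
                      median_distance = x$observed$median_distance,
                      n_source = x$observed$n_source,
                      n_target = x$observed$n_target),
      null = list(n_rounds = x$null$n_rounds,
                  mean_median = x$null$mean_median,
                  sd_median = x$null$sd_median,
                  seed = x$null$seed,
                  sampled_medians = x$null$sampled_medians),
      score = x$score, percentile = x$percentile,
      config_echo = x$config_echo,
      version = as.character(utils::packageVersion("nncoloc")))
  } else if (inherits(x, "group_summary")) {
    doc <- list(
      type = "group_summary",
      group_label = x$group_label, scores = x$scores,
      n_samples = x$n_samples, mean_score = x$mean_score,
      sd_score = x$sd_score, ci95 = x$ci95,
      association_call = x$association_call,
      version = as.character(utils::packageVersion("nncoloc")))
  } else stop_nncoloc("nncoloc_schema",
                      "write_result() accepts nn_assoc or group_summary")
  write_json_atomic(doc, path)
}

#' Read back a result written by [write_result()]
#' @param path JSON file.
#' @return The reconstructed `nn_assoc` or `group_summary` object.
#' @export
read_result <- function(path) {
  if (!file.exists(path))
    stop_nncoloc("nncoloc_missing_file", paste("no such file:", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(doc$type, "nn_assoc")) {
    obs <- nn_summary(doc$observed$distances, doc$mode,
                      n_target = doc$observed$n_target)
    null <- mc_null(doc$null$sampled_medians, doc$null$seed)
    res <- association_score(obs, null, sample_id = doc$sample_id,
                             config_echo = doc$config_echo)
    res
  } else if (identical(doc$type, "group_summary")) {
    summarize_group(doc$scores, doc$group_label)
  } else stop_nncoloc("nncoloc_schema", "unrecognized result document")
}
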