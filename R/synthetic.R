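#' Specification for a synthetic tissue sample
#'
#' Describes one simulated two-class sample: an irregular valid region
#' (tissue ellipse whose outer rim is "epithelium", with circular "follicle"
#' holes), a reference class ("parents", e.g. senescent cells) placed
#' uniformly, and a query class ("offspring", e.g. immune cells) placed
#' under one of three patterns — `csr` (complete spatial randomness,
#' independent of parents), `attracted` (Thomas-type clustering: each
#' offspring picks a uniform random parent and is displaced by an isotropic
#' Gaussian of scale `sigma_c`, re-drawn until inside the valid region) or
#' `inhibited` (uniform, re-drawn until at least `r_min` from every
#' parent). Rendering draws each cell as an isotropic Gaussian spot of
#' scale `spot_sigma` and peak `amplitude` on a constant `background`, with
#' optional Poisson shot noise and/or additive Gaussian read noise.
#'
#' @param shape raster dimensions `c(nrow, ncol)`.
#' @param n_parents,n_offspring class sizes.
#' @param pattern `"csr"`, `"attracted"` or `"inhibited"`.
#' @param sigma_c Gaussian displacement scale (px); required for
#'   `attracted`.
#' @param r_min exclusion radius (px); required for `inhibited`.
#' @param band_frac fraction of the tissue ellipse radius forming the
#'   epithelial rim.
#' @param n_holes number of circular follicle holes.
#' @param hole_radius `c(min, max)` follicle radius range (px).
#' @param spot_sigma rendered spot scale (px).
#' @param amplitude spot peak intensity above background.
#' @param background constant background intensity.
#' @param noise_model `"poisson"`, `"gaussian"` or `"none"`.
#' @param noise_sd read-noise standard deviation (gaussian model).
#' @param seed integer seed; every generator stage is bit-reproducible
#'   from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(shape = c(512L, 512L), n_parents = 30L,
                           n_offspring = 150L,
                           pattern = c("csr", "attracted", "inhibited"),
                           sigma_c = NULL, r_min = NULL,
                           band_frac = 0.15, n_holes = 6L,
                           hole_radius = c(8, 16),
                           spot_sigma = 0.7, amplitude = 150,
                           background = 10,
                           noise_model = c("poisson", "gaussian", "none"),
                           noise_sd = 3, seed = 1L) {
  pattern <- match.arg(pattern)
  noise_model <- match.arg(noise_model)
  if (any(shape < 1)) stop_nncoloc("nncoloc_schema", "shape must be positive")
  if (n_parents < 0 || n_offspring < 0)
    stop_nncoloc("nncoloc_schema", "counts must be >= 0")
  if (pattern == "attracted" && (is.null(sigma_c) || sigma_c <= 0))
    stop_nncoloc("nncoloc_schema", "attracted pattern requires sigma_c > 0")
  if (pattern == "inhibited" && (is.null(r_min) || r_min <= 0))
    stop_nncoloc("nncoloc_schema", "inhibited pattern requires r_min > 0")
  structure(list(shape = as.integer(shape), n_parents = as.integer(n_parents),
                 n_offspring = as.integer(n_offspring), pattern = pattern,
                 sigma_c = sigma_c, r_min = r_min, band_frac = band_frac,
                 n_holes = as.integer(n_holes), hole_radius = hole_radius,
                 spot_sigma = spot_sigma, amplitude = amplitude,
                 background = background, noise_model = noise_model,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate an irregular region mask
#'
#' Tissue = an ellipse inscribed in the frame; its outer rim (`band_frac`
#' of the normalized radius) is the excluded "epithelium"; `n_holes`
#' seeded circular "follicle" holes are cut from the interior; everything
#' outside the ellipse is "background". Valid stroma is the remainder.
#' Excluded regions and valid stroma partition the frame exactly.
#'
#' @param spec a [synthetic_spec].
#' @return A [region_mask] with excluded regions `epithelium`,
#'   `follicle_i`, `background`.
#' @export
generate_mask <- function(spec) {
  nr <- spec$shape[1]; nc <- spec$shape[2]
  cy <- (nr - 1) / 2; cx <- (nc - 1) / 2
  ay <- 0.48 * nr; ax <- 0.48 * nc
  px <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  py <- matrix(rep(seq_len(nr) - 1, times = nc), nr, nc)
  rho <- sqrt(((px - cx) / ax)^2 + ((py - cy) / ay)^2)
  background <- rho > 1
  epithelium <- rho <= 1 & rho > (1 - spec$band_frac)
  interior <- rho <= (1 - spec$band_frac)
  excluded <- list(epithelium = epithelium)
  taken <- epithelium
  if (spec$n_holes > 0) {
    holes <- with_seed(spec$seed, {
      lapply(seq_len(spec$n_holes), function(i) {
        list(hx = runif(1, 0.15 * nc, 0.85 * nc),
             hy = runif(1, 0.15 * nr, 0.85 * nr),
             hr = runif(1, spec$hole_radius[1], spec$hole_radius[2]))
      })
    })
    for (i in seq_along(holes)) {
      h <- holes[[i]]
      circ <- (px - h$hx)^2 + (py - h$hy)^2 <= h$hr^2
      reg <- circ & interior & !taken
      excluded[[paste0("follicle_", i)]] <- reg
      taken <- taken | reg
    }
  }
  excluded[["background"]] <- background
  valid <- interior & !taken
  if (!any(valid))
    stop_nncoloc("nncoloc_empty_valid", "spec leaves no valid pixel")
  region_mask(valid, excluded)
}

# uniform placement over the valid area: uniform pixel + sub-pixel jitter
draw_uniform <- function(n, valid_idx, nr) {
  pick <- valid_idx[sample.int(length(valid_idx), n, replace = TRUE)]
  rows <- (pick - 1L) %% nr + 1L
  cols <- (pick - 1L) %/% nr + 1L
  list(x = cols - 1 + runif(n, -0.5, 0.5), y = rows - 1 + runif(n, -0.5, 0.5))
}

in_valid <- function(x, y, valid) {
  nr <- nrow(valid); nc <- ncol(valid)
  ri <- round(y) + 1; ci <- round(x) + 1
  ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
  ok[ok] <- valid[cbind(ri[ok], ci[ok])]
  ok
}

#' Generate parent and offspring point classes
#'
#' Parents are uniform over the valid region. Offspring follow
#' `spec$pattern` (see [synthetic_spec()]); placements violating the mask
#' (or, for `inhibited`, the exclusion radius) are rejection-resampled so
#' the within-mask law is exactly the intended one, with a cap of 10000
#' attempts per point.
#'
#' @param spec a [synthetic_spec].
#' @param mask a [region_mask] (typically from [generate_mask()]).
#' @return `list(parents, offspring)` of [point_set]s with
#'   `provenance = "simulated"`.
#' @export
generate_points <- function(spec, mask) {
  valid <- mask$valid
  valid_idx <- which(valid)
  nr <- nrow(valid)
  with_seed(spec$seed + 1L, {
    par <- draw_uniform(spec$n_parents, valid_idx, nr)
    if (spec$n_offspring == 0) {
      off <- list(x = numeric(0), y = numeric(0))
    } else if (spec$pattern == "csr") {
      off <- draw_uniform(spec$n_offspring, valid_idx, nr)
    } else if (spec$pattern == "attracted") {
      if (spec$n_parents < 1L)
        stop_nncoloc("nncoloc_schema", "attracted pattern needs >= 1 parent")
      ox <- numeric(spec$n_offspring); oy <- numeric(spec$n_offspring)
      for (i in seq_len(spec$n_offspring)) {
        for (att in seq_len(10000L)) {
          k <- sample.int(spec$n_parents, 1L)
          x <- par$x[k] + rnorm(1, sd = spec$sigma_c)
          y <- par$y[k] + rnorm(1, sd = spec$sigma_c)
          if (in_valid(x, y, valid)) break
          if (att == 10000L)
            stop_nncoloc("nncoloc_generation_failure",
                         "could not place attracted offspring in 10000 tries")
        }
        ox[i] <- x; oy[i] <- y
      }
      off <- list(x = ox, y = oy)
    } else {
      ox <- numeric(spec$n_offspring); oy <- numeric(spec$n_offspring)
      for (i in seq_len(spec$n_offspring)) {
        for (att in seq_len(10000L)) {
          cand <- draw_uniform(1L, valid_idx, nr)
          d2 <- (cand$x - par$x)^2 + (cand$y - par$y)^2
          if (!length(d2) || min(d2) >= spec$r_min^2) break
          if (att == 10000L)
            stop_nncoloc("nncoloc_generation_failure",
                         "could not place inhibited offspring in 10000 tries")
        }
        ox[i] <- cand$x; oy[i] <- cand$y
      }
      off <- list(x = ox, y = oy)
    }
    list(parents = point_set(par$x, par$y, cell_class = "reference",
                             sample_id = paste0("sim", spec$seed),
                             provenance = "simulated", shape = spec$shape),
         offspring = point_set(off$x, off$y, cell_class = "query",
                               sample_id = paste0("sim", spec$seed),
                               provenance = "simulated", shape = spec$shape))
  })
}

#' Render a point class as a fluorescence channel
#'
#' Sum of isotropic Gaussian spots (scale `spot_sigma`, peak `amplitude`)
#' on a constant `background`, followed by the configured noise: Poisson
#' shot noise on signal plus background (the standard fluorescence forward
#' model), additive Gaussian read noise, or none.
#'
#' @param points a [point_set] within `spec$shape`.
#' @param spec a [synthetic_spec].
#' @param channel_name marker label for the output channel.
#' @return A [channel_image]; the generating coordinates stay available as
#'   the input `points` (ground truth for detection benchmarks).
#' @export
render_image <- function(points, spec, channel_name = "synthetic") {
  nr <- spec$shape[1]; nc <- spec$shape[2]
  img <- matrix(spec$background, nr, nc)
  half <- ceiling(5 * spec$spot_sigma)
  s2 <- 2 * spec$spot_sigma^2
  for (i in seq_len(nrow(points))) {
    x0 <- points$x[i]; y0 <- points$y[i]
    r0 <- max(1L, floor(y0) + 1L - half); r1 <- min(nr, floor(y0) + 1L + half)
    c0 <- max(1L, floor(x0) + 1L - half); c1 <- min(nc, floor(x0) + 1L + half)
    rr <- r0:r1; cc <- c0:c1
    gy <- exp(-((rr - 1 - y0)^2) / s2)
    gx <- exp(-((cc - 1 - x0)^2) / s2)
    img[rr, cc] <- img[rr, cc] + spec$amplitude * (gy %o% gx)
  }
  img <- with_seed(spec$seed + 2L + nrow(points), {
    switch(spec$noise_model,
           none = img,
           poisson = matrix(rpois(length(img), img), nr, nc),
           gaussian = {
             noisy <- matrix(rpois(length(img), img), nr, nc) +
               matrix(rnorm(length(img), sd = spec$noise_sd), nr, nc)
             pmax(noisy, 0)
           })
  })
  channel_image(img, channel_name, sample_id = paste0("sim", spec$seed))
}

#' Generate one complete synthetic sample
#'
#' Convenience wrapper: mask, parent and offspring point sets, and (if
#' `render = TRUE`) the two rendered marker channels.
#'
#' @param spec a [synthetic_spec].
#' @param render also render the two channels.
#' @return `list(mask, parents, offspring, reference_image?, query_image?)`.
#' @export
generate_sample <- function(spec, render = FALSE) {
  mask <- generate_mask(spec)
  pts <- generate_points(spec, mask)
  out <- list(mask = mask, parents = pts$parents, offspring = pts$offspring)
  if (render) {
    out$reference_image <- render_image(pts$parents, spec, "reference")
    qspec <- spec; qspec$seed <- spec$seed + 7919L  # independent noise stream
    out$query_image <- render_image(pts$offspring, qspec, "query")
  }
  out
}
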