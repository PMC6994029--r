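# Radius multiplier per dispersion class: strictly increasing so the
# rendered footprint of class k is a subset of class k+1's at fixed
# centre and rotation.
.CLASS_RADIUS_SCALE <- c(0.25, 0.45, 0.65, 0.85, 1.0)

# Canonical background colours. Green and blue are strongly chromatic so
# a hue band can pick the background out for transparency measurement.
.BACKGROUNDS <- list(
  white = c(255, 255, 255),
  black = c(0, 0, 0),
  green = c(0, 170, 0),
  blue  = c(0, 90, 200)
)

#' Specify one synthetic chromatosome
#'
#' A chromatosome is rendered as a solid core disk plus, for dispersion
#' classes 2-5, `n_branches` radial rays whose length grows with the
#' class (multipliers 0.25, 0.45, 0.65, 0.85, 1.0 of `base_radius`) and
#' whose width tapers linearly from the core radius down to 1 px at the
#' tip. Class 1 is the punctate state: the core disk only. The shapes are
#' a simulator convention that echoes the punctate-to-dispersed series of
#' the 5-class dispersion scale; they are not a claim about real
#' chromatosome morphology.
#'
#' @param center numeric `(row, col)`, 0-based pixel coordinates of the
#'   chromatosome centre.
#' @param dispersion_class integer 1..5.
#' @param base_radius maximum ray length in pixels (at class 5).
#' @param n_branches number of rays for classes >= 2.
#' @param rotation ray rotation offset in radians (fixed per
#'   chromatosome so class sweeps nest).
#' @param pigment_rgb length-3 pigment colour, default black.
#' @return an object of class `chromatosome_spec`.
#' @export
chromatosome_spec <- function(center, dispersion_class, base_radius = 12,
                              n_branches = 8, rotation = 0,
                              pigment_rgb = c(0, 0, 0)) {
  if (!dispersion_class %in% 1:5) stop("dispersion_class must be in 1..5")
  if (base_radius <= 0) stop("base_radius must be positive")
  if (n_branches < 0) stop("n_branches must be >= 0")
  structure(list(center = as.numeric(center),
                 dispersion_class = as.integer(dispersion_class),
                 base_radius = base_radius,
                 n_branches = as.integer(n_branches),
                 rotation = rotation,
                 pigment_rgb = as.numeric(pigment_rgb)),
            class = "chromatosome_spec")
}

#' Specify a synthetic chromatosome scene
#'
#' @param height,width canvas size in pixels.
#' @param background `"white"`, `"black"`, `"green"` or `"blue"`; the
#'   uniform backdrop the tissue is photographed on.
#' @param chromatosomes list of [chromatosome_spec]s (may overlap).
#' @param noise_sigma standard deviation of the additive Gaussian camera
#'   noise, in grey levels (applied per channel, clamped to bytes).
#' @param seed integer seed; identical specs render byte-identical images.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(height, width, background = "white",
                       chromatosomes = list(), noise_sigma = 0, seed = 1) {
  background <- match.arg(background, names(.BACKGROUNDS))
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(height = as.integer(height), width = as.integer(width),
                 background = background, chromatosomes = chromatosomes,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "scene_spec")
}

# run code with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  code
}

# footprint of one chromatosome as TRUE cells of an H x W matrix.
# Core disk always; rays for classes >= 2. Ray width at arc distance s
# along a ray of length L is w0 + (1 - w0) * s / L (w0 = core radius),
# which is non-decreasing in L at fixed s, giving class nesting.
.chromatosome_mask <- function(cs, H, W) {
  scale <- .CLASS_RADIUS_SCALE[cs$dispersion_class]
  L <- cs$base_radius * scale
  core_r <- cs$base_radius * .CLASS_RADIUS_SCALE[1]
  reach <- ceiling(max(L, core_r)) + 1L
  r0 <- max(1L, floor(cs$center[1] + 1 - reach))
  r1 <- min(H, ceiling(cs$center[1] + 1 + reach))
  c0 <- max(1L, floor(cs$center[2] + 1 - reach))
  c1 <- min(W, ceiling(cs$center[2] + 1 + reach))
  if (r0 > r1 || c0 > c1) stop("chromatosome lies fully outside the canvas")
  rows <- r0:r1; cols <- c0:c1
  dy <- outer(rows - 1 - cs$center[1], rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - 1 - cs$center[2])
  rad <- sqrt(dy^2 + dx^2)
  m <- rad <= core_r
  if (cs$dispersion_class >= 2L && cs$n_branches > 0L) {
    ang <- atan2(dy, dx)
    w0 <- core_r
    for (b in seq_len(cs$n_branches)) {
      theta <- cs$rotation + 2 * pi * (b - 1) / cs$n_branches
      # distance along / across the ray direction
      s <- rad * cos(ang - theta)
      dperp <- abs(rad * sin(ang - theta))
      w <- w0 + (1 - w0) * s / L
      m <- m | (s >= 0 & s <= L & dperp <= w / 2)
    }
  }
  if (!any(m)) stop("chromatosome footprint is empty")
  list(rows = rows, cols = cols, mask = m)
}

#' Render a synthetic scene with exact ground truth
#'
#' Paints the background, unions all chromatosome footprints into a pigment
#' mask (frozen as ground truth before any noise), paints the pigment, and
#' finally adds i.i.d. Gaussian camera noise per channel, rounded and
#' clamped to bytes. The returned cover is therefore exact by
#' construction.
#'
#' @param spec a [scene_spec].
#' @return list with `image` (a [raster_image], sRGB) and `truth` (class
#'   `ground_truth`: `pigment_mask`, `cover`, `per_chromatosome_class`,
#'   `mean_ci`).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$height; W <- spec$width
  bg <- .BACKGROUNDS[[spec$background]]
  px <- array(rep(bg, each = H * W), c(H, W, 3))
  pigment_mask <- matrix(FALSE, H, W)
  for (cs in spec$chromatosomes) {
    stopifnot(inherits(cs, "chromatosome_spec"))
    if (cs$center[1] < -cs$base_radius || cs$center[1] > H - 1 + cs$base_radius ||
        cs$center[2] < -cs$base_radius || cs$center[2] > W - 1 + cs$base_radius)
      stop("chromatosome lies fully outside the canvas")
    fp <- .chromatosome_mask(cs, H, W)
    sub <- pigment_mask[fp$rows, fp$cols]
    pigment_mask[fp$rows, fp$cols] <- sub | fp$mask
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[fp$rows, fp$cols][fp$mask] <- cs$pigment_rgb[ch]
      px[, , ch] <- plane
    }
  }
  classes <- vapply(spec$chromatosomes, `[[`, integer(1), "dispersion_class")
  truth <- structure(list(
    pigment_mask = pigment_mask,
    cover = sum(pigment_mask) / (H * W),
    per_chromatosome_class = classes,
    mean_ci = if (length(classes)) mean(classes) else NA_real_
  ), class = "ground_truth")
  if (spec$noise_sigma > 0) {
    px <- .with_seed(spec$seed, {
      noisy <- px + stats::rnorm(length(px), 0, spec$noise_sigma)
      array(pmin(pmax(.round_half_up(noisy), 0), 255), dim(px))
    })
  }
  list(image = raster_image(px, space = "sRGB"), truth = truth)
}

# derive an independent per-scene seed from (seed, index), kept < 2^31
.scene_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 7919) %% 2147483647)
}

#' Simulate a CI / pigment-cover dataset end to end
#'
#' Renders `n_scenes` seeded scenes spanning the five dispersion classes
#' and a range of chromatosome densities, runs the full measurement
#' pipeline on each (HSB conversion, maximum-entropy brightness threshold,
#' particle analysis, PiC), and returns one row per scene. The table is
#' suitable for [fit_beta_regression] of `measured_pic` on `mean_ci`.
#'
#' Each scene's chromatosomes share a dominant dispersion class; a small
#' fraction deviate by one class, mimicking the within-image variation a
#' human scorer averages over.
#'
#' @param n_scenes number of scenes.
#' @param class_distribution weights for the dominant class 1..5.
#' @param density_range integer range: chromatosomes per scene.
#' @param seed integer master seed; each scene uses an independent stream
#'   derived from `(seed, scene index)`.
#' @param height,width scene size in pixels.
#' @param base_radius chromatosome size in pixels.
#' @param noise_sigma camera noise (grey levels).
#' @return data.frame with columns `scene`, `n_chromatosomes`, `mean_ci`,
#'   `true_cover`, `measured_pic`.
#' @export
simulate_ci_pic_dataset <- function(n_scenes, class_distribution = rep(1, 5),
                                    density_range = c(4, 28), seed = 1,
                                    height = 128, width = 128,
                                    base_radius = 12, noise_sigma = 8) {
  stopifnot(n_scenes >= 1)
  rows <- lapply(seq_len(n_scenes), function(j) {
    sseed <- .scene_seed(seed, j)
    sc <- .with_seed(sseed, {
      k <- sample(seq.int(density_range[1], density_range[2]), 1)
      dominant <- sample(1:5, 1, prob = class_distribution)
      cls <- pmin(pmax(dominant +
        sample(c(-1, 0, 1), k, replace = TRUE, prob = c(.15, .7, .15)),
        1), 5)
      margin <- base_radius
      chrom <- lapply(seq_len(k), function(i) chromatosome_spec(
        center = c(stats::runif(1, margin, height - 1 - margin),
                   stats::runif(1, margin, width - 1 - margin)),
        dispersion_class = cls[i],
        base_radius = base_radius,
        rotation = stats::runif(1, 0, 2 * pi)
      ))
      scene_spec(height, width, background = "white",
                 chromatosomes = chrom, noise_sigma = noise_sigma,
                 seed = sseed)
    })
    rs <- render_scene(sc)
    res <- measure_pic(rs$image, measurement_config(target = "dark_pigment",
                                                    background = "white",
                                                    method = "maxentropy"))
    data.frame(scene = j,
               n_chromatosomes = length(sc$chromatosomes),
               mean_ci = rs$truth$mean_ci,
               true_cover = rs$truth$cover,
               measured_pic = res$pic)
  })
  do.call(rbind, rows)
}
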