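# Default hue bands (bytes, circular) used to select each chromatic
# background for transparency measurement; centred on the rendered
# background hues (green ~85, blue ~151) with a +/-18 byte (~25 degree)
# half-width.
.BG_HUE_BANDS <- list(
  green = c(67L, 103L),
  blue  = c(133L, 169L)
)

#' Configure a pigment-cover measurement
#'
#' Bundles everything a batch run needs so that each result row carries
#' full provenance: what is being measured, on which background, how the
#' threshold is chosen, the optional ROI and contrast normalization.
#'
#' Dark pigment is measured on a white background (mask: brightness at or
#' below the automatic threshold); light pigment on a black background
#' (brightness above the threshold); transparency on a green or blue
#' background (hue band around the background colour plus a saturation
#' floor).
#'
#' @param target `"dark_pigment"`, `"light_pigment"` or `"transparency"`.
#' @param background `"white"`, `"black"`, `"green"` or `"blue"`;
#'   transparency requires green or blue.
#' @param method automatic threshold method: `"default"` (the IsoData-based
#'   intermeans variant, the recommended general-purpose choice),
#'   `"isodata"`, `"maxentropy"`, or `"manual"` with explicit
#'   `manual_bands`. The maximum-entropy criterion can place its cut at
#'   the edge of a histogram mode when the histogram is sharply bimodal;
#'   prefer `"default"` unless a threshold-quality check on your images
#'   says otherwise.
#' @param manual_bands a [color_threshold_spec]; required iff
#'   `method = "manual"`. Recording the manually adapted band limits keeps
#'   hand-tuned measurements reproducible.
#' @param roi optional [roi] applied before analysis.
#' @param roi_mm2 optional physical ROI area (mm^2), resolved through the
#'   image's pixel size; ignored when `roi` is given.
#' @param contrast_saturation fraction of pixels allowed to saturate in
#'   the pre-threshold contrast stretch of the brightness plane; 0
#'   disables the stretch.
#' @param min_saturation saturation floor (byte) for transparency.
#' @param min_size,max_size particle-area filter in pixels.
#' @param connectivity particle connectivity, 4 or 8.
#' @return an object of class `measurement_config`.
#' @export
measurement_config <- function(target = c("dark_pigment", "light_pigment",
                                          "transparency"),
                               background = c("white", "black", "green",
                                              "blue"),
                               method = c("default", "isodata",
                                          "maxentropy", "manual"),
                               manual_bands = NULL, roi = NULL,
                               roi_mm2 = NULL, contrast_saturation = 0,
                               min_saturation = 30, min_size = 1,
                               max_size = Inf, connectivity = 8) {
  target <- match.arg(target)
  background <- match.arg(background)
  method <- match.arg(method)
  if (method == "manual" && is.null(manual_bands))
    stop("method 'manual' requires manual_bands")
  if (method != "manual" && !is.null(manual_bands))
    stop("manual_bands given but method is not 'manual'")
  if (target == "transparency" && !background %in% c("green", "blue"))
    stop("transparency measurement requires a green or blue background")
  if (!is.null(manual_bands))
    stopifnot(inherits(manual_bands, "color_threshold_spec"))
  if (!is.null(roi)) stopifnot(inherits(roi, "pic_roi"))
  structure(list(target = target, background = background, method = method,
                 manual_bands = manual_bands, roi = roi, roi_mm2 = roi_mm2,
                 contrast_saturation = contrast_saturation,
                 min_saturation = min_saturation, min_size = min_size,
                 max_size = max_size, connectivity = connectivity),
            class = "measurement_config")
}

.auto_threshold <- function(h, method) {
  switch(method,
         maxentropy = threshold_max_entropy(h),
         isodata = threshold_isodata(h),
         default = threshold_ij_default(h),
         stop("unknown threshold method '", method, "'"))
}

#' Measure pigment cover or transparency on one image
#'
#' Runs the full single-image pipeline: optional ROI crop, optional
#' contrast stretch of the brightness plane, HSB conversion, colour
#' thresholding (automatic or manual), connected-component particle
#' analysis, and cover computation.
#'
#' @param img a [raster_image] in sRGB.
#' @param config a [measurement_config].
#' @return a `pic_result` (see [compute_pic]) whose `spec` field records
#'   the exact bands used; automatic runs also carry the chosen threshold
#'   in `threshold`.
#' @export
measure_pic <- function(img, config) {
  stopifnot(inherits(img, "raster_image"),
            inherits(config, "measurement_config"))
  if (img$space != "sRGB") stop("measure_pic() expects an sRGB image")
  r <- config$roi
  if (is.null(r) && !is.null(config$roi_mm2))
    r <- roi_physical(img, config$roi_mm2)
  if (!is.null(r)) img <- crop_roi(img, r)
  hsb <- srgb_to_hsb(img)
  if (config$contrast_saturation > 0)
    hsb$pixels[, , 3] <- enhance_contrast(hsb$pixels[, , 3],
                                          config$contrast_saturation)
  roi_area <- prod(dim(hsb$pixels)[1:2])

  if (config$target == "transparency") {
    band <- .BG_HUE_BANDS[[config$background]]
    hue_band <- if (config$method == "manual") config$manual_bands$hue
                else threshold_band(band[1], band[2], circular = TRUE)
    res <- measure_transparency(hsb, hue_band, roi_area = roi_area,
                                min_saturation = config$min_saturation,
                                background = config$background)
    return(res)
  }

  if (config$method == "manual") {
    spec <- config$manual_bands
    thr <- NA_integer_
  } else {
    bplane <- hsb$pixels[, , 3]
    thr <- .auto_threshold(histogram_of(bplane), config$method)
    spec <- if (config$target == "dark_pigment") {
      # dark pigment on a light background: brightness at or below t
      color_threshold_spec(brightness = threshold_band(0L, thr),
                           method = config$method)
    } else {
      # light pigment on a dark background: brightness above t
      color_threshold_spec(brightness = threshold_band(min(thr + 1L, 255L),
                                                       255L),
                           method = config$method)
    }
  }
  mask <- apply_color_threshold(hsb, spec)
  ps <- label_components(mask, connectivity = config$connectivity)
  ps <- analyze_particles(ps, config$min_size, config$max_size)
  res <- compute_pic(ps, roi_area, spec = spec,
                     background = config$background)
  res$threshold <- thr
  res
}

#' Batch-measure a set of images
#'
#' Applies [measure_pic] to each image path and collects one provenance
#' row per image. Unreadable or ill-formed images produce a row with an
#' `error` message and the batch continues; contradictory configurations
#' abort before any image is touched.
#'
#' @param images character vector of image paths (TIFF or PNG).
#' @param config a [measurement_config].
#' @param output_csv optional path; when given the table is also written
#'   as CSV (UTF-8, '.' decimal, header row).
#' @param pixel_size optional um/px attached to every image.
#' @return data.frame with one row per image: `image`, `target`,
#'   `background`, `method`, `threshold`, the three band limits,
#'   `pic`, `n_particles`, `roi_area`, `error`.
#' @export
run_measure <- function(images, config, output_csv = NULL,
                        pixel_size = NULL) {
  stopifnot(inherits(config, "measurement_config"))
  if (length(images) == 0L) {
    warning("no images given; returning an empty table")
    tab <- data.frame(image = character(), target = character(),
                      background = character(), method = character(),
                      threshold = integer(), hue_band = character(),
                      saturation_band = character(),
                      brightness_band = character(), pic = numeric(),
                      n_particles = integer(), roi_area = integer(),
                      error = character())
  } else {
    rows <- lapply(images, function(path) {
      out <- data.frame(image = path, target = config$target,
                        background = config$background,
                        method = config$method, threshold = NA_integer_,
                        hue_band = NA_character_,
                        saturation_band = NA_character_,
                        brightness_band = NA_character_, pic = NA_real_,
                        n_particles = NA_integer_, roi_area = NA_integer_,
                        error = NA_character_)
      res <- tryCatch(
        measure_pic(read_image(path, pixel_size = pixel_size), config),
        error = function(e) e)
      if (inherits(res, "error")) {
        out$error <- conditionMessage(res)
      } else {
        bandtxt <- function(b) sprintf("%d-%d%s", b$lo, b$hi,
                                       if (b$polarity == "stop") "!" else "")
        out$threshold <- if (is.null(res$threshold)) NA_integer_
                         else res$threshold
        out$hue_band <- bandtxt(res$spec$hue)
        out$saturation_band <- bandtxt(res$spec$saturation)
        out$brightness_band <- bandtxt(res$spec$brightness)
        out$pic <- res$pic
        out$n_particles <- res$n_particles
        out$roi_area <- res$roi_area
      }
      out
    })
    tab <- do.call(rbind, rows)
  }
  if (!is.null(output_csv))
    utils::write.csv(tab, output_csv, row.names = FALSE, fileEncoding = "UTF-8")
  tab
}

#' Parameter-recovery simulation for the PiC ~ CI calibration
#'
#' Repeatedly simulates datasets from a log-link beta-regression model
#' (the form of the published dark-pigment calibration) and refits each
#' one, returning the per-replicate estimates. Used to check that the
#' fitting routine recovers the generating coefficients without bias at
#' the study's sample size.
#'
#' @param n_reps number of simulated datasets.
#' @param n observations per dataset.
#' @param intercept,slope generating coefficients on the log scale.
#' @param phi generating beta precision.
#' @param seed integer master seed.
#' @param ci_grid predictor values sampled uniformly with replacement.
#' @return data.frame with one row per replicate: `rep`, `intercept`,
#'   `slope`, `phi`, `converged`.
#' @export
simulate_beta_recovery <- function(n_reps = 200, n = 50,
                                   intercept = -3.362, slope = 0.659,
                                   phi = 200, seed = 1,
                                   ci_grid = seq(1, 5, by = 0.5)) {
  rows <- lapply(seq_len(n_reps), function(r) {
    fit <- .with_seed(.scene_seed(seed, r), {
      ci <- sample(ci_grid, n, replace = TRUE)
      mu <- exp(intercept + slope * ci)
      pic <- stats::rbeta(n, mu * phi, (1 - mu) * phi)
      suppressMessages(fit_beta_regression(pic, ci, link = "log"))
    })
    data.frame(rep = r, intercept = fit$coefficients[["intercept"]],
               slope = fit$coefficients[["slope"]], phi = fit$phi)
  })
  do.call(rbind, rows)
}
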