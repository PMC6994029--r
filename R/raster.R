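# Colour-space tags understood by raster_image(). LAB8 stores L* rescaled
# from [0,100] to [0,255] and a*/b* offset so that byte 128 ~ 0.
.SPACES <- c("sRGB", "HSB", "Lab8")

#' Create a raster image
#'
#' The unit of analysis throughout the package: an H x W x 3 array of 8-bit
#' channel values plus a colour-space tag. All pipeline operations take and
#' return this class.
#'
#' @param pixels numeric or integer H x W x 3 array with values in 0..255.
#' @param space one of `"sRGB"`, `"HSB"`, `"Lab8"`. In HSB, channel 1 is hue
#'   scaled to 0..255 over the full circle and channels 2-3 are saturation
#'   and brightness scaled to 0..255.
#' @param pixel_size optional physical pixel size in micrometres per pixel,
#'   used to resolve physical region sizes (e.g. a 1 mm^2 crop).
#' @return an object of class `raster_image`.
#' @export
raster_image <- function(pixels, space = "sRGB", pixel_size = NULL) {
  space <- match.arg(space, .SPACES)
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have H >= 1 and W >= 1")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("channel values must lie in [0, 255]")
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, space = space, pixel_size = pixel_size),
    class = "raster_image"
  )
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_image %d x %d, space %s%s>\n", d[1], d[2], x$space,
              if (!is.null(x$pixel_size))
                sprintf(", %.3g um/px", x$pixel_size) else ""))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$pixels)

#' Extract one channel as a matrix
#'
#' @param img a [raster_image].
#' @param which channel index 1..3, or one of `"hue"`, `"saturation"`,
#'   `"brightness"` for HSB images.
#' @return integer H x W matrix.
#' @export
image_channel <- function(img, which) {
  stopifnot(inherits(img, "raster_image"))
  if (is.character(which)) {
    if (img$space != "HSB")
      stop("named channels require an HSB image")
    which <- match(match.arg(which, c("hue", "saturation", "brightness")),
                   c("hue", "saturation", "brightness"))
  }
  img$pixels[, , which]
}

#' Define a rectangular region of interest
#'
#' Coordinates are 0-based and half-open: the ROI covers rows
#' `row0 .. row0 + height - 1` and columns `col0 .. col0 + width - 1`.
#'
#' @param row0,col0 top-left corner (0-based).
#' @param height,width extent in pixels; both must be >= 1.
#' @return an object of class `pic_roi`.
#' @export
roi <- function(row0, col0, height, width) {
  v <- c(row0 = row0, col0 = col0, height = height, width = width)
  if (anyNA(v) || any(v != floor(v))) stop("ROI fields must be integers")
  if (row0 < 0 || col0 < 0) stop("ROI origin must be non-negative")
  if (height < 1 || width < 1) stop("ROI must have height*width >= 1")
  structure(as.list(as.integer(v)), names = names(v), class = "pic_roi")
}

#' Centred square ROI of a given physical area
#'
#' Resolves a physical crop size (for example the 1 mm^2 regions used when
#' scoring shrimp exopods) into pixels via the image's `pixel_size`,
#' rounding the side length to the nearest whole pixel.
#'
#' @param img a [raster_image] with non-NULL `pixel_size` (um/px).
#' @param area_mm2 target area in square millimetres.
#' @return a [roi] centred in the image.
#' @export
roi_physical <- function(img, area_mm2 = 1) {
  stopifnot(inherits(img, "raster_image"))
  if (is.null(img$pixel_size))
    stop("image has no pixel_size; cannot resolve a physical ROI")
  side_px <- as.integer(round(1000 * sqrt(area_mm2) / img$pixel_size))
  d <- dim(img$pixels)
  if (side_px > d[1] || side_px > d[2])
    stop(sprintf("a %.3g mm^2 ROI (%d px side) does not fit in %d x %d",
                 area_mm2, side_px, d[1], d[2]))
  roi((d[1] - side_px) %/% 2L, (d[2] - side_px) %/% 2L, side_px, side_px)
}

#' Crop an image to a region of interest
#'
#' @param img a [raster_image].
#' @param r a [roi]; must lie fully inside the image.
#' @return a new [raster_image] of size `height x width`; colour space and
#'   pixel size are preserved.
#' @export
crop_roi <- function(img, r) {
  stopifnot(inherits(img, "raster_image"), inherits(r, "pic_roi"))
  d <- dim(img$pixels)
  if (r$row0 + r$height > d[1])
    stop(sprintf("ROI bottom edge %d exceeds image height %d",
                 r$row0 + r$height, d[1]))
  if (r$col0 + r$width > d[2])
    stop(sprintf("ROI right edge %d exceeds image width %d",
                 r$col0 + r$width, d[2]))
  px <- img$pixels[(r$row0 + 1L):(r$row0 + r$height),
                   (r$col0 + 1L):(r$col0 + r$width), , drop = FALSE]
  raster_image(px, space = img$space, pixel_size = img$pixel_size)
}

# round half away from zero; channel values are non-negative so this is
# floor(x + 0.5)
.round_half_up <- function(x) floor(x + 0.5)

#' Convert sRGB bytes to HSB bytes
#'
#' Standard hexcone model: brightness is max(R,G,B)/255, saturation is
#' (max-min)/max (0 for black), hue is the piecewise sector angle rescaled
#' so that the full circle maps to 0..255. Achromatic pixels (S = 0) get
#' hue 0 by convention.
#'
#' @param img a [raster_image] in sRGB.
#' @return a [raster_image] with `space = "HSB"`.
#' @export
srgb_to_hsb <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  if (img$space != "sRGB") stop("srgb_to_hsb() requires an sRGB image")
  d <- dim(img$pixels)
  rgb <- matrix(as.numeric(aperm(img$pixels, c(3, 1, 2))), nrow = 3)
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  hsv[1, hsv[2, ] == 0] <- 0  # hue of achromatic pixels fixed at 0
  out <- .round_half_up(hsv * 255)
  raster_image(aperm(array(out, c(3, d[1], d[2])), c(2, 3, 1)),
               space = "HSB", pixel_size = img$pixel_size)
}

#' Convert sRGB bytes to byte-scaled CIELAB
#'
#' Applies the standard chain: IEC 61966-2-1 piecewise gamma decode,
#' linear RGB to XYZ (D65), XYZ to L*a*b* against the D65 white point,
#' then byte scaling: L* from [0,100] to [0,255] and a*/b* offset by 128
#' (clamped to 0..255). Linearization of the sRGB tone curve happens inside
#' this conversion, so downstream thresholds act on linear-light lightness.
#'
#' @param img a [raster_image] in sRGB.
#' @return a [raster_image] with `space = "Lab8"`.
#' @export
srgb_to_lab <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  if (img$space != "sRGB") stop("srgb_to_lab() requires an sRGB image")
  d <- dim(img$pixels)
  rgb01 <- matrix(as.numeric(img$pixels), ncol = 3) / 255
  lab <- grDevices::convertColor(rgb01, from = "sRGB", to = "Lab")
  bytes <- cbind(lab[, 1] * 255 / 100, lab[, 2] + 128, lab[, 3] + 128)
  bytes <- .round_half_up(pmin(pmax(bytes, 0), 255))
  raster_image(array(bytes, c(d[1], d[2], 3)),
               space = "Lab8", pixel_size = img$pixel_size)
}

#' Percentile contrast stretch of a byte plane
#'
#' Finds low/high clip values so that at most `saturated_fraction / 2` of
#' the pixels lie below the low clip and at most the same fraction above
#' the high clip, then linearly rescales `[low, high]` to `[0, 255]` with
#' clamping. `saturated_fraction = 0` gives a plain min-max stretch. The
#' total fraction is split equally between the two tails.
#'
#' @param channel integer matrix with values in 0..255.
#' @param saturated_fraction fraction of pixels allowed to saturate,
#'   in `[0, 1)`. A light over-saturation (~0.01) is typical for
#'   visual-contrast normalization.
#' @return integer matrix of the same shape.
#' @export
enhance_contrast <- function(channel, saturated_fraction = 0.01) {
  stopifnot(is.matrix(channel))
  if (saturated_fraction < 0 || saturated_fraction >= 1)
    stop("saturated_fraction must lie in [0, 1)")
  v <- sort(as.integer(channel))
  n <- length(v)
  k <- floor(n * saturated_fraction / 2)
  lo <- v[k + 1L]
  hi <- v[n - k]
  if (hi <= lo) {
    warning("channel has no dynamic range after clipping; returned unchanged")
    return(channel)
  }
  out <- (as.numeric(channel) - lo) * 255 / (hi - lo)
  out <- .round_half_up(pmin(pmax(out, 0), 255))
  matrix(as.integer(out), nrow(channel), ncol(channel))
}

#' Read a TIFF or PNG image as an sRGB raster
#'
#' Uncompressed/deflate TIFF and PNG are supported. Images with an alpha
#' channel are rejected: cover measurement assumes every pixel is either
#' tissue or background, and transparency in the file format would make
#' that ambiguous.
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @param pixel_size optional um/px to attach to the result.
#' @return a [raster_image] in sRGB.
#' @export
read_image <- function(path, pixel_size = NULL) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format '.", ext, "' (use TIFF or PNG)")
  )
  if (length(dim(arr)) == 2L)           # greyscale: replicate to 3 channels
    arr <- array(rep(arr, 3), c(dim(arr), 3))
  if (dim(arr)[3] == 4L)
    stop("image has an alpha channel; flatten it before analysis")
  if (dim(arr)[3] != 3L)
    stop("expected a 1-, 3- or 4-channel image")
  raster_image(.round_half_up(arr * 255), space = "sRGB",
               pixel_size = pixel_size)
}

#' Write an image or binary mask as PNG
#'
#' @param x a [raster_image] or a logical/0-1 matrix (mask).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_png <- function(x, path) {
  if (inherits(x, "raster_image")) {
    png::writePNG(x$pixels / 255, path)
  } else if (is.matrix(x)) {
    png::writePNG((x != 0) * 1, path)
  } else stop("`x` must be a raster_image or a matrix mask")
  invisible(path)
}
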