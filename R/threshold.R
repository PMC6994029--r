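#' Histogram of a byte plane
#'
#' @param channel integer matrix with values in 0..255.
#' @param mask optional logical matrix of the same shape; only masked-in
#'   pixels are counted.
#' @return an object of class `pic_histogram`: `counts` (length 256,
#'   index i holds the count of value i-1) and `total`.
#' @export
histogram_of <- function(channel, mask = NULL) {
  stopifnot(is.matrix(channel))
  v <- as.integer(channel)
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(channel)))
    v <- v[as.logical(mask)]
    if (length(v) == 0L) stop("no pixels to histogram (empty mask)")
  }
  if (min(v) < 0L || max(v) > 255L) stop("channel values must lie in 0..255")
  counts <- tabulate(v + 1L, nbins = 256L)
  structure(list(counts = counts, total = sum(counts)),
            class = "pic_histogram")
}

#' @export
print.pic_histogram <- function(x, ...) {
  occ <- which(x$counts > 0L) - 1L
  cat(sprintf("<pic_histogram: %d pixels, %d occupied bins in [%d, %d]>\n",
              x$total, length(occ), min(occ), max(occ)))
  invisible(x)
}

# round half DOWN: 127.5 -> 127. Used at the intermeans update step to
# prevent oscillation between adjacent thresholds on symmetric histograms.
.round_half_down <- function(x) ceiling(x - 0.5)

.check_hist <- function(h) {
  stopifnot(inherits(h, "pic_histogram"))
  occ <- which(h$counts > 0L) - 1L
  if (length(occ) < 2L)
    stop("degenerate histogram: fewer than 2 occupied bins")
  occ
}

# one intermeans update: mean of values <= t and mean of values > t,
# averaged and rounded half-down. Values are bin indices 0..255.
.intermeans_update <- function(counts, t) {
  v <- 0:255
  below <- v <= t
  mu_lo <- sum(v[below] * counts[below]) / sum(counts[below])
  mu_hi <- sum(v[!below] * counts[!below]) / sum(counts[!below])
  .round_half_down((mu_lo + mu_hi) / 2)
}

.intermeans_iterate <- function(h, t) {
  occ <- which(h$counts > 0L) - 1L
  lo <- min(occ); hi <- max(occ)
  clamp <- function(t) min(max(t, lo), hi - 1L)  # both classes stay non-empty
  t <- clamp(t)
  for (i in seq_len(256L)) {
    t2 <- clamp(.intermeans_update(h$counts, t))
    if (t2 == t) return(as.integer(t))
    t <- t2
  }
  stop("intermeans iteration did not converge within 256 steps")
}

#' IsoData automatic threshold
#'
#' Iterative intermeans: the threshold is the fixed point of
#' `t <- round((mean of values <= t) + (mean of values > t)) / 2`, started
#' from the midpoint of the occupied value range, with the update rounded
#' half-down. Foreground convention: values strictly above the returned
#' threshold.
#'
#' @param h a [histogram_of] result with at least 2 occupied bins.
#' @return integer threshold in 0..254.
#' @export
threshold_isodata <- function(h) {
  occ <- .check_hist(h)
  .intermeans_iterate(h, floor((min(occ) + max(occ)) / 2))
}

#' Default (ImageJ-style) automatic threshold
#'
#' The same iterative-intermeans fixed point as [threshold_isodata] but
#' initialised at the mean of the occupied extremes (rounded half-down),
#' which is the behaviour most image-analysis defaults approximate. The
#' two variants usually agree; both are exposed so a measurement protocol
#' can name the variant it used.
#'
#' @inheritParams threshold_isodata
#' @return integer threshold in 0..254.
#' @export
threshold_ij_default <- function(h) {
  occ <- .check_hist(h)
  .intermeans_iterate(h, .round_half_down((min(occ) + max(occ)) / 2))
}

#' Maximum-entropy automatic threshold (Kapur-Sahoo-Wong)
#'
#' Returns the threshold t maximizing the sum of Shannon entropies of the
#' two class-conditional normalized histograms (values <= t and values
#' > t). Empty bins contribute 0 (0 log 0 := 0); an empty class has entropy
#' 0; ties break toward the smallest t. Natural logarithms are used.
#'
#' @inheritParams threshold_isodata
#' @return integer threshold in 0..255.
#' @export
threshold_max_entropy <- function(h) {
  .check_hist(h)
  p <- h$counts / h$total
  # cumulative class probabilities and cumulative plogp sums
  plogp <- ifelse(p > 0, p * log(p), 0)
  Plo <- cumsum(p)
  Slo <- cumsum(plogp)
  Phi <- pmax(1 - Plo, 0)
  Shi <- sum(plogp) - Slo
  H_lo <- ifelse(Plo > 0, log(Plo) - Slo / Plo, 0)
  H_hi <- ifelse(Phi > 0, log(Phi) - Shi / Phi, 0)
  tot <- H_lo + H_hi
  as.integer(which.max(tot) - 1L)  # which.max takes the first (smallest t)
}

#' Threshold band on one HSB channel
#'
#' @param lo,hi byte limits, 0..255. For a circular band (hue) `lo > hi`
#'   wraps through 255 -> 0; non-circular bands require `lo <= hi`.
#' @param polarity `"pass"` selects values inside the band, `"stop"`
#'   selects the complement.
#' @param circular logical; only hue is circular.
#' @return an object of class `threshold_band`.
#' @export
threshold_band <- function(lo = 0L, hi = 255L, polarity = c("pass", "stop"),
                           circular = FALSE) {
  polarity <- match.arg(polarity)
  if (lo < 0 || lo > 255 || hi < 0 || hi > 255)
    stop("band limits must lie in 0..255")
  if (!circular && lo > hi)
    stop("non-circular band requires lo <= hi")
  structure(list(lo = as.integer(lo), hi = as.integer(hi),
                 polarity = polarity, circular = isTRUE(circular)),
            class = "threshold_band")
}

# band membership before polarity
.band_inside <- function(values, band) {
  if (band$circular && band$lo > band$hi)
    values >= band$lo | values <= band$hi
  else
    values >= band$lo & values <= band$hi
}

.band_member <- function(values, band) {
  inside <- .band_inside(values, band)
  if (band$polarity == "stop") !inside else inside
}

#' Full HSB colour-threshold specification
#'
#' Bundles one band per HSB channel plus the name of the method that chose
#' the limits, so every measurement records how its mask was made. The hue
#' band is always circular; saturation and brightness are linear.
#'
#' @param hue,saturation,brightness [threshold_band]s; defaults pass
#'   everything.
#' @param method one of `"default"`, `"isodata"`, `"maxentropy"`,
#'   `"manual"`; recorded in results for provenance.
#' @return an object of class `color_threshold_spec`.
#' @export
color_threshold_spec <- function(hue = threshold_band(circular = TRUE),
                                 saturation = threshold_band(),
                                 brightness = threshold_band(),
                                 method = c("manual", "default", "isodata",
                                            "maxentropy")) {
  method <- match.arg(method)
  stopifnot(inherits(hue, "threshold_band"),
            inherits(saturation, "threshold_band"),
            inherits(brightness, "threshold_band"))
  hue$circular <- TRUE
  if (saturation$circular || brightness$circular)
    stop("only the hue band may be circular")
  structure(list(hue = hue, saturation = saturation,
                 brightness = brightness, method = method),
            class = "color_threshold_spec")
}

#' @export
format.color_threshold_spec <- function(x, ...) {
  b <- function(bd) sprintf("[%d,%d]%s", bd$lo, bd$hi,
                            if (bd$polarity == "stop") "!" else "")
  sprintf("H%s S%s B%s (%s)", b(x$hue), b(x$saturation), b(x$brightness),
          x$method)
}

#' Apply an HSB colour threshold to an image
#'
#' A pixel is selected iff it satisfies all three bands. A `pass` band
#' selects values inside `[lo, hi]` (wrapping through 255 -> 0 if circular
#' and `lo > hi`); a `stop` band selects the complement.
#'
#' @param img a [raster_image] with `space = "HSB"`.
#' @param spec a [color_threshold_spec].
#' @return logical H x W mask.
#' @export
apply_color_threshold <- function(img, spec) {
  stopifnot(inherits(img, "raster_image"),
            inherits(spec, "color_threshold_spec"))
  if (img$space != "HSB")
    stop("apply_color_threshold() requires an HSB image (see srgb_to_hsb)")
  .band_member(img$pixels[, , 1], spec$hue) &
    .band_member(img$pixels[, , 2], spec$saturation) &
    .band_member(img$pixels[, , 3], spec$brightness)
}
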