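#' Label connected components of a binary mask
#'
#' Two-pass run-based labelling with union-find. Foreground pixels are
#' grouped into maximal connected components under 4- or 8-connectivity.
#' Labels 1..K are assigned in raster order (row-major) of each
#' component's first-encountered pixel, so labelling is deterministic.
#'
#' @param mask logical or 0/1 matrix; non-zero is foreground.
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent;
#'   the default, matching common particle-analysis behaviour).
#' @return an object of class `particle_set`: `labels` (integer matrix,
#'   0 = background), `particles` (data.frame with `label`, `area`,
#'   `centroid_row`, `centroid_col`, `bbox_*` in 0-based pixel
#'   coordinates), `connectivity`.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  H <- nrow(mask); W <- ncol(mask)
  m <- mask != 0
  labels <- matrix(0L, H, W)
  empty <- data.frame(label = integer(), area = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      bbox_row0 = integer(), bbox_col0 = integer(),
                      bbox_height = integer(), bbox_width = integer())
  if (!any(m)) {
    return(structure(list(labels = labels, particles = empty,
                          connectivity = connectivity),
                     class = "particle_set"))
  }
  # vertical runs per column: a run is a maximal same-column block
  above <- rbind(FALSE, m[-H, , drop = FALSE])
  below <- rbind(m[-1, , drop = FALSE], FALSE)
  starts <- which(m & !above)   # column-major linear indices, sorted
  ends   <- which(m & !below)
  col  <- (starts - 1L) %/% H + 1L
  r0   <- (starts - 1L) %%  H + 1L
  r1   <- (ends   - 1L) %%  H + 1L
  nrun <- length(starts)

  # union-find over runs
  parent <- seq_len(nrun)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  slack <- if (connectivity == 8) 1L else 0L
  # runs are sorted by (col, r0); walk adjacent column pairs with two pointers
  col_first <- match(seq_len(W), col)
  run_idx <- seq_len(nrun)
  for (cc in seq_len(W)[-1]) {
    a <- col_first[cc]
    if (is.na(a)) next
    b <- col_first[cc - 1L]
    if (is.na(b)) next
    i <- a
    j <- b
    while (i <= nrun && col[i] == cc) {
      while (j <= nrun && col[j] == cc - 1L && r1[j] < r0[i] - slack)
        j <- j + 1L
      k <- j
      while (k <= nrun && col[k] == cc - 1L && r0[k] <= r1[i] + slack) {
        ri <- find(i); rk <- find(k)
        if (ri != rk) parent[max(ri, rk)] <- min(ri, rk)
        k <- k + 1L
      }
      i <- i + 1L
    }
  }
  root <- vapply(run_idx, find, integer(1))
  comp <- match(root, root)            # representative per run
  # first-encountered pixel in row-major order: smallest (r0-1)*W + col
  first_px <- (r0 - 1L) * W + col
  comp_first <- tapply(first_px, comp, min)
  ord <- rank(comp_first, ties.method = "first")
  lab_of_run <- as.integer(ord[match(comp, as.integer(names(comp_first)))])

  run_len <- r1 - r0 + 1L
  labels[sequence(run_len, from = starts)] <- rep(lab_of_run, run_len)

  K <- max(lab_of_run)
  area  <- as.vector(tapply(run_len, lab_of_run, sum))
  # centroid from run sums: rows sum per run = (r0+r1)*len/2
  rowsum_ <- tapply((r0 + r1) * run_len / 2, lab_of_run, sum)
  colsum_ <- tapply(col * run_len, lab_of_run, sum)
  rmin <- tapply(r0, lab_of_run, min); rmax <- tapply(r1, lab_of_run, max)
  cmin <- tapply(col, lab_of_run, min); cmax <- tapply(col, lab_of_run, max)
  particles <- data.frame(
    label = seq_len(K),
    area = as.integer(area),
    centroid_row = as.vector(rowsum_) / area - 1,   # 0-based
    centroid_col = as.vector(colsum_) / area - 1,
    bbox_row0 = as.integer(rmin) - 1L,
    bbox_col0 = as.integer(cmin) - 1L,
    bbox_height = as.integer(rmax - rmin + 1L),
    bbox_width = as.integer(cmax - cmin + 1L)
  )
  structure(list(labels = labels, particles = particles,
                 connectivity = connectivity),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set: %d particles, total area %d px, %d-connected>\n",
              nrow(x$particles), sum(x$particles$area), x$connectivity))
  invisible(x)
}

#' Filter particles by area
#'
#' Retains particles whose pixel area lies in `[min_size, max_size]`;
#' removed particles are zeroed out of the label image as well.
#'
#' @param ps a [particle_set].
#' @param min_size,max_size inclusive area limits in pixels.
#' @return a filtered [particle_set].
#' @export
analyze_particles <- function(ps, min_size = 1, max_size = Inf) {
  stopifnot(inherits(ps, "particle_set"))
  if (min_size < 0 || min_size > max_size)
    stop("require 0 <= min_size <= max_size")
  keep <- ps$particles$area >= min_size & ps$particles$area <= max_size
  kept <- ps$particles[keep, , drop = FALSE]
  labels <- ps$labels
  labels[!(labels %in% kept$label)] <- 0L
  if (nrow(kept) > 0L) {
    relab <- match(labels, kept$label)
    labels <- matrix(ifelse(is.na(relab), 0L, relab),
                     nrow(labels), ncol(labels))
    kept$label <- seq_len(nrow(kept))
  }
  rownames(kept) <- NULL
  structure(list(labels = labels, particles = kept,
                 connectivity = ps$connectivity),
            class = "particle_set")
}

#' Pigment cover from a particle set
#'
#' PiC is the fraction of the region of interest covered by pigment
#' particles: total particle area / ROI area, computed in integer
#' arithmetic before the final division.
#'
#' @param ps a [particle_set].
#' @param roi_area ROI size in pixels; must be >= the total particle area.
#' @param spec optional [color_threshold_spec] recorded for provenance.
#' @param background optional background-colour tag (`"white"`, `"black"`,
#'   `"green"`, `"blue"`, `"other"`).
#' @return an object of class `pic_result` with fields `pic` (fraction in
#'   `[0,1]`), `n_particles`, `total_area`, `roi_area`, `spec`,
#'   `background`.
#' @export
compute_pic <- function(ps, roi_area, spec = NULL, background = "other") {
  stopifnot(inherits(ps, "particle_set"))
  if (roi_area <= 0) stop("roi_area must be positive")
  total <- sum(ps$particles$area)
  if (total > roi_area)
    stop("total particle area exceeds roi_area; wrong ROI?")
  structure(list(pic = total / roi_area,
                 n_particles = nrow(ps$particles),
                 total_area = as.integer(total),
                 roi_area = as.integer(roi_area),
                 spec = spec, background = background),
            class = "pic_result")
}

#' @export
print.pic_result <- function(x, ...) {
  cat(sprintf("PiC = %.4f (%d particles, %d / %d px%s)\n",
              x$pic, x$n_particles, x$total_area, x$roi_area,
              if (!is.null(x$spec))
                paste0("; ", format(x$spec)) else ""))
  invisible(x)
}

#' Measure transparency against a chromatic background
#'
#' Transparency is the fraction of the region through which the coloured
#' background (a hue absent from the animal, typically green or blue) is
#' visible. Pixels are selected by a hue band centred on the background
#' colour plus a minimum-saturation band, so grey or white glare is not
#' mistaken for background.
#'
#' @param img a [raster_image] with `space = "HSB"`.
#' @param background_hue_band circular [threshold_band] for the background
#'   hue; must not cover the full circle.
#' @param roi_area region size in pixels; defaults to the whole image.
#' @param min_saturation saturation floor (byte), default 30.
#' @param background background tag recorded in the result.
#' @return a [compute_pic]-style `pic_result` whose `pic` field holds the
#'   transparency fraction.
#' @export
measure_transparency <- function(img, background_hue_band,
                                 roi_area = NULL, min_saturation = 30,
                                 background = "green") {
  stopifnot(inherits(img, "raster_image"),
            inherits(background_hue_band, "threshold_band"))
  if (img$space != "HSB")
    stop("measure_transparency() requires an HSB image")
  bw <- if (background_hue_band$lo > background_hue_band$hi)
    (255L - background_hue_band$lo) + background_hue_band$hi + 1L
  else background_hue_band$hi - background_hue_band$lo + 1L
  if (bw >= 256L) stop("hue band covers the full circle: band selects everything")
  spec <- color_threshold_spec(
    hue = background_hue_band,
    saturation = threshold_band(lo = min_saturation, hi = 255L),
    method = "manual"
  )
  sel <- apply_color_threshold(img, spec)
  if (is.null(roi_area)) roi_area <- length(sel)
  ps <- label_components(sel)
  compute_pic(ps, roi_area, spec = spec, background = background)
}

#' Binary mask of a particle set
#'
#' @param ps a [particle_set].
#' @return logical matrix, TRUE where any particle is present.
#' @export
particle_mask <- function(ps) {
  stopifnot(inherits(ps, "particle_set"))
  ps$labels > 0L
}
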