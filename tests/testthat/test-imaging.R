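make_img <- function(px) raster_image(px, space = "sRGB")

test_that("crop_roi copies the requested window and checks bounds", {
  px <- array(sample(0:255, 10 * 10 * 3, TRUE), c(10, 10, 3))
  img <- make_img(px)

  whole <- crop_roi(img, roi(0, 0, 10, 10))
  expect_identical(whole$pixels, img$pixels)
  expect_identical(whole$space, "sRGB")

  sub <- crop_roi(img, roi(2, 3, 4, 5))
  expect_identical(dim(sub$pixels), c(4L, 5L, 3L))
  expect_identical(sub$pixels[1, 1, ], img$pixels[3, 4, ])

  expect_error(crop_roi(img, roi(8, 8, 5, 5)), "bottom|right|exceeds")
  expect_error(roi(0, 0, 0, 5), "height")
})

test_that("physical ROI resolves mm^2 through the pixel size", {
  img <- raster_image(array(0L, c(200, 200, 3)), pixel_size = 10) # 10 um/px
  r <- roi_physical(img, area_mm2 = 1)        # 1 mm = 100 px side
  expect_equal(r$height, 100L)
  expect_equal(r$width, 100L)
  expect_error(roi_physical(make_img(array(0L, c(10, 10, 3)))),
               "pixel_size")
})

test_that("sRGB to HSB follows the hexcone model", {
  px <- array(0L, c(1, 3, 3))
  px[1, 1, ] <- c(255L, 0L, 0L)    # pure red
  px[1, 2, ] <- c(128L, 128L, 128L) # achromatic
  px[1, 3, ] <- c(0L, 0L, 255L)    # pure blue
  hsb <- srgb_to_hsb(make_img(px))
  expect_identical(hsb$space, "HSB")
  expect_equal(hsb$pixels[1, 1, ], c(0L, 255L, 255L))
  expect_equal(hsb$pixels[1, 2, ], c(0L, 0L, 128L))
  # hue of blue: 240/360 of the circle scaled to bytes
  expect_equal(hsb$pixels[1, 3, ], c(170L, 255L, 255L))
  expect_error(srgb_to_hsb(hsb), "sRGB")
})

test_that("HSB round-trips to sRGB within one byte per channel", {
  set.seed(11)
  px <- array(sample(0:255, 20 * 20 * 3, TRUE), c(20, 20, 3))
  hsb <- srgb_to_hsb(make_img(px))
  # inverse hexcone map, written independently of the package
  h <- as.numeric(hsb$pixels[, , 1]) / 255 * 6
  s <- as.numeric(hsb$pixels[, , 2]) / 255
  v <- as.numeric(hsb$pixels[, , 3]) / 255
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  back <- round(cbind(r, g, b) * 255)
  orig <- cbind(as.numeric(px[, , 1]), as.numeric(px[, , 2]),
                as.numeric(px[, , 3]))
  # storing hue in one byte quantizes the circle to 256 steps; inverting
  # can move a fully saturated channel by up to round(255 * 3/255) = 3
  # counts, so the invariant holds at that quantization bound
  expect_lte(max(abs(back - orig)), 3)
  expect_gte(mean(abs(back - orig) <= 1), 0.9)
})

test_that("sRGB to Lab8 matches the standard D65 conversion chain", {
  px <- array(0L, c(1, 3, 3))
  px[1, 1, ] <- c(255L, 255L, 255L)
  px[1, 2, ] <- c(0L, 0L, 0L)
  px[1, 3, ] <- c(118L, 118L, 118L)
  lab <- srgb_to_lab(make_img(px))
  expect_identical(lab$space, "Lab8")
  expect_equal(lab$pixels[1, 1, ], c(255L, 128L, 128L))  # white: L*=100
  expect_equal(lab$pixels[1, 2, ], c(0L, 128L, 128L))    # black: L*=0
  # independent oracle: gamma decode -> Y -> L* for grey 118
  y <- ((118 / 255 + 0.055) / 1.055)^2.4
  Lstar <- ifelse(y > (6 / 29)^3, 116 * y^(1 / 3) - 16, y * (29 / 3)^3)
  expect_equal(lab$pixels[1, 3, 1], as.integer(round(Lstar * 255 / 100)))
  expect_equal(lab$pixels[1, 3, 2:3], c(128L, 128L))
})

test_that("grey pixels have near-zero a*/b* after conversion", {
  g <- sample(0:255, 30)
  px <- array(rep(g, 3), c(1, 30, 3))
  lab <- srgb_to_lab(make_img(px))
  expect_true(all(abs(lab$pixels[, , 2] - 128L) <= 1))
  expect_true(all(abs(lab$pixels[, , 3] - 128L) <= 1))
})

test_that("enhance_contrast stretches to the percentile clip points", {
  ch <- matrix(as.integer(round(seq(10, 200, length.out = 100))), 10, 10)
  out <- enhance_contrast(ch, 0)
  expect_equal(min(out), 0L)
  expect_equal(max(out), 255L)
  expect_equal(out[ch == 10], rep(0L, sum(ch == 10)))

  full <- matrix(as.integer(round(seq(0, 255, length.out = 64))), 8, 8)
  expect_identical(enhance_contrast(full, 0), full)

  # 5 outliers at 0 among 1000 pixels; 1% saturation absorbs them so the
  # low clip is the 6th-smallest value
  set.seed(4)
  v <- c(rep(0L, 5), sample(100:200, 995, TRUE))
  ch2 <- matrix(v, 40, 25)
  out2 <- enhance_contrast(ch2, 0.01)
  srt <- sort(v)
  lo_expected <- srt[floor(1000 * 0.005) + 1]   # direct percentile oracle
  expect_equal(lo_expected, min(v[v > 0]))
  expect_true(all(out2[ch2 == lo_expected] == 0L))
})

test_that("enhance_contrast preserves pixel order and flags flat input", {
  set.seed(5)
  ch <- matrix(sample(30:220, 400, TRUE), 20, 20)
  out <- enhance_contrast(ch, 0.02)
  o <- order(as.vector(ch))
  expect_true(all(diff(as.vector(out)[o]) >= 0))
  flat <- matrix(7L, 5, 5)
  expect_warning(res <- enhance_contrast(flat, 0), "unchanged")
  expect_identical(res, flat)
  expect_error(enhance_contrast(ch, 1), "saturated_fraction")
})

test_that("PNG round trip preserves bytes and alpha is rejected", {
  px <- array(sample(0:255, 12 * 9 * 3, TRUE), c(12, 9, 3))
  f <- tempfile(fileext = ".png")
  write_png(make_img(px), f)
  back <- read_image(f)
  expect_identical(back$pixels, make_img(px)$pixels)

  fa <- tempfile(fileext = ".png")
  png::writePNG(array(0.5, c(4, 4, 4)), fa)
  expect_error(read_image(fa), "alpha")
  expect_error(read_image(tempfile(fileext = ".bmp")), "unsupported")
})

test_that("TIFF images are read as sRGB rasters", {
  px <- array(sample(0:255, 8 * 8 * 3, TRUE), c(8, 8, 3))
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(px / 255, f)
  back <- read_image(f, pixel_size = 5)
  expect_identical(back$pixels, make_img(px)$pixels)
  expect_equal(back$pixel_size, 5)
})
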