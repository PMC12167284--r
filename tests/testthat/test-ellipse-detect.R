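# a fixed desk-scale scene with 5 well-separated spheres
detectFixture <- function(f = 1400, w = 1000, h = 1000) {
  cam <- camera(f, f, (w - 1) / 2, (h - 1) / 2, w, h, id = "img001")
  centers <- rbind(c(-150, -120, 850), c(160, -140, 900), c(-170, 150, 800),
                   c(140, 160, 950), c(0, 10, 1000))
  mk <- lapply(seq_len(nrow(centers)), function(i)
    sphereMarker(centers[i, ], 30, "W", sprintf("m%02d", i)))
  list(cam = cam, markers = mk)
}

test_that("rendered spheres are detected with sub-pixel accuracy", {
  fx <- detectFixture()
  rend <- renderImages(fx$markers, list(img001 = fx$cam), seed = 121)
  dets <- detectEllipses(rend$img001$image, imageId = "img001")
  expect_length(dets, 5)
  for (d in dets) {
    pd <- conicParams(d@conic)
    errs <- vapply(rend$img001$conics, function(co)
      sqrt(sum((conicParams(co)$center - pd$center)^2)), 0)
    truth <- conicParams(rend$img001$conics[[which.min(errs)]])
    expect_lt(min(errs), 0.5)
    expect_lt(abs(pd$semiAxes[1] - truth$semiAxes[1]) / truth$semiAxes[1],
              0.01)
    expect_lt(abs(pd$semiAxes[2] - truth$semiAxes[2]) / truth$semiAxes[2],
              0.01)
    # outline samples of the fitted conic satisfy the conic identity
    expect_lt(max(abs(conicResidual(d@conic, sampleOutline(d@conic, 40)))),
              1e-6)
  }
  # detections sorted by descending support
  sup <- vapply(dets, function(d) d@supportPixelCount, 0L)
  expect_true(all(diff(sup) <= 0))
})

test_that("blank images yield no detections and bad input errors", {
  set.seed(122)
  blank <- matrix(0.1 + 0.02 * rnorm(400 * 400), 400, 400)
  expect_length(detectEllipses(blank), 0)
  expect_error(detectEllipses(array(0, c(4, 4, 3))), "2D")
})

test_that("merged silhouettes of overlapping spheres are rejected", {
  cam <- camera(1400, 1400, 499.5, 499.5, 1000, 1000, id = "img001")
  mk <- list(sphereMarker(c(-14, 0, 900), 30, "W", "a"),
             sphereMarker(c(14, 0, 900), 30, "W", "b"))
  rend <- renderImages(mk, list(img001 = cam), seed = 123)
  expect_message(dets <- detectEllipses(rend$img001$image),
                 "rejected.*non-elliptical")
  expect_length(dets, 0)
})

test_that("fitted conics converge to the analytic conic with resolution", {
  errAt <- function(scale) {
    w <- as.integer(1000 * scale)
    fx <- detectFixture(f = 1400 * scale, w = w, h = w)
    rend <- renderImages(fx$markers, list(img001 = fx$cam), seed = 124)
    dets <- detectEllipses(rend$img001$image, imageId = "img001")
    expect_length(dets, 5)
    # mean centre error in units of the coarse grid, for comparability
    mean(vapply(dets, function(d) {
      pd <- conicParams(d@conic)
      min(vapply(rend$img001$conics, function(co)
        sqrt(sum((conicParams(co)$center - pd$center)^2)), 0)) / scale
    }, 0))
  }
  expect_lt(errAt(4), errAt(1))
})

test_that("adaptive threshold detection is invariant to gain and offset", {
  fx <- detectFixture()
  rend <- renderImages(fx$markers, list(img001 = fx$cam), seed = 125)
  img <- rend$img001$image
  dets0 <- detectEllipses(img, imageId = "img001")
  dets1 <- detectEllipses(0.4 * img + 0.2, imageId = "img001")
  expect_length(dets1, length(dets0))
  c0 <- t(vapply(dets0, function(d) conicParams(d@conic)$center, numeric(2)))
  c1 <- t(vapply(dets1, function(d) conicParams(d@conic)$center, numeric(2)))
  expect_equal(c1, c0, tolerance = 1e-8)
})

test_that("dark-polarity detection finds dark markers on bright background", {
  fx <- detectFixture()
  rend <- renderImages(fx$markers, list(img001 = fx$cam), seed = 126)
  inv <- 1 - rend$img001$image
  dets <- detectEllipses(inv, detectionConfig(polarity = "dark"),
                         imageId = "img001")
  expect_length(dets, 5)
})
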