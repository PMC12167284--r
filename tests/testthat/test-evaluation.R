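test_that("radial error closed forms", {
  cam <- deskCamera()
  m <- sphereMarker(c(0, 0, 800), 15, frame = "W")
  # ray through the centre: error equals the radius
  ctr <- projectPoints(cam, m@center)
  expect_equal(radialError(ctr[1, ], cam, m), 15, tolerance = 1e-9)
  # exact tangent ray: outline point of the true conic
  pt <- sampleOutline(projectSphere(m, cam), 8)[3, ]
  expect_lt(radialError(pt, cam, m), 1e-9)
  # perpendicular distance 16 mm to an r = 15 sphere: 1 mm
  # build a pixel whose ray passes at exactly 16 mm from the centre
  d <- sqrt(sum(m@center^2))
  ang <- asin(16 / d)
  px <- cam@fx * tan(ang)
  expect_equal(radialError(c(cam@cx + px, cam@cy), cam, m), 1,
               tolerance = 1e-6)
  expect_error(radialError(c(0, 0), cam,
                           sphereMarker(c(0, 0, -500), 15, "W")),
               "behind")
})

test_that("radial error is invariant under a joint rigid transform", {
  set.seed(111)
  for (i in 1:20) {
    cam <- lookAtCamera()
    m <- sphereMarker(runif(3, -60, 60), 15, frame = "W")
    px <- projectPoints(cam, m@center) + rnorm(2, sd = 40)
    e0 <- radialError(px[1, ], cam, m)
    G <- randTransform(from = "W", to = "W2")
    camG <- camera(cam@fx, cam@fy, cam@cx, cam@cy, cam@width, cam@height,
                   pose = compose(cam@pose, invertTransform(G)))
    mG <- sphereMarker(applyTransform(G, m@center), 15, "W2")
    expect_equal(radialError(px[1, ], camG, mG), e0, tolerance = 1e-10)
  }
})

test_that("reprojection error closed forms and convergence", {
  c1 <- paramsToConic(c(500, 400), c(100, 100), 0)
  expect_equal(reprojectionError(c1, c1), 0, tolerance = 1e-12)
  c2 <- paramsToConic(c(500, 400), c(103, 103), 0)
  expect_equal(reprojectionError(c1, c2), 3, tolerance = 1e-9)
  # translated congruent ellipses: error in (0, |t|), shrinking toward the
  # circular case; dense-sampling oracle agreement
  set.seed(112)
  for (asp in c(3, 1.5, 1.05)) {
    a <- paramsToConic(c(0, 0), c(60, 60 / asp), 0.4)
    b <- paramsToConic(c(5, 0), c(60, 60 / asp), 0.4)
    e <- reprojectionError(a, b, 400)
    expect_gt(e, 0)
    expect_lt(e, 5)
    dense <- reprojectionError(a, b, 20000)
    expect_lt(abs(e - dense) / dense, 0.01)
  }
  # doubling the sample count changes the value by < 1%
  for (i in 1:10) {
    a <- paramsToConic(runif(2, -50, 50), sort(runif(2, 20, 80),
                                               decreasing = TRUE),
                       runif(1, -1, 1))
    b <- paramsToConic(runif(2, -50, 50), sort(runif(2, 20, 80),
                                               decreasing = TRUE),
                       runif(1, -1, 1))
    expect_lt(abs(reprojectionError(a, b, 200) -
                  reprojectionError(a, b, 400)) /
              reprojectionError(a, b, 400), 0.01)
  }
})

test_that("chamfer distance closed forms, symmetry and translation bound", {
  s15 <- sphereMesh(c(0, 0, 0), 15, nRings = 48, nSegments = 96)
  s16 <- sphereMesh(c(0, 0, 0), 16, nRings = 48, nSegments = 96)
  set.seed(113)
  expect_equal(chamferDistance(s15, s15, 2000), 0, tolerance = 1e-12)
  # concentric spheres: the radial gap (tessellation sag ~ r * theta^2 / 8)
  expect_equal(chamferDistance(s15, s16, 5000), 1, tolerance = 5e-3)
  # symmetric by construction
  set.seed(114)
  d1 <- chamferDistance(s15, s16, 3000)
  set.seed(114)
  d2 <- chamferDistance(s16, s15, 3000)
  expect_equal(d1, d2, tolerance = 1e-4)  # identical up to sampling draws
  # translated copy: bounded by the translation, matches a dense oracle
  m <- ellipsoidMesh <- sphereMesh(c(0, 0, 0), 20, nRings = 16, nSegments = 32)
  delta <- 0.05
  mt <- surfaceMesh(sweep(m@vertices, 2, c(delta, 0, 0), "+"), m@faces)
  d <- chamferDistance(m, mt, 5000)
  expect_lte(d, delta + 1e-12)
  dDense <- chamferDistance(m, mt, 50000)
  expect_lt(abs(d - dDense), 0.01 * delta + 2e-3)
  expect_error(chamferDistance(m, surfaceMesh(matrix(0, 1, 3))),
               "non-empty")
})

test_that("registration evaluation aggregates radial errors correctly", {
  scn <- generateScene(sceneConfig(seed = 115))
  res <- refineRegistration(scn$exactObs, scn$truth$transform, "rigid")
  report <- evaluateRegistration(res, scn$exactControlObs)
  expect_lt(report@meanMm, 1e-8)
  expect_equal(report@meanMm, mean(report@perPoint$error_mm))
  # overall mean equals the count-weighted mean of per-marker means
  expect_equal(report@meanMm,
               sum(report@perMarker$mean_mm * report@perMarker$n) /
                 sum(report@perMarker$n))
  expect_error(evaluateRegistration(res, structure(scn$exactControlObs,
                                                   markers = list())))
})

test_that("a known translation of the transform shows up as radial error", {
  # single fronto-parallel camera, control markers along the optical axis:
  # translating the scene along the axis leaves rays near-tangent, while a
  # lateral 1 mm shift moves the hulls by ~1 mm against fixed rays
  cam <- deskCamera(id = "img001")
  mks <- lapply(1:3, function(i)
    sphereMarker(c(0, 0, 600 + 100 * i), 15, frame = "S",
                 label = sprintf("c%02d", i)))
  names(mks) <- vapply(mks, function(m) m@label, "")
  entries <- do.call(rbind, lapply(mks, function(m) {
    pts <- sampleOutline(projectSphere(sphereMarker(m@center, 15, "W"), cam),
                         40)
    data.frame(image = "img001", marker = m@label, x = pts[, 1],
               y = pts[, 2])
  }))
  obs <- observationSet(list(img001 = cam), mks, entries)
  pts <- entries[entries$marker == "c01", c("x", "y")]
  mkRes <- function(Tr) new("RegistrationResult", transform = Tr, scale = 1,
                            finalCost = 0, initialCost = 0,
                            perImageRms = numeric(), nIterations = 0L,
                            converged = TRUE)
  lat <- evaluateRegistration(
    mkRes(rigidTransform(diag(3), c(1, 0, 0), frameFrom = "S",
                         frameTo = "W")), obs)
  # oracle: per-ray |d(ray, c + (1,0,0)) - r| computed directly for c01
  mW <- sphereMarker(mks$c01@center + c(1, 0, 0), 15, "W")
  oracle <- mean(sapply(seq_len(nrow(pts)), function(i)
    radialError(as.numeric(pts[i, ]), cam, mW)))
  latC01 <- lat@perMarker$mean_mm[lat@perMarker$marker == "c01"]
  expect_equal(latC01, oracle, tolerance = 1e-12)
  expect_gt(lat@meanMm, 0.5)   # lateral shift: errors approach 1 mm
  expect_lt(lat@meanMm, 1.0)
  axial <- evaluateRegistration(
    mkRes(rigidTransform(diag(3), c(0, 0, 1), frameFrom = "S",
                         frameTo = "W")), obs)
  expect_lt(axial@meanMm, 0.05)  # axial shift barely breaks tangency
})

test_that("validity: an ObservationSet needs 5 points per pair and 3 markers", {
  cam <- deskCamera(id = "img001")
  mks <- lapply(1:3, function(i)
    sphereMarker(c(50 * i, 0, 800), 15, "S", sprintf("m%02d", i)))
  names(mks) <- sapply(mks, function(m) m@label)
  good <- do.call(rbind, lapply(names(mks), function(lb)
    data.frame(image = "img001", marker = lb, x = rnorm(5), y = rnorm(5))))
  expect_s4_class(observationSet(list(img001 = cam), mks, good),
                  "ObservationSet")
  expect_error(observationSet(list(img001 = cam), mks, good[-1, ]),
               ">= 5 outline points")
  expect_error(observationSet(list(img001 = cam), mks,
                              good[good$marker != "m03", ]),
               "3 distinct markers")
})
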