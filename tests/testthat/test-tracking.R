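# Detection and tracking: distance images, suppressed maxima, the
# Gaussian-weighted search, duplicate pruning and the full tracker loop.

diskImage <- function(H, W, cx, cy, r, fg = 255, bg = 0) {
  img <- matrix(bg, H, W)
  mask <- (col(img) - 1 - cx)^2 + (row(img) - 1 - cy)^2 <= r^2
  img[mask] <- fg
  img
}

test_that("a frame entirely below threshold maps to an all-zero distance image", {
  d <- preprocessFrame(matrix(10, 32, 32),
                       detectionParams(blurSigma = 0, threshold = 100))
  expect_true(all(d == 0))
})

test_that("the distance image of a disk peaks near its centre at ~radius", {
  img <- diskImage(100, 100, 50, 50, 10)
  d <- preprocessFrame(img, detectionParams(blurSigma = 0, threshold = 128))
  expect_lt(abs(max(d) - 10), 1 + 1e-9)
  peak <- which(d == max(d), arr.ind = TRUE)[1, ]
  expect_lt(abs((peak[2] - 1) - 50), 1 + 1e-9)
  expect_lt(abs((peak[1] - 1) - 50), 1 + 1e-9)
})

test_that("preprocessFrame equals the brute-force distance transform", {
  set.seed(21)
  for (i in 1:8) {
    H <- sample(16:64, 1); W <- sample(16:64, 1)
    bin <- matrix(rbinom(H * W, 1, runif(1, 0.2, 0.8)), H, W) * 255
    d <- preprocessFrame(bin, detectionParams(blurSigma = 0, threshold = 128))
    expect_equal(d, bruteDistanceTransform(bin > 128), tolerance = 0)
  }
})

test_that("two disjoint disks give two regions peaking at the centres", {
  img <- diskImage(64, 64, 15, 20, 7) + diskImage(64, 64, 45, 44, 7)
  d <- preprocessFrame(img, detectionParams(blurSigma = 0, threshold = 128))
  expect_equal(d, bruteDistanceTransform(img > 128), tolerance = 0)
  dets <- detectCells(d, detectionParams(suppressionRadius = 8,
                                         minPeakValue = 3))
  expect_equal(nrow(dets), 2)
  dets <- dets[order(dets$x), ]
  expect_lt(max(abs(dets$x - c(15, 45))), 1 + 1e-9)
  expect_lt(max(abs(dets$y - c(20, 44))), 1 + 1e-9)
})

test_that("detection on an all-zero image is empty", {
  expect_equal(nrow(detectCells(matrix(0, 20, 20))), 0)
})

test_that("equal maxima within the suppression radius collapse to one, row-major", {
  d <- matrix(0, 10, 10)
  d[3, 3] <- 5; d[3, 6] <- 5        # (x=2,y=2) and (x=5,y=2), 0-based
  dets <- detectCells(d, detectionParams(suppressionRadius = 4,
                                         minPeakValue = 1))
  expect_equal(nrow(dets), 1)
  expect_equal(dets$x, 2)           # smaller x wins the tie
  expect_equal(dets$y, 2)
})

test_that("detection order is a deterministic function of the image", {
  set.seed(3)
  d <- matrix(runif(400), 20, 20)
  a <- detectCells(d, detectionParams(suppressionRadius = 3, minPeakValue = 0.1))
  b <- detectCells(d[, ], detectionParams(suppressionRadius = 3,
                                          minPeakValue = 0.1))
  expect_identical(a, b)
})

test_that("trackStep follows stationary and displaced disks", {
  p <- detectionParams(blurSigma = 0, threshold = 128)
  t1 <- preprocessFrame(diskImage(64, 64, 30, 30, 8), p)
  expect_equal(unname(trackStep(t1, c(30, 30))), c(30, 30))
  t2 <- preprocessFrame(diskImage(64, 64, 32, 30, 8), p)
  nxt <- trackStep(t2, c(30, 30))
  expect_lt(abs(nxt[["x"]] - 32), 1 + 1e-9)
  expect_lt(abs(nxt[["y"]] - 30), 1 + 1e-9)
})

test_that("trackStep reports lost over pure background", {
  expect_null(trackStep(matrix(0, 50, 50), c(25, 25)))
})

test_that("trackStep matches an exhaustive weighted argmax", {
  set.seed(7)
  d <- matrix(runif(64 * 64, 0, 10), 64, 64)
  prm <- trackingParams(searchHalfwidth = 10, gaussianSigma = 5)
  prev <- c(31, 27)
  got <- trackStep(d, prev, prm)
  best <- -Inf; bx <- NA; by <- NA
  for (r in 1:64) for (cc in 1:64) {
    x <- cc - 1; y <- r - 1
    if (abs(x - prev[1]) > 10 || abs(y - prev[2]) > 10) next
    w <- d[r, cc] * exp(-((x - prev[1])^2 + (y - prev[2])^2) / (2 * 25))
    if (w > best) { best <- w; bx <- x; by <- y }
  }
  expect_equal(unname(got), c(bx, by))
})

test_that("duplicate pruning keeps the longer-lived track, lower id on ties", {
  act <- data.frame(id = 1:3, x = c(10, 11, 12), y = c(10, 10, 11),
                    age = c(5, 3, 3))
  kept <- pruneDuplicates(act, duplicateRadius = 5)
  expect_equal(kept$id, 1)
  act2 <- data.frame(id = 1:2, x = c(10, 10), y = c(10, 10), age = c(2, 2))
  expect_equal(pruneDuplicates(act2, 1)$id, 1)
  act3 <- data.frame(id = 1:3, x = c(0, 50, 100), y = 0, age = c(1, 1, 1))
  expect_equal(sort(pruneDuplicates(act3, 5)$id), 1:3)
})

test_that("a stationary cell yields exactly one full-length track", {
  frames <- replicate(50, diskImage(64, 64, 30, 30, 8, fg = 200, bg = 50),
                      simplify = FALSE)
  tr <- runTracking(frames, detectionParams(blurSigma = 0),
                    trackingParams())
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 50)
  expect_equal(sort(unique(tr$frame)), 0:49)
})

test_that("an empty video yields no tracks", {
  frames <- replicate(12, matrix(50L, 64, 64), simplify = FALSE)
  tr <- runTracking(frames)
  expect_equal(nrow(tr), 0)
})

test_that("tracking invariants hold on a synthetic scene", {
  sc <- generateScene(sceneConfig(nCells = 10, nFrames = 30, fieldWidth = 256,
                                  fieldHeight = 256, speedMean = 2,
                                  speedSd = 0.3, noiseSd = 3, seed = 14))
  trk <- trackingParams()
  tr <- runTracking(frames(sc), detectionParams(), trk)
  # gapless frames and in-field positions
  expect_true(all(vapply(split(tr$frame, tr$track_id),
                         function(f) all(diff(f) == 1), logical(1))))
  expect_true(all(tr$x >= 0 & tr$x <= 255 & tr$y >= 0 & tr$y <= 255))
  # no two concurrent positions within the duplicate radius
  minSep <- Inf
  for (f in unique(tr$frame)) {
    sub <- tr[tr$frame == f, ]
    if (nrow(sub) >= 2) minSep <- min(minSep, min(dist(sub[, c("x", "y")])))
  }
  expect_gt(minSep, trk$duplicateRadius)
  # and the scene is essentially recovered
  ev <- evaluateTracking(trueTracks(sc), tr, tol = 3)
  expect_gt(ev$recovered, 0.9)
})
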