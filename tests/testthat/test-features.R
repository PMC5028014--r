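# The ten per-video features and their kinematic building blocks.

lineTrack <- function(xy) data.frame(track_id = 1L,
                                     frame = seq_len(nrow(xy)) - 1L,
                                     x = xy[, 1], y = xy[, 2])

test_that("step speed is the Euclidean displacement per frame", {
  expect_equal(stepSpeeds(lineTrack(rbind(c(74, 32), c(75, 33)))), sqrt(2))
  expect_equal(stepSpeeds(lineTrack(rbind(c(0, 0), c(3, 4)))), 5)
  expect_equal(stepSpeeds(lineTrack(rbind(c(5, 5), c(5, 5), c(5, 5)))),
               c(0, 0))
  expect_length(stepSpeeds(lineTrack(rbind(c(1, 1)))), 0)
})

test_that("headings are atan2 of the step vector; zero steps are undefined", {
  expect_equal(stepDirections(lineTrack(rbind(c(0, 0), c(1, 0)))), 0)
  expect_equal(stepDirections(lineTrack(rbind(c(0, 0), c(0, 1)))), pi / 2)
  expect_equal(stepDirections(lineTrack(rbind(c(0, 0), c(0, 0)))), NA_real_)
})

test_that("angular velocity wraps to [0, pi]", {
  # straight line: all zero
  straight <- lineTrack(cbind(0:5, 0))
  expect_equal(angularVelocities(straight), rep(0, 4))
  # right-angle turn
  ra <- lineTrack(rbind(c(0, 0), c(1, 0), c(1, 1)))
  expect_equal(angularVelocities(ra), pi / 2)
  # reversal is the maximal wrapped difference
  rev <- lineTrack(rbind(c(0, 0), c(1, 0), c(0, 0)))
  expect_equal(angularVelocities(rev), pi)
  # crossing the +/-pi seam stays small
  seam <- lineTrack(rbind(c(0, 0), c(-1, 0.01), c(-2, 0)))
  expect_lt(angularVelocities(seam), 0.05)
  # zero-displacement steps are skipped as undefined
  z <- lineTrack(rbind(c(0, 0), c(1, 0), c(1, 0), c(2, 0)))
  expect_equal(angularVelocities(z), c(NA_real_, NA_real_))
})

test_that("kinematic features pool steps across tracks", {
  tr <- rbind(data.frame(track_id = 1, frame = 0:3,
                         x = cumsum(c(0, 2, 2, 2)), y = 0),
              data.frame(track_id = 2, frame = 0:3,
                         x = 100 + cumsum(c(0, 4, 4, 4)), y = 50))
  f <- extractFeatures(tr)
  expect_equal(unname(f["avg_migration_speed"]), 3)   # (3*2 + 3*4)/6
  expect_equal(unname(f["avg_angular_velocity"]), 0)
  expect_true(is.na(f["in_contact_speed"]))
  expect_true(is.na(f["post_contact_speed"]))
})

test_that("pooled mean equals the step-count-weighted mean of track means", {
  set.seed(5)
  trs <- lapply(1:4, function(id) {
    n <- sample(3:9, 1)
    data.frame(track_id = id, frame = seq_len(n) - 1,
               x = cumsum(runif(n, 0, 4)), y = cumsum(runif(n, 0, 4)))
  })
  tr <- do.call(rbind, trs)
  pooled <- unname(extractFeatures(tr,
    contactParams(contactRadius = 0.1))["avg_migration_speed"])
  per <- lapply(trs, stepSpeeds)
  weighted <- sum(vapply(per, sum, numeric(1))) / sum(lengths(per))
  expect_equal(pooled, weighted)
})

test_that("cohesivity averages contacts per cell over frames", {
  cp <- contactParams(contactRadius = 10)
  g0 <- contactGraph(data.frame(id = 1:4, x = c(0, 100, 200, 300), y = 0), cp)
  expect_equal(cohesivity(list(g0)), 0)
  g1 <- contactGraph(data.frame(id = 1:4, x = c(0, 8, 200, 300), y = 0), cp)
  expect_equal(cohesivity(list(g1)), 0.5)            # 2 * 1 / 4
  gK <- contactGraph(data.frame(id = 1:5, x = c(0, 4, 8, 2, 6),
                                y = c(0, 0, 0, 4, 4)), cp)
  expect_equal(cohesivity(list(gK)), 4)              # complete graph on 5
  expect_equal(cohesivity(list(g0, g1)), 0.25)
})

test_that("cell count is max tracked minus initially tracked", {
  mk <- function(counts) {
    do.call(rbind, lapply(seq_along(counts), function(i)
      data.frame(track_id = seq_len(counts[i]) * 100 + i, frame = i - 1,
                 x = seq_len(counts[i]) * 50, y = 0)))
  }
  # track ids here are not contiguous across frames; only counts matter
  f <- extractFeatures(mk(c(10, 12, 15, 14)),
                       contactParams(contactRadius = 1))
  expect_equal(unname(f["cell_count"]), 5)
})

test_that("a stationary isolated cell yields the degenerate vector", {
  tr <- data.frame(track_id = 1, frame = 0:5, x = 10, y = 10)
  f <- extractFeatures(tr)
  expect_equal(unname(f["avg_migration_speed"]), 0)
  expect_equal(unname(f["cohesivity"]), 0)
  expect_equal(unname(f["cell_count"]), 0)
  expect_true(all(is.na(f[c("post_contact_speed", "in_contact_speed",
                            "avg_angular_velocity",
                            "post_contact_angular_velocity",
                            "in_contact_angular_velocity",
                            "avg_clump_size", "avg_contact_duration")])))
})

test_that("clump features: a persistent 5-clump with one visiting member", {
  # 5 cells packed together for frames 0..6; a 6th far away
  clump <- do.call(rbind, lapply(1:5, function(i)
    data.frame(track_id = i, frame = 0:6, x = i * 4, y = 0)))
  lone <- data.frame(track_id = 6, frame = 0:6, x = 500, y = 500)
  f <- extractFeatures(rbind(clump, lone), contactParams(contactRadius = 5))
  expect_equal(unname(f["avg_clump_size"]), 5)
  expect_equal(unname(f["avg_contact_duration"]), 7)
})

test_that("in-contact statistics restrict to clump-member start frames", {
  # five cells creep outward from a tight cluster (clump, speed 0.5), then
  # disperse radially at speed 25; only the single transition step leaks
  # into the in-contact pool
  mkTrack <- function(id) {
    a <- 2 * pi * id / 5
    r <- c(2 + 0.5 * (0:9), 6.5 + 25 * (1:3))
    data.frame(track_id = id, frame = 0:12,
               x = 50 + r * cos(a), y = 50 + r * sin(a))
  }
  tr <- do.call(rbind, lapply(1:5, mkTrack))
  f <- extractFeatures(tr, contactParams(contactRadius = 16,
                                         postContactWindow = 3))
  expect_false(is.na(f["in_contact_speed"]))
  expect_gt(unname(f["avg_migration_speed"]),
            unname(f["in_contact_speed"]))
})

test_that("feature extraction is invariant to track id relabelling", {
  sc <- generateScene(sceneConfig(nCells = 8, nFrames = 15, fieldWidth = 150,
                                  fieldHeight = 150, clumpAttraction = 1,
                                  noiseSd = 0, seed = 12))
  tr <- trueTracks(sc)
  f1 <- extractFeatures(tr)
  tr2 <- tr
  ids <- unique(tr2$track_id)
  remap <- setNames(rev(ids) * 7 + 1, ids)
  tr2$track_id <- remap[as.character(tr2$track_id)]
  f2 <- extractFeatures(tr2)
  expect_equal(f1, f2)
})

test_that("slowing clumped cells depresses the in-contact speed", {
  sc <- generateScene(sceneConfig(nCells = 10, nFrames = 50, fieldWidth = 220,
                                  fieldHeight = 220, speedMean = 3,
                                  speedSd = 0.2, clumpAttraction = 1.5,
                                  attractionRange = 120,
                                  contactSlowdown = 0.5, noiseSd = 0,
                                  seed = 6))
  cfg <- sceneConfigOf(sc)
  f <- extractFeatures(trueTracks(sc),
                       contactParams(contactRadius = cfg$contactRadius))
  expect_false(is.na(f["in_contact_speed"]))
  expect_lt(unname(f["in_contact_speed"]), unname(f["avg_migration_speed"]))
})

test_that("scenes differing only in speedMean preserve the speed ordering", {
  mk <- function(sp) generateScene(sceneConfig(nCells = 10, nFrames = 40,
                                               fieldWidth = 400,
                                               fieldHeight = 400,
                                               speedMean = sp, speedSd = 0.2,
                                               noiseSd = 0, seed = 77))
  fFast <- extractFeatures(trueTracks(mk(3.5)))
  fSlow <- extractFeatures(trueTracks(mk(2.0)))
  expect_gt(unname(fFast["avg_migration_speed"]),
            unname(fSlow["avg_migration_speed"]))
})
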