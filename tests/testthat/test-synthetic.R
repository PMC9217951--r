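# Synthetic-data generator: construction guarantees, determinism, and the
# statistical structure the downstream analysis assumes.

test_that("noise-free events obey the construction geometry", {
  p <- noiselessParams()
  ev <- simulateEvent(p, "cme_arpc3_negative", seed = 1)
  d <- ev$tracks[ev$tracks$channel == "DNM2", ]
  expect_equal(d$frame[which.max(d$amplitude)], ev$truth$scission_frame)

  evl <- simulateEvent(p, "cme_arpc3_late", seed = 2)
  a <- evl$tracks[evl$tracks$channel == "AP2", ]
  th <- evl$third
  m <- match(th$t, a$t)
  dist <- sqrt((th$x - a$x[m])^2 + (th$y - a$y[m])^2)
  expect_equal(dist, rep(p$arpc3Offset, length(dist)), tolerance = 1e-12)
  expect_equal(sqrt(evl$truth$offset_x^2 + evl$truth$offset_y^2),
               p$arpc3Offset)
  # DNM2 argmax still marks scission for the stalled class
  dl <- evl$tracks[evl$tracks$channel == "DNM2", ]
  expect_equal(dl$frame[which.max(dl$amplitude)], evl$truth$scission_frame)
})

test_that("invalid class labels and parameters are rejected", {
  expect_error(simulateEvent(eventParams(), "plaque", seed = 1),
               "invalid class label")
  expect_error(eventParams(fracVisitors = 1.2), "must lie in")
  expect_error(eventParams(frameInterval = 0), "frameInterval")
  expect_error(eventParams(lifetimeSigma = -1), "lifetimeSigma")
})

test_that("Rayleigh MLE on drawn base lifetimes recovers sigma within 2%", {
  p <- eventParams(fracVisitors = 0, stallPlateau = 0)
  ds <- simulateDataset(p, 5000, seed = 11)
  lt <- ds$truth$base_lifetime
  sigmaHat <- sqrt(sum(lt^2) / (2 * length(lt)))   # closed-form MLE
  expect_lt(abs(sigmaHat - 20) / 20, 0.02)
})

test_that("generated base lifetimes pass a Rayleigh goodness-of-fit test", {
  p <- eventParams(fracVisitors = 0, stallPlateau = 0)
  pvals <- vapply(1:5, function(s) {
    ds <- simulateDataset(p, 1000, seed = 100 + s)
    suppressWarnings(ks.test(ds$truth$base_lifetime, function(q)
      1 - exp(-q^2 / (2 * 20^2)))$p.value)
  }, numeric(1L))
  expect_gte(sum(pvals > 0.01), 4L)
})

test_that("datasets are reproducible and class fractions behave", {
  p <- eventParams()
  d1 <- simulateDataset(p, 60, seed = 5)
  d2 <- simulateDataset(p, 60, seed = 5)
  expect_identical(trackData(d1$events), trackData(d2$events))
  expect_identical(trackData(d1$third), trackData(d2$third))
  expect_identical(d1$truth, d2$truth)
  expect_false(any(duplicated(d1$truth$event_id)))

  # ~70% of non-visitor events ARPC3-positive (binomial 95% bounds)
  p0 <- eventParams(fracVisitors = 0)
  ds <- simulateDataset(p0, 100, seed = 7)
  nPos <- sum(ds$truth$class == "cme_arpc3_late")
  expect_gt(nPos, 70 - 1.96 * sqrt(100 * 0.7 * 0.3))
  expect_lt(nPos, 70 + 1.96 * sqrt(100 * 0.7 * 0.3))

  dv <- simulateDataset(eventParams(fracVisitors = 0), 50, seed = 8)
  expect_false(any(dv$truth$class == "visitor"))
})

test_that("localization pairs realize their generating offset", {
  lp <- simulateLocalizationPair(c(100, 0), 1000, 10, seed = 3)
  se <- 10 / sqrt(1000)
  expect_lt(abs(centroidDistance(lp$a, lp$b) - 100), 3 * se * sqrt(2))

  lp0 <- simulateLocalizationPair(c(40, -25), 1, 0, seed = 4)
  expect_equal(centroidDistance(lp0$a, lp0$b), sqrt(40^2 + 25^2))
})

test_that("randomized pairing rejects shared id namespaces and is seeded", {
  p <- eventParams()
  A <- simulateDataset(p, 30, seed = 9)
  B <- simulateDataset(p, 30, seed = 10)
  expect_error(randomizeChannelPairing(A, A), "share an id namespace")
  r1 <- randomizeChannelPairing(A, B, seed = 1)
  r2 <- randomizeChannelPairing(A, B, seed = 1)
  expect_identical(trackData(r1$third), trackData(r2$third))
  expect_true(all(is.na(r1$truth$third_id)))
  # dataset B stripped of ARPC3 tracks -> nothing to link, all negative
  emptyThird <- TrackSet(trackData(B$third)[0, ], frameInterval(B$third))
  rEmpty <- randomizeChannelPairing(A, list(events = B$events,
                                            third = emptyThird,
                                            truth = B$truth), seed = 2)
  expect_equal(nEvents(rEmpty$third), 0L)
})
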