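# Third-channel linking, timing classification and the positive fraction.

test_that("linking respects the radius and is translation invariant", {
  p <- noiselessParams(fracVisitors = 0, fracArpc3Positive = 1)
  ev <- simulateEvent(p, "cme_arpc3_late", seed = 51, anchor = c(5000, 5000))
  events <- TrackSet(ev$tracks, 1)
  third <- TrackSet(ev$third, 1)
  links <- linkThirdChannel(events, third, linkRadius = 300, minOverlap = 3)
  expect_equal(nrow(links), 1L)
  expect_equal(links$median_sep, 150, tolerance = 1e-9)
  # a 1000 nm offset track stays unlinked
  far <- ev$third
  far$x <- far$x + 1000
  linksFar <- linkThirdChannel(events, TrackSet(far, 1), 300, 3)
  expect_equal(nrow(linksFar), 0L)
  expect_equal(attr(linksFar, "unlinked"), ev$truth$third_id)
  # global translation changes nothing
  sh <- function(df) { df$x <- df$x + 1e5; df$y <- df$y - 5e4; df }
  linksSh <- linkThirdChannel(TrackSet(sh(ev$tracks), 1),
                              TrackSet(sh(ev$third), 1), 300, 3)
  expect_equal(linksSh$median_sep, links$median_sep, tolerance = 1e-9)
})

test_that("linking recovers the generator's true associations", {
  p <- eventParams(fracVisitors = 0)
  ds <- simulateDataset(p, 300, seed = 52)
  links <- linkThirdChannel(ds$events, ds$third)
  tr <- ds$truth[ds$truth$class == "cme_arpc3_late", ]
  m <- match(tr$event_id, links$event_id)
  recall <- mean(!is.na(m) & links$track_id[m] == tr$third_id)
  inLate <- links[links$event_id %in% tr$event_id, ]
  precision <- mean(inLate$track_id ==
                      tr$third_id[match(inLate$event_id, tr$event_id)])
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("timing classes follow the declared onset rules", {
  mkAnn <- function(lifetime, scission) {
    data.frame(event_id = "e1", n_dnm2_peaks = 1L,
               scission_frame = scission, t_scission = scission,
               ap2_onset_frame = 0L, t_ap2_onset = scission - lifetime,
               lifetime = lifetime)
  }
  mkTrack <- function(onset, end, id = "t1") {
    i <- 0:(end - onset)
    TrackSet(data.frame(event_id = id, channel = "ARPC3", frame = i,
                        t = onset + i, x = 0, y = 0, amplitude = 50,
                        amplitude_present = TRUE, position_sd = 15), 1)
  }
  lk <- data.frame(track_id = "t1", event_id = "e1", median_sep = 100,
                   n_overlap = 5L, t_first = 0)
  evDummy <- mkTrack(0, 5, "e1")
  # onset 5 s before scission on a 60 s event -> late
  a1 <- classifyTiming(mkAnn(60, 60), evDummy, mkTrack(55, 65), lk)
  expect_equal(a1$arpc3_class, "late")
  expect_equal(a1$assembly_duration, 5)
  # onset at 10% of an 80 s lifetime (72 s before scission) -> early
  a2 <- classifyTiming(mkAnn(80, 80), evDummy, mkTrack(8, 20), lk)
  expect_equal(a2$arpc3_class, "early")
  # no linked track -> negative
  a3 <- classifyTiming(mkAnn(60, 60), evDummy, mkTrack(55, 65),
                       lk[0, , drop = FALSE])
  expect_equal(a3$arpc3_class, "negative")
  # linked track with no significant frames -> negative
  dead <- mkTrack(55, 65)
  dd <- trackData(dead)
  dd$amplitude_present <- FALSE
  a4 <- classifyTiming(mkAnn(60, 60), evDummy, TrackSet(dd, 1), lk)
  expect_equal(a4$arpc3_class, "negative")
  # onset only after scission -> negative
  a5 <- classifyTiming(mkAnn(60, 60), evDummy, mkTrack(61, 70), lk)
  expect_equal(a5$arpc3_class, "negative")
})

test_that("true late events are classified late at the defaults", {
  p <- eventParams(fracVisitors = 0)
  ds <- simulateDataset(p, 300, seed = 53)
  sel <- selectPeakParameters(ds$events)
  fsp <- filterSinglePeak(ds$events, sel$params)
  links <- linkThirdChannel(fsp$events, ds$third)
  ann <- classifyTiming(fsp$annotations, fsp$events, ds$third, links)
  cls <- ds$truth$class[match(ann$event_id, ds$truth$event_id)]
  expect_gte(mean(ann$arpc3_class[cls == "cme_arpc3_late"] == "late"), 0.95)
})

test_that("positiveFraction recovers the generating fraction with a CI", {
  ann0 <- data.frame(event_id = "a", arpc3_class = "negative")
  expect_equal(positiveFraction(ann0, nBoot = 10)$fraction, 0)
  p <- eventParams(fracVisitors = 0, strayArpc3PerEvent = 0)
  ds <- simulateDataset(p, 1000, seed = 54)
  sel <- selectPeakParameters(ds$events)
  fsp <- filterSinglePeak(ds$events, sel$params)
  links <- linkThirdChannel(fsp$events, ds$third)
  ann <- classifyTiming(fsp$annotations, fsp$events, ds$third, links)
  pf <- positiveFraction(ann, seed = 55)
  halfWidth <- 2.58 * sqrt(0.7 * 0.3 / pf$n)
  expect_lt(abs(pf$fraction - 0.7), halfWidth + 0.02)  # + small link loss
  expect_lt(pf$ci[1], pf$fraction)
  expect_gt(pf$ci[2], pf$fraction)
})
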