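# Event-level statistics: lifetimes, assembly durations, cohorts,
# separations, motility, straightness, group tests.

mkAnnRow <- function(id, onset, scission, cls = "negative",
                     arpOnset = NA_real_, third = NA_character_) {
  data.frame(event_id = id, n_dnm2_peaks = 1L, scission_frame = scission,
             t_scission = scission, ap2_onset_frame = onset,
             t_ap2_onset = onset, lifetime = scission - onset,
             arpc3_class = cls, arpc3_onset_t = arpOnset,
             assembly_duration = scission - arpOnset, third_id = third,
             stringsAsFactors = FALSE)
}

test_that("lifetime and assembly duration are plain aligned arithmetic", {
  ann <- mkAnnRow("e1", 5, 50)
  expect_equal(unname(eventLifetime(ann)), 45)
  ann0 <- mkAnnRow("e2", 50, 50)
  expect_equal(unname(eventLifetime(ann0)), 0)
  bad <- mkAnnRow("e3", 60, 50)
  expect_error(eventLifetime(bad), "precedes")
  annA <- mkAnnRow("e4", 0, 60, "late", arpOnset = 40, third = "t1")
  expect_equal(unname(assemblyDuration(annA)), 20)
  annB <- mkAnnRow("e5", 0, 60, "late", arpOnset = 60, third = "t1")
  expect_equal(unname(assemblyDuration(annB)), 0)
})

test_that("noise-free assembly durations equal the generator onset lead", {
  p <- noiselessParams(fracVisitors = 0, fracArpc3Positive = 1,
                       arpc3OnsetLead = 15, strayArpc3PerEvent = 0)
  ds <- simulateDataset(p, 60, seed = 61)
  sel <- selectPeakParameters(ds$events)
  fsp <- filterSinglePeak(ds$events, sel$params)
  links <- linkThirdChannel(fsp$events, ds$third)
  ann <- classifyTiming(fsp$annotations, fsp$events, ds$third, links)
  dur <- assemblyDuration(ann)
  # the onset lead is realized exactly; events shorter than the lead start
  # their ARPC3 track at frame 0, so the duration saturates at the lifetime
  lt <- eventLifetime(ann)[names(dur)]
  expect_true(all(abs(dur - pmin(15, lt)) <= 1e-9))
})

test_that("stalled events live ~plateau longer than unstalled events", {
  p <- eventParams(fracVisitors = 0, fracArpc3Positive = 0.5,
                   stallPlateau = 10)
  ds <- simulateDataset(p, 300, seed = 62)
  lt <- ds$truth$lifetime
  stalled <- ds$truth$class == "cme_arpc3_late"
  expect_lt(abs((mean(lt[stalled]) - mean(lt[!stalled])) - 10), 3)
})

test_that("cohort averages align at scission and sum to 100 percent", {
  p <- noiselessParams(fracVisitors = 0)
  ds <- simulateDataset(p, 120, seed = 63)
  sel <- selectPeakParameters(ds$events)
  fsp <- filterSinglePeak(ds$events, sel$params)
  cs <- cohortAverage(fsp$events, fsp$annotations,
                      edges = c(5, 20, 40, 60, 120))
  expect_equal(sum(cs$cohorts$percent), 100)
  d <- cs$summary[cs$summary$channel == "DNM2", ]
  for (co in unique(d$cohort)) {
    sub <- d[d$cohort == co, ]
    expect_equal(sub$tau[which.max(sub$mean)], 0)
  }
  expect_equal(cs$summary$band, cs$summary$sd / 4)
})

test_that("a single-event cohort reproduces that event's trace exactly", {
  p <- noiselessParams(fracVisitors = 0, fracArpc3Positive = 0)
  ev <- simulateEvent(p, "cme_arpc3_negative", seed = 64, tStart = 0)
  ts <- TrackSet(ev$tracks, 1)
  pk <- peakParams(2, 1, 3)
  fsp <- filterSinglePeak(ts, pk)
  cs <- cohortAverage(ts, fsp$annotations, edges = c(0, 200))
  a <- cs$summary[cs$summary$channel == "AP2", ]
  orig <- ev$tracks[ev$tracks$channel == "AP2", ]
  expect_equal(a$mean, orig$amplitude[match(a$tau + fsp$annotations$t_scission,
                                            orig$t)], tolerance = 1e-12)
  expect_true(all(a$sd == 0))
})

test_that("interchannel distances are zero for coincident channels and rotation invariant", {
  p <- noiselessParams(fracVisitors = 0, fracArpc3Positive = 1)
  ev <- simulateEvent(p, "cme_arpc3_late", seed = 65, anchor = c(3000, 4000))
  ts <- TrackSet(ev$tracks, 1)
  third <- TrackSet(ev$third, 1)
  ann <- filterSinglePeak(ts, peakParams(2, 1, 3))$annotations
  ann$third_id <- ev$truth$third_id
  dAD <- interchannelDistance(ts, ann, "AP2", "DNM2", window = c(-10, 3))
  expect_true(all(dAD$distance == 0))  # channels share the anchor, no noise
  dAA <- interchannelDistance(ts, ann, "AP2", "ARPC3", window = c(-5, 0),
                              third = third)
  expect_equal(dAA$distance, rep(150, nrow(dAA)), tolerance = 1e-9)
  # rotate the whole field by 37 degrees about an arbitrary pivot
  rot <- function(df, th = 37 * pi / 180, pv = c(1000, -2000)) {
    xr <- pv[1] + cos(th) * (df$x - pv[1]) - sin(th) * (df$y - pv[2])
    yr <- pv[2] + sin(th) * (df$x - pv[1]) + cos(th) * (df$y - pv[2])
    df$x <- xr; df$y <- yr; df
  }
  dR <- interchannelDistance(TrackSet(rot(ev$tracks), 1), ann, "AP2",
                             "ARPC3", window = c(-5, 0),
                             third = TrackSet(rot(ev$third), 1))
  expect_equal(dR$distance, dAA$distance, tolerance = 1e-9)
})

test_that("scission-frame separations match the closed-form Rice mean", {
  p <- eventParams(fracVisitors = 0, fracArpc3Positive = 1,
                   positionNoiseSd = 20, strayArpc3PerEvent = 0)
  ds <- simulateDataset(p, 300, seed = 66)
  sel <- selectPeakParameters(ds$events)
  fsp <- filterSinglePeak(ds$events, sel$params)
  links <- linkThirdChannel(fsp$events, ds$third)
  ann <- classifyTiming(fsp$annotations, fsp$events, ds$third, links)
  d0 <- interchannelDistance(fsp$events, ann, "AP2", "ARPC3",
                             window = c(0, 0), third = ds$third)
  expected <- riceMean(150, sqrt(2) * 20)
  expect_lt(abs(mean(d0$distance) - expected), 15)
})

test_that("lateral motility matches elementary kinematics", {
  mkTrack <- function(xy, id = "m1") {
    n <- nrow(xy)
    i <- 0:(n - 1)
    rbind(data.frame(event_id = id, channel = "AP2", frame = i, t = i,
                     x = xy[, 1], y = xy[, 2], amplitude = 10,
                     amplitude_present = TRUE, position_sd = 15),
          data.frame(event_id = id, channel = "DNM2", frame = i, t = i,
                     x = xy[, 1], y = xy[, 2],
                     amplitude = c(rep(1, n - 3), 10, 1, 1),
                     amplitude_present = TRUE, position_sd = 15))
  }
  xy <- cbind(seq(0, 950, by = 50), 0)   # straight, 50 nm/frame
  ts <- TrackSet(mkTrack(xy), 1)
  ann <- filterSinglePeak(ts, peakParams(2, 1, 3))$annotations
  mot <- lateralMotility(ts, ann, "before", windowFrames = 10)
  expect_equal(as.numeric(mot), 50)
  xyS <- cbind(rep(5, 20), rep(-3, 20))  # stationary
  tsS <- TrackSet(mkTrack(xyS, "m2"), 1)
  annS <- filterSinglePeak(tsS, peakParams(2, 1, 3))$annotations
  expect_equal(as.numeric(lateralMotility(tsS, annS, "before")), 0)
  # pure diffusion: mean 2-D step length = stepSd * sqrt(pi / 2) per axis sd
  set.seed(67)
  stepSd <- 30
  xyD <- apply(matrix(rnorm(2 * 5000, 0, stepSd), 5000, 2), 2, cumsum)
  expect_lt(abs(mean(sqrt(rowSums(diff(xyD)^2))) - stepSd * sqrt(pi / 2)) /
              (stepSd * sqrt(pi / 2)), 0.05)
})

test_that("straightness index follows the stated geometry", {
  expect_equal(straightnessIndex(rbind(c(0, 0), c(1, 0), c(2, 0))), 1)
  expect_equal(straightnessIndex(rbind(c(0, 0), c(1, 0), c(0, 0))), 0)
  expect_equal(straightnessIndex(rbind(c(0, 0), c(1, 0), c(1, 1))),
               sqrt(2) / 2)
  # literal path/net convention available behind the flag
  expect_equal(straightnessIndex(rbind(c(0, 0), c(1, 0), c(1, 1)),
                                 convention = "path_over_net"), sqrt(2))
  # scale and rotation invariant
  xy <- cbind(cumsum(rnorm(20)), cumsum(rnorm(20)))
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(straightnessIndex(xy * 12.5), straightnessIndex(xy))
  expect_equal(straightnessIndex(xy %*% R), straightnessIndex(xy))
  # stationary trajectory imputed as 1
  expect_equal(straightnessIndex(rbind(c(1, 1), c(1, 1))), 1)
})

test_that("separation-exceeds-motility mirrors the geometry of its inputs", {
  p <- eventParams(fracVisitors = 0, fracArpc3Positive = 1,
                   positionNoiseSd = 20, strayArpc3PerEvent = 0)
  ds <- simulateDataset(p, 200, seed = 68)
  sel <- selectPeakParameters(ds$events)
  fsp <- filterSinglePeak(ds$events, sel$params)
  links <- linkThirdChannel(fsp$events, ds$third)
  ann <- classifyTiming(fsp$annotations, fsp$events, ds$third, links)
  sem <- separationExceedsMotility(fsp$events, ann, ds$third)
  expect_gt(sem$fraction, 0.95)
  # offset 0: separation is pure noise, comparable to the step length
  p0 <- eventParams(fracVisitors = 0, fracArpc3Positive = 1,
                    arpc3Offset = 0, positionNoiseSd = 20,
                    strayArpc3PerEvent = 0)
  ds0 <- simulateDataset(p0, 200, seed = 69)
  fsp0 <- filterSinglePeak(ds0$events, sel$params)
  links0 <- linkThirdChannel(fsp0$events, ds0$third)
  ann0 <- classifyTiming(fsp0$annotations, fsp0$events, ds0$third, links0)
  sem0 <- separationExceedsMotility(fsp0$events, ann0, ds0$third)
  expect_lt(sem0$fraction, 0.7)
})

test_that("compareGroups wraps Welch and KS with their degenerate cases", {
  x <- rnorm(50)
  ksSame <- compareGroups(x, x, "ks")
  expect_equal(unname(ksSame$statistic), 0)
  expect_equal(ksSame$p.value, 1)
  set.seed(70)
  w <- compareGroups(rnorm(100, 0), rnorm(100, 5), "welch")
  expect_lt(w$p.value, 1e-10)
  expect_error(compareGroups(rep(1, 5), rep(2, 5), "welch"), "degenerate")
  expect_error(compareGroups(1, c(1, 2), "ks"), "at least 2")
  # null calibration: p roughly uniform under resampling of one pool
  set.seed(71)
  pool <- rnorm(60)
  ps <- replicate(200, {
    idx <- sample.int(60, 30)
    compareGroups(pool[idx], pool[-idx], "welch")$p.value
  })
  expect_gt(mean(ps < 0.5), 0.35)
  expect_lt(mean(ps < 0.5), 0.65)
  expect_lt(mean(ps < 0.05), 0.15)
})
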