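# Track statistics shared by simulation and experiment, and TrackMate IO.

test_that("TrackMate XML round-trips through the package writer", {
  df <- simulateTracks("brownian", nTracks = 3, nPoints = 15, dt = 0.05,
                       D = 0.2, seed = 1, intensity = c(500, 900, 1400))
  path <- tempfile(fileext = ".xml")
  writeTrackMateXML(df, path)
  back <- readTrackMateXML(path)
  expect_equal(attr(back, "spatialUnits"), "micron")
  for (col in c("frame", "t", "x", "y", "intensity"))
    expect_equal(back[[col]], as.numeric(df[[col]]), ignore_attr = TRUE)
  # and a second write/read reproduces itself exactly
  path2 <- tempfile(fileext = ".xml")
  writeTrackMateXML(back, path2)
  again <- readTrackMateXML(path2)
  expect_identical(again$x, back$x)
})

test_that("a single 12-spot track file parses to one track of length 12", {
  df <- simulateTracks("brownian", nTracks = 1, nPoints = 12, dt = 0.05,
                       D = 0.1, seed = 2)
  path <- tempfile(fileext = ".xml")
  writeTrackMateXML(df, path)
  back <- readTrackMateXML(path)
  expect_equal(length(unique(back$track)), 1)
  expect_equal(nrow(back), 12)
  expect_error(readTrackMateXML(tempfile(fileext = ".xml")))
})

test_that("gap-closing edges leave a flagged gap that lag statistics skip", {
  df <- simulateTracks("brownian", nTracks = 1, nPoints = 30, dt = 1,
                       D = 1, seed = 3)
  gap <- df[df$frame != 14, ]               # remove one frame: a bridged gap
  path <- tempfile(fileext = ".xml")
  writeTrackMateXML(gap, path)
  back <- readTrackMateXML(path)
  trs <- trackList(back)
  expect_true(attr(trs[[1]], "hasGap"))
  # lag-1 MSD uses only the within-segment pairs: 13 before + 14 after
  cur <- msdCurve(back, maxLag = 1)
  expect_equal(cur@counts, 27)
  full <- msdCurve(df, maxLag = 1)
  expect_equal(full@counts, 29)
})

test_that("MSD reproduces stationary, diffusive and drifting motion", {
  still <- data.frame(track = 1, frame = 0:29, t = 0:29, x = 2, y = 3)
  expect_true(all(msdCurve(still, 5)@values == 0))
  # 2-d Brownian: slope/4 recovers D within 5%
  df <- simulateTracks("brownian", nTracks = 250, nPoints = 60, dt = 0.5,
                       D = 0.8, dim = 2, seed = 4)
  fd <- fitDiffusivity(msdCurve(df, 10), dt = 0.5, dim = 2)
  expect_equal(fd$D, 0.8, tolerance = 0.05)
  # pure drift: MSD quadratic in lag (v^2 t^2)
  drift <- data.frame(track = 1, frame = 0:49, t = 0:49, x = 3 * (0:49), y = 0)
  cur <- msdCurve(drift, 6)
  expect_equal(cur@values, 9 * (1:6)^2)
  expect_error(msdCurve(still[1:5, ], 5), "length filter")
})

test_that("angle correlation is +1 for lines, -1 for reversals, 0 for Brownian", {
  line <- data.frame(track = 1, frame = 0:40, t = 0:40, x = 1.7 * (0:40),
                     y = 0.4 * (0:40))
  ac <- angleCorrelation(line, lags = 1:5)
  expect_equal(ac@values, rep(1, 5))
  zig <- data.frame(track = 1, frame = 0:40, t = 0:40,
                    x = rep(c(0, 1), length.out = 41), y = 0)
  expect_equal(angleCorrelation(zig, lags = 1)@values, -1)
  free <- simulateTracks("brownian", nTracks = 120, nPoints = 60, dt = 1,
                         D = 1, seed = 5)
  acF <- angleCorrelation(free, lags = 1:5)
  expect_true(all(abs(acF@values) <= 3 * acF@se))
  expect_true(all(acF@values >= -1 & acF@values <= 1))
  # strongly trapped (stiff OU): negative at lag 1
  trap <- simulateTracks("confined_ou", nTracks = 60, nPoints = 60, dt = 1,
                         D = 1, stiffness = 2, seed = 6)
  expect_lt(angleCorrelation(trap, lags = 1)@values, -0.3)
  # per-track weighting stays bounded and close to the pooled value
  acP <- angleCorrelation(free, lags = 1:3, perTrack = TRUE)
  expect_true(all(abs(acP@values - acF@values[1:3]) < 0.05))
})

test_that("normalized VACF matches the discrete OU closed form", {
  # constant velocity: C(L)/C(0) = 1 at every lag
  line <- data.frame(track = 1, frame = 0:30, t = 0:30, x = 2 * (0:30), y = 0)
  v <- velocityAutocorrelation(line, lags = 0:4)
  expect_equal(v@values, rep(1, 5))
  # Brownian: 0 at positive lags within 3 SEM; exactly 1 at lag 0
  free <- simulateTracks("brownian", nTracks = 120, nPoints = 60, dt = 1,
                         D = 1, seed = 7)
  vf <- velocityAutocorrelation(free, lags = 0:5)
  expect_equal(vf@values[1], 1)
  expect_true(all(abs(vf@values[-1]) <= 3 * vf@se[-1]))
  # OU trap: C(L)/C(0) = -a^(L-1) (1-a)/2 with a = exp(-kappa dt)
  kappa <- 0.8; dt <- 1; a <- exp(-kappa * dt)
  trap <- simulateTracks("confined_ou", nTracks = 400, nPoints = 80, dt = dt,
                         D = 1, stiffness = kappa, seed = 8)
  vt <- velocityAutocorrelation(trap, lags = 0:4, dt = dt)
  want <- -a^(0:3) * (1 - a) / 2
  expect_equal(vt@values[-1], want, tolerance = 0.08)
  expect_lt(vt@values[2], 0)   # the negative elastic peak
})

test_that("density grids conserve counts and smooth separately", {
  g1 <- suppressWarnings(densityGrid(rep(1, 5), rep(2, 5)))
  expect_equal(sum(g1$counts), 5)
  g2 <- densityGrid(c(0, 1), c(0, 1), bins = 25)
  expect_equal(dim(g2$counts), c(25, 25))
  expect_equal(sum(g2$counts), 2)
  set.seed(9)
  x <- runif(1e4); y <- runif(1e4)
  g3 <- densityGrid(x, y, bins = 25)
  expect_equal(sum(g3$counts), 1e4)
  # per-cell counts consistent with the multinomial expectation
  chi <- stats::chisq.test(as.numeric(g3$counts),
                           p = rep(1 / 625, 625))
  expect_gt(chi$p.value, 0.01)
  # smoothing preserves the total up to edge truncation and keeps raw counts
  expect_equal(sum(g3$counts), 1e4)
  expect_false(identical(g3$smooth, g3$counts))
})

test_that("synthetic track generators have the documented moments", {
  expect_true(all(simulateTracks("brownian", 3, 20, D = 0, seed = 1)$x == 0))
  df <- simulateTracks("brownian", nTracks = 100, nPoints = 200, dt = 0.2,
                       D = 1.5, dim = 2, seed = 10)
  steps <- unlist(lapply(split(df, df$track), function(tr) diff(tr$x)))
  expect_equal(var(steps), 2 * 1.5 * 0.2, tolerance = 0.02)
  # OU: long-time MSD plateau at 2 D / kappa per axis
  ou <- simulateTracks("confined_ou", nTracks = 200, nPoints = 120, dt = 1,
                       D = 2, stiffness = 0.5, dim = 1, seed = 11)
  m <- msdCurve(ou, maxLag = 40, minPoints = 10)
  plateau <- mean(m@values[30:40])
  expect_equal(plateau, 2 * 2 / 0.5, tolerance = 0.1)
  expect_error(simulateTracks("levy", 1, 10), "arg")
})

test_that("intensity selection filters tracks like a hand filter", {
  df <- simulateTracks("brownian", nTracks = 6, nPoints = 20, dt = 1, D = 1,
                       seed = 12, intensity = c(100, 400, 900, 901, 1500, 50))
  sel <- selectByIntensity(df, threshold = 900)
  expect_equal(sort(unique(sel$track)), c(1, 2, 3, 6))
  expect_equal(attr(sel, "excluded"), 2)
  expect_warning(selectByIntensity(df, threshold = 10), "below")
  all6 <- selectByIntensity(df, threshold = 1e9)
  expect_equal(nrow(all6), nrow(df))
  expect_error(selectByIntensity(df[, setdiff(names(df), "intensity")],
                                 threshold = 1), "intensity")
})

test_that("the more-than-10-points filter is idempotent", {
  df <- rbind(
    simulateTracks("brownian", nTracks = 2, nPoints = 30, dt = 1, D = 1,
                   seed = 13),
    within(simulateTracks("brownian", nTracks = 2, nPoints = 5, dt = 1,
                          D = 1, seed = 14), track <- track + 10))
  f1 <- filterTracks(df, 10)
  expect_equal(attr(f1, "nFiltered"), 2)
  f2 <- filterTracks(f1, 10)
  expect_equal(nrow(f2), nrow(f1))
  expect_equal(attr(f2, "nFiltered"), 0)
  expect_equal(sort(unique(f1$track)), c(1, 2))
})
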