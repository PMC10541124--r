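# Propagation, potentials, initialization, crowder insertion, compression.

test_that("soft repulsion has the quartic form, cutoff and smooth window", {
  ff <- ForceFieldParams()
  rc <- 20
  expect_equal(softRepulsion(rc, rc, ff)$energy, 0)
  expect_equal(softRepulsion(50, rc, ff)$energy, 0)
  expect_equal(softRepulsion(0, rc, ff, smooth = FALSE)$energy, 500)
  # U(r_cut/sqrt(2)) = (1 - 1/4) eps without smoothing
  expect_equal(softRepulsion(rc / sqrt(2), rc, ff, smooth = FALSE)$energy,
               0.75 * 500)
  # bare quartic by substitution on a grid
  r <- seq(0, 0.94 * rc, length.out = 21)
  expect_equal(softRepulsion(r, rc, ff)$energy, 500 * (1 - (r / rc)^4))
  # continuity at r_on and r_cut: the jump across each matching point
  # (epsilon-bracket) is below 1e-6 eps
  eps <- 1e-9
  for (rs in c(0.95 * rc, rc)) {
    u2 <- softRepulsion(c(rs - eps, rs + eps), rc, ff)$energy
    expect_lt(abs(diff(u2)), 1e-6 * 500)
  }
  # force is -dU/dr (central difference) everywhere including the window
  h <- 1e-6
  for (r0 in c(5, 15, 0.96 * rc, 0.99 * rc)) {
    num <- -(softRepulsion(r0 + h, rc, ff)$energy -
             softRepulsion(r0 - h, rc, ff)$energy) / (2 * h)
    expect_equal(softRepulsion(r0, rc, ff)$force, num, tolerance = 1e-5)
  }
})

test_that("zero temperature and no forces leave the state unchanged", {
  st <- facing_pair_state(gap = 30)
  ip <- IntegratorParams(temperatures = c(default = 0), seed = 1)
  st2 <- langevinStep(st, ip)
  expect_equal(st2@positions, st@positions)
  expect_equal(st2@quaternions, st@quaternions)
})

test_that("free spheres recover the Einstein relation and the drag rule", {
  # two species, diameters d and 2d, under the diameter drag rule: fitted D
  # ratio must be 2 (diffusivity inversely proportional to diameter)
  sp <- list(small = sphereSpec("small", 20), big = sphereSpec("big", 40))
  comp <- SystemComposition(sp, c(small = 30, big = 30), SimulationBox(2000))
  st <- initializeLattice(comp, seed = 3)
  ip <- IntegratorParams(dt = 0.002, referenceDiameter = 20, seed = 3)
  tr <- runSimulation(st, ip, ForceFieldParams(epsSoft = 0), nSteps = 8000,
                      stride = 80, seed = 3)
  fits <- lapply(c("small", "big"), function(s) {
    tracks <- trajectoryTracks(tr, s)
    fitDiffusivity(msdCurve(tracks, 10), dt = 0.16, dim = 3)$D
  })
  expect_equal(fits[[1]], 1.0, tolerance = 0.05)     # D = refD/d = 1
  expect_equal(fits[[1]] / fits[[2]], 2, tolerance = 0.1)
})

test_that("free displacement per axis is Gaussian with variance 2 D dt", {
  sp <- list(gem = sphereSpec("gem", 40))
  comp <- SystemComposition(sp, c(gem = 1000), SimulationBox(4000))
  st <- initializeLattice(comp, seed = 5)
  ip <- IntegratorParams(dt = 0.002, seed = 5)
  tr <- runSimulation(st, ip, ForceFieldParams(epsSoft = 0), nSteps = 4,
                      stride = 1, seed = 5)
  D <- 12.6 / 40
  steps <- do.call(rbind, lapply(2:5, function(f)
    tr@framePositions[[f]] - tr@framePositions[[f - 1]]))
  x <- as.numeric(steps)   # 12000 axis displacements
  expect_gte(length(x), 1e4)
  ks <- stats::ks.test(x, "pnorm", 0, sqrt(2 * D * 0.002))
  expect_gt(ks$p.value, 0.01)
  expect_equal(var(x), 2 * D * 0.002, tolerance = 0.05)
})

test_that("crowders at a different thermostat diffuse with T_c, binders do not", {
  sp <- list(crowder = sphereSpec("crowder", 30, temperatureGroup = "crowder"),
             gem = sphereSpec("gem", 40))
  comp <- SystemComposition(sp, c(crowder = 60, gem = 60), SimulationBox(4000))
  st <- initializeLattice(comp, seed = 7)
  Dg <- c(); Dc <- c()
  for (tc in c(1, 2)) {
    ip <- IntegratorParams(dt = 0.002, seed = 7,
                           temperatures = c(default = 1, crowder = tc))
    tr <- runSimulation(st, ip, ForceFieldParams(epsSoft = 0), nSteps = 6000,
                        stride = 60, seed = 7)
    Dc[length(Dc) + 1] <-
      fitDiffusivity(msdCurve(trajectoryTracks(tr, "crowder"), 10),
                     dt = 0.12, dim = 3)$D
    Dg[length(Dg) + 1] <-
      fitDiffusivity(msdCurve(trajectoryTracks(tr, "gem"), 10),
                     dt = 0.12, dim = 3)$D
  }
  expect_equal(Dc[2] / Dc[1], 2, tolerance = 0.1)   # noise scales with T_c
  expect_equal(Dg[2] / Dg[1], 1, tolerance = 0.1)   # thermal group untouched
})

test_that("lattice initialization is deterministic, overlap-free, capacity-checked", {
  comp <- presetComposition("hoomd_style")   # 1170 + 390 + 20 molecules
  st <- initializeLattice(comp, seed = 1)
  st2 <- initializeLattice(comp, seed = 1)
  expect_identical(st@positions, st2@positions)
  expect_equal(nParticles(st), 1580)
  # brute-force all-pairs check: no two bodies closer than their extents
  ext <- vapply(comp@species, synDropSim:::.speciesExtent, 0)[st@speciesIndex]
  d <- as.matrix(dist(st@positions))
  need <- outer(ext, ext, "+")
  diag(d) <- Inf
  expect_true(all(d > need - 1e-9))
  # two particles sit on lattice sites at least a contact apart
  tiny <- SystemComposition(list(gem = sphereSpec("gem", 40)), c(gem = 2),
                            SimulationBox(200))
  st3 <- initializeLattice(tiny, seed = 1)
  expect_gte(sqrt(sum(diff(st3@positions)^2)), 40)
  # empty composition -> empty state
  st4 <- initializeLattice(SystemComposition(list(gem = sphereSpec("gem", 40)),
                                             c(gem = 0), SimulationBox(200)))
  expect_equal(nParticles(st4), 0)
  # unplaceable composition -> capacity error
  cramped <- SystemComposition(list(gem = sphereSpec("gem", 40)),
                               c(gem = 500), SimulationBox(100))
  expect_error(initializeLattice(cramped), "does not fit")
})

test_that("random sequential insertion realises phi without overlaps", {
  box <- SimulationBox(860)
  expect_equal(crowderCount(0.30, box, 30), 13498)  # phi V / (pi d^3/6)
  comp <- presetComposition("hoomd_style", scale = 1 / 64)
  st <- initializeLattice(comp, seed = 2)
  expect_identical(insertCrowders(st, 0), st)
  st2 <- insertCrowders(st, 0.35, seed = 2)
  expect_equal(measuredVolumeFraction(st2), 0.35, tolerance = 0.005)
  # overlap-free by brute force on the inserted spheres
  idx <- which(particleSpecies(st2) == "crowder")
  p <- st2@positions[idx, ]
  L <- comp@box@edgeLengths[1]
  dmin <- Inf
  for (i in seq_len(nrow(p) - 1)) {
    dd <- sweep(p[(i + 1):nrow(p), , drop = FALSE], 2, p[i, ])
    dd <- dd - round(dd / L) * L
    dmin <- min(dmin, sqrt(min(rowSums(dd^2))))
  }
  expect_gte(dmin, 30 - 1e-9)
  expect_error(insertCrowders(st, 0.4), "compress")
})

test_that("compression interpolates the box linearly to the target", {
  comp <- presetComposition("hoomd_style", scale = 1 / 64)
  big <- comp
  big@box <- SimulationBox(rep(350, 3))
  st <- initializeLattice(big, seed = 3)
  ip <- presetIntegrator("hoomd_style", seed = 3)
  # no-op when initial == target
  same <- CompressionSchedule(350, 350, 10)
  expect_identical(compressToTarget(st, same, ip), st)
  # printed schedule compresses 4.3x in volume
  expect_equal((1400 / 860)^3, 4.3, tolerance = 0.02)
  # midpoint of the linear edge interpolation: after 1 of 2 steps the edge
  # is halfway (1400 -> 1130 for the printed schedule, scaled here)
  half <- synDropSim:::.runKernel(st, ip, presetForceField("hoomd_style"),
                                  NULL, nSteps = 1, stride = 0,
                                  integrate = TRUE, logEvents = FALSE,
                                  boxFinal = rep(215, 3), compressSteps = 2L,
                                  seed = 3)
  expect_equal(half@finalState@composition@box@edgeLengths, rep(282.5, 3))
  expect_equal((1400 + 860) / 2, 1130)
  # full compression reaches the target and keeps everything inside
  sched <- CompressionSchedule(350, 215, 2000)
  st2 <- compressToTarget(st, sched, ip, seed = 3)
  expect_equal(st2@composition@box@edgeLengths, rep(215, 3))
  expect_true(all(abs(st2@positions) <= 215 / 2 + 1e-9))
})

test_that("runs are reproducible and conserve particles", {
  comp <- presetComposition("hoomd_style", scale = 1 / 64)
  st <- initializeLattice(comp, seed = 4)
  ip <- presetIntegrator("hoomd_style", seed = 4)
  ff <- presetForceField("hoomd_style")
  bp <- presetBonding("hoomd_style")
  # zero steps: a single initial frame
  tr0 <- runSimulation(st, ip, ff, bp, nSteps = 0)
  expect_equal(nFrames(tr0), 1)
  expect_equal(tr0@framePositions[[1]], st@positions)
  # same seed twice: identical frame streams
  trA <- runSimulation(st, ip, ff, bp, nSteps = 2000, stride = 500, seed = 9)
  trB <- runSimulation(st, ip, ff, bp, nSteps = 2000, stride = 500, seed = 9)
  expect_identical(trA@framePositions, trB@framePositions)
  expect_identical(trA@frameBonds, trB@frameBonds)
  # particle count constant across frames; wrapped positions stay in box
  for (f in seq_len(nFrames(trA))) {
    expect_equal(nrow(trA@framePositions[[f]]), nParticles(st))
    expect_true(all(abs(trA@framePositions[[f]]) <=
                      comp@box@edgeLengths[1] / 2 + 1e-9))
  }
  expect_true(validObject(trA@finalState))
})
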