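# Frame-to-frame cluster linking and cluster diffusivity.

box200 <- SimulationBox(200)

test_that("cluster COM handles boundary-straddling clusters", {
  pos <- rbind(c(10, 0, 0), c(20, 0, 0), c(-5, 3, 1))
  expect_equal(clusterCOM(pos, 1, box200), c(10, 0, 0))
  # two molecules symmetric about the box centre
  expect_equal(clusterCOM(rbind(c(-30, 0, 0), c(30, 0, 0)), 1:2, box200),
               c(0, 0, 0))
  # a cluster wrapped across the boundary: circular mean equals the oracle
  # computed in an explicitly unwrapped copy
  wrapped <- rbind(c(98, 0, 0), c(-98, 0, 0), c(96, 0, 0))
  unwrapped <- rbind(c(98, 0, 0), c(102, 0, 0), c(96, 0, 0))
  comW <- clusterCOM(wrapped, 1:3, box200)
  comU <- colMeans(unwrapped)
  comU[1] <- comU[1] - 200 * round(comU[1] / 200)
  # the circular mean agrees with the unwrapped mean to O((spread/L)^2)
  expect_equal(comW, comU, tolerance = 1e-4)
  # and lies within the cluster's span after unwrapping
  expect_true(abs(comW[1]) > 95 || abs(comW[1] - 200) < 104)
})

# build a per-frame partition list from a membership list-of-lists
.frames <- function(...) list(...)

test_that("cluster linking follows the largest-shared-members rule", {
  # identical partitions: every track extends, no splits
  p <- list(list(1:30, 31:45), list(1:30, 31:45), list(1:30, 31:45))
  pos <- replicate(3, matrix(0, 45, 3), simplify = FALSE)
  tracks <- linkClusters(p, pos, times = 0:2, box = box200)
  expect_equal(length(tracks), 2)
  expect_equal(vapply(tracks, nrow, 0L), c(3L, 3L))
  # growth by >= 20 in one interval starts a new track (30 -> 55)
  p2 <- list(list(1:30), list(1:55))
  pos2 <- replicate(2, matrix(0, 55, 3), simplify = FALSE)
  tracks2 <- linkClusters(p2, pos2, times = 0:1, box = box200)
  expect_equal(length(tracks2), 2)
  expect_equal(vapply(tracks2, nrow, 0L), c(1L, 1L))
  # growth below the threshold extends (30 -> 45)
  p3 <- list(list(1:30), list(1:45))
  tracks3 <- linkClusters(p3, pos2, times = 0:1, box = box200)
  expect_equal(length(tracks3), 1)
  expect_equal(tracks3[[1]]$size, c(30, 45))
  # boundary case delta = 20 splits by default, extends when exclusive
  p4 <- list(list(1:30), list(1:50))
  expect_equal(length(linkClusters(p4, pos2, 0:1, box200)), 2)
  expect_equal(length(linkClusters(p4, pos2, 0:1, box200,
                                   splitInclusive = FALSE)), 1)
})

test_that("a merge is assigned to the larger-overlap parent, as brute force", {
  # 15 + 18 -> 33: the merged cluster shares 18 with parent B, 15 with A
  pA <- list(list(1:15, 16:33), list(1:33))
  pos <- replicate(2, matrix(rnorm(99), 33, 3), simplify = FALSE)
  tracks <- linkClusters(pA, pos, 0:1, box200, minSize = 10,
                         splitThreshold = 100)   # disable splitting here
  # brute-force overlap matrix says the merged cluster continues 16:33
  overlaps <- c(length(intersect(1:33, 1:15)), length(intersect(1:33, 16:33)))
  expect_equal(which.max(overlaps), 2)
  ext <- vapply(tracks, nrow, 0L)
  expect_equal(sort(ext), c(1L, 2L))
  cont <- tracks[[which(ext == 2)]]
  expect_equal(attr(cont, "members")[[1]], 16:33)
  expect_equal(attr(cont, "members")[[2]], 1:33)
  # linking is invariant to permutation of cluster order within a frame
  pB <- list(list(16:33, 1:15), list(1:33))
  tracksB <- linkClusters(pB, pos, 0:1, box200, minSize = 10,
                          splitThreshold = 100)
  expect_equal(sort(vapply(tracksB, nrow, 0L)), sort(ext))
  contB <- tracksB[[which(vapply(tracksB, nrow, 0L) == 2)]]
  expect_equal(attr(contB, "members")[[1]], 16:33)
})

test_that("only clusters above the minimum size are tracked, disjointly", {
  p <- list(list(1:12, 13:20, 21:24), list(1:12, 13:20, 21:24))
  pos <- replicate(2, matrix(0, 24, 3), simplify = FALSE)
  tracks <- linkClusters(p, pos, 0:1, box200, minSize = 10)
  expect_equal(length(tracks), 1)   # only the 12-mer passes size > 10
  # no molecule in two tracked clusters at the same frame (by construction
  # of partitions, checked through the stored member sets)
  mem <- attr(tracks[[1]], "members")
  expect_equal(lengths(mem), c(12L, 12L))
})

test_that("diffusivity estimation recovers known motion", {
  # stationary track: D = 0
  still <- matrix(5, 40, 3)
  est <- estimateDiffusivity(still, dt = 1)
  expect_equal(est$D, 0)
  # ballistic track: MSD quadratic, flagged by the curvature diagnostic
  tt <- 0:39
  ball <- cbind(2 * tt, 0 * tt, 0 * tt)
  estB <- estimateDiffusivity(ball, dt = 1)
  expect_gt(estB$curvature, 0.3)
  # short tracks are filtered
  expect_false(estimateDiffusivity(still[1:10, ], dt = 1)$ok)
  # 3-d Brownian tracks with known D: median recovered within 5%
  tracks <- simulateTracks("brownian", nTracks = 400, nPoints = 100, dt = 1,
                           D = 2.5, dim = 3, seed = 99)
  Ds <- vapply(split(tracks, tracks$track), function(tr)
    estimateDiffusivity(as.matrix(tr[, c("x", "y", "z")]), dt = 1)$D, 0)
  expect_equal(median(Ds) * 1e6, 2.5, tolerance = 0.05)
})

test_that("the D-versus-size scaling fit recovers known slopes", {
  sizes <- rep(c(12, 15, 20, 30, 50, 80), each = 4)
  expect_equal(sizeScalingFit(sizes, 3 / sizes)$slope, -1, tolerance = 1e-9)
  expect_equal(sizeScalingFit(sizes, rep(2, length(sizes)))$slope, 0,
               tolerance = 1e-9)
  set.seed(7)
  noisy <- 2 * sizes^-0.4 * exp(rnorm(length(sizes), sd = 0.1))
  expect_equal(sizeScalingFit(sizes, noisy)$slope, -0.4, tolerance = 0.05)
  expect_error(sizeScalingFit(c(10, 10, 12), c(1, 1, 1)), "distinct")
})
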