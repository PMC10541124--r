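# Independent oracles used against the implementation paths, plus small
# fixture builders.  Oracles are deliberately naive (brute force /
# enumeration / closed forms) and never call the code paths they check.

# ---- graph oracles ---------------------------------------------------------

# union-find partition of ids given an edge list (two-column matrix of ids)
oracle_union_find <- function(ids, edges) {
  parent <- stats::setNames(ids, as.character(ids))
  find <- function(x) {
    while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]
    x
  }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
    if (ra != rb) parent[[as.character(ra)]] <- rb
  }
  roots <- vapply(ids, find, ids[1])
  unname(lapply(split(ids, roots), sort))
}

# Floyd-Warshall all-pairs shortest paths on an adjacency matrix (0/1)
oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# random simple bipartite-ish edge list over n nodes
random_edges <- function(n, m, seed) {
  set.seed(seed)
  if (m == 0) return(matrix(0L, 0, 2))
  e <- cbind(sample.int(n, m, replace = TRUE), sample.int(n, m, replace = TRUE))
  e <- e[e[, 1] != e[, 2], , drop = FALSE]
  e
}

# ---- kinetics oracles ------------------------------------------------------

# Gillespie simulation of nA + nB <-> AB with per-pair association propensity
# ka (per unbound pair) and dissociation rate koff (per bond)
oracle_gillespie <- function(nTotal, ka, koff, tEnd, seed) {
  set.seed(seed)
  t <- 0; nAB <- 0
  ts <- c(0); ns <- c(0)
  while (t < tEnd) {
    free <- nTotal - nAB
    aOn <- ka * free * free
    aOff <- koff * nAB
    aTot <- aOn + aOff
    if (aTot <= 0) break
    t <- t + stats::rexp(1, aTot)
    if (stats::runif(1) < aOn / aTot) nAB <- nAB + 1 else nAB <- nAB - 1
    ts <- c(ts, t); ns <- c(ns, nAB)
  }
  data.frame(time = ts, bonds = ns)
}

# exact stationary mean of the birth-death chain above (detailed balance:
# pi(k+1)/pi(k) = ka (n-k)^2 / (koff (k+1)))
oracle_stationary_mean <- function(nTotal, ka, koff) {
  logw <- cumsum(c(0, log(ka * (nTotal - 0:(nTotal - 1))^2 /
                            (koff * (1:nTotal)))))
  w <- exp(logw - max(logw))
  sum((0:nTotal) * w) / sum(w)
}

# ---- state fixtures --------------------------------------------------------

# a hexamer (valence vHex) and rod dimer (valence vDim) facing each other so
# that their +x / -x sites sit `gap` apart, pinned in a 200-nm periodic box
facing_pair_state <- function(gap = 1, vHex = 1, vDim = 1, edge = 200) {
  sp <- list(hexamer = hexamerSpec(valence = vHex),
             dimer = dimerRodSpec(valence = vDim),
             crowder = sphereSpec("crowder", 30, temperatureGroup = "crowder"),
             gem = sphereSpec("gem", 40))
  comp <- SystemComposition(sp, c(hexamer = 1, dimer = 1, crowder = 0,
                                  gem = 0), SimulationBox(edge))
  # hexamer site 1 at +7.3 x; rotated dimer's site 1 at centre - 12.725 x
  new("SystemState", composition = comp, speciesIndex = c(1L, 2L),
      positions = rbind(c(0, 0, 0), c(7.3 + gap + 12.725, 0, 0)),
      quaternions = rbind(c(1, 0, 0, 0), c(0, 0, 0, 1)),
      bonds = matrix(0L, 0, 4), time = 0)
}

# n independently pinned facing pairs (no interactions: spread far apart in a
# large box), optionally all bound; used for Markov-chain and decay tests
pinned_pairs_state <- function(n, gap = 1, bound = FALSE, edge = 4000) {
  sp <- list(hexamer = hexamerSpec(valence = 1),
             dimer = dimerRodSpec(valence = 1))
  comp <- SystemComposition(sp, c(hexamer = n, dimer = n),
                            SimulationBox(edge))
  m <- ceiling(n^(1 / 3))
  a <- edge / m
  g <- as.matrix(expand.grid(i = 0:(m - 1), j = 0:(m - 1), k = 0:(m - 1)))
  base <- (g[seq_len(n), , drop = FALSE] + 0.5) * a - edge / 2
  posH <- base
  posD <- sweep(base, 2, c(7.3 + gap + 12.725, 0, 0), "+")
  qs <- rbind(matrix(rep(c(1, 0, 0, 0), n), n, 4, byrow = TRUE),
              matrix(rep(c(0, 0, 0, 1), n), n, 4, byrow = TRUE))
  bonds <- if (bound)
    cbind(seq_len(n), 1L, n + seq_len(n), 1L) else matrix(0L, 0, 4)
  new("SystemState", composition = comp,
      speciesIndex = c(rep(1L, n), rep(2L, n)),
      positions = rbind(posH, posD), quaternions = qs,
      bonds = matrix(as.integer(bonds), nrow(bonds), 4), time = 0)
}

# brute-force candidate enumeration from site positions (minimum image)
oracle_candidates <- function(state, dBind, center = TRUE) {
  sdf <- sitePositions(state)
  L <- state@composition@box@edgeLengths
  A <- sdf[sdf$siteType == "A" & !sdf$bound, ]
  B <- sdf[sdf$siteType == "B" & !sdf$bound, ]
  rad <- 1  # site radius, nm (2-nm patches)
  out <- NULL
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d <- c(A$x[i] - B$x[j], A$y[i] - B$y[j], A$z[i] - B$z[j])
    d <- d - L * round(d / L)
    r <- sqrt(sum(d^2))
    reach <- if (center) dBind else dBind + 2 * rad
    if (r <= reach)
      out <- rbind(out, c(A$molecule[i], A$site[i], B$molecule[j], B$site[j]))
  }
  out
}

# canonical string form of a candidate/bond set for order-free comparison
pair_key <- function(m) {
  if (is.null(m) || nrow(m) == 0) return(character())
  sort(apply(m, 1, paste, collapse = "-"))
}
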