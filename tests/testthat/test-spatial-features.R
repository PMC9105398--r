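cfg <- morphologyConfig()

test_that("connected components match the flood-fill oracle", {
  # diagonal pair: split under 4-connectivity, merged under 8
  g <- matrix(FALSE, 3, 3); g[1, 1] <- TRUE; g[2, 2] <- TRUE
  expect_length(connectedComponents(g, 4)$sizes, 2L)
  expect_length(connectedComponents(g, 8)$sizes, 1L)

  for (seed in 1:40) {
    g <- randomGrid(30, 30, runif(1, 0.2, 0.7), seed)
    for (conn in c(4, 8)) {
      got <- connectedComponents(g, conn)
      ref <- floodFillComponents(g, conn)
      expect_true(samePartition(got$labels, ref$labels))
      expect_equal(sort(got$sizes), sort(ref$sizes))
    }
  }
})

test_that("desert scoring follows the component and area rules", {
  # one 10x10 TIL-free block in a 20x20 all-tumor map: 25% -> desert
  lym <- matrix(TRUE, 20, 20); lym[1:10, 1:10] <- FALSE
  expect_equal(scoreDeserts(allTumorMap(lym), cfg), 1L)

  # fully infiltrated tumor has no TIL-free cells
  expect_equal(scoreDeserts(allTumorMap(matrix(TRUE, 20, 20)), cfg), 0L)

  # scattered singletons below the component minimum never qualify
  lym2 <- matrix(TRUE, 20, 20)
  set.seed(9)
  # pick 30 isolated cells (no two adjacent) on the even sublattice
  cells <- expand.grid(r = seq(1, 19, 2), c = seq(1, 19, 2))
  pick <- cells[sample(nrow(cells), 30), ]
  lym2[cbind(pick$r, pick$c)] <- FALSE
  expect_equal(scoreDeserts(allTumorMap(lym2), cfg), 0L)

  expect_error(scoreDeserts(CompositeMap(matrix(FALSE, 5, 5),
                                         matrix(FALSE, 5, 5)), cfg),
               class = "tilscape_undefined_error")
})

test_that("forest scoring follows the component and area rules", {
  # one connected 40-cell block in 400 tumor cells: 10% -> forest
  lym <- matrix(FALSE, 20, 20); lym[1:4, 1:10] <- TRUE
  expect_equal(scoreForests(allTumorMap(lym), cfg), 1L)

  # no intratumoral TILs -> absent
  expect_equal(scoreForests(allTumorMap(matrix(FALSE, 20, 20)), cfg), 0L)

  # two small confluent groups (2% total) stay below both thresholds
  lym2 <- matrix(FALSE, 20, 20)
  lym2[1:2, 1:2] <- TRUE; lym2[10:11, 10:11] <- TRUE
  expect_equal(scoreForests(allTumorMap(lym2), cfg), 0L)
})

test_that("desert and forest flip exactly at their area thresholds", {
  # grow one contiguous block a cell at a time across an all-tumor grid
  lastDesert <- 0L
  desertFlip <- NA_integer_
  for (k in 1:400) {
    lym <- matrix(TRUE, 20, 20)
    lym[seq_len(k)] <- FALSE          # contiguous in column-major order
    s <- scoreDeserts(allTumorMap(lym), cfg)
    expect_gte(s, lastDesert)         # monotone in block size
    if (s == 1L && is.na(desertFlip)) desertFlip <- k
    lastDesert <- s
  }
  expect_equal(desertFlip / 400, cfg@desertAreaFracThreshold)

  forestFlip <- NA_integer_
  for (k in 1:400) {
    lym <- matrix(FALSE, 20, 20)
    lym[seq_len(k)] <- TRUE
    if (scoreForests(allTumorMap(lym), cfg) == 1L) { forestFlip <- k; break }
  }
  expect_equal(forestFlip / 400, cfg@forestAreaFracThreshold)
})

test_that("deserts and forests agree with a flood-fill + area-sum oracle", {
  oracleBinary <- function(mask, tumorArea, minFrac, thrFrac) {
    cc <- floodFillComponents(mask, 4)
    qual <- sum(cc$sizes[cc$sizes >= minFrac * tumorArea])
    as.integer(qual >= thrFrac * tumorArea)
  }
  nAgree <- 0L
  for (seed in 1:60) {
    tum <- randomGrid(40, 40, 0.7, seed)
    lym <- randomGrid(40, 40, runif(1, 0.1, 0.6), seed + 1000)
    if (!any(tum)) next
    m <- CompositeMap(tum, lym)
    ta <- sum(tum)
    expect_equal(scoreDeserts(m, cfg),
                 oracleBinary(tum & !lym, ta, cfg@desertMinComponentFrac,
                              cfg@desertAreaFracThreshold))
    expect_equal(scoreForests(m, cfg),
                 oracleBinary(tum & lym, ta, cfg@forestMinComponentFrac,
                              cfg@forestAreaFracThreshold))
    nAgree <- nAgree + 1L
  }
  expect_gt(nAgree, 50L)
})

test_that("intratumoral strength grades the infiltration fraction", {
  tum <- matrix(TRUE, 20, 20)
  mkMap <- function(k) {
    lym <- matrix(FALSE, 20, 20); lym[seq_len(k)] <- TRUE
    CompositeMap(tum, lym)
  }
  expect_equal(scoreIntratumoralStrength(mkMap(0), cfg), 0L)
  expect_equal(scoreIntratumoralStrength(mkMap(20), cfg), 1L)   # 5%
  expect_equal(scoreIntratumoralStrength(mkMap(60), cfg), 2L)   # 15%
  expect_equal(scoreIntratumoralStrength(mkMap(80), cfg), 3L)   # 20%

  # strictly increasing infiltration gives non-decreasing grades
  grades <- vapply(seq(0, 400, by = 20), function(k) {
    scoreIntratumoralStrength(mkMap(k), cfg)
  }, integer(1))
  expect_true(all(diff(grades) >= 0))
})

test_that("the peritumoral band is a dilation ring matching the distance
          oracle", {
  tum <- matrix(FALSE, 5, 5); tum[3, 3] <- TRUE
  m <- CompositeMap(tum, matrix(FALSE, 5, 5))
  band1 <- peritumoralBand(m, morphologyConfig(bandWidthCells = 1))
  expect_equal(sum(band1), 8L)                       # 8-cell ring
  expect_false(band1[3, 3])

  # tumor filling the grid leaves no exterior
  full <- CompositeMap(matrix(TRUE, 4, 4), matrix(FALSE, 4, 4))
  expect_equal(sum(peritumoralBand(full, cfg)), 0L)

  for (seed in 1:10) {
    tum <- dilateMask(randomGrid(25, 25, 0.03, seed), 1)   # random blobs
    if (!any(tum)) next
    m <- CompositeMap(tum, matrix(FALSE, 25, 25))
    expect_identical(peritumoralBand(m, cfg),
                     bandByDistance(tum, cfg@bandWidthCells))
  }
})

test_that("peritumoral strength grades the band lymph fraction", {
  tum <- matrix(FALSE, 20, 20); tum[8:13, 8:13] <- TRUE
  band <- peritumoralBand(CompositeMap(tum, matrix(FALSE, 20, 20)), cfg)

  mkMap <- function(frac) {
    cells <- which(band)
    lym <- matrix(FALSE, 20, 20)
    lym[cells[seq_len(round(frac * length(cells)))]] <- TRUE
    CompositeMap(tum, lym)
  }
  expect_equal(scorePeritumoralStrength(mkMap(0), cfg), 0L)
  expect_equal(scorePeritumoralStrength(mkMap(1), cfg), 3L)  # saturated band
  expect_equal(scorePeritumoralStrength(mkMap(0.10), cfg), 2L)

  # empty band is flagged undefined
  full <- CompositeMap(matrix(TRUE, 4, 4), matrix(FALSE, 4, 4))
  expect_error(scorePeritumoralStrength(full, cfg),
               class = "tilscape_undefined_error")
})

test_that("aggregates require multifocal distal clusters", {
  tum <- matrix(FALSE, 30, 30); tum[13:18, 13:18] <- TRUE

  # no lymph outside the band
  expect_equal(scoreAggregates(CompositeMap(tum, matrix(FALSE, 30, 30)),
                               cfg), 0L)

  # two 6-cell distal clusters -> positive
  lym <- matrix(FALSE, 30, 30)
  lym[2:3, 2:4] <- TRUE; lym[27:28, 26:28] <- TRUE
  expect_equal(scoreAggregates(CompositeMap(tum, lym), cfg), 1L)

  # one large distal cluster only: not multifocal
  lym1 <- matrix(FALSE, 30, 30); lym1[2:6, 2:6] <- TRUE
  expect_equal(scoreAggregates(CompositeMap(tum, lym1), cfg), 0L)

  # clusters touching the band do not qualify
  lymB <- matrix(FALSE, 30, 30)
  lymB[10:12, 13:15] <- TRUE; lymB[19:21, 13:15] <- TRUE
  expect_equal(scoreAggregates(CompositeMap(tum, lymB), cfg), 0L)

  # sub-minimum clusters do not qualify
  lymS <- matrix(FALSE, 30, 30)
  lymS[2:3, 2:3] <- TRUE; lymS[27:28, 27:28] <- TRUE   # 4 cells each
  expect_equal(scoreAggregates(CompositeMap(tum, lymS), cfg), 0L)
})

test_that("scoreAll composes the five rules and flags unscorable maps", {
  # tumor filling the lattice: band undefined -> excluded, not an error
  s <- scoreAll(allTumorMap(matrix(FALSE, 20, 20)), cfg)
  expect_true(s@excluded)
  expect_match(s@reason, "band")

  # embedded tumor with no lymph: (0, 1, 0, 0, 0)
  tum <- matrix(FALSE, 30, 30); tum[6:25, 6:25] <- TRUE
  s0 <- scoreAll(CompositeMap(tum, matrix(FALSE, 30, 30)), cfg)
  expect_equal(s0@intratumoralStrength, 0L)
  expect_equal(s0@deserts, 1L)
  expect_equal(s0@forests, 0L)
  expect_equal(s0@peritumoralStrength, 0L)
  expect_equal(s0@aggregates, 0L)

  # dense diffuse TILs + saturated band + two distal clusters:
  # (3, 0, 1, 3, 1)
  lym <- matrix(FALSE, 30, 30)
  lym[6:25, 6:25] <- TRUE                       # full infiltration
  lym[4:5, 4:27] <- TRUE; lym[26:27, 4:27] <- TRUE
  lym[6:27, 4:5] <- TRUE; lym[6:27, 26:27] <- TRUE   # saturated band
  lym[1:2, 1:3] <- TRUE; lym[29:30, 28:30] <- TRUE   # distal clusters
  s1 <- scoreAll(CompositeMap(tum, lym), cfg)
  expect_equal(s1@intratumoralStrength, 3L)
  expect_equal(s1@deserts, 0L)
  expect_equal(s1@forests, 1L)
  expect_equal(s1@peritumoralStrength, 3L)
  expect_equal(s1@aggregates, 1L)

  # no tumor at all -> excluded with reason, not an error
  sx <- scoreAll(CompositeMap(matrix(FALSE, 10, 10), matrix(FALSE, 10, 10)),
                 cfg)
  expect_true(sx@excluded)
  expect_match(sx@reason, "tumor")
  expect_true(is.na(sx@deserts))
})

test_that("high-risk profiles enumerate the indicator table", {
  prof <- function(st, de, fo, pe, ag = 1L, ...) {
    highRiskProfile(FeatureScores(st, de, fo, pe, ag), ...)
  }
  # no indicator fires
  p0 <- prof(3, 0, 1, 3)
  expect_equal(p0@count, 0L)
  expect_equal(p0@group, "low-risk")
  # every default indicator fires
  p4 <- prof(1, 1, 0, 1)
  expect_equal(p4@count, 4L)
  expect_equal(p4@group, "high-risk")
  # a single indicator stays low-risk
  p1 <- prof(0, 0, 1, 2)
  expect_equal(p1@count, 1L)
  expect_equal(p1@group, "low-risk")
  expect_equal(p1@indicators, "low_intratumoral")
  # aggregates only counted when activated
  pa <- prof(3, 0, 1, 3, ag = 0L)
  expect_equal(pa@count, 0L)
  pb <- prof(3, 0, 1, 3, ag = 0L, active = highRiskFeatureNames())
  expect_equal(pb@count, 1L)
  expect_equal(pb@indicators, "aggregates_absent")

  # exhaustive: count equals the sum of fired indicators; threshold at 2
  for (st in 0:3) for (de in 0:1) for (fo in 0:1) for (pe in 0:3) {
    p <- prof(st, de, fo, pe)
    want <- (st <= 1) + (de == 1) + (fo == 0) + (pe <= 1)
    expect_equal(p@count, as.integer(want))
    expect_equal(p@group == "high-risk", want >= 2)
  }

  # excluded scores are refused
  expect_error(highRiskProfile(FeatureScores(excluded = TRUE, reason = "x")),
               class = "tilscape_undefined_error")
})

test_that("adding a firing indicator never lowers the risk group", {
  # monotone: flip any non-firing feature to its firing value
  base <- list(st = 2L, de = 0L, fo = 1L, pe = 2L)
  mk <- function(b) highRiskProfile(FeatureScores(b$st, b$de, b$fo, b$pe, 1L))
  for (flip in names(base)) {
    worse <- base
    worse[[flip]] <- switch(flip, st = 1L, de = 1L, fo = 0L, pe = 1L)
    expect_gte(mk(worse)@count, mk(base)@count)
    if (mk(base)@group == "high-risk") {
      expect_equal(mk(worse)@group, "high-risk")
    }
  }
})
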