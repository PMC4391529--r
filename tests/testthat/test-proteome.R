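gelTable <- function(volumes, gel = "g1", condition = "control", rep = 1) {
  data.frame(gel_id = gel, condition = condition, replicate = rep,
             spot_id = sprintf("s%02d", seq_along(volumes)),
             raw_volume = volumes)
}

test_that("normalization expresses spots as percent of total gel quantity", {
  one <- normalizeSpots(gelTable(42))
  expect_equal(one$normalized_volume, 100)
  three <- normalizeSpots(gelTable(c(1, 1, 2)))
  expect_equal(three$normalized_volume, c(25, 25, 50))
  expect_error(normalizeSpots(gelTable(c(0, 0))), "zero total")
})

test_that("per-gel normalized volumes always sum to 100", {
  st <- simulateSpotTable(SimulationConfig(seed = 3, nSpots = 100L,
                                           nPlantedSpots = 10L))
  norm <- normalizeSpots(st$spots)
  sums <- tapply(norm$normalized_volume, norm$gel_id, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("low-abundance elimination requires the cut-off to fail on every image", {
  tab <- rbind(gelTable(c(0.01, 0.01, 99.98) * 10, gel = "g1"),
               gelTable(c(0.01, 0.05, 99.94) * 10, gel = "g2"))
  norm <- normalizeSpots(tab)
  gone <- lowAbundanceFilter(norm, minVolume = 0.02)
  expect_equal(gone, "s01")          # faint on all gels
  expect_false("s02" %in% gone)      # rescued by one gel at 0.05%
})

test_that("planted faint spots are eliminated exactly", {
  set.seed(5)
  k <- 4
  vols <- c(runif(k, 1e-5, 1e-4), runif(46, 10, 100))
  tab <- rbind(gelTable(vols, gel = "g1"), gelTable(vols, gel = "g2"))
  gone <- lowAbundanceFilter(normalizeSpots(tab))
  expect_setequal(gone, sprintf("s%02d", 1:k))
})

test_that("standardization centers to mean 0 and scales to unit sd", {
  expect_equal(standardizeValues(c(1, 2, 3))$values, c(-1, 0, 1))
  expect_true(standardizeValues(c(5, 5, 5))$degenerate)
  set.seed(8)
  z <- standardizeValues(rnorm(20, 50, 9))$values
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
})

test_that("ANOVA degenerate and textbook cases behave", {
  # equal group means with within-group spread: F = 0, p = 1
  av <- anovaPerSpot(c(1, 3, 1, 3, 1, 3),
                     rep(c("control", "NaCl", "sucrose"), each = 2))
  expect_equal(av$F, 0)
  expect_equal(av$p, 1)
  # insufficient replication is skipped with a reason
  sk <- anovaPerSpot(c(1, 2, 3), c("a", "b", "c"))
  expect_true(sk$skipped)
  sk2 <- anovaPerSpot(c(1, 2), c("a", "a"))
  expect_true(sk2$skipped)
})

test_that("two-group F equals the square of the pooled t statistic", {
  set.seed(9)
  for (k in 1:20) {
    x <- rnorm(4); y <- rnorm(5, 1)
    av <- anovaPerSpot(c(x, y), rep(c("a", "b"), c(4, 5)))
    t <- tOracle(x, y)$t
    expect_equal(av$F, t^2, tolerance = 1e-9)
  }
})

test_that("F is invariant under uniform standardization of a spot", {
  set.seed(10)
  vals <- rnorm(9, 10, 2)
  cond <- rep(c("control", "NaCl", "sucrose"), each = 3)
  raw <- anovaPerSpot(vals, cond)
  std <- anovaPerSpot(standardizeValues(vals)$values, cond)
  expect_equal(raw$F, std$F, tolerance = 1e-9)
  expect_equal(raw$p, std$p, tolerance = 1e-9)
})

test_that("null simulation rejects at about the nominal alpha of 0.1", {
  set.seed(11)
  n <- 600
  rej <- vapply(seq_len(n), function(i) {
    anovaPerSpot(rnorm(9), rep(c("control", "NaCl", "sucrose"), each = 3),
                 alpha = 0.1)$significant
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.10), 0.04)  # ~3 binomial sd
})

test_that("fold-change calls use strict two-fold bounds", {
  expect_true(foldChangeCall(3, 1)$substantial)
  expect_false(foldChangeCall(1.9, 1)$substantial)
  expect_false(foldChangeCall(2, 1)$substantial)   # strictly exceeding
  expect_true(foldChangeCall(0.4, 1)$substantial)
  expect_true(is.na(foldChangeCall(1, 0)$ratio))
})

test_that("planted three-fold spots are exactly the substantial ones at zero noise", {
  cfg <- SimulationConfig(seed = 13, nSpots = 80L, nPlantedSpots = 6L,
                          spotCv = 0, plantedSpotFold = 3)
  st <- simulateSpotTable(cfg)
  res <- spotStats(st$spots)
  planted <- st$truth$spot_id[st$truth$planted]
  flagged <- res$stats$spot_id[res$stats$substantial_NaCl]
  expect_setequal(flagged, planted)
})

test_that("planted folds at low noise are flagged with high power", {
  cfg <- SimulationConfig(seed = 17, nSpots = 200L, nPlantedSpots = 20L,
                          spotCv = 0.1, plantedSpotFold = 3)
  st <- simulateSpotTable(cfg)
  res <- spotStats(st$spots)
  planted <- st$truth$spot_id[st$truth$planted]
  hit <- res$stats$substantial_NaCl[match(planted, res$stats$spot_id)]
  expect_gt(mean(hit), 0.99)
})

test_that("RSD formula and summary", {
  # gels built with equal totals so normalization preserves raw proportions
  tab <- rbind(gelTable(c(10, 8, 30, 2), gel = "g1", rep = 1),
               gelTable(c(10, 12, 26, 2), gel = "g2", rep = 2))
  qc <- rsdQC(normalizeSpots(tab))
  rsd <- setNames(qc$rsd$rsd, qc$rsd$spot_id)
  expect_equal(rsd[["s01"]], 0)
  expect_equal(rsd[["s02"]], 100 * sd(c(8, 12)) / 10)
  expect_equal(rsd[["s04"]], 0)
})

test_that("the identification rule truth table holds at its boundaries", {
  expect_equal(identificationFilter(c(55, 62), 35), "accepted")
  expect_equal(identificationFilter(c(50, 50), 30), "accepted")  # inclusive
  expect_equal(identificationFilter(c(55, 62), 20), "needs_msms")
  expect_equal(identificationFilter(c(50, 50), 29.9), "needs_msms")
  expect_equal(identificationFilter(c(80), 90), "rejected")      # one score
  expect_equal(identificationFilter(c(49, 49, 49), 90), "rejected")
  expect_error(identificationFilter(numeric(), 50), "at least one")
  expect_error(identificationFilter(60, 101), "coverage")
})

test_that("the spot pipeline assembles per-spot statistics coherently", {
  cfg <- SimulationConfig(seed = 19, nSpots = 60L, nPlantedSpots = 5L,
                          spotCv = 0.15, plantedSpotFold = 3)
  st <- simulateSpotTable(cfg)
  res <- spotStats(st$spots)
  expect_equal(nrow(res$stats), 60L - length(res$eliminated))
  expect_true(all(res$stats$p >= 0 & res$stats$p <= 1, na.rm = TRUE))
  expect_true(all(c("mean_control", "mean_NaCl", "mean_sucrose", "F", "p",
                    "ratio_NaCl", "substantial_sucrose", "rsd_control")
                  %in% names(res$stats)))
  expect_true(res$qc$fractionBelowCutoff > 0.9)  # cv 0.15 well under RSD 35
})
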