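makeProbes <- function(geneMeans, offsets = c(10, 150), contrast = "c1") {
  # one gene per element; every probe carries the gene's replicate means
  do.call(rbind, lapply(names(geneMeans), function(g) {
    m <- geneMeans[[g]]
    data.frame(probe_id = paste0(g, "_p", seq_along(offsets)),
               gene_id = g, offset = offsets, contrast = contrast,
               rep1 = m[1], rep2 = m[2], rep3 = m[3])
  }))
}

test_that("the positional filter keeps exactly the downstream probes", {
  probes <- data.frame(offset = c(-120, -5, 10, 150), probe_id = 1:4)
  kept <- filterProbes(probes)
  expect_equal(kept$offset, c(10, 150))
  expect_equal(kept$probe_id, 3:4)  # order preserved
  expect_equal(nrow(filterProbes(data.frame(offset = c(-10, -1)))), 0L)
})

test_that("gene ratios are arithmetic probe means per replicate", {
  expect_equal(unname(geneRatio(data.frame(rep1 = c(1, 1, 1)))), 1)
  expect_equal(unname(geneRatio(data.frame(rep1 = c(2, 0)))), 1)
  expect_null(geneRatio(data.frame(rep1 = numeric())))
})

test_that("the all-replicates rule decides up, down, unchanged", {
  calls <- callDE(makeProbes(list(
    gUp = c(1.4, 1.2, 1.1),
    gFail = c(1.4, 1.2, 0.9),
    gDown = c(-1.3, -1.6, -1.1),
    gFlat = c(0.2, -0.1, 0.4))))
  status <- setNames(calls$status, calls$gene_id)
  expect_equal(status[["gUp"]], "up")
  expect_equal(status[["gFail"]], "unchanged")  # one replicate misses
  expect_equal(status[["gDown"]], "down")
  expect_equal(status[["gFlat"]], "unchanged")
  # strict inequality at the threshold
  border <- callDE(makeProbes(list(gEdge = c(1.0, 1.2, 1.3))))
  expect_equal(border$status, "unchanged")
})

test_that("genes with only upstream probes are not evaluated", {
  probes <- makeProbes(list(g1 = c(2, 2, 2)), offsets = c(-200, -50))
  calls <- callDE(probes)
  expect_equal(calls$status, "not_evaluated")
  expect_equal(calls$n_probes, 0L)
  mixed <- rbind(probes, makeProbes(list(g2 = c(2, 2, 2))))
  callsMixed <- callDE(mixed)
  expect_equal(setNames(callsMixed$status, callsMixed$gene_id)[["g2"]], "up")
})

test_that("caller output equals the row-by-row oracle on noisy simulated data", {
  cfg <- SimulationConfig(seed = 29, nGenes = 100L, probeNoiseSd = 0.2)
  pt <- simulateProbeTable(cfg)
  calls <- callDE(pt$probes)
  oracle <- deOracle(pt$probes)
  merged <- merge(calls[, c("gene_id", "contrast", "status")], oracle,
                  by = c("gene_id", "contrast"))
  expect_equal(nrow(merged), nrow(calls))
  expect_equal(merged$status.x, merged$status.y)
})

test_that("noiseless planted truth is recovered with perfect recall and precision", {
  cfg <- SimulationConfig(seed = 31, nGenes = 120L, probeNoiseSd = 0)
  pt <- simulateProbeTable(cfg)
  calls <- callDE(pt$probes)
  m <- merge(calls, pt$truth, by = c("gene_id", "contrast"))
  called <- m$status %in% c("up", "down")
  planted <- m$direction != "none"
  expect_true(all(m$status[planted] == m$direction[planted]))  # recall 1
  expect_true(all(planted[called]))                            # precision 1
})

test_that("negating every ratio swaps up and down calls exactly", {
  cfg <- SimulationConfig(seed = 37, nGenes = 60L, probeNoiseSd = 0.4)
  pt <- simulateProbeTable(cfg)
  neg <- pt$probes
  for (rc in grep("^rep", names(neg), value = TRUE)) neg[[rc]] <- -neg[[rc]]
  a <- callDE(pt$probes)
  b <- callDE(neg)
  swap <- c(up = "down", down = "up", unchanged = "unchanged",
            not_evaluated = "not_evaluated")
  expect_equal(unname(swap[a$status]), b$status)
})

test_that("raising the threshold never increases the number of DE calls", {
  cfg <- SimulationConfig(seed = 41, nGenes = 80L, probeNoiseSd = 0.6)
  pt <- simulateProbeTable(cfg)
  nDE <- vapply(c(0.5, 1, 1.5, 2, 3), function(th)
    sum(callDE(pt$probes, DEConfig(threshold = th))$status
        %in% c("up", "down")), numeric(1))
  expect_true(all(diff(nDE) <= 0))
})

test_that("sucrose/NaCl response groups follow the legend rules", {
  mk <- function(nacl, suc, direct) {
    data.frame(gene_id = "g",
               contrast = c("NaCl_vs_control", "sucrose_vs_control",
                            "sucrose_vs_NaCl"),
               status = c(nacl, suc, direct))
  }
  grp <- function(...) assignGroups(mk(...))$group
  expect_equal(grp("unchanged", "up", "unchanged"), "G1")   # up only sucrose
  expect_equal(grp("unchanged", "unchanged", "up"), "G1")   # higher in sucrose
  expect_equal(grp("unchanged", "down", "unchanged"), "G2")
  expect_equal(grp("unchanged", "unchanged", "down"), "G3") # higher in NaCl
  expect_equal(grp("up", "unchanged", "unchanged"), "G3")   # up only NaCl
  expect_equal(grp("down", "unchanged", "unchanged"), "G4")
  expect_equal(grp("unchanged", "unchanged", "unchanged"), "none")
  expect_equal(grp("up", "up", "unchanged"), "none")        # shared response
  # direct contrast takes precedence over single-condition routes
  expect_equal(grp("up", "unchanged", "up"), "G1")
})

test_that("every gene lands in at most one group on simulated data", {
  cfg <- SimulationConfig(seed = 43, nGenes = 150L, probeNoiseSd = 0.3)
  calls <- callDE(simulateProbeTable(cfg)$probes)
  groups <- assignGroups(calls)
  expect_equal(nrow(groups), 150L)
  expect_equal(anyDuplicated(groups$gene_id), 0L)
  expect_true(all(groups$group %in% c("G1", "G2", "G3", "G4", "none")))
})

test_that("category summary counts match an independent tabulation", {
  cfg <- SimulationConfig(seed = 47, nGenes = 100L, probeNoiseSd = 0.2)
  pt <- simulateProbeTable(cfg)
  ann <- simulateAnnotation(cfg)
  calls <- callDE(pt$probes)
  summary <- categorySummary(calls, ann)
  de <- calls[calls$status %in% c("up", "down"), ]
  de$role <- ann$main_role[match(de$gene_id, ann$gene_id)]
  for (k in seq_len(nrow(summary))) {
    sub <- de[de$contrast == summary$contrast[k] &
                de$role == summary$main_role[k], ]
    expect_equal(summary$up[k], sum(sub$status == "up"))
    expect_equal(summary$down[k], sum(sub$status == "down"))
  }
  expect_equal(sum(summary$up + summary$down), nrow(de))
  # single annotated up gene and the empty set
  oneUp <- callDE(makeProbes(list(gA = c(1.5, 1.6, 1.7))))
  s1 <- categorySummary(oneUp, data.frame(gene_id = "gA",
                                          main_role = "Transport"))
  expect_equal(s1$up, 1L)
  expect_equal(s1$main_role, "Transport")
  s0 <- categorySummary(oneUp[oneUp$status == "down", ],
                        data.frame(gene_id = "gA", main_role = "Transport"))
  expect_equal(nrow(s0), 0L)
})

test_that("unannotated called genes are counted under the unknown role", {
  calls <- callDE(makeProbes(list(gX = c(2, 2, 2))))
  s <- categorySummary(calls, data.frame(gene_id = "other",
                                         main_role = "Transport"))
  expect_equal(s$main_role, "unknown")
  expect_equal(s$up, 1L)
})
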