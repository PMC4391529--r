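test_that("an exact copy in the proteome is the best hit", {
  set.seed(10)
  q <- randomProtein(150)
  prot <- Biostrings::AAStringSet(c(other = randomProtein(150), self = q,
                                    more = randomProtein(120)))
  hit <- bestHit(q, prot)
  expect_equal(hit@subjectId, "self")
  expect_equal(identityFraction(hit), 1.0)
})

test_that("no subject passing the score threshold means no hit", {
  set.seed(11)
  q <- randomProtein(20)  # too short to reach score 100 against noise
  prot <- Biostrings::AAStringSet(c(a = randomProtein(20),
                                    b = randomProtein(25)))
  expect_null(bestHit(q, prot, ScreenConfig()))
})

test_that("the overlap threshold rejects short local matches", {
  set.seed(12)
  core <- randomProtein(120)
  # subject carries the query core but is four times longer
  subject <- paste0(randomProtein(200), core, randomProtein(200))
  prot <- Biostrings::AAStringSet(c(s = subject))
  expect_null(bestHit(core, prot, ScreenConfig(minOverlap = 0.75)))
  hit <- bestHit(core, prot, ScreenConfig(minOverlap = 0.2))
  expect_equal(hit@subjectId, "s")
})

test_that("a planted ortholog at 60% identity wins over random decoys", {
  cfg <- SimulationConfig(seed = 17, orthologIdentityLevels = 0.6,
                          orthologLengthRange = c(300L, 300L),
                          decoyCount = 10L)
  gp <- simulateGenomePair(cfg)
  hit <- bestHit(as.character(gp$source[["SRC_001"]]), gp$target)
  expect_equal(hit@subjectId, "TGT_001")
})

test_that("identical proteomes give reciprocal presence at identity 1", {
  set.seed(13)
  prot <- Biostrings::AAStringSet(setNames(
    vapply(1:4, function(i) randomProtein(200), character(1)),
    paste0("g", 1:4)))
  seeds <- data.frame(seed_id = names(prot), organism = "A")
  pm <- buildPresenceMatrix(seeds, list(A = prot))
  calls <- presenceCalls(pm)
  expect_true(all(calls$status == "present"))
  expect_true(all(calls$identity == 1))
})

test_that("a duplicated paralog capturing the back-search yields absent", {
  set.seed(14)
  a <- strsplit(randomProtein(200), "")[[1]]
  paralog <- a
  idx <- sample(200, 12)
  for (p in idx) paralog[p] <- sample(setdiff(AA20, paralog[p]), 1)
  b <- paralog  # target gene: exact copy of the paralog
  src <- Biostrings::AAStringSet(c(seedA = paste(a, collapse = ""),
                                   paralogA = paste(paralog, collapse = "")))
  tgt <- Biostrings::AAStringSet(c(geneB = paste(b, collapse = "")))
  callSeed <- reciprocalBestHit("seedA", src, tgt)
  expect_equal(callSeed$status, "absent")
  expect_equal(callSeed$hit_id, "geneB")  # forward hit existed
  # the paralog itself is reciprocally present
  callPar <- reciprocalBestHit("paralogA", src, tgt)
  expect_equal(callPar$status, "present")
  expect_equal(callPar$identity, 1.0)
})

test_that("raising the score threshold never converts absent to present", {
  cfg <- SimulationConfig(seed = 19,
                          orthologIdentityLevels = c(0.45, 0.6, 0.8, 1.0),
                          orthologLengthRange = c(200L, 250L),
                          decoyCount = 4L)
  gp <- simulateGenomePair(cfg)
  seeds <- data.frame(seed_id = gp$truth$seed_id, organism = "SRC")
  prot <- list(SRC = gp$source, TGT = gp$target)
  present <- lapply(c(60, 100, 300, 800), function(ms) {
    pm <- buildPresenceMatrix(seeds, prot, ScreenConfig(minScore = ms),
                              organisms = "TGT")
    presenceCalls(pm)$status == "present"
  })
  for (k in seq_len(length(present) - 1))
    expect_true(all(present[[k]] >= present[[k + 1]]))
})

test_that("the presence matrix recovers the planted truth on a genome pair", {
  cfg <- SimulationConfig(seed = 23,
                          orthologIdentityLevels = seq(0.4, 1.0, length.out = 8),
                          orthologLengthRange = c(200L, 300L),
                          decoyCount = 5L)
  gp <- simulateGenomePair(cfg)
  seeds <- data.frame(seed_id = gp$truth$seed_id, organism = "SRC")
  pm <- buildPresenceMatrix(seeds, list(SRC = gp$source, TGT = gp$target),
                            organisms = "TGT")
  calls <- presenceCalls(pm)
  expect_true(all(calls$status == "present"))
  expect_equal(calls$hit_id, gp$truth$target_id)
  # measured identity close to the planted one (alignment may trim ends)
  expect_true(all(abs(calls$identity - gp$truth$realized_identity) < 0.05))
})

test_that("the shipped osmolyte seed panel yields one matrix row per seed gene", {
  panel <- osmolyteSeedPanel()
  expect_equal(nrow(panel), 28L)
  expect_true(all(c("kup", "trkA", "kdpF", "glnA", "betS", "proZ", "ostB")
                  %in% panel$seed_id))
  set.seed(15)
  eco <- Biostrings::AAStringSet(setNames(
    vapply(seq_len(nrow(panel)), function(i) randomProtein(180),
           character(1)), panel$seed_id))
  pm <- buildPresenceMatrix(panel, list(Eco = eco))
  expect_equal(length(pm@seeds), nrow(panel))
  expect_equal(dim(pm@status), c(nrow(panel), 1L))
  expect_true(all(pm@status == "present"))  # screened against itself
})

test_that("input validation of the screen surface", {
  prot <- Biostrings::AAStringSet(c(g = "MKTAYIAKQR"))
  expect_error(reciprocalBestHit("missing", prot, prot),
               "not part of the source")
  expect_error(buildPresenceMatrix(
    data.frame(seed_id = "g", organism = "A"),
    list(A = prot, B = Biostrings::AAStringSet())), "empty proteome")
  expect_error(buildPresenceMatrix(
    data.frame(seed_id = character(), organism = character()),
    list(A = prot)), "non-empty")
})

test_that("presence matrix writes a TSV with identity cells and an SVG heatmap", {
  set.seed(16)
  prot <- Biostrings::AAStringSet(setNames(
    c(randomProtein(150), randomProtein(150)), c("g1", "g2")))
  pm <- buildPresenceMatrix(data.frame(seed_id = c("g1", "g2"),
                                       organism = "A"), list(A = prot))
  tsv <- tempfile(fileext = ".tsv")
  writePresenceMatrix(pm, tsv)
  back <- readTsv(tsv)
  expect_equal(back$seed_id, c("g1", "g2"))
  expect_equal(back$A, c(1, 1))
  svg <- tempfile(fileext = ".svg")
  renderPresenceHeatmap(pm, svg)
  txt <- readLines(svg)
  expect_equal(sum(grepl("class=\"cell\"", txt)), 2L)
})
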