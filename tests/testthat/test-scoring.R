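# CaseOLAP component scores and the composite score table.

mentionsFixture <- function() {
  m <- data.frame(
    pmid = c("d1", "d2", "d2", "d3", "d4"),
    uniprot_id = c("P1", "P1", "P2", "P2", "P1"),
    tf = c(2L, 3L, 1L, 4L, 5L),
    stringsAsFactors = FALSE)
  attr(m, "pmids") <- c("d1", "d2", "d3", "d4", "d5")
  m
}

test_that("cell statistics sum per-document counts, multi-label included", {
  cells <- list(c1 = c("d1", "d2"), c2 = c("d2", "d3"), empty = "d5")
  st <- aggregateCellStats(mentionsFixture(), cells)
  expect_equal(st$tf["P1", "c1"], 5)           # 2 + 3
  expect_equal(st$tf["P1", "c2"], 3)           # d2 counts in both cells
  expect_equal(st$tf["P2", "c2"], 5)
  expect_equal(unname(st$cntP), unname(colSums(st$tf)))
  expect_equal(unname(st$cntP["empty"]), 0)
  expect_true(all(st$tf <= matrix(st$cntP, nrow(st$tf), 3, byrow = TRUE)))
})

test_that("cells referencing unknown pmids are rejected", {
  expect_error(
    aggregateCellStats(mentionsFixture(), list(c1 = c("d1", "zzz"))),
    "zzz")
})

test_that("popularity is log-damped prevalence with fixed conventions", {
  expect_equal(popularityScore(9, 99), 0.5)    # log 10 / log 100
  expect_equal(popularityScore(0, 50), 0)
  expect_equal(popularityScore(50, 50), 1)
  expect_equal(popularityScore(3, 0), 0)
})

test_that("relevance is the traffic share, normalizing within a cell", {
  expect_equal(relevanceScore(5, 50), 0.1)
  expect_equal(relevanceScore(0, 50), 0)
  expect_equal(relevanceScore(2, 0), 0)
  tf <- c(3, 7, 10)
  expect_equal(sum(relevanceScore(tf, sum(tf))), 1)
})

test_that("distinctiveness ratios relevances over the comparison set", {
  expect_equal(distinctivenessScore(c(0.1, 0.01))[1], 0.1 / 0.11)
  expect_equal(distinctivenessScore(c(0, 0.3, 0))[2], 1)
  expect_equal(distinctivenessScore(rep(0.05, 6)), rep(1 / 6, 6))
  expect_true(all(is.na(distinctivenessScore(c(0, 0)))))
})

test_that("composite scores multiply the three components", {
  # one protein monopolising c1 at tf 9 of cntP 99, absent elsewhere,
  # second protein supplying the rest of the traffic in both cells
  m <- data.frame(
    pmid = c("a", "a", "b"),
    uniprot_id = c("P1", "P2", "P2"),
    tf = c(9L, 90L, 90L), stringsAsFactors = FALSE)
  attr(m, "pmids") <- c("a", "b")
  st <- scoreCorpus(m, list(c1 = "a", c2 = "b"))
  s <- as.data.frame(st)
  p1 <- s[s$uniprot_id == "P1" & s$cell == "c1", ]
  expect_equal(p1$integrity, 1.0)
  expect_equal(p1$popularity, 0.5)             # log(10)/log(100)
  rel1 <- 9 / 99
  expect_equal(p1$distinctiveness, 1.0)        # only mentioned in c1
  expect_equal(p1$score, p1$integrity * p1$popularity * p1$distinctiveness)
  # P2 split across both cells: rel 90/99 vs 90/90
  p2 <- s[s$uniprot_id == "P2", ]
  expect_equal(sum(p2$distinctiveness), 1)
  expect_false("P1" %in% s$uniprot_id[s$cell == "c2"])  # tf = 0: no record
})

test_that("worked component product matches the spec arithmetic", {
  expect_equal(1.0 * 0.5 * (0.1 / 0.11), 0.45454545454545453)
})

test_that("score table matches the naive oracle on a small corpus", {
  set.seed(31)
  m <- data.frame(
    pmid = rep(sprintf("d%02d", 1:10), each = 2),
    uniprot_id = sample(c("P1", "P2", "P3"), 20, replace = TRUE),
    tf = sample(1:5, 20, replace = TRUE), stringsAsFactors = FALSE)
  m <- aggregate(tf ~ pmid + uniprot_id, m, sum)
  attr(m, "pmids") <- sprintf("d%02d", 1:10)
  cells <- list(c1 = sprintf("d%02d", 1:6), c2 = sprintf("d%02d", 5:10))
  got <- as.data.frame(scoreCorpus(m, cells))
  got <- got[order(got$uniprot_id, got$cell), ]
  rownames(got) <- NULL
  want <- oracleScoreTable(m, cells)
  expect_equal(got, want, tolerance = 1e-14)
})

test_that("all components are bounded and distinctiveness normalizes", {
  set.seed(12)
  spec <- syntheticCorpusSpec(nCells = 3, docsPerCell = 20,
                              nBackgroundProteins = 25, plantedPerCell = 3,
                              mentionsPerDocMean = 5, seed = 12)
  sim <- simulateCorpus(spec)
  cube <- assignDomains(sim$documents, sim$meshTree, sim$domains)
  st <- scoreCorpus(countCorpusMentions(sim$documents, sim$lexicon), cube)
  s <- as.data.frame(st)
  expect_true(all(s$integrity >= 0 & s$integrity <= 1))
  expect_true(all(s$popularity >= 0 & s$popularity <= 1))
  expect_true(all(s$distinctiveness >= 0 & s$distinctiveness <= 1))
  expect_true(all(s$score >= 0 & s$score <= 1))
  sums <- tapply(s$distinctiveness, s$uniprot_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_equal(s$score, s$integrity * s$popularity * s$distinctiveness)
})

test_that("raising tf never lowers popularity or distinctiveness", {
  baseTf <- 4; cntP <- 60
  popBase <- popularityScore(baseTf, cntP)
  relOthers <- c(0.02, 0.05)
  for (extra in 1:10) {
    tf2 <- baseTf + extra
    # the cell's total traffic grows with the protein's own mentions
    expect_gte(popularityScore(tf2, cntP + extra), popBase)
    dBase <- distinctivenessScore(c(baseTf / cntP, relOthers))[1]
    d2 <- distinctivenessScore(c(tf2 / (cntP + extra), relOthers))[1]
    expect_gte(d2, dBase)
  }
})

test_that("a protein mentioned only in one cell is fully distinct there", {
  m <- data.frame(pmid = c("a", "b", "b"),
                  uniprot_id = c("X", "Y", "Z"),
                  tf = c(1L, 7L, 2L), stringsAsFactors = FALSE)
  attr(m, "pmids") <- c("a", "b")
  st <- scoreCorpus(m, list(c1 = "a", c2 = "b"))
  s <- as.data.frame(st)
  expect_equal(s$distinctiveness[s$uniprot_id == "X"], 1)
  # single supporting mention still yields a scored record
  expect_true("X" %in% s$uniprot_id)
})

test_that("per-protein integrity values and strategies can be injected", {
  m <- data.frame(pmid = c("a", "b"), uniprot_id = c("P1", "P2"),
                  tf = c(3L, 5L), stringsAsFactors = FALSE)
  attr(m, "pmids") <- c("a", "b")
  cells <- list(c1 = "a", c2 = "b")
  st <- scoreCorpus(m, cells, integrity = c(P1 = 0.5, P2 = 0.25))
  s <- as.data.frame(st)
  expect_equal(s$integrity[s$uniprot_id == "P1"], 0.5)
  expect_equal(s$score[s$uniprot_id == "P2"],
               0.25 * s$popularity[s$uniprot_id == "P2"] *
                 s$distinctiveness[s$uniprot_id == "P2"])
  # a swapped-in linear popularity strategy feeds straight through
  stLin <- scoreCorpus(m, cells,
                       popularityFun = function(tf, cntP)
                         ifelse(cntP <= 0, 0, tf / cntP))
  expect_equal(as.data.frame(stLin)$popularity, c(1, 1))
})
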