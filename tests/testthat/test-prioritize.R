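# Score-distribution cutoffs, attribution classes, rankings, overlaps.

test_that("histogram bins are fixed-width, half-open, conserving counts", {
  st <- scoresInCell(c(0.1, 0.1, 0.3))
  h <- scoreHistogram(st, "c1", binWidth = 0.1)
  expect_equal(h$bin_edges, c(0, 0.1, 0.2, 0.3))
  expect_equal(h$counts, c(0, 2, 1))           # 0.3 falls in the closed last bin
  expect_equal(sum(h$counts), 3)

  h1 <- scoreHistogram(scoresInCell(0.42), "c1", binWidth = 0.1)
  expect_equal(sum(h1$counts > 0), 1)

  set.seed(3)
  hr <- scoreHistogram(scoresInCell(runif(57, 0.01, 0.9)), "c1")
  expect_equal(sum(hr$counts), 57)
  expect_true(all(diff(hr$bin_edges) > 0))
})

test_that("empty or unknown cells are rejected", {
  st <- scoresInCell(c(0.2, 0.4))
  expect_error(scoreHistogram(st, "nope"), "unknown cell")
})

test_that("cutoff sits at the steepest drop of the count trace", {
  h <- list(cell = "c1", bin_edges = seq(0, 0.06, 0.01),
            counts = c(50, 40, 39, 5, 4, 3))
  co <- detectCutoff(h, smoothWindow = 1)
  expect_equal(co@cutoff, 0.03)                # drop of -34 between bins 3 and 4
  expect_false(co@degenerate)
  expect_equal(co@derivative, diff(c(50, 40, 39, 5, 4, 3)))

  # ties resolve to the smallest score
  ht <- list(cell = "c1", bin_edges = seq(0, 0.05, 0.01),
             counts = c(30, 10, 15, 20, 0))
  expect_equal(detectCutoff(ht, smoothWindow = 1)@cutoff, 0.01)
})

test_that("flat or rising histograms are flagged degenerate", {
  h <- list(cell = "c1", bin_edges = seq(0, 0.04, 0.01),
            counts = c(5, 5, 5, 5))
  co <- detectCutoff(h, smoothWindow = 1)
  expect_true(co@degenerate)
  expect_equal(co@cutoff, 0.04)                # max score convention
  expect_true(detectCutoff(list(cell = "c", bin_edges = c(0, 0.01),
                                counts = 7))@degenerate)
})

test_that("padding empty bins beyond the max score changes nothing", {
  h <- list(cell = "c1", bin_edges = seq(0, 0.06, 0.01),
            counts = c(50, 40, 39, 5, 4, 3))
  hpad <- list(cell = "c1", bin_edges = seq(0, 0.1, 0.01),
               counts = c(50, 40, 39, 5, 4, 3, 0, 0, 0, 0))
  for (w in c(1, 3)) {
    a <- detectCutoff(h, smoothWindow = w)
    b <- detectCutoff(hpad, smoothWindow = w)
    expect_equal(b@cutoff, a@cutoff)
    expect_equal(b@degenerate, a@degenerate)
  }
})

test_that("cutoff recovers the gap of a bimodal planted distribution", {
  recovered <- 0
  for (seed in 1:10) {
    set.seed(seed)
    scores <- c(pmax(rnorm(2000, 0.10, 0.03), 0.001),
                pmin(rnorm(300, 0.40, 0.05), 1))
    st <- scoresInCell(scores)
    co <- detectCutoff(scoreHistogram(st, "c1", binWidth = 0.005),
                       smoothWindow = 3)
    if (co@cutoff > 0.10 && co@cutoff < 0.40) recovered <- recovered + 1
  }
  expect_gte(recovered, 9)
})

test_that("attribution classes follow the cutoff and loose fraction", {
  st <- makeScoreTable(data.frame(
    uniprot_id = c("A", "B", "C"), cell = "c1",
    integrity = 1, popularity = c(0.2, 0.09, 0.01), distinctiveness = 1,
    score = c(0.2, 0.09, 0.01), stringsAsFactors = FALSE))
  cutoffs <- data.frame(cell = "c1", cutoff = 0.1, degenerate = FALSE)
  cls <- classifyAttributions(st, cutoffs, looseFraction = 0.25)
  expect_equal(cls$class, c("strong", "moderate", "loose"))
  expect_equal(attr(cls, "looseFraction"), 0.25)
  expect_error(classifyAttributions(st, data.frame(cell = "zz", cutoff = 1)),
               "missing cutoff")
})

test_that("top-k ranking is score-descending with lexicographic ties", {
  st <- makeScoreTable(data.frame(
    uniprot_id = c("A", "B", "C"), cell = "c1", integrity = 1,
    popularity = c(0.3, 0.2, 0.1), distinctiveness = 1,
    score = c(0.3, 0.2, 0.1), stringsAsFactors = FALSE))
  expect_equal(topProteins(st, "c1", 2)$uniprot_id, c("A", "B"))

  tie <- makeScoreTable(data.frame(
    uniprot_id = c("ZZ", "AA", "MM"), cell = "c1", integrity = 1,
    popularity = c(0.2, 0.2, 0.5), distinctiveness = 1,
    score = c(0.2, 0.2, 0.5), stringsAsFactors = FALSE))
  expect_equal(topProteins(tie, "c1", 2)$uniprot_id, c("MM", "AA"))

  expect_warning(full <- topProteins(st, "c1", 10), "full ranking")
  expect_equal(nrow(full), 3)
  expect_error(topProteins(st, "c1", 0), ">= 1")
})

test_that("the top protein of a planted-exclusive cell is the planted one", {
  spec <- syntheticCorpusSpec(nCells = 2, docsPerCell = 40,
                              nBackgroundProteins = 20, plantedPerCell = 1,
                              plantedMultiplier = 10,
                              mentionsPerDocMean = 6,
                              multilabelFraction = 0, seed = 21)
  sim <- simulateCorpus(spec)
  cube <- assignDomains(sim$documents, sim$meshTree, sim$domains)
  st <- scoreCorpus(countCorpusMentions(sim$documents, sim$lexicon), cube)
  for (cn in names(sim$groundTruth$plantedByCell)) {
    expect_equal(topProteins(st, cn, 1)$uniprot_id,
                 sim$groundTruth$plantedByCell[[cn]])
  }
})

test_that("overlap regions partition the union of scored proteins", {
  st <- makeScoreTable(data.frame(
    uniprot_id = c("p1", "p2", "p3", "p2", "p3", "p3"),
    cell = c("A", "A", "A", "B", "B", "C"),
    integrity = 1, popularity = 0.1, distinctiveness = 1 / 3,
    score = 0.1 / 3, stringsAsFactors = FALSE), cellSet = c("A", "B", "C"))
  ov <- overlapSets(st)
  expect_equal(unname(ov$regions["A"]), 1)          # p1 exclusive to A
  expect_equal(unname(ov$regions["A&B"]), 1)        # p2
  expect_equal(unname(ov$regions["A&B&C"]), 1)      # p3
  expect_equal(unname(ov$regions["B"]), 0)
  expect_equal(sum(ov$regions), 3)
  expect_equal(ov$pairwise["A", "B"], 2L)
  expect_equal(ov$pairwise, t(ov$pairwise))

  disj <- makeScoreTable(data.frame(
    uniprot_id = c("x", "y"), cell = c("A", "B"), integrity = 1,
    popularity = 0.5, distinctiveness = 1, score = 0.5,
    stringsAsFactors = FALSE), cellSet = c("A", "B"))
  ovd <- overlapSets(disj)
  expect_equal(unname(ovd$regions["A&B"]), 0)
  expect_equal(ovd$pairwise["A", "B"], 0L)

  # random corpora: region counts always sum to the union size
  set.seed(8)
  for (i in 1:5) {
    prot <- sprintf("q%02d", 1:12)
    recs <- expand.grid(uniprot_id = prot, cell = c("A", "B", "C"),
                        stringsAsFactors = FALSE)
    recs <- recs[runif(nrow(recs)) < 0.4, , drop = FALSE]
    if (!nrow(recs)) next
    recs$integrity <- 1; recs$popularity <- 0.1
    recs$distinctiveness <- 1; recs$score <- 0.1
    sti <- makeScoreTable(recs, cellSet = c("A", "B", "C"))
    ovi <- overlapSets(sti)
    expect_equal(sum(ovi$regions), length(unique(recs$uniprot_id)))
  }
})
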