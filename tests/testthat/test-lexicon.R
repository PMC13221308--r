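# Dictionary loading, normalization and mention counting.

test_that("normalization lowers case, maps hyphens, collapses whitespace", {
  expect_equal(normalizeText("Alpha‑1  Antitrypsin"),
               "alpha 1 antitrypsin")
  expect_equal(normalizeText("already normal"), "already normal")
  expect_equal(normalizeText(""), "")
  # idempotence over assorted inputs
  inputs <- c("BNP–receptor", "  A  B ", "Café-au-lait",
              "pro-BNP", "ﬁbrosis")
  for (x in inputs) {
    once <- normalizeText(x)
    expect_identical(normalizeText(once), once)
  }
})

test_that("lexicon index covers all distinct synonyms and gene symbols", {
  lex <- makeLexicon(c("P1", "P2", "P3"),
                     symbols = c("AAA", "BBB", "CCC"),
                     synonyms = list(c("alpha one"), c("beta two"),
                                     character(0)))
  # 3 symbols + 2 extra synonyms
  expect_length(synonymIndex(lex), 5)
  expect_equal(unname(synonymIndex(lex)["alpha one"]), "P1")
  expect_length(droppedAmbiguous(lex), 0)
})

test_that("ambiguous synonyms are dropped from the index with a warning", {
  tab <- data.frame(uniprot_id = c("P1", "P2"),
                    gene_symbol = c("AAA", "BBB"),
                    stringsAsFactors = FALSE)
  tab$synonyms <- I(list("CAT", "cat"))
  expect_warning(lex <- loadLexicon(tab), "ambiguous")
  expect_equal(droppedAmbiguous(lex), "cat")
  expect_false("cat" %in% names(synonymIndex(lex)))
  # the multi-assign flag keeps both assignments instead
  lex2 <- loadLexicon(tab, multiAssign = TRUE)
  expect_equal(sum(names(synonymIndex(lex2)) == "cat"), 2)
})

test_that("case-variant synonyms of one entry collapse to a single key", {
  lex <- makeLexicon("P1", symbols = "Bnp",
                     synonyms = list(c("BNP", "bnp")))
  expect_equal(sum(names(synonymIndex(lex)) == "bnp"), 1)
})

test_that("degenerate dictionaries are rejected", {
  tab <- data.frame(uniprot_id = c("P1", "P1"), gene_symbol = c("A", "B"),
                    synonyms = c("", ""), stringsAsFactors = FALSE)
  expect_error(loadLexicon(tab), "duplicate uniprot_id")
  empty <- data.frame(uniprot_id = character(0),
                      gene_symbol = character(0),
                      synonyms = character(0), stringsAsFactors = FALSE)
  expect_error(loadLexicon(empty), "empty")
})

test_that("occurrences are counted leftmost-longest at token boundaries", {
  lex <- makeLexicon(c("P1", "P2"), symbols = c("BNP", "CATX"),
                     synonyms = list(c("pro bnp"), character(0)))
  doc <- list(title = "", keywords = character(0),
              abstract = "BNP and pro-BNP rose")
  counts <- countMentions(doc, lex)
  expect_equal(unname(counts["P1"]), 2L)  # "bnp" + "pro bnp"

  lex2 <- makeLexicon(c("P1", "P2"), symbols = c("BNP", "BNPR"),
                      synonyms = list(character(0), c("bnp receptor")))
  c2 <- countMentions(list(title = "", abstract = "bnp receptor",
                           keywords = character(0)), lex2)
  expect_equal(unname(c2["P2"]), 1L)
  expect_false("P1" %in% names(c2))

  # token anchoring: "cat" must not match inside "catalase"
  lex3 <- makeLexicon("P1", symbols = "CAT")
  c3 <- countMentions(list(title = "", abstract = "catalase activity",
                           keywords = character(0)), lex3)
  expect_length(c3, 0)

  c4 <- countMentions(list(title = "no dictionary phrase here",
                           abstract = "", keywords = character(0)), lex3)
  expect_length(c4, 0)
})

test_that("title, abstract and keywords are all scanned", {
  lex <- makeLexicon(c("P1", "P2", "P3"),
                     symbols = c("ACE", "renin", "TNF"))
  counts <- countMentions(list(title = "ACE inhibition",
                               abstract = "renin levels fell",
                               keywords = c("tnf", "cytokine")), lex)
  expect_equal(sort(names(counts)), c("P1", "P2", "P3"))
})

test_that("counting is stable under repeated normalization", {
  lex <- makeLexicon(c("P1", "P2"), symbols = c("BNP", "SPARC"),
                     synonyms = list(c("pro bnp"), c("basement membrane protein 40")))
  raw <- "Pro‑BNP and SPARC; basement membrane—protein 40"
  doc1 <- list(title = "", abstract = raw, keywords = character(0))
  doc2 <- list(title = "", abstract = normalizeText(raw),
               keywords = character(0))
  expect_identical(countMentions(doc1, lex), countMentions(doc2, lex))
})

test_that("corpus counting matches the brute-force substring oracle", {
  set.seed(99)
  lex <- makeLexicon(sprintf("P%02d", 1:8),
                     symbols = sprintf("GEN%02d", 1:8),
                     synonyms = list("alpha factor", "alpha factor receptor",
                                     "beta unit", character(0), "gamma",
                                     "delta chain", "epsilon", "zeta zeta"))
  vocab <- c("alpha", "factor", "receptor", "beta", "unit", "gamma",
             "delta", "chain", "filler", "study", "GEN01", "GEN05",
             "epsilon", "zeta")
  docs <- makeDocs(sprintf("d%02d", 1:30),
                   abstract = vapply(1:30, function(i)
                     paste(sample(vocab, sample(5:25, 1), replace = TRUE),
                           collapse = " "), character(1)))
  got <- countCorpusMentions(docs, lex)
  want <- oracleCountCorpus(docs, lex)
  ord <- function(d) {
    d <- d[order(d$pmid, d$uniprot_id), c("pmid", "uniprot_id", "tf")]
    rownames(d) <- NULL
    d
  }
  expect_identical(ord(as.data.frame(got)), ord(want))
})

test_that("matched spans never overlap (reconstruction property)", {
  # every match consumes its tokens: total matched token count can never
  # exceed the document token count
  set.seed(5)
  # one synonym per protein so each match consumes a known token span
  lex <- makeLexicon(c("P1", "P2", "P3"),
                     symbols = c("aa bb", "bb cc", "cc"))
  tokLen <- c(P1 = 2L, P2 = 2L, P3 = 1L)
  for (i in 1:20) {
    words <- sample(c("aa", "bb", "cc", "dd"), sample(1:12, 1),
                    replace = TRUE)
    doc <- list(title = "", abstract = paste(words, collapse = " "),
                keywords = character(0))
    counts <- countMentions(doc, lex)
    consumed <- sum(counts * tokLen[names(counts)])
    expect_lte(consumed, length(words))
  }
})
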