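# Shared fixtures, all built in code.

# minimal document table constructor
makeDocs <- function(pmid, title = NULL, abstract = NULL, keywords = NULL,
                     mesh = NULL) {
  n <- length(pmid)
  if (is.null(title)) title <- sprintf("title %s", pmid)
  if (is.null(abstract)) abstract <- rep("", n)
  if (is.null(keywords)) keywords <- rep(list(character(0)), n)
  if (is.null(mesh)) mesh <- rep(list(character(0)), n)
  data.frame(pmid = pmid, title = title, abstract = abstract,
             keywords = I(keywords), mesh_ids = I(mesh),
             date = rep(NA_character_, n), stringsAsFactors = FALSE)
}

# dictionary data.frame -> Lexicon
makeLexicon <- function(ids, symbols = NULL, synonyms = NULL) {
  if (is.null(symbols)) symbols <- sprintf("G%s", ids)
  tab <- data.frame(uniprot_id = ids, gene_symbol = symbols,
                    stringsAsFactors = FALSE)
  tab$synonyms <- I(if (is.null(synonyms))
    as.list(symbols) else synonyms)
  loadLexicon(tab)
}

# ScoreTable straight from a record data.frame (for prioritize/stats tests)
makeScoreTable <- function(df, cellSet = NULL) {
  if (is.null(cellSet)) cellSet <- unique(df$cell)
  for (col in c("integrity", "popularity", "distinctiveness"))
    if (is.null(df[[col]])) df[[col]] <- 1
  if (is.null(df$score))
    df$score <- df$integrity * df$popularity * df$distinctiveness
  methods::new("ScoreTable",
               scores = df[, c("uniprot_id", "cell", "integrity",
                               "popularity", "distinctiveness", "score")],
               cellSet = cellSet,
               strategy = c(popularity = "log", relevance = "ratio"))
}

# a ScoreTable whose composite scores are a given numeric vector in one cell
scoresInCell <- function(x, cell = "c1") {
  makeScoreTable(data.frame(
    uniprot_id = sprintf("P%04d", seq_along(x)), cell = cell,
    integrity = 1, popularity = x, distinctiveness = 1, score = x,
    stringsAsFactors = FALSE))
}

# hand-written two-article PubMed XML fixture
twoArticleXml <- function() {
  paste0(
    "<PubmedArticleSet>",
    "<PubmedArticle><MedlineCitation><PMID>101</PMID>",
    "<Article><ArticleTitle>BNP in cardiomyopathy</ArticleTitle>",
    "<Abstract><AbstractText>Plasma BNP rose.</AbstractText></Abstract>",
    "<Journal><JournalIssue><PubDate><Year>2019</Year></PubDate>",
    "</JournalIssue></Journal></Article>",
    "<MeshHeadingList><MeshHeading>",
    "<DescriptorName UI=\"D009202\">Cardiomyopathies</DescriptorName>",
    "</MeshHeading></MeshHeadingList>",
    "<KeywordList><Keyword>biomarker</Keyword></KeywordList>",
    "</MedlineCitation></PubmedArticle>",
    "<PubmedArticle><MedlineCitation><PMID>102</PMID>",
    "<Article><ArticleTitle>Troponin assay</ArticleTitle></Article>",
    "</MedlineCitation></PubmedArticle>",
    "</PubmedArticleSet>")
}

# small synthetic MeSH tree: two domains plus descendants
toyMeshTree <- function() {
  methods::new("MeshTree",
    entries = data.frame(
      descriptor_id = c("D001", "D002", "D003", "D004", "D005"),
      name = c("heart disease root", "heart disease sub", "stroke root",
               "stroke sub", "near miss"),
      stringsAsFactors = FALSE),
    treeNumbers = list(D001 = "C14.280", D002 = "C14.280.434",
                       D003 = "C10.228", D004 = c("C10.228.140", "Z01.1"),
                       D005 = "C14.2801"))
}
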