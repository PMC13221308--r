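# Synthetic corpora, expression tables and tissue tables with planted
# ground truth. Generators are pure functions of their spec (seed included)
# and emit the exact same objects/file formats the real pipeline consumes.

.fillerVocab <- c("the", "of", "study", "results", "clinical", "analysis",
                  "patients", "cohort", "observed", "levels", "signal",
                  "report", "data", "with", "in", "were", "was", "higher",
                  "lower", "assay")

#' Specification of a synthetic literature corpus
#'
#' Defines the study conditions a generated corpus emulates: multi-label
#' documents drawn per cell, heavy-tailed background phrase traffic,
#' planted cell-exclusive proteins at an elevated mention rate, optional
#' cell-shared proteins, and Poisson mention counts per document.
#'
#' @param nCells number of domain cells.
#' @param docsPerCell documents generated per cell.
#' @param nBackgroundProteins background proteins mentioned in every cell,
#'   with per-protein rates drawn log-uniformly over one decade
#'   (`10^U(-1, 0)`) to mimic the heavy-tailed mention distribution of real
#'   literature.
#' @param plantedPerCell cell-exclusive proteins planted per cell.
#' @param plantedMultiplier mention-rate multiplier of planted proteins
#'   relative to the mean background rate (>= 1), applied in the home cell
#'   only.
#' @param nSharedProteins proteins shared across `sharedCells`.
#' @param sharedCells integer indices of the cells carrying the shared
#'   proteins (default: all cells).
#' @param mentionsPerDocMean Poisson mean of dictionary mentions per
#'   document.
#' @param multilabelFraction fraction of documents annotated with a second
#'   domain's descriptor (multi-label documents).
#' @param includeMonopolyCell add one extra cell whose documents mention a
#'   single dedicated protein — the boundary case where one phrase accounts
#'   for all of a cell's traffic and attains the composite-score upper
#'   bound.
#' @param seed mandatory RNG seed; generation is fully reproducible.
#' @return validated spec (list) for [simulateCorpus()].
#' @export
syntheticCorpusSpec <- function(nCells = 6, docsPerCell = 200,
                                nBackgroundProteins = 300,
                                plantedPerCell = 20, plantedMultiplier = 10,
                                nSharedProteins = 0, sharedCells = NULL,
                                mentionsPerDocMean = 8,
                                multilabelFraction = 0.1,
                                includeMonopolyCell = FALSE, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  counts <- c(nCells, docsPerCell, nBackgroundProteins, plantedPerCell,
              nSharedProteins, mentionsPerDocMean)
  if (any(counts < 0)) stop("all counts must be >= 0", call. = FALSE)
  if (nCells < 1 || docsPerCell < 1)
    stop("degenerate spec: need >= 1 cell and >= 1 doc per cell",
         call. = FALSE)
  if (plantedMultiplier < 1) stop("multiplier must be >= 1", call. = FALSE)
  if (multilabelFraction < 0 || multilabelFraction > 1)
    stop("multilabelFraction must lie in [0, 1]", call. = FALSE)
  if (is.null(sharedCells)) sharedCells <- seq_len(nCells)
  list(nCells = as.integer(nCells), docsPerCell = as.integer(docsPerCell),
       nBackgroundProteins = as.integer(nBackgroundProteins),
       plantedPerCell = as.integer(plantedPerCell),
       plantedMultiplier = plantedMultiplier,
       nSharedProteins = as.integer(nSharedProteins),
       sharedCells = as.integer(sharedCells),
       mentionsPerDocMean = mentionsPerDocMean,
       multilabelFraction = multilabelFraction,
       includeMonopolyCell = isTRUE(includeMonopolyCell),
       seed = as.integer(seed))
}

#' Generate a synthetic corpus with planted structure
#'
#' Builds documents, a synthetic MeSH tree placing each document under its
#' cell's root descriptor, a matching protein dictionary, and the ground
#' truth of planted proteins. Mentions are drawn on a closed synthetic
#' vocabulary (dictionary phrases plus filler tokens absent from the
#' dictionary) so brute-force oracle counting is trivial. Background
#' proteins are mentioned in every cell; planted proteins only in their
#' home cell, at `plantedMultiplier` times the mean background rate.
#'
#' @param spec a spec from [syntheticCorpusSpec()].
#' @return list with `documents` (data.frame), `meshTree`
#'   ([MeshTree-class]), `domains` (named list of root descriptor ids),
#'   `lexicon` ([Lexicon-class]) and `groundTruth` (planted ids per cell,
#'   shared ids, monopoly id, spec echo).
#' @export
simulateCorpus <- function(spec) {
  set.seed(spec$seed)
  nc <- spec$nCells
  cellNames <- sprintf("domain%02d", seq_len(nc))
  monopoly <- spec$includeMonopolyCell
  allCells <- c(cellNames, if (monopoly) "monopoly")

  # synthetic MeSH: one root + two children per cell
  rootIds <- sprintf("D%06d", seq_along(allCells) * 1000L)
  meshIds <- character(0); meshNames <- character(0); meshTrees <- list()
  cellDescriptors <- vector("list", length(allCells))
  for (i in seq_along(allCells)) {
    ids <- c(rootIds[i], sprintf("D%06d", i * 1000L + 1:2))
    trees <- list(sprintf("C%02d", i),
                  sprintf("C%02d.100", i), sprintf("C%02d.200", i))
    meshIds <- c(meshIds, ids)
    meshNames <- c(meshNames, paste(allCells[i], c("root", "sub a", "sub b")))
    meshTrees <- c(meshTrees, trees)
    cellDescriptors[[i]] <- ids
  }
  names(meshTrees) <- meshIds
  meshTree <- new("MeshTree",
                  entries = data.frame(descriptor_id = meshIds,
                                       name = meshNames,
                                       stringsAsFactors = FALSE),
                  treeNumbers = meshTrees)
  domains <- setNames(as.list(rootIds), allCells)
  domains <- lapply(domains, identity)

  # dictionary: background + planted + shared (+ monopoly) proteins
  nb <- spec$nBackgroundProteins
  bgIds <- if (nb) sprintf("B%05d", seq_len(nb)) else character(0)
  dict <- data.frame(uniprot_id = bgIds,
                     gene_symbol = sprintf("BGN%04d", seq_len(nb)),
                     stringsAsFactors = FALSE)[seq_len(nb), , drop = FALSE]
  dict$synonyms <- I(lapply(seq_len(nb), function(i)
    sprintf("background protein %04d", i)))
  plantedByCell <- setNames(vector("list", nc), cellNames)
  for (i in seq_len(nc)) {
    np <- spec$plantedPerCell
    if (np == 0) { plantedByCell[[i]] <- character(0); next }
    ids <- sprintf("X%02d%03d", i, seq_len(np))
    plantedByCell[[i]] <- ids
    add <- data.frame(uniprot_id = ids,
                      gene_symbol = sprintf("PLT%02d%03d", i, seq_len(np)),
                      stringsAsFactors = FALSE)
    add$synonyms <- I(lapply(seq_len(np), function(j)
      sprintf("planted marker %02d %03d", i, j)))
    dict <- rbind(dict, add)
  }
  sharedIds <- character(0)
  if (spec$nSharedProteins > 0) {
    sharedIds <- sprintf("S%05d", seq_len(spec$nSharedProteins))
    add <- data.frame(uniprot_id = sharedIds,
                      gene_symbol = sprintf("SHR%04d",
                                            seq_len(spec$nSharedProteins)),
                      stringsAsFactors = FALSE)
    add$synonyms <- I(lapply(seq_len(spec$nSharedProteins), function(j)
      sprintf("shared marker %04d", j)))
    dict <- rbind(dict, add)
  }
  monoId <- NULL
  if (monopoly) {
    monoId <- "M00001"
    add <- data.frame(uniprot_id = monoId, gene_symbol = "MONO1",
                      stringsAsFactors = FALSE)
    add$synonyms <- I(list("monopoly marker"))
    dict <- rbind(dict, add)
  }
  lexicon <- loadLexicon(dict)

  # per-cell mention weights
  bgRate <- if (nb) 10^runif(nb, -1, 0) else numeric(0)
  meanBg <- if (nb) mean(bgRate) else 1
  proteinIds <- dict$uniprot_id
  weights <- matrix(0, length(proteinIds), length(allCells),
                    dimnames = list(proteinIds, allCells))
  for (i in seq_len(nc)) {
    if (nb) weights[bgIds, i] <- bgRate
    if (length(plantedByCell[[i]]))
      weights[plantedByCell[[i]], i] <- spec$plantedMultiplier * meanBg
    if (length(sharedIds) && i %in% spec$sharedCells)
      weights[sharedIds, i] <- meanBg
  }
  if (monopoly) weights[monoId, "monopoly"] <- 1

  # synonym pool per protein (gene symbol + names), as written in text
  synPool <- setNames(lexiconEntries(lexicon)$synonyms, proteinIds)

  nDocs <- spec$docsPerCell * length(allCells)
  pmids <- sprintf("%07d", seq_len(nDocs))
  rows <- vector("list", nDocs)
  d <- 0L
  for (i in seq_along(allCells)) {
    isMono <- monopoly && allCells[i] == "monopoly"
    for (j in seq_len(spec$docsPerCell)) {
      d <- d + 1L
      nMent <- rpois(1, spec$mentionsPerDocMean)
      if (isMono) nMent <- max(1L, nMent)
      phrases <- character(0)
      if (nMent > 0 && any(weights[, i] > 0)) {
        picks <- sample(proteinIds, nMent, replace = TRUE,
                        prob = weights[, i])
        phrases <- vapply(picks, function(p) {
          pool <- synPool[[p]]
          pool[sample.int(length(pool), 1)]
        }, character(1))
      }
      words <- character(0)
      for (ph in phrases)
        words <- c(words,
                   sample(.fillerVocab, sample.int(3, 1), replace = TRUE),
                   ph)
      words <- c(words, sample(.fillerVocab, 2, replace = TRUE))
      mesh <- sample(cellDescriptors[[i]], 1)
      if (!isMono && nc > 1 && runif(1) < spec$multilabelFraction) {
        other <- sample(setdiff(seq_len(nc), i), 1)
        mesh <- c(mesh, sample(cellDescriptors[[other]], 1))
      }
      rows[[d]] <- list(pmid = pmids[d],
                        title = sprintf("Synthetic record %s", pmids[d]),
                        abstract = paste(words, collapse = " "),
                        keywords = character(0), mesh_ids = mesh,
                        date = sprintf("%d", sample(2000:2024, 1)))
    }
  }
  documents <- data.frame(
    pmid = vapply(rows, `[[`, character(1), "pmid"),
    title = vapply(rows, `[[`, character(1), "title"),
    abstract = vapply(rows, `[[`, character(1), "abstract"),
    keywords = I(lapply(rows, `[[`, "keywords")),
    mesh_ids = I(lapply(rows, `[[`, "mesh_ids")),
    date = vapply(rows, `[[`, character(1), "date"),
    stringsAsFactors = FALSE)

  list(documents = documents, meshTree = meshTree, domains = domains,
       lexicon = lexicon,
       groundTruth = list(plantedByCell = plantedByCell,
                          sharedProteins = sharedIds,
                          monopolyProtein = monoId, spec = spec))
}

#' Write a synthetic corpus in the formats the pipeline consumes
#'
#' @param sim result of [simulateCorpus()].
#' @param dir output directory (created if needed). Writes `corpus.xml`,
#'   `mesh.tsv`, `dictionary.tsv`, `domains.yaml` and `ground_truth.json`.
#' @return invisibly, the named vector of paths.
#' @export
writeSyntheticCorpus <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(corpus = file.path(dir, "corpus.xml"),
             mesh = file.path(dir, "mesh.tsv"),
             dictionary = file.path(dir, "dictionary.tsv"),
             domains = file.path(dir, "domains.yaml"),
             truth = file.path(dir, "ground_truth.json"))
  writeMedlineXml(sim$documents, paths["corpus"])
  writeMeshTree(sim$meshTree, paths["mesh"])
  writeLexicon(sim$lexicon, paths["dictionary"])
  writeDomainConfig(sim$domains, paths["domains"])
  jsonlite::write_json(sim$groundTruth[c("plantedByCell", "sharedProteins",
                                         "monopolyProtein")],
                       paths["truth"], auto_unbox = TRUE, null = "null")
  invisible(paths)
}

#' Specification of a synthetic expression table
#'
#' @param nProteins number of proteins (rows).
#' @param nCase,nControl samples per group (defaults mirror a small biopsy
#'   cohort: 10 cases, 9 controls).
#' @param plantedCount proteins given a group mean shift (<= nProteins).
#' @param delta mean shift of planted proteins in the case group, in units
#'   of the noise standard deviation.
#' @param noiseSd within-group noise standard deviation.
#' @param seed mandatory RNG seed.
#' @return validated spec (list) for [simulateExpression()].
#' @export
syntheticExpressionSpec <- function(nProteins, nCase = 10, nControl = 9,
                                    plantedCount = 0, delta = 0,
                                    noiseSd = 1, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (plantedCount > nProteins)
    stop("plantedCount must be <= nProteins", call. = FALSE)
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  list(nProteins = as.integer(nProteins), nCase = as.integer(nCase),
       nControl = as.integer(nControl),
       plantedCount = as.integer(plantedCount), delta = delta,
       noiseSd = noiseSd, seed = as.integer(seed))
}

#' Generate an expression table with planted group shifts
#'
#' Per-protein baselines are uniform over \[5, 15\]; values are Gaussian
#' around the baseline with `noiseSd`; planted proteins are shifted upward
#' by `delta * noiseSd` in the case group.
#'
#' @param spec a spec from [syntheticExpressionSpec()].
#' @return list with `expr` (matrix proteins x samples), `groups`
#'   (character vector, `"control"`/`"case"`), and `groundTruth` (planted
#'   protein ids, spec echo).
#' @export
simulateExpression <- function(spec) {
  set.seed(spec$seed)
  ids <- sprintf("E%05d", seq_len(spec$nProteins))
  nS <- spec$nCase + spec$nControl
  base <- runif(spec$nProteins, 5, 15)
  expr <- matrix(rnorm(spec$nProteins * nS, mean = base, sd = spec$noiseSd),
                 nrow = spec$nProteins, ncol = nS)
  groups <- c(rep("control", spec$nControl), rep("case", spec$nCase))
  planted <- if (spec$plantedCount)
    sort(sample(ids, spec$plantedCount)) else character(0)
  if (length(planted))
    expr[match(planted, ids), groups == "case"] <-
      expr[match(planted, ids), groups == "case"] + spec$delta * spec$noiseSd
  dimnames(expr) <- list(ids, sprintf("%s_%02d", groups,
                                      c(seq_len(spec$nControl),
                                        seq_len(spec$nCase))))
  list(expr = expr, groups = groups,
       groundTruth = list(planted = planted, spec = spec))
}

#' Generate a tissue expression table with known dominant tissues
#'
#' Every protein receives a background value in \[0, 10\] for each tissue and
#' a dominant value in \[50, 100\] in one known tissue, so
#' [tissueMaxAssignment()] recovers the dominant tissue by construction.
#'
#' @param nProteins number of proteins.
#' @param tissues character vector of tissue names (>= 1).
#' @param seed RNG seed.
#' @return list with `table` (long data.frame `protein`, `tissue`, `value`)
#'   and `groundTruth` (named character vector: protein -> dominant tissue).
#' @export
simulateTissueTable <- function(nProteins, tissues, seed) {
  if (!length(tissues)) stop("need at least one tissue", call. = FALSE)
  set.seed(seed)
  ids <- sprintf("T%05d", seq_len(nProteins))
  dominant <- setNames(sample(tissues, nProteins, replace = TRUE), ids)
  tab <- expand.grid(protein = ids, tissue = tissues,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$value <- runif(nrow(tab), 0, 10)
  hit <- tab$tissue == dominant[tab$protein]
  tab$value[hit] <- runif(sum(hit), 50, 100)
  tab <- tab[order(tab$protein, tab$tissue), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, groundTruth = dominant)
}
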