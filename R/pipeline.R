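# End-to-end orchestration: configuration, staged execution, manifest.

.configError <- function(...) {
  stop(structure(class = c("caseolap_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Assemble and validate a pipeline run configuration
#'
#' All defaults are echoed into the run manifest so a run is auditable.
#' Referenced input paths must exist at run start (config error otherwise);
#' the expression/tissue inputs are optional and gate the validation stage.
#'
#' @param corpusXml path to the article-set XML.
#' @param meshTsv path to the MeSH descriptor TSV.
#' @param dictionaryTsv path to the protein dictionary TSV.
#' @param domainConfig path to the domain YAML.
#' @param outDir output directory for all stage outputs.
#' @param expressionTsv,groupsTsv optional expression table + group labels.
#' @param tissueTsv optional long-format tissue table.
#' @param binWidth,smoothWindow cutoff-detection parameters.
#' @param looseFraction moderate/loose boundary as a fraction of the cutoff.
#' @param topK literature list size for ranking and enrichment.
#' @param topDifferential differential list size for the overlap comparison.
#' @param backgroundN enrichment background size (default: dictionary size).
#' @param focalCell cell whose top-k list is validated (default: first).
#' @param clusterStandardize `"zscore"` or `"unitnorm"`.
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return validated config list for [runPipeline()].
#' @export
pipelineConfig <- function(corpusXml, meshTsv, dictionaryTsv, domainConfig,
                           outDir, expressionTsv = NULL, groupsTsv = NULL,
                           tissueTsv = NULL, binWidth = 0.005,
                           smoothWindow = 3L, looseFraction = 0.25,
                           topK = 20L, topDifferential = 100L,
                           backgroundN = NULL, focalCell = NULL,
                           clusterStandardize = "zscore", seed = 1L) {
  cfg <- list(corpusXml = corpusXml, meshTsv = meshTsv,
              dictionaryTsv = dictionaryTsv, domainConfig = domainConfig,
              outDir = outDir, expressionTsv = expressionTsv,
              groupsTsv = groupsTsv, tissueTsv = tissueTsv,
              binWidth = binWidth, smoothWindow = as.integer(smoothWindow),
              looseFraction = looseFraction, topK = as.integer(topK),
              topDifferential = as.integer(topDifferential),
              backgroundN = backgroundN, focalCell = focalCell,
              clusterStandardize = clusterStandardize,
              seed = as.integer(seed))
  req <- c("corpusXml", "meshTsv", "dictionaryTsv", "domainConfig")
  for (f in req) {
    if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
      .configError("input path missing or not found: ", f,
                   " = ", if (is.null(cfg[[f]])) "NULL" else cfg[[f]])
  }
  for (f in c("expressionTsv", "groupsTsv", "tissueTsv")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      .configError("input path not found: ", f, " = ", cfg[[f]])
  }
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys use snake_case versions of the [pipelineConfig()] arguments
#' (`corpus_xml`, `mesh_tsv`, `dictionary_tsv`, `domain_config`, `out_dir`,
#' `expression_tsv`, `groups_tsv`, `tissue_tsv`, `bin_width`,
#' `smooth_window`, `loose_fraction`, `top_k`, `top_differential`,
#' `background_n`, `focal_cell`, `cluster_standardize`, `seed`).
#'
#' @param path YAML file path.
#' @return validated config list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) .configError("config file not found: ", path)
  y <- yaml::read_yaml(path)
  key <- function(k, default = NULL) if (is.null(y[[k]])) default else y[[k]]
  pipelineConfig(
    corpusXml = key("corpus_xml"), meshTsv = key("mesh_tsv"),
    dictionaryTsv = key("dictionary_tsv"),
    domainConfig = key("domain_config"), outDir = key("out_dir", "."),
    expressionTsv = key("expression_tsv"), groupsTsv = key("groups_tsv"),
    tissueTsv = key("tissue_tsv"), binWidth = key("bin_width", 0.005),
    smoothWindow = key("smooth_window", 3L),
    looseFraction = key("loose_fraction", 0.25), topK = key("top_k", 20L),
    topDifferential = key("top_differential", 100L),
    backgroundN = key("background_n"), focalCell = key("focal_cell"),
    clusterStandardize = key("cluster_standardize", "zscore"),
    seed = key("seed", 1L))
}

#' Run the full pipeline: corpus, lexicon, scoring, prioritize, stats,
#' validate
#'
#' Stages execute in order, each writing its outputs before the next
#' starts; warnings raised anywhere (ambiguous synonyms, ties, degenerate
#' cutoffs, short rankings) are collected into the manifest. The manifest
#' also records package version, every parameter (defaults included) and
#' md5 checksums of all inputs.
#'
#' @param config a list from [pipelineConfig()]/[readPipelineConfig()].
#' @return invisibly, the manifest list (also written to
#'   `out_dir/manifest.json`).
#' @export
runPipeline <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  warnings <- character(0)
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  out <- function(...) file.path(config$outDir, ...)
  manifest <- list(
    package = "caseolap",
    version = as.character(utils::packageVersion("caseolap")),
    parameters = config[setdiff(names(config), "outDir")],
    inputs = list(), outputs = character(0), warnings = character(0))
  for (f in c("corpusXml", "meshTsv", "dictionaryTsv", "domainConfig",
              "expressionTsv", "groupsTsv", "tissueTsv")) {
    if (!is.null(config[[f]]))
      manifest$inputs[[f]] <- list(
        path = config[[f]],
        md5 = unname(tools::md5sum(config[[f]])))
  }

  # stage: corpus
  docs <- collect(readMedlineXml(config$corpusXml))
  docs <- collect(deduplicateDocuments(docs))
  tree <- readMeshTree(config$meshTsv)
  domains <- readDomainConfig(config$domainConfig)
  cube <- assignDomains(docs, tree, domains)
  sdm <- sharedDocumentMatrix(cube)
  write.table(data.frame(cell = rownames(sdm), sdm, check.names = FALSE),
              out("shared_documents.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # stage: lexicon
  lex <- collect(loadLexicon(config$dictionaryTsv))
  mentions <- countCorpusMentions(docs, lex)
  writeMentionCounts(mentions, out("mentions.tsv"))

  # stage: scoring
  st <- scoreCorpus(mentions, cube)
  writeScoreTable(st, out("scores.tsv"))

  # stage: prioritize
  cutoffs <- detectCutoffs(st, binWidth = config$binWidth,
                           smoothWindow = config$smoothWindow)
  write.table(cutoffs, out("cutoffs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (any(cutoffs$degenerate))
    warnings <- c(warnings,
                  paste("degenerate cutoff in:",
                        paste(cutoffs$cell[cutoffs$degenerate],
                              collapse = ", ")))
  classes <- classifyAttributions(st, cutoffs,
                                  looseFraction = config$looseFraction)
  write.table(classes, out("classes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  scoredCells <- intersect(cellNames(st), unique(as.data.frame(st)$cell))
  if (length(scoredCells) >= 2) {
    ov <- overlapSets(st, scoredCells)
    jsonlite::write_json(as.list(ov$regions), out("venn_regions.json"),
                         auto_unbox = TRUE)
    write.table(data.frame(cell = rownames(ov$pairwise), ov$pairwise,
                           check.names = FALSE),
                out("shared_proteins.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  focal <- if (is.null(config$focalCell)) scoredCells[1] else config$focalCell
  topTab <- collect(topProteins(st, focal, config$topK))
  write.table(topTab, out("top_proteins.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # stage: stats
  summaries <- do.call(rbind, lapply(scoredCells, function(cn)
    data.frame(cell = cn, as.data.frame(summarizeScores(st, cn)))))
  write.table(summaries, out("score_summaries.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  others <- setdiff(scoredCells, focal)
  if (length(others)) {
    reg <- do.call(rbind, lapply(others, function(cn) {
      r <- tryCatch(crossDomainRegression(st, focal, cn),
                    error = function(e) NULL)
      if (is.null(r)) return(NULL)
      data.frame(cell_x = focal, cell_y = cn, as.data.frame(r))
    }))
    if (!is.null(reg))
      write.table(reg, out("regressions.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
  }
  if (length(scoredProteins(st)) >= 2) {
    ct <- clusterProteins(st, scoredCells,
                          standardize = config$clusterStandardize)
    writeClusterTree(ct, linkagePath = out("linkage.tsv"),
                     newickPath = out("dendrogram.nwk"))
  }

  # stage: validate (optional)
  if (!is.null(config$expressionTsv) && !is.null(config$groupsTsv)) {
    ex <- readExpressionTable(config$expressionTsv, config$groupsTsv)
    dr <- collect(differentialRank(ex$expr, ex$groups))
    write.table(dr, out("differential.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    # background defaults to every protein seen anywhere: the dictionary
    # plus any dataset proteins outside it
    bgN <- if (is.null(config$backgroundN))
      length(union(lexiconEntries(lex)$uniprot_id, dr$protein))
    else config$backgroundN
    litList <- topTab$uniprot_id
    topDiff <- head(dr$protein, config$topDifferential)
    enr <- list(
      vs_top_differential = hypergeomEnrichment(
        N = bgN, K = length(litList), n = length(topDiff),
        k = length(intersect(litList, topDiff))),
      vs_all_dataset = hypergeomEnrichment(
        N = bgN, K = length(litList), n = nrow(dr),
        k = length(intersect(litList, dr$protein))))
    jsonlite::write_json(enr, out("enrichment.json"), auto_unbox = TRUE,
                         digits = NA)
    if (!is.null(config$tissueTsv)) {
      tt <- readTissueTable(config$tissueTsv)
      tp <- collect(tissueMaxAssignment(tt, litList))
      write.table(data.frame(tissue = names(tp$counts),
                             count = as.integer(tp$counts)),
                  out("tissue_counts.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
  }

  manifest$warnings <- warnings
  manifest$outputs <- list.files(config$outDir)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(manifest)
}
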