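#' @import methods
#' @importFrom stats median quantile sd var cor cor.test lm coef ks.test
#'   phyper hclust dist rpois rnorm runif setNames cophenetic
#' @importFrom utils head write.table read.delim
NULL

setOldClass("hclust")

#' MeshTree: the MeSH descriptor hierarchy
#'
#' Holds, for every descriptor identifier, its display name and the set of
#' dotted tree numbers that place it in the MeSH hierarchy. A descriptor may
#' own several tree numbers; ancestor/descendant relations are tested by
#' string prefix restricted to dot boundaries.
#'
#' @slot entries data.frame with columns `descriptor_id` and `name`.
#' @slot treeNumbers named list (by descriptor id) of character vectors of
#'   dotted tree numbers, e.g. `"C14.280.434"`.
#'
#' @seealso [readMeshTree()], [assignDomains()]
#' @export
setClass("MeshTree",
  representation(entries = "data.frame", treeNumbers = "list"))

setValidity("MeshTree", function(object) {
  msg <- character(0)
  if (!all(c("descriptor_id", "name") %in% names(object@entries)))
    msg <- c(msg, "entries must have columns descriptor_id and name")
  if (anyDuplicated(object@entries$descriptor_id))
    msg <- c(msg, "duplicate descriptor ids")
  if (!setequal(names(object@treeNumbers), object@entries$descriptor_id))
    msg <- c(msg, "treeNumbers names must match descriptor ids")
  tn <- unlist(object@treeNumbers, use.names = FALSE)
  if (length(tn) && !all(grepl("^[A-Z][0-9]+(\\.[0-9]+)*$", tn)))
    msg <- c(msg, "tree numbers must match the dotted-level pattern")
  if (length(msg)) msg else TRUE
})

#' TextCube: a corpus partitioned into domain cells
#'
#' A text cube couples a document table with named cells, each cell being the
#' subset of documents assigned to one disease/comorbidity/mechanism domain
#' via MeSH descriptor-tree descent. Documents may belong to several cells
#' (multi-label) or to none.
#'
#' @slot documents data.frame with columns `pmid`, `title`, `abstract`,
#'   `keywords` (list column), `mesh_ids` (list column), `date`.
#' @slot cells named list of character vectors of pmids, one per domain.
#' @slot domains named list of character vectors of root MeSH descriptor ids.
#'
#' @seealso [assignDomains()], [cellMembers()], [sharedDocumentMatrix()]
#' @export
setClass("TextCube",
  representation(documents = "data.frame", cells = "list", domains = "list"))

setValidity("TextCube", function(object) {
  msg <- character(0)
  if (!all(c("pmid", "title", "abstract") %in% names(object@documents)))
    msg <- c(msg, "documents must have pmid, title, abstract columns")
  if (anyDuplicated(object@documents$pmid))
    msg <- c(msg, "duplicate pmids in documents")
  if (is.null(names(object@cells)) && length(object@cells))
    msg <- c(msg, "cells must be named")
  extra <- setdiff(unlist(object@cells, use.names = FALSE),
                   object@documents$pmid)
  if (length(extra))
    msg <- c(msg, sprintf("cell doc ids not in corpus: %s",
                          paste(head(extra, 3), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Lexicon: protein synonym dictionary with an unambiguous match index
#'
#' Entries carry a UniProt accession, a gene symbol and the synonym list
#' (names and abbreviations). The index maps each normalized synonym to the
#' single accession it identifies; synonyms claimed by more than one protein
#' are excluded and recorded in `droppedAmbiguous`.
#'
#' @slot entries data.frame with columns `uniprot_id`, `gene_symbol`,
#'   `synonyms` (list column of character vectors).
#' @slot index named character vector: normalized synonym -> uniprot id.
#' @slot droppedAmbiguous character vector of normalized synonyms removed
#'   because they mapped to more than one protein.
#'
#' @seealso [loadLexicon()], [countMentions()]
#' @export
setClass("Lexicon",
  representation(entries = "data.frame", index = "character",
                 droppedAmbiguous = "character"))

setValidity("Lexicon", function(object) {
  msg <- character(0)
  if (!all(c("uniprot_id", "gene_symbol", "synonyms") %in%
           names(object@entries)))
    msg <- c(msg, "entries must have uniprot_id, gene_symbol, synonyms")
  if (anyDuplicated(object@entries$uniprot_id))
    msg <- c(msg, "uniprot ids must be unique")
  if (length(object@index)) {
    # duplicate keys appear only under multi-assignment of ambiguous
    # synonyms; a (synonym, id) pair is never repeated
    if (is.null(names(object@index)) ||
        anyDuplicated(paste(names(object@index), object@index)))
      msg <- c(msg, "each (synonym, protein) index pair must be unique")
    if (!all(object@index %in% object@entries$uniprot_id))
      msg <- c(msg, "index values must be entry uniprot ids")
  }
  if (length(msg)) msg else TRUE
})

#' ScoreTable: CaseOLAP component and composite scores per protein-cell pair
#'
#' Long-format records for every pair with at least one mention: integrity,
#' popularity and distinctiveness components in \[0, 1\] and their product, the
#' composite CaseOLAP score. Proteins never mentioned in any cell of the
#' comparison set carry no record. For every scored protein the
#' distinctiveness values sum to 1 across the comparison cells.
#'
#' @slot scores data.frame with columns `uniprot_id`, `cell`, `integrity`,
#'   `popularity`, `distinctiveness`, `score`.
#' @slot cellSet character vector naming the comparison cell set the
#'   distinctiveness denominators were computed over.
#' @slot strategy named character vector recording the popularity/relevance
#'   strategy used (metadata, echoed to outputs).
#'
#' @seealso [scoreCorpus()], [topProteins()], [detectCutoffs()]
#' @export
setClass("ScoreTable",
  representation(scores = "data.frame", cellSet = "character",
                 strategy = "character"))

setValidity("ScoreTable", function(object) {
  msg <- character(0)
  need <- c("uniprot_id", "cell", "integrity", "popularity",
            "distinctiveness", "score")
  if (!all(need %in% names(object@scores)))
    msg <- c(msg, paste("scores must have columns:",
                        paste(need, collapse = ", ")))
  else {
    s <- object@scores
    if (nrow(s)) {
      if (!all(s$cell %in% object@cellSet))
        msg <- c(msg, "score cells must belong to the comparison cell set")
      comp <- c(s$integrity, s$popularity, s$distinctiveness, s$score)
      if (any(comp < -1e-12 | comp > 1 + 1e-12))
        msg <- c(msg, "all components must lie in [0, 1]")
      if (anyDuplicated(paste(s$uniprot_id, s$cell)))
        msg <- c(msg, "one record per (protein, cell) pair")
    }
  }
  if (length(msg)) msg else TRUE
})

#' CutoffResult: score cutoff separating strong from weaker attributions
#'
#' The cutoff is the score at the steepest drop of the (smoothed) per-cell
#' score histogram: the edge between the adjacent bin pair with the most
#' negative forward difference of counts. Degenerate distributions (fewer
#' than two bins, or counts that never fall) are flagged and assigned the
#' maximum score.
#'
#' @slot cell character; the cell the cutoff belongs to.
#' @slot cutoff numeric score threshold.
#' @slot derivative numeric vector of forward differences of the smoothed
#'   counts (the trace the cutoff was read from).
#' @slot degenerate logical flag.
#'
#' @seealso [detectCutoff()], [classifyAttributions()]
#' @export
setClass("CutoffResult",
  representation(cell = "character", cutoff = "numeric",
                 derivative = "numeric", degenerate = "logical"))

#' ClusterTree: complete-linkage tree over proteins as score vectors
#'
#' Wraps the agglomeration result of clustering proteins represented as
#' vectors of per-cell composite scores (unscored coordinates imputed as 0),
#' after per-dimension standardization, under Euclidean distance and
#' complete linkage.
#'
#' @slot hc an [stats::hclust] object (merge sequence, heights, leaf order).
#' @slot cells character; the cells used as coordinates.
#' @slot standardize character; `"zscore"` or `"unitnorm"`.
#'
#' @seealso [clusterProteins()]
#' @export
setClass("ClusterTree",
  representation(hc = "hclust", cells = "character",
                 standardize = "character"))
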