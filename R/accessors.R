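# Generics, accessors and show() methods for the core classes.

#' Cell names of a text cube or score table
#' @param x a `TextCube` or `ScoreTable`.
#' @return character vector of cell names.
#' @export
setGeneric("cellNames", function(x) standardGeneric("cellNames"))

#' @rdname cellNames
#' @export
setMethod("cellNames", "TextCube", function(x) names(x@cells))

#' @rdname cellNames
#' @export
setMethod("cellNames", "ScoreTable", function(x) x@cellSet)

#' Documents of a text cube
#' @param x a `TextCube`.
#' @return the document data.frame.
#' @export
setGeneric("documents", function(x) standardGeneric("documents"))

#' @rdname documents
#' @export
setMethod("documents", "TextCube", function(x) x@documents)

#' Member pmids of cells
#' @param x a `TextCube`.
#' @param cell optional cell name; if omitted, the full named list.
#' @return character vector of pmids, or a named list of them.
#' @export
setGeneric("cellMembers", function(x, cell) standardGeneric("cellMembers"))

#' @rdname cellMembers
#' @export
setMethod("cellMembers", "TextCube", function(x, cell) {
  if (missing(cell)) return(x@cells)
  if (!cell %in% names(x@cells))
    stop("unknown cell: ", cell, call. = FALSE)
  x@cells[[cell]]
})

#' Domain root descriptors of a text cube
#' @param x a `TextCube`.
#' @return named list of root MeSH descriptor ids.
#' @export
setGeneric("domainRoots", function(x) standardGeneric("domainRoots"))

#' @rdname domainRoots
#' @export
setMethod("domainRoots", "TextCube", function(x) x@domains)

#' Tree numbers of a MeSH tree
#' @param x a `MeshTree`.
#' @return named list of character vectors of tree numbers.
#' @export
setGeneric("treeNumbers", function(x) standardGeneric("treeNumbers"))

#' @rdname treeNumbers
#' @export
setMethod("treeNumbers", "MeshTree", function(x) x@treeNumbers)

#' Descriptor table of a MeSH tree
#' @param x a `MeshTree`.
#' @return data.frame of descriptor ids and names.
#' @export
setGeneric("meshEntries", function(x) standardGeneric("meshEntries"))

#' @rdname meshEntries
#' @export
setMethod("meshEntries", "MeshTree", function(x) x@entries)

#' Dictionary entries of a lexicon
#' @param x a `Lexicon`.
#' @return data.frame with uniprot_id, gene_symbol and synonyms list column.
#' @export
setGeneric("lexiconEntries", function(x) standardGeneric("lexiconEntries"))

#' @rdname lexiconEntries
#' @export
setMethod("lexiconEntries", "Lexicon", function(x) x@entries)

#' Normalized synonym match index
#' @param x a `Lexicon`.
#' @return named character vector: normalized synonym -> uniprot id.
#' @export
setGeneric("synonymIndex", function(x) standardGeneric("synonymIndex"))

#' @rdname synonymIndex
#' @export
setMethod("synonymIndex", "Lexicon", function(x) x@index)

#' Synonyms dropped for ambiguity
#' @param x a `Lexicon`.
#' @return character vector of normalized synonyms excluded from the index.
#' @export
setGeneric("droppedAmbiguous", function(x) standardGeneric("droppedAmbiguous"))

#' @rdname droppedAmbiguous
#' @export
setMethod("droppedAmbiguous", "Lexicon", function(x) x@droppedAmbiguous)

#' Proteins carrying at least one score
#' @param x a `ScoreTable`.
#' @param cell optional cell name restricting the query.
#' @return character vector of uniprot ids.
#' @export
setGeneric("scoredProteins", function(x, cell) standardGeneric("scoredProteins"))

#' @rdname scoredProteins
#' @export
setMethod("scoredProteins", "ScoreTable", function(x, cell) {
  s <- x@scores
  if (!missing(cell)) {
    if (!cell %in% x@cellSet) stop("unknown cell: ", cell, call. = FALSE)
    s <- s[s$cell == cell, , drop = FALSE]
  }
  sort(unique(s$uniprot_id))
})

#' @describeIn ScoreTable-class long-format score records as a data.frame.
#' @param x a `ScoreTable`.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "ScoreTable", function(x, ...) x@scores)

#' @describeIn ClusterTree-class the underlying [stats::hclust] object.
#' @param x a `ClusterTree`.
#' @param ... ignored.
#' @export
as.hclust.ClusterTree <- function(x, ...) x@hc

setMethod("show", "MeshTree", function(object) {
  cat(sprintf("MeshTree with %d descriptors, %d tree numbers\n",
              nrow(object@entries),
              length(unlist(object@treeNumbers, use.names = FALSE))))
})

setMethod("show", "TextCube", function(object) {
  cat(sprintf("TextCube: %d documents, %d cells\n",
              nrow(object@documents), length(object@cells)))
  if (length(object@cells)) {
    sizes <- vapply(object@cells, length, integer(1))
    cat(paste(sprintf("  %s: %d docs", names(sizes), sizes),
              collapse = "\n"), "\n")
  }
})

setMethod("show", "Lexicon", function(object) {
  cat(sprintf(
    "Lexicon: %d proteins, %d indexed synonyms (%d dropped as ambiguous)\n",
    nrow(object@entries), length(object@index),
    length(object@droppedAmbiguous)))
})

setMethod("show", "ScoreTable", function(object) {
  cat(sprintf("ScoreTable: %d records, %d proteins, %d cells\n",
              nrow(object@scores), length(unique(object@scores$uniprot_id)),
              length(object@cellSet)))
  if (nrow(object@scores))
    cat(sprintf("  composite score range: [%.4g, %.4g]\n",
                min(object@scores$score), max(object@scores$score)))
})

setMethod("show", "CutoffResult", function(object) {
  cat(sprintf("CutoffResult[%s]: cutoff %.4g%s\n", object@cell,
              object@cutoff,
              if (object@degenerate) " (degenerate)" else ""))
})

setMethod("show", "ClusterTree", function(object) {
  cat(sprintf(
    "ClusterTree: %d proteins over %d cells (complete linkage, %s)\n",
    length(object@hc$labels), length(object@cells), object@standardize))
})
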