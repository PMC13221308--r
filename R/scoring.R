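# CaseOLAP scoring: per-cell phrase frequencies and the integrity x
# popularity x distinctiveness composite.

#' Aggregate per-document mention counts into per-cell phrase statistics
#'
#' For each cell c, tf(p, c) is the total number of occurrences of protein p
#' across the documents of c, and cntP(c) is the total frequency of all
#' dictionary phrases in c (so cntP(c) = sum over p of tf(p, c)). A document
#' belonging to several cells contributes to each.
#'
#' @param mentions long-format mention counts from [countCorpusMentions()].
#' @param cells a [TextCube-class] or named list of pmid character vectors.
#' @param corpusPmids optional character vector of all corpus pmids; defaults
#'   to `attr(mentions, "pmids")`. Cells referencing unknown pmids error.
#' @return list with `tf` (numeric matrix, proteins x cells), `cntP` (named
#'   numeric vector) and `docCount` (named integer vector).
#' @export
aggregateCellStats <- function(mentions, cells, corpusPmids = NULL) {
  if (is(cells, "TextCube")) cells <- cellMembers(cells)
  if (is.null(corpusPmids)) corpusPmids <- attr(mentions, "pmids")
  if (!is.null(corpusPmids)) {
    unknown <- setdiff(unlist(cells, use.names = FALSE), corpusPmids)
    if (length(unknown))
      stop("cell(s) reference pmids absent from the mention corpus: ",
           paste(head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  proteins <- sort(unique(mentions$uniprot_id))
  tf <- matrix(0, nrow = length(proteins), ncol = length(cells),
               dimnames = list(proteins, names(cells)))
  for (cn in names(cells)) {
    sub <- mentions[mentions$pmid %in% cells[[cn]], , drop = FALSE]
    if (nrow(sub)) {
      agg <- tapply(sub$tf, sub$uniprot_id, sum)
      tf[names(agg), cn] <- as.numeric(agg)
    }
  }
  list(tf = tf, cntP = colSums(tf),
       docCount = vapply(cells, length, integer(1)))
}

#' Popularity of a protein in a cell
#'
#' Log-damped prevalence of the phrase relative to the cell's total phrase
#' traffic: `log(1 + tf) / log(1 + cntP)`, which is 0 at tf = 0, 1 at
#' tf = cntP, and 0 by convention when cntP = 0.
#'
#' @param tf occurrences of the protein in the cell.
#' @param cntP total phrase occurrences in the cell.
#' @return popularity in \[0, 1\]; vectorized.
#' @examples
#' popularityScore(9, 99)  # log(10)/log(100) = 0.5
#' @export
popularityScore <- function(tf, cntP) {
  out <- log1p(tf) / log1p(cntP)
  out[!is.finite(out)] <- 0  # cntP = 0 convention
  out
}

#' Relevance of a protein to a cell
#'
#' The share of the cell's phrase traffic carried by the protein:
#' `tf / cntP`, 0 by convention when cntP = 0. Relevances over all proteins
#' of a non-empty cell sum to 1.
#'
#' @inheritParams popularityScore
#' @return relevance in \[0, 1\]; vectorized.
#' @export
relevanceScore <- function(tf, cntP) {
  out <- tf / cntP
  out[!is.finite(out)] <- 0  # cntP = 0 convention
  out
}

#' Distinctiveness of a protein for a cell within a comparison set
#'
#' Exclusivity of the protein's relevance to one cell compared with the
#' remaining cells of the comparison set: `rel(p, c) / sum(rel(p, c'))` over
#' the set. Undefined (NA) when the denominator is 0 — such pairs carry no
#' score record.
#'
#' @param rel numeric vector of relevances of one protein over the
#'   comparison cells (names optional).
#' @return numeric vector of distinctiveness values summing to 1, or all-NA
#'   when every relevance is 0.
#' @export
distinctivenessScore <- function(rel) {
  denom <- sum(rel)
  if (denom <= 0) return(rep(NA_real_, length(rel)))
  rel / denom
}

#' Compute the CaseOLAP score table for a corpus
#'
#' For every protein with at least one mention in the comparison cells,
#' computes integrity (constant 1.0 for a curated dictionary, or per-protein
#' values via `integrity`), popularity, distinctiveness and their product,
#' the composite score in \[0, 1\]. Pairs with tf = 0 carry no record, so a
#' protein "has no CaseOLAP score" in cells where it is never mentioned;
#' proteins with a single supporting mention are still scored.
#'
#' @param mentions long-format mention counts from [countCorpusMentions()].
#' @param cells a [TextCube-class] or named list of pmid vectors; this is the
#'   explicit comparison cell set the distinctiveness denominator runs over.
#' @param integrity either a single number, a named numeric vector by
#'   uniprot id, or a function of the uniprot id vector (hook for
#'   phrase-mining integrity input). Default 1.0.
#' @param popularityFun strategy function `(tf, cntP) -> \[0, 1\]`
#'   (default [popularityScore()]).
#' @param relevanceFun strategy function `(tf, cntP) -> \[0, 1\]`
#'   (default [relevanceScore()]).
#' @return a [ScoreTable-class] object.
#' @export
scoreCorpus <- function(mentions, cells, integrity = 1.0,
                        popularityFun = popularityScore,
                        relevanceFun = relevanceScore) {
  cellList <- if (is(cells, "TextCube")) cellMembers(cells) else cells
  stats <- aggregateCellStats(mentions, cellList,
                              corpusPmids = attr(mentions, "pmids"))
  tf <- stats$tf
  cntP <- stats$cntP
  cellSet <- colnames(tf)
  if (nrow(tf) == 0) {
    return(new("ScoreTable",
               scores = data.frame(uniprot_id = character(0),
                                   cell = character(0), integrity = numeric(0),
                                   popularity = numeric(0),
                                   distinctiveness = numeric(0),
                                   score = numeric(0)),
               cellSet = cellSet,
               strategy = c(popularity = "log", relevance = "ratio")))
  }
  cntPmat <- matrix(cntP, nrow(tf), ncol(tf), byrow = TRUE)
  pop <- popularityFun(tf, cntPmat)
  rel <- relevanceFun(tf, cntPmat)
  dimnames(pop) <- dimnames(rel) <- dimnames(tf)
  denom <- rowSums(rel)
  scored <- denom > 0
  ids <- rownames(tf)
  intg <- if (is.function(integrity)) integrity(ids)
          else if (length(integrity) == 1 && is.null(names(integrity)))
            rep(as.numeric(integrity), length(ids))
          else {
            v <- integrity[ids]
            v[is.na(v)] <- 1.0
            as.numeric(v)
          }
  names(intg) <- ids
  recs <- vector("list", sum(scored))
  k <- 0L
  for (p in ids[scored]) {
    dist <- rel[p, ] / denom[p]
    present <- tf[p, ] > 0
    if (!any(present)) next
    k <- k + 1L
    recs[[k]] <- data.frame(
      uniprot_id = p, cell = cellSet[present],
      integrity = intg[[p]],
      popularity = unname(pop[p, present]),
      distinctiveness = unname(dist[present]),
      score = unname(intg[[p]] * pop[p, present] * dist[present]),
      stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, recs[seq_len(k)])
  rownames(scores) <- NULL
  new("ScoreTable", scores = scores, cellSet = cellSet,
      strategy = c(popularity = "log", relevance = "ratio"))
}

#' Write a score table as TSV
#' @param st a [ScoreTable-class] object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeScoreTable <- function(st, path) {
  write.table(as.data.frame(st), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
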