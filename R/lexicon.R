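# Protein dictionary loading, text normalization and dictionary-based
# mention counting (leftmost-longest, non-overlapping, token-anchored).

#' Normalize text for dictionary matching
#'
#' Unicode compatibility (NFKC) normalization, lower-casing, hyphen family
#' mapped to spaces, whitespace collapsed and trimmed. Idempotent, so
#' matching on normalized text is stable under re-normalization.
#'
#' @param x character vector.
#' @return normalized character vector of the same length.
#' @examples
#' normalizeText("Alpha‑1  Antitrypsin")  # "alpha 1 antitrypsin"
#' @export
normalizeText <- function(x) {
  x <- stringi::stri_trans_nfkc(as.character(x))
  x <- stringi::stri_trans_tolower(x)
  x <- stringi::stri_replace_all_regex(
    x, "[\\-‐‑‒–—−]", " ")
  x <- stringi::stri_replace_all_regex(x, "\\s+", " ")
  stringi::stri_trim_both(x)
}

# alphanumeric token runs of a normalized string
.tokenize <- function(x) {
  toks <- stringi::stri_extract_all_regex(x, "[\\p{L}\\p{N}]+")[[1]]
  if (length(toks) == 1 && is.na(toks[1])) character(0) else toks
}

#' Load a protein synonym dictionary
#'
#' Reads a dictionary table (UniProt-style export: accession, gene symbol,
#' synonyms and abbreviations), normalizes every synonym with
#' [normalizeText()] and builds the unambiguous match index. A synonym whose
#' normalized form maps to more than one protein is excluded from the index
#' and reported, unless `multiAssign = TRUE`, in which case ambiguous
#' synonyms are indexed for each claiming protein.
#'
#' @param table path to a TSV with columns `uniprot_id`, `gene_symbol`,
#'   `synonyms` (pipe-separated), or an equivalent data.frame (synonyms as a
#'   list column or pipe-separated strings).
#' @param multiAssign logical; keep ambiguous synonyms, assigned to every
#'   claiming protein (default `FALSE`, drop them).
#' @return a [Lexicon-class] object. The gene symbol is always included
#'   among the synonyms.
#' @export
loadLexicon <- function(table, multiAssign = FALSE) {
  if (is.character(table) && length(table) == 1) {
    tab <- read.delim(table, stringsAsFactors = FALSE,
                      colClasses = "character")
  } else tab <- as.data.frame(table)
  need <- c("uniprot_id", "gene_symbol", "synonyms")
  if (!all(need %in% names(tab)))
    stop("dictionary must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(tab) == 0) stop("empty dictionary", call. = FALSE)
  if (anyDuplicated(tab$uniprot_id))
    stop("duplicate uniprot_id rows in dictionary", call. = FALSE)
  syns <- if (is.list(tab$synonyms)) tab$synonyms else
    strsplit(tab$synonyms, "|", fixed = TRUE)
  syns <- Map(function(s, g) unique(c(g, s[nzchar(trimws(s))])),
              syns, tab$gene_symbol)
  entries <- data.frame(uniprot_id = tab$uniprot_id,
                        gene_symbol = tab$gene_symbol,
                        stringsAsFactors = FALSE)
  entries$synonyms <- I(unname(syns))

  norm <- lapply(syns, function(s) unique(normalizeText(s)))
  norm <- lapply(norm, function(s) s[nzchar(s)])
  key <- unlist(norm, use.names = FALSE)
  id <- rep(entries$uniprot_id, lengths(norm))
  byKey <- split(id, key)
  ambiguous <- names(byKey)[lengths(byKey) > 1]
  if (length(ambiguous) && !multiAssign) {
    warning(sprintf("%d ambiguous synonym(s) dropped from index: %s",
                    length(ambiguous),
                    paste(head(sort(ambiguous), 5), collapse = ", ")),
            call. = FALSE)
    keep <- !(key %in% ambiguous)
    index <- setNames(id[keep], key[keep])
  } else {
    index <- setNames(id, key)
    ambiguous <- character(0)
  }
  new("Lexicon", entries = entries, index = index,
      droppedAmbiguous = sort(ambiguous))
}

#' Write a dictionary table
#' @param lex a [Lexicon-class] object.
#' @param path output TSV path (synonyms pipe-separated).
#' @return `path`, invisibly.
#' @export
writeLexicon <- function(lex, path) {
  e <- lexiconEntries(lex)
  out <- data.frame(uniprot_id = e$uniprot_id, gene_symbol = e$gene_symbol,
                    synonyms = vapply(e$synonyms, paste, character(1),
                                      collapse = "|"),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Compile the synonym index into a first-token automaton: an environment
# keyed by the first token of each synonym, holding candidate token
# sequences sorted by decreasing length (for leftmost-longest matching).
.compileMatcher <- function(lex) {
  idx <- synonymIndex(lex)
  if (!length(idx)) return(new.env(parent = emptyenv()))
  tokseqs <- lapply(names(idx), .tokenize)
  keep <- lengths(tokseqs) > 0
  tokseqs <- tokseqs[keep]
  ids <- unname(idx)[keep]
  first <- vapply(tokseqs, `[[`, character(1), 1)
  env <- new.env(parent = emptyenv(), size = length(unique(first)))
  groups <- split(seq_along(tokseqs), first)
  for (ft in names(groups)) {
    g <- groups[[ft]]
    g <- g[order(-lengths(tokseqs[g]))]
    assign(ft, lapply(g, function(i) list(toks = tokseqs[[i]], id = ids[i])),
           envir = env)
  }
  env
}

# single scan over a token vector; returns uniprot ids, one per match
.scanTokens <- function(tokens, matcher) {
  n <- length(tokens)
  hits <- character(0)
  i <- 1L
  while (i <= n) {
    cands <- matcher[[tokens[i]]]
    advanced <- FALSE
    if (!is.null(cands)) {
      for (cand in cands) {  # longest candidates first
        L <- length(cand$toks)
        if (i + L - 1L <= n &&
            all(tokens[i:(i + L - 1L)] == cand$toks)) {
          hits <- c(hits, cand$id)
          i <- i + L
          advanced <- TRUE
          break
        }
      }
    }
    if (!advanced) i <- i + 1L
  }
  hits
}

#' Count protein mentions in one document
#'
#' Scans the concatenation of title, abstract and keywords on normalized
#' text. Matches are leftmost-longest, non-overlapping and anchored at
#' alphanumeric token boundaries, so `"cat"` never matches inside
#' `"catalase"`, and `"bnp receptor"` takes precedence over `"bnp"` where
#' both start at the same position. Occurrences (not documents) are counted.
#'
#' @param doc a one-row document data.frame, or a list with `title`,
#'   `abstract`, `keywords` fields.
#' @param lex a [Lexicon-class] object.
#' @param matcher optional pre-compiled matcher (internal reuse).
#' @return named integer vector of occurrence counts by uniprot id; empty
#'   when no dictionary phrase occurs.
#' @export
countMentions <- function(doc, lex, matcher = NULL) {
  if (is.null(matcher)) matcher <- .compileMatcher(lex)
  if (is.data.frame(doc)) doc <- as.list(doc[1, , drop = FALSE])
  kw <- doc$keywords
  if (is.list(kw)) kw <- unlist(kw, use.names = FALSE)
  text <- paste(c(doc$title, doc$abstract, kw), collapse = " ")
  hits <- .scanTokens(.tokenize(normalizeText(text)), matcher)
  if (!length(hits)) return(setNames(integer(0), character(0)))
  tab <- table(hits)
  setNames(as.integer(tab), names(tab))
}

#' Count protein mentions over a whole corpus
#'
#' @param docs document data.frame.
#' @param lex a [Lexicon-class] object.
#' @return long-format data.frame (`pmid`, `uniprot_id`, `tf`) with one row
#'   per document-protein pair with tf >= 1. The full set of scanned pmids is
#'   attached as `attr(, "pmids")` so downstream stages can check cell
#'   membership even for documents with zero mentions.
#' @export
countCorpusMentions <- function(docs, lex) {
  matcher <- .compileMatcher(lex)
  out <- vector("list", nrow(docs))
  for (i in seq_len(nrow(docs))) {
    counts <- countMentions(list(title = docs$title[i],
                                 abstract = docs$abstract[i],
                                 keywords = docs$keywords[[i]]),
                            lex, matcher = matcher)
    if (length(counts))
      out[[i]] <- data.frame(pmid = docs$pmid[i],
                             uniprot_id = names(counts),
                             tf = as.integer(counts),
                             stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(pmid = character(0), uniprot_id = character(0),
               tf = integer(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "pmids") <- docs$pmid
  res
}

#' Write mention counts as long-format TSV
#' @param mentions data.frame from [countCorpusMentions()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeMentionCounts <- function(mentions, path) {
  write.table(mentions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
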