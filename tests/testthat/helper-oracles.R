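# Independent oracles: deliberately naive re-implementations that never
# touch the package's own matching/scoring code paths.

# brute-force substring scan of one text: leftmost-longest, non-overlapping,
# anchored at alphanumeric boundaries, on the normalized string
oracleCountText <- function(text, synToId) {
  s <- caseolap::normalizeText(text)
  syns <- names(synToId)[order(-nchar(names(synToId)))]
  counts <- integer(0)
  isBoundary <- function(pos) {
    pos < 1 || pos > nchar(s) ||
      !grepl("[[:alnum:]]", substr(s, pos, pos))
  }
  i <- 1
  while (i <= nchar(s)) {
    hit <- FALSE
    for (syn in syns) {
      L <- nchar(syn)
      if (i + L - 1 <= nchar(s) && substr(s, i, i + L - 1) == syn &&
          isBoundary(i - 1) && isBoundary(i + L)) {
        id <- synToId[[syn]]
        counts[id] <- if (is.na(counts[id])) 1L else counts[id] + 1L
        i <- i + L
        hit <- TRUE
        break
      }
    }
    if (!hit) i <- i + 1
  }
  counts[!is.na(counts)]
}

# naive per-document recount of a whole corpus -> long (pmid, uniprot_id, tf)
oracleCountCorpus <- function(docs, lex) {
  synToId <- caseolap::synonymIndex(lex)
  out <- list()
  for (i in seq_len(nrow(docs))) {
    text <- paste(c(docs$title[i], docs$abstract[i],
                    unlist(docs$keywords[[i]])), collapse = " ")
    cnt <- oracleCountText(text, synToId)
    if (length(cnt))
      out[[length(out) + 1]] <- data.frame(
        pmid = docs$pmid[i], uniprot_id = names(cnt), tf = as.integer(cnt),
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(pmid = character(0), uniprot_id = character(0),
                      tf = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# naive CaseOLAP rescore with plain loops from per-document counts
oracleScoreTable <- function(mentions, cells) {
  proteins <- sort(unique(mentions$uniprot_id))
  cellNames <- names(cells)
  tf <- matrix(0, length(proteins), length(cellNames),
               dimnames = list(proteins, cellNames))
  for (p in proteins) for (cn in cellNames) {
    tot <- 0
    for (r in seq_len(nrow(mentions))) {
      if (mentions$uniprot_id[r] == p && mentions$pmid[r] %in% cells[[cn]])
        tot <- tot + mentions$tf[r]
    }
    tf[p, cn] <- tot
  }
  cntP <- colSums(tf)
  rows <- list()
  for (p in proteins) {
    rel <- numeric(length(cellNames))
    for (j in seq_along(cellNames))
      rel[j] <- if (cntP[j] > 0) tf[p, j] / cntP[j] else 0
    if (sum(rel) == 0) next
    for (j in seq_along(cellNames)) {
      if (tf[p, j] == 0) next
      pop <- if (cntP[j] > 0) log(1 + tf[p, j]) / log(1 + cntP[j]) else 0
      dis <- rel[j] / sum(rel)
      rows[[length(rows) + 1]] <- data.frame(
        uniprot_id = p, cell = cellNames[j], integrity = 1,
        popularity = pop, distinctiveness = dis, score = 1 * pop * dis,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$uniprot_id, out$cell), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# double-loop ECDF max-difference KS statistic
oracleKsStat <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  dmax <- 0
  for (t in pts) {
    fa <- sum(a <= t) / length(a)
    fb <- sum(b <= t) / length(b)
    dmax <- max(dmax, abs(fa - fb))
  }
  dmax
}

# exhaustive hypergeometric upper tail by enumerating all C(N, n) draws;
# overlap counts are memoized per (N, K, n) so sweeping k stays cheap
.hyperMemo <- new.env(parent = emptyenv())
oracleHyperTail <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  key <- paste(N, K, n)
  hits <- .hyperMemo[[key]]
  if (is.null(hits)) {
    draws <- utils::combn(N, n)
    marked <- seq_len(K)
    hits <- apply(draws, 2, function(d) sum(d %in% marked))
    .hyperMemo[[key]] <- hits
  }
  mean(hits >= k)
}

# sorted-order type-7 quantile (the textbook linear interpolation)
oracleQuantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
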