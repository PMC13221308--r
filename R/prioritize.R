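# Score-distribution characterization: histograms, steepest-drop cutoffs,
# attribution classes, top-k ranking and multi-domain overlap sets.

#' Histogram of composite scores in a cell
#'
#' Fixed-width bins over (0, max score]; bins are half-open
#' `[edge, edge + width)` except the last, which is closed so the maximum
#' score is counted.
#'
#' @param st a [ScoreTable-class] object.
#' @param cell cell name.
#' @param binWidth bin width on the score axis (default 0.005; composite
#'   scores live in \[0, 1\]).
#' @return list with `cell`, `bin_edges` (length nbins + 1) and `counts`.
#' @export
scoreHistogram <- function(st, cell, binWidth = 0.005) {
  if (!cell %in% cellNames(st)) stop("unknown cell: ", cell, call. = FALSE)
  s <- as.data.frame(st)
  x <- s$score[s$cell == cell]
  if (!length(x)) stop("cell has no scored proteins: ", cell, call. = FALSE)
  nbins <- max(1L, as.integer(ceiling(max(x) / binWidth - 1e-9)))
  edges <- seq(0, by = binWidth, length.out = nbins + 1L)
  idx <- pmin(floor(x / binWidth) + 1L, nbins)
  counts <- tabulate(idx, nbins)
  list(cell = cell, bin_edges = edges, counts = counts)
}

# centered moving average with shrinking windows at the ends
.smoothCounts <- function(counts, window) {
  if (window <= 1L || length(counts) < 2L) return(as.numeric(counts))
  half <- (window - 1L) %/% 2L
  n <- length(counts)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(counts[lo:hi])
  }, numeric(1))
}

#' Detect the per-cell score cutoff at the steepest histogram drop
#'
#' Counts are smoothed by a centered moving average (window 3 by default),
#' forward differences are taken, and the cutoff is placed at the shared
#' edge of the adjacent bin pair with the most negative difference — the
#' score where the number of proteins drops most steeply, so proteins at the
#' drop itself are not called strong. Ties resolve to the smallest score.
#' Distributions whose counts never fall (or with fewer than two bins) are
#' flagged degenerate with cutoff at the maximum score.
#'
#' @param h histogram from [scoreHistogram()].
#' @param smoothWindow centered moving-average window (odd; 1 = none).
#' @return a [CutoffResult-class] object.
#' @export
detectCutoff <- function(h, smoothWindow = 3L) {
  # trailing empty bins beyond the last occupied score carry no signal;
  # trimming them makes detection invariant to padding past the max score
  occ <- which(h$counts > 0)
  if (length(occ) && max(occ) < length(h$counts)) {
    h$counts <- h$counts[seq_len(max(occ))]
    h$bin_edges <- h$bin_edges[seq_len(max(occ) + 1L)]
  }
  edges <- h$bin_edges
  maxScore <- edges[length(edges)]
  if (length(h$counts) < 2L)
    return(new("CutoffResult", cell = h$cell, cutoff = maxScore,
               derivative = numeric(0), degenerate = TRUE))
  sm <- .smoothCounts(h$counts, as.integer(smoothWindow))
  d <- diff(sm)
  if (min(d) >= 0)
    return(new("CutoffResult", cell = h$cell, cutoff = maxScore,
               derivative = d, degenerate = TRUE))
  i <- which.min(d)  # first index at ties -> smallest score
  new("CutoffResult", cell = h$cell, cutoff = edges[i + 1L],
      derivative = d, degenerate = FALSE)
}

#' Cutoffs for every cell of a score table
#'
#' @param st a [ScoreTable-class] object.
#' @param binWidth passed to [scoreHistogram()].
#' @param smoothWindow passed to [detectCutoff()].
#' @return data.frame with columns `cell`, `cutoff`, `degenerate` (one row
#'   per cell with at least one scored protein).
#' @export
detectCutoffs <- function(st, binWidth = 0.005, smoothWindow = 3L) {
  s <- as.data.frame(st)
  cells <- intersect(cellNames(st), unique(s$cell))
  res <- lapply(cells, function(cn) {
    co <- detectCutoff(scoreHistogram(st, cn, binWidth), smoothWindow)
    data.frame(cell = cn, cutoff = co@cutoff, degenerate = co@degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Classify attribution strength against per-cell cutoffs
#'
#' Strong: score above the cell's cutoff. Loose: score below
#' `looseFraction * cutoff`. Moderate: in between (inclusive of both
#' boundaries).
#'
#' @param st a [ScoreTable-class] object.
#' @param cutoffs data.frame from [detectCutoffs()] (or with columns `cell`,
#'   `cutoff`); a cutoff must exist for every cell present in the table.
#' @param looseFraction fraction of the cutoff below which an attribution is
#'   loose (default 0.25; echoed in the output as an attribute).
#' @return the score data.frame with an added `class` column
#'   (strong/moderate/loose); `attr(, "looseFraction")` records the setting.
#' @export
classifyAttributions <- function(st, cutoffs, looseFraction = 0.25) {
  s <- as.data.frame(st)
  miss <- setdiff(unique(s$cell), cutoffs$cell)
  if (length(miss))
    stop("missing cutoff for cell(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cut <- setNames(cutoffs$cutoff, cutoffs$cell)[s$cell]
  s$class <- ifelse(s$score > cut, "strong",
                    ifelse(s$score < looseFraction * cut, "loose",
                           "moderate"))
  attr(s, "looseFraction") <- looseFraction
  s
}

#' Top-k proteins of a cell by composite score
#'
#' Descending by score; ties broken by uniprot id lexicographic order so the
#' ranking is deterministic.
#'
#' @param st a [ScoreTable-class] object.
#' @param cell cell name.
#' @param k number of proteins requested (>= 1). When k exceeds the number
#'   of scored proteins the full ranking is returned with a warning.
#' @return data.frame of the ranked records (columns of the score table).
#' @export
topProteins <- function(st, cell, k) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  s <- as.data.frame(st)
  s <- s[s$cell == cell, , drop = FALSE]
  s <- s[order(-s$score, s$uniprot_id), , drop = FALSE]
  if (k > nrow(s)) {
    warning(sprintf("k = %d exceeds the %d scored protein(s) in %s; %s",
                    k, nrow(s), cell, "returning the full ranking"),
            call. = FALSE)
    k <- nrow(s)
  }
  out <- head(s, k)
  rownames(out) <- NULL
  out
}

#' Exclusive/shared protein counts across cells
#'
#' Membership means a score record exists for the (protein, cell) pair —
#' i.e. the protein is mentioned at least once in the cell — matching the
#' inclusion of single-mention proteins, not strong attribution. For every
#' non-empty subset S of the cells, the region count is the number of
#' proteins scored in exactly the cells of S (a multi-way Venn partition of
#' the union); the pairwise matrix counts proteins shared by each cell pair.
#'
#' @param st a [ScoreTable-class] object.
#' @param cells cells to compare (default: all cells of the table; >= 2).
#' @return list with `regions` (named integer vector; names like
#'   `"A&B"` list the member cells of the region) and `pairwise` (symmetric
#'   matrix; diagonal = per-cell scored protein counts).
#' @export
overlapSets <- function(st, cells = NULL) {
  if (is.null(cells)) cells <- cellNames(st)
  if (length(cells) < 2) stop("need at least two cells", call. = FALSE)
  s <- as.data.frame(st)
  s <- s[s$cell %in% cells, , drop = FALSE]
  members <- lapply(setNames(cells, cells),
                    function(cn) unique(s$uniprot_id[s$cell == cn]))
  prot <- sort(unique(s$uniprot_id))
  memb <- vapply(members, function(m) prot %in% m,
                 logical(length(prot)))
  if (length(prot) == 1) memb <- matrix(memb, nrow = 1,
                                        dimnames = list(prot, cells))
  sig <- apply(memb, 1, function(r) paste(cells[r], collapse = "&"))
  # every non-empty subset, including empty regions
  regions <- integer(0)
  for (sz in seq_along(cells)) {
    combos <- utils::combn(cells, sz, simplify = FALSE)
    for (co in combos) {
      key <- paste(co, collapse = "&")
      regions[key] <- sum(sig == key)
    }
  }
  n <- length(cells)
  pw <- matrix(0L, n, n, dimnames = list(cells, cells))
  for (i in seq_len(n)) for (j in i:n)
    pw[i, j] <- pw[j, i] <- length(intersect(members[[i]], members[[j]]))
  list(regions = regions, pairwise = pw)
}
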