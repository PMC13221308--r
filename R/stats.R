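# Cross-domain statistics over composite scores: OLS regression between
# cells, distribution summaries, and complete-linkage clustering of
# proteins as score vectors.

#' Regression of composite scores between two cells
#'
#' Ordinary least squares of the y-cell scores on the x-cell scores over the
#' proteins scored in BOTH cells, with the Pearson correlation and its
#' two-sided p-value from the t distribution on n - 2 degrees of freedom.
#' Zero-variance input yields a degenerate fit reported with r = 0.
#'
#' @param st a [ScoreTable-class] object.
#' @param cellX predictor cell name.
#' @param cellY response cell name.
#' @return list with `slope`, `intercept`, `pearson_r`, `p_value`,
#'   `n_shared`, `degenerate`.
#' @export
crossDomainRegression <- function(st, cellX, cellY) {
  s <- as.data.frame(st)
  x <- s[s$cell == cellX, c("uniprot_id", "score")]
  y <- s[s$cell == cellY, c("uniprot_id", "score")]
  m <- merge(x, y, by = "uniprot_id", suffixes = c("_x", "_y"))
  if (nrow(m) < 2)
    stop("fewer than 2 proteins scored in both cells", call. = FALSE)
  xv <- m$score_x; yv <- m$score_y
  if (var(xv) == 0 || var(yv) == 0) {
    slope <- if (var(xv) == 0) NA_real_ else 0
    intercept <- if (var(xv) == 0) NA_real_ else mean(yv)
    return(list(slope = slope, intercept = intercept, pearson_r = 0,
                p_value = NA_real_, n_shared = nrow(m), degenerate = TRUE))
  }
  fit <- lm(yv ~ xv)
  ct <- cor.test(xv, yv, method = "pearson", alternative = "two.sided")
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       pearson_r = unname(ct$estimate), p_value = ct$p.value,
       n_shared = nrow(m), degenerate = FALSE)
}

#' Distribution summary of a cell's composite scores
#'
#' @param st a [ScoreTable-class] object.
#' @param cell cell name (must have at least one scored protein).
#' @return list with `mean`, `median`, `q1`, `q3`, `min`, `max`, `n`.
#' @export
summarizeScores <- function(st, cell) {
  s <- as.data.frame(st)
  x <- s$score[s$cell == cell]
  if (!length(x)) stop("cell has no scored proteins: ", cell, call. = FALSE)
  q <- unname(quantile(x, c(0.25, 0.75)))
  list(mean = mean(x), median = median(x), q1 = q[1], q3 = q[2],
       min = min(x), max = max(x), n = length(x))
}

#' Score-vector matrix of proteins over cells
#'
#' Each protein becomes a vector of its composite scores over the requested
#' cells; an unscored coordinate is 0 (no literature attribution, not
#' missing-at-random).
#'
#' @param st a [ScoreTable-class] object.
#' @param cells cells to use as coordinates (default: all).
#' @return numeric matrix, proteins x cells.
#' @export
scoreMatrix <- function(st, cells = NULL) {
  if (is.null(cells)) cells <- cellNames(st)
  s <- as.data.frame(st)
  s <- s[s$cell %in% cells, , drop = FALSE]
  prot <- sort(unique(s$uniprot_id))
  m <- matrix(0, length(prot), length(cells),
              dimnames = list(prot, cells))
  m[cbind(match(s$uniprot_id, prot), match(s$cell, cells))] <- s$score
  m
}

#' Complete-linkage clustering of proteins as score vectors
#'
#' Proteins are embedded as vectors of per-cell composite scores (unscored
#' coordinates 0). Under the default `"zscore"` normalization each dimension
#' is standardized to zero mean / unit variance across proteins before
#' Euclidean distances are taken ("normalized Euclidean"); the alternative
#' `"unitnorm"` divides each protein vector by its Euclidean norm instead.
#' Agglomeration is complete linkage ([stats::hclust]), whose merge heights
#' are non-decreasing; tie handling is deterministic.
#'
#' @param st a [ScoreTable-class] object with >= 2 scored proteins.
#' @param cells cells to use as coordinates (default: all).
#' @param standardize `"zscore"` (default) or `"unitnorm"`.
#' @return a [ClusterTree-class] object.
#' @export
clusterProteins <- function(st, cells = NULL,
                            standardize = c("zscore", "unitnorm")) {
  standardize <- match.arg(standardize)
  m <- scoreMatrix(st, cells)
  if (nrow(m) < 2) stop("need at least 2 scored proteins", call. = FALSE)
  if (standardize == "zscore") {
    sds <- apply(m, 2, sd)
    mu <- colMeans(m)
    m <- sweep(m, 2, mu, "-")
    nz <- sds > 0
    m[, nz] <- sweep(m[, nz, drop = FALSE], 2, sds[nz], "/")
    m[, !nz] <- 0  # constant dimension carries no distance
  } else {
    nrm <- sqrt(rowSums(m^2))
    nz <- nrm > 0
    m[nz, ] <- m[nz, , drop = FALSE] / nrm[nz]
  }
  hc <- hclust(dist(m, method = "euclidean"), method = "complete")
  new("ClusterTree", hc = hc, cells = colnames(m),
      standardize = standardize)
}

#' Serialize a cluster tree
#'
#' Writes the merge sequence as a linkage-matrix TSV (columns `merge1`,
#' `merge2`, `height`; negative indices are leaves, positive indices earlier
#' merges, the [stats::hclust] convention) and, optionally, the dendrogram
#' as Newick.
#'
#' @param ct a [ClusterTree-class] object.
#' @param linkagePath output TSV path for the linkage matrix (or NULL).
#' @param newickPath output Newick path (or NULL).
#' @return invisibly, a list of the paths written.
#' @export
writeClusterTree <- function(ct, linkagePath = NULL, newickPath = NULL) {
  hc <- ct@hc
  if (!is.null(linkagePath)) {
    link <- data.frame(merge1 = hc$merge[, 1], merge2 = hc$merge[, 2],
                       height = hc$height)
    write.table(link, linkagePath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(newickPath)) {
    phy <- ape::as.phylo(hc)
    ape::write.tree(phy, file = newickPath)
  }
  invisible(list(linkage = linkagePath, newick = newickPath))
}
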