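# Validation stage: KS-based differential ranking of expression tables,
# exact hypergeometric enrichment of list overlaps, and tissue assignment.

#' Two-sample Kolmogorov-Smirnov test
#'
#' Statistic = maximum absolute difference between the two empirical CDFs.
#' The default p-value comes from the asymptotic two-sided Kolmogorov
#' distribution with effective size |a||b|/(|a|+|b|) (standard library
#' behavior even at small n); `exact = TRUE` requests the exact permutation
#' distribution, appropriate when |a|*|b| <= 1e4 and there are no ties.
#'
#' @param a,b numeric sample vectors, each of length >= 2.
#' @param exact logical; exact two-sample p-value instead of asymptotic.
#' @return list with `statistic` (D in \[0, 1\]) and `p_value`.
#' @examples
#' ksTwoSample(c(1, 2, 3), c(4, 5, 6))$statistic  # 1: disjoint supports
#' @export
ksTwoSample <- function(a, b, exact = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 values", call. = FALSE)
  res <- suppressWarnings(ks.test(a, b, exact = exact))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Rank proteins by differential expression between two groups
#'
#' For each protein the group means, their absolute difference, and a
#' two-sample KS test between the groups are computed; missing values are
#' excluded per protein. Proteins are sorted by absolute mean difference
#' (descending), then p-value (ascending), then protein id. Proteins whose
#' values are entirely missing — or leave fewer than two usable values in a
#' group — are excluded with a warning.
#'
#' @param expr numeric matrix, proteins (rows) x samples (columns).
#' @param groups character/factor of length `ncol(expr)` with exactly two
#'   levels; `case` names the level treated as case (default: second level).
#' @param case,control optional explicit level names.
#' @param top optional integer; return only the first `top` records.
#' @param exact passed to [ksTwoSample()].
#' @return data.frame with columns `protein`, `mean_case`, `mean_control`,
#'   `abs_mean_diff`, `ks_stat`, `p_value`, in rank order.
#' @export
differentialRank <- function(expr, groups, case = NULL, control = NULL,
                             top = NULL, exact = FALSE) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required", call. = FALSE)
  if (is.null(case)) case <- lev[2]
  if (is.null(control)) control <- setdiff(lev, case)[1]
  if (!all(c(case, control) %in% lev))
    stop("case/control labels not present in groups", call. = FALSE)
  ci <- which(groups == case); ki <- which(groups == control)
  rows <- vector("list", nrow(expr))
  dropped <- character(0)
  for (i in seq_len(nrow(expr))) {
    p <- rownames(expr)[i]
    a <- expr[i, ci]; a <- a[!is.na(a)]
    b <- expr[i, ki]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) { dropped <- c(dropped, p); next }
    ks <- ksTwoSample(a, b, exact = exact)
    rows[[i]] <- data.frame(protein = p, mean_case = mean(a),
                            mean_control = mean(b),
                            abs_mean_diff = abs(mean(a) - mean(b)),
                            ks_stat = ks$statistic, p_value = ks$p_value,
                            stringsAsFactors = FALSE)
  }
  if (length(dropped))
    warning(sprintf("%d protein(s) excluded for insufficient values: %s",
                    length(dropped),
                    paste(head(dropped, 5), collapse = ", ")),
            call. = FALSE)
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- out[order(-out$abs_mean_diff, out$p_value, out$protein), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top)) out <- head(out, top)
  out
}

#' Exact hypergeometric enrichment of an observed overlap
#'
#' Tests whether the overlap k between a size-K protein list and a size-n
#' dataset, drawn from a background of N proteins, exceeds chance. The
#' p-value is the exact upper tail P(X >= k) of the hypergeometric null
#' (the standard over-representation convention); expected overlap is
#' n*K/N and the enrichment factor k/expected.
#'
#' @param N background size (e.g. the full dictionary).
#' @param K literature list size (e.g. top-k CaseOLAP proteins).
#' @param n dataset size (e.g. proteins quantified in the biopsy set).
#' @param k observed overlap.
#' @return list with `N`, `K`, `n`, `k`, `expected`, `enrichment`,
#'   `p_value`.
#' @examples
#' hypergeomEnrichment(10, 3, 4, 2)$p_value  # exactly 1/3
#' @export
hypergeomEnrichment <- function(N, K, n, k) {
  if (K > N || n > N || k > min(K, n) || k < max(0, K + n - N))
    stop("infeasible hypergeometric counts", call. = FALSE)
  expected <- n * K / N
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(N = N, K = K, n = n, k = k, expected = expected,
       enrichment = if (expected > 0) k / expected else NA_real_,
       p_value = p)
}

#' Assign proteins to their tissue of maximal expression
#'
#' Each query protein is assigned to the tissue where its expression value
#' is highest; ties resolve to the alphabetically first tissue name with a
#' warning. Proteins absent from the table are counted in a
#' `"not detected"` bucket, so tissue counts plus that bucket always equal
#' the number of query proteins.
#'
#' @param tissueTable long-format data.frame with columns `protein`,
#'   `tissue`, `value` (Human Protein Atlas style, e.g. nTPM).
#' @param proteins character vector of query protein ids.
#' @return list with `assignments` (data.frame `protein`, `tissue`) and
#'   `counts` (named integer vector by tissue, including `"not detected"`).
#' @export
tissueMaxAssignment <- function(tissueTable, proteins) {
  need <- c("protein", "tissue", "value")
  if (!all(need %in% names(tissueTable)) || nrow(tissueTable) == 0)
    stop("tissue table must be non-empty with columns protein, tissue, value",
         call. = FALSE)
  assigned <- character(length(proteins))
  ties <- character(0)
  for (i in seq_along(proteins)) {
    rows <- tissueTable[tissueTable$protein == proteins[i], , drop = FALSE]
    if (!nrow(rows)) { assigned[i] <- "not detected"; next }
    best <- rows$tissue[rows$value == max(rows$value)]
    if (length(best) > 1) {
      ties <- c(ties, proteins[i])
      best <- sort(best)[1]
    }
    assigned[i] <- best
  }
  if (length(ties))
    warning(sprintf("tissue tie(s) broken alphabetically for: %s",
                    paste(head(ties, 5), collapse = ", ")), call. = FALSE)
  counts <- table(factor(assigned,
                         levels = unique(c(sort(unique(
                           tissueTable$tissue[tissueTable$protein %in%
                                                proteins])),
                           unique(assigned)))))
  list(assignments = data.frame(protein = proteins, tissue = assigned,
                                stringsAsFactors = FALSE),
       counts = setNames(as.integer(counts), names(counts)))
}

#' Read an expression table and its group labels
#'
#' @param valuesPath wide TSV: first column `protein`, remaining columns one
#'   per sample.
#' @param groupsPath two-column TSV `sample`, `group`.
#' @return list with `expr` (numeric matrix proteins x samples) and
#'   `groups` (named character vector by sample).
#' @export
readExpressionTable <- function(valuesPath, groupsPath) {
  tab <- read.delim(valuesPath, stringsAsFactors = FALSE, check.names = FALSE)
  expr <- as.matrix(tab[, -1, drop = FALSE])
  rownames(expr) <- tab[[1]]
  g <- read.delim(groupsPath, stringsAsFactors = FALSE)
  groups <- setNames(as.character(g$group), g$sample)
  if (!all(colnames(expr) %in% names(groups)))
    stop("every sample column needs a group label", call. = FALSE)
  list(expr = expr, groups = unname(groups[colnames(expr)]))
}

#' Write an expression table and group labels
#' @param expr numeric matrix proteins x samples.
#' @param groups character vector of group labels per column.
#' @param valuesPath,groupsPath output TSV paths.
#' @return invisibly, the paths.
#' @export
writeExpressionTable <- function(expr, groups, valuesPath, groupsPath) {
  tab <- data.frame(protein = rownames(expr), expr, check.names = FALSE)
  write.table(tab, valuesPath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = colnames(expr), group = groups),
              groupsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(valuesPath, groupsPath))
}

#' Read a long-format tissue expression table
#' @param path TSV with columns `protein`, `tissue`, `value`.
#' @return data.frame.
#' @export
readTissueTable <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write a long-format tissue expression table
#' @param tissueTable data.frame with columns `protein`, `tissue`, `value`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeTissueTable <- function(tissueTable, path) {
  write.table(tissueTable, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
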