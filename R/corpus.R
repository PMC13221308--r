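# Corpus construction: MEDLINE/PubMed XML parsing, deduplication, and
# assignment of documents to domain cells by MeSH descriptor-tree descent.

#' Read a MEDLINE/PubMed article-set XML file
#'
#' Parses a `PubmedArticleSet` document into a document table. Each
#' `PubmedArticle` yields one row; a missing abstract or keyword list yields
#' empty fields. MeSH headings are captured by descriptor identifier (the
#' `UI` attribute of `DescriptorName`); qualifiers are ignored. Publication
#' dates are parsed leniently (year-only allowed) and carried but unused by
#' scoring.
#'
#' @param path path to an article-set XML file (or a literal XML string).
#' @return data.frame with columns `pmid`, `title`, `abstract`,
#'   `keywords` (list column), `mesh_ids` (list column), `date` (character,
#'   `NA` when absent). Articles lacking a PMID are skipped with a warning.
#' @examples
#' xml <- paste0(
#'   "<PubmedArticleSet><PubmedArticle><MedlineCitation>",
#'   "<PMID>1</PMID><Article><ArticleTitle>BNP in heart failure",
#'   "</ArticleTitle></Article></MedlineCitation></PubmedArticle>",
#'   "</PubmedArticleSet>")
#' readMedlineXml(xml)
#' @export
readMedlineXml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
    error = function(e) stop("malformed article-set XML: ",
                             conditionMessage(e), call. = FALSE))
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  rows <- vector("list", length(arts))
  skipped <- 0L
  for (i in seq_along(arts)) {
    a <- arts[[i]]
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//MedlineCitation/PMID"))
    if (is.na(pmid) || !nzchar(pmid)) { skipped <- skipped + 1L; next }
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle"))
    abstract <- paste(
      xml2::xml_text(xml2::xml_find_all(a, ".//Abstract/AbstractText")),
      collapse = " ")
    kw <- xml2::xml_text(xml2::xml_find_all(a, ".//KeywordList/Keyword"))
    mesh <- xml2::xml_attr(
      xml2::xml_find_all(a, ".//MeshHeadingList/MeshHeading/DescriptorName"),
      "UI")
    mesh <- mesh[!is.na(mesh)]
    rows[[i]] <- list(pmid = pmid,
                      title = if (is.na(title)) "" else title,
                      abstract = abstract,
                      keywords = kw, mesh_ids = mesh,
                      date = .parseLenientDate(a))
  }
  if (skipped > 0L)
    warning(sprintf("%d article(s) lacked a PMID and were skipped", skipped),
            call. = FALSE)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  data.frame(
    pmid = vapply(rows, `[[`, character(1), "pmid"),
    title = vapply(rows, `[[`, character(1), "title"),
    abstract = vapply(rows, `[[`, character(1), "abstract"),
    keywords = I(lapply(rows, `[[`, "keywords")),
    mesh_ids = I(lapply(rows, `[[`, "mesh_ids")),
    date = vapply(rows, `[[`, character(1), "date"),
    stringsAsFactors = FALSE)
}

# Year[-Month[-Day]] from PubDate or DateCompleted; NA when absent.
.parseLenientDate <- function(article) {
  for (xp in c(".//Article/Journal/JournalIssue/PubDate",
               ".//DateCompleted")) {
    node <- xml2::xml_find_first(article, xp)
    if (inherits(node, "xml_node")) {
      y <- xml2::xml_text(xml2::xml_find_first(node, "./Year"))
      if (!is.na(y) && nzchar(y)) {
        m <- xml2::xml_text(xml2::xml_find_first(node, "./Month"))
        d <- xml2::xml_text(xml2::xml_find_first(node, "./Day"))
        return(paste(c(y, m[!is.na(m)], d[!is.na(d)]), collapse = "-"))
      }
    }
  }
  NA_character_
}

#' Write a document table as MEDLINE/PubMed article-set XML
#'
#' Emits the same `PubmedArticleSet` dialect [readMedlineXml()] consumes, so
#' synthetic corpora round-trip through the real reader.
#'
#' @param docs document data.frame as returned by [readMedlineXml()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMedlineXml <- function(docs, path) {
  root <- xml2::read_xml("<PubmedArticleSet/>")
  for (i in seq_len(nrow(docs))) {
    art <- xml2::xml_add_child(root, "PubmedArticle")
    cit <- xml2::xml_add_child(art, "MedlineCitation")
    xml2::xml_add_child(cit, "PMID", docs$pmid[i])
    a <- xml2::xml_add_child(cit, "Article")
    xml2::xml_add_child(a, "ArticleTitle", docs$title[i])
    if (nzchar(docs$abstract[i])) {
      ab <- xml2::xml_add_child(a, "Abstract")
      xml2::xml_add_child(ab, "AbstractText", docs$abstract[i])
    }
    if (!is.na(docs$date[i])) {
      parts <- strsplit(docs$date[i], "-", fixed = TRUE)[[1]]
      pd <- xml2::xml_add_child(
        xml2::xml_add_child(xml2::xml_add_child(a, "Journal"),
                            "JournalIssue"), "PubDate")
      xml2::xml_add_child(pd, "Year", parts[1])
      if (length(parts) > 1) xml2::xml_add_child(pd, "Month", parts[2])
      if (length(parts) > 2) xml2::xml_add_child(pd, "Day", parts[3])
    }
    mesh <- docs$mesh_ids[[i]]
    if (length(mesh)) {
      ml <- xml2::xml_add_child(cit, "MeshHeadingList")
      for (m in mesh) {
        dn <- xml2::xml_add_child(xml2::xml_add_child(ml, "MeshHeading"),
                                  "DescriptorName", m)
        xml2::xml_set_attr(dn, "UI", m)
      }
    }
    kw <- docs$keywords[[i]]
    if (length(kw)) {
      kl <- xml2::xml_add_child(cit, "KeywordList")
      for (k in kw) xml2::xml_add_child(kl, "Keyword", k)
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Read a MeSH descriptor table
#'
#' @param path TSV with columns `descriptor_id`, `name`, `tree_numbers`
#'   (semicolon-separated dotted codes).
#' @return a [MeshTree-class] object.
#' @export
readMeshTree <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("descriptor_id", "name", "tree_numbers")
  if (!all(need %in% names(tab)))
    stop("MeSH table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tn <- strsplit(tab$tree_numbers, ";", fixed = TRUE)
  tn <- lapply(tn, function(x) trimws(x[nzchar(trimws(x))]))
  names(tn) <- tab$descriptor_id
  new("MeshTree",
      entries = data.frame(descriptor_id = tab$descriptor_id,
                           name = tab$name, stringsAsFactors = FALSE),
      treeNumbers = tn)
}

#' Write a MeSH descriptor table
#' @param tree a [MeshTree-class] object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeMeshTree <- function(tree, path) {
  tab <- meshEntries(tree)
  tab$tree_numbers <- vapply(treeNumbers(tree)[tab$descriptor_id],
                             paste, character(1), collapse = ";")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a domain configuration
#'
#' Maps each domain name to the root MeSH descriptor ids whose subtrees
#' define the domain's document cell.
#'
#' @param path YAML file: `domain_name: [descriptor_id, ...]`.
#' @return named list of character vectors of root descriptor ids.
#' @export
readDomainConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!length(cfg) || is.null(names(cfg)) || anyDuplicated(names(cfg)))
    stop("domain config must map unique domain names to root descriptors",
         call. = FALSE)
  lapply(cfg, function(x) {
    x <- as.character(unlist(x))
    if (!length(x)) stop("domain with no root descriptors", call. = FALSE)
    x
  })
}

#' Write a domain configuration
#' @param domains named list of character vectors of root descriptor ids.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
writeDomainConfig <- function(domains, path) {
  yaml::write_yaml(lapply(domains, as.list), path)
  invisible(path)
}

#' Remove duplicate documents by PMID
#'
#' Keeps the first occurrence of each pmid in input order (deterministic and
#' order-auditable); the number of removed duplicates is reported via a
#' message. Idempotent.
#'
#' @param docs document data.frame.
#' @return the deduplicated data.frame, input order preserved.
#' @export
deduplicateDocuments <- function(docs) {
  dup <- duplicated(docs$pmid)
  if (any(dup))
    message(sprintf("deduplicate: removed %d duplicate record(s)", sum(dup)))
  docs[!dup, , drop = FALSE]
}

# TRUE where any tree number in `trees` equals or extends (at a dot
# boundary) any root tree number. "C14.280" matches "C14.280.434" but not
# "C14.2801" -- MeSH tree semantics.
.descendsFrom <- function(trees, rootTrees) {
  for (r in rootTrees) {
    if (any(trees == r | startsWith(trees, paste0(r, ".")))) return(TRUE)
  }
  FALSE
}

#' Assign documents to domain cells via MeSH descriptor-tree descent
#'
#' A document belongs to a domain cell iff one of its MeSH descriptors sits
#' at, or anywhere below, one of the domain's root descriptors in the MeSH
#' hierarchy (tree-number prefix at a dot boundary). Documents matching
#' several domains appear in each cell; documents with no MeSH descriptors
#' belong to no cell but remain in the corpus. Only MeSH descriptors are
#' used; keywords play no part.
#'
#' @param docs document data.frame (see [readMedlineXml()]).
#' @param tree a [MeshTree-class] object covering every root descriptor.
#' @param domains named list of character vectors of root descriptor ids.
#' @return a [TextCube-class] with one cell per domain.
#' @export
assignDomains <- function(docs, tree, domains) {
  tn <- treeNumbers(tree)
  missing <- setdiff(unique(unlist(domains, use.names = FALSE)), names(tn))
  if (length(missing))
    stop("root descriptor id(s) absent from MeSH tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  # per domain, precompute the full descendant descriptor-id set
  cells <- lapply(domains, function(roots) {
    rootTrees <- unlist(tn[roots], use.names = FALSE)
    hit <- vapply(tn, .descendsFrom, logical(1), rootTrees = rootTrees)
    descSet <- names(tn)[hit]
    inCell <- vapply(docs$mesh_ids, function(m) any(m %in% descSet),
                     logical(1))
    docs$pmid[inCell]
  })
  new("TextCube", documents = docs, cells = cells, domains = domains)
}

#' Shared-document count matrix across cells
#'
#' @param cube a [TextCube-class], or a named list of pmid character vectors.
#' @return symmetric integer matrix; diagonal = cell sizes, entry (i, j) the
#'   number of documents shared by cells i and j.
#' @export
sharedDocumentMatrix <- function(cube) {
  cells <- if (is(cube, "TextCube")) cellMembers(cube) else cube
  if (!length(cells)) stop("need at least one cell", call. = FALSE)
  n <- length(cells)
  m <- matrix(0L, n, n, dimnames = list(names(cells), names(cells)))
  for (i in seq_len(n)) for (j in i:n) {
    m[i, j] <- m[j, i] <- length(intersect(cells[[i]], cells[[j]]))
  }
  m
}
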