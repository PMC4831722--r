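# PubTator corpus data model and I/O.
#
# A corpus is an ordered list of documents.  Each document holds a title, an
# abstract, a table of entity mentions (character offsets into the string
# `title + " " + abstract`, 0-based, end-exclusive) and a table of
# document-level chemical-disease relations given as MeSH identifier pairs.

SENTINEL_ID <- "unmapped"
PUBTATOR_SENTINEL <- "-1"
COMPOSITE_SEP <- "|"

#' Construct an entity mention table
#'
#' Builds the mention table used inside [pt_document()] objects.  Offsets are
#' 0-based and end-exclusive over the document text (title, one space,
#' abstract).  A mention may normalize to several MeSH identifiers (composite
#' annotations); these are kept as a character vector per mention.  The
#' sentinel `"unmapped"` marks mentions without an identifier.
#'
#' @param start,end Integer character offsets, 0-based, end-exclusive.
#' @param text Surface text of each mention.
#' @param type `"chemical"` or `"disease"`.
#' @param concept_ids A list of character vectors (one per mention), or a
#'   character vector for single-identifier mentions.
#' @return A `data.frame` with columns `start`, `end`, `text`, `type`,
#'   `concept_ids` (list column).
#' @export
mention_table <- function(start = integer(), end = integer(),
                          text = character(), type = character(),
                          concept_ids = list()) {
  if (!is.list(concept_ids)) concept_ids <- as.list(concept_ids)
  n <- length(start)
  stopifnot(length(end) == n, length(text) == n, length(type) == n,
            length(concept_ids) == n)
  if (n > 0) {
    bad <- !(type %in% c("chemical", "disease"))
    if (any(bad)) stop("unknown entity type: ", paste(unique(type[bad]), collapse = ", "))
    if (any(start < 0) || any(end <= start)) {
      stop("mention offsets must satisfy 0 <= start < end")
    }
    if (any(!vapply(concept_ids, length, 1L))) {
      stop("every mention needs at least one concept id (use the sentinel)")
    }
  }
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   text = as.character(text), type = as.character(type),
                   stringsAsFactors = FALSE)
  df$concept_ids <- lapply(concept_ids, as.character)
  df
}

#' Construct a relation table
#'
#' @param chem_id,dis_id Character vectors of MeSH identifiers.
#' @return A `data.frame` with columns `chem_id`, `dis_id`.
#' @export
relation_table <- function(chem_id = character(), dis_id = character()) {
  stopifnot(length(chem_id) == length(dis_id))
  if (any(chem_id == SENTINEL_ID) || any(dis_id == SENTINEL_ID)) {
    stop("relation identifiers must not be the unmapped sentinel")
  }
  data.frame(chem_id = as.character(chem_id), dis_id = as.character(dis_id),
             stringsAsFactors = FALSE)
}

#' Construct a document
#'
#' @param doc_id Non-empty document identifier (PMID-like).
#' @param title,abstract Document text fields.
#' @param mentions A mention table from [mention_table()].
#' @param relations A relation table from [relation_table()].
#' @param validate Check the span invariant (every mention's offsets slice to
#'   its surface text)?  Default `TRUE`.
#' @return An object of class `pt_document`.
#' @export
pt_document <- function(doc_id, title, abstract,
                        mentions = mention_table(),
                        relations = relation_table(),
                        validate = TRUE) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  doc <- structure(list(doc_id = doc_id, title = title, abstract = abstract,
                        mentions = mentions, relations = relations),
                   class = "pt_document")
  if (validate) validate_document(doc)
  doc
}

#' Full document text: title, one space separator, abstract
#' @param doc A `pt_document`.
#' @return A single string; mention offsets index into it.
#' @export
doc_text <- function(doc) paste(doc$title, doc$abstract, sep = " ")

validate_document <- function(doc) {
  txt <- doc_text(doc)
  m <- doc$mentions
  if (nrow(m) > 0) {
    sliced <- substring(txt, m$start + 1L, m$end)
    bad <- which(sliced != m$text)
    if (length(bad)) {
      stop(sprintf(
        "document %s: mention span does not slice to surface text at offsets %s",
        doc$doc_id,
        paste(sprintf("(%d,%d)", m$start[bad], m$end[bad]), collapse = " ")))
    }
  }
  invisible(doc)
}

#' Construct a corpus
#'
#' @param documents A list of `pt_document` objects with unique `doc_id`s.
#' @return An object of class `pt_corpus`.
#' @export
pt_corpus <- function(documents = list()) {
  ids <- vapply(documents, function(d) d$doc_id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate doc_id in corpus: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(list(documents = documents), class = "pt_corpus")
}

#' @export
length.pt_corpus <- function(x) length(x$documents)

#' @export
print.pt_corpus <- function(x, ...) {
  s <- corpus_stats(x)
  cat(sprintf(paste0(
    "<pt_corpus> %d documents | %d chemical / %d disease mentions | ",
    "%d relations\n"),
    s$documents, s$chemical_mentions, s$disease_mentions, s$relations))
  invisible(x)
}

#' @export
print.pt_document <- function(x, ...) {
  cat(sprintf("<pt_document %s> \"%s\" | %d mentions | %d relations\n",
              x$doc_id, x$title, nrow(x$mentions), nrow(x$relations)))
  invisible(x)
}

split_composite <- function(ids) {
  if (!length(ids)) return(character())
  unlist(strsplit(ids, COMPOSITE_SEP, fixed = TRUE))
}

#' Read a PubTator-format corpus
#'
#' Parses the line-oriented PubTator format: per document a `PMID|t|` title
#' line, a `PMID|a|` abstract line, tab-separated mention lines
#' (`PMID start end text Chemical|Disease MeSH`), tab-separated relation
#' lines (`PMID CID chem dis`), and a blank line between documents.  The
#' sentinel identifier `-1` is mapped to `"unmapped"`; composite identifiers
#' (`D001|D002`) become multi-element concept vectors.  Every mention is
#' validated against the span invariant.  Relation identifiers that never
#' occur as mention identifiers are kept with a warning (evaluation is
#' identifier based, not mention based).
#'
#' @param path Path to a PubTator file (UTF-8).
#' @return A [pt_corpus()].
#' @export
read_pubtator <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  docs <- list()
  cur <- NULL    # list(doc_id, title, abstract, mention rows, relation rows)
  flush_doc <- function(cur) {
    if (is.null(cur)) return(NULL)
    if (is.null(cur$title)) stop("document ", cur$doc_id, " has no title line")
    if (is.null(cur$abstract)) cur$abstract <- ""
    men <- cur$mentions
    rel <- cur$relations
    mt <- if (!length(men)) mention_table() else
      mention_table(
        start = vapply(men, function(r) as.integer(r$start), 1L),
        end = vapply(men, function(r) as.integer(r$end), 1L),
        text = vapply(men, function(r) r$text, ""),
        type = vapply(men, function(r) r$type, ""),
        concept_ids = lapply(men, function(r) r$ids))
    rt <- if (!length(rel)) relation_table() else
      relation_table(vapply(rel, `[`, "", 1L), vapply(rel, `[`, "", 2L))
    doc <- pt_document(cur$doc_id, cur$title, cur$abstract, mt, rt)
    mention_ids <- unique(split_composite(unlist(mt$concept_ids)))
    orphan <- setdiff(unique(c(rt$chem_id, rt$dis_id)), mention_ids)
    if (length(orphan)) {
      warning(sprintf("document %s: relation identifier(s) %s not found among mentions (kept)",
                      doc$doc_id, paste(orphan, collapse = ", ")),
              call. = FALSE)
    }
    doc
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (line == "") {
      d <- flush_doc(cur)
      if (!is.null(d)) docs[[length(docs) + 1L]] <- d
      cur <- NULL
      next
    }
    tm <- regmatches(line, regexec("^([^|\t]+)\\|([ta])\\|(.*)$", line))[[1]]
    if (length(tm) == 4L) {
      pmid <- tm[2]
      if (is.null(cur)) cur <- list(doc_id = pmid, mentions = list(), relations = list())
      if (cur$doc_id != pmid) stop("line ", i, ": document id changes without blank line")
      if (tm[3] == "t") cur$title <- tm[4] else cur$abstract <- tm[4]
      next
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (is.null(cur)) stop("line ", i, ": annotation line before any title line")
    if (length(fields) == 4L && fields[2] == "CID") {
      cur$relations[[length(cur$relations) + 1L]] <- fields[c(3, 4)]
    } else if (length(fields) == 6L) {
      type <- tolower(fields[5])
      if (!type %in% c("chemical", "disease")) {
        stop("line ", i, ": unknown entity type '", fields[5], "'")
      }
      if (is.na(suppressWarnings(as.integer(fields[2]))) ||
          is.na(suppressWarnings(as.integer(fields[3])))) {
        stop("line ", i, ": non-numeric mention offsets")
      }
      ids <- split_composite(fields[6])
      ids[ids == PUBTATOR_SENTINEL] <- SENTINEL_ID
      cur$mentions[[length(cur$mentions) + 1L]] <-
        list(start = fields[2], end = fields[3], text = fields[4],
             type = type, ids = ids)
    } else {
      stop("line ", i, ": malformed PubTator line: ", line)
    }
  }
  d <- flush_doc(cur)
  if (!is.null(d)) docs[[length(docs) + 1L]] <- d
  pt_corpus(docs)
}

#' Write a corpus in PubTator format
#'
#' Inverse of [read_pubtator()]: `read_pubtator(write_pubtator(x))` is the
#' identity on valid corpora.  Composite concept identifiers are joined with
#' `|`; the `"unmapped"` sentinel is written as `-1`.
#'
#' @param corpus A [pt_corpus()].
#' @param path Output path.
#' @export
write_pubtator <- function(corpus, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  out <- character()
  for (doc in corpus$documents) {
    out <- c(out,
             paste0(doc$doc_id, "|t|", doc$title),
             paste0(doc$doc_id, "|a|", doc$abstract))
    m <- doc$mentions
    if (nrow(m) > 0) {
      ids <- vapply(m$concept_ids, function(v) {
        v[v == SENTINEL_ID] <- PUBTATOR_SENTINEL
        paste(v, collapse = COMPOSITE_SEP)
      }, "")
      out <- c(out, sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                            doc$doc_id, m$start, m$end, m$text,
                            ifelse(m$type == "chemical", "Chemical", "Disease"),
                            ids))
    }
    r <- doc$relations
    if (nrow(r) > 0) {
      out <- c(out, sprintf("%s\tCID\t%s\t%s", doc$doc_id, r$chem_id, r$dis_id))
    }
    out <- c(out, "")
  }
  writeLines(out, con, useBytes = TRUE)
  invisible(NULL)
}

#' Summary statistics of a corpus
#'
#' Counts documents, chemical and disease mentions (one per annotation line),
#' unique chemical and disease identifiers (composite identifiers split, the
#' unmapped sentinel dropped) and document-level relations.  Totals are
#' additive over corpus concatenation.
#'
#' @param corpus A [pt_corpus()].
#' @return A list with elements `documents`, `chemical_mentions`,
#'   `disease_mentions`, `unique_chemical_ids`, `unique_disease_ids`,
#'   `relations`.
#' @export
corpus_stats <- function(corpus) {
  n_chem <- 0L; n_dis <- 0L; n_rel <- 0L
  chem_ids <- character(); dis_ids <- character()
  for (doc in corpus$documents) {
    m <- doc$mentions
    is_chem <- m$type == "chemical"
    n_chem <- n_chem + sum(is_chem)
    n_dis <- n_dis + sum(!is_chem)
    ids <- function(sel) {
      v <- split_composite(unlist(m$concept_ids[sel]))
      v[v != SENTINEL_ID]
    }
    chem_ids <- c(chem_ids, ids(is_chem))
    dis_ids <- c(dis_ids, ids(!is_chem))
    n_rel <- n_rel + nrow(doc$relations)
  }
  list(documents = length(corpus$documents),
       chemical_mentions = n_chem,
       disease_mentions = n_dis,
       unique_chemical_ids = length(unique(chem_ids)),
       unique_disease_ids = length(unique(dis_ids)),
       relations = n_rel)
}

#' Subset a corpus by document identifiers
#'
#' @param corpus A [pt_corpus()].
#' @param doc_ids Character vector of document ids to keep (order follows
#'   the corpus, not `doc_ids`).
#' @return A [pt_corpus()].
#' @export
corpus_subset <- function(corpus, doc_ids) {
  keep <- vapply(corpus$documents, function(d) d$doc_id %in% doc_ids, TRUE)
  pt_corpus(corpus$documents[keep])
}

#' Per-document unique entity identifiers
#'
#' Expands composite identifiers and drops the sentinel.  Used by instance
#' generation and the baselines.
#'
#' @param doc A `pt_document`.
#' @param type `"chemical"` or `"disease"`.
#' @return Character vector of unique MeSH identifiers.
#' @export
doc_entity_ids <- function(doc, type) {
  m <- doc$mentions
  v <- split_composite(unlist(m$concept_ids[m$type == type]))
  unique(v[v != SENTINEL_ID])
}
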