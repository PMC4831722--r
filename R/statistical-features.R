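# Document-level statistical features for a chemical-disease identifier pair.

#' Statistical features of an identifier pair in a document
#'
#' Counts of mentions carrying each identifier, the implied number of
#' mention pairs, their ratios against the document totals (all chemical
#' mentions, all disease mentions, all possible chemical-disease mention
#' pairs), minimal sentence and word distances between mentions of the two
#' identifiers, and title flags.  Sentence indices come from the CoNLL-U
#' parses, the title being sentence 0; the word distance is the number of
#' parsed tokens strictly between the closest mention boundaries
#' (overlapping or adjacent mentions give 0).
#'
#' @param doc A `pt_document`.
#' @param parses_doc List of `sentence_parse` with character offsets.
#' @param chem_id,dis_id MeSH identifiers; both must occur in the document.
#' @return A list: `n_chem_mentions`, `n_dis_mentions`, `n_pairs`,
#'   `ratio_chem`, `ratio_dis`, `ratio_pairs`, `min_sentence_dist`,
#'   `min_word_dist`, `chem_in_title`, `dis_in_title`, `both_in_title`,
#'   `chem_id`, `dis_id`.
#' @export
stat_features <- function(doc, parses_doc, chem_id, dis_id) {
  m <- doc$mentions
  has_id <- function(i, id) id %in% split_composite(m$concept_ids[[i]])
  chem <- which(m$type == "chemical" &
                vapply(seq_len(nrow(m)), has_id, TRUE, id = chem_id))
  dis <- which(m$type == "disease" &
               vapply(seq_len(nrow(m)), has_id, TRUE, id = dis_id))
  if (!length(chem) || !length(dis)) {
    stop(sprintf("document %s: identifier %s has no mention", doc$doc_id,
                 if (!length(chem)) chem_id else dis_id))
  }
  tot_chem <- sum(m$type == "chemical")
  tot_dis <- sum(m$type == "disease")
  n_c <- length(chem); n_d <- length(dis)
  # token/sentence coordinates; token positions are counted document-wide
  tok_index <- token_coordinates(parses_doc)
  coord <- function(i) {
    loc <- locate_mention(parses_doc, m$start[i], m$end[i])
    if (is.null(loc)) return(NULL)
    list(sent = loc$sent,
         first = tok_index[[loc$sent]][loc$first_tok],
         last = tok_index[[loc$sent]][loc$last_tok])
  }
  sdist <- Inf; wdist <- Inf
  for (ci in chem) for (di in dis) {
    a <- coord(ci); b <- coord(di)
    if (is.null(a) || is.null(b)) next
    sdist <- min(sdist, abs(a$sent - b$sent))
    gap <- if (a$first > b$last) a$first - b$last - 1L
           else if (b$first > a$last) b$first - a$last - 1L
           else 0L
    wdist <- min(wdist, gap)
  }
  if (!is.finite(sdist)) sdist <- length(parses_doc)   # unlocatable fallback
  if (!is.finite(wdist)) wdist <- sum(vapply(parses_doc, nrow, 1L))
  title_end <- nchar(doc$title)
  in_title <- function(ix) any(m$start[ix] < title_end)
  list(n_chem_mentions = n_c,
       n_dis_mentions = n_d,
       n_pairs = n_c * n_d,
       ratio_chem = n_c / tot_chem,
       ratio_dis = n_d / tot_dis,
       ratio_pairs = (n_c * n_d) / (tot_chem * tot_dis),
       min_sentence_dist = as.integer(sdist),
       min_word_dist = as.integer(wdist),
       chem_in_title = in_title(chem),
       dis_in_title = in_title(dis),
       both_in_title = in_title(chem) && in_title(dis),
       chem_id = chem_id,
       dis_id = dis_id)
}

# document-wide running token positions: list (per sentence) of integer
# vectors mapping token id -> global token position
token_coordinates <- function(parses_doc) {
  offset <- 0L
  out <- vector("list", length(parses_doc))
  for (i in seq_along(parses_doc)) {
    n <- nrow(parses_doc[[i]])
    out[[i]] <- offset + seq_len(n)
    offset <- offset + n
  }
  out
}
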