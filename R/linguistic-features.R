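# Dependency-tree linguistic features: governing verbs, relating words,
# negation, the representative-pair heuristic, and the per-pair and
# aggregate feature sets.

#' Is a part-of-speech tag a verb tag?
#' @param upos Tag(s): Penn tags starting `VB` or the UPOS tag `VERB`.
#' @param tagset Ignored placeholder for alternative conventions.
#' @return Logical vector.
#' @export
is_verb_tag <- function(upos, tagset = c("penn+upos")) {
  startsWith(upos, "VB") | upos == "VERB"
}

# self-exclusive ancestor chain: head, head-of-head, ..., root (token ids)
head_chain <- function(parse, token_index) {
  heads <- parse$head
  chain <- integer()
  cur <- heads[token_index]
  while (cur != 0L) {
    chain <- c(chain, cur)
    cur <- heads[cur]
  }
  chain
}

#' Governing verb of a token
#'
#' The first verb encountered when the dependency tree is walked from the
#' token towards the root.  The walk starts at the token's head, so a verb
#' is never its own governing verb.
#'
#' @param parse A `sentence_parse`.
#' @param token_index 1-based token id.
#' @return The governing verb's token id, or `NA_integer_` if no verb lies
#'   on the path to the root.
#' @export
governing_verb <- function(parse, token_index) {
  stopifnot(token_index >= 1L, token_index <= nrow(parse))
  for (a in head_chain(parse, token_index)) {
    if (is_verb_tag(parse$upos[a])) return(a)
  }
  NA_integer_
}

#' Relating word of a token pair
#'
#' The first word the two tokens have in common when each walks towards the
#' root, with self-inclusive ancestor sets: if one token dominates the
#' other, the dominating token itself is the relating word.  Undefined
#' (by contract) for tokens of different sentences.
#'
#' @param parse A `sentence_parse` containing both tokens.
#' @param i,j 1-based token ids.
#' @return Token id of the lowest common ancestor (self-inclusive).
#' @export
relating_word <- function(parse, i, j) {
  ai <- c(i, head_chain(parse, i))
  aj <- c(j, head_chain(parse, j))
  hit <- ai[ai %in% aj][1]
  if (is.na(hit)) NA_integer_ else hit
}

#' Is a token negated?
#'
#' True iff some dependent of the token bears a negation dependency label,
#' or is an adverbial modifier whose form is in the negation lexicon.
#'
#' @param parse A `sentence_parse`.
#' @param token_index 1-based token id (NA allowed, gives `FALSE`).
#' @param negation_labels Dependency labels marking negation.
#' @param lexicon Negation words checked on adverbial-modifier dependents.
#' @return Logical scalar.
#' @export
is_negated <- function(parse, token_index,
                       negation_labels = c("neg"),
                       lexicon = c("not", "no", "never", "without")) {
  if (is.na(token_index)) return(FALSE)
  deps <- which(parse$head == token_index)
  any(parse$deprel[deps] %in% negation_labels) ||
    any(parse$deprel[deps] %in% c("advmod") &
        tolower(parse$form[deps]) %in% lexicon)
}

# Locate a mention in the document parses.  Returns list(sent = sentence
# list-index (1-based; sentence 0 of the document is index 1), tok = id of
# the mention's syntactic head token, first_tok, last_tok), or NULL if the
# mention overlaps no parsed token.
locate_mention <- function(parses_doc, start, end) {
  for (s_ix in seq_along(parses_doc)) {
    p <- parses_doc[[s_ix]]
    ids <- which(!is.na(p$start) & p$start < end & start < p$end)
    if (!length(ids)) next
    head_tok <- ids[!(p$head[ids] %in% p$id[ids])]
    if (!length(head_tok)) head_tok <- ids[1]
    return(list(sent = s_ix, tok = head_tok[1],
                first_tok = min(ids), last_tok = max(ids)))
  }
  NULL
}

# strict descendant test: is token d a descendant of token a?
is_descendant <- function(parse, d, a) a %in% head_chain(parse, d)

# all located mention pairs (chemical x disease, any identifiers) of a
# document; rows: c_start, c_end, d_start, d_end, c_sent, d_sent, c_tok, d_tok
all_pair_locations <- function(doc, parses_doc) {
  m <- doc$mentions
  chem <- which(m$type == "chemical")
  dis <- which(m$type == "disease")
  out <- list()
  locs <- lapply(seq_len(nrow(m)), function(i)
    locate_mention(parses_doc, m$start[i], m$end[i]))
  for (ci in chem) for (di in dis) {
    lc <- locs[[ci]]; ld <- locs[[di]]
    if (is.null(lc) || is.null(ld)) next
    out[[length(out) + 1L]] <- list(
      chem_row = ci, dis_row = di, chem_loc = lc, dis_loc = ld)
  }
  out
}

#' Select the representative mention pair for an identifier pair
#'
#' Ranks all (chemical mention, disease mention) combinations of the two
#' identifiers: (1) same-sentence pairs precede cross-sentence pairs;
#' (2) among same-sentence pairs, those under which no other chemical-disease
#' mention pair sits lower in the parse tree (no other pair's relating word
#' is a strict descendant of this pair's relating word) precede the rest;
#' remaining ties break by earliest chemical then disease document position.
#' If only cross-sentence pairs exist, the last pair (by document position)
#' with the chemical before the disease is chosen; failing that, the first
#' chemical and first disease mentions.
#'
#' @param doc A `pt_document` with mentions.
#' @param parses_doc List of `sentence_parse` for the document.
#' @param chem_id,dis_id MeSH identifiers.
#' @return A list with `chem_row`, `dis_row` (mention-table row indices),
#'   `chem_loc`, `dis_loc` (from the internal locator; may be `NULL` when
#'   the mention is outside every parse), and `same_sentence`.
#' @export
select_representative_pair <- function(doc, parses_doc, chem_id, dis_id) {
  m <- doc$mentions
  has_id <- function(i, id) id %in% split_composite(m$concept_ids[[i]])
  chem <- which(m$type == "chemical" &
                vapply(seq_len(nrow(m)), has_id, TRUE, id = chem_id))
  dis <- which(m$type == "disease" &
               vapply(seq_len(nrow(m)), has_id, TRUE, id = dis_id))
  if (!length(chem) || !length(dis)) {
    stop(sprintf("document %s: no mention of %s", doc$doc_id,
                 if (!length(chem)) chem_id else dis_id))
  }
  cand <- list()
  for (ci in chem) for (di in dis) {
    lc <- locate_mention(parses_doc, m$start[ci], m$end[ci])
    ld <- locate_mention(parses_doc, m$start[di], m$end[di])
    cand[[length(cand) + 1L]] <- list(chem_row = ci, dis_row = di,
                                      chem_loc = lc, dis_loc = ld)
  }
  same <- Filter(function(p) !is.null(p$chem_loc) && !is.null(p$dis_loc) &&
                   p$chem_loc$sent == p$dis_loc$sent, cand)
  if (length(same)) {
    # pairs with no other chemical-disease pair lower in the parse tree first
    others <- all_pair_locations(doc, parses_doc)
    no_lower <- vapply(same, function(p) {
      parse <- parses_doc[[p$chem_loc$sent]]
      r <- relating_word(parse, p$chem_loc$tok, p$dis_loc$tok)
      !any(vapply(others, function(q) {
        if (q$chem_row == p$chem_row && q$dis_row == p$dis_row) return(FALSE)
        if (q$chem_loc$sent != p$chem_loc$sent ||
            q$dis_loc$sent != p$chem_loc$sent) return(FALSE)
        rq <- relating_word(parse, q$chem_loc$tok, q$dis_loc$tok)
        !is.na(rq) && !is.na(r) && rq != r && is_descendant(parse, rq, r)
      }, TRUE))
    }, TRUE)
    pool <- if (any(no_lower)) same[no_lower] else same
    ord <- order(vapply(pool, function(p) m$start[p$chem_row], 1L),
                 vapply(pool, function(p) m$start[p$dis_row], 1L))
    p <- pool[[ord[1]]]
    p$same_sentence <- TRUE
    return(p)
  }
  fwd <- Filter(function(p) m$start[p$chem_row] < m$start[p$dis_row], cand)
  if (length(fwd)) {
    ord <- order(vapply(fwd, function(p) m$start[p$chem_row], 1L),
                 vapply(fwd, function(p) m$start[p$dis_row], 1L))
    p <- fwd[[ord[length(ord)]]]
  } else {
    p <- list(chem_row = chem[which.min(m$start[chem])],
              dis_row = dis[which.min(m$start[dis])])
    p$chem_loc <- locate_mention(parses_doc, m$start[p$chem_row], m$end[p$chem_row])
    p$dis_loc <- locate_mention(parses_doc, m$start[p$dis_row], m$end[p$dis_row])
  }
  p$same_sentence <- FALSE
  p
}

#' Per-pair linguistic features
#'
#' Features of the representative mention pair: the governing verbs of the
#' chemical and the disease, the relating word and its governing verb (both
#' undefined for cross-sentence pairs), mention order, whether another
#' chemical-disease pair sits lower in the parse tree, negation of the four
#' anchor words, and the three identity features comparing token positions
#' (chemical vs relating word; disease's governing verb vs relating word;
#' both governing verbs vs relating word).
#'
#' @param doc A `pt_document`.
#' @param parses_doc List of `sentence_parse` for the document.
#' @param chem_id,dis_id MeSH identifiers.
#' @param negation_lexicon Words counting as negators on adverbial modifiers.
#' @return A list of 13 features (words as strings or `NA_character_`,
#'   booleans as logicals).
#' @export
pair_linguistic_features <- function(doc, parses_doc, chem_id, dis_id,
                                     negation_lexicon = c("not", "no", "never", "without")) {
  p <- select_representative_pair(doc, parses_doc, chem_id, dis_id)
  m <- doc$mentions
  word <- function(parse, ix) if (is.null(parse) || is.na(ix)) NA_character_
                              else tolower(parse$form[ix])
  cp <- if (!is.null(p$chem_loc)) parses_doc[[p$chem_loc$sent]] else NULL
  dp <- if (!is.null(p$dis_loc)) parses_doc[[p$dis_loc$sent]] else NULL
  gv_c <- if (!is.null(cp)) governing_verb(cp, p$chem_loc$tok) else NA_integer_
  gv_d <- if (!is.null(dp)) governing_verb(dp, p$dis_loc$tok) else NA_integer_
  if (isTRUE(p$same_sentence)) {
    rel <- relating_word(cp, p$chem_loc$tok, p$dis_loc$tok)
    gv_r <- if (!is.na(rel)) governing_verb(cp, rel) else NA_integer_
  } else {
    rel <- NA_integer_; gv_r <- NA_integer_
  }
  neg <- function(parse, ix) !is.null(parse) && !is.na(ix) &&
    is_negated(parse, ix, lexicon = negation_lexicon)
  # another chemical-disease pair lower in the tree than this pair?
  other_lower <- FALSE
  if (isTRUE(p$same_sentence) && !is.na(rel)) {
    others <- all_pair_locations(doc, parses_doc)
    other_lower <- any(vapply(others, function(q) {
      if (q$chem_row == p$chem_row && q$dis_row == p$dis_row) return(FALSE)
      if (q$chem_loc$sent != p$chem_loc$sent ||
          q$dis_loc$sent != p$chem_loc$sent) return(FALSE)
      rq <- relating_word(cp, q$chem_loc$tok, q$dis_loc$tok)
      !is.na(rq) && rq != rel && is_descendant(cp, rq, rel)
    }, TRUE))
  }
  list(
    gov_verb_chem = word(cp, gv_c),
    gov_verb_dis = word(dp, gv_d),
    relating_word = word(cp, rel),
    gov_verb_relating = word(cp, gv_r),
    chem_before_dis = m$start[p$chem_row] < m$start[p$dis_row],
    other_pair_lower = other_lower,
    neg_relating = isTRUE(p$same_sentence) && neg(cp, rel),
    neg_gov_chem = neg(cp, gv_c),
    neg_gov_dis = neg(dp, gv_d),
    neg_gov_relating = isTRUE(p$same_sentence) && neg(cp, gv_r),
    chem_is_relating = isTRUE(p$same_sentence) && !is.na(rel) &&
      !is.null(p$chem_loc) && p$chem_loc$tok == rel,
    govdis_is_relating = isTRUE(p$same_sentence) && !is.na(rel) &&
      !is.na(gv_d) && gv_d == rel,
    both_gov_are_relating = isTRUE(p$same_sentence) && !is.na(rel) &&
      !is.na(gv_c) && !is.na(gv_d) && gv_c == rel && gv_d == rel)
}

#' Aggregate governing-verb / relating-word counts over all mention pairs
#'
#' For every chemical-mention x disease-mention pair of the document,
#' the chemical's governing verb, the disease's governing verb and (for
#' same-sentence pairs) the relating word are determined; occurrences of
#' each vocabulary word are counted, one count per role per pair.
#' Out-of-vocabulary words are ignored.
#'
#' @param doc A `pt_document`.
#' @param parses_doc List of `sentence_parse`.
#' @param vocabulary Character vector fixed at training time (possibly empty).
#' @return Named numeric vector of counts over `vocabulary`.
#' @export
aggregate_linguistic_features <- function(doc, parses_doc, vocabulary) {
  counts <- stats::setNames(numeric(length(vocabulary)), vocabulary)
  for (w in collect_pair_words(doc, parses_doc)) {
    if (w %in% vocabulary) counts[[w]] <- counts[[w]] + 1
  }
  counts
}

# every governing-verb / relating-word occurrence over all mention pairs
collect_pair_words <- function(doc, parses_doc) {
  words <- character()
  for (q in all_pair_locations(doc, parses_doc)) {
    cp <- parses_doc[[q$chem_loc$sent]]
    dp <- parses_doc[[q$dis_loc$sent]]
    gv_c <- governing_verb(cp, q$chem_loc$tok)
    gv_d <- governing_verb(dp, q$dis_loc$tok)
    if (!is.na(gv_c)) words <- c(words, tolower(cp$form[gv_c]))
    if (!is.na(gv_d)) words <- c(words, tolower(dp$form[gv_d]))
    if (q$chem_loc$sent == q$dis_loc$sent) {
      rel <- relating_word(cp, q$chem_loc$tok, q$dis_loc$tok)
      if (!is.na(rel)) words <- c(words, tolower(cp$form[rel]))
    }
  }
  words
}
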