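# Dictionary-based disease recognition and normalization.
#
# The recognizer chain: tokenize -> greedy longest match against a token
# index built from a term dictionary -> abbreviation propagation ->
# adjacent-span merging -> exclusion-list filtering -> MeSH normalization.

#' Tokenize text into lowercased alphanumeric tokens with offsets
#'
#' Splits on any run of non-alphanumeric characters and case-folds.  Digits
#' are retained, so "Q10" survives as a token.  Offsets are 0-based,
#' end-exclusive into the input string.
#'
#' @param text A single string.
#' @return A `data.frame` with columns `token` (lowercased), `start`, `end`.
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) {
    return(data.frame(token = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  m <- gregexpr("[[:alnum:]]+", text)[[1]]
  if (m[1] == -1) {
    return(data.frame(token = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(token = tolower(regmatches(text, list(m))[[1]]),
             start = start, end = start + len, stringsAsFactors = FALSE)
}

#' Normalize a token before matching
#'
#' The builtin `"sstem"` normalizer is an S-stemmer: it conflates plural and
#' singular forms by suffix stripping ("ies" -> "y"; trailing "s" dropped
#' unless the token ends in "ss", "us" or "is").  It is idempotent, so index
#' keys and query tokens normalize identically no matter how often the rule
#' is applied.  `"identity"` disables stemming.
#'
#' @param token A lowercased token (vectorized).
#' @param normalizer `"sstem"` (default) or `"identity"`, or a function
#'   mapping a character vector to a character vector (external adapter).
#' @return Normalized token(s).
#' @export
normalize_token <- function(token, normalizer = "sstem") {
  if (is.function(normalizer)) return(normalizer(token))
  switch(normalizer,
    identity = token,
    sstem = sstem(token),
    stop("unknown normalizer: ", normalizer))
}

sstem <- function(token) {
  token <- tolower(token)
  out <- token
  n <- nchar(token)
  ies <- n > 3 & endsWith(token, "ies")
  out[ies] <- paste0(substr(token[ies], 1, n[ies] - 3L), "y")
  plain <- !ies & n > 2 & endsWith(token, "s") &
    !endsWith(token, "ss") & !endsWith(token, "us") & !endsWith(token, "is")
  out[plain] <- substr(token[plain], 1, n[plain] - 1L)
  out
}

#' Build a term index from dictionary entries
#'
#' Each dictionary term is tokenized, stopwords are removed, the remaining
#' tokens are normalized, and the resulting token sequence becomes an index
#' key mapping to the set of concept identifiers sharing that sequence.
#' Entries that reduce to the empty sequence (all stopwords or punctuation)
#' are dropped with a warning.
#'
#' @param entries A `data.frame` with columns `concept_id`, `term`.
#' @param stopwords Character vector of stopwords (lowercase).
#' @param normalizer Passed to [normalize_token()].
#' @return A `term_index` object (environment keyed by space-joined token
#'   sequences) with attributes `stopwords`, `normalizer`, `max_len`.
#' @export
build_index <- function(entries, stopwords = character(), normalizer = "sstem") {
  stopifnot(is.data.frame(entries), nrow(entries) > 0,
            all(c("concept_id", "term") %in% names(entries)))
  idx <- new.env(parent = emptyenv())
  max_len <- 0L
  dropped <- character()
  for (i in seq_len(nrow(entries))) {
    toks <- tokenize(entries$term[i])$token
    toks <- toks[!(toks %in% stopwords)]
    if (!length(toks)) {
      dropped <- c(dropped, entries$term[i])
      next
    }
    key <- paste(normalize_token(toks, normalizer), collapse = " ")
    idx[[key]] <- union(if (is.null(idx[[key]])) character() else idx[[key]],
                        entries$concept_id[i])
    max_len <- max(max_len, length(toks))
  }
  if (length(dropped)) {
    warning("dropped ", length(dropped),
            " dictionary term(s) that reduce to stopwords only: ",
            paste(utils::head(unique(dropped), 5), collapse = ", "),
            call. = FALSE)
  }
  structure(idx, stopwords = stopwords, normalizer = normalizer,
            max_len = max_len, class = "term_index")
}

#' Greedy leftmost-longest dictionary matching
#'
#' Scans the token sequence left to right, skipping stopword tokens, and at
#' each position takes the longest indexed token sequence; matching resumes
#' after the matched span.  Ties between equal-length candidates cannot arise
#' (the index is keyed by exact sequences), and among positions the earlier
#' start wins, which makes the rule deterministic.
#'
#' @param tokens Token table from [tokenize()] over the same text.
#' @param index A `term_index` from [build_index()].
#' @param skip_text_stopwords Skip stopword tokens inside the document text
#'   as well as in dictionary terms (default `TRUE`)?
#' @return A `data.frame` of concept spans: `start`, `end` (character offsets
#'   covering the matched phrase), `term` (normalized key) and `concept_ids`
#'   (list column).
#' @export
match_longest <- function(tokens, index, skip_text_stopwords = TRUE) {
  stopwords <- attr(index, "stopwords")
  normalizer <- attr(index, "normalizer")
  max_len <- attr(index, "max_len")
  keep <- if (skip_text_stopwords) !(tokens$token %in% stopwords)
          else rep(TRUE, nrow(tokens))
  pos <- which(keep)           # candidate token positions
  norm <- normalize_token(tokens$token, normalizer)
  out <- list()
  j <- 1L
  while (j <= length(pos)) {
    hit_len <- 0L
    for (L in seq.int(min(max_len, length(pos) - j + 1L), 1L)) {
      span <- pos[j:(j + L - 1L)]
      key <- paste(norm[span], collapse = " ")
      ids <- index[[key]]
      if (!is.null(ids)) {
        out[[length(out) + 1L]] <- list(
          start = tokens$start[span[1L]],
          end = tokens$end[span[L]],
          term = key, concept_ids = ids)
        hit_len <- L
        break
      }
    }
    j <- j + max(hit_len, 1L)
  }
  span_table(out)
}

span_table <- function(rows) {
  if (!length(rows)) {
    df <- data.frame(start = integer(), end = integer(), term = character(),
                     stringsAsFactors = FALSE)
    df$concept_ids <- list()
    return(df)
  }
  df <- data.frame(start = vapply(rows, function(r) as.integer(r$start), 1L),
                   end = vapply(rows, function(r) as.integer(r$end), 1L),
                   term = vapply(rows, function(r) r$term, ""),
                   stringsAsFactors = FALSE)
  df$concept_ids <- lapply(rows, function(r) sort(unique(as.character(r$concept_ids))))
  df
}

# Schwartz-Hearst short-form/long-form detection on one text.  Returns a
# data.frame of pairs (short, long, with character offsets).  A candidate
# short form sits in parentheses, is 2-10 characters, at most two words, and
# contains a letter; the long form is sought among at most min(|sf|+5, 2|sf|)
# words before the parenthesis by the right-to-left character alignment of
# the original algorithm.
find_abbreviations <- function(text) {
  out <- list()
  m <- gregexpr("\\(([^()]+)\\)", text)[[1]]
  if (m[1] == -1) return(out)
  starts <- as.integer(m); lens <- attr(m, "match.length")
  for (k in seq_along(starts)) {
    sf <- substr(text, starts[k] + 1L, starts[k] + lens[k] - 2L)
    sf_start <- starts[k]            # 0-based offset of the short form
    if (nchar(sf) < 2 || nchar(sf) > 10) next
    if (lengths(regmatches(sf, gregexpr("[^ ]+", sf))) > 2) next
    if (!grepl("[[:alpha:]]", sf)) next
    if (!grepl("^[[:alnum:]]", sf)) next
    before <- substr(text, 1L, starts[k] - 1L)
    # candidate long-form window: last min(|sf|+5, 2|sf|) words before "("
    wm <- gregexpr("[^ ]+", before)[[1]]
    if (wm[1] == -1) next
    nw <- min(nchar(sf) + 5L, 2L * nchar(sf))
    w_start <- as.integer(wm)
    first_w <- max(1L, length(w_start) - nw + 1L)
    window_start <- w_start[first_w]
    candidate <- sub("[[:space:]]+$", "", substr(before, window_start, nchar(before)))
    lf <- sh_best_long_form(sf, candidate)
    if (is.null(lf)) next
    lf_start0 <- window_start - 1L + (nchar(candidate) - nchar(lf))
    out[[length(out) + 1L]] <- list(
      short = sf, short_start = sf_start, short_end = sf_start + nchar(sf),
      long = lf, long_start = lf_start0, long_end = lf_start0 + nchar(lf))
  }
  out
}

# Right-to-left alignment from the Schwartz & Hearst algorithm: every
# character of the short form must match in order; the first character must
# match at the start of a word.  Returns the shortest valid suffix of the
# candidate, or NULL.
sh_best_long_form <- function(sf, candidate) {
  s <- tolower(sf); c_ <- tolower(candidate)
  si <- nchar(s); ci <- nchar(c_)
  while (si >= 1L) {
    ch <- substr(s, si, si)
    if (!grepl("[[:alnum:]]", ch)) { si <- si - 1L; next }
    while (ci >= 1L &&
           (substr(c_, ci, ci) != ch ||
            (si == 1L && ci > 1L && grepl("[[:alnum:]]", substr(c_, ci - 1L, ci - 1L))))) {
      ci <- ci - 1L
    }
    if (ci < 1L) return(NULL)
    si <- si - 1L; ci <- ci - 1L
  }
  # extend left to the start of the word containing position ci+1
  while (ci >= 1L && grepl("[[:alnum:]]", substr(c_, ci, ci))) ci <- ci - 1L
  lf <- substr(candidate, ci + 1L, nchar(candidate))
  if (!nzchar(trimws(lf))) return(NULL)
  sub("^[[:space:]]+", "", lf)
}

#' Propagate concepts between abbreviations and their long forms
#'
#' Detects abbreviation definitions of the form "long form (SF)" with the
#' Schwartz-Hearst character-alignment pattern.  If either form of a detected
#' pair overlaps a recognized concept span, every occurrence of both forms in
#' the document is tagged with that concept.  When short and long form carry
#' conflicting concepts, the long form wins and a warning is issued.
#'
#' @param text Document text (title + space + abstract).
#' @param spans Concept span table from [match_longest()].
#' @return Augmented span table, sorted by start, duplicates removed.
#' @export
propagate_abbreviations <- function(text, spans) {
  pairs <- find_abbreviations(text)
  if (!length(pairs)) return(spans[order(spans$start, spans$end), , drop = FALSE])
  rows <- lapply(seq_len(nrow(spans)), function(i) as.list(spans[i, , drop = FALSE]))
  rows <- lapply(rows, function(r) {
    r$concept_ids <- r$concept_ids[[1]]; r
  })
  overlap <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1
  for (p in pairs) {
    ids_long <- unique(unlist(lapply(rows, function(r)
      if (overlap(r$start, r$end, p$long_start, p$long_end)) r$concept_ids else NULL)))
    ids_short <- unique(unlist(lapply(rows, function(r)
      if (overlap(r$start, r$end, p$short_start, p$short_end)) r$concept_ids else NULL)))
    ids <- if (length(ids_long)) ids_long else ids_short
    if (length(ids_long) && length(ids_short) && !setequal(ids_long, ids_short)) {
      warning(sprintf("abbreviation '%s'/'%s': conflicting concepts, keeping long form's",
                      p$short, p$long), call. = FALSE)
    }
    if (!length(ids)) next
    for (form in c(p$short, p$long)) {
      occ <- find_word_occurrences(text, form)
      for (o in occ) {
        rows[[length(rows) + 1L]] <- list(
          start = o[1], end = o[2],
          term = paste(normalize_token(tokenize(form)$token), collapse = " "),
          concept_ids = ids)
      }
    }
  }
  df <- span_table(lapply(rows, function(r) {
    r$concept_ids <- list(r$concept_ids); list(start = r$start, end = r$end,
                                               term = r$term,
                                               concept_ids = unlist(r$concept_ids))
  }))
  dedupe_spans(df[order(df$start, df$end), , drop = FALSE])
}

# word-boundary occurrences of a literal form; returns list of c(start0, end0)
find_word_occurrences <- function(text, form) {
  pat <- paste0("(?<![[:alnum:]])", escape_regex(form), "(?![[:alnum:]])")
  m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] == -1) return(list())
  lapply(seq_along(m), function(i)
    c(as.integer(m[i]) - 1L, as.integer(m[i]) - 1L + attr(m, "match.length")[i]))
}

escape_regex <- function(x) gsub("([^[:alnum:]])", "\\\\\\1", x)

# collapse spans with identical (start, end); union their concept sets
dedupe_spans <- function(df) {
  if (nrow(df) < 2) return(df)
  key <- paste(df$start, df$end)
  rows <- lapply(split(seq_len(nrow(df)), key), function(ix) {
    list(start = df$start[ix[1]], end = df$end[ix[1]], term = df$term[ix[1]],
         concept_ids = unique(unlist(df$concept_ids[ix])))
  })
  out <- span_table(rows)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Merge adjacent spans carrying the same concept set
#'
#' Spans with identical concept-identifier sets separated only by whitespace
#' or punctuation are merged into one span.  The rule is applied to a fixed
#' point (a chain of adjacent same-concept spans collapses to a single span).
#'
#' @param text Document text (needed to inspect the gap between spans).
#' @param spans Span table sorted by start.
#' @return Merged span table.
#' @export
merge_adjacent <- function(text, spans) {
  if (nrow(spans) < 2) return(spans)
  spans <- spans[order(spans$start, spans$end), , drop = FALSE]
  rows <- lapply(seq_len(nrow(spans)), function(i)
    list(start = spans$start[i], end = spans$end[i], term = spans$term[i],
         concept_ids = spans$concept_ids[[i]]))
  out <- list(rows[[1]])
  for (r in rows[-1]) {
    last <- out[[length(out)]]
    gap <- if (r$start <= last$end) "" else
      substring(text, last$end + 1L, r$start)
    if (setequal(last$concept_ids, r$concept_ids) &&
        !grepl("[[:alnum:]]", gap)) {
      last$end <- max(last$end, r$end)
      last$term <- paste(last$term, r$term)
      out[[length(out)]] <- last
    } else {
      out[[length(out) + 1L]] <- r
    }
  }
  span_table(out)
}

#' Filter spans through an exclusion list
#'
#' The exclusion list carries, per normalized term, counts of true-positive
#' and false-positive recognitions on an annotated corpus.  A span is removed
#' when its term has `fp > 0` and `tp / fp` is strictly lower than the
#' threshold (default 0.3); a ratio equal to the threshold keeps the span.
#' `ratio_threshold = Inf` removes every listed term with a false positive
#' (the remove-all behaviour); `ratio_threshold = 0` is the identity.
#'
#' @param spans Span table.
#' @param exclusion A `data.frame` with columns `term`, `tp`, `fp`; terms are
#'   normalized token sequences as produced by [match_longest()].
#' @param ratio_threshold Non-negative number, default 0.3.
#' @return Filtered span table.
#' @export
apply_exclusion <- function(spans, exclusion, ratio_threshold = 0.3) {
  stopifnot(ratio_threshold >= 0)
  if (!nrow(spans) || is.null(exclusion) || !nrow(exclusion)) return(spans)
  ix <- match(spans$term, exclusion$term)
  tp <- exclusion$tp[ix]; fp <- exclusion$fp[ix]
  drop <- !is.na(ix) & fp > 0 & (tp / fp) < ratio_threshold
  spans[!drop, , drop = FALSE]
}

#' Map recognized concepts to MeSH identifiers
#'
#' Translates source-vocabulary concept identifiers through a precompiled
#' concept-to-MeSH table.  Concepts absent from the table are either dropped
#' or kept under the `"unmapped"` sentinel.  Spans whose identifier set
#' becomes empty are removed; duplicate MeSH identifiers at one span are
#' collapsed.
#'
#' @param spans Span table.
#' @param mesh_map A `data.frame` with columns `concept_id`, `mesh_id`.
#' @param unmapped `"drop"` (default) or `"sentinel"`.
#' @return Span table with MeSH identifiers in `concept_ids`.
#' @export
normalize_to_mesh <- function(spans, mesh_map, unmapped = c("drop", "sentinel")) {
  unmapped <- match.arg(unmapped)
  if (!nrow(spans)) return(spans)
  lookup <- stats::setNames(mesh_map$mesh_id, mesh_map$concept_id)
  rows <- list()
  for (i in seq_len(nrow(spans))) {
    ids <- spans$concept_ids[[i]]
    mapped <- unname(lookup[ids])
    if (unmapped == "drop") {
      mapped <- mapped[!is.na(mapped)]
    } else {
      mapped[is.na(mapped)] <- SENTINEL_ID
    }
    mapped <- unique(mapped)
    if (!length(mapped)) next
    rows[[length(rows) + 1L]] <- list(start = spans$start[i], end = spans$end[i],
                                      term = spans$term[i], concept_ids = mapped)
  }
  span_table(rows)
}

#' Recognize and normalize disease mentions in a document
#'
#' Runs the full recognition chain on the document text (title + space +
#' abstract): tokenization, greedy longest dictionary match, abbreviation
#' propagation, adjacent-span merging, exclusion filtering and MeSH mapping.
#' Existing disease mentions on the document are replaced; chemical mentions
#' are left untouched.
#'
#' @param doc A `pt_document`.
#' @param index A `term_index`.
#' @param exclusion Exclusion-list `data.frame` (`term`, `tp`, `fp`) or `NULL`.
#' @param mesh_map Concept-to-MeSH `data.frame`.
#' @param config List of options: `ratio_threshold` (default 0.3),
#'   `unmapped` (`"drop"`/`"sentinel"`), `skip_text_stopwords` (default TRUE).
#' @return The document with recognized disease mentions.
#' @export
recognize_diseases <- function(doc, index, exclusion = NULL, mesh_map,
                               config = list()) {
  ratio <- config$ratio_threshold %||% 0.3
  unmapped <- config$unmapped %||% "drop"
  skip <- config$skip_text_stopwords %||% TRUE
  text <- doc_text(doc)
  spans <- match_longest(tokenize(text), index, skip_text_stopwords = skip)
  spans <- propagate_abbreviations(text, spans)
  spans <- merge_adjacent(text, spans)
  spans <- apply_exclusion(spans, exclusion, ratio)
  spans <- normalize_to_mesh(spans, mesh_map, unmapped)
  keep <- doc$mentions[doc$mentions$type == "chemical", , drop = FALSE]
  new_m <- if (nrow(spans)) {
    mention_table(start = spans$start, end = spans$end,
                  text = substring(text, spans$start + 1L, spans$end),
                  type = rep("disease", nrow(spans)),
                  concept_ids = spans$concept_ids)
  } else mention_table()
  all_m <- rbind_mentions(keep, new_m)
  pt_document(doc$doc_id, doc$title, doc$abstract, all_m, doc$relations)
}

rbind_mentions <- function(a, b) {
  out <- rbind(a[, c("start", "end", "text", "type")],
               b[, c("start", "end", "text", "type")])
  out$concept_ids <- c(a$concept_ids, b$concept_ids)
  ord <- order(out$start, out$end)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tally term-level true/false positives against gold mentions
#'
#' Compares recognizer output with gold disease mentions on an annotated
#' corpus and counts, per normalized term, how often a recognized span was
#' correct (offsets and at least one identifier match a gold mention) versus
#' spurious.  The result feeds [apply_exclusion()].
#'
#' @param recognized Corpus processed with [recognize_diseases()].
#' @param gold Gold-annotated corpus (same documents).
#' @return Exclusion-list `data.frame` with columns `term`, `tp`, `fp`.
#' @export
build_exclusion_list <- function(recognized, gold) {
  gold_docs <- stats::setNames(gold$documents,
                               vapply(gold$documents, function(d) d$doc_id, ""))
  tally <- new.env(parent = emptyenv())
  bump <- function(term, slot) {
    cur <- tally[[term]] %||% c(tp = 0L, fp = 0L)
    cur[slot] <- cur[slot] + 1L
    tally[[term]] <- cur
  }
  for (doc in recognized$documents) {
    g <- gold_docs[[doc$doc_id]]
    gm <- if (is.null(g)) mention_table() else
      g$mentions[g$mentions$type == "disease", , drop = FALSE]
    m <- doc$mentions[doc$mentions$type == "disease", , drop = FALSE]
    for (i in seq_len(nrow(m))) {
      term <- paste(normalize_token(tokenize(m$text[i])$token), collapse = " ")
      hit <- FALSE
      for (j in seq_len(nrow(gm))) {
        if (gm$start[j] == m$start[i] && gm$end[j] == m$end[i] &&
            length(intersect(gm$concept_ids[[j]], m$concept_ids[[i]]))) {
          hit <- TRUE; break
        }
      }
      bump(term, if (hit) "tp" else "fp")
    }
  }
  terms <- ls(tally)
  data.frame(term = terms,
             tp = vapply(terms, function(t) tally[[t]][["tp"]], 1L),
             fp = vapply(terms, function(t) tally[[t]][["fp"]], 1L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a two-column dictionary file (concept_id, term)
#' @param path Tab-separated file, no header.
#' @return `data.frame` with columns `concept_id`, `term`.
#' @export
read_dictionary <- function(path) {
  df <- utils::read.delim(path, header = FALSE, quote = "",
                          col.names = c("concept_id", "term"),
                          colClasses = "character", fileEncoding = "UTF-8")
  df
}

#' Read a two-column concept-to-MeSH mapping file
#' @param path Tab-separated file, no header.
#' @return `data.frame` with columns `concept_id`, `mesh_id`.
#' @export
read_mesh_map <- function(path) {
  utils::read.delim(path, header = FALSE, quote = "",
                    col.names = c("concept_id", "mesh_id"),
                    colClasses = "character", fileEncoding = "UTF-8")
}

#' Read an exclusion list (term, tp, fp)
#' @param path Tab-separated file, no header.
#' @return `data.frame` with columns `term`, `tp`, `fp`.
#' @export
read_exclusion_list <- function(path) {
  df <- utils::read.delim(path, header = FALSE, quote = "",
                          col.names = c("term", "tp", "fp"),
                          colClasses = c("character", "integer", "integer"),
                          fileEncoding = "UTF-8")
  df
}
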