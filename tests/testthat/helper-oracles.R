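# Independent brute-force oracles.  Each re-derives the expected behaviour
# from the rule definitions by exhaustive enumeration, without reusing the
# package's search code paths.

# --- dictionary matching -----------------------------------------------------

# Enumerate every contiguous run of non-stopword token positions whose
# normalized sequence is a dictionary key; resolve overlaps by accepting
# candidates in (start ascending, length descending) order.
oracle_match <- function(tokens, entries, stopwords, normalizer = "sstem") {
  keys <- vapply(entries$term, function(tm) {
    t <- tokenize(tm)$token
    t <- t[!(t %in% stopwords)]
    paste(normalize_token(t, normalizer), collapse = " ")
  }, "")
  keyset <- split(entries$concept_id, keys)
  keyset[[""]] <- NULL
  pos <- which(!(tokens$token %in% stopwords))
  norm <- normalize_token(tokens$token, normalizer)
  cand <- list()
  for (i in seq_along(pos)) for (j in i:length(pos)) {
    key <- paste(norm[pos[i:j]], collapse = " ")
    if (!is.null(keyset[[key]])) {
      cand[[length(cand) + 1L]] <- list(i = i, j = j, key = key,
                                        ids = sort(unique(keyset[[key]])))
    }
  }
  if (!length(cand)) {
    return(data.frame(start = integer(), end = integer(), term = character(),
                      ids = character(), stringsAsFactors = FALSE))
  }
  ord <- order(vapply(cand, `[[`, 1L, "i"), -vapply(cand, `[[`, 1L, "j"))
  taken <- rep(FALSE, length(pos))
  acc <- list()
  for (c_ in cand[ord]) {
    if (any(taken[c_$i:c_$j])) next
    taken[c_$i:c_$j] <- TRUE
    acc[[length(acc) + 1L]] <- c_
  }
  acc <- acc[order(vapply(acc, `[[`, 1L, "i"))]
  data.frame(start = vapply(acc, function(c_) tokens$start[pos[c_$i]], 1L),
             end = vapply(acc, function(c_) tokens$end[pos[c_$j]], 1L),
             term = vapply(acc, `[[`, "", "key"),
             ids = vapply(acc, function(c_) paste(c_$ids, collapse = ","), ""),
             stringsAsFactors = FALSE)
}

random_dictionary <- function(alphabet, max_terms = 8) {
  n <- sample.int(max_terms, 1L)
  terms <- vapply(seq_len(n), function(i)
    paste(sample(alphabet, sample.int(3, 1L), replace = TRUE), collapse = " "), "")
  data.frame(concept_id = sprintf("C%02d", seq_len(n)), term = terms,
             stringsAsFactors = FALSE)
}

random_text <- function(alphabet, max_tokens = 20) {
  paste(sample(alphabet, sample.int(max_tokens, 1L), replace = TRUE),
        collapse = " ")
}

# --- knowledge-graph paths ---------------------------------------------------

# Exhaustive enumeration of length-1 and length-2 chains with the
# orientation filter and direct-suppresses-indirect rule, straight from the
# aggregated edge table.  Returns a canonical character set for comparison.
oracle_paths <- function(graph, a, b) {
  e <- graph$edges
  joins <- function(i, u, v) {
    (e$subject[i] == u && e$object[i] == v) ||
      (e$subject[i] == v && e$object[i] == u)
  }
  oriented <- function(i, u, v) {
    !e$directed[i] || (e$subject[i] == u && e$object[i] == v)
  }
  direct <- Filter(function(i) joins(i, a, b), seq_len(nrow(e)))
  if (length(direct)) {
    return(sort(vapply(direct, function(i) paste0("D", i), "")))
  }
  out <- character()
  nodes <- unique(c(e$subject, e$object))
  for (x in setdiff(nodes, c(a, b))) {
    for (i in seq_len(nrow(e))) for (j in seq_len(nrow(e))) {
      if (joins(i, a, x) && joins(j, x, b) &&
          oriented(i, a, x) && oriented(j, x, b)) {
        out <- c(out, paste0("I", i, ".", j))
      }
    }
  }
  sort(unique(out))
}

canonical_paths <- function(paths) {
  sort(vapply(paths, function(p) {
    if (p$kind == "direct") paste0("D", p$edges[1])
    else paste0("I", p$edges[1], ".", p$edges[2])
  }, ""))
}

random_graph <- function(n_nodes = 8, n_edges = 12) {
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  n <- sample.int(n_edges, 1L)
  s <- sample(nodes, n, replace = TRUE)
  o <- sample(nodes, n, replace = TRUE)
  keep <- s != o
  s <- s[keep]; o <- o[keep]
  if (!length(s)) { s <- nodes[1]; o <- nodes[2] }
  suppressWarnings(kg_graph(data.frame(
    subject = s, predicate = sample(c("causes", "treats", "binds"), length(s), TRUE),
    object = o, directed = sample(0:1, length(s), TRUE),
    source = sample(c("ctd", "medline"), length(s), TRUE),
    count = sample.int(9, length(s), TRUE), stringsAsFactors = FALSE)))
}

# --- dependency trees --------------------------------------------------------

# full ancestor chain via repeated head lookup, then linear scan
oracle_ancestors <- function(parse, i, include_self = FALSE) {
  chain <- if (include_self) i else integer()
  cur <- parse$head[i]
  while (cur != 0L) {
    chain <- c(chain, cur)
    cur <- parse$head[cur]
  }
  chain
}

oracle_gov_verb <- function(parse, i) {
  anc <- oracle_ancestors(parse, i)
  verbs <- anc[is_verb_tag(parse$upos[anc])]
  if (length(verbs)) verbs[1] else NA_integer_
}

# depth-based lowest common ancestor with self-inclusive sets
oracle_relating <- function(parse, i, j) {
  depth <- function(t) length(oracle_ancestors(parse, t, include_self = TRUE))
  common <- intersect(oracle_ancestors(parse, i, TRUE),
                      oracle_ancestors(parse, j, TRUE))
  if (!length(common)) return(NA_integer_)
  common[which.max(vapply(common, depth, 1L))]
}

random_tree <- function(n = 10) {
  head <- c(0L, vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L))
  upos <- sample(c("VERB", "VBD", "NOUN", "ADJ", "ADV", "ADP"), n, TRUE,
                 prob = c(.15, .1, .4, .15, .1, .1))
  deprel <- sample(c("nsubj", "dobj", "nmod", "advmod", "neg", "amod"), n, TRUE)
  sentence_parse(form = sprintf("w%02d", seq_len(n)), upos = upos,
                 head = head, deprel = deprel)
}

# --- threshold sweep ---------------------------------------------------------

oracle_best_threshold <- function(prob, truth, step = 0.01) {
  grid <- seq(step, 1 - step, by = step)
  f <- vapply(grid, function(t) {
    pred <- prob >= t
    tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (p + r > 0) 2 * p * r / (p + r) else 0
  }, 1)
  list(threshold = grid[which.max(f)], f = max(f))
}
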