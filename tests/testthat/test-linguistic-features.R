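test_that("read_conllu parses documents, offsets, and validates trees", {
  tmp <- tempfile(); file.create(tmp)
  expect_length(read_conllu(tmp), 0)
  fx <- generate_fixtures(fixture_config(seed = 5, n_docs = 4))
  tmp2 <- tempfile()
  write_conllu(fx$parses, tmp2)
  back <- read_conllu(tmp2)
  expect_identical(names(back), names(fx$parses))
  for (d in names(back)) {
    expect_equal(lapply(back[[d]], as.data.frame),
                 lapply(fx$parses[[d]], as.data.frame))
  }
  # every head chain reaches the root
  p <- back[[1]][[1]]
  for (t in p$id) {
    expect_identical(utils::tail(c(t, cidre:::head_chain(p, t)), 1) %in%
                       which(p$head == 0L), TRUE)
  }
  # a cycle is rejected with the sentence named
  bad <- c("# doc_id = z", "1\ta\t_\tNOUN\t_\t_\t2\tdep\t_\t_",
           "2\tb\t_\tNOUN\t_\t_\t1\tdep\t_\t_", "")
  tmp3 <- tempfile(); writeLines(bad, tmp3)
  expect_error(read_conllu(tmp3), "root")
  bad2 <- c("# doc_id = z", "1\ta\t_\tNOUN\t_\t_\t0\troot\t_\t_",
            "2\tb\t_\tNOUN\t_\t_\t0\troot\t_\t_", "")
  tmp4 <- tempfile(); writeLines(bad2, tmp4)
  expect_error(read_conllu(tmp4), "one root")
})

test_that("the worked-example tree yields the published anchor words", {
  f2 <- example_dependency_tree()
  p <- f2$parse
  expect_identical(p$form[governing_verb(p, f2$dis_tok)], "produce")
  expect_identical(p$form[governing_verb(p, f2$chem_tok)], "demonstrated")
  expect_identical(p$form[relating_word(p, f2$chem_tok, f2$dis_tok)],
                   "demonstrated")
})

test_that("governing verb and relating word match ancestor-chain oracles", {
  set.seed(19)
  for (rep in 1:150) {
    p <- random_tree(sample(2:15, 1))
    i <- sample.int(nrow(p), 1); j <- sample.int(nrow(p), 1)
    expect_identical(governing_verb(p, i), oracle_gov_verb(p, i))
    expect_identical(relating_word(p, i, j), oracle_relating(p, i, j))
    expect_identical(relating_word(p, i, j), relating_word(p, j, i))
  }
})

test_that("a token dominating the other is itself the relating word", {
  p <- sentence_parse(form = c("a", "b", "c"), upos = c("NOUN", "VERB", "NOUN"),
                      head = c(2L, 0L, 1L), deprel = c("nsubj", "root", "nmod"))
  # c hangs under a: relating word of (a, c) is a
  expect_identical(relating_word(p, 1L, 3L), 1L)
})

test_that("negation needs a negation label or a lexicon adverbial dependent", {
  p <- sentence_parse(form = c("x", "did", "not", "induce", "y"),
                      upos = c("NOUN", "AUX", "PART", "VERB", "NOUN"),
                      head = c(4L, 4L, 4L, 0L, 4L),
                      deprel = c("nsubj", "aux", "neg", "root", "dobj"))
  expect_true(is_negated(p, 4L))
  expect_false(is_negated(p, 1L))   # no dependents
  p2 <- sentence_parse(form = c("x", "never", "recurred"),
                       upos = c("NOUN", "ADV", "VERB"),
                       head = c(3L, 3L, 0L),
                       deprel = c("nsubj", "advmod", "root"))
  expect_true(is_negated(p2, 3L))
  expect_false(is_negated(p2, 3L, lexicon = c("not")))
})

make_two_sentence_doc <- function() {
  # s1: "tox induced rash ."  s2: "tox was measured ."
  t1 <- list(form = c("tox", "induced", "rash", "."),
             upos = c("NOUN", "VERB", "NOUN", "PUNCT"),
             head = c(2L, 0L, 2L, 2L),
             deprel = c("nsubj", "root", "dobj", "punct"))
  t2 <- list(form = c("tox", "was", "measured", "."),
             upos = c("NOUN", "AUX", "VERB", "PUNCT"),
             head = c(3L, 3L, 0L, 3L),
             deprel = c("nsubj", "auxpass", "root", "punct"))
  text1 <- paste(t1$form, collapse = " ")
  text2 <- paste(t2$form, collapse = " ")
  off <- function(tpl, base) {
    starts <- integer(length(tpl$form)); pos <- base
    for (i in seq_along(tpl$form)) {
      starts[i] <- pos; pos <- pos + nchar(tpl$form[i]) + 1L
    }
    list(start = starts, end = starts + nchar(tpl$form))
  }
  o1 <- off(t1, 0L); o2 <- off(t2, nchar(text1) + 1L)
  parses <- list(
    sentence_parse(t1$form, t1$upos, t1$head, t1$deprel, o1$start, o1$end),
    sentence_parse(t2$form, t2$upos, t2$head, t2$deprel, o2$start, o2$end))
  m <- mention_table(
    start = c(o1$start[1], o2$start[1], o1$start[3]),
    end = c(o1$end[1], o2$end[1], o1$end[3]),
    text = c("tox", "tox", "rash"),
    type = c("chemical", "chemical", "disease"),
    concept_ids = list("D1", "D1", "D2"))
  doc <- pt_document("55", text1, text2, m)
  list(doc = doc, parses = parses)
}

test_that("same-sentence mention pairs take precedence", {
  x <- make_two_sentence_doc()
  p <- select_representative_pair(x$doc, x$parses, "D1", "D2")
  expect_true(p$same_sentence)
  expect_identical(p$chem_loc$sent, 1L)
  expect_error(select_representative_pair(x$doc, x$parses, "D1", "D9"),
               "no mention")
})

test_that("cross-sentence selection takes the last chemical-before-disease pair", {
  # two chemicals before the disease, in separate sentences
  t <- list(form = c("alpha", "seen", "."), upos = c("NOUN", "VERB", "PUNCT"),
            head = c(2L, 0L, 2L), deprel = c("nsubj", "root", "punct"))
  mk <- function(forms, base) {
    starts <- integer(length(forms)); pos <- base
    for (i in seq_along(forms)) { starts[i] <- pos; pos <- pos + nchar(forms[i]) + 1L }
    list(start = starts, end = starts + nchar(forms))
  }
  f1 <- c("aaa", "seen", "."); f2 <- c("bbb", "seen", "."); f3 <- c("rash", "seen", ".")
  o1 <- mk(f1, 0L); o2 <- mk(f2, o1$end[3] + 1L); o3 <- mk(f3, o2$end[3] + 1L)
  ps <- list(sentence_parse(f1, t$upos, t$head, t$deprel, o1$start, o1$end),
             sentence_parse(f2, t$upos, t$head, t$deprel, o2$start, o2$end),
             sentence_parse(f3, t$upos, t$head, t$deprel, o3$start, o3$end))
  m <- mention_table(start = c(o1$start[1], o2$start[1], o3$start[1]),
                     end = c(o1$end[1], o2$end[1], o3$end[1]),
                     text = c("aaa", "bbb", "rash"),
                     type = c("chemical", "chemical", "disease"),
                     concept_ids = list("DA", "DA", "DX"))
  doc <- pt_document("60", paste(f1, collapse = " "),
                     paste(c(paste(f2, collapse = " "),
                             paste(f3, collapse = " ")), collapse = " "), m)
  p <- select_representative_pair(doc, ps, "DA", "DX")
  expect_false(p$same_sentence)
  expect_identical(p$chem_loc$sent, 2L)   # the later chemical wins
  # disease-before-chemical only: first mentions of each
  m2 <- mention_table(start = c(o1$start[1], o2$start[1], o3$start[1]),
                      end = c(o1$end[1], o2$end[1], o3$end[1]),
                      text = c("aaa", "bbb", "rash"),
                      type = c("disease", "disease", "chemical"),
                      concept_ids = list("DX", "DX", "DA"))
  doc2 <- pt_document("61", paste(f1, collapse = " "),
                      paste(c(paste(f2, collapse = " "),
                              paste(f3, collapse = " ")), collapse = " "), m2)
  p2 <- select_representative_pair(doc2, ps, "DA", "DX")
  expect_identical(p2$dis_loc$sent, 1L)
  expect_identical(p2$chem_loc$sent, 3L)
})

test_that("pair features cover anchors, order, negation and identity flags", {
  x <- make_two_sentence_doc()
  f <- pair_linguistic_features(x$doc, x$parses, "D1", "D2")
  expect_identical(f$gov_verb_chem, "induced")
  expect_identical(f$gov_verb_dis, "induced")
  expect_identical(f$relating_word, "induced")
  expect_true(f$chem_before_dis)
  expect_true(f$govdis_is_relating)     # disease's governing verb is the LCA
  expect_true(f$both_gov_are_relating)
  expect_false(f$chem_is_relating)
  expect_false(f$neg_relating)
  # cross-sentence pair: relating word and its negation undefined/false
  y <- make_two_sentence_doc()
  y$doc$mentions$concept_ids[[3]] <- "D2"
  # force cross-sentence by moving the disease id to a chem-free sentence
  m <- y$doc$mentions
  m$concept_ids[[1]] <- "D9"     # sentence-1 chemical no longer carries D1
  doc2 <- pt_document(y$doc$doc_id, y$doc$title, y$doc$abstract, m)
  f2 <- pair_linguistic_features(doc2, y$parses, "D1", "D2")
  expect_identical(f2$relating_word, NA_character_)
  expect_identical(f2$gov_verb_relating, NA_character_)
  expect_false(f2$neg_relating)
  expect_identical(f2$gov_verb_chem, "measured")
  expect_identical(f2$gov_verb_dis, "induced")
})

test_that("negated-template features mark the governing verbs as negated", {
  t <- cidre:::tpl_not_cause("tox", "rash")
  o <- local({
    starts <- integer(length(t$form)); pos <- 0L
    for (i in seq_along(t$form)) { starts[i] <- pos; pos <- pos + nchar(t$form[i]) + 1L }
    list(start = starts, end = starts + nchar(t$form))
  })
  ps <- list(sentence_parse(t$form, t$upos, t$head, t$deprel, o$start, o$end))
  m <- mention_table(start = o$start[c(t$chem_tok, t$dis_tok)],
                     end = o$end[c(t$chem_tok, t$dis_tok)],
                     text = t$form[c(t$chem_tok, t$dis_tok)],
                     type = c("chemical", "disease"),
                     concept_ids = list("D1", "D2"))
  doc <- pt_document("70", paste(t$form, collapse = " "), "pad.", m)
  f <- pair_linguistic_features(doc, ps, "D1", "D2")
  expect_true(f$neg_relating)
  expect_identical(f$relating_word, "cause")
})

test_that("aggregate counts tally anchor-word occurrences against a vocabulary", {
  x <- make_two_sentence_doc()
  counts <- aggregate_linguistic_features(x$doc, x$parses,
                                          c("induced", "measured", "absent"))
  # two chem mentions x one disease: pair 1 same-sentence gives
  # gov_chem+gov_dis+relating = 3 "induced"; pair 2 cross-sentence gives
  # "measured" (gov chem) + "induced" (gov dis)
  expect_identical(unname(counts["induced"]), 4)
  expect_identical(unname(counts["measured"]), 1)
  expect_identical(unname(counts["absent"]), 0)
  expect_length(aggregate_linguistic_features(x$doc, x$parses, character()), 0)
  nochem <- pt_document("80", "rash seen", "rash again.",
                        mention_table(0L, 4L, "rash", "disease", list("D2")))
  expect_identical(sum(aggregate_linguistic_features(nochem, x$parses,
                                                     c("induced"))), 0)
})
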