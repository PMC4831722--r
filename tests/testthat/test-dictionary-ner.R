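test_that("tokenize splits on non-alphanumerics, case-folds, keeps offsets", {
  expect_identical(nrow(tokenize("")), 0L)
  expect_identical(nrow(tokenize("--- !!")), 0L)
  t <- tokenize("heart-attack, acute")
  expect_identical(t$token, c("heart", "attack", "acute"))
  expect_identical(substring("heart-attack, acute", t$start + 1, t$end),
                   c("heart", "attack", "acute"))
  expect_identical(tokenize("Q10 deficiency")$token, c("q10", "deficiency"))
})

test_that("the builtin stemmer conflates plural forms and is idempotent", {
  expect_identical(normalize_token("seizures", "identity"), "seizures")
  expect_identical(normalize_token("seizures"), normalize_token("seizure"))
  expect_identical(normalize_token("allergies"), normalize_token("allergy"))
  words <- c("diseases", "tremors", "fibrosis", "virus", "illness", "nausea")
  once <- normalize_token(words)
  expect_identical(normalize_token(once), once)
  expect_error(normalize_token("x", "bogus"), "unknown normalizer")
})

test_that("build_index tokenizes terms, strips stopwords, drops empty entries", {
  idx <- build_index(data.frame(concept_id = "C1", term = "fever"), character())
  expect_identical(idx[["fever"]], "C1")
  idx2 <- build_index(data.frame(concept_id = "C2", term = "pain in chest"),
                      stopwords = "in")
  expect_identical(idx2[["pain chest"]], "C2")
  expect_warning(
    idx3 <- build_index(data.frame(concept_id = c("C3", "C4"),
                                   term = c("the", "rash")),
                        stopwords = "the"),
    "stopwords only")
  expect_null(idx3[["the"]])
  expect_identical(idx3[["rash"]], "C4")
})

test_that("match_longest prefers the longest phrase at each position", {
  idx <- build_index(data.frame(concept_id = c("C1", "C2"),
                                term = c("liver failure", "liver")),
                     character())
  sp <- match_longest(tokenize("acute liver failure"), idx)
  expect_identical(nrow(sp), 1L)
  expect_identical(sp$concept_ids[[1]], "C1")
  expect_identical(substring("acute liver failure", sp$start + 1, sp$end),
                   "liver failure")
  sp2 <- match_longest(tokenize("liver disease"), idx)
  expect_identical(sp2$concept_ids[[1]], "C2")
})

test_that("match_longest agrees with the brute-force oracle on random cases", {
  set.seed(42)
  alphabet <- c("liver", "failure", "acute", "renal", "the", "pain", "chest",
                "severe", "fever")
  stop_sets <- list(character(), "the")
  for (rep in 1:120) {
    entries <- random_dictionary(alphabet)
    text <- random_text(alphabet)
    sw <- stop_sets[[sample.int(2, 1)]]
    idx <- build_index(entries, sw)
    got <- match_longest(tokenize(text), idx)
    want <- oracle_match(tokenize(text), entries, sw)
    expect_identical(got$start, want$start)
    expect_identical(got$end, want$end)
    expect_identical(vapply(got$concept_ids, paste, "", collapse = ","),
                     want$ids)
  }
})

test_that("abbreviation definitions propagate concepts to all occurrences", {
  txt <- "Non-Hodgkin lymphoma (NHL) was studied. Later NHL recurred."
  idx <- build_index(data.frame(concept_id = "C9",
                                term = "non-hodgkin lymphoma"), character())
  sp <- propagate_abbreviations(txt, match_longest(tokenize(txt), idx))
  nhl <- sp[sp$end - sp$start == 3, ]
  expect_identical(nrow(nhl), 2L)
  expect_true(all(vapply(nhl$concept_ids, identical, TRUE, "C9")))
  # short form recognized, long form not: long-form occurrences gain the id
  txt2 <- "The fever syndrome (FS) persisted. FS was severe."
  idx2 <- build_index(data.frame(concept_id = "C2", term = "fs"), character())
  sp2 <- propagate_abbreviations(txt2, match_longest(tokenize(txt2), idx2))
  long <- sp2[sp2$start == 4, ]
  expect_identical(long$concept_ids[[1]], "C2")
  expect_identical(substring(txt2, long$start + 1, long$end), "fever syndrome")
})

test_that("a parenthesized token without a preceding long form does not propagate", {
  txt <- "(NHL) cohort data."
  idx <- build_index(data.frame(concept_id = "C1", term = "cohort"), character())
  sp <- propagate_abbreviations(txt, match_longest(tokenize(txt), idx))
  expect_false(any(grepl("nhl", sp$term)))
})

test_that("adjacent same-concept spans merge across whitespace and punctuation", {
  txt <- "abcde fghi"
  base <- span_table_for_tests(list(
    list(start = 0L, end = 5L, term = "abcde", concept_ids = "C1"),
    list(start = 6L, end = 10L, term = "fghi", concept_ids = "C1")))
  merged <- merge_adjacent(txt, base)
  expect_identical(nrow(merged), 1L)
  expect_identical(merged$start, 0L)
  expect_identical(merged$end, 10L)
  # different concepts stay apart
  base2 <- span_table_for_tests(list(
    list(start = 0L, end = 5L, term = "abcde", concept_ids = "C1"),
    list(start = 6L, end = 10L, term = "fghi", concept_ids = "C2")))
  expect_identical(nrow(merge_adjacent(txt, base2)), 2L)
  # a chain of three collapses in one pass and the result is a fixed point
  txt3 <- "aa, bb; cc"
  base3 <- span_table_for_tests(list(
    list(start = 0L, end = 2L, term = "aa", concept_ids = "C1"),
    list(start = 4L, end = 6L, term = "bb", concept_ids = "C1"),
    list(start = 8L, end = 10L, term = "cc", concept_ids = "C1")))
  m3 <- merge_adjacent(txt3, base3)
  expect_identical(nrow(m3), 1L)
  expect_equal(merge_adjacent(txt3, m3)[, c("start", "end")],
               m3[, c("start", "end")])
})

test_that("exclusion removes terms strictly below the ratio threshold", {
  spans <- span_table_for_tests(list(
    list(start = 0L, end = 4L, term = "low", concept_ids = "C1"),
    list(start = 5L, end = 9L, term = "edge", concept_ids = "C2"),
    list(start = 10L, end = 14L, term = "free", concept_ids = "C3")))
  excl <- data.frame(term = c("low", "edge"), tp = c(1L, 3L), fp = c(9L, 10L))
  out <- apply_exclusion(spans, excl, 0.3)
  expect_identical(out$term, c("edge", "free"))   # 1/9 < 0.3 removed; 3/10 kept
  expect_identical(apply_exclusion(spans, excl, 0), spans)
  inf <- apply_exclusion(spans, excl, Inf)
  expect_identical(inf$term, "free")
})

test_that("MeSH normalization maps, drops or sentinels, and deduplicates", {
  spans <- span_table_for_tests(list(
    list(start = 0L, end = 3L, term = "one", concept_ids = "C1"),
    list(start = 4L, end = 7L, term = "two", concept_ids = "C9"),
    list(start = 8L, end = 11L, term = "dup", concept_ids = c("C2", "C3"))))
  mm <- data.frame(concept_id = c("C1", "C2", "C3"),
                   mesh_id = c("D001", "D777", "D777"))
  dropped <- normalize_to_mesh(spans, mm, "drop")
  expect_identical(dropped$concept_ids, list("D001", "D777"))
  kept <- normalize_to_mesh(spans, mm, "sentinel")
  expect_identical(kept$concept_ids[[2]], "unmapped")
})

test_that("the full recognition chain reproduces a hand-traced document", {
  # engineered to exercise longest match, abbreviation, merging, exclusion
  doc <- pt_document("77", "Acute liver failure (ALF) case",
                     "ALF and biliary cirrhosis, cirrhosis worsened; noise term seen.")
  dict <- data.frame(
    concept_id = c("C1", "C2", "C3", "C4"),
    term = c("liver failure", "liver", "cirrhosis", "noise term"))
  mm <- data.frame(concept_id = c("C1", "C2", "C3", "C4"),
                   mesh_id = c("D100", "D200", "D300", "D400"))
  excl <- data.frame(term = "noise term", tp = 1L, fp = 10L)
  idx <- build_index(dict, default_stopwords())
  out <- recognize_diseases(doc, idx, excl, mm, list())
  dm <- out$mentions[out$mentions$type == "disease", ]
  txt <- doc_text(out)
  surfaces <- substring(txt, dm$start + 1, dm$end)
  # longest match takes "liver failure" (C1) not "liver" (C2); abbreviation
  # propagation plus same-concept merging fuse the definition into one span
  expect_true("Acute liver failure (ALF" %in% surfaces)
  expect_false(any(vapply(dm$concept_ids, function(v) "D200" %in% v, TRUE)))
  # the later bare ALF occurrence is tagged with the long form's identifier
  alf <- dm[surfaces == "ALF", ]
  expect_identical(nrow(alf), 1L)
  expect_true(all(vapply(alf$concept_ids, identical, TRUE, "D100")))
  # adjacent same-concept merge: "biliary cirrhosis, cirrhosis" is one span
  expect_true("cirrhosis, cirrhosis" %in% surfaces)
  # exclusion removed the noisy term (1/10 < 0.3)
  expect_false(any(grepl("noise", surfaces)))
  # deterministic on re-run
  out2 <- recognize_diseases(doc, idx, excl, mm, list())
  expect_equal(out, out2)
})

test_that("a document with no dictionary hits yields no disease mentions", {
  doc <- pt_document("1", "Nothing here", "Plain text only.")
  idx <- build_index(data.frame(concept_id = "C1", term = "fever"), character())
  out <- recognize_diseases(doc, idx, NULL,
                            data.frame(concept_id = "C1", mesh_id = "D1"))
  expect_identical(sum(out$mentions$type == "disease"), 0L)
})

test_that("recognized output never overlaps and always slices to its text", {
  fx <- generate_fixtures(fixture_config(seed = 31, n_docs = 15))
  idx <- build_index(fx$dictionary, default_stopwords())
  for (doc in fx$corpus$documents[1:10]) {
    out <- recognize_diseases(doc, idx, NULL, fx$mesh_map)
    dm <- out$mentions[out$mentions$type == "disease", ]
    if (nrow(dm) < 2) next
    dm <- dm[order(dm$start), ]
    expect_true(all(dm$start[-1] >= dm$end[-nrow(dm)]))
    expect_identical(substring(doc_text(doc), dm$start + 1, dm$end), dm$text)
  }
})

test_that("build_exclusion_list tallies term-level hits against gold", {
  gold <- pt_document("9", "x", "severe rash seen",
                      mention_table(9L, 13L, "rash", "disease", list("D1")))
  dict <- data.frame(concept_id = c("C1", "C2"), term = c("rash", "seen"))
  mm <- data.frame(concept_id = c("C1", "C2"), mesh_id = c("D1", "D2"))
  idx <- build_index(dict, character())
  rec <- pt_corpus(list(recognize_diseases(gold, idx, NULL, mm)))
  excl <- build_exclusion_list(rec, pt_corpus(list(gold)))
  expect_identical(excl$tp[excl$term == "rash"], 1L)
  expect_identical(excl$fp[excl$term == "rash"], 0L)
  expect_identical(excl$fp[excl$term == "seen"], 1L)
})
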