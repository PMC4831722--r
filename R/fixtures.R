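# Seeded generator of synthetic corpora, dictionaries, knowledge graphs and
# dependency parses with planted ground truth.
#
# Documents are assembled from a small set of sentence templates with
# hand-authored dependency trees, so the whole pipeline can be exercised
# hermetically: related pairs are expressed with causal verbs ("induced",
# "produce") in one sentence or split across two sentences; unrelated pairs
# are expressed with negation ("did not cause"), treatment ("was treated
# with") or in unconnected sentences.  A knowledge graph plants "causes"
# edges preferentially for truly related pairs.  The generated text is
# telegraphic by design; it emulates the statistical structure of an
# annotated abstract corpus, not English prose.

#' Fixture generator configuration
#'
#' Defaults emulate the structure of the reference corpus: about a fifth of
#' co-mentioned identifier pairs are truly related, 70 percent of related
#' pairs share a sentence (the published corpus has ~19% positive pairs and
#' ~72% same-sentence relations), and the entity vocabularies are of the
#' same order as the document count, matching the sparse unique-identifier
#' regime of annotated abstract corpora (roughly three unique chemicals and
#' diseases per document, most pairs seen in only one document).
#'
#' @param seed Integer seed; every draw derives from it.
#' @param n_docs Number of documents.
#' @param n_chemicals,n_diseases Vocabulary sizes.
#' @param p_relation Probability a co-mentioned slot pair is truly related.
#' @param p_same_sentence Probability a related pair shares a sentence.
#' @param p_kg_edge_given_rel,p_kg_edge_given_unrel Probability of a direct
#'   "causes" edge for related / unrelated slot pairs.
#' @param p_kg_indirect_given_rel Probability that a related pair without a
#'   direct edge gets an indirect two-edge chain through a gene node.
#' @param p_treat_edge Probability of a "treats" edge for unrelated pairs.
#' @param p_title_chem Probability the first chemical also appears in the title.
#' @param max_slots Maximum chemical-disease slots per document (1 to this).
#' @param n_noise_edges Undirected "associated_with" distractor edges.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L, n_docs = 50L, n_chemicals = 150L,
                           n_diseases = 150L, p_relation = 0.2,
                           p_same_sentence = 0.7,
                           p_kg_edge_given_rel = 0.9,
                           p_kg_edge_given_unrel = 0.05,
                           p_kg_indirect_given_rel = 0.5,
                           p_treat_edge = 0.5,
                           p_title_chem = 0.5,
                           max_slots = 3L,
                           n_noise_edges = 40L) {
  cfg <- list(seed = as.integer(seed), n_docs = as.integer(n_docs),
              n_chemicals = as.integer(n_chemicals),
              n_diseases = as.integer(n_diseases),
              p_relation = p_relation, p_same_sentence = p_same_sentence,
              p_kg_edge_given_rel = p_kg_edge_given_rel,
              p_kg_edge_given_unrel = p_kg_edge_given_unrel,
              p_kg_indirect_given_rel = p_kg_indirect_given_rel,
              p_treat_edge = p_treat_edge, p_title_chem = p_title_chem,
              max_slots = as.integer(max_slots),
              n_noise_edges = as.integer(n_noise_edges))
  probs <- unlist(cfg[startsWith(names(cfg), "p_")])
  stopifnot(all(probs >= 0 & probs <= 1), cfg$n_docs >= 1,
            cfg$n_chemicals >= 1, cfg$n_diseases >= 1, cfg$max_slots >= 1)
  structure(cfg, class = "fixture_config")
}

# deterministic vocabularies (independent of the seed)
fixture_chemical_names <- function(n) {
  pre <- c("zana", "belo", "cori", "dexa", "fluvo", "gami", "halo", "imi",
           "keto", "lami", "meto", "nifa", "oxa", "pirolo", "quina", "rito")
  suf <- c("pril", "mab", "zole", "statin", "cillin", "mycin", "fen", "dronate")
  vapply(seq_len(n), function(i)
    paste0(pre[(i - 1L) %% length(pre) + 1L],
           suf[(i - 1L) %/% length(pre) %% length(suf) + 1L],
           if (i > length(pre) * length(suf)) i else ""), "")
}

fixture_disease_names <- function(n) {
  pre <- c("cardi", "nephr", "hepat", "derm", "neur", "oste", "gastr", "pulm",
           "angi", "myel", "arthr", "enceph", "retin", "vascul", "thromb", "glomerul")
  suf <- c("itis", "osis", "opathy", "emia", "algia", "oma", "odynia", "asthenia")
  vapply(seq_len(n), function(i)
    paste0(pre[(i - 1L) %% length(pre) + 1L],
           suf[(i - 1L) %/% length(pre) %% length(suf) + 1L],
           if (i > length(pre) * length(suf)) i else ""), "")
}

# --- sentence templates (hand-authored trees) --------------------------------
# Each template function returns list(form, upos, head, deprel, chem_tok,
# dis_tok) with 0 for absent roles.

tpl_title_chem <- function(chem) list(
  form = c("Effects", "of", chem, "in", "patients", "."),
  upos = c("NOUN", "ADP", "NOUN", "ADP", "NOUN", "PUNCT"),
  head = c(0L, 3L, 1L, 5L, 1L, 1L),
  deprel = c("root", "case", "nmod", "case", "nmod", "punct"),
  chem_tok = 3L, dis_tok = 0L)

tpl_title_plain <- function() list(
  form = c("Clinical", "observations", "in", "patients", "."),
  upos = c("ADJ", "NOUN", "ADP", "NOUN", "PUNCT"),
  head = c(2L, 0L, 4L, 2L, 2L),
  deprel = c("amod", "root", "case", "nmod", "punct"),
  chem_tok = 0L, dis_tok = 0L)

tpl_induced <- function(chem, dis) list(
  form = c(chem, "induced", dis, "."),
  upos = c("NOUN", "VERB", "NOUN", "PUNCT"),
  head = c(2L, 0L, 2L, 2L),
  deprel = c("nsubj", "root", "dobj", "punct"),
  chem_tok = 1L, dis_tok = 3L)

tpl_produce <- function(chem, dis) list(
  form = c("Challenge", "with", chem, "demonstrated", "that", "the", "drug",
           "can", "produce", dis, "."),
  upos = c("NOUN", "ADP", "NOUN", "VERB", "SCONJ", "DET", "NOUN", "AUX",
           "VERB", "NOUN", "PUNCT"),
  head = c(4L, 3L, 1L, 0L, 9L, 7L, 9L, 9L, 4L, 9L, 4L),
  deprel = c("nsubj", "case", "nmod", "root", "mark", "det", "nsubj", "aux",
             "ccomp", "dobj", "punct"),
  chem_tok = 3L, dis_tok = 10L)

tpl_chem_given <- function(chem) list(
  form = c(chem, "was", "administered", "to", "the", "patient", "."),
  upos = c("NOUN", "AUX", "VERB", "ADP", "DET", "NOUN", "PUNCT"),
  head = c(3L, 3L, 0L, 6L, 6L, 3L, 3L),
  deprel = c("nsubjpass", "auxpass", "root", "case", "det", "nmod", "punct"),
  chem_tok = 1L, dis_tok = 0L)

tpl_dis_developed <- function(dis) list(
  form = c("Subsequently", "severe", dis, "developed", "."),
  upos = c("ADV", "ADJ", "NOUN", "VERB", "PUNCT"),
  head = c(4L, 3L, 4L, 0L, 4L),
  deprel = c("advmod", "amod", "nsubj", "root", "punct"),
  chem_tok = 0L, dis_tok = 3L)

tpl_not_cause <- function(chem, dis) list(
  form = c(chem, "did", "not", "cause", dis, "."),
  upos = c("NOUN", "AUX", "PART", "VERB", "NOUN", "PUNCT"),
  head = c(4L, 4L, 4L, 0L, 4L, 4L),
  deprel = c("nsubj", "aux", "neg", "root", "dobj", "punct"),
  chem_tok = 1L, dis_tok = 5L)

tpl_treated <- function(chem, dis) list(
  form = c(dis, "was", "treated", "with", chem, "."),
  upos = c("NOUN", "AUX", "VERB", "ADP", "NOUN", "PUNCT"),
  head = c(3L, 3L, 0L, 5L, 3L, 3L),
  deprel = c("nsubjpass", "auxpass", "root", "case", "nmod", "punct"),
  chem_tok = 5L, dis_tok = 1L)

tpl_chem_measured <- function(chem) list(
  form = c(chem, "levels", "were", "measured", "."),
  upos = c("NOUN", "NOUN", "AUX", "VERB", "PUNCT"),
  head = c(2L, 4L, 4L, 0L, 4L),
  deprel = c("compound", "nsubjpass", "auxpass", "root", "punct"),
  chem_tok = 1L, dis_tok = 0L)

tpl_dis_observed <- function(dis) list(
  form = c("Transient", dis, "was", "observed", "."),
  upos = c("ADJ", "NOUN", "AUX", "VERB", "PUNCT"),
  head = c(2L, 4L, 4L, 0L, 4L),
  deprel = c("amod", "nsubjpass", "auxpass", "root", "punct"),
  chem_tok = 0L, dis_tok = 0L)  # dis_tok set by caller: mention is token 2

#' The worked-example dependency tree
#'
#' A hand-encoded parse of a sentence about the chemical "acetaminophen"
#' and the disease "anaphylaxis" in which the disease's governing verb is
#' "produce" while the chemical's governing verb -- and the relating word of
#' the pair -- is "demonstrated".
#'
#' @return A list: `parse` (a `sentence_parse`), `chem_tok`, `dis_tok`.
#' @export
example_dependency_tree <- function() {
  t <- tpl_produce("acetaminophen", "anaphylaxis")
  list(parse = sentence_parse(t$form, t$upos, t$head, t$deprel),
       chem_tok = t$chem_tok, dis_tok = t$dis_tok)
}

# --- document assembly -------------------------------------------------------

# incrementally build a document: sentences joined by single spaces
new_doc_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$sentences <- list()   # each: list(tpl, offsets start/end per token)
  env$mentions <- list()    # list(start, end, text, type, ids)
  env$len <- 0L             # chars so far (0 when empty)
  env
}

push_sentence <- function(b, tpl, mentions = list()) {
  # mentions: list of list(tok = index, type, id)
  base <- if (b$len == 0L) 0L else b$len + 1L   # +1 for joining space
  starts <- integer(length(tpl$form)); ends <- integer(length(tpl$form))
  pos <- base
  for (i in seq_along(tpl$form)) {
    starts[i] <- pos
    ends[i] <- pos + nchar(tpl$form[i])
    pos <- ends[i] + 1L
  }
  b$len <- ends[length(ends)]
  b$sentences[[length(b$sentences) + 1L]] <-
    list(tpl = tpl, start = starts, end = ends)
  for (mn in mentions) {
    b$mentions[[length(b$mentions) + 1L]] <-
      list(start = starts[mn$tok], end = ends[mn$tok],
           text = tpl$form[mn$tok], type = mn$type, id = mn$id)
  }
  invisible(b)
}

builder_text <- function(b) {
  paste(vapply(b$sentences, function(s) paste(s$tpl$form, collapse = " "), ""),
        collapse = " ")
}

builder_parses <- function(b) {
  lapply(b$sentences, function(s)
    sentence_parse(s$tpl$form, s$tpl$upos, s$tpl$head, s$tpl$deprel,
                   start = s$start, end = s$end))
}

#' Generate a synthetic fixture set
#'
#' Builds a corpus with planted mentions and relations, the matching
#' dictionary, concept-to-MeSH map, knowledge graph and dependency parses.
#' Deterministic for a fixed config: the same config yields byte-identical
#' files.
#'
#' @param config A [fixture_config()].
#' @param dir Optional output directory; when given, the six artifact files
#'   are written (`corpus.pubtator`, `dictionary.tsv`, `mesh_map.tsv`,
#'   `kg_edges.tsv`, `parses.conllu`, `gold_relations.tsv`).
#' @return A list: `corpus` ([pt_corpus()]), `parses`, `graph`
#'   (`kg_graph`), `dictionary`, `mesh_map`, `relations`
#'   (`data.frame`), `config`.
#' @export
generate_fixtures <- function(config = fixture_config(), dir = NULL) {
  set.seed(config$seed)
  chem_names <- fixture_chemical_names(config$n_chemicals)
  dis_names <- fixture_disease_names(config$n_diseases)
  chem_ids <- sprintf("D1%04d", seq_len(config$n_chemicals))
  dis_ids <- sprintf("D2%04d", seq_len(config$n_diseases))
  dis_cui <- sprintf("C%06d", seq_len(config$n_diseases))
  dictionary <- data.frame(concept_id = dis_cui, term = dis_names,
                           stringsAsFactors = FALSE)
  mesh_map <- data.frame(concept_id = dis_cui, mesh_id = dis_ids,
                         stringsAsFactors = FALSE)

  docs <- list(); parses <- list(); rel_rows <- list(); kg_rows <- list()
  add_edge <- function(s, p, o, directed, source, count) {
    kg_rows[[length(kg_rows) + 1L]] <<- data.frame(
      subject = s, predicate = p, object = o, directed = directed,
      source = source, count = count, stringsAsFactors = FALSE)
  }
  for (d in seq_len(config$n_docs)) {
    doc_id <- sprintf("90%05d", d)
    n_slots <- sample.int(config$max_slots, 1L)
    chems <- sample.int(config$n_chemicals, n_slots, replace = FALSE)
    diss <- sample.int(config$n_diseases, n_slots, replace = FALSE)
    b <- new_doc_builder()
    # title (sentence 0)
    title_chem <- stats::runif(1) < config$p_title_chem
    if (title_chem) {
      t <- tpl_title_chem(chem_names[chems[1]])
      push_sentence(b, t, list(list(tok = t$chem_tok, type = "chemical",
                                    id = chem_ids[chems[1]])))
    } else {
      push_sentence(b, tpl_title_plain())
    }
    title_ntok <- length(b$sentences[[1]]$tpl$form)
    title_len <- b$len
    doc_rel <- list()
    for (s in seq_len(n_slots)) {
      cn <- chem_names[chems[s]]; ci <- chem_ids[chems[s]]
      dn <- dis_names[diss[s]]; di <- dis_ids[diss[s]]
      related <- stats::runif(1) < config$p_relation
      if (related) {
        doc_rel[[length(doc_rel) + 1L]] <- c(ci, di)
        if (stats::runif(1) < config$p_same_sentence) {
          t <- if (stats::runif(1) < 0.5) tpl_induced(cn, dn) else tpl_produce(cn, dn)
          push_sentence(b, t, list(
            list(tok = t$chem_tok, type = "chemical", id = ci),
            list(tok = t$dis_tok, type = "disease", id = di)))
        } else {
          t1 <- tpl_chem_given(cn)
          push_sentence(b, t1, list(list(tok = t1$chem_tok, type = "chemical", id = ci)))
          t2 <- tpl_dis_developed(dn)
          push_sentence(b, t2, list(list(tok = t2$dis_tok, type = "disease", id = di)))
        }
        if (stats::runif(1) < config$p_kg_edge_given_rel) {
          add_edge(ci, "causes", di, 1L, "ctd", sample.int(40, 1L) + 2L)
        } else if (stats::runif(1) < config$p_kg_indirect_given_rel) {
          g <- sprintf("G%03d", sample.int(30, 1L))
          add_edge(ci, "upregulates", g, 1L, "medline", sample.int(20, 1L))
          add_edge(g, "causes", di, 1L, "ctd", sample.int(20, 1L))
        }
      } else {
        kind <- sample(c("neg", "treat", "apart"), 1L)
        if (kind == "neg") {
          t <- tpl_not_cause(cn, dn)
          push_sentence(b, t, list(
            list(tok = t$chem_tok, type = "chemical", id = ci),
            list(tok = t$dis_tok, type = "disease", id = di)))
        } else if (kind == "treat") {
          t <- tpl_treated(cn, dn)
          push_sentence(b, t, list(
            list(tok = t$chem_tok, type = "chemical", id = ci),
            list(tok = t$dis_tok, type = "disease", id = di)))
        } else if (stats::runif(1) < 0.5) {
          # same sentence shapes as a cross-sentence related pair: distant
          # mentions carry no syntactic signal, only the knowledge graph
          # can tell these apart
          t1 <- tpl_chem_given(cn)
          push_sentence(b, t1, list(list(tok = t1$chem_tok, type = "chemical", id = ci)))
          t2 <- tpl_dis_developed(dn)
          push_sentence(b, t2, list(list(tok = t2$dis_tok, type = "disease", id = di)))
        } else {
          t1 <- tpl_chem_measured(cn)
          push_sentence(b, t1, list(list(tok = t1$chem_tok, type = "chemical", id = ci)))
          t2 <- tpl_dis_observed(dn)
          push_sentence(b, t2, list(list(tok = 2L, type = "disease", id = di)))
        }
        if (stats::runif(1) < config$p_kg_edge_given_unrel) {
          add_edge(ci, "causes", di, 1L, "medline", sample.int(5, 1L))
        }
        if (stats::runif(1) < config$p_treat_edge) {
          add_edge(ci, "treats", di, 1L, "ctd", sample.int(30, 1L) + 1L)
        }
      }
    }
    text <- builder_text(b)
    title <- substr(text, 1L, title_len)
    abstract <- substr(text, title_len + 2L, nchar(text))
    men <- b$mentions
    mt <- mention_table(
      start = vapply(men, function(m) m$start, 1L),
      end = vapply(men, function(m) m$end, 1L),
      text = vapply(men, function(m) m$text, ""),
      type = vapply(men, function(m) m$type, ""),
      concept_ids = lapply(men, function(m) m$id))
    rt <- if (length(doc_rel)) relation_table(
      chem_id = vapply(doc_rel, `[`, "", 1L),
      dis_id = vapply(doc_rel, `[`, "", 2L)) else relation_table()
    docs[[length(docs) + 1L]] <- pt_document(doc_id, title, abstract, mt, rt)
    parses[[doc_id]] <- builder_parses(b)
    for (r in doc_rel) {
      rel_rows[[length(rel_rows) + 1L]] <- data.frame(
        doc_id = doc_id, chem_id = r[1], dis_id = r[2], stringsAsFactors = FALSE)
    }
  }
  # distractor edges between random entities through shared intermediates
  for (i in seq_len(config$n_noise_edges)) {
    a <- sample(c(chem_ids, dis_ids), 1L)
    g <- sprintf("G%03d", sample.int(30, 1L))
    add_edge(a, "associated_with", g, 0L, "medline", sample.int(10, 1L))
  }
  edges <- if (length(kg_rows)) do.call(rbind, kg_rows) else
    data.frame(subject = character(), predicate = character(),
               object = character(), directed = integer(),
               source = character(), count = integer(), stringsAsFactors = FALSE)
  relations <- if (length(rel_rows)) do.call(rbind, rel_rows) else
    data.frame(doc_id = character(), chem_id = character(),
               dis_id = character(), stringsAsFactors = FALSE)
  out <- list(corpus = pt_corpus(docs), parses = parses,
              graph = suppressWarnings(kg_graph(edges)),
              dictionary = dictionary, mesh_map = mesh_map,
              edges = edges, relations = relations, config = config)
  if (!is.null(dir)) write_fixtures(out, dir)
  out
}

#' Write a fixture set to disk
#' @param fx Output of [generate_fixtures()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths.
#' @export
write_fixtures <- function(fx, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("corpus.pubtator", "dictionary.tsv", "mesh_map.tsv",
                            "kg_edges.tsv", "parses.conllu", "gold_relations.tsv"))
  names(paths) <- c("corpus", "dictionary", "mesh_map", "kg", "parses", "relations")
  write_pubtator(fx$corpus, paths["corpus"])
  write_tsv0 <- function(df, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    if (nrow(df)) {
      writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con,
                 useBytes = TRUE)
    }
  }
  write_tsv0(fx$dictionary, paths["dictionary"])
  write_tsv0(fx$mesh_map, paths["mesh_map"])
  write_tsv0(fx$edges, paths["kg"])
  write_conllu(fx$parses, paths["parses"])
  write_tsv0(fx$relations, paths["relations"])
  invisible(paths)
}
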