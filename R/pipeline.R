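# End-to-end pipeline: corpus -> (optional) disease recognition ->
# features -> train/tune -> predict -> evaluate, driven by a config list or
# YAML file.

#' Default stopword list
#'
#' The PubMed stopword list shipped with the package, used for dictionary
#' indexing and text matching.
#'
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "pubmed_stopwords.txt", package = "cidre")
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

#' Read a pipeline configuration
#'
#' @param path YAML file; keys are the arguments of [run_pipeline()]'s
#'   config (file paths `corpus`, `parses`, `kg`, optional `test_corpus`,
#'   `test_parses`, `dictionary`, `mesh_map`, `exclusion`; switches
#'   `ner`, `use_knowledge`, `use_statistical`, `use_linguistic`; numbers
#'   `seed`, `folds`, `class_weight`, `ratio_threshold`, `threshold`;
#'   vectors `cost_grid`, `gamma_grid`; output `out_dir`).
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  yaml::read_yaml(path)
}

required_file <- function(config, key) {
  p <- config[[key]]
  if (is.null(p)) stop("configuration key missing: ", key)
  if (!file.exists(p)) stop("configured path does not exist (", key, "): ", p)
  p
}

#' Run the relation-extraction pipeline
#'
#' Stages, in order: load resources; optionally re-recognize disease
#' mentions with the dictionary recognizer (otherwise the corpus annotations
#' are used as-is); generate labeled instances from the training corpus;
#' assemble and scale features; grid-search and train the class-weighted
#' SVM; tune the decision threshold on out-of-fold probabilities; predict on
#' the test corpus; evaluate against its gold relations.  Artifacts
#' (`predictions.tsv`, `report.tsv`, `run_info.yaml`) are written to
#' `out_dir` when given; the run info records the seed and a hash of the
#' configuration.
#'
#' @param config A list (see [read_config()]) or a path to a YAML file.
#' @return A list: `model`, `space`, `predictions`, `evaluation`, `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  seed <- as.integer(config$seed %||% 1L)
  train_corpus <- read_pubtator(required_file(config, "corpus"))
  parses <- read_conllu(required_file(config, "parses"))
  test_corpus <- if (!is.null(config$test_corpus))
    read_pubtator(required_file(config, "test_corpus")) else train_corpus
  test_parses <- if (!is.null(config$test_parses))
    read_conllu(required_file(config, "test_parses")) else parses
  use_kg <- config$use_knowledge %||% TRUE
  graph <- if (use_kg) load_graph(required_file(config, "kg")) else NULL

  if (isTRUE(config$ner)) {
    dict <- read_dictionary(required_file(config, "dictionary"))
    mm <- read_mesh_map(required_file(config, "mesh_map"))
    excl <- if (!is.null(config$exclusion))
      read_exclusion_list(required_file(config, "exclusion")) else NULL
    index <- build_index(dict, default_stopwords())
    ner_cfg <- list(ratio_threshold = config$ratio_threshold %||% 0.3)
    rec <- function(corpus) pt_corpus(lapply(corpus$documents, recognize_diseases,
                                             index = index, exclusion = excl,
                                             mesh_map = mm, config = ner_cfg))
    train_corpus <- rec(train_corpus)
    test_corpus <- rec(test_corpus)
  }

  fcfg <- list(use_knowledge = use_kg,
               use_statistical = config$use_statistical %||% TRUE,
               use_linguistic = config$use_linguistic %||% TRUE,
               scorer = config$scorer %||% "log-provenance")
  train_asm <- assemble_features(train_corpus, parses, graph, fcfg)
  space <- fit_feature_space(train_asm)
  X <- vectorize_instances(train_asm, space)
  model <- train_relation_model(
    X, train_asm$instances$label,
    cost_grid = unlist(config$cost_grid %||% 2^(-2:6)),
    gamma_grid = unlist(config$gamma_grid %||% 2^(-6:2)),
    folds = config$folds %||% 10, class_weight = config$class_weight %||% 5,
    seed = seed)
  model <- tune_threshold(model)
  test_asm <- assemble_features(test_corpus, test_parses, graph, fcfg)
  Xt <- vectorize_instances(test_asm, space)
  predictions <- predict_relations(model, Xt, test_asm$instances,
                                   threshold = config$threshold)
  evaluation <- evaluate_cid(test_corpus, predictions)

  if (!is.null(config$out_dir)) {
    write_run_artifacts(config$out_dir, config, seed, model, predictions, evaluation)
  }
  list(model = model, space = space, predictions = predictions,
       evaluation = evaluation, config = config)
}

write_run_artifacts <- function(out_dir, config, seed, model, predictions,
                                evaluation) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wb <- function(lines, path) {
    con <- file(path, open = "wb"); on.exit(close(con))
    writeLines(lines, con, useBytes = TRUE)
  }
  wb(c("doc_id\tchem_id\tdis_id\tprobability",
       sprintf("%s\t%s\t%s\t%.6f", predictions$doc_id, predictions$chem_id,
               predictions$dis_id, predictions$probability)),
     file.path(out_dir, "predictions.tsv"))
  wb(c("metric\tvalue",
       sprintf("tp\t%d", evaluation$tp),
       sprintf("fp\t%d", evaluation$fp),
       sprintf("fn\t%d", evaluation$fn),
       sprintf("precision\t%.6f", evaluation$precision),
       sprintf("recall\t%.6f", evaluation$recall),
       sprintf("f_score\t%.6f", evaluation$f_score),
       sprintf("threshold\t%.2f", model$threshold),
       sprintf("cost\t%g", model$cost),
       sprintf("gamma\t%g", model$gamma)),
     file.path(out_dir, "report.tsv"))
  cfg_hash <- config_hash(config)
  wb(c(sprintf("seed: %d", seed),
       sprintf("config_hash: %s", cfg_hash)),
     file.path(out_dir, "run_info.yaml"))
  invisible(NULL)
}

config_hash <- function(config) {
  config$out_dir <- NULL        # output location does not affect results
  canon <- yaml::as.yaml(config[order(names(config))])
  # small deterministic polynomial hash; avoids external digest dependencies
  h <- 0
  for (b in utf8ToInt(canon)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
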