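# Instance generation, feature assembly and normalization, class-weighted
# RBF-SVM training with grid search, Platt-calibrated probabilities,
# decision-threshold tuning, prediction and the co-occurrence baseline.

#' Generate classification instances from a corpus
#'
#' One instance per document per (unique chemical identifier x unique
#' disease identifier); composite identifiers are expanded and the unmapped
#' sentinel is skipped.  Pairs may cross the title-abstract border (the pair
#' exists as soon as both identifiers occur anywhere in the document).  With
#' `use_gold_labels`, an instance is positive iff the pair appears among the
#' document's gold relations.
#'
#' @param corpus A [pt_corpus()] with chemical and disease mentions.
#' @param use_gold_labels Attach labels from the gold relations?
#' @return `data.frame` with columns `doc_id`, `chem_id`, `dis_id`, `label`
#'   (`"pos"`/`"neg"`, or `NA` when unlabeled).
#' @export
generate_instances <- function(corpus, use_gold_labels = TRUE) {
  rows <- list()
  for (doc in corpus$documents) {
    chems <- sort(doc_entity_ids(doc, "chemical"))
    diss <- sort(doc_entity_ids(doc, "disease"))
    if (!length(chems) || !length(diss)) next
    gold <- paste(doc$relations$chem_id, doc$relations$dis_id, sep = "\t")
    for (c_ in chems) for (d_ in diss) {
      lab <- if (!use_gold_labels) NA_character_
             else if (paste(c_, d_, sep = "\t") %in% gold) "pos" else "neg"
      rows[[length(rows) + 1L]] <- data.frame(
        doc_id = doc$doc_id, chem_id = c_, dis_id = d_, label = lab,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(doc_id = character(), chem_id = character(),
               dis_id = character(), label = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assemble raw features for every instance
#'
#' Computes, per instance, the prior-knowledge path features, the
#' document-level statistical features, the per-pair linguistic features of
#' the representative mention pair, and the document's multiset of
#' governing-verb / relating-word occurrences (shared by all instances of a
#' document) feeding the aggregate linguistic counts.
#'
#' @param corpus A [pt_corpus()].
#' @param parses Named list doc_id -> list of `sentence_parse`.
#' @param graph A `kg_graph`, or `NULL` to skip knowledge features.
#' @param config List: `scorer`, `negation_lexicon`, and the group switches
#'   `use_knowledge`, `use_statistical`, `use_linguistic` (all default TRUE).
#' @param instances Optional precomputed instance table.
#' @return A list with `instances` (the table) and `raw` (list of per-
#'   instance named feature lists).
#' @export
assemble_features <- function(corpus, parses, graph = NULL, config = list(),
                              instances = NULL) {
  if (is.null(instances)) instances <- generate_instances(corpus)
  use_kg <- config$use_knowledge %||% TRUE
  use_stat <- config$use_statistical %||% TRUE
  use_ling <- config$use_linguistic %||% TRUE
  scorer <- config$scorer %||% "log-provenance"
  neg_lex <- config$negation_lexicon %||% c("not", "no", "never", "without")
  docs <- stats::setNames(corpus$documents,
                          vapply(corpus$documents, function(d) d$doc_id, ""))
  word_cache <- list()
  raw <- vector("list", nrow(instances))
  for (i in seq_len(nrow(instances))) {
    doc <- docs[[instances$doc_id[i]]]
    pd <- parses[[instances$doc_id[i]]] %||% list()
    f <- list()
    if (use_kg) {
      pf <- if (is.null(graph)) {
        list(path_type = "none", score = 0, n_paths = 0L,
             predicates = character(), provenance_count = 0L, forward = FALSE)
      } else {
        path_features(graph, instances$chem_id[i], instances$dis_id[i], scorer)
      }
      f$kg_direct <- pf$path_type == "direct"
      f$kg_indirect <- pf$path_type == "indirect"
      f$kg_score <- pf$score
      f$kg_n_paths <- as.numeric(pf$n_paths)
      f$kg_provenance <- as.numeric(pf$provenance_count)
      f$kg_forward <- pf$forward
      f$kg_predicates <- pf$predicates
    }
    if (use_stat) {
      sf <- stat_features(doc, pd, instances$chem_id[i], instances$dis_id[i])
      f[names(sf)] <- sf
    }
    if (use_ling) {
      lf <- pair_linguistic_features(doc, pd, instances$chem_id[i],
                                     instances$dis_id[i], neg_lex)
      f[names(lf)] <- lf
      if (is.null(word_cache[[doc$doc_id]])) {
        word_cache[[doc$doc_id]] <- collect_pair_words(doc, pd)
      }
      f$agg_words <- word_cache[[doc$doc_id]]
    }
    raw[[i]] <- f
  }
  list(instances = instances, raw = raw, config = config)
}

NUMERIC_FEATURES <- c("kg_score", "kg_n_paths", "kg_provenance",
                      "n_chem_mentions", "n_dis_mentions", "n_pairs",
                      "ratio_chem", "ratio_dis", "ratio_pairs",
                      "min_sentence_dist", "min_word_dist")
BOOL_FEATURES <- c("kg_direct", "kg_indirect", "kg_forward",
                   "chem_in_title", "dis_in_title", "both_in_title",
                   "chem_before_dis", "other_pair_lower",
                   "neg_relating", "neg_gov_chem", "neg_gov_dis",
                   "neg_gov_relating", "chem_is_relating",
                   "govdis_is_relating", "both_gov_are_relating")
NOMINAL_FEATURES <- c("chem_id", "dis_id", "gov_verb_chem", "gov_verb_dis",
                      "relating_word", "gov_verb_relating")

#' Fit the feature space on training instances
#'
#' Records, from the training data only: the min/max of every numeric
#' feature (for zero-one scaling), the level vocabulary of every nominal
#' feature (for one-hot encoding; unseen values at test time give an
#' all-zero block), the knowledge-graph predicate vocabulary, and the
#' aggregate governing-verb / relating-word vocabulary.
#'
#' @param assembled Output of [assemble_features()] on the training corpus.
#' @return A `feature_space` object.
#' @export
fit_feature_space <- function(assembled) {
  raw <- assembled$raw
  present <- if (length(raw)) names(raw[[1]]) else character()
  num <- intersect(NUMERIC_FEATURES, present)
  boo <- intersect(BOOL_FEATURES, present)
  nom <- intersect(NOMINAL_FEATURES, present)
  agg_vocab <- if ("agg_words" %in% present)
    sort(unique(unlist(lapply(raw, `[[`, "agg_words")))) else character()
  num_bounds <- lapply(stats::setNames(num, num), function(nm) {
    v <- vapply(raw, function(f) as.numeric(f[[nm]]), 1)
    c(min = min(v), max = max(v))
  })
  agg_bounds <- if (length(agg_vocab)) {
    counts <- vapply(raw, function(f)
      tabulate_words(f$agg_words, agg_vocab), numeric(length(agg_vocab)))
    counts <- matrix(counts, nrow = length(agg_vocab))
    lapply(seq_along(agg_vocab), function(i)
      c(min = min(counts[i, ]), max = max(counts[i, ])))
  } else list()
  names(agg_bounds) <- agg_vocab
  nominal_levels <- lapply(stats::setNames(nom, nom), function(nm) {
    v <- vapply(raw, function(f) {
      x <- f[[nm]]
      if (is.null(x) || is.na(x)) NA_character_ else as.character(x)
    }, "")
    sort(unique(v[!is.na(v)]))
  })
  pred_vocab <- if ("kg_predicates" %in% present)
    sort(unique(unlist(lapply(raw, `[[`, "kg_predicates")))) else character()
  structure(list(numeric = num, bool = boo, nominal = nom,
                 num_bounds = num_bounds, nominal_levels = nominal_levels,
                 predicate_vocab = pred_vocab,
                 agg_vocab = agg_vocab, agg_bounds = agg_bounds),
            class = "feature_space")
}

tabulate_words <- function(words, vocab) {
  if (!length(vocab)) return(numeric())
  as.numeric(table(factor(words[words %in% vocab], levels = vocab)))
}

scale01 <- function(x, bounds) {
  if (bounds["max"] > bounds["min"]) {
    pmin(1, pmax(0, (x - bounds["min"]) / (bounds["max"] - bounds["min"])))
  } else rep(0, length(x))          # constant feature scales to 0
}

#' Vectorize assembled instances under a fitted feature space
#'
#' Numeric features are scaled to zero-one by the training bounds and
#' clipped; booleans map to 0/1; nominal features one-hot encode against the
#' training vocabulary (unseen or undefined values give all zeros); the
#' knowledge-graph predicate set becomes one indicator per training
#' predicate; aggregate word counts are scaled like numerics.
#'
#' @param assembled Output of [assemble_features()].
#' @param space A `feature_space` from [fit_feature_space()].
#' @return Numeric matrix, one row per instance, fixed column set.
#' @export
vectorize_instances <- function(assembled, space) {
  raw <- assembled$raw
  n <- length(raw)
  cols <- list()
  for (nm in space$numeric) {
    v <- vapply(raw, function(f) as.numeric(f[[nm]]), 1)
    cols[[nm]] <- scale01(v, space$num_bounds[[nm]])
  }
  for (nm in space$bool) {
    cols[[nm]] <- vapply(raw, function(f) as.numeric(isTRUE(f[[nm]])), 1)
  }
  for (nm in space$nominal) {
    levs <- space$nominal_levels[[nm]]
    v <- vapply(raw, function(f) {
      x <- f[[nm]]
      if (is.null(x) || is.na(x)) NA_character_ else as.character(x)
    }, "")
    for (lv in levs) {
      cols[[paste0(nm, "=", lv)]] <- as.numeric(!is.na(v) & v == lv)
    }
  }
  for (pv in space$predicate_vocab) {
    cols[[paste0("kg_pred=", pv)]] <- vapply(raw, function(f)
      as.numeric(pv %in% (f$kg_predicates %||% character())), 1)
  }
  for (w in space$agg_vocab) {
    v <- vapply(raw, function(f)
      sum((f$agg_words %||% character()) == w), 1)
    cols[[paste0("agg=", w)]] <- scale01(v, space$agg_bounds[[w]])
  }
  X <- do.call(cbind, cols)
  if (is.null(X)) X <- matrix(0, nrow = n, ncol = 0)
  rownames(X) <- NULL
  X
}

# stratified fold assignment, deterministic under the seed
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    ix <- which(y == cls)
    fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
  }
  fold
}

micro_f <- function(truth, pred) {
  tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (p + r > 0) 2 * p * r / (p + r) else 0
}

# decision values oriented so larger = more positive
svm_decision <- function(fit, X) {
  pr <- stats::predict(fit, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  sgn <- if (colnames(dv)[1] == "pos/neg") 1 else -1
  sgn * as.numeric(dv[, 1])
}

fit_svm <- function(X, y, cost, gamma, class_weight) {
  e1071::svm(x = X, y = factor(y, levels = c("neg", "pos")),
             type = "C-classification", kernel = "radial",
             cost = cost, gamma = gamma, scale = FALSE,
             class.weights = c(neg = 1, pos = class_weight))
}

# Platt scaling: logistic fit of the labels on out-of-fold decision values
fit_platt <- function(dv, y) {
  y01 <- as.numeric(y == "pos")
  co <- tryCatch(
    suppressWarnings(stats::glm(y01 ~ dv, family = stats::binomial())$coefficients),
    error = function(e) NULL)
  if (is.null(co) || any(!is.finite(co))) co <- c(0, 4)   # generic steep sigmoid
  if (co[2] < 0) co[2] <- abs(co[2])   # orientation guard; dv is pos-oriented
  unname(co)
}

#' Train the relation classifier
#'
#' C-support-vector classification with an RBF kernel and a 5:1 cost
#' matrix favouring the minority (positive) class.  Cost and gamma are
#' selected by grid search under stratified k-fold cross-validation,
#' maximizing the micro-averaged F-score of the positive class at the
#' default decision threshold; the winning pair is refit on all data.
#' Positive-class probabilities come from Platt sigmoid scaling fitted on
#' out-of-fold decision values, so prediction is fully deterministic given
#' the seed.
#'
#' @param X Feature matrix from [vectorize_instances()].
#' @param y Labels, `"pos"`/`"neg"`.
#' @param cost_grid,gamma_grid Grids searched; defaults `2^(-2:6)` and
#'   `2^(-6:2)`.
#' @param folds Number of cross-validation folds (default 10).
#' @param class_weight Weight of the positive class (default 5).
#' @param seed Seed for fold assignment.
#' @return A `relation_model`: the refit SVM, the Platt coefficients, the
#'   selected `cost`/`gamma`, the grid-search table, fold assignment
#'   parameters, and `threshold` (0.5 until tuned).
#' @export
train_relation_model <- function(X, y, cost_grid = 2^(-2:6),
                                 gamma_grid = 2^(-6:2), folds = 10,
                                 class_weight = 5, seed = 1L) {
  y <- as.character(y)
  if (length(unique(y)) < 2L) stop("training data must contain both classes")
  fold <- stratified_folds(y, folds, seed)
  truth <- y == "pos"
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  grid$f <- NA_real_
  for (g in seq_len(nrow(grid))) {
    pred <- logical(length(y))
    ok <- TRUE
    for (k in seq_len(folds)) {
      tr <- fold != k; te <- fold == k
      if (!any(te)) next
      if (length(unique(y[tr])) < 2L) { ok <- FALSE; break }
      fit <- fit_svm(X[tr, , drop = FALSE], y[tr], grid$cost[g], grid$gamma[g],
                     class_weight)
      pred[te] <- svm_decision(fit, X[te, , drop = FALSE]) > 0
    }
    grid$f[g] <- if (ok) micro_f(truth, pred) else 0
  }
  best <- which.max(grid$f)
  cost <- grid$cost[best]; gamma <- grid$gamma[best]
  fit <- fit_svm(X, y, cost, gamma, class_weight)
  # out-of-fold decision values for calibration
  dv_oof <- numeric(length(y))
  for (k in seq_len(folds)) {
    tr <- fold != k; te <- fold == k
    if (!any(te)) next
    f_k <- fit_svm(X[tr, , drop = FALSE], y[tr], cost, gamma, class_weight)
    dv_oof[te] <- svm_decision(f_k, X[te, , drop = FALSE])
  }
  platt <- fit_platt(dv_oof, y)
  structure(list(fit = fit, platt = platt, cost = cost, gamma = gamma,
                 class_weight = class_weight, folds = folds, seed = seed,
                 grid = grid, threshold = 0.5,
                 oof = list(dv = dv_oof, y = y, fold = fold)),
            class = "relation_model")
}

#' @export
print.relation_model <- function(x, ...) {
  cat(sprintf(
    "<relation_model> RBF C-SVC | cost %.4g gamma %.4g | weight pos:neg %g:1 | threshold %.2f\n",
    x$cost, x$gamma, x$class_weight, x$threshold))
  invisible(x)
}

#' Positive-class probabilities
#' @param model A `relation_model`.
#' @param X Feature matrix.
#' @return Numeric vector of calibrated probabilities.
#' @export
predict_probabilities <- function(model, X) {
  dv <- svm_decision(model$fit, X)
  stats::plogis(model$platt[1] + model$platt[2] * dv)
}

#' Tune the decision threshold
#'
#' Sweeps thresholds over a fixed grid and returns the one maximizing the
#' micro-averaged F-score on the model's out-of-fold calibrated
#' probabilities; ties resolve to the lowest threshold.  Degenerate inputs
#' (fewer than two instances or a single class) fall back to 0.5 with a
#' warning.
#'
#' @param model A `relation_model`.
#' @param step Grid step, default 0.01 over (0, 1).
#' @return The model with `threshold` set.
#' @export
tune_threshold <- function(model, step = 0.01) {
  y <- model$oof$y
  if (length(y) < 2L || length(unique(y)) < 2L) {
    warning("degenerate instance set; keeping threshold 0.5", call. = FALSE)
    model$threshold <- 0.5
    return(model)
  }
  prob <- stats::plogis(model$platt[1] + model$platt[2] * model$oof$dv)
  truth <- y == "pos"
  grid <- seq(step, 1 - step, by = step)
  f <- vapply(grid, function(t) micro_f(truth, prob >= t), 1)
  model$threshold <- grid[which.max(f)]    # which.max takes the first (lowest)
  model$threshold_sweep <- data.frame(threshold = grid, f = f)
  model
}

#' Predict document-level relations
#'
#' A pair is predicted positive iff its calibrated probability is at least
#' the decision threshold.
#'
#' @param model A `relation_model`.
#' @param X Feature matrix for `instances`.
#' @param instances Instance table aligned with `X`.
#' @param threshold Optional override of the model's threshold.
#' @return `data.frame` of predicted pairs (`doc_id`, `chem_id`, `dis_id`,
#'   `probability`).
#' @export
predict_relations <- function(model, X, instances, threshold = NULL) {
  t_ <- threshold %||% model$threshold
  prob <- predict_probabilities(model, X)
  out <- instances[prob >= t_, c("doc_id", "chem_id", "dis_id"), drop = FALSE]
  out$probability <- prob[prob >= t_]
  rownames(out) <- NULL
  out
}

#' Sentence co-occurrence baseline
#'
#' Predicts a pair as related iff some mention of the chemical and some
#' mention of the disease occur in the same sentence (sentences defined by
#' the parses; the title is a sentence).
#'
#' @param corpus A [pt_corpus()].
#' @param parses Named list doc_id -> list of `sentence_parse`.
#' @return `data.frame` of predicted pairs.
#' @export
cooccurrence_baseline <- function(corpus, parses) {
  rows <- list()
  for (doc in corpus$documents) {
    pd <- parses[[doc$doc_id]] %||% list()
    m <- doc$mentions
    seen <- character()
    for (q in all_pair_locations(doc, pd)) {
      if (q$chem_loc$sent != q$dis_loc$sent) next
      for (c_ in setdiff(split_composite(m$concept_ids[[q$chem_row]]), SENTINEL_ID))
        for (d_ in setdiff(split_composite(m$concept_ids[[q$dis_row]]), SENTINEL_ID)) {
          key <- paste(c_, d_, sep = "\t")
          if (key %in% seen) next
          seen <- c(seen, key)
          rows[[length(rows) + 1L]] <- data.frame(
            doc_id = doc$doc_id, chem_id = c_, dis_id = d_,
            stringsAsFactors = FALSE)
        }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(doc_id = character(), chem_id = character(),
               dis_id = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
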