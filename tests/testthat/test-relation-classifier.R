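test_that("instances are the per-document product of unique identifiers", {
  m <- mention_table(start = c(0L, 3L, 8L), end = c(2L, 7L, 12L),
                     text = c("aa", "bbbb", "rash"),
                     type = c("chemical", "chemical", "disease"),
                     concept_ids = list("A", "B", "X"))
  doc <- pt_document("1", "aa bbbb rash", "pad.", m, relation_table("A", "X"))
  inst <- generate_instances(pt_corpus(list(doc)))
  expect_identical(nrow(inst), 2L)
  expect_identical(inst$label[inst$chem_id == "A"], "pos")
  expect_identical(inst$label[inst$chem_id == "B"], "neg")
})

test_that("pairs may cross the title-abstract border and sentinels are skipped", {
  m <- mention_table(start = c(0L, 9L, 14L), end = c(8L, 13L, 18L),
                     text = c("chemical", "rash", "pain"),
                     type = c("chemical", "disease", "disease"),
                     concept_ids = list("A", "X", "unmapped"))
  doc <- pt_document("2", "chemical", "rash pain here.", m)
  inst <- generate_instances(pt_corpus(list(doc)))
  expect_identical(nrow(inst), 1L)   # sentinel pair skipped
  expect_identical(inst$chem_id, "A")
})

test_that("instance counts equal the sum of per-document identifier products", {
  fx <- generate_fixtures(fixture_config(seed = 23, n_docs = 25))
  inst <- generate_instances(fx$corpus)
  want <- sum(vapply(fx$corpus$documents, function(d)
    length(doc_entity_ids(d, "chemical")) * length(doc_entity_ids(d, "disease")),
    1L))
  expect_identical(nrow(inst), as.integer(want))
  expect_false(anyDuplicated(paste(inst$doc_id, inst$chem_id, inst$dis_id)) > 0)
})

test_that("zero-one scaling uses training bounds with clipping", {
  fake <- function(vals) list(instances = NULL,
                              raw = lapply(vals, function(v)
                                list(kg_score = v, kg_direct = FALSE,
                                     kg_indirect = FALSE, kg_n_paths = 0,
                                     kg_provenance = 0, kg_forward = FALSE,
                                     kg_predicates = character())))
  sp <- fit_feature_space(fake(c(2, 4, 10)))
  X <- vectorize_instances(fake(c(2, 4, 10)), sp)
  expect_equal(unname(X[, "kg_score"]), c(0, 0.25, 1))
  Xt <- vectorize_instances(fake(c(12, -5)), sp)
  expect_equal(unname(Xt[, "kg_score"]), c(1, 0))
  # constant features scale to zero
  spc <- fit_feature_space(fake(c(3, 3)))
  expect_equal(unname(vectorize_instances(fake(c(3, 7)), spc)[, "kg_score"]),
               c(0, 0))
})

test_that("vectorization has a fixed dimension and stays in [0,1]", {
  fx <- generate_fixtures(fixture_config(seed = 13, n_docs = 30))
  asm <- assemble_features(fx$corpus, fx$parses, fx$graph)
  sp <- fit_feature_space(asm)
  X <- vectorize_instances(asm, sp)
  expect_identical(nrow(X), nrow(asm$instances))
  expect_true(all(X >= 0 & X <= 1))
  fx2 <- generate_fixtures(fixture_config(seed = 14, n_docs = 10))
  asm2 <- assemble_features(fx2$corpus, fx2$parses, fx$graph)
  X2 <- vectorize_instances(asm2, sp)
  expect_identical(ncol(X2), ncol(X))
  expect_true(all(X2 >= 0 & X2 <= 1))
})

make_blobs <- function(n_pos, n_neg, sep = 3, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(2 * n_pos, mean = sep / 6), ncol = 2),
             matrix(stats::rnorm(2 * n_neg, mean = -sep / 6), ncol = 2))
  X <- (X - min(X)) / (max(X) - min(X))
  colnames(X) <- c("f1", "f2")
  list(X = X, y = c(rep("pos", n_pos), rep("neg", n_neg)))
}

test_that("separable synthetic clusters are learned nearly perfectly", {
  b <- make_blobs(40, 160, sep = 9, seed = 2)
  m <- train_relation_model(b$X, b$y, cost_grid = c(1, 8), gamma_grid = c(0.25, 1),
                            folds = 5, seed = 4)
  expect_gte(max(m$grid$f), 0.95)
  expect_error(train_relation_model(b$X, rep("neg", nrow(b$X))), "both classes")
})

test_that("the class weight trades precision for recall on imbalanced data", {
  b <- make_blobs(25, 225, sep = 2.2, seed = 6)
  recall_at <- function(w) {
    m <- train_relation_model(b$X, b$y, cost_grid = 1, gamma_grid = 0.5,
                              folds = 5, class_weight = w, seed = 9)
    prob <- stats::plogis(m$platt[1] + m$platt[2] * m$oof$dv)
    sum(prob >= 0.5 & b$y == "pos") / sum(b$y == "pos")
  }
  expect_gte(recall_at(5), recall_at(1))
})

test_that("training is deterministic for a fixed seed", {
  b <- make_blobs(20, 80, sep = 4, seed = 3)
  m1 <- train_relation_model(b$X, b$y, cost_grid = c(1, 4), gamma_grid = c(0.5, 2),
                             folds = 5, seed = 11)
  m2 <- train_relation_model(b$X, b$y, cost_grid = c(1, 4), gamma_grid = c(0.5, 2),
                             folds = 5, seed = 11)
  expect_identical(m1$cost, m2$cost)
  expect_identical(m1$gamma, m2$gamma)
  expect_identical(m1$oof$dv, m2$oof$dv)
  expect_identical(predict_probabilities(m1, b$X), predict_probabilities(m2, b$X))
})

test_that("threshold tuning reproduces the exhaustive sweep and its tie rule", {
  # craft a model whose out-of-fold probabilities are known exactly
  fake_model <- function(prob, y) {
    list(platt = c(0, 1), oof = list(dv = stats::qlogis(prob), y = y),
         threshold = 0.5)
  }
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    prob <- (sample.int(999, n, TRUE) + 0.41) / 1000   # off the grid: no float ties
    y <- ifelse(stats::runif(n) < 0.4, "pos", "neg")
    if (length(unique(y)) < 2) next
    m <- tune_threshold(fake_model(prob, y))
    want <- oracle_best_threshold(prob, y == "pos")
    got_f <- max(m$threshold_sweep$f)
    expect_equal(got_f, want$f)
    expect_equal(m$threshold, want$threshold)
  }
  # perfectly separated: the lowest maximizing threshold is returned
  m <- tune_threshold(fake_model(c(0.205, 0.305, 0.605, 0.905),
                                 c("neg", "neg", "pos", "pos")))
  expect_equal(m$threshold, 0.31)
  expect_warning(t1 <- tune_threshold(fake_model(0.7, "pos")), "degenerate")
  expect_equal(t1$threshold, 0.5)
})

test_that("prediction respects the threshold and is monotone in it", {
  b <- make_blobs(20, 60, sep = 3, seed = 8)
  inst <- data.frame(doc_id = as.character(seq_len(nrow(b$X))),
                     chem_id = "c", dis_id = "d", stringsAsFactors = FALSE)
  m <- train_relation_model(b$X, b$y, cost_grid = 1, gamma_grid = 0.5,
                            folds = 5, seed = 2)
  all_pos <- predict_relations(m, b$X, inst, threshold = 0)
  expect_identical(nrow(all_pos), nrow(b$X))
  prev <- NULL
  for (t in c(0.9, 0.6, 0.3, 0.05)) {
    cur <- predict_relations(m, b$X, inst, threshold = t)$doc_id
    if (!is.null(prev)) expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("the co-occurrence baseline flags exactly same-sentence pairs", {
  fx <- generate_fixtures(fixture_config(seed = 40, n_docs = 30,
                                         p_relation = 1, p_same_sentence = 1))
  pred <- cooccurrence_baseline(fx$corpus, fx$parses)
  ev <- evaluate_cid(fx$corpus, pred)
  expect_equal(ev$recall, 1)
  fx2 <- generate_fixtures(fixture_config(seed = 41, n_docs = 30,
                                          p_relation = 1, p_same_sentence = 0))
  pred2 <- cooccurrence_baseline(fx2$corpus, fx2$parses)
  ev2 <- evaluate_cid(fx2$corpus, pred2)
  expect_equal(ev2$recall, 0)
})
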