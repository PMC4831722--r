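# Micro-averaged precision / recall / F for relation extraction and for
# disease recognition, plus error listings for manual analysis.

eval_result <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
       precision = p, recall = r, f_score = f,
       zero_denominator = (tp + fp == 0) || (tp + fn == 0))
}

#' Evaluate document-level relation predictions
#'
#' Pools true/false positives and false negatives over `(doc_id, chem_id,
#' dis_id)` triples across all documents (micro-averaging), then computes
#' precision, recall and F-score.  Gold relations with composite identifiers
#' are expanded before comparison.  Predictions for unknown documents are
#' counted as false positives with a warning.
#'
#' @param gold A [pt_corpus()] carrying gold relations.
#' @param predictions `data.frame` with columns `doc_id`, `chem_id`, `dis_id`.
#' @return A result list: `tp`, `fp`, `fn`, `precision`, `recall`, `f_score`.
#' @export
evaluate_cid <- function(gold, predictions) {
  gold_keys <- unlist(lapply(gold$documents, function(d) {
    r <- d$relations
    if (!nrow(r)) return(character())
    paste(d$doc_id, split_expand(r$chem_id), split_expand(r$dis_id), sep = "\t")
  }))
  gold_keys <- unique(gold_keys)
  pred_keys <- unique(paste(predictions$doc_id, predictions$chem_id,
                            predictions$dis_id, sep = "\t"))
  if (!nrow(predictions)) pred_keys <- character()
  known <- vapply(gold$documents, function(d) d$doc_id, "")
  unknown <- setdiff(unique(predictions$doc_id), known)
  if (length(unknown)) {
    warning("predictions for unknown document(s): ",
            paste(unknown, collapse = ", "), " (counted as false positives)",
            call. = FALSE)
  }
  tp <- sum(pred_keys %in% gold_keys)
  eval_result(tp, length(pred_keys) - tp, length(gold_keys) - tp)
}

# expand composite ids elementwise is not needed for relations (single-id by
# construction), but gold files in the wild occasionally carry them
split_expand <- function(ids) vapply(ids, function(x)
  split_composite(x)[1], "", USE.NAMES = FALSE)

#' Evaluate disease recognition and normalization
#'
#' `strict_span`: a predicted mention is a true positive iff its offsets
#' equal a gold disease mention's offsets and the two share at least one
#' concept identifier; matching is one-to-one.  `id_level`: the per-document
#' sets of disease identifiers (composites expanded, sentinel dropped) are
#' compared.
#'
#' @param gold Gold-annotated [pt_corpus()].
#' @param predicted Corpus (or list of documents) with predicted disease
#'   mentions; matched to gold by `doc_id`.
#' @param mode `"strict_span"` or `"id_level"`.
#' @return A result list as in [evaluate_cid()].
#' @export
evaluate_dner <- function(gold, predicted, mode = c("strict_span", "id_level")) {
  mode <- match.arg(mode)
  pred_docs <- if (inherits(predicted, "pt_corpus")) predicted$documents else predicted
  pred_by_id <- stats::setNames(pred_docs, vapply(pred_docs, function(d) d$doc_id, ""))
  tp <- 0L; fp <- 0L; fn <- 0L
  for (g in gold$documents) {
    p <- pred_by_id[[g$doc_id]]
    gm <- g$mentions[g$mentions$type == "disease", , drop = FALSE]
    pm <- if (is.null(p)) mention_table() else
      p$mentions[p$mentions$type == "disease", , drop = FALSE]
    if (mode == "id_level") {
      gids <- unique(setdiff(split_composite(unlist(gm$concept_ids)), SENTINEL_ID))
      pids <- unique(setdiff(split_composite(unlist(pm$concept_ids)), SENTINEL_ID))
      tp <- tp + length(intersect(gids, pids))
      fp <- fp + length(setdiff(pids, gids))
      fn <- fn + length(setdiff(gids, pids))
    } else {
      used <- rep(FALSE, nrow(gm))
      for (i in seq_len(nrow(pm))) {
        hit <- FALSE
        for (j in seq_len(nrow(gm))) {
          if (!used[j] && gm$start[j] == pm$start[i] && gm$end[j] == pm$end[i] &&
              length(intersect(split_composite(gm$concept_ids[[j]]),
                               split_composite(pm$concept_ids[[i]])))) {
            used[j] <- TRUE; hit <- TRUE; break
          }
        }
        if (hit) tp <- tp + 1L else fp <- fp + 1L
      }
      fn <- fn + sum(!used)
    }
  }
  eval_result(tp, fp, fn)
}

#' List false-positive and false-negative relation predictions
#'
#' Deterministically ordered by document id then identifiers; optionally a
#' seeded random sample of each error class for manual review.
#'
#' @param gold Gold [pt_corpus()].
#' @param predictions `data.frame` with `doc_id`, `chem_id`, `dis_id`.
#' @param n Optional sample size per error class.
#' @param seed Seed for the sample.
#' @return `data.frame` with columns `doc_id`, `chem_id`, `dis_id`, `error`
#'   (`"FP"`/`"FN"`).
#' @export
error_listing <- function(gold, predictions, n = NULL, seed = 1L) {
  gold_df <- do.call(rbind, lapply(gold$documents, function(d) {
    if (!nrow(d$relations)) return(NULL)
    data.frame(doc_id = d$doc_id, chem_id = d$relations$chem_id,
               dis_id = d$relations$dis_id, stringsAsFactors = FALSE)
  }))
  if (is.null(gold_df)) gold_df <- data.frame(doc_id = character(),
                                              chem_id = character(),
                                              dis_id = character())
  key <- function(df) paste(df$doc_id, df$chem_id, df$dis_id, sep = "\t")
  pk <- key(predictions); gk <- key(gold_df)
  fp <- predictions[!(pk %in% gk), , drop = FALSE]
  fn <- gold_df[!(gk %in% pk), , drop = FALSE]
  fp$error <- rep("FP", nrow(fp)); fn$error <- rep("FN", nrow(fn))
  out <- rbind(fp[, c("doc_id", "chem_id", "dis_id", "error")],
               fn[, c("doc_id", "chem_id", "dis_id", "error")])
  out <- out[order(out$doc_id, out$chem_id, out$dis_id, out$error), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(n)) {
    pick <- function(df) {
      if (nrow(df) <= n) {
        if (nrow(df) < n) warning("sample size exceeds population; returning all",
                                  call. = FALSE)
        return(df)
      }
      set.seed(seed)
      df[sort(sample.int(nrow(df), n)), , drop = FALSE]
    }
    out <- rbind(pick(out[out$error == "FP", , drop = FALSE]),
                 pick(out[out$error == "FN", , drop = FALSE]))
    rownames(out) <- NULL
  }
  out
}
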