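# Knowledge-graph store with direct/indirect path semantics.
#
# Edges come from a delimited edge list (subject, predicate, object,
# directed flag, source, record count).  Paths of length one (direct) or two
# (indirect, through a single intermediate) are enumerated with orientation
# constraints on one-directional edges; direct paths suppress indirect ones.

#' Load a knowledge graph from a delimited edge list
#'
#' Columns: `subject`, `predicate`, `object`, `directed` (0/1), `source`,
#' `count`.  Rows duplicating (subject, predicate, object, directed, source)
#' have their record counts summed with a warning.  Multi-edges (same node
#' pair, different predicate or source) are allowed; per-source counts are
#' kept as provenance and their sum is the edge's total provenance.
#'
#' @param path Tab-separated file, no header.
#' @return A `kg_graph` object.
#' @export
load_graph <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, header = FALSE, quote = "",
                           colClasses = c("character", "character", "character",
                                          "integer", "character", "integer"),
                           col.names = c("subject", "predicate", "object",
                                         "directed", "source", "count"),
                           fileEncoding = "UTF-8")
  kg_graph(raw)
}

#' Build a knowledge graph from an edge table
#'
#' @param edges `data.frame` with columns `subject`, `predicate`, `object`,
#'   `directed` (0/1 or logical), `source`, `count`.
#' @return A `kg_graph`: an edge table aggregated to one row per
#'   (subject, predicate, object, directed) with total provenance, plus an
#'   adjacency index.
#' @export
kg_graph <- function(edges) {
  need <- c("subject", "predicate", "object", "directed", "source", "count")
  stopifnot(all(need %in% names(edges)))
  if (nrow(edges)) {
    if (any(edges$count < 1)) stop("provenance counts must be >= 1")
    if (any(edges$subject == edges$object)) stop("self-loop edges not allowed")
  }
  # sum duplicated (s,p,o,directed,source) rows
  if (nrow(edges)) {
    key5 <- paste(edges$subject, edges$predicate, edges$object,
                  as.integer(edges$directed), edges$source, sep = "\r")
    if (anyDuplicated(key5)) {
      warning("duplicate edge rows: provenance counts summed", call. = FALSE)
      agg <- stats::aggregate(count ~ key5, data = cbind(edges["count"], key5 = key5), sum)
      first <- edges[!duplicated(key5), , drop = FALSE]
      first$count <- agg$count[match(paste(first$subject, first$predicate,
                                           first$object, as.integer(first$directed),
                                           first$source, sep = "\r"), agg$key5)]
      edges <- first
    }
    # aggregate sources per logical edge
    key4 <- paste(edges$subject, edges$predicate, edges$object,
                  as.integer(edges$directed), sep = "\r")
    ix <- split(seq_len(nrow(edges)), key4)
    rows <- lapply(ix, function(i) {
      data.frame(subject = edges$subject[i[1]], predicate = edges$predicate[i[1]],
                 object = edges$object[i[1]],
                 directed = as.logical(edges$directed[i[1]]),
                 provenance = sum(edges$count[i]), stringsAsFactors = FALSE)
    })
    etab <- do.call(rbind, rows)
    rownames(etab) <- NULL
    etab$sources <- lapply(ix, function(i)
      stats::setNames(edges$count[i], edges$source[i]))
  } else {
    etab <- data.frame(subject = character(), predicate = character(),
                       object = character(), directed = logical(),
                       provenance = integer(), stringsAsFactors = FALSE)
    etab$sources <- list()
  }
  structure(list(edges = etab), class = "kg_graph")
}

#' @export
print.kg_graph <- function(x, ...) {
  cat(sprintf("<kg_graph> %d edges, %d nodes\n", nrow(x$edges),
              length(unique(c(x$edges$subject, x$edges$object)))))
  invisible(x)
}

# edge indices incident to node v (either role)
incident_edges <- function(graph, v) {
  e <- graph$edges
  which(e$subject == v | e$object == v)
}

#' Enumerate knowledge-graph paths between two concepts
#'
#' A direct path is a single edge joining `a` and `b` in either role (a
#' one-directional edge counts whichever of the two is its subject; the
#' orientation is recorded in `forward`).  An indirect path is a chain
#' a - x - b through one intermediate node, where a one-directional first
#' edge must point towards the intermediate (a -> x) and a one-directional
#' second edge away from it (x -> b); two-directional edges impose no
#' constraint.  If any direct path exists, indirect paths are suppressed.
#'
#' @param graph A `kg_graph`.
#' @param a,b Concept identifiers.  Unknown identifiers give an empty result.
#' @return A list of path records, each a list with elements `kind`
#'   (`"direct"`/`"indirect"`), `edges` (edge-row indices), `intermediate`
#'   (node or `NA`), `predicates`, `provenance` (direct: the edge total;
#'   indirect: min over the two edges) and `forward` (direct paths only:
#'   `TRUE` if a two-directional edge or oriented a -> b).
#' @export
find_paths <- function(graph, a, b) {
  e <- graph$edges
  if (a == b) return(list())
  direct_ix <- which((e$subject == a & e$object == b) |
                     (e$subject == b & e$object == a))
  if (length(direct_ix)) {
    return(lapply(direct_ix, function(i) list(
      kind = "direct", edges = i, intermediate = NA_character_,
      predicates = e$predicate[i], provenance = e$provenance[i],
      forward = !e$directed[i] || (e$subject[i] == a && e$object[i] == b))))
  }
  # indirect: a - x - b
  first <- which((e$subject == a) | (!e$directed & e$object == a))
  out <- list()
  for (i in first) {
    x <- if (e$subject[i] == a) e$object[i] else e$subject[i]
    if (x == b) next
    second <- which(((e$subject == x & e$object == b) & e$directed) |
                    ((!e$directed) & ((e$subject == x & e$object == b) |
                                      (e$subject == b & e$object == x))))
    for (j in second) {
      out[[length(out) + 1L]] <- list(
        kind = "indirect", edges = c(i, j), intermediate = x,
        predicates = c(e$predicate[i], e$predicate[j]),
        provenance = min(e$provenance[i], e$provenance[j]),
        forward = NA)
    }
  }
  out
}

#' Score a knowledge-graph path
#'
#' The default `"log-provenance"` scorer sums `log(1 + total provenance)`
#' over the path's edges; `"raw-provenance"` sums the totals; `"constant-1"`
#' scores every path 1.  The scorer is pluggable because confidence formulas
#' differ between graph platforms; any deterministic function of the edge
#' provenance totals preserves the feature semantics.
#'
#' @param graph A `kg_graph`.
#' @param path A path record from [find_paths()].
#' @param scorer Name or function(edge provenance totals) -> number.
#' @return A number.
#' @export
score_path <- function(graph, path, scorer = "log-provenance") {
  prov <- graph$edges$provenance[path$edges]
  if (is.function(scorer)) return(scorer(prov))
  switch(scorer,
    "log-provenance" = sum(log1p(prov)),
    "raw-provenance" = sum(prov),
    "constant-1" = 1,
    stop("unknown scorer: ", scorer))
}

#' Prior-knowledge features for a concept pair
#'
#' Aggregates the paths between `a` and `b`: the path type (direct if any
#' direct path exists, else indirect if any, else none), the maximum path
#' score, the number of paths, the union of predicates, and the maximum path
#' provenance count (a direct path's provenance is its edge's total; an
#' indirect path's is the minimum over its two edges).
#'
#' @inheritParams score_path
#' @param a,b Concept identifiers.
#' @return A list: `path_type`, `score`, `n_paths`, `predicates`,
#'   `provenance_count`, `forward` (any direct path oriented a -> b).
#' @export
path_features <- function(graph, a, b, scorer = "log-provenance") {
  paths <- find_paths(graph, a, b)
  if (!length(paths)) {
    return(list(path_type = "none", score = 0, n_paths = 0L,
                predicates = character(), provenance_count = 0L,
                forward = FALSE))
  }
  scores <- vapply(paths, function(p) score_path(graph, p, scorer), 1)
  list(path_type = paths[[1]]$kind,
       score = max(scores),
       n_paths = length(paths),
       predicates = sort(unique(unlist(lapply(paths, `[[`, "predicates")))),
       provenance_count = max(vapply(paths, `[[`, 1, "provenance")),
       forward = any(vapply(paths, function(p) isTRUE(p$forward), TRUE)))
}

#' Knowledge-base relation baseline
#'
#' Predicts a chemical-disease pair as related iff the two concepts are
#' joined by a direct edge whose predicate is not a treatment predicate.
#'
#' @param graph A `kg_graph`.
#' @param pairs `data.frame` with columns `doc_id`, `chem_id`, `dis_id`.
#' @param treatment_predicates Character vector, e.g. `c("treats", "prevents")`.
#' @return The subset of `pairs` predicted positive.
#' @export
kb_baseline_predict <- function(graph, pairs,
                                treatment_predicates = c("treats", "prevents")) {
  e <- graph$edges
  pos <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$chem_id[i]; b <- pairs$dis_id[i]
    ix <- which((e$subject == a & e$object == b) |
                (e$subject == b & e$object == a))
    any(!(e$predicate[ix] %in% treatment_predicates))
  }, TRUE)
  pairs[pos, , drop = FALSE]
}
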