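# CoNLL-U reading and dependency-tree validation.
#
# Parses are an input artifact: 10-column CoNLL-U with `# doc_id = <id>`
# comments separating documents and MISC-column character offsets
# `start=<n>|end=<n>` (0-based, end-exclusive, into the document text).

#' Read dependency parses from a CoNLL-U file
#'
#' Sentences are grouped under the preceding `# doc_id = <id>` comment.
#' Multiword-token and empty-node lines (ids containing `-` or `.`) are
#' skipped.  Every sentence is validated: exactly one root (head 0) and no
#' cycles; a violation is an error naming the document and sentence.
#'
#' @param path CoNLL-U file.
#' @return A named list mapping doc_id to a list of `sentence_parse` objects
#'   (data.frames with columns `id`, `form`, `upos`, `head`, `deprel`,
#'   `start`, `end`).
#' @export
read_conllu <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  docs <- list()
  cur_doc <- NULL
  cur_rows <- list()
  sent_no <- 0L
  flush_sentence <- function() {
    if (!length(cur_rows)) return()
    sent_no <<- sent_no + 1L
    df <- do.call(rbind, lapply(cur_rows, function(r)
      data.frame(id = r$id, form = r$form, upos = r$upos, head = r$head,
                 deprel = r$deprel, start = r$start, end = r$end,
                 stringsAsFactors = FALSE)))
    rownames(df) <- NULL
    validate_parse(df, cur_doc, length(docs[[cur_doc]] %||% list()))
    docs[[cur_doc]][[length(docs[[cur_doc]]) + 1L]] <<-
      structure(df, class = c("sentence_parse", "data.frame"))
    cur_rows <<- list()
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (startsWith(line, "#")) {
      m <- regmatches(line, regexec("^#\\s*doc_id\\s*=\\s*(\\S+)", line))[[1]]
      if (length(m) == 2L) {
        flush_sentence()
        cur_doc <- m[2]
        if (is.null(docs[[cur_doc]])) docs[[cur_doc]] <- list()
      }
      next
    }
    if (line == "") { flush_sentence(); next }
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 10L) stop("line ", i, ": expected 10 CoNLL-U fields")
    if (grepl("[-.]", f[1])) next
    if (is.null(cur_doc)) stop("line ", i, ": token line before any doc_id comment")
    misc <- f[10]
    off <- c(NA_integer_, NA_integer_)
    mm <- regmatches(misc, regexec("start=(\\d+)\\|end=(\\d+)", misc))[[1]]
    if (length(mm) == 3L) off <- as.integer(mm[2:3])
    cur_rows[[length(cur_rows) + 1L]] <-
      list(id = as.integer(f[1]), form = f[2], upos = f[4],
           head = as.integer(f[7]), deprel = f[8],
           start = off[1], end = off[2])
  }
  flush_sentence()
  docs
}

validate_parse <- function(df, doc_id = "?", sent_ix = 0L) {
  where <- sprintf("document %s, sentence %d", doc_id %||% "?", sent_ix + 1L)
  if (sum(df$head == 0L) != 1L) stop(where, ": parse must have exactly one root")
  if (any(df$head == df$id)) stop(where, ": token is its own head")
  if (any(!(df$head %in% c(0L, df$id)))) stop(where, ": head index out of range")
  # cycle check: follow head chain from every token
  n <- nrow(df)
  heads <- stats::setNames(df$head, df$id)
  for (t in df$id) {
    seen <- 0L; cur <- t
    while (cur != 0L) {
      cur <- heads[[as.character(cur)]]
      seen <- seen + 1L
      if (seen > n) stop(where, ": cycle in head chain starting at token ", t)
    }
  }
  invisible(df)
}

#' Construct a sentence parse from vectors
#'
#' Convenience constructor for hand-authored trees (fixtures, tests).
#'
#' @param form Token strings.
#' @param upos Part-of-speech tags (UPOS like `"VERB"` or Penn like `"VBD"`).
#' @param head 1-based head indices, 0 for the root.
#' @param deprel Dependency labels.
#' @param start,end Optional 0-based character offsets into the document text.
#' @return A `sentence_parse` data.frame.
#' @export
sentence_parse <- function(form, upos, head, deprel,
                           start = rep(NA_integer_, length(form)),
                           end = rep(NA_integer_, length(form))) {
  df <- data.frame(id = seq_along(form), form = form, upos = upos,
                   head = as.integer(head), deprel = deprel,
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  validate_parse(df)
  structure(df, class = c("sentence_parse", "data.frame"))
}

#' Write parses back to CoNLL-U
#' @param parses Named list (doc_id -> list of `sentence_parse`).
#' @param path Output path.
#' @export
write_conllu <- function(parses, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  out <- character()
  for (doc_id in names(parses)) {
    out <- c(out, paste0("# doc_id = ", doc_id))
    for (s in parses[[doc_id]]) {
      misc <- ifelse(is.na(s$start), "_",
                     sprintf("start=%d|end=%d", s$start, s$end))
      out <- c(out, sprintf("%d\t%s\t_\t%s\t_\t_\t%d\t%s\t_\t%s",
                            s$id, s$form, s$upos, s$head, s$deprel, misc), "")
    }
  }
  writeLines(out, con, useBytes = TRUE)
  invisible(NULL)
}
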