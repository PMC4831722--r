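# Small in-code builders shared by the unit tests.

# A two-mention document: chemical in the title or abstract, disease in the
# abstract, with explicit offsets computed from the strings.
make_pair_doc <- function(doc_id = "1001",
                          title = "Aspirin study",
                          abstract = "Aspirin induced asthma.",
                          chem = "Aspirin", chem_id = "D9001",
                          dis = "asthma", dis_id = "D9002",
                          relations = NULL) {
  text <- paste(title, abstract, sep = " ")
  cpos <- regexpr(chem, text, fixed = TRUE)
  dpos <- regexpr(dis, text, fixed = TRUE)
  m <- mention_table(
    start = c(cpos - 1L, dpos - 1L),
    end = c(cpos - 1L + nchar(chem), dpos - 1L + nchar(dis)),
    text = c(chem, dis), type = c("chemical", "disease"),
    concept_ids = list(chem_id, dis_id))
  r <- if (is.null(relations)) relation_table(chem_id, dis_id) else relations
  pt_document(doc_id, title, abstract, m, r)
}

# write a PubTator file from text lines and read it back
read_pubtator_lines <- function(lines) {
  tmp <- tempfile(fileext = ".pubtator")
  writeLines(lines, tmp)
  on.exit(unlink(tmp))
  read_pubtator(tmp)
}

tsv_file <- function(df) {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), tmp)
  tmp
}

# concept-span table in the recognizer's internal layout
span_table_for_tests <- function(rows) cidre:::span_table(rows)

# a tiny edge-table graph for path tests
graph_from_rows <- function(...) {
  rows <- list(...)
  suppressWarnings(kg_graph(do.call(rbind, lapply(rows, function(r)
    data.frame(subject = r[[1]], predicate = r[[2]], object = r[[3]],
               directed = as.integer(r[[4]]),
               source = if (length(r) > 4) r[[5]] else "src",
               count = if (length(r) > 5) as.integer(r[[6]]) else 1L,
               stringsAsFactors = FALSE)))))
}
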