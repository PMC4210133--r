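#' Default free-text fields of a ClinicalTrials.gov study record
#'
#' The registry's public XML schema mixes structured and free-text elements;
#' these are the free-text ones whose character content is concatenated into
#' a record's analysable text. The set is configurable in every reader.
#'
#' @return character vector of XML element names.
#' @export
default_text_fields <- function() {
  c("brief_title", "official_title", "brief_summary", "detailed_description",
    "condition", "intervention_type", "intervention_name", "keyword")
}

#' Parse one ClinicalTrials.gov study record
#'
#' Extracts the NCT identifier and the character content of the configured
#' free-text fields from a study-record XML document. Field contents are
#' whitespace-trimmed and joined by single newlines in document order; the
#' newline acts as a hard field boundary downstream (bigrams never cross it).
#' Absent fields are skipped silently.
#'
#' @param xml path to an XML file, an XML string, or an `xml2` document.
#' @param fields character vector of element names to extract, in the sense of
#'   [default_text_fields()].
#' @return a `ct_record`: list with `nct_id`, `text` and `source_fields` (the
#'   configured fields actually found, in document order).
#' @examples
#' rec <- parse_ct_record(
#'   "<clinical_study><id_info><nct_id>NCT00000001</nct_id></id_info>
#'    <brief_summary><textblock>Liposomal doxorubicin study</textblock>
#'    </brief_summary></clinical_study>")
#' rec$text
#' @export
parse_ct_record <- function(xml, fields = default_text_fields()) {
  doc <- if (inherits(xml, "xml_document")) xml else xml2::read_xml(xml)
  id_node <- xml2::xml_find_first(doc, ".//nct_id")
  if (inherits(id_node, "xml_missing")) {
    stop("invalid record: no <nct_id> element found")
  }
  nct_id <- trimws(xml2::xml_text(id_node))
  if (!grepl("^NCT[0-9]{8}$", nct_id)) {
    stop("invalid record: malformed NCT identifier: ", dQuote(nct_id))
  }
  xpath <- paste0(".//", fields, collapse = " | ")
  nodes <- xml2::xml_find_all(doc, xpath)
  contents <- trimws(gsub("[[:space:]]+", " ", xml2::xml_text(nodes)))
  used <- xml2::xml_name(nodes)[nzchar(contents)]
  contents <- contents[nzchar(contents)]
  structure(
    list(nct_id = nct_id,
         text = paste(contents, collapse = "\n"),
         source_fields = used),
    class = "ct_record"
  )
}

#' @export
print.ct_record <- function(x, ...) {
  cat("<ct_record>", x$nct_id, "-", length(x$source_fields), "fields,",
      nchar(x$text), "characters of text\n")
  invisible(x)
}

#' Read all study records under a directory
#'
#' @param path directory containing `*.xml` study records, or a character
#'   vector of file paths.
#' @param fields passed to [parse_ct_record()].
#' @return list of `ct_record` objects.
#' @export
read_ct_records <- function(path, fields = default_text_fields()) {
  files <- if (length(path) == 1L && dir.exists(path)) {
    list.files(path, pattern = "\\.xml$", full.names = TRUE)
  } else {
    path
  }
  lapply(files, parse_ct_record, fields = fields)
}

#' Load a label table mapping NCT identifiers to classes
#'
#' Reads a delimited text file (comma or tab separated, with a header) whose
#' columns include `nct_id` and `label`. Duplicate identifiers and labels
#' outside the permitted alphabet are errors.
#'
#' @param path file path.
#' @param classes the permitted label alphabet (two values).
#' @return named character vector mapping `nct_id` to label, with a `counts`
#'   attribute giving the per-class record counts.
#' @export
load_label_table <- function(path, classes = c("nano", "non-nano")) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (!all(c("nct_id", "label") %in% names(tab))) {
    stop("label table must have columns `nct_id` and `label`")
  }
  ids <- trimws(as.character(tab$nct_id))
  labels <- trimws(as.character(tab$label))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate nct_id in label table: ", paste(unique(dup), collapse = ", "))
  }
  bad <- setdiff(unique(labels), classes)
  if (length(bad) > 0) {
    stop("unrecognized label(s): ", paste(bad, collapse = ", "),
         " (expected one of: ", paste(classes, collapse = ", "), ")")
  }
  out <- stats::setNames(labels, ids)
  counts <- table(factor(labels, levels = classes))
  attr(out, "counts") <- stats::setNames(as.integer(counts), names(counts))
  message("label table: ",
          paste(sprintf("%s=%d", names(counts), as.integer(counts)),
                collapse = ", "))
  out
}

#' Construct a labeled corpus
#'
#' A `labeled_corpus` is an ordered collection of records (NCT identifier plus
#' concatenated text) with a parallel class label, stored as a data frame
#' sorted by `nct_id` so downstream fold assignment is reproducible.
#'
#' @param nct_id character vector of unique record identifiers.
#' @param text character vector of record texts.
#' @param label character vector of class labels.
#' @return a `labeled_corpus` (data frame with columns `nct_id`, `text`,
#'   `label`).
#' @export
labeled_corpus <- function(nct_id, text, label) {
  if (length(nct_id) != length(text) || length(nct_id) != length(label)) {
    stop("nct_id, text and label must have equal length")
  }
  if (anyDuplicated(nct_id)) {
    stop("duplicate nct_id in corpus: ",
         paste(unique(nct_id[duplicated(nct_id)]), collapse = ", "))
  }
  if (anyNA(label) || anyNA(nct_id)) stop("labels and ids must be non-missing")
  ord <- order(nct_id)
  structure(
    data.frame(nct_id = as.character(nct_id)[ord],
               text = as.character(text)[ord],
               label = as.character(label)[ord],
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("labeled_corpus", "data.frame")
  )
}

#' @export
print.labeled_corpus <- function(x, ...) {
  counts <- table(x$label)
  cat("<labeled_corpus> ", nrow(x), " records (",
      paste(sprintf("%s: %d", names(counts), as.integer(counts)),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Assemble parsed records and a label map into a labeled corpus
#'
#' @param records list of `ct_record` objects.
#' @param label_map named character vector (from [load_label_table()]).
#' @param strict if `TRUE` (default), a record without a label is an error;
#'   if `FALSE`, unlabeled records are dropped with a message.
#' @return a [labeled_corpus()].
#' @export
assemble_corpus <- function(records, label_map, strict = TRUE) {
  ids <- vapply(records, `[[`, character(1), "nct_id")
  texts <- vapply(records, `[[`, character(1), "text")
  unlabeled <- setdiff(ids, names(label_map))
  if (length(unlabeled) > 0) {
    if (strict) {
      stop("records without a label: ", paste(unlabeled, collapse = ", "))
    }
    message("skipping ", length(unlabeled), " unlabeled record(s): ",
            paste(unlabeled, collapse = ", "))
    keep <- !(ids %in% unlabeled)
    ids <- ids[keep]
    texts <- texts[keep]
  }
  labeled_corpus(ids, texts, unname(label_map[ids]))
}

#' Write / read a corpus as JSON lines
#'
#' One JSON object per line with keys `nct_id`, `text`, `label` — the on-disk
#' interchange format between pipeline stages.
#'
#' @param corpus a [labeled_corpus()].
#' @param path file path.
#' @return `write_corpus_jsonl` returns `path` invisibly; `read_corpus_jsonl`
#'   returns a [labeled_corpus()].
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(list(nct_id = corpus$nct_id[i],
                          text = corpus$text[i],
                          label = corpus$label[i]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  objs <- lapply(lines, jsonlite::fromJSON)
  labeled_corpus(
    nct_id = vapply(objs, `[[`, character(1), "nct_id"),
    text = vapply(objs, `[[`, character(1), "text"),
    label = vapply(objs, `[[`, character(1), "label")
  )
}
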