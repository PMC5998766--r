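# Reading and writing DDIExtraction-2013 style XML corpora and prediction
# tables. This is the only file that touches on-disk formats.

#' Read a DDI-style annotated XML corpus
#'
#' Parses the DDIExtraction-2013 XML dialect (`document` > `sentence` >
#' `entity` / `pair` elements) into an in-memory corpus object. Entity
#' `charOffset` attributes are 0-based inclusive character ranges,
#' semicolon-separated for discontinuous mentions; they are converted
#' internally to 0-based half-open intervals. Pair labels are normalised to
#' the five-class set: `ddi="false"` becomes `"none"`, `ddi="true"` with a
#' `type` attribute becomes that type, and `ddi="true"` without a type is
#' mapped to the catch-all class `"int"` with a warning.
#'
#' Unknown XML attributes are ignored. Structural problems (a pair
#' referencing an unknown entity id, an offset outside the sentence text)
#' raise errors naming the offending element.
#'
#' @param source Path to an XML file, a URL-free connection, or a length-1
#'   character string containing XML.
#' @return An object of class `ddi_corpus`: a list with elements
#'   `documents` (list of `list(id, sentences)`) and `provenance`.
#'   Each sentence is a list with `id`, `text`, `mentions` (each mention a
#'   list with `id`, `text`, `spans` -- a two-column matrix of half-open
#'   0-based intervals -- and `discontinuous`) and `pairs` (each pair a list
#'   with `id`, `e1`, `e2`, `label`).
#' @seealso [write_ddi_corpus()], [ddi_synthetic_corpus()]
#' @export
read_ddi_corpus <- function(source) {
  if (is.character(source) && length(source) == 1L &&
      grepl("^\\s*<", source)) {
    doc <- xml2::read_xml(source)
  } else {
    doc <- xml2::read_xml(source)
  }
  docs <- xml2::xml_find_all(doc, ".//document")
  if (length(docs) == 0L && xml2::xml_name(doc) == "document")
    docs <- list(doc)
  seen_sent <- character(0)
  documents <- lapply(docs, function(dn) {
    did <- xml2::xml_attr(dn, "id")
    sents <- lapply(xml2::xml_find_all(dn, "./sentence"), parse_sentence_node)
    list(id = did, sentences = sents)
  })
  sids <- unlist(lapply(documents, function(d)
    vapply(d$sentences, `[[`, "", "id")))
  dup <- sids[duplicated(sids)]
  if (length(dup))
    stop("duplicate sentence id(s): ", paste(unique(dup), collapse = ", "))
  structure(list(documents = documents,
                 provenance = if (is.character(source) && file.exists(source))
                   source else "in-memory"),
            class = "ddi_corpus")
}

parse_sentence_node <- function(sn) {
  sid <- xml2::xml_attr(sn, "id")
  text <- xml2::xml_attr(sn, "text")
  if (is.na(text)) text <- ""
  mentions <- lapply(xml2::xml_find_all(sn, "./entity"), function(en) {
    eid <- xml2::xml_attr(en, "id")
    off <- xml2::xml_attr(en, "charOffset")
    spans <- parse_char_offset(off, eid)
    if (any(spans[, 2] > nchar(text)) || any(spans[, 1] < 0))
      stop("entity '", eid, "': charOffset '", off,
           "' outside sentence text (", nchar(text), " chars)")
    list(id = eid,
         text = xml2::xml_attr(en, "text"),
         spans = spans,
         discontinuous = nrow(spans) > 1L)
  })
  ids <- vapply(mentions, `[[`, "", "id")
  pairs <- lapply(xml2::xml_find_all(sn, "./pair"), function(pn) {
    pid <- xml2::xml_attr(pn, "id")
    e1 <- xml2::xml_attr(pn, "e1")
    e2 <- xml2::xml_attr(pn, "e2")
    if (!e1 %in% ids || !e2 %in% ids)
      stop("pair '", pid, "' references unknown entity id")
    if (identical(e1, e2))
      stop("pair '", pid, "' references the same entity twice")
    ddi <- xml2::xml_attr(pn, "ddi")
    type <- xml2::xml_attr(pn, "type")
    label <- if (identical(tolower(ddi), "true")) {
      if (is.na(type) || !nzchar(type)) {
        warning("pair '", pid, "' is ddi=\"true\" without a type; ",
                "labelled 'int'", call. = FALSE)
        "int"
      } else type
    } else "none"
    check_labels(label)
    list(id = pid, e1 = e1, e2 = e2, label = label)
  })
  list(id = sid, text = text, mentions = mentions, pairs = pairs)
}

# "0-9;25-40" (0-based inclusive) -> half-open matrix; spans sorted,
# non-overlapping
parse_char_offset <- function(off, eid) {
  if (is.na(off) || !nzchar(off))
    stop("entity '", eid, "' has no charOffset")
  parts <- strsplit(off, ";", fixed = TRUE)[[1]]
  m <- t(vapply(parts, function(p) {
    se <- suppressWarnings(as.integer(strsplit(p, "-", fixed = TRUE)[[1]]))
    if (length(se) != 2L || anyNA(se))
      stop("entity '", eid, "': malformed charOffset '", off, "'")
    c(se[1], se[2] + 1L)  # inclusive end -> half-open
  }, integer(2)))
  dimnames(m) <- list(NULL, c("start", "end"))
  m <- m[order(m[, 1]), , drop = FALSE]
  if (nrow(m) > 1L && any(m[-nrow(m), 2] > m[-1, 1]))
    stop("entity '", eid, "': overlapping charOffset spans '", off, "'")
  m
}

#' Serialize a corpus back to DDI-style XML
#'
#' Inverse of [read_ddi_corpus()] for the fields the pipeline consumes;
#' `serialize` then `parse` is lossless for sentences, mentions and pairs.
#'
#' @param corpus A `ddi_corpus`.
#' @param path Optional file path; if `NULL` the XML is returned as a
#'   character string.
#' @return Invisibly, the XML as a single character string.
#' @export
write_ddi_corpus <- function(corpus, path = NULL) {
  stopifnot(inherits(corpus, "ddi_corpus"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>", "<corpus>")
  for (d in corpus$documents) {
    lines <- c(lines, sprintf("  <document id=\"%s\">", esc(d$id)))
    for (s in d$sentences) {
      lines <- c(lines, sprintf("    <sentence id=\"%s\" text=\"%s\">",
                                esc(s$id), esc(s$text)))
      for (m in s$mentions) {
        off <- paste(sprintf("%d-%d", m$spans[, 1], m$spans[, 2] - 1L),
                     collapse = ";")
        lines <- c(lines, sprintf(
          "      <entity id=\"%s\" charOffset=\"%s\" type=\"drug\" text=\"%s\"/>",
          esc(m$id), off, esc(m$text)))
      }
      for (p in s$pairs) {
        attr_tail <- if (p$label == "none") " ddi=\"false\"" else
          sprintf(" ddi=\"true\" type=\"%s\"", p$label)
        lines <- c(lines, sprintf(
          "      <pair id=\"%s\" e1=\"%s\" e2=\"%s\"%s/>",
          esc(p$id), esc(p$e1), esc(p$e2), attr_tail))
      }
      lines <- c(lines, "    </sentence>")
    }
    lines <- c(lines, "  </document>")
  }
  lines <- c(lines, "</corpus>")
  xml <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) writeLines(xml, path, sep = "")
  invisible(xml)
}

#' @export
print.ddi_corpus <- function(x, ...) {
  ns <- sum(vapply(x$documents, function(d) length(d$sentences), 0L))
  np <- sum(unlist(lapply(x$documents, function(d)
    vapply(d$sentences, function(s) length(s$pairs), 0L))), 0L)
  nm <- sum(unlist(lapply(x$documents, function(d)
    vapply(d$sentences, function(s) length(s$mentions), 0L))), 0L)
  cat("DDI corpus: ", length(x$documents), " document(s), ", ns,
      " sentence(s), ", nm, " drug mention(s), ", np,
      " candidate pair(s)\n", sep = "")
  cat("source:", x$provenance, "\n")
  invisible(x)
}

# flat list of all sentences in a corpus
corpus_sentences <- function(corpus) {
  unlist(lapply(corpus$documents, `[[`, "sentences"), recursive = FALSE)
}

#' Write per-instance predictions as TSV
#'
#' One row per candidate pair: sentence id, pair id, optional gold label,
#' predicted label, and the five class scores (softmax probabilities).
#' Row order follows the input. Duplicate pair ids are an error.
#'
#' @param predictions Data frame with columns `sentence_id`, `pair_id`,
#'   optionally `gold`, `predicted`, and one `score_<class>` column per
#'   class in [DDI_CLASSES].
#' @param path File path or connection.
#' @return Invisibly, `predictions`.
#' @export
write_ddi_predictions <- function(predictions, path) {
  need <- c("sentence_id", "pair_id", "predicted",
            paste0("score_", DDI_CLASSES))
  miss <- setdiff(need, names(predictions))
  if (length(miss))
    stop("predictions missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(predictions$pair_id))
    stop("duplicate pair id(s) in predictions")
  cols <- intersect(c("sentence_id", "pair_id", "gold", "predicted",
                      paste0("score_", DDI_CLASSES)), names(predictions))
  utils::write.table(predictions[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(predictions)
}

#' Read back a predictions TSV
#' @param path File path.
#' @return Data frame as written by [write_ddi_predictions()].
#' @export
read_ddi_predictions <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
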