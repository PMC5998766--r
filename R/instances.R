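# Candidate-pair instance generation (entity blinding), the rule-based
# negative-instance filter, and corpus-level dataset preparation.

FILTER_REASONS <- c("none", "coordination", "apposition", "discontinuous")

#' Generate blinded relation instances for one sentence
#'
#' One instance per annotated pair. In each instance the pair's first
#' entity is replaced by the token `drug1`, the second by `drug2`, and
#' every other drug mention in the sentence by `drug0` (entity blinding).
#' Instances whose pair touches a discontinuous mention are marked
#' `filtered = "discontinuous"`: the network input cannot represent a
#' two-part mention, so such pairs are removed from training rather than
#' encoded.
#'
#' @param sentence A sentence as produced by [read_ddi_corpus()].
#' @return List of relation instances (class `ddi_instance`), each a list
#'   with `sentence_id`, `pair_id`, `tokens`, `p1`, `p2` (1-based token
#'   indices of `drug1`/`drug2`), `label`, `filtered` (one of
#'   `r paste(FILTER_REASONS, collapse=", ")`) and `dropped_mentions`.
#' @export
ddi_instances <- function(sentence) {
  lapply(sentence$pairs, function(pr) {
    ids <- vapply(sentence$mentions, `[[`, "", "id")
    m1 <- sentence$mentions[[match(pr$e1, ids)]]
    m2 <- sentence$mentions[[match(pr$e2, ids)]]
    others <- sentence$mentions[!ids %in% c(pr$e1, pr$e2)]
    # targets first: their blinding wins over overlapping other mentions
    tk <- ddi_tokenize(sentence$text, c(list(m1, m2), others))
    toks <- tk$tokens
    p1 <- tk$mention_tokens[[pr$e1]]
    p2 <- tk$mention_tokens[[pr$e2]]
    toks[p1] <- "drug1"
    toks[p2] <- "drug2"
    for (om in others) {
      pos <- tk$mention_tokens[om$id]
      if (!is.na(pos)) toks[pos] <- "drug0"
    }
    filtered <- if (m1$discontinuous || m2$discontinuous)
      "discontinuous" else "none"
    structure(list(sentence_id = sentence$id, pair_id = pr$id,
                   tokens = toks, p1 = p1, p2 = p2, label = pr$label,
                   filtered = filtered, dropped_mentions = tk$dropped),
              class = "ddi_instance")
  })
}

#' @export
print.ddi_instance <- function(x, ...) {
  cat(x$pair_id, " [", x$label, "]",
      if (x$filtered != "none") paste0(" (filtered: ", x$filtered, ")"),
      "\n  ", paste(x$tokens, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Default negative-instance filter rules
#'
#' Token-level regular expressions, applied to the space-joined blinded
#' token sequence, that recognise candidate pairs which cannot interact:
#'
#' * **coordination** -- `drug1` and `drug2` are conjuncts of the same
#'   and/or structure (only commas, `and`, `or` and other drug mentions
#'   between them). The rule is blocked when `drug1` is the object of a
#'   `between ... and ...` frame, where `and` links the two interacting
#'   drugs rather than conjuncts.
#' * **apposition** -- a hyponymous apposition: a trigger (`such as`,
#'   `including`, `like`, `e.g.`) or a parenthetical list links `drug1` to
#'   a list containing `drug2`.
#'
#' The original system's expressions were never published; these defaults
#' are an auditable stand-in operating on blinded tokens, and can be
#' replaced or extended via a config file (see [read_ddi_filter_rules()]).
#'
#' @param coordination,apposition Character vectors of Perl-compatible
#'   regular expressions; each must mention both `drug1` and `drug2`.
#' @return Object of class `ddi_filter_rules`.
#' @export
ddi_filter_rules <- function(coordination = NULL, apposition = NULL) {
  conj <- "(?: (?:,|and|or|drug0))*"
  trig <- "(?:such as|including|like|e g)"
  if (is.null(coordination)) coordination <- c(
    paste0("(?<!between )drug1(?: (?:,|drug0))* (?:and|or)", conj, " drug2"),
    paste0("(?<!between )drug2(?: (?:,|drug0))* (?:and|or)", conj, " drug1"))
  if (is.null(apposition)) apposition <- c(
    paste0("drug1 (?:, )?", trig, conj, " drug2"),
    paste0("drug2 (?:, )?", trig, conj, " drug1"),
    paste0("drug1 \\( (?:(?:,|and|or|drug0|e g|such as|including|like) )*drug2"))
  rules <- structure(list(coordination = coordination,
                          apposition = apposition),
                     class = "ddi_filter_rules")
  validate_rules(rules)
  rules
}

validate_rules <- function(rules) {
  for (reason in c("coordination", "apposition")) {
    for (p in rules[[reason]]) {
      ok <- tryCatch({suppressWarnings(grepl(p, "", perl = TRUE)); TRUE},
                     error = function(e) FALSE)
      if (!ok) stop("invalid ", reason, " pattern: ", p)
      if (!grepl("drug1", p, fixed = TRUE) ||
          !grepl("drug2", p, fixed = TRUE))
        stop(reason, " pattern must reference drug1 and drug2: ", p)
    }
  }
  invisible(rules)
}

#' @export
print.ddi_filter_rules <- function(x, ...) {
  cat("DDI negative-filter rules:", length(x$coordination),
      "coordination,", length(x$apposition), "apposition pattern(s)\n")
  invisible(x)
}

#' Read / write filter rules as plain text
#'
#' One pattern per line, `reason<TAB>pattern`, reason `coordination` or
#' `apposition`. Blank lines and `#` comments are ignored.
#'
#' @param path File path.
#' @return `read_ddi_filter_rules()` returns a `ddi_filter_rules` object.
#' @export
read_ddi_filter_rules <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 0L) != 2L
  if (any(bad)) stop("malformed rule line(s): ",
                     paste(lines[bad], collapse = "; "))
  reason <- vapply(parts, `[[`, "", 1L)
  pat <- vapply(parts, `[[`, "", 2L)
  if (!all(reason %in% c("coordination", "apposition")))
    stop("rule reasons must be 'coordination' or 'apposition'")
  ddi_filter_rules(coordination = pat[reason == "coordination"],
                   apposition = pat[reason == "apposition"])
}

#' @rdname read_ddi_filter_rules
#' @param rules A `ddi_filter_rules` object.
#' @export
write_ddi_filter_rules <- function(rules, path) {
  stopifnot(inherits(rules, "ddi_filter_rules"))
  lines <- c(paste("coordination", rules$coordination, sep = "\t"),
             paste("apposition", rules$apposition, sep = "\t"))
  writeLines(lines, path)
  invisible(rules)
}

#' Apply the negative-instance filter to one instance
#'
#' Marks the instance `filtered = "coordination"` or `"apposition"` when a
#' rule matches the blinded token sequence; an already-filtered instance
#' (e.g. discontinuous) is returned unchanged, and filtering never alters
#' the tokens. Coordination rules are tried before apposition rules.
#'
#' @param instance A `ddi_instance`.
#' @param rules A [ddi_filter_rules()] object.
#' @return The instance, with `filtered` possibly set.
#' @export
ddi_apply_filter <- function(instance, rules = ddi_filter_rules()) {
  stopifnot(inherits(instance, "ddi_instance"))
  if (instance$filtered != "none") return(instance)
  hay <- paste0(" ", paste(instance$tokens, collapse = " "), " ")
  for (reason in c("coordination", "apposition")) {
    for (p in rules[[reason]]) {
      if (grepl(p, hay, perl = TRUE)) {
        instance$filtered <- reason
        return(instance)
      }
    }
  }
  instance
}

#' Prepare a corpus for training: instances, filtering, audit
#'
#' Runs instance generation and (optionally) the negative filter over every
#' sentence of a corpus, and tabulates an audit of filtered instances by
#' reason and gold label -- so mistaken filtering of true interactions is
#' directly measurable.
#'
#' @param corpus A `ddi_corpus`.
#' @param rules A [ddi_filter_rules()] object, or `NULL` to skip the
#'   coordination/apposition filter (discontinuous pairs are always
#'   removed).
#' @return Object of class `ddi_dataset`: list with `instances` (all
#'   generated instances), `kept` (those with `filtered == "none"`), and
#'   `audit` (data frame `reason`, `label`, `count`).
#' @export
ddi_prepare <- function(corpus, rules = ddi_filter_rules()) {
  stopifnot(inherits(corpus, "ddi_corpus"))
  instances <- unlist(lapply(corpus_sentences(corpus), ddi_instances),
                      recursive = FALSE)
  if (is.null(instances)) instances <- list()
  if (!is.null(rules))
    instances <- lapply(instances, ddi_apply_filter, rules = rules)
  reason <- vapply(instances, `[[`, "", "filtered")
  label <- vapply(instances, `[[`, "", "label")
  audit <- as.data.frame(table(
    reason = factor(reason, levels = FILTER_REASONS),
    label = factor(label, levels = DDI_CLASSES)),
    responseName = "count", stringsAsFactors = FALSE)
  structure(list(instances = instances,
                 kept = instances[reason == "none"],
                 audit = audit),
            class = "ddi_dataset")
}

#' @export
print.ddi_dataset <- function(x, ...) {
  nf <- length(x$instances) - length(x$kept)
  cat("DDI dataset: ", length(x$instances), " instance(s), ",
      length(x$kept), " kept, ", nf, " filtered\n", sep = "")
  flt <- x$audit[x$audit$reason != "none" & x$audit$count > 0, ]
  if (nrow(flt)) {
    cat("filtered by reason x gold label:\n")
    print(flt, row.names = FALSE)
  }
  invisible(x)
}

#' Write the filter audit as TSV
#' @param dataset A `ddi_dataset`.
#' @param path File path.
#' @export
write_ddi_audit <- function(dataset, path) {
  utils::write.table(dataset$audit, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dataset)
}
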