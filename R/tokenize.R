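# Tokenization and normalisation of DDI sentences. Mentions are collapsed to
# single tokens before normalisation so multi-word drug names survive as one
# position; the rest of the text is lower-cased, standalone numbers become
# the literal token "NUM", commas and parentheses are kept as their own
# tokens (the negative-filter rules need them) and all other special
# characters are stripped.

MARK <- "\x01"  # sentinel delimiting collapsed mention tokens

#' Tokenize and normalise a sentence
#'
#' Lower-cases the text, replaces every standalone number by the token
#' `"NUM"`, keeps commas and parentheses as separate tokens, strips all
#' other punctuation and special characters, and collapses each drug
#' mention to a single token (multi-word surfaces joined with `_`). For a
#' discontinuous mention the first span carries the token and the remaining
#' spans are deleted. A mention overlapping an earlier-listed mention is
#' dropped from the alignment (earlier mentions win; callers put the target
#' pair first).
#'
#' Normalisation is idempotent: re-tokenizing the space-joined token
#' sequence reproduces it.
#'
#' @param text Raw sentence string.
#' @param mentions List of mention objects as in a [read_ddi_corpus()]
#'   sentence (`id`, `spans` half-open 0-based matrix). May be empty.
#' @return List with `tokens` (character vector), `mention_tokens` (named
#'   integer vector, mention id -> 1-based token index) and `dropped`
#'   (character vector of mention ids dropped because of overlap).
#' @export
ddi_tokenize <- function(text, mentions = list()) {
  stopifnot(is.character(text), length(text) == 1L)
  accepted <- list()
  dropped <- character(0)
  occupied <- matrix(numeric(0), ncol = 2)
  for (m in mentions) {
    sp <- m$spans
    clash <- FALSE
    if (nrow(occupied))
      for (i in seq_len(nrow(sp)))
        if (any(sp[i, 1] < occupied[, 2] & sp[i, 2] > occupied[, 1]))
          clash <- TRUE
    if (clash) {
      dropped <- c(dropped, m$id)
    } else {
      accepted[[length(accepted) + 1L]] <- m
      occupied <- rbind(occupied, sp)
    }
  }
  # replace mention regions with sentinel markers, editing from the right so
  # earlier offsets stay valid
  edits <- list()
  for (k in seq_along(accepted)) {
    sp <- accepted[[k]]$spans
    marker <- paste0(MARK, index_code(k), MARK)
    edits[[length(edits) + 1L]] <- list(start = sp[1, 1], end = sp[1, 2],
                                        repl = paste0(" ", marker, " "))
    if (nrow(sp) > 1L)  # discontinuous: delete trailing spans
      for (i in 2:nrow(sp))
        edits[[length(edits) + 1L]] <- list(start = sp[i, 1], end = sp[i, 2],
                                            repl = " ")
  }
  if (length(edits)) {
    ord <- order(vapply(edits, `[[`, 0, "start"), decreasing = TRUE)
    for (e in edits[ord])
      text <- paste0(substr(text, 1L, e$start),
                     e$repl,
                     substr(text, e$end + 1L, nchar(text)))
  }
  toks <- normalize_tokens(text)
  mention_tokens <- integer(0)
  for (k in seq_along(accepted)) {
    marker <- paste0(MARK, index_code(k), MARK)
    pos <- which(toks == marker)
    if (length(pos) != 1L)
      stop("alignment failure for mention '", accepted[[k]]$id, "'")
    surface <- mention_token(accepted[[k]])
    toks[pos] <- surface
    mention_tokens[accepted[[k]]$id] <- pos
  }
  list(tokens = toks, mention_tokens = mention_tokens, dropped = dropped)
}

index_code <- function(k) chartr("0123456789", "abcdefghij", as.character(k))

# normalised single-token form of a mention surface
mention_token <- function(m) {
  s <- tolower(paste(m$text, collapse = " "))
  s <- gsub("[^a-z0-9]+", "_", s)
  s <- gsub("^_+|_+$", "", s)
  if (!nzchar(s)) "_" else s
}

# the character-level normaliser shared by ddi_tokenize and the idempotence
# contract
normalize_tokens <- function(text) {
  x <- tolower(text)
  # standalone numbers (ints or decimals) -> num; '_' counts as word-internal
  x <- gsub("(?<![a-z0-9_])[0-9]+(\\.[0-9]+)?(?![a-z0-9_])", " num ", x,
            perl = TRUE)
  x <- gsub("([,()])", " \\1 ", x)
  x <- gsub(paste0("[^a-z0-9_,()", MARK, "]+"), " ", x)
  toks <- strsplit(trimws(x), "[ ]+")[[1]]
  toks <- toks[nzchar(toks)]
  toks[toks == "num"] <- "NUM"
  toks
}
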