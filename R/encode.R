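# Fixed-length encoding: vocabulary, relative positions and their
# regrouping into non-negative indices, padding and truncation.

PAD_TOKEN <- "<pad>"
UNK_TOKEN <- "<unk>"
PAD_ID <- 1L
UNK_ID <- 2L
PAD_POS <- 0L  # reserved position code for pad tokens (regrouped range is
               # 1 .. 2n-1, so 0 is free)

#' Build a vocabulary from training instances
#'
#' Deterministic (sorted insertion): every distinct training token gets an
#' index, after the two reserved entries for the padding token and the
#' unknown-word token that absorbs unseen test tokens.
#'
#' @param instances List of `ddi_instance` (typically `$kept` from
#'   [ddi_prepare()]), or a character vector of tokens.
#' @return Named integer vector of class `ddi_vocab` mapping token to
#'   index; indices are dense in `1..|V|` with `<pad> = 1`, `<unk> = 2`.
#' @export
ddi_vocab <- function(instances) {
  toks <- if (is.character(instances)) instances
          else unlist(lapply(instances, `[[`, "tokens"))
  if (length(toks) == 0L) stop("cannot build a vocabulary: no tokens")
  words <- sort(unique(toks))
  words <- setdiff(words, c(PAD_TOKEN, UNK_TOKEN))
  v <- seq_len(length(words) + 2L)
  names(v) <- c(PAD_TOKEN, UNK_TOKEN, words)
  class(v) <- "ddi_vocab"
  v
}

#' @export
print.ddi_vocab <- function(x, ...) {
  cat("DDI vocabulary:", length(x), "entries (incl. <pad>, <unk>)\n")
  invisible(x)
}

# token -> index, unseen -> UNK
vocab_lookup <- function(vocab, tokens) {
  i <- unclass(vocab)[tokens]
  i[is.na(i)] <- UNK_ID
  unname(i)
}

#' Save / load a vocabulary as a two-column text file
#' @param vocab A `ddi_vocab`.
#' @param path File path (`token<TAB>index`).
#' @export
write_ddi_vocab <- function(vocab, path) {
  writeLines(paste(names(vocab), unclass(vocab), sep = "\t"), path)
  invisible(vocab)
}

#' @rdname write_ddi_vocab
#' @export
read_ddi_vocab <- function(path) {
  parts <- strsplit(readLines(path), "\t", fixed = TRUE)
  v <- as.integer(vapply(parts, `[[`, "", 2L))
  names(v) <- vapply(parts, `[[`, "", 1L)
  if (v[PAD_TOKEN] != PAD_ID || v[UNK_TOKEN] != UNK_ID)
    stop("corrupt vocabulary file: reserved entries out of place")
  class(v) <- "ddi_vocab"
  v
}

#' Signed relative positions of a token to the two target drugs
#'
#' For token index `i` and target positions `p1`, `p2` the distances are
#' `i - p1` and `i - p2` (e.g. a token four places after `drug1` and two
#' before `drug2` has distances 4 and -2).
#'
#' @param i Token index (vectorised).
#' @param p1,p2 Indices of the `drug1`/`drug2` tokens (same origin as `i`).
#' @return A two-column integer matrix with columns `d1`, `d2`.
#' @export
ddi_relative_positions <- function(i, p1, p2) {
  cbind(d1 = as.integer(i - p1), d2 = as.integer(i - p2))
}

#' Regroup a signed distance into a non-negative index
#'
#' Maps the distance range `(-n+1, n-1)` affinely onto `(1, 2n-1)` so
#' position-embedding tables need no negative indices: `d -> d + n`.
#' Distances outside the range (possible after truncation) clip to the
#' boundary rather than fail.
#'
#' @param d Signed distance(s).
#' @param n Maximum sentence length.
#' @return Integer index/indices in `1..(2n-1)`.
#' @export
ddi_regroup <- function(d, n) {
  as.integer(pmin(pmax(d, -n + 1L), n - 1L) + n)
}

#' Encoder configuration
#'
#' @param n Maximum sentence length; shorter instances are padded to `n`,
#'   longer ones truncated around the target pair.
#' @param m_e Word embedding dimension.
#' @param m_d Position embedding dimension (each of the two tables).
#' @return List of class `ddi_encoder_config`.
#' @export
ddi_encoder_config <- function(n = 128L, m_e = 300L, m_d = 5L) {
  stopifnot(n >= 2, m_e >= 1, m_d >= 1)
  structure(list(n = as.integer(n), m_e = as.integer(m_e),
                 m_d = as.integer(m_d)),
            class = "ddi_encoder_config")
}

#' Encode a kept instance as fixed-length index sequences
#'
#' Tokens become word indices (unseen tokens map to `<unk>`), positions are
#' computed relative to the two targets and regrouped, and the three
#' sequences are padded to length `n` with the pad word index and the
#' reserved pad position code 0. Sentences longer than `n` are truncated
#' symmetrically around the target span so both targets survive; if the
#' targets cannot both fit, `NULL` is returned (the instance is dropped).
#'
#' @param instance A kept `ddi_instance`.
#' @param vocab A [ddi_vocab()].
#' @param config A [ddi_encoder_config()].
#' @return List of class `ddi_encoded` with `word_ids`, `pos1_ids`,
#'   `pos2_ids` (length-`n` integer vectors; position ids are regrouped
#'   codes in `0..2n-1`, 0 for padding), `label_id` (1..5 in the order of
#'   [DDI_CLASSES]), `p1`, `p2`, `pad_start` and the instance ids; or
#'   `NULL` if the pair cannot fit in `n` tokens.
#' @export
ddi_encode <- function(instance, vocab, config) {
  stopifnot(inherits(instance, "ddi_instance"),
            inherits(config, "ddi_encoder_config"))
  n <- config$n
  toks <- instance$tokens
  p1 <- instance$p1
  p2 <- instance$p2
  len <- length(toks)
  if (len > n) {
    lo <- min(p1, p2); hi <- max(p1, p2)
    if (hi - lo + 1L > n) return(NULL)
    start <- lo - ((n - (hi - lo + 1L)) %/% 2L)
    start <- max(1L, min(start, len - n + 1L))
    toks <- toks[start:(start + n - 1L)]
    p1 <- p1 - start + 1L
    p2 <- p2 - start + 1L
    len <- n
  }
  word_ids <- c(vocab_lookup(vocab, toks), rep(PAD_ID, n - len))
  idx <- seq_len(len)
  pos1 <- c(ddi_regroup(idx - p1, n), rep(PAD_POS, n - len))
  pos2 <- c(ddi_regroup(idx - p2, n), rep(PAD_POS, n - len))
  structure(list(word_ids = word_ids, pos1_ids = pos1, pos2_ids = pos2,
                 label_id = match(instance$label, DDI_CLASSES),
                 p1 = p1, p2 = p2, pad_start = len + 1L,
                 sentence_id = instance$sentence_id,
                 pair_id = instance$pair_id),
            class = "ddi_encoded")
}

# encode a list of instances, silently dropping the (rare) unencodable ones
ddi_encode_set <- function(instances, vocab, config) {
  enc <- lapply(instances, ddi_encode, vocab = vocab, config = config)
  keep <- !vapply(enc, is.null, TRUE)
  out <- enc[keep]
  attr(out, "n_dropped") <- sum(!keep)
  out
}
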