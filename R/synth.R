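# Seeded generator of DDI-style corpora with known ground truth. Sentences
# are built from class-specific trigger templates, so the class of every
# candidate pair is determined by the trigger phrase (a known learnability
# ceiling of 1.0), and planted coordination / apposition / discontinuous
# structures come with per-pair truth of which filter rule must fire.

# syllable pools for pseudo-drug names (single alphabetic tokens, disjoint
# from all template vocabulary)
DRUG_PRE <- c("zal", "dor", "mek", "vel", "tri", "lom", "fex", "cab",
              "rin", "sul", "pra", "quin", "tor", "bena", "cli", "xan")
DRUG_SUF <- c("azole", "imab", "avir", "astin", "omicin", "epril",
              "olol", "idone", "oxetine", "icillin", "azepam", "eparin")

# template catalogue ---------------------------------------------------------
# Plain templates: one class-bearing trigger, targets X and Y, optional
# third drug Z via the multi-drug suffix. All blind to token sequences no
# filter rule matches.
PLAIN_TEMPLATES <- list(
  mechanism = c(
    "{X} inhibits the metabolism of {Y}",
    "{X} decreases the renal clearance of {Y}",
    "{X} markedly increases the plasma concentration of {Y}"),
  effect = c(
    "{X} increases the hypotensive effect of {Y}",
    "{X} potentiates the sedative action of {Y}",
    "{X} enhances the anticoagulant response to {Y}"),
  advice = c(
    "{X} should not be administered together with {Y}",
    "caution is recommended when {X} is combined with {Y}",
    "concurrent use of {X} with {Y} should be avoided"),
  int = c(
    "{X} interacts with {Y}",
    "a significant interaction between {X} and {Y} was reported in 2 studies"),
  none = c(
    "{X} did not alter the pharmacokinetics of {Y}",
    "no interaction between {X} and {Y} was observed in 12 patients",
    "{X} was administered in the morning and {Y} was given at night"))

MULTI_SUFFIX <- " in patients also receiving {Z}"

# structural templates carry per-pair truth: (slot1, slot2, label, planted)
COORD_TEMPLATES <- list(
  list(text = "{A} and {B} were coadministered during the study",
       pairs = list(c("A", "B", "none", "coordination"))),
  list(text = "{A} and {B} or {C} were given concomitantly",
       pairs = list(c("A", "B", "none", "coordination"),
                    c("A", "C", "none", "coordination"),
                    c("B", "C", "none", "coordination"))),
  list(text = "treatment with {A} or {B} was continued for 5 days",
       pairs = list(c("A", "B", "none", "coordination"))))

APPOS_TEMPLATES <- list(
  list(text = "{G}, such as {A} and {B}, are often given prophylactically",
       pairs = list(c("G", "A", "none", "apposition"),
                    c("G", "B", "none", "apposition"),
                    c("A", "B", "none", "coordination"))),
  list(text = "{G}, including {A}, should be used with caution",
       pairs = list(c("G", "A", "none", "apposition"))),
  list(text = "{G} (e.g. {A} and {B}) may cause drowsiness",
       pairs = list(c("G", "A", "none", "apposition"),
                    c("G", "B", "none", "apposition"),
                    c("A", "B", "none", "coordination"))))

FILLER <- " and the dose was adjusted according to the clinical response"

#' Generate a synthetic DDI-style corpus with known ground truth
#'
#' Emits the same XML dialect [read_ddi_corpus()] parses, together with a
#' truth table listing every candidate pair, its gold class and -- for
#' planted coordination, apposition and discontinuous structures -- the
#' filter reason that must fire on it. Sentence classes are determined by
#' trigger phrases, so a classifier can in principle reach F1 = 1 unless
#' `label_noise` is set. Fully deterministic for a given seed (the caller's
#' RNG state is restored on exit).
#'
#' @param n_sentences Number of sentences.
#' @param class_mix Named probability vector over [DDI_CLASSES] for plain
#'   (non-structural) sentences; must sum to 1.
#' @param p_multi Probability that a plain sentence carries a third drug
#'   (adding two `none` pairs).
#' @param p_coordination,p_apposition,p_discontinuous Probabilities that a
#'   sentence is a planted coordination list, hyponymous apposition, or
#'   contains a discontinuous mention.
#' @param n_drugs Size of the pseudo-drug name pool.
#' @param label_noise Probability of replacing a plain sentence's gold
#'   class by a random different one ("hard mode": breaks separability).
#' @param length_mode `"natural"` leaves template lengths; `"bimodal"` pads
#'   half the sentences with filler clauses up to `max_tokens` words, the
#'   padding-stress condition for pooling experiments.
#' @param max_tokens Approximate token target for padded sentences.
#' @param sentences_per_doc Sentences grouped per document.
#' @param seed Integer seed.
#' @return Object of class `ddi_synth`: list with `corpus` (a
#'   `ddi_corpus`), `xml` (the corpus serialized, byte-identical per
#'   seed), and `truth` (data frame `sentence_id`, `pair_id`, `label`,
#'   `planted` in `none`/`coordination`/`apposition`/`discontinuous`).
#' @export
ddi_synthetic_corpus <- function(n_sentences,
                                 class_mix = c(mechanism = 0.15,
                                               effect = 0.15,
                                               advice = 0.15,
                                               int = 0.15, none = 0.40),
                                 p_multi = 0.2,
                                 p_coordination = 0.10,
                                 p_apposition = 0.05,
                                 p_discontinuous = 0.05,
                                 n_drugs = 40L,
                                 label_noise = 0,
                                 length_mode = c("natural", "bimodal"),
                                 max_tokens = 40L,
                                 sentences_per_doc = 8L,
                                 seed = 1L) {
  length_mode <- match.arg(length_mode)
  stopifnot(n_sentences >= 0,
            abs(sum(class_mix) - 1) < 1e-8,
            setequal(names(class_mix), DDI_CLASSES),
            p_multi >= 0, p_multi <= 1,
            p_coordination >= 0, p_apposition >= 0, p_discontinuous >= 0,
            p_coordination + p_apposition + p_discontinuous <= 1,
            label_noise >= 0, label_noise <= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  drugs <- unique(paste0(
    sample(DRUG_PRE, n_drugs * 3L, replace = TRUE),
    sample(DRUG_SUF, n_drugs * 3L, replace = TRUE)))[seq_len(n_drugs)]

  sentences <- vector("list", n_sentences)
  truth <- vector("list", n_sentences)
  for (i in seq_len(n_sentences)) {
    sid <- sprintf("synth.d%d.s%d",
                   (i - 1L) %/% sentences_per_doc + 1L,
                   (i - 1L) %% sentences_per_doc)
    structure_kind <- sample(
      c("coordination", "apposition", "discontinuous", "plain"), 1L,
      prob = c(p_coordination, p_apposition, p_discontinuous,
               1 - p_coordination - p_apposition - p_discontinuous))
    s <- switch(structure_kind,
      plain = synth_plain(sid, drugs, class_mix, p_multi, label_noise),
      coordination = synth_structural(sid, drugs, COORD_TEMPLATES),
      apposition = synth_structural(sid, drugs, APPOS_TEMPLATES),
      discontinuous = synth_discontinuous(sid, drugs))
    if (length_mode == "bimodal" && stats::runif(1) < 0.5)
      s$sentence <- pad_sentence(s$sentence, max_tokens)
    sentences[[i]] <- s$sentence
    truth[[i]] <- s$truth
  }

  docs <- list()
  if (n_sentences > 0) {
    grp <- (seq_len(n_sentences) - 1L) %/% sentences_per_doc + 1L
    docs <- lapply(unique(grp), function(g)
      list(id = sprintf("synth.d%d", g), sentences = sentences[grp == g]))
  }
  corpus <- structure(list(documents = docs, provenance = "synthetic"),
                      class = "ddi_corpus")
  truth_df <- if (n_sentences > 0) do.call(rbind, truth) else
    data.frame(sentence_id = character(0), pair_id = character(0),
               label = character(0), planted = character(0),
               stringsAsFactors = FALSE)
  structure(list(corpus = corpus, xml = write_ddi_corpus(corpus),
                 truth = truth_df),
            class = "ddi_synth")
}

#' @export
print.ddi_synth <- function(x, ...) {
  cat("Synthetic DDI corpus:\n")
  print(x$corpus)
  if (nrow(x$truth)) {
    cat("pairs by gold label:\n")
    print(table(x$truth$label))
    if (any(x$truth$planted != "none")) {
      cat("planted filter structures:\n")
      print(table(x$truth$planted[x$truth$planted != "none"]))
    }
  }
  invisible(x)
}

# --- internal sentence builders --------------------------------------------

# fill "{X}"-style slots, recording half-open character spans per slot
fill_template <- function(template, fills) {
  m <- gregexpr("\\{[A-Z]\\}", template)[[1]]
  text <- ""
  spans <- list()
  prev_end <- 0L
  if (m[1] != -1L) {
    for (j in seq_along(m)) {
      text <- paste0(text, substr(template, prev_end + 1L, m[j] - 1L))
      slot <- substr(template, m[j] + 1L, m[j] + 1L)
      surf <- fills[[slot]]
      spans[[slot]] <- c(start = nchar(text), end = nchar(text) + nchar(surf))
      text <- paste0(text, surf)
      prev_end <- m[j] + 2L
    }
  }
  text <- paste0(text, substr(template, prev_end + 1L, nchar(template)))
  list(text = text, spans = spans)
}

make_sentence <- function(sid, text, ent_slots, spans, surfaces, pair_defs) {
  mentions <- lapply(seq_along(ent_slots), function(j) {
    slot <- ent_slots[j]
    sp <- matrix(spans[[slot]], 1L, 2L,
                 dimnames = list(NULL, c("start", "end")))
    list(id = sprintf("%s.e%d", sid, j - 1L), text = surfaces[[slot]],
         spans = sp, discontinuous = FALSE)
  })
  eid <- function(slot) sprintf("%s.e%d", sid, match(slot, ent_slots) - 1L)
  pairs <- lapply(seq_along(pair_defs), function(j) {
    pd <- pair_defs[[j]]
    list(id = sprintf("%s.p%d", sid, j - 1L), e1 = eid(pd[1]),
         e2 = eid(pd[2]), label = pd[3])
  })
  sentence <- list(id = sid, text = text, mentions = mentions, pairs = pairs)
  truth <- data.frame(
    sentence_id = sid,
    pair_id = vapply(pairs, `[[`, "", "id"),
    label = vapply(pair_defs, `[[`, "", 3L),
    planted = vapply(pair_defs, `[[`, "", 4L),
    stringsAsFactors = FALSE)
  list(sentence = sentence, truth = truth)
}

synth_plain <- function(sid, drugs, class_mix, p_multi, label_noise) {
  label <- sample(names(class_mix), 1L, prob = class_mix)
  template <- sample(PLAIN_TEMPLATES[[label]], 1L)
  multi <- stats::runif(1) < p_multi
  if (multi) template <- paste0(template, MULTI_SUFFIX)
  picked <- sample(drugs, if (multi) 3L else 2L)
  if (label_noise > 0 && stats::runif(1) < label_noise)
    label <- sample(setdiff(DDI_CLASSES, label), 1L)
  fills <- list(X = picked[1], Y = picked[2])
  if (multi) fills$Z <- picked[3]
  ft <- fill_template(template, fills)
  pair_defs <- list(c("X", "Y", label, "none"))
  if (multi) pair_defs <- c(pair_defs, list(c("X", "Z", "none", "none"),
                                            c("Y", "Z", "none", "none")))
  make_sentence(sid, ft$text, names(fills), ft$spans, fills, pair_defs)
}

synth_structural <- function(sid, drugs, templates) {
  tp <- templates[[sample(length(templates), 1L)]]
  slots <- unique(regmatches(tp$text,
                             gregexpr("(?<=\\{)[A-Z](?=\\})", tp$text,
                                      perl = TRUE))[[1]])
  picked <- sample(drugs, length(slots))
  fills <- as.list(picked)
  names(fills) <- slots
  if ("G" %in% slots) fills$G <- paste0(fills$G, "s")  # hypernym plural
  ft <- fill_template(tp$text, fills)
  make_sentence(sid, ft$text, slots, ft$spans, fills, tp$pairs)
}

# a discontinuous mention shares its head noun with the sentence frame:
# "oral or topical <H> preparations ..." annotates the discontinuous drug
# "oral ... <H>" (two spans) interacting with a second, continuous drug
synth_discontinuous <- function(sid, drugs) {
  picked <- sample(drugs, 2L)
  variant <- sample(2L, 1L)
  if (variant == 1L) {
    pre <- "oral or topical "
    mid <- " preparations may interact with "
    first_word <- "oral"
    label <- "none"
  } else {
    pre <- "either intravenous or oral "
    mid <- " therapy may reduce the effect of "
    first_word <- "intravenous"
    label <- "effect"
  }
  h <- picked[1]; c2 <- picked[2]
  text <- paste0(pre, h, mid, c2)
  sp1 <- matrix(c(regexpr(first_word, text, fixed = TRUE) - 1L,
                  regexpr(first_word, text, fixed = TRUE) - 1L +
                    nchar(first_word),
                  nchar(pre), nchar(pre) + nchar(h)),
                2L, 2L, byrow = TRUE,
                dimnames = list(NULL, c("start", "end")))
  sp2 <- matrix(c(nchar(pre) + nchar(h) + nchar(mid), nchar(text)),
                1L, 2L, dimnames = list(NULL, c("start", "end")))
  mentions <- list(
    list(id = sprintf("%s.e0", sid), text = paste(first_word, h),
         spans = sp1, discontinuous = TRUE),
    list(id = sprintf("%s.e1", sid), text = c2, spans = sp2,
         discontinuous = FALSE))
  pairs <- list(list(id = sprintf("%s.p0", sid),
                     e1 = sprintf("%s.e0", sid),
                     e2 = sprintf("%s.e1", sid), label = label))
  sentence <- list(id = sid, text = text, mentions = mentions, pairs = pairs)
  truth <- data.frame(sentence_id = sid, pair_id = sprintf("%s.p0", sid),
                      label = label, planted = "discontinuous",
                      stringsAsFactors = FALSE)
  list(sentence = sentence, truth = truth)
}

# padding-stress: lengthen the text with drug-free filler clauses; entity
# offsets are unaffected because filler is appended at the end
pad_sentence <- function(sentence, max_tokens) {
  n_tok <- length(strsplit(sentence$text, " ", fixed = TRUE)[[1]])
  fill_len <- length(strsplit(trimws(FILLER), " ", fixed = TRUE)[[1]])
  reps <- max(0L, (max_tokens - n_tok) %/% fill_len)
  if (reps > 0)
    sentence$text <- paste0(sentence$text,
                            paste(rep(FILLER, reps), collapse = ""))
  sentence
}
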