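# tokenization, entity blinding and negative-instance filtering

test_that("numbers become NUM and punctuation is stripped", {
  expect_equal(ddi_tokenize("Take 10 mg daily.")$tokens,
               c("take", "NUM", "mg", "daily"))
  expect_equal(ddi_tokenize("dosed at 2.5 mg/kg!")$tokens,
               c("dosed", "at", "NUM", "mg", "kg"))
})

test_that("mentions collapse to single aligned tokens", {
  s <- make_test_sentence("DRUG-X increases Y", "DRUG-X", list())
  tk <- ddi_tokenize(s$text, s$mentions)
  expect_equal(unname(tk$mention_tokens["e1"]), 1L)
  expect_equal(tk$tokens[1], "drug_x")
  s2 <- make_test_sentence("beta adrenergic blockers reduce effects",
                           "beta adrenergic blockers", list())
  tk2 <- ddi_tokenize(s2$text, s2$mentions)
  expect_equal(tk2$tokens[1], "beta_adrenergic_blockers")
  expect_length(tk2$tokens, 3L)
})

test_that("normalisation is idempotent on generated sentences", {
  syn <- ddi_synthetic_corpus(150, length_mode = "bimodal", seed = 31)
  for (s in ddipool:::corpus_sentences(syn$corpus)) {
    t1 <- ddi_tokenize(s$text)$tokens
    t2 <- ddipool:::normalize_tokens(paste(t1, collapse = " "))
    expect_identical(t2, t1)
  }
})

test_that("overlapping non-target mentions are dropped, targets win", {
  text <- "peripheral adrenergic blockers reduce pressure with reserpine"
  mentions <- list(
    list(id = "tgt", text = "peripheral adrenergic blockers",
         spans = matrix(c(0L, 30L), 1, 2,
                        dimnames = list(NULL, c("start", "end"))),
         discontinuous = FALSE),
    list(id = "nested", text = "adrenergic blockers",
         spans = matrix(c(11L, 30L), 1, 2,
                        dimnames = list(NULL, c("start", "end"))),
         discontinuous = FALSE))
  tk <- ddi_tokenize(text, mentions)
  expect_equal(tk$dropped, "nested")
  expect_equal(unname(tk$mention_tokens["tgt"]), 1L)
})

test_that("entity blinding reproduces the three worked instances", {
  text <- paste("Interaction on the antinociceptive effect between",
                "neurotensin and enkephalins or tuftsin")
  s <- make_test_sentence(text,
                          c("neurotensin", "enkephalins", "tuftsin"),
                          list(c("e1", "e2", "effect"),
                               c("e1", "e3", "none"),
                               c("e2", "e3", "none")))
  inst <- ddi_instances(s)
  strings <- vapply(inst, function(x) paste(x$tokens, collapse = " "), "")
  stem <- "interaction on the antinociceptive effect between"
  expect_equal(strings, paste(stem, c("drug1 and drug2 or drug0",
                                      "drug1 and drug0 or drug2",
                                      "drug0 and drug1 or drug2")))
  # the pair in the same coordinate structure, and only it, is filtered
  filt <- vapply(lapply(inst, ddi_apply_filter), `[[`, "", "filtered")
  expect_equal(filt, c("none", "none", "coordination"))
})

test_that("hyponymous apposition removes all pairs of the example", {
  text <- paste("Anticoagulants, such as heparin and warfarin, are often",
                "given prophylactically to prevent DVT")
  s <- make_test_sentence(text, c("Anticoagulants", "heparin", "warfarin"),
                          list(c("e1", "e2", "none"),
                               c("e1", "e3", "none"),
                               c("e2", "e3", "none")))
  filt <- vapply(lapply(ddi_instances(s), ddi_apply_filter),
                 `[[`, "", "filtered")
  expect_setequal(unique(filt), c("apposition", "coordination"))
  expect_false(any(filt == "none"))
})

test_that("plain trigger instances are not filtered", {
  s <- make_test_sentence("azathioprine increases the effect of warfarin",
                          c("azathioprine", "warfarin"),
                          list(c("e1", "e2", "effect")))
  inst <- ddi_apply_filter(ddi_instances(s)[[1]])
  expect_equal(inst$filtered, "none")
  # filtering never alters tokens
  coord <- make_test_sentence("heparin and warfarin were used",
                              c("heparin", "warfarin"),
                              list(c("e1", "e2", "none")))
  before <- ddi_instances(coord)[[1]]
  after <- ddi_apply_filter(before)
  expect_equal(after$filtered, "coordination")
  expect_identical(after$tokens, before$tokens)
})

test_that("blinding is complete: placeholders only, surfaces gone", {
  syn <- ddi_synthetic_corpus(80, seed = 17)
  ds <- ddi_prepare(read_ddi_corpus(syn$xml))
  for (inst in ds$instances) {
    expect_equal(sum(inst$tokens == "drug1"), 1L)
    expect_equal(sum(inst$tokens == "drug2"), 1L)
    expect_equal(inst$tokens[inst$p1], "drug1")
    expect_equal(inst$tokens[inst$p2], "drug2")
  }
  # no generated drug surface survives in any token sequence
  surfaces <- unlist(lapply(ddipool:::corpus_sentences(syn$corpus),
    function(s) vapply(s$mentions, `[[`, "", "text")))
  toks <- unique(unlist(lapply(ds$instances, `[[`, "tokens")))
  expect_length(intersect(tolower(surfaces), toks), 0L)
})

test_that("prepare conserves instances and audits planted structures", {
  syn <- ddi_synthetic_corpus(120, seed = 23)
  ds <- ddi_prepare(read_ddi_corpus(syn$xml))
  expect_equal(length(ds$instances), nrow(syn$truth))
  expect_equal(length(ds$kept) +
                 sum(vapply(ds$instances, `[[`, "", "filtered") != "none"),
               length(ds$instances))
  got <- data.frame(
    pair_id = vapply(ds$instances, `[[`, "", "pair_id"),
    filtered = vapply(ds$instances, `[[`, "", "filtered"))
  m <- merge(syn$truth, got, by = "pair_id")
  expect_identical(m$filtered, m$planted)
  # the audit table agrees with the raw counts
  for (r in seq_len(nrow(ds$audit))) {
    expect_equal(ds$audit$count[r],
                 sum(got$filtered == ds$audit$reason[r] &
                       vapply(ds$instances, `[[`, "", "label") ==
                         ds$audit$label[r]))
  }
})

test_that("enlarging the rule set never unfilters an instance", {
  syn <- ddi_synthetic_corpus(60, seed = 29)
  corp <- read_ddi_corpus(syn$xml)
  full <- ddi_filter_rules()
  smaller <- ddi_filter_rules(
    coordination = full$coordination[1],
    apposition = full$apposition[1])
  f_small <- vapply(ddi_prepare(corp, smaller)$instances, `[[`, "",
                    "filtered")
  f_full <- vapply(ddi_prepare(corp, full)$instances, `[[`, "", "filtered")
  expect_true(all(f_full[f_small != "none"] != "none"))
})

test_that("rules validate and round-trip through a config file", {
  expect_error(ddi_filter_rules(coordination = "drug1 only"),
               "drug1 and drug2")
  expect_error(ddi_filter_rules(coordination = "drug1 (drug2"), "invalid")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  rules <- ddi_filter_rules()
  write_ddi_filter_rules(rules, tmp)
  back <- read_ddi_filter_rules(tmp)
  expect_equal(back$coordination, rules$coordination)
  expect_equal(back$apposition, rules$apposition)
})

test_that("discontinuous pairs are marked for removal", {
  syn <- ddi_synthetic_corpus(200, p_discontinuous = 0.3, seed = 41)
  ds <- ddi_prepare(read_ddi_corpus(syn$xml))
  disc <- vapply(ds$instances, `[[`, "", "filtered") == "discontinuous"
  expect_equal(sum(disc), sum(syn$truth$planted == "discontinuous"))
  expect_gt(sum(disc), 0L)
})
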