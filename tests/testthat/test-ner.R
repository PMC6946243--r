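# Dictionary NER: lexicon loading, tagging rules, conjunction resolution.

test_that("lexicon loads, indexes aliases and drops ambiguous ones", {
  lex <- humanLexicon()
  expect_s4_class(lex, "GeneLexicon")
  expect_equal(nrow(lexiconEntries(lex)), 12L)
  # ambiguous alias across two genes is removed and reported
  expect_message(
    amb <- makeLexicon(data.frame(
      gene_id = c("1", "2"), symbol = c("A1", "B1"),
      synonyms = c("p53", "p53"), stringsAsFactors = FALSE)),
    "ambiguous")
  expect_false("p53" %in% amb@index$alias)
  expect_true(all(c("a1", "b1") %in% amb@index$key))
})

test_that("duplicate gene_id in a lexicon is rejected", {
  expect_error(makeLexicon(data.frame(gene_id = c("1", "1"),
                                      symbol = c("A", "B"),
                                      synonyms = "")),
               "duplicate gene_id")
})

test_that("lexicon TSV round-trips and stop list filters aliases", {
  lex <- humanLexicon()
  f <- tempfile(fileext = ".tsv")
  writeLexicon(lex, f)
  back <- readLexicon(f)
  expect_equal(lexiconEntries(back), lexiconEntries(lex))
  sl <- tempfile()
  writeLines("INS", sl)
  noIns <- readLexicon(f, stopListPath = sl)
  expect_false("ins" %in% noIns@index$key)
  expect_true("insulin" %in% noIns@index$alias)
})

test_that("tagging is token-bounded, longest-match and normalizes aliases", {
  lex <- humanLexicon()
  corp <- smallCorpus(list(
    title = "T.",
    abstract = paste("VEGFA and IL6 levels.",
                     "High interleukin 6 here.",
                     "TNFRSF1A was assayed.",
                     "The word pill6like is not a gene.")))
  men <- tagMentions(corp, lex)
  expect_setequal(men$gene_id[men$sentence_index == 2],
                  c("7422", "3569"))
  # multi-word synonym normalized to IL6's id
  expect_equal(men$gene_id[men$sentence_index == 3], "3569")
  expect_equal(men$surface[men$sentence_index == 3], "interleukin 6")
  # longest match: TNFRSF1A wins over substring TNF; token boundary
  # prevents matches inside other words
  expect_equal(men$gene_id[men$sentence_index == 4], "7132")
  expect_equal(nrow(men[men$sentence_index == 5, ]), 0L)
})

test_that("case folding and hyphen/space equivalence unify variants", {
  lex <- humanLexicon()
  corp <- smallCorpus(list(
    title = "T.",
    abstract = "IL-6 rose. il 6 fell. VEGF-A and vegfa agreed."))
  men <- tagMentions(corp, lex)
  expect_equal(sum(men$gene_id == "3569"), 2L)
  expect_equal(sum(men$gene_id == "7422"), 2L)
  # surface equals the corpus text at the span
  txt <- documentText(corp)[["d1"]]
  expect_identical(men$surface,
                   substring(txt, men$start + 1, men$end))
})

test_that("mention spans lie inside their sentence and do not overlap", {
  lex <- humanLexicon()
  corp <- smallCorpus(list(
    title = "TNF in sepsis.",
    abstract = "VEGFA, IL6 and TNF interact. TNFRSF1A binds TNF."))
  men <- tagMentions(corp, lex)
  s <- sentenceTable(corp)
  for (i in seq_len(nrow(men))) {
    si <- s[s$doc_id == men$doc_id[i] &
              s$sentence_index == men$sentence_index[i], ]
    expect_gte(men$start[i], si$start)
    expect_lte(men$end[i], si$end)
  }
  plain <- men[!men$expanded, ]
  bySent <- split(plain, paste(plain$doc_id, plain$sentence_index))
  for (g in bySent) {
    g <- g[order(g$start), ]
    if (nrow(g) > 1)
      expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
})

test_that("conjunction patterns expand and re-validate against the lexicon", {
  lex <- humanLexicon()
  corp <- smallCorpus(list(
    title = "T.",
    abstract = paste("IL-2, -4 and -6 were elevated.",
                     "MMP-2/9 activity rose.",
                     "VEGF-A/B both fell.",
                     "IL-2 and -99 were mixed.",
                     "TNF alone here.")))
  men <- tagMentions(corp, lex)
  s2 <- men[men$sentence_index == 2, ]
  expect_setequal(s2$gene_id, c("3558", "3565", "3569"))
  expect_equal(sum(s2$expanded), 2L)
  expect_setequal(men$gene_id[men$sentence_index == 3], c("4313", "4318"))
  expect_setequal(men$gene_id[men$sentence_index == 4], c("7422", "7423"))
  # expansion not in the lexicon is discarded
  expect_setequal(men$gene_id[men$sentence_index == 5], "3558")
  # no coordination pattern: mentions unchanged
  expect_equal(men$gene_id[men$sentence_index == 6], "7124")
  # expanded spans point at the eliding fragment
  txt <- documentText(corp)[["d1"]]
  exp4 <- s2[s2$expanded, ]
  expect_identical(exp4$surface,
                   substring(txt, exp4$start + 1, exp4$end))
  expect_setequal(exp4$surface, c("4", "6"))
})

test_that("resolveConjunctions works standalone on one sentence", {
  lex <- humanLexicon()
  sent <- "IL-4 and -6 were measured"
  men <- data.frame(start = 0L, end = 4L, surface = "IL-4",
                    gene_id = "3565", stringsAsFactors = FALSE)
  out <- resolveConjunctions(sent, men, lex)
  expect_equal(nrow(out), 2L)
  expect_setequal(out$gene_id, c("3565", "3569"))
  # identity on a sentence without coordination
  men2 <- data.frame(start = 0L, end = 3L, surface = "TNF",
                     gene_id = "7124", stringsAsFactors = FALSE)
  expect_equal(nrow(resolveConjunctions("TNF alone", men2, lex)), 1L)
})

test_that("tagging is deterministic and order-independent across docs", {
  lex <- humanLexicon()
  docs <- list(title = c("TNF story.", "IL6 story."),
               abstract = c("VEGFA and TNF.", "IL-2, -4 and -6."))
  corp <- smallCorpus(docs)
  rev_corp <- newCorpus(data.frame(doc_id = c("d2", "d1"),
                                   title = rev(docs$title),
                                   abstract = rev(docs$abstract)))
  m1 <- tagMentions(corp, lex)
  m2 <- tagMentions(rev_corp, lex)
  key <- function(m) {
    k <- m[order(m$doc_id, m$sentence_index, m$start, m$gene_id),
           c("doc_id", "sentence_index", "start", "end", "gene_id")]
    rownames(k) <- NULL
    k
  }
  expect_identical(key(m1), key(m2))
  expect_identical(tagMentions(corp, lex), m1)
  # closed world: every emitted id is in the lexicon
  expect_true(all(m1$gene_id %in% lexiconEntries(lex)$gene_id))
})

test_that("titles are scanned by default and excludable by flag", {
  lex <- humanLexicon()
  corp <- smallCorpus(list(title = "TNF in lung.", abstract = "Nothing."))
  expect_equal(tagMentions(corp, lex)$gene_id, "7124")
  expect_equal(nrow(tagMentions(corp, lex, scanTitles = FALSE)), 0L)
})
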