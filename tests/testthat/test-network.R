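# Network assembly, topology analysis and export.

writeKgmlFixture <- function(entries, relations) {
  f <- tempfile(fileext = ".xml")
  writeLines(c("<?xml version=\"1.0\"?>",
               "<pathway name=\"path:test\" org=\"hsa\" number=\"1\">",
               entries, relations, "</pathway>"), f)
  f
}

test_that("KGML relations resolve to typed gene-pair edges", {
  f <- writeKgmlFixture(
    c('<entry id="1" name="hsa:7124" type="gene"/>',
      '<entry id="2" name="hsa:7422 hsa:7423" type="gene"/>',
      '<entry id="3" name="cpd:C00001" type="compound"/>'),
    c(paste0('<relation entry1="1" entry2="2" type="PPrel">',
             '<subtype name="binding"/></relation>'),
      '<relation entry1="1" entry2="3" type="ECrel"/>',
      paste0('<relation entry1="1" entry2="2" type="PPrel">',
             '<subtype name="binding"/></relation>')))
  e <- readKgml(f)
  # compound relation skipped; multi-gene entry expands; duplicate
  # relation deduplicated
  expect_equal(nrow(e), 2L)
  expect_true(all(e$type == "PPrel"))
  expect_setequal(e$gene_b, c("7422", "7423"))
  expect_true(all(grepl("binding", e$evidence)))
  f2 <- tempfile(); writeLines("<pathway><entry", f2)
  expect_error(readKgml(f2), "malformed")
})

test_that("PPI tables drop self-loops, collapse reciprocals, check ids", {
  f <- tempfile()
  writeLines(c("7124\t7422", "7422\t7124", "7124\t7124", "7423\t9999"), f)
  e <- readPpiTable(f)
  expect_equal(nrow(e), 2L)
  expect_true(all(e$gene_a <= e$gene_b))
  expect_message(e2 <- readPpiTable(f, lexicon = humanLexicon()),
                 "skipped")
  expect_equal(nrow(e2), 1L)
  expect_equal(e2$type, "PPrel")
  expect_equal(e2$evidence, "ppi-table")
})

test_that("co-citation edges use sentence counts and the exact tail", {
  lex <- humanLexicon()
  # 30 sentences total; TNF and VEGFA co-occur in exactly their 3
  # sentences: p = 1 / C(30,3) = 1/4060
  filler <- paste(rep("Nothing here today.", 9), collapse = " ")
  docs <- list(
    title = c("Joint one.", "Joint two.", "Joint three."),
    abstract = c(paste("TNF binds VEGFA.", filler),
                 paste("TNF binds VEGFA.", filler),
                 paste("TNF binds VEGFA.", filler)))
  corp <- smallCorpus(docs)
  expect_equal(nrow(sentenceTable(corp)), 33L)  # 3 titles + 30
  # empty titles keep N' at exactly the 30 constructed sentences
  corpNoTitle <- newCorpus(data.frame(doc_id = paste0("d", 1:3),
                                      title = "",
                                      abstract = docs$abstract))
  men2 <- tagMentions(corpNoTitle, lex)
  e <- cocitationEdges(corpNoTitle, men2, alpha = 0.05)
  expect_equal(nrow(e), 1L)
  expect_equal(e$type, "cocitation")
  expect_equal(e$p_value, 1 / 4060, tolerance = 1e-12)
  expect_equal(e$p_value, hypergeomTail(3, 3, 3, 30), tolerance = 1e-14)
})

test_that("minimum support suppresses single-sentence coincidences", {
  lex <- humanLexicon()
  filler <- paste(rep("Filler sentence here.", 30), collapse = " ")
  corp <- smallCorpus(list(title = "",
                           abstract = paste("TNF binds VEGFA.", filler)))
  men <- tagMentions(corp, lex)
  # k' = 1: significant at alpha but below the support threshold
  expect_equal(nrow(cocitationEdges(corp, men, alpha = 0.5)), 0L)
  expect_equal(nrow(cocitationEdges(corp, men, alpha = 0.5,
                                    minSupport = 1)), 1L)
  # genes never in one sentence: no edge at any alpha
  corp2 <- smallCorpus(list(title = "",
                            abstract = "TNF rose. VEGFA fell."))
  men2 <- tagMentions(corp2, lex)
  expect_equal(nrow(cocitationEdges(corp2, men2, alpha = 0.999,
                                    minSupport = 1)), 0L)
})

test_that("merge deduplicates pairs and concatenates evidence", {
  pp <- data.frame(gene_a = "a", gene_b = "b", type = "PPrel",
                   evidence = "ppi-table", p_value = NA_real_)
  cc <- data.frame(gene_a = "b", gene_b = "a", type = "cocitation",
                   evidence = "cocitation", p_value = 0.001)
  net <- mergeNetwork(pp, cc)
  e <- networkEdges(net)
  expect_equal(nrow(e), 1L)
  expect_setequal(strsplit(e$types, ";")[[1]], c("PPrel", "cocitation"))
  expect_setequal(strsplit(e$evidence, ";")[[1]],
                  c("ppi-table", "cocitation"))
  expect_equal(e$p_value, 0.001)
  # disjoint lists simply union
  e2 <- randomEdgeList(1, nEdges = 2)
  e3 <- randomEdgeList(2, nEdges = 3)
  n23 <- mergeNetwork(e2, e3)
  expect_equal(sum(networkDegrees(n23)), 2L * nrow(networkEdges(n23)))
})

test_that("merge is commutative, idempotent and obeys the handshake lemma", {
  for (seed in 1:12) {
    A <- randomEdgeList(seed)
    B <- randomEdgeList(seed + 100)
    ab <- mergeNetwork(A, B)
    ba <- mergeNetwork(B, A)
    expect_identical(networkEdges(ab), networkEdges(ba))
    aa <- mergeNetwork(A, A)
    a1 <- mergeNetwork(A)
    expect_identical(networkEdges(aa), networkEdges(a1))
    expect_equal(sum(networkDegrees(ab)), 2L * nrow(networkEdges(ab)))
    # re-merging a merged network is a fixed point
    expect_identical(networkEdges(mergeNetwork(ab)), networkEdges(ab))
  }
})

test_that("network restriction keeps the set plus neighbors or strict", {
  E <- data.frame(gene_a = c("a", "b", "c"), gene_b = c("b", "c", "d"),
                  type = "PPrel", evidence = "kgml", p_value = NA_real_)
  nb <- mergeNetwork(E, restrictTo = "b")
  expect_setequal(networkNodes(nb), c("a", "b", "c"))
  st <- mergeNetwork(E, restrictTo = c("b", "c"), restrictMode = "strict")
  expect_equal(nrow(networkEdges(st)), 1L)
})

test_that("degree histogram is exact on canonical small graphs", {
  tri <- mergeNetwork(data.frame(gene_a = c("a", "b", "a"),
                                 gene_b = c("b", "c", "c"),
                                 type = "PPrel", evidence = "x",
                                 p_value = NA_real_))
  h <- degreeHistogram(tri)
  expect_equal(h, data.frame(degree = 2L, count = 3L))
  star <- mergeNetwork(data.frame(gene_a = "hub",
                                  gene_b = paste0("leaf", 1:4),
                                  type = "PPrel", evidence = "x",
                                  p_value = NA_real_))
  hs <- degreeHistogram(star)
  expect_equal(hs$count[hs$degree == 1], 4L)
  expect_equal(hs$count[hs$degree == 4], 1L)
  path3 <- mergeNetwork(data.frame(gene_a = c("a", "b"),
                                   gene_b = c("b", "c"),
                                   type = "PPrel", evidence = "x",
                                   p_value = NA_real_))
  hp <- degreeHistogram(path3)
  expect_equal(hp, data.frame(degree = 1:2, count = c(2L, 1L)))
  expect_equal(sum(hp$count), 3L)
  expect_error(degreeHistogram(mergeNetwork(randomEdgeList(1)[0, ])),
               "empty")
})

test_that("collinear log-log histograms recover the exponent exactly", {
  h <- data.frame(degree = c(1, 2, 4, 8), count = c(512, 64, 8, 1))
  fit <- fitPowerLaw(h)
  expect_equal(fit@exponent, 3, tolerance = 1e-12)
  expect_equal(fit@goodness, 1, tolerance = 1e-12)
  expect_true(fit@isPowerLaw)
  # flat histogram: zero slope, flagged non-power-law
  flat <- fitPowerLaw(data.frame(degree = c(1, 2, 3, 4), count = 5))
  expect_equal(flat@exponent, 0)
  expect_false(flat@isPowerLaw)
  expect_error(fitPowerLaw(data.frame(degree = 1:2, count = c(2, 1))),
               ">= 3")
})

test_that("MLE mode recovers a steep planted exponent", {
  set.seed(21)
  # degrees drawn from a discrete power law gamma = 2.5 via inverse cdf
  u <- runif(4000)
  d <- floor((1 - u)^(-1 / 1.5))
  d <- d[d >= 1 & d <= 10000]
  fit <- fitPowerLaw(data.frame(degree = as.numeric(names(table(d))),
                                count = as.vector(table(d))),
                     method = "mle", dMin = "auto")
  expect_equal(fit@exponent, 2.5, tolerance = 0.1)
  expect_true(fit@goodness < 0.1)
})

test_that("hub selection rules include cutoff ties and rank by degree", {
  E <- data.frame(
    gene_a = c("h1", "h1", "h1", "h1", "h1", "h2", "h2", "h2", "h2",
               "m1", "m1", "m2"),
    gene_b = c("h2", "m1", "m2", "x1", "x2", "m1", "m2", "x3", "x4",
               "m2", "x5", "x6"),
    type = "PPrel", evidence = "x", p_value = NA_real_,
    stringsAsFactors = FALSE)
  net <- mergeNetwork(E)
  deg <- networkDegrees(net)
  expect_equal(unname(deg[c("h1", "h2", "m1", "m2")]), c(5L, 5L, 4L, 4L))
  top2 <- identifyHubs(net, rule = "top_k", param = 2)
  expect_setequal(top2$gene_id, c("h1", "h2"))
  # ties at the cutoff are all included
  top3 <- identifyHubs(net, rule = "top_k", param = 3)
  expect_setequal(top3$gene_id, c("h1", "h2", "m1", "m2"))
  thr <- identifyHubs(net, rule = "degree_threshold", param = 4)
  expect_setequal(thr$gene_id, c("h1", "h2", "m1", "m2"))
  frac <- identifyHubs(net, rule = "top_fraction", param = 0.1)
  expect_setequal(frac$gene_id, c("h1", "h2"))
  expect_true(all(diff(frac$degree) <= 0))
  expect_error(identifyHubs(net, rule = "top_fraction", param = 2),
               "\\(0, 1\\]")
  # star graph: top_k = 1 selects the center
  star <- mergeNetwork(data.frame(gene_a = "hub",
                                  gene_b = paste0("l", 1:4),
                                  type = "PPrel", evidence = "x",
                                  p_value = NA_real_))
  expect_equal(identifyHubs(star, rule = "top_k", param = 1)$gene_id,
               "hub")
})

test_that("hub selection is stable under node relabeling", {
  A <- randomEdgeList(33, nGenes = 10, nEdges = 14)
  perm <- setNames(sprintf("z%02d", sample(10)), sprintf("g%02d", 1:10))
  B <- A
  B$gene_a <- unname(perm[A$gene_a]); B$gene_b <- unname(perm[A$gene_b])
  hA <- identifyHubs(mergeNetwork(A), rule = "degree_threshold", param = 3)
  hB <- identifyHubs(mergeNetwork(B), rule = "degree_threshold", param = 3)
  expect_setequal(unname(perm[hA$gene_id]), hB$gene_id)
  expect_equal(sort(hA$degree), sort(hB$degree))
})

test_that("SIF and TSV exports serialize every edge", {
  net <- mergeNetwork(randomEdgeList(3, nEdges = 6))
  f <- tempfile(fileext = ".sif")
  exportNetwork(net, f, "sif")
  expect_equal(length(readLines(f)), nrow(networkEdges(net)))
  ftsv <- tempfile(fileext = ".tsv")
  exportNetwork(net, ftsv, "tsv")
  back <- utils::read.delim(ftsv, colClasses = c(p_value = "numeric"),
                            stringsAsFactors = FALSE)
  expect_equal(back$gene_a, networkEdges(net)$gene_a)
  # empty network exports an empty valid file
  emptyNet <- mergeNetwork(randomEdgeList(1)[0, ])
  fe <- tempfile(fileext = ".sif")
  exportNetwork(emptyNet, fe, "sif")
  expect_equal(length(readLines(fe)), 0L)
  expect_error(exportNetwork(net, tempfile(), "dot"), "arg")
})

test_that("GraphML round-trips nodes, edges and attributes", {
  net <- mergeNetwork(randomEdgeList(9, nEdges = 10))
  f <- tempfile(fileext = ".graphml")
  exportNetwork(net, f, "graphml")
  back <- readNetworkGraphml(f)
  expect_setequal(networkNodes(back), networkNodes(net))
  expect_equal(networkEdges(back), networkEdges(net))
})
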