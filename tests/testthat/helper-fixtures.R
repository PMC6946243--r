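# Shared fixtures, built in code at test time.

# Small human-style lexicon exercising synonyms, families and substrings.
humanLexicon <- function(extraRows = NULL, stopList = character(0)) {
  rows <- data.frame(
    gene_id = c("3558", "3565", "3569", "7422", "7423", "7124", "7132",
                "4313", "4318", "7157", "3630", "3552"),
    symbol = c("IL2", "IL4", "IL6", "VEGFA", "VEGFB", "TNF", "TNFRSF1A",
               "MMP2", "MMP9", "TP53", "INS", "IL1B"),
    synonyms = c("", "", "interleukin 6", "VEGF-A", "", "", "", "", "",
                 "p53", "insulin", "interleukin 1 beta"),
    stringsAsFactors = FALSE)
  if (!is.null(extraRows)) rows <- rbind(rows, extraRows)
  makeLexicon(rows, stopList = stopList)
}

smallCorpus <- function(docs) {
  newCorpus(data.frame(doc_id = paste0("d", seq_along(docs$title)),
                       title = docs$title, abstract = docs$abstract,
                       stringsAsFactors = FALSE))
}

# Minimal PubMed article-set XML.
writePubmedFixture <- function(path, pmids, titles, abstracts) {
  art <- vapply(seq_along(pmids), function(i) {
    abst <- if (is.na(abstracts[i])) "" else sprintf(
      "<Abstract><AbstractText>%s</AbstractText></Abstract>", abstracts[i])
    sprintf(paste0("<PubmedArticle><MedlineCitation><PMID>%s</PMID>",
                   "<Article><ArticleTitle>%s</ArticleTitle>%s</Article>",
                   "</MedlineCitation></PubmedArticle>"),
            pmids[i], titles[i], abst)
  }, "")
  writeLines(c("<?xml version=\"1.0\"?>", "<PubmedArticleSet>", art,
               "</PubmedArticleSet>"), path)
  path
}

# Random edge list over a small gene universe, for merge/round-trip
# property tests.
randomEdgeList <- function(seed, nGenes = 12, nEdges = 15,
                           types = c("ECrel", "PPrel", "GErel",
                                     "cocitation")) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(nGenes))
  a <- sample(genes, nEdges, replace = TRUE)
  b <- sample(genes, nEdges, replace = TRUE)
  keep <- a != b
  ty <- sample(types, nEdges, replace = TRUE)
  data.frame(gene_a = a, gene_b = b, type = ty,
             evidence = ifelse(ty == "cocitation", "cocitation", "kgml"),
             p_value = ifelse(ty == "cocitation",
                              round(runif(nEdges), 6), NA_real_),
             stringsAsFactors = FALSE)[keep, , drop = FALSE]
}

# Exact tail values frozen from a big-integer rational enumeration
# (sum of C(m,i) C(N-m,n-i) / C(N,n) over the upper tail, computed with
# arbitrary-precision integers on random and boundary tuples).
exactTailFixture <- function() {
  data.frame(
    k = c(1,0,4,0,0,41,6,7,1,0,2,2,1,13,0,1,13,5,1,17,10,3,12,43,1,2,10,
          23,2,17,24,2,2,2,27,3,16,7,17,2,0,6,29,2,0,1,48,0,1,7,11,6,23,
          5,1,0,4,1,1,8,0,10,0,3,2,5,30),
    m = c(7,7,34,1,7,41,14,10,8,21,3,16,7,18,11,14,14,8,5,17,40,7,35,49,
          1,2,45,31,9,17,37,11,31,7,43,3,16,7,17,4,0,6,32,5,33,1,53,1,7,
          10,16,12,41,33,7,1,5,2,4,31,5,10,0,3,4,5,60),
    n = c(1,4,5,0,0,44,8,44,4,6,11,2,24,23,1,18,55,14,5,44,10,6,14,49,10,
          6,20,25,16,17,27,7,5,9,27,3,35,43,49,6,16,19,38,2,0,7,51,7,1,7,
          13,19,23,28,2,1,5,1,1,13,5,10,0,3,5,5,30),
    N = c(42,17,45,29,15,47,16,50,23,50,26,40,31,37,14,44,56,26,12,44,40,
          12,42,55,16,19,58,43,31,17,49,27,34,57,52,6,35,45,50,9,31,34,
          42,11,51,33,58,17,7,10,18,36,44,59,17,3,6,16,6,44,10,10,1,30,
          20,60,60),
    p = c(0.16666666666666666,1.0,0.6452925658824694,1.0,1.0,
          0.0012334258402713536,1.0,0.9890445354830184,0.8458498023715415,
          1.0,0.38076923076923075,0.15384615384615385,0.9999996197104095,
          0.18733247151489643,1.0,0.9999159877162914,1.0,
          0.43707093821510296,0.9734848484848485,1.0,1.0,
          0.8787878787878788,0.5708982409880998,1.0,0.625,
          0.08771929824561403,0.999961040379539,0.0009089156027687836,
          0.9946446131772824,1.0,0.018442994520270085,0.8879227053140096,
          1.0,0.30377253643799584,0.0005552957680617255,0.05,1.0,
          0.7101010101010101,0.66,0.9523809523809523,1.0,
          0.020173930629992922,0.6787277762887519,0.18181818181818182,
          1.0,0.21212121212121213,0.10557480430438689,1.0,1.0,1.0,1.0,
          0.7223804226918799,0.10042283298097252,0.999999999757013,
          0.6691176470588235,1.0,1.0,0.125,0.6666666666666666,
          0.8840750641355261,1.0,1.0,1.0,0.0002463054187192118,
          0.24871001031991744,1.830994786791643e-07,1.0))
}

pipelineFixture <- function(dir, nDocs = 250, nGenes = 30, nPlanted = 4,
                            seed = 71, withAnnotations = TRUE,
                            withRelations = TRUE, rho = 8) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- generatorConfig(nDocs = nDocs, nGenes = nGenes,
                         nPlanted = nPlanted, rho = rho,
                         mAttach = if (withRelations) 2 else 0,
                         edgeDocRate = 0.008, seed = seed)
  lex <- simulateLexicon(cfg, path = file.path(dir, "lexicon.tsv"))
  sim <- simulateCorpus(cfg, lexicon = lex, dir = dir)
  gmt <- NULL
  if (withAnnotations) {
    gmt <- file.path(dir, "sets.gmt")
    ids <- lexiconEntries(lex)$gene_id
    set.seed(seed)
    writeLines(vapply(1:6, function(i)
      paste(c(sprintf("path%02d", i), "synthetic set",
              sample(ids, 8)), collapse = "\t"), ""), gmt)
  }
  kgml <- ppi <- NULL
  if (withRelations) {
    rel <- simulateRelationFiles(cfg, dir)
    kgml <- rel$kgml; ppi <- rel$ppi
  }
  pipelineConfig(corpus = file.path(dir, "corpus.jsonl"),
                 lexicon = file.path(dir, "lexicon.tsv"),
                 outputDir = file.path(dir, "out"),
                 diseaseTerms = cfg$diseaseTerm,
                 gmt = gmt, kgml = kgml, ppi = ppi, seed = seed)
}
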