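# Synthetic-corpus generator: determinism, self-consistency, planted
# structure, recovery scoring.

test_that("config validation enforces the generator's invariants", {
  expect_error(generatorConfig(nDocs = 10, nGenes = 5), "seed")
  expect_error(generatorConfig(nDocs = 0, nGenes = 5, seed = 1), "nDocs")
  expect_error(generatorConfig(nDocs = 10, nGenes = 0, seed = 1),
               "nGenes")
  expect_error(generatorConfig(nDocs = 10, nGenes = 5, piDisease = 1.2,
                               seed = 1), "probability")
  expect_warning(generatorConfig(nDocs = 10, nGenes = 5, nPlanted = 1,
                                 piGene = 0.5, rho = 4, seed = 1),
                 "clipped")
})

test_that("lexicon generation is deterministic and collision-free", {
  cfg <- generatorConfig(nDocs = 10, nGenes = 10, seed = 5)
  f1 <- tempfile(); f2 <- tempfile()
  lex1 <- simulateLexicon(cfg, path = f1)
  lex2 <- simulateLexicon(cfg, path = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(nrow(lexiconEntries(lex1)), 10L)
  expect_equal(anyDuplicated(lex1@index$key), 0L)
  expect_length(lex1@dropped, 0L)
})

test_that("identical config and seed give byte-identical corpus files", {
  cfg <- generatorConfig(nDocs = 60, nGenes = 20, nPlanted = 3, rho = 5,
                         mAttach = 2, conjFraction = 0.3, seed = 99)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  simulateCorpus(cfg, dir = d1)
  simulateCorpus(cfg, dir = d2)
  expect_identical(readLines(file.path(d1, "corpus.jsonl")),
                   readLines(file.path(d2, "corpus.jsonl")))
  expect_identical(readLines(file.path(d1, "truth.json")),
                   readLines(file.path(d2, "truth.json")))
  r1 <- simulateRelationFiles(cfg, d1)
  r2 <- simulateRelationFiles(cfg, d2)
  expect_identical(readLines(r1$kgml), readLines(r2$kgml))
  expect_identical(readLines(r1$ppi), readLines(r2$ppi))
})

test_that("re-tagging the generated corpus reproduces the truth exactly", {
  cfg <- generatorConfig(nDocs = 400, nGenes = 60, nPlanted = 6, rho = 6,
                         mAttach = 2, edgeDocRate = 0.01,
                         conjFraction = 0.25, seed = 17)
  sim <- simulateCorpus(cfg)
  men <- tagMentions(sim$corpus, sim$lexicon)
  cnt <- countGeneDisease(sim$corpus, men, cfg$diseaseTerm)
  tr <- sim$truth@counts
  mm <- merge(tr, cnt, by = "gene_id", all.x = TRUE)
  mm$m.y[is.na(mm$m.y)] <- 0L
  mm$k.y[is.na(mm$k.y)] <- 0L
  expect_identical(mm$m.y, mm$m.x)
  expect_identical(mm$k.y, mm$k.x)
  expect_true(all(cnt$n == sim$truth@nDiseaseDocs))
  expect_true(all(cnt$N == sim$truth@nDocs))
})

test_that("truth JSON round-trips", {
  cfg <- generatorConfig(nDocs = 30, nGenes = 8, nPlanted = 2, rho = 4,
                         mAttach = 1, seed = 3)
  sim <- simulateCorpus(cfg)
  f <- tempfile(fileext = ".json")
  writeTruthJson(sim$truth, f)
  back <- readTruthJson(f)
  expect_identical(back@plantedGenes, sim$truth@plantedGenes)
  expect_identical(back@counts$m, sim$truth@counts$m)
  expect_identical(back@nDiseaseDocs, sim$truth@nDiseaseDocs)
})

test_that("null model: planted-free corpora hold the association null", {
  cfg <- generatorConfig(nDocs = 500, nGenes = 50, seed = 23)
  sim <- simulateCorpus(cfg)
  # by construction every gene has rho = 1
  expect_length(sim$truth@plantedGenes, 0L)
  men <- tagMentions(sim$corpus, sim$lexicon)
  cnt <- countGeneDisease(sim$corpus, men, cfg$diseaseTerm)
  res <- scoreAllGenes(cnt)
  # conservative null: p-values not stochastically below uniform
  expect_lte(mean(res$p_value < 0.25), 0.35)
})

test_that("boundary config: gene exclusive to disease docs has k = m", {
  cfg <- generatorConfig(nDocs = 400, nGenes = 5, nPlanted = 1,
                         piGene = 0.004, rho = 200, seed = 31)
  expect_equal(cfg$pPlanted, 0.8)
  sim <- simulateCorpus(cfg)
  tr <- sim$truth@counts
  planted <- tr[tr$gene_id == sim$truth@plantedGenes, ]
  # background rate ~0: planted gene appears (almost) only with disease
  expect_gte(planted$k / planted$m, 0.9)
})

test_that("preferential attachment has the documented edge count", {
  g <- sampleScaleFreeGraph(200, 2, seed = 1)
  expect_equal(nrow(g), 2 * (200 - 2) + 1)
  g3 <- sampleScaleFreeGraph(100, 3, seed = 1)
  expect_equal(nrow(g3), 1 + sum(pmin(2:99, 3)))
  expect_error(sampleScaleFreeGraph(100, 0, seed = 1), "mAttach")
  cfgBad <- generatorConfig(nDocs = 10, nGenes = 10, seed = 1)
  expect_error(simulateRelationFiles(cfgBad, tempfile()), "mAttach")
})

test_that("relation files partition the planted graph and parse back", {
  cfg <- generatorConfig(nDocs = 10, nGenes = 40, mAttach = 2, seed = 11)
  dir <- tempfile()
  rel <- simulateRelationFiles(cfg, dir)
  kg <- readKgml(rel$kgml)
  pp <- readPpiTable(rel$ppi)
  got <- rbind(kg[, c("gene_a", "gene_b")], pp[, c("gene_a", "gene_b")])
  want <- rel$edges[, c("gene_a", "gene_b")]
  keyOf <- function(d) sort(unique(paste(d$gene_a, d$gene_b)))
  expect_identical(keyOf(got), keyOf(want))
  expect_true(all(kg$type %in% c("ECrel", "PPrel", "GErel")))
})

test_that("planted co-mention edges surface as co-citation edges", {
  cfg <- generatorConfig(nDocs = 1500, nGenes = 30, mAttach = 1,
                         piGene = 0.003, edgeDocRate = 0.004, seed = 47)
  sim <- simulateCorpus(cfg)
  men <- tagMentions(sim$corpus, sim$lexicon)
  got <- cocitationEdges(sim$corpus, men, alpha = 0.01)
  ev <- evaluateRecovery(
    scoreAllGenes(countGeneDisease(sim$corpus, men, cfg$diseaseTerm)),
    sim$truth, edges = got)
  expect_gt(ev$edge_jaccard, 0.5)
})

test_that("recovery report handles perfect, empty and mismatched input", {
  truth <- new("SyntheticTruth", plantedGenes = c("1", "2"),
               plantedEdges = data.frame(gene_a = character(0),
                                         gene_b = character(0)),
               counts = data.frame(gene_id = as.character(1:4),
                                   m = 5L, k = 2L),
               nDiseaseDocs = 10L, nDocs = 50L)
  perfect <- data.frame(gene_id = as.character(1:4),
                        significant = c(TRUE, TRUE, FALSE, FALSE))
  ev <- evaluateRecovery(perfect, truth)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$fpr, 0)
  none <- data.frame(gene_id = as.character(1:4), significant = FALSE)
  ev0 <- evaluateRecovery(none, truth)
  expect_equal(ev0$recall, 0)
  expect_true(is.na(ev0$precision))
  alien <- data.frame(gene_id = "99", significant = TRUE)
  expect_error(evaluateRecovery(alien, truth), "absent")
})
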