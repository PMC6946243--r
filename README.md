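# litGeneNet

Literature mining of gene–disease associations and co-citation gene
networks.

`litGeneNet` re-implements, as a reusable and fully testable R pipeline,
the classic text-mining workflow used to chart the molecular landscape of
a disease from bibliographic records — the kind of analysis applied to
bronchopulmonary dysplasia (BPD), the chronic lung disease of premature
infants. Starting from a corpus of titles and abstracts it:

1. **tags gene mentions** with a deterministic dictionary matcher
   (case-insensitive, hyphen/space-equivalent, longest match), normalizes
   synonyms to Entrez-style gene ids and expands coordinated elided forms
   ("IL-2, -4 and -6" → IL2, IL4, IL6);
2. **scores gene–disease association** with an exact hypergeometric upper
   tail: with *N* documents in the corpus, *n* citing the disease, *m*
   citing the gene and *k* citing both,

   P(X ≥ k) = Σᵢ₌ₖ^min(m,n) C(m,i)·C(N−m,n−i) / C(N,n),

   keeping genes with *P* < .05 (raw, matching the original convention;
   Benjamini–Hochberg available);
3. **characterizes the significant set** by hypergeometric
   over-representation against GO (GAF 2.x) and pathway (GMT) gene-set
   collections — the same exact statistic as the one-sided Fisher test;
4. **builds a merged undirected gene network** from curated KGML
   relations (ECrel/PPrel/GErel), two-column PPI tables and
   sentence-level co-citation edges (hypergeometric on sentence counts,
   minimum support 2), then analyzes its degree topology: exact degree
   histogram, power-law fit c(d) ∝ d^(−γ) (log–log least squares or
   KS-selected discrete MLE), and hub genes (top 5 % by degree, ties
   included);
5. **simulates corpora with known ground truth** — planted
   disease-associated genes, planted scale-free co-mention graphs,
   controllable background rates — so every stage can be validated
   end-to-end without any external download.

The intended users are bioinformaticians who want a transparent,
deterministic alternative to ad-hoc mining scripts, with the statistics
exposed as plain functions.

## Worked example

A synthetic corpus of 2000 documents and 100 genes, 8 of them planted
with an eight-fold mention-rate enrichment in disease-positive documents:

```r
library(litGeneNet)
cfg <- generatorConfig(nDocs = 2000, nGenes = 100, nPlanted = 8, rho = 8,
                       mAttach = 2, edgeDocRate = 0.004, seed = 42)
sim <- simulateCorpus(cfg)
sim$corpus
#> Corpus with 2000 documents, 13584 sentences

mentions <- tagMentions(sim$corpus, sim$lexicon)
counts <- countGeneDisease(sim$corpus, mentions, "bronchopulmonary dysplasia")
assoc <- scoreAllGenes(counts, alpha = 0.05, lexicon = sim$lexicon)
head(assoc, 5)
#>   gene_id symbol  k   m   n    N      p_value significant
#> 1    1004  G0004 72 201 403 2000 3.239911e-08        TRUE
#> 2    1006  G0006 34  72 403 2000 1.268521e-07        TRUE
#> 3    1008  G0008 36  83 403 2000 7.549865e-07        TRUE
#> 4    1005  G0005 59 167 403 2000 1.223154e-06        TRUE
#> 5    1001  G0001 31  83 403 2000 1.595952e-04        TRUE
```

Each row is one gene: `k` of the `n = 403` disease documents also cite
it, out of `m` citing the gene anywhere in the `N = 2000` document
corpus; `p_value` is the exact tail probability of so much overlap under
random placement. All 8 planted genes are recovered:

```r
evaluateRecovery(assoc, sim$truth)
#>   n_tested n_significant precision recall       fpr
#> 1      100            11 0.7272727      1 0.0326087
```

Sentence-level co-citation gives a network whose degree distribution is
heavy-tailed (the generator planted a preferential-attachment co-mention
graph):

```r
net <- mergeNetwork(cocitationEdges(sim$corpus, mentions))
net
#> GeneNetwork: 100 nodes, 205 edges
fitPowerLaw(net, method = "mle", dMin = "auto")
#> PowerLawFit (mle): gamma = 2.5498, KS = 0.0829, d_min = 3
head(identifyHubs(net, lexicon = sim$lexicon), 3)
#>   rank gene_id symbol degree
#> 1    1    1002  G0002     26
#> 2    2    1003  G0003     20
#> 3    3    1004  G0004     19
```

Real corpora enter through `readPubmedXml()` (PubMed/MEDLINE article
sets) or `readCorpusJsonl()`, lexicons through `readLexicon()` (TSV:
gene id, symbol, pipe-separated synonyms), annotations through
`readGmt()`/`readGaf()`, relations through `readKgml()`/
`readPpiTable()`. `runAll(pipelineConfig(...))` drives the whole flow
from one config (YAML supported via `readPipelineConfig()`) and writes a
reproducible bundle — TSV tables, SIF/GraphML exports and a manifest
whose re-run is byte-identical. A thin command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

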