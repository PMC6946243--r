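---
title: "Mining gene–disease associations and co-citation networks from a bibliographic corpus"
author: "litGeneNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining gene–disease associations and co-citation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litGeneNet)
```

## The problem

A large share of what is known about a disease — which genes are
involved, how they interact — sits in the free text of titles and
abstracts rather than in structured databases. For diseases studied by
many small clinical cohorts, such as bronchopulmonary dysplasia in
premature infants, mining that text is often the only way to assemble a
gene-level picture. `litGeneNet` implements the standard co-occurrence
recipe for this task as a deterministic, testable pipeline: tag gene
mentions, score gene–disease association, characterize the significant
set by gene-set over-representation, and build a multi-evidence gene
network whose topology singles out hub genes.

Everything downstream of the corpus is a function of exact integer
counts, so the whole pipeline is reproducible bit for bit: re-running a
configuration rewrites every output byte-identically.

## The association model

Counting is **binary at the document level**: a document either cites a
gene (anywhere in title or abstract, however many times) or it does not,
and likewise for the disease phrase. With

* $N$ — documents in the corpus,
* $n$ — documents citing the disease,
* $m$ — documents citing the gene,
* $k$ — documents citing both,

the null hypothesis is that the $m$ gene documents are an exchangeable
random subset of the corpus, independent of the $n$ disease documents.
The association statistic is the exact hypergeometric upper tail

$$P(X \ge k) \;=\; \sum_{i=k}^{\min(m,n)}
  \frac{\binom{m}{i}\binom{N-m}{n-i}}{\binom{N}{n}},$$

computed in log space (log-binomials, log-sum-exp). Whichever tail lies
on $k$'s side of the mode is summed directly, so a small upper tail is
never obtained by subtracting from 1 and keeps full relative precision;
the complement is used only where the result is near 1 and absolute
precision suffices. No intermediate quantity overflows for corpora up to
$10^7$ documents. Genes with raw $P < \alpha$ (default $\alpha = 0.05$)
are retained.

Three conventions deserve a note, because the recipe leaves them open:

* **Inclusive tail.** $P(X \ge k)$ is the standard, conservative
  over-representation convention ("at least as extreme"); a strict
  $P(X > k)$ flag is provided for comparison.
* **Corpus definition.** $N$ is the size of the supplied corpus, which
  is expected to contain disease-negative documents. If the corpus were
  only disease-query hits, $n$ would equal $N$ and the statistic would
  degenerate to 1 for every gene.
* **No multiplicity correction by default.** The raw-$p$ rule is the
  historical convention of this analysis family and is kept as the
  default; `correction = "BH"` switches the significance flag to
  Benjamini–Hochberg-adjusted values.

`rankByFrequency()` gives the complementary descriptive view — genes
ordered by $k$, the raw co-citation count — which is how "most
frequently cited genes" tables are built.

## Gene mention tagging

Named-entity recognition is **dictionary-based and deterministic**: a
lexicon (Entrez-style id, canonical symbol, pipe-separated synonyms)
is compiled into a normalized match index. Normalization case-folds and
removes non-alphanumerics, so `IL-6`, `il 6` and `IL6` share one key.
Matching is anchored at token boundaries, scans n-grams up to the
longest alias (counting both alias tokens and letter/digit segments, so
one-token aliases still match their hyphenated surface forms), and
resolves overlaps longest-match, left to right. Aliases whose normalized
key maps to more than one gene are dropped at load time with a message;
a user-supplied stop list removes aliases colliding with common words.
A trained statistical recognizer would buy recall at the cost of
determinism and an undistributable model; with a dictionary the
recall/precision trade-off is entirely in the user's lexicon, and every
downstream count is exactly testable.

**Conjunction resolution** expands coordinated elided mentions with a
finite pattern set: an anchored mention whose surface splits into base +
suffix (`IL-2`, `MMP-2`, `VEGF-A`) followed by fragments of the form
`, -4`, `/9`, `and -6` yields candidate base+suffix forms, each
re-validated against the lexicon before emission. Expanded mentions
carry the span of the eliding fragment and are marked `expanded`, and
are exempt from the non-overlap rule. The pattern set is a documented
stand-in for whatever heuristics a full NLP stack would use: anything it
does not match is left untouched, which errs on the side of
under-counting.

Titles are scanned by default (sentence 1 of every document) and can be
excluded with `scanTitles = FALSE`.

## Sentence segmentation

Sentence-level counting (used by co-citation) needs a deterministic
splitter. A boundary is terminal punctuation (`.`, `!`, `?`) followed by
whitespace and an uppercase letter or digit, suppressed after a guard
list of abbreviations (`Fig.`, `et al.`, `e.g.`, `i.e.`, `vs.`, ...).
Titles are always one sentence. Intervals are 0-based, half-open,
trimmed of surrounding whitespace, and jointly cover all non-whitespace
text; segmentation is idempotent.

## Enrichment

`enrichGeneSets()` tests the significant gene set against GO (read from
GAF 2.x, aspects P/F/C mapped to BP/MF/CC, `NOT` rows skipped) and
pathway collections (GMT), using the same exact tail — equivalently the
one-sided Fisher exact test on the $2\times 2$ overlap table. Two
standard conventions are applied: the background universe defaults to
genes carrying at least one annotation (testing unannotatable genes
deflates every p-value), and term gene sets are intersected with the
background before testing. Annotation propagation up the GO graph is
deliberately out of scope; supply pre-propagated annotations if you
need it.

## The gene network

Edges come from three evidence classes, following the KEGG vocabulary:

* **KGML relations** (`readKgml()`): ECrel (successive catalytic
  steps), PPrel (binding/modification), GErel (transcription factor →
  target). Non-gene entries (compounds, map nodes) are skipped;
  multi-gene entries expand to all cross pairs; subtype names are kept
  as evidence.
* **PPI tables** (`readPpiTable()`): two-column exports of
  protein-interaction databases, typed PPrel.
* **Co-citation** (`cocitationEdges()`): the hypergeometric tail at
  *sentence* granularity — $N'$ sentences overall, $m'$, $n'$
  sentences citing each gene, $k'$ citing both. An edge requires
  $p < \alpha$ **and** $k' \ge 2$ co-citing sentences; the minimum
  support suppresses single-sentence coincidences that can reach
  nominal significance in a large corpus, and is configurable down
  to 1.

`mergeNetwork()` forms the undirected union, deduplicated by unordered
pair with evidence concatenated and the smallest co-citation $p$ kept.
The network is undirected throughout: GErel directionality is evidence
metadata, not an edge direction, because degree and hub analysis treat
connections symmetrically. Merging is commutative and idempotent, nodes
exist only through edges, and the degree sum always equals twice the
edge count. An optional restriction keeps edges touching a supplied
gene set (by default the significant genes plus their direct partners
when run through the pipeline); when nothing is significant the
pipeline falls back to co-citation edges over all mentioned genes.

### Degree topology and hubs

`fitPowerLaw()` fits $c(d) \propto d^{-\gamma}$ two ways:

* **`ls`** (default): least squares of $\log c$ on $\log d$, matching
  the straight-line log–log presentation such analyses report. On
  exactly collinear input it recovers the exponent and $R^2 = 1$ to
  machine precision. It is, however, a biased estimator on sampled
  degree sequences — the noisy high-degree tail flattens the slope.
* **`mle`**: the discrete maximum-likelihood estimate
  $\hat\gamma = 1 + n\,\big(\sum_i \ln \frac{d_i}{d_{\min}-1/2}\big)^{-1}$
  with a Kolmogorov–Smirnov goodness. With `dMin = "auto"` the cutoff
  is chosen by scanning candidate $d_{\min}$ values and keeping the one
  minimizing the KS distance (the Clauset–Shalizi–Newman procedure).
  The scan matters: at $d_{\min} = 1$ the continuous approximation in
  the formula is poor and preferential-attachment degree sequences are
  not yet in their power-law regime, biasing $\hat\gamma$ far below
  the theoretical value of 3; with the KS-selected cutoff, 2000-node
  preferential-attachment graphs yield $\hat\gamma \approx 2.5$–$3.1$.

A non-positive fitted exponent (for example a flat histogram) is
flagged `isPowerLaw = FALSE`. Fits require at least three distinct
degrees.

`identifyHubs()` ranks nodes by degree (ties by gene id) and selects by
`top_fraction` (default 0.05 — in a network of a few hundred nodes this
yields the familiar "15–20 hub genes" scale), `top_k`, or
`degree_threshold`. Ties at the cutoff are always all included, which
makes the selection invariant under node relabeling.

## The synthetic-corpus generator

No public snapshot of a bibliographic corpus can be bundled, so the
package ships a generator whose output has *known* ground truth and
exactly the statistical structure the association model assumes:

* each document is disease-positive with probability $\pi_d$ (default
  0.2 — a corpus retrieved around a disease plus its background
  literature);
* each gene is mentioned in a document with probability $\pi_g$
  (default 0.01, a realistic per-abstract rate for any single gene),
  independently across genes given disease status — exactly the
  hypergeometric null;
* planted genes have their mention probability raised to
  $\min(1, \rho\,\pi_g)$ in disease-positive documents ($\rho \ge 1$,
  clipped with a warning);
* an optional planted co-mention graph (preferential attachment,
  `mAttach` edges per arriving node from a seed dyad, hence
  $1+\sum_{v\ge 3}\min(v-1,m)$ edges) is realized by extra sentences
  naming both endpoint genes in a small fraction of documents — the
  only dependence between genes;
* mentions are placed as symbols or synonyms inside template sentences;
  a configurable fraction of multi-gene sentences is rendered as a
  coordinated elided form to exercise conjunction resolution.

Documents are bags of template sentences; the generator makes no
attempt at linguistic realism beyond what the matcher and the
conjunction resolver consume. Identical configuration and seed give
byte-identical files, and re-tagging generated text with the real
pipeline reproduces the stored truth counts *exactly* — a
self-consistency property the test suite enforces. What passing these
tests shows is that the statistics and the plumbing are correct under
the model's assumptions; it does not certify recall on real prose,
where lexicon coverage, ambiguous abbreviations and richer syntax
dominate performance.

The default study conditions used by the test suite and the acceptance
script are 5000 documents and 500 genes, with 20 planted genes at
$\rho = 8$ in the signal arm, ten seeds per arm. Under these
conditions the model-level expected power at $\alpha = 0.05$ is
essentially 1 and the null false-positive rate sits near 0.035 —
slightly below $\alpha$ because the discrete statistic cannot spend the
whole level. Power-law estimates use twenty 2000-node
preferential-attachment graphs. These sizes keep the full suite at
roughly two minutes while leaving every estimate's Monte-Carlo error
well inside the asserted bands.

## Numerical and degenerate-input choices

* `hypergeomTail` validates integrality and $0 \le k \le \min(m,n) \le
  N$ and errors otherwise; $k = 0$ returns exactly 1; the strict tail
  at the support maximum returns exactly 0.
* Ties in association results are ordered by ascending $p$, then
  descending $k$, then gene id — fully deterministic output files.
* Empty corpora refuse to score; empty networks refuse degree
  histograms and fits; empty significant sets skip enrichment and fall
  back to the all-genes co-citation network.
* Ambiguous lexicon aliases are dropped rather than guessed; expansion
  candidates not in the lexicon are discarded.
* The pipeline's output directory is write-once: a re-run requires
  `overwrite = TRUE` and reproduces every byte, and the manifest
  records the config hash and per-file checksums.

## Known limitations

* Dictionary NER cannot find genes absent from the lexicon and does not
  disambiguate species or abbreviation senses (no Schwartz–Hearst
  step); precision on real text depends on the supplied stop list.
* The conjunction pattern set covers the common coordinated-suffix
  forms only.
* GO annotations are used as given — no ancestor propagation.
* Curated-relation parsing keeps gene entries only; compound-mediated
  ECrel chains are not bridged.
* The least-squares power-law fit is descriptive; use the MLE with the
  KS scan for estimation, and treat any single-corpus exponent with the
  usual caution.
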