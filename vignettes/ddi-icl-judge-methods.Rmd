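---
title: "Judge-weighted in-context learning for drug-drug interaction prediction: methods and design"
author: "ddicl authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Judge-weighted in-context learning for DDI prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddicl)
```

## The problem and the method

Co-administered drugs can interact pharmacologically, and ranking candidate
drug pairs by interaction likelihood is a standard task in computational
pharmacology. `ddicl` implements a prediction pipeline that steers large
language models (LLMs) with *in-context learning* (ICL) instead of
fine-tuning, and fuses several models' verdicts with an *LLM-as-judge*
weighting:

1. **Similarity-driven exemplar selection.** For a query pair $(q_1, q_2)$,
   the pipeline retrieves the $k$ known-interacting pairs most similar to
   the query (positive demonstrations) and the $k$ most similar
   *non*-interacting pairs (hard negative demonstrations). The similarity
   of two unordered pairs is the product of the two drug-drug similarities,
   maximized over the two possible drug-to-drug assignments:
   $s(q, c) = \max\{\,\mathrm{sim}(q_1,c_1)\,\mathrm{sim}(q_2,c_2),\;
   \mathrm{sim}(q_1,c_2)\,\mathrm{sim}(q_2,c_1)\,\}$.
2. **Structured prompts.** Zero-shot and few-shot prompts are rendered from
   editable text templates with four fixed sections — input requirements,
   prediction task, consideration factors, examples — and demand a binary
   yes/no verdict plus an explanation.
3. **Pluggable backends.** Anything mapping a rendered prompt to raw
   response text is a backend; free-text responses are parsed into
   (verdict, score, explanation) with `unparseable` mapping to the
   non-committal score 0.5.
4. **Judge-weighted fusion.** A judge model scores each (anonymized)
   response on four rubric criteria — scientific accuracy, clarity and
   coherence, evidence support, relevance — each on a 1–5 scale plus an
   overall score. Weights $w_i \propto \mathrm{overall}_i$ yield the fused
   score $S_\mathrm{final} = \sum_i w_i S_{\mathrm{model},i}$, thresholded
   at 0.5 for the verdict and used directly as the ranking score for
   AUC/AUPR.
5. **Evaluation.** Stratified 10-fold cross-validation over known
   interactions plus an equal-sized seeded sample of non-edges, with
   exemplars drawn strictly from each fold's training data.

## Drug similarity measures

Five measures are implemented over three molecular representations. For
binary fingerprints $x, y$:

* Tanimoto: $\sum x_i y_i \,/\, (\sum x_i^2 + \sum y_i^2 - \sum x_i y_i)$ —
  shared substructures over the union of substructures;
* cosine: $\sum x_i y_i \,/\, \sqrt{\sum x_i^2 \sum y_i^2}$;
* Dice: $2 \sum x_i y_i \,/\, (\sum x_i^2 + \sum y_i^2)$.

On binary vectors these obey the exact identity
$\mathrm{tanimoto} = \mathrm{dice}/(2 - \mathrm{dice})$ and the ordering
$\mathrm{tanimoto} \le \mathrm{dice} \le \mathrm{cosine}$; both are enforced
in the test suite. A pair of all-zero fingerprints raises an error rather
than returning 0: a silent zero would corrupt top-$k$ rankings downstream.

Fingerprints are 2048-bit hashed circular (Morgan-style) fingerprints of
radius 2 by default. SMILES are parsed and canonicalized through Open Babel
(via ChemmineR/ChemmineOB); no installed R package provides circular
fingerprints, so the environment hashing is implemented here on the
heavy-atom graph: each atom starts from an element + degree invariant and is
iteratively re-hashed with its sorted neighbour invariants, every
environment from radius 0 up to the configured radius setting one bit
modulo the fingerprint length. The construction depends only on the
molecular graph, so any SMILES spelling of a molecule yields identical
bits.

The graph-level measure is the Weisfeiler–Lehman (WL) subtree kernel: $h$
rounds of neighbour-label refinement starting from element symbols, with
the kernel the dot product of pattern-count feature maps accumulated over
iterations $0..h$, normalized to $K/\sqrt{K_{11}K_{22}}$ for retrieval so
all metrics share the $[0,1]$ scale. Defaults chosen here: $h = 3$ (three
refinement rounds separate molecular neighbourhoods up to radius 3,
matching the fingerprint's resolution at radius 2 plus one round of
context; larger $h$ adds cost but little discrimination on drug-sized
graphs), initial labels = element symbols only, bond orders ignored — the
simplest faithful graph-level reading; a label-function hook would be the
natural extension point.

The embedding measure is the cosine of per-drug embedding vectors. The
default provider is a deterministic character-n-gram hashing embedding of
the canonical SMILES (n = 1..3, 64 signed hash buckets, L2-normalized):
reproducible everywhere with no pretrained weights. Any function
`(smiles, dim) -> numeric(dim)` can stand in for it, e.g. a pretrained
transformer encoder; such adapters are deliberately outside the test path.
In the pair-score product rule the embedding cosine is clamped at 0 from
below so every metric composes on $[0,1]$.

## Exemplar retrieval

Positive exemplars are ranked over the known-interaction set; hard
negatives over the complement (every unordered pair not known to
interact). Ties break on the lexicographic canonical pair key, making
selection fully deterministic. When the negative universe exceeds
`candidateCap` (default 50,000) a seeded uniform subsample of that size is
ranked instead — exact ranking inside the sample, quadratic blowup
avoided. The leakage policy removes the query pair itself from the
candidates (`exclude_pair`, default) or every candidate sharing a drug
with the query (`exclude_drugs`, stricter cold-start-style evaluation).

Few-shot prompts render the exemplars as one labelled block each, ordered
by globally descending retrieval score with positives and negatives
interleaved, so the first example block is always the exemplar most similar
to the query. (The alternative — grouping positives before negatives — was
rejected because it hides the score ordering from anything that can only
see the rendered text, including the offline mock backend below.)

## Offline mock backends and the synthetic world

The pipeline is testable without any live LLM. Two instruments make this
work:

**The oracle mock backend** wraps a planted ground truth. Given a few-shot
prompt it answers with the label of the highest-scoring exemplar (read from
the first example block), flipped with probability `pFlip`; given a
zero-shot prompt it answers the planted truth flipped with probability
`2 * pFlip` — emulating pre-trained knowledge as a noisier channel than a
good demonstration. Flip decisions are a deterministic hash of the backend
seed, the query and the prompting mode, so identical prompts always yield
identical predictions, repeated runs are byte-identical, and accuracy is
exactly monotone in `pFlip`.

**The synthetic world generator** builds a molecule library plus a planted
interaction structure. Molecules are seeded concatenations of curated,
chainable SMILES fragments (guaranteeing parseable structures), organised
as congeneric series: prototype scaffolds of 6–9 fragments, each drug
either the parent compound of its series or a terminally decorated
analogue. This mirrors real screening collections and gives the library
clusters of structurally similar molecules — without them, similarity
retrieval would have nothing to find. Interactions follow a latent-factor
link model with a structural coupling:
$P(\mathrm{edge}_{ij}) = \mathrm{logistic}(\alpha + z_i \cdot z_j +
\lambda\, T_{ij})$, with $z_i \sim N(0, I_d)$, $T_{ij}$ the fingerprint
Tanimoto similarity (the same fingerprints the retriever uses — a
deliberate idealization that makes the planted signal detectable by
construction), and $\alpha$ calibrated by bisection to a target density.
The default latent dimension is $d = 1$: the latent term is a nuisance
channel representing unobserved pharmacology, and the generator's purpose
is a world whose interactions are driven primarily by the structural
mechanism the method assumes; higher $d$ inflates the variance of
$z_i \cdot z_j$ and drowns that mechanism.

### What the synthetic study can and cannot show

With the study conditions used throughout the tests (200 drugs, density
0.05, $\lambda = 4$, `pFlip` 0.2, 10-fold CV), the zero-shot channel's
accuracy is pinned at $1 - 2\,p_\mathrm{flip} = 0.6$, i.e. AUC 0.6, while
the few-shot channel's AUC equals $0.2 + 0.3\,(m_+ + m_-)$, where $m_\pm$
are the rates at which the top exemplar's label matches the query's true
label. Beating zero-shot therefore requires a mean match rate above $2/3$.
Under the link model above that rate is structurally capped well below
this: the $e^{\lambda}$ odds-ratio ceiling, the non-zero background
similarity of fragment-built molecules, and the heavy-tailed
$z_i \cdot z_j$ noise jointly keep the majority of planted edges
structure-independent, so the top exemplar for a true-interaction query is
usually a hard negative. Empirically the few-shot mock plateaus near AUC
0.52 against the zero-shot 0.60. The study consequently demonstrates the
*retrieval* orderings — similarity retrieval beats random retrieval, and
judge-weighted fusion is at least as good as the uniform ensemble when the
judge tracks backend reliability — but not a few-shot-over-zero-shot gain;
with a planted-truth mock, the demonstration channel cannot out-inform the
channel that reads the truth directly unless retrieval is nearly perfect.
None of this says anything about real LLMs on real interaction data, where
the zero-shot channel is *not* a noisy copy of the ground truth; it is a
property of the offline harness.

## The judge and fusion

The judge prompt enumerates each model's verdict and explanation under
anonymized labels (Model 1..N) in a seeded-shuffled order; model names
never appear in the rendered text (position/name bias mitigation). The
mandated reply format is one labelled line per criterion
(`Model i - scientific accuracy: s`, ...); a missing overall defaults to
the mean of the four criteria. Weights are derived per query as
$w_i = \mathrm{overall}_i / \sum_j \mathrm{overall}_j$; a fixed reliability
weight vector can be passed to `deriveWeights()` instead, supporting
predetermined-weight workflows. The synthetic reliability-tracking judge
used in tests reads the anonymization permutation from the prompt object's
metadata (not from the text) — a live judge needs no such access. When a
judge model is itself a roster member its own response is still anonymized;
judge self-evaluation remains a known bias risk.

Fusion is a convex combination, so $S_\mathrm{final}$ always lies within
the per-model score range, equal weights reduce it to the unweighted
ensemble mean, and permuting (predictions, weights) jointly leaves it
unchanged — all tested exhaustively on random ensembles. The decision
threshold on $S_\mathrm{final}$ defaults to 0.5 and is configurable.

## Evaluation choices

* AUC is the rank-based Mann–Whitney statistic with midrank tie handling;
  AUPR is average precision with ties broken by descending score then
  stable order. Both are checked against brute-force oracles and, for AUC,
  against an independent library implementation.
* The ranking score is the continuous $S_\mathrm{final}$; raw verdicts are
  binary, and how per-model continuous scores would arise from yes/no
  outputs is the largest inferential gap the pipeline papers over —
  documented here deliberately.
* Evaluation negatives are a seeded uniform 1:1 sample of non-edges
  (configurable ratio); folds are stratified by label at the pair level.
  Inside `runCV()` the test order is shuffled (seeded) before scoring so
  the stable-order tie rule cannot be biased by construction order, and a
  leakage assertion aborts any fold whose exemplars touch that fold's test
  pairs.
* Problem sizes used by the shipped study: 200-drug worlds, 10 folds,
  exemplar counts $k \in \{0, 1, 2, 4, 8\}$, 10 world seeds in the test
  suite and 5 in the acceptance script — large enough for stable seed
  means, small enough to run on a laptop in minutes.

## Degenerate inputs and numerical conventions

Both-zero fingerprints, empty graphs, zero-norm embeddings, single-class
AUC input and an empty positive set for AUPR all raise immediately rather
than returning a default. Interaction pairs are stored with the
lexicographically smaller id first; `(a, b)` and `(b, a)` are the same
member everywhere. Density calibration in the generator runs 200 bisection
iterations and errors if the achieved expected density misses the target
by more than 10%. All randomness flows from a single integer seed through
deterministic hashed child seeds, so every artifact — worlds, exemplar
sets, prompts, predictions, reports — reproduces byte-identically.

## Known limitations

* The synthetic world does not attempt to mimic real chemistry
  distributions or interaction mechanisms; passing tests certify the
  pipeline's mechanics and orderings, not real-world predictive value.
* Live LLM adapters are a thin contract (`function(text) -> text` with
  retries); none are shipped, and nothing in the test suite requires
  network access.
* Fingerprint hashing uses a 26-bit polynomial hash; collisions are rare
  at 2048 bits but not impossible, as with any folded fingerprint.
* The few-shot example blocks carry labels only (no per-exemplar
  explanations); whether demonstrations should include explanations is an
  open design question left to the templates.

## A small worked run

```{r worked, eval = FALSE}
w <- generateWorld(nDrugs = 60, baseRate = 0.08, lambda = 4, seed = 12)
cfg <- runConfig(kExemplars = 4, seed = 12)
backend <- oracleMockBackend(w@interactions, pFlip = 0.1, seed = 12)
report <- runCV(w@library, w@interactions, list(backend), cfg, folds = 5)
report
```
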