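---
title: "Pan-cancer network prioritization of disease risk lncRNAs: models and methods"
author: "lncprior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pan-cancer network prioritization of disease risk lncRNAs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncprior)
```

## The problem and the model

Known disease–lncRNA associations are scarce, while known disease *genes*
are comparatively abundant. `lncprior` ranks candidate risk lncRNAs for each
of a set of cancer types using only known disease genes, under two
assumptions:

1. **Guilt by association.** Genes and lncRNAs with correlated expression
   across tumor samples tend to share function, so proximity in a
   co-expression network is evidence of shared involvement in disease.
2. **Phenotype similarity implies mechanistic similarity.** Diseases with
   similar clinical phenotypes tend to share molecular mechanisms, so a
   disease can borrow evidence from phenotypically similar diseases.

The pipeline has four stages.

**Probe re-annotation.** Legacy exon arrays measure lncRNAs incidentally.
A probe is assigned to an lncRNA when it falls completely inside one of that
lncRNA's exons and does not overlap the genomic span of any protein-coding
gene; probes contained in exons of two distinct lncRNAs are discarded as
ambiguous, and an lncRNA is retained only if at least four probes survive.
Expression is then per-probe log2, averaged per lncRNA, and
quantile-normalized across samples. Interval tests are delegated to
`GenomicRanges`; coding overlap is tested against the full gene span
(introns included), the stricter reading, because intronic probes are
ambiguous between the lncRNA and unprocessed coding transcripts. Strand is
ignored by default (exon-array hybridization is effectively unstranded); a
`stranded` flag restores strand-matched assignment.

**Network construction (GLCPN).** For each disease, Pearson correlation is
computed for every gene–gene and gene–lncRNA pair; a pair becomes an edge
when its co-expression score strictly exceeds 0.8 (gene–gene) or 0.7
(gene–lncRNA). lncRNA–lncRNA pairs are never formed. The per-disease
networks are integrated into one pan-cancer network whose edge weight is
the *frequency* of the pair across disease types (k of n diseases gives
k/n), placing co-expression weights on the same [0, 1] scale as the
protein–protein interaction probabilities that are merged afterwards: a
pair supported by both sources takes the maximum of the two weights — the
stronger evidence wins and no edge is ever down-weighted by the merge.

**Propagation and integration.** The weighted adjacency is column-normalized
into a transition matrix and, per disease, a random walk with restart is
iterated from the uniform distribution over that disease's seed genes,

$$p^{(t+1)} = (1 - r)\,W p^{(t)} + r\,p_0,$$

until the L1 change falls below `tol`. The converged \(p\) scores every node's
proximity to the seeds; stacking the per-disease rows gives a score matrix
\(S\). Integration across diseases is a single matrix product with the
disease phenotype similarity matrix \(P\):

$$s_{ik} = \sum_{j=1}^{N} P_{ij}\, s_{jk},$$

including \(j = i\) (a disease's own scores enter with weight
\(P_{ii} = 1\)). Candidates are then ranked per disease by \(s_{ik}\),
descending, with score ties broken by lexicographic node id so rankings are
deterministic.

**Evaluation.** ROC/AUC against known disease lncRNAs (negatives: all other
lncRNA nodes — no curated negative set exists); leave-one-out
cross-validation of the seed genes, with the held-out disease's walk
honestly recomputed and scores re-integrated for every fold; phenotype
ablations (replace \(P\) by the identity, or permute its off-diagonal
entries as symmetric pairs with the diagonal fixed, so permuted matrices
remain valid similarity matrices); a random-seed control that redraws
equal-size seed sets from a non-disease gene pool; disease-subset sweeps
that restrict \(P\) and \(S\) to sampled subsets always containing the
evaluated disease; and leave-disease-out prediction,
\(s_{ik} = \sum_{j \ne i} P_{ij} s_{jk}\).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `gg_threshold` | 0.8 | gene–gene co-expression cutoff (strict `>`, on \(\lvert r\rvert\)) |
| `gl_threshold` | 0.7 | gene–lncRNA co-expression cutoff |
| `signed` | `FALSE` | threshold raw \(r\) instead of \(\lvert r\rvert\) |
| `restart` | 0.7 | RWR restart probability \(r\) |
| `tol` | 1e-10 | L1 convergence tolerance of the walk |
| `max_iter` | 1000 | iteration cap (exceeding it is an error, with residual) |

The restart probability is the one genuinely free parameter of the walk;
0.7 is the long-standing community default for disease-gene propagation and
results are insensitive to it over a broad range because only the *ranking*
of steady-state scores matters. Whether co-expression should be signed is a
real modelling choice: absolute correlation is the common convention (strong
negative co-regulation is still evidence of shared pathway membership) and
is the default, with `signed = TRUE` preserving the alternative.

## Numerical choices

* **Column normalization, dangling mass.** The walk moves *to* a node in
  proportion to incident edge weights. Columns of isolated nodes are all
  zero; their outgoing mass is redirected to the restart vector each
  iteration, so \(\sum_k p_k = 1\) always holds. The redistributed fixed
  point equals the direct solve
  \(p = r\,(I - (1-r)W)^{-1} p_0\) up to a scalar, so rankings are
  unaffected.
* **Quantile-normalization ties.** By default, tied values within a column
  are assigned reference quantiles in their original order
  (`ties = "first"`), which makes the defining property of quantile
  normalization — identical sorted values in every column — hold *exactly*,
  ties included. The alternative `ties = "average"` gives tied entries the
  mean of the reference values at their rank positions (the `limma`
  convention); tied entries then share one value, at the cost of exact
  column identity. We default to `"first"` because downstream correlation
  thresholds are sensitive to the column distributions being genuinely
  identical.
* **Log2 before averaging.** Probe intensities are log2-transformed before
  the per-lncRNA mean, i.e. the summarized value is a geometric mean of raw
  intensities — the conventional choice for the multiplicative noise of
  hybridization arrays. The opposite order is defensible; it is fixed here
  and documented so results are reproducible.
* **Tie-breaking in rankings** is lexicographic by node id, making ranked
  lists byte-stable across runs and platforms.
* **Strict thresholds.** Edges require score strictly greater than the
  cutoff, matching the published rule "greater than 0.8 and 0.7".
* **Degenerate inputs.** Zero-variance features are skipped (with a warning)
  during correlation; empty seed sets, non-positive intensities, asymmetric
  phenotype matrices and malformed intervals are errors naming the record.

## The synthetic benchmark

Real inputs for this method (thousands of arrays, curated disease-gene and
disease-lncRNA databases, a text-mined phenotype similarity matrix) are not
shippable, so the package carries a generator whose output has the same
statistical shape and *known* ground truth.

Diseases are partitioned into phenotype blocks; each block owns planted
co-expression modules whose members are generated from a shared latent
factor, \(x = \sqrt{\rho}\, z + \sqrt{1-\rho}\,\varepsilon\), so the
expected within-module correlation is exactly \(\rho\) (testable by direct
simulation). Within a block, each disease's seed genes are drawn from a
*different* module while its positive lncRNAs span all the block's modules:
a disease's own walk cannot reach half of its positives, and only phenotype
pooling with its block partner recovers them. This makes the integration
step genuinely informative rather than decorative, mirroring the motivating
setting of diseases with incomplete knowledge. PPI edges are added within
modules at high confidence (scores ~ U(0.7, 1)) and as random background at
low confidence (U(0.1, 0.4)), exercising the max-merge rule.

Defaults: 6 diseases in 3 blocks of 2, 500 genes, 200 lncRNAs, 60 samples
per disease, 2 modules of 30 members per block, \(\rho = 0.9\), unit noise,
within/between-block similarity 0.8/0.2, 10 seeds and 12 positives per
disease, generator seed 42. These sizes keep the full pipeline (network,
walks, all ablations) under a minute on one CPU while leaving every effect
direction resolvable; they were chosen once, before evaluation, as a
realistic miniature of a pan-cancer compendium (hundreds of features per
module-bearing pathway, tens of samples per study).

What the benchmark does **not** emulate: probe-level artifacts (GC bias,
batch effects), heavy-tailed expression, overlapping modules, scale-free
degree structure, and incomplete/noisy seed or positive lists. Passing the
planted-signal tests therefore shows the machinery is correct and the
integration direction is real — not that the method attains any particular
accuracy on real tumor compendia, whose published headline AUCs depend on
the original array collections and database snapshots.

A second, probe-level fixture (`probe_fixture()`) covers the re-annotation
rules with hand-enumerated expected assignments: containment, coding-span
overlap, boundary straddling, the four-probe minimum and ambiguity discard.

## Design choices where the design was open

* **Internal coordinates** are Bioconductor-native 1-based closed
  `GRanges`; BED input is converted on read by `rtracklayer`. One container,
  one conversion point.
* **Frequency scale.** Pan-cancer edge weights are k/n rather than raw
  counts so they share the PPI probability scale; the combination rule for
  dual-source edges is `max`.
* **Negatives.** For lncRNA ROC: all lncRNA nodes not listed positive for
  the disease. For gene LOOCV: all gene nodes never used as a seed for the
  disease.
* **Permutation scheme.** Off-diagonal entries of \(P\) are shuffled as
  symmetric pairs with the diagonal fixed — permuted matrices remain
  symmetric similarity matrices, which entry-wise shuffling would not
  guarantee.
* **Empirical p-values** use the +1 correction, \(p = (b + 1)/(m + 1)\),
  never exactly zero.
* **Mean AUC** across diseases is unweighted.
* **Seed fan-out.** The pipeline derives per-stage RNG seeds by hashing the
  stage name into the global seed, so adding a stage never perturbs another
  stage's randomness.

## A worked run

```{r example}
bench <- generate_benchmark(synthetic_spec())
net <- build_glcpn(bench$expr, bench$node_types, bench$ppi)
fit <- lnc_prioritize(net, bench$seeds, bench$P)
fit
head(predict(fit, "D1", type = "lncRNA"), 3)
evaluate_roc(fit, bench$positives)$mean_auc
```

## Known limitations

* Co-expression is Pearson-only by design (no mutual information or
  Spearman alternative), and lncRNA–lncRNA edges are deliberately absent.
* The walk treats the network as a single homogeneous layer; heterogeneous
  multi-layer walks with inter-layer jump probabilities are out of scope.
* All-pairs correlation is O(features²) per disease; it is computed
  blockwise to bound memory, but feature sets in the 10⁵ range will be slow
  in plain R.
* The LOOCV recomputes one walk per held-out seed; for seed sets in the
  hundreds this is the dominant cost (it is exact, not an approximation).
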