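---
title: "Ranking oligogenic variant combinations with oligorank: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking oligogenic variant combinations with oligorank: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligorank)
library(tibble)
```

## The model

`oligorank` addresses candidate-variant prioritization when digenic or
oligogenic inheritance is suspected — variable penetrance or expressivity
in a pedigree, or the failure of single-variant prioritization. Its inputs
are (i) a set of variants from a personal genome with a score
$\sigma(v) \in [0,1]$ per variant, and (ii) a background gene-interaction
network $\Upsilon$ whose nodes are genes. An $n$-tuple of distinct variants
$(v_1,\dots,v_n)$ located in genes $g_1,\dots,g_n$ receives

$$
\bar\sigma(v_1,\dots,v_n) =
\begin{cases}
\sigma(v_1)+\dots+\sigma(v_n) & \text{if } g_1,\dots,g_n \text{ form a
connected subgraph of } \Upsilon\\
0 & \text{otherwise.}
\end{cases}
$$

The additive form means the ranking among *connected* tuples is exactly the
ranking by summed member evidence; the connectivity gate encodes the
disease-module assumption that jointly causative genes interact — by
protein contact, co-expression, shared pathway or regulatory relationship,
whatever the network's edges represent. A tuple whose genes lack
interaction evidence scores 0 and carries no ranking information, so it is
omitted from output by default (`include_disconnected` restores it).

Two readings of "connected subgraph" are possible: connectivity of the
subgraph *induced* on the tuple's genes, or connectivity within the full
network where genes outside the tuple may bridge. We default to the
stricter induced reading — every reported combination then has direct
interaction evidence among its own genes — and expose the relaxed one as
`is_connected_tuple(..., via_bridges = TRUE)`. This was a genuinely open
choice; the strict reading makes the reported modules self-contained and
is the one validated throughout the test suite.

**Compound heterozygosity.** Two different alleles of one gene can jointly
cause disease. We model this by adding a self-loop to every node
(`add_self_loops()`): a tuple may then repeat a gene, and the repeated gene
"interacts with itself". Tuple enumeration additionally gates same-gene
tuples behind `allow_compound_het`, so both the network marker and the
configuration flag must be present — enabling self-loops for one analysis
cannot silently change another. A triallelic combination is three variant
alleles over two genes, the doubled gene self-looped.

**Gene assignment.** Exonic and non-exonic variants are both admitted. A
variant inside a gene interval gets that gene; a variant outside all
intervals gets the gene with the nearest interval boundary (distance in
bases to the closer of start/end, 0 inside). The tie-break is the
lexicographically smallest gene id; coordinates are 1-based inclusive
throughout, and strand is ignored. Boundary distance was chosen over
midpoint or TSS distance for simplicity and determinism.

**No filtering.** `read_vcf()` keeps every record: non-PASS FILTER values,
all qualities, all allele frequencies, and it applies no inheritance-model
filter. Modifier alleles can be common enough, and individually benign
enough, that any of the usual rare-disease filters would remove them
before the combination could be scored.

## Per-variant scores

Tuple ranking consumes only a `[0,1]` score per variant, so any external
phenotype-aware pathogenicity predictor can supply them via
`load_scores()` (variants missing from the table score 0, with a warning).
The built-in scorer is a deliberately transparent stand-in, not a trained
classifier:

$$\sigma(v) = w \cdot \text{pathogenicity}(v) + (1-w) \cdot
\text{sim}(\text{profile}, \text{gene}(v)), \qquad w = 0.5 .$$

The similarity is Resnik best-match-average over a phenotype ontology:
annotations are propagated to ancestors (true-path closure), each term's
information content is $IC(t) = -\log(n_t/N)$ with natural logarithm
($n_t$ genes annotated to $t$, $N$ annotated genes), and for a profile
$P$ and gene term set $G$

$$\text{sim}(P, G) = \frac{1}{2\,IC_{\max}} \left(
\frac{1}{|P|}\sum_{p \in P} \max_{g \in G} IC(\mathrm{MICA}(p,g)) +
\frac{1}{|G|}\sum_{g \in G} \max_{p \in P} IC(\mathrm{MICA}(p,g))
\right),$$

where MICA is the most informative common ancestor and $IC_{\max}$ the
corpus-wide maximum IC (configurable). The averages run over the
*asserted* term sets; the closure enters through the IC corpus and the
common-ancestor search. This keeps self-similarity of a maximally specific
profile at exactly 1 and makes the measure symmetric in the two sets at a
fixed corpus. Terms annotating no gene have undefined IC and are excluded
from maxima; a gene without annotations scores 0. The default weight
$w = 0.5$ gives the molecular and the phenotypic evidence equal voice; it
is a parameter, not a fitted value.

## Enumeration: exhaustive oracle and beam search

`rank_tuples_exhaustive()` scores every $k$-subset (worst case
$O(n^k)$; it refuses above `max_candidates`, default $2\times10^6$). It is
the reference semantics and the oracle that the beam implementation is
validated against.

`rank_tuples_beam()` bounds memory: level 1 seeds the beam with the
`beam_width` highest-$\sigma$ variants whose gene is in the network; each
later level extends every partial tuple by variants whose gene is adjacent
to at least one gene already in the tuple (self-loop adjacency permits
same-gene extension when compound heterozygotes are allowed), deduplicates
by member set, and keeps the `beam_width` best partial sums. Because every
extension is adjacent to the existing members, each completed tuple's
induced subgraph is connected by construction; a strict final re-scoring
with the tuple score is applied regardless, and final scores are recomputed
in a canonical member order so beam and exhaustive output are
bit-identical when the beam saturates. Extension-time connectivity is
deliberately weaker than the final check so that valid modules can be
assembled one adjacent gene at a time.

Determinism is treated as part of the contract: all orderings use
descending score with a C-locale lexicographic tie-break over the sorted
member variant ids (single variants tie-break on genomic position), so
identical inputs give byte-identical output. A narrow beam can
legitimately lose tuples — with `beam_width = 1` and the top variant in an
isolated gene the search dead-ends and returns nothing; that is documented
behaviour, not an error. The default `beam_width` of 1000 is generous for
the candidate-set sizes (tens to a few thousand variants) this tool is
meant for.

## The spike-in benchmark

Real evaluations of this kind insert curated causative combinations into
sequenced genomes and ask whether the method recovers them. The package's
generator (`generate_case()`) reproduces the *structure* of that protocol
at desk scale with fully synthetic material:

* background: `n_background = 100` variants with scores drawn from
  Beta(2, 5) — right-skewed, most variants benign-looking — assigned
  uniformly to `n_genes = 20` genes;
* network: Erdős–Rényi with `edge_prob = 0.2` (average degree ≈ 4,
  comparable to the gene-level density of curated interactome exports);
* truth: a pair (or triple) of variants in distinct genes, spiked in at
  heterozygous genotype and scored at the `truth_score_quantile` of the
  background law (1.0 by default: the strongest plausible signal). When
  `truth_connected`, a path is added among the truth genes; otherwise all
  edges among truth genes are removed, so the combination is guaranteed to
  lack interaction evidence and the two regimes are cleanly separated.

Everything is reproducible from one seed; `run_benchmark()` derives case
$i$'s seed as `seed + i`. Recovery is reported as Top-set (all truth
variants at the very top ranks — ranks 1..2 for a pair, 1..3 for a
triallelic truth in single-variant ranking; rank 1 tuple identity in tuple
ranking) and Top-10, each for an "all cases" split and an "interacting
only" split containing the cases whose truth genes are connected in that
case's network. Whether the tuple-level criterion should instead flatten
the tuple list into a variant ranking is ambiguous in general; the
tuple-level reading is the default and the flattened one is available via
`evaluate_tuple_ranking(..., criterion = "flattened")`.

What the generator does *not* emulate: linkage structure, realistic score
distributions of a trained predictor, network degree heterogeneity and
study bias, shared pathways between background genes and phenotypes. A
passing benchmark therefore demonstrates the correctness of the machinery
(enumeration, connectivity gating, evaluation bookkeeping) and the
qualitative behaviour of the method — not clinical performance on real
genomes.

Rank distributions of competing methods are compared with a two-sided
Mann-Whitney U test (`compare_rank_distributions()`): exact via the null U
distribution for tie-free samples of at most 20 per group; exact by full
enumeration of the permutation null when ties are present and
$\binom{n_1+n_2}{n_1}$ is at most $2\times10^5$; otherwise the normal
approximation with tie and continuity correction. Sidedness was an open
choice; two-sided is the conservative default.

## Numerical and degenerate-input choices

* Scores are validated into $[0,1]$; tuple scores are recomputed from
  members in a canonical order, so the additivity invariant holds to
  $10^{-12}$ (in practice exactly).
* Duplicate edges collapse keeping the maximum confidence; STRING-style
  integer scores are divided by 1000; the confidence threshold default is
  0 (no cutoff).
* Empty inputs: an empty edge list yields an empty network; ranking over
  it yields an empty (header-only) result; an empty tuple or phenotype
  profile is an error.
* `k = 1` degenerates to single-variant ranking restricted to in-network
  genes.
* A variant with no assignable gene can never appear in a returned tuple
  (its tuples are disconnected by definition).

## Validation problem sizes

The test suite validates beam-vs-exhaustive identity on 200 random
instances of up to 30 variants over up to 15 genes with $k \in \{2,3\}$
(beam width saturating), connectivity against an independent
breadth-first/igraph oracle exhaustively on small networks, and the
benchmark at its default conditions with 50 cases, each cross-checked
against exhaustive enumeration. These sizes exercise every code path —
including compound-heterozygote instances — while keeping the whole suite
fast enough to run habitually.

## Known limitations

* The built-in scorer is a stand-in; results on real data hinge on the
  external predictor supplied via `load_scores()`.
* The method is bounded by the completeness and bias of the interaction
  network: a true causative combination without recorded interactions
  cannot rank (by design — this is the method's stated trade-off).
* Exhaustive enumeration does not scale beyond small $k$; beam search
  trades completeness for memory, and narrow beams can miss modules whose
  members all score modestly.
* Variant normalization (left-alignment), structural variants and phasing
  are out of scope; compound-heterozygote handling therefore trusts the
  input genotypes.
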