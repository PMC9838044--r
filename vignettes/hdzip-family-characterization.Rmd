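---
title: "Characterizing a plant HD-Zip gene family: methods and design notes"
author: "HDZipKit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a plant HD-Zip gene family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HDZipKit)
```

HDZipKit characterizes a plant HD-Zip transcription-factor gene family
from transcriptome-scale evidence: membership and subfamily calls from
Pfam-style domain hits, genome locus assignment from alignment tables,
Ka/Ks-based duplication dating, expression-breadth analysis against random
background genes, Spearman co-expression networks with a bootstrap
network-formation-tendency test and connectivity-based hub calling, and a
qPCR stress-response analysis. This vignette explains the models and the
design choices behind each step, and what the synthetic-data generator
does and does not emulate.

## Family identification and subfamily classification

HD-Zip proteins couple a homeodomain (HD) to a leucine zipper. Because
some subfamily III/IV members carry a zipper-loop-zipper variant rather
than the canonical HALZ domain, membership is defined by domain
*combinations*: HD together with HALZ, or HD together with the START
lipid-transfer domain. The four subfamilies are then told apart by extra
diagnostic motifs:

| subfamily | diagnostic domain content |
|---|---|
| I | HD + HALZ |
| II | HD + HALZ + CPSCE |
| III | HD + START + MEKHLA |
| IV | HD + START |

The definitions of I/II and III/IV are nested, so `classifySubfamily()`
gives the motif rules precedence: CPSCE decides II before the plain
HD+HALZ default, MEKHLA decides III before the plain HD+START default.
When both HALZ and START are present the HALZ branch wins (the
I/II side is the canonical definition; such transcripts are rare and
worth manual review). The classifier is total: every domain set maps to
exactly one of I–IV or a rejection with a recorded reason, mirroring the
"deleted" candidates of a manual screen. Real families contain
discordant members (e.g. subfamily II genes whose detectable domains are
only HD+HALZ); the classifier follows the domain evidence it is given and
leaves reconciliation against phylogeny to the analyst.

Candidate sets from several search strategies (domain tblastn, known-gene
BLAST, HMM search) are merged by exact union with per-id provenance, so
method-exclusive identifications are countable — the reason multi-method
screens are worthwhile.

**Locus assignment.** Transcript-to-genome alignments are filtered by
aligned length ≥ 180 bp (about the span of the HD domain), identity
≥ 99 % and E-value ≤ 1e-6 — all configurable. Each transcript is placed
at its best surviving alignment (lowest E-value, ties broken by higher
identity, then leftmost start, for deterministic output), and best
alignments overlapping by ≥ 1 bp on the same chromosome are merged
transitively into loci (via `IRanges::reduce`). The ≥ 1 bp transitive
rule is the minimal reading of "transcripts positioned to the same
locus"; no strand information is used because the alignment tables carry
none. A locus whose members all come from one genotype is
genotype-specific (`findGenotypeSpecific()`).

**GO summary.** `summarizeGo()` partitions annotated members into the
seven disjoint cells of the BP/MF/CC Venn diagram, per subfamily; cells
always sum to the annotated total, which the tests enforce as an
invariant.

## Ka, Ks and duplication dating

Duplicate pairs are screened by all-vs-all global alignment identity
(`selectDuplicatePairs()`), and each pair is dated from its coding
alignment. The substitution counting is the Nei–Gojobori (1986) method,
the classical counting estimator:

- **Sites.** For each codon, each of the nine single-nucleotide changes
  either preserves the amino acid (synonymous) or not; the synonymous
  site count is the synonymous fraction per position summed over the
  three positions. Changes creating a stop codon count as nonsynonymous
  (they change the protein). Site counts are averaged between the two
  sequences; N + S = 3 × codons exactly.
- **Differences.** Codons differing at *k* positions are connected by
  *k*! single-step pathways; synonymous/nonsynonymous step counts are
  averaged over pathways with equal weight, excluding pathways that pass
  through a stop codon (if every pathway does, all are kept with
  stop-crossing steps counted as nonsynonymous).
- **Correction.** The proportions pN = Nd/N and pS = Sd/S are corrected
  for multiple hits with the Jukes–Cantor formula
  d = −(3/4)·ln(1 − (4/3)p), undefined (flagged saturated) at p ≥ 3/4.

The tests verify the counter against an independent brute-force
pathway enumerator on every sense-codon pair with ≤ 2 differences, plus
symmetry and site-conservation properties. Codons containing gaps or
ambiguity codes are dropped pairwise with a logged count. Unaligned
pairs are first aligned at protein level (Needleman–Wunsch, BLOSUM62)
and the gaps projected back to codons (`alignCodons()`).

Divergence is dated with a synonymous molecular clock, T = Ks/(2λ), with
λ = 6.5e-9 substitutions per synonymous site per year by default (the
classical dicot rate). Note the convention: Ka is *nonsynonymous*, Ks
*synonymous*; only this reading is consistent with dating from the
synonymous distance. ω = Ka/Ks < 1 indicates purifying selection.

```{r kaks-example}
r <- computeKaKs("TTTGATGCC", "TTCGATGCC")
r
divergenceTime(0.364)   # MYA at the default clock rate
```

## Expression breadth and the random-background control

A gene is called expressed at TPM > 0 by default (strict inequality;
threshold configurable). Breadth is the number of samples with
expression, summarized over three sample designs: four root ages
(5/12/18/25 years), 14 tissues of a four-year-old plant, and
four-year-old roots of 42 cultivars. `coreGeneSet()` intersects the
all-samples sets of the designs; `ageTrendGenes()` flags strictly
monotone age profiles with fold span ≥ 2 (an operationalization of
"regular variation with age"; both parameters configurable);
`clusterSamples()` groups samples by average-linkage clustering of
1 − Spearman ρ.

**Background comparison.** The family's breadth is compared with
`nBoot = 20` random same-size gene sets drawn without replacement from a
background pool (target genes excluded from the pool first). Significance
of the "expressed in ≥ 1 sample" count uses a **prediction-interval
t-test**: under the null the target's count is one more draw from the
replicate distribution, so

t = (obs − mean) / (sd · √(1 + 1/nBoot)),  df = nBoot − 1.

A two-sample t-test between bootstrap replicates would treat within-side
resampling spread as the sampling variance of the set-level statistic,
which it underestimates badly (replicates share genes), inflating false
positives by an order of magnitude; the prediction form is calibrated,
and the acceptance suite verifies ≈ 1 % type-I error at the 1 % level
over 1000 null simulations. No multiple-testing correction is applied by
default (`p.adjust` can be applied downstream). The same test is used
per threshold in the network tendency analysis below.

## Co-expression networks, tendency test and hubs

`spearmanEdges()` scores all gene pairs by Spearman ρ on average ranks
(tie-corrected, equivalent to Pearson on ranks) with two-sided p from
t = ρ·√((n−2)/(1−ρ²)) on n−2 df; at n = 8 this approximation stays
within 0.02 of the exact 8!-permutation law for representative rank
configurations (worst case ≈ 0.024, measured in the test suite).
Zero-variance genes (e.g. never expressed) are excluded with a warning,
and by default the tendency analysis drops genes expressed in zero
samples, as only expressed transcripts are networked.

Networks retain edges with p ≤ threshold regardless of the sign of ρ
(only significance cutoffs are defined for the analysis; an |ρ| filter
can be applied to the edge table by the user). Clusters are connected
components — the minimal reading of network "clusters"; Markov
clustering would be a stricter alternative but is deliberately not
implemented. Component labels are anchored at the lexicographically
smallest member for deterministic output. The threshold sweep defaults to
decade steps 5e-2 … 1e-8. Hubs are nodes with degree strictly greater
than the cutoff (15 for the 42-sample design, 10 for the 14-sample
design in the motivating study), `findHubs()`.

## qPCR stress response

`relativeExpression()` implements the Livak 2^−ΔΔCt method: per
replicate ΔCt = Ct_target − Ct_reference, ΔΔCt subtracts the mean ΔCt of
the calibrator group (pH 6.0 control), fold = 2^−ΔΔCt. Group folds are
summarized by the **geometric mean** (computed as a difference of means
on the Ct scale), which makes the calibrator group's mean fold exactly 1
by construction — the arithmetic mean is ≥ 1 by Jensen's inequality
whenever replicates scatter, so it cannot satisfy that anchor; spread is
reported as the sd of log2 folds. Treatment-vs-control comparisons
(fresh weight or expression) use a two-tailed Welch t-test with the star
code `*` p ≤ 0.05, `**` p ≤ 0.01. Hub-response correlations are Spearman
over all 15 group × replicate folds by default (n = 15 for power;
`useGroupMeans = TRUE` correlates the 5 group means instead).

## Synthetic data: what it emulates, and what it does not

Every input has a seeded generator emitting data plus ground truth:

- `simDomainTable()` — domain evidence whose planted subfamily labels the
  classifier must recover exactly; defaults mirror the 73/13/11/20
  subfamily sizes.
- `simCandidateSets()` — three candidate sets with prescribed sizes,
  union and method-exclusive counts (defaults 114/83/112 → 117, one id
  exclusive to the second method).
- `simGenomeAlignments()` — planted shared and genotype-specific loci
  (defaults 60 + 5); every planted alignment spans its locus midpoint
  with ≥ 100 bp on each side so it passes the 180 bp filter and merges
  transitively; decoys exercise each filter.
- `simCdsPair()` — at most one substitution per codon, synonymous with
  probability pS·s_c and nonsynonymous with pN·n_c, so expected
  difference proportions hit the targets and NG86 recovers the planted
  counts exactly (single-difference codons are pathway-unambiguous).
  Infeasible target/ancestor combinations (per-codon probability > 1,
  possible above 1/3) raise an error rather than biasing the draw.
- `simExpression()` — a latent-factor Gaussian model exponentiated to
  TPM-like values; Spearman statistics are invariant to the per-gene
  monotone transform, so planted rank correlations survive exactly.
  Breadth classes are structural zeros, so the TPM > 0 call is exact on
  fixtures. Defaults mirror the motivating study's scale (117 family
  genes; 4/14/42 samples; 20 bootstrap draws).
- `simQpcr()` — Ct tables with planted fold changes recovered exactly at
  zero noise.

The generators emulate correlation structure, breadth classes and effect
sizes — not library-size artefacts, count overdispersion, isoform
redundancy, batch effects or real TPM marginals. Passing tests therefore
demonstrate algorithmic correctness and statistical calibration under a
clean generative model, not robustness to every artefact of real
RNA-seq; dataset-dependent published counts (e.g. a specific network's
10 clusters / 826 edges) require the original data and are out of scope.

## Numerical choices and problem sizes

Floating comparisons in tests use 1e-9 absolute tolerance where exact
arithmetic is expected. Deterministic tie-breaks are used everywhere
ordering is visible (locus ids, edge ordering, hub sorting, cluster
labels). Degenerate inputs: constant genes/samples warn and are excluded
or assigned conservatively; saturated substitution proportions flag
rather than error; empty networks and empty generators return typed
empty objects. Simulation-based checks use 100 seeds (recovery rates),
1000 null repeats (type-I calibration) and 500-codon alignments (Ks
recovery), sizes chosen to give binomial/Monte-Carlo error comfortably
below the asserted margins. Every stochastic API takes a mandatory seed
and logs it in its output.
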