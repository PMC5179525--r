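---
title: "Methods: gene-family evolution analysis with lrrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family evolution analysis with lrrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrrkit)
```

## Scope

`lrrkit` implements the standard analysis chain used in genome-wide surveys
of plant LRR receptor-like kinase (LRR-RLK) families, from candidate
screening to codon-level selection tests. The external discovery tools of
such surveys (BLASTp, CDD, TMHMM, Pfam, MUSCLE, RAxML, MEME, read mappers)
are deliberately out of scope: the package consumes their standard tabular,
FASTA and Newick outputs and implements everything downstream — the decision
rules, the statistics, and a full ML implementation of the codon site
models. A synthetic-family generator with complete ground truth closes the
loop so that every stage can be validated without external downloads.

## Membership screening

A candidate enters the family when it has at least one homology hit with
E-value strictly below the cutoff (default `1e-10`; strict inequality
mirrors the usual "< cutoff" reporting convention) or appears in the
pre-annotated candidate list; the two sources are merged by union, which is
the natural reading when a survey combines a BLAST screen with
domain-annotation lookups. Membership then requires the receptor
architecture: at least one LRR repeat, at least one transmembrane (TM)
span, and exactly one kinase domain (KD), with the topology rule that all
LRRs end before the first TM begins (extracellular) and the KD starts after
the last TM ends (intracellular). The topology rule is an interpretation of
"LRRs in the ectodomain, kinase inside"; since annotation pipelines
occasionally mis-order domains, it is enforced with its own reason code
(`bad_topology`) and can be disabled (`require_topology = FALSE`).
"Defective" sequences are operationalized as those with an internal stop
symbol or fewer than `min_aa = 100` residues — a threshold chosen so that
fragments shorter than a kinase domain cannot pass; exact duplicates keep
the lexicographically smallest identifier so results are deterministic.

## Tandem duplication on scaffolds

Genes are chained per scaffold: consecutive genes (sorted by start) whose
start-to-start distance is at most 200 kb are linked, and chains of two or
more genes form proximity clusters. Two choices deserve note. First, the
threshold is applied to adjacent start-to-start distances (chaining), not
to the total cluster span, so a cluster may span more than 200 kb end to
end; a span rule would make the cluster definition order-dependent in
unpleasant ways. Second, the boundary is inclusive — a pair at exactly
200,000 bp is linked — because "within 200 kb" includes its endpoint in
common usage. A cluster is validated as a tandem-duplication cluster iff
its members are strictly monophyletic on the rooted family tree (the MRCA's
leaf set equals the cluster). Clusters of three or more genes that fail
whole-cluster monophyly additionally report their cherry sub-pairs, and a
lenient mode (`mode = "subfamily"`) accepts clusters whose members merely
share a subfamily call, since published analyses sometimes describe
rejected clusters only as "not in the same clade". The tandem fraction is
the number of genes in validated clusters over the family size.

## Midpoint rooting and subfamily classification

The root is placed halfway along the maximal-patristic-distance leaf pair;
ties between equally distant pairs are broken by lexicographic order of the
leaf labels, making the operation deterministic. All leaf-to-leaf patristic
distances are preserved; trees whose branch lengths are all zero are
rejected because the midpoint is undefined.

Classification uses reference leaves with known subfamily labels. For each
label the maximal clade containing only that label's references is located
(starting from the references' MRCA and extending rootward while the clade
stays pure); query leaves inside inherit the label, and `supported` records
whether the clade's bootstrap support exceeds the threshold (default 80,
strict inequality — "support above 80"). When a label's references do not
form such a clade, the label is flagged `monophyly_uncertain` (the asterisk
convention) and its queries are assigned by the majority label of the
references in their smallest reference-containing ancestor, with
lexicographic tie-break; queries whose majority label belongs to a cleanly
monophyletic subfamily they fall outside of remain `unclassified` rather
than being forced into a clade that excludes them. Subfamily subdivisions
(e.g. VI-1 versus VI-2) must be supplied in the reference table — no rule
can infer them from topology alone.

## Domain, motif and intron conservation

Per-subfamily LRR counts and intron counts are summarized as (min, max,
mode), the mode being the value a table would print in bold; ties report
all tied values. Motif presence per subfamily is categorized as `all`
(every member), `most` (more than 50% but not all), `some` (at most 50%
but not none) and `none`; the 50% split operationalizes "most members" and
is configurable. A motif is subfamily-specific when it reaches `all`/`most`
in exactly one subfamily and `none` elsewhere.

Column information content is bits = log2(20) − H with H the Shannon
entropy of amino-acid frequencies over non-gap symbols, without
small-sample correction; gaps are excluded by default (`gap_as_symbol`
switches to a 21-letter alphabet). The consensus residue is the modal
residue (lexicographic tie-break) and its rendering follows the bits
thresholds: `x` below 1, lowercase in [1, 2), uppercase in [2, 3), bold at
3 and above.

Intron positions are expressed as cumulative coding-nucleotide offsets
before each intron, in transcription order (strand-normalized), with phase
= offset mod 3; UTR introns are invisible by construction since only CDS
gaps count. Two profiles share an intron when offsets differ by at most
`tolerance_nt` (default 0 — "roughly the same position" is qualitative, so
exact matching is the defensible default) and phases are equal. Because
equal phase forces offsets to be congruent mod 3, the matching decomposes
by phase class, within which an in-order greedy sweep attains the maximum
matching; similarity is reported as Jaccard shared/(nA + nB − shared),
defined as 1 for two intronless genes.

## Codon site models

The selection machinery is a self-contained ML implementation of the six
classic site models over the 61 sense codons of the universal code, in the
Goldman–Yang parameterization: the rate of a single-nucleotide codon change
i→j is π_j, times κ for transitions, times ω for non-synonymous changes;
multi-nucleotide changes are prohibited. Matrices are scaled so that the
expected substitution rate per codon is one *at the mixture level* (the
class matrices share a common scale factor), so branch lengths are expected
substitutions per codon. Reversibility (π_i q_ij = π_j q_ji) holds by
construction and transition probabilities are computed by symmetric
eigendecomposition.

Site classes: M0 one ratio; M1a ω0 ∈ (0,1) with proportion p0 plus ω = 1;
M2a adds ω2 ≥ 1; M3 three free (ω, p) classes (reported sorted by ω);
M7 a Beta(p, q) on (0,1) discretized into 10 equal-probability categories
represented by their conditional means (computed in closed form from the
incomplete-beta function); M8 adds an extra class ω_s ≥ 1 with proportion
1 − p0. Likelihoods use Felsenstein pruning per site and class with
per-node rescaling against underflow; alignment columns with gaps are
retained, gaps entering as missing data (partial likelihood one over all
codons — the `cleandata = 0` convention), and an all-missing column
contributes zero log-likelihood with a warning. Codon frequencies default
to F3x4 (position-specific nucleotide frequencies), with an `equal` option
and user-supplied π; the original analyses do not state their choice, so
the codeml default was adopted.

Optimization maximizes over κ (log scale, initial value 2 — κ is estimated
even though published tables rarely print it), the class parameters
(logit for quantities in (0,1), additive log-ratio for simplexes, a
shifted log for the ω ≥ 1 classes so the boundary is approachable), and
optionally all branch lengths (log scale, seeded by the input tree), using
BFGS with three seeded restarts by default; the returned fit is never
worse than its initialization, and non-convergence is reported via a flag,
never silently. ω ≥ 1 estimates within 1e-4 of the boundary are reported
as exactly 1, matching the convention of published tables. `nested_start()`
maps a fitted null model onto starting values for its alternative that
reproduce the null likelihood to numerical precision (for M8 the extra
class gets proportion 1e-8, since p0 = 1 is not attainable under the logit
transform), which both accelerates the alternative fits and guarantees the
nesting inequalities lnL(M3) ≥ lnL(M0), lnL(M2) ≥ lnL(M1),
lnL(M8) ≥ lnL(M7) up to a 1e-6 numerical slack for boundary-attained
optima.

Likelihood-ratio tests use 2|ΔlnL| floored at zero against chi-square with
df 4 (M0 vs M3), 2 (M1 vs M2), 2 (M7 vs M8), significant at P < 0.01.
Positive-site identification is naive empirical Bayes: the per-site
posterior of the ω > 1 classes (class prior × class likelihood / site
likelihood), reported above a 0.95 cutoff. BEB, branch and branch-site
models are out of scope.

The forward simulator draws each site's class from the class proportions,
the root codon from π, and descendant states through the class transition
probabilities, recording true class labels; it is deterministic given its
seed and shares the rate machinery with the likelihood (their agreement is
itself checked against an independent series-expansion matrix exponential
and brute-force ancestral-state enumeration in the test suite).

## Expression

FPKM = counts × 10^9 / (effective length × total mapped fragments), with
effective length the summed exon length of the representative transcript.
The published survey never defines its high/moderate/low bands, so the
defaults are the community's usual round numbers — low below 1 FPKM, high
above 10, moderate between, boundaries inclusive into `moderate` — with a
rank-based tertile mode as an alternative; per-subfamily roll-ups report
category fractions that sum to one.

## The synthetic generator

`simulate_family()` emulates the statistical structure of a scaffold-level
receptor-kinase family survey: subfamilies with conserved LRR and intron
counts, subfamily-specific motif vocabularies, tandem clusters placed
within 50 kb (well inside the 200-kb window, so boundary behaviour is
probed separately) on shared scaffolds and forming clades, dispersed and
ancestral copies on their own scaffolds spaced far beyond the window,
codon alignments evolved per subfamily under known site models, bootstrap
supports high (88–100) on subfamily crowns and low (25–70) on the backbone,
and negative-binomial counts (size 10) around planted per-subfamily FPKM
levels (0.3 / 5 / 50 for low / moderate / high) with library size 2×10^7.
Protein sequences are translations of the simulated CDS, so all files
cross-validate. `fixture_paper_scale()` instantiates the study-scale
shape: 94 genes in 18 subfamilies (sizes from the published table, largest
24 and 16), 60 scaffolds, five tandem clusters of sizes 3, 3, 2, 2, 2
(12 tandem genes, ≈12.8%).

What the generator does *not* emulate: alignment error, recombination,
rate variation along the genome, incomplete lineage sorting, annotation
noise, or read-level sequencing artefacts. Passing recovery tests
therefore demonstrates correctness of the implementations under their own
model assumptions, not robustness to real-data violations of them.

## Problem sizes and numerical choices

The recovery experiments refit 20 replicate alignments of 8 taxa × 300
codons (M0) and 8 taxa × 500 codons (M1) on random trees of total length
2 — sizes chosen to match the subfamily alignments such surveys analyze
(4–16 kinase-domain sequences, a few hundred codons) while keeping each
experiment in the minutes range; single-start fits are used there because
the M0/M1 surfaces at these sizes are unimodal in practice, and estimator
spread across 20 independent replicates provides the robustness that
restarts would otherwise add. Nesting-inequality checks use 4 taxa × 80
codons across ten datasets generated under rotating models. BFGS runs with
`reltol 1e-8` (1e-7 in the bulk nesting checks) and up to 500 iterations;
branch lengths are floored at 1e-6.

## Known limitations

Re-creating the published per-subfamily fitted values exactly would
require the original subfamily alignments from the external genome
resource, which the package deliberately does not fetch; the published
numbers are used as generating values for recovery experiments and for
statistic recomputation instead. One published value is internally
inconsistent (a one-ratio log-likelihood that cannot be reconciled with
its own model pair's LRT statistic); the shipped reference table carries
the reconstructed value with an explicit flag. The classifier assumes the
reference labels are correct and at least one reference per subfamily is
present; midpoint rooting assumes a roughly clock-like divergence and can
misroot strongly rate-heterogeneous trees — both are inherent to the
underlying methods, not to this implementation.
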