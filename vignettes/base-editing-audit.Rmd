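---
title: "Auditing in vivo base-editing outcomes: methods and design"
author: "editaudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing in vivo base-editing outcomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editaudit)
options(editaudit.verbose = FALSE)
```

# Scope

`editaudit` implements the downstream computations used to audit an in
vivo adenine-base-editor (ABE) treatment from sequencing data. An ABE,
delivered here conceptually by a cardiotropic AAV to repair a pathogenic
point mutation, raises four analysis questions that this package answers
with testable, reusable code:

1. **DNA off-targets** — after whole-genome sequencing of treated and
   untreated tissues, which variants are tissue-specific, what is their
   substitution spectrum, and do their flanking sequences resemble the
   guide RNA?
2. **Editing outcomes at the target locus** — from amplicon reads, what
   fraction of alleles is repaired, how frequent are bystander edits and
   indels, and what are the bystanders' codon consequences?
3. **Splicing rescue** — comparing rMATS output of treated and untreated
   mutants against wild type, which mis-splicing events were rescued?
4. **Transcriptional rescue at single-nucleus resolution** — using a
   small marker set, how does a per-cell activity score distribute across
   genotypes, and at which threshold do the genotypes separate?

Read alignment, the variant callers themselves, PSI estimation and FDR
computation, and single-cell integration/clustering are upstream tools
whose *outputs* this package consumes; a synthetic-data module emulates
all of them with known ground truth.

# The variant audit

Per-caller, per-tissue call sets (a VCF subset: CHROM, POS, REF, ALT,
and AD/AF from the first sample column) are first **normalized**:
shared trailing bases are trimmed — extending left over the reference
when an allele would become empty, which left-aligns indels through
homopolymers — then shared leading bases are trimmed down to the 1-base
indel anchor. This re-implements the standard left-align/parsimony
convention so keys `(chrom, pos, ref, alt)` are comparable across
callers; the tests verify it against exhaustive enumeration of all
equivalent representations.

Calls are then **merged** into one consensus record per key. Per tissue,
supporting callers are those reporting the key with alternate-allele
evidence; allelic depths are taken from the highest-priority caller that
measured them (WGS default MU, HC, then LF; RNA default PL, HC, ST),
mirroring the convention of preferring one caller's depths and falling
back to the next. Cohort-mode callers report depths even in tissues
where a variant is absent; this yields a *measured* AF of 0 there, which
is distinct from "unmeasured" (NA) — the distinction the
tissue-specificity rule depends on.

**Confidence filters** retain a variant iff it is (1) supported by at
least 2 callers in some tissue, (2) covered by at least 5 reads in every
tissue, and (3) carries at least 2 alternate reads summed over tissues.
Rule (1) is evaluated as "≥ 2 callers in at least one tissue" because a
genuinely tissue-specific variant is legitimately absent elsewhere.
Rule (2) uses the total depth recorded by the priority caller; a tissue
with no depth record fails the rule by default (`unmeasured_depth_passes`
relaxes this for single-sample-caller panels). **Common** variants
(AF > 0 in all tissues) are identified on the quality-filtered set
*before* known-variant exclusion; **tissue-specific** variants (AF > 0
in one tissue, AF = 0 or unmeasured in the others) are drawn from the
novel pool *after* excluding known variants — following the stated order
of the published filtering procedure. Conversion spectra are tabulated
over the 12 ordered substitutions and collapsed to the 6
strand-symmetric classes.

# Guide homology scanning

For each candidate variant, the ±30-base window around its start site is
searched on both strands for the best constrained alignment of the
20-nt protospacer plus its IUPAC PAM pattern. The distance is
substitutions + gapped bases, minimized over all placements, subject to:
gap events of at most 1 base (configurable), at most 2 per alignment,
and a PAM aligned gaplessly. The published description — "only allowing
1 bp indels or mismatches in the seed region but not in the PAM site" —
admits two readings (edits confined to the seed, or 1-bp edits anywhere
but never in the PAM). Both are representable here: the default counts
substitutions anywhere, treats the PAM as inviolable (`strict` mode; the
unambiguous clause), and reports seed-region edits as a sub-count, with
`forbid_seed_gaps` to disallow gaps in the seed and `lenient` mode to
count PAM mismatches into the distance instead (useful when summarizing
"mismatches to the gRNA and PAM sequence").

The production scanner enumerates gap configurations explicitly (with
alignment traceback) in C++; the test suite checks it, on hundreds of
random window/guide pairs in both modes, against an independent
exhaustive dynamic program over alignment moves, and verifies
reverse-complement symmetry and exact recovery of sites planted at known
edit distance. Ties are broken by fewest gaps, then smallest offset,
then the + strand. Windows clipped at contig ends are scanned as-is. A
strict-mode window with no PAM-compatible placement is reported "not
alignable" rather than given a fabricated distance.

# Amplicon editing metrics

Reads arrive pre-aligned to the window (equal length, `-` for a deleted
base; the upstream extraction is an aligner's job). Positions are
labeled in the guide frame: protospacer 1..20, PAM 21..23, negative
indices upstream (no zero), rendered `<refbase>_<index>` (e.g. `A_2`).
Replicates are summed before per-position base fractions are taken.
"Repaired" is deliberately strict: the fraction of reads exactly equal
to the wild-type sequence over the quantification span — a read carrying
a synonymous bystander is *not* repaired. No sequencing-error correction
is applied to this metric, reproducing its published definition; the
span defaults to the full window and is configurable because the
original read-out's span is not stated. Bystander positions are
editable bases in the guide frame outside the PAM; their codon
consequences come from standard genetic-code translation given a coding
frame. The conditional analysis partitions reads by on-target state and
reports bystander frequencies per partition, with an empty partition
reported as undefined rather than 0.

Because "repaired" counts only exactly-wild-type reads, the repair *rate
parameter* of a simulation is estimated by the on-target edit fraction;
the exact-wild-type fraction is lower by construction whenever
bystanders, indels or sequencing errors are simulated (e.g. ≈ 64% vs a
70% repair parameter at the default mixture), and both are reported.

# Splice rescue classification

Events are matched across the (mutant-untreated vs WT) and
(mutant-edited vs WT) comparisons; group means use available replicates;
deltas are group mean − WT mean. The significance gate is strict:
FDR < 0.01 and |ΔPSI| > 0.1, both consumed from the upstream caller.
With o and e the untreated and edited deltas, the classifier is:
unchanged if |o − e| < 0.1; otherwise, for o > 0, rescued iff
−0.2 ≤ e < o, else mis-spliced; symmetric for o < 0. The published
criteria block contains a typo and ambiguous operator precedence; this
closed form is the unique reading under which the published sub-rules
become mutually exclusive and the three categories partition every
significant event — the inclusive −0.2/0.2 overshoot bounds are kept on
the rescued side, so overshoot beyond them is strictly mis-spliced. The
test suite verifies the partition on a delta grid against a literal
transcription of the published clauses. The unchanged band is applied to
all events significant in the untreated comparison, matching the figure
legend describing both treatment arms relative to WT.

# Single-nucleus activity score

Within a cluster, per-gene Wilcoxon rank-sum tests (p ≤ 0.05) between
two genotypes yield up to 15 up- and 15 downregulated markers; since the
source states only "up to 15", ranking is by ascending p with ties
broken by absolute mean difference. Each marker is min–max rescaled
across the scored cells (making the score invariant to any positive
affine rescaling of a gene and bounding it in [0, 1]); a cell's score is
the mean over the set; constant genes are dropped with a warning. The
rescaling population defaults to the cells passed in — "across cells"
is ambiguous between cluster and dataset, and the cluster subset is what
the published figure scores. A threshold scan reports, per condition,
the percentage of cells with score strictly above each grid value (step
0.01); the critical threshold is the smallest grid value at which the
downregulated condition (lowest mean score) drops strictly below 50%
active cells. PCA for the pairwise-distance read-out is computed on
centered (not rescaled) expression, matching upstream log-normalized
conventions, with component signs fixed by largest-loading positivity;
distances are non-reference → reference pairs in the first-two-PC plane
("relative to WT"), with an all-pairs option.

# What the synthetic data emulates — and what it does not

Every generator is deterministic under a seed, returns its ground truth
alongside the data, and leaves the caller's RNG state untouched.

* `make_reference` plants protospacer+PAM cassettes with an exact number
  of protospacer substitutions (PAM kept pattern-matching) in uniform
  random background.
* `simulate_variant_truth`/`simulate_caller_vcfs` plant germline
  (AF 0.5/1, all tissues, exported as the known set), common, and
  tissue-specific variants (somatic AF uniform on 0.2–0.5, chosen so a
  40× binomial read-out detects them reliably, as in the sequenced
  tissues' ≈47× coverage), with substitution classes from a configurable
  collapsed 6-class spectrum (default uniform, so recovery tests can use
  multinomial bounds). Callers have per-caller sensitivity, cohort or
  single-sample reporting, Poisson(depth) coverage, binomial alternate
  reads, and uniformly placed false positives with Beta(1, 20) allele
  frequencies — low-frequency caller noise whose exact shape no test
  depends on.
* `simulate_amplicon_reads` draws mutually exclusive repaired /
  unrepaired / 1-bp-deletion read classes, bystanders per position
  (optionally only on repaired reads, emulating the observation that
  bystander edits ride on correctly edited alleles), and a
  substitution-only error channel (indels are modeled by the indel class,
  not the error channel).
* `simulate_splice_table` draws (o, e) pairs inside each category's
  decision region with ≥ 0.02 margins from every boundary and builds
  replicate PSIs by mean-centered jitter, so group means — and hence
  categories — are exact.
* `simulate_expression_matrix` uses Gaussian noise (sd 0.5) around
  uniform baselines with ±effect shifts on designated genes, floored at
  0; truth genes get baselines in [2, 3] so the downshift survives the
  floor.

None of this reproduces real data's alignment artifacts, strand bias,
overdispersed coverage, ambient RNA, or cell-type mixture; passing tests
demonstrate that the *computations* are correct under their stated
models, not that the biological conclusions of any particular dataset
follow. The deposited animal datasets behind the original study are
deliberately not required.

# Numerical choices and problem sizes

Thresholds default to the published values (≥2 callers, ≥5 reads/tissue,
≥2 alternate reads; FDR < 0.01, |ΔPSI| > 0.1, unchanged band 0.1,
overshoot 0.2; p ≤ 0.05, top 15 markers; ±30-base windows; grid step
0.01 with strict inequalities on both "above threshold" and "drops
below 50%"). Homology alignment: ≤2 gap events of ≤1 base — a ±30
window leaves no room for more under a 23-base pattern. Stochastic
recovery tests use 3σ binomial/multinomial bounds at their stated sizes
(200 homology oracle pairs; 50+50+100 variants at 40×, sensitivity 0.95;
10,000 amplicon reads; 200 splice events; 500 cells per condition,
effect = 2 sd, 20 marker-selection replicates); these sizes keep the
whole suite around a minute on one CPU while leaving the bounds sharp.
The Wilcoxon null check compares the average false-positive rate to its
nominal 5% within 3σ sampling error of the replicate design. VCF AF
fields are written with 17 significant digits so round-trips are exact
at double precision.

# Known limitations

* The VCF reader covers the audited subset (first sample column, AD/AF),
  not the full specification; symbolic/breakend alleles are skipped with
  a count.
* Same-position, different-allele records are keyed independently; how
  the original analysis keyed multi-allelic sites across callers is not
  stated.
* The repaired metric has no sequencing-error floor; at high error rates
  it understates repair (by design, matching its definition).
* The homology scanner is variant-anchored; it is not a genome-wide
  off-target enumerator, and it does not implement weighted
  position-penalty scores (CFD/MIT).
* Whether the published distance figure counts PAM mismatches is
  ambiguous; both modes are first-class and reported side by side.
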