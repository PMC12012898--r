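---
title: "Methods: trio binning, allele-specific expression, and heterosis expression modes"
author: "trioase authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio binning, allele-specific expression, and heterosis expression modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`trioase` analyses a parent–parent–hybrid trio: it partitions the hybrid's
sequencing reads by haplotype of origin using k-mer evidence, quality-controls
the phasing of haplotype-resolved assemblies, quantifies allele-specific
expression (ASE) in the hybrid by two complementary routes, and classifies
each gene's hybrid expression into heterosis modes (additive, dominant,
over-/underdominant) relative to its parents and the mid-parent value. A
synthetic-data module generates fully labelled fixtures so that every stage
can be validated against planted truth without external data.

## Trio binning

All k-mer work uses canonical k-mers: a k-mer is represented by the
lexicographic minimum of itself and its reverse complement, so strandedness
never matters; k is odd (default 21, the community standard for genome
surveys) precisely so that no k-mer can equal its own reverse complement.
Windows containing non-ACGT symbols are skipped.

**Solid k-mers.** Raw read sets contain abundant error k-mers (low
multiplicity) and repeat k-mers (very high multiplicity). A *solid* k-mer is
one whose multiplicity falls in a coverage window: by default the lower bound
is the first interior minimum of the multiplicity histogram (the valley
between the error peak and the coverage peak) and the upper bound is 4x the
coverage-peak multiplicity. When the histogram has no interior valley — e.g.
error-free simulated reads — the window must be given explicitly; the
function refuses to guess.

**Hap-mers.** With solid sets for maternal reads (M), paternal reads (P) and
hybrid reads (H), the maternal hap-mers are (M ∩ H) \ P and the paternal
hap-mers (P ∩ H) \ M. Subtracting the other parent is essential: without it
every k-mer from sequence shared by the parents would sit in both sets and
the exclusive-evidence rule below would leave almost every read ambiguous.
The two sets are disjoint by construction and asserted as such.

**Read classification.** A read is assigned maternal (paternal) only when it
contains at least one maternal (paternal) hap-mer and none of the other
type; reads hitting both sets, neither set, or shorter than k are ambiguous.
This is deliberately conservative — ambiguous reads are usable by downstream
haploid assembly of either haplotype, whereas a misassigned read
contaminates one of them.

**Phasing QC.** For a haplotype assembly we report: hap-mer *recovery* (the
percentage of that haplotype's hap-mers present in the assembly), hap-mer
*contamination* (the percentage of hap-mers present that belong to the
opposite haplotype; the denominator is hap-mers of either type present in
that assembly, so the two percentages sum to 100), k-mer *completeness* (the
percentage of solid read k-mers represented in the assembly), and the
consensus *QV*. The QV model treats each assembly base as independently
correct with probability P; a k-mer is then error-free with probability
P^k. Equating P^k with the observed fraction f of distinct assembly k-mers
supported by the read set gives P = f^(1/k), per-base error E = 1 − P, and
QV = −10·log10(E), capped at 99 when E = 0 (a perfect assembly has no
finite Phred value). For example, f = 0.99 at k = 21 gives QV ≈ 33.2.

**Telomeres.** Chromosome ends are recognized by tandem runs of the plant
telomere motif TTTAGGG (forward strand) or its reverse complement CCCTAAA
(reverse strand). Runs tolerate inter-copy gaps up to 100 bp, require at
least 10 copies (comfortably below the counts observed in real telomeric
arrays), and are flagged terminal within 10 kb of a sequence end — the
operational signature of telomere-to-telomere resolution. Coordinates are
0-based half-open, exported as BED6 with the copy number as score.

## Allele-specific expression

**Diagnostic-SNP route.** From per-position pileups of the two parents, a
position is a diagnostic SNP when both parents have depth ≥ 10, each
parent's major allele has frequency ≥ 0.9 (near-fixed), and the major
alleles differ. The coverage and purity thresholds are package defaults
chosen at typical RNA-seq depths; both are exposed as parameters. A hybrid
read is then assigned by consensus ("strict" mode): all informative sites
must support the same parent, any conflict leaves the read unassigned —
conservative, and the source of the unassignable fraction one observes in
real data. A majority mode (> 50% of sites) is available. Assigned reads
increment exactly one gene — largest overlap, ties to the smallest gene id —
per replicate, giving the gene × replicate × {maternal, paternal} allelic
count matrix.

**Haplotype-resolved route.** When both hybrid haplotypes are assembled, the
two annotated gene sets are combined ("metagenome") and reads quantified
per haplotype copy. One-to-one *allele pairs* between the haplotypes are
required before interpreting those counts allelically; a pair must satisfy
two conditions: (i) it is an anchor in a collinear gene block, and (ii) its
orthogroup contains exactly one gene from each haplotype. Collinear blocks
are found by dynamic-programming chaining of homology anchors over gene
ranks (both rank gaps ≤ 25, linear penalty of 1 score unit per skipped rank,
minimum 5 anchors per block, inverted blocks via reversed rank order); the
chaining defaults follow common practice of collinearity tools. Chains are
extracted greedily (best chain, remove anchors, repeat), and the DP is
verified against exhaustive enumeration in the test suite for anchor sets up
to 12. Orthogroups are single-linkage connected components over homology
hits — a deliberately lightweight stand-in for full orthogroup inference
that is adequate for two near-identical haplotype gene sets, and documented
as an approximation. Homology hits come either from a standard 12-column
tabular search file or from the built-in affine-gap Smith–Waterman aligner
(Gotoh algorithm, default scoring 2/−3 with gap open 5 and extend 2, i.e.
standard nucleotide-search stringency; hits require score ≥ 50 and aligned
fraction ≥ 0.5 of the shorter sequence). The built-in aligner is quadratic
and intended for fixture-scale inputs, not genome-wide proteomes.

**ASE calls.** Two callers operate on the allelic matrix. The *model test*
contrasts maternal vs paternal columns with the negative-binomial test below,
normalizing both columns of a replicate by that replicate's total assigned
allelic counts (scaled to geometric mean 1) so the within-replicate allelic
ratio is preserved; a gene is an ASEG at raw p < 0.01 and |log2FC| > 1,
labelled by the higher allele. The *ratio threshold* computes, per
replicate, r = maternal FPKM / (maternal + paternal FPKM), and calls
maternal dominance when r > 0.7 in ≥ 2 replicates, paternal when r < 0.3 in
≥ 2 replicates — a deliberately less stringent screen for reproducible
allelic bias in small gene panels. Replicates with zero combined signal are
excluded; genes with fewer than 2 usable replicates are balanced with an
insufficient-data flag.

## Expression-mode classification

**The NB test.** Counts are normalized by median-of-ratios size factors.
Per-gene dispersions are estimated by pooled within-group method of moments,
a parametric mean–dispersion trend φ(μ) = a0 + a1/μ is fitted across genes
by gamma GLM, and each gene's working dispersion is the log-scale weighted
average of its own estimate and the trend with weight df/(df + prior df),
prior df = 40 — with 3 replicates per group (4 residual df) the test leans
mostly on the trend, which is what makes it honest at this design size. The
statistic is the log2 fold change of group means (pseudo-count 0.5) over its
delta-method standard error, referred to a t distribution with
df + prior df degrees of freedom. This moderated-t reference, rather than a
normal, is what keeps the type-I rate at its nominal level in 3-vs-3
designs; calibration (rejection rate at α ∈ {0.01, 0.05} within 3 binomial
SDs of α under the NB null) and power (≥ 0.95 for 8-fold changes at
|log2FC| > 2, p < 0.01) are the contract, verified by simulation in the
test suite. Numerical agreement with any specific DE package is a non-goal;
one test cross-checks call-level concordance with DESeq2 on planted data.
BH-adjusted p-values are always reported alongside raw ones; thresholds in
the calling functions use raw p-values (with adjusted values available),
since the printed analyses this package emulates do not state which was
used.

**MPV additivity.** The mid-parent value is built as pseudo-replicates: the
average of the two parents' normalized counts at each replicate index,
rounded to integers on the normalized scale. Pairing by replicate index is
an arbitrary but deterministic choice — under the model replicates are
exchangeable, so any pairing is equally valid. The hybrid (normalized,
rounded) is tested against the MPV; genes at |log2FC| > 1 and p < 0.01 are
nonadditive (up/down by sign), the rest additive. Note that a *global*
expression shift of the hybrid is absorbed by normalization, as in any
count-based DE analysis: nonadditivity is identified relative to the bulk of
the transcriptome.

**Decision table.** Three pairwise tests (parent1 vs parent2, hybrid vs
each parent, all at |log2FC| > 1, p < 0.01 by default) map each gene to one
category, in precedence order: hybrid significantly above both parents →
overdominance; below both → underdominance; no significant differences →
conserved; parents different, hybrid different from neither → additive
(intermediate); parents different, hybrid indistinguishable from the higher
parent and above the lower → high-parent dominance (mirrored → low-parent);
everything else (including missing or untestable tests) → ambiguous. The
table is total: a property test enumerates all outcome combinations.

A structural caveat the package documents rather than hides: when the
parents differ by 4-fold or more, the mid-parent sits more than 2-fold above
the lower parent, so a perfectly additive gene is statistically
indistinguishable from high-parent dominance in the pairwise table (both
patterns read "different from the lower parent, not from the higher"). The
MPV test is therefore the arbiter of additivity, and the pairwise table is
read for dominance and over-/underdominance among genes the MPV test flags
or for parental-direction detail. The validation suite measures
additive-category recall through the MPV test and dominance/overdominance
recall through the decision table, which is how the two instruments are
meant to be combined.

**Pathway reporting.** Mode categories and ASE labels are cross-tabulated
over gene sets; percentages are 100 × count / pathway size, rounded
half-away-from-zero to 2 decimals so that every printed percentage
recomputes exactly from its printed counts. Multi-copy genes can first be
consolidated by summing copy-level FPKM per family, and expression
quantified against two parental references can be averaged per ortholog
pair (single-reference genes are carried through flagged) — both linear
operations that commute.

## The synthetic-data generator

The generator is the package's study design, not a tuning knob. Defaults:
two 100 kb haplotypes derived from one random ancestor with substitution
divergence 0.046 (the heterozygosity regime of a wide interspecific hybrid,
where roughly every 22nd base differs); 21-mers; error-free 150 bp reads at
30-fold coverage, uniform starts on both strands (error rate settable; the
error model is uniform substitution with constant FASTQ qualities);
single-exon, non-overlapping gene models of 400 bp placed identically on
both haplotypes; 3 replicates per group; negative-binomial counts with
variance μ + φμ² at φ = 0.05 (a typical biological-replicate dispersion;
φ = 0 falls back to Poisson); planted expression modes at 4-fold effects
with proportions conserved 0.35, additive 0.25, each dominance 0.10, over-
and underdominance 0.10 each; planted maternal allelic fractions recycled
from {0.1, 0.3, 0.5, 0.7, 0.9}; hybrid maternal counts binomially thinned
from the hybrid total. Every read and gene carries truth labels
(haplotype, coordinates, introduced errors, mode, means, allelic fraction),
and reverting the recorded errors reproduces the source fragment exactly.

Substitution-only divergence keeps the two haplotypes on a shared
coordinate system, so the variant table doubles as the diagnostic-SNP truth
set and read positions transfer across haplotypes. That is also the main
idealization: real hybrid genomes contain indels and structural variation,
gene models overlap and have introns, homologous genes are not at identical
coordinates, sequencing errors are not uniform, and RNA-seq counts carry
mapping bias toward the reference allele. Passing tests on these fixtures
therefore demonstrate correctness of the algorithms under their stated
models — exact set algebra, conservation, calibration, recovery of planted
signal — not robustness to alignment artefacts or reference bias, which are
upstream of this package's inputs.

Determinism: one top-level seed, with per-stage streams derived from it, so
identical configurations reproduce byte-identical fixture bundles and
checksum-identical pipeline runs (manifests record MD5 per file).

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen so the full set of
simulations completes in well under half an hour on one core: 100 kb
genomes with ~20,000 reads per read set for binning; 2,000 genes × 3
replicates for calibration, power and mode-recovery experiments; 600 genes
for the ASE-method agreement experiment; exhaustive chaining verification
up to 12 anchors. Sampling-based assertions use 3-SD tolerances of the
corresponding binomial or Poisson laws. Degenerate inputs are defined, not
errors: empty assemblies yield zeroed QC with a flag, motif-free sequences
yield empty telomere tables, all-zero genes are flagged untestable, empty
pathways report undefined percentages, and zero-signal replicates are
excluded from ratio calls. Ties are broken deterministically throughout
(gene ids lexicographically, chain starts by rank).

## Limitations

Beyond the generator idealizations above: in-memory k-mer counting is sized
for fixtures and small genomes, not gigabase read sets; the built-in
aligner is quadratic; single-linkage orthogrouping will merge tandem
arrays into one group (such genes are correctly excluded from allele pairs
rather than mispaired); the NB test approximates, by design, the behaviour
of mature DE packages without replicating their shrinkage estimators; and
read alignment, transcript quantification and annotation are out of scope —
counts, pileups and gene models enter as inputs.
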