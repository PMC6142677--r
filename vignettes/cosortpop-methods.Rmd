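---
title: "Methods: population genomics of co-sorted symbiont SAGs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genomics of co-sorted symbiont SAGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosortpop)
```

## The scientific problem

Ultra-small archaeal ectosymbionts (Nanoarchaeota and relatives) can be
captured by fluorescence-activated cell sorting while still attached to
their host cell, so a single sorting event may amplify two genomes at once
(a "co-sort"). Read-level analysis of such single amplified genomes (SAGs)
answers two questions:

1. **Clonality** — are the several symbiont cells attached to one host
   genetically identical? If they are, the within-SAG SNP density of a
   co-sorted symbiont bin should sit at the same error baseline as bins
   known to derive from single cells; if distinct cells are attached, the
   density should approach the population's pairwise divergence.
2. **Selection** — across a population of SAGs from one species-level
   clade, which genes accumulate amino-acid-changing polymorphism? The
   package measures this with pN/pS over degenerate sites and per-gene
   non-synonymous SNP densities compared across functional categories.

A third component groups genome bins into species-level clades from three
independent evidence types (16S identity, ANI, phylogeny position), since
every population statistic is only meaningful within such a clade.

`cosortpop` implements the full chain plus a synthetic-data module that
generates every input with known ground truth, so the pipeline's accuracy
is measurable rather than assumed.

## Read filtering and pileup

Alignments are filtered with strict less-than semantics — a record is
discarded when

* identity `1 - NM / aligned_length` **< 0.95** (`NM` is the SAM edit
  distance; `aligned_length` the reference-consuming CIGAR length),
* mean Phred score of the read **< 30** (arithmetic mean of per-base
  scores; the simplest reading of "average read quality"),
* mapping quality **< 20**,

and, in the pileup, individual bases with quality **< 30** are not
counted. Records exactly at a threshold are kept. Secondary and
supplementary records (FLAG 0x100/0x800) are excluded along with unmapped
ones (0x4); mappers differ in how they report these, so the exclusion is
a declared choice of this package rather than an inherited convention. Pileup columns at
ambiguous reference bases (N) are excluded from SNP calling and from all
density denominators, avoiding spurious variants.

## Downsampling, SNP calling, and the clonality contrast

To make SNP counts comparable between unevenly covered SAGs, every site
with depth ≥ 50 is subsampled to exactly 50 base observations *without
replacement* (multivariate hypergeometric — the analogue of subsetting
real reads; the allele proportions are unbiased). Sites below 50 are
dropped from all denominators. A SNP is called when the minor allele
reaches **MAF ≥ 10%** (inclusive), i.e. ≥ 5 of 50 reads; at a residual
per-base error rate of ~10⁻³ after quality filtering, five identical
errors at one site are essentially impossible, which is what makes the
threshold robust for single cells. SNP density is SNPs per kb of sites
that survived downsampling, not per kb of assembly — densities stay
comparable when coverage differs.

The pooled-SAG experiment emulates k distinct attached cells: SAGs
covering more than 25% of the reference are retained, and at every
position each of the k SAGs contributes exactly `floor(50 / k)` reads
(positions where any SAG has fewer are skipped). "Equal reads per SAG"
leaves the shortfall rule open; requiring all k SAGs keeps the
contribution exactly equal, and the choice is exposed as configuration. Group densities are compared with a one-sided Wilcoxon
rank-sum test — read as one-sided in the direction "co-sorted density
greater than the single-cell baseline", the biologically motivated
alternative (large observed p-values are then evidence of clonality). The
p-value is exact by full enumeration of all `choose(n1+n2, n1)` rank
assignments whenever `n1 + n2 ≤ 12` with no ties, and a tie- and
continuity-corrected normal approximation otherwise.

## Consensus, cross-SAG SNPs, and pN/pS

Within each SAG the consensus allele at a position is the modal base of
the filtered (not downsampled) counts; the site is masked when **more than
10%** of reads disagree with the mode (exactly 10% survives), or when the
mode is tied — a 50/50 site is maximally ambiguous, so masking beats an
arbitrary tie-break. Positions covered by at least **5** SAG consensuses
are eligible; a cross-SAG SNP is any eligible position where the consensus
alleles plus the reference contain two or more distinct bases.

Degeneracy is classified per reference codon under translation table 11
(bacterial/archaeal), strand-aware: a codon position is **fourfold** when
all three substitutions are synonymous and **onefold** when all three are
non-synonymous (a stop counts as a change). pN/pS is then

$$\mathrm{pN/pS} = \frac{\#\mathrm{nSNP} / \#\mathrm{onefold\ sites}}
                        {\#\mathrm{sSNP} / \#\mathrm{fourfold\ sites}}$$

with both denominators restricted to the same eligible positions. This is
the strict polymorphism definition: two- and threefold degenerate
sites are wholly excluded (no Nei–Gojobori fractional site counting), so
values are not numerically comparable to dN/dS from codon models. When no
sSNP is observed the ratio is reported as undefined (`NaN` with a flag),
never as 0. Codon degeneracy is defined from the full reference codon even
when neighbouring positions are not eligible.

Per-gene densities divide by **mapped sites** (eligible positions inside
the gene), not gene length, and genes with fewer than **100** mapped sites
are excluded, which keeps the density denominators honest for partially
covered genes. Functional categories with at least **10** genes enter a
one-way ANOVA on per-gene nSNP density with post hoc Tukey HSD
(studentized range at the residual degrees of freedom); the compact letter
display is a greedy colouring of the non-significance graph at α = 0.05 in
descending-mean order. For proteins with per-residue region labels
(internal / external / transmembrane), the distribution of nSNP-bearing
residues across regions is tested with a chi-square goodness-of-fit
against expectation proportional to region sizes; empty region classes are
dropped from the degrees of freedom.

The heuristic cell-surface ("hypothetical external") call requires exactly
one hydrophobic motif — a single maximal run of 19-residue windows with
mean Kyte–Doolittle hydropathy ≥ 1.6 — starting within the first 60
residues.

## Clade delineation

Two genomes can be grouped when at least **two of three** criteria pass,
with inclusive thresholds: 16S identity ≥ 98% (over pairwise-comparable
alignment columns), ANI ≥ 95% over ≥ 20 kb of aligned length, and the tree
criterion (mutual nearest leaves by patristic distance, or a monophyletic
group containing no non-members). ANI backed by less than 20 kb of
alignment is recorded as *missing* evidence, never as a numeric 0 or a
failure — the "0% ANI" seen in heatmap displays is treated as a display
convention only. Seeding additionally requires **zero failing criteria**;
the extension rule below makes explicit that conflicts block grouping,
and the same principle is applied at seeding (what a PASS-PASS-FAIL pair
should do is otherwise underdetermined, so this is a declared choice). After seeding, an unassigned genome joins a clade when its ANI
criterion passes against at least one member and nothing fails against any
member — missing data tolerated, conflicting data not. Processing order is
lexicographic in genome ids, making the partition invariant to input
order; a genome qualifying for two clades stops the run with an explicit
conflict report.

ANI itself is fragment-based (ANIb convention): consecutive 1020 bp query
fragments, each located in the subject by exact 16-mer seeding and aligned
with a local Smith–Waterman (blastn-like scoring +2/−3, gap open 5,
extend 2) inside a banded window around the seeded diagonal; fragments are
retained at ≥ 30% identity and ≥ 70% coverage, and the result is the mean
of both directions. The retention thresholds follow the convention of the
fragment-ANI tools; the seeded banded design keeps a 50 kb × 50 kb
comparison at around a second. Self-ANI is exactly 100; unrelated random
sequences produce no seeds and hence missing evidence.

## What the synthetic data emulates — and what it does not

`make_genome()` packs non-overlapping protein-coding genes (ATG … stop,
no internal stops, translation table 11, both strands) to a configurable
coding density (default 0.85, in the range of compact symbiont genomes),
with functional categories sampled from configurable weights and an
N-terminal transmembrane run labelled on "Hypothetical external" genes.

`simulate_population()` places synonymous variants only at fourfold sites
and non-synonymous variants only at onefold sites (verified against the
genetic code at generation time), so the population's true pN/pS is known
exactly. Variant frequencies default to the uniform exchangeable spectrum
{1/n, …, (n−1)/n} — a deliberately simple choice; a real population under
purifying selection would be skewed toward rare variants, which lowers
detection probability equally for both classes and therefore leaves the
ratio, the quantity under test, unbiased.

`simulate_sag_reads()` emulates MDA amplification bias with log-normal
per-window depth multipliers (window 1 kb, σ = 1.0 by default — published
SAG datasets do not come with a quantified amplification-bias parameter,
so σ is a free modelling choice documented here; at 50–60× it reproduces
the practically relevant feature,
namely that a substantial fraction of sites fails the 50-read threshold).
Substitution errors are applied at a per-base rate (default 0.002) with
low Phred scores (uniform 2–20) against a high correct-base quality (40),
so the base-quality filter removes the bulk of simulated errors the same
way it does real ones. Reads carry their true positions: no read mapper is
implemented, because mapping itself is upstream software, not part of the
method; mapping imperfection enters through the identity/quality filters
acting on the perturbed records, and the NM field counts haplotype
variants plus errors against the *reference*, exactly as after real
mapping.

Not modelled: indels, chimeric MDA artefacts, assembly errors, and
reference bias. Single-cell baselines reported for real SAG data (a few
tenths of a SNP per kb) mix amplification, sequencing *and assembly*
error; the simulator reproduces only the read-level components, so clonal
baselines here are expected to be lower (near zero), not matched. Passing tests therefore demonstrate
correctness of the statistical machinery under controlled conditions, not
that real SAG data are this clean.

## Validation design and problem sizes

The test suite validates each stage against independent oracles: all 192
codon-position degeneracy cases against a second translation
implementation; exact rank-sum p-values against `wilcox.test`'s exact
method; the two-group ANOVA F against the pooled-variance t²; chi-square
zero under proportional placement; the clade rule against a hand-derived
seven-genome fixture under input permutation. Pipeline-level checks use
500 kb genomes: 20 replicates of the clonality contrast at 60× (clonal
density ≤ 1 SNP/kb; a 50/50 two-cell mixture within ±15% of its true
30 SNPs/kb divergence; pooled density strictly increasing for k = 1…4
cells with private variants), and 50 replicates of pN/pS recovery through
7 SAGs at 50× with true ratios in {0.1, 0.16, 0.5, 1.0} (recovered within
±20% in ≥ 90% of replicates; neutral placement gives a confidence interval
covering 1). These sizes were chosen as the smallest at which the binomial
and hypergeometric sampling errors are clearly below the tolerances being
asserted.

## Known limitations

* Substitutions only; no indel calling or realignment.
* pN/pS uses the strict onefold/fourfold site definition — do not compare
  its absolute value to dN/dS estimates.
* The pooling rule (`floor(50/k)` from every SAG, all-covered requirement)
  is one of several defensible readings of "the same number of reads from
  each SAG"; it is configurable and documented rather than inferred.
* Tukey letter groups come from a greedy algorithm; like all compact
  letter displays they summarise, but do not replace, the pairwise table.
* `anib()` is tuned for closely related or unrelated genome pairs (the
  regimes the clade rule needs); highly rearranged mid-identity genomes
  may retain fewer fragments than a full blastn-based implementation.
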