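---
title: "Methods: divergence scanning, marker design and their simulated test-bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: divergence scanning, marker design and their simulated test-bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the statistical models, conventions and numerical
choices behind `divscan`, in the order the pipeline runs.  It is the
authoritative description of *why* the code does what it does; the README
shows *how* to run it.

## Setting and assumptions

The package addresses a two-population design: two closely related species
or diverged populations, each represented by a few dozen diploid samples,
genotyped jointly against one reference assembly.  Throughout, genotypes
are stored as copies of the *first* (reference) allele, 0/1/2 with `NA`
for missing calls, and all coordinates are 1-based inclusive.  Toolchains
in this space often keep 0-based half-open coordinates internally; we
deliberately use 1-based inclusive everywhere because that is the
convention of R, VCF, GFF and the Bioconductor ranges stack, and a single
internal convention is what actually prevents off-by-one drift.  BED
output is converted at the boundary.

Sites are assumed independent for every estimator below: no linkage
information is used, and the island scan exploits *positional* clustering
of high-F_ST sites rather than LD.

## Site filters

The joint-calling filters keep a site when total depth < `max_total_depth`
(default 1,200 reads, guarding against collapsed repeats), mean mapping
quality > 30, and MQ0 fraction < 0.05 — all strict inequalities, so a site
at exactly the threshold is removed.  The "high-quality" subset used for
marker work applies Phred site quality ≥ 900 *inclusive*, as that rule is
stated with a ≥.  The depth filter uses the VCF `INFO/DP` field as given;
whether that depth is raw or deduplicated is the caller's concern, not
ours.  Missing genotypes are carried as `NA` and excluded site-wise from
allele counts; a site all-missing in either population has no defined
F_ST.  Multiallelic records are rejected by default — the analysis
concerns sites with two observed alleles — with an opt-in `"split"` mode
that expands each ALT into a biallelic row (reference-allele copy counts
are unaffected by the split).

## Reich–Patterson F_ST

For allele counts $a_i$ of $n_i$ chromosomes, with $\hat p_i = a_i/n_i$
and $h_i = a_i(n_i-a_i)/\{n_i(n_i-1)\}$ (the unbiased estimator of
$p_i(1-p_i)$),

$$N = (\hat p_1-\hat p_2)^2 - h_1/n_1 - h_2/n_2, \qquad
  D = N + h_1 + h_2, \qquad \hat F_{ST} = N/D .$$

The estimator corrects for finite sampling, can be negative at
undifferentiated sites, and equals exactly 1 at reciprocal fixation.  When
$D=0$ (both populations monomorphic for the same allele) the site carries
no information and is excluded — *not* scored 0, which would bias window
means and the scan.  Genome-wide, the canonical combination is the ratio
of sums $\sum N / \sum D$; because genome-wide "average F_ST" figures are
often per-site means, `fst_overall()` reports both.  On Balding–Nichols
simulations the ratio of sums recovers the differentiation parameter (the
acceptance suite checks 0.05, 0.25 and 0.50 within 10% on three ~5,000-site
panels each); the per-site mean is systematically lower because
low-information sites contribute noisy ratios.

## Windowed π and d_XY

Windows are fixed 500-b non-overlapping bins requiring at least 10
informative SNVs.  Per SNV, $\pi = 2\hat p(1-\hat p)\,n/(n-1)$ within each
population and $d_{XY} = \hat p_1(1-\hat p_2)+\hat p_2(1-\hat p_1)$.  Both
are averaged *per SNV* within the window, the denominator used by the
common windowing scripts for this analysis; the SNV count is reported per
window so a per-base normalization can be recomputed.  Sites monomorphic
across both populations are not SNVs and are ignored.  When the two
populations have identical frequencies, $d_{XY}$ equals $\pi$ once the
$n/(n-1)$ correction is removed — a property the tests assert directly.

## The island scan

Each per-SNV F_ST is shifted by a constant (default 0.90).  "Shift set to
90%" is read as the constant 0.90, not an empirical percentile, because
the procedure is stated numerically as subtracting 0.90.  Per scaffold,
the score sequence is decomposed into **all maximal-scoring
subsequences** (Ruzzo–Tompa): disjoint runs with positive total score that
cannot be improved by adding or removing SNVs at either end, with the
canonical left-to-right tie behaviour.  Undefined-F_ST sites are dropped
before scanning, so they neither join nor break runs.  Interval
coordinates are first-to-last member SNV, 1-based inclusive, and the
reported span is `end − start` (a 4-SNV interval at 321,729–321,734 spans
5 b).  Single-SNV intervals (every lone fixed difference scores +0.10 at
the default shift) are *retained*; since whether such intervals should
count is a matter of taste, the `n_snvs` column lets callers filter, and
both retained and filtered counts are one `subset()` away.

The correctness anchor is an independent oracle: recursively extracting
the brute-force best-scoring contiguous subsegment and recursing on the
flanks yields the same decomposition; the acceptance suite equates the two
on 1,000 random vectors of length ≤ 200.  Ties between decompositions can
occur only at exact score equalities, which have probability zero under
continuous scores; test vectors are therefore drawn continuously.

Islands are contrasted with *length-matched random intervals*: for each
detected interval, an equal number of consecutive SNVs is placed at a
uniformly drawn SNV position (seeded), and 500-b windows overlapping the
islands are compared with windows overlapping the random intervals by
two-sided Mann–Whitney U (normal approximation with continuity
correction) on π of each population and on d_XY.

## Trees, distances, identity-by-state

The per-SNV distance between two diploids is $|g_i - g_j|$ on the 0/1/2
copy scale, summed over sites where both are called; identity-by-state is
$1 - \sum|g_i-g_j|/(2\times\text{sites compared})$.  Neighbour joining is
delegated to the standard Saitou–Nei implementation in **ape**; because NJ
can emit small negative branches on non-additive inputs, a post-pass
clamps each negative branch to zero and moves the deficit to its sister
edge, preserving path lengths through the node.  On additive matrices the
topology is recovered exactly (Robinson–Foulds 0 on 100 random 5–8 taxon
trees in the acceptance suite).

## Marker and RFLP design

A **fixed difference** requires every non-missing sample of one population
homozygous for one allele and every sample of the other homozygous for the
alternate, at quality ≥ 900.  Strict mode (default) lets any missing call
disqualify the site — the cautious choice for assay design; lenient mode
ignores missing samples.  Optional "deep sample" anchors reproduce the
design in which each shallow genome must match its species' deeply
sequenced reference individual.

**PCR-ready** screening excludes a candidate when any other SNV, any base
of an indel's reference span, any low-complexity-tract base or any N lies
within 50 b.  Distance exactly 50 is treated as inside the window — the
boundary is not specified in the source procedure, and the conservative
reading costs at most a few candidates.  "Unassembled regions" are
interpreted as N runs (plus any gap tracts supplied explicitly).
Low-complexity detection is a windowed DUST-style triplet score
$\sum_t c_t(c_t-1)/2 / (k-1)$ over 48-b windows stepped by 8 b, flagged
above a threshold of 2: uniform sequence scores ≈ 0.4, dinucleotide
repeats ≥ 10, so detection is robust to the threshold, which remains
configurable.  This scanner is implemented in-package because no single
canonical masking rule is prescribed for this step; the simulator plants
unambiguous tracts so the tests do not depend on threshold minutiae.

**RFLP design**: both allelic versions of the 101-b core are built and
each enzyme's IUPAC motif is matched on both strands (restriction enzymes
are double-stranded cutters; the default panel's motifs are palindromic,
but the code does not assume it) at placements overlapping the SNV.  An
enzyme qualifies iff exactly one allele carries a site — that allele's
product is cut.  The amplicon extends to just before the nearest flanking
occurrence of the same recognition site, so the cut allele's amplicon
digests into exactly two fragments; heterozygotes show three bands (uncut
plus both fragments).  Fragments under 20 b are dropped as unresolvable on
agarose (configurable).  Multilocus genotypes assign samples as parent 1,
parent 2, F1-like (heterozygous at every locus) or mixed.

## Pathway enrichment

Per pathway, a two-tailed Fisher's exact test on the overlap $k$ between
the target gene set ($n$ genes) and the pathway ($K$ genes) in a universe
of $N$; the two-tailed p sums all hypergeometric outcomes whose point
probability does not exceed the observed one (the convention of
`stats::fisher.test`, which serves as the independent oracle in the
tests — the implementation itself is a direct hypergeometric summation).
The universe defaults to every gene annotated to any pathway, since the
enrichment question is posed within the annotation; it is configurable.
Because pathway tests are dependent and discrete, the false-discovery
burden is estimated by randomization: uniform random gene sets of the
target's size (drawn without replacement), re-ranked identically;
`expected_fp(t)` is the mean count of pathways with $p \le t$, and
FDR = expected_fp / observed discoveries (undefined when nothing is
observed).  The procedure is seed-deterministic and the per-pathway FDR
annotation evaluates it at each pathway's own p-value.

## The simulator: what it emulates, and what it does not

The generator produces the study conditions every test runs under: two
populations of 21 diploids (the resequencing design it emulates), several
scaffolds, background differentiation F_ST = 0.25 — the neighbourhood of
the genome-wide estimate reported for the two coral species — implanted
near-fixed islands (differential 0.95), a set of reciprocally fixed
sites, interspersed 1–20-b indels, homopolymer/dinucleotide tracts and N
gaps.  Background population frequencies follow a **Balding–Nichols**
model: ancestral frequency $p \sim U(0.05, 0.95)$, population frequencies
$\sim \mathrm{Beta}\big(p(1-F)/F,\,(1-p)(1-F)/F\big)$ independently for
the two populations.  This model was chosen because its parameter *is*
the expected F_ST, which turns estimator validation into parameter
recovery.  Island sites take frequencies $(1\pm d)/2$ with random
orientation; fixed sites take $(1,0)$ or $(0,1)$.  Genotypes are binomial
draws per diploid.  Sites where no sample shows the alternate allele are
dropped, as a variant caller would never report them; the realized SNV
density is therefore slightly below nominal.  The default density
(0.02/b) is desk-scale: high enough that 500-b windows clear the 10-SNV
floor, far above genome-scale reality.

QUAL, depth, mapping quality and MQ0 fraction are drawn from simple
lognormal/mixture models so that every filter rejects a realistic
minority of sites; planted fixed sites are given QUAL ≥ 950, reflecting
the deep joint support such calls have, so the high-quality subset never
silently loses the planted truth.  Background sites can also drift to
in-sample reciprocal fixation at F = 0.25 — as in real data — so the
planted count is a lower bound on detected fixed differences; the truth
table's `fixed_diff` flag identifies the planted ones.

Not emulated: linkage and coalescent structure (islands are frequency
shifts, not sweeps with hitchhiking), read-level errors, genotype
likelihood uncertainty, missingness (present in the containers, absent
from the generator), and multiallelic sites.  Passing tests therefore
demonstrate the *estimators and procedures* are correct under their
stated models, not that the pipeline is robust to every artefact of real
sequencing.

## Problem sizes and determinism

Everything is seeded: the simulator takes its seed from `sim_config`,
scan randomization and enrichment randomization take explicit `seed`
arguments, and identical configurations produce byte-identical output
files.  The test and acceptance suites use panels of roughly 1,000–6,000
SNVs, 5,000-site estimator-recovery panels (three replicates per
parameter value), 1,000 random vectors for the scan oracle, complete
Fisher enumeration for all margins up to 30, and 1,000 random gene sets
for the null-FDR check — sizes chosen so the whole suite documents the
methods thoroughly while running in minutes.

## Known limitations

* The window denominator is per SNV, not per base; both are recomputable
  but the defaults follow the windowing-script convention.
* `islands_vs_background` samples random intervals uniformly over SNVs,
  so regions of high SNV density are proportionally more likely to serve
  as background — intentional, as the background should share the
  ascertainment of the islands.
* NJ tie-breaking follows **ape**'s deterministic implementation; trees
  from distance ties may differ from other NJ codes in arbitrary but
  stable ways.
* The enrichment randomization treats genes as exchangeable; gene length
  or SNV-density bias in who enters the target set is not modelled.
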