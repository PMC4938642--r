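---
title: "Models and methods behind chromquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chromquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`chromquant` quantifies four sequencing assays — ChIP-seq, anchored
metaplots, MNase-seq, and whole-genome bisulfite sequencing — around one
shared idea: in a compact genome with a single mitochondrial contig, the
mitochondrion is an internal control. It cannot be enriched by
immunoprecipitation of a nuclear protein, and it carries no DNA
methylation, so it calibrates both the ChIP enrichment unit and the
bisulfite error rate. This vignette explains the models, the parameters
that matter, what the synthetic-data generator does and does not
emulate, the numerical conventions, and the design choices that were
genuinely open.

## Coordinates and containers

All internal coordinates are 0-based half-open, the BED/bedGraph
convention; GTF input (1-based inclusive) is converted on read and the
per-cytosine report stores 1-based positions on disk, converted on read.
A single convention eliminates whole classes of off-by-one errors, at
the cost of one documented subtlety: the TSS of a minus-strand gene is
`end - 1`, the last base of its interval. The mitochondrial contig is
identified by an explicit configured name, never guessed from contig
size — both normalizations hinge on this partition, and guessing would
fail silently on unusual assemblies.

## ChIP-seq enrichment over background

Fragment coverage is counted in fixed windows (default 1000 bp) tiling
each contig from zero; the final partial window is kept as-is and
flagged, mirroring fixed-step window generators, so downstream code can
exclude it. The default counting rule scores a fragment in every window
it overlaps by at least one base pair — the semantics of the standard
coverage tools, which means boundary-straddling fragments are counted
twice; a `start_in_window` rule that conserves the total count exactly
is provided for users who prefer strict conservation. Every window's
count is then divided by the *median* count over mitochondrial windows.
The median (midpoint of the central pair when the window count is even)
is robust to the occasional high-coverage mitochondrial window and
defines the enrichment unit: normalized enrichment 1 means
"indistinguishable from background", and the mitochondrial windows
themselves map to a median of exactly 1. Normalization refuses to run
when the mitochondrial median is zero rather than producing infinities.

## Anchored metaplots

Gene metaplots extract the window `[anchor − flank, anchor + flank)`
around the TSS or TTS in gene orientation (minus-strand genes are
mirrored so positive offsets always point into the gene body), average
per-base signal within 10 bp bins, and then average across genes with
*equal weight per gene*. Genes whose window crosses a contig edge
contribute only their defined bases instead of being dropped — on small
genomes, dropping them would bias every profile. The flank defaults to
1000 bp and is configurable. For ChIP metaplots the pipeline first
scales each library to genome-wide mean coverage 1 (`scale_unit_mean`),
so replicate curves of different sequencing depth overlay; the raw-depth
signal can be passed directly when absolute coverage is wanted.

Methylated-domain metaplots use the opposite weighting: counts are
*pooled* across domains per bin (20 × 50 bp bins on each flank, 20 body
bins of 5 % of each domain's length), and the bin value is the weighted
methylation percent of the pooled counts. The two conventions differ on
purpose: aggregate-profile tools weight genes equally, while the
weighted methylation level is by definition coverage-weighted; the
`m_pooled`/`n_pooled` columns expose the pooling so the identity
"coverage-weighted mean of body bins = pooled level of all bodies" can
be checked. Domain flanks that overlap an adjacent domain are still
counted in the anchoring domain's flank — the simplest reproducible
rule.

Expression quintiles sort genes by RPKM descending, break ties by gene
identifier so the grouping is total and deterministic, and split into
five contiguous groups with remainders assigned to the most-expressed
groups. Genes missing from the expression table get RPKM 0 and land in
the lowest quintile, which is where silent and unannotated genes belong.

## MNase-seq

Insert size is fragment length `end − start`; statistics use the sample
standard deviation (n − 1). Duplicate fragments are collapsed on
`(contig, start, end)` ignoring strand, because a paired-end fragment's
two reads share outer coordinates; the pipeline reports insert-size
statistics both before and after deduplication since the original
metric's timing relative to duplicate removal is a common point of
ambiguity in published pipelines. Nucleosome-edge profiles count only
5′ fragment ends. By default the ends are strand-matched to the gene:
plus-strand ends for plus-strand genes, minus-strand ends for
minus-strand genes, flipped at the metaplot stage — this is what makes
profile peaks mark the promoter-proximal nucleosome edge for genes of
either orientation, and makes a minus-strand gene's profile the exact
mirror image of a plus-strand gene's. A `plus_only` mode using genome
plus-strand ends for every gene is retained because aggregation tools
differ in this behaviour.

## Bisulfite methylome

The nonconversion rate ε is the pooled, coverage-weighted ratio
`Σm/Σn` over mitochondrial cytosines — the maximum-likelihood estimate
of a shared error rate, preferred over averaging per-site ratios, which
would weight a 1-read site as much as a 100-read site. Sites with
coverage below 3 are labelled `insufficient_coverage` and excluded both
from testing and from the multiple-testing family; including them in the
family would dilute the correction with tests that were never performed.
Tested sites get the one-sided binomial tail `p = P(X ≥ m)` under
`X ~ Bin(n, ε)` and Benjamini–Hochberg correction; a site is methylated
when `q ≤ 0.05`. The threshold is on `q`, not `p`, and α = 0.05 is the
field convention (the calling procedure fixes the correction but not a
threshold, so α is exposed in the configuration). Strands are never
collapsed: *Neurospora* methylation is not confined to symmetric
contexts, and the per-cytosine report is per-strand.

Weighted methylation levels are `100·Σm/Σn` over a region's qualifying
sites; a region with no qualifying site is `NA`, never a silent zero —
an unmethylated region and an unmeasured region are different results.

DMR detection is fully specified here because the procedure it follows
is conventionally delegated to citations: sliding windows (1000 bp,
step 100) are scored on cytosines covered ≥ 3× in *both* strains; the
pooled 2×2 table per window gets a two-sided Fisher exact test; BH
correction runs over the tested windows (those with at least 5 shared
covered sites — the `dmr_min_sites` floor is an extension beyond the
published description, exposed and defaulted to 5, because windows with
one or two sites otherwise dominate the family); windows need both
`q ≤ 0.05` and an absolute weighted-level difference ≥ 20 percentage
points; significant windows merge across gaps ≤ 500 bp, separately per
direction of change. The effect-size gate matters: with deep coverage,
trivially small differences become statistically significant, and 20
points is the scale of biologically meaningful domain-level change.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the
package's study conditions: two 300 kb nuclear contigs plus a 20 kb
mitochondrial contig; 150 non-overlapping 1.5 kb genes with log-normal
RPKM (meanlog 2.3, sdlog 2.0 — median ~10 RPKM with the heavy right
tail expression data show) and 20 % of genes set to exactly zero
(silent genes populate the lowest quintile); ten 5 kb methylated
domains disjoint from genes; per-cytosine methylation frequency 0.45
inside domains and 0 outside (methylation in *Neurospora* is confined
to heterochromatic RIP-relic domains; outside them the only unconverted
reads come from the 0.005 nonconversion rate); Poisson 20× bisulfite
coverage; ChIP libraries of 200,000 fragments with 3× nuclear
enrichment and a promoter boost (default 2×, scaled by expression
quintile rank — rank, not raw RPKM, so the heavy expression tail cannot
concentrate the whole boost in one gene) in the 500 bp upstream of each
TSS; MNase libraries of 50,000 fragments from nucleosome arrays phased
every 200 bp downstream of the TSS behind a 150 bp nucleosome-free
region, with 20 bp edge jitter and truncated-normal fragment lengths of
140 ± 23 bp (floor 50 bp — a hard floor avoids rejection loops while
leaving the moments essentially untouched, since 50 bp is nearly four
standard deviations below the mean). The true amplitude of
expression-dependent promoter enrichment is only known qualitatively,
so it is a free parameter rather than a fixed constant.

Feature placement draws gaps as a uniform partition of each contig's
free space after random contig assignment, which guarantees
non-overlapping genes and domains in a single pass instead of rejection
sampling; placement fails loudly if the requested features would occupy
more than 80 % of the nuclear genome. Every simulator is a pure
function of its inputs and a seed.

Matched strain pairs — two libraries simulated from the same seed,
differing only in the domain methylation frequency — are the intended
way to test orderings (more methylated cytosines, higher shared-site
levels, planted DMRs). Because each random variate consumes exactly one
uniform, the two streams never desynchronize: coverage and background
counts are identical between the pair and domain counts are coupled
monotonically in the frequency, so a planted difference propagates to
every downstream comparison without being masked by library-to-library
noise, exactly as in a paired experimental design.

What the generator does *not* emulate: sequence composition bias and
mappability, PCR duplication structure, MNase sequence preference,
heterogeneous per-site methylation frequencies within a domain (every
domain site shares one frequency), and read-level errors — there are no
reads, only fragments and counts. Passing tests therefore demonstrate
that the estimators recover their generating parameters under clean
sampling noise, not that they are robust to alignment artifacts. One
consequence is worth spelling out: at 20× coverage a uniform 45 %
domain frequency saturates site detection (nearly every domain cytosine
is called in both strains of a 45 %/55 % pair), so the *count* of
methylated cytosines separates matched strain pairs cleanly but is not
a robust single-run discriminator for fully independent library pairs,
where it differs only through borderline sites near the BH threshold.
Real mutant methylomes gain many sites that cross the detection
threshold from near zero — per-site heterogeneity the uniform-frequency
model deliberately omits.

## Numerical conventions and problem sizes

bedGraph values are written with 10 significant digits so tracks
round-trip through read/write to float precision; empty tracks produce
empty files with no header. Readers reject invariant violations
(negative lengths, `m > n`, duplicate sites, unknown contigs) instead of
repairing them. BH q-values use the standard step-up with capping at 1;
ties in quintile assignment and deduplication are broken
deterministically. Identical Fisher tables short-circuit to `p = 1`.

The test suite and the acceptance script run everything at desk scale
as a deliberate design choice: a 620 kb genome (1 Mb for the caller's
null control, where 20 replicates of ~500,000 cytosines give the
false-call rate enough resolution), 150 genes, 50,000 MNase and 200,000
ChIP fragments. These sizes recover every generating parameter within
the tolerances the tests assert while keeping a full run in tens of
seconds; all statistics are either scale-free (medians, proportions,
weighted levels) or improve with size, so nothing about the method
depends on the small genome.

## Known limitations

- The caller's discreteness makes it conservative at low coverage; at
  3× a site needs every read unconverted to approach significance.
- With many true discoveries, BH's adaptive threshold admits borderline
  null sites by design (that is what FDR ≤ α means); total site counts
  therefore carry noise from the borderline band, which matched-pair
  designs cancel and independent pairs do not.
- DMR boundaries are window-quantized: a boundary is located no more
  precisely than one window minus one step.
- `find_dmrs` compares pooled proportions and will not detect
  differences that change per-site variance but not the pooled mean.
- The generator's promoter boost is a rectangular window; real
  promoter footprints are not rectangular, so only the ordering of
  quintile profiles — not their shape — should be read from simulated
  metaplots.
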