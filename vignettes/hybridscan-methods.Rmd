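---
title: "hybridscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hybridscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hybridscan analyses cohorts of yeast isolates whose genomes mix diploids
and allotriploids — triploids formed by a moderately heterozygous diploid
genome combined with a divergent haploid genome, as seen in wine- and
beer-spoilage *Brettanomyces*-like populations. Everything runs from
variant calls (VCF), read-depth tracks and gene models against a shared
reference; no read-level data is touched. A synthetic-population generator
with the same genome model makes every stage testable against known truth.

## The genome model

An isolate is modelled as a set of genome copies:

* **diploid**: haplotypes D1 and D2, heterozygous at `het_rate` sites/kb
  outside loss-of-heterozygosity (LOH) blocks;
* **allotriploid**: D1, D2 plus a haploid subgenome H diverged from the
  diploid lineage at rate `subgenome_divergence` per site. Divergence
  mutations fall on either lineage with equal probability, so half the
  subgenome-distinguishing sites carry the variant on H (allele balance
  1/3) and half on both diploid copies (balance 2/3). This is what
  produces the twin 0.33/0.66 modes in triploid allele-balance
  histograms, against the single 0.5 mode of diploids.

Site classes (diploid-subgenome het, subgenome-distinguishing, homozygous
substitution) are mutually exclusive by position. At every variant site the
generator records which copies carry the alternate allele, so the expected
allele balance after any structural event is an exact copy-count ratio:
a supplemental diploid copy gives 1/4 and 3/4 (configuration 3:1), a
duplicated haploid version gives 2/4 (2:2), deleting the haploid version
drives formerly heterozygous sites to 1 (2:0), and deleting one diploid
copy gives 1/2 (1:1). These identities are encoded once, in
`subgenome_templates()`, and derived from copy counts rather than written
as constants.

Calls are simulated at the *variant-call* level: per-site depth is
Poisson(mean depth x local copies / ploidy), the alternate-read count is
binomial at the true copy fraction, genotypes are diploid-style calls
(het whenever both alleles are present, as a caller run at ploidy 2 would
emit), and QUAL is drawn so a configurable fraction (default 2%, a
realistic failure rate for deep short-read data) falls below the standard
filter threshold of 25. Read-level artefacts — mapping bias, GC bias,
sequencing error — are deliberately not modelled, so a green recovery test
establishes correctness of the analysis logic on idealised calls, not
robustness to dirty alignments.

## Key parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `min_depth`, `min_qual` | 10x, 25 | hard filter; strict-inequality removal, boundary kept |
| `het_rate` | 7.1 /kb | diploid heterozygosity outside LOH |
| `subgenome_divergence` | 0.024 | per-site distance between subgenomes; with a 10/kb diploid-subgenome het rate it yields the ~34 het/kb seen in triploid clusters |
| `loh_fraction` | 0.13 | genome fraction in LOH blocks |
| `loh_block_length`, `loh_block_min` | 150 kb, 100 kb | block length = min + exponential excess |
| LOH scan | 50 kb / 25 kb / <=10 het | window / step / threshold |
| diversity window | 10 kb | nonoverlapping |
| CNV | 1 kb / 200 bp / 6 kb | window / step / edge exclusion |
| `cnv_min_span` | 10 kb | minimum segment span (break-point penalty analog) |
| ploidy bands | [0.45,0.55]; [0.28,0.38] and [0.62,0.72] | diploid / triploid balance bands, margin 1.5 |

LOH block sizing follows the reported totals: ~1.8 Mb across ~12 regions of
a ~13 Mb genome gives a ~150 kb mean region; the 100-kb minimum keeps
every simulated block above the 50-kb detection window. The remainder
needed to hit the requested genome fraction exactly is folded into the
last block rather than emitted as an undetectable fragment.

## Ploidy classification

The allele-balance histogram (0.01 bins) of heterozygous calls is reduced
to the site mass inside the diploid band versus the two triploid bands.
Masses are compared *per unit of band width*: the triploid bands jointly
span twice the balance range of the diploid band, so comparing raw masses
would label a flat, uninformative histogram triploid, whereas the
normalised comparison ties exactly and returns "ambiguous". Band widths
were chosen so binomial spread at 40x depth does not bleed between bands;
at 40x and 2,000+ het sites classification is error-free in simulation.
Isolates with fewer than `min_sites` (500) het calls are reported
ambiguous rather than haploid/homozygous — the rule cannot distinguish
those states.

Subgenome divergence is estimated as twice the density of heterozygous
sites with balance above 0.5: only the diploid-lineage half of the
subgenome-distinguishing sites sits at 2/3, and doubling it removes the
need to know the diploid subgenome's own het rate, which shares the 1/3
band.

## LOH detection

Windows of 50 kb at 25-kb steps are flagged when they hold at most 10
heterozygous sites; trailing partial windows use a threshold prorated by
length (rounded down) so scaffold ends are not over-called. Flagged
windows merge into maximal regions. Because the step grid quantises the
merged extent (about half a step lost per region edge — roughly 1 point
of genome fraction per region on a 2-Mb genome), regions are then refined
outward to the nearest flanking heterozygous site, i.e. to the maximal
het-free interval. `refine_boundaries = FALSE` reproduces the raw window
union, which is what the exhaustive window-enumeration oracle in the test
suite checks. Heterozygosity "excluding LOH" discards het sites inside
detected regions and subtracts their length from the genome before
dividing.

## Diversity statistics

Each isolate contributes one IUPAC-encoded sequence (het sites as
ambiguity codes), mirroring the one-sequence-per-sample construction used
with variscan-style windowed scans. Comparisons involving ambiguity codes
score the expected mismatch under equal-probability resolution:
`1 - sum_b p1(b) p2(b)`, so A vs R and R vs R both contribute 0.5. pi is
the mean per-site expected mismatch over all pairs; a column counts as
segregating when any two isolates carry different codes; Watterson's
theta is S/(a1 L); Tajima's D uses the canonical 1989 constants and is
flagged undefined (not zero) at S = 0.

Two consequences are worth stating. First, heterozygous columns inflate S
(n sequences with one R among them segregate) far more than they inflate
pi (0.5 per pair involving the carrier), so cohorts with substantial
heterozygosity have negative D by construction; the near-zero-D neutrality
property is therefore exercised on het-free cohorts whose shared variants
are drawn from the neutral site-frequency spectrum P(i) proportional to
1/i, for which E[pi] equals theta and E[D] is ~0. Second, cohort pi
decomposes additively as (shared-variant theta) + (het rate per site),
because every het site adds exactly 0.5 to every pair it touches; the
generator's `target_pi` argument uses this identity — it is algebra, not a
calibration against observed output.

## Phylogeny and clusters

Distances are average-state distances over the union of polymorphic
columns only (invariant columns are excluded and the column count is
reported). The tree is BioNJ (`ape::bionj`), with classic NJ available as
a cross-check; negative branch lengths are clamped to zero and logged.
Cluster assignment cuts the k-1 longest *internal* branches and takes the
connected leaf groups: under average-state logic every isolate carries a
terminal branch of length ~0.5 x its het density that reflects ploidy, not
population structure, so terminal branches are excluded by default
(`include_terminal = TRUE` restores the behaviour where an outlier on a
long private branch becomes a singleton).

## Copy-number analysis

Depth is summarised in 1-kb windows at 200-bp steps, excluded within 6 kb
of scaffold ends, and divided by the genome-wide median window depth.
Per-window copy number is `round(ratio x ploidy)`; equal-CN runs merge,
and segments spanning under 10 kb are absorbed into their longer flank —
a transparent stand-in for a break-point penalty. Since the generator
produces GC-flat coverage, no GC correction is implemented. Segment
boundaries fall midway between flanking window centers, so segments tile
the non-excluded span exactly and boundary error is bounded by half a
step plus noise (~2 kb in practice at 40x and events >= 50 kb).
Whole-scaffold aneuploidy is called when at least 90% of a scaffold's
20-kb windows round to a consistent non-ploidy CN — a reproducible
surrogate for reading coverage plots by eye. Genes take the CN of the
segment class covering more than half their length, else keep the base
ploidy; genes are core when CN >= 1 in every isolate.

### Subgenome attribution

The analytic templates share their lower modes once the diploid
subgenome's surviving het sites are considered: a 2:2 gain also shows
sites near 0.25 (het sites on a single diploid copy out of four), and a
1:1 loss is unimodal at 0.5, a subset of 2:0's {0.5, 1}. A
mean-absolute-deviation match against nested mode sets cannot separate
these pairs, so the decision uses the mode unique to one configuration —
0.75 for gains, 1.0 for losses, both derived from the templates at run
time. A segment is attributed to the discriminative configuration when at
least 20% of its variant-site balances fall within 0.125 of that mode, to
the alternative when at most 10% do, and is otherwise unresolved (as are
segments with fewer than 20 usable sites). At the default triploid
parameters the discriminative mass is ~35% under the true discriminative
configuration and ~0 under the alternative, so the dead zone only catches
genuinely borderline segments.

## Numerical and degenerate-input choices

* Intervals are 1-based closed internally (the Bioconductor convention);
  BED output is 0-based half-open via `rtracklayer`.
* Undefined quantities (pi with one sequence, D at S = 0, heterozygosity
  when LOH spans the genome, zero-depth allele balance) signal a classed
  condition (`hybridscan_undefined`) rather than returning 0.
* Histogram bins are right-open with balance 1 folded into the last bin;
  modal ties take the first bin.
* The scan, segmentation and pipeline are deterministic; all randomness
  lives in the generator and derives from explicit seeds.

## Known limitations

* Cohort simulation has no recombination, selection or linkage; shared
  variants are exchangeable across positions.
* Tetraploids, mosaic ploidy and balanced rearrangements are out of
  scope; depth data cannot resolve the latter.
* The LOH scan cannot detect blocks materially shorter than the 50-kb
  window; detection of "reduced but nonzero" heterozygosity regions (as
  opposed to near-complete LOH) is not attempted.
* Ambiguity-aware distances make no attempt to phase haplotypes; with two
  haplotypes per isolate both n and the distance scale would change.
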