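---
title: "Quantifying histone inheritance on nascent chromatin: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying histone inheritance on nascent chromatin: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scarchor)
```

When a replication fork passes, the parental nucleosomes ahead of it are
displaced and mostly recycled onto the two daughter duplexes, while newly
synthesized histones fill the remaining slots. Because the two daughter
strands are synthesized by different machinery (continuous leading-strand vs
discontinuous lagging-strand synthesis), dedicated chaperone pathways balance
which daughter receives the recycled, modification-carrying parental
histones. `scarchor` implements the strand-resolved and spike-in calibrated
quantification used to study this process, together with a generative
simulator that produces every input the pipeline consumes, so the whole
analysis closes the loop from known parameters to recovered estimates.

## The partition statistic

Strand-resolved ChIP of EdU-labeled nascent chromatin (SCAR-seq) yields, for
a histone mark, forward- and reverse-strand read counts $F$ and $R$ in fixed
genomic windows. The partition score per window is

$$\mathrm{Partition} = \frac{F - R}{F + R} \in [-1, 1],$$

+1 meaning all mark-bearing nascent fragments map to the forward strand. The
processing order is fixed: reads are counted per strand in 1-kb bins (each
read assigned by the floor of its fragment midpoint), normalized to counts
per million (CPM) of the library's total retained target reads, smoothed by
a uniform blur over the 30 neighboring bins on each side, corrected by
subtracting the identically processed matched input with negative values set
to zero, and windows whose input-corrected CPM falls below 0.3 on *both*
strands are masked. Masked windows propagate as absent values — never as
zeros — into every downstream statistic. Libraries prepared with adapters
that sequence the complementary strand report a mirrored ratio and are
corrected by multiplying by −1 (`flip = TRUE`).

Three conventions in this chain were genuinely open and are our documented
choices:

* **Midpoint binning.** Fragment-midpoint assignment is symmetric with
  respect to strand and bin boundaries; 5′-end assignment would shift the
  two strands in opposite directions by half a fragment length.
* **CPM uses the combined-strand library size.** Normalizing each strand to
  its own total would erase exactly the asymmetry the statistic measures.
* **Order of operations.** CPM and blur are applied before input
  subtraction, and the 0.3-CPM filter applies to input-corrected values; the
  input passes through the identical CPM + blur stages so that the
  subtraction compares like with like at the same effective resolution.

At chromosome edges the blur window truncates and renormalizes over the bins
actually present, so constant tracks are exact fixed points; signal mass is
deliberately not conserved under truncation.

## Orientation around initiation zones

Replication initiation zones (IZs) fix the local fork geometry: downstream
(higher coordinate) of an IZ midpoint the fork moves rightward, so the
leading nascent strand maps to the forward genome strand; upstream the
assignments swap. Partition windows within a flank (default ±250 kb) of each
IZ midpoint are therefore *oriented* by multiplying upstream windows by −1,
which pools leading-strand enrichment as positive values on both sides. A
leading-biased mark shows an S-shaped antisymmetric mean profile through
zero at the midpoint; the oriented windows of two conditions, paired by
genomic bin, are compared with a two-sided Wilcoxon signed-rank test.

The signed-rank p-value is exact for up to 25 pairs, computed from the full
rank-sum distribution with midranks for ties (equivalent to enumerating all
$2^n$ sign assignments) after dropping zero differences; larger samples use
the normal approximation with continuity correction. The exact path is
needed because tied absolute differences are common in partition data and
the standard exact algorithm refuses ties.

The leading-strand fraction of a mark is the linear map

$$\mathrm{leading\ fraction} = 100 \times \frac{\overline{\mathrm{partition}_{\mathrm{oriented}}} + 1}{2},$$

with a bootstrap confidence interval over IZs (the exchangeable unit —
windows within one IZ share fork geometry and smoothing). Windows within the
blur half-width of the IZ midpoint (default 30 bins) are excluded from the
mean: inside the smoothing window the blur averages the two diverging forks
and the partition ramps through zero regardless of the true bias, so those
bins measure geometry rather than segregation.

## Spike-in calibrated occupancy (RRPM)

ChIP of nascent chromatin (ChOR-seq) measures where a mark sits on newly
replicated DNA, but read-depth normalization erases genome-wide losses. A
constant proportion of exogenous (Drosophila) chromatin — 0.05% of total
chromatin, identical across conditions — provides the absolute anchor.
Reads are classified as target or spike-in by a contig-name prefix. Per-bin
reads per million (RPM) are rescaled to reference-adjusted RPM (RRPM) by

$$\alpha = \frac{\mathrm{input\ spike\ fraction}}{\mathrm{IP\ spike\ fraction}},$$

which is 1 when IP and input have the same composition and reduces to
classic ChIP-Rx scaling when inputs are condition-invariant. The same counts
give the global enrichment statistic
$(\mathrm{ip}_t/\mathrm{ip}_s)/(\mathrm{input}_t/\mathrm{input}_s)$. The
formula lives in a single function (`spike_scale_factor()`) so alternates
can be swapped.

Peaks supported by all replicates form the quantification universe: peak
sets are concatenated, sorted, merged when separated by at most 500 bp
(end-to-start gap, half-open intervals, ≥1 bp overlap semantics
everywhere), and merged intervals are kept only if they overlap at least one
peak from every replicate. Every 1-kb bin overlapping a consensus peak (or a
cognate mark domain) is quantified; the bin set depends only on the peaks,
never on the signal, so conditions share a bin universe. The
recycling-efficiency change is
$100 \times (1 - \sum \mathrm{RRPM}_{\mathrm{treated}} / \sum \mathrm{RRPM}_{\mathrm{control}})$,
reported within cognate domains and genome-wide.

## Histone PTM relative abundance

From an MS1 peptidoform area table, the relative abundance of a site:mod
token is the percent of the backbone's total area carried by peptidoforms
containing that token, charge states summed — e.g. %K18ac on H3 18–26 is
(K18ac·K23un + K18ac·K23ac) over all four K18/K23 combinations. Abundances
over the exhaustive state set of one site sum to 100%; an empty denominator
is reported as missing, never as zero. Coeluting isobaric peptidoforms
(H3K36me3 vs H3K27me2K36me1) are split by the averaged ratio of analogous
MS2 fragment ions; we take the arithmetic mean of per-ion ratios (the
geometric mean is available behind a flag), and the two component areas sum
to the pooled area exactly. Upstream spectrum processing (search,
retention-time alignment, isotopomer extraction) is out of scope; the
package starts from the exported area table.

## The simulator

`sim_config()` parameterizes one round of replication on a desk-scale
genome. The defaults are:

| parameter | default | meaning |
|---|---|---|
| `n_chroms` × `chrom_length` | 3 × 80 Mb | target genome (240 Mb, 240k bins) |
| `iz_spacing` | 16 Mb | 15 IZs, midpoints on a regular grid |
| `pulse_track` | ±300 kb | EdU-labeled nascent track per IZ |
| `nucleosome_spacing` | 200 bp | one nucleosome slot per 200 bp |
| `p_lead` | 0.5 | leading-strand probability for recycled histones |
| `evict_frac`, `redeposit_frac` | 0, 0 | eviction and redeposition of parental histones |
| `ip_depth`, `input_depth` | 2×10⁶, 8×10⁶ | reads per library |
| `spike_fraction` | 5×10⁻⁴ | spike-in proportion of total chromatin |

Each replicated slot's parental histone is evicted with probability
`evict_frac`; otherwise it is recycled in place, to the leading strand with
probability `p_lead`. Evicted histones are redeposited with probability
`redeposit_frac` at a uniformly random slot outside the mark domains (on a
uniformly random daughter strand, keeping their marks) and are otherwise
lost to the soluble pool, so conservation —
recycled + redeposited + lost = parental — holds exactly in the truth
record. New histones fill every remaining slot: nucleosome density is
conserved across conditions, mirroring the observation that nascent
chromatin accessibility does not change when recycling is impaired. Parental
histones carry H4K20me2 (and H3K27me3 when their slot of origin lies in a
domain); new histones carry H4K20me0.

SCAR IPs sample mark-bearing nascent nucleosomes uniformly; the read strand
follows the daughter-strand identity and the local fork direction. The SCAR
input is a *total-chromatin* (pre-capture) input — uniform positions over
the whole genome with Bernoulli(0.5) strand. This matters: an input with the
same nascent footprint as the IP would, after CPM matching, subtract the
signal wholesale for a genome-uniform mark; a pre-capture input is also what
the subtraction is for — removing fragmentation/mappability background.
ChOR inputs are EdU-captured (all nascent nucleosomes plus spike), matching
spike-in calibration against an EdU input. Spike-in chromatin enters every
library as a constant immunoprecipitable pool of
`spike_fraction` × (genome nucleosome slots), identical across conditions —
the one assumption RRPM calibration actually requires.

The presets encode the studied conditions: `wt` (`p_lead = 0.50`, no
eviction), `dpole4` (0.42), `mcm2-2a` (0.85), and `dpole4-mcm2-2a`
(`p_lead = 0.80`, `evict_frac = 0.20`, `redeposit_frac = 0.25`, redeposition
outside domains). The last preset's arithmetic pins the two efficiency
targets: in-domain retention 0.80 and genome-wide retention
0.80 + 0.20 × 0.25 = 0.85. Note that under this preset the *remaining*
parental histones sit on the leading strand with probability
(0.8 × 0.8 + 0.05 × 0.5)/0.85 ≈ 78.2% — the "about 80%" figure — because
redeposited histones land on either strand.

### Why this geometry

Two biases of the fixed pipeline informed the desk-scale geometry, chosen by
error analysis before any end-to-end run:

* **Input subtraction inflates partition.** Subtracting a flat input level
  $c$ from both strands multiplies the partition by roughly
  $1/(1 - f)$ where $f$ is the labeled fraction of the genome (here
  $f = 0.0375$, a ~4% relative inflation). Real genomes with denser IZs and
  shorter pulse tracks sit at larger $f$, where this bias is material — one
  reason the simulator keeps IZs far apart (16 Mb) relative to real mESC IZ
  spacing.
* **The blur widens the IZ transition.** The 61-bin smoothing window mixes
  the two diverging forks within ±30 bins of the midpoint, producing the
  S-ramp through zero. Pulse tracks (±300 bins) are long relative to the
  blur so the ramp carries little weight, and `leading_fraction()` excludes
  it by default.

The input depth (8×10⁶) is set by the precision of the spike-in scale
factor: $\alpha$ is estimated from the input's spike-read count, and at this
depth its Monte-Carlo error contributes well under one percentage point to
the efficiency estimates.

### What the simulator does and does not emulate

It emulates strand-resolved read generation under a parental-histone
segregation model, constant-proportion spike-in, matched inputs, mark
domains, and peptidoform tables with unbiased multiplicative noise. It does
*not* emulate stochastic origin firing or replication timing (one
deterministic fork per position), sequence-level reads (no base calls or
mappability structure), fragment-length variation, duplicate or blacklist
artifacts, continuous fork-directionality gradients (IZ midpoints alone
define orientation), or read-write spreading of marks after deposition.
Passing tests therefore demonstrate that the estimators recover their
generative parameters under the stated model — not that any particular
biological dataset satisfies that model.

## Numerical and degenerate-input choices

Coordinates are 0-based half-open everywhere; bedGraph output prints six
decimals and round-trips losslessly at that precision. Bins with zero
coverage are masked regardless of the CPM filter. Zero differences are
dropped from the signed-rank test (identical inputs give p = 1). An empty
replicate peak set yields an empty consensus with a warning; zero spike
counts are a hard error advising deeper simulation or sequencing; an empty
MS denominator is missing, not zero. All randomness in an experiment flows
from the single config seed, and identical config plus seed gives
byte-identical outputs, including the on-disk report of `reproduce()`.

## Problem sizes used in the test suite

Unit and property tests run on a one-chromosome 8-Mb configuration
(`tiny_cfg()` in the helpers) with 5 IZs and 1–4 × 10⁵ reads per library;
the end-to-end recovery tests use the full default presets (240-Mb genome,
2×10⁶ IP reads, seed 1), and the determinism check runs the complete
`reproduce()` harness at 5% depth twice. These sizes were chosen so the
Monte-Carlo error of each check is several times smaller than the tolerance
it asserts.

## Known limitations

The RRPM formula is one of several spike-in scalings in use; it is isolated
in `spike_scale_factor()` precisely because published pipelines differ in
whether inputs are rescaled per condition. Orientation uses IZ midpoints
only — quantitative fork-directionality weighting is a non-goal. Replicates
are compared (paired tests over shared bins), never pooled at the signal
level. The leading-fraction map assumes the oriented mean is taken over
windows with homogeneous fork direction; near-termination regions violate
this and are excluded only insofar as the flank keeps clear of basin
boundaries.
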