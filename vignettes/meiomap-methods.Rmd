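---
title: "Recombination landscapes and bin maps in DH populations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recombination landscapes and bin maps in DH populations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiomap)
```

## The problem

A doubled-haploid (DH) line carries the doubled genome of a single gamete: it
is fully homozygous, and its genotype along each chromosome is a direct record
of one meiotic product. Genotyping a DH population with a physically anchored
SNP array therefore reads out, line by line, where meiotic crossovers (COs)
happened. `meiomap` turns such a genotype matrix into:

* population-level **recombination bins** (maximal marker runs with one
  genotype pattern across all lines) and per-line **CO events** at bin
  junctions;
* a sliding-window **CO frequency landscape** in cM/Mb with **hot regions**;
* **CO-to-gene context**: tract lengths, distances to the nearest gene's
  TSS/TTS, and expression differences across CO-frequency strata;
* **homoeologous segments** (runs of collinear homologous gene pairs between
  subgenomes, as in allotetraploid AACC genomes) and candidate exchange lines;
* a **Kosambi bin map** and a Haley–Knott **QTL scan** over that map.

Because array datasets of this kind are rarely deposited, the package ships a
meiosis simulator that generates DH populations with known CO positions, gene
annotations, expression, homolog pairs and traits, so that every stage has a
ground-truth recovery test.

## Genotype representation and quality control

Calls live in a fixed internal alphabet `P1`, `P2`, `HET`, `MISSING`;
input alphabets (`A/B/H/-` or similar) are translated at read time.
Coordinates are 1-based inclusive bp throughout, and all interval lengths are
`end - start + 1`.

Marker QC keeps markers whose parents carry opposite homozygous calls
(when parent rows are available) and whose missing fraction is below a
threshold (default 10%). Line QC drops lines whose HET fraction or missing
fraction exceeds 10%: a DH line is homozygous by construction, so a high HET
fraction marks a failed or contaminated sample. The thresholds are
parameters; 10% is our operationalization of "plants that are not credibly
doubled haploids", and the line filter reports per-line HET fractions so the
cutoff can be audited.

## Bin segmentation and CO calling

Per line, two cleaning rules precede segmentation: HET calls become MISSING,
and any maximal homozygous run shorter than `min_run` markers (default 2)
flanked on both sides by the same opposite genotype becomes MISSING. At
~62 kb marker spacing a single-marker genotype island implies a double CO
within ~124 kb, which crossover interference makes implausible; such islands
are overwhelmingly genotyping errors. The cost of this rule is that a *true*
double CO bracketing exactly one marker is also masked; at array densities
this affects a fraction of a percent of events (see "What the simulator
shows" below).

A bin boundary is placed wherever at least one line switches parental
genotype between consecutive informative markers. If the switch falls inside
a run of MISSING calls, the ambiguous markers join the closer flanking
informative marker (bp distance, ties left), which is where the boundary then
lands. Bins tile the marker list; each line's bin genotype is the consensus
of its informative calls in the bin, and a line with no informative call in a
bin is MISSING there, inheriting the surrounding context downstream.

A CO event is the junction between two successive informative bins with
opposite genotypes for a line (MISSING bins are skipped). Its interval is
bounded by the line's own flanking informative *markers*, not the bin edges,
so tract lengths can shrink to a single inter-marker gap; the midpoint
(integer floor) represents the event in all window and gene analyses.
The replacement rate of a line is the fraction of informative physical
genome (bins' tiling spans, with boundaries halfway between flanking
markers) genotyped as the non-background parent.

## Landscape, hot regions, strata

CO frequency is estimated in sliding windows (default 3 Mb window, 1 Mb
step; windows are half-open `[start, end)` so midpoint assignment is
unambiguous). Genetic distance per window is the direct recombinant-fraction
estimate `100 cM × (COs in window / n lines)`; per-window fractions are small
enough that a mapping-function correction would change nothing visible, and
this keeps window frequencies exactly additive over a non-overlapping tiling.
The terminal partial window uses its true span in the denominator. Hot
regions are maximal unions of overlapping or adjacent windows above the
threshold (default 2 cM/Mb); both the merged-region count and the raw count
of above-threshold windows are reported, since either convention appears in
the literature.

For expression strata, a gene takes the mean frequency of the windows
containing its midpoint, and falls in the cold (< 1 cM/Mb), intermediate
(1–2) or hot (> 2) stratum. Up to `n_sample` genes per stratum (default
1000) are drawn without replacement under a recorded seed; per tissue, the
hot and cold strata are compared by a two-sided Wilcoxon rank-sum test
(expression is heavy-tailed, so a rank test rather than a t-test), with
adjacent-pair contrasts reported alongside and Benjamini–Hochberg adjustment
across tissues for the primary hot-vs-cold contrast.

Distances from CO midpoints to genes use only events with tract length below
100 kb (wider intervals localize too poorly to say anything about individual
genes). The nearest gene is found by bp distance to the gene interval;
inside/outside is decided by the midpoint falling within the gene body, and
TSS versus TTS by whichever site is closer in bp, strand-aware, with exact
ties resolved to the TSS (deterministic and disclosed). Signed distances
(positive downstream in gene orientation) are histogrammed at 1.4 kb, half
of a typical 2.8 kb transcript.

## Homoeologous segments

A homologous segment is a run of *more than 10* consecutive homologous gene
pairs (`min_run = 11`, strict reading of "more than 10"), scanned in gene
index order with `max_gap = 0` by default (strictly consecutive; a gap
parameter is exposed). Runs may be collinear or inverted; orientation is
fixed by the first advancing step. The exchange-candidate flag is explicitly
a screening heuristic: a line is flagged for a segment only when both spans
intersect hot regions, the line carries complementary parental runs fully
covering the two spans, and the run lengths agree within a relative
tolerance (default 0.25). Distinguishing a real homoeologous exchange from
two coincidental COs requires evidence (read depth, cytology) outside the
scope of array genotypes.

## Bin map and QTL scan

Linkage groups are chromosomes and bin order is physical order — the markers
are physically anchored, so de-novo grouping and ordering (as a stand-alone
mapping program would do) is deliberately not reimplemented; this is the one
place the pipeline substitutes a simpler, deterministic procedure for a
legacy tool. Adjacent-bin recombination fractions use the direct DH
estimator (discordant / jointly informative lines), are capped at 0.49 with
a warning, and are converted by the Kosambi function
$d = 25\,\ln\frac{1+2r}{1-2r}$. Adjacent pairs with no jointly informative
line are bridged against the nearest informative bin so cumulative positions
stay finite and monotone. The mean adjacent-bin distance is defined as total
cM / number of bins.

The QTL scan is Haley–Knott regression on a 2 cM grid: expected QTL
genotypes come from the nearest informative flanking bins via the standard
DH conditional probabilities (flanking distances inverted through Kosambi,
combined without interference), lines with no informative flank are dropped
per position, and $LOD = (n/2)\log_{10}(RSS_0/RSS_1)$. Peaks above LOD 2.5
are reported with 1-LOD-drop intervals and $PVE = 1 - 10^{-2\,LOD/n}$.
A composite-interval-mapping-style mode adds forward-stepwise cofactor bins
(default up to 5, ≥ 10 cM apart) to both models, excluding cofactors within
a 10 cM window of the test position; it is off by default because the plain
scan is easier to reason about and calibrate. The fixed 2.5 threshold is a
field convention; a permutation-based threshold would be more rigorous per
trait and can be built from `interval_scan` directly by permuting the trait.

## The simulator: what it emulates and what it does not

`default_genome_model()` is a 19-chromosome AACC genome with realistic
per-chromosome bp lengths (~780 Mb total). Each chromosome carries a U-shaped
crossover intensity: ten equal segments weighted `10, 1.2, 0.8, 0.3, 0.05`
mirrored, so the distal ~10% of each arm is hot (≳ 10 cM/Mb) and the
pericentromere nearly silent. Genetic lengths are proportional to physical
lengths and scaled to 23 expected COs per gamete (~1.2 per chromosome,
~2300 cM genome), the regime typical of DH populations in *Brassica napus*.
Within these conditions, window frequencies, hot-region spans, bin counts
and map lengths come out in the ranges reported for real AACC DH
populations. A deliberate property of the hot distal blocks is that distinct
lines' COs often share an inter-marker gap, so the number of distinct bin
junctions is far below the number of CO events — as observed in real bin
maps.

Crossover counts per chromosome are Poisson with mean genetic length/100 by
default; setting `interference_shape` > 1 switches to a stationary
gamma-renewal process on the genetic scale (the standard interference
model; the first event uses the equilibrium forward-recurrence draw, so the
expected count is unchanged). `obligate_co` resamples zero-CO chromosomes
once. Marker positions are uniform draws (sorted), so spacings are
approximately exponential with mean `marker_spacing`; a real array is more
evenly spaced, which means simulated CO tracts have a *heavier* tail than a
real 62 kb array would give (the gap containing a CO is length-biased,
Gamma(2)-distributed): the simulated fraction of tracts under 100 kb is
~49% where an evenly spaced array would approach 100%. Comparisons of tract
fractions against real arrays should keep that in mind.

Genotyping noise is applied per call, independently, in the fixed order
allele-flip → HET → MISSING (defaults 0.2%, 0.5%, 1%), so tests are exactly
reproducible from the seed; a single seed in `sim_config()` determines the
whole population. Expression is log-normal per tissue with the arithmetic
mean set by the gene's true intensity stratum; homolog pairs are planted
collinear blocks plus random background; traits are additive QTL effects at
the nearest marker plus Gaussian noise scaled to a target heritability, with
realized per-QTL variance fractions recorded as truth.

What the simulator does *not* model: sequence-level variation and probe
chemistry, tetrad constraints (gametes are drawn independently),
chromatin-feature covariates of recombination, segregation distortion, and
genuine homoeologous exchanges (the exchange flag is validated on
constructed fixtures instead). Passing recovery tests therefore show that
the pipeline's inference is correct under a faithful stochastic model of a
DH array experiment — not that any particular biological dataset will meet
the model's assumptions.

## Numerical choices and degenerate inputs

* A CO falling exactly on a marker position switches that marker (interval
  arithmetic is closed on the left flank); midpoints use integer floor.
* Window assignment is half-open; a midpoint on a window edge belongs to the
  window starting there.
* Recombination fractions ≥ 0.5 (possible under noise at small n) clamp to
  0.49 with a warning, never silently.
* Chromosomes with a single bin contribute 0 cM and stay in the map; a
  zero-intensity chromosome simulates to a single parental segment.
* Stratum boundaries are `(-Inf, 1], (1, 2], (2, Inf)`; a gene whose
  window-mean frequency is exactly 1 or 2 goes to the lower stratum.
* Marker positions within a chromosome must be unique; duplicated marker ids
  anywhere are a hard error, as is a matrix marker absent from the map.

## What the recovery tests measure

Three measurement conventions in the test suite are worth stating precisely.
First, at finite marker density some true COs are unobservable in principle:
events distal to the terminal markers, and pairs of COs inside one
inter-marker gap (which cancel in parity). Exactness tests compare against
the marker-observable truth; the noise-robustness test (99% recovery at
62 kb spacing and 0.5% flip error) scores a true CO as recovered when a
detected interval for that line intersects the CO's flanking-marker
interval, which credits the one-marker boundary shifts that a flip error
adjacent to a true CO inevitably causes. Second, profile-convergence checks
compare the seed-averaged window profile against the generating intensity
with binomial standard errors and ask that ≥ 95% of windows sit within
3 s.e. — the per-window 3 s.e. event itself has ~99.7% probability, so
demanding all windows pass would fail by chance. Third, QTL PVE accuracy is
asserted on the mean over seeds, because the per-seed sampling spread of an
$R^2$-type estimate at n = 292 (~0.04 s.d. at PVE 0.17) is of the same
order as the tolerance.

Problem sizes in the suite (populations of 100–292 lines, single
chromosomes for the QTL and map-length loops, 20–200 seeds per property)
were chosen as the smallest sizes at which the binomial/normal error bands
above are decisive; they are stated in each test.

## Known limitations

* The adjacent-pair map estimator matches dedicated mapping software only
  when marker order is correct a priori; it does not detect ordering errors.
* `CONFLICT` bin genotypes (both parental alleles informative within one
  bin for one line) can only arise on uncleaned input; they are warned
  about and treated as missing downstream.
* The CIM-style cofactor mode uses a fixed forward-stepwise rule, not the
  model-selection machinery of dedicated QTL packages.
* Hot-region counts depend on window and step; the defaults (3 Mb / 1 Mb /
  2 cM/Mb) follow common practice for ~Mb-scale array landscapes, and both
  are exposed.
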