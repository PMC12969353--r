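---
title: "Models and methods behind oripool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oripool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oripool)
```

This vignette explains the models, rules and numerical choices implemented
in `oripool`, in the spirit of a methods section: what each stage assumes,
which parameters matter and why their defaults are what they are, what the
synthetic-data generators do and do not emulate, and where the known limits
are. It states no empirical number that the package's test suite or
`scripts/acceptance.R` does not itself compute.

## The screen being modeled

A "magic pool" is a combinatorial plasmid library: each member carries one
origin-of-replication variant (part 1), one resistance-gene promoter with
RBS (part 2), one resistance CDS (part 3), and a common barcoded backbone
(part 4) holding a conditional R6K origin for maintenance in the
pir-positive cloning host, an oriT, and a counter-selectable marker. A
random 20-mer barcode between fixed PCR priming sites identifies each
member. The pool is conjugated into candidate hosts; plating or serial
liquid passaging under selection enriches members whose origin replicates
in that host; BarSeq counts per barcode per sample read out the outcome.
Because only the barcode is sequenced in the screen itself, everything
hinges on first deconvoluting barcode-to-parts associations from long reads
of the pool.

## Library modeling

Junctions between parts are abstract 4-nt overhang labels, not simulated
type-IIS digestion. The pipeline's requirement is junction *validity*
(every downstream overhang must meet the matching upstream overhang, around
the full circle), not restriction chemistry; modeling digestion would add
sequence constraints the analysis never consults.

Assembled plasmids are circular; all rotations and the reverse complement
are the same molecule. The canonical linearization starts at the first
base of `flank_left`, which pins the barcode to fixed coordinates
(`[len(flank_left), len(flank_left) + 20)` in 0-based half-open
convention) for every member of a pool. The total length is the sum of
part-body lengths plus the four junction overhangs plus the inserted
barcode.

The bundled `example_design()` mirrors the study-scale composition — 38
origin variants, 10 promoter variants, 2 resistance variants, one backbone
(760 combinations) — from random sequences. All of its sequences, including
the 20-nt priming sites, are synthetic inventions; real screens must supply
their own registry and flanks, which is why `library_design()` has no flank
defaults. `confound_promoter = TRUE` plants a promoter variant carrying a
160-bp block copied from the backbone, reproducing a real failure mode (a
promoter/backbone sequence ambiguity) exercised by the tests.

## Long-read deconvolution

**Barcode extraction.** Both priming sites are located on either strand by
approximate matching allowing up to 2 edits each (substitutions or indels).
The intervening segment must be exactly the design's barcode length:
indel-shifted barcodes are dropped, not corrected, because no error
correction rule is defined for the cassette, and a wrong correction would
silently merge distinct members. A `length_tolerance` option relaxes this
for users who want it. Reads carrying two distinct cassettes (chimera
signature) are discarded as ambiguous.

**Part identification.** Candidate parts are shortlisted by exact 24-mer
seed tags tiled every 32 nt along each part body, then scored by a full
local dynamic-programming alignment (Biostrings, unit match/mismatch/gap
costs) of the part body against the tagged read window. Identity is
matches over alignment columns (gaps counted); coverage is the aligned
fraction of the part body. A hit needs identity >= 0.90 over >= 90% of the
body — defaults declared here, not derived from any reference dataset; at
the ~1.5% combined error rate of the simulated reads, true parts score
~0.985 identity, so the margin is wide on both sides. Seed tags make the
search linear-time in practice while the final score remains the full
alignment; with error rates up to a few percent, a part that fails to leave
a single exact 24-mer among its tags is vanishingly rare.

Two rules handle known confounds. A hit whose matched read interval also
aligns to the backbone at >= 0.90 identity over >= 100 nt is flagged
ambiguous and its category reported unmapped — the promoter/backbone
confound — and this check runs per candidate *before* within-category
conflict resolution, so a backbone-like variant (which matches every read)
cannot crowd out a genuine promoter hit. Second, a read with two distinct
non-ambiguous passing hits in one category votes for neither: within-read
conflicts indicate chimeras, and a chimera's vote is untrustworthy in both
directions.

**Association rules.** Distinct supporting reads are tallied per
(barcode, category, part). A part is assigned iff exactly one candidate
reaches `min_support = 2` distinct reads; two candidates at support in the
same category eliminate the barcode outright; a barcode whose best origin
candidate has fewer than 2 reads is kept as `insufficient_support`.
Tallying is order-independent, with lexicographic tie-breaking, so a
shuffled FASTQ yields a byte-identical table.

One default deviates from treating barcodes as exact keys. A substitution
inside the barcode mints a phantom barcode one edit from the real one; at
10x coverage, two reads occasionally coin the *same* phantom, which then
clears the two-read rule and maps — with the correct parts but a barcode
that does not exist in the library. `build_association()` therefore drops,
by default, any barcode at edit distance <= 1 of a barcode with at least
twice its read count. Random 20-mers essentially never sit at distance 1
of each other (probability ~ n^2 * 61 / 4^20 for an n-member library), so
the rule removes error products, not members; `drop_error_variants = FALSE`
restores exact-key behaviour.

## BarSeq analysis

Counts below 6 are removed ("below": 5 goes, 6 stays) and the retained
count fraction is reported per sample. The enrichment fraction of an
origin in a sample is its mapped barcodes' summed counts over *all*
filtered counts in the sample; barcodes missing from the association table
accumulate into an explicit `unmapped_fraction`, so the per-sample
fractions sum to one. The all-counts denominator is the conservative
reading of "fraction of total barcodes in the sample" — it can only shrink
origin fractions — and a mapped-only denominator is available as an option.
Barcode diversity is the count of distinct mapped barcodes per origin per
sample.

Origin calls per host follow four rules, evaluated in order:

* `artifact_single_barcode`: some fraction >= `min_fraction` but never more
  than one distinct barcode — enrichment resting on a single barcode says
  nothing about the origin, whatever its counts.
* `functional`: at least one plate-mode sample (plate or its outgrowth;
  both are treated as plate-mode evidence) with >= `min_diversity`
  barcodes at fraction >= `min_fraction`, and the liquid series not
  strictly monotonically declining.
* `carryover`: fractions below `min_fraction` in every sample, strictly
  declining across the liquid timepoints, *and* pool abundance (mapped
  barcodes per origin) in the top quartile. Both legs are required: donor
  carryover is material that arrives because the origin is common in the
  pool and washes out because it does not replicate. The trend test is
  exact strict decline — passive dilution admits no rebound — and abstains
  below 3 timepoints, flagging the call `partial_evidence`.
* `not_detected` otherwise.

`min_diversity = 2` encodes the multiple-barcode requirement (the weakest
version of "multiple"); `min_fraction = 0.05` is a declared default with no
canonical value — at ~5,000 founders a 5% share is ~250 colonies, far above
carryover noise. Both are arguments. Hosts are classified independently and
no multiple-testing correction is applied; the calls are descriptive
labels, not hypothesis tests.

## Copy number from colony qPCR

The estimator is the efficiency-corrected delta-Ct model:
`CN = 2^-(Ct_plasmid - Ct_gDNA)`, then `CN_adj = CN * A_gDNA / A_plasmid`,
with `A` the per-cycle amplification factor (perfect doubling `A = 2`).
Interpreting the "efficiency" `E` of the correction as the amplification
*factor* keeps the correction dimensionally coherent with the base-2
delta-Ct term (a percent-efficiency reading would enter as `1 + e`); the
correction is exact when each amplicon truly multiplies by its own constant
factor each cycle.

`compute_ct()` is the threshold-crossing cycle with linear interpolation
between the bracketing cycles — the plain instrument convention. Linear
interpolation on an exponential curve carries a phase-dependent bias of up
to ~0.09 cycles, which does not cancel between the two wells of a pairing,
so the curve-based pipeline inside `estimate_copy_number()` instead
interpolates on the log scale of baseline-subtracted signal (exact for
exponential growth); the linear rule remains the default of the public
`compute_ct()`.

`estimate_efficiency()` works per well: a baseline from the first 5 cycles
(used only if that stretch is flat, CV < 0.2); a window starting at the
first run of >= 4 consecutive points above 3 baseline SDs (isolated noise
spikes are skipped), capped at 10 points and at half the curve maximum; and
a weighted least-squares fit of log signal against cycle. When the curve
has resolved its plateau `K` (flat final cycles), the fit uses the logistic
linearization `log(y / (K - y))`, which is *exactly* linear in cycle for
logistic growth — removing the downward bias that plateau curvature
otherwise imposes on late window points — and weights are the delta-method
precisions of each log point under additive fluorescence noise
(proportional to `y^2`, or `(y (K - y) / K)^2` under the transform), so
barely-detectable early points do not dominate the slope. On unsaturated
noiseless exponentials the estimate is exact to machine precision.

Aggregation mirrors the plate design: technical triplicate Cts are
averaged arithmetically (no combination rule being canonical, the mean is
the variance-minimizing choice for symmetric noise); plasmid and gDNA
strata are paired within (replicate, dilution); dilutions are treated as
independent estimates of the same ratio, since delta-Ct is
dilution-invariant in expectation, rather than fitted as a standard curve.
Efficiencies enter as the per-target mean across wells by default — the
amplification factor is a property of the primer pair and template, so
averaging over the plate reduces its noise roughly sixfold — with
`efficiency_pooling = "per_well"` available. The headline value is the
nearest integer of the mean (0.5 rounds away from zero); the median,
linear-interpolation quartiles, SD over all pairings and SD across
biological-replicate means are all reported, since a quoted spread can
reasonably mean either.

A statistical note on integer-exact recovery: with per-well Ct noise of SD
`s` cycles, triplicates averaged, and `R x D` pairings, the SD of the mean
estimate is about `CN * ln(2) * s * sqrt(2/3) / sqrt(R*D)`. At `s = 0.15`
and the 3 x 4 design this is ~2.4% of CN — about 0.8 copies at CN 34 — so
rounding to the exact integer at high copy numbers succeeds only about half
the time *regardless of estimator*, while recovery within one copy is
nearly certain. The tests assert what this bound allows.

## Synthetic data: what it emulates, what it does not

All generators are deterministic functions of their arguments and a seed,
which they record in their outputs.

**Library** (`simulate_library()`): unique random barcodes, uniformly
random part selections, log-normal abundance skew, with members of
designated high-copy origins boosted 10x before renormalization — the
minimal mechanism for the observed over-representation of high-copy-origin
plasmids in a real pool.

**Long reads** (`simulate_long_reads()`): full-length reads of the circular
molecule at uniform random rotation and strand, i.i.d. per-base
substitutions and indels, and splice chimeras at a configurable rate.
Poisson counts per member, proportional to abundance or uniform. This is
deliberately not a platform error model: no homopolymer-length errors, no
quality strings worth trusting, no fragmented reads. Passing recovery tests
on these reads demonstrates the deconvolution logic — support thresholds,
conflict elimination, strand/rotation handling, chimera resistance — not
robustness to platform-specific artifacts.

**BarSeq** (`simulate_barseq()`): selection acts at the founder level
(~5,000 colonies drawn multinomially, echoing the experimental bottleneck)
with read counts multinomial on top, rather than modeling antibiotic
killing kinetics per cell. Members nonfunctional in a host enter only
through a passive carryover term proportional to pool abundance, decaying
geometrically (default 0.3 per passage) — the simplest mechanism consistent
with donor carryover; whether the residue is persistent plasmid or
surviving donor cells is not something this model can distinguish. Liquid
passages update replicating-founder frequencies by `p <- p*w / sum(p*w)`
with a multinomial bottleneck at 1/21 of the grown population (500 uL into
10 mL + 500 uL). Read totals default to 1e5 per sample so the full
pipeline runs in seconds; the study-scale 4e6 reads/sample (~800x per
colony) is a documented setting of `reads_per_sample`. Promoter-driven
fitness differences within the functional set are supported via the
per-(host, origin) fitness table but are not part of the default recovery
fixtures, where equal fitness isolates the carryover signature from
legitimate competitive decline.

**qPCR** (`simulate_qpcr()`): logistic-capped exponential curves over a
flat noisy baseline with multiplicative signal noise; per-well Ct jitter is
injected by scaling the starting level by `A^N(0, sd)`, i.e. an SD in
cycle units. The gDNA and plasmid wells of a pairing are placed so that
their ideal threshold crossings satisfy
`delta-Ct = -log2(CN * A_plasmid / A_gDNA)` — the unique parameterization
under which the efficiency-corrected estimator is exact in the noiseless
limit, making the generator the generative model *of* the estimator's
equations. Recovery tests on it therefore measure noise propagation and
estimator implementation, not the adequacy of the delta-Ct model for real
chemistry.

## Problem sizes and numerical conventions

The test suite and acceptance script run at desk scale by design: 200-member
libraries at 10x long-read coverage (~2,000 reads of ~1.7 kb), 1e5-read
BarSeq samples, and 12-pairing qPCR plates; these sizes exercise every code
path while keeping a full run in minutes. Coordinates are 0-based
half-open on the canonical strand; fractions are exact ratios checked to
1e-9; quartiles use the linear-interpolation convention; `round_half_up()`
(0.5 away from zero) is used for headline copy numbers so 8.5 never rounds
down by parity.

## Known limitations

* Deconvolution assumes reads long enough to span parts; heavily
  fragmented long reads reduce recall before they harm precision.
* The classifier consumes one count table per sample; replicate screens of
  the same host are classified independently rather than jointly.
* Donor carryover is detected only through the declining-trend + abundance
  heuristic; a nonfunctional but low-abundance origin is reported
  `not_detected`, not `carryover`, even when its trace signal is donor
  material.
* Copy-number estimation is relative (plasmid per genome); no absolute
  quantification, standard curves or melt-curve analysis.
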