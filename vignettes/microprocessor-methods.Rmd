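---
title: "Models and methods behind mirproc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mirproc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mirproc implements the quantitative analyses used to characterize
Microprocessor nuclear condensates and IDR-dependent miRNA biogenesis in
*C. elegans*: small RNA quantification and differential abundance, isomiR
cleavage-fidelity statistics, FRAP recovery fitting, nuclear focus
quantification, and pri-miRNA feature association. This vignette explains
the models, the conventions, and the design decisions — particularly the
points where a published methods description leaves a choice open and the
package had to fix one.

## Coordinate and sign conventions

All contig coordinates are 0-based half-open internally; GFF3 output is
1-based inclusive, produced by a single tested converter pair
(`zero_based_to_gff` / `gff_to_zero_based`). Each miRNA locus carries a
hairpin interval with annotated 5p and 3p mature-arm intervals; the ends of
those arms are the canonical Microprocessor cut coordinates. Alignment and
isomiR work happens in *hairpin-local* coordinates along the hairpin's
5'→3' sense (position 0 at the hairpin start, flanks negative), so
minus-strand loci behave identically to plus-strand loci after one reverse
complement at sequence-extraction time.

End offsets are signed as observed − canonical along the hairpin sense for
both arms. The biologically meaningful direction "toward the basal
junction" (away from the apical loop) therefore maps to −1 for the 5' end
of a 5p arm and +1 for the 3' end of a 3p arm. A locus with a 1 bp
basal-junction shift in a mutant — the mir-259-like case — shows modal
non-canonical offsets of −1 (5p) and +1 (3p), which is exactly what
`compare_fidelity` reports in `shift_direction`.

Reads are stored in DNA alphabet (U→T) and mature-strand orientation, as
sequencers deliver them.

## Read simulation

`simulate_reads` draws reads multinomially over the category space
(miRNA locus × arm × Microprocessor-end offset, piRNA loci, spike-ins).
Default class mass is 55% miRNA / 40% piRNA / 5% spike-in, a typical
composition for a worm small RNA library after adapter trimming; per-locus
baseline abundances are log-normal (sd 0.8 in natural log), arms are
weighted equally within a locus, and a genotype spec supplies per-locus
abundance multipliers and offset distributions (default 90% canonical,
5% at ±1). Tails of 1–3 nt are appended with probability `tail_rate`
(default 0.1) from a U-biased alphabet (80% T in DNA space), matching the
dominance of uridylation among 3' additions in *C. elegans*.

Ground truth distinguishes tails that happen to match the downstream
genomic sequence ("templated lookalikes") from decidably untemplated ones,
because only the latter are recognizable in real data; classifier accuracy
can thus be scored on decidable cases only. What the generator does *not*
model: sequencing errors, adapter remnants (inputs are assumed
adapter-trimmed), ligation bias, or 5' heterogeneity beyond the offset
model. Tests passing on these reads therefore demonstrate correctness of
the analysis logic, not robustness to base-call noise.

## Alignment and counting

The aligner is a deliberately simple, fully specified stand-in for a
short-read mapper plus isomiR annotator: for t = 0..3 the read prefix of
length L−t is searched as an exact substring of every hairpin ± 10 nt
flank (hairpin sense), every piRNA and every spike-in; only placements at
the smallest t are kept (maximal matched core; zero substitutions; no 5'
clipping; matched core ≥ 13 nt so a 16 nt read can still carry a 3 nt
tail). Among the reported placements each receives weight 1/n, the
fractional-assignment rule; arm is assigned by whether the core midpoint
falls inside a mature interval, with loop-straddling cores counted as
`other` and excluded from fidelity work. The whole aligner is checked
against a brute-force (target, position, t) enumeration oracle for exact
set equality.

Size factors are class-total based: `s_j = T_j / geomean(T)` with T the
per-sample total of piRNA (or spike-in) counts. Whether the original
analysis used raw class totals or a median-of-ratios restricted to the
class is not derivable from the methods text; totals were chosen as the
stated reading and are flagged here.

Differential abundance is a self-contained simplification of a
negative-binomial Wald test: Welch's t on log2(normalized + 0.5),
BH-adjusted over features with baseMean > 5, calls at |log2FC| > 1 and
padj < 0.05. It has no dispersion shrinkage, so it is conservative at very
low counts and anti-conservative if replicates are severely overdispersed;
at the synthetic effect sizes used here (|log2FC| = 2, three replicates,
10% log-normal replicate jitter over multinomial sampling at 100k depth)
its calibration is verified by simulation: a median of at least 8/10 true
arms recovered and at most 5 false `down` calls among 100 nulls across 20
seeds.

## isomiR fidelity

Records with unambiguous untemplated tails are removed, as only those are
decidably non-genomic. Templated-ambiguous tails are *retained and counted
as templated 3' sequence* (they shift the observed 3' coordinate by the
tail length): an all-genomic extension cannot be distinguished from a
longer Microprocessor cut, which is precisely the published confound for
3p-arm 3' ends, and the package makes the same conservative choice
explicit. Consequently 3p-arm percent-canonical values are expected to run
lower than 5p values in tailed libraries — a feature of the measurement,
not a bug.

Arms enter the analysis when their baseMean (from the matching
differential-abundance run on the same dataset) exceeds 25. Fidelity
comparisons round weight sums half-to-even to integers (exact tests need
counts; the rounding rule is fixed for reproducibility), use a two-sided
Fisher exact test on the canonical/non-canonical 2×2, and BH-adjust across
all compared arms. A *significant* fidelity change additionally requires
an absolute percent-canonical difference of ≥ 10 points; the statistical
test alone would flag trivial shifts at high depth, while the published
observation is that exactly one locus shows a biologically meaningful
change. Both thresholds are arguments. Which statistical test the original
analysis used for this comparison is not stated; Fisher-on-canonical-vs-not
is this package's explicit choice.

## FRAP

Normalization follows the stated measurement procedure in order:
background subtraction with an equal-area adjacent nuclear ROI;
multiplicative correction for acquisition photobleaching (divide by
whole-image intensity relative to its pre-bleach mean — the methods say
the whole-image decrease was "used", multiplicative is the standard
reading and is exactly invertible); affine rescale pinning the 10-frame
pre-bleach mean to 1 and the first post-bleach frame to 0; bleach-pulse
frame dropped. The fit model is the one-phase association
`y(t) = P(1 − e^{−kt})` with t = 0 at the first post-bleach frame (the
normalization anchor forces y(0) = 0), bounded least squares with
deterministic initialization (P0 = last value, k0 = ln2 / time-to-half)
and a fixed restart ladder, so fits are reproducible without a seed.
`t½ = ln2/k`, immobile fraction `1 − P`; small negative immobile fractions
from noise are tolerated down to −0.1 and flagged.

The simulator's `noise_sd` is defined on the *normalized* recovery scale —
the scale on which FRAP curves are reported and the only one on which a
noise level can be read off a published figure; channel-level noise is
calibrated so the normalized trace has exactly that per-frame sd. Under
the default fixture (P = 0.5, t½ = 4 s, 60 post-bleach frames at 1 s,
noise sd 0.05) the median per-trace relative recovery error is below 10%
for both parameters, and the mean over 23 traces recovers the fixture
truth well within 3 SEM. Worth knowing: because the first post-bleach
frame is itself noisy, anchoring y(0) = 0 to it propagates that single
frame's noise into every fit — a genuine property of the published
normalization, and the main contributor to fit variance here.

## Nucleus images and focus quantification

The image generator builds a small z-stack: flat extracellular background
everywhere, a diffuse nuclear level inside a circular nucleus mask (zero
inside a central nucleolus, which excludes the tagged protein), and
Gaussian-profile foci each confined to one plane. Focus amplitudes are
scaled so the summed excess equals `f/(1−f)` × diffuse total — the foci
hold *exactly* fraction f of total nuclear signal, which is the recorded
truth. Kernels are truncated at the measurement ROI radius so the injected
excess lies wholly inside the ROI; with that construction the zero-noise
measurement is exact, and the noisy measurement is unbiased. Default
fixture: f = 0.02 (2% of nuclear signal in foci), 4 foci, 64×64×5 stack,
diffuse level 100, noise sd 3; the hemizygous variant scales nuclear
concentration by 0.6. A per-session gain multiplies the whole image to
emulate acquisition differences between imaging sessions (the acceptance
run uses gains 1.0 and 1.25).

Quantification deliberately uses two projections, as the measurement
protocol does: ranked focus brightness from a single plane per focus, but
the fraction-in-foci from sum projections. Background for each focus is
the nearest equal-area set of valid pixels (inside nucleus, outside the
nucleolus and all focus ROIs); foci measuring negative are excluded and
counted. Nuclear totals subtract an area-scaled extranuclear ring.
Session normalization divides each quantity by the same-session control
mean only — sessions never share a denominator. Colocalization uses a
center-distance rule (an A-focus counts if any B-center lies within the
threshold, default the ~250 nm diffraction limit in pixels); the original
scoring criterion is not described, and center distance is the simplest
defensible rule at diffraction-limited granule sizes. No focus detection,
segmentation or size estimation is attempted — ROIs are inputs, matching a
manually-measured protocol.

## Feature association

IDR1 sensitivity is operationalized as the signed log2FC (mutant vs
wild type), not the binary down-call, for both correlations and group
comparisons — matching how such associations are plotted. The feature
table (cleavage score, DRES/midBMW/mGHG flags, loop/stem/lower-stem
lengths, mismatch and bulge counts, clustered/intronic context) is
consumed as an input; no structure prediction or motif scoring is
performed. Set overlap between stage-specific downregulated sets uses the
smaller set as the percent denominator (the conservative convention; the
alternative denominators are the other set or the union) and a one-sided
hypergeometric enrichment tail, both verified against exhaustive
summation.

## Synthetic-generator defaults and what the tests show

Generator defaults are the study conditions: FRAP fixture at plateau 0.5
and t½ = 4 s with 23 traces; image fixture at 2% focus fraction with 50
nuclei; hemizygous dosage 0.6 with 30 + 30 nuclei per session over two
sessions; the replicate count per sequencing group defaults to 3
(unstated in the source protocol; three biological replicates is the
field norm). Problem sizes in the test-suite simulations (e.g. 10–50k
reads per sample, 200 FRAP traces, 20-seed calibration loops) were chosen
so every distributional check has clear resolution at its tolerance while
the whole suite stays desk-scale. Passing tests demonstrate that each
pipeline stage recovers the generator's ground truth under the stated
noise models; they cannot demonstrate robustness to artifacts the
generator does not emulate (ligation bias, sequencing error, optical
aberrations, focus drift).

## Known limitations

- The aligner searches hairpin ± flank, piRNA and spike-in sequences only;
  genomic background mapping is out of scope.
- The differential-abundance test is not a negative-binomial model; with
  strong overdispersion or n = 2 replicates its error control degrades.
- 3' trimming cannot be separated from alternative cleavage for templated
  isoforms; the package reports the confounded quantity explicitly rather
  than deconvolving it.
- FRAP fitting assumes the focus stays in plane and recovery is single
  exponential; reaction-diffusion models are out of scope.
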