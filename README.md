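# mirproc

Quantitative analysis of Microprocessor (Drosha/DGCR8) nuclear condensates
and miRNA biogenesis in *C. elegans*, as a tested R pipeline. The package
covers the five analyses such a study runs, each exercisable end-to-end on
synthetic data with machine-readable ground truth:

1. **Small RNA quantification** — length filtering (16–30 nt inclusive) and
   UMI collapsing of reads; exact-core alignment to miRNA hairpins
   (± flank), piRNAs and spike-ins with up to 3 nt of unmatched 3' tail
   (no substitutions, no 5' clipping); fractional feature counting
   (weight 1/n over n equally good placements); size factors from total
   piRNA or spike-in counts, `s_j = T_j / geomean(T)`; and a simplified
   differential-abundance caller (Welch t on log2(normalized + 0.5),
   Benjamini–Hochberg, calls at |log2FC| > 1 and padj < 0.05, detection at
   baseMean > 5).
2. **isomiR cleavage fidelity** — per-read signed end offsets against the
   annotated canonical Microprocessor cut sites (5' end of 5p arms, 3' end
   of 3p arms; position 0 = canonical), removal of unambiguous untemplated
   3' additions, per-arm end distributions and % canonical cleavage
   (arms with baseMean > 25), and genotype comparisons by Fisher's exact
   test with BH adjustment.
3. **FRAP analysis** — methods-faithful normalization (equal-area background
   subtraction, multiplicative whole-image photobleach correction,
   pre-bleach mean = 1, first post-bleach frame = 0, bleach frame excluded)
   and a bounded least-squares fit of the one-phase association
   `y(t) = P(1 − e^{−kt})`, reporting `t½ = ln2/k` and immobile fraction
   `1 − P`.
4. **Nuclear focus quantification** — single-plane focus intensities with
   equal-area adjacent background subtraction, negative-focus exclusion,
   brightest/second-brightest ranking, sum-projection nuclear totals, the
   percent of nuclear signal residing in foci, per-session normalization to
   control nuclei, and center-distance colocalization rates.
5. **pri-miRNA feature association** — Pearson correlation of IDR1
   sensitivity (log2FC) with continuous hairpin features, Welch group
   comparisons for categorical features, and hypergeometric set-overlap
   tests between stage-specific downregulated sets.

A seeded generator (`make_reference`, `simulate_reads`,
`simulate_frap_trace`, `simulate_nucleus_image`, `simulate_feature_table`)
produces every input the pipeline consumes — FASTA/GFF3 references, FASTQ
reads with isomiR end heterogeneity and U-biased 3' tails, FRAP CSV traces,
nucleus image stacks and feature tables — so all stages are testable
without external downloads.

## Worked example

Simulate a wild-type vs IDR-deletion contrast in which one miRNA locus is
produced at 25% of its wild-type level, then quantify and call differential
abundance with piRNA-total normalization:

```r
library(mirproc)

bundle <- make_reference(n_mirna = 6, n_pirna = 10, n_spikein = 3, seed = 42)
wt  <- genotype_spec("WT", bundle$mirna_loci$name)
mut <- genotype_spec("dIDR1", bundle$mirna_loci$name,
                     multipliers = setNames(c(0.25, rep(1, 5)),
                                            bundle$mirna_loci$name))

counts <- count_matrix(setNames(lapply(1:6, function(i) {
  gt  <- if (i <= 3) wt else mut
  sim <- simulate_reads(bundle, gt, 50000, replicate_id = i, seed = 100 + i)
  count_features(align_reads(sim$reads, bundle), bundle)
}), c(paste0("WT_", 1:3), paste0("dIDR1_", 1:3))))

sf <- compute_size_factors(counts, "pirna_total")
de <- differential_abundance(counts$counts, sf,
                             rep(c("WT", "dIDR1"), each = 3), "dIDR1", "WT")
```

The top of the result table (miRNA arms, baseMean > 5, ordered by padj):

```
        feature baseMean log2FC     padj call
  syn-mir-01-5p     1031 -1.879 0.000043 down
  syn-mir-01-3p     1018 -1.903 0.003577 down
  syn-mir-03-3p      679  0.171 0.042476   ns
  syn-mir-02-5p     4919  0.129 0.066759   ns
```

Both arms of the knocked-down locus are called `down` (observed log2FC near
−2, slightly shrunk by the +0.5 pseudocount); note `syn-mir-03-3p` stays
`ns` despite padj < 0.05 because its effect does not clear the |log2FC| > 1
threshold. FRAP and imaging run the same way:

```r
tr  <- simulate_frap_trace(plateau = 0.5, rate = log(2)/4,
                           noise_sd = 0.05, seed = 11)
fit <- fit_recovery(normalize_trace(tr))
#> FRAP fit: t_half = 4.35 s, immobile fraction = 0.50

img <- do.call(simulate_nucleus_image,
               c(nucleus_fixture_defaults(), list(seed = 3)))
nucleus_totals(img)
#>   session genotype  total brightest second_brightest allfoci fraction_in_foci
#>        S1       WT 588545      3466             3263   11682            1.985
```

A single noisy trace fits to `t½ = 4.35 s` with half the signal immobile,
and the synthetic hypodermal nucleus measures ~2% of its nuclear signal in
foci — the generator's ground truth for that fixture.

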