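# radmix

Local-ancestry inference and introgression analysis for sparse RAD-seq
panels of two recently hybridizing species.

## The problem

When an invading population and a related endemic species hybridize, donor
haplotypes enter the invader's genome as Mb-scale ancestry blocks that
erode over generations of recombination.  With reduced-representation
(ddRAD) data — short loci scattered sparsely across the genome, with
sample-specific dropout — classical phased local-ancestry methods are not
applicable, but window-level counts of raw sequence differences still
carry the signal: a window of donor ancestry is about as divergent from a
donor reference panel as two donor samples are from each other
(π_donor), a native window is as divergent as the two species are
(d_XY), and a heterozygous window sits at their mean m = (π + d_XY)/2.

radmix implements this programme end to end for R users (population
geneticists working on invasion, hybridization, and admixture mapping):

1. **Pairwise divergence counting.**  For samples A, B and window w,
   `n = 2 ×` (bp covered in both samples in w) and `k` = summed per-site
   differences under a fixed pseudo-haplotype pairing (alleles sorted at
   each site; per-site contribution `|dosage_A − dosage_B|`), so `k` is an
   integer and `k/n` estimates π (within-population pairs) or d_XY
   (between-population pairs).
2. **Ancestry HMM.**  Three hidden states (donor `SRC`, native `NAT`,
   heterozygous `HET`) with binomial emissions
   `k ~ Bin(n, p_state)`, `p = (π_donor, m, d_XY)` estimated as
   genome-wide medians of window rates; symmetric transitions with
   per-window switch rate τ (default 10⁻³ per 100 kb); per-chromosome
   log-space Viterbi decoding with conservative tie-breaking toward
   native ancestry.
3. **Blocks.**  Maximal same-state runs become genomic blocks (data-free
   windows bridged when flanked by the same state), with admixture
   proportions (HET weighted ½), shared-breakpoint grouping, and
   logarithmic block dating `t = ln(x)/ln(1 − c)`.
4. **Admixture mapping.**  Yates-corrected χ² tests of donor-ancestry
   carrier status (dominance coding) against a binary phenotype, per
   locus or as a genome scan with Benjamini–Hochberg q-values.
5. **Population statistics.**  S, Watterson's θ, π, observed
   heterozygosity, Tajima's D; folded site-frequency spectra with
   hypergeometric down-projection and interval masking; SFS bootstrap;
   Patterson's ABBA-BABA D with block bootstrap; rescaling of
   coalescent-unit demographic estimates (`N_ref = θ/(4μL)`).
6. **Synthetic data.**  A seeded generator of two-species diploid panels
   with RAD-like sparse coverage, planted donor tracts, a causal locus
   with a dominant phenotype, and full ground truth, so every stage is
   testable without external data.

## Worked example

```r
library(radmix)

cfg <- mg114Scenario(seed = 4)     # 15 focal + 10 donor diploids, 12 x 5 Mb;
res <- runScenario(cfg)            # six carriers of one 2.2 Mb donor tract

res$recovery$sensitivity
#> [1] 1
res$recovery$fpr
#> [1] 0.00022553
table(res$carriers)
#> non-carrier het-carrier hom-carrier
#>           9           0           6

subset(res$scan, !is.na(q) & q == min(q, na.rm = TRUE))[1, c("chrom",
  "start", "end", "a", "b", "c", "d", "chi2", "p", "candidate")]
#>     chrom   start     end a b c d     chi2            p candidate
#> 113 chr03 1200000 1300000 6 0 0 9 11.12269 0.0008527824     FALSE
```

Every window of the planted 2.2 Mb tract is recovered in the six carriers
(sensitivity 1) with a 0.02% false-positive window rate; carrier status
at the causal locus separates the phenotype perfectly, and the scan's top
windows give the Yates-corrected χ² = 11.12 (p ≈ 0.0009) expected for a
perfect 6/9 split of 15 individuals.

Locus-wise test and block dating:

```r
ancestryPhenotypeTest(c(6, 0, 0, 6))
#> chi2 = 8.33; df = 1; p = 0.003892 (Yates-corrected)
#>             phenotype+ phenotype-
#> carrier              6          0
#> non-carrier          0          6

estimateBlockAge(x = 0.792, c = 0.054)   # block at 79.2% of its chromosome
#> [1] 4.20073                             # generations
```

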