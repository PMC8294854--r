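---
title: "radmix: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{radmix: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, and the choices made where the design was
genuinely open.

## 1. Divergence counting on unphased diploid data

The pipeline's primitive is the pair-window count `(k, n)`: for two
diploid samples and a genomic window, `n` is twice the number of base
pairs covered in *both* samples (so invariant positions enter the
denominator, as they must for `k/n` to estimate a per-site rate), and `k`
is the integer number of sequence differences.  Phase is unavailable in
RAD data, so each sample is represented per site by two pseudo-haplotypes
with alleles sorted (0 before 1); first is compared to first and second
to second, giving a per-site contribution of `|dosage_A − dosage_B|`
(0, 1 or 2).  This rule is deliberate on two counts:

* `k` stays integral, so a binomial emission model on `(k, n)` is
  well-formed;
* it is symmetric in the pair and sums exactly over windows (no
  double-counting at window borders), which the test suite checks.

A site where either sample lacks a genotype call but both are covered is
treated as equal (contributes to `n`, not `k`) — the convention of
divergence counting over assembled loci, where invariant positions
dominate.  Multi-allelic and non-SNP records are dropped at the VCF
boundary with a message.  Coordinates are 0-based half-open at the
BED/TSV boundary and 1-based inside `GRanges`.

Within-population pairs' `k/n` estimate nucleotide diversity π;
between-population pairs estimate d~XY~; genome-wide values use each
pair's whole-genome ratio Σk/Σn (coverage-weighted by construction).
Windows are nonoverlapping tiles (default 100 kb).  Overlapping windows
would only smooth the same information while breaking the additivity
invariant above, so a sliding/step option is intentionally not offered.

## 2. The three-state ancestry HMM

Hidden states are donor ancestry (`SRC`), native ancestry (`NAT`) and
heterozygous ancestry (`HET`).  The emission model for a focal
individual's window observation `(k, n)` against a donor reference panel
is binomial with success rate

* `pSrc` ≈ within-donor π — under donor ancestry the focal window is
  just another donor haplotype pair;
* `pNat` ≈ d~XY~ — a native window differs from the panel at the
  between-species rate;
* `pHet` = (pSrc + pNat)/2 exactly — one haplotype of each kind.

`pSrc` and `pNat` are estimated as genome-wide *medians* of per-window
pair rates (within-panel, and native-reference-vs-panel respectively);
medians resist contamination from windows that are themselves
introgressed in the reference individuals.  Estimates are clipped to
[10⁻⁶, 1 − 10⁻⁶] so log-likelihoods stay finite, and `pNat ≤ pSrc` is a
diagnostic error: the populations are not diverged enough for window
ancestry assignment.

**Transitions.**  A symmetric stay/switch model: leave the current state
with probability τ per window, split equally between the other two
states; uniform initial distribution.  The default τ = 10⁻³ per 100 kb
window encodes the prior that ancestry blocks in a recently admixed
population span tens of Mb (expected dwell ≈ 1/τ windows = 100 Mb scale);
an optional distinct leave rate for `HET` is available because
heterozygous tracts erode faster.  τ is a smoothing prior, not a fitted
quantity.

**Decoding.**  Per-chromosome Viterbi, entirely in log space (binomial
log-pmfs at these rates are far below double-precision probability
range).  Windows with fewer than `minSites` = 100 compared allele-sites
are uninformative: their emission log-likelihood is 0 for every state, so
the path bridges them on transitions alone; the reported state is
`MISSING` while the raw decoded state is retained for block bridging.
Exact log-likelihood ties break toward `NAT`, then `HET`, then `SRC` —
conservative against false introgression calls.  Correctness is checked
against exhaustive enumeration of all 3^L paths on random short tracks.

**Panel aggregation and pseudo-replication.**  Two observation modes are
provided.  The default of `decodeIndividual` sums `(k, n)` over all
focal×panel pairs and applies a single binomial — the simplest reading of
"three binomial models" on aggregated comparisons.  But the summands are
not independent: every pair re-counts the focal haplotypes' divergence to
the *shared* donor ancestor, so `n` grows with panel size while the
independent information does not, and the binomial becomes overconfident
— window-scale fluctuations in the local density of fixed differences
(a Poisson process along the genome) then masquerade as strong ancestry
signals.  The `maxPanel` option caps how many panel samples are
aggregated; the pipeline wrapper `runScenario` uses `maxPanel = 1`
(a per-pair binomial, for which the independence assumption is honest),
and this is what the package's recovery benchmarks use.  Users with very
noisy single pairs can raise `maxPanel` and lower τ to compensate.

## 3. Blocks, breakpoints and ages

Maximal runs of identical non-`MISSING` state become blocks; interior
`MISSING` runs flanked by the same state are bridged into the block (and
counted), mirroring the "ghost shading" convention for data-free windows;
`MISSING` flanked by different states belongs to no block.  Only `SRC`
and `HET` blocks are reported — native ancestry is the background — and
block + native + unbridged-missing lengths partition each chromosome
exactly (tested).

The admixture proportion of an individual is
(SRC bp + ½·HET bp) / non-missing bp — the ½ is diploid dosage: a
heterozygous window carries one donor haplotype of two.

Shared breakpoints: blocks of one chromosome and state whose starts *and*
ends agree within a tolerance (default 1 window, the HMM's resolution)
are grouped by transitive closure; groups of near-identical blocks across
individuals indicate a single hybridization event or close kinship.

**Block age.**  The observed block, at fraction `x` of its chromosome, is
dated by survival decay: if each generation erodes a fraction `c` of the
tract, `x(t) = (1 − c)^t`, so `t = ln x / ln(1 − c)`.  `c` may be given
directly or derived as `c = r_bp × L_chrom × κ` from a per-bp
recombination rate.  This is a deliberately coarse, order-of-magnitude
model — it ignores the full tract-length likelihood, recombination-map
variation, and selection — and is flagged as such; it is suited to
answering "single digits or hundreds of generations?", not to precise
dating.

## 4. Admixture mapping

Carrier status at a locus is dominant by default: any `SRC` or `HET`
block overlapping the locus (half-open semantics) makes a carrier,
because one donor haplotype suffices for a dominant donor phenotype; a
dosage coding is available.  The 2×2 carrier-by-phenotype table is tested
by Pearson's χ² with the Yates continuity correction **on by default**:

χ² = N(|ad − bc| − N/2)² / ((a+b)(c+d)(a+c)(b+d)), floored at 0,

p from the upper tail of χ²₁.  The correction matters for the small
samples this method is used at — a perfect 6/9 split gives 11.12
corrected versus 15 uncorrected, and a perfect 6/6 split 8.33 versus 12 —
and the corrected values are the ones pinned in the acceptance tests.
The genome scan tests every window with at least one carrier and one
non-carrier among informative individuals and reports Benjamini–Hochberg
q-values across tested windows; supplied candidate loci are flagged, and
a candidate-restricted lookup needs no correction.

## 5. Population statistics

* **S, θ_W, π, H, Tajima's D** use the textbook estimators; π sums
  per-site `2j(m − j)/(m(m − 1))` with `m` the called chromosomes at the
  site, Tajima's D uses the standard variance constants at the nominal
  sample size n = 2 × samples.  With S = 0, D is `NA`, never silently 0.
  Windowed D is reported as mean ± sd across windows with at least
  `minSeg` segregating sites.  All three are verified against an
  all-pairs pseudo-haplotype enumeration oracle on random matrices.
* **Folded SFS** with optional down-projection to `n'` chromosomes: each
  site with `m ≥ n'` called chromosomes and `j` alternate alleles
  contributes its *expected* hypergeometric allocation over draws of `n'`
  chromosomes, folded to minor-allele classes.  Expected (fractional)
  projection is deterministic and conserves per-site mass — each retained
  site contributes total weight 1, which the tests assert — unlike
  resampling-based projection.  Interval masking (typically of
  HMM-inferred introgression tracts, which otherwise inflate the rare
  tail and mimic a bottleneck) is applied before anything else; an empty
  mask is the identity.
* **SFS bootstrap** resamples sites across bins by a multinomial with the
  observed proportions (sites assumed independent, appropriate after LD
  pruning), deterministic given its seed.
* **Patterson's D** is frequency-weighted: ABBA = Σ(1−p₁)p₂p₃(1−p₄),
  BABA = Σp₁(1−p₂)p₃(1−p₄), D = (ABBA − BABA)/(ABBA + BABA).  The
  outgroup's major allele is ancestral; outgroup-polymorphic sites are
  dropped.  Uncertainty comes from a block bootstrap over genomic blocks
  (default 1 Mb — comfortably above the LD scale of pruned RAD data,
  small enough to leave hundreds of blocks) with a one-sided sign-based
  p-value.  D is antisymmetric in P1↔P2 (tested).
* **Demographic rescaling**: diffusion-based fits report θ and
  parameters in coalescent units; with per-generation mutation rate μ and
  L queried bp, `N_ref = θ/(4μL)`, sizes scale by `N_ref` and times by
  `2·N_ref` generations.  Epoch times already in generations sum directly
  to the total bottleneck age.

## 6. The synthetic generator

The generator emulates the *first moments* a divergence-based HMM
consumes, not full coalescent genealogies.  A root genome receives
species-ancestor mutations on each species branch at per-site rate
`(d − (π_src + π_nat)/2)/2`, then every haplotype receives private
mutations at rate `π_pop/2`.  In expectation, a within-population pair
differs at π_pop per site and a between-species pair at d.  Donor tracts
replace the designated focal haplotype segment (one haplotype for `het`,
both for `hom`) with freshly drawn donor haplotypes.  Mutations are
placed by Poisson draws on integer positions *without replacement*
(no recurrence), and only within the RAD locus set — positions outside
any locus are unobservable by every sample, so omitting them changes no
per-covered-bp rate.  Coverage is a shared set of ~300 bp loci
(~310/Mb), thinned per sample at 80% retention to emulate RAD dropout;
genotypes at dropped loci are missing.  The phenotype is dominant: 1 for
individuals whose tract overlaps the causal locus.

Defaults are anchored to the study system the package targets: 12
chromosomes, donor π = 4.5×10⁻⁴, native π = 2.3×10⁻⁴, between-species
d = 2.3×10⁻³.  Chromosomes default to 5 Mb — a scaled-down genome that
keeps a full multi-seed pipeline benchmark to minutes while leaving
~600 windows and tract:genome proportions realistic; the
`mg114Scenario` preset (15 focal + 10 donor diploids, six carriers of a
breakpoint-identical homozygous 2.2 Mb tract = 3.67% of the genome over
a causal locus) is the standing end-to-end benchmark, run over 20 seeds
in the acceptance suite.

**What the generator does not emulate** — and hence what passing
recovery tests do and do not show: there is no linkage disequilibrium or
genealogical correlation between loci (a star-like model), no incomplete
lineage sorting (in real data, ILS produces small d~XY~ dips that the
100 kb window scale is chosen to average over), no allele dropout bias,
no selection, and no read-level error.  Recovery results on this
generator demonstrate the inference machinery is correct and calibrated
under its own model; they do not by themselves establish power on real
RAD data, where the above processes add noise.

## 7. Numerical and degenerate-case conventions

* All HMM arithmetic in log space; `n = 0` (or `< minSites`) windows have
  emission log-likelihood 0 in every state.
* Viterbi ties broken deterministically NAT > HET > SRC.
* `k > n` is a hard error; `n = 0` pair rates are `NA`, never 0; a pair
  with no shared coverage anywhere is `NA` in the distance matrix.
* Degenerate 2×2 tables (a zero margin) are an explicit error; the Yates
  numerator floors at zero.
* Emission rates clipped to [10⁻⁶, 1 − 10⁻⁶].
* Projection size must be even and at most the available chromosomes;
  empty SFS bootstrap is an error; single-bin SFS bootstraps to itself.
* The generator requires an explicit seed; identical config + seed gives
  identical output (tested byte-for-byte on the genotype matrix).

## 8. Problem sizes

The shipped tests and the acceptance script run, per seed, a 60 Mb
12-chromosome genome, 25 diploid samples, ~45–55k segregating sites,
~18.6k RAD loci, 600 windows, and 195 sample pairs; 20 seeds for the
recovery benchmark; 200 random instances for Viterbi-vs-enumeration; 100
random matrices for the statistics oracles.  These sizes were chosen so
the full suite completes in a few minutes on one CPU while every window
of interest retains well over the `minSites` threshold of compared
sites.

## 9. Known limitations

* Two source populations only; no phasing; forward–backward posteriors
  are not implemented (Viterbi point paths only).
* The block-age relationship is a coarse survival-decay model (Section 3).
* Tajima's D uses nominal sample size for its variance constants even
  with per-site missingness (exact on complete data, the case the
  oracles cover).
* The default aggregated observation mode is overdispersed for large
  panels (Section 2); prefer `maxPanel = 1` unless per-pair counts are
  very sparse.
* F_ST, LD pruning, genotype calling and diffusion-based demographic
  fitting are out of scope; the package only prepares inputs for and
  rescales outputs of external demographic fitters.
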