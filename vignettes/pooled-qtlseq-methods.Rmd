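---
title: "Methods: pooled delta-SNP-index mapping of case/control exome pools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled delta-SNP-index mapping of case/control exome pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

pooldelta implements a QTL-seq-style bulk-segregant analysis for human
case/control designs. Equimolar genomic DNA of $n$ diploid individuals per
phenotype group (two case pools and one control pool of unaffected family
members; $n = 20$ by default) is exome-captured and sequenced as a single
library per pool, so individual genotypes are never observed — only pooled
read counts at variant positions.

At a biallelic SNV with total read depth $d$ and $a$ variant-supporting
reads, the **SNP index** is the variant-read fraction

$$\mathrm{SI} = a / d,$$

an estimate of the pooled alternate-allele dosage. For a case pool $c$ and
the control pool $N$ sharing a site, the **delta SNP index**

$$\Delta \mathrm{SI} = \mathrm{SI}_c - \mathrm{SI}_N$$

is centred at zero wherever cases and controls are draws from the same
population, and shifts away from zero near a susceptibility locus whose
allele frequency differs between the phenotype groups. Unlike inbred-plant
QTL-seq, where the index sits at 0.5 and sweeps to 0/1 under selection,
human complex-trait signals are small frequency displacements; the method
therefore looks for consistent regional shifts rather than fixed alleles.

The sampling model used throughout (simulation and null bands) is
two-stage binomial: the pool's alternate haplotype count is
$k \sim \mathrm{Bin}(2n, p)$ for population frequency $p$, the pool allele
fraction is $f = k/2n$, and the observed variant reads are
$a \sim \mathrm{Bin}(d, f(1-e) + (1-f)e)$ with per-read miscall rate $e$.
Both binomial stages matter: at $d \approx 40$ and $n = 20$ they contribute
comparable variance to $\Delta\mathrm{SI}$.

## The filter cascade

Variant records pass a staged cascade, applied per pool and then
intersected:

1. **Call filter** — records with a mismatch annotation above 6 or depth
   below `min_call_depth` are removed as alignment/sequencing artefacts.
   The two published descriptions of this stage disagree (a "depth ≥ 3"
   label on the staged count table versus "depth of fewer than 5 were
   eliminated" in the methods text); both thresholds are exposed as
   parameters and the default is `min_call_depth = 5`, following the
   methods text. Mismatch annotations are produced by alignment-level
   tooling outside this package's scope; when absent the criterion is
   skipped with a message.
2. **SNP-index computation** — zero-depth records are dropped with a count.
3. **Depth filter** — `depth >= 20`.
4. **SNP-index filter** — `snp_index >= 0.3`, removing low-frequency calls
   that behave as noise in pooled data.
5. **Pairing** — an inner join of the two pools' survivors on
   `(chrom, pos, ref, alt)`. Joining on the full allele key (not position
   alone) prevents pairing different substitutions at one site.

Filtering per pool *before* pairing is deliberate: the staged count table
this mirrors reports per-pool survivor counts alongside a smaller paired
count, which is only consistent with per-pool filtering followed by
intersection. `snp_index_cascade()` returns the staged report; counts are
non-increasing down the cascade by construction.

Combining the two case pools into a "combined-case" pool
(`combine_pools()`) is a read-level union: depths and variant reads are
summed per site and the index recomputed, which equals the depth-weighted
mean of the member indices.

## Windows and the concatenated coordinate

Trendlines are means of $\Delta\mathrm{SI}$ over sliding windows
(default 4 Mb width, 10 kb slide — the widest of the published scan
configurations, retained there as best-resolving). Windows are anchored at
position 0 of each chromosome, half-open, with SNP membership
`win_start <= pos < win_end`; trailing windows are truncated at the
chromosome end and empty windows are kept (with `NA` mean) so trendline
gaps over uncaptured regions stay visible.

Windowing runs on **genomic** coordinates: window sizes in bp are
physically meaningful there, whereas the spacer-concatenated coordinate
(200 bp of "N" between adjacent target loci) exists to compress sparse
exome loci for plotting. The source method description does not say which
coordinate its windows used; we compute on genomic coordinates and use the
concatenation map (`build_concat_map()`) only for display, which
`plot_delta_genome()` does when given a map.

## Null confidence bands

The published figures draw "statistical confidence intervals under the
null hypothesis of no QTL" without specifying their construction. We
reconstruct them in the QTL-seq tradition as pointwise Monte-Carlo
quantiles. For each non-empty window, every member SNP is simulated
independently under the two-stage binomial null — a common population
frequency $p$ per replicate drawn from a frequency model, haplotype counts
for both pools, then reads at the SNP's *observed* depth pair — and the
per-replicate window mean is collected; the 2.5/97.5% and 0.5/99.5%
empirical quantiles give the 95% (green) and 99% (yellow) bands. Because
the null is simulated at the observed depths, bands widen over
low-coverage windows exactly as the data noise does.

The default frequency model resamples the empirical control-pool SNP-index
distribution truncated to $[0.05, 0.95]$ (truncation avoids degenerate
monomorphic draws); fixed-$p$, uniform, and Beta alternatives are
accepted. Bands are pointwise, not family-wise: the published lines do not
state a multiplicity adjustment, and the alternative is noted here rather
than implemented.

Validation sizes: band calibration is checked on a null synthetic dataset
of 20,000 SNPs over three 50 Mb chromosomes with a 25 kb non-overlapping
tiling (≈ 5,800 occupied windows, 2,000 replicates each), chosen so that
window exceedance events are independent and the 95%/99% exceedance rates
can be required to land within ±0.01/±0.005 of nominal.

## Region-level comparison of two contrasts

To ask whether two case phenotypes (esotropia and exotropia) have
different genetic backgrounds, the per-SNP differences
$d_i = \Delta\mathrm{SI}^{ET/N}_i - \Delta\mathrm{SI}^{XT/N}_i$ are tested
region by region with a two-sided Wilcoxon signed-rank test. Because both
contrasts subtract the same control pool, $d_i$ reduces to
$\mathrm{SI}^{ET}_i - \mathrm{SI}^{XT}_i$, which is symmetric about zero
under exchangeability of the two case pools — precisely the signed-rank
null. Pairing is over SNPs present in both contrasts (the only
construction that makes a paired test well-defined).

Three region systems are supported: cytogenetic bands; 50 consecutive
SNPs (each SNP with its 25 preceding and 24 following neighbours,
truncated at chromosome ends); and 4 Mb / 10 kb sliding windows.

Choices the source description leaves open, fixed here as defaults:

* **Zero differences** are dropped before ranking (classic Wilcoxon
  convention); Pratt's method is available via `zero_method = "pratt"`.
* **Exact vs approximate**: the exact signed-rank distribution (base
  `psignrank`) is used up to $n = 25$ when $|d_i|$ are tie-free, else the
  normal approximation with tie and continuity corrections.
* **Minimum region size** `min_n = 5`: with fewer pairs the two-sided
  exact p-value cannot fall below $2/2^5 = 0.0625$, so smaller regions are
  reported untested rather than contributing guaranteed-null tests.
* **Bonferroni scope**: the threshold is $\alpha / m$ with $m$ the number
  of *tested* regions of the chosen kind (per-kind, not pooled across
  kinds).
* **Storey q-values**: $\hat\pi_0$ from the $\lambda$-grid smoother
  (natural cubic smoothing spline through
  $\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m(1-\lambda))$,
  $\lambda = 0, 0.05, \dots, 0.90$, evaluated at the largest $\lambda$),
  then the step-down $q_{(i)} = \min_{j \ge i} \hat\pi_0 m p_{(j)} / j$.
  Forcing $\pi_0 = 1$ reproduces Benjamini–Hochberg exactly, which the
  test suite checks against an independently coded step-up oracle. A
  fixed-$\lambda$ estimator is available via `pi0_method = "fixed"`.
* **Y chromosome** regions are excluded by default: unequal male/female
  ratios between pools confound the pooled index there.

Note that 50-SNP regions overlap heavily, so neighbouring tests are
strongly correlated; family-wise conclusions should rest on the Bonferroni
or q-value flags, not on counts of significant regions.

## The synthetic-data generator

`simulate_pooled_exome()` generates data with exactly the statistical
structure the analysis assumes, so every downstream stage is testable
without any external download. Its defaults are the study conditions:

* **3 pools × 20 diploid individuals**, equimolar. A lognormal
  per-individual weight jitter (`weight_sd`) exists for robustness
  experiments and is off by default.
* **Depth**: discretized Gamma with mean 39.3 and SD 16.3 reads, floored
  at one read. A Gamma (not Poisson) is needed to reproduce the reported
  overdispersion (SD ≈ 16 at mean ≈ 39); the floor keeps zero-depth
  records out of the generator (real pooled VCFs may still contain them,
  and the cascade drops them gracefully).
* **Baseline frequencies**: i.i.d. Beta(2, 2) across SNPs, shared by all
  pools under the null. No default is published; Beta(2, 2) is symmetric
  about 0.5 — echoing the diploid-plant baseline the pipeline descends
  from — and keeps mass away from the monomorphic edges where the index
  filter would discard nearly everything. Both shapes are configurable.
* **Sequencing error**: per-read miscall probability 0.002, a typical
  short-read substitution rate.
* **Genome**: three 50 Mb chromosomes with a deterministic sparse "exome"
  of 50 kb target loci every 200 kb (25% coverage, ≈ 37.5 Mb of target —
  comparable to the ≈ 37 Mb human exome target the design sequences);
  `n_snps = 24000` positions uniform over the loci. The configuration can
  mirror all 24 human chromosomes, at desk-scale cost.
* **Planted QTLs** (`qtl_spec()`): an additive alternate-frequency shift
  over a region in one or both case pools, clipped to $[0, 1]$ — the
  synthetic counterpart of a susceptibility locus producing a "slight
  increase in a certain genotype".

What the generator deliberately does **not** emulate: linkage
disequilibrium and haplotype structure (SNPs are independent), relatedness
among the pooled individuals (family-member controls are treated as
unrelated), population stratification, capture-efficiency and GC biases,
and alignment artefacts. Passing tests therefore demonstrate correctness
of the statistical machinery under the stated sampling model, not
robustness to those real-data complications; on real data the
per-SNP-independence assumption makes the null bands and region tests
anti-conservative to a degree governed by local LD.

## Numerical and degenerate-input choices

* VCF positions are 1-based; BED/cytoband intervals 0-based half-open;
  interval membership converts explicitly. A 1-based position $x$ is in
  0-based $[s, e)$ iff $s < x \le e$.
* Multi-allelic sites are split per alternate allele, each split record
  keeping the **full** site depth as denominator (the index is "variant
  reads over all reads"). Indels and non-SNV alleles are dropped with a
  count.
* Window means are accumulated with per-window `sum()` over the sorted
  member deltas, so they are bit-identical to a brute-force recomputation.
* Empirical band quantiles use the default continuous quantile estimator;
  with 2,000 replicates the 99% band rests on ≈ 10 tail points, so bands
  at that level carry Monte-Carlo noise of a few times $10^{-3}$.
* Degenerate cases: all-zero difference vectors give $p = 1$ with a flag;
  frequency models concentrated on $\{0, 1\}$ are rejected; planted-QTL
  regions containing no SNPs warn and no-op; empty VCF bodies parse to
  empty tables.

## Validation problem sizes

The test suite runs entirely on generated data: enumeration oracles for
the exact Wilcoxon branch (all $2^n$ sign assignments, $n \le 12$), an
independently coded per-individual Monte-Carlo for the null sampler
(100,000 replicates), brute-force window recomputation (5,000 SNPs under a
4 Mb / 10 kb scan), band calibration as described above, and planted-QTL
recovery (20 seeds, 24,000 SNPs, +0.25 shift over 2 Mb at 40× depth,
requiring the top window center within 1 Mb of the planted center in at
least 90% of seeds). These sizes were chosen to give each check a
comfortable Monte-Carlo margin at interactive runtimes.

## Limitations

Beyond the generator simplifications above: the package consumes annotated
variant records (VCF), not reads or alignments, so alignment-level filters
are honored only via annotations; covariates cannot be adjusted in a
pooled design; and region significance identifies *differential* signal
between two contrasts, not which contrast carries the causal locus —
follow-up on individual genotypes is required for that.
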