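---
title: "Methods: windowed diversity statistics and the synthetic-data model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed diversity statistics and the synthetic-data model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyodiv)
```

# Scope and model

`karyodiv` compares patterns of DNA variation between three chromosome
classes — autosomes, X and Y — from a multi-sample VCF, a merged GFF3 gene
annotation and a reference FASTA. The analysis unit is the fixed
non-overlapping window (default 100 kb, 1-based closed windows
`[1, 100000]`, `[100001, 200000]`, ..., the last window truncated at the
chromosome end). All inputs keep their native 1-based closed coordinates;
interval arithmetic happens through IRanges, so there is a single,
well-tested overlap engine rather than ad hoc index shifts.

Upstream steps — read alignment, variant calling, consequence annotation
(SO terms, impact classes, SIFT scores) — are consumed as VCF fields, never
recomputed. The package's own contribution is everything from the VCF
onwards.

## Estimators

**Per-site heterozygosity.** For a site with AN called alleles and per-alt
counts AC, the probability that two alleles drawn without replacement
differ is $h = \sum_{alt} 2\,AC(AN-AC)/(AN(AN-1))$. Missing genotypes
reduce AN and are never imputed; haploid calls (hemizygous Y) contribute
one allele. Sites with AN < 2 are skipped and counted, not silently
dropped. Windowed diversity `pi_std` is the sum of $h$ over the window's
SNPs divided by the window length. On complete data, $\sum_i h_i$ is
algebraically identical to the mean pairwise difference
$\hat\theta_\pi = \sum_{i<j} d_{ij}/\binom{n}{2}$; the suite verifies the
identity numerically on hundreds of random genotype matrices at 1e-9.

**The alternative ratio form.** A second windowed expression,
$\hat\pi_{alt} = (\sum AN(AN-1) + (w-k)p) / (2\sum AC(AN-AC))$, is
implemented verbatim as `window_pi_alt` and emitted alongside `pi_std`.
As written it is dimensionally inconsistent with per-bp diversity — the
allele-count products sit on the wrong sides of the fraction, and the
$(w-k)p$ term (with $p$ a count of pairwise window comparisons) has no
standard interpretation — so it is quarantined: reported for reference,
never used downstream, and no "corrected" variant is guessed. This is a
deliberate fidelity/correctness split: the conventional estimator drives
all comparisons.

**Watterson's θ and Tajima's D.** $\hat\theta_W = S/a_1$ with
$a_1=\sum_{i=1}^{n-1}1/i$, and
$D = (\hat\theta_\pi - \hat\theta_W)/\sqrt{e_1 S + e_2 S(S-1)}$ with the
standard Tajima (1989) constants ($b_1, b_2, c_1, c_2, e_1, e_2$ as in
`?tajima_d`). The variance parameterisation is the universal convention
(it is also what vcftools implements), adopted because the defining
papers' shorthand "Var(θ̂π − θ̂W)" does not pin the constants down by
itself. The per-window sample size $n$ is the mean AN over the window's
segregating SNP sites, rounded to the nearest integer: with missing
genotypes AN varies site to site and no single $n$ is exact; the mean is
the least arbitrary summary and is reported (`n_chrom_mean`) so users can
filter windows with heavy missingness. Undefined statistics (S = 0,
n < 2, non-positive variance) are emitted as `NA`, never 0 — zero is a
meaningful D value.

**Ka/Ks.** The default mode is the raw count ratio
$n_{nonsyn}/n_{syn}$ of annotated SNPs, the form used when comparing
selection pressure across chromosomes from annotation counts alone. The
`per_site` mode normalises by Nei–Gojobori (1986) mutational-opportunity
site counts (`ng86_site_counts`): each codon position contributes the
fraction of its three possible substitutions that are synonymous, weights
of 1/3 each; totals conserve sequence length exactly, changes to or from
stop codons count as nonsynonymous, and ambiguous codons are skipped and
counted. A ratio with $n_{syn}=0$ is reported as undefined, never
infinity; ratios below 1 are read as purifying selection (the ratio
cannot be negative).

## Window classification and hotspots

Each window gets a gene-overlap fraction (against gene spans, not CDS —
empty-window and hotspot descriptions in this literature speak of genes,
and CDS-only overlap would understate transcribed context) and a gap
fraction (against maximal N runs in the reference). Labels partition the
grid: GAP when the gap fraction is at least 0.5 (a configurable
threshold; 0.5 makes the label mean "mostly gap"), otherwise INTERGENIC
when no gene overlaps, otherwise GENIC. Because the CDS/genic distinction
is genuinely ambiguous in chromosome-scale summaries, region-level
variant density (`region_density`) is computed against merged CDS
intervals separately, so both readings are available.

Hotspots are windows whose SNP or InDel count *strictly* exceeds the
threshold (defaults 10,000 SNPs, 2,000 InDels per 100-kb window).
Truncated final windows are excluded from hotspot flagging — a short
window cannot be compared against a full-window threshold — but
participate in the density uniformity test with a length-scaled
expectation ($E_i = \text{total} \cdot w_i/\sum w$).

## The statistical test battery

The four tests are implemented from their defining formulas rather than
wrapped, because their exact form (tie handling, continuity correction,
normal approximation) is part of the package's contract; base R's
implementations serve as independent cross-checks in the test suite, and
the two agree to numerical precision.

- χ² goodness of fit: $\sum (O_i-E_i)^2/E_i$ on $k-1$ df; all expected
  counts must be positive.
- Kruskal–Wallis: $H = \frac{12}{N(N+1)}\sum R_i^2/n_i - 3(N+1)$ with
  midranks; the standard tie correction divides by
  $1-\sum(t^3-t)/(N^3-N)$ and can be switched off to evaluate the
  uncorrected textbook formula (windowed statistics contain many ties, so
  the correction is on by default).
- Mann–Whitney U: $U = R_1 - n(n+1)/2$; two-sided p from the large-sample
  normal approximation $U \sim N(nm/2,\; nm(N+1)/12)$ with tie-corrected
  variance and a continuity correction. An exact mode (no ties, intended
  for $nm \le 400$) uses the exact Mann–Whitney distribution as a
  small-sample cross-check.
- Shapiro–Wilk: $W = (\sum a_i x_{(i)})^2/\sum(x_i-\bar x)^2$ with
  coefficients and p-value from the Royston (1995) approximation — the
  computable form of the classical tabulated coefficients, and the same
  algorithm base R uses.

Class comparisons run Kruskal–Wallis across the classes present, then all
pairwise Mann–Whitney tests with Bonferroni correction. The family size
is the number of pairwise comparisons actually run (3 when all of
autosome/X/Y are present), not a global count across metrics: each metric
answers its own question and is corrected within it.

Calibration is tested empirically: at 5,000 null replicates each, the
three location/GOF tests' type-I error must fall inside the binomial 95%
CI of α = 0.05. The null designs use large samples (20 multinomial cells
of expected count 50; three groups of 50; two groups of 100) because the
implemented p-values are large-sample approximations; with small samples
the discreteness of the rank statistics, not the implementation, would
dominate the rejection rate.

# The synthetic-data generator

The simulator exists so that every pipeline stage can be exercised against
known truth. It is a standard neutral coalescent with infinite-sites
mutation, written directly: for $k$ active lineages the waiting time is
exponential with rate $\binom{k}{2}/\lambda(t)$, where $\lambda(t)$ is the
relative population size (time in units of $2N_0$ generations); mutations
are dropped on the tree as Poisson$(\theta/2 \times L)$ with $L$ the total
branch length, each mutation creating one biallelic site carried by the
leaves beneath it. Under constant size $E[S] = \theta a_1$, which the
suite checks against simulation at 3 standard errors.

Demography is a single size step. `EXPANSION(factor, onset)` makes the
ancestral epoch $1/\text{factor}$ of the present size: lineages that
survive past the onset coalesce quickly, trees become star-like, rare
variants accumulate and mean D goes negative. `CONTRACTION` is the mirror
image (ancestral epoch `factor` times larger, positive D). Defaults
(factor 10, onset 0.1) are chosen for unambiguous sign recovery — the
cattle-breed history behind real data is not quantified anywhere usable,
so the scenarios are labelled as sign/ordering devices, not demographic
estimates.

Scenario defaults encode the study conditions the package targets:

- **Effective-size scaling** autosome : X : Y = 1 : 3/4 : 1/4, the
  equal-sex-ratio expectation, applied to the per-window θ.
- **Hemizygous Y**: Y windows are simulated as haploid samples from the
  males only; in the VCF, male genotypes on Y are haploid (`0`/`1`) and
  females are missing (`.`), so AN on Y equals the number of males.
  X is emitted diploid for all samples — male X hemizygosity affects the
  sample size bookkeeping, not the estimator code paths, and the Y
  already exercises the haploid path; this is the one deliberate
  simplification of the sex-chromosome model.
- **Autosomal θ = 100 per 100-kb window** (π ≈ 10⁻³/bp), a realistic
  magnitude for a diverse multi-breed cattle panel; 10 diploid samples,
  5 male.
- **InDels**: 13.7% of emitted variants, with lengths
  $1+\text{Geometric}(p=0.35)$, giving modal length 1 bp and median 2 bp
  — the reported shape of real InDel length distributions — without
  attempting to fit the long tail.
- **Annotation emission**: variants in planted CDS get coding terms
  (missense : synonymous = 2 : 1), intron/upstream/downstream/intergenic
  assigned by position with 5-kb flanks; SIFT scores are drawn uniform
  above 0.05 for tolerated calls and Beta-skewed low for deleterious
  ones. These are structurally valid, not biologically calibrated: they
  exist so the summary and test machinery has correctly shaped input.
- **Gaps**: planted N runs (default 150 kb total on Y, echoing the
  heavily gapped state of real Y assemblies) that `detect_gap_runs` must
  recover exactly.

Seeds are mandatory and all randomness flows from them; the same scenario
writes byte-identical FASTA/GFF3/VCF/truth files, which the suite checks
by checksum. The VCF is written as plain VCF v4.2 text with AN/AC INFO
recomputed from the emitted genotypes, so the reader's AN/AC
reconstruction can be validated against the writer's.

**What passing tests do and do not show.** The generator has no
recombination within windows (every window is one tree, so windowed
statistics have realistic means but larger between-window variance than
real data), no linked selection, no population structure, no genotyping
error or depth-dependent missingness, and independent windows. Recovery
of the diversity ordering and D signs therefore demonstrates that the
estimators and tests are computed correctly and respond to effective-size
and demographic signals in the right direction — not that the pipeline
would be robust to artefacts of real sequencing data.

# Problem sizes and numerical choices

The shipped checks run at desk scale, chosen to keep the full suite in a
few minutes while leaving comfortable statistical margins: simulator
calibration at n = 20, θ = 5 over 500 windows (the mean of Tajima's D is
required within ±0.15 of 0; note D has a known small negative bias of
roughly −0.07 at these settings, so the band is not centred on the
estimator's true expectation but comfortably contains it); sign checks at
200 windows per demography; the class-ordering run at 100 windows per
class and the Kruskal–Wallis power estimate over 100 seeded runs of 30
windows per class; test calibration at 5,000 replicates. The end-to-end
pipeline example uses three 1-Mb chromosomes.

Numerical conventions, in one place: undefined statistics are `NA`, never
0 or ∞; all report doubles are written with 17 significant digits so TSVs
round-trip bit-exactly; multiallelic sites count once for density and
per-alt for diversity, and mixed SNP/InDel multiallelics contribute to
both class counts (the least lossy reading); InDels are assigned to
windows by their anchor POS; the SIFT deleterious boundary is inclusive
at 0.05; symbolic alleles, AN < 2 sites and out-of-range SIFT scores are
rejected with counters surfaced in the run manifest, because silently
dropped records are the classic pipeline bug.

# Known limitations

- Consequence priority is taken from the upstream annotator (one term per
  variant); the package never re-ranks overlapping consequences.
- `per_site` Ka/Ks requires the user to supply CDS sequence for the site
  counts; the pipeline default is the count ratio.
- The uniformity χ² assumes independent windows; with strong
  autocorrelation (real recombination landscapes) its p-values are
  anti-conservative. It is reported per chromosome as a descriptive
  screen, as is conventional.
- The Shapiro–Wilk p-value is approximate for n = 3 (exact) through
  n ≤ 5000 (Royston); beyond that the test refuses rather than
  extrapolating.
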