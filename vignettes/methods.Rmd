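---
title: "Models and methods behind anatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind anatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anatlas)
```

anatlas implements the analytical stages of a tissue- and sex-resolved
expression atlas for *Anopheles gambiae*: detection calling from
perfect-match/mismatch (PM/MM) probe signals, moderated tests of sexually
dimorphic and gonad-enriched expression, tissue-breadth scoring,
chromosome-arm distribution tests, SNP-based selection estimates, and
cross-species expression-conservation analysis. This vignette records the
model behind each stage, the defaults and why they were chosen, and what
the synthetic-data generators do and do not emulate.

## Detection calls

For a probe set with PM/MM intensity pairs the per-pair discrimination
score is $R_i = (PM_i - MM_i)/(PM_i + MM_i)$. `detect_probe()` tests
$H_0\!: \mathrm{median}(R) = \tau_{det}$ against
$H_1\!: \mathrm{median}(R) > \tau_{det}$ with a one-sided Wilcoxon
signed-rank statistic. Defaults are the classic Affymetrix P/M/A
parameterization: $\tau_{det} = 0.015$, $\alpha_1 = 0.04$ (present),
$\alpha_2 = 0.06$ (marginal). The source data name only a signal-to-noise
criterion on PM and MM probes, so this exact test is our reconstruction;
all three constants are exposed in `read_config()`.

Numerical details: zeros ($R_i = \tau_{det}$ exactly) are dropped; ties in
$|R_i - \tau_{det}|$ take midranks; the null distribution is the exact
signed-rank distribution for up to 25 informative pairs (the statistic is
compared to its ceiling, so midrank statistics are treated conservatively)
and a tie-corrected normal approximation with continuity correction
beyond. With 11 pairs all positive, the smallest attainable p is
$2^{-11} \approx 4.9\times10^{-4}$.

Replicate consensus (`consensus_present()`) requires present calls — not
marginal — in at least `min_present = 3` replicates, and demands more
replicates than `min_present` so that "3 of 4" semantics cannot be
satisfied degenerately by 3 of 3. Gene-level detection is the logical OR
over a gene's probes: a gene is detected wherever any of its probes is.
`tissue_specific_detected()` reports genes detected in exactly one
(tissue, sex) cell.

## Sexual dimorphism and gonad enrichment

Each gene is fit with the two-group linear model on log2 intensities
(female vs male within a tissue, or gonad vs carcass within a sex). With
two groups this is the same test whether one calls it a linear model,
ANOVA, or a t-test, which is how we read the interchangeable use of those
terms in the atlas literature. Because four replicates per group make raw
variances unstable, residual variances are moderated: marginally
$s^2/s_0^2 \sim F(d, d_0)$ under a scaled inverse-chi-square prior, so the
prior degrees of freedom $d_0$ and scale $s_0^2$ are estimated from the
mean and coefficient of variation of the observed $s^2$ by method of
moments, and each gene's posterior variance is
$\tilde{s}^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ with a moderated $t$ on
$d_0 + d$ df. Setting `prior_df = 0` recovers the ordinary equal-variance
t-test exactly, which the test suite exploits, and the suite cross-checks
classifications against limma's independent implementation.

Classification applies the atlas rules: sex-biased iff
$|M| \ge 1$ (2-fold, applied to the model's effect estimate, not the raw
ratio of means) with Benjamini–Hochberg $q < 0.05$; gonad-enriched iff
$M > 2$ strictly with $q < 0.05$. The $M > 2$ threshold is read as a
log2 ratio (4-fold), distinct from the 2-fold sex-bias rule; both are
config-exposed because the convention is not pinned down by the source.
Detection filtering before fitting is the caller's responsibility: the
intended workflow restricts to probes consensus-detected in at least one
sex of the tissue.

## Tissue breadth

The tau statistic over $N$ tissues is
$\tau = \sum_i (1 - x_i/x_{max})/(N-1)$: 0 for uniform, 1 for
single-tissue expression. `tau_table()` builds profiles from per-tissue
mean log2 intensities, sexes combined as the unweighted mean of the two
sex means, probes collapsed by the per-tissue maximum, and values floored
at 0 (the formula requires non-negativity; the tau literature works on
log-scale values). Cutoffs are strict: $\tau < 0.15$ housekeeping,
$\tau > 0.85$ narrow. Whether to restrict a gene's profile to
consensus-detected tissues is a config switch (`tau_detection_filter`,
default off); with the filter on, genes detected in fewer than two
tissues cannot be scored and are tallied instead.

`top_decile_enrichment()` is the df-1 goodness-of-fit chi-square of a gene
set's observed vs expected membership in the top 10% of a tissue's
intensity ranking, without continuity correction.

## Selection from coding SNPs

Site counting follows unweighted Nei–Gojobori (1986): for each codon
position, the synonymous-site fraction is the number of the three
single-base changes preserving the amino acid divided by three, so every
position contributes exactly one site and every codon three. Changes
creating a stop codon are non-synonymous; a terminal stop codon is
excluded from counting and an internal stop is an error. SNPs are
classified synonymous iff the mutated codon translates identically.

The A/S estimate of a gene set pools counts —
$A = \sum \text{nonsyn SNPs} / \sum \text{nonsyn sites}$, likewise $S$ —
rather than averaging per-gene ratios, which is robust to genes with zero
synonymous SNPs and reproduces the genome-wide arithmetic $A/S = A \div S$
exactly. Confidence intervals resample genes (the exchangeable unit in
per-tissue gene sets) with replacement, carrying each gene's SNPs and
sites; the 95% CI is the 2.5/97.5 percentile over replicates with a
defined ratio, and the undefined fraction is reported. SNPs are supplied
in CDS space (CHROM = gene, POS = 1-based within the CDS) so that no
genome liftover is needed; multi-allelic records contribute one SNP per
alternate allele. X-vs-autosome contrasts are 2×2 chi-squares on
{syn, nonsyn} × {set1, set2} counts without continuity correction.

## Chromosome-arm tests

`arm_distribution()` is a goodness-of-fit chi-square of a gene set's arm
counts against background proportions over {X, 2R, 2L, 3R, 3L}, with
standardized residuals giving the direction per arm. The background is an
argument: the intended default is all genes passing the same detection
filter as the set, with "all annotated genes" as the alternative, since
the appropriate reference population is analysis-specific. When any
expected count drops below 1 the tail probability switches to a seeded
Monte-Carlo multinomial p-value (10,000 draws).

## Cross-species conservation

Because the two species' arrays have incomparable absolute intensities,
each gene is represented as relative abundance (RA): its linear-scale
tissue vector divided by the row total. The RA definition as
proportion-of-total is our choice (max-normalization is available for
sensitivity analysis), applied after combining sexes (mean of sex means;
the comparison species' atlas is unsexed) and collapsing probes by the
per-tissue maximum.

Co-expression clusters: agglomerative average-linkage on the distance
$1 - r$ (Pearson). The published selection rule gives thresholds (mean
similarity > 0.8, size > 50) but not a cut procedure, so we cut by
scanning merge order and emitting the *maximal* subtrees whose mean
pairwise correlation exceeds the threshold — every reported cluster
satisfies the rule and no qualifying cluster is split. Constant-profile
genes, for which Pearson is undefined, are excluded with a tally.

Cluster overlap across species maps clusters through one-to-one orthologue
pairs; for clusters of mapped sizes $m, n$ with overlap $k$ in a universe
of $N$ pairs, $p = \sum_{i \ge k} \binom{m}{i}\binom{N-m}{n-i}/\binom{N}{n}$,
BH-corrected over all cluster pairs with bands at $q < 0.05$ and
$q < 0.01$. The universe is the set of one-to-one pairs present in both
species' clustering inputs, a choice we log since it is not dictated by
the source.

Tissue dendrograms use Euclidean distance with average linkage; rows are
pre-sorted by label so ties break deterministically. Bootstrap support
resamples feature columns (genes) with replacement, rebuilds the tree and
counts, per internal branch, the fraction of replicate trees containing
the same leaf set (topology only, ignoring branch lengths); the root is
reported as NA since it is trivially present. Family origin follows
strict precedence on outgroup membership — any *C. elegans* member makes
the family Metazoan, else honeybee → Hymenoptera, else beetle →
Coleoptera, else Diptera — and a family is single-copy iff it has exactly
one *Anopheles* member.

## Synthetic data: what it emulates

`simulate_atlas()` emulates a seven-tissue, two-sex, four-replicate
dissection atlas. Baseline log2 expression is lognormal (mean 6, sd 1.5 on
the log2 scale, truncated below at 2 so expressed genes clear the
detection floor) — arbitrary but fixed values giving a realistic dynamic
range. Planted classes are mutually exclusive: dimorphic genes carry a +2
log2 effect for one sex in one tissue; narrow genes are expressed in
exactly one (tissue, sex) cell; housekeeping genes are flat; the remaining
broad genes get a +3 log2 preference in one tissue, which keeps their tau
in the intermediate band. Silent cells sit at log2 = 0, the detection
floor, so single-tissue genes score exactly $\tau = 1$ at zero noise and
all planted classes are recovered exactly in the zero-noise limit — the
property the invariant tests rely on. PM/MM signals add a linear-scale
signal to a constant background with multiplicative log-normal noise;
silent cells have PM distributed symmetrically around MM. The `gonad`
tissue stands for ovary in females and testis in males, mirroring the
dissection design without doubling the panel.

`simulate_orthologs()` plants conserved co-expression clusters as shared
peaked archetypes: within-cluster noise is calibrated as
$\sigma_e = \sigma_a\sqrt{1/r - 1}$ so realized mean pairwise correlation
lands near the target $r = 0.9$, and the planted peak tissue is enforced
exactly (so zero divergence implies shared argmax in both species).
Background pairs get near-flat archetypes — broadly expressed genes —
whose correlation with any peaked cluster stays near zero. Diverged pairs
receive an independent profile in the second species. Family tables plant
outgroup memberships for origin labels and 2–4-copy *Anopheles*
expansions.

`simulate_snps()` draws CDS of 100–500 random sense codons (terminal stop
appended). Every possible single-base change is placed as a SNP
independently with probability $\mu_S/3$ if synonymous and
$\mu_S \cdot (A/S)_{target}/3$ if non-synonymous, making the expected
per-site rates $S = \mu_S$ and $A = \mu_S (A/S)_{target}$ — the planted
ratio is recovered in expectation by construction, with binomial sampling
noise of about $\pm 0.04$ at 500 genes and $\mu_S = 0.007$.

What the generators do **not** emulate: probe sequence affinity biases,
array spatial artifacts, correlated noise between replicates,
bloodmeal time-course dynamics (pooled into a single tissue sample),
overlapping gene classes (a real dimorphic gene can also be narrow), and
real linkage between chromosomal position and expression class. Passing
tests therefore demonstrate correctness of the statistical machinery
under its stated model, not robustness to those real-data complications.

## Problem sizes and numerical choices

The test and acceptance workloads use deliberately desk-scale designs:
atlases of 500–2,000 genes, selection regimes of 500 genes with
$\mu_S = 0.007$ and 1,000 bootstrap replicates, cluster recovery with
three 60-gene blocks over 380 pairs, 5,000 silent probe sets for
detection calibration, 100-seed power runs for the arm test, and B = 200
for dendrogram supports (scaled down from the production default of
10,000, which remains the `bootstrap_B` config default). Tolerances
follow the quantity: exact assertions for closed forms and deterministic
arithmetic ($10^{-12}$ for enumeration cross-checks), and planted-truth
bands for stochastic recoveries (±0.1 on A/S, ≥95% sensitivity / ≤10%
FDR on sex bias, ≥90/100 CI coverage).

Degenerate inputs are contracts, not surprises: all-zero tau profiles,
sets with no synonymous SNPs (ratio flagged undefined rather than
numeric), bootstrap replicates with undefined ratios (dropped and
tallied), constant gene profiles (excluded), expected counts below 1
(Monte-Carlo fallback), and zero-variance genes without moderation
information (flagged, p = NA, excluded from BH).

## Known limitations

The detection test is a reconstruction of a named-but-unspecified
signal-to-noise procedure; with heavy ties its exact-distribution p-values
are conservative approximations. The method-of-moments variance prior is
simpler than limma's profiled F-fit and can differ in small ways on real
data. Tau is computed on log-scale means by default; on linear intensities
(the config alternative) breadth classes shift towards narrow. The cluster
cut rule and the hypergeometric universe are principled choices among
several defensible ones, and cluster counts are sensitive to the
similarity/size thresholds, as threshold sensitivity is inherent to the
selection rule. A/S here is a polymorphism ratio: it is not comparable to
divergence-based dN/dS without the usual caveats about segregating
deleterious variation.
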