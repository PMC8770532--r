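---
title: "Methods: glucose-specific responsive genes and route inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glucose-specific responsive genes and route inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsrpipe)
```

## The experimental design and its data model

The package analyzes a reciprocal medium-shift design for mixotrophic
algal cultures: cells adapted to low (1.25 g/L) or high (5 g/L)
glucose supplementation (`LL`, `HH`) and cells sampled 36 h after a
shift in either direction (`L2H`, `H2L`), each in triplicate. Each
condition carries a *target level* — the glucose level the
transcriptome is responding to — which is the post-shift level for
shifted cultures (`condition_info()`). The rationale of the design is
that a genuinely glucose-responsive gene must react to both shift
directions with opposite signs, which separates it from transient
shift responders and from growth-rate covariates that move the same
way after any perturbation.

Inputs are a gene × sample matrix of non-negative integer read counts
with per-sample condition metadata (`count_matrix()`), a gene
annotation table carrying EC numbers and isoform groups, a pathway map
in GMT dialect, and a compounds × samples metabolite intensity table
for the two steady states. The pipeline deliberately starts at the
count matrix: read mapping and quantification are upstream concerns
with mature tooling of their own.

## Differential expression

**Normalization.** Abundances are transcripts per million:
$\mathrm{TPM}_g = 10^6 (c_g/L_g) / \sum_j (c_j/L_j)$ with effective
lengths $L$ defaulting to 1,000 nt when unknown, which makes TPM
proportional to counts. No between-sample scaling beyond the TPM
denominator (and library-size factors in the test) is applied; TMM/RLE
style composition corrections are out of scope and would matter only
with much larger asymmetric regulation than the designs targeted here.

**Test.** Counts are modelled NB with a single common dispersion
$\phi$ (variance $\mu + \phi\mu^2$), estimated by method of moments on
library-size-scaled counts — per gene
$\hat\phi_g = \max(0, (s^2 - \bar m)/\bar m^2)$ within conditions,
averaged over the two conditions, with the common value the median
over genes with scaled mean ≥ 5 (low counts destabilize the moment
estimate; the suite verifies recovery of $\phi = 0$ and $\phi = 0.1$
truths). The two-group comparison is a conditional exact test: counts
are scaled to a common library size, summed within group (a group of
$n$ replicates has an NB total with size $n/\phi$), and the group-A
total is tested against its conditional distribution given the grand
total. The two-sided p-value sums the probabilities of all outcomes no
more probable than the observed one, ties included — stated precisely
so that an enumeration oracle can check it. At $\phi = 0$ the
conditional distribution is exactly binomial, which the test suite
exploits: one hundred small seeded cases are compared against a direct
enumeration at $10^{-12}$.

**Calls.** A gene is `significant_up`/`significant_down` at fold > 4
on pseudocounted mean TPM and BH q < 0.01, `moderate_up`/`moderate_down`
at fold > 1.2, else `unchanged`. The fold threshold applies to the
mean-TPM ratio (the convention is configurable; count-ratio and
TPM-ratio differ only through effective lengths). The pseudocount (0.5
TPM on both means) prevents infinite ratios at zero counts at the cost
of shrinking fold-changes of weakly expressed genes — a deliberate,
documented bias (see *Power* below).

**Summative (isoform-group) calls.** Enzymes with several isoforms are
additionally tested as one unit: member counts are summed per sample
for the p-value and member TPMs are summed for the fold-change, with
the laxer thresholds fold > 2, raw p < 0.05. The abundances come from
the full-matrix TPM, not from a re-normalized grouped matrix, which
would erase relative abundance. A group is flagged *discordant* when
the summative direction opposes the majority direction of its
individually significant isoforms — the situation where one abundant
isoform masks several regulated ones, which is exactly why the
metabolite evidence is consulted in route inference.

## GSR identification

The common set is every gene significant in both shift comparisons.
Classification is by sign: `positive_gsr` requires log2FC(L2H/LL) > 0
and log2FC(H2L/HH) < 0; `negative_gsr` the mirror; same-signed
responses are `non_monotonic`. One further rule resolves a genuinely
open design point: a common gene that is *also* significant in the
steady-state HH vs LL contrast must agree in sign with its L2H/LL
response, else it is demoted to `non_monotonic`. This operationalizes
"monotonic with the glucose level" purely through signs, without
inventing magnitude comparisons the design does not support. Ranking
of top up/down GSR genes uses |log2FC(HH/LL)| — the steady-state
contrast — with lexicographic gene-id tie-break for determinism.

## The two pathway statistics

**Enrichment.** For a pathway with $K$ members in a transcriptome of
$N$ genes, $k$ of which fall in a subset of $n$ genes, the package
reports $\log_2(kN/(Kn))$ and the exact binomial upper tail
$P(X \ge k)$, $X \sim \mathrm{Binomial}(n, K/N)$ — subset membership
as the trial, pathway membership as the success. Among the possible
binomial conventions this is the one that reproduces the reference
enrichment table (all five fold-enrichments to 2 decimals and all five
p-values to ≤ 3%), so it is fixed. The tail is computed by the stable
distribution routine, never a normal or Poisson approximation; a
rational-arithmetic enumeration oracle checks it across a parameter
grid. No multiple-testing correction is applied to the primary
statistic (a BH column is emitted alongside). Pathways with zero
overlap report p = 1 and an undefined fold-enrichment.

**Direction consistency.** For a route in which $M$ of $N$ enzymes
move in the same direction, the success probability of a single enzyme
is taken as $2^{-M}$ and the p-value is $P(X \ge M)$ for
$X \sim \mathrm{Binomial}(N, 2^{-M})$. With $M = N$ this collapses to
$2^{-M^2}$. The statistic is used uniformly as an upper tail; the one
reference value it cannot reproduce that way (a 7-of-8 case printed as
1.5E-14 where the upper tail gives 1.41e-14) is accepted as a rounding
inconsistency at the source rather than a reason to special-case the
point probability. Values printed as "< 2.2e-16" are display floors,
not targets.

## Metabolome processing

Single-ion intensities pass an RSD filter (removal above 30%; the
replicate set used — biological or QC injections — is a parameter,
defaulting to all samples) and median scaling, in which each sample is
scaled so its median intensity equals the grand median. Median scaling
stands in for injection-order LOESS drift correction, which requires a
QC schedule and injection order the data model does not carry; the
normalizer is pluggable. Identification support is limited to the mass
filter: a candidate matches iff
$10^6|m_{obs}-m_{theo}|/m_{theo} < 10$ ppm, strictly. Differential
compounds use Welch tests on log2 intensities (the unspecified "t
test" choice; log-scale variance is closer to homoscedastic for
multiplicative noise) at fold > 4, p < 0.01, where the fold is the
ratio of geometric means. A PCA score report is provided as a
replicate-agreement QC; discriminant methods (PLS-DA/VIP) are out of
scope.

## Route integration

The candidate glucose-assimilation routes — EMP upper, ED, OPP, EMP
lower, plus starch biosynthesis — are hard-coded graphs of EC-numbered
enzyme nodes and compound nodes. Three ED enzymes are retained as
nodes flagged absent from the transcriptome and never count toward
$N$; the two glucose-6-phosphate entry enzymes shared between ED and
OPP are flagged `shared` on the OPP graph and likewise excluded from
the OPP count, so the OPP statistic covers its six proper enzymes.
Enzyme nodes are graded from summative records keyed by EC
(significant / moderate / unchanged / missing), metabolite nodes from
DEC records with the compound thresholds. A route verdict counts
$M$ as the larger same-direction tally among graded (significant or
moderate) calls — moderate changes count, because coordinated weak
movement is exactly what the statistic is designed to aggregate — and
takes the consistency p-value on $(N, M)$. Metabolites are partitioned
into supporting and conflicting by direction agreement and are
reported, not folded into the p-value: the metabolite evidence is
qualitative corroboration, not independent trials. The preferred route
is the upregulated verdict with the smallest p below 0.05, ties broken
by larger $M$ then name; all tie-breaks are deterministic.

## The synthetic-data generator

`simulate_transcriptome()` emulates the study conditions: 9,277 genes,
4 conditions × 3 replicates, ~2 × 10⁶ reads per sample (library sizes
log-normal with CV 0.1), NB counts with dispersion 0.1. Baseline
relative expression is log-normal with sdlog 1.25, chosen once so the
median count is ≈ 100 at the default library size — a realistic bulk
RNA-seq dynamic range. Planted structure: 1.5% positive and 1.5%
negative GSR genes whose expected expression is multiplied by
$2^{\pm e}$ in the two high-target conditions (HH, L2H), with $e$
drawn from a normal with mean 3 and sd 0.5 truncated below at
log2(4) = 2 so every planted gene clears the calling threshold in
expectation; and 0.6% transient genes whose multiplier applies in both
shifted conditions, landing them in the common set with equal signs —
the material the monotonicity filter must reject. All randomness flows
from one integer seed; identical seeds give byte-identical output.

`simulate_pathway_map()` fills each member slot of an enriched pathway
from the planted-GSR pool with probability $\min(1, E f)$ ($E$ the
enrichment factor, $f$ the GSR fraction), giving the closed-form
expected overlap $\mathrm{size} \cdot \min(1, Ef)$ that the suite
checks by Monte Carlo. Defaults (50 pathways, sizes 10–90, 5 enriched,
$E = 16$) bracket the sizes and strengths of the reference enrichment
table. `simulate_metabolome()` plants a differential fraction of 18%
among 409 compounds at 8-fold with log-normal noise (sdlog 0.3), m/z
uniform over the 50–1,200 Da scan range.

What the generator does *not* emulate: per-comparison-specific DEGs
(genes responding to only one shift), batch or injection-order drift,
isoform structure in the annotation, count outliers, or gene-specific
dispersion. Consequently the realized per-shift DEG fraction is the
planted ~3.6%, not the ~8–9% seen in real shift experiments where
transient single-shift responders dominate; recovery tests therefore
say nothing about the false-positive burden such genes would add to
the *individual* DEG lists (they cannot enter the GSR set, whose
intersection-plus-sign filter is the point of the design).

## Power and known limitations

With 3 replicates and dispersion 0.1 the log2 fold-change estimate of
a typical gene has standard deviation ≈ 0.38, so a planted effect near
the 4-fold bound is estimated above it in only about half of the
draws, and GSR membership requires clearing the bound in two
independent comparisons. Integrating over the truncated effect
distribution gives an expected GSR sensitivity of roughly 88–89% at
the default settings — the per-comparison sensitivity is ~93–95% —
with essentially zero false GSR calls (the intersection makes the
empirical FDR collapse). Raising sensitivity further would require
more replicates, larger planted effects, or relaxing the fold
threshold, none of which are the analysis conditions this package
models; the recovery test documents the achieved operating point
rather than an idealized one.

Other limitations, by construction: a single common dispersion (no
tagwise shrinkage, no GLM designs); total-count size factors; the
monotonicity rule is sign-based only; route graphs are fixed rather
than retrieved from a pathway database; metabolite identification
starts from caller-supplied candidate masses. The test suite runs the
full pipeline at the study scale (9,277 genes) once, and exercises all
other properties on matrices of 150–3,000 genes and metabolomes of
40–409 compounds, which keeps the default check fast while covering
the same code paths.
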