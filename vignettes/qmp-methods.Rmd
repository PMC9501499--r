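---
title: "Quantitative microbiome profiling and compositional artifacts: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative microbiome profiling and compositional artifacts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmpguilds)
```

## The problem

Amplicon sequencing of the 16S rRNA gene yields *relative* taxon
abundances: read fractions that must sum to one. When the total
microbial load of a gut compartment collapses — as it does when mice
are switched from a chow diet (CD) to a fiber-free diet (FFD) — any
taxon whose absolute population merely stays constant will appear to
*bloom* on the relative scale. Mucus-degrading genera such as
*Akkermansia* are the canonical example: relative profiles suggest the
fiber-deprived gut selects for mucus degraders, while flow-cytometry-
anchored absolute profiles show their populations unchanged and
everything else shrinking.

This package implements quantitative microbiome profiling (QMP) and the
surrounding analysis stages, plus a synthetic-study generator with
known ground truth so the whole chain is testable at desk scale without
any sequencing data.

## The QMP model

For sample $i$ with read counts $r_{ij}$ and 16S gene copy numbers
$c_j$, the copy-number-corrected relative abundance is

$$\tilde p_{ij} = \frac{r_{ij}/c_j}{\sum_k r_{ik}/c_k},$$

invariant to a global rescaling of the $c_j$. With the flow-cytometry
total cell density $D_i$ (cells per gram of luminal content, the mean
of a triplicate) and the content wet weight $w_i$ (grams),

$$A_{ij} = \tilde p_{ij}\, D_i \quad (\text{cells g}^{-1}), \qquad
L_{ij} = A_{ij}\, w_i \quad (\text{cells per compartment}),$$

and the sample load is $\sum_j L_{ij} = D_i w_i$ exactly — an algebraic
identity the tests assert. Feces samples carry no content weight, so
per-compartment load is undefined for them and the functions refuse to
compute it. Zero-read taxa get absolute abundance 0; no pseudocount is
applied at this stage, so detection limits stay explicit.

Wet weight (not dry) defines the compartment content mass, matching how
luminal contents are weighed at dissection.

## Differential abundance and artifact flags

Per terminal compartment (small intestine, cecum, colon; day 7), the
top 50 genera by mean absolute abundance (diets pooled, ties broken
lexicographically) are tested on *both* scales:

$$\mathrm{L2FC} = \log_2\frac{\overline{x}_{\mathrm{FFD}} + pc}
{\overline{x}_{\mathrm{CD}} + pc},$$

with the pseudocount $pc$ defaulting to the smallest non-zero value of
the compartment's table on that scale — scale-appropriate both for
loads ($\sim 10^9$) and fractions ($\sim 10^{-4}$), and configurable.
Significance uses Welch's t-test (the classical "t-test" leaves the
variance assumption open; Student's is available) with
Benjamini–Hochberg correction across the 50 genera within each
compartment and scale (Bonferroni optional); the choice is recorded in
the report's metadata.

A taxon significant on the relative scale with a positive fold change
but not significant on the absolute scale is flagged
`relative_only_increase` — the compositional artifact. If a taxon's
absolute distribution is unchanged while total load shrinks by a factor
$\rho$, its expected relative L2FC is $-\log_2\rho$ (2.32 at
$\rho = 0.2$) at a true absolute L2FC of 0; the acceptance tests verify
both, and that the flag fires in $\ge 90\%$ of replicate studies.

## Guild clustering and concordance

Co-abundance guilds are found per compartment: Spearman correlations
$\rho_{jk}$ between taxon profiles across all samples (diets pooled),
distance $1 - \rho_{jk}$, Ward linkage (`hclust` method `ward.D2`; the
variant is recorded in the result), and the cluster number $k \in 2..8$
maximizing the mean silhouette width. Ranking agreement among taxa is
quantified by Kendall's $W$ with tie correction and a $\chi^2$
approximation, $\chi^2 = m(n-1)W$ on $n-1$ degrees of freedom. The
implementation is cross-checked in the tests against
`vegan::kendall.global` and the direct rank-sum formula. Per-cluster
total abundances are compared between diets by t-test, reproducing the
study design's expected outcome: two clusters per compartment, the
dominant one collapsing under FFD, the degrader-containing one
unaffected.

## Diversity

Alpha diversity (observed richness, Shannon with natural log,
Gini–Simpson $1-\sum p^2$ — the bounded form usually plotted; "Simpson
index" alone is ambiguous, so the choice is recorded in the run
manifest) is computed on counts rarefied to 1763 reads, after dropping
libraries under 1000 reads. Rarefaction draws without replacement, so
rarefied counts are hypergeometric; a property test checks the
expectation $d\,p_j$ to three standard errors.

Beta diversity uses Bray–Curtis on *unrarefied* copy-number-corrected
relative abundances (rarefying before Bray–Curtis is a legitimate
alternative; the choice is logged). PCoA is the Gower-centered
eigen-decomposition (via `ape::pcoa`). PERMANOVA is implemented
in-package in the trace form: with the centered matrix
$G = C(-\tfrac12 D^2)C$ and hat matrices $H$ of the sequentially
nested designs, each term's sum of squares is
$\mathrm{tr}(H_kG) - \mathrm{tr}(H_{k-1}G)$ and
$p = (\#\{F^* \ge F\} + 1)/(n_{\mathrm{perm}} + 1)$ over raw label
permutations (999 by default; a permutation matrix can be supplied for
exact tests). Observed $F$, $R^2$ and SS agree with `vegan::adonis2`
to $10^{-10}$ in the tests; p-values are checked against exhaustive
enumeration on six samples. PERMANOVA defaults to relative abundances;
absolute is exposed because the two answer different questions.

## Tracer flux and expression

Mucus secretion is probed with intravenous ${}^{13}$C-threonine. The
atom fraction excess is
$\mathrm{AFE} = \max(0, a_{\mathrm{sample}} - a_{\mathrm{baseline}})/100$,
with the baseline taken from unlabeled ${}^{12}$C-control animals of the
same compartment when present and the natural-abundance constant 1.07%
otherwise. Secreted carbon flux per compartment is

$$\Phi = \mathrm{AFE} \times \frac{\%C}{100} \times m_{\mathrm{dry}}
\quad (\text{mg excess }{}^{13}\text{C}),$$

i.e. the excess-${}^{13}$C reading multiplied by total carbon content
and the dry mass of the compartment contents. "Amount of ${}^{13}$C"
is read as the *excess* atom fraction: the unlabeled controls only make
sense under this reading. ${}^{15}$N is carried through reports but not
used in the flux. C:N is the mass ratio $\%C/\%N$; water content is
$100(w_{\mathrm{wet}} - w_{\mathrm{dry}})/w_{\mathrm{wet}}$.

qPCR expression uses the $2^{-\Delta\Delta C_T}$ method against the
36B4 housekeeping gene; the estimator is invariant to plate offsets,
and a simulation shows it recovers a true four-fold reduction at
$\sigma_{C_T} = 0.2$.

## The ANOVA workflow

Host and microbiome endpoints share one workflow: fit
`value ~ A * B`, Shapiro–Wilk on the residuals at $\alpha = 0.05$; if
non-normal, square-root transform once and refit (negative values are
an error advising an offset). Levene's test (median-centered, the
Brown–Forsythe variant, for robustness) documents homoscedasticity.
Balanced designs use sequential sums of squares (identical to the
classical decomposition, which the tests verify by hand); unbalanced
designs use Type II, since the real cohort is 18 vs 20 mice. $R^2$ is
reported per factor as that factor's share of the *total* SS, matching
the "ANOVA, $R^2 = …$" reporting style; partial $\eta^2$ would
condition differently and is deliberately not the default. Significant
factors trigger pairwise Student t-tests, Bonferroni-adjusted over the
comparisons of that factor.

## The synthetic generator

`default_scenario()` (shipped as `inst/extdata/cecum_collapse.yaml`)
encodes the study conditions: 10 mice per diet, fecal pellets at days
0/2/7 plus terminal small-intestine/cecum/colon samples at day 7, 50
genera in three guilds — 31 fiber-responsive taxa at FFD multiplier
0.1, one mucus degrader at 1.0, and 18 neutral taxa whose multiplier is
solved so the total FFD/CD load ratio is exactly
`diet_load_ratio = 0.2`. Within a guild, baseline fractions follow a
geometric rank-abundance series (decay 0.85).

The observation model, per sample:

* diet multipliers act on **per-compartment loads** (population
  sizes); terminal per-gram densities absorb the FFD wet-weight
  reduction (less content mass, same cells, higher density) — this is
  what keeps a "constant-load" taxon constant in the quantity the
  analysis actually tests;
* a lognormal host effect shared by all taxa of a mouse
  ($\sigma_{\log} = 0.3$) creates inter-host variability, plus
  per-taxon lognormal noise ($\sigma_{\log} = 0.2$); all lognormals are
  mean-one;
* library sizes are negative binomial (mean 50,000, dispersion 10) so
  the 1000-read filter has work to do; reads are multinomial with
  probabilities $\propto$ load $\times$ copy number, the exact forward
  model that copy-number correction inverts;
* flow-cytometry triplicates are lognormal at CV 0.1 around the true
  total density; content weights are lognormal at CV 0.1, with the dry
  fraction given independent (smaller) noise so water content varies
  within groups;
* tracer enrichments, %C and %N are per-diet, per-compartment
  constants with CV-0.1 lognormal measurement noise; one mouse per diet
  is an unlabeled ${}^{12}$C control;
* the fecal time series ramps the diet effect in as
  $m_j^{\{0, 0.5, 1\}}$ on days 0/2/7.

Noise magnitudes are stated assumptions (the real experiment publishes
none); they are surfaced in the YAML and chosen once at what a
microbiome scientist would call realistic levels. A
`noise_free_scenario()` variant zeroes every noise source and switches
to exact expected read counts, which makes the QMP chain exactly
invertible — the basis of the $10^{-6}$ inverse-consistency check.

What the generator does **not** emulate: sequencing error and chimeras,
strain-level dynamics, compartment-specific community composition
(baseline fractions are shared across compartments, so a
compartment effect in PERMANOVA is essentially absent by construction),
ecological interactions beyond the planted diet response, and any
time-series population dynamics. Passing tests therefore demonstrate
that the *analysis chain* is correct and calibrated, not that it would
be similarly powered on arbitrary real data.

## Numerical choices and degenerate inputs

* Top-50 ties break lexicographically; silhouette ties at different
  $k$ resolve to the smaller $k$ (first maximum).
* Constant taxon profiles have undefined Spearman correlations and are
  dropped from clustering with a warning; an all-constant matrix is an
  error for Kendall's $W$.
* Empty samples are errors for diversity indices; zero-library samples
  are representable in a study but flagged.
* A sample's rarefaction depth exceeding its library size is an error
  directing the caller to filter first, not a silent skip.
* Missing copy numbers fall back to a configurable default (1.0 = no
  correction) with a warning, or are an error when no default is given.
* PERMANOVA with duplicated samples ties permutations that preserve
  the group partition, so the attainable minimum p-value is larger
  than $1/(n_{\mathrm{perm}}+1)$; ties count as exceedances
  (conservative).
* All TSV reals are written with 17 significant digits, so disk
  round trips are exact and byte-identical reruns are testable.

## Problem sizes

The shipped analyses and tests run the default scenario (120 samples
$\times$ 50 genera, depth 50,000) in a couple of seconds per study;
calibration checks use 500–1000 replicates of small designs, and
exact-permutation oracles use six samples. These sizes give stable
Monte-Carlo estimates at interactive runtimes and are recorded in each
script.
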