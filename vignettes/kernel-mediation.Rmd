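---
title: "Kernel-based high-dimensional mediation: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel-based high-dimensional mediation: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kermed)
```

## The problem

In a genetically diverse population measured at three levels — genome
(founder-haplotype dosages), transcriptome (expression in one or more
tissues), and phenome (clinical traits) — we want the single axis of
transcriptional variation that *mediates* genetic effects on the traits.
The causal hypothesis is the chain G → T → P with no direct G → P edge:
once the mediating component of the transcriptome is accounted for, the
genome should carry no further information about the phenome. kermed fits
this model as a constrained projection problem on kernels and provides the
surrounding machinery: permutation calibration, local/distal heritability
partitioning, and transfer of the learned transcript weights to
independent populations.

## Model and fitting procedure

Each modality is first reduced to an individual-by-individual similarity
matrix. Features (transcripts, traits) are rank-inverse-normalized
(`rank_inverse_normal()`), optionally residualized on covariates, and
combined into a linear kernel $K = ZZ'/m$ on column-standardized features,
double-centered and trace-normalized to $\mathrm{tr}(K) = n$
(`linear_kernel()`, `genome_kernel()`). The linear family is used for all
three modalities: the fit below is a constrained relative of canonical
correlation analysis, which is exact for linear kernels, and linear
kernels make loadings well-defined back-projections onto measured
variables. Trace normalization puts the three modalities on one scale so
the path coefficient is unit-free.

`fit_hdma()` represents each kernel by its leading eigenvectors and
searches for unit-variance composite scores $G_C$, $T_C$, $P_C$ — one per
modality, each constrained to its kernel's top-rank eigenspace —
maximizing the mediated path
$\rho(G_C, T_C)\,\rho(T_C, P_C)$. The alternation has two exact steps:

1. given $t$, the genome and phenome scores are the orthogonal projections
   of $t$ into their eigenspaces (each maximizes its correlation with $t$);
2. given $g$ and $p$, the transcriptome score maximizing
   $\rho(g,t)\rho(t,p)$ over its eigenspace has a closed form: writing
   $t = U_T b$, the objective is $(a'b)(c'b)/b'b$ with $a, c$ the
   coefficient vectors of $g$ and $p$, and the maximizer is the normalized
   angle bisector of $a$ and $c$.

Both steps are monotone in the objective, so the alternation converges; we
iterate to a relative path-coefficient change below `tol` (default 1e-8,
`max_iter` 500). We use the closed-form bisector rather than a gradient
step because it is exact, parameter-free, and deterministic. Because the
eigenvector bases are orthonormal, the entire alternation runs in
eigen-coefficient space; the $n$-vectors are reconstructed once at
convergence.

At convergence the perfect-mediation constraint is imposed *exactly*: the
component of $g$ orthogonal to $t$ is regressed out of $p$, after which
$\rho(G_C, P_C \mid T_C) = 0$ to floating-point roundoff. The constraint
is a hard projection, not a penalty: the returned fit always satisfies the
stated causal hypothesis, and the price paid in $\rho(T_C, P_C)$ is
visible in the reported partials.

**Rank.** The default rank per kernel is the smallest number of
eigencomponents capturing 95% of the kernel trace, capped at $n/2$
(`choose_rank()`). Unrestricted maximization of correlations between
high-dimensional score spaces is trivially prone to overfitting; the cap
keeps the search space well below the sample size. Overfitting that
remains is exactly what the permutation test measures — in permuted data
the null path coefficient is itself large, and inference rests on the
observed value's position in that null, not on its distance from zero.

**Signs.** A mediation triple is sign-ambiguous. We flip scores so that
$\rho(T_C, P_C) \ge 0$ and $\rho(G_C, T_C) \ge 0$, and — when a trait
matrix is supplied as the anchor — so that the trait with the largest
absolute loading has a positive loading. With body-weight-like traits
dominating, high composite phenome scores then read as "more disease",
which is the intended orientation of a metabolic disease index.

**Loadings.** The loading of a transcript or trait is its Pearson
correlation with the composite score (`variable_loadings()`), bounded by 1
and comparable across features; `z_loading` standardizes within tissue so
selection rules like "beyond 2.5 SD" are tissue-fair. Constant features
get loading 0 and a flag. `marker_set_test()` compares the mean loading of
a feature set (e.g. cell-type marker genes) against means of random
same-size sets, two-sided, with the add-one rule.

## Permutation null

`permutation_null_path()` permutes the individual labels of the
transcriptome only, keeping the genome-phenome pairing intact, and refits
the full model per permutation with identical settings. Feature-wise
standardization commutes with row permutation, so the permuted kernel is
exactly $PKP'$ and its eigenvectors are the row-permuted eigenvectors of
$K$; the implementation uses this identity instead of rebuilding the
kernel from the permuted matrix — an exact algebraic shortcut, not an
approximation. Each permutation derives its own RNG stream from
`seed + index`, so results are independent of execution order. The
p-value uses the add-one rule, $(1 + \#\{\text{null} \ge
\text{obs}\})/(n_{perm}+1)$, and the same constraint-projected statistic
is used for the observed and every permuted fit.

## Local and distal heritability

For a transcript at TSS $x$ on chromosome $c$, `split_kinship()` builds a
local kinship from markers on $c$ within $\pm$`window_bp` of $x$ (closed
interval; default 10 Mb — a deliberately generous cis-window for sparse
multiparent marker maps, configurable) and a distal kinship from all
remaining markers, including the rest of chromosome $c$.
`fit_two_component()` then maximizes the restricted likelihood of
$y \sim N(\mu,\ \sigma^2(h_l K_{loc} + h_d K_{dist} + (1-h_l-h_d)I))$
over the simplex. We reparameterize to $(w, h)$ with $h_l = wh$,
$h_d = (1-w)h$: for fixed $w$ one eigendecomposition of
$wK_{loc} + (1-w)K_{dist}$ makes the profile over $h$ a cheap
one-dimensional optimization, and those eigendecompositions are shared
across every transcript fit on the same kernel pair. The $w$ grid (step
0.01 by default) is refined by quadratic interpolation of the profile
likelihood, so the effective resolution is finer than the grid. Kinships
are rescaled to mean diagonal 1 and $y$ is rank-inverse-normalized, making
the estimates scale-free variance ratios. Boundary solutions
($h \approx 0$ or 1, $w \in \{0,1\}$) are flagged; kinship pairs with
off-diagonal correlation above 0.999 identify only the total, which is
then split evenly and flagged `non_identifiable`.

Trait relevance (`trait_relevance()`) is the maximum absolute correlation
of a transcript with any measured trait;
`relevance_heritability_correlation()` relates it to either heritability
component across transcripts.

## Translation to independent populations

`fit_local_models()` regresses each transcript on the eight founder
dosages at the single marker nearest its TSS; the dosages sum to 2, so the
minimum-norm least-squares solution via the Moore–Penrose pseudoinverse
absorbs the intercept collinearity. One marker (rather than a window
average) is the simplest faithful "local genotype" model on a sparse map
and is the default. `impute_expression()` applies these founder effects to
a new population's dosages — valid across populations precisely because
both carry the same founder alleles. `predict_scores()` scores new
individuals as the loading-weighted sum of per-gene standardized
expression; standardization uses the *new* population's means and SDs,
because loadings encode direction and relative importance, not absolute
expression scale, and this makes predictions invariant to per-gene affine
changes in measurement. `evaluate_prediction()` reports Pearson $r$ for
continuous outcomes and a rank-sum test for two-group designs.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates the study conditions all tests run under:

- **Genomes.** Eight-founder diploid mosaics: two independent founder-label
  Markov chains per chromosome (switch probability `recomb_prob` = 0.1
  between adjacent markers, 10 chromosomes x 20 markers 5 Mb apart),
  giving uniform founder frequencies — a Diversity-Outbred-like design.
  The validation population instead crosses fully inbred mosaic lines in
  pairs (F1s), reusing the *same* founder allele effects under a visibly
  different kinship: F1s sharing a parental line are more related than
  F1s sharing none.
- **Transcripts.** 2,000 transcripts, each with a local founder-effect
  term at its own marker and a distal term summing weak founder effects at
  50 trans-loci; components are rescaled so realized sample-variance
  shares hit their targets (background defaults 0.30 local / 0.20 distal).
- **The core module.** 50 core transcripts mediate the phenotype. They are
  predominantly distally heritable (0.05 local / 0.45 distal) and share
  one polygenic distal factor with signed membership
  $\rho_j = w_j/\max|w|$, where $w_j$ is the transcript's mediating
  weight. This correlated-module architecture is deliberate: mediating
  transcripts are expected to be co-regulated and organized into coherent
  programs, and it is what makes per-transcript loadings statistically
  recoverable — with 50 mutually independent core transcripts the
  mediation signal spreads over 50 orthogonal directions and no method
  could rank individual transcripts reliably at $n = 300$.
- **Phenotypes.** Each of 10 traits is its own positive coefficient times
  the standardized core score plus Gaussian noise (SD 1, so roughly half
  of each trait's variance is mediated). No direct genotype term enters:
  perfect mediation holds by construction.

Not emulated: realistic recombination maps or linkage disequilibrium
decay, X-chromosome dosage, dominance or epistasis, tissue-shared
expression structure beyond the core module, batch effects, or count
noise. Passing tests therefore demonstrate correctness of the machinery
and recoverability under a faithful additive multiparent design — not
robustness to everything real data contains.

## Problem sizes used in the checks

The package's property checks run at sizes chosen to be informative at
desk scale: the default study (n = 300, 2,000 transcripts, 50 core) for
fit and loading recovery; 200 null datasets (n = 100, 300 transcripts, 99
permutations each) for permutation calibration; 200 transcript draws on an
n = 400 genome for REML recovery of (0.40, 0.30); 50 replicates (n = 150,
60 transcripts) for the heritability-relevance directions; and 100
replicates (n = 200 train / 150 validation) for the measured-vs-imputed
prediction contrast, with a 30-replicate purely-local control.

## Numerical notes and edge cases

- Constant features are dropped from kernels (with a warning) and flagged
  with zero loadings; constant traits are excluded from variance-explained
  summaries.
- Eigencomponents with eigenvalues below `1e-10` (relative) are never used;
  kernels failing PSD beyond `1e-8` (relative) are rejected.
- The degenerate noise-free chain (a score exactly collinear with $t$)
  makes the partial correlation 0/0; it is reported as 0, the value every
  nearby non-degenerate configuration takes after the projection.
- All randomness flows from one master seed through `derive_seed(seed,
  offset)` (a fixed integer recurrence below $2^{31}$); identical seeds
  give bitwise-identical simulations, fits, and permutation nulls.
- The anti-parallel bisector case (projections of $g$ and $p$ exactly
  opposed in the transcriptome space) leaves $t$ unchanged for that sweep;
  it has measure zero and has not been observed in practice.

## Known limitations

- One mediated axis only: the fit extracts the leading mediation
  component, with no deflation for secondary axes, and no sparsity on
  loadings.
- The hard constraint is enforced on the phenome score; alternative
  formulations (penalizing the direct path) would trade constraint
  violation against a larger $\rho(T_C, P_C)$ and are not implemented.
- REML by profile grid is robust but not as fast as specialized AI-REML
  at biobank scale; it is intended for multiparent-population sample
  sizes (hundreds).
- Permutation refits inherit the fit's rank cap; calibration statements
  hold for the default settings under which they were checked.
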