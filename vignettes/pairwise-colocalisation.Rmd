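---
title: "Pairwise colocalisation: model, priors, and multiple causal variants"
author: "paircoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise colocalisation: model, priors, and multiple causal variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Given single-SNP summary statistics for two traits over a common region of
$n$ SNPs, we ask whether the traits share a causal variant. Under the
working assumption of *at most one causal variant per trait*, every
assignment of causal status ("configuration") falls under one of five
mutually exclusive regional hypotheses:

* $H_0$: no association with either trait;
* $H_1$ / $H_2$: association with trait 1 / trait 2 only;
* $H_3$: both traits associated, two distinct causal variants;
* $H_4$: both traits associated, one shared causal variant.

Evidence at a single SNP is summarised by the Wakefield approximate Bayes
factor. With effect estimate $\hat\beta$, its variance $V$
(`varbeta`), $z = \hat\beta/\sqrt{V}$ and a normal prior
$\mathcal{N}(0, W)$ on the true effect,

$$\log \mathrm{ABF} = \tfrac12 \log(1 - r) + \tfrac{r z^2}{2}, \qquad
  r = \frac{W}{V + W},$$

which is exactly the log ratio of the marginal likelihoods
$\mathcal{N}(\hat\beta; 0, V+W) / \mathcal{N}(\hat\beta; 0, V)$
(`wakefield_labf()` is checked against numerical quadrature of that
ratio in the test suite). Per-hypothesis Bayes factors relative to $H_0$
sum the per-SNP factors over each hypothesis' configurations
(`hypothesis_labf()`), all in log space:
$\mathrm{BF}_1 = \sum_i L_{1i}$, $\mathrm{BF}_4 = \sum_i L_{1i}L_{2i}$,
and $\mathrm{BF}_3 = \mathrm{BF}_1\mathrm{BF}_2 - \mathrm{BF}_4$.
Posteriors weight these by per-configuration priors
($1, p_1, p_2, p_1 p_2, p_{12}$) and renormalise.

When only p-values and minor allele frequencies are available, unsigned
effects are reconstructed (`reconstruct_effects()`) using
$V = \mathrm{sd}_Y^2 / (2 N f (1-f))$ for quantitative traits and
$V = 1/(2 N f (1-f) s (1-s))$ for case-control traits with case fraction
$s$. Reconstructed effects carry no sign and are refused by conditioning,
which needs signs aligned to an LD matrix.

## Numerical choices

* The $H_3$ subtraction is performed as
  $\log\mathrm{BF}_3 = a + \log(1 - e^{\,b-a})$ with
  $a = \log \mathrm{BF}_1 + \log\mathrm{BF}_2$, $b = \log\mathrm{BF}_4$;
  when $e^{\,b-a} > 0.99$ (one SNP dominating both traits) the explicit
  sum over ordered pairs $i \ne j$ is used instead, avoiding
  catastrophic cancellation.
* A single-SNP region has no $H_3$ configuration; its $H_3$ log Bayes
  factor is $-\infty$ and drops out of the normalisation.
* p-to-z conversion runs through log-space quantiles and p-values are
  floored at $10^{-300}$ with a warning; stepwise selection ranks SNPs on
  log p computed from $z$ so extreme signals never tie at the floor.
* Effect-prior standard deviations default to 0.2 trait-SD units for
  quantitative traits ($W = 0.04\,\mathrm{sd}_Y^2$) and 0.15 on the
  log-odds scale for case-control traits. These are deliberately exposed
  (`effect_prior()`) since the evidence scale depends on them.
* For a quantitative trait with unknown $\mathrm{sd}_Y$, the package
  estimates it by regressing $1/V$ through the origin on $2Nf(1-f)$
  (`estimate_sdY()`); if that fails it assumes
  $\mathrm{sd}_Y = 1$ with a warning, consistent with the simulation
  design below.

## Priors: elicitation, translation and bounds

The per-SNP parameters $p_1, p_2, p_{12}$ are hard to think about
directly. Two translations help (`marginal_priors()`,
`persnp_priors()`, `p12_from_conditional()`):

* marginal causality probabilities $q_1 = p_1 + p_{12}$,
  $q_2 = p_2 + p_{12}$, which can be anchored on observed hit rates in
  large single-trait studies (`marginal_prior_from_counts()`): roughly
  $100$–$1000$ independent hits among $\sim 2$ million common SNPs gives
  $q \in [5\times10^{-5}, 5\times10^{-4}]$, supporting the conventional
  $q \approx 10^{-4}$; and
* the conditional probability $q_{1|2}$ that a known trait-2 causal
  variant also drives trait 1, with $p_{12} = q_{1|2} \, q_2$.

`single_snp_ppa()` connects $q$ to significance testing: it returns the
posterior probability of association of a single SNP from its p-value via
$\mathrm{BF}\cdot\pi / (\mathrm{BF}\cdot\pi + 1 - \pi)$ with $\pi = q$.
(The source derivation prints $1-\pi_0$ in the denominator where the
algebra requires $1-\pi$; we implement $1-\pi$, treating the subscript as
a typo.) Note the curve is *not* exactly design-free: the Bayes factor at
fixed $z$ depends on $r = W/(V+W)$, so underpowered designs (small
case-control studies at low MAF, where $V \approx W$) give visibly
smaller posteriors. Across quantitative designs with
$N \in [2000, 10000]$ and MAF $\in [0.05, 0.5]$ the value at
$p = 5\times10^{-8}$ moves by less than 0.05, which the test suite
checks.

Per-hypothesis priors at region size $n$ (`hypothesis_priors()`) use the
linear approximation $P(H_1) = np_1$, $P(H_3) = n(n-1)p_1p_2$,
$P(H_4) = np_{12}$, accurate to $O(np)$ of the exact multinomial form
(`exact_hypothesis_priors()` is provided as a cross-check). Because
$P(H_3)$ grows quadratically in $n$, the same per-SNP priors favour $H_4$
only below the crossing size $n^* = 1 + p_{12}/(p_1p_2)$
(`h3_h4_crossing()`; 1001 SNPs at the defaults).

Admissible values of $p_{12}$ are bounded (`p12_bounds()`): chance
co-occurrence among the functional fraction $f$ of variants gives
$p_{12} > q_1 q_2 / f$, a genetic correlation $r_g$ gives
$p_{12} > |r_g|\sqrt{q_1 q_2}$ (via the count bound in
`rg_upper_bound()`), and $p_{12} < \min(q_1, q_2)$ always.

The software default is $p_{12} = 10^{-5}$. Simulation summaries
produced by `expected_posterior_table()` show that this can be liberal —
$H_3$-generated data lend some support to $H_4$ at small sample sizes,
which shrinks at $5\times10^{-6}$ — while judgement-based elicitation for
closely related trait pairs can justify larger values. We keep the
conventional default and steer users to sensitivity analysis rather than
silently changing it.

## Sensitivity analysis

Posteriors factor as $P(H_i \mid D, \pi) \propto \mathrm{BF}_i \,
P(H_i \mid \pi)$, so results can be re-expressed under any prior without
touching the Bayes factors:
$P(H_i \mid D, \pi^*) \propto P(H_i \mid D, \pi)\,
P(H_i\mid\pi^*)/P(H_i\mid\pi)$. `reweight_posteriors()` applies this
identity using the same per-configuration prior weights as the original
fit (so the $H_0$ ratio is 1 and the identity is exact to machine
precision, which the tests verify against full recomputation).
`sensitivity_grid()` scans a log-spaced grid of $p_{12}$ (default 100
points; $p_1, p_2$ held fixed, with $H_0$'s prior recomputed as the
complement at each point so the priors remain a distribution) and
evaluates a decision rule such as `"H4 > 0.5"` at every point. Rules are
parsed in a deliberately tiny arithmetic-comparison grammar over
`H0`..`H4` — no general code can run. A multi-parameter scan can be
built by calling `reweight_posteriors()` over any prior set; the default
scan varies $p_{12}$ only, matching how such analyses are usually read.

## Multiple causal variants: conditioning and masking

A single analysis effectively compares the *strongest* signal per trait,
which misses colocalisations that are secondary to an independent primary
signal. `coloc_signals()` relaxes this by discovering up to
`max_signals` independent leads per trait (`stepwise_signals()`) and
running one analysis per lead pair ($n \times m$ comparisons), in one of
two ways per trait:

* **cond** — approximate conditional estimates from summary statistics
  plus signed, allele-aligned LD (`conditional_summary()`). The centred
  cross-product matrix is rebuilt as
  $X'X_{jk} = r_{jk}\sqrt{D_jD_k}$; the per-SNP sums of squares $D_j$
  come from the exact OLS identity
  $D_j = (N-1)\mathrm{sd}_Y^2 / (V_j (N-2) + \hat\beta_j^2)$ when
  $\mathrm{sd}_Y$ is known (exact when LD is computed in the study
  sample, as the tests confirm against individual-level joint
  regression), falling back to $2Nf(1-f)$ otherwise. Conditional
  variances divide the marginal implied residual variance by the Schur
  complement, so conditioning on an uncorrelated SNP changes nothing.
  Targets or conditioning sets with $r^2 > 0.9$ to each other are
  flagged/refused rather than inverted.
* **mask** — no alignment needed: lead SNPs are found by successively
  excluding SNPs with $r^2 \ge$ `r2_threshold` to previous leads, and in
  each comparison the per-SNP Bayes factors of SNPs in LD with the
  trait's *other* leads are set to 1 (`mask_labf()`). This approximates
  conditioning when the causal variants are in linkage equilibrium, and
  the two modes may be mixed (condition in the fully-characterised
  dataset, mask in the public one). Masks are applied per trait
  independently; secondary $H_3$ conclusions under masking deserve
  caution, because a masked shared signal in LD with another lead can
  masquerade as distinct.

Defaults, and why: `r2_threshold = 0.01` (strict independence, the
threshold used to define independent eQTL signals in practice; the
masking threshold is configurable since no canonical value exists),
`p_threshold = 1e-6` (a conventional stepwise threshold, slightly looser
than genome-wide), `max_signals = 3` (the evaluated designs have at most
two causal variants per trait; one spare). If stepwise discovery finds
nothing, the trait falls back to its top SNP so a comparison is still
reported. LD may come from a reference panel, but small reference-vs-study
LD deviations can corrupt conditional estimates — one more reason masking
exists.

## The simulator

`synth_haplotype_panel()` builds a binary haplotype panel with
block-structured LD: allele frequencies drawn uniformly on (0.01, 0.5),
latent Gaussians sharing a per-block factor (loading
$\sqrt{0.9}$, blocks of 25 SNPs) and thresholded at the frequency
quantile, 1000 haplotypes by default — the scale of a one-population
reference panel. Genotypes are drawn by resampling haplotype pairs
(`sample_genotypes()`), traits follow $Y = \sum_i b_i G_i + e$,
$e \sim \mathcal{N}(0,1)$ with causal variants restricted to common SNPs
(MAF $> 5\%$) and effects drawn from
`gwas_effect_sizes` $= \{0.17, 0.33, \dots, 1.50\}$, and summaries come
from marginal OLS (`single_snp_regression()`). All randomness flows from
one explicit seed, with per-replicate seeds derived deterministically.

What the synthetic panel does *not* emulate: realistic site-frequency
spectra, LD decay with distance, near-perfect proxy SNPs (the
thresholded-Gaussian construction caps within-block genotype $r^2$ around
0.6), population structure or admixture, strand/allele-coding ambiguity,
and binary-trait liability (case-control designs enter only through the
closed-form reconstruction). Passing simulation tests therefore
demonstrate correctness of the inferential machinery under the stated
generative model, not robustness to the full messiness of real GWAS
panels; user-supplied panels can be loaded with
`read_haplotype_panel()`.

Problem sizes used by the test suite (chosen to exercise the claims at
desk scale): regions of 250 SNPs; sample sizes 1000–10000; 100
replicates per cell for the scenario table over all five generating
hypotheses; 50–60 replicates for the conditioning-recovery and
secondary-signal comparisons at $N = 5000$.

## Known limitations

* At most one causal variant per trait per comparison; more than two
  traits, or traits sharing controls, are out of scope.
* No allele harmonisation or strand flipping: signed inputs must already
  be aligned to their LD matrix (palindromic SNPs are a known hazard and
  one motivation for masking).
* Conditioning from summary statistics inherits the usual approximate
  conditional-analysis caveats under reference-panel LD.
* The linear prior approximation breaks down when $np$ approaches 1; the
  package refuses such prior/region-size combinations rather than
  renormalising silently.
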