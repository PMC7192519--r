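#' Per-SNP prior probabilities of causality
#'
#' `p1`, `p2` and `p12` are the prior probabilities that any random SNP in
#' the region is causally associated with exactly trait 1, exactly trait 2,
#' or both traits. The defaults (`1e-4`, `1e-4`, `1e-5`) are the
#' conventional software defaults; the choice of `p12` in particular
#' deserves thought and a sensitivity analysis (see [sensitivity_grid()]),
#' and simulation evidence supports more conservative values of the order
#' `5e-6` for smaller studies.
#'
#' @param p1,p2,p12 per-SNP prior probabilities, each in (0,1) with
#'   `p1 + p2 + p12 < 1`.
#' @return An object of class `prior_params`.
#' @seealso [marginal_priors()], [hypothesis_priors()], [p12_bounds()]
#' @export
prior_params <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  for (nm in c("p1", "p2", "p12"))
    if (!is_scalar_prob(get(nm)))
      stopf("'%s' must be a single probability in (0, 1)", nm)
  if (p1 + p2 + p12 >= 1)
    stopf("p1 + p2 + p12 must be < 1")
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "prior_params")
}

#' @export
print.prior_params <- function(x, ...) {
  cat(sprintf("Per-SNP priors: p1 = %g, p2 = %g, p12 = %g  (q1 = %g, q2 = %g)\n",
              x$p1, x$p2, x$p12, x$p1 + x$p12, x$p2 + x$p12))
  invisible(x)
}

#' Translate per-SNP priors to marginal per-trait priors
#'
#' The marginal events "SNP is causal for trait 1" and "... for trait 2"
#' have probabilities `q1 = p1 + p12` and `q2 = p2 + p12`. These marginal
#' quantities are the ones most readily elicited from single-trait
#' association data.
#'
#' @param p a [prior_params()] object.
#' @return Named numeric vector `c(q1, q2)`.
#' @export
marginal_priors <- function(p) {
  stopifnot(inherits(p, "prior_params"))
  c(q1 = p$p1 + p$p12, q2 = p$p2 + p$p12)
}

#' Translate marginal priors back to the per-SNP parameterisation
#'
#' Inverse of [marginal_priors()]: `p1 = q1 - p12`, `p2 = q2 - p12`.
#'
#' @param q1,q2 marginal per-SNP causality probabilities.
#' @param p12 per-SNP probability of joint causality; must satisfy
#'   `p12 < min(q1, q2)`.
#' @return A [prior_params()] object.
#' @export
persnp_priors <- function(q1, q2, p12) {
  for (nm in c("q1", "q2", "p12"))
    if (!is_scalar_prob(get(nm)))
      stopf("'%s' must be a single probability in (0, 1)", nm)
  if (p12 >= min(q1, q2))
    stopf("p12 (%g) must be below its upper bound min(q1, q2) = %g",
          p12, min(q1, q2))
  prior_params(p1 = q1 - p12, p2 = q2 - p12, p12 = p12)
}

#' Joint prior from a conditional causality probability
#'
#' `p12 = q1|2 * q2`, where `q1|2` is the probability that a SNP already
#' known to be causal for trait 2 is also causal for trait 1. Conditioning
#' on the better-understood trait (e.g. the chance that an eQTL variant
#' also affects disease) is often the easiest way to elicit `p12`.
#'
#' @param q1_given_2 conditional probability in \[0, 1\].
#' @param q2 marginal causality probability for trait 2, in (0, 1).
#' @return `p12` as a scalar.
#' @export
p12_from_conditional <- function(q1_given_2, q2) {
  if (!is.numeric(q1_given_2) || length(q1_given_2) != 1L ||
      q1_given_2 < 0 || q1_given_2 > 1)
    stopf("'q1_given_2' must be a single value in [0, 1]")
  if (!is_scalar_prob(q2)) stopf("'q2' must be a single probability in (0, 1)")
  if (q1_given_2 == 0)
    warnf("q1|2 = 0 gives p12 = 0: colocalisation is excluded a priori")
  q1_given_2 * q2
}

#' Per-hypothesis prior probabilities at a given region size
#'
#' Per-SNP priors translate into regional, per-hypothesis priors that
#' depend on the number of SNPs `n`: `P(H1) = n p1`, `P(H2) = n p2`,
#' `P(H3) = n (n-1) p1 p2`, `P(H4) = n p12`, with `P(H0)` the complement
#' (the linear-approximation form, accurate when `n p << 1`). `P(H3)`
#' scales with the square of the region size, so the same per-SNP priors
#' can favour either distinct or shared causal variants depending on `n`;
#' see [h3_h4_crossing()]. The prior odds `P(H4)/P(H1) = p12/p1` are
#' independent of `n`.
#'
#' @param n number of SNPs in the region (>= 1).
#' @param p a [prior_params()] object.
#' @return Named numeric vector `c(H0, H1, H2, H3, H4)`.
#' @seealso [exact_hypothesis_priors()] for the exact multinomial form.
#' @export
hypothesis_priors <- function(n, p) {
  stopifnot(inherits(p, "prior_params"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) stopf("'n' must be >= 1")
  h <- c(H1 = n * p$p1, H2 = n * p$p2,
         H3 = n * (n - 1) * p$p1 * p$p2, H4 = n * p$p12)
  if (sum(h) >= 1)
    stopf(paste("per-hypothesis priors sum to %.3g >= 1 at n = %d;",
                "the region is too large for these per-SNP priors"),
          sum(h), n)
  c(H0 = 1 - sum(h), h)
}

#' Exact configuration-count hypothesis priors
#'
#' The exact multinomial counterpart of [hypothesis_priors()], retaining
#' the `(1 - p1 - p2 - p12)^k` factors for the non-causal SNPs:
#' `P(H0) = p0^n`, `P(H1) = n p1 p0^(n-1)`, and so on, with
#' `p0 = 1 - p1 - p2 - p12`. Provided as a cross-check; the linear form is
#' used throughout the package and diverges from this by `O(n p)`.
#'
#' @inheritParams hypothesis_priors
#' @param renormalise if `TRUE`, rescale so the five hypothesis priors sum
#'   to 1 over the restricted (at most one causal variant per trait)
#'   configuration space.
#' @return Named numeric vector `c(H0, H1, H2, H3, H4)`.
#' @export
exact_hypothesis_priors <- function(n, p, renormalise = FALSE) {
  stopifnot(inherits(p, "prior_params"))
  p0 <- 1 - p$p1 - p$p2 - p$p12
  h <- c(H0 = p0^n,
         H1 = n * p$p1 * p0^(n - 1),
         H2 = n * p$p2 * p0^(n - 1),
         H3 = n * (n - 1) * p$p1 * p$p2 * p0^(n - 2),
         H4 = n * p$p12 * p0^(n - 1))
  if (renormalise) h <- h / sum(h)
  h
}

#' Region size at which the H3 and H4 priors cross
#'
#' `P(H3)/P(H4) = (n-1) p1 p2 / p12` grows with `n`, so the shared-variant
#' hypothesis is favoured a priori only in regions smaller than
#' `n* = 1 + p12 / (p1 p2)`.
#'
#' @param p a [prior_params()] object.
#' @return A list with `n_star` (the crossing region size) and
#'   `h4_dominates` (`"below"`: H4 has the larger prior for `n < n_star`).
#' @export
h3_h4_crossing <- function(p) {
  stopifnot(inherits(p, "prior_params"))
  list(n_star = 1 + p$p12 / (p$p1 * p$p2), h4_dominates = "below")
}

#' Admissible interval for the joint-causality prior
#'
#' Bounds on `p12` implied by the marginal priors: even for genetically
#' independent traits, causal variants co-occur by chance among the
#' functional fraction `f` of the genome, giving `p12 > q1 q2 / f`; a
#' genome-wide genetic correlation `rg` between the traits implies
#' `p12 > |rg| sqrt(q1 q2)`; and joint causality can be no more likely
#' than either marginal event, `p12 < min(q1, q2)`.
#'
#' @param q1,q2 marginal per-SNP causality priors.
#' @param f proportion of variants assumed functional, in (0, 1\];
#'   literature estimates range from 0.25 to 0.8.
#' @param rg genetic correlation between the traits, in \[-1, 1\].
#' @return Named numeric vector `c(lower, upper)`. Errors if the lower
#'   bound exceeds the upper (possible when `|rg|` is large relative to
#'   `sqrt(min(q1,q2)/max(q1,q2))`).
#' @export
p12_bounds <- function(q1, q2, f = 0.25, rg = 0) {
  for (nm in c("q1", "q2"))
    if (!is_scalar_prob(get(nm)))
      stopf("'%s' must be a single probability in (0, 1)", nm)
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1)
    stopf("'f' must lie in (0, 1]")
  if (!is.numeric(rg) || length(rg) != 1L || abs(rg) > 1)
    stopf("'rg' must lie in [-1, 1]")
  lower <- max(q1 * q2 / f, abs(rg) * sqrt(q1 * q2))
  upper <- min(q1, q2)
  if (lower > upper)
    stopf("infeasible: lower bound %.3g exceeds upper bound %.3g", lower, upper)
  c(lower = lower, upper = upper)
}

#' Upper bound on genetic correlation from shared-variant counts
#'
#' When shared causal variants have no systematically different
#' distribution of frequencies or effects than trait-specific ones, the
#' genetic correlation is bounded by
#' `|rg| <= n12 / sqrt((n12 + n1)(n12 + n2))`, where `n12` variants are
#' shared and `n1`, `n2` are specific to each trait. Inverting this bound
#' motivates the `|rg| sqrt(q1 q2)` lower bound on `p12` in
#' [p12_bounds()].
#'
#' @param n1,n2 counts of variants causal for one trait only.
#' @param n12 count of shared causal variants.
#' @return Scalar bound in \[0, 1\].
#' @export
rg_upper_bound <- function(n1, n2, n12) {
  for (nm in c("n1", "n2", "n12")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0)
      stopf("'%s' must be a nonnegative count", nm)
  }
  if (n12 + n1 <= 0 || n12 + n2 <= 0)
    stopf("each trait must have at least one causal variant")
  n12 / sqrt((n12 + n1) * (n12 + n2))
}

#' Marginal prior from empirical hit counts
#'
#' Estimates the marginal per-SNP causality prior `q` as the ratio of
#' independent association signals to the number of (common) SNPs
#' examined, the natural empirical estimate from large single-trait
#' studies or association catalogues.
#'
#' @param n_hits number of independent significant associations.
#' @param n_snps number of SNPs considered (e.g. ~2 million common SNPs
#'   genome-wide).
#' @return Scalar estimate of `q`.
#' @export
marginal_prior_from_counts <- function(n_hits, n_snps) {
  if (!is.numeric(n_hits) || n_hits < 0 || !is.numeric(n_snps) || n_snps <= 0)
    stopf("counts must be nonnegative with n_snps > 0")
  n_hits / n_snps
}

#' Posterior probability of association at a single SNP
#'
#' For a SNP with two-sided p-value `p` in a study of the given design,
#' computes the Wakefield approximate Bayes factor `BF1` for association
#' at that SNP (via the reconstructed `varbeta` and the z-score implied by
#' `p`) and combines it with a marginal prior probability of association
#' `q` as `BF1 * q / (BF1 * q + (1 - q))`. Vectorised over `p` (and over
#' `maf`/`N` by recycling), so it traces the posterior-of-association
#' curve as a function of significance.
#'
#' @param p two-sided p-value(s) in (0, 1).
#' @param q marginal prior probability of association, in (0, 1).
#' @param type `"quant"` or `"cc"`.
#' @param N sample size.
#' @param maf minor allele frequency.
#' @param s case fraction (case-control only).
#' @param sdY trait standard deviation (quantitative; default 1).
#' @param effect_prior an [effect_prior()] giving the prior effect SD.
#' @return Posterior probability (vector matching `p`).
#' @export
single_snp_ppa <- function(p, q, type = c("quant", "cc"), N, maf,
                           s = NULL, sdY = 1, effect_prior = NULL) {
  type <- match.arg(type)
  if (is.null(effect_prior)) effect_prior <- paircoloc::effect_prior()
  if (!is_scalar_prob(q)) stopf("'q' must be a single probability in (0, 1)")
  if (any(p <= 0 | p >= 1)) stopf("p-values must lie in (0, 1)")
  if (any(maf <= 0 | maf > 0.5)) stopf("maf must lie in (0, 0.5]")
  denom <- 2 * N * maf * (1 - maf)
  if (type == "cc") {
    if (is.null(s) || !is_scalar_prob(s))
      stopf("case fraction 's' is required for case-control designs")
    V <- 1 / (denom * s * (1 - s))
    W <- effect_prior$sd_cc^2
  } else {
    V <- sdY^2 / denom
    W <- (effect_prior$sd_quant * sdY)^2
  }
  z <- p_to_z(p)
  labf <- wakefield_labf(z * sqrt(V), V, W)
  stats::plogis(labf + log(q) - log1p(-q))
}
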