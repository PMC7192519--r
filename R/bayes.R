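#' Prior standard deviation of true effect sizes
#'
#' The Wakefield approximate Bayes factor places a normal prior with
#' variance `W` on the true effect at a causal SNP. `W` is
#' `(sd_quant * sdY)^2` for quantitative traits (so `sd_quant` is in
#' trait-SD units) and `sd_cc^2` on the log-odds scale for case-control
#' traits.
#'
#' @param sd_quant prior effect SD for quantitative traits, in trait-SD
#'   units per allele dose (default 0.2).
#' @param sd_cc prior SD of the true log odds ratio (default 0.15).
#' @return An object of class `effect_prior`.
#' @export
effect_prior <- function(sd_quant = 0.2, sd_cc = 0.15) {
  if (!is.numeric(sd_quant) || sd_quant <= 0 || !is.numeric(sd_cc) || sd_cc <= 0)
    stopf("prior effect SDs must be positive")
  structure(list(sd_quant = sd_quant, sd_cc = sd_cc), class = "effect_prior")
}

#' Wakefield log approximate Bayes factor for a single SNP
#'
#' Closed-form Bayes factor comparing association against the null at one
#' SNP, from its effect estimate, squared standard error `V = varbeta` and
#' a normal effect prior with variance `W`:
#' `log ABF = 0.5 log(1 - r) + r z^2 / 2` with `r = W / (V + W)` and
#' `z = beta / sqrt(varbeta)`. Equivalent to the log ratio of the marginal
#' normal densities `N(beta; 0, V + W) / N(beta; 0, V)`. Vectorised; all
#' arithmetic is in log space and finite for finite inputs.
#'
#' @param beta effect estimate(s).
#' @param varbeta squared standard error(s), strictly positive.
#' @param W prior variance of the true effect (>= 0; `W = 0` gives log
#'   ABF = 0 since prior mass collapses on the null).
#' @return Log Bayes factor(s) in favour of association.
#' @export
wakefield_labf <- function(beta, varbeta, W) {
  if (any(varbeta <= 0)) stopf("varbeta must be strictly positive")
  if (any(W < 0)) stopf("prior variance W must be >= 0")
  r <- W / (varbeta + W)
  z2 <- beta^2 / varbeta
  0.5 * log1p(-r) + r * z2 / 2
}

# per-trait log ABFs, reconstructing effects and resolving sdY/W as needed
trait_labf <- function(d, ep) {
  if (requires_reconstruction(d)) d <- reconstruct_effects(d)
  if (d$type == "cc") {
    W <- ep$sd_cc^2
  } else {
    sdY <- d$sdY
    if (is.null(sdY)) {
      sdY <- if (!is.null(d$maf) && length(d$snp) >= 2L)
        tryCatch(estimate_sdY(d), error = function(e) NULL) else NULL
      if (is.null(sdY)) {
        warnf("sdY unavailable and not estimable; assuming sdY = 1")
        sdY <- 1
      }
    }
    W <- (ep$sd_quant * sdY)^2
  }
  labf <- wakefield_labf(d$beta, d$varbeta, W)
  names(labf) <- d$snp
  list(d = d, labf = labf)
}

#' Per-hypothesis log Bayes factors from per-SNP log ABFs
#'
#' Sums per-SNP Bayes factors over the causal-variant configurations of
#' each regional hypothesis: `BF(H1) = sum_i L1_i`, `BF(H2) = sum_j L2_j`,
#' `BF(H4) = sum_i L1_i L2_i` and `BF(H3) = sum_{i != j} L1_i L2_j =
#' BF(H1) BF(H2) - BF(H4)`, all relative to H0 and computed with
#' log-sum-exp. The H3 subtraction is replaced by the explicit sum over
#' ordered pairs whenever `BF(H4)` exceeds 99% of `BF(H1) BF(H2)`, to
#' avoid catastrophic cancellation. For a single-SNP region no
#' two-distinct-SNP configuration exists and `H3` is reported as `-Inf`
#' (log of zero), which drops out of posterior normalisation.
#'
#' @param labf1,labf2 per-SNP log ABFs for the two traits (equal length).
#' @return Named numeric vector `c(H1, H2, H3, H4)` of log Bayes factors
#'   relative to H0.
#' @export
hypothesis_labf <- function(labf1, labf2) {
  n <- length(labf1)
  if (n == 0L) stopf("empty log ABF input")
  if (length(labf2) != n) stopf("log ABF vectors must have equal length")
  lH1 <- logsumexp(labf1)
  lH2 <- logsumexp(labf2)
  lH4 <- logsumexp(labf1 + labf2)
  if (n == 1L) {
    lH3 <- -Inf
  } else {
    a <- lH1 + lH2
    delta <- lH4 - a                       # always <= 0 up to rounding
    if (delta > log(0.99)) {
      # near-cancellation: explicit sum over ordered pairs i != j
      lH3 <- logsumexp(vapply(seq_len(n), function(i)
        labf1[i] + logsumexp(labf2[-i]), numeric(1)))
    } else {
      lH3 <- a + log1p(-exp(delta))
    }
  }
  c(H1 = lH1, H2 = lH2, H3 = lH3, H4 = lH4)
}

#' Posterior hypothesis probabilities from regional Bayes factors
#'
#' Combines the per-hypothesis log Bayes factors with per-configuration
#' prior weights: unnormalised weights are `S0 = 1`, `S1 = p1 BF(H1)`,
#' `S2 = p2 BF(H2)`, `S3 = p1 p2 BF(H3)`, `S4 = p12 BF(H4)` (the
#' configuration-count factors are already inside the BF sums), and the
#' posterior is `S / sum(S)`, evaluated in log space.
#'
#' @param log_bf named vector `c(H1, H2, H3, H4)` from
#'   [hypothesis_labf()].
#' @param priors a [prior_params()] object.
#' @param nsnps region size, used to check prior feasibility.
#' @return Named numeric vector `c(H0, ..., H4)` summing to 1.
#' @export
coloc_posterior <- function(log_bf, priors, nsnps) {
  stopifnot(inherits(priors, "prior_params"))
  if (length(log_bf) != 4L)
    stopf("'log_bf' must hold the four hypothesis log Bayes factors")
  lw <- c(0,
          log(priors$p1) + log_bf[[1]],
          log(priors$p2) + log_bf[[2]],
          log(priors$p1) + log(priors$p2) + log_bf[[3]],
          log(priors$p12) + log_bf[[4]])
  pp <- exp(lw - logsumexp(lw))
  names(pp) <- paste0("H", 0:4)
  pp
}

#' Per-SNP posterior of being the shared causal variant
#'
#' Conditional on H4, the posterior that SNP `i` is the single shared
#' causal variant is the softmax of the joint per-SNP log ABFs
#' `labf1 + labf2`.
#'
#' @inheritParams hypothesis_labf
#' @return Numeric vector summing to 1 (names preserved from `labf1`).
#' @export
per_snp_h4 <- function(labf1, labf2) {
  if (length(labf1) != length(labf2))
    stopf("log ABF vectors must have equal length")
  j <- labf1 + labf2
  out <- exp(j - logsumexp(j))
  names(out) <- names(labf1)
  out
}

#' Colocalisation analysis of two traits under a single causal variant
#'
#' The core analysis: computes per-SNP Wakefield log ABFs for each trait
#' (reconstructing effects from p-values and MAF where necessary),
#' combines them into per-hypothesis Bayes factors by configuration
#' enumeration, and returns posterior probabilities for H0-H4 together
#' with the per-SNP posterior for the shared variant under H4. Assumes at
#' most one causal variant per trait; see [coloc_signals()] to relax this.
#'
#' @param d1,d2 [region_summary()] objects on an identical SNP set in
#'   identical order (use [harmonise_regions()] first).
#' @param priors a [prior_params()] object.
#' @param effect_prior an [effect_prior()] object.
#' @return An object of class `coloc_result`: a list with elements
#'   `nsnps`, `snp`, `log_bf` (H1-H4), `pp` (H0-H4), `priors`,
#'   `per_snp_h4`, the per-trait log ABF vectors `labf1`/`labf2`, and
#'   `leads` (lead-SNP annotations, filled by [coloc_signals()]).
#' @export
coloc_abf <- function(d1, d2, priors = prior_params(),
                      effect_prior = NULL) {
  stopifnot(inherits(d1, "region_summary"), inherits(d2, "region_summary"))
  if (is.null(effect_prior)) effect_prior <- paircoloc::effect_prior()
  if (length(d1$snp) != length(d2$snp) || !all(d1$snp == d2$snp))
    stopf("datasets are not on a common SNP set/order; run harmonise_regions()")
  t1 <- trait_labf(d1, effect_prior)
  t2 <- trait_labf(d2, effect_prior)
  build_coloc_result(t1$labf, t2$labf, priors)
}

# assemble a coloc_result from per-trait log ABF vectors
build_coloc_result <- function(labf1, labf2, priors,
                               leads = c(trait1 = NA_character_,
                                         trait2 = NA_character_),
                               modes = c("single", "single")) {
  n <- length(labf1)
  lbf <- hypothesis_labf(labf1, labf2)
  pp <- coloc_posterior(lbf, priors, n)
  structure(list(nsnps = n, snp = names(labf1), log_bf = lbf, pp = pp,
                 priors = priors, per_snp_h4 = per_snp_h4(labf1, labf2),
                 labf1 = labf1, labf2 = labf2, leads = leads, modes = modes),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, digits = 4, ...) {
  cat(sprintf("Colocalisation over %d SNPs", x$nsnps))
  if (!all(is.na(x$leads)))
    cat(sprintf("  [leads: %s / %s; modes: %s / %s]",
                x$leads[[1]], x$leads[[2]], x$modes[[1]], x$modes[[2]]))
  cat("\n")
  print(round(x$pp, digits))
  best <- names(x$pp)[which.max(x$pp)]
  cat(sprintf("Maximum posterior: %s (%.3f); top shared-variant candidate: %s\n",
              best, max(x$pp), names(x$per_snp_h4)[which.max(x$per_snp_h4)]))
  cat("Posterior conclusions depend on the priors; consider sensitivity_grid().\n")
  invisible(x)
}
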