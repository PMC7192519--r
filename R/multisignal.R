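#' Stepwise discovery of independent association signals
#'
#' Identifies lead SNPs for the distinct association signals in a region.
#' With `method = "cond"`, classic stepwise selection: the most significant
#' SNP is selected, association statistics for the remainder are
#' recomputed conditional on the selected set ([conditional_summary()]),
#' and selection repeats until no eligible SNP reaches `p_threshold`.
#' With `method = "mask"`, conditioning is replaced by successively
#' removing from eligibility every SNP with `r^2 >= r2_threshold` to any
#' selected lead, which approximates conditioning when the causal variants
#' are in linkage equilibrium and needs no allele alignment.
#'
#' @param d a [region_summary()]; signed effects are required for
#'   `method = "cond"`.
#' @param ld signed LD matrix covering the region's SNPs.
#' @param method `"mask"` or `"cond"`.
#' @param p_threshold stepwise significance threshold (default `1e-6`).
#' @param r2_threshold LD threshold defining independence for masking
#'   (default 0.01).
#' @param max_signals cap on the number of signals sought (default 3).
#' @return An object of class `signal_set`: lead ids in discovery order
#'   plus the parameters used. Empty when nothing reaches the threshold.
#' @export
stepwise_signals <- function(d, ld, method = c("mask", "cond"),
                             p_threshold = 1e-6, r2_threshold = 0.01,
                             max_signals = 3) {
  method <- match.arg(method)
  stopifnot(inherits(d, "region_summary"))
  if (missing(ld) || is.null(ld)) stopf("stepwise signal discovery requires LD")
  miss <- setdiff(d$snp, rownames(ld))
  if (length(miss))
    stopf("LD matrix lacks %d region SNP(s), e.g. %s", length(miss), miss[1])
  ld <- ld[d$snp, d$snp, drop = FALSE]
  if (method == "cond" && (!d$signed || requires_reconstruction(d)))
    stopf("conditioning requires signed beta estimates aligned to the LD matrix")
  leads <- character(0)
  lead_p <- numeric(0)
  repeat {
    if (length(leads) >= max_signals) break
    # selection works on log p so extreme signals rank correctly
    if (method == "mask") {
      elig <- if (length(leads)) {
        apply(r2_with(ld, leads), 1, max) < r2_threshold
      } else rep(TRUE, length(d$snp))
      if (!any(elig)) break
      lp <- region_logp(d)
      lp[!elig] <- Inf
    } else {
      stats <- if (length(leads)) conditional_summary(d, ld, leads) else d
      lp <- rep(Inf, length(d$snp))
      lp[match(stats$snp, d$snp)] <-
        logp_from_z(stats$beta / sqrt(stats$varbeta))
      flagged <- attr(stats, "collinear")
      if (!is.null(flagged) && any(flagged))
        lp[match(stats$snp[flagged], d$snp)] <- Inf
    }
    i <- which.min(lp)
    if (!is.finite(lp[i]) || lp[i] > log(p_threshold)) break
    leads <- c(leads, d$snp[i])
    lead_p <- c(lead_p, exp(max(lp[i], log(1e-300))))
  }
  structure(list(lead_ids = leads, lead_p = lead_p, method = method,
                 p_threshold = p_threshold, r2_threshold = r2_threshold,
                 max_signals = max_signals),
            class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  cat(sprintf("%d independent signal(s) [%s, p < %g]%s\n",
              length(x$lead_ids), x$method, x$p_threshold,
              if (length(x$lead_ids))
                paste0(": ", paste(x$lead_ids, collapse = ", ")) else ""))
  invisible(x)
}

#' Approximate conditional summary statistics from LD
#'
#' Recomputes single-SNP effect estimates conditional on a set of SNPs
#' using only summary statistics plus a signed LD matrix, in the spirit of
#' approximate conditional/joint analysis: the centred genotype
#' cross-product matrix is reconstructed from LD, allele frequencies and
#' the sample size, and the conditional effect of each remaining SNP `j`
#' is the multivariate least-squares solution over `{j} U condition_on`
#' restricted to `j`. Per-SNP genotype sums of squares are recovered from
#' `varbeta` and `sdY` where `sdY` is available (exact when the LD comes
#' from the study sample itself) and otherwise from `2 N maf (1-maf)`.
#' The conditional variance divides the marginal residual variance by the
#' Schur complement; SNPs with `r^2` above the collinearity cap to the
#' conditioning set are flagged and their conditional z set to 0. LD
#' estimated in an external reference panel makes all of this
#' approximate; small LD mismatches can produce occasional large errors,
#' which is the motivation for masking.
#'
#' @param d a [region_summary()] with signed effects.
#' @param ld signed LD matrix aligned to the same effect alleles.
#' @param condition_on SNP ids to condition on (subset of `d$snp`).
#' @param freqs effect-allele frequencies used for the frequency-based
#'   fallback; defaults to `d$maf`.
#' @param collinearity_r2 cap above which a SNP is considered collinear
#'   with the conditioning set (default 0.9).
#' @return A `region_summary` for the SNPs not in `condition_on`, with
#'   conditional `beta`/`varbeta` and an attribute `collinear` flagging
#'   targets at the cap.
#' @export
conditional_summary <- function(d, ld, condition_on, freqs = d$maf,
                                collinearity_r2 = 0.9) {
  stopifnot(inherits(d, "region_summary"))
  if (!d$signed || requires_reconstruction(d))
    stopf("conditioning requires signed beta estimates; reconstructed unsigned effects are not usable")
  condition_on <- as.character(condition_on)
  if (!length(condition_on)) stopf("'condition_on' must name at least one SNP")
  if (!all(condition_on %in% d$snp))
    stopf("condition_on SNP(s) not in dataset: %s",
          paste(setdiff(condition_on, d$snp), collapse = ", "))
  ld <- ld[d$snp, d$snp, drop = FALSE]
  idx_s <- match(condition_on, d$snp)
  if (length(idx_s) > 1L) {
    rs <- ld[idx_s, idx_s]^2
    diag(rs) <- 0
    if (max(rs) > collinearity_r2) {
      w <- which(rs == max(rs), arr.ind = TRUE)[1, ]
      stopf("collinear conditioning set: r^2(%s, %s) = %.3f exceeds %.2f",
            condition_on[w[1]], condition_on[w[2]], max(rs), collinearity_r2)
    }
  }
  n <- d$N
  # per-SNP genotype sum of squares about the mean (X'X diagonal)
  D <- if (!is.null(d$sdY)) {
    (n - 1) * d$sdY^2 / (d$varbeta * (n - 2) + d$beta^2)
  } else {
    if (is.null(freqs)) stopf("allele frequencies (or sdY) are required")
    2 * n * freqs * (1 - freqs)
  }
  sD <- sqrt(D)
  Xy <- D * d$beta
  Bss <- ld[idx_s, idx_s, drop = FALSE] * tcrossprod(sD[idx_s])
  inv <- tryCatch(solve(Bss), error = function(e)
    stopf("conditioning set is numerically singular"))
  targets <- setdiff(seq_along(d$snp), idx_s)
  Bts <- ld[targets, idx_s, drop = FALSE] *
    outer(sD[targets], sD[idx_s])
  M1 <- Bts %*% inv
  dcond <- D[targets] - rowSums(M1 * Bts)
  flag <- apply(ld[targets, idx_s, drop = FALSE]^2, 1, max) > collinearity_r2
  flag <- flag | dcond <= .Machine$double.eps * D[targets]
  bc <- (Xy[targets] - as.vector(M1 %*% Xy[idx_s])) / dcond
  vc <- (d$varbeta[targets] * D[targets]) / dcond
  bc[flag] <- 0
  vc[flag] <- d$varbeta[targets][flag]
  out <- subset_region(d, targets)
  out$beta <- unname(bc)
  out$varbeta <- unname(vc)
  out$pvalues <- z_to_p(bc / sqrt(vc))
  attr(out, "collinear") <- flag
  attr(out, "conditioned_on") <- condition_on
  out
}

#' Mask per-SNP Bayes factors around lead signals
#'
#' Sets the log ABF to 0 (Bayes factor 1, i.e. the SNP contributes no
#' evidence for any SNP-specific hypothesis) for every SNP with
#' `r^2 >= r2_threshold` to any of the given leads. This removes the
#' masked signals from a colocalisation comparison without requiring
#' allele-aligned effect estimates.
#'
#' @param labf named per-SNP log ABF vector (names are SNP ids).
#' @param ld LD matrix covering the SNPs.
#' @param leads_to_mask lead SNP ids whose LD neighbourhoods are masked;
#'   may be empty (identity).
#' @param r2_threshold masking LD threshold (default 0.01).
#' @return The masked log ABF vector.
#' @export
mask_labf <- function(labf, ld, leads_to_mask, r2_threshold = 0.01) {
  if (is.null(names(labf))) stopf("'labf' must be named by SNP id")
  leads_to_mask <- as.character(leads_to_mask)
  if (!length(leads_to_mask)) return(labf)
  miss <- setdiff(leads_to_mask, names(labf))
  if (length(miss)) stopf("unknown lead id(s): %s", paste(miss, collapse = ", "))
  r2 <- r2_with(ld[names(labf), names(labf), drop = FALSE], leads_to_mask)
  labf[apply(r2, 1, max) >= r2_threshold] <- 0
  labf
}

#' Colocalise all pairs of independent signals in a region
#'
#' Relaxes the single-causal-variant assumption: independent signals are
#' discovered per trait with [stepwise_signals()] (or the single top SNP
#' when `mode = "single"`), and one colocalisation is run for every pair
#' of leads (`n x m` analyses for `n` and `m` signals). For a trait in
#' `"cond"` mode, each comparison uses statistics conditioned on all of
#' that trait's *other* leads; in `"mask"` mode the per-SNP Bayes factors
#' of SNPs in LD with the other leads are set to 1 instead. Modes may be
#' mixed, e.g. conditioning in a fully-characterised in-house dataset and
#' masking in a public one.
#'
#' @param d1,d2 harmonised [region_summary()] objects.
#' @param ld1,ld2 per-trait LD matrices (required for any trait in
#'   `"cond"` or `"mask"` mode; they may come from different populations).
#' @param mode1,mode2 `"single"`, `"cond"` or `"mask"` per trait.
#' @param priors,effect_prior as in [coloc_abf()].
#' @param p_threshold,r2_threshold,max_signals stepwise parameters, see
#'   [stepwise_signals()].
#' @return An object of class `coloc_signals`: a list of `coloc_result`
#'   objects (one per lead pair, annotated with the lead ids) plus the
#'   per-trait `signal_set`s. `summary()` tabulates the posteriors.
#' @export
coloc_signals <- function(d1, d2, ld1 = NULL, ld2 = NULL,
                          mode1 = c("single", "cond", "mask"),
                          mode2 = c("single", "cond", "mask"),
                          priors = prior_params(), effect_prior = NULL,
                          p_threshold = 1e-6, r2_threshold = 0.01,
                          max_signals = 3) {
  mode1 <- match.arg(mode1); mode2 <- match.arg(mode2)
  if (is.null(effect_prior)) effect_prior <- paircoloc::effect_prior()
  if (length(d1$snp) != length(d2$snp) || !all(d1$snp == d2$snp))
    stopf("datasets are not on a common SNP set/order; run harmonise_regions()")

  prep_trait <- function(d, ld, mode) {
    if (mode != "single" && is.null(ld))
      stopf("mode '%s' requires an LD matrix", mode)
    if (mode == "single") {
      top <- which.min(region_logp(d))
      sig <- structure(list(lead_ids = d$snp[top], lead_p = region_p(d)[top],
                            method = "single", p_threshold = NA,
                            r2_threshold = NA, max_signals = 1),
                       class = "signal_set")
    } else {
      sig <- stepwise_signals(d, ld, method = mode, p_threshold = p_threshold,
                              r2_threshold = r2_threshold,
                              max_signals = max_signals)
      if (!length(sig$lead_ids)) {
        # no signal reaches the threshold: fall back to the top SNP so a
        # (null-ish) comparison is still reported
        top <- which.min(region_logp(d))
        sig$lead_ids <- d$snp[top]
        sig$lead_p <- region_p(d)[top]
      }
    }
    # per-lead log ABF vectors, adjusted for the trait's other leads
    labfs <- lapply(sig$lead_ids, function(lead) {
      others <- setdiff(sig$lead_ids, lead)
      if (mode == "cond" && length(others)) {
        dc <- conditional_summary(d, ld, others)
        tl <- trait_labf(dc, effect_prior)$labf
        # conditioned-out SNPs contribute no evidence
        full <- stats::setNames(rep(0, length(d$snp)), d$snp)
        full[names(tl)] <- tl
        full
      } else {
        labf <- trait_labf(d, effect_prior)$labf
        if (mode == "mask" && length(others))
          labf <- mask_labf(labf, ld, others, r2_threshold)
        labf
      }
    })
    list(sig = sig, labfs = labfs)
  }

  t1 <- prep_trait(d1, ld1, mode1)
  t2 <- prep_trait(d2, ld2, mode2)
  results <- list()
  for (i in seq_along(t1$sig$lead_ids))
    for (j in seq_along(t2$sig$lead_ids)) {
      res <- build_coloc_result(t1$labfs[[i]], t2$labfs[[j]], priors,
                                leads = c(trait1 = t1$sig$lead_ids[i],
                                          trait2 = t2$sig$lead_ids[j]),
                                modes = c(mode1, mode2))
      results[[length(results) + 1L]] <- res
    }
  structure(list(results = results, signals1 = t1$sig, signals2 = t2$sig,
                 modes = c(mode1, mode2)),
            class = "coloc_signals")
}

#' @export
summary.coloc_signals <- function(object, ...) {
  rows <- lapply(object$results, function(r)
    data.frame(lead1 = r$leads[["trait1"]], lead2 = r$leads[["trait2"]],
               nsnps = r$nsnps, t(r$pp), check.names = FALSE))
  do.call(rbind, rows)
}

#' @export
print.coloc_signals <- function(x, ...) {
  cat(sprintf("Multi-signal colocalisation (%s / %s): %d comparison(s)\n",
              x$modes[1], x$modes[2], length(x$results)))
  print(summary(x), digits = 3)
  invisible(x)
}

#' Label a lead-SNP comparison against known causal variants
#'
#' For simulation studies where the causal variants are known: each lead
#' SNP is labelled with the causal variant it tags most strongly, provided
#' `r^2 >= 0.8`; leads with `r^2 < 0.8` to every causal variant are
#' labelled `"?"` (the comparison cannot be unambiguously assigned).
#'
#' @param lead1,lead2 lead SNP ids for the two traits.
#' @param causal_ids nonempty set of true causal variant ids.
#' @param ld LD matrix containing leads and causal variants.
#' @param r2_label labelling threshold (default 0.8).
#' @return Named character vector `c(trait1_hit, trait2_hit)`.
#' @export
label_comparison <- function(lead1, lead2, causal_ids, ld, r2_label = 0.8) {
  causal_ids <- as.character(causal_ids)
  if (!length(causal_ids)) stopf("'causal_ids' must be nonempty")
  ids <- c(lead1, lead2, causal_ids)
  miss <- setdiff(ids, rownames(ld))
  if (length(miss)) stopf("unknown id(s): %s", paste(miss, collapse = ", "))
  lab <- function(lead) {
    r2 <- ld[lead, causal_ids]^2
    if (max(r2) >= r2_label) causal_ids[which.max(r2)] else "?"
  }
  c(trait1_hit = lab(lead1), trait2_hit = lab(lead2))
}
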