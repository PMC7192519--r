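#' Canonical effect-size set for regional GWAS simulations
#'
#' Per-allele effects (in residual-SD units) from which causal effects are
#' drawn in the simulation design.
#' @export
gwas_effect_sizes <- c(0.17, 0.33, 0.50, 0.67, 0.83, 1.00, 1.17, 1.33, 1.50)

#' Generate a synthetic haplotype reference panel with block LD
#'
#' Builds a binary haplotype matrix with block-structured linkage
#' disequilibrium: per-SNP allele frequencies are drawn uniformly, latent
#' Gaussians share a per-block factor with loading
#' `sqrt(within_block_corr)` and are thresholded at the frequency
#' quantile. SNPs in the same block are therefore correlated while
#' different blocks are independent (up to sampling noise), mimicking the
#' haplotype-block structure of a real reference panel without any
#' download. Deterministic given `seed`.
#'
#' @param n_hap number of haplotypes (default 1000, the scale of a
#'   one-population reference panel).
#' @param n_snp number of SNPs in the region.
#' @param block_size SNPs per LD block (default 25).
#' @param within_block_corr latent correlation within a block, in
#'   \[0, 1) (default 0.9).
#' @param maf_range range from which allele frequencies are drawn
#'   (default `c(0.01, 0.5)`).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return An object of class `haplotype_panel`: binary matrix
#'   `haplotypes` (haplotype x SNP), `snp` ids, realised allele `freq`,
#'   folded `maf` and `block` index.
#' @export
synth_haplotype_panel <- function(n_hap = 1000, n_snp = 500, block_size = 25,
                                  within_block_corr = 0.9,
                                  maf_range = c(0.01, 0.5), seed = NULL) {
  if (n_hap < 2 || n_snp < 1 || block_size < 1)
    stopf("panel dimensions must be positive")
  if (within_block_corr < 0 || within_block_corr >= 1)
    stopf("'within_block_corr' must lie in [0, 1)")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stopf("'maf_range' must lie within (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  freq <- stats::runif(n_snp, maf_range[1], maf_range[2])
  nblock <- ceiling(n_snp / block_size)
  block <- rep(seq_len(nblock), each = block_size)[seq_len(n_snp)]
  U <- matrix(stats::rnorm(n_hap * nblock), n_hap, nblock)
  Z <- sqrt(within_block_corr) * U[, block, drop = FALSE] +
    sqrt(1 - within_block_corr) * matrix(stats::rnorm(n_hap * n_snp), n_hap)
  H <- (Z < matrix(stats::qnorm(freq), n_hap, n_snp, byrow = TRUE)) * 1L
  ids <- sprintf("rs%04d", seq_len(n_snp))
  colnames(H) <- ids
  realised <- colMeans(H)
  structure(list(haplotypes = H, snp = ids, freq = realised,
                 maf = pmin(realised, 1 - realised), block = block),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("Haplotype panel: %d haplotypes x %d SNPs (%d LD blocks), MAF %.3f-%.3f\n",
              nrow(x$haplotypes), length(x$snp), max(x$block),
              min(x$maf), max(x$maf)))
  invisible(x)
}

#' Load a user-supplied haplotype panel from a plain 0/1 matrix
#'
#' Reads a whitespace-delimited file of 0/1 entries (haplotype per row)
#' whose header row names the SNPs.
#'
#' @param path path to the file.
#' @return A `haplotype_panel` (see [synth_haplotype_panel()]).
#' @export
read_haplotype_panel <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  H <- as.matrix(utils::read.table(path, header = TRUE, check.names = FALSE))
  if (!all(H %in% c(0L, 1L))) stopf("panel entries must be 0/1")
  storage.mode(H) <- "integer"
  realised <- colMeans(H)
  structure(list(haplotypes = H, snp = colnames(H), freq = realised,
                 maf = pmin(realised, 1 - realised),
                 block = rep(NA_integer_, ncol(H))),
            class = "haplotype_panel")
}

#' Restrict a panel to SNPs above a MAF threshold
#'
#' @param panel a `haplotype_panel`.
#' @param min_maf minimum minor allele frequency (default 0.05, the usual
#'   common-SNP filter).
#' @return The filtered panel.
#' @export
filter_maf <- function(panel, min_maf = 0.05) {
  stopifnot(inherits(panel, "haplotype_panel"))
  keep <- panel$maf >= min_maf
  panel$haplotypes <- panel$haplotypes[, keep, drop = FALSE]
  panel$snp <- panel$snp[keep]
  panel$freq <- panel$freq[keep]
  panel$maf <- panel$maf[keep]
  panel$block <- panel$block[keep]
  panel
}

#' Sample diploid genotypes from a haplotype panel
#'
#' Draws `2N` haplotypes with replacement and sums them pairwise, giving
#' an `N x M` genotype matrix with entries in `{0, 1, 2}` under
#' Hardy-Weinberg random mating.
#'
#' @param panel a `haplotype_panel`.
#' @param N number of individuals.
#' @param seed optional integer seed.
#' @return Genotype matrix with SNP ids as column names.
#' @export
sample_genotypes <- function(panel, N, seed = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"), N >= 1)
  if (!is.null(seed)) set.seed(seed)
  nh <- nrow(panel$haplotypes)
  i1 <- sample.int(nh, N, replace = TRUE)
  i2 <- sample.int(nh, N, replace = TRUE)
  panel$haplotypes[i1, , drop = FALSE] + panel$haplotypes[i2, , drop = FALSE]
}

#' LD matrix of a panel or genotype matrix
#'
#' Signed correlation between SNP columns, as a validated LD matrix.
#' Monomorphic columns are an error (filter first).
#'
#' @param x a `haplotype_panel` or a genotype matrix with SNP column
#'   names.
#' @return A validated LD matrix (see [ld_matrix()]).
#' @export
panel_ld <- function(x) {
  G <- if (inherits(x, "haplotype_panel")) x$haplotypes else x
  v <- apply(G, 2, stats::var)
  if (any(v == 0))
    stopf("monomorphic column(s): %s",
          paste(utils::head(colnames(G)[v == 0], 3), collapse = ", "))
  r <- stats::cor(G)
  # clamp tiny numerical excursions outside [-1, 1]
  r[r > 1] <- 1; r[r < -1] <- -1
  ld_matrix(r)
}

#' Ground truth for a simulated trait pair
#'
#' Records the generating hypothesis, the causal SNP ids per trait and
#' their per-allele effects. Under H4 the two traits share the same
#' causal variant; under H0 both sets are empty.
#'
#' @param hypothesis one of `"H0"`..`"H4"` or `"custom"` (any layout,
#'   e.g. the multi-causal designs used to study conditioning).
#' @param causal1,causal2 causal SNP ids per trait.
#' @param beta1,beta2 per-allele effects, same lengths as the causal
#'   sets.
#' @return An object of class `sim_truth`.
#' @export
sim_truth <- function(hypothesis = c("H0", "H1", "H2", "H3", "H4", "custom"),
                      causal1 = character(0), causal2 = character(0),
                      beta1 = numeric(0), beta2 = numeric(0)) {
  hypothesis <- match.arg(hypothesis)
  causal1 <- as.character(causal1); causal2 <- as.character(causal2)
  if (length(beta1) != length(causal1) || length(beta2) != length(causal2))
    stopf("effects must match causal sets in length")
  chk <- switch(hypothesis,
    H0 = length(causal1) == 0 && length(causal2) == 0,
    H1 = length(causal1) == 1 && length(causal2) == 0,
    H2 = length(causal1) == 0 && length(causal2) == 1,
    H3 = length(causal1) == 1 && length(causal2) == 1 && causal1 != causal2,
    H4 = length(causal1) == 1 && identical(causal1, causal2),
    custom = TRUE)
  if (!chk) stopf("causal layout inconsistent with hypothesis %s", hypothesis)
  structure(list(hypothesis = hypothesis, causal1 = causal1,
                 causal2 = causal2, beta1 = beta1, beta2 = beta2),
            class = "sim_truth")
}

#' Draw a random ground truth for a given hypothesis
#'
#' Causal variants are selected at random among common SNPs
#' (`maf >= min_maf`) and effects are drawn from `effect_set`. For H3 an
#' optional `max_causal_r2` constrains the two causal variants to be in
#' approximate linkage equilibrium.
#'
#' @param panel a `haplotype_panel`.
#' @param hypothesis `"H0"`..`"H4"`.
#' @param effect_set effects to sample from (default
#'   [gwas_effect_sizes]).
#' @param min_maf common-SNP filter for causal candidates (default 0.05).
#' @param max_causal_r2 optional cap on r^2 between the two H3 causal
#'   variants (`NULL`: unconstrained, as in the base design).
#' @param ld optional precomputed panel LD (required with
#'   `max_causal_r2`).
#' @return A [sim_truth()].
#' @export
draw_truth <- function(panel, hypothesis, effect_set = gwas_effect_sizes,
                       min_maf = 0.05, max_causal_r2 = NULL, ld = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  common <- panel$snp[panel$maf >= min_maf]
  if (length(common) < 2) stopf("fewer than 2 common SNPs in panel")
  pick <- function(k) sample(common, k)
  eff <- function(k) sample(effect_set, k, replace = TRUE)
  switch(hypothesis,
    H0 = sim_truth("H0"),
    H1 = sim_truth("H1", causal1 = pick(1), beta1 = eff(1)),
    H2 = sim_truth("H2", causal2 = pick(1), beta2 = eff(1)),
    H3 = {
      cs <- pick(2)
      if (!is.null(max_causal_r2)) {
        if (is.null(ld)) ld <- panel_ld(panel)
        for (tries in 1:100) {
          if (ld[cs[1], cs[2]]^2 <= max_causal_r2) break
          cs <- pick(2)
        }
      }
      sim_truth("H3", causal1 = cs[1], causal2 = cs[2],
                beta1 = eff(1), beta2 = eff(1))
    },
    H4 = {
      cs <- pick(1)
      sim_truth("H4", causal1 = cs, causal2 = cs, beta1 = eff(1),
                beta2 = eff(1))
    },
    stopf("unknown hypothesis '%s'", hypothesis))
}

#' Marginal single-SNP regressions of a trait on every SNP
#'
#' Ordinary least squares of the trait on each genotype column separately
#' (with intercept): slope `beta = Sxy/Sxx` and its sampling variance
#' `varbeta = SSE / ((N-2) Sxx)` — the per-SNP summary statistics a GWAS
#' would report.
#'
#' @param G genotype matrix (individuals x SNPs), no constant columns.
#' @param Y trait vector.
#' @return A data frame with columns `beta` and `varbeta` (one row per
#'   SNP, SNP ids as row names when `G` has column names).
#' @export
single_snp_regression <- function(G, Y) {
  if (!is.matrix(G)) G <- as.matrix(G)
  N <- length(Y)
  if (nrow(G) != N) stopf("genotype and trait dimensions disagree")
  if (N < 3) stopf("need at least 3 individuals")
  Gc <- sweep(G, 2, colMeans(G))
  Yc <- Y - mean(Y)
  Sxx <- colSums(Gc^2)
  if (any(Sxx == 0)) stopf("monomorphic SNP(s) present; filter before regression")
  Sxy <- as.vector(crossprod(Gc, Yc))
  Syy <- sum(Yc^2)
  beta <- Sxy / Sxx
  sse <- pmax(Syy - beta * Sxy, 0)
  data.frame(beta = beta, varbeta = sse / ((N - 2) * Sxx),
             row.names = colnames(G))
}

#' Simulate a pair of regional GWAS with known ground truth
#'
#' Draws independent genotype samples for each trait from the panel,
#' generates quantitative traits `Y = sum_i b_i G_i + e` with
#' `e ~ N(0, 1)` (residual SD 1), and summarises each trait by marginal
#' single-SNP regressions. Sample allele frequencies and the realised
#' trait SD are stored in the returned summaries, so the pair can feed
#' straight into [coloc_abf()] or [coloc_signals()].
#'
#' @param panel a `haplotype_panel`.
#' @param N1,N2 per-trait sample sizes (`N2` defaults to `N1`).
#' @param truth a [sim_truth()]; causal SNPs must be in the panel and
#'   (by design) common.
#' @param seed optional integer seed.
#' @param min_maf causal variants below this panel MAF are an error
#'   (default 0.05).
#' @param keep_genotypes also return the raw genotype matrices and trait
#'   vectors (for exact individual-level oracles).
#' @param return_ld also return per-trait LD computed from the sampled
#'   genotypes.
#' @return A list with `d1`, `d2` ([region_summary()]), `truth`, and
#'   optionally `G1`, `G2`, `ld1`, `ld2`.
#' @export
simulate_trait_pair <- function(panel, N1, N2 = N1, truth, seed = NULL,
                                min_maf = 0.05, keep_genotypes = FALSE,
                                return_ld = FALSE) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(truth, "sim_truth"))
  if (!is.null(seed)) set.seed(seed)
  causal <- unique(c(truth$causal1, truth$causal2))
  miss <- setdiff(causal, panel$snp)
  if (length(miss)) stopf("causal SNP(s) not in panel: %s",
                          paste(miss, collapse = ", "))
  low <- causal[panel$maf[match(causal, panel$snp)] < min_maf]
  if (length(low))
    stopf("causal SNP(s) below the MAF filter (%g): %s", min_maf,
          paste(low, collapse = ", "))
  one_trait <- function(N, ids, b) {
    G <- sample_genotypes(panel, N)
    Y <- stats::rnorm(N)
    if (length(ids))
      Y <- Y + as.vector(G[, ids, drop = FALSE] %*% b)
    ss <- single_snp_regression(G, Y)
    f <- colMeans(G) / 2
    d <- region_summary(snp = panel$snp, beta = ss$beta, varbeta = ss$varbeta,
                        pvalues = z_to_p(ss$beta / sqrt(ss$varbeta)),
                        maf = pmin(f, 1 - f), type = "quant", N = N,
                        sdY = stats::sd(Y))
    list(d = d, G = G, Y = Y)
  }
  t1 <- one_trait(N1, truth$causal1, truth$beta1)
  t2 <- one_trait(N2, truth$causal2, truth$beta2)
  out <- list(d1 = t1$d, d2 = t2$d, truth = truth)
  if (keep_genotypes) {
    out$G1 <- t1$G; out$G2 <- t2$G
    out$Y1 <- t1$Y; out$Y2 <- t2$Y
  }
  if (return_ld) { out$ld1 <- panel_ld(t1$G); out$ld2 <- panel_ld(t2$G) }
  out
}

#' Mean posterior probabilities over a grid of simulation scenarios
#'
#' For each combination of generating hypothesis and sample size, runs
#' seeded replicate simulations, analyses each with [coloc_abf()] under
#' the first `p12` value and re-expresses the posterior under the
#' remaining values by exact reweighting, then averages the per-hypothesis
#' posteriors. This is the summary used to study how prior choice and
#' sample size drive expected inference.
#'
#' @param hypotheses generating hypotheses (default all five).
#' @param N sample sizes to cross with the hypotheses.
#' @param reps replicates per cell.
#' @param p12 vector of joint-causality priors to report
#'   (`p1 = p2 = 1e-4` held fixed).
#' @param panel a `haplotype_panel`; by default a synthetic panel of 1000
#'   haplotypes and 250 SNPs is generated from `seed`.
#' @param effect_set causal-effect set (default [gwas_effect_sizes]).
#' @param effect_prior an [effect_prior()].
#' @param seed integer seed controlling panel, truths and traits.
#' @return A data frame with one row per hypothesis x N x p12: mean
#'   posterior per hypothesis (`pp.H0`..`pp.H4`) and the replicate count.
#' @export
expected_posterior_table <- function(hypotheses = c("H0", "H1", "H2", "H3", "H4"),
                                     N = c(1000, 10000), reps = 100,
                                     p12 = c(1e-5, 5e-6), panel = NULL,
                                     effect_set = gwas_effect_sizes,
                                     effect_prior = NULL, seed = 1) {
  if (is.null(effect_prior)) effect_prior <- paircoloc::effect_prior()
  if (is.null(panel))
    panel <- synth_haplotype_panel(n_hap = 1000, n_snp = 250, seed = seed)
  priors_list <- lapply(p12, function(g) prior_params(1e-4, 1e-4, g))
  cells <- expand.grid(hypothesis = hypotheses, N = N,
                       stringsAsFactors = FALSE)
  out <- list()
  counter <- 0L
  for (ci in seq_len(nrow(cells))) {
    hyp <- cells$hypothesis[ci]; n <- cells$N[ci]
    acc <- matrix(0, length(p12), 5)
    for (r in seq_len(reps)) {
      counter <- counter + 1L
      set.seed(seed + counter)          # deterministic per-replicate stream
      truth <- draw_truth(panel, hyp, effect_set = effect_set)
      sim <- simulate_trait_pair(panel, N1 = n, truth = truth)
      res <- coloc_abf(sim$d1, sim$d2, priors = priors_list[[1]],
                       effect_prior = effect_prior)
      acc[1, ] <- acc[1, ] + res$pp
      for (k in seq_along(p12)[-1])
        acc[k, ] <- acc[k, ] + reweight_posteriors(res, priors_list[[k]])$pp
    }
    for (k in seq_along(p12))
      out[[length(out) + 1L]] <- data.frame(
        hypothesis = hyp, N = n, p12 = p12[k],
        stats::setNames(as.data.frame(t(acc[k, ] / reps)),
                        paste0("pp.H", 0:4)),
        reps = reps)
  }
  do.call(rbind, out)
}
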