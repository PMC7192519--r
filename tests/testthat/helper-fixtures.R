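# shared fixtures, built in code and cached across test files

.fixtures <- new.env(parent = emptyenv())

# one region-scale panel reused by the simulation-heavy tests
shared_panel <- function() {
  if (is.null(.fixtures$panel))
    .fixtures$panel <- synth_haplotype_panel(n_hap = 1000, n_snp = 250,
                                             seed = 20260921)
  .fixtures$panel
}

shared_panel_ld <- function() {
  if (is.null(.fixtures$panel_ld))
    .fixtures$panel_ld <- panel_ld(shared_panel())
  .fixtures$panel_ld
}

# small analytic region with exact varbeta structure (sdY = 1)
toy_region <- function(beta = c(0.1, -0.05, 0.02), N = 10000,
                       maf = c(0.3, 0.2, 0.45), sdY = 1, signed = TRUE) {
  varbeta <- sdY^2 / (2 * N * maf * (1 - maf))
  region_summary(snp = paste0("s", seq_along(beta)), beta = beta,
                 varbeta = varbeta, maf = maf, type = "quant", N = N,
                 sdY = sdY, signed = signed)
}

# brute-force configuration enumeration: hypothesis BFs by explicit loops
enum_hypothesis_bf <- function(labf1, labf2) {
  L1 <- exp(labf1); L2 <- exp(labf2)
  n <- length(L1)
  bf3 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    bf3 <- bf3 + L1[i] * L2[j]
  c(H1 = sum(L1), H2 = sum(L2), H3 = bf3, H4 = sum(L1 * L2))
}

# enumeration-based posterior over hypotheses (independent of the
# log-sum-exp path): linear-space configuration weights
enum_posterior <- function(labf1, labf2, priors) {
  bf <- enum_hypothesis_bf(labf1, labf2)
  s <- c(1, priors$p1 * bf[["H1"]], priors$p2 * bf[["H2"]],
         priors$p1 * priors$p2 * bf[["H3"]], priors$p12 * bf[["H4"]])
  stats::setNames(s / sum(s), paste0("H", 0:4))
}
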