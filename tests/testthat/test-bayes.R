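# independent oracle: the ABF is the ratio of marginal likelihoods
# integral N(bhat; b, V) N(b; 0, W) db / N(bhat; 0, V), by quadrature
quadrature_labf <- function(beta, varbeta, W) {
  num <- integrate(function(b) dnorm(beta, b, sqrt(varbeta)) *
                     dnorm(b, 0, sqrt(W)),
                   lower = -10, upper = 10, rel.tol = 1e-12)$value
  log(num) - dnorm(beta, 0, sqrt(varbeta), log = TRUE)
}

test_that("Wakefield log ABF matches numerical quadrature of the marginal likelihood ratio", {
  cases <- list(c(beta = 0, varbeta = 1e-4, W = 0.04),
                c(beta = 0.1, varbeta = 4e-4, W = 0.04),
                c(beta = -0.3, varbeta = 2e-3, W = 0.0225),
                c(beta = 0.02, varbeta = 1e-3, W = 0.09))
  for (cs in cases)
    expect_equal(wakefield_labf(cs["beta"], cs["varbeta"], cs["W"]),
                 quadrature_labf(cs["beta"], cs["varbeta"], cs["W"]),
                 tolerance = 1e-6, ignore_attr = TRUE)
  # frozen values from the quadrature oracle
  expect_equal(wakefield_labf(0, 1e-4, 0.04), -2.99698, tolerance = 1e-5)
  expect_equal(wakefield_labf(0.1, 4e-4, 0.04), 10.06868, tolerance = 1e-5)
})

test_that("degenerate effect priors and null z behave as expected", {
  expect_equal(wakefield_labf(0.5, 1e-3, 0), 0)
  expect_error(wakefield_labf(0.1, 0, 0.04), "varbeta")
  # at z = 0 the ABF penalises association, strictly unless W = 0
  W <- c(0, 0.01, 0.04, 1)
  labf <- wakefield_labf(0, 1e-4, W)
  expect_true(all(labf <= 0))
  expect_identical(labf == 0, W == 0)
})

test_that("hypothesis Bayes factors count configurations and match brute force", {
  lbf <- hypothesis_labf(rep(0, 3), rep(0, 3))
  expect_equal(lbf, c(H1 = log(3), H2 = log(3), H3 = log(6), H4 = log(3)))

  # single-SNP region: no H3 configuration exists
  lbf1 <- hypothesis_labf(2, 3)
  expect_identical(lbf1[["H3"]], -Inf)
  pp1 <- coloc_posterior(lbf1, prior_params(), nsnps = 1)
  expect_equal(pp1[["H3"]], 0)
  expect_equal(sum(pp1), 1, tolerance = 1e-12)

  set.seed(1)
  for (n in c(2, 5, 17, 50)) {
    labf1 <- rnorm(n, sd = 4); labf2 <- rnorm(n, sd = 4)
    lbf <- hypothesis_labf(labf1, labf2)
    expect_equal(exp(lbf), enum_hypothesis_bf(labf1, labf2),
                 tolerance = 1e-10)
  }
})

test_that("H3 survives near-cancellation when one SNP dominates both traits", {
  labf1 <- c(25, 0, 0, 0)
  labf2 <- c(24, 0, 0, 0)
  lbf <- hypothesis_labf(labf1, labf2)
  expect_equal(exp(lbf[["H3"]]),
               enum_hypothesis_bf(labf1, labf2)[["H3"]],
               tolerance = 1e-10)
})

test_that("posteriors equal configuration enumeration and respond to p12", {
  set.seed(2)
  pr <- prior_params(1e-4, 1e-4, 1e-5)
  for (rep in 1:5) {
    n <- sample(2:30, 1)
    labf1 <- rnorm(n, sd = 3); labf2 <- rnorm(n, sd = 3)
    pp <- coloc_posterior(hypothesis_labf(labf1, labf2), pr, n)
    expect_equal(pp, enum_posterior(labf1, labf2, pr), tolerance = 1e-10)
    expect_equal(sum(pp), 1, tolerance = 1e-12)
  }

  # uninformative data over 1000 SNPs: posterior equals the enumeration
  # prior weights
  labf0 <- rep(0, 1000)
  pp0 <- coloc_posterior(hypothesis_labf(labf0, labf0), pr, 1000)
  s <- c(1, 0.1, 0.1, 1000 * 999 * 1e-8, 0.01)
  expect_equal(unname(pp0), s / sum(s), tolerance = 1e-10)

  # doubling p12 strictly increases pp[H4]
  lbf <- hypothesis_labf(rnorm(20), rnorm(20))
  pp_a <- coloc_posterior(lbf, prior_params(1e-4, 1e-4, 1e-5), 20)
  pp_b <- coloc_posterior(lbf, prior_params(1e-4, 1e-4, 2e-5), 20)
  expect_gt(pp_b[["H4"]], pp_a[["H4"]])
})

test_that("trait swap exchanges H1/H2 and per-trait rescaling cancels", {
  set.seed(3)
  labf1 <- rnorm(30, sd = 2); labf2 <- rnorm(30, sd = 2)
  pr <- prior_params(2e-4, 5e-5, 1e-5)
  pr_sw <- prior_params(5e-5, 2e-4, 1e-5)
  pp <- coloc_posterior(hypothesis_labf(labf1, labf2), pr, 30)
  pp_sw <- coloc_posterior(hypothesis_labf(labf2, labf1), pr_sw, 30)
  expect_equal(pp[["H1"]], pp_sw[["H2"]], tolerance = 1e-12)
  expect_equal(pp[["H2"]], pp_sw[["H1"]], tolerance = 1e-12)
  expect_equal(pp[c("H0", "H3", "H4")], pp_sw[c("H0", "H3", "H4")],
               tolerance = 1e-12)

  # adding a constant c to every log ABF of trait 1 multiplies the
  # evidence for each trait-1-involving hypothesis (H1, H3, H4) by e^c and
  # leaves H0/H2 alone: relative weights within each group are unchanged,
  # as is the per-SNP H4 posterior
  lbf <- hypothesis_labf(labf1, labf2)
  lbf_c <- hypothesis_labf(labf1 + 7.3, labf2)
  expect_equal(lbf_c - lbf, c(H1 = 7.3, H2 = 0, H3 = 7.3, H4 = 7.3),
               tolerance = 1e-9)
  pp_c <- coloc_posterior(lbf_c, pr, 30)
  expect_equal(pp_c[["H4"]] / pp_c[["H3"]], pp[["H4"]] / pp[["H3"]],
               tolerance = 1e-9)
  expect_equal(pp_c[["H0"]] / pp_c[["H2"]], pp[["H0"]] / pp[["H2"]],
               tolerance = 1e-9)
  expect_equal(per_snp_h4(labf1 + 7.3, labf2), per_snp_h4(labf1, labf2),
               tolerance = 1e-12)
})

test_that("per-SNP H4 posterior is the softmax of the joint evidence", {
  expect_equal(per_snp_h4(rep(1, 4), rep(2, 4)), rep(0.25, 4))
  p <- per_snp_h4(c(20, rep(0, 9)), rep(0, 10))
  expect_gt(p[1], 0.999)
  set.seed(4)
  labf1 <- rnorm(12); labf2 <- rnorm(12)
  joint <- exp(labf1 + labf2)
  expect_equal(per_snp_h4(labf1, labf2), joint / sum(joint),
               tolerance = 1e-12)
  expect_error(per_snp_h4(1:3, 1:2), "equal length")
})

test_that("coloc_abf recovers the generating hypothesis on seeded simulations", {
  panel <- shared_panel()
  cm <- filter_maf(panel)
  run <- function(truth, seed) {
    set.seed(seed)
    sim <- simulate_trait_pair(panel, N1 = 5000, truth = truth)
    names(which.max(coloc_abf(sim$d1, sim$d2)$pp))
  }
  set.seed(100)
  t4 <- draw_truth(cm, "H4", effect_set = 1.0)
  expect_identical(run(t4, 101), "H4")
  set.seed(102)
  t3 <- draw_truth(cm, "H3", effect_set = 1.0, max_causal_r2 = 0.01,
                   ld = shared_panel_ld())
  expect_identical(run(t3, 103), "H3")
  expect_identical(run(sim_truth("H0"), 104), "H0")
})

# drop one SNP to break harmonisation
drop_first_snp <- function(d) {
  region_summary(snp = d$snp[-1], beta = d$beta[-1], varbeta = d$varbeta[-1],
                 maf = d$maf[-1], type = d$type, N = d$N, sdY = d$sdY)
}

test_that("coloc_abf accepts p-value input and insists on harmonised SNP sets", {
  panel <- shared_panel()
  set.seed(110)
  t4 <- draw_truth(filter_maf(panel), "H4", effect_set = 1.0)
  sim <- simulate_trait_pair(panel, N1 = 3000, truth = t4, seed = 111)
  # strip trait 2 down to p-values + MAF: reconstruction path
  d2p <- region_summary(snp = sim$d2$snp, pvalues = sim$d2$pvalues,
                        maf = sim$d2$maf, type = "quant", N = sim$d2$N,
                        sdY = sim$d2$sdY)
  res <- coloc_abf(sim$d1, d2p)
  expect_identical(names(which.max(res$pp)), "H4")
  expect_error(coloc_abf(sim$d1, drop_first_snp(sim$d2)), "harmonise")
})
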