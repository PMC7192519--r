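# identity LD over a toy region: conditioning must be a no-op
test_that("conditioning on an uncorrelated SNP leaves other statistics unchanged", {
  d <- toy_region(beta = c(0.1, -0.05, 0.02, 0.2), maf = rep(c(0.3, 0.2), 2))
  ld <- diag(4); dimnames(ld) <- list(d$snp, d$snp)
  cond <- conditional_summary(d, ld, "s4")
  expect_equal(cond$beta, d$beta[1:3], tolerance = 1e-10)
  expect_equal(cond$varbeta, d$varbeta[1:3], tolerance = 1e-10)
  expect_false(any(attr(cond, "collinear")))
})

test_that("conditional estimates reproduce exact joint least squares on genotypes", {
  panel <- shared_panel()
  truth <- sim_truth("custom", causal1 = c("rs0040", "rs0125"),
                     beta1 = c(0.5, 0.33), causal2 = "rs0125", beta2 = 0.5)
  sim <- simulate_trait_pair(panel, N1 = 4000, truth = truth, seed = 31,
                             keep_genotypes = TRUE, return_ld = TRUE)
  cond <- conditional_summary(sim$d1, sim$ld1, "rs0040")
  keep <- !attr(cond, "collinear")
  A <- sim$G1[, "rs0040"]
  exact <- vapply(cond$snp[keep], function(j)
    coef(lm(sim$Y1 ~ sim$G1[, j] + A))[2], numeric(1))
  expect_equal(cond$beta[keep], unname(exact), tolerance = 1e-8)
})

test_that("collinear conditioning sets and targets are refused or flagged", {
  d <- toy_region(beta = c(0.1, 0.11, 0.02), maf = rep(0.3, 3))
  ld <- matrix(c(1, 0.99, 0, 0.99, 1, 0, 0, 0, 1), 3,
               dimnames = list(d$snp, d$snp))
  expect_error(conditional_summary(d, ld, c("s1", "s2")), "collinear")
  # a target collinear with the conditioning set gets z = 0
  cond <- conditional_summary(d, ld, "s1")
  expect_true(attr(cond, "collinear")[cond$snp == "s2"])
  expect_equal(cond$beta[cond$snp == "s2"], 0)
  # unsigned (reconstructed) input refuses to condition
  du <- region_summary(snp = d$snp, pvalues = c(1e-8, 1e-6, 0.5),
                       maf = rep(0.3, 3), type = "quant", N = 10000, sdY = 1)
  expect_error(conditional_summary(reconstruct_effects(du), ld, "s1"),
               "unsigned")
})

test_that("masking zeroes the Bayes factors of LD neighbourhoods only", {
  panel <- shared_panel()
  ld <- shared_panel_ld()
  labf <- setNames(rnorm(length(panel$snp), sd = 2), panel$snp)
  expect_identical(mask_labf(labf, ld, character(0)), labf)

  m <- mask_labf(labf, ld, "rs0030", r2_threshold = 0.01)
  hit <- ld[, "rs0030"]^2 >= 0.01
  expect_true(all(m[hit] == 0))
  expect_identical(m[!hit], labf[!hit])
  expect_equal(m[["rs0030"]], 0)       # the lead itself is masked

  # a lead isolated from everything masks only itself
  iso <- diag(3); dimnames(iso) <- list(letters[1:3], letters[1:3])
  lv <- setNames(c(1, 2, 3), letters[1:3])
  expect_equal(mask_labf(lv, iso, "b"), setNames(c(1, 0, 3), letters[1:3]))

  # masking everything reduces hypothesis BFs to configuration counts
  all_masked <- mask_labf(labf, ld, panel$snp[c(1, 50, 100, 150, 200, 240)],
                          r2_threshold = 0)
  expect_true(all(all_masked == 0))
  n <- length(all_masked)
  expect_equal(hypothesis_labf(all_masked, all_masked),
               c(H1 = log(n), H2 = log(n), H3 = log(n * (n - 1)),
                 H4 = log(n)))
  expect_error(mask_labf(labf, ld, "nosuch"), "nosuch")
})

# per-SNP z from a signed summary, for readable assertions
region_z_public <- function(d) d$beta / sqrt(d$varbeta)

test_that("stepwise discovery finds the right number of independent signals", {
  panel <- shared_panel()
  cm <- filter_maf(panel)
  pl <- shared_panel_ld()

  # null region: nothing reaches the threshold
  sim0 <- simulate_trait_pair(panel, N1 = 2000, truth = sim_truth("H0"),
                              seed = 41, return_ld = TRUE)
  s0 <- stepwise_signals(sim0$d1, sim0$ld1, method = "mask")
  expect_length(s0$lead_ids, 0)

  # one strong causal variant: exactly one lead, the top SNP
  set.seed(42)
  t1 <- draw_truth(cm, "H1", effect_set = 0.5)
  sim1 <- simulate_trait_pair(panel, N1 = 5000, truth = t1, seed = 43,
                              return_ld = TRUE)
  for (m in c("mask", "cond")) {
    s1 <- stepwise_signals(sim1$d1, sim1$ld1, method = m)
    expect_identical(s1$lead_ids,
                     sim1$d1$snp[which.max(abs(region_z_public(sim1$d1)))])
  }

  # two independent causal variants, both significant: two leads tagging
  # distinct causal variants
  t2 <- sim_truth("custom", causal1 = c("rs0052", "rs0188"),
                  beta1 = c(0.5, 0.5), causal2 = character(0),
                  beta2 = numeric(0))
  expect_lt(pl["rs0052", "rs0188"]^2, 0.01)
  sim2 <- simulate_trait_pair(panel, N1 = 5000, truth = t2, seed = 44,
                              return_ld = TRUE)
  for (m in c("mask", "cond")) {
    s2 <- stepwise_signals(sim2$d1, sim2$ld1, method = m)
    expect_length(s2$lead_ids, 2)
    r2_to_causal <- sim2$ld1[s2$lead_ids, c("rs0052", "rs0188")]^2
    # each lead tags one causal variant strongly, and different ones
    expect_true(all(apply(r2_to_causal, 1, max) > 0.8))
    expect_length(unique(apply(r2_to_causal, 1, which.max)), 2)
  }

  # the cap reduces every mode to single-signal behaviour
  s_cap <- stepwise_signals(sim2$d1, sim2$ld1, method = "mask",
                            max_signals = 1)
  expect_length(s_cap$lead_ids, 1)
})

test_that("coloc_signals reduces to coloc_abf for one signal per trait", {
  panel <- shared_panel()
  set.seed(51)
  t4 <- draw_truth(filter_maf(panel), "H4", effect_set = 0.67)
  sim <- simulate_trait_pair(panel, N1 = 5000, truth = t4, seed = 52,
                             return_ld = TRUE)
  plain <- coloc_abf(sim$d1, sim$d2)
  sg <- coloc_signals(sim$d1, sim$d2, sim$ld1, sim$ld2,
                      mode1 = "cond", mode2 = "mask")
  expect_length(sg$results, 1)
  expect_equal(sg$results[[1]]$pp, plain$pp, tolerance = 1e-10)
  expect_false(any(is.na(sg$results[[1]]$leads)))
})

test_that("n leads for trait 1 and m for trait 2 give n x m comparisons", {
  panel <- shared_panel()
  truth <- sim_truth("custom", causal1 = c("rs0052", "rs0188"),
                     beta1 = c(0.5, 0.5), causal2 = "rs0188", beta2 = 0.5)
  sim <- simulate_trait_pair(panel, N1 = 5000, truth = truth, seed = 53,
                             return_ld = TRUE)
  sg <- coloc_signals(sim$d1, sim$d2, sim$ld1, sim$ld2,
                      mode1 = "cond", mode2 = "cond")
  expect_length(sg$results, 2 * 1)
  tab <- summary(sg)
  expect_identical(sort(unique(tab$lead1)), sort(sg$signals1$lead_ids))
})

test_that("comparisons are labelled by LD with known causal variants", {
  ld <- shared_panel_ld()
  # an artificial near-perfect proxy: copy rs0125's column into the matrix
  proxy_ld <- unclass(ld)
  proxy_ld["rs0101", ] <- proxy_ld[, "rs0101"] <- 0.98 * proxy_ld["rs0125", ]
  proxy_ld["rs0101", "rs0101"] <- 1
  proxy_ld["rs0101", "rs0125"] <- proxy_ld["rs0125", "rs0101"] <- 0.98
  lab <- label_comparison("rs0101", "rs0125", c("rs0125", "rs0052"), proxy_ld)
  expect_identical(unname(lab), c("rs0125", "rs0125"))
  # the causal variant itself always labels as itself (r2 = 1)
  lab2 <- label_comparison("rs0052", "rs0052", c("rs0125", "rs0052"), ld)
  expect_identical(unname(lab2), c("rs0052", "rs0052"))
  # weak LD to every causal variant: ambiguous
  far <- "rs0001"
  expect_lt(max(ld[far, c("rs0125", "rs0052")]^2), 0.8)
  lab3 <- label_comparison(far, "rs0125", c("rs0125", "rs0052"), ld)
  expect_identical(unname(lab3), c("?", "rs0125"))
  expect_error(label_comparison("nosuch", "rs0125", "rs0125", ld), "nosuch")
})

test_that("masking approximates conditioning when causal variants are independent", {
  # trait 1 has two independent causal variants, trait 2 shares the weaker
  # one; compare matched lead pairs between mask and cond analyses
  panel <- shared_panel()
  pl <- shared_panel_ld()
  truth <- sim_truth("custom", causal1 = c("rs0052", "rs0188"),
                     beta1 = c(0.67, 0.33), causal2 = "rs0188", beta2 = 0.67)
  diffs <- c()
  for (r in 1:40) {
    sim <- simulate_trait_pair(panel, N1 = 5000, truth = truth,
                               seed = 6000 + r, return_ld = TRUE)
    res <- lapply(c("cond", "mask"), function(m)
      summary(coloc_signals(sim$d1, sim$d2, sim$ld1, sim$ld2,
                            mode1 = m, mode2 = m)))
    key <- function(tab) {
      labs <- t(mapply(function(a, b)
        label_comparison(a, b, c("rs0052", "rs0188"), pl),
        tab$lead1, tab$lead2))
      paste(labs[, 1], labs[, 2])
    }
    k1 <- key(res[[1]]); k2 <- key(res[[2]])
    shared <- intersect(k1, k2)
    diffs <- c(diffs, abs(res[[1]]$H4[match(shared, k1)] -
                            res[[2]]$H4[match(shared, k2)]))
  }
  expect_gt(length(diffs), 40)
  expect_lt(mean(diffs), 0.1)
})
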