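Package: paircoloc
Title: Bayesian Pairwise Colocalisation of GWAS Summary Statistics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Colocalisation analysis for pairs of genetic association
    studies from regional summary statistics. Enumerates causal-variant
    configurations under the assumption of at most one causal variant per
    trait, scoring the five regional hypotheses (no association;
    association to one trait only; two distinct causal variants; one
    shared causal variant) with Wakefield approximate Bayes factors.
    Provides principled elicitation of the per-SNP prior parameters via a
    marginal reparameterisation and admissible bounds, fast posterior
    sensitivity analysis by prior reweighting, relaxation of the
    single-causal-variant assumption by approximate conditioning from
    summary statistics plus a signed LD matrix or by LD-masking of lead
    signals, and a haplotype-based simulator of regional association
    statistics with known ground truth for validating inference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: grDevices, graphics, stats, utils
Suggests: jsonlite, optparse, testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
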