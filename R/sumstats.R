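#' Regional GWAS summary statistics for one trait
#'
#' Container for per-SNP single-SNP association statistics in one genomic
#' region for one trait, together with the study metadata needed by the
#' colocalisation machinery. Either signed effect estimates with their
#' squared standard errors (`beta`, `varbeta`) or two-sided `pvalues` with
#' minor allele frequencies must be supplied for every SNP; in the latter
#' case unsigned effects can be recovered with [reconstruct_effects()].
#'
#' @param snp character vector of unique SNP identifiers.
#' @param beta per-SNP effect estimates (trait units per allele dose),
#'   signed and aligned to the same effect alleles as any LD matrix used
#'   downstream.
#' @param varbeta per-SNP squared standard errors, strictly positive.
#' @param pvalues two-sided p-values, an alternative to `beta`/`varbeta`.
#' @param maf minor allele frequencies in (0, 0.5].
#' @param position optional base-pair positions (informational only; SNP
#'   identity is by id string).
#' @param type trait type, `"quant"` (quantitative) or `"cc"`
#'   (case-control with effects on the log-odds scale).
#' @param N total sample size of the study.
#' @param s case fraction in (0,1); required when `type = "cc"`.
#' @param sdY standard deviation of the quantitative trait; may be `NULL`,
#'   in which case it is estimated from the data where possible (see
#'   [estimate_sdY()]).
#' @param signed logical; `TRUE` when `beta` carries its true sign.
#'   Effects reconstructed from p-values are unsigned and are refused by
#'   operations that need signs (conditioning).
#'
#' @return An object of class `region_summary`.
#' @seealso [read_region_summary()], [reconstruct_effects()],
#'   [harmonise_regions()]
#' @export
region_summary <- function(snp, beta = NULL, varbeta = NULL, pvalues = NULL,
                           maf = NULL, position = NULL,
                           type = c("quant", "cc"), N, s = NULL, sdY = NULL,
                           signed = !is.null(beta)) {
  type <- match.arg(type)
  snp <- as.character(snp)
  n <- length(snp)
  if (n < 1L) stopf("a region must contain at least one SNP")
  if (anyDuplicated(snp))
    stopf("duplicate SNP id(s): %s",
          paste(unique(snp[duplicated(snp)]), collapse = ", "))
  chk_len <- function(x, nm, numeric = TRUE) {
    if (is.null(x)) return(NULL)
    if (numeric) x <- as.numeric(x)
    if (length(x) != n)
      stopf("'%s' must have length %d (one entry per SNP)", nm, n)
    x
  }
  beta <- chk_len(beta, "beta")
  varbeta <- chk_len(varbeta, "varbeta")
  pvalues <- chk_len(pvalues, "pvalues")
  maf <- chk_len(maf, "maf")
  position <- chk_len(position, "position", numeric = FALSE)

  have_bv <- !is.null(beta) && !is.null(varbeta)
  have_pm <- !is.null(pvalues) && !is.null(maf)
  if (!have_bv && !have_pm)
    stopf("either (beta, varbeta) or (pvalues, maf) must be given for every SNP")
  if (have_bv) {
    if (any(!is.finite(beta)) || any(!is.finite(varbeta)))
      stopf("beta and varbeta must be finite")
    if (any(varbeta <= 0)) stopf("varbeta must be strictly positive")
  }
  if (!is.null(maf) && any(maf <= 0 | maf > 0.5))
    stopf("maf must lie in (0, 0.5]")
  if (!is.null(pvalues) && any(pvalues <= 0 | pvalues > 1))
    stopf("pvalues must lie in (0, 1]")
  if (!is.numeric(N) || length(N) != 1L || N < 2)
    stopf("'N' must be a single sample size >= 2")
  if (type == "cc") {
    if (is.null(s) || !is_scalar_prob(s))
      stopf("case fraction 's' in (0,1) is required for case-control traits")
  }
  if (!is.null(sdY) && (!is.numeric(sdY) || sdY <= 0))
    stopf("'sdY' must be a positive scalar")

  structure(list(snp = snp, position = position, beta = beta,
                 varbeta = varbeta, pvalues = pvalues, maf = maf,
                 type = type, N = N, s = s, sdY = sdY,
                 signed = isTRUE(signed) && have_bv),
            class = "region_summary")
}

#' @export
print.region_summary <- function(x, ...) {
  cat(sprintf("Regional summary statistics: %d SNPs, %s trait, N = %g\n",
              length(x$snp), if (x$type == "quant") "quantitative"
              else sprintf("case-control (s = %g)", x$s), x$N))
  if (requires_reconstruction(x))
    cat("  p-value + MAF input: effects require reconstruction",
        "(see reconstruct_effects)\n")
  else
    cat(sprintf("  effect estimates %s\n",
                if (x$signed) "signed" else "unsigned (reconstructed)"))
  invisible(x)
}

#' Does a region still need effect reconstruction?
#'
#' `TRUE` when a [region_summary()] was supplied with p-values and MAF only,
#' so that `beta`/`varbeta` must be filled in by [reconstruct_effects()]
#' before Bayes factors can be computed.
#'
#' @param d a `region_summary`.
#' @return logical scalar.
#' @export
requires_reconstruction <- function(d) {
  stopifnot(inherits(d, "region_summary"))
  is.null(d$beta) || is.null(d$varbeta)
}

#' Read regional summary statistics from a delimited file
#'
#' Reads a tab- (or general whitespace-) delimited file with header columns
#' `snp`, optionally `position`, and either `beta` and `varbeta` or
#' `pvalue` and `maf` (both pairs may be present). Rows with missing
#' required fields are dropped with a message stating the count.
#'
#' @param path path to the file.
#' @inheritParams region_summary
#' @return A validated [region_summary()].
#' @export
read_region_summary <- function(path, type = c("quant", "cc"), N,
                                s = NULL, sdY = NULL) {
  type <- match.arg(type)
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"snp" %in% names(tab))
    stopf("missing required column 'snp' in %s", path)
  have_bv <- all(c("beta", "varbeta") %in% names(tab))
  have_pm <- all(c("pvalue", "maf") %in% names(tab))
  if (!have_bv && !have_pm)
    stopf("%s must contain columns (beta, varbeta) and/or (pvalue, maf)", path)
  need <- c("snp", if (have_bv) c("beta", "varbeta"),
            if (have_pm) c("pvalue", "maf"))
  keep <- stats::complete.cases(tab[need])
  if (any(!keep)) {
    message(sprintf("dropped %d row(s) with missing required fields", sum(!keep)))
    tab <- tab[keep, , drop = FALSE]
  }
  if (nrow(tab) == 0L) stopf("no complete rows in %s", path)
  if (anyDuplicated(tab$snp))
    stopf("duplicate SNP id(s) in %s: %s", path,
          paste(unique(tab$snp[duplicated(tab$snp)]), collapse = ", "))
  region_summary(snp = tab$snp,
                 beta = if (have_bv) tab$beta,
                 varbeta = if (have_bv) tab$varbeta,
                 pvalues = if (have_pm) tab$pvalue,
                 maf = if ("maf" %in% names(tab)) tab$maf,
                 position = if ("position" %in% names(tab)) tab$position,
                 type = type, N = N, s = s, sdY = sdY)
}

#' Reconstruct (unsigned) effect estimates from p-values and MAF
#'
#' Recovers per-SNP effect estimates and their variances from two-sided
#' p-values, minor allele frequencies and the study design:
#' `varbeta = sdY^2 / (2 N maf (1 - maf))` for quantitative traits and
#' `varbeta = 1 / (2 N maf (1 - maf) s (1 - s))` for case-control traits,
#' with `|beta| = z * sqrt(varbeta)` where `z` is the two-sided standard
#' normal quantile of the p-value. Reconstructed betas are unsigned and the
#' result is flagged accordingly; operations requiring signs (conditioning)
#' will refuse it.
#'
#' @param d a [region_summary()] with `pvalues` and `maf`.
#' @return A `region_summary` with `beta` and `varbeta` filled in and
#'   `signed = FALSE`.
#' @export
reconstruct_effects <- function(d) {
  stopifnot(inherits(d, "region_summary"))
  if (is.null(d$pvalues) || is.null(d$maf))
    stopf("reconstruction requires both pvalues and maf")
  sdY <- d$sdY
  if (d$type == "quant" && is.null(sdY)) {
    warnf("sdY neither supplied nor estimable from p-value input; assuming sdY = 1")
    sdY <- 1
  }
  denom <- 2 * d$N * d$maf * (1 - d$maf)
  varbeta <- if (d$type == "quant") sdY^2 / denom
             else 1 / (denom * d$s * (1 - d$s))
  z <- p_to_z(d$pvalues)
  d$beta <- z * sqrt(varbeta)
  d$varbeta <- varbeta
  d$signed <- FALSE
  d
}

#' Estimate the trait standard deviation from summary statistics
#'
#' For a quantitative trait, `1/varbeta` is approximately
#' `2 N maf (1-maf) / sdY^2`, so a regression through the origin of
#' `1/varbeta` on `2 N maf (1-maf)` has slope `1/sdY^2`. Returns
#' `sqrt(1/slope)`.
#'
#' @param d a [region_summary()] with `varbeta`, `maf` and `N`
#'   (at least 2 SNPs).
#' @return Positive scalar estimate of the trait SD.
#' @export
estimate_sdY <- function(d) {
  stopifnot(inherits(d, "region_summary"))
  if (is.null(d$varbeta) || is.null(d$maf))
    stopf("sdY estimation requires varbeta and maf")
  if (length(d$snp) < 2L) stopf("sdY estimation requires at least 2 SNPs")
  x <- 2 * d$N * d$maf * (1 - d$maf)
  y <- 1 / d$varbeta
  slope <- sum(x * y) / sum(x * x)
  if (!is.finite(slope) || slope <= 0)
    stopf("non-positive slope in sdY estimation; please supply 'sdY' explicitly")
  sqrt(1 / slope)
}

# restrict a region_summary to an index vector, preserving metadata
subset_region <- function(d, idx) {
  for (f in c("snp", "position", "beta", "varbeta", "pvalues", "maf"))
    if (!is.null(d[[f]])) d[[f]] <- d[[f]][idx]
  d
}

# per-SNP |z| (or signed z when signs are available)
region_z <- function(d) {
  if (!requires_reconstruction(d)) d$beta / sqrt(d$varbeta)
  else p_to_z(d$pvalues)
}

# marginal two-sided p-values, from stored values or from z
region_p <- function(d) {
  if (!is.null(d$pvalues)) d$pvalues else z_to_p(region_z(d))
}

# log p-values for ranking: computed from z where possible so that
# extremely significant SNPs are ordered correctly instead of tying at the
# double floor
region_logp <- function(d) {
  if (!requires_reconstruction(d)) logp_from_z(region_z(d))
  else log(d$pvalues)
}

logp_from_z <- function(z) log(2) + stats::pnorm(-abs(z), log.p = TRUE)

#' Restrict two regions (and optional LD matrices) to their shared SNPs
#'
#' Subsets both [region_summary()] objects, and any accompanying LD
#' matrices, to the SNPs present in both, in a single common order (that of
#' `d1`). Counts of dropped SNPs are reported per input. The operation is
#' idempotent.
#'
#' @param d1,d2 `region_summary` objects for the two traits.
#' @param ld1,ld2 optional signed LD matrices (see [ld_matrix()]) aligned
#'   to the respective datasets.
#' @return A list with elements `d1`, `d2`, `ld1`, `ld2` restricted to the
#'   shared SNP set.
#' @export
harmonise_regions <- function(d1, d2, ld1 = NULL, ld2 = NULL) {
  stopifnot(inherits(d1, "region_summary"), inherits(d2, "region_summary"))
  shared <- intersect(d1$snp, d2$snp)
  if (length(shared) == 0L)
    stopf("no SNP ids shared between the two datasets")
  shared <- d1$snp[d1$snp %in% shared]   # keep d1 order
  report <- function(nm, tot) {
    nd <- tot - length(shared)
    if (nd > 0) message(sprintf("harmonise: dropped %d SNP(s) from %s", nd, nm))
  }
  report("trait 1", length(d1$snp)); report("trait 2", length(d2$snp))
  out <- list(d1 = subset_region(d1, match(shared, d1$snp)),
              d2 = subset_region(d2, match(shared, d2$snp)))
  for (nm in c("ld1", "ld2")) {
    ld <- get(nm)
    if (!is.null(ld)) {
      miss <- setdiff(shared, rownames(ld))
      if (length(miss))
        stopf("%s lacks SNP(s) present in both datasets: %s", nm,
              paste(utils::head(miss, 3), collapse = ", "))
      report(nm, nrow(ld))
      out[[nm]] <- ld[shared, shared, drop = FALSE]
    } else out[nm] <- list(NULL)
  }
  out
}
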