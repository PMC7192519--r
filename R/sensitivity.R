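#' Re-derive posteriors under alternative priors without new Bayes factors
#'
#' Posteriors satisfy `P(Hi | D, prior*) ∝ P(Hi | D, prior) *
#' P(Hi | prior*) / P(Hi | prior)`, so a fitted [coloc_abf()] result can
#' be re-expressed under any alternative prior by reweighting and
#' renormalising; the data enter only through the already-computed Bayes
#' factors, which are left untouched. The prior ratios are taken in the
#' same per-configuration form used by [coloc_posterior()], making the
#' identity exact.
#'
#' @param result a `coloc_result`.
#' @param new_priors a [prior_params()] object, feasible at the result's
#'   region size (checked via [hypothesis_priors()]).
#' @return A `coloc_result` with updated `pp` and `priors`.
#' @export
reweight_posteriors <- function(result, new_priors) {
  stopifnot(inherits(result, "coloc_result"), inherits(new_priors, "prior_params"))
  hypothesis_priors(result$nsnps, new_priors)   # errors if infeasible
  old <- result$priors
  lr <- c(0,
          log(new_priors$p1) - log(old$p1),
          log(new_priors$p2) - log(old$p2),
          log(new_priors$p1 * new_priors$p2) - log(old$p1 * old$p2),
          log(new_priors$p12) - log(old$p12))
  lpp <- log(result$pp) + lr
  pp <- exp(lpp - logsumexp(lpp))
  names(pp) <- names(result$pp)
  result$pp <- pp
  result$priors <- new_priors
  result
}

#' Evaluate a decision rule on posterior probabilities
#'
#' Rules are tiny arithmetic-comparison expressions over the symbols
#' `H0`..`H4`, numeric literals, `+ - * /`, parentheses, comparisons and
#' logical connectives, e.g. `"H4 > 0.5"` or `"H4/(H3+H4) > 0.9"`. No
#' other function or symbol is allowed; the expression is parsed and
#' checked before evaluation, so rules cannot execute general code.
#'
#' @param pp a named posterior vector (`H0`..`H4`) or a `coloc_result`.
#' @param rule the rule as a character string.
#' @return Logical verdict.
#' @export
evaluate_rule <- function(pp, rule) {
  if (inherits(pp, "coloc_result")) pp <- pp$pp
  if (is.null(names(pp)) || !all(paste0("H", 0:4) %in% names(pp)))
    stopf("'pp' must carry names H0..H4")
  expr <- tryCatch(str2lang(rule),
                   error = function(e)
                     stopf("parse error in rule '%s': %s", rule,
                           conditionMessage(e)))
  allowed_ops <- c("+", "-", "*", "/", "(", ">", "<", ">=", "<=",
                   "==", "!=", "&", "|", "!", "&&", "||")
  check <- function(e) {
    if (is.numeric(e)) return(invisible())
    if (is.symbol(e)) {
      if (!as.character(e) %in% paste0("H", 0:4))
        stopf("unknown symbol '%s' in rule (only H0..H4 are allowed)",
              as.character(e))
      return(invisible())
    }
    if (is.call(e)) {
      op <- as.character(e[[1]])
      if (!op %in% allowed_ops)
        stopf("operator or function '%s' is not allowed in rules", op)
      for (i in seq_along(e)[-1]) check(e[[i]])
      return(invisible())
    }
    stopf("unsupported element in rule: %s", deparse(e))
  }
  check(expr)
  isTRUE(eval(expr, envir = as.list(pp), enclos = baseenv()))
}

#' Scan a decision rule over a grid of joint-causality priors
#'
#' Reweights a fitted result over a log-spaced grid of `p12` values
#' (holding `p1` and `p2` fixed at their analysis values), records
#' per-hypothesis priors and posteriors at each point, and evaluates a
#' decision rule, summarising the range of `p12` over which the
#' conclusion survives.
#'
#' @param result a `coloc_result`.
#' @param rule decision rule string (see [evaluate_rule()]); default
#'   `"H4 > 0.5"`.
#' @param p12_from,p12_to endpoints of the `p12` grid.
#' @param n_grid number of (log-spaced) grid points.
#' @return A data frame of class `sensitivity_table` with columns `p12`,
#'   `prior.H0`..`prior.H4`, `pp.H0`..`pp.H4` and `pass`; attributes
#'   record the rule and the analysis `p12`.
#' @export
sensitivity_grid <- function(result, rule = "H4 > 0.5",
                             p12_from = 1e-8, p12_to = 1e-4, n_grid = 100) {
  stopifnot(inherits(result, "coloc_result"))
  if (!(p12_from > 0 && p12_to > p12_from))
    stopf("need 0 < p12_from < p12_to")
  p1 <- result$priors$p1; p2 <- result$priors$p2
  grid <- 10^seq(log10(p12_from), log10(p12_to), length.out = n_grid)
  feasible <- vapply(grid, function(g) {
    ok <- tryCatch({
      hypothesis_priors(result$nsnps, prior_params(p1, p2, g)); TRUE
    }, error = function(e) FALSE)
    ok
  }, logical(1))
  if (!any(feasible)) stopf("no feasible p12 values in the requested range")
  grid <- grid[feasible]
  rows <- lapply(grid, function(g) {
    pr <- prior_params(p1, p2, g)
    hp <- hypothesis_priors(result$nsnps, pr)
    pp <- reweight_posteriors(result, pr)$pp
    c(p12 = g, stats::setNames(hp, paste0("prior.", names(hp))),
      stats::setNames(pp, paste0("pp.", names(pp))))
  })
  out <- as.data.frame(do.call(rbind, rows))
  out$pass <- vapply(seq_len(nrow(out)), function(i)
    evaluate_rule(stats::setNames(unlist(out[i, paste0("pp.H", 0:4)]),
                                  paste0("H", 0:4)), rule),
    logical(1))
  attr(out, "rule") <- rule
  attr(out, "p12_analysis") <- result$priors$p12
  class(out) <- c("sensitivity_table", "data.frame")
  out
}

#' @export
print.sensitivity_table <- function(x, ...) {
  rule <- attr(x, "rule")
  cat(sprintf("Sensitivity scan of rule '%s' over %d values of p12 in [%.3g, %.3g]\n",
              rule, nrow(x), min(x$p12), max(x$p12)))
  if (any(x$pass))
    cat(sprintf("rule passes for p12 in [%.3g, %.3g] (%d/%d grid points)\n",
                min(x$p12[x$pass]), max(x$p12[x$pass]), sum(x$pass), nrow(x)))
  else cat("rule passes nowhere on the grid\n")
  invisible(x)
}

#' Plot prior and posterior sensitivity panels
#'
#' Two panels against `log10(p12)`: per-hypothesis priors (H0 omitted so
#' the other hypotheses remain visible) and posteriors, with the analysis
#' `p12` marked and the passing region shaded.
#'
#' @param x a `sensitivity_table`.
#' @param ... ignored.
#' @export
plot.sensitivity_table <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  lx <- log10(x$p12)
  cols <- c("grey40", "#1b9e77", "#7570b3", "#d95f02", "#e7298a")
  draw <- function(ycols, main, omit_h0) {
    idx <- if (omit_h0) 2:5 else 1:5
    graphics::matplot(lx, as.matrix(x[, ycols[idx]]), type = "l", lty = 1,
                      col = cols[idx], xlab = "log10(p12)",
                      ylab = "probability", main = main)
    if (any(x$pass))
      graphics::rect(min(lx[x$pass]), -0.04, max(lx[x$pass]), 1.04,
                     col = grDevices::adjustcolor("green", 0.1), border = NA)
    graphics::abline(v = log10(attr(x, "p12_analysis")), lty = 2)
    graphics::legend("topleft", legend = paste0("H", idx - 1), col = cols[idx],
                     lty = 1, bty = "n", cex = 0.8)
  }
  draw(paste0("prior.H", 0:4), "priors", omit_h0 = TRUE)
  draw(paste0("pp.H", 0:4), sprintf("posteriors (rule: %s)", attr(x, "rule")),
       omit_h0 = FALSE)
  invisible(x)
}
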