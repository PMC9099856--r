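#' Correlate computed binding free energies with experimental potencies
#'
#' Ordinary least squares of (optionally log10-transformed) potency on the
#' computed free energy (`y = x * a + b`), with the Pearson correlation
#' coefficient of the pairs. Potencies are log10-transformed by default
#' (pharmacological convention for IC50 values in nM).
#'
#' @param dg computed free energies, kcal/mol.
#' @param potency experimental potencies (e.g. IC50 in nM).
#' @param transform `"log10"` (default) or `"identity"`.
#' @return object of class `regression_result`: `slope`, `intercept`,
#'   `pearson_r`, `n`, `conf_int_slope` (95%), and the underlying `lm`
#'   fit.
#' @export
fit_dg_activity <- function(dg, potency, transform = c("log10", "identity")) {
  transform <- match.arg(transform)
  if (length(dg) != length(potency)) stop("input error: unequal lengths")
  if (length(dg) < 3) stop("input error: need at least 3 pairs")
  y <- if (transform == "log10") {
    if (any(potency <= 0)) stop("input error: non-positive potency under log10")
    log10(potency)
  } else potency
  if (stats::sd(dg) < 1e-12 || stats::sd(y) < 1e-12)
    stop("undefined-r error: zero variance in one variable")
  fit <- stats::lm(y ~ dg)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    pearson_r = stats::cor(dg, y),
    n = length(dg),
    conf_int_slope = unname(stats::confint(fit)["dg", ]),
    transform = transform,
    fit = fit
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "Linear fit (n = %d, %s potency): y = x * %.4f + %.4f, Pearson r = %.4f\n",
    x$n, x$transform, x$slope, x$intercept, x$pearson_r))
  invisible(x)
}

#' Compare the free energies of two orientation ensembles
#'
#' Two-sided Welch unequal-variance t-test of the group means, with the
#' group moments reported alongside.
#'
#' @param dg_a,dg_b free energies of the two groups, kcal/mol (each
#'   n >= 2).
#' @param alpha significance level for the `significant` flag.
#' @return object of class `group_comparison`: group means/SDs/sizes,
#'   `t_statistic`, `df`, `p_value`, `significant`, `test = "Welch"`.
#' @export
compare_orientations <- function(dg_a, dg_b, alpha = 0.05) {
  if (length(dg_a) < 2 || length(dg_b) < 2)
    stop("input error: each group needs at least 2 values")
  ht <- stats::t.test(dg_a, dg_b, var.equal = FALSE,
                      alternative = "two.sided")
  structure(list(
    mean_a = mean(dg_a), sd_a = stats::sd(dg_a), n_a = length(dg_a),
    mean_b = mean(dg_b), sd_b = stats::sd(dg_b), n_b = length(dg_b),
    t_statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value, significant = ht$p.value < alpha,
    test = "Welch"
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("Group A: %.2f +/- %.2f (n = %d)\n",
           "Group B: %.2f +/- %.2f (n = %d)\n",
           "Welch t = %.3f (df = %.1f), two-sided p = %.4g%s\n"),
    x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b,
    x$t_statistic, x$df, x$p_value,
    if (x$significant) " *" else ""))
  invisible(x)
}
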