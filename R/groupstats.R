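# One-way fixed-effects group comparisons: ANOVA decomposition, orthogonal
# contrasts and Tukey-adjusted pairwise tests. The single-effect mixed-model
# layout used for this design (species-plus-origin as one fixed effect, no
# random terms) reduces exactly to one-way ANOVA, so it is implemented as
# such, with closed-form sums of squares; stats::aov serves as independent
# oracle in the test suite.

#' Fit a one-way group model
#'
#' @param values Numeric response, one value per sample.
#' @param groups Group labels (coerced to factor; level order is kept as
#'   given for factors, otherwise order of first appearance).
#' @return An object of class `oneway_fit`: group means and sizes, sums of
#'   squares, `mse`, `df1`, `df2`, `f`, `p`, and the pooled `sem`
#'   (`sqrt(MSE/n)` under balance). With zero within-group variance the F
#'   statistic is `NA` and `zero_variance` is `TRUE`.
#' @export
#' @examples
#' fit <- fit_oneway(c(1, 2, 3, 2, 3, 4, 6, 7, 8), rep(c("a", "b", "c"), each = 3))
#' fit$f    # 21
#' fit$sem  # 0.5774
fit_oneway <- function(values, groups) {
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  groups <- droplevels(groups)
  values <- as.numeric(values)
  if (length(values) != length(groups))
    stop("'values' and 'groups' lengths differ", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite values", call. = FALSE)
  n_i <- tabulate(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(n_i < 2L))
    stop("every group needs at least 2 samples", call. = FALSE)

  g <- nlevels(groups); N <- length(values)
  means <- stats::setNames(as.numeric(tapply(values, groups, mean)),
                           levels(groups))
  grand <- mean(values)
  ss_between <- sum(n_i * (means - grand)^2)
  ss_within <- sum((values - means[as.integer(groups)])^2)
  df1 <- g - 1L; df2 <- N - g
  mse <- ss_within / df2
  zero_var <- mse <= .Machine$double.eps * max(1, grand^2)
  f <- if (zero_var) NA_real_ else (ss_between / df1) / mse
  p <- if (zero_var) NA_real_ else stats::pf(f, df1, df2, lower.tail = FALSE)
  balanced <- length(unique(n_i)) == 1L
  sem <- if (balanced) sqrt(mse / n_i[1L]) else sqrt(mse * mean(1 / n_i))
  structure(list(levels = levels(groups), n = stats::setNames(n_i, levels(groups)),
                 means = means, grand_mean = grand,
                 ss_between = ss_between, ss_within = ss_within,
                 df1 = df1, df2 = df2, mse = mse, f = f, p = p,
                 sem = sem, balanced = balanced, zero_variance = zero_var),
            class = "oneway_fit")
}

#' @export
print.oneway_fit <- function(x, ...) {
  cat("One-way fit: ", length(x$levels), " groups, N = ", sum(x$n), "\n", sep = "")
  print(round(x$means, 4))
  cat(sprintf("  MSE = %.4g, pooled SEM = %.4g, F(%d, %d) = %.4g, p = %.4g\n",
              x$mse, x$sem, x$df1, x$df2,
              ifelse(is.na(x$f), NaN, x$f), ifelse(is.na(x$p), NaN, x$p)))
  invisible(x)
}

#' Built-in orthogonal contrasts for the three-origin design
#'
#' `a_vs_p` compares the unweighted average of the two Atlantic origins
#' (Norway, Iceland) with the Pacific origin (Alaska); `n_vs_i` compares
#' Norway with Iceland. The two weight vectors are orthogonal under the
#' balanced design.
#'
#' @return Named list of two named weight vectors over
#'   (Norway, Iceland, Alaska).
#' @export
cod_contrasts <- function() {
  list(a_vs_p = c(Norway = 0.5, Iceland = 0.5, Alaska = -1),
       n_vs_i = c(Norway = 1, Iceland = -1, Alaska = 0))
}

#' Test a linear contrast of group means
#'
#' Estimate `sum(c_i * mean_i)` with standard error
#' `sqrt(MSE * sum(c_i^2 / n_i))`, a t statistic on the residual degrees of
#' freedom, and a two-sided p-value.
#'
#' @param fit An `oneway_fit`.
#' @param weights Numeric contrast weights summing to zero; if named, they
#'   are matched to the fit's group levels.
#' @return List with `estimate`, `se`, `t`, `df`, `p`, `weights`.
#' @export
#' @examples
#' fit <- fit_oneway(c(1, 2, 3, 2, 3, 4, 6, 7, 8), rep(c("a", "b", "c"), each = 3))
#' contrast_test(fit, c(1, -1, 0))
contrast_test <- function(fit, weights) {
  stopifnot(inherits(fit, "oneway_fit"))
  if (!is.null(names(weights))) {
    if (!setequal(names(weights), fit$levels))
      stop("contrast names must match the group levels", call. = FALSE)
    weights <- weights[fit$levels]
  }
  if (length(weights) != length(fit$levels))
    stop("need one weight per group", call. = FALSE)
  if (abs(sum(weights)) > 1e-8)
    stop("contrast weights must sum to zero", call. = FALSE)
  est <- sum(weights * fit$means)
  se <- sqrt(fit$mse * sum(weights^2 / fit$n))
  tt <- est / se
  list(estimate = est, se = se, t = tt, df = fit$df2,
       p = 2 * stats::pt(-abs(tt), fit$df2), weights = weights)
}

#' Tukey-adjusted pairwise comparisons
#'
#' Pairwise least-squares mean differences tested against the studentized
#' range distribution at the fitted MSE (Tukey HSD adjustment).
#'
#' @param fit An `oneway_fit`.
#' @return Data frame with one row per group pair: `group1`, `group2`,
#'   `diff`, `se`, `q`, `p_adj`.
#' @export
tukey_pairwise <- function(fit) {
  stopifnot(inherits(fit, "oneway_fit"))
  lv <- fit$levels; k <- length(lv)
  out <- NULL
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    d <- fit$means[j] - fit$means[i]
    se <- sqrt(fit$mse / 2 * (1 / fit$n[i] + 1 / fit$n[j]))
    q <- abs(d) / se
    p <- stats::ptukey(q, k, fit$df2, lower.tail = FALSE)
    out <- rbind(out, data.frame(group1 = lv[i], group2 = lv[j],
                                 diff = unname(d), se = unname(se),
                                 q = unname(q), p_adj = unname(p),
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Group comparison table across variables
#'
#' Applies the one-way fit plus the two built-in contrasts to every named
#' variable of a per-sample table, producing the familiar layout of group
#' means, pooled SEM and contrast p-values.
#'
#' @param data Data frame of per-sample values including an `origin` column.
#' @param variables Character vector of numeric column names to compare.
#' @param alpha Significance level annotated on the output (default 0.05).
#' @return Data frame, one row per variable: per-origin means, `sem`,
#'   `p_avsp`, `p_nvsi`, `f`, `p_overall`, `signif` flag at `alpha`.
#' @export
compare_groups <- function(data, variables, alpha = 0.05) {
  stopifnot(is.data.frame(data), "origin" %in% names(data))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  ctr <- cod_contrasts()
  origin <- factor(data$origin, levels = origin_levels())
  rows <- lapply(variables, function(v) {
    fit <- fit_oneway(data[[v]], origin)
    ca <- contrast_test(fit, ctr$a_vs_p)
    cn <- contrast_test(fit, ctr$n_vs_i)
    data.frame(variable = v, t(fit$means), sem = fit$sem,
               p_avsp = ca$p, p_nvsi = cn$p, f = fit$f, p_overall = fit$p,
               signif = !is.na(fit$p) && fit$p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
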