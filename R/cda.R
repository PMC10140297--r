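# Canonical discriminant analysis for origin authentication: Wilks-lambda
# forward stepwise variable selection, eigen-decomposition of the
# within/between scatter problem, a pooled-covariance (linear, equal-prior)
# Mahalanobis classifier, and leave-one-out cross-validation.

# between/within/total scatter matrices for X (n x p) and a factor g
scatter_matrices <- function(X, g) {
  X <- as.matrix(X)
  g <- droplevels(as.factor(g))
  Tm <- crossprod(sweep(X, 2, colMeans(X)))
  W <- matrix(0, ncol(X), ncol(X), dimnames = dimnames(Tm))
  for (lv in levels(g)) {
    Xi <- X[g == lv, , drop = FALSE]
    W <- W + crossprod(sweep(Xi, 2, colMeans(Xi)))
  }
  list(total = Tm, within = W, between = Tm - W)
}

# Wilks' lambda det(W)/det(T) on a variable subset, NA when singular
wilks_lambda <- function(X, g, vars = colnames(X)) {
  if (!length(vars)) return(1)
  s <- scatter_matrices(X[, vars, drop = FALSE], g)
  dw <- determinant(s$within, logarithm = TRUE)
  dt <- determinant(s$total, logarithm = TRUE)
  if (dw$sign <= 0 || dt$sign <= 0) return(NA_real_)
  exp(as.numeric(dw$modulus - dt$modulus))
}

#' Forward stepwise discriminant variable selection
#'
#' Greedy selection on the partial F derived from the reduction in Wilks'
#' lambda: at each step the candidate with the largest partial F enters if
#' its p-value is below `entry_alpha`; any selected variable whose partial F
#' p-value rises above `stay_alpha` is then removed. Iteration stops when no
#' variable enters or leaves. Candidates that make the within-group scatter
#' singular at a step are skipped with a warning.
#'
#' @param data Data frame holding the candidate columns and the grouping.
#' @param candidates Character vector of candidate column names.
#' @param grouping Factor (or column name in `data`) of class labels.
#' @param entry_alpha,stay_alpha Significance levels to enter and to stay
#'   (default 0.15 each, the conventional stepwise default).
#' @return Character vector of selected variables, in entry order, with a
#'   `steps` attribute tracing each action (variable, partial F, p).
#' @export
select_variables <- function(data, candidates, grouping,
                             entry_alpha = 0.15, stay_alpha = 0.15) {
  if (is.character(grouping) && length(grouping) == 1L)
    grouping <- data[[grouping]]
  g <- droplevels(as.factor(grouping))
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  stopifnot(all(candidates %in% names(data)))
  if (!(entry_alpha > 0 && entry_alpha < 1 && stay_alpha > 0 && stay_alpha < 1))
    stop("alphas must be in (0,1)", call. = FALSE)
  X <- data[, candidates, drop = FALSE]
  N <- nrow(X); k <- nlevels(g)

  partial_f <- function(l_full, l_base, p_in) {
    lp <- l_full / l_base
    df2 <- N - k - p_in
    if (df2 < 1 || !is.finite(lp) || lp <= 0) return(c(NA, NA))
    f <- (1 - lp) / lp * df2 / (k - 1)
    c(f, stats::pf(f, k - 1, df2, lower.tail = FALSE))
  }

  selected <- character(0)
  steps <- NULL
  repeat {
    changed <- FALSE
    # entry step
    l_base <- wilks_lambda(X, g, selected)
    pool <- setdiff(candidates, selected)
    best <- NULL
    for (v in pool) {
      l_full <- wilks_lambda(X, g, c(selected, v))
      if (is.na(l_full)) {
        warning("skipping '", v, "': singular within-group scatter",
                call. = FALSE)
        next
      }
      fp <- partial_f(l_full, l_base, length(selected))
      if (!is.na(fp[1]) && (is.null(best) || fp[1] > best$f))
        best <- list(v = v, f = fp[1], p = fp[2])
    }
    if (!is.null(best) && best$p < entry_alpha) {
      selected <- c(selected, best$v)
      steps <- rbind(steps, data.frame(action = "enter", variable = best$v,
                                       partial_f = best$f, p = best$p))
      changed <- TRUE
    }
    # removal step
    if (length(selected) > 1L) {
      repeat {
        worst <- NULL
        l_sel <- wilks_lambda(X, g, selected)
        for (v in selected) {
          l_red <- wilks_lambda(X, g, setdiff(selected, v))
          fp <- partial_f(l_sel, l_red, length(selected) - 1L)
          if (!is.na(fp[1]) && (is.null(worst) || fp[2] > worst$p))
            worst <- list(v = v, f = fp[1], p = fp[2])
        }
        if (is.null(worst) || worst$p <= stay_alpha) break
        selected <- setdiff(selected, worst$v)
        steps <- rbind(steps, data.frame(action = "remove", variable = worst$v,
                                         partial_f = worst$f, p = worst$p))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  attr(selected, "steps") <- steps
  selected
}

#' Fit a canonical discriminant model
#'
#' Solves the generalized eigenproblem of the between-group scatter against
#' the within-group scatter on the selected variables; the
#' `min(groups - 1, variables)` canonical roots maximize the between- to
#' within-group variance ratio. Raw coefficients are scaled so each
#' canonical variate has unit pooled within-group variance; standardized
#' coefficients multiply the raw ones by the pooled within-group standard
#' deviations. The sign of each root is fixed by making its first nonzero
#' coefficient positive. Per-root significance uses Bartlett's chi-squared
#' approximation for the residual roots.
#'
#' @param data Data frame (or `aa_cohort`) holding the variables.
#' @param variables Character vector of variable names; defaults to the 19
#'   amino acid keys when `data` is an `aa_cohort`.
#' @param grouping Class labels; defaults to `data$origin` when present.
#' @return An object of class `cda` with components `variables`, `levels`,
#'   `counts`, `means` (group means), `grand_mean`, `pooled_cov`,
#'   `coef_raw`, `coef_std`, `eigenvalues`, `canonical_r`, `cum_prop`,
#'   `p_values`, `centroids`, `scores`, `grouping`.
#' @seealso [predict.cda()], [loo_crossvalidate()], [select_variables()]
#' @export
#' @examples
#' d <- data.frame(x = c(0, 1, 3, 4), g = c("a", "a", "b", "b"))
#' fit <- fit_cda(d, "x", d$g)
#' fit$eigenvalues    # 9
#' fit$canonical_r    # 0.9487
fit_cda <- function(data, variables = NULL, grouping = NULL) {
  if (is.null(grouping) && "origin" %in% names(data)) grouping <- data$origin
  if (is.null(variables))
    variables <- if (inherits(data, "aa_cohort")) aa_keys() else
      stop("'variables' must be given for a plain data frame", call. = FALSE)
  g <- droplevels(as.factor(grouping))
  X <- as.matrix(as.data.frame(data)[, variables, drop = FALSE])
  storage.mode(X) <- "double"
  N <- nrow(X); p <- ncol(X); k <- nlevels(g)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  if (N <= p + k)
    stop("need more samples than variables + groups (N > p + g)", call. = FALSE)

  sc <- scatter_matrices(X, g)
  R <- tryCatch(chol(sc$within), error = function(e)
    stop("singular within-group scatter; reduce the variable set",
         call. = FALSE))
  # A = R^-T B R^-1 is symmetric with the same eigenvalues as W^-1 B
  Y <- backsolve(R, sc$between, transpose = TRUE)
  A <- backsolve(R, t(Y), transpose = TRUE)
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  s <- min(k - 1L, p)
  lambda <- pmax(e$values[seq_len(s)], 0)
  V <- backsolve(R, e$vectors[, seq_len(s), drop = FALSE]) * sqrt(N - k)
  # sign convention: first nonzero coefficient of each root positive
  for (j in seq_len(s)) {
    nz <- which(abs(V[, j]) > 1e-10)
    if (length(nz) && V[nz[1L], j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(variables, paste0("Root", seq_len(s)))

  pooled_cov <- sc$within / (N - k)
  coef_std <- V * sqrt(diag(pooled_cov))
  grand <- colMeans(X)
  scores <- sweep(X, 2, grand) %*% V
  centroids <- apply(scores, 2, function(col) tapply(col, g, mean))
  if (is.null(dim(centroids)))
    centroids <- matrix(centroids, ncol = 1,
                        dimnames = list(levels(g), colnames(V)))
  means <- apply(X, 2, function(col) tapply(col, g, mean))
  if (is.null(dim(means)))
    means <- matrix(means, ncol = 1, dimnames = list(levels(g), variables))

  # Bartlett chi-squared for roots j..s
  pv <- numeric(s)
  for (j in seq_len(s)) {
    chi <- (N - 1 - (p + k) / 2) * sum(log(1 + lambda[j:s]))
    df <- (p - j + 1) * (k - j)
    pv[j] <- stats::pchisq(chi, df, lower.tail = FALSE)
  }

  structure(list(variables = variables, levels = levels(g),
                 counts = stats::setNames(tabulate(g), levels(g)),
                 means = means, grand_mean = grand, pooled_cov = pooled_cov,
                 coef_raw = V, coef_std = coef_std, eigenvalues = lambda,
                 canonical_r = sqrt(lambda / (1 + lambda)),
                 cum_prop = if (sum(lambda) > 0) cumsum(lambda) / sum(lambda)
                            else rep(NA_real_, s),
                 p_values = pv, centroids = centroids, scores = scores,
                 grouping = g, call = match.call()),
            class = "cda")
}

#' @export
print.cda <- function(x, ...) {
  s <- length(x$eigenvalues)
  cat("Canonical discriminant analysis\n")
  cat("  groups:", paste(x$levels, collapse = ", "),
      " |  variables:", paste(x$variables, collapse = ", "), "\n")
  stat <- rbind(`Canonical R` = x$canonical_r,
                Eigenvalue = x$eigenvalues,
                `Cumulative proportion` = x$cum_prop,
                Probability = x$p_values)
  colnames(stat) <- paste0("Root", seq_len(s))
  print(round(stat, 4))
  invisible(x)
}

#' @export
summary.cda <- function(object, ...) {
  print(object)
  cat("\nStandardized canonical coefficients:\n")
  print(round(object$coef_std, 4))
  cat("\nGroup centroids (canonical space):\n")
  print(round(object$centroids, 4))
  invisible(object)
}

#' @export
#' @param standardized Return standardized instead of raw coefficients.
#' @rdname fit_cda
coef.cda <- function(object, standardized = FALSE, ...) {
  if (standardized) object$coef_std else object$coef_raw
}

#' Classify samples with a fitted canonical model
#'
#' Linear discriminant rule with pooled within-group covariance and equal
#' priors: each sample is assigned to the group whose mean minimizes the
#' Mahalanobis distance. Exact distance ties are broken deterministically
#' by group (level) order and flagged.
#'
#' @param object A fitted `cda`.
#' @param newdata Data frame or matrix containing the model's variables; by
#'   default the training data are classified.
#' @param ... Unused.
#' @return A factor of predicted groups with attributes `d2` (the n x g
#'   squared-distance matrix), `posterior` (equal-prior normal posteriors)
#'   and `tied` (logical, any exact tie).
#' @export
predict.cda <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    stop("supply 'newdata' (e.g. the training table) to classify", call. = FALSE)
  nd <- as.data.frame(newdata)
  missing <- setdiff(object$variables, names(nd))
  if (length(missing))
    stop("missing variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(nd[, object$variables, drop = FALSE])
  storage.mode(X) <- "double"
  Sinv <- solve(object$pooled_cov)
  d2 <- sapply(object$levels, function(lv) {
    stats::mahalanobis(X, object$means[lv, ], Sinv, inverted = TRUE)
  })
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1,
                                     dimnames = list(NULL, object$levels))
  idx <- apply(d2, 1, which.min)  # first minimum: deterministic level-order tie-break
  tied <- apply(d2, 1, function(r) sum(r == min(r)) > 1L)
  post <- exp(-sweep(d2, 1, apply(d2, 1, min)) / 2)
  post <- post / rowSums(post)
  structure(factor(object$levels[idx], levels = object$levels),
            d2 = d2, posterior = post, tied = tied)
}

#' Plot canonical scores
#'
#' Scatter of the first two canonical roots, coloured by group, with group
#' centroids marked.
#'
#' @param x A fitted `cda` with at least two roots.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cda <- function(x, ...) {
  if (ncol(x$scores) < 2L)
    stop("need at least two canonical roots to plot", call. = FALSE)
  cols <- seq_along(x$levels) + 1L
  graphics::plot(x$scores[, 1], x$scores[, 2],
                 col = cols[as.integer(x$grouping)],
                 pch = as.integer(x$grouping),
                 xlab = "Root 1", ylab = "Root 2", ...)
  graphics::points(x$centroids[, 1], x$centroids[, 2], pch = 8, cex = 1.6,
                   col = cols)
  graphics::legend("topright", legend = x$levels, col = cols,
                   pch = seq_along(x$levels), bty = "n")
  invisible(x)
}

#' Leave-one-out cross-validated classification
#'
#' For each sample in turn, the group means and pooled covariance are
#' recomputed without it (the variable set stays fixed) and the held-out
#' sample is classified with the equal-prior linear rule.
#'
#' @param data Data frame (or `aa_cohort`) with the variables.
#' @param variables Character vector of variable names.
#' @param grouping Class labels; defaults to `data$origin` when present.
#' @return A `classification_matrix`: list with `counts` (true x predicted),
#'   `row_pct`, `accuracy`, `predicted`.
#' @export
loo_crossvalidate <- function(data, variables, grouping = NULL) {
  if (is.null(grouping) && "origin" %in% names(data)) grouping <- data$origin
  g <- droplevels(as.factor(grouping))
  X <- as.matrix(as.data.frame(data)[, variables, drop = FALSE])
  storage.mode(X) <- "double"
  N <- nrow(X); k <- nlevels(g)
  if (any(tabulate(g) < 3L))
    stop("each group needs at least 3 samples for leave-one-out", call. = FALSE)
  pred <- character(N)
  for (i in seq_len(N)) {
    Xi <- X[-i, , drop = FALSE]; gi <- g[-i]
    mu <- apply(Xi, 2, function(col) tapply(col, gi, mean))
    if (is.null(dim(mu)))
      mu <- matrix(mu, ncol = 1, dimnames = list(levels(g), variables))
    W <- scatter_matrices(Xi, gi)$within
    Sp <- W / (nrow(Xi) - k)
    Sinv <- tryCatch(solve(Sp), error = function(e)
      stop("singular pooled covariance in fold ", i, call. = FALSE))
    d2 <- apply(mu, 1, function(m)
      stats::mahalanobis(X[i, , drop = FALSE], m, Sinv, inverted = TRUE))
    pred[i] <- levels(g)[which.min(d2)]
  }
  pred <- factor(pred, levels = levels(g))
  counts <- table(true = g, predicted = pred)
  row_pct <- prop.table(counts, 1) * 100
  structure(list(counts = unclass(counts), row_pct = unclass(row_pct),
                 accuracy = sum(diag(counts)) / N * 100, predicted = pred),
            class = "classification_matrix")
}

#' @export
print.classification_matrix <- function(x, ...) {
  cat("Leave-one-out classification matrix (counts, row %):\n")
  k <- nrow(x$counts)
  disp <- matrix(sprintf("%d (%.2f%%)", x$counts, x$row_pct), k,
                 dimnames = dimnames(x$counts))
  print(disp, quote = FALSE)
  cat(sprintf("Overall accuracy: %.2f%%\n", x$accuracy))
  invisible(x)
}

#' Candidate variable table for discriminant analysis
#'
#' The 19 per-sample amino acid concentrations (edible basis) plus the
#' derived total amino acid content (`TotalAA`, edible basis), the
#' candidate list used for origin discrimination.
#'
#' @param cohort An `aa_cohort`.
#' @return Data frame with `origin` plus the 20 candidate columns.
#' @export
cda_candidates <- function(cohort) {
  stopifnot(inherits(cohort, "aa_cohort"))
  out <- as.data.frame(cohort)[, c("origin", aa_keys())]
  out$TotalAA <- rowSums(as.data.frame(cohort)[, aa_keys()])
  out
}
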