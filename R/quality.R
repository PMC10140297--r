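# Protein quality scoring: AAS against the FAO/WHO adult pattern, limiting
# amino acids, EAAI (uncapped geometric mean) and quality grades.

# protein-basis concentrations for the nine scoring keys; MetCys is scored
# on methionine alone (cysteine unmeasured), PheTyr sums both.
score_concentrations <- function(cohort) {
  p <- convert_basis(cohort, "protein")
  cbind(His = p[, "His"], Ile = p[, "Ile"], Leu = p[, "Leu"],
        Lys = p[, "Lys"], MetCys = p[, "Met"],
        PheTyr = p[, "Phe"] + p[, "Tyr"],
        Thr = p[, "Thr"], Trp = p[, "Trp"], Val = p[, "Val"])
}

#' Amino acid score (AAS)
#'
#' Per scoring key, the protein-basis concentration relative to the
#' reference requirement, in percent:
#' `AAS = (g AA / 100 g protein) / requirement * 100`.
#'
#' @param cohort An `aa_cohort` (one or more samples).
#' @param pattern A [reference_pattern()].
#' @return A samples x 9 matrix of AAS values (percent), one row per
#'   sample; a single-row cohort yields a 1 x 9 matrix.
#' @export
#' @examples
#' compute_aas(fixture_mean_profiles())["Norway_mean", "His"]  # 84.1
compute_aas <- function(cohort, pattern = reference_pattern()) {
  conc <- score_concentrations(cohort)
  sweep(conc, 2, unclass(pattern)[colnames(conc)], "/") * 100
}

#' Limiting amino acids
#'
#' Scoring keys whose AAS falls below 100%, ordered from most to least
#' limiting (ascending AAS). Ties at the minimum are retained in stable key
#' order.
#'
#' @param aas A named numeric vector of AAS values (percent), e.g. one row
#'   of [compute_aas()].
#' @return A list with `laa` (named, ascending AAS, possibly empty) and
#'   `most_limiting` (key or `NA` if none).
#' @export
#' @examples
#' t3 <- builtin_fixture("table3")
#' find_laa(setNames(t3$Alaska, t3$score_key))
find_laa <- function(aas) {
  if (!length(aas) || is.null(names(aas)))
    stop("'aas' must be a non-empty named vector", call. = FALSE)
  lim <- aas[aas < 100]
  ord <- order(lim, seq_along(lim))  # stable on ties
  lim <- lim[ord]
  list(laa = lim,
       most_limiting = if (length(lim)) names(lim)[1L] else NA_character_)
}

#' Essential amino acid index (EAAI)
#'
#' Geometric mean of the nine scoring-key ratios to the reference pattern,
#' in percent: `EAAI = 100 * (prod r_i)^(1/9)`. Ratios are not capped at 1,
#' so an EAAI above 100 is possible when most keys exceed the pattern.
#'
#' @inheritParams compute_aas
#' @return Numeric vector of EAAI values (percent), one per sample.
#' @export
compute_eaai <- function(cohort, pattern = reference_pattern()) {
  aas <- compute_aas(cohort, pattern)
  apply(aas, 1, eaai_from_aas)
}

#' @rdname compute_eaai
#' @param aas Numeric vector of AAS values (percent) to aggregate directly.
#' @export
eaai_from_aas <- function(aas) {
  r <- aas / 100
  if (any(!is.finite(r)) || any(r <= 0))
    stop("EAAI needs all scoring ratios > 0", call. = FALSE)
  100 * exp(mean(log(r)))
}

#' Protein quality grade from the EAAI
#'
#' Bands (lower bound inclusive): `matching` for EAAI >= 100, `high` for
#' [95, 100), `good` for [86, 95), `useful` for [75, 86), `inadequate`
#' below 75.
#'
#' @param eaai EAAI in percent (vectorized), > 0.
#' @return Factor with levels matching/high/good/useful/inadequate.
#' @export
#' @examples
#' grade_protein(c(99.15, 77.32, 88.61))  # high, useful, good
grade_protein <- function(eaai) {
  if (any(!is.finite(eaai)) || any(eaai <= 0))
    stop("EAAI must be finite and > 0", call. = FALSE)
  cut(eaai, breaks = c(0, 75, 86, 95, 100, Inf),
      labels = c("inadequate", "useful", "good", "high", "matching"),
      right = FALSE)
}

#' Protein quality report
#'
#' Scores a cohort against a reference pattern and assembles AAS, limiting
#' amino acids, EAAI and quality grade. With `aggregate = "per_sample"`
#' (default, matching how group means with SEM are tabulated) AAS and EAAI
#' are computed per sample and arithmetically averaged; with
#' `"mean_profile"` the metrics are computed once on the mean concentration
#' profile, which reproduces worked arithmetic on printed group means.
#'
#' @inheritParams compute_aas
#' @param aggregate `"per_sample"` or `"mean_profile"`.
#' @return An object of class `quality_report`: list with `aas` (named
#'   vector, percent), `laa`, `most_limiting`, `eaai`, `grade`, `n`,
#'   `aggregate`.
#' @export
#' @examples
#' protein_quality(fixture_mean_profiles()[1, ])
protein_quality <- function(cohort, pattern = reference_pattern(),
                            aggregate = c("per_sample", "mean_profile")) {
  aggregate <- match.arg(aggregate)
  if (aggregate == "mean_profile" && nrow(cohort) > 1L) {
    mp <- cohort[1L, ]
    mp$sample_id <- "mean_profile"
    mp$tp <- mean(cohort$tp)
    for (k in aa_keys()) mp[[k]] <- mean(cohort[[k]])
    cohort <- as_aa_cohort(as.data.frame(mp)[, c("sample_id", "origin", "tp", aa_keys())])
  }
  aas_mat <- compute_aas(cohort, pattern)
  eaai_vec <- apply(aas_mat, 1, eaai_from_aas)
  aas <- colMeans(aas_mat)
  eaai <- mean(eaai_vec)
  lim <- find_laa(aas)
  out <- list(aas = aas, laa = lim$laa, most_limiting = lim$most_limiting,
              eaai = eaai, grade = as.character(grade_protein(eaai)),
              n = nrow(cohort), aggregate = aggregate)
  class(out) <- "quality_report"
  out
}

#' @export
print.quality_report <- function(x, digits = 4, ...) {
  cat("Protein quality report (", x$aggregate, ", n = ", x$n, ")\n", sep = "")
  cat("  AAS (%):\n")
  print(round(x$aas, 1))
  if (length(x$laa)) {
    cat("  Limiting amino acids (ascending AAS): ",
        paste(sprintf("%s (%.1f)", names(x$laa), x$laa), collapse = ", "),
        "\n", sep = "")
    cat("  Most limiting: ", x$most_limiting, "\n", sep = "")
  } else cat("  No limiting amino acids (all AAS >= 100)\n")
  cat(sprintf("  EAAI: %.2f%%  ->  grade: %s\n", x$eaai, x$grade))
  invisible(x)
}
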