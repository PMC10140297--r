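#' Convert amino acid concentrations between bases
#'
#' Concentrations are stored per 100 g of edible portion; the protein basis
#' expresses them per 100 g of protein via the sample's total protein:
#' `protein = edible / tp * 100`.
#'
#' @param cohort An `aa_cohort`.
#' @param target `"edible"` or `"protein"`.
#' @return A numeric matrix (samples x 19 amino acids) in the target basis,
#'   with sample ids as row names.
#' @export
#' @examples
#' prof <- fixture_mean_profiles()
#' convert_basis(prof, "protein")["Norway_mean", "Thr"]  # 5.9155
convert_basis <- function(cohort, target = c("edible", "protein")) {
  stopifnot(inherits(cohort, "aa_cohort"))
  target <- match.arg(target)
  m <- as.matrix(cohort[, aa_keys()])
  rownames(m) <- cohort$sample_id
  if (target == "protein") {
    if (any(cohort$tp <= 0)) stop("total protein must be > 0", call. = FALSE)
    m <- sweep(m, 1, cohort$tp, "/") * 100
  }
  m
}

#' Class partial sums
#'
#' Per-sample sums of the indispensable (IAA), conditionally indispensable
#' (CIAA) and dispensable (DAA) amino acid classes, plus the total (TAA),
#' in the requested basis.
#'
#' @inheritParams convert_basis
#' @param basis `"edible"` or `"protein"`.
#' @param scheme A class scheme, by default [aa_class_scheme()].
#' @return A data frame with columns `sample_id`, `origin`, `basis`, `taa`,
#'   `iaa`, `ciaa`, `daa`.
#' @export
#' @examples
#' partial_sums(fixture_mean_profiles())[, c("origin", "iaa", "daa")]
partial_sums <- function(cohort, basis = c("edible", "protein"),
                         scheme = aa_class_scheme()) {
  basis <- match.arg(basis)
  m <- convert_basis(cohort, basis)
  data.frame(sample_id = cohort$sample_id, origin = cohort$origin,
             basis = basis,
             taa  = rowSums(m),
             iaa  = rowSums(m[, scheme$iaa,  drop = FALSE]),
             ciaa = rowSums(m[, scheme$ciaa, drop = FALSE]),
             daa  = rowSums(m[, scheme$daa,  drop = FALSE]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Amino acid class ratios
#'
#' Dimensionless ratios IAA/TAA, DAA/TAA, CIAA/TAA and IAA/DAA, computed
#' from class partial sums. Ratios are basis-invariant.
#'
#' @param sums Output of [partial_sums()].
#' @return The input with four ratio columns appended.
#' @export
aa_ratios <- function(sums) {
  stopifnot(all(c("taa", "iaa", "ciaa", "daa") %in% names(sums)))
  if (any(sums$taa <= 0) || any(sums$daa <= 0))
    stop("ratios need TAA > 0 and DAA > 0", call. = FALSE)
  sums$iaa_taa  <- sums$iaa  / sums$taa
  sums$daa_taa  <- sums$daa  / sums$taa
  sums$ciaa_taa <- sums$ciaa / sums$taa
  sums$iaa_daa  <- sums$iaa  / sums$daa
  sums
}

#' Taste-active amino acid sums
#'
#' Per-sample sums over the sweet, bitter, acidic and umami groups, on the
#' edible-portion basis. The groups overlap (histidine is both bitter and
#' acidic) and omit some amino acids, so the four sums do not partition the
#' total.
#'
#' @inheritParams partial_sums
#' @return Data frame with columns `sample_id`, `origin`, `sweet`,
#'   `bitter`, `acidic`, `umami` (g/100 g edible portion).
#' @export
#' @examples
#' flavor_sums(fixture_mean_profiles())
flavor_sums <- function(cohort, scheme = aa_class_scheme()) {
  m <- convert_basis(cohort, "edible")
  data.frame(sample_id = cohort$sample_id, origin = cohort$origin,
             sweet  = rowSums(m[, scheme$sweet,  drop = FALSE]),
             bitter = rowSums(m[, scheme$bitter, drop = FALSE]),
             acidic = rowSums(m[, scheme$acidic, drop = FALSE]),
             umami  = rowSums(m[, scheme$umami,  drop = FALSE]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Superiority of one value over another
#'
#' The relative excess of the larger of two positive values over the
#' smaller, `(max - min) / min * 100`, in percent. Symmetric in argument
#' order and invariant under common rescaling.
#'
#' @param a,b Positive numeric values (vectorized).
#' @return Superiority in percent, always >= 0.
#' @export
#' @examples
#' superiority(1.18, 0.65)   # 81.5% (rounded)
superiority <- function(a, b) {
  if (any(pmin(a, b) <= 0))
    stop("superiority needs both values > 0", call. = FALSE)
  (pmax(a, b) - pmin(a, b)) / pmin(a, b) * 100
}

#' Full composition summary for a cohort
#'
#' Convenience wrapper assembling total amino acids, class sums, ratios and
#' flavour sums per sample.
#'
#' @inheritParams partial_sums
#' @return A data frame of class `composition_summary`.
#' @export
composition_summary <- function(cohort, basis = c("edible", "protein"),
                                scheme = aa_class_scheme()) {
  basis <- match.arg(basis)
  out <- aa_ratios(partial_sums(cohort, basis, scheme))
  fl <- flavor_sums(cohort, scheme)
  out <- cbind(out, fl[, c("sweet", "bitter", "acidic", "umami")])
  class(out) <- c("composition_summary", "data.frame")
  out
}
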