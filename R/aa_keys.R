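#' Amino acid keys and classification scheme
#'
#' The package works with the 19 amino acids quantified in dried salted cod
#' muscle, identified by their 3-letter keys. They partition into
#' indispensable (IAA), conditionally indispensable (CIAA) and dispensable
#' (DAA) classes, and overlap four taste-active groups (sweet, bitter,
#' acidic, umami).
#'
#' @format `aa_keys()` returns the character vector of the 19 keys, in class
#'   order (9 IAA, 4 CIAA, 6 DAA). `aa_class_scheme()` returns a list with
#'   elements `iaa`, `ciaa`, `daa`, `sweet`, `bitter`, `acidic`, `umami`.
#' @details Asparagine, glutamine and cysteine are not quantified in the
#'   underlying assay and are therefore absent from the key set; the acidic
#'   taste group consequently reduces to aspartate, glutamate and histidine.
#' @return See Format.
#' @export
#' @examples
#' aa_keys()
#' aa_class_scheme()$umami
aa_keys <- function() {
  c("His", "Ile", "Leu", "Lys", "Met", "Phe", "Thr", "Trp", "Val",
    "Arg", "Gly", "Pro", "Tyr",
    "Ala", "Asp", "Glu", "Hyp", "Orn", "Ser")
}

#' @rdname aa_keys
#' @export
aa_class_scheme <- function() {
  scheme <- list(
    iaa    = c("His", "Ile", "Leu", "Lys", "Met", "Phe", "Thr", "Trp", "Val"),
    ciaa   = c("Arg", "Gly", "Pro", "Tyr"),
    daa    = c("Ala", "Asp", "Glu", "Hyp", "Orn", "Ser"),
    sweet  = c("Ala", "Gly", "Hyp", "Pro", "Ser", "Thr"),
    bitter = c("Arg", "His", "Ile", "Leu", "Met", "Phe", "Trp", "Val"),
    acidic = c("Asp", "Glu", "His"),
    umami  = c("Asp", "Glu")
  )
  stopifnot(setequal(c(scheme$iaa, scheme$ciaa, scheme$daa), aa_keys()))
  scheme
}

#' FAO/WHO adult reference scoring pattern
#'
#' Requirement pattern for the nine scoring keys used by the amino acid
#' score (AAS) and the essential amino acid index (EAAI), in g of amino acid
#' per 100 g of protein. The default is the FAO/WHO pattern for adults.
#' Two scoring keys are composites: `MetCys` (methionine + cysteine; scored
#' on methionine alone here because cysteine is not quantified) and `PheTyr`
#' (phenylalanine + tyrosine).
#'
#' @param requirement Named numeric vector over the nine scoring keys
#'   (`His`, `Ile`, `Leu`, `Lys`, `MetCys`, `PheTyr`, `Thr`, `Trp`, `Val`),
#'   all values strictly positive. Defaults to the adult pattern.
#' @return A named numeric vector of class `reference_pattern`.
#' @export
#' @examples
#' reference_pattern()                    # FAO/WHO adult default
#' reference_pattern(c(His = 2, Ile = 3, Leu = 6.1, Lys = 4.8, MetCys = 2.3,
#'                     PheTyr = 4.1, Thr = 2.5, Trp = 0.67, Val = 4.0))
reference_pattern <- function(requirement = NULL) {
  default <- c(His = 1.6, Ile = 3, Leu = 6.1, Lys = 4.8, MetCys = 2.3,
               PheTyr = 4.1, Thr = 2.5, Trp = 0.67, Val = 4.0)
  if (is.null(requirement)) requirement <- default
  if (!is.numeric(requirement) || is.null(names(requirement)))
    stop("'requirement' must be a named numeric vector", call. = FALSE)
  if (!setequal(names(requirement), names(default)))
    stop("reference pattern must cover exactly the nine scoring keys: ",
         paste(names(default), collapse = ", "), call. = FALSE)
  requirement <- requirement[names(default)]
  if (any(!is.finite(requirement)) || any(requirement <= 0))
    stop("all reference requirements must be finite and > 0", call. = FALSE)
  structure(requirement, class = c("reference_pattern", "numeric"))
}

#' Read a reference pattern from a small key,value CSV
#'
#' @param path CSV file with columns `key` and `requirement`.
#' @return A `reference_pattern`.
#' @export
read_reference_pattern <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("key", "requirement") %in% names(tab)))
    stop("pattern file needs columns 'key' and 'requirement'", call. = FALSE)
  reference_pattern(stats::setNames(tab$requirement, tab$key))
}

# scoring keys in pattern order
score_keys <- function() names(reference_pattern())

#' Origins and species labels
#'
#' Samples are labelled by the Exclusive Economic Zone they were harvested
#' in. Species is derived from origin, never stored: Norway and Iceland are
#' Atlantic cod, Alaska is Pacific cod.
#'
#' @param origin Character or factor of origin labels.
#' @return `origin_levels()` the three origin labels; `species_of()` a factor
#'   of species labels (`Atlantic`/`Pacific`) parallel to `origin`.
#' @export
#' @examples
#' species_of(c("Norway", "Alaska"))
origin_levels <- function() c("Norway", "Iceland", "Alaska")

#' @rdname origin_levels
#' @export
species_of <- function(origin) {
  origin <- as.character(origin)
  bad <- setdiff(unique(origin), origin_levels())
  if (length(bad))
    stop("unknown origin label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  factor(ifelse(origin == "Alaska", "Pacific", "Atlantic"),
         levels = c("Atlantic", "Pacific"))
}
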