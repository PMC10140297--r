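#' Amino acid profile cohorts
#'
#' A cohort is a validated data frame with one row per specimen: a sample
#' id, an origin label, total protein (`tp`, g/100 g edible portion) and the
#' 19 amino acid concentrations (g/100 g edible portion). A derived
#' `species` column (Atlantic/Pacific) is attached from the origin. All
#' concentrations are stored on the edible-portion basis; use
#' [convert_basis()] for the protein basis.
#'
#' @param df A data frame with columns `sample_id`, `origin`, `tp` and the
#'   19 keys of [aa_keys()].
#' @return A data frame of class `aa_cohort`.
#' @export
#' @examples
#' prof <- data.frame(sample_id = "s1", origin = "Norway", tp = 31.95,
#'                    as.list(setNames(rep(1, 19), aa_keys())))
#' as_aa_cohort(prof)
as_aa_cohort <- function(df) {
  stopifnot(is.data.frame(df))
  needed <- c("sample_id", "origin", "tp", aa_keys())
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  extra <- intersect(names(df), aa_keys())
  if (!setequal(extra, aa_keys()))
    stop("profile key set must be exactly the 19 amino acid keys", call. = FALSE)

  df$sample_id <- as.character(df$sample_id)
  df$origin <- as.character(df$origin)
  bad_origin <- setdiff(unique(df$origin), origin_levels())
  if (length(bad_origin))
    stop("unknown origin label(s): ", paste(bad_origin, collapse = ", "),
         call. = FALSE)

  for (v in c("tp", aa_keys())) {
    df[[v]] <- as.numeric(df[[v]])
    if (any(!is.finite(df[[v]])))
      stop("non-numeric or missing value in column '", v, "'", call. = FALSE)
  }
  if (any(df$tp <= 0)) {
    i <- which(df$tp <= 0)[1L]
    stop("total protein must be > 0 (sample '", df$sample_id[i], "')",
         call. = FALSE)
  }
  for (k in aa_keys()) {
    if (any(df[[k]] < 0)) {
      i <- which(df[[k]] < 0)[1L]
      stop("negative concentration for '", k, "' (sample '",
           df$sample_id[i], "')", call. = FALSE)
    }
  }

  out <- df[, needed, drop = FALSE]
  out$species <- species_of(out$origin)
  out <- out[, c("sample_id", "origin", "species", "tp", aa_keys())]
  class(out) <- c("aa_cohort", "data.frame")
  out
}

#' Read amino acid profiles from CSV
#'
#' Reads a per-sample table (comma-separated, UTF-8, dot decimal, header
#' required) and returns a validated cohort. Column names default to
#' `sample_id`, `origin`, `tp` and the 3-letter amino acid keys; alternate
#' headers can be mapped with `schema`.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names (names) to the file's column names (values), e.g.
#'   `c(sample_id = "ID", tp = "protein")`. Unmapped columns keep the
#'   canonical names.
#' @return An `aa_cohort` with rows in file order.
#' @seealso [write_profiles()]
#' @export
read_profiles <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty input file: ", path, call. = FALSE)
  if (!is.null(schema)) {
    if (is.null(names(schema)))
      stop("'schema' must be a named character vector", call. = FALSE)
    for (canon in names(schema)) {
      col <- schema[[canon]]
      if (!col %in% names(raw))
        stop("schema column '", col, "' not found in file", call. = FALSE)
      names(raw)[names(raw) == col] <- canon
    }
  }
  as_aa_cohort(raw)
}

#' Write amino acid profiles to CSV
#'
#' Deterministic serialization: numeric values are written with full
#' precision (up to 15 significant digits), so a read/write round trip
#' preserves values to well below 1e-9.
#'
#' @param cohort An `aa_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(cohort, path) {
  stopifnot(inherits(cohort, "aa_cohort"))
  out <- cohort[, c("sample_id", "origin", "tp", aa_keys())]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 15, format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.aa_cohort <- function(x, ...) {
  cat("Amino acid cohort: ", nrow(x), " sample(s)\n", sep = "")
  tab <- table(factor(x$origin, levels = origin_levels()))
  cat("  per origin: ", paste(names(tab), tab, sep = " = ", collapse = ", "),
      "\n", sep = "")
  NextMethod()
  invisible(x)
}

#' Group-mean profiles from the packaged reference tables
#'
#' Builds one profile per origin from the packaged group means (amino acids
#' from the profile table, total protein from the composition table). These
#' "mean profiles" support worked-example arithmetic on printed means; they
#' are not per-sample data.
#'
#' @return An `aa_cohort` with three rows (Norway, Iceland, Alaska).
#' @export
#' @examples
#' fixture_mean_profiles()
fixture_mean_profiles <- function() {
  t1 <- builtin_fixture("table1")
  t2 <- builtin_fixture("table2")
  tp <- stats::setNames(
    unlist(t1[t1$variable == "TP", origin_levels()]), origin_levels())
  aa <- t2[t2$key %in% aa_keys(), ]
  prof <- data.frame(sample_id = paste0(origin_levels(), "_mean"),
                     origin = origin_levels(), tp = tp,
                     row.names = NULL)
  for (k in aa_keys())
    prof[[k]] <- unlist(aa[aa$key == k, origin_levels()])
  as_aa_cohort(prof)
}
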