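# Deterministic report serialization. Floats are rendered with 4
# significant decimals, so identical inputs give byte-identical files.

fmt_num <- function(x) {
  ifelse(is.na(x), "", formatC(signif(x, 4), format = "g", digits = 4))
}

#' Write an analysis result to disk
#'
#' Deterministic serialization of package results: a `quality_report`
#' becomes JSON (keys `aas`, `laa`, `most_limiting`, `eaai`, `grade`); a
#' `classification_matrix` becomes a CSV of counts with row percentages; a
#' data frame becomes CSV. Numbers are rendered with 4 significant
#' decimals; writing the same object twice produces identical bytes.
#'
#' @param results A result produced by this package.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) UseMethod("write_report")

#' @export
write_report.quality_report <- function(results, path) {
  obj <- list(aas = as.list(round(results$aas, 4)),
              laa = as.list(round(results$laa, 4)),
              most_limiting = results$most_limiting,
              eaai = round(results$eaai, 4),
              grade = results$grade)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             con, useBytes = TRUE)
  invisible(path)
}

#' @export
write_report.classification_matrix <- function(results, path) {
  k <- nrow(results$counts)
  cells <- matrix(sprintf("%d (%s%%)", results$counts, fmt_num(results$row_pct)),
                  k, dimnames = dimnames(results$counts))
  df <- data.frame(origin = rownames(cells), cells,
                   total = sprintf("%d (100%%)", rowSums(results$counts)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_report.data.frame(df, path)
}

#' @export
write_report.data.frame <- function(results, path) {
  out <- as.data.frame(results)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], fmt_num)
  lines <- c(paste(names(out), collapse = ","),
             apply(out, 1, paste, collapse = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' @export
write_report.composition_summary <- function(results, path) {
  write_report.data.frame(results, path)
}

#' @export
write_report.default <- function(results, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(results, auto_unbox = TRUE, digits = 8,
                              pretty = TRUE, force = TRUE),
             con, useBytes = TRUE)
  invisible(path)
}
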