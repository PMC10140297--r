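# Packaged group-mean tables (printed least-squares means, pooled SEM, and
# contrast p-values). p-values printed as upper bounds ("<x") carry the
# corresponding *_lt flag; cells that had to be repaired carry corrected =
# TRUE and a note. Values are stored exactly as printed otherwise.

#' Packaged group-mean reference tables
#'
#' Returns one of the three packaged tables of printed group means for the
#' dried salted cod study design (three origins, n = 15 per origin):
#' \describe{
#'   \item{`table1`}{Total protein and total amino acid content, class
#'     partial sums (protein basis), ratios and flavour sums, with pooled
#'     SEM and the two contrast p-values (Atlantic vs Pacific, Norway vs
#'     Iceland).}
#'   \item{`table2`}{Per-amino-acid profile (edible-portion basis), class
#'     subtotals and the per-sample EAAI row.}
#'   \item{`table3`}{Amino acid scores (AAS, %) for the nine scoring keys.}
#' }
#' Known misprints are repaired and flagged via the `corrected` column: the
#' Iceland CIAA subtotal (printed as a truncated "1") is replaced by the sum
#' of its printed components, 10.47; an A-vs-P p-value printed as an upper
#' bound "<0.021" is stored as 0.021 with `p_avsp_lt = TRUE`.
#'
#' @param name One of `"table1"`, `"table2"`, `"table3"`.
#' @return A data frame; means live in columns `Norway`, `Iceland`,
#'   `Alaska`, with `sem`, `p_avsp`, `p_nvsi` and logical flags
#'   `p_avsp_lt`, `p_nvsi_lt` (p printed as "<"), `corrected`.
#' @export
#' @examples
#' builtin_fixture("table2")[1:3, ]
builtin_fixture <- function(name = c("table1", "table2", "table3")) {
  name <- match.arg(name)
  switch(name,
         table1 = fixture_table1(),
         table2 = fixture_table2(),
         table3 = fixture_table3())
}

fx_row <- function(variable, basis, no, ic, al, sem, pa, pa_lt, pn, pn_lt,
                   corrected = FALSE, note = "") {
  data.frame(variable = variable, basis = basis, Norway = no, Iceland = ic,
             Alaska = al, sem = sem, p_avsp = pa, p_avsp_lt = pa_lt,
             p_nvsi = pn, p_nvsi_lt = pn_lt, corrected = corrected,
             note = note, stringsAsFactors = FALSE)
}

fixture_table1 <- function() {
  rows <- rbind(
    fx_row("TP",       "edible",  31.95, 35.85, 33.10, 1.17,  0.017, FALSE, 0.324, FALSE),
    fx_row("TAA",      "edible",  30.32, 34.71, 32.04, 1.13,  0.015, FALSE, 0.288, FALSE),
    fx_row("sum_TAA",  "protein", 96.91, 96.81, 96.61, 0.11,  0.021, TRUE,  0.012, FALSE,
           TRUE, "A-vs-P p printed as '<0.021'; stored as 0.021 upper bound"),
    fx_row("sum_IAA",  "protein", 35.38, 28.90, 32.83, 0.76,  0.001, TRUE,  0.042, FALSE),
    fx_row("sum_CIAA", "protein", 25.58, 29.19, 27.04, 0.92,  0.011, FALSE, 0.207, FALSE),
    fx_row("sum_DAA",  "protein", 36.05, 38.67, 36.74, 0.69,  0.009, FALSE, 0.423, FALSE),
    fx_row("IAA/TAA",  "ratio",    0.37,  0.30,  0.34, 0.008, 0.001, TRUE,  0.036, FALSE),
    fx_row("DAA/TAA",  "ratio",    0.37,  0.40,  0.38, 0.007, 0.013, FALSE, 0.470, FALSE),
    fx_row("CIAA/TAA", "ratio",    0.26,  0.30,  0.28, 0.01,  0.013, FALSE, 0.222, FALSE),
    fx_row("IAA/DAA",  "ratio",    0.98,  0.75,  0.89, 0.03,  0.001, TRUE,  0.066, FALSE),
    fx_row("bitter",   "edible",  10.40, 12.00, 10.05, 0.42,  0.001, FALSE, 0.558, FALSE,
           TRUE, "Norway cell printed with stray '+/- SEM'; mean and SEM stored separately"),
    fx_row("sweet",    "edible",   8.88, 10.79, 11.74, 0.50,  0.437, FALSE, 0.001, TRUE,
           TRUE, "Norway cell printed with stray '+/- SEM'; mean and SEM stored separately"),
    fx_row("acidic",   "edible",   7.60,  9.12,  7.98, 0.27,  0.001, TRUE,  0.324, FALSE,
           TRUE, "Norway cell printed with stray '+/- SEM'; mean and SEM stored separately"),
    fx_row("umami",    "edible",   7.17,  8.49,  7.49, 0.24,  0.001, TRUE,  0.358, FALSE,
           TRUE, "Norway cell printed with stray '+/- SEM'; mean and SEM stored separately")
  )
  rows
}

fixture_table2 <- function() {
  fx2 <- function(key, class, no, ic, al, sem, pa, pa_lt, pn, pn_lt,
                  corrected = FALSE, note = "") {
    data.frame(key = key, class = class, Norway = no, Iceland = ic,
               Alaska = al, sem = sem, p_avsp = pa, p_avsp_lt = pa_lt,
               p_nvsi = pn, p_nvsi_lt = pn_lt, corrected = corrected,
               note = note, stringsAsFactors = FALSE)
  }
  rbind(
    fx2("His", "IAA",  0.43, 0.63, 0.49, 0.03,  0.001, TRUE,  0.196, FALSE),
    fx2("Ile", "IAA",  0.72, 0.74, 0.61, 0.03,  0.009, FALSE, 0.018, FALSE),
    fx2("Leu", "IAA",  2.58, 2.43, 2.43, 0.12,  0.600, FALSE, 0.394, FALSE),
    fx2("Lys", "IAA",  2.33, 1.58, 1.61, 0.22,  0.156, FALSE, 0.024, FALSE),
    fx2("Met", "IAA",  0.50, 0.38, 0.47, 0.02,  0.001, TRUE,  0.263, FALSE),
    fx2("Phe", "IAA",  0.90, 0.81, 0.80, 0.04,  0.329, FALSE, 0.060, FALSE),
    fx2("Thr", "IAA",  1.89, 2.52, 2.96, 0.18,  0.673, FALSE, 0.001, TRUE),
    fx2("Trp", "IAA",  0.76, 0.53, 0.65, 0.14,  0.306, FALSE, 0.568, FALSE),
    fx2("Val", "IAA",  0.90, 0.73, 0.85, 0.04,  0.002, FALSE, 0.260, FALSE),
    fx2("sum_IAA", "IAA", 11.01, 10.39, 10.88, 0.45, 0.318, FALSE, 0.833, FALSE),
    fx2("Arg", "CIAA", 3.60, 5.71, 3.74, 0.33,  0.001, TRUE,  0.771, FALSE),
    fx2("Gly", "CIAA", 2.47, 2.49, 3.49, 0.18,  0.028, FALSE, 0.001, TRUE),
    fx2("Pro", "CIAA", 0.50, 0.55, 0.81, 0.05,  0.075, FALSE, 0.001, TRUE),
    fx2("Tyr", "CIAA", 1.43, 1.72, 1.01, 0.12,  0.002, FALSE, 0.023, FALSE),
    fx2("sum_CIAA", "CIAA", 8.01, 10.47, 9.05, 0.48, 0.002, FALSE, 0.132, FALSE,
        TRUE, "Iceland cell printed as truncated '1'; replaced by component sum 10.47"),
    fx2("Ala", "DAA",  1.87, 2.82, 1.68, 0.14,  0.001, TRUE,  0.342, FALSE),
    fx2("Asp", "DAA",  2.96, 3.79, 2.98, 0.12,  0.001, TRUE,  0.917, FALSE),
    fx2("Glu", "DAA",  4.21, 4.70, 4.51, 0.14,  0.055, FALSE, 0.144, FALSE),
    fx2("Hyp", "DAA",  0.70, 0.60, 1.18, 0.10,  0.010, FALSE, 0.002, FALSE),
    fx2("Orn", "DAA",  0.12, 0.12, 0.16, 0.002, 0.001, TRUE,  0.001, TRUE),
    fx2("Ser", "DAA",  1.44, 1.81, 1.61, 0.07,  0.001, FALSE, 0.090, FALSE),
    fx2("sum_DAA", "DAA", 11.30, 13.84, 12.11, 0.43, 0.001, TRUE, 0.185, FALSE),
    fx2("EAAI", "index", 99.15, 77.32, 88.61, 2.02, 0.001, TRUE, 0.001, TRUE)
  )
}

fixture_table3 <- function() {
  fx3 <- function(key, no, ic, al, sem, pa, pa_lt, pn, pn_lt) {
    data.frame(score_key = key, Norway = no, Iceland = ic, Alaska = al,
               sem = sem, p_avsp = pa, p_avsp_lt = pa_lt, p_nvsi = pn,
               p_nvsi_lt = pn_lt, corrected = FALSE, stringsAsFactors = FALSE)
  }
  rbind(
    fx3("His",    84.67, 109.2,  92.34, 3.71,  0.001, TRUE,  0.151, FALSE),
    fx3("Ile",    76.17, 72.15,  61.40, 2.05,  0.188, FALSE, 0.001, TRUE),
    fx3("Leu",    134.6, 110.8,  120.9, 4.21,  0.002, FALSE, 0.027, FALSE),
    fx3("Lys",    155.6, 60.93,  100.3, 12.7,  0.022, FALSE, 0.004, FALSE),
    fx3("MetCys", 69.23, 46.74,  61.96, 1.75,  0.001, TRUE,  0.005, FALSE),
    fx3("PheTyr", 181.2, 172.3,  133.3, 8.63,  0.161, FALSE, 0.001, TRUE),
    fx3("Thr",    238.4, 279.5,  354.0, 16.4,  0.411, FALSE, 0.001, TRUE),
    fx3("Trp",    37.17, 23.32,  31.01, 6.40,  0.177, FALSE, 0.499, FALSE),
    fx3("Val",    71.98, 51.27,  64.25, 2.27,  0.001, TRUE,  0.021, FALSE)
  )
}
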