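# fixtures built in code

# single profile with given overrides; all other amino acids at `fill`
make_profile <- function(sample_id = "s1", origin = "Norway", tp = 20,
                         fill = 1, ...) {
  aa <- stats::setNames(rep(fill, 19), aa_keys())
  over <- list(...)
  aa[names(over)] <- unlist(over)
  as_aa_cohort(data.frame(sample_id = sample_id, origin = origin, tp = tp,
                          as.list(aa)))
}

# small well-separated 3-group cohort in the full 19-variable space
make_separated_cohort <- function(n = 6, gap = 8, sd = 0.3, seed = 11) {
  set.seed(seed)
  rows <- NULL
  for (oi in seq_along(origin_levels())) {
    o <- origin_levels()[oi]
    base <- 5 + gap * oi
    m <- matrix(abs(stats::rnorm(n * 19, base, sd)), n, 19,
                dimnames = list(NULL, aa_keys()))
    rows <- rbind(rows, data.frame(sample_id = paste0(o, seq_len(n)),
                                   origin = o, tp = 30, m))
  }
  as_aa_cohort(rows)
}

# profile whose protein-basis scoring vector equals the reference pattern
pattern_profile <- function(tp = 50) {
  req <- reference_pattern()
  make_profile(tp = tp, fill = 0.5,
               His = req[["His"]] * tp / 100, Ile = req[["Ile"]] * tp / 100,
               Leu = req[["Leu"]] * tp / 100, Lys = req[["Lys"]] * tp / 100,
               Met = req[["MetCys"]] * tp / 100,
               Phe = req[["PheTyr"]] * tp / 100, Tyr = 0,
               Thr = req[["Thr"]] * tp / 100, Trp = req[["Trp"]] * tp / 100,
               Val = req[["Val"]] * tp / 100)
}
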